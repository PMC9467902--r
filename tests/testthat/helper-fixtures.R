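# Shared fixtures: small deterministic objects rebuilt in code at test time.

# default 12-interval schedule
fixSchedule <- function() buildSchedule(30, 60, 240, 480)

# fast-decay kinetics whose terminal tail is clean within the 480-min window
fixFastKinetics <- function() tissueKinetics("fast", 25, 0.048, 0.012)

# the worked spec-style example curve
fixExampleKinetics <- function() tissueKinetics("example", 30, 0.02, 0.005)

# noise-free, no-dropout study config (nAnimals kept small for speed)
fixCleanConfig <- function(nAnimals = 2L, seed = 1L)
  defaultStudyConfig(nAnimals = nAnimals, pMalfunction = 0, pDisplaced = 0,
                     seed = seed)

# simulate the noise-free, RR = 100 study used by oracle-equivalence tests
fixCleanStudy <- function(nAnimals = 2L, seed = 1L)
  simulateStudy(fixCleanConfig(nAnimals, seed), noise = noiselessModel(),
                fixedRR = 100)

# random positive concentration profile on the default midpoints
fixRandomProfile <- function(n = 12L) {
  t <- sort(sample(seq(15, 450, by = 15), n))
  list(times = t, concs = stats::rlnorm(n, meanlog = 1, sdlog = 1))
}
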