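# Shared fixtures, built in code and memoized across test files.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# minimal valid atom table; override columns via ...
makeAtoms <- function(n, ...) {
  df <- data.frame(
    serial = seq_len(n), name = rep("X", n), beadType = rep("BAS", n),
    partner = rep("DENDRIMER", n), residueIndex = seq_len(n),
    qProt = 0, qDeprot = 0, ljSigma = 3, ljEpsilon = 0.1, radius = 2,
    isPhosphate = FALSE, isMajorGroove = FALSE, isMinorGroove = FALSE,
    isTitratable = FALSE, isTerminalBp = FALSE, isCentralBp = FALSE,
    isHydrophobic = FALSE, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

emptySites <- function() {
  data.frame(siteId = integer(), group = character(),
             atomSerial = integer(), pkaIntrinsic = numeric())
}

boundEnsemble <- function(ph = 7, nf = 40, seed = 101, rep = 1L)
  memo(sprintf("bound_%g_%d_%d_%d", ph, nf, seed, rep),
       sampleEnsemble(nFrames = nf, ph = ph, bound = TRUE, seed = seed,
                      replicateId = rep))

apoEnsemble <- function(ph = 7, nf = 40, seed = 101, rep = 1L)
  memo(sprintf("apo_%g_%d_%d_%d", ph, nf, seed, rep),
       sampleEnsemble(nFrames = nf, ph = ph, bound = FALSE, seed = seed,
                      replicateId = rep))

# pH-grid ensembles for titration analyses (shared by several files)
phGridEnsembles <- function(bound, variant = "MH18", reps = 3, nf = 40,
                            seed = 11) {
  memo(sprintf("grid_%d_%s_%d_%d_%d", bound, variant, reps, nf, seed), {
    grid <- seq(4, 9.5, by = 0.5)
    do.call(c, lapply(grid, function(p)
      lapply(seq_len(reps), function(r)
        sampleEnsemble(dend = DendrimerSpec(variant), nFrames = nf,
                       ph = p, bound = bound, seed = seed,
                       replicateId = r))))
  })
}

# golden-spiral directions, used to build occluding cages in fixtures
.cage <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}
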