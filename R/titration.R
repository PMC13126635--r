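#' Construct a coupled-site titration model
#'
#' @param pkaIntrinsic Per-site intrinsic pKa values.
#' @param coupling Symmetric site-site interaction matrix (kcal/mol, paid
#'   when both sites are protonated); defaults to no coupling.
#' @param field Per-site environment term (kcal/mol when protonated;
#'   negative stabilizes the protonated form); defaults to zero.
#' @param temperature Kelvin.
#' @return A [TitrationModel-class].
#' @export
TitrationModel <- function(pkaIntrinsic, coupling = NULL, field = NULL,
                           temperature = 310) {
  n <- length(pkaIntrinsic)
  if (is.null(coupling)) coupling <- matrix(0, n, n)
  if (is.null(field)) field <- rep(0, n)
  new("TitrationModel", pkaIntrinsic = as.numeric(pkaIntrinsic),
      coupling = coupling, field = as.numeric(field),
      temperature = temperature)
}

.siteEnergies <- function(model, ph) {
  rt <- .RGAS * model@temperature
  .LN10 * rt * (ph - model@pkaIntrinsic) + model@field
}

#' Metropolis sampling of coupled protonation states at fixed pH
#'
#' Single-site Metropolis flips over the microstate energy of the
#' [TitrationModel-class]. One cycle attempts `n_sites` flips. The first
#' `n_cycles / 10` cycles are discarded as burn-in; the returned
#' occupancies are averaged over the recorded cycles and the final state
#' of the last cycle is reported separately (the state a constant-pH MD
#' cycle would adopt).
#'
#' @param model A [TitrationModel-class].
#' @param ph pH value.
#' @param nCycles Number of MC cycles (>= 1).
#' @param seed Optional integer seed; when NULL the current RNG state is
#'   used (and advanced).
#' @param initialState Optional starting occupancy vector.
#' @return list with `finalState`, `meanOccupancy`, `seOccupancy` (batch
#'   means Monte Carlo standard error) and `nRecorded`.
#' @export
sampleStates <- function(model, ph, nCycles = 1000L, seed = NULL,
                         initialState = NULL) {
  stopifnot(nCycles >= 1)
  n <- length(model@pkaIntrinsic)
  if (is.null(initialState)) initialState <- rep(1L, n)
  stopifnot(length(initialState) == n)
  a <- .siteEnergies(model, ph)
  rt <- .RGAS * model@temperature
  run <- function() cpp_sample_states(a, model@coupling, rt,
                                      as.integer(nCycles),
                                      as.integer(nCycles %/% 10L),
                                      as.integer(initialState))
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(finalState = res$final_state, meanOccupancy = res$mean_occupancy,
       seOccupancy = res$se_occupancy, nRecorded = res$n_recorded)
}

#' Exact per-site occupancies by Boltzmann enumeration
#'
#' Enumerates all 2^N protonation microstates (N <= 20) and returns the
#' exact thermal average occupancy of each site. Serves as the
#' verification oracle for [sampleStates()].
#'
#' @inheritParams sampleStates
#' @return Numeric vector of per-site mean occupancies.
#' @export
exactOccupancies <- function(model, ph) {
  n <- length(model@pkaIntrinsic)
  if (n > 20) stop("size error: exact enumeration requires n_sites <= 20")
  if (n == 0) return(numeric(0))
  a <- .siteEnergies(model, ph)
  rt <- .RGAS * model@temperature
  cpp_exact_occupancies(a, model@coupling, rt)
}

#' Henderson-Hasselbalch occupancy
#'
#' Single-site closed form `1 / (1 + 10^(ph - pka))`, the zero-coupling
#' limit of the titration model.
#'
#' @param ph pH value(s).
#' @param pka Site pKa.
#' @return Protonated fraction.
#' @export
hendersonHasselbalch <- function(ph, pka) 1 / (1 + 10^(ph - pka))
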