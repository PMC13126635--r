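## Group titration curves, Hill fits and conditional apparent pKa values.

#' Build a group titration curve from ensembles over a pH grid
#'
#' Pools post-burn-in occupancies of all sites in `group` (sites treated
#' as replicates of each other), across all ensembles, into one curve
#' over the distinct pH values present. With `context` "PHOS" or "GROOVE"
#' the pooling is restricted, frame by frame, to the site-frames whose
#' groove-assignment context matches, mirroring the ensemble-average
#' reading of phosphate- and groove-conditional pKa values.
#'
#' @param ensembles List of [ComplexEnsemble-class] objects (one per
#'   replicate and pH; must share the bound flag).
#' @param group Site group ("G3_NTR", "G3_SIDE" or "G2").
#' @param context "ALL", "PHOS" or "GROOVE".
#' @param burnInFraction Fraction of initial frames discarded (default
#'   1/3, the equilibration convention).
#' @param phosCutoff,grooveCutoff Context cutoffs, Angstrom.
#' @return A [TitrationCurve-class]. pH points where the context subset
#'   is empty carry NA and a warning is raised (a flagged gap, never a
#'   silent zero).
#' @export
buildTitrationCurve <- function(ensembles, group = "G3_NTR",
                                context = c("ALL", "PHOS", "GROOVE"),
                                burnInFraction = 1 / 3, phosCutoff = 4,
                                grooveCutoff = 6) {
  context <- match.arg(context)
  stopifnot(length(ensembles) >= 1)
  boundFlags <- vapply(ensembles, isBound, logical(1))
  if (length(unique(boundFlags)) != 1)
    stop("ensembles must share the bound/apo flag")
  phs <- sort(unique(vapply(ensembles, pH, numeric(1))))
  reps <- sort(unique(vapply(ensembles, replicateId, integer(1))))

  sums <- matrix(0, length(reps), length(phs))
  counts <- matrix(0, length(reps), length(phs))
  for (ens in ensembles) {
    iPh <- match(pH(ens), phs)
    iRep <- match(replicateId(ens), reps)
    s <- sites(ens)
    sel <- which(s$group == group)
    if (!length(sel)) next
    keep <- .postBurnIn(nFrames(ens), burnInFraction)
    occ <- occupancy(ens)
    if (context == "ALL") {
      sums[iRep, iPh] <- sums[iRep, iPh] + sum(occ[keep, sel])
      counts[iRep, iPh] <- counts[iRep, iPh] + length(keep) * length(sel)
    } else {
      a <- atoms(ens)
      for (f in keep) {
        ga <- assignGrooves(getFrame(ens, f), a, s, phosCutoff,
                            grooveCutoff)
        use <- sel[ga$context[sel] == context]
        if (length(use)) {
          sums[iRep, iPh] <- sums[iRep, iPh] + sum(occ[f, use])
          counts[iRep, iPh] <- counts[iRep, iPh] + length(use)
        }
      }
    }
  }
  perRep <- ifelse(counts > 0, sums / counts, NA_real_)
  pooledCounts <- colSums(counts)
  pooled <- ifelse(pooledCounts > 0, colSums(sums) / pooledCounts,
                   NA_real_)
  if (anyNA(pooled))
    warning("empty ", context, " subset at pH ",
            paste(phs[is.na(pooled)], collapse = ", "),
            "; flagged as gap")
  dimnames(perRep) <- list(replicate = reps, ph = phs)
  new("TitrationCurve", ph = phs, occupancy = as.numeric(pooled),
      perReplicate = perRep, group = group, context = context,
      bound = boundFlags[1])
}

.hillFitCore <- function(ph, occ, weights = NULL) {
  ok <- is.finite(ph) & is.finite(occ)
  ph <- ph[ok]; occ <- occ[ok]
  if (!is.null(weights)) weights <- weights[ok]
  fail <- function(msg) new("HillFit", pka = NA_real_, n = NA_real_,
                            sePka = NA_real_, seN = NA_real_,
                            converged = FALSE, diagnostics = msg)
  if (length(unique(ph)) < 3)
    return(fail("fewer than 3 distinct pH points"))
  if (diff(range(occ)) < 1e-6)
    return(fail("degenerate curve: occupancies all equal"))
  pka0 <- ph[which.min(abs(occ - 0.5))]
  dat <- data.frame(ph = ph, occ = occ)
  args <- list(occ ~ 1 / (1 + 10^(n * (ph - pka))), data = dat,
               start = list(pka = pka0, n = 1), lower = c(0, 1e-3),
               upper = c(14, 4),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
                  error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear least squares did not converge"))
  co <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    c(pka = NA_real_, n = NA_real_))
  if (co[["n"]] <= 1e-3 + 1e-9)
    return(fail("Hill coefficient collapsed to the lower bound"))
  new("HillFit", pka = unname(co[["pka"]]), n = unname(co[["n"]]),
      sePka = unname(se[["pka"]]), seN = unname(se[["n"]]),
      converged = TRUE, diagnostics = "ok")
}

#' Fit the Hill equation to a titration curve
#'
#' Fits \eqn{f(pH) = 1 / (1 + 10^{n (pH - pKa)})} by nonlinear least
#' squares (Levenberg-Marquardt; start at the pH of half-occupancy with
#' n = 1; bounds n in (0, 4\], pKa in \[0, 14\]). Standard errors come
#' from the fit covariance. Non-convergence and degenerate inputs yield
#' `converged = FALSE` with diagnostics, never fabricated values.
#'
#' @param x A [TitrationCurve-class], or a numeric vector of pH values.
#' @param occ Occupancies when `x` is numeric.
#' @param ... Unused.
#' @return A [HillFit-class].
#' @export
setMethod("hillFit", "TitrationCurve", function(x, ...) {
  .hillFitCore(x@ph, x@occupancy)
})

#' @rdname hillFit-TitrationCurve-method
#' @export
setMethod("hillFit", "numeric", function(x, occ, ...) {
  .hillFitCore(x, occ)
})

.replicatePkaSem <- function(curve) {
  fits <- apply(curve@perReplicate, 1, function(row)
    .hillFitCore(curve@ph, row))
  pk <- vapply(fits, function(f) if (f@converged) f@pka else NA_real_,
               numeric(1))
  nn <- vapply(fits, function(f) if (f@converged) f@n else NA_real_,
               numeric(1))
  sem <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
  }
  c(pka = sem(pk), n = sem(nn))
}

#' Apparent and context-conditional pKa table
#'
#' For one dendrimer variant: Hill fits of the group titration curve in
#' the apo and bound states, plus phosphate- and groove-conditional fits
#' of the bound state. Central values come from pooled fits; the errors
#' are standard errors of the mean over per-replicate fits.
#'
#' @param apoEnsembles,boundEnsembles Lists of [ComplexEnsemble-class]
#'   objects spanning the pH grid (and replicates).
#' @param group Site group analysed (default the N-termini).
#' @param variant Label for the output row.
#' @param burnInFraction,phosCutoff,grooveCutoff Passed to
#'   [buildTitrationCurve()].
#' @return One-row data.frame: system, pKaApo, nApo, pKaBound, nBound,
#'   pKaPhos, pKaGroove and their errors.
#' @export
conditionalPkaTable <- function(apoEnsembles, boundEnsembles,
                                group = "G3_NTR", variant = "MH18",
                                burnInFraction = 1 / 3, phosCutoff = 4,
                                grooveCutoff = 6) {
  cApo <- buildTitrationCurve(apoEnsembles, group, "ALL", burnInFraction)
  cBound <- buildTitrationCurve(boundEnsembles, group, "ALL",
                                burnInFraction, phosCutoff, grooveCutoff)
  cPhos <- suppressWarnings(
    buildTitrationCurve(boundEnsembles, group, "PHOS", burnInFraction,
                        phosCutoff, grooveCutoff))
  cGroove <- suppressWarnings(
    buildTitrationCurve(boundEnsembles, group, "GROOVE", burnInFraction,
                        phosCutoff, grooveCutoff))
  fits <- lapply(list(cApo, cBound, cPhos, cGroove), hillFit)
  sems <- lapply(list(cApo, cBound, cPhos, cGroove), .replicatePkaSem)
  get <- function(i, what) {
    f <- fits[[i]]
    if (!f@converged) NA_real_ else slot(f, what)
  }
  data.frame(
    system = variant,
    pKaApo = get(1, "pka"), pKaApoErr = sems[[1]][["pka"]],
    nApo = get(1, "n"), nApoErr = sems[[1]][["n"]],
    pKaBound = get(2, "pka"), pKaBoundErr = sems[[2]][["pka"]],
    nBound = get(2, "n"), nBoundErr = sems[[2]][["n"]],
    pKaPhos = get(3, "pka"), pKaPhosErr = sems[[3]][["pka"]],
    pKaGroove = get(4, "pka"), pKaGrooveErr = sems[[4]][["pka"]],
    stringsAsFactors = FALSE)
}
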