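## Conditional free-energy landscapes over (signed groove distance,
## phosphate distance): 2D Gaussian kernel density -> E = -RT ln(P/Pmax).

#' 2D Gaussian kernel density on a regular grid
#'
#' Product-Gaussian kernel density estimate. Bandwidth defaults to
#' Scott's rule per axis (sigma * n^(-1/6)) with a 0.25 Angstrom floor;
#' the grid spans the observed range padded by `padding` on each side
#' with spacing `gridSpacing`. The density integrates to ~1 over a grid
#' covering the samples plus a few bandwidths.
#'
#' @param x,y Sample coordinates (>= 10 samples).
#' @param bandwidth Numeric length-2 kernel standard deviations; NULL for
#'   Scott's rule with the 0.25 A floor.
#' @param gridSpacing Grid spacing, Angstrom.
#' @param padding Range padding, Angstrom.
#' @return list with `x`, `y` (grid centers), `z` (density matrix, rows
#'   index x) and `bandwidth`.
#' @export
kdeDensity <- function(x, y, bandwidth = NULL, gridSpacing = 0.1,
                       padding = 3) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  if (is.null(bandwidth)) {
    n <- length(x)
    raw <- c(sd(x), sd(y)) * n^(-1 / 6)
    if (any(!is.finite(raw) | raw < 0.25))
      warning("degenerate or tight sample cloud; bandwidth floor applied")
    raw[!is.finite(raw)] <- 0
    bandwidth <- pmax(0.25, raw)
  }
  bandwidth <- rep_len(bandwidth, 2)
  lims <- c(range(x) + c(-1, 1) * padding, range(y) + c(-1, 1) * padding)
  nx <- max(2L, ceiling(diff(lims[1:2]) / gridSpacing) + 1L)
  ny <- max(2L, ceiling(diff(lims[3:4]) / gridSpacing) + 1L)
  ## MASS parameterizes the kernel scale as 4 x the Gaussian sd
  d <- MASS::kde2d(x, y, h = 4 * bandwidth, n = c(nx, ny), lims = lims)
  list(x = d$x, y = d$y, z = d$z, bandwidth = bandwidth)
}

#' Conditional free-energy surface from a density grid
#'
#' \eqn{E(r) = -RT \ln(P(r)/P_{max})}: zero at the density maximum,
#' positive elsewhere; cells where the density underflows to zero are
#' masked (NA), never reported as zero energy.
#'
#' @param density Output of [kdeDensity()] (or any list with x, y, z).
#' @param temperature Kelvin (default 310).
#' @return An [EnergyLandscape-class].
#' @export
energySurface <- function(density, temperature = 310) {
  z <- density$z
  if (!any(z > 0)) stop("all-zero density")
  pMax <- max(z)
  rt <- .RGAS * temperature
  e <- matrix(NA_real_, nrow(z), ncol(z))
  pos <- z > 0
  e[pos] <- -rt * log(z[pos] / pMax)
  bw <- if (is.null(density$bandwidth)) c(NA_real_, NA_real_)
        else density$bandwidth
  new("EnergyLandscape", x = density$x, y = density$y, density = z,
      energy = e, pMax = pMax, temperature = temperature, bandwidth = bw)
}

#' Per-site, per-frame groove/phosphate coordinates with protonation
#'
#' For each site of `group` in each post-burn-in frame of each bound
#' ensemble: the signed groove distance (positive = closer to the major
#' groove), the phosphate distance, and the site's protonation state.
#'
#' @param ensembles List of bound [ComplexEnsemble-class] objects.
#' @param group Site group.
#' @param burnInFraction Fraction of initial frames discarded.
#' @return data.frame with ph, replicate, frame, siteId, signedGroove,
#'   phosphateDistance, occupancy.
#' @export
protonationScatter <- function(ensembles, group = "G3_NTR",
                               burnInFraction = 1 / 3) {
  rows <- lapply(ensembles, function(ens) {
    stopifnot(isBound(ens))
    a <- atoms(ens)
    s <- sites(ens)
    sel <- which(s$group == group)
    keep <- .postBurnIn(nFrames(ens), burnInFraction)
    occ <- occupancy(ens)
    do.call(rbind, lapply(keep, function(f) {
      ga <- assignGrooves(getFrame(ens, f), a, s)
      data.frame(ph = pH(ens), replicate = replicateId(ens),
                 frame = f - 1L, siteId = s$siteId[sel],
                 signedGroove = ga$signedDistance[sel],
                 phosphateDistance = ga$phosphateDistance[sel],
                 occupancy = occ[f, sel])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conditional free-energy landscape from bound ensembles
#'
#' Convenience wrapper: [protonationScatter()] coordinates ->
#' [kdeDensity()] -> [energySurface()].
#'
#' @inheritParams protonationScatter
#' @param temperature Kelvin.
#' @param ... Passed to [kdeDensity()].
#' @return An [EnergyLandscape-class].
#' @export
landscapeFromEnsembles <- function(ensembles, group = "G3_NTR",
                                   burnInFraction = 1 / 3,
                                   temperature = 310, ...) {
  sc <- protonationScatter(ensembles, group, burnInFraction)
  energySurface(kdeDensity(sc$signedGroove, sc$phosphateDistance, ...),
                temperature)
}

#' Write an energy landscape grid as TSV
#'
#' Long format with columns x, y, E; masked cells serialize as empty
#' fields, never as zero.
#'
#' @param landscape An [EnergyLandscape-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeLandscapeTsv <- function(landscape, path) {
  grid <- expand.grid(x = landscape@x, y = landscape@y,
                      KEEP.OUT.ATTRS = FALSE)
  grid$E <- as.vector(landscape@energy)
  write.table(grid, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}
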