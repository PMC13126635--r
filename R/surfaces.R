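## Shrake-Rupley solvent-accessible surface areas, phosphate shielding and
## interface area on the bead models.

## deterministic quasi-uniform sphere points (golden-spiral construction)
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point SASA with a deterministic golden-spiral point set: for
#' each atom, test points on the sphere of radius `r_atom + probe` are
#' counted as exposed when outside every other atom's probe-expanded
#' sphere. Occluders are the atoms in `context` (defaults to the same
#' atoms as `subset`); restricting `subset` gives the area of a group
#' within a larger structure.
#'
#' @param frame Coordinate matrix.
#' @param atoms Atom table (radii taken from the `radius` column).
#' @param subset Logical/integer index of atoms whose area is reported.
#' @param context Logical/integer index of occluding atoms.
#' @param probe Probe radius, Angstrom (default 1.4).
#' @param nPoints Test points per atom (default 960).
#' @return list with `perAtom` (Angstrom^2, aligned with `subset`),
#'   `total`, `probe`, `nPoints`.
#' @export
sasa <- function(frame, atoms, subset = seq_len(nrow(atoms)),
                 context = subset, probe = 1.4, nPoints = 960L) {
  idx <- seq_len(nrow(atoms))[subset]
  ctx <- seq_len(nrow(atoms))[context]
  stopifnot(all(atoms$radius > 0))
  pts <- .spherePoints(nPoints)
  rads <- atoms$radius + probe
  cxyz <- frame[ctx, , drop = FALSE]
  crad2 <- rads[ctx]^2
  perAtom <- vapply(idx, function(i) {
    ri <- rads[i]
    ## candidate occluders within reach of atom i's expanded sphere
    d2 <- rowSums(sweep(cxyz, 2, frame[i, ])^2)
    near <- which(d2 < (ri + sqrt(crad2))^2 & ctx != i)
    if (!length(near)) return(4 * pi * ri^2)
    testPts <- sweep(pts * ri, 2, frame[i, ], "+")
    exposed <- rep(TRUE, nPoints)
    for (j in near) {
      dj2 <- rowSums(sweep(testPts, 2, cxyz[j, ])^2)
      exposed <- exposed & dj2 > crad2[j]
      if (!any(exposed)) break
    }
    4 * pi * ri^2 * mean(exposed)
  }, numeric(1))
  list(perAtom = perAtom, total = sum(perAtom), probe = probe,
       nPoints = nPoints)
}

#' Electrostatic shielding of the duplex phosphates
#'
#' Percentage of the phosphate SASA (computed within the RNA alone) that
#' is covered when the dendrimer is present:
#' `100 * (1 - SASA_phos(complex) / SASA_phos(RNA alone))`, clamped to
#' \[0, 100\].
#'
#' @inheritParams sasa
#' @return Shielding percentage.
#' @export
shielding <- function(frame, atoms, probe = 1.4, nPoints = 960L) {
  phos <- which(atoms$isPhosphate)
  if (!length(phos)) stop("no phosphates present")
  rna <- which(atoms$partner != "DENDRIMER")
  all_ <- seq_len(nrow(atoms))
  iso <- sasa(frame, atoms, subset = phos, context = rna, probe = probe,
              nPoints = nPoints)$total
  if (iso <= 0)
    stop("undefined shielding: isolated phosphate SASA is zero")
  cov <- sasa(frame, atoms, subset = phos, context = all_, probe = probe,
              nPoints = nPoints)$total
  min(100, max(0, 100 * (1 - cov / iso)))
}

#' Dendrimer-RNA interface area
#'
#' Buried-surface convention:
#' `(SASA_dend + SASA_rna - SASA_complex) / 2`.
#'
#' @inheritParams sasa
#' @return Interface area in Angstrom^2 (>= 0 up to point-sampling noise).
#' @export
interfaceArea <- function(frame, atoms, probe = 1.4, nPoints = 960L) {
  dend <- which(atoms$partner == "DENDRIMER")
  rna <- which(atoms$partner != "DENDRIMER")
  if (!length(dend) || !length(rna))
    stop("both partners must be present")
  all_ <- seq_len(nrow(atoms))
  sd_ <- sasa(frame, atoms, subset = dend, context = dend, probe = probe,
              nPoints = nPoints)$total
  sr <- sasa(frame, atoms, subset = rna, context = rna, probe = probe,
             nPoints = nPoints)$total
  sc <- sasa(frame, atoms, subset = all_, context = all_, probe = probe,
             nPoints = nPoints)$total
  (sd_ + sr - sc) / 2
}

#' Per-frame surface table for an ensemble
#'
#' @param ensemble A bound [ComplexEnsemble-class].
#' @param burnInFraction Fraction of initial frames discarded.
#' @param probe,nPoints SASA parameters.
#' @return data.frame with frame, shieldingPct, interfaceA2.
#' @export
surfacesTable <- function(ensemble, burnInFraction = 0, probe = 1.4,
                          nPoints = 960L) {
  stopifnot(isBound(ensemble))
  keep <- .postBurnIn(nFrames(ensemble), burnInFraction)
  a <- atoms(ensemble)
  rows <- lapply(keep, function(f) {
    xyz <- getFrame(ensemble, f)
    data.frame(frame = f - 1L,
               shieldingPct = shielding(xyz, a, probe, nPoints),
               interfaceA2 = interfaceArea(xyz, a, probe, nPoints))
  })
  do.call(rbind, rows)
}
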