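## Per-frame geometric statistics: duplex position, bending, groove
## assignment, amine-phosphate contacts, radius of gyration, RMSD, charge.
## All functions operate on a coordinate matrix plus the atom table, so
## they apply equally to generated and file-loaded ensembles.

.duplexEnds <- function(frame, atoms) {
  term <- atoms$isTerminalBp
  if (!any(term)) stop("no TERMINAL_BP atoms present")
  bp <- atoms$residueIndex[term]
  lo <- min(bp); hi <- max(bp)
  if (lo == hi) stop("geometry error: only one terminal base pair flagged")
  end0 <- colMeans(frame[term & atoms$residueIndex == lo, , drop = FALSE])
  end1 <- colMeans(frame[term & atoms$residueIndex == hi, , drop = FALSE])
  if (sqrt(sum((end0 - end1)^2)) < 1e-6)
    stop("geometry error: coincident duplex ends")
  list(end0 = end0, end1 = end1)
}

#' Dendrimer position along the duplex (0-100)
#'
#' Distance from the dendrimer geometric center to the closest duplex end,
#' projected onto the end-to-end axis through the cosine of the angle at
#' that end, then expressed on a global 0-100 coordinate anchored at the
#' end containing the RNA_A 5' terminus (base pair 1). Projections beyond
#' the ends give values below 0 or above 100.
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param atoms Atom table with TERMINAL_BP flags and dendrimer atoms.
#' @return Position percentage (may fall outside 0-100).
#' @export
positionAlongDuplex <- function(frame, atoms) {
  ends <- .duplexEnds(frame, atoms)
  dend <- frame[atoms$partner == "DENDRIMER", , drop = FALSE]
  if (!nrow(dend)) stop("no dendrimer atoms present")
  ctr <- colMeans(dend)
  L <- sqrt(sum((ends$end1 - ends$end0)^2))
  d0 <- sqrt(sum((ctr - ends$end0)^2))
  d1 <- sqrt(sum((ctr - ends$end1)^2))
  if (d0 <= d1) {
    if (d0 < 1e-9) return(0)
    cosang <- sum((ctr - ends$end0) * (ends$end1 - ends$end0)) / (d0 * L)
    100 * (d0 * cosang) / L
  } else {
    if (d1 < 1e-9) return(100)
    cosang <- sum((ctr - ends$end1) * (ends$end0 - ends$end1)) / (d1 * L)
    100 * (1 - (d1 * cosang) / L)
  }
}

#' Duplex bending angle
#'
#' Angle at the geometric center of the CENTRAL_BP set between the
#' geometric centers of the two TERMINAL_BP sets; 180 degrees for a
#' straight helix.
#'
#' @inheritParams positionAlongDuplex
#' @return Angle in degrees, in (0, 180].
#' @export
bendingAngle <- function(frame, atoms) {
  ends <- .duplexEnds(frame, atoms)
  cen <- atoms$isCentralBp
  if (!any(cen)) stop("no CENTRAL_BP atoms present")
  ctr <- colMeans(frame[cen, , drop = FALSE])
  v1 <- ends$end0 - ctr
  v2 <- ends$end1 - ctr
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9)
    stop("geometry error: degenerate bending arm")
  cosang <- sum(v1 * v2) / (n1 * n2)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Assign titratable sites to grooves and interaction contexts
#'
#' For each site, the minimum distance to the major and minor groove
#' marker sets decides the groove (ties go to MAJOR); the signed distance
#' is positive towards the major groove and negative towards the minor
#' groove. Context is PHOS when the site is within `phosCutoff` of any
#' phosphate (phosphate contact takes precedence), else GROOVE when the
#' assigned groove distance is within `grooveCutoff`, else FREE.
#'
#' @inheritParams positionAlongDuplex
#' @param sitesDf Site table.
#' @param phosCutoff Phosphate contact cutoff, Angstrom (default 4).
#' @param grooveCutoff Groove contact cutoff, Angstrom (default 6).
#' @return data.frame with siteId, group, groove, signedDistance,
#'   phosphateDistance, context.
#' @export
assignGrooves <- function(frame, atoms, sitesDf, phosCutoff = 4,
                          grooveCutoff = 6) {
  majXyz <- frame[atoms$isMajorGroove, , drop = FALSE]
  minXyz <- frame[atoms$isMinorGroove, , drop = FALSE]
  if (!nrow(majXyz) || !nrow(minXyz))
    stop("both groove marker sets must be non-empty")
  phosXyz <- frame[atoms$isPhosphate, , drop = FALSE]
  sXyz <- frame[match(sitesDf$atomSerial, atoms$serial), , drop = FALSE]
  dMaj <- apply(.crossDist(sXyz, majXyz), 1, min)
  dMin <- apply(.crossDist(sXyz, minXyz), 1, min)
  dPhos <- if (nrow(phosXyz))
    apply(.crossDist(sXyz, phosXyz), 1, min) else rep(Inf, nrow(sXyz))
  major <- dMaj <= dMin
  signedDistance <- ifelse(major, dMaj, -dMin)
  context <- ifelse(dPhos <= phosCutoff, "PHOS",
                    ifelse(abs(signedDistance) <= grooveCutoff,
                           "GROOVE", "FREE"))
  data.frame(siteId = sitesDf$siteId, group = sitesDf$group,
             groove = ifelse(major, "MAJOR", "MINOR"),
             signedDistance = signedDistance, phosphateDistance = dPhos,
             context = context, stringsAsFactors = FALSE)
}

#' Count amine-phosphate contacts
#'
#' Number of (titratable amine, phosphate) pairs within `cutoff`.
#'
#' @inheritParams assignGrooves
#' @param cutoff Contact cutoff, Angstrom.
#' @return Integer pair count (0 for apo frames).
#' @export
countPhosphateContacts <- function(frame, atoms, sitesDf, cutoff = 4) {
  phosXyz <- frame[atoms$isPhosphate, , drop = FALSE]
  if (!nrow(phosXyz)) return(0L)
  sXyz <- frame[match(sitesDf$atomSerial, atoms$serial), , drop = FALSE]
  if (!nrow(sXyz)) return(0L)
  sum(.crossDist(sXyz, phosXyz) <= cutoff)
}

#' Radius of gyration of a selection
#'
#' Unweighted: sqrt of the mean squared distance to the centroid.
#'
#' @param frame Coordinate matrix.
#' @param selection Logical or integer index of atoms.
#' @return Rg in Angstrom.
#' @export
radiusOfGyration <- function(frame, selection) {
  xyz <- frame[selection, , drop = FALSE]
  if (!nrow(xyz)) stop("empty selection")
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' RMSD after least-squares superposition
#'
#' @param frame Coordinate matrix to fit.
#' @param reference Reference coordinate matrix.
#' @param selection Logical or integer index of atoms used both for the
#'   fit and the RMSD.
#' @return RMSD in Angstrom.
#' @export
superposedRmsd <- function(frame, reference, selection) {
  a <- frame[selection, , drop = FALSE]
  b <- reference[selection, , drop = FALSE]
  if (!nrow(a)) stop("empty selection")
  if (nrow(a) == 1) return(0)
  if (nrow(a) == 2) {
    ## two points superpose up to the difference of their separations
    da <- sqrt(sum((a[1, ] - a[2, ])^2))
    db <- sqrt(sum((b[1, ] - b[2, ])^2))
    return(abs(da - db) / 2)
  }
  bio3d::rmsd(as.vector(t(b)), as.vector(t(a)), fit = TRUE)
}

#' Total charge of a selection given a protonation state
#'
#' Sum of deprotonated-state partial charges plus one elementary charge
#' per protonated site in the selection (phosphates contribute -1 e).
#'
#' @param occRow Binary occupancy vector over sites.
#' @param atoms Atom table.
#' @param sitesDf Site table.
#' @param selection Logical or integer atom index (default: all atoms).
#' @return Charge in e.
#' @export
totalCharge <- function(occRow, atoms, sitesDf,
                        selection = seq_len(nrow(atoms))) {
  idx <- seq_len(nrow(atoms))[selection]
  base <- sum(atoms$qDeprot[idx])
  siteAtom <- match(sitesDf$atomSerial, atoms$serial)
  inSel <- siteAtom %in% idx
  base + sum(occRow[inSel])
}

#' Per-frame geometry table for an ensemble
#'
#' @param ensemble A [ComplexEnsemble-class].
#' @param burnInFraction Fraction of initial frames discarded.
#' @param phosCutoff,grooveCutoff Context cutoffs, Angstrom.
#' @return data.frame with frame, positionPct, bendDeg, nContacts, rg,
#'   charge, rmsd (position/bend are NA for apo ensembles; rmsd is to the
#'   first retained frame over dendrimer atoms).
#' @export
geometryTable <- function(ensemble, burnInFraction = 0, phosCutoff = 4,
                          grooveCutoff = 6) {
  keep <- .postBurnIn(nFrames(ensemble), burnInFraction)
  a <- atoms(ensemble)
  s <- sites(ensemble)
  dendSel <- a$partner == "DENDRIMER"
  ref <- getFrame(ensemble, keep[1])
  rows <- lapply(keep, function(f) {
    xyz <- getFrame(ensemble, f)
    data.frame(
      frame = f - 1L,
      positionPct = if (isBound(ensemble))
        positionAlongDuplex(xyz, a) else NA_real_,
      bendDeg = if (isBound(ensemble)) bendingAngle(xyz, a) else NA_real_,
      nContacts = countPhosphateContacts(xyz, a, s, phosCutoff),
      rg = radiusOfGyration(xyz, dendSel),
      charge = totalCharge(occupancy(ensemble)[f, ], a, s, dendSel),
      rmsd = superposedRmsd(xyz, ref, dendSel))
  })
  do.call(rbind, rows)
}

.postBurnIn <- function(n, burnInFraction) {
  stopifnot(burnInFraction >= 0, burnInFraction < 1)
  start <- floor(n * burnInFraction) + 1L
  seq.int(start, n)
}
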