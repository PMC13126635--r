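## Synthetic stand-in for constant-pH MD ensembles of dendrimer-duplex
## complexes: a rigid idealized A-form-like 21-bp duplex scaffold with
## phosphate pseudo-atoms and groove marker sets, a branched bead-tree
## dendrimer with titratable amines (G3-NTR / G3-side / G2), heterogeneous
## contact-forming placement along the duplex, and per-frame protonation
## sampled from the coupled-site titration model with a screened-Coulomb
## environment field from the RNA phosphates.

#' Duplex geometry specification
#'
#' @slot nBp Number of base pairs.
#' @slot rise Helical rise per bp, Angstrom.
#' @slot twist Helical twist per bp, degrees.
#' @slot phosphateRadius Radial distance of phosphate pseudo-atoms from the
#'   helix axis, Angstrom.
#' @slot groovePhaseMajor,groovePhaseMinor Angular offsets (degrees, from
#'   the strand-A backbone angle) of the major/minor groove marker sets.
#' @slot centralWindow Number of central base pairs flagged CENTRAL_BP.
#' @export
setClass("DuplexSpec",
  representation(nBp = "integer", rise = "numeric", twist = "numeric",
                 phosphateRadius = "numeric", groovePhaseMajor = "numeric",
                 groovePhaseMinor = "numeric", centralWindow = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nBp < 5L) msg <- c(msg, "nBp must be >= 5")
    if (object@rise <= 0) msg <- c(msg, "rise must be positive")
    if (object@twist <= 0 || object@twist >= 360)
      msg <- c(msg, "twist must be in (0, 360)")
    if (object@centralWindow < 1L || object@centralWindow > object@nBp)
      msg <- c(msg, "centralWindow must be in [1, nBp]")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

#' @rdname DuplexSpec-class
#' @param nBp,rise,twist,phosphateRadius,groovePhaseMajor,groovePhaseMinor,centralWindow
#'   See slot documentation. Defaults are representative A-form values.
#' @return A `DuplexSpec`.
#' @export
DuplexSpec <- function(nBp = 21L, rise = 2.81, twist = 32.7,
                       phosphateRadius = 8.8, groovePhaseMajor = 257,
                       groovePhaseMinor = 77,
                       centralWindow = min(7L, as.integer(nBp))) {
  new("DuplexSpec", nBp = as.integer(nBp), rise = rise, twist = twist,
      phosphateRadius = phosphateRadius, groovePhaseMajor = groovePhaseMajor,
      groovePhaseMinor = groovePhaseMinor,
      centralWindow = as.integer(centralWindow))
}

#' Dendrimer topology specification
#'
#' Third-generation lysine/leucine peptide dendrimer bead model: a
#' hydrophobic core tail, two G1 branches, four G2 branches and eight G3
#' arms, with titratable amines at the 8 N-termini (G3_NTR), the 8
#' third-generation lysine side chains (G3_SIDE) and the second-generation
#' lysine side chains (G2). The MH47 variant replaces the four G2 lysines
#' by hydrophobic beads. Chirality variants (DMH18, MH18D3) are
#' topologically identical bead models.
#'
#' @slot variant One of MH18, DMH18, MH18D3, MH47.
#' @slot nG2Lys Number of G2 lysine amines (0 for MH47, else 4).
#' @slot nG3Side Number of G3 side-chain amines (8).
#' @slot nNtr Number of N-termini (8).
#' @slot nHydrophobic Total hydrophobic beads.
#' @slot bondLength Bead-bead bond length, Angstrom.
#' @export
setClass("DendrimerSpec",
  representation(variant = "character", nG2Lys = "integer",
                 nG3Side = "integer", nNtr = "integer",
                 nHydrophobic = "integer", bondLength = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@variant %in% c("MH18", "DMH18", "MH18D3", "MH47"))
      msg <- c(msg, "unknown variant")
    if (object@variant == "MH47") {
      if (object@nG2Lys != 0L) msg <- c(msg, "MH47 must have nG2Lys = 0")
      if (object@nHydrophobic <= 4L)
        msg <- c(msg, "MH47 must have a larger hydrophobic bead count")
    } else if (object@nG2Lys != 4L) {
      msg <- c(msg, "non-MH47 variants must have nG2Lys = 4")
    }
    if (object@bondLength <= 0) msg <- c(msg, "bondLength must be positive")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

#' @rdname DendrimerSpec-class
#' @param variant Dendrimer sequence variant.
#' @param bondLength Bead spacing, Angstrom.
#' @return A `DendrimerSpec`.
#' @export
DendrimerSpec <- function(variant = "MH18", bondLength = 3.8) {
  g2 <- if (variant == "MH47") 0L else 4L
  new("DendrimerSpec", variant = variant, nG2Lys = g2, nG3Side = 8L,
      nNtr = 8L, nHydrophobic = 4L + (4L - g2), bondLength = bondLength)
}

#' Dendrimer placement model
#'
#' @slot targetPositionPct Target position along the duplex, 0-100.
#' @slot approachDistance Initial radial clearance from the phosphate
#'   shell, Angstrom.
#' @slot jitterSigma Gaussian jitter of the placement, Angstrom.
#' @slot seed Seed stored with the model (informational).
#' @export
setClass("PlacementModel",
  representation(targetPositionPct = "numeric", approachDistance = "numeric",
                 jitterSigma = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@jitterSigma < 0) "jitterSigma must be >= 0" else TRUE
  })

#' @rdname PlacementModel-class
#' @param targetPositionPct,approachDistance,jitterSigma,seed See slots.
#' @return A `PlacementModel`.
#' @export
PlacementModel <- function(targetPositionPct = 50, approachDistance = 4,
                           jitterSigma = 3, seed = 1L) {
  new("PlacementModel", targetPositionPct = targetPositionPct,
      approachDistance = approachDistance, jitterSigma = jitterSigma,
      seed = as.integer(seed))
}

.unit <- function(v) v / sqrt(sum(v^2))

.atomRow <- function(serial, name, beadType, partner, residueIndex, params,
                     isPhosphate = FALSE, isMajorGroove = FALSE,
                     isMinorGroove = FALSE, isTitratable = FALSE,
                     isTerminalBp = FALSE, isCentralBp = FALSE,
                     isHydrophobic = FALSE) {
  b <- params$beads[[beadType]]
  data.frame(serial = as.integer(serial), name = name, beadType = beadType,
             partner = partner, residueIndex = as.integer(residueIndex),
             qProt = b$q_prot, qDeprot = b$q_deprot, ljSigma = b$lj_sigma,
             ljEpsilon = b$lj_epsilon, radius = b$radius,
             isPhosphate = isPhosphate, isMajorGroove = isMajorGroove,
             isMinorGroove = isMinorGroove, isTitratable = isTitratable,
             isTerminalBp = isTerminalBp, isCentralBp = isCentralBp,
             isHydrophobic = isHydrophobic, stringsAsFactors = FALSE)
}

## Angular separation of the strand-B backbone from strand A at the same
## base pair (degrees); the groove phase defaults bisect the two gaps.
.STRAND_GAP <- 154

#' Build the idealized duplex scaffold
#'
#' Two antiparallel phosphate helices on a common axis (one phosphate
#' pseudo-atom per nucleotide except each 5' terminus, so `2 nBp - 2`
#' phosphates carrying -1 e each), base-pair pseudo-atoms near the axis
#' (carrying the TERMINAL_BP / CENTRAL_BP flags), and major/minor groove
#' marker sets at fixed phase offsets between the strands. The helix axis
#' is z, running from z = 0 (base pair 1, the RNA_A 5' end) to
#' z = (nBp - 1) * rise.
#'
#' @param spec A [DuplexSpec-class].
#' @param params Bead parameters from [readBeadParams()].
#' @return list with `atoms` (data.frame) and `coords` (matrix, Angstrom).
#' @export
buildDuplex <- function(spec, params = readBeadParams()) {
  n <- spec@nBp
  rise <- spec@rise
  rad <- spec@phosphateRadius
  grooveRad <- 0.75 * rad
  baseRad <- 2.0
  thetaA <- (seq_len(n) - 1) * spec@twist * pi / 180
  thetaB <- thetaA + .STRAND_GAP * pi / 180
  z <- (seq_len(n) - 1) * rise
  cw0 <- floor((n - spec@centralWindow) / 2) + 1L
  central <- seq(cw0, cw0 + spec@centralWindow - 1L)

  rows <- list()
  coords <- list()
  serial <- 0L
  add <- function(row, xyz) {
    rows[[length(rows) + 1L]] <<- row
    coords[[length(coords) + 1L]] <<- xyz
  }
  for (i in seq_len(n)) {
    term <- i == 1L || i == n
    cent <- i %in% central
    ## base-pair pseudo-atoms, one per strand, diametrically opposed so
    ## their centroid sits exactly on the axis
    serial <- serial + 1L
    add(.atomRow(serial, "C1A", "BAS", "RNA_A", i, params,
                 isTerminalBp = term, isCentralBp = cent),
        c(baseRad * cos(thetaA[i]), baseRad * sin(thetaA[i]), z[i]))
    serial <- serial + 1L
    add(.atomRow(serial, "C1B", "BAS", "RNA_B", i, params,
                 isTerminalBp = term, isCentralBp = cent),
        c(baseRad * cos(thetaA[i] + pi), baseRad * sin(thetaA[i] + pi), z[i]))
    ## phosphates: strand A 5' end is bp 1, strand B 5' end is bp n
    if (i > 1L) {
      serial <- serial + 1L
      add(.atomRow(serial, "P", "PHO", "RNA_A", i, params,
                   isPhosphate = TRUE),
          c(rad * cos(thetaA[i]), rad * sin(thetaA[i]), z[i]))
    }
    if (i < n) {
      serial <- serial + 1L
      add(.atomRow(serial, "P", "PHO", "RNA_B", i, params,
                   isPhosphate = TRUE),
          c(rad * cos(thetaB[i]), rad * sin(thetaB[i]), z[i]))
    }
    ## groove markers between the strands
    aMaj <- thetaA[i] + spec@groovePhaseMajor * pi / 180
    aMin <- thetaA[i] + spec@groovePhaseMinor * pi / 180
    serial <- serial + 1L
    add(.atomRow(serial, "MAJ", "MAJ", "RNA_A", i, params,
                 isMajorGroove = TRUE),
        c(grooveRad * cos(aMaj), grooveRad * sin(aMaj), z[i]))
    serial <- serial + 1L
    add(.atomRow(serial, "MIN", "MIN", "RNA_B", i, params,
                 isMinorGroove = TRUE),
        c(grooveRad * cos(aMin), grooveRad * sin(aMin), z[i]))
  }
  list(atoms = do.call(rbind, rows), coords = do.call(rbind, coords))
}

#' Build the dendrimer bead tree
#'
#' Branched tree: hydrophobic core tail, 2 G1 backbone beads, 4 G2, 8 G3
#' arms; titratable amines at the 8 N-termini (G3_NTR, intrinsic pKa from
#' the parameter file, ~7.5), 8 G3 side chains and `nG2Lys` G2 side chains
#' (lysine amines, intrinsic pKa ~10.4). MH47 carries hydrophobic beads in
#' place of its G2 amines. Every bonded bead pair is exactly `bondLength`
#' apart.
#'
#' @param spec A [DendrimerSpec-class].
#' @param params Bead parameters.
#' @return list with `atoms`, `coords`, `sites` (data.frame) and `bonds`
#'   (two-column index matrix).
#' @export
buildDendrimer <- function(spec, params = readBeadParams()) {
  bl <- spec@bondLength
  rows <- list(); coords <- list(); bonds <- list()
  siteRows <- list()
  serial <- 0L
  add <- function(name, beadType, xyz, parent = NA_integer_, ...) {
    serial <<- serial + 1L
    rows[[serial]] <<- .atomRow(serial, name, beadType, "DENDRIMER",
                                serial, params, ...)
    coords[[serial]] <<- xyz
    if (!is.na(parent))
      bonds[[length(bonds) + 1L]] <<- c(parent, serial)
    serial
  }
  ntail <- spec@nHydrophobic - (4L - spec@nG2Lys)
  core <- add("COR", "HYD", c(0, 0, 0), isHydrophobic = TRUE)
  prev <- core
  for (t in seq_len(ntail - 1L))
    prev <- add("TAL", "HYD", c(0, 0, -t * bl), parent = prev,
                isHydrophobic = TRUE)

  g2Lys <- spec@nG2Lys
  g2Count <- 0L
  pkaNtr <- params$pka_intrinsic$ntr
  pkaLys <- params$pka_intrinsic$lys_side
  addSite <- function(group, atomSerial, pka) {
    siteRows[[length(siteRows) + 1L]] <<- data.frame(
      siteId = length(siteRows) + 1L, group = group,
      atomSerial = atomSerial, pkaIntrinsic = pka,
      stringsAsFactors = FALSE)
  }
  for (s1 in c(-1, 1)) {
    d1 <- .unit(c(s1, 0, 0.35))
    g1 <- add("G1", "BCK", bl * d1, parent = core)
    p1 <- bl * d1
    for (s2 in c(-1, 1)) {
      d2 <- .unit(d1 + c(0, 0.9 * s2, 0.1))
      p2 <- p1 + bl * d2
      g2 <- add("G2", "BCK", p2, parent = g1)
      g2Count <- g2Count + 1L
      side2 <- .unit(c(-d2[2], d2[1], 0.6))
      if (g2Count <= g2Lys) {
        amn <- add("NZ2", "AMN", p2 + bl * side2, parent = g2,
                   isTitratable = TRUE)
        addSite("G2", amn, pkaLys)
      } else {
        add("LE2", "HYD", p2 + bl * side2, parent = g2,
            isHydrophobic = TRUE)
      }
      for (s3 in c(-1, 1)) {
        d3 <- .unit(d2 + c(0, 0, 0.9 * s3))
        p3 <- p2 + bl * d3
        g3 <- add("G3", "BCK", p3, parent = g2)
        side3 <- .unit(c(-d3[2], d3[1], 0.5 * s3))
        amnS <- add("NZ3", "AMN", p3 + bl * side3, parent = g3,
                    isTitratable = TRUE)
        ntr <- add("NTR", "AMN", p3 + bl * d3, parent = g3,
                   isTitratable = TRUE)
        addSite("G3_SIDE", amnS, pkaLys)
        addSite("G3_NTR", ntr, pkaNtr)
      }
    }
  }
  sitesDf <- do.call(rbind, siteRows)
  ## order site ids by group for readability: NTR, then G3 side, then G2
  ord <- order(match(sitesDf$group, .SITE_GROUPS), sitesDf$atomSerial)
  sitesDf <- sitesDf[ord, , drop = FALSE]
  sitesDf$siteId <- seq_len(nrow(sitesDf))
  rownames(sitesDf) <- NULL
  list(atoms = do.call(rbind, rows), coords = do.call(rbind, coords),
       sites = sitesDf, bonds = do.call(rbind, bonds))
}

.randomRotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

## Debye-screened Coulomb environment field on site atoms from the RNA
## phosphates (kcal/mol when the site is protonated): a crude stand-in for
## the Poisson-Boltzmann step. The exponential screening keeps the summed
## field of many phosphates from overwhelming a single direct contact, so
## phosphate-contact sites shift more than groove-buried ones.
.environmentField <- function(siteXyz, phosXyz, params) {
  epsEff <- params$environment_field$eps_eff
  cutoff <- params$environment_field$cutoff
  debye <- params$environment_field$debye
  vapply(seq_len(nrow(siteXyz)), function(i) {
    d <- sqrt(colSums((t(phosXyz) - siteXyz[i, ])^2))
    d <- pmax(d, 1.0)
    sum(ifelse(d <= cutoff,
               -.KCOULOMB / (epsEff * d) * exp(-d / debye), 0))
  }, numeric(1))
}

## Debye-screened site-site coupling (kcal/mol when both protonated),
## emulating ionic screening between solvent-exposed amines.
.siteCoupling <- function(siteXyz, params) {
  n <- nrow(siteXyz)
  epsEff <- params$site_coupling$eps_eff
  cutoff <- params$site_coupling$cutoff
  debye <- params$site_coupling$debye
  W <- matrix(0, n, n)
  if (n < 2) return(W)
  d <- as.matrix(stats::dist(siteXyz))
  d[d < 1] <- 1
  W <- .KCOULOMB / (epsEff * d) * exp(-d / debye)
  W[d > cutoff] <- 0
  diag(W) <- 0
  W
}

## internal thermal jitter (A) applied to bead coordinates per frame
.BEAD_JITTER_DEND <- 0.30
.BEAD_JITTER_RNA <- 0.15

#' Sample a synthetic bound or apo ensemble
#'
#' Bound frames place the (randomly oriented) dendrimer at
#' `targetPositionPct` along the duplex with Gaussian jitter and pull it
#' radially until the closest amine-phosphate pair sits at a
#' contact-forming distance (drawn around 3.2 A), so that at least one
#' amine lies within 4 A of a phosphate in most frames. Apo frames contain
#' the dendrimer alone under isotropic jitter. Per-frame protonation
#' occupancies are drawn from the coupled-site Monte Carlo titration model
#' ([sampleStates()]) with the screened-Coulomb phosphate field in the
#' bound state and zero field in the apo state. Reproducible under a fixed
#' seed; `replicateId` offsets the seed deterministically.
#'
#' @param duplex A [DuplexSpec-class].
#' @param dend A [DendrimerSpec-class].
#' @param placement A [PlacementModel-class].
#' @param nFrames Number of frames (>= 1).
#' @param ph Simulation pH.
#' @param bound TRUE for complex, FALSE for apo dendrimer.
#' @param seed Integer seed.
#' @param replicateId Replicate identifier (offsets the seed).
#' @param mcCycles Monte Carlo cycles per frame for protonation sampling.
#' @param params Bead parameters.
#' @return A [ComplexEnsemble-class].
#' @export
sampleEnsemble <- function(duplex = DuplexSpec(), dend = DendrimerSpec(),
                           placement = PlacementModel(), nFrames = 200L,
                           ph = 7, bound = TRUE, seed = 1L,
                           replicateId = 1L, mcCycles = 200L,
                           params = readBeadParams()) {
  stopifnot(nFrames >= 1)
  dup <- buildDuplex(duplex, params)
  den <- buildDendrimer(dend, params)
  L <- (duplex@nBp - 1) * duplex@rise

  if (bound) {
    dAtoms <- den$atoms
    offset <- nrow(dup$atoms)
    dAtoms$serial <- dAtoms$serial + offset
    dAtoms$residueIndex <- dAtoms$residueIndex + duplex@nBp
    sitesDf <- den$sites
    sitesDf$atomSerial <- sitesDf$atomSerial + offset
    allAtoms <- rbind(dup$atoms, dAtoms)
  } else {
    allAtoms <- den$atoms
    sitesDf <- den$sites
  }
  rownames(allAtoms) <- NULL
  dendIdx <- which(allAtoms$partner == "DENDRIMER")
  siteAtomIdx <- match(sitesDf$atomSerial, allAtoms$serial)
  phosIdx <- which(allAtoms$isPhosphate)

  denBase <- sweep(den$coords, 2, colMeans(den$coords))
  rt <- .RGAS * 310
  effSeed <- as.integer(seed) + 10007L * (as.integer(replicateId) - 1L)

  frames <- vector("list", nFrames)
  occ <- matrix(0, nrow = nFrames, ncol = nrow(sitesDf))
  withr::with_seed(effSeed, {
    state <- rep(1L, nrow(sitesDf))
    for (f in seq_len(nFrames)) {
      if (bound) {
        rnaXyz <- dup$coords + matrix(
          rnorm(length(dup$coords), 0, .BEAD_JITTER_RNA), ncol = 3)
        ## placement can push arm tips through the helix axis or clash
        ## beads for unlucky orientations; retry with a fresh rotation,
        ## error if persistent (e.g. a placement spec that embeds the
        ## dendrimer by design)
        ok <- FALSE
        for (attempt in seq_len(25L)) {
          rot <- .randomRotation()
          dxyz <- denBase %*% t(rot)
          zT <- placement@targetPositionPct / 100 * L +
            rnorm(1, 0, placement@jitterSigma)
          psi <- runif(1, 0, 2 * pi)
          u <- c(cos(psi), sin(psi), 0)
          center <- u * (duplex@phosphateRadius +
                           placement@approachDistance) + c(0, 0, zT)
          dxyz <- sweep(dxyz, 2, center, "+")
          ## radial pull to a contact-forming amine-phosphate distance
          sXyz <- dxyz[siteAtomIdx - nrow(dup$atoms), , drop = FALSE]
          pXyz <- rnaXyz[phosIdx, , drop = FALSE]
          dm <- .crossDist(sXyz, pXyz)
          hit <- arrayInd(which.min(dm), dim(dm))
          dTarget <- max(2.6, rnorm(1, 3.2, 0.5))
          pullDir <- .unit(pXyz[hit[2], ] - sXyz[hit[1], ])
          dxyz <- sweep(dxyz, 2, pullDir * (min(dm) - dTarget), "+")
          ## relax outward until no cross pair is closer than 2.5 A (the
          ## controlled amine contact is usually the global minimum)
          for (relax in seq_len(6L)) {
            m <- min(.crossDist(dxyz, rnaXyz))
            if (m >= 2.5) break
            dxyz <- sweep(dxyz, 2, pullDir * (m - 2.5), "+")
          }
          dxyz <- dxyz + matrix(rnorm(length(dxyz), 0,
                                      .BEAD_JITTER_DEND), ncol = 3)
          radial <- sqrt(dxyz[, 1]^2 + dxyz[, 2]^2)
          inSpan <- dxyz[, 3] > -2 & dxyz[, 3] < L + 2
          clash <- min(.crossDist(dxyz, rnaXyz)) < 2.0
          contact <- min(.crossDist(
            dxyz[siteAtomIdx - nrow(dup$atoms), , drop = FALSE],
            pXyz)) <= 3.9
          if (!clash && contact && !any(radial < 2 & inSpan)) {
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("geometry error: dendrimer bead embedded in the duplex axis")
        fullXyz <- rbind(rnaXyz, dxyz)
      } else {
        rot <- .randomRotation()
        dxyz <- denBase %*% t(rot)
        center <- rnorm(3, 0, placement@jitterSigma)
        dxyz <- sweep(dxyz, 2, center, "+")
        fullXyz <- dxyz + matrix(rnorm(length(dxyz), 0, .BEAD_JITTER_DEND),
                                 ncol = 3)
      }
      frames[[f]] <- fullXyz

      sXyz <- fullXyz[siteAtomIdx, , drop = FALSE]
      phi <- if (bound)
        .environmentField(sXyz, fullXyz[phosIdx, , drop = FALSE], params)
      else rep(0, nrow(sXyz))
      W <- .siteCoupling(sXyz, params)
      a <- .LN10 * rt * (ph - sitesDf$pkaIntrinsic) + phi
      mc <- cpp_sample_states(a, W, rt, as.integer(mcCycles),
                              as.integer(mcCycles %/% 10L), state)
      state <- mc$final_state
      occ[f, ] <- state
    }
  })
  ComplexEnsemble(allAtoms, sitesDf, frames, occ, ph = ph,
                  replicateId = replicateId, bound = bound,
                  frameInterval = 20)
}

.crossDist <- function(a, b) {
  ## n_a x n_b Euclidean distance matrix
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
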