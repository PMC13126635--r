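## Central S4 containers. Atom and site tables are plain data.frames with a
## fixed column contract (see .ATOM_COLS / .SITE_COLS); coordinates live in
## per-frame n_atoms x 3 matrices (Angstrom).

.ATOM_COLS <- c("serial", "name", "beadType", "partner", "residueIndex",
                "qProt", "qDeprot", "ljSigma", "ljEpsilon", "radius",
                "isPhosphate", "isMajorGroove", "isMinorGroove",
                "isTitratable", "isTerminalBp", "isCentralBp",
                "isHydrophobic")

.SITE_COLS <- c("siteId", "group", "atomSerial", "pkaIntrinsic")

.PARTNERS <- c("DENDRIMER", "RNA_A", "RNA_B")
.SITE_GROUPS <- c("G3_NTR", "G3_SIDE", "G2")

.validateAtoms <- function(atoms) {
  msg <- character()
  missing <- setdiff(.ATOM_COLS, names(atoms))
  if (length(missing))
    return(paste("atom table missing columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(atoms$serial)) msg <- c(msg, "duplicated atom serials")
  if (!all(atoms$partner %in% .PARTNERS))
    msg <- c(msg, "partner must be one of DENDRIMER, RNA_A, RNA_B")
  if (any(atoms$radius <= 0)) msg <- c(msg, "atom radii must be positive")
  dq <- atoms$qProt - atoms$qDeprot
  if (any(abs(dq[atoms$isTitratable] - 1) > 1e-9))
    msg <- c(msg, "titratable atoms must have qProt - qDeprot = +1")
  if (any(abs(dq[!atoms$isTitratable]) > 1e-9))
    msg <- c(msg, "non-titratable atoms must have qProt = qDeprot")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

.validateSites <- function(sites, atoms) {
  msg <- character()
  missing <- setdiff(.SITE_COLS, names(sites))
  if (length(missing))
    return(paste("site table missing columns:", paste(missing, collapse = ", ")))
  if (nrow(sites)) {
    if (!all(sites$group %in% .SITE_GROUPS))
      msg <- c(msg, "site group must be one of G3_NTR, G3_SIDE, G2")
    hit <- match(sites$atomSerial, atoms$serial)
    if (anyNA(hit)) {
      msg <- c(msg, "site atomSerial does not resolve to an atom")
    } else if (!all(atoms$isTitratable[hit])) {
      msg <- c(msg, "site atomSerial must refer to a TITRATABLE_N atom")
    }
    tser <- atoms$serial[atoms$isTitratable]
    if (!setequal(tser, sites$atomSerial))
      msg <- c(msg, "site groups must exhaust all titratable atoms")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

#' ComplexEnsemble: frames, protonation occupancies and metadata
#'
#' Holds a multi-frame coordinate ensemble of a dendrimer-duplex complex
#' (or an apo dendrimer), the per-frame binary protonation occupancy of
#' each titratable site, and run metadata (pH, replicate, bound/apo).
#' Atom order is identical across frames; occupancy rows align with frames
#' and columns with the site table.
#'
#' @slot atoms data.frame of per-atom static properties (serials, partner,
#'   charges in the protonated/deprotonated states, Lennard-Jones and SASA
#'   parameters, structural flags).
#' @slot sites data.frame of titratable sites (siteId, group, atomSerial,
#'   pkaIntrinsic).
#' @slot frames list of n_atoms x 3 coordinate matrices in Angstrom.
#' @slot occupancy n_frames x n_sites binary matrix (1 = protonated).
#' @slot ph Simulation pH.
#' @slot replicateId Integer replicate identifier.
#' @slot bound TRUE for dendrimer-duplex complexes, FALSE for apo.
#' @slot frameInterval Nominal time between frames in ps.
#' @export
setClass("ComplexEnsemble",
  representation(atoms = "data.frame", sites = "data.frame",
                 frames = "list", occupancy = "matrix", ph = "numeric",
                 replicateId = "integer", bound = "logical",
                 frameInterval = "numeric"),
  validity = function(object) {
    msg <- character()
    va <- .validateAtoms(object@atoms)
    if (!isTRUE(va)) msg <- c(msg, va)
    vs <- .validateSites(object@sites, object@atoms)
    if (!isTRUE(vs)) msg <- c(msg, vs)
    na <- nrow(object@atoms)
    for (f in object@frames) {
      if (!is.matrix(f) || ncol(f) != 3 || nrow(f) != na) {
        msg <- c(msg, "all frames must be n_atoms x 3 matrices")
        break
      }
      if (!all(is.finite(f))) {
        msg <- c(msg, "frame coordinates must be finite")
        break
      }
    }
    nf <- length(object@frames)
    if (nrow(object@occupancy) != nf)
      msg <- c(msg, "occupancy must have one row per frame")
    if (ncol(object@occupancy) != nrow(object@sites))
      msg <- c(msg, "occupancy must have one column per site")
    if (length(object@occupancy) &&
        !all(object@occupancy %in% c(0, 1)))
      msg <- c(msg, "occupancy values must be binary")
    if (length(object@ph) != 1 || object@ph < 0 || object@ph > 14)
      msg <- c(msg, "ph must be a single value in [0, 14]")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

#' TitrationModel: coupled-site protonation free energy model
#'
#' Defines the microstate energy
#' \deqn{E(s, pH) = \sum_i s_i [\ln(10) R T (pH - pKa_i) + \phi_i] +
#'   \sum_{i<j} W_{ij} s_i s_j}
#' over binary protonation states \eqn{s}. \eqn{\phi_i} is an environment
#' term (kcal/mol, negative values stabilize the protonated form) and
#' \eqn{W_{ij}} a symmetric site-site interaction paid when both sites are
#' protonated.
#'
#' @slot pkaIntrinsic Per-site intrinsic pKa values.
#' @slot coupling Symmetric site-site interaction matrix, kcal/mol,
#'   zero diagonal.
#' @slot field Per-site environment term, kcal/mol.
#' @slot temperature Kelvin.
#' @export
setClass("TitrationModel",
  representation(pkaIntrinsic = "numeric", coupling = "matrix",
                 field = "numeric", temperature = "numeric"),
  prototype(temperature = 310),
  validity = function(object) {
    n <- length(object@pkaIntrinsic)
    msg <- character()
    if (!identical(dim(object@coupling), c(n, n)))
      msg <- c(msg, "coupling must be n_sites x n_sites")
    else {
      if (max(abs(object@coupling - t(object@coupling))) > 1e-9)
        msg <- c(msg, "coupling must be symmetric")
      if (n && any(abs(diag(object@coupling)) > 1e-12))
        msg <- c(msg, "coupling diagonal must be zero")
    }
    if (length(object@field) != n)
      msg <- c(msg, "field must have one entry per site")
    if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

#' TitrationCurve: group titration data over a pH grid
#'
#' @slot ph Strictly increasing pH grid.
#' @slot occupancy Pooled mean occupancy at each pH.
#' @slot perReplicate replicate x pH matrix of per-replicate means
#'   (NA where a replicate has no data in the requested context).
#' @slot group Site group label.
#' @slot context "ALL", "PHOS" or "GROOVE".
#' @slot bound Whether the curve comes from bound ensembles.
#' @export
setClass("TitrationCurve",
  representation(ph = "numeric", occupancy = "numeric",
                 perReplicate = "matrix", group = "character",
                 context = "character", bound = "logical"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@ph, strictly = TRUE))
      msg <- c(msg, "ph values must be strictly increasing")
    if (length(object@occupancy) != length(object@ph))
      msg <- c(msg, "occupancy must align with ph")
    ok <- stats::na.omit(object@occupancy)
    if (length(ok) && (min(ok) < -1e-9 || max(ok) > 1 + 1e-9))
      msg <- c(msg, "occupancies must lie in [0, 1]")
    if (ncol(object@perReplicate) != length(object@ph))
      msg <- c(msg, "perReplicate must have one column per pH")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

#' HillFit: result of a Hill-equation fit to a titration curve
#'
#' The fitted model is \eqn{f(pH) = 1 / (1 + 10^{n (pH - pKa)})}.
#'
#' @slot pka Fitted apparent pKa.
#' @slot n Fitted Hill coefficient.
#' @slot sePka,seN Standard errors from the fit covariance.
#' @slot converged Honest convergence flag; when FALSE the point estimates
#'   are NA and `diagnostics` says why.
#' @slot diagnostics Character diagnostic message.
#' @export
setClass("HillFit",
  representation(pka = "numeric", n = "numeric", sePka = "numeric",
                 seN = "numeric", converged = "logical",
                 diagnostics = "character"),
  validity = function(object) {
    if (isTRUE(object@converged) && !(object@n > 0))
      "converged fit requires n > 0" else TRUE
  })

#' EnergyLandscape: conditional free-energy surface over a 2D grid
#'
#' Grid over (signed groove distance, phosphate distance) with
#' \eqn{E(r) = -RT \ln(P(r)/P_{max})}. Cells where the density underflows
#' to zero are masked (NA), never reported as zero energy.
#'
#' @slot x,y Grid center coordinates (Angstrom). x is the signed groove
#'   distance (positive = major groove side), y the phosphate distance.
#' @slot density Probability density matrix (per A^2), rows index x.
#' @slot energy Energy matrix in kcal/mol, NA where masked.
#' @slot pMax Density maximum.
#' @slot temperature Kelvin.
#' @slot bandwidth Kernel standard deviations used per axis.
#' @export
setClass("EnergyLandscape",
  representation(x = "numeric", y = "numeric", density = "matrix",
                 energy = "matrix", pMax = "numeric",
                 temperature = "numeric", bandwidth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@density), dim(object@energy)))
      msg <- c(msg, "density and energy grids must match")
    e <- object@energy[!is.na(object@energy)]
    if (length(e) && min(e) < -1e-9)
      msg <- c(msg, "energies must be non-negative")
    if (length(e) && abs(min(e)) > 1e-9)
      msg <- c(msg, "energy must be zero at the density maximum")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

#' BindingDecomposition: per-frame MM/PBSA components and summary
#'
#' Component differences are complex - (dendrimer + RNA) computed from the
#' same coordinates (single-trajectory protocol), so
#' \eqn{\Delta G_{bind} = E_{Coul} + E_{VdW} + Solv_{polar} + Solv_{apolar}}
#' holds exactly on every frame.
#'
#' @slot perFrame data.frame with columns replicate, frame, eCoul, eVdw,
#'   solvPolar, solvApolar, dGbind (kcal/mol).
#' @slot mean Named mean components over all frames.
#' @slot sem Standard error of the per-replicate means of dGbind
#'   (NA with fewer than two replicates).
#' @export
setClass("BindingDecomposition",
  representation(perFrame = "data.frame", mean = "numeric", sem = "numeric"),
  validity = function(object) {
    need <- c("replicate", "frame", "eCoul", "eVdw", "solvPolar",
              "solvApolar", "dGbind")
    if (!all(need %in% names(object@perFrame)))
      return("perFrame missing required columns")
    pf <- object@perFrame
    if (nrow(pf)) {
      resid <- pf$dGbind - (pf$eCoul + pf$eVdw + pf$solvPolar + pf$solvApolar)
      if (max(abs(resid)) > 1e-8)
        return("dGbind must equal the sum of its four components")
    }
    TRUE
  })
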