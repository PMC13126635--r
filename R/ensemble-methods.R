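#' Construct a ComplexEnsemble
#'
#' @param atoms Atom table (see [ComplexEnsemble-class]).
#' @param sites Site table.
#' @param frames List of n_atoms x 3 coordinate matrices (Angstrom).
#' @param occupancy n_frames x n_sites binary matrix.
#' @param ph Simulation pH.
#' @param replicateId Replicate identifier.
#' @param bound TRUE for complex ensembles, FALSE for apo dendrimer.
#' @param frameInterval Nominal frame spacing, ps.
#' @return A validated [ComplexEnsemble-class] object.
#' @export
ComplexEnsemble <- function(atoms, sites, frames, occupancy, ph,
                            replicateId = 1L, bound = TRUE,
                            frameInterval = 20) {
  if (is.null(occupancy))
    occupancy <- matrix(numeric(0), nrow = length(frames), ncol = 0)
  new("ComplexEnsemble", atoms = atoms, sites = sites, frames = frames,
      occupancy = occupancy, ph = as.numeric(ph),
      replicateId = as.integer(replicateId), bound = bound,
      frameInterval = frameInterval)
}

#' @describeIn ComplexEnsemble Atom table accessor.
#' @param x A ComplexEnsemble.
#' @export
setMethod("atoms", "ComplexEnsemble", function(x) x@atoms)

#' @describeIn ComplexEnsemble Site table accessor.
#' @export
setMethod("sites", "ComplexEnsemble", function(x) x@sites)

#' @describeIn ComplexEnsemble List of coordinate frames.
#' @export
setMethod("frames", "ComplexEnsemble", function(x) x@frames)

#' @describeIn ComplexEnsemble Single coordinate frame.
#' @param i Frame index (1-based).
#' @export
setMethod("getFrame", "ComplexEnsemble", function(x, i) x@frames[[i]])

#' @describeIn ComplexEnsemble Occupancy matrix accessor.
#' @export
setMethod("occupancy", "ComplexEnsemble", function(x) x@occupancy)

#' @describeIn ComplexEnsemble Number of frames.
#' @export
setMethod("nFrames", "ComplexEnsemble", function(x) length(x@frames))

#' @describeIn ComplexEnsemble Number of atoms.
#' @export
setMethod("nAtoms", "ComplexEnsemble", function(x) nrow(x@atoms))

#' @describeIn ComplexEnsemble Number of titratable sites.
#' @export
setMethod("nSites", "ComplexEnsemble", function(x) nrow(x@sites))

#' @describeIn ComplexEnsemble Simulation pH.
#' @export
setMethod("pH", "ComplexEnsemble", function(x) x@ph)

#' @describeIn ComplexEnsemble Bound/apo flag.
#' @export
setMethod("isBound", "ComplexEnsemble", function(x) x@bound)

#' @describeIn ComplexEnsemble Replicate identifier.
#' @export
setMethod("replicateId", "ComplexEnsemble", function(x) x@replicateId)

setMethod("show", "ComplexEnsemble", function(object) {
  cat(sprintf(
    "ComplexEnsemble: %d frames, %d atoms, %d sites | pH %.1f | %s | rep %d\n",
    nFrames(object), nAtoms(object), nSites(object), pH(object),
    if (isBound(object)) "bound" else "apo", replicateId(object)))
  tab <- table(object@atoms$partner)
  cat("  partners:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if (nSites(object))
    cat("  site groups:",
        paste(names(table(object@sites$group)), table(object@sites$group),
              sep = "=", collapse = " "), "\n")
})

setMethod("show", "HillFit", function(object) {
  if (object@converged) {
    cat(sprintf("HillFit: pKa = %.3f +/- %.3f, n = %.3f +/- %.3f\n",
                object@pka, object@sePka, object@n, object@seN))
  } else {
    cat("HillFit: not converged (", object@diagnostics, ")\n", sep = "")
  }
})

setMethod("show", "TitrationCurve", function(object) {
  cat(sprintf(
    "TitrationCurve: group %s, context %s, %s | %d pH points, %d replicates\n",
    object@group, object@context, if (object@bound) "bound" else "apo",
    length(object@ph), nrow(object@perReplicate)))
})

setMethod("show", "EnergyLandscape", function(object) {
  cat(sprintf(
    "EnergyLandscape: %d x %d grid, T = %g K, bandwidth (%.2f, %.2f) A\n",
    length(object@x), length(object@y), object@temperature,
    object@bandwidth[1], object@bandwidth[2]))
  cat(sprintf("  %d masked cells; max E = %.2f kcal/mol\n",
              sum(is.na(object@energy)), max(object@energy, na.rm = TRUE)))
})

setMethod("show", "BindingDecomposition", function(object) {
  m <- object@mean
  cat("BindingDecomposition (kcal/mol):\n")
  cat(sprintf("  E_Coul %.2f  E_VdW %.2f  Solv_polar %.2f  Solv_apolar %.2f\n",
              m["eCoul"], m["eVdw"], m["solvPolar"], m["solvApolar"]))
  cat(sprintf("  dG_bind %.2f +/- %s (SEM over replicates, n frames = %d)\n",
              m["dGbind"],
              if (is.na(object@sem)) "NA" else sprintf("%.2f", object@sem),
              nrow(object@perFrame)))
})
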