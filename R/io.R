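## On-disk artifact plumbing. Frames travel as multi-model PDB (chain D =
## dendrimer, A/B = RNA strands; occupancy column = SASA/PB radius, B-factor
## column = structural flag bitmask), occupancies as TSV (frame, site_id,
## state), sites as JSON, bead parameters as a versioned JSON file shipped
## under inst/extdata, run metadata as key=value text.

.FLAG_BITS <- c(isPhosphate = 1L, isMajorGroove = 2L, isMinorGroove = 4L,
                isTitratable = 8L, isTerminalBp = 16L, isCentralBp = 32L,
                isHydrophobic = 64L)

.CHAIN_OF_PARTNER <- c(DENDRIMER = "D", RNA_A = "A", RNA_B = "B")

.encodeFlags <- function(atoms) {
  bits <- integer(nrow(atoms))
  for (nm in names(.FLAG_BITS))
    bits <- bits + .FLAG_BITS[[nm]] * as.integer(atoms[[nm]])
  bits
}

.decodeFlags <- function(bits) {
  out <- lapply(.FLAG_BITS, function(b) bitwAnd(as.integer(bits), b) > 0L)
  as.data.frame(out)
}

#' Read the bead parameter file
#'
#' The package ships a versioned JSON parameter file with toy bead charges,
#' Lennard-Jones parameters, SASA/PB radii, intrinsic pKa values and the
#' apolar-solvation coefficients used by the synthetic models.
#'
#' @param path Path to a parameter JSON; defaults to the shipped file.
#' @return Nested list of parameters.
#' @export
readBeadParams <- function(path = system.file("extdata", "bead_params.json",
                                              package = "dendripH")) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.beadLookup <- function(beadType, params, what) {
  vals <- vapply(beadType, function(bt) {
    b <- params$beads[[bt]]
    if (is.null(b)) stop("unknown bead type in frames file: ", bt)
    b[[what]]
  }, numeric(1))
  unname(vals)
}

#' Write an ensemble to disk
#'
#' Writes `frames.pdb` (multi-model PDB), `occupancy.tsv`, `sites.json` and
#' `config.txt` into `dir`.
#'
#' @param ensemble A [ComplexEnsemble-class].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeEnsemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  a <- atoms(ensemble)
  xyz <- do.call(rbind, lapply(frames(ensemble), function(m) as.vector(t(m))))
  bio3d::write.pdb(file = file.path(dir, "frames.pdb"), xyz = xyz,
                   eleno = a$serial, elety = a$name, resid = a$beadType,
                   resno = a$residueIndex,
                   chain = unname(.CHAIN_OF_PARTNER[a$partner]),
                   o = a$radius, b = .encodeFlags(a))
  writeOccupancy(occupancy(ensemble), sites(ensemble)$siteId,
                 file.path(dir, "occupancy.tsv"))
  writeSites(sites(ensemble), file.path(dir, "sites.json"))
  writeRunMeta(list(ph = pH(ensemble), replicate = replicateId(ensemble),
                    bound = isBound(ensemble),
                    frame_interval = ensemble@frameInterval),
               file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read an ensemble from its on-disk artifacts
#'
#' @param framesPath Multi-model PDB of coordinate frames.
#' @param occupancyPath TSV with columns frame (0-based), site_id, state.
#' @param sitesPath JSON list of site definitions.
#' @param paramsPath Bead parameter JSON (defaults to the shipped file).
#' @param configPath key=value run metadata (ph, replicate, bound,
#'   frame_interval).
#' @return A validated [ComplexEnsemble-class]; atom order is identical
#'   across frames.
#' @export
readEnsemble <- function(framesPath, occupancyPath, sitesPath,
                         paramsPath = system.file("extdata",
                                                  "bead_params.json",
                                                  package = "dendripH"),
                         configPath = NULL) {
  params <- readBeadParams(paramsPath)
  pdb <- bio3d::read.pdb(framesPath, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nAtom <- nrow(at)
  if (ncol(pdb$xyz) != 3L * nAtom)
    stop("structural error: atom count mismatch between models")
  chain2partner <- setNames(names(.CHAIN_OF_PARTNER), .CHAIN_OF_PARTNER)
  if (!all(at$chain %in% names(chain2partner)))
    stop("structural error: unknown chain identifier (expected D/A/B)")
  flags <- .decodeFlags(round(at$b))
  atomsDf <- data.frame(
    serial = as.integer(at$eleno), name = at$elety, beadType = at$resid,
    partner = unname(chain2partner[at$chain]),
    residueIndex = as.integer(at$resno),
    qProt = .beadLookup(at$resid, params, "q_prot"),
    qDeprot = .beadLookup(at$resid, params, "q_deprot"),
    ljSigma = .beadLookup(at$resid, params, "lj_sigma"),
    ljEpsilon = .beadLookup(at$resid, params, "lj_epsilon"),
    radius = at$o, stringsAsFactors = FALSE)
  atomsDf <- cbind(atomsDf, flags)

  sitesDf <- readSites(sitesPath)
  bad <- setdiff(sitesDf$atomSerial, atomsDf$serial)
  if (length(bad))
    stop("definition error: unresolved site atom serial(s): ",
         paste(bad, collapse = ", "))

  nf <- nrow(pdb$xyz)
  frameList <- lapply(seq_len(nf), function(i)
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE))
  occ <- readOccupancy(occupancyPath, nf, sitesDf$siteId)

  meta <- list(ph = 7, replicate = 1L, bound = TRUE, frame_interval = 20)
  if (!is.null(configPath)) meta <- modifyList(meta, readRunMeta(configPath))
  ComplexEnsemble(atomsDf, sitesDf, frameList, occ, ph = meta$ph,
                  replicateId = meta$replicate, bound = isTRUE(meta$bound),
                  frameInterval = meta$frame_interval)
}

#' Read an ensemble directory written by [writeEnsemble()]
#'
#' @param dir Directory with frames.pdb, occupancy.tsv, sites.json,
#'   config.txt.
#' @param paramsPath Bead parameter JSON.
#' @return A [ComplexEnsemble-class].
#' @export
readEnsembleDir <- function(dir,
                            paramsPath = system.file("extdata",
                                                     "bead_params.json",
                                                     package = "dendripH")) {
  readEnsemble(file.path(dir, "frames.pdb"), file.path(dir, "occupancy.tsv"),
               file.path(dir, "sites.json"), paramsPath,
               file.path(dir, "config.txt"))
}

#' @rdname writeEnsemble
#' @param occ n_frames x n_sites binary matrix.
#' @param siteIds Site identifiers, one per occupancy column.
#' @param path Output TSV path.
#' @export
writeOccupancy <- function(occ, siteIds, path) {
  nf <- nrow(occ)
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, times = ncol(occ)),
    site_id = rep(as.integer(siteIds), each = nf),
    state = as.integer(occ))
  df <- df[order(df$frame, df$site_id), ]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname readEnsemble
#' @param path TSV path.
#' @param nFrames Expected number of frames.
#' @param siteIds Expected site identifiers.
#' @export
readOccupancy <- function(path, nFrames, siteIds) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("frame", "site_id", "state") %in% names(df)))
    stop("format error: occupancy TSV needs columns frame, site_id, state")
  if (!all(df$state %in% c(0L, 1L)))
    stop("format error: occupancy states must be 0 or 1")
  ns <- length(siteIds)
  occ <- matrix(NA_real_, nrow = nFrames, ncol = ns)
  fi <- df$frame + 1L
  si <- match(df$site_id, siteIds)
  if (anyNA(si)) stop("format error: unknown site_id in occupancy TSV")
  if (any(fi < 1L | fi > nFrames))
    stop("format error: occupancy frame index out of range")
  occ[cbind(fi, si)] <- df$state
  if (ns > 0 && anyNA(occ))
    stop("format error: missing (frame, site) occupancy entries")
  occ
}

#' @rdname writeEnsemble
#' @param sitesDf Site table.
#' @export
writeSites <- function(sitesDf, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(sitesDf)), function(i) list(
      site_id = sitesDf$siteId[i], group = sitesDf$group[i],
      atom_serial = sitesDf$atomSerial[i],
      pka_intrinsic = sitesDf$pkaIntrinsic[i])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname readEnsemble
#' @export
readSites <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(raw))
    return(data.frame(siteId = integer(), group = character(),
                      atomSerial = integer(), pkaIntrinsic = numeric()))
  data.frame(
    siteId = vapply(raw, function(s) as.integer(s$site_id), integer(1)),
    group = vapply(raw, function(s) s$group, character(1)),
    atomSerial = vapply(raw, function(s) as.integer(s$atom_serial),
                        integer(1)),
    pkaIntrinsic = vapply(raw, function(s) as.numeric(s$pka_intrinsic),
                          numeric(1)),
    stringsAsFactors = FALSE)
}

#' @rdname writeEnsemble
#' @param meta Named list of scalar values.
#' @export
writeRunMeta <- function(meta, path) {
  writeLines(paste0(names(meta), " = ", vapply(meta, format, character(1))),
             path)
  invisible(path)
}

#' @rdname readEnsemble
#' @export
readRunMeta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- lapply(kv, function(p) {
    v <- p[2]
    if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else if (grepl("^-?[0-9.eE+-]+$", v)) as.numeric(v)
    else v
  })
  setNames(out, vapply(kv, `[`, character(1), 1))
}

#' Write a homogeneous result table as CSV
#'
#' Deterministic column order (that of the input), UTF-8, header always
#' written (header-only file for an empty table).
#'
#' @param rows data.frame of records (possibly zero rows).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
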