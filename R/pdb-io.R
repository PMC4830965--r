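#' @include model-core.R
NULL

## Internal units are nm; PDB files carry Angstrom. All conversion happens
## here, at the I/O boundary.
.A2NM <- 0.1

.parseCryst1 <- function(lines) {
  i <- grep("^CRYST1", lines)
  if (!length(i)) return(NULL)
  ln <- lines[i[1]]
  fld <- suppressWarnings(as.numeric(c(
    substr(ln, 7, 15), substr(ln, 16, 24), substr(ln, 25, 33),
    substr(ln, 34, 40), substr(ln, 41, 47), substr(ln, 48, 54))))
  if (any(is.na(fld))) stop("malformed CRYST1 record at line ", i[1])
  if (any(abs(fld[4:6] - 90) > 1e-3)) {
    stop("triclinic boxes are not supported (CRYST1 angles must be 90)")
  }
  fld[1:3] * .A2NM
}

.cryst1Line <- function(box_nm) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          box_nm[1] / .A2NM, box_nm[2] / .A2NM, box_nm[3] / .A2NM,
          90, 90, 90)
}

## validation pass over raw PDB lines: numeric fields of every ATOM/HETATM
## record must parse; reports the 1-based file line number on failure.
.checkAtomLines <- function(lines) {
  rec <- grep("^(ATOM  |HETATM)", lines)
  for (i in rec) {
    ln <- lines[i]
    num <- suppressWarnings(as.numeric(c(
      substr(ln, 7, 11), substr(ln, 23, 26),
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (nchar(ln) < 54 || any(is.na(num))) {
      stop("malformed ATOM/HETATM record at line ", i)
    }
  }
  invisible(rec)
}

.elementFromName <- function(name) {
  ## fall back on the leading alphabetic character of the atom name
  sub("^[0-9]*([A-Za-z]).*$", "\\1", name)
}

#' Load a structure from a PDB file
#'
#' Reads a (single-model) PDB file into a [StructureModel-class]. Coordinates
#' are converted from Angstrom to nm on load. Molecule classes are inferred
#' from residue names via [moleculeClass()]; `classOverrides` extends that
#' lookup. The orthorhombic box is taken from the `CRYST1` record; triclinic
#' boxes are rejected. Files without `CRYST1` get a bounding-box-sized box
#' with a warning. TM helix annotations are attached from `helixTable` /
#' `bwAnchors` (typically read from a config file, see
#' [readAnalysisConfig()]).
#'
#' @param path PDB file path
#' @param format only `"pdb"` is supported
#' @param classOverrides named character vector of residue-name to
#'   molecule-class overrides
#' @param helixTable,bwAnchors TM annotations (see [StructureModel-class])
#' @return a [StructureModel-class]
#' @seealso [writeStructure()], [readTrajectory()]
#' @export
loadStructure <- function(path, format = c("pdb"), classOverrides = NULL,
                          helixTable = NULL, bwAnchors = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  .checkAtomLines(lines)
  box <- .parseCryst1(lines)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  if (anyDuplicated(at$eleno)) {
    stop("duplicate atom serial numbers in ", path)
  }
  elesy <- at$elesy
  miss <- is.na(elesy) | elesy == ""
  elesy[miss] <- .elementFromName(at$elety[miss])
  chain <- at$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = at$elety,
    element = toupper(elesy),
    resname = at$resid,
    resid = as.integer(at$resno),
    chain = chain,
    class = moleculeClass(at$resid, classOverrides),
    stringsAsFactors = FALSE
  )
  xyz <- cbind(at$x, at$y, at$z) * .A2NM
  if (is.null(box)) {
    box <- apply(xyz, 2, function(v) diff(range(v))) + 1
    warning("no CRYST1 record in ", path,
            "; using the coordinate bounding box (+1 nm) as the box")
  }
  if (is.null(helixTable)) {
    helixTable <- data.frame(helix = integer(), start = integer(),
                             end = integer())
  }
  if (is.null(bwAnchors)) bwAnchors <- integer()
  StructureModel(atoms, xyz, box, helixTable, bwAnchors)
}

## shared ATOM-line emitter: writes one frame's records via bio3d, returns
## the character lines without the trailing END. Serials beyond 99999 wrap
## modulo 100000 (documented dialect rule).
.pdbLines <- function(model, xyz_nm) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  a <- model@atoms
  bio3d::write.pdb(
    file = tmp,
    xyz = as.vector(t(xyz_nm / .A2NM)),
    type = ifelse(a$class == "protein", "ATOM", "HETATM"),
    resno = a$resid,
    resid = a$resname,
    eleno = a$serial %% 100000L,
    elety = a$name,
    chain = ifelse(a$chain == " ", NA, a$chain),
    elesy = a$element,
    end = FALSE
  )
  readLines(tmp, warn = FALSE)
}

#' Write a StructureModel to a PDB file
#'
#' Emits fixed-column PDB (coordinates back-converted to Angstrom, 3
#' decimals) with a `CRYST1` box record. `loadStructure(writeStructure(m))`
#' reproduces `m` up to the 1e-3 Angstrom coordinate rounding of the format.
#'
#' @param model a [StructureModel-class]
#' @param path output file path
#' @param format only `"pdb"`
#' @return invisibly, the path
#' @export
writeStructure <- function(model, path, format = c("pdb")) {
  format <- match.arg(format)
  lines <- c(.cryst1Line(model@box), .pdbLines(model, model@coords), "END")
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write PDB file: ", path)
  invisible(path)
}

#' Read a trajectory from a multi-model PDB file
#'
#' Each `MODEL`/`ENDMDL` block is one frame and must contain exactly the
#' topology's atom count (a mismatch is an error naming the offending frame).
#' Frame times in ns are taken from `REMARK   6 TIME_NS <t>` records inside
#' each block when present, else the 0-based frame index is used.
#'
#' @param topology the [StructureModel-class] the frames refer to
#' @param path multi-model PDB file
#' @param format only `"pdb"`
#' @return a [Trajectory-class]
#' @seealso [writeTrajectory()]
#' @export
readTrajectory <- function(topology, path, format = c("pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  .checkAtomLines(lines)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) {
    starts <- 0L
    ends <- length(lines) + 1L
  }
  if (length(starts) != length(ends)) {
    stop("unbalanced MODEL/ENDMDL records in ", path)
  }
  natom <- nrow(topology@atoms)
  times <- rep(NA_real_, length(starts))
  for (f in seq_along(starts)) {
    blk <- lines[(starts[f] + 1L):(ends[f] - 1L)]
    n <- sum(grepl("^(ATOM  |HETATM)", blk))
    if (n != natom) {
      stop(sprintf("frame %d has %d atoms, expected %d", f, n, natom))
    }
    tl <- grep("^REMARK   6 TIME_NS", blk, value = TRUE)
    if (length(tl)) {
      times[f] <- suppressWarnings(as.numeric(sub(
        "^REMARK   6 TIME_NS *", "", tl[1])))
    }
  }
  if (anyNA(times)) times <- seq_along(starts) - 1
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  arr <- array(0, dim = c(natom, 3, nf))
  for (f in seq_len(nf)) {
    arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) * .A2NM
  }
  box <- .parseCryst1(lines)
  if (is.null(box)) box <- topology@box
  Trajectory(topology, arr, times = times,
             boxes = matrix(box, 3, nf))
}

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL` block per frame, each carrying a
#' `REMARK   6 TIME_NS <t>` record so [readTrajectory()] round-trips the
#' frame times.
#'
#' @param traj a [Trajectory-class]
#' @param path output file path
#' @param format only `"pdb"`
#' @return invisibly, the path
#' @export
writeTrajectory <- function(traj, path, format = c("pdb")) {
  format <- match.arg(format)
  nf <- dim(traj@coords)[3]
  out <- vector("list", nf + 2L)
  out[[1]] <- .cryst1Line(traj@model@box)
  for (f in seq_len(nf)) {
    out[[f + 1L]] <- c(
      sprintf("MODEL     %4d", f),
      sprintf("REMARK   6 TIME_NS %.6f", traj@times[f]),
      .pdbLines(traj@model, traj@coords[, , f]),
      "ENDMDL"
    )
  }
  out[[nf + 2L]] <- "END"
  ok <- tryCatch({
    writeLines(unlist(out), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write PDB file: ", path)
  invisible(path)
}

#' Read an analysis configuration file
#'
#' YAML configuration holding the receptor annotations and analysis defaults:
#' `helix_table` (list of `{helix, start, end}`), `bw_anchors` (helix ->
#' residue id), `molecule_class_overrides` (residue name -> class),
#' `rotamer_bounds`, `thresholds` (triage thresholds, see [triageVariant()])
#' and free-form `cutoffs`. Missing sections yield empty defaults.
#'
#' @param path YAML file path
#' @return a named list with elements `helixTable`, `bwAnchors`,
#'   `classOverrides`, `rotamerBounds`, `thresholds`, `cutoffs`
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  ht <- data.frame(helix = integer(), start = integer(), end = integer())
  if (!is.null(y$helix_table)) {
    ht <- do.call(rbind, lapply(y$helix_table, function(r) {
      data.frame(helix = as.integer(r$helix), start = as.integer(r$start),
                 end = as.integer(r$end))
    }))
  }
  anchors <- integer()
  if (!is.null(y$bw_anchors)) {
    anchors <- vapply(y$bw_anchors, as.integer, 1L)
  }
  ov <- NULL
  if (!is.null(y$molecule_class_overrides)) {
    ov <- vapply(y$molecule_class_overrides, as.character, "")
  }
  list(
    helixTable = ht,
    bwAnchors = anchors,
    classOverrides = ov,
    rotamerBounds = y$rotamer_bounds,
    thresholds = y$thresholds,
    cutoffs = y$cutoffs
  )
}
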