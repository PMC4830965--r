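#' @import methods
NULL

#' StructureModel: the structural ground truth of a simulated system
#'
#' A `StructureModel` holds one set of atoms (protein, lipid pseudo-molecules,
#' waters and optional ligand), their reference coordinates in nm, an
#' orthorhombic periodic box, and the receptor annotations used throughout the
#' pipeline: the transmembrane (TM) helix table and the Ballesteros-Weinstein
#' (BW) anchor residues (the x.50 residue of each helix).
#'
#' @slot atoms a `data.frame` with one row per atom and columns
#'   `serial` (unique positive integer), `name` (PDB atom name, e.g. `"CA"`,
#'   `"P"`, `"OW"`), `element` (element symbol), `resname` (residue name),
#'   `resid` (integer residue number, preserved verbatim from input),
#'   `chain` (single character) and `class` (one of `"protein"`, `"lipid"`,
#'   `"water"`, `"ligand"`).
#' @slot coords numeric N x 3 matrix of coordinates in nm.
#' @slot box numeric length-3 vector of orthorhombic box lengths in nm.
#' @slot helixTable `data.frame` with columns `helix`, `start`, `end`
#'   giving inclusive residue-id ranges of the TM helices (possibly 0 rows).
#' @slot bwAnchors named integer vector mapping helix index (as name) to the
#'   residue id of that helix's x.50 residue.
#'
#' @seealso [loadStructure()], [buildSystem()], [selectAtoms()], [bwNumber()]
#' @export
setClass("StructureModel",
  representation(
    atoms = "data.frame",
    coords = "matrix",
    box = "numeric",
    helixTable = "data.frame",
    bwAnchors = "integer"
  )
)

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msgs <- character()
  need <- c("serial", "name", "element", "resname", "resid", "chain", "class")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(a$serial)) {
    msgs <- c(msgs, "atom serial numbers must be unique")
  }
  if (!all(a$class %in% c("protein", "lipid", "water", "ligand"))) {
    msgs <- c(msgs, "molecule class must be protein/lipid/water/ligand")
  }
  if (nrow(a) > 0) {
    rk <- paste(a$chain, a$resid)
    if (any(vapply(split(a$class, rk), function(x) length(unique(x)), 1L) > 1L)) {
      msgs <- c(msgs, "molecule class must be constant within a residue")
    }
  }
  if (!is.numeric(object@coords) || ncol(object@coords) != 3 ||
      nrow(object@coords) != nrow(a)) {
    msgs <- c(msgs, "coords must be an N x 3 matrix matching atoms")
  } else if (!all(is.finite(object@coords))) {
    msgs <- c(msgs, "coordinates must be finite")
  }
  if (length(object@box) != 3 || any(!is.finite(object@box)) ||
      any(object@box <= 0)) {
    msgs <- c(msgs, "box must be three positive lengths (nm)")
  }
  h <- object@helixTable
  if (nrow(h) > 0) {
    if (!all(c("helix", "start", "end") %in% names(h))) {
      msgs <- c(msgs, "helixTable needs columns helix, start, end")
    } else {
      if (any(h$end < h$start)) msgs <- c(msgs, "helix ranges must have start <= end")
      o <- order(h$start)
      if (nrow(h) > 1 && any(h$start[o][-1] <= h$end[o][-nrow(h)])) {
        msgs <- c(msgs, "helix residue ranges must not overlap")
      }
      if (length(object@bwAnchors)) {
        hx <- as.integer(names(object@bwAnchors))
        for (i in seq_along(object@bwAnchors)) {
          row <- h[h$helix == hx[i], , drop = FALSE]
          if (nrow(row) != 1 || object@bwAnchors[i] < row$start ||
              object@bwAnchors[i] > row$end) {
            msgs <- c(msgs, sprintf(
              "BW anchor for helix %d must lie inside that helix range", hx[i]))
          }
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Trajectory: ordered coordinate frames sharing one StructureModel
#'
#' @slot model the [StructureModel-class] all frames refer to.
#' @slot coords numeric array of dimension N x 3 x F (atoms, xyz, frames), nm.
#' @slot times numeric length-F vector of frame times in ns, non-decreasing.
#' @slot boxes numeric 3 x F matrix of per-frame box lengths in nm.
#'
#' @seealso [readTrajectory()], [generateTrajectory()], [tmRmsdSeries()]
#' @export
setClass("Trajectory",
  representation(
    model = "StructureModel",
    coords = "array",
    times = "numeric",
    boxes = "matrix"
  )
)

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  msgs <- character()
  if (length(d) != 3 || d[2] != 3) {
    return("coords must be an N x 3 x F array")
  }
  if (d[1] != nrow(object@model@atoms)) {
    msgs <- c(msgs, "frame atom count must equal the model atom count")
  }
  if (d[3] < 1) msgs <- c(msgs, "a trajectory needs at least one frame")
  if (length(object@times) != d[3]) {
    msgs <- c(msgs, "times length must equal the frame count")
  } else if (d[3] > 1 && any(diff(object@times) < 0)) {
    msgs <- c(msgs, "frame times must be non-decreasing")
  }
  if (!all(dim(object@boxes) == c(3, d[3]))) {
    msgs <- c(msgs, "boxes must be a 3 x F matrix")
  }
  if (length(msgs)) msgs else TRUE
})

#' DihedralSeries: per-frame chi1 angles with rotamer states and flips
#'
#' Produced by [chi1Series()]. Angles follow the IUPAC sign convention and lie
#' in (-180, 180] degrees; states are `"gauche-"`, `"gauche+"` or `"trans"`
#' (see [classifyRotamer()]); `events` is the flip-event table from
#' [detectFlips()] (columns `start`, `end`, `from`, `to`, 1-based frames).
#'
#' @slot resid integer residue id the series refers to.
#' @slot times numeric frame times, ns.
#' @slot chi1 numeric chi1 angles, degrees.
#' @slot states character rotamer-state labels, one per frame.
#' @slot events `data.frame` of flip events.
#' @export
setClass("DihedralSeries",
  representation(
    resid = "integer",
    times = "numeric",
    chi1 = "numeric",
    states = "character",
    events = "data.frame"
  )
)

setValidity("DihedralSeries", function(object) {
  msgs <- character()
  if (any(object@chi1 <= -180 - 1e-9 | object@chi1 > 180 + 1e-9)) {
    msgs <- c(msgs, "chi1 angles must lie in (-180, 180]")
  }
  if (length(object@states) != length(object@chi1)) {
    msgs <- c(msgs, "states must have one label per frame")
  }
  e <- object@events
  if (nrow(e) > 0) {
    if (any(e$start >= e$end)) msgs <- c(msgs, "flip events must have start < end")
    if (any(e$from == e$to)) msgs <- c(msgs, "flip events must change state")
  }
  if (length(msgs)) msgs else TRUE
})

#' ThicknessMap: a 2D grid of time-averaged leaflet-to-leaflet distances
#'
#' Thickness is the distance between the mean upper-leaflet and mean
#' lower-leaflet phosphate z inside each xy grid cell, averaged over frames.
#' Cells that never saw phosphates from both leaflets are `NA` (undefined),
#' never zero-filled.
#'
#' @slot origin numeric length-2, xy of the grid corner (cell \[1,1\] lower
#'   left), nm.
#' @slot spacing numeric cell edge length, nm.
#' @slot thickness numeric nx x ny matrix of mean thickness, nm (`NA` where
#'   undefined).
#' @slot counts integer nx x ny matrix of per-cell frame-sample counts.
#' @seealso [thicknessMap()], [thicknessDifference()]
#' @export
setClass("ThicknessMap",
  representation(
    origin = "numeric",
    spacing = "numeric",
    thickness = "matrix",
    counts = "matrix"
  )
)

setValidity("ThicknessMap", function(object) {
  msgs <- character()
  if (length(object@origin) != 2) msgs <- c(msgs, "origin must be xy (length 2)")
  if (length(object@spacing) != 1 || object@spacing <= 0) {
    msgs <- c(msgs, "spacing must be a single positive number")
  }
  if (!all(dim(object@thickness) == dim(object@counts))) {
    msgs <- c(msgs, "thickness and counts grids must have identical shape")
  } else {
    def <- object@counts > 0
    if (any(is.na(object@thickness[def]))) {
      msgs <- c(msgs, "cells with samples must have a thickness value")
    }
    if (any(object@thickness[def] < 0, na.rm = TRUE)) {
      msgs <- c(msgs, "thickness must be >= 0 where defined")
    }
    if (any(!is.na(object@thickness[!def]))) {
      msgs <- c(msgs, "cells without samples must be NA, not zero-filled")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' MetricSummary: pooled per-system metric means and spreads
#'
#' One summary per simulated system (wildtype, negative control, or variant),
#' pooled over replicate trajectories by [summarizeMetrics()].
#'
#' @slot label system name.
#' @slot nReplicates number of replicate trajectories pooled.
#' @slot stats `data.frame` with columns `metric`, `mean`, `sd_frames`
#'   (per-frame SD pooled over replicates), `sd_replicates` (SD of replicate
#'   means; `NA` with a single replicate), `n` (total frames pooled).
#' @slot flipCounts integer vector of flip-event counts, one per replicate.
#' @slot maxThicknessDiff numeric, max |thickness difference| vs the
#'   reference map, nm (`NA` if not computed).
#' @slot maxHeadgroupDz numeric, max |mean headgroup z-displacement| over
#'   tracked lipids, nm (`NA` if not computed).
#' @export
setClass("MetricSummary",
  representation(
    label = "character",
    nReplicates = "integer",
    stats = "data.frame",
    flipCounts = "integer",
    maxThicknessDiff = "numeric",
    maxHeadgroupDz = "numeric"
  )
)

setValidity("MetricSummary", function(object) {
  msgs <- character()
  if (object@nReplicates < 1L) msgs <- c(msgs, "at least one replicate required")
  if (any(object@flipCounts < 0L)) msgs <- c(msgs, "flip counts must be >= 0")
  s <- object@stats
  if (nrow(s) && any(s$sd_frames < 0, na.rm = TRUE)) {
    msgs <- c(msgs, "SDs must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' VariantReport: triage flags and label for one variant
#'
#' Produced by [triageVariant()]. The triage label is a pure function of the
#' flags: `activating-candidate` if a rotamer flip is observed without
#' membrane/pocket/hydration damage flags, `neutral-like` if no flag is set,
#' otherwise `damaging-candidate`.
#'
#' @slot variant variant system label.
#' @slot flags named logical vector: `flip_observed`, `elevated_rmsd`,
#'   `pocket_enlarged`, `hydration_changed`, `membrane_perturbed`.
#' @slot triage one of `"activating-candidate"`, `"damaging-candidate"`,
#'   `"neutral-like"`.
#' @slot thresholds named list of the thresholds used.
#' @slot details named list of the numeric comparisons behind each flag.
#' @export
setClass("VariantReport",
  representation(
    variant = "character",
    flags = "logical",
    triage = "character",
    thresholds = "list",
    details = "list"
  )
)

setValidity("VariantReport", function(object) {
  need <- c("flip_observed", "elevated_rmsd", "pocket_enlarged",
            "hydration_changed", "membrane_perturbed")
  msgs <- character()
  if (!all(need %in% names(object@flags))) {
    msgs <- c(msgs, paste("flags must include:", paste(need, collapse = ", ")))
  }
  if (!object@triage %in% c("activating-candidate", "damaging-candidate",
                            "neutral-like")) {
    msgs <- c(msgs, "unknown triage label")
  }
  if (length(msgs)) msgs else TRUE
})
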