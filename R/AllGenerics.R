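#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small accessor generics so user code never touches slots directly:
#' `atoms()` returns the atom table, `coords()` the coordinates (model
#' reference coordinates, or the N x 3 x F array for a trajectory),
#' `boxLengths()` the orthorhombic box lengths in nm, `helixTable()` and
#' `bwAnchors()` the TM annotations, `nFrames()` and `frameTimes()` the
#' trajectory shape, and `frameCoords()` one frame's N x 3 coordinate matrix.
#'
#' @param x a [StructureModel-class] or [Trajectory-class]
#' @param i frame index (1-based) for `frameCoords`
#' @return the corresponding component; see the class documentation for types.
#' @name accessors
#' @aliases atoms coords boxLengths helixTable bwAnchors nFrames frameTimes
#'   frameCoords
#' @examples
#' cfg <- generatorConfig(seed = 1, n_frames = 2, lipids_per_leaflet = 8,
#'                        waters = list(count = 10))
#' m <- buildSystem(cfg)
#' nrow(atoms(m))
#' boxLengths(m)
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("boxLengths", function(x) standardGeneric("boxLengths"))
#' @rdname accessors
#' @export
setGeneric("helixTable", function(x) standardGeneric("helixTable"))
#' @rdname accessors
#' @export
setGeneric("bwAnchors", function(x) standardGeneric("bwAnchors"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname accessors
setMethod("atoms", "StructureModel", function(x) x@atoms)
#' @rdname accessors
setMethod("coords", "StructureModel", function(x) x@coords)
#' @rdname accessors
setMethod("boxLengths", "StructureModel", function(x) x@box)
#' @rdname accessors
setMethod("helixTable", "StructureModel", function(x) x@helixTable)
#' @rdname accessors
setMethod("bwAnchors", "StructureModel", function(x) x@bwAnchors)

#' @rdname accessors
setMethod("atoms", "Trajectory", function(x) x@model@atoms)
#' @rdname accessors
setMethod("coords", "Trajectory", function(x) x@coords)
#' @rdname accessors
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
#' @rdname accessors
setMethod("frameTimes", "Trajectory", function(x) x@times)
#' @rdname accessors
setMethod("frameCoords", "Trajectory", function(x, i) {
  stopifnot(i >= 1, i <= dim(x@coords)[3])
  x@coords[, , i, drop = TRUE]
})
#' @rdname accessors
setMethod("boxLengths", "Trajectory", function(x) x@boxes)

#' Model accessor for a Trajectory
#' @param x a [Trajectory-class]
#' @return the shared [StructureModel-class]
#' @export
setGeneric("trajectoryModel", function(x) standardGeneric("trajectoryModel"))
#' @rdname trajectoryModel
setMethod("trajectoryModel", "Trajectory", function(x) x@model)

#' Accessors for DihedralSeries
#' @param x a [DihedralSeries-class]
#' @return `chi1Angles`: numeric degrees; `rotamerStates`: character labels;
#'   `flipEvents`: the event `data.frame`.
#' @name dihedral-accessors
NULL

#' @rdname dihedral-accessors
#' @export
setGeneric("chi1Angles", function(x) standardGeneric("chi1Angles"))
#' @rdname dihedral-accessors
#' @export
setGeneric("rotamerStates", function(x) standardGeneric("rotamerStates"))
#' @rdname dihedral-accessors
#' @export
setGeneric("flipEvents", function(x) standardGeneric("flipEvents"))
#' @rdname dihedral-accessors
setMethod("chi1Angles", "DihedralSeries", function(x) x@chi1)
#' @rdname dihedral-accessors
setMethod("rotamerStates", "DihedralSeries", function(x) x@states)
#' @rdname dihedral-accessors
setMethod("flipEvents", "DihedralSeries", function(x) x@events)
#' @rdname dihedral-accessors
setMethod("frameTimes", "DihedralSeries", function(x) x@times)

#' Accessors for ThicknessMap
#' @param x a [ThicknessMap-class]
#' @return `thicknessValues`: nx x ny numeric matrix (NA = undefined cell);
#'   `cellCounts`: matching sample counts; `gridOrigin`/`gridSpacing`: grid
#'   geometry in nm.
#' @name thickness-accessors
NULL

#' @rdname thickness-accessors
#' @export
setGeneric("thicknessValues", function(x) standardGeneric("thicknessValues"))
#' @rdname thickness-accessors
#' @export
setGeneric("cellCounts", function(x) standardGeneric("cellCounts"))
#' @rdname thickness-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname thickness-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname thickness-accessors
setMethod("thicknessValues", "ThicknessMap", function(x) x@thickness)
#' @rdname thickness-accessors
setMethod("cellCounts", "ThicknessMap", function(x) x@counts)
#' @rdname thickness-accessors
setMethod("gridOrigin", "ThicknessMap", function(x) x@origin)
#' @rdname thickness-accessors
setMethod("gridSpacing", "ThicknessMap", function(x) x@spacing)

#' Accessors for triage results
#' @param x a [VariantReport-class] or [MetricSummary-class]
#' @return `triageLabel`: the triage string; `triageFlags`: named logicals;
#'   `metricStats`: the pooled statistics `data.frame`.
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
setGeneric("triageLabel", function(x) standardGeneric("triageLabel"))
#' @rdname report-accessors
#' @export
setGeneric("triageFlags", function(x) standardGeneric("triageFlags"))
#' @rdname report-accessors
#' @export
setGeneric("metricStats", function(x) standardGeneric("metricStats"))
#' @rdname report-accessors
setMethod("triageLabel", "VariantReport", function(x) x@triage)
#' @rdname report-accessors
setMethod("triageFlags", "VariantReport", function(x) x@flags)
#' @rdname report-accessors
setMethod("metricStats", "MetricSummary", function(x) x@stats)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel:", nrow(a), "atoms\n")
  if (nrow(a)) {
    tb <- table(a$class)
    cat(" ", paste(sprintf("%s: %d", names(tb), as.integer(tb)),
                   collapse = ", "), "\n")
  }
  cat("  box (nm):", paste(sprintf("%.3f", object@box), collapse = " x "), "\n")
  if (nrow(object@helixTable)) {
    cat("  TM helices:", nrow(object@helixTable),
        sprintf("(residues %d-%d)", min(object@helixTable$start),
                max(object@helixTable$end)), "\n")
  }
})

setMethod("show", "Trajectory", function(object) {
  f <- dim(object@coords)[3]
  cat("Trajectory:", f, "frames x", dim(object@coords)[1], "atoms,",
      sprintf("t = %.3f..%.3f ns\n", object@times[1], object@times[f]))
})

setMethod("show", "DihedralSeries", function(object) {
  cat("DihedralSeries: chi1 of residue", object@resid, "over",
      length(object@chi1), "frames\n")
  tb <- table(object@states)
  cat("  states:", paste(sprintf("%s: %d", names(tb), as.integer(tb)),
                         collapse = ", "), "\n")
  cat("  flip events:", nrow(object@events), "\n")
})

setMethod("show", "ThicknessMap", function(object) {
  d <- dim(object@thickness)
  cat("ThicknessMap:", d[1], "x", d[2], "cells, spacing",
      object@spacing, "nm\n")
  def <- object@counts > 0
  if (any(def)) {
    cat(sprintf("  defined cells: %d/%d, mean thickness %.3f nm\n",
                sum(def), length(def), mean(object@thickness[def])))
  } else {
    cat("  no defined cells\n")
  }
})

setMethod("show", "MetricSummary", function(object) {
  cat("MetricSummary for", object@label, "(", object@nReplicates,
      "replicate(s) )\n")
  print(object@stats, row.names = FALSE, digits = 4)
  cat("  flip events per replicate:",
      paste(object@flipCounts, collapse = ", "), "\n")
})

setMethod("show", "VariantReport", function(object) {
  cat("VariantReport:", object@variant, "->", object@triage, "\n")
  on <- names(object@flags)[object@flags]
  cat("  flags set:", if (length(on)) paste(on, collapse = ", ") else "none",
      "\n")
})
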