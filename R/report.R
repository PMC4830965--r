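#' @include AllClasses.R
NULL

#' Run the full per-trajectory analysis bundle
#'
#' Convenience driver running every metric the triage consumes on one
#' trajectory: TM backbone RMSD, chi1 rotamer series and flips on the probe
#' residue, pocket volume (when a pocket definition is given), hydration
#' around a residue, one inter-residue distance, and membrane readouts
#' (thickness map; headgroup profile near a residue). Any stage whose inputs
#' are absent is skipped with an `NA`/`NULL` entry.
#'
#' @param traj a [Trajectory-class]
#' @param reference reference [StructureModel-class] for RMSD/pocket
#'   superposition (default: the trajectory's own model)
#' @param probeResid chi1 probe residue (default 286); `NA` skips
#' @param minDwell flip dwell criterion, frames
#' @param pocket optional pocket definition (see [definePocketResidues()])
#' @param hydrationResid optional residue for [hydrationCountSeries()]
#' @param distancePair optional length-2 residue ids for
#'   [residueDistanceSeries()]
#' @param headgroupResid optional residue for [headgroupProfile()]
#' @param referenceMap optional wildtype [ThicknessMap-class] to difference
#'   against
#' @param gridSpacing thickness-map grid, nm
#' @return a named list of metric results (the "metrics bundle" consumed by
#'   [summarizeMetrics()])
#' @export
analyzeTrajectory <- function(traj, reference = trajectoryModel(traj),
                              probeResid = 286L, minDwell = 5L,
                              pocket = NULL, hydrationResid = NULL,
                              distancePair = NULL, headgroupResid = NULL,
                              referenceMap = NULL, gridSpacing = 0.2) {
  out <- list()
  ht <- traj@model@helixTable
  out$rmsd <- if (nrow(ht)) tmRmsdSeries(traj, reference)$rmsd_nm else NULL
  out$chi1 <- NULL
  out$flips <- NA_integer_
  if (!is.na(probeResid)) {
    ds <- tryCatch(chi1Series(traj, probeResid, minDwell = minDwell),
                   error = function(e) NULL)
    if (!is.null(ds)) {
      out$chi1 <- ds
      out$flips <- nrow(ds@events)
    }
  }
  out$volume <- if (!is.null(pocket)) {
    pocketVolumeSeries(traj, pocket, reference)$volume_nm3
  } else NULL
  out$hydration <- if (!is.null(hydrationResid)) {
    hydrationCountSeries(traj, hydrationResid)$n_waters
  } else NULL
  out$distance <- if (!is.null(distancePair)) {
    residueDistanceSeries(traj, distancePair[1], distancePair[2])$distance_nm
  } else NULL
  out$thicknessMap <- tryCatch(thicknessMap(traj, gridSpacing),
                               error = function(e) NULL)
  out$thicknessDiffMax <- NA_real_
  if (!is.null(referenceMap) && !is.null(out$thicknessMap)) {
    dm <- thicknessDifference(out$thicknessMap, referenceMap)
    v <- dm@thickness[dm@counts > 0]
    if (length(v)) out$thicknessDiffMax <- max(abs(v))
  }
  out$headgroupDzMax <- NA_real_
  if (!is.null(headgroupResid)) {
    hp <- headgroupProfile(traj, headgroupResid)
    if (nrow(hp)) out$headgroupDzMax <- max(abs(hp$dz_nm))
  }
  out
}

.poolMetric <- function(replicates, what) {
  vals <- lapply(replicates, function(r) r[[what]])
  vals <- vals[!vapply(vals, is.null, TRUE)]
  if (!length(vals)) {
    return(data.frame(metric = what, mean = NA_real_, sd_frames = NA_real_,
                      sd_replicates = NA_real_, n = 0L))
  }
  allv <- unlist(vals)
  repMeans <- vapply(vals, mean, 1.0)
  data.frame(
    metric = what,
    mean = mean(allv),
    sd_frames = if (length(allv) > 1) stats::sd(allv) else 0,
    sd_replicates = if (length(vals) > 1) stats::sd(repMeans) else NA_real_,
    n = length(allv)
  )
}

#' Pool replicate metric bundles into a MetricSummary
#'
#' Means and SDs are pooled across replicate trajectories of one system
#' (mirroring per-system averages over simulation triplicates): `sd_frames`
#' is the SD over all pooled frames, `sd_replicates` the SD of replicate
#' means (`NA` with a single replicate).
#'
#' @param label system name (e.g. `"wildtype"`, `"F290S"`)
#' @param replicates a non-empty list of metric bundles from
#'   [analyzeTrajectory()]
#' @return a [MetricSummary-class]
#' @export
summarizeMetrics <- function(label, replicates) {
  if (!length(replicates)) stop("empty metrics bundle for ", label)
  stats <- do.call(rbind, lapply(
    c("rmsd", "volume", "hydration", "distance"),
    function(w) .poolMetric(replicates, w)))
  flips <- vapply(replicates, function(r) {
    f <- r$flips
    if (is.null(f) || is.na(f)) 0L else as.integer(f)
  }, 1L)
  tmax <- suppressWarnings(max(vapply(replicates, function(r) {
    v <- r$thicknessDiffMax
    if (is.null(v)) NA_real_ else v
  }, 1.0), na.rm = TRUE))
  hmax <- suppressWarnings(max(vapply(replicates, function(r) {
    v <- r$headgroupDzMax
    if (is.null(v)) NA_real_ else v
  }, 1.0), na.rm = TRUE))
  new("MetricSummary", label = label, nReplicates = length(replicates),
      stats = stats, flipCounts = flips,
      maxThicknessDiff = if (is.finite(tmax)) tmax else NA_real_,
      maxHeadgroupDz = if (is.finite(hmax)) hmax else NA_real_)
}

#' Default triage thresholds
#'
#' `k`: SD multiplier for "elevated vs wildtype" comparisons;
#' `rmsd_floor_nm`, `pocket_floor_nm3`, `hydration_floor`: minimum absolute
#' excess required for the respective flag (guards against flagging on a
#' zero-variance wildtype); `thickness_nm` and `headgroup_nm`: absolute
#' membrane-perturbation thresholds.
#'
#' @return named list of thresholds
#' @export
triageThresholds <- function() {
  list(k = 2, rmsd_floor_nm = 0.02, pocket_floor_nm3 = 0.05,
       hydration_floor = 2, thickness_nm = 0.1, headgroup_nm = 0.2)
}

.statRow <- function(summary, metric) {
  s <- summary@stats
  s[s$metric == metric, , drop = FALSE]
}

.exceeds <- function(v, wt, k, floor_) {
  if (nrow(v) == 0 || nrow(wt) == 0 || is.na(v$mean) || is.na(wt$mean)) {
    return(FALSE)
  }
  sd <- wt$sd_frames
  if (is.na(sd)) sd <- 0
  v$mean > wt$mean + max(k * sd, floor_)
}

#' Triage a variant against wildtype (and a negative control)
#'
#' Sets the five flags by threshold comparisons against the wildtype
#' summary and maps them to a label: `activating-candidate` if the rotamer
#' flip is observed without membrane/pocket/hydration damage flags,
#' `neutral-like` if no flag is set, else `damaging-candidate`. The flip
#' flag requires flips in a majority of variant replicates and none in any
#' wildtype replicate. If a negative-control summary is supplied it is
#' triaged against the wildtype too, and a warning is issued if it does not
#' come out neutral-like (the control contract).
#'
#' @param variant,wildtype [MetricSummary-class] objects computed with
#'   identical analysis settings (identical metric sets are enforced)
#' @param control optional negative-control [MetricSummary-class]
#' @param thresholds see [triageThresholds()]; partial lists are completed
#'   with the defaults
#' @return a [VariantReport-class]
#' @export
triageVariant <- function(variant, wildtype, control = NULL,
                          thresholds = triageThresholds()) {
  th <- utils::modifyList(triageThresholds(), thresholds)
  if (!identical(variant@stats$metric, wildtype@stats$metric)) {
    stop("variant and wildtype summaries hold different metric sets")
  }
  flags <- c(
    flip_observed =
      mean(variant@flipCounts > 0) > 0.5 && all(wildtype@flipCounts == 0),
    elevated_rmsd = .exceeds(.statRow(variant, "rmsd"),
                             .statRow(wildtype, "rmsd"),
                             th$k, th$rmsd_floor_nm),
    pocket_enlarged = .exceeds(.statRow(variant, "volume"),
                               .statRow(wildtype, "volume"),
                               th$k, th$pocket_floor_nm3),
    hydration_changed = local({
      v <- .statRow(variant, "hydration")
      w <- .statRow(wildtype, "hydration")
      if (!nrow(v) || !nrow(w) || is.na(v$mean) || is.na(w$mean)) FALSE
      else {
        sd <- ifelse(is.na(w$sd_frames), 0, w$sd_frames)
        abs(v$mean - w$mean) > max(th$k * sd, th$hydration_floor)
      }
    }),
    membrane_perturbed =
      (!is.na(variant@maxThicknessDiff) &&
         variant@maxThicknessDiff > th$thickness_nm) ||
      (!is.na(variant@maxHeadgroupDz) &&
         variant@maxHeadgroupDz > th$headgroup_nm)
  )
  damage <- flags[["pocket_enlarged"]] || flags[["hydration_changed"]] ||
            flags[["membrane_perturbed"]]
  label <- if (flags[["flip_observed"]] && !damage) {
    "activating-candidate"
  } else if (!any(flags)) {
    "neutral-like"
  } else {
    "damaging-candidate"
  }
  rep <- new("VariantReport", variant = variant@label, flags = flags,
             triage = label, thresholds = th,
             details = list(
               variant_stats = variant@stats,
               wildtype_stats = wildtype@stats,
               variant_flips = variant@flipCounts,
               wildtype_flips = wildtype@flipCounts,
               max_thickness_diff_nm = variant@maxThicknessDiff,
               max_headgroup_dz_nm = variant@maxHeadgroupDz))
  if (!is.null(control)) {
    ctrl <- triageVariant(control, wildtype, control = NULL,
                          thresholds = th)
    if (ctrl@triage != "neutral-like") {
      warning("negative control '", control@label,
              "' is not neutral-like under these thresholds")
    }
  }
  rep
}

#' Write a variant report to disk
#'
#' Emits a machine-readable YAML document and, beside it, a human-readable
#' text summary (`<path>.txt`).
#'
#' @param report a [VariantReport-class]
#' @param path output YAML path
#' @return invisibly, the YAML path
#' @export
writeReport <- function(report, path) {
  doc <- list(
    variant = report@variant,
    triage = report@triage,
    flags = as.list(report@flags),
    thresholds = report@thresholds,
    external_energies = list(   # reserved for externally computed inputs
      ligand_binding_kcal = NULL,
      gprotein_binding_kcal = NULL
    )
  )
  yaml::write_yaml(doc, path)
  txt <- c(
    sprintf("Variant %s: %s", report@variant, report@triage),
    sprintf("  %-18s %s", names(report@flags),
            ifelse(report@flags, "YES", "no"))
  )
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
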