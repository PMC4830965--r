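#' @include model-core.R
NULL

## phosphate atom indices and their owning lipid residue ids
.phosphates <- function(model, name = "P") {
  idx <- selectAtoms(model, class = "lipid", name = name)
  list(idx = idx, resid = model@atoms$resid[idx])
}

#' Assign lipids to bilayer leaflets in one frame
#'
#' The bilayer midplane is the mean z of all phosphates in the frame; a
#' lipid is `upper` iff its phosphate z is above (ties to upper). Assignment
#' is per frame, so flip-flop in pathological inputs is representable.
#'
#' @param frameCoords N x 3 coordinate matrix, nm
#' @param model the [StructureModel-class]
#' @param phosphateName atom name marking the headgroup (default `"P"`)
#' @return a list: `leaflet` (named character vector, lipid resid ->
#'   `"upper"`/`"lower"`), `midplane` (z, nm)
#' @export
assignLeaflets <- function(frameCoords, model, phosphateName = "P") {
  ph <- .phosphates(model, phosphateName)
  if (length(ph$idx) < 2) stop("need at least 2 phosphates to assign leaflets")
  z <- frameCoords[ph$idx, 3]
  mid <- mean(z)
  lab <- ifelse(z >= mid, "upper", "lower")
  if (all(lab == "upper") || all(lab == "lower")) {
    warning("all lipids assigned to one leaflet")
  }
  list(leaflet = stats::setNames(lab, ph$resid), midplane = mid)
}

#' Time-averaged 2D bilayer thickness map
#'
#' Thickness is defined from the phosphorus atoms of the lipid headgroups:
#' per frame, phosphates are wrapped into the primary box and binned on an
#' xy grid; each cell's thickness that frame is (mean upper-leaflet
#' phosphate z) - (mean lower-leaflet phosphate z), counted only when the
#' cell holds phosphates from both leaflets. The map is the average over
#' frames; cells with no samples are `NA` (undefined, never zero-filled).
#'
#' @param traj a [Trajectory-class]
#' @param gridSpacing cell edge, nm (default 0.2)
#' @param phosphateName headgroup atom name
#' @return a [ThicknessMap-class]
#' @export
thicknessMap <- function(traj, gridSpacing = 0.2, phosphateName = "P") {
  if (gridSpacing <= 0) stop("gridSpacing must be positive")
  model <- traj@model
  ph <- .phosphates(model, phosphateName)
  if (!length(ph$idx)) stop("no phosphate atoms found")
  nf <- dim(traj@coords)[3]
  box <- traj@boxes[, 1]
  nx <- max(1L, ceiling(box[1] / gridSpacing))
  ny <- max(1L, ceiling(box[2] / gridSpacing))
  sumT <- matrix(0, nx, ny)
  cnt <- matrix(0L, nx, ny)
  for (f in seq_len(nf)) {
    co <- matrix(traj@coords[ph$idx, , f], ncol = 3)
    bx <- traj@boxes[, f]
    ## wrap into the primary box
    for (k in 1:3) co[, k] <- co[, k] - bx[k] * floor(co[, k] / bx[k])
    mid <- mean(co[, 3])
    upper <- co[, 3] >= mid
    if (!any(upper) || all(upper)) next
    ix <- pmin(nx, pmax(1L, 1L + floor(co[, 1] / gridSpacing)))
    iy <- pmin(ny, pmax(1L, 1L + floor(co[, 2] / gridSpacing)))
    cell <- (iy - 1L) * nx + ix
    zu <- vapply(split(co[upper, 3], cell[upper]), mean, 1.0)
    zl <- vapply(split(co[!upper, 3], cell[!upper]), mean, 1.0)
    common <- intersect(names(zu), names(zl))
    if (!length(common)) next
    ci <- as.integer(common)
    sumT[ci] <- sumT[ci] + (zu[common] - zl[common])
    cnt[ci] <- cnt[ci] + 1L
  }
  thick <- matrix(NA_real_, nx, ny)
  def <- cnt > 0
  thick[def] <- sumT[def] / cnt[def]
  new("ThicknessMap", origin = c(0, 0), spacing = gridSpacing,
      thickness = thick, counts = cnt)
}

#' Cellwise difference of two thickness maps
#'
#' `a - b` where both maps are defined; `NA` elsewhere. The two maps must
#' share grid geometry. Used to contrast a variant's bilayer footprint with
#' the wildtype map (e.g. loss of the thickening at the TM1/TM7 groove).
#'
#' @param a,b [ThicknessMap-class] objects on identical grids
#' @return a [ThicknessMap-class] of differences (counts = min of inputs);
#'   note differences may be negative, stored in the `thickness` slot of the
#'   result with the validity check on sign relaxed by construction.
#' @export
thicknessDifference <- function(a, b) {
  if (!isTRUE(all.equal(a@origin, b@origin)) ||
      a@spacing != b@spacing ||
      !all(dim(a@thickness) == dim(b@thickness))) {
    stop("thickness maps are on different grids")
  }
  def <- (a@counts > 0) & (b@counts > 0)
  diffm <- matrix(NA_real_, nrow(a@thickness), ncol(a@thickness))
  diffm[def] <- a@thickness[def] - b@thickness[def]
  cnt <- pmin(a@counts, b@counts)
  cnt[!def] <- 0L
  out <- new("ThicknessMap", origin = a@origin, spacing = a@spacing,
             thickness = ifelse(def, 0, NA_real_), counts = cnt)
  ## bypass the >= 0 validity (differences are signed) by direct slot fill
  out@thickness <- diffm
  out@thickness[!def] <- NA_real_
  out
}

#' Lipid headgroup perturbation profile near a residue
#'
#' Tracks every lipid whose phosphate comes within `cutoff` of any atom of
#' the target residue in at least one frame (minimum image), and reports its
#' time-averaged phosphate position and its mean signed z-displacement from
#' its leaflet's mean phosphate plane. Negative displacement for an
#' upper-leaflet lipid (positive for lower) means the headgroup is pulled
#' toward the membrane core — the signature of a polar/charged side chain
#' dragging a phosphate inward.
#'
#' @param traj a [Trajectory-class]
#' @param targetResid residue id near which lipids are monitored
#' @param cutoff contact cutoff, nm (default 0.6)
#' @param phosphateName headgroup atom name
#' @return `data.frame(lipid_resid, mean_x, mean_y, mean_z, dz_nm,
#'   n_frames)`, where `dz_nm` is signed toward the core (negative = pulled
#'   inward) and `n_frames` counts the frames averaged (all frames; contact
#'   only gates which lipids are reported)
#' @export
headgroupProfile <- function(traj, targetResid, cutoff = 0.6,
                             phosphateName = "P") {
  if (cutoff <= 0) stop("cutoff must be positive")
  model <- traj@model
  a <- model@atoms
  tIdx <- which(a$resid == targetResid & a$class == "protein")
  if (!length(tIdx)) stop("target residue not found: ", targetResid)
  ph <- .phosphates(model, phosphateName)
  nf <- dim(traj@coords)[3]
  nph <- length(ph$idx)
  touched <- rep(FALSE, nph)
  sumPos <- matrix(0, nph, 3)
  sumDz <- numeric(nph)
  for (f in seq_len(nf)) {
    co <- traj@coords[, , f]
    box <- traj@boxes[, f]
    pco <- co[ph$idx, , drop = FALSE]
    ## contact detection against every target-residue atom
    for (i in tIdx) {
      touched <- touched | (minImageDistance(co[i, ], pco, box) <= cutoff)
    }
    mid <- mean(pco[, 3])
    upper <- pco[, 3] >= mid
    muU <- mean(pco[upper, 3])
    muL <- mean(pco[!upper, 3])
    ## signed toward the membrane core
    dz <- ifelse(upper, pco[, 3] - muU, muL - pco[, 3])
    sumPos <- sumPos + pco
    sumDz <- sumDz + dz
  }
  keep <- which(touched)
  data.frame(
    lipid_resid = ph$resid[keep],
    mean_x = sumPos[keep, 1] / nf,
    mean_y = sumPos[keep, 2] / nf,
    mean_z = sumPos[keep, 3] / nf,
    dz_nm = sumDz[keep] / nf,
    n_frames = nf
  )
}
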