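#' @include model-core.R
#' @include structure-metrics.R
NULL

#' Bondi van der Waals radii (nm), by element symbol
#'
#' Standard element-based vdW radii used for voxel occlusion in
#' [pocketVolumeSeries()]. User-overridable by passing a modified copy.
#'
#' @return named numeric vector of radii in nm
#' @examples
#' bondiRadii()[["C"]]
#' @export
bondiRadii <- function() {
  c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, F = 0.147, P = 0.180,
    S = 0.180, CL = 0.175, BR = 0.185, I = 0.198, NA_ = 0.227, K = 0.275,
    DEFAULT = 0.170)
}

.vdwFor <- function(elements, table) {
  r <- table[toupper(elements)]
  r[is.na(r)] <- table[["DEFAULT"]]
  unname(r)
}

#' Define binding-pocket residues from a reference ligand
#'
#' Protein residues with any heavy atom within `cutoff` (minimum image) of
#' any heavy atom of the ligand residue. With the 0.7 nm default this is the
#' classic crystallographic pocket definition around a co-crystallised
#' antagonist.
#'
#' @param model a [StructureModel-class] containing the ligand
#' @param ligandResid residue id of the ligand
#' @param cutoff nm (default 0.7); a cutoff of 0 yields an empty set with a
#'   warning
#' @return a list with elements `resids` (integer vector), `source`,
#'   `cutoff`
#' @export
definePocketResidues <- function(model, ligandResid, cutoff = 0.7) {
  a <- model@atoms
  lig <- which(a$resid == ligandResid & a$class == "ligand" & a$element != "H")
  if (!length(lig)) stop("no ligand heavy atoms in residue ", ligandResid)
  prot <- which(a$class == "protein" & a$element != "H")
  hit <- rep(FALSE, length(prot))
  for (i in lig) {
    hit <- hit | (minImageDistance(model@coords[i, ],
                                   model@coords[prot, , drop = FALSE],
                                   model@box) <= cutoff)
  }
  resids <- sort(unique(a$resid[prot[hit]]))
  if (!length(resids)) warning("empty pocket definition at cutoff ", cutoff)
  list(resids = as.integer(resids), source = "reference-ligand cutoff",
       cutoff = cutoff)
}

#' Explicit-list pocket definition
#' @param resids integer vector of residue ids
#' @return a pocket definition list (see [definePocketResidues()])
#' @export
pocketFromResidues <- function(resids) {
  if (!length(resids)) stop("pocket definition must be non-empty")
  list(resids = as.integer(sort(unique(resids))), source = "explicit list",
       cutoff = NA_real_)
}

## deterministic quasi-uniform unit directions (Fibonacci sphere); used for
## the supporting-halfspace convex-hull membership test
.sphereDirections <- function(k = 162L) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

#' Per-frame binding-pocket volume by grid-void detection
#'
#' Tracks the non-occluded space enclosed by the pocket residues. Per frame:
#' the frame is rigidly superposed onto the reference model on the pocket
#' residues' heavy atoms ([kabschFit()]), then (1) a shared voxel grid is
#' laid over the reference pocket bounding box padded by probe + max vdW;
#' (2) voxels whose centre lies within vdW(atom) + probe of any system heavy
#' atom are occluded; (3) free voxels outside the convex hull of the pocket
#' heavy-atom centres are discarded (hull membership via a supporting-
#' halfspace test over a fixed set of sphere directions); (4) only the
#' 6-connected component containing the pocket seed (centroid of pocket CA
#' atoms, or the nearest free voxel within 0.3 nm if that is occluded) is
#' kept. Volume = voxel count x voxel^3. An occluded seed with no nearby
#' free voxel gives volume 0 with a warning, not an error.
#'
#' @param traj a [Trajectory-class]
#' @param pocket pocket definition (from [definePocketResidues()] or
#'   [pocketFromResidues()])
#' @param reference reference [StructureModel-class] (defaults to the
#'   trajectory model) defining the shared grid
#' @param voxel voxel edge, nm (default 0.08)
#' @param probe probe radius, nm (default 0.14, a water-sized probe)
#' @param vdwTable named vdW radius table, nm (default [bondiRadii()])
#' @return a list: `volume_nm3` (per-frame numeric), `times`, `voxel`,
#'   `probe`
#' @export
pocketVolumeSeries <- function(traj, pocket, reference = trajectoryModel(traj),
                               voxel = 0.08, probe = 0.14,
                               vdwTable = bondiRadii()) {
  model <- traj@model
  a <- model@atoms
  pocketAtoms <- which(a$resid %in% pocket$resids & a$class == "protein" &
                       a$element != "H")
  if (!length(pocketAtoms)) stop("pocket residues not present in the model")
  heavy <- which(a$element != "H" & a$class != "water")
  radii <- .vdwFor(a$element[heavy], vdwTable)

  refP <- reference@coords[pocketAtoms, , drop = FALSE]
  pad <- probe + max(radii)
  lo <- apply(refP, 2, min) - pad
  hi <- apply(refP, 2, max) + pad
  n <- pmax(1L, ceiling((hi - lo) / voxel))
  ## voxel centres of the shared grid
  cx <- lo[1] + (seq_len(n[1]) - 0.5) * voxel
  cy <- lo[2] + (seq_len(n[2]) - 0.5) * voxel
  cz <- lo[3] + (seq_len(n[3]) - 0.5) * voxel

  ## convex-hull membership of the reference pocket cloud: a point is kept
  ## iff its projection on every test direction stays below the cloud's
  ## support in that direction (outer hull approximation, fixed directions)
  dirs <- .sphereDirections()
  support <- apply(tcrossprod(refP, dirs), 2, max)
  grid <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  insideHull <- array(
    rowSums(sweep(tcrossprod(grid, dirs), 2, support + 1e-9, ">")) == 0,
    dim = n)

  ## seed: centroid of pocket CA atoms (fallback: pocket heavy-atom centroid)
  caIdx <- which(a$resid %in% pocket$resids & a$name == "CA")
  seed <- if (length(caIdx)) colMeans(reference@coords[caIdx, , drop = FALSE])
          else colMeans(refP)

  nf <- dim(traj@coords)[3]
  vols <- numeric(nf)
  for (f in seq_len(nf)) {
    co <- traj@coords[, , f]
    fit <- kabschFit(co[pocketAtoms, , drop = FALSE], refP)
    moved <- sweep(tcrossprod(co[heavy, , drop = FALSE], fit$rotation),
                   2, fit$translation, "+")
    occ <- array(FALSE, dim = n)
    ## mark each atom's occlusion sphere on the grid
    for (k in seq_along(heavy)) {
      r <- radii[k] + probe
      p <- moved[k, ]
      ix <- which(abs(cx - p[1]) <= r)
      if (!length(ix)) next
      iy <- which(abs(cy - p[2]) <= r)
      if (!length(iy)) next
      iz <- which(abs(cz - p[3]) <= r)
      if (!length(iz)) next
      dx2 <- (cx[ix] - p[1])^2
      dy2 <- (cy[iy] - p[2])^2
      dz2 <- (cz[iz] - p[3])^2
      sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r * r
      occ[ix, iy, iz] <- occ[ix, iy, iz] | c(sub)
    }
    free <- !occ & insideHull
    ## connected component (6-connectivity) containing the seed
    si <- pmin(n, pmax(1L, 1L + floor((seed - lo) / voxel)))
    if (!free[si[1], si[2], si[3]]) {
      ## nearest free voxel within 0.3 nm of the seed
      fr <- which(free, arr.ind = TRUE)
      if (nrow(fr)) {
        pos <- cbind(cx[fr[, 1]], cy[fr[, 2]], cz[fr[, 3]])
        dd <- sqrt(rowSums(sweep(pos, 2, seed)^2))
        j <- which.min(dd)
        if (dd[j] <= 0.3) si <- fr[j, ] else si <- NULL
      } else si <- NULL
    }
    if (is.null(si)) {
      warning("pocket seed occluded in frame ", f, "; volume 0")
      vols[f] <- 0
      next
    }
    comp <- .floodFill6(free, si)
    vols[f] <- sum(comp) * voxel^3
  }
  list(volume_nm3 = vols, times = traj@times, voxel = voxel, probe = probe)
}

## 6-connected flood fill on a logical 3D array from a start voxel
.floodFill6 <- function(free, start) {
  n <- dim(free)
  comp <- array(FALSE, dim = n)
  lin <- function(i) i[1] + (i[2] - 1L) * n[1] + (i[3] - 1L) * n[1] * n[2]
  stack <- matrix(as.integer(start), ncol = 3)
  comp[stack] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  while (nrow(stack)) {
    nxt <- vector("list", 6)
    for (o in 1:6) {
      cand <- sweep(stack, 2, offs[o, ], "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= n[1] &
            cand[, 2] >= 1 & cand[, 2] <= n[2] &
            cand[, 3] >= 1 & cand[, 3] <= n[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) next
      keep <- free[cand] & !comp[cand]
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand)) {
        comp[cand] <- TRUE
        nxt[[o]] <- cand
      }
    }
    stack <- do.call(rbind, nxt)
    if (is.null(stack)) break
    stack <- unique(stack)
  }
  comp
}

#' Per-frame count of waters near a residue's CA atom
#'
#' Counts water molecules (judged by their oxygen atom) whose oxygen lies
#' within `cutoff` of the residue's CA under the minimum-image convention —
#' the local-hydration readout used to detect water influx around a variant
#' site.
#'
#' @param traj a [Trajectory-class]
#' @param resid residue id (must have a CA atom)
#' @param cutoff nm (default 0.8)
#' @return `data.frame(time, n_waters)`
#' @export
hydrationCountSeries <- function(traj, resid, cutoff = 0.8) {
  a <- traj@model@atoms
  ca <- which(a$resid == resid & a$name == "CA" & a$class == "protein")
  if (length(ca) != 1) stop("residue ", resid, " has no unique CA atom")
  ow <- which(a$class == "water" &
              a$name %in% c("OW", "O", "OH2") & a$element == "O")
  nf <- dim(traj@coords)[3]
  cnt <- vapply(seq_len(nf), function(f) {
    if (!length(ow)) return(0L)
    co <- traj@coords[, , f]
    sum(minImageDistance(co[ca, ], co[ow, , drop = FALSE],
                         traj@boxes[, f]) <= cutoff)
  }, 1L)
  data.frame(time = traj@times, n_waters = cnt)
}
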