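#' @include model-core.R
NULL

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rigid superposition of `mobile` onto `reference` via SVD of
#' the covariance matrix, with the determinant correction that excludes
#' reflections. The returned transform maps mobile points as
#' `R x + t`; `rmsd` is the post-fit root-mean-square deviation.
#'
#' @param mobile,reference M x 3 coordinate matrices, nm (M >= 3,
#'   non-degenerate)
#' @return a list with elements `rotation` (3 x 3, det = +1),
#'   `translation` (length 3) and `rmsd` (nm)
#' @examples
#' p <- matrix(rnorm(36), 12, 3)
#' kabschFit(p, p)$rmsd
#' @export
kabschFit <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3) {
    stop("mobile and reference must be matching M x 3 matrices")
  }
  if (nrow(mobile) < 3) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate (collinear) point set: superposition is ill-defined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  t <- cr - as.vector(R %*% cm)
  fitted <- sweep(tcrossprod(mobile, R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

## backbone atom indices of the TM helix ranges, in model order
.tmBackboneIdx <- function(model, helixTable, atomNames) {
  a <- model@atoms
  keep <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(helixTable))) {
    keep <- keep | (a$resid >= helixTable$start[i] &
                    a$resid <= helixTable$end[i])
  }
  keep <- keep & a$class == "protein" & a$name %in% atomNames
  idx <- which(keep)
  ## every helix residue must carry all requested backbone atoms
  want <- unlist(lapply(seq_len(nrow(helixTable)), function(i) {
    helixTable$start[i]:helixTable$end[i]
  }))
  got <- table(factor(a$resid[idx], levels = want))
  bad <- names(got)[got < length(atomNames)]
  if (length(bad)) {
    stop("missing backbone atom(s) in residue ", bad[1])
  }
  idx
}

#' Per-frame TM backbone RMSD against a reference structure
#'
#' For every frame, the transmembrane backbone atoms are superposed onto the
#' reference with [kabschFit()] and the post-fit RMSD over the same atoms is
#' reported — the classic receptor-stability readout (a stable receptor
#' stays flat and low; destabilising variants drift upward).
#'
#' @param traj a [Trajectory-class]
#' @param reference the reference [StructureModel-class] (same atom layout)
#' @param helixTable TM residue ranges; defaults to the trajectory model's
#'   annotation
#' @param atomNames backbone atom set; default the 4-atom backbone
#'   `c("N","CA","C","O")`, use `"CA"` for CA-only
#' @return `data.frame(time, rmsd_nm)`, one row per frame
#' @export
tmRmsdSeries <- function(traj, reference = trajectoryModel(traj),
                         helixTable = NULL,
                         atomNames = c("N", "CA", "C", "O")) {
  model <- traj@model
  if (is.null(helixTable)) helixTable <- model@helixTable
  if (!nrow(helixTable)) stop("no TM helix ranges annotated")
  idx <- .tmBackboneIdx(model, helixTable, atomNames)
  refIdx <- .tmBackboneIdx(reference, helixTable, atomNames)
  if (length(idx) != length(refIdx)) {
    stop("trajectory and reference TM backbones differ in atom count")
  }
  refxyz <- reference@coords[refIdx, , drop = FALSE]
  nf <- dim(traj@coords)[3]
  rmsd <- vapply(seq_len(nf), function(f) {
    kabschFit(traj@coords[idx, , f], refxyz)$rmsd
  }, 1.0)
  data.frame(time = traj@times, rmsd_nm = rmsd)
}

## signed torsion angle (IUPAC convention), degrees in (-180, 180]
.torsion <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' chi1 side-chain dihedral of one residue in one frame
#'
#' The chi1 torsion is defined by the atoms N-CA-CB-CG (IUPAC sign
#' convention), the angle whose gauche-to-trans transition constitutes the
#' rotamer toggle switch of residue 6.48 in class-A GPCR activation.
#'
#' @param frameCoords N x 3 coordinate matrix of one frame, nm
#' @param model the [StructureModel-class]
#' @param resid residue id; must carry atoms N, CA, CB and CG
#' @return the chi1 angle in degrees, in (-180, 180]
#' @export
dihedralChi1 <- function(frameCoords, model, resid) {
  a <- model@atoms
  pick <- function(nm) {
    i <- which(a$resid == resid & a$name == nm & a$class == "protein")
    if (length(i) != 1) {
      stop(sprintf("residue %d is missing atom %s", resid, nm))
    }
    i
  }
  i <- vapply(c("N", "CA", "CB", "CG"), pick, 1L)
  .torsion(frameCoords[i[1], ], frameCoords[i[2], ],
           frameCoords[i[3], ], frameCoords[i[4], ])
}

#' Classify a chi1 angle into a rotamer state
#'
#' Standard three-state rotamer windows: `trans` for |angle| >= 120 degrees,
#' `gauche-` for angles in (-120, 0), `gauche+` for \[0, 120). The window
#' bound is closed on the trans side (exactly +/-120 is `trans`), a
#' documented tie-break. Bounds are overridable.
#'
#' @param angle numeric vector of angles in degrees, (-180, 180]
#' @param bound window half-width boundary in degrees (default 120)
#' @return character vector of `"gauche-"`, `"gauche+"`, `"trans"`
#' @examples
#' classifyRotamer(c(-60, 60, 180, 120))
#' @export
classifyRotamer <- function(angle, bound = 120) {
  out <- character(length(angle))
  out[abs(angle) >= bound] <- "trans"
  out[angle > -bound & angle < 0] <- "gauche-"
  out[angle >= 0 & angle < bound] <- "gauche+"
  out
}

#' Detect rotamer flip events in a state series
#'
#' A flip is recorded when the rotamer state changes and the new state then
#' persists for at least `minDwell` frames; shorter excursions are treated
#' as noise and ignored (the dwell criterion operationalises a "transient
#' flip" as opposed to jitter). Events are returned in time order with
#' 1-based frame indices: `start` is the last frame of the old state's
#' occupancy, `end` the first frame of the accepted new state.
#'
#' @param states character vector of per-frame rotamer states, or a
#'   [DihedralSeries-class]
#' @param minDwell minimum persistence, frames (>= 1)
#' @return `data.frame(start, end, from, to)` (0 rows if no flips)
#' @export
detectFlips <- function(states, minDwell = 5L) {
  if (is(states, "DihedralSeries")) states <- states@states
  stopifnot(minDwell >= 1)
  n <- length(states)
  ev <- list()
  if (n == 0) {
    return(data.frame(start = integer(), end = integer(),
                      from = character(), to = character()))
  }
  cur <- states[1]
  curStart <- 1L
  f <- 2L
  while (f <= n) {
    if (states[f] != cur) {
      ## candidate new state: accept only if it persists minDwell frames
      run <- 1L
      while (f + run <= n && states[f + run] == states[f]) run <- run + 1L
      if (run >= minDwell) {
        ev[[length(ev) + 1L]] <- data.frame(
          start = f - 1L, end = f, from = cur, to = states[f],
          stringsAsFactors = FALSE)
        cur <- states[f]
        curStart <- f
        f <- f + run
      } else {
        f <- f + run   # sub-dwell excursion: skip it, keep current state
      }
    } else {
      f <- f + 1L
    }
  }
  if (!length(ev)) {
    return(data.frame(start = integer(), end = integer(),
                      from = character(), to = character()))
  }
  do.call(rbind, ev)
}

#' chi1 series with rotamer states and flip events for one residue
#'
#' Convenience wrapper computing [dihedralChi1()] per frame,
#' [classifyRotamer()] labels and [detectFlips()] events, returned as a
#' [DihedralSeries-class].
#'
#' @param traj a [Trajectory-class]
#' @param resid residue id (must have N, CA, CB, CG)
#' @param minDwell flip persistence criterion, frames
#' @param bound rotamer window boundary, degrees
#' @param stride keep every `stride`-th frame (default 1 = all frames)
#' @return a [DihedralSeries-class]
#' @export
chi1Series <- function(traj, resid, minDwell = 5L, bound = 120, stride = 1L) {
  keep <- seq(1L, dim(traj@coords)[3], by = stride)
  chi1 <- vapply(keep, function(f) {
    dihedralChi1(traj@coords[, , f], traj@model, resid)
  }, 1.0)
  states <- classifyRotamer(chi1, bound)
  new("DihedralSeries", resid = as.integer(resid),
      times = traj@times[keep], chi1 = chi1, states = states,
      events = detectFlips(states, minDwell))
}

#' Per-frame distance between two residues
#'
#' Either the CA-CA distance or the minimum heavy-atom distance, always
#' under the minimum-image convention. Useful for tracking binding-site
#' rearrangements such as the separation of the toggle-switch tryptophan
#' from its aromatic-core partners.
#'
#' @param traj a [Trajectory-class]
#' @param residA,residB residue ids
#' @param mode `"CA"` or `"min-heavy-atom"`
#' @return `data.frame(time, distance_nm)`
#' @export
residueDistanceSeries <- function(traj, residA, residB,
                                  mode = c("CA", "min-heavy-atom")) {
  mode <- match.arg(mode)
  a <- traj@model@atoms
  pick <- function(resid) {
    i <- if (mode == "CA") {
      which(a$resid == resid & a$name == "CA")
    } else {
      which(a$resid == resid & a$element != "H")
    }
    if (!length(i)) stop("unknown residue or no matching atoms: ", resid)
    i
  }
  ia <- pick(residA)
  ib <- pick(residB)
  nf <- dim(traj@coords)[3]
  d <- vapply(seq_len(nf), function(f) {
    co <- traj@coords[, , f]
    box <- traj@boxes[, f]
    min(vapply(ia, function(i) {
      min(minImageDistance(co[i, ], co[ib, , drop = FALSE], box))
    }, 1.0))
  }, 1.0)
  data.frame(time = traj@times, distance_nm = d)
}

#' Ballesteros-Weinstein number of a residue
#'
#' GPCR residue scheme "h.nn": the most conserved residue of helix `h` is
#' h.50 and others are numbered by sequence offset from it. Requires the
#' residue to lie in an annotated helix with a BW anchor.
#'
#' @param model a [StructureModel-class] with helix table and anchors
#' @param resid residue id
#' @return the label string, e.g. `"6.48"`
#' @examples
#' ht <- data.frame(helix = 6:7, start = c(241, 289), end = c(288, 336))
#' m <- StructureModel(
#'   data.frame(serial = 1L, name = "CA", element = "C", resname = "ALA",
#'              resid = 286L, chain = "A", class = "protein"),
#'   matrix(0, 1, 3), c(10, 10, 10), ht, c(`6` = 288L, `7` = 323L))
#' bwNumber(m, 286)
#' @export
bwNumber <- function(model, resid) {
  ht <- model@helixTable
  row <- ht[ht$start <= resid & ht$end >= resid, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("residue ", resid, " lies outside the annotated TM helices")
  }
  h <- row$helix
  anchor <- model@bwAnchors[as.character(h)]
  if (is.na(anchor)) stop("no BW anchor annotated for helix ", h)
  sprintf("%d.%02d", h, 50L + as.integer(resid) - as.integer(anchor))
}
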