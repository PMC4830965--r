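#' @include model-core.R
NULL

## run code with a fixed seed without clobbering the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.unit <- function(v) v / sqrt(sum(v^2))

## internal-coordinate atom placement (NeRF): position D such that
## |CD| = bond, angle(B,C,D) = theta and torsion(A,B,C,D) = phi.
.placeAtom <- function(A, B, C, bond, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  bc <- .unit(C - B)
  n <- .unit(.cross(B - A, bc))
  m <- .cross(n, bc)
  d <- c(-bond * cos(th), bond * sin(th) * cos(ph), -bond * sin(th) * sin(ph))
  C + bc * d[1] + m * d[2] + n * d[3]
}

#' Configuration for the synthetic membrane-receptor generator
#'
#' Builds the validated configuration list consumed by [buildSystem()] and
#' [generateTrajectory()]. The generated system emulates a 7-helix
#' transmembrane bundle in a two-leaflet bilayer of 3-bead lipid
#' pseudo-molecules (choline bead, phosphate `P`, tail bead) plus single-atom
#' `OW` waters. All distances are nm, times ns, angles degrees.
#'
#' @param seed mandatory RNG seed; the single RNG stream is consumed in
#'   documented atom order so identical (seed, config) pairs give
#'   bit-identical output.
#' @param n_frames number of trajectory frames (>= 1)
#' @param dt time per frame, ns
#' @param helix_count number of TM helices (default 7)
#' @param residues_per_helix residues per helix; the default 50 puts the
#'   toggle-switch probe residue 286 (and its 6.52 neighbour 290) in helix 6
#'   and residues 323/326 in helix 7, matching class-A receptor numbering.
#' @param bundle_radius distance of each helix axis from the bundle centre, nm
#' @param helix_radius backbone helix radius, nm (ideal alpha helix 0.23)
#' @param rise helical rise per residue, nm (ideal 0.15)
#' @param twist helical twist per residue, degrees (ideal 100)
#' @param probe_resid residue that carries a CB/CG side chain with a
#'   scriptable chi1 (default 286); `NA` disables the probe.
#' @param chi1_schedule list of `list(frames = c(first, last), angle = deg)`
#'   entries (1-based inclusive frame ranges) scripting the probe chi1;
#'   frames not covered keep the first entry's angle. Default: constant -60
#'   (gauche-).
#' @param bilayer list: `lipids_per_leaflet`, `leaflet_z` (+/- nm of the
#'   phosphate planes), `spacing` (lattice constant, nm), `exclusion_radius`
#'   (no lipids within this xy radius of the bundle axis), optional
#'   `lattice_n` (fixed lattice side; error if too small).
#' @param waters list: `count` (total, split between the two slabs),
#'   `slab_offset` (gap above the phosphate plane, nm), `slab_width` (nm)
#' @param noise_sigma isotropic Gaussian positional noise per atom per
#'   frame, nm
#' @param drift_sigma per-frame random-walk step SD applied cumulatively to
#'   protein atoms (models progressive backbone drift), nm
#' @param lipid_pull optional list `list(target_resid, dz, onset,
#'   lipid_resid = NULL)`: from frame `onset` on, displace one lipid (the one
#'   whose phosphate is closest to the target residue CA unless
#'   `lipid_resid` names it) by `dz` in z.
#' @param thickness_field optional list `list(amplitude, width, center =
#'   NULL)`: a static Gaussian thickness modulation (positive amplitude =
#'   thickening), applied half to each leaflet's phosphates; `center`
#'   defaults to the box centre xy.
#' @param helix_radial_shift optional named numeric, helix index -> outward
#'   radial displacement in nm (e.g. to enlarge the pocket on one side)
#' @param ligand if `TRUE`, place a small 4-atom pseudo-ligand (`LIG`) at the
#'   bundle lumen centre
#' @return a validated `GeneratorConfig` list
#' @seealso [buildSystem()], [generateTrajectory()]
#' @export
generatorConfig <- function(seed,
                            n_frames = 100L,
                            dt = 0.1,
                            helix_count = 7L,
                            residues_per_helix = 50L,
                            bundle_radius = 1.6,
                            helix_radius = 0.23,
                            rise = 0.15,
                            twist = 100,
                            probe_resid = 286L,
                            chi1_schedule = list(list(frames = c(1L, n_frames),
                                                      angle = -60)),
                            bilayer = list(),
                            waters = list(),
                            noise_sigma = 0,
                            drift_sigma = 0,
                            lipid_pull = NULL,
                            thickness_field = NULL,
                            helix_radial_shift = NULL,
                            ligand = FALSE) {
  if (missing(seed)) stop("a seed is mandatory in the generator config")
  bl <- utils::modifyList(
    list(lipids_per_leaflet = 64L, leaflet_z = 1.9, spacing = 0.8,
         exclusion_radius = 2.2, lattice_n = NULL), bilayer)
  wt <- utils::modifyList(
    list(count = 100L, slab_offset = 0.6, slab_width = 1.2), waters)
  cfg <- list(seed = as.integer(seed), n_frames = as.integer(n_frames),
              dt = dt, helix_count = as.integer(helix_count),
              residues_per_helix = as.integer(residues_per_helix),
              bundle_radius = bundle_radius, helix_radius = helix_radius,
              rise = rise, twist = twist,
              probe_resid = probe_resid,
              chi1_schedule = chi1_schedule, bilayer = bl, waters = wt,
              noise_sigma = noise_sigma, drift_sigma = drift_sigma,
              lipid_pull = lipid_pull, thickness_field = thickness_field,
              helix_radial_shift = helix_radial_shift, ligand = ligand)
  if (cfg$n_frames < 1L) stop("n_frames must be >= 1")
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (bl$leaflet_z <= 0) stop("leaflet_z must be positive")
  for (entry in cfg$chi1_schedule) {
    fr <- entry$frames
    if (length(fr) != 2 || fr[1] > fr[2] || fr[1] < 1 || fr[2] > cfg$n_frames) {
      stop("chi1_schedule frame ranges must lie within [1, n_frames]")
    }
  }
  if (!is.null(cfg$lipid_pull)) {
    lp <- cfg$lipid_pull
    if (is.null(lp$dz) || is.null(lp$onset)) {
      stop("lipid_pull needs dz and onset")
    }
    if (lp$onset < 1 || lp$onset > cfg$n_frames) {
      stop("lipid_pull onset must lie within [1, n_frames]")
    }
  }
  class(cfg) <- "GeneratorConfig"
  cfg
}

## lattice sites for one leaflet, centred on the bundle axis; deterministic
## row-major order. Returns an M x 2 matrix of xy, nm.
.leafletSites <- function(bl, protein_present) {
  want <- bl$lipids_per_leaflet
  siteXY <- function(n) {
    u <- (seq_len(n) - (n + 1) / 2) * bl$spacing
    g <- expand.grid(x = u, y = u)
    g <- as.matrix(g)
    if (protein_present) {
      g <- g[sqrt(rowSums(g^2)) >= bl$exclusion_radius, , drop = FALSE]
    }
    g
  }
  if (!is.null(bl$lattice_n)) {
    g <- siteXY(bl$lattice_n)
    if (nrow(g) < want) {
      stop(sprintf("lattice too small: %d free sites for %d lipids",
                   nrow(g), want))
    }
    return(list(sites = g[seq_len(want), , drop = FALSE], n = bl$lattice_n))
  }
  n <- max(2L, ceiling(sqrt(want)))
  repeat {
    g <- siteXY(n)
    if (nrow(g) >= want) {
      return(list(sites = g[seq_len(want), , drop = FALSE], n = n))
    }
    n <- n + 1L
  }
}

#' Build the synthetic membrane-receptor reference system
#'
#' Constructs the [StructureModel-class] described by a [generatorConfig()]:
#' ideal alpha-helices (backbone N, CA, C, O per residue on the helical
#' parametric curve; the probe residue additionally carries CB and CG placed
#' by internal-coordinate construction so its chi1 equals the first
#' scheduled angle), two leaflet lattices of 3-bead lipids, optional
#' pseudo-ligand and single-atom waters, inside an orthorhombic box sized to
#' contain everything. Water placement is the only random element and is
#' drawn from the config seed, so the builder is deterministic.
#'
#' @param config a [generatorConfig()]
#' @return a [StructureModel-class] with helix table and BW anchors attached
#'   (with the default layout: helix-6 anchor residue 288 = 6.50, helix-7
#'   anchor 323 = 7.50)
#' @export
buildSystem <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  bl <- config$bilayer
  rph <- config$residues_per_helix
  nms <- character()
  ele <- character()
  resname <- character()
  resid <- integer()
  chain <- character()
  xyz <- matrix(0, 0, 3)

  first_chi1 <- if (length(config$chi1_schedule)) {
    config$chi1_schedule[[1]]$angle
  } else -60

  ## --- protein: ideal helix bundle --------------------------------------
  if (config$helix_count > 0) {
    for (h in seq_len(config$helix_count)) {
      th <- 2 * pi * (h - 1) / config$helix_count
      ax <- c(config$bundle_radius * cos(th),
              config$bundle_radius * sin(th))
      dr <- 0
      if (!is.null(config$helix_radial_shift)) {
        key <- as.character(h)
        if (key %in% names(config$helix_radial_shift)) {
          dr <- config$helix_radial_shift[[key]]
        }
      }
      ax <- ax + dr * c(cos(th), sin(th))
      dir <- if (h %% 2 == 1) 1 else -1
      curve <- function(t) {
        ## t is a continuous residue coordinate along the helix
        phi <- th + config$twist * t * pi / 180
        z <- dir * config$rise * (t - (rph + 1) / 2)
        c(ax[1] + config$helix_radius * cos(phi),
          ax[2] + config$helix_radius * sin(phi),
          z)
      }
      for (j in seq_len(rph)) {
        rid <- (h - 1L) * rph + j
        pos <- rbind(curve(j - 0.35), curve(j), curve(j + 0.35),
                     curve(j + 0.6))
        an <- c("N", "CA", "C", "O")
        el <- c("N", "C", "C", "O")
        if (!is.na(config$probe_resid) && rid == config$probe_resid) {
          N <- pos[1, ]; CA <- pos[2, ]; C <- pos[3, ]
          CB <- .placeAtom(C, N, CA, 0.153, 110, -120)
          CG <- .placeAtom(N, CA, CB, 0.152, 114, first_chi1)
          pos <- rbind(pos, CB, CG)
          an <- c(an, "CB", "CG")
          el <- c(el, "C", "C")
        }
        rnm <- if (!is.na(config$probe_resid) && rid == config$probe_resid) {
          "TRP"
        } else "ALA"
        nms <- c(nms, an)
        ele <- c(ele, el)
        resname <- c(resname, rep(rnm, length(an)))
        resid <- c(resid, rep(rid, length(an)))
        chain <- c(chain, rep("A", length(an)))
        xyz <- rbind(xyz, pos)
      }
    }
  }
  nprot_res <- config$helix_count * rph

  ## --- lipids: two leaflet lattices of 3-bead pseudo-molecules ----------
  ls <- .leafletSites(bl, protein_present = config$helix_count > 0)
  sites <- ls$sites
  lz <- bl$leaflet_z
  next_rid <- nprot_res
  for (leaf in c(1, -1)) {
    for (i in seq_len(nrow(sites))) {
      next_rid <- next_rid + 1L
      x <- sites[i, 1]; y <- sites[i, 2]
      pos <- rbind(c(x, y, leaf * (lz + 0.35)),   # choline bead
                   c(x, y, leaf * lz),            # phosphate
                   c(x, y, leaf * (lz - 0.6)))    # tail bead
      nms <- c(nms, "NC3", "P", "C2")
      ele <- c(ele, "N", "P", "C")
      resname <- c(resname, rep("POP", 3))
      resid <- c(resid, rep(next_rid, 3))
      chain <- c(chain, rep("L", 3))
      xyz <- rbind(xyz, pos)
    }
  }

  ## --- optional pseudo-ligand at the lumen centre -----------------------
  if (isTRUE(config$ligand)) {
    next_rid <- next_rid + 1L
    d <- 0.25
    pos <- rbind(c(d, 0, 0), c(-d, 0, 0), c(0, d, 0), c(0, -d, 0))
    nms <- c(nms, paste0("C", 1:4))
    ele <- c(ele, rep("C", 4))
    resname <- c(resname, rep("LIG", 4))
    resid <- c(resid, rep(next_rid, 4))
    chain <- c(chain, rep("X", 4))
    xyz <- rbind(xyz, pos)
  }

  ## --- waters: seeded uniform placement in two slabs --------------------
  halfxy <- ls$n * bl$spacing / 2
  wt <- config$waters
  nw <- wt$count
  if (nw > 0) {
    wpos <- .withSeed(config$seed, {
      n_up <- ceiling(nw / 2)
      n_dn <- nw - n_up
      z0 <- lz + wt$slab_offset
      up <- cbind(stats::runif(n_up, -halfxy, halfxy),
                  stats::runif(n_up, -halfxy, halfxy),
                  stats::runif(n_up, z0, z0 + wt$slab_width))
      dn <- cbind(stats::runif(n_dn, -halfxy, halfxy),
                  stats::runif(n_dn, -halfxy, halfxy),
                  -stats::runif(n_dn, z0, z0 + wt$slab_width))
      rbind(up, dn)
    })
    for (i in seq_len(nw)) {
      next_rid <- next_rid + 1L
      nms <- c(nms, "OW")
      ele <- c(ele, "O")
      resname <- c(resname, "HOH")
      resid <- c(resid, next_rid)
      chain <- c(chain, "W")
    }
    xyz <- rbind(xyz, wpos)
  }

  ## --- box sized to contain everything, system centred ------------------
  zmax <- max(abs(xyz[, 3])) + 0.3
  Lxy <- 2 * max(halfxy, max(abs(xyz[, 1:2])) + 0.3)
  box <- c(Lxy, Lxy, 2 * zmax)
  xyz <- sweep(xyz, 2, box / 2, "+")

  atoms <- data.frame(serial = seq_along(nms), name = nms, element = ele,
                      resname = resname, resid = resid, chain = chain,
                      class = moleculeClass(resname),
                      stringsAsFactors = FALSE)
  ht <- data.frame(helix = seq_len(config$helix_count),
                   start = (seq_len(config$helix_count) - 1L) * rph + 1L,
                   end = seq_len(config$helix_count) * rph)
  anchors <- integer()
  if (config$helix_count == 7L && rph == 50L) {
    ## class-A receptor-like anchors: helix-6 x.50 at 288, helix-7 at 323
    anchors <- c(`1` = 25L, `2` = 75L, `3` = 125L, `4` = 175L, `5` = 225L,
                 `6` = 288L, `7` = 323L)
  } else if (config$helix_count > 0) {
    anchors <- stats::setNames(
      as.integer(round((ht$start + ht$end) / 2)), ht$helix)
  }
  StructureModel(atoms, xyz, box, ht, anchors)
}

## scheduled chi1 angle for frame f (1-based); frames outside every range
## keep the first entry's angle
.scheduledChi1 <- function(schedule, f) {
  ang <- schedule[[1]]$angle
  for (entry in schedule) {
    if (f >= entry$frames[1] && f <= entry$frames[2]) ang <- entry$angle
  }
  ang
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Emits `n_frames` frames from the reference system. Per frame, in this
#' order: (1) the probe residue's CG is re-placed so its chi1 tracks the
#' schedule; (2) leaflet phosphates are displaced by the static thickness
#' field (half the amplitude per leaflet, opposite signs); (3) the pulled
#' lipid is translated in z after its onset frame; (4) cumulative
#' random-walk drift is added to protein atoms (if `drift_sigma > 0`);
#' (5) i.i.d. Gaussian noise of SD `noise_sigma` is added to every atom.
#' The RNG stream (seeded from the config) is consumed in that order,
#' drift first then noise, atom-major, so identical (seed, config) pairs are
#' bit-identical.
#'
#' @param model the [StructureModel-class] built by [buildSystem()] with the
#'   same config
#' @param config the [generatorConfig()]
#' @return a list with elements `trajectory` ([Trajectory-class]) and
#'   `truth`, a list holding the per-frame true chi1 (`chi1`), the thickness
#'   modulation function (`thicknessFn(x, y)`, nm, in box coordinates), the
#'   pulled lipid residue id and per-frame displacement (`pullResid`,
#'   `pullDz`), and the per-frame protein drift RMS (`driftRMS`).
#' @export
generateTrajectory <- function(model, config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  ref <- model@coords
  a <- model@atoms
  nat <- nrow(a)
  nf <- config$n_frames
  box <- model@box

  ## probe-residue atom indices for the chi1 script
  probe <- NULL
  if (!is.na(config$probe_resid)) {
    idx <- function(nm) {
      i <- which(a$resid == config$probe_resid & a$name == nm &
                 a$class == "protein")
      if (length(i) != 1) NULL else i
    }
    pN <- idx("N"); pCA <- idx("CA"); pCB <- idx("CB"); pCG <- idx("CG")
    if (!is.null(pN) && !is.null(pCA) && !is.null(pCB) && !is.null(pCG)) {
      probe <- list(N = pN, CA = pCA, CB = pCB, CG = pCG)
    }
  }

  ## thickness field, evaluated at reference phosphate xy
  tf <- config$thickness_field
  thicknessFn <- function(x, y) 0 * x
  pAll <- which(a$class == "lipid" & a$name == "P")
  lipidUpper <- ref[pAll, 3] > box[3] / 2
  if (!is.null(tf)) {
    ctr <- if (is.null(tf$center)) box[1:2] / 2 else tf$center
    thicknessFn <- function(x, y) {
      tf$amplitude * exp(-((x - ctr[1])^2 + (y - ctr[2])^2) /
                           (2 * tf$width^2))
    }
  }
  tfShift <- thicknessFn(ref[pAll, 1], ref[pAll, 2]) / 2

  ## resolve the pulled lipid
  pull <- config$lipid_pull
  pullResid <- NA_integer_
  pullIdx <- integer()
  if (!is.null(pull)) {
    if (!is.null(pull$lipid_resid)) {
      pullResid <- as.integer(pull$lipid_resid)
    } else {
      tca <- which(a$resid == pull$target_resid & a$name == "CA" &
                   a$class == "protein")
      if (length(tca) != 1) stop("lipid_pull target residue has no CA atom")
      dd <- minImageDistance(ref[tca, ], ref[pAll, , drop = FALSE], box)
      pullResid <- a$resid[pAll[which.min(dd)]]
    }
    pullIdx <- which(a$resid == pullResid & a$class == "lipid")
    if (!length(pullIdx)) stop("pulled lipid residue not found: ", pullResid)
  }

  protIdx <- which(a$class == "protein")
  arr <- array(0, dim = c(nat, 3, nf))
  truth_chi1 <- numeric(nf)
  truth_dz <- numeric(nf)
  driftRMS <- numeric(nf)

  .withSeed(config$seed, {
    D <- matrix(0, length(protIdx), 3)
    for (f in seq_len(nf)) {
      co <- ref
      if (!is.null(probe)) {
        ang <- .scheduledChi1(config$chi1_schedule, f)
        co[probe$CG, ] <- .placeAtom(ref[probe$N, ], ref[probe$CA, ],
                                     ref[probe$CB, ], 0.152, 114, ang)
        truth_chi1[f] <- ang
      }
      if (!is.null(tf)) {
        co[pAll, 3] <- co[pAll, 3] + ifelse(lipidUpper, tfShift, -tfShift)
      }
      if (length(pullIdx) && f >= pull$onset) {
        co[pullIdx, 3] <- co[pullIdx, 3] + pull$dz
        truth_dz[f] <- pull$dz
      }
      if (config$drift_sigma > 0) {
        D <- D + matrix(stats::rnorm(length(D), 0, config$drift_sigma),
                        nrow(D), 3)
        co[protIdx, ] <- co[protIdx, ] + D
      }
      driftRMS[f] <- sqrt(mean(rowSums(D^2)))
      if (config$noise_sigma > 0) {
        co <- co + matrix(stats::rnorm(3 * nat, 0, config$noise_sigma),
                          nat, 3)
      }
      arr[, , f] <- co
    }
  })

  traj <- Trajectory(model, arr, times = (seq_len(nf) - 1) * config$dt)
  truth <- list(chi1 = if (is.null(probe)) NULL else truth_chi1,
                thicknessFn = thicknessFn,
                pullResid = pullResid, pullDz = truth_dz,
                driftRMS = driftRMS)
  list(trajectory = traj, truth = truth)
}
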