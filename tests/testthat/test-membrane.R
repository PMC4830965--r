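test_that("leaflet assignment splits a symmetric bilayer at midplane zero", {
  cfg <- generatorConfig(seed = 1, n_frames = 1, noise_sigma = 0,
                         bilayer = list(lipids_per_leaflet = 16),
                         waters = list(count = 0))
  m <- buildSystem(cfg)
  la <- assignLeaflets(coords(m), m)
  expect_equal(sum(la$leaflet == "upper"), 16)
  expect_equal(sum(la$leaflet == "lower"), 16)
  # midplane is at the box centre (system is centred in the box)
  expect_equal(la$midplane, boxLengths(m)[3] / 2, tolerance = 1e-9)
})

test_that("a lipid pulled across the midplane is reassigned", {
  cfg <- generatorConfig(seed = 1, n_frames = 1, noise_sigma = 0,
                         bilayer = list(lipids_per_leaflet = 8),
                         waters = list(count = 0))
  m <- buildSystem(cfg)
  la0 <- assignLeaflets(coords(m), m)
  victim <- names(la0$leaflet)[la0$leaflet == "upper"][1]
  co <- coords(m)
  pIdx <- selectAtoms(m, class = "lipid", name = "P",
                      resid = as.integer(victim))
  co[pIdx, 3] <- co[pIdx, 3] - 4.5   # push well below the midplane
  la1 <- assignLeaflets(co, m)
  expect_identical(unname(la1$leaflet[victim]), "lower")
})

test_that("an all-upper pathological frame warns but still labels", {
  cfg <- generatorConfig(seed = 1, n_frames = 1, noise_sigma = 0,
                         bilayer = list(lipids_per_leaflet = 4),
                         waters = list(count = 0))
  m <- buildSystem(cfg)
  co <- coords(m)
  pIdx <- selectAtoms(m, class = "lipid", name = "P")
  co[pIdx, 3] <- co[pIdx, 3] * 0 + 5   # identical z: ties go upper
  expect_warning(la <- assignLeaflets(co, m), "one leaflet")
  expect_true(all(la$leaflet == "upper"))
  expect_error(assignLeaflets(coords(m)[1:3, ],
                              buildSystem(generatorConfig(
                                seed = 1, n_frames = 1, helix_count = 1L,
                                residues_per_helix = 1L, probe_resid = NA,
                                bilayer = list(lipids_per_leaflet = 0),
                                waters = list(count = 0)))),
               "2 phosphates")
})

test_that("a noise-free flat bilayer gives an exactly uniform map", {
  cfg <- generatorConfig(seed = 2, n_frames = 3, noise_sigma = 0,
                         bilayer = list(lipids_per_leaflet = 32),
                         waters = list(count = 0))
  m <- buildSystem(cfg)
  tr <- generateTrajectory(m, cfg)$trajectory
  tm <- thicknessMap(tr, gridSpacing = 0.2)
  v <- thicknessValues(tm)
  def <- cellCounts(tm) > 0
  expect_gt(sum(def), 0)
  expect_equal(unique(v[def]), 3.8, tolerance = 1e-12)
  expect_true(all(is.na(v[!def])))
})

test_that("grid mean conserves the whole-box leaflet separation", {
  cfg <- generatorConfig(seed = 3, n_frames = 5, noise_sigma = 0.01,
                         bilayer = list(lipids_per_leaflet = 36,
                                        exclusion_radius = 0),
                         helix_count = 0L, probe_resid = NA,
                         waters = list(count = 0))
  m <- buildSystem(cfg)
  tr <- generateTrajectory(m, cfg)$trajectory
  # one cell per lattice site: each defined cell holds exactly one lipid
  # pair, so the count-weighted cell mean must equal the global mean
  tm <- thicknessMap(tr, gridSpacing = 0.8)
  v <- thicknessValues(tm)
  cnt <- cellCounts(tm)
  def <- cnt > 0
  gridMean <- sum(v[def] * cnt[def]) / sum(cnt[def])
  ph <- selectAtoms(m, class = "lipid", name = "P")
  glob <- mean(vapply(seq_len(nFrames(tr)), function(f) {
    z <- frameCoords(tr, f)[ph, 3]
    mid <- mean(z)
    mean(z[z >= mid]) - mean(z[z < mid])
  }, 1.0))
  expect_equal(gridMean, glob, tolerance = 1e-6)
})

test_that("a programmed Gaussian thickness field is recovered", {
  amp <- -0.4   # thinning
  cfg <- generatorConfig(seed = 4, n_frames = 40, noise_sigma = 0.02,
                         bilayer = list(lipids_per_leaflet = 64),
                         waters = list(count = 0),
                         thickness_field = list(amplitude = amp, width = 1.5))
  m <- buildSystem(cfg)
  g <- generateTrajectory(m, cfg)
  tm <- thicknessMap(g$trajectory, gridSpacing = 0.4)
  v <- thicknessValues(tm)
  def <- which(cellCounts(tm) > 0, arr.ind = TRUE)
  cx <- gridOrigin(tm)[1] + (def[, 1] - 0.5) * gridSpacing(tm)
  cy <- gridOrigin(tm)[2] + (def[, 2] - 0.5) * gridSpacing(tm)
  want <- 3.8 + g$truth$thicknessFn(cx, cy)
  got <- v[def]
  rms <- sqrt(mean((got - want)^2))
  expect_lt(rms, 0.05)
  # thinning is radial: cells near the field centre are thinner than the rim
  ctr <- boxLengths(m)[1:2] / 2
  r <- sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2)
  expect_lt(mean(got[r < 3]), mean(got[r >= 3]) - 0.05)
})

test_that("a programmed thick spot localises the map maximum", {
  # thickening offset from the bundle, as at a helix-groove contact
  cfg <- generatorConfig(seed = 5, n_frames = 20, noise_sigma = 0.01,
                         bilayer = list(lipids_per_leaflet = 64),
                         waters = list(count = 0),
                         thickness_field = list(amplitude = 0.4, width = 1.0,
                                                center = c(2.2, 2.2)))
  m <- buildSystem(cfg)
  g <- generateTrajectory(m, cfg)
  tm <- thicknessMap(g$trajectory, gridSpacing = 0.4)
  v <- thicknessValues(tm)
  def <- which(cellCounts(tm) > 0, arr.ind = TRUE)
  vals <- v[def]
  top <- def[which.max(vals), ]
  cx <- (top[1] - 0.5) * gridSpacing(tm)
  cy <- (top[2] - 0.5) * gridSpacing(tm)
  expect_lt(sqrt((cx - 2.2)^2 + (cy - 2.2)^2), 1.0)
})

test_that("thickness differencing is cellwise with NA propagation", {
  cfg <- generatorConfig(seed = 6, n_frames = 2, noise_sigma = 0,
                         bilayer = list(lipids_per_leaflet = 16),
                         waters = list(count = 0))
  m <- buildSystem(cfg)
  tr <- generateTrajectory(m, cfg)$trajectory
  tm <- thicknessMap(tr, gridSpacing = 0.4)
  d0 <- thicknessDifference(tm, tm)
  v0 <- thicknessValues(d0)
  expect_equal(unique(v0[cellCounts(d0) > 0]), 0)
  # variant with programmed thinning: difference shows -delta at its cells
  cfg2 <- generatorConfig(seed = 6, n_frames = 2, noise_sigma = 0,
                          bilayer = list(lipids_per_leaflet = 16),
                          waters = list(count = 0),
                          thickness_field = list(amplitude = -0.4,
                                                 width = 50))  # ~uniform
  tr2 <- generateTrajectory(buildSystem(cfg2), cfg2)$trajectory
  d1 <- thicknessDifference(thicknessMap(tr2, 0.4), tm)
  v1 <- thicknessValues(d1)
  def <- cellCounts(d1) > 0
  expect_lt(max(abs(v1[def] + 0.4)), 0.01)
  # grid mismatch is an error; single-sided cells become undefined
  expect_error(thicknessDifference(tm, thicknessMap(tr, 0.3)),
               "different grids")
})

test_that("headgroup displacements are null without a programmed pull", {
  cfg <- generatorConfig(seed = 7, n_frames = 25, noise_sigma = 0.02,
                         bilayer = list(lipids_per_leaflet = 32),
                         waters = list(count = 0))
  m <- buildSystem(cfg)
  tr <- generateTrajectory(m, cfg)$trajectory
  hp <- headgroupProfile(tr, 38, cutoff = 2.0)
  expect_gt(nrow(hp), 0)
  expect_lt(max(abs(hp$dz_nm)), 4 * 0.02 / sqrt(25))
})

test_that("a programmed lipid pull is recovered on the right lipid only", {
  # residue 38 sits near the upper phosphate plane; pull its nearest lipid
  # 0.5 nm toward the membrane core
  cfg <- generatorConfig(seed = 8, n_frames = 50, noise_sigma = 0.02,
                         bilayer = list(lipids_per_leaflet = 64),
                         waters = list(count = 0),
                         lipid_pull = list(target_resid = 38, dz = -0.5,
                                           onset = 1))
  m <- buildSystem(cfg)
  g <- generateTrajectory(m, cfg)
  hp <- headgroupProfile(g$trajectory, 38, cutoff = 2.5)
  expect_true(g$truth$pullResid %in% hp$lipid_resid)
  pulled <- hp$dz_nm[hp$lipid_resid == g$truth$pullResid]
  others <- hp$dz_nm[hp$lipid_resid != g$truth$pullResid]
  expect_equal(pulled, -0.5, tolerance = 0.05)
  if (length(others)) expect_lt(max(abs(others)), 0.05)
})

test_that("maps are invariant under rigid xy translation modulo re-origin", {
  cfg <- generatorConfig(seed = 9, n_frames = 3, noise_sigma = 0,
                         bilayer = list(lipids_per_leaflet = 16),
                         waters = list(count = 0))
  m <- buildSystem(cfg)
  tr <- generateTrajectory(m, cfg)$trajectory
  tm1 <- thicknessMap(tr, 0.4)
  # translate the whole system by an exact multiple of the grid spacing
  shift <- c(0.8, 1.2, 0)
  co <- coords(tr)
  for (f in seq_len(nFrames(tr))) co[, , f] <- sweep(co[, , f], 2, shift, "+")
  tr2 <- Trajectory(trajectoryModel(tr), co, frameTimes(tr))
  tm2 <- thicknessMap(tr2, 0.4)
  # same multiset of defined-cell values, re-origined
  expect_equal(sort(thicknessValues(tm1)[cellCounts(tm1) > 0]),
               sort(thicknessValues(tm2)[cellCounts(tm2) > 0]),
               tolerance = 1e-9)
})

test_that("thickness maps serialize to TSV and back", {
  cfg <- generatorConfig(seed = 10, n_frames = 2, noise_sigma = 0.01,
                         bilayer = list(lipids_per_leaflet = 16),
                         waters = list(count = 0))
  m <- buildSystem(cfg)
  tm <- thicknessMap(generateTrajectory(m, cfg)$trajectory, 0.4)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeThicknessMapTSV(tm, f)
  tm2 <- readThicknessMapTSV(f)
  expect_equal(thicknessValues(tm2), thicknessValues(tm), tolerance = 1e-9)
  expect_identical(cellCounts(tm2), cellCounts(tm))
  expect_equal(gridSpacing(tm2), gridSpacing(tm))
})
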