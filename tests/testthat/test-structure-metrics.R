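test_that("superposing a set onto itself gives zero RMSD and identity", {
  set.seed(1)
  p <- matrix(rnorm(36), 12, 3)
  fit <- kabschFit(p, p)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
})

test_that("a known rigid transform is recovered exactly", {
  set.seed(2)
  p <- matrix(rnorm(36), 12, 3)
  R <- rotationMatrix(c(1, 2, 3), 0.7)
  t <- c(0.5, -1.2, 2.0)
  q <- sweep(tcrossprod(p, R), 2, t, "+")
  fit <- kabschFit(p, q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(fit$translation, t, tolerance = 1e-8)
})

test_that("Kabsch RMSD matches the quaternion-method oracle", {
  set.seed(3)
  for (i in 1:200) {
    p <- matrix(rnorm(36), 12, 3)
    q <- matrix(rnorm(36), 12, 3)
    expect_equal(kabschFit(p, q)$rmsd, quatRMSD(p, q), tolerance = 1e-10)
  }
})

test_that("RMSD is invariant under a common rigid transform of both sets", {
  set.seed(4)
  p <- matrix(rnorm(60), 20, 3)
  q <- p + matrix(rnorm(60, sd = 0.1), 20, 3)
  base <- kabschFit(p, q)$rmsd
  for (i in 1:10) {
    R <- rotationMatrix(rnorm(3), runif(1, 0, pi))
    t <- rnorm(3)
    pr <- sweep(tcrossprod(p, R), 2, t, "+")
    qr <- sweep(tcrossprod(q, R), 2, t, "+")
    expect_equal(kabschFit(pr, qr)$rmsd, base, tolerance = 1e-10)
  }
})

test_that("degenerate point sets are a geometry error", {
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabschFit(line, line + 0.1), "degenerate|collinear")
  expect_error(kabschFit(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("TM RMSD is zero on a noise-free trajectory vs its own reference", {
  cfg <- smallConfig(seed = 6, n_frames = 4, noise_sigma = 0)
  m <- buildSystem(cfg)
  tr <- generateTrajectory(m, cfg)$trajectory
  r <- tmRmsdSeries(tr)
  expect_equal(r$rmsd_nm, rep(0, 4), tolerance = 1e-10)
})

test_that("TM RMSD under i.i.d. noise matches the analytic expectation", {
  sigma <- 0.02
  cfg <- smallConfig(seed = 8, n_frames = 30, noise_sigma = sigma)
  m <- buildSystem(cfg)
  tr <- generateTrajectory(m, cfg)$trajectory
  r <- tmRmsdSeries(tr)
  # fitted RMSD of M noisy points vs reference: ~ sigma*sqrt(3) less the
  # 6-parameter fit correction, negligible at M = 1400 backbone atoms
  expect_equal(mean(r$rmsd_nm), sigma * sqrt(3), tolerance = 0.03)
  # and equals a per-frame brute-force quaternion average
  idx <- selectAtoms(m, class = "protein", name = c("N", "CA", "C", "O"))
  brute <- mean(vapply(seq_len(nFrames(tr)), function(f) {
    quatRMSD(frameCoords(tr, f)[idx, ], coords(m)[idx, ])
  }, 1.0))
  expect_equal(mean(r$rmsd_nm), brute, tolerance = 1e-10)
})

test_that("drift-programmed variant rises above a stable wildtype", {
  wt <- smallConfig(seed = 10, n_frames = 25, noise_sigma = 0.01)
  mv <- smallConfig(seed = 10, n_frames = 25, noise_sigma = 0.01,
                    drift_sigma = 0.01)
  m1 <- buildSystem(wt)
  m2 <- buildSystem(mv)
  r1 <- tmRmsdSeries(generateTrajectory(m1, wt)$trajectory)
  r2 <- tmRmsdSeries(generateTrajectory(m2, mv)$trajectory)
  thr <- 0.05
  expect_lt(mean(r1$rmsd_nm), thr)
  expect_gt(mean(r2$rmsd_nm[20:25]), thr)
})

test_that("chi1 is definitional on constructed cis/trans geometries", {
  cis <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0))
  trans <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0))
  a <- data.frame(serial = 1:4, name = c("N", "CA", "CB", "CG"),
                  element = c("N", "C", "C", "C"), resname = "TRP",
                  resid = 1L, chain = "A", class = "protein")
  mc <- StructureModel(a, cis, c(10, 10, 10))
  expect_equal(dihedralChi1(cis, mc, 1), 0, tolerance = 1e-10)
  expect_equal(abs(dihedralChi1(trans, mc, 1)), 180, tolerance = 1e-10)
})

test_that("chi1 is rigid-motion invariant and mirror-antisymmetric", {
  set.seed(5)
  a <- data.frame(serial = 1:4, name = c("N", "CA", "CB", "CG"),
                  element = c("N", "C", "C", "C"), resname = "TRP",
                  resid = 1L, chain = "A", class = "protein")
  for (i in 1:20) {
    xyz <- matrix(rnorm(12), 4, 3)
    mc <- StructureModel(a, xyz, c(10, 10, 10))
    ang <- dihedralChi1(xyz, mc, 1)
    R <- rotationMatrix(rnorm(3), runif(1, 0, pi))
    moved <- sweep(tcrossprod(xyz, R), 2, rnorm(3), "+")
    expect_lt(angDiff(dihedralChi1(moved, mc, 1), ang), 1e-8)
    mirror <- xyz %*% diag(c(-1, 1, 1))
    expect_lt(angDiff(dihedralChi1(mirror, mc, 1), -ang), 1e-8)
  }
})

test_that("a missing side-chain atom names the atom and residue", {
  cfg <- smallConfig(seed = 1, n_frames = 1)
  m <- buildSystem(cfg)
  expect_error(dihedralChi1(coords(m), m, 100), "CB")
})

test_that("rotamer windows partition (-180, 180] exactly", {
  expect_identical(classifyRotamer(-60), "gauche-")
  expect_identical(classifyRotamer(180), "trans")
  expect_identical(classifyRotamer(120), "trans")   # closed bound tie-break
  expect_identical(classifyRotamer(-120), "trans")
  expect_identical(classifyRotamer(0), "gauche+")
  set.seed(6)
  angs <- c(runif(500, -180 + 1e-9, 180), -119.999, 119.999, 180)
  st <- classifyRotamer(angs)
  expect_true(all(st %in% c("gauche-", "gauche+", "trans")))
  expect_false(any(st == ""))
})

test_that("flip detection honours the dwell rule", {
  # constant series: no events
  expect_equal(nrow(detectFlips(rep("gauche-", 50), 5)), 0L)
  # programmed 50/50 switch: one event at the boundary
  st <- c(rep("gauche-", 50), rep("trans", 50))
  ev <- detectFlips(st, 5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 50L)
  expect_equal(ev$end, 51L)
  expect_identical(ev$from, "gauche-")
  expect_identical(ev$to, "trans")
  # a single-frame spike is ignored at min_dwell 5
  spike <- rep("gauche-", 20)
  spike[10] <- "trans"
  expect_equal(nrow(detectFlips(spike, 5)), 0L)
  expect_equal(nrow(detectFlips(spike, 1)), 2L)
})

test_that("event count is monotone non-increasing in min_dwell", {
  set.seed(7)
  st <- sample(c("gauche-", "trans", "gauche+"), 300, replace = TRUE,
               prob = c(0.5, 0.3, 0.2))
  counts <- vapply(1:12, function(d) nrow(detectFlips(st, d)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("programmed flip schedules are recovered under angular noise", {
  # dwell 50 >> min_dwell 5; sigma 0.01 nm is a few degrees of chi1 noise
  cfg <- generatorConfig(seed = 13, n_frames = 150, noise_sigma = 0.01,
                         chi1_schedule = list(
                           list(frames = c(1, 50), angle = -60),
                           list(frames = c(51, 100), angle = 180),
                           list(frames = c(101, 150), angle = -60)),
                         bilayer = list(lipids_per_leaflet = 4),
                         waters = list(count = 0))
  m <- buildSystem(cfg)
  s <- chi1Series(generateTrajectory(m, cfg)$trajectory, 286)
  ev <- flipEvents(s)
  expect_equal(nrow(ev), 2L)
  expect_identical(ev$to, c("trans", "gauche-"))
})

test_that("residue distances honour mode and periodic boundaries", {
  a <- data.frame(serial = 1:2, name = "CA", element = "C", resname = "ALA",
                  resid = 1:2, chain = "A", class = "protein")
  xyz <- rbind(c(0.2, 5, 5), c(0.7, 5, 5))
  m <- StructureModel(a, xyz, c(10, 10, 10))
  tr <- oneFrameTrajectory(m)
  expect_equal(residueDistanceSeries(tr, 1, 2, "CA")$distance_nm, 0.5)
  # across the boundary the minimum-image value wins
  xyz2 <- rbind(c(0.2, 5, 5), c(9.8, 5, 5))
  tr2 <- oneFrameTrajectory(m, xyz2)
  expect_equal(residueDistanceSeries(tr2, 1, 2, "CA")$distance_nm, 0.4)
  expect_equal(residueDistanceSeries(tr2, 1, 2, "min-heavy-atom")$distance_nm,
               bruteMinDistance(xyz2[1, ], xyz2[2, ], c(10, 10, 10)))
  expect_error(residueDistanceSeries(tr, 1, 99), "unknown residue")
})

test_that("min-heavy-atom distance equals the all-pairs brute force", {
  cfg <- smallConfig(seed = 14, n_frames = 2, noise_sigma = 0.05)
  m <- buildSystem(cfg)
  tr <- generateTrajectory(m, cfg)$trajectory
  d <- residueDistanceSeries(tr, 286, 320, "min-heavy-atom")$distance_nm
  a <- atoms(m)
  ia <- which(a$resid == 286 & a$class == "protein")
  ib <- which(a$resid == 320 & a$class == "protein")
  for (f in 1:2) {
    co <- frameCoords(tr, f)
    brute <- min(outer(ia, ib, Vectorize(function(i, j) {
      bruteMinDistance(co[i, ], co[j, ], boxLengths(m))
    })))
    expect_equal(d[f], brute, tolerance = 1e-12)
  }
})

test_that("BW numbering reproduces the canonical class-A labels", {
  m <- buildSystem(smallConfig())
  expect_identical(bwNumber(m, 286), "6.48")
  expect_identical(bwNumber(m, 290), "6.52")
  expect_identical(bwNumber(m, 326), "7.53")
  expect_identical(bwNumber(m, 288), "6.50")
  expect_error(bwNumber(m, 9999), "outside")
})
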