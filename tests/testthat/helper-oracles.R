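# Independent oracles and shared fixtures for the suite. Everything here is
# deliberately brute-force / closed-form and shares no code with the
# implementation paths it checks.

# Horn quaternion-method RMSD: independent of the SVD/Kabsch route.
quatRMSD <- function(mobile, reference) {
  M <- nrow(mobile)
  P <- scale(mobile, scale = FALSE)
  Q <- scale(reference, scale = FALSE)
  S <- crossprod(P, Q)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sq <- (sum(P^2) + sum(Q^2) - 2 * lam) / M
  sqrt(max(0, sq))
}

# brute-force minimum-image displacement: search all 27 periodic images
bruteMinImage <- function(a, b, box) {
  best <- NULL
  bestd <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- (b + c(i, j, k) * box) - a
    if (sum(d^2) < bestd) {
      bestd <- sum(d^2)
      best <- d
    }
  }
  best
}

bruteMinDistance <- function(a, b, box) sqrt(sum(bruteMinImage(a, b, box)^2))

# rotation matrix from an axis (unit vector) and angle in radians
rotationMatrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  U <- outer(u, u)
  W <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  c_ * diag(3) + s_ * W + (1 - c_) * U
}

# hollow spherical shell of single-CA residues: the analytic pocket fixture
shellModel <- function(nAtoms = 600, radius = 1.0, center = c(5, 5, 5),
                       box = c(10, 10, 10)) {
  i <- seq_len(nAtoms) - 0.5
  phi <- acos(1 - 2 * i / nAtoms)
  th <- pi * (1 + sqrt(5)) * i
  xyz <- cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi)) * radius
  xyz <- sweep(xyz, 2, center, "+")
  atomsDf <- data.frame(serial = seq_len(nAtoms), name = "CA",
                        element = "C", resname = "ALA",
                        resid = seq_len(nAtoms), chain = "A",
                        class = "protein", stringsAsFactors = FALSE)
  StructureModel(atomsDf, xyz, box)
}

oneFrameTrajectory <- function(model, coords = NULL) {
  if (is.null(coords)) coords <- coords(model)
  Trajectory(model, array(coords, dim = c(nrow(coords), 3, 1)))
}

# small standard generator fixtures
smallConfig <- function(seed = 1, n_frames = 5, ...) {
  generatorConfig(seed = seed, n_frames = n_frames,
                  bilayer = list(lipids_per_leaflet = 16),
                  waters = list(count = 30), ...)
}

ligandConfig <- function(seed = 2, n_frames = 3, ...) {
  generatorConfig(seed = seed, n_frames = n_frames, bundle_radius = 1.15,
                  bilayer = list(lipids_per_leaflet = 16),
                  waters = list(count = 0), ligand = TRUE, ...)
}

# circular angle difference in degrees, in [0, 180]
angDiff <- function(a, b) abs(((a - b + 180) %% 360) - 180)
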