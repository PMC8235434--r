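# Independent oracles: naive double loops, quadrature and grid searches kept
# deliberately separate from the package's vectorized implementations.

KE <- 332.0636

# Plain double-loop Coulomb sum (no masks).
oracle_coulomb <- function(xyz, q, ke = KE) {
  n <- nrow(xyz)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      e <- e + ke * q[i] * q[j] / r
    }
  }
  e
}

# Double-loop Lennard-Jones with Lorentz-Berthelot combination.
oracle_lj <- function(xyz, sigma, epsilon) {
  n <- nrow(xyz)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      s <- (sigma[i] + sigma[j]) / 2
      ep <- sqrt(epsilon[i] * epsilon[j])
      e <- e + 4 * ep * ((s / r)^12 - (s / r)^6)
    }
  }
  e
}

# Double-loop Still-form GB (uses the package's born_radii on purpose only
# when the radii themselves are under test elsewhere; here radii are passed
# in so the sum is independent).
oracle_gb_sum <- function(xyz, q, R, eps_in, eps_out, ke = KE) {
  n <- nrow(xyz)
  e <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r2 <- sum((xyz[i, ] - xyz[j, ])^2)
      f <- if (i == j) R[i] else sqrt(r2 + R[i] * R[j] * exp(-r2 / (4 * R[i] * R[j])))
      e <- e + q[i] * q[j] / f
    }
  }
  -(ke / 2) * (1 / eps_in - 1 / eps_out) * e
}

# Shell-quadrature oracle for the pairwise descreening integral:
# (1/4pi) int over (scaled sphere of j) minus (ball rho_i around i) of
# |x - x_i|^-4 dV, evaluated as int frac(s) / s^2 ds over shells.
oracle_descreen <- function(r, rho_i, srho_j) {
  frac <- function(s) {
    vapply(s, function(si) {
      if (si + r <= srho_j) return(1)
      if (si >= r + srho_j || si + srho_j <= r) return(0)
      cosp <- (si^2 + r^2 - srho_j^2) / (2 * si * r)
      (1 - cosp) / 2
    }, numeric(1))
  }
  stats::integrate(function(s) frac(s) / s^2, lower = rho_i,
                   upper = r + srho_j, rel.tol = 1e-10,
                   subdivisions = 2000L)$value
}

# Brute-force rotation-grid RMSD minimum (coarse-to-fine Euler-angle search).
oracle_min_rmsd <- function(mobile, reference) {
  cm_m <- colMeans(mobile)
  cm_r <- colMeans(reference)
  X <- sweep(mobile, 2, cm_m)
  Y <- sweep(reference, 2, cm_r)
  rot <- function(a, b, c) {
    Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz2 <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
    Rz1 %*% Ry %*% Rz2
  }
  eval_rmsd <- function(a, b, c) {
    sqrt(mean(rowSums((X %*% rot(a, b, c) - Y)^2)))
  }
  best <- c(0, 0, 0)
  width <- pi
  step <- pi / 12
  best_val <- Inf
  for (refine in 1:5) {
    as <- seq(best[1] - width, best[1] + width, by = step)
    bs <- seq(max(0, best[2] - width / 2), min(pi, best[2] + width / 2), by = step / 2)
    cs <- seq(best[3] - width, best[3] + width, by = step)
    for (a in as) for (b in bs) for (c in cs) {
      v <- eval_rmsd(a, b, c)
      if (v < best_val) {
        best_val <- v
        best <- c(a, b, c)
      }
    }
    width <- 2 * step
    step <- step / 4
  }
  best_val
}

# Random small system with well-separated atoms and full parameter set.
random_system <- function(n, seed, spread = 8) {
  set.seed(seed)
  repeat {
    xyz <- matrix(runif(3 * n, 0, spread), ncol = 3)
    if (n < 2 || min(dist(xyz)) > 0.8) break
  }
  list(
    xyz = xyz,
    params = tibble::tibble(
      charge = round(runif(n, -1, 1), 3),
      sigma = round(runif(n, 2.5, 3.5), 3),
      epsilon = round(runif(n, 0.05, 0.3), 3),
      gb_radius = round(runif(n, 1.2, 2.0), 3),
      screen = round(runif(n, 0.6, 0.95), 3)
    )
  )
}

# A trajectory with exactly one planted open frame among n_frames.
planted_single_open <- function(receptor, n_frames, open_at, displacement,
                                sigma, seed) {
  closed <- gen_two_basin_trajectory(receptor, n_frames = n_frames,
                                     open_fraction = 0, displacement = displacement,
                                     sigma = sigma, seed = seed)
  open1 <- gen_two_basin_trajectory(receptor, n_frames = 1,
                                    open_fraction = 1, displacement = displacement,
                                    sigma = sigma, seed = seed + 1L)
  frames <- closed$trajectory$frames
  frames[[open_at]] <- open1$trajectory$frames[[1]]
  md_trajectory(receptor$atoms, frames)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_r <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_r)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Replicate the generator's seeded binomial draw for planted-count checks.
with_seed_count <- function(seed, n, p) {
  withr::with_seed(as.integer(seed), sum(stats::rbinom(n, 1L, p)))
}
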