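# Schedules, soft-core perturbed energies, Metropolis sampling, trapezoidal
# integration and replicate pooling.

test_that("schedule builder places N+1 uniform nodes per stage, charge first", {
  sch <- build_schedule(5, 12)
  expect_equal(unique(sch$stage), c("charge", "vdw"))
  expect_equal(sch$lambda[sch$stage == "charge"], seq(0, 1, by = 0.2))
  expect_length(sch$lambda[sch$stage == "vdw"], 13L)
  expect_equal(diff(sch$lambda[sch$stage == "vdw"]), rep(1 / 12, 12), tolerance = 1e-12)
  minimal <- build_schedule(1, 1)
  expect_equal(minimal$lambda, c(0, 1, 0, 1))
  expect_error(build_schedule(0, 12), class = "helixbind_config_error")
})

test_that("perturbed energy obeys both endpoint identities", {
  toy <- gen_toy_complex(n_receptor = 5, n_ligand = 2, separation = 4, seed = 9)
  sys <- toy$system
  params <- sys$params
  full <- perturbed_energy(sys, 1, 1)
  # unperturbed reference: plain Coulomb + LJ over all pairs
  ref <- coulomb_energy(sys$xyz, params) + lj_energy(sys$xyz, params)
  expect_equal(full$energy, ref, tolerance = 1e-12)
  off <- perturbed_energy(sys, 0, 0)
  mask_intra <- !inter_mask(nrow(sys$xyz), setdiff(seq_len(nrow(sys$xyz)), sys$ligand),
                            sys$ligand)
  diag(mask_intra) <- FALSE
  ref_intra <- coulomb_energy(sys$xyz, params, mask_intra) +
    lj_energy(sys$xyz, params, mask_intra)
  expect_equal(off$energy, ref_intra, tolerance = 1e-12)
  expect_error(perturbed_energy(sys, -0.1, 1), class = "helixbind_domain_error")
})

test_that("dH/dlambda matches central finite differences on random toys", {
  toy <- gen_toy_complex(n_receptor = 6, n_ligand = 2, separation = 4, seed = 21)
  sys <- toy$system
  h <- 1e-5
  for (lam in c(0.25, 0.6, 0.9)) {
    # charge stage at full vdW
    d_ana <- perturbed_energy(sys, lam, 1, stage = "charge")$dhdl
    d_num <- (perturbed_energy(sys, lam + h, 1)$energy -
                perturbed_energy(sys, lam - h, 1)$energy) / (2 * h)
    expect_equal(d_ana, d_num, tolerance = 1e-5)
    # vdw stage at zero charge
    d_ana <- perturbed_energy(sys, 0, lam, stage = "vdw")$dhdl
    d_num <- (perturbed_energy(sys, 0, lam + h)$energy -
                perturbed_energy(sys, 0, lam - h)$energy) / (2 * h)
    expect_equal(d_ana, d_num, tolerance = 1e-5)
  }
})

test_that("frozen sampling returns the point evaluation with zero SE; seeds reproduce", {
  toy <- gen_toy_complex(n_receptor = 4, n_ligand = 1, separation = 4, seed = 2)
  sch <- build_schedule(2, 2)
  frozen <- sample_dhdl(toy$system, sch, n_sweeps = 20, burn_in = 5, step = 0,
                        seed = 123)
  expect_equal(frozen$dhdl_se, rep(0, nrow(frozen)))
  point <- vapply(seq_len(nrow(sch)), function(k) {
    st <- sch$stage[k]
    perturbed_energy(toy$system, if (st == "charge") sch$lambda[k] else 0,
                     if (st == "vdw") sch$lambda[k] else 1, stage = st)$dhdl
  }, numeric(1))
  expect_equal(frozen$dhdl_mean, point, tolerance = 1e-12)

  a <- sample_dhdl(toy$system, sch, n_sweeps = 30, burn_in = 10, seed = 7)
  b <- sample_dhdl(toy$system, sch, n_sweeps = 30, burn_in = 10, seed = 7)
  expect_identical(a, b)
  expect_error(sample_dhdl(toy$system, sch, n_sweeps = 30, burn_in = 10),
               class = "helixbind_config_error")
})

test_that("trapezoid integration is exact for constants and affine integrands", {
  s_const <- tibble::tibble(stage = "charge", lambda = c(0, 0.5, 1),
                            dhdl_mean = 2, dhdl_se = 0, n_samples = 1)
  expect_equal(trapezoid_integrate(s_const)$total, 2, tolerance = 1e-15)
  for (nodes in list(c(0, 0.3, 1), seq(0, 1, 0.25), c(0, 0.1, 0.15, 0.9, 1))) {
    s_lin <- tibble::tibble(stage = "vdw", lambda = nodes,
                            dhdl_mean = 2 * nodes, dhdl_se = 0, n_samples = 1)
    expect_equal(trapezoid_integrate(s_lin)$total, 1, tolerance = 1e-15)
  }
  s_quad <- gen_lambda_series("quadratic", coef = 3,
                              schedule = single_stage_schedule("charge", 5))
  expect_equal(trapezoid_integrate(s_quad)$total, 1.02, tolerance = 1e-12)
  expect_equal(attr(s_quad, "ground_truth"), 1)
  bad <- tibble::tibble(stage = "x", lambda = c(0, 0.5, 0.4, 1), dhdl_mean = 1)
  expect_error(trapezoid_integrate(bad), class = "helixbind_domain_error")
})

test_that("trapezoid SE propagation uses the quadrature weights", {
  s <- tibble::tibble(stage = "charge", lambda = c(0, 0.2, 0.6, 1),
                      dhdl_mean = c(1, 2, 3, 4), dhdl_se = c(0.1, 0.2, 0.3, 0.4),
                      n_samples = 10)
  w <- c(0.1, 0.3, 0.4, 0.2)
  expect_equal(trapezoid_integrate(s)$se, sqrt(sum((w * s$dhdl_se)^2)),
               tolerance = 1e-12)
})

test_that("replicate pooling matches closed-form mean and SE arithmetic", {
  mk <- function(total) {
    structure(list(stages = tibble::tibble(stage = "charge", dg = total, se = 0),
                   total = total, se = 0, replicates = NULL), class = "ti_result")
  }
  pooled <- pool_replicates(lapply(c(1, 2, 3, 4), mk))
  expect_equal(pooled$total, 2.5)
  expect_equal(pooled$se, stats::sd(c(1, 2, 3, 4)) / 2, tolerance = 1e-12)
  expect_equal(pooled$se, 0.6455, tolerance = 1e-4)
  same <- pool_replicates(lapply(rep(1.7, 4), mk))
  expect_equal(same$se, 0)
  expect_error(pool_replicates(list(mk(1))), class = "helixbind_config_error")
  g <- glance(pooled)
  expect_equal(g$n_replicates, 4L)
})

test_that("harmonic alchemical change is recovered within 3 pooled SE", {
  model <- harmonic_alchemy(k1 = 1, k2 = 4, kT = 1)
  # single-stage leg, as the analytic toy is defined
  sch <- single_stage_schedule("switch", 6)
  seeds <- 101:104
  reps <- lapply(seeds, function(s) {
    trapezoid_integrate(sample_dhdl(model, sch, n_sweeps = 800, burn_in = 200,
                                    step = 1.5, seed = s))
  })
  pooled <- pool_replicates(reps)
  exact <- 0.5 * log(4)
  expect_lt(abs(pooled$total - exact), 3 * max(pooled$se, 0.01))
})

test_that("staged schedule on the harmonic toy has the same closed form", {
  model <- harmonic_alchemy(k1 = 1, k2 = 4, kT = 1)
  sch <- build_schedule(5, 12)
  reps <- lapply(201:204, function(s) {
    trapezoid_integrate(sample_dhdl(model, sch, n_sweeps = 600, burn_in = 200,
                                    step = 1.5, seed = s))
  })
  pooled <- pool_replicates(reps)
  expect_lt(abs(pooled$total - 0.5 * log(4)), 3 * max(pooled$se, 0.01))
})

test_that("identical-leg double decoupling is zero within 3 pooled SE", {
  toy <- gen_toy_complex(n_receptor = 4, n_ligand = 1, separation = 4,
                         restraint_k = 2, seed = 5)
  res <- decoupling_free_energy(toy$system, toy$system,
                                schedule = build_schedule(3, 6),
                                n_replicates = 4, seed = 99,
                                n_sweeps = 150, burn_in = 80, step = 0.35)
  expect_lt(abs(res$dg_bind), 3 * max(res$se, 0.05))
})

test_that("vdW decoupling in a small LJ fluid agrees with Widom insertion", {
  # fluid of 14 LJ particles in a periodic box; the "ligand" is one of them,
  # uncharged, decoupled through the soft-core vdW stage only
  set.seed(31)
  n <- 14
  box <- 12
  xyz <- matrix(runif(3 * n, 0, box), ncol = 3)
  # relax overlaps deterministically before sampling
  params <- tibble::tibble(charge = 0, sigma = 3, epsilon = 0.15,
                           gb_radius = 1.7, screen = 0.8)[rep(1, n), ]
  sys <- toy_system(xyz, params, ligand = n, temperature = 310, box = box)
  sch <- single_stage_schedule("vdw", 8)
  reps <- lapply(311:313, function(s) {
    trapezoid_integrate(sample_dhdl(sys, sch, n_sweeps = 250, burn_in = 150,
                                    step = 1.0, seed = s))
  })
  pooled <- pool_replicates(reps)
  mu_ti <- pooled$total  # coupling free energy of the test particle

  # Widom oracle: sample the 13-particle fluid with its own plain Metropolis
  # and average exp(-dU/kT) over random insertions
  kT <- 0.0019872041 * 310
  fluid <- xyz[-n, , drop = FALSE]
  pair_u <- function(d2) {
    s6 <- (3^2 / d2)^3
    4 * 0.15 * (s6^2 - s6)
  }
  u_part <- function(conf, xi, skip = 0L) {
    dv <- sweep(conf, 2, xi, "-")
    dv <- dv - box * round(dv / box)
    d2 <- rowSums(dv^2)
    if (skip > 0L) d2 <- d2[-skip]
    sum(pair_u(pmax(d2, 1e-4)))
  }
  set.seed(777)
  conf <- fluid
  acc <- 0
  w_sum <- 0
  w_n <- 0
  blocks <- numeric(10)
  for (sweep in 1:600) {
    for (i in 1:(n - 1)) {
      trial <- conf[i, ] + runif(3, -1, 1)
      du <- u_part(conf, trial, skip = i) - u_part(conf, conf[i, ], skip = i)
      if (runif(1) < exp(-du / kT)) conf[i, ] <- trial
    }
    if (sweep > 100) {
      for (t in 1:5) {
        xi <- runif(3, 0, box)
        w <- exp(-u_part(conf, xi) / kT)
        w_sum <- w_sum + w
        w_n <- w_n + 1
        b <- ceiling((sweep - 100) / 50)
        blocks[b] <- blocks[b] + w
      }
    }
  }
  mu_widom <- -kT * log(w_sum / w_n)
  block_mu <- -kT * log(blocks / (w_n / 10))
  se_widom <- stats::sd(block_mu) / sqrt(10)
  expect_lt(abs(mu_ti - mu_widom), 3 * sqrt(pooled$se^2 + se_widom^2) + 0.05)
})

test_that("full-chain determinism: same seeds give bit-identical results", {
  toy <- gen_toy_complex(n_receptor = 3, n_ligand = 1, separation = 4,
                         restraint_k = 2, seed = 6)
  run <- function() {
    decoupling_free_energy(toy$system, toy$system, schedule = build_schedule(2, 3),
                           n_replicates = 2, seed = 42, n_sweeps = 40,
                           burn_in = 20, step = 0.3)
  }
  a <- run()
  b <- run()
  expect_identical(a$dg_bind, b$dg_bind)
  expect_identical(a$complex$replicates, b$complex$replicates)
})
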