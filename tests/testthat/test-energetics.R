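# Closed-form checks, brute-force-oracle equivalence and invariances of the
# implicit-solvent energy terms and the MM-GB/SA estimator.

pair_params <- function(q = c(1, 1), sigma = 3, epsilon = 0.1,
                        gb_radius = 1.5, screen = 0.8) {
  tibble::tibble(charge = q, sigma = sigma, epsilon = epsilon,
                 gb_radius = gb_radius, screen = screen)
}

test_that("Coulomb term reproduces the closed-form constant and zero-charge limit", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(coulomb_energy(xyz, pair_params(c(1, 1))), 332.0636)
  expect_equal(coulomb_energy(xyz, pair_params(c(0, 0.7))), 0)
  expect_error(coulomb_energy(rbind(c(0, 0, 0), c(0, 0, 0)), pair_params()),
               class = "helixbind_geometry_error")
})

test_that("LJ term has its root at sigma and its minimum -epsilon at 2^(1/6) sigma", {
  p <- pair_params(q = c(0, 0), sigma = 3.2, epsilon = 0.25)
  expect_equal(lj_energy(rbind(c(0, 0, 0), c(3.2, 0, 0)), p), 0, tolerance = 1e-12)
  expect_equal(lj_energy(rbind(c(0, 0, 0), c(2^(1 / 6) * 3.2, 0, 0)), p), -0.25,
               tolerance = 1e-12)
})

test_that("Coulomb and LJ match brute-force double loops on random systems", {
  for (seed in c(11, 23, 37)) {
    sys <- random_system(20, seed)
    expect_equal(coulomb_energy(sys$xyz, sys$params),
                 oracle_coulomb(sys$xyz, sys$params$charge),
                 tolerance = 1e-10)
    expect_equal(lj_energy(sys$xyz, sys$params),
                 oracle_lj(sys$xyz, sys$params$sigma, sys$params$epsilon),
                 tolerance = 1e-10)
  }
})

test_that("pair masks restrict the sums to inter-group pairs", {
  sys <- random_system(10, 5)
  mask <- inter_mask(10, 1:6, 7:10)
  direct <- 0
  for (i in 1:6) {
    for (j in 7:10) {
      r <- sqrt(sum((sys$xyz[i, ] - sys$xyz[j, ])^2))
      s <- (sys$params$sigma[i] + sys$params$sigma[j]) / 2
      ep <- sqrt(sys$params$epsilon[i] * sys$params$epsilon[j])
      direct <- direct + KE * sys$params$charge[i] * sys$params$charge[j] / r +
        4 * ep * ((s / r)^12 - (s / r)^6)
    }
  }
  expect_equal(coulomb_energy(sys$xyz, sys$params, mask) +
                 lj_energy(sys$xyz, sys$params, mask),
               direct, tolerance = 1e-10)
})

test_that("Born radii: isolated and distant atoms keep their intrinsic radius", {
  p1 <- pair_params(q = 1, gb_radius = 1.5)[1, ]
  expect_equal(born_radii(matrix(0, 1, 3), p1), 1.5)
  p2 <- pair_params(q = c(1, -1), gb_radius = c(1.5, 1.8))
  R <- born_radii(rbind(c(0, 0, 0), c(100, 0, 0)), p2)
  expect_equal(R, c(1.5, 1.8), tolerance = 1e-6)
})

test_that("Born radii match the shell-quadrature descreening oracle", {
  p <- pair_params(q = c(0, 0), gb_radius = c(1.5, 1.7), screen = c(0.8, 0.85))
  for (r in c(3, 4.5, 2.4)) {
    xyz <- rbind(c(0, 0, 0), c(r, 0, 0))
    R <- born_radii(xyz, p)
    psi_1 <- oracle_descreen(r, 1.5, 0.85 * 1.7)
    psi_2 <- oracle_descreen(r, 1.7, 0.8 * 1.5)
    expect_equal(R[1], 1 / (1 / 1.5 - psi_1), tolerance = 1e-4)
    expect_equal(R[2], 1 / (1 / 1.7 - psi_2), tolerance = 1e-4)
  }
})

test_that("Born radii grow monotonically as a neighbour approaches", {
  p <- pair_params(q = c(0, 0))
  radii <- vapply(seq(10, 3, by = -0.5), function(r) {
    born_radii(rbind(c(0, 0, 0), c(r, 0, 0)), p)[1]
  }, numeric(1))
  expect_true(all(diff(radii) > 0))
  expect_true(all(radii >= 1.5 - 1e-9))
  expect_error(born_radii(rbind(c(0, 0, 0), c(0, 0, 0)), p),
               class = "helixbind_geometry_error")
})

test_that("GB energy reproduces the Born ion and the distant-ion sum", {
  pion <- pair_params(q = 1, gb_radius = 2, epsilon = 0)[1, ]
  expect_equal(gb_energy(matrix(0, 1, 3), pion),
               -(332.0636 / 2) * (1 - 1 / 78.5) / 2, tolerance = 1e-9)
  # two far-apart ions: sum of the two Born self energies
  p2 <- pair_params(q = c(1, -1), gb_radius = c(2, 1.6))
  far <- gb_energy(rbind(c(0, 0, 0), c(500, 0, 0)), p2)
  self <- function(R) -(332.0636 / 2) * (1 - 1 / 78.5) / R
  # the screened cross term -ke (1-1/78.5) q1 q2 / r is ~0.66 kcal/mol at
  # 500 A; after removing it the self-energy part must match much tighter
  cross <- -332.0636 * (1 - 1 / 78.5) * (1 * -1) / 500
  expect_equal(far - cross, self(2) + self(1.6), tolerance = 1e-4)
  expect_equal(gb_energy(rbind(c(0, 0, 0), c(3, 0, 0)),
                         pair_params(q = c(0, 0))), 0)
})

test_that("GB pair sum matches the double-loop oracle given the same radii", {
  for (seed in c(3, 19)) {
    sys <- random_system(15, seed)
    R <- born_radii(sys$xyz, sys$params)
    expect_equal(gb_energy(sys$xyz, sys$params),
                 oracle_gb_sum(sys$xyz, sys$params$charge, R, 1, 78.5),
                 tolerance = 1e-10)
  }
})

test_that("SASA: isolated sphere, distant pair additivity, buried atom", {
  sol <- solvent_model()
  p1 <- pair_params(q = 0, gb_radius = 1.6)[1, ]
  a1 <- sasa(matrix(0, 1, 3), p1, sol)
  expect_equal(a1$total, 4 * pi * 3^2, tolerance = 0.005 * 4 * pi * 9)
  p2 <- pair_params(q = c(0, 0), gb_radius = c(1.6, 2.0))
  a2 <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), p2, sol)
  expect_equal(a2$total, 4 * pi * (3^2 + 3.4^2), tolerance = 1e-6 * a2$total)
  # small atom fully inside a big one
  p3 <- pair_params(q = c(0, 0), gb_radius = c(8, 1))
  a3 <- sasa(rbind(c(0, 0, 0), c(1, 0, 0)), p3, sol)
  expect_equal(a3$per_atom$area[2], 0)
  expect_equal(sum(a3$per_atom$area), a3$total)
})

test_that("energies and SASA are invariant under rigid motion and atom reordering", {
  sys <- random_system(12, 42)
  sol <- solvent_model()
  Q <- random_rotation(7)
  moved <- sweep(sys$xyz %*% Q, 2, c(5, -3, 11), "+")
  expect_equal(coulomb_energy(moved, sys$params), coulomb_energy(sys$xyz, sys$params),
               tolerance = 1e-8)
  expect_equal(lj_energy(moved, sys$params), lj_energy(sys$xyz, sys$params),
               tolerance = 1e-8)
  expect_equal(gb_energy(moved, sys$params), gb_energy(sys$xyz, sys$params),
               tolerance = 1e-8)
  expect_equal(sasa(moved, sys$params, sol)$total, sasa(sys$xyz, sys$params, sol)$total,
               tolerance = 0.01)
  perm <- sample(12)
  expect_equal(coulomb_energy(sys$xyz[perm, ], sys$params[perm, ]),
               coulomb_energy(sys$xyz, sys$params), tolerance = 1e-10)
  expect_equal(gb_energy(sys$xyz[perm, ], sys$params[perm, ]),
               gb_energy(sys$xyz, sys$params), tolerance = 1e-10)
})

test_that("Coulomb and GB scale quadratically with a global charge scaling", {
  sys <- random_system(10, 8)
  scaled <- sys$params
  scaled$charge <- 3 * scaled$charge
  expect_equal(coulomb_energy(sys$xyz, scaled), 9 * coulomb_energy(sys$xyz, sys$params),
               tolerance = 1e-10)
  expect_equal(gb_energy(sys$xyz, scaled), 9 * gb_energy(sys$xyz, sys$params),
               tolerance = 1e-10)
})

test_that("decompose_energy total is the exact component sum", {
  sys <- random_system(8, 13)
  d <- decompose_energy(sys$xyz, sys$params)
  expect_equal(d$total, d$e_coul + d$e_lj + d$g_gb + d$g_sa, tolerance = 1e-9)
})

test_that("force-field table round-trips through TSV and validates invariants", {
  toy <- gen_toy_complex(seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_forcefield(toy$ff, path)
  back <- read_forcefield(path)
  expect_equal(back$charge, toy$ff$charge)
  expect_equal(back$sigma, toy$ff$sigma)
  bad <- toy$ff
  bad$screen[1] <- 1.5
  expect_error(validate_forcefield(bad), "screen", class = "helixbind_config_error")
  bad2 <- toy$ff
  bad2$sigma[1] <- -1
  expect_error(validate_forcefield(bad2), "sigma", class = "helixbind_config_error")
})

test_that("MM-GB/SA of a neutral LJ-silent ligand at 100 A is zero", {
  toy <- gen_toy_complex(n_receptor = 4, n_ligand = 1, separation = 100,
                         ligand_charges = 0, seed = 2)
  ff <- toy$ff
  ff$epsilon[ff$resname == "LIG"] <- 0
  traj <- md_trajectory(toy$structure$atoms, list(toy$structure$xyz))
  res <- mmgbsa_binding(traj, toy$ligand_sel, toy$receptor_sel, ff)
  expect_equal(res$mean, 0, tolerance = 0.05)
  expect_equal(res$sem, 0)
})

test_that("MM-GB/SA on a two-ion toy equals the hand-composed component sum", {
  toy <- gen_toy_complex(n_receptor = 1, n_ligand = 1, separation = 3,
                         receptor_charges = 1, ligand_charges = -1, seed = 1)
  traj <- md_trajectory(toy$structure$atoms, list(toy$structure$xyz))
  sol <- solvent_model()
  res <- mmgbsa_binding(traj, toy$ligand_sel, toy$receptor_sel, toy$ff, sol)
  params <- match_parameters(toy$structure$atoms, toy$ff)
  xyz <- toy$structure$xyz
  expected <- coulomb_energy(xyz, params, inter_mask(2, 1, 2), sol) +
    lj_energy(xyz, params, inter_mask(2, 1, 2)) +
    gb_energy(xyz, params, sol) -
    gb_energy(xyz[1, , drop = FALSE], params[1, ], sol) -
    gb_energy(xyz[2, , drop = FALSE], params[2, ], sol) +
    (sasa(xyz, params, sol)$total -
       sasa(xyz[1, , drop = FALSE], params[1, ], sol)$total -
       sasa(xyz[2, , drop = FALSE], params[2, ], sol)$total) * sol$gamma
  expect_equal(res$mean, expected, tolerance = 1e-8)
})

test_that("frozen multi-frame trajectory gives SEM 0; tidiers expose the frames", {
  toy <- gen_toy_complex(n_receptor = 3, n_ligand = 1, separation = 5, seed = 4)
  traj <- md_trajectory(toy$structure$atoms,
                        rep(list(toy$structure$xyz), 10))
  res <- mmgbsa_binding(traj, toy$ligand_sel, toy$receptor_sel, toy$ff)
  expect_equal(res$sem, 0)
  expect_equal(nrow(tidy(res)), 10L)
  g <- glance(res)
  expect_equal(g$dg_mean, res$mean)
  expect_equal(g$n_frames, 10L)
  expect_equal(res$frames$dg,
               res$frames$e_coul + res$frames$e_lj + res$frames$g_gb + res$frames$g_sa,
               tolerance = 1e-9)
})

test_that("relative binding table follows the positive-is-weaker convention", {
  mk <- function(vals) {
    structure(list(frames = tibble::tibble(frame = seq_along(vals), dg = vals),
                   mean = mean(vals),
                   sem = stats::sd(vals) / sqrt(length(vals)),
                   components = c(e_coul = 0, e_lj = 0, g_gb = 0, g_sa = 0)),
              class = "binding_result")
  }
  results <- list(
    reference = mk(c(-50.1, -49.9)),
    weaker = mk(c(-40.2, -40.0)),
    stronger = mk(c(-55.0, -55.2))
  )
  rel <- relative_binding(results, "reference")
  expect_equal(nrow(rel), 3L)
  expect_equal(rel$ddg[rel$ligand == "reference"], 0)
  expect_equal(rel$se[rel$ligand == "reference"], 0)
  expect_equal(rel$ddg[rel$ligand == "weaker"], 9.9, tolerance = 1e-9)
  expect_true(rel$weaker_than_ref[rel$ligand == "weaker"])
  expect_false(rel$weaker_than_ref[rel$ligand == "stronger"])
  expect_equal(rel$se[rel$ligand == "weaker"],
               sqrt(results$weaker$sem^2 + results$reference$sem^2))
  expect_error(relative_binding(results, "absent"), class = "helixbind_config_error")
})
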