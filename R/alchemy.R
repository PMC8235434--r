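# Staged alchemical decoupling with thermodynamic integration.
#
# The decoupling protocol switches the ligand's interactions with its
# environment off in two stages: first the ligand partial charges are scaled
# linearly from full strength (lambda = 1) to zero, with van der Waals intact;
# then the ligand-environment Lennard-Jones interactions are scaled to zero
# through a Beutler-style soft-core form that keeps dH/dlambda finite at the
# vanishing endpoint. <dH/dlambda> is estimated per lambda node by Metropolis
# sampling (standing in for an MD engine) and integrated with the trapezoidal
# rule; independent replicates are pooled by their sample mean and standard
# error.

boltzmann_kcal <- 0.0019872041  # kcal/(mol K)

#' Build the staged lambda schedule
#'
#' `n_charge` and `n_vdw` are numbers of uniform lambda *intervals* per
#' stage; each stage gets `n + 1` equally spaced nodes including both
#' endpoints (trapezoidal integration needs endpoint evaluations). The
#' default protocol is 5 charge steps followed by 12 van der Waals steps.
#'
#' @param n_charge,n_vdw Number of uniform intervals per stage (>= 1).
#' @return A tibble of class `lambda_schedule` with columns `stage`
#'   (`"charge"`, `"vdw"`) and `lambda`; the charge stage precedes vdW.
#' @examples
#' build_schedule(5, 12)  # 6 + 13 nodes
#' @export
build_schedule <- function(n_charge = 5L, n_vdw = 12L) {
  if (n_charge < 1L || n_vdw < 1L) {
    stop_config("step counts must be >= 1.")
  }
  out <- dplyr::bind_rows(
    tibble::tibble(stage = "charge", lambda = seq(0, 1, length.out = n_charge + 1L)),
    tibble::tibble(stage = "vdw", lambda = seq(0, 1, length.out = n_vdw + 1L))
  )
  class(out) <- c("lambda_schedule", class(out))
  out
}

#' @rdname build_schedule
#' @param stage Stage label for a custom single-stage schedule.
#' @param n_steps Number of uniform intervals.
#' @export
single_stage_schedule <- function(stage, n_steps) {
  if (n_steps < 1L) stop_config("step count must be >= 1.")
  out <- tibble::tibble(stage = stage, lambda = seq(0, 1, length.out = n_steps + 1L))
  class(out) <- c("lambda_schedule", class(out))
  out
}

validate_schedule <- function(schedule) {
  if (!all(c("stage", "lambda") %in% names(schedule))) {
    stop_config("schedule needs columns `stage` and `lambda`.")
  }
  for (st in unique(schedule$stage)) {
    lam <- schedule$lambda[schedule$stage == st]
    if (length(lam) < 2L) stop_domain(sprintf("stage '%s' needs >= 2 nodes.", st))
    if (any(diff(lam) <= 0)) stop_domain(sprintf("stage '%s' nodes are not strictly increasing.", st))
    if (any(lam < 0 | lam > 1)) stop_domain(sprintf("stage '%s' nodes outside [0, 1].", st))
  }
  schedule
}

# ---------------------------------------------------------------------------
# Toy systems

#' Desk-scale particle system for alchemical sampling
#'
#' A small set of point particles with nonbonded parameters, a designated
#' ligand subset, and either a periodic cubic box (minimum-image convention)
#' or an optional harmonic tether of every particle to its starting position
#' (used to keep a decoupled ligand localized in unbounded legs).
#'
#' @param xyz `n x 3` coordinate matrix (Angstrom).
#' @param params Per-atom tibble with `charge`, `sigma`, `epsilon` (and
#'   optionally `gb_radius`, `screen`, unused here).
#' @param ligand Integer indices of the ligand particles.
#' @param temperature Kelvin.
#' @param box Cubic box edge (Angstrom) for periodic systems, or `NULL`.
#' @param restraint_k Harmonic tether force constant, kcal/(mol A^2);
#'   0 disables the tether.
#' @param pair_mask Optional logical `n x n` matrix; `FALSE` pairs are
#'   excluded from all nonbonded sums (exclusion support for toys).
#' @return Object of class `toy_system`.
#' @export
toy_system <- function(xyz, params, ligand, temperature = 310,
                       box = NULL, restraint_k = 0, pair_mask = NULL) {
  assert_coords(xyz)
  n <- nrow(xyz)
  params <- tibble::as_tibble(params)
  if (nrow(params) != n) stop_config("one parameter row per particle required.")
  ligand <- as.integer(ligand)
  if (length(ligand) == 0L || any(ligand < 1L | ligand > n)) {
    stop_config("`ligand` must be a non-empty subset of particle indices.")
  }
  if (!is.null(box) && (!is.numeric(box) || box <= 0)) stop_config("box edge must be positive.")
  # precompute the distinct-pair list and its inter/intra classification
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (!is.null(pair_mask)) {
    keep <- pair_mask[pr]
    pr <- pr[keep, , drop = FALSE]
  }
  is_lig <- seq_len(n) %in% ligand
  structure(
    list(
      xyz = xyz, params = params, ligand = ligand, is_lig = is_lig,
      temperature = temperature, kT = boltzmann_kcal * temperature,
      box = box, restraint_k = restraint_k, xref = xyz,
      pairs = pr, inter = xor(is_lig[pr[, 1]], is_lig[pr[, 2]]),
      ke = 332.0636
    ),
    class = "toy_system"
  )
}

# Minimum-image displacement vectors.
min_image <- function(dvec, box) {
  if (is.null(box)) return(dvec)
  dvec - box * round(dvec / box)
}

# Beutler soft-core LJ: u = 4 eps lam [A^-2 - A^-1], A = alpha (1-lam)^2 + (r/sigma)^6
softcore_lj <- function(r, sigma, epsilon, lam, alpha = 0.5, deriv = FALSE) {
  A <- pmax(alpha * (1 - lam)^2 + (r / sigma)^6, 1e-12)
  u <- 4 * epsilon * lam * (A^-2 - A^-1)
  if (!deriv) return(u)
  dA <- -2 * alpha * (1 - lam)
  du <- 4 * epsilon * (A^-2 - A^-1) + 4 * epsilon * lam * (-2 * A^-3 + A^-2) * dA
  list(u = u, du = du)
}

plain_lj <- function(r, sigma, epsilon) {
  s6 <- (sigma / pmax(r, 1e-12))^6
  ifelse(epsilon > 0, 4 * epsilon * (s6^2 - s6), 0)
}

#' Perturbed Hamiltonian of a toy system
#'
#' Ligand-environment Coulomb interactions are scaled linearly by
#' `lambda_q`; ligand-environment Lennard-Jones interactions by `lambda_v`
#' through the soft-core form. Environment-environment and intra-ligand
#' terms, and any restraint, are unscaled. At `lambda_q = lambda_v = 1` the
#' full Hamiltonian is recovered exactly; at `lambda_q = lambda_v = 0` the
#' ligand is non-interacting.
#'
#' @param sys A [toy_system()].
#' @param lambda_q,lambda_v Coupling parameters in `[0, 1]`.
#' @param stage Which stage's derivative to report (`"charge"` or `"vdw"`).
#' @param xyz Optional coordinates overriding the system's.
#' @return List with `energy` (kcal/mol) and `dhdl` (kcal/mol per unit
#'   lambda of the active stage).
#' @export
perturbed_energy <- function(sys, lambda_q, lambda_v,
                             stage = c("charge", "vdw"), xyz = NULL) {
  stage <- match.arg(stage)
  if (lambda_q < 0 || lambda_q > 1 || lambda_v < 0 || lambda_v > 1) {
    stop_domain("lambda values must lie in [0, 1].")
  }
  if (is.null(xyz)) xyz <- sys$xyz
  pr <- sys$pairs
  dvec <- min_image(xyz[pr[, 2], , drop = FALSE] - xyz[pr[, 1], , drop = FALSE], sys$box)
  r <- sqrt(rowSums(dvec^2))
  q <- sys$params$charge
  sig <- (sys$params$sigma[pr[, 1]] + sys$params$sigma[pr[, 2]]) / 2
  eps <- sqrt(sys$params$epsilon[pr[, 1]] * sys$params$epsilon[pr[, 2]])
  qq <- q[pr[, 1]] * q[pr[, 2]]
  inter <- sys$inter

  e_coul_intra <- sys$ke * sum(qq[!inter] / pmax(r[!inter], 1e-12))
  e_lj_intra <- sum(plain_lj(r[!inter], sig[!inter], eps[!inter]))
  coul_inter_full <- sys$ke * sum(qq[inter] / pmax(r[inter], 1e-12))
  sc <- softcore_lj(r[inter], sig[inter], eps[inter], lambda_v, deriv = TRUE)
  e_rest <- if (sys$restraint_k > 0) {
    0.5 * sys$restraint_k * sum((xyz - sys$xref)^2)
  } else 0

  energy <- e_coul_intra + e_lj_intra + lambda_q * coul_inter_full + sum(sc$u) + e_rest
  dhdl <- if (stage == "charge") coul_inter_full else sum(sc$du)
  list(energy = energy, dhdl = dhdl)
}

# Energy of particle i (at trial position xi) with all partners, under the
# current coupling. Used for single-particle Metropolis moves.
particle_energy <- function(sys, xyz, i, xi, lambda_q, lambda_v) {
  n <- nrow(xyz)
  others <- setdiff(seq_len(n), i)
  dvec <- min_image(sweep(xyz[others, , drop = FALSE], 2, xi, "-"), sys$box)
  r <- sqrt(rowSums(dvec^2))
  q <- sys$params$charge
  sig <- (sys$params$sigma[i] + sys$params$sigma[others]) / 2
  eps <- sqrt(sys$params$epsilon[i] * sys$params$epsilon[others])
  qq <- q[i] * q[others]
  inter <- xor(sys$is_lig[i], sys$is_lig[others])
  e <- sys$ke * sum(qq[!inter] / pmax(r[!inter], 1e-12)) +
    sum(plain_lj(r[!inter], sig[!inter], eps[!inter])) +
    lambda_q * sys$ke * sum(qq[inter] / pmax(r[inter], 1e-12)) +
    sum(softcore_lj(r[inter], sig[inter], eps[inter], lambda_v))
  if (sys$restraint_k > 0) {
    e <- e + 0.5 * sys$restraint_k * sum((xi - sys$xref[i, ])^2)
  }
  e
}

# ---------------------------------------------------------------------------
# Metropolis sampling of <dH/dlambda>

mc_node_toy <- function(sys, lambda_q, lambda_v, stage, n_sweeps, burn_in, step0) {
  xyz <- sys$xyz
  n <- nrow(xyz)
  step <- step0
  acc <- 0L
  att <- 0L
  acc_burn <- 0L
  frozen <- step0 == 0
  samples <- numeric(n_sweeps)
  for (sweep in seq_len(burn_in + n_sweeps)) {
    for (i in seq_len(n)) {
      xi_new <- xyz[i, ] + runif(3, -step, step)
      e_old <- particle_energy(sys, xyz, i, xyz[i, ], lambda_q, lambda_v)
      e_new <- particle_energy(sys, xyz, i, xi_new, lambda_q, lambda_v)
      att <- att + 1L
      if (is.finite(e_new) && runif(1) < exp(-(e_new - e_old) / sys$kT)) {
        xyz[i, ] <- xi_new
        acc <- acc + 1L
        if (sweep <= burn_in) acc_burn <- acc_burn + 1L
      }
    }
    if (!frozen && sweep <= burn_in && sweep %% 10L == 0L) {
      rate <- acc / att
      if (rate < 0.3) step <- step * 0.8
      if (rate > 0.5) step <- step * 1.25
      acc <- 0L
      att <- 0L
    }
    if (sweep == burn_in && !frozen && burn_in > 0L && acc_burn == 0L) {
      abort(paste(
        "Metropolis acceptance was zero throughout burn-in;",
        "reduce the proposal step size or check the system energies."
      ), class = "helixbind_diagnostics_error")
    }
    if (sweep > burn_in) {
      pe <- perturbed_energy(sys, lambda_q, lambda_v, stage, xyz = xyz)
      samples[sweep - burn_in] <- pe$dhdl
    }
  }
  m <- mean(samples)
  se <- if (n_sweeps > 1L) stats::sd(samples) / sqrt(n_sweeps) else 0
  list(mean = m, se = se, n = n_sweeps)
}

#' Sample the lambda-derivative series of a decoupling leg
#'
#' Runs fixed-lambda Metropolis sampling at every node of the schedule
#' (charge stage at full vdW coupling, vdW stage at zero charge coupling)
#' and records the mean and standard error of `dH/dlambda` after discarding
#' the burn-in. The proposal width is auto-tuned during burn-in toward
#' 30-50% acceptance, then frozen so production sampling obeys detailed
#' balance. Deterministic given `seed`.
#'
#' @param sys A [toy_system()] or an [alchemical_model()].
#' @param schedule A [build_schedule()] tibble (or single-stage schedule).
#' @param n_sweeps Production sweeps per node.
#' @param burn_in Discarded equilibration sweeps per node.
#' @param step Initial proposal half-width (Angstrom); 0 freezes the system
#'   (useful for point-evaluation checks).
#' @param seed Mandatory RNG seed.
#' @return A tibble of class `lambda_series`: `stage`, `lambda`,
#'   `dhdl_mean`, `dhdl_se`, `n_samples`.
#' @export
sample_dhdl <- function(sys, schedule, n_sweeps = 500L, burn_in = 200L,
                        step = 0.3, seed) {
  UseMethod("sample_dhdl")
}

#' @export
sample_dhdl.toy_system <- function(sys, schedule, n_sweeps = 500L,
                                   burn_in = 200L, step = 0.3, seed) {
  if (missing(seed)) stop_config("an explicit `seed` is required.")
  schedule <- validate_schedule(schedule)
  if (!all(schedule$stage %in% c("charge", "vdw"))) {
    stop_config("toy-system sampling supports stages 'charge' and 'vdw' only.")
  }
  with_seed(seed, {
    rows <- purrr::pmap_dfr(
      list(schedule$stage, schedule$lambda),
      function(st, lam) {
        lq <- if (st == "charge") lam else 0
        lv <- if (st == "vdw") lam else 1
        res <- mc_node_toy(sys, lq, lv, st, n_sweeps, burn_in, step)
        tibble::tibble(stage = st, lambda = lam, dhdl_mean = res$mean,
                       dhdl_se = res$se, n_samples = res$n)
      }
    )
    class(rows) <- c("lambda_series", class(rows))
    rows
  })
}

#' Generic alchemical model for analytic validation
#'
#' Wraps an arbitrary lambda-dependent Hamiltonian over a low-dimensional
#' coordinate vector so the same sampling/integration chain can be validated
#' against closed-form free energies.
#'
#' @param energy_fn `function(x, lambda, stage)` returning
#'   `list(energy, dhdl)`.
#' @param x0 Numeric starting coordinate vector.
#' @param kT Thermal energy in the same units as `energy_fn`.
#' @return Object of class `alchemical_model`.
#' @export
alchemical_model <- function(energy_fn, x0, kT = 1) {
  structure(list(energy_fn = energy_fn, x0 = x0, kT = kT),
            class = "alchemical_model")
}

#' @rdname alchemical_model
#' @param k1,k2 Initial and final spring constants of the harmonic
#'   alchemical change `H(lambda) = 0.5 [(1 - lambda) k1 + lambda k2] x^2`,
#'   whose exact free-energy change is `0.5 kT log(k2 / k1)`. On a
#'   single-stage schedule the switch runs `k1 -> k2` directly; on the
#'   two-stage charge/vdw schedule the charge stage runs `k1 ->
#'   sqrt(k1 k2)` and the vdW stage `sqrt(k1 k2) -> k2`, so the staged
#'   total has the same closed form.
#' @export
harmonic_alchemy <- function(k1 = 1, k2 = 4, kT = 1) {
  k_mid <- sqrt(k1 * k2)
  alchemical_model(
    function(x, lambda, stage) {
      ks <- switch(stage, charge = c(k1, k_mid), vdw = c(k_mid, k2), c(k1, k2))
      k <- (1 - lambda) * ks[1] + lambda * ks[2]
      list(energy = 0.5 * k * sum(x^2), dhdl = 0.5 * (ks[2] - ks[1]) * sum(x^2))
    },
    x0 = 0, kT = kT
  )
}

#' @export
sample_dhdl.alchemical_model <- function(sys, schedule, n_sweeps = 500L,
                                         burn_in = 200L, step = 0.3, seed) {
  if (missing(seed)) stop_config("an explicit `seed` is required.")
  schedule <- validate_schedule(schedule)
  with_seed(seed, {
    rows <- purrr::pmap_dfr(
      list(schedule$stage, schedule$lambda),
      function(st, lam) {
        x <- sys$x0
        stp <- step
        acc <- 0L
        att <- 0L
        acc_burn <- 0L
        frozen <- step == 0
        samples <- numeric(n_sweeps)
        e_cur <- sys$energy_fn(x, lam, st)$energy
        for (sw in seq_len(burn_in + n_sweeps)) {
          for (i in seq_along(x)) {
            x_new <- x
            x_new[i] <- x[i] + runif(1, -stp, stp)
            e_new <- sys$energy_fn(x_new, lam, st)$energy
            att <- att + 1L
            if (is.finite(e_new) && runif(1) < exp(-(e_new - e_cur) / sys$kT)) {
              x <- x_new
              e_cur <- e_new
              acc <- acc + 1L
              if (sw <= burn_in) acc_burn <- acc_burn + 1L
            }
          }
          if (!frozen && sw <= burn_in && sw %% 10L == 0L) {
            rate <- acc / att
            if (rate < 0.3) stp <- stp * 0.8
            if (rate > 0.5) stp <- stp * 1.25
            acc <- 0L
            att <- 0L
          }
          if (sw == burn_in && !frozen && burn_in > 0L && acc_burn == 0L) {
            abort("Metropolis acceptance was zero throughout burn-in.",
                  class = "helixbind_diagnostics_error")
          }
          if (sw > burn_in) samples[sw - burn_in] <- sys$energy_fn(x, lam, st)$dhdl
        }
        tibble::tibble(
          stage = st, lambda = lam, dhdl_mean = mean(samples),
          dhdl_se = if (n_sweeps > 1L) stats::sd(samples) / sqrt(n_sweeps) else 0,
          n_samples = n_sweeps
        )
      }
    )
    class(rows) <- c("lambda_series", class(rows))
    rows
  })
}

#' Read/write a lambda-derivative series as TSV
#'
#' Exchange format for series produced by external engines: tab-separated
#' with header `stage`, `lambda`, `dhdl_mean`, `dhdl_se`, `n_samples`.
#'
#' @param path TSV path.
#' @return A `lambda_series` tibble.
#' @export
read_lambda_series <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("stage", "lambda", "dhdl_mean", "dhdl_se", "n_samples")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop_parse(sprintf("lambda-series table lacks columns: %s.",
                       paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(df[need])
  class(out) <- c("lambda_series", class(out))
  out
}

#' @rdname read_lambda_series
#' @param series A `lambda_series` tibble.
#' @export
write_lambda_series <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Integration and pooling

#' Trapezoidal thermodynamic integration of a lambda series
#'
#' Integrates the node means of `dH/dlambda` per stage with the trapezoidal
#' rule and propagates node standard errors through the trapezoid weights in
#' quadrature (node estimates treated as independent). The total is the sum
#' of stage integrals.
#'
#' @param series A `lambda_series` tibble (see [sample_dhdl()]).
#' @return Object of class `ti_result`: per-stage tibble (`stage`, `dg`,
#'   `se`), `total` and `se`.
#' @export
trapezoid_integrate <- function(series) {
  if (!all(c("stage", "lambda", "dhdl_mean") %in% names(series))) {
    stop_config("series needs columns stage, lambda, dhdl_mean.")
  }
  if (!"dhdl_se" %in% names(series)) series$dhdl_se <- 0
  stages <- purrr::map_dfr(unique(series$stage), function(st) {
    sub <- series[series$stage == st, ]
    lam <- sub$lambda
    if (length(lam) < 2L) stop_domain(sprintf("stage '%s' needs >= 2 nodes.", st))
    if (any(diff(lam) <= 0)) stop_domain(sprintf("stage '%s' nodes not strictly increasing.", st))
    m <- sub$dhdl_mean
    dg <- sum(diff(lam) * (head(m, -1) + tail(m, -1)) / 2)
    n <- length(lam)
    w <- numeric(n)
    w[1] <- (lam[2] - lam[1]) / 2
    w[n] <- (lam[n] - lam[n - 1]) / 2
    if (n > 2L) w[2:(n - 1)] <- (lam[3:n] - lam[1:(n - 2)]) / 2
    se <- sqrt(sum((w * sub$dhdl_se)^2))
    tibble::tibble(stage = st, dg = dg, se = se)
  })
  structure(
    list(stages = stages, total = sum(stages$dg),
         se = sqrt(sum(stages$se^2)), replicates = NULL),
    class = "ti_result"
  )
}

#' @export
print.ti_result <- function(x, ...) {
  cat(sprintf("<ti_result> total dG = %.4f +/- %.4f kcal/mol (%d stage(s)%s)\n",
              x$total, x$se, nrow(x$stages),
              if (is.null(x$replicates)) "" else
                sprintf(", %d replicates", length(x$replicates))))
  invisible(x)
}

#' Pool independent replicate integrations
#'
#' The pooled estimate is the arithmetic mean of the replicate totals and
#' its standard error the sample standard deviation over sqrt(n).
#'
#' @param results List of `ti_result` objects (>= 2).
#' @return A pooled `ti_result` carrying the replicate totals.
#' @export
pool_replicates <- function(results) {
  if (!is.list(results) || length(results) < 2L) {
    abort("pooling needs at least 2 replicates (pooled SE undefined otherwise).",
          class = "helixbind_config_error")
  }
  totals <- vapply(results, function(r) r$total, numeric(1))
  stages <- purrr::map_dfr(unique(results[[1]]$stages$stage), function(st) {
    vals <- vapply(results, function(r) r$stages$dg[r$stages$stage == st], numeric(1))
    tibble::tibble(stage = st, dg = mean(vals),
                   se = stats::sd(vals) / sqrt(length(vals)))
  })
  structure(
    list(stages = stages, total = mean(totals),
         se = stats::sd(totals) / sqrt(length(totals)), replicates = totals),
    class = "ti_result"
  )
}

#' Double-decoupling binding free energy
#'
#' Runs the full staged decoupling (sampling + trapezoidal integration +
#' replicate pooling) on a complex leg and a solvent leg and returns
#' `dG_bind = dG_decouple(solvent) - dG_decouple(complex)`, where each leg's
#' decoupling free energy is the free-energy change of switching the ligand
#' off (the negative of the coupling integral from lambda 0 to 1).
#'
#' @param sys_complex,sys_solvent [toy_system()]s for the two legs.
#' @param schedule A [build_schedule()] tibble.
#' @param n_replicates Independent replicates per leg (>= 2).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @inheritParams sample_dhdl
#' @return List of class `decoupling_result`: pooled `ti_result` per leg,
#'   `dg_bind` and `se`.
#' @export
decoupling_free_energy <- function(sys_complex, sys_solvent,
                                   schedule = build_schedule(),
                                   n_replicates = 4L, seed,
                                   n_sweeps = 500L, burn_in = 200L,
                                   step = 0.3) {
  if (missing(seed)) stop_config("an explicit `seed` is required.")
  if (n_replicates < 2L) stop_config("need >= 2 replicates per leg.")
  seeds <- derive_seeds(seed, 2L * n_replicates)
  run_leg <- function(sys, leg_seeds) {
    reps <- lapply(leg_seeds, function(s) {
      trapezoid_integrate(sample_dhdl(sys, schedule, n_sweeps = n_sweeps,
                                      burn_in = burn_in, step = step, seed = s))
    })
    pooled <- pool_replicates(reps)
    # decoupling work = -(coupling integral)
    pooled$stages$dg <- -pooled$stages$dg
    pooled$total <- -pooled$total
    pooled$replicates <- -pooled$replicates
    pooled
  }
  leg_complex <- run_leg(sys_complex, seeds[seq_len(n_replicates)])
  leg_solvent <- run_leg(sys_solvent, seeds[n_replicates + seq_len(n_replicates)])
  structure(
    list(
      complex = leg_complex, solvent = leg_solvent,
      dg_bind = leg_solvent$total - leg_complex$total,
      se = sqrt(leg_solvent$se^2 + leg_complex$se^2)
    ),
    class = "decoupling_result"
  )
}

#' @export
print.decoupling_result <- function(x, ...) {
  cat(sprintf("<decoupling_result> dG_bind = %.4f +/- %.4f kcal/mol\n",
              x$dg_bind, x$se))
  invisible(x)
}
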