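# Implicit-solvent molecular-mechanics energetics: Coulomb and Lennard-Jones
# pair sums, Hawkins-Cramer-Truhlar effective Born radii, Still-form
# generalized Born polar solvation, Shrake-Rupley solvent-accessible surface
# area, and the single-trajectory MM-GB/SA binding estimator built on them.
#
# Units: kcal/mol for energies, Angstrom for lengths, elementary charge for
# charges. No distance cutoffs are applied anywhere: these are end-state
# rescoring energies, not simulation forces.

#' Solvent and scoring model constants
#'
#' Bundles the physical constants of the implicit-solvent scorer. Defaults
#' are the standard MM-GB/SA choices: vacuum interior dielectric, high
#' exterior dielectric, a 1.4-Angstrom water probe and a small positive
#' surface tension for the nonpolar term.
#'
#' @param eps_in Interior (solute) dielectric; must be >= 1.
#' @param eps_out Exterior (solvent) dielectric; must exceed `eps_in`.
#' @param gamma Nonpolar surface tension, kcal/(mol A^2).
#' @param beta Nonpolar offset, kcal/mol.
#' @param probe Solvent probe radius, Angstrom.
#' @param ke Coulomb constant, kcal A / (mol e^2).
#' @param sasa_points Number of deterministic sphere-sample points per atom.
#' @return A list of class `solvent_model`.
#' @export
solvent_model <- function(eps_in = 1, eps_out = 78.5, gamma = 0.0072,
                          beta = 0, probe = 1.4, ke = 332.0636,
                          sasa_points = 960L) {
  if (eps_in < 1 || eps_out <= eps_in) {
    stop_config("need eps_out > eps_in >= 1.")
  }
  if (probe < 0) stop_config("probe radius must be >= 0.")
  if (sasa_points < 1) stop_config("sasa_points must be >= 1.")
  structure(
    list(eps_in = eps_in, eps_out = eps_out, gamma = gamma, beta = beta,
         probe = probe, ke = ke, sasa_points = as.integer(sasa_points)),
    class = "solvent_model"
  )
}

#' Read and validate a per-atom force-field table
#'
#' The exchange format is tab-separated text with header columns
#' `residue_name`, `atom_name`, `charge_e`, `sigma_A`, `epsilon_kcal`,
#' `gb_radius_A`, `screen`. Internally the table is a tibble with columns
#' `resname`, `name`, `charge`, `sigma`, `epsilon`, `gb_radius`, `screen`.
#'
#' @param path TSV file path.
#' @return A validated force-field tibble.
#' @export
read_forcefield <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("residue_name", "atom_name", "charge_e", "sigma_A",
            "epsilon_kcal", "gb_radius_A", "screen")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop_parse(sprintf("force-field table lacks columns: %s.",
                       paste(missing, collapse = ", ")))
  }
  ff <- tibble::tibble(
    resname = df$residue_name, name = df$atom_name, charge = df$charge_e,
    sigma = df$sigma_A, epsilon = df$epsilon_kcal,
    gb_radius = df$gb_radius_A, screen = df$screen
  )
  validate_forcefield(ff)
}

#' @rdname read_forcefield
#' @param ff Force-field tibble.
#' @export
write_forcefield <- function(ff, path) {
  ff <- validate_forcefield(ff)
  out <- data.frame(
    residue_name = ff$resname, atom_name = ff$name, charge_e = ff$charge,
    sigma_A = ff$sigma, epsilon_kcal = ff$epsilon,
    gb_radius_A = ff$gb_radius, screen = ff$screen
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_forcefield
#' @export
validate_forcefield <- function(ff) {
  ff <- tibble::as_tibble(ff)
  need <- c("resname", "name", "charge", "sigma", "epsilon", "gb_radius", "screen")
  missing <- setdiff(need, names(ff))
  if (length(missing) > 0L) {
    stop_config(sprintf("force-field tibble lacks columns: %s.",
                        paste(missing, collapse = ", ")))
  }
  if (any(ff$epsilon < 0)) stop_config("LJ epsilon must be >= 0.")
  if (any(ff$sigma <= 0)) stop_config("LJ sigma must be > 0.")
  if (any(ff$gb_radius <= 0)) stop_config("GB radius must be > 0.")
  if (any(ff$screen <= 0 | ff$screen > 1)) stop_config("screen must be in (0, 1].")
  if (anyDuplicated(paste(ff$resname, ff$name))) {
    stop_config("duplicate (residue_name, atom_name) rows in force-field table.")
  }
  ff
}

#' Match per-atom parameters to a structure's atoms
#'
#' Each atom must match exactly one force-field row by (residue name, atom
#' name).
#'
#' @param atoms Atom tibble (from [md_structure()] / [md_trajectory()]).
#' @param ff Force-field tibble (see [read_forcefield()]).
#' @return Tibble with one parameter row per atom, in atom order.
#' @export
match_parameters <- function(atoms, ff) {
  ff <- validate_forcefield(ff)
  key <- paste(atoms$resname, atoms$name)
  idx <- match(key, paste(ff$resname, ff$name))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop_config(sprintf("no force-field parameters for atom %s of residue %s %d.",
                        atoms$name[miss], atoms$resname[miss], atoms$resid[miss]))
  }
  ff[idx, c("charge", "sigma", "epsilon", "gb_radius", "screen")]
}

check_params <- function(xyz, params) {
  if (nrow(params) != nrow(xyz)) {
    stop_config(sprintf("parameter table has %d rows for %d atoms.",
                        nrow(params), nrow(xyz)))
  }
  invisible(params)
}

# A pair mask is a logical n x n matrix; TRUE marks pairs that contribute.
# NULL means every distinct pair. Masks are used to restrict pair sums to
# intermolecular (ligand <-> receptor) terms and to express exclusions in
# toy systems.

#' Pair mask selecting only inter-group pairs
#'
#' @param n Total atom count.
#' @param idx_a,idx_b Disjoint index sets.
#' @return Logical `n x n` matrix, `TRUE` for pairs with one atom in each set.
#' @export
inter_mask <- function(n, idx_a, idx_b) {
  if (length(intersect(idx_a, idx_b)) > 0L) stop_config("index sets overlap.")
  m <- matrix(FALSE, n, n)
  m[idx_a, idx_b] <- TRUE
  m[idx_b, idx_a] <- TRUE
  m
}

pair_weights <- function(n, mask) {
  if (is.null(mask)) {
    w <- matrix(1, n, n)
  } else {
    if (!is.matrix(mask) || any(dim(mask) != n)) {
      stop_config("pair mask must be an n x n logical matrix.")
    }
    w <- (mask | t(mask)) * 1
  }
  diag(w) <- 0
  w
}

check_pair_distances <- function(d, w) {
  if (any(d < 1e-12 & w > 0)) {
    stop_geometry("coincident atoms in an unmasked pair (zero distance).")
  }
}

#' Pairwise Coulomb energy
#'
#' Plain `ke * q_i * q_j / (eps_in * r_ij)` summed over unmasked distinct
#' pairs, with no distance cutoff.
#'
#' @param xyz `n x 3` coordinate matrix (Angstrom).
#' @param params Per-atom parameter tibble (needs `charge`).
#' @param mask Optional logical pair mask (see [inter_mask()]); `NULL` for
#'   all pairs.
#' @param solvent A [solvent_model()] supplying `ke` and `eps_in`.
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(xyz, params, mask = NULL, solvent = solvent_model()) {
  assert_coords(xyz)
  check_params(xyz, params)
  n <- nrow(xyz)
  if (n < 2L) return(0)
  w <- pair_weights(n, mask)
  d <- dist_matrix(xyz)
  check_pair_distances(d, w)
  q <- params$charge
  qq <- outer(q, q)
  diag(d) <- Inf
  sum(w * qq / d) / 2 * solvent$ke / solvent$eps_in
}

#' Pairwise Lennard-Jones energy
#'
#' `4 eps_ij [ (sigma_ij/r)^12 - (sigma_ij/r)^6 ]` with Lorentz-Berthelot
#' combination (arithmetic-mean sigma, geometric-mean epsilon), no cutoff.
#'
#' @inheritParams coulomb_energy
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(xyz, params, mask = NULL) {
  assert_coords(xyz)
  check_params(xyz, params)
  n <- nrow(xyz)
  if (n < 2L) return(0)
  w <- pair_weights(n, mask)
  d <- dist_matrix(xyz)
  check_pair_distances(d, w)
  sig <- outer(params$sigma, params$sigma, function(a, b) (a + b) / 2)
  eps <- sqrt(outer(params$epsilon, params$epsilon))
  diag(d) <- Inf
  s6 <- (sig / d)^6
  sum(w * 4 * eps * (s6^2 - s6)) / 2
}

# Hawkins-Cramer-Truhlar pairwise descreening term: the analytic integral of
# |x - x_i|^-4 / (4 pi) over the scaled sphere of neighbour j (radius
# s_j * rho_j at distance r), restricted to |x - x_i| > rho_i.
hct_term <- function(r, rho_i, srho_j) {
  U <- r + srho_j
  out <- numeric(length(r))
  active <- rho_i < U
  if (!any(active)) return(out)
  r_ <- r[active]; U_ <- U[active]
  srho <- if (length(srho_j) == 1L) rep(srho_j, length(r))[active] else srho_j[active]
  rho <- if (length(rho_i) == 1L) rep(rho_i, length(r))[active] else rho_i[active]
  L_ <- pmax(rho, abs(r_ - srho))
  h <- 0.5 * ((1 / L_ - 1 / U_) +
                (r_ / 4) * (1 / U_^2 - 1 / L_^2) +
                (1 / (2 * r_)) * log(L_ / U_) +
                (srho^2 / (4 * r_)) * (1 / L_^2 - 1 / U_^2))
  engulfed <- rho < (srho - r_)
  if (any(engulfed)) {
    h[engulfed] <- h[engulfed] + 2 * (1 / rho[engulfed] - 1 / L_[engulfed])
  }
  out[active] <- h
  out
}

#' Effective Born radii (Hawkins-Cramer-Truhlar pairwise descreening)
#'
#' The inverse effective radius of each atom is its inverse intrinsic radius
#' minus the summed pairwise descreening integrals over all scaled neighbour
#' spheres. An isolated atom's effective radius equals its intrinsic radius;
#' descreening by approaching neighbours can only increase it.
#'
#' @inheritParams coulomb_energy
#' @param params Needs `gb_radius` (intrinsic radius, Angstrom) and `screen`
#'   (descreening scale in (0, 1]).
#' @return Numeric vector of per-atom effective radii (Angstrom).
#' @export
born_radii <- function(xyz, params) {
  assert_coords(xyz)
  check_params(xyz, params)
  n <- nrow(xyz)
  rho <- params$gb_radius
  s <- params$screen
  if (any(rho <= 0)) stop_config("intrinsic GB radii must be positive.")
  if (n == 1L) return(rho)
  d <- dist_matrix(xyz)
  if (any(d[upper.tri(d)] < 1e-12)) {
    stop_geometry("overlapping identical centers: zero interatomic distance.")
  }
  inv_r <- numeric(n)
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    psi <- sum(hct_term(d[i, j], rho[i], s[j] * rho[j]))
    inv_r[i] <- 1 / rho[i] - psi
  }
  1 / pmax(inv_r, 1e-6)
}

#' Generalized Born polar solvation energy (Still form)
#'
#' `-(ke/2) (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_ij` over all ordered
#' pairs including self terms, with
#' `f_ij = sqrt(r_ij^2 + R_i R_j exp(-r_ij^2 / (4 R_i R_j)))` and
#' `f_ii = R_i`, using [born_radii()] effective radii.
#'
#' @inheritParams coulomb_energy
#' @param params Needs `charge`, `gb_radius`, `screen`.
#' @return Polar solvation energy in kcal/mol (<= 0 for any real charge set).
#' @export
gb_energy <- function(xyz, params, solvent = solvent_model()) {
  assert_coords(xyz)
  check_params(xyz, params)
  R <- born_radii(xyz, params)
  q <- params$charge
  n <- nrow(xyz)
  d2 <- dist_matrix(xyz)^2
  RR <- outer(R, R)
  f <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
  diag(f) <- R
  pref <- -(solvent$ke / 2) * (1 / solvent$eps_in - 1 / solvent$eps_out)
  pref * sum(outer(q, q) / f)
}

# Deterministic, roughly uniform unit sphere point set (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere (intrinsic GB radius plus probe) is sampled with a
#' fixed deterministic Fibonacci point lattice; points falling inside any
#' neighbour's extended sphere are buried. Per-atom areas sum to the total.
#'
#' @inheritParams coulomb_energy
#' @param params Needs `gb_radius` (used as the atomic radius).
#' @return A list with `total` (Angstrom^2) and `per_atom` tibble
#'   (`atom`, `radius`, `area`).
#' @export
sasa <- function(xyz, params, solvent = solvent_model()) {
  assert_coords(xyz)
  check_params(xyz, params)
  if (solvent$sasa_points < 1L) stop_config("need at least one sample point.")
  n <- nrow(xyz)
  R <- params$gb_radius + solvent$probe
  pts <- fibonacci_sphere(solvent$sasa_points)
  area <- numeric(n)
  if (n > 1L) d <- dist_matrix(xyz)
  for (i in seq_len(n)) {
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    if (n > 1L) {
      nb <- which(d[i, ] < R[i] + R & seq_len(n) != i)
      for (j in nb) {
        dd <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
        acc <- acc & dd > R[j]^2
        if (!any(acc)) break
      }
    }
    area[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  list(
    total = sum(area),
    per_atom = tibble::tibble(atom = seq_len(n), radius = R, area = area)
  )
}

#' One-shot energy decomposition of a configuration
#'
#' Computes the four MM-GB/SA components and their total for a single
#' coordinate set. `total` is the exact sum of the components.
#'
#' @inheritParams coulomb_energy
#' @return One-row tibble: `e_coul`, `e_lj`, `g_gb`, `g_sa`, `total`.
#' @export
decompose_energy <- function(xyz, params, solvent = solvent_model(), mask = NULL) {
  ec <- coulomb_energy(xyz, params, mask, solvent)
  el <- lj_energy(xyz, params, mask)
  gg <- gb_energy(xyz, params, solvent)
  gs <- solvent$gamma * sasa(xyz, params, solvent)$total + solvent$beta
  tibble::tibble(e_coul = ec, e_lj = el, g_gb = gg, g_sa = gs,
                 total = ec + el + gg + gs)
}

sa_term <- function(xyz, params, solvent) {
  solvent$gamma * sasa(xyz, params, solvent)$total + solvent$beta
}

#' Single-trajectory MM-GB/SA binding free energy
#'
#' For every frame of a complex trajectory, the binding estimate is the
#' intermolecular molecular-mechanics energy (Coulomb + Lennard-Jones between
#' ligand and receptor) plus the change in solvation free energy
#' (generalized Born + surface-area term) on separating the complex into
#' receptor and ligand, all three species taken from the same frame. Under
#' this single-trajectory scheme intramolecular bonded terms cancel exactly,
#' which is why only intermolecular MM terms appear.
#'
#' @param traj Complex trajectory ([md_trajectory()]).
#' @param ligand_sel,receptor_sel [atom_selection()]s resolving to disjoint
#'   atom sets.
#' @param ff Force-field tibble (see [read_forcefield()]).
#' @param solvent A [solvent_model()].
#' @return Object of class `binding_result`: per-frame component tibble plus
#'   mean, standard error and component means. See [tidy.binding_result()].
#' @export
mmgbsa_binding <- function(traj, ligand_sel, receptor_sel, ff,
                           solvent = solvent_model()) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx_l <- select_atoms(traj, ligand_sel)
  idx_r <- select_atoms(traj, receptor_sel)
  if (length(idx_l) == 0L) stop_config("empty ligand selection.")
  if (length(idx_r) == 0L) stop_config("empty receptor selection.")
  if (length(intersect(idx_l, idx_r)) > 0L) {
    stop_config("ligand and receptor selections overlap.")
  }
  sub <- sort(c(idx_l, idx_r))
  atoms <- traj$atoms[sub, ]
  params <- match_parameters(atoms, ff)
  pos_l <- match(idx_l, sub)
  pos_r <- match(idx_r, sub)
  mask <- inter_mask(length(sub), pos_l, pos_r)

  rows <- purrr::map_dfr(seq_along(traj$frames), function(k) {
    xyz <- traj$frames[[k]][sub, , drop = FALSE]
    ec <- coulomb_energy(xyz, params, mask, solvent)
    el <- lj_energy(xyz, params, mask)
    gb_c <- gb_energy(xyz, params, solvent)
    gb_r <- gb_energy(xyz[pos_r, , drop = FALSE], params[pos_r, ], solvent)
    gb_l <- gb_energy(xyz[pos_l, , drop = FALSE], params[pos_l, ], solvent)
    sa_c <- sa_term(xyz, params, solvent)
    sa_r <- sa_term(xyz[pos_r, , drop = FALSE], params[pos_r, ], solvent)
    sa_l <- sa_term(xyz[pos_l, , drop = FALSE], params[pos_l, ], solvent)
    tibble::tibble(
      frame = k, e_coul = ec, e_lj = el,
      g_gb = gb_c - gb_r - gb_l, g_sa = sa_c - sa_r - sa_l,
      dg = ec + el + (gb_c - gb_r - gb_l) + (sa_c - sa_r - sa_l)
    )
  })
  nf <- nrow(rows)
  sem <- if (nf > 1L) stats::sd(rows$dg) / sqrt(nf) else 0
  structure(
    list(
      frames = rows,
      mean = mean(rows$dg),
      sem = sem,
      components = colMeans(rows[, c("e_coul", "e_lj", "g_gb", "g_sa")])
    ),
    class = "binding_result"
  )
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("<binding_result> dG = %.3f +/- %.3f kcal/mol over %d frames\n",
              x$mean, x$sem, nrow(x$frames)))
  invisible(x)
}

#' Relative binding free energies against a reference ligand
#'
#' Expresses each ligand's mean binding estimate as a difference from a
#' reference ligand (e.g. the natural agonist). A positive difference means
#' weaker binding than the reference. Standard errors combine in quadrature;
#' the reference row is exactly zero.
#'
#' @param results Named list of `binding_result` objects, one per ligand.
#' @param reference Name of the reference ligand (must be in `results`).
#' @return Tibble: `ligand`, `dg_mean`, `ddg`, `se`, `weaker_than_ref`.
#' @export
relative_binding <- function(results, reference) {
  if (!is.list(results) || is.null(names(results)) || any(names(results) == "")) {
    stop_config("`results` must be a named list of binding_result objects.")
  }
  if (!reference %in% names(results)) {
    stop_config(sprintf("reference ligand '%s' not found in results.", reference))
  }
  ref <- results[[reference]]
  purrr::imap_dfr(results, function(res, lig) {
    ddg <- res$mean - ref$mean
    se <- if (identical(lig, reference)) 0 else sqrt(res$sem^2 + ref$sem^2)
    tibble::tibble(
      ligand = lig, dg_mean = res$mean,
      ddg = if (identical(lig, reference)) 0 else ddg,
      se = se, weaker_than_ref = ddg > 0
    )
  })
}
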