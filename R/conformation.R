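# Agonist/antagonist conformational analysis: optimal rigid superposition,
# backbone RMSD against an antagonist-bound reference, kernel-density
# comparison of RMSD distributions, helix-12 open/closed state calls and
# docking-pose contact triage.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) RMSD between two matched point sets; reflections are excluded
#' by the determinant correction.
#'
#' @param mobile,reference `n x 3` matrices of matched points (n >= 3,
#'   non-collinear).
#' @param weights Optional non-negative per-point weights.
#' @return Object of class `superposition`: `rotation` (3x3, proper),
#'   `translation` (length-3), `rmsd` (Angstrom). The aligned mobile set is
#'   `mobile %*% rotation + translation` (rows).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  assert_coords(mobile, "mobile coordinates")
  assert_coords(reference, "reference coordinates")
  n <- nrow(mobile)
  if (nrow(reference) != n) stop_domain("point counts differ.")
  if (n < 3L) stop_geometry("superposition needs at least 3 points.")
  w <- if (is.null(weights)) rep(1, n) else weights
  if (length(w) != n || any(w < 0) || sum(w) <= 0) {
    stop_config("weights must be non-negative with positive sum.")
  }
  cm_m <- colSums(mobile * w) / sum(w)
  cm_r <- colSums(reference * w) / sum(w)
  X <- sweep(mobile, 2, cm_m)
  Y <- sweep(reference, 2, cm_r)
  C <- t(X * w) %*% Y
  sv <- svd(C)
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1e-300)) {
    stop_geometry("degenerate geometry (collinear points): rotation is not unique.")
  }
  d <- sign(det(sv$u) * det(sv$v))
  U <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- X %*% U
  rmsd <- sqrt(sum(w * rowSums((aligned - Y)^2)) / sum(w))
  structure(
    list(rotation = U, translation = as.numeric(cm_r - cm_m %*% U), rmsd = rmsd),
    class = "superposition"
  )
}

#' @rdname kabsch_superpose
#' @param xyz Coordinates to transform with a fitted superposition.
#' @param sp A `superposition` object.
#' @export
apply_superposition <- function(xyz, sp) {
  sweep(xyz %*% sp$rotation, 2, sp$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Per-frame RMSD of a trajectory against a reference structure
#'
#' For every frame, superposes the frame onto the reference over the fit
#' selection (Kabsch) and reports the RMSD over the measure selection
#' without refitting. Both selections default to the backbone (N, CA, C, O),
#' the standard choice for monomer-backbone RMSD analyses.
#'
#' @param traj An [md_trajectory()].
#' @param reference An [md_structure()] (e.g. an antagonist-bound reference).
#' @param fit_sel,measure_sel [atom_selection()]s; `measure_sel` defaults to
#'   `fit_sel`.
#' @return Tibble with columns `frame`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference,
                        fit_sel = atom_selection(atoms = "backbone"),
                        measure_sel = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  reference <- as_structure(reference)
  if (is.null(measure_sel)) measure_sel <- fit_sel
  fi_t <- select_atoms(traj, fit_sel)
  fi_r <- select_atoms(reference, fit_sel)
  mi_t <- select_atoms(traj, measure_sel)
  mi_r <- select_atoms(reference, measure_sel)
  if (length(fi_t) != length(fi_r)) {
    stop_domain(sprintf(
      "fit selection resolves to %d atoms in the trajectory but %d in the reference.",
      length(fi_t), length(fi_r)
    ))
  }
  if (length(mi_t) != length(mi_r)) {
    stop_domain(sprintf(
      "measure selection resolves to %d atoms in the trajectory but %d in the reference.",
      length(mi_t), length(mi_r)
    ))
  }
  ref_fit <- reference$xyz[fi_r, , drop = FALSE]
  ref_meas <- reference$xyz[mi_r, , drop = FALSE]
  vals <- vapply(traj$frames, function(f) {
    sp <- kabsch_superpose(f[fi_t, , drop = FALSE], ref_fit)
    moved <- apply_superposition(f[mi_t, , drop = FALSE], sp)
    sqrt(mean(rowSums((moved - ref_meas)^2)))
  }, numeric(1))
  tibble::tibble(frame = seq_along(vals), rmsd = vals)
}

#' Gaussian kernel density of an RMSD sample
#'
#' Density on a grid spanning `[min - 3h, max + 3h]` with Silverman's
#' rule-of-thumb bandwidth by default (floored at 0.01 Angstrom for
#' degenerate samples, with a warning). The trapezoid integral of the
#' density over the grid is 1 to within 1e-3.
#'
#' @param values Numeric vector of RMSD values (>= 10), or a tibble with an
#'   `rmsd` column as returned by [rmsd_series()].
#' @param bandwidth `"auto"` (Silverman) or a bandwidth in Angstrom.
#' @param n_grid Grid size.
#' @return Object of class `rmsd_density`: `values`, `grid` tibble
#'   (`x`, `density`), `bandwidth`, `summary` (median, 5th/95th percentiles).
#' @export
density_estimate <- function(values, bandwidth = "auto", n_grid = 512L) {
  values <- extract_rmsd_values(values)
  if (length(values) < 10L) {
    stop_domain(sprintf("density estimation needs >= 10 values (got %d).", length(values)))
  }
  h <- if (identical(bandwidth, "auto")) {
    bw <- if (stats::sd(values) == 0) 0 else {
      tryCatch(stats::bw.nrd0(values), error = function(e) 0)
    }
    if (!is.finite(bw) || bw < 0.01) {
      warn("auto bandwidth below the 0.01 A floor (near-degenerate sample); using 0.01 A.")
      0.01
    } else bw
  } else {
    if (!is.numeric(bandwidth) || bandwidth <= 0) stop_config("bandwidth must be positive.")
    bandwidth
  }
  d <- stats::density(values, bw = h, from = min(values) - 3 * h,
                      to = max(values) + 3 * h, n = n_grid)
  structure(
    list(
      values = values,
      grid = tibble::tibble(x = d$x, density = d$y),
      bandwidth = h,
      summary = tibble::tibble(
        median = stats::median(values),
        q05 = unname(stats::quantile(values, 0.05)),
        q95 = unname(stats::quantile(values, 0.95))
      )
    ),
    class = "rmsd_density"
  )
}

extract_rmsd_values <- function(x) {
  if (inherits(x, "rmsd_density")) return(x$values)
  if (is.data.frame(x)) {
    if (!"rmsd" %in% names(x)) stop_config("data frame input needs an `rmsd` column.")
    return(x$rmsd)
  }
  if (!is.numeric(x)) stop_config("expected numeric values, an rmsd tibble, or an rmsd_density.")
  x
}

#' @export
print.rmsd_density <- function(x, ...) {
  cat(sprintf("<rmsd_density> n = %d, bw = %.3f A, median = %.3f A\n",
              length(x$values), x$bandwidth, x$summary$median))
  invisible(x)
}

# Stochastic ordering by exhaustive pairing of two samples.
ordering_prob <- function(a, b) {
  cmp <- outer(a, b, "-")
  list(p_less = mean(cmp < 0), p_greater = mean(cmp > 0), p_tie = mean(cmp == 0))
}

#' Classify a ligand's conformational tendency against two controls
#'
#' Compares the RMSD-to-antagonist-reference distribution of a query ligand
#' with agonist- and antagonist-control distributions. Higher RMSD from the
#' antagonist-bound reference means the ensemble stays away from the open
#' (antagonist) conformation, i.e. behaves agonist-like. The verdict
#' compares sample medians with a small tie margin: agonist-like when the
#' query median is at or above the agonist control's (minus the margin),
#' antagonist-like when at or below the antagonist control's (plus the
#' margin), intermediate otherwise; when the two control medians themselves
#' fall within one margin the nearer control wins. Verdicts are always
#' reported together with the medians and exhaustive-pairing ordering
#' probabilities, never alone.
#'
#' @param query,agonist_ctrl,antagonist_ctrl RMSD samples (numeric vectors,
#'   [rmsd_series()] tibbles or [density_estimate()] objects), >= 10 frames
#'   each.
#' @param margin Median tie margin in Angstrom.
#' @return Object of class `tendency_report`: `medians` tibble (role, n,
#'   median, rank), `ordering` tibble of pairwise ordering probabilities,
#'   `verdict`, `margin`.
#' @export
classify_tendency <- function(query, agonist_ctrl, antagonist_ctrl,
                              margin = 0.1) {
  q <- extract_rmsd_values(query)
  a <- extract_rmsd_values(agonist_ctrl)
  b <- extract_rmsd_values(antagonist_ctrl)
  for (v in list(q = q, a = a, b = b)) {
    if (length(v) < 10L) stop_domain("each distribution needs >= 10 frames.")
  }
  med <- c(query = stats::median(q), agonist_ctrl = stats::median(a),
           antagonist_ctrl = stats::median(b))
  agonist_like <- med["query"] >= med["agonist_ctrl"] - margin
  antagonist_like <- med["query"] <= med["antagonist_ctrl"] + margin
  verdict <- if (agonist_like && antagonist_like) {
    # controls closer than one margin: side with the nearer control
    if (abs(med["query"] - med["agonist_ctrl"]) <=
          abs(med["query"] - med["antagonist_ctrl"])) "agonist-like" else "antagonist-like"
  } else if (agonist_like) {
    "agonist-like"
  } else if (antagonist_like) {
    "antagonist-like"
  } else {
    "intermediate"
  }
  pairs <- list(
    c("query", "agonist_ctrl"), c("query", "antagonist_ctrl"),
    c("agonist_ctrl", "antagonist_ctrl")
  )
  samples <- list(query = q, agonist_ctrl = a, antagonist_ctrl = b)
  ordering <- purrr::map_dfr(pairs, function(p) {
    op <- ordering_prob(samples[[p[1]]], samples[[p[2]]])
    tibble::tibble(a = p[1], b = p[2], p_less = op$p_less,
                   p_greater = op$p_greater, p_tie = op$p_tie)
  })
  medians <- tibble::tibble(
    role = names(med), n = vapply(samples, length, integer(1)),
    median = unname(med), rank = rank(med, ties.method = "first")
  )
  structure(
    list(medians = medians, ordering = ordering, verdict = verdict,
         margin = margin),
    class = "tendency_report"
  )
}

#' @export
print.tendency_report <- function(x, ...) {
  cat(sprintf("<tendency_report> verdict: %s\n", x$verdict))
  cat(sprintf("  medians (A): query %.3f | agonist ctrl %.3f | antagonist ctrl %.3f\n",
              x$medians$median[x$medians$role == "query"],
              x$medians$median[x$medians$role == "agonist_ctrl"],
              x$medians$median[x$medians$role == "antagonist_ctrl"]))
  invisible(x)
}

#' Helix-12 open/closed state of trajectory frames
#'
#' Superposes each frame on the non-helix-12 backbone of each reference and
#' compares the unrefitted helix-12 RMSD to the active (closed) and inactive
#' (open) references. A frame is `closed` when its helix-12 RMSD to the
#' active reference beats the inactive one by more than `margin`, `open` for
#' the converse, `intermediate` otherwise; the margin avoids flip-flopping
#' labels on boundary frames.
#'
#' @param x An [md_trajectory()] or [md_structure()].
#' @param active_ref,inactive_ref Reference [md_structure()]s (agonist-bound
#'   closed and antagonist-bound open conformations).
#' @param h12_sel [atom_selection()] for the helix-12 backbone (default
#'   residues 532-552).
#' @param margin Decision margin in Angstrom.
#' @return Tibble: `frame`, `rmsd_active`, `rmsd_inactive`, `state`.
#' @export
h12_state <- function(x, active_ref, inactive_ref,
                      h12_sel = atom_selection(resid = 532:552, atoms = "backbone"),
                      margin = 0.5) {
  traj <- if (inherits(x, "md_structure")) md_trajectory(x$atoms, list(x$xyz)) else x
  stopifnot(inherits(traj, "md_trajectory"))
  active_ref <- as_structure(active_ref)
  inactive_ref <- as_structure(inactive_ref)
  h12_resid <- h12_sel$resid
  if (is.null(h12_resid)) stop_config("h12_sel must restrict residue ids.")
  fit_sel <- atom_selection(
    chain = h12_sel$chain,
    resid = setdiff(unique(traj$atoms$resid), h12_resid),
    atoms = "backbone"
  )
  one_ref <- function(ref) {
    fi_t <- select_atoms(traj, fit_sel)
    fi_r <- select_atoms(ref, fit_sel)
    hi_t <- select_atoms(traj, h12_sel)
    hi_r <- select_atoms(ref, h12_sel)
    if (length(hi_t) == 0L || length(hi_r) == 0L) {
      stop_domain("helix-12 selection resolves to no atoms.")
    }
    if (length(fi_t) != length(fi_r) || length(hi_t) != length(hi_r)) {
      stop_domain("selections resolve to different atom counts in frame and reference.")
    }
    vapply(traj$frames, function(f) {
      sp <- kabsch_superpose(f[fi_t, , drop = FALSE], ref$xyz[fi_r, , drop = FALSE])
      moved <- apply_superposition(f[hi_t, , drop = FALSE], sp)
      sqrt(mean(rowSums((moved - ref$xyz[hi_r, , drop = FALSE])^2)))
    }, numeric(1))
  }
  ra <- one_ref(active_ref)
  ri <- one_ref(inactive_ref)
  state <- dplyr::case_when(
    ra < ri - margin ~ "closed",
    ri < ra - margin ~ "open",
    TRUE ~ "intermediate"
  )
  tibble::tibble(frame = seq_along(ra), rmsd_active = ra,
                 rmsd_inactive = ri, state = state)
}

#' Docking-pose contact triage against key binding-site residues
#'
#' Reports the minimum heavy-atom distance between the ligand and each key
#' binding-site residue (for the estrogen receptor alpha pocket: Glu353,
#' Arg394, His524) and labels the pose. A pose is `agonist-like` when all
#' key residues are within the interaction cutoff; when exactly one residue
#' is out of reach the label names it (e.g. `His524-lost`, the classic
#' antagonist signature); anything else is `other`.
#'
#' @param complex An [md_structure()] of the docked complex.
#' @param ligand_resname Residue name of the ligand (HETATM residue).
#' @param key_resids Integer residue ids of the key binding-site residues.
#' @param cutoff Interaction distance cutoff in Angstrom. The default 4.0
#'   covers hydrogen bonds and close polar contacts.
#' @return Object of class `contact_report`: `contacts` tibble (`residue`,
#'   `resid`, `min_dist`, `interacting`), `label`, `cutoff`.
#' @export
pose_contacts <- function(complex, ligand_resname,
                          key_resids = c(353L, 394L, 524L), cutoff = 4.0) {
  complex <- as_structure(complex)
  a <- complex$atoms
  lig <- which(a$resname == ligand_resname & a$element != "H")
  if (length(lig) == 0L) {
    stop_domain(sprintf("ligand residue '%s' not found.", ligand_resname))
  }
  rows <- purrr::map_dfr(key_resids, function(rid) {
    idx <- which(a$resid == rid & !a$het & a$element != "H")
    if (length(idx) == 0L) {
      stop_domain(sprintf("key residue %d not found in receptor numbering.", rid))
    }
    d2 <- outer(rowSums(complex$xyz[lig, , drop = FALSE]^2),
                rowSums(complex$xyz[idx, , drop = FALSE]^2), "+") -
      2 * complex$xyz[lig, , drop = FALSE] %*% t(complex$xyz[idx, , drop = FALSE])
    dmin <- sqrt(max(min(d2), 0))
    tibble::tibble(
      residue = paste0(substr(a$resname[idx[1]], 1, 1),
                       tolower(substr(a$resname[idx[1]], 2, 3)), rid),
      resid = rid, min_dist = dmin, interacting = dmin <= cutoff
    )
  })
  lost <- which(!rows$interacting)
  label <- if (length(lost) == 0L) {
    "agonist-like"
  } else if (length(lost) == 1L) {
    paste0(rows$residue[lost], "-lost")
  } else {
    "other"
  }
  structure(list(contacts = rows, label = label, cutoff = cutoff),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("<contact_report> label: %s (cutoff %.1f A)\n", x$label, x$cutoff))
  print(x$contacts)
  invisible(x)
}
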