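# Synthetic fixtures: ideal helices with receptor-style author numbering,
# receptor mimics with a plantable helix-12 displacement, two-basin
# conformational ensembles with known per-frame labels, toy receptor-ligand
# complexes with printed parameters, and lambda series with known integrals.
# Everything is deterministic under a fixed seed.

#' Ideal alpha-helix backbone
#'
#' Places backbone atoms (N, CA, C, O) of each residue on an ideal helical
#' lattice (default rise 1.5 A and twist 100 degrees per residue, giving the
#' canonical ~3.8 A consecutive CA-CA distance). Residue ids run
#' sequentially from `start_resid`, so a 21-residue helix started at 532
#' carries the helix-12 author numbering (532-552) used for real receptor
#' structures.
#'
#' @param n_residues Number of residues (>= 3).
#' @param rise Rise per residue, Angstrom.
#' @param twist Twist per residue, degrees.
#' @param start_resid First residue id.
#' @param chain Chain id.
#' @param resname Residue name used for every residue.
#' @param origin Length-3 offset added to all coordinates.
#' @return An [md_structure()] with `4 * n_residues` atoms.
#' @examples
#' h12 <- make_ideal_helix(21, start_resid = 532)
#' nrow(h12$atoms)  # 84
#' @export
make_ideal_helix <- function(n_residues, rise = 1.5, twist = 100,
                             start_resid = 1L, chain = "A", resname = "ALA",
                             origin = c(0, 0, 0)) {
  if (n_residues < 3L) stop_config("an ideal helix needs >= 3 residues.")
  helix_pos <- function(t, radius) {
    th <- twist * pi / 180 * t
    cbind(radius * cos(th), radius * sin(th), rise * t)
  }
  i <- seq_len(n_residues) - 1
  coords <- vector("list", n_residues)
  for (k in seq_len(n_residues)) {
    t <- i[k]
    coords[[k]] <- rbind(
      helix_pos(t - 0.35, 1.6),  # N
      helix_pos(t, 2.3),         # CA
      helix_pos(t + 0.42, 2.0),  # C
      helix_pos(t + 0.42, 3.2)   # O (radially out from C)
    )
  }
  xyz <- do.call(rbind, coords)
  xyz <- sweep(xyz, 2, -origin)
  n_atoms <- 4L * n_residues
  atoms <- tibble::tibble(
    serial = seq_len(n_atoms),
    name = rep(c("N", "CA", "C", "O"), n_residues),
    altloc = "",
    resname = resname,
    chain = chain,
    resid = rep(as.integer(start_resid) + as.integer(i), each = 4L),
    element = rep(c("N", "C", "C", "O"), n_residues),
    het = FALSE
  )
  md_structure(atoms, xyz)
}

#' Receptor mimic with a plantable helix-12
#'
#' Builds a minimal two-helix receptor: a 31-residue core helix (residues
#' 400-430) and a 21-residue helix-12 mimic (residues 532-552) packed next
#' to it. With `open = TRUE` the helix-12 is rigidly displaced by
#' `displacement`, emulating the open (antagonist) conformation; the closed
#' and open builds serve as active and inactive references.
#'
#' @param open Logical; build the open (displaced helix-12) conformation?
#' @param displacement Length-3 rigid displacement of helix-12 (Angstrom)
#'   used for the open state.
#' @param chain Chain id.
#' @return An [md_structure()].
#' @export
make_mimic_receptor <- function(open = FALSE, displacement = c(6, 6, 0),
                                chain = "A") {
  core <- make_ideal_helix(31, start_resid = 400L, chain = chain)
  h12_origin <- c(10, 0, 7.5)
  if (open) h12_origin <- h12_origin + displacement
  h12 <- make_ideal_helix(21, start_resid = 532L, chain = chain,
                          origin = h12_origin)
  atoms <- dplyr::bind_rows(core$atoms, h12$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  md_structure(atoms, rbind(core$xyz, h12$xyz))
}

#' Two-basin conformational ensemble with planted labels
#'
#' Draws each frame open with probability `open_fraction`; open frames have
#' the helix-12 atoms rigidly displaced by `displacement`; isotropic
#' Gaussian jitter of standard deviation `sigma` is added to every atom of
#' every frame. The planted per-frame labels are returned alongside the
#' trajectory for recovery tests (write them with [write_labels()]; they are
#' never embedded in the PDB).
#'
#' @param receptor Closed-state receptor [md_structure()] (e.g.
#'   [make_mimic_receptor()]).
#' @param n_frames Number of frames.
#' @param open_fraction Probability in `[0, 1]` that a frame is open.
#' @param displacement Length-3 rigid helix-12 displacement for open frames.
#' @param sigma Per-atom Gaussian jitter standard deviation, Angstrom.
#' @param seed Mandatory RNG seed.
#' @param h12_sel [atom_selection()] identifying the helix-12 atoms.
#' @param frame_ns Optional time-per-frame metadata.
#' @return List with `trajectory` ([md_trajectory()]) and `labels` tibble
#'   (`frame`, `state`).
#' @export
gen_two_basin_trajectory <- function(receptor, n_frames, open_fraction,
                                     displacement = c(6, 6, 0), sigma = 0.3,
                                     seed,
                                     h12_sel = atom_selection(resid = 532:552, atoms = "all"),
                                     frame_ns = NA_real_) {
  if (missing(seed)) stop_config("an explicit `seed` is required.")
  if (open_fraction < 0 || open_fraction > 1) stop_config("open_fraction must be in [0, 1].")
  if (sigma < 0) stop_config("sigma must be >= 0.")
  if (n_frames < 1L) stop_config("need at least one frame.")
  receptor <- as_structure(receptor)
  h12_idx <- select_atoms(receptor, h12_sel)
  n_atoms <- nrow(receptor$xyz)
  with_seed(seed, {
    open <- stats::rbinom(n_frames, 1L, open_fraction) == 1L
    frames <- lapply(seq_len(n_frames), function(k) {
      xyz <- receptor$xyz
      if (open[k]) {
        xyz[h12_idx, ] <- sweep(xyz[h12_idx, , drop = FALSE], 2, -displacement)
      }
      xyz + matrix(stats::rnorm(3L * n_atoms, sd = sigma), ncol = 3L)
    })
    list(
      trajectory = md_trajectory(receptor$atoms, frames, frame_ns = frame_ns),
      labels = tibble::tibble(frame = seq_len(n_frames),
                              state = ifelse(open, "open", "closed"))
    )
  })
}

#' @rdname gen_two_basin_trajectory
#' @param labels Labels tibble.
#' @param path TSV path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(as.data.frame(labels), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname gen_two_basin_trajectory
#' @export
read_labels <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Toy receptor-ligand complex with printed parameters
#'
#' Builds a reproducible desk-scale complex: `n_receptor` particles
#' clustered at the origin and `n_ligand` particles displaced by
#' `separation` along x, with fully specified nonbonded parameters. Returns
#' the sampling system, the force-field table and an [md_structure()] (the
#' receptor as residue `REC`, the ligand as HETATM residue `LIG`) so the
#' same fixture can be written to PDB and scored by every stage.
#'
#' @param n_receptor,n_ligand Particle counts (>= 1).
#' @param separation Receptor-ligand center separation, Angstrom.
#' @param receptor_charges,ligand_charges Charge vectors (recycled); the
#'   defaults alternate small +/- charges on the receptor and put a small
#'   positive charge on the ligand.
#' @param sigma,epsilon,gb_radius,screen Shared LJ/GB parameters.
#' @param temperature Kelvin.
#' @param seed Seed for the deterministic receptor-cluster jitter.
#' @param box,restraint_k Passed to [toy_system()].
#' @return List with `system` ([toy_system()]), `ff` (force-field tibble),
#'   `structure` ([md_structure()]), `ligand_sel`, `receptor_sel`.
#' @export
gen_toy_complex <- function(n_receptor = 8L, n_ligand = 2L, separation = 6,
                            receptor_charges = NULL, ligand_charges = NULL,
                            sigma = 3.0, epsilon = 0.15, gb_radius = 1.7,
                            screen = 0.8, temperature = 310, seed = 1L,
                            box = NULL, restraint_k = 0) {
  if (n_receptor < 1L || n_ligand < 1L) stop_config("particle counts must be >= 1.")
  if (is.null(receptor_charges)) {
    receptor_charges <- rep_len(c(0.2, -0.2), n_receptor)
  }
  if (is.null(ligand_charges)) ligand_charges <- rep_len(0.1, n_ligand)
  receptor_charges <- rep_len(receptor_charges, n_receptor)
  ligand_charges <- rep_len(ligand_charges, n_ligand)

  with_seed(seed, {
    xyz_r <- if (n_receptor == 1L) {
      matrix(0, 1L, 3L)
    } else {
      # jittered cubic-ish cluster, spacing ~ sigma so LJ is near its well
      side <- ceiling(n_receptor^(1 / 3))
      g <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side)))
      g <- g[seq_len(n_receptor), , drop = FALSE] * sigma * 1.12
      sweep(g, 2, colMeans(g)) + matrix(stats::runif(3L * n_receptor, -0.1, 0.1), ncol = 3L)
    }
    xyz_l <- matrix(0, n_ligand, 3L)
    if (n_ligand > 1L) xyz_l[, 2] <- (seq_len(n_ligand) - (n_ligand + 1) / 2) * 1.5
    xyz_l[, 1] <- xyz_l[, 1] + separation + max(xyz_r[, 1])
    xyz <- rbind(xyz_r, xyz_l)
    n <- n_receptor + n_ligand

    ff <- tibble::tibble(
      resname = c(rep("REC", n_receptor), rep("LIG", n_ligand)),
      name = c(paste0("R", seq_len(n_receptor)), paste0("L", seq_len(n_ligand))),
      charge = c(receptor_charges, ligand_charges),
      sigma = sigma, epsilon = epsilon, gb_radius = gb_radius, screen = screen
    )
    atoms <- tibble::tibble(
      serial = seq_len(n),
      name = ff$name,
      altloc = "",
      resname = ff$resname,
      chain = "A",
      resid = c(rep(1L, n_receptor), rep(2L, n_ligand)),
      element = "C",
      het = ff$resname == "LIG"
    )
    sys <- toy_system(
      xyz, ff[, c("charge", "sigma", "epsilon", "gb_radius", "screen")],
      ligand = n_receptor + seq_len(n_ligand), temperature = temperature,
      box = box, restraint_k = restraint_k
    )
    list(
      system = sys, ff = validate_forcefield(ff),
      structure = md_structure(atoms, xyz),
      ligand_sel = atom_selection(resid = 2L, atoms = "all"),
      receptor_sel = atom_selection(resid = 1L, atoms = "all")
    )
  })
}

#' Lambda series with a known analytic integral
#'
#' Generates node means from a constant, linear or quadratic model of
#' lambda, optionally perturbed by Gaussian noise, and attaches the exact
#' per-schedule integral as the `ground_truth` attribute, for validating
#' the trapezoidal integrator.
#'
#' @param model `"constant"` (`coef`), `"linear"` (`coef * lambda`) or
#'   `"quadratic"` (`coef * lambda^2`).
#' @param coef Model coefficient.
#' @param noise Gaussian noise standard deviation added to node means.
#' @param schedule A [build_schedule()] / [single_stage_schedule()] tibble.
#' @param seed Seed (required when `noise > 0`).
#' @param n_samples Reported per-node sample count metadata.
#' @return A `lambda_series` tibble with attribute `ground_truth` (the
#'   analytic integral summed over stages).
#' @export
gen_lambda_series <- function(model = c("constant", "linear", "quadratic"),
                              coef = 1, noise = 0,
                              schedule = single_stage_schedule("charge", 5L),
                              seed = NULL, n_samples = 1000L) {
  model <- match.arg(model)
  schedule <- validate_schedule(schedule)
  if (noise > 0 && is.null(seed)) stop_config("a `seed` is required when noise > 0.")
  f <- switch(model,
    constant = function(l) rep(coef, length(l)),
    linear = function(l) coef * l,
    quadratic = function(l) coef * l^2
  )
  per_stage <- switch(model, constant = coef, linear = coef / 2, quadratic = coef / 3)
  out <- with_seed(seed, {
    m <- f(schedule$lambda) + if (noise > 0) stats::rnorm(nrow(schedule), sd = noise) else 0
    tibble::tibble(
      stage = schedule$stage, lambda = schedule$lambda, dhdl_mean = m,
      dhdl_se = noise, n_samples = n_samples
    )
  })
  class(out) <- c("lambda_series", class(out))
  attr(out, "ground_truth") <- per_stage * length(unique(schedule$stage))
  out
}

#' Synthetic docked pose for contact triage
#'
#' Places single-atom stand-ins for the three key binding-site residues
#' (Glu353, Arg394, His524) at fixed, well-separated positions and a
#' three-atom ligand with one atom at a chosen distance from each residue,
#' so any pattern of kept/lost contacts can be planted exactly.
#'
#' @param dist_glu353,dist_arg394,dist_his524 Planted minimum distances
#'   (Angstrom).
#' @param ligand_resname Ligand residue name.
#' @return An [md_structure()] of the synthetic pose.
#' @export
gen_docked_pose <- function(dist_glu353 = 3.5, dist_arg394 = 3.5,
                            dist_his524 = 3.5, ligand_resname = "LIG") {
  key <- rbind(c(0, 0, 0), c(12, 0, 0), c(6, 10, 0))
  d <- c(dist_glu353, dist_arg394, dist_his524)
  lig <- key + cbind(0, 0, d)
  atoms <- tibble::tibble(
    serial = 1:6,
    name = c("CB", "CB", "CB", "C1", "C2", "C3"),
    altloc = "",
    resname = c("GLU", "ARG", "HIS", rep(ligand_resname, 3)),
    chain = "A",
    resid = c(353L, 394L, 524L, 600L, 600L, 600L),
    element = "C",
    het = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  md_structure(atoms, rbind(key, lig))
}
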