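#' Structure and trajectory containers
#'
#' A structure is a light S3 list holding an atom table (tibble, one row per
#' atom) and an `n x 3` coordinate matrix in Angstrom. A trajectory holds the
#' same atom table (the topology) plus an ordered list of coordinate matrices,
#' one per frame, and optional time-per-frame metadata in nanoseconds.
#'
#' Atom table columns: `serial`, `name`, `altloc`, `resname`, `chain`,
#' `resid`, `element`, `het`. Residue ids are the author numbering read
#' verbatim from the file, so selections written for real receptor structures
#' (e.g. helix-12 at residues 532-552, or binding-site residues Glu353,
#' Arg394, His524) mean the same thing on synthetic mimics.
#'
#' @param atoms Atom tibble as described above.
#' @param xyz Numeric `n x 3` coordinate matrix (Angstrom).
#' @param frames List of `n x 3` coordinate matrices.
#' @param frame_ns Time per frame in nanoseconds, or `NA` if unknown.
#' @return `md_structure()` returns an object of class `md_structure`;
#'   `md_trajectory()` an object of class `md_trajectory`.
#' @export
md_structure <- function(atoms, xyz) {
  atoms <- tibble::as_tibble(atoms)
  assert_coords(xyz, "structure coordinates")
  if (nrow(atoms) != nrow(xyz)) {
    stop_domain(sprintf(
      "atom count (%d) does not match coordinate count (%d).",
      nrow(atoms), nrow(xyz)
    ))
  }
  structure(list(atoms = atoms, xyz = xyz), class = "md_structure")
}

#' @rdname md_structure
#' @export
md_trajectory <- function(atoms, frames, frame_ns = NA_real_) {
  atoms <- tibble::as_tibble(atoms)
  if (!is.list(frames) || length(frames) == 0L) {
    stop_domain("`frames` must be a non-empty list of coordinate matrices.")
  }
  for (k in seq_along(frames)) {
    assert_coords(frames[[k]], sprintf("frame %d coordinates", k))
    if (nrow(frames[[k]]) != nrow(atoms)) {
      stop_domain(sprintf(
        "frame %d has %d atoms but the topology has %d.",
        k, nrow(frames[[k]]), nrow(atoms)
      ))
    }
  }
  structure(
    list(atoms = atoms, frames = frames, frame_ns = frame_ns),
    class = "md_trajectory"
  )
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf(
    "<md_structure> %d atoms, %d residues, chains: %s\n",
    nrow(x$atoms), dplyr::n_distinct(x$atoms$resid, x$atoms$chain),
    paste(unique(x$atoms$chain), collapse = ",")
  ))
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "<md_trajectory> %d atoms x %d frames%s\n",
    nrow(x$atoms), length(x$frames),
    if (is.na(x$frame_ns)) "" else sprintf(" (%.4g ns/frame)", x$frame_ns)
  ))
  invisible(x)
}

#' @rdname md_structure
#' @param x A trajectory.
#' @param frame Frame index.
#' @export
as_structure <- function(x, frame = 1L) {
  if (inherits(x, "md_structure")) return(x)
  if (!inherits(x, "md_trajectory")) stop_domain("expected md_structure or md_trajectory.")
  if (frame < 1L || frame > length(x$frames)) {
    stop_domain(sprintf("frame %d out of range (1..%d).", frame, length(x$frames)))
  }
  md_structure(x$atoms, x$frames[[frame]])
}

#' @rdname md_structure
#' @export
n_frames <- function(x) {
  if (inherits(x, "md_trajectory")) length(x$frames) else 1L
}

#' Total simulated time of a trajectory
#'
#' Multiplies the frame count by the per-frame duration metadata. Returns
#' `NA` with a warning when the trajectory carries no time metadata;
#' bookkeeping operations warn rather than fail in that case.
#'
#' @param traj An `md_trajectory`.
#' @return Total time in nanoseconds (scalar), or `NA`.
#' @export
traj_time_ns <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.na(traj$frame_ns)) {
    warn("trajectory has no time metadata; returning NA.")
    return(NA_real_)
  }
  length(traj$frames) * traj$frame_ns
}

# ---------------------------------------------------------------------------
# PDB parsing (fixed-column dialect)

pdb_field <- function(lines, from, to) substr(lines, from, to)

infer_element <- function(raw_name) {
  # PDB convention: a name starting in column 13 (no leading blank in the
  # 4-char field) signals a two-letter element (CL, NA, FE ...).
  two <- grepl("^[A-Za-z]{2}", raw_name)
  nm <- gsub("[^A-Za-z]", "", raw_name)
  el <- toupper(substr(nm, 1L, ifelse(two, 2L, 1L)))
  el[el == ""] <- "X"
  el
}

#' Read a PDB file or character stream into a trajectory
#'
#' Fixed-column parsing of ATOM/HETATM records. Multi-MODEL files are read as
#' trajectories (one frame per MODEL block); files without MODEL records give
#' a single-frame trajectory. Alternate locations other than blank or 'A' are
#' dropped; insertion codes are rejected; HETATM records (ligands, ions) are
#' kept and flagged in the `het` column so they can be selected by residue
#' name.
#'
#' @param input Path to a PDB file, or a character vector of PDB lines
#'   (a single string is split on newlines).
#' @param frame_ns Optional time-per-frame metadata (ns) to attach.
#' @return An [md_trajectory()].
#' @examples
#' helix <- make_ideal_helix(5)
#' path <- tempfile(fileext = ".pdb")
#' write_pdb(helix, path)
#' parse_pdb(path)
#' @export
parse_pdb <- function(input, frame_ns = NA_real_) {
  lines <- if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else if (length(input) == 1L) {
    strsplit(input, "\n", fixed = TRUE)[[1]]
  } else {
    input
  }
  rec <- pdb_field(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | grepl("^(ATOM|HETATM)", rec)
  is_model <- grepl("^MODEL", rec)
  is_endmdl <- grepl("^ENDMDL", rec)
  if (!any(is_atom)) stop_parse("no ATOM/HETATM records found.")

  # Assign a model index to every atom line.
  model_idx <- cumsum(is_model)
  has_models <- any(is_model)
  atom_lineno <- which(is_atom)
  atom_model <- if (has_models) model_idx[atom_lineno] else rep(1L, length(atom_lineno))
  if (has_models && any(atom_model == 0L)) {
    stop_parse("ATOM records found before the first MODEL record.")
  }

  al <- lines[atom_lineno]
  altloc <- pdb_field(al, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  al <- al[keep]
  atom_model <- atom_model[keep]
  atom_lineno <- atom_lineno[keep]

  icode <- trimws(pdb_field(al, 27, 27))
  if (any(icode != "")) {
    stop_parse(sprintf(
      "insertion codes are not supported (first at line %d).",
      atom_lineno[which(icode != "")[1]]
    ))
  }

  coord_txt <- cbind(pdb_field(al, 31, 38), pdb_field(al, 39, 46), pdb_field(al, 47, 54))
  coords <- suppressWarnings(matrix(as.numeric(coord_txt), ncol = 3L))
  if (any(!is.finite(coords))) {
    bad <- which(rowSums(!is.finite(coords)) > 0)[1]
    stop_parse(sprintf("non-numeric coordinate field at line %d.", atom_lineno[bad]))
  }

  models <- sort(unique(atom_model))
  per_model <- split(seq_along(al), atom_model)
  counts <- lengths(per_model)
  if (length(unique(counts)) > 1L) {
    bad <- models[which(counts != counts[1])[1]]
    stop_parse(sprintf(
      "inconsistent atom count across models: model %d has %d atoms, model %d has %d.",
      models[1], counts[1], bad, counts[names(counts) == as.character(bad)]
    ))
  }

  first <- per_model[[1]]
  fl <- al[first]
  resid_txt <- trimws(pdb_field(fl, 23, 26))
  resid <- suppressWarnings(as.integer(resid_txt))
  if (any(is.na(resid))) {
    stop_parse(sprintf("non-numeric residue id at line %d.", atom_lineno[first[which(is.na(resid))[1]]]))
  }
  raw_name <- pdb_field(fl, 13, 16)
  elem_col <- toupper(trimws(pdb_field(fl, 77, 78)))
  element <- ifelse(elem_col == "" | is.na(elem_col), infer_element(raw_name), elem_col)
  atoms <- tibble::tibble(
    serial = suppressWarnings(as.integer(trimws(pdb_field(fl, 7, 11)))),
    name = trimws(raw_name),
    altloc = trimws(pdb_field(fl, 17, 17)),
    resname = trimws(pdb_field(fl, 18, 20)),
    chain = pdb_field(fl, 22, 22),
    resid = resid,
    element = element,
    het = grepl("^HETATM", fl)
  )

  frames <- lapply(per_model, function(ix) {
    m <- coords[ix, , drop = FALSE]
    dimnames(m) <- NULL
    m
  })
  names(frames) <- NULL
  md_trajectory(atoms, frames, frame_ns = frame_ns)
}

#' Write a structure or trajectory as PDB
#'
#' Trajectories are written as multi-MODEL files (one MODEL/ENDMDL block per
#' frame), which is also the fixture trajectory format used throughout the
#' package.
#'
#' @param x An [md_structure()] or [md_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  fmt_atom <- function(a, xyz, i) {
    name <- a$name[i]
    # names shorter than 4 chars start in column 14
    name_f <- if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
    sprintf(
      "%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      if (isTRUE(a$het[i])) "HETATM" else "ATOM",
      a$serial[i] %% 100000L, name_f,
      ifelse(is.na(a$altloc[i]) | a$altloc[i] == "", " ", a$altloc[i]),
      a$resname[i], a$chain[i], a$resid[i],
      xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, a$element[i]
    )
  }
  emit_frame <- function(a, xyz) vapply(seq_len(nrow(a)), function(i) fmt_atom(a, xyz, i), character(1))
  if (inherits(x, "md_structure")) {
    lines <- c(emit_frame(x$atoms, x$xyz), "END")
  } else if (inherits(x, "md_trajectory")) {
    blocks <- lapply(seq_along(x$frames), function(k) {
      c(sprintf("MODEL     %4d", k), emit_frame(x$atoms, x$frames[[k]]), "ENDMDL")
    })
    lines <- c(unlist(blocks), "END")
  } else {
    stop_domain("expected md_structure or md_trajectory.")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write simple XYZ files (toy systems)
#'
#' Plain XYZ: atom count, comment line, then `element x y z` rows. Atom
#' metadata beyond the element is synthesized on read (serial order, residue
#' 1, chain A).
#'
#' @param x An [md_structure()].
#' @param path File path.
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` an
#'   [md_structure()].
#' @export
write_xyz <- function(x, path) {
  stopifnot(inherits(x, "md_structure"))
  lines <- c(
    sprintf("%d", nrow(x$atoms)),
    "generated by helixbind",
    sprintf("%-3s %12.6f %12.6f %12.6f", x$atoms$element,
            x$xyz[, 1], x$xyz[, 2], x$xyz[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop_parse("XYZ: first line must be the atom count.")
  rows <- strsplit(trimws(lines[2 + seq_len(n)]), "\\s+")
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop_parse("XYZ: non-numeric coordinate field.")
  el <- vapply(rows, `[[`, character(1), 1)
  atoms <- tibble::tibble(
    serial = seq_len(n), name = el, altloc = "", resname = "UNK",
    chain = "A", resid = 1L, element = toupper(el), het = FALSE
  )
  md_structure(atoms, xyz)
}

# ---------------------------------------------------------------------------
# Selections

#' Atom selections
#'
#' A selection is a structured predicate over chain id, residue-id range and
#' atom-name set. The `atoms` argument takes either explicit PDB atom names
#' or one of the keywords `"backbone"` (N, CA, C, O), `"heavy"` (all
#' non-hydrogen; the default) or `"all"`. Selections act on topology only, so
#' the result is independent of frames.
#'
#' @param chain Chain id (single character), or `NULL` for any chain.
#' @param resid Integer vector of residue ids (e.g. `532:552`), or `NULL`.
#' @param atoms Atom-name character vector or a keyword (see above).
#' @return An object of class `atom_selection`.
#' @examples
#' h12_backbone <- atom_selection(resid = 532:552, atoms = "backbone")
#' @export
atom_selection <- function(chain = NULL, resid = NULL, atoms = "heavy") {
  kw <- c("backbone", "heavy", "all")
  if (is.character(atoms) && length(atoms) == 1L && !(atoms %in% kw) &&
      grepl("^[a-z]+$", atoms)) {
    stop_config(sprintf(
      "unknown atom-name keyword '%s' (known: %s).", atoms, paste(kw, collapse = ", ")
    ))
  }
  structure(list(chain = chain, resid = resid, atoms = atoms),
            class = "atom_selection")
}

#' Resolve a selection to atom indices
#'
#' Returns the indices (in topology order) of the atoms matched by a
#' selection. Selecting on a chain that is absent gives an empty result with
#' a warning rather than an error.
#'
#' @param x An [md_structure()] or [md_trajectory()].
#' @param sel An [atom_selection()], or `NULL` for all heavy atoms.
#' @return Integer vector of atom indices.
#' @examples
#' helix <- make_ideal_helix(21, start_resid = 532)
#' length(select_atoms(helix, atom_selection(resid = 532:552, atoms = "backbone")))
#' @export
select_atoms <- function(x, sel = NULL) {
  if (is.null(sel)) sel <- atom_selection()
  if (!inherits(sel, "atom_selection")) {
    if (is.list(sel)) sel <- do.call(atom_selection, sel) else stop_config("`sel` must be an atom_selection.")
  }
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) {
    keep <- keep & a$chain %in% sel$chain
    if (!any(a$chain %in% sel$chain)) {
      warn(sprintf("chain '%s' not present in structure; empty selection.",
                   paste(sel$chain, collapse = ",")))
    }
  }
  if (!is.null(sel$resid)) keep <- keep & a$resid %in% sel$resid
  at <- sel$atoms
  if (is.character(at) && length(at) == 1L && at %in% c("backbone", "heavy", "all")) {
    keep <- keep & switch(at,
      backbone = a$name %in% c("N", "CA", "C", "O"),
      heavy = a$element != "H",
      all = TRUE
    )
  } else {
    keep <- keep & a$name %in% at
  }
  which(keep)
}

# ---------------------------------------------------------------------------
# Run / monomer bookkeeping

#' Concatenate the two subunit trajectories of a dimer
#'
#' Homodimer simulations sample each monomer independently, so per-monomer
#' statistics can be pooled by concatenating the trajectory of chain A over
#' all runs with the (atom-matched) trajectory of chain B. The result is a
#' single monomeric trajectory whose total simulated time is twice the sum of
#' the per-run durations: e.g. eight 50-ns runs of a dimer (400 ns aggregate)
#' yield an 800-ns monomeric trajectory.
#'
#' Both chains must be mappable atom-by-atom (identical residue ids and atom
#' names in order); the first divergent residue is named in the error
#' otherwise.
#'
#' @param runs A list of [md_trajectory()] objects (or a single one).
#' @param chain_a,chain_b Chain ids of the two subunits.
#' @return An [md_trajectory()] over the chain-A topology with
#'   `runs * frames * 2` frames.
#' @export
concatenate_monomers <- function(runs, chain_a = "A", chain_b = "B") {
  if (inherits(runs, "md_trajectory")) runs <- list(runs)
  stopifnot(length(runs) >= 1L)
  pick <- function(traj, ch) which(traj$atoms$chain == ch)
  first <- runs[[1]]
  ia <- pick(first, chain_a)
  ib <- pick(first, chain_b)
  if (length(ia) == 0L) stop_domain(sprintf("chain '%s' absent from run 1.", chain_a))
  if (length(ib) == 0L) stop_domain(sprintf("chain '%s' absent from run 1.", chain_b))
  if (length(ia) != length(ib)) {
    stop_domain(sprintf("chains '%s' (%d atoms) and '%s' (%d atoms) differ in size.",
                        chain_a, length(ia), chain_b, length(ib)))
  }
  aa <- first$atoms[ia, ]
  ab <- first$atoms[ib, ]
  mismatch <- which(aa$resid != ab$resid | aa$name != ab$name)
  if (length(mismatch) > 0L) {
    m <- mismatch[1]
    stop_domain(sprintf(
      "chains not atom-mappable: first divergence at residue %d (%s/%s, atom %s vs %s).",
      aa$resid[m], aa$resname[m], ab$resname[m], aa$name[m], ab$name[m]
    ))
  }

  frames_a <- list()
  frames_b <- list()
  durations <- numeric(length(runs))
  for (r in seq_along(runs)) {
    tr <- runs[[r]]
    if (!identical(tr$atoms$name, first$atoms$name) ||
        !identical(tr$atoms$resid, first$atoms$resid)) {
      stop_domain(sprintf("run %d topology differs from run 1.", r))
    }
    frames_a <- c(frames_a, lapply(tr$frames, function(f) f[ia, , drop = FALSE]))
    frames_b <- c(frames_b, lapply(tr$frames, function(f) f[ib, , drop = FALSE]))
    durations[r] <- if (is.na(tr$frame_ns)) NA_real_ else length(tr$frames) * tr$frame_ns
  }
  frame_ns <- NA_real_
  if (anyNA(durations)) {
    warn("one or more runs lack time metadata; concatenated trajectory has no total time.")
  } else {
    total_ns <- 2 * sum(durations)  # two monomers per dimer
    frame_ns <- total_ns / (length(frames_a) + length(frames_b))
  }
  md_trajectory(first$atoms[ia, ], c(frames_a, frames_b), frame_ns = frame_ns)
}
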