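#' Construct a trajectory object
#'
#' A trajectory holds per-frame Cartesian coordinates (in angstroms) for a
#' fixed, ordered set of atoms, plus the atom metadata needed to form domain
#' selections. Every frame must have the same atom count and ordering.
#'
#' @param coords Numeric array of dimension `c(n_frames, n_atoms, 3)`, in
#'   angstroms. A single `n_atoms x 3` matrix is promoted to one frame.
#' @param atoms A data frame with one row per atom and columns
#'   `residue_number` (1-based integer), `residue_name` (3-letter code),
#'   `atom_name` (e.g. `"CA"`), and `chain_id`.
#' @param frame_times Optional numeric vector of frame times (ns). When
#'   absent, analyses depend only on frame order.
#'
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, atoms, frame_times = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort_config("`coords` must be an n_frames x n_atoms x 3 array.")
  }
  if (dim(coords)[1] < 1L || dim(coords)[2] < 1L) {
    abort_config("A trajectory needs at least one frame and one atom.")
  }
  if (!all(is.finite(coords))) {
    abort_dicckit("Trajectory coordinates must all be finite.",
                  class = "dicckit_malformed_trajectory_error")
  }
  atoms <- tibble::as_tibble(atoms)
  required <- c("residue_number", "residue_name", "atom_name", "chain_id")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L) {
    abort_config(paste0("`atoms` is missing column(s): ",
                        paste(missing, collapse = ", "), "."))
  }
  if (nrow(atoms) != dim(coords)[2]) {
    abort_dicckit(
      sprintf("Atom table has %d rows but coordinates have %d atoms.",
              nrow(atoms), dim(coords)[2]),
      class = "dicckit_malformed_trajectory_error")
  }
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[1]) {
    abort_config("`frame_times` must have one entry per frame.")
  }
  structure(
    list(coords = coords, atoms = atoms, frame_times = frame_times),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames, %d atoms, %d residues>\n",
              n_frames(x), n_atoms(x),
              length(unique(paste(x$atoms$chain_id, x$atoms$residue_number)))))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj A [trajectory()].
#' @return An integer.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame of a trajectory as an n_atoms x 3 matrix
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @return A numeric matrix with columns x, y, z.
#' @export
frame_coords <- function(traj, i) {
  check_scalar_number(i, "i", min = 1, max = n_frames(traj), integerish = TRUE)
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Define a named protein domain as residue ranges
#'
#' Domains are named, inclusive 1-based residue intervals (for instance the
#' lumenal N-terminal domain as residues 23-259). Overlapping or abutting
#' intervals are merged on construction, so `[10-19] + [15-25]` selects the
#' same atoms as `[10-25]`.
#'
#' @param name Domain label, e.g. `"NTD"`, `"MLD"`, `"CTD"`, `"TMD"`.
#' @param ranges Either a list of length-2 integer vectors `c(start, end)` or
#'   a character vector of `"start-end"` strings.
#' @param chain_id Optional chain identifier. When `NULL` (default) all
#'   chains match; the systems this package was designed around are
#'   single-chain.
#' @return An object of class `domain_definition`.
#' @export
domain_definition <- function(name, ranges, chain_id = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_config("`name` must be a non-empty string.")
  }
  if (is.character(ranges)) {
    ranges <- lapply(strsplit(ranges, "-", fixed = TRUE), function(p) {
      if (length(p) != 2L) abort_config("Range strings must look like \"23-259\".")
      as.integer(p)
    })
  }
  if (!is.list(ranges)) ranges <- list(ranges)
  if (length(ranges) == 0L) abort_config("A domain needs at least one residue range.")
  mat <- do.call(rbind, lapply(ranges, function(r) {
    if (length(r) != 2L || anyNA(r)) abort_config("Each range must be c(start, end).")
    r <- as.integer(r)
    if (r[1] > r[2]) abort_config(sprintf(
      "Empty range %d-%d in domain %s (start must be <= end).", r[1], r[2], name))
    r
  }))
  mat <- merge_intervals(mat)
  structure(list(name = name, ranges = mat, chain_id = chain_id),
            class = "domain_definition")
}

# Merge overlapping or abutting inclusive integer intervals. Rows of `mat`
# are c(start, end); returns the same shape, sorted, disjoint.
#' @noRd
merge_intervals <- function(mat) {
  mat <- mat[order(mat[, 1], mat[, 2]), , drop = FALSE]
  out <- mat[1, , drop = FALSE]
  for (i in seq_len(nrow(mat))[-1]) {
    last <- nrow(out)
    if (mat[i, 1] <= out[last, 2] + 1L) {
      out[last, 2] <- max(out[last, 2], mat[i, 2])
    } else {
      out <- rbind(out, mat[i, , drop = FALSE])
    }
  }
  colnames(out) <- c("start", "end")
  out
}

#' @export
print.domain_definition <- function(x, ...) {
  cat(sprintf("<domain %s: %s%s>\n", x$name,
              paste(sprintf("%d-%d", x$ranges[, 1], x$ranges[, 2]), collapse = ", "),
              if (is.null(x$chain_id)) "" else paste0(" chain ", x$chain_id)))
  invisible(x)
}

#' Read domain definitions from a YAML config file
#'
#' The file maps each domain name to a list of `"start-end"` strings and an
#' optional `chain` entry, e.g.
#' ```yaml
#' NTD: ["23-259"]
#' MLD: ["372-620"]
#' ```
#'
#' @param path Path to a YAML file.
#' @return A named list of [domain_definition()] objects.
#' @export
read_domain_definitions <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("No such file: %s", path))
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) abort_config("Domain definition file is empty.")
  out <- purrr::imap(raw, function(entry, nm) {
    if (is.list(entry) && !is.null(entry$ranges)) {
      domain_definition(nm, unlist(entry$ranges), chain_id = entry$chain)
    } else {
      domain_definition(nm, unlist(entry))
    }
  })
  if (anyDuplicated(names(out))) abort_config("Domain names must be unique.")
  out
}

#' Select atoms of a trajectory by domain and atom name
#'
#' Returns the (sorted, unique) indices into the trajectory's atom table of
#' atoms whose residue number falls in any of the domain's intervals and
#' whose atom name is in `atom_names`. Selecting nothing is treated as an
#' error: an empty selection is always a mistake in this pipeline.
#'
#' @param traj A [trajectory()].
#' @param domain A [domain_definition()].
#' @param atom_names Character vector of atom names. Use `"CA"` (the default)
#'   for alignment and DiCC; use `c("N", "CA", "C", "O")` for backbone RMSD.
#' @return An integer vector of class `atom_selection` with a `label`
#'   attribute.
#' @export
select_atoms <- function(traj, domain, atom_names = "CA") {
  if (length(atom_names) == 0L) abort_config("`atom_names` must be non-empty.")
  at <- traj$atoms
  in_range <- rep(FALSE, nrow(at))
  for (i in seq_len(nrow(domain$ranges))) {
    in_range <- in_range |
      (at$residue_number >= domain$ranges[i, 1] &
       at$residue_number <= domain$ranges[i, 2])
  }
  keep <- in_range & at$atom_name %in% atom_names
  if (!is.null(domain$chain_id)) keep <- keep & at$chain_id == domain$chain_id
  idx <- which(keep)
  if (length(idx) == 0L) {
    abort_dicckit(
      sprintf("Domain %s with atom names {%s} selects no atoms.",
              domain$name, paste(atom_names, collapse = ", ")),
      class = "dicckit_empty_selection_error")
  }
  structure(as.integer(idx), class = "atom_selection", label = domain$name)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is read as a single frame. Atom metadata is taken from the first
#' model. Parsing of the fixed-column format is delegated to
#' [bio3d::read.pdb()]; this wrapper adds the consistency checks the
#' trajectory contract requires (equal atom count and ordering in every
#' model).
#'
#' @param path Path to a PDB file.
#' @return A [trajectory()].
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("No such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 0L) {
    model_id <- findInterval(which(is_atom), model_starts)
    counts <- tabulate(model_id, nbins = length(model_starts))
    if (length(unique(counts[counts > 0])) > 1L || any(model_id == 0L)) {
      abort_dicckit(
        sprintf("Models differ in atom count (%s): not a valid trajectory.",
                paste(counts, collapse = ", ")),
        class = "dicckit_malformed_trajectory_error")
    }
  }
  bad <- which(is_atom & is.na(suppressWarnings(
    as.numeric(substr(lines, 31, 38)))))
  if (length(bad) > 0L) {
    abort_dicckit(
      sprintf("Unparsable coordinate field at line %d of %s.", bad[1], path),
      class = "dicckit_parse_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort_dicckit(
      sprintf("Failed to parse %s: %s", path, conditionMessage(e)),
      class = "dicckit_parse_error"))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  na_at <- nrow(pdb$atom)
  if (ncol(xyz) != 3L * na_at) {
    abort_dicckit("Atom ordering differs between models.",
                  class = "dicckit_malformed_trajectory_error")
  }
  coords <- array(NA_real_, dim = c(nf, na_at, 3L))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  atoms <- tibble::tibble(
    residue_number = as.integer(pdb$atom$resno),
    residue_name = pdb$atom$resid,
    atom_name = pdb$atom$elety,
    chain_id = ifelse(is.na(pdb$atom$chain), "", pdb$atom$chain))
  trajectory(coords, atoms)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Writes standard `MODEL`/`ENDMDL` blocks with fixed-column coordinates at
#' the format's 3-decimal angstrom precision, via [bio3d::write.pdb()]. The
#' output round-trips through [read_multimodel_pdb()] exactly on atom
#' metadata and to within 1e-3 angstrom on coordinates.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  if (any(traj$atoms$residue_number > 9999L)) {
    abort_dicckit("Residue numbers above 9999 overflow the PDB format.",
                  class = "dicckit_overflow_error")
  }
  if (!dir.exists(dirname(path))) {
    abort_dicckit(sprintf("Cannot write to %s: no such directory.", path),
                  class = "dicckit_io_error")
  }
  nf <- n_frames(traj)
  na_at <- n_atoms(traj)
  xyz <- matrix(0, nrow = nf, ncol = 3L * na_at)
  for (f in seq_len(nf)) {
    xyz[f, ] <- as.vector(t(frame_coords(traj, f)))
  }
  chain <- traj$atoms$chain_id
  chain[!nzchar(chain)] <- " "
  tryCatch(
    bio3d::write.pdb(
      pdb = NULL, file = path, xyz = xyz,
      resno = traj$atoms$residue_number,
      resid = traj$atoms$residue_name,
      elety = traj$atoms$atom_name,
      chain = chain),
    error = function(e) abort_dicckit(
      sprintf("Failed to write %s: %s", path, conditionMessage(e)),
      class = "dicckit_io_error"))
  # bio3d omits MODEL records for a single frame; the interchange contract
  # is one MODEL/ENDMDL block per frame, always
  if (nf == 1L) {
    lines <- readLines(path, warn = FALSE)
    if (!any(startsWith(lines, "MODEL"))) {
      is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
      first <- which(is_atom)[1]
      last <- max(which(is_atom))
      lines <- append(lines, "ENDMDL", after = last)
      lines <- append(lines, sprintf("MODEL %8d", 1L), after = first - 1L)
      writeLines(lines, path)
    }
  }
  invisible(path)
}
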