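# Small builders shared across the suite. Everything is generated in code;
# no stored fixtures.

# n_res residues on a line, one CA each, plus optional extra backbone atoms
toy_trajectory <- function(n_frames = 2, n_res = 3, atom_names = "CA",
                           jitter_fun = NULL) {
  n_at <- n_res * length(atom_names)
  atoms <- tibble::tibble(
    residue_number = rep(seq_len(n_res), each = length(atom_names)),
    residue_name = "ALA",
    atom_name = rep(atom_names, n_res),
    chain_id = "A")
  base <- cbind(seq_len(n_at) * 3.8, 0, 0)
  coords <- array(0, dim = c(n_frames, n_at, 3))
  for (f in seq_len(n_frames)) {
    fr <- base
    if (!is.null(jitter_fun)) fr <- jitter_fun(fr, f)
    coords[f, , ] <- fr
  }
  trajectory(coords, atoms)
}

# proper rotation about z by theta
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), nrow = 3)
}

# random non-collinear point cloud
random_cloud <- function(n, seed) {
  withr::with_seed(seed, matrix(stats::rnorm(3 * n, sd = 2), ncol = 3))
}

# O(n^2) double-loop distance covariance, kept deliberately naive: the
# independent oracle for the vectorized implementation
dcov_loop <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  da <- matrix(0, n, n); db <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    da[i, j] <- sqrt(sum((a[i, ] - a[j, ])^2))
    db[i, j] <- sqrt(sum((b[i, ] - b[j, ])^2))
  }
  rma <- rowMeans(da); cma <- colMeans(da); ga <- mean(da)
  rmb <- rowMeans(db); cmb <- colMeans(db); gb <- mean(db)
  ca <- matrix(0, n, n); cb <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    ca[i, j] <- da[i, j] - rma[i] - cma[j] + ga
    cb[i, j] <- db[i, j] - rmb[i] - cmb[j] + gb
  }
  s <- 0
  for (i in 1:n) for (j in 1:n) s <- s + ca[i, j] * cb[i, j]
  s / n^2
}

dicc_loop <- function(a, b) {
  dcov_loop(a, b) / sqrt(dcov_loop(a, a) * dcov_loop(b, b))
}

# a multi-model PDB file written line by line, independent of the package
# writer, for reader tests
write_raw_pdb <- function(path, models) {
  lines <- character(0)
  for (m in seq_along(models)) {
    lines <- c(lines, sprintf("MODEL %8d", m))
    coords <- models[[m]]
    for (i in seq_len(nrow(coords))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, coords[i, 1], coords[i, 2], coords[i, 3]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# tiny trajectory config file for CLI tests
local_mini_cfg <- function(dir) {
  path <- file.path(dir, "mini.yaml")
  writeLines(c("n_domains: 2", "atoms_per_domain: 3", "n_frames: 6"), path)
  path
}
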