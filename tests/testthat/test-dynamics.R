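test_that("superposing a frame onto itself is the identity", {
  x <- random_cloud(6, 1)
  fit <- kabsch_superpose(x, x)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$translation, rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
})

test_that("a known rigid motion is recovered exactly", {
  x <- random_cloud(6, 2)
  moved <- sweep(x %*% rot_z(pi / 2), 2, c(1, 2, 3), `+`)
  fit <- kabsch_superpose(moved, x)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  expect_equal(apply_rigid_transform(moved, fit), x,
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches a dense rotation-grid search oracle", {
  # Oracle: minimize RMSD over an Euler-angle grid with optimal translation
  # (centroid matching) at each rotation. The analytic fit can never do
  # worse, and the grid comes within its discretization error.
  x <- random_cloud(5, 3)
  y <- sweep(x %*% rot_z(0.7), 2, c(0.5, -1, 2), `+`) +
    random_cloud(5, 4) * 0.05
  fit <- kabsch_superpose(y, x)
  grid_rmsd <- function(mob, ref) {
    angles <- seq(0, 2 * pi, by = pi / 18)
    half <- seq(0, pi, by = pi / 18)
    mc <- sweep(mob, 2, colMeans(mob))
    rc <- sweep(ref, 2, colMeans(ref))
    best <- Inf
    for (a in angles) for (b in half) for (c in angles) {
      rz1 <- rot_z(a)
      ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
      r <- rz1 %*% ry %*% rot_z(c)
      v <- sqrt(mean(rowSums((mc %*% r - rc)^2)))
      if (v < best) best <- v
    }
    best
  }
  oracle <- grid_rmsd(y, x)
  expect_lte(fit$rmsd, oracle + 1e-9)
  expect_lt(oracle - fit$rmsd, 0.05)
})

test_that("degenerate point sets cannot be superposed", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line),
               class = "dicckit_degenerate_superposition_error")
  expect_error(kabsch_superpose(random_cloud(2, 1), random_cloud(2, 2)),
               class = "dicckit_degenerate_superposition_error")
})

test_that("post-fit RMSD never exceeds the pre-fit RMSD", {
  for (s in 1:5) {
    x <- random_cloud(8, s)
    y <- random_cloud(8, s + 100)
    pre <- sqrt(mean(rowSums((y - x)^2)))
    expect_lte(kabsch_superpose(y, x)$rmsd, pre + 1e-12)
  }
})

test_that("alignment collapses rigid motions of one structure to the reference", {
  base <- random_cloud(10, 7) + 10
  motions <- withr::with_seed(8, dicckit:::random_rigid_motions(4))
  coords <- array(0, dim = c(4, 10, 3))
  for (t in 1:4) {
    coords[t, , ] <- sweep(base %*% motions[[t]]$rotation, 2,
                           motions[[t]]$translation, `+`)
  }
  atoms <- tibble::tibble(residue_number = 1:10, residue_name = "ALA",
                          atom_name = "CA", chain_id = "A")
  traj <- align_trajectory(trajectory(coords, atoms))
  for (t in 1:4) {
    expect_lt(max(abs(frame_coords(traj, t) - frame_coords(traj, 1))), 1e-9)
  }
  # idempotence
  again <- align_trajectory(traj)
  expect_lt(max(abs(again$coords - traj$coords)), 1e-9)
})

test_that("alignment preserves intra-frame distances (rigidity)", {
  cfg <- trajectory_config(n_domains = 2, atoms_per_domain = 6, n_frames = 5,
                           global_rigid_motion = TRUE, seed = 31)
  traj <- simulate_trajectory(cfg)$trajectory
  aligned <- align_trajectory(traj)
  for (t in c(1, 3, 5)) {
    d0 <- dist(frame_coords(traj, t))
    d1 <- dist(frame_coords(aligned, t))
    expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  }
})

test_that("RMSD series has the closed-form and brute-force values", {
  traj <- toy_trajectory(n_frames = 2, n_res = 2)
  traj$coords[2, 1, 1] <- traj$coords[1, 1, 1] + 1  # one atom moves 1 A
  sel <- select_atoms(traj, domain_definition("d", list(c(1, 2))))
  rs <- rmsd_series(traj, sel)
  expect_equal(rs$rmsd[1], 0)
  expect_equal(rs$rmsd[2], 1 / sqrt(2), tolerance = 1e-12)

  # random displacements vs a direct per-atom loop
  cfg <- trajectory_config(n_domains = 1, atoms_per_domain = 8, n_frames = 6,
                           seed = 17)
  traj2 <- simulate_trajectory(cfg)$trajectory
  sel2 <- select_atoms(traj2, domain_definition("d", list(c(1, 8))))
  rs2 <- rmsd_series(traj2, sel2)
  for (f in 1:6) {
    acc <- 0
    for (i in seq_along(sel2)) {
      acc <- acc + sum((traj2$coords[f, sel2[i], ] -
                          traj2$coords[1, sel2[i], ])^2)
    }
    expect_equal(rs2$rmsd[f], sqrt(acc / length(sel2)), tolerance = 1e-12)
  }
})

test_that("domain vector series reduce coordinates as documented", {
  traj <- toy_trajectory(n_frames = 3, n_res = 5)
  one <- domain_definition("r3", list(c(3, 3)))
  vs_cat <- domain_vector_series(traj, one, "concatenated")
  vs_cen <- domain_vector_series(traj, one, "centroid")
  expect_equal(dim(vs_cat), c(3, 3))
  expect_equal(unclass(vs_cen), unclass(vs_cat), ignore_attr = TRUE)
  expect_equal(vs_cen[1, ], traj$coords[1, 3, ], ignore_attr = TRUE)

  two <- domain_definition("pair", list(c(1, 2)))
  cen <- domain_vector_series(traj, two, "centroid")
  expect_equal(cen[2, ],
               colMeans(frame_coords(traj, 2)[1:2, ]), ignore_attr = TRUE)
  cat2 <- domain_vector_series(traj, two, "concatenated")
  expect_equal(ncol(cat2), 3 * 2)
})

test_that("distance covariance matches hand values and the loop oracle", {
  # constant series: all pairwise distances are zero
  const <- matrix(1, nrow = 4, ncol = 3)
  wiggle <- random_cloud(4, 5)
  expect_equal(distance_covariance(const, wiggle), 0)
  # scalar series {0, 2}: double-centered matrix is [[-1,1],[1,-1]]
  s <- matrix(c(0, 2))
  expect_equal(distance_covariance(s, s), 1.0)
  # seeded random series vs the O(n^2) loop
  a <- random_cloud(50, 11)
  b <- random_cloud(50, 12)
  expect_equal(distance_covariance(a, b), dcov_loop(a, b),
               tolerance = 1e-10)
  expect_error(distance_covariance(random_cloud(3, 1), random_cloud(4, 1)),
               class = "dicckit_shape_error")
})

test_that("double-centered distance matrices have zero row and column sums", {
  a <- random_cloud(20, 21)
  dc <- dicckit:::double_centered_distances(a)
  expect_lt(max(abs(rowSums(dc))), 1e-8 * max(abs(dc)))
  expect_lt(max(abs(colSums(dc))), 1e-8 * max(abs(dc)))
  expect_equal(dc, t(dc), tolerance = 1e-12)
})

test_that("DiCC of a series with itself is exactly 1 and degenerate series fail", {
  a <- random_cloud(30, 13)
  expect_equal(dicc(a, a), 1.0)
  expect_error(dicc(matrix(1, 5, 3), a),
               class = "dicckit_degenerate_series_error")
})

test_that("DiCC is invariant to translation, rotation and uniform scaling", {
  a <- random_cloud(40, 14)
  b <- random_cloud(40, 15)
  ref <- dicc(a, b)
  moved <- sweep(2.5 * (b %*% rot_z(1.1)), 2, c(5, -3, 7), `+`)
  expect_equal(dicc(a, moved), ref, tolerance = 1e-10)
  expect_equal(dicc(a, 2 * a + 3), 1.0, tolerance = 1e-12)
  # symmetry
  expect_equal(dicc(a, b), dicc(b, a), tolerance = 1e-12)
})

test_that("independent long series give a small DiCC that matches the loop oracle", {
  a <- random_cloud(500, 16)
  b <- random_cloud(500, 17)
  v <- dicc(a, b)
  expect_lt(v, 0.2)
  expect_equal(v, dicc_loop(a, b), tolerance = 1e-10)
})

test_that("fully coupled domains give an all-ones DiCC matrix", {
  cfg <- trajectory_config(n_domains = 4, atoms_per_domain = 10,
                           n_frames = 60, latent_loadings = 1,
                           independent_noise_sd = 0, seed = 19)
  sim <- simulate_trajectory(cfg)
  m <- dicc_matrix(sim$trajectory, sim$domains, align_first = FALSE)
  expect_lt(max(abs(unclass(m) - 1)), 1e-9)
  expect_identical(unname(diag(unclass(m))), rep(1, 4))
})

test_that("the locked pair is the arg-max off-diagonal entry", {
  cfg <- locked_pair_config(
    trajectory_config(n_domains = 4, atoms_per_domain = 10, n_frames = 300,
                      latent_loadings = 0.5, seed = 23),
    pair = c(2, 3))
  sim <- simulate_trajectory(cfg)
  m <- dicc_matrix(sim$trajectory, sim$domains, align_first = FALSE)
  expect_identical(attr(m, "max_pair")$pair, c("CTD", "MLD"))
  expect_gt(m["MLD", "CTD"], 0.99)
})

test_that("replica averaging is element-wise with label checking", {
  cfg <- trajectory_config(n_domains = 2, atoms_per_domain = 5, n_frames = 40,
                           seed = 29)
  sim <- simulate_trajectory(cfg)
  m1 <- dicc_matrix(sim$trajectory, sim$domains, align_first = FALSE)
  same <- replica_average(list(m1, m1))
  expect_equal(as.numeric(same), as.numeric(m1))
  expect_identical(dimnames(same), dimnames(m1))

  m2 <- m1
  m2[1, 2] <- m2[2, 1] <- 1.0
  m1[1, 2] <- m1[2, 1] <- 0.8
  avg <- replica_average(list(m1, m2))
  expect_equal(avg[1, 2], 0.9)
  expect_equal(unname(diag(unclass(avg))), rep(1, 2))

  flipped <- m1[2:1, 2:1]
  flipped <- dicckit:::new_dicc_matrix(flipped, "concatenated", 40, 1)
  expect_error(replica_average(list(m1, flipped)),
               class = "dicckit_label_error")
})

test_that("tidy, glance and output writers expose the matrix faithfully", {
  cfg <- trajectory_config(n_domains = 3, atoms_per_domain = 5, n_frames = 50,
                           seed = 37)
  sim <- simulate_trajectory(cfg)
  m <- dicc_matrix(sim$trajectory, sim$domains, align_first = FALSE)
  td <- tidy(m)
  expect_equal(nrow(td), 6)  # 3 diagonal + 3 pairs
  expect_true(all(td$dicc[td$domain1 == td$domain2] == 1))
  gl <- glance(m)
  expect_equal(gl$n_domains, 3)
  expect_match(gl$max_pair, "-")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dicc_tsv(m, tsv)
  tab <- readr::read_tsv(tsv, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  expect_equal(names(tab), c("domain", rownames(m)))
  expect_true(all(tab[[2]][1] == "1.000"))

  js <- withr::local_tempfile(fileext = ".json")
  write_dicc_json(m, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$entries, unclass(m), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("rmsd series of an aligned rigid-motion trajectory is zero and writes as TSV", {
  base <- random_cloud(8, 41) + 15
  motions <- withr::with_seed(42, dicckit:::random_rigid_motions(3))
  coords <- array(0, dim = c(3, 8, 3))
  for (t in 1:3) {
    coords[t, , ] <- sweep(base %*% motions[[t]]$rotation, 2,
                           motions[[t]]$translation, `+`)
  }
  atoms <- tibble::tibble(residue_number = 1:8, residue_name = "GLY",
                          atom_name = "CA", chain_id = "A")
  traj <- trajectory(coords, atoms)
  sel <- select_atoms(traj, domain_definition("all", list(c(1, 8))))
  rs <- rmsd_series(traj, sel, align_first = TRUE)
  expect_lt(max(rs$rmsd), 1e-9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rmsd_tsv(rs, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("frame", "rmsd_A"))
  expect_equal(nrow(back), 3)
})
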