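#' Kabsch superposition of two frames
#'
#' Finds the proper rigid transform (rotation with determinant +1, plus
#' translation) that minimizes the RMSD of the selected atoms of `mobile`
#' onto the corresponding atoms of `reference`, via the singular value
#' decomposition of the 3x3 cross-covariance matrix.
#'
#' The returned transform maps row-vector coordinates as `x %*% rotation +
#' translation` (see [apply_rigid_transform()]).
#'
#' @param mobile,reference Numeric `n_atoms x 3` coordinate matrices with
#'   identical atom ordering.
#' @param selection Optional [select_atoms()] result (or integer indices)
#'   naming the atoms used for the fit. Default: all atoms.
#' @return A list of class `kabsch_fit` with elements `rotation` (3x3),
#'   `translation` (length 3) and `rmsd` (post-fit RMSD of the selected
#'   atoms, in angstroms).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference))) {
    abort_dicckit("`mobile` and `reference` must have identical dimensions.",
                  class = "dicckit_shape_error")
  }
  idx <- if (is.null(selection)) seq_len(nrow(mobile)) else as.integer(selection)
  m <- mobile[idx, , drop = FALSE]
  r <- reference[idx, , drop = FALSE]
  if (nrow(m) < 3L) {
    abort_dicckit("Superposition needs at least 3 selected atoms.",
                  class = "dicckit_degenerate_superposition_error")
  }
  cm <- colMeans(m)
  cr <- colMeans(r)
  mc <- sweep(m, 2, cm)
  rc <- sweep(r, 2, cr)
  # collinear point sets leave the rotation about the line undetermined
  sv_m <- svd(mc, nu = 0, nv = 0)$d
  if (sv_m[2] <= 1e-8 * max(sv_m[1], 1e-12)) {
    abort_dicckit("Selected atoms are collinear: superposition is degenerate.",
                  class = "dicckit_degenerate_superposition_error")
  }
  h <- crossprod(mc, rc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- cr - as.vector(cm %*% rot)
  fitted <- sweep(m %*% rot, 2, trans, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - r)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "kabsch_fit")
}

#' Apply a rigid transform to coordinates
#' @param coords An `n x 3` coordinate matrix.
#' @param fit A `kabsch_fit` from [kabsch_superpose()].
#' @return The transformed `n x 3` matrix.
#' @export
apply_rigid_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% fit$rotation, 2, fit$translation, `+`)
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' Each frame receives its own best-fit (Kabsch) rigid transform onto the
#' selected atoms of the reference frame; the transform is then applied to
#' all atoms of that frame. Atom metadata is unchanged. Alignment is
#' idempotent and preserves all intra-frame distances.
#'
#' @param traj A [trajectory()].
#' @param selection Atoms used for the fit (default: all C-alpha atoms; an
#'   error if the trajectory has none).
#' @param reference_frame 1-based frame index of the reference (default the
#'   first frame).
#' @return The aligned [trajectory()].
#' @export
align_trajectory <- function(traj, selection = NULL, reference_frame = 1L) {
  check_scalar_number(reference_frame, "reference_frame",
                      min = 1, max = n_frames(traj), integerish = TRUE)
  if (is.null(selection)) selection <- ca_selection(traj)
  ref <- frame_coords(traj, reference_frame)
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    fit <- withCallingHandlers(
      kabsch_superpose(frame_coords(traj, f), ref, selection),
      error = function(e) {
        if (inherits(e, "dicckit_degenerate_superposition_error")) {
          abort_dicckit(sprintf("Frame %d: %s", f, conditionMessage(e)),
                        class = "dicckit_degenerate_superposition_error")
        }
      })
    out[f, , ] <- apply_rigid_transform(frame_coords(traj, f), fit)
  }
  traj$coords <- out
  traj
}

# all-CA selection without a domain definition
#' @noRd
ca_selection <- function(traj) {
  idx <- which(traj$atoms$atom_name == "CA")
  if (length(idx) == 0L) {
    abort_dicckit("Trajectory has no C-alpha atoms to align on.",
                  class = "dicckit_empty_selection_error")
  }
  structure(idx, class = "atom_selection", label = "all-CA")
}

#' Per-frame RMSD of selected atoms against a reference frame
#'
#' Root-mean-square deviation (angstroms) of the selected atoms of each
#' frame from the same atoms of the reference frame, without per-frame
#' re-fitting. Align the trajectory first (or set `align_first = TRUE`) to
#' obtain the conventional backbone-RMSD-versus-time trace.
#'
#' @param traj A [trajectory()].
#' @param selection A [select_atoms()] result; typically the backbone
#'   atoms `c("N", "CA", "C", "O")` of the whole protein.
#' @param reference_frame 1-based reference frame index.
#' @param align_first If `TRUE`, superpose every frame onto the reference
#'   on `selection` before measuring.
#' @return A tibble of class `rmsd_series` with columns `frame` and `rmsd`,
#'   and a `selection_label` attribute.
#' @export
rmsd_series <- function(traj, selection, reference_frame = 1L,
                        align_first = FALSE) {
  if (length(selection) == 0L) {
    abort_dicckit("Empty selection for RMSD.",
                  class = "dicckit_empty_selection_error")
  }
  if (align_first) {
    traj <- align_trajectory(traj, selection, reference_frame)
  }
  ref <- frame_coords(traj, reference_frame)[selection, , drop = FALSE]
  rmsd <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)[selection, , drop = FALSE]
    sqrt(mean(rowSums((x - ref)^2)))
  }, numeric(1))
  out <- tibble::tibble(frame = seq_len(n_frames(traj)), rmsd = rmsd)
  class(out) <- c("rmsd_series", class(out))
  attr(out, "selection_label") <- attr(selection, "label") %||% "selection"
  attr(out, "reference_frame") <- reference_frame
  out
}

#' Per-frame position series of one domain
#'
#' Reduces a trajectory to the vector series fed into the distance
#' covariance: either the unweighted centroid of the domain's C-alpha atoms
#' (`n x 3`) or all of its C-alpha coordinates concatenated in atom order
#' (`n x 3m`).
#'
#' @param traj An aligned [trajectory()].
#' @param domain A [domain_definition()].
#' @param mode `"concatenated"` (default) or `"centroid"`.
#' @return A numeric matrix of class `vector_series` with a `label`
#'   attribute; rows are frames.
#' @export
domain_vector_series <- function(traj, domain,
                                 mode = c("concatenated", "centroid")) {
  mode <- match.arg(mode)
  sel <- select_atoms(traj, domain, atom_names = "CA")
  nf <- n_frames(traj)
  if (mode == "centroid") {
    values <- t(vapply(seq_len(nf), function(f) {
      colMeans(frame_coords(traj, f)[sel, , drop = FALSE])
    }, numeric(3)))
  } else {
    values <- t(vapply(seq_len(nf), function(f) {
      as.vector(t(frame_coords(traj, f)[sel, , drop = FALSE]))
    }, numeric(3L * length(sel))))
  }
  structure(values, class = c("vector_series", "matrix", "array"),
            label = domain$name)
}

# Double-centered inter-frame Euclidean distance matrix of a vector series.
# Row sums and column sums of the result are zero (to round-off).
#' @noRd
double_centered_distances <- function(values) {
  d <- as.matrix(stats::dist(values))
  sweep(sweep(d, 1, rowMeans(d)), 2, colMeans(d)) + mean(d)
}

#' Distance covariance between two vector series
#'
#' The biased V-statistic: with `d_ij` the Euclidean distance between frames
#' i and j of a series and `a_ij` its double-centered form (row mean, column
#' mean subtracted, grand mean added back), the distance covariance is
#' `v(A, B) = (1/n^2) * sum_ij a_ij b_ij`. It is non-negative by
#' construction and zero when either series is constant. The `1/n^2`
#' normalization is kept exactly as defined; no unbiasedness correction is
#' applied.
#'
#' @param a,b Numeric matrices (rows = frames) or [domain_vector_series()]
#'   objects with the same number of rows (at least 2). Dimensions may
#'   differ between the two series.
#' @return A non-negative scalar.
#' @export
distance_covariance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) {
    abort_dicckit("Series must have the same number of frames.",
                  class = "dicckit_shape_error")
  }
  if (nrow(a) < 2L) {
    abort_dicckit("Distance covariance needs at least 2 frames.",
                  class = "dicckit_shape_error")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    abort_config("Vector series must be finite.")
  }
  ac <- double_centered_distances(a)
  bc <- double_centered_distances(b)
  sum(ac * bc) / nrow(a)^2
}

#' Distance correlation coefficient (DiCC) between two vector series
#'
#' `DiCC = v(A, B) / sqrt(v(A, A) * v(B, B))` with `v` the distance
#' covariance of [distance_covariance()]. The coefficient approaches 1 for
#' highly correlated (concerted) domain motion and 0 for independent
#' motion, and is invariant to translation, proper rotation, and uniform
#' positive scaling of either series. The ratio is formed directly from the
#' V-statistics; under the common convention this quantity corresponds to
#' the squared distance correlation, and no additional square root is taken.
#'
#' @inheritParams distance_covariance
#' @return A scalar in `[0, 1]`. Tiny negative round-off (above `-1e-12`)
#'   is clamped to 0.
#' @export
dicc <- function(a, b) {
  vaa <- distance_covariance(a, a)
  vbb <- distance_covariance(b, b)
  if (vaa <= 0 || vbb <= 0) {
    abort_dicckit(
      "Constant (degenerate) series: distance variance is zero.",
      class = "dicckit_degenerate_series_error")
  }
  val <- distance_covariance(a, b) / sqrt(vaa * vbb)
  if (val < 0) {
    if (val < -1e-12) {
      abort_dicckit(sprintf("Distance covariance came out negative (%g).", val),
                    class = "dicckit_numeric_error")
    }
    val <- 0
  }
  if (val > 1 && val < 1 + 1e-9) val <- 1
  val
}

#' DiCC matrix over a set of domains
#'
#' Computes the symmetric matrix of distance correlation coefficients
#' between the motions of every pair of domains. The trajectory is first
#' superposed on all protein C-alpha atoms (frame 1 reference) unless
#' `align_first = FALSE`; each domain is then reduced to a vector series
#' (see [domain_vector_series()]). Diagonal entries are set to 1 by
#' construction without being computed. The strongest inter-domain
#' correlation (arg-max off-diagonal pair) is recorded and reported by
#' [glance.dicc_matrix()]; ties break by lexicographic label order.
#'
#' @param traj A [trajectory()].
#' @param domains A list of [domain_definition()]s (at least 2, unique
#'   names).
#' @param mode Passed to [domain_vector_series()].
#' @param align_first Superpose on all C-alpha atoms first (default `TRUE`).
#' @param reference_frame Alignment reference frame (1-based).
#' @return A named numeric matrix of class `dicc_matrix` with attributes
#'   `mode`, `n_frames` and `max_pair`.
#' @export
dicc_matrix <- function(traj, domains, mode = c("concatenated", "centroid"),
                        align_first = TRUE, reference_frame = 1L) {
  mode <- match.arg(mode)
  if (length(domains) < 2L) abort_config("Need at least 2 domains.")
  labels <- vapply(domains, function(d) d$name, character(1))
  if (anyDuplicated(labels)) abort_config("Domain names must be unique.")
  if (align_first) traj <- align_trajectory(traj, reference_frame = reference_frame)
  series <- lapply(domains, function(d) domain_vector_series(traj, d, mode))
  k <- length(domains)
  m <- diag(1, k)
  dimnames(m) <- list(labels, labels)
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      val <- withCallingHandlers(
        dicc(series[[i]], series[[j]]),
        error = function(e) {
          if (inherits(e, "dicckit_degenerate_series_error")) {
            bad <- if (distance_covariance(series[[i]], series[[i]]) <= 0)
              labels[i] else labels[j]
            abort_dicckit(sprintf("Domain %s has a degenerate (constant) series.", bad),
                          class = "dicckit_degenerate_series_error")
          }
        })
      m[i, j] <- m[j, i] <- val
    }
  }
  new_dicc_matrix(m, mode = mode, n_frames = n_frames(traj), n_replicas = 1L)
}

#' @noRd
new_dicc_matrix <- function(m, mode, n_frames, n_replicas) {
  structure(m, class = c("dicc_matrix", "matrix", "array"),
            mode_used = mode, n_frames = n_frames, n_replicas = n_replicas,
            max_pair = argmax_offdiag(m))
}

# arg-max off-diagonal entry; ties broken by lexicographic label order
#' @noRd
argmax_offdiag <- function(m) {
  labels <- rownames(m)
  pairs <- utils::combn(seq_along(labels), 2)
  vals <- apply(pairs, 2, function(p) m[p[1], p[2]])
  keys <- apply(pairs, 2, function(p) paste(sort(labels[p]), collapse = "|"))
  ord <- order(-vals, keys)
  best <- pairs[, ord[1]]
  list(pair = sort(labels[best]), value = vals[ord[1]])
}

#' Element-wise average of replica DiCC matrices
#'
#' Averages the matrices obtained from independent trajectory replicas of
#' the same system (same domains, same label order). The diagonal remains
#' exactly 1.
#'
#' @param matrices A list of `dicc_matrix` objects with identical labels.
#' @return A `dicc_matrix`.
#' @export
replica_average <- function(matrices) {
  if (length(matrices) < 1L) abort_config("Need at least one matrix.")
  labels <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(rownames(m), labels) || !identical(colnames(m), labels)) {
      abort_dicckit("Replica matrices have mismatched domain labels.",
                    class = "dicckit_label_error")
    }
  }
  avg <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  diag(avg) <- 1
  new_dicc_matrix(avg, mode = attr(matrices[[1]], "mode_used"),
                  n_frames = attr(matrices[[1]], "n_frames"),
                  n_replicas = sum(vapply(matrices, function(m)
                    attr(m, "n_replicas") %||% 1L, numeric(1))))
}

#' @export
print.dicc_matrix <- function(x, ...) {
  cat(sprintf("<dicc_matrix: %d domains, mode=%s, %s frames>\n",
              nrow(x), attr(x, "mode_used"), attr(x, "n_frames")))
  m <- round(unclass(x), 3)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(m)
  mp <- attr(x, "max_pair")
  cat(sprintf("strongest inter-domain correlation: %s-%s = %.3f\n",
              mp$pair[1], mp$pair[2], mp$value))
  invisible(x)
}
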