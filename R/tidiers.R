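#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a DiCC matrix into long format
#'
#' @param x A `dicc_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `domain1`, `domain2`, `dicc`, one row per
#'   unordered pair (diagonal included).
#' @export
tidy.dicc_matrix <- function(x, ...) {
  labels <- rownames(x)
  idx <- which(upper.tri(x, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    domain1 = labels[idx[, 1]],
    domain2 = labels[idx[, 2]],
    dicc = unclass(x)[idx])
}

#' One-row summary of a DiCC matrix
#'
#' @param x A `dicc_matrix`.
#' @param ... Unused.
#' @return A tibble with `n_domains`, `mode`, `n_frames`, `n_replicas`,
#'   and the strongest inter-domain pair (`max_pair`, `max_dicc`).
#' @export
glance.dicc_matrix <- function(x, ...) {
  mp <- attr(x, "max_pair")
  tibble::tibble(
    n_domains = nrow(x),
    mode = attr(x, "mode_used"),
    n_frames = attr(x, "n_frames"),
    n_replicas = attr(x, "n_replicas"),
    max_pair = paste(mp$pair, collapse = "-"),
    max_dicc = mp$value)
}

#' Heat-map of a DiCC matrix
#'
#' @param object A `dicc_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dicc_matrix <- function(object, ...) {
  labels <- rownames(object)
  df <- tidy(object)
  df2 <- df[df$domain1 != df$domain2,
            c("domain2", "domain1", "dicc")]
  names(df2) <- c("domain1", "domain2", "dicc")
  df <- rbind(df, df2)
  df$domain1 <- factor(df$domain1, levels = labels)
  df$domain2 <- factor(df$domain2, levels = rev(labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$domain1, .data$domain2,
                                   fill = .data$dicc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$dicc)),
                       color = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "DiCC") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Inter-domain distance correlation") +
    ggplot2::coord_fixed()
}

#' RMSD trace plot
#'
#' @param object An `rmsd_series`.
#' @param ... Unused.
#' @return A ggplot of RMSD (angstroms) against frame.
#' @export
autoplot.rmsd_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frame, .data$rmsd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frame",
                  y = expression(RMSD ~ (ring(A))),
                  title = attr(object, "selection_label"))
}

#' Tidy a protection fit
#'
#' @param x A `protection_fit`.
#' @param ... Unused.
#' @return A tibble with one row per grid position: `mz` (if a grid is
#'   attached), `observed` and `fitted` intensities.
#' @export
tidy.protection_fit <- function(x, ...) {
  out <- tibble::tibble(observed = x$observed, fitted = x$fitted)
  if (!is.null(x$grid)) out <- tibble::add_column(out, mz = x$grid, .before = 1)
  out
}

#' One-row summary of a protection fit
#'
#' @param x A `protection_fit`.
#' @param ... Unused.
#' @return A tibble with `fraction_protected`, the component weights and
#'   the residual fraction.
#' @export
glance.protection_fit <- function(x, ...) {
  tibble::tibble(
    fraction_protected = x$fraction_protected,
    weight_light = x$component_weights[["light"]],
    weight_heavy = x$component_weights[["heavy"]],
    residual_norm = x$residual_norm)
}

#' Observed-versus-fitted envelope plot for a protection fit
#'
#' @param object A `protection_fit` carrying a grid (from
#'   [quantify_site()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.protection_fit <- function(object, ...) {
  df <- tidy(object)
  if (!"mz" %in% names(df)) {
    abort_config("This fit has no m/z grid; use quantify_site().")
  }
  long <- tidyr::pivot_longer(df, c("observed", "fitted"),
                              names_to = "which", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(.data$mz, .data$intensity,
                                     color = .data$which)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "m/z", y = "Intensity", color = NULL,
                  subtitle = sprintf("fraction protected = %.3f",
                                     object$fraction_protected))
}

#' Write a DiCC matrix as TSV (fixed 3 decimals) or JSON (full precision)
#'
#' The TSV mirrors the conventional table layout: domain-labelled rows and
#' columns, fixed-point with three decimals. The JSON carries full
#' precision plus metadata (mode, frame count, replica count, strongest
#' pair).
#'
#' @param x A `dicc_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dicc_tsv <- function(x, path) {
  labels <- rownames(x)
  m <- matrix(sprintf("%.3f", unclass(x)), nrow = nrow(x))
  df <- data.frame(domain = labels, m, check.names = FALSE)
  names(df) <- c("domain", labels)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_dicc_tsv
#' @export
write_dicc_json <- function(x, path) {
  mp <- attr(x, "max_pair")
  jsonlite::write_json(
    list(labels = rownames(x),
         entries = unclass(x),
         mode = attr(x, "mode_used"),
         n_frames = attr(x, "n_frames"),
         n_replicas = attr(x, "n_replicas"),
         max_pair = mp$pair,
         max_dicc = mp$value),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Write an RMSD series as two-column TSV
#'
#' Columns `frame` and `rmsd_A` (angstroms).
#'
#' @param x An `rmsd_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rmsd_tsv <- function(x, path) {
  df <- tibble::tibble(frame = x$frame, rmsd_A = x$rmsd)
  readr::write_tsv(df, path)
  invisible(path)
}
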