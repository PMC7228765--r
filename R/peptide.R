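#' @name mass-constants
#' @title Atomic mass constants
#' @description
#' Monoisotopic masses (Da) of the elements handled by the mass arithmetic,
#' fixed as module constants, plus the proton mass used for m/z. Enriched
#' labels (`13C`, `D`) are treated as isotopically pure.
#' @keywords internal
NULL

ATOMIC_MASS <- c(
  H = 1.007825, D = 2.014102, C = 12.000000, `13C` = 13.003355,
  N = 14.003074, O = 15.994915, S = 31.972071)

PROTON_MASS <- 1.007276

# average spacing between adjacent isotopologue peaks (Da)
ISOTOPE_SPACING <- 1.00336

# natural isotope patterns: nominal mass shift and abundance per element
ISOTOPE_TABLE <- list(
  H = list(shift = c(0L, 1L), abundance = c(0.999885, 0.000115)),
  C = list(shift = c(0L, 1L), abundance = c(0.9893, 0.0107)),
  N = list(shift = c(0L, 1L), abundance = c(0.99636, 0.00364)),
  O = list(shift = c(0L, 1L, 2L), abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(shift = c(0L, 1L, 2L, 4L),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  # enriched labels: no isotope spread
  D = list(shift = 0L, abundance = 1),
  `13C` = list(shift = 0L, abundance = 1))

# residue (= amino acid minus water) elemental compositions, one-letter code
RESIDUE_COMPOSITION <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

WATER <- c(H = 2, O = 1)

#' Elemental composition objects
#'
#' A named integer vector of element (or labeled-isotope) counts over the
#' symbols H, D, C, 13C, N, O, S. Compositions add element-wise with `+`
#' and subtract with `-`; subtraction below zero is an error.
#'
#' @param counts A named numeric vector, e.g. `c(C = 2, H = 3, N = 1, O = 1)`.
#' @return An object of class `elemental_composition`.
#' @export
elemental_composition_of <- function(counts) {
  if (length(counts) == 0L) counts <- c(H = 0)
  bad <- setdiff(names(counts), names(ATOMIC_MASS))
  if (length(bad) > 0L) {
    abort_dicckit(sprintf("Unknown element symbol(s): %s.",
                          paste(bad, collapse = ", ")),
                  class = "dicckit_unknown_element_error")
  }
  if (any(counts < 0)) {
    abort_dicckit("Element counts must be non-negative.",
                  class = "dicckit_composition_error")
  }
  full <- stats::setNames(rep(0, length(ATOMIC_MASS)), names(ATOMIC_MASS))
  full[names(counts)] <- full[names(counts)] + counts
  structure(full, class = "elemental_composition")
}

#' @export
`+.elemental_composition` <- function(e1, e2) {
  elemental_composition_of(unclass(e1) + unclass(e2))
}

#' @export
`-.elemental_composition` <- function(e1, e2) {
  out <- unclass(e1) - unclass(e2)
  if (any(out < 0)) {
    abort_dicckit("Composition subtraction went negative.",
                  class = "dicckit_composition_error")
  }
  elemental_composition_of(out)
}

#' @export
format.elemental_composition <- function(x, ...) {
  hill <- c("C", "13C", "H", "D", "N", "O", "S")
  nz <- unclass(x)[hill]
  nz <- nz[nz > 0]
  paste0(names(nz), ifelse(nz == 1, "", nz), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<composition ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Named cysteine modifications
#'
#' Composition deltas for the shipped modifications, derived from the
#' element table rather than hard-coded masses:
#' * `"carbamidomethyl"` — +C2H3NO (+57.02146 Da) from unlabeled
#'   iodoacetamide ("light").
#' * `"carbamidomethyl-heavy"` — the same adduct from
#'   13C2,D2-iodoacetamide (+13C2 H D2 N O, +61.04072 Da, "heavy").
#'
#' @param name Modification name.
#' @return An `elemental_composition` delta.
#' @export
modification_delta <- function(name) {
  switch(name,
    "carbamidomethyl" = elemental_composition_of(c(C = 2, H = 3, N = 1, O = 1)),
    "carbamidomethyl-heavy" =
      elemental_composition_of(c(`13C` = 2, H = 1, D = 2, N = 1, O = 1)),
    abort_dicckit(sprintf("Unknown modification: %s.", name),
                  class = "dicckit_unknown_modification_error"))
}

#' Construct a peptide
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @param modifications A list of modifications, each a list with `name`
#'   (a [modification_delta()] name or an arbitrary label), `site` (1-based
#'   residue position), and optionally `delta` (an
#'   `elemental_composition`; defaults to `modification_delta(name)`).
#'   Cysteine-targeted carbamidomethyl modifications must sit on a C
#'   residue.
#' @return An object of class `peptide`.
#' @export
peptide <- function(sequence, modifications = list()) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    abort_dicckit("Peptide sequence must be a non-empty string.",
                  class = "dicckit_unknown_residue_error")
  }
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters1, names(RESIDUE_COMPOSITION))
  if (length(bad) > 0L) {
    abort_dicckit(sprintf("Unknown residue letter(s): %s.",
                          paste(unique(bad), collapse = ", ")),
                  class = "dicckit_unknown_residue_error")
  }
  modifications <- lapply(modifications, function(m) {
    if (is.null(m$name) || is.null(m$site)) {
      abort_config("Each modification needs `name` and `site`.")
    }
    check_scalar_number(m$site, "site", min = 1, max = nchar(sequence),
                        integerish = TRUE)
    if (is.null(m$delta)) m$delta <- modification_delta(m$name)
    if (grepl("^carbamidomethyl", m$name) && letters1[m$site] != "C") {
      abort_config(sprintf(
        "Modification %s targets cysteine but residue %d is %s.",
        m$name, m$site, letters1[m$site]))
    }
    m
  })
  structure(list(sequence = sequence, modifications = modifications),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  mods <- if (length(x$modifications) == 0L) "" else
    paste0(" + ", paste(vapply(x$modifications, function(m)
      sprintf("%s@%d", m$name, m$site), character(1)), collapse = ", "))
  cat("<peptide ", x$sequence, mods, ">\n", sep = "")
  invisible(x)
}

#' Carbamidomethylate the free cysteines of a peptide
#'
#' Adds a light or heavy carbamidomethyl group to every cysteine that does
#' not already carry a modification.
#'
#' @param p A [peptide()].
#' @param heavy Use the 13C2,D2-labeled reagent delta?
#' @return A modified [peptide()].
#' @export
carbamidomethylate <- function(p, heavy = FALSE) {
  name <- if (heavy) "carbamidomethyl-heavy" else "carbamidomethyl"
  taken <- vapply(p$modifications, function(m) m$site, numeric(1))
  sites <- setdiff(which(strsplit(p$sequence, "")[[1]] == "C"), taken)
  if (length(sites) == 0L) {
    abort_dicckit("Peptide has no free cysteine to alkylate.",
                  class = "dicckit_no_cysteine_error")
  }
  mods <- c(p$modifications,
            lapply(sites, function(s) list(name = name, site = s,
                                           delta = modification_delta(name))))
  peptide(p$sequence, mods)
}

# number of cysteines not carrying any modification
#' @noRd
free_cysteines <- function(p) {
  taken <- vapply(p$modifications, function(m) m$site, numeric(1))
  setdiff(which(strsplit(p$sequence, "")[[1]] == "C"), taken)
}

#' Elemental composition of a peptide
#'
#' Sum of residue compositions, plus one water, plus all modification
#' deltas.
#'
#' @param p A [peptide()].
#' @return An `elemental_composition`.
#' @export
elemental_composition <- function(p) {
  letters1 <- strsplit(p$sequence, "")[[1]]
  counts <- Reduce(`+`, lapply(RESIDUE_COMPOSITION[letters1],
                               elemental_composition_of),
                   accumulate = FALSE)
  counts <- counts + elemental_composition_of(WATER)
  for (m in p$modifications) counts <- counts + m$delta
  counts
}

#' Monoisotopic mass of a composition or peptide
#'
#' Sum of count times lightest-isotope (or labeled-isotope) mass, using the
#' fixed atomic mass table (see `mass-constants`).
#'
#' @param x An `elemental_composition` or a [peptide()].
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(x) {
  if (inherits(x, "peptide")) x <- elemental_composition(x)
  if (!inherits(x, "elemental_composition")) x <- elemental_composition_of(x)
  sum(unclass(x) * ATOMIC_MASS[names(x)])
}

#' m/z of a protonated peptide
#'
#' `(M + z * 1.007276) / z` with M the monoisotopic mass.
#'
#' @param p A [peptide()] (or an `elemental_composition`).
#' @param z Positive integer charge.
#' @return m/z in Th.
#' @export
peptide_mz <- function(p, z) {
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z)) {
    abort_dicckit("Charge must be a positive integer.",
                  class = "dicckit_charge_error")
  }
  (monoisotopic_mass(p) + z * PROTON_MASS) / z
}

#' Neutral monoisotopic mass of an interpeptide disulfide
#'
#' Disulfide formation between one cysteine of each peptide removes two
#' hydrogens: `mass(p1) + mass(p2) - 2 * m_H`. Symmetric in its arguments.
#' Each peptide must carry at least one unmodified cysteine.
#'
#' @param p1,p2 [peptide()]s.
#' @return Mass in Da.
#' @export
disulfide_mass <- function(p1, p2) {
  for (p in list(p1, p2)) {
    if (length(free_cysteines(p)) == 0L) {
      abort_dicckit(sprintf("Peptide %s has no free cysteine.", p$sequence),
                    class = "dicckit_no_cysteine_error")
    }
  }
  monoisotopic_mass(p1) + monoisotopic_mass(p2) - 2 * ATOMIC_MASS[["H"]]
}

#' m/z of a protonated interpeptide disulfide
#' @inheritParams disulfide_mass
#' @param z Positive integer charge.
#' @return m/z in Th.
#' @export
disulfide_mz <- function(p1, p2, z) {
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z)) {
    abort_dicckit("Charge must be a positive integer.",
                  class = "dicckit_charge_error")
  }
  (disulfide_mass(p1, p2) + z * PROTON_MASS) / z
}

#' ETD fragment masses of a disulfide-linked peptide pair
#'
#' Electron-transfer dissociation preferentially cleaves the S-S bond,
#' yielding a thiol fragment and a thiyl-radical fragment. Under the
#' conventions used here the thiol fragment's neutral mass is the peptide
#' monoisotopic mass plus one hydrogen and the radical fragment's neutral
#' mass equals the peptide monoisotopic mass; both assignments (either
#' peptide as the thiol) are returned.
#'
#' @inheritParams disulfide_mass
#' @return A tibble with columns `thiol_peptide`, `radical_peptide`,
#'   `thiol_mass`, `radical_mass` (Da), one row per assignment.
#' @export
etd_disulfide_fragments <- function(p1, p2) {
  for (p in list(p1, p2)) {
    if (length(free_cysteines(p)) == 0L) {
      abort_dicckit(sprintf("Peptide %s has no free cysteine.", p$sequence),
                    class = "dicckit_no_cysteine_error")
    }
  }
  m1 <- monoisotopic_mass(p1)
  m2 <- monoisotopic_mass(p2)
  h <- ATOMIC_MASS[["H"]]
  tibble::tibble(
    thiol_peptide = c(p1$sequence, p2$sequence),
    radical_peptide = c(p2$sequence, p1$sequence),
    thiol_mass = c(m1 + h, m2 + h),
    radical_mass = c(m2, m1))
}

#' Theoretical isotope envelope of a composition
#'
#' Builds the aggregated isotopologue distribution by successive
#' convolution of per-element natural-isotope vectors, binned at unit
#' nominal-mass spacing (no fine structure). Peak m/z values are placed at
#' `monoisotopic_mz + k * 1.00336 / z`; intensities are renormalized over
#' the retained peaks. Enriched labels (13C, D) contribute no isotope
#' spread.
#'
#' @param x An `elemental_composition` or [peptide()].
#' @param z Positive integer charge.
#' @param max_peaks Number of isotopologue peaks retained (default 6).
#' @return An object of class `isotope_envelope`: a list with `peaks` (a
#'   tibble of `mz`, `relative_intensity`), `charge`, and
#'   `monoisotopic_mz`. The first peak is the monoisotopic peak and
#'   intensities sum to 1.
#' @export
isotope_distribution <- function(x, z, max_peaks = 6L) {
  if (inherits(x, "peptide")) x <- elemental_composition(x)
  if (!inherits(x, "elemental_composition")) x <- elemental_composition_of(x)
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z)) {
    abort_dicckit("Charge must be a positive integer.",
                  class = "dicckit_charge_error")
  }
  check_scalar_number(max_peaks, "max_peaks", min = 1, integerish = TRUE)
  dist <- 1  # probability vector over nominal mass shifts 0, 1, 2, ...
  for (el in names(x)) {
    n <- unclass(x)[[el]]
    if (n == 0) next
    iso <- ISOTOPE_TABLE[[el]]
    vec <- rep(0, max(iso$shift) + 1L)
    vec[iso$shift + 1L] <- iso$abundance
    for (k in seq_len(n)) dist <- convolve_shift(dist, vec, max_len = 64L)
  }
  keep <- dist[seq_len(min(max_peaks, length(dist)))]
  keep <- keep / sum(keep)
  mono_mz <- (monoisotopic_mass(x) + z * PROTON_MASS) / z
  peaks <- tibble::tibble(
    mz = mono_mz + (seq_along(keep) - 1L) * ISOTOPE_SPACING / z,
    relative_intensity = keep)
  structure(list(peaks = peaks, charge = as.integer(z),
                 monoisotopic_mz = mono_mz),
            class = "isotope_envelope")
}

# linear convolution of two probability vectors, truncated at max_len
#' @noRd
convolve_shift <- function(a, b, max_len) {
  out <- rep(0, min(length(a) + length(b) - 1L, max_len))
  for (j in seq_along(b)) {
    if (b[j] == 0) next
    upto <- min(length(a), max_len - j + 1L)
    if (upto < 1L) break
    idx <- seq_len(upto) + j - 1L
    out[idx] <- out[idx] + a[seq_len(upto)] * b[j]
  }
  out
}

#' @export
print.isotope_envelope <- function(x, ...) {
  cat(sprintf("<isotope_envelope: z=%d, monoisotopic m/z %.4f, %d peaks>\n",
              x$charge, x$monoisotopic_mz, nrow(x$peaks)))
  print(x$peaks)
  invisible(x)
}
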