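test_that("elemental compositions follow residue + water + modification arithmetic", {
  comp_g <- elemental_composition(peptide("G"))
  expect_equal(format(comp_g), "C2H5NO2")
  comp_ag <- elemental_composition(peptide("AG"))
  expect_equal(unclass(comp_ag)[c("C", "H", "N", "O")],
               c(C = 5, H = 10, N = 2, O = 3))
  expect_error(peptide(""), class = "dicckit_unknown_residue_error")
  expect_error(peptide("AZB"), class = "dicckit_unknown_residue_error")

  # additivity: composition of concatenated residues = sum - one water
  c1 <- elemental_composition(peptide("CQPPPPPMK"))
  c2 <- elemental_composition(peptide("NAAECDTY"))
  joint <- elemental_composition(peptide("CQPPPPPMKNAAECDTY"))
  expect_equal(unclass(c1 + c2 - elemental_composition_of(c(H = 2, O = 1))),
               unclass(joint))
  expect_equal(monoisotopic_mass(c1) + monoisotopic_mass(c2),
               monoisotopic_mass(joint) + monoisotopic_mass(
                 elemental_composition_of(c(H = 2, O = 1))),
               tolerance = 1e-9)
})

test_that("monoisotopic masses reproduce the published fragment values", {
  expect_equal(monoisotopic_mass(elemental_composition_of(c(H = 2, O = 1))),
               18.0106, tolerance = 5e-5)
  # thiol fragment of CQPPPPPMK: peptide + H = 994.49 Da at 2 decimals
  expect_equal(monoisotopic_mass(peptide("CQPPPPPMK")) + 1.00783,
               994.49, tolerance = 5e-3)
  # thiyl radical of NAAECDTY: the bare peptide mass, 885.32 Da
  expect_equal(monoisotopic_mass(peptide("NAAECDTY")),
               885.32, tolerance = 5e-3)
})

test_that("carbamidomethylated peptide m/z values match the published precursors", {
  cam1 <- carbamidomethylate(peptide("CQPPPPPMK"))
  cam2 <- carbamidomethylate(peptide("NAAECDTY"))
  expect_equal(peptide_mz(cam1, 2), 526.2569, tolerance = 1e-4)
  expect_equal(peptide_mz(cam2, 1), 943.3462, tolerance = 1e-4)
  expect_error(peptide_mz(cam1, 0), class = "dicckit_charge_error")
})

test_that("modification deltas are derived from the isotope table", {
  light <- modification_delta("carbamidomethyl")
  heavy <- modification_delta("carbamidomethyl-heavy")
  expect_equal(monoisotopic_mass(light), 57.02146, tolerance = 1e-5)
  expect_equal(monoisotopic_mass(heavy), 61.04072, tolerance = 1e-5)
  expect_equal(monoisotopic_mass(heavy) - monoisotopic_mass(light),
               4.019268, tolerance = 1e-5)
  # internal consistency tying the delta to two printed numbers:
  # mz(CAM-NAAECDTY, 1) - mass(NAAECDTY) - proton = CAM delta
  lhs <- peptide_mz(carbamidomethylate(peptide("NAAECDTY")), 1) -
    monoisotopic_mass(peptide("NAAECDTY")) - 1.00728
  expect_equal(lhs, 57.0215, tolerance = 1e-4)
})

test_that("cysteine-targeted modifications must sit on cysteines", {
  expect_error(peptide("AGA", list(list(name = "carbamidomethyl", site = 2))),
               class = "dicckit_config_error")
  expect_error(carbamidomethylate(carbamidomethylate(peptide("ACA"))),
               class = "dicckit_no_cysteine_error")
})

test_that("disulfide mass arithmetic loses two hydrogens and is symmetric", {
  p1 <- peptide("CQPPPPPMK")
  p2 <- peptide("NAAECDTY")
  expect_equal(disulfide_mass(p1, p2),
               monoisotopic_mass(p1) + monoisotopic_mass(p2) - 2 * 1.007825,
               tolerance = 1e-9)
  expect_equal(disulfide_mass(p1, p2), disulfide_mass(p2, p1))
  expect_equal(disulfide_mz(p1, p2, 3), 626.6005, tolerance = 1e-4)
  blocked <- carbamidomethylate(p1)
  expect_error(disulfide_mass(blocked, p2),
               class = "dicckit_no_cysteine_error")
})

test_that("ETD fragment conventions give thiol = peptide + H, radical = peptide", {
  p1 <- peptide("CQPPPPPMK")
  p2 <- peptide("NAAECDTY")
  fr <- etd_disulfide_fragments(p1, p2)
  expect_equal(nrow(fr), 2)
  row1 <- fr[fr$thiol_peptide == "CQPPPPPMK", ]
  expect_equal(row1$thiol_mass, 994.49, tolerance = 5e-3)
  expect_equal(row1$radical_mass, 885.32, tolerance = 5e-3)
  # thiol(p) - radical(p) = one hydrogen for every peptide
  row2 <- fr[fr$thiol_peptide == "NAAECDTY", ]
  expect_equal(row1$thiol_mass - row2$radical_mass, 1.00783,
               tolerance = 1e-4)
  expect_equal(row2$thiol_mass - row1$radical_mass, 1.00783,
               tolerance = 1e-4)
})

test_that("single-element isotope patterns come straight from the table", {
  env_c <- isotope_distribution(elemental_composition_of(c(C = 1)), 1,
                                max_peaks = 2)
  expect_equal(env_c$peaks$relative_intensity, c(0.9893, 0.0107),
               tolerance = 1e-9)
  # an enriched label is treated as pure: a single peak, no isotope spread
  env_13c <- isotope_distribution(elemental_composition_of(c(`13C` = 1)), 1,
                                  max_peaks = 6)
  expect_equal(nrow(env_13c$peaks), 1)
  expect_equal(env_13c$peaks$relative_intensity, 1)
})

test_that("envelope invariants hold: normalized, ordered, monoisotopic first", {
  env <- isotope_distribution(carbamidomethylate(peptide("NAAECDTY")), 1)
  expect_equal(sum(env$peaks$relative_intensity), 1, tolerance = 1e-6)
  expect_false(is.unsorted(env$peaks$mz, strictly = TRUE))
  expect_equal(env$peaks$mz[1], env$monoisotopic_mz)
  expect_true(all(env$peaks$relative_intensity >= 0))
  spacing <- diff(env$peaks$mz)
  expect_equal(spacing, rep(1.00336, 5), tolerance = 1e-9)
})

test_that("the aggregated envelope matches exhaustive isotopologue enumeration", {
  # Oracle: enumerate, element by element, every combination of heavy-isotope
  # counts (multinomial probabilities), accumulate probability by total
  # nominal mass shift, then truncate and renormalize exactly as the
  # implementation documents. Run on carbamidomethylated CQPPPPPMK.
  pep <- carbamidomethylate(peptide("CQPPPPPMK"))
  comp <- unclass(elemental_composition(pep))
  max_shift <- 7L
  # closed-form shift distribution of n atoms of one element:
  # binomial for two isotopes, multinomial enumeration otherwise
  element_shift_dist <- function(n, shifts, probs) {
    out <- rep(0, max_shift + 1L)
    if (length(shifts) == 2L) {
      for (k in 0:min(n, max_shift)) {
        out[k * shifts[2] + 1L] <- stats::dbinom(k, n, probs[2])
      }
    } else {
      heavy <- shifts[-1]
      counts <- expand.grid(lapply(heavy, function(s) 0:min(n, max_shift)))
      for (r in seq_len(nrow(counts))) {
        ks <- as.integer(counts[r, ])
        if (sum(ks) > n) next
        shift <- sum(ks * heavy)
        if (shift > max_shift) next
        out[shift + 1L] <- out[shift + 1L] +
          stats::dmultinom(c(n - sum(ks), ks), prob = probs)
      }
    }
    out
  }
  combine <- function(a, b) {
    out <- rep(0, max_shift + 1L)
    for (i in 0:max_shift) for (j in 0:(max_shift - i)) {
      out[i + j + 1L] <- out[i + j + 1L] + a[i + 1L] * b[j + 1L]
    }
    out
  }
  acc <- Reduce(combine, list(
    element_shift_dist(comp[["C"]], c(0L, 1L), c(0.9893, 0.0107)),
    element_shift_dist(comp[["H"]], c(0L, 1L), c(0.999885, 0.000115)),
    element_shift_dist(comp[["N"]], c(0L, 1L), c(0.99636, 0.00364)),
    element_shift_dist(comp[["O"]], c(0L, 1L, 2L),
                       c(0.99757, 0.00038, 0.00205)),
    element_shift_dist(comp[["S"]], c(0L, 1L, 2L, 4L),
                       c(0.9499, 0.0075, 0.0425, 0.0001))))
  oracle <- acc[1:6] / sum(acc[1:6])
  env <- isotope_distribution(pep, 2, max_peaks = 6)
  expect_equal(env$peaks$relative_intensity, oracle, tolerance = 1e-6)
})

test_that("unknown element symbols are rejected", {
  expect_error(elemental_composition_of(c(Xx = 1)),
               class = "dicckit_unknown_element_error")
  expect_error(elemental_composition_of(c(C = -1)),
               class = "dicckit_composition_error")
})
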