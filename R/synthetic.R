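#' Configuration for a synthetic multi-domain trajectory
#'
#' The generator emulates rigid-body motion of several protein domains
#' with a shared latent displacement process plus independent per-domain
#' noise. Domain k is displaced at frame t by
#' `u_k(t) = lambda_k * s(t) + eta_k(t)`, where `s` is a shared 3-vector
#' latent process, `lambda_k` its per-domain loading in `[0, 1]`, and
#' `eta_k` an independent per-domain process. Both processes are either
#' mean-reverting (stationary AR(1), the default, mimicking an
#' equilibrated production trajectory) or a random walk (mimicking a
#' drifting one). An optional global rigid rotation+translation per frame
#' and per-atom jitter can be layered on top. The seed is mandatory so no
#' downstream test is silently stochastic.
#'
#' @param n_domains Number of domains (default 4, matching the
#'   NTD/MLD/CTD/TMD partition this pipeline was designed around).
#' @param atoms_per_domain C-alpha atoms (= residues) per domain.
#' @param n_frames Number of frames.
#' @param latent_loadings Per-domain loading `lambda_k` in `[0, 1]`
#'   (recycled if scalar).
#' @param independent_noise_sd Per-domain step sd of the independent
#'   process, in angstroms (recycled if scalar).
#' @param latent_process List with `type` (`"mean-reverting"` or
#'   `"random-walk"`), `step_sd` (angstroms per frame) and
#'   `reversion_rate` (per frame; ignored for random walks).
#' @param per_atom_jitter_sd Sd of iid per-atom positional jitter
#'   (angstroms, default 0).
#' @param global_rigid_motion Apply a random rigid rotation+translation to
#'   every frame (removable by [align_trajectory()])?
#' @param seed Integer seed (mandatory).
#' @return A list of class `trajectory_config`.
#' @export
trajectory_config <- function(n_domains = 4L,
                              atoms_per_domain = 30L,
                              n_frames = 1000L,
                              latent_loadings = 0.7,
                              independent_noise_sd = 0.5,
                              latent_process = list(type = "mean-reverting",
                                                    step_sd = 1.0,
                                                    reversion_rate = 0.1),
                              per_atom_jitter_sd = 0,
                              global_rigid_motion = FALSE,
                              seed) {
  if (missing(seed)) abort_config("`seed` is mandatory in trajectory_config.")
  check_scalar_number(seed, "seed", min = -2^31 + 1, max = 2^31 - 10,
                      integerish = TRUE)
  check_scalar_number(n_domains, "n_domains", min = 1, integerish = TRUE)
  check_scalar_number(atoms_per_domain, "atoms_per_domain", min = 1,
                      integerish = TRUE)
  check_scalar_number(n_frames, "n_frames", min = 1, integerish = TRUE)
  latent_loadings <- rep_len(latent_loadings, n_domains)
  if (any(latent_loadings < 0 | latent_loadings > 1)) {
    abort_config("`latent_loadings` must lie in [0, 1].")
  }
  independent_noise_sd <- rep_len(independent_noise_sd, n_domains)
  if (any(independent_noise_sd < 0)) {
    abort_config("`independent_noise_sd` must be non-negative.")
  }
  if (!latent_process$type %in% c("mean-reverting", "random-walk")) {
    abort_config("latent_process$type must be \"mean-reverting\" or \"random-walk\".")
  }
  check_scalar_number(latent_process$step_sd, "latent_process$step_sd", min = 0)
  if (latent_process$type == "mean-reverting") {
    check_scalar_number(latent_process$reversion_rate,
                        "latent_process$reversion_rate", min = 0, max = 1)
  }
  check_scalar_number(per_atom_jitter_sd, "per_atom_jitter_sd", min = 0)
  structure(
    list(n_domains = as.integer(n_domains),
         atoms_per_domain = as.integer(atoms_per_domain),
         n_frames = as.integer(n_frames),
         latent_loadings = latent_loadings,
         independent_noise_sd = independent_noise_sd,
         latent_process = latent_process,
         per_atom_jitter_sd = per_atom_jitter_sd,
         global_rigid_motion = isTRUE(global_rigid_motion),
         locked_pair = NULL,
         seed = as.integer(seed)),
    class = "trajectory_config")
}

#' Derive a disulfide-locked configuration
#'
#' Emulates an engineered inter-domain disulfide: the two locked domains
#' share one fully common displacement (loading 1 on a pair-specific
#' latent process, with a single shared independent-noise process), so
#' their motions are identical and their DiCC is maximal. All other
#' domains are untouched.
#'
#' @param base A [trajectory_config()].
#' @param pair Integer vector of two distinct 1-based domain indices.
#' @return A modified `trajectory_config`.
#' @export
locked_pair_config <- function(base, pair) {
  if (!inherits(base, "trajectory_config")) {
    abort_config("`base` must be a trajectory_config.")
  }
  if (length(pair) != 2L || anyNA(pair) || pair[1] == pair[2]) {
    abort_config("`pair` must be two distinct domain indices.")
  }
  pair <- as.integer(sort(pair))
  if (any(pair < 1L | pair > base$n_domains)) {
    abort_config("`pair` indices must lie within 1..n_domains.")
  }
  base$locked_pair <- pair
  base
}

#' Reference geometry for a synthetic trajectory
#'
#' Places each domain as a compact point cloud (one C-alpha per residue,
#' uniform in a cube of half-width 4 angstroms) with domain centers 50
#' angstroms apart along x, guaranteeing >= 20 angstroms between clouds.
#' Residue numbering is contiguous across domains, starting at 1.
#' Deterministic for a given seed.
#'
#' @param cfg A [trajectory_config()].
#' @return A one-frame [trajectory()].
#' @export
make_geometry <- function(cfg) {
  if (!inherits(cfg, "trajectory_config")) {
    abort_config("`cfg` must be a trajectory_config.")
  }
  withr::with_seed(cfg$seed, {
    n_at <- cfg$n_domains * cfg$atoms_per_domain
    coords <- matrix(0, nrow = n_at, ncol = 3L)
    for (k in seq_len(cfg$n_domains)) {
      rows <- ((k - 1L) * cfg$atoms_per_domain + 1L):(k * cfg$atoms_per_domain)
      center <- c((k - 1L) * 50, 0, 0)
      cloud <- matrix(stats::runif(3L * cfg$atoms_per_domain, -4, 4),
                      ncol = 3L)
      coords[rows, ] <- sweep(cloud, 2, center, `+`)
    }
    atoms <- tibble::tibble(
      residue_number = seq_len(n_at),
      residue_name = "ALA",
      atom_name = "CA",
      chain_id = "A")
    trajectory(coords, atoms)
  })
}

# default domain labels for the synthetic systems
#' @noRd
synthetic_domain_labels <- function(n) {
  base <- c("NTD", "MLD", "CTD", "TMD")
  if (n <= 4L) base[seq_len(n)] else c(base, paste0("D", seq(5L, n)))
}

#' Domain definitions matching a synthetic geometry
#'
#' @param cfg A [trajectory_config()].
#' @return A list of [domain_definition()]s (NTD, MLD, CTD, TMD, D5, ...)
#'   covering the generator's contiguous residue blocks.
#' @export
synthetic_domains <- function(cfg) {
  labels <- synthetic_domain_labels(cfg$n_domains)
  purrr::map(seq_len(cfg$n_domains), function(k) {
    lo <- (k - 1L) * cfg$atoms_per_domain + 1L
    domain_definition(labels[k], list(c(lo, lo + cfg$atoms_per_domain - 1L)))
  })
}

# simulate one 3-vector process of length n
#' @noRd
simulate_process <- function(n, type, step_sd, reversion_rate) {
  x <- matrix(0, nrow = n, ncol = 3L)
  if (step_sd == 0 || n == 1L) {
    if (step_sd == 0) return(x)
  }
  eps <- matrix(stats::rnorm(3L * n, sd = step_sd), ncol = 3L)
  keep <- if (type == "mean-reverting") 1 - reversion_rate else 1
  x[1, ] <- eps[1, ]
  for (t in seq_len(n)[-1]) x[t, ] <- keep * x[t - 1, ] + eps[t, ]
  x
}

# random small rigid motion per frame (rotation up to ~15 deg, translation
# sd 2 A)
#' @noRd
random_rigid_motions <- function(n) {
  lapply(seq_len(n), function(i) {
    axis <- stats::rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    theta <- stats::runif(1, -pi / 12, pi / 12)
    k <- matrix(c(0, -axis[3], axis[2],
                  axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), nrow = 3, byrow = TRUE)
    rot <- diag(3) + sin(theta) * k + (1 - cos(theta)) * (k %*% k)
    list(rotation = rot, translation = stats::rnorm(3, sd = 2))
  })
}

#' Simulate a multi-domain trajectory with known coupling
#'
#' Generates frames from the reference geometry of [make_geometry()] by
#' displacing all atoms of each domain rigidly by
#' `u_k(t) = lambda_k * s(t) + eta_k(t)` (see [trajectory_config()]).
#' When the configuration carries a locked pair (see
#' [locked_pair_config()]) the paired domains instead share a
#' pair-specific latent plus one shared noise process, so their
#' displacement series are identical. An optional global rigid motion per
#' frame and per-atom jitter are applied last. Bit-reproducible for a
#' given seed and configuration.
#'
#' @param cfg A [trajectory_config()].
#' @return A list with `trajectory` (a [trajectory()]), `domains` (the
#'   matching [synthetic_domains()]), and `truth`: the latent series
#'   (`latent`), per-domain displacement series (`displacements`, a list
#'   of `n_frames x 3` matrices), and the configuration. The truth record
#'   suffices to recompute every analysis quantity independently.
#' @export
simulate_trajectory <- function(cfg) {
  if (!inherits(cfg, "trajectory_config")) {
    abort_config("`cfg` must be a trajectory_config.")
  }
  geom <- make_geometry(cfg)
  ref <- frame_coords(geom, 1L)
  nf <- cfg$n_frames
  nd <- cfg$n_domains
  withr::with_seed(cfg$seed + 1L, {
    latent <- simulate_process(nf, cfg$latent_process$type,
                               cfg$latent_process$step_sd,
                               cfg$latent_process$reversion_rate %||% 0)
    noise <- lapply(seq_len(nd), function(k) {
      simulate_process(nf, cfg$latent_process$type,
                       cfg$independent_noise_sd[k],
                       cfg$latent_process$reversion_rate %||% 0)
    })
    disp <- lapply(seq_len(nd), function(k) {
      cfg$latent_loadings[k] * latent + noise[[k]]
    })
    if (!is.null(cfg$locked_pair)) {
      pair_latent <- simulate_process(nf, cfg$latent_process$type,
                                      cfg$latent_process$step_sd,
                                      cfg$latent_process$reversion_rate %||% 0)
      shared_noise <- simulate_process(
        nf, cfg$latent_process$type,
        mean(cfg$independent_noise_sd[cfg$locked_pair]),
        cfg$latent_process$reversion_rate %||% 0)
      locked_disp <- pair_latent + shared_noise
      for (k in cfg$locked_pair) disp[[k]] <- locked_disp
    }
    coords <- array(0, dim = c(nf, nrow(ref), 3L))
    for (k in seq_len(nd)) {
      rows <- ((k - 1L) * cfg$atoms_per_domain + 1L):(k * cfg$atoms_per_domain)
      for (d in 1:3) {
        coords[, rows, d] <- matrix(ref[rows, d], nrow = nf,
                                    ncol = length(rows), byrow = TRUE) +
          disp[[k]][, d]
      }
    }
    if (cfg$global_rigid_motion) {
      motions <- random_rigid_motions(nf)
      for (t in seq_len(nf)) {
        coords[t, , ] <- sweep(coords[t, , ] %*% motions[[t]]$rotation, 2,
                               motions[[t]]$translation, `+`)
      }
    }
    if (cfg$per_atom_jitter_sd > 0) {
      coords <- coords + array(
        stats::rnorm(length(coords), sd = cfg$per_atom_jitter_sd),
        dim = dim(coords))
    }
    list(trajectory = trajectory(coords, geom$atoms),
         domains = synthetic_domains(cfg),
         truth = list(latent = latent, displacements = disp, config = cfg))
  })
}

#' Configuration for a synthetic labeled-peptide spectrum
#'
#' Emulates the MS1 spectra of a heavy/light iodoacetamide labeling
#' experiment: the observed envelope is a mixture
#' `f * light + (1 - f) * heavy` of the two carbamidomethylated isotope
#' envelopes, with normal m/z jitter on the ppm scale, multiplicative
#' intensity noise, and optional unrelated decoy peaks kept at least 50
#' ppm from any expected peak.
#'
#' @param pep The unmodified [peptide()] carrying the quantified cysteine.
#' @param true_fraction_protected The ground-truth protected fraction `f`
#'   in `[0, 1]`.
#' @param charge Charge state of the envelopes.
#' @param ppm_jitter_sd Sd of m/z jitter in ppm (default 3).
#' @param intensity_noise_cv Coefficient of variation of multiplicative
#'   intensity noise (default 0.02).
#' @param baseline_peaks Number of random decoy peaks (default 0).
#' @param max_peaks Isotopologue peaks per label envelope (default 6).
#' @param centroid_merge_ppm Species closer in m/z than this are reported
#'   as a single centroid at the intensity-weighted mean position,
#'   emulating the finite resolving power of the analyzer (default 10 ppm;
#'   an Orbitrap at R = 60,000 has a ~17 ppm FWHM near m/z 500).
#' @param seed Integer seed (mandatory).
#' @return A list of class `spectrum_config`.
#' @export
spectrum_config <- function(pep, true_fraction_protected, charge = 2L,
                            ppm_jitter_sd = 3, intensity_noise_cv = 0.02,
                            baseline_peaks = 0L, max_peaks = 6L,
                            centroid_merge_ppm = 10, seed) {
  if (missing(seed)) abort_config("`seed` is mandatory in spectrum_config.")
  check_scalar_number(seed, "seed", min = -2^31 + 1, max = 2^31 - 10,
                      integerish = TRUE)
  check_scalar_number(centroid_merge_ppm, "centroid_merge_ppm", min = 0)
  if (!inherits(pep, "peptide")) abort_config("`pep` must be a peptide.")
  check_scalar_number(true_fraction_protected, "true_fraction_protected",
                      min = 0, max = 1)
  check_scalar_number(charge, "charge", min = 1, integerish = TRUE)
  check_scalar_number(ppm_jitter_sd, "ppm_jitter_sd", min = 0)
  check_scalar_number(intensity_noise_cv, "intensity_noise_cv", min = 0)
  check_scalar_number(baseline_peaks, "baseline_peaks", min = 0,
                      integerish = TRUE)
  check_scalar_number(max_peaks, "max_peaks", min = 1, integerish = TRUE)
  structure(
    list(pep = pep, true_fraction_protected = true_fraction_protected,
         charge = as.integer(charge), ppm_jitter_sd = ppm_jitter_sd,
         intensity_noise_cv = intensity_noise_cv,
         baseline_peaks = as.integer(baseline_peaks),
         max_peaks = as.integer(max_peaks),
         centroid_merge_ppm = centroid_merge_ppm, seed = as.integer(seed)),
    class = "spectrum_config")
}

# apply jitter/noise to (mz, intensity) and return a sorted peak list
#' @noRd
noisy_peaks <- function(mz, intensity, ppm_sd, cv, label) {
  mz2 <- mz * (1 + stats::rnorm(length(mz), sd = ppm_sd) * 1e-6)
  int2 <- intensity * (1 + stats::rnorm(length(mz), sd = cv))
  int2[int2 < 0] <- 0
  ord <- order(mz2)
  peak_list(tibble::tibble(mz = mz2[ord], intensity = int2[ord]), label)
}

#' Simulate heavy/light labeling peak lists with known ground truth
#'
#' Produces three centroided peak lists: the observed heavy/light mixture
#' at the configured protected fraction, a light/light control, and a
#' heavy/heavy control. With all noise set to zero, `f = 1` makes the
#' observed list equal the light control exactly and `f = 0` the heavy
#' control. Decoy peaks never fall within 50 ppm of any expected peak.
#' Bit-reproducible for a given seed and configuration.
#'
#' @param cfg A [spectrum_config()].
#' @param total_intensity Total envelope intensity in arbitrary units
#'   (default 1e5).
#' @return A list with `observed`, `light_control`, `heavy_control`
#'   ([peak_list()]s) and `truth` (the configuration, including the true
#'   fraction).
#' @export
simulate_peak_list <- function(cfg, total_intensity = 1e5) {
  if (!inherits(cfg, "spectrum_config")) {
    abort_config("`cfg` must be a spectrum_config.")
  }
  cg <- combined_label_grid(cfg$pep, cfg$charge, cfg$max_peaks)
  f <- cfg$true_fraction_protected
  light_mz <- cg$light$peaks$mz
  heavy_mz <- cg$heavy$peaks$mz
  light_int <- cg$light$peaks$relative_intensity * total_intensity
  heavy_int <- cg$heavy$peaks$relative_intensity * total_intensity
  withr::with_seed(cfg$seed, {
    obs_mz <- c(light_mz, heavy_mz)
    obs_int <- c(f * light_int, (1 - f) * heavy_int)
    keep <- obs_int > 0
    merged <- merge_close_peaks(obs_mz[keep], obs_int[keep],
                                cfg$centroid_merge_ppm)
    observed <- noisy_peaks(merged$mz, merged$intensity,
                            cfg$ppm_jitter_sd, cfg$intensity_noise_cv,
                            "heavy/light")
    light_ctrl <- noisy_peaks(light_mz, light_int, cfg$ppm_jitter_sd,
                              cfg$intensity_noise_cv, "light/light")
    heavy_ctrl <- noisy_peaks(heavy_mz, heavy_int, cfg$ppm_jitter_sd,
                              cfg$intensity_noise_cv, "heavy/heavy")
    if (cfg$baseline_peaks > 0L) {
      expected <- sort(c(light_mz, heavy_mz))
      lo <- min(expected) - 2
      hi <- max(expected) + 2
      decoys <- numeric(0)
      while (length(decoys) < cfg$baseline_peaks) {
        cand <- stats::runif(cfg$baseline_peaks, lo, hi)
        ok <- vapply(cand, function(m) {
          all(abs(m - expected) / expected * 1e6 >= 50)
        }, logical(1))
        decoys <- c(decoys, cand[ok])
      }
      decoys <- decoys[seq_len(cfg$baseline_peaks)]
      dint <- stats::runif(cfg$baseline_peaks, 0.01, 0.2) * total_intensity
      all_mz <- c(observed$mz, decoys)
      all_int <- c(observed$intensity, dint)
      ord <- order(all_mz)
      observed <- peak_list(tibble::tibble(mz = all_mz[ord],
                                           intensity = all_int[ord]),
                            "heavy/light")
    }
    list(observed = observed, light_control = light_ctrl,
         heavy_control = heavy_ctrl, truth = cfg)
  })
}
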