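# Synthetic cohort generator.
#
# The downstream statistics assume probe-level intensities that follow the
# RMA convolution model: a normally distributed optical/background component
# plus an exponentially distributed true signal.  The generator inverts that
# model: for probe p on sample s,
#
#   I(p,s) = c_s * [ N(mu_b, sigma_b^2) + Exp(mean = theta * phi_p * a(p,s)) ]
#
# where c_s is the per-array scale, phi_p the probe affinity and
# a(p,s) = (1 - psi_s) for probes interrogating the skipped (target) exon,
# 1 otherwise.  psi_s is the per-sample exon-skipping fraction.

#' Specify a synthetic probe-level cohort
#'
#' Bundles all parameters of the probe-level simulator.  Skip fractions are
#' drawn per sample from a Beta distribution parameterised by mean and
#' concentration (`psi ~ Beta(mean * conc, (1 - mean) * conc)`); a mean of 0
#' or 1, or an infinite concentration, gives a point mass.
#'
#' The simulated chip contains one multi-probe probeset spanning the skipped
#' exon and its flanking exons (11 probes: 3 on the target exon, 7 on
#' flanking exons, 1 left unassigned, mirroring a typical splice-sensitive
#' probeset) plus `n_background_probesets` ordinary probesets that give the
#' normalization steps a realistic intensity distribution to work with.
#'
#' @param n_reference,n_case group sizes (reference = normal samples,
#'   case = leukemic samples).
#' @param skip_fraction_reference,skip_fraction_case lists with elements
#'   `mean` (in `[0, 1]`) and `concentration` (> 0, possibly `Inf`).
#' @param target_affinities multiplicative affinities for the 11 probes of
#'   the indexed probeset (order: 3 target-exon probes, 7 flanking probes,
#'   1 unassigned probe); all > 0.
#' @param background_mean,background_sd normal background parameters
#'   (intensity units; sd >= 0).
#' @param signal_scale mean of the exponential signal component for a probe
#'   of unit affinity (> 0).
#' @param affinity_sdlog log-normal sdlog of background-probe affinities.
#' @param n_background_probesets,probes_per_probeset chip layout of the
#'   background probesets.
#' @param array_scale per-array multiplicative factor; scalar or vector of
#'   length `n_reference + n_case`; all > 0.
#' @param seed integer master seed; identical specs give identical datasets.
#' @return An object of class `"cohort_spec"`.
#' @seealso [simulate_probe_intensities()], [default_cohort_spec()]
#' @export
cohort_spec <- function(n_reference,
                        n_case,
                        skip_fraction_reference = list(mean = 0, concentration = Inf),
                        skip_fraction_case = list(mean = 0.5, concentration = 30),
                        target_affinities = rep(1, 11),
                        background_mean = 100,
                        background_sd = 10,
                        signal_scale = 3000,
                        affinity_sdlog = 0.5,
                        n_background_probesets = 150,
                        probes_per_probeset = 11,
                        array_scale = 1,
                        seed = 1L) {
  check_scalar(n_reference, "n_reference", lower = 1)
  check_scalar(n_case, "n_case", lower = 1)
  for (nm in c("skip_fraction_reference", "skip_fraction_case")) {
    sf <- get(nm)
    if (!is.list(sf) || !all(c("mean", "concentration") %in% names(sf))) {
      stop(sprintf("`%s` must be list(mean=, concentration=)", nm), call. = FALSE)
    }
    check_scalar(sf$mean, paste0(nm, "$mean"), lower = 0, upper = 1)
    if (sf$concentration <= 0) {
      stop(sprintf("`%s$concentration` must be > 0", nm), call. = FALSE)
    }
  }
  if (!is.numeric(target_affinities) || length(target_affinities) != 11L ||
      any(target_affinities <= 0)) {
    stop("`target_affinities` must be 11 strictly positive values", call. = FALSE)
  }
  check_scalar(background_sd, "background_sd", lower = 0)
  check_scalar(background_mean, "background_mean")
  check_scalar(signal_scale, "signal_scale", lower = 0, strict_lower = TRUE)
  n <- as.integer(n_reference + n_case)
  if (length(array_scale) == 1L) array_scale <- rep(array_scale, n)
  if (length(array_scale) != n || any(array_scale <= 0)) {
    stop("`array_scale` must be positive, length 1 or n_reference + n_case",
         call. = FALSE)
  }
  structure(
    list(n_reference = as.integer(n_reference),
         n_case = as.integer(n_case),
         skip_fraction_reference = skip_fraction_reference,
         skip_fraction_case = skip_fraction_case,
         target_affinities = target_affinities,
         background_mean = background_mean,
         background_sd = background_sd,
         signal_scale = signal_scale,
         affinity_sdlog = affinity_sdlog,
         n_background_probesets = as.integer(n_background_probesets),
         probes_per_probeset = as.integer(probes_per_probeset),
         array_scale = array_scale,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Calibrated default cohort
#'
#' Preset whose group sizes and index calibration follow the published
#' pediatric cohort: 74 reference and 279 case samples, with the
#' target/flanking affinity offset chosen so the expected exon-skipping
#' index is about +0.52 in the reference group, and the case skip fraction
#' chosen so it drops to about -0.15 (a shift of `2^-0.67`).  See the
#' methods vignette for the derivation.
#'
#' @param n_reference,n_case group sizes; defaults are the published cohort.
#' @param seed integer master seed.
#' @return A `"cohort_spec"`.
#' @export
default_cohort_spec <- function(n_reference = 74, n_case = 279, seed = 1L) {
  # mean(log2 phi_target) - mean(log2 phi_flank) = 0.52  => ref index ~ 0.52
  # log2(1 - psi_case) = -0.67                           => case index ~ -0.15
  cohort_spec(
    n_reference = n_reference,
    n_case = n_case,
    skip_fraction_reference = list(mean = 0.02, concentration = 100),
    skip_fraction_case = list(mean = 1 - 2^-0.67, concentration = 30),
    target_affinities = c(rep(2^0.52, 3), rep(1, 7), 1),
    seed = seed)
}

draw_skip_fractions <- function(n, sf) {
  if (!is.finite(sf$concentration) || sf$mean %in% c(0, 1)) {
    return(rep(sf$mean, n))
  }
  rbeta(n, sf$mean * sf$concentration, (1 - sf$mean) * sf$concentration)
}

#' Simulate probe-level intensities
#'
#' Draws a probes-by-samples intensity matrix under the normal + exponential
#' convolution model, attenuating the exponential signal mean of target-exon
#' probes by `(1 - psi)` for each sample's skip fraction `psi`.  The skip
#' fraction scales only the true signal, never the background.  Each random
#' layer (affinities, skip fractions, background, signal) uses its own
#' stream derived from `spec$seed`, so identical specs give identical data.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `"probe_level_dataset"` with elements
#'   `intensities` (matrix, probes x samples, non-negative), `probe_ids`,
#'   `probeset_ids`, `sample_ids`, `group_labels` (`"reference"` /
#'   `"case"`), and `truth` (per-sample `psi`, per-probe `exon_group`
#'   in target/flanking/unassigned/background, and `affinity`).
#' @export
simulate_probe_intensities <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_reference + spec$n_case
  group <- rep(c("reference", "case"), c(spec$n_reference, spec$n_case))
  sample_ids <- sprintf("S%03d", seq_len(n))

  # chip layout: indexed probeset first, then background probesets
  idx_probes <- sprintf("PSX_probe_%02d", 1:11)
  idx_group <- c(rep("target", 3), rep("flanking", 7), "unassigned")
  bg_ids <- unlist(lapply(seq_len(spec$n_background_probesets), function(i) {
    sprintf("PS%03d_probe_%02d", i, seq_len(spec$probes_per_probeset))
  }))
  probe_ids <- c(idx_probes, bg_ids)
  probeset_ids <- c(rep("PSX", 11),
                    rep(sprintf("PS%03d", seq_len(spec$n_background_probesets)),
                        each = spec$probes_per_probeset))
  exon_group <- c(idx_group, rep("background", length(bg_ids)))
  p <- length(probe_ids)

  affin <- with_seed(derive_stream_seed(spec$seed, "affinity"), {
    c(spec$target_affinities,
      exp(rnorm(length(bg_ids), 0, spec$affinity_sdlog)))
  })
  psi <- with_seed(derive_stream_seed(spec$seed, "psi"), {
    c(draw_skip_fractions(spec$n_reference, spec$skip_fraction_reference),
      draw_skip_fractions(spec$n_case, spec$skip_fraction_case))
  })

  # attenuation matrix a(p, s): (1 - psi_s) on target-exon probes only
  atten <- matrix(1, p, n)
  atten[exon_group == "target", ] <-
    matrix(1 - psi, nrow = sum(exon_group == "target"), ncol = n, byrow = TRUE)

  bg <- with_seed(derive_stream_seed(spec$seed, "background"), {
    matrix(rnorm(p * n, spec$background_mean, spec$background_sd), p, n)
  })
  sig <- with_seed(derive_stream_seed(spec$seed, "signal"), {
    means <- spec$signal_scale * affin * atten
    matrix(rexp(p * n, rate = 1), p, n) * means
  })
  intens <- sweep(bg + sig, 2, spec$array_scale, `*`)
  intens[intens < 0] <- 0  # raw scanner intensities are non-negative

  dimnames(intens) <- list(probe_ids, sample_ids)
  structure(
    list(intensities = intens,
         probe_ids = probe_ids,
         probeset_ids = probeset_ids,
         sample_ids = sample_ids,
         group_labels = group,
         truth = list(psi = setNames(psi, sample_ids),
                      exon_group = setNames(exon_group, probe_ids),
                      affinity = setNames(affin, probe_ids))),
    class = "probe_level_dataset")
}

#' Simulate an index-level two-group cohort
#'
#' Draws per-sample exon-skipping index values directly at the index scale,
#' calibrated to published group summaries: each group is
#' `Normal(mean, (se * sqrt(n))^2)`, i.e. the printed standard errors are
#' converted back to per-sample standard deviations.
#'
#' @param n_reference,n_case group sizes (each >= 2).
#' @param mean_reference,mean_case group means (index units).
#' @param se_reference,se_case group standard errors of the mean (>= 0).
#' @param seed integer seed.
#' @return A list with numeric vectors `reference` and `case`.
#' @examples
#' simulate_index_cohort(74, 0.52, 0.07, 279, -0.15, 0.03, seed = 1)
#' @export
simulate_index_cohort <- function(n_reference, mean_reference, se_reference,
                                  n_case, mean_case, se_case, seed = 1L) {
  check_scalar(n_reference, "n_reference", lower = 2)
  check_scalar(n_case, "n_case", lower = 2)
  check_scalar(se_reference, "se_reference", lower = 0)
  check_scalar(se_case, "se_case", lower = 0)
  with_seed(as.integer(seed), {
    list(reference = rnorm(n_reference, mean_reference,
                           se_reference * sqrt(n_reference)),
         case = rnorm(n_case, mean_case, se_case * sqrt(n_case)))
  })
}

#' Simulate a duplicate-spot antibody array experiment
#'
#' Emulates a phosphoprotein antibody microarray: each antibody is printed
#' in replicate spots, with blank spots and negative-control spots on every
#' array.  True per-protein baselines are log10-normal; case samples receive
#' the supplied additive log10 `group_effects`.
#'
#' @param n_antibodies number of distinct antibodies (platform default 1318).
#' @param n_replicates_per_spot replicate spots per antibody (default 2).
#' @param group_effects per-protein log10 effect of case vs reference;
#'   scalar or length `n_antibodies`.
#' @param noise_sd log10-scale measurement noise per spot (>= 0).
#' @param n_reference,n_case numbers of arrays per group.
#' @param blank_level mean intensity of blank spots.
#' @param seed integer seed.
#' @return A list of class `"antibody_array_dataset"` with a long `spots`
#'   data frame (`antibody_id`, `spot_type`, `replicate`, `sample_id`,
#'   `group`, `intensity`), a `samples` data frame, and `truth`
#'   (`log10_effects`).
#' @export
simulate_antibody_array <- function(n_antibodies = 1318,
                                    n_replicates_per_spot = 2,
                                    group_effects = 0,
                                    noise_sd = 0.05,
                                    n_reference = 4,
                                    n_case = 4,
                                    blank_level = 50,
                                    seed = 1L) {
  check_scalar(n_antibodies, "n_antibodies", lower = 1)
  check_scalar(n_replicates_per_spot, "n_replicates_per_spot", lower = 1)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (length(group_effects) == 1L) {
    group_effects <- rep(group_effects, n_antibodies)
  }
  stopifnot(length(group_effects) == n_antibodies)

  n <- n_reference + n_case
  group <- rep(c("reference", "case"), c(n_reference, n_case))
  sample_ids <- sprintf("A%02d", seq_len(n))
  ab_ids <- sprintf("Ab%04d", seq_len(n_antibodies))

  base <- with_seed(derive_stream_seed(seed, "ab_base"), {
    rnorm(n_antibodies, 3, 0.4)  # log10 baseline intensity per protein
  })
  spots <- with_seed(derive_stream_seed(seed, "ab_spots"), {
    recs <- vector("list", n)
    for (s in seq_len(n)) {
      eff <- if (group[s] == "case") group_effects else rep(0, n_antibodies)
      mu <- rep(base + eff, each = n_replicates_per_spot)
      signal <- 10^(mu + rnorm(length(mu), 0, noise_sd))
      ab <- data.frame(
        antibody_id = rep(ab_ids, each = n_replicates_per_spot),
        spot_type = "antibody",
        replicate = rep(seq_len(n_replicates_per_spot), n_antibodies),
        sample_id = sample_ids[s],
        group = group[s],
        intensity = blank_level + signal)
      ctrl <- data.frame(
        antibody_id = c(sprintf("EMPTY%d", 1:4), sprintf("NEG%d", 1:4)),
        spot_type = rep(c("blank", "negative_control"), each = 4),
        replicate = 1L,
        sample_id = sample_ids[s],
        group = group[s],
        intensity = pmax(0, rnorm(8, blank_level, blank_level / 10)))
      recs[[s]] <- rbind(ab, ctrl)
    }
    do.call(rbind, recs)
  })
  structure(
    list(spots = spots,
         samples = data.frame(sample_id = sample_ids, group = group),
         truth = list(log10_effects = setNames(group_effects, ab_ids))),
    class = "antibody_array_dataset")
}
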