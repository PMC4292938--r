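# Antibody-array differential pipeline: spot processing, per-array median
# normalization, log10 transform, centering to control samples, Welch
# tests, fold/P filtering, and the naive expected-false-positive FDR
# estimate.

#' Process antibody-array spots into a protein x sample matrix
#'
#' Per array: (1) subtract the mean blank-spot signal from every antibody
#' spot, clipping non-positive results to a small positive floor;
#' (2) average replicate spots per antibody; (3) divide by the median over
#' all antibodies on that array; (4) log10 transform.  After step (3) the
#' per-array median of normalized values is exactly 1 (log10 median 0), so
#' any whole-array scale factor cancels.
#'
#' @param dataset an `"antibody_array_dataset"` (see
#'   [simulate_antibody_array()]) or a long data frame with columns
#'   `antibody_id`, `spot_type` (`"antibody"`/`"blank"`/others),
#'   `sample_id`, `intensity`.
#' @param floor positive floor applied after blank subtraction (intensity
#'   units; default 1).
#' @return Numeric matrix of log10 normalized values, antibodies x samples.
#' @export
process_spots <- function(dataset, floor = 1) {
  spots <- if (inherits(dataset, "antibody_array_dataset")) {
    dataset$spots
  } else {
    dataset
  }
  stopifnot(all(c("antibody_id", "spot_type", "sample_id", "intensity")
                %in% names(spots)))
  check_scalar(floor, "floor", lower = 0, strict_lower = TRUE)
  samples <- unique(spots$sample_id)
  ab_ids <- unique(spots$antibody_id[spots$spot_type == "antibody"])
  if (length(ab_ids) == 0L) {
    stop("array contains no antibody spots", call. = FALSE)
  }
  out <- matrix(NA_real_, length(ab_ids), length(samples),
                dimnames = list(ab_ids, samples))
  for (s in samples) {
    arr <- spots[spots$sample_id == s, ]
    blanks <- arr$intensity[arr$spot_type == "blank"]
    if (length(blanks) == 0L) {
      stop("no blank spots on array ", sQuote(s), call. = FALSE)
    }
    ab <- arr[arr$spot_type == "antibody", ]
    corrected <- pmax(ab$intensity - mean(blanks), floor)
    per_ab <- tapply(corrected, factor(ab$antibody_id, levels = ab_ids), mean)
    med <- median(per_ab, na.rm = TRUE)
    if (!is.finite(med) || med <= 0) {
      stop("non-positive median signal on array ", sQuote(s), call. = FALSE)
    }
    out[, s] <- log10(per_ab / med)
  }
  out
}

#' Center a log10 antibody matrix to reference samples
#'
#' Identical operation to [mean_center_to_reference()] (shared
#' implementation); provided under the antibody-array pipeline name.
#'
#' @inheritParams mean_center_to_reference
#' @return Centered matrix.
#' @export
center_to_reference <- function(x, reference_ids) {
  mean_center_to_reference(x, reference_ids)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#' When both groups have zero variance: equal means give P = 1 by
#' convention; unequal means give P = 0 flagged degenerate.
#'
#' @param group_a,group_b numeric vectors, each n >= 2.
#' @return A list with `t`, `df`, `p`, `mean_difference`, `degenerate`.
#' @export
welch_test <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("Welch test needs n >= 2 per group", call. = FALSE)
  }
  d <- mean(a) - mean(b)
  if (sd(a) == 0 && sd(b) == 0) {
    if (d == 0) {
      return(list(t = 0, df = NA_real_, p = 1, mean_difference = 0,
                  degenerate = TRUE))
    }
    return(list(t = Inf * sign(d), df = NA_real_, p = 0,
                mean_difference = d, degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value), mean_difference = d, degenerate = FALSE)
}

#' Differential testing of an antibody matrix
#'
#' Runs a Welch test per antibody between case and reference columns of a
#' centered log10 matrix and computes linear-scale fold changes
#' (`max(ratio, 1/ratio)` of the unlogged group means of normalized
#' values, signed by direction).
#'
#' @param centered log10 matrix (antibodies x samples), typically from
#'   [process_spots()] + [center_to_reference()].
#' @param case_ids,reference_ids column names of the two groups.
#' @return A data frame with one row per antibody: `antibody_id`,
#'   `log10_difference`, `fold` (>= 1), `direction` (`"up"`/`"down"`),
#'   `t`, `df`, `p`.
#' @export
differential_antibodies <- function(centered, case_ids, reference_ids) {
  x <- as.matrix(centered)
  stopifnot(all(case_ids %in% colnames(x)),
            all(reference_ids %in% colnames(x)))
  res <- lapply(rownames(x), function(ab) {
    a <- x[ab, case_ids]; b <- x[ab, reference_ids]
    w <- welch_test(a, b)
    diff <- w$mean_difference
    data.frame(antibody_id = ab,
               log10_difference = diff,
               fold = 10^abs(diff),
               direction = if (diff >= 0) "up" else "down",
               t = w$t, df = w$df, p = w$p)
  })
  do.call(rbind, res)
}

#' Filter differential results by P and fold thresholds
#'
#' An antibody passes when `p < p_threshold` and its linear fold change
#' exceeds `fold_threshold`.  Direction follows the sign of the centered
#' difference.
#'
#' @param results data frame from [differential_antibodies()].
#' @param p_threshold raw P cutoff (default 0.02).
#' @param fold_threshold linear fold cutoff (default 1.1).
#' @return The input with a logical `pass` column plus attributes; also
#'   returned component lists `up` and `down` of passing antibody ids, and
#'   the naive FDR estimate for the P filter alone, as a list:
#'   `list(results, up, down, fdr)`.
#' @export
filter_differential <- function(results, p_threshold = 0.02,
                                fold_threshold = 1.1) {
  stopifnot(all(c("antibody_id", "fold", "direction", "p") %in% names(results)))
  pass <- results$p < p_threshold & results$fold > fold_threshold
  results$pass <- pass
  k <- sum(results$p < p_threshold, na.rm = TRUE)
  fdr <- if (k >= 1) {
    estimate_fdr(nrow(results), p_threshold, k)
  } else {
    list(raw_percent = NA_real_, percent = NA_integer_,
         m = nrow(results), alpha = p_threshold, k = 0L)
  }
  list(results = results,
       up = results$antibody_id[pass & results$direction == "up"],
       down = results$antibody_id[pass & results$direction == "down"],
       fdr = fdr)
}

#' Naive false-discovery-rate estimate for a raw-P filter
#'
#' Expected false positives over observed positives:
#' `100 * (m * alpha) / k` percent, capped at 100 and reported truncated
#' to an integer percentage (the raw value is retained).
#'
#' @param m number of tests performed.
#' @param alpha raw P threshold used.
#' @param k number of tests with P below the threshold (1 <= k <= m).
#' @return A list with `percent` (integer, truncated), `raw_percent`,
#'   `m`, `alpha`, `k`.
#' @examples
#' estimate_fdr(1318, 0.02, 142)$percent  # 18
#' @export
estimate_fdr <- function(m, alpha, k) {
  check_scalar(m, "m", lower = 1)
  check_scalar(alpha, "alpha", lower = 0, upper = 1)
  check_scalar(k, "k", lower = 1)
  if (k > m) stop("`k` cannot exceed `m`", call. = FALSE)
  raw <- min(100, 100 * (m * alpha) / k)
  list(percent = as.integer(floor(raw)), raw_percent = raw,
       m = m, alpha = alpha, k = k)
}
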