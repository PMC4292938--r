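# Exon-skipping index: probe-to-exon assignment, per-sample median
# centering, the target-exon index, reference-interval incidence calling,
# and the associated group tests.

#' Parse printed probe-alignment records
#'
#' Reads lines of the form
#' `"<probe_id> aligned to chrN:<start>-<end> (Exon k)"` (as printed in
#' array annotation reports; en dashes and stray spaces are tolerated) into
#' a data frame of alignment records.  Coordinates are 1-based inclusive,
#' exactly as printed; they are treated as trusted labels and never
#' recomputed.
#'
#' @param lines character vector; empty/whitespace lines are skipped.
#' @return A data frame with columns `probe_id`, `chrom`, `start`, `end`,
#'   `exon_label`.
#' @export
parse_probe_alignments <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(probe_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      exon_label = character()))
  }
  pat <- paste0("^(\\S+)\\s+aligned\\s+to\\s+(\\S+?):\\s*",
                "(\\d+)\\s*[–-]\\s*(\\d+)\\s*\\((.+)\\)[;.]?$")
  m <- regmatches(lines, regexec(pat, lines))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed alignment line: ", sQuote(lines[which(bad)[1]]),
         call. = FALSE)
  }
  rec <- do.call(rbind, m)
  out <- data.frame(probe_id = rec[, 2],
                    chrom = rec[, 3],
                    start = as.integer(rec[, 4]),
                    end = as.integer(rec[, 5]),
                    exon_label = trimws(rec[, 6]))
  bad_span <- out$start > out$end
  if (any(bad_span)) {
    stop("alignment with start > end for probe ",
         out$probe_id[which(bad_span)[1]], call. = FALSE)
  }
  out
}

#' Assign probes to target / flanking groups
#'
#' Probes aligned to the target exon form the `target` group; all other
#' aligned probes form the `flanking` group.  Probes of the probeset that
#' appear in a dataset but not in the alignment list are later treated as
#' `unassigned`: they take part in per-sample median centering but in
#' neither group mean.
#'
#' @param alignments data frame from [parse_probe_alignments()] or an
#'   equivalent table with `probe_id` and `exon_label` columns.
#' @param target_exon exon label of the skipped exon, e.g. `"Exon 12"`.
#' @return A list of class `"exon_map"` with `groups` (named character
#'   vector, probe id -> `"target"`/`"flanking"`) and `target_exon`.
#' @export
build_exon_map <- function(alignments, target_exon) {
  stopifnot(all(c("probe_id", "exon_label") %in% names(alignments)))
  grp <- ifelse(alignments$exon_label == target_exon, "target", "flanking")
  names(grp) <- alignments$probe_id
  if (sum(grp == "target") == 0L) {
    stop("no probes aligned to target exon ", sQuote(target_exon),
         call. = FALSE)
  }
  if (sum(grp == "flanking") == 0L) {
    stop("no flanking probes; index needs both groups", call. = FALSE)
  }
  structure(list(groups = grp, target_exon = target_exon),
            class = "exon_map")
}

#' Median-center one sample's probe values
#'
#' Subtracts the median across all probes of the probeset for that sample;
#' the centered values have median exactly 0, so any per-array additive
#' (log-scale) effect is absorbed.
#'
#' @param values numeric vector (>= 2 finite values) of log2 probe values.
#' @return Centered vector of the same length and names.
#' @export
median_center_sample <- function(values) {
  if (sum(is.finite(values)) < 2L) {
    stop("median centering needs at least 2 finite probe values",
         call. = FALSE)
  }
  values - median(values, na.rm = TRUE)
}

#' Exon-skipping index for one sample
#'
#' The index is the mean of the median-centered target-exon probe values
#' minus the mean of the median-centered flanking-exon probe values.
#' Probes not present in the exon map contribute to the centering only.
#'
#' @param centered named numeric vector of median-centered probe values.
#' @param exon_map an [build_exon_map()] result.
#' @return A single index value (log2 units), or `NA` with attribute
#'   `undefined = TRUE` when all target or all flanking values are missing.
#' @export
compute_delta_index <- function(centered, exon_map) {
  stopifnot(inherits(exon_map, "exon_map"), !is.null(names(centered)))
  grp <- exon_map$groups[names(centered)]
  t_vals <- centered[which(grp == "target")]
  f_vals <- centered[which(grp == "flanking")]
  t_vals <- t_vals[is.finite(t_vals)]
  f_vals <- f_vals[is.finite(f_vals)]
  if (length(t_vals) == 0L || length(f_vals) == 0L) {
    return(structure(NA_real_, undefined = TRUE))
  }
  mean(t_vals) - mean(f_vals)
}

#' Exon-skipping index for every sample of a probe matrix
#'
#' Applies [median_center_sample()] and [compute_delta_index()] column by
#' column to the log2 probe values of one probeset.
#'
#' @param probe_log2 matrix of log2 probe values (probes x samples) with
#'   probe ids as row names.
#' @param exon_map an [build_exon_map()] result.
#' @param aggregate group aggregator for the centered values, `"mean"`
#'   (default) or `"median"`.
#' @return Named numeric vector of per-sample index values.
#' @export
exon_skip_index <- function(probe_log2, exon_map, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  probe_log2 <- as.matrix(probe_log2)
  stopifnot(!is.null(rownames(probe_log2)))
  agg <- if (aggregate == "mean") mean else median
  vapply(seq_len(ncol(probe_log2)), function(j) {
    centered <- median_center_sample(probe_log2[, j])
    grp <- exon_map$groups[names(centered)]
    t_vals <- centered[which(grp == "target")]
    f_vals <- centered[which(grp == "flanking")]
    t_vals <- t_vals[is.finite(t_vals)]
    f_vals <- f_vals[is.finite(f_vals)]
    if (length(t_vals) == 0L || length(f_vals) == 0L) return(NA_real_)
    agg(t_vals) - agg(f_vals)
  }, numeric(1), USE.NAMES = FALSE) -> idx
  setNames(idx, colnames(probe_log2))
}

#' Confidence interval for the reference-group index mean
#'
#' t-based two-sided confidence interval on the mean of the reference
#' (normal, non-leukemic) group's index values:
#' `mean +/- t_{(1+level)/2, n-1} * SE`.
#'
#' @param reference numeric vector of reference index values (n >= 2).
#' @param level confidence level, default 0.95.
#' @return A list with `lower`, `upper`, `mean`, `se`, `n`, `level`.
#' @export
reference_interval <- function(reference, level = 0.95) {
  x <- reference[is.finite(reference)]
  n <- length(x)
  if (n < 2L) stop("reference interval needs n >= 2", call. = FALSE)
  check_scalar(level, "level", lower = 0, upper = 1, strict_lower = TRUE)
  m <- mean(x)
  se <- sd(x) / sqrt(n)
  if (se == 0) {
    warning("zero variance in reference group; degenerate interval")
    return(list(lower = m, upper = m, mean = m, se = 0, n = n, level = level))
  }
  tq <- qt((1 + level) / 2, df = n - 1)
  list(lower = m - tq * se, upper = m + tq * se,
       mean = m, se = se, n = n, level = level)
}

#' Classify cases against the reference interval
#'
#' A case is called positive when its index is strictly below the lower
#' bound of the reference interval.  Incidence is the positive fraction,
#' with an exact (Clopper-Pearson) binomial 95% interval.  Samples with an
#' undefined (missing) index are excluded from the denominator.
#'
#' @param case numeric vector of case index values.
#' @param interval a [reference_interval()] result.
#' @return A list of class `"index_result"` with `below_lower` (logical per
#'   case), `n_below`, `n_cases`, `incidence` (proportion),
#'   `incidence_ci` (exact 95% interval), and the `interval` used.
#' @export
call_incidence <- function(case, interval) {
  stopifnot(is.list(interval), !is.null(interval$lower))
  ok <- is.finite(case)
  if (sum(ok) == 0L) stop("no cases with a defined index", call. = FALSE)
  below <- case < interval$lower
  k <- sum(below[ok])
  n <- sum(ok)
  bt <- stats::binom.test(k, n)
  structure(
    list(below_lower = below,
         n_below = k,
         n_cases = n,
         incidence = k / n,
         incidence_ci = as.numeric(bt$conf.int),
         interval = interval),
    class = "index_result")
}

#' One-way ANOVA across index groups
#'
#' Classical fixed-effects one-way analysis of variance (equal-variance
#' F test) across two or more groups of index values.
#'
#' @param groups named list of numeric vectors, each with n >= 2.
#' @return A list with `f`, `df1`, `df2`, `p`, and `degenerate` (TRUE when
#'   the within-group variance is zero and F is undefined).
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  lens <- lengths(groups)
  if (any(lens < 2L)) stop("each group needs n >= 2", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lens))
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  sse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (sse == 0) {
    means <- tapply(y, g, mean)
    if (max(means) == min(means)) {
      return(list(f = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
                  degenerate = TRUE))
    }
    return(list(f = Inf, df1 = df1, df2 = df2, p = 0, degenerate = TRUE))
  }
  ow <- oneway.test(y ~ g, var.equal = TRUE)
  list(f = unname(ow$statistic), df1 = df1, df2 = df2,
       p = unname(ow$p.value), degenerate = FALSE)
}

#' Dunnett many-to-one post hoc comparisons (Monte Carlo)
#'
#' Compares every group against a designated control with family-wise
#' error control via the max-|t| null distribution.  The null distribution
#' is sampled by seeded Monte Carlo: group means are drawn as independent
#' normals scaled by their group sizes and the pooled SD as a scaled
#' chi-square draw, which reproduces the equicorrelated multivariate-t
#' structure of the balanced and unbalanced Dunnett statistics exactly.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param control_index position of the control group in `groups`.
#' @param n_mc number of Monte-Carlo draws; at least 1000 (precision guard).
#' @param seed integer seed for the Monte-Carlo stream.
#' @return A data frame with one row per non-control group: `comparison`,
#'   `estimate` (mean difference vs control), `t`, `p_adjusted`, `mc_se`
#'   (Monte-Carlo standard error of the adjusted P).
#' @export
dunnett_posthoc <- function(groups, control_index = 1L, n_mc = 1e5, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (n_mc < 1000) {
    stop("n_mc < 1000 gives unusably imprecise adjusted P-values",
         call. = FALSE)
  }
  lens <- lengths(groups)
  if (any(lens < 2L)) stop("each group needs n >= 2", call. = FALSE)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  ctl <- as.integer(control_index)
  stopifnot(ctl >= 1L, ctl <= k)

  y <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lens)
  means <- tapply(y, g, mean)
  df <- length(y) - k
  s2 <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df
  others <- setdiff(seq_len(k), ctl)
  sed <- sqrt(s2 * (1 / lens[others] + 1 / lens[ctl]))
  est <- means[others] - means[ctl]

  if (s2 == 0) {
    # all observations constant within groups
    p_adj <- ifelse(est == 0, 1, 0)
    return(data.frame(comparison = paste(names(groups)[others], "-",
                                         names(groups)[ctl]),
                      estimate = as.numeric(est),
                      t = ifelse(est == 0, 0, Inf * sign(est)),
                      p_adjusted = p_adj,
                      mc_se = 0))
  }
  tobs <- est / sed

  maxT <- with_seed(as.integer(seed), {
    z <- matrix(rnorm(n_mc * k), n_mc, k)
    m <- sweep(z, 2, sqrt(lens), `/`)
    s_null <- sqrt(rchisq(n_mc, df) / df)
    tstar <- (m[, others, drop = FALSE] - m[, ctl]) /
      outer(s_null, sqrt(1 / lens[others] + 1 / lens[ctl]))
    apply(abs(tstar), 1, max)
  })
  p_adj <- vapply(abs(tobs), function(tt) mean(maxT >= tt), numeric(1))
  data.frame(comparison = paste(names(groups)[others], "-",
                                names(groups)[ctl]),
             estimate = as.numeric(est),
             t = as.numeric(tobs),
             p_adjusted = as.numeric(p_adj),
             mc_se = sqrt(p_adj * (1 - p_adj) / n_mc))
}
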