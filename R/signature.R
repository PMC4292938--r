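# Cross-cohort signature scoring: centering to a reference cohort,
# a random-intercept two-factor mixed-model ANOVA fitted by profiled REML,
# per-probeset linear contrasts, and index--expression correlation tests.

#' Mean-center every feature to a reference sample set
#'
#' Subtracts, per feature (row), the mean over the reference samples, so the
#' reference group has mean 0 for every feature.  Used both for log2
#' expression matrices (centered to normal cells) and log10 antibody-array
#' matrices (centered to wild-type samples).
#'
#' @param x numeric matrix, features x samples, with sample ids as column
#'   names.
#' @param reference_ids column names of the reference samples (non-empty).
#' @return Centered matrix of the same shape.
#' @export
mean_center_to_reference <- function(x, reference_ids) {
  x <- as.matrix(x)
  ref <- intersect(reference_ids, colnames(x))
  if (length(ref) == 0L) {
    stop("no reference samples found among the matrix columns", call. = FALSE)
  }
  ref_means <- rowMeans(x[, ref, drop = FALSE], na.rm = TRUE)
  sweep(x, 1, ref_means, `-`)
}

# REML deviance of the random-intercept model, profiled over the fixed
# effects and the residual variance, as a function of the variance ratio
# lambda = sigma^2_random / sigma^2_resid.  Uses the balanced-within-sample
# block structure: V* = I + lambda Z Z' has per-sample blocks whose inverse
# is I - w J with w = lambda / (1 + lambda p), so all GLS cross-products
# reduce to ordinary cross-products minus weighted per-sample sums.
reml_profile <- function(lambda, pre) {
  w <- lambda / (1 + lambda * pre$p)
  A <- pre$XtX - w * crossprod(pre$Sx)
  b <- pre$Xty - w * crossprod(pre$Sx, pre$Sy)
  yy <- pre$yty - w * sum(pre$Sy^2)
  ch <- chol(A)
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  rss <- max(yy - sum(b * beta), .Machine$double.eps)
  sigma2 <- rss / (pre$N - pre$q)
  dev <- (pre$N - pre$q) * log(sigma2) +
    pre$n_samples * log(1 + lambda * pre$p) +
    2 * sum(log(diag(ch)))
  list(deviance = dev, beta = beta, sigma2 = sigma2, A = A)
}

#' Fit the two-factor random-intercept signature model
#'
#' Fits `value ~ probeset * group + (1 | sample)` by REML for the exact
#' design used in cross-cohort signature scoring: two crossed fixed factors
#' (probeset and diagnostic group), their interaction, and a random
#' intercept per sample.  Every sample must be measured on every probeset
#' (balanced within sample), which lets the REML criterion be profiled down
#' to a one-dimensional optimization over the variance ratio
#' `lambda = sigma^2_sample / sigma^2_resid`.
#'
#' The group-effect F statistic is the whole-plot test: a one-way ANOVA of
#' the per-sample means across groups, on (groups - 1, samples - groups)
#' degrees of freedom.
#'
#' @param data data frame with columns `value`, `probeset`, `group`,
#'   `sample_id` (long format).
#' @return A list of class `"signature_mixed_fit"` with `lambda`,
#'   `sigma2_random`, `sigma2_resid`, `beta` (fixed effects, treatment
#'   coding), `ls_means` (data frame: probeset, group, estimate, se),
#'   `group_f` (list `f`, `df1`, `df2`, `p`), and `converged`.
#' @export
fit_signature_mixed_model <- function(data) {
  stopifnot(all(c("value", "probeset", "group", "sample_id") %in% names(data)))
  data$probeset <- factor(data$probeset)
  data$group <- factor(data$group)
  data$sample_id <- factor(data$sample_id)
  p <- nlevels(data$probeset)
  g <- nlevels(data$group)
  if (p < 2L || g < 2L) {
    stop("need >= 2 probesets and >= 2 groups", call. = FALSE)
  }
  tab <- table(data$sample_id, data$probeset)
  if (any(tab != 1L)) {
    stop("design must be balanced within sample: every sample measured ",
         "exactly once on every probeset", call. = FALSE)
  }
  samp_group <- tapply(as.character(data$group), data$sample_id,
                       function(v) unique(v))
  if (any(lengths(samp_group) != 1L)) {
    stop("each sample must belong to exactly one group", call. = FALSE)
  }

  X <- stats::model.matrix(~ probeset * group, data)
  y <- data$value
  pre <- list(
    XtX = crossprod(X),
    Xty = crossprod(X, y),
    yty = sum(y^2),
    Sx = rowsum(X, data$sample_id),
    Sy = as.numeric(rowsum(y, data$sample_id)),
    p = p, N = length(y), q = ncol(X),
    n_samples = nlevels(data$sample_id))

  opt <- optimize(function(ll) reml_profile(exp(ll), pre)$deviance,
                  interval = c(log(1e-10), log(1e6)), tol = 1e-8)
  lambda <- exp(opt$minimum)
  # snap to the boundary when the optimum sits at effectively zero ratio
  if (reml_profile(1e-12, pre)$deviance <= opt$objective + 1e-8) {
    lambda <- 0
  }
  fit <- reml_profile(lambda, pre)

  # LS-means: fitted cell means for every probeset x group combination
  grid <- expand.grid(probeset = levels(data$probeset),
                      group = levels(data$group))
  L <- stats::model.matrix(~ probeset * group, grid)
  Ainv <- chol2inv(chol(fit$A))
  est <- as.numeric(L %*% fit$beta)
  se <- sqrt(fit$sigma2 * rowSums((L %*% Ainv) * L))
  ls_means <- data.frame(probeset = grid$probeset, group = grid$group,
                         estimate = est, se = se)

  samp_means <- tapply(y, data$sample_id, mean)
  f_groups <- split(as.numeric(samp_means),
                    unlist(samp_group)[names(samp_means)])
  group_f <- one_way_anova(f_groups)

  structure(
    list(lambda = lambda,
         sigma2_resid = fit$sigma2,
         sigma2_random = lambda * fit$sigma2,
         beta = setNames(as.numeric(fit$beta), colnames(X)),
         vcov_beta = fit$sigma2 * chol2inv(chol(fit$A)),
         ls_means = ls_means,
         group_f = group_f,
         n_samples = pre$n_samples,
         n_probesets = p,
         groups = levels(data$group),
         converged = is.finite(opt$objective)),
    class = "signature_mixed_fit")
}

#' Per-probeset linear contrast between two groups
#'
#' Difference of LS-means for one probeset between two diagnostic groups,
#' reported as a linear-scale fold difference (`2^diff` for log2 data)
#' with a two-sided contrast P-value.  The t reference distribution uses
#' the between-sample degrees of freedom (samples - groups), the standard
#' choice for a whole-plot contrast in this design.
#'
#' @param fit a [fit_signature_mixed_model()] result.
#' @param probeset probeset identifier.
#' @param groups length-2 character vector, `c(numerator, denominator)`;
#'   defaults to the fit's two groups in order.
#' @return A list with `log2_difference`, `fold` (linear scale), `se`,
#'   `t`, `df`, `p`, `degenerate`.
#' @export
per_probeset_contrast <- function(fit, probeset, groups = NULL) {
  stopifnot(inherits(fit, "signature_mixed_fit"))
  if (is.null(groups)) groups <- rev(fit$groups[1:2])
  lm_tab <- fit$ls_means
  i1 <- which(lm_tab$probeset == probeset & lm_tab$group == groups[1])
  i2 <- which(lm_tab$probeset == probeset & lm_tab$group == groups[2])
  if (length(i1) != 1L || length(i2) != 1L) {
    stop("probeset/group combination not found in fit", call. = FALSE)
  }
  diff <- lm_tab$estimate[i1] - lm_tab$estimate[i2]
  # var of the cell-mean difference from the fixed-effect covariance
  gridL <- expand.grid(probeset = unique(lm_tab$probeset),
                       group = unique(lm_tab$group))
  Lfull <- stats::model.matrix(~ probeset * group, gridL)
  lvec <- Lfull[which(gridL$probeset == probeset & gridL$group == groups[1]), ] -
    Lfull[which(gridL$probeset == probeset & gridL$group == groups[2]), ]
  v <- as.numeric(t(lvec) %*% fit$vcov_beta %*% lvec)
  df <- fit$n_samples - length(fit$groups)
  if (v <= 0) {
    return(list(log2_difference = diff, fold = 2^diff, se = 0,
                t = NA_real_, df = df, p = NA_real_, degenerate = TRUE))
  }
  tt <- diff / sqrt(v)
  list(log2_difference = diff, fold = 2^diff, se = sqrt(v),
       t = tt, df = df, p = 2 * pt(-abs(tt), df), degenerate = FALSE)
}

#' Correlation between the exon-skipping index and expression
#'
#' Pearson correlation with the classical regression-ANOVA test:
#' `F = r^2 (n - 2) / (1 - r^2)` on (1, n - 2) degrees of freedom.
#'
#' @param index numeric vector of per-sample index values.
#' @param expression numeric vector of the same length (n >= 3).
#' @return A list with `r`, `f`, `df1`, `df2`, `p`, `n`, `degenerate`.
#' @export
index_expression_correlation <- function(index, expression) {
  ok <- is.finite(index) & is.finite(expression)
  x <- index[ok]; y <- expression[ok]
  n <- length(x)
  if (n < 3L) stop("correlation needs n >= 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, f = NA_real_, df1 = 1L, df2 = n - 2L,
                p = NA_real_, n = n, degenerate = TRUE))
  }
  r <- cor(x, y)
  f <- r^2 * (n - 2) / (1 - r^2)
  list(r = r, f = f, df1 = 1L, df2 = n - 2L,
       p = stats::pf(f, 1, n - 2, lower.tail = FALSE), n = n,
       degenerate = FALSE)
}

#' Map a signature across species through an ortholog table
#'
#' Expands each source-species signature gene to the probesets of its
#' orthologs on the target platform, using a supplied mapping table.
#'
#' @param signature_genes character vector of source gene symbols.
#' @param ortholog_map data frame with columns `source_gene` and
#'   `target_probeset`.
#' @return A list of class `"signature_set"` with `probesets` (unique,
#'   in first-appearance order) and `unmapped` (genes with no map rows).
#' @export
map_signature_across_species <- function(signature_genes, ortholog_map) {
  stopifnot(all(c("source_gene", "target_probeset") %in% names(ortholog_map)))
  if (length(signature_genes) == 0L) {
    stop("empty signature", call. = FALSE)
  }
  rows <- ortholog_map[ortholog_map$source_gene %in% signature_genes, ]
  unmapped <- setdiff(signature_genes, rows$source_gene)
  if (nrow(rows) == 0L) {
    warning("no signature gene could be mapped to the target platform")
  }
  structure(list(probesets = unique(rows$target_probeset),
                 unmapped = unmapped),
            class = "signature_set")
}
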