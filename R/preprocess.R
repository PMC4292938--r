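# Probe-level normalization stack: norm-exp background correction,
# quantile normalization toward the averaged order-statistic target,
# log2 transform, and median-polish summarization to probeset level.

#' Fit the normal + exponential convolution to one array
#'
#' Models observed intensities as X = B + S with background
#' B ~ Normal(mu, sigma^2) and true signal S ~ Exp(mean = alpha), and
#' estimates (mu, sigma, alpha) by maximum likelihood (bounded numerical
#' optimization from moment-based starting values, as provided by limma).
#'
#' @param column numeric vector of raw intensities for one array
#'   (at least 10 finite values, not all equal).
#' @return A list of class `"normexp_params"` with `mu`, `sigma`, `alpha`.
#' @export
normexp_fit <- function(column) {
  x <- column[is.finite(column)]
  if (length(x) < 10L) {
    stop("normexp_fit needs at least 10 finite intensities", call. = FALSE)
  }
  if (sd(x) == 0) {
    stop("normexp_fit: degenerate input (constant column); ",
         "cannot separate background from signal", call. = FALSE)
  }
  fit <- limma::normexp.fit(x, method = "mle")
  structure(list(mu = fit$par[1],
                 sigma = exp(fit$par[2]),
                 alpha = exp(fit$par[3])),
            class = "normexp_params")
}

#' Background-correct one array under fitted norm-exp parameters
#'
#' Replaces each observed intensity x by the posterior mean E[S | X = x]
#' of the exponential signal given the normal + exponential convolution.
#' The output is strictly positive and order-preserving in x.
#'
#' @param column numeric intensities.
#' @param params a `"normexp_params"` fit (see [normexp_fit()]).
#' @return Corrected intensities, same length as `column`.
#' @export
normexp_correct <- function(column, params) {
  stopifnot(inherits(params, "normexp_params"))
  par <- c(params$mu, log(params$sigma), log(params$alpha))
  limma::normexp.signal(par, column)
}

#' Quantile-normalize the columns of an intensity matrix
#'
#' Two-pass procedure: the target distribution is the mean of the ordered
#' values across arrays, then every array is mapped onto that target.
#' Within-column rank order is preserved and ties receive the average of
#' the target values across their rank span.  A single-column matrix is
#' returned unchanged.  Missing values are left missing and excluded from
#' the target.
#'
#' @param x numeric matrix (features x samples).
#' @return Matrix of the same shape; every column has the same multiset of
#'   values (up to missingness).
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) <= 1L) return(x)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Summarize one probeset by median polish
#'
#' Fits the log-additive model value ~ overall + probe + sample by
#' iteratively sweeping medians out of rows (probes) and columns (samples),
#' and returns the per-sample summary `overall + sample_effect`.
#'
#' @param x numeric matrix of log2 probe intensities for a single probeset
#'   (probes x samples).
#' @param maxiter maximum number of polish iterations.
#' @param eps convergence tolerance on the change in absolute residual sum.
#' @return A list with `summary` (per-sample values), `overall`,
#'   `probe_effects`, `sample_effects`, `residuals`, and `converged`.
#' @export
median_polish_summarize <- function(x, maxiter = 20L, eps = 1e-6) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 1L, ncol(x) >= 1L)
  if (nrow(x) == 1L) {
    # single probe: the summary is that probe's values
    smry <- drop(x)
    return(list(summary = setNames(as.numeric(smry), colnames(x)),
                overall = median(x, na.rm = TRUE),
                probe_effects = 0,
                sample_effects = as.numeric(smry) - median(x, na.rm = TRUE),
                residuals = x * 0,
                converged = TRUE))
  }
  mp <- suppressWarnings(
    medpolish(x, maxiter = maxiter, eps = eps * length(x),
              trace.iter = FALSE, na.rm = TRUE))
  resid_med <- max(abs(apply(mp$residuals, 1, median, na.rm = TRUE)),
                   abs(apply(mp$residuals, 2, median, na.rm = TRUE)))
  converged <- resid_med <= 1e-6 * max(1, max(abs(x), na.rm = TRUE))
  if (!converged) {
    warning("median polish did not fully converge; returning last iterate")
  }
  list(summary = setNames(mp$overall + mp$col, colnames(x)),
       overall = mp$overall,
       probe_effects = mp$row,
       sample_effects = mp$col,
       residuals = mp$residuals,
       converged = converged)
}

#' Full probe-level preprocessing stack
#'
#' Applies, in order: per-array norm-exp background correction, quantile
#' normalization toward the averaged order-statistic target, and log2
#' transformation.  Optionally also summarizes each probeset by median
#' polish.  Probe-level (unsummarized) values are always returned because
#' the exon-skipping index is computed from individual probes.
#'
#' @param intensities raw matrix, probes x samples (non-negative).
#' @param probeset_ids per-probe probeset membership (only needed when
#'   `summarize = TRUE`).
#' @param summarize also return probeset-level summaries?
#' @return A list with `probe_log2` (probes x samples, log2 scale),
#'   `normexp_params` (per-array fits), and, if requested, `probeset_log2`.
#' @export
rma_preprocess <- function(intensities, probeset_ids = NULL,
                           summarize = FALSE) {
  x <- as.matrix(intensities)
  fits <- vector("list", ncol(x))
  corrected <- x
  for (j in seq_len(ncol(x))) {
    fits[[j]] <- normexp_fit(x[, j])
    corrected[, j] <- normexp_correct(x[, j], fits[[j]])
  }
  qn <- quantile_normalize(corrected)
  probe_log2 <- log2(qn)
  out <- list(probe_log2 = probe_log2,
              normexp_params = setNames(fits, colnames(x)))
  if (summarize) {
    stopifnot(!is.null(probeset_ids), length(probeset_ids) == nrow(x))
    sets <- split(seq_len(nrow(x)), probeset_ids)
    ps <- t(vapply(sets, function(idx) {
      median_polish_summarize(probe_log2[idx, , drop = FALSE])$summary
    }, numeric(ncol(x))))
    colnames(ps) <- colnames(x)
    out$probeset_log2 <- ps
  }
  out
}
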