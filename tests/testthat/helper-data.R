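# Balanced long-format signature dataset: probeset + group fixed effects,
# a random intercept per sample, and iid residual noise.
make_signature_data <- function(n_per_group, p, sigma_b, sigma_e,
                                group_shift = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    dat <- expand.grid(sample_id = sprintf("s%03d", seq_len(n)),
                       probeset = sprintf("ps%02d", seq_len(p)),
                       KEEP.OUT.ATTRS = FALSE)
    gi <- rep(c("ref", "case"), each = n_per_group)
    dat$group <- gi[as.integer(factor(dat$sample_id))]
    b <- rnorm(n, 0, sigma_b)
    dat$value <- 0.3 * as.integer(factor(dat$probeset)) +
      group_shift * (dat$group == "case") +
      b[as.integer(factor(dat$sample_id))] +
      rnorm(nrow(dat), 0, sigma_e)
    dat
  })
}
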