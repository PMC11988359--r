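## Shared fixtures and independent oracles, all built in code.

the_protocol <- breast_protocol()
the_index <- impulsed:::protocol_index(the_protocol)

seq25 <- the_protocol$sequences$ogse25
seq50 <- the_protocol$sequences$ogse50
seqp <- the_protocol$sequences$pgse

## Noiseless forward signal table, optionally with Rician noise applied the
## way the phantom applies it.
signal_table <- function(d, v_in, d_ex, snr = Inf, d_in = 1.56) {
  tab <- forward_signal_table(microstructure_params(d, v_in, d_ex, d_in),
                              the_protocol)
  names(tab)[names(tab) == "signal"] <- "signal"
  if (is.finite(snr)) {
    sd <- 1 / (snr * sqrt(tab$nsa))
    tab$signal <- sqrt((tab$signal + rnorm(nrow(tab), 0, sd))^2 +
                         rnorm(nrow(tab), 0, sd)^2)
  }
  tab
}

## Empirical AUC by exhaustive pair counting (Mann-Whitney), oriented for
## the given positive class: independent of pROC.
auc_pair_count <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## Two-way ANOVA mean squares computed via aov(), used as the independent
## oracle for the hand-rolled ICC estimator.
icc_a1_from_aov <- function(x, y) {
  n <- length(x)
  dat <- data.frame(value = c(x, y),
                    subject = factor(rep(seq_len(n), 2)),
                    rater = factor(rep(1:2, each = n)))
  tab <- summary(aov(value ~ subject + rater, data = dat))[[1]]
  ms_r <- tab["subject", "Mean Sq"]
  ms_c <- tab["rater", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  k <- 2
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
}
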