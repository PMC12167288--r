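# Independent oracles used to cross-check the implementation.

# AUC by explicit pair counting, ties scored 1/2.
auc_pair_oracle <- function(pos, neg) {
  total <- 0
  for (x in pos) {
    total <- total + sum(x > neg) + 0.5 * sum(x == neg)
  }
  total / (length(pos) * length(neg))
}

# Two-sided Fisher p by full hypergeometric enumeration over the support,
# summing probabilities <= observed (relative tolerance 1e-7).
fisher_enum_oracle <- function(tp, fp, fn, tn) {
  row1 <- tp + fp
  row2 <- fn + tn
  col1 <- tp + fn
  if (row1 == 0 || row2 == 0 || col1 == 0 || (fp + tn) == 0) {
    return(1)
  }
  support <- max(0, col1 - row2):min(row1, col1)
  pr <- stats::dhyper(support, row1, row2, col1)
  p_obs <- stats::dhyper(tp, row1, row2, col1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Minimal valid cohort rows for rule-level tests.
make_cohort <- function(b_type, depth, suv_max = NA_real_, ...) {
  validate_cohort(tibble::tibble(
    lesion_id = sprintf("L%03d", seq_along(b_type)),
    b_type = b_type, depth = depth, suv_max = suv_max, ...
  ))
}

# Random small cohort with independent fields (structure-free).
random_cohort <- function(n) {
  make_cohort(
    b_type = sample(c("B1", "B2", "B3"), n, replace = TRUE),
    depth = sample(c("EP", "LPM", "MM", "SM1", "SM2", "SM3"), n,
                   replace = TRUE),
    suv_max = round(stats::rexp(n, 1 / 2.5), 1)
  )
}
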