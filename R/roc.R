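check_score_groups <- function(scores_pos, scores_neg) {
  scores_pos <- as.numeric(scores_pos)
  scores_neg <- as.numeric(scores_neg)
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  if (!length(scores_pos) || !length(scores_neg)) {
    abort("both score groups must contain at least one non-missing value")
  }
  list(pos = scores_pos, neg = scores_neg)
}

# Mann-Whitney AUC with ties counted 1/2, via mid-ranks (O(n log n)).
auc_rank <- function(pos, neg) {
  m <- length(pos)
  n <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# DeLong placement values and variance of the AUC estimate.
delong_var <- function(pos, neg) {
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n        # per-positive placements
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m # per-negative placements
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  s10 / m + s01 / n
}

auc_boot_ci <- function(pos, neg, conf.level, n_boot = 2000, seed = 20240) {
  with_local_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      auc_rank(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    }, numeric(1))
    alpha <- 1 - conf.level
    unname(quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 6))
  })
}

#' Concordance (c-statistic / AUC) of a continuous score
#'
#' The probability that a randomly chosen positive-class score exceeds a
#' randomly chosen negative-class score, ties counted 1/2 — equal to the
#' area under the empirical ROC curve. The confidence interval uses the
#' DeLong analytic variance; when that variance degenerates to zero (e.g.
#' perfect separation) a seeded bootstrap percentile interval (2000
#' resamples) is used instead.
#'
#' @param scores_pos Scores of the positive class (e.g. SUVmax of deep
#'   lesions); `NA` dropped.
#' @param scores_neg Scores of the negative class; `NA` dropped.
#' @param conf.level Confidence level, default 0.95.
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`, `n_pos`,
#'   `n_neg`, `ci_method`.
#' @examples
#' c_statistic(c(0, 3.2, 5), c(0, 0, 2.5)) # 7/9
#' @export
c_statistic <- function(scores_pos, scores_neg, conf.level = 0.95) {
  g <- check_score_groups(scores_pos, scores_neg)
  auc <- auc_rank(g$pos, g$neg)
  v <- delong_var(g$pos, g$neg)
  if (v > 0) {
    z <- qnorm(1 - (1 - conf.level) / 2)
    ci <- c(auc - z * sqrt(v), auc + z * sqrt(v))
    method <- "delong"
  } else {
    ci <- auc_boot_ci(g$pos, g$neg, conf.level)
    method <- "bootstrap"
  }
  ci <- pmin(pmax(ci, 0), 1)
  tibble(
    estimate = auc, conf.low = min(ci[1], auc), conf.high = max(ci[2], auc),
    n_pos = length(g$pos), n_neg = length(g$neg), ci_method = method
  )
}

#' Empirical ROC curve for a continuous score
#'
#' Operating points at every unique observed score (positivity convention:
#' `score >= threshold` is test-positive) plus `-Inf`/`Inf` sentinel ends,
#' with the c-statistic and its confidence interval.
#'
#' @inheritParams c_statistic
#' @return An object of class `roc_curve`: list with `points` (tibble of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `auc_ci`,
#'   `ci_method`, `n_pos`, `n_neg`.
#' @examples
#' roc_points(c(3, 4), c(1, 2))
#' @export
roc_points <- function(scores_pos, scores_neg, conf.level = 0.95) {
  g <- check_score_groups(scores_pos, scores_neg)
  thr <- c(-Inf, sort(unique(c(g$pos, g$neg))), Inf)
  sens <- vapply(thr, function(t) mean(g$pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(g$neg < t), numeric(1))
  cs <- c_statistic(g$pos, g$neg, conf.level)
  structure(
    list(
      points = tibble(threshold = thr, sensitivity = sens,
                      specificity = spec),
      auc = cs$estimate,
      auc_ci = c(cs$conf.low, cs$conf.high),
      ci_method = cs$ci_method,
      conf.level = conf.level,
      n_pos = cs$n_pos, n_neg = cs$n_neg
    ),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "ROC curve: %d positive / %d negative scores\n", x$n_pos, x$n_neg))
  cat(sprintf("c-statistic %.3f (%.0f%% CI %.3f-%.3f, %s)\n",
              x$auc, 100 * x$conf.level, x$auc_ci[1], x$auc_ci[2],
              x$ci_method))
  invisible(x)
}

#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble(auc = x$auc, conf.low = x$auc_ci[1], conf.high = x$auc_ci[2],
         ci_method = x$ci_method, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  pts <- arrange(object$points, .data$sensitivity)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("c-statistic %.2f (%.2f-%.2f)", object$auc,
                      object$auc_ci[1], object$auc_ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' Youden-index optimal cutoff
#'
#' Chooses the threshold maximising Youden's J = sensitivity + specificity
#' - 1 over the unique observed scores (so the selected cutoff is itself an
#' observed value). Ties are broken toward the lowest threshold by default,
#' favouring sensitivity.
#'
#' @inheritParams c_statistic
#' @param tie_break `"lowest"` (default) or `"highest"` threshold among
#'   J-maximising candidates.
#' @return One-row tibble: `threshold`, `youden_j`, `sensitivity`,
#'   `specificity`.
#' @examples
#' youden_cutoff(c(2.4, 3.2, 5), c(0, 1))
#' @export
youden_cutoff <- function(scores_pos, scores_neg,
                          tie_break = c("lowest", "highest")) {
  tie_break <- arg_match(tie_break)
  g <- check_score_groups(scores_pos, scores_neg)
  thr <- sort(unique(c(g$pos, g$neg)))
  sens <- vapply(thr, function(t) mean(g$pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(g$neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- if (tie_break == "lowest") best[1] else best[length(best)]
  tibble(threshold = thr[pick], youden_j = j[pick],
         sensitivity = sens[pick], specificity = spec[pick])
}

#' ROC and cutoff for SUVmax against deep invasion
#'
#' Convenience wrapper splitting a cohort's measured `suv_max` by deep
#' (SM2/SM3) versus shallower histopathological depth; lesions without a
#' measured SUVmax are dropped.
#'
#' @param data A cohort data frame with `suv_max` and `depth` columns.
#' @inheritParams c_statistic
#' @return A `roc_curve` object (see [roc_points()]).
#' @examples
#' suv_roc(generate_cohort(np_cohort_config(n = 200, seed = 7)))
#' @export
suv_roc <- function(data, conf.level = 0.95) {
  data <- as_tibble(data)
  keep <- !is.na(data$suv_max)
  deep <- is_deep(data$depth[keep])
  roc_points(data$suv_max[keep][deep], data$suv_max[keep][!deep],
             conf.level = conf.level)
}
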