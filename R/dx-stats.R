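#' Construct a 2x2 diagnostic contingency table
#'
#' Counts of a binary predictor against binary truth: `tp` (predictor and
#' truth positive), `fp`, `fn`, `tn`.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `contingency_2x2`.
#' @examples
#' contingency_2x2(tp = 44, fp = 9, fn = 9, tn = 75)
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    abort("contingency cells must be non-negative integers")
  }
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- as.matrix(x)
  cat("2x2 contingency table (n =", sum(m), ")\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
         dimnames = list(predictor = c("positive", "negative"),
                         truth = c("positive", "negative")))
}

as_contingency <- function(x) {
  if (inherits(x, "contingency_2x2")) return(x)
  if (is.matrix(x) && all(dim(x) == c(2, 2))) {
    return(contingency_2x2(tp = x[1, 1], fp = x[1, 2],
                           fn = x[2, 1], tn = x[2, 2]))
  }
  abort("expected a contingency_2x2 or a 2x2 matrix (rows = predictor, cols = truth, positive first)")
}

#' Cross-classify a cohort by predictor and truth
#'
#' Evaluates two logical expressions per lesion and tabulates them; rows
#' where either is `NA` are skipped and attached (with a reason) as the
#' `"skipped"` attribute.
#'
#' @param data A per-lesion data frame.
#' @param predictor,truth Expressions evaluated in `data` yielding logicals,
#'   e.g. `np_risk == "high"`, `is_deep(depth)`.
#' @return A `contingency_2x2` with a `"skipped"` tibble attribute.
#' @examples
#' co <- add_np_risk(generate_cohort(np_cohort_config(n = 100, seed = 3)))
#' confusion_table(co, np_risk == "high", is_deep(depth))
#' @export
confusion_table <- function(data, predictor, truth) {
  data <- as_tibble(data)
  pred <- as.logical(eval_tidy(enquo(predictor), data))
  tru <- as.logical(eval_tidy(enquo(truth), data))
  pred <- rep_len(pred, nrow(data))
  tru <- rep_len(tru, nrow(data))
  skip <- is.na(pred) | is.na(tru)
  skipped <- mutate(
    data[skip, , drop = FALSE],
    skip_reason = dplyr::case_when(
      is.na(pred[skip]) & is.na(tru[skip]) ~ "predictor and truth undefined",
      is.na(pred[skip]) ~ "predictor undefined",
      TRUE ~ "truth undefined"
    )
  )
  out <- contingency_2x2(
    tp = sum(pred & tru, na.rm = TRUE),
    fp = sum(pred & !tru, na.rm = TRUE),
    fn = sum(!pred & tru, na.rm = TRUE),
    tn = sum(!pred & !tru, na.rm = TRUE)
  )
  attr(out, "skipped") <- skipped
  out
}

#' Diagnostic performance of a 2x2 table
#'
#' Sensitivity, specificity, positive and negative predictive values and
#' accuracy, each with an exact (Clopper-Pearson) binomial confidence
#' interval. Metrics whose denominator is zero are reported as `NA`
#' (undefined). `pct` is the estimate as a percentage rounded half-up to one
#' decimal, the precision used in reports.
#'
#' @param table A `contingency_2x2` (or 2x2 matrix, predictor in rows,
#'   positives first).
#' @param conf.level Confidence level for the exact intervals, default 0.95.
#' @return A tibble with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate`, `conf.low`, `conf.high`, `pct`.
#' @examples
#' dx_metrics(contingency_2x2(44, 9, 9, 75))
#' @export
dx_metrics <- function(table, conf.level = 0.95) {
  x <- as_contingency(table)
  defs <- list(
    sensitivity = c(x$tp, x$tp + x$fn),
    specificity = c(x$tn, x$tn + x$fp),
    ppv = c(x$tp, x$tp + x$fp),
    npv = c(x$tn, x$tn + x$fn),
    accuracy = c(x$tp + x$tn, x$tp + x$fp + x$fn + x$tn)
  )
  rows <- purrr::imap(defs, function(d, nm) {
    if (d[2] == 0) {
      return(tibble(metric = nm, numerator = d[1], denominator = 0,
                    estimate = NA_real_, conf.low = NA_real_,
                    conf.high = NA_real_, pct = NA_real_))
    }
    ci <- binom.test(d[1], d[2], conf.level = conf.level)$conf.int
    tibble(metric = nm, numerator = d[1], denominator = d[2],
           estimate = d[1] / d[2], conf.low = ci[1], conf.high = ci[2],
           pct = as_pct(d[1] / d[2]))
  })
  bind_rows(rows)
}

#' Tabulate JES vessel class against collapsed histopathological depth
#'
#' The 3x3 table of B-type (rows) by depth group (columns), and its per-row
#' one-vs-rest diagnostic performance: each B class as a binary predictor of
#' its corresponding depth group.
#'
#' @param data A cohort data frame with `b_type` and `depth`.
#' @return `jes_table()`: a 3x3 integer matrix. `jes_performance()`: a
#'   tibble of one-vs-rest metrics for B1/B2/B3 with a `b_type` column.
#' @examples
#' co <- generate_cohort(np_cohort_config(n = 137, seed = 11))
#' jes_table(co)
#' jes_performance(co)
#' @export
jes_table <- function(data) {
  data <- as_tibble(data)
  tab <- table(
    factor(as.character(data$b_type), b_type_levels()),
    depth_group(data$depth)
  )
  m <- matrix(as.integer(tab), nrow = 3,
              dimnames = list(b_type = b_type_levels(),
                              depth_group = depth_group_levels()))
  m
}

#' One-vs-rest diagnostic metrics from a multi-class table
#'
#' Collapses a B-type-by-depth-group count matrix to the 2x2 of
#' `row == b_class` against `column == target_group` and computes
#' [dx_metrics()]. Every lesion in the table contributes to exactly one
#' cell of the collapsed 2x2.
#'
#' @param table A 3x3 count matrix (rows `B1`,`B2`,`B3`; columns
#'   [depth_group_levels()]).
#' @param b_class Row treated as test-positive, e.g. `"B3"`.
#' @param target_group Column treated as truth-positive, e.g. `"SM2_SM3"`.
#' @inheritParams dx_metrics
#' @return A metrics tibble as in [dx_metrics()].
#' @examples
#' m <- matrix(c(49, 8, 0, 6, 19, 2, 1, 30, 22), nrow = 3,
#'             dimnames = list(c("B1", "B2", "B3"),
#'                             c("EP_LPM", "MM_SM1", "SM2_SM3")))
#' one_vs_rest_metrics(m, "B3", "SM2_SM3")
#' @export
one_vs_rest_metrics <- function(table, b_class, target_group,
                                conf.level = 0.95) {
  if (!is.matrix(table) || !all(dim(table) == c(3, 3))) {
    abort("table must be a 3x3 count matrix")
  }
  if (is.null(rownames(table))) rownames(table) <- b_type_levels()
  if (is.null(colnames(table))) colnames(table) <- depth_group_levels()
  if (!b_class %in% rownames(table)) abort("unknown b_class row")
  if (!target_group %in% colnames(table)) abort("unknown target_group column")
  pred <- rownames(table) == b_class
  tru <- colnames(table) == target_group
  dx_metrics(contingency_2x2(
    tp = sum(table[pred, tru]),
    fp = sum(table[pred, !tru]),
    fn = sum(table[!pred, tru]),
    tn = sum(table[!pred, !tru])
  ), conf.level = conf.level)
}

#' @rdname jes_table
#' @inheritParams dx_metrics
#' @export
jes_performance <- function(data, conf.level = 0.95) {
  tab <- jes_table(data)
  targets <- c(B1 = "EP_LPM", B2 = "MM_SM1", B3 = "SM2_SM3")
  bind_rows(purrr::imap(targets, function(grp, b) {
    mutate(one_vs_rest_metrics(tab, b, grp, conf.level = conf.level),
           b_type = b, target_group = grp, .before = 1)
  }))
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional exact two-sided p-value: with margins fixed, the sum of
#' hypergeometric probabilities of all tables no more probable than the
#' observed one (within relative tolerance 1e-7). A table with a zero margin
#' carries no information and returns p = 1 by convention.
#'
#' @inheritParams dx_metrics
#' @return A single two-sided p-value.
#' @examples
#' fisher_exact(contingency_2x2(3, 1, 1, 3)) # 34/70
#' @export
fisher_exact <- function(table) {
  x <- as_contingency(table)
  m <- as.matrix(x)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product odds ratio with a Wald confidence interval on the log
#' scale. When any cell is zero the Haldane-Anscombe correction (0.5 added
#' to every cell) is applied and flagged in the `corrected` column.
#'
#' @inheritParams dx_metrics
#' @return One-row tibble: `estimate` (OR), `conf.low`, `conf.high`,
#'   `p.value` (Wald), `corrected`.
#' @examples
#' odds_ratio(contingency_2x2(44, 9, 9, 75))
#' @export
odds_ratio <- function(table, conf.level = 0.95) {
  x <- as_contingency(table)
  cells <- c(x$tp, x$fp, x$fn, x$tn)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  log_or <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble(
    estimate = exp(log_or),
    conf.low = exp(log_or - z * se),
    conf.high = exp(log_or + z * se),
    p.value = 2 * pnorm(-abs(log_or / se)),
    corrected = corrected
  )
}

#' Rank-sum (Mann-Whitney U) comparison of two groups
#'
#' Two-sided comparison of a continuous variable between two groups, as used
#' to compare SUVmax between deep and shallow lesions. The U statistic uses
#' mid-ranks for ties. For small samples (`n_a + n_b <= exact_max`) the
#' p-value is computed by full enumeration of all group assignments (exact
#' even with ties); otherwise the normal approximation with tie correction
#' (no continuity correction) is used.
#'
#' @param group_a,group_b Numeric vectors, `NA` dropped; both non-empty.
#' @param exact_max Largest combined sample size for which the exact
#'   permutation distribution is enumerated; default 20.
#' @return A list with `summary` (tibble of n, median, q1, q3 per group),
#'   `u` (U for `group_a` over `group_b`), `p_value`, `method`.
#' @examples
#' rank_sum_compare(c(1, 2), c(3, 4))$p_value # 1/3
#' @export
rank_sum_compare <- function(group_a, group_b, exact_max = 20) {
  a <- as.numeric(group_a); a <- a[!is.na(a)]
  b <- as.numeric(group_b); b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled, ties.method = "average")
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (n <= exact_max) {
    idx <- combn(n, na)
    w <- colSums(matrix(r[idx], nrow = na))
    u_all <- w - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    tie_adj <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_adj)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      p <- min(1, 2 * pnorm(-abs(u_obs - mu) / sqrt(sigma2)))
    }
    method <- "normal approximation with tie correction"
  }
  five <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
  }
  list(
    summary = mutate(bind_rows(five(a), five(b)),
                     group = c("a", "b"), .before = 1),
    u = u_obs,
    p_value = p,
    method = method
  )
}
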