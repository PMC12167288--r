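#' Run the full depth-prediction analysis on a lesion cohort
#'
#' Executes the complete pipeline: eligibility filtering; JES B-type versus
#' depth-group cross-tabulation with per-class one-vs-rest performance; ROC
#' of SUVmax against deep (SM2/SM3) invasion with the c-statistic and —
#' when `suv_cutoff = "derive"` — Youden-index cutoff selection; FDG-PET
#' 2x2 at the cutoff; the combined N-P risk category with its 2x2, exact
#' test and odds ratio; and a logistic adjustment of the N-P indicator for
#' elevated morphology when morphology varies.
#'
#' Lesions without a measured SUVmax are excluded from the ROC and PET
#' blocks; B2 lesions without SUVmax are unclassifiable under the N-P rule
#' and are listed (not silently dropped) in the result.
#'
#' @param cohort A lesion cohort data frame (see [validate_cohort()]).
#' @param suv_cutoff Either `"derive"` (Youden-optimal from the cohort,
#'   requires measured SUVmax in both depth classes) or a fixed positive
#'   SUV value.
#' @param conf.level Confidence level used throughout, default 0.95.
#' @return An object of class `np_analysis`; see [tidy.np_analysis()],
#'   [glance.np_analysis()], [autoplot.np_analysis()], [write_report()].
#' @examples
#' run_full_analysis(reconstructed_cohort(), suv_cutoff = 2.4)
#' @export
run_full_analysis <- function(cohort, suv_cutoff = "derive",
                              conf.level = 0.95) {
  derive <- identical(suv_cutoff, "derive")
  if (!derive && (!is.numeric(suv_cutoff) || length(suv_cutoff) != 1 ||
                  !is.finite(suv_cutoff) || suv_cutoff <= 0)) {
    abort("suv_cutoff must be \"derive\" or a single positive SUV value")
  }
  cohort <- validate_cohort(cohort)
  elig <- apply_eligibility(cohort)
  co <- elig$kept
  if (!nrow(co)) abort("no eligible lesions")

  tab1 <- jes_table(co)
  perf1 <- jes_performance(co, conf.level = conf.level)

  with_suv <- co[!is.na(co$suv_max), , drop = FALSE]
  deep_scores <- with_suv$suv_max[is_deep(with_suv$depth)]
  shallow_scores <- with_suv$suv_max[!is_deep(with_suv$depth)]
  have_both <- length(deep_scores) > 0 && length(shallow_scores) > 0

  roc <- NULL
  cutoff_res <- NULL
  if (derive) {
    if (!have_both) {
      abort("cutoff derivation needs measured SUVmax in both depth classes")
    }
    cutoff_res <- youden_cutoff(deep_scores, shallow_scores)
    cutoff <- cutoff_res$threshold
  } else {
    cutoff <- suv_cutoff
  }
  if (have_both) {
    roc <- roc_points(deep_scores, shallow_scores, conf.level = conf.level)
  }

  pet <- NULL
  if (have_both) {
    pet_tab <- confusion_table(with_suv, .data$suv_max >= cutoff,
                               is_deep(.data$depth))
    pet <- list(
      table = pet_tab,
      metrics = dx_metrics(pet_tab, conf.level = conf.level),
      fisher_p = fisher_exact(pet_tab),
      n_unmeasured = nrow(co) - nrow(with_suv)
    )
  }

  co_np <- add_np_risk(co, suv_cutoff = cutoff)
  unclassifiable <- co_np[is.na(co_np$np_risk), , drop = FALSE]
  np_tab <- confusion_table(co_np, .data$np_risk == "high",
                            is_deep(.data$depth))
  np <- list(
    table = np_tab,
    metrics = dx_metrics(np_tab, conf.level = conf.level),
    fisher_p = fisher_exact(np_tab),
    odds_ratio = odds_ratio(np_tab, conf.level = conf.level)
  )

  logistic <- NULL
  covs <- "np_high"
  if ("elevated" %in% names(co) && !any(is.na(co$elevated)) &&
      length(unique(co$elevated)) == 2) {
    covs <- c("np_high", "elevated")
  }
  logistic <- tryCatch(
    fit_depth_logistic(co, covariates = covs, suv_cutoff = cutoff,
                       conf.level = conf.level),
    error = function(e) conditionMessage(e)
  )

  structure(
    list(
      eligibility = list(
        n_input = nrow(cohort), n_kept = nrow(co),
        n_excluded = nrow(elig$excluded),
        exclusion_reasons = as.list(table(elig$excluded$reason))
      ),
      jes = list(table = tab1, performance = perf1),
      roc = roc,
      cutoff = list(mode = if (derive) "derive" else "fixed",
                    value = cutoff, youden = cutoff_res),
      pet = pet,
      np = np,
      unclassifiable = unclassifiable,
      logistic = logistic,
      conf.level = conf.level,
      provenance = list(
        input_hash = rlang::hash(cohort),
        suv_cutoff = cutoff,
        cutoff_mode = if (derive) "derive" else "fixed",
        package = "npdepth",
        version = as.character(utils::packageVersion("npdepth"))
      )
    ),
    class = "np_analysis"
  )
}

#' @export
print.np_analysis <- function(x, ...) {
  cat("Combined NBI-ME + FDG-PET depth-prediction analysis\n")
  cat(sprintf("  lesions: %d eligible of %d (%d excluded)\n",
              x$eligibility$n_kept, x$eligibility$n_input,
              x$eligibility$n_excluded))
  cat(sprintf("  SUV cutoff: %.3g (%s)\n", x$cutoff$value, x$cutoff$mode))
  if (!is.null(x$roc)) {
    cat(sprintf("  c-statistic: %.3f (%.3f-%.3f)\n", x$roc$auc,
                x$roc$auc_ci[1], x$roc$auc_ci[2]))
  }
  m <- x$np$metrics
  cat(sprintf(
    "  N-P high-risk: sens %.1f%%, spec %.1f%%, accuracy %.1f%% (Fisher p %s)\n",
    m$pct[m$metric == "sensitivity"], m$pct[m$metric == "specificity"],
    m$pct[m$metric == "accuracy"], format.pval(x$np$fisher_p, digits = 3)))
  if (nrow(x$unclassifiable)) {
    cat(sprintf("  unclassifiable (B2 without SUVmax): %d lesion(s)\n",
                nrow(x$unclassifiable)))
  }
  invisible(x)
}

#' Tidy the headline diagnostic-performance table of an analysis
#'
#' One row per method and metric, mirroring the layout of a diagnostic
#' performance summary table: type B3 alone, SUVmax at the cutoff, and the
#' combined N-P high-risk category, each against deep (SM2/SM3) invasion.
#'
#' @param x An `np_analysis`.
#' @param ... Unused.
#' @return A tibble with columns `method`, `metric`, `numerator`,
#'   `denominator`, `estimate`, `conf.low`, `conf.high`, `pct`.
#' @method tidy np_analysis
#' @export
tidy.np_analysis <- function(x, ...) {
  b3 <- filter(x$jes$performance, .data$b_type == "B3")
  b3 <- select(b3, -"b_type", -"target_group")
  blocks <- list(b3_jes = b3)
  if (!is.null(x$pet)) {
    blocks$suv_cutoff <- x$pet$metrics
  }
  blocks$np_high_risk <- x$np$metrics
  bind_rows(purrr::imap(blocks, ~ mutate(.x, method = .y, .before = 1)))
}

#' One-row summary of an analysis
#'
#' @param x An `np_analysis`.
#' @param ... Unused.
#' @return A one-row tibble: cohort sizes, prevalence of deep invasion,
#'   cutoff, c-statistic, N-P accuracy and Fisher p-value.
#' @method glance np_analysis
#' @export
glance.np_analysis <- function(x, ...) {
  nptab <- x$np$table
  n <- nptab$tp + nptab$fp + nptab$fn + nptab$tn
  tibble(
    n_input = x$eligibility$n_input,
    n_eligible = x$eligibility$n_kept,
    n_classified = n,
    n_deep = nptab$tp + nptab$fn,
    prevalence_deep = (nptab$tp + nptab$fn) / n,
    suv_cutoff = x$cutoff$value,
    auc = if (is.null(x$roc)) NA_real_ else x$roc$auc,
    np_accuracy =
      x$np$metrics$estimate[x$np$metrics$metric == "accuracy"],
    np_fisher_p = x$np$fisher_p
  )
}

#' @rdname tidy.np_analysis
#' @param object An `np_analysis`.
#' @method autoplot np_analysis
#' @export
autoplot.np_analysis <- function(object, ...) {
  if (is.null(object$roc)) {
    abort("no ROC available: the cohort has no measured SUVmax in both depth classes")
  }
  p <- autoplot(object$roc)
  pts <- object$roc$points
  at <- pts[which.min(abs(pts$threshold - object$cutoff$value)), ]
  p + ggplot2::geom_point(
    data = at,
    ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity),
    colour = "red", size = 2
  ) +
    ggplot2::labs(subtitle = sprintf("SUVmax cutoff %.3g (%s)",
                                     object$cutoff$value,
                                     object$cutoff$mode))
}

contingency_as_list <- function(x) {
  list(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

#' Serialise an analysis report to JSON
#'
#' Writes every block of an [run_full_analysis()] result — counts, metric
#' tables, ROC operating points, effect estimates, provenance — as a single
#' JSON document. Each metrics block embeds its 2x2 counts so all metrics
#' are recomputable from the report alone.
#'
#' @param x An `np_analysis`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_report(run_full_analysis(reconstructed_cohort(), 2.4), f)
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "np_analysis"))
  report <- list(
    eligibility = x$eligibility,
    jes = list(
      table = as.data.frame(as.table(x$jes$table)) |>
        setNames(c("b_type", "depth_group", "n")),
      performance = x$jes$performance
    ),
    roc = if (!is.null(x$roc)) {
      list(points = x$roc$points, auc = x$roc$auc,
           auc_ci = x$roc$auc_ci, ci_method = x$roc$ci_method)
    },
    cutoff = list(mode = x$cutoff$mode, value = x$cutoff$value,
                  youden = x$cutoff$youden),
    pet = if (!is.null(x$pet)) {
      list(counts = contingency_as_list(x$pet$table),
           metrics = x$pet$metrics, fisher_p = x$pet$fisher_p,
           n_unmeasured = x$pet$n_unmeasured)
    },
    np = list(
      counts = contingency_as_list(x$np$table),
      metrics = x$np$metrics,
      fisher_p = x$np$fisher_p,
      odds_ratio = x$np$odds_ratio,
      n_unclassifiable = nrow(x$unclassifiable),
      unclassifiable_ids = x$unclassifiable$lesion_id
    ),
    logistic = if (is.character(x$logistic)) {
      list(error = x$logistic)
    } else if (!is.null(x$logistic)) {
      list(estimates = x$logistic)
    },
    conf_level = x$conf.level,
    provenance = x$provenance
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
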