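#' Histopathological depth codes and groupings
#'
#' Superficial esophageal squamous cell carcinoma is staged into six ordered
#' invasion-depth codes: `EP` (intraepithelial), `LPM` (lamina propria
#' mucosae), `MM` (muscularis mucosae), `SM1` (submucosal invasion within
#' 200 um of the muscularis mucosae), and `SM2`/`SM3` (deeper submucosal
#' invasion). Analyses collapse these into three groups mirroring the three
#' JES type-B vessel classes: `EP_LPM`, `MM_SM1`, `SM2_SM3`. Lesions in
#' `SM2_SM3` ("deep") are the clinically critical class: they are poor
#' candidates for endoscopic resection.
#'
#' @param depth Character or factor vector of six-level depth codes.
#' @return `depth_group()`: a factor with levels `EP_LPM`, `MM_SM1`,
#'   `SM2_SM3`. `is_deep()`: a logical vector, `TRUE` for SM2/SM3.
#' @examples
#' depth_group(c("EP", "SM1", "SM3"))
#' is_deep(c("LPM", "SM2"))
#' @export
depth_group <- function(depth) {
  depth <- as.character(depth)
  bad <- !is.na(depth) & !depth %in% depth_levels()
  if (any(bad)) {
    abort(sprintf(
      "unknown depth code(s): %s (expected one of %s)",
      paste(unique(depth[bad]), collapse = ", "),
      paste(depth_levels(), collapse = ", ")
    ))
  }
  map <- c(
    EP = "EP_LPM", LPM = "EP_LPM",
    MM = "MM_SM1", SM1 = "MM_SM1",
    SM2 = "SM2_SM3", SM3 = "SM2_SM3"
  )
  factor(unname(map[depth]), levels = depth_group_levels())
}

#' @rdname depth_group
#' @export
is_deep <- function(depth) depth_group(depth) == "SM2_SM3"

#' @rdname depth_group
#' @export
depth_levels <- function() c("EP", "LPM", "MM", "SM1", "SM2", "SM3")

#' @rdname depth_group
#' @export
depth_group_levels <- function() c("EP_LPM", "MM_SM1", "SM2_SM3")

b_type_levels <- function() c("B1", "B2", "B3")

#' Dichotomise macroscopic type into elevated / non-elevated
#'
#' Japanese Classification codes `0-IIa` and `0-Is` are elevated; every other
#' code (e.g. `0-IIb`, `0-IIc`, `0-III`) is non-elevated.
#'
#' @param macro_type Character vector of macroscopic type codes.
#' @return Factor with levels `elevated`, `non_elevated`; `NA` stays `NA`.
#' @examples
#' classify_morphology(c("0-IIa", "0-IIc", "0-Is"))
#' @export
classify_morphology <- function(macro_type) {
  macro_type <- as.character(macro_type)
  if (any(!is.na(macro_type) & !nzchar(macro_type))) {
    abort("empty macroscopic type code; use NA for unknown morphology")
  }
  out <- ifelse(
    is.na(macro_type), NA_character_,
    ifelse(macro_type %in% c("0-IIa", "0-Is"), "elevated", "non_elevated")
  )
  factor(out, levels = c("elevated", "non_elevated"))
}

#' Body-weight standardised uptake value
#'
#' SUV normalises a lesion's radiotracer concentration by the injected dose
#' per gram of body weight: `conc / (dose / weight)`. Dimensionless.
#'
#' @param tissue_conc Radioactive concentration of the lesion, MBq/mL.
#' @param injected_dose Injected FDG dose, MBq.
#' @param body_weight Patient body weight, g.
#' @return Numeric SUV.
#' @examples
#' compute_suv(0.01, 200, 60000) # 3.0
#' @export
compute_suv <- function(tissue_conc, injected_dose, body_weight) {
  if (any(!is.finite(tissue_conc)) || any(!is.finite(injected_dose)) ||
      any(!is.finite(body_weight)) ||
      any(tissue_conc <= 0) || any(injected_dose <= 0) ||
      any(body_weight <= 0)) {
    abort("compute_suv() requires strictly positive, finite arguments")
  }
  tissue_conc / (injected_dose / body_weight)
}

cohort_required_cols <- c("lesion_id", "b_type", "depth")

#' Validate a lesion cohort table
#'
#' Checks codes, ranges and cross-field consistency of a per-lesion table and
#' returns it with typed columns. Required columns: `lesion_id`, `b_type`
#' (B1/B2/B3), `depth` (EP/LPM/MM/SM1/SM2/SM3). Recognised optional columns:
#' `suv_max` (non-negative or `NA` = not measured; 0 = undetectable uptake),
#' `macro_type`, `elevated`, `treatment` (ER/surgery), `prior_therapy`,
#' `depth_over_t1b`, `patient_id`. Missing logical flags default to `FALSE`;
#' `elevated` is derived from `macro_type` when absent, and when both are
#' present they must agree.
#'
#' @param cohort A data frame of lesion records.
#' @return A validated tibble with typed columns, rows in input order.
#' @examples
#' validate_cohort(data.frame(lesion_id = "L1", b_type = "B2", depth = "SM2"))
#' @export
validate_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  missing_cols <- setdiff(cohort_required_cols, names(cohort))
  if (length(missing_cols)) {
    abort(sprintf(
      "cohort is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }

  check_codes <- function(x, valid, col) {
    bad <- which(!is.na(x) & !as.character(x) %in% valid)
    if (length(bad)) {
      abort(sprintf(
        "invalid %s %s in row %d (expected one of %s)",
        col, encodeString(as.character(x)[bad[1]], quote = "'"), bad[1],
        paste(valid, collapse = ", ")
      ))
    }
  }
  check_codes(cohort$b_type, b_type_levels(), "b_type")
  check_codes(cohort$depth, depth_levels(), "depth")
  if (any(is.na(cohort$b_type))) {
    abort(sprintf("missing b_type in row %d", which(is.na(cohort$b_type))[1]))
  }
  if (any(is.na(cohort$depth))) {
    abort(sprintf("missing depth in row %d", which(is.na(cohort$depth))[1]))
  }
  cohort$lesion_id <- as.character(cohort$lesion_id)
  cohort$b_type <- factor(as.character(cohort$b_type), b_type_levels())
  cohort$depth <- factor(as.character(cohort$depth), depth_levels())

  if (!"suv_max" %in% names(cohort)) {
    cohort$suv_max <- NA_real_
  }
  cohort$suv_max <- as.numeric(cohort$suv_max)
  neg <- which(!is.na(cohort$suv_max) & cohort$suv_max < 0)
  if (length(neg)) {
    abort(sprintf("negative suv_max in row %d", neg[1]))
  }

  if (!"macro_type" %in% names(cohort)) cohort$macro_type <- NA_character_
  cohort$macro_type <- as.character(cohort$macro_type)
  derived <- classify_morphology(cohort$macro_type) == "elevated"
  if ("elevated" %in% names(cohort)) {
    cohort$elevated <- as.logical(cohort$elevated)
    clash <- which(!is.na(cohort$elevated) & !is.na(derived) &
                     cohort$elevated != derived)
    if (length(clash)) {
      abort(sprintf(
        "row %d: elevated = %s contradicts macro_type '%s'",
        clash[1], cohort$elevated[clash[1]], cohort$macro_type[clash[1]]
      ))
    }
    cohort$elevated <- ifelse(is.na(cohort$elevated), derived, cohort$elevated)
  } else {
    cohort$elevated <- derived
  }

  if ("treatment" %in% names(cohort)) {
    check_codes(cohort$treatment, c("ER", "surgery"), "treatment")
    cohort$treatment <- factor(as.character(cohort$treatment),
                               c("ER", "surgery"))
  } else {
    cohort$treatment <- factor(NA_character_, c("ER", "surgery"))
  }

  for (flag in c("prior_therapy", "depth_over_t1b")) {
    if (!flag %in% names(cohort)) cohort[[flag]] <- FALSE
    cohort[[flag]] <- as.logical(cohort[[flag]])
    cohort[[flag]][is.na(cohort[[flag]])] <- FALSE
  }
  cohort
}

#' Read / write a lesion cohort table
#'
#' Delimited text (CSV by default, UTF-8, header required, empty cell =
#' missing) with the schema documented in [validate_cohort()]. Reading
#' validates every row; writing uses empty cells for `NA` so that a
#' read/write cycle round-trips all field values.
#'
#' @param file Path to the delimited file.
#' @param delim Field delimiter, default `","`.
#' @return `read_cohort()`: a validated tibble. `write_cohort()`: `file`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(
#'   validate_cohort(data.frame(lesion_id = "L1", b_type = "B2",
#'                              suv_max = 3.2, depth = "SM2")),
#'   f
#' )
#' read_cohort(f)
#' @export
read_cohort <- function(file, delim = ",") {
  raw <- readr::read_delim(
    file,
    delim = delim, na = "", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  for (col in intersect(c("suv_max"), names(raw))) {
    vals <- raw[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad)) {
      abort(sprintf("row %d: %s value '%s' is not numeric",
                    bad[1], col, vals[bad[1]]))
    }
    raw[[col]] <- num
  }
  for (col in intersect(c("elevated", "prior_therapy", "depth_over_t1b"),
                        names(raw))) {
    vals <- raw[[col]]
    lg <- as.logical(vals)
    lg[vals %in% "1"] <- TRUE
    lg[vals %in% "0"] <- FALSE
    bad <- which(!is.na(vals) & is.na(lg))
    if (length(bad)) {
      abort(sprintf("row %d: %s value '%s' is not logical",
                    bad[1], col, vals[bad[1]]))
    }
    raw[[col]] <- lg
  }
  validate_cohort(raw)
}

#' @rdname read_cohort
#' @param cohort A validated cohort tibble.
#' @export
write_cohort <- function(cohort, file, delim = ",") {
  readr::write_delim(cohort, file, delim = delim, na = "")
  invisible(file)
}

#' Apply study eligibility criteria
#'
#' Treatment-naive superficial lesions only: excludes records flagged with
#' prior chemotherapy/chemoradiotherapy (`prior_therapy`) and those whose
#' resected specimen showed invasion beyond T1b (`depth_over_t1b`).
#' Idempotent: the kept set passes unchanged through a second application.
#'
#' @param cohort A validated cohort tibble.
#' @return A list with elements `kept` (eligible tibble) and `excluded`
#'   (excluded rows plus a `reason` column).
#' @examples
#' co <- validate_cohort(data.frame(
#'   lesion_id = c("L1", "L2"), b_type = "B1", depth = "EP",
#'   prior_therapy = c(FALSE, TRUE)
#' ))
#' apply_eligibility(co)$excluded$reason
#' @export
apply_eligibility <- function(cohort) {
  cohort <- validate_cohort(cohort)
  reason <- dplyr::case_when(
    cohort$prior_therapy & cohort$depth_over_t1b ~
      "prior_therapy; depth_beyond_T1b",
    cohort$prior_therapy ~ "prior_therapy",
    cohort$depth_over_t1b ~ "depth_beyond_T1b",
    TRUE ~ NA_character_
  )
  list(
    kept = cohort[is.na(reason), , drop = FALSE],
    excluded = mutate(cohort[!is.na(reason), , drop = FALSE],
                      reason = reason[!is.na(reason)])
  )
}

#' Summarise a lesion cohort
#'
#' Counts by collapsed depth group, elevated morphology within the binary
#' (deep vs shallow) depth split, and treatment modality.
#'
#' @param cohort A validated cohort tibble.
#' @return A list of class `cohort_summary`; serialise with
#'   [jsonlite::toJSON()] or [write_cohort_summary()].
#' @examples
#' cohort_summary(generate_cohort(np_cohort_config(n = 50, seed = 1)))
#' @export
cohort_summary <- function(cohort) {
  cohort <- validate_cohort(cohort)
  grp <- depth_group(cohort$depth)
  deep <- grp == "SM2_SM3"
  out <- list(
    n_lesions = nrow(cohort),
    n_per_depth_group = as.list(table(grp)),
    n_elevated_per_binary_depth = list(
      shallow = sum(cohort$elevated[!deep], na.rm = TRUE),
      deep = sum(cohort$elevated[deep], na.rm = TRUE)
    ),
    n_treatment = list(
      ER = sum(cohort$treatment == "ER", na.rm = TRUE),
      surgery = sum(cohort$treatment == "surgery", na.rm = TRUE)
    )
  )
  structure(out, class = "cohort_summary")
}

#' @rdname cohort_summary
#' @param x A `cohort_summary`.
#' @param path Output path for the JSON summary.
#' @export
write_cohort_summary <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Lesion cohort:", x$n_lesions, "lesions\n")
  cat("  depth groups:",
      paste(names(x$n_per_depth_group), unlist(x$n_per_depth_group),
            sep = "=", collapse = ", "), "\n")
  cat("  elevated: shallow", x$n_elevated_per_binary_depth$shallow,
      "| deep", x$n_elevated_per_binary_depth$deep, "\n")
  cat("  treatment: ER", x$n_treatment$ER,
      "| surgery", x$n_treatment$surgery, "\n")
  invisible(x)
}
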