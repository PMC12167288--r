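#' Depth predicted from the JES type-B vessel class
#'
#' Under magnifying narrow-band imaging, intratumoral microvessels are graded
#' B1, B2 or B3; each class carries a predicted invasion depth: B1 ->
#' EP/LPM, B2 -> MM/SM1, B3 -> SM2 or deeper.
#'
#' @param b_type Character or factor vector of `B1`/`B2`/`B3`.
#' @return Factor of predicted depth groups (levels as
#'   [depth_group_levels()]).
#' @examples
#' jes_predicted_depth(c("B1", "B2", "B3"))
#' @export
jes_predicted_depth <- function(b_type) {
  b_type <- as.character(b_type)
  bad <- !is.na(b_type) & !b_type %in% b_type_levels()
  if (any(bad)) {
    abort(sprintf("unknown b_type: %s",
                  paste(unique(b_type[bad]), collapse = ", ")))
  }
  map <- c(B1 = "EP_LPM", B2 = "MM_SM1", B3 = "SM2_SM3")
  factor(unname(map[b_type]), levels = depth_group_levels())
}

#' The combined N-P risk category
#'
#' Sequential combination of the endoscopic microvessel class with FDG-PET
#' uptake for predicting deep (SM2 or deeper) invasion. B1 lesions are
#' low-risk and B3 lesions high-risk regardless of SUVmax (PET is not needed
#' for them); B2 lesions — the ambiguous class — are resolved by PET:
#' high-risk iff `suv_max >= suv_cutoff` (boundary inclusive).
#'
#' A B2 lesion without a measured SUVmax cannot be classified; by default
#' this is an error, or set `unclassifiable = "na"` to return `NA` for those
#' lesions.
#'
#' @param b_type Character or factor vector of `B1`/`B2`/`B3`.
#' @param suv_max Numeric SUVmax vector (`NA` = not measured), recycled
#'   against `b_type`.
#' @param suv_cutoff Positive SUV cutoff; default 2.4.
#' @param unclassifiable `"error"` (default) or `"na"` for B2 lesions with
#'   missing SUVmax.
#' @return Factor with levels `low`, `high`.
#' @examples
#' np_risk(c("B1", "B2", "B2", "B3"), c(10, 2.4, 1.1, NA))
#' @export
np_risk <- function(b_type, suv_max = NA_real_, suv_cutoff = 2.4,
                    unclassifiable = c("error", "na")) {
  unclassifiable <- arg_match(unclassifiable)
  if (!is.numeric(suv_cutoff) || length(suv_cutoff) != 1 ||
      !is.finite(suv_cutoff) || suv_cutoff <= 0) {
    abort("suv_cutoff must be a single positive number")
  }
  pred <- jes_predicted_depth(b_type) # validates b_type
  b_type <- as.character(b_type)
  n <- length(b_type)
  suv_max <- rep_len(as.numeric(suv_max), n)

  no_pet <- b_type == "B2" & is.na(suv_max)
  if (any(no_pet) && unclassifiable == "error") {
    abort(sprintf(
      "unclassifiable: B2 lesion(s) without SUVmax at position(s) %s (the rule requires PET for B2)",
      paste(head(which(no_pet), 5), collapse = ", ")
    ))
  }
  out <- ifelse(
    b_type == "B3", "high",
    ifelse(b_type == "B1", "low",
           ifelse(is.na(suv_max), NA_character_,
                  ifelse(suv_max >= suv_cutoff, "high", "low")))
  )
  factor(out, levels = c("low", "high"))
}

#' Append N-P risk columns to a cohort
#'
#' Adds `np_risk` (factor low/high, `NA` for B2 lesions without SUVmax) to a
#' per-lesion table.
#'
#' @param data A cohort data frame with `b_type` and `suv_max` columns.
#' @param suv_cutoff Positive SUV cutoff; default 2.4.
#' @return `data` as a tibble with an `np_risk` column appended.
#' @examples
#' generate_cohort(np_cohort_config(n = 5, seed = 1)) |> add_np_risk()
#' @export
add_np_risk <- function(data, suv_cutoff = 2.4) {
  data <- as_tibble(data)
  mutate(data, np_risk = np_risk(.data$b_type, .data$suv_max,
                                 suv_cutoff = suv_cutoff,
                                 unclassifiable = "na"))
}
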