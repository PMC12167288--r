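#' Round half away from zero
#'
#' Rounding used when metrics are rendered as percentages: ties go up
#' (0.05 -> 0.1), unlike base [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(86.85, 86.95), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

# fraction -> percentage at the reporting precision (1 decimal, half-up)
as_pct <- function(x) round_half_up(100 * x, 1)

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
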