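#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (2.675 -> 2.68),
#' the convention used for all presentation-layer rounding in this package.
#' Base [round()] uses round-half-even, which disagrees with published
#' tables on exact .5 ties (e.g. shares such as 21.875).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(21.875)       # 21.88
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  scale <- 10^digits
  # small epsilon guards against binary representation just below a .5 tie
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# classed condition helpers -------------------------------------------------

stop_canmp <- function(message, class = "error", ...) {
  rlang::abort(message, class = c(paste0("canmp_", class), "canmp_error"), ...)
}

check_number <- function(x, name, min = -Inf, allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x)) {
    stop_canmp(sprintf("`%s` must be numeric and non-missing.", name),
               class = "validation")
  }
  if (any(x < min)) {
    stop_canmp(sprintf("`%s` must be >= %s.", name, format(min)),
               class = "validation")
  }
  invisible(x)
}

check_df_cols <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    stop_canmp(sprintf("`%s` must be a data frame.", what), class = "validation")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_canmp(sprintf("`%s` is missing required column(s): %s.",
                       what, paste(missing, collapse = ", ")),
               class = "validation")
  }
  invisible(df)
}

producer_of <- function(code) sub("-.*$", "", code)
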