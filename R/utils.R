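#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded away from zero,
#' matching the convention of most clinical reporting (e.g. -3.75 -> -3.8),
#' unlike [base::round()] which rounds halves to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(2.5)        # 3
#' round_half_up(-3.719, 1)  # -3.7
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# format a fraction as a paper-style percentage string, one decimal by default
fmt_percent <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * x, digits))
}

stop_pneumorisk <- function(..., class) {
  stop(structure(
    class = c(class, "pneumorisk_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_binary01 <- function(x) {
  all(is.na(x) | x %in% c(0, 1))
}

# run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_pneumorisk("`seed` must be a single integer", class = "pneumorisk_input_error")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
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
  set.seed(as.integer(seed))
  force(code)
}
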