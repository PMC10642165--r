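#' Derive a reproducible sub-stream seed
#'
#' All generators in the package draw their randomness from sub-streams of a
#' single master seed. Sub-streams are derived by a stable polynomial hash of
#' the master seed together with string tags (typically the stage name and a
#' patient id), so adding patients or reordering stages never perturbs the
#' stream of an unrelated unit.
#'
#' @param master integer master seed.
#' @param ... character or numeric tags identifying the sub-stream
#'   (e.g. `"tissue"`, a patient id).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "tissue", "P001")
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  mod <- 2147483647 # 2^31 - 1, prime; keeps arithmetic exact in doubles
  h <- as.numeric(master) %% mod
  for (tag in list(...)) {
    for (code in utf8ToInt(paste0("|", as.character(tag)))) {
      h <- (h * 131 + code) %% mod
    }
  }
  as.integer(h)
}

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Round half-up at a fixed number of decimals
#'
#' Base `round()` rounds half to even; clinical tables conventionally round
#' half away from zero, which is what this helper does.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator, at printed precision
#'
#' @param count numerator count(s).
#' @param denominator denominator count.
#' @param digits decimals to keep (0 or 1 in typical cohort tables),
#'   rounded half-up.
#' @return Percentage(s) on the 0-100 scale.
#' @export
#' @examples
#' percent_of(31, 107)      # 29
#' percent_of(54, 107, 1)   # 50.5
percent_of <- function(count, denominator, digits = 0) {
  stopifnot(denominator > 0, all(count >= 0))
  round_half_up(100 * count / denominator, digits)
}

# Shared input checkers -------------------------------------------------

stop_spec <- function(...) {
  stop(errorCondition(paste0(...), class = c("tmectx_spec_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("tmectx_data_error", "error")))
}

check_fractions <- function(x, what, tol = 1e-9) {
  if (any(x < 0 | x > 1)) {
    stop_spec(what, " must lie in [0, 1]")
  }
  if (abs(sum(x) - 1) > tol) {
    stop_spec(what, " must sum to 1 (got ", format(sum(x), digits = 12), ")")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
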