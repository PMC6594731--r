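#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all displayed person counts and
#' dollar figures. Base R's `round()` rounds half to even, which disagrees
#' with the convention used in published demographic tables (e.g. 194.5
#' persons displays as 195, not 194).
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
#' @examples
#' round_half_up(194.5)   # 195
#' round_half_up(0.4465, 3)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: scalar numeric check with a readable error
check_number <- function(x, name, min = -Inf, max = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be a finite numeric of length %d", name, len),
         call. = FALSE)
  }
  if (any(x < min)) {
    stop(sprintf("`%s` must be >= %s (got %s)", name, format(min),
                 format(min(x))), call. = FALSE)
  }
  if (any(x > max)) {
    stop(sprintf("`%s` must be <= %s (got %s)", name, format(max),
                 format(max(x))), call. = FALSE)
  }
  invisible(x)
}

check_fraction <- function(x, name, len = 1L) {
  check_number(x, name, min = 0, max = 1, len = len)
}

# internal: run code with a temporary RNG state seeded from `seed`,
# restoring the caller's stream afterwards so seeded generators do not
# perturb the session
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_number(seed, "seed")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
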