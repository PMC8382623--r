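#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all displayed counts and currency
#' amounts. Differs from [base::round()], which rounds half to even: here 0.5
#' rounds to 1 and -0.5 to -1. Internal model arithmetic is never rounded;
#' this is a display-time operation only.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep (default 0).
#' @return numeric vector, rounded.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5, -0.5))
#' round_half_up(4197.69) # 4198
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Thousands-separated integer formatting for human-readable output, in the
## house style of published budget tables: separators only from five digits
## up ("5674" but "15,312"). CSV/JSON writers never call this.
fmt_int <- function(x) {
  r <- round_half_up(x)
  ifelse(abs(r) < 10000,
         formatC(r, format = "d"),
         formatC(r, format = "d", big.mark = ","))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a reproducible sub-seed (< 2^31) for a named random stream, so each
## generator has its own stream and adding one never perturbs another.
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 2147483647
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

## Run fn under a named stream without disturbing the caller's RNG state.
with_stream <- function(seed, name, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  fn()
}

stop_bim <- function(...) stop(..., call. = FALSE)

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_bim(sprintf("`%s` must be a single number in [%g, %g] (got %s)",
                     name, lo, hi, paste(format(x), collapse = ", ")))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stop_bim(sprintf("`%s` must be non-negative", name))
  invisible(x)
}
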