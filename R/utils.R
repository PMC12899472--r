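#' @importFrom rlang abort warn %||%
NULL

abort_tc <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("tremorcam_error_", class), "tremorcam_error"), ...)
}

# Run code with its own RNG stream without disturbing the caller's seed.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_band <- function(band, fs = NULL) {
  if (!is.numeric(band) || length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    abort_tc("`band` must be c(lo, hi) with 0 < lo < hi.", "spec")
  }
  if (!is.null(fs) && band[2] >= fs / 2) {
    abort_tc(sprintf("Band upper edge %.3g Hz is not below the Nyquist frequency %.3g Hz.",
                     band[2], fs / 2), "spec")
  }
  invisible(band)
}
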