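#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed through named
#' substreams so that stages (balancing, fold assignment, selection,
#' simulation) can be re-run in isolation and stay paired across frames.
#' The derived value stays below 2^31 so it is always a valid integer seed.
#'
#' @param seed integer root seed.
#' @param offset integer substream offset (each stage uses a fixed one).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  seed <- as.numeric(seed) %% 2147483563
  as.integer((seed * 69069 + as.numeric(offset)) %% 2147483563)
}

# substream offsets, fixed so runs are comparable across versions
.substreams <- c(
  balance = 101L, split = 211L, grid = 307L, cv = 401L,
  sbs = 503L, perm = 601L, simulate = 701L, orientation = 809L
)

stage_seed <- function(seed, stage) {
  derive_seed(seed, .substreams[[stage]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cm_log <- function(...) {
  if (isTRUE(getOption("cowmotion.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

#' Render seconds as HH:MM:SS
#'
#' @param s non-negative seconds.
#' @return character string `"HH:MM:SS"`.
#' @export
format_hms <- function(s) {
  s <- round(s)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}
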