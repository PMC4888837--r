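# Internal helpers shared across modules.
#
# All genomic intervals in this package are 0-based half-open [start, end).
# Bioconductor containers are 1-based closed; conversion happens only at the
# IRanges boundary, through the two helpers below.

# 0-based half-open -> IRanges (1-based closed)
.as_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# IRanges -> 0-based half-open data.frame columns
.from_iranges <- function(ir) {
  list(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Derive a stage-specific random seed
#'
#' All simulator stages draw their randomness from one top-level seed through
#' this function, so adding or re-running a stage never perturbs another
#' stage's random stream.
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage label (e.g. `"genome"`, `"reads:A"`).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483562) + 1L
}

.stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

.msg <- function(verbose, ...) {
  if (isTRUE(verbose)) message(...)
}

# round() in R does banker's rounding; thresholds and reported percents want
# conventional half-up rounding so 0.5 cases are stable and predictable.
.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
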