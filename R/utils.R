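#' @importFrom stats rnorm runif rbinom dbinom pbinom setNames filter sd
#' @importFrom utils read.csv write.csv head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# The 12 directed substitution classes, in the conventional order used for
# EMS spectra (G:C->A:T transitions first).
SUBSTITUTION_CLASSES <- c(
  "G>A", "C>T", "T>A", "A>T", "T>C", "A>G",
  "G>T", "C>A", "A>C", "T>G", "C>G", "G>C"
)

TRANSITION_CLASSES <- c("G>A", "C>T", "T>C", "A>G")

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published tables in this field
#' round half away from zero (15.65 -> 15.7). All report formatting in this
#' package goes through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

revcomp <- function(s) {
  vapply(s, function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  }
  invisible(x)
}

# Derive a stream-specific 32-bit seed from a master seed so that the
# independent stages (population, layout, reads per pool) do not share RNG
# streams but remain reproducible from one integer.
derive_seed <- function(seed, stream) {
  # arithmetic in doubles (exact below 2^53) to avoid integer overflow
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483647)
}
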