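#' @keywords internal
"_PACKAGE"

# Canonical amino-acid alphabet used by the motif stage.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Round half away from zero
#'
#' Reporting columns of the comparison tables round .5 upwards (19.7 -> 20,
#' 32.4 -> 32), unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), 0)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Stable 31-bit string hash (polynomial, base 31, modulus 2^31 - 1).
# Used to derive per-spot RNG seeds from the master seed so that simulated
# datasets are reproducible independent of iteration order or platform.
# All intermediates stay below 2^53 so double arithmetic is exact.
stable_hash <- function(key, seed = 0L) {
  stopifnot(length(key) == 1L, is.character(key))
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% mod
  as.integer(h)
}

# path to a packaged fixture, with a hard failure naming the file
pamkin_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pamkin")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged fixture not found: inst/extdata/", file, call. = FALSE)
  }
  path
}
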