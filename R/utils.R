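#' @keywords internal
"_PACKAGE"

#' Derive a named substream seed from a base seed
#'
#' One user-facing seed drives every source of randomness; each entity or
#' stage gets its own reproducible substream via a polynomial string hash
#' of its name folded with the base seed (kept inside 32-bit integer range
#' so the result is always a legal \code{set.seed()} argument). Used by
#' [build_profiles_bulk()] (per-chemical substreams) and by the synthetic
#' generator (per-stage substreams).
#'
#' @param seed base integer seed.
#' @param key character label of the substream.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(key) == 1L)
  mod <- 2147483629  # largest prime below 2^31
  h <- 0
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% mod
  }
  as.integer((h + (as.numeric(seed) %% mod) * 40503) %% mod)
}

# Evaluate expr with a temporary RNG state; caller's stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Presentation rounding used throughout the package (recall to 3 decimals,
#' shared-pathway fractions to 1 decimal, shared-phenotype fractions to the
#' nearest integer). Base \code{round()} rounds half to even, which would
#' turn 26/32 into 0.812 and 44.5 into 44; reported fractions in this field
#' are conventionally rounded half away from zero.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_away(26 / 32, 3)  # 0.813
#' round_half_away(44.5, 0)     # 45
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stderr logging with a package-level quiet switch
mp_log <- function(..., quiet = getOption("metaprof.quiet", FALSE)) {
  if (!isTRUE(quiet)) {
    message(format(Sys.time(), "[%H:%M:%S] "), ...)
  }
  invisible(NULL)
}

fmt6 <- function(x) formatC(signif(x, 6), format = "g", digits = 6)
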