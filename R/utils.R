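#' Round half away from zero
#'
#' Decimal rounding with the "round half up" convention used throughout the
#' published-style reports (e.g. 20.85 -> 20.9), as opposed to base R's
#' round-half-to-even. Only intended for display arithmetic.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Deterministic 31-bit hash of a key string, for per-stratum RNG substreams.
# Polynomial rolling hash mod the Mersenne prime 2^31 - 1.
hash_key <- function(key) {
  m <- 2147483647
  vapply(key, function(k) {
    h <- 0
    for (ch in utf8ToInt(k)) h <- (h * 31 + ch) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-stratum seed derived from a master seed and a stratum key
#'
#' Independent substreams keyed by the stratum identity, so that adding or
#' removing one stratum does not perturb the draws of any other.
#'
#' @param master_seed integer master seed
#' @param key character key (one string per stratum)
#' @return integer vector of seeds in [0, 2^31 - 2]
#' @export
stratum_seed <- function(master_seed, key) {
  m <- 2147483647
  as.integer((as.numeric(master_seed) %% m * 48271 + hash_key(key)) %% m)
}

# Canonical categorical levels -------------------------------------------

#' @export
age_group6_levels <- function() {
  c("0-39", "40-49", "50-59", "60-69", "70-79", ">=80")
}

#' @export
seer_stage_levels <- function() {
  c("in situ", "localized", "regional", "distant", "unknown")
}

#' @export
region17_levels <- function() {
  c("Seoul", "Busan", "Daegu", "Incheon", "Gwangju", "Daejeon", "Ulsan",
    "Sejong", "Gyeonggi", "Gangwon", "Chungbuk", "Chungnam", "Jeonbuk",
    "Jeonnam", "Gyeongbuk", "Gyeongnam", "Jeju")
}

#' Example 17-to-3 region recoding
#'
#' The released cohorts report region as metropolitan / city / rural, but the
#' exact 17-level recoding is administrative and configurable; this example
#' mapping (special/metropolitan cities vs. Gyeonggi vs. provinces) is
#' provided for testing and demonstration only.
#'
#' @return named character vector mapping each of the 17 region labels to
#'   one of "metropolitan", "city", "rural"
#' @export
example_region3_mapping <- function() {
  c(Seoul = "metropolitan", Busan = "metropolitan", Daegu = "metropolitan",
    Incheon = "metropolitan", Gwangju = "metropolitan",
    Daejeon = "metropolitan", Ulsan = "metropolitan", Sejong = "metropolitan",
    Gyeonggi = "city",
    Gangwon = "rural", Chungbuk = "rural", Chungnam = "rural",
    Jeonbuk = "rural", Jeonnam = "rural", Gyeongbuk = "rural",
    Gyeongnam = "rural", Jeju = "rural")
}
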