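# Seed plumbing -----------------------------------------------------------

# Every stochastic stage draws its own sub-seed from the run seed through
# this splitter, so stages can be re-run independently and a whole run is
# reproducible from one integer. Multiplicative congruential step keeps the
# result a valid positive 32-bit integer.
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  for (ch in utf8ToInt(as.character(stream))) {
    s <- (s * 48271 + ch) %% m
  }
  as.integer(s + 1)
}

with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Validation helpers -------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "surfid_config_error")
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x),
          class = "surfid_config_error")
  }
  invisible(x)
}

# fraction of duplicated rows in a numeric matrix
duplicate_fraction <- function(x) {
  mean(duplicated(asplit(x, 1)))
}

log2_ <- function(x) log(x) / log(2)
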