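# internal helpers

# evaluate `code` under set.seed(seed), restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# deterministic substream seed derived from a master seed (kept < 2^31)
derive_seed <- function(master, stream) {
  as.integer((as.double(master) * 48271 + stream * 16807) %% 2147483647)
}

# polynomial evaluation, coefficients in increasing degree
polyval_inc <- function(coefs, x) {
  out <- 0
  for (j in rev(seq_along(coefs))) out <- out * x + coefs[j]
  out
}

age_band <- function(age) {
  cut(age, breaks = c(10, 18, 30, 50, 65, 87), right = FALSE,
      labels = c("10-17", "18-29", "30-49", "50-64", "65-86"),
      include.lowest = TRUE)
}
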