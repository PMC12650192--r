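# Independent brute-force reference for extremum detection: per-index scan
# with explicit plateau walking, then greedy highest-first suppression.
ref_extrema <- function(x, mpd) {
  n <- length(x)
  cand_max <- integer(0)
  cand_min <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] == x[i - 1]) next  # only the first index of a plateau counts
    j <- i - 1
    k <- i + 1
    while (k <= n && x[k] == x[i]) k <- k + 1
    if (k > n) next
    if (x[j] < x[i] && x[k] < x[i]) cand_max <- c(cand_max, i)
    if (x[j] > x[i] && x[k] > x[i]) cand_min <- c(cand_min, i)
  }
  pick <- function(idx, h) {
    kept <- integer(0)
    for (i in idx[order(-h, idx)])
      if (length(kept) == 0 || min(abs(kept - i)) >= mpd)
        kept <- c(kept, i)
    sort(kept)
  }
  list(peaks = pick(cand_max, x[cand_max]),
       valleys = pick(cand_min, -x[cand_min]))
}

# analytic magnitude of the package's cascaded bandpass at frequency f,
# evaluated directly from the filter polynomials
analytic_gain <- function(fs, f, p = preprocess_params()) {
  st <- bandpass_design(fs, p)
  z <- exp(-1i * 2 * pi * f / fs)
  g <- function(co) abs(sum(co$b * z^(seq_along(co$b) - 1)) /
                          sum(co$a * z^(seq_along(co$a) - 1)))
  g(st$hp) * g(st$lp)
}

# steady-state amplitude of the mid-section of a series
mid_amplitude <- function(y) {
  n <- length(y)
  max(abs(y[floor(n / 3):floor(2 * n / 3)]))
}
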