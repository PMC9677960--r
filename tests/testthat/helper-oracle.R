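# Independent brute-force oracles, coded directly from the statistic
# definitions with plain loops. These deliberately share no code with the
# package's vectorized implementations.

oracle_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  d <- x - mu
  m2 <- sum(d^2) / n
  # type-7 quantile at position (n-1)*p, linear interpolation
  q7 <- function(p) {
    s <- sort(x)
    pos <- (n - 1) * p
    lo <- floor(pos)
    s[lo + 1] + (pos - lo) * (s[min(lo + 2, n)] - s[lo + 1])
  }
  # zero crossings with explicit carry of the previous nonzero sign
  zc <- 0L
  prev <- 0
  for (i in seq_len(n)) {
    s <- if (d[i] > 0) 1 else if (d[i] < 0) -1 else prev
    if (prev != 0 && s != 0 && s != prev) zc <- zc + 1L
    if (s != 0) prev <- s
  }
  asc <- 0
  for (i in seq_len(n - 1)) asc <- asc + abs(x[i + 1] - x[i])
  c(mean = mu,
    sd = sqrt(sum(d^2) / (n - 1)),
    max = max(x), min = min(x),
    iqr = q7(0.75) - q7(0.25),
    range = max(x) - min(x),
    pos_count = sum(d > 0), neg_count = sum(d < 0),
    skewness = if (m2 > 0) (sum(d^3) / n) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) (sum(d^4) / n) / m2^2 - 3 else 0,
    zero_cross = zc,
    sse = sum(d^2),
    abs_sum_changes = asc,
    l2norm = sqrt(sum(x^2)))
}

# one-sided magnitude spectrum by explicit DFT sums (no fft)
oracle_spectrum <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  t <- 0:(n - 1)
  vapply(seq_len(floor(n / 2)), function(k) {
    re <- sum(xc * cos(-2 * pi * k * t / n))
    im <- sum(xc * sin(-2 * pi * k * t / n))
    sqrt(re^2 + im^2)
  }, 0)
}

oracle_pitch_roll <- function(acc) {
  p <- r <- numeric(0)
  for (i in seq_len(nrow(acc))) {
    a <- acc[i, ]
    if (all(a == 0)) next
    p <- c(p, atan2(a[1], sqrt(a[2]^2 + a[3]^2)) * 180 / pi)
    r <- c(r, atan2(a[2], sqrt(a[1]^2 + a[3]^2)) * 180 / pi)
  }
  if (length(p) == 0) c(pitch = 0, roll = 0) else c(pitch = mean(p), roll = mean(r))
}

# exhaustive window enumeration: try every start position
oracle_window_count <- function(n, ws, ss) {
  count <- 0L
  start <- 0L
  repeat {
    if (start + ws > n) break
    count <- count + 1L
    start <- start + ss
  }
  count
}
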