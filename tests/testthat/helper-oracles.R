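# Independent oracles used across tests. These deliberately avoid the code
# paths they are checking: pair enumeration is done with plain R loops, the
# autocorrelation oracle uses the FFT directly on the raw field, and
# summaries use naive two-pass arithmetic.

# Enumerate all in-bounds ordered pixel pairs at offset (dx, dy) with loops;
# returns a two-column matrix of (value at p, value at p + offset).
enumerate_pairs <- function(m, dx, dy) {
  nr <- nrow(m)
  nc <- ncol(m)
  a <- numeric(0)
  b <- numeric(0)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      r2 <- r + dy
      c2 <- cc + dx
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        a <- c(a, m[r, cc])
        b <- c(b, m[r2, c2])
      }
    }
  }
  cbind(a, b)
}

# Pearson correlation of the pixel-pair sample; with symmetric = TRUE the
# sample is doubled with reversed pairs, matching a symmetric GLCM.
pairwise_pearson <- function(m, dx, dy, symmetric = TRUE) {
  p <- enumerate_pairs(m, dx, dy)
  if (symmetric) p <- rbind(p, p[, 2:1])
  stats::cor(p[, 1], p[, 2])
}

# Normalized spatial autocorrelation of a field at integer lags along the
# two axes, computed with the Wiener-Khinchin theorem on the raw field.
fft_axis_autocorr <- function(field, lags) {
  f <- field - mean(field)
  n <- nrow(field)
  ac <- Re(stats::fft(Mod(stats::fft(f))^2, inverse = TRUE)) / length(f)
  ac <- ac / ac[1, 1]
  list(
    h = ac[1, lags + 1], # column shifts
    v = ac[lags + 1, 1]  # row shifts
  )
}

# Naive two-pass mean and sample SD.
two_pass_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  c(mean = m, sd = s)
}

# Closed-form Hertz load in newtons for depth h_m (metres).
hertz_oracle <- function(h_m, E_Pa, nu, R_m) {
  (4 / 3) * (E_Pa / (1 - nu^2)) * sqrt(R_m) * h_m^1.5
}

# Random category-size spec for concordance-partition property tests.
random_deg_sizes <- function() {
  sizes <- sample(0:30, 8, replace = TRUE)
  names(sizes) <- c("a_up", "a_down", "b_up", "b_down",
                    "common_up", "common_down", "discordant", "unchanged")
  sizes
}
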