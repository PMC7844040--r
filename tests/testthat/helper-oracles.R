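# Independent oracles and small fixture builders shared across tests.

# Horizontal sinusoidal stripe image: intensity varies only along rows.
stripe_image <- function(nr = 110, nc = 110, period_px = 10) {
  matrix(rep(127.5 * (1 + sin(2 * pi * seq_len(nr) / period_px)), nc), nr, nc)
}

# Brute-force symmetric GLCM by explicit double loop over all pixel pairs.
brute_glcm <- function(q, d, ang, levels) {
  off <- switch(as.character(ang),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  cnt <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q))
      cnt[q[r, cc] + 1, q[r2, c2] + 1] <- cnt[q[r, cc] + 1, q[r2, c2] + 1] + 1
  }
  p <- cnt + t(cnt)
  p / sum(p)
}

# Hand sums-of-squares one-way ANOVA F statistic.
brute_anova_F <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Sinusoidal fiber centerline in (row, col) px, optionally rotated.
sine_centerline <- function(length_px, period_px, amp_px, angle_deg = 0,
                            n = 400) {
  xs <- seq(0, length_px, length.out = n)
  d <- amp_px * sin(2 * pi * xs / period_px)
  pts <- cbind(row = d, col = xs)
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  pts %*% t(R) + 200
}
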