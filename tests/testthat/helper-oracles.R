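# Brute-force oracles written directly from the metric definitions; they
# share no code with the package implementations.

psnr_oracle <- function(a, b, max_hu = 4000) {
  rmse <- sqrt(mean((a - b)^2))
  10 * log10(max_hu^2 / rmse^2)
}

ssim_oracle <- function(a, b, win = 11, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                        L = 4000) {
  h <- (win - 1) / 2
  g <- outer(exp(-((-h:h)^2) / (2 * sigma^2)),
             exp(-((-h:h)^2) / (2 * sigma^2)))
  g <- g / sum(g)
  c1 <- (K1 * L)^2; c2 <- (K2 * L)^2
  vals <- c()
  for (i in (1 + h):(nrow(a) - h)) {
    for (j in (1 + h):(ncol(a) - h)) {
      wa <- a[(i - h):(i + h), (j - h):(j + h)]
      wb <- b[(i - h):(i + h), (j - h):(j + h)]
      mu1 <- sum(g * wa); mu2 <- sum(g * wb)
      s11 <- sum(g * wa^2) - mu1^2
      s22 <- sum(g * wb^2) - mu2^2
      s12 <- sum(g * wa * wb) - mu1 * mu2
      vals <- c(vals, ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
                        ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)))
    }
  }
  mean(vals)
}


# Exhaustive gamma search written directly from the definition: for every
# reference point, minimise over *all* test points.
gamma_oracle <- function(ref, test, dta, dd_pct, spacing = c(1, 1)) {
  dnorm_val <- max(ref)
  den <- dd_pct / 100 * dnorm_val
  nr <- nrow(ref); nc <- ncol(ref)
  gam <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- Inf
    for (k in seq_len(nr)) for (l in seq_len(nc)) {
      d2 <- ((i - k) * spacing[1])^2 + ((j - l) * spacing[2])^2
      g2 <- d2 / dta^2 + ((ref[i, j] - test[k, l]) / den)^2
      if (g2 < best) best <- g2
    }
    gam[i, j] <- sqrt(best)
  }
  100 * mean(gam <= 1)
}

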