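## Small numerical utilities shared across modules.

# Central-difference Hessian of a scalar function. Step is relative:
# h_i = h * (1 + |x_i|).
num_hessian <- function(f, x, h = 1e-5) {
  p <- length(x)
  hh <- h * (1 + abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- hh[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hh[i]^2
    if (i < p) for (j in (i + 1):p) {
      ej <- numeric(p); ej[j] <- hh[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hh[i] * hh[j])
    }
  }
  H
}
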