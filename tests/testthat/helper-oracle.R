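# Independent fixed-step RK4 integrator with its own derivative formulas,
# used as a numerical oracle for the package's adaptive solver. Kept
# deliberately separate from the package implementation.
rk4_oracle <- function(pars, y0, t_end, h) {
  deriv <- function(y) {
    hc <- pars$healthy
    lc <- pars$leukemic
    consumers <- if (pars$variant == "model2") y[2] else y[2] + y[4]
    s <- 1 / (1 + pars$k * consumers)
    sl <- if (pars$variant == "model2") 1 else s
    crowd <- pars$dbar * (y[1] + y[3])
    c((2 * hc$a * s - 1) * hc$p * y[1] - crowd * y[1],
      2 * (1 - hc$a * s) * hc$p * y[1] - hc$d * y[2],
      (2 * lc$a * sl - 1) * lc$p * y[3] - crowd * y[3],
      2 * (1 - lc$a * sl) * lc$p * y[3] - lc$d * y[4])
  }
  n <- round(t_end / h)
  y <- as.numeric(y0)
  out <- matrix(NA_real_, n + 1L, 4L)
  out[1L, ] <- y
  for (i in seq_len(n)) {
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- y
  }
  out
}

# first blast-fraction crossing time from an RK4 grid, by linear
# interpolation between steps
rk4_crossing_time <- function(pars, y0, t_end, h, threshold) {
  o <- rk4_oracle(pars, y0, t_end, h)
  bf <- o[, 3] / (o[, 1] + o[, 3])
  i <- which(bf >= threshold)[1L]
  if (is.na(i)) return(Inf)
  if (i == 1L) return(0)
  ((i - 2L) + (threshold - bf[i - 1L]) / (bf[i] - bf[i - 1L])) * h
}
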