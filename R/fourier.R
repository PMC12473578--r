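# Periodic (Fourier) representation of joint-angle profiles over one gait
# cycle. Coefficients are stored as c(a0, a1, b1, a2, b2, ...) so that
#   f(phase) = a0 + sum_k a_k cos(2*pi*k*phase) + b_k sin(2*pi*k*phase)
# with phase in cycle fractions (0 = heel strike, 1 = next ipsilateral
# heel strike).

fourier_eval <- function(coef, phase) {
  stopifnot(length(coef) >= 1, length(coef) %% 2 == 1)
  y <- rep(coef[1], length(phase))
  K <- (length(coef) - 1L) %/% 2L
  if (K > 0) {
    for (k in seq_len(K)) {
      w <- 2 * pi * k * phase
      y <- y + coef[2 * k] * cos(w) + coef[2 * k + 1] * sin(w)
    }
  }
  y
}

# derivative with respect to phase (per cycle fraction)
fourier_deriv <- function(coef, phase) {
  y <- numeric(length(phase))
  K <- (length(coef) - 1L) %/% 2L
  if (K > 0) {
    for (k in seq_len(K)) {
      w <- 2 * pi * k * phase
      y <- y + 2 * pi * k * (-coef[2 * k] * sin(w) + coef[2 * k + 1] * cos(w))
    }
  }
  y
}

# coefficients of g(phase) = f(phase + delta)
fourier_shift <- function(coef, delta) {
  out <- coef
  K <- (length(coef) - 1L) %/% 2L
  if (K > 0) {
    for (k in seq_len(K)) {
      d <- 2 * pi * k * delta
      a <- coef[2 * k]; b <- coef[2 * k + 1]
      out[2 * k]     <- a * cos(d) + b * sin(d)
      out[2 * k + 1] <- b * cos(d) - a * sin(d)
    }
  }
  out
}
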