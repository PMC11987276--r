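# Analytic sine-curve fixtures and independent quadrature oracles used by the
# morphometry tests. These deliberately re-derive curvature and tortuosity
# from the closed-form expressions rather than calling package code.

# y = A sin(omega * x): signed curvature at x
sine_kappa_analytic <- function(x, A, omega) {
  -A * omega^2 * sin(omega * x) / (1 + A^2 * omega^2 * cos(omega * x)^2)^1.5
}

# points on the sine curve resampled to uniform arc-length spacing, together
# with the x-parameter at each sample (for evaluating the analytic kappa)
sine_arc_samples <- function(A, omega, x_max, spacing, x_step = 1e-3) {
  x <- seq(0, x_max, by = x_step)
  y <- A * sin(omega * x)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  s_new <- seq(0, L, by = spacing)
  list(points = cbind(approx(arc, x, xout = s_new)$y,
                      approx(arc, y, xout = s_new)$y),
       x_at = approx(arc, x, xout = s_new)$y,
       spacing = spacing, L = L)
}

# high-resolution quadrature of tau = (1/L) int (dkappa/ds)^2 ds from the
# analytic curvature, independent of the package estimators
sine_tau_oracle <- function(A, omega, x_max, x_step = 5e-4) {
  x <- seq(0, x_max, by = x_step)
  k <- sine_kappa_analytic(x, A, omega)
  ds <- sqrt(1 + (A * omega * cos(omega * x))^2) * x_step # arc element per dx
  seg <- (ds[-1] + ds[-length(ds)]) / 2
  dk <- diff(k) / seg
  L <- sum(seg)
  sum(dk^2 * seg) / L
}

# rigid rotation of an n x 2 point set
rotate_points <- function(p, angle, center = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(sweep(p, 2, center) %*% t(R), 2, -center)
}
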