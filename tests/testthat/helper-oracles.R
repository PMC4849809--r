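# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# Brute-force broken-stick oracle: scan a fine breakpoint grid, fitting at
# each candidate the constrained two-segment model by explicit
# normal-equation algebra (eliminating the upper intercept through the
# continuity constraint), and return the grid breakpoint with minimal RSS.
oracle_breakpoint <- function(po2, mo2, n_grid = 2001) {
  ord <- order(po2)
  x <- po2[ord]
  y <- mo2[ord]
  grid <- seq(min(x), max(x), length.out = n_grid)
  grid <- grid[grid > sort(x)[2] & grid < sort(x, decreasing = TRUE)[2]]
  best_rss <- Inf
  best_c <- NA
  for (c0 in grid) {
    lo <- x < c0
    if (sum(lo) < 2 || sum(!lo) < 2) next
    # model: y = a + b1*(x - c0) for x < c0, y = a + b2*(x - c0) otherwise
    z1 <- ifelse(lo, x - c0, 0)
    z2 <- ifelse(lo, 0, x - c0)
    A <- cbind(1, z1, z2)
    coef <- solve(t(A) %*% A, t(A) %*% y)
    rss <- sum((y - A %*% coef)^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best_c <- c0
    }
  }
  list(breakpoint = best_c, rss = best_rss)
}

# polynomial coefficient convolution (coefficients in increasing powers)
pmul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) out[i:(i + length(b) - 1)] <-
      out[i:(i + length(b) - 1)] + a[i] * b
  out
}
padd <- function(...) {
  ps <- list(...)
  n <- max(lengths(ps))
  Reduce(`+`, lapply(ps, function(p) c(p, numeric(n - length(p)))))
}

# Carbonate oracle: solve the total-alkalinity equation for [H+] as a
# polynomial root (polyroot), instead of the package's bracketed
# root-finding on pH. Constants are taken as given (they are pinned by
# design); what this checks is the solver.
oracle_pco2_from_ta_dic <- function(ta, dic, temperature, salinity) {
  k <- carb_constants(temperature, salinity)
  TAm <- ta * 1e-6
  DICm <- dic * 1e-6
  D <- c(k$K1 * k$K2, k$K1, 1)          # H^2 + K1 H + K1 K2, ascending
  B <- c(k$KB, 1)                        # KB + H
  H1 <- c(0, 1)                          # H
  # 0 = DIC*(K1 H + 2 K1 K2)*B*H + TB*KB*D*H + KW*D*B - (H^2/fH)*D*B - TA*D*B*H
  p <- padd(
    pmul(pmul(c(2 * k$K1 * k$K2, k$K1) * DICm, B), H1),
    pmul(k$TB * k$KB * D, H1),
    pmul(k$KW * D, B),
    -pmul(pmul(c(0, 0, 1 / k$fH), D), B),
    -pmul(pmul(TAm * D, B), H1))
  roots <- polyroot(p)
  h <- Re(roots[abs(Im(roots)) < 1e-12 * Mod(roots) & Re(roots) > 0])
  h <- h[h > 1e-13 & h < 1e-1]
  stopifnot(length(h) >= 1)
  h <- h[which.min(abs(log(h / 1e-8)))]   # the physically relevant root
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  co2 <- DICm * h^2 / denom
  list(pH = -log10(h), pco2 = co2 / k$K0 * 1e6)
}

# analytic two-point closed-chamber MO2, straight from the mass balance
oracle_mo2_two_point <- function(vr, vf, bw, c_start, c_end, dt) {
  (vr - vf) * (c_start - c_end) / (dt * bw)
}
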