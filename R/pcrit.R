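#' Estimate standard/routine metabolic rate from normoxic MO2 values
#'
#' Implements the SMR quantification conventions in common use: the single
#' lowest normoxic MO2, the mean of the N lowest values, an empirical
#' quantile of all normoxic values (linear interpolation), or
#' extrapolation of swimming MO2 back to zero activity (least-squares line
#' through ln(MO2) vs speed, exponentiated intercept).
#'
#' @param mo2 Numeric vector of normoxic MO2 values (mg O2 kg^-1 h^-1);
#'   at least 5 values for the first three methods.
#' @param method One of `"lowest"`, `"mean_lowest_n"`, `"quantile"`,
#'   `"zero_speed_extrapolation"`.
#' @param parameter Method parameter: N for `mean_lowest_n`
#'   (integer, `1 <= N <= length(mo2)`), probability p for `quantile`.
#'   Ignored otherwise.
#' @param speed Swimming speeds paired with `mo2`, required for
#'   `zero_speed_extrapolation` (all `mo2 > 0`).
#'
#' @return An object of class `smr_estimate`: list with `value`,
#'   `method`, `n_used`, `parameter`.
#' @examples
#' estimate_smr(c(10, 8, 12, 9, 11), "lowest")$value            # 8
#' estimate_smr(c(10, 8, 12, 9, 11), "mean_lowest_n", 2)$value  # 8.5
#' @export
estimate_smr <- function(mo2, method = c("lowest", "mean_lowest_n",
                                         "quantile",
                                         "zero_speed_extrapolation"),
                         parameter = NULL, speed = NULL) {
  method <- match.arg(method)
  if (method == "zero_speed_extrapolation") {
    if (is.null(speed) || length(speed) != length(mo2))
      stop("zero_speed_extrapolation needs (speed, mo2) pairs", call. = FALSE)
    if (any(mo2 <= 0))
      stop("non-positive MO2 cannot be log-extrapolated", call. = FALSE)
    fit <- stats::lm(log(mo2) ~ speed)
    value <- exp(unname(stats::coef(fit)[1]))
    return(structure(list(value = value, method = method,
                          n_used = length(mo2), parameter = NA_real_),
                     class = "smr_estimate"))
  }
  if (length(mo2) < 5)
    stop("need >= 5 normoxic MO2 values", call. = FALSE)
  value <- switch(method,
    lowest = min(mo2),
    mean_lowest_n = {
      n <- parameter
      if (is.null(n) || n < 1 || n > length(mo2) || n != round(n))
        stop("mean_lowest_n needs integer N in [1, length(mo2)]",
             call. = FALSE)
      mean(sort(mo2)[seq_len(n)])
    },
    quantile = {
      p <- parameter
      if (is.null(p) || p <= 0 || p >= 1)
        stop("quantile needs p in (0, 1)", call. = FALSE)
      unname(stats::quantile(mo2, p, type = 7))
    })
  structure(list(value = value, method = method,
                 n_used = if (method == "mean_lowest_n") as.integer(parameter)
                          else length(mo2),
                 parameter = parameter %||% NA_real_),
            class = "smr_estimate")
}

#' @export
print.smr_estimate <- function(x, ...) {
  cat(sprintf("SMR estimate: %.4g mg O2/kg/h (%s, n_used = %d)\n",
              x$value, x$method, x$n_used))
  invisible(x)
}

pcrit_result <- function(pcrit, method, classification, segment_above = NULL,
                         segment_below = NULL, rss_two = NA, rss_one = NA,
                         stat = NA, ci = NULL, extra = list()) {
  structure(c(list(pcrit = pcrit, method = method,
                   classification = classification,
                   segment_above = segment_above,
                   segment_below = segment_below,
                   rss_two_segment = rss_two, rss_one_segment = rss_one,
                   model_comparison_stat = stat,
                   confidence_interval = ci), extra),
            class = "pcrit_result")
}

#' @export
print.pcrit_result <- function(x, ...) {
  cat(sprintf("Pcrit (%s): ", x$method))
  if (x$classification == "oxyconformer") {
    cat("oxyconformer -- no discernible Pcrit\n")
  } else {
    cat(sprintf("%.3f kPa (oxyregulator)\n", x$pcrit))
    if (!is.null(x$confidence_interval))
      cat(sprintf("  bootstrap 95%% CI: [%.3f, %.3f] kPa\n",
                  x$confidence_interval[1], x$confidence_interval[2]))
  }
  invisible(x)
}

check_series <- function(series) {
  if (inherits(series, "mo2_series") || is.data.frame(series)) {
    po2 <- series$po2
    mo2 <- series$mo2
  } else stop("series must be an mo2_series or data frame with po2, mo2",
              call. = FALSE)
  if (length(po2) < 8)
    stop("Pcrit estimation needs >= 8 (po2, mo2) points", call. = FALSE)
  if (max(po2) < 4 * max(min(po2), 1e-12) && min(po2) > 0)
    stop("Pcrit estimation needs at least a 4-fold PO2 range", call. = FALSE)
  ord <- order(po2)
  list(po2 = po2[ord], mo2 = mo2[ord])
}

# Fit the continuous two-segment model with knot c:
#   mo2 = b0 + b1*min(po2-c, 0) + b2*max(po2-c, 0)
# Returns NULL if either side has < 2 points.
fit_two_segment <- function(po2, mo2, c0) {
  lo <- po2 < c0
  if (sum(lo) < 2 || sum(!lo) < 2) return(NULL)
  x1 <- pmin(po2 - c0, 0)
  x2 <- pmax(po2 - c0, 0)
  fit <- stats::lm.fit(cbind(1, x1, x2), mo2)
  b <- fit$coefficients
  rss <- sum(fit$residuals^2)
  list(breakpoint = c0, rss = rss,
       below = c(slope = unname(b[2]), intercept = unname(b[1] - b[2] * c0)),
       above = c(slope = unname(b[3]), intercept = unname(b[1] - b[3] * c0)),
       mo2_at_break = unname(b[1]))
}

bic_of_rss <- function(rss, n, k) n * log(rss / n) + k * log(n)

broken_stick_fit <- function(po2, mo2) {
  ux <- sort(unique(po2))
  interior <- ux[-c(1, length(ux))]
  cands <- sort(unique(c(interior, (ux[-1] + ux[-length(ux)]) / 2)))
  # continuous refinement: within each inter-point interval the RSS is a
  # smooth function of the knot, so polish the discrete scan with a 1-d
  # optimizer per admissible interval
  rss_at <- function(c0) {
    f <- fit_two_segment(po2, mo2, c0)
    if (is.null(f)) Inf else f$rss
  }
  polished <- numeric(0)
  for (i in seq_len(length(ux) - 1)) {
    if (is.finite(rss_at((ux[i] + ux[i + 1]) / 2))) {
      opt <- stats::optimize(rss_at, c(ux[i], ux[i + 1]), tol = 1e-8)
      polished <- c(polished, opt$minimum)
    }
  }
  # drop polished knots that merely re-find an admissible discrete
  # candidate, so exact breakpoints at observed PO2 stay exact
  adm <- cands[vapply(cands, function(c0) is.finite(rss_at(c0)), logical(1))]
  snap <- 1e-6 * diff(range(ux))
  if (length(adm))
    polished <- polished[vapply(polished,
                                function(p) min(abs(p - adm)) > snap,
                                logical(1))]
  cands <- sort(unique(c(cands, polished)))
  fits <- lapply(cands, function(c0) fit_two_segment(po2, mo2, c0))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("no admissible breakpoint (need >= 2 points each side)",
         call. = FALSE)
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  # ties broken toward lower PO2: candidates are sorted ascending
  tol <- 1e-10 * (min(rss) + stats::var(mo2))
  fits[[which(rss <= min(rss) + tol)[1]]]
}

#' Pcrit by broken-stick (segmented) regression
#'
#' Exhaustive search over candidate breakpoints (every interior observed
#' PO2 and the midpoints between adjacent PO2 values), fitting at each
#' candidate two least-squares line segments constrained to meet at the
#' breakpoint, and returning the breakpoint minimising the total residual
#' sum of squares (ties broken toward lower PO2). A single straight line
#' is also fitted; when BIC prefers it the series is classified an
#' oxyconformer and no Pcrit is reported.
#'
#' @param series An `mo2_series` (or data frame with `po2` in kPa and
#'   `mo2`), >= 8 points spanning at least a 4-fold PO2 range.
#' @param n_boot Number of residual-bootstrap resamples for a 95%
#'   confidence interval on the breakpoint (0 = no interval).
#' @param seed RNG seed for the bootstrap.
#'
#' @return A `pcrit_result` with the breakpoint (kPa), the two segment
#'   fits, RSS of the one- and two-segment models, the BIC difference
#'   (`model_comparison_stat = BIC_one - BIC_two`, positive favouring the
#'   breakpoint model) and the classification.
#' @export
pcrit_broken_stick <- function(series, n_boot = 0, seed = NULL) {
  s <- check_series(series)
  n <- length(s$po2)
  best <- broken_stick_fit(s$po2, s$mo2)
  one <- stats::lm.fit(cbind(1, s$po2), s$mo2)
  rss_one <- sum(one$residuals^2)
  # guard against log(0) on noiseless data
  eps <- max(1e-300, 1e-12 * sum(s$mo2^2))
  d_bic <- bic_of_rss(max(rss_one, eps), n, 2) -
    bic_of_rss(max(best$rss, eps), n, 4)
  conformer <- d_bic <= 0
  ci <- NULL
  if (!conformer && n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    fitted <- ifelse(s$po2 < best$breakpoint,
                     best$below["intercept"] + best$below["slope"] * s$po2,
                     best$above["intercept"] + best$above["slope"] * s$po2)
    resid <- s$mo2 - fitted
    bp <- vapply(seq_len(n_boot), function(i) {
      yb <- fitted + sample(resid, n, replace = TRUE)
      tryCatch(broken_stick_fit(s$po2, yb)$breakpoint, error = function(e) NA)
    }, numeric(1))
    ci <- unname(stats::quantile(bp, c(0.025, 0.975), na.rm = TRUE))
  }
  pcrit_result(pcrit = if (conformer) NA_real_ else best$breakpoint,
               method = "broken_stick",
               classification = if (conformer) "oxyconformer"
                                else "oxyregulator",
               segment_above = best$above, segment_below = best$below,
               rss_two = best$rss, rss_one = rss_one, stat = d_bic, ci = ci)
}

#' Pcrit as the intersection of the conforming line with the SMR/RMR level
#'
#' Fits a least-squares line through the points below a data-driven split
#' (the breakpoint found by the broken-stick search) and reports the PO2
#' at which that line crosses the horizontal SMR (or RMR) level.
#'
#' @param series As in [pcrit_broken_stick()].
#' @param smr An [estimate_smr()] result, or a single numeric SMR/RMR
#'   value (mg O2 kg^-1 h^-1).
#' @return A `pcrit_result`; `segment_above` is the horizontal SMR line.
#'   `pcrit = (SMR - intercept) / slope` of the conforming line. An SMR of
#'   0 is degenerate and flagged in `$degenerate`.
#' @export
pcrit_intersection <- function(series, smr) {
  s <- check_series(series)
  level <- if (inherits(smr, "smr_estimate")) smr$value else as.numeric(smr)
  split <- broken_stick_fit(s$po2, s$mo2)$breakpoint
  lo <- s$po2 < split
  fit <- stats::lm.fit(cbind(1, s$po2[lo]), s$mo2[lo])
  a <- unname(fit$coefficients[1])
  b <- unname(fit$coefficients[2])
  if (b <= 0) stop("conforming-segment slope <= 0: no intersection",
                   call. = FALSE)
  pc <- (level - a) / b
  pcrit_result(pcrit = pc, method = "regulation_intersection",
               classification = "oxyregulator",
               segment_above = c(slope = 0, intercept = level),
               segment_below = c(slope = b, intercept = a),
               rss_two = sum(fit$residuals^2), rss_one = NA,
               extra = list(smr = level, degenerate = level <= 0))
}

#' Pcrit from a saturating (Michaelis-Menten) fit
#'
#' Fits `MO2 = MO2max * PO2 / (K + PO2)` by least squares with
#' multi-start Levenberg-Marquardt, and reports as Pcrit the PO2 at which
#' the fitted curve reaches a given fraction of its asymptote:
#' `pcrit = fraction / (1 - fraction) * K` (so 0.9 gives `9 K`). The
#' fraction used is recorded in the result.
#'
#' @param series As in [pcrit_broken_stick()].
#' @param fraction Fraction of the asymptotic MO2 defining Pcrit
#'   (default 0.90).
#' @return A `pcrit_result` with `$mo2max`, `$K` and `$fraction`. A fitted
#'   `K` near zero (flat, saturated data) is flagged in `$degenerate`.
#' @export
pcrit_nonlinear <- function(series, fraction = 0.9) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  s <- check_series(series)
  df <- data.frame(po2 = s$po2, mo2 = s$mo2)
  mo2max0 <- max(s$mo2)
  starts <- lapply(c(0.05, 0.2, 0.5, 1, 2) * max(s$po2),
                   function(k0) list(mo2max = mo2max0, K = max(k0, 1e-6)))
  best <- NULL
  best_res <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(mo2 ~ mo2max * po2 / (K + po2), data = df,
                        start = st, lower = c(mo2max = 0, K = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_res) {
        best <- fit
        best_res <- rss
      }
    }
  }
  if (is.null(best))
    stop("nonlinear fit failed to converge from all starts (best residual ",
         format(best_res), ")", call. = FALSE)
  cf <- stats::coef(best)
  K <- unname(cf["K"])
  mo2max <- unname(cf["mo2max"])
  pc <- fraction / (1 - fraction) * K
  pcrit_result(pcrit = pc, method = "nonlinear_mm",
               classification = "oxyregulator",
               rss_two = best_res, rss_one = NA,
               extra = list(mo2max = mo2max, K = K, fraction = fraction,
                            degenerate = K < 1e-6 * max(s$po2)))
}
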