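#' Respirometer configuration
#'
#' Geometry, animal mass and operating mode of a respirometry chamber.
#'
#' @param volume_respirometer Chamber volume Vr, litres.
#' @param volume_fish Fish volume Vf, litres (`Vr > Vf >= 0`).
#' @param body_mass Fish mass bw, kilograms (> 0).
#' @param mode One of `"closed"`, `"flow_through"`, `"intermittent"`.
#' @param flow_rate Water flow Fw, litres per hour; required for
#'   `flow_through` mode.
#' @param conditions A [water_conditions()] object describing the water in
#'   the chamber (needed to convert between O2 units).
#' @param background_mo2 Optional blank (microbial) respiration rate,
#'   mg O2 kg^-1 h^-1, subtracted from every estimate. Default 0.
#'
#' @return An object of class `respirometer_config`.
#' @export
respirometer_config <- function(volume_respirometer, volume_fish, body_mass,
                                mode = c("closed", "flow_through",
                                         "intermittent"),
                                flow_rate = NULL, conditions = NULL,
                                background_mo2 = 0) {
  mode <- match.arg(mode)
  if (volume_respirometer <= volume_fish || volume_fish < 0)
    stop("need volume_respirometer > volume_fish >= 0", call. = FALSE)
  if (body_mass <= 0) stop("body_mass must be > 0", call. = FALSE)
  if (mode == "flow_through" && (is.null(flow_rate) || flow_rate <= 0))
    stop("flow_through mode requires flow_rate > 0", call. = FALSE)
  if (!is.null(conditions)) conditions <- as_water_conditions(conditions)
  structure(list(volume_respirometer = volume_respirometer,
                 volume_fish = volume_fish, body_mass = body_mass,
                 mode = mode, flow_rate = flow_rate, conditions = conditions,
                 background_mo2 = background_mo2),
            class = "respirometer_config")
}

#' Respirometry trace
#'
#' A time series of dissolved-oxygen readings from one chamber, with a
#' single O2 unit throughout and optional measure/flush phase labels for
#' intermittent-flow designs.
#'
#' @param time_h Sampling times in hours, strictly increasing, length >= 2.
#' @param o2 Dissolved-oxygen readings (>= 0), one per time point.
#' @param o2_unit The unit of `o2` (see [convert_o2()]).
#' @param config A [respirometer_config()].
#' @param phase Optional character vector of `"measure"`/`"flush"` labels,
#'   only meaningful (and only allowed to contain `"flush"`) in
#'   intermittent mode.
#'
#' @return An object of class `respirometry_trace` (a data frame with
#'   attributes `config` and `o2_unit`).
#' @export
respirometry_trace <- function(time_h, o2, o2_unit, config, phase = NULL) {
  stopifnot(inherits(config, "respirometer_config"))
  if (length(time_h) < 2) stop("need >= 2 samples", call. = FALSE)
  if (length(o2) != length(time_h)) stop("time_h and o2 lengths differ",
                                         call. = FALSE)
  if (any(diff(time_h) <= 0)) stop("time_h must be strictly increasing",
                                   call. = FALSE)
  if (any(o2 < 0)) stop("o2 values must be >= 0", call. = FALSE)
  o2_unit <- normalize_o2_unit(o2_unit)
  if (!is.null(phase)) {
    if (!all(phase %in% c("measure", "flush")))
      stop("phase labels must be 'measure' or 'flush'", call. = FALSE)
    if (any(phase == "flush") && config$mode != "intermittent")
      stop("flush-labelled samples only allowed in intermittent mode",
           call. = FALSE)
  }
  out <- data.frame(time_h = time_h, o2 = o2)
  if (!is.null(phase)) out$phase <- phase
  structure(out, class = c("respirometry_trace", "data.frame"),
            config = config, o2_unit = o2_unit)
}

#' @export
print.respirometry_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Respirometry trace: %d samples over %.3g h (%s mode, unit %s)\n",
              nrow(x), diff(range(x$time_h)), cfg$mode, attr(x, "o2_unit")))
  invisible(x)
}

# convert a trace's O2 readings to both mg/L and kPa
trace_concentration <- function(trace) {
  cfg <- attr(trace, "config")
  unit <- attr(trace, "o2_unit")
  cond <- cfg$conditions
  if (is.null(cond) && unit != "mg_per_L")
    stop("trace unit '", unit, "' needs water_conditions in the config",
         call. = FALSE)
  conc <- convert_o2(trace$o2, unit, "mg_per_L", cond)
  po2 <- if (is.null(cond)) rep(NA_real_, nrow(trace)) else
    convert_o2(trace$o2, unit, "kPa", cond)
  list(conc = conc, po2 = po2)
}

mo2_series <- function(po2, mo2, window_span, quality = NULL, r2 = NULL) {
  out <- data.frame(po2 = po2, mo2 = mo2)
  if (!is.null(r2)) out$r2 <- r2
  out$quality <- quality %||% rep("ok", length(po2))
  structure(out, class = c("mo2_series", "data.frame"),
            window_span = window_span)
}

#' @export
print.mo2_series <- function(x, ...) {
  cat(sprintf("MO2 series: %d windows (span %.3g h), PO2 %.2f-%.2f kPa\n",
              nrow(x), attr(x, "window_span") %||% NA,
              min(x$po2), max(x$po2)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

# least-squares slope of y on x; returns c(slope, r2)
ls_slope <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sxx <- sum(xm^2)
  slope <- sum(xm * ym) / sxx
  sst <- sum(ym^2)
  r2 <- if (sst == 0) 1 else 1 - sum((ym - slope * xm)^2) / sst
  c(slope = slope, r2 = r2)
}

#' MO2 from a closed respirometry trace
#'
#' Computes oxygen uptake per window from the closed-chamber balance
#' `MO2 = (Vr - Vf) * dO2 / (dt * bw)`, where `dO2/dt` is the
#' least-squares slope of O2 concentration (mg/L) against time within the
#' window (identical to the first-minus-last difference for 2-point
#' windows). MO2 is positive for declining O2; windows in which O2 rises
#' give MO2 <= 0 and are flagged `"suspect"` but retained.
#'
#' @param trace A [respirometry_trace()] with `mode = "closed"`.
#' @param window Window length: number of samples (when
#'   `window_unit = "samples"`, >= 2) or hours. Consecutive
#'   non-overlapping windows are used; a short trailing remainder is
#'   merged into the final window.
#' @param window_unit `"samples"` or `"hours"`.
#'
#' @return An `mo2_series` data frame with per-window mean `po2` (kPa),
#'   `mo2` (mg O2 kg^-1 h^-1), slope-fit `r2` and a `quality` flag.
#' @export
mo2_closed <- function(trace, window = 2, window_unit = c("samples", "hours")) {
  stopifnot(inherits(trace, "respirometry_trace"))
  cfg <- attr(trace, "config")
  if (cfg$mode != "closed") stop("trace mode is not 'closed'", call. = FALSE)
  window_unit <- match.arg(window_unit)
  n <- nrow(trace)
  if (window_unit == "samples") {
    k <- as.integer(window)
    if (k < 2) stop("window must cover >= 2 samples", call. = FALSE)
    if (k > n) stop("window longer than trace", call. = FALSE)
    idx <- split(seq_len(n), pmin((seq_len(n) - 1) %/% k, (n - 1) %/% k))
    # merge a 1-sample remainder into the previous window
    last <- idx[[length(idx)]]
    if (length(last) < 2 && length(idx) > 1) {
      idx[[length(idx) - 1]] <- c(idx[[length(idx) - 1]], last)
      idx[[length(idx)]] <- NULL
    }
  } else {
    if (window > diff(range(trace$time_h)))
      stop("window longer than trace", call. = FALSE)
    bin <- floor((trace$time_h - trace$time_h[1]) / window)
    idx <- split(seq_len(n), bin)
    idx <- Filter(function(i) length(i) >= 2, idx)
    if (!length(idx)) stop("no window covers >= 2 samples", call. = FALSE)
  }
  cc <- trace_concentration(trace)
  vol <- cfg$volume_respirometer - cfg$volume_fish
  res <- vapply(idx, function(i) {
    fit <- ls_slope(trace$time_h[i], cc$conc[i])
    mo2 <- vol * (-fit[["slope"]]) / cfg$body_mass - cfg$background_mo2
    c(po2 = mean(cc$po2[i]), mo2 = mo2, r2 = fit[["r2"]],
      span = diff(range(trace$time_h[i])))
  }, numeric(4))
  mo2_series(po2 = res["po2", ], mo2 = res["mo2", ],
             window_span = mean(res["span", ]),
             quality = ifelse(res["mo2", ] <= 0, "suspect", "ok"),
             r2 = res["r2", ])
}

#' MO2 from a flow-through respirometry trace
#'
#' Per-sample oxygen uptake from the steady-state balance
#' `MO2 = Fw * (C_in - C_out) / bw`, with inflow and outflow
#' concentrations in mg/L. Samples taken less than `washout` mean chamber
#' residence times (`Vr / Fw`) after the start of the trace or after a
#' change in inflow O2 are flagged `"equilibrating"`: the chamber has not
#' washed out and the steady-state balance is biased there.
#'
#' @param trace A [respirometry_trace()] with `mode = "flow_through"`;
#'   `trace$o2` is the outflow O2.
#' @param o2_in Inflow O2 readings, same length and unit as `trace$o2`.
#' @param washout Number of residence times to flag, default 3.
#'
#' @return An `mo2_series` with `po2` = outflow PO2 (kPa).
#' @export
mo2_flow_through <- function(trace, o2_in, washout = 3) {
  stopifnot(inherits(trace, "respirometry_trace"))
  cfg <- attr(trace, "config")
  if (cfg$mode != "flow_through")
    stop("trace mode is not 'flow_through'", call. = FALSE)
  if (is.null(cfg$flow_rate)) stop("flow_rate absent from config",
                                   call. = FALSE)
  if (length(o2_in) != nrow(trace))
    stop("o2_in must match the trace length", call. = FALSE)
  unit <- attr(trace, "o2_unit")
  cond <- cfg$conditions
  c_out <- convert_o2(trace$o2, unit, "mg_per_L", cond)
  c_in <- convert_o2(o2_in, unit, "mg_per_L", cond)
  mo2 <- cfg$flow_rate * (c_in - c_out) / cfg$body_mass - cfg$background_mo2
  tau <- cfg$volume_respirometer / cfg$flow_rate
  # times at which the inflow stepped (plus trace start)
  changes <- trace$time_h[c(TRUE, abs(diff(c_in)) > 1e-12 * pmax(c_in[-1], 1))]
  since <- vapply(trace$time_h,
                  function(t) t - max(changes[changes <= t]), numeric(1))
  flag <- ifelse(since < washout * tau, "equilibrating",
                 ifelse(mo2 <= 0, "suspect", "ok"))
  po2 <- trace_concentration(trace)$po2
  mo2_series(po2 = po2, mo2 = mo2, window_span = 0, quality = flag)
}

#' MO2 from an intermittent-flow respirometry trace
#'
#' One MO2 estimate per closed measurement phase, computed as in
#' [mo2_closed()] from the within-phase concentration slope; flush-phase
#' samples are excluded. Measurement phases with fewer than 3 samples are
#' skipped with a warning.
#'
#' @param trace A [respirometry_trace()] with `mode = "intermittent"` and
#'   phase labels.
#' @return An `mo2_series` with one row per usable measure phase,
#'   including the slope-fit `r2`.
#' @export
mo2_intermittent <- function(trace) {
  stopifnot(inherits(trace, "respirometry_trace"))
  cfg <- attr(trace, "config")
  if (cfg$mode != "intermittent")
    stop("trace mode is not 'intermittent'", call. = FALSE)
  if (is.null(trace$phase)) stop("phase labels required", call. = FALSE)
  runs <- rle(trace$phase)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values == "measure")
  if (!length(keep))
    return(mo2_series(numeric(0), numeric(0), window_span = 0,
                      r2 = numeric(0)))
  cc <- trace_concentration(trace)
  vol <- cfg$volume_respirometer - cfg$volume_fish
  rows <- lapply(keep, function(j) {
    i <- starts[j]:ends[j]
    if (length(i) < 3) {
      warning("measure phase with < 3 samples skipped", call. = FALSE)
      return(NULL)
    }
    fit <- ls_slope(trace$time_h[i], cc$conc[i])
    mo2 <- vol * (-fit[["slope"]]) / cfg$body_mass - cfg$background_mo2
    data.frame(po2 = mean(cc$po2[i]), mo2 = mo2, r2 = fit[["r2"]],
               span = diff(range(trace$time_h[i])))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(mo2_series(numeric(0), numeric(0), window_span = 0,
                      r2 = numeric(0)))
  mo2_series(po2 = rows$po2, mo2 = rows$mo2, window_span = mean(rows$span),
             quality = ifelse(rows$mo2 <= 0, "suspect", "ok"), r2 = rows$r2)
}
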