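#' Idealised fish metabolic profile
#'
#' The piecewise-linear abstraction of hypoxic metabolic responses: an
#' oxyregulator holds MO2 at its routine rate above Pcrit and declines
#' linearly through the origin below it; an obligate oxyconformer's MO2 is
#' proportional to ambient PO2 everywhere.
#'
#' @param kind `"regulator"` or `"conformer"`.
#' @param rmr Routine metabolic rate, mg O2 kg^-1 h^-1 (> 0; regulators).
#' @param pcrit Critical oxygen level, kPa (regulators; 0 < pcrit < 21).
#' @param conform_slope MO2 per kPa for conformers.
#' @param body_mass Fish mass, kg.
#' @return An object of class `fish_profile`.
#' @export
fish_profile <- function(kind = c("regulator", "conformer"), rmr = 100,
                         pcrit = 5, conform_slope = 10, body_mass = 0.1) {
  kind <- match.arg(kind)
  if (kind == "regulator") {
    if (rmr <= 0) stop("rmr must be > 0", call. = FALSE)
    if (pcrit <= 0 || pcrit >= 21)
      stop("regulator pcrit must be in (0, 21) kPa", call. = FALSE)
  } else if (conform_slope <= 0) {
    stop("conform_slope must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, rmr = rmr, pcrit = pcrit,
                 conform_slope = conform_slope, body_mass = body_mass),
            class = "fish_profile")
}

#' True MO2 at a given ambient PO2
#'
#' @param profile A [fish_profile()].
#' @param po2 Ambient PO2, kPa (>= 0); vectorised.
#' @return MO2 in mg O2 kg^-1 h^-1.
#' @examples
#' mo2_of_po2(fish_profile("regulator", rmr = 100, pcrit = 5), c(10, 2.5))
#' @export
mo2_of_po2 <- function(profile, po2) {
  stopifnot(inherits(profile, "fish_profile"), all(po2 >= 0))
  if (profile$kind == "regulator") {
    ifelse(po2 >= profile$pcrit, profile$rmr,
           profile$rmr * po2 / profile$pcrit)
  } else {
    profile$conform_slope * po2
  }
}

#' Simulation configuration for synthetic respirometry traces
#'
#' @param chamber A [respirometer_config()] (its `conditions` must be
#'   present; its `body_mass` is overridden by the fish profile's mass).
#' @param sampling_interval Probe sampling interval, hours (> 0).
#' @param noise_sd Relative (multiplicative) Gaussian noise on O2
#'   readings (>= 0).
#' @param seed Integer RNG seed, recorded in the output.
#' @param depletion `"fish_respiration"` (O2 falls through the fish's own
#'   uptake) or `"programmed_ramp"` (linear PO2 ramp at `ramp_rate`).
#' @param ramp_rate kPa per hour, programmed mode only.
#' @param duration Maximum simulated time, hours.
#' @param flush_schedule Optional list with `measure` and `flush` phase
#'   lengths in hours, to generate intermittent-flow traces.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chamber, sampling_interval = 0.01, noise_sd = 0,
                       seed = 1, depletion = c("fish_respiration",
                                               "programmed_ramp"),
                       ramp_rate = 4, duration = 12,
                       flush_schedule = NULL) {
  depletion <- match.arg(depletion)
  stopifnot(inherits(chamber, "respirometer_config"),
            sampling_interval > 0, noise_sd >= 0)
  if (is.null(chamber$conditions))
    stop("chamber conditions required to simulate O2 in physical units",
         call. = FALSE)
  structure(list(chamber = chamber, sampling_interval = sampling_interval,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 depletion = depletion, ramp_rate = ramp_rate,
                 duration = duration, flush_schedule = flush_schedule),
            class = "sim_config")
}

#' Simulate a closed (or intermittent) respirometry trace
#'
#' Integrates the chamber oxygen balance
#' `d[O2]/dt = -MO2(PO2) * bw / (Vr - Vf)` (concentration in mg/L,
#' `PO2 = [O2] / beta`) with fixed-step 4th-order Runge-Kutta at a step of
#' one tenth of the sampling interval, starting from air saturation.
#' Multiplicative Gaussian probe noise is applied at the sampling times.
#' Integration stops when PO2 reaches 0.5 kPa or at the configured
#' duration. With a `flush_schedule`, flush phases instantaneously
#' restore air saturation and samples are phase-labelled, producing an
#' intermittent-flow trace.
#'
#' @param profile A [fish_profile()].
#' @param config A [sim_config()].
#' @return A [respirometry_trace()] in mg/L, with attribute `"truth"`
#'   recording the generating profile, config and seed.
#' @export
simulate_closed_trace <- function(profile, config) {
  stopifnot(inherits(profile, "fish_profile"), inherits(config, "sim_config"))
  ch <- config$chamber
  vol <- ch$volume_respirometer - ch$volume_fish
  if (vol <= 0) stop("chamber volume must exceed fish volume", call. = FALSE)
  sol <- o2_solubility(ch$conditions)
  beta <- sol$beta
  bw <- profile$body_mass
  dt <- config$sampling_interval / 10

  deriv <- function(t, y, parms) {
    po2 <- max(y[1], 0) / beta
    dc <- if (config$depletion == "programmed_ramp") {
      -config$ramp_rate * beta
    } else {
      -mo2_of_po2(profile, po2) * bw / vol
    }
    list(dc)
  }

  intermittent <- !is.null(config$flush_schedule)
  t_grid <- seq(0, config$duration, by = dt)
  if (intermittent) {
    cyc <- config$flush_schedule$measure + config$flush_schedule$flush
    phase_of <- function(t) ifelse(t %% cyc < config$flush_schedule$measure,
                                   "measure", "flush")
    # integrate piecewise: reset to saturation at each flush
    conc <- numeric(length(t_grid))
    conc[1] <- sol$c_sat
    for (i in seq_along(t_grid)[-1]) {
      if (phase_of(t_grid[i]) == "flush") {
        conc[i] <- sol$c_sat
      } else if (phase_of(t_grid[i - 1]) == "flush") {
        conc[i] <- sol$c_sat   # measure phase restarts from saturation
      } else {
        step <- deSolve::rk4(c(conc[i - 1]), c(t_grid[i - 1], t_grid[i]),
                             deriv, NULL)
        conc[i] <- max(step[2, 2], 0)
      }
    }
  } else {
    out <- deSolve::rk4(c(sol$c_sat), t_grid, deriv, NULL)
    conc <- pmax(out[, 2], 0)
    stop_at <- which(conc / beta <= 0.5)[1]
    if (!is.na(stop_at)) {
      t_grid <- t_grid[seq_len(stop_at)]
      conc <- conc[seq_len(stop_at)]
    }
  }

  keep <- seq(1, length(t_grid), by = 10)
  set.seed(config$seed)
  noisy <- conc[keep] * (1 + stats::rnorm(length(keep), 0, config$noise_sd))
  noisy <- pmax(noisy, 0)
  cfg_mode <- if (intermittent) "intermittent" else "closed"
  chamber <- respirometer_config(ch$volume_respirometer, ch$volume_fish,
                                 bw, mode = cfg_mode,
                                 conditions = ch$conditions,
                                 background_mo2 = ch$background_mo2)
  trace <- respirometry_trace(t_grid[keep], noisy, "mg_per_L", chamber,
                              phase = if (intermittent)
                                phase_of(t_grid[keep]))
  attr(trace, "truth") <- list(profile = profile, config = config,
                               seed = config$seed, c_sat = sol$c_sat,
                               beta = beta)
  trace
}

#' Simulate an (PO2, MO2) series directly
#'
#' Evaluates a fish profile on a PO2 grid and adds multiplicative
#' Gaussian noise; the direct route to inputs for the Pcrit estimators.
#'
#' @param profile A [fish_profile()].
#' @param po2_grid Descending PO2 grid, kPa, >= 8 points.
#' @param noise_sd Relative noise SD (>= 0).
#' @param seed Integer RNG seed.
#' @return An `mo2_series` with attribute `"truth"`.
#' @export
simulate_mo2_series <- function(profile, po2_grid, noise_sd = 0.05,
                                seed = 1) {
  stopifnot(inherits(profile, "fish_profile"))
  if (length(po2_grid) < 8 || any(diff(po2_grid) >= 0))
    stop("po2_grid must be descending with >= 8 points", call. = FALSE)
  set.seed(seed)
  true <- mo2_of_po2(profile, po2_grid)
  mo2 <- true * (1 + stats::rnorm(length(po2_grid), 0, noise_sd))
  out <- mo2_series(po2 = po2_grid, mo2 = mo2, window_span = 0)
  attr(out, "truth") <- list(profile = profile, noise_sd = noise_sd,
                             seed = seed)
  out
}

# Table-4-style generating model: covariate means/SDs, predictor
# correlations (salinity, temperature, body mass, RMR) and the printed
# regression structure.
.db_defaults <- list(
  means = c(salinity = 23.54, temperature = 23.1, body_mass = 0.13,
            rmr = 23.84),
  sds = c(salinity = 15.36, temperature = 7.9, body_mass = 0.34,
          rmr = 34.04),
  # upper triangle in order (S,T) (S,M) (S,R) (T,M) (T,R) (M,R)
  cors = c(0.317, -0.165, 0.354, 0.366, -0.141, 0.166),
  coefs = c(salinity = 0.047, temperature = -0.083, body_mass = 1.931,
            rmr = 0.001),
  intercept = 5.689,
  adj_r2 = 0.195)

# mean and sd of a normal censored (not truncated: probability mass piles
# at the bounds) to [L, U]
censored_norm_moments <- function(mu, sigma, L = -Inf, U = Inf) {
  a <- (L - mu) / sigma
  b <- (U - mu) / sigma
  pa <- stats::pnorm(a); pb <- stats::pnorm(b)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  mid <- pb - pa
  m1 <- (if (is.finite(L)) L * pa else 0) +
    (if (is.finite(U)) U * (1 - pb) else 0) +
    mu * mid + sigma * (da - db)
  ez2 <- mu^2 * mid + 2 * mu * sigma * (da - db) +
    sigma^2 * (mid + (if (is.finite(a)) a * da else 0) -
                 (if (is.finite(b)) b * db else 0))
  m2 <- (if (is.finite(L)) L^2 * pa else 0) +
    (if (is.finite(U)) U^2 * (1 - pb) else 0) + ez2
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# pre-censoring (mu, sigma) such that the censored variable has the target
# mean and sd
calibrate_censored <- function(m, s, L = -Inf, U = Inf) {
  obj <- function(p) {
    mm <- censored_norm_moments(p[1], exp(p[2]), L, U)
    (mm["mean"] - m)^2 / s^2 + (mm["sd"] - s)^2 / s^2
  }
  fit <- stats::optim(c(unname(m), log(unname(s))), obj, method = "BFGS")
  c(mu = unname(fit$par[1]), sigma = exp(unname(fit$par[2])))
}

# latent-normal correlation needed so that, after exponentiation of the
# lognormal margins, the Pearson correlation hits `target`.
latent_cor <- function(target, sdlog1, sdlog2 = NULL) {
  if (is.null(sdlog2)) {                 # normal x lognormal pair
    target * sqrt(exp(sdlog1^2) - 1) / sdlog1
  } else {                               # lognormal x lognormal pair
    log(1 + target * sqrt((exp(sdlog1^2) - 1) * (exp(sdlog2^2) - 1))) /
      (sdlog1 * sdlog2)
  }
}

#' Generate a synthetic Pcrit trait database
#'
#' Draws (salinity, temperature, body mass, RMR) from a correlated
#' multivariate model with the covariate means, SDs and predictor
#' zero-order correlations of the trait-database regression analysis
#' (body mass and RMR lognormal, moment-matched, since their SDs exceed
#' their means; the latent normal correlations are adjusted so the
#' observed Pearson correlations converge to target), then generates
#' Pcrit from the linear model
#' `intercept + b.S*salinity + b.T*temperature + b.M*mass + b.R*RMR`
#' plus Gaussian noise calibrated so the population R^2 equals `adj_r2`.
#' Fed state, stressor, acclimation, latitude and method columns are
#' filled so that control-subset filtering and climate-zone analyses are
#' exercisable; the control-passing fraction is 297/331 by deterministic
#' allocation, so `n_rows = 331` yields exactly 297 control rows.
#'
#' @param n_rows Number of database rows (>= 50).
#' @param seed Integer RNG seed.
#' @param targets Optional overrides of the generating model: a list with
#'   any of `means`, `sds`, `cors`, `coefs`, `intercept`, `adj_r2`,
#'   `noise_sd` (setting `noise_sd = 0` gives exact linear data).
#' @return A data frame of database rows (classes `pcrit_db`), with the
#'   full generating parameter set (including the noise SD used and the
#'   seed) in attribute `"truth"`.
#' @export
generate_pcrit_database <- function(n_rows, seed = 1, targets = list()) {
  if (n_rows < 50) stop("n_rows must be >= 50", call. = FALSE)
  p <- utils::modifyList(.db_defaults, targets)
  set.seed(seed)

  mu <- p$means
  sd <- p$sds
  # lognormal parameters for body mass and RMR
  lp <- function(m, s) {
    m <- unname(m)
    s <- unname(s)
    s2 <- log(1 + (s / m)^2)
    c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }
  lm_ <- lp(mu["body_mass"], sd["body_mass"])
  lr <- lp(mu["rmr"], sd["rmr"])

  r <- p$cors
  lat <- diag(4)
  lat[1, 2] <- lat[2, 1] <- r[1]
  lat[1, 3] <- lat[3, 1] <- latent_cor(r[2], lm_["sdlog"])
  lat[1, 4] <- lat[4, 1] <- latent_cor(r[3], lr["sdlog"])
  lat[2, 3] <- lat[3, 2] <- latent_cor(r[4], lm_["sdlog"])
  lat[2, 4] <- lat[4, 2] <- latent_cor(r[5], lr["sdlog"])
  lat[3, 4] <- lat[4, 3] <- latent_cor(r[6], lm_["sdlog"], lr["sdlog"])
  ev <- eigen(lat, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    # the printed correlation targets are not jointly attainable with the
    # positivity-respecting lognormal margins; project to the nearest
    # positive-semidefinite latent matrix (eigenvalue floor, unit diagonal)
    lam <- pmax(ev$values, 1e-6)
    lat <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    d <- sqrt(diag(lat))
    lat <- lat / outer(d, d)
    ev <- eigen(lat, symmetric = TRUE)
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  z <- matrix(stats::rnorm(n_rows * 4), n_rows, 4) %*% L

  # physical bounds censor the normal margins; the pre-censoring moments
  # are calibrated so the observed mean/SD still hit the targets
  cs <- calibrate_censored(mu["salinity"], sd["salinity"], 0, 100)
  ct <- calibrate_censored(mu["temperature"], sd["temperature"], -1.5, 36)
  salinity <- pmin(pmax(cs["mu"] + cs["sigma"] * z[, 1], 0), 100)
  temperature <- pmin(pmax(ct["mu"] + ct["sigma"] * z[, 2], -1.5), 36)
  body_mass <- exp(lm_["meanlog"] + lm_["sdlog"] * z[, 3])
  rmr <- exp(lr["meanlog"] + lr["sdlog"] * z[, 4])

  b <- p$coefs
  signal <- p$intercept + b["salinity"] * salinity +
    b["temperature"] * temperature + b["body_mass"] * body_mass +
    b["rmr"] * rmr
  noise_sd <- if (!is.null(p$noise_sd)) p$noise_sd else {
    # population noise SD such that R^2 = adj_r2 under the generating model
    sig <- cbind(salinity, temperature, body_mass, rmr)
    var_sig <- stats::var(as.vector(sig %*% b))
    sqrt(var_sig * (1 - p$adj_r2) / p$adj_r2)
  }
  pcrit_kpa <- pmax(signal + stats::rnorm(n_rows, 0, noise_sd), 0.1)

  # deterministic control-subset structure: 297/331 of rows pass
  n_fail <- n_rows - round(n_rows * 297 / 331)
  fail_idx <- if (n_fail > 0) seq(1, n_rows, length.out = n_fail) else integer(0)
  fail_idx <- unique(round(fail_idx))
  fed_state <- rep("post_absorptive", n_rows)
  stressor <- rep(FALSE, n_rows)
  acclim <- rep(14, n_rows)
  reason <- rep_len(c("fed", "stressor", "acclimation"), length(fail_idx))
  fed_state[fail_idx[reason == "fed"]] <- "fed"
  stressor[fail_idx[reason == "stressor"]] <- TRUE
  acclim[fail_idx[reason == "acclimation"]] <- 2

  lat_deg <- stats::runif(n_rows, -70, 70)
  df <- data.frame(
    family = paste0("Family", sample.int(58, n_rows, replace = TRUE)),
    genus = paste0("Genus", sample.int(120, n_rows, replace = TRUE)),
    species = paste0("sp", sample.int(151, n_rows, replace = TRUE)),
    latitude = lat_deg,
    longitude = stats::runif(n_rows, -180, 180),
    acclimation_temperature = temperature,
    trial_temperature = unname(temperature),
    salinity = unname(salinity),
    body_mass = unname(body_mass),
    rmr = unname(rmr),
    pcrit_value = unname(pcrit_kpa),
    pcrit_unit = "kPa",
    respirometry_type = sample(c("closed_static_individual",
                                 "closed_static_grouped",
                                 "intermittent_flow", "open_flow_through"),
                               n_rows, replace = TRUE,
                               prob = c(0.6, 0.1, 0.2, 0.1)),
    o2_depletion = sample(c("fish_respiration", "n2_equilibration",
                            "gas_mix"), n_rows, replace = TRUE,
                          prob = c(0.7, 0.2, 0.1)),
    metabolic_baseline = sample(c("RMR", "SMR"), n_rows, replace = TRUE,
                                prob = c(0.84, 0.16)),
    fed_state = fed_state,
    additional_stressor = stressor,
    acclimation_days = acclim,
    stringsAsFactors = FALSE)
  attr(df, "truth") <- list(means = p$means, sds = p$sds, cors = p$cors,
                            latent_cor = lat,
                            coefs = p$coefs, intercept = p$intercept,
                            adj_r2 = p$adj_r2, noise_sd = noise_sd,
                            seed = seed)
  class(df) <- c("pcrit_db", "data.frame")
  df
}

#' Simulate freshwater vs seawater Pcrit groups with a common
#' concentration distribution
#'
#' Draws Pcrit *concentrations* (mg/L) for freshwater and seawater study
#' groups from one common lognormal distribution and converts each
#' record's value to kPa at its own temperature and salinity. Because
#' oxygen is more soluble in cold fresh water, identical concentration
#' thresholds translate into systematically lower partial-pressure
#' thresholds in the freshwater group (about 23% at the default
#' temperatures) -- the solubility artefact that a partial-pressure
#' comparison of freshwater and seawater species picks up while a
#' concentration comparison does not.
#'
#' @param n_fw,n_sw Group sizes (defaults 116 and 150).
#' @param seed Integer RNG seed.
#' @param mgl_mean,mgl_cv Mean and coefficient of variation of the shared
#'   Pcrit concentration distribution (mg/L).
#' @param fw_temp_range,sw_temp_range Uniform trial-temperature ranges
#'   (degC) for the two groups.
#' @return A data frame with `habitat`, `salinity`, `trial_temperature`,
#'   `pcrit_mgl`, `pcrit_kpa` per record.
#' @export
simulate_fw_sw_pcrit <- function(n_fw = 116, n_sw = 150, seed = 1,
                                 mgl_mean = 2.2, mgl_cv = 0.35,
                                 fw_temp_range = c(10, 15),
                                 sw_temp_range = c(14, 19)) {
  set.seed(seed)
  n <- n_fw + n_sw
  habitat <- rep(c("freshwater", "seawater"), c(n_fw, n_sw))
  salinity <- c(stats::runif(n_fw, 0, 0.5), stats::runif(n_sw, 30, 38))
  temperature <- c(stats::runif(n_fw, fw_temp_range[1], fw_temp_range[2]),
                   stats::runif(n_sw, sw_temp_range[1], sw_temp_range[2]))
  s2 <- log(1 + mgl_cv^2)
  mgl <- stats::rlnorm(n, log(mgl_mean) - s2 / 2, sqrt(s2))
  kpa <- vapply(seq_len(n), function(i)
    convert_o2(mgl[i], "mg_per_L", "kPa",
               water_conditions(temperature[i], salinity[i])), numeric(1))
  data.frame(habitat = habitat, salinity = salinity,
             trial_temperature = temperature, pcrit_mgl = mgl,
             pcrit_kpa = kpa, stringsAsFactors = FALSE)
}
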