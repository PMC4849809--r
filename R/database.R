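#' Load a Pcrit trait database from delimited text
#'
#' Reads a delimited file of Pcrit records, optionally renaming columns
#' through `column_map`, typing the schema fields it recognises and
#' validating each row. Rows missing a mandatory field (species,
#' pcrit_value, pcrit_unit, trial_temperature) are rejected with a logged
#' reason; unknown columns are passed through untouched.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping file headers to schema
#'   field names, e.g. `c("Species" = "species")`; `NULL` if the headers
#'   already match.
#' @param sep Field separator (default comma).
#' @return A data frame of records (class `pcrit_db`) with a per-row
#'   validation report in attribute `"report"` (columns `row`, `status`,
#'   `reason`).
#' @export
load_pcrit_database <- function(path, column_map = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    hit <- names(raw) %in% names(column_map)
    names(raw)[hit] <- column_map[names(raw)[hit]]
  }
  if (nrow(raw) == 0) {
    rep0 <- data.frame(row = integer(0), status = character(0),
                       reason = character(0))
    out <- raw
    class(out) <- c("pcrit_db", "data.frame")
    attr(out, "report") <- rep0
    return(out)
  }
  numeric_fields <- c("latitude", "longitude", "acclimation_temperature",
                      "trial_temperature", "salinity", "body_mass", "rmr",
                      "pcrit_value", "acclimation_days")
  for (f in intersect(numeric_fields, names(raw)))
    raw[[f]] <- suppressWarnings(as.numeric(raw[[f]]))
  if ("additional_stressor" %in% names(raw))
    raw$additional_stressor <- as.logical(raw$additional_stressor)

  mandatory <- c("species", "pcrit_value", "pcrit_unit", "trial_temperature")
  reason <- rep(NA_character_, nrow(raw))
  for (f in mandatory) {
    bad <- if (f %in% names(raw)) is.na(raw[[f]]) | raw[[f]] == ""
           else rep(TRUE, nrow(raw))
    reason[bad & is.na(reason)] <- paste0("missing_", f)
  }
  bad_val <- !is.na(raw$pcrit_value) & raw$pcrit_value <= 0
  reason[bad_val & is.na(reason)] <- "nonpositive_pcrit"
  if ("latitude" %in% names(raw)) {
    bad_lat <- !is.na(raw$latitude) & abs(raw$latitude) > 90
    reason[bad_lat & is.na(reason)] <- "invalid_latitude"
  }
  keep <- is.na(reason)
  report <- data.frame(row = seq_len(nrow(raw)),
                       status = ifelse(keep, "ok", "rejected"),
                       reason = ifelse(keep, "", reason))
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pcrit_db", "data.frame")
  attr(out, "report") <- report
  out
}

#' Harmonize Pcrit units across a database
#'
#' Attaches to every record its Pcrit as a partial pressure in kPa
#' (`pcrit_kpa`) and, where trial temperature and salinity are both
#' present, as a concentration in mg/L (`pcrit_mgl`), using
#' [convert_o2()] at the record's own conditions (barometric pressure 760
#' mmHg unless a `barometric_pressure` column is present). Pure
#' pressure-unit records convert to kPa without conditions; conversions
#' that need missing conditions leave the value `NA` and set
#' `conversion_flag`. Idempotent: re-running recomputes the same values.
#'
#' @param records A `pcrit_db` data frame with `pcrit_value`,
#'   `pcrit_unit`, `trial_temperature` and optionally `salinity`.
#' @return The records with `pcrit_kpa`, `pcrit_mgl` and
#'   `conversion_flag` columns appended.
#' @export
harmonize_units <- function(records) {
  n <- nrow(records)
  kpa <- rep(NA_real_, n)
  mgl <- rep(NA_real_, n)
  flag <- rep("", n)
  pres <- if ("barometric_pressure" %in% names(records))
    records$barometric_pressure else rep(760, n)
  for (i in seq_len(n)) {
    unit <- normalize_o2_unit(records$pcrit_unit[i])
    t <- records$trial_temperature[i]
    s <- if ("salinity" %in% names(records)) records$salinity[i] else NA
    cond <- if (!is.na(t) && !is.na(s))
      water_conditions(t, s, ifelse(is.na(pres[i]), 760, pres[i]))
    if (unit %in% c("kPa", "mmHg", "torr")) {
      kpa[i] <- convert_o2(records$pcrit_value[i], unit, "kPa")
    } else if (!is.null(cond)) {
      kpa[i] <- convert_o2(records$pcrit_value[i], unit, "kPa", cond)
    } else {
      flag[i] <- "kpa_needs_conditions"
      next
    }
    if (!is.null(cond)) {
      mgl[i] <- convert_o2(kpa[i], "kPa", "mg_per_L", cond)
    } else {
      flag[i] <- "mgl_needs_conditions"
    }
  }
  records$pcrit_kpa <- kpa
  records$pcrit_mgl <- mgl
  records$conversion_flag <- flag
  records
}

#' Control subset of a Pcrit database
#'
#' Applies the inclusion rules used to build an unbiased comparison set:
#' fish (i) unfed or post-absorptive, (ii) under no abiotic stressor other
#' than hypoxia, and (iii) temperature-acclimated for more than 2 days
#' (strictly). Records missing any of the three fields are excluded with
#' reason `"missing_field"`; nothing is thrown, every exclusion is logged.
#'
#' @param records A `pcrit_db` data frame with `fed_state`,
#'   `additional_stressor`, `acclimation_days`.
#' @return A list of class `control_subset`: `records` (the included
#'   rows) and `exclusion_log` (row index + reason per excluded row).
#' @export
control_subset <- function(records) {
  n <- nrow(records)
  need <- c("fed_state", "additional_stressor", "acclimation_days")
  reason <- rep(NA_character_, n)
  for (f in need) {
    miss <- if (f %in% names(records)) is.na(records[[f]]) else rep(TRUE, n)
    reason[miss & is.na(reason)] <- "missing_field"
  }
  ok <- is.na(reason)
  fed_bad <- ok & !(records$fed_state %in% c("unfed", "post_absorptive"))
  reason[fed_bad] <- "fed"
  ok <- is.na(reason)
  str_bad <- ok & records$additional_stressor
  reason[str_bad] <- "stressor"
  ok <- is.na(reason)
  acc_bad <- ok & !(records$acclimation_days > 2)
  reason[acc_bad] <- "acclimation"
  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  log <- data.frame(row = which(!keep), reason = reason[!keep])
  stopifnot(nrow(out) + nrow(log) == n)
  structure(list(records = out, exclusion_log = log),
            class = "control_subset")
}

#' @export
print.control_subset <- function(x, ...) {
  cat(sprintf("Control subset: %d included, %d excluded\n",
              nrow(x$records), nrow(x$exclusion_log)))
  if (nrow(x$exclusion_log))
    print(table(x$exclusion_log$reason))
  invisible(x)
}

#' Climate zone from latitude
#'
#' Labels latitudes by climate band. Default cutoffs are the astronomical
#' tropic (23.44 deg) and polar (66.56 deg) circles with a conventional
#' 35 deg subtropical boundary; all three are configurable.
#'
#' @param latitude Decimal degrees, |latitude| <= 90; vectorised. `NA`
#'   gives `NA`.
#' @param cutoffs Numeric vector of the three ascending |latitude|
#'   boundaries tropical/subtropical/temperate.
#' @return Character vector of `"tropical"`, `"subtropical"`,
#'   `"temperate"`, `"polar"`.
#' @examples
#' assign_climate_zone(c(-14.67, 0, 70))
#' @export
assign_climate_zone <- function(latitude, cutoffs = c(23.44, 35, 66.56)) {
  stopifnot(length(cutoffs) == 3, !is.unsorted(cutoffs))
  if (any(abs(latitude) > 90, na.rm = TRUE))
    stop("|latitude| must be <= 90", call. = FALSE)
  al <- abs(latitude)
  ifelse(is.na(al), NA_character_,
         ifelse(al <= cutoffs[1], "tropical",
                ifelse(al <= cutoffs[2], "subtropical",
                       ifelse(al <= cutoffs[3], "temperate", "polar"))))
}

#' One-way ANOVA of Pcrit across climate zones with Sidak post hoc tests
#'
#' Fixed-effects one-way ANOVA of Pcrit (kPa) on climate zone over the
#' tropical/subtropical/temperate bands -- polar records are excluded
#' (there are never enough of them) -- followed by all pairwise
#' comparisons using the ANOVA mean-square error, with Sidak-adjusted
#' p-values (`p_adj = 1 - (1 - p)^m` over the m comparisons).
#'
#' @param subset A `control_subset` or `pcrit_db` data frame with
#'   `pcrit_kpa` and either a `climate_zone` column or `latitude`.
#' @param zones Zones entering the ANOVA.
#' @return A list of class `zone_anova`: `anova` (the `aov` summary
#'   table), `f`, `df`, `p`, `group_stats`, and `pairwise` (mean
#'   difference, t, raw and Sidak-adjusted p per zone pair).
#' @export
zone_anova <- function(subset, zones = c("tropical", "subtropical",
                                         "temperate")) {
  df <- if (inherits(subset, "control_subset")) subset$records else subset
  if (is.null(df$pcrit_kpa)) df <- harmonize_units(df)
  if (is.null(df$climate_zone)) df$climate_zone <- assign_climate_zone(df$latitude)
  df <- df[!is.na(df$climate_zone) & df$climate_zone %in% zones &
             !is.na(df$pcrit_kpa), , drop = FALSE]
  sizes <- table(factor(df$climate_zone, levels = zones))
  if (sum(sizes >= 2) < 2)
    stop("need >= 2 zones with >= 2 records; sizes: ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "),
         call. = FALSE)
  df$climate_zone <- factor(df$climate_zone,
                            levels = zones[zones %in% df$climate_zone])
  fit <- stats::aov(pcrit_kpa ~ climate_zone, data = df)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  mse <- tab["Residuals", "Mean Sq"]
  dfr <- tab["Residuals", "Df"]
  gs <- do.call(rbind, lapply(split(df$pcrit_kpa, df$climate_zone),
    function(v) data.frame(n = length(v), mean = mean(v),
                           sem = stats::sd(v) / sqrt(length(v)))))
  gs$zone <- rownames(gs)
  pairs <- utils::combn(levels(df$climate_zone), 2)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    na <- gs[a, "n"]; nb <- gs[b, "n"]
    diff <- gs[a, "mean"] - gs[b, "mean"]
    t <- diff / sqrt(mse * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(t), dfr)
    data.frame(zone_a = a, zone_b = b, mean_diff = diff, t = t,
               p_raw = p, p_sidak = 1 - (1 - p)^m)
  }))
  structure(list(anova = tab,
                 f = tab["climate_zone", "F value"],
                 df = c(tab["climate_zone", "Df"], dfr),
                 p = tab["climate_zone", "Pr(>F)"],
                 group_stats = gs, pairwise = pw),
            class = "zone_anova")
}

#' @export
print.zone_anova <- function(x, ...) {
  cat(sprintf("Climate-zone ANOVA: F(%d,%d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f, x$p))
  print(x$group_stats[, c("zone", "n", "mean", "sem")], row.names = FALSE)
  cat("Sidak pairwise comparisons:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Within-species comparisons of respirometry methods
#'
#' For every species represented by more than two records under each of
#' at least two respirometry types, runs Student's unpaired two-sample
#' t-tests (equal variances) on Pcrit (kPa) between each pair of methods.
#'
#' @param subset A `control_subset` or `pcrit_db` data frame with
#'   `species`, `respirometry_type`, `pcrit_kpa`.
#' @param min_n Minimum records per method (strictly greater than;
#'   default 2, i.e. n > 2).
#' @return A data frame with one row per species x method pair: `species`,
#'   `method_a`, `method_b`, `n_a`, `n_b`, `t`, `df`, `p`. Empty (with a
#'   warning) when no species qualifies.
#' @export
method_comparisons <- function(subset, min_n = 2) {
  df <- if (inherits(subset, "control_subset")) subset$records else subset
  if (is.null(df$pcrit_kpa)) df <- harmonize_units(df)
  df <- df[!is.na(df$pcrit_kpa), , drop = FALSE]
  out <- list()
  for (sp in unique(df$species)) {
    d <- df[df$species == sp, , drop = FALSE]
    counts <- table(d$respirometry_type)
    meth <- names(counts)[counts > min_n]
    if (length(meth) < 2) next
    pairs <- utils::combn(meth, 2)
    for (j in seq_len(ncol(pairs))) {
      xa <- d$pcrit_kpa[d$respirometry_type == pairs[1, j]]
      xb <- d$pcrit_kpa[d$respirometry_type == pairs[2, j]]
      tt <- stats::t.test(xa, xb, var.equal = TRUE)
      out[[length(out) + 1]] <- data.frame(
        species = sp, method_a = pairs[1, j], method_b = pairs[2, j],
        n_a = length(xa), n_b = length(xb),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
    }
  }
  if (!length(out)) {
    warning("no species with > ", min_n, " records under >= 2 methods",
            call. = FALSE)
    return(data.frame(species = character(0), method_a = character(0),
                      method_b = character(0), n_a = integer(0),
                      n_b = integer(0), t = numeric(0), df = numeric(0),
                      p = numeric(0)))
  }
  do.call(rbind, out)
}

# Mann-Whitney U with tie-corrected normal approximation
mann_whitney <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  z <- (u1 - n1 * n2 / 2) / sigma
  list(U = u1, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Freshwater vs seawater comparison of Pcrit
#'
#' Mann-Whitney U tests (normal approximation with tie correction)
#' comparing Pcrit between freshwater and seawater records, run
#' separately on the partial-pressure (kPa) and concentration (mg/L)
#' representations. The two representations can disagree: identical
#' concentration thresholds map to lower partial pressures in fresh
#' water because oxygen is more soluble there.
#'
#' @param subset A `control_subset` or data frame; records are classed
#'   freshwater when `salinity <= fw_max` and seawater when
#'   `salinity >= sw_min` (others are dropped). Alternatively an existing
#'   `habitat` column of `"freshwater"`/`"seawater"` is honoured. Needs
#'   `pcrit_kpa` and (for the concentration test) `pcrit_mgl`.
#' @param fw_max,sw_min Salinity cutoffs, PSU.
#' @return A list of class `salinity_comparison` with one element per
#'   representation (`kpa`, `mgl`), each containing `U`, `z`, `p`, group
#'   `n`, medians, means, and `percent_diff_means` (freshwater relative
#'   to seawater).
#' @export
salinity_comparison <- function(subset, fw_max = 1, sw_min = 25) {
  df <- if (inherits(subset, "control_subset")) subset$records else subset
  if (is.null(df$pcrit_kpa) && !is.null(df$pcrit_value))
    df <- harmonize_units(df)
  if (is.null(df$habitat)) {
    df$habitat <- ifelse(df$salinity <= fw_max, "freshwater",
                         ifelse(df$salinity >= sw_min, "seawater", NA))
  }
  df <- df[!is.na(df$habitat), , drop = FALSE]
  one <- function(values) {
    fw <- values[df$habitat == "freshwater" & !is.na(values)]
    sw <- values[df$habitat == "seawater" & !is.na(values)]
    if (!length(fw) || !length(sw))
      stop("both freshwater and seawater groups must be non-empty",
           call. = FALSE)
    mw <- mann_whitney(fw, sw)
    c(mw, list(n_fw = length(fw), n_sw = length(sw),
               median_fw = stats::median(fw), median_sw = stats::median(sw),
               mean_fw = mean(fw), mean_sw = mean(sw),
               percent_diff_means = 100 * (mean(fw) - mean(sw)) / mean(sw)))
  }
  out <- list(kpa = one(df$pcrit_kpa))
  if (!is.null(df$pcrit_mgl)) out$mgl <- one(df$pcrit_mgl)
  structure(out, class = "salinity_comparison")
}

#' @export
print.salinity_comparison <- function(x, ...) {
  for (nm in names(x)) {
    e <- x[[nm]]
    cat(sprintf(
      "%s: U = %.1f, z = %.3f, p = %.4g | FW mean %.3f vs SW mean %.3f (%.1f%%)\n",
      nm, e$U, e$z, e$p, e$mean_fw, e$mean_sw, e$percent_diff_means))
  }
  invisible(x)
}

#' Multiple linear regression of Pcrit on environmental and biotic
#' covariates
#'
#' Ordinary least squares of Pcrit (kPa) on salinity, temperature, body
#' mass and RMR over complete cases, either as the full model or with
#' forward stepwise selection (F-test to enter at `p_enter`). Reports raw
#' coefficients b, standardized coefficients beta, squared semipartial
#' correlations sr2, the intercept, adjusted r2 and the overall F test.
#'
#' @param subset A `control_subset` or data frame with `pcrit_kpa`,
#'   `salinity`, `trial_temperature` (or `temperature`), `body_mass`,
#'   `rmr`.
#' @param selection `"none"` (full model) or `"stepwise"` (forward).
#' @param p_enter Entry threshold for forward selection (default 0.05).
#' @return A list of class `pcrit_regression`: `coefficients` (data frame
#'   with `b`, `beta`, `sr2` per predictor), `intercept`, `adj_r2`, `f`,
#'   `df`, `p`, `n`, `selection_log`, and the underlying `lm` fit.
#' @export
pcrit_regression <- function(subset, selection = c("none", "stepwise"),
                             p_enter = 0.05) {
  selection <- match.arg(selection)
  df <- if (inherits(subset, "control_subset")) subset$records else subset
  if (is.null(df$pcrit_kpa)) df <- harmonize_units(df)
  if (is.null(df$temperature) && !is.null(df$trial_temperature))
    df$temperature <- df$trial_temperature
  vars <- c("salinity", "temperature", "body_mass", "rmr")
  df <- df[stats::complete.cases(df[, c("pcrit_kpa", vars)]),
           c("pcrit_kpa", vars), drop = FALSE]
  n <- nrow(df)
  log <- character(0)
  usable <- vars[vapply(vars, function(v) stats::sd(df[[v]]) > 0, logical(1))]
  for (v in setdiff(vars, usable))
    log <- c(log, paste0(v, ": constant predictor excluded"))

  if (selection == "stepwise") {
    included <- character(0)
    candidates <- usable
    repeat {
      if (!length(candidates)) break
      base_f <- stats::as.formula(paste("pcrit_kpa ~",
        if (length(included)) paste(included, collapse = " + ") else "1"))
      base <- stats::lm(base_f, data = df)
      adds <- stats::add1(base, scope = stats::as.formula(
        paste("~", paste(c(included, candidates), collapse = " + "))),
        test = "F")
      pvals <- adds[candidates, "Pr(>F)"]
      best <- which.min(pvals)
      if (!length(best) || is.na(pvals[best]) || pvals[best] >= p_enter) break
      log <- c(log, sprintf("enter %s (F-test p = %.3g)",
                            candidates[best], pvals[best]))
      included <- c(included, candidates[best])
      candidates <- candidates[-best]
    }
    for (v in candidates)
      log <- c(log, sprintf("%s: not entered (p >= %.2g)", v, p_enter))
    usable <- included
    if (!length(usable)) stop("no predictor met the entry criterion",
                              call. = FALSE)
  }

  X <- as.matrix(df[, usable, drop = FALSE])
  if (kappa(cbind(1, X)) > 1e10)
    stop("collinear design: condition number > 1e10", call. = FALSE)
  fit <- stats::lm(stats::as.formula(
    paste("pcrit_kpa ~", paste(usable, collapse = " + "))), data = df)
  sm <- summary(fit)
  b <- stats::coef(fit)[usable]
  beta <- b * vapply(usable, function(v) stats::sd(df[[v]]), numeric(1)) /
    stats::sd(df$pcrit_kpa)
  tvals <- sm$coefficients[usable, "t value"]
  sr2 <- tvals^2 * (1 - sm$r.squared) / fit$df.residual
  fstat <- sm$fstatistic
  structure(list(
    coefficients = data.frame(predictor = usable, b = unname(b),
                              beta = unname(beta), sr2 = unname(sr2)),
    intercept = unname(stats::coef(fit)[1]),
    adj_r2 = sm$adj.r.squared,
    f = unname(fstat[1]), df = unname(fstat[2:3]),
    p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = n, selection = selection, selection_log = log, fit = fit),
    class = "pcrit_regression")
}

#' @export
print.pcrit_regression <- function(x, ...) {
  cat(sprintf(
    "Pcrit regression (%s, n = %d): F(%g,%g) = %.3f, p = %.3g, adj r2 = %.3f\n",
    x$selection, x$n, x$df[1], x$df[2], x$f, x$p, x$adj_r2))
  cat(sprintf("Intercept = %.4g\n", x$intercept))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
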