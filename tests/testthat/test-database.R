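make_db_file <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("database loading validates rows and preserves unknown columns", {
  db <- generate_pcrit_database(331, seed = 4)
  db$lab_notes <- "free text"
  path <- make_db_file(db)
  got <- load_pcrit_database(path)
  expect_equal(nrow(got), 331)
  expect_true(all(attr(got, "report")$status == "ok"))
  expect_true("lab_notes" %in% names(got))

  # empty table
  empty <- make_db_file(db[0, ])
  got0 <- load_pcrit_database(empty)
  expect_equal(nrow(got0), 0)
  expect_equal(nrow(attr(got0, "report")), 0)

  # a record in mmHg is stored, not rejected; missing mandatory fields are
  bad <- db[1:3, ]
  bad$pcrit_unit[1] <- "mmHg"
  bad$species[2] <- ""
  bad$pcrit_value[3] <- NA
  got_bad <- load_pcrit_database(make_db_file(bad))
  expect_equal(nrow(got_bad), 1)
  expect_equal(got_bad$pcrit_unit, "mmHg")
  expect_setequal(attr(got_bad, "report")$reason[2:3],
                  c("missing_species", "missing_pcrit_value"))

  # column_map renames file headers into the schema
  ren <- db[1:5, ]
  names(ren)[names(ren) == "species"] <- "Species name"
  got_map <- load_pcrit_database(make_db_file(ren),
                                 column_map = c("Species name" = "species"))
  expect_equal(nrow(got_map), 5)
})

test_that("unit harmonization attaches kPa and mg/L representations", {
  db <- data.frame(species = "sp1",
                   pcrit_value = c(38.6, 6, 6, 5, 2),
                   pcrit_unit = c("mmHg", "kPa", "kPa", "mg_per_L",
                                  "umol_per_L"),
                   trial_temperature = c(15, 15, 15, 15, NA),
                   salinity = c(NA, 35, 0, 35, 35))
  h <- harmonize_units(db)
  expect_equal(h$pcrit_kpa[1], 38.6 * 101.325 / 760, tolerance = 1e-12)
  expect_true(is.na(h$pcrit_mgl[1]))   # no salinity: flagged, not fatal
  expect_equal(h$conversion_flag[1], "mgl_needs_conditions")
  # cross-check against the solubility module
  expect_equal(h$pcrit_mgl[2],
               convert_o2(6, "kPa", "mg_per_L", water_conditions(15, 35)))
  # same kPa in fresh vs salt water differs in concentration
  expect_gt(h$pcrit_mgl[3], h$pcrit_mgl[2])
  # concentration unit without conditions cannot reach kPa
  expect_true(is.na(h$pcrit_kpa[5]))
  expect_equal(h$conversion_flag[5], "kpa_needs_conditions")
  # idempotent
  expect_identical(harmonize_units(h)$pcrit_kpa, h$pcrit_kpa)
  expect_identical(harmonize_units(h)$pcrit_mgl, h$pcrit_mgl)
})

test_that("control-subset rules partition the database exhaustively", {
  db <- data.frame(species = paste0("sp", 1:6),
                   fed_state = c("fed", "unfed", "post_absorptive", "unfed",
                                 "unfed", NA),
                   additional_stressor = c(FALSE, TRUE, FALSE, FALSE, FALSE,
                                           FALSE),
                   acclimation_days = c(10, 10, 10, 2, 3, 10))
  cs <- control_subset(db)
  expect_equal(nrow(cs$records), 2)   # rows 3 and 5
  expect_equal(cs$exclusion_log$reason,
               c("fed", "stressor", "acclimation", "missing_field"))
  expect_equal(nrow(cs$records) + nrow(cs$exclusion_log), nrow(db))

  # the synthetic full database is built to the 331 -> 297 structure
  big <- control_subset(generate_pcrit_database(331, seed = 9))
  expect_equal(nrow(big$records), 297)
})

test_that("climate zones are assigned by configurable latitude bands", {
  expect_equal(assign_climate_zone(c(-14.67, 0, 70, -30, 50)),
               c("tropical", "tropical", "polar", "subtropical",
                 "temperate"))
  expect_true(is.na(assign_climate_zone(NA)))
  expect_error(assign_climate_zone(100), "latitude")
  # cutoffs are configurable and totally ordered
  expect_equal(assign_climate_zone(30, cutoffs = c(15, 25, 60)), "temperate")
  lat <- seq(-90, 90, by = 0.5)
  expect_false(anyNA(assign_climate_zone(lat)))
})

test_that("zone ANOVA with Sidak post hoc behaves at its edge cases", {
  df <- data.frame(pcrit_kpa = rep(c(4, 5, 6), 3),
                   climate_zone = rep(c("tropical", "subtropical",
                                        "temperate"), each = 3))
  fit <- zone_anova(df)
  expect_equal(fit$f, 0)
  expect_equal(fit$p, 1)
  # large separation is detected
  df2 <- data.frame(pcrit_kpa = c(rnorm(20, 5, 0.5), rnorm(20, 10, 0.5)),
                    climate_zone = rep(c("tropical", "temperate"), each = 20))
  expect_lt(zone_anova(df2)$p, 1e-6)
  expect_error(zone_anova(df[1, , drop = FALSE]), "zones")
})

test_that("a zone-structured subset reproduces a modest climate effect", {
  set.seed(31)
  n <- c(tropical = 118, subtropical = 96, temperate = 86)
  means <- c(4.92, 5.0, 5.74)
  sds <- c(0.190 * sqrt(118), 0.24 * sqrt(96), 0.24 * sqrt(86))
  df <- data.frame(
    pcrit_kpa = unlist(mapply(rnorm, n, means, sds, SIMPLIFY = FALSE)),
    climate_zone = rep(names(n), n))
  fit <- zone_anova(df)
  # in the vicinity of the weak effect such means/SEMs imply
  expect_gt(fit$f, 0.5)
  expect_lt(fit$f, 12)
  expect_equal(sum(fit$df), 2 + sum(n) - 3)
  expect_equal(nrow(fit$pairwise), 3)
  expect_true(all(fit$pairwise$p_sidak >= fit$pairwise$p_raw))
})

test_that("within-species method comparisons run Student's t-tests", {
  df <- data.frame(species = rep("carp", 8),
                   respirometry_type = rep(c("closed_static_individual",
                                             "intermittent_flow"), each = 4),
                   pcrit_kpa = c(5, 6, 5.5, 6.5, 5, 6, 5.5, 6.5))
  out <- method_comparisons(df)
  expect_equal(nrow(out), 1)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  expect_equal(out$df, 6)
  # a shifted group is flagged
  df$pcrit_kpa[5:8] <- df$pcrit_kpa[5:8] + 10
  expect_lt(method_comparisons(df)$p, 1e-5)
  # n = 2 per method is not enough (needs n > 2)
  expect_warning(method_comparisons(df[c(1:2, 5:6), ]), "no species")
})

test_that("no method effect means few significant within-species tests", {
  n_sig <- 0
  for (seed in 1:100) {
    set.seed(seed)
    df <- data.frame(species = rep("carp", 8),
                     respirometry_type = rep(c("closed", "intermittent"),
                                             each = 4),
                     pcrit_kpa = rnorm(8, 5, 0.8))
    if (method_comparisons(df)$p < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 10)
})

test_that("Mann-Whitney statistics match the reference implementation", {
  set.seed(15)
  for (i in 1:20) {
    x <- round(rnorm(25, 5, 2), 1)    # rounding induces ties
    y <- round(rnorm(30, 5.5, 2), 1)
    df <- data.frame(salinity = rep(c(0.1, 35), c(25, 30)),
                     pcrit_kpa = c(x, y))
    got <- salinity_comparison(df)$kpa
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("identical freshwater and seawater samples give p = 1", {
  df <- data.frame(salinity = rep(c(0.1, 35), each = 10),
                   pcrit_kpa = rep(1:10, 2))
  got <- salinity_comparison(df)$kpa
  expect_equal(got$z, 0)
  expect_equal(got$p, 1)
})

test_that("the FW/SW split is significant in kPa but not in mg/L", {
  sim <- simulate_fw_sw_pcrit(n_fw = 116, n_sw = 150, seed = 8)
  cmp <- salinity_comparison(sim)
  expect_lt(cmp$kpa$p, 0.001)
  expect_gt(cmp$mgl$p, 0.05)
  # freshwater Pcrit sits roughly a quarter lower in partial pressure
  expect_lt(cmp$kpa$percent_diff_means, -15)
  expect_gt(cmp$kpa$percent_diff_means, -32)
})

test_that("OLS on its own noise-free generating model is exact", {
  db <- generate_pcrit_database(400, seed = 2,
                                targets = list(noise_sd = 0))
  fit <- suppressWarnings(pcrit_regression(db))   # "essentially perfect fit"
  expect_equal(fit$coefficients$b, c(0.047, -0.083, 1.931, 0.001),
               tolerance = 1e-8)
  expect_equal(fit$intercept, 5.689, tolerance = 1e-8)
  expect_gt(fit$adj_r2, 0.999999)
})

test_that("forward stepwise selection logs exclusions and refuses
          degenerate designs", {
  db <- generate_pcrit_database(400, seed = 2,
                                targets = list(noise_sd = 0.5))
  db$salinity <- 35   # constant predictor
  fit <- pcrit_regression(db, selection = "stepwise")
  expect_false("salinity" %in% fit$coefficients$predictor)
  expect_true(any(grepl("salinity: constant", fit$selection_log)))
  # collinear design is refused
  db2 <- generate_pcrit_database(200, seed = 3)
  db2$rmr <- db2$salinity * 2
  expect_error(pcrit_regression(db2), "collinear")
})

test_that("a Table-4-structured database yields the expected fit quality", {
  db <- generate_pcrit_database(1159, seed = 6)
  fit <- pcrit_regression(db)
  expect_lt(abs(fit$adj_r2 - 0.195), 0.05)
  expect_equal(fit$n, 1159)
  expect_equal(unname(fit$df[1]), 4)
})

test_that("regression CIs cover the generating coefficients", {
  true_b <- c(0.047, -0.083, 1.931, 0.001)
  covered <- matrix(FALSE, 100, 4)
  for (i in 1:100) {
    db <- generate_pcrit_database(150, seed = 1000 + i)
    fit <- pcrit_regression(db)
    ci <- stats::confint(fit$fit)[-1, , drop = FALSE]
    covered[i, ] <- ci[, 1] <= true_b & true_b <= ci[, 2]
  }
  expect_true(all(colMeans(covered) >= 0.90))
})
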