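multi_stratum_records <- function(slopes, n_per = 20, sigma = 0.3,
                                  intercepts = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(intercepts)) intercepts <- rep(25, length(slopes))
  purrr::imap_dfr(slopes, function(s, i) {
    line_records(n_per, intercepts[i], s, sigma = sigma,
                 chemical = sprintf("chem_%02d", i), log_dow = i)
  })
}

test_that("stratified fits on a single stratum equal the pooled fit", {
  set.seed(42)
  rec <- line_records(30, 25, -8000, sigma = 0.3)
  sf <- stratified_fits(rec, by = "chemical", min_distinct_temps = 4)
  pooled <- fit_arrhenius(rec)
  expect_equal(nrow(sf), 1)
  expect_equal(sf$slope_K, pooled$slope_K)
  expect_equal(sf$fit[[1]]$ci95_slope, pooled$ci95_slope)
})

test_that("thin strata are excluded and reported, not silently dropped", {
  set.seed(43)
  rich <- line_records(20, 25, -8000, sigma = 0.3, chemical = "rich")
  thin <- make_records(celsius_to_kelvin(c(10, 15, 20)), k = c(1, 2, 3),
                       chemical = "thin")
  sf <- stratified_fits(dplyr::bind_rows(rich, thin), by = "chemical")
  expect_equal(sf$stratum, "rich")
  expect_equal(attr(sf, "excluded")$stratum, "thin")
  expect_match(attr(sf, "excluded")$reason, "4 distinct")
  expect_error(stratified_fits(thin, by = "chemical"), "No stratum")
})

test_that("noiseless strata sharing a slope all fit that slope", {
  set.seed(44)
  rec <- multi_stratum_records(rep(-9000, 4), sigma = 0,
                               intercepts = c(20, 22, 24, 26))
  sf <- stratified_fits(rec, by = "chemical")
  expect_equal(nrow(sf), 4)
  expect_equal(sf$slope_K, rep(-9000, 4), tolerance = 1e-8)
})

test_that("a stratum duplicated as two strata gives F = 0, p = 1", {
  set.seed(45)
  a <- line_records(15, 25, -8000, sigma = 0.3, chemical = "a")
  b <- dplyr::mutate(a, chemical = "b")
  res <- test_slope_equality(dplyr::bind_rows(a, b), by = "chemical")
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$common_slope, fit_arrhenius(a)$slope_K, tolerance = 1e-10)
})

test_that("the nested F-test matches the ANCOVA interaction test from lm", {
  rec <- multi_stratum_records(c(-8000, -9500, -7000), n_per = 18,
                               sigma = 0.4, seed = 46)
  res <- test_slope_equality(rec, by = "chemical")
  d <- data.frame(y = log(rec$k), x = 1 / rec$temperature_K, g = rec$chemical)
  ref <- stats::anova(stats::lm(y ~ g + x, d), stats::lm(y ~ g * x, d))
  expect_equal(res$f_statistic, ref$F[2], tolerance = 1e-10)
  expect_equal(res$p_value, ref$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(res$df_num, ref$Df[2])
  expect_equal(res$df_den, ref$Res.Df[2])
})

test_that("slope-equality test is invariant to relabeling and y shifts", {
  rec <- multi_stratum_records(c(-8000, -9000), n_per = 15, sigma = 0.3,
                               seed = 47)
  res <- test_slope_equality(rec, by = "chemical")
  relabeled <- dplyr::mutate(rec, chemical = ifelse(chemical == "chem_01",
                                                    "zzz", "aaa"))
  shifted <- dplyr::mutate(rec, k = k * exp(3))
  expect_equal(test_slope_equality(relabeled, by = "chemical")$f_statistic,
               res$f_statistic, tolerance = 1e-12)
  expect_equal(test_slope_equality(shifted, by = "chemical")$f_statistic,
               res$f_statistic, tolerance = 1e-12)
})

test_that("a strongly deviating stratum is detected with high power", {
  set.seed(48)
  # controlled-gradient design: 4 evenly spaced temperature levels, the
  # minimal design the distinct-temperature rule admits
  levels_K <- seq(278, 303, length.out = 4)
  reject <- replicate(100, {
    rec <- purrr::imap_dfr(c(-8000, -8000, -8000, -5000), function(s, i) {
      make_records(rep(levels_K, each = 10),
                   k = exp(25 + s / rep(levels_K, each = 10) + rnorm(40, 0, 0.5)),
                   chemical = sprintf("chem_%02d", i), log_dow = i)
    })
    test_slope_equality(rec, by = "chemical")$p_value < 0.05
  })
  expect_gt(mean(reject), 0.8)
})

test_that("unfittable strata are named in the error", {
  ok <- line_records(15, 25, -8000, sigma = 0.3, chemical = "ok")
  tiny <- make_records(c(290, 295), k = c(1, 2), chemical = "tiny")
  expect_error(test_slope_equality(dplyr::bind_rows(ok, tiny), by = "chemical"),
               "tiny")
})

test_that("BCF slope difference is antisymmetric and exact on identical fits", {
  set.seed(49)
  up <- fit_arrhenius(line_records(40, 40, -10000, sigma = 0.4))
  el <- fit_arrhenius(line_records(40, 25, -7800, sigma = 0.4,
                                   rate_type = "elimination"))
  ab <- assess_bcf_temperature_dependence(up, el)
  ba <- assess_bcf_temperature_dependence(el, up)
  expect_equal(ab$delta_slope_K, -ba$delta_slope_K)
  expect_equal(ab$se_delta, ba$se_delta)
  same <- assess_bcf_temperature_dependence(up, up)
  expect_equal(same$delta_slope_K, 0)
  expect_true(same$temperature_independent)
})

test_that("paired records yield a direct ln(BCF) regression", {
  temps <- seq(278, 303, length.out = 10)
  pu <- arrhenius_params(12, -9000, "uptake")
  pe <- arrhenius_params(3, -9000, "elimination")
  paired <- tibble::tibble(temperature_K = temps,
                           k_u = arrhenius_rate(pu, temps),
                           k_e = arrhenius_rate(pe, temps))
  up <- fit_arrhenius(make_records(temps, k = paired$k_u))
  el <- fit_arrhenius(make_records(temps, k = paired$k_e,
                                   rate_type = "elimination"))
  res <- assess_bcf_temperature_dependence(up, el, paired_records = paired)
  expect_lt(abs(res$paired_fit$slope_K), 1e-6)
  expect_equal(res$paired_fit$intercept, 9, tolerance = 1e-8)
})

test_that("the pipeline runs end to end, deterministically, with 4 pooled fits", {
  cfg <- generator_config(n_uptake = 120, n_elimination = 120,
                          noise_sigma_ln = 0.5, seed = 13)
  rep1 <- run_pipeline(cfg, quiet = TRUE)
  expect_s3_class(rep1, "tk_report")
  expect_length(rep1$comparisons, 2)  # 2 rate types x 2 corrections = 4 fits
  expect_s3_class(rep1$comparisons$uptake$corrected, "arrhenius_fit")
  expect_s3_class(rep1$bcf, "bcf_assessment")

  rep2 <- run_pipeline(cfg, quiet = TRUE)
  expect_equal(tidy(rep2$comparisons$uptake), tidy(rep1$comparisons$uptake))
  expect_equal(rep2$bcf$delta_slope_K, rep1$bcf$delta_slope_K)

  # relaxing the temperature filter can only add strata; pooled unchanged
  rep3 <- run_pipeline(cfg, min_distinct_temps = 3, quiet = TRUE)
  expect_gte(nrow(rep3$strata$uptake), nrow(rep1$strata$uptake))
  expect_equal(rep3$comparisons$uptake$uncorrected$slope_K,
               rep1$comparisons$uptake$uncorrected$slope_K)

  # outputs are written when a directory is supplied
  out <- withr::local_tempdir()
  run_pipeline(cfg, out_dir = out, quiet = TRUE)
  expect_true(file.exists(file.path(out, "pooled_fits.csv")))
  expect_true(file.exists(file.path(out, "stratified_fits.csv")))
  expect_true(file.exists(file.path(out, "report.txt")))
})

test_that("autoplot methods return ggplot objects", {
  set.seed(50)
  rec <- multi_stratum_records(rep(-8000, 3), n_per = 15, sigma = 0.3)
  fit <- fit_arrhenius(rec)
  expect_s3_class(autoplot(fit), "ggplot")
  sf <- stratified_fits(rec, by = "chemical")
  expect_s3_class(autoplot(sf), "ggplot")
  tk <- tk_parameters(100, 0.5)
  d <- exposure_design(0.01, 7, c(1, 2, 4, 7, 9, 12, 16))
  expect_s3_class(plot_timecourse(simulate_exposure(tk, d), tk, 0.01, 7),
                  "ggplot")
})
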