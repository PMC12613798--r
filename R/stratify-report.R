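# Chemical- (hydrophobicity) and species-stratified Arrhenius fits, the
# nested F-test of slope equality across strata, the assessment of
# whether the bioconcentration factor depends on temperature, and the
# end-to-end pipeline driver.

#' Per-stratum Arrhenius fits
#'
#' Splits records by a stratum key (a chemical, a species, or a
#' precomputed log D_ow bin column), applies the minimum-distinct-
#' temperature filter within each stratum, and fits the linearized
#' Arrhenius model per surviving stratum. Strata failing the filter or
#' the fit are listed in `attr(, "excluded")`, never silently dropped.
#'
#' @param records Tibble of prepped rate records of a single rate type.
#' @param by Name of the stratifying column (default `"chemical"`;
#'   `"species"` for species-specific analysis).
#' @param min_distinct_temps Minimum distinct rounded temperatures a
#'   stratum must span (default 4); the filter is applied per stratum.
#' @return A tibble of class `stratum_fits`: one row per fitted stratum
#'   with `stratum`, `log_dow` (when stratifying by chemical), `n`,
#'   coefficient columns as in [tidy.arrhenius_fit()] (slope row), and a
#'   list-column `fit` of `arrhenius_fit` objects. Excluded strata (with
#'   reasons) in `attr(, "excluded")`.
#' @examples
#' rec <- generate_dataset(generator_config(n_uptake = 400, n_elimination = 400,
#'                                          noise_sigma_ln = 0.3, seed = 2))
#' stratified_fits(dplyr::filter(rec, rate_type == "uptake"), by = "chemical")
#' @export
stratified_fits <- function(records, by = "chemical", min_distinct_temps = 4) {
  if (!by %in% names(records)) {
    stop("Stratum column `", by, "` not found in records.", call. = FALSE)
  }
  kept <- filter_min_temperatures(records, min_distinct = min_distinct_temps,
                                  keys = c(by, "rate_type"))
  all_strata <- unique(records[[by]])
  excluded <- tibble::tibble(
    stratum = setdiff(all_strata, unique(kept[[by]])),
    reason = sprintf("fewer than %d distinct temperatures", min_distinct_temps)
  )
  if (nrow(kept) == 0L) {
    stop("No stratum spans ", min_distinct_temps,
         " distinct temperatures; nothing to fit.", call. = FALSE)
  }

  rows <- kept |>
    dplyr::group_by(stratum = .data[[by]]) |>
    dplyr::group_map(function(d, key) {
      fit <- tryCatch(fit_arrhenius(d), error = function(e) e)
      if (inherits(fit, "error")) {
        return(tibble::tibble(stratum = key$stratum,
                              error = conditionMessage(fit)))
      }
      tibble::tibble(
        stratum = key$stratum,
        log_dow = if (by == "chemical") d$log_dow[1] else NA_real_,
        n = fit$n, slope_K = fit$slope_K, se_slope = fit$se_slope,
        conf.low = fit$ci95_slope[1], conf.high = fit$ci95_slope[2],
        intercept = fit$intercept, r_squared = fit$r_squared,
        p.value = fit$p_value_slope, fit = list(fit)
      )
    }) |>
    dplyr::bind_rows()

  if ("error" %in% names(rows)) {
    excluded <- dplyr::bind_rows(
      excluded,
      rows |> dplyr::filter(!is.na(.data$error)) |>
        dplyr::select("stratum", reason = "error"))
    rows <- rows |> dplyr::filter(is.na(.data$error)) |>
      dplyr::select(-"error")
  }
  out <- rows
  class(out) <- c("stratum_fits", class(out))
  attr(out, "excluded") <- excluded
  attr(out, "by") <- by
  out
}

#' Arrhenius plot of stratified fits
#'
#' ln k against 1/T with one regression line per stratum, colored by
#' log D_ow when stratifying by chemical (blue = hydrophilic, red =
#' hydrophobic).
#'
#' @param object A `stratum_fits` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stratum_fits <- function(object, ...) {
  pts <- purrr::map2_dfr(object$fit, object$stratum, function(f, s) {
    dplyr::mutate(f$data, stratum = s,
                  log_dow = object$log_dow[match(s, object$stratum)])
  })
  lines <- tibble::as_tibble(object[c("stratum", "log_dow", "slope_K", "intercept")])
  use_dow <- !all(is.na(pts$log_dow))
  if (!use_dow) {
    pts$log_dow <- NULL
    lines$log_dow <- NULL
    pts$colour_var <- pts$stratum
    lines$colour_var <- lines$stratum
  } else {
    pts$colour_var <- pts$log_dow
    lines$colour_var <- lines$log_dow
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$inv_T, y = .data$ln_k)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$colour_var), alpha = 0.5) +
    ggplot2::geom_abline(
      data = lines,
      mapping = ggplot2::aes(slope = .data$slope_K,
                             intercept = .data$intercept,
                             colour = .data$colour_var)) +
    ggplot2::labs(x = expression(1 / T ~ (K^-1)), y = expression(ln ~ k),
                  colour = attr(object, "by"))
  if (use_dow) {
    p <- p + ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                            name = expression(log ~ D[ow]))
  }
  p
}

#' Nested F-test of slope equality across strata
#'
#' Compares the separate-slopes model (one slope and intercept per
#' stratum) against the common-slope model (one shared slope, per-
#' stratum intercepts):
#' \deqn{F = \frac{(RSS_{common} - RSS_{separate})/(G-1)}
#'            {RSS_{separate}/(N - 2G)}}
#' computed in closed form from within-stratum sums. A small p-value
#' means the temperature sensitivities differ between strata; a large
#' one supports a shared Arrhenius slope (e.g. no slope dependence on
#' hydrophobicity).
#'
#' @param records Tibble of rate records of a single rate type,
#'   restricted to the strata under test (apply
#'   [filter_min_temperatures()] or [stratified_fits()] first).
#' @param by Name of the stratifying column.
#' @return An object of class `slope_equality_test`: `f_statistic`,
#'   `p_value`, `df_num`, `df_den`, `common_slope`, `n_strata`,
#'   `rss_common`, `rss_separate`.
#' @export
test_slope_equality <- function(records, by = "chemical") {
  strata <- split(records, records[[by]])
  g <- length(strata)
  if (g < 2L) stop("Need at least 2 strata to test slope equality.",
                   call. = FALSE)
  sums <- purrr::imap(strata, function(d, nm) {
    if (nrow(d) < 3L) {
      stop("Stratum `", nm, "` has fewer than 3 records; unfittable.",
           call. = FALSE)
    }
    x <- 1 / d$temperature_K
    y <- log(d$k)
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (sxx <= 0) {
      stop("Stratum `", nm, "` has zero temperature variance; unfittable.",
           call. = FALSE)
    }
    list(sxx = sxx, sxy = sum(xc * (y - mean(y))),
         syy = sum((y - mean(y))^2), n = nrow(d))
  })
  sxx <- purrr::map_dbl(sums, "sxx")
  sxy <- purrr::map_dbl(sums, "sxy")
  syy <- purrr::map_dbl(sums, "syy")
  n_tot <- sum(purrr::map_dbl(sums, "n"))

  rss_separate <- sum(syy - sxy^2 / sxx)
  common_slope <- sum(sxy) / sum(sxx)        # pooled within-stratum slope
  rss_common <- sum(syy) - sum(sxy)^2 / sum(sxx)
  df_num <- g - 1L
  df_den <- as.integer(n_tot - 2L * g)
  if (df_den < 1L) stop("Not enough records for the separate-slopes model.",
                        call. = FALSE)
  f <- max(0, (rss_common - rss_separate) / df_num) / (rss_separate / df_den)
  structure(
    list(f_statistic = f,
         p_value = stats::pf(f, df_num, df_den, lower.tail = FALSE),
         df_num = df_num, df_den = df_den, common_slope = common_slope,
         n_strata = g, rss_common = rss_common, rss_separate = rss_separate),
    class = "slope_equality_test"
  )
}

#' @export
print.slope_equality_test <- function(x, ...) {
  cat(sprintf(
    "Slope-equality F-test across %d strata: F(%d, %d) = %.3f, p = %.4g\n",
    x$n_strata, x$df_num, x$df_den, x$f_statistic, x$p_value))
  cat(sprintf("  common slope = %.0f K\n", x$common_slope))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slope_equality_test <- function(x, ...) {
  tibble::tibble(statistic = x$f_statistic, p.value = x$p_value,
                 df = x$df_num, df.residual = x$df_den,
                 common_slope_K = x$common_slope, n_strata = x$n_strata)
}

#' Assess temperature (in)dependence of the bioconcentration factor
#'
#' In the one-compartment model BCF = k_u/k_e, so
#' \eqn{\ln BCF = (\ln A_u - \ln A_e) + (s_u - s_e)/T}: the BCF is
#' temperature-independent exactly when the uptake and elimination
#' Arrhenius slopes are equal. The test quantity is
#' \eqn{\Delta s = s_u - s_e} with SE
#' \eqn{\sqrt{SE_u^2 + SE_e^2}} (the two fits use disjoint record sets,
#' so they are treated as independent) and a normal 95% CI. When paired
#' per-organism records exist, ln(k_u/k_e) is additionally regressed on
#' 1/T directly.
#'
#' @param uptake_fit,elimination_fit `arrhenius_fit` objects for the two
#'   processes.
#' @param paired_records Optional tibble with columns `k_u`, `k_e`,
#'   `temperature_K` of paired observations.
#' @return An object of class `bcf_assessment`: `delta_slope_K`,
#'   `se_delta`, `ci95`, `temperature_independent` (TRUE iff the CI
#'   contains 0), and optionally `paired_fit` (an `arrhenius_fit` of
#'   ln BCF on 1/T).
#' @export
assess_bcf_temperature_dependence <- function(uptake_fit, elimination_fit,
                                              paired_records = NULL) {
  stopifnot(inherits(uptake_fit, "arrhenius_fit"),
            inherits(elimination_fit, "arrhenius_fit"))
  delta <- uptake_fit$slope_K - elimination_fit$slope_K
  se <- sqrt(uptake_fit$se_slope^2 + elimination_fit$se_slope^2)
  ci <- delta + c(-1, 1) * stats::qnorm(0.975) * se
  paired_fit <- NULL
  if (!is.null(paired_records)) {
    paired_fit <- fit_arrhenius(
      tibble::tibble(temperature_K = paired_records$temperature_K,
                     k = bcf(paired_records$k_u, paired_records$k_e),
                     rate_type = "uptake"))  # placeholder type: y is ln BCF
    paired_fit$rate_type <- "bcf"
  }
  structure(
    list(delta_slope_K = delta, se_delta = se, ci95 = ci,
         temperature_independent = ci[1] <= 0 && ci[2] >= 0,
         slope_uptake_K = uptake_fit$slope_K,
         slope_elimination_K = elimination_fit$slope_K,
         paired_fit = paired_fit),
    class = "bcf_assessment"
  )
}

#' @export
print.bcf_assessment <- function(x, ...) {
  cat(sprintf("BCF temperature dependence: delta slope = %.0f K (SE %.0f)\n",
              x$delta_slope_K, x$se_delta))
  cat(sprintf("  95%% CI [%.0f, %.0f] -> %s\n", x$ci95[1], x$ci95[2],
              if (x$temperature_independent)
                "consistent with a temperature-independent BCF"
              else "BCF depends on temperature"))
  if (!is.null(x$paired_fit)) {
    cat(sprintf("  paired ln(BCF) ~ 1/T slope: %.0f K (p = %.3g)\n",
                x$paired_fit$slope_K, x$paired_fit$p_value_slope))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bcf_assessment <- function(x, ...) {
  tibble::tibble(
    delta_slope_K = x$delta_slope_K, std.error = x$se_delta,
    conf.low = x$ci95[1], conf.high = x$ci95[2],
    temperature_independent = x$temperature_independent
  )
}

#' Run the full temperature--toxicokinetics analysis
#'
#' Executes, in order: data generation (or ingestion), duplicate
#' averaging and mass imputation, pooled uncorrected and mass-corrected
#' Arrhenius fits for both rate types, chemical- and species-stratified
#' fits with slope-equality tests, and the BCF temperature-independence
#' assessment. Each stage logs its record count; a stage failure aborts
#' with the stage name.
#'
#' @param config A [generator_config()], used when no `dataset` is given
#'   (and always recorded in the report).
#' @param dataset Optional path to a canonical dataset CSV; when `NULL`
#'   a dataset is generated from `config`.
#' @param mass_table Optional mass-reference tibble for imputation.
#' @param min_distinct_temps Filter threshold for the stratified stages.
#' @param out_dir Optional directory; when given, results CSVs and a
#'   plain-text report are written there.
#' @param quiet Suppress stage messages.
#' @return An object of class `tk_report`: record counts per stage,
#'   pooled `comparisons` (per rate type), `strata` and
#'   `slope_equality` (per rate type, by chemical), `species_strata`,
#'   and `bcf` assessment.
#' @examples
#' \donttest{
#' rep <- run_pipeline(generator_config(n_uptake = 150, n_elimination = 150,
#'                                      noise_sigma_ln = 0.5, seed = 11))
#' rep
#' }
#' @export
run_pipeline <- function(config = generator_config(), dataset = NULL,
                         mass_table = NULL, min_distinct_temps = 4,
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("Pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  records <- stage("ingest", {
    if (is.null(dataset)) {
      say("Generating synthetic dataset (seed %d)", config$seed)
      generate_dataset(config)
    } else {
      say("Reading dataset from %s", dataset)
      read_rate_dataset(dataset)
    }
  })
  say("Records ingested: %d", nrow(records))

  prepped <- stage("prep", prepare_records(records, mass_table))
  say("Records after duplicate averaging: %d", nrow(prepped))

  comparisons <- list()
  strata <- list()
  slope_eq <- list()
  for (rt in c("uptake", "elimination")) {
    sub <- dplyr::filter(prepped, .data$rate_type == rt)
    comparisons[[rt]] <- stage(paste0("pooled_fit_", rt), compare_models(sub))
    strata[[rt]] <- stage(paste0("stratified_", rt),
                          stratified_fits(sub, by = "chemical",
                                          min_distinct_temps = min_distinct_temps))
    kept <- filter_min_temperatures(sub, min_distinct = min_distinct_temps,
                                    keys = c("chemical", "rate_type"))
    slope_eq[[rt]] <- stage(paste0("slope_equality_", rt),
                            test_slope_equality(kept, by = "chemical"))
    say("%s: pooled n = %d, fitted strata = %d", rt,
        comparisons[[rt]]$uncorrected$n, nrow(strata[[rt]]))
  }

  species_strata <- stage("species_stratified", {
    purrr::map(c(uptake = "uptake", elimination = "elimination"), function(rt) {
      sub <- dplyr::filter(prepped, .data$rate_type == rt)
      tryCatch(stratified_fits(sub, by = "species",
                               min_distinct_temps = min_distinct_temps),
               error = function(e) NULL)
    })
  })

  bcf_res <- stage("bcf", assess_bcf_temperature_dependence(
    comparisons$uptake$uncorrected, comparisons$elimination$uncorrected))

  report <- structure(
    list(config = config,
         n_records = nrow(records), n_prepped = nrow(prepped),
         comparisons = comparisons, strata = strata,
         slope_equality = slope_eq, species_strata = species_strata,
         bcf = bcf_res),
    class = "tk_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pooled <- purrr::map_dfr(comparisons, tidy, .id = "rate_type")
    readr::write_csv(pooled, file.path(out_dir, "pooled_fits.csv"))
    strata_tbl <- purrr::map_dfr(strata,
                                 ~ dplyr::select(tibble::as_tibble(.x), -"fit"),
                                 .id = "rate_type")
    readr::write_csv(strata_tbl, file.path(out_dir, "stratified_fits.csv"))
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
    say("Report written to %s", out_dir)
  }
  report
}

#' @export
print.tk_report <- function(x, ...) {
  cat("Temperature-toxicokinetics analysis report\n")
  cat(sprintf("  records: %d ingested, %d after duplicate averaging (seed %d)\n",
              x$n_records, x$n_prepped, x$config$seed))
  for (rt in names(x$comparisons)) {
    cat(sprintf("\n== %s ==\n", rt))
    print(x$comparisons[[rt]])
    cat(sprintf("  chemical strata fitted: %d (excluded: %d); slope equality p = %.3g\n",
                nrow(x$strata[[rt]]),
                nrow(attr(x$strata[[rt]], "excluded")),
                x$slope_equality[[rt]]$p_value))
  }
  cat("\n")
  print(x$bcf)
  invisible(x)
}
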