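# Seeded generator of rate-constant compilations with the statistical
# structure the downstream analysis assumes: multi-taxon composition,
# log-uniform body masses, chemical-specific intercept shifts driven by
# hydrophobicity, lognormal noise on the rate constants, and optional
# duplicated (species, chemical, rounded-temperature) entries.

# per-taxon composition of published multispecies rate-constant
# compilations (data points per taxon, uptake + elimination combined)
default_taxa_weights <- function() {
  counts <- c(
    Amphibia = 2, Bivalvia = 172, Camarodonta = 1, Copepoda = 1,
    Crustacea = 487, Gastropoda = 34, Insecta = 99, Oligochaeta = 46,
    Osteichthyes = 628, Polychaeta = 14, Pycnogonida = 1, Thecostraca = 1
  )
  counts / sum(counts)
}

default_chemical_group_weights <- function() {
  counts <- c(
    BDEs = 30, chloronaphthalenes = 19, halobiocides = 104,
    halobenzenes = 74, PAHs = 206, PCBs = 370, phosphorbiocides = 87,
    others = 598
  )
  counts / sum(counts)
}

# log-uniform body-mass intervals (kg) by taxon: small invertebrates
# microgram-to-gram, molluscs up to tens of grams, vertebrates up to 1 kg
default_mass_law <- function() {
  list(
    Amphibia = c(1e-3, 1), Bivalvia = c(1e-4, 1e-1), Camarodonta = c(1e-4, 1e-1),
    Copepoda = c(1e-7, 1e-5), Crustacea = c(1e-6, 1e-3),
    Gastropoda = c(1e-5, 1e-2), Insecta = c(1e-6, 1e-3),
    Oligochaeta = c(1e-6, 1e-3), Osteichthyes = c(1e-3, 1),
    Polychaeta = c(1e-6, 1e-3), Pycnogonida = c(1e-6, 1e-3),
    Thecostraca = c(1e-6, 1e-3)
  )
}

#' Configuration for the synthetic rate-constant generator
#'
#' The defaults emulate the scale and structure of published multispecies
#' compilations: 530 uptake and 958 elimination records, temperatures
#' uniform over 278--303 K (5--30 °C), per-taxon record proportions from
#' the compilation's composition table, log-uniform body masses spanning
#' copepods to fish, hydrophobicity (log D_ow) shifting intercepts
#' upward for uptake and downward for elimination, and Gaussian noise of
#' SD 2.0 on ln k (which yields pooled Arrhenius R-squared on the order
#' of 0.1, as pooled compilations show).
#'
#' @param true_params_uptake,true_params_elimination [arrhenius_params()]
#'   generating values; defaults are the published pooled uncorrected
#'   estimates (see [reference_pooled_fits()]).
#' @param n_uptake,n_elimination Record counts (> 0).
#' @param temperature_range_K Length-2 interval inside (270, 320) K.
#' @param taxa_weights Named proportions summing to 1.
#' @param mass_law Named list of length-2 log-uniform mass intervals (kg)
#'   per taxon; taxa absent from the list fall back to 1e-6--1e-3 kg.
#' @param n_species_per_taxon,n_chemicals Pool sizes for synthetic
#'   species and chemical labels.
#' @param dow_range Interval of log D_ow values chemicals are drawn from.
#' @param dow_intercept_coeff_uptake Shift of ln A per log D_ow unit
#'   (>= 0: hydrophobic chemicals taken up faster).
#' @param dow_intercept_coeff_elimination Shift per log unit (<= 0:
#'   hydrophobic chemicals eliminated more slowly).
#' @param dow_slope_coeff_uptake,dow_slope_coeff_elimination Optional
#'   slope--hydrophobicity interaction (K per log D_ow unit), 0 by
#'   default so all chemicals share the generating slope.
#' @param noise_sigma_ln SD of Gaussian noise on ln k (>= 0).
#' @param duplicate_fraction Fraction of records re-observed at the same
#'   (species, chemical, rounded temperature), in `[0, 0.5]`.
#' @param seed Integer seed; same seed, same dataset.
#' @return An object of class `generator_config`.
#' @examples
#' cfg <- generator_config(n_uptake = 50, n_elimination = 80, seed = 1)
#' @export
generator_config <- function(
    true_params_uptake = arrhenius_params(40.11, -10000, "uptake"),
    true_params_elimination = arrhenius_params(25.73, -7888, "elimination"),
    n_uptake = 530,
    n_elimination = 958,
    temperature_range_K = c(278, 303),
    taxa_weights = default_taxa_weights(),
    mass_law = default_mass_law(),
    n_species_per_taxon = 5,
    n_chemicals = 25,
    dow_range = c(0, 8),
    dow_intercept_coeff_uptake = 0.3,
    dow_intercept_coeff_elimination = -0.5,
    dow_slope_coeff_uptake = 0,
    dow_slope_coeff_elimination = 0,
    noise_sigma_ln = 2.0,
    duplicate_fraction = 0.05,
    seed = 1L) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)

  if (!inherits(true_params_uptake, "arrhenius_params")) {
    add("true_params_uptake: must be an arrhenius_params object")
  }
  if (!inherits(true_params_elimination, "arrhenius_params")) {
    add("true_params_elimination: must be an arrhenius_params object")
  }
  if (n_uptake <= 0 || n_elimination <= 0) {
    add("n_uptake/n_elimination: record counts must be > 0")
  }
  if (length(temperature_range_K) != 2L || diff(temperature_range_K) <= 0 ||
      temperature_range_K[1] <= 270 || temperature_range_K[2] >= 320) {
    add("temperature_range_K: must be an increasing interval within (270, 320) K")
  }
  if (is.null(names(taxa_weights)) || any(taxa_weights < 0) ||
      abs(sum(taxa_weights) - 1) > 1e-8) {
    add("taxa_weights: must be named, non-negative, and sum to 1")
  }
  if (noise_sigma_ln < 0) add("noise_sigma_ln: must be >= 0")
  if (duplicate_fraction < 0 || duplicate_fraction > 0.5) {
    add("duplicate_fraction: must lie in [0, 0.5]")
  }
  if (length(dow_range) != 2L || diff(dow_range) <= 0) {
    add("dow_range: must be an increasing interval")
  }
  if (dow_intercept_coeff_uptake < 0) {
    add("dow_intercept_coeff_uptake: must be >= 0")
  }
  if (dow_intercept_coeff_elimination > 0) {
    add("dow_intercept_coeff_elimination: must be <= 0")
  }
  if (length(problems) > 0L) {
    stop("Invalid generator configuration:\n",
         paste0("  - ", problems, collapse = "\n"), call. = FALSE)
  }

  structure(
    list(
      true_params_uptake = true_params_uptake,
      true_params_elimination = true_params_elimination,
      n_uptake = as.integer(n_uptake), n_elimination = as.integer(n_elimination),
      temperature_range_K = temperature_range_K,
      taxa_weights = taxa_weights, mass_law = mass_law,
      n_species_per_taxon = as.integer(n_species_per_taxon),
      n_chemicals = as.integer(n_chemicals),
      dow_range = dow_range,
      dow_intercept_coeff_uptake = dow_intercept_coeff_uptake,
      dow_intercept_coeff_elimination = dow_intercept_coeff_elimination,
      dow_slope_coeff_uptake = dow_slope_coeff_uptake,
      dow_slope_coeff_elimination = dow_slope_coeff_elimination,
      noise_sigma_ln = noise_sigma_ln,
      duplicate_fraction = duplicate_fraction,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# synthetic chemical pool: id, group label, fixed log_dow
draw_chemicals <- function(config) {
  groups <- default_chemical_group_weights()
  tibble::tibble(
    chemical = sprintf("chem_%02d", seq_len(config$n_chemicals)),
    chemical_group = sample(names(groups), config$n_chemicals,
                            replace = TRUE, prob = groups),
    log_dow = stats::runif(config$n_chemicals,
                           config$dow_range[1], config$dow_range[2])
  )
}

# records of one rate type, without duplicates
draw_records <- function(config, rate_type, n, chemicals) {
  params <- if (rate_type == "uptake") config$true_params_uptake
            else config$true_params_elimination
  icoef <- if (rate_type == "uptake") config$dow_intercept_coeff_uptake
           else config$dow_intercept_coeff_elimination
  scoef <- if (rate_type == "uptake") config$dow_slope_coeff_uptake
           else config$dow_slope_coeff_elimination
  dow_mid <- mean(config$dow_range)

  taxa <- sample(names(config$taxa_weights), n, replace = TRUE,
                 prob = config$taxa_weights)
  species <- sprintf("%s_sp%02d", taxa,
                     sample.int(config$n_species_per_taxon, n, replace = TRUE))
  mass_iv <- purrr::map(taxa, ~ config$mass_law[[.x]] %||% c(1e-6, 1e-3))
  mass_kg <- purrr::map_dbl(mass_iv, ~ exp(stats::runif(1, log(.x[1]), log(.x[2]))))
  chem <- chemicals[sample.int(nrow(chemicals), n, replace = TRUE), ]
  temperature_K <- stats::runif(n, config$temperature_range_K[1],
                                config$temperature_range_K[2])

  ln_A_eff <- params$ln_A + icoef * (chem$log_dow - dow_mid)
  slope_eff <- params$slope_K + scoef * (chem$log_dow - dow_mid)
  ln_k <- ln_A_eff + slope_eff / temperature_K +
    stats::rnorm(n, 0, config$noise_sigma_ln)

  tibble::tibble(
    source_id = sprintf("src_%02d", sample.int(40, n, replace = TRUE)),
    species = species, taxon = taxa,
    life_stage = sample(c("adult", "juvenile"), n, replace = TRUE,
                        prob = c(0.7, 0.3)),
    chemical = chem$chemical, chemical_group = chem$chemical_group,
    log_dow = chem$log_dow,
    temperature_K = temperature_K,
    rate_type = rate_type,
    k = exp(ln_k),
    mass_kg = mass_kg
  )
}

# re-observe selected records at the same rounded temperature with a
# fresh noise draw, emulating duplicate literature entries
add_duplicates <- function(records, config, params_by_type) {
  m <- round(config$duplicate_fraction * nrow(records))
  if (m == 0L) return(records)
  idx <- sample.int(nrow(records), m)
  dup <- records[idx, ]
  for (rt in unique(dup$rate_type)) {
    sel <- dup$rate_type == rt
    p <- params_by_type[[rt]]
    icoef <- if (rt == "uptake") config$dow_intercept_coeff_uptake
             else config$dow_intercept_coeff_elimination
    scoef <- if (rt == "uptake") config$dow_slope_coeff_uptake
             else config$dow_slope_coeff_elimination
    dow_mid <- mean(config$dow_range)
    ln_k <- p$ln_A + icoef * (dup$log_dow[sel] - dow_mid) +
      (p$slope_K + scoef * (dup$log_dow[sel] - dow_mid)) / dup$temperature_K[sel] +
      stats::rnorm(sum(sel), 0, config$noise_sigma_ln)
    dup$k[sel] <- exp(ln_k)
  }
  dup$source_id <- sprintf("src_%02d", sample.int(40, m, replace = TRUE))
  dplyr::bind_rows(records, dup)
}

#' Generate a synthetic rate-constant compilation
#'
#' Draws `n_uptake + n_elimination` records (plus duplicates) whose log
#' rate constants follow
#' \eqn{\ln k = \ln A_{eff} + s_{eff}/T + \epsilon}, with
#' \eqn{\ln A_{eff}} shifted per chemical in proportion to its log D_ow
#' distance from the midpoint of `dow_range`, and
#' \eqn{\epsilon \sim N(0, \sigma^2)}. Output is byte-identical under the
#' same seed.
#'
#' @param config A [generator_config()].
#' @return A tibble of rate records with columns `source_id`, `species`,
#'   `taxon`, `life_stage`, `chemical`, `chemical_group`, `log_dow`,
#'   `temperature_K`, `rate_type`, `k`, `mass_kg`.
#' @examples
#' head(generate_dataset(generator_config(n_uptake = 20, n_elimination = 30,
#'                                        seed = 7)))
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  chemicals <- draw_chemicals(config)
  records <- dplyr::bind_rows(
    draw_records(config, "uptake", config$n_uptake, chemicals),
    draw_records(config, "elimination", config$n_elimination, chemicals)
  )
  add_duplicates(records, config,
                 list(uptake = config$true_params_uptake,
                      elimination = config$true_params_elimination))
}

#' Generate paired time-course experiments with a truth table
#'
#' End-to-end fixture for the estimation stage: for every
#' (species, chemical, temperature) cell, true uptake and elimination
#' rate constants are derived from the configured Arrhenius parameters
#' (with the chemical's hydrophobicity shift) and a one-compartment
#' experiment is simulated under `design`.
#'
#' @param config A [generator_config()]; its seed drives all draws.
#' @param design An [exposure_design()] applied to every cell (its own
#'   `seed` is ignored; noise comes from the config seed stream).
#' @param n_species,n_chemicals Grid sizes.
#' @param temperatures_K Temperature levels; default 6 evenly spaced
#'   levels across the config range.
#' @return List with `series` (long tibble: cell keys + `time_d`,
#'   `c_internal`, `phase`) and `truth` (one row per cell: `k_u`, `k_e`,
#'   `bcf` used to simulate).
#' @export
generate_timecourse_study <- function(config, design, n_species = 3,
                                      n_chemicals = 2,
                                      temperatures_K = NULL) {
  stopifnot(inherits(config, "generator_config"),
            inherits(design, "exposure_design"))
  if (is.null(temperatures_K)) {
    temperatures_K <- seq(config$temperature_range_K[1],
                          config$temperature_range_K[2], length.out = 6)
  }
  set.seed(config$seed)
  chemicals <- draw_chemicals(config)[seq_len(n_chemicals), ]
  dow_mid <- mean(config$dow_range)
  grid <- tidyr::expand_grid(
    species = sprintf("Crustacea_sp%02d", seq_len(n_species)),
    chemical = chemicals$chemical,
    temperature_K = temperatures_K
  ) |>
    dplyr::left_join(chemicals, by = "chemical")

  truth <- grid |>
    dplyr::mutate(
      k_u = exp(config$true_params_uptake$ln_A +
                  config$dow_intercept_coeff_uptake * (.data$log_dow - dow_mid) +
                  config$true_params_uptake$slope_K / .data$temperature_K),
      k_e = exp(config$true_params_elimination$ln_A +
                  config$dow_intercept_coeff_elimination * (.data$log_dow - dow_mid) +
                  config$true_params_elimination$slope_K / .data$temperature_K),
      bcf = .data$k_u / .data$k_e
    )

  design_noseed <- design
  design_noseed$seed <- NULL  # draws come from the config seed stream
  series <- truth |>
    dplyr::mutate(sim = purrr::map2(.data$k_u, .data$k_e, function(ku, ke) {
      simulate_exposure(tk_parameters(ku, ke), design_noseed)
    })) |>
    dplyr::select("species", "chemical", "log_dow", "temperature_K", "sim") |>
    tidyr::unnest("sim")

  list(series = series, truth = truth)
}

#' Read or write a generator configuration as YAML
#'
#' Serializes every scalar field plus the Arrhenius generating parameters
#' so a dataset can be regenerated from the file alone (the seed is part
#' of the file).
#'
#' @param config A [generator_config()].
#' @param path File path.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns a `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- config
  x$true_params_uptake <- unclass(x$true_params_uptake)
  x$true_params_elimination <- unclass(x$true_params_elimination)
  x$taxa_weights <- as.list(x$taxa_weights)  # keep names in the YAML mapping
  yaml::write_yaml(unclass(x), path, precision = 17)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$true_params_uptake <- arrhenius_params(
    x$true_params_uptake$ln_A, x$true_params_uptake$slope_K,
    x$true_params_uptake$process)
  x$true_params_elimination <- arrhenius_params(
    x$true_params_elimination$ln_A, x$true_params_elimination$slope_K,
    x$true_params_elimination$process)
  x$taxa_weights <- unlist(x$taxa_weights)
  do.call(generator_config, x)
}
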