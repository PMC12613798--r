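# build a minimal rate-record tibble with canonical internal columns
make_records <- function(temperature_K, k, rate_type = "uptake",
                         species = "Crustacea_sp01", chemical = "chem_01",
                         taxon = "Crustacea", chemical_group = "PCBs",
                         log_dow = 4, mass_kg = NA_real_,
                         life_stage = NA_character_, source_id = "src_01") {
  tibble::tibble(
    source_id = source_id, species = species, taxon = taxon,
    life_stage = life_stage, chemical = chemical,
    chemical_group = chemical_group, log_dow = log_dow,
    temperature_K = temperature_K, rate_type = rate_type, k = k,
    mass_kg = mass_kg
  )
}

# records with ln k exactly or noisily on an Arrhenius line
line_records <- function(n, ln_A, slope_K, sigma = 0, t_range = c(278, 303),
                         rate_type = "uptake", ...) {
  temp <- stats::runif(n, t_range[1], t_range[2])
  ln_k <- ln_A + slope_K / temp + stats::rnorm(n, 0, sigma)
  make_records(temperature_K = temp, k = exp(ln_k), rate_type = rate_type, ...)
}

# direct normal-equations solution, kept independent of the package path
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}
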