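# Ingestion of rate-constant tables and the data-treatment rules applied
# to compiled literature datasets: duplicate averaging at rounded
# temperatures, body-mass imputation with life-stage preference, and the
# minimum-distinct-temperature filter for stratified analyses.

dataset_schema <- c(
  "source_id", "species", "taxon", "life_stage", "chemical",
  "chemical_group", "log_dow", "temperature_value", "temperature_unit",
  "rate_type", "k_value", "k_unit", "mass_kg"
)

#' Read a rate-constant dataset from CSV
#'
#' Expects the canonical comma-separated schema (header required):
#' `source_id, species, taxon, life_stage, chemical, chemical_group,
#' log_dow, temperature_value, temperature_unit{C,K},
#' rate_type{uptake,elimination}, k_value, k_unit, mass_kg` (empty
#' `mass_kg` = missing). Temperatures given in °C are converted to
#' Kelvin; the internal canonical unit is K. Rows violating the record
#' invariants (k > 0, T > 200 K, mass > 0 when present, known rate type
#' and unit) are rejected with row-numbered diagnostics, available via
#' `attr(x, "rejected")` and reported with a message.
#'
#' @param path Path to the CSV file.
#' @return A tibble of typed rate records (`temperature_K`, `k`, ...);
#'   rejected rows in `attr(, "rejected")`.
#' @export
read_rate_dataset <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(dataset_schema, names(raw))
  if (length(missing_cols) > 0L) {
    stop("Dataset is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw |>
    dplyr::mutate(.row = dplyr::row_number(),
                  k = suppressWarnings(as.numeric(.data$k_value)),
                  temp = suppressWarnings(as.numeric(.data$temperature_value)),
                  log_dow = suppressWarnings(as.numeric(.data$log_dow)),
                  mass_kg = suppressWarnings(as.numeric(.data$mass_kg)),
                  temperature_K = dplyr::if_else(.data$temperature_unit == "C",
                                                 celsius_to_kelvin(.data$temp),
                                                 .data$temp))

  problems <- dplyr::bind_rows(
    diagnose(raw, is.na(raw$k) | raw$k <= 0,
             "k_value must be a positive number"),
    diagnose(raw, is.na(raw$temperature_K) | raw$temperature_K <= 200,
             "temperature must be numeric and > 200 K"),
    diagnose(raw, !raw$temperature_unit %in% c("C", "K"),
             "temperature_unit must be 'C' or 'K'"),
    diagnose(raw, !raw$rate_type %in% c("uptake", "elimination"),
             "rate_type must be 'uptake' or 'elimination'"),
    diagnose(raw, !is.na(raw$mass_kg) & raw$mass_kg <= 0,
             "mass_kg, when present, must be > 0")
  )
  keep <- !raw$.row %in% problems$row
  if (nrow(problems) > 0L) {
    message(sprintf("Rejected %d row(s); see attr(, 'rejected'). First: row %d: %s",
                    length(unique(problems$row)), problems$row[1],
                    problems$rule[1]))
  }
  out <- raw[keep, ] |>
    dplyr::select("source_id", "species", "taxon", "life_stage", "chemical",
                  "chemical_group", "log_dow", "temperature_K", "rate_type",
                  "k", "mass_kg")
  attr(out, "rejected") <- problems
  out
}

diagnose <- function(raw, bad, rule) {
  tibble::tibble(row = raw$.row[which(bad)], rule = rule)
}

#' Write rate records to the canonical CSV schema
#'
#' @param records Tibble of rate records (internal representation).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_dataset <- function(records, path) {
  records |>
    dplyr::mutate(temperature_value = .data$temperature_K,
                  temperature_unit = "K",
                  k_value = .data$k,
                  k_unit = dplyr::if_else(.data$rate_type == "uptake",
                                          "L/kg/d", "1/d")) |>
    dplyr::select(dplyr::all_of(dataset_schema)) |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}

#' Average duplicate observations at the same rounded temperature
#'
#' Literature compilations often contain several observations of the
#' same species--chemical pair at effectively the same temperature; to
#' avoid overweighting those combinations, observations sharing
#' (species, chemical, rate type, temperature rounded to the nearest
#' whole °C — ties away from zero) are collapsed to a single record
#' carrying the arithmetic mean rate constant (geometric mean with
#' `scale = "log"`) and the mean exact temperature in Kelvin. Masses are
#' averaged; other fields are taken from the first member. Idempotent.
#'
#' @param records Tibble of rate records.
#' @param scale `"natural"` (arithmetic mean of k, default) or `"log"`
#'   (geometric mean).
#' @return Tibble with one record per duplicate group.
#' @export
average_duplicates <- function(records, scale = c("natural", "log")) {
  scale <- match.arg(scale)
  if (nrow(records) == 0L) return(records)
  records |>
    dplyr::mutate(.t_round = round_half_away(kelvin_to_celsius(.data$temperature_K))) |>
    dplyr::group_by(.data$species, .data$chemical, .data$rate_type,
                    .data$.t_round) |>
    dplyr::summarise(
      source_id = dplyr::first(.data$source_id),
      taxon = dplyr::first(.data$taxon),
      life_stage = dplyr::first(.data$life_stage),
      chemical_group = dplyr::first(.data$chemical_group),
      log_dow = dplyr::first(.data$log_dow),
      temperature_K = mean(.data$temperature_K),
      k = if (scale == "natural") mean(.data$k) else exp(mean(log(.data$k))),
      mass_kg = if (all(is.na(.data$mass_kg))) NA_real_
                else mean(.data$mass_kg, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::select(-".t_round") |>
    dplyr::select("source_id", "species", "taxon", "life_stage", "chemical",
                  "chemical_group", "log_dow", "temperature_K", "rate_type",
                  "k", "mass_kg")
}

#' Read a body-mass reference table
#'
#' CSV schema: `species, life_stage, mass_kg, n_source_studies`; empty
#' `life_stage` denotes a species-level average. One entry per
#' (species, life_stage) pair.
#'
#' @param path Path to the CSV.
#' @return Validated tibble.
#' @export
read_mass_reference <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    species = "c", life_stage = "c", mass_kg = "d", n_source_studies = "i"
  ), progress = FALSE)
  validate_mass_reference(tbl)
}

validate_mass_reference <- function(tbl) {
  need <- c("species", "life_stage", "mass_kg")
  if (!all(need %in% names(tbl))) {
    stop("Mass reference needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(tbl$mass_kg <= 0 | is.na(tbl$mass_kg))) {
    stop("Mass reference masses must be positive.", call. = FALSE)
  }
  dups <- tbl |>
    dplyr::count(.data$species, .data$life_stage) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dups) > 0L) {
    stop("Mass reference has multiple entries for: ",
         paste(paste(dups$species, dups$life_stage, sep = "/"), collapse = "; "),
         call. = FALSE)
  }
  tbl
}

#' Impute missing body masses from a reference table
#'
#' Records that already carry a mass are untouched. Missing masses are
#' filled by an exact (species, life stage) match when one exists —
#' the life-stage average is preferred — and otherwise by the mean of
#' the species' reference entries. Records still lacking a mass are
#' flagged (`mass_missing = TRUE`) so they can be excluded from
#' mass-corrected analyses while remaining available for uncorrected
#' ones; they are summarized in `attr(, "unmatched")`.
#'
#' @param records Tibble of rate records.
#' @param mass_table Reference tibble (see [read_mass_reference()]).
#' @return Records with `mass_kg` filled where possible and columns
#'   `mass_imputed`, `mass_missing` added.
#' @export
impute_mass <- function(records, mass_table) {
  mass_table <- validate_mass_reference(mass_table)
  by_stage <- mass_table |>
    dplyr::filter(!is.na(.data$life_stage)) |>
    dplyr::select("species", "life_stage", stage_mass = "mass_kg")
  by_species <- mass_table |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(species_mass = mean(.data$mass_kg), .groups = "drop")

  out <- records |>
    dplyr::left_join(by_stage, by = c("species", "life_stage")) |>
    dplyr::left_join(by_species, by = "species") |>
    dplyr::mutate(
      mass_imputed = is.na(.data$mass_kg) &
        (!is.na(.data$stage_mass) | !is.na(.data$species_mass)),
      mass_kg = dplyr::coalesce(.data$mass_kg, .data$stage_mass,
                                .data$species_mass),
      mass_missing = is.na(.data$mass_kg)
    ) |>
    dplyr::select(-"stage_mass", -"species_mass")

  unmatched <- out |>
    dplyr::filter(.data$mass_missing) |>
    dplyr::count(.data$species, .data$life_stage, name = "n_records")
  if (nrow(unmatched) > 0L) {
    message(sprintf("%d record(s) remain without mass (%d species); see attr(, 'unmatched').",
                    sum(out$mass_missing), nrow(unmatched)))
  }
  attr(out, "unmatched") <- unmatched
  out
}

#' Keep only groups observed at enough distinct temperatures
#'
#' Reliable per-chemical or per-species Arrhenius regressions need a
#' temperature gradient; groups (by default species x chemical x rate
#' type) observed at fewer than `min_distinct` distinct rounded
#' temperatures (°C) are dropped. This filter applies to the stratified
#' analyses only — pooled fits use all records.
#'
#' @param records Tibble of rate records.
#' @param min_distinct Minimum number of distinct rounded temperatures
#'   (default 4).
#' @param keys Grouping columns defining a dataset.
#' @return Filtered tibble.
#' @export
filter_min_temperatures <- function(records, min_distinct = 4,
                                    keys = c("species", "chemical", "rate_type")) {
  if (nrow(records) == 0L) return(records)
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::filter(dplyr::n_distinct(
      round_half_away(kelvin_to_celsius(.data$temperature_K))) >= min_distinct) |>
    dplyr::ungroup()
}

#' Apply the full data-treatment sequence
#'
#' Convenience wrapper: duplicate averaging, then (when a mass table is
#' given) mass imputation. The minimum-temperature filter is *not*
#' applied here because it only concerns stratified analyses; see
#' [filter_min_temperatures()].
#'
#' @param records Tibble of rate records.
#' @param mass_table Optional mass reference tibble.
#' @param scale Averaging scale passed to [average_duplicates()].
#' @return Prepared tibble.
#' @export
prepare_records <- function(records, mass_table = NULL,
                            scale = c("natural", "log")) {
  out <- average_duplicates(records, scale = match.arg(scale))
  if (!is.null(mass_table)) out <- impute_mass(out, mass_table)
  out
}
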