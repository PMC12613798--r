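write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  header <- paste("source_id,species,taxon,life_stage,chemical,chemical_group",
                  "log_dow,temperature_value,temperature_unit,rate_type",
                  "k_value,k_unit,mass_kg", sep = ",")
  writeLines(c(header, lines), path)
  path
}

test_that("read_rate_dataset types valid rows and converts Celsius", {
  path <- write_fixture_csv(c(
    "s1,Gammarus pulex,Crustacea,adult,pyrene,PAHs,4.9,20,C,uptake,150,L/kg/d,0.00005",
    "s1,Gammarus pulex,Crustacea,adult,pyrene,PAHs,4.9,293.15,K,elimination,0.8,1/d,",
    "s2,Danio rerio,Osteichthyes,juvenile,PCB52,PCBs,6.1,15,C,uptake,90,L/kg/d,0.0004"
  ))
  rec <- read_rate_dataset(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$temperature_K[1], 293.15)
  expect_equal(rec$temperature_K[2], 293.15)
  expect_equal(rec$temperature_K[3], 288.15)
  expect_true(is.na(rec$mass_kg[2]))
  expect_equal(nrow(attr(rec, "rejected")), 0)
})

test_that("invalid rows are rejected with row-numbered diagnostics", {
  path <- write_fixture_csv(c(
    "s1,A,Crustacea,adult,p,PAHs,4,20,C,uptake,150,L/kg/d,",
    "s1,A,Crustacea,adult,p,PAHs,4,20,C,uptake,-1,L/kg/d,",       # bad k
    "s1,A,Crustacea,adult,p,PAHs,4,abc,C,uptake,2,L/kg/d,",       # bad T
    "s1,A,Crustacea,adult,p,PAHs,4,20,C,sorption,2,L/kg/d,",      # bad type
    "s1,A,Crustacea,adult,p,PAHs,4,20,C,uptake,2,L/kg/d,-0.1"     # bad mass
  ))
  expect_message(rec <- read_rate_dataset(path), "Rejected")
  expect_equal(nrow(rec), 1)
  rej <- attr(rec, "rejected")
  expect_setequal(rej$row, 2:5)
  expect_match(rej$rule[rej$row == 2], "k_value")
  expect_match(rej$rule[rej$row == 5], "mass_kg")
})

test_that("a missing mandatory column is a schema error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,k_value", "A,1"), path)
  expect_error(read_rate_dataset(path), "mass_kg")
})

test_that("duplicates at the same rounded Celsius are averaged", {
  rec <- make_records(celsius_to_kelvin(c(19.6, 20.4)), k = c(2, 4))
  out <- average_duplicates(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$k, 3)                                  # arithmetic mean
  expect_equal(out$temperature_K, celsius_to_kelvin(20))  # mean exact T
  expect_equal(exp(mean(log(c(2, 4)))),
               average_duplicates(rec, scale = "log")$k)  # geometric option

  # 19.4 and 20.6 round to 19 and 21: both survive
  rec2 <- make_records(celsius_to_kelvin(c(19.4, 20.6)), k = c(2, 4))
  expect_equal(nrow(average_duplicates(rec2)), 2)
})

test_that("halfway temperatures round away from zero", {
  # 20.5 and 21.4 both map to 21 under away-from-zero rounding (bankers'
  # rounding would separate them)
  rec <- make_records(celsius_to_kelvin(c(20.5, 21.4)), k = c(1, 3))
  expect_equal(nrow(average_duplicates(rec)), 1)
  expect_equal(thermotk:::round_half_away(c(0.5, 1.5, -0.5, 2.5)),
               c(1, 2, -1, 3))
})

test_that("averaging never merges across rate type, species, or chemical", {
  base <- celsius_to_kelvin(c(20.1, 19.9))
  rec <- dplyr::bind_rows(
    make_records(base, k = c(1, 2), rate_type = "uptake"),
    make_records(base, k = c(3, 4), rate_type = "elimination"),
    make_records(base, k = c(5, 6), species = "Other_sp"),
    make_records(base, k = c(7, 8), chemical = "chem_99")
  )
  out <- average_duplicates(rec)
  expect_equal(nrow(out), 4)
  expect_setequal(out$k, c(1.5, 3.5, 5.5, 7.5))
})

test_that("duplicate averaging is idempotent and never grows the data", {
  set.seed(5)
  rec <- generate_dataset(generator_config(n_uptake = 80, n_elimination = 80,
                                           duplicate_fraction = 0.15, seed = 5))
  once <- average_duplicates(rec)
  expect_lte(nrow(once), nrow(rec))
  expect_equal(average_duplicates(once), once)
})

test_that("prep commutes with restriction to a rate type", {
  rec <- generate_dataset(generator_config(n_uptake = 70, n_elimination = 90,
                                           duplicate_fraction = 0.1, seed = 6))
  a <- average_duplicates(dplyr::filter(rec, rate_type == "uptake"))
  b <- dplyr::filter(average_duplicates(rec), rate_type == "uptake")
  expect_equal(dplyr::arrange(a, species, chemical, temperature_K),
               dplyr::arrange(b, species, chemical, temperature_K))
})

test_that("mass imputation prefers the matching life stage", {
  mass_table <- tibble::tibble(
    species = c("X", "X", "Y"),
    life_stage = c("juvenile", NA, "adult"),
    mass_kg = c(0.001, 0.01, 0.3),
    n_source_studies = c(2L, 3L, 1L)
  )
  rec <- dplyr::bind_rows(
    make_records(293, 1, species = "X", life_stage = "juvenile"),
    make_records(294, 1, species = "X", life_stage = "larva"),
    make_records(295, 1, species = "X", mass_kg = 0.5),
    make_records(296, 1, species = "Z")
  )
  expect_message(out <- impute_mass(rec, mass_table), "without mass")
  expect_equal(out$mass_kg[1], 0.001)          # life-stage match wins
  expect_equal(out$mass_kg[2], mean(c(0.001, 0.01)))  # species fallback
  expect_equal(out$mass_kg[3], 0.5)            # present mass untouched
  expect_false(out$mass_imputed[3])
  expect_true(out$mass_missing[4])             # flagged, not dropped
  expect_equal(attr(out, "unmatched")$species, "Z")
})

test_that("mass reference validation rejects duplicated entries", {
  bad <- tibble::tibble(species = c("X", "X"), life_stage = c("adult", "adult"),
                        mass_kg = c(1, 2), n_source_studies = c(1L, 1L))
  expect_error(impute_mass(make_records(293, 1), bad), "multiple entries")
})

test_that("minimum-distinct-temperature filter keeps only rich datasets", {
  rec <- dplyr::bind_rows(
    make_records(celsius_to_kelvin(c(10, 15, 20, 25)), k = 1:4, species = "A"),
    make_records(celsius_to_kelvin(c(10, 15, 20)), k = 1:3, species = "B"),
    # 4 records but only 2 distinct rounded temperatures
    make_records(celsius_to_kelvin(c(10, 10.2, 15, 15.3)), k = 1:4,
                 species = "C")
  )
  out <- filter_min_temperatures(rec)
  expect_setequal(unique(out$species), "A")
  expect_equal(filter_min_temperatures(rec, min_distinct = 1), rec)
})

test_that("CSV writer and reader roundtrip the internal representation", {
  rec <- generate_dataset(generator_config(n_uptake = 15, n_elimination = 15,
                                           duplicate_fraction = 0, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rate_dataset(rec, path)
  back <- read_rate_dataset(path)
  expect_equal(back$k, rec$k, tolerance = 1e-12)
  expect_equal(back$temperature_K, rec$temperature_K, tolerance = 1e-12)
  expect_equal(back$species, rec$species)
})
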