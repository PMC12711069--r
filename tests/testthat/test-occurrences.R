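test_that("well-formed files read cleanly and malformed rows are reported", {
  path <- write_occ_csv(data.frame(
    species = c("Porites baracoaensis", "Acropora palmata", "Montastraea cavernosa"),
    lat = c(20, 18, 22), lng = c(-70, -75, -80),
    min_ma = c(5, 1, 10), max_ma = c(10, 3, 15)))
  res <- read_occurrences(path)
  expect_equal(nrow(res$records), 3L)
  expect_equal(nrow(res$rejects), 0L)
  expect_equal(res$records$genus, c("Porites", "Acropora", "Montastraea"))

  bad <- write_occ_csv(data.frame(
    species = c("Porites baracoaensis", "Acropora palmata"),
    lat = c(20, 18), lng = c(-70, -75),
    min_ma = c(12, 1), max_ma = c(10, 3)))
  res2 <- read_occurrences(bad)
  expect_equal(nrow(res2$records), 1L)
  expect_equal(res2$rejects$reason, "inverted age interval")
})

test_that("a missing required column is a hard error naming the column", {
  path <- write_occ_csv(data.frame(species = "A b", lat = 1, lng = 2, min_ma = 3))
  expect_error(read_occurrences(path), "max_ma")
})

test_that("generator output round-trips losslessly through write/read", {
  truth <- make_truth(ts = runif(30, 5, 10), te = runif(30, 0, 2), origin = 10)
  occ <- sample_preservation(truth, q = 2, seed = 4)$occurrences
  path <- tempfile(fileext = ".csv")
  write_occurrences(occ, path)
  back <- read_occurrences(path)
  expect_equal(nrow(back$rejects), 0L)
  expect_equal(back$records[, c("species", "lat", "lon", "min_ma", "max_ma")],
               occ, tolerance = 1e-12)
})

test_that("curation applies the geographic box and qualifier rules in order", {
  rec <- read_occurrences(write_occ_csv(data.frame(
    species = c("Porites baracoaensis", "Agaricia agaricites", "Porites sp.",
                "Acropora aff. cervicornis"),
    lat = c(20, 20, 20, 20), lng = c(-70, -50, -70, -70),
    min_ma = c(5, 5, 5, 5), max_ma = c(10, 10, 10, 10))))$records
  out <- curate_occurrences(rec)
  expect_equal(out$records$species, "Porites baracoaensis")
  expect_equal(out$audit$geographic, 1L)   # lon -50 is east of the box
  expect_equal(out$audit$qualifier, 2L)    # "sp." and "aff." removed
  expect_equal(out$audit$rows_in - out$audit$rows_out,
               out$audit$geographic + out$audit$qualifier +
                 out$audit$drop_list + out$audit$duplicate)
})

test_that("synonym mapping and drop lists are honoured", {
  rec <- read_occurrences(write_occ_csv(data.frame(
    species = c("Old name", "Deep coral", "Kept species"),
    lat = c(20, 20, 20), lng = c(-70, -70, -70),
    min_ma = c(5, 5, 5), max_ma = c(10, 10, 10))))$records
  cfg <- curation_config(synonym_map = c("Old name" = "New name"),
                         drop_list = "Deep coral")
  out <- curate_occurrences(rec, cfg)
  expect_setequal(out$records$species, c("New name", "Kept species"))
  expect_equal(out$audit$drop_list, 1L)
})

test_that("curation is idempotent and tolerates empty output", {
  rec <- read_occurrences(write_occ_csv(data.frame(
    species = c("Porites baracoaensis", "Agaricia agaricites"),
    lat = c(20, 21), lng = c(-70, -71),
    min_ma = c(5, 6), max_ma = c(10, 11))))$records
  once <- curate_occurrences(rec)
  twice <- curate_occurrences(once$records)
  expect_equal(twice$records, once$records)
  # a box excluding everything is legal
  far <- curate_occurrences(rec, curation_config(lon_range = c(0, 1),
                                                 lat_range = c(0, 1)))
  expect_equal(nrow(far$records), 0L)
  expect_equal(far$audit$rows_out, 0L)
})

test_that("age resampling stays inside intervals and honours degenerate ones", {
  rec <- data.frame(species = c("A b", "C d"), lat = 20, lon = -70,
                    min_ma = c(10, 20), max_ma = c(10, 30))
  reps <- resample_ages(rec, n_replicates = 5, seed = 1)
  expect_length(reps, 5L)
  for (r in reps) {
    expect_equal(r$age[r$species == "A b"], 10)
    expect_true(all(r$age[r$species == "C d"] >= 20 &
                    r$age[r$species == "C d"] <= 30))
  }
})

test_that("resampled ages are uniform on their interval", {
  rec <- data.frame(species = sprintf("s%04d a", 1:10000), lat = 20, lon = -70,
                    min_ma = 20, max_ma = 30)
  ds <- resample_ages(rec, n_replicates = 1, seed = 2)[[1]]
  se <- stats::sd(ds$age) / sqrt(nrow(ds))
  expect_lt(abs(mean(ds$age) - 25), 3 * se)
})

test_that("resampling is deterministic per (seed, replicate)", {
  rec <- data.frame(species = rep("A b", 50), lat = 20, lon = -70,
                    min_ma = 5, max_ma = 15)
  a <- resample_ages(rec, n_replicates = 3, seed = 9)
  b <- resample_ages(rec, n_replicates = 3, seed = 9)
  expect_identical(a, b)
  c <- resample_ages(rec, n_replicates = 3, seed = 10)
  expect_false(identical(a[[1]]$age, c[[1]]$age))
})

test_that("the fossil dataset text layout round-trips", {
  rec <- data.frame(species = c("A b", "A b", "C d"), lat = 20, lon = -70,
                    min_ma = c(5, 6, 7), max_ma = c(10, 11, 12))
  ds <- resample_ages(rec, n_replicates = 1, seed = 4)[[1]]
  path <- tempfile(fileext = ".txt")
  write_fossil_dataset(ds, path)
  back <- read_fossil_dataset(path)
  expect_equal(back$species, ds$species)
  expect_equal(back$age, ds$age, tolerance = 1e-12)
})

test_that("species are binned into every epoch their intervals intersect", {
  rec <- data.frame(
    species = c("Olig only", "Straddler", "Straddler"),
    lat = 20, lon = -70,
    min_ma = c(28.1, 33.0, 28), max_ma = c(30.5, 34.2, 29))
  sets <- bin_species_by_epoch(rec)
  expect_equal(sets$Oligocene, sort(c("Olig only", "Straddler")))
  expect_true("Straddler" %in% sets$Eocene)
  expect_false("Olig only" %in% sets$Eocene)
  # multi-membership: per-epoch counts sum to at least the distinct count
  expect_gte(sum(lengths(sets)), length(unique(rec$species)))
})

test_that("occurrences outside epoch coverage are warned about, not assigned", {
  rec <- data.frame(species = "Ancient", lat = 20, lon = -70,
                    min_ma = 80, max_ma = 90)
  expect_warning(sets <- bin_species_by_epoch(rec), "outside epoch coverage")
  expect_equal(sum(lengths(sets)), 0L)
})
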