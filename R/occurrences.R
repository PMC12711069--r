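#' Column dialect for Paleobiology-Database-style occurrence files
#'
#' Maps the canonical field names used internally to candidate column names
#' accepted in input CSVs. The default accepts both the PBDB download dialect
#' (accepted_name, lat, lng, min_ma, max_ma) and the plain dialect written by
#' \code{\link{write_occurrences}} (species, lat, lon, min_ma, max_ma).
#'
#' @return Named list, canonical field -> character vector of accepted names.
#' @export
pbdb_dialect <- function() {
  list(species = c("species", "accepted_name"),
       lat = "lat",
       lon = c("lon", "lng"),
       min_ma = "min_ma",
       max_ma = "max_ma")
}

# Open-nomenclature qualifiers detected in species name strings.
default_qualifiers <- function() c("sp.", "aff.", "cf.", "?")

qualifiers_in_name <- function(name, qualifiers = default_qualifiers()) {
  tokens <- strsplit(name, "[[:space:]]+")
  vapply(tokens, function(tk) {
    hit <- qualifiers[qualifiers %in% tk |
                        vapply(qualifiers, function(q) any(grepl(q, tk, fixed = TRUE)),
                               logical(1))]
    paste(hit, collapse = ",")
  }, character(1))
}

#' Read an occurrence table
#'
#' Reads a CSV of fossil occurrences, resolves the column dialect, types the
#' fields and separates malformed rows into a rejects report instead of
#' silently dropping them. Validation covers missing/non-numeric coordinates
#' and ages, inverted age intervals (min_ma > max_ma), negative ages and
#' out-of-range coordinates.
#'
#' @param path CSV file path.
#' @param dialect Column dialect as from \code{\link{pbdb_dialect}}.
#' @return List with \code{records} (data frame: species, genus, lat, lon,
#'   min_ma, max_ma, qualifiers) and \code{rejects} (data frame with a
#'   \code{reason} column; zero rows when the file is clean).
#' @export
read_occurrences <- function(path, dialect = pbdb_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- lapply(dialect, function(cands) {
    hit <- cands[cands %in% names(raw)]
    if (length(hit)) hit[1] else NA_character_
  })
  missing <- names(cols)[vapply(cols, is.na, logical(1))]
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  rec <- data.frame(species = as.character(raw[[cols$species]]),
                    lat = suppressWarnings(as.numeric(raw[[cols$lat]])),
                    lon = suppressWarnings(as.numeric(raw[[cols$lon]])),
                    min_ma = suppressWarnings(as.numeric(raw[[cols$min_ma]])),
                    max_ma = suppressWarnings(as.numeric(raw[[cols$max_ma]])),
                    stringsAsFactors = FALSE)
  reason <- rep(NA_character_, nrow(rec))
  bad_num <- !is.finite(rec$lat) | !is.finite(rec$lon) |
    !is.finite(rec$min_ma) | !is.finite(rec$max_ma)
  reason[bad_num] <- "non-numeric field"
  inv <- !bad_num & rec$min_ma > rec$max_ma
  reason[inv] <- "inverted age interval"
  neg <- !bad_num & !inv & rec$min_ma < 0
  reason[neg] <- "negative age"
  oob <- !bad_num & !inv & !neg &
    (abs(rec$lat) > 90 | abs(rec$lon) > 180)
  reason[oob] <- "coordinate out of range"
  keep <- is.na(reason)
  records <- rec[keep, , drop = FALSE]
  records$genus <- vapply(strsplit(records$species, "[[:space:]]+"),
                          `[`, character(1), 1L)
  records$qualifiers <- qualifiers_in_name(records$species)
  rejects <- cbind(rec[!keep, , drop = FALSE],
                   reason = reason[!keep], stringsAsFactors = FALSE)
  row.names(records) <- NULL
  row.names(rejects) <- NULL
  list(records = records, rejects = rejects)
}

#' Write an occurrence table
#'
#' Writes the plain dialect (species, lat, lon, min_ma, max_ma) consumed by
#' \code{\link{read_occurrences}}.
#'
#' @param records Occurrence data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records[, c("species", "lat", "lon", "min_ma", "max_ma")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Curation configuration
#'
#' Defaults reproduce the Caribbean-ecoregion shortlist: a geographic box of
#' longitude -98.3424 to -55.9778 and latitude 7.4 to 33.514, and removal of
#' open-nomenclature identifications (sp., aff., cf., ?). Taxonomic synonymy
#' is handled by an offline user-supplied map, and ecological exclusions
#' (solitary-only, azooxanthellate, deep-water species) by a user-supplied
#' drop list -- membership of those categories is never guessed.
#'
#' @param lon_range,lat_range Closed intervals \code{c(lo, hi)}.
#' @param excluded_qualifiers Qualifier strings whose presence in a name
#'   removes the record.
#' @param synonym_map Named character vector, old name -> accepted name.
#' @param drop_list Character vector of species names to remove (applied
#'   after synonym mapping).
#' @return A \code{curation_config} list.
#' @export
curation_config <- function(lon_range = c(-98.3424, -55.9778),
                            lat_range = c(7.4, 33.514),
                            excluded_qualifiers = default_qualifiers(),
                            synonym_map = NULL,
                            drop_list = character()) {
  stopifnot(lon_range[1] <= lon_range[2], lat_range[1] <= lat_range[2])
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 excluded_qualifiers = excluded_qualifiers,
                 synonym_map = synonym_map, drop_list = drop_list),
            class = "curation_config")
}

#' Curate an occurrence table
#'
#' Applies, in order: geographic box filter, open-nomenclature qualifier
#' exclusion, synonym mapping, drop-list removal, and exact-duplicate
#' removal. Every rule's removal count is recorded in an audit log; an empty
#' result is legal.
#'
#' @param records Occurrence data frame from \code{\link{read_occurrences}}.
#' @param config A \code{\link{curation_config}}.
#' @return List with \code{records} (clean table) and \code{audit} (named
#'   removal counts summing to rows_in - rows_out, plus rows_in/rows_out).
#' @export
curate_occurrences <- function(records, config = curation_config()) {
  audit <- list(rows_in = nrow(records))
  # geographic box
  keep <- records$lon >= config$lon_range[1] & records$lon <= config$lon_range[2] &
    records$lat >= config$lat_range[1] & records$lat <= config$lat_range[2]
  audit$geographic <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  # open nomenclature
  qual <- qualifiers_in_name(records$species, config$excluded_qualifiers)
  keep <- qual == ""
  audit$qualifier <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  # synonym mapping (renames, removes nothing)
  if (!is.null(config$synonym_map) && length(config$synonym_map)) {
    hit <- records$species %in% names(config$synonym_map)
    records$species[hit] <- unname(config$synonym_map[records$species[hit]])
    records$genus[hit] <- vapply(strsplit(records$species[hit], "[[:space:]]+"),
                                 `[`, character(1), 1L)
  }
  audit$synonymized <- 0L
  # drop list
  keep <- !(records$species %in% config$drop_list)
  audit$drop_list <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  # exact duplicates
  key <- paste(records$species, records$lat, records$lon,
               records$min_ma, records$max_ma, sep = "|")
  keep <- !duplicated(key)
  audit$duplicate <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  audit$rows_out <- nrow(records)
  row.names(records) <- NULL
  list(records = records, audit = audit)
}

#' Resample occurrence ages into point-age replicates
#'
#' Draws each occurrence's point age uniformly within its [min_ma, max_ma]
#' interval, independently per replicate. Replicate r uses a seed derived
#' deterministically from (seed, r), so any replicate can be regenerated in
#' isolation.
#'
#' @param records Curated occurrence data frame.
#' @param n_replicates Number of replicates (default 10).
#' @param seed Integer RNG seed.
#' @return List of \code{fossil_dataset} data frames (columns \code{species},
#'   \code{age}, sorted by species then decreasing age) with attributes
#'   \code{replicate} and \code{seed}.
#' @export
resample_ages <- function(records, n_replicates = 10, seed = 1) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates), function(r) {
    rs <- derive_seed(seed, r)
    set.seed(rs)
    age <- stats::runif(nrow(records), records$min_ma, records$max_ma)
    ds <- data.frame(species = records$species, age = age,
                     stringsAsFactors = FALSE)
    ds <- ds[order(ds$species, -ds$age), , drop = FALSE]
    row.names(ds) <- NULL
    attr(ds, "replicate") <- r
    attr(ds, "seed") <- rs
    class(ds) <- c("fossil_dataset", class(ds))
    ds
  })
}

#' Write / read the two-column fossil dataset layout
#'
#' Tab-separated text with columns \code{species} and \code{age} (Ma), the
#' layout commonly used as input for fossil MCMC analyses.
#'
#' @param dataset A \code{fossil_dataset} data frame.
#' @param path File path.
#' @return \code{path} (writer) or the \code{fossil_dataset} (reader).
#' @export
write_fossil_dataset <- function(dataset, path) {
  utils::write.table(dataset[, c("species", "age")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fossil_dataset
#' @export
read_fossil_dataset <- function(path) {
  ds <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "age") %in% names(ds)))
  class(ds) <- c("fossil_dataset", class(ds))
  ds
}

#' ICS epoch boundary table
#'
#' Cenozoic epoch boundaries (Ma): Paleocene 66-56, Eocene 56-33.9,
#' Oligocene 33.9-23.03, Miocene 23.03-5.333, Pliocene 5.333-2.58,
#' Pleistocene 2.58-0.0117.
#'
#' @return Data frame with columns \code{epoch}, \code{start} (older bound)
#'   and \code{end} (younger bound), ordered old to young.
#' @export
ics_epochs <- function() {
  data.frame(
    epoch = c("Paleocene", "Eocene", "Oligocene", "Miocene",
              "Pliocene", "Pleistocene"),
    start = c(66, 56, 33.9, 23.03, 5.333, 2.58),
    end = c(56, 33.9, 23.03, 5.333, 2.58, 0.0117),
    stringsAsFactors = FALSE)
}

#' Bin species into epochs by age-interval intersection
#'
#' A species is assigned to every epoch that any of its occurrence age
#' intervals intersects, so one species may appear in several epochs.
#' Occurrences intersecting no epoch are assigned to none, with a warning.
#'
#' @param records Occurrence data frame (\code{species}, \code{min_ma},
#'   \code{max_ma}).
#' @param epochs Epoch table as from \code{\link{ics_epochs}}.
#' @return Named list of per-epoch species character vectors.
#' @export
bin_species_by_epoch <- function(records, epochs = ics_epochs()) {
  sets <- lapply(seq_len(nrow(epochs)), function(i) {
    hit <- records$min_ma <= epochs$start[i] & records$max_ma >= epochs$end[i]
    sort(unique(records$species[hit]))
  })
  names(sets) <- epochs$epoch
  in_any <- records$min_ma <= max(epochs$start) & records$max_ma >= min(epochs$end)
  covered <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(epochs))) {
    covered <- covered | (records$min_ma <= epochs$start[i] &
                            records$max_ma >= epochs$end[i])
  }
  if (any(!covered)) {
    warning(sum(!covered), " occurrence(s) outside epoch coverage, assigned to none")
  }
  sets
}
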