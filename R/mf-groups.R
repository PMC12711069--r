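#' Coral growth forms used for morpho-functional grouping
#'
#' The six colonial growth forms scored as binary traits, in the letter
#' precedence used to build canonical group labels: branching (B),
#' massive (M), columnar (C), laminar (L), foliaceous (F), encrusting (E).
#'
#' @return Named character vector mapping form name to its single-letter code.
#' @export
growth_forms <- function() {
  c(branching = "B", massive = "M", columnar = "C",
    laminar = "L", foliaceous = "F", encrusting = "E")
}

#' Canonical label for a growth-form combination
#'
#' Concatenates single-letter codes in the fixed precedence B, M, C, L, F, E,
#' so the label is independent of input order (e.g. massive + branching and
#' branching + massive both yield "BM").
#'
#' @param flags Either a character vector of form names (subset of
#'   \code{names(growth_forms())}), or a logical/0-1 vector named by form.
#' @return A single character label such as "BM" or "LFE".
#' @export
#' @examples
#' canonical_label(c("massive", "branching"))  # "BM"
canonical_label <- function(flags) {
  forms <- growth_forms()
  if (is.character(flags)) {
    bad <- setdiff(flags, names(forms))
    if (length(bad)) stop("unknown growth form(s): ", paste(bad, collapse = ", "))
    on <- names(forms) %in% flags
  } else {
    if (is.null(names(flags))) stop("flag vector must be named by growth form")
    flags <- flags[names(forms)]
    on <- !is.na(flags) & as.logical(flags)
  }
  if (!any(on)) stop("empty growth-form combination")
  paste(forms[on], collapse = "")
}

#' Alias map for published group abbreviations
#'
#' Some published summary tables abbreviate Laminar + Encrusting as "LM",
#' which collides with the natural reading of Massive + Laminar ("ML").
#' This map translates canonical labels to those report abbreviations when
#' table parity is wanted; the package itself always emits canonical labels.
#'
#' @return Named character vector, canonical label -> report abbreviation.
#' @export
mf_label_aliases <- function() {
  c(LE = "LM")
}

#' Build morpho-functional groups from binary growth-form scores
#'
#' Each distinct combination of the six binary growth forms defines one
#' morpho-functional (MF) group; every species belongs to exactly one group.
#'
#' @param traits Data frame with a \code{species} column plus the six 0/1
#'   columns named as in \code{names(growth_forms())}.
#' @param occurrences Optional occurrence data frame with a \code{species}
#'   column, used to compute each group's share of total occurrences. Every
#'   species appearing in \code{occurrences} must have a trait row.
#' @return Data frame with columns \code{label}, \code{n_species},
#'   \code{n_occurrences}, \code{occurrence_share}, sorted by decreasing
#'   species count; the per-group species sets are in \code{attr(, "members")}.
#' @export
build_mf_groups <- function(traits, occurrences = NULL) {
  needed <- c("species", names(growth_forms()))
  miss <- setdiff(needed, names(traits))
  if (length(miss)) stop("trait table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(traits$species)) stop("duplicated species in trait table")
  flag_mat <- as.matrix(traits[, names(growth_forms())]) != 0
  if (any(rowSums(flag_mat) == 0)) {
    stop("species with no growth form set: ",
         paste(traits$species[rowSums(flag_mat) == 0], collapse = ", "))
  }
  labels <- apply(flag_mat, 1L, function(row) canonical_label(row))
  if (!is.null(occurrences)) {
    missing_sp <- setdiff(unique(occurrences$species), traits$species)
    if (length(missing_sp)) {
      stop("species missing from trait table: ", paste(missing_sp, collapse = ", "))
    }
  }
  members <- split(traits$species, labels)
  n_species <- vapply(members, length, integer(1))
  if (!is.null(occurrences)) {
    occ_label <- labels[match(occurrences$species, traits$species)]
    occ_counts <- table(factor(occ_label, levels = names(members)))
    n_occ <- as.integer(occ_counts)
    share <- n_occ / sum(n_occ)
  } else {
    n_occ <- rep(NA_integer_, length(members))
    share <- rep(NA_real_, length(members))
  }
  out <- data.frame(label = names(members), n_species = n_species,
                    n_occurrences = n_occ, occurrence_share = share,
                    row.names = NULL, stringsAsFactors = FALSE)
  ord <- order(-out$n_species, out$label)
  out <- out[ord, , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "members") <- members[out$label]
  class(out) <- c("mf_groups", class(out))
  out
}

#' Classify MF groups as dominant, vulnerable or other
#'
#' Dominant groups carry enough species and occurrences to support
#' diversity-dependence analysis (defaults: at least 5 species and 70
#' occurrences). Functionally vulnerable groups hold 3 or fewer species.
#'
#' @param groups Output of \code{\link{build_mf_groups}} (or any data frame
#'   with \code{n_species} and, if occurrence thresholds are used,
#'   \code{n_occurrences}).
#' @param min_species,min_occurrences Dominance thresholds.
#' @param vulnerable_max Species count at or below which a group is
#'   functionally vulnerable.
#' @return The input with an added \code{class} column
#'   ("dominant"/"vulnerable"/"other").
#' @export
classify_dominant <- function(groups, min_species = 5, min_occurrences = 70,
                              vulnerable_max = 3) {
  stopifnot(min_species >= 0, min_occurrences >= 0)
  n_occ <- groups$n_occurrences
  if (is.null(n_occ) || all(is.na(n_occ))) n_occ <- rep(Inf, nrow(groups))
  dominant <- groups$n_species >= min_species & n_occ >= min_occurrences
  vulnerable <- groups$n_species <= vulnerable_max
  cls <- ifelse(dominant, "dominant", ifelse(vulnerable, "vulnerable", "other"))
  groups$class <- cls
  groups
}

#' Log-calibrated redundancy category of a group
#'
#' Species counts are mapped to five ordinal categories on a log10 scale:
#' n = 1 -> 1; n < 4 -> 2; n < 10 -> 3; n < 32 -> 4; n >= 32 -> 5
#' (thresholds at log10 n = 0, 0.5, 1, 1.5). Vectorised.
#'
#' @param n_species Integer vector of per-group species counts (>= 1).
#' @return Integer vector of categories in 1..5.
#' @export
#' @examples
#' redundancy_category(c(1, 9, 123))  # 1 3 5
redundancy_category <- function(n_species) {
  if (any(n_species < 1)) stop("n_species must be >= 1")
  ifelse(n_species == 1, 1L,
    ifelse(n_species < 4, 2L,
      ifelse(n_species < 10, 3L,
        ifelse(n_species < 32, 4L, 5L))))
}
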