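#' Build the diversity-dependence effect network
#'
#' Filters effect tables to shrinkage weight >= threshold and emits a
#' directed edge list. Edge weight is |median effect|; the sign attaches to
#' the rate itself: a positive coefficient promotes the rate (origination
#' or extinction) and a negative one suppresses it. Self-loops are retained.
#'
#' @param effects Data frame with columns \code{from}, \code{to},
#'   \code{rate_type}, \code{median_G}, \code{omega} (e.g. stacked
#'   \code{mbd_fit} effects with from = predictor, to = target group).
#' @param threshold Minimum shrinkage weight (default 0.6).
#' @return Data frame of edges: from, to, rate_type, weight, omega, sign
#'   ("promote"/"suppress").
#' @export
build_network <- function(effects, threshold = 0.6) {
  need <- c("from", "to", "rate_type", "median_G", "omega")
  miss <- setdiff(need, names(effects))
  if (length(miss)) stop("effect table lacks column(s): ", paste(miss, collapse = ", "))
  keep <- effects$omega >= threshold
  out <- effects[keep, , drop = FALSE]
  edges <- data.frame(from = out$from, to = out$to, rate_type = out$rate_type,
                      weight = abs(out$median_G), omega = out$omega,
                      sign = ifelse(out$median_G > 0, "promote", "suppress"),
                      stringsAsFactors = FALSE)
  row.names(edges) <- NULL
  edges
}

#' Write an edge list in DOT format
#'
#' @param edges Edge data frame from \code{\link{build_network}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_network_dot <- function(edges, path) {
  style <- ifelse(edges$sign == "promote", "solid", "dashed")
  lines <- c("digraph effects {",
             sprintf('  "%s" -> "%s" [label="%s", style=%s, penwidth=%.2f];',
                     edges$from, edges$to, edges$rate_type, style,
                     pmin(5, 0.5 + edges$weight)),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write the standard report tables
#'
#' Emits the group summary (label, occurrence share, species count,
#' dominance class, redundancy category), the per-epoch functional index
#' profile, and the thresholded effect lists, as CSV files.
#'
#' @param results List with any of \code{groups} (classified
#'   \code{mf_groups}), \code{epoch_profile}, \code{effects} (stacked
#'   effect table with from/to columns).
#' @param dir Output directory (created if needed).
#' @param threshold Shrinkage-weight threshold for the effect lists.
#' @return Character vector of files written, invisibly.
#' @export
table_reports <- function(results, dir, threshold = 0.6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(results$groups)) {
    g <- results$groups
    g$redundancy_category <- redundancy_category(g$n_species)
    f <- file.path(dir, "group_summary.csv")
    utils::write.csv(as.data.frame(g), f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(results$epoch_profile)) {
    f <- file.path(dir, "epoch_indices.csv")
    utils::write.csv(results$epoch_profile, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(results$effects)) {
    eff <- results$effects
    eff <- eff[eff$omega >= threshold, , drop = FALSE]
    eff <- eff[order(eff$rate_type, eff$to, eff$from), , drop = FALSE]
    for (rt in c("origination", "extinction")) {
      f <- file.path(dir, paste0("effects_", rt, ".csv"))
      utils::write.csv(eff[eff$rate_type == rt, , drop = FALSE], f,
                       row.names = FALSE)
      written <- c(written, f)
    }
  }
  invisible(written)
}
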