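#' Functional redundancy
#'
#' Mean number of species per morpho-functional group, FR = S / FG.
#'
#' @param S Total species count.
#' @param FG Number of morpho-functional groups (>= 1, <= S).
#' @return The exact quotient S / FG.
#' @export
#' @examples
#' compute_fr(111, 12)  # 9.25
compute_fr <- function(S, FG) {
  if (FG < 1) stop("FG must be >= 1")
  if (S < FG) stop("S must be >= FG")
  S / FG
}

#' Functional over-redundancy
#'
#' Fraction of species packed above the group mean:
#' FOR = sum_g max(n_g - FR, 0) / S with FR = S / FG. Bounded in
#' [0, 1 - 1/FG]; zero for perfectly even packing.
#'
#' @param counts Vector of per-group species counts, all >= 1.
#' @return FOR in [0, 1 - 1/FG].
#' @export
#' @examples
#' compute_for(c(6, 1, 1, 1, 1))  # 0.4
compute_for <- function(counts) {
  if (length(counts) == 0) stop("empty count vector")
  if (any(counts < 1)) stop("all group counts must be >= 1")
  S <- sum(counts)
  fr <- S / length(counts)
  sum(pmax(counts - fr, 0)) / S
}

#' Permutation null model for functional over-redundancy
#'
#' Simulates the over-redundancy expected when S species are assigned
#' independently and uniformly to FG groups, conditioned on no group being
#' left empty (S and FG are both held constant). Reports the null mean and
#' standard deviation of FOR, a permutation p-value with the +1 correction,
#' and a two-sided one-sample t-test of the null draws against the observed
#' value.
#'
#' @param S,FG Species and group totals (S >= FG >= 1).
#' @param observed_for Observed FOR to test against (optional; p-values are
#'   NA when absent).
#' @param n_sims Number of null assignments (default 9999).
#' @param seed Integer RNG seed.
#' @param keep_counts Also return the simulated count vectors (an
#'   \code{n_sims} x \code{FG} matrix), for invariant checks.
#' @return List with \code{n_sims}, \code{null_mean}, \code{null_sd},
#'   \code{p_perm}, \code{p_t}, the vector of null \code{draws} and,
#'   if requested, \code{counts}.
#' @export
null_model <- function(S, FG, observed_for = NULL, n_sims = 9999, seed = 1,
                       keep_counts = FALSE) {
  if (S < FG) stop("cannot fill ", FG, " groups with ", S, " species")
  stopifnot(n_sims >= 1)
  set.seed(seed)
  counts <- if (keep_counts) matrix(NA_integer_, n_sims, FG) else NULL
  if (S == FG) {
    draws <- rep(0, n_sims)           # every assignment is forced uniform
    if (keep_counts) counts[] <- 1L
  } else {
    fr <- S / FG
    draws <- numeric(n_sims)
    got <- 0L
    while (got < n_sims) {
      batch <- max(64L, min(n_sims - got, 8192L))
      cnt <- stats::rmultinom(batch, S, rep(1 / FG, FG))
      ok <- which(colSums(cnt == 0) == 0)
      if (length(ok)) {
        take <- ok[seq_len(min(length(ok), n_sims - got))]
        draws[got + seq_along(take)] <- colSums(pmax(cnt[, take, drop = FALSE] - fr, 0)) / S
        if (keep_counts) counts[got + seq_along(take), ] <- t(cnt[, take, drop = FALSE])
        got <- got + length(take)
      }
    }
  }
  null_mean <- mean(draws)
  null_sd <- stats::sd(draws)
  p_perm <- NA_real_
  p_t <- NA_real_
  if (!is.null(observed_for)) {
    p_perm <- (1 + sum(draws >= observed_for)) / (n_sims + 1)
    if (null_sd > 0) {
      p_t <- stats::t.test(draws, mu = observed_for)$p.value
    } else {
      p_t <- if (abs(null_mean - observed_for) < 1e-12) 1 else 0
    }
  }
  out <- list(n_sims = n_sims, null_mean = null_mean, null_sd = null_sd,
              p_perm = p_perm, p_t = p_t, draws = draws)
  if (keep_counts) out$counts <- counts
  out
}

#' Pearson correlation with t-based p-value
#'
#' Pearson r with the two-sided p-value from t = r sqrt(n-2) / sqrt(1-r^2)
#' on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with \code{r}, \code{p}, \code{t}, \code{df}.
#' @export
pearson_with_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  r <- stats::cor(x, y)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(r = r, p = p, t = tval, df = n - 2)
}

#' Per-epoch functional index profile
#'
#' For each epoch, collects the species present (occurrence-interval
#' intersection), builds MF groups from their growth-form rows, and computes
#' S, FG, FR, FOR and the permutation null summary.
#'
#' @param records Curated occurrence data frame (\code{species},
#'   \code{min_ma}, \code{max_ma}).
#' @param traits Growth-form trait table covering all species.
#' @param epochs Epoch boundary table as from \code{\link{ics_epochs}}.
#' @param n_sims Null-model replicates per epoch.
#' @param seed Integer RNG seed.
#' @return Data frame with one row per epoch containing \code{epoch},
#'   \code{S}, \code{FG}, \code{FR}, \code{FOR}, \code{null_mean},
#'   \code{null_sd}, \code{p_perm}, \code{p_t}; epochs with no species are
#'   omitted.
#' @export
epoch_profile <- function(records, traits, epochs = ics_epochs(),
                          n_sims = 9999, seed = 1) {
  sets <- bin_species_by_epoch(records, epochs)
  rows <- lapply(seq_along(sets), function(i) {
    sp <- sets[[i]]
    if (length(sp) == 0) return(NULL)
    tr <- traits[traits$species %in% sp, , drop = FALSE]
    miss <- setdiff(sp, tr$species)
    if (length(miss)) stop("no trait row for: ", paste(miss, collapse = ", "))
    grp <- build_mf_groups(tr)
    counts <- grp$n_species
    S <- sum(counts); FG <- length(counts)
    obs_for <- compute_for(counts)
    nm <- null_model(S, FG, observed_for = obs_for, n_sims = n_sims,
                     seed = derive_seed(seed, i))
    data.frame(epoch = names(sets)[i], S = S, FG = FG,
               FR = compute_fr(S, FG), FOR = obs_for,
               null_mean = nm$null_mean, null_sd = nm$null_sd,
               p_perm = nm$p_perm, p_t = nm$p_t,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
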