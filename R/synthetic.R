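#' Simulation configuration for the forward birth-death generator
#'
#' Defines the study conditions for a synthetic fossil record: a multi-group
#' species pool evolving under a birth-death process whose log-rates may
#' depend on the (scaled) standing diversity of each group, observed through
#' Poisson fossil preservation with interval-dated occurrences.
#'
#' @param origin_time Process origin, Ma before present (default 66, the
#'   base of the Cenozoic).
#' @param n_groups Number of morpho-functional groups.
#' @param seed_species_per_group Seed lineages per group at the origin.
#' @param base_lambda,base_mu Baseline origination/extinction rates
#'   (events/lineage/Myr).
#' @param q_true Preservation rate (occurrences/lineage/Myr); scalar for a
#'   homogeneous process or a vector of per-bin rates for a time-variable one.
#' @param G_matrix n_groups x n_groups matrix of diversity-effect
#'   coefficients on log-rates: entry [h, g] is the effect of group h's
#'   scaled diversity on group g's rates (same matrix used for origination
#'   and, with \code{G_matrix_mu}, extinction).
#' @param G_matrix_mu Like \code{G_matrix} but acting on extinction;
#'   defaults to a zero matrix.
#' @param covariate_effects Optional named list of true per-covariate
#'   effects applied to every group's rates: each element is a list with
#'   \code{series} (data frame \code{age_ma}, \code{value} spanning
#'   [0, origin], values typically scaled to [0, 1]), \code{G_lambda} and
#'   \code{G_mu} (log-rate effects per unit covariate).
#' @param age_interval_width Width (Myr) of the dating interval wrapped
#'   around each sampled occurrence age (default 2, stage-level imprecision).
#' @param rng_seed Integer seed; the whole simulation is deterministic
#'   given it.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(origin_time = 66, n_groups = 3,
                       seed_species_per_group = 1,
                       base_lambda = 0.3, base_mu = 0.1, q_true = 1,
                       G_matrix = NULL, G_matrix_mu = NULL,
                       covariate_effects = NULL,
                       age_interval_width = 2, rng_seed = 1) {
  if (is.null(G_matrix)) G_matrix <- matrix(0, n_groups, n_groups)
  if (is.null(G_matrix_mu)) G_matrix_mu <- matrix(0, n_groups, n_groups)
  stopifnot(origin_time > 0, n_groups >= 1, seed_species_per_group >= 1,
            base_lambda >= 0, base_mu >= 0, all(q_true >= 0),
            all(is.finite(G_matrix)), all(is.finite(G_matrix_mu)),
            all(dim(G_matrix) == n_groups), all(dim(G_matrix_mu) == n_groups),
            age_interval_width > 0)
  structure(list(origin_time = origin_time, n_groups = n_groups,
                 seed_species_per_group = seed_species_per_group,
                 base_lambda = base_lambda, base_mu = base_mu,
                 q_true = q_true, G_matrix = G_matrix,
                 G_matrix_mu = G_matrix_mu,
                 covariate_effects = covariate_effects,
                 age_interval_width = age_interval_width,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Forward Gillespie simulation of a diversity-dependent birth-death process
#'
#' Event-driven simulation from \code{origin_time} down to the present.
#' Per-species rates are
#' lambda_g(t) = base_lambda * exp(sum_h G[h, g] * D_h(t) / Dmax_h(t)) and
#' analogously for extinction, where D_h(t) is the standing diversity of
#' group h and Dmax_h(t) its running maximum (so the diversity covariate is
#' scaled to [0, 1], commensurable with the scaled predictors used when
#' fitting). External covariate effects, when configured, multiply all
#' groups' rates by exp(G_lambda * C(t)) / exp(G_mu * C(t)), with C(t)
#' held piecewise constant on the 0.1 Myr grid so the event-driven scheme
#' stays exact. Speciation is budding: the parent persists and the child
#' inherits its group. Total extinction before the present is a reported
#' outcome, not an error; runaway diversification beyond 1e5 species aborts.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{sim_truth} list: \code{species} (data frame: species,
#'   group, ts, te with te = 0 for extant), \code{grid} (0.1 Myr age grid),
#'   \code{trajectories} (grid x group diversity matrix),
#'   \code{extinct_all} flag, and the \code{config}.
#' @export
simulate_bd_forward <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  K <- config$n_groups
  n0 <- config$seed_species_per_group
  cap <- 100000L

  group <- rep(seq_len(K), each = n0)
  ts <- rep(config$origin_time, K * n0)
  te <- rep(NA_real_, K * n0)
  alive <- rep(TRUE, K * n0)
  D <- tabulate(group, K)
  Dmax <- D

  # external covariate multipliers, piecewise constant per 0.1 Myr cell;
  # without covariate effects the rates are constant between events and the
  # cell machinery (and its extra waiting-time draws) is bypassed entirely
  has_covariates <- length(config$covariate_effects %||% list()) > 0
  cell_grid <- seq(config$origin_time, 0, by = -0.1)
  mult_l <- rep(1, length(cell_grid))
  mult_m <- rep(1, length(cell_grid))
  for (ce in config$covariate_effects %||% list()) {
    v <- stats::approx(ce$series$age_ma, ce$series$value, xout = cell_grid,
                       rule = 2)$y
    mult_l <- mult_l * exp((ce$G_lambda %||% 0) * v)
    mult_m <- mult_m * exp((ce$G_mu %||% 0) * v)
  }
  cell_of_t <- function(t) {
    # cell k spans ages [origin - k*0.1, origin - (k-1)*0.1); epsilon guards
    # against floating-point stalls at cell boundaries
    min(length(cell_grid),
        max(1L, floor((config$origin_time - t) / 0.1 + 1e-9) + 1L))
  }

  t <- config$origin_time
  repeat {
    n_alive <- sum(alive)
    if (n_alive == 0L) break
    if (length(ts) > cap) {
      stop("runaway diversification: more than ", cap, " species simulated")
    }
    rel <- ifelse(Dmax > 0, D / Dmax, 0)
    g_alive <- group[alive]
    k <- if (has_covariates) cell_of_t(t) else 1L
    lam <- config$base_lambda * mult_l[k] *
      exp(as.vector(crossprod(config$G_matrix, rel)))[g_alive]
    mu <- config$base_mu * mult_m[k] *
      exp(as.vector(crossprod(config$G_matrix_mu, rel)))[g_alive]
    total <- sum(lam) + sum(mu)
    if (total <= 0) break                       # no events possible
    t_new <- t - stats::rexp(1, total)
    if (has_covariates) {
      cell_floor <- cell_grid[1] - k * 0.1      # younger edge of current cell
      if (t_new < cell_floor && cell_floor > 0) {
        t <- cell_floor                          # rates change at the boundary
        next
      }
    }
    t <- t_new
    if (t <= 0) break
    w <- c(lam, mu)
    pick <- sample.int(2L * n_alive, 1L, prob = w)
    idx_alive <- which(alive)
    if (pick <= n_alive) {                      # budding speciation
      parent <- idx_alive[pick]
      ts <- c(ts, t); te <- c(te, NA_real_)
      group <- c(group, group[parent]); alive <- c(alive, TRUE)
      D[group[parent]] <- D[group[parent]] + 1L
      Dmax <- pmax(Dmax, D)
    } else {                                    # extinction
      victim <- idx_alive[pick - n_alive]
      te[victim] <- t
      alive[victim] <- FALSE
      D[group[victim]] <- D[group[victim]] - 1L
    }
  }
  te[is.na(te)] <- 0
  extinct_all <- all(te > 0)

  grid <- seq(config$origin_time, 0, by = -0.1)
  traj <- vapply(seq_len(K), function(g) {
    sel <- group == g
    vapply(grid, function(tt) sum(ts[sel] >= tt & te[sel] < tt), numeric(1))
  }, numeric(length(grid)))
  colnames(traj) <- paste0("g", seq_len(K))

  structure(list(
    species = data.frame(species = sprintf("sp%05d", seq_along(ts)),
                         group = paste0("g", group), ts = ts, te = te,
                         stringsAsFactors = FALSE),
    grid = grid, trajectories = traj,
    extinct_all = extinct_all, config = config), class = "sim_truth")
}

#' Sample fossil occurrences under a Poisson preservation model
#'
#' Per species, the occurrence count is Poisson with mean equal to the
#' integral of the preservation rate over the species' lifespan; point ages
#' are uniform within the lifespan (HPP) or bin-weighted (TPP). Each point
#' age is wrapped into a dating interval of the configured width, clipped to
#' [0, origin]. Species with zero occurrences are dropped and reported.
#'
#' @param truth A \code{sim_truth}.
#' @param q Preservation rate; scalar (HPP) or per-bin vector (TPP).
#' @param model "HPP" or "TPP".
#' @param bins For TPP, descending vector of bin edges of length
#'   \code{length(q) + 1}; defaults to equal bins tiling [origin, 0].
#' @param interval_width Dating-interval width in Myr.
#' @param seed Integer RNG seed.
#' @return List with \code{occurrences} (species, lat, lon, min_ma, max_ma)
#'   and \code{dropped} (species IDs with no preserved occurrence).
#' @export
sample_preservation <- function(truth, q, model = c("HPP", "TPP"), bins = NULL,
                                interval_width = truth$config$age_interval_width,
                                seed = truth$config$rng_seed + 1L) {
  model <- match.arg(model)
  stopifnot(all(q >= 0), any(q > 0), interval_width > 0,
            nrow(truth$species) > 0)
  set.seed(seed)
  origin <- truth$config$origin_time
  sp <- truth$species
  if (model == "HPP") {
    stopifnot(length(q) == 1L)
    expect <- q * (sp$ts - sp$te)
  } else {
    if (is.null(bins)) bins <- seq(origin, 0, length.out = length(q) + 1L)
    stopifnot(length(bins) == length(q) + 1L, all(diff(bins) < 0))
    ov <- vapply(seq_along(q), function(k) {
      interval_overlap(sp$te, sp$ts, bins[k + 1L], bins[k])
    }, numeric(nrow(sp)))
    ov <- matrix(ov, nrow = nrow(sp))
    expect <- as.vector(ov %*% q)
  }
  n_occ <- stats::rpois(nrow(sp), expect)
  rows <- vector("list", nrow(sp))
  for (i in which(n_occ > 0)) {
    if (model == "HPP") {
      ages <- stats::runif(n_occ[i], sp$te[i], sp$ts[i])
    } else {
      wk <- q * ov[i, ]
      bk <- sample.int(length(q), n_occ[i], replace = TRUE, prob = wk)
      lo <- pmax(sp$te[i], bins[bk + 1L])
      hi <- pmin(sp$ts[i], bins[bk])
      ages <- stats::runif(n_occ[i], lo, hi)
    }
    rows[[i]] <- data.frame(species = sp$species[i],
                            age = ages, stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, rows)
  dropped <- sp$species[n_occ == 0]
  if (is.null(occ)) {
    occ <- data.frame(species = character(), lat = numeric(), lon = numeric(),
                      min_ma = numeric(), max_ma = numeric(),
                      stringsAsFactors = FALSE)
    return(list(occurrences = occ, dropped = dropped))
  }
  w2 <- interval_width / 2
  occ$min_ma <- pmax(occ$age - w2, 0)
  occ$max_ma <- pmin(occ$age + w2, origin)
  # placeholder collection coordinates inside the default Caribbean box
  occ$lat <- stats::runif(nrow(occ), 8, 33)
  occ$lon <- stats::runif(nrow(occ), -98, -56)
  occ <- occ[, c("species", "lat", "lon", "min_ma", "max_ma")]
  row.names(occ) <- NULL
  list(occurrences = occ, dropped = dropped)
}

#' Simulate a smooth environmental covariate series
#'
#' Gaussian random walk on the age grid, smoothed by a moving average of
#' width \code{smoothness} Myr and min-max scaled to [0, 1]; a degenerate
#' (zero-range) series is defined as all zeros. Stands in for scaled
#' paleotemperature or sea-level curves.
#'
#' @param grid Descending age grid (Ma), typically 0.1 Myr steps.
#' @param smoothness Smoothing window in Myr.
#' @param seed Integer RNG seed.
#' @return Data frame with columns \code{age_ma}, \code{value}.
#' @export
simulate_covariate <- function(grid, smoothness = 5, seed = 1) {
  if (length(grid) == 0) stop("empty grid")
  stopifnot(all(diff(grid) < 0))
  set.seed(seed)
  x <- cumsum(stats::rnorm(length(grid)))
  step <- if (length(grid) > 1) abs(grid[1] - grid[2]) else 0.1
  w <- max(1L, round(smoothness / step))
  if (w > 1L) {
    kern <- rep(1 / w, w)
    x <- stats::filter(c(rep(x[1], w), x, rep(x[length(x)], w)), kern, sides = 2)
    x <- as.numeric(x)[w + seq_along(grid)]
  }
  data.frame(age_ma = grid, value = minmax_scale(x))
}

#' Assign growth forms consistent with simulated group membership
#'
#' Expands a mapping from simulated group labels to growth-form subsets into
#' a per-species binary trait table, so that rebuilding MF groups from the
#' table recovers the simulated partition exactly.
#'
#' @param truth A \code{sim_truth}.
#' @param group_to_forms Named list, group label -> character vector of
#'   growth-form names (non-empty subsets of \code{names(growth_forms())}).
#' @return Trait data frame: \code{species} plus the six 0/1 form columns.
#' @export
assign_growth_forms <- function(truth, group_to_forms) {
  sp <- truth$species
  unmapped <- setdiff(unique(sp$group), names(group_to_forms))
  if (length(unmapped)) stop("unmapped group(s): ", paste(unmapped, collapse = ", "))
  forms <- names(growth_forms())
  rows <- t(vapply(sp$group, function(g) {
    sel <- group_to_forms[[g]]
    if (length(sel) == 0) stop("group ", g, " mapped to empty form set")
    bad <- setdiff(sel, forms)
    if (length(bad)) stop("unknown growth form(s): ", paste(bad, collapse = ", "))
    as.integer(forms %in% sel)
  }, integer(length(forms))))
  out <- data.frame(species = sp$species, rows, stringsAsFactors = FALSE)
  names(out) <- c("species", forms)
  row.names(out) <- NULL
  out
}

#' Serialise simulation truth to JSON
#'
#' @param truth A \code{sim_truth}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(species = truth$species,
                            extinct_all = truth$extinct_all,
                            origin_time = truth$config$origin_time),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a covariate series as TSV
#'
#' @param series Data frame with \code{age_ma} and \code{value}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_covariate <- function(series, path) {
  utils::write.table(series, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
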