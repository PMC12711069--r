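#' Interpolate and scale a covariate series onto the analysis grid
#'
#' Linear interpolation of a raw (age, value) series onto the analysis age
#' grid, followed by min-max scaling to [0, 1] so all predictors are
#' commensurable.
#'
#' @param raw Data frame with columns \code{age_ma} (or \code{age}) and
#'   \code{value}; must span the grid.
#' @param grid Descending age grid (Ma).
#' @return Data frame \code{age_ma}, \code{value} with values in [0, 1].
#' @export
prepare_covariates <- function(raw, grid) {
  age_col <- intersect(c("age_ma", "age"), names(raw))[1]
  if (is.na(age_col)) stop("raw series needs an age_ma (or age) column")
  age <- raw[[age_col]]; val <- raw$value
  if (min(age) > min(grid) || max(age) < max(grid)) {
    stop("raw series does not span the analysis grid; refusing to extrapolate")
  }
  if (diff(range(val)) <= 0) stop("zero-range covariate series")
  v <- stats::approx(age, val, xout = grid)$y
  data.frame(age_ma = grid, value = minmax_scale(v))
}

#' Per-group relative diversity predictors
#'
#' Mean range-through lineage count of each MF group across the pooled
#' (Ts, Te) draws, evaluated at every gridpoint and min-max scaled per
#' group, yielding relative-diversity predictor series in [0, 1].
#'
#' @param draws An \code{fbd_draws} (or \code{fbd_chain}) with \code{ts},
#'   \code{te} matrices and \code{species}.
#' @param group_of Named character vector mapping species to group label.
#' @param grid Descending age grid (Ma).
#' @return Named list of predictor data frames (\code{age_ma},
#'   \code{value}), one per group.
#' @export
group_diversity_predictors <- function(draws, group_of, grid) {
  sp <- draws$species
  miss <- setdiff(sp, names(group_of))
  if (length(miss)) stop("no group for species: ", paste(miss, collapse = ", "))
  groups <- unique(unname(group_of[sp]))
  out <- lapply(groups, function(g) {
    cols <- which(unname(group_of[sp]) == g)
    if (length(cols) == 0) stop("empty group: ", g)
    ts <- draws$ts[, cols, drop = FALSE]
    te <- draws$te[, cols, drop = FALSE]
    meanN <- vapply(grid, function(t) mean(rowSums(ts >= t & te < t)), numeric(1))
    if (diff(range(meanN)) <= 0) {
      warning("group ", g, " has constant diversity over the grid; predictor set to 0")
    }
    data.frame(age_ma = grid, value = minmax_scale(meanN))
  })
  names(out) <- groups
  out
}

#' Configuration for the MBD sampler
#'
#' @param iterations,sampling_freq Chain length and thinning.
#' @param burnin_frac Fraction of samples dropped before summarising
#'   (default 0.2).
#' @param link "exponential" (rates = baseline * exp(sum G C)) or "linear"
#'   (baseline * max(0, 1 + sum G C)).
#' @param win_log_base,win_g Proposal widths for baselines (log scale) and
#'   effect coefficients.
#' @param prior_base_shape,prior_base_rate Gamma prior on the baseline rates.
#' @return An \code{mbd_config} list.
#' @export
mbd_config <- function(iterations = 20000, sampling_freq = 10,
                       burnin_frac = 0.2,
                       link = c("exponential", "linear"),
                       win_log_base = 0.3, win_g = 0.3,
                       prior_base_shape = 1.1, prior_base_rate = 1) {
  link <- match.arg(link)
  stopifnot(iterations >= sampling_freq)
  structure(list(iterations = as.integer(iterations),
                 sampling_freq = as.integer(sampling_freq),
                 burnin_frac = burnin_frac, link = link,
                 win_log_base = win_log_base, win_g = win_g,
                 prior_base_shape = prior_base_shape,
                 prior_base_rate = prior_base_rate),
            class = "mbd_config")
}

# Grid-cell birth-death log-likelihood for one draw, given per-cell rates.
# Precomputed per-draw pieces: s_cells (cells of non-origin originations),
# e_cells (cells of extinctions), Ldt (lineage time per cell).
mbd_cell_loglik <- function(lam, mu, piece) {
  if (any(!is.finite(lam)) || any(!is.finite(mu)) ||
      any(lam <= 0) || any(mu <= 0)) return(-Inf)
  sum(log(lam[piece$s_cells])) + sum(log(mu[piece$e_cells])) -
    sum(piece$Ldt * (lam + mu))
}

#' Multivariate birth-death model with horseshoe shrinkage
#'
#' Models origination and extinction rates as a baseline modulated by
#' scaled covariates: lambda(t) = lambda0 exp(sum_j Glambda_j C_j(t)) (and
#' analogously for mu) under the exponential link, evaluated on the 0.1 Myr
#' grid. The (Ts, Te) draws from the birth-death engine are cycled through
#' the MCMC, integrating over age uncertainty. Effect coefficients carry a
#' horseshoe prior G_j ~ N(0, tau^2 psi_j^2) with half-Cauchy local and
#' global scales, updated through exact inverse-gamma conditionals; each
#' predictor's shrinkage weight is the posterior mean of
#' omega_j = 1 - 1 / (1 + tau^2 psi_j^2), bounded in [0, 1], with omega >
#' 0.5 read as escape from shrinkage (non-noise).
#'
#' @param draws An \code{fbd_draws} (pooled Ts/Te draw set).
#' @param predictors Named list of predictor series (data frames
#'   \code{age_ma}, \code{value}) on a common descending grid.
#' @param config An \code{\link{mbd_config}}.
#' @param seed Integer RNG seed.
#' @return An \code{mbd_fit} list: \code{effects} (data frame: predictor,
#'   rate_type, median_G, omega), \code{baselines} (posterior medians of
#'   lambda0, mu0), \code{samples} (post-burn-in matrices of G and omega
#'   draws), \code{config}, \code{seed}.
#' @export
mbd_fit <- function(draws, predictors, config = mbd_config(), seed = 1) {
  stopifnot(length(predictors) >= 1, nrow(draws$ts) >= 1)
  set.seed(seed)
  cfg <- config
  grid <- predictors[[1]]$age_ma
  for (p in predictors) {
    if (!isTRUE(all.equal(p$age_ma, grid))) stop("predictors on mismatched grids")
  }
  C <- vapply(predictors, `[[`, numeric(length(grid)), "value")
  C <- matrix(C, ncol = length(predictors),
              dimnames = list(NULL, names(predictors)))
  p <- ncol(C)
  G <- length(grid)
  step <- abs(grid[1] - grid[2])
  # cell k spans (grid[k] - step/2, grid[k] + step/2]
  cell_of <- function(t) pmin(G, pmax(1L, round((grid[1] - t) / step) + 1L))
  n_draws <- nrow(draws$ts)
  pieces <- lapply(seq_len(n_draws), function(d) {
    s <- draws$ts[d, ]; e <- draws$te[d, ]
    Ldt <- vapply(seq_len(G), function(k) {
      sum(interval_overlap(e, s, grid[k] - step / 2, grid[k] + step / 2))
    }, numeric(1))
    list(s_cells = cell_of(s[s < max(s) - 1e-9]),  # origin ties are censored
         e_cells = cell_of(e[e > 0]),
         Ldt = Ldt)
  })

  rate_fn <- if (cfg$link == "exponential") {
    function(base, g) base * exp(as.vector(C %*% g))
  } else {
    function(base, g) base * pmax(1e-12, 1 + as.vector(C %*% g))
  }

  # state
  log_l0 <- log(0.1); log_m0 <- log(0.1)
  Gl <- rep(0, p); Gm <- rep(0, p)
  psi2_l <- rep(1, p); nu_l <- rep(1, p); tau2_l <- 1; xi_l <- 1
  psi2_m <- rep(1, p); nu_m <- rep(1, p); tau2_m <- 1; xi_m <- 1

  loglik <- function(piece) {
    mbd_cell_loglik(rate_fn(exp(log_l0), Gl), rate_fn(exp(log_m0), Gm), piece)
  }
  piece <- pieces[[1]]
  cur <- loglik(piece)
  if (!is.finite(cur)) stop("non-finite likelihood at initialization")

  n_samp <- cfg$iterations %/% cfg$sampling_freq
  Gl_s <- matrix(NA_real_, n_samp, p); Gm_s <- matrix(NA_real_, n_samp, p)
  wl_s <- matrix(NA_real_, n_samp, p); wm_s <- matrix(NA_real_, n_samp, p)
  base_s <- matrix(NA_real_, n_samp, 2)
  rinvgamma <- function(shape, scale) 1 / stats::rgamma(1, shape, rate = scale)

  si <- 0L
  for (it in seq_len(cfg$iterations)) {
    piece <- pieces[[1L + (it %% n_draws)]]
    cur <- loglik(piece)
    # baselines
    for (b in 1:2) {
      d <- stats::runif(1, -cfg$win_log_base, cfg$win_log_base)
      if (b == 1) log_l0 <- log_l0 + d else log_m0 <- log_m0 + d
      new <- loglik(piece)
      pr_new <- stats::dgamma(exp(if (b == 1) log_l0 else log_m0),
                              cfg$prior_base_shape, cfg$prior_base_rate, log = TRUE)
      old_val <- (if (b == 1) log_l0 else log_m0) - d
      pr_old <- stats::dgamma(exp(old_val), cfg$prior_base_shape,
                              cfg$prior_base_rate, log = TRUE)
      # multiplier proposal on the rate scale: Jacobian term = d
      if (log(stats::runif(1)) < new - cur + pr_new - pr_old + d) {
        cur <- new
      } else {
        if (b == 1) log_l0 <- log_l0 - d else log_m0 <- log_m0 - d
      }
    }
    # effect coefficients, random-walk MH with horseshoe prior
    for (j in seq_len(p)) {
      for (side in 1:2) {
        if (side == 1) {
          old <- Gl[j]; Gl[j] <- old + stats::rnorm(1, 0, cfg$win_g)
          new <- loglik(piece)
          lpr <- stats::dnorm(Gl[j], 0, sqrt(tau2_l * psi2_l[j]), log = TRUE) -
            stats::dnorm(old, 0, sqrt(tau2_l * psi2_l[j]), log = TRUE)
          if (log(stats::runif(1)) < new - cur + lpr) cur <- new else Gl[j] <- old
        } else {
          old <- Gm[j]; Gm[j] <- old + stats::rnorm(1, 0, cfg$win_g)
          new <- loglik(piece)
          lpr <- stats::dnorm(Gm[j], 0, sqrt(tau2_m * psi2_m[j]), log = TRUE) -
            stats::dnorm(old, 0, sqrt(tau2_m * psi2_m[j]), log = TRUE)
          if (log(stats::runif(1)) < new - cur + lpr) cur <- new else Gm[j] <- old
        }
      }
    }
    # horseshoe scales: exact inverse-gamma conditionals
    for (j in seq_len(p)) {
      psi2_l[j] <- rinvgamma(1, 1 / nu_l[j] + Gl[j]^2 / (2 * tau2_l))
      nu_l[j] <- rinvgamma(1, 1 + 1 / psi2_l[j])
      psi2_m[j] <- rinvgamma(1, 1 / nu_m[j] + Gm[j]^2 / (2 * tau2_m))
      nu_m[j] <- rinvgamma(1, 1 + 1 / psi2_m[j])
    }
    tau2_l <- rinvgamma((p + 1) / 2, 1 / xi_l + sum(Gl^2 / psi2_l) / 2)
    xi_l <- rinvgamma(1, 1 + 1 / tau2_l)
    tau2_m <- rinvgamma((p + 1) / 2, 1 / xi_m + sum(Gm^2 / psi2_m) / 2)
    xi_m <- rinvgamma(1, 1 + 1 / tau2_m)

    if (it %% cfg$sampling_freq == 0L) {
      si <- si + 1L
      Gl_s[si, ] <- Gl; Gm_s[si, ] <- Gm
      wl_s[si, ] <- 1 - 1 / (1 + tau2_l * psi2_l)
      wm_s[si, ] <- 1 - 1 / (1 + tau2_m * psi2_m)
      base_s[si, ] <- c(exp(log_l0), exp(log_m0))
    }
  }
  keep <- seq.int(floor(cfg$burnin_frac * n_samp) + 1L, n_samp)
  lab <- names(predictors)
  effects <- rbind(
    data.frame(predictor = lab, rate_type = "origination",
               median_G = apply(Gl_s[keep, , drop = FALSE], 2, stats::median),
               omega = colMeans(wl_s[keep, , drop = FALSE])),
    data.frame(predictor = lab, rate_type = "extinction",
               median_G = apply(Gm_s[keep, , drop = FALSE], 2, stats::median),
               omega = colMeans(wm_s[keep, , drop = FALSE])))
  row.names(effects) <- NULL
  structure(list(effects = effects,
                 baselines = c(lambda0 = stats::median(base_s[keep, 1]),
                               mu0 = stats::median(base_s[keep, 2])),
                 samples = list(G_lambda = Gl_s[keep, , drop = FALSE],
                                G_mu = Gm_s[keep, , drop = FALSE],
                                omega_lambda = wl_s[keep, , drop = FALSE],
                                omega_mu = wm_s[keep, , drop = FALSE],
                                baselines = base_s[keep, , drop = FALSE]),
                 config = cfg, seed = seed),
            class = "mbd_fit")
}

#' Configuration for the MTE sampler
#'
#' @param iterations,sampling_freq Chain length and thinning.
#' @param burnin_frac Fraction of samples dropped before summarising.
#' @param win_log Proposal half-width on the log scale for the baseline and
#'   the multiplier weights.
#' @param prior_base_shape,prior_base_rate Gamma prior on the baseline
#'   extinction rate mu0.
#' @param dirichlet_alpha Concentration of the per-level multiplier
#'   weights: raw weights are Gamma(alpha, alpha) (mean 1), rescaled to
#'   mean 1, i.e. symmetric-Dirichlet up to scale. The default \code{NULL}
#'   places an exponential hyperprior on alpha and learns it per feature
#'   (Bayesian shrinkage: a noise feature drives alpha up and its
#'   multipliers to 1); a positive number fixes it.
#' @param alpha_hyper_rate Rate of the exponential hyperprior on alpha
#'   when it is learned (default 0.02, prior mean 50).
#' @param prior_inclusion Prior inclusion probability of each feature.
#' @return An \code{mte_config} list.
#' @export
mte_config <- function(iterations = 20000, sampling_freq = 10,
                       burnin_frac = 0.2, win_log = 0.4,
                       prior_base_shape = 1.1, prior_base_rate = 1,
                       dirichlet_alpha = NULL, alpha_hyper_rate = 0.02,
                       prior_inclusion = 0.5) {
  stopifnot(iterations >= sampling_freq)
  structure(list(iterations = as.integer(iterations),
                 sampling_freq = as.integer(sampling_freq),
                 burnin_frac = burnin_frac, win_log = win_log,
                 prior_base_shape = prior_base_shape,
                 prior_base_rate = prior_base_rate,
                 dirichlet_alpha = dirichlet_alpha,
                 alpha_hyper_rate = alpha_hyper_rate,
                 prior_inclusion = prior_inclusion),
            class = "mte_config")
}

#' Multi-trait-dependent extinction model
#'
#' Lifespan model: an extinct species' duration Ts - Te is exponential with
#' rate mu_i, and extant species are right-censored at the present. The
#' species rate is mu_i = mu0 * prod_f m_f[level_f(i)] over the included
#' features, each feature's multiplier vector being Dirichlet-distributed
#' (raw Gamma weights rescaled to mean 1 at every sample, so excluded or
#' single-level features contribute exactly 1). A per-feature binary
#' inclusion indicator is sampled; the log Bayes factor is the posterior
#' minus prior log inclusion odds (thresholds 2 / 6 / 10 for positive /
#' strong / very strong support). (Ts, Te) draws are cycled through the
#' MCMC.
#'
#' @param draws An \code{fbd_draws}.
#' @param features Data frame of categorical per-species features (factors
#'   or characters), row order matching \code{draws$species}, e.g. MF-group
#'   label and redundancy category.
#' @param config An \code{\link{mte_config}}.
#' @param seed Integer RNG seed.
#' @return An \code{mte_fit} list: \code{multipliers} (data frame: feature,
#'   level, mean, lo95, hi95), \code{inclusion} (data frame: feature,
#'   prob, log_bf), \code{mu0} posterior summary, \code{samples},
#'   \code{config}, \code{seed}.
#' @export
mte_fit <- function(draws, features, config = mte_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  n <- length(draws$species)
  if (!is.data.frame(features) && length(features) == 0) features <- data.frame()
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) > 0 && nrow(features) != n) {
    stop("features must have one row per species")
  }
  F <- ncol(features)
  lev <- lapply(features, function(col) sort(unique(as.character(col))))
  idx <- lapply(seq_len(F), function(f) match(as.character(features[[f]]), lev[[f]]))
  n_draws <- nrow(draws$ts)

  # state: log mu0, per-feature raw gamma weights, concentrations, inclusion
  log_m0 <- log(0.1)
  gw <- lapply(lev, function(lv) rep(1, length(lv)))
  z <- rep(TRUE, F)
  fixed_alpha <- !is.null(cfg$dirichlet_alpha)
  alpha <- rep(if (fixed_alpha) cfg$dirichlet_alpha else 1, F)

  mult_of <- function(f) {
    m <- gw[[f]] / mean(gw[[f]])
    m
  }
  rate_vec <- function() {
    r <- rep(exp(log_m0), n)
    for (f in seq_len(F)) {
      if (z[f] && length(lev[[f]]) > 1L) r <- r * mult_of(f)[idx[[f]]]
    }
    r
  }
  ll_of <- function(dur, ext, r) {
    sum(log(r[ext])) - sum(r * dur)
  }
  d <- 1L
  dur <- draws$ts[d, ] - draws$te[d, ]
  ext <- draws$te[d, ] > 0
  cur <- ll_of(dur, ext, rate_vec())

  n_samp <- cfg$iterations %/% cfg$sampling_freq
  m0_s <- numeric(n_samp)
  z_s <- matrix(NA, n_samp, max(F, 1L))
  mult_s <- lapply(lev, function(lv) matrix(NA_real_, n_samp, length(lv)))
  si <- 0L
  for (it in seq_len(cfg$iterations)) {
    d <- 1L + (it %% n_draws)
    dur <- draws$ts[d, ] - draws$te[d, ]
    ext <- draws$te[d, ] > 0
    cur <- ll_of(dur, ext, rate_vec())
    # baseline
    step <- stats::runif(1, -cfg$win_log, cfg$win_log)
    log_m0 <- log_m0 + step
    new <- ll_of(dur, ext, rate_vec())
    pr <- stats::dgamma(exp(log_m0), cfg$prior_base_shape, cfg$prior_base_rate,
                        log = TRUE) -
      stats::dgamma(exp(log_m0 - step), cfg$prior_base_shape,
                    cfg$prior_base_rate, log = TRUE)
    if (log(stats::runif(1)) < new - cur + pr + step) cur <- new
    else log_m0 <- log_m0 - step
    # multiplier weights (one random level per feature)
    for (f in seq_len(F)) {
      if (length(lev[[f]]) < 2L) next
      l <- sample.int(length(lev[[f]]), 1L)
      old <- gw[[f]][l]
      fac <- exp(stats::runif(1, -cfg$win_log, cfg$win_log))
      gw[[f]][l] <- old * fac
      new <- ll_of(dur, ext, rate_vec())
      pr <- stats::dgamma(gw[[f]][l], alpha[f], alpha[f], log = TRUE) -
        stats::dgamma(old, alpha[f], alpha[f], log = TRUE)
      if (log(stats::runif(1)) < new - cur + pr + log(fac)) cur <- new
      else gw[[f]][l] <- old
    }
    # concentration hyperparameters (the likelihood only sees the normalized
    # multipliers, so alpha moves on the prior alone)
    if (!fixed_alpha) for (f in seq_len(F)) {
      if (length(lev[[f]]) < 2L) next
      fac <- exp(stats::runif(1, -cfg$win_log, cfg$win_log))
      a_new <- alpha[f] * fac
      lp <- sum(stats::dgamma(gw[[f]], a_new, a_new, log = TRUE)) -
        sum(stats::dgamma(gw[[f]], alpha[f], alpha[f], log = TRUE)) +
        stats::dexp(a_new, cfg$alpha_hyper_rate, log = TRUE) -
        stats::dexp(alpha[f], cfg$alpha_hyper_rate, log = TRUE) + log(fac)
      if (log(stats::runif(1)) < lp) alpha[f] <- a_new
    }
    # inclusion flips
    for (f in seq_len(F)) {
      if (length(lev[[f]]) < 2L) next
      z[f] <- !z[f]
      new <- ll_of(dur, ext, rate_vec())
      lp <- log(ifelse(z[f], cfg$prior_inclusion, 1 - cfg$prior_inclusion)) -
        log(ifelse(z[f], 1 - cfg$prior_inclusion, cfg$prior_inclusion))
      if (log(stats::runif(1)) < new - cur + lp) cur <- new else z[f] <- !z[f]
    }
    if (it %% cfg$sampling_freq == 0L) {
      si <- si + 1L
      m0_s[si] <- exp(log_m0)
      if (F > 0) z_s[si, seq_len(F)] <- z
      for (f in seq_len(F)) mult_s[[f]][si, ] <- mult_of(f)
    }
  }
  keep <- seq.int(floor(cfg$burnin_frac * n_samp) + 1L, n_samp)
  mult_tab <- NULL
  incl_tab <- NULL
  if (F > 0) {
    mult_tab <- do.call(rbind, lapply(seq_len(F), function(f) {
      m <- mult_s[[f]][keep, , drop = FALSE]
      data.frame(feature = names(features)[f], level = lev[[f]],
                 mean = colMeans(m),
                 lo95 = apply(m, 2, stats::quantile, 0.025),
                 hi95 = apply(m, 2, stats::quantile, 0.975))
    }))
    row.names(mult_tab) <- NULL
    nk <- length(keep)
    pz <- colMeans(z_s[keep, seq_len(F), drop = FALSE])
    pz <- pmin(pmax(pz, 1 / (nk + 1)), nk / (nk + 1))
    log_bf <- log(pz / (1 - pz)) -
      log(cfg$prior_inclusion / (1 - cfg$prior_inclusion))
    incl_tab <- data.frame(feature = names(features), prob = pz,
                           log_bf = log_bf)
    row.names(incl_tab) <- NULL
  }
  structure(list(multipliers = mult_tab, inclusion = incl_tab,
                 mu0 = c(mean = mean(m0_s[keep]),
                         sd = stats::sd(m0_s[keep]),
                         lo95 = unname(stats::quantile(m0_s[keep], 0.025)),
                         hi95 = unname(stats::quantile(m0_s[keep], 0.975))),
                 samples = list(mu0 = m0_s[keep],
                                inclusion = if (F > 0) z_s[keep, seq_len(F), drop = FALSE] else NULL,
                                multipliers = lapply(mult_s, function(m) m[keep, , drop = FALSE])),
                 config = cfg, seed = seed),
            class = "mte_fit")
}
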