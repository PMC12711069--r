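#' Configuration for the fossil birth-death rjMCMC
#'
#' Desk-scale defaults (2e5 iterations, sampling every 200) keep a ~100
#' species analysis in the minutes range; \code{full_scale = TRUE} switches
#' to the full-fidelity settings (5e6 iterations, sampling every 5000) used
#' for production runs.
#'
#' @param iterations,sampling_freq Chain length and thinning interval.
#' @param preservation "HPP", "NHPP" or "TPP".
#' @param tpp_bins Descending bin edges when \code{preservation = "TPP"}.
#' @param prior_rate_shape,prior_rate_rate Gamma prior on birth/death rates
#'   (default Gamma(1.1, 1)).
#' @param prior_q_shape,prior_q_rate Gamma prior on preservation rates.
#' @param prior_shift_poisson Poisson prior mean on the number of rate
#'   shifts per rate type (default 0.5).
#' @param win_age Sliding-window half-width (Myr) for origination/extinction
#'   time proposals.
#' @param win_log_q,win_log_rate Half-widths of the log-scale multiplier
#'   proposals for preservation and birth/death rates.
#' @param update_fraction Fraction of species whose times are updated per
#'   time move.
#' @param max_update Cap on the number of species updated per time move
#'   (small blocks keep the joint acceptance rate workable).
#' @param move_weights Probabilities of the four move families (times, q,
#'   rates, rj shift birth/death).
#' @param likelihood_off If TRUE the likelihood is forced to zero so the
#'   chain samples the prior (used for prior-recovery checks).
#' @param max_init_retries Re-initialisation attempts before failing on a
#'   non-finite starting posterior.
#' @param full_scale Use full-fidelity chain settings.
#' @return An \code{fbd_config} list.
#' @export
fbd_config <- function(iterations = 2e5, sampling_freq = 200,
                       preservation = "HPP", tpp_bins = NULL,
                       prior_rate_shape = 1.1, prior_rate_rate = 1,
                       prior_q_shape = 1.1, prior_q_rate = 1,
                       prior_shift_poisson = 0.5,
                       win_age = 1.5, win_log_q = 0.4, win_log_rate = 0.5,
                       update_fraction = 0.05, max_update = 5,
                       move_weights = c(times = 0.5, q = 0.1,
                                        rates = 0.25, rj = 0.15),
                       likelihood_off = FALSE, max_init_retries = 20,
                       full_scale = FALSE) {
  if (full_scale) {
    iterations <- 5e6
    sampling_freq <- 5000
  }
  stopifnot(iterations >= sampling_freq, sampling_freq >= 1,
            preservation %in% c("HPP", "NHPP", "TPP"))
  mw <- move_weights / sum(move_weights)
  structure(list(iterations = as.integer(iterations),
                 sampling_freq = as.integer(sampling_freq),
                 preservation = preservation, tpp_bins = tpp_bins,
                 prior_rate_shape = prior_rate_shape,
                 prior_rate_rate = prior_rate_rate,
                 prior_q_shape = prior_q_shape, prior_q_rate = prior_q_rate,
                 prior_shift_poisson = prior_shift_poisson,
                 win_age = win_age, win_log_q = win_log_q,
                 win_log_rate = win_log_rate,
                 update_fraction = update_fraction, max_update = max_update,
                 move_weights = mw,
                 likelihood_off = likelihood_off,
                 max_init_retries = max_init_retries),
            class = "fbd_config")
}

# log prior of the full rate history + preservation state
fbd_log_prior <- function(q, lambda, mu, k_l, k_m, span, cfg) {
  sum(stats::dgamma(q, cfg$prior_q_shape, cfg$prior_q_rate, log = TRUE)) +
    sum(stats::dgamma(lambda, cfg$prior_rate_shape, cfg$prior_rate_rate, log = TRUE)) +
    sum(stats::dgamma(mu, cfg$prior_rate_shape, cfg$prior_rate_rate, log = TRUE)) +
    stats::dpois(k_l, cfg$prior_shift_poisson, log = TRUE) +
    stats::dpois(k_m, cfg$prior_shift_poisson, log = TRUE) +
    lfactorial(k_l) - k_l * log(span) +
    lfactorial(k_m) - k_m * log(span)
}

#' Reversible-jump MCMC over origination/extinction times and rates
#'
#' Metropolis-Hastings sampler over per-species origination (Ts) and
#' extinction (Te) times, preservation rate(s) q, and piecewise-constant
#' origination/extinction rate histories whose shift counts are sampled by
#' reversible-jump birth/death moves (new shift times uniform over the span,
#' new rates drawn from the prior, Jacobian 1). The posterior combines the
#' Poisson preservation likelihood, the birth-death likelihood of (Ts, Te),
#' and Gamma/Poisson priors.
#'
#' @param dataset A \code{fossil_dataset} (columns species, age).
#' @param config An \code{\link{fbd_config}}.
#' @param seed Integer RNG seed; identical seeds give identical chains.
#' @param extant Character vector of species treated as extant (Te fixed
#'   at 0); defaults to \code{attr(dataset, "extant")}.
#' @return An \code{fbd_chain}: \code{trace} (data frame of iteration,
#'   log-likelihood, log-posterior, q, shift counts, mean rates), \code{ts}
#'   and \code{te} sample matrices (samples x species), \code{rates} (list
#'   of per-sample rate histories), \code{species}, \code{span},
#'   \code{acceptance} per move family, \code{config}, \code{seed}.
#' @export
run_rjmcmc <- function(dataset, config = fbd_config(), seed = 1,
                       extant = attr(dataset, "extant")) {
  stopifnot(nrow(dataset) > 0)
  set.seed(seed)
  cfg <- config
  fd <- index_fossil_data(dataset)
  n <- length(fd$species)
  is_extant <- fd$species %in% (extant %||% character(0))
  span <- max(fd$ages) * 1.1 + 1          # fixed span for shift-time prior

  make_pm <- function(q) {
    if (cfg$preservation == "TPP") {
      bins <- cfg$tpp_bins %||% seq(span, 0, length.out = 5)
      structure(list(kind = "TPP", q = q, bins = bins),
                class = "preservation_model")
    } else {
      structure(list(kind = cfg$preservation, q = q, bins = NULL),
                class = "preservation_model")
    }
  }
  n_q <- if (cfg$preservation == "TPP") {
    length(cfg$tpp_bins %||% seq(span, 0, length.out = 5)) - 1L
  } else 1L

  pres_ll <- function(s, e, q) {
    if (cfg$likelihood_off) return(0)
    preservation_loglik_indexed(fd, s, e, make_pm(q))
  }
  bd_ll <- function(s, e, lambda, mu, sh_l, sh_m) {
    if (cfg$likelihood_off) return(0)
    bd_loglik(s, e, lambda, mu, sh_l, sh_m)
  }

  # --- initialization (retry with jitter on non-finite posterior) ---
  init_ok <- FALSE
  for (try in seq_len(cfg$max_init_retries)) {
    s <- fd$max_occ + stats::runif(n, 0.05, 0.5)
    e <- ifelse(is_extant, 0, pmax(0, fd$min_occ - stats::runif(n, 0.05, 0.5)))
    q <- rep(max(sum(fd$n) / max(sum(s - e), 1), 0.1), n_q)
    lambda <- n / max(sum(s - e), 1) + 0.05
    mu <- lambda * 0.7
    sh_l <- numeric(0); sh_m <- numeric(0)
    cur_pres <- pres_ll(s, e, q)
    cur_bd <- bd_ll(s, e, lambda, mu, sh_l, sh_m)
    cur_prior <- fbd_log_prior(q, lambda, mu, 0L, 0L, span, cfg)
    if (is.finite(cur_pres + cur_bd + cur_prior)) { init_ok <- TRUE; break }
  }
  if (!init_ok) stop("could not initialize a finite posterior after ",
                     cfg$max_init_retries, " attempts")

  n_samp <- cfg$iterations %/% cfg$sampling_freq
  ts_out <- matrix(NA_real_, n_samp, n, dimnames = list(NULL, fd$species))
  te_out <- matrix(NA_real_, n_samp, n, dimnames = list(NULL, fd$species))
  rates_out <- vector("list", n_samp)
  trace <- data.frame(it = integer(n_samp), loglik = numeric(n_samp),
                      logpost = numeric(n_samp), q = numeric(n_samp),
                      k_lambda = integer(n_samp), k_mu = integer(n_samp),
                      mean_lambda = numeric(n_samp), mean_mu = numeric(n_samp))
  acc <- c(times = 0, q = 0, rates = 0, rj = 0)
  prop <- c(times = 0, q = 0, rates = 0, rj = 0)
  n_upd <- max(1L, min(cfg$max_update, round(cfg$update_fraction * n)))
  pois_death <- function(k) if (k == 0L) 0 else 0.5
  pois_birth <- function(k) if (k == 0L) 1 else 0.5

  si <- 0L
  for (it in seq_len(cfg$iterations)) {
    mv <- sample.int(4L, 1L, prob = cfg$move_weights)
    if (mv == 1L) {                                     # Ts / Te windows
      prop["times"] <- prop["times"] + 1
      pick <- sample.int(n, min(n_upd, n))
      s_new <- s; e_new <- e
      if (stats::runif(1) < 0.5) {
        s_new[pick] <- s[pick] + stats::runif(length(pick), -cfg$win_age, cfg$win_age)
        valid <- all(s_new[pick] > fd$max_occ[pick])
      } else {
        upd <- pick[!is_extant[pick]]
        if (length(upd)) {
          e_new[upd] <- e[upd] + stats::runif(length(upd), -cfg$win_age, cfg$win_age)
          valid <- all(e_new[upd] >= 0 & e_new[upd] < fd$min_occ[upd])
        } else {
          valid <- FALSE
        }
      }
      if (valid) {
        new_pres <- pres_ll(s_new, e_new, q)
        new_bd <- bd_ll(s_new, e_new, lambda, mu, sh_l, sh_m)
        if (log(stats::runif(1)) < (new_pres + new_bd) - (cur_pres + cur_bd)) {
          s <- s_new; e <- e_new
          cur_pres <- new_pres; cur_bd <- new_bd
          acc["times"] <- acc["times"] + 1
        }
      }
    } else if (mv == 2L) {                              # preservation rate
      prop["q"] <- prop["q"] + 1
      j <- sample.int(n_q, 1L)
      fac <- exp(stats::runif(1, -cfg$win_log_q, cfg$win_log_q))
      q_new <- q; q_new[j] <- q[j] * fac
      new_pres <- pres_ll(s, e, q_new)
      new_prior <- fbd_log_prior(q_new, lambda, mu, length(sh_l), length(sh_m),
                                 span, cfg)
      if (log(stats::runif(1)) <
          (new_pres + new_prior) - (cur_pres + cur_prior) + log(fac)) {
        q <- q_new; cur_pres <- new_pres; cur_prior <- new_prior
        acc["q"] <- acc["q"] + 1
      }
    } else if (mv == 3L) {                              # rate multiplier
      prop["rates"] <- prop["rates"] + 1
      on_lambda <- stats::runif(1) < 0.5
      vec <- if (on_lambda) lambda else mu
      j <- sample.int(length(vec), 1L)
      fac <- exp(stats::runif(1, -cfg$win_log_rate, cfg$win_log_rate))
      vec_new <- vec; vec_new[j] <- vec[j] * fac
      l_new <- if (on_lambda) vec_new else lambda
      m_new <- if (on_lambda) mu else vec_new
      new_bd <- bd_ll(s, e, l_new, m_new, sh_l, sh_m)
      new_prior <- fbd_log_prior(q, l_new, m_new, length(sh_l), length(sh_m),
                                 span, cfg)
      if (log(stats::runif(1)) <
          (new_bd + new_prior) - (cur_bd + cur_prior) + log(fac)) {
        lambda <- l_new; mu <- m_new
        cur_bd <- new_bd; cur_prior <- new_prior
        acc["rates"] <- acc["rates"] + 1
      }
    } else {                                            # rj shift birth/death
      prop["rj"] <- prop["rj"] + 1
      on_lambda <- stats::runif(1) < 0.5
      vec <- if (on_lambda) lambda else mu
      sh <- if (on_lambda) sh_l else sh_m
      k <- length(sh)
      birth <- stats::runif(1) < pois_birth(k)
      if (birth) {
        t_star <- stats::runif(1, 0, span)
        r_star <- stats::rgamma(1, cfg$prior_rate_shape, cfg$prior_rate_rate)
        sh_sorted <- sort(sh, decreasing = TRUE)
        j <- findInterval(-t_star, -sh_sorted) + 1L   # segment containing t*
        sh_new <- sort(c(sh_sorted, t_star), decreasing = TRUE)
        vec_new <- append(vec, r_star, after = j - 1L)
        log_prop <- log(pois_death(k + 1L)) - log(k + 1) -
          (log(pois_birth(k)) - log(span) +
             stats::dgamma(r_star, cfg$prior_rate_shape, cfg$prior_rate_rate,
                           log = TRUE))
      } else {
        sh_sorted <- sort(sh, decreasing = TRUE)
        j <- sample.int(k, 1L)
        r_removed <- vec[j]
        sh_new <- sh_sorted[-j]
        vec_new <- vec[-j]
        log_prop <- log(pois_birth(k - 1L)) - log(span) +
          stats::dgamma(r_removed, cfg$prior_rate_shape, cfg$prior_rate_rate,
                        log = TRUE) -
          (log(pois_death(k)) - log(k))
      }
      l_new <- if (on_lambda) vec_new else lambda
      m_new <- if (on_lambda) mu else vec_new
      shl_new <- if (on_lambda) sh_new else sh_l
      shm_new <- if (on_lambda) sh_m else sh_new
      new_bd <- bd_ll(s, e, l_new, m_new, shl_new, shm_new)
      new_prior <- fbd_log_prior(q, l_new, m_new, length(shl_new),
                                 length(shm_new), span, cfg)
      if (log(stats::runif(1)) <
          (new_bd + new_prior) - (cur_bd + cur_prior) + log_prop) {
        lambda <- l_new; mu <- m_new; sh_l <- shl_new; sh_m <- shm_new
        cur_bd <- new_bd; cur_prior <- new_prior
        acc["rj"] <- acc["rj"] + 1
      }
    }

    if (it %% cfg$sampling_freq == 0L) {
      si <- si + 1L
      ts_out[si, ] <- s
      te_out[si, ] <- e
      rates_out[[si]] <- list(lambda = lambda, mu = mu,
                              lambda_shifts = sh_l, mu_shifts = sh_m, q = q)
      trace$it[si] <- it
      trace$loglik[si] <- cur_pres + cur_bd
      trace$logpost[si] <- cur_pres + cur_bd + cur_prior
      trace$q[si] <- mean(q)
      trace$k_lambda[si] <- length(sh_l)
      trace$k_mu[si] <- length(sh_m)
      trace$mean_lambda[si] <- mean(lambda)
      trace$mean_mu[si] <- mean(mu)
    }
  }
  structure(list(trace = trace, ts = ts_out, te = te_out, rates = rates_out,
                 species = fd$species, span = span,
                 acceptance = ifelse(prop > 0, acc / prop, NA),
                 config = cfg, seed = seed),
            class = "fbd_chain")
}

#' Combine replicate chains into a pooled draw set
#'
#' Per replicate chain, drops the first \code{burnin_frac} of samples as
#' burn-in and draws \code{n_per_chain} samples uniformly without
#' replacement from the remainder; draws are pooled across replicates
#' (10 chains x 100 draws = 1000 pooled draws by default).
#'
#' @param chains List of \code{fbd_chain} objects over the same species.
#' @param burnin_frac Fraction of each chain discarded (default 0.1).
#' @param n_per_chain Draws retained per chain (default 100).
#' @param seed Integer RNG seed.
#' @return An \code{fbd_draws} list: \code{ts}, \code{te} pooled sample
#'   matrices, \code{species}, and \code{source} (chain and sample index of
#'   every pooled draw).
#' @export
combine_replicates <- function(chains, burnin_frac = 0.1, n_per_chain = 100,
                               seed = 1) {
  stopifnot(length(chains) >= 1)
  species <- chains[[1]]$species
  for (ch in chains) {
    if (!identical(ch$species, species)) stop("chains cover different species")
  }
  set.seed(seed)
  pieces <- lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    n <- nrow(ch$ts)
    burn <- floor(burnin_frac * n)
    avail <- seq.int(burn + 1L, n)
    if (length(avail) < n_per_chain) {
      stop("chain ", i, " has only ", length(avail),
           " post-burn-in samples; need ", n_per_chain)
    }
    keep <- sort(sample(avail, n_per_chain))
    list(ts = ch$ts[keep, , drop = FALSE], te = ch$te[keep, , drop = FALSE],
         source = data.frame(chain = i, index = keep))
  })
  structure(list(ts = do.call(rbind, lapply(pieces, `[[`, "ts")),
                 te = do.call(rbind, lapply(pieces, `[[`, "te")),
                 species = species,
                 source = do.call(rbind, lapply(pieces, `[[`, "source"))),
            class = "fbd_draws")
}

#' Rate- and diversity-through-time curves
#'
#' Summarises a chain (or pooled draws) on a regular age grid: posterior
#' mean and central 95% interval of origination, extinction and net
#' diversification rates; range-through diversity N(t); and the fraction of
#' samples placing at least one rate shift in each grid bin.
#'
#' @param x An \code{fbd_chain} (rates + times) or \code{fbd_draws}
#'   (diversity only).
#' @param grid_step Grid step in Myr (default 0.1).
#' @param grid Optional explicit descending age grid.
#' @return List with \code{curves} (long data frame: age, curve, mean,
#'   lo95, hi95) and, for chains, \code{shift_frequency} (data frame: age,
#'   rate_type, freq).
#' @export
rtt_curves <- function(x, grid_step = 0.1, grid = NULL) {
  has_rates <- inherits(x, "fbd_chain")
  ts <- x$ts; te <- x$te
  if (is.null(grid)) {
    top <- ceiling(max(ts) / grid_step) * grid_step
    grid <- seq(top, 0, by = -grid_step)
  }
  D <- nrow(ts)
  qs <- function(m) {
    data.frame(mean = colMeans(m),
               lo95 = apply(m, 2, stats::quantile, 0.025),
               hi95 = apply(m, 2, stats::quantile, 0.975))
  }
  div <- vapply(grid, function(t) rowSums(ts >= t & te < t), numeric(D))
  div <- matrix(div, nrow = D)
  out <- list()
  s <- qs(div)
  out$diversity <- data.frame(age = grid, curve = "diversity", s)
  if (has_rates) {
    lam <- vapply(grid, function(t) {
      vapply(x$rates, function(r) rate_at(r$lambda, r$lambda_shifts, t), numeric(1))
    }, numeric(D))
    mu <- vapply(grid, function(t) {
      vapply(x$rates, function(r) rate_at(r$mu, r$mu_shifts, t), numeric(1))
    }, numeric(D))
    lam <- matrix(lam, nrow = D); mu <- matrix(mu, nrow = D)
    out$lambda <- data.frame(age = grid, curve = "origination", qs(lam))
    out$mu <- data.frame(age = grid, curve = "extinction", qs(mu))
    out$net <- data.frame(age = grid, curve = "net_diversification", qs(lam - mu))
    edges_hi <- grid + grid_step / 2
    edges_lo <- grid - grid_step / 2
    freq_of <- function(field) {
      vapply(seq_along(grid), function(i) {
        mean(vapply(x$rates, function(r) {
          any(r[[field]] >= edges_lo[i] & r[[field]] < edges_hi[i])
        }, logical(1)))
      }, numeric(1))
    }
    shift_frequency <- rbind(
      data.frame(age = grid, rate_type = "origination",
                 freq = freq_of("lambda_shifts")),
      data.frame(age = grid, rate_type = "extinction",
                 freq = freq_of("mu_shifts")))
  }
  curves <- do.call(rbind, out)
  row.names(curves) <- NULL
  res <- list(curves = curves)
  if (has_rates) res$shift_frequency <- shift_frequency
  res
}
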