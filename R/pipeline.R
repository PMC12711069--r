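#' Default pipeline configuration
#'
#' Desk-scale settings for the end-to-end pipeline: a small synthetic
#' multi-group fossil record, a handful of age-resampling replicates, short
#' rjMCMC chains and reduced-length covariate-model chains. Any entry can
#' be overridden by the user's YAML file; unknown keys are rejected.
#'
#' @return Nested list of stage settings.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = "reefdd-output",
    simulate = list(origin_time = 30, n_groups = 3, seed_species_per_group = 2,
                    base_lambda = 0.25, base_mu = 0.12, q_true = 1.5,
                    age_interval_width = 2),
    occurrences = list(n_replicates = 3),
    indices = list(n_sims = 999),
    fbd = list(iterations = 20000, sampling_freq = 20, preservation = "HPP"),
    combine = list(burnin_frac = 0.1, n_per_chain = 100),
    mbd = list(iterations = 4000, sampling_freq = 10),
    mte = list(iterations = 4000, sampling_freq = 10),
    network = list(threshold = 0.6)
  )
}

# Merge a user config over defaults, rejecting unknown keys at both levels.
merge_pipeline_config <- function(user) {
  base <- default_pipeline_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), names(base[[k]]))
      if (length(bad)) {
        stop("unknown config key(s) under '", k, "': ", paste(bad, collapse = ", "))
      }
      base[[k]][names(user[[k]])] <- user[[k]]
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

# Default mapping of simulated groups to growth-form subsets (up to 6 groups).
default_group_forms <- function(n_groups) {
  pool <- list(g1 = "massive", g2 = "branching",
               g3 = c("massive", "encrusting"), g4 = "laminar",
               g5 = "encrusting", g6 = c("branching", "massive"))
  if (n_groups > length(pool)) stop("default form mapping supports up to 6 groups")
  pool[seq_len(n_groups)]
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-data generation, occurrence write/read
#' round-trip and curation, MF-group construction, functional indices with
#' permutation nulls, per-replicate rjMCMC estimation of (Ts, Te) and
#' rates, replicate combination, covariate and group-diversity predictor
#' preparation, MBD and MTE fits, network construction and report tables.
#' Every stage derives its seed deterministically from the top-level seed,
#' so a rerun with the same configuration reproduces every numeric table
#' byte for byte. A failing stage halts with the stage name; outputs
#' written before the failure remain on disk. Stage results are
#' checkpointed under \code{out_dir/checkpoints} and reused when
#' \code{resume = TRUE}.
#'
#' @param config Path to a YAML configuration file, or an equivalent nested
#'   list (see \code{\link{default_pipeline_config}}).
#' @param out_dir Output directory override.
#' @param resume Reuse existing stage checkpoints.
#' @return Invisible list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, resume = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_pipeline_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ckpt_dir <- file.path(cfg$out_dir, "checkpoints")
  dir.create(ckpt_dir, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)

  stage <- function(name, fun) {
    ck <- file.path(ckpt_dir, paste0(name, ".rds"))
    if (resume && file.exists(ck)) return(readRDS(ck))
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    saveRDS(res, ck)
    res
  }

  sim <- stage("simulate", function() {
    sc <- do.call(sim_config, c(cfg$simulate, list(rng_seed = derive_seed(seed, 1))))
    truth <- simulate_bd_forward(sc)
    if (truth$extinct_all) message("note: all simulated lineages extinct before present")
    prs <- sample_preservation(truth, q = sc$q_true, model = "HPP",
                               seed = derive_seed(seed, 2))
    traits <- assign_growth_forms(truth, default_group_forms(sc$n_groups))
    covariate <- simulate_covariate(truth$grid, seed = derive_seed(seed, 3))
    write_occurrences(prs$occurrences, file.path(cfg$out_dir, "occurrences.csv"))
    utils::write.csv(traits, file.path(cfg$out_dir, "traits.csv"), row.names = FALSE)
    write_covariate(covariate, file.path(cfg$out_dir, "covariate.tsv"))
    write_truth(truth, file.path(cfg$out_dir, "truth.json"))
    list(truth = truth, dropped = prs$dropped, traits = traits,
         covariate = covariate)
  })

  cur <- stage("curate", function() {
    occ <- read_occurrences(file.path(cfg$out_dir, "occurrences.csv"))
    if (nrow(occ$rejects)) stop("synthetic occurrences failed validation")
    res <- curate_occurrences(occ$records)
    jsonlite::write_json(res$audit, file.path(cfg$out_dir, "curation_audit.json"),
                         auto_unbox = TRUE)
    res
  })

  grp <- stage("groups", function() {
    traits <- sim$traits[sim$traits$species %in% cur$records$species, , drop = FALSE]
    g <- build_mf_groups(traits, cur$records)
    classify_dominant(g)
  })

  idx <- stage("indices", function() {
    traits <- sim$traits
    epochs <- ics_epochs()
    epoch_profile(cur$records, traits, epochs,
                  n_sims = cfg$indices$n_sims, seed = derive_seed(seed, 4))
  })

  chains <- stage("fbd", function() {
    reps <- resample_ages(cur$records, n_replicates = cfg$occurrences$n_replicates,
                          seed = derive_seed(seed, 5))
    extant <- sim$truth$species$species[sim$truth$species$te == 0]
    fc <- fbd_config(iterations = cfg$fbd$iterations,
                     sampling_freq = cfg$fbd$sampling_freq,
                     preservation = cfg$fbd$preservation)
    lapply(seq_along(reps), function(r) {
      run_rjmcmc(reps[[r]], fc, seed = derive_seed(seed, 100 + r), extant = extant)
    })
  })

  draws <- stage("combine", function() {
    n_samp <- nrow(chains[[1]]$ts)
    npc <- min(cfg$combine$n_per_chain,
               n_samp - floor(cfg$combine$burnin_frac * n_samp))
    combine_replicates(chains, burnin_frac = cfg$combine$burnin_frac,
                       n_per_chain = npc, seed = derive_seed(seed, 6))
  })

  fit_mbd <- stage("mbd", function() {
    grid <- sim$truth$grid
    traits <- sim$traits
    grp_map <- stats::setNames(
      apply(traits[, names(growth_forms())] != 0, 1, canonical_label),
      traits$species)
    preds <- group_diversity_predictors(draws, grp_map, grid)
    preds$temperature <- prepare_covariates(sim$covariate, grid)
    mc <- mbd_config(iterations = cfg$mbd$iterations,
                     sampling_freq = cfg$mbd$sampling_freq)
    mbd_fit(draws, preds, mc, seed = derive_seed(seed, 7))
  })

  fit_mte <- stage("mte", function() {
    traits <- sim$traits
    grp_map <- stats::setNames(
      apply(traits[, names(growth_forms())] != 0, 1, canonical_label),
      traits$species)
    glab <- unname(grp_map[draws$species])
    gsize <- table(glab)
    features <- data.frame(
      mf_group = glab,
      redundancy = as.character(redundancy_category(as.integer(gsize[glab]))),
      stringsAsFactors = FALSE)
    mc <- mte_config(iterations = cfg$mte$iterations,
                     sampling_freq = cfg$mte$sampling_freq)
    mte_fit(draws, features, mc, seed = derive_seed(seed, 8))
  })

  net <- stage("network", function() {
    eff <- fit_mbd$effects
    eff$from <- eff$predictor
    eff$to <- "All"
    build_network(eff, threshold = cfg$network$threshold)
  })

  reports <- stage("reports", function() {
    eff <- fit_mbd$effects
    eff$from <- eff$predictor
    eff$to <- "All"
    rtt <- rtt_curves(chains[[1]])
    utils::write.csv(rtt$curves, file.path(cfg$out_dir, "rtt_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(net, file.path(cfg$out_dir, "network_edges.csv"),
                     row.names = FALSE)
    table_reports(list(groups = grp, epoch_profile = idx, effects = eff),
                  cfg$out_dir, threshold = cfg$network$threshold)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefdd")),
    seed = seed,
    config = cfg,
    input_hashes = as.list(tools::md5sum(
      Filter(file.exists, file.path(cfg$out_dir,
        c("occurrences.csv", "traits.csv", "covariate.tsv")))))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(sim = sim, curated = cur, groups = grp, indices = idx,
                 chains = chains, draws = draws, mbd = fit_mbd, mte = fit_mte,
                 network = net, manifest = manifest))
}
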