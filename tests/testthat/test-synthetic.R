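test_that("a rate-free configuration yields exactly the seed lineage", {
  sc <- sim_config(origin_time = 66, n_groups = 1, seed_species_per_group = 1,
                   base_lambda = 0, base_mu = 0, rng_seed = 1)
  tr <- simulate_bd_forward(sc)
  expect_equal(nrow(tr$species), 1L)
  expect_equal(tr$species$ts, 66)
  expect_equal(tr$species$te, 0)
  expect_false(tr$extinct_all)
})

test_that("mean extant diversity matches the linear birth-death expectation", {
  # E[N(t)] = exp((lambda - mu) t) for a single seed lineage
  n_seeds <- 300
  extant <- vapply(seq_len(n_seeds), function(sd) {
    sc <- sim_config(origin_time = 20, n_groups = 1, seed_species_per_group = 1,
                     base_lambda = 0.3, base_mu = 0.1, rng_seed = sd)
    tr <- simulate_bd_forward(sc)
    sum(tr$species$te == 0)
  }, numeric(1))
  expected <- exp((0.3 - 0.1) * 20)
  se <- stats::sd(extant) / sqrt(n_seeds)
  expect_lt(abs(mean(extant) - expected), 3 * se)
})

test_that("a negative diversity effect depresses the target group's origination", {
  # G[1,2] = -3: group 1's scaled diversity suppresses group 2's origination.
  # Group 1 is given a self-extinction feedback so its relative diversity
  # rises and falls (without it the running-max scaling saturates near 1 and
  # carries no contrast). Poisson regression of group 2's per-cell
  # origination events on group 1's relative diversity (offset = group 2
  # lineage time) must recover a negative slope in nearly all seeds.
  n_seeds <- 50
  slope_sign <- vapply(seq_len(n_seeds), function(sd) {
    G <- matrix(0, 2, 2); G[1, 2] <- -3
    Gm <- matrix(0, 2, 2); Gm[1, 1] <- 3
    sc <- sim_config(origin_time = 18, n_groups = 2, seed_species_per_group = 6,
                     base_lambda = 0.35, base_mu = 0.05, G_matrix = G,
                     G_matrix_mu = Gm, rng_seed = sd)
    tr <- simulate_bd_forward(sc)
    sp <- tr$species
    grid <- tr$grid
    d1 <- tr$trajectories[, "g1"]
    d1rel <- ifelse(cummax(d1) > 0, d1 / pmax(cummax(d1), 1), 0)
    sel2 <- sp$group == "g2"
    ev_ages <- sp$ts[sel2 & sp$ts < max(sp$ts) - 1e-9]
    cell <- pmin(length(grid), pmax(1, round((grid[1] - ev_ages) / 0.1) + 1))
    ev <- tabulate(cell, length(grid))
    lt <- vapply(grid, function(t) {
      sum(pmax(0, pmin(sp$ts[sel2], t + 0.05) - pmax(sp$te[sel2], t - 0.05)))
    }, numeric(1))
    keep <- lt > 0
    if (sum(keep) < 10 || stats::sd(d1rel[keep]) == 0) return(NA)
    fit <- suppressWarnings(
      stats::glm(ev[keep] ~ d1rel[keep], family = stats::poisson(),
                 offset = log(lt[keep])))
    unname(stats::coef(fit)[2]) < 0
  }, logical(1))
  slope_sign <- slope_sign[!is.na(slope_sign)]
  expect_gt(length(slope_sign), 40)
  expect_gte(mean(slope_sign), 0.95)
})

test_that("runaway diversification aborts with a clear signal", {
  sc <- sim_config(origin_time = 200, n_groups = 1, seed_species_per_group = 1,
                   base_lambda = 0.5, base_mu = 0, rng_seed = 3)
  expect_error(simulate_bd_forward(sc), "runaway")
})

test_that("preservation counts follow the Poisson lifespan integral", {
  truth <- make_truth(ts = rep(10, 1000), te = rep(0, 1000), origin = 10)
  res <- sample_preservation(truth, q = 1, model = "HPP", seed = 5)
  counts <- table(factor(res$occurrences$species,
                         levels = truth$species$species))
  counts <- as.numeric(counts)
  # mean ~ q * lifespan = 10, within 3 SE; dispersion index near 1
  expect_lt(abs(mean(counts) - 10), 3 * stats::sd(counts) / sqrt(1000))
  truth5 <- make_truth(ts = rep(5, 1000), te = rep(0, 1000), origin = 5)
  res5 <- sample_preservation(truth5, q = 1, model = "HPP", seed = 6)
  c5 <- as.numeric(table(factor(res5$occurrences$species,
                                levels = truth5$species$species)))
  disp <- stats::var(c5) / mean(c5)
  expect_gt(disp, 0.8)
  expect_lt(disp, 1.2)
})

test_that("species without occurrences are dropped and accounted for", {
  truth <- make_truth(ts = runif(50, 5, 10), te = runif(50, 0, 2), origin = 10)
  res <- sample_preservation(truth, q = 1e-4, model = "HPP", seed = 2)
  retained <- length(unique(res$occurrences$species))
  expect_equal(retained + length(res$dropped), 50)
  expect_gt(length(res$dropped), 40)
})

test_that("a zero-rate TPP bin receives no occurrences", {
  truth <- make_truth(ts = rep(10, 200), te = rep(0, 200), origin = 10)
  res <- sample_preservation(truth, q = c(2, 0), model = "TPP",
                             bins = c(10, 5, 0), seed = 3)
  expect_true(all(res$occurrences$min_ma + res$occurrences$max_ma > 0))
  # every sampled point age lies in the older (active) bin
  mid <- (res$occurrences$min_ma + res$occurrences$max_ma) / 2
  expect_true(all(mid >= 5 - truth$config$age_interval_width / 2))
})

test_that("emitted age intervals respect the [0, origin] bounds", {
  truth <- make_truth(ts = runif(100, 3, 10), te = runif(100, 0, 2), origin = 10)
  res <- sample_preservation(truth, q = 2, model = "HPP", seed = 9)
  occ <- res$occurrences
  expect_true(all(occ$min_ma >= 0))
  expect_true(all(occ$max_ma <= 10))
  expect_true(all(occ$min_ma <= occ$max_ma))
})

test_that("covariate simulation scales to [0,1] and is seed-deterministic", {
  grid <- seq(20, 0, by = -0.1)
  a <- simulate_covariate(grid, seed = 1)
  b <- simulate_covariate(grid, seed = 1)
  c <- simulate_covariate(grid, seed = 2)
  expect_equal(min(a$value), 0)
  expect_equal(max(a$value), 1)
  expect_identical(a, b)
  expect_false(identical(a$value, c$value))
  # degenerate single-point grid has zero range -> defined as 0
  expect_equal(simulate_covariate(5, seed = 1)$value, 0)
  expect_error(simulate_covariate(numeric(0)), "empty")
})

test_that("growth-form assignment is consistent and invertible", {
  sc <- sim_config(origin_time = 15, n_groups = 3, seed_species_per_group = 3,
                   base_lambda = 0.25, base_mu = 0.05, rng_seed = 11)
  tr <- simulate_bd_forward(sc)
  mapping <- list(g1 = "massive", g2 = c("branching", "massive"),
                  g3 = c("laminar", "foliaceous", "encrusting"))
  traits <- assign_growth_forms(tr, mapping)
  expect_equal(nrow(traits), nrow(tr$species))
  expect_equal(ncol(traits), 7L)
  expect_true(all(unlist(traits[, -1]) %in% 0:1))
  # group mapped to {massive} gives the row (B=0,C=0,E=0,F=0,L=0,M=1)
  m_row <- traits[tr$species$group == "g1", -1][1, ]
  expect_equal(unlist(m_row), c(branching = 0, massive = 1, columnar = 0,
                                laminar = 0, foliaceous = 0, encrusting = 0))
  # round trip: rebuilding MF groups recovers the simulated partition
  grp <- build_mf_groups(traits)
  members <- attr(grp, "members")
  got <- lapply(members, sort)
  want <- lapply(split(tr$species$species, tr$species$group), sort)
  names(want) <- vapply(mapping[names(want)], canonical_label, character(1))
  expect_equal(got[order(names(got))], want[order(names(want))])
  expect_error(assign_growth_forms(tr, mapping[1:2]), "unmapped")
})

test_that("the full simulation is deterministic given its seed", {
  sc <- sim_config(origin_time = 20, n_groups = 2, seed_species_per_group = 2,
                   base_lambda = 0.3, base_mu = 0.1, rng_seed = 77)
  t1 <- simulate_bd_forward(sc)
  t2 <- simulate_bd_forward(sc)
  expect_identical(t1$species, t2$species)
  p1 <- sample_preservation(t1, q = 1, seed = 5)
  p2 <- sample_preservation(t2, q = 1, seed = 5)
  expect_identical(p1$occurrences, p2$occurrences)
})

test_that("diversity trajectories equal brute-force interval counts", {
  sc <- sim_config(origin_time = 20, n_groups = 2, seed_species_per_group = 2,
                   base_lambda = 0.3, base_mu = 0.15, rng_seed = 13)
  tr <- simulate_bd_forward(sc)
  sp <- tr$species
  for (g in c("g1", "g2")) {
    sel <- sp$group == g
    brute <- vapply(tr$grid, function(t) {
      n <- 0
      for (i in which(sel)) if (sp$ts[i] >= t && sp$te[i] < t) n <- n + 1
      n
    }, numeric(1))
    expect_equal(unname(tr$trajectories[, g]), brute)
  }
})
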