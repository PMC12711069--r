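# Shared fixture builders; everything is generated in code.

# Minimal pooled-draw object as produced by combine_replicates().
make_draws <- function(ts, te, species = sprintf("sp%03d", seq_along(ts))) {
  if (is.null(dim(ts))) ts <- matrix(ts, nrow = 1)
  if (is.null(dim(te))) te <- matrix(te, nrow = 1)
  structure(list(ts = ts, te = te, species = species), class = "fbd_draws")
}

# Hand-built truth object for preservation tests (bypasses the simulator).
make_truth <- function(ts, te, group = rep("g1", length(ts)), origin = max(ts)) {
  cfg <- sim_config(origin_time = origin, n_groups = length(unique(group)),
                    rng_seed = 1)
  structure(list(
    species = data.frame(species = sprintf("sp%05d", seq_along(ts)),
                         group = group, ts = ts, te = te,
                         stringsAsFactors = FALSE),
    grid = seq(origin, 0, by = -0.1),
    trajectories = NULL, extinct_all = all(te > 0), config = cfg),
    class = "sim_truth")
}

# Species counts of the 17-group summary fixture used in dominance tests.
table1_counts <- function() {
  c(123, 49, 15, 10, 10, 10, 8, 7, 5, 3, 3, 2, 1, 1, 1, 1, 1)
}

# Write a small occurrence CSV and return its path.
write_occ_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Trait row constructor: species plus named growth forms set to 1.
trait_row <- function(species, forms) {
  all_forms <- names(growth_forms())
  row <- as.list(as.integer(all_forms %in% forms))
  names(row) <- all_forms
  cbind(data.frame(species = species, stringsAsFactors = FALSE),
        as.data.frame(row))
}
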