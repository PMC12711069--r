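#' @keywords internal
"_PACKAGE"

# Ages are Ma before present throughout: larger = older. Rate histories are
# piecewise constant over age segments delimited by shift times (Ma).

# Derive a reproducible child seed from a base seed and an index; kept below
# 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973) %% 2147483647L)
}

# Rate lookup for a piecewise-constant history. `shifts` are ages strictly
# inside (0, origin); segment 1 is the oldest. Vectorised over `t`.
rate_at <- function(rates, shifts, t) {
  if (length(shifts) == 0L) {
    return(rep(rates[1L], length(t)))
  }
  sh <- sort(shifts, decreasing = TRUE)
  idx <- findInterval(-t, -sh) + 1L  # number of shifts >= t, plus one
  rates[idx]
}

# Total lineage time spent inside each age segment of a piecewise history.
# Returns a vector of length(rates): sum_i |(e_i, s_i) /\ segment_k|.
segment_lineage_time <- function(s, e, shifts, origin = max(s)) {
  edges_hi <- c(origin, sort(shifts, decreasing = TRUE))
  edges_lo <- c(sort(shifts, decreasing = TRUE), 0)
  vapply(seq_along(edges_hi), function(k) {
    sum(pmax(0, pmin(s, edges_hi[k]) - pmax(e, edges_lo[k])))
  }, numeric(1))
}

# Interval overlap |[lo1,hi1] /\ [lo2,hi2]|, vectorised.
interval_overlap <- function(lo1, hi1, lo2, hi2) {
  pmax(0, pmin(hi1, hi2) - pmax(lo1, lo2))
}

# Min-max scale to [0,1]; a zero-range input maps to all zeros (documented
# convention for degenerate series).
minmax_scale <- function(x) {
  r <- range(x)
  if (diff(r) <= 0) {
    return(rep(0, length(x)))
  }
  (x - r[1]) / diff(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
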