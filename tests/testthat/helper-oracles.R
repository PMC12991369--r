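# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::p.adjust, which the package calls),
# so that agreement is evidence, not tautology.

# Brute-force distribution of maximal insertion-free run lengths: list all
# C(b, h) placements of h insertion sites among b positions, collect every
# maximal run of insertion-free positions, and tabulate run-length
# frequencies over all (placement, run) pairs.
enum_run_pmf <- function(b, h) {
  placements <- utils::combn(b, h)
  runs <- integer(0)
  for (j in seq_len(ncol(placements))) {
    r <- diff(c(0L, placements[, j], b + 1L)) - 1L
    runs <- c(runs, r[r > 0L])
  }
  tabulate(runs, nbins = b - h) / length(runs)
}

# Hand-coded step-up/step-down adjustments (textbook definitions).
ref_adjust <- function(p, method) {
  m <- length(p)
  if (method == "bonferroni") return(pmin(1, m * p))
  if (method == "holm") {
    o <- order(p)
    adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
    return(adj[order(o)])
  }
  if (method == "bh") {
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(m / seq.int(m, 1) * p[o]))
    return(adj[order(o)])
  }
  p
}

# Position-by-position scan of one gene interval.
naive_gene_scan <- function(s, e, pos) {
  inside <- (s:e) %in% pos
  r <- rle(!inside)
  free_runs <- r$lengths[r$values]
  list(k = sum(inside), l = max(c(0L, free_runs)), runs = free_runs)
}

# Monte-Carlo tail of the longest failure run among n Bernoulli(p) trials.
mc_longest_run <- function(n, p, reps, seed = 1) {
  set.seed(seed)
  replicate(reps, {
    k <- rbinom(1, n, p)
    if (k == 0) n else max(diff(c(0L, sort(sample.int(n, k)), n + 1L))) - 1L
  })
}

# Small, quick synthetic library used by several end-to-end tests.
easy_library <- function(seed = 3) {
  simulate_library(sim_config(genome_length = 5e5, n_genes = 400,
                              n_essential = 40, n_is = 5e4, n_noise = 0,
                              free_fraction = 0.9, profile = "uniform",
                              seed = seed))
}
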