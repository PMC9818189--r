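# Shared fixtures and independent oracles for the test suite.

# Small simulated atlas, depth-normalised, used across modules.
small_atlas <- function(n_types = 5, n_genes = 800, n_cells = 40,
                        dispersion = 0.5, seed = 2, ...) {
  normalize_counts(simulate_atlas(atlas_spec(
    n_types = n_types, n_genes = n_genes, n_cells_per_type = n_cells,
    dispersion = dispersion, seed = seed, ...)))
}

# Brute-force two-group log-rank oracle: explicit risk-set tabulation
# over distinct event times, hypergeometric variance with ties.
# Independent of survival::survdiff, which the implementation uses.
logrank_oracle <- function(time, event, in_a) {
  event <- as.logical(event)
  o <- e <- v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_a)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & in_a)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o - e)^2 / v else 0
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Exhaustive cut-point search done from scratch with the oracle above.
split_oracle <- function(fractions, cohort, min_group = 1) {
  ord <- order(-fractions, as.character(cohort$sample_id))
  time <- cohort$time[ord]
  event <- as.logical(cohort$event[ord])
  n <- length(time)
  cuts <- seq.int(min_group, n - min_group)
  p <- vapply(cuts, function(k)
    logrank_oracle(time, event, seq_len(n) <= k)$p_value, numeric(1))
  list(cuts = cuts, p = p, best_cut = cuts[which.min(p)],
       min_p = min(p))
}

# Hand-built two-type atlas with fully exclusive marker genes.
exclusive_atlas <- function() {
  set.seed(11)
  n_bg <- 24
  genes <- c("mkA1", "mkA2", "mkA3", "mkB1", "mkB2", "mkB3",
             sprintf("bg%02d", seq_len(n_bg)))
  cells <- sprintf("c%02d", 1:20)
  labels <- rep(c("typeA", "typeB"), each = 10)
  expr <- matrix(rpois(length(genes) * 20, 5), length(genes), 20,
                 dimnames = list(genes, cells))
  expr[1:3, labels == "typeB"] <- 0
  expr[4:6, labels == "typeA"] <- 0
  expr[1:6, ] <- expr[1:6, ] * 10  # strong exclusive signal
  new_atlas(expr, setNames(labels, cells))
}
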