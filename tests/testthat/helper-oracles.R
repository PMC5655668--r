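# Independent oracles and shared fixtures, kept deliberately naive.

# quadratic brute-force concordance: enumerate every pair
ci_bruteforce <- function(pred, obs) {
  n <- length(obs)
  num <- 0
  den <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (obs[i] == obs[j]) next
      den <- den + 1
      d <- (pred[i] - pred[j]) * (obs[i] - obs[j])
      if (d > 0) num <- num + 1
      if (d == 0) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Benjamini-Hochberg step-up, written from the definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# a 9-dose triplicate plate (already normalized) in which exactly two doses
# violate the SD/CV > 0.2 replicate rule
qc_fixture_plate <- function() {
  doses <- 2^(0:8) / 16
  v <- rbind(
    c(1.00, 0.98, 0.95, 0.90, 0.10, 0.70, 0.55, 0.40, 0.30),
    c(1.02, 0.99, 0.96, 0.88, 0.60, 0.72, 0.57, 0.42, 0.31),
    c(0.98, 1.00, 0.94, 0.92, 0.95, 0.68, 0.05, 0.41, 0.29))
  # dose 5: SD ~ 0.43 > 0.2; dose 7: SD ~ 0.29 > 0.2; all others well below
  dose_response_experiment(doses, v, normalized = TRUE)
}

# tiny two-tissue expression dataset built by hand
toy_expression <- function(n = 40, n_genes = 6, seed = 1) {
  set.seed(seed)
  cells <- sprintf("c%02d", seq_len(n))
  genes <- sprintf("g%02d", seq_len(n_genes))
  iso <- matrix(pmax(rnorm(2 * n_genes * n, mean = 4), 0), 2 * n_genes, n)
  rownames(iso) <- paste0(rep(genes, each = 2), ".t", 1:2)
  colnames(iso) <- cells
  map <- data.frame(isoform_id = rownames(iso),
                    gene_id = rep(genes, each = 2))
  tissues <- setNames(rep(c("lung", "breast"), length.out = n), cells)
  expression_dataset(iso, map, tissues)
}
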