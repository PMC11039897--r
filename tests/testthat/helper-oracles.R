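# Independent brute-force oracles, deliberately naive, used to check the
# package implementations on small instances.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Greedy clumping by literal restatement: repeatedly pick the remaining
# variant with the smallest p (ties by id), then delete all remaining
# variants on the same chromosome within the window with r^2 >= threshold.
oracle_clump <- function(stats, ld, r2_threshold, window_kb) {
  df <- as.data.frame(stats)
  kept <- character(0)
  while (nrow(df) > 0) {
    df <- df[order(df$pval, df$snp_id), ]
    index <- df[1, ]
    kept <- c(kept, index$snp_id)
    df <- df[-1, , drop = FALSE]
    if (nrow(df) == 0) break
    remove <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (df$chrom[i] != index$chrom) next
      if (abs(df$pos[i] - index$pos) > window_kb * 1000) next
      r <- 0
      if (!is.null(ld) && index$snp_id %in% rownames(ld) &&
            df$snp_id[i] %in% rownames(ld)) {
        r <- ld[index$snp_id, df$snp_id[i]]
      }
      if (r^2 >= r2_threshold) remove[i] <- TRUE
    }
    df <- df[!remove, , drop = FALSE]
  }
  kept
}

# Benjamini-Hochberg by the step-up definition: adjusted p for the i-th
# order statistic is min over j >= i of min(1, m * p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  ps <- p[ord]
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m * ps[j] / j), numeric(1))
    adj_sorted[i] <- min(vals)
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# Core number of every vertex by repeated minimum-degree peeling on an
# adjacency matrix.
oracle_coreness <- function(adj) {
  n <- nrow(adj)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0
  while (any(alive)) {
    repeat {
      if (!any(alive)) break
      deg <- rowSums(adj[, alive, drop = FALSE])
      low <- alive & (deg <= k)
      if (!any(low)) break
      core[low] <- k
      alive[low] <- FALSE
    }
    k <- k + 1
  }
  core
}

# MCODE vertex weight by direct enumeration: build the closed-neighbourhood
# adjacency matrix, peel for core numbers, take the highest-core subgraph
# and compute k * density.
oracle_vertex_weight <- function(adj, v, degree_cutoff = 2) {
  deg <- rowSums(adj)
  if (deg[v] < degree_cutoff) return(0)
  nbhd <- c(v, which(adj[v, ] > 0))
  sub <- adj[nbhd, nbhd, drop = FALSE]
  core <- oracle_coreness(sub)
  k_max <- max(core)
  if (k_max == 0) return(0)
  keep <- core >= k_max
  ksub <- sub[keep, keep, drop = FALSE]
  nv <- nrow(ksub)
  dens <- if (nv < 2) 0 else sum(ksub) / (nv * (nv - 1))
  k_max * dens
}

random_adjacency <- function(n, p_edge) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

graph_from_adjacency_named <- function(adj) {
  labels <- sprintf("N%02d", seq_len(nrow(adj)))
  dimnames(adj) <- list(labels, labels)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Build a harmonised-pair table directly from effect vectors, as produced
# by a perfectly concordant harmonisation (all variants kept).
make_pairs <- function(beta_exposure, beta_outcome, se_exposure,
                       se_outcome) {
  n <- length(beta_exposure)
  tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(n)),
    effect_allele = "A", other_allele = "G",
    beta_exposure = beta_exposure,
    se_exposure = rep_len(se_exposure, n),
    eaf_exposure = 0.3, pval_exposure = 1e-8,
    beta_outcome = beta_outcome,
    se_outcome = rep_len(se_outcome, n),
    eaf_outcome = 0.3, pval_outcome = 0.5,
    disposition = "kept"
  )
}

# Simulate one exposure/outcome pair and return the harmonised usable
# pairs, skipping instrument selection (for estimator-level simulations).
sim_usable_pairs <- function(seed, n_snps = 30, theta = 0.3, ...) {
  sim <- simulate_mr_pair(n_snps = n_snps, theta = theta, seed = seed,
                          palindrome_prob = 0, ...)
  usable_pairs(harmonise(sim$exposure, sim$outcome))
}

random_gwas_table <- function(n, seed) {
  withr::with_seed(seed, {
    pairs_pool <- rbind(
      c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
      c("A", "T"), c("C", "G")
    )
    idx <- sample.int(nrow(pairs_pool), n, replace = TRUE)
    tibble::tibble(
      snp_id = sprintf("rs%05d", sample.int(99999, n)),
      chrom = as.character(sample.int(22, n, replace = TRUE)),
      pos = sample.int(5e7, n),
      effect_allele = pairs_pool[idx, 1],
      other_allele = pairs_pool[idx, 2],
      eaf = stats::runif(n, 0.01, 0.99),
      beta = stats::rnorm(n, 0, 0.2),
      se = stats::runif(n, 0.001, 0.1),
      pval = stats::runif(n),
      n = sample(1000:100000, n, replace = TRUE)
    )
  })
}
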