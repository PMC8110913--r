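# Independent brute-force oracles. These deliberately take different
# algorithmic routes from the package: centralities are recomputed from a
# Floyd-Warshall distance matrix with explicit shortest-path counting,
# enrichment p-values by direct combinatorial summation, and triplets by
# exhaustive triple enumeration.

# all-pairs shortest-path distances by Floyd-Warshall on an adjacency matrix
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# number of shortest paths between every pair, by dynamic programming over
# increasing distance from each source
sp_counts <- function(adj, d) {
  n <- nrow(adj)
  sig <- matrix(0, n, n)
  diag(sig) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (v in ord) {
      if (v == s || !is.finite(d[s, v])) next
      pred <- which(adj[, v] == 1 & d[s, ] == d[s, v] - 1)
      sig[s, v] <- sum(sig[s, pred])
    }
  }
  sig
}

# normalized betweenness and within-component closeness for an undirected
# simple graph given as a 0/1 adjacency matrix
brute_centralities <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  sig <- sp_counts(adj, d)
  btw <- numeric(n)
  if (n > 2) {
    for (v in seq_len(n)) {
      acc <- 0
      for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t])
          acc <- acc + sig[s, v] * sig[v, t] / sig[s, t]
      }
      btw[v] <- acc / ((n - 1) * (n - 2) / 2)
    }
  }
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) 0 else length(di) / sum(di)
  }, numeric(1))
  list(betweenness = btw, closeness = clo)
}

# Erdos-Renyi style random undirected simple graph with named nodes
random_graph <- function(n, p = 0.3) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  dimnames(adj) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  adj
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# upper-tail hypergeometric p by direct summation of the mass function
hyper_p_sum <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg by the literal step-up recipe
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive triple enumeration over every lncRNA x miRNA x mRNA combination
brute_triplets <- function(pairs, lnc_edges, mrna_edges, de_records,
                           refine_fc = 2, refine_p = 0.05) {
  ls <- unique(c(pairs$lncrna, lnc_edges$target))
  ms <- unique(c(lnc_edges$mirna, mrna_edges$mirna))
  gs <- unique(c(pairs$mrna, mrna_edges$target))
  ok <- function(id) {
    i <- match(id, de_records$gene)
    !is.na(i) && abs(de_records$signed_fc[i]) > refine_fc &&
      de_records$p_value[i] < refine_p
  }
  out <- character()
  for (l in ls) for (m in ms) for (g in gs) {
    has_pair <- any(pairs$lncrna == l & pairs$mrna == g)
    has_ml <- any(lnc_edges$mirna == m & lnc_edges$target == l)
    has_mg <- any(mrna_edges$mirna == m & mrna_edges$target == g)
    if (has_pair && has_ml && has_mg && ok(l) && ok(g))
      out <- c(out, paste(l, m, g))
  }
  sort(out)
}

# small random triplet-assembly instance with consistent DE records
random_triplet_instance <- function(n_l = 5, n_m = 5, n_g = 5) {
  ls <- sprintf("L%d", 1:n_l)
  ms <- sprintf("M%d", 1:n_m)
  gs <- sprintf("G%d", 1:n_g)
  de <- data.frame(
    gene = c(ls, gs),
    kind = rep(c("lncRNA", "mRNA"), c(n_l, n_g)),
    signed_fc = sample(c(-4, -2.5, -1.8, 1.8, 2.5, 4), n_l + n_g,
                       replace = TRUE),
    p_value = sample(c(0.001, 0.02, 0.2), n_l + n_g, replace = TRUE),
    stringsAsFactors = FALSE)
  de$direction <- ifelse(abs(de$signed_fc) > 1.5 & de$p_value < 0.05,
                         ifelse(de$signed_fc > 0, "up", "down"), "ns")
  grid <- expand.grid(lncrna = ls, mrna = gs, stringsAsFactors = FALSE)
  pairs <- grid[stats::runif(nrow(grid)) < 0.3, , drop = FALSE]
  pairs$r <- 0.995
  pairs$p_value <- 0.01
  pairs$n <- 6L
  le <- expand.grid(mirna = ms, target = ls, stringsAsFactors = FALSE)
  le <- le[stats::runif(nrow(le)) < 0.3, , drop = FALSE]
  le$kind <- "lncRNA"; le$score <- 180
  me <- expand.grid(mirna = ms, target = gs, stringsAsFactors = FALSE)
  me <- me[stats::runif(nrow(me)) < 0.3, , drop = FALSE]
  me$kind <- "mRNA"; me$score <- 90
  list(pairs = pairs, lnc_edges = le, mrna_edges = me, de = de)
}
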