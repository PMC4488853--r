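# Shared builders for in-code fixtures and independent oracles.

# n aligned sequences of length L mutated from one random root
make_seqs <- function(n, L = 60, n_mut = 2, seed = 1) {
  set.seed(seed)
  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  vapply(seq_len(n), function(i) {
    s <- root
    if (n_mut > 0) {
      pos <- sample(L, n_mut)
      for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    }
    paste(s, collapse = "")
  }, "")
}

# tiny MT sample_set over two subpops
make_mt_set <- function(n = 6, seed = 1) {
  set.seed(seed)
  seqs <- make_seqs(n, L = 40, n_mut = 2, seed = seed)
  names(seqs) <- sprintf("id%02d", seq_len(n))
  sample_set(
    data.frame(sample_id = names(seqs),
               subpop = rep(c("A", "B"), length.out = n),
               haplogroup = sample(c("U5b1", "H1", "J1c2", "HV1"), n,
                                   replace = TRUE),
               source = "test"),
    marker = "MT", sequences = seqs)
}

# brute-force nucleotide diversity: mean per-site difference over all
# individual pairs, pairwise deletion
brute_pi <- function(seqs) {
  n <- length(seqs)
  chars <- lapply(toupper(seqs), function(s) strsplit(s, "")[[1]])
  vals <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- chars[[i]]; b <- chars[[j]]
    ok <- a != "N" & a != "-" & b != "N" & b != "-"
    vals <- c(vals, sum(a[ok] != b[ok]) / sum(ok))
  }
  mean(vals)
}

# independent AMOVA oracle: literal sums-of-squares evaluation
brute_amova <- function(d2, pop) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ss_total <- 0
  for (i in seq_len(N - 1)) for (j in seq(i + 1, N))
    ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / N
  ss_within <- 0
  for (p in pops) {
    idx <- which(pop == p)
    acc <- 0
    if (length(idx) > 1)
      for (a in seq_along(idx)) for (b in seq_along(idx))
        if (a < b) acc <- acc + d2[idx[a], idx[b]]
    ss_within <- ss_within + acc / length(idx)
  }
  sigma_b <- ss_within / (N - P)
  n_prime <- (N - sum(table(pop)^2) / N) / (P - 1)
  sigma_a <- ((ss_total - ss_within) / (P - 1) - sigma_b) / n_prime
  list(sigma2_a = sigma_a, sigma2_b = sigma_b,
       phi_st = sigma_a / (sigma_a + sigma_b))
}

# random connected graph on letter-coded nodes
random_connected_graph <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n)]
  repeat {
    edges <- NULL
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      if (runif(1) < p) edges <- rbind(edges, c(nodes[i], nodes[j]))
    if (is.null(edges)) next
    g <- try(adjacency_graph(nodes, edges), silent = TRUE)
    if (!inherits(g, "try-error")) return(g)
  }
}

# all bipartitions of a graph kept/rejected by brute-force connectivity
brute_contiguous <- function(graph, min_side = 1) {
  nodes <- graph$nodes
  n <- length(nodes)
  ig <- graph$graph
  out <- list()
  for (code in 0:(2^(n - 1) - 2)) {
    in_a <- c(TRUE, bitwAnd(code, 2^(seq_len(n - 1) - 1)) > 0)
    if (sum(in_a) < min_side || n - sum(in_a) < min_side) next
    sub_a <- igraph::induced_subgraph(ig, nodes[in_a])
    sub_b <- igraph::induced_subgraph(ig, nodes[!in_a])
    if (igraph::is_connected(sub_a) && igraph::is_connected(sub_b))
      out[[length(out) + 1L]] <- paste(sort(nodes[in_a]), collapse = ",")
  }
  sort(unlist(out))
}

fixture_samples <- function() counts_to_samples(finland_mtdna_counts())
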