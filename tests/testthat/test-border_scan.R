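test_that("contiguous bipartition enumeration is exact on known graphs", {
  path3 <- adjacency_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  got <- contiguous_bipartitions(path3)
  keys <- sort(vapply(got, function(b) paste(b$side_a, collapse = ","), ""))
  expect_equal(keys, c("A", "A,B"))   # {B}|{A,C} correctly rejected

  tri <- adjacency_graph(c("A", "B", "C"),
                         rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  expect_length(contiguous_bipartitions(tri), 3L)

  # path of n nodes has exactly n - 1 contiguous splits (edge cuts)
  n <- 7
  nodes <- LETTERS[1:n]
  pathn <- adjacency_graph(nodes, cbind(nodes[-n], nodes[-1]))
  expect_length(contiguous_bipartitions(pathn), n - 1L)

  # min_side filters one-node sides
  expect_length(contiguous_bipartitions(pathn, min_side = 2), n - 3L)

  big <- igraph::make_ring(30)
  igraph::V(big)$name <- sprintf("N%02d", 1:30)
  bigg <- adjacency_graph(igraph::V(big)$name,
                          igraph::as_edgelist(big))
  expect_error(contiguous_bipartitions(bigg), "24")
})

test_that("enumeration equals brute-force connectivity filtering (<=10 nodes)", {
  graphs <- list(
    random_connected_graph(5, 0.5, seed = 1),
    random_connected_graph(7, 0.4, seed = 2),
    random_connected_graph(9, 0.3, seed = 3),
    random_connected_graph(10, 0.35, seed = 4))
  for (g in graphs) {
    got <- sort(vapply(contiguous_bipartitions(g),
                       function(b) paste(b$side_a, collapse = ","), ""))
    expect_equal(got, brute_contiguous(g))
  }
})

test_that("side-contrast GLM equals the closed-form 2x2 log odds ratio", {
  set.seed(77)
  for (r in 1:20) {
    k <- sample(4:8, 1)
    totals <- sample(30:80, k)
    succ <- rbinom(k, totals, runif(1, 0.1, 0.6))
    side <- rep(FALSE, k)
    side[sample(k, sample(1:(k - 1), 1))] <- TRUE
    sa <- sum(succ[side]);  fa <- sum(totals[side]) - sa
    sb <- sum(succ[!side]); fb <- sum(totals[!side]) - sb
    if (sa == 0 || sb == 0 || fa == 0 || fb == 0) next
    fit <- fit_side_glm(succ, totals, side)
    expect_true(fit$converged)
    expect_equal(fit$beta, log((sa / fa) / (sb / fb)), tolerance = 1e-6)
    expect_equal(fit$se, sqrt(1 / sa + 1 / fa + 1 / sb + 1 / fb),
                 tolerance = 1e-6)
  }
  # equal frequencies on both sides
  flat <- fit_side_glm(c(10, 10), c(40, 40), c(TRUE, FALSE))
  expect_equal(flat$beta, 0, tolerance = 1e-10)
  expect_equal(flat$p, 1, tolerance = 1e-10)
  # separation is flagged, not silently estimated
  sep <- fit_side_glm(c(0, 0, 5), c(20, 20, 20), c(TRUE, TRUE, FALSE))
  expect_false(sep$converged)
  expect_equal(sep$p, 1.0)
})

test_that("scan scores agree with the user-facing GLM route", {
  g <- finland_graph()
  counts <- subpop_cluster_counts(fixture_samples(), nodes = g$nodes)
  res <- scan_border(counts$hunt, counts$farm, counts$totals, g,
                     null_draws = 0)
  side <- g$nodes %in% res$best$side_a
  p_hunt <- fit_side_glm(counts$hunt, counts$totals, side)$p
  p_farm <- fit_side_glm(counts$farm, counts$totals, side)$p
  expect_equal(res$p_hunt, p_hunt, tolerance = 1e-6)
  expect_equal(res$p_farm, p_farm, tolerance = 1e-6)
  expect_equal(res$product, p_hunt * p_farm, tolerance = 1e-6)
  # best really is the argmin of the audited score list
  expect_equal(res$product, min(res$all_scores$S))
})

test_that("a strongly planted border is recovered exactly", {
  g <- finland_graph()
  base <- c(U = 0.243, V = 0.036, H = 0.332, J = 0.055, T = 0.061,
            K = 0.055)
  cfg <- sim_config(marker = "MT", freqs = base, delta = 1.5,
                    n_per_subpop = setNames(rep(60L, 13), g$nodes),
                    haplotypes = FALSE)
  planted <- paste(cfg$border$side_a, collapse = ",")
  for (s in 1:5) {
    sim <- simulate_dataset(cfg, seed = 200 + s)
    counts <- subpop_cluster_counts(sim$samples, nodes = g$nodes)
    res <- scan_border(counts$hunt, counts$farm, counts$totals, g,
                       null_draws = 0)
    expect_equal(paste(res$best$side_a, collapse = ","), planted)
  }
})

test_that("single-edge graphs and ties behave deterministically", {
  g2 <- adjacency_graph(c("A", "B"), rbind(c("A", "B")))
  res <- scan_border(c(A = 5, B = 9), c(A = 9, B = 5),
                     c(A = 30, B = 30), g2, null_draws = 0)
  expect_equal(res$best$side_a, "A")
  # all-flat counts: every score is 1; tie broken to most balanced split
  g <- finland_graph()
  flat_h <- setNames(rep(0, 13), g$nodes)
  flat_t <- setNames(rep(50, 13), g$nodes)
  r1 <- scan_border(flat_h, flat_h, flat_t, g, null_draws = 0)
  r2 <- scan_border(flat_h, flat_h, flat_t, g, null_draws = 0)
  expect_identical(r1$best$side_a, r2$best$side_a)
  expect_gte(min(length(r1$best$side_a), length(r1$best$side_b)), 6)
})

test_that("null draws are non-contiguous, reproducible and scored alike", {
  g <- finland_graph()
  counts <- subpop_cluster_counts(fixture_samples(), nodes = g$nodes)
  n1 <- random_bipartition_null(counts$hunt, counts$farm, counts$totals, g,
                                k = 10, seed = 3)
  n2 <- random_bipartition_null(counts$hunt, counts$farm, counts$totals, g,
                                k = 10, seed = 3)
  expect_identical(n1, n2)
  expect_equal(nrow(n1), 10L)
  for (i in seq_len(nrow(n1))) {
    side_a <- strsplit(n1$side_a[i], ",")[[1]]
    bp <- bipartition(side_a, setdiff(g$nodes, side_a), g)
    expect_false(bp$contiguous)
  }
  # complete graph: every bipartition is contiguous, no null draw exists
  nodes <- LETTERS[1:4]
  cg <- adjacency_graph(nodes, t(combn(nodes, 2)))
  expect_error(random_bipartition_null(setNames(rep(1, 4), nodes),
                                       setNames(rep(1, 4), nodes),
                                       setNames(rep(10, 4), nodes),
                                       cg, k = 2, seed = 1),
               "contiguous")
})

test_that("without a border, a fixed split's score is exchangeable with the null", {
  # under no planted structure the product statistic of any one fixed
  # bipartition is drawn from the same distribution as the random
  # non-contiguous products, so its rank among k = 10 of them is uniform
  # over 0..10 (the argmin over all candidates is NOT, being a minimum)
  g <- finland_graph()
  cfg0 <- sim_config(marker = "MT",
                     freqs = c(U = 0.243, V = 0.036, H = 0.332, J = 0.055,
                               T = 0.061, K = 0.055),
                     delta = 0, haplotypes = FALSE)
  part <- finland_partition()
  side <- g$nodes %in% names(part)[part == "SW"]
  ranks <- vapply(1:300, function(r) {
    sim <- simulate_dataset(cfg0, seed = 80000 + r)
    counts <- subpop_cluster_counts(sim$samples, nodes = g$nodes)
    s_fixed <- fit_side_glm(counts$hunt, counts$totals, side)$p *
      fit_side_glm(counts$farm, counts$totals, side)$p
    nulls <- random_bipartition_null(counts$hunt, counts$farm,
                                     counts$totals, g, k = 10,
                                     seed = 90000 + r)
    sum(nulls$S < s_fixed)
  }, 0L)
  chi <- suppressWarnings(
    chisq.test(tabulate(ranks + 1L, nbins = 11L), p = rep(1 / 11, 11)))
  expect_gt(chi$p.value, 0.001)
})

test_that("per-haplogroup bias matches the pooled 2x2 oracle on the fixture", {
  x <- fixture_samples()
  bias <- suppressWarnings(haplogroup_bias(x, finland_partition()))
  u <- bias[bias$haplogroup == "U", ]
  # U: 70/389 in SW vs 132/443 in NE
  expect_equal(u$beta, log((70 / 319) / (132 / 311)), tolerance = 1e-6)
  expect_equal(u$se, sqrt(1 / 70 + 1 / 319 + 1 / 132 + 1 / 311),
               tolerance = 1e-6)
  expect_true(all(c("U", "V", "H", "J", "T", "K") %in% bias$haplogroup))
  # J is strongly southwest-biased in the fixture (33/389 vs 13/443)
  j <- bias[bias$haplogroup == "J", ]
  expect_gt(j$beta, 0)
  expect_lt(j$p, 0.01)
  # near-equal frequencies give beta ~ 0
  hrow <- bias[bias$haplogroup == "H", ]
  expect_lt(abs(hrow$beta), 0.15)
  # haplogroups under min_count are skipped with a warning
  expect_warning(haplogroup_bias(x, finland_partition(), min_count = 10),
                 "skipped")
})
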