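test_that("datasets are byte-identical under a fixed seed", {
  cfg <- sim_config(marker = "MT")
  a <- simulate_dataset(cfg, seed = 11)
  b <- simulate_dataset(cfg, seed = 11)
  expect_identical(a$samples$samples, b$samples$samples)
  expect_identical(a$samples$sequences, b$samples$sequences)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_samples(a$samples, f1)
  write_samples(b$samples, f2)
  expect_identical(readLines(f1), readLines(f2))
  c_ <- simulate_dataset(cfg, seed = 12)
  expect_false(identical(a$samples$sequences, c_$samples$sequences))
})

test_that("planted frequencies are recovered within binomial noise", {
  # calibrated contrast: HUNT 0.211 vs 0.339 with region totals 389/443
  cfg <- sim_config(marker = "MT", haplotypes = FALSE)
  sim <- simulate_dataset(cfg, seed = 21)
  r <- sim$truth$realised
  p_a <- sum(cfg$freqs_a[c("U", "V")]); n_a <- r$n[r$side == "A"]
  p_b <- sum(cfg$freqs_b[c("U", "V")]); n_b <- r$n[r$side == "B"]
  expect_equal(n_a, 389); expect_equal(n_b, 443)
  expect_lt(abs(r$hunt[r$side == "A"] - p_a),
            3 * sqrt(p_a * (1 - p_a) / n_a))
  expect_lt(abs(r$hunt[r$side == "B"] - p_b),
            3 * sqrt(p_b * (1 - p_b) / n_b))
  # null configuration: no side contrast beyond noise
  cfg0 <- sim_config(marker = "MT",
                     freqs = c(U = 0.243, V = 0.036, H = 0.332, J = 0.055,
                               T = 0.061, K = 0.055),
                     delta = 0, haplotypes = FALSE)
  sim0 <- simulate_dataset(cfg0, seed = 22)
  r0 <- sim0$truth$realised
  p0 <- 0.243 + 0.036
  se_diff <- sqrt(p0 * (1 - p0) * (1 / 389 + 1 / 443))
  expect_lt(abs(diff(r0$hunt)), 3 * se_diff)
})

test_that("label counts are multinomial-consistent with the configuration", {
  cfg <- sim_config(marker = "MT", haplotypes = FALSE)
  sim <- simulate_dataset(cfg, seed = 31)
  sw <- sim$samples$samples$subpop %in% cfg$border$side_a
  obs <- table(factor(match_scheme_token(sim$samples$samples$haplogroup),
                      levels = c(names(cfg$freqs_a), "OTHER")))
  obs["OTHER"] <- 832 - sum(obs[names(cfg$freqs_a)])
  expected <- 389 * c(cfg$freqs_a, OTHER = 1 - sum(cfg$freqs_a)) +
    443 * c(cfg$freqs_b, OTHER = 1 - sum(cfg$freqs_b))
  chi <- suppressWarnings(chisq.test(as.numeric(obs),
                                     p = expected / sum(expected)))
  expect_gt(chi$p.value, 0.001)
})

test_that("sequence classes follow infinite-sites accounting", {
  root <- strrep("A", 50)
  expect_equal(simulate_sequence_class(root, 0)$seq, root)
  set.seed(41)
  c1 <- simulate_sequence_class(root, 2)
  c2 <- simulate_sequence_class(root, 3, used = c1$positions)
  expect_length(intersect(c1$positions, c2$positions), 0)
  d <- distance_matrix(c(c1$seq, c2$seq), "seqdiff")
  expect_equal(d[1, 2], 5)
  expect_error(simulate_sequence_class(root, 51), "exhausted")
  expect_error(simulate_sequence_class(root, 11, used = 1:40), "exhausted")
})

test_that("stepwise STR mutation matches its moment oracle", {
  anc <- setNames(rep(14L, 16), sprintf("L%02d", 1:16))
  expect_identical(simulate_str_profile(anc, depth = 200, mu_str = 0), anc)
  set.seed(51)
  depth <- 200; mu <- 0.002
  m <- 10000
  sq <- replicate(m, {
    a <- simulate_str_profile(anc, depth, mu)
    b <- simulate_str_profile(anc, depth, mu)
    mean((a - b)^2)
  })
  # E[(a-b)^2] per locus = 2 * depth * mu under +/-1 steps
  expect_lt(abs(mean(sq) - 2 * depth * mu) / (2 * depth * mu), 0.05)
  # identical stream gives identical profiles
  set.seed(52); p1 <- simulate_str_profile(anc, depth, mu)
  set.seed(52); p2 <- simulate_str_profile(anc, depth, mu)
  expect_identical(p1, p2)
})

test_that("the innovation process yields the harmonic-mean class count", {
  theta <- 30; n <- 200
  expected_K <- sum(theta / (theta + seq_len(n) - 1))
  cfg <- sim_config(marker = "MT",
                    freqs = c(U = 1), delta = 0, border = "none",
                    n_per_subpop = setNames(rep(n / 5, 5),
                                            c("AL", "TU", "HA", "VA", "UU")),
                    graph = adjacency_graph(
                      c("AL", "TU", "HA", "VA", "UU"),
                      cbind(c("AL", "TU", "HA", "VA"),
                            c("TU", "HA", "VA", "UU"))),
                    theta = theta)
  set.seed(61)
  ks <- replicate(60, {
    sim <- simulate_dataset(cfg, seed = sample.int(1e6, 1))
    length(haplotype_spectrum(sim$samples$sequences))
  })
  expect_lt(abs(mean(ks) - expected_K) / expected_K, 0.1)
  # haplotype diversity lands in the study's observed range
  sim <- simulate_dataset(cfg, seed = 62)
  H <- haplotype_diversity(haplotype_spectrum(sim$samples$sequences))$H
  expect_gt(H, 0.93)
  expect_lt(H, 1)
})

test_that("simulate-then-summarize closes the loop on configured frequencies", {
  cfg <- sim_config(marker = "MT", haplotypes = FALSE)
  sim <- simulate_dataset(cfg, seed = 71)
  part <- setNames(
    ifelse(names(finland_partition()) %in% cfg$border$side_a, "SW", "NE"),
    names(finland_partition()))
  cc <- cluster_counts(sim$samples, partition = part)
  for (reg in c("SW", "NE")) {
    f_cfg <- if (reg == "SW") cfg$freqs_a else cfg$freqs_b
    tot <- cc$total[cc$region == reg][1]
    for (cl in c("HUNT", "FARM")) {
      members <- if (cl == "HUNT") c("U", "V") else c("H", "J", "T", "K")
      p <- sum(f_cfg[members])
      obs <- cc$count[cc$region == reg & cc$cluster == cl] / tot
      expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / tot))
    }
  }
})
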