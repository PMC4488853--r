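#' Squared molecular distance matrix between haplotypes
#'
#' Three distance models feed the AMOVA:
#' * `identity` — 0/1 mismatch; the variance decomposition then reduces to
#'   the conventional haplotype-frequency F_ST;
#' * `seqdiff` — number of differing aligned sites (pairwise deletion of
#'   `N`/gaps); gives Phi_ST for sequence data;
#' * `strsq` — sum over loci of squared repeat-count differences (R_ST
#'   style); gives Phi_ST for Y-STR profiles.
#'
#' @param haplotypes character vector of aligned sequences, or an integer
#'   matrix of STR profiles (rows = samples); for `identity` any vector of
#'   comparable haplotype keys works.
#' @param model `"identity"`, `"seqdiff"` or `"strsq"`.
#' @return Symmetric matrix of squared distances with zero diagonal.
#' @export
distance_matrix <- function(haplotypes,
                            model = c("identity", "seqdiff", "strsq")) {
  model <- match.arg(model)
  if (model == "strsq") {
    if (!is.matrix(haplotypes)) stop("strsq model requires an STR matrix")
    n <- nrow(haplotypes)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d[i, j] <- sum((haplotypes[i, ] - haplotypes[j, ])^2)
    }
  } else {
    if (is.matrix(haplotypes))
      haplotypes <- apply(haplotypes, 1L, paste, collapse = "|")
    haplotypes <- toupper(as.character(haplotypes))
    n <- length(haplotypes)
    if (model == "identity") {
      d <- outer(haplotypes, haplotypes, FUN = function(a, b)
        as.numeric(a != b))
    } else {
      lens <- nchar(haplotypes)
      if (any(lens != lens[1])) stop("sequence length mismatch")
      chars <- lapply(haplotypes, function(s) strsplit(s, "")[[1]])
      d <- matrix(0, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i < j) d[i, j] <- .pairwise_diff(chars[[i]], chars[[j]])[["diff"]]
      }
      d <- d + t(d)
    }
  }
  diag(d) <- 0
  unname(d)
}

# Phi_ST from a squared-distance matrix and population labels; core of the
# permutation loop, so kept allocation-light. Returns c(sigma_a, sigma_b).
.amova_components <- function(d2, pop) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  n_p <- numeric(P)
  for (k in seq_len(P)) {
    idx <- which(pop == pops[k])
    n_p[k] <- length(idx)
    if (n_p[k] > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / n_p[k]
    }
  }
  ss_among <- ss_total - ss_within
  sigma_b <- ss_within / (N - P)
  n_prime <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_a <- (ss_among / (P - 1) - sigma_b) / n_prime
  c(sigma_a, sigma_b)
}

#' Two-level AMOVA variance components
#'
#' Excoffier–Smouse–Quattro decomposition of squared molecular distances
#' into among- and within-population components:
#' \deqn{SS_{tot} = \frac{1}{N}\sum_{i<j} d^2_{ij},\quad
#'       SS_{within} = \sum_p \frac{1}{n_p}\sum_{i<j\in p} d^2_{ij}}
#' \deqn{\sigma^2_b = SS_{within}/(N-P),\quad
#'       \sigma^2_a = \frac{SS_{among}/(P-1) - \sigma^2_b}{n'},\quad
#'       n' = \frac{N - \sum_p n_p^2/N}{P-1}}
#' and \eqn{\Phi_{ST} = \sigma^2_a/(\sigma^2_a+\sigma^2_b)}. Negative
#' components are reported as-is (the estimator is unbiased, not
#' constrained), so Phi_ST may be slightly negative.
#'
#' @param d2 symmetric squared-distance matrix (zero diagonal).
#' @param pop population label per row of `d2`; at least two populations,
#'   each non-empty, total N at least 3.
#' @return list with `sigma2_a`, `sigma2_b`, `phi_st`, `n`, `populations`.
#' @export
amova_two_level <- function(d2, pop) {
  d2 <- as.matrix(d2)
  pop <- as.character(pop)
  N <- length(pop)
  if (nrow(d2) != N) stop("distance matrix and labels disagree in size")
  if (N < 3) stop("AMOVA requires at least 3 individuals")
  if (length(unique(pop)) < 2) stop("AMOVA requires at least 2 populations")
  if (any(table(pop) < 1)) stop("empty population")
  comp <- .amova_components(d2, pop)
  list(sigma2_a = comp[1], sigma2_b = comp[2],
       phi_st = comp[1] / (comp[1] + comp[2]),
       n = N, populations = sort(unique(pop)))
}

#' Permutation p-value for Phi_ST
#'
#' Individuals are shuffled among populations (sizes preserved); the p-value
#' is `(1 + #{permuted Phi >= observed}) / (n_perm + 1)`, never exactly zero.
#'
#' @param d2 squared-distance matrix.
#' @param pop population labels.
#' @param n_perm number of randomization steps (the analysis convention is
#'   10000).
#' @param seed integer seed; fixed seed gives identical p.
#' @return list with `p_value`, `phi_st` (observed), `n_permutations`,
#'   `seed`.
#' @export
permutation_p <- function(d2, pop, n_perm = 10000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  d2 <- as.matrix(d2)
  pop <- as.character(pop)
  obs <- .amova_components(d2, pop)
  phi_obs <- obs[1] / (obs[1] + obs[2])
  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    comp <- .amova_components(d2, sample(pop))
    phi <- comp[1] / (comp[1] + comp[2])
    if (!is.na(phi) && phi >= phi_obs) hits <- hits + 1L
  }
  list(p_value = (1 + hits) / (n_perm + 1), phi_st = phi_obs,
       n_permutations = n_perm, seed = as.integer(seed))
}

#' Pairwise differentiation between two regions
#'
#' Convenience wrapper computing conventional F_ST (identity distances) and
#' molecular Phi_ST (`seqdiff` for mtDNA, `strsq` for Y-STRs) between the
#' two regions of a partition, each with a permutation p-value.
#'
#' @param x a [sample_set()] carrying haplotypes.
#' @param partition named region map over subpopulation codes (two regions).
#' @param n_perm randomization steps per test.
#' @param seed integer seed.
#' @return data.frame with one row per statistic (`F_ST`, `Phi_ST`).
#' @export
pairwise_differentiation <- function(x, partition, n_perm = 10000,
                                     seed = 1L) {
  stopifnot(inherits(x, "sample_set"))
  region <- unname(partition[x$samples$subpop])
  if (any(is.na(region))) stop("partition does not cover all subpopulations")
  haps <- if (x$marker == "MT") x$sequences[x$samples$sample_id]
          else x$profiles[x$samples$sample_id, , drop = FALSE]
  if (is.null(haps)) stop("sample set carries no haplotypes")
  mol_model <- if (x$marker == "MT") "seqdiff" else "strsq"
  out <- lapply(c(F_ST = "identity", Phi_ST = mol_model), function(model) {
    d2 <- distance_matrix(haps, model)
    perm <- permutation_p(d2, region, n_perm = n_perm, seed = seed)
    data.frame(statistic = NA_character_, value = perm$phi_st,
               p_value = perm$p_value, n_permutations = n_perm)
  })
  res <- do.call(rbind, out)
  res$statistic <- names(out)
  rownames(res) <- NULL
  res[c("statistic", "value", "p_value", "n_permutations")]
}
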