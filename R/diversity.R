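#' Haplogroup frequency
#'
#' @param n_group samples in the haplogroup.
#' @param n_total denominator sample count (> 0).
#' @return `n_group / n_total`.
#' @export
haplogroup_frequency <- function(n_group, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_group < 0) || any(n_group > n_total))
    stop("need 0 <= n_group <= n_total")
  n_group / n_total
}

#' Haplotype spectrum of a group
#'
#' Collapses haplotypes into identity classes: exact string equality after
#' uppercasing for sequences, exact repeat-vector equality for STR profiles.
#'
#' @param haplotypes character vector of sequences, or an integer matrix of
#'   STR profiles (one row per sample).
#' @return Integer vector of class counts (sums to the sample size); the
#'   number of distinct haplotypes `A` is its length.
#' @export
haplotype_spectrum <- function(haplotypes) {
  if (is.matrix(haplotypes)) {
    key <- apply(haplotypes, 1L, paste, collapse = "|")
  } else {
    if (!length(haplotypes)) stop("empty group")
    key <- toupper(as.character(haplotypes))
  }
  if (!length(key)) stop("empty group")
  as.integer(table(key))
}

#' Nei's unbiased haplotype diversity
#'
#' \deqn{\hat H = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' with the analytic sampling variance
#' \deqn{V(\hat H) = \frac{2}{n(n-1)}\left[2(n-2)\left(\sum p_i^3 -
#'   (\sum p_i^2)^2\right) + \sum p_i^2 - (\sum p_i^2)^2\right]}
#' (Nei 1987, eqs. 8.4 and 8.12). The `n/(n-1)` correction makes a fully
#' distinct sample attain exactly 1.
#'
#' @param counts haplotype class counts; `sum(counts)` must be at least 2
#'   (the estimator is undefined for a single observation).
#' @return list with `H` and `H_sd`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity requires n >= 2")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  H <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(H = H, H_sd = sqrt(max(V, 0)))
}

# Pairwise differences between two aligned strings with pairwise deletion:
# positions where either base is N or '-' are excluded. Returns the number
# of differing sites and the number of comparable sites.
.pairwise_diff <- function(a, b) {
  ok <- a != "N" & a != "-" & b != "N" & b != "-"
  c(diff = sum(a[ok] != b[ok]), sites = sum(ok))
}

#' Nucleotide diversity (per site) with Tajima's variance
#'
#' Mean pairwise per-site difference across all sequence pairs, unbiased by
#' the `n/(n-1)` factor, with pairwise deletion of `N`/gap positions:
#' \deqn{\pi = \frac{n}{n-1} \sum_{i<j} 2 p_i p_j d_{ij} / \tilde L}
#' over haplotype classes, where \eqn{\tilde L} is the mean number of
#' comparable sites. The standard deviation uses Tajima's (1983) total
#' variance \eqn{V = \frac{n+1}{3(n-1)\tilde L}\pi +
#' \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}.
#'
#' @param seqs character vector of aligned sequences (all one length).
#' @return list with `pi`, `pi_sd`, `L_eff` (mean comparable sites).
#' @export
nucleotide_diversity <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  if (n < 2) stop("nucleotide diversity requires n >= 2")
  lens <- nchar(seqs)
  if (any(lens != lens[1]))
    stop("sequence length mismatch within group")
  spectrum <- table(seqs)
  classes <- names(spectrum)
  counts <- as.numeric(spectrum)
  k <- length(classes)
  mats <- lapply(classes, function(s) strsplit(s, "")[[1]])
  p <- counts / n
  num <- 0
  wsum <- 0
  sites_sum <- 0
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      d <- .pairwise_diff(mats[[i]], mats[[j]])
      if (d["sites"] == 0) stop("no comparable sites between haplotypes")
      w <- 2 * p[i] * p[j]
      num <- num + w * d["diff"] / d["sites"]
      wsum <- wsum + w
      sites_sum <- sites_sum + w * d["sites"]
    }
  }
  pi <- n / (n - 1) * num
  L_eff <- if (wsum > 0) sites_sum / wsum else lens[1]
  V <- (n + 1) / (3 * (n - 1) * L_eff) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = unname(pi), pi_sd = sqrt(max(unname(V), 0)), L_eff = unname(L_eff))
}

# Diversity cell for one group of samples (indices into x).
.diversity_cell <- function(x, idx, denom) {
  n <- length(idx)
  out <- list(N = n, f = if (denom > 0) n / denom else NA_real_,
              A = NA_integer_, H = NA_real_, H_sd = NA_real_,
              pi = NA_real_, pi_sd = NA_real_)
  if (n == 0) return(out)
  haps <- if (x$marker == "MT") x$sequences[x$samples$sample_id[idx]]
          else x$profiles[x$samples$sample_id[idx], , drop = FALSE]
  if (is.null(haps)) return(out)
  spec <- haplotype_spectrum(haps)
  out$A <- length(spec)
  if (n >= 2) {
    hd <- haplotype_diversity(spec)
    out$H <- hd$H
    out$H_sd <- hd$H_sd
    if (x$marker == "MT") {
      nd <- nucleotide_diversity(haps)
      out$pi <- nd$pi
      out$pi_sd <- nd$pi_sd
    }
  }
  out
}

#' Diversity summary table per haplogroup and region
#'
#' Builds the classic haplogroup-frequency-and-diversity table: one row per
#' haplogroup and region (`ALL` plus each region of the partition), with
#' sample count `N`, frequency `f` (denominator: the region's total sample
#' count), number of distinct haplotypes `A`, Nei's unbiased haplotype
#' diversity `H` with analytic SD, and per-site nucleotide diversity `pi`
#' with Tajima's SD (mtDNA only). Cluster rows (`HUNT`, `FARM`) aggregate
#' their member haplogroups, and an `ALL` row totals everything.
#'
#' @param x a [sample_set()].
#' @param scheme a [cluster_scheme()] used for the cluster rows and for
#'   grouping; haplogroup rows use the scheme token matched by each label
#'   (so U5b1 and U2 both aggregate under `U`), unmatched labels group
#'   verbatim.
#' @param partition named region map over subpopulation codes; `NULL` for a
#'   single `ALL` column.
#' @return data.frame with columns `group`, `region`, `N`, `f`, `A`, `H`,
#'   `H_sd`, `pi`, `pi_sd`.
#' @export
summarize_diversity <- function(x, scheme = cluster_scheme(),
                                partition = NULL) {
  stopifnot(inherits(x, "sample_set"))
  labels <- x$samples$haplogroup
  matched <- match_scheme_token(labels, scheme)
  cl <- assign_cluster(labels, scheme)

  regions <- "ALL"
  region_of <- rep("ALL", nrow(x$samples))
  if (!is.null(partition)) {
    unmapped <- setdiff(unique(x$samples$subpop), names(partition))
    if (length(unmapped))
      stop("subpopulation(s) not mapped by partition: ",
           paste(unmapped, collapse = ", "))
    region_of <- unname(partition[x$samples$subpop])
    regions <- c("ALL", unique(unname(partition)))
  }

  groups <- c(sort(unique(matched)),
              intersect(c("HUNT", "FARM"), unique(cl)), "ALL")
  rows <- list()
  for (reg in regions) {
    in_reg <- if (reg == "ALL") rep(TRUE, length(matched)) else region_of == reg
    denom <- sum(in_reg)
    if (denom == 0) {
      warning("region ", reg, " has no samples; row omitted")
      next
    }
    for (g in groups) {
      idx <- which(in_reg & switch(g,
        ALL = rep(TRUE, length(matched)),
        HUNT = cl == "HUNT",
        FARM = cl == "FARM",
        matched == g))
      if (!length(idx) && !g %in% c("HUNT", "FARM", "ALL")) next
      cell <- .diversity_cell(x, idx, denom)
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, region = reg, N = cell$N, f = cell$f,
                   A = cell$A, H = cell$H, H_sd = cell$H_sd,
                   pi = cell$pi, pi_sd = cell$pi_sd)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
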