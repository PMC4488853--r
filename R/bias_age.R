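#' Read a haplogroup age-contrast table
#'
#' Age contrasts are user-supplied external estimates (e.g. published
#' founder-age differences between European and Near Eastern populations):
#' one row per haplogroup with `delta_age` = age(Europe) - age(Near East)
#' in years. The packaged `example_haplogroup_ages.tsv` is an illustrative
#' example, not a reference dataset.
#'
#' @param path TSV with columns `haplogroup`, `delta_age`; lines starting
#'   with `#` are comments.
#' @return data.frame with unique, uppercased haplogroup labels.
#' @export
read_ages <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("haplogroup", "delta_age") %in% names(tab)))
    stop("age table needs columns 'haplogroup' and 'delta_age'")
  tab$haplogroup <- toupper(trimws(tab$haplogroup))
  if (anyDuplicated(tab$haplogroup)) stop("duplicate haplogroup labels")
  tab$delta_age <- as.numeric(tab$delta_age)
  tab
}

#' Correlate regional haplogroup bias with haplogroup age contrasts
#'
#' Joins per-haplogroup bias estimates (log-odds of occurrence on side A,
#' from [haplogroup_bias()]) with age contrasts by normalised label and
#' reports the squared Pearson correlation of the least-squares fit of bias
#' on `delta_age`, the Spearman rank correlation (average ranks on ties)
#' and a two-sided permutation p-value for the latter (`n_perm` shuffles of
#' the pairing, +1 correction).
#'
#' @param bias data.frame with columns `haplogroup` and `beta` (or a named
#'   numeric vector of bias values).
#' @param ages data.frame with columns `haplogroup`, `delta_age` (see
#'   [read_ages()]).
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @return list with `n`, `r2`, `rho`, `p_rho`, `pairs` (the joined table),
#'   `n_permutations`, `seed`.
#' @export
correlate_bias_age <- function(bias, ages, n_perm = 10000, seed = 1L) {
  if (is.numeric(bias) && !is.null(names(bias)))
    bias <- data.frame(haplogroup = names(bias), beta = unname(bias))
  stopifnot(all(c("haplogroup", "beta") %in% names(bias)))
  key_b <- toupper(trimws(bias$haplogroup))
  key_a <- toupper(trimws(ages$haplogroup))
  common <- intersect(key_b, key_a)
  if (length(common) < 3)
    stop("need at least 3 haplogroups common to both tables; got ",
         length(common))
  b <- bias$beta[match(common, key_b)]
  d <- ages$delta_age[match(common, key_a)]
  keep <- is.finite(b) & is.finite(d)
  b <- b[keep]; d <- d[keep]; common <- common[keep]
  if (length(common) < 3) stop("fewer than 3 finite bias/age pairs")
  r2 <- stats::cor(b, d)^2
  rho <- stats::cor(b, d, method = "spearman")
  set.seed(as.integer(seed))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    r <- stats::cor(b, sample(d), method = "spearman")
    if (abs(r) >= abs(rho) - 1e-12) hits <- hits + 1L
  }
  list(n = length(common), r2 = r2, rho = rho,
       p_rho = (1 + hits) / (n_perm + 1),
       pairs = data.frame(haplogroup = common, bias = b, delta_age = d),
       n_permutations = n_perm, seed = as.integer(seed))
}
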