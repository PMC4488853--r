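#' Packaged Finnish mtDNA haplogroup count fixture
#'
#' Per-subpopulation haplogroup counts whose regional margins equal the
#' published Finnish control-region summary: 832 samples, 389 southwest /
#' 443 northeast, with U = 202, V = 30, H = 276, J = 46, T = 51, K = 46 and
#' the remainder over haplogroups D, HV, I, N, R, W, X, Z. Within each
#' region the haplogroup counts are split as evenly as possible across the
#' region's subpopulations (the per-subpopulation resolution of the source
#' data is not published).
#'
#' @return data.frame with columns `subpop`, `haplogroup`, `count`.
#' @export
finland_mtdna_counts <- function() {
  utils::read.table(system.file("extdata", "finland_mtdna_counts.tsv",
                                package = "ancientborder", mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Expand a haplogroup count table into a label-only sample collection
#'
#' @param counts data.frame with columns `subpop`, `haplogroup`, `count`.
#' @param marker marker class of the resulting [sample_set()].
#' @return A [sample_set()] without haplotype payloads (one record per
#'   counted sample, ids `F0001`, ...).
#' @export
counts_to_samples <- function(counts, marker = "MT") {
  idx <- rep(seq_len(nrow(counts)), counts$count)
  n <- length(idx)
  sample_set(data.frame(sample_id = sprintf("F%04d", seq_len(n)),
                        subpop = counts$subpop[idx],
                        haplogroup = counts$haplogroup[idx],
                        source = "count fixture"),
             marker = marker)
}
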