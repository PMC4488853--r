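#' Haplogroup cluster schemes
#'
#' A cluster scheme maps haplogroup labels to ancestry clusters. The default
#' follows the classic assignment of mitochondrial haplogroups to post-glacial
#' ancestry components: `HUNT` (Mesolithic hunter-gatherer associated: U, V)
#' and `FARM` (Neolithic farmer associated: H, J, T, K); haplogroups HV, D,
#' I, N, R, W, X, Z are explicit `OTHER` tokens. Note that `HV` must be an
#' explicit token — matching is longest-token-first, so `HV1` resolves to
#' `OTHER` via `HV` and never to `FARM` via `H`.
#'
#' @param tokens character vector of haplogroup tokens.
#' @param clusters parallel vector over `HUNT`, `FARM`, `OTHER`.
#' @return A `cluster_scheme` data.frame with columns `token`, `cluster`.
#' @export
cluster_scheme <- function(tokens = NULL, clusters = NULL) {
  if (is.null(tokens)) {
    tokens <- c("U", "V", "H", "J", "T", "K",
                "HV", "D", "I", "N", "R", "W", "X", "Z")
    clusters <- c(rep("HUNT", 2), rep("FARM", 4), rep("OTHER", 8))
  }
  tokens <- toupper(as.character(tokens))
  clusters <- toupper(as.character(clusters))
  if (anyDuplicated(tokens)) stop("duplicate scheme tokens")
  if (!all(clusters %in% c("HUNT", "FARM", "OTHER")))
    stop("clusters must be HUNT, FARM or OTHER")
  structure(data.frame(token = tokens, cluster = clusters),
            class = c("cluster_scheme", "data.frame"))
}

#' @rdname cluster_scheme
#' @param path TSV with columns `token`, `cluster`; the packaged default
#'   lives at `system.file("extdata", "default_scheme.tsv", package =
#'   "ancientborder")`.
#' @export
read_scheme <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  cluster_scheme(tab$token, tab$cluster)
}

# Split a haplogroup label into letter/digit run tokens: "U5b1" -> U,5,B,1.
# Prefix matching is on whole runs, so scheme token "H" never captures "HV".
.label_tokens <- function(label) {
  regmatches(label, gregexpr("[A-Z]+|[0-9]+", toupper(label)))[[1]]
}

#' Assign a haplogroup label to a cluster
#'
#' The longest scheme token that is a prefix of the label — respecting the
#' letter/digit run boundaries of phylotree-style nomenclature — decides the
#' cluster. `UNKNOWN` and unmatched labels map to `OTHER`; the function is
#' total and the result is independent of scheme row order.
#'
#' @param label haplogroup label(s), e.g. `"U5b1"`.
#' @param scheme a [cluster_scheme()].
#' @return Character vector over `HUNT`, `FARM`, `OTHER`.
#' @export
assign_cluster <- function(label, scheme = cluster_scheme()) {
  tok <- match_scheme_token(label, scheme)
  cl <- scheme$cluster[match(tok, scheme$token)]
  cl[is.na(cl)] <- "OTHER"
  cl
}

#' Match labels to their longest scheme token
#'
#' Groups haplogroup labels under the scheme token that [assign_cluster()]
#' would match (U5b1 under U, HV1 under HV); labels matching no token are
#' returned verbatim (uppercased), missing/empty ones as `UNKNOWN`.
#'
#' @param labels haplogroup label vector.
#' @param scheme a [cluster_scheme()].
#' @return Character vector of group names.
#' @export
match_scheme_token <- function(labels, scheme = cluster_scheme()) {
  labels <- as.character(labels)
  uniq <- unique(labels)
  scheme_runs <- lapply(scheme$token, .label_tokens)
  matched <- vapply(uniq, function(lab) {
    if (is.na(lab) || !nzchar(lab) || toupper(lab) == "UNKNOWN")
      return("UNKNOWN")
    runs <- .label_tokens(lab)
    best <- ""
    for (i in seq_along(scheme_runs)) {
      tr <- scheme_runs[[i]]
      if (length(tr) <= length(runs) &&
          identical(tr, runs[seq_along(tr)]) &&
          nchar(scheme$token[i]) > nchar(best))
        best <- scheme$token[i]
    }
    if (nzchar(best)) best else toupper(lab)
  }, "", USE.NAMES = FALSE)
  unname(matched[match(labels, uniq)])
}

#' Motif tables for lightweight haplogroup classification
#'
#' A motif table lists, per haplogroup, the set of defining variants as
#' alignment position plus derived base (e.g. `"126C"` = base C at alignment
#' column 126). It stands in for full phylogenetic-tree projection when only
#' control-region data are available.
#'
#' @param haplogroup character vector of unique labels.
#' @param motif character vector; comma-separated `"<pos><base>"` variants.
#' @return A `motif_table` with parsed positions/bases.
#' @export
motif_table <- function(haplogroup, motif) {
  if (anyDuplicated(haplogroup)) stop("duplicate haplogroup labels")
  parsed <- lapply(as.character(motif), function(m) {
    parts <- trimws(strsplit(m, ",")[[1]])
    pos <- as.integer(sub("([0-9]+)[ACGT-]$", "\\1", parts))
    base <- sub("^[0-9]+", "", parts)
    if (any(is.na(pos)) || any(!base %in% c("A", "C", "G", "T", "-")))
      stop("malformed motif: ", m)
    data.frame(pos = pos, base = base)
  })
  structure(list(haplogroup = as.character(haplogroup), motifs = parsed),
            class = "motif_table")
}

#' @rdname motif_table
#' @param path TSV with columns `haplogroup`, `motif`.
#' @export
read_motifs <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  motif_table(tab$haplogroup, tab$motif)
}

#' Conservatively classify a sequence by motif matching
#'
#' A haplogroup's motif matches when every defining variant is observed in
#' the sequence (an `N` or gap at a motif position does not count as a
#' match). The call is made only when it is unambiguous: among all fully
#' matching haplogroups, one must strictly dominate the rest by motif-set
#' inclusion; zero matches or two incomparable matches yield `UNASSIGNED`.
#' The policy is conservative by construction: removing a haplogroup from
#' the table can turn an assignment into `UNASSIGNED` but never into a
#' different haplogroup.
#'
#' @param seq an aligned sequence string.
#' @param motifs a [motif_table()].
#' @return A haplogroup label or `"UNASSIGNED"`.
#' @export
classify_by_motif <- function(seq, motifs) {
  seq <- toupper(seq)
  L <- nchar(seq)
  bases <- strsplit(seq, "")[[1]]
  full <- vapply(motifs$motifs, function(m) {
    if (any(m$pos < 1L | m$pos > L))
      stop("motif position out of alignment range (1..", L, ")")
    all(bases[m$pos] == m$base)
  }, TRUE)
  hits <- which(full)
  if (!length(hits)) return("UNASSIGNED")
  if (length(hits) == 1L) return(motifs$haplogroup[hits])
  keys <- lapply(motifs$motifs[hits], function(m) paste0(m$pos, m$base))
  dominates <- vapply(seq_along(hits), function(i) {
    all(vapply(seq_along(hits)[-i], function(j) {
      all(keys[[j]] %in% keys[[i]]) && length(keys[[i]]) > length(keys[[j]])
    }, TRUE))
  }, TRUE)
  if (sum(dominates) == 1L) motifs$haplogroup[hits[dominates]] else "UNASSIGNED"
}

#' Tabulate cluster membership per region
#'
#' Counts, for every region of a partition and every cluster of a scheme,
#' how many samples fall in the cluster, together with the region totals —
#' the success/total pairs consumed by the border-scan GLMs.
#'
#' @param x a [sample_set()].
#' @param scheme a [cluster_scheme()].
#' @param partition named character vector mapping every subpopulation code
#'   to a region label.
#' @return data.frame with columns `region`, `cluster`, `count`, `total`.
#' @export
cluster_counts <- function(x, scheme = cluster_scheme(), partition) {
  stopifnot(inherits(x, "sample_set"))
  unmapped <- setdiff(unique(x$samples$subpop), names(partition))
  if (length(unmapped))
    stop("subpopulation(s) not mapped by partition: ",
         paste(unmapped, collapse = ", "))
  region <- unname(partition[x$samples$subpop])
  cl <- assign_cluster(x$samples$haplogroup, scheme)
  regions <- unique(unname(partition))
  out <- expand.grid(region = regions, cluster = c("HUNT", "FARM", "OTHER"),
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(r, k) sum(region == r & cl == k),
                      out$region, out$cluster)
  out$total <- vapply(out$region, function(r) sum(region == r), 0L)
  out[order(out$region, out$cluster), c("region", "cluster", "count", "total")]
}

#' Default SW/NE region partition of the Finland fixture
#'
#' @return Named character vector over the 13 packaged subpopulation codes:
#'   `SW` for AL, TU, HA, VA, UU, LMO and `NE` for MI, CF, KU, KY, NC, OU, LA.
#' @export
finland_partition <- function() {
  c(AL = "SW", TU = "SW", HA = "SW", VA = "SW", UU = "SW", LMO = "SW",
    MI = "NE", CF = "NE", KU = "NE", KY = "NE", NC = "NE", OU = "NE",
    LA = "NE")
}
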