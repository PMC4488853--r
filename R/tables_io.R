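#' Construct a sample collection
#'
#' A `sample_set` bundles one marker class worth of individuals: a per-sample
#' table (id, subpopulation, haplogroup label, provenance) plus the haplotype
#' payload — aligned control-region sequences for mtDNA (`marker = "MT"`) or
#' Y-STR repeat-count profiles (`marker = "Y"`).
#'
#' @param samples data.frame with columns `sample_id`, `subpop`, `haplogroup`
#'   and optionally `source`. Missing haplogroups are stored as `"UNKNOWN"`.
#' @param marker `"MT"` or `"Y"`.
#' @param sequences named character vector of aligned sequences (bases over
#'   `A,C,G,T,N,-`), names matching `sample_id`; MT only. All sequences must
#'   share one alignment length.
#' @param profiles integer matrix of repeat counts, rownames matching
#'   `sample_id`, colnames the STR locus panel; Y only.
#' @param codes declared subpopulation codes; defaults to the codes present.
#'   Rows whose `subpop` is not among `codes` are an error.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(samples, marker = c("MT", "Y"), sequences = NULL,
                       profiles = NULL, codes = NULL) {
  marker <- match.arg(marker)
  stopifnot(is.data.frame(samples))
  required <- c("sample_id", "subpop", "haplogroup")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$subpop <- as.character(samples$subpop)
  samples$haplogroup <- as.character(samples$haplogroup)
  samples$haplogroup[is.na(samples$haplogroup) | samples$haplogroup == ""] <- "UNKNOWN"
  if (is.null(samples$source)) samples$source <- rep("", nrow(samples))
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup))
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  if (is.null(codes)) codes <- sort(unique(samples$subpop))
  bad <- setdiff(unique(samples$subpop), codes)
  if (length(bad))
    stop("subpopulation code(s) not declared: ", paste(bad, collapse = ", "))

  L <- NULL
  loci <- NULL
  if (marker == "MT" && !is.null(sequences)) {
    nm <- names(sequences)
    sequences <- stats::setNames(toupper(as.character(sequences)), nm)
    lens <- nchar(sequences)
    L <- lens[1]
    if (any(lens != L))
      stop("sequence length mismatch for sample(s): ",
           paste(names(sequences)[lens != L], collapse = ", "))
    if (any(grepl("[^ACGTN-]", sequences)))
      stop("sequences contain characters outside {A,C,G,T,N,-}")
    absent <- setdiff(samples$sample_id, names(sequences))
    if (length(absent))
      stop("no sequence for sample(s): ", paste(absent, collapse = ", "))
    sequences <- sequences[samples$sample_id]
  }
  if (marker == "Y" && !is.null(profiles)) {
    profiles <- as.matrix(profiles)
    storage.mode(profiles) <- "integer"
    if (any(profiles < 1L, na.rm = TRUE))
      stop("STR repeat counts must be positive integers")
    absent <- setdiff(samples$sample_id, rownames(profiles))
    if (length(absent))
      stop("no STR profile for sample(s): ", paste(absent, collapse = ", "))
    profiles <- profiles[samples$sample_id, , drop = FALSE]
    loci <- colnames(profiles)
  }
  structure(
    list(samples = samples, marker = marker, sequences = sequences,
         profiles = profiles, codes = codes, L = L, loci = loci),
    class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %s marker, %d samples, %d subpopulations\n",
              x$marker, nrow(x$samples), length(unique(x$samples$subpop))))
  if (!is.null(x$L)) cat(sprintf("  aligned length: %d\n", x$L))
  if (!is.null(x$loci)) cat(sprintf("  STR panel: %d loci\n", length(x$loci)))
  invisible(x)
}

#' @export
length.sample_set <- function(x) nrow(x$samples)

# Field separator auto-detection: tab wins if the header contains one.
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a per-sample table
#'
#' Reads a UTF-8 CSV or TSV (auto-detected from the header line) with columns
#' `sample_id`, `subpop`, `haplogroup` and optionally `source`. For mtDNA a
#' `sequence` column or a companion FASTA keyed by `sample_id` carries the
#' aligned haplotypes; for Y data every column named in `loci` (default: all
#' columns starting with `DYS`) is read as an STR repeat count.
#'
#' Rows are never silently dropped: any unparseable row is an error naming
#' its (1-based data) row number. Records with an empty haplogroup are kept
#' with haplogroup `UNKNOWN`.
#'
#' @param path table file.
#' @param marker `"MT"` or `"Y"`.
#' @param fasta optional FASTA path with MT sequences keyed by sample id.
#' @param codes optional declared subpopulation codes (e.g. the nodes of an
#'   adjacency graph); rows with other codes are an error.
#' @param loci optional explicit STR locus column names (Y only).
#' @return A [sample_set()].
#' @export
read_samples <- function(path, marker = c("MT", "Y"), fasta = NULL,
                         codes = NULL, loci = NULL) {
  marker <- match.arg(marker)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- .detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "",
                           comment.char = "", fill = TRUE,
                           blank.lines.skip = FALSE, encoding = "UTF-8")
  required <- c("sample_id", "subpop", "haplogroup")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("header lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  # field counts via separator counts (strsplit drops trailing empties)
  n_seps <- function(lines) {
    vapply(gregexpr(sep, lines, fixed = TRUE), function(m)
      if (m[1] == -1L) 0L else length(m), 0L)
  }
  ncols <- n_seps(readLines(path, n = 1L)) + 1L
  raw <- readLines(path)
  raw <- raw[-1L]
  bad_rows <- which(nzchar(raw) & n_seps(raw) + 1L != ncols)
  if (length(bad_rows))
    stop("malformed row(s): ", paste(bad_rows, collapse = ", "))
  empty <- which(!nzchar(raw))
  if (length(empty)) tab <- tab[nzchar(raw), , drop = FALSE]
  if (any(!nzchar(tab$sample_id) | !nzchar(tab$subpop)))
    stop("malformed row(s): ",
         paste(which(!nzchar(tab$sample_id) | !nzchar(tab$subpop)),
               collapse = ", "))

  sequences <- NULL
  profiles <- NULL
  if (marker == "MT") {
    if (!is.null(fasta)) {
      sequences <- read_alignment(fasta)
    } else if ("sequence" %in% names(tab)) {
      sequences <- stats::setNames(tab$sequence, tab$sample_id)
      tab$sequence <- NULL
    }
  } else {
    if (is.null(loci)) loci <- grep("^DYS", names(tab), value = TRUE)
    if (length(loci)) {
      prof <- suppressWarnings(
        vapply(tab[loci], function(col) as.integer(col), integer(nrow(tab))))
      prof <- matrix(prof, nrow = nrow(tab),
                     dimnames = list(tab$sample_id, loci))
      if (any(is.na(prof))) {
        bad <- which(apply(is.na(prof), 1L, any))
        stop("malformed row(s): non-integer repeat count in row(s) ",
             paste(bad, collapse = ", "))
      }
      profiles <- prof
      tab <- tab[setdiff(names(tab), loci)]
    }
  }
  sample_set(tab[intersect(c("sample_id", "subpop", "haplogroup", "source"),
                           names(tab))],
             marker = marker, sequences = sequences, profiles = profiles,
             codes = codes)
}

#' Write a per-sample table (and FASTA for mtDNA)
#'
#' Inverse of [read_samples()]: `write_samples` followed by `read_samples`
#' reproduces the collection exactly.
#'
#' @param x a [sample_set()].
#' @param path output table path; tab-separated.
#' @param fasta optional FASTA path for MT sequences; if `NULL`, sequences
#'   are written inline as a `sequence` column.
#' @return `path`, invisibly.
#' @export
write_samples <- function(x, path, fasta = NULL) {
  stopifnot(inherits(x, "sample_set"))
  tab <- x$samples
  if (x$marker == "MT" && !is.null(x$sequences)) {
    if (is.null(fasta)) {
      tab$sequence <- unname(x$sequences[tab$sample_id])
    } else {
      write_alignment(x$sequences, fasta)
    }
  }
  if (x$marker == "Y" && !is.null(x$profiles)) {
    tab <- cbind(tab, as.data.frame(x$profiles[tab$sample_id, , drop = FALSE]))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a fixed-length alignment as FASTA
#'
#' Thin wrappers over \pkg{ape}'s FASTA support, returning plain named
#' character strings (one per sample) so that downstream code can treat the
#' alignment as a matrix of single characters. All sequences must share one
#' length.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), paste0, "", collapse = "")
  seqs <- stats::setNames(toupper(seqs), names(seqs))
  lens <- nchar(seqs)
  if (length(seqs) && any(lens != lens[1]))
    stop("sequence length mismatch for sample(s): ",
         paste(names(seqs)[lens != lens[1]], collapse = ", "))
  seqs
}

#' @rdname read_alignment
#' @param seqs named character vector of sequences.
#' @export
write_alignment <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[i]), con)
  invisible(path)
}

#' Read a subpopulation adjacency graph
#'
#' The adjacency file is YAML with a `nodes` list of subpopulation codes and
#' an `edges` list of two-element code pairs. The graph must be simple,
#' undirected and connected — contiguity of a bipartition is defined as both
#' sides inducing connected subgraphs of this graph.
#'
#' @param path YAML file; see `system.file("extdata", "finland_adjacency.yaml",
#'   package = "ancientborder")` for the packaged 13-subpopulation fixture.
#' @return An `adjacency_graph`: list with `nodes`, `edges` (2-column
#'   character matrix) and `graph` (an \pkg{igraph} object).
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  spec <- yaml::read_yaml(path)
  if (is.null(spec$nodes) || is.null(spec$edges))
    stop("adjacency file must define 'nodes' and 'edges'")
  edges <- do.call(rbind, lapply(spec$edges, function(e) {
    if (length(e) != 2L) stop("edge must name exactly two codes")
    as.character(e)
  }))
  adjacency_graph(as.character(spec$nodes), edges)
}

#' @rdname read_adjacency
#' @param nodes character vector of unique subpopulation codes.
#' @param edges 2-column character matrix of undirected edges.
#' @export
adjacency_graph <- function(nodes, edges) {
  if (anyDuplicated(nodes)) stop("duplicate subpopulation codes")
  if (any(edges[, 1] == edges[, 2]))
    stop("self-loop in edge list: ", edges[edges[, 1] == edges[, 2], 1][1])
  unknown <- setdiff(unique(as.vector(edges)), nodes)
  if (length(unknown))
    stop("edge references unknown code(s): ", paste(unknown, collapse = ", "))
  key <- apply(cbind(pmin(edges[, 1], edges[, 2]),
                     pmax(edges[, 1], edges[, 2])), 1L, paste, collapse = "|")
  edges <- edges[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                            name = setdiff(nodes, igraph::V(g)$name))
  if (!igraph::is_connected(g))
    stop("adjacency graph is disconnected")
  structure(list(nodes = sort(nodes), edges = edges, graph = g),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d nodes, %d edges: %s\n",
              length(x$nodes), nrow(x$edges),
              paste(x$nodes, collapse = " ")))
  invisible(x)
}

#' Packaged 13-subpopulation Finland adjacency fixture
#'
#' Adjacency graph over the thirteen Finnish subpopulation codes
#' (AL, TU, HA, VA, UU, LMO in the southwest; MI, CF, KU, KY, NC, OU, LA in
#' the northeast), with edges reflecting geographic neighbourhood.
#'
#' @return An `adjacency_graph`.
#' @export
finland_graph <- function() {
  read_adjacency(system.file("extdata", "finland_adjacency.yaml",
                             package = "ancientborder", mustWork = TRUE))
}

#' Write an analysis report
#'
#' Serialises any of the package's tabular summaries (data.frames go to TSV)
#' or structured results (lists, e.g. [scan_border()] output, go to JSON).
#' Numeric fields survive a write/read round trip at 12 significant digits.
#'
#' @param result a data.frame or list.
#' @param path output path.
#' @param format `"tsv"` or `"json"`; default guessed from `result`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = NULL) {
  if (is.null(format)) format <- if (is.data.frame(result)) "tsv" else "json"
  format <- match.arg(tolower(format), c("tsv", "json"))
  if (format == "tsv") {
    if (!is.data.frame(result)) stop("TSV reports require a data.frame")
    out <- result
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], function(v) formatC(v, digits = 15,
                                                     format = "g"))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    payload <- .strip_unserializable(result)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

# igraph handles and environments cannot go to JSON; drop them recursively.
.strip_unserializable <- function(x) {
  if (inherits(x, "igraph") || is.environment(x) || is.function(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    x <- lapply(x, .strip_unserializable)
    if (!is.null(names(x))) x <- x[!vapply(x, is.null, TRUE)]
    x
  } else x
}

#' Read a TSV report back
#'
#' @param path TSV written by [write_report()].
#' @return data.frame with numeric columns restored.
#' @export
read_report <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           quote = "", comment.char = "", encoding = "UTF-8",
                           stringsAsFactors = FALSE)
  for (j in seq_along(tab)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    if (!any(is.na(v) & !is.na(tab[[j]]) & tab[[j]] != "NA")) tab[[j]] <- v
  }
  tab
}
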