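#' Bipartition of a subpopulation graph
#'
#' Unordered two-sided split of the graph's nodes. Canonical form: the side
#' containing the lexicographically smallest code is `side_a`. A bipartition
#' is contiguous when both sides induce connected subgraphs — the search
#' space of the border scan.
#'
#' @param side_a,side_b character vectors of subpopulation codes.
#' @param graph an `adjacency_graph` (see [read_adjacency()]).
#' @return A `bipartition`: list with sorted `side_a`, `side_b` and a
#'   `contiguous` flag.
#' @export
bipartition <- function(side_a, side_b, graph) {
  side_a <- sort(unique(as.character(side_a)))
  side_b <- sort(unique(as.character(side_b)))
  if (length(intersect(side_a, side_b))) stop("sides must be disjoint")
  if (!length(side_a) || !length(side_b)) stop("sides must be nonempty")
  if (!setequal(c(side_a, side_b), graph$nodes))
    stop("sides must cover all graph nodes")
  if (side_b[1] < side_a[1]) { tmp <- side_a; side_a <- side_b; side_b <- tmp }
  adj <- .adjlist(graph)
  structure(list(side_a = side_a, side_b = side_b,
                 contiguous = .is_connected_subset(side_a, adj) &&
                   .is_connected_subset(side_b, adj)),
            class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat(sprintf("<bipartition%s> {%s} | {%s}\n",
              if (x$contiguous) ", contiguous" else "",
              paste(x$side_a, collapse = ","),
              paste(x$side_b, collapse = ",")))
  invisible(x)
}

# adjacency list keyed by node code
.adjlist <- function(graph) {
  adj <- lapply(graph$nodes, function(v) character(0))
  names(adj) <- graph$nodes
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges[i, 1]; b <- graph$edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# BFS connectivity of the subgraph induced by `nodes`
.is_connected_subset <- function(nodes, adj) {
  if (length(nodes) <= 1L) return(TRUE)
  seen <- stats::setNames(logical(length(nodes)), nodes)
  queue <- nodes[1]
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- intersect(adj[[v]], nodes)
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Enumerate all geographically contiguous bipartitions
#'
#' Exhaustive scan over the `2^(n-1) - 1` unordered bipartitions of the
#' graph's nodes, keeping exactly those in which both sides induce connected
#' subgraphs and both sides have at least `min_side` nodes.
#'
#' @param graph an `adjacency_graph` with at most 24 nodes (the scan is
#'   exponential; larger graphs need a sampling strategy, not provided).
#' @param min_side minimum nodes per side (default 1).
#' @return List of contiguous [bipartition()]s, no duplicates.
#' @export
contiguous_bipartitions <- function(graph, min_side = 1L) {
  n <- length(graph$nodes)
  if (n > 24) stop("graph has more than 24 nodes; exhaustive enumeration ",
                   "infeasible — use a sampling mode instead")
  memb <- .enumerate_sides(graph, min_side, contiguous = TRUE)
  lapply(seq_len(nrow(memb)), function(i)
    bipartition(graph$nodes[memb[i, ]], graph$nodes[!memb[i, ]], graph))
}

# enumeration results are deterministic per (graph, min_side, contiguous);
# cache them so repeated scans of one graph pay the exponential sweep once
.enum_cache <- new.env(parent = emptyenv())

# Membership matrix (rows = bipartitions, cols = graph$nodes, TRUE = side
# containing the lexicographically smallest node). contiguous = TRUE keeps
# splits with both sides connected; FALSE keeps the complement.
.enumerate_sides <- function(graph, min_side = 1L, contiguous = TRUE) {
  nodes <- graph$nodes    # sorted; nodes[1] anchors side_a
  n <- length(nodes)
  key <- paste(c(nodes, t(graph$edges), min_side, contiguous),
               collapse = "\r")
  hit <- .enum_cache[[key]]
  if (!is.null(hit)) return(hit)
  adj <- .adjlist(graph)
  keep <- list()
  for (code in 0:(2^(n - 1) - 2)) {
    # bit i of code selects nodes[i + 1]; nodes[1] always on side_a,
    # code 2^(n-1)-1 (everything on side_a) is excluded
    in_a <- c(TRUE, bitwAnd(code, 2^(seq_len(n - 1) - 1)) > 0)
    size_a <- sum(in_a)
    if (size_a < min_side || n - size_a < min_side) next
    ok <- .is_connected_subset(nodes[in_a], adj) &&
      .is_connected_subset(nodes[!in_a], adj)
    if (ok == contiguous) keep[[length(keep) + 1L]] <- in_a
  }
  out <- do.call(rbind, keep)
  if (is.null(out)) out <- matrix(logical(0), 0, n)
  colnames(out) <- nodes
  .enum_cache[[key]] <- out
  out
}

#' Fit the side-contrast binomial GLM
#'
#' Logistic regression of per-subpopulation cluster counts on a side
#' indicator: `cbind(successes, failures) ~ side`, binomial family, logit
#' link, fitted by iteratively reweighted least squares (deviance tolerance
#' 1e-12, up to 100 iterations). `beta` is the coefficient of membership in side A
#' (with side A the southwest-like side, `beta < 0` means lower odds in the
#' southwest); `p` is the two-sided Wald p-value.
#'
#' Since side is the only covariate, the maximum-likelihood fit depends on
#' the data only through the pooled per-side totals, and `beta`/`se` equal
#' the pooled 2x2-table log odds ratio and its standard error. Complete
#' separation (zero successes or zero failures pooled on a side) is flagged
#' `converged = FALSE` with `p` penalised to 1.
#'
#' @param successes,totals named numeric vectors per subpopulation.
#' @param side logical vector (or vector of the side-A codes): `TRUE` =
#'   side A.
#' @return A `glm_fit`: list with `beta`, `se`, `p`, `converged`.
#' @export
fit_side_glm <- function(successes, totals, side) {
  if (is.character(side)) side <- names(successes) %in% side
  stopifnot(length(successes) == length(totals),
            length(side) == length(successes))
  if (any(successes < 0) || any(successes > totals))
    stop("need 0 <= successes <= totals")
  if (!any(side) || all(side)) stop("both sides must be represented")
  sa <- sum(successes[side]);  ta <- sum(totals[side])
  sb <- sum(successes[!side]); tb <- sum(totals[!side])
  if (sa == 0 || sb == 0 || sa == ta || sb == tb) {
    return(structure(list(beta = NA_real_, se = NA_real_, p = 1.0,
                          converged = FALSE), class = "glm_fit"))
  }
  fit <- stats::glm(cbind(successes, totals - successes) ~ side,
                    family = stats::binomial("logit"),
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  beta <- unname(stats::coef(fit)["sideTRUE"])
  se <- unname(sqrt(diag(stats::vcov(fit))["sideTRUE"]))
  structure(list(beta = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 converged = fit$converged),
            class = "glm_fit")
}

# Closed-form Wald statistics of the side-contrast GLM (the exact IRLS fixed
# point for this one-covariate design): pooled 2x2 log-OR. Vectorised over
# side assignments given as a membership matrix.
.wald_two_group <- function(sa, ta, sb, tb) {
  sep <- sa == 0 | sb == 0 | sa == ta | sb == tb
  beta <- log((sa / (ta - sa)) / (sb / (tb - sb)))
  se <- sqrt(1 / sa + 1 / (ta - sa) + 1 / sb + 1 / (tb - sb))
  p <- 2 * stats::pnorm(-abs(beta / se))
  beta[sep] <- NA_real_; se[sep] <- NA_real_; p[sep] <- 1.0
  list(beta = beta, se = se, p = p, converged = !sep)
}

# Per-bipartition product-of-p score for given membership matrix
.score_bipartitions <- function(memb, hunt, farm, totals) {
  ta <- as.vector(memb %*% totals)
  tb <- sum(totals) - ta
  ha <- as.vector(memb %*% hunt)
  fa <- as.vector(memb %*% farm)
  p_hunt <- .wald_two_group(ha, ta, sum(hunt) - ha, tb)$p
  p_farm <- .wald_two_group(fa, ta, sum(farm) - fa, tb)$p
  data.frame(size_a = rowSums(memb), p_hunt = p_hunt, p_farm = p_farm,
             S = p_hunt * p_farm)
}

#' Per-subpopulation cluster counts for the border scan
#'
#' @param x a [sample_set()].
#' @param scheme a [cluster_scheme()].
#' @param nodes subpopulation codes ordering the output (default: codes
#'   present, sorted).
#' @return list of named vectors `hunt`, `farm`, `totals`.
#' @export
subpop_cluster_counts <- function(x, scheme = cluster_scheme(),
                                  nodes = NULL) {
  stopifnot(inherits(x, "sample_set"))
  if (is.null(nodes)) nodes <- sort(unique(x$samples$subpop))
  missing_nodes <- setdiff(unique(x$samples$subpop), nodes)
  if (length(missing_nodes))
    stop("samples from undeclared subpopulation(s): ",
         paste(missing_nodes, collapse = ", "))
  cl <- assign_cluster(x$samples$haplogroup, scheme)
  sub <- factor(x$samples$subpop, levels = nodes)
  list(hunt = stats::setNames(as.numeric(table(sub[cl == "HUNT"])), nodes),
       farm = stats::setNames(as.numeric(table(sub[cl == "FARM"])), nodes),
       totals = stats::setNames(as.numeric(table(sub)), nodes))
}

#' Scan contiguous bipartitions for the strongest ancestry border
#'
#' Evaluates every geographically contiguous bipartition of the graph,
#' scoring each with the product `S = p_HUNT * p_FARM` of the two-sided
#' Wald p-values from the side-contrast binomial GLMs of hunter-gatherer
#' and farmer cluster counts, and returns the bipartition minimising `S`.
#' Ties are broken toward the more balanced split (larger smaller side),
#' then by canonical lexicographic order. As a validity control the optimum
#' is contrasted with `null_draws` random non-contiguous bipartitions
#' scored the same way (see [random_bipartition_null()]).
#'
#' @param hunt,farm,totals named per-subpopulation count vectors, keyed by
#'   the graph's nodes (see [subpop_cluster_counts()]).
#' @param graph an `adjacency_graph`.
#' @param min_side minimum nodes per side.
#' @param null_draws random non-contiguous control bipartitions (0 = none).
#' @param seed integer seed for the null draws.
#' @return A `border_scan_result`: list with `best` ([bipartition()]),
#'   `p_hunt`, `p_farm`, `product`, `all_scores` (audit data.frame over all
#'   contiguous candidates), `null_products`, `seed`.
#' @export
scan_border <- function(hunt, farm, totals, graph, min_side = 1L,
                        null_draws = 10L, seed = 1L) {
  nodes <- graph$nodes
  miss <- setdiff(nodes, names(totals))
  if (length(miss)) stop("counts missing for node(s): ",
                         paste(miss, collapse = ", "))
  hunt <- hunt[nodes]; farm <- farm[nodes]; totals <- totals[nodes]
  memb <- .enumerate_sides(graph, min_side, contiguous = TRUE)
  if (!nrow(memb)) stop("no contiguous bipartition satisfies min_side")
  scores <- .score_bipartitions(memb, hunt, farm, totals)
  scores$side_a <- apply(memb, 1L, function(m)
    paste(nodes[m], collapse = ","))
  ord <- order(scores$S, -pmin(scores$size_a, length(nodes) - scores$size_a),
               scores$side_a)
  best_i <- ord[1]
  best <- bipartition(nodes[memb[best_i, ]], nodes[!memb[best_i, ]], graph)
  nulls <- NULL
  if (null_draws > 0)
    nulls <- random_bipartition_null(hunt, farm, totals, graph,
                                     k = null_draws, seed = seed)
  structure(
    list(best = best, p_hunt = scores$p_hunt[best_i],
         p_farm = scores$p_farm[best_i], product = scores$S[best_i],
         all_scores = scores[order(scores$S),
                             c("side_a", "size_a", "p_hunt", "p_farm", "S")],
         null_products = nulls, seed = as.integer(seed)),
    class = "border_scan_result")
}

#' @export
print.border_scan_result <- function(x, ...) {
  cat("<border_scan_result>\n  best: ")
  print(x$best)
  cat(sprintf("  p_HUNT = %.3g, p_FARM = %.3g, S = %.3g\n",
              x$p_hunt, x$p_farm, x$product))
  if (!is.null(x$null_products))
    cat(sprintf("  null (non-contiguous, k = %d): S in [%.3g, %.3g]\n",
                nrow(x$null_products), min(x$null_products$S),
                max(x$null_products$S)))
  invisible(x)
}

#' Random non-contiguous control bipartitions
#'
#' Draws `k` bipartitions uniformly from those that are *not* contiguous
#' (rejection sampling over uniform random splits) and scores each with the
#' same product-of-p-values statistic as the scan. On a graph where every
#' bipartition is contiguous (e.g. a complete graph) no draw exists and an
#' error names the condition.
#'
#' @inheritParams scan_border
#' @param k number of control draws.
#' @return data.frame with `side_a`, `size_a`, `p_hunt`, `p_farm`, `S`.
#' @export
random_bipartition_null <- function(hunt, farm, totals, graph, k = 10L,
                                    seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  nodes <- graph$nodes
  n <- length(nodes)
  hunt <- hunt[nodes]; farm <- farm[nodes]; totals <- totals[nodes]
  adj <- .adjlist(graph)
  set.seed(as.integer(seed))
  draws <- matrix(FALSE, k, n, dimnames = list(NULL, nodes))
  got <- 0L
  attempts <- 0L
  while (got < k) {
    attempts <- attempts + 1L
    if (attempts > 20000L * k)
      stop("could not draw a non-contiguous bipartition: every bipartition ",
           "of this graph appears to be contiguous")
    in_a <- stats::runif(n) < 0.5
    if (!any(in_a) || all(in_a)) next
    if (.is_connected_subset(nodes[in_a], adj) &&
        .is_connected_subset(nodes[!in_a], adj)) next
    if (!in_a[1]) in_a <- !in_a   # canonical: anchor node on side_a
    got <- got + 1L
    draws[got, ] <- in_a
  }
  scores <- .score_bipartitions(draws, hunt, farm, totals)
  scores$side_a <- apply(draws, 1L, function(m)
    paste(nodes[m], collapse = ","))
  scores[c("side_a", "size_a", "p_hunt", "p_farm", "S")]
}

#' Per-haplogroup regional bias estimates
#'
#' For every haplogroup with at least `min_count` samples, fits the
#' side-contrast binomial GLM of membership-in-the-haplogroup on region,
#' giving the log-odds bias of the side-A (southwest-like) region relative
#' to side B, its standard error, two-sided Wald p-value and a significance
#' tier (`***` p < 0.001, `**` < 0.01, `*` < 0.05).
#'
#' @param x a [sample_set()].
#' @param partition named region map over subpopulation codes (two regions).
#' @param scheme a [cluster_scheme()]; samples are grouped under their
#'   matched scheme token (U5b1 under U), unmatched labels verbatim.
#' @param side_a region label taken as side A; defaults to the region
#'   containing the lexicographically smallest subpopulation code.
#' @param min_count haplogroups below this total are skipped with a warning.
#' @return data.frame with `haplogroup`, `n`, `beta`, `se`, `p`,
#'   `converged`, `signif`.
#' @export
haplogroup_bias <- function(x, partition, scheme = cluster_scheme(),
                            side_a = NULL, min_count = 10L) {
  stopifnot(inherits(x, "sample_set"))
  unmapped <- setdiff(unique(x$samples$subpop), names(partition))
  if (length(unmapped))
    stop("subpopulation(s) not mapped by partition: ",
         paste(unmapped, collapse = ", "))
  if (length(unique(unname(partition))) != 2)
    stop("bias estimation requires a two-region partition")
  if (is.null(side_a))
    side_a <- unname(partition[sort(names(partition))[1]])
  nodes <- sort(unique(x$samples$subpop))
  side <- unname(partition[nodes]) == side_a
  totals <- vapply(nodes, function(v) sum(x$samples$subpop == v), 0)
  matched <- match_scheme_token(x$samples$haplogroup, scheme)
  rows <- list()
  for (g in sort(unique(matched))) {
    n_g <- sum(matched == g)
    if (n_g < min_count) {
      warning("haplogroup ", g, " below min_count (", n_g, " < ",
              min_count, "); skipped")
      next
    }
    succ <- vapply(nodes, function(v)
      sum(matched == g & x$samples$subpop == v), 0)
    fit <- fit_side_glm(succ, totals, side)
    tier <- if (!fit$converged) "" else
      if (fit$p < 0.001) "***" else if (fit$p < 0.01) "**" else
      if (fit$p < 0.05) "*" else ""
    rows[[length(rows) + 1L]] <-
      data.frame(haplogroup = g, n = n_g, beta = fit$beta, se = fit$se,
                 p = fit$p, converged = fit$converged, signif = tier)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
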