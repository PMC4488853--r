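# 17-locus Yfiler panel; the 16-locus variant drops DYS635 (the locus most
# often absent from community datasets).
.yfiler_loci <- c("DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391",
                  "DYS392", "DYS393", "DYS437", "DYS438", "DYS439",
                  "DYS448", "DYS456", "DYS458", "DYS635", "YGATAH4",
                  "DYS385a", "DYS385b")

# even split of a region total across k subpopulations (remainder to the
# first nodes) — deterministic
.split_total <- function(total, k) {
  base <- total %/% k
  out <- rep(base, k)
  extra <- total - base * k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}

#' Study-scale default haplogroup frequencies per side
#'
#' Southwest/northeast per-haplogroup frequencies at the magnitudes observed
#' in the Finnish study system: mtDNA (HUNT members U, V at 0.211 vs 0.339
#' combined; FARM members H, J, T, K at 0.560 vs 0.454 combined; remainder
#' OTHER), and Y data dominated by two haplogroups (N1c vs I1 with opposite
#' regional bias).
#'
#' @param marker `"MT"` or `"Y"`.
#' @return list with named frequency vectors `a` (southwest-like side) and
#'   `b` (northeast-like side); remainders are emitted as OTHER haplogroups.
#' @export
default_side_frequencies <- function(marker = c("MT", "Y")) {
  marker <- match.arg(marker)
  if (marker == "MT") {
    list(a = c(U = 0.180, V = 0.031, H = 0.342, J = 0.085, T = 0.072,
               K = 0.062),
         b = c(U = 0.298, V = 0.041, H = 0.323, J = 0.029, T = 0.052,
               K = 0.050))
  } else {
    # exact ratios of the regional haplogroup counts (printed 3-decimal
    # frequencies round to sums slightly above 1)
    list(a = c(N1c = 115, I1 = 170, I2 = 2, R1a = 11, R1b = 6) / 306,
         b = c(N1c = 162, I1 = 58, I2 = 6, R1a = 9, R1b = 8) / 243)
  }
}

#' Apply a logit-scale border effect to a baseline frequency vector
#'
#' The planted side's frequencies are obtained by shifting the logit of
#' every HUNT-member haplogroup by `+delta` and every FARM-member by
#' `-delta` (OTHER mass unchanged), then renormalising to sum 1.
#'
#' @param freqs named baseline haplogroup frequencies (sum <= 1; remainder
#'   is OTHER).
#' @param delta non-negative logit shift.
#' @param scheme a [cluster_scheme()].
#' @return Shifted, renormalised frequency vector including an `OTHER`
#'   component.
#' @export
shift_frequencies <- function(freqs, delta, scheme = cluster_scheme()) {
  if (delta < 0) stop("delta must be >= 0")
  if (sum(freqs) > 1 + 1e-12) stop("frequencies sum above 1")
  full <- c(freqs, OTHER = max(0, 1 - sum(freqs)))
  cl <- assign_cluster(names(full), scheme)
  shift <- ifelse(cl == "HUNT", delta, ifelse(cl == "FARM", -delta, 0))
  shifted <- stats::plogis(stats::qlogis(pmin(pmax(full, 1e-12),
                                              1 - 1e-12)) + shift)
  shifted["OTHER"] <- full["OTHER"]
  shifted / sum(shifted)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study conditions: the packaged 13-subpopulation graph, the
#' southwest/northeast planted border, per-side haplogroup frequencies of
#' the observed magnitudes ([default_side_frequencies()]), region totals
#' 389 (southwest) and 443 (northeast) for mtDNA — 306/243 for Y — split
#' evenly across each side's subpopulations, 643-column alignments, a
#' 16-locus Y-STR panel, and a haplotype-spectrum innovation parameter
#' `theta = 30` (haplotype diversities around 0.97).
#'
#' @param marker `"MT"` or `"Y"`.
#' @param graph an `adjacency_graph`.
#' @param border a [bipartition()] of the graph, or `"none"` for no planted
#'   structure.
#' @param side_freqs list of per-side frequency vectors `a`, `b`; overrides
#'   `freqs`/`delta`.
#' @param freqs baseline frequencies used with `delta` (side A keeps the
#'   baseline, side B gets [shift_frequencies()] applied); with
#'   `border = "none"` or `delta = 0`, both sides share the baseline.
#' @param delta logit-scale border effect (>= 0).
#' @param n_per_subpop named sample sizes per subpopulation code; default
#'   splits the study region totals evenly.
#' @param theta innovation parameter of the haplotype-spectrum process.
#' @param L alignment length (MT).
#' @param str_loci Y-STR panel size (16 or 17).
#' @param mu_str per-locus per-generation stepwise mutation rate.
#' @param depth star-genealogy depth in generations.
#' @param mu_private mean number of extra private variants per new sequence
#'   class (each class gets `1 + rpois(mu_private)`).
#' @param root_muts haplogroup-defining variants separating each haplogroup
#'   root from the shared reference sequence (controls between-haplogroup
#'   nucleotide diversity).
#' @param haplotypes generate haplotype payloads (set `FALSE` for
#'   label-only datasets when only frequencies are analysed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(marker = c("MT", "Y"), graph = finland_graph(),
                       border = NULL, side_freqs = NULL, freqs = NULL,
                       delta = NULL, n_per_subpop = NULL, theta = 30,
                       L = 643L, str_loci = 16L, mu_str = 0.002,
                       depth = 200L, mu_private = 1, root_muts = 3L,
                       haplotypes = TRUE) {
  marker <- match.arg(marker)
  if (is.null(border)) {
    part <- finland_partition()
    border <- bipartition(names(part)[part == "SW"],
                          names(part)[part == "NE"], graph)
  }
  planted <- !identical(border, "none")
  if (planted && !inherits(border, "bipartition"))
    stop("border must be a bipartition or \"none\"")
  if (is.null(side_freqs) && is.null(freqs))
    side_freqs <- default_side_frequencies(marker)
  if (!is.null(side_freqs)) {
    fa <- side_freqs$a; fb <- side_freqs$b
  } else {
    if (is.null(delta)) delta <- 0
    fa <- freqs
    fb <- if (planted) shift_frequencies(freqs, delta) else freqs
  }
  if (sum(fa) > 1 + 1e-9 || sum(fb) > 1 + 1e-9)
    stop("frequency vector sums above 1")
  if (is.null(n_per_subpop)) {
    if (planted) {
      na <- .split_total(if (marker == "MT") 389L else 306L,
                         length(border$side_a))
      nb <- .split_total(if (marker == "MT") 443L else 243L,
                         length(border$side_b))
      n_per_subpop <- stats::setNames(c(na, nb),
                                      c(border$side_a, border$side_b))
    } else {
      n_per_subpop <- stats::setNames(
        .split_total(if (marker == "MT") 832L else 584L,
                     length(graph$nodes)), graph$nodes)
    }
  }
  if (!setequal(names(n_per_subpop), graph$nodes))
    stop("n_per_subpop must cover exactly the graph nodes")
  if (any(n_per_subpop < 1)) stop("sample counts must be positive")
  structure(list(marker = marker, graph = graph, border = border,
                 freqs_a = fa, freqs_b = fb, n_per_subpop = n_per_subpop,
                 theta = theta, L = as.integer(L),
                 str_loci = as.integer(str_loci), mu_str = mu_str,
                 depth = as.integer(depth), mu_private = mu_private,
                 root_muts = as.integer(root_muts),
                 haplotypes = isTRUE(haplotypes)),
            class = "sim_config")
}

#' Realise one sequence haplotype class from a haplogroup root
#'
#' Infinite-sites sprinkling: `n_private` distinct alignment positions, not
#' previously used within the haplogroup, are mutated away from the root
#' base. Two classes built from the same root with disjoint private sets of
#' sizes `a` and `b` therefore differ at exactly `a + b` sites.
#'
#' @param root root sequence string of the haplogroup.
#' @param n_private number of private variants (0 returns the root).
#' @param used integer positions already consumed within this haplogroup.
#' @return list with `seq` and the `positions` consumed.
#' @export
simulate_sequence_class <- function(root, n_private, used = integer(0)) {
  L <- nchar(root)
  if (n_private == 0) return(list(seq = root, positions = integer(0)))
  pool <- setdiff(seq_len(L), used)
  if (n_private > length(pool))
    stop("position pool exhausted: need ", n_private, ", have ",
         length(pool))
  pos <- if (length(pool) == 1L) pool else sample(pool, n_private)
  bases <- strsplit(root, "")[[1]]
  for (p in pos) {
    bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
  }
  list(seq = paste(bases, collapse = ""), positions = pos)
}

#' Evolve a Y-STR profile down a star genealogy branch
#'
#' Per locus, the number of mutation events is Poisson(`depth * mu_str`)
#' and each event moves the repeat count by +1 or -1 with equal
#' probability (stepwise mutation model); counts are floored at 1. The
#' expected squared distance between two independent descendants of one
#' ancestor is `2 * depth * mu_str` per locus.
#'
#' @param ancestral named integer vector of ancestral repeat counts.
#' @param depth branch length in generations.
#' @param mu_str per-locus per-generation mutation rate (0 returns the
#'   ancestor unchanged).
#' @return Named integer vector of descendant repeat counts.
#' @export
simulate_str_profile <- function(ancestral, depth, mu_str) {
  k <- length(ancestral)
  events <- stats::rpois(k, depth * mu_str)
  steps <- vapply(events, function(e)
    if (e == 0) 0L else sum(sample(c(-1L, 1L), e, replace = TRUE)), 0L)
  pmax(ancestral + steps, 1L)
}

# Chinese-restaurant style class draw: new class with prob theta/(theta+i-1)
# at the i-th within-haplogroup draw, else an existing class proportional to
# its current count. State kept in a plain list per haplogroup.
.draw_class <- function(state, theta) {
  i <- state$n + 1L
  if (stats::runif(1) < theta / (theta + i - 1)) {
    state$k <- state$k + 1L
    cls <- state$k
    state$counts[cls] <- 0L
  } else {
    cls <- sample.int(state$k, 1L, prob = state$counts)
  }
  state$counts[cls] <- state$counts[cls] + 1L
  state$n <- i
  list(state = state, class = cls)
}

#' Generate a synthetic uniparental dataset with a planted border
#'
#' Per subpopulation, haplogroup labels are drawn from the side-specific
#' frequency vector (the remainder mass becomes OTHER haplogroups drawn
#' from a fixed outgroup label set). Within each haplogroup, haplotype
#' classes follow a sequential innovation process with parameter `theta`
#' (a new class appears at draw *i* with probability `theta/(theta+i-1)`),
#' and every class is realised as a concrete haplotype: an aligned sequence
#' carrying class-private variants on a star genealogy
#' ([simulate_sequence_class()]) or a stepwise-mutated Y-STR profile
#' ([simulate_str_profile()]). The returned truth record stores the planted
#' bipartition and the realised per-side cluster frequencies; the analysis
#' pipeline never reads it.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; equal seeds give byte-identical datasets.
#' @return list with `samples` (a [sample_set()]) and `truth`.
#' @export
simulate_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  nodes <- names(config$n_per_subpop)
  planted <- inherits(config$border, "bipartition")
  other_labels <- if (config$marker == "MT")
    c("I", "W", "X", "D", "N1a", "Z", "HV", "R0") else c("Q", "E1b1", "J2")

  hg <- character(0); subpop <- character(0)
  for (v in nodes) {
    f <- if (planted && v %in% config$border$side_b) config$freqs_b
         else config$freqs_a
    probs <- c(f, OTHER = max(0, 1 - sum(f)))
    n_v <- config$n_per_subpop[[v]]
    lab <- sample(names(probs), n_v, replace = TRUE, prob = probs)
    is_other <- lab == "OTHER"
    if (any(is_other))
      lab[is_other] <- sample(other_labels, sum(is_other), replace = TRUE)
    hg <- c(hg, lab)
    subpop <- c(subpop, rep(v, n_v))
  }
  n <- length(hg)
  ids <- sprintf("S%04d", seq_len(n))
  samples <- data.frame(sample_id = ids, subpop = subpop, haplogroup = hg,
                        source = "synthetic")

  sequences <- NULL; profiles <- NULL
  if (config$haplotypes) {
    states <- list()
    class_haps <- list()   # per haplogroup: list of realised haplotypes
    roots <- list()
    used <- list()
    assigned <- vector("list", n)
    if (config$marker == "Y") {
      loci <- if (config$str_loci == 16L) setdiff(.yfiler_loci, "DYS635")
              else .yfiler_loci[seq_len(config$str_loci)]
    } else {
      # one reference per dataset; haplogroup roots carry root_muts
      # defining variants, so between-haplogroup distances stay at the
      # few-per-mille scale of real control regions
      reference <- paste(sample(c("A", "C", "G", "T"), config$L,
                                replace = TRUE), collapse = "")
    }
    for (i in seq_len(n)) {
      g <- hg[i]
      if (is.null(states[[g]])) {
        states[[g]] <- list(n = 0L, k = 0L, counts = integer(0))
        class_haps[[g]] <- list()
        if (config$marker == "MT") {
          root <- simulate_sequence_class(reference, config$root_muts)
          roots[[g]] <- root$seq
          used[[g]] <- root$positions
        } else {
          roots[[g]] <- stats::setNames(
            sample(10:20, length(loci), replace = TRUE), loci)
          used[[g]] <- integer(0)
        }
      }
      drawn <- .draw_class(states[[g]], config$theta)
      states[[g]] <- drawn$state
      cls <- drawn$class
      if (cls > length(class_haps[[g]]) || is.null(class_haps[[g]][[cls]])) {
        if (config$marker == "MT") {
          n_priv <- if (cls == 1L) 0L else 1L + stats::rpois(1, config$mu_private)
          realised <- simulate_sequence_class(roots[[g]], n_priv,
                                              used[[g]])
          used[[g]] <- c(used[[g]], realised$positions)
          class_haps[[g]][[cls]] <- realised$seq
        } else {
          class_haps[[g]][[cls]] <-
            simulate_str_profile(roots[[g]], config$depth, config$mu_str)
        }
      }
      assigned[[i]] <- class_haps[[g]][[cls]]
    }
    if (config$marker == "MT") {
      sequences <- stats::setNames(vapply(assigned, identity, ""), ids)
    } else {
      profiles <- do.call(rbind, assigned)
      rownames(profiles) <- ids
    }
  }
  x <- sample_set(samples, marker = config$marker, sequences = sequences,
                  profiles = profiles, codes = config$graph$nodes)
  cl <- assign_cluster(hg)
  side <- if (planted)
    ifelse(subpop %in% config$border$side_a, "A", "B") else rep("A", n)
  realised <- do.call(rbind, lapply(unique(side), function(s) {
    data.frame(side = s,
               hunt = mean(cl[side == s] == "HUNT"),
               farm = mean(cl[side == s] == "FARM"),
               n = sum(side == s))
  }))
  list(samples = x,
       truth = list(border = if (planted) config$border else NULL,
                    freqs_a = config$freqs_a, freqs_b = config$freqs_b,
                    realised = realised, seed = as.integer(seed)))
}
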