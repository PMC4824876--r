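# Pairwise distances, average-neighbor OTU clustering, rarefaction.

#' Pairwise sequence distance
#'
#' Distance on the pairwise global alignment with terminal gaps excluded. By
#' default a contiguous gap run counts as a single difference event (the
#' common 16S convention), giving
#' `(n_sub + n_gap_events) / (n_match + n_sub + n_gap_events)`; with
#' `count_gap_runs_as_one = FALSE` every gapped base counts.
#'
#' @param a,b Sequences.
#' @param count_gap_runs_as_one Count an indel run as one event (default).
#' @param exclude_terminal_gaps Exclude terminal gap columns (default).
#' @param band Optional alignment band (see [align_pair()]).
#' @return Distance in `[0, 1]`.
#' @export
pairwise_distance <- function(a, b, count_gap_runs_as_one = TRUE,
                              exclude_terminal_gaps = TRUE, band = NULL) {
  aln <- align_pair(a, b, band = band, free_ends = FALSE,
                    exclude_terminal = exclude_terminal_gaps)
  if (count_gap_runs_as_one) {
    events <- aln$n_ins_runs + aln$n_del_runs
    denom <- aln$n_match + aln$n_sub + events
    num <- aln$n_sub + events
  } else {
    denom <- aln$n_match + aln$n_sub + aln$n_ins + aln$n_del
    num <- aln$n_sub + aln$n_ins + aln$n_del
  }
  if (denom == 0) return(0)
  num / denom
}

#' All-pairs distance matrix
#'
#' @param seqs Character vector of sequences (names become matrix ids).
#' @param ids Optional ids (default names or `seq_1..n`).
#' @param ... Passed to [pairwise_distance()].
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs, ids = NULL, ...) {
  n <- length(seqs)
  if (is.null(ids)) ids <- names(seqs) %||% paste0("seq_", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pairwise_distance(seqs[[i]], seqs[[j]], ...)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

#' Average-neighbor OTU clustering
#'
#' Agglomerative clustering in which the distance between two clusters is the
#' unweighted arithmetic mean of all cross-pair distances (UPGMA); merging
#' proceeds while the minimum inter-cluster distance is at most `cutoff`, and
#' the partition at the cutoff is returned. Computed via
#' [stats::hclust()]`(method = "average")` cut at height `cutoff`.
#'
#' @param dm Symmetric distance matrix (see [distance_matrix()]).
#' @param cutoff Distance cutoff defining OTUs (default 0.03).
#' @param abundances Optional per-sequence abundances (default 1 each) used
#'   for the OTU abundance table.
#' @return A `ccs_otus` object with `assignment` (tibble `id`, `otu`),
#'   `otu_abundances` (tibble `otu`, `abundance`), `n_otus` and `cutoff`.
#' @export
average_neighbor <- function(dm, cutoff = 0.03, abundances = NULL) {
  ids <- rownames(dm) %||% paste0("seq_", seq_len(nrow(dm)))
  n <- nrow(dm)
  if (is.null(abundances)) abundances <- rep(1L, n)
  if (n == 1) {
    memb <- setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(dm), method = "average")
    memb <- stats::cutree(hc, h = cutoff)
    names(memb) <- ids
  }
  otu_label <- sprintf("Otu%03d", memb)
  assignment <- tibble(id = ids, otu = otu_label)
  otu_abundances <- tibble(otu = otu_label, abundance = abundances) |>
    dplyr::summarise(abundance = sum(.data$abundance), .by = "otu") |>
    dplyr::arrange(dplyr::desc(.data$abundance), .data$otu)
  structure(list(cutoff = cutoff, assignment = assignment,
                 otu_abundances = otu_abundances,
                 n_otus = length(unique(memb))),
            class = "ccs_otus")
}

#' @export
print.ccs_otus <- function(x, ...) {
  cat("Average-neighbor clustering at", x$cutoff, "cutoff:", x$n_otus,
      "OTUs from", nrow(x$assignment), "sequences\n")
  invisible(x)
}

#' @export
tidy.ccs_otus <- function(x, ...) x$assignment

#' @export
glance.ccs_otus <- function(x, ...) {
  tibble(cutoff = x$cutoff, n_sequences = nrow(x$assignment),
         n_otus = x$n_otus)
}

#' Expected OTU richness under rarefaction
#'
#' The expected number of OTUs observed in a random subsample of `depth`
#' sequences drawn without replacement, by the closed form
#' `sum_i 1 - choose(N - n_i, depth) / choose(N, depth)` (computed on the log
#' scale). A seeded Monte-Carlo mode is available as a cross-check.
#'
#' @param otu_abundances Integer abundances per OTU.
#' @param depth Subsampling depth (default 1000). Must not exceed the total
#'   abundance (samples below the depth are reported as not determined).
#' @param method `"exact"` closed form (default) or `"montecarlo"`.
#' @param n_rep Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo mode.
#' @return Expected OTU count.
#' @export
rarefied_otu_count <- function(otu_abundances, depth = 1000L,
                               method = c("exact", "montecarlo"),
                               n_rep = 1000L, seed = NULL) {
  method <- match.arg(method)
  ab <- as.numeric(otu_abundances)
  stopifnot(all(ab > 0))
  N <- sum(ab)
  if (depth > N) {
    stop("rarefaction depth (", depth, ") exceeds total abundance (", N,
         "); not determined", call. = FALSE)
  }
  if (method == "exact") {
    miss <- exp(lchoose(N - ab, depth) - lchoose(N, depth))
    return(sum(1 - miss))
  }
  draw <- function() {
    pool <- rep.int(seq_along(ab), ab)
    length(unique(sample(pool, depth)))
  }
  run <- function() mean(vapply(seq_len(n_rep), function(i) draw(), numeric(1)))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
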