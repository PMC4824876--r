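# Abundance-sorted pre-clustering: absorb rare error variants into abundant
# near-identical sequences.

#' Length-scaled pre-clustering threshold
#'
#' The recommended mismatch threshold is one nucleotide difference per 100 nt
#' of sequence, truncated: `floor(length * rate / 100)`. A 250-nt fragment
#' therefore gets a threshold of 2 nt and a 1,458-nt fragment 14 nt.
#'
#' @param length Fragment length in nt.
#' @param rate Differences allowed per 100 nt (default 1).
#' @return Integer threshold.
#' @export
precluster_threshold <- function(length, rate = 1) {
  stopifnot(all(length >= 0), rate >= 0)
  as.integer(floor(length * rate / 100))
}

#' Pre-cluster a count table
#'
#' Sequences are processed in decreasing order of abundance (ties broken
#' lexicographically by sequence). Each sequence is compared against the
#' already-retained, more abundant sequences in retained order and merged into
#' the first one whose pairwise alignment difference count
#' (`n_sub + n_ins + n_del`) is at most `threshold`; its abundance (and any
#' per-sample counts) is added to that representative. Sequences that match no
#' retained representative are themselves retained. Total abundance is
#' conserved exactly.
#'
#' @param tab Count table (see [as_count_table()]).
#' @param threshold Mismatch threshold; when `NULL`, derived from the median
#'   sequence length via [precluster_threshold()] at `rate`.
#' @param rate Differences per 100 nt used for the derived threshold.
#' @param merge `"first"` (the described greedy pass, default) or
#'   `"closest"` (merge into the retained sequence at minimal distance).
#' @param band Optional alignment band (see [align_pair()]).
#' @return The pre-clustered count table, ordered by decreasing abundance,
#'   with an `n_merged` column and a `"map"` attribute giving the
#'   sequence-to-representative assignment.
#' @export
precluster <- function(tab, threshold = NULL, rate = 1,
                       merge = c("first", "closest"), band = NULL) {
  merge <- match.arg(merge)
  if (nrow(tab) == 0) return(tab)
  if (is.null(threshold)) {
    threshold <- precluster_threshold(stats::median(nchar(tab$sequence)), rate)
  }
  ord <- order(-tab$abundance, tab$sequence)
  tab <- tab[ord, , drop = FALSE]
  count_cols <- names(tab)[vapply(tab, is.numeric, logical(1))]
  n <- nrow(tab)
  retained <- integer(0)            # row indices of representatives
  rep_of <- integer(n)              # representative row for each input row
  lens <- nchar(tab$sequence)
  for (i in seq_len(n)) {
    target <- NA_integer_
    best_d <- Inf
    for (r in retained) {
      if (abs(lens[r] - lens[i]) > threshold) next
      d <- count_diffs(tab$sequence[i], tab$sequence[r], band = band)
      if (d <= threshold) {
        if (merge == "first") { target <- r; break }
        if (d < best_d) { best_d <- d; target <- r }
      }
    }
    if (is.na(target)) {
      retained <- c(retained, i)
      rep_of[i] <- i
    } else {
      rep_of[i] <- target
    }
  }
  out <- tab[retained, , drop = FALSE]
  for (col in count_cols) {
    out[[col]] <- vapply(retained, function(r) {
      sum(tab[[col]][rep_of == r])
    }, numeric(1))
  }
  out$abundance <- as.integer(out$abundance)
  out$n_merged <- vapply(retained, function(r) sum(rep_of == r), integer(1))
  out <- dplyr::arrange(out, dplyr::desc(.data$abundance), .data$sequence)
  attr(out, "map") <- tibble(sequence = tab$sequence,
                             representative = tab$sequence[rep_of])
  out
}
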