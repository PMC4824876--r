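# Demultiplexing, orientation, trimming and the error-correlated filters.

# 4-bit masks for IUPAC codes; two codes match when their masks intersect.
iupac_mask_table <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(map, function(s) {
    sum(bit[strsplit(s, "", fixed = TRUE)[[1]]])
  }, integer(1))
}

.mask_env <- new.env(parent = emptyenv())

seq_to_mask <- function(x) {
  if (is.null(.mask_env$tab)) .mask_env$tab <- iupac_mask_table()
  tab <- .mask_env$tab
  m <- tab[strsplit(toupper(x), "", fixed = TRUE)[[1]]]
  m[is.na(m)] <- 0L
  unname(m)
}

mask_mismatches <- function(mask_a, mask_b) {
  sum(bitwAnd(mask_a, mask_b) == 0L)
}

#' Longest homopolymer run
#'
#' Length of the longest run of one identical character; reads whose longest
#' run exceeds eight bases are removed by the basic screen.
#'
#' @param bases Character vector of sequences.
#' @return Integer vector of run lengths (0 for empty strings).
#' @export
max_homopolymer <- function(bases) {
  vapply(bases, function(s) {
    if (is.na(s) || nchar(s) == 0) return(0L)
    max(rle(strsplit(s, "", fixed = TRUE)[[1]])$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

#' Predicted error rate from per-base qualities
#'
#' Fallback per-read error estimate when the base caller's own prediction is
#' absent: the mean over bases of `10^(-Q/10)`, with quality-0 (ambiguous)
#' positions assigned an error probability of 0.75.
#'
#' @param quals An integer vector of qualities, or a list of them.
#' @return Numeric error fraction(s).
#' @export
predicted_error_from_quals <- function(quals) {
  one <- function(q) {
    if (length(q) == 0) stop("empty quality vector", call. = FALSE)
    if (any(q < 0 | q > 93)) stop("quality outside [0, 93]", call. = FALSE)
    p <- 10^(-q / 10)
    p[q == 0] <- 0.75
    mean(p)
  }
  if (is.list(quals)) vapply(quals, one, numeric(1)) else one(quals)
}

# Best placement of barcode+primer at the 5' end of `s` within `max_shift`
# leading positions. Barcodes are compared exactly (A/C/G/T alphabet); primers
# are IUPAC-aware. Returns mismatch counts and the first insert position.
best_end_match <- function(s_chars, s_masks, barcode, primer_masks, max_shift,
                           from_end = FALSE) {
  lb <- nchar(barcode)
  lp <- length(primer_masks)
  L <- length(s_chars)
  bc_chars <- strsplit(toupper(barcode), "", fixed = TRUE)[[1]]
  best <- list(total = Inf, bc = NA_integer_, primer = NA_integer_,
               insert_at = NA_integer_)
  for (shift in 0:max_shift) {
    if (from_end) {
      bc_idx <- (L - shift - lb + 1):(L - shift)
      pr_idx <- (L - shift - lb - lp + 1):(L - shift - lb)
      if (L - shift - lb - lp + 1 < 1) next
    } else {
      bc_idx <- (shift + 1):(shift + lb)
      pr_idx <- (shift + lb + 1):(shift + lb + lp)
      if (shift + lb + lp > L) next
    }
    mm_bc <- sum(s_chars[bc_idx] != bc_chars)
    mm_pr <- mask_mismatches(primer_masks, s_masks[pr_idx])
    if (mm_bc + mm_pr < best$total) {
      best <- list(
        total = mm_bc + mm_pr, bc = mm_bc, primer = mm_pr,
        insert_at = if (from_end) L - shift - lb - lp else shift + lb + lp + 1L
      )
    }
  }
  best
}

find_and_trim_one <- function(bases, quals, barcodes, region, max_shift,
                              max_bc_mismatch, max_primer_mismatch) {
  fwd_primer_masks <- seq_to_mask(region$fwd_primer)
  rev_primer_rc_masks <- seq_to_mask(revcomp(region$rev_primer))
  orientations <- list(
    list(bases = bases, quals = quals, flipped = FALSE),
    list(bases = revcomp(bases),
         quals = if (is.null(quals)) NULL else rev(quals), flipped = TRUE)
  )
  attempts <- list()
  for (ori in orientations) {
    s_chars <- strsplit(toupper(ori$bases), "", fixed = TRUE)[[1]]
    s_masks <- seq_to_mask(ori$bases)
    for (k in seq_len(nrow(barcodes))) {
      m5 <- best_end_match(s_chars, s_masks, barcodes$fwd_barcode[k],
                           fwd_primer_masks, max_shift, from_end = FALSE)
      m3 <- best_end_match(s_chars, s_masks, revcomp(barcodes$rev_barcode[k]),
                           rev_primer_rc_masks, max_shift, from_end = TRUE)
      att <- list(
        sample = barcodes$sample[k], flipped = ori$flipped,
        bases = ori$bases, quals = ori$quals,
        total = m5$total + m3$total,
        bc_mismatches = max(m5$bc, m3$bc),
        primer_mismatches = max(m5$primer, m3$primer),
        from = m5$insert_at, to = m3$insert_at
      )
      attempts <- c(attempts, list(att))
    }
    # accept the best barcode in this orientation if it passes the thresholds
    totals <- vapply(attempts, function(x) x$total, numeric(1))
    flip_here <- vapply(attempts, function(x) x$flipped, logical(1))
    here <- which(flip_here == ori$flipped)
    if (length(here) > 0) {
      cand <- attempts[[here[which.min(totals[here])]]]
      ok <- is.finite(cand$total) &&
        !is.na(cand$from) && !is.na(cand$to) && cand$from <= cand$to &&
        cand$bc_mismatches <= max_bc_mismatch &&
        cand$primer_mismatches <= max_primer_mismatch
      if (ok) {
        ins <- substr(cand$bases, cand$from, cand$to)
        q <- if (is.null(cand$quals)) NULL else cand$quals[cand$from:cand$to]
        return(list(bases = ins, quals = q, sample = cand$sample,
                    bc_mismatches = cand$bc_mismatches,
                    primer_mismatches = cand$primer_mismatches,
                    orientation_flipped = cand$flipped))
      }
    }
  }
  # unassigned: report the best-scoring attempt, sequence untrimmed
  totals <- vapply(attempts, function(x) x$total, numeric(1))
  best <- attempts[[which.min(totals)]]
  list(bases = bases, quals = quals, sample = NA_character_,
       bc_mismatches = if (is.finite(best$total)) best$bc_mismatches else NA_integer_,
       primer_mismatches = if (is.finite(best$total)) best$primer_mismatches else NA_integer_,
       orientation_flipped = FALSE)
}

#' Demultiplex, orient and trim reads
#'
#' Searches each read for `fwd_barcode + fwd_primer` at the 5' end and the
#' reverse complement of `rev_primer + rev_barcode` at the 3' end, each within
#' `max_shift` leading/trailing positions, minimising mismatches (exact
#' comparison for barcodes, IUPAC-aware for the degenerate primers). If no
#' barcode pair passes the mismatch thresholds in the given orientation the
#' reverse complement of the read is tried and `orientation_flipped` is set.
#' Reads failing both orientations are returned unassigned (`sample` is `NA`),
#' untrimmed.
#'
#' @param reads A reads tibble (see [ccs_reads()]).
#' @param barcodes Barcode tibble (`sample`, `fwd_barcode`, `rev_barcode`).
#' @param region One-row region tibble (see [region_design()]).
#' @param max_shift Leading/trailing window searched for the barcode (default 2).
#' @param max_bc_mismatch,max_primer_mismatch Acceptance thresholds used for
#'   orientation and sample assignment; the reported counts are the maximum
#'   over the two barcodes and the two primers respectively.
#' @return A tibble of trimmed reads (insert only) with columns
#'   `bc_mismatches`, `primer_mismatches`, `orientation_flipped`, `sample`.
#' @export
find_and_trim <- function(reads, barcodes, region, max_shift = 2L,
                          max_bc_mismatch = 1L, max_primer_mismatch = 1L) {
  if (nrow(barcodes) == 0) stop("no barcodes supplied", call. = FALSE)
  res <- purrr::map(seq_len(nrow(reads)), function(i) {
    find_and_trim_one(reads$bases[[i]], reads$quals[[i]], barcodes, region,
                      max_shift, max_bc_mismatch, max_primer_mismatch)
  })
  tibble(
    id = reads$id,
    bases = vapply(res, `[[`, character(1), "bases"),
    quals = lapply(res, `[[`, "quals"),
    passes = reads$passes,
    predicted_error = reads$predicted_error,
    orientation_flipped = vapply(res, `[[`, logical(1), "orientation_flipped"),
    bc_mismatches = vapply(res, `[[`, integer(1), "bc_mismatches"),
    primer_mismatches = vapply(res, `[[`, integer(1), "primer_mismatches"),
    sample = vapply(res, `[[`, character(1), "sample")
  )
}

#' Filter configuration for the read screen
#'
#' Defaults follow the curation procedure: homopolymer runs of at most 8,
#' insert length within 10% of the region's expected insert, at most one
#' mismatch to each barcode and each primer, at least 10 sequencing passes,
#' and a predicted error rate of at most 0.01% (0.0001). Setting a threshold
#' to `NULL` disables that filter.
#'
#' @param max_homopolymer Longest allowed homopolymer run (default 8).
#' @param insert_length_window Length-two numeric `(min, max)` in nt, or
#'   `NULL` to derive `expected_insert_len * (1 +/- length_tolerance)` from
#'   the region at screening time.
#' @param length_tolerance Relative half-width of the derived length window.
#' @param max_bc_mismatch,max_primer_mismatch Mismatch thresholds (per
#'   element: each barcode and each primer).
#' @param combined_mismatch_budget Optional alternative: a single budget
#'   compared against `bc_mismatches + primer_mismatches`.
#' @param min_passes Minimum pass count (default 10).
#' @param max_predicted_error Maximum predicted error fraction (default 1e-4).
#' @return A `ccs_filter_config` list.
#' @export
filter_config <- function(max_homopolymer = 8L,
                          insert_length_window = NULL,
                          length_tolerance = 0.10,
                          max_bc_mismatch = 1L,
                          max_primer_mismatch = 1L,
                          combined_mismatch_budget = NULL,
                          min_passes = 10L,
                          max_predicted_error = 1e-4) {
  thresholds <- list(max_homopolymer = max_homopolymer,
                     insert_length_window = insert_length_window,
                     max_bc_mismatch = max_bc_mismatch,
                     max_primer_mismatch = max_primer_mismatch,
                     min_passes = min_passes,
                     max_predicted_error = max_predicted_error)
  num <- unlist(Filter(Negate(is.null), thresholds))
  if (any(num < 0)) stop("filter thresholds must be >= 0", call. = FALSE)
  structure(list(max_homopolymer = max_homopolymer,
                 insert_length_window = insert_length_window,
                 length_tolerance = length_tolerance,
                 max_bc_mismatch = max_bc_mismatch,
                 max_primer_mismatch = max_primer_mismatch,
                 combined_mismatch_budget = combined_mismatch_budget,
                 min_passes = min_passes,
                 max_predicted_error = max_predicted_error),
            class = "ccs_filter_config")
}

screen_filters <- c("homopolymer", "length", "mismatch", "coverage",
                    "predicted_error")

#' Screen reads with the basic and error-correlated filters
#'
#' A read is kept iff it passes every enabled filter: longest homopolymer run
#' at most `max_homopolymer`; insert length within the region window (the
#' stand-in for starting and ending at the expected alignment coordinates);
#' barcode and primer mismatches within their thresholds; pass count at least
#' `min_passes`; predicted error rate at most `max_predicted_error` (falling
#' back to [predicted_error_from_quals()] when no predicted error was
#' supplied). The kept set is a pure conjunction and so does not depend on
#' filter order; the per-filter attrition in the report is tallied in the
#' order homopolymer, length, mismatch, coverage, predicted error.
#'
#' @param reads A trimmed reads tibble (see [find_and_trim()]); the mismatch
#'   filter requires its `bc_mismatches`/`primer_mismatches` columns.
#' @param config A [filter_config()].
#' @param region One-row region tibble; required when the length filter is
#'   enabled with a derived window.
#' @param filters Character vector of filters to apply (default all).
#' @return The kept reads tibble, with the per-filter report attached as the
#'   `"filter_report"` attribute (see [filter_report()]).
#' @export
screen <- function(reads, config = filter_config(), region = NULL,
                   filters = screen_filters) {
  unknown <- setdiff(filters, screen_filters)
  if (length(unknown) > 0) {
    stop("unknown filter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(reads)
  pass <- list()
  if ("homopolymer" %in% filters && !is.null(config$max_homopolymer)) {
    pass$homopolymer <- max_homopolymer(reads$bases) <= config$max_homopolymer
  }
  if ("length" %in% filters) {
    win <- config$insert_length_window
    if (is.null(win)) {
      if (is.null(region)) {
        stop("length filter enabled but no window or region supplied",
             call. = FALSE)
      }
      expected <- theoretical_insert_length(region)
      win <- c(floor(expected * (1 - config$length_tolerance)),
               ceiling(expected * (1 + config$length_tolerance)))
    }
    len <- nchar(reads$bases)
    pass$length <- len >= win[1] & len <= win[2]
  }
  if ("mismatch" %in% filters && n > 0 &&
      (!is.null(config$max_bc_mismatch) || !is.null(config$combined_mismatch_budget))) {
    if (!all(c("bc_mismatches", "primer_mismatches") %in% names(reads)) ||
        anyNA(reads$bc_mismatches)) {
      stop("mismatch filter enabled but reads carry no mismatch counts",
           call. = FALSE)
    }
    if (!is.null(config$combined_mismatch_budget)) {
      pass$mismatch <- (reads$bc_mismatches + reads$primer_mismatches) <=
        config$combined_mismatch_budget
    } else {
      pass$mismatch <- reads$bc_mismatches <= config$max_bc_mismatch &
        reads$primer_mismatches <= config$max_primer_mismatch
    }
  }
  if ("coverage" %in% filters && !is.null(config$min_passes)) {
    if (n > 0 && anyNA(reads$passes)) {
      stop("coverage filter enabled but pass counts are missing", call. = FALSE)
    }
    pass$coverage <- reads$passes >= config$min_passes
  }
  if ("predicted_error" %in% filters && !is.null(config$max_predicted_error)) {
    pe <- reads$predicted_error
    if (n > 0 && anyNA(pe)) {
      has_q <- vapply(reads$quals, Negate(is.null), logical(1))
      if (all(has_q[is.na(pe)])) {
        pe[is.na(pe)] <- predicted_error_from_quals(reads$quals[is.na(pe)])
      } else {
        stop("predicted_error filter enabled but predicted errors and ",
             "qualities are both missing", call. = FALSE)
      }
    }
    pass$predicted_error <- pe <= config$max_predicted_error
  }
  keep <- rep(TRUE, n)
  report <- tibble(filter = character(), evaluated = integer(),
                   failed = integer())
  for (f in intersect(screen_filters, names(pass))) {
    evaluated <- sum(keep)
    failed <- sum(keep & !pass[[f]])
    keep <- keep & pass[[f]]
    report <- dplyr::bind_rows(report,
                               tibble(filter = f, evaluated = evaluated,
                                      failed = failed))
  }
  kept <- reads[keep, , drop = FALSE]
  attr(kept, "filter_report") <- structure(
    report,
    input = n, retained = sum(keep),
    fraction_retained = if (n > 0) sum(keep) / n else NA_real_,
    class = c("ccs_filter_report", class(report))
  )
  kept
}

#' Per-filter attrition report of a screened read set
#'
#' @param x The tibble returned by [screen()].
#' @return A tibble with one row per applied filter (`filter`, `evaluated`,
#'   `failed`) carrying `input`, `retained` and `fraction_retained`
#'   attributes.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report")
}

#' @export
glance.ccs_filter_report <- function(x, ...) {
  tibble(input = attr(x, "input"), retained = attr(x, "retained"),
         fraction_retained = attr(x, "fraction_retained"))
}
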