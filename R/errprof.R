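# Measuring true error rates against known references, error-type spectra,
# reference-based (in silico) chimeras, and the 1-nt variant spectrum.

as_ref_tibble <- function(refs) {
  if (inherits(refs, "DNAStringSet")) {
    return(tibble(id = names(refs), bases = as.character(refs)))
  }
  if (is.character(refs)) {
    ids <- names(refs)
    if (is.null(ids)) ids <- paste0("ref_", seq_along(refs))
    return(tibble(id = ids, bases = unname(refs)))
  }
  refs <- as_tibble(refs)
  if (!"bases" %in% names(refs) && "sequence" %in% names(refs)) {
    refs <- dplyr::rename(refs, bases = "sequence")
  }
  refs
}

as_read_tibble <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
    return(tibble(id = ids, bases = unname(reads), quals = rep(list(NULL), length(reads))))
  }
  as_tibble(reads)
}

#' Align each read to its best-matching reference
#'
#' Every read is globally aligned (free terminal gaps, terminal columns
#' excluded from counts) against every reference; the reference minimising the
#' difference count `n_sub + n_ins + n_del` wins, with ties broken by the
#' first reference in input order. The per-read error rate is
#' `(n_sub + n_ins + n_del) / (n_match + n_sub + n_ins + n_del)`.
#'
#' @param reads Reads tibble or character vector.
#' @param refs Reference sequences (tibble, named character, or DNAStringSet).
#' @param band Optional alignment band half-width (see [align_pair()]).
#' @return A tibble with columns `read_id`, `best_ref`, `aligned_read`,
#'   `aligned_ref`, `n_match`, `n_sub`, `n_ins`, `n_del`, `error_rate`.
#' @export
align_to_best_reference <- function(reads, refs, band = NULL) {
  reads <- as_read_tibble(reads)
  refs <- as_ref_tibble(refs)
  if (nrow(refs) == 0) stop("no references supplied", call. = FALSE)
  rows <- purrr::map(seq_len(nrow(reads)), function(i) {
    best <- NULL
    best_d <- Inf
    for (k in seq_len(nrow(refs))) {
      aln <- align_pair(reads$bases[[i]], refs$bases[[k]], band = band)
      d <- aln$n_sub + aln$n_ins + aln$n_del
      if (d < best_d) {
        best_d <- d
        best <- list(ref = refs$id[[k]], aln = aln)
      }
    }
    a <- best$aln
    denom <- a$n_match + a$n_sub + a$n_ins + a$n_del
    tibble(read_id = reads$id[[i]], best_ref = best$ref,
           aligned_read = a$aligned_read %||% a$aligned_a,
           aligned_ref = a$aligned_ref %||% a$aligned_b,
           n_match = a$n_match, n_sub = a$n_sub, n_ins = a$n_ins,
           n_del = a$n_del,
           error_rate = if (denom > 0) (a$n_sub + a$n_ins + a$n_del) / denom else 0)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ccs_alignments", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# walk one alignment; returns per-column classification restricted to
# non-terminal columns: type in {match, sub, ins, del}, ref base, read base,
# read position (NA for deletions), ref position (position of the preceding
# ref base for insertions)
alignment_columns <- function(aligned_read, aligned_ref) {
  a <- strsplit(aligned_read, "", fixed = TRUE)[[1]]
  b <- strsplit(aligned_ref, "", fixed = TRUE)[[1]]
  n <- length(a)
  from <- 1L
  while (from <= n && (a[from] == "-" || b[from] == "-")) from <- from + 1L
  to <- n
  while (to >= from && (a[to] == "-" || b[to] == "-")) to <- to - 1L
  read_pos <- cumsum(a != "-")
  ref_pos <- cumsum(b != "-")
  if (from > to) {
    return(tibble(type = character(), ref_base = character(),
                  read_base = character(), read_pos = integer(),
                  ref_pos = integer()))
  }
  idx <- from:to
  type <- ifelse(a[idx] == "-", "del",
                 ifelse(b[idx] == "-", "ins",
                        ifelse(a[idx] == b[idx], "match", "sub")))
  tibble(type = type,
         ref_base = b[idx],
         read_base = a[idx],
         read_pos = ifelse(a[idx] == "-", NA_integer_, read_pos[idx]),
         ref_pos = ref_pos[idx])
}

#' Tally an error profile from read-vs-reference alignments
#'
#' Aggregates, over a set of alignments, the counts of substitutions,
#' insertions and deletions, the error-type fractions, the substitution matrix
#' (reference base by read base, zero diagonal), the base composition of
#' inserted and deleted bases, and, when qualities are available, the fraction
#' of positions holding the maximum quality value among correct calls,
#' substitutions and insertions.
#'
#' @param alignments Output of [align_to_best_reference()].
#' @param reads Optional reads tibble supplying `quals` (matched by id) for
#'   the quality cross-tabulation.
#' @param max_quality The maximum quality value (default 93).
#' @return A `ccs_error_profile` object; see also [tidy()] and [glance()]
#'   methods.
#' @export
tally_errors <- function(alignments, reads = NULL, max_quality = 93L) {
  bases4 <- c("A", "C", "G", "T")
  sub_mat <- matrix(0L, 4, 4, dimnames = list(ref = bases4, read = bases4))
  ins_counts <- setNames(rep(0L, 4), bases4)
  del_counts <- setNames(rep(0L, 4), bases4)
  totals <- c(sub = 0L, ins = 0L, del = 0L)
  n_positions <- 0L
  qual_tab <- list(correct = c(max = 0L, n = 0L),
                   substitution = c(max = 0L, n = 0L),
                   insertion = c(max = 0L, n = 0L))
  quals_by_id <- NULL
  if (!is.null(reads)) {
    quals_by_id <- setNames(reads$quals, reads$id)
  }
  for (i in seq_len(nrow(alignments))) {
    cols <- alignment_columns(alignments$aligned_read[[i]],
                              alignments$aligned_ref[[i]])
    n_positions <- n_positions + nrow(cols)
    totals["sub"] <- totals["sub"] + sum(cols$type == "sub")
    totals["ins"] <- totals["ins"] + sum(cols$type == "ins")
    totals["del"] <- totals["del"] + sum(cols$type == "del")
    sub_rows <- cols[cols$type == "sub" & cols$ref_base %in% bases4 &
                       cols$read_base %in% bases4, ]
    if (nrow(sub_rows) > 0) {
      tb <- table(factor(sub_rows$ref_base, bases4),
                  factor(sub_rows$read_base, bases4))
      sub_mat <- sub_mat + unclass(tb)
    }
    ib <- cols$read_base[cols$type == "ins" & cols$read_base %in% bases4]
    if (length(ib) > 0) {
      ins_counts <- ins_counts + table(factor(ib, bases4))
    }
    db <- cols$ref_base[cols$type == "del" & cols$ref_base %in% bases4]
    if (length(db) > 0) {
      del_counts <- del_counts + table(factor(db, bases4))
    }
    if (!is.null(quals_by_id)) {
      q <- quals_by_id[[alignments$read_id[[i]]]]
      if (!is.null(q)) {
        for (cls in c("match", "sub", "ins")) {
          pos <- cols$read_pos[cols$type == cls]
          if (length(pos) > 0) {
            key <- c(match = "correct", sub = "substitution",
                     ins = "insertion")[[cls]]
            qual_tab[[key]]["n"] <- qual_tab[[key]]["n"] + length(pos)
            qual_tab[[key]]["max"] <- qual_tab[[key]]["max"] +
              sum(q[pos] == max_quality)
          }
        }
      }
    }
  }
  n_errors <- sum(totals)
  type_fractions <- if (n_errors > 0) totals / n_errors else
    setNames(rep(NA_real_, 3), names(totals))
  crosstab <- tibble(
    class = c("correct", "substitution", "insertion"),
    n = unname(vapply(qual_tab, `[[`, integer(1), "n")),
    frac_max_quality = unname(vapply(qual_tab, function(x) {
      if (x[["n"]] > 0) x[["max"]] / x[["n"]] else NA_real_
    }, numeric(1)))
  )
  structure(list(
    n_reads = nrow(alignments),
    n_positions = n_positions,
    n_errors = n_errors,
    totals = totals,
    type_fractions = type_fractions,
    error_rate = if (n_positions > 0) n_errors / n_positions else NA_real_,
    substitution_matrix = sub_mat,
    insertion_base_counts = as.integer(ins_counts) |> setNames(bases4),
    deletion_base_counts = as.integer(del_counts) |> setNames(bases4),
    deletion_base_fractions = if (sum(del_counts) > 0)
      as.numeric(del_counts / sum(del_counts)) |> setNames(bases4)
    else setNames(rep(NA_real_, 4), bases4),
    quality_crosstab = crosstab
  ), class = "ccs_error_profile")
}

#' @export
print.ccs_error_profile <- function(x, ...) {
  cat("CCS error profile:", x$n_errors, "errors over", x$n_positions,
      "aligned positions")
  if (!is.na(x$error_rate)) {
    cat(sprintf(" (error rate %.4g%%)", 100 * x$error_rate))
  }
  cat("\n")
  if (x$n_errors > 0) {
    cat(sprintf("  type mix: sub %.1f%%, ins %.1f%%, del %.1f%%\n",
                100 * x$type_fractions[["sub"]],
                100 * x$type_fractions[["ins"]],
                100 * x$type_fractions[["del"]]))
    if (!anyNA(x$deletion_base_fractions)) {
      cat("  deleted-base composition:",
          paste(sprintf("%s %.1f%%", names(x$deletion_base_fractions),
                        100 * x$deletion_base_fractions), collapse = ", "),
          "\n")
    }
  }
  invisible(x)
}

#' @export
tidy.ccs_error_profile <- function(x, ...) {
  tibble(type = c("substitution", "insertion", "deletion"),
         count = as.integer(x$totals[c("sub", "ins", "del")]),
         fraction = as.numeric(x$type_fractions[c("sub", "ins", "del")]))
}

#' @export
glance.ccs_error_profile <- function(x, ...) {
  tibble(n_reads = x$n_reads, n_positions = x$n_positions,
         n_errors = x$n_errors, error_rate = x$error_rate)
}

#' Enumerate all single-breakpoint in-silico chimeras of a reference set
#'
#' For every ordered pair of references the parents are aligned pairwise and
#' one chimera is emitted per internal breakpoint column: the left parent's
#' columns up to the breakpoint joined to the right parent's remaining
#' columns, degapped. Exact duplicate products are removed, as are products
#' identical to either parent.
#'
#' @param refs Reference set.
#' @return A tibble `id`, `parent_a`, `parent_b`, `breakpoint`, `bases`.
#' @export
enumerate_in_silico_chimeras <- function(refs) {
  refs <- as_ref_tibble(refs)
  n <- nrow(refs)
  if (n < 2) {
    return(tibble(id = character(), parent_a = character(),
                  parent_b = character(), breakpoint = integer(),
                  bases = character()))
  }
  parents <- toupper(refs$bases)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      aln <- align_pair(parents[i], parents[j], free_ends = FALSE)
      a <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
      b <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
      L <- length(a)
      for (bp in seq_len(L - 1)) {
        chim <- paste(c(a[1:bp], b[(bp + 1):L]), collapse = "")
        chim <- gsub("-", "", chim, fixed = TRUE)
        out[[length(out) + 1]] <- list(parent_a = refs$id[i],
                                       parent_b = refs$id[j],
                                       breakpoint = bp, bases = chim)
      }
    }
  }
  tab <- dplyr::bind_rows(lapply(out, as_tibble))
  tab <- tab[!(tab$bases %in% parents), , drop = FALSE]
  tab <- tab[!duplicated(tab$bases), , drop = FALSE]
  if (nrow(tab) == 0) {
    return(tibble(id = character(), parent_a = character(),
                  parent_b = character(), breakpoint = integer(),
                  bases = character()))
  }
  tab$id <- sprintf("chimera_%05d", seq_len(nrow(tab)))
  dplyr::relocate(tab, "id")
}

#' Classify reads as chimeric against enumerated in-silico chimeras
#'
#' A read is flagged as chimeric when it is `delta` or more nucleotides more
#' similar to an in-silico chimera than to any non-chimeric reference: with
#' `d_ref` the minimum alignment difference count to any reference and
#' `d_chimera` the minimum to any enumerated chimera, the read is chimeric iff
#' `d_ref - d_chimera >= delta`.
#'
#' @param reads Reads tibble or character vector.
#' @param refs Reference set.
#' @param chimeras Output of [enumerate_in_silico_chimeras()] (computed from
#'   `refs` when omitted).
#' @param delta Difference margin (default 3).
#' @param band Optional alignment band.
#' @return A tibble `read_id`, `d_ref`, `d_chimera`, `is_chimeric`.
#' @export
classify_chimeric <- function(reads, refs, chimeras = NULL, delta = 3L,
                              band = NULL) {
  reads <- as_read_tibble(reads)
  refs <- as_ref_tibble(refs)
  if (is.null(chimeras)) chimeras <- enumerate_in_silico_chimeras(refs)
  min_d <- function(seq, targets) {
    if (length(targets) == 0) return(Inf)
    min(vapply(targets, function(t) count_diffs(seq, t, band = band),
               numeric(1)))
  }
  purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    d_ref <- min_d(reads$bases[[i]], refs$bases)
    d_chi <- min_d(reads$bases[[i]], chimeras$bases)
    tibble(read_id = reads$id[[i]], d_ref = d_ref, d_chimera = d_chi,
           is_chimeric = is.finite(d_chi) && (d_ref - d_chi >= delta))
  })
}

#' Spectrum of 1-nt variants
#'
#' Among reads lying at exactly one alignment difference from their best
#' reference, identical error signatures (reference, position, error type,
#' base) are grouped and the occurrence counts are histogrammed over
#' `1..max_count`. Recurrent (systematic) errors show up as heavy upper bins
#' and a large most-abundant-variant count.
#'
#' @param alignments Output of [align_to_best_reference()].
#' @param max_count Largest occurrence bin (default 10); variants seen more
#'   often are still reflected in `top_variant_count`.
#' @return A `ccs_variant_spectrum` object: histogram tibble (`occurrences`,
#'   `n_variants`, `fraction`), `n_variants`, `n_reads_1nt`,
#'   `top_variant_count`, `top_variant`.
#' @export
variant_spectrum <- function(alignments, max_count = 10L) {
  one_diff <- alignments[alignments$n_sub + alignments$n_ins +
                           alignments$n_del == 1L, , drop = FALSE]
  sig <- vapply(seq_len(nrow(one_diff)), function(i) {
    cols <- alignment_columns(one_diff$aligned_read[[i]],
                              one_diff$aligned_ref[[i]])
    e <- cols[cols$type != "match", ][1, ]
    base <- if (e$type == "del") e$ref_base else e$read_base
    paste(one_diff$best_ref[[i]], e$type, e$ref_pos, base, sep = ":")
  }, character(1))
  counts <- sort(table(sig), decreasing = TRUE)
  occ <- as.integer(counts)
  hist <- tibble(occurrences = seq_len(max_count),
                 n_variants = vapply(seq_len(max_count),
                                     function(k) sum(occ == k), integer(1)))
  hist$fraction <- if (length(occ) > 0) hist$n_variants / length(occ) else
    rep(NA_real_, nrow(hist))
  structure(list(
    histogram = hist,
    n_variants = length(occ),
    n_reads_1nt = nrow(one_diff),
    top_variant_count = if (length(occ) > 0) occ[1] else 0L,
    top_variant = if (length(occ) > 0) names(counts)[1] else NA_character_
  ), class = "ccs_variant_spectrum")
}

#' @export
tidy.ccs_variant_spectrum <- function(x, ...) x$histogram

#' @export
glance.ccs_variant_spectrum <- function(x, ...) {
  tibble(n_variants = x$n_variants, n_reads_1nt = x$n_reads_1nt,
         top_variant_count = x$top_variant_count)
}

#' Binomial error-distribution utilities
#'
#' Under a binomial model of independent per-base errors at rate `p` along a
#' fragment of `n` nt, `expected_error_free_fraction()` returns the chance a
#' read has no errors, `(1 - p)^n`, and `prob_at_least_k_errors()` the chance
#' of `k` or more errors.
#'
#' @param p Per-base error fraction.
#' @param n Fragment length in nt.
#' @param k Error count.
#' @return A probability.
#' @export
expected_error_free_fraction <- function(p, n) {
  stopifnot(p >= 0, p <= 1, n >= 0)
  (1 - p)^n
}

#' @rdname expected_error_free_fraction
#' @export
prob_at_least_k_errors <- function(p, n, k) {
  stopifnot(p >= 0, p <= 1, n >= 0, k >= 0)
  pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}
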