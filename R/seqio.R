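#' Construct a tibble of consensus reads
#'
#' The package represents consensus (CCS) reads as a tibble with one row per
#' read: `id`, `bases` (IUPAC string), `quals` (list column of integer Phred
#' values, one per base, or `NULL`), `passes` (number of sequencing passes the
#' consensus was built from), `predicted_error` (per-read error-rate estimate
#' from the base caller) and `orientation_flipped`.
#'
#' @param id Character vector of read identifiers.
#' @param bases Character vector of sequences.
#' @param quals Optional list of integer vectors (one per read) in `[0, 93]`.
#' @param passes Optional integer vector of pass counts.
#' @param predicted_error Optional numeric vector of predicted error fractions.
#' @return A tibble of reads.
#' @export
ccs_reads <- function(id, bases, quals = NULL, passes = NA_integer_,
                      predicted_error = NA_real_) {
  n <- length(bases)
  if (length(id) != n) stop("`id` and `bases` lengths differ", call. = FALSE)
  if (is.null(quals)) {
    quals <- rep(list(NULL), n)
  } else {
    ok <- vapply(seq_len(n), function(i) {
      is.null(quals[[i]]) || length(quals[[i]]) == nchar(bases[[i]])
    }, logical(1))
    if (!all(ok)) {
      stop("record ", which(!ok)[1], ": bases and quals lengths differ",
           call. = FALSE)
    }
  }
  tibble(
    id = as.character(id),
    bases = toupper(as.character(bases)),
    quals = quals,
    passes = rep_len(as.integer(passes), n),
    predicted_error = rep_len(as.numeric(predicted_error), n),
    orientation_flipped = FALSE
  )
}

parse_read_header <- function(x) {
  np <- suppressWarnings(as.integer(sub(".*;np=([0-9]+).*", "\\1", x)))
  np[!grepl(";np=", x)] <- NA_integer_
  pe <- suppressWarnings(as.numeric(sub(".*;pe=([0-9.eE+-]+).*", "\\1", x)))
  pe[!grepl(";pe=", x)] <- NA_real_
  id <- sub(";np=.*$", "", x)
  id <- sub(";pe=.*$", "", id)
  list(id = id, passes = np, predicted_error = pe)
}

format_read_header <- function(id, passes, predicted_error) {
  out <- id
  has_np <- !is.na(passes)
  out[has_np] <- paste0(out[has_np], ";np=", passes[has_np])
  has_pe <- !is.na(predicted_error)
  out[has_pe] <- paste0(out[has_pe], ";pe=",
                        sprintf("%.10g", predicted_error[has_pe]))
  out
}

#' Read a FASTQ file of consensus reads
#'
#' Parses FASTQ (Phred+`offset` encoding). In `pacbio_mode` a quality score of
#' zero is the base caller's sentinel for an ambiguous call, so every base with
#' quality 0 is rewritten to `N`; quality values outside `[0, 93]` are
#' rejected. Pass counts and predicted error rates are taken from the header
#' dialect `@id;np=<int>;pe=<float>` or, preferentially, from a sidecar
#' tab-delimited table `read_id<TAB>passes<TAB>predicted_error`.
#'
#' @param path FASTQ file.
#' @param pacbio_mode Apply the quality-zero-to-N convention (default `TRUE`).
#' @param offset Quality encoding offset (default 33).
#' @param metadata Optional path to a sidecar metadata table.
#' @return A reads tibble (see [ccs_reads()]).
#' @export
read_fastq <- function(path, pacbio_mode = TRUE, offset = 33L,
                       metadata = NULL) {
  if (file.size(path) == 0) return(ccs_reads(character(), character()))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  bases <- as.character(x)
  qstr <- as.character(S4Vectors::mcols(x)$qualities)
  quals <- lapply(qstr, function(q) as.integer(charToRaw(q)) - as.integer(offset))
  bad <- which(vapply(quals, function(q) any(q < 0L | q > 93L), logical(1)))
  if (length(bad) > 0) {
    stop("record ", bad[1], ": quality value outside [0, 93] at offset ",
         offset, call. = FALSE)
  }
  if (pacbio_mode) {
    for (i in seq_along(bases)) {
      z <- which(quals[[i]] == 0L)
      if (length(z) > 0) {
        bs <- strsplit(bases[[i]], "", fixed = TRUE)[[1]]
        bs[z] <- "N"
        bases[[i]] <- paste(bs, collapse = "")
      }
    }
  }
  hdr <- parse_read_header(names(x))
  out <- ccs_reads(hdr$id, bases, quals, hdr$passes, hdr$predicted_error)
  if (!is.null(metadata)) {
    meta <- read.delim(metadata, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    m <- match(out$id, meta$read_id)
    hit <- !is.na(m)
    out$passes[hit] <- as.integer(meta$passes[m[hit]])
    out$predicted_error[hit] <- as.numeric(meta$predicted_error[m[hit]])
  }
  out
}

#' Write reads to FASTA or FASTQ
#'
#' Pass counts and predicted errors are carried in the header dialect
#' `id;np=<int>;pe=<float>` so that [read_fastq()] round-trips them. In
#' `pacbio_mode`, `N` bases are written with quality 0 (the inverse of the
#' parsing rule).
#'
#' @param records A reads tibble.
#' @param path Output file.
#' @param format `"fasta"` or `"fastq"`.
#' @param offset Quality encoding offset (default 33).
#' @param pacbio_mode Write `N` bases with quality 0 (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("fasta", "fastq"),
                          offset = 33L, pacbio_mode = TRUE) {
  format <- match.arg(format)
  nm <- format_read_header(records$id, records$passes, records$predicted_error)
  dna <- Biostrings::DNAStringSet(if (nrow(records) > 0) records$bases else character())
  names(dna) <- nm
  if (format == "fasta") {
    Biostrings::writeXStringSet(dna, path, format = "fasta")
    return(invisible(path))
  }
  has_q <- vapply(records$quals, function(q) !is.null(q), logical(1))
  if (nrow(records) > 0 && !all(has_q)) {
    stop("fastq output requested but record ", which(!has_q)[1],
         " has no quality values", call. = FALSE)
  }
  qstr <- vapply(seq_len(nrow(records)), function(i) {
    q <- as.integer(records$quals[[i]])
    if (pacbio_mode) {
      bs <- strsplit(records$bases[[i]], "", fixed = TRUE)[[1]]
      q[bs == "N"] <- 0L
    }
    rawToChar(as.raw(q + as.integer(offset)))
  }, character(1))
  quals <- Biostrings::BStringSet(qstr)
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return A tibble with columns `id` and `bases`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  tibble(id = sub("\\s.*$", "", names(x)), bases = as.character(x))
}

#' Write sequences to FASTA
#'
#' @param x A tibble with `id` and `bases` columns, or a named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- tibble(id = names(x), bases = unname(x))
  dna <- Biostrings::DNAStringSet(x$bases)
  names(dna) <- x$id
  Biostrings::writeXStringSet(dna, path, format = "fasta")
  invisible(path)
}

#' Dereplicate sequences into a count table
#'
#' Collapses identical sequences into one row with a total abundance and, when
#' a `sample` column is present, per-sample abundances. Rows are ordered by
#' decreasing abundance with ties broken lexicographically by sequence, the
#' processing order used by [precluster()].
#'
#' @param x A reads tibble (uses `bases`), a character vector of sequences, or
#'   a data frame with columns `sequence`/`bases` and optionally `sample`.
#' @return A tibble with columns `sequence` and `abundance` (plus one column
#'   per sample when sample information is present).
#' @export
as_count_table <- function(x) {
  if (is.character(x)) x <- tibble(sequence = x)
  x <- as_tibble(x)
  if (!"sequence" %in% names(x) && "bases" %in% names(x)) {
    x <- dplyr::rename(x, sequence = "bases")
  }
  if (!"sequence" %in% names(x)) stop("no sequence column found", call. = FALSE)
  if ("sample" %in% names(x)) {
    wide <- x |>
      dplyr::count(.data$sequence, .data$sample) |>
      tidyr::pivot_wider(names_from = "sample", values_from = "n",
                         values_fill = 0L)
    wide$abundance <- as.integer(rowSums(wide[, -1, drop = FALSE]))
    out <- dplyr::relocate(wide, "abundance", .after = "sequence")
  } else {
    out <- dplyr::count(x, .data$sequence, name = "abundance")
  }
  dplyr::arrange(out, dplyr::desc(.data$abundance), .data$sequence)
}

#' Read/write a count table
#'
#' Tab-delimited with a header: `sequence`, `abundance`, then optional
#' per-sample columns.
#'
#' @param path File path.
#' @rdname count_table_io
#' @export
read_count_table <- function(path) {
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @param tab A count table tibble.
#' @rdname count_table_io
#' @export
write_count_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
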