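#' Amplified 16S rRNA regions shipped with the package
#'
#' The six primer pairs used to amplify sub-regions of the 16S rRNA gene (V4,
#' V1-V3, V3-V5, V1-V5, V1-V6, V1-V9). Coordinates are 1-based inclusive
#' positions on the *E. coli* 16S reference; `amplicon_length` is the insert
#' between (excluding) the primers, and satisfies
#' `ref_end - ref_start + 1 - nchar(fwd_primer) - nchar(rev_primer)` for every
#' row.
#'
#' @return A tibble with one row per region: `region`, `fwd_primer`,
#'   `rev_primer`, `ref_start`, `ref_end`, `amplicon_length`.
#' @export
ccs_regions <- function() {
  path <- system.file("extdata", "regions.tsv", package = "ccs16s")
  load_region_table(path)
}

#' Load a region/primer table
#'
#' Tab-delimited with the columns of [ccs_regions()]. Every row is checked
#' against the coordinate identity
#' `amplicon_length == ref_end - ref_start + 1 - nchar(fwd) - nchar(rev)`.
#'
#' @param path Tab-delimited region table.
#' @return A tibble of regions.
#' @export
load_region_table <- function(path) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  out <- as_tibble(raw)
  if (nrow(out) == 0) return(out)
  expect <- out$ref_end - out$ref_start + 1L -
    nchar(out$fwd_primer) - nchar(out$rev_primer)
  bad <- which(expect != out$amplicon_length)
  if (length(bad) > 0) {
    stop("region table row ", bad[1], " (", out$region[bad[1]],
         "): amplicon_length ", out$amplicon_length[bad[1]],
         " does not equal span minus primer lengths (", expect[bad[1]], ")",
         call. = FALSE)
  }
  out
}

#' Fetch one region design by name
#'
#' @param name Region name, e.g. `"V4"` or `"V1-V9"` (en-dashes accepted).
#' @param regions Region table (defaults to the packaged six regions).
#' @return A one-row tibble.
#' @export
region_design <- function(name, regions = ccs_regions()) {
  norm <- function(x) gsub("–", "-", x)
  hit <- which(norm(regions$region) == norm(name))
  if (length(hit) != 1) {
    stop("unknown region '", name, "'; available: ",
         paste(regions$region, collapse = ", "), call. = FALSE)
  }
  regions[hit, ]
}

#' Theoretical insert length of a region
#'
#' The length of the amplified insert between (excluding) the primers:
#' `ref_end - ref_start + 1 - nchar(fwd_primer) - nchar(rev_primer)`.
#'
#' @param region A one-row region tibble (see [region_design()]).
#' @return Integer insert length in nt.
#' @export
theoretical_insert_length <- function(region) {
  len <- region$ref_end - region$ref_start + 1L -
    nchar(region$fwd_primer) - nchar(region$rev_primer)
  if (any(len < 0)) {
    stop("primers longer than the amplified span", call. = FALSE)
  }
  as.integer(len)
}

iupac_sets <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(map, function(s) strsplit(s, "", fixed = TRUE)[[1]])
}

#' Do two IUPAC nucleotide codes match?
#'
#' Two degenerate codes match when their expansion sets intersect (e.g. `M` =
#' \{A,C\} matches `A` but not `G`). Vectorised over both arguments.
#'
#' @param code_a,code_b IUPAC nucleotide codes (single characters).
#' @return Logical vector.
#' @export
iupac_match <- function(code_a, code_b) {
  sets <- iupac_sets()
  a <- toupper(code_a)
  b <- toupper(code_b)
  bad <- !(a %in% names(sets)) | !(b %in% names(sets))
  if (any(bad)) {
    stop("not an IUPAC nucleotide code: ",
         paste(unique(c(a[!(a %in% names(sets))],
                        b[!(b %in% names(sets))])), collapse = ", "),
         call. = FALSE)
  }
  mapply(function(x, y) length(intersect(sets[[x]], sets[[y]])) > 0, a, b,
         USE.NAMES = FALSE)
}

#' IUPAC-aware mismatch count between a degenerate pattern and a sequence
#'
#' Position-wise comparison of equal-length strings; a position matches when
#' the IUPAC expansion sets intersect. Used for primer matching.
#'
#' @param pattern Degenerate IUPAC string (e.g. a primer).
#' @param subject Concrete sequence of the same length.
#' @return Integer mismatch count.
#' @export
iupac_mismatches <- function(pattern, subject) {
  if (nchar(pattern) != nchar(subject)) stop("length mismatch", call. = FALSE)
  if (nchar(pattern) == 0) return(0L)
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  s <- strsplit(toupper(subject), "", fixed = TRUE)[[1]]
  sets <- iupac_sets()
  ok <- p %in% names(sets) & s %in% names(sets)
  m <- logical(length(p))
  m[ok] <- mapply(function(x, y) length(intersect(sets[[x]], sets[[y]])) > 0,
                  p[ok], s[ok], USE.NAMES = FALSE)
  sum(!m)
}

#' Load a barcode table
#'
#' Tab-delimited `sample<TAB>fwd_barcode<TAB>rev_barcode`. The library design
#' uses paired 16-nt symmetric barcodes on both ends of the amplicon.
#'
#' @param path Barcode table path.
#' @param barcode_length Required barcode length (default 16; `NULL` skips the
#'   check).
#' @return A tibble with columns `sample`, `fwd_barcode`, `rev_barcode`.
#' @export
load_barcode_table <- function(path, barcode_length = 16L) {
  out <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  if (!is.null(barcode_length) && nrow(out) > 0) {
    bad <- which(nchar(out$fwd_barcode) != barcode_length |
                   nchar(out$rev_barcode) != barcode_length)
    if (length(bad) > 0) {
      stop("barcode row ", bad[1], ": barcodes must be ", barcode_length,
           " nt", call. = FALSE)
    }
  }
  out
}

#' Reverse complement (IUPAC-aware)
#'
#' @param x Character vector of IUPAC nucleotide strings.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
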