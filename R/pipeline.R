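# One reproducible simulate -> trim -> screen -> error-profile -> precluster
# -> cluster run with a consolidated report.

#' Pipeline configuration
#'
#' Bundles every knob of a simulated end-to-end run. The defaults simulate a
#' 21-template mock community for the chosen region, curate with the default
#' [filter_config()], pre-cluster at 1 difference per 100 nt, and cluster
#' OTUs by average neighbor at a 3% cutoff with rarefaction to 1,000
#' sequences.
#'
#' @param region Region name (see [ccs_regions()]).
#' @param n_templates,divergence Mock reference parameters
#'   (see [make_mock_references()]).
#' @param abundances Optional template abundances.
#' @param n_reads Number of simulated reads.
#' @param model A [error_model()].
#' @param filter A [filter_config()].
#' @param precluster_rate Differences per 100 nt for [precluster()].
#' @param cluster_cutoff OTU distance cutoff (default 0.03).
#' @param rarefaction_depth Rarefaction depth (default 1000; samples below
#'   the depth report `NA`).
#' @param max_shift Barcode search window for [find_and_trim()].
#' @param band Alignment band half-width used throughout the run.
#' @param chimera_removal `"truth"` removes reads the truth table marks as
#'   chimeric before error assessment (perfect removal); `"none"` keeps them.
#' @param barcodes Optional barcode tibble; one synthetic sample is generated
#'   when omitted.
#' @param seed Seed controlling the whole run.
#' @return A `ccs_pipeline_config` list.
#' @export
pipeline_config <- function(region = "V4", n_templates = 21L,
                            divergence = 0.10, abundances = NULL,
                            n_reads = 2000L, model = error_model(),
                            filter = filter_config(), precluster_rate = 1,
                            cluster_cutoff = 0.03, rarefaction_depth = 1000L,
                            max_shift = 2L, band = 40L,
                            chimera_removal = c("truth", "none"),
                            barcodes = NULL, seed = 1L) {
  structure(list(region = region, n_templates = n_templates,
                 divergence = divergence, abundances = abundances,
                 n_reads = n_reads, model = model, filter = filter,
                 precluster_rate = precluster_rate,
                 cluster_cutoff = cluster_cutoff,
                 rarefaction_depth = rarefaction_depth,
                 max_shift = max_shift, band = band,
                 chimera_removal = match.arg(chimera_removal),
                 barcodes = barcodes, seed = seed),
            class = "ccs_pipeline_config")
}

random_barcodes <- function(n_samples = 1L, length = 16L) {
  bases4 <- c("A", "C", "G", "T")
  draw <- function() paste(sample(bases4, length, replace = TRUE),
                           collapse = "")
  tibble(sample = sprintf("sample_%02d", seq_len(n_samples)),
         fwd_barcode = vapply(seq_len(n_samples), function(i) draw(),
                              character(1)),
         rev_barcode = vapply(seq_len(n_samples), function(i) draw(),
                              character(1)))
}

# abundance-weighted pooled error rate over unique sequences
pooled_error_rate <- function(stats, sequences, weights) {
  m <- match(sequences, stats$sequence)
  err <- stats$n_err[m]
  denom <- stats$denom[m]
  if (sum(weights * denom) == 0) return(NA_real_)
  sum(weights * err) / sum(weights * denom)
}

#' Run the full simulated pipeline
#'
#' Simulates mock-community reads, demultiplexes/orients/trims them, removes
#' chimeras (perfectly, from the truth table), applies the basic screen
#' (homopolymer + insert length) and then the three error-correlated filters
#' (mismatches, coverage, predicted error), pre-clusters, and clusters OTUs.
#' The report carries per-stage read counts and the observed error rate after
#' the basic screen, after the predicted-error filters, and after
#' pre-clustering, measured against the known templates.
#'
#' @param config A [pipeline_config()].
#' @return A `ccs_run_report`; see [tidy()] and [glance()] methods.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  withr::with_seed(config$seed, run_pipeline_impl(config))
}

run_pipeline_impl <- function(config) {
  region <- region_design(config$region)
  insert_len <- theoretical_insert_length(region)
  refs <- make_mock_references(config$n_templates, insert_len,
                               config$divergence)
  barcodes <- config$barcodes
  if (is.null(barcodes)) barcodes <- random_barcodes(1L)
  sim <- simulate_ccs_reads(refs, config$n_reads, config$model,
                            abundances = config$abundances,
                            barcodes = barcodes, region = region)
  stages <- list()
  note_stage <- function(stage, n_in, n_out, error_rate = NA_real_) {
    tibble(stage = stage, reads_in = n_in, reads_out = n_out,
           error_rate = error_rate)
  }
  trimmed <- find_and_trim(sim$reads, barcodes, region,
                           max_shift = config$max_shift,
                           max_bc_mismatch = config$filter$max_bc_mismatch %||% 1L,
                           max_primer_mismatch = config$filter$max_primer_mismatch %||% 1L)
  assigned <- trimmed[!is.na(trimmed$sample), , drop = FALSE]
  stages$demux <- note_stage("demultiplex", nrow(sim$reads), nrow(assigned))

  is_chim <- sim$truth$is_chimera[match(assigned$id, sim$truth$read_id)]
  if (config$chimera_removal == "truth") {
    after_chim <- assigned[!is_chim, , drop = FALSE]
  } else {
    after_chim <- assigned
  }
  stages$chimera <- note_stage("chimera_removal", nrow(assigned),
                               nrow(after_chim))

  basic <- screen(after_chim, config$filter, region,
                  filters = c("homopolymer", "length"))
  # alignment stats per unique sequence, shared by the three error columns
  uniq <- unique(basic$bases)
  aln <- align_to_best_reference(uniq, refs, band = config$band)
  stats <- tibble(sequence = uniq,
                  n_err = aln$n_sub + aln$n_ins + aln$n_del,
                  denom = aln$n_match + aln$n_sub + aln$n_ins + aln$n_del)
  e_basic <- pooled_error_rate(stats, basic$bases,
                               rep(1, nrow(basic)))
  stages$basic <- note_stage("basic_screen", nrow(after_chim), nrow(basic),
                             e_basic)

  filtered <- screen(basic, config$filter, region,
                     filters = c("mismatch", "coverage", "predicted_error"))
  e_filtered <- pooled_error_rate(stats, filtered$bases,
                                  rep(1, nrow(filtered)))
  stages$filtered <- note_stage("error_filters", nrow(basic), nrow(filtered),
                                e_filtered)

  tab <- as_count_table(filtered)
  thr <- precluster_threshold(stats::median(nchar(tab$sequence)),
                              config$precluster_rate)
  pc <- precluster(tab, threshold = thr, band = config$band)
  e_pre <- pooled_error_rate(stats, pc$sequence, pc$abundance)
  # pre-clustering reassigns reads to representatives but drops none
  stages$precluster <- note_stage("precluster", nrow(filtered),
                                  nrow(filtered), e_pre)

  otus <- NULL
  rarefied <- NA_real_
  if (nrow(pc) > 0) {
    dm <- distance_matrix(setNames(pc$sequence,
                                   sprintf("uniq_%05d", seq_len(nrow(pc)))),
                          band = config$band)
    otus <- average_neighbor(dm, cutoff = config$cluster_cutoff,
                             abundances = pc$abundance)
    if (sum(pc$abundance) >= config$rarefaction_depth) {
      rarefied <- rarefied_otu_count(otus$otu_abundances$abundance,
                                     depth = config$rarefaction_depth)
    }
  }
  tdm <- distance_matrix(setNames(refs$bases, refs$id), band = config$band)
  template_otus <- average_neighbor(tdm, cutoff = config$cluster_cutoff)

  structure(list(
    config = config,
    stages = dplyr::bind_rows(stages),
    filter_reports = list(basic = filter_report(basic),
                          error_filters = filter_report(filtered)),
    n_chimeras_removed = if (config$chimera_removal == "truth")
      sum(is_chim) else 0L,
    n_chimeras_simulated = sum(sim$truth$is_chimera),
    precluster_threshold = thr,
    n_unique_before_precluster = nrow(tab),
    n_unique_after_precluster = nrow(pc),
    otus = otus,
    n_otus = if (is.null(otus)) NA_integer_ else otus$n_otus,
    n_template_otus = template_otus$n_otus,
    rarefied_otu_count = rarefied,
    stage_reads = list(basic = basic, filtered = filtered,
                       precluster_table = pc),
    fraction_retained = nrow(filtered) / max(1L, nrow(sim$reads)),
    truth = sim$truth,
    refs = refs
  ), class = "ccs_run_report")
}

#' @export
print.ccs_run_report <- function(x, ...) {
  cat("CCS curation pipeline run (region", x$config$region, ", seed",
      x$config$seed, ")\n")
  df <- as.data.frame(x$stages)
  df$error_rate <- ifelse(is.na(df$error_rate), "",
                          sprintf("%.4g%%", 100 * df$error_rate))
  print(df, row.names = FALSE)
  cat(sprintf("reads retained: %.1f%%; precluster threshold: %d nt (%d -> %d unique sequences)\n",
              100 * x$fraction_retained, x$precluster_threshold,
              x$n_unique_before_precluster, x$n_unique_after_precluster))
  cat("OTUs at", x$config$cluster_cutoff, "cutoff:", x$n_otus,
      "(templates alone give", paste0(x$n_template_otus, ")"), "\n")
  if (!is.na(x$rarefied_otu_count)) {
    cat(sprintf("expected OTUs rarefied to %d sequences: %.1f\n",
                x$config$rarefaction_depth, x$rarefied_otu_count))
  }
  invisible(x)
}

#' @export
tidy.ccs_run_report <- function(x, ...) x$stages

#' @export
glance.ccs_run_report <- function(x, ...) {
  er <- function(stage) {
    v <- x$stages$error_rate[x$stages$stage == stage]
    if (length(v) == 1) v else NA_real_
  }
  tibble(n_reads = x$config$n_reads,
         fraction_retained = x$fraction_retained,
         error_rate_basic = er("basic_screen"),
         error_rate_filtered = er("error_filters"),
         error_rate_preclustered = er("precluster"),
         n_otus = x$n_otus,
         n_template_otus = x$n_template_otus,
         rarefied_otu_count = x$rarefied_otu_count)
}
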