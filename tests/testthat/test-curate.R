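# Demultiplexing/orientation/trimming and the read screen.

v4 <- region_design("V4")
fwd_primer_c <- "GTGCCAGCAGCCGCGGTAA"        # M -> A
rev_primer_c <- "GGACTACACGGGTTTCTAAT"       # H -> A, V -> C, W -> T
bc <- tibble::tibble(sample = "mock",
                     fwd_barcode = strrep("ACGT", 4),
                     rev_barcode = strrep("TGCA", 4))

build_read <- function(insert) {
  paste0(bc$fwd_barcode, fwd_primer_c, insert,
         revcomp(rev_primer_c), revcomp(bc$rev_barcode))
}

test_that("a constructed exact read is trimmed back to its insert", {
  withr::local_seed(11)
  insert <- rand_seq(253)
  tr <- find_and_trim(ccs_reads("r1", build_read(insert)), bc, v4)
  expect_equal(tr$bases, insert)
  expect_equal(tr$bc_mismatches, 0L)
  expect_equal(tr$primer_mismatches, 0L)
  expect_false(tr$orientation_flipped)
  expect_equal(tr$sample, "mock")
})

test_that("reverse-complemented reads are recognised and flipped", {
  withr::local_seed(12)
  insert <- rand_seq(253)
  fwd <- find_and_trim(ccs_reads("r1", build_read(insert)), bc, v4)
  rc <- find_and_trim(ccs_reads("r1", revcomp(build_read(insert))), bc, v4)
  expect_true(rc$orientation_flipped)
  expect_equal(rc$bases, fwd$bases)
  expect_equal(rc$bc_mismatches, fwd$bc_mismatches)
  expect_equal(rc$sample, "mock")
})

test_that("quals are trimmed and reversed together with the bases", {
  withr::local_seed(121)
  insert <- rand_seq(50)
  read <- build_read(insert)
  q <- sample(2:93, nchar(read), replace = TRUE)
  tr <- find_and_trim(ccs_reads("r1", read, list(q)), bc, v4)
  expect_equal(tr$quals[[1]], q[(16 + 19 + 1):(16 + 19 + 50)])
  rc <- find_and_trim(ccs_reads("r1", revcomp(read), list(rev(q))), bc, v4)
  expect_equal(rc$quals[[1]], tr$quals[[1]])
})

test_that("a substitution inside the forward primer counts one primer mismatch", {
  withr::local_seed(13)
  insert <- rand_seq(253)
  read <- build_read(insert)
  pos <- 16L + 5L   # inside the forward primer
  ch <- strsplit(read, "")[[1]]
  ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
  tr <- find_and_trim(ccs_reads("r1", paste(ch, collapse = "")), bc, v4)
  expect_equal(tr$primer_mismatches, 1L)
  expect_equal(tr$bc_mismatches, 0L)
  expect_equal(tr$bases, insert)
})

test_that("leading shifts within max_shift are absorbed", {
  withr::local_seed(14)
  insert <- rand_seq(253)
  tr <- find_and_trim(ccs_reads("r1", paste0("GG", build_read(insert))), bc,
                      v4, max_shift = 2)
  expect_equal(tr$bases, insert)
  expect_equal(tr$sample, "mock")
})

test_that("unmatchable reads come back unassigned rather than erroring", {
  withr::local_seed(15)
  tr <- find_and_trim(ccs_reads("r1", rand_seq(300)), bc, v4)
  expect_true(is.na(tr$sample))
  expect_equal(tr$bases, tr$bases)  # untrimmed record is preserved
  expect_equal(nchar(tr$bases), 300L)
})

test_that("max_homopolymer measures the longest run", {
  expect_equal(max_homopolymer("AAAAAAAAA"), 9L)
  expect_equal(max_homopolymer("ACGTACGT"), 1L)
  expect_equal(max_homopolymer("CCGGGGTT"), 4L)
  expect_equal(max_homopolymer(""), 0L)
})

test_that("predicted error from quals averages per-base error probabilities", {
  expect_equal(predicted_error_from_quals(rep(30L, 10)), 1e-3)
  expect_equal(predicted_error_from_quals(rep(20L, 4)), 1e-2)
  expect_equal(predicted_error_from_quals(c(10L, 20L, 30L)),
               mean(c(0.1, 0.01, 0.001)))
  # ambiguous positions count as 0.75
  expect_equal(predicted_error_from_quals(c(0L, 30L)), mean(c(0.75, 0.001)))
  expect_error(predicted_error_from_quals(integer(0)), "empty")
})

make_screen_fixture <- function() {
  withr::local_seed(21)
  bases <- vapply(1:10, function(i) rand_seq(253), character(1))
  bases[1] <- paste0(rand_seq(244), strrep("A", 9))        # homopolymer 9
  reads <- ccs_reads(sprintf("r%02d", 1:10), bases,
                     passes = c(15L, 15L, 5L, rep(15L, 7)),
                     predicted_error = c(1e-5, 1e-5, 1e-5, 1e-3, rep(1e-5, 6)))
  reads$bc_mismatches <- rep(0L, 10)
  reads$primer_mismatches <- rep(0L, 10)
  reads
}

test_that("screen keeps only reads passing every enabled filter and attributes attrition", {
  reads <- make_screen_fixture()
  kept <- screen(reads, filter_config(), v4)
  expect_equal(nrow(kept), 7L)
  expect_setequal(kept$id, sprintf("r%02d", c(2, 5:10)))
  rep <- filter_report(kept)
  expect_equal(rep$failed[rep$filter == "homopolymer"], 1L)
  expect_equal(rep$failed[rep$filter == "coverage"], 1L)
  expect_equal(rep$failed[rep$filter == "predicted_error"], 1L)
  expect_equal(rep$failed[rep$filter == "length"], 0L)
  # retained + failed-at-least-once == input
  expect_equal(attr(rep, "retained") + sum(rep$failed), nrow(reads))
  expect_equal(glance(rep)$fraction_retained, 0.7)
})

test_that("screening with no filters is the identity", {
  reads <- make_screen_fixture()
  kept <- screen(reads, filter_config(), v4, filters = character(0))
  expect_equal(nrow(kept), nrow(reads))
  expect_equal(attr(filter_report(kept), "fraction_retained"), 1)
  expect_equal(nrow(screen(ccs_reads(character(), character()),
                           filter_config(), v4)), 0L)
})

test_that("the kept set is the order-independent conjunction of the filters", {
  reads <- make_screen_fixture()
  kept <- screen(reads, filter_config(), v4)
  manual <- reads[max_homopolymer(reads$bases) <= 8 &
                    nchar(reads$bases) >= floor(253 * 0.9) &
                    nchar(reads$bases) <= ceiling(253 * 1.1) &
                    reads$bc_mismatches <= 1 & reads$primer_mismatches <= 1 &
                    reads$passes >= 10 &
                    reads$predicted_error <= 1e-4, ]
  expect_setequal(kept$id, manual$id)
})

test_that("tightening any threshold never grows the kept set", {
  withr::local_seed(22)
  reads <- ccs_reads(sprintf("r%03d", 1:60),
                     vapply(1:60, function(i) rand_seq(sample(220:280, 1)),
                            character(1)),
                     passes = sample(3:25, 60, replace = TRUE),
                     predicted_error = 10^runif(60, -6, -2))
  reads$bc_mismatches <- sample(0:3, 60, replace = TRUE)
  reads$primer_mismatches <- sample(0:3, 60, replace = TRUE)
  base_cfg <- filter_config()
  kept0 <- screen(reads, base_cfg, v4)$id
  tighter <- list(
    filter_config(max_homopolymer = 5L),
    filter_config(min_passes = 15L),
    filter_config(max_predicted_error = 1e-5),
    filter_config(max_bc_mismatch = 0L),
    filter_config(length_tolerance = 0.05)
  )
  for (cfg in tighter) {
    expect_true(all(screen(reads, cfg, v4)$id %in% kept0))
  }
})

test_that("enabled filters with missing metadata reject the run by name", {
  reads <- ccs_reads("r1", "ACGT")
  expect_error(screen(reads, filter_config(), v4, filters = "coverage"),
               "coverage")
  expect_error(screen(reads, filter_config(), v4, filters = "mismatch"),
               "mismatch")
  expect_error(screen(reads, filter_config(), region = NULL,
                      filters = "length"), "length")
})

test_that("the predicted-error filter lowers the observed error rate on simulated reads", {
  refs <- make_mock_references(1, 250, 0.05, seed = 31)
  model <- error_model(orient_flip_prob = 0)
  sim <- simulate_ccs_reads(refs, 400, model, seed = 32)
  aln <- align_to_best_reference(sim$reads, refs, band = 30)
  all_rate <- tally_errors(aln)$error_rate
  keep <- sim$reads$predicted_error <= 1e-4
  expect_gt(sum(keep), 0)
  kept_rate <- tally_errors(aln[keep, , drop = FALSE])$error_rate
  expect_lte(kept_rate, all_rate)
})
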