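# The read simulator: determinism, truth-table fidelity, parameter recovery.

test_that("identical seeds give identical references and reads", {
  r1 <- make_mock_references(5, 300, 0.1, seed = 71)
  r2 <- make_mock_references(5, 300, 0.1, seed = 71)
  expect_identical(r1, r2)
  s1 <- simulate_ccs_reads(r1, 50, error_model(), seed = 72)
  s2 <- simulate_ccs_reads(r1, 50, error_model(), seed = 72)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_ccs_reads(r1, 50, error_model(), seed = 73)
  expect_false(identical(s1$reads$bases, s3$reads$bases))
})

test_that("a zero error rate reproduces the templates exactly", {
  refs <- make_mock_references(3, 200, 0.1, seed = 74)
  model <- error_model(per_base_error_rate = 0, rate_dispersion_sdlog = 0,
                       orient_flip_prob = 0)
  sim <- simulate_ccs_reads(refs, 40, model, seed = 75)
  expect_true(all(sim$truth$n_errors == 0))
  tmpl <- refs$bases[match(sim$truth$template, refs$id)]
  expect_identical(sim$reads$bases, tmpl)
  expect_true(all(sim$reads$predicted_error < 1e-4))
})

test_that("mock references approach the requested pairwise divergence", {
  refs <- make_mock_references(6, 800, 0.10, seed = 76)
  pairs <- utils::combn(6, 2)
  d <- apply(pairs, 2, function(p) {
    a <- strsplit(refs$bases[p[1]], "")[[1]]
    b <- strsplit(refs$bases[p[2]], "")[[1]]
    mean(a != b)
  })
  se <- sqrt(0.10 * 0.90 / 800)
  expect_lt(abs(mean(d) - 0.10), 3 * se)
})

test_that("error-type mixture and quality model are recovered from alignments", {
  refs <- make_mock_references(1, 600, 0.05, seed = 77)
  model <- error_model(per_base_error_rate = 0.02, rate_dispersion_sdlog = 0,
                       orient_flip_prob = 0)
  sim <- simulate_ccs_reads(refs, 2500, model, seed = 78)
  aln <- align_to_best_reference(sim$reads, refs, band = 30)
  prof <- tally_errors(aln, reads = sim$reads)
  n <- prof$n_errors
  expect_gt(n, 2e4)
  mix <- c(sub = 0.509, ins = 0.312, del = 0.179)
  for (ty in names(mix)) {
    se <- sqrt(mix[[ty]] * (1 - mix[[ty]]) / n)
    expect_lt(abs(prof$type_fractions[[ty]] - mix[[ty]]), 3 * se + 0.005)
  }
  ct <- prof$quality_crosstab
  expected <- c(correct = 0.805, substitution = 0.800, insertion = 0.804)
  for (cls in names(expected)) {
    row <- ct[ct$class == cls, ]
    se <- sqrt(expected[[cls]] * (1 - expected[[cls]]) / row$n)
    expect_lt(abs(row$frac_max_quality - expected[[cls]]), 3 * se + 0.002)
  }
})

test_that("the measured error rate converges to the configured rate", {
  refs <- make_mock_references(2, 400, 0.1, seed = 79)
  model <- error_model(per_base_error_rate = 0.01, rate_dispersion_sdlog = 0,
                       orient_flip_prob = 0)
  sim <- simulate_ccs_reads(refs, 600, model, seed = 80)
  prof <- tally_errors(align_to_best_reference(sim$reads, refs, band = 25))
  N <- prof$n_positions
  se <- sqrt(0.01 * 0.99 / N)
  expect_lt(abs(prof$error_rate - 0.01), 3 * se + 0.001)
})

test_that("simulated chimeras are flagged and clean reads are not", {
  refs <- make_mock_references(3, 120, 0.2, seed = 81)
  model <- error_model(per_base_error_rate = 0, rate_dispersion_sdlog = 0,
                       orient_flip_prob = 0, chimera_rate = 0.1)
  sim <- simulate_ccs_reads(refs, 150, model, seed = 82)
  chim <- enumerate_in_silico_chimeras(refs)
  cls <- classify_chimeric(sim$reads, refs, chim, band = 25)
  truth_chim <- sim$truth$is_chimera
  # error-free non-chimeric reads sit at distance 0 from a reference
  expect_true(all(!cls$is_chimeric[!truth_chim]))
  expect_true(all(cls$d_ref[!truth_chim] == 0))
  # most chimeras diverge enough from both parents to be flagged
  expect_gt(mean(cls$is_chimeric[truth_chim]), 0.6)
  expect_gt(sum(truth_chim), 5)
})

test_that("reads are wrapped in barcodes and primers and flipped as requested", {
  refs <- make_mock_references(2, 100, 0.1, seed = 83)
  bc <- tibble::tibble(sample = "mock",
                       fwd_barcode = strrep("ACGT", 4),
                       rev_barcode = strrep("TGCA", 4))
  region <- region_design("V4")
  model <- error_model(per_base_error_rate = 0, rate_dispersion_sdlog = 0,
                       orient_flip_prob = 0.5)
  sim <- simulate_ccs_reads(refs, 60, model, barcodes = bc, region = region,
                            seed = 84)
  expect_true(any(sim$truth$flipped) && any(!sim$truth$flipped))
  expect_equal(unique(nchar(sim$reads$bases)),
               100L + 2L * 16L + nchar(region$fwd_primer) +
                 nchar(region$rev_primer))
  tr <- find_and_trim(sim$reads, bc, region)
  expect_true(all(tr$sample == "mock"))
  expect_identical(tr$orientation_flipped, sim$truth$flipped)
  tmpl <- refs$bases[match(sim$truth$template, refs$id)]
  expect_identical(tr$bases, tmpl)
})
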