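# Error measurement against references, chimera rules, variant spectrum,
# binomial utilities.

test_that("identical and one-off reads give the expected error rates", {
  withr::local_seed(41)
  ref <- rand_seq(100)
  aln <- align_to_best_reference(c(r1 = ref), c(ref1 = ref))
  expect_equal(aln$error_rate, 0)
  expect_equal(aln$n_match, 100L)
  ch <- strsplit(ref, "")[[1]]
  ch[50] <- setdiff(c("A", "C", "G", "T"), ch[50])[1]
  aln <- align_to_best_reference(c(r1 = paste(ch, collapse = "")),
                                 c(ref1 = ref))
  expect_equal(aln$n_sub, 1L)
  expect_equal(aln$error_rate, 0.01)
})

test_that("best-reference search matches the brute-force dynamic program", {
  withr::local_seed(42)
  for (t in 1:30) {
    anc <- rand_seq(sample(50:70, 1))
    refs <- vapply(1:3, function(k) mutate_seq(anc, n_sub = sample(3:8, 1)),
                   character(1))
    read <- mutate_seq(refs[sample(3, 1)], n_sub = sample(0:3, 1),
                       n_ins = sample(0:1, 1), n_del = sample(0:1, 1))
    got <- align_to_best_reference(c(x = read),
                                   setNames(refs, paste0("ref", 1:3)))
    want <- oracle_best_ref(read, refs)
    expect_equal(got$best_ref, paste0("ref", want$ref))
    expect_equal(got$n_sub, want$n_sub)
    expect_equal(got$n_ins, want$n_ins)
    expect_equal(got$n_del, want$n_del)
  }
})

test_that("per-read error rates are self-consistent with their aligned strings", {
  withr::local_seed(43)
  refs <- setNames(vapply(1:2, function(k) rand_seq(80), character(1)),
                   c("a", "b"))
  reads <- vapply(1:10, function(k) {
    mutate_seq(refs[[sample(2, 1)]], n_sub = sample(0:4, 1),
               n_ins = sample(0:2, 1), n_del = sample(0:2, 1))
  }, character(1))
  aln <- align_to_best_reference(reads, refs)
  for (i in seq_len(nrow(aln))) {
    cts <- oracle_counts(aln$aligned_read[i], aln$aligned_ref[i])
    denom <- cts$n_match + cts$n_sub + cts$n_ins + cts$n_del
    expect_equal(aln$error_rate[i], (cts$n_sub + cts$n_ins + cts$n_del) / denom)
  }
})

test_that("tally_errors flags zero-error sets and counts a deleted G", {
  ref <- c(ref1 = "ATTCGAAC")
  prof0 <- tally_errors(align_to_best_reference(c(r1 = "ATTCGAAC"), ref))
  expect_equal(prof0$n_errors, 0L)
  expect_true(all(is.na(prof0$type_fractions)))
  prof1 <- tally_errors(align_to_best_reference(c(r1 = "ATTCAAC"), ref))
  expect_equal(unname(prof1$totals["del"]), 1L)
  expect_equal(prof1$deletion_base_counts,
               c(A = 0L, C = 0L, G = 1L, T = 0L))
  expect_equal(sum(prof1$type_fractions), 1)
  expect_true(all(diag(prof1$substitution_matrix) == 0))
})

test_that("the quality cross-tab separates correct, substituted and inserted calls", {
  ref <- c(ref1 = "ACGTACGTAC")
  # read 1: identical, half maximum quality
  # read 2: one substitution with maximum quality
  reads <- ccs_reads(c("r1", "r2"), c("ACGTACGTAC", "ACGTTCGTAC"),
                     quals = list(c(rep(93L, 5), rep(50L, 5)),
                                  c(rep(50L, 4), 93L, rep(50L, 5))))
  aln <- align_to_best_reference(reads, ref)
  prof <- tally_errors(aln, reads = reads)
  ct <- prof$quality_crosstab
  expect_equal(ct$frac_max_quality[ct$class == "substitution"], 1)
  expect_equal(ct$n[ct$class == "correct"], 19L)
  expect_equal(ct$frac_max_quality[ct$class == "correct"], 5 / 19)
})

test_that("chimera enumeration matches exhaustive enumeration on small parents", {
  expect_equal(nrow(enumerate_in_silico_chimeras(c(a = "ACGTACGT"))), 0L)
  expect_equal(nrow(enumerate_in_silico_chimeras(c(a = "ACGTACGT",
                                                   b = "ACGTACGT"))), 0L)
  withr::local_seed(44)
  for (t in 1:10) {
    p1 <- rand_seq(20)
    p2 <- mutate_seq(p1, n_sub = 4)
    got <- enumerate_in_silico_chimeras(c(a = p1, b = p2))
    expect_setequal(got$bases, oracle_chimeras(c(p1, p2)))
  }
})

test_that("the chimera rule flags at a margin of 3 and not below", {
  withr::local_seed(45)
  repeat {   # parents differing at >=3 sites in each half
    p1 <- rand_seq(40)
    ch <- strsplit(p1, "")[[1]]
    pos <- c(sample(1:20, 3), sample(21:40, 3))
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    p2 <- paste(ch, collapse = "")
    if (count_diffs(substr(p1, 1, 20), substr(p2, 1, 20)) >= 3 &&
        count_diffs(substr(p1, 21, 40), substr(p2, 21, 40)) >= 3) break
  }
  refs <- c(a = p1, b = p2)
  chim <- enumerate_in_silico_chimeras(refs)
  perfect <- paste0(substr(p1, 1, 20), substr(p2, 21, 40))
  res <- classify_chimeric(c(x = perfect), refs, chim)
  expect_true(res$is_chimeric)
  expect_equal(res$d_chimera, 0)
  expect_gte(res$d_ref, 3)
  # a read equal to a reference is always clean
  res0 <- classify_chimeric(c(x = p1), refs, chim)
  expect_false(res0$is_chimeric)
  expect_equal(res0$d_ref, 0)
  # parents differing by only 2 nt total: margin at most 2, always clean
  q1 <- rand_seq(40)
  ch <- strsplit(q1, "")[[1]]
  for (p in c(10, 30)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  q2 <- paste(ch, collapse = "")
  refs2 <- c(a = q1, b = q2)
  chim2 <- enumerate_in_silico_chimeras(refs2)
  res2 <- classify_chimeric(c(x = paste0(substr(q1, 1, 20),
                                         substr(q2, 21, 40))),
                            refs2, chim2)
  expect_false(res2$is_chimeric)
})

test_that("chimera classification does not depend on reference input order", {
  withr::local_seed(46)
  p1 <- rand_seq(30)
  p2 <- mutate_seq(p1, n_sub = 8)
  read <- paste0(substr(p1, 1, 15), substr(p2, 16, 30))
  r12 <- classify_chimeric(c(x = read), c(a = p1, b = p2))
  r21 <- classify_chimeric(c(x = read), c(b = p2, a = p1))
  expect_equal(r12$is_chimeric, r21$is_chimeric)
  expect_equal(r12$d_ref, r21$d_ref)
  expect_equal(r12$d_chimera, r21$d_chimera)
})

test_that("variant spectrum separates unique and recurrent 1-nt errors", {
  withr::local_seed(47)
  ref <- c(ref1 = rand_seq(60))
  variants <- vapply(c(5, 15, 25, 35, 45), function(p) {
    ch <- strsplit(ref, "")[[1]]
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }, character(1))
  aln <- align_to_best_reference(variants, ref)
  sp <- variant_spectrum(aln)
  expect_equal(sp$n_variants, 5L)
  expect_equal(sp$histogram$n_variants[1], 5L)
  expect_equal(sp$histogram$fraction[1], 1)
  # three copies of one variant
  aln2 <- align_to_best_reference(c(variants, variants[1], variants[1]), ref)
  sp2 <- variant_spectrum(aln2)
  expect_equal(sp2$histogram$n_variants[3], 1L)
  expect_equal(sp2$top_variant_count, 3L)
  expect_equal(sp2$n_reads_1nt, 7L)
})

test_that("a recurrent injected variant is recovered at its injection rate", {
  refs <- make_mock_references(1, 300, 0.05, seed = 48)
  model <- error_model(per_base_error_rate = 0.003,
                       rate_dispersion_sdlog = 0, orient_flip_prob = 0,
                       systematic_error_rate = 0.05)
  sim <- simulate_ccs_reads(refs, 1500, model, seed = 49)
  aln <- align_to_best_reference(sim$reads, refs, band = 25)
  sp <- variant_spectrum(aln)
  n_sys <- sum(sim$truth$n_errors == 1 &
                 sim$truth$n_sub == 1)   # includes systematic reads
  expect_gte(sp$top_variant_count, 0.5 * 0.05 * 1500)
  se <- sqrt(0.05 * 0.95 / 1500)
  expect_lt(abs(sp$top_variant_count / 1500 - 0.05), 3 * se + 0.003)
})

test_that("binomial error utilities follow the closed forms", {
  expect_equal(expected_error_free_fraction(0, 1234), 1)
  expect_equal(expected_error_free_fraction(0.01, 2), 0.9801)
  expect_equal(prob_at_least_k_errors(0.01, 100, 1),
               1 - dbinom(0, 100, 0.01))
  expect_equal(prob_at_least_k_errors(0.002, 1500, 3),
               sum(dbinom(3:1500, 1500, 0.002)))
})
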