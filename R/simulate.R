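# Mock-community CCS read simulator: the package's fixture generator and the
# ground truth for parameter-recovery tests.

#' Error model for simulated CCS reads
#'
#' Defaults reproduce the measured consensus-read error structure: an average
#' per-base error rate of 0.65%, an error-type mixture of 31.2% insertions,
#' 17.9% deletions and 50.9% substitutions, deletions striking guanines
#' (39.4%) and adenines (24.3%) more often than cytosines (18.3%) or
#' thymidines (18.0%), substitution targets and inserted bases uniform, and a
#' quality model in which the maximum value (93) is carried by 80.5% of
#' correct calls, 80.0% of substitutions and 80.4% of insertions, the
#' remaining mass spread uniformly over 2..92.
#'
#' Two read-level dials emulate the platform's read-to-read variability: a
#' lognormal per-read rate multiplier (`rate_dispersion_sdlog`, mean 1)
#' mirroring coverage-dependent consensus accuracy, and a lognormal-noised
#' predicted error rate derived from the read's latent rate
#' (`predicted_error_sdlog`), so predicted and observed error rates correlate
#' as the base caller's estimates do in practice.
#'
#' @param per_base_error_rate Mean per-base error fraction (default 0.0065).
#' @param type_mixture Named fractions `insertion`, `deletion`,
#'   `substitution`; must sum to 1.
#' @param deletion_base_weights Named weights `A`,`C`,`G`,`T` for the deleted
#'   base; must sum to 1.
#' @param max_quality Maximum quality value (default 93).
#' @param p_max_quality Probability a call carries the maximum quality, by
#'   class (`correct`, `substitution`, `insertion`).
#' @param quality_range Range of non-maximum quality values (default 2..92).
#' @param passes_range Range of the uniform pass-count distribution
#'   (default 3..25).
#' @param predicted_error_sdlog Lognormal sdlog of predicted-error noise
#'   (default 0.5).
#' @param rate_dispersion_sdlog Lognormal sdlog of the per-read rate
#'   multiplier (mean held at 1; 0 gives every read the same rate). The
#'   default 2.5 makes the per-read rate distribution strongly right-skewed:
#'   most consensus reads are nearly error-free while a poor minority carries
#'   most of the errors, so that roughly a third to a half of reads fall
#'   under the 0.01% predicted-error threshold, as a real run does.
#' @param chimera_rate Fraction of reads built as single-breakpoint bimeras
#'   (default 0).
#' @param systematic_error_rate Fraction of reads carrying one fixed,
#'   recurrent 1-nt substitution instead of random errors (default 0);
#'   reproduces the heavy tail of the 1-nt variant spectrum.
#' @param orient_flip_prob Probability a read is emitted reverse-complemented
#'   (default 0.5).
#' @return A `ccs_error_model` list.
#' @export
error_model <- function(per_base_error_rate = 0.0065,
                        type_mixture = c(insertion = 0.312, deletion = 0.179,
                                         substitution = 0.509),
                        deletion_base_weights = c(A = 0.243, C = 0.183,
                                                  G = 0.394, T = 0.180),
                        max_quality = 93L,
                        p_max_quality = c(correct = 0.805,
                                          substitution = 0.800,
                                          insertion = 0.804),
                        quality_range = c(2L, 92L),
                        passes_range = c(3L, 25L),
                        predicted_error_sdlog = 0.5,
                        rate_dispersion_sdlog = 2.5,
                        chimera_rate = 0,
                        systematic_error_rate = 0,
                        orient_flip_prob = 0.5) {
  stopifnot(per_base_error_rate >= 0, per_base_error_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            systematic_error_rate >= 0, systematic_error_rate <= 1,
            orient_flip_prob >= 0, orient_flip_prob <= 1)
  if (abs(sum(type_mixture) - 1) > 1e-8) {
    stop("type_mixture must sum to 1", call. = FALSE)
  }
  if (abs(sum(deletion_base_weights) - 1) > 1e-8) {
    stop("deletion_base_weights must sum to 1", call. = FALSE)
  }
  structure(list(per_base_error_rate = per_base_error_rate,
                 type_mixture = type_mixture[c("insertion", "deletion",
                                               "substitution")],
                 deletion_base_weights = deletion_base_weights[c("A", "C",
                                                                 "G", "T")],
                 max_quality = as.integer(max_quality),
                 p_max_quality = p_max_quality,
                 quality_range = as.integer(quality_range),
                 passes_range = as.integer(passes_range),
                 predicted_error_sdlog = predicted_error_sdlog,
                 rate_dispersion_sdlog = rate_dispersion_sdlog,
                 chimera_rate = chimera_rate,
                 systematic_error_rate = systematic_error_rate,
                 orient_flip_prob = orient_flip_prob),
            class = "ccs_error_model")
}

#' Generate synthetic mock-community reference sequences
#'
#' One random ancestor is drawn and mutated independently per template with a
#' per-site substitution probability chosen so that the expected pairwise
#' divergence between templates equals `divergence` (two independently
#' mutated copies differ at a site with probability `2q(1-q) + (2/3)q^2`).
#'
#' @param n_templates Number of templates (default 21, the size of a typical
#'   defined mock community).
#' @param length Template length in nt.
#' @param divergence Expected pairwise divergence between templates.
#' @param seed Optional seed; identical seeds give identical sequences.
#' @return A tibble `id`, `bases`.
#' @export
make_mock_references <- function(n_templates = 21L, length = 1500L,
                                 divergence = 0.10, seed = NULL) {
  stopifnot(n_templates >= 1, length >= 1, divergence > 0, divergence < 1)
  q <- (3 - sqrt(9 - 12 * divergence)) / 4
  gen <- function() {
    bases4 <- c("A", "C", "G", "T")
    anc <- sample(bases4, length, replace = TRUE)
    seqs <- vapply(seq_len(n_templates), function(i) {
      s <- anc
      hit <- which(runif(length) < q)
      if (base::length(hit) > 0) {
        s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases4, b), 1),
                         character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    tibble(id = sprintf("template_%02d", seq_len(n_templates)), bases = seqs)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

concretize_iupac <- function(x) {
  sets <- iupac_sets()
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(c) {
    s <- sets[[c]]
    if (length(s) == 1) s else sample(s, 1)
  }, character(1)), collapse = "")
}

# inject errors into a character vector of bases; returns bases, per-base call
# class, and event counts
inject_errors <- function(chars, n_err, model) {
  bases4 <- c("A", "C", "G", "T")
  L <- length(chars)
  cls <- rep("correct", L)
  if (n_err == 0) {
    return(list(chars = chars, cls = cls, n_sub = 0L, n_ins = 0L, n_del = 0L))
  }
  types <- sample(c("ins", "del", "sub"), n_err, replace = TRUE,
                  prob = model$type_mixture[c("insertion", "deletion",
                                              "substitution")])
  n_si <- sum(types != "del")
  n_de <- sum(types == "del")
  used <- logical(L)
  events <- list()
  if (n_si > 0) {
    pos_si <- sample.int(L, min(n_si, L))
    used[pos_si] <- TRUE
    si_types <- types[types != "del"][seq_along(pos_si)]
    for (k in seq_along(pos_si)) {
      events[[length(events) + 1]] <- list(type = si_types[k], pos = pos_si[k])
    }
  }
  if (n_de > 0) {
    w <- model$deletion_base_weights
    for (k in seq_len(n_de)) {
      avail <- bases4[vapply(bases4, function(b) any(!used & chars == b),
                             logical(1))]
      if (length(avail) == 0) break
      b <- sample(avail, 1, prob = w[avail] / sum(w[avail]))
      cand <- which(!used & chars == b)
      p <- if (length(cand) == 1) cand else sample(cand, 1)
      used[p] <- TRUE
      events[[length(events) + 1]] <- list(type = "del", pos = p)
    }
  }
  ord <- order(vapply(events, `[[`, numeric(1), "pos"), decreasing = TRUE)
  n_sub <- n_ins <- n_del <- 0L
  for (e in events[ord]) {
    p <- e$pos
    if (e$type == "sub") {
      chars[p] <- sample(setdiff(bases4, chars[p]), 1)
      cls[p] <- "sub"
      n_sub <- n_sub + 1L
    } else if (e$type == "ins") {
      chars <- append(chars, sample(bases4, 1), after = p)
      cls <- append(cls, "ins", after = p)
      n_ins <- n_ins + 1L
    } else {
      chars <- chars[-p]
      cls <- cls[-p]
      n_del <- n_del + 1L
    }
  }
  list(chars = chars, cls = cls, n_sub = n_sub, n_ins = n_ins, n_del = n_del)
}

#' Simulate mock-community CCS reads with a known truth table
#'
#' Each read picks a template proportionally to `abundances` (or is built as a
#' single-breakpoint bimera of two templates with probability
#' `model$chimera_rate`), is optionally wrapped in barcodes and concretised
#' degenerate primers for the given region, receives errors at the model's
#' per-read rate (type from the mixture; deleted bases drawn by the weighted
#' base composition; substitution targets and inserted bases uniform),
#' per-base qualities from the quality model, a pass count, a noised predicted
#' error rate, and is reverse-complemented with probability
#' `model$orient_flip_prob`. Fully deterministic for a given seed.
#'
#' @param refs Reference templates (see [make_mock_references()]).
#' @param n_reads Number of reads.
#' @param model A [error_model()].
#' @param abundances Template sampling weights (default uniform; normalised).
#' @param barcodes Optional barcode tibble; reads are assigned to its samples
#'   uniformly at random. When `NULL` naked inserts are emitted.
#' @param region One-row region tibble (required with `barcodes`).
#' @param seed Optional seed.
#' @return A list with `reads` (a reads tibble), `truth` (per-read template,
#'   chimera parents/breakpoint, injected event counts and true error rate)
#'   and `refs`.
#' @export
simulate_ccs_reads <- function(refs, n_reads, model = error_model(),
                               abundances = NULL, barcodes = NULL,
                               region = NULL, seed = NULL) {
  refs <- as_ref_tibble(refs)
  if (!is.null(barcodes) && is.null(region)) {
    stop("supply `region` together with `barcodes`", call. = FALSE)
  }
  nt <- nrow(refs)
  if (is.null(abundances)) abundances <- rep(1, nt)
  abundances <- abundances / sum(abundances)
  gen <- function() {
    # fixed recurrent 1-nt substitution (systematic-error mode)
    sys_template <- 1L
    sys_len <- nchar(refs$bases[sys_template])
    sys_pos <- max(1L, sys_len %/% 2L)
    reads <- vector("list", n_reads)
    truth <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      is_chimera <- runif(1) < model$chimera_rate
      parent_a <- parent_b <- NA_character_
      breakpoint <- NA_integer_
      if (is_chimera && nt >= 2) {
        pq <- sample.int(nt, 2, prob = abundances)
        aln <- align_pair(refs$bases[pq[1]], refs$bases[pq[2]],
                          free_ends = FALSE)
        a <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
        b <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
        bp <- sample.int(length(a) - 1L, 1)
        tmpl <- gsub("-", "", paste(c(a[1:bp], b[(bp + 1):length(b)]),
                                    collapse = ""), fixed = TRUE)
        template_id <- NA_character_
        parent_a <- refs$id[pq[1]]
        parent_b <- refs$id[pq[2]]
        breakpoint <- bp
      } else {
        is_chimera <- FALSE
        k <- sample.int(nt, 1, prob = abundances)
        tmpl <- refs$bases[k]
        template_id <- refs$id[k]
      }
      sample_id <- NA_character_
      if (!is.null(barcodes)) {
        bcrow <- sample.int(nrow(barcodes), 1)
        sample_id <- barcodes$sample[bcrow]
        tmpl <- paste0(barcodes$fwd_barcode[bcrow],
                       concretize_iupac(region$fwd_primer),
                       tmpl,
                       revcomp(concretize_iupac(region$rev_primer)),
                       revcomp(barcodes$rev_barcode[bcrow]))
      }
      chars <- strsplit(tmpl, "", fixed = TRUE)[[1]]
      L0 <- length(chars)
      m <- if (model$rate_dispersion_sdlog > 0) {
        exp(rnorm(1, -model$rate_dispersion_sdlog^2 / 2,
                  model$rate_dispersion_sdlog))
      } else 1
      rate_i <- min(0.5, model$per_base_error_rate * m)
      systematic <- !is_chimera && identical(template_id, refs$id[sys_template]) &&
        runif(1) < model$systematic_error_rate
      if (systematic) {
        bases4 <- c("A", "C", "G", "T")
        cls <- rep("correct", L0)
        off <- if (is.null(barcodes)) 0L else
          nchar(barcodes$fwd_barcode[1]) + nchar(region$fwd_primer)
        p <- sys_pos + off
        idx <- match(chars[p], bases4)
        chars[p] <- bases4[(idx %% 4L) + 1L]
        cls[p] <- "sub"
        inj <- list(chars = chars, cls = cls, n_sub = 1L, n_ins = 0L,
                    n_del = 0L)
      } else {
        n_err <- rbinom(1, L0, rate_i)
        inj <- inject_errors(chars, n_err, model)
      }
      n_errors <- inj$n_sub + inj$n_ins + inj$n_del
      Lr <- length(inj$chars)
      pmax_by_cls <- c(correct = model$p_max_quality[["correct"]],
                       sub = model$p_max_quality[["substitution"]],
                       ins = model$p_max_quality[["insertion"]])
      is_max <- runif(Lr) < pmax_by_cls[inj$cls]
      q <- integer(Lr)
      q[is_max] <- model$max_quality
      if (any(!is_max)) {
        q[!is_max] <- sample(model$quality_range[1]:model$quality_range[2],
                             sum(!is_max), replace = TRUE)
      }
      passes <- sample(model$passes_range[1]:model$passes_range[2], 1)
      pe <- max(rate_i, 1e-6) * exp(rnorm(1, 0, model$predicted_error_sdlog))
      bases <- paste(inj$chars, collapse = "")
      flipped <- runif(1) < model$orient_flip_prob
      if (flipped) {
        bases <- revcomp(bases)
        q <- rev(q)
      }
      rid <- sprintf("read_%06d", i)
      reads[[i]] <- list(id = rid, bases = bases, quals = q,
                         passes = passes, predicted_error = pe)
      truth[[i]] <- tibble(read_id = rid, template = template_id,
                           sample = sample_id,
                           is_chimera = is_chimera, parent_a = parent_a,
                           parent_b = parent_b, breakpoint = breakpoint,
                           n_sub = inj$n_sub, n_ins = inj$n_ins,
                           n_del = inj$n_del, n_errors = n_errors,
                           true_error_rate = n_errors / L0,
                           latent_rate = rate_i, flipped = flipped)
    }
    rd <- ccs_reads(
      id = vapply(reads, `[[`, character(1), "id"),
      bases = vapply(reads, `[[`, character(1), "bases"),
      quals = lapply(reads, `[[`, "quals"),
      passes = vapply(reads, `[[`, integer(1), "passes"),
      predicted_error = vapply(reads, `[[`, numeric(1), "predicted_error")
    )
    list(reads = rd, truth = dplyr::bind_rows(truth), refs = refs)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
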