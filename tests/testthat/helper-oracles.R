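# Independent plain-R reference implementations used to cross-check the
# package's compiled/optimised code paths on small instances.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# introduce point errors into a sequence; returns the mutated string
mutate_seq <- function(s, n_sub = 0, n_ins = 0, n_del = 0) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (n_sub > 0) {
    pos <- sample(length(ch), n_sub)
    for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  }
  if (n_del > 0) {
    ch <- ch[-sample(length(ch), n_del)]
  }
  if (n_ins > 0) {
    for (k in seq_len(n_ins)) {
      p <- sample(0:length(ch), 1)
      ch <- append(ch, sample(BASES, 1), after = p)
    }
  }
  paste(ch, collapse = "")
}

# Full-matrix affine-gap Needleman-Wunsch in plain R. Mirrors the documented
# scoring (gap run of length L costs open + (L-1)*extend, free terminal gaps)
# and tie preferences (M/I predecessors prefer M > I > D, D prefers
# M > D > I; end cell prefers (na,nb), then row na by decreasing j, then
# column nb by decreasing i, replaced only on strictly greater score).
oracle_align <- function(a, b, match = 1, mismatch = -1, go = -2, ge = -1,
                         free_ends = TRUE) {
  A <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  B <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  na <- length(A); nb <- length(B)
  NEG <- -1e9
  M <- I <- D <- matrix(NEG, na + 1, nb + 1)
  tM <- tI <- tD <- matrix(0L, na + 1, nb + 1)
  M[1, 1] <- 0
  for (j in 2:(nb + 1)) {
    if (free_ends) M[1, j] <- 0 else { D[1, j] <- go + (j - 2) * ge; tD[1, j] <- 2L }
  }
  for (i in 2:(na + 1)) {
    if (free_ends) M[i, 1] <- 0 else { I[i, 1] <- go + (i - 2) * ge; tI[i, 1] <- 1L }
  }
  pick <- function(vals, pref) {
    best <- vals[pref[1]]; tb <- pref[1]
    for (s in pref[-1]) if (vals[s] > best) { best <- vals[s]; tb <- s }
    list(score = best, tb = tb)
  }
  for (i in 2:(na + 1)) {
    for (j in 2:(nb + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      p <- pick(c(M[i - 1, j - 1], I[i - 1, j - 1], D[i - 1, j - 1]), c(1, 2, 3))
      M[i, j] <- if (p$score <= NEG / 2) NEG else p$score + s
      tM[i, j] <- p$tb
      p <- pick(c(M[i - 1, j] + go, I[i - 1, j] + ge, D[i - 1, j] + go), c(1, 2, 3))
      I[i, j] <- max(p$score, NEG)
      tI[i, j] <- p$tb
      p <- pick(c(M[i, j - 1] + go, I[i, j - 1] + go, D[i, j - 1] + ge), c(1, 3, 2))
      D[i, j] <- max(p$score, NEG)
      tD[i, j] <- p$tb
    }
  }
  ei <- na + 1; ej <- nb + 1; est <- 1L
  esc <- M[ei, ej]
  for (s in 1:3) {
    v <- list(M, I, D)[[s]][na + 1, nb + 1]
    if (v > esc) { esc <- v; est <- s }
  }
  if (free_ends) {
    for (j in (nb + 1):1) {
      if (j == nb + 1) next
      for (s in 1:3) {
        v <- list(M, I, D)[[s]][na + 1, j]
        if (v > esc) { esc <- v; ei <- na + 1; ej <- j; est <- s }
      }
    }
    for (i in na:1) {
      for (s in 1:3) {
        v <- list(M, I, D)[[s]][i, nb + 1]
        if (v > esc) { esc <- v; ei <- i; ej <- nb + 1; est <- s }
      }
    }
  }
  ra <- rb <- character(0)
  # trailing free gaps
  if (ej <= nb) for (j in nb:ej) { ra <- c("-", ra); rb <- c(B[j], rb) }
  if (ei <= na) for (i in na:ei) { ra <- c(A[i], ra); rb <- c("-", rb) }
  i <- ei; j <- ej; st <- est
  while (i > 1 && j > 1) {
    if (st == 1L) {
      tb <- tM[i, j]
      ra <- c(A[i - 1], ra); rb <- c(B[j - 1], rb)
      i <- i - 1; j <- j - 1; st <- tb
    } else if (st == 2L) {
      tb <- tI[i, j]
      ra <- c(A[i - 1], ra); rb <- c("-", rb)
      i <- i - 1; st <- tb
    } else {
      tb <- tD[i, j]
      ra <- c("-", ra); rb <- c(B[j - 1], rb)
      j <- j - 1; st <- tb
    }
  }
  while (i > 1) { ra <- c(A[i - 1], ra); rb <- c("-", rb); i <- i - 1 }
  while (j > 1) { ra <- c("-", ra); rb <- c(B[j - 1], rb); j <- j - 1 }
  list(aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""), score = esc)
}

oracle_counts <- function(aligned_a, aligned_b, exclude_terminal = TRUE) {
  a <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  n <- length(a)
  from <- 1; to <- n
  if (exclude_terminal) {
    while (from <= n && (a[from] == "-" || b[from] == "-")) from <- from + 1
    while (to >= from && (a[to] == "-" || b[to] == "-")) to <- to - 1
  }
  if (from > to) {
    return(list(n_match = 0L, n_sub = 0L, n_ins = 0L, n_del = 0L))
  }
  idx <- from:to
  list(n_match = sum(a[idx] != "-" & b[idx] != "-" & a[idx] == b[idx]),
       n_sub = sum(a[idx] != "-" & b[idx] != "-" & a[idx] != b[idx]),
       n_ins = sum(b[idx] == "-"),
       n_del = sum(a[idx] == "-"))
}

oracle_diffs <- function(a, b) {
  aln <- oracle_align(a, b, free_ends = FALSE)
  cts <- oracle_counts(aln$aligned_a, aln$aligned_b)
  cts$n_sub + cts$n_ins + cts$n_del
}

oracle_best_ref <- function(read, refs) {
  best <- 1L; best_d <- Inf; best_cts <- NULL
  for (k in seq_along(refs)) {
    aln <- oracle_align(read, refs[[k]])
    cts <- oracle_counts(aln$aligned_a, aln$aligned_b)
    d <- cts$n_sub + cts$n_ins + cts$n_del
    if (d < best_d) { best_d <- d; best <- k; best_cts <- cts }
  }
  c(list(ref = best, diffs = best_d), best_cts)
}

# naive O(n^3) average-linkage agglomeration: merge the pair of clusters with
# the smallest unweighted mean cross-pair distance while it is <= cutoff
oracle_average_neighbor <- function(dm, cutoff) {
  clusters <- as.list(seq_len(nrow(dm)))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (x in seq_len(length(clusters) - 1)) {
      for (y in (x + 1):length(clusters)) {
        d <- mean(dm[clusters[[x]], clusters[[y]]])
        if (d < best_d) { best_d <- d; best <- c(x, y) }
      }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  memb <- integer(nrow(dm))
  for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
  memb
}

# partition equality up to label permutation
same_partition <- function(m1, m2) {
  identical(as.integer(factor(m1, levels = unique(m1))),
            as.integer(factor(m2, levels = unique(m2))))
}

# brute-force re-implementation of the greedy pre-clustering rule using the
# oracle aligner for difference counts
oracle_precluster <- function(sequences, abundances, threshold) {
  ord <- order(-abundances, sequences)
  sequences <- sequences[ord]; abundances <- abundances[ord]
  reps <- integer(0)
  out_ab <- numeric(0)
  rep_of <- integer(length(sequences))
  for (i in seq_along(sequences)) {
    hit <- NA
    for (r in seq_along(reps)) {
      if (oracle_diffs(sequences[i], sequences[reps[r]]) <= threshold) {
        hit <- r; break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, i); out_ab <- c(out_ab, abundances[i])
      rep_of[i] <- length(reps)
    } else {
      out_ab[hit] <- out_ab[hit] + abundances[i]
      rep_of[i] <- hit
    }
  }
  data.frame(sequence = sequences[reps], abundance = out_ab)
}

# exhaustive bimera enumeration: one product per internal column of the
# parents' pairwise (plain-R) global alignment, degapped, parents excluded
oracle_chimeras <- function(refs) {
  out <- character(0)
  for (i in seq_along(refs)) {
    for (j in seq_along(refs)) {
      if (i == j) next
      aln <- oracle_align(refs[i], refs[j], free_ends = FALSE)
      a <- strsplit(aln$aligned_a, "")[[1]]
      b <- strsplit(aln$aligned_b, "")[[1]]
      for (bp in 1:(length(a) - 1)) {
        chim <- paste(c(a[1:bp], b[(bp + 1):length(b)]), collapse = "")
        out <- c(out, gsub("-", "", chim, fixed = TRUE))
      }
    }
  }
  setdiff(unique(out), refs)
}

# Monte-Carlo rarefaction
oracle_rarefy_mc <- function(ab, depth, n_rep) {
  pool <- rep.int(seq_along(ab), ab)
  mean(vapply(seq_len(n_rep), function(i) length(unique(sample(pool, depth))),
              numeric(1)))
}
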