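# Fixture builders and independent oracles used across the suite.

rnd_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exactly k substitutions, each to a different base
mutate_n <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in sample(length(ch), k)) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

# a family of n sequences, each k substitutions away from the base
seq_family <- function(base, n, k = 2L) {
  vapply(seq_len(n), function(i) mutate_n(base, k), character(1))
}

default_sub_matrix <- function(scoring = alignment_scoring()) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = TRUE)
}

# independent exhaustive Smith-Waterman oracle (Biostrings), coordinates
# converted to 0-based half-open
oracle_local <- function(q, s, scoring = alignment_scoring()) {
  pa <- Biostrings::pairwiseAlignment(
    q, s, type = "local",
    substitutionMatrix = default_sub_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  list(score = Biostrings::score(pa),
       q_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
       q_end = Biostrings::end(Biostrings::pattern(pa)),
       s_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
       s_end = Biostrings::end(Biostrings::subject(pa)))
}

# independent identity oracle: ends-free alignment, identities over the
# shorter sequence (Biostrings PID3 convention)
oracle_identity <- function(a, b, scoring = alignment_scoring()) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "overlap",
    substitutionMatrix = default_sub_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  Biostrings::pid(pa, type = "PID3") / 100
}

# the greedy clustering rule re-implemented over the oracle identity
oracle_greedy <- function(seqs, threshold, scoring = alignment_scoring()) {
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  reps <- character(0)
  membership <- character(0)
  for (id in names(seqs)) {
    placed <- FALSE
    for (r in reps) {
      if (oracle_identity(seqs[[id]], seqs[[r]], scoring) >= threshold) {
        membership[[id]] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, id); membership[[id]] <- id }
  }
  membership
}

# naive per-window mismatch recount straight off the alignment strings
oracle_scan <- function(aln, window, min_mismatches) {
  qchars <- strsplit(aln$query_row, "", fixed = TRUE)[[1]]
  refs <- lapply(aln$reference_rows, function(r) strsplit(r, "", fixed = TRUE)[[1]])
  qcols <- which(qchars != "-")
  L <- length(qcols)
  n_win <- L - window + 1L
  frac <- numeric(n_win)
  for (w in seq_len(n_win)) {
    cols <- qcols[w]:qcols[w + window - 1L]
    if (length(refs) == 0L) { frac[w] <- 1; next }
    differs <- vapply(refs, function(rc) {
      mm <- 0L
      for (cc in cols) {
        qc <- qchars[cc]; rc1 <- rc[cc]
        same <- (qc == rc1) && (qc %in% c("A", "C", "G", "T", "-"))
        if (!same) mm <- mm + 1L
      }
      mm >= min_mismatches
    }, logical(1))
    frac[w] <- mean(differs)
  }
  frac
}

# small well-separated multi-group read fixture for OTU selection tests:
# each group's reads come from its own unrelated source sequence
separated_groups <- function(n_groups = 6L, reads_per_group = 12L,
                             read_len = 250L, seed = 7L) {
  withr::with_seed(seed, {
    sources <- vapply(seq_len(n_groups), function(i) rnd_dna(read_len),
                      character(1))
    reads <- lapply(seq_len(n_groups), function(g) {
      rs <- vapply(seq_len(reads_per_group), function(i) {
        mutate_n(sources[g], 2L)
      }, character(1))
      names(rs) <- sprintf("g%d_read_%02d", g, seq_len(reads_per_group))
      rs
    })
    names(reads) <- sprintf("group%d", seq_len(n_groups))
    list(reads = reads, sources = sources)
  })
}
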