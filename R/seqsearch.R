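# Shared sequence-algorithm core: k-mer seeded local alignment search with
# Karlin-Altschul E-values, and CD-HIT-style greedy identity clustering.

#' Alignment scoring parameters
#'
#' Match/mismatch and affine gap scores used throughout the package. A gap
#' of length L costs `gap_open + L * gap_extend`. Defaults approximate
#' megablast-like stringency for nucleotide search.
#'
#' @param match Match reward (positive integer).
#' @param mismatch Mismatch penalty (negative integer).
#' @param gap_open Gap opening penalty (negative integer).
#' @param gap_extend Per-base gap extension penalty (negative integer).
#' @return A list of class `avimark_scoring`.
#' @export
alignment_scoring <- function(match = 1L, mismatch = -2L,
                              gap_open = -5L, gap_extend = -2L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0L) stop("match score must be positive", call. = FALSE)
  if (mismatch >= 0L) stop("mismatch score must be negative", call. = FALSE)
  if (gap_open > 0L || gap_extend >= 0L)
    stop("gap penalties must be negative", call. = FALSE)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "avimark_scoring")
}

#' Karlin-Altschul parameters for an ungapped scoring pair
#'
#' Computes lambda by root finding on the moment condition
#' `sum_s p_s exp(lambda s) = 1`, the relative entropy H, and K by the
#' standard partial-sum convolution series on the score lattice. The
#' resulting triple parameterizes the E-value
#' `E = K * m * n * exp(-lambda * S)`. The ungapped parameters are reused
#' for gapped scores (documented approximation).
#'
#' @param scoring An [alignment_scoring()] object (only match/mismatch used).
#' @param p_match Probability that two random letters match (0.25 for
#'   uniform base composition).
#' @return List with `lambda`, `K`, `H`.
#' @export
karlin_altschul <- function(scoring = alignment_scoring(), p_match = 0.25) {
  key <- paste("ka", scoring$match, scoring$mismatch, signif(p_match, 12),
               sep = "_")
  cached <- .avimark_cache[[key]]
  if (!is.null(cached)) return(cached)

  scores <- c(scoring$mismatch, scoring$match)
  probs <- c(1 - p_match, p_match)
  f <- function(l) sum(probs * exp(l * scores)) - 1
  lambda <- stats::uniroot(f, c(1e-8, 20), tol = 1e-14)$root
  H <- lambda * sum(scores * probs * exp(lambda * scores))

  # K via the partial-sum series: Sigma = sum_k (1/k) * [ E(e^{lambda S_k};
  # S_k < 0) + P(S_k >= 0) ], distributions of S_k by lattice convolution.
  d <- abs(Reduce(function(a, b) {
    while (b) { t <- b; b <- a %% b; a <- t }
    a
  }, abs(scores)))
  lo <- min(scores); hi <- max(scores)
  base <- numeric(hi - lo + 1)
  base[scores - lo + 1] <- base[scores - lo + 1] + probs
  cur <- base; curlo <- lo
  Sigma <- 0
  for (k in 1:500) {
    if (k > 1) {
      n1 <- length(cur); n2 <- length(base)
      out <- numeric(n1 + n2 - 1)
      for (i in seq_len(n1)) {
        rng <- i:(i + n2 - 1)
        out[rng] <- out[rng] + cur[i] * base
      }
      cur <- out; curlo <- curlo + lo
    }
    vals <- curlo + seq_along(cur) - 1
    neg <- vals < 0
    term <- sum(cur[neg] * exp(lambda * vals[neg])) + sum(cur[!neg])
    Sigma <- Sigma + term / k
    if (term / k < 1e-13) break
  }
  K <- (d * lambda * exp(-2 * Sigma)) / (H * (1 - exp(-d * lambda)))
  out <- list(lambda = lambda, K = K, H = H)
  .avimark_cache[[key]] <- out
  out
}

#' Build an exact k-mer index over a set of subject sequences
#'
#' Postings map each k-mer to (subject, 0-based offset) pairs on the
#' forward strand; reverse-strand matches are found at search time by
#' also searching the reverse complement of the query.
#'
#' @param subjects Named character vector of DNA sequences.
#' @param k Word size, between 4 and 15.
#' @return An object of class `kmer_index`.
#' @export
kmer_index <- function(subjects, k = 11L) {
  k <- as.integer(k)
  if (k < 4L || k > 15L) stop("k must be between 4 and 15", call. = FALSE)
  if (length(subjects) == 0) stop("subjects must be non-empty", call. = FALSE)
  if (is.null(names(subjects)) || anyNA(names(subjects)) || any(names(subjects) == ""))
    stop("subjects must be named", call. = FALSE)
  subjects <- toupper(subjects)
  per_subject <- lapply(subjects, function(s) {
    L <- nchar(s)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    list(kmers = substring(s, starts, starts + k - 1L), offsets = starts - 1L)
  })
  all_kmers <- unlist(lapply(per_subject, `[[`, "kmers"), use.names = FALSE)
  all_offsets <- unlist(lapply(per_subject, `[[`, "offsets"), use.names = FALSE)
  all_subjects <- rep(seq_along(subjects),
                      vapply(per_subject, function(x) length(x$kmers %||% character(0)),
                             integer(1)))
  post <- new.env(parent = emptyenv(), size = 4096L)
  if (length(all_kmers)) {
    sp <- split(seq_along(all_kmers), all_kmers)
    for (km in names(sp)) {
      idx <- sp[[km]]
      post[[km]] <- cbind(subject = all_subjects[idx], offset = all_offsets[idx])
    }
  }
  structure(list(k = k, subjects = subjects, postings = post),
            class = "kmer_index")
}

#' Look up a k-mer in an index
#'
#' @param index A [kmer_index()].
#' @param kmer A single k-mer string.
#' @return Integer matrix with columns `subject` (index into the subject
#'   set) and `offset` (0-based), zero rows when absent.
#' @export
kmer_lookup <- function(index, kmer) {
  hit <- index$postings[[toupper(kmer)]]
  if (is.null(hit)) {
    hit <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("subject", "offset")))
  }
  hit
}

#' Local alignment search of a query against a sequence database
#'
#' Exact k-mer seeds are grouped along diagonals per subject; candidate
#' subjects are aligned with banded affine-gap Smith-Waterman around the
#' seeded diagonals. Both strands are searched (via the reverse complement
#' of the query); coordinates are always reported on the subject's forward
#' strand, 0-based half-open. E-values use the Karlin-Altschul parameters
#' of the ungapped scoring pair with m = query length and n = total
#' database length.
#'
#' In `"exhaustive"` mode every subject is aligned with full (unbanded)
#' Smith-Waterman, which is exact; `"auto"` (the default) selects
#' exhaustive mode while the total number of DP cells is small and falls
#' back to the seeded heuristic for larger databases.
#'
#' @param query DNA string (length >= k in seeded mode).
#' @param index A [kmer_index()], or a named character vector of subjects
#'   (an index is then built with word size `k`).
#' @param scoring An [alignment_scoring()].
#' @param max_evalue Report hits with E-value at or below this bound.
#' @param query_id Identifier used in the result table.
#' @param mode `"auto"`, `"seeded"` or `"exhaustive"`.
#' @param k Word size used when `index` is a plain sequence set.
#' @param band_pad Extra diagonals added on both sides of the seeded
#'   diagonal range in seeded mode.
#' @param exhaustive_cells In auto mode, the largest total DP-cell count
#'   (query length times total database length) still run exhaustively.
#' @return A data frame of hits in BLAST outfmt-6-like column order
#'   (`query_id`, `subject_id`, `identity`, `length`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `evalue`, `score`) plus a trailing `strand`
#'   column, sorted by ascending E-value, ties by descending score then
#'   subject id.
#' @export
local_search <- function(query, index, scoring = alignment_scoring(),
                         max_evalue = 10, query_id = "query",
                         mode = c("auto", "seeded", "exhaustive"),
                         k = 11L, band_pad = 48L, exhaustive_cells = 4e6) {
  mode <- match.arg(mode)
  if (is.character(index)) index <- kmer_index(index, k = k)
  stopifnot(inherits(index, "kmer_index"))
  subjects <- index$subjects
  query <- toupper(query)
  m <- nchar(query)
  n_total <- sum(nchar(subjects))
  if (m == 0L || length(subjects) == 0L) return(empty_hits())
  if (mode == "auto") {
    mode <- if (m * n_total <= exhaustive_cells) "exhaustive" else "seeded"
  }
  if (mode == "seeded" && m < index$k)
    stop("query shorter than the index word size", call. = FALSE)
  ka <- karlin_altschul(scoring)

  res <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else revcomp(query)
    if (mode == "exhaustive") {
      cand <- lapply(seq_along(subjects), function(i) {
        c(lo = -m - 1L, hi = nchar(subjects[[i]]) + 1L)
      })
      names(cand) <- as.character(seq_along(subjects))
    } else {
      cand <- seed_candidates(qs, index, band_pad)
    }
    for (ci in names(cand)) {
      i <- as.integer(ci)
      aln <- align_local_cpp(qs, subjects[[i]],
                             scoring$match, scoring$mismatch,
                             scoring$gap_open, scoring$gap_extend,
                             cand[[ci]][["lo"]], cand[[ci]][["hi"]])
      if (aln$score <= 0L) next
      ev <- ka$K * m * n_total * exp(-ka$lambda * aln$score)
      if (ev > max_evalue) next
      qse <- c(aln$q_start, aln$q_end)
      if (strand == "-") qse <- c(m - aln$q_end, m - aln$q_start)
      res[[length(res) + 1L]] <- data.frame(
        query_id = query_id, subject_id = names(subjects)[i],
        identity = aln$matches / aln$columns, length = aln$columns,
        q_start = qse[1], q_end = qse[2],
        s_start = aln$s_start, s_end = aln$s_end,
        evalue = ev, score = aln$score, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) return(empty_hits())
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$evalue, -hits$score, hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             identity = numeric(0), length = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             evalue = numeric(0), score = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

# Collect seeded subjects and their diagonal bands for one query strand.
# Diagonal of a seed = subject offset - query offset (0-based).
seed_candidates <- function(qs, index, band_pad) {
  k <- index$k
  L <- nchar(qs)
  if (L < k) return(structure(list(), names = character(0)))
  starts <- seq_len(L - k + 1L)
  kmers <- substring(qs, starts, starts + k - 1L)
  seeds <- lapply(seq_along(kmers), function(j) {
    hit <- index$postings[[kmers[j]]]
    if (is.null(hit)) return(NULL)
    cbind(hit[, "subject"], hit[, "offset"] - (starts[j] - 1L))
  })
  seeds <- do.call(rbind, seeds)
  if (is.null(seeds)) return(structure(list(), names = character(0)))
  # chain seeds along diagonals: the band spans diagonals supported by at
  # least two seeds (stray single-seed diagonals from chance k-mer repeats
  # would widen the band to near-full width); with no such diagonal, the
  # best-supported single diagonal is used
  lapply(split(seeds[, 2], seeds[, 1]), function(d) {
    tab <- table(d)
    good <- as.integer(names(tab))[tab >= 2L]
    if (!length(good)) good <- as.integer(names(tab))[which.max(tab)]
    c(lo = min(good) - band_pad, hi = max(good) + band_pad)
  })
}

#' Write a hit table to TSV
#'
#' BLAST outfmt-6-like columns with 0-based half-open coordinates
#' (documented divergence from BLAST's 1-based closed convention).
#'
#' @param hits Data frame from [local_search()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise identity between two sequences (CD-HIT convention)
#'
#' Ends-free (overlap) global alignment; identity is the number of
#' identical aligned bases divided by the length of the shorter sequence.
#'
#' @param a,b DNA strings.
#' @param scoring An [alignment_scoring()].
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, scoring = alignment_scoring()) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  aln <- align_overlap_cpp(a, b, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend)
  aln$matches / min(nchar(a), nchar(b))
}

#' Greedy incremental identity clustering
#'
#' CD-HIT-style algorithm: sequences are sorted by decreasing length
#' (ties by ascending id); the first founds a cluster, and each subsequent
#' sequence joins the first existing cluster whose representative it
#' matches at or above the identity threshold (identity over the shorter
#' sequence's length), else founds a new cluster. Representatives are
#' therefore always a longest member of their cluster.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param identity Identity threshold in (0, 1].
#' @param scoring An [alignment_scoring()].
#' @return Object of class `avimark_clusters`: list with `clusters` (each
#'   a list with `representative_id`, `member_ids`), `membership` (named
#'   vector id -> representative id) and `threshold`.
#' @export
greedy_cluster <- function(seqs, identity = 0.97,
                           scoring = alignment_scoring()) {
  if (identity <= 0 || identity > 1)
    stop("identity threshold must be in (0, 1]", call. = FALSE)
  if (length(seqs) == 0L) {
    return(structure(list(clusters = list(), membership = character(0),
                          threshold = identity), class = "avimark_clusters"))
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names", call. = FALSE)
  seqs <- toupper(seqs)
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  reps <- character(0)           # representative ids in founding order
  members <- list()
  membership <- character(0)
  for (id in names(seqs)) {
    s <- seqs[[id]]
    placed <- FALSE
    for (r in reps) {
      if (pairwise_identity(s, seqs[[r]], scoring) >= identity) {
        members[[r]] <- c(members[[r]], id)
        membership[[id]] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[id]] <- id
      membership[[id]] <- id
    }
  }
  clusters <- lapply(reps, function(r) {
    list(representative_id = r, member_ids = members[[r]])
  })
  structure(list(clusters = clusters, membership = membership,
                 threshold = identity),
            class = "avimark_clusters")
}

#' @export
print.avimark_clusters <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$member_ids), integer(1))
  cat(sprintf("avimark clusters: %d clusters over %d sequences (threshold %.2f)\n",
              length(x$clusters), length(x$membership), x$threshold))
  if (length(sizes)) cat("cluster sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Cluster membership as a data frame
#'
#' @param x An `avimark_clusters` object.
#' @param ... Unused.
#' @return Data frame with columns `id`, `representative_id`.
#' @export
as.data.frame.avimark_clusters <- function(x, ...) {
  data.frame(id = names(x$membership),
             representative_id = unname(x$membership),
             stringsAsFactors = FALSE)
}
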