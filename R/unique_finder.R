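# Marker-discovery core: gather database homologs of a candidate sequence,
# reduce redundancy, build a query-anchored trimmed alignment, and scan for
# windows in which the candidate differs from (nearly) all homologs.

#' Gather database homologs of a candidate sequence
#'
#' Runs [local_search()] against the reference database and extracts, for
#' each hit, the subject subsequence spanning the hit
#' (reverse-complemented for minus-strand hits so all homolog
#' subsequences are query-co-oriented). No homologs is a valid outcome:
#' every window of the candidate is then unique by definition.
#'
#' @param query Candidate DNA string.
#' @param db Named character vector of reference sequences, or a
#'   [kmer_index()] over them.
#' @param max_evalue Homolog inclusion bound (default 1e-10).
#' @param scoring An [alignment_scoring()].
#' @param ... Passed on to [local_search()].
#' @return List with `hits` (the hit table) and `homologs` (named
#'   character vector of hit-spanning subject subsequences).
#' @export
gather_homologs <- function(query, db, max_evalue = 1e-10,
                            scoring = alignment_scoring(), ...) {
  if (is.character(db)) db <- kmer_index(db)
  hits <- local_search(query, db, scoring = scoring,
                       max_evalue = max_evalue, ...)
  if (nrow(hits) == 0L)
    return(list(hits = hits, homologs = character(0)))
  subs <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- db$subjects[[hits$subject_id[i]]]
    frag <- substr(s, hits$s_start[i] + 1L, hits$s_end[i])
    if (hits$strand[i] == "-") frag <- revcomp(frag)
    subs[i] <- frag
  }
  names(subs) <- make.unique(hits$subject_id, sep = "/hit")
  list(hits = hits, homologs = subs)
}

#' Reduce redundancy among homolog subsequences
#'
#' Greedy identity clustering ([greedy_cluster()], default threshold
#' 0.95); the longest representative of each cluster is retained, in
#' order of the cluster's first appearance in the input.
#'
#' @param homologs Named character vector of homolog subsequences.
#' @param identity Clustering identity threshold.
#' @param scoring An [alignment_scoring()].
#' @return Named character vector of cluster representatives.
#' @export
dedupe_homologs <- function(homologs, identity = 0.95,
                            scoring = alignment_scoring()) {
  if (length(homologs) == 0L) return(character(0))
  cl <- greedy_cluster(homologs, identity = identity, scoring = scoring)
  rep_ids <- vapply(cl$clusters, `[[`, character(1), "representative_id")
  first_seen <- vapply(cl$clusters, function(x) {
    min(match(x$member_ids, names(homologs)))
  }, numeric(1))
  rep_ids <- rep_ids[order(first_seen)]
  homologs[rep_ids]
}

#' Query-anchored star alignment, trimmed to the query span
#'
#' Each representative is globally aligned to the query with free end
#' gaps (ends-free Needleman-Wunsch, same scoring defaults as the search
#' layer); the pairwise alignments are merged on the query coordinate
#' frame ("once a gap, always a gap"), and columns outside the query's
#' first and last aligned positions are removed. Choosing the query as
#' the star centre makes trimming and coordinate mapping exact, at the
#' cost of not being a general-purpose multiple aligner.
#'
#' @param query Candidate DNA string (ungapped).
#' @param representatives Named character vector of homolog
#'   representatives (may be empty).
#' @param query_id Identifier carried into the result.
#' @param scoring An [alignment_scoring()].
#' @return Object of class `trimmed_alignment`: list with `query_id`,
#'   `query` (ungapped query), `query_row` (gapped), `reference_rows`
#'   (named character vector of gapped rows, all the same width), and
#'   `column_span` (0-based half-open span on the ungapped query).
#' @export
align_to_query <- function(query, representatives, query_id = "query",
                           scoring = alignment_scoring()) {
  query <- toupper(query)
  L <- nchar(query)
  n_ref <- length(representatives)
  if (n_ref == 0L) {
    return(structure(list(query_id = query_id, query = query,
                          query_row = query,
                          reference_rows = character(0),
                          column_span = c(0L, L)),
                     class = "trimmed_alignment"))
  }
  # per representative: inserted string before each query position
  # (slots 1..L; insertions before position 1 or after position L fall
  # outside the query span and are trimmed), plus the aligned symbol at
  # each query position.
  ins <- matrix("", nrow = n_ref, ncol = L + 1L)   # slot j = before query pos j
  sym <- matrix("-", nrow = n_ref, ncol = L)
  for (r in seq_len(n_ref)) {
    aln <- align_overlap_cpp(query, toupper(representatives[[r]]),
                             scoring$match, scoring$mismatch,
                             scoring$gap_open, scoring$gap_extend)
    qa <- strsplit(aln$q_aln, "", fixed = TRUE)[[1]]
    sa <- strsplit(aln$s_aln, "", fixed = TRUE)[[1]]
    qpos <- 0L
    for (cidx in seq_along(qa)) {
      if (qa[cidx] == "-") {
        ins[r, qpos + 1L] <- paste0(ins[r, qpos + 1L], sa[cidx])
      } else {
        qpos <- qpos + 1L
        sym[r, qpos] <- sa[cidx]
      }
    }
  }
  # merged column widths: max insertion length per interior slot
  # (slots 1 and L+1 trimmed: outside the query's aligned span)
  ins_len <- apply(ins, 2L, function(x) max(nchar(x)))
  ins_len[c(1L, L + 1L)] <- 0L
  pad <- function(x, w) paste0(x, strrep("-", w - nchar(x)))
  qchars <- strsplit(query, "", fixed = TRUE)[[1]]
  query_row <- paste(vapply(seq_len(L), function(j) {
    paste0(strrep("-", ins_len[j]), qchars[j])
  }, character(1)), collapse = "")
  reference_rows <- vapply(seq_len(n_ref), function(r) {
    paste(vapply(seq_len(L), function(j) {
      paste0(pad(if (j == 1L) "" else ins[r, j], ins_len[j]), sym[r, j])
    }, character(1)), collapse = "")
  }, character(1))
  names(reference_rows) <- names(representatives)
  structure(list(query_id = query_id, query = query, query_row = query_row,
                 reference_rows = reference_rows,
                 column_span = c(0L, L)),
            class = "trimmed_alignment")
}

#' @export
print.trimmed_alignment <- function(x, ...) {
  cat(sprintf("trimmed_alignment '%s': %d reference rows, %d columns, span [%d, %d)\n",
              x$query_id, length(x$reference_rows), nchar(x$query_row),
              x$column_span[1], x$column_span[2]))
  invisible(x)
}

#' Write a trimmed alignment as aligned FASTA
#'
#' @param aln A `trimmed_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  rows <- c(stats::setNames(aln$query_row, aln$query_id), aln$reference_rows)
  lines <- as.vector(rbind(paste0(">", names(rows)), unname(rows)))
  writeLines(lines, path)
  invisible(path)
}

#' Scan a trimmed alignment for host-unique windows
#'
#' A window of fixed length slides over the ungapped query positions
#' (step 1). For each window and each reference row, mismatches are
#' counted over the alignment columns covering the window's query
#' positions: a gap or a non-identical symbol in the reference row is a
#' mismatch, and a reference row with no aligned residue in the window
#' counts as fully mismatched (absence of a homologous segment is
#' evidence of uniqueness). A reference row "differs" iff its mismatch
#' count reaches `min_mismatches`; the window's difference fraction is
#' the fraction of reference rows that differ (1.0 when there are no
#' reference rows), and the window is flagged iff that fraction reaches
#' `difference_threshold`.
#'
#' @param aln A `trimmed_alignment` from [align_to_query()].
#' @param window Window length on the ungapped query (default 18, probe
#'   sized).
#' @param difference_threshold Flagging threshold on the difference
#'   fraction (default 0.90).
#' @param min_mismatches Mismatches needed for a reference row to count
#'   as differing (default 2: a single mismatch rarely prevents
#'   hybridization).
#' @param per_column Alternative per-column reading of the difference
#'   fraction: the mean mismatch fraction over all row-by-column cells of
#'   the window (default `FALSE`, the per-sequence reading).
#' @return Data frame of windows in coordinate order: `q_start` (0-based
#'   on the ungapped query), `length`, `difference_fraction`, `flagged`,
#'   `window_sequence`. Empty (with a warning) when the window exceeds
#'   the trimmed query length.
#' @export
scan_windows <- function(aln, window = 18L, difference_threshold = 0.90,
                         min_mismatches = 2L, per_column = FALSE) {
  window <- as.integer(window)
  L <- nchar(aln$query)
  empty <- data.frame(q_start = integer(0), length = integer(0),
                      difference_fraction = numeric(0), flagged = logical(0),
                      window_sequence = character(0), stringsAsFactors = FALSE)
  if (window > L) {
    warning("window longer than the trimmed query; no windows emitted")
    return(empty)
  }
  qchars <- strsplit(aln$query_row, "", fixed = TRUE)[[1]]
  qcols <- which(qchars != "-")          # column of each ungapped query position
  n_ref <- length(aln$reference_rows)
  n_win <- L - window + 1L
  q_starts <- 0:(n_win - 1L)
  win_seq <- substring(aln$query, q_starts + 1L, q_starts + window)
  if (n_ref == 0L) {
    frac <- rep(1.0, n_win)
  } else {
    acgt <- c("A", "C", "G", "T")
    # per-row cumulative mismatch counts over alignment columns
    col_from <- qcols[q_starts + 1L]
    col_to <- qcols[q_starts + window]
    mm_win <- matrix(0L, nrow = n_ref, ncol = n_win)
    ncol_win <- col_to - col_from + 1L
    for (r in seq_len(n_ref)) {
      rchars <- strsplit(aln$reference_rows[[r]], "", fixed = TRUE)[[1]]
      mm <- (qchars != rchars) | (qchars == rchars & !(qchars %in% c(acgt, "-")))
      cs <- c(0L, cumsum(mm))
      mm_win[r, ] <- cs[col_to + 1L] - cs[col_from]
    }
    if (per_column) {
      frac <- colSums(mm_win) / (n_ref * ncol_win)
    } else {
      frac <- colSums(mm_win >= min_mismatches) / n_ref
    }
  }
  data.frame(q_start = q_starts, length = window,
             difference_fraction = frac,
             flagged = frac >= difference_threshold,
             window_sequence = win_seq, stringsAsFactors = FALSE)
}

#' Merge runs of flagged windows into candidate regions
#'
#' Maximal runs of consecutive flagged windows are merged into regions
#' `[first q_start, last q_start + window)` suitable for probe/primer
#' design; each region carries the minimum and mean difference fraction
#' of its windows.
#'
#' @param windows Data frame from [scan_windows()].
#' @return Data frame of regions: `q_start`, `q_end`, `n_windows`,
#'   `min_difference`, `mean_difference`, `region_sequence` (when the
#'   windows carry sequences a region sequence is reassembled from them).
#' @export
merge_flagged <- function(windows) {
  empty <- data.frame(q_start = integer(0), q_end = integer(0),
                      n_windows = integer(0), min_difference = numeric(0),
                      mean_difference = numeric(0),
                      region_sequence = character(0), stringsAsFactors = FALSE)
  fl <- windows[windows$flagged, , drop = FALSE]
  if (nrow(fl) == 0L) return(empty)
  w <- windows$length[1]
  run_id <- cumsum(c(1L, diff(fl$q_start) != 1L))
  out <- do.call(rbind, lapply(split(fl, run_id), function(run) {
    first <- run$q_start[1]; last <- run$q_start[nrow(run)]
    seq_full <- paste0(run$window_sequence[1],
                       paste(substring(run$window_sequence[-1], w, w),
                             collapse = ""))
    data.frame(q_start = first, q_end = last + w, n_windows = nrow(run),
               min_difference = min(run$difference_fraction),
               mean_difference = mean(run$difference_fraction),
               region_sequence = seq_full, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Full uniqueness scan of one candidate against a reference database
#'
#' Convenience wrapper chaining [gather_homologs()],
#' [dedupe_homologs()], [align_to_query()], [scan_windows()] and
#' [merge_flagged()].
#'
#' @param query Candidate DNA string.
#' @param db Named character vector of reference sequences or a
#'   [kmer_index()].
#' @param query_id Candidate identifier.
#' @param max_evalue Homolog inclusion bound (default 1e-10).
#' @param cluster_identity Redundancy-reduction threshold (default 0.95).
#' @param window,difference_threshold,min_mismatches,per_column See
#'   [scan_windows()].
#' @param scoring An [alignment_scoring()].
#' @return List with `hits`, `homologs`, `representatives`, `alignment`,
#'   `windows`, `regions`.
#' @export
find_unique <- function(query, db, query_id = "query", max_evalue = 1e-10,
                        cluster_identity = 0.95, window = 18L,
                        difference_threshold = 0.90, min_mismatches = 2L,
                        per_column = FALSE, scoring = alignment_scoring()) {
  gh <- gather_homologs(query, db, max_evalue = max_evalue,
                        scoring = scoring, query_id = query_id)
  reps <- dedupe_homologs(gh$homologs, identity = cluster_identity,
                          scoring = scoring)
  aln <- align_to_query(query, reps, query_id = query_id, scoring = scoring)
  windows <- scan_windows(aln, window = window,
                          difference_threshold = difference_threshold,
                          min_mismatches = min_mismatches,
                          per_column = per_column)
  regions <- merge_flagged(windows)
  list(hits = gh$hits, homologs = gh$homologs, representatives = reps,
       alignment = aln, windows = windows, regions = regions)
}
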