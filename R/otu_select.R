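# Group-exclusive OTU selection from grouped amplicon read sets.

#' Quality pre-filter for amplicon reads
#'
#' Reproduces the usual pyrosequencing library pre-filter: minimum read
#' length, no ambiguous bases, and (when per-base qualities are supplied)
#' a minimum mean quality score. Without qualities only the length and
#' ambiguity rules apply.
#'
#' @param reads Named list of named character vectors (one per group).
#' @param qualities Optional named list matching `reads`, each element a
#'   list/vector of numeric quality vectors per read.
#' @param min_length Minimum read length kept (default 200).
#' @param min_quality Minimum mean quality score (default 25).
#' @param max_ambiguous Maximum number of non-ACGT bases allowed (default 0).
#' @return Filtered `reads` list.
#' @export
filter_reads <- function(reads, qualities = NULL, min_length = 200L,
                         min_quality = 25, max_ambiguous = 0L) {
  out <- lapply(names(reads), function(g) {
    rs <- toupper(reads[[g]])
    keep <- nchar(rs) >= min_length &
      (nchar(rs) - vapply(gregexpr("[ACGT]", rs),
                          function(m) sum(m > 0L), integer(1))) <= max_ambiguous
    if (!is.null(qualities) && !is.null(qualities[[g]])) {
      mq <- vapply(qualities[[g]], mean, numeric(1))
      keep <- keep & mq >= min_quality
    }
    rs[keep]
  })
  names(out) <- names(reads)
  out
}

#' Pick OTUs from grouped read sets by greedy identity clustering
#'
#' Pools all groups' reads and clusters them with [greedy_cluster()] at
#' the identity threshold (default 0.97, the usual species-level proxy).
#' Per-group read counts are tallied per cluster and the cluster
#' representative (a longest member) becomes the OTU representative.
#'
#' @param reads Named list (group -> named character vector of reads).
#'   Read ids must be unique across groups.
#' @param identity Clustering identity threshold.
#' @param scoring An [alignment_scoring()].
#' @return Object of class `otu_set`: list with `counts` (integer matrix,
#'   OTU x group), `representatives` (named character vector of
#'   representative sequences), `members` (list OTU -> read ids),
#'   `read_groups` (named vector read id -> group) and `clusters`.
#' @export
pick_otus <- function(reads, identity = 0.97, scoring = alignment_scoring()) {
  if (length(reads) == 0L || all(lengths(reads) == 0L))
    stop("at least one non-empty read group is required", call. = FALSE)
  read_groups <- rep(names(reads), lengths(reads))
  pooled <- unlist(unname(reads))
  if (anyDuplicated(names(pooled)))
    stop("read ids must be unique across groups", call. = FALSE)
  names(read_groups) <- names(pooled)
  cl <- greedy_cluster(pooled, identity = identity, scoring = scoring)
  otu_ids <- sprintf("OTU_%04d", seq_along(cl$clusters))
  counts <- matrix(0L, nrow = length(cl$clusters), ncol = length(reads),
                   dimnames = list(otu_ids, names(reads)))
  members <- vector("list", length(cl$clusters))
  names(members) <- otu_ids
  reps <- character(length(cl$clusters))
  for (i in seq_along(cl$clusters)) {
    mem <- cl$clusters[[i]]$member_ids
    members[[i]] <- mem
    reps[i] <- pooled[[cl$clusters[[i]]$representative_id]]
    tab <- table(read_groups[mem])
    counts[i, names(tab)] <- as.integer(tab)
  }
  names(reps) <- otu_ids
  structure(list(counts = counts, representatives = reps, members = members,
                 read_groups = read_groups, clusters = cl,
                 identity = identity),
            class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("otu_set: %d OTUs over %d reads in %d groups (identity %.2f)\n",
              nrow(x$counts), length(x$read_groups), ncol(x$counts),
              x$identity))
  invisible(x)
}

#' Write an OTU count table to TSV
#'
#' Rows are OTUs, columns sample groups (spreadsheet-importable).
#'
#' @param otus An `otu_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(otus, path) {
  df <- data.frame(otu_id = rownames(otus$counts), otus$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select OTUs exclusive to a single sample group
#'
#' An OTU is table-exclusive iff exactly one group has a positive read
#' count and that count reaches `min_reads` (default 8). "Assigned only
#' to a single group" is read strictly: zero reads in all other groups.
#'
#' @param otus An `otu_set`, or a count matrix (OTU x group).
#' @param min_reads Minimum read support in the owning group.
#' @return Data frame of exclusivity calls: `otu_id`, `owner_group`
#'   (`NA` when not exclusive), `table_exclusive`, `search_confirmed`
#'   (`NA` until verified), `offending_groups`, `total_reads`.
#' @export
select_exclusive <- function(otus, min_reads = 8L) {
  counts <- if (inherits(otus, "otu_set")) otus$counts else as.matrix(otus)
  if (min_reads < 1L) stop("min_reads must be >= 1", call. = FALSE)
  pos <- counts > 0L
  n_pos_groups <- rowSums(pos)
  owner_idx <- apply(counts, 1L, which.max)
  owner <- colnames(counts)[owner_idx]
  excl <- n_pos_groups == 1L & counts[cbind(seq_len(nrow(counts)), owner_idx)] >= min_reads
  data.frame(
    otu_id = rownames(counts),
    owner_group = ifelse(excl, owner, NA_character_),
    table_exclusive = unname(excl),
    search_confirmed = NA,
    offending_groups = "",
    total_reads = unname(rowSums(counts)),
    stringsAsFactors = FALSE)
}

#' Verify one exclusivity call by similarity search against grouped reads
#'
#' The OTU representative is searched ([local_search()]) against every
#' group's reads; the call is search-confirmed iff qualifying hits
#' (E-value at most `max_evalue`, and, when `min_identity` is set,
#' identity at least that floor) occur only in the owner group. Any other
#' group with a qualifying hit is reported as offending. Verification
#' never upgrades a call - it only confirms or refutes a table-exclusive
#' one.
#'
#' @param call A single-row exclusivity call (from [select_exclusive()]);
#'   must be table-exclusive.
#' @param representative The OTU representative sequence.
#' @param reads Named list of grouped reads (must contain the owner group).
#' @param max_evalue Disqualification E-value bound (default 0.001).
#' @param min_identity Optional identity floor for a hit to count as a
#'   match (default `NULL`: any hit at the E-value bound disqualifies).
#' @param scoring An [alignment_scoring()].
#' @param k Word size for the read search index (default 8, short-read
#'   verification).
#' @param index Optional pre-built [kmer_index()] over the pooled reads
#'   (avoids rebuilding when verifying many calls).
#' @return The call with `search_confirmed` and `offending_groups` set.
#' @export
verify_exclusive <- function(call, representative, reads,
                             max_evalue = 0.001, min_identity = NULL,
                             scoring = alignment_scoring(), k = 8L,
                             index = NULL) {
  call <- as.data.frame(call, stringsAsFactors = FALSE)
  if (nrow(call) != 1L) stop("verify_exclusive takes a single call", call. = FALSE)
  if (!isTRUE(call$table_exclusive))
    stop("verify_exclusive requires a table-exclusive call", call. = FALSE)
  if (!call$owner_group %in% names(reads))
    stop(sprintf("owner group '%s' absent from read sets", call$owner_group),
         call. = FALSE)
  read_groups <- rep(names(reads), lengths(reads))
  pooled <- unlist(unname(reads))
  names(read_groups) <- names(pooled)
  if (is.null(index)) index <- kmer_index(pooled, k = k)
  hits <- local_search(representative, index, scoring = scoring,
                       max_evalue = max_evalue, query_id = call$otu_id,
                       k = k)
  if (!is.null(min_identity)) hits <- hits[hits$identity >= min_identity, , drop = FALSE]
  hit_groups <- unique(read_groups[hits$subject_id])
  offending <- setdiff(hit_groups, call$owner_group)
  call$search_confirmed <- length(offending) == 0L
  call$offending_groups <- paste(sort(offending), collapse = ",")
  call
}

#' Verify all table-exclusive calls of a panel
#'
#' Applies [verify_exclusive()] to every table-exclusive row of a call
#' table (one shared read index); non-exclusive rows keep
#' `search_confirmed = NA`.
#'
#' @param otus The `otu_set` the calls came from.
#' @param calls Data frame from [select_exclusive()].
#' @param reads Named list of grouped reads.
#' @inheritParams verify_exclusive
#' @return The call table with verification columns filled in.
#' @export
verify_exclusive_panel <- function(otus, calls, reads, max_evalue = 0.001,
                                   min_identity = NULL,
                                   scoring = alignment_scoring(), k = 8L) {
  pooled <- unlist(unname(reads))
  index <- kmer_index(pooled, k = k)
  for (i in which(calls$table_exclusive)) {
    v <- verify_exclusive(calls[i, ], otus$representatives[[calls$otu_id[i]]],
                          reads, max_evalue = max_evalue,
                          min_identity = min_identity, scoring = scoring,
                          k = k, index = index)
    calls$search_confirmed[i] <- v$search_confirmed
    calls$offending_groups[i] <- v$offending_groups
  }
  calls
}
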