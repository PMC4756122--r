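# End-to-end discovery pipeline: build-db -> exclusive-otus -> find-unique,
# with a machine-readable run manifest.

#' Configuration for a discovery run
#'
#' Collects input locations and every tunable threshold of the pipeline.
#' Thresholds are validated against their documented ranges. The
#' configuration round-trips losslessly through JSON.
#'
#' @param genbank GenBank flat file path, or a parsed `reference_db`.
#' @param reads Named list: group name -> FASTA path or named character
#'   vector of reads.
#' @param out_dir Output directory (created if needed).
#' @param otu_identity OTU clustering identity (default 0.97,
#'   species-level proxy).
#' @param min_reads Minimum read support for an exclusive OTU (default 8).
#' @param verify_evalue E-value bound for exclusivity verification
#'   (default 0.001).
#' @param verify_min_identity Identity floor for a verification hit to
#'   count as a cross-group match (default 0.97: with a conserved 16S
#'   backbone every read matches every candidate at permissive E-values,
#'   so a match is defined at the species level, consistently with the
#'   OTU threshold; set `NULL` for the strict E-value-only rule).
#' @param db_evalue Homolog-gathering E-value bound (default 1e-10).
#' @param dedupe_identity Homolog redundancy threshold (default 0.95).
#' @param window,difference_threshold,min_mismatches See [scan_windows()].
#' @param min_read_length Read pre-filter length (default 200).
#' @param group_hosts Optional named character vector mapping group names
#'   to host binomials (defaults to group names with underscores read as
#'   spaces); used to exclude a candidate's own host from its uniqueness
#'   search, since the reference database stands for sources other than
#'   the focal samples.
#' @param scoring An [alignment_scoring()].
#' @return List of class `run_config`.
#' @export
run_config <- function(genbank, reads, out_dir = tempfile("avimark_run_"),
                       otu_identity = 0.97, min_reads = 8L,
                       verify_evalue = 0.001, verify_min_identity = 0.97,
                       db_evalue = 1e-10, dedupe_identity = 0.95,
                       window = 18L, difference_threshold = 0.90,
                       min_mismatches = 2L, min_read_length = 200L,
                       group_hosts = NULL, scoring = alignment_scoring()) {
  stopifnot(otu_identity > 0, otu_identity <= 1,
            dedupe_identity > 0, dedupe_identity <= 1,
            is.null(verify_min_identity) ||
              (verify_min_identity > 0 && verify_min_identity <= 1),
            min_reads >= 1L, window >= 4L,
            difference_threshold > 0, difference_threshold <= 1,
            min_mismatches >= 1L, verify_evalue > 0, db_evalue > 0)
  structure(list(genbank = genbank, reads = reads, out_dir = out_dir,
                 otu_identity = otu_identity, min_reads = as.integer(min_reads),
                 verify_evalue = verify_evalue,
                 verify_min_identity = verify_min_identity,
                 db_evalue = db_evalue, dedupe_identity = dedupe_identity,
                 window = as.integer(window),
                 difference_threshold = difference_threshold,
                 min_mismatches = as.integer(min_mismatches),
                 min_read_length = as.integer(min_read_length),
                 group_hosts = group_hosts, scoring = scoring),
            class = "run_config")
}

#' Run the full marker-discovery pipeline
#'
#' Orchestrates the two bioinformatic filtering stages and the
#' uniqueness scan: (1) build the host-annotated fecal reference
#' database; (2) pick OTUs from the grouped reads, select group-exclusive
#' ones and verify them by similarity search; (3) for every confirmed
#' candidate, scan for host-unique windows against the reference database
#' (excluding the candidate's own host records) and merge flagged windows
#' into candidate regions. All stage outputs plus a machine-readable run
#' manifest (parameters, package version, output checksums) are written
#' under `config$out_dir`. On stage failure, partial outputs are retained
#' and the manifest marks the failure point before the error is
#' re-raised.
#'
#' @param config A [run_config()].
#' @return (Invisibly) list with `manifest`, `refdb` (filtered records),
#'   `otus`, `calls`, and `candidates` (per confirmed OTU: the
#'   [find_unique()] result).
#' @export
run_discover <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "avimark discover",
    version = as.character(utils::packageVersion("avimark")),
    parameters = config[setdiff(names(config), c("genbank", "reads", "scoring"))],
    scoring = unclass(config$scoring),
    stages = list(), outputs = list())
  finish <- function(status) {
    manifest$status <- status
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      finish("failed")
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(res)),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }
  register <- function(paths) {
    for (p in paths) {
      manifest$outputs[[basename(p)]] <<- unname(tools::md5sum(p))
    }
  }

  # stage 1: reference database
  refdb <- run_stage("build_db", {
    db <- config$genbank
    if (is.character(db)) {
      if (!file.exists(db)) stop(sprintf("GenBank input '%s' not found", db))
      db <- read_genbank(db)
    }
    filt <- filter_fecal(db)
    paths <- write_refdb(filt$records, file.path(config$out_dir, "refdb"),
                         report = filt$report)
    register(paths)
    filt
  })

  # stage 2: grouped reads -> exclusive OTUs
  reads <- run_stage("load_reads", {
    rd <- lapply(config$reads, function(x) {
      # a length-1 unnamed character is a FASTA path; otherwise in-memory reads
      if (is.character(x) && length(x) == 1L && is.null(names(x))) {
        if (!file.exists(x)) stop(sprintf("read FASTA '%s' not found", x))
        read_fasta(x)
      } else x
    })
    filter_reads(rd, min_length = config$min_read_length)
  })
  otus <- run_stage("pick_otus", {
    o <- pick_otus(reads, identity = config$otu_identity,
                   scoring = config$scoring)
    p <- file.path(config$out_dir, "otu_table.tsv")
    write_otu_table(o, p)
    register(p)
    o
  })
  calls <- run_stage("exclusive_otus", {
    cl <- select_exclusive(otus, min_reads = config$min_reads)
    cl <- verify_exclusive_panel(otus, cl, reads,
                                 max_evalue = config$verify_evalue,
                                 min_identity = config$verify_min_identity,
                                 scoring = config$scoring)
    p <- file.path(config$out_dir, "exclusivity_calls.tsv")
    write.table(cl, p, sep = "\t", quote = FALSE, row.names = FALSE)
    register(p)
    cl
  })

  # stage 3: uniqueness scan per confirmed candidate
  candidates <- run_stage("find_unique", {
    group_hosts <- config$group_hosts %||%
      stats::setNames(gsub("_", " ", names(reads)), names(reads))
    confirmed <- calls[isTRUE_vec(calls$search_confirmed), , drop = FALSE]
    res <- list()
    windows_all <- list(); regions_all <- list(); region_seqs <- character(0)
    for (i in seq_len(nrow(confirmed))) {
      otu_id <- confirmed$otu_id[i]
      owner_host <- group_hosts[[confirmed$owner_group[i]]]
      rec <- refdb$records
      keep <- is.na(rec$host_normalized) | rec$host_normalized != owner_host
      db_seqs <- stats::setNames(rec$sequence[keep], rec$accession[keep])
      fu <- find_unique(otus$representatives[[otu_id]], db_seqs,
                        query_id = otu_id, max_evalue = config$db_evalue,
                        cluster_identity = config$dedupe_identity,
                        window = config$window,
                        difference_threshold = config$difference_threshold,
                        min_mismatches = config$min_mismatches,
                        scoring = config$scoring)
      fu$owner_group <- confirmed$owner_group[i]
      fu$owner_host <- owner_host
      res[[otu_id]] <- fu
      if (nrow(fu$windows)) {
        windows_all[[otu_id]] <- data.frame(query_id = otu_id,
                                            fu$windows,
                                            stringsAsFactors = FALSE)
      }
      if (nrow(fu$regions)) {
        regions_all[[otu_id]] <- data.frame(query_id = otu_id, fu$regions,
                                            stringsAsFactors = FALSE)
        rs <- fu$regions$region_sequence
        names(rs) <- sprintf("%s_region_%d_%d", otu_id, fu$regions$q_start,
                             fu$regions$q_end)
        region_seqs <- c(region_seqs, rs)
      }
    }
    wp <- file.path(config$out_dir, "unique_windows.tsv")
    win_df <- if (length(windows_all)) do.call(rbind, windows_all) else
      data.frame(query_id = character(0))
    write.table(win_df[, setdiff(names(win_df), "window_sequence")], wp,
                sep = "\t", quote = FALSE, row.names = FALSE)
    rp <- file.path(config$out_dir, "candidate_regions.tsv")
    reg_df <- if (length(regions_all)) do.call(rbind, regions_all) else
      data.frame(query_id = character(0))
    write.table(reg_df, rp, sep = "\t", quote = FALSE, row.names = FALSE)
    register(c(wp, rp))
    if (length(region_seqs)) {
      fp <- file.path(config$out_dir, "candidate_regions.fasta")
      write_fasta(region_seqs, fp)
      register(fp)
    }
    res
  })

  manifest <- finish("ok")
  invisible(list(manifest = manifest, refdb = refdb, otus = otus,
                 calls = calls, candidates = candidates))
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE
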