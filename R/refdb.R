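# Host-annotated fecal 16S reference database: GenBank flat-file parsing
# and fecal-source filtering.

#' Default fecal isolation-source search terms
#'
#' @return Character vector of terms matched case-insensitively as
#'   substrings of the `isolation_source` qualifier.
#' @export
fecal_source_terms <- function() {
  c("feces", "fecal", "faeces", "faecal", "stool")
}

#' Default common-name to binomial host mapping
#'
#' Case-insensitive exact-token lookup table used by [normalize_host()].
#' User-extensible: supply your own named vector (names are common names,
#' values binomials) or extend this one with `c()`.
#'
#' @return Named character vector.
#' @export
default_host_map <- function() {
  c(swine = "Sus scrofa", pig = "Sus scrofa", dog = "Canis lupus",
    cow = "Bos taurus", bovine = "Bos taurus", cattle = "Bos taurus",
    human = "Homo sapiens", chicken = "Gallus gallus", hen = "Gallus gallus",
    turkey = "Meleagris gallopavo", duck = "Anas platyrhynchos",
    goose = "Anser anser", stork = "Ciconia ciconia", swan = "Cygnus olor",
    horse = "Equus caballus", sheep = "Ovis aries", goat = "Capra hircus",
    mouse = "Mus musculus", rat = "Rattus norvegicus", cat = "Felis catus")
}

#' Default viral/vertebrate organism exclusion predicate
#'
#' The reference database must contain bacterial (and archaeal) 16S
#' records, so records whose source organism is viral or a vertebrate are
#' excluded. Full taxonomy resolution is an external resource; the shipped
#' default is a word-list predicate over the organism name (names
#' containing virus/phage/viroid, or matching a configurable vertebrate
#' name list). Plug in a real taxonomy by supplying any
#' `function(organism) logical` to [filter_fecal()].
#'
#' @param vertebrates Character vector of vertebrate names (binomials or
#'   common names) treated as excluded organisms.
#' @return A predicate `function(organism)` returning TRUE when the
#'   organism must be excluded.
#' @export
default_taxon_exclude <- function(vertebrates = c(
    "Homo sapiens", "Sus scrofa", "Bos taurus", "Canis lupus",
    "Gallus gallus", "Mus musculus", "Rattus norvegicus",
    "Danio rerio", "Equus caballus", "Ovis aries")) {
  viral_re <- "virus|phage|viroid|virales|viridae|satellite RNA"
  vert <- tolower(vertebrates)
  function(organism) {
    org <- tolower(trimws(as.character(organism)))
    out <- grepl(viral_re, org) | org %in% vert
    out[is.na(organism)] <- FALSE
    out
  }
}

#' Parse GenBank flat-file text into reference records
#'
#' Extracts accession, organism, the `/host` and `/isolation_source`
#' qualifiers of the source feature, and the ORIGIN sequence from each
#' LOCUS...// entry. Malformed records are collected as record-level
#' errors (attribute `"errors"`) and parsing continues.
#'
#' @param lines Character vector of flat-file lines (as from `readLines`).
#' @return A data frame of class `reference_db` with columns `accession`,
#'   `organism`, `host_raw`, `isolation_source_raw`, `length`, `sequence`;
#'   attribute `"errors"` holds messages for skipped records.
#' @export
parse_genbank <- function(lines) {
  recs <- list(); errors <- character(0)
  if (length(lines)) {
    ends <- grep("^//\\s*$", lines)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    if (length(ends) == 0L && any(nzchar(trimws(lines)))) {
      errors <- "trailing text without record terminator '//' ignored"
      starts <- integer(0)
    }
    for (b in seq_along(ends)) {
      block <- lines[starts[b]:(ends[b] - 1L)]
      rec <- tryCatch(parse_genbank_record(block),
                      error = function(e) conditionMessage(e))
      if (is.character(rec)) errors <- c(errors, rec) else recs[[length(recs) + 1L]] <- rec
    }
  }
  out <- if (length(recs)) {
    do.call(rbind, lapply(recs, as.data.frame, stringsAsFactors = FALSE))
  } else {
    data.frame(accession = character(0), organism = character(0),
               host_raw = character(0), isolation_source_raw = character(0),
               length = integer(0), sequence = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  class(out) <- c("reference_db", "data.frame")
  out
}

parse_genbank_record <- function(block) {
  locus <- grep("^LOCUS", block, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                    "\\s+")[[1]][1] else "<unknown>"
  acc_line <- grep("^ACCESSION", block, value = TRUE)
  accession <- if (length(acc_line)) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else id
  if (is.na(accession) || !nzchar(accession) || accession == "<unknown>")
    stop("record without LOCUS/ACCESSION identifier", call. = FALSE)
  org_line <- grep("^\\s{2,}ORGANISM", block, value = TRUE)
  organism <- if (length(org_line)) trimws(sub("^\\s+ORGANISM", "", org_line[1])) else NA_character_

  feat_start <- grep("^FEATURES", block)
  origin_start <- grep("^ORIGIN", block)
  host <- src <- NA_character_
  if (length(feat_start)) {
    feat_end <- if (length(origin_start)) origin_start[1] - 1L else length(block)
    feat <- paste(trimws(block[(feat_start[1] + 1L):feat_end]), collapse = " ")
    host <- qualifier_value(feat, "host")
    src <- qualifier_value(feat, "isolation_source")
    if (is.na(organism)) organism <- qualifier_value(feat, "organism")
  }
  if (!length(origin_start))
    stop(sprintf("record %s: no ORIGIN sequence", accession), call. = FALSE)
  seq_lines <- block[(origin_start[1] + 1L):length(block)]
  sequence <- toupper(gsub("[0-9 \t/]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence))
    stop(sprintf("record %s: empty ORIGIN sequence", accession), call. = FALSE)
  if (grepl("[^ACGTRYSWKMBDHVN]", sequence))
    stop(sprintf("record %s: non-IUPAC characters in sequence", accession),
         call. = FALSE)
  list(accession = accession, organism = organism, host_raw = host,
       isolation_source_raw = src, length = nchar(sequence),
       sequence = sequence)
}

qualifier_value <- function(feat_text, qualifier) {
  m <- regmatches(feat_text,
                  regexpr(sprintf('/%s="[^"]*"', qualifier), feat_text))
  if (!length(m)) return(NA_character_)
  sub(sprintf('^/%s="', qualifier), "", sub('"$', "", m[1]))
}

#' Read a GenBank flat file
#'
#' @param path Path to a flat file (plain text or gzip).
#' @return A `reference_db` data frame; see [parse_genbank()].
#' @export
read_genbank <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  parse_genbank(readLines(con, warn = FALSE))
}

#' Normalize host names to binomial species names
#'
#' Case-insensitive exact-token lookup after whitespace trimming. Names
#' that already look binomial (capitalized genus followed by a lower-case
#' epithet) pass through unchanged. Unmatched names are returned as `NA`
#' (unresolved) - never guessed.
#'
#' @param host_raw Character vector of host qualifier values.
#' @param mapping Named character vector, common name -> binomial; see
#'   [default_host_map()].
#' @return Character vector of binomials, `NA` where unresolved.
#' @export
normalize_host <- function(host_raw, mapping = default_host_map()) {
  x <- gsub("\\s+", " ", trimws(as.character(host_raw)))
  out <- rep(NA_character_, length(x))
  is_binomial <- !is.na(x) & grepl("^[A-Z][a-z]+ [a-z][a-z-]+$", x)
  out[is_binomial] <- x[is_binomial]
  key <- tolower(x)
  hit <- !is_binomial & !is.na(x) & key %in% tolower(names(mapping))
  out[hit] <- unname(mapping[match(key[hit], tolower(names(mapping)))])
  out
}

host_is_trivial <- function(host_raw) {
  x <- tolower(trimws(as.character(host_raw)))
  is.na(host_raw) | x %in% c("", "unknown", "not determined", "missing",
                             "na", "n/a", "not applicable")
}

#' Filter reference records down to host-annotated fecal 16S sequences
#'
#' A record passes iff, tested in this fixed order:
#' (a) its `isolation_source` qualifier is present and contains at least
#' one of the source terms (case-insensitive substring match, so
#' "fecal swab" passes); (b) its organism is not classified viral or
#' vertebrate by the exclusion predicate; and (c) its host qualifier is
#' present and non-trivial. Each rejected record is tallied under the
#' first failing rule, so reports are deterministic. Passing records gain
#' a `host_normalized` column via [normalize_host()] (`NA` when the host
#' cannot be resolved to a binomial).
#'
#' @param db A `reference_db` data frame from [parse_genbank()].
#' @param source_terms Source search terms; see [fecal_source_terms()].
#' @param taxon_exclude Predicate `function(organism) logical`; see
#'   [default_taxon_exclude()].
#' @param host_map Mapping for [normalize_host()].
#' @return List with `records` (the passing subset, with
#'   `host_normalized`), `report` (the filter report; see below) and
#'   `fates` (per-input-record fate strings). The report fields are
#'   `n_input`, `n_pass_source`, `n_fail_source`, `n_fail_taxon`,
#'   `n_fail_host`, `n_final`, and always satisfy
#'   `n_input = n_final + n_fail_source + n_fail_taxon + n_fail_host`.
#' @export
filter_fecal <- function(db, source_terms = fecal_source_terms(),
                         taxon_exclude = default_taxon_exclude(),
                         host_map = default_host_map()) {
  n <- nrow(db)
  src <- db$isolation_source_raw
  pass_source <- !is.na(src) &
    Reduce(`|`, lapply(source_terms, function(t) {
      grepl(t, src, ignore.case = TRUE, fixed = FALSE)
    }), rep(FALSE, n))
  excluded <- as.logical(taxon_exclude(db$organism))
  excluded[is.na(excluded)] <- FALSE
  trivial_host <- host_is_trivial(db$host_raw)

  fates <- rep("pass", n)
  fates[!pass_source] <- "fail_source"
  fates[pass_source & excluded] <- "fail_taxon"
  fates[pass_source & !excluded & trivial_host] <- "fail_host"

  records <- db[fates == "pass", , drop = FALSE]
  records$host_normalized <- normalize_host(records$host_raw, host_map)
  rownames(records) <- NULL
  class(records) <- c("reference_db", "data.frame")
  report <- list(
    n_input = n,
    n_pass_source = sum(pass_source),
    n_fail_source = sum(fates == "fail_source"),
    n_fail_taxon = sum(fates == "fail_taxon"),
    n_fail_host = sum(fates == "fail_host"),
    n_final = sum(fates == "pass"))
  list(records = records, report = report, fates = fates)
}

#' Write a filtered reference database to disk
#'
#' Writes `<prefix>.fasta` with headers
#' `>accession|host=<binomial>|src=<isolation_source>`, a TSV metadata
#' sidecar `<prefix>.tsv` and, when a report is supplied, a JSON filter
#' report `<prefix>.report.json`.
#'
#' @param records Filtered `reference_db` (with `host_normalized`).
#' @param prefix Output path prefix.
#' @param report Optional filter report list from [filter_fecal()].
#' @return Character vector of written paths, invisibly.
#' @export
write_refdb <- function(records, prefix, report = NULL) {
  headers <- sprintf("%s|host=%s|src=%s", records$accession,
                     ifelse(is.na(records$host_normalized), "NA",
                            records$host_normalized),
                     ifelse(is.na(records$isolation_source_raw), "NA",
                            records$isolation_source_raw))
  seqs <- stats::setNames(records$sequence, headers)
  paths <- c(fasta = paste0(prefix, ".fasta"), tsv = paste0(prefix, ".tsv"))
  write_fasta(seqs, paths[["fasta"]])
  meta_cols <- c("accession", "organism", "host_raw", "host_normalized",
                 "isolation_source_raw", "length")
  write.table(as.data.frame(records)[, meta_cols], paths[["tsv"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report)) {
    paths <- c(paths, report = paste0(prefix, ".report.json"))
    jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE)
  }
  invisible(paths)
}
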