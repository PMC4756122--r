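# Deterministic, seeded generators for every input the toolkit consumes,
# with ground truth for parameter-recovery tests. The defaults are the
# package's reference study conditions (documented in the methods
# vignette); all generators are pure functions of (spec, seed).

avian_hosts <- function() {
  c("Gallus gallus", "Meleagris gallopavo", "Anser anser",
    "Anas platyrhynchos", "Ciconia ciconia", "Cygnus olor")
}

#' Specification of a synthetic marker-discovery study
#'
#' Describes a multi-host 16S-like world: a shared conserved backbone
#' with hypervariable regions diverged per host, an 18+ nt fully
#' randomized host-unique segment planted per host, amplicon-style reads
#' (primer-anchored prefixes with substitution errors), and a qPCR
#' dilution-series model (log-linear Ct with Gaussian noise and logistic
#' detection dropout around the limit of detection).
#'
#' @param seed Default seed used by the generators.
#' @param n_hosts Number of host species (at most 6 named avian hosts).
#' @param backbone_length Backbone length in bp (V1-V3 amplicon sized).
#' @param n_refs_per_host Reference records per host.
#' @param variable_regions Data frame `start`, `end` (0-based half-open),
#'   `divergence` (per-host per-position mutation probability).
#' @param planted_unique Data frame `host`, `start`, `length`,
#'   `divergence` (1.0 = every position replaced); regions must not
#'   overlap each other.
#' @param within_host_noise Per-record per-position mutation probability
#'   inside the hypervariable regions (keeps a host's records distinct
#'   but nearly identical; conserved backbone positions are not touched,
#'   as strain-level 16S variation concentrates in the variable regions).
#' @param reads_per_host Reads sampled per host group.
#' @param min_read_length Shortest read (reads are record prefixes of
#'   length uniform between this and the record length, emulating
#'   3'-truncated amplicon reads).
#' @param read_error_rate Per-base substitution probability in reads
#'   (post-quality-filter substitution-specific rate; indels are out of
#'   scope).
#' @param n_fail_source,n_fail_taxon,n_fail_host Distractor records
#'   destined to fail each database filter rule.
#' @param qpcr List: `slope_magnitude`, `intercept`, `sigma_ct`,
#'   `lod_copies`, `dropout_steepness` (logistic slope per log10 copies;
#'   detection probability is 0.90 at `lod_copies`, matching the LOD
#'   definition; steepness 0 disables dropout).
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, n_hosts = 6L, backbone_length = 500L,
                       n_refs_per_host = 3L,
                       variable_regions = data.frame(
                         start = c(60L, 210L, 380L),
                         end = c(120L, 270L, 440L),
                         divergence = 0.15),
                       planted_unique = NULL,
                       within_host_noise = 0.005,
                       reads_per_host = 40L, min_read_length = 420L,
                       read_error_rate = 2e-4,
                       n_fail_source = 4L, n_fail_taxon = 3L,
                       n_fail_host = 3L,
                       qpcr = list(slope_magnitude = 3.4, intercept = 40.1,
                                   sigma_ct = 0.3, lod_copies = 5,
                                   dropout_steepness = 8)) {
  hosts <- avian_hosts()[seq_len(n_hosts)]
  if (is.null(planted_unique)) {
    starts <- c(126L, 156L, 186L, 276L, 306L, 336L)[seq_len(n_hosts)]
    planted_unique <- data.frame(host = hosts, start = starts, length = 24L,
                                 divergence = 1.0, stringsAsFactors = FALSE)
  }
  stopifnot(all(variable_regions$start >= 0),
            all(variable_regions$end <= backbone_length),
            all(variable_regions$divergence >= 0 & variable_regions$divergence <= 1),
            all(planted_unique$start >= 0),
            all(planted_unique$start + planted_unique$length <= backbone_length),
            all(planted_unique$length >= 18L),
            within_host_noise >= 0, within_host_noise <= 1,
            read_error_rate >= 0, read_error_rate <= 1,
            min_read_length <= backbone_length)
  pu <- planted_unique[order(planted_unique$start), , drop = FALSE]
  if (nrow(pu) > 1L &&
      any(utils::head(pu$start + pu$length, -1) > utils::tail(pu$start, -1)))
    stop("planted unique regions must not overlap", call. = FALSE)
  structure(list(seed = as.integer(seed), n_hosts = as.integer(n_hosts),
                 hosts = hosts, backbone_length = as.integer(backbone_length),
                 n_refs_per_host = as.integer(n_refs_per_host),
                 variable_regions = variable_regions,
                 planted_unique = planted_unique,
                 within_host_noise = within_host_noise,
                 reads_per_host = as.integer(reads_per_host),
                 min_read_length = as.integer(min_read_length),
                 read_error_rate = read_error_rate,
                 n_fail_source = as.integer(n_fail_source),
                 n_fail_taxon = as.integer(n_fail_taxon),
                 n_fail_host = as.integer(n_fail_host),
                 qpcr = qpcr),
            class = "synth_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate positions `at` (1-based) of `seq` to a different base each
mutate_positions <- function(seq, at) {
  if (length(at) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in at) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

mutate_at_rate <- function(seq, rate, from = 1L, to = nchar(seq)) {
  if (rate <= 0) return(seq)
  span <- from:to
  hit <- span[runif(length(span)) < rate]
  mutate_positions(seq, hit)
}

#' Generate a synthetic host-annotated 16S reference database
#'
#' Per host, `n_refs_per_host` records share the backbone, mutated in the
#' hypervariable regions at the stated per-host divergence, carry that
#' host's fully randomized planted unique segment, and differ from each
#' other by a small within-host noise rate. Distractor records destined
#' to fail each database filter rule (non-fecal source, viral/vertebrate
#' organism, missing host) are appended. The truth table records every
#' record's intended filter fate and every planted region.
#'
#' @param spec A [synth_spec()].
#' @param seed Seed (defaults to `spec$seed`).
#' @return List with `genbank` (flat-file lines), `records` (data frame
#'   with sequences, fields and intended `fate`), `planted` (data frame
#'   `host`, `start`, `end`), `backbone`, and `spec`.
#' @export
make_reference_db <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(seed, {
    backbone <- random_dna(spec$backbone_length)
    host_common <- c("Gallus gallus" = "chicken",
                     "Meleagris gallopavo" = "turkey",
                     "Anser anser" = "goose",
                     "Anas platyrhynchos" = "duck",
                     "Ciconia ciconia" = "stork",
                     "Cygnus olor" = "swan")
    genera <- c("Lactobacillus", "Gallibacterium", "Fusobacterium",
                "Clostridium", "Enterococcus", "Campylobacter")
    fecal_sources <- c("fecal sample", "feces", "faeces, fresh droppings",
                       "stool", "cloacal fecal swab")
    nonfecal_sources <- c("soil", "freshwater sediment", "skin swab",
                          "activated sludge")

    host_variant <- character(spec$n_hosts)
    names(host_variant) <- spec$hosts
    for (h in seq_len(spec$n_hosts)) {
      s <- backbone
      vr <- spec$variable_regions
      for (v in seq_len(nrow(vr))) {
        s <- mutate_at_rate(s, vr$divergence[v], vr$start[v] + 1L, vr$end[v])
      }
      pu <- spec$planted_unique[spec$planted_unique$host == spec$hosts[h], ,
                                drop = FALSE]
      for (p in seq_len(nrow(pu))) {
        s <- mutate_at_rate(s, pu$divergence[p], pu$start[p] + 1L,
                            pu$start[p] + pu$length[p])
      }
      host_variant[h] <- s
    }

    recs <- list()
    add <- function(accession, organism, host_raw, src, sequence, fate,
                    host_binomial) {
      recs[[length(recs) + 1L]] <<- data.frame(
        accession = accession, organism = organism,
        host_raw = host_raw, isolation_source_raw = src,
        sequence = sequence, length = nchar(sequence), fate = fate,
        host = host_binomial, stringsAsFactors = FALSE)
    }
    idx <- 0L
    for (h in seq_len(spec$n_hosts)) {
      host <- spec$hosts[h]
      for (r in seq_len(spec$n_refs_per_host)) {
        idx <- idx + 1L
        # within-host (strain-level) noise sits in the hypervariable
        # regions; the conserved backbone stays conserved
        seq_r <- host_variant[h]
        vr <- spec$variable_regions
        for (v in seq_len(nrow(vr))) {
          seq_r <- mutate_at_rate(seq_r, spec$within_host_noise,
                                  vr$start[v] + 1L, vr$end[v])
        }
        host_raw <- if (r %% 2L == 1L) host else unname(host_common[host])
        add(sprintf("AVSYN%03d", idx),
            sprintf("%s sp. AVS%02d", genera[(h - 1L) %% length(genera) + 1L], idx),
            host_raw,
            fecal_sources[(idx - 1L) %% length(fecal_sources) + 1L],
            seq_r, "pass", host)
      }
    }
    for (i in seq_len(spec$n_fail_source)) {
      idx <- idx + 1L
      add(sprintf("AVSYN%03d", idx), sprintf("Pseudomonas sp. ENV%02d", i),
          "Sus scrofa", nonfecal_sources[(i - 1L) %% length(nonfecal_sources) + 1L],
          random_dna(spec$backbone_length), "fail_source", NA_character_)
    }
    bad_orgs <- c("Avian leukosis virus", "Enterobacteria phage T4",
                  "Sus scrofa")
    for (i in seq_len(spec$n_fail_taxon)) {
      idx <- idx + 1L
      add(sprintf("AVSYN%03d", idx), bad_orgs[(i - 1L) %% length(bad_orgs) + 1L],
          "Gallus gallus", "fecal sample",
          random_dna(spec$backbone_length), "fail_taxon", NA_character_)
    }
    for (i in seq_len(spec$n_fail_host)) {
      idx <- idx + 1L
      add(sprintf("AVSYN%03d", idx), sprintf("Bacteroides sp. NH%02d", i),
          if (i %% 2L == 1L) NA_character_ else "unknown", "feces",
          random_dna(spec$backbone_length), "fail_host", NA_character_)
    }
    records <- do.call(rbind, recs)
    planted <- data.frame(host = spec$planted_unique$host,
                          start = spec$planted_unique$start,
                          end = spec$planted_unique$start +
                            spec$planted_unique$length,
                          stringsAsFactors = FALSE)
    list(genbank = write_genbank(records), records = records,
         planted = planted, backbone = backbone, spec = spec)
  })
}

#' Render reference records as GenBank flat-file lines
#'
#' @param records Data frame with columns `accession`, `organism`,
#'   `host_raw`, `isolation_source_raw`, `sequence` (`NA` qualifiers are
#'   omitted).
#' @param path Optional output file; when given, lines are written there.
#' @return Character vector of flat-file lines (invisibly when `path` is
#'   given).
#' @export
write_genbank <- function(records, path = NULL) {
  out <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    L <- nchar(r$sequence)
    lines <- c(
      sprintf("LOCUS       %-16s %6d bp    DNA     linear   BCT 01-JAN-2000",
              r$accession, L),
      "DEFINITION  Synthetic 16S ribosomal RNA gene, partial sequence.",
      sprintf("ACCESSION   %s", r$accession),
      sprintf("SOURCE      %s", r$organism),
      sprintf("  ORGANISM  %s", r$organism),
      "            Bacteria.",
      "FEATURES             Location/Qualifiers",
      sprintf("     source          1..%d", L),
      sprintf("                     /organism=\"%s\"", r$organism))
    if (!is.na(r$host_raw))
      lines <- c(lines, sprintf("                     /host=\"%s\"", r$host_raw))
    if (!is.na(r$isolation_source_raw))
      lines <- c(lines, sprintf("                     /isolation_source=\"%s\"",
                                r$isolation_source_raw))
    lines <- c(lines, "ORIGIN")
    starts <- seq(1L, L, by = 60L)
    for (s in starts) {
      chunk <- substr(r$sequence, s, min(s + 59L, L))
      blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      lines <- c(lines, sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))))
    }
    out <- c(out, lines, "//")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Generate per-host amplicon read sets with ground-truth labels
#'
#' Reads are primer-anchored prefixes of the host's reference records
#' (length uniform between `min_read_length` and the record length),
#' with independent per-base substitution errors at `read_error_rate`.
#'
#' @param spec A [synth_spec()].
#' @param seed Seed (defaults to `spec$seed`).
#' @param db Optional reference database from [make_reference_db()]
#'   (regenerated from `(spec, seed)` when omitted).
#' @return List with `reads` (named list group -> named character
#'   vector), `truth` (data frame `read_id`, `group`, `host`,
#'   `source_accession`, `length`, `n_errors`) and `group_hosts` (named
#'   character vector, group name -> host binomial).
#' @export
make_grouped_reads <- function(spec, seed = spec$seed, db = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(db)) db <- make_reference_db(spec, seed)
  pass <- db$records[db$records$fate == "pass", , drop = FALSE]
  with_seed(seed + 1000003L, {
    reads <- list(); truth <- list()
    for (h in seq_len(spec$n_hosts)) {
      host <- spec$hosts[h]
      group <- gsub(" ", "_", host)
      srcs <- pass[pass$host == host, , drop = FALSE]
      rs <- character(spec$reads_per_host)
      ids <- sprintf("%s_read_%03d", group, seq_len(spec$reads_per_host))
      nerr <- integer(spec$reads_per_host)
      accs <- character(spec$reads_per_host)
      for (i in seq_len(spec$reads_per_host)) {
        j <- sample(nrow(srcs), 1L)
        src <- srcs$sequence[j]
        accs[i] <- srcs$accession[j]
        len <- sample(spec$min_read_length:nchar(src), 1L)
        read <- substr(src, 1L, len)
        n_err <- rbinom(1L, len, spec$read_error_rate)
        if (n_err > 0L) read <- mutate_positions(read, sample(len, n_err))
        rs[i] <- read
        nerr[i] <- n_err
      }
      names(rs) <- ids
      reads[[group]] <- rs
      truth[[group]] <- data.frame(read_id = ids, group = group, host = host,
                                   source_accession = accs,
                                   length = nchar(rs), n_errors = nerr,
                                   stringsAsFactors = FALSE)
    }
    group_hosts <- stats::setNames(spec$hosts, gsub(" ", "_", spec$hosts))
    list(reads = reads, truth = do.call(rbind, truth),
         group_hosts = group_hosts)
  })
}

#' Simulate a qPCR dilution series with detection dropout
#'
#' Ct follows `intercept - slope_magnitude * log10(copies)` with Gaussian
#' noise `sigma_ct`; each well is detected with logistic probability in
#' log10 copies, calibrated so detection probability is exactly 0.90 at
#' `lod_copies` (steepness 0 disables dropout). Undetected wells have
#' `NA` Ct.
#'
#' @param spec A [synth_spec()] (its `qpcr` component is used).
#' @param copies_levels Copy numbers of the dilution series.
#' @param seed Seed (defaults to `spec$seed`).
#' @param n_replicates Wells per level (default 9: triplicates of three
#'   independent curves).
#' @return List with `table` (data frame `copies`, `replicate`,
#'   `detected`, `ct`) and `truth` (model parameters, per-level detection
#'   probabilities, and `lod_level`, the smallest level with true
#'   detection probability >= 0.9).
#' @export
make_qpcr_series <- function(spec, copies_levels = 2 * 10^(0:8),
                             seed = spec$seed, n_replicates = 9L) {
  stopifnot(inherits(spec, "synth_spec"))
  q <- spec$qpcr
  p_detect <- if (q$dropout_steepness == 0 || q$lod_copies <= 0) {
    rep(1, length(copies_levels))
  } else {
    plogis(qlogis(0.9) + q$dropout_steepness *
             (log10(copies_levels) - log10(q$lod_copies)))
  }
  with_seed(seed + 2000003L, {
    rows <- list()
    for (i in seq_along(copies_levels)) {
      det <- runif(n_replicates) < p_detect[i]
      ct <- q$intercept - q$slope_magnitude * log10(copies_levels[i]) +
        rnorm(n_replicates, 0, q$sigma_ct)
      ct[!det] <- NA_real_
      rows[[i]] <- data.frame(copies = copies_levels[i],
                              replicate = seq_len(n_replicates),
                              detected = det, ct = ct)
    }
    qualifying <- p_detect >= 0.9 - 1e-12
    list(table = do.call(rbind, rows),
         truth = list(slope_magnitude = q$slope_magnitude,
                      intercept = q$intercept, sigma_ct = q$sigma_ct,
                      lod_copies = q$lod_copies,
                      p_detect = stats::setNames(p_detect, copies_levels),
                      lod_level = if (any(qualifying))
                        min(copies_levels[qualifying]) else NA_real_))
  })
}

#' Summarize a simulated dilution series into per-level detection counts
#'
#' @param table Data frame from [make_qpcr_series()].
#' @return Data frame `copies`, `n_positive`, `n_total` suitable for
#'   [estimate_lod()].
#' @export
qpcr_detection_counts <- function(table) {
  agg <- stats::aggregate(detected ~ copies, data = table,
                          FUN = function(x) c(sum(x), length(x)))
  data.frame(copies = agg$copies,
             n_positive = agg$detected[, 1],
             n_total = agg$detected[, 2])
}
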