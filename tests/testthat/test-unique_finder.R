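test_that("homolog gathering returns hit-spanning subsequences", {
  withr::with_seed(51, {
    q <- rnd_dna(120)
    db <- c(copy = q, bg1 = rnd_dna(150), bg2 = rnd_dna(150))
    gh <- gather_homologs(q, db, max_evalue = 1e-10)
    expect_identical(names(gh$homologs), "copy")
    expect_identical(unname(gh$homologs), q)
    # zero database relatives is a valid outcome
    gh0 <- gather_homologs(rnd_dna(120), db[c("bg1", "bg2")],
                           max_evalue = 1e-10)
    expect_length(gh0$homologs, 0L)
    # a minus-strand homolog comes back query-co-oriented
    dbrc <- c(rc = revcomp(q), bg = rnd_dna(150))
    ghrc <- gather_homologs(q, dbrc, max_evalue = 1e-10)
    expect_identical(ghrc$hits$strand[1], "-")
    expect_identical(unname(ghrc$homologs[1]), q)
  })
})

test_that("homolog gathering matches the exhaustive alignment oracle", {
  withr::with_seed(53, {
    q <- rnd_dna(150)
    db <- c(setNames(seq_family(q, 6, k = 10L), sprintf("hom%d", 1:6)),
            setNames(vapply(1:14, function(i) rnd_dna(150), character(1)),
                     sprintf("bg%02d", 1:14)))
    gh <- gather_homologs(q, db, max_evalue = 1e-10)
    ka <- karlin_altschul()
    n_total <- sum(nchar(db))
    oracle_pass <- names(db)[vapply(db, function(s) {
      sc <- oracle_local(q, s)$score
      ka$K * nchar(q) * n_total * exp(-ka$lambda * sc) <= 1e-10
    }, logical(1))]
    expect_setequal(gh$hits$subject_id[gh$hits$strand == "+"], oracle_pass)
  })
})

test_that("homolog dedup keeps the longest representative per cluster", {
  ten <- setNames(rep(strrep("ACGTC", 30), 10), paste0("h", 1:10))
  expect_length(dedupe_homologs(ten, identity = 0.95), 1L)
  withr::with_seed(57, {
    solo <- setNames(vapply(1:5, function(i) rnd_dna(120), character(1)),
                     paste0("s", 1:5))
    expect_identical(names(dedupe_homologs(solo, identity = 0.95)),
                     names(solo))
    # mixed fixture vs the all-pairs oracle clustering
    bases <- vapply(1:3, function(i) rnd_dna(160), character(1))
    seqs <- unlist(lapply(1:3, function(f) {
      setNames(seq_family(bases[f], 4, k = 2L), sprintf("f%d_%d", f, 1:4))
    }))
    reps <- dedupe_homologs(seqs, identity = 0.95)
    membership <- oracle_greedy(seqs, 0.95)
    expect_setequal(names(reps), unique(unname(membership)))
  })
})

test_that("star alignment is query-anchored and round-trips its inputs", {
  q <- "ACGTACGTACGTACGTACGT"
  # identical representative: two identical gap-free rows
  a1 <- align_to_query(q, c(r1 = q))
  expect_identical(a1$query_row, q)
  expect_identical(unname(a1$reference_rows), q)
  expect_identical(a1$column_span, c(0L, 20L))

  # representative with one internal deletion: a gap column in that row
  del <- paste0(substr(q, 1, 9), substr(q, 12, 20))
  a2 <- align_to_query(q, c(r1 = del))
  expect_identical(a2$query_row, q)            # no gap in the query row
  expect_identical(nchar(a2$reference_rows[["r1"]]), 20L)
  expect_identical(sum(strsplit(a2$reference_rows[["r1"]], "")[[1]] == "-"), 2L)

  # a representative with an internal insertion opens a query-row gap
  # (a non-repetitive query, so the gap placement is unambiguous)
  withr::with_seed(58, {
    qr <- rnd_dna(40)
    ins <- paste0(substr(qr, 1, 20), "TTTT", substr(qr, 21, 40))
    a3 <- align_to_query(qr, c(r1 = ins))
    expect_identical(gsub("-", "", a3$query_row), qr)
    expect_identical(gsub("-", "", a3$reference_rows[["r1"]]), ins)
  })

  withr::with_seed(59, {
    # several noisy representatives: de-gapping reproduces each input
    qq <- rnd_dna(200)
    reps <- setNames(lapply(1:5, function(i) {
      s <- mutate_n(qq, 6L)
      # one random internal deletion of 1-3 bases
      at <- sample(50:150, 1); w <- sample(1:3, 1)
      paste0(substr(s, 1, at - 1), substr(s, at + w, nchar(s)))
    }), paste0("r", 1:5))
    aln <- align_to_query(qq, unlist(reps))
    expect_identical(gsub("-", "", aln$query_row), qq)
    widths <- nchar(c(aln$query_row, aln$reference_rows))
    expect_length(unique(widths), 1L)
    for (r in names(reps)) {
      expect_identical(gsub("-", "", aln$reference_rows[[r]]), reps[[r]])
    }
  })
})

test_that("window scanning counts mismatches like the brute-force oracle", {
  withr::with_seed(61, {
    q <- rnd_dna(100)
    # sole identical reference row: nothing differs, nothing flagged
    a <- align_to_query(q, c(r = q))
    w <- scan_windows(a, window = 18)
    expect_identical(nrow(w), 100L - 18L + 1L)
    expect_true(all(w$difference_fraction == 0))
    expect_false(any(w$flagged))
    expect_identical(w$window_sequence[1], substr(q, 1, 18))

    # planted 30-nt randomized segment against 10 otherwise-identical
    # references: flagged windows sit exactly inside the planted segment
    seg <- c(41L, 70L) # 1-based inclusive
    qchars <- strsplit(q, "")[[1]]
    planted <- vapply(seg[1]:seg[2], function(i) {
      sample(setdiff(c("A", "C", "G", "T"), qchars[i]), 1)
    }, character(1))
    q2 <- q
    substr(q2, seg[1], seg[2]) <- paste(planted, collapse = "")
    refs <- setNames(rep(q, 10), paste0("r", 1:10))
    a2 <- align_to_query(q2, refs)
    w2 <- scan_windows(a2, window = 18, difference_threshold = 0.9,
                       min_mismatches = 2)
    oracle <- oracle_scan(a2, 18L, 2L)
    expect_equal(w2$difference_fraction, oracle)
    # fully-interior windows flagged; windows overlapping <2 planted bases not
    start0 <- seg[1] - 1L
    inside <- w2$q_start >= start0 & (w2$q_start + 18L) <= seg[2]
    expect_true(all(w2$flagged[inside]))
    outside <- (w2$q_start + 18L) <= start0 + 1L | w2$q_start >= seg[2] - 1L
    expect_false(any(w2$flagged[outside]))

    # no reference rows: every window unique by definition
    a0 <- align_to_query(q, character(0))
    w0 <- scan_windows(a0, window = 18)
    expect_true(all(w0$difference_fraction == 1))
    expect_true(all(w0$flagged))

    # degenerate: window longer than the query
    expect_warning(w_long <- scan_windows(a0, window = 200), "window longer")
    expect_identical(nrow(w_long), 0L)
  })
})

test_that("window flagging is monotone in its thresholds and dilutes", {
  withr::with_seed(63, {
    q <- rnd_dna(120)
    refs <- setNames(c(seq_family(q, 4, k = 25L), rep(q, 1)), paste0("r", 1:5))
    a <- align_to_query(q, refs)
    thresholds <- c(0.5, 0.7, 0.8, 0.9, 1.0)
    flagged_n <- vapply(thresholds, function(th) {
      sum(scan_windows(a, difference_threshold = th)$flagged)
    }, integer(1))
    expect_false(is.unsorted(rev(flagged_n)))      # raising threshold never adds
    mm <- 1:5
    frac_by_mm <- lapply(mm, function(m) {
      scan_windows(a, min_mismatches = m)$difference_fraction
    })
    for (i in seq_len(length(mm) - 1)) {           # raising min_mismatches never
      expect_true(all(frac_by_mm[[i + 1]] <= frac_by_mm[[i]]))  # raises fractions
    }
    # dilution: adding query-identical rows pushes fractions below 1 and,
    # with enough copies, unflags everything
    a1 <- align_to_query(q, c(refs, setNames(rep(q, 1), "id1")))
    w1 <- scan_windows(a1)
    expect_true(all(w1$difference_fraction < 1))
    a9 <- align_to_query(q, c(refs, setNames(rep(q, 45), paste0("id", 1:45))))
    expect_false(any(scan_windows(a9)$flagged))
  })
})

test_that("flagged windows merge into maximal runs", {
  win <- data.frame(q_start = 0:29, length = 18L,
                    difference_fraction = 0, flagged = FALSE,
                    window_sequence = strrep("A", 18))
  win$flagged[win$q_start %in% 5:7] <- TRUE
  win$difference_fraction[win$q_start %in% 5:7] <- c(0.9, 1.0, 0.95)
  reg <- merge_flagged(win)
  expect_identical(nrow(reg), 1L)
  expect_identical(reg$q_start, 5L)
  expect_identical(reg$q_end, 25L)
  expect_identical(reg$n_windows, 3L)
  expect_equal(reg$min_difference, 0.9)

  expect_identical(nrow(merge_flagged(win[!win$flagged, ])), 0L)

  withr::with_seed(67, {
    # random flag patterns equal the run-length-encoding oracle
    for (i in 1:20) {
      w <- win
      w$flagged <- runif(30) < 0.4
      reg <- merge_flagged(w)
      r <- rle(w$flagged)
      starts <- cumsum(c(1, utils::head(r$lengths, -1)))
      exp_start <- w$q_start[starts[r$values]]
      exp_end <- w$q_start[starts[r$values] + r$lengths[r$values] - 1L] + 18L
      expect_identical(reg$q_start, exp_start)
      expect_identical(reg$q_end, exp_end)
    }
  })
})

test_that("the scan recovers planted host-unique regions over seeded replicates", {
  for (seed in 1:20) {
    spec <- synth_spec(seed = seed)
    db <- make_reference_db(spec)
    pass <- db$records[db$records$fate == "pass", ]
    for (host in spec$hosts) {
      # clean candidate: the host's first reference record
      query <- pass$sequence[pass$host == host][1]
      foreign <- pass[pass$host != host, ]
      fu <- find_unique(query, setNames(foreign$sequence, foreign$accession),
                        query_id = host)
      planted <- db$planted[db$planted$host == host, ]
      covered <- any(fu$regions$q_start <= planted$start &
                       fu$regions$q_end >= planted$end)
      expect_true(covered, label = sprintf("seed %d, %s region recovered",
                                           seed, host))
      # nothing flagged wholly inside the conserved backbone
      vr <- rbind(spec$variable_regions[c("start", "end")],
                  db$planted[c("start", "end")])
      fl <- fu$windows[fu$windows$flagged, ]
      in_backbone <- vapply(fl$q_start, function(s) {
        all(s + 18L <= vr$start | s >= vr$end)
      }, logical(1))
      expect_identical(sum(in_backbone), 0L,
                       label = sprintf("seed %d, %s backbone clean", seed, host))
    }
  }
})
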