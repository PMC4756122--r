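test_that("Karlin-Altschul parameters match published ungapped constants", {
  ka <- karlin_altschul(alignment_scoring(match = 1, mismatch = -2))
  expect_equal(ka$lambda, 1.332706, tolerance = 1e-5)
  expect_equal(ka$K, 0.6210, tolerance = 1e-3)
  expect_equal(ka$H, 1.1241, tolerance = 1e-3)
  ka3 <- karlin_altschul(alignment_scoring(match = 1, mismatch = -3))
  expect_equal(ka3$lambda, 1.374063, tolerance = 1e-5)
  expect_equal(ka3$K, 0.7106, tolerance = 1e-3)
})

test_that("k-mer index postings match a brute-force substring scan", {
  idx <- kmer_index(c(s1 = "ACGTACGT"), k = 4)
  n_postings <- sum(vapply(ls(idx$postings), function(km) {
    nrow(kmer_lookup(idx, km))
  }, integer(1)))
  expect_identical(n_postings, 5L) # length - k + 1

  idx2 <- kmer_index(c(s1 = "ACGTACGT", s2 = "ACGTACGT"), k = 4)
  n2 <- sum(vapply(ls(idx2$postings), function(km) {
    nrow(kmer_lookup(idx2, km))
  }, integer(1)))
  expect_identical(n2, 10L)

  expect_error(kmer_index(c(a = "ACGT"), k = 3), "between 4 and 15")

  withr::with_seed(11, {
    subjects <- setNames(vapply(1:20, function(i) rnd_dna(60), character(1)),
                         sprintf("r%02d", 1:20))
    idx <- kmer_index(subjects, k = 6)
    for (kmer in vapply(1:25, function(i) rnd_dna(6), character(1))) {
      got <- kmer_lookup(idx, kmer)
      want <- do.call(rbind, lapply(seq_along(subjects), function(j) {
        offs <- gregexpr(kmer, subjects[[j]], fixed = TRUE)[[1]]
        # gregexpr misses overlapping matches; rescan positions
        L <- nchar(subjects[[j]])
        pos <- which(vapply(1:(L - 5L), function(p) {
          substr(subjects[[j]], p, p + 5L) == kmer
        }, logical(1)))
        if (length(pos)) cbind(subject = j, offset = pos - 1L) else NULL
      }))
      if (is.null(want)) {
        expect_identical(nrow(got), 0L)
      } else {
        expect_identical(got[order(got[, 1], got[, 2]), , drop = FALSE],
                         want[order(want[, 1], want[, 2]), , drop = FALSE])
      }
    }
  })
})

test_that("a verbatim database copy is the top hit with identity 1", {
  withr::with_seed(3, {
    q <- rnd_dna(150)
    db <- c(copy = q, other = rnd_dna(150))
    hits <- local_search(q, db, max_evalue = 1e-10)
    expect_identical(hits$subject_id[1], "copy")
    expect_identical(hits$strand[1], "+")
    expect_equal(hits$identity[1], 1.0)
    expect_identical(hits$q_start[1], 0L)
    expect_identical(hits$q_end[1], 150L)
    expect_identical(hits$s_start[1], 0L)
    expect_identical(hits$s_end[1], 150L)
    expect_identical(hits$score[1], 150L)
  })
})

test_that("unrelated random queries yield no hits at a stringent E-value", {
  withr::with_seed(17, {
    db <- setNames(vapply(1:10, function(i) rnd_dna(200), character(1)),
                   sprintf("d%02d", 1:10))
    idx <- kmer_index(db, k = 11)
    n_hits <- vapply(1:100, function(i) {
      nrow(local_search(rnd_dna(150), idx, max_evalue = 1e-10))
    }, integer(1))
    expect_identical(sum(n_hits), 0L)
  })
})

test_that("E-values double with database duplication and ignore subject order", {
  withr::with_seed(23, {
    q <- rnd_dna(120)
    fam <- setNames(seq_family(q, 4, k = 6L), sprintf("f%d", 1:4))
    db <- c(fam, setNames(vapply(1:4, function(i) rnd_dna(150), character(1)),
                          sprintf("bg%d", 1:4)))
    h1 <- local_search(q, db, max_evalue = 1e-3)
    expect_gt(nrow(h1), 0)
    # duplicating every subject doubles each hit's E-value
    db2 <- c(db, setNames(db, paste0(names(db), "_dup")))
    h2 <- local_search(q, db2, max_evalue = 1e-3)
    for (i in seq_len(nrow(h1))) {
      ev2 <- h2$evalue[h2$subject_id == h1$subject_id[i] &
                         h2$strand == h1$strand[i]]
      expect_equal(ev2, 2 * h1$evalue[i], tolerance = 1e-9)
    }
    # permutation invariance of the hit set
    h3 <- local_search(q, db[sample(names(db))], max_evalue = 1e-3)
    key <- function(h) {
      o <- order(h$subject_id, h$strand)
      h[o, c("subject_id", "strand", "score", "evalue", "q_start", "q_end",
             "s_start", "s_end")]
    }
    expect_equal(key(h3), key(h1), ignore_attr = TRUE)
    # E-value is decreasing in score: sorting by descending score sorts
    # E-values ascending
    expect_false(is.unsorted(h1$evalue[order(-h1$score)]))
  })
})

test_that("seeded and exhaustive search agree on high-identity hits", {
  withr::with_seed(29, {
    q <- rnd_dna(300)
    db <- c(setNames(seq_family(q, 3, k = 8L), c("a", "b", "c")),
            bg = rnd_dna(300))
    hx <- local_search(q, db, max_evalue = 1e-10, mode = "exhaustive")
    hs <- local_search(q, db, max_evalue = 1e-10, mode = "seeded")
    cols <- c("subject_id", "strand", "score", "q_start", "q_end")
    expect_equal(hx[hx$strand == "+", cols], hs[hs$strand == "+", cols],
                 ignore_attr = TRUE)
  })
})

test_that("greedy clustering partitions input and recovers planted families", {
  # five identical sequences -> one cluster of five
  same <- setNames(rep(strrep("ACGT", 20), 5), paste0("x", 1:5))
  cl <- greedy_cluster(same, identity = 0.97)
  expect_length(cl$clusters, 1L)
  expect_setequal(cl$clusters[[1]]$member_ids, names(same))
  expect_identical(cl$clusters[[1]]$representative_id, "x1")

  withr::with_seed(31, {
    # pairwise-unrelated sequences -> all singletons
    solo <- setNames(vapply(1:6, function(i) rnd_dna(120), character(1)),
                     sprintf("s%d", 1:6))
    cls <- greedy_cluster(solo, identity = 0.9)
    expect_length(cls$clusters, 6L)

    # three mutated families at ~99% within-family identity, threshold 0.97
    bases <- vapply(1:3, function(i) rnd_dna(200), character(1))
    seqs <- unlist(lapply(1:3, function(f) {
      setNames(seq_family(bases[f], 10, k = 2L),
               sprintf("fam%d_%02d", f, 1:10))
    }))
    cl3 <- greedy_cluster(seqs, identity = 0.97)
    expect_length(cl3$clusters, 3L)
    for (cluster in cl3$clusters) {
      fams <- unique(sub("_.*", "", cluster$member_ids))
      expect_length(fams, 1L)
      # every member aligns to the representative at >= threshold
      rep_seq <- seqs[[cluster$representative_id]]
      for (m in cluster$member_ids) {
        expect_gte(pairwise_identity(seqs[[m]], rep_seq), 0.97)
      }
    }
    # clusters partition the input
    membership <- as.data.frame(cl3)
    expect_setequal(membership$id, names(seqs))
    expect_identical(anyDuplicated(membership$id), 0L)
  })
})
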