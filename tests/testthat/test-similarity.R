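test_that("dereplication keeps one representative per sequence per site", {
  recs <- sequence_records(
    c("a1", "a2", "b1", "c1", "c2"),
    c("ACGTACGT", "ACGTACGT", "ACGTACGT", "TTTTCCCC", "ACGTACGT"),
    site = c("Oslo", "Oslo", "Naples", "Oslo", "Oslo"),
    habitat = "DCM")
  d <- dereplicate(recs)
  # identical sequences at Oslo collapse; the Naples copy survives separately
  expect_setequal(d$records$id, c("a1", "b1", "c1"))
  expect_identical(d$multiplicity$n_replaced[d$multiplicity$id == "a1"], 3L)
  expect_identical(d$multiplicity$n_replaced[d$multiplicity$id == "b1"], 1L)

  # all-distinct input is untouched
  recs2 <- sequence_records(c("x", "y"), c("AAAA", "CCCC"), site = "Oslo",
                            habitat = "DCM")
  expect_identical(dereplicate(recs2)$records$id, c("x", "y"))

  # cultured records group by epoch, not site
  recs3 <- sequence_records(c("k1", "k2"), c("GGGG", "GGGG"),
                            epoch = "cultured")
  expect_identical(nrow(dereplicate(recs3)$records), 1L)
})

test_that("align_pair reports exact identity for identical and mismatched pairs", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 380, replace = TRUE), collapse = "")
  a <- list(id = "a", sequence = s)
  h <- align_pair(a, list(id = "b", sequence = s))
  expect_equal(h$pct_identity, 100)
  expect_identical(h$align_length, 380L)

  # 19 interior substitutions out of 380 -> 95.0% by the Hamming closed form
  ch <- strsplit(s, "")[[1]]
  pos <- seq(20, 360, length.out = 19)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  b <- list(id = "b", sequence = paste(ch, collapse = ""))
  h2 <- align_pair(a, b)
  expect_equal(h2$pct_identity, 95.0, tolerance = 1e-10)
  expect_equal(h2$pct_identity, hamming_pid(a$sequence, b$sequence),
               tolerance = 0.01)

  expect_error(align_pair(list(id = "x", sequence = "ACGT!"), a), "IUPAC")
})

test_that("alignment identity is symmetric and matches the Hamming form for indel-free pairs", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  for (k in 1:50) {
    n <- sample(150:400, 1)
    a <- sample(bases, n, replace = TRUE)
    b <- a
    nm <- sample(3:25, 1)
    pos <- sample(seq(10, n - 10), nm)
    for (p in pos) b[p] <- setdiff(bases, b[p])[sample(3, 1)]
    ra <- list(id = "a", sequence = paste(a, collapse = ""))
    rb <- list(id = "b", sequence = paste(b, collapse = ""))
    hab <- align_pair(ra, rb); hba <- align_pair(rb, ra)
    expect_equal(hab$pct_identity, hba$pct_identity, tolerance = 1e-12)
    expect_equal(hab$pct_identity,
                 hamming_pid(ra$sequence, rb$sequence), tolerance = 0.01)
  }
})

test_that("compiled Smith-Waterman scores agree with the Biostrings reference", {
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -2, baseOnly = FALSE)
  for (k in 1:20) {
    a <- paste(sample(bases, sample(80:250, 1), replace = TRUE), collapse = "")
    b <- if (k %% 2 == 0) {
      ch <- strsplit(a, "")[[1]]
      ch[sample(length(ch), 10)] <- sample(bases, 10, replace = TRUE)
      if (k %% 4 == 0) ch <- ch[-sample(length(ch), 2)]  # deletions
      paste(ch, collapse = "")
    } else paste(sample(bases, sample(80:250, 1), replace = TRUE), collapse = "")
    st <- seqsimnet:::.sw_align_batch(a, b, 1L, -2L, 5L, 2L)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
    expect_identical(unname(st[1, "score"]), as.integer(Biostrings::score(ref)))
  }
})

test_that("Karlin-Altschul parameters follow the score-generating equation", {
  p <- align_params()
  # closed form for +1/-2 under uniform composition: e^lambda = (3+sqrt(21))/2
  expect_equal(p$lambda, log((3 + sqrt(21)) / 2), tolerance = 1e-9)
  # identical 380-mers in a small database: E-value far below any threshold
  h <- align_pair(list(id = "a", sequence = strrep("ACGT", 95)),
                  list(id = "b", sequence = strrep("ACGT", 95)),
                  align_params(db_size = 1e6))
  expect_lt(h$evalue, 1e-100)
})

test_that("BLAST tabular files round-trip and malformed rows are reported by line", {
  f <- tempfile()
  writeLines(c("s1\ts2\t97.4\t385\t10\t0\t1\t385\t1\t385\t1e-180\t600",
               "s1\ts3\t85.0\t380\t57\t0\t1\t380\t1\t380\t2e-50\t200"), f)
  h <- read_blast_tab(f)
  expect_identical(nrow(h), 2L)
  expect_equal(h$pct_identity[1], 97.4)
  expect_identical(h$align_length[1], 385L)
  expect_equal(h$evalue[1], 1e-180)

  writeLines(character(0), f)
  expect_identical(nrow(read_blast_tab(f)), 0L)

  writeLines(c("s1\ts2\t97.4\t385\t10\t0\t1\t385\t1\t385\t1e-180\t600",
               "s1\ts2\t97.4\t385"), f)
  expect_error(read_blast_tab(f), "line 2")

  h2 <- read_blast_tab({
    writeLines("s1\ts2\t97.4\t385\t10\t0\t1\t385\t1\t385\t1e-180\t600", f); f
  })
  f2 <- tempfile()
  write_blast_tab(h2, f2)
  h3 <- read_blast_tab(f2)
  expect_equal(h3$pct_identity, h2$pct_identity, tolerance = 1e-3)
  unlink(c(f, f2))
})

test_that("filter_hits is idempotent and symmetric under role swap", {
  recs <- rbind(mock_records(c("a", "b", "c"), len = 380L))
  hits <- rbind(
    mock_hits(c("a", "b", "a"), c("b", "c", "c"), c(97, 92, 88)),
    mock_hits("b", "a", 96),             # duplicate pair, lower identity
    mock_hits("a", "a", 100)             # self-hit
  )
  f1 <- filter_hits(hits, recs)
  expect_identical(nrow(f1), 3L)
  expect_true(all(f1$query_id < f1$subject_id))
  # per-pair max identity wins
  expect_equal(f1$pct_identity[f1$query_id == "a" & f1$subject_id == "b"], 97)
  expect_identical(filter_hits(f1, recs), f1)

  swapped <- hits
  swapped[, c("query_id", "subject_id")] <- swapped[, c("subject_id", "query_id")]
  f2 <- filter_hits(swapped, recs)
  expect_identical(f1[, c("query_id", "subject_id", "pct_identity")],
                   f2[, c("query_id", "subject_id", "pct_identity")])

  expect_error(filter_hits(mock_hits("a", "zz", 90), recs), "zz")
})

test_that("all-vs-all search finds within-species pairs and no unrelated ones", {
  cfg <- scenario_config(n_species = 3, seqs_per_species = 4,
                         species_per_family = 1,  # unrelated families
                         frac_cultured = 1, frac_novel = 0, seed = 29)
  sim <- generate_dataset(cfg)
  hits <- filter_hits(all_vs_all_hits(sim$records), sim$records)
  sp <- stats::setNames(sim$records$truth_species, sim$records$id)
  expect_true(all(sp[hits$query_id] == sp[hits$subject_id]))
  # every within-species pair of the 6-member groups is recovered
  expect_identical(nrow(hits), as.integer(3 * choose(6, 2)))
  expect_true(all(hits$pct_identity > 95))
})
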