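test_that("longest ORF follows the ATG..stop six-frame convention", {
  expect_equal(longest_orf("ATGAAATAA"), 2L)        # M-K-stop
  expect_equal(longest_orf("CCCCCC"), 0L)           # no start
  expect_equal(longest_orf(lnckit:::revcomp("ATGAAATAA")), 2L)
  # ORF running off the end is not counted
  expect_equal(longest_orf("ATGAAAAAA"), 0L)
  # an ambiguity codon blocks the reading frame
  expect_equal(longest_orf("ATGNAATAA"), 0L)
  # vectorized
  expect_equal(longest_orf(c("ATGAAATAA", "CCCCCC")), c(2L, 0L))
})

test_that("longest ORF agrees with O(n^2) substring enumeration", {
  set.seed(10)
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:150, 1),
                      replace = TRUE), collapse = "")
    expect_equal(longest_orf(s), brute_longest_orf(s), info = s)
  }
  # with occasional ambiguity codes
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 90, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    expect_equal(longest_orf(s), brute_longest_orf(s), info = s)
  }
})

# deterministic sequences with an exact planted ORF length (aa), GCA body
orf_seq <- function(aa) {
  paste0("ATG", strrep("GCA", aa - 1), "TAA")
}

test_that("intrinsic coding score is deterministic with its boundary at 0", {
  s100 <- orf_seq(100)
  s101 <- orf_seq(101)
  expect_equal(longest_orf(c(s100, s101)), c(100L, 101L))
  expect_lt(cnci_like_score(s100), 0)
  expect_gt(cnci_like_score(s101), 0)
  expect_identical(cnci_like_score(s101), cnci_like_score(s101))

  # generator calibration: coding transcripts positive, noncoding negative
  tx <- simulate_transcripts(c(coding = 15, lncRNA = 15), seed = 11)
  joined <- dplyr::left_join(tx$transcripts, tx$truth, by = "transcript_id")
  sc <- cnci_like_score(joined$sequence)
  expect_true(all(sc[joined$class == "coding"] > 0))
  expect_true(all(sc[joined$class == "lncRNA"] < 0))
})

test_that("evidence-aware score honours protein hits and its -1 boundary", {
  lnc <- simulate_transcripts(c(lncRNA = 10), seed = 12)
  # hit-free noncoding transcripts fall below -1
  expect_true(all(cpc_like_score(lnc$transcripts$sequence) < -1))
  # a 150-aa ORF with empty hits is retained (score above -1)
  expect_gt(cpc_like_score(orf_seq(150)), -1)
  # a strong protein hit forces the score to at least 0
  hit <- tibble::tibble(query_id = "x", subject_id = "p",
                        percent_identity = 95, evalue = 1e-30, db = "nr")
  expect_gte(cpc_like_score(lnc$transcripts$sequence[1], hit, "x"), 0)
  # a hit failing the E-value filter does not
  weak <- dplyr::mutate(hit, evalue = 1e-3)
  expect_lt(cpc_like_score(lnc$transcripts$sequence[1], weak, "x"), -1)
})

test_that("cascade stages classify boundary cases in pipeline order", {
  set.seed(13)
  short <- paste(sample(c("A", "C", "G", "T"), 199, replace = TRUE),
                 collapse = "")
  while (longest_orf(short) > 100) {
    short <- paste(sample(c("A", "C", "G", "T"), 199, replace = TRUE),
                   collapse = "")
  }
  tx <- transcript_tibble("t_short", short)
  res <- run_cascade(tx)
  expect_equal(tidy(res)$final_class, "too_short")

  # protein-annotated transcript removed first, regardless of length
  hit <- tibble::tibble(query_id = "t_short", subject_id = "p",
                        percent_identity = 95, evalue = 1e-30, db = "nr")
  res2 <- run_cascade(tx, protein_hits = hit)
  expect_equal(tidy(res2)$final_class, "annotated_coding")

  # 400-nt transcript with a 120-aa ORF: external scores calling it
  # noncoding push it through stage 3, the ORF filter then removes it
  s120 <- paste0(strrep("C", 18), orf_seq(120), strrep("C", 19))
  tx3 <- transcript_tibble("t_orf", s120)
  expect_equal(tx3$length, 400L)
  res3 <- run_cascade(tx3, cnci_scores = c(t_orf = -5),
                      cpc_scores = c(t_orf = -5))
  expect_equal(tidy(res3)$final_class, "orf_coding")
  # with the built-in scorers the same transcript fails coding potential
  expect_equal(tidy(run_cascade(tx3))$final_class, "coding_potential")

  # qualifying miRNA evidence makes a clean noncoding transcript pri_miRNA
  lnc <- simulate_transcripts(c(lncRNA = 1), seed = 14)
  mir_hit <- tibble::tibble(
    query_id = lnc$transcripts$transcript_id, subject_id = "mir-166",
    percent_identity = 95, evalue = 1e-12, db = "mirbase"
  )
  res4 <- run_cascade(lnc$transcripts, ncrna_hits = mir_hit)
  expect_equal(tidy(res4)$final_class, "pri_miRNA")
  # the same hit below the identity bar leaves it a novel lncRNA
  weak <- dplyr::mutate(mir_hit, percent_identity = 90)
  res5 <- run_cascade(lnc$transcripts, ncrna_hits = weak)
  expect_equal(tidy(res5)$final_class, "lncRNA_novel")
})

test_that("ncRNA triage precedence is miRNA > other Rfam > NONCODE", {
  lnc <- simulate_transcripts(c(lncRNA = 1), seed = 15)
  id <- lnc$transcripts$transcript_id
  mk <- function(subject, db) tibble::tibble(
    query_id = id, subject_id = subject, percent_identity = 96,
    evalue = 1e-20, db = db
  )
  both <- dplyr::bind_rows(mk("mir-5", "mirbase"), mk("NONHSAT1", "noncode"))
  expect_equal(tidy(run_cascade(lnc$transcripts, ncrna_hits = both))$final_class,
               "pri_miRNA")
  rf <- dplyr::bind_rows(mk("RF00005_tRNA", "rfam"), mk("NONHSAT1", "noncode"))
  expect_equal(tidy(run_cascade(lnc$transcripts, ncrna_hits = rf))$final_class,
               "other_ncRNA")
  expect_equal(
    tidy(run_cascade(lnc$transcripts,
                     ncrna_hits = mk("NONHSAT1", "noncode")))$final_class,
    "lncRNA_known"
  )
})

test_that("verdicts partition the input and stage counts telescope", {
  ds <- simulate_dataset(
    seed = 16,
    n_by_class = c(coding = 20, lncRNA = 20, pri_miRNA = 5,
                   other_ncRNA = 5, short_nc = 10),
    known_fraction = 0.2
  )
  prot <- dplyr::filter(ds$hits, db %in% c("nr", "swissprot"))
  nc <- dplyr::filter(ds$hits, db %in% c("rfam", "mirbase", "noncode"))
  res <- run_cascade(ds$transcripts, prot, nc)
  v <- tidy(res)
  expect_equal(nrow(v), 60L)
  expect_false(any(is.na(v$final_class)))
  sc <- res$stage_counts
  expect_equal(sc$survivors[1] - cumsum(sc$removed)[-1],
               sc$survivors[-1])
  # trace never mentions a transcript after its removal stage
  removed_at <- dplyr::filter(res$trace, decision == "removed") |>
    dplyr::distinct(transcript_id, .keep_all = TRUE)
  stage_rank <- setNames(seq_along(unique(res$trace$stage)),
                         unique(res$trace$stage))
  later <- dplyr::inner_join(res$trace, removed_at, by = "transcript_id",
                             suffix = c("", "_rm"))
  expect_true(all(stage_rank[later$stage] <= stage_rank[later$stage_rm]))

  # order-independence of verdicts
  shuf <- ds$transcripts[sample(nrow(ds$transcripts)), ]
  v2 <- tidy(run_cascade(shuf, prot, nc))
  expect_equal(v2$final_class[match(v$transcript_id, v2$transcript_id)],
               v$final_class)

  # every surviving lncRNA respects the length and ORF bounds
  keep <- v$final_class %in% c("lncRNA_known", "lncRNA_novel")
  expect_true(all(v$length[keep] >= 200))
  expect_true(all(v$longest_orf_aa[keep] <= 100))
})

test_that("cascade recovers every planted transcript class", {
  ds <- simulate_dataset(
    seed = 17,
    n_by_class = c(coding = 30, lncRNA = 40, pri_miRNA = 8,
                   other_ncRNA = 8, short_nc = 14),
    known_fraction = 0.25
  )
  prot <- dplyr::filter(ds$hits, db %in% c("nr", "swissprot"))
  nc <- dplyr::filter(ds$hits, db %in% c("rfam", "mirbase", "noncode"))
  v <- tidy(run_cascade(ds$transcripts, prot, nc))
  expected <- dplyr::case_when(
    ds$truth$class == "coding" ~ "annotated_coding",
    ds$truth$class == "short_nc" ~ "too_short",
    ds$truth$class == "pri_miRNA" ~ "pri_miRNA",
    ds$truth$class == "other_ncRNA" ~ "other_ncRNA",
    ds$truth$noncode_known ~ "lncRNA_known",
    TRUE ~ "lncRNA_novel"
  )
  expect_equal(v$final_class[match(ds$truth$transcript_id, v$transcript_id)],
               expected)
})

test_that("hits for unknown transcripts warn and are ignored", {
  lnc <- simulate_transcripts(c(lncRNA = 2), seed = 18)
  ghost <- tibble::tibble(query_id = "NOPE", subject_id = "p",
                          percent_identity = 99, evalue = 1e-40, db = "nr")
  expect_warning(res <- run_cascade(lnc$transcripts, protein_hits = ghost),
                 "absent")
  expect_true(all(tidy(res)$final_class %in%
                    c("lncRNA_novel", "lncRNA_known")))
})

test_that("cascade summaries and plots expose the verdict table", {
  ds <- simulate_dataset(seed = 19, n_by_class = c(coding = 5, lncRNA = 5))
  prot <- dplyr::filter(ds$hits, db %in% c("nr", "swissprot"))
  res <- run_cascade(ds$transcripts, prot)
  g <- glance(res)
  expect_equal(g$n_input, 10L)
  expect_equal(g$n_lncRNA, g$n_known + g$n_novel)
  expect_s3_class(autoplot(res), "ggplot")
})
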