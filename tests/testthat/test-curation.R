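make_hits <- function(qseqid, sseqids, bitscores = NULL, evalues = NULL) {
  n <- length(sseqids)
  tibble::tibble(
    qseqid = qseqid, sseqid = sseqids,
    pident = 90, length = 100L, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = if (is.null(evalues)) rep(1e-30, n) else evalues,
    bitscore = if (is.null(bitscores)) seq(500, by = -1, length.out = n)
               else bitscores)
}

test_that("first viral rank honours depth and ordering policy", {
  h <- make_hits("q1", c("n1", "v1", "n2"))
  r <- first_viral_rank(h, c("v1"), depth = 30)
  expect_equal(r$first_viral_rank, 2L)

  # viral hit just beyond the window is invisible
  h35 <- make_hits("q1", c(paste0("n", 1:30), "v1", paste0("m", 1:4)))
  expect_true(is.na(first_viral_rank(h35, "v1", depth = 30)$first_viral_rank))
  expect_equal(first_viral_rank(h35, "v1", depth = 31)$first_viral_rank, 31L)

  # boundary: viral at exactly rank 10 with depth 10
  h10 <- make_hits("q1", c(paste0("n", 1:9), "v1"))
  expect_equal(first_viral_rank(h10, "v1", depth = 10)$first_viral_rank, 10L)

  # bitscore re-ranking promotes a late file row; file_order replays as-is
  hx <- make_hits("q1", c("n1", "v1"), bitscores = c(100, 300))
  expect_equal(first_viral_rank(hx, "v1")$first_viral_rank, 1L)
  expect_equal(first_viral_rank(hx, "v1", order_policy = "file_order")$first_viral_rank,
               2L)

  # bitscore ties break by evalue, then input order
  ht <- make_hits("q1", c("a", "v1", "b"), bitscores = c(200, 200, 200),
                  evalues = c(1e-10, 1e-30, 1e-30))
  expect_equal(first_viral_rank(ht, "v1")$first_viral_rank, 1L)

  expect_equal(nrow(first_viral_rank(make_hits("q", character()), "v1")), 0)
  expect_error(first_viral_rank(h, "v1", depth = 0), "depth")
})

test_that("the curation verdict matches the closed-form truth table exhaustively", {
  grid <- truth_table_grid()
  got <- classify_candidate(grid$rank, grid$domain)
  expect_equal(got, grid$expected)
  # spot the decision structure: domain needs a hit anywhere in the window,
  # no-domain candidates need one in the rescue window
  expect_equal(classify_candidate(25L, TRUE), "retained_domain_rule")
  expect_equal(classify_candidate(25L, FALSE), "excluded")
  expect_equal(classify_candidate(8L, FALSE), "retained_top10_rule")
  expect_equal(classify_candidate(NA_integer_, TRUE), "excluded")
  expect_error(classify_candidate(31L, TRUE), "outside")
})

test_that("curate_candidates joins ranks with domain evidence", {
  h <- dplyr::bind_rows(make_hits("q1", c("n1", "v1", "n2")),
                        make_hits("q2", c("n1", "n2", "n3")))
  flags <- tibble::tibble(sseqid = "v1", is_viral = TRUE)
  domains <- tibble::tibble(qseqid = "q1", domain_accession = "cl40470",
                            is_viral_domain = TRUE)
  d <- curate_candidates(h, flags, domains)
  expect_equal(d$verdict[d$qseqid == "q1"], "retained_domain_rule")
  expect_equal(d$verdict[d$qseqid == "q2"], "excluded")
  expect_match(d$rationale[d$qseqid == "q2"], "no viral hit")
})

test_that("the exogenous length filter is strictly greater-than", {
  seqs <- tibble::tibble(
    id = c("a", "b", "c"),
    residues = vapply(c(400, 500, 501), function(n) strrep("A", n),
                      character(1)))
  expect_equal(length_filter(seqs)$id, "c")
  expect_equal(nrow(length_filter(seqs[0, ])), 0)
  expect_equal(length_filter(seqs, 0)$id, c("a", "b", "c"))
})

test_that("greedy clustering recovers templates and matches the all-pairs oracle", {
  fx <- cluster_fixture(42)
  cl <- greedy_cluster(fx, 0.90)

  # output partitions the input
  expect_setequal(cl$member_id, fx$id)
  expect_equal(anyDuplicated(cl$member_id), 0L)

  # 4 planted templates -> 4 clusters whose members share a template
  expect_equal(length(unique(cl$cluster)), 4)
  joined <- dplyr::left_join(cl, fx[, c("id", "template")],
                             by = c(member_id = "id"))
  expect_equal(dplyr::n_distinct(paste(joined$cluster, joined$template)), 4)

  # oracle: each member is >= 0.90 identical to its representative, and
  # representatives of different clusters are < 0.90 identical
  reps <- unique(cl$representative_id)
  res <- setNames(fx$residues, fx$id)
  for (i in seq_len(nrow(cl))) {
    ident <- virotriage:::global_identity(res[cl$representative_id[i]],
                                          res[cl$member_id[i]])
    expect_gte(ident, 0.90)
  }
  for (i in seq_along(reps)) {
    for (j in seq_len(i - 1)) {
      expect_lt(virotriage:::global_identity(res[reps[i]], res[reps[j]]),
                0.90)
    }
  }

  # representative is the longest (first-sorted) member of its cluster
  lens <- setNames(nchar(fx$residues), fx$id)
  by_cl <- split(cl$member_id, cl$cluster)
  for (k in names(by_cl)) {
    rep_id <- unique(cl$representative_id[cl$cluster == as.integer(k)])
    expect_equal(unname(lens[rep_id]), max(lens[by_cl[[k]]]))
  }
})

test_that("clustering edge cases: identical pair, disjoint pair, empty input", {
  two_same <- tibble::tibble(id = c("a", "b"),
                             residues = rep(strrep("ACGT", 30), 2))
  cl <- greedy_cluster(two_same)
  expect_equal(length(unique(cl$cluster)), 1)
  expect_equal(unique(cl$representative_id), "a")  # length tie -> id order

  disjoint <- tibble::tibble(id = c("a", "b"),
                             residues = c(strrep("A", 100), strrep("C", 100)))
  expect_equal(length(unique(greedy_cluster(disjoint)$cluster)), 2)

  expect_equal(nrow(greedy_cluster(two_same[0, ])), 0)
  expect_error(greedy_cluster(two_same, 1.5), "identity_threshold")
})

test_that("candidate hosts require strictly more than the identity bound", {
  h <- tibble::tibble(
    qseqid = c("c1", "c1", "c2", "c3"),
    sseqid = c("fungusA", "fungusB", "fungusC", "fungusC"),
    pident = c(89.9, 90.0, 90.1, 95.0),
    length = 100L, mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L, evalue = 1e-50, bitscore = 200)
  sel <- select_candidate_hosts(h, 90)
  expect_equal(sel$sseqid, "fungusC")  # one row despite two queries
  expect_equal(sel$max_pident, 95)

  expect_equal(nrow(select_candidate_hosts(h[0, ], 90)), 0)
  expect_equal(nrow(select_candidate_hosts(h, 90,
                                           mito_available = "fungusA")), 0)
  expect_equal(select_candidate_hosts(h, 80,
                                      mito_available = c("fungusA", "fungusC"))$sseqid,
               c("fungusA", "fungusC"))
})
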