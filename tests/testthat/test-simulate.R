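test_that("host profile generation is deterministic and concentration-controlled", {
  a <- make_host_profiles(3, concentration = 0.5, seed = 5)
  b <- make_host_profiles(3, concentration = 0.5, seed = 5)
  expect_equal(a, b)
  expect_equal(vapply(a, function(p) p$entity_id, character(1)),
               paste0("host_", 1:3))
  for (p in a) expect_equal(sum(p$codon_fractions), 1, tolerance = 1e-12)

  # high concentration -> near-uniform families, RSCU near 1
  flat <- make_host_profiles(1, concentration = 1e5, seed = 5)[[1]]
  expect_lt(max(abs(flat$rscu - 1)), 0.05)

  # low concentration -> mutually divergent profiles
  div <- make_host_profiles(5, concentration = 0.3, seed = 9)
  m <- profile_matrix(div, "codon_fractions")
  vals <- as.matrix(m[, -1])
  l1 <- as.matrix(dist(vals, method = "manhattan"))
  expect_gt(min(l1[upper.tri(l1)]), 0.2)

  expect_error(make_host_profiles(0), "n_hosts")
})

test_that("sampled viral ORFs are valid complete ORFs tracking the host profile", {
  host <- make_host_profiles(1, concentration = 0.5, seed = 3)[[1]]
  v <- sample_viral_orfs(host, orf_codons = 50, noise_fraction = 0.2,
                         seed = 8, n_viruses = 3)
  expect_equal(nrow(v), 3)
  expect_equal(v, sample_viral_orfs(host, 50, 0.2, seed = 8, n_viruses = 3))

  orfs <- find_orfs(v, mode = "complete", min_len = 30, max_len = 6000,
                    strands = "forward")
  # frame 0 carries exactly one complete ORF spanning each full sequence
  # (shifted frames may contain incidental short ORFs)
  f0 <- orfs[orfs$frame == 0, ]
  expect_equal(nrow(f0), 3)
  expect_equal(f0$start, rep(0L, 3))
  expect_equal(f0$length_nt, nchar(v$residues)[match(f0$parent_id, v$id)])
  expect_true(all(orfs$has_start_codon & orfs$has_stop_codon))
  expect_true(all(orfs$length_nt %% 3 == 0))

  # long noiseless ORFs converge to the host codon fractions at the rate of
  # direct multinomial sampling from the profile (the independent oracle)
  n_codons <- 10000
  long <- sample_viral_orfs(host, orf_codons = n_codons, noise_fraction = 0,
                            seed = 12)
  p <- codon_profile(long)
  l1 <- sum(abs(p$codon_fractions - host$codon_fractions))
  oracle_l1 <- vapply(1:10, function(s) {
    set.seed(7000 + s)
    code <- Biostrings::getGeneticCode("1")
    sense <- names(code)[code != "*"]
    aa <- sample(unique(code[sense]), n_codons, replace = TRUE)
    codons <- vapply(aa, function(a) {
      fam <- sense[code[sense] == a]
      sample(fam, 1, prob = host$family_probs[fam])
    }, character(1))
    f <- table(factor(codons, levels = names(host$codon_fractions))) / n_codons
    sum(abs(as.numeric(f) - host$codon_fractions))
  }, numeric(1))
  expect_lt(l1, max(oracle_l1) * 1.5)
  expect_lt(l1, 0.1)

  expect_error(sample_viral_orfs(host, orf_codons = 5), "orf_codons")
  expect_error(sample_viral_orfs(host, 50, noise_fraction = 2),
               "noise_fraction")
})

test_that("assignment accuracy sits near chance when noise destroys the signal", {
  hosts <- make_host_profiles(5, concentration = 0.5, seed = 31)
  host_tbl <- profile_matrix(hosts, "codon_fractions")
  accs <- vapply(1:10, function(seed) {
    seqs <- dplyr::bind_rows(purrr::imap(hosts, function(p, i) {
      sample_viral_orfs(p, 300, noise_fraction = 1, seed = seed * 50 + i,
                        n_viruses = 3)
    }))
    profs <- purrr::map(seq_len(nrow(seqs)), function(i) {
      codon_profile(seqs[i, ], entity_id = seqs$id[i])
    })
    a <- predict_host(spearman_matrix(profile_matrix(profs, "codon_fractions"),
                                      host_tbl))
    mean(a$best_host == seqs$host_id[match(a$virus_id, seqs$id)])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.2), 0.12)
})

test_that("planted hit tables replay through the readers to the planted verdicts", {
  spec <- tibble::tibble(planted_rank = c(5L, NA, 8L, 25L),
                         has_domain = c(TRUE, FALSE, FALSE, FALSE))
  ht <- make_hit_tables(spec, seed = 4)
  hits <- read_blast_tab(ht$blast_text)
  expect_equal(nrow(hits), 4 * 30)
  # strictly decreasing bitscores per query make ranking unambiguous
  for (q in unique(hits$qseqid)) {
    b <- hits$bitscore[hits$qseqid == q]
    expect_true(all(diff(b) < 0))
  }
  d <- curate_candidates(hits, read_viral_flags(ht$viral_flags_text),
                         read_domain_table(ht$domains_text))
  expect_equal(d$verdict, c("retained_domain_rule", "excluded",
                            "retained_top10_rule", "excluded"))
  expect_equal(d$first_viral_rank, c(5L, NA, 8L, 25L))

  expect_error(make_hit_tables(tibble::tibble(planted_rank = 31L,
                                              has_domain = TRUE)),
               "planted_rank")
})

test_that("expression fixtures carry the planted structure and exact TPM back-computation", {
  fx <- make_expression_fixture(planted_fold = 10, seed = 6)
  expect_equal(fx, make_expression_fixture(planted_fold = 10, seed = 6))
  expect_equal(names(fx$quants), fx$metadata$library_id)

  for (lib in names(fx$quants)) {
    q <- fx$quants[[lib]]
    expect_equal(sum(q$tpm), 1e6, tolerance = 1e-6)
    # counts reproduce the planted TPM through plain TPM normalization
    expect_equal(tpm_from_counts(q$num_reads, q$length), q$tpm,
                 tolerance = 1e-9)
  }

  # null case: planted fold 1 leaves fold estimates centred at 1
  folds <- vapply(1:40, function(s) {
    f <- make_expression_fixture(planted_fold = 1, n_viruses = 2, seed = s)
    mat <- expression_matrix(f$quants, control_ids = f$control_ids)
    fc <- group_fold_change(mat, f$group_a, f$group_b)
    median(fc$fold_change[grepl("^virus", fc$feature_id)])
  }, numeric(1))
  expect_lt(abs(log10(median(folds))), log10(1.25))
})

test_that("control-relative ratios in fixtures reflect planted levels up to noise", {
  ratios <- vapply(1:30, function(s) {
    fx <- make_expression_fixture(planted_fold = 1, baseline_tpm = 1600,
                                  n_viruses = 1, sigma_log10 = 0.2, seed = s)
    mat <- expression_matrix(fx$quants, control_ids = fx$control_ids)
    median(relative_to_controls(mat, "virus_01")$ratio)
  }, numeric(1))
  # planted: virus at 1600 TPM vs control mean (800 + 400 + 1200)/3 = 800
  expect_lt(abs(log10(median(ratios) / 2)), log10(1.5))
})
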