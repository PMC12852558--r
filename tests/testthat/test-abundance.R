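test_that("TPM follows the closed form and always sums to one million", {
  expect_equal(tpm_from_counts(c(10, 10), c(100, 100)), c(5e5, 5e5))
  expect_equal(tpm_from_counts(c(10, 10), c(100, 200)),
               c(2e6 / 3, 1e6 / 3))
  for (seed in 1:5) {
    set.seed(seed)
    tpm <- tpm_from_counts(rpois(50, 100), sample(200:5000, 50))
    expect_equal(sum(tpm), 1e6)
  }
  expect_error(tpm_from_counts(c(0, 0), c(100, 100)), "undefined")
  expect_error(tpm_from_counts(c(1, -1), c(100, 100)), "non-negative")
  expect_error(tpm_from_counts(c(1, 1), c(100, 0)), "positive")
})

fixture_matrix <- function(seed = 3, ...) {
  fx <- make_expression_fixture(seed = seed, ...)
  list(fx = fx,
       mat = expression_matrix(fx$quants, fx$metadata, fx$control_ids,
                               recompute_tpm = TRUE))
}

test_that("expression_matrix assembles libraries and validates inputs", {
  z <- fixture_matrix()
  expect_s3_class(z$mat, "expression_matrix")
  expect_equal(colnames(z$mat$values), z$fx$metadata$library_id)
  expect_equal(unname(colSums(z$mat$values)), rep(1e6, 6), tolerance = 1e-9)

  td <- tidy(z$mat)
  expect_true(all(c("feature_id", "library_id", "tpm", "is_control",
                    "treatment") %in% names(td)))
  expect_equal(sum(td$is_control), 3 * 6)

  expect_error(expression_matrix(unname(z$fx$quants)), "named list")
  expect_error(expression_matrix(z$fx$quants, control_ids = "nope"),
               "Control gene")
})

test_that("control-relative activity divides by the per-library control mean", {
  q <- list(
    L1 = tibble::tibble(name = c("v", "c1", "c2", "c3"),
                        length = c(1000L, 1000L, 1000L, 1000L),
                        effective_length = NA_real_,
                        num_reads = c(40, 10, 30, 20), tpm = NA_real_),
    L2 = tibble::tibble(name = c("v", "c1", "c2", "c3"),
                        length = c(1000L, 1000L, 1000L, 1000L),
                        effective_length = NA_real_,
                        num_reads = c(10, 0, 0, 0), tpm = NA_real_))
  mat <- expression_matrix(q, control_ids = c("c1", "c2", "c3"))
  r <- relative_to_controls(mat, "v")
  # equal lengths: TPM ratios equal count ratios; 40 / mean(10,30,20) = 2
  expect_equal(r$ratio[r$library_id == "L1"], 2)
  expect_true(is.na(r$ratio[r$library_id == "L2"]))  # all controls zero

  # a control gene is compared to the mean of all controls, not to itself
  rc <- relative_to_controls(mat, "c2")
  expect_equal(rc$ratio[rc$library_id == "L1"], 30 / 20)
  expect_error(relative_to_controls(mat, "ghost"), "not in the matrix")
})

test_that("presence calls use an at-least threshold and feed prevalence", {
  q <- list(L1 = tibble::tibble(name = c("a", "b"), length = 1000L,
                                effective_length = NA_real_,
                                num_reads = c(99, 1), tpm = c(0.99, 1.0)),
            L2 = tibble::tibble(name = c("a", "b"), length = 1000L,
                                effective_length = NA_real_,
                                num_reads = c(1, 1), tpm = c(1.01, 0)))
  mat <- expression_matrix(q)
  pres <- detect_presence(mat, 1.0)
  expect_equal(pres$present[pres$feature_id == "a"], c(FALSE, TRUE))
  expect_equal(pres$present[pres$feature_id == "b"], c(TRUE, FALSE))
  prev <- feature_prevalence(mat, 1.0)
  expect_equal(prev$n_present, c(1L, 1L))
  # threshold 0 calls everything present (TPM >= 0 by construction)
  expect_true(all(detect_presence(mat, 0)$present))
})

test_that("group fold change is a ratio of arithmetic means with pseudocount policy", {
  q <- purrr::map(c(A1 = 224, A2 = 224, B1 = 2, B2 = 2), function(v) {
    tibble::tibble(name = c("v", "bg"), length = c(1000L, 1000L),
                   effective_length = NA_real_,
                   num_reads = c(v, 1e6 - v), tpm = c(v, 1e6 - v))
  })
  mat <- expression_matrix(q)
  fc <- group_fold_change(mat, c("A1", "A2"), c("B1", "B2"))
  expect_equal(fc$fold_change[fc$feature_id == "v"], 112)

  # scale invariance at pseudocount 0
  q2 <- purrr::map(q, function(t) dplyr::mutate(t, tpm = tpm * 3))
  fc2 <- group_fold_change(expression_matrix(q2), c("A1", "A2"),
                           c("B1", "B2"))
  expect_equal(fc2$fold_change, fc$fold_change)

  # zero denominator -> NA; pseudocount restores a neutral value
  qz <- purrr::map(c(A1 = 5, B1 = 0), function(v) {
    tibble::tibble(name = c("v", "bg"), length = c(1000L, 1000L),
                   effective_length = NA_real_,
                   num_reads = c(v, 1e6 - v), tpm = c(v, 1e6 - v))
  })
  matz <- expression_matrix(qz)
  expect_true(is.na(group_fold_change(matz, "A1", "B1")$fold_change[1]))
  both0 <- group_fold_change(matz, "A1", "B1", pseudocount = 1)
  expect_equal(both0$fold_change[both0$feature_id == "v"], 6 / 1)

  expect_error(group_fold_change(mat, c("A1", "B1"), c("B1", "B2")),
               "disjoint")
  expect_error(group_fold_change(mat, character(), "B1"), "non-empty")
  expect_error(group_fold_change(mat, "A1", "nope"), "Unknown")
})

test_that("heatmap matrix log-transforms and clusters rows by Pearson distance", {
  q <- purrr::map(c(L1 = 0, L2 = 0, L3 = 0), function(v) {
    tibble::tibble(name = paste0("f", 1:4), length = 1000L,
                   effective_length = NA_real_,
                   num_reads = 1, tpm = NA_real_)
  })
  # craft a matrix directly: two identical rows, one anti-correlated, one flat
  mat <- expression_matrix(q, recompute_tpm = TRUE)
  mat$values <- rbind(
    f1 = c(10, 100, 1000),
    f2 = c(10, 100, 1000),
    f3 = c(1000, 100, 10),
    f4 = c(5, 5, 5))
  colnames(mat$values) <- c("L1", "L2", "L3")
  expect_message(hm <- heatmap_matrix(mat, pseudocount = 1),
                 "zero-variance")
  expect_equal(hm$values["f1", "L1"], log10(11), ignore_attr = TRUE)

  d <- virotriage:::pearson_row_distance(log10(mat$values + 1))
  expect_equal(d["f1", "f2"], 0)
  expect_gt(d["f1", "f3"], 1.99)  # near-perfect anticorrelation
  expect_equal(unname(d["f4", c("f1", "f2", "f3")]), rep(1, 3))

  # an exactly negated row sits at the maximal distance 2
  dn <- virotriage:::pearson_row_distance(rbind(x = c(1, 2, 3),
                                                y = c(-1, -2, -3)))
  expect_equal(unname(dn["x", "y"]), 2)

  # identical rows are adjacent leaves
  ord <- hm$row_order
  expect_equal(abs(which(ord == "f1") - which(ord == "f2")), 1)

  # single-row matrix: trivial order, no dendrogram
  mat1 <- mat; mat1$values <- mat$values[1, , drop = FALSE]
  hm1 <- heatmap_matrix(mat1)
  expect_equal(hm1$row_order, "f1")
  expect_null(hm1$hclust)
})

test_that("planted correlation blocks separate in the clustered row order", {
  set.seed(77)
  base1 <- sin(seq(0, 3 * pi, length.out = 12))
  base2 <- cos(seq(0, 3 * pi, length.out = 12))
  rows <- rbind(
    t(sapply(1:5, function(i) 100 * exp(base1 + rnorm(12, 0, 0.1)))),
    t(sapply(1:5, function(i) 100 * exp(base2 + rnorm(12, 0, 0.1)))))
  rownames(rows) <- c(paste0("a", 1:5), paste0("b", 1:5))
  colnames(rows) <- paste0("L", 1:12)
  q <- purrr::map(setNames(1:12, paste0("L", 1:12)), function(i) {
    tibble::tibble(name = rownames(rows), length = 1000L,
                   effective_length = NA_real_, num_reads = rows[, i],
                   tpm = rows[, i])
  })
  mat <- expression_matrix(q)
  mat$values <- rows
  hm <- heatmap_matrix(mat)
  blocks <- substr(hm$row_order, 1, 1)
  expect_equal(length(rle(blocks)$lengths), 2)  # one contiguous run each
})
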