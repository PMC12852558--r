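# Control-relative transcriptional abundance: TPM computation, an
# expression-matrix container with library metadata and endogenous control
# genes, prevalence calls, group fold changes, and the log10/Pearson
# clustered matrix behind abundance heatmaps.

#' Transcripts per million from raw counts and feature lengths
#'
#' TPM_i = (c_i / l_i) / sum_j (c_j / l_j) x 1e6. Length-normalized relative
#' abundance; every library's values sum to one million by construction.
#'
#' @param counts Non-negative read counts (at least one positive).
#' @param lengths Feature lengths in nt (all positive).
#' @return Numeric TPM vector summing to 1e6.
#' @examples
#' tpm_from_counts(c(10, 10), c(100, 200))
#' @export
tpm_from_counts <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    abort("counts and lengths must have equal length.")
  }
  if (any(lengths <= 0)) abort("All lengths must be positive.")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  rate <- counts / lengths
  total <- sum(rate)
  if (total == 0) abort("All counts are zero; TPM is undefined.")
  rate / total * 1e6
}

#' Assemble an expression matrix from per-library quantification tables
#'
#' Builds the features x libraries TPM container used by all downstream
#' abundance operations. When a quant table lacks a TPM column, TPM is
#' recomputed from counts and lengths via [tpm_from_counts()]; with
#' `recompute_tpm = TRUE` it is recomputed even when present, which
#' guarantees the column-sum invariant.
#'
#' @param quants Named list of quant tibbles ([read_quant_table()]), one
#'   per library; names are library ids.
#' @param metadata Library metadata tibble ([read_library_metadata()]);
#'   optional.
#' @param control_ids Character vector of endogenous control gene ids
#'   (stably expressed host genes used as the reference for relative
#'   activity).
#' @param recompute_tpm Recompute TPM from counts even when the table
#'   carries a TPM column.
#' @return An `expression_matrix` object: list with `values` (numeric
#'   matrix, features x libraries), `metadata`, `control_ids`.
#' @export
expression_matrix <- function(quants, metadata = NULL,
                              control_ids = character(),
                              recompute_tpm = FALSE) {
  if (is.null(names(quants)) || any(!nzchar(names(quants)))) {
    abort("`quants` must be a named list (names = library ids).")
  }
  feats <- unique(unlist(lapply(quants, function(q) q$name)))
  vals <- sapply(names(quants), function(lib) {
    q <- quants[[lib]]
    tpm <- q$tpm
    if (recompute_tpm || all(is.na(tpm))) {
      tpm <- tpm_from_counts(q$num_reads, q$length)
    }
    setNames(tpm, q$name)[feats]
  })
  vals <- matrix(vals, nrow = length(feats),
                 dimnames = list(feats, names(quants)))
  if (anyNA(vals)) {
    abort("Every library must quantify the same feature set.")
  }
  missing_controls <- setdiff(control_ids, feats)
  if (length(missing_controls)) {
    abort(sprintf("Control gene(s) not in the matrix: %s.",
                  paste(missing_controls, collapse = ", ")))
  }
  if (!is.null(metadata)) {
    need_cols(metadata, c("library_id", "project_id", "treatment"),
              "library metadata")
    missing_meta <- setdiff(names(quants), metadata$library_id)
    if (length(missing_meta)) {
      abort(sprintf("No metadata for library(ies): %s.",
                    paste(missing_meta, collapse = ", ")))
    }
    metadata <- metadata[match(names(quants), metadata$library_id), ]
  }
  structure(list(values = vals, metadata = metadata,
                 control_ids = control_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d libraries, %d control gene(s)\n",
              nrow(x$values), ncol(x$values), length(x$control_ids)))
  invisible(x)
}

#' Tidy an expression matrix into long format
#'
#' @param x An `expression_matrix`.
#' @param ... Unused.
#' @return Long tibble: `feature_id`, `library_id`, `tpm`, `is_control`,
#'   plus metadata columns when present.
#' @export
tidy.expression_matrix <- function(x, ...) {
  out <- tibble::as_tibble(x$values, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "library_id",
                        values_to = "tpm") |>
    dplyr::mutate(is_control = .data$feature_id %in% x$control_ids)
  if (!is.null(x$metadata)) {
    out <- dplyr::left_join(out, x$metadata, by = "library_id")
  }
  out
}

#' Per-library activity of a feature relative to the control genes
#'
#' ratio(library) = TPM(feature, library) / mean TPM of the endogenous
#' control genes in that library. Libraries where the control mean is zero
#' get `NA` with a message.
#'
#' @param mat An `expression_matrix` with non-empty `control_ids`.
#' @param feature Feature id to profile.
#' @return Tibble with `library_id`, `tpm`, `control_mean`, `ratio`.
#' @export
relative_to_controls <- function(mat, feature) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (length(mat$control_ids) == 0L) {
    abort("The matrix has no control genes set.")
  }
  if (!feature %in% rownames(mat$values)) {
    abort(sprintf("Feature '%s' is not in the matrix.", feature))
  }
  ctrl <- colMeans(mat$values[mat$control_ids, , drop = FALSE])
  ratio <- ifelse(ctrl == 0, NA_real_, mat$values[feature, ] / ctrl)
  if (any(ctrl == 0)) {
    inform(sprintf("Control mean is zero in %d library(ies); ratio set to NA.",
                   sum(ctrl == 0)))
  }
  tibble::tibble(library_id = colnames(mat$values),
                 tpm = unname(mat$values[feature, ]),
                 control_mean = unname(ctrl),
                 ratio = unname(ratio))
}

#' Presence calls and per-feature prevalence
#'
#' A feature is called present in a library when its TPM is at or above
#' `tpm_threshold`.
#'
#' @param mat An `expression_matrix`.
#' @param tpm_threshold Detection floor in TPM (default 1).
#' @return Tibble with `feature_id`, `library_id`, `tpm`, `present`.
#' @export
detect_presence <- function(mat, tpm_threshold = 1.0) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (tpm_threshold < 0) abort("tpm_threshold must be >= 0.")
  tibble::as_tibble(mat$values, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "library_id",
                        values_to = "tpm") |>
    dplyr::mutate(present = .data$tpm >= tpm_threshold)
}

#' Number of libraries each feature is detected in
#'
#' @inheritParams detect_presence
#' @return Tibble with `feature_id`, `n_present`, `n_libraries`.
#' @export
feature_prevalence <- function(mat, tpm_threshold = 1.0) {
  detect_presence(mat, tpm_threshold) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(n_present = sum(.data$present),
                     n_libraries = dplyr::n(), .groups = "drop")
}

#' Per-feature fold change between two library groups
#'
#' fold = (mean_a + pseudocount) / (mean_b + pseudocount), arithmetic means
#' of TPM within each group. A zero denominator (pseudocount 0) yields
#' `NA`.
#'
#' @param mat An `expression_matrix`.
#' @param group_a,group_b Disjoint, non-empty character vectors of library
#'   ids (numerator group first, e.g. inoculated vs uninfected).
#' @param pseudocount Added to both means before the ratio (default 0).
#' @return Tibble with `feature_id`, `mean_a`, `mean_b`, `fold_change`.
#' @export
group_fold_change <- function(mat, group_a, group_b, pseudocount = 0) {
  stopifnot(inherits(mat, "expression_matrix"))
  libs <- colnames(mat$values)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("Both groups must be non-empty.")
  }
  if (length(intersect(group_a, group_b))) {
    abort("Groups must be disjoint.")
  }
  unknown <- setdiff(c(group_a, group_b), libs)
  if (length(unknown)) {
    abort(sprintf("Unknown library(ies): %s.", paste(unknown, collapse = ", ")))
  }
  mean_a <- rowMeans(mat$values[, group_a, drop = FALSE])
  mean_b <- rowMeans(mat$values[, group_b, drop = FALSE])
  denom <- mean_b + pseudocount
  fold <- ifelse(denom == 0, NA_real_, (mean_a + pseudocount) / denom)
  tibble::tibble(feature_id = rownames(mat$values),
                 mean_a = unname(mean_a), mean_b = unname(mean_b),
                 fold_change = unname(fold))
}

#' Log-transformed matrix with correlation-based row clustering
#'
#' Transforms TPM to log10(x + pseudocount) and orders rows by hierarchical
#' clustering on 1 - Pearson correlation with average linkage — the layout
#' of an abundance heatmap. Zero-variance rows (correlation undefined) are
#' placed at distance 1 from every other row, with a message.
#'
#' @param mat An `expression_matrix`.
#' @param pseudocount Added before the log (default 1, so zeros map to 0).
#' @return A `heatmap_matrix` object: list with `values` (transformed
#'   matrix in clustered row order), `row_order`, `hclust` (`NULL` for a
#'   single row), `pseudocount`.
#' @export
heatmap_matrix <- function(mat, pseudocount = 1) {
  stopifnot(inherits(mat, "expression_matrix"))
  v <- log10(mat$values + pseudocount)
  if (nrow(v) == 0L) abort("The matrix has no features.")
  if (nrow(v) == 1L) {
    return(structure(list(values = v, row_order = rownames(v),
                          hclust = NULL, pseudocount = pseudocount),
                     class = "heatmap_matrix"))
  }
  d <- pearson_row_distance(v)
  hc <- hclust(as.dist(d), method = "average")
  ord <- hc$order
  structure(list(values = v[ord, , drop = FALSE],
                 row_order = rownames(v)[ord],
                 hclust = hc, pseudocount = pseudocount),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("<heatmap_matrix> %d features x %d libraries (log10(TPM + %g))\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  cat("row order:", paste(head(x$row_order, 8), collapse = ", "),
      if (length(x$row_order) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
tidy.heatmap_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "library_id",
                        values_to = "log10_tpm") |>
    dplyr::mutate(feature_id = factor(.data$feature_id,
                                      levels = rev(x$row_order)))
}

# 1 - Pearson r between rows; rows with zero variance get distance 1 to all
# others (and 0 to themselves).
pearson_row_distance <- function(v) {
  sds <- apply(v, 1, stats::sd)
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    inform(sprintf("%d zero-variance row(s) placed at distance 1 from all others.",
                   sum(flat)))
  }
  r <- suppressWarnings(cor(t(v)))
  d <- 1 - r
  d[is.na(d)] <- 1
  diag(d) <- 0
  d
}
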