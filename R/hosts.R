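# Compositional virus -> host assignment: Spearman correlation between
# viral and candidate-host composition profiles, best-correlate host
# prediction, and hierarchical clustering of the pooled profiles.

#' Spearman correlation matrix between viral and host profiles
#'
#' Correlates each viral entity's composition features (codon fractions,
#' dinucleotide odds ratios, or both) against each candidate host's.
#' Features are restricted to columns present in both tables; ranks use
#' average ties and rho is Pearson on ranks (the classical definition).
#'
#' @param viral,hosts Feature tibbles from [profile_matrix()] (`entity_id`
#'   plus numeric feature columns).
#' @return A `correlation_matrix` object: list with `rho` (viruses x hosts
#'   matrix), `n_features`, `features`.
#' @export
spearman_matrix <- function(viral, hosts) {
  vm <- feature_matrix(viral)
  hm <- feature_matrix(hosts)
  shared <- intersect(colnames(vm), colnames(hm))
  if (length(shared) < 2L) {
    abort("Fewer than 2 shared feature columns between the two tables.")
  }
  rho <- cor(t(vm[, shared, drop = FALSE]), t(hm[, shared, drop = FALSE]),
             method = "spearman")
  structure(list(rho = rho, n_features = length(shared), features = shared),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d virus(es) x %d host(s) on %d shared features\n",
              nrow(x$rho), ncol(x$rho), x$n_features))
  invisible(x)
}

#' Tidy a correlation matrix into long format
#'
#' @param x A `correlation_matrix`.
#' @param ... Unused.
#' @return Tibble with `virus_id`, `host_id`, `rho`.
#' @export
tidy.correlation_matrix <- function(x, ...) {
  tibble::as_tibble(x$rho, rownames = "virus_id") |>
    tidyr::pivot_longer(-"virus_id", names_to = "host_id",
                        values_to = "rho")
}

#' Best-correlate host assignment
#'
#' Assigns each virus the candidate host with the highest Spearman rho.
#' Exact ties are broken deterministically by host id (ascending) and
#' flagged. The margin (rho of the best host minus rho of the runner-up)
#' is a simple confidence measure.
#'
#' @param corr A `correlation_matrix` from [spearman_matrix()].
#' @param virus_id Optional single virus to report; default all rows.
#' @return Tibble with `virus_id`, `best_host`, `rho`, `margin`, `tie`.
#' @export
predict_host <- function(corr, virus_id = NULL) {
  stopifnot(inherits(corr, "correlation_matrix"))
  rows <- rownames(corr$rho)
  if (!is.null(virus_id)) {
    if (!virus_id %in% rows) {
      abort(sprintf("Virus '%s' is not in the correlation matrix.", virus_id))
    }
    rows <- virus_id
  }
  purrr::map(rows, function(v) {
    r <- corr$rho[v, ]
    if (all(is.na(r))) {
      abort(sprintf("All correlations are missing for virus '%s'.", v))
    }
    ord <- order(-r, names(r), na.last = TRUE)
    r_sorted <- r[ord]
    best <- r_sorted[1L]
    runner <- if (length(r_sorted) > 1L) r_sorted[2L] else NA_real_
    tibble::tibble(
      virus_id = v,
      best_host = names(r_sorted)[1L],
      rho = unname(best),
      margin = if (is.na(runner)) NA_real_ else unname(best - runner),
      tie = !is.na(runner) && runner == best)
  }) |> dplyr::bind_rows()
}

#' Hierarchical clustering of pooled composition profiles
#'
#' Clusters viruses and candidate hosts together on 1 - Spearman rho with
#' average linkage — the dendrogram view of compositional affinity. Input
#' is either a pooled feature tibble ([profile_matrix()] of viruses and
#' hosts together) or a square entity-by-entity `correlation_matrix`.
#'
#' @param x Pooled feature tibble, or a `correlation_matrix` whose rows and
#'   columns are the same entities.
#' @return A `profile_clustering` object: list with `hclust`, `leaf_order`,
#'   `dist` (entity x entity distance matrix).
#' @export
hier_cluster <- function(x) {
  if (inherits(x, "correlation_matrix")) {
    if (!identical(rownames(x$rho), colnames(x$rho))) {
      abort("Clustering a correlation_matrix requires identical row/column entities.")
    }
    rho <- x$rho
  } else {
    m <- feature_matrix(x)
    if (nrow(m) < 2L) abort("At least 2 entities are required.")
    rho <- cor(t(m), method = "spearman")
  }
  if (nrow(rho) < 2L) abort("At least 2 entities are required.")
  d <- 1 - rho
  d[is.na(d)] <- 1
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  structure(list(hclust = hc, leaf_order = rownames(d)[hc$order], dist = d),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("<profile_clustering> %d entities, average linkage on 1 - Spearman rho\n",
              length(x$leaf_order)))
  cat("leaf order:", paste(head(x$leaf_order, 8), collapse = ", "),
      if (length(x$leaf_order) > 8) "..." else "", "\n")
  invisible(x)
}

#' Export a profile clustering as a Newick tree
#'
#' @param x A `profile_clustering`.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "profile_clustering"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Package 'ape' is required for Newick export.")
  }
  phy <- ape::as.phylo(x$hclust)
  nwk <- ape::write.tree(phy)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

# entity_id-keyed tibble -> numeric matrix with entity rownames
feature_matrix <- function(tbl) {
  if (!is.data.frame(tbl) || !"entity_id" %in% names(tbl)) {
    abort("Expected a feature tibble with an 'entity_id' column.")
  }
  num <- vapply(tbl, is.numeric, logical(1))
  m <- as.matrix(tbl[, num, drop = FALSE])
  rownames(m) <- tbl$entity_id
  m
}
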