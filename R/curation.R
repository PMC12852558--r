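# Candidate-filtering logic for virome triage: ranked-hit viral evidence
# rules, the strict >500 nt exogenous-contig filter, greedy identity
# clustering for redundancy reduction, and the >90%-identity candidate-host
# selector.

#' Rank of the first viral hit per query
#'
#' For each query, finds the 1-based rank of the first hit whose subject is
#' flagged viral, considering only the first `depth` hits after ordering.
#' The default ordering re-sorts each query's hits by bitscore (ties broken
#' by ascending evalue, then input order), matching how similarity-search
#' tools rank their output; `"file_order"` replays the file exactly.
#'
#' @param hits Hit tibble as from [read_blast_tab()].
#' @param viral_flags Tibble with `sseqid`, `is_viral` (see
#'   [read_viral_flags()]), or a character vector of viral subject ids.
#' @param depth Number of top hits to inspect (default 30).
#' @param order_policy `"bitscore_desc"` or `"file_order"`.
#' @return Tibble with `qseqid` and `first_viral_rank` (`NA` when no viral
#'   hit occurs within `depth`).
#' @export
first_viral_rank <- function(hits, viral_flags, depth = 30L,
                             order_policy = c("bitscore_desc",
                                              "file_order")) {
  order_policy <- match.arg(order_policy)
  if (depth < 1L) abort("depth must be >= 1.")
  viral <- viral_subject_set(viral_flags)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(qseqid = character(),
                          first_viral_rank = integer()))
  }
  hits |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::group_by(.data$qseqid) |>
    dplyr::group_modify(function(h, key) {
      if (order_policy == "bitscore_desc") {
        h <- h[order(-h$bitscore, h$evalue, h$.file_order), ]
      }
      top <- head(h$sseqid, depth)
      r <- which(top %in% viral)
      tibble::tibble(first_viral_rank = if (length(r)) as.integer(r[1L])
                     else NA_integer_)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$qseqid, unique(hits$qseqid)))
}

#' Curation verdict from viral-hit rank and domain evidence
#'
#' Implements the two retention criteria of the endogenous-viral-element
#' screen: a candidate is retained when (i) a viral hit occurs within the
#' top `depth` protein-level matches AND a conserved viral domain was
#' detected (`retained_domain_rule`); or, lacking a domain, (ii) the first
#' viral hit falls within the top `rescue_depth` results
#' (`retained_top10_rule`). Anything else is excluded. A viral hit within
#' the inspected window is mandatory: a domain alone never rescues.
#'
#' @param first_viral_rank Integer vector of 1-based ranks (`NA` = no viral
#'   hit within the inspected window).
#' @param has_viral_domain Logical vector.
#' @param depth,rescue_depth Window sizes (defaults 30 and 10).
#' @return Character vector of verdicts: `"retained_domain_rule"`,
#'   `"retained_top10_rule"` or `"excluded"`.
#' @export
classify_candidate <- function(first_viral_rank, has_viral_domain,
                               depth = 30L, rescue_depth = 10L) {
  n <- max(length(first_viral_rank), length(has_viral_domain))
  rank <- rep_len(as.integer(first_viral_rank), n)
  dom <- rep_len(as.logical(has_viral_domain), n)
  bad <- !is.na(rank) & (rank < 1L | rank > depth)
  if (any(bad)) {
    abort(sprintf("first_viral_rank %d outside [1, %d].",
                  rank[bad][1L], depth))
  }
  dplyr::case_when(
    !is.na(rank) & dom ~ "retained_domain_rule",
    !is.na(rank) & rank <= rescue_depth & !dom ~ "retained_top10_rule",
    .default = "excluded")
}

#' Full curation pass over a hit table
#'
#' Joins ranked-hit evidence with domain annotations and applies
#' [classify_candidate()] to every query, producing the per-candidate
#' decisions table of the screen.
#'
#' @param hits Hit tibble ([read_blast_tab()]).
#' @param viral_flags Viral subject flags ([read_viral_flags()]) or a
#'   character vector.
#' @param domains Domain tibble ([read_domain_table()]); a query has viral
#'   domain evidence when any of its rows has `is_viral_domain = TRUE`.
#'   `NULL` means no domain evidence for any query.
#' @param depth,rescue_depth Inspection windows (30 / 10).
#' @param order_policy Passed to [first_viral_rank()].
#' @return Tibble with `qseqid`, `first_viral_rank`, `has_viral_domain`,
#'   `verdict`, `rationale`.
#' @export
curate_candidates <- function(hits, viral_flags, domains = NULL,
                              depth = 30L, rescue_depth = 10L,
                              order_policy = c("bitscore_desc",
                                               "file_order")) {
  ranks <- first_viral_rank(hits, viral_flags, depth = depth,
                            order_policy = match.arg(order_policy))
  dom_ids <- character()
  if (!is.null(domains) && nrow(domains)) {
    dom_ids <- unique(domains$qseqid[domains$is_viral_domain])
  }
  out <- ranks |>
    dplyr::mutate(
      has_viral_domain = .data$qseqid %in% dom_ids,
      verdict = classify_candidate(.data$first_viral_rank,
                                   .data$has_viral_domain,
                                   depth = depth,
                                   rescue_depth = rescue_depth))
  out$rationale <- dplyr::case_when(
    out$verdict == "retained_domain_rule" ~ sprintf(
      "viral hit at rank %d within top %d + conserved viral domain",
      out$first_viral_rank, depth),
    out$verdict == "retained_top10_rule" ~ sprintf(
      "no viral domain, but first viral hit at rank %d within top %d",
      out$first_viral_rank, rescue_depth),
    is.na(out$first_viral_rank) ~ sprintf(
      "no viral hit within top %d", depth),
    .default = sprintf(
      "first viral hit at rank %d beyond rescue window %d and no viral domain",
      out$first_viral_rank, rescue_depth))
  out
}

#' Strict length filter for exogenous-contig selection
#'
#' Retains sequences strictly longer than `min_exclusive` nucleotides (the
#' selection step keeps contigs longer than 500 nt; a 500 nt contig is
#' dropped).
#'
#' @param seqs Sequence tibble.
#' @param min_exclusive Exclusive lower bound in nt (default 500).
#' @return The retained rows of `seqs`.
#' @export
length_filter <- function(seqs, min_exclusive = 500L) {
  check_seq_tbl(seqs)
  seqs[nchar(seqs$residues) > min_exclusive, ]
}

#' Greedy incremental identity clustering
#'
#' Redundancy reduction in the style of greedy clustering tools: sequences
#' are sorted by length descending (ties by id ascending); each sequence
#' joins the first existing cluster whose representative it matches at
#' `identity_threshold` or better, otherwise it founds a new cluster.
#' Identity is alignment-based — exact matches over the global alignment
#' length (gap columns included); the alignment itself is selected with
#' match +1, mismatch 0, gap open -10, gap extend -1. Representatives are
#' always the longest (first-sorted) member.
#'
#' @param seqs Sequence tibble.
#' @param identity_threshold Identity fraction in (0, 1]; default 0.90.
#' @return Tibble with `member_id`, `representative_id`, `cluster` (integer
#'   label), `identity` (to the representative; 1 for representatives
#'   themselves); `identity_threshold` is carried as an attribute.
#' @export
greedy_cluster <- function(seqs, identity_threshold = 0.90) {
  check_seq_tbl(seqs)
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort("identity_threshold must be in (0, 1].")
  }
  if (nrow(seqs) == 0L) {
    out <- tibble::tibble(member_id = character(),
                          representative_id = character(),
                          cluster = integer(), identity = numeric())
    attr(out, "identity_threshold") <- identity_threshold
    return(out)
  }
  ord <- order(-nchar(seqs$residues), seqs$id)
  ids <- seqs$id[ord]
  res <- seqs$residues[ord]
  rep_idx <- integer()        # indices (into ord) of representatives
  assign <- integer(length(ids))
  ident <- numeric(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (k in seq_along(rep_idx)) {
      pid <- global_identity(res[rep_idx[k]], res[i])
      if (pid >= identity_threshold) {
        assign[i] <- k
        ident[i] <- pid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assign[i] <- length(rep_idx)
      ident[i] <- 1
    }
  }
  out <- tibble::tibble(member_id = ids,
                        representative_id = ids[rep_idx][assign],
                        cluster = assign,
                        identity = ident)
  attr(out, "identity_threshold") <- identity_threshold
  out
}

#' Select candidate host subjects by strict identity
#'
#' Subjects reaching strictly more than `min_identity` percent identity in
#' at least one hit are candidate hosts for compositional profiling.
#' Optionally intersect with the set of subjects for which a mitochondrial
#' genome is available, mirroring a mitochondria-focused host shortlist.
#'
#' @param hits Hit tibble.
#' @param min_identity Exclusive percent-identity bound (default 90).
#' @param mito_available Optional character vector (or tibble with
#'   `sseqid`) restricting the result to subjects with mitochondrial
#'   genome data.
#' @return Tibble with `sseqid` and `max_pident`, one row per retained
#'   subject, sorted by id.
#' @export
select_candidate_hosts <- function(hits, min_identity = 90,
                                   mito_available = NULL) {
  if (nrow(hits) == 0L) {
    return(tibble::tibble(sseqid = character(), max_pident = numeric()))
  }
  out <- hits |>
    dplyr::group_by(.data$sseqid) |>
    dplyr::summarise(max_pident = max(.data$pident), .groups = "drop") |>
    dplyr::filter(.data$max_pident > min_identity) |>
    dplyr::arrange(.data$sseqid)
  if (!is.null(mito_available)) {
    keep <- if (is.data.frame(mito_available)) mito_available$sseqid
            else mito_available
    out <- out[out$sseqid %in% keep, ]
  }
  out
}

# ---- internals --------------------------------------------------------------

viral_subject_set <- function(viral_flags) {
  if (is.data.frame(viral_flags)) {
    need_cols(viral_flags, c("sseqid", "is_viral"), "viral flag table")
    unique(viral_flags$sseqid[viral_flags$is_viral])
  } else {
    unique(as.character(viral_flags))
  }
}

# Fraction of identical columns over the global alignment length.
global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = 0, baseOnly = TRUE),
    gapOpening = 10, gapExtension = 1)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}
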