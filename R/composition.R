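# Codon-usage and dinucleotide-composition profiling: the quantitative
# signature used for compositional virus-host matching. Counts are pooled at
# count level across all sequences/ORFs of one entity (concatenation
# semantics, as genome-scale codon-usage tools do).

#' Codon-usage profile of a set of ORFs
#'
#' Counts codons in frame over all supplied ORFs, pooled at count level.
#' Terminal stop codons are excluded by default so RSCU is defined over
#' sense codons only. RSCU(c) = count(c) x family_size / family_total within
#' each synonymous amino-acid family; an unobserved family yields RSCU 0 for
#' its codons.
#'
#' @param orfs ORF tibble as from [find_orfs()], or any tibble with an
#'   `nt_sequence` column of in-frame sequences.
#' @param entity_id Label for the profiled entity.
#' @param genetic_code NCBI code id (1 or 4); defines synonymous families.
#' @param include_stops Count stop codons too (classical CUSP behaviour);
#'   stops still get no RSCU value.
#' @return A `composition_profile` object (see [tidy.composition_profile()]).
#' @examples
#' orfs <- tibble::tibble(nt_sequence = "ATGGAAGAGTAA")
#' p <- codon_profile(orfs)
#' p$rscu[c("GAA", "GAG")]
#' @export
codon_profile <- function(orfs, entity_id = "entity", genetic_code = 1,
                          include_stops = FALSE) {
  if (!is.data.frame(orfs) || !"nt_sequence" %in% names(orfs)) {
    abort("Expected a tibble with an 'nt_sequence' column.")
  }
  code <- genetic_code_table(genetic_code)
  counts <- setNames(integer(64), ALL_CODONS)
  for (s in orfs$nt_sequence) {
    s <- toupper(s)
    if (nchar(s) %% 3 != 0) abort("Every ORF length must be a multiple of 3.")
    if (nchar(s) == 0L) next
    # drop a terminal stop before counting
    last <- substr(s, nchar(s) - 2L, nchar(s))
    if (!include_stops && !is.na(code[last]) && code[last] == "*") {
      s <- substr(s, 1L, nchar(s) - 3L)
    }
    if (nchar(s) == 0L) next
    cc <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(s),
                                             step = 3)
    counts <- counts + cc[ALL_CODONS]
  }
  n_codons <- sum(counts)
  fractions <- if (n_codons > 0) counts / n_codons else counts * 0
  new_composition_profile(
    entity_id = entity_id,
    codon_counts = counts,
    codon_fractions = fractions,
    rscu = rscu_from_counts(counts, code),
    genetic_code = genetic_code,
    n_codons = n_codons)
}

#' Dinucleotide and mononucleotide profile of nucleotide sequences
#'
#' Overlapping dinucleotides are counted linearly per sequence (no
#' wraparound) and pooled; windows containing a non-ACGT symbol are skipped.
#' The Karlin odds ratio odds(XY) = f(XY) / (f(X) f(Y)) measures departure
#' from the composition expected under independent bases; values near 1 are
#' unbiased, and the 16-vector is a genome signature.
#'
#' @param seqs Sequence tibble (`id`, `residues`) or tibble with a
#'   `residues`/`nt_sequence` column.
#' @param entity_id Label for the profiled entity.
#' @return A `composition_profile` object with `mono_freqs`, `dinuc_freqs`,
#'   `dinuc_odds` and `n_dinucs` populated.
#' @examples
#' dinuc_profile(tibble::tibble(id = "x", residues = "ATAT"))$dinuc_odds["AT"]
#' @export
dinuc_profile <- function(seqs, entity_id = "entity") {
  col <- intersect(c("residues", "nt_sequence"), names(seqs))[1]
  if (!is.data.frame(seqs) || is.na(col)) {
    abort("Expected a tibble with a 'residues' or 'nt_sequence' column.")
  }
  di <- setNames(integer(16), ALL_DINUCS)
  mono <- setNames(integer(4), DNA_BASES)
  for (s in seqs[[col]]) {
    x <- Biostrings::DNAString(toupper(s))
    mono <- mono + Biostrings::letterFrequency(x, DNA_BASES)[DNA_BASES]
    if (length(x) >= 2L) {
      di <- di + Biostrings::dinucleotideFrequency(x)[ALL_DINUCS]
    }
  }
  n_dinucs <- sum(di)
  n_mono <- sum(mono)
  mono_f <- if (n_mono > 0) mono / n_mono else mono * 0
  di_f <- if (n_dinucs > 0) di / n_dinucs else di * 0
  expected <- outer(mono_f, mono_f)
  expected <- setNames(as.vector(t(expected)),
                       as.vector(t(outer(DNA_BASES, DNA_BASES, paste0))))
  odds <- di_f[ALL_DINUCS] / expected[ALL_DINUCS]
  odds[expected[ALL_DINUCS] == 0] <- NA_real_
  if (n_dinucs == 0) odds[] <- NA_real_
  new_composition_profile(
    entity_id = entity_id,
    mono_freqs = mono_f,
    dinuc_freqs = di_f,
    dinuc_odds = odds,
    n_dinucs = n_dinucs)
}

#' Combine codon and dinucleotide profiles of one entity
#'
#' @param codon,dinuc `composition_profile` objects for the same entity.
#' @return A merged `composition_profile`.
#' @export
merge_profiles <- function(codon, dinuc) {
  stopifnot(inherits(codon, "composition_profile"),
            inherits(dinuc, "composition_profile"))
  out <- utils::modifyList(unclass(codon),
                           Filter(Negate(is.null), unclass(dinuc)))
  out$entity_id <- codon$entity_id
  structure(out, class = "composition_profile")
}

#' Feature matrix from a list of composition profiles
#'
#' Assembles entities x features tables for correlation and clustering.
#' Feature ordering is fixed (alphabetical codons, then alphabetical
#' dinucleotides) so matrices from different runs align. Columns with a
#' missing value in any profile are dropped with a message (the default
#' missing-value policy).
#'
#' @param profiles List of `composition_profile` objects.
#' @param features `"codon_fractions"`, `"rscu"`, `"dinuc_odds"` or
#'   `"concatenated"` (codon fractions + dinucleotide odds).
#' @return Tibble with `entity_id` plus one numeric column per feature.
#' @export
profile_matrix <- function(profiles,
                           features = c("concatenated", "codon_fractions",
                                        "rscu", "dinuc_odds")) {
  features <- match.arg(features)
  if (length(profiles) == 0L) abort("No profiles supplied.")
  blocks <- switch(features,
    codon_fractions = "codon_fractions",
    rscu = "rscu",
    dinuc_odds = "dinuc_odds",
    concatenated = c("codon_fractions", "dinuc_odds"))
  rows <- purrr::map(profiles, function(p) {
    stopifnot(inherits(p, "composition_profile"))
    vals <- unlist(lapply(blocks, function(b) {
      v <- p[[b]]
      if (is.null(v)) abort(sprintf(
        "Profile '%s' does not carry the '%s' block.", p$entity_id, b))
      v
    }))
    tibble::as_tibble(as.list(vals)) |>
      dplyr::mutate(entity_id = p$entity_id, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  has_na <- names(out)[vapply(out, anyNA, logical(1))]
  if (length(has_na)) {
    inform(sprintf("Dropping feature column(s) with missing values: %s.",
                   paste(has_na, collapse = ", ")))
    out <- out[, setdiff(names(out), has_na)]
  }
  out
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("<composition_profile> ", x$entity_id, "\n", sep = "")
  if (!is.null(x$n_codons)) cat("  codons counted: ", x$n_codons, "\n", sep = "")
  if (!is.null(x$n_dinucs)) cat("  dinucleotide windows: ", x$n_dinucs, "\n",
                                sep = "")
  invisible(x)
}

#' Tidy a composition profile into a long tibble
#'
#' @param x A `composition_profile`.
#' @param ... Unused.
#' @return Tibble with `entity_id`, `metric`, `feature`, `value`.
#' @export
tidy.composition_profile <- function(x, ...) {
  blocks <- c("codon_counts", "codon_fractions", "rscu", "mono_freqs",
              "dinuc_freqs", "dinuc_odds")
  rows <- purrr::map(blocks, function(b) {
    v <- x[[b]]
    if (is.null(v)) return(NULL)
    tibble::tibble(entity_id = x$entity_id, metric = b,
                   feature = names(v), value = as.numeric(v))
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a composition profile
#'
#' @param x A `composition_profile`.
#' @param ... Unused.
#' @return One-row tibble with counts and GC content.
#' @export
glance.composition_profile <- function(x, ...) {
  gc <- if (!is.null(x$mono_freqs)) unname(x$mono_freqs["G"] +
                                           x$mono_freqs["C"]) else NA_real_
  tibble::tibble(entity_id = x$entity_id,
                 n_codons = x$n_codons %||% NA_integer_,
                 n_dinucs = x$n_dinucs %||% NA_integer_,
                 gc_content = gc)
}

# ---- internals --------------------------------------------------------------

new_composition_profile <- function(entity_id, codon_counts = NULL,
                                    codon_fractions = NULL, rscu = NULL,
                                    mono_freqs = NULL, dinuc_freqs = NULL,
                                    dinuc_odds = NULL, genetic_code = NULL,
                                    n_codons = NULL, n_dinucs = NULL) {
  structure(list(entity_id = entity_id, codon_counts = codon_counts,
                 codon_fractions = codon_fractions, rscu = rscu,
                 mono_freqs = mono_freqs, dinuc_freqs = dinuc_freqs,
                 dinuc_odds = dinuc_odds, genetic_code = genetic_code,
                 n_codons = n_codons, n_dinucs = n_dinucs),
            class = "composition_profile")
}

rscu_from_counts <- function(counts, code) {
  sense <- names(code)[code != "*"]
  fam <- split(sense, code[sense])
  out <- setNames(numeric(length(sense)), sort(sense))
  for (codons in fam) {
    total <- sum(counts[codons])
    k <- length(codons)
    out[codons] <- if (total > 0) counts[codons] * k / total else 0
  }
  out[sort(sense)]
}
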