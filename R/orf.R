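# ORF prediction in the two modes used for virome triage: "complete"
# (ATG -> in-frame stop, ORFfinder-like contig characterization) and
# "region" (maximal stop-free stretch between stops, getorf-like genome
# screening). Coordinates are 0-based half-open on the forward strand.

#' Predict open reading frames
#'
#' Two modes mirror the two prediction styles used in virome triage:
#'
#' * `mode = "complete"`: spans from an `ATG` to the next in-frame stop
#'   codon; the stop codon is included in the reported length. By default
#'   only the longest ORF per (frame, stop) is reported — internal ATGs are
#'   suppressed unless `all_starts = TRUE`.
#' * `mode = "region"`: maximal stop-free translatable regions between stop
#'   codons (or sequence ends), stop excluded — the convention of
#'   getorf-style genome screens for endogenous viral elements.
#'
#' ORFs whose span contains an ambiguity code (`N` etc.) in any codon are
#' excluded. Both strands are scanned unless `strands = "forward"`.
#'
#' @param seqs Sequence tibble (`id`, `residues`), as from [read_fasta()].
#' @param mode `"complete"` or `"region"`.
#' @param min_len,max_len Length bounds in nucleotides, inclusive. The
#'   defaults (100-6000 nt) are the screening range used for endogenous
#'   viral element discovery.
#' @param genetic_code NCBI genetic code id: `1` (standard) or `4` (mold /
#'   protozoan mitochondrial, where `TGA` reads Trp) — relevant because
#'   mitoviruses are translated by the mitochondrial machinery.
#' @param strands `"both"` or `"forward"`.
#' @param all_starts In complete mode, also report nested ORFs from
#'   internal ATGs sharing a stop.
#' @return Tibble with one row per ORF: `parent_id`, `start` (0-based),
#'   `end` (exclusive, forward-strand coordinates), `strand` (`"+"`/`"-"`),
#'   `length_nt`, `frame`, `has_start_codon`, `has_stop_codon`,
#'   `nt_sequence`. Sorted by (`parent_id`, `start`, `strand`).
#' @examples
#' seqs <- tibble::tibble(id = "x", residues = "ATGAAATAG")
#' find_orfs(seqs, mode = "complete", min_len = 3)
#' @export
find_orfs <- function(seqs, mode = c("region", "complete"),
                      min_len = 100L, max_len = 6000L,
                      genetic_code = 1, strands = c("both", "forward"),
                      all_starts = FALSE) {
  check_seq_tbl(seqs)
  mode <- match.arg(mode)
  strands <- match.arg(strands)
  if (min_len < 3) abort("min_len must be >= 3 nt.")
  if (max_len < min_len) abort("max_len must be >= min_len.")
  stops <- stop_codons(genetic_code)

  rows <- purrr::map2(seqs$id, seqs$residues, function(id, res) {
    n <- nchar(res)
    if (n < 3L) return(NULL)
    strand_set <- if (strands == "both") c("+", "-") else "+"
    purrr::map(strand_set, function(strand) {
      s <- if (strand == "+") res else revcomp(res)
      out <- purrr::map(0:2, function(frame) {
        orfs_in_frame(s, frame, mode, stops, all_starts)
      })
      out <- dplyr::bind_rows(out)
      if (nrow(out) == 0L) return(out)
      out$strand <- strand
      if (strand == "-") {
        # mirror scanned (revcomp) coordinates back to the forward strand
        tmp <- out$start
        out$start <- n - out$end
        out$end <- n - tmp
      }
      out$parent_id <- id
      out
    })
  })
  out <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  if (nrow(out) == 0L) return(empty_orf_tbl())
  out$length_nt <- out$end - out$start
  out <- out[out$length_nt >= min_len & out$length_nt <= max_len, ]
  out <- out[!grepl("[^ACGT]", out$nt_sequence), ]
  out <- tibble::as_tibble(out[, c("parent_id", "start", "end", "strand",
                                   "length_nt", "frame", "has_start_codon",
                                   "has_stop_codon", "nt_sequence")])
  out[order(out$parent_id, out$start, out$strand), ]
}

#' Translate an in-frame nucleotide sequence
#'
#' @param nt Character vector of nucleotide sequences, each with length a
#'   multiple of 3.
#' @param genetic_code NCBI code id `1` or `4` (`TGA` is Trp under code 4).
#' @param ambiguous `"error"` (default) to fail on codons containing
#'   ambiguity characters, `"X"` to translate them as `X`.
#' @return Character vector of amino-acid strings; stops rendered as `*`.
#' @examples
#' translate_dna("ATGTGA")                  # "M*"
#' translate_dna("ATGTGA", genetic_code = 4)  # "MW"
#' @export
translate_dna <- function(nt, genetic_code = 1,
                          ambiguous = c("error", "X")) {
  ambiguous <- match.arg(ambiguous)
  code <- genetic_code_table(genetic_code)
  vapply(nt, function(s) {
    s <- toupper(s)
    if (nchar(s) %% 3 != 0) {
      abort("Sequence length is not a multiple of 3.")
    }
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- unname(code[codons])
    if (anyNA(aa)) {
      if (ambiguous == "error") {
        abort(sprintf("Codon '%s' contains ambiguous characters.",
                      codons[which(is.na(aa))[1L]]))
      }
      aa[is.na(aa)] <- "X"
    }
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of IUPAC DNA strings.
#' @return Reverse complement(s), uppercase.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      toupper(s))))
  }, character(1), USE.NAMES = FALSE)
}

# ---- internals --------------------------------------------------------------

genetic_code_table <- function(genetic_code) {
  id <- as.character(genetic_code)
  if (!id %in% c("1", "4")) {
    abort(sprintf("Unsupported genetic code '%s'; use 1 or 4.", id))
  }
  Biostrings::getGeneticCode(id)
}

stop_codons <- function(genetic_code) {
  code <- genetic_code_table(genetic_code)
  names(code)[code == "*"]
}

# Scan one frame of one (already strand-resolved) sequence. Coordinates
# returned are relative to the scanned string; caller mirrors minus-strand.
orfs_in_frame <- function(s, frame, mode, stops, all_starts) {
  n <- nchar(s)
  n_codons <- (n - frame) %/% 3
  if (n_codons < 1L) return(NULL)
  starts_nt <- frame + 3L * (seq_len(n_codons) - 1L)   # 0-based codon starts
  codons <- substring(s, starts_nt + 1L, starts_nt + 3L)
  is_stop <- codons %in% stops
  is_atg <- codons == "ATG"

  if (mode == "region") {
    # runs of non-stop codons delimited by stops or sequence ends
    r <- rle(is_stop)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    keep <- !r$values
    purrr::map(which(keep), function(k) {
      i <- idx_start[k]; j <- idx_end[k]
      tibble::tibble(
        start = starts_nt[i],
        end = starts_nt[j] + 3L,
        frame = frame,
        has_start_codon = is_atg[i],
        has_stop_codon = FALSE,
        nt_sequence = substr(s, starts_nt[i] + 1L, starts_nt[j] + 3L))
    }) |> dplyr::bind_rows()
  } else {
    if (!any(is_atg) || !any(is_stop)) return(NULL)
    stop_idx <- which(is_stop)
    atg_idx <- which(is_atg)
    # next in-frame stop at-or-after each ATG
    nxt <- stop_idx[findInterval(atg_idx, stop_idx) + 1L]
    ok <- !is.na(nxt)
    atg_idx <- atg_idx[ok]; nxt <- nxt[ok]
    if (length(atg_idx) == 0L) return(NULL)
    if (!all_starts) {
      first_per_stop <- !duplicated(nxt)   # atg_idx ascending => first = longest
      atg_idx <- atg_idx[first_per_stop]; nxt <- nxt[first_per_stop]
    }
    tibble::tibble(
      start = starts_nt[atg_idx],
      end = starts_nt[nxt] + 3L,
      frame = frame,
      has_start_codon = TRUE,
      has_stop_codon = TRUE,
      nt_sequence = substr(s, starts_nt[atg_idx] + 1L, starts_nt[nxt] + 3L))
  }
}

empty_orf_tbl <- function() {
  tibble::tibble(parent_id = character(), start = integer(),
                 end = integer(), strand = character(),
                 length_nt = integer(), frame = integer(),
                 has_start_codon = logical(), has_stop_codon = logical(),
                 nt_sequence = character())
}
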