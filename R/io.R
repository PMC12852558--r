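# Readers and writers for the external formats the pipeline touches.
# Sequences travel as tibbles (id, description, residues); hit tables and
# quantification tables as tibbles in file order.

#' Read a FASTA file or literal FASTA text into a sequence tibble
#'
#' Residues are uppercased and `U` is normalized to `T` on ingest so all
#' downstream codon/k-mer arithmetic runs on a DNA alphabet, regardless of
#' whether the source was an RNA virus genome or a DNA reference.
#'
#' @param source Path to a FASTA file, or a character scalar/vector of
#'   FASTA-formatted text (anything containing a newline or starting with
#'   `>` is treated as literal text).
#' @return A tibble with columns `id` (header token up to the first
#'   whitespace), `description` (full header line) and `residues`
#'   (uppercase IUPAC DNA string).
#' @examples
#' read_fasta(">s1 a demo\nacgu\n>s2\nTTTT")
#' @export
read_fasta <- function(source) {
  lines <- source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(id = character(), description = character(),
                          residues = character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    abort("FASTA input does not start with a '>' header line.")
  }
  rec <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  ids <- sub("\\s.*$", "", headers)
  seqs <- vapply(split(lines[!is_header], rec[!is_header]),
                 paste0, character(1), collapse = "")
  # records with no body lines are absent from `seqs`
  present <- as.character(seq_along(headers)) %in% names(seqs)
  if (!all(present)) {
    abort(sprintf("FASTA record '%s' has an empty sequence.",
                  ids[which(!present)[1L]]))
  }
  seqs <- unname(seqs[as.character(seq_along(headers))])
  residues <- toupper(seqs)
  residues <- gsub("U", "T", residues, fixed = TRUE)
  bad <- grepl(paste0("[^", paste(IUPAC_NT, collapse = ""), "]"), residues)
  if (any(bad)) {
    abort(sprintf("Record '%s' contains non-IUPAC nucleotide characters.",
                  ids[which(bad)[1L]]))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate sequence id '%s' in FASTA input.",
                  ids[anyDuplicated(ids)]))
  }
  tibble::tibble(id = ids, description = headers, residues = residues)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with `id`, `residues` and optionally `description`.
#' @param path Output file path.
#' @param width Line-wrap width for residues.
#' @return `seqs`, invisibly, so the call can sit inside a pipe.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  check_seq_tbl(seqs)
  desc <- if ("description" %in% names(seqs)) seqs$description else seqs$id
  desc <- ifelse(is.na(desc) | !nzchar(desc), seqs$id, desc)
  out <- purrr::map2(desc, seqs$residues, function(d, s) {
    body <- substring(s, seq(1L, nchar(s), width),
                      pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    c(paste0(">", d), body)
  })
  writeLines(unlist(out), path)
  invisible(seqs)
}

BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column BLAST/DIAMOND tabular hit file
#'
#' Expects the standard tabular column order (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`). Within-query
#' row order is preserved exactly; downstream rank semantics depend on it.
#'
#' @param source Path or literal tab-separated text.
#' @return Tibble with the 12 standard columns, rows in file order.
#' @export
read_blast_tab <- function(source) {
  lines <- source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::as_tibble(setNames(
      as.list(rep(list(character(0)), 12)), BLAST6_COLS))[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    abort(sprintf("Line %d has %d columns; 12 expected.",
                  which(nf != 12L)[1L], nf[nf != 12L][1L]))
  }
  m <- do.call(rbind, fields)
  num_cols <- c(3:12)
  suppressWarnings(nums <- apply(m[, num_cols, drop = FALSE], 2, as.numeric))
  nums <- matrix(nums, ncol = length(num_cols))
  if (anyNA(nums)) {
    bad_line <- which(apply(is.na(nums), 1, any))[1L]
    abort(sprintf("Non-numeric value in numeric column on line %d.", bad_line))
  }
  out <- tibble::tibble(
    qseqid = m[, 1], sseqid = m[, 2], pident = nums[, 1],
    length = as.integer(nums[, 2]), mismatch = as.integer(nums[, 3]),
    gapopen = as.integer(nums[, 4]), qstart = as.integer(nums[, 5]),
    qend = as.integer(nums[, 6]), sstart = as.integer(nums[, 7]),
    send = as.integer(nums[, 8]), evalue = nums[, 9], bitscore = nums[, 10])
  if (any(out$pident < 0 | out$pident > 100)) {
    abort("pident outside [0, 100].")
  }
  if (any(out$evalue < 0)) abort("Negative evalue.")
  if (any(out$qstart < 1L | out$qend < 1L)) {
    abort("Query coordinates must be 1-based (>= 1).")
  }
  out
}

#' Read a Salmon-style quantification table
#'
#' Accepts `quant.sf`-style headers (`Name`, `Length`, `EffectiveLength`,
#' `TPM`, `NumReads`, case-insensitive) or minimal `name/length/num_reads`
#' tables. Optional columns absent from the file are returned as `NA`.
#'
#' @param source Path or literal TSV text.
#' @return Tibble with columns `name`, `length`, `effective_length`,
#'   `num_reads`, `tpm`.
#' @export
read_quant_table <- function(source) {
  df <- read_tsv_quiet(source)
  names(df) <- tolower(gsub("[^A-Za-z]", "_", names(df)))
  aliases <- c(name = "name", length = "length",
               effectivelength = "effective_length",
               effective_length = "effective_length",
               numreads = "num_reads", num_reads = "num_reads", tpm = "tpm")
  keep <- names(df) %in% names(aliases)
  names(df)[keep] <- unname(aliases[names(df)[keep]])
  for (col in c("name", "length", "num_reads")) {
    if (!col %in% names(df)) {
      abort(sprintf("Quantification table is missing mandatory column '%s'.",
                    col))
    }
  }
  out <- tibble::tibble(
    name = as.character(df$name),
    length = as.integer(df$length),
    effective_length = if ("effective_length" %in% names(df))
      as.numeric(df$effective_length) else NA_real_,
    num_reads = as.numeric(df$num_reads),
    tpm = if ("tpm" %in% names(df)) as.numeric(df$tpm) else NA_real_)
  if (any(out$length < 1L)) abort("Feature length must be >= 1 nt.")
  if (any(out$num_reads < 0)) abort("num_reads must be non-negative.")
  out
}

#' Read a viral-subject flag table
#'
#' Two-column TSV (`sseqid`, `is_viral`) marking which subject accessions in
#' a hit table count as viral. This flag table stands in for a live viral
#' sequence database: the pipeline never queries one.
#'
#' @param source Path or literal TSV text.
#' @return Tibble with `sseqid` (character) and `is_viral` (logical).
#' @export
read_viral_flags <- function(source) {
  df <- read_tsv_quiet(source)
  need_cols(df, c("sseqid", "is_viral"), "viral flag table")
  tibble::tibble(sseqid = as.character(df$sseqid),
                 is_viral = as_flag(df$is_viral))
}

#' Read a conserved-domain annotation table
#'
#' TSV with one row per (query, domain accession) pair and a flag saying
#' whether the domain is viral; produced externally by CD-Search-like tools.
#'
#' @param source Path or literal TSV text.
#' @return Tibble with `qseqid`, `domain_accession`, `is_viral_domain`.
#' @export
read_domain_table <- function(source) {
  df <- read_tsv_quiet(source)
  need_cols(df, c("qseqid", "domain_accession", "is_viral_domain"),
            "domain annotation table")
  out <- tibble::tibble(qseqid = as.character(df$qseqid),
                        domain_accession = as.character(df$domain_accession),
                        is_viral_domain = as_flag(df$is_viral_domain))
  dplyr::distinct(out, .data$qseqid, .data$domain_accession, .keep_all = TRUE)
}

#' Read library metadata (library, project, treatment)
#'
#' @param source Path or literal TSV text.
#' @return Tibble with `library_id`, `project_id`, `treatment`.
#' @export
read_library_metadata <- function(source) {
  df <- read_tsv_quiet(source)
  need_cols(df, c("library_id", "project_id", "treatment"),
            "library metadata")
  if (anyDuplicated(df$library_id)) {
    abort("library_id values must be unique.")
  }
  tibble::tibble(library_id = as.character(df$library_id),
                 project_id = as.character(df$project_id),
                 treatment = as.character(df$treatment))
}

# ---- internal helpers -------------------------------------------------------

source_lines <- function(source) {
  literal <- length(source) != 1L || !nzchar(source[1]) ||
    grepl("[\n\t>]", source[1])
  if (literal) {
    unlist(strsplit(source, "\n", fixed = TRUE))
  } else if (file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    abort(sprintf("File not found: '%s'.", source))
  }
}

read_tsv_quiet <- function(source) {
  if (length(source) == 1L && !grepl("\n", source)) {
    if (!file.exists(source)) abort(sprintf("File not found: '%s'.", source))
    readr::read_tsv(source, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(I(paste(source, collapse = "\n")),
                    show_col_types = FALSE, progress = FALSE)
  }
}

need_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s.", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  out <- v %in% c("true", "t", "1", "yes", "y")
  bad <- !v %in% c("true", "t", "1", "yes", "y", "false", "f", "0", "no", "n")
  if (any(bad)) abort(sprintf("Cannot interpret '%s' as a logical flag.",
                              v[bad][1L]))
  out
}

check_seq_tbl <- function(seqs) {
  if (!is.data.frame(seqs) || !all(c("id", "residues") %in% names(seqs))) {
    abort("Expected a sequence tibble with columns 'id' and 'residues'.")
  }
  invisible(seqs)
}
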