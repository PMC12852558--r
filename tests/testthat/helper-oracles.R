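# Independent oracles and fixture builders. The oracles deliberately use
# naive enumeration (nested loops over positions, hand-computed ranks) so
# they share no code path with the implementation they check.

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Brute-force six-frame ORF scan. Enumerates every codon position; complete
# mode walks ATG -> first in-frame stop (stop included, longest per stop
# unless all_starts); region mode emits maximal stop-free codon runs.
# Returns forward-strand 0-based half-open coordinates.
oracle_orfs <- function(s, mode, min_len, max_len, all_starts = FALSE) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    x <- if (strand == "+") s else oracle_revcomp(s)
    for (frame in 0:2) {
      starts <- seq(frame + 1, n - 2, by = 3)
      if (length(starts) == 0) next
      codons <- substring(x, starts, starts + 2)
      if (mode == "complete") {
        spans <- list()
        for (i in seq_along(codons)) {
          if (codons[i] != "ATG") next
          j <- i
          while (j <= length(codons) && !(codons[j] %in% stops)) j <- j + 1
          if (j > length(codons)) next
          spans[[length(spans) + 1]] <- c(i, j)
        }
        if (!all_starts && length(spans)) {
          ends <- vapply(spans, `[`, numeric(1), 2)
          spans <- spans[!duplicated(ends)]   # first ATG per stop = longest
        }
      } else {
        spans <- list()
        i <- 1
        while (i <= length(codons)) {
          if (codons[i] %in% stops) { i <- i + 1; next }
          j <- i
          while (j + 1 <= length(codons) && !(codons[j + 1] %in% stops)) {
            j <- j + 1
          }
          spans[[length(spans) + 1]] <- c(i, j)
          i <- j + 2
        }
      }
      for (sp in spans) {
        a <- starts[sp[1]] - 1          # 0-based on scanned strand
        b <- starts[sp[2]] + 2
        len <- b - a
        if (len < min_len || len > max_len) next
        nt <- substr(x, a + 1, b)
        if (grepl("[^ACGT]", nt)) next
        if (strand == "-") { tmp <- a; a <- n - b; b <- n - tmp }
        out[[length(out) + 1]] <- tibble::tibble(
          start = a, end = b, strand = strand, length_nt = len)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), length_nt = integer()))
  }
  dplyr::arrange(res, start, strand)
}

# Hand-rolled Spearman: average ranks, then the Pearson formula written out.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Naive stride-3 codon counter (string chopping only).
oracle_codon_counts <- function(nt) {
  codons <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
  table(codons)
}

# Mutate a template with a given substitution rate (no indels).
mutate_seq <- function(s, rate, seed) {
  set.seed(seed)
  chars <- strsplit(s, "")[[1]]
  hit <- runif(length(chars)) < rate
  chars[hit] <- vapply(chars[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(chars, collapse = "")
}

# 4 templates x 5 mutated copies at 3% substitutions: the clustering fixture.
cluster_fixture <- function(seed = 42) {
  set.seed(seed)
  templates <- vapply(1:4, function(i) {
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  }, character(1))
  rows <- purrr::map(1:4, function(t) {
    purrr::map(1:5, function(k) {
      tibble::tibble(
        id = sprintf("t%d_copy%d", t, k),
        template = t,
        residues = if (k == 1) templates[t]
                   else mutate_seq(templates[t], 0.03, seed * 100 + t * 10 + k))
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

# Closed-form curation truth table over the full (rank, domain) grid.
truth_table_grid <- function(depth = 30L, rescue = 10L) {
  grid <- tidyr::expand_grid(rank = c(NA, seq_len(depth)),
                             domain = c(TRUE, FALSE))
  grid$expected <- dplyr::case_when(
    !is.na(grid$rank) & grid$domain ~ "retained_domain_rule",
    !is.na(grid$rank) & grid$rank <= rescue & !grid$domain ~
      "retained_top10_rule",
    .default = "excluded")
  grid
}
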