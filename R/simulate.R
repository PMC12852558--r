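# Seeded generators of synthetic inputs carrying the statistical structure
# every pipeline stage assumes: divergent host codon-usage profiles, viral
# ORFs sampled from a host profile with controllable noise, ranked hit
# tables with a planted first-viral-hit rank, and expression fixtures with
# planted between-group fold changes. Every generator is a pure function of
# its arguments plus `seed`.

#' Generate divergent host codon-usage profiles
#'
#' For each host, each synonymous amino-acid family receives an independent
#' symmetric Dirichlet draw over its codons. Low `concentration` produces
#' spiky, mutually divergent codon preferences (strong codon bias); as
#' `concentration` grows the families approach uniform use and RSCU tends
#' to 1. Amino acids themselves are taken as uniformly used, so the
#' codon-fraction vector is p(aa) x p(codon | aa) with p(aa) = 1/20.
#'
#' @param n_hosts Number of host profiles.
#' @param concentration Dirichlet concentration per family codon
#'   (default 0.5: clearly divergent hosts).
#' @param seed Integer seed; same seed, same profiles.
#' @param genetic_code NCBI code id defining the synonymous families.
#' @return List of `composition_profile` objects (`host_1`, `host_2`, ...),
#'   each carrying `codon_fractions`, `rscu` and a `family_probs` element
#'   (p(codon | amino acid), used by [sample_viral_orfs()]).
#' @export
make_host_profiles <- function(n_hosts, concentration = 0.5, seed = 1,
                               genetic_code = 1) {
  if (n_hosts < 1) abort("n_hosts must be >= 1.")
  code <- genetic_code_table(genetic_code)
  sense <- names(code)[code != "*"]
  fams <- split(sense, code[sense])
  fams <- fams[setdiff(names(fams), "M")]  # ATG fixed; no choice to draw
  with_seed_(seed, {
    purrr::map(seq_len(n_hosts), function(h) {
      probs <- setNames(numeric(64), ALL_CODONS)
      probs["ATG"] <- 1
      for (codons in fams) {
        g <- rgamma(length(codons), shape = concentration)
        if (sum(g) == 0) g <- rep(1, length(codons))
        probs[codons] <- g / sum(g)
      }
      aas <- unique(code[sense])
      fractions <- setNames(numeric(64), ALL_CODONS)
      for (aa in aas) {
        codons <- sense[code[sense] == aa]
        fractions[codons] <- probs[codons] / length(aas)
      }
      counts <- round(fractions * 1e6)
      p <- new_composition_profile(
        entity_id = paste0("host_", h),
        codon_counts = counts,
        codon_fractions = fractions,
        rscu = rscu_from_counts(fractions * 1e6, code),
        genetic_code = genetic_code,
        n_codons = sum(counts))
      p$family_probs <- probs
      p
    })
  })
}

#' Sample viral ORFs from a host codon-usage profile
#'
#' Generates complete ORFs (ATG, coding body, terminal stop) whose
#' amino-acid sequence is uniform over the 20 amino acids while each codon
#' choice follows the host's family preferences with probability
#' `1 - noise_fraction` and is uniform over the family with probability
#' `noise_fraction`. This isolates exactly the signal compositional host
#' inference is meant to detect: at noise 0 the viral codon usage converges
#' to the host's; at noise 1 it is independent of it.
#'
#' @param host_profile A profile from [make_host_profiles()] (must carry
#'   `family_probs`).
#' @param orf_codons Number of body codons per ORF (>= 10).
#' @param noise_fraction Probability in \[0, 1\] that a codon ignores the
#'   host preference.
#' @param seed Integer seed.
#' @param n_viruses Number of ORFs to sample.
#' @param ids Optional ids; default `"<host>_virus_<i>"`.
#' @return Sequence tibble with `id`, `host_id`, `residues` and
#'   `nt_sequence` (identical to `residues`, so the result feeds both
#'   [codon_profile()] and [dinuc_profile()] directly).
#' @export
sample_viral_orfs <- function(host_profile, orf_codons = 300,
                              noise_fraction = 0, seed = 1, n_viruses = 1,
                              ids = NULL) {
  stopifnot(inherits(host_profile, "composition_profile"))
  if (is.null(host_profile$family_probs)) {
    abort("host_profile must carry family_probs (see make_host_profiles()).")
  }
  if (orf_codons < 10) abort("orf_codons must be >= 10.")
  if (noise_fraction < 0 || noise_fraction > 1) {
    abort("noise_fraction must be in [0, 1].")
  }
  code <- genetic_code_table(host_profile$genetic_code %||% 1)
  sense <- names(code)[code != "*"]
  fams <- split(sense, code[sense])
  stops <- names(code)[code == "*"]
  aas <- names(fams)
  probs <- host_profile$family_probs
  if (is.null(ids)) {
    ids <- paste0(host_profile$entity_id, "_virus_", seq_len(n_viruses))
  }
  with_seed_(seed, {
    residues <- vapply(seq_len(n_viruses), function(v) {
      aa_seq <- sample(aas, orf_codons, replace = TRUE)
      codons <- vapply(aa_seq, function(aa) {
        codons_aa <- fams[[aa]]
        if (length(codons_aa) == 1L) return(codons_aa)
        if (runif(1) < noise_fraction) {
          sample(codons_aa, 1L)
        } else {
          sample(codons_aa, 1L, prob = probs[codons_aa])
        }
      }, character(1))
      paste0("ATG", paste(codons, collapse = ""),
             sample(stops, 1L))
    }, character(1))
    tibble::tibble(id = ids, host_id = host_profile$entity_id,
                   residues = residues, nt_sequence = residues)
  })
}

#' Build synthetic ranked hit tables with planted viral ranks
#'
#' For each query, emits 30 hits with strictly decreasing bitscores; when a
#' viral rank is planted, the subject at that rank is flagged viral in the
#' companion flag table. Domain rows are emitted for queries marked as
#' carrying a conserved viral domain. The three outputs are plain text in
#' the exact formats the package readers consume, so fixtures round-trip
#' through the normal IO path.
#'
#' @param spec Tibble with columns `planted_rank` (integer in \[1, 30\] or
#'   `NA`) and `has_domain` (logical); optional `qseqid`.
#' @param seed Integer seed (jitters scores and coordinates only).
#' @param n_hits Hits emitted per query (default 30).
#' @return List with `blast_text`, `viral_flags_text`, `domains_text`
#'   (character scalars) and `spec` (the input with qseqids filled in).
#' @export
make_hit_tables <- function(spec, seed = 1, n_hits = 30L) {
  need_cols(spec, c("planted_rank", "has_domain"), "hit-table spec")
  if (any(!is.na(spec$planted_rank) &
          (spec$planted_rank < 1 | spec$planted_rank > n_hits))) {
    abort(sprintf("planted_rank must be in [1, %d] or NA.", n_hits))
  }
  if (!"qseqid" %in% names(spec)) {
    spec$qseqid <- sprintf("query_%03d", seq_len(nrow(spec)))
  }
  with_seed_(seed, {
    per_query <- purrr::pmap(
      list(spec$qseqid, spec$planted_rank, spec$has_domain),
      function(q, rank, has_dom) {
        viral_rank <- if (is.na(rank)) 0L else as.integer(rank)
        sbj <- ifelse(seq_len(n_hits) == viral_rank,
                      paste0(q, "_viralsubj"),
                      sprintf("%s_subj_%02d", q, seq_len(n_hits)))
        bits <- round(500 - 5 * (seq_len(n_hits) - 1) - runif(n_hits, 0, 2), 1)
        alen <- sample(80:300, n_hits, replace = TRUE)
        lines <- sprintf(
          "%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.1f",
          q, sbj, round(runif(n_hits, 40, 99), 1), alen,
          sample(0:20, n_hits, replace = TRUE),
          sample(0:3, n_hits, replace = TRUE),
          1L, alen, 1L, alen,
          10^(-bits / 10), bits)
        flags <- sprintf("%s\t%s", sbj,
                         ifelse(seq_len(n_hits) == viral_rank,
                                "TRUE", "FALSE"))
        list(blast = lines, flags = flags,
             domain = if (has_dom) sprintf("%s\tcl%05d\tTRUE", q,
                                           sample(10000:99999, 1))
                      else character())
      })
    list(
      blast_text = paste(unlist(lapply(per_query, `[[`, "blast")),
                         collapse = "\n"),
      viral_flags_text = paste(
        c("sseqid\tis_viral", unlist(lapply(per_query, `[[`, "flags"))),
        collapse = "\n"),
      domains_text = paste(
        c("qseqid\tdomain_accession\tis_viral_domain",
          unlist(lapply(per_query, `[[`, "domain"))),
        collapse = "\n"),
      spec = spec)
  })
}

#' Build a synthetic expression fixture with planted fold changes
#'
#' Emulates an inoculated-vs-uninfected design: endogenous control genes at
#' stable TPM across all libraries, and infection-associated viral features
#' at `baseline_tpm` in group B and `baseline_tpm x planted_fold` in group
#' A, each observation perturbed by lognormal noise (`sigma_log10` on the
#' log10 scale, median-preserving). A background feature absorbs the
#' remainder of each library so per-library TPM sums to one million, and
#' read counts are back-computed so [tpm_from_counts()] reproduces the
#' planted TPM values exactly.
#'
#' @param n_viruses Number of planted viral features.
#' @param planted_fold True group-A / group-B fold change (> 0).
#' @param baseline_tpm Group-B median TPM of viral features.
#' @param control_tpm Named vector of control-gene median TPM levels.
#' @param n_libraries_per_group Libraries per group (default 3 vs 3).
#' @param sigma_log10 Lognormal noise SD on the log10 scale (default 0.5).
#' @param seed Integer seed.
#' @return List with `quants` (named list of quant tibbles), `metadata`
#'   (library metadata tibble), `control_ids`, `group_a`, `group_b`,
#'   `truth` (planted per-feature fold tibble).
#' @export
make_expression_fixture <- function(n_viruses = 4, planted_fold = 112,
                                    baseline_tpm = 20,
                                    control_tpm = c(ACT7 = 800, H1 = 400,
                                                    COX2 = 1200),
                                    n_libraries_per_group = 3,
                                    sigma_log10 = 0.5, seed = 1) {
  if (planted_fold <= 0) abort("planted_fold must be > 0.")
  if (n_libraries_per_group < 1) abort("Need at least one library per group.")
  virus_ids <- sprintf("virus_%02d", seq_len(n_viruses))
  ctrl_ids <- names(control_tpm)
  feats <- c(virus_ids, ctrl_ids, "background")
  lengths <- setNames(c(sample_lengths(n_viruses, seed),
                        rep(1200L, length(ctrl_ids)), 100000L), feats)
  group_a <- sprintf("libA_%d", seq_len(n_libraries_per_group))
  group_b <- sprintf("libB_%d", seq_len(n_libraries_per_group))
  libs <- c(group_a, group_b)
  with_seed_(seed, {
    quants <- setNames(purrr::map(libs, function(lib) {
      in_a <- lib %in% group_a
      virus_mu <- baseline_tpm * if (in_a) planted_fold else 1
      tpm <- c(virus_mu * 10^rnorm(n_viruses, 0, sigma_log10),
               control_tpm * 10^rnorm(length(ctrl_ids), 0, sigma_log10))
      tpm <- setNames(tpm, c(virus_ids, ctrl_ids))
      if (sum(tpm) >= 1e6) abort("Planted TPM levels exceed one million.")
      tpm <- c(tpm, background = 1e6 - sum(tpm))
      # fractional reads: rate proportional to TPM x length
      reads <- tpm * lengths[feats] / 1e3
      tibble::tibble(name = feats, length = unname(lengths[feats]),
                     effective_length = unname(lengths[feats]),
                     num_reads = unname(reads), tpm = unname(tpm))
    }), libs)
    metadata <- tibble::tibble(
      library_id = libs,
      project_id = "SIM0001",
      treatment = ifelse(libs %in% group_a, "inoculated", "uninfected"))
    list(quants = quants, metadata = metadata, control_ids = ctrl_ids,
         group_a = group_a, group_b = group_b,
         truth = tibble::tibble(
           feature_id = feats,
           planted_fold = c(rep(planted_fold, n_viruses),
                            rep(1, length(ctrl_ids)), NA_real_)))
  })
}

# ---- internals --------------------------------------------------------------

sample_lengths <- function(n, seed) {
  with_seed_(seed + 104729L, as.integer(round(runif(n, 800, 6000))))
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed_ <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Host-recovery experiment on synthetic viruses
#'
#' Generates divergent host profiles, samples viral ORFs from each at a
#' given codon-choice noise level, profiles the viruses, and scores how
#' often best-correlate assignment recovers the generating host. This is
#' the calibration experiment for compositional host inference: accuracy
#' near 1 at low noise and near 1/n_hosts at noise 1 brackets the signal
#' the method can exploit.
#'
#' @param n_hosts Number of generating hosts (default 5).
#' @param viruses_per_host Viruses sampled per host (default 6, i.e. 30
#'   viruses in total at the default host count).
#' @param orf_codons Body codons per viral ORF (default 300).
#' @param noise_fraction Codon-choice noise in \[0, 1\].
#' @param concentration Host-divergence Dirichlet concentration.
#' @param seed Integer seed.
#' @return One-row tibble: `noise_fraction`, `accuracy`, `n_viruses`.
#' @export
simulate_host_recovery <- function(n_hosts = 5, viruses_per_host = 6,
                                   orf_codons = 300, noise_fraction = 0.1,
                                   concentration = 0.5, seed = 1) {
  hosts <- make_host_profiles(n_hosts, concentration, seed = seed)
  host_tbl <- profile_matrix(hosts, "codon_fractions")
  seqs <- dplyr::bind_rows(purrr::imap(hosts, function(p, i) {
    sample_viral_orfs(p, orf_codons, noise_fraction,
                      seed = seed * 1000L + i, n_viruses = viruses_per_host)
  }))
  profs <- purrr::map(seq_len(nrow(seqs)), function(i) {
    codon_profile(seqs[i, ], entity_id = seqs$id[i])
  })
  a <- predict_host(spearman_matrix(profile_matrix(profs, "codon_fractions"),
                                    host_tbl))
  truth <- seqs$host_id[match(a$virus_id, seqs$id)]
  tibble::tibble(noise_fraction = noise_fraction,
                 accuracy = mean(a$best_host == truth),
                 n_viruses = nrow(seqs))
}

#' Fold-change recovery experiment on synthetic expression fixtures
#'
#' Replicates the planted-fold design (`make_expression_fixture()`) and
#' returns the estimated fold change of every planted viral feature in
#' every replicate, for comparison of the estimate's median against the
#' planted value.
#'
#' @param planted_fold True fold change to plant.
#' @param n_replicates Number of independent fixtures.
#' @param seed Integer seed.
#' @param ... Passed on to [make_expression_fixture()].
#' @return Tibble with `replicate`, `feature_id`, `fold_change`.
#' @export
simulate_fold_recovery <- function(planted_fold, n_replicates = 200,
                                   seed = 1, ...) {
  purrr::map(seq_len(n_replicates), function(r) {
    fx <- make_expression_fixture(planted_fold = planted_fold,
                                  seed = seed * 100000L + r, ...)
    mat <- expression_matrix(fx$quants, control_ids = fx$control_ids)
    fc <- group_fold_change(mat, fx$group_a, fx$group_b)
    fc <- fc[grepl("^virus_", fc$feature_id), c("feature_id", "fold_change")]
    fc$replicate <- r
    fc
  }) |> dplyr::bind_rows()
}
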