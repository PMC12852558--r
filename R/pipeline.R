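# End-to-end orchestration. Stages communicate only through files
# (TSV/FASTA/Newick) so each is independently replayable; every output TSV
# carries a comment header naming the producing stage and a hash of the
# configuration that produced it.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    depth = 30L,            # hits inspected for viral evidence
    rescue_depth = 10L,     # no-domain rescue window
    min_len = 500L,         # exclusive exogenous-contig length floor, nt
    identity = 0.90,        # redundancy-clustering identity fraction
    fungal_identity = 90,   # exclusive % identity for candidate hosts
    tpm_threshold = 1.0,    # presence floor, TPM
    pseudocount = 1,        # log10 heatmap pseudocount
    feature_mode = "concatenated",  # host-inference feature block
    orf_min_len = 100L, orf_max_len = 6000L, orf_mode = "region",
    genetic_code = 1L,
    inputs = NULL,          # list of file paths; NULL = simulate
    simulate = list(n_hosts = 5L, n_viruses_per_host = 2L,
                    concentration = 0.5, orf_codons = 300L,
                    noise_fraction = 0.1, planted_fold = 112,
                    n_libraries_per_group = 3L,
                    n_queries = 8L))
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are rejected; thresholds are checked against their
#' documented ranges. `config` may be a list or the path of a YAML file.
#'
#' @param config List or YAML path; omitted fields take their defaults.
#' @return The completed configuration list (invisible `config_hash`
#'   attribute attached).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("Config file not found: '%s'.",
                                            config))
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config)
  if (cfg$depth < 1) abort("depth must be >= 1.")
  if (cfg$rescue_depth < 1 || cfg$rescue_depth > cfg$depth) {
    abort("rescue_depth must be in [1, depth].")
  }
  if (cfg$identity <= 0 || cfg$identity > 1) {
    abort("identity must be in (0, 1].")
  }
  if (cfg$min_len < 0) abort("min_len must be >= 0.")
  if (cfg$tpm_threshold < 0) abort("tpm_threshold must be >= 0.")
  if (!cfg$feature_mode %in% c("concatenated", "codon_fractions", "rscu",
                               "dinuc_odds")) {
    abort("feature_mode must be one of concatenated, codon_fractions, rscu, dinuc_odds.")
  }
  # hash over the analytical settings only: where outputs land does not
  # change what was computed
  attr(cfg, "config_hash") <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  cfg
}

#' Run the full triage pipeline
#'
#' Executes the stages in dependency order — simulate (when no input files
#' are configured), curate, orfs, profile, hosts, abundance — writing one
#' artifact per stage under `out_dir` and returning a manifest. With the
#' default configuration the pipeline runs entirely on seeded synthetic
#' fixtures and is deterministic given (`config`, `seed`).
#'
#' @param config List or YAML path accepted by [pipeline_config()]; must
#'   provide `out_dir`.
#' @return Manifest tibble: `stage`, `artifact`, `path`, `n_rows`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  if (is.null(cfg$out_dir)) abort("config$out_dir is required.")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- attr(cfg, "config_hash")
  manifest <- list()
  note <- function(stage, artifact, path, n) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage, artifact = artifact, path = path, n_rows = n)
  }

  # ---- inputs: configured files or seeded simulation ----
  if (is.null(cfg$inputs)) {
    sim <- cfg$simulate
    grid <- tibble::tibble(
      planted_rank = rep(c(NA, 3L, 8L, 25L), length.out = sim$n_queries),
      has_domain = rep(c(TRUE, FALSE), length.out = sim$n_queries))
    ht <- make_hit_tables(grid, seed = cfg$seed)
    hits <- read_blast_tab(ht$blast_text)
    flags <- read_viral_flags(ht$viral_flags_text)
    domains <- read_domain_table(ht$domains_text)
    hostp <- make_host_profiles(sim$n_hosts, sim$concentration,
                                seed = cfg$seed,
                                genetic_code = cfg$genetic_code)
    seqs <- dplyr::bind_rows(purrr::imap(hostp, function(p, i) {
      sample_viral_orfs(p, sim$orf_codons, sim$noise_fraction,
                        seed = cfg$seed + i, n_viruses = sim$n_viruses_per_host)
    }))
    fx <- make_expression_fixture(
      planted_fold = sim$planted_fold,
      n_libraries_per_group = sim$n_libraries_per_group, seed = cfg$seed)
    quants <- fx$quants; metadata <- fx$metadata
    control_ids <- fx$control_ids
    group_a <- fx$group_a; group_b <- fx$group_b
  } else {
    inp <- cfg$inputs
    hits <- if (!is.null(inp$blastx)) read_blast_tab(inp$blastx)
    flags <- if (!is.null(inp$viral_flags)) read_viral_flags(inp$viral_flags)
    domains <- if (!is.null(inp$domains)) read_domain_table(inp$domains)
    seqs <- if (!is.null(inp$contigs)) read_fasta(inp$contigs)
    hostp <- NULL
    quants <- if (!is.null(inp$quants)) {
      paths <- inp$quants
      setNames(lapply(paths, read_quant_table),
               names(paths) %||% tools::file_path_sans_ext(basename(unlist(paths))))
    }
    metadata <- if (!is.null(inp$metadata)) read_library_metadata(inp$metadata)
    control_ids <- inp$control_ids %||% character()
    group_a <- inp$group_a; group_b <- inp$group_b
  }

  # ---- curate ----
  if (!is.null(hits) && !is.null(flags)) {
    decisions <- curate_candidates(hits, flags, domains,
                                   depth = cfg$depth,
                                   rescue_depth = cfg$rescue_depth)
    p <- file.path(cfg$out_dir, "curation_decisions.tsv")
    write_stage_tsv(decisions, p, "curate", hash)
    note("curate", "decisions", p, nrow(decisions))
    hosts_tbl <- select_candidate_hosts(hits, cfg$fungal_identity)
    p <- file.path(cfg$out_dir, "candidate_hosts.tsv")
    write_stage_tsv(hosts_tbl, p, "curate", hash)
    note("curate", "candidate_hosts", p, nrow(hosts_tbl))
  }

  # ---- orfs + composition profiles + host inference ----
  if (!is.null(seqs) && nrow(seqs)) {
    retained <- length_filter(seqs, cfg$min_len)
    orfs <- find_orfs(retained, mode = cfg$orf_mode,
                      min_len = cfg$orf_min_len, max_len = cfg$orf_max_len,
                      genetic_code = cfg$genetic_code)
    p <- file.path(cfg$out_dir, "orfs.tsv")
    write_stage_tsv(dplyr::select(orfs, -"nt_sequence"), p, "orfs", hash)
    note("orfs", "orfs", p, nrow(orfs))

    profiles <- purrr::map(unique(orfs$parent_id), function(id) {
      merge_profiles(
        codon_profile(orfs[orfs$parent_id == id, ], entity_id = id,
                      genetic_code = cfg$genetic_code),
        dinuc_profile(retained[retained$id == id, ], entity_id = id))
    })
    if (length(profiles)) {
      viral_tbl <- profile_matrix(profiles, cfg$feature_mode)
      p <- file.path(cfg$out_dir, "viral_profiles.tsv")
      write_stage_tsv(viral_tbl, p, "profile", hash)
      note("profile", "viral_profiles", p, nrow(viral_tbl))

      if (!is.null(hostp)) {
        host_mode <- if (cfg$feature_mode %in% c("concatenated", "dinuc_odds"))
          "codon_fractions" else cfg$feature_mode
        host_tbl <- profile_matrix(hostp, host_mode)
        viral_cmp <- profile_matrix(profiles, host_mode)
        corr <- spearman_matrix(viral_cmp, host_tbl)
        assign_tbl <- predict_host(corr)
        p <- file.path(cfg$out_dir, "host_assignments.tsv")
        write_stage_tsv(assign_tbl, p, "hosts", hash)
        note("hosts", "host_assignments", p, nrow(assign_tbl))
        pooled <- dplyr::bind_rows(viral_cmp, host_tbl)
        clus <- hier_cluster(pooled)
        p <- file.path(cfg$out_dir, "profile_clustering.nwk")
        write_newick(clus, p)
        note("hosts", "profile_clustering", p, length(clus$leaf_order))
      }
    }
  }

  # ---- abundance ----
  if (!is.null(quants)) {
    mat <- expression_matrix(quants, metadata, control_ids)
    tpm_tbl <- tibble::as_tibble(mat$values, rownames = "feature_id")
    p <- file.path(cfg$out_dir, "tpm_matrix.tsv")
    write_stage_tsv(tpm_tbl, p, "abundance", hash)
    note("abundance", "tpm_matrix", p, nrow(tpm_tbl))

    prev <- feature_prevalence(mat, cfg$tpm_threshold)
    p <- file.path(cfg$out_dir, "prevalence.tsv")
    write_stage_tsv(prev, p, "abundance", hash)
    note("abundance", "prevalence", p, nrow(prev))

    if (!is.null(group_a) && !is.null(group_b)) {
      contrast <- group_fold_change(mat, group_a, group_b)
      p <- file.path(cfg$out_dir, "group_contrast.tsv")
      write_stage_tsv(contrast, p, "abundance", hash)
      note("abundance", "group_contrast", p, nrow(contrast))
    }

    hm <- heatmap_matrix(mat, cfg$pseudocount)
    hm_tbl <- tibble::as_tibble(hm$values, rownames = "feature_id")
    p <- file.path(cfg$out_dir, "heatmap_matrix.tsv")
    write_stage_tsv(hm_tbl, p, "abundance", hash)
    note("abundance", "heatmap_matrix", p, nrow(hm_tbl))
  }

  out <- dplyr::bind_rows(manifest)
  p <- file.path(cfg$out_dir, "manifest.tsv")
  readr::write_tsv(out, p)
  out
}

# TSV with a one-line comment header recording provenance.
write_stage_tsv <- function(df, path, stage, config_hash) {
  writeLines(sprintf("# produced_by: virotriage/%s; config_hash: %s",
                     stage, config_hash), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a pipeline stage TSV, skipping the provenance header
#'
#' @param path Path written by [run_pipeline()].
#' @return Tibble.
#' @export
read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
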