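# One-call orchestration of the full synthetic RRBS study: genome ->
# per-arm profiles -> digestion/size selection -> bisulfite reads ->
# placement and calling -> sample comparison -> DMR discovery ->
# annotation/enrichment -> amplicon and cytometry tables, with a manifest
# of parameters and per-file checksums.

#' Default pipeline configuration
#'
#' Returns the full parameter set of a pipeline run as a nested list:
#' genome size and annotation counts, per-arm methylation profile settings
#' (including the TSDR-like locus that is demethylated only in the
#' TGF-beta + pVC arm and ground-truth DMR cassettes hypomethylated in both
#' pVC arms), read-simulation settings, DMR criteria (5 sites, 2-fold,
#' p < 0.05, hypomethylation threshold 0.2, 500 bp merge gap), annotation
#' and assay settings.  The four culture arms are medium, pVC, TGFb and
#' TGFb_pVC.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    genome = list(n_chrom = 1, chrom_length = 60000, gc_fraction = 0.5,
                  ccgg_boost = 3, n_genes = 20, n_truth_dmrs = 4),
    profile = list(
      base_cg_level = 0.75, base_noncg_level = 0.01, jitter_sd = 0.05,
      tsdr_levels = list(medium = 0.9, pVC = 0.9,
                         TGFb = 0.9, TGFb_pVC = 0.1),
      truth_dmr_levels = list(medium = 0.9, pVC = 0.1,
                              TGFb = 0.9, TGFb_pVC = 0.1)),
    reads = list(read_length = 50, mean_depth = 15,
                 conversion_rate = 0.995, error_rate = 0.001),
    size_select = list(min_bp = 40, max_bp = 220),
    calling = list(min_coverage = 1, max_mismatch = 2),
    dmr = list(context = "CpG", min_sites = 5, min_cov = 5, fold_min = 2,
               p_max = 0.05, hypo_threshold = 0.2, max_gap = 500,
               hypo_rule = "not_both"),
    annotation = list(promoter_up = 2000, promoter_down = 500,
                      n_random_sets = 5, random_set_size = 8),
    amplicon = list(n_reads = 1000, n_cpgs = 7,
                    levels = list(FOXP3pos_pVC = 0.1, FOXP3pos_noPVC = 0.85,
                                  FOXP3neg_pVC = 0.85, FOXP3neg_noPVC = 0.9)),
    cytometry = list(n_standard_added = 10000,
                     counts = list(gd = 20000, cd4 = 20000),
                     cfse_divided_fraction = 0.74))
}

#' Write a pipeline configuration to YAML
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path written by [write_run_config()].
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

.stage_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  writeLines(line, con)
}

#' Run the full synthetic RRBS pipeline
#'
#' Executes all stages in order and writes every output under `out_dir`:
#' genome FASTA, feature BED, gene GTF, per-arm FASTQ, CX methylome TSVs and
#' bedGraphs, the shared-site matrix with Pearson/PCA tables, context
#' summaries, DMR BED/TSV for medium-vs-pVC and TGFb-vs-TGFb+pVC, gene
#' assignments and enrichment, amplicon and cytometry CSVs, a ground-truth
#' manifest (`truth.json`) and a run manifest (`manifest.json`) with the
#' config hash and per-file MD5 checksums.  Identical config and seed give
#' identical checksums.
#'
#' @param config Configuration list from [default_run_config()] (possibly
#'   modified) or [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logc <- file(log_path, open = "wt")
  on.exit(close(logc), add = TRUE)
  seed <- config$seed
  outputs <- character()
  emit <- function(path) { outputs <<- c(outputs, path); path }
  run_stage <- function(stage, expr) {
    .stage_log(logc, stage, "start")
    res <- tryCatch(expr, error = function(e) {
      .stage_log(logc, stage, paste("FAILED:", conditionMessage(e)))
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
    .stage_log(logc, stage, "done")
    res
  }

  # --- synthesis ------------------------------------------------------
  genome <- run_stage("genome", {
    g <- config$genome
    gen <- generate_genome(g$n_chrom, g$chrom_length, g$gc_fraction,
                           g$ccgg_boost, g$n_genes, g$n_truth_dmrs,
                           seed = seed)
    write_genome_fasta(gen, emit(file.path(out_dir, "genome.fa")))
    export_features_bed(gen, emit(file.path(out_dir, "features.bed")))
    export_genes_gtf(gen, emit(file.path(out_dir, "genes.gtf")))
    gen
  })

  pr <- config$profile
  dmr_spec <- c(
    list(tsdr = unlist(pr$tsdr_levels)),
    stats::setNames(
      rep(list(unlist(pr$truth_dmr_levels)),
          sum(genome$features$kind == "truth_dmr")),
      genome$features$id[genome$features$kind == "truth_dmr"]))
  profiles <- run_stage("profiles", {
    stats::setNames(lapply(seq_along(ARM_LABELS), function(i) {
      assign_profile(genome, ARM_LABELS[i], pr$base_cg_level,
                     pr$base_noncg_level, dmr_spec, pr$jitter_sd,
                     seed = seed + 10L + i)
    }), ARM_LABELS)
  })

  fragments <- run_stage("digest", {
    size_select(digest_mspi(genome), config$size_select$min_bp,
                config$size_select$max_bp)
  })

  tables <- run_stage("reads_and_calling", {
    rd <- config$reads
    stats::setNames(lapply(seq_along(ARM_LABELS), function(i) {
      arm <- ARM_LABELS[i]
      reads <- simulate_reads(genome, fragments, profiles[[arm]],
                              rd$read_length, rd$mean_depth,
                              rd$conversion_rate, rd$error_rate,
                              seed = seed + 20L + i)
      write_fastq(reads, emit(file.path(out_dir,
                                        sprintf("reads_%s.fastq", arm))))
      pl <- place_reads(reads, genome, config$calling$max_mismatch)
      tab <- call_cytosines(pl, genome, config$calling$min_coverage,
                            sample = arm)
      export_cx(tab, emit(file.path(out_dir,
                                    sprintf("methylome_%s.tsv", arm))))
      export_bedgraph(tab, emit(file.path(out_dir,
                                          sprintf("levels_%s.bedGraph", arm))))
      tab
    }), ARM_LABELS)
  })

  # --- sample comparison ---------------------------------------------
  run_stage("sample_comparison", {
    m <- build_matrix(tables, context = "CpG",
                      min_cov = config$dmr$min_cov)
    readr::write_tsv(as_tibble(cbind(site = rownames(m), as.data.frame(m))),
                     emit(file.path(out_dir, "site_matrix.tsv")))
    pm <- pearson_matrix(m)
    utils::write.csv(pm, emit(file.path(out_dir, "pearson.csv")))
    pca <- pca_samples(m)
    utils::write.csv(as.data.frame(pca$coordinates),
                     emit(file.path(out_dir, "pca.csv")))
    utils::write.csv(
      data.frame(component = paste0("PC", seq_along(pca$var_explained)),
                 var_explained = pca$var_explained),
      emit(file.path(out_dir, "pca_varexp.csv")), row.names = FALSE)
    ctx <- bind_rows(lapply(ARM_LABELS, function(arm) {
      s <- context_feature_summary(tables[[arm]], genome)
      s$sample <- arm
      s
    }))
    readr::write_tsv(ctx, emit(file.path(out_dir, "context_summary.tsv")))
    NULL
  })

  # --- DMR discovery + annotation ------------------------------------
  comparisons <- list(medium_vs_pVC = c("medium", "pVC"),
                      TGFb_vs_TGFb_pVC = c("TGFb", "TGFb_pVC"))
  dmr_sets <- run_stage("dmr", {
    lapply(comparisons, function(cmp) {
      d <- config$dmr
      dm <- call_dmrs(tables[[cmp[1]]], tables[[cmp[2]]], d$context,
                      d$min_sites, d$min_cov, d$fold_min, d$p_max,
                      d$hypo_threshold, d$max_gap, d$hypo_rule)
      dm
    })
  })
  run_stage("dmr_export", {
    for (nm in names(dmr_sets)) {
      export_dmrs_bed(dmr_sets[[nm]],
                      emit(file.path(out_dir, sprintf("dmrs_%s.bed", nm))))
      readr::write_tsv(dmr_sets[[nm]],
                       emit(file.path(out_dir, sprintf("dmrs_%s.tsv", nm))))
    }
    NULL
  })

  run_stage("annotation", {
    an <- config$annotation
    genes <- genome_features(genome, "gene")$id
    assignments <- bind_rows(lapply(names(dmr_sets), function(nm) {
      a <- assign_regions(dmr_sets[[nm]], genome, an$promoter_up,
                          an$promoter_down)
      if (nrow(a)) a$comparison <- nm
      a
    }))
    readr::write_tsv(assignments, emit(file.path(out_dir,
                                                 "gene_assignments.tsv")))
    # synthetic gene sets: random terms plus one built from DMR genes
    sets <- withr::with_seed(seed + 40L, {
      s <- lapply(seq_len(an$n_random_sets), function(i) {
        sample(genes, min(an$random_set_size, length(genes)))
      })
      names(s) <- sprintf("random_set_%d", seq_along(s))
      if (nrow(assignments)) {
        s$dmr_associated <- unique(assignments$gene_id)
      }
      s
    })
    write_gmt(sets, emit(file.path(out_dir, "gene_sets.gmt")))
    if (nrow(assignments)) {
      er <- enrich(unique(assignments$gene_id), sets, genes)
      readr::write_tsv(er, emit(file.path(out_dir, "enrichment.tsv")))
    }
    NULL
  })

  # --- targeted amplicon + cytometry ---------------------------------
  run_stage("assays", {
    am <- config$amplicon
    amp <- lapply(names(am$levels), function(g) {
      simulate_amplicon(rep(am$levels[[g]], am$n_cpgs), am$n_reads,
                        sample = g, seed = seed + 50L + match(g,
                                                             names(am$levels)))
    })
    names(amp) <- names(am$levels)
    amp_tab <- bind_rows(lapply(amp, function(a) {
      cbind(sample = attr(a, "sample"), a)
    }))
    readr::write_csv(amp_tab, emit(file.path(out_dir, "amplicon.csv")))
    summaries <- lapply(amp, summarize_amplicon)
    colors <- lapply(summaries, function(s) heatmap_color(s$percent))
    col_tab <- bind_rows(lapply(names(colors), function(g) {
      as_tibble(cbind(data.frame(sample = g,
                                 cpg = seq_len(nrow(colors[[g]]))),
                      as.data.frame(colors[[g]])))
    }))
    readr::write_csv(col_tab, emit(file.path(out_dir, "amplicon_colors.csv")))

    cy <- config$cytometry
    gens <- c(1 - cy$cfse_divided_fraction,
              rep(cy$cfse_divided_fraction / 4, 4))
    ev <- simulate_suppression_assay(unlist(cy$counts), cy$n_standard_added,
                                     gens, seed = seed + 60L)
    readr::write_csv(ev, emit(file.path(out_dir, "cytometry.csv")))
    NULL
  })

  # --- manifests ------------------------------------------------------
  truth <- list(
    seed = seed,
    truth_regions = genome$features[
      genome$features$kind %in% c("truth_dmr", "tsdr"), ],
    arm_levels = dmr_spec)
  jsonlite::write_json(truth, emit(file.path(out_dir, "truth.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_path <- emit(file.path(out_dir, "config.yaml"))
  write_run_config(config, cfg_path)
  sums <- tools::md5sum(sort(outputs))
  names(sums) <- basename(names(sums))
  manifest <- list(
    package_version = as.character(utils::packageVersion("rrbsdmr")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    checksums = as.list(sums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
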