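#' Default pipeline configuration
#'
#' Nested key/value configuration for [run_pipeline()].  `sim` holds
#' [sim_config()] arguments, `filter` [filter_params()] arguments, `cn`
#' [cn_thresholds()] arguments, `fish` the `min_cells` threshold, `de` the
#' significance cutoffs, and `target_gene` the gene whose multi-assay
#' status is integrated.  A YAML file with the same structure can be passed
#' to [run_pipeline()] directly.
#'
#' @param seed master seed.
#' @return configuration list.
#' @export
demo_config <- function(seed = 1) {
  list(seed = seed,
       sim = list(),
       filter = list(),
       cn = list(),
       fish = list(min_cells = 200),
       de = list(padj_cutoff = 0.05, min_abs_log2fc = 0),
       target_gene = "CDKN2A")
}

load_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_input("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  utils::modifyList(demo_config(), config)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> filter-variants -> call-loss -> fish -> integrate ->
#' slc-profile/ihc, writing every intermediate table, a cohort summary, a
#' human-readable report and a run manifest (package version, seed, all
#' parameter values, file checksums) under `outdir`.  Identical
#' configuration and seed give byte-identical outputs; the manifest contains
#' no timestamps and only paths relative to `outdir`.  Any stage failure
#' aborts with an error naming the stage.
#'
#' @param config configuration list (see [demo_config()]) or path to a YAML
#'   file with the same structure.
#' @param outdir output directory (created if needed).
#' @param seed optional seed overriding `config$seed`.
#' @return (invisibly) a list with the cohort summary, SLC summary, marker
#'   and IHC fractions, somatic-call summary and the manifest path.
#' @export
run_pipeline <- function(config = demo_config(), outdir, seed = NULL) {
  cfg <- load_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(file.path(outdir, "cohort"), recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  log_msg <- function(fmt, ...) message(sprintf(paste0("[%s] ", fmt),
                                               "cdclossmap", ...))

  # -- simulate ---------------------------------------------------------
  sim_cfg <- stage("simulate", do.call(sim_config, c(cfg$sim, list(seed = cfg$seed))))
  cohort <- stage("simulate", simulate_cohort(sim_cfg))
  stage("simulate", {
    write_variant_table(cohort$variants, p("cohort", "variants.tsv"))
    write_table_tsv(cohort$variant_truth, p("cohort", "variant_truth.tsv"))
    write_seg(cohort$segments, p("cohort", "segments.seg"))
    write_table_tsv(cohort$cn_truth, p("cohort", "cn_truth.tsv"))
    write_gene_bed(cohort$genes, p("cohort", "genes.bed"))
    write_table_tsv(cohort$fish, p("cohort", "fish.tsv"))
    write_table_tsv(cohort$fish_truth, p("cohort", "fish_truth.tsv"))
    write_table_tsv(cohort$de, p("cohort", "de.tsv"))
    writeLines(cohort$family_genes, p("cohort", "family_genes.txt"))
    write_table_tsv(cohort$de_truth, p("cohort", "de_truth.tsv"))
    write_table_tsv(cohort$ihc, p("cohort", "ihc.tsv"))
    write_table_tsv(cohort$marker_lfc, p("cohort", "marker_lfc.tsv"))
  })
  log_msg("simulate: %d variant candidates, %d segments, %d FISH cases",
          nrow(cohort$variants), nrow(cohort$segments), nrow(cohort$fish_truth))

  # -- filter-variants --------------------------------------------------
  params <- stage("filter-variants", do.call(filter_params, cfg$filter))
  verdicts <- stage("filter-variants", {
    cand <- read_variant_table(p("cohort", "variants.tsv"))
    apply_somatic_filters(cand, params)
  })
  call_summary <- summarize_calls(verdicts)
  stage("filter-variants", {
    write_table_tsv(verdicts, p("verdicts.tsv"))
    write_table_tsv(call_summary, p("call_summary.tsv"))
  })
  log_msg("filter-variants: %d/%d candidates called somatic",
          sum(verdicts$is_somatic), nrow(verdicts))

  # -- call-loss --------------------------------------------------------
  thr <- stage("call-loss", do.call(cn_thresholds, cfg$cn))
  gene_status <- stage("call-loss", {
    segs <- read_seg(p("cohort", "segments.seg"))
    genes <- read_gene_bed(p("cohort", "genes.bed"))
    gs <- genome_loss_profile(segs, genes, thr)
    write_table_tsv(gs, p("gene_status.tsv"))
    gs
  })

  # -- fish -------------------------------------------------------------
  fish_calls <- stage("fish", {
    fish <- read_table_tsv(p("cohort", "fish.tsv"))
    fc <- evaluate_fish_table(fish, min_cells = cfg$fish$min_cells)
    write_table_tsv(fc, p("fish_calls.tsv"))
    fc
  })

  # -- integrate --------------------------------------------------------
  gene <- cfg$target_gene
  integrated <- stage("integrate", {
    samples <- sort(unique(c(fish_calls$sample_id, gene_status$sample_id)))
    gs <- gene_status[gene_status$gene == gene, , drop = FALSE]
    ai <- match(samples, gs$sample_id)
    fi <- match(samples, fish_calls$sample_id)
    trunc <- vapply(samples, function(s) {
      any(verdicts$is_somatic & !is.na(verdicts$gene) & verdicts$gene == gene &
            verdicts$sample_id == s &
            verdicts$consequence %in% c("nonsense", "frameshift"))
    }, logical(1))
    ev <- data.frame(
      sample_id = samples, gene = gene,
      array_status = ifelse(is.na(ai), "not_assayed", gs$status[ai]),
      fish_status = ifelse(is.na(fi), "not_assayed", fish_calls$call[fi]),
      truncating_snv = unname(trunc),
      loh_at_locus = ifelse(is.na(ai), FALSE, gs$loh[ai]),
      stringsAsFactors = FALSE)
    iv <- integrate_gene_status(ev)
    write_table_tsv(iv, p("integrated.tsv"))
    iv
  })
  summary_df <- stage("integrate", {
    cs <- cohort_frequencies(integrated)
    write_table_tsv(cs, p("cohort_summary.tsv"))
    cs
  })
  log_msg("integrate: %s loss in %.1f%% of %d samples", gene,
          summary_df$pct_any_loss, summary_df$n_samples)

  # -- slc-profile / ihc ------------------------------------------------
  profile <- stage("slc-profile", {
    de <- read_table_tsv(p("cohort", "de.tsv"))
    fam <- readLines(p("cohort", "family_genes.txt"))
    fs <- family_alteration_summary(de, fam,
                                    padj_cutoff = cfg$de$padj_cutoff,
                                    min_abs_log2fc = cfg$de$min_abs_log2fc)
    write_table_tsv(data.frame(family = fs$family_name,
                               n_family = fs$n_family, n_up = fs$n_up,
                               n_down = fs$n_down, n_altered = fs$n_altered,
                               pct_altered = fs$pct_altered),
                    p("slc_summary.tsv"))
    marker <- per_sample_up_fraction(read_table_tsv(p("cohort", "marker_lfc.tsv")))
    ihc <- read_table_tsv(p("cohort", "ihc.tsv"))
    ihc$bin <- classify_ihc(ihc$pct_positive)
    ihc_frac <- ihc_cohort_fraction(ihc)
    write_table_tsv(data.frame(
      n_marker_up = marker$n_up, n_marker_total = marker$n_total,
      pct_marker_up = marker$pct, n_ihc_high = ihc_frac$n_high,
      n_ihc_total = ihc_frac$n_total, pct_ihc_high = ihc_frac$pct),
      p("expression_summary.tsv"))
    list(family = fs, marker = marker, ihc = ihc_frac)
  })

  # -- report + manifest ------------------------------------------------
  stage("report", {
    lines <- c(
      "cdclossmap pipeline report",
      sprintf("seed: %d", cfg$seed),
      sprintf("somatic calls: %d (of %d candidates)",
              attr(call_summary, "total"), nrow(verdicts)),
      sprintf("%s: %d homozygous (%.1f%%), %d heterozygous (%.1f%%), any loss %.1f%% of %d",
              gene, summary_df$n_homo, summary_df$pct_homo, summary_df$n_het,
              summary_df$pct_het, summary_df$pct_any_loss, summary_df$n_samples),
      sprintf("%s family: %d/%d altered (%.1f%%), %d up / %d down",
              profile$family$family_name, profile$family$n_altered,
              profile$family$n_family, profile$family$pct_altered,
              profile$family$n_up, profile$family$n_down),
      sprintf("marker up-regulated in %d/%d samples (%.1f%%)",
              profile$marker$n_up, profile$marker$n_total, profile$marker$pct),
      sprintf("IHC high in %d/%d cases (%.1f%%)",
              profile$ihc$n_high, profile$ihc$n_total, profile$ihc$pct))
    writeLines(lines, p("report.txt"))
  })
  manifest_path <- stage("manifest", {
    files <- sort(c(list.files(p("cohort"), full.names = TRUE),
                    setdiff(list.files(outdir, full.names = TRUE),
                            c(p("cohort"), p("manifest.json")))))
    files <- files[!dir.exists(files)]
    sums <- tools::md5sum(files)
    names(sums) <- sub(paste0("^", outdir, "/?"), "", names(sums))
    manifest <- list(
      package = "cdclossmap",
      version = as.character(utils::packageVersion("cdclossmap")),
      seed = cfg$seed,
      parameters = list(sim = unclass(sim_cfg)[!vapply(sim_cfg, is.data.frame, TRUE)],
                        filter = unclass(params), cn = unclass(thr),
                        fish = cfg$fish, de = cfg$de,
                        target_gene = cfg$target_gene),
      md5 = as.list(sums))
    jsonlite::write_json(manifest, p("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    p("manifest.json")
  })
  log_msg("done: outputs under %s", outdir)
  invisible(list(cohort_summary = summary_df, slc = profile$family,
                 marker = profile$marker, ihc = profile$ihc,
                 call_summary = call_summary, manifest = manifest_path))
}
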