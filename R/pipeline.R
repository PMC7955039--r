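## End-to-end orchestration: synthetic (or file-based) inputs through
## design, counting, activity, allelic, enrichment, allelic binding,
## motif classification, and annotation, with a summary report.

#' Default pipeline configuration
#'
#' All decision thresholds default to the values used throughout the
#' package: adjusted-p 0.05, enhancer fold 1.5, allelic fold 1.25,
#' negative-set fold 1.10, 2000 resampling iterations, imbalance-score
#' threshold 0.4, relative-PWM-score cutoffs 70/40, 25-bp motif padding,
#' 30 minimum barcodes, 3 minimum altering events, 5 minimum predicted
#' sites.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return Nested configuration list; see the fields themselves.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("mpra_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    thresholds = list(
      padj = 0.05, enhancer_fold = 1.5, allelic_fold = 1.25,
      negative_fold = 1.10, reli_iterations = 2000, ars_threshold = 0.4,
      relative_strong = 70, relative_weak = 40, motif_pad = 25,
      min_barcodes = 30, min_total_reads = 6, min_events = 3, min_sites = 5
    ),
    sim = list(
      n_variants = 24, n_loci = 6, n_replicates = 3,
      barcode_median = 729, barcode_sigma = 0.4, dispersion = 0.05,
      mean_depth = 30, n_enhancers = 8, enhancer_fold = 2.5,
      n_allelic = 4, allelic_fold = 2, n_datasets = 4,
      p_target = 0.5, p_background = 0.1, n_pwms = 4, pwm_width = 8
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override [default_config()]; everything
#' else keeps its default.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_lists(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  merge_lists(cfg, user)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a seeded synthetic study (genome, variants, oligo design,
#' barcode counts, ChIP-seq peaks and allelic reads, motifs, annotation
#' tables) and runs every analysis stage in order, writing per-stage TSV
#' outputs and a JSON report into `config$out_dir`.
#'
#' @param config Configuration from [default_config()] or
#'   [read_config()].
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, the report list: per-stage counts (`n_variants`,
#'   `n_oligos_retained`, `n_enAlleles`, `n_enVars`, `n_allelic_enVars`,
#'   `n_loci_with_allelic`), thresholds, seed, and output paths.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  th <- config$thresholds
  sm <- config$sim
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  say("stage 1/8: synthetic genome + variants")
  sim <- gen_reference_and_variants(sm$n_variants, sm$n_loci,
                                    seed = derive_seed(config$seed, 1))
  write_tsv(sim$variants, out("variants.tsv"))

  say("stage 2/8: oligo design")
  manifest <- design_oligos(sim$variants, sim$genome)
  write_tsv(manifest[, c("variant_id", "allele", "orientation", "oligo_id")],
            out("design_manifest.tsv"))
  write_design_fasta(manifest, out("oligos.fasta"))

  say("stage 3/8: barcode counts -> count matrix")
  set.seed(derive_seed(config$seed, 2))
  enh_ids <- sample(sim$variants$id, min(sm$n_enhancers, nrow(sim$variants)))
  allelic_ids <- sample(enh_ids, min(sm$n_allelic, length(enh_ids)))
  effects <- do.call(rbind, lapply(seq_len(nrow(sim$variants)), function(i) {
    v <- sim$variants[i, ]
    alleles <- c(v$ref, strsplit(v$alts, ",")[[1]])
    fold <- rep(1, length(alleles))
    if (v$id %in% enh_ids) {
      fold[] <- sm$enhancer_fold
      if (v$id %in% allelic_ids) fold[1] <- sm$enhancer_fold * sm$allelic_fold
    }
    data.frame(variant_id = v$id, allele = alleles, fold = fold,
               stringsAsFactors = FALSE)
  }))
  mpra <- gen_mpra_counts(manifest, effects = effects,
                          n_replicates = sm$n_replicates,
                          barcode_median = sm$barcode_median,
                          barcode_sigma = sm$barcode_sigma,
                          dispersion = sm$dispersion,
                          mean_depth = sm$mean_depth,
                          seed = derive_seed(config$seed, 3))
  map <- build_barcode_map(mpra$barcode_map)
  counted <- count_barcodes(mpra$barcode_counts, map, mpra$sample_sheet,
                            min_barcodes = th$min_barcodes)
  write_count_matrix(counted, out("count_matrix.tsv"))

  say("stage 4/8: enhancer activity")
  groups <- setNames(mpra$sample_sheet$role, mpra$sample_sheet$sample)
  activity <- test_activity(counted$counts, groups)
  calls <- call_enhancers(activity,
                          fc_threshold = th$enhancer_fold,
                          padj_threshold = th$padj,
                          negative_fc = th$negative_fold)
  write_tsv(calls$results, out("activity_results.tsv"))

  say("stage 5/8: allelic activity")
  allelic <- call_allelic(mpra$barcode_counts, mpra$sample_sheet,
                          en_vars = calls$enVars, variants = sim$variants,
                          fc_threshold = th$allelic_fold,
                          padj_threshold = th$padj)
  if (!is.null(allelic$pairs)) write_tsv(allelic$pairs, out("allelic_results.tsv"))

  say("stage 6/8: peak-set enrichment")
  chip <- gen_chipseq_data(sim$variants, n_datasets = sm$n_datasets,
                           target_ids = enh_ids, p_target = sm$p_target,
                           p_background = sm$p_background,
                           allelic_ratio = setNames(
                             rep(0.8, length(allelic_ids)), allelic_ids),
                           seed = derive_seed(config$seed, 4))
  for (nm in names(chip$peak_sets)) {
    write_bed(chip$peak_sets[[nm]], out(paste0("peaks_", nm, ".bed")))
  }
  enrich <- NULL
  if (length(calls$enVars) > 0 && length(calls$non_enVars) >= length(calls$enVars)) {
    vgr <- variants_to_granges(sim$variants)
    enrich <- reli_batch(vgr[calls$enVars], vgr[calls$non_enVars],
                         chip$peak_sets, n_iter = th$reli_iterations,
                         seed = derive_seed(config$seed, 5))
    write_tsv(enrich, out("reli_enrichment.tsv"))
  } else {
    say("  skipped: negative set smaller than input set")
  }

  say("stage 7/8: allelic binding + motif classification")
  binding_calls <- score_allelic_reads(chip$allelic_reads,
                                       ars_threshold = th$ars_threshold,
                                       min_total = th$min_total_reads)
  retained <- apply_consistency_filters(binding_calls)
  profile <- summarize_allelic_profile(retained, binding_calls)
  write_tsv(profile, out("allelic_binding.tsv"))
  pwms <- gen_pwms(sm$n_pwms, width = sm$pwm_width,
                   seed = derive_seed(config$seed, 6))
  write_meme(pwms, out("motifs.meme"))
  tf_classes <- list()
  for (vid in unique(retained$variant_id)) {
    v <- sim$variants[sim$variants$id == vid, ]
    seqs <- padded_allele_seqs(v, sim$genome, pad = th$motif_pad)
    events <- detect_altering_events(seqs, pwms, variant_id = vid,
                                     strong_threshold = th$relative_strong,
                                     weak_threshold = th$relative_weak)
    proteins <- retained$protein[retained$variant_id == vid]
    tf_classes[[vid]] <- classify_tfs(proteins, events, pwms)
    tf_classes[[vid]]$variant_id <- vid
  }
  tf_classes <- if (length(tf_classes)) do.call(rbind, tf_classes) else
    data.frame(tf_name = character(), class = character(),
               no_motif = logical(), variant_id = character())
  write_tsv(tf_classes, out("tf_classes.tsv"))

  say("stage 8/8: gene annotation")
  ann_in <- gen_annotation_tables(sim$variants, tiers = rep(1:4, length.out =
                                                              nrow(sim$variants)),
                                  seed = derive_seed(config$seed, 7))
  annotation <- assign_targets(sim$variants, ann_in$loop_table,
                               ann_in$eqtl_table, ann_in$genes)
  write_tsv(annotation, out("annotation.tsv"))

  locus_of <- setNames(sim$variants$locus_id, sim$variants$id)
  per_locus <- data.frame(
    locus_id = sort(unique(sim$variants$locus_id)),
    stringsAsFactors = FALSE)
  per_locus$n_variants <- vapply(per_locus$locus_id, function(l) {
    sum(sim$variants$locus_id == l)
  }, numeric(1))
  per_locus$n_allelic <- vapply(per_locus$locus_id, function(l) {
    sum(locus_of[allelic$allelic_enVars] == l)
  }, numeric(1))
  write_tsv(per_locus, out("per_locus.tsv"))

  report <- list(
    seed = config$seed,
    thresholds = th,
    n_variants = nrow(sim$variants),
    n_oligos_retained = nrow(counted$counts),
    n_enAlleles = length(calls$enAlleles),
    n_enVars = length(calls$enVars),
    n_non_enVars = length(calls$non_enVars),
    n_allelic_enVars = length(allelic$allelic_enVars),
    n_loci_with_allelic = sum(per_locus$n_allelic > 0),
    n_allelic_binding_events = nrow(retained),
    truth = list(planted_enhancers = sort(enh_ids),
                 planted_allelic = sort(allelic_ids)),
    outputs = list.files(config$out_dir)
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(report)
}
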