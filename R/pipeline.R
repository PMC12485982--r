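## End-to-end pipeline: simulate (or load) -> classify elements -> QC ->
## quantify -> specificity -> shape -> pausing -> origin, with a JSON
## manifest (outputs, checksums, wall times) and a resolved-config dump so
## that runs are reproducible and auditable.

#' Pipeline configuration
#'
#' Collects every stage threshold in one place. Defaults are the
#' conventional values used throughout the package: divergent pairing gap
#' 300 bp, proximity cutoff 500 bp, QC exclusion at gene-body ratio
#' 0.025, shape-index cut -1.5, non-specific score cuts 0.1 (distal) /
#' 0.02 (proximal), tissue-specific top fraction 5%, PCA variance target
#' 90%.
#'
#' @param simulate list of [truth_config()] arguments for the synthetic
#'   dataset (ignored when `input_dir` is given)
#' @param input_dir optional directory holding a dataset written by
#'   [write_dataset()]; replaces simulation
#' @param stages character vector of stages to run after data
#'   acquisition; subset of elements, qc, quantify, specificity, shape,
#'   pausing, origin
#' @param pairing_gap,proximity_cutoff,qc_threshold,si_min_reads
#'   stage thresholds (see module docs)
#' @param top_frac,distal_cut,proximal_cut specificity selection
#'   parameters
#' @param peak_min_count,peak_window naive peak-caller parameters
#' @param pca_variance PCA variance target for similarity analyses
#' @param seed integer seed used for every stochastic stage
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(simulate = list(), input_dir = NULL,
                            stages = c("elements", "qc", "quantify",
                                       "specificity", "shape", "pausing",
                                       "origin"),
                            pairing_gap = 300L, proximity_cutoff = 500L,
                            qc_threshold = 0.025, si_min_reads = 50L,
                            top_frac = 0.05, distal_cut = 0.1,
                            proximal_cut = 0.02,
                            peak_min_count = 10L, peak_window = 100L,
                            pca_variance = 0.90, seed = 1L) {
  cfg <- list(simulate = simulate, input_dir = input_dir,
              stages = stages, pairing_gap = pairing_gap,
              proximity_cutoff = proximity_cutoff,
              qc_threshold = qc_threshold, si_min_reads = si_min_reads,
              top_frac = top_frac, distal_cut = distal_cut,
              proximal_cut = proximal_cut,
              peak_min_count = peak_min_count,
              peak_window = peak_window, pca_variance = pca_variance,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read/write a pipeline configuration as JSON
#'
#' @param path JSON file
#' @param config a `pipeline_config`
#' @return the config (read) or `path` invisibly (write)
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$simulate <- as.list(j$simulate)
  if ("tissues" %in% names(j$simulate))
    j$simulate$tissues <- unlist(j$simulate$tissues)
  do.call(pipeline_config, j)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory
#' @return a list shaped like [simulate_dataset()] output (tracks, pairs,
#'   genes, design; plus the truth table when present)
#' @export
read_dataset <- function(dir) {
  design <- read_design(file.path(dir, "design.tsv"))
  genes <- read_genes_bed(file.path(dir, "genes.bed"))
  tracks <- list()
  pairs <- list()
  for (sid in design$sample_id) {
    tr <- list()
    for (endt in c("five", "three")) {
      plus <- read_bedgraph(file.path(dir, sprintf("%s.%s.plus.bedgraph",
                                                   sid, endt)),
                            paste0(endt, "_prime"), "+")
      minus <- read_bedgraph(file.path(dir, sprintf("%s.%s.minus.bedgraph",
                                                    sid, endt)),
                             paste0(endt, "_prime"), "-")
      tr[[paste0(endt, "_prime")]] <- merge_tracks(plus, minus)
    }
    tracks[[sid]] <- tr
    pairs[[sid]] <- read_pairs(file.path(dir, sprintf("%s.pairs.tsv",
                                                      sid)))
  }
  truth_path <- file.path(dir, "elements_truth.tsv")
  elements <- if (file.exists(truth_path)) fread(truth_path) else NULL
  list(genes = genes, design = design, tracks = tracks, pairs = pairs,
       elements = elements)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order, writing each
#' stage's tables under `out_dir` together with the resolved
#' configuration and a JSON manifest (per stage: outputs, md5 checksums,
#' wall time, headline counts). Rerunning with an identical config and
#' seed reproduces identical checksums.
#'
#' @param config a `pipeline_config` (or path to its JSON form)
#' @param out_dir output directory (created)
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(config, file.path(out_dir, "config.json"))
  manifest <- list()
  log_stage <- function(name, outputs, info = list()) {
    files <- file.path(out_dir, outputs)
    manifest[[name]] <<- list(
      outputs = outputs,
      md5 = unname(tools::md5sum(files)),
      info = info)
  }

  ## --- data acquisition ------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(config$input_dir)) {
    ds <- read_dataset(config$input_dir)
  } else {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    tc <- do.call(truth_config, sim_args)
    ds <- simulate_dataset(tc)
    write_dataset(ds, file.path(out_dir, "dataset"))
  }
  log_stage("data", character(),
            list(n_samples = nrow(ds$design),
                 elapsed_s = proc.time()[["elapsed"]] - t0))
  five_tracks <- lapply(ds$tracks, `[[`, "five_prime")

  ## --- element classification -----------------------------------------
  elements <- NULL
  if ("elements" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    pooled <- merge_tracks(five_tracks)
    peaks <- naive_peak_call(pooled, min_count = config$peak_min_count,
                             window = config$peak_window)
    elements <- pair_divergent(peaks[strand == "+"],
                               peaks[strand == "-"],
                               max_gap = config$pairing_gap)
    elements <- annotate_proximity(elements, ds$genes,
                                   cutoff = config$proximity_cutoff)
    elements <- annotate_context(elements, ds$genes)
    fwrite(elements, file.path(out_dir, "elements.tsv"), sep = "\t")
    write_elements_bed(elements, file.path(out_dir, "elements.bed"))
    log_stage("elements", c("elements.tsv", "elements.bed"),
              list(n_elements = nrow(elements),
                   n_divergent = sum(elements$directionality ==
                                       "divergent"),
                   elapsed_s = proc.time()[["elapsed"]] - t0))
  }

  ## --- QC ---------------------------------------------------------------
  if ("qc" %in% config$stages) {
    t0 <- proc.time()[["elapsed"]]
    qc <- qc_report(five_tracks, ds$genes,
                    threshold = config$qc_threshold)
    fwrite(qc, file.path(out_dir, "qc.tsv"), sep = "\t")
    log_stage("qc", "qc.tsv",
              list(n_fail = sum(!qc$pass),
                   elapsed_s = proc.time()[["elapsed"]] - t0))
  }

  ## --- quantification ---------------------------------------------------
  norm <- NULL
  if ("quantify" %in% config$stages) {
    if (is.null(elements))
      stop_procapr("stage 'quantify' requires stage 'elements'")
    t0 <- proc.time()[["elapsed"]]
    counts <- build_count_matrix(five_tracks, elements)
    norm <- normalize_counts(counts)
    fwrite(data.table(element_id = rownames(counts), counts),
           file.path(out_dir, "counts.tsv"), sep = "\t")
    fwrite(data.table(sample_id = colnames(counts),
                      size_factor = norm$size_factors),
           file.path(out_dir, "size_factors.tsv"), sep = "\t")
    fwrite(data.table(element_id = rownames(counts),
                      round(norm$log2, 6)),
           file.path(out_dir, "normalized_log2.tsv"), sep = "\t")
    log_stage("quantify", c("counts.tsv", "size_factors.tsv",
                            "normalized_log2.tsv"),
              list(elapsed_s = proc.time()[["elapsed"]] - t0))
  }

  ## --- specificity -------------------------------------------------------
  sets <- NULL
  if ("specificity" %in% config$stages) {
    if (is.null(norm))
      stop_procapr("stage 'specificity' requires stage 'quantify'")
    t0 <- proc.time()[["elapsed"]]
    scores <- specificity_scores(norm, ds$design)
    eligible <- names(which(table(ds$design$tissue) >= 3L))
    t_by_tissue <- lapply(stats::setNames(nm = eligible), function(t)
      tissue_t_statistics(norm, ds$design, t))
    sets <- select_sets(t_by_tissue, scores,
                        stats::setNames(elements$proximity,
                                        elements$element_id),
                        top_frac = config$top_frac,
                        distal_cut = config$distal_cut,
                        proximal_cut = config$proximal_cut)
    fwrite(scores, file.path(out_dir, "specificity_scores.tsv"),
           sep = "\t")
    membership <- rbindlist(lapply(names(sets$specific), function(t)
      data.table(set = t, element_id = sets$specific[[t]])))
    membership <- rbind(membership,
                        data.table(set = "non_specific",
                                   element_id = sets$non_specific))
    fwrite(membership, file.path(out_dir, "specific_sets.tsv"),
           sep = "\t")
    log_stage("specificity",
              c("specificity_scores.tsv", "specific_sets.tsv"),
              list(n_tissues_tested = length(eligible),
                   elapsed_s = proc.time()[["elapsed"]] - t0))
  }

  ## --- shape --------------------------------------------------------------
  if ("shape" %in% config$stages) {
    if (is.null(elements))
      stop_procapr("stage 'shape' requires stage 'elements'")
    t0 <- proc.time()[["elapsed"]]
    pooled <- merge_tracks(five_tracks)
    sh <- shape_classify(pooled, elements,
                         min_reads = config$si_min_reads)
    fwrite(sh$strands, file.path(out_dir, "shape_strands.tsv"),
           sep = "\t")
    fwrite(sh$elements, file.path(out_dir, "shape_elements.tsv"),
           sep = "\t")
    log_stage("shape", c("shape_strands.tsv", "shape_elements.tsv"),
              list(n_scored = sum(!sh$elements$filtered),
                   elapsed_s = proc.time()[["elapsed"]] - t0))
  }

  ## --- pausing -------------------------------------------------------------
  if ("pausing" %in% config$stages) {
    if (is.null(elements))
      stop_procapr("stage 'pausing' requires stage 'elements'")
    t0 <- proc.time()[["elapsed"]]
    all_pairs <- rbindlist(ds$pairs, use.names = TRUE,
                           fill = TRUE)[, .(chrom, strand,
                                            five_prime_pos,
                                            three_prime_pos)]
    pd <- pause_distances(all_pairs, elements)
    classes <- classify_pausing(pd$summary)
    fwrite(pd$summary, file.path(out_dir, "pause_summary.tsv"),
           sep = "\t")
    fwrite(classes, file.path(out_dir, "pause_classes.tsv"), sep = "\t")
    log_stage("pausing", c("pause_summary.tsv", "pause_classes.tsv"),
              list(tally = as.list(pd$tally),
                   elapsed_s = proc.time()[["elapsed"]] - t0))
  }

  ## --- origin ---------------------------------------------------------------
  if ("origin" %in% config$stages) {
    if (is.null(norm) || is.null(sets))
      stop_procapr("stage 'origin' requires stages 'quantify' and ",
                   "'specificity'")
    t0 <- proc.time()[["elapsed"]]
    hc <- hier_cluster(norm)
    fwrite(data.table(step = seq_len(nrow(hc$merge)),
                      left = hc$merge[, 1L], right = hc$merge[, 2L],
                      height = round(hc$height, 10)),
           file.path(out_dir, "cluster_merges.tsv"), sep = "\t")
    model <- train_origin_model(norm, ds$design, sets$specific)
    write_origin_model(model, file.path(out_dir, "origin_model.json"))
    preds <- predict_topk(model, norm$log2,
                          k = min(3L, length(model$classes)))
    fwrite(preds, file.path(out_dir, "origin_predictions.tsv"),
           sep = "\t")
    top1 <- preds[rank == 1L]
    truth <- ds$design$tissue[match(top1$sample_id,
                                    ds$design$sample_id)]
    log_stage("origin",
              c("cluster_merges.tsv", "origin_model.json",
                "origin_predictions.tsv"),
              list(train_top1_accuracy = mean(top1$tissue == truth),
                   elapsed_s = proc.time()[["elapsed"]] - t0))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
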