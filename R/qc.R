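## Library quality control: the gene-body ratio.
##
## High-quality capped-RNA libraries concentrate reads at TSSs; uncapped
## contamination shows up as signal spread along gene bodies. The gene-body
## ratio compares length-normalized gene-body density against TSS-region
## density over highly expressed genes; libraries at or above 0.025 are
## flagged for exclusion.

#' Select highly expressed genes by promoter-proximal signal
#'
#' Genes are ranked by summed 5'-end counts on the gene's own strand in
#' the promoter-proximal window (1 kb upstream to 100 bp downstream of
#' the TSS, strand-oriented) and the top fraction is returned.
#'
#' @param track a 5' `signal_track`
#' @param genes gene annotation table
#' @param top_frac fraction of genes to keep (default 0.10); the number
#'   kept is `ceiling(top_frac * n_genes)`
#' @return the selected subset of `genes`, with a `proximal_signal`
#'   column, ordered by decreasing signal (ties broken by gene id)
#' @export
select_expressed_genes <- function(track, genes, top_frac = 0.10) {
  g <- as.data.table(genes)
  stopifnot(nrow(g) > 0, top_frac > 0, top_frac <= 1)
  sig <- vapply(seq_len(nrow(g)), function(i) {
    w <- oriented_window(g$tss[i], g$strand[i], up = 1000L, down = 100L)
    lo <- max(0L, w[["start"]])
    count_in_interval(track, g$chrom[i], lo, w[["end"]],
                      strand_mode = if (g$strand[i] == "+") "plus"
                                    else "minus",
                      warn_missing = FALSE)
  }, numeric(1L))
  if (all(sig == 0))
    stop_procapr("no expressed genes: all promoter-proximal windows empty")
  g[, proximal_signal := sig]
  setorder(g, -proximal_signal, gene_id)
  g[seq_len(ceiling(top_frac * nrow(g)))]
}

#' Compute the gene-body ratio QC metric for one library
#'
#' For each selected gene, the per-base read density in the gene body
#' (500 bp downstream of the TSS to 500 bp upstream of the transcription
#' termination site) is divided by the sum of the gene-body and TSS-region
#' (0-500 bp downstream of the TSS) densities, each normalized by its
#' region length; only reads on the gene's own strand are counted. Genes
#' whose body region is empty by construction (shorter than about 1 kb)
#' are skipped with a warning. The per-gene ratios are averaged (`mode =
#' "per_gene"`, default) or the densities are pooled across genes before
#' one division (`mode = "pooled"`). A library passes when the ratio is
#' below `threshold`.
#'
#' @param track a 5' `signal_track`
#' @param genes_subset genes to use, typically from
#'   [select_expressed_genes()]
#' @param sample_id label for the report
#' @param mode `"per_gene"` (mean of per-gene ratios) or `"pooled"`
#' @param threshold exclusion threshold (default 0.025); libraries with
#'   ratio >= threshold fail
#' @return one-row data.table: sample_id, n_genes_used, gene_body_ratio,
#'   pass
#' @export
gene_body_ratio <- function(track, genes_subset, sample_id = "sample",
                            mode = c("per_gene", "pooled"),
                            threshold = 0.025) {
  mode <- match.arg(mode)
  g <- as.data.table(genes_subset)
  if (nrow(g) == 0L) stop_procapr("empty gene subset")
  body_cnt <- body_len <- tss_cnt <- numeric(nrow(g))
  usable <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    sm <- if (g$strand[i] == "+") "plus" else "minus"
    tw <- oriented_window(g$tss[i], g$strand[i], up = 0L, down = 500L)
    if (g$strand[i] == "+") {
      b_lo <- g$tss[i] + 500L
      b_hi <- g$tts[i] - 500L + 1L   # half-open end
    } else {
      b_lo <- g$tts[i] + 500L
      b_hi <- g$tss[i] - 500L + 1L
    }
    if (b_hi - b_lo < 1L) {
      warning("gene ", g$gene_id[i],
              " shorter than ~1 kb; body undefined, skipped",
              call. = FALSE)
      next
    }
    usable[i] <- TRUE
    body_len[i] <- b_hi - b_lo
    body_cnt[i] <- count_in_interval(track, g$chrom[i], b_lo, b_hi,
                                     strand_mode = sm,
                                     warn_missing = FALSE)
    tss_cnt[i] <- count_in_interval(track, g$chrom[i], tw[["start"]],
                                    tw[["end"]], strand_mode = sm,
                                    warn_missing = FALSE)
  }
  if (!any(usable)) stop_procapr("no usable genes (all bodies undefined)")
  d_body <- body_cnt[usable] / body_len[usable]
  d_tss <- tss_cnt[usable] / 500
  if (mode == "per_gene") {
    r <- ifelse(d_body + d_tss == 0, 0, d_body / (d_body + d_tss))
    ratio <- mean(r)
  } else {
    db <- sum(body_cnt[usable]) / sum(body_len[usable])
    dt_ <- sum(tss_cnt[usable]) / (500 * sum(usable))
    ratio <- if (db + dt_ == 0) 0 else db / (db + dt_)
  }
  data.table(sample_id = sample_id, n_genes_used = sum(usable),
             gene_body_ratio = ratio, pass = ratio < threshold)
}

#' Run gene-body-ratio QC across samples
#'
#' @param tracks named list of 5' `signal_track`s (one per sample)
#' @param genes full gene annotation table
#' @param top_frac,mode,threshold passed to the per-sample computation
#' @return data.table with one QC row per sample
#' @export
qc_report <- function(tracks, genes, top_frac = 0.10,
                      mode = "per_gene", threshold = 0.025) {
  rbindlist(lapply(names(tracks), function(sid) {
    sel <- select_expressed_genes(tracks[[sid]], genes, top_frac)
    gene_body_ratio(tracks[[sid]], sel, sample_id = sid, mode = mode,
                    threshold = threshold)
  }))
}
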