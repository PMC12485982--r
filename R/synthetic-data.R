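## Synthetic PRO-cap data generator.
##
## Emulates the observables the analysis stack consumes: negative-binomial
## element read counts with tissue-restricted activity, within-element 5'
## position distributions that are peaked (two-sided geometric around the
## summit) or broad (uniform over the span), divergent two-strand geometry
## with configurable summit separation, per-read 3' pause offsets, and a
## uniform genomic background. Every planted quantity is returned as ground
## truth so parameter recovery can be tested.

#' Configuration for the synthetic PRO-cap dataset generator
#'
#' Defaults describe a small but realistic multi-tissue study: a toy
#' genome, genes laid out with wide intergenic gaps, divergent elements at
#' promoters and enhancers, four tissues with three replicate libraries
#' each, moderate negative-binomial dispersion, and a sparse uniform
#' background.
#'
#' @param n_chroms number of chromosomes
#' @param chrom_length length of each chromosome in bases
#' @param n_genes number of genes (10 kb each, laid out on a 25 kb grid)
#' @param n_elements number of transcribed regulatory elements
#' @param frac_divergent fraction of elements with peaks on both strands
#' @param divergent_gap_range range (min, max) from which each divergent
#'   element's summit-to-summit separation is drawn uniformly; max 300 by
#'   default, matching the divergent-pairing definition
#' @param frac_proximal fraction of elements placed at gene TSSs
#' @param tissues named integer vector: samples per tissue
#' @param baseline_mean negative-binomial mean read count per element per
#'   library at size factor 1
#' @param nb_dispersion negative-binomial size parameter (larger = closer
#'   to Poisson)
#' @param frac_specific fraction of elements active in exactly one tissue
#' @param fold_change activity multiplier in a specific element's active
#'   tissue
#' @param off_level residual activity multiplier of a specific element in
#'   its inactive tissues (tissue-specific enhancers are nearly silent
#'   elsewhere)
#' @param frac_peaked probability that a strand's initiation profile is
#'   peaked (P) rather than broad (B)
#' @param peak_concentration geometric decay parameter of the peaked
#'   profile (probability in (0, 1]; 1 collapses to a point mass at the
#'   summit)
#' @param pause_regime_means mean 3'-5' pause offsets (bases) of the
#'   early/intermediate/late pausing regimes; each element is assigned one
#'   regime
#' @param pause_sd standard deviation of per-read pause offsets
#' @param background_rate uniform background reads per kilobase per
#'   library
#' @param size_factor_range library size factors are drawn log-uniformly
#'   from this range
#' @param seed integer seed; the generator is bit-reproducible given the
#'   config
#' @return a `truth_config` list
#' @export
truth_config <- function(n_chroms = 2L, chrom_length = 1e6,
                         n_genes = 20L, n_elements = 60L,
                         frac_divergent = 0.8,
                         divergent_gap_range = c(40L, 300L),
                         frac_proximal = 0.3,
                         tissues = c(brain = 3L, liver = 3L,
                                     lung = 3L, colon = 3L),
                         baseline_mean = 100, nb_dispersion = 100,
                         frac_specific = 0.2, fold_change = 8,
                         off_level = 0.1,
                         frac_peaked = 0.5, peak_concentration = 0.5,
                         pause_regime_means = c(early = 25,
                                                intermediate = 50,
                                                late = 90),
                         pause_sd = 5,
                         background_rate = 0.05,
                         size_factor_range = c(0.5, 2),
                         seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              n_elements = as.integer(n_elements),
              frac_divergent = frac_divergent,
              divergent_gap_range = as.integer(divergent_gap_range),
              frac_proximal = frac_proximal,
              tissues = tissues,
              baseline_mean = baseline_mean,
              nb_dispersion = nb_dispersion,
              frac_specific = frac_specific,
              fold_change = fold_change,
              off_level = off_level,
              frac_peaked = frac_peaked,
              peak_concentration = peak_concentration,
              pause_regime_means = pause_regime_means,
              pause_sd = pause_sd,
              background_rate = background_rate,
              size_factor_range = size_factor_range,
              seed = as.integer(seed))
  stopifnot(cfg$n_chroms > 0, cfg$chrom_length > 0, cfg$n_genes > 0,
            cfg$n_elements > 0,
            cfg$frac_divergent >= 0, cfg$frac_divergent <= 1,
            cfg$frac_proximal >= 0, cfg$frac_proximal <= 1,
            cfg$frac_specific >= 0, cfg$frac_specific <= 1,
            all(cfg$divergent_gap_range >= 0),
            diff(cfg$divergent_gap_range) >= 0,
            cfg$peak_concentration > 0, cfg$peak_concentration <= 1,
            all(cfg$tissues >= 1), length(cfg$tissues) >= 1,
            cfg$background_rate >= 0)
  class(cfg) <- "truth_config"
  cfg
}

## genome layout constants of the generator
.sim_unit <- 25000L       # one gene + one distal-element slot per unit
.sim_gene_offset <- 2000L
.sim_gene_length <- 10000L
.sim_distal_center <- 18500L
.sim_summit_margin <- 100L  # span extends this far beyond the summits

#' Simulate a PRO-cap dataset with known ground truth
#'
#' See [truth_config()] for the generative model. Returns per-sample 5'
#' and 3' signal tracks on both strands, per-sample matched read-end
#' tables, the gene annotation, the element ground-truth table (geometry,
#' directionality, proximity, strand shape labels, pause regime, tissue
#' activity), the sample design, and the planted size factors.
#'
#' @param config a [truth_config()]
#' @return a list of class `procap_sim` with components `genes`,
#'   `elements`, `activity` (element x tissue expected mean count at size
#'   factor 1), `design`, `size_factors`, `tracks` (per sample:
#'   `five_prime`, `three_prime`), `pairs` (per sample), `config`
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  units_per_chrom <- as.integer(cfg$chrom_length %/% .sim_unit)
  if (units_per_chrom < 1L)
    stop_procapr("chromosomes too short for the generator layout (need >= ",
                 .sim_unit, " bases)")
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  total_units <- cfg$n_chroms * units_per_chrom
  n_prox <- round(cfg$frac_proximal * cfg$n_elements)
  n_dist <- cfg$n_elements - n_prox
  if (cfg$n_genes > total_units)
    stop_procapr("infeasible geometry: ", cfg$n_genes, " genes but only ",
                 total_units, " genome slots")
  if (n_prox > cfg$n_genes)
    stop_procapr("infeasible geometry: ", n_prox,
                 " proximal elements but only ", cfg$n_genes, " genes")
  if (n_dist > total_units)
    stop_procapr("infeasible geometry: ", n_dist,
                 " distal elements but only ", total_units, " slots")

  unit_chrom <- rep(chroms, each = units_per_chrom)
  unit_start <- rep((seq_len(units_per_chrom) - 1L) * .sim_unit,
                    times = cfg$n_chroms)

  ## genes on the first n_genes units, strands alternating
  gi <- seq_len(cfg$n_genes)
  g_start <- unit_start[gi] + .sim_gene_offset
  genes <- gene_annotation(sprintf("gene_%04d", gi), unit_chrom[gi],
                           g_start, g_start + .sim_gene_length,
                           ifelse(gi %% 2L == 1L, "+", "-"))

  ## element placement: proximal elements centred at gene TSSs, distal
  ## elements at the intergenic slot of each unit
  el_ids <- sprintf("el_%05d", seq_len(cfg$n_elements))
  is_prox <- c(rep(TRUE, n_prox), rep(FALSE, n_dist))
  centers <- integer(cfg$n_elements)
  el_chrom <- character(cfg$n_elements)
  if (n_prox > 0L) {
    pg <- sample(cfg$n_genes, n_prox)
    centers[seq_len(n_prox)] <- genes$tss[pg]
    el_chrom[seq_len(n_prox)] <- genes$chrom[pg]
  }
  if (n_dist > 0L) {
    du <- sample(total_units, n_dist)
    centers[n_prox + seq_len(n_dist)] <- unit_start[du] + .sim_distal_center
    el_chrom[n_prox + seq_len(n_dist)] <- unit_chrom[du]
  }

  n_div <- round(cfg$frac_divergent * cfg$n_elements)
  div <- rep(FALSE, cfg$n_elements)
  div[sample(cfg$n_elements, n_div)] <- TRUE
  gaps <- sample(seq(cfg$divergent_gap_range[1L],
                     cfg$divergent_gap_range[2L]),
                 cfg$n_elements, replace = TRUE)
  uni_strand <- sample(c("+", "-"), cfg$n_elements, replace = TRUE)
  half <- gaps %/% 2L
  plus_summit <- ifelse(div, centers + half, centers)
  minus_summit <- ifelse(div, centers - (gaps - half), centers)
  start <- pmin(minus_summit, plus_summit) - .sim_summit_margin
  end <- pmax(minus_summit, plus_summit) + .sim_summit_margin + 1L
  if (any(start < 0) || any(end > cfg$chrom_length))
    stop_procapr("infeasible geometry: element extends past a chromosome")

  shape_plus <- sample(c("P", "B"), cfg$n_elements, replace = TRUE,
                       prob = c(cfg$frac_peaked, 1 - cfg$frac_peaked))
  shape_minus <- sample(c("P", "B"), cfg$n_elements, replace = TRUE,
                        prob = c(cfg$frac_peaked, 1 - cfg$frac_peaked))
  regimes <- names(cfg$pause_regime_means)
  pause_regime <- sample(regimes, cfg$n_elements, replace = TRUE)
  pause_mean <- unname(cfg$pause_regime_means[pause_regime])

  ## tissue activity multipliers
  tissue_names <- names(cfg$tissues)
  n_tis <- length(tissue_names)
  mult <- matrix(1, cfg$n_elements, n_tis,
                 dimnames = list(el_ids, tissue_names))
  n_spec <- round(cfg$frac_specific * cfg$n_elements)
  spec_tissue <- rep(NA_character_, cfg$n_elements)
  if (n_spec > 0L && n_tis >= 2L) {
    spec_idx <- sample(cfg$n_elements, n_spec)
    spec_tis <- rep_len(tissue_names, n_spec)
    for (k in seq_len(n_spec)) {
      mult[spec_idx[k], ] <- cfg$off_level
      mult[spec_idx[k], spec_tis[k]] <- cfg$fold_change
      spec_tissue[spec_idx[k]] <- spec_tis[k]
    }
  }
  activity <- cfg$baseline_mean * mult

  elements <- data.table(
    element_id = el_ids, chrom = el_chrom,
    start = as.integer(start), end = as.integer(end),
    directionality = ifelse(div, "divergent", "unidirectional"),
    proximity = ifelse(is_prox, "proximal", "distal"),
    plus_summit = as.integer(ifelse(div | uni_strand == "+",
                                    plus_summit, NA)),
    minus_summit = as.integer(ifelse(div | uni_strand == "-",
                                     minus_summit, NA)),
    shape_plus = ifelse(div | uni_strand == "+", shape_plus, NA),
    shape_minus = ifelse(div | uni_strand == "-", shape_minus, NA),
    pause_regime = pause_regime, pause_mean = pause_mean,
    specific_tissue = spec_tissue)
  setorder(elements, chrom, start)

  ## samples
  design <- data.table(
    sample_id = unlist(lapply(tissue_names, function(t)
      sprintf("%s_s%d", t, seq_len(cfg$tissues[[t]])))),
    tissue = rep(tissue_names, times = unname(cfg$tissues)))
  sf <- exp(runif(nrow(design), log(cfg$size_factor_range[1L]),
                  log(cfg$size_factor_range[2L])))
  names(sf) <- design$sample_id

  chrom_len <- cfg$chrom_length
  genome_kb <- cfg$n_chroms * chrom_len / 1000
  mid_regime <- cfg$pause_regime_means[ceiling(length(regimes) / 2)]

  el <- elements  # placement order (sorted); index aligned below
  act <- activity[el$element_id, , drop = FALSE]
  tracks <- list()
  pairs <- list()
  for (j in seq_len(nrow(design))) {
    tis <- design$tissue[j]
    mu <- act[, tis] * sf[j]
    n_reads <- rnbinom(nrow(el), mu = mu, size = cfg$nb_dispersion)
    reads <- sim_element_reads(el, n_reads, cfg)
    ## uniform background
    n_bg <- rpois(1L, cfg$background_rate * genome_kb)
    if (n_bg > 0L) {
      bg5 <- as.integer(floor(runif(n_bg, 0, chrom_len)))
      bg_strand <- sample(c("+", "-"), n_bg, replace = TRUE)
      off <- pmax(0, round(rnorm(n_bg, mid_regime, cfg$pause_sd)))
      bg3 <- ifelse(bg_strand == "+", bg5 + off, bg5 - off)
      bg3 <- pmin(pmax(bg3, 0L), chrom_len - 1L)
      reads <- rbind(reads, data.table(
        chrom = sample(sprintf("chr%d", seq_len(cfg$n_chroms)), n_bg,
                       replace = TRUE),
        strand = bg_strand, five_prime_pos = bg5,
        three_prime_pos = as.integer(bg3),
        element_id = NA_character_))
    }
    sid <- design$sample_id[j]
    pairs[[sid]] <- reads
    tracks[[sid]] <- list(
      five_prime = track_from_dt(
        reads[, .(chrom, strand, pos = five_prime_pos)], "five_prime"),
      three_prime = track_from_dt(
        reads[, .(chrom, strand, pos = three_prime_pos)], "three_prime"))
  }

  structure(list(genes = genes, elements = elements, activity = activity,
                 design = design, size_factors = sf, tracks = tracks,
                 pairs = pairs, config = cfg),
            class = "procap_sim")
}

## place n_reads[i] reads for each element row; returns a read table
sim_element_reads <- function(el, n_reads, cfg) {
  total <- sum(n_reads)
  if (total == 0L)
    return(data.table(chrom = character(), strand = character(),
                      five_prime_pos = integer(),
                      three_prime_pos = integer(),
                      element_id = character()))
  idx <- rep(seq_len(nrow(el)), n_reads)
  div <- el$directionality[idx] == "divergent"
  has_plus <- !is.na(el$plus_summit[idx])
  ## divergent: each read picks a strand with equal probability;
  ## unidirectional: the element's single strand
  on_plus <- ifelse(div, runif(total) < 0.5, has_plus)
  strand <- ifelse(on_plus, "+", "-")
  summit <- ifelse(on_plus, el$plus_summit[idx], el$minus_summit[idx])
  shape <- ifelse(on_plus, el$shape_plus[idx], el$shape_minus[idx])
  span_lo <- el$start[idx]
  span_hi <- el$end[idx] - 1L
  pos <- integer(total)
  pk <- shape == "P"
  if (any(pk)) {
    n <- sum(pk)
    off <- rgeom(n, cfg$peak_concentration) *
      sample(c(-1L, 1L), n, replace = TRUE)
    pos[pk] <- pmin(pmax(summit[pk] + off, span_lo[pk]), span_hi[pk])
  }
  if (any(!pk)) {
    n <- sum(!pk)
    pos[!pk] <- span_lo[!pk] +
      as.integer(floor(runif(n) * (span_hi[!pk] - span_lo[!pk] + 1L)))
  }
  off3 <- pmax(0, round(rnorm(total, el$pause_mean[idx], cfg$pause_sd)))
  pos3 <- ifelse(strand == "+", pos + off3, pos - off3)
  pos3 <- pmin(pmax(pos3, 0L), as.integer(cfg$chrom_length) - 1L)
  data.table(chrom = el$chrom[idx], strand = strand,
             five_prime_pos = as.integer(pos),
             three_prime_pos = as.integer(pos3),
             element_id = el$element_id[idx])
}

#' Move a fraction of a library's reads into gene bodies
#'
#' Emulates loss of 5' (cap) enrichment: the stated fraction of reads is
#' relocated to positions drawn uniformly over gene intervals (on each
#' gene's own strand), which is what degraded or poorly enriched capped
#' libraries look like. Library size is conserved. Used as the fixture for
#' the gene-body-ratio QC.
#'
#' @param track a 5' `signal_track`
#' @param genes gene annotation table
#' @param contamination_fraction fraction of reads to move, in \[0, 1\]
#' @param seed integer seed
#' @return a degraded `signal_track`
#' @export
degrade_library <- function(track, genes, contamination_fraction,
                            seed = 1L) {
  stopifnot(inherits(track, "signal_track"))
  if (contamination_fraction < 0 || contamination_fraction > 1)
    stop_procapr("contamination_fraction must be in [0, 1]")
  if (contamination_fraction == 0) return(track)
  g <- as.data.table(genes)
  stopifnot(nrow(g) > 0)
  with_seed(seed, {
    reads <- track$data[rep(seq_len(.N), count),
                        .(chrom, strand, pos)]
    n_move <- round(contamination_fraction * nrow(reads))
    if (n_move > 0L) {
      mv <- sample(nrow(reads), n_move)
      glen <- g$end - g$start
      gi <- sample(nrow(g), n_move, replace = TRUE, prob = glen)
      newpos <- g$start[gi] +
        as.integer(floor(runif(n_move) * glen[gi]))
      reads[mv, `:=`(chrom = g$chrom[gi], strand = g$strand[gi],
                     pos = newpos)]
    }
    track_from_dt(reads, track$end_type)
  })
}

#' Simulate a count-level tissue cohort for origin prediction
#'
#' Generates an element-by-sample count cohort directly at the count level
#' (no read placement): a panel of normal training samples from many
#' tissues, each tissue with a disjoint set of specifically active
#' elements on top of a shared ubiquitous background, plus metastatic-like
#' query samples whose expected signal is a fixed mixture of a primary and
#' a destination tissue signature with negative-binomial noise.
#'
#' @param n_tissues number of tissues
#' @param n_train total training samples, divided as evenly as possible
#'   across tissues
#' @param n_queries number of metastatic-like query samples
#' @param n_specific specifically active elements per tissue
#' @param n_shared ubiquitously active elements
#' @param baseline_mean,fold_change,off_level,nb_dispersion activity model
#'   as in [truth_config()]
#' @param mix mixing weights (primary, destination) of query signatures
#' @param size_factor_range per-sample size factors, log-uniform
#' @param seed integer seed
#' @return list with `counts` (train matrix), `design`, `query_counts`,
#'   `query_truth` (sample_id, primary, destination), `truth_sets`
#'   (per-tissue planted specific element ids), `size_factors`
#' @export
simulate_origin_cohort <- function(n_tissues = 15L, n_train = 93L,
                                   n_queries = 23L, n_specific = 8L,
                                   n_shared = 80L, baseline_mean = 100,
                                   fold_change = 8, off_level = 0.1,
                                   nb_dispersion = 10,
                                   mix = c(0.7, 0.3),
                                   size_factor_range = c(0.5, 2),
                                   seed = 1L) {
  stopifnot(n_tissues >= 2L, n_train >= n_tissues, n_queries >= 1L,
            abs(sum(mix) - 1) < 1e-9)
  with_seed(seed, {
    tissues <- sprintf("tissue%02d", seq_len(n_tissues))
    per <- rep(n_train %/% n_tissues, n_tissues)
    extra <- n_train - sum(per)
    if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    design <- data.table(
      sample_id = unlist(lapply(seq_len(n_tissues), function(i)
        sprintf("%s_s%d", tissues[i], seq_len(per[i])))),
      tissue = rep(tissues, times = per))

    n_el <- n_tissues * n_specific + n_shared
    el_ids <- sprintf("oel_%05d", seq_len(n_el))
    mu_mat <- matrix(baseline_mean, n_el, n_tissues,
                     dimnames = list(el_ids, tissues))
    truth_sets <- list()
    for (i in seq_len(n_tissues)) {
      rows <- (i - 1L) * n_specific + seq_len(n_specific)
      mu_mat[rows, ] <- baseline_mean * off_level
      mu_mat[rows, i] <- baseline_mean * fold_change
      truth_sets[[tissues[i]]] <- el_ids[rows]
    }

    sf <- exp(runif(n_train + n_queries, log(size_factor_range[1L]),
                    log(size_factor_range[2L])))
    counts <- matrix(0, n_el, n_train,
                     dimnames = list(el_ids, design$sample_id))
    for (j in seq_len(n_train))
      counts[, j] <- rnbinom(n_el, mu = mu_mat[, design$tissue[j]] * sf[j],
                             size = nb_dispersion)

    primary <- sample(tissues, n_queries, replace = TRUE)
    destination <- vapply(primary, function(p)
      sample(setdiff(tissues, p), 1L), character(1L))
    qids <- sprintf("met_q%02d", seq_len(n_queries))
    query_counts <- matrix(0, n_el, n_queries,
                           dimnames = list(el_ids, qids))
    for (q in seq_len(n_queries)) {
      mu <- (mix[1L] * mu_mat[, primary[q]] +
               mix[2L] * mu_mat[, destination[q]]) * sf[n_train + q]
      query_counts[, q] <- rnbinom(n_el, mu = mu, size = nb_dispersion)
    }
    names(sf) <- c(design$sample_id, qids)
    list(counts = counts, design = design, query_counts = query_counts,
         query_truth = data.table(sample_id = qids, primary = primary,
                                  destination = destination),
         truth_sets = truth_sets, size_factors = sf)
  })
}

#' Write a simulated dataset to disk
#'
#' Writes per-sample bedGraph tracks (one per end type and strand), the
#' gene and element BED files, the design and read-pair TSVs, and a JSON
#' truth manifest.
#'
#' @param sim a `procap_sim` from [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "procap_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chroms <- sprintf("chr%d", seq_len(sim$config$n_chroms))
  for (sid in names(sim$tracks)) {
    for (endt in c("five_prime", "three_prime")) {
      for (s in c("+", "-")) {
        tag <- if (s == "+") "plus" else "minus"
        path <- file.path(dir, sprintf("%s.%s.%s.bedgraph", sid,
                                       sub("_prime", "", endt), tag))
        tr <- sim$tracks[[sid]][[endt]]
        lines <- character()
        for (cc in chroms) {
          tmp <- tempfile()
          write_bedgraph(tr, cc, s, tmp)
          lines <- c(lines, readLines(tmp))
          unlink(tmp)
        }
        writeLines(lines, path)
      }
    }
    fwrite(sim$pairs[[sid]][, .(chrom, strand, five_prime_pos,
                                three_prime_pos)],
           file.path(dir, sprintf("%s.pairs.tsv", sid)), sep = "\t")
  }
  fwrite(sim$genes[, .(chrom, start, end, gene_id, score = 0L, strand)],
         file.path(dir, "genes.bed"), sep = "\t", col.names = FALSE)
  fwrite(sim$elements, file.path(dir, "elements_truth.tsv"), sep = "\t")
  fwrite(sim$design, file.path(dir, "design.tsv"), sep = "\t")
  jsonlite::write_json(
    list(config = unclass(sim$config),
         size_factors = as.list(sim$size_factors),
         activity = as.data.frame(sim$activity)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
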