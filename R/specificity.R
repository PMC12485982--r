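## Entropy-based tissue specificity and tissue-specific set selection.
##
## For element e and tissue t, q[e,t] is the mean normalized expression
## across samples of t; converting to probabilities p[t|e] =
## q[e,t]/sum_t q[e,t] gives the entropy H_e = -sum p log2 p and the
## specificity score S_e = 1 - H_e / log2(N), bounded in [0, 1]
## (0 = ubiquitous, 1 = exclusively one tissue).

#' Compute entropy-based tissue specificity scores
#'
#' Uses the nonnegative normalized counts (count / size factor), not the
#' log-transformed values, since the tissue probabilities require
#' nonnegative expression. Elements with zero total expression get an
#' undefined (NA) score and are flagged.
#'
#' @param norm a `procap_norm` from [normalize_counts()]
#' @param design sample design table (sample_id, tissue) covering the
#'   matrix columns; at least 2 tissues
#' @return data.table with element_id, per-tissue mean expression columns
#'   `q_<tissue>`, entropy `H` (bits), score `S`, and `defined` flag
#' @export
specificity_scores <- function(norm, design) {
  stopifnot(inherits(norm, "procap_norm"))
  design <- as.data.table(design)
  x <- norm$norm
  if (any(x < 0)) stop_procapr("negative normalized expression")
  stopifnot(all(colnames(x) %in% design$sample_id))
  tis <- design$tissue[match(colnames(x), design$sample_id)]
  tissues <- sort(unique(tis))
  n_tis <- length(tissues)
  if (n_tis < 2L) stop_procapr("specificity needs >= 2 tissue types")
  q <- matrix(0, nrow(x), n_tis, dimnames = list(rownames(x), tissues))
  for (t in tissues)
    q[, t] <- rowMeans(x[, tis == t, drop = FALSE])
  tot <- rowSums(q)
  defined <- tot > 0
  p <- q / ifelse(tot > 0, tot, 1)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  H <- -rowSums(plogp)
  S <- 1 - H / log2(n_tis)
  H[!defined] <- NA_real_
  S[!defined] <- NA_real_
  out <- data.table(element_id = rownames(x))
  for (t in tissues) set(out, j = paste0("q_", t), value = q[, t])
  set(out, j = "H", value = H)
  set(out, j = "S", value = S)
  set(out, j = "defined", value = defined)
  out[]
}

#' Per-element OLS t-statistics for tissue membership
#'
#' For one tissue, regresses each element's normalized (log) expression
#' across samples on an intercept and a membership indicator coded +1 for
#' samples of the tissue and -1 otherwise, and returns the t-statistic of
#' the membership coefficient (residual degrees of freedom n - 2). For a
#' balanced comparison this equals the classical equal-variance two-sample
#' t-statistic. Zero residual variance yields +/-Inf with the sign of the
#' coefficient (0 when the coefficient is also 0).
#'
#' @param norm a `procap_norm`; the log2 matrix is used
#' @param design sample design table
#' @param tissue tissue to test; must have at least `min_samples` samples
#' @param min_samples minimum samples in the tissue (default 3)
#' @return named numeric vector of t-statistics per element
#' @export
tissue_t_statistics <- function(norm, design, tissue, min_samples = 3L) {
  stopifnot(inherits(norm, "procap_norm"))
  design <- as.data.table(design)
  y <- norm$log2
  tis <- design$tissue[match(colnames(y), design$sample_id)]
  n <- ncol(y)
  n_in <- sum(tis == tissue)
  if (n_in < min_samples)
    stop_procapr("tissue '", tissue, "' has ", n_in, " samples; need >= ",
                 min_samples)
  if (n <= 2L) stop_procapr("need more than 2 samples in total")
  m <- ifelse(tis == tissue, 1, -1)
  ## closed-form simple regression on the +/-1 indicator
  mbar <- mean(m)
  sxx <- sum((m - mbar)^2)
  if (sxx == 0) stop_procapr("membership indicator is constant")
  yc <- sweep(y, 1L, rowMeans(y))
  beta <- as.vector(yc %*% (m - mbar)) / sxx
  fitted_dev <- outer(beta, m - mbar)          # deviations from row mean
  resid <- yc - fitted_dev
  rss <- rowSums(resid^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- ifelse(se > 0, beta / se,
              ifelse(beta == 0, 0, sign(beta) * Inf))
  names(t) <- rownames(y)
  t
}

#' Select tissue-specific and non-tissue-specific element sets
#'
#' Per tissue, the top `ceiling(top_frac * n)` elements of the scored
#' union set ranked by membership t-statistic (ties broken by element id)
#' form the tissue-specific set. The non-tissue-specific set collects
#' distal elements with specificity score below `distal_cut` and proximal
#' elements below `proximal_cut`, excluding anything that appears in any
#' tissue-specific set. Elements with undefined scores are excluded
#' throughout.
#'
#' @param t_by_tissue named list of per-element t-statistic vectors (one
#'   per eligible tissue), as from [tissue_t_statistics()]
#' @param scores specificity score table from [specificity_scores()]
#' @param proximity named character vector (or element table with
#'   `element_id` and `proximity`) giving "proximal"/"distal" per element
#' @param top_frac fraction for the specific sets (default 0.05)
#' @param distal_cut,proximal_cut score thresholds for the non-specific
#'   set (defaults 0.1 and 0.02)
#' @return list with `specific` (named list of element-id vectors per
#'   tissue), `non_specific` (element ids), `ranked` (named list of full
#'   rankings with t values)
#' @export
select_sets <- function(t_by_tissue, scores, proximity,
                        top_frac = 0.05, distal_cut = 0.1,
                        proximal_cut = 0.02) {
  scores <- as.data.table(scores)
  if (is.data.frame(proximity) || is.data.table(proximity)) {
    pr <- as.data.table(proximity)
    proximity <- stats::setNames(pr$proximity, pr$element_id)
  }
  eligible <- scores$element_id[scores$defined]
  n_top <- ceiling(top_frac * length(eligible))
  specific <- list()
  ranked <- list()
  for (tname in names(t_by_tissue)) {
    t <- t_by_tissue[[tname]]
    t <- t[names(t) %in% eligible]
    ord <- order(-t, names(t))
    ranked[[tname]] <- data.table(element_id = names(t)[ord],
                                  t_statistic = unname(t[ord]))
    specific[[tname]] <- names(t)[ord][seq_len(min(n_top, length(t)))]
  }
  in_specific <- unique(unlist(specific))
  S <- stats::setNames(scores$S, scores$element_id)
  prox_el <- eligible[proximity[eligible] == "proximal"]
  dist_el <- eligible[proximity[eligible] == "distal"]
  ns <- c(dist_el[S[dist_el] < distal_cut],
          prox_el[S[prox_el] < proximal_cut])
  ns <- setdiff(ns, in_specific)
  list(specific = specific, non_specific = sort(ns), ranked = ranked)
}
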