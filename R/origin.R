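## Tissue-of-origin analyses: sample clustering, PCA-truncated Pearson
## similarity of tumour versus normal samples, and a linear SVM that
## predicts a metastatic sample's primary site from tissue-specific
## element signal.

#' Hierarchical clustering of samples by expression correlation
#'
#' Agglomerative clustering of the sample columns with distance
#' 1 - Pearson correlation and average linkage.
#'
#' @param norm a `procap_norm`; the log2 matrix is used
#' @param element_ids optional subset of elements (e.g. divergent distal
#'   elements) to cluster on
#' @param method linkage method (default "average")
#' @return an `hclust` object
#' @export
hier_cluster <- function(norm, element_ids = NULL, method = "average") {
  stopifnot(inherits(norm, "procap_norm"))
  x <- norm$log2
  if (!is.null(element_ids)) x <- x[element_ids, , drop = FALSE]
  if (ncol(x) < 2L) stop_procapr("clustering needs >= 2 samples")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    stop_procapr("constant expression (zero variance) in sample(s): ",
                 paste(colnames(x)[sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(x))
  hclust(d, method = method)
}

#' Tumour-normal similarity in truncated principal-component space
#'
#' Fits a PCA on all included samples jointly (elements as variables,
#' samples as observations, mean-centred), keeps the smallest number of
#' leading components whose cumulative explained variance reaches
#' `variance_target`, and computes Pearson correlations between sample
#' score vectors in that space. For each tumour, normals are grouped as
#' primary-site, metastatic-site or other, and mean correlations per
#' group are reported.
#'
#' @param norm a `procap_norm` containing both tumour and normal samples
#' @param tumor_info data.frame with sample_id, primary, metastatic_site
#'   for each tumour sample
#' @param normal_design data.frame with sample_id, tissue for the normal
#'   samples
#' @param variance_target cumulative explained-variance threshold
#'   (default 0.90)
#' @param element_ids optional element subset
#' @return list with `n_components`, `pairwise` (tumor, normal, group,
#'   r), and `summary` (per tumour: mean r to primary-site, to
#'   metastatic-site, to other normals)
#' @export
pc_correlations <- function(norm, tumor_info, normal_design,
                            variance_target = 0.90,
                            element_ids = NULL) {
  stopifnot(inherits(norm, "procap_norm"))
  tumor_info <- as.data.table(tumor_info)
  normal_design <- as.data.table(normal_design)
  x <- norm$log2
  if (!is.null(element_ids)) x <- x[element_ids, , drop = FALSE]
  ids <- c(tumor_info$sample_id, normal_design$sample_id)
  stopifnot(all(ids %in% colnames(x)))
  x <- x[, ids, drop = FALSE]
  pca <- prcomp(t(x), center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  cum <- cumsum(ev) / sum(ev)
  m <- which(cum >= variance_target)[1L]
  if (is.na(m)) m <- length(ev)   # cannot happen; cumulative reaches 1
  scores <- pca$x[, seq_len(m), drop = FALSE]
  pw <- list()
  for (i in seq_len(nrow(tumor_info))) {
    tid <- tumor_info$sample_id[i]
    for (j in seq_len(nrow(normal_design))) {
      nid <- normal_design$sample_id[j]
      grp <- if (normal_design$tissue[j] == tumor_info$primary[i])
        "primary_site"
      else if (normal_design$tissue[j] == tumor_info$metastatic_site[i])
        "metastatic_site"
      else "other"
      pw[[length(pw) + 1L]] <- data.table(
        tumor = tid, normal = nid, group = grp,
        r = cor(scores[tid, ], scores[nid, ]))
    }
  }
  pw <- rbindlist(pw)
  summ <- dcast(pw[, .(mean_r = mean(r)), by = .(tumor, group)],
                tumor ~ group, value.var = "mean_r")
  list(n_components = m, pairwise = pw, summary = summ)
}

#' Train a linear SVM tissue-of-origin model
#'
#' Features are the union of the per-tissue specific element sets with
#' elements appearing in more than one tissue's set excluded, so every
#' feature marks exactly one tissue. A one-vs-rest linear support vector
#' classifier (cost 1) is trained per tissue on the normalized (log2)
#' expression of normal samples; the model stores explicit weight vectors
#' and intercepts, so prediction is a plain linear scoring.
#'
#' @param norm a `procap_norm` of the normal (training) samples
#' @param design sample design table for the training samples
#' @param specific_sets named list of per-tissue element-id vectors (the
#'   `specific` component of [select_sets()])
#' @param cost SVM regularization constant (default 1)
#' @return object of class `origin_model`: features, classes, weights
#'   (features x classes), intercepts
#' @export
train_origin_model <- function(norm, design, specific_sets, cost = 1) {
  stopifnot(inherits(norm, "procap_norm"), length(specific_sets) >= 2L)
  design <- as.data.table(design)
  all_ids <- unlist(specific_sets, use.names = FALSE)
  shared <- unique(all_ids[duplicated(all_ids)])
  kept <- lapply(specific_sets, function(s) setdiff(s, shared))
  empty <- names(kept)[lengths(kept) == 0L]
  if (length(empty))
    stop_procapr("tissue(s) with no features left after excluding ",
                 "shared elements: ", paste(empty, collapse = ", "))
  features <- unique(unlist(kept, use.names = FALSE))
  features <- features[features %in% rownames(norm$log2)]
  x <- t(norm$log2[features, , drop = FALSE])
  tis <- design$tissue[match(rownames(x), design$sample_id)]
  classes <- sort(unique(tis))
  w <- matrix(0, length(features), length(classes),
              dimnames = list(features, classes))
  b <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    y <- factor(ifelse(tis == cl, cl, "rest"), levels = c(cl, "rest"))
    fit <- e1071::svm(x, y, kernel = "linear", cost = cost,
                      scale = FALSE)
    wv <- as.vector(t(fit$coefs) %*% fit$SV)
    bv <- -fit$rho
    ## e1071 orients the decision value toward whichever label appears
    ## first in the training data; flip so positive always means `cl`
    pos_class <- fit$levels[fit$labels[1L]]
    if (pos_class != cl) {
      wv <- -wv
      bv <- -bv
    }
    w[, cl] <- wv
    b[cl] <- bv
  }
  structure(list(features = features, classes = classes, weights = w,
                 intercepts = b, feature_tissue = kept, cost = cost),
            class = "origin_model")
}

#' @export
print.origin_model <- function(x, ...) {
  cat(sprintf("<origin_model: %d classes, %d features>\n",
              length(x$classes), length(x$features)))
  invisible(x)
}

#' Predict tissue of origin with top-k ranking
#'
#' Scores each query sample against every class's one-vs-rest hyperplane
#' and ranks tissues by decreasing decision score (ties broken by tissue
#' name). Query features missing from the matrix are imputed as 0 with a
#' warning.
#'
#' @param model an `origin_model`
#' @param query normalized log2 expression matrix (elements x query
#'   samples), e.g. the `log2` slot of [normalize_counts()]
#' @param k how many top predictions to flag (default 3; at most the
#'   number of classes)
#' @return data.table: sample_id, rank, tissue, score, top_k flag
#' @export
predict_topk <- function(model, query, k = 3L) {
  stopifnot(inherits(model, "origin_model"))
  if (k > length(model$classes))
    stop_procapr("k (", k, ") exceeds number of classes (",
                 length(model$classes), ")")
  query <- as.matrix(query)
  missing <- setdiff(model$features, rownames(query))
  if (length(missing)) {
    warning(length(missing),
            " model feature(s) absent from query; imputed as 0",
            call. = FALSE)
    pad <- matrix(0, length(missing), ncol(query),
                  dimnames = list(missing, colnames(query)))
    query <- rbind(query, pad)
  }
  xq <- t(query[model$features, , drop = FALSE])
  sc <- sweep(xq %*% model$weights, 2L, model$intercepts, `+`)
  out <- rbindlist(lapply(seq_len(nrow(sc)), function(i) {
    ord <- order(-sc[i, ], model$classes)
    data.table(sample_id = rownames(sc)[i],
               rank = seq_along(ord),
               tissue = model$classes[ord],
               score = unname(sc[i, ord]),
               top_k = seq_along(ord) <= k)
  }))
  out[]
}

#' Serialize / restore an origin model as JSON
#'
#' @param model an `origin_model`
#' @param path JSON file
#' @return `path` invisibly / the restored `origin_model`
#' @export
write_origin_model <- function(model, path) {
  stopifnot(inherits(model, "origin_model"))
  jsonlite::write_json(
    list(features = model$features, classes = model$classes,
         weights = as.data.frame(model$weights),
         intercepts = as.list(model$intercepts),
         feature_tissue = model$feature_tissue, cost = model$cost),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_origin_model
#' @export
read_origin_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- as.matrix(j$weights)
  rownames(w) <- j$features
  structure(list(features = j$features, classes = j$classes,
                 weights = w,
                 intercepts = unlist(j$intercepts),
                 feature_tissue = j$feature_tissue, cost = j$cost),
            class = "origin_model")
}
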