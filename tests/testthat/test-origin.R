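## Small deterministic expression fixtures for the classifier tests:
## two tissues with disjoint active features.
toy_norm <- function(noise = 0, seed = 1) {
  set.seed(seed)
  ids <- sprintf("f%02d", 1:10)
  samples <- c(paste0("a_s", 1:3), paste0("b_s", 1:3))
  x <- matrix(1, 10, 6, dimnames = list(ids, samples))
  x[1:5, 1:3] <- 8     # features 1-5 mark tissue a
  x[6:10, 4:6] <- 8    # features 6-10 mark tissue b
  x <- x + matrix(rnorm(60, 0, noise), 10, 6)
  structure(list(log2 = x, norm = 2^x - 1, size_factors = rep(1, 6)),
            class = "procap_norm")
}

toy_design <- data.table(sample_id = c(paste0("a_s", 1:3),
                                       paste0("b_s", 1:3)),
                         tissue = rep(c("a", "b"), each = 3))

test_that("identical samples merge first in the dendrogram", {
  x <- matrix(c(1, 2, 3, 4,
                1, 2, 3, 4,
                4, 3, 2, 1), 4, 3,
              dimnames = list(paste0("e", 1:4), c("s1", "s2", "s3")))
  nm <- structure(list(log2 = x, norm = x, size_factors = rep(1, 3)),
                  class = "procap_norm")
  hc <- hier_cluster(nm)
  ## first merge joins the two identical samples at height ~0
  expect_equal(sort(-hc$merge[1, ]), c(1, 2))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)

  xc <- x; xc[, 2] <- 5
  nmc <- structure(list(log2 = xc, norm = xc,
                        size_factors = rep(1, 3)),
                   class = "procap_norm")
  expect_error(hier_cluster(nmc), "s2")
})

test_that("clustering recovers a planted two-tissue partition", {
  sim <- simulate_dataset(truth_config(
    tissues = c(liver = 3L, brain = 3L), frac_specific = 0.4,
    fold_change = 8, seed = 55))
  cm <- build_count_matrix(lapply(sim$tracks, `[[`, "five_prime"),
                           sim$elements)
  nm <- normalize_counts(cm)
  hc <- hier_cluster(nm)
  grp <- cutree(hc, k = 2)
  tis <- sim$design$tissue[match(names(grp), sim$design$sample_id)]
  expect_equal(length(unique(grp[tis == "liver"])), 1L)
  expect_equal(length(unique(grp[tis == "brain"])), 1L)
  expect_false(grp[tis == "liver"][1] == grp[tis == "brain"][1])
})

test_that("PC truncation keeps the fewest components reaching the target", {
  ## one dominant direction: m = 1
  set.seed(4)
  base <- rnorm(30)
  x <- sapply(seq(0, 4.5, length.out = 10), function(k) base * (1 + k))
  x <- x + matrix(rnorm(300, 0, 1e-3), 30, 10)
  rownames(x) <- paste0("e", 1:30)
  colnames(x) <- c("tum1", paste0("n", 1:9))
  nm <- structure(list(log2 = x, norm = x, size_factors = rep(1, 10)),
                  class = "procap_norm")
  res <- pc_correlations(
    nm,
    tumor_info = data.table(sample_id = "tum1", primary = "a",
                            metastatic_site = "b"),
    normal_design = data.table(sample_id = paste0("n", 1:9),
                               tissue = rep(c("a", "b", "c"), 3)))
  expect_equal(res$n_components, 1L)
  expect_equal(nrow(res$pairwise), 9L)
  expect_true(all(c("primary_site", "metastatic_site", "other") %in%
                    res$pairwise$group))
})

test_that("a tumour identical to a normal correlates perfectly with it", {
  set.seed(12)
  x <- matrix(rnorm(200), 20, 10)
  x[, 10] <- x[, 1]   # tumour duplicates normal n1
  rownames(x) <- paste0("e", 1:20)
  colnames(x) <- c(paste0("n", 1:9), "tum1")
  nm <- structure(list(log2 = x, norm = x, size_factors = rep(1, 10)),
                  class = "procap_norm")
  res <- pc_correlations(
    nm, data.table(sample_id = "tum1", primary = "a",
                   metastatic_site = "b"),
    data.table(sample_id = paste0("n", 1:9),
               tissue = rep(c("a", "b", "c"), each = 3)),
    variance_target = 0.99)
  r_n1 <- res$pairwise[normal == "n1"]$r
  expect_equal(r_n1, 1, tolerance = 1e-8)
})

test_that("tumour mixtures rank primary > metastatic site > other", {
  ok <- 0
  for (seed in 1:20) {
    oc <- simulate_origin_cohort(n_tissues = 6, n_train = 24,
                                 n_queries = 4, seed = seed)
    norm_all <- normalize_counts(cbind(oc$counts, oc$query_counts))
    res <- pc_correlations(
      norm_all,
      data.table(sample_id = oc$query_truth$sample_id,
                 primary = oc$query_truth$primary,
                 metastatic_site = oc$query_truth$destination),
      oc$design)
    s <- res$summary
    good <- mean(s$primary_site) > mean(s$metastatic_site) &&
      mean(s$metastatic_site) > mean(s$other)
    ok <- ok + good
  }
  expect_gte(ok, 18)
})

test_that("separable toy problem is learned perfectly", {
  nm <- toy_norm()
  sets <- list(a = sprintf("f%02d", 1:5), b = sprintf("f%02d", 6:10))
  model <- train_origin_model(nm, toy_design, sets)
  expect_setequal(model$features, sprintf("f%02d", 1:10))
  pred <- predict_topk(model, nm$log2, k = 1)
  top1 <- pred[rank == 1]
  expect_equal(top1$tissue,
               toy_design$tissue[match(top1$sample_id,
                                       toy_design$sample_id)])
  ## query at a training centroid
  centroid <- rowMeans(nm$log2[, 1:3, drop = FALSE])
  q <- matrix(centroid, ncol = 1,
              dimnames = list(names(centroid), "query"))
  expect_equal(predict_topk(model, q, k = 1)[rank == 1]$tissue, "a")
})

test_that("shared features are excluded and emptied tissues are an error", {
  nm <- toy_norm()
  sets <- list(a = sprintf("f%02d", 1:5),
               b = c(sprintf("f%02d", 5:10)))   # f05 shared
  model <- train_origin_model(nm, toy_design, sets)
  expect_false("f05" %in% model$features)
  sets_bad <- list(a = "f01", b = c("f01", "f06"))
  expect_error(train_origin_model(nm, toy_design, sets_bad), "a")
})

test_that("prediction ranking, ties, k bounds and missing features", {
  nm <- toy_norm()
  sets <- list(a = sprintf("f%02d", 1:5), b = sprintf("f%02d", 6:10))
  model <- train_origin_model(nm, toy_design, sets)
  expect_error(predict_topk(model, nm$log2, k = 3), "exceeds")
  ## k = number of classes always contains the truth
  pred <- predict_topk(model, nm$log2, k = 2)
  expect_true(all(tapply(pred$top_k, pred$sample_id, sum) == 2))
  ## missing feature rows are zero-imputed with a warning
  q <- nm$log2[1:8, , drop = FALSE]
  expect_warning(p2 <- predict_topk(model, q, k = 1), "imputed")
  expect_equal(nrow(p2), 12L)
})

test_that("ranking is invariant to tissue label order at train time", {
  nm <- toy_norm(noise = 0.1, seed = 3)
  sets <- list(a = sprintf("f%02d", 1:5), b = sprintf("f%02d", 6:10))
  m1 <- train_origin_model(nm, toy_design, sets)
  m2 <- train_origin_model(nm, toy_design[c(4:6, 1:3)], rev(sets))
  p1 <- predict_topk(m1, nm$log2, k = 1)
  p2 <- predict_topk(m2, nm$log2, k = 1)
  expect_equal(p1[rank == 1, .(sample_id, tissue)],
               p2[rank == 1, .(sample_id, tissue)])
})

test_that("origin model survives a JSON round trip", {
  nm <- toy_norm(noise = 0.05, seed = 6)
  sets <- list(a = sprintf("f%02d", 1:5), b = sprintf("f%02d", 6:10))
  model <- train_origin_model(nm, toy_design, sets)
  path <- withr::local_tempfile(fileext = ".json")
  write_origin_model(model, path)
  back <- read_origin_model(path)
  expect_equal(back$weights, model$weights, tolerance = 1e-12)
  expect_equal(back$intercepts, model$intercepts, tolerance = 1e-12)
  expect_equal(predict_topk(back, nm$log2, k = 1),
               predict_topk(model, nm$log2, k = 1))
})

test_that("metastatic-like queries are traced to their primary site", {
  top1 <- top3 <- numeric(20)
  for (seed in 1:20) {
    oc <- simulate_origin_cohort(seed = 700 + seed)
    nm <- normalize_counts(oc$counts)
    model <- train_origin_model(nm, oc$design, oc$truth_sets)
    qn <- normalize_against(oc$query_counts, oc$counts)
    pred <- predict_topk(model, qn$log2, k = 3)
    truth <- oc$query_truth
    t1 <- pred[rank == 1]
    top1[seed] <- mean(t1$tissue ==
                         truth$primary[match(t1$sample_id,
                                             truth$sample_id)])
    in3 <- pred[top_k == TRUE,
                .(hit = truth$primary[match(sample_id[1],
                                            truth$sample_id)] %in%
                    tissue), by = sample_id]
    top3[seed] <- mean(in3$hit)
  }
  expect_gte(mean(top1), 0.90)
  expect_gte(mean(top3), 0.95)
})

test_that("accuracy does not increase with generator noise", {
  acc_at <- function(size) {
    mean(vapply(1:10, function(s) {
      oc <- simulate_origin_cohort(nb_dispersion = size, seed = 40 + s)
      nm <- normalize_counts(oc$counts)
      model <- train_origin_model(nm, oc$design, oc$truth_sets)
      qn <- normalize_against(oc$query_counts, oc$counts)
      t1 <- predict_topk(model, qn$log2, k = 1)[rank == 1]
      mean(t1$tissue ==
             oc$query_truth$primary[match(t1$sample_id,
                                          oc$query_truth$sample_id)])
    }, numeric(1)))
  }
  accs <- c(acc_at(10), acc_at(2), acc_at(0.8))
  expect_true(all(diff(accs) <= 1e-9))
  expect_lt(accs[3], accs[1])  # heavy noise must actually hurt
})
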