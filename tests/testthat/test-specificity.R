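## Build a procap_norm directly from a normalized-count matrix
## (size factors 1) so score arithmetic can be checked exactly.
norm_from_matrix <- function(x) {
  normalize_counts(as.matrix(x), s = rep(1, ncol(x)))
}

design4 <- data.table(sample_id = paste0("s", 1:4),
                      tissue = c("a", "b", "c", "d"))

test_that("specificity score hits its theoretical limits exactly", {
  ## uniform across 4 tissues -> H = 2 bits, S = 0
  m <- matrix(5, 1, 4, dimnames = list("e1", paste0("s", 1:4)))
  sc <- specificity_scores(norm_from_matrix(m), design4)
  expect_equal(sc$H, 2)
  expect_equal(sc$S, 0)

  ## single tissue -> H = 0, S = 1
  m2 <- matrix(c(9, 0, 0, 0), 1, 4,
               dimnames = list("e1", paste0("s", 1:4)))
  sc2 <- specificity_scores(norm_from_matrix(m2), design4)
  expect_equal(sc2$H, 0)
  expect_equal(sc2$S, 1)

  ## equal expression in 2 of 4 tissues -> H = 1, S = 0.5
  m3 <- matrix(c(4, 4, 0, 0), 1, 4,
               dimnames = list("e1", paste0("s", 1:4)))
  sc3 <- specificity_scores(norm_from_matrix(m3), design4)
  expect_equal(sc3$H, 1)
  expect_equal(sc3$S, 0.5)

  ## zero-expression elements are flagged undefined
  m4 <- rbind(e1 = rep(2, 4), e2 = rep(0, 4))
  colnames(m4) <- paste0("s", 1:4)
  sc4 <- specificity_scores(norm_from_matrix(m4), design4)
  expect_equal(sc4$defined, c(TRUE, FALSE))
  expect_true(is.na(sc4$S[2]))
})

test_that("scores are invariant to global rescaling of expression", {
  set.seed(8)
  m <- matrix(rpois(40, 20), 10, 4,
              dimnames = list(paste0("e", 1:10), paste0("s", 1:4)))
  a <- specificity_scores(norm_from_matrix(m), design4)
  b <- specificity_scores(norm_from_matrix(m * 7), design4)
  expect_equal(a$S, b$S)
  expect_equal(a$H, b$H)
})

test_that("probabilities sum to one and tissue means average samples", {
  design <- data.table(sample_id = paste0("s", 1:6),
                       tissue = rep(c("a", "b", "c"), each = 2))
  m <- matrix(c(2, 4, 0, 0, 1, 3), 1, 6,
              dimnames = list("e1", paste0("s", 1:6)))
  sc <- specificity_scores(norm_from_matrix(m), design)
  expect_equal(sc$q_a, 3)
  expect_equal(sc$q_b, 0)
  expect_equal(sc$q_c, 2)
  p <- c(3, 0, 2) / 5
  expect_equal(sc$H, -sum(p[p > 0] * log2(p[p > 0])))
})

test_that("membership t-statistic equals the two-sample t and lm", {
  set.seed(99)
  design <- data.table(sample_id = paste0("s", 1:8),
                       tissue = rep(c("x", "y"), each = 4))
  for (rep in 1:25) {
    y <- matrix(rnorm(5 * 8), 5, 8,
                dimnames = list(paste0("e", 1:5), paste0("s", 1:8)))
    nm <- structure(list(log2 = y, norm = 2^y - 1,
                         size_factors = rep(1, 8)),
                    class = "procap_norm")
    t_pkg <- tissue_t_statistics(nm, design, "x")
    for (e in rownames(y)) {
      tt <- t.test(y[e, 1:4], y[e, 5:8], var.equal = TRUE)
      expect_equal(unname(t_pkg[e]), unname(tt$statistic),
                   tolerance = 1e-8)
      ## independent normal-equations oracle for the OLS fit
      X <- cbind(1, ifelse(design$tissue == "x", 1, -1))
      bhat <- solve(t(X) %*% X, t(X) %*% y[e, ])
      res <- y[e, ] - X %*% bhat
      se <- sqrt(drop(crossprod(res)) / 6 * solve(t(X) %*% X)[2, 2])
      expect_equal(unname(t_pkg[e]), drop(bhat[2] / se),
                   tolerance = 1e-10)
    }
  }
})

test_that("t-statistic edge cases: equal means and zero variance", {
  design <- data.table(sample_id = paste0("s", 1:6),
                       tissue = rep(c("x", "y"), each = 3))
  y <- rbind(e1 = c(1, 2, 3, 1, 2, 3),   # equal group means -> t = 0
             e2 = c(5, 5, 5, 2, 2, 2),   # zero residual variance -> Inf
             e3 = c(2, 2, 2, 2, 2, 2))   # no signal at all -> 0
  colnames(y) <- design$sample_id
  nm <- structure(list(log2 = y, norm = 2^y - 1,
                       size_factors = rep(1, 6)),
                  class = "procap_norm")
  t <- tissue_t_statistics(nm, design, "x")
  expect_equal(unname(t["e1"]), 0)
  expect_equal(unname(t["e2"]), Inf)
  expect_equal(unname(t["e3"]), 0)
  expect_error(tissue_t_statistics(nm, design, "x", min_samples = 4),
               "need >= 4")
})

test_that("set selection applies the top-fraction and exclusion rules", {
  n <- 100
  ids <- sprintf("e%03d", 1:n)
  scores <- data.table(element_id = ids, H = 1,
                       S = seq(0, 0.99, length.out = n), defined = TRUE)
  prox <- setNames(rep(c("distal", "proximal"), length.out = n), ids)
  t1 <- setNames(as.numeric(1:n), ids)        # liver: top ids at the end
  t2 <- setNames(as.numeric(n:1), ids)        # brain: top ids at the start
  sets <- select_sets(list(liver = t1, brain = t2), scores, prox)
  expect_length(sets$specific$liver, 5L)      # ceiling(0.05 * 100)
  expect_equal(sets$specific$liver, rev(ids)[1:5])
  expect_equal(sets$specific$brain, ids[1:5])

  ## non-specific: distal S < 0.1, proximal S < 0.02, minus specific sets
  expected <- ids[(scores$S < 0.1 & prox == "distal") |
                    (scores$S < 0.02 & prox == "proximal")]
  expected <- setdiff(expected, c(ids[1:5], rev(ids)[1:5]))
  expect_equal(sets$non_specific, sort(expected))

  ## an element in a specific set is excluded even with a low score
  expect_false(ids[1] %in% sets$non_specific)
  expect_true(ids[1] %in% sets$specific$brain)
})

test_that("tie at the top-fraction boundary is broken by element id", {
  ids <- sprintf("e%02d", 1:40)
  scores <- data.table(element_id = ids, H = 1, S = 0.5, defined = TRUE)
  tvals <- setNames(rep(1, 40), ids)
  sets <- select_sets(list(liver = tvals), scores,
                      setNames(rep("distal", 40), ids))
  expect_equal(sets$specific$liver, ids[1:2])  # ceiling(2), lexicographic
})

test_that("planted single-tissue elements are found by the pipeline", {
  cfg <- truth_config(n_chroms = 3, chrom_length = 2e6,
                      n_elements = 200, n_genes = 30,
                      frac_proximal = 0.1,
                      tissues = c(t1 = 3L, t2 = 3L, t3 = 3L, t4 = 3L,
                                  t5 = 3L, t6 = 3L, t7 = 3L, t8 = 3L),
                      frac_specific = 0.08, fold_change = 8,
                      baseline_mean = 100, seed = 404)
  sim <- simulate_dataset(cfg)
  cm <- build_count_matrix(lapply(sim$tracks, `[[`, "five_prime"),
                           sim$elements)
  nm <- normalize_counts(cm)
  scores <- specificity_scores(nm, sim$design)
  t_by <- lapply(setNames(nm = names(cfg$tissues)), function(t)
    tissue_t_statistics(nm, sim$design, t))
  sets <- select_sets(t_by, scores,
                      setNames(sim$elements$proximity,
                               sim$elements$element_id))
  truth <- sim$elements[!is.na(specific_tissue)]
  hit <- vapply(seq_len(nrow(truth)), function(i)
    truth$element_id[i] %in% sets$specific[[truth$specific_tissue[i]]],
    logical(1))
  s_of_truth <- scores$S[match(truth$element_id, scores$element_id)]
  expect_gte(mean(hit & s_of_truth >= 0.5), 0.9)
})
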