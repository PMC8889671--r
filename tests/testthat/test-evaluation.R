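triple <- function(labels) {
  x <- matrix(1, nrow = 3, ncol = 2)  # identical feature vectors
  noise_ceiling(x, labels)
}

test_that("the noise ceiling enumerates replicate pairs exactly", {
  agree <- triple(c(0, 0, 0))
  expect_equal(agree$conflicting_pairs, 0L)
  expect_equal(agree$total_pairs, 3L)
  expect_equal(agree$max_nn, 1)

  mixed <- triple(c(0, 0, 1))
  expect_equal(mixed$conflicting_pairs, 2L)
  expect_equal(mixed$max_nn, 1 / 3)

  alldiff <- triple(c(0, 1, 2))
  expect_equal(alldiff$max_nn, 0)

  # no duplicated feature vectors: ceiling 1 by convention, flagged
  x <- matrix(1:8, nrow = 4)
  unique_rows <- noise_ceiling(x, c(0, 1, 2, 3))
  expect_equal(unique_rows$max_nn, 1)
  expect_true(unique_rows$flagged)
})

test_that("the noise ceiling is invariant to row permutation and grouping", {
  dat <- planted_dataset(seed = 61, noise_sd = 0.08)
  a <- noise_ceiling(dat$features, dat$labels)
  perm <- sample(nrow(dat$features))
  b <- noise_ceiling(dat$features[perm, ], dat$labels[perm])
  expect_equal(a$max_nn, b$max_nn)
  expect_equal(a$conflicting_pairs, b$conflicting_pairs)
  # explicit guide-ID grouping coincides with exact feature equality
  c <- noise_ceiling(dat$features, dat$labels,
                     group = dat$observations$guide_id)
  expect_equal(a$max_nn, c$max_nn)
  expect_true(a$max_nn >= 0 && a$max_nn <= 1)
})

test_that("noise-normalized accuracy reduces to raw accuracy when clean", {
  dat <- planted_dataset(seed = 63, noise_sd = 0)
  cv <- cross_validate(dat$features, dat$labels,
                       list(features = colnames(dat$features)),
                       repeats = 5, seed = 2)
  expect_equal(cv$max_nn, 1)
  expect_equal(cv$noise_normalized_accuracy, cv$raw_accuracy)
})

test_that("cross-validation is deterministic and scheme-checked", {
  dat <- planted_dataset(seed = 65, noise_sd = 0.05)
  spec <- list(features = colnames(dat$features))
  a <- cross_validate(dat$features, dat$labels, spec, repeats = 4,
                      seed = 9)
  b <- cross_validate(dat$features, dat$labels, spec, repeats = 4,
                      seed = 9)
  expect_identical(a$per_fold, b$per_fold)
  expect_identical(a$per_class_auc, b$per_class_auc)
  expect_gte(a$noise_normalized_accuracy, a$raw_accuracy)

  three <- cross_validate(dat$features, dat$labels, spec,
                          scheme = "threefold_replicate",
                          replicate_id = dat$replicate_id, seed = 9)
  expect_equal(three$repeats, 3L)
  expect_length(three$per_fold, 3L)
  expect_error(
    cross_validate(dat$features, dat$labels, spec,
                   scheme = "threefold_replicate",
                   replicate_id = rep(1:2, length.out = nrow(dat$features))),
    "exactly 3")
  expect_error(
    cross_validate(dat$features, dat$labels, spec,
                   scheme = "threefold_replicate"),
    "replicate_id")
})

test_that("hyperparameter sweeps record the averaged best parameter", {
  dat <- planted_dataset(seed = 67, noise_sd = 0.05)
  cv <- cross_validate(dat$features, dat$labels,
                       list(architecture = "knn",
                            features = colnames(dat$features)),
                       repeats = 3, seed = 4, sweep = list(k = c(1, 3, 5)))
  expect_named(cv$best_hyperparameters, "k")
  expect_true(cv$best_hyperparameters$k >= 1 &&
                cv$best_hyperparameters$k <= 5)
})

test_that("one-vs-all AUC matches brute-force concordance counting", {
  # perfect separation
  scores <- diag(4)[c(1, 2, 3, 4, 1, 2), ]
  colnames(scores) <- 0:3
  auc <- roc_one_vs_all(scores, c(0, 1, 2, 3, 0, 1))
  expect_equal(unname(auc[c("0", "1")]), c(1, 1))

  set.seed(71)
  for (i in 1:100) {
    n <- sample(10:20, 1)
    labels <- sample(0:3, n, replace = TRUE)
    scores <- matrix(runif(4 * n), n, 4, dimnames = list(NULL, 0:3))
    mine <- roc_one_vs_all(scores, labels)
    for (cl in as.character(0:3)) {
      pos <- labels == as.integer(cl)
      if (!any(pos) || all(pos)) {
        expect_true(is.na(mine[cl]))
      } else {
        expect_equal(unname(mine[cl]), brute_auc(scores[, cl], pos),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("AUC agrees with pROC on a larger instance", {
  skip_if_not_installed("pROC")
  set.seed(72)
  labels <- sample(0:3, 120, replace = TRUE)
  scores <- matrix(runif(480), 120, 4, dimnames = list(NULL, 0:3))
  scores[cbind(1:120, labels + 1)] <-
    scores[cbind(1:120, labels + 1)] + runif(120)
  mine <- roc_one_vs_all(scores, labels)
  for (cl in 0:3) {
    ref <- suppressMessages(
      pROC::auc(as.integer(labels == cl), scores[, cl + 1]))
    expect_equal(unname(mine[as.character(cl)]), as.numeric(ref),
                 tolerance = 1e-10)
  }
})

test_that("roc_points trace a monotone curve from (0,0) to (1,1)", {
  set.seed(73)
  labels <- sample(0:3, 40, replace = TRUE)
  scores <- matrix(runif(160), 40, 4, dimnames = list(NULL, 0:3))
  pts <- roc_points(scores, labels, "2")
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("the benchmark grid is complete and reproducible", {
  dat <- planted_dataset(seed = 75, noise_sd = 0.05, n_transcripts = 2,
                         length_range = c(100, 140))
  keep <- c(grep("\\|8$", colnames(dat$features), value = TRUE),
            "relpos", "comp|A", "comp|G")
  x <- dat$features[, keep]
  lists <- list(pval = keep, z2 = keep[1:6], z3 = keep[1:4],
                gini = keep, gini_dt = character(0))
  grid <- benchmark_grid(x, dat$labels, lists,
                         replicate_id = dat$replicate_id, repeats = 2,
                         seed = 3,
                         sweeps = list(knn = list(k = c(3, 5)),
                                       random_forest = list(
                                         ntree = c(20, 50))))
  expect_equal(nrow(grid), 7 * 5 * 2)
  filled <- grid[grid$feature_list != "gini_dt", ]
  expect_false(anyNA(filled$accuracy))
  expect_true(all(is.na(grid$accuracy[grid$feature_list == "gini_dt"])))
  expect_true(all(!is.na(grid$best_param[
    grid$architecture %in% c("knn", "random_forest") &
      grid$feature_list != "gini_dt"])))

  grid2 <- benchmark_grid(x, dat$labels, lists,
                          replicate_id = dat$replicate_id, repeats = 2,
                          seed = 3,
                          sweeps = list(knn = list(k = c(3, 5)),
                                        random_forest = list(
                                          ntree = c(20, 50))))
  expect_identical(grid, grid2)

  path <- withr::local_tempfile(fileext = ".txt")
  write_benchmark_grid(grid, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^# ", lines)), 2L)  # one block per scheme
  expect_equal(sum(!grepl("^#", lines) & !grepl("^architecture", lines)),
               14L)
})

test_that("ablation attributes accuracy to the planted feature", {
  set.seed(81)
  n <- 240
  signal <- rbinom(n, 1, 0.5)
  x <- cbind(planted = signal, copy = signal,
             matrix(rbinom(n * 4, 1, 0.5), n,
                    dimnames = list(NULL, paste0("noise", 1:4))))
  y <- ifelse(signal == 1, 0, 2)
  abl <- feature_ablation(x, y,
                          list(architecture = "decision_tree",
                               features = colnames(x)),
                          repeats = 10, seed = 5)
  expect_equal(abl$runs_executed, 10 * (1 + ncol(x)))
  # redundant copies compensate for each other
  expect_lt(abs(abl$per_feature_delta["planted"]), 0.05)
  expect_lt(abs(abl$per_feature_delta["copy"]), 0.05)

  x2 <- x[, -2]  # drop the redundant copy: now the signal is unique
  abl2 <- feature_ablation(x2, y,
                           list(architecture = "decision_tree",
                                features = colnames(x2)),
                           repeats = 10, seed = 5)
  expect_equal(names(which.max(abl2$per_feature_delta)), "planted")
  expect_gt(max(abl2$per_feature_delta), 0.2)
  expect_error(feature_ablation(x, y, list(features = "planted")),
               "2 features")
})
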