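make_indicator_matrix <- function(bases, position = 8, k = 1) {
  space <- default_feature_space(1, extras = character(0))
  m <- matrix(0, length(bases), nrow(space),
              dimnames = list(NULL, space$name))
  m[cbind(seq_along(bases),
          match(paste("kmer", 1, bases, position, sep = "|"),
                space$name))] <- 1
  m
}

test_that("chi-squared representation test matches hand computation", {
  # perfectly uniform: 16 of each base at position 8 -> statistic 0, p 1
  uni <- make_indicator_matrix(rep(c("A", "C", "G", "T"), each = 16))
  res <- kmer_representation_test(uni, 1, 8)
  expect_equal(res$statistic, rep(0, 4))
  expect_equal(res$p_value, rep(1, 4))

  # 64 guides all A: O = (64,0,0,0), E = 16 each -> statistic 192
  allA <- make_indicator_matrix(rep("A", 64))
  res2 <- kmer_representation_test(allA, 1, 8)
  expect_equal(unique(res2$statistic), 192)
  expect_equal(res2$direction, c("over", "under", "under", "under"))
  expect_equal(res2$expected, rep(16, 4))

  expect_error(kmer_representation_test(allA, 1, 28), "out of range")
})

test_that("chi-squared statistic agrees with stats::chisq.test", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(40:200, 1)
    bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                    prob = runif(4, 0.1, 1))
    m <- make_indicator_matrix(bases)
    mine <- kmer_representation_test(m, 1, 8)
    counts <- colSums(m[, paste("kmer", 1, c("A", "C", "G", "T"), 8,
                                sep = "|")])
    ref <- suppressWarnings(chisq.test(counts, p = rep(0.25, 4)))
    expect_equal(unique(mine$statistic), unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(unique(mine$p_value), ref$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis wrapper matches the rank-sum formula", {
  # textbook two-group case, no ties
  kw <- positional_kruskal_wallis(c(1, 2, 3, 10, 11, 12),
                                  rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  expect_equal(kw$H, manual_kruskal_H(c(1, 2, 3, 10, 11, 12),
                                      rep(c("a", "b"), each = 3)),
               tolerance = 1e-12)

  # all-tied data: H = 0 by convention
  flat <- positional_kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), 3))
  expect_equal(flat$H, 0)
  expect_equal(flat$p_value, 1)

  # single group is flagged not-applicable
  single <- positional_kruskal_wallis(1:5, rep("a", 5))
  expect_false(single$applicable)

  set.seed(88)
  for (i in 1:100) {
    n <- sample(12:60, 1)
    vals <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    grp <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    if (length(unique(grp)) < 2 || length(unique(vals)) < 2) next
    kw <- positional_kruskal_wallis(vals, grp)
    expect_equal(kw$H, manual_kruskal_H(vals, grp), tolerance = 1e-10)
  }
})

test_that("the position scan flags positions whose nucleotide drives
           expression", {
  dat <- planted_dataset(seed = 27, noise_sd = 0.02)
  spacers <- dat$guides$spacer[match(dat$observations$guide_id,
                                     dat$guides$guide_id)]
  scan <- kw_position_scan(spacers, dat$expression)
  expect_equal(nrow(scan), 28L)
  expect_true(scan$flagged[scan$position == 8])
  # the planted position carries by far the strongest H statistic
  expect_equal(scan$position[which.max(scan$H)], 8)
})

test_that("univariate regression p-values match lm on random data", {
  set.seed(99)
  n <- 40
  for (i in 1:50) {
    x <- matrix(runif(n), ncol = 1, dimnames = list(NULL, "f"))
    y <- pmin(pmax(0.5 + 0.3 * x[, 1] * rbinom(1, 1, 0.5) +
                     rnorm(n, 0, 0.2), 0), 1)
    mine <- univariate_significance(x, y)
    ref <- summary(lm(y ~ x[, 1]))$coefficients[2, 4]
    expect_equal(unname(mine), ref, tolerance = 1e-8)
  }
})

test_that("univariate significance handles degenerate features", {
  x <- cbind(same = rep(0.3, 10), copy = seq(0, 1, length.out = 10))
  y <- x[, "copy"]
  p <- univariate_significance(x, y)
  expect_equal(unname(p["same"]), 1)
  expect_equal(unname(p["copy"]), .Machine$double.xmin)
  expect_error(univariate_significance(x[1:2, ], y[1:2]), "3 rows")
  expect_error(univariate_significance(x, y + 5), "\\[0, 1\\]")
})

test_that("p-value selection is strict and ordered", {
  sel <- select_by_pvalue(c(f1 = 0.01, f2 = 0.5))
  expect_equal(sel$selected, "f1")
  expect_warning(empty <- select_by_pvalue(c(a = 1, b = 1)), "no features")
  expect_equal(empty$selected, character(0))
  boundary <- select_by_pvalue(c(edge = 0.05, in_ = 0.049))
  expect_equal(boundary$selected, "in_")
  ordered <- select_by_pvalue(c(b = 0.02, a = 0.02, c = 0.001))
  expect_equal(ordered$selected, c("c", "a", "b"))
})

test_that("Z-score selection finds outliers and nests by cutoff", {
  set.seed(12)
  p <- c(setNames(runif(99, 0.4, 0.6), paste0("null", 1:99)),
         hit = 1e-20)
  z3 <- select_by_zscore(p, 3)
  expect_equal(z3$selected, "hit")
  z2 <- select_by_zscore(p, 2)
  expect_true(all(z3$selected %in% z2$selected))
  expect_warning(flat <- select_by_zscore(c(a = 0.5, b = 0.5), 2), "zero")
  expect_equal(flat$selected, character(0))

  # near-uniform p-values yield at most a tail of false outliers
  set.seed(13)
  u <- setNames(runif(200), paste0("f", 1:200))
  expect_lt(length(select_by_zscore(u, 3)$selected), 10)
})

test_that("Gini selection recovers a planted determining feature", {
  set.seed(14)
  bases <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  m <- make_indicator_matrix(bases)
  # add noise columns so the signal has competition
  noise <- matrix(rbinom(200 * 20, 1, 0.5), 200,
                  dimnames = list(NULL, paste0("noise", 1:20)))
  m <- cbind(m, noise)
  cls <- c(A = 0, C = 1, G = 2, T = 3)[bases]
  for (learner in c("decision_tree", "random_forest")) {
    sel <- select_by_gini(m, cls, learner, top_n = 5, seed = 3)
    expect_true(grepl("\\|8$", sel$selected[1]),
                info = paste(learner, "top:", sel$selected[1]))
    expect_equal(sum(sel$scores), 1, tolerance = 1e-10)
    expect_true(all(sel$scores >= 0))
    again <- select_by_gini(m, cls, learner, top_n = 5, seed = 3)
    expect_identical(sel$selected, again$selected)
  }
  expect_error(select_by_gini(m, rep(0, 200), "decision_tree"),
               "2 classes")
})

test_that("the ladder nests pval over z2 over z3 and exports cleanly", {
  dat <- planted_dataset(seed = 19)
  ladder <- selection_ladder(dat$features, dat$expression, dat$labels,
                             top_n = 10, seed = 2)
  expect_named(ladder, c("pval", "z2", "z3", "gini_dt", "gini_rf"))
  expect_true(all(ladder$z2$selected %in% ladder$pval$selected))
  expect_true(all(ladder$z3$selected %in% ladder$z2$selected))

  path <- withr::local_tempfile(fileext = ".txt")
  write_selection(ladder$pval, path)
  out <- read.delim(path)
  expect_equal(names(out), c("kmer", "position", "p_value"))
  expect_equal(nrow(out), length(ladder$pval$selected))
  expect_true(all(out$p_value < 0.05))
})

test_that("zero-variance features are never selected by any rung", {
  dat <- planted_dataset(seed = 23)
  x <- cbind(dat$features, dead = 0)
  ladder <- selection_ladder(x, dat$expression, dat$labels, top_n = 10,
                             seed = 2)
  for (m in names(ladder)) {
    expect_false("dead" %in% ladder[[m]]$selected, info = m)
  }
})
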