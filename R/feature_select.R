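#' Chi-squared k-mer representation test at one spacer position
#'
#' Tests whether the k-mers observed at a given 0-based position across a
#' set of guides deviate from the null of uniform k-mer frequency
#' (`1/4^k` each). The statistic is the omnibus `sum((O - E)^2 / E)` over
#' the `4^k` siblings with `4^k - 1` degrees of freedom; each k-mer is
#' additionally annotated as over- or under-represented by the sign of
#' `O - E`. An optional background null uses the global k-mer frequency
#' across all positions instead of the uniform one.
#'
#' @param features Feature matrix containing the positional indicators for
#'   `(k, position)` (columns `kmer|k|KMER|position`).
#' @param k K-mer size in `1:3`.
#' @param position 0-based position in `[0, 28 - k]`.
#' @param null `"uniform"` (default) or `"background"`.
#' @return Data frame with one row per k-mer: `kmer`, `observed`,
#'   `expected`, `statistic`, `p_value` (statistic and p shared across the
#'   position), `direction` (`"over"`/`"under"`).
#' @export
kmer_representation_test <- function(features, k, position,
                                     null = c("uniform", "background")) {
  null <- match.arg(null)
  if (position < 0L || position > SPACER_LEN - k) {
    stop("position ", position, " out of range for k = ", k)
  }
  kmers <- all_kmers(k)
  cols <- paste("kmer", k, kmers, position, sep = "|")
  missing <- setdiff(cols, colnames(features))
  if (length(missing)) {
    stop("feature matrix lacks positional indicators: ",
         paste(utils::head(missing, 4L), collapse = ", "))
  }
  observed <- colSums(features[, cols, drop = FALSE])
  n <- nrow(features)
  if (null == "uniform") {
    expected <- rep(n / length(kmers), length(kmers))
  } else {
    all_cols <- grep(paste0("^kmer\\|", k, "\\|"), colnames(features),
                     value = TRUE)
    kmer_of <- vapply(strsplit(all_cols, "|", fixed = TRUE), `[`,
                      character(1), 3L)
    totals <- tapply(colSums(features[, all_cols, drop = FALSE]), kmer_of,
                     sum)[kmers]
    expected <- n * as.numeric(totals) / sum(totals)
  }
  if (any(expected < 5)) {
    warning("expected count below 5 at (k = ", k, ", position = ", position,
            "); chi-squared approximation may be poor")
  }
  statistic <- sum((observed - expected)^2 / expected)
  p_value <- stats::pchisq(statistic, df = length(kmers) - 1L,
                           lower.tail = FALSE)
  data.frame(
    kmer = kmers,
    observed = as.numeric(observed),
    expected = expected,
    statistic = statistic,
    p_value = p_value,
    direction = ifelse(observed > expected, "over", "under"),
    stringsAsFactors = FALSE
  )
}

#' Kruskal-Wallis test of expression by group
#'
#' Rank-based H test (with the standard tie correction) of whether
#' normalized expression differs between guide groups, typically guides
#' partitioned by the nucleotide they carry at one spacer position. Used
#' as a reported diagnostic alongside the representation test, not as a
#' filter. Degenerate inputs are handled by convention: a single nonempty
#' group is flagged not-applicable, and all-tied data yields `H = 0`
#' (constancy carries no signal) rather than the undefined 0/0.
#'
#' @param expressions Numeric vector of normalized expression values.
#' @param groups Vector (coerced to factor) of group membership.
#' @return List with `H`, `p_value`, `df`, `applicable`.
#' @export
positional_kruskal_wallis <- function(expressions, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) {
    return(list(H = NA_real_, p_value = NA_real_, df = NA_integer_,
                applicable = FALSE))
  }
  if (length(unique(expressions)) == 1L) {
    return(list(H = 0, p_value = 1, df = nlevels(groups) - 1L,
                applicable = TRUE))
  }
  kt <- stats::kruskal.test(expressions, groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), applicable = TRUE)
}

#' Scan spacer positions with the Kruskal-Wallis test
#'
#' At every 0-based position, guides are grouped by the nucleotide at
#' that position and expression is tested across groups. Positions with
#' `p < alpha` are flagged for cross-reference against over/under-
#' represented k-mers at the same position.
#'
#' @param spacers Character vector of 28-nt spacers.
#' @param expressions Numeric vector, one value per spacer.
#' @param alpha Flagging threshold on the p-value.
#' @return Data frame with `position` (0-based), `H`, `p_value`,
#'   `flagged`.
#' @export
kw_position_scan <- function(spacers, expressions, alpha = 0.05) {
  stopifnot(length(spacers) == length(expressions))
  rows <- lapply(0:(SPACER_LEN - 1L), function(p) {
    nt <- substring(spacers, p + 1L, p + 1L)
    kw <- positional_kruskal_wallis(expressions, nt)
    data.frame(position = p, H = kw$H, p_value = kw$p_value,
               flagged = isTRUE(kw$p_value < alpha))
  })
  do.call(rbind, rows)
}

#' Univariate regression significance of each feature
#'
#' For every feature column, the p-value of the F-test of a simple linear
#' regression of the response on that feature alone, computed from the
#' squared Pearson correlation: `F = r^2 (n - 2) / (1 - r^2)` on
#' `(1, n - 2)` degrees of freedom. Constant features receive `p = 1`; a
#' p-value underflowing to zero is reported as the smallest positive
#' double.
#'
#' @param features Numeric feature matrix.
#' @param response Numeric response in `[0, 1]`, one value per row.
#' @return Named vector of p-values, one per feature column.
#' @export
univariate_significance <- function(features, response) {
  n <- nrow(features)
  if (n < 3L) {
    stop("univariate significance needs at least 3 rows")
  }
  if (length(response) != n) {
    stop("response length must equal the number of feature rows")
  }
  if (any(response < 0 | response > 1)) {
    stop("response values must lie in [0, 1]")
  }
  sds <- apply(features, 2L, stats::sd)
  p <- rep(1, ncol(features))
  names(p) <- colnames(features)
  ok <- sds > 0 & stats::sd(response) > 0
  if (any(ok)) {
    r <- suppressWarnings(stats::cor(features[, ok, drop = FALSE], response))
    r2 <- pmin(as.numeric(r)^2, 1)
    f <- r2 * (n - 2) / pmax(1 - r2, .Machine$double.eps)
    p[ok] <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  pmax(p, .Machine$double.xmin)
}

new_selection <- function(method, selected, scores, threshold) {
  structure(list(method = method, selected = selected, scores = scores,
                 threshold_used = threshold),
            class = "cas13_selection")
}

#' @export
print.cas13_selection <- function(x, ...) {
  cat("Feature selection (", x$method, "): ", length(x$selected),
      " feature(s), threshold ", format(x$threshold_used), "\n", sep = "")
  if (length(x$selected)) {
    cat("top:", paste(utils::head(x$selected, 5L), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Select features by raw p-value
#'
#' Keeps features with `p < alpha` (strict inequality, so a p-value of
#' exactly `alpha` is excluded), ordered by ascending p with ties broken
#' by name. No multiple-testing correction is applied by default; see
#' `adjust` for an optional FDR variant.
#'
#' @param pvals Named vector of per-feature p-values.
#' @param alpha Significance cutoff (default 0.05).
#' @param adjust Optional p-adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); `"none"` (default) reproduces the
#'   raw filtering.
#' @return A `cas13_selection` with `method = "pval"`.
#' @export
select_by_pvalue <- function(pvals, alpha = 0.05, adjust = "none") {
  stopifnot(length(pvals) > 0)
  p <- if (adjust == "none") pvals else stats::p.adjust(pvals, adjust)
  keep <- names(p)[p < alpha]
  if (!length(keep)) {
    warning("no features pass p < ", alpha)
  }
  keep <- keep[order(p[keep], keep)]
  new_selection("pval", keep, pvals, alpha)
}

#' Select outlier features by Z-score of -log10 p
#'
#' Standardizes `s = -log10(p)` over the supplied features and keeps
#' those with `(s - mean(s)) / sd(s) > z_cutoff` (strict). The log base
#' only rescales the scores identically, so it does not affect the
#' selection; base 10 is used. Applied to the significant subset this
#' yields the nested `z2`/`z3` feature lists.
#'
#' @param pvals Named vector of p-values in `(0, 1]`.
#' @param z_cutoff Z threshold, conventionally 2 or 3.
#' @return A `cas13_selection` with `method = "z<cutoff>"`.
#' @export
select_by_zscore <- function(pvals, z_cutoff) {
  stopifnot(length(pvals) > 0)
  s <- -log10(pvals)
  sdev <- stats::sd(s)
  method <- paste0("z", z_cutoff)
  if (!is.finite(sdev) || sdev == 0) {
    warning("zero variance in -log10 p; empty selection")
    return(new_selection(method, character(0), pvals, z_cutoff))
  }
  z <- (s - mean(s)) / sdev
  keep <- names(pvals)[z > z_cutoff]
  keep <- keep[order(-z[keep], keep)]
  new_selection(method, keep, pvals, z_cutoff)
}

# learners want syntactic column names; map f1..fn and back
with_safe_names <- function(features) {
  safe <- paste0("f", seq_len(ncol(features)))
  map <- stats::setNames(colnames(features), safe)
  colnames(features) <- safe
  list(features = features, map = map)
}

#' Select features by Gini importance
#'
#' Fits a decision tree or random forest with Gini impurity on the
#' quartile class labels and ranks features by mean decrease in impurity,
#' normalized to sum to 1 over the full feature space (features the
#' learner never split on get importance 0). Selection keeps the `top_n`
#' by importance, or all features above `importance_floor` when given.
#'
#' @param features Numeric feature matrix.
#' @param labels Class labels (coerced to factor, at least 2 classes).
#' @param learner `"decision_tree"` or `"random_forest"`.
#' @param top_n Number of features to keep (default 20).
#' @param importance_floor Optional importance threshold overriding
#'   `top_n`.
#' @param seed Integer seed; the same seed gives identical selections.
#' @param ntree Forest size for the random-forest learner.
#' @return A `cas13_selection` with `method` `"gini_dt"` or `"gini_rf"`
#'   and normalized importances as `scores`.
#' @export
select_by_gini <- function(features, labels,
                           learner = c("decision_tree", "random_forest"),
                           top_n = 20L, importance_floor = NULL, seed = 1L,
                           ntree = 100L) {
  learner <- match.arg(learner)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("Gini selection needs at least 2 classes")
  }
  safe <- with_safe_names(features)
  set.seed(seed)
  if (learner == "decision_tree") {
    df <- as.data.frame(safe$features)
    df$.class <- labels
    fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                        parms = list(split = "gini"),
                        control = rpart::rpart.control(cp = 0, xval = 0,
                                                       minsplit = 2))
    raw <- fit$variable.importance
    method <- "gini_dt"
  } else {
    fit <- randomForest::randomForest(safe$features, labels, ntree = ntree)
    raw <- fit$importance[, "MeanDecreaseGini"]
    method <- "gini_rf"
  }
  imp <- stats::setNames(numeric(ncol(features)), colnames(features))
  if (!is.null(raw) && length(raw)) {
    imp[safe$map[names(raw)]] <- as.numeric(raw)
  }
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  ord <- order(-imp, names(imp))
  if (is.null(importance_floor)) {
    keep <- names(imp)[ord][seq_len(min(top_n, ncol(features)))]
    keep <- keep[imp[keep] > 0]
    threshold <- as.numeric(top_n)
  } else {
    keep <- names(imp)[ord][imp[names(imp)[ord]] > importance_floor]
    threshold <- importance_floor
  }
  if (!length(keep)) {
    warning("no feature received positive Gini importance")
  }
  new_selection(method, keep, imp, threshold)
}

#' Run the full five-way feature-selection ladder
#'
#' Produces the five candidate feature lists benchmarked against each
#' other: univariate-regression significant features (`p < alpha`), their
#' Z > 2 and Z > 3 outlier subsets (so `pval` contains `z2` contains
#' `z3` by construction), and decision-tree and random-forest Gini
#' rankings. Non-k-mer features (composition, position, occupancy, hit
#' count) are appended to every list downstream by the model builder.
#'
#' @param features Numeric feature matrix (guide x replicate rows).
#' @param expressions Normalized expression per row, for the regression
#'   ladder.
#' @param labels Quartile class per row, for the Gini ladder.
#' @param alpha Significance cutoff for the p-value rung.
#' @param top_n Gini list size.
#' @param seed Integer seed for the tree learners.
#' @return Named list of five `cas13_selection` objects: `pval`, `z2`,
#'   `z3`, `gini_dt`, `gini_rf`.
#' @export
selection_ladder <- function(features, expressions, labels, alpha = 0.05,
                             top_n = 20L, seed = 1L) {
  pvals <- univariate_significance(features, expressions)
  pval_sel <- select_by_pvalue(pvals, alpha)
  sub <- pvals[pval_sel$selected]
  z2 <- if (length(sub)) select_by_zscore(sub, 2) else
    new_selection("z2", character(0), pvals, 2)
  z3 <- if (length(sub)) select_by_zscore(sub, 3) else
    new_selection("z3", character(0), pvals, 3)
  list(
    pval = pval_sel,
    z2 = z2,
    z3 = z3,
    gini_dt = select_by_gini(features, labels, "decision_tree",
                             top_n = top_n, seed = seed),
    gini_rf = select_by_gini(features, labels, "random_forest",
                             top_n = top_n, seed = seed)
  )
}

#' Export a selection result as a k-mer table
#'
#' Tab-delimited text with one row per selected feature: the k-mer, its
#' 0-based position in the guide, and the associated score (p-value or
#' importance). Non-k-mer features carry their name in the k-mer column
#' and an empty position.
#'
#' @param selection A `cas13_selection`.
#' @param path Output path.
#' @export
write_selection <- function(selection, path) {
  parts <- strsplit(selection$selected, "|", fixed = TRUE)
  is_kmer <- lengths(parts) == 4L
  df <- data.frame(
    kmer = ifelse(is_kmer, vapply(parts, function(p) p[3L], character(1)),
                  selection$selected),
    position = ifelse(is_kmer, vapply(parts, function(p) p[4L],
                                      character(1)), ""),
    p_value = as.numeric(selection$scores[selection$selected]),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
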