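#' Replicate-noise ceiling on classification accuracy
#'
#' Experimental replicates of the same guide share the feature vector but
#' may fall in different expression quartiles, so no classifier can label
#' both correctly. The ceiling counts, over all unordered pairs of
#' distinct rows with identical feature vectors, the fraction whose class
#' labels disagree:
#' `max_nn = 1 - conflicting_pairs / total_pairs`.
#' Raw accuracy divided by this ceiling gives noise-normalized accuracy.
#'
#' @param x Numeric feature matrix.
#' @param labels Class label per row.
#' @param group Optional explicit grouping vector (e.g. guide IDs) to use
#'   instead of exact feature-vector equality; replicates share the guide
#'   sequence, so the two coincide by construction.
#' @return List with `conflicting_pairs`, `total_pairs`, `max_nn`, and
#'   `flagged` (`TRUE` when no identical-feature pairs exist, in which
#'   case `max_nn = 1` by convention: no noise is measurable).
#' @export
noise_ceiling <- function(x, labels, group = NULL) {
  n <- if (is.null(group)) nrow(x) else length(group)
  if (n < 2L) {
    stop("noise ceiling needs at least 2 rows")
  }
  if (is.null(group)) {
    group <- do.call(paste, c(as.data.frame(x), sep = "\r"))
  }
  labels <- as.character(labels)
  sizes <- table(group)
  total <- sum(choose(sizes, 2))
  if (total == 0) {
    return(list(conflicting_pairs = 0L, total_pairs = 0L, max_nn = 1,
                flagged = TRUE))
  }
  same <- sum(choose(table(group, labels), 2))
  conflicting <- total - same
  list(conflicting_pairs = as.integer(conflicting),
       total_pairs = as.integer(total),
       max_nn = 1 - conflicting / total,
       flagged = FALSE)
}

accuracy <- function(truth, predicted) {
  mean(as.character(truth) == as.character(predicted))
}

fit_and_score <- function(x, labels, model_spec, train_idx, test_idx,
                          fit_seed) {
  fit <- cas13_fit(x[train_idx, , drop = FALSE], labels[train_idx],
                   architecture = model_spec$architecture %||%
                     "decision_tree",
                   hyperparameters = model_spec$hyperparameters %||% list(),
                   features = model_spec$features %||% colnames(x),
                   seed = fit_seed)
  prob <- predict(fit, x[test_idx, , drop = FALSE], type = "prob")
  lev <- colnames(prob)
  pred <- lev[max.col(prob, ties.method = "first")]
  list(acc = accuracy(labels[test_idx], pred), prob = prob,
       levels = lev)
}

#' Cross-validate a guide efficacy classifier
#'
#' Implements the two evaluation schemes: `"threefold_replicate"` holds
#' one experimental replicate out per fold (training on the other two,
#' averaged over the three rotations) and `"fivefold_random"` draws, per
#' repeat, a random 80/20 train/test split of all replicate rows and
#' averages accuracy over the repeats. Raw accuracy is plain multiclass
#' fraction-correct; noise-normalized accuracy divides it by the
#' replicate-noise ceiling ([noise_ceiling()]) computed on the full
#' dataset. Per-class one-vs-all AUCs are computed on the pooled
#' out-of-fold score matrix. For knn and random-forest parameter sweeps,
#' the per-fold best parameter is recorded and averaged.
#'
#' @param x Numeric feature matrix (guide x replicate rows).
#' @param labels Class codes per row.
#' @param model_spec List with `architecture`, `hyperparameters`,
#'   `features` (defaults: decision tree, empty, all columns).
#' @param scheme `"fivefold_random"` or `"threefold_replicate"`.
#' @param repeats Number of random splits for the fivefold scheme
#'   (default 100).
#' @param replicate_id Replicate identifier per row; required (with
#'   exactly 3 distinct values) for the threefold scheme.
#' @param seed Integer seed; the full report is reproducible.
#' @param sweep Optional named list of candidate values for one
#'   hyperparameter, e.g. `list(k = 1:15)` or `list(ntree = seq(10, 100,
#'   10))`; per fold the best test accuracy is kept.
#' @param ceiling_group Optional grouping vector forwarded to
#'   [noise_ceiling()].
#' @return A `cas13_cv` list: `scheme`, `repeats`, `raw_accuracy`,
#'   `noise_normalized_accuracy`, `max_nn`, `per_fold`, `per_class_auc`,
#'   `best_hyperparameters`.
#' @export
cross_validate <- function(x, labels,
                           model_spec = list(),
                           scheme = c("fivefold_random",
                                      "threefold_replicate"),
                           repeats = 100L, replicate_id = NULL, seed = 1L,
                           sweep = NULL, ceiling_group = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(x)
  labels <- as.character(labels)
  ceiling <- noise_ceiling(x, labels, group = ceiling_group)

  set.seed(seed)
  if (scheme == "threefold_replicate") {
    if (is.null(replicate_id)) {
      stop("threefold_replicate requires replicate_id")
    }
    reps <- sort(unique(replicate_id))
    if (length(reps) != 3L) {
      stop("threefold_replicate requires exactly 3 replicates, got ",
           length(reps))
    }
    folds <- lapply(reps, function(r) which(replicate_id == r))
  } else {
    stopifnot(repeats >= 1L)
    n_test <- max(1L, round(0.2 * n))
    folds <- lapply(seq_len(repeats), function(r) sample.int(n, n_test))
  }
  fit_seeds <- sample.int(1e6, length(folds))

  per_fold <- numeric(length(folds))
  best_par <- numeric(length(folds))
  pooled_prob <- NULL
  pooled_truth <- character(0)
  sweep_name <- if (!is.null(sweep)) names(sweep)[1L] else NULL

  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n), test_idx)
    if (is.null(sweep)) {
      res <- fit_and_score(x, labels, model_spec, train_idx, test_idx,
                           fit_seeds[f])
    } else {
      cand <- lapply(sweep[[1L]], function(v) {
        spec <- model_spec
        spec$hyperparameters <- model_spec$hyperparameters %||% list()
        spec$hyperparameters[[sweep_name]] <- v
        fit_and_score(x, labels, spec, train_idx, test_idx, fit_seeds[f])
      })
      accs <- vapply(cand, `[[`, numeric(1), "acc")
      best <- which.max(accs)
      best_par[f] <- sweep[[1L]][best]
      res <- cand[[best]]
    }
    per_fold[f] <- res$acc
    all_lev <- sort(unique(labels))
    prob <- matrix(0, nrow(res$prob), length(all_lev),
                   dimnames = list(NULL, all_lev))
    prob[, res$levels] <- res$prob
    pooled_prob <- rbind(pooled_prob, prob)
    pooled_truth <- c(pooled_truth, labels[test_idx])
  }

  acc <- mean(per_fold)
  structure(list(
    scheme = scheme,
    repeats = length(folds),
    raw_accuracy = acc,
    noise_normalized_accuracy =
      if (ceiling$max_nn > 0) acc / ceiling$max_nn else NA_real_,
    max_nn = ceiling$max_nn,
    per_fold = per_fold,
    per_class_auc = roc_one_vs_all(pooled_prob, pooled_truth),
    best_hyperparameters =
      if (is.null(sweep)) NULL else
        stats::setNames(list(mean(best_par)), sweep_name),
    seed = seed
  ), class = "cas13_cv")
}

#' @export
print.cas13_cv <- function(x, ...) {
  cat("Cross-validation (", x$scheme, ", ", x$repeats, " fold(s))\n",
      sep = "")
  cat(sprintf("  raw accuracy:              %.4f\n", x$raw_accuracy))
  cat(sprintf("  noise ceiling (max_nn):    %.4f\n", x$max_nn))
  cat(sprintf("  noise-normalized accuracy: %.4f\n",
              x$noise_normalized_accuracy))
  auc <- x$per_class_auc
  cat("  per-class AUC: ",
      paste(sprintf("%s: %.3f", names(auc), auc), collapse = ", "), "\n")
  if (!is.null(x$best_hyperparameters)) {
    cat("  mean best ", names(x$best_hyperparameters), ": ",
        format(x$best_hyperparameters[[1L]]), "\n", sep = "")
  }
  invisible(x)
}

#' One-vs-all ROC AUC per class
#'
#' For each class, the score column for that class is compared against
#' the indicator of membership using the rank (Mann-Whitney) formulation
#' with midranks for ties; this equals the trapezoidal area under the
#' ROC curve. Classes absent from the labels (or covering all rows) get
#' `NA`.
#'
#' @param scores Numeric matrix of per-class scores, columns named by
#'   class.
#' @param labels Vector of true classes.
#' @return Named numeric vector of AUCs, one per score column.
#' @export
roc_one_vs_all <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels))
  vapply(colnames(scores), function(cl) {
    pos <- labels == cl
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos == 0L || n_neg == 0L) return(NA_real_)
    r <- rank(scores[, cl])
    (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }, numeric(1))
}

#' ROC curve points for one class vs the rest
#'
#' @param scores Per-class score matrix.
#' @param labels True classes.
#' @param class Class (column name) to treat as positive.
#' @return Data frame of `(fpr, tpr)` points ordered along the curve.
#' @export
roc_points <- function(scores, labels, class) {
  pos <- as.character(labels) == class
  s <- scores[, class]
  ord <- order(-s)
  tpr <- cumsum(pos[ord]) / sum(pos)
  fpr <- cumsum(!pos[ord]) / sum(!pos)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Benchmark architectures against feature lists
#'
#' Runs the full architecture x feature-list x scheme grid: every
#' classifier architecture is cross-validated under both the replicate-
#' wise 3-fold and the repeated random-split 5-fold protocol on each
#' candidate feature list. knn and random_forest cells sweep their main
#' hyperparameter and report the averaged per-fold best value.
#'
#' @param x Feature matrix (guide x replicate rows).
#' @param labels Class codes per row.
#' @param feature_lists Named list of feature-name vectors (e.g. the
#'   [selection_ladder()] lists with the non-k-mer features appended).
#' @param architectures Architectures to include (default: all seven).
#' @param replicate_id Replicate identifier per row.
#' @param repeats Random-split repeats for the fivefold scheme.
#' @param seed Integer seed.
#' @param sweeps Named list of sweeps per architecture; defaults to
#'   `k = 1:15` for knn and `ntree = seq(10, 100, 10)` for the forest.
#' @return Data frame with one row per grid cell: `scheme`,
#'   `architecture`, `feature_list`, `n_features`, `accuracy`, `acc_nn`,
#'   `best_param`. Cells with an empty feature list hold `NA`.
#' @export
benchmark_grid <- function(x, labels, feature_lists,
                           architectures = ARCHITECTURES,
                           replicate_id = NULL, repeats = 20L, seed = 1L,
                           sweeps = list(
                             knn = list(k = 1:15),
                             random_forest = list(ntree = seq(10L, 100L,
                                                              10L)))) {
  schemes <- c("threefold_replicate", "fivefold_random")
  rows <- list()
  for (scheme in schemes) {
    for (arch in architectures) {
      for (fl in names(feature_lists)) {
        feats <- feature_lists[[fl]]
        cell_seed <- (seed + 7L * length(rows)) %% .Machine$integer.max
        if (!length(feats)) {
          rows[[length(rows) + 1L]] <- data.frame(
            scheme = scheme, architecture = arch, feature_list = fl,
            n_features = 0L, accuracy = NA_real_, acc_nn = NA_real_,
            best_param = NA_real_, stringsAsFactors = FALSE)
          next
        }
        cv <- cross_validate(
          x, labels, model_spec = list(architecture = arch,
                                       features = feats),
          scheme = scheme, repeats = repeats,
          replicate_id = replicate_id, seed = cell_seed,
          sweep = sweeps[[arch]])
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = scheme, architecture = arch, feature_list = fl,
          n_features = length(feats), accuracy = cv$raw_accuracy,
          acc_nn = cv$noise_normalized_accuracy,
          best_param = if (is.null(cv$best_hyperparameters)) NA_real_ else
            cv$best_hyperparameters[[1L]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a benchmark grid as a wide table
#'
#' One block per scheme, architectures as rows and feature lists as
#' columns; knn and random-forest cells carry the averaged best
#' parameter in brackets.
#'
#' @param grid Data frame from [benchmark_grid()].
#' @param path Output path.
#' @export
write_benchmark_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (scheme in unique(grid$scheme)) {
    sub <- grid[grid$scheme == scheme, , drop = FALSE]
    lists <- unique(sub$feature_list)
    writeLines(paste0("# ", scheme), con)
    writeLines(paste(c("architecture", lists), collapse = "\t"), con)
    for (arch in unique(sub$architecture)) {
      cells <- vapply(lists, function(fl) {
        row <- sub[sub$architecture == arch & sub$feature_list == fl, ]
        if (!nrow(row) || is.na(row$accuracy)) return("NA")
        cell <- sprintf("%.3f", row$accuracy)
        if (!is.na(row$best_param)) {
          cell <- sprintf("%s [%.4g]", cell, row$best_param)
        }
        cell
      }, character(1))
      writeLines(paste(c(arch, cells), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Leave-one-feature-out ablation
#'
#' Establishes a background as the mean accuracy over `repeats` repeated
#' random-split cross-validations on the full feature list, then removes
#' one feature at a time and re-evaluates another `repeats` times. The
#' drop from background attributable to each feature is its ablation
#' delta (positive = the feature helps).
#'
#' @param x Feature matrix.
#' @param labels Class codes per row.
#' @param model_spec Model specification as in [cross_validate()]; must
#'   name at least 2 features.
#' @param repeats Evaluations per condition (default 100).
#' @param seed Integer seed.
#' @return List with `background_mean`, `per_feature_delta` (named,
#'   `background_mean - mean accuracy without the feature`), and
#'   `runs_executed` (= `repeats * (1 + n_features)`).
#' @export
feature_ablation <- function(x, labels, model_spec, repeats = 100L,
                             seed = 1L) {
  feats <- model_spec$features %||% colnames(x)
  if (length(feats) < 2L) {
    stop("ablation needs a model with at least 2 features")
  }
  set.seed(seed)
  cond_seeds <- sample.int(1e6, length(feats) + 1L)
  bg <- cross_validate(x, labels, model_spec, scheme = "fivefold_random",
                       repeats = repeats, seed = cond_seeds[1L])
  deltas <- vapply(seq_along(feats), function(i) {
    spec <- model_spec
    spec$features <- feats[-i]
    cv <- cross_validate(x, labels, spec, scheme = "fivefold_random",
                         repeats = repeats, seed = cond_seeds[i + 1L])
    bg$raw_accuracy - cv$raw_accuracy
  }, numeric(1))
  list(background_mean = bg$raw_accuracy,
       per_feature_delta = stats::setNames(deltas, feats),
       runs_executed = repeats * (1L + length(feats)))
}
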