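EFFICACY_LABELS <- c("highly_efficient", "efficient", "inefficient",
                     "highly_inefficient")

ARCHITECTURES <- c("decision_tree", "random_forest", "knn", "svc_linear",
                   "svc_poly", "svc_sigmoid", "svc_rbf")

#' Quartile efficacy class of a normalized expression value
#'
#' Bins normalized target-transcript expression (lower = better
#' knockdown) into the four efficacy classes: 0 `[0, 0.25)` highly
#' efficient, 1 `[0.25, 0.5)` efficient, 2 `[0.5, 0.75)` inefficient,
#' 3 `[0.75, 1]` highly inefficient. Boundary values go to the higher
#' class and 1.0 is capped into class 3, so the four bins partition
#' `[0, 1]` exactly.
#'
#' @param expression Numeric vector in `[0, 1]`.
#' @return Integer vector of class codes 0-3.
#' @export
assign_class <- function(expression) {
  if (any(expression < 0 | expression > 1)) {
    stop("expression values must lie in [0, 1]")
  }
  as.integer(pmin(floor(expression / 0.25), 3))
}

#' Human-readable label of an efficacy class code
#'
#' @param code Integer class code(s) 0-3.
#' @return Character label(s).
#' @export
class_label <- function(code) {
  stopifnot(all(code %in% 0:3))
  EFFICACY_LABELS[code + 1L]
}

model_fingerprint <- function(payload) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(payload, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

#' Fit a guide efficacy classifier
#'
#' Trains one of seven classifier architectures to map guide feature
#' vectors to the four knockdown-efficacy quartile classes. The default
#' published-style configuration is a Gini decision tree on a random-
#' forest-Gini feature list; the remaining architectures exist for the
#' benchmark grid. Fits are deterministic given `seed`.
#'
#' @param x Numeric feature matrix (one row per guide x replicate
#'   observation). Replicates of one guide contribute identical feature
#'   rows with possibly different labels; that duplication is what makes
#'   the replicate-noise accuracy ceiling bind.
#' @param labels Class codes 0-3 (or any factor with >= 2 levels).
#' @param architecture One of `"decision_tree"`, `"random_forest"`,
#'   `"knn"`, `"svc_linear"`, `"svc_poly"`, `"svc_sigmoid"`, `"svc_rbf"`.
#' @param hyperparameters Named list: `k` (knn neighbors, default 3),
#'   `ntree` (forest size, default 100), `cost`/`gamma`/`degree`/`coef0`
#'   for the SVC kernels, `cp`/`minsplit` for the tree.
#' @param features Feature names to train on, in order (default: all
#'   columns of `x`).
#' @param seed Integer seed.
#' @return An object of class `cas13_model` with `print`, `summary` and
#'   `predict` methods. `training_fingerprint` hashes (data, features,
#'   architecture, hyperparameters, seed): equal fingerprints imply
#'   identical predictions.
#' @seealso [predict.cas13_model()], [predict_guides()], [cross_validate()]
#' @export
cas13_fit <- function(x, labels,
                      architecture = "decision_tree",
                      hyperparameters = list(),
                      features = colnames(x),
                      seed = 1L) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  missing <- setdiff(features, colnames(x))
  if (length(missing)) {
    stop("feature(s) absent from x: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  x <- x[, features, drop = FALSE]
  y <- factor(labels)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training labels contain a single class")
  }
  hp <- hyperparameters
  safe <- with_safe_names(x)
  set.seed(seed)
  fitted <- switch(
    architecture,
    decision_tree = {
      df <- as.data.frame(safe$features)
      df$.class <- y
      rpart::rpart(.class ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(
                     cp = hp$cp %||% 0.001,
                     minsplit = hp$minsplit %||% 5L, xval = 0))
    },
    random_forest = randomForest::randomForest(
      safe$features, y, ntree = hp$ntree %||% 100L),
    knn = list(train = safe$features, cl = y, k = hp$k %||% 3L),
    {
      kernel <- sub("^svc_", "", architecture)
      kernel <- c(linear = "linear", poly = "polynomial",
                  sigmoid = "sigmoid", rbf = "radial")[kernel]
      e1071::svm(safe$features, y, kernel = kernel,
                 cost = hp$cost %||% 1,
                 degree = hp$degree %||% 3,
                 coef0 = hp$coef0 %||% 0,
                 gamma = hp$gamma %||% (1 / ncol(safe$features)),
                 probability = TRUE)
    })
  obj <- structure(list(
    architecture = architecture,
    hyperparameters = hp,
    feature_list = features,
    name_map = safe$map,
    levels = levels(y),
    fitted_state = fitted,
    seed = seed,
    n_train = nrow(x)
  ), class = "cas13_model")
  obj$training_fingerprint <- model_fingerprint(
    list(x = x, y = as.character(y), features = features,
         architecture = architecture, hp = hp, seed = seed))
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_feature_match <- function(model, x) {
  missing <- setdiff(model$feature_list, colnames(x))
  extra <- setdiff(colnames(x), model$feature_list)
  if (length(missing)) {
    stop("prediction matrix is missing feature(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  x[, model$feature_list, drop = FALSE]
}

#' Predict efficacy classes for new guides
#'
#' @param object A `cas13_model`.
#' @param newdata Numeric matrix containing at least the model's feature
#'   columns; extra columns are dropped, missing ones are an error.
#' @param type `"class"` for hard class codes, `"prob"` for the per-class
#'   score matrix. Class scores are the model's class-membership
#'   estimates: leaf class fractions for the tree, vote fractions for the
#'   forest, neighbor vote share for knn, and probability estimates for
#'   the SVCs.
#' @param ... Unused.
#' @return Integer class codes, or a rows x classes numeric matrix with
#'   the class codes as column names.
#' @export
predict.cas13_model <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  x <- check_feature_match(object, newdata)
  colnames(x) <- names(object$name_map)[match(colnames(x),
                                              object$name_map)]
  lev <- object$levels
  prob <- switch(
    object$architecture,
    decision_tree = {
      p <- stats::predict(object$fitted_state, as.data.frame(x),
                          type = "prob")
      p[, lev, drop = FALSE]
    },
    random_forest = {
      p <- stats::predict(object$fitted_state, x, type = "prob")
      p[, lev, drop = FALSE]
    },
    knn = {
      st <- object$fitted_state
      pred <- class::knn(st$train, x, st$cl, k = st$k, prob = TRUE)
      share <- attr(pred, "prob")
      p <- matrix((1 - share) / max(length(lev) - 1L, 1L),
                  nrow = nrow(x), ncol = length(lev),
                  dimnames = list(rownames(x), lev))
      p[cbind(seq_len(nrow(x)), match(as.character(pred), lev))] <- share
      p
    },
    {
      pr <- stats::predict(object$fitted_state, x, probability = TRUE)
      p <- attr(pr, "probabilities")
      p[, lev, drop = FALSE]
    })
  if (type == "prob") {
    return(prob)
  }
  as.integer(lev[max.col(prob, ties.method = "first")])
}

#' @export
print.cas13_model <- function(x, ...) {
  cat("Cas13 guide efficacy classifier\n")
  cat("  architecture:", x$architecture, "\n")
  cat("  features:    ", length(x$feature_list), "\n")
  cat("  classes:     ", paste(x$levels, collapse = ", "), "\n")
  cat("  trained on:  ", x$n_train, "observations\n")
  cat("  fingerprint: ", x$training_fingerprint, "\n")
  invisible(x)
}

#' @export
summary.cas13_model <- function(object, ...) {
  print(object)
  cat("  feature list:\n")
  cat("   ", paste(utils::head(object$feature_list, 15L), collapse = ", "))
  if (length(object$feature_list) > 15L) cat(", ...")
  cat("\n")
  invisible(object)
}

#' Rank and export at-least-efficient guide predictions
#'
#' Classifies every candidate guide and, per source transcript, ranks the
#' guides predicted at least efficient (classes 0 and 1, i.e. expected
#' normalized expression below 0.5) by descending model confidence, with
#' ties broken by ascending target start. When `out_dir` is given, one
#' tab-delimited file per transcript is written with columns rank,
#' spacer, 0-based target start, predicted class and confidence;
#' transcripts with no efficient prediction get an empty file and a
#' warning.
#'
#' @param model A `cas13_model`.
#' @param features Per-guide feature matrix (rows in guide order).
#' @param guides Guide data frame matching `features` rows.
#' @param out_dir Optional output directory for per-transcript files.
#' @return Data frame over all guides: `guide_id`, `source_transcript`,
#'   `target_start`, `spacer`, `predicted_class`, `confidence`, and
#'   `rank` (NA for guides predicted inefficient).
#' @export
predict_guides <- function(model, features, guides, out_dir = NULL) {
  stopifnot(nrow(features) == nrow(guides))
  prob <- predict(model, features, type = "prob")
  cls <- as.integer(model$levels[max.col(prob, ties.method = "first")])
  conf <- prob[cbind(seq_len(nrow(prob)),
                     match(as.character(cls), colnames(prob)))]
  out <- data.frame(
    guide_id = guides$guide_id,
    source_transcript = guides$source_transcript,
    target_start = guides$target_start,
    spacer = guides$spacer,
    predicted_class = cls,
    confidence = as.numeric(conf),
    rank = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (tx in unique(out$source_transcript)) {
    sel <- which(out$source_transcript == tx & out$predicted_class <= 1L)
    if (length(sel)) {
      ord <- sel[order(-out$confidence[sel], out$target_start[sel])]
      out$rank[ord] <- seq_along(ord)
    }
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", tx),
                                        "_guides.txt"))
      cols <- c("rank", "spacer", "target_start", "predicted_class",
                "confidence")
      if (length(sel)) {
        eff <- out[sel, , drop = FALSE]
        eff <- eff[order(eff$rank), cols, drop = FALSE]
        utils::write.table(eff, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      } else {
        warning("no guides predicted at least efficient for ", tx)
        utils::write.table(out[0L, cols, drop = FALSE], path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
  }
  out
}

#' Persist / restore a fitted model
#'
#' Round-trips are bit-identical on a probe matrix: the restored model
#' carries the same fingerprint and produces the same predictions.
#'
#' @param model A `cas13_model`.
#' @param path File path.
#' @return `load_model` returns the restored `cas13_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cas13_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cas13_model")) {
    stop("file does not contain a cas13_model: ", path)
  }
  model
}
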