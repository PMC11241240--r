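#' Ligand-function classification pipeline
#'
#' The pipeline mirrors the conventional structure-based workflow: a
#' randomized 75/25 train/test split of the feature table; preprocessing
#' fitted on the training split only (ordinal encoding of the categorical
#' interaction types with the "NA" category kept as its own code, mean
#' imputation of missing numeric energies, and standardization of every
#' column to zero mean and unit variance); a random forest with 500 trees,
#' depth cap 30, sqrt(p) features per split, min_samples_split 2,
#' min_samples_leaf 1, no bootstrap resampling and inverse-frequency class
#' weights (the balanced-subsample convention degenerates to full-sample
#' balancing when bootstrap is off); 10-fold cross-validation on the
#' training split; probability-averaged prediction of the four functional
#' classes; and two post-processing steps, merged-active reconfiguration and
#' majority-rule voting over docked-pose groups.
#'
#' @name classify
NULL

.class_registry <- c("agonist", "antagonist", "inverse_agonist", "inactive")
.merged_registry <- c("active", "inactive")

.meta_cols <- c("complex_id", "label", "model_id", "ligand_id")

# run code under a temporary RNG state so callers' streams are untouched
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Randomized train/test split
#'
#' @param table a feature table (any data.frame).
#' @param test_fraction held-out fraction (default 0.25); the training size
#'   is \code{round((1 - test_fraction) * n)}, so 1820 rows give 1365/455.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return list(train, test) of disjoint row subsets.
#' @export
split_table <- function(table, test_fraction = 0.25, seed = 1L) {
  n <- nrow(table)
  if (n < 2L) stop("need at least 2 rows to split")
  n_train <- round((1 - test_fraction) * n)
  idx <- .with_seed(seed, sample.int(n, n_train))
  list(train = table[idx, , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

.feature_cols <- function(table) setdiff(names(table), .meta_cols)

#' Fit preprocessing state on a training table
#'
#' @param train training feature table.
#' @return preprocessing state: per-categorical-column encoder registries,
#'   per-numeric-column imputation means, and per-column center/scale.
#' @export
fit_preprocessing <- function(train) {
  stopifnot(nrow(train) >= 1L)
  cols <- .feature_cols(train)
  cat_cols <- cols[vapply(train[cols], is.character, TRUE)]
  num_cols <- setdiff(cols, cat_cols)
  encoders <- lapply(train[cat_cols], function(x) sort(unique(x)))
  means <- vapply(num_cols, function(nm) {
    v <- train[[nm]]
    if (all(is.na(v))) {
      warning("all-NA numeric column '", nm, "' imputed to 0")
      0
    } else mean(v, na.rm = TRUE)
  }, 1.0)
  state <- list(columns = cols, cat_cols = cat_cols, num_cols = num_cols,
                encoders = encoders, impute_means = means,
                center = NULL, scale = NULL)
  m <- .encode_impute(state, train)
  center <- colMeans(m)
  scale <- apply(m, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  state$center <- center
  state$scale <- scale
  state
}

.encode_impute <- function(state, table) {
  n <- nrow(table)
  m <- matrix(0, n, length(state$columns),
              dimnames = list(NULL, state$columns))
  for (nm in state$columns) {
    if (!nm %in% names(table)) stop("column '", nm, "' missing from table")
    v <- table[[nm]]
    if (nm %in% state$cat_cols) {
      code <- match(as.character(v), state$encoders[[nm]])
      # unseen category at predict time -> reserved code past the registry
      code[is.na(code)] <- length(state$encoders[[nm]]) + 1L
      m[, nm] <- code - 1
    } else {
      v <- as.numeric(v)
      v[is.na(v)] <- state$impute_means[[nm]]
      m[, nm] <- v
    }
  }
  m
}

#' Apply fitted preprocessing to a table
#'
#' @param state output of \code{\link{fit_preprocessing}}.
#' @param table a feature table with the same feature columns.
#' @return numeric matrix (rows = complexes) with standardized columns.
#' @export
apply_preprocessing <- function(state, table) {
  m <- .encode_impute(state, table)
  sweep(sweep(m, 2, state$center), 2, state$scale, "/")
}

#' Default forest configuration
#' @export
forest_config <- function(n_trees = 500L, max_depth = 30L, mtry = NULL,
                          min_split = 2L, min_leaf = 1L) {
  list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
       mtry = mtry, min_split = as.integer(min_split),
       min_leaf = as.integer(min_leaf))
}

.fit_forest <- function(X, y_int, K, config, seed) {
  counts <- tabulate(y_int + 1L, K)
  cw <- ifelse(counts > 0, length(y_int) / (K * counts), 0)
  mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(X))))
  .rf_fit_cpp(X, y_int, K, cw, config$n_trees, as.integer(mtry),
              config$max_depth, config$min_split, config$min_leaf,
              as.integer(seed))
}

#' Train the ligand-function classifier
#'
#' Fits preprocessing on the supplied training table, runs k-fold
#' cross-validation (10 folds, reduced with a warning below 10 rows), and
#' fits the final forest on the whole training split.
#'
#' @param train training feature table with a \code{label} column.
#' @param seed integer seed controlling fold assignment and tree feature
#'   sampling.
#' @param config forest configuration from \code{\link{forest_config}}.
#' @param classes label registry (default the four functional classes);
#'   labels outside it are an error.
#' @param cv_folds number of cross-validation folds (default 10).
#' @return object of class \code{gifp_classifier} with elements prep,
#'   config, forest, classes, cv_score, seed.
#' @export
train_classifier <- function(train, seed = 1L, config = forest_config(),
                             classes = .class_registry, cv_folds = 10L) {
  if (!"label" %in% names(train)) stop("training table has no 'label' column")
  if (!all(train$label %in% classes)) {
    stop("labels outside the class registry: ",
         paste(setdiff(train$label, classes), collapse = ", "))
  }
  present <- intersect(classes, unique(train$label))
  if (length(present) < 2L) stop("training labels contain a single class")
  prep <- fit_preprocessing(train)
  X <- apply_preprocessing(prep, train)
  y <- match(train$label, classes) - 1L
  K <- length(classes)

  n <- nrow(X)
  folds <- min(cv_folds, n)
  if (folds < cv_folds) warning("reducing CV folds to ", folds,
                                " (only ", n, " rows)")
  fold_id <- .with_seed(seed, sample(rep_len(seq_len(folds), n)))
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2L) next
    forest_f <- .fit_forest(X[tr, , drop = FALSE], y[tr], K, config,
                            seed + f)
    pr <- .rf_predict_cpp(forest_f, X[!tr, , drop = FALSE], K)
    correct <- correct + sum(max.col(pr, ties.method = "first") - 1L == y[!tr])
  }
  cv_score <- correct / n

  forest <- .fit_forest(X, y, K, config, seed)
  structure(list(prep = prep, config = config, forest = forest,
                 classes = classes, cv_score = cv_score,
                 seed = as.integer(seed)),
            class = "gifp_classifier")
}

#' Predict ligand function
#'
#' Class probabilities are averaged over trees; the predicted label is the
#' argmax, with ties broken toward the first label in the registry order.
#'
#' @param bundle a \code{gifp_classifier}.
#' @param table feature table (may carry complex_id / label / model_id /
#'   ligand_id metadata columns, which are passed through).
#' @return data.frame (class \code{gifp_predictions}): metadata columns,
#'   true_label when available, pred_label, and one prob_<class> column per
#'   class, each row's probabilities summing to 1.
#' @export
predict_classifier <- function(bundle, table) {
  stopifnot(inherits(bundle, "gifp_classifier"))
  if (nrow(table) == 0L) {
    out <- data.frame(pred_label = character(0))
    class(out) <- c("gifp_predictions", "data.frame")
    return(out)
  }
  X <- apply_preprocessing(bundle$prep, table)
  pr <- .rf_predict_cpp(bundle$forest, X, length(bundle$classes))
  colnames(pr) <- paste0("prob_", bundle$classes)
  pred <- bundle$classes[max.col(pr, ties.method = "first")]
  vals <- list()
  for (nm in setdiff(intersect(.meta_cols, names(table)), "label")) {
    vals[[nm]] <- table[[nm]]
  }
  if ("label" %in% names(table)) vals$true_label <- table$label
  vals$pred_label <- pred
  out <- cbind(as.data.frame(vals, stringsAsFactors = FALSE),
               as.data.frame(pr))
  class(out) <- c("gifp_predictions", "data.frame")
  out
}

#' Merge the three active classes into one
#'
#' Agonist, antagonist and inverse agonist collapse to "active"; inactive is
#' unchanged. Already-merged labels pass through.
#'
#' @param labels character vector of 4-class (or merged) labels.
#' @return character vector over {active, inactive}.
#' @export
merge_active <- function(labels) {
  known <- c(.class_registry, .merged_registry)
  if (any(!labels %in% known)) {
    stop("unknown label(s): ", paste(setdiff(labels, known), collapse = ", "))
  }
  ifelse(labels == "inactive", "inactive", "active")
}

#' Majority-rule voting over docked-pose groups
#'
#' Each (model_id, ligand_id) group of per-pose predictions is collapsed to
#' the modal predicted label. Ties go to the label with the largest summed
#' probability across the group's poses, then to registry order. An odd
#' number of poses per group is recommended; even groups trigger a warning.
#'
#' @param predictions a \code{gifp_predictions} data.frame.
#' @param group_by columns defining the pose groups.
#' @return one row per group: group keys, true_label (if constant within the
#'   group), pred_label, and group-mean probabilities.
#' @export
majority_vote <- function(predictions, group_by = c("model_id", "ligand_id")) {
  group_by <- intersect(group_by, names(predictions))
  if (length(group_by) == 0L) stop("no grouping columns present")
  key <- do.call(paste, c(predictions[group_by], sep = "\r"))
  prob_cols <- grep("^prob_", names(predictions), value = TRUE)
  classes <- sub("^prob_", "", prob_cols)
  if (any(table(key) %% 2L == 0L)) {
    warning("even pose-group size(s): an odd number of docked poses is ",
            "recommended for majority voting")
  }
  rows <- lapply(split(seq_len(nrow(predictions)), key), function(i) {
    g <- predictions[i, , drop = FALSE]
    counts <- table(factor(g$pred_label, levels = classes))
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1L) {
      psum <- colSums(g[, paste0("prob_", top), drop = FALSE])
      top <- top[psum == max(psum)]
      top <- top[which.min(match(top, classes))]
    }
    out <- g[1, group_by, drop = FALSE]
    if ("true_label" %in% names(g) && length(unique(g$true_label)) == 1L) {
      out$true_label <- g$true_label[1]
    }
    out$pred_label <- top
    out$n_poses <- nrow(g)
    for (pc in prob_cols) out[[pc]] <- mean(g[[pc]])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gifp_predictions", "data.frame")
  out
}

#' Confusion matrix (rows = actual, columns = predicted)
#'
#' @param true,predicted label vectors of equal length.
#' @param labels ordered label set; labels outside it are an error.
#' @return integer matrix of class \code{gifp_confusion}.
#' @export
confusion <- function(true, predicted,
                      labels = union(unique(true), unique(predicted))) {
  stopifnot(length(true) == length(predicted))
  if (any(!c(true, predicted) %in% labels)) {
    stop("label(s) outside the supplied order: ",
         paste(setdiff(c(true, predicted), labels), collapse = ", "))
  }
  cm <- table(factor(true, levels = labels), factor(predicted, levels = labels))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("actual", "predicted")
  structure(cm, class = c("gifp_confusion", class(cm)))
}

#' Performance metrics from a confusion matrix
#'
#' Micro-averaged precision and recall over single-label multiclass output
#' both equal the accuracy (trace / total); per-class values are reported for
#' transparency. The hit rate, 100 x actual actives among predicted actives /
#' predicted actives, is defined only for a binary active/inactive matrix and
#' is NA when nothing is predicted active.
#'
#' @param cm a \code{gifp_confusion} matrix.
#' @return object of class \code{gifp_metrics}: accuracy, precision, recall
#'   (micro), per_class data.frame, hit_rate, n.
#' @export
classifier_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix")
  acc <- sum(diag(cm)) / total
  per_class <- data.frame(
    label = rownames(cm),
    precision = ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), NA_real_),
    recall = ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  hit_rate <- NA_real_
  if (nrow(cm) == 2L && setequal(rownames(cm), .merged_registry)) {
    pred_active <- sum(cm[, "active"])
    hit_rate <- if (pred_active > 0) 100 * cm["active", "active"] / pred_active
                else NA_real_
  }
  structure(list(accuracy = acc, precision = acc, recall = acc,
                 per_class = per_class, hit_rate = hit_rate, n = total),
            class = "gifp_metrics")
}

#' @export
print.gifp_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f  precision %.2f  recall %.2f  (n = %d)\n",
              x$accuracy, x$precision, x$recall, x$n))
  if (!is.na(x$hit_rate)) cat(sprintf("hit rate (%%) %.1f\n", x$hit_rate))
  invisible(x)
}

#' Save / load a fitted classifier as a JSON artifact directory
#'
#' @param bundle a \code{gifp_classifier}.
#' @param dir artifact directory (created if absent): metadata.json carries
#'   the preprocessing state, configuration, class registry, CV score and
#'   seed; forest.json carries the serialized trees.
#' @export
save_classifier <- function(bundle, dir) {
  stopifnot(inherits(bundle, "gifp_classifier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- bundle[c("prep", "config", "classes", "cv_score", "seed")]
  # named numeric vectors must go out as objects, not nameless arrays
  for (nm in c("impute_means", "center", "scale")) {
    meta$prep[[nm]] <- as.list(meta$prep[[nm]])
  }
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(bundle$forest, file.path(dir, "forest.json"),
                       digits = NA)
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  forest <- jsonlite::read_json(file.path(dir, "forest.json"),
                                simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  forest <- lapply(forest, function(tr) {
    probs <- tr$probs
    if (!is.matrix(probs)) probs <- matrix(probs, nrow = length(tr$feature))
    list(feature = as.integer(tr$feature), threshold = as.numeric(tr$threshold),
         left = as.integer(tr$left), right = as.integer(tr$right),
         probs = matrix(as.numeric(probs), nrow = nrow(probs)))
  })
  prep <- meta$prep
  prep$encoders <- lapply(prep$encoders, as.character)
  prep$impute_means <- unlist(prep$impute_means)
  prep$center <- unlist(prep$center)
  prep$scale <- unlist(prep$scale)
  structure(list(prep = prep, config = meta$config, forest = forest,
                 classes = meta$classes, cv_score = meta$cv_score,
                 seed = meta$seed),
            class = "gifp_classifier")
}
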