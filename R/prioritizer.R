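#' Hyperparameter grid for the boosted-tree classifier
#'
#' Defaults are the full reference grid: learning_rate {0.01, 0.1, 0.5},
#' max_depth {1, 2, 3, 5, 10}, n_estimators 100, gamma {0, 0.3},
#' reg_lambda {0, 0.1, 1.0}, reg_alpha {0, 0.1, 1}, binary logistic
#' objective, 5-fold cross-validation. Grid iteration order (used to break
#' AUC ties toward the earliest row) nests learning_rate slowest, then
#' max_depth, gamma, reg_lambda, and reg_alpha fastest.
#'
#' @param learning_rate,max_depth,gamma,reg_lambda,reg_alpha candidate values.
#' @param n_estimators boosting rounds (fixed scalar).
#' @param cv_folds number of stratified CV folds, >= 2.
#' @return list of class \code{grid_config} with a \code{grid} data.frame.
#' @export
grid_config <- function(learning_rate = c(0.01, 0.1, 0.5),
                        max_depth = c(1L, 2L, 3L, 5L, 10L),
                        gamma = c(0, 0.3),
                        reg_lambda = c(0, 0.1, 1.0),
                        reg_alpha = c(0, 0.1, 1),
                        n_estimators = 100L, cv_folds = 5L) {
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  grid <- expand.grid(reg_alpha = reg_alpha, reg_lambda = reg_lambda,
                      gamma = gamma, max_depth = as.integer(max_depth),
                      learning_rate = learning_rate,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("learning_rate", "max_depth", "gamma", "reg_lambda",
                   "reg_alpha")]
  rownames(grid) <- NULL
  structure(list(grid = grid, n_estimators = as.integer(n_estimators),
                 cv_folds = as.integer(cv_folds)),
            class = "grid_config")
}

# internal: fit one boosted-tree model
xgb_fit <- function(x, y, params, n_estimators) {
  trees <- .xgb_train_cpp(as.matrix(x), as.numeric(y), n_estimators,
                          params$learning_rate, as.integer(params$max_depth),
                          params$gamma, params$reg_lambda, params$reg_alpha,
                          1.0)
  structure(list(trees = trees, params = params,
                 n_estimators = n_estimators), class = "xgb_model")
}

#' Predict positive-class probabilities from a fitted boosted-tree model
#' @param object an \code{xgb_model} from the ensemble fit.
#' @param newdata numeric feature matrix.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.xgb_model <- function(object, newdata, ...) {
  as.numeric(.xgb_predict_cpp(object$trees, as.matrix(newdata)))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: ties in scores contribute 1/2.
#'
#' @param scores numeric predictions.
#' @param labels binary 0/1 labels (both classes present).
#' @return AUC in [0,1].
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build resampled labeled datasets
#'
#' Each dataset pairs all positives with \code{n_negatives} genes sampled
#' uniformly without replacement (within a dataset) from the non-positive
#' universe; sampling is independent across datasets with per-dataset child
#' seeds. Mirrors the 100 x (31 positive + 500 negative) resampling design.
#'
#' @param latent N x d latent feature matrix with gene rownames.
#' @param positives character vector of positive genes (subset of rownames).
#' @param n_datasets number of datasets, default 100.
#' @param n_negatives negatives per dataset, default 500.
#' @param seed run seed.
#' @return list of \code{labeled_dataset}s: each has \code{x}, \code{y}
#'   (1 = positive), \code{genes}, \code{index}.
#' @export
build_datasets <- function(latent, positives, n_datasets = 100L,
                           n_negatives = 500L, seed = 1L) {
  latent <- as.matrix(latent)
  if (is.null(rownames(latent))) stop("latent matrix needs gene rownames")
  universe <- rownames(latent)
  if (!all(positives %in% universe))
    stop("positives must be a subset of the latent matrix genes")
  negpool <- setdiff(universe, positives)
  if (n_negatives > length(negpool))
    stop(sprintf("requested %d negatives but only %d genes are available",
                 n_negatives, length(negpool)))
  lapply(seq_len(n_datasets), function(k) {
    neg <- with_seed(seed + k, sample(negpool, n_negatives))
    genes <- c(sort(positives), sort(neg))
    structure(list(x = latent[genes, , drop = FALSE],
                   y = c(rep(1L, length(positives)),
                         rep(0L, n_negatives)),
                   genes = genes, index = k),
              class = "labeled_dataset")
  })
}

#' SMOTE: synthetic minority oversampling
#'
#' Each synthetic row is \code{x + u * (x_nn - x)} for a uniformly chosen
#' minority base row \code{x}, one of its \code{k} Euclidean nearest minority
#' neighbors \code{x_nn} (uniform among the k; ties broken by row order), and
#' \code{u ~ Uniform(0,1)}. Only minority rows participate, so synthetic rows
#' lie on segments between minority pairs (hence inside their bounding box).
#'
#' @param minority_rows numeric matrix of minority-class feature rows (>= 2).
#' @param k neighbor count, default 2 (capped at \code{nrow - 1}).
#' @param n_synthetic number of synthetic rows to create.
#' @param seed integer seed.
#' @return \code{n_synthetic} x d numeric matrix.
#' @export
smote_oversample <- function(minority_rows, k = 2L, n_synthetic, seed = 1L) {
  minority_rows <- as.matrix(minority_rows)
  n <- nrow(minority_rows)
  if (n < 2L) stop("SMOTE needs at least 2 minority rows to interpolate")
  if (k < 1L) stop("k must be >= 1")
  k <- min(as.integer(k), n - 1L)
  if (n_synthetic == 0L)
    return(minority_rows[0L, , drop = FALSE])
  d2 <- as.matrix(stats::dist(minority_rows))^2
  diag(d2) <- Inf
  ord <- apply(d2, 1L, function(row) order(row)[seq_len(k)])
  nn_idx <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
  with_seed(seed, {
    base <- sample.int(n, n_synthetic, replace = TRUE)
    pick <- sample.int(k, n_synthetic, replace = TRUE)
    u <- stats::runif(n_synthetic)
    nb <- nn_idx[cbind(base, pick)]
    minority_rows[base, , drop = FALSE] +
      u * (minority_rows[nb, , drop = FALSE] -
           minority_rows[base, , drop = FALSE])
  })
}

# internal: stratified fold assignment, seeded; errors if any fold would be
# positive-free
stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  if (min(table(factor(folds[y == 1L], levels = seq_len(n_folds)))) == 0L)
    stop("a CV fold has no positives; check stratification / class sizes")
  folds
}

#' Grid-search a boosted-tree classifier on one dataset
#'
#' For every grid row, stratified \code{cv_folds}-fold CV over the ORIGINAL
#' rows: within each fold, SMOTE (with \code{smote_k}) is applied only to the
#' training portion to synthesize minority rows up to class parity; the
#' validation fold contains original rows only (the data split happens before
#' oversampling, so no synthetic row can leak into validation — the returned
#' \code{leakage_audit} counts synthetic rows seen in validation and is zero
#' by construction). The grid row with the highest mean fold AUC wins (ties
#' to the earliest row), and is refitted on the full SMOTE-balanced dataset.
#'
#' @param dataset a \code{labeled_dataset}.
#' @param grid a \code{grid_config}.
#' @param seed integer seed (fold assignment and SMOTE draws).
#' @param smote_k SMOTE neighbor count, default 2.
#' @return list of class \code{fitted_dataset}: \code{model},
#'   \code{best_params}, \code{cv_auc}, \code{grid_results},
#'   \code{leakage_audit}.
#' @export
fit_one_dataset <- function(dataset, grid, seed = 1L, smote_k = 2L) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(grid, "grid_config"))
  x <- dataset$x; y <- dataset$y
  if (length(unique(y)) < 2L) stop("dataset must contain both classes")
  folds <- stratified_folds(y, grid$cv_folds, seed)
  # pre-build per-fold SMOTE-balanced training sets (shared across grid rows:
  # the oversampled points do not depend on the classifier hyperparameters)
  fold_data <- lapply(seq_len(grid$cv_folds), function(f) {
    tr <- which(folds != f); va <- which(folds == f)
    ytr <- y[tr]
    n_min <- min(table(ytr)); n_maj <- max(table(ytr))
    minority_class <- as.integer(names(which.min(table(ytr))))
    syn <- smote_oversample(x[tr[ytr == minority_class], , drop = FALSE],
                            k = smote_k, n_synthetic = n_maj - n_min,
                            seed = seed + 1000L + f)
    list(xtr = rbind(x[tr, , drop = FALSE], syn),
         ytr = c(ytr, rep(minority_class, nrow(syn))),
         provenance = c(rep("original", length(tr)),
                        rep("synthetic", nrow(syn))),
         xva = x[va, , drop = FALSE], yva = y[va],
         va_provenance = rep("original", length(va)))
  })
  leakage <- sum(vapply(fold_data, function(fd)
    sum(fd$va_provenance != "original"), 0L))
  g <- grid$grid
  fold_auc <- matrix(NA_real_, nrow(g), grid$cv_folds)
  for (gi in seq_len(nrow(g))) {
    params <- as.list(g[gi, ])
    for (f in seq_len(grid$cv_folds)) {
      fd <- fold_data[[f]]
      m <- xgb_fit(fd$xtr, fd$ytr, params, grid$n_estimators)
      fold_auc[gi, f] <- auc_roc(predict(m, fd$xva), fd$yva)
    }
  }
  mean_auc <- rowMeans(fold_auc)
  best <- which.max(mean_auc)  # which.max returns the first maximum
  # refit best grid point on the full SMOTE-balanced dataset
  n_min <- min(table(y)); n_maj <- max(table(y))
  minority_class <- as.integer(names(which.min(table(y))))
  syn <- smote_oversample(x[y == minority_class, , drop = FALSE],
                          k = smote_k, n_synthetic = n_maj - n_min,
                          seed = seed + 2000L)
  model <- xgb_fit(rbind(x, syn), c(y, rep(minority_class, nrow(syn))),
                   as.list(g[best, ]), grid$n_estimators)
  structure(list(model = model, best_params = as.list(g[best, ]),
                 cv_auc = mean_auc[best],
                 grid_results = cbind(g, mean_auc = mean_auc),
                 leakage_audit = leakage, dataset_index = dataset$index),
            class = "fitted_dataset")
}

#' Fit the classifier ensemble over all resampled datasets
#'
#' One grid-searched boosted-tree model per dataset, with per-dataset child
#' seeds derived from the run seed.
#'
#' @param datasets list from \code{\link{build_datasets}}.
#' @param grid a \code{grid_config}.
#' @param seed run seed.
#' @param smote_k SMOTE neighbor count, default 2.
#' @return list of class \code{ensemble_result}: \code{fits}, \code{mean_cv_auc},
#'   \code{cv_auc} (per dataset).
#' @export
fit_ensemble <- function(datasets, grid, seed = 1L, smote_k = 2L) {
  if (length(datasets) == 0L) stop("need at least one dataset")
  fits <- lapply(datasets, function(ds)
    fit_one_dataset(ds, grid, seed = seed + 10000L * ds$index,
                    smote_k = smote_k))
  aucs <- vapply(fits, function(f) f$cv_auc, 0)
  structure(list(fits = fits, cv_auc = aucs, mean_cv_auc = mean(aucs)),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result: %d models, mean CV AUC %.3f\n",
              length(x$fits), x$mean_cv_auc))
  invisible(x)
}

#' Mean positive-class probability per gene
#'
#' Applies every ensemble model to the latent rows of all genes NOT in the
#' known-positive set and averages the positive-class probabilities; the
#' result is the prioritization score, sorted descending.
#'
#' @param ensemble an \code{ensemble_result}.
#' @param latent N x d matrix with gene rownames.
#' @param positives known positive genes (excluded from the ranking).
#' @return named numeric vector of mean probabilities, descending.
#' @export
score_genes <- function(ensemble, latent, positives = character()) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  latent <- as.matrix(latent)
  if (is.null(rownames(latent))) stop("latent matrix needs gene rownames")
  genes <- setdiff(rownames(latent), positives)
  x <- latent[genes, , drop = FALSE]
  probs <- vapply(ensemble$fits, function(f) predict(f$model, x),
                  numeric(length(genes)))
  if (length(genes) == 1L) probs <- matrix(probs, nrow = 1L)
  s <- rowMeans(probs)
  names(s) <- genes
  sort(s, decreasing = TRUE)
}

#' Select putative targets above a probability threshold
#'
#' Genes with mean positive-class probability strictly greater than
#' \code{threshold} (default 0.75), sorted descending.
#'
#' @param scores named scores from \code{\link{score_genes}}.
#' @param threshold cutoff, default 0.75.
#' @return named numeric vector of class \code{putative_target_set}.
#' @export
select_putative <- function(scores, threshold = 0.75) {
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0,1]")
  sel <- sort(scores[scores > threshold], decreasing = TRUE)
  if (length(sel) == 0L)
    warning("no gene exceeds the probability threshold ", threshold)
  structure(sel, threshold = threshold, class = "putative_target_set")
}

#' Write ranked gene scores as TSV
#' @param scores named scores.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gene_scores <- function(scores, path) {
  utils::write.table(
    data.frame(gene = names(scores),
               mean_probability = sprintf("%.10f", as.numeric(scores)),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
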