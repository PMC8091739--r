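# deterministic toy latent matrix with a separable positive class
toy_latent <- function(n = 40L, d = 4L, n_pos = 10L, shift = 10, seed = 1L) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * d), n, d,
              dimnames = list(sprintf("g%03d", seq_len(n)),
                              paste0("dim_", seq_len(d))))
  pos <- rownames(x)[seq_len(n_pos)]
  x[pos, 1L] <- x[pos, 1L] + shift
  list(x = x, pos = pos)
}

test_that("build_datasets pairs fixed positives with resampled negatives", {
  tl <- toy_latent()
  ds <- build_datasets(tl$x, tl$pos, n_datasets = 3L, n_negatives = 30L,
                       seed = 1L)
  expect_length(ds, 3L)
  for (d in ds) {
    expect_equal(nrow(d$x), 40L)
    expect_equal(sum(d$y), 10L)
    expect_setequal(d$genes[d$y == 1L], tl$pos)
    expect_equal(anyDuplicated(d$genes), 0L)
  }
  # exhaustion: all negatives used -> identical datasets
  ds_all <- build_datasets(tl$x, tl$pos, n_datasets = 2L, n_negatives = 30L,
                           seed = 2L)
  expect_setequal(ds_all[[1L]]$genes, ds_all[[2L]]$genes)
  expect_error(build_datasets(tl$x, tl$pos, n_datasets = 1L,
                              n_negatives = 31L), "available")
})

test_that("SMOTE interpolates on segments between minority rows", {
  two <- rbind(c(0, 0), c(2, 2))
  syn <- smote_oversample(two, k = 1L, n_synthetic = 50L, seed = 3L)
  expect_equal(syn[, 1L], syn[, 2L])          # collinear on the diagonal
  expect_true(all(syn >= 0 & syn <= 2))

  same <- rbind(c(1, 5), c(1, 5), c(1, 5))
  syn2 <- smote_oversample(same, k = 2L, n_synthetic = 10L, seed = 4L)
  expect_true(all(syn2[, 1L] == 1 & syn2[, 2L] == 5))

  expect_error(smote_oversample(matrix(1, 1, 3), n_synthetic = 5L),
               "at least 2")
  # determinism
  m <- matrix(stats::runif(20), 10)
  expect_identical(smote_oversample(m, 2L, 7L, seed = 9L),
                   smote_oversample(m, 2L, 7L, seed = 9L))
})

test_that("synthetic rows stay inside the minority bounding box", {
  set.seed(11)
  mino <- matrix(stats::rnorm(31 * 100), 31, 100)
  syn <- smote_oversample(mino, k = 2L, n_synthetic = 469L, seed = 12L)
  lo <- apply(mino, 2L, min); hi <- apply(mino, 2L, max)
  expect_true(all(t(syn) >= lo - 1e-12))
  expect_true(all(t(syn) <= hi + 1e-12))
})

test_that("grid search finds a separable dataset and guards leakage", {
  tl <- toy_latent()
  ds <- build_datasets(tl$x, tl$pos, n_datasets = 1L, n_negatives = 30L,
                       seed = 5L)[[1L]]
  fit <- fit_one_dataset(ds, desk_grid(), seed = 6L)
  expect_equal(fit$cv_auc, 1.0)
  expect_equal(fit$leakage_audit, 0L)
  expect_true(all(c("learning_rate", "max_depth", "gamma", "reg_lambda",
                    "reg_alpha") %in% names(fit$best_params)))

  # grid iteration order: learning_rate slowest, reg_alpha fastest
  g <- grid_config()$grid
  expect_equal(nrow(g), 270L)
  expect_equal(g$learning_rate[1:90], rep(0.01, 90))
  expect_equal(g$reg_alpha[1:3], c(0, 0.1, 1))
})

test_that("shuffled labels yield chance-level CV AUC", {
  tl <- toy_latent(shift = 0)
  aucs <- vapply(1:6, function(s) {
    set.seed(100 + s)
    y <- sample(c(rep(1L, 10L), rep(0L, 30L)))
    genes <- sprintf("g%03d", 1:40)
    ds <- structure(list(x = tl$x, y = y, genes = genes, index = 1L),
                    class = "labeled_dataset")
    fit_one_dataset(ds, desk_grid(), seed = s)$cv_auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("ensembles are deterministic and separable data scores 1", {
  tl <- toy_latent()
  ds <- build_datasets(tl$x, tl$pos, n_datasets = 3L, n_negatives = 25L,
                       seed = 7L)
  e1 <- fit_ensemble(ds, desk_grid(), seed = 8L)
  e2 <- fit_ensemble(ds, desk_grid(), seed = 8L)
  expect_equal(e1$mean_cv_auc, 1.0)
  expect_identical(lapply(e1$fits, `[[`, "best_params"),
                   lapply(e2$fits, `[[`, "best_params"))
  expect_identical(e1$cv_auc, e2$cv_auc)
})

test_that("score_genes excludes known positives and ranks them out", {
  tl <- toy_latent()
  ds <- build_datasets(tl$x, tl$pos, n_datasets = 2L, n_negatives = 25L,
                       seed = 9L)
  ens <- fit_ensemble(ds, desk_grid(), seed = 10L)
  sc <- score_genes(ens, tl$x, tl$pos)
  expect_length(sc, 40L - 10L)
  expect_false(any(tl$pos %in% names(sc)))
  expect_true(all(diff(sc) <= 0))
  expect_true(all(sc >= 0 & sc <= 1))

  # held-out positives are recovered near the top
  held <- tl$pos[1:3]
  train_pos <- setdiff(tl$pos, held)
  ds2 <- build_datasets(tl$x, train_pos, n_datasets = 2L, n_negatives = 20L,
                        seed = 11L)
  sc2 <- score_genes(fit_ensemble(ds2, desk_grid(), seed = 12L), tl$x,
                     train_pos)
  ranks <- match(held, names(sc2))
  expect_lt(stats::median(ranks), length(sc2) / 4)
})

test_that("select_putative uses a strict threshold and stays monotone", {
  sc <- c(a = 0.76, b = 0.75, c = 0.2)
  sel <- select_putative(sc)
  expect_equal(names(sel), "a")
  expect_warning(sel0 <- select_putative(c(x = 0.1)), "threshold")
  expect_length(sel0, 0L)
  expect_error(select_putative(c(a = 1.2)), "0,1")

  set.seed(13)
  sc2 <- stats::setNames(stats::runif(50), paste0("g", 1:50))
  sizes <- vapply(c(0.2, 0.5, 0.8),
                  function(th) length(suppressWarnings(
                    select_putative(sc2, th))), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("auc_roc is the rank statistic", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(c(0.1, 0.9, 0.2, 0.8), c(1, 0, 1, 0)), 0)
  expect_equal(auc_roc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(auc_roc(c(0.5, 0.4), c(1, 1)), "both classes")
})
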