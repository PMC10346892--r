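fake_circuit_index <- function(n_subjects, n_circuits) {
  tidyr::expand_grid(subject_id = sprintf("S%02d", seq_len(n_subjects)),
                     circuit_id = sprintf("C%02d", seq_len(n_circuits)))
}

test_that("LOSO folds reproduce the 56/14/4 benchmark split", {
  idx <- fake_circuit_index(8, 10)
  folds <- make_loso_folds(idx, seed = 1)
  expect_equal(length(unique(folds$fold)), 8)
  counts <- dplyr::count(folds, fold, split)
  expect_true(all(counts$n[counts$split == "train"] == 56))
  expect_true(all(counts$n[counts$split == "val"] == 14))
  expect_true(all(counts$n[counts$split == "test"] == 4))
  for (f in unique(folds$fold)) {
    ff <- folds[folds$fold == f, ]
    expect_true(all(ff$subject_id[ff$split == "test"] == ff$test_subject[1]))
    expect_false(any(ff$subject_id[ff$split != "test"] == ff$test_subject[1]))
    expect_false(anyDuplicated(ff[, c("subject_id", "circuit_id")]) > 0)
  }
})

test_that("fold construction scales to small designs and flags shortages", {
  idx <- fake_circuit_index(2, 3)
  folds <- make_loso_folds(idx, val_per_subject = 1, test_per_subject = 2,
                           train_cap = 8, seed = 3)
  counts <- dplyr::count(folds, fold, split)
  expect_true(all(counts$n[counts$split == "train"] == 2))
  expect_true(all(counts$n[counts$split == "val"] == 1))
  expect_true(all(counts$n[counts$split == "test"] == 2))
  expect_error(make_loso_folds(fake_circuit_index(2, 3), val_per_subject = 3,
                               test_per_subject = 1),
               "S01", class = "gaitrec_config_error")
  expect_error(make_loso_folds(fake_circuit_index(1, 10)),
               class = "gaitrec_config_error")
})

test_that("confusion matrices count true/predicted pairs in canonical order", {
  lv <- activity_levels()
  cm <- confusion_matrix(lv[c(1, 1, 2)], lv[c(1, 2, 2)])
  expect_equal(cm["sitting", "sitting"], 1L)
  expect_equal(cm["sitting", "standing"], 1L)
  expect_equal(cm["standing", "standing"], 1L)
  expect_equal(sum(cm), 3L)
  expect_equal(rownames(cm), lv)

  y <- withr::with_seed(5, sample(lv, 200, replace = TRUE))
  expect_equal(confusion_matrix(y, y), diag(table(factor(y, lv))),
               ignore_attr = TRUE)
  expect_error(confusion_matrix(lv[1:3], lv[1:2]),
               class = "gaitrec_shape_error")
})

test_that("accuracy is the diagonal mass and F1 matches Eq-style anchors", {
  cm <- matrix(0L, 7, 7, dimnames = list(truth = activity_levels(),
                                         predicted = activity_levels()))
  cm[1, 1] <- 9L; cm[2, 1] <- 1L; cm[1, 2] <- 1L
  f1 <- f1_per_class(cm)
  expect_equal(f1$f1[1], 0.9)  # TP 9, FP 1, FN 1
  expect_true(f1$degenerate[3])
  expect_equal(f1$f1[3], 0)

  perfect <- diag(5L)
  dimnames(perfect) <- list(letters[1:5], letters[1:5])
  expect_equal(f1_per_class(perfect)$f1, rep(1, 5))
  expect_equal(accuracy(perfect), 1)
})

test_that("F1 equals the precision/recall harmonic mean on random matrices", {
  withr::with_seed(8, {
    for (i in 1:100) {
      k <- sample(2:7, 1)
      cm <- matrix(rpois(k * k, 3), k, k,
                   dimnames = list(letters[1:k], letters[1:k]))
      expect_equal(f1_per_class(cm)$f1, naive_f1(cm), tolerance = 1e-12)
      expect_equal(accuracy(cm), sum(diag(cm)) / sum(cm))
    }
  })
})

test_that("metrics agree with an independent oracle on random predictions", {
  lv <- activity_levels()
  withr::with_seed(12, {
    y <- sample(lv, 500, replace = TRUE)
    p <- sample(lv, 500, replace = TRUE)
  })
  cm <- confusion_matrix(y, p)
  expect_equal(accuracy(cm), mean(y == p), tolerance = 1e-12)
  expect_equal(macro_f1(cm), mean(naive_f1(cm)), tolerance = 1e-12)
})

test_that("a small LOSO experiment runs end to end and is reproducible", {
  circ <- tiny_dataset(n_subjects = 3, circuits_per_subject = 4,
                       duration_range = c(0.5, 0.8), seed = 31)
  rep1 <- run_experiment(circ, seg_cfg = tiny_seg(),
                         ann_cfg = ann_config(hidden = 10, max_iters = 40),
                         val_per_subject = 1, test_per_subject = 2,
                         train_cap = 3, seed = 5)
  m <- tidy(rep1)
  expect_equal(nrow(m), 9)  # 3 folds x 3 splits
  expect_true(all(m$accuracy >= 0 & m$accuracy <= 1))
  expect_equal(length(rep1$confusion), 3)
  expect_named(rep1$confusion[["1"]], c("train", "val", "test"))
  # confusion totals equal split sizes, accuracy = trace / N
  for (f in names(rep1$confusion)) {
    for (s in names(rep1$confusion[[f]])) {
      cm <- rep1$confusion[[f]][[s]]
      row <- m[m$fold == as.integer(f) & m$split == s, ]
      expect_equal(sum(cm), row$n)
      expect_equal(accuracy(cm), row$accuracy)
    }
  }
  g <- glance(rep1)
  expect_equal(g$n_folds, 3)
  expect_true(g$mean_train_accuracy > 0.9)  # seen-subject training is easy

  rep2 <- run_experiment(circ, seg_cfg = tiny_seg(),
                         ann_cfg = ann_config(hidden = 10, max_iters = 40),
                         val_per_subject = 1, test_per_subject = 2,
                         train_cap = 3, seed = 5)
  expect_identical(tidy(rep1), tidy(rep2))
})

test_that("pipeline timing reports non-negative per-row summaries", {
  circ <- tiny_dataset()
  st <- stack_context(build_feature_table(circ, tiny_seg()), 3)
  fit <- gait_ann(balance_classes(st, seed = 1),
                  ann_config(hidden = 5, max_iters = 10))
  tm <- time_pipeline(fit, circ, tiny_seg(), n_rows = 50)
  expect_equal(tm$stage, c("preprocess", "inference"))
  expect_true(all(tm$mean_us_per_row > 0))
  expect_true(all(tm$sd_us_per_row >= 0))
  tm1 <- time_pipeline(fit, circ[circ$circuit_id == "C01", ], tiny_seg(),
                       n_rows = 1)
  expect_equal(tm1$sd_us_per_row[2], 0)
})

test_that("tidiers and plots expose model and report summaries", {
  circ <- tiny_dataset()
  st <- stack_context(build_feature_table(circ, tiny_seg()), 3)
  fit <- gait_ann(balance_classes(st, seed = 1),
                  ann_config(hidden = 5, max_iters = 15))
  tr <- tidy(fit)
  expect_true(all(c("iter", "cost", "grad_norm", "wolfe_ok") %in% names(tr)))
  expect_equal(glance(fit)$hidden, 5)
  expect_s3_class(autoplot(fit), "ggplot")
  cm <- confusion_matrix(st$activity, predict(fit, st))
  expect_s3_class(plot_confusion(cm), "ggplot")
})
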