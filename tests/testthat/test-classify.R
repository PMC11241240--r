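test_that("75/25 splitting reproduces the canonical sizes", {
  big <- data.frame(x = seq_len(1820))
  sp <- split_table(big, seed = 3)
  expect_equal(nrow(sp$train), 1365L)
  expect_equal(nrow(sp$test), 455L)
  expect_equal(length(intersect(rownames(sp$train), rownames(sp$test))), 0L)
  small <- split_table(data.frame(x = 1:4), seed = 1)
  expect_equal(nrow(small$train), 3L)
  expect_equal(nrow(small$test), 1L)
  # determinism and RNG hygiene
  expect_identical(split_table(big, seed = 7), split_table(big, seed = 7))
  expect_error(split_table(data.frame(x = 1)), "at least 2")
})

test_that("preprocessing encodes, imputes and standardizes like the contract says", {
  tr <- data.frame(complex_id = c("a", "b", "c"), label = "agonist",
                   is_modeled = c(0L, 1L, 0L),
                   `3.32_sum` = c(1, NA, 3),
                   `3.32_type1` = c("Hbond", "NA", "None"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  st <- fit_preprocessing(tr)
  m <- apply_preprocessing(st, tr)
  # mean imputation: NA -> 2, then standardized to mean 0 sd 1
  expect_equal(unname(colMeans(m)), rep(0, ncol(m)), tolerance = 1e-8)
  sds <- apply(m, 2, sd)
  expect_equal(unname(sds[sds > 0]), rep(1, sum(sds > 0)), tolerance = 1e-6)
  raw <- gifp:::.encode_impute(st, tr)
  expect_equal(unname(raw[, "3.32_sum"]), c(1, 2, 3))
  # categorical "NA" is its own ordinal category
  expect_equal(length(st$encoders$`3.32_type1`), 3L)
  # unseen category at predict time -> reserved code, no crash
  new <- tr[1, ]; new$`3.32_type1` <- "Covalent"
  m2 <- apply_preprocessing(st, new)
  expect_true(is.finite(m2[, "3.32_type1"]))
  raw2 <- gifp:::.encode_impute(st, new)
  expect_equal(unname(raw2[, "3.32_type1"]), 3)  # reserved = registry size
  # all-NA numeric column imputes to 0 with a warning
  tr2 <- tr; tr2$`3.32_sum` <- NA_real_
  expect_warning(st2 <- fit_preprocessing(tr2), "all-NA")
  expect_equal(unname(st2$impute_means["3.32_sum"]), 0)
})

test_that("training rejects degenerate labels and interpolates separable data", {
  tab <- toy_feature_table(n_per_class = 15, seed = 5)
  cfg <- forest_config(n_trees = 80)
  expect_error(train_classifier(tab[tab$label == "agonist", ], config = cfg),
               "single class")
  expect_error(train_classifier(transform(tab, label = "mystery"),
                                config = cfg), "outside the class registry")
  b <- train_classifier(tab, seed = 2, config = cfg)
  # unpruned no-bootstrap forest memorizes a separable training set
  pr <- predict_classifier(b, tab)
  expect_equal(mean(pr$pred_label == pr$true_label), 1.0)
  expect_gte(b$cv_score, 0.9)
  # probabilities sum to 1 per row
  psum <- rowSums(pr[, grep("^prob_", names(pr))])
  expect_equal(psum, rep(1, nrow(pr)), tolerance = 1e-9)
  # determinism: same seed, same predictions
  b2 <- train_classifier(tab, seed = 2, config = cfg)
  expect_identical(predict_classifier(b2, tab)$pred_label, pr$pred_label)
  # empty matrix -> empty prediction set
  expect_equal(nrow(predict_classifier(b, tab[0, ])), 0L)
  # fold reduction warning below 10 rows
  tiny <- tab[c(1:4, 16:19), ]
  expect_warning(train_classifier(tiny, config = forest_config(n_trees = 10)),
                 "reducing CV folds")
})

test_that("model artifacts round-trip through the JSON directory format", {
  tab <- toy_feature_table(n_per_class = 10, seed = 8)
  b <- train_classifier(tab, seed = 4, config = forest_config(n_trees = 25))
  dir <- file.path(tempdir(), "gifp-model-test")
  save_classifier(b, dir)
  b2 <- load_classifier(dir)
  expect_identical(predict_classifier(b2, tab)$pred_label,
                   predict_classifier(b, tab)$pred_label)
  expect_equal(b2$cv_score, b$cv_score)
})

test_that("merged-active relabeling follows the 3-to-1 collapse", {
  expect_equal(merge_active("inverse_agonist"), "active")
  expect_equal(merge_active("agonist"), "active")
  expect_equal(merge_active("inactive"), "inactive")
  expect_error(merge_active("banana"), "unknown label")
})

test_that("merging never lowers accuracy (1000 random prediction sets)", {
  classes <- c("agonist", "antagonist", "inverse_agonist", "inactive")
  set.seed(77)
  for (rep in 1:1000) {
    n <- sample(3:40, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    acc4 <- mean(truth == pred)
    acc2 <- mean(merge_active(truth) == merge_active(pred))
    expect_gte(acc2, acc4)
  }
})

test_that("majority voting reproduces the worked example and its tie-break", {
  mk_preds <- function(labels, probs = NULL) {
    classes <- c("agonist", "antagonist", "inverse_agonist", "inactive")
    df <- data.frame(model_id = "m1", ligand_id = "L1", pred_label = labels,
                     stringsAsFactors = FALSE)
    for (cl in classes) {
      df[[paste0("prob_", cl)]] <- ifelse(labels == cl, 0.7, 0.1)
    }
    if (!is.null(probs)) {
      df$prob_agonist <- probs$agonist; df$prob_inactive <- probs$inactive
    }
    class(df) <- c("gifp_predictions", "data.frame")
    df
  }
  # 3 agonist + 2 inactive poses -> agonist
  v <- suppressWarnings(majority_vote(mk_preds(
    c("agonist", "agonist", "agonist", "inactive", "inactive"))))
  expect_equal(v$pred_label, "agonist")
  expect_equal(v$n_poses, 5L)
  # unanimous inactive
  v2 <- suppressWarnings(majority_vote(mk_preds(rep("inactive", 5))))
  expect_equal(v2$pred_label, "inactive")
  # 2-pose tie broken by summed probability (1.3 vs 0.7)
  tie <- mk_preds(c("agonist", "inactive"),
                  probs = list(agonist = c(0.7, 0.6), inactive = c(0.3, 0.4)))
  expect_warning(v3 <- majority_vote(tie), "odd number")
  expect_equal(v3$pred_label, "agonist")
})

test_that("confusion matrices count with actual rows and predicted columns", {
  cm <- confusion(c("a", "a", "b"), c("a", "a", "b"), labels = c("a", "b"))
  expect_equal(unname(diag(cm)), c(2L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  cm2 <- confusion(c("a", "b"), c("b", "a"), labels = c("a", "b"))
  expect_equal(unclass(t(cm2)), unclass(confusion(c("b", "a"), c("a", "b"),
                                                  labels = c("a", "b"))),
               ignore_attr = TRUE)
  expect_error(confusion("a", "z", labels = c("a", "b")), "outside")
})

test_that("micro precision = micro recall = accuracy on random matrices", {
  set.seed(31)
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    cm <- structure(matrix(rpois(k * k, 5), k, k,
                           dimnames = list(letters[1:k], letters[1:k])),
                    class = c("gifp_confusion", "matrix"))
    if (sum(cm) == 0) next
    m <- classifier_metrics(cm)
    expect_equal(m$precision, m$accuracy)
    expect_equal(m$recall, m$accuracy)
    expect_equal(m$accuracy, sum(diag(cm)) / sum(cm))
  }
})

test_that("hit rate is the active-class precision in percent", {
  cm <- confusion(rep(c("active", "inactive"), c(6, 4)),
                  c(rep("active", 5), "inactive", "active", "active",
                    "inactive", "inactive"),
                  labels = c("active", "inactive"))
  m <- classifier_metrics(cm)
  expect_equal(m$hit_rate,
               100 * m$per_class$precision[m$per_class$label == "active"])
  # zero predicted actives -> NA
  cm0 <- confusion(c("active", "inactive"), c("inactive", "inactive"),
                   labels = c("active", "inactive"))
  expect_true(is.na(classifier_metrics(cm0)$hit_rate))
  expect_error(classifier_metrics(cm0 * 0L), "empty")
})
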