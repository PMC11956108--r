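test_that("predictive ability is the squared Pearson correlation", {
  expect_equal(as.numeric(predictive_ability(1:5, 1:5)), 1)
  expect_warning(ab <- predictive_ability(1:4, rep(2, 4)), "constant")
  expect_equal(as.numeric(ab), 0)
  obs <- c(1, 2, 3, 4); pred <- c(1.1, 1.9, 3.2, 3.8)
  # hand Pearson computation, written out
  r_hand <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(as.numeric(predictive_ability(obs, pred)), r_hand^2,
               tolerance = 1e-6)
  expect_equal(as.numeric(predictive_ability(obs, pred, method = "R2")),
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
  expect_error(predictive_ability(1:3, 1:4), "mismatch")
})

test_that("fold partitions are balanced and reproducible", {
  f1 <- cv_folds(100, 10, seed = 3, rep = 2)
  f2 <- cv_folds(100, 10, seed = 3, rep = 2)
  expect_identical(f1, f2)
  expect_equal(unname(table(f1)), rep(10L, 10), ignore_attr = TRUE)
  expect_false(identical(f1, cv_folds(100, 10, seed = 3, rep = 3)))
  expect_error(cv_folds(10, 1, 1), "k must be")
})

test_that("cross_validate is deterministic and covers every hybrid once", {
  d <- small_bundle()$data
  cv1 <- cross_validate(d, "trait", "GP", k = 5, repeats = 2, seed = 4)
  cv2 <- cross_validate(d, "trait", "GP", k = 5, repeats = 2, seed = 4)
  expect_identical(cv1$repeat_ability, cv2$repeat_ability)
  expect_identical(cv1$predictions, cv2$predictions)
  for (r in 1:2) {
    expect_equal(sort(unique(cv1$fold_assignments[[r]])), 1:5)
    expect_false(anyNA(cv1$predictions[, r]))
  }
  expect_equal(cv1$mean_ability, mean(cv1$repeat_ability))
})

test_that("no test-fold phenotype leaks into its own prediction", {
  # canary: perturbing the phenotypes of fold-1 hybrids must leave the
  # fold-1 predictions bitwise unchanged (they are produced by a model
  # trained without them), for kernel and marker-selecting configurations
  sim <- small_bundle()
  d <- sim$data
  for (tag in c("GP", "MM_GP")) {
    cv <- cross_validate(d, "trait", tag, k = 5, repeats = 1, seed = 6)
    fold1 <- which(cv$fold_assignments[[1]] == 1)
    d2 <- d
    idx <- match(rownames(cv$predictions)[fold1],
                 rownames(d2$hybrid_phenotypes$values))
    d2$hybrid_phenotypes$values[idx, "trait"] <-
      rev(d2$hybrid_phenotypes$values[idx, "trait"]) + 5
    cv2 <- cross_validate(d2, "trait", tag, k = 5, repeats = 1, seed = 6)
    expect_identical(cv$predictions[fold1, 1], cv2$predictions[fold1, 1])
  }
})

test_that("marker modes select markers without touching hybrid data", {
  d <- small_bundle()$data
  cv_g <- cross_validate(d, "trait", "MM_GP", k = 5, repeats = 1,
                         seed = 2, marker_mode = "global")
  expect_s3_class(cv_g, "CVResult")
  expect_error(cross_validate(d, "trait", "MM_GP", k = 5, repeats = 1,
                              seed = 2, marker_mode = "fixed"),
               "marker_ids")
  cv_f <- cross_validate(d, "trait", "MM_GP", k = 5, repeats = 1,
                         seed = 2, marker_mode = "fixed",
                         marker_ids = metabolite_ids(d$metabolome)[1:4])
  expect_s3_class(cv_f, "CVResult")
})

test_that("compare_models assigns letters consistently", {
  d <- small_bundle()$data
  cv1 <- cross_validate(d, "trait", "GP", k = 5, repeats = 3, seed = 5)
  cmp_self <- compare_models(list(cv1, cv1))
  expect_equal(unname(cmp_self$p_matrix[1, 2]), 1)
  expect_equal(cmp_self$table$letters[1], cmp_self$table$letters[2])
  # clearly separated synthetic results
  cv_hi <- cv1; cv_hi$repeat_ability <- cv1$repeat_ability + 0.2
  cv_hi$mean_ability <- mean(cv_hi$repeat_ability)
  cv_hi$model_tag <- "MM_GP"
  cmp <- compare_models(list(cv1, cv_hi))
  expect_lt(cmp$p_matrix[1, 2], 0.01)
  expect_false(cmp$table$letters[1] == cmp$table$letters[2])
  cv_bad <- cross_validate(d, "trait", "GP", k = 5, repeats = 2, seed = 5)
  expect_error(compare_models(list(cv1, cv_bad)), "share")
})

test_that("random metabolite control reuses folds and respects seeds", {
  d <- small_bundle()$data
  ctrl <- random_metabolite_control(d, "trait", n_markers = 4,
                                    n_draws = 2, seed = 8, k = 5,
                                    repeats = 1)
  ctrl2 <- random_metabolite_control(d, "trait", n_markers = 4,
                                     n_draws = 2, seed = 8, k = 5,
                                     repeats = 1)
  expect_identical(ctrl$draws, ctrl2$draws)
  expect_identical(ctrl$mean_abilities, ctrl2$mean_abilities)
  expect_error(random_metabolite_control(d, "trait", n_markers = 0,
                                         n_draws = 1, seed = 1),
               ">= 1")
  # degenerate draw: the full metabolome reproduces M_GP exactly
  m <- ncol(d$metabolome$values)
  ctrl_full <- random_metabolite_control(d, "trait", n_markers = m,
                                         n_draws = 1, seed = 8, k = 5,
                                         repeats = 1)
  mgp <- cross_validate(d, "trait", "M_GP", k = 5, repeats = 1, seed = 8)
  expect_equal(ctrl_full$results[[1]]$repeat_ability, mgp$repeat_ability,
               tolerance = 1e-10)
})

test_that("relative improvements follow the percent-change arithmetic", {
  g <- selection_gain(0.190, 0.138)
  expect_equal(g$percent, 100 * (0.190 - 0.138) / 0.138, tolerance = 1e-12)
  expect_equal(round(g$percent, 1), 37.7)
})

test_that("CV results serialize as long-format tables", {
  d <- small_bundle()$data
  cv <- cross_validate(d, "trait", "GP", k = 5, repeats = 2, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cv_result(cv, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 10)  # 2 repeats x 5 folds
  expect_identical(unique(tab$model), "GP")
})
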