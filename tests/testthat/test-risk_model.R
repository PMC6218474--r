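test_that("assemble_features builds the 14-predictor schema", {
  ft <- toy_features(n = 40, seed = 2)
  expect_equal(nrow(ft), 40)
  expect_setequal(names(ft),
                  c("species_id", "high_hfp_extent", "high_hfp_change",
                    "popdensity", "pop_growth", "travel_time", "taxon_order",
                    "gestation_length", "weaning_age", "body_mass", "diet",
                    "habitat_class", "ndvi", "tree_cover",
                    "habitat_prevalence", "label"))
  expect_equal(ncol(ft), 16)  # id + 14 predictors + label
  expect_true(is.numeric(ft$taxon_order))  # integer-encoded categorical
  expect_named(attr(ft, "levels"), c("taxon_order", "diet", "habitat_class"))
  expect_equal(attr(ft, "threshold"), 2L)
})

test_that("assemble_features: change is the extent difference; errors name ids", {
  ov <- data.frame(species_id = c("a", "b"), t = 2L, extent93 = c(0.5, 0.1),
                   extent09 = c(0.6, 0.4), delta = c(0.1, 0.3),
                   clamped = TRUE)
  cov_df <- data.frame(species_id = c("a", "b"), popdensity = 1,
                       pop_growth = 0, travel_time = 1, taxon_order = "X",
                       gestation_length = 1, weaning_age = 1, body_mass = 1,
                       diet = "omnivore", habitat_class = "forest", ndvi = 0.5,
                       tree_cover = 10, habitat_prevalence = 0.5)
  lab <- data.frame(species_id = c("a", "b"),
                    risk_class = c("low-risk", "high-risk"))
  ft <- assemble_features(ov, cov_df, lab, 2)
  expect_equal(ft$high_hfp_change, c(0.1, 0.3))
  expect_equal(ft$high_hfp_extent, c(0.6, 0.4))
  lab2 <- rbind(lab, data.frame(species_id = "zz", risk_class = "low-risk"))
  expect_error(assemble_features(ov, cov_df, lab2, 2), "zz")
  expect_error(assemble_features(ov, cov_df, rbind(lab, lab), 2), "duplicate")
  # missing continuous covariates are median-imputed and recorded
  cov_na <- cov_df; cov_na$ndvi[2] <- NA
  ft2 <- assemble_features(ov, cov_na, lab, 2)
  expect_equal(ft2$ndvi[2], 0.5)
  expect_equal(attr(ft2, "imputation")$variable, "ndvi")
})

test_that("fit_evaluate: TSS identity, confusion bookkeeping, determinism", {
  ft <- toy_features(n = 80, seed = 3, separation = 1)
  st <- rf_settings(ntree = 100, folds = 5, seed = 11)
  r1 <- fit_evaluate(ft, st)
  expect_equal(r1$tss, r1$sensitivity + r1$specificity - 1)
  expect_equal(sum(r1$confusion), 80)
  expect_true(all(c(r1$accuracy, r1$sensitivity, r1$specificity) >= 0 &
                    c(r1$accuracy, r1$sensitivity, r1$specificity) <= 1))
  r2 <- fit_evaluate(ft, st)
  expect_identical(r1, r2)  # byte-identical given the seed
  r3 <- fit_evaluate(ft, rf_settings(ntree = 100, folds = 5, seed = 12))
  expect_false(identical(r1$confusion, r3$confusion) &&
                 identical(r1$importance, r3$importance))
})

test_that("fit_evaluate separates separable classes and rejects bad input", {
  ft <- toy_features(n = 80, seed = 4, separation = 8)  # disjoint supports
  r <- fit_evaluate(ft, rf_settings(ntree = 100, folds = 5, seed = 1))
  expect_gte(r$tss, 0.95)
  ft1 <- ft; ft1$label <- "low-risk"
  expect_error(fit_evaluate(ft1), "single-class")
  expect_error(fit_evaluate(ft[1:6, ], rf_settings(folds = 10)),
               "fewer species than folds")
})

test_that("shuffled labels give TSS near zero", {
  tsses <- sapply(1:10, function(s) {
    ft <- toy_features(n = 80, seed = 20, separation = 1.5)
    set.seed(s)
    ft$label <- sample(ft$label)
    fit_evaluate(ft, rf_settings(ntree = 100, folds = 5, seed = s))$tss
  })
  expect_lt(abs(mean(tsses)), 0.1)
})

test_that("planted signal outranks pure noise in permutation importance", {
  hits <- sapply(1:10, function(s) {
    ft <- toy_features(n = 80, seed = s, separation = 2)
    imp <- fit_evaluate(ft, rf_settings(ntree = 100, folds = 5,
                                        seed = s))$importance
    sig <- imp$mean_decrease_accuracy[imp$variable == "high_hfp_extent"]
    noise <- imp$mean_decrease_accuracy[imp$variable == "ndvi"]
    noise <= sig
  })
  expect_gte(sum(hits), 9)
})

test_that("threshold_selection scans the grid and tie-breaks low", {
  # identical features at every threshold: TSS curve is flat, lowest t wins
  n <- 60
  ft0 <- toy_features(n = n, seed = 6, separation = 2)
  ov <- do.call(rbind, lapply(c(1L, 3L, 5L), function(tt) {
    data.frame(species_id = ft0$species_id, t = tt,
               extent93 = 0.2, extent09 = ft0$high_hfp_extent,
               delta = ft0$high_hfp_change, clamped = TRUE)
  }))
  cov <- data.frame(species_id = ft0$species_id,
                    ft0[, c("popdensity", "pop_growth", "travel_time",
                            "gestation_length", "weaning_age", "body_mass",
                            "ndvi", "tree_cover", "habitat_prevalence")],
                    taxon_order = "X", diet = "omnivore",
                    habitat_class = "forest")
  lab <- data.frame(species_id = ft0$species_id, risk_class = ft0$label)
  sel <- threshold_selection(ov, cov, lab, t_grid = c(1, 3, 5),
                             settings = rf_settings(ntree = 50, folds = 5,
                                                    seed = 2))
  expect_equal(nrow(sel$curve), 3)
  expect_equal(length(unique(sel$curve$tss)), 1)  # flat curve
  expect_equal(sel$best_t, 1)                     # tie -> lowest threshold
  expect_error(threshold_selection(ov, cov, lab, t_grid = 3), ">= 2")
})

test_that("tss helper computes the identity", {
  expect_equal(tss(0.604, 0.924), 0.528)
  expect_equal(tss(1, 1), 1)
  expect_error(tss(1.2, 0.5))
})

test_that("uplisted model warns on severe imbalance", {
  ft <- toy_features(n = 100, seed = 8)
  ft$label <- c(rep("uplisted", 5), rep("not-uplisted", 95))
  expect_warning(fit_evaluate(ft, rf_settings(ntree = 50, folds = 5,
                                              seed = 1)),
                 "imbalance")
})
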