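test_that("EC50 labeling is inclusive at 1000 nM and deduplicates ids", {
  rec <- data.frame(
    id = c("a", "b", "c", "d"),
    smiles = "CCO",
    ec50_nM = c(1000, 1001, 0.5, NA))
  lab <- suppressMessages(label_activities(rec))
  expect_identical(nrow(lab), 3L)  # NA EC50 dropped
  expect_identical(as.character(lab$label[lab$id == "a"]), "active")
  expect_identical(as.character(lab$label[lab$id == "b"]), "inactive")
  expect_identical(attr(lab, "n_removed_undefined"), 1L)

  rec10 <- data.frame(id = c(letters[1:8], "a", "b"), smiles = "CCO",
                      ec50_nM = c(1:8 * 100, 50, 20))
  lab10 <- suppressMessages(label_activities(rec10))
  expect_identical(nrow(lab10), 8L)  # 2 duplicate ids among 10 removed
  expect_equal(lab10$ec50_nM[lab10$id == "a"], 50)  # lowest EC50 kept
  expect_error(label_activities(data.frame(id = "x", smiles = "C",
                                           ec50_nM = NA)), "no rows")
})

test_that("stratified splits are deterministic with exact class balance", {
  y <- factor(rep(c("inactive", "active"), each = 50),
              levels = c("inactive", "active"))
  tr1 <- pharmfunnel:::stratified_split(y, 0.8, seed = 3)
  tr2 <- pharmfunnel:::stratified_split(y, 0.8, seed = 3)
  expect_identical(tr1, tr2)
  expect_length(tr1, 80L)
  expect_identical(sum(y[tr1] == "active"), 40L)
  expect_error(pharmfunnel:::stratified_split(
    factor(c("active", rep("inactive", 9)),
           levels = c("inactive", "active")), 0.8, 1), "class")
})

test_that("every family separates a linearly separable toy problem", {
  set.seed(5)
  x <- cbind(f1 = c(rnorm(40, -3), rnorm(40, 3)), f2 = rnorm(80))
  y <- factor(rep(c("inactive", "active"), each = 40),
              levels = c("inactive", "active"))
  cmp <- train_compare(x, y, x, y, seed = 2)
  expect_identical(nrow(cmp$leaderboard), 7L)
  expect_true(all(cmp$leaderboard$accuracy == 1))
})

test_that("metrics are recomputable from the stored confusion matrix", {
  fx <- ml_fixture()
  tr <- pharmfunnel:::stratified_split(fx$y, 0.8, seed = 7)
  fit <- triage_fit(fx$x[tr, ], fx$y[tr], "gradient_boosting", seed = 7)
  rep <- model_report(predict(fit, fx$x[-tr, ]), fx$y[-tr], "gb")
  cm <- rep$confusion
  expect_identical(sum(cm), length(fx$y) - length(tr))
  expect_equal(rep$accuracy, (cm["tp"] + cm["tn"]) / sum(cm),
               ignore_attr = TRUE)
  prec <- cm["tp"] / (cm["tp"] + cm["fp"])
  rec <- cm["tp"] / (cm["tp"] + cm["fn"])
  expect_equal(rep$f1, 2 * prec * rec / (prec + rec), ignore_attr = TRUE)
  expect_equal(rep$precision[["active"]], unname(prec))
  expect_equal(rep$recall[["active"]], unname(rec))
})

test_that("the split sweep recovers the planted rule and is deterministic", {
  fx <- ml_fixture()
  fams <- c("gradient_boosting", "decision_tree", "adaboost")
  sw1 <- split_sweep(fx$x, fx$y, families = fams, seed = 11)
  sw2 <- split_sweep(fx$x, fx$y, families = fams, seed = 11)
  expect_identical(sw1$best$model, sw2$best$model)
  expect_identical(sw1$leaderboards, sw2$leaderboards)
  expect_gte(sw1$best$accuracy, 0.9)
  expect_identical(names(sw1$leaderboards),
                   sprintf("%.2f", seq(0.80, 0.70, by = -0.02)))
})

test_that("20-fold cross-validation is stratified, seeded and consistent", {
  fx <- ml_fixture()
  cv1 <- cross_validate(fx$x, fx$y, "gradient_boosting", k = 20, seed = 3)
  cv2 <- cross_validate(fx$x, fx$y, "gradient_boosting", k = 20, seed = 3)
  expect_identical(cv1, cv2)
  expect_length(cv1$scores, 20L)
  expect_gte(cv1$mean, 0.9)
  expect_error(cross_validate(fx$x, fx$y, k = 10000), "minority")
})

test_that("library classification preserves order and reports retention", {
  fx <- ml_fixture()
  fit <- triage_fit(fx$x, fx$y, "gradient_boosting", seed = 1)
  mols <- molecules_from_smiles(fx$table$smiles[1:40],
                                ids = fx$table$id[1:40])
  res <- classify_library(fit, mols)
  expect_identical(res$kept, fx$table$id[1:40][fx$table$id[1:40] %in%
                                                res$kept])
  truth <- fx$table$label[1:40] == "active"
  recall <- sum(res$kept %in% fx$table$id[1:40][truth]) / sum(truth)
  expect_gte(recall, 0.85)
  expect_equal(res$retention_pct,
               retention_percentage(length(res$kept), 40))
})

test_that("retention arithmetic matches the published screening cut", {
  # 2432 retained of 3772 pharmacophore hits
  expect_equal(retention_percentage(2432, 3772), 64.48)
  expect_equal(retention_percentage(100, 100), 100)
  expect_error(retention_percentage(1, 0), "positive")
})
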