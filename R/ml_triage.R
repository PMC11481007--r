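#' Label an activity table by the EC50 potency threshold
#'
#' Rows without a defined positive EC50 are dropped; duplicate ids keep
#' the lowest (most potent) EC50. A compound is `active` when its EC50 is
#' at or below the threshold (1 uM inclusive by default).
#'
#' @param records data.frame with columns `id`, `smiles` and `ec50_nM`
#'   (or `ec50`, taken as nM).
#' @param threshold_nM activity threshold in nM (default 1000).
#' @return the cleaned data.frame with a `label` factor
#'   (`inactive`/`active`); attributes `n_removed_undefined` and
#'   `n_removed_duplicates` count the dropped rows.
#' @export
label_activities <- function(records, threshold_nM = 1000) {
  if (!"ec50_nM" %in% names(records) && "ec50" %in% names(records))
    records$ec50_nM <- records$ec50
  ec <- suppressWarnings(as.numeric(records$ec50_nM))
  ok <- !is.na(ec) & ec > 0
  n_undef <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  records$ec50_nM <- ec[ok]
  records <- records[order(records$id, records$ec50_nM), , drop = FALSE]
  dup <- duplicated(records$id)
  n_dup <- sum(dup)
  records <- records[!dup, , drop = FALSE]
  if (nrow(records) == 0L)
    stop("no rows left after removing undefined EC50 values")
  if (n_dup > 0L)
    message(n_dup, " duplicate id(s) removed (lowest EC50 kept)")
  records$label <- factor(ifelse(records$ec50_nM <= threshold_nM,
                                 "active", "inactive"),
                          levels = c("inactive", "active"))
  rownames(records) <- NULL
  attr(records, "n_removed_undefined") <- n_undef
  attr(records, "n_removed_duplicates") <- n_dup
  records
}

#' Featurize molecules for activity modeling
#'
#' Column blocks: physicochemical descriptors (H-bond donors/acceptors,
#' logP, molar refractivity, molecular weight, TPSA, plus graph counts),
#' the 166 MACCS structural keys, and the 2048-bit radius-2 circular
#' fingerprint. Constant columns are dropped (and counted); remaining
#' missing values are imputed with the column median.
#'
#' @param x list of [molecule()]s, or a character vector of SMILES.
#' @return numeric matrix (rows = molecules, named by id) with attributes
#'   `n_dropped_constant` and `n_skipped` (unfeaturizable inputs).
#' @export
featurize_molecules <- function(x) {
  if (is.character(x)) x <- molecules_from_smiles(x)
  skipped <- attr(x, "n_skipped") %||% 0L
  sdfs <- list(); ids <- character(); keep <- list()
  for (m in x) {
    s <- tryCatch(molecule_to_sdf(m), error = function(e) NULL)
    if (is.null(s)) { skipped <- skipped + 1L; next }
    sdfs[[length(sdfs) + 1L]] <- s
    ids <- c(ids, m$id)
    keep[[length(keep) + 1L]] <- m
  }
  if (!length(sdfs)) stop("no featurizable molecules")
  sdfset <- methods::new("SDFset", SDF = sdfs, ID = ids)
  prop <- ChemmineR::propOB(sdfset)
  num <- prop[, vapply(prop, is.numeric, logical(1)), drop = FALSE]
  graph <- do.call(rbind, lapply(keep, function(m) c(
    n_atoms = n_atoms(m),
    n_bonds = nrow(m$bonds),
    n_aromatic_rings = length(aromatic_rings(m)),
    n_O = sum(m$atoms$element == "O"),
    n_N = sum(m$atoms$element == "N"),
    n_halogen = sum(m$atoms$element %in% c("F", "Cl", "Br", "I")),
    mw_graph = molecular_weight(m))))
  fp_m <- fingerprint(keep, "maccs")
  fp_g <- fingerprint(keep, "morgan")
  bits <- cbind(
    do.call(rbind, lapply(fp_m, function(f) as.integer(f$bits))),
    do.call(rbind, lapply(fp_g, function(f) as.integer(f$bits))))
  colnames(bits) <- c(paste0("maccs", seq_len(166)),
                      paste0("mrgn", seq_len(2048)))
  X <- cbind(as.matrix(num), graph, bits)
  rownames(X) <- ids
  # median imputation, then drop constants
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- stats::median(X[, j], na.rm = TRUE)
  }
  const <- apply(X, 2, function(v) length(unique(v)) <= 1L)
  out <- X[, !const, drop = FALSE]
  attr(out, "n_dropped_constant") <- sum(const)
  attr(out, "n_skipped") <- skipped
  out
}

# --- classifier families ------------------------------------------------

# small SAMME AdaBoost over decision stumps
fit_adaboost <- function(x, y, rounds = 40L) {
  df <- data.frame(y = y, x, check.names = FALSE)
  w <- rep(1 / length(y), length(y))
  stumps <- list(); alphas <- numeric()
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w / mean(w),
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = 0, xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5 || err <= 1e-12) {
      if (err <= 1e-12) { stumps <- list(fit); alphas <- 1 }
      break
    }
    a <- log((1 - err) / err)
    w <- w * exp(a * (pred != y))
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, a)
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  votes <- matrix(0, nrow(df), 2)
  for (m in seq_along(fit$stumps)) {
    cls <- predict(fit$stumps[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(cls))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(cls))] + fit$alphas[m]
  }
  votes[, 2] / pmax(rowSums(votes), 1e-12)
}

fit_bagging <- function(x, y, n_bags = 25L) {
  df <- data.frame(y = y, x, check.names = FALSE)
  trees <- lapply(seq_len(n_bags), function(b) {
    idx <- sample.int(nrow(df), replace = TRUE)
    rpart::rpart(y ~ ., data = df[idx, , drop = FALSE],
                 control = rpart::rpart.control(maxdepth = 8, cp = 0.001,
                                                xval = 0))
  })
  list(trees = trees, levels = levels(y))
}

predict_bagging <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  probs <- vapply(fit$trees, function(t)
    predict(t, df, type = "prob")[, "active"], numeric(nrow(df)))
  rowMeans(matrix(probs, nrow = nrow(df)))
}

.model_families <- function() list(
  gradient_boosting = list(
    fit = function(x, y) xgboost::xgboost(
      x = x, y = y, nrounds = 60, max_depth = 4,
      learning_rate = 0.3, nthreads = 1, verbosity = 0),
    # probability of the second factor level ("active")
    predict = function(fit, x) as.numeric(predict(fit, x))),
  random_forest = list(
    fit = function(x, y) randomForest::randomForest(x, y, ntree = 200),
    predict = function(fit, x) predict(fit, x, type = "prob")[, "active"]),
  extra_trees = list(
    fit = function(x, y) ranger::ranger(
      x = x, y = y, num.trees = 200, splitrule = "extratrees",
      probability = TRUE, num.threads = 1, seed = 1),
    predict = function(fit, x)
      predict(fit, x, num.threads = 1)$predictions[, "active"]),
  adaboost = list(fit = fit_adaboost, predict = predict_adaboost),
  decision_tree = list(
    fit = function(x, y) rpart::rpart(
      y ~ ., data = data.frame(y = y, x, check.names = FALSE),
      control = rpart::rpart.control(xval = 0)),
    predict = function(fit, x)
      predict(fit, data.frame(x, check.names = FALSE),
              type = "prob")[, "active"]),
  bagging = list(fit = fit_bagging, predict = predict_bagging),
  svm_rbf = list(
    fit = function(x, y) e1071::svm(x, y, probability = TRUE,
                                    kernel = "radial"),
    predict = function(fit, x) {
      p <- predict(fit, x, probability = TRUE)
      attr(p, "probabilities")[, "active"]
    }))

#' Train one classifier family
#'
#' @param x numeric feature matrix.
#' @param y factor with levels `inactive`, `active`.
#' @param family one of `gradient_boosting`, `random_forest`,
#'   `extra_trees`, `adaboost`, `decision_tree`, `bagging`, `svm_rbf`.
#' @param seed integer seed (training is deterministic given it).
#' @return `triage_model` object usable with `predict()` (returns the
#'   probability of the active class).
#' @export
triage_fit <- function(x, y, family = "gradient_boosting", seed = 1L) {
  fams <- .model_families()
  if (!family %in% names(fams))
    stop("unknown model family '", family, "'")
  fit <- with_seed(seed, fams[[family]]$fit(x, y))
  structure(list(family = family, fit = fit,
                 feature_columns = colnames(x), seed = seed),
            class = "triage_model")
}

#' @export
predict.triage_model <- function(object, newdata, ...) {
  newdata <- align_features(newdata, object$feature_columns)
  .model_families()[[object$family]]$predict(object$fit, newdata)
}

align_features <- function(x, cols) {
  miss <- setdiff(cols, colnames(x))
  if (length(miss)) {
    x <- cbind(x, matrix(0, nrow(x), length(miss),
                         dimnames = list(NULL, miss)))
  }
  x[, cols, drop = FALSE]
}

#' @export
print.triage_model <- function(x, ...) {
  cat("<triage_model>", x$family, "over", length(x$feature_columns),
      "features (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Evaluate predicted probabilities against labels
#'
#' @param prob probability of the active class.
#' @param y factor truth (`inactive`/`active`).
#' @param model name reported in the output.
#' @return `model_report` list: accuracy, roc_auc, f1, confusion
#'   (tn, fp, fn, tp), per-class precision/recall.
#' @export
model_report <- function(prob, y, model = "model") {
  pred <- factor(ifelse(prob >= 0.5, "active", "inactive"),
                 levels = c("inactive", "active"))
  tp <- sum(pred == "active" & y == "active")
  tn <- sum(pred == "inactive" & y == "inactive")
  fp <- sum(pred == "active" & y == "inactive")
  fn <- sum(pred == "inactive" & y == "active")
  prec_a <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec_a <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec_i <- if (tn + fn > 0) tn / (tn + fn) else 0
  rec_i <- if (tn + fp > 0) tn / (tn + fp) else 0
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = prob, levels = c("inactive", "active"),
    direction = "<", quiet = TRUE)))
  structure(list(
    model = model,
    accuracy = (tp + tn) / length(y),
    roc_auc = auc,
    f1 = if (prec_a + rec_a > 0) 2 * prec_a * rec_a / (prec_a + rec_a) else 0,
    confusion = c(tn = tn, fp = fp, fn = fn, tp = tp),
    precision = c(inactive = prec_i, active = prec_a),
    recall = c(inactive = rec_i, active = rec_a)),
    class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s: acc %.3f, AUC %.3f, F1 %.3f\n",
              x$model, x$accuracy, x$roc_auc, x$f1))
  cat(sprintf("  confusion: tn %d fp %d fn %d tp %d\n",
              x$confusion["tn"], x$confusion["fp"],
              x$confusion["fn"], x$confusion["tp"]))
  invisible(x)
}

#' Train and compare classifier families on one split
#'
#' @param x_train,y_train,x_test,y_test featurized split.
#' @param families family names (default: all seven).
#' @param seed integer seed.
#' @return list: `reports` (per family), `leaderboard` (data.frame sorted
#'   by test accuracy), `fits` (the trained `triage_model`s). A family
#'   whose training fails is skipped with a warning.
#' @export
train_compare <- function(x_train, y_train, x_test, y_test,
                          families = names(.model_families()),
                          seed = 1L) {
  reports <- list(); fits <- list()
  for (fam in families) {
    res <- tryCatch({
      fit <- triage_fit(x_train, y_train, fam, seed = seed)
      rep <- model_report(predict(fit, x_test), y_test, model = fam)
      list(fit = fit, rep = rep)
    }, error = function(e) {
      warning("family ", fam, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    reports[[fam]] <- res$rep
    fits[[fam]] <- res$fit
  }
  if (!length(reports)) stop("every model family failed to train")
  lb <- do.call(rbind, lapply(reports, function(r)
    data.frame(model = r$model, accuracy = r$accuracy,
               roc_auc = r$roc_auc, f1 = r$f1)))
  lb <- lb[order(-lb$accuracy, lb$model), , drop = FALSE]
  rownames(lb) <- NULL
  list(reports = reports, leaderboard = lb, fits = fits)
}

# deterministic stratified index split: fraction `train_frac` per class
stratified_split <- function(y, train_frac, seed) {
  with_seed(seed, {
    train <- integer()
    for (lv in levels(y)) {
      idx <- which(y == lv)
      n_tr <- round(length(idx) * train_frac)
      if (n_tr < 1L || n_tr >= length(idx))
        stop("stratification leaves a class empty in train or test")
      train <- c(train, sample(idx, n_tr))
    }
    sort(train)
  })
}

#' Sweep train/test ratios and pick the best (ratio, family) pair
#'
#' Stratified shuffled splits at train fractions from 0.80 down to 0.70
#' in steps of 0.02; the pair with the highest test accuracy wins, ties
#' resolved toward the larger training fraction and then by family name.
#'
#' @param x feature matrix.
#' @param y factor labels.
#' @param ratios train fractions to try.
#' @param families families to compare.
#' @param seed integer seed.
#' @return list: `best` (ratio, model, accuracy, fit), `leaderboards`
#'   (per-ratio comparison tables).
#' @export
split_sweep <- function(x, y, ratios = seq(0.80, 0.70, by = -0.02),
                        families = names(.model_families()), seed = 1L) {
  if (min(table(y)) < 20L)
    stop("split sweep needs at least 20 rows per class")
  boards <- list()
  best <- NULL
  for (r in ratios) {
    tr <- stratified_split(y, r, seed)
    cmp <- train_compare(x[tr, , drop = FALSE], y[tr],
                         x[-tr, , drop = FALSE], y[-tr],
                         families, seed = seed)
    boards[[sprintf("%.2f", r)]] <- cmp$leaderboard
    top <- cmp$leaderboard[1L, ]
    cand <- list(ratio = r, model = top$model, accuracy = top$accuracy,
                 fit = cmp$fits[[top$model]])
    if (is.null(best) ||
        cand$accuracy > best$accuracy + 1e-12 ||
        (abs(cand$accuracy - best$accuracy) <= 1e-12 &&
         (cand$ratio > best$ratio ||
          (cand$ratio == best$ratio && cand$model < best$model))))
      best <- cand
  }
  list(best = best, leaderboards = boards)
}

#' Stratified k-fold cross-validation accuracy
#'
#' @param x feature matrix.
#' @param y factor labels.
#' @param family model family name.
#' @param k number of folds (default 20); must not exceed the minority
#'   class count.
#' @param seed integer seed (fold assignment is deterministic given it).
#' @return list: `scores` (per-fold accuracy) and `mean`.
#' @export
cross_validate <- function(x, y, family = "gradient_boosting", k = 20L,
                           seed = 1L) {
  if (k > min(table(y)))
    stop("k exceeds the minority class count")
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  scores <- vapply(seq_len(k), function(fold) {
    tr <- folds != fold
    fit <- triage_fit(x[tr, , drop = FALSE], y[tr], family, seed = seed)
    prob <- predict(fit, x[!tr, , drop = FALSE])
    mean((prob >= 0.5) == (y[!tr] == "active"))
  }, numeric(1))
  list(scores = scores, mean = mean(scores))
}

#' Apply a trained triage model to filter a molecule library
#'
#' @param model a `triage_model`.
#' @param molecules list of [molecule()]s (or SMILES vector).
#' @param threshold predicted-active probability cutoff (default 0.5).
#' @return list: `kept` (ids predicted active, input order preserved),
#'   `retention_pct` (percentage of the input retained, 2 decimals),
#'   `prob` (per-molecule probabilities), `n_skipped`.
#' @export
classify_library <- function(model, molecules, threshold = 0.5) {
  X <- featurize_molecules(molecules)
  prob <- predict(model, X)
  keep <- prob >= threshold
  n_in <- nrow(X) + (attr(X, "n_skipped") %||% 0L)
  list(kept = rownames(X)[keep],
       retention_pct = retention_percentage(sum(keep), n_in),
       prob = stats::setNames(prob, rownames(X)),
       n_skipped = attr(X, "n_skipped") %||% 0L)
}

#' Library retention percentage
#'
#' @param kept,total counts.
#' @return `100 * kept / total`, rounded to 2 decimals.
#' @export
retention_percentage <- function(kept, total) {
  if (total < 1) stop("total must be positive")
  round(100 * kept / total, 2)
}
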