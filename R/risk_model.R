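COVARIATE_NUMERIC <- c("popdensity", "pop_growth", "travel_time",
                       "gestation_length", "weaning_age", "body_mass",
                       "ndvi", "tree_cover", "habitat_prevalence")
COVARIATE_CATEGORICAL <- c("taxon_order", "diet", "habitat_class")
FEATURE_COLUMNS <- c("high_hfp_extent", "high_hfp_change",
                     COVARIATE_NUMERIC, COVARIATE_CATEGORICAL)

#' Random-forest and cross-validation settings
#'
#' Conventional defaults: 500 trees, \code{floor(sqrt(p))} features per
#' split, terminal nodes grown to purity, 10-fold stratified
#' cross-validation.
#'
#' @param ntree number of trees.
#' @param mtry features tried per split (\code{NULL} = \code{floor(sqrt(p))}).
#' @param min_node minimum node size to attempt a split.
#' @param folds number of stratified CV folds.
#' @param seed integer seed controlling folds, tree growing and permutations.
#' @return a list of class \code{rf_settings}.
#' @export
rf_settings <- function(ntree = 500, mtry = NULL, min_node = 2, folds = 10,
                        seed = 1) {
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 min_node = as.integer(min_node), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "rf_settings")
}

#' Fit a random forest (low-level)
#'
#' @param x numeric feature matrix.
#' @param y binary outcome (0/1, logical, or two-level factor/character).
#' @param ntree,mtry,min_node,seed see \code{\link{rf_settings}}.
#' @return forest object of class \code{hfp_rf} (with per-feature Gini
#'   importance in \code{gini_importance}).
#' @export
rf_fit <- function(x, y, ntree = 500, mtry = NULL, min_node = 2, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.character(y)) y <- factor(y)
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("y must be binary")
    y <- as.integer(y) - 1L
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("single-class input")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  f <- rf_train_cpp(x, y, as.integer(ntree), as.integer(mtry),
                    as.integer(min_node), as.integer(seed))
  f$features <- colnames(x)
  names(f$gini_importance) <- colnames(x)
  class(f) <- "hfp_rf"
  f
}

#' Predict classes from a fitted forest
#' @param object an \code{hfp_rf}.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return integer vector of 0/1 class predictions (majority vote; exact vote
#'   ties resolve to class 0).
#' @export
predict.hfp_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$features) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  rf_predict_cpp(unclass(object), newdata)
}

#' Assemble the per-species feature table
#'
#' Joins the overlap table (at one threshold), the covariate table and the
#' transition labels into one row per species with exactly the 14 predictors:
#' the two HFP variables (final-epoch extent above t and its 1993-2009 delta)
#' plus the nine continuous and three categorical covariates. Range size is
#' deliberately absent (circularity with risk estimation). Categorical
#' predictors are integer-encoded; the level maps are kept in the
#' \code{"levels"} attribute. Missing continuous covariates are
#' median-imputed, recorded in the \code{"imputation"} attribute.
#'
#' @param overlaps long overlap table (\code{\link{overlap_table}}).
#' @param covariates data.frame keyed by \code{species_id} with the Table-1
#'   style covariate columns.
#' @param labels data.frame with \code{species_id} and \code{risk_class} (or
#'   \code{uplist_class} via \code{label_col}).
#' @param t threshold (0..49) at which the HFP variables are taken.
#' @param label_col column of \code{labels} to use as the outcome.
#' @return data.frame of class \code{feature_table}: \code{species_id}, the
#'   14 predictors, \code{label}; attributes \code{threshold}, \code{levels},
#'   \code{imputation}.
#' @export
assemble_features <- function(overlaps, covariates, labels, t,
                              label_col = "risk_class") {
  stopifnot(length(t) == 1, t %in% 0:49)
  if (!label_col %in% names(labels)) stop("label column missing: ", label_col)
  if (anyDuplicated(labels$species_id)) stop("duplicate species in labels")
  if (anyDuplicated(covariates$species_id))
    stop("duplicate species in covariates")
  ov <- overlaps[overlaps$t == t, ]
  if (anyDuplicated(ov$species_id))
    stop("duplicate species in overlaps at t = ", t)
  ids <- labels$species_id
  miss_ov <- setdiff(ids, ov$species_id)
  if (length(miss_ov))
    stop("species missing from overlaps: ", paste(miss_ov, collapse = ", "))
  miss_cv <- setdiff(ids, covariates$species_id)
  if (length(miss_cv))
    stop("species missing from covariates: ", paste(miss_cv, collapse = ", "))
  need <- c(COVARIATE_NUMERIC, COVARIATE_CATEGORICAL)
  miss_col <- setdiff(need, names(covariates))
  if (length(miss_col))
    stop("covariate columns missing: ", paste(miss_col, collapse = ", "))
  lab <- labels[[label_col]]
  if (anyNA(lab)) stop("missing labels")

  ov <- ov[match(ids, ov$species_id), ]
  cv <- covariates[match(ids, covariates$species_id), ]
  out <- data.frame(species_id = ids,
                    high_hfp_extent = ov$extent09,
                    high_hfp_change = ov$delta)
  if (any(out$high_hfp_extent < 0 | out$high_hfp_extent > 1))
    stop("high_hfp_extent outside [0, 1]")
  imput <- data.frame(species_id = character(0), variable = character(0))
  for (v in COVARIATE_NUMERIC) {
    x <- as.numeric(cv[[v]])
    if (anyNA(x)) {
      na_i <- which(is.na(x))
      imput <- rbind(imput, data.frame(species_id = ids[na_i], variable = v))
      x[na_i] <- stats::median(x, na.rm = TRUE)
    }
    out[[v]] <- x
  }
  levmaps <- list()
  for (v in COVARIATE_CATEGORICAL) {
    f <- factor(as.character(cv[[v]]))
    if (anyNA(f)) stop("missing categorical covariate ", v)
    levmaps[[v]] <- stats::setNames(seq_along(levels(f)), levels(f))
    out[[v]] <- as.integer(f)
  }
  out$label <- lab
  structure(out, class = c("feature_table", "data.frame"),
            threshold = t, levels = levmaps, imputation = imput)
}

#' True skill statistic
#'
#' \code{TSS = sensitivity + specificity - 1}: the balance of positive- and
#' negative-class recall, insensitive to class prevalence.
#'
#' @param sensitivity positive-class recall in [0, 1].
#' @param specificity negative-class recall in [0, 1].
#' @return TSS in [-1, 1].
#' @export
tss <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  sensitivity + specificity - 1
}

positive_class <- function(lab) {
  u <- unique(lab)
  if ("high-risk" %in% u) "high-risk"
  else if ("uplisted" %in% u) "uplisted"
  else stop("cannot identify positive class in labels: ",
            paste(u, collapse = ", "))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Cross-validated random-forest evaluation with variable importance
#'
#' Stratified k-fold cross-validation of a binary random forest. Performance
#' is the pooled confusion matrix over held-out folds: accuracy, sensitivity
#' (positive-class recall), specificity (reference-class recall) and
#' TSS = sensitivity + specificity - 1. Importance combines CV permutation
#' importance (mean decrease in held-out accuracy when one predictor is
#' permuted) and Gini importance (mean total impurity decrease per tree),
#' both averaged over folds. Deterministic given \code{settings$seed}.
#'
#' @param features a \code{feature_table} from \code{\link{assemble_features}}.
#' @param settings an \code{\link{rf_settings}}.
#' @return list of class \code{model_report}: threshold, metrics, confusion
#'   counts, importance table, settings, level maps, n.
#' @export
fit_evaluate <- function(features, settings = rf_settings()) {
  stopifnot(inherits(features, "feature_table"))
  x <- as.matrix(features[, FEATURE_COLUMNS])
  lab <- features$label
  if (length(unique(lab)) < 2) stop("single-class input")
  pos <- positive_class(lab)
  y <- as.integer(lab == pos)
  n <- length(y)
  if (n < settings$folds) stop("fewer species than folds")
  if (pos == "uplisted" && mean(y) < 0.1)
    warning("severe class imbalance (", round(100 * mean(y), 1),
            "% uplisted): expect biased classification toward not-uplisted")
  p <- ncol(x)
  mtry <- settings$mtry %||% max(1L, floor(sqrt(p)))

  with_seed(settings$seed, {
    fold <- stratified_folds(y, settings$folds)
    conf <- matrix(0L, 2, 2, dimnames = list(truth = c("neg", "pos"),
                                             pred = c("neg", "pos")))
    perm_drop <- matrix(0, settings$folds, p,
                        dimnames = list(NULL, colnames(x)))
    gini <- matrix(0, settings$folds, p, dimnames = list(NULL, colnames(x)))
    for (k in seq_len(settings$folds)) {
      tr <- fold != k
      te <- !tr
      f <- rf_fit(x[tr, , drop = FALSE], y[tr], ntree = settings$ntree,
                  mtry = mtry, min_node = settings$min_node,
                  seed = settings$seed + k)
      ph <- predict(f, x[te, , drop = FALSE])
      conf <- conf + table(factor(y[te], 0:1), factor(ph, 0:1))
      base_acc <- mean(ph == y[te])
      for (j in seq_len(p)) {
        xp <- x[te, , drop = FALSE]
        xp[, j] <- xp[sample(nrow(xp)), j]
        perm_drop[k, j] <- base_acc - mean(predict(f, xp) == y[te])
      }
      gini[k, ] <- f$gini_importance
    }
    sens <- conf[2, 2] / sum(conf[2, ])
    spec <- conf[1, 1] / sum(conf[1, ])
    importance <- data.frame(
      variable = colnames(x),
      mean_decrease_accuracy = colMeans(perm_drop),
      mean_decrease_gini = colMeans(gini), row.names = NULL)
    importance <- importance[order(-importance$mean_decrease_accuracy), ]
    structure(list(
      threshold = attr(features, "threshold"),
      accuracy = sum(diag(conf)) / sum(conf),
      sensitivity = sens, specificity = spec, tss = sens + spec - 1,
      confusion = conf, importance = importance,
      positive_class = pos, n = n,
      levels = attr(features, "levels"),
      settings = list(ntree = settings$ntree, mtry = mtry,
                      min_node = settings$min_node, folds = settings$folds,
                      seed = settings$seed)),
      class = "model_report")
  })
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(paste0("<model_report> t > %s, n = %d: accuracy %.3f, ",
                     "sensitivity %.3f, specificity %.3f, TSS %.3f\n"),
              x$threshold, x$n, x$accuracy, x$sensitivity, x$specificity,
              x$tss))
  invisible(x)
}

#' Select the HFP threshold by predictive performance
#'
#' Fits \code{\link{fit_evaluate}} at every threshold in \code{t_grid} and
#' returns the threshold maximizing TSS (ties toward the lowest threshold),
#' with the per-threshold performance curve and the importance of the two HFP
#' variables along it.
#'
#' @param overlaps long overlap table.
#' @param covariates covariate table.
#' @param labels label table.
#' @param t_grid integer thresholds to scan (>= 2 values).
#' @param settings an \code{\link{rf_settings}}.
#' @param label_col outcome column of \code{labels}.
#' @return list of class \code{threshold_selection}: \code{best_t},
#'   \code{curve} (t, accuracy, sensitivity, specificity, tss, HFP variable
#'   importances) and \code{reports} (full \code{model_report} per t).
#' @export
threshold_selection <- function(overlaps, covariates, labels, t_grid = 0:49,
                                settings = rf_settings(),
                                label_col = "risk_class") {
  t_grid <- sort(unique(as.integer(t_grid)))
  if (length(t_grid) < 2) stop("need >= 2 thresholds in t_grid")
  reports <- lapply(t_grid, function(tt) {
    ft <- assemble_features(overlaps, covariates, labels, tt,
                            label_col = label_col)
    fit_evaluate(ft, settings)
  })
  names(reports) <- t_grid
  curve <- do.call(rbind, lapply(reports, function(r) {
    imp <- r$importance
    data.frame(t = r$threshold, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               tss = r$tss,
               imp_acc_extent = imp$mean_decrease_accuracy[
                 imp$variable == "high_hfp_extent"],
               imp_acc_change = imp$mean_decrease_accuracy[
                 imp$variable == "high_hfp_change"])
  }))
  rownames(curve) <- NULL
  best_t <- curve$t[which.max(curve$tss)]  # first max: lowest t on ties
  structure(list(best_t = best_t, curve = curve, reports = reports),
            class = "threshold_selection")
}
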