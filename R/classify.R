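#' Enumerate the feature-combination catalogue
#'
#' Default catalogue: hemisphere scope (left-only, right-only, both)
#' crossed with five feature-family sets — posterior activity (IAF +
#' amplitude), posterior activity + intra-hemispheric connectivity, all
#' activity (adding frontal IAF/amplitude), all activity + intra
#' connectivity, and all activity + intra + inter-hemispheric
#' connectivity. Lateralised features never cross the scope boundary;
#' inter-hemispheric features appear only in the last family set.
#'
#' @param scopes subset of `c("L", "R", "LR")`.
#' @param family_sets subset of the five family-set names.
#' @return Tibble with `combination`, `scope`, `family_set`,
#'   `features` (list column) and `n_features`, in deterministic order.
#' @export
enumerate_combinations <- function(
    scopes = c("L", "R", "LR"),
    family_sets = c("posterior_activity", "posterior_activity_intra",
                    "all_activity", "all_activity_intra",
                    "all_activity_intra_inter")) {
  if (length(scopes) == 0 || length(family_sets) == 0)
    stop("empty combination catalogue")
  feats_for <- function(scope, fam) {
    hems <- if (scope == "LR") c("L", "R") else scope
    post <- c(outer(c("iaf_posterior_", "amp_posterior_"), hems, paste0))
    front <- c(outer(c("iaf_frontal_", "amp_frontal_"), hems, paste0))
    intra <- c(outer(c("wpli_intra_", "tli_intra_"), hems, paste0))
    inter <- c("wpli_inter", "tli_inter")
    switch(fam,
           posterior_activity = post,
           posterior_activity_intra = c(post, intra),
           all_activity = c(post, front),
           all_activity_intra = c(post, front, intra),
           all_activity_intra_inter = c(post, front, intra, inter),
           stop("unknown family set: ", fam))
  }
  grid <- expand.grid(family_set = family_sets, scope = scopes,
                      stringsAsFactors = FALSE)
  feats <- purrr::map2(grid$scope, grid$family_set, feats_for)
  tibble::tibble(
    combination = paste(grid$scope, grid$family_set, sep = "."),
    scope = grid$scope, family_set = grid$family_set,
    features = feats,
    n_features = lengths(feats)
  )
}

#' Default model-selection grid
#'
#' Classifier families (L2-regularised logistic regression and linear
#' C-SVM), regularisation strengths `C` in `{0.1, 0.2, 0.3}` and the
#' feature-combination catalogue.
#'
#' @param combinations a catalogue from [enumerate_combinations()].
#' @param C candidate regularisation values (> 0).
#' @param families classifier families, in tie-break preference order.
#' @return A `search_grid` list.
#' @export
default_search_grid <- function(combinations = enumerate_combinations(),
                                C = c(0.1, 0.2, 0.3),
                                families = c("logistic", "svm")) {
  stopifnot(nrow(combinations) > 0, all(C > 0), length(families) > 0)
  structure(list(combinations = combinations, C = sort(C),
                 families = families), class = "search_grid")
}

# ---- internal fitting helpers -------------------------------------------

# y: factor with levels c("LSG","HSG") -> positive class HSG
fit_predict <- function(family, x_tr, y_tr, x_te, C) {
  if (family == "logistic") {
    lam <- 1 / (nrow(x_tr) * C)
    # small folds trip glmnet's tiny-class advisory warning
    fit <- suppressWarnings(
      glmnet::glmnet(x_tr, y_tr, family = "binomial", alpha = 0,
                     lambda = lam, standardize = FALSE))
    p <- as.numeric(stats::predict(fit, x_te, type = "response"))
    list(score = p, pred = ifelse(p >= 0.5, "HSG", "LSG"))
  } else {
    fit <- e1071::svm(x_tr, y_tr, kernel = "linear", cost = C,
                      scale = FALSE)
    pr <- stats::predict(fit, x_te, decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))
    if (colnames(attr(pr, "decision.values")) != "HSG/LSG") dv <- -dv
    list(score = dv, pred = as.character(pr))
  }
}

# logistic path over all C values in one glmnet call
fit_predict_logistic_path <- function(x_tr, y_tr, x_te, Cs) {
  lam <- 1 / (nrow(x_tr) * Cs)  # decreasing in C -> sort decreasing
  o <- order(lam, decreasing = TRUE)
  fit <- suppressWarnings(
    glmnet::glmnet(x_tr, y_tr, family = "binomial", alpha = 0,
                   lambda = lam[o], standardize = FALSE))
  p <- stats::predict(fit, x_te, type = "response")
  p[, order(o), drop = FALSE]  # columns back in the order of Cs
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

scale_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  list(center = mu, scale = sd)
}
scale_apply <- function(x, sc)
  sweep(sweep(x, 2, sc$center), 2, sc$scale, `/`)

balanced_accuracy <- function(truth, pred) {
  sens <- mean(pred[truth == "HSG"] == "HSG")
  spec <- mean(pred[truth == "LSG"] == "LSG")
  (sens + spec) / 2
}

rank_auc <- function(scores, truth) {
  pos <- scores[truth == "HSG"]; neg <- scores[truth == "LSG"]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Classification metrics from confusion counts and scores
#'
#' Sensitivity (high-schizotypy = positive class), specificity, balanced
#' accuracy and rank-statistic AUC. Metrics needing an absent class are
#' `NA`.
#'
#' @param tp,fn,tn,fp confusion counts (HSG positive).
#' @param scores,truth optional decision scores and true labels for the
#'   AUC.
#' @return One-row tibble: `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `auc`.
#' @export
classification_metrics <- function(tp, fn, tn, fp, scores = NULL,
                                   truth = NULL) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    auc = if (is.null(scores)) NA_real_ else rank_auc(scores, truth))
}

#' Nested stratified cross-validation of the alpha-feature classifier
#'
#' Outer stratified k-fold loop for unbiased evaluation; inner
#' stratified k-fold loop on each outer training set jointly selects the
#' feature combination, classifier family and `C` maximising mean
#' balanced accuracy. Feature standardisation is fitted on training rows
#' only at every level. Ties prefer fewer features, then lower `C`, then
#' logistic regression before the SVM. The whole procedure repeats
#' `n_repeats` times with fresh fold assignments.
#'
#' @param features feature tibble with `group` (`"HSG"`/`"LSG"`) and the
#'   columns named by the grid's combinations; rows with missing values
#'   are rejected.
#' @param grid a [default_search_grid()].
#' @param k_outer,k_inner fold counts (default 10; the inner count drops
#'   to the largest feasible stratified value, at least 2).
#' @param n_repeats repetitions of the whole nested procedure.
#' @param seed integer seed; identical seeds give identical reports.
#' @return A `cv_report` list: `folds` (per repetition x outer fold:
#'   selection, confusion counts, metrics, test indices, scaler),
#'   `repetitions` (per-repetition mean metrics), `selection`
#'   (combination frequency table), `roc` (averaged ROC curve), `summary`
#'   (mean/SD of the four metrics), `grid`, `seed`.
#' @export
nested_cv <- function(features, grid = default_search_grid(),
                      k_outer = 10, k_inner = 10, n_repeats = 50,
                      seed = 1) {
  y <- factor(features$group, levels = c("LSG", "HSG"))
  if (any(is.na(y)) || nlevels(droplevels(y)) < 2)
    stop("both classes must be present")
  feat_names <- unique(unlist(grid$combinations$features))
  X <- as.matrix(features[, feat_names])
  if (anyNA(X)) stop("missing feature values: exclude incomplete subjects")
  if (min(table(y)) < k_outer)
    stop("class counts must be >= k_outer")
  # config table in tie-break preference order
  cfg <- expand.grid(ci = seq_len(nrow(grid$combinations)),
                     C = grid$C,
                     family = factor(grid$families, levels = grid$families))
  cfg$n_features <- grid$combinations$n_features[cfg$ci]
  cfg <- cfg[order(cfg$n_features, cfg$ci, cfg$C,
                   as.integer(cfg$family)), ]
  set.seed(seed)
  fold_rows <- vector("list", n_repeats * k_outer)
  roc_scores <- vector("list", n_repeats * k_outer)
  ri <- 0L
  for (rep_i in seq_len(n_repeats)) {
    outer_fold <- stratified_folds(y, k_outer)
    for (of in seq_len(k_outer)) {
      te <- which(outer_fold == of); tr <- which(outer_fold != of)
      sel <- inner_select(X[tr, , drop = FALSE], y[tr], grid, cfg, k_inner)
      sel_feats <- grid$combinations$features[[sel$ci]]
      sc <- scale_fit(X[tr, sel_feats, drop = FALSE])
      xtr <- scale_apply(X[tr, sel_feats, drop = FALSE], sc)
      xte <- scale_apply(X[te, sel_feats, drop = FALSE], sc)
      out <- fit_predict(sel$family, xtr, y[tr], xte, sel$C)
      truth <- as.character(y[te])
      tp <- sum(truth == "HSG" & out$pred == "HSG")
      fn <- sum(truth == "HSG" & out$pred == "LSG")
      tn <- sum(truth == "LSG" & out$pred == "LSG")
      fp <- sum(truth == "LSG" & out$pred == "HSG")
      m <- classification_metrics(tp, fn, tn, fp, out$score, truth)
      ri <- ri + 1L
      fold_rows[[ri]] <- tibble::tibble(
        repetition = rep_i, fold = of,
        combination = grid$combinations$combination[sel$ci],
        family = sel$family, C = sel$C,
        tp = tp, fn = fn, tn = tn, fp = fp,
        sensitivity = m$sensitivity, specificity = m$specificity,
        balanced_accuracy = m$balanced_accuracy, auc = m$auc,
        test_idx = list(te), scaler = list(sc))
      roc_scores[[ri]] <- list(scores = out$score, truth = truth)
    }
  }
  folds <- dplyr::bind_rows(fold_rows)
  repetitions <- dplyr::summarise(
    dplyr::group_by(folds, .data$repetition),
    dplyr::across(c("sensitivity", "specificity", "balanced_accuracy",
                    "auc"), ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  selection <- selection_frequencies(folds, grid)
  summary <- tibble::tibble(
    metric = c("sensitivity", "specificity", "balanced_accuracy", "auc"),
    mean = c(mean(repetitions$sensitivity), mean(repetitions$specificity),
             mean(repetitions$balanced_accuracy), mean(repetitions$auc)),
    sd = c(stats::sd(repetitions$sensitivity),
           stats::sd(repetitions$specificity),
           stats::sd(repetitions$balanced_accuracy),
           stats::sd(repetitions$auc)))
  structure(list(folds = folds, repetitions = repetitions,
                 selection = selection,
                 roc = aggregate_roc(roc_scores),
                 summary = summary, grid = grid, seed = seed,
                 k_outer = k_outer, k_inner = k_inner,
                 n_repeats = n_repeats),
            class = "cv_report")
}

# inner-loop joint selection of (combination, family, C)
inner_select <- function(Xtr, ytr, grid, cfg, k_inner) {
  k <- min(k_inner, min(table(ytr)))
  k <- max(k, 2)
  inner_fold <- stratified_folds(ytr, k)
  ba <- matrix(0, nrow(cfg), k)
  combos <- grid$combinations
  for (f in seq_len(k)) {
    va <- which(inner_fold == f); tr <- which(inner_fold != f)
    sc_full <- scale_fit(Xtr[tr, , drop = FALSE])
    xtr_full <- scale_apply(Xtr[tr, , drop = FALSE], sc_full)
    xva_full <- scale_apply(Xtr[va, , drop = FALSE], sc_full)
    truth <- as.character(ytr[va])
    for (ci in unique(cfg$ci)) {
      cols <- combos$features[[ci]]
      xtr <- xtr_full[, cols, drop = FALSE]
      xva <- xva_full[, cols, drop = FALSE]
      # logistic: one path call across all C
      p <- fit_predict_logistic_path(xtr, ytr[tr], xva, grid$C)
      for (j in seq_along(grid$C)) {
        pred <- ifelse(p[, j] >= 0.5, "HSG", "LSG")
        rows <- which(cfg$ci == ci & cfg$family == "logistic" &
                        cfg$C == grid$C[j])
        ba[rows, f] <- balanced_accuracy(truth, pred)
      }
      if ("svm" %in% grid$families) {
        for (j in seq_along(grid$C)) {
          out <- fit_predict("svm", xtr, ytr[tr], xva, grid$C[j])
          rows <- which(cfg$ci == ci & cfg$family == "svm" &
                          cfg$C == grid$C[j])
          ba[rows, f] <- balanced_accuracy(truth, out$pred)
        }
      }
    }
  }
  mean_ba <- rowMeans(ba)
  best <- which.max(mean_ba)  # cfg is in tie-break preference order
  list(ci = cfg$ci[best], family = as.character(cfg$family[best]),
       C = cfg$C[best], mean_ba = mean_ba[best])
}

selection_frequencies <- function(folds, grid) {
  counts <- table(factor(folds$combination,
                         levels = grid$combinations$combination))
  out <- tibble::tibble(
    combination = names(counts),
    scope = grid$combinations$scope[match(names(counts),
                                          grid$combinations$combination)],
    n_selected = as.integer(counts),
    frequency_pct = 100 * as.integer(counts) / sum(counts))
  dplyr::arrange(out, dplyr::desc(.data$frequency_pct))
}

#' Vertical averaging of per-fold ROC curves
#'
#' Each fold's empirical ROC is evaluated on a common false-positive-rate
#' grid (step interpolation, anchored at (0,0) and (1,1)); the mean,
#' standard deviation and 99.9% normal-approximation confidence interval
#' of the mean true-positive rate are reported per grid point. Folds
#' with a missing class are skipped and counted.
#'
#' @param fold_scores list of `list(scores =, truth =)` per fold, or a
#'   `cv_report`.
#' @param n_grid number of FPR grid points (default 101).
#' @return Tibble of class `roc_summary`: `fpr`, `tpr_mean`, `tpr_sd`,
#'   `tpr_lo`, `tpr_hi`; attribute `n_folds_used`, `n_folds_skipped`.
#' @export
aggregate_roc <- function(fold_scores, n_grid = 101) {
  if (inherits(fold_scores, "cv_report"))
    stop("pass the per-fold score list, not the report")
  fpr_grid <- seq(0, 1, length.out = n_grid)
  curves <- lapply(fold_scores, function(fs) {
    truth <- fs$truth
    if (length(unique(truth)) < 2) return(NULL)
    roc_curve_at(fs$scores, truth, fpr_grid)
  })
  skipped <- sum(vapply(curves, is.null, logical(1)))
  curves <- curves[!vapply(curves, is.null, logical(1))]
  if (length(curves) < 2) stop("need at least two usable fold curves")
  tprs <- do.call(rbind, curves)
  m <- colMeans(tprs)
  s <- apply(tprs, 2, stats::sd)
  z <- stats::qnorm(1 - 0.001 / 2)
  half <- z * s / sqrt(nrow(tprs))
  out <- tibble::tibble(fpr = fpr_grid, tpr_mean = m, tpr_sd = s,
                        tpr_lo = pmax(0, m - half),
                        tpr_hi = pmin(1, m + half))
  attr(out, "n_folds_used") <- nrow(tprs)
  attr(out, "n_folds_skipped") <- skipped
  class(out) <- c("roc_summary", class(out))
  out
}

# stepwise empirical ROC evaluated at given FPR values
roc_curve_at <- function(scores, truth, fpr_grid) {
  pos <- truth == "HSG"
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)), 1)
  stats::approx(fpr, tpr, xout = fpr_grid, method = "constant",
                ties = max, yleft = 0, yright = 1)$y
}

#' Ordered feature-combination selection frequencies
#'
#' @param report a `cv_report`.
#' @return Tibble ordered by decreasing selection frequency; frequencies
#'   sum to 100.
#' @export
ranking_report <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  report$selection
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d repetitions x %d outer folds (inner k = %d, seed %d)\n",
    x$n_repeats, x$k_outer, x$k_inner, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s %.3f (SD %.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  top <- x$selection[1, ]
  cat(sprintf("  top combination: %s (%.1f%%)\n",
              top$combination, top$frequency_pct))
  invisible(x)
}
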