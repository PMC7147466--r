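#' Geometric mean of sensitivity and specificity
#'
#' The model-selection metric: `sqrt(SN * SP)`, on the same percentage scale
#' as its arguments, giving sensitivity and specificity equal weight.
#'
#' @param sn,sp Sensitivity and specificity in percent (0-100).
#' @return Gmean in percent.
#' @examples
#' gmean(100, 99.73)  # 99.86
#' @export
gmean <- function(sn, sp) {
  if (any(!is.finite(c(sn, sp))) || any(c(sn, sp) < 0) || any(c(sn, sp) > 100)) {
    abort("`sn` and `sp` must lie in [0, 100].",
          class = "nhpred_validation_error")
  }
  sqrt(sn * sp)
}

#' Classification metrics from confusion counts
#'
#' @param tp,fn,tn,fp Confusion counts (positives = Class 1, nights with
#'   hypoglycemia).
#' @return One-row tibble `tp`, `fn`, `tn`, `fp`, `sn`, `sp`, `accuracy`,
#'   `gmean`, the rates in percent.
#' @export
metric_set <- function(tp, fn, tn, fp) {
  if (any(c(tp, fn, tn, fp) < 0)) {
    abort("Confusion counts must be nonnegative.",
          class = "nhpred_validation_error")
  }
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  tibble::tibble(
    tp = tp, fn = fn, tn = tn, fp = fp, sn = sn, sp = sp,
    accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
    gmean = if (is.na(sn) || is.na(sp)) NA_real_ else sqrt(sn * sp)
  )
}

#' Stratified fold assignment
#'
#' Assigns instances to `k` cross-validation folds so that each fold's count
#' per class differs from the proportional share by less than one instance.
#' The assignment is a deterministic function of `(labels, k, seed)`.
#'
#' @param labels Vector of class labels (0/1).
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1:k`, one per instance.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  counts <- table(labels)
  small <- counts[counts < k]
  if (length(small) > 0) {
    abort(sprintf("Cannot build %d stratified folds: class %s has only %d member(s).",
                  k, names(small)[1], small[1]),
          class = "nhpred_stratification_error")
  }
  folds <- integer(length(labels))
  local_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}

# Column z-scoring with training-set statistics; zero-variance columns are
# left centred but unscaled.
zscore_apply <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sdev <- apply(x_train, 2, sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sdev, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, sdev, "/"))
}

fit_predict <- function(x_train, y_train, x_test, cv) {
  if (cv$classifier == "svm") {
    w <- length(y_train) / (2 * table(factor(y_train, levels = c(0, 1))))
    v <- var(as.vector(x_train))
    g <- if (is.finite(v) && v > 0) 1 / (ncol(x_train) * v) else 1 / ncol(x_train)
    fit <- e1071::svm(x = x_train, y = factor(y_train, levels = c(0, 1)),
                      kernel = "radial", cost = 1, gamma = g, scale = FALSE,
                      class.weights = c("0" = unname(w["0"]), "1" = unname(w["1"])))
    as.integer(as.character(predict(fit, x_test)))
  } else {
    fit <- nnet::nnet(x = x_train, y = y_train, size = cv$hidden,
                      maxit = cv$maxit, entropy = TRUE, trace = FALSE,
                      rang = 0.5)
    as.integer(predict(fit, x_test) >= 0.5)
  }
}

# Map an 11-bit group mask to feature column indices (catalog order).
mask_to_columns <- function(mask, catalog = feature_catalog()) {
  mask <- as.logical(mask)
  if (length(mask) != max(catalog$group_id)) {
    abort("Mask length must equal the number of feature groups.",
          class = "nhpred_validation_error")
  }
  catalog$index[mask[catalog$group_id]]
}

#' Evaluate one feature-group subset by repeated stratified k-fold CV
#'
#' For every repetition `r` (seeded `base_seed + r`) a stratified fold
#' assignment is drawn; within each fold features are z-scored on the
#' training part, the classifier is fitted and the held-out fold predicted.
#' The k folds' confusion counts are pooled into one metric set per
#' repetition; the subset's score is the arithmetic mean of the
#' per-repetition metrics (in particular mean Gmean is the mean of the
#' per-repetition Gmeans, not the Gmean of mean SN/SP).
#'
#' When the minority class has fewer than `k` members, `k` is reduced to
#' that count (with a message) so the patient remains evaluable.
#'
#' @param x Numeric feature matrix (instances x 29) or a [build_dataset()]
#'   tibble (feature columns `f1`..`f29` are extracted).
#' @param y Integer labels (0/1); taken from `x$label` when `x` is a tibble.
#' @param mask Logical vector over the 11 feature groups.
#' @param cv A [cv_config()].
#' @param catalog The [feature_catalog()].
#' @return A `subset_result` list: `mask`, `columns`, `per_rep` (tibble of
#'   per-repetition metrics), and means `sn`, `sp`, `accuracy`, `gmean`.
#' @export
evaluate_subset <- function(x, y = NULL, mask = rep(TRUE, 11), cv = cv_config(),
                            catalog = feature_catalog()) {
  if (is.data.frame(x)) {
    if (is.null(y)) y <- x$label
    x <- as.matrix(x[paste0("f", catalog$index)])
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!any(mask)) {
    abort("The feature-group mask must select at least one group.",
          class = "nhpred_validation_error")
  }
  cols <- mask_to_columns(mask, catalog)
  xs <- x[, cols, drop = FALSE]
  n_min <- min(table(y))
  k_use <- cv$k
  if (n_min < k_use) {
    k_use <- as.integer(n_min)
    message(sprintf("Minority class has %d member(s); using k = %d.",
                    n_min, k_use))
    if (k_use < 2) {
      abort("Minority class too small for cross-validation.",
            class = "nhpred_stratification_error")
    }
  }
  per_rep <- vector("list", cv$repetitions)
  for (r in seq_len(cv$repetitions)) {
    rep_seed <- cv$base_seed + r
    folds <- stratified_folds(y, k_use, seed = rep_seed)
    tp <- fn <- tn <- fp <- 0L
    skip <- FALSE
    local_seed(rep_seed, {
      for (f in seq_len(k_use)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2) {
          skip <- TRUE
          break
        }
        z <- zscore_apply(xs[tr, , drop = FALSE], xs[!tr, , drop = FALSE])
        pred <- fit_predict(z$train, y[tr], z$test, cv)
        truth <- y[!tr]
        tp <- tp + sum(pred == 1 & truth == 1)
        fn <- fn + sum(pred == 0 & truth == 1)
        tn <- tn + sum(pred == 0 & truth == 0)
        fp <- fp + sum(pred == 1 & truth == 0)
      }
    })
    if (skip) {
      message(sprintf("Repetition %d skipped: degenerate training fold.", r))
      next
    }
    per_rep[[r]] <- metric_set(tp, fn, tn, fp)
  }
  per_rep <- dplyr::bind_rows(per_rep)
  structure(list(
    mask = as.logical(mask),
    columns = cols,
    k = k_use,
    per_rep = per_rep,
    sn = mean(per_rep$sn), sp = mean(per_rep$sp),
    accuracy = mean(per_rep$accuracy), gmean = mean(per_rep$gmean)
  ), class = "subset_result")
}

#' Exhaustive feature-group search
#'
#' Enumerates all 2^11 = 2048 masks over the 11 feature groups (2047
#' evaluated once the empty mask is skipped), scores each by
#' [evaluate_subset()], and ranks by mean Gmean. Ties are broken by fewer
#' selected features, then by ascending mask id.
#'
#' @inheritParams evaluate_subset
#' @param groups Optional integer subset of group ids to search over
#'   (default all 11); the mask space is then `2^length(groups)`.
#' @param progress_every Emit a progress message every this many masks
#'   (0 = silent).
#' @return List with `results` (tibble: `mask_id`, `mask`, `n_features`,
#'   `sn`, `sp`, `accuracy`, `gmean`, `rank`) and `best` (the top
#'   `subset_result`).
#' @export
exhaustive_search <- function(x, y = NULL, cv = cv_config(),
                              catalog = feature_catalog(), groups = NULL,
                              progress_every = 0) {
  n_groups <- max(catalog$group_id)
  if (is.null(groups)) groups <- seq_len(n_groups)
  gbits <- length(groups)
  n_masks <- 2^gbits - 1
  rows <- vector("list", n_masks)
  best <- NULL
  for (m in seq_len(n_masks)) {
    bits <- as.logical(bitwAnd(m, 2^(seq_len(gbits) - 1)))
    mask <- rep(FALSE, n_groups)
    mask[groups[bits]] <- TRUE
    res <- evaluate_subset(x, y, mask, cv, catalog)
    rows[[m]] <- tibble::tibble(
      mask_id = m,
      mask = paste(as.integer(mask), collapse = ""),
      n_features = length(res$columns),
      sn = res$sn, sp = res$sp, accuracy = res$accuracy, gmean = res$gmean
    )
    score <- if (is.finite(res$gmean)) res$gmean else -Inf
    best_score <- if (is.null(best)) -Inf else best$score
    if (is.null(best) || score > best_score ||
        (score == best_score &&
           length(res$columns) < length(best$result$columns))) {
      best <- list(mask_id = m, result = res, score = score)
    }
    if (progress_every > 0 && m %% progress_every == 0) {
      message(sprintf("Evaluated %d / %d masks.", m, n_masks))
    }
  }
  results <- dplyr::bind_rows(rows)
  ord <- order(-results$gmean, results$n_features, results$mask_id)
  results <- results[ord, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  list(results = results, best = best)
}
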