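#' Train a Gaussian naive-Bayes disease-class model
#'
#' Fits, for each class and selected (interval, PC) feature, a univariate
#' Gaussian (mean and variance) plus class priors. The population variance
#' convention (divide by n) is used, so duplicating every training row
#' leaves the model unchanged. Variances are floored at `1e-9` times the
#' mean overall feature variance to keep densities proper.
#' The default feature set is the final model of the pipeline: PC3-PC6
#' scores of the seven [model_intervals()].
#'
#' @param table A `sers_scores` table from [build_score_table()], with
#'   class-labelled rows (>= 2 rows per class).
#' @param features Character vector of feature keys (default
#'   `feature_keys(model_intervals(), 3:6)`).
#' @param priors `"empirical"` (class frequencies, default) or `"uniform"`.
#' @return A `sers_nb` model.
#' @export
train_nb <- function(table, features = feature_keys(model_intervals(), 3:6),
                     priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  missing <- setdiff(features, names(table))
  if (length(missing) > 0) {
    abort(sprintf("Feature(s) not in the score table: %s", paste(missing, collapse = ", ")))
  }
  labs <- as.character(table$class_label)
  classes <- intersect(.CLASS_LEVELS, unique(labs))
  counts <- table(factor(labs, levels = classes))
  if (any(counts < 2)) {
    abort(sprintf(
      "Every class needs at least 2 rows; %s has %d.",
      names(counts)[which.min(counts)], min(counts)
    ))
  }
  x <- as.matrix(table[, features, drop = FALSE])
  floor_var <- 1e-9 * mean(apply(x, 2, var))
  mu <- matrix(NA_real_, length(classes), length(features),
    dimnames = list(classes, features)
  )
  v <- mu
  for (cl in classes) {
    xc <- x[labs == cl, , drop = FALSE]
    mu[cl, ] <- colMeans(xc)
    pop_var <- colMeans(sweep(xc, 2, mu[cl, ])^2)
    v[cl, ] <- pmax(pop_var, floor_var)
  }
  pr <- if (priors == "empirical") {
    as.numeric(counts) / sum(counts)
  } else {
    rep(1 / length(classes), length(classes))
  }
  names(pr) <- classes
  structure(
    list(
      features = features, classes = classes,
      mean = mu, variance = v, priors = pr,
      variance_floor = floor_var, prior_kind = priors,
      n_train = nrow(x)
    ),
    class = "sers_nb"
  )
}

#' @export
print.sers_nb <- function(x, ...) {
  cat(sprintf(
    "<sers_nb: %d classes (%s), %d features, %s priors, trained on %d rows>\n",
    length(x$classes), paste(x$classes, collapse = "/"),
    length(x$features), x$prior_kind, x$n_train
  ))
  invisible(x)
}

#' Classify score-table rows with a naive-Bayes model
#'
#' Computes, in the log domain, `posterior proportional to prior * product
#' of per-feature Gaussian densities` and assigns each row the
#' maximum-posterior class; exact posterior ties are broken by the fixed
#' class order Ctr < MCI < AD.
#'
#' @param model A `sers_nb` model.
#' @param table A score table containing every model feature column.
#' @return A tibble: the table's identity columns, `predicted`, and one
#'   posterior-probability column per class (`post_<class>`), summing to 1
#'   per row.
#' @export
classify_nb <- function(model, table) {
  missing <- setdiff(model$features, names(table))
  if (length(missing) > 0) {
    abort(sprintf("Score table lacks model feature(s): %s", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(table[, model$features, drop = FALSE])
  logpost <- vapply(model$classes, function(cl) {
    ll <- rep(log(model$priors[[cl]]), nrow(x))
    for (j in seq_along(model$features)) {
      ll <- ll + stats::dnorm(x[, j], model$mean[cl, j], sqrt(model$variance[cl, j]), log = TRUE)
    }
    ll
  }, numeric(nrow(x)))
  logpost <- matrix(logpost, nrow = nrow(x))
  mx <- apply(logpost, 1, max)
  post <- exp(logpost - mx)
  post <- post / rowSums(post)
  colnames(post) <- paste0("post_", model$classes)
  pred <- model$classes[apply(logpost, 1, which.max)] # which.max: first max wins
  out <- tibble(
    subject_id = table$subject_id %||% NA_character_,
    replicate_id = table$replicate_id %||% NA_character_,
    class_label = table$class_label %||% factor(NA, levels = .CLASS_LEVELS),
    predicted = factor(pred, levels = .CLASS_LEVELS)
  )
  cbind(out, as_tibble(post)) |> as_tibble()
}

#' @rdname classify_nb
#' @param object A `sers_nb` model.
#' @param newdata A score table.
#' @param ... Unused.
#' @export
predict.sers_nb <- function(object, newdata, ...) {
  classify_nb(object, newdata)
}

#' Overall recall of a model on a labelled score table
#'
#' Overall accuracy (spectra correctly classified over spectra considered),
#' its complement the overall misclassification rate, and the confusion
#' matrix (rows = true class, columns = predicted).
#'
#' @param model A `sers_nb` model.
#' @param table A labelled score table.
#' @return A list: `overall_accuracy`, `misclassification_rate`,
#'   `confusion` (table), `n`.
#' @export
evaluate_recall <- function(model, table) {
  if (is.null(table$class_label) || anyNA(table$class_label)) {
    abort("Recall evaluation needs class labels on every row.")
  }
  calls <- classify_nb(model, table)
  truth <- factor(as.character(table$class_label), levels = model$classes)
  pred <- factor(as.character(calls$predicted), levels = model$classes)
  acc <- mean(as.character(truth) == as.character(pred))
  list(
    overall_accuracy = acc,
    misclassification_rate = 1 - acc,
    confusion = table(truth = truth, predicted = pred),
    n = nrow(calls)
  )
}

#' @describeIn train_nb Per class-feature parameters, one row each.
#' @param x A `sers_nb` model.
#' @param ... Unused.
#' @method tidy sers_nb
#' @export
tidy.sers_nb <- function(x, ...) {
  grid <- expand.grid(
    class = x$classes, feature = x$features,
    stringsAsFactors = FALSE
  )
  tibble(
    class = grid$class, feature = grid$feature,
    mean = x$mean[cbind(grid$class, grid$feature)],
    variance = x$variance[cbind(grid$class, grid$feature)],
    prior = x$priors[grid$class]
  )
}

#' @describeIn train_nb One-row model summary.
#' @method glance sers_nb
#' @export
glance.sers_nb <- function(x, ...) {
  tibble(
    n_classes = length(x$classes), n_features = length(x$features),
    prior_kind = x$prior_kind, n_train = x$n_train,
    variance_floor = x$variance_floor
  )
}

#' Search (interval, PC) feature subsets for the best training recall
#'
#' Mechanises the manual model inspection step: enumerates combinations of
#' candidate intervals and candidate PC index sets, trains a naive-Bayes
#' model on each, and returns the combination maximising training-set
#' recall. Enumeration is exhaustive over PC sets crossed with a greedy
#' forward search over intervals, capped at `budget` evaluated models. Ties
#' are broken by fewer features, then lexicographic feature keys.
#'
#' @param table A labelled `sers_scores` table.
#' @param candidate_intervals Character vector of interval labels.
#' @param candidate_pcs List of integer vectors, each a candidate PC set
#'   (default: all contiguous ranges within 1..7).
#' @param budget Maximum number of models evaluated (default 500).
#' @param priors Passed to [train_nb()].
#' @return A list: `model` (best `sers_nb`), `recall`, `features`,
#'   `intervals`, `pcs`, and `log` (tibble of every evaluated subset).
#' @export
search_feature_subsets <- function(table,
                                   candidate_intervals = model_intervals(),
                                   candidate_pcs = NULL,
                                   budget = 500,
                                   priors = "empirical") {
  if (length(candidate_intervals) == 0) abort("`candidate_intervals` must be non-empty.")
  if (is.null(candidate_pcs)) {
    candidate_pcs <- list()
    for (a in 1:7) {
      for (b in a:7) candidate_pcs[[length(candidate_pcs) + 1]] <- a:b
    }
  }
  if (length(candidate_pcs) == 0) abort("`candidate_pcs` must be non-empty.")
  evals <- 0L
  log <- list()
  best <- NULL
  consider <- function(intervals, pcs) {
    if (evals >= budget) {
      return(NULL)
    }
    evals <<- evals + 1L
    feats <- feature_keys(intervals, pcs)
    fit <- train_nb(table, features = feats, priors = priors)
    rec <- evaluate_recall(fit, table)$overall_accuracy
    log[[length(log) + 1L]] <<- tibble(
      intervals = paste(intervals, collapse = ","),
      pcs = paste(pcs, collapse = ","),
      n_features = length(feats), recall = rec
    )
    cand <- list(
      model = fit, recall = rec, features = feats,
      intervals = intervals, pcs = pcs
    )
    if (is.null(best) ||
      rec > best$recall ||
      (rec == best$recall && length(feats) < length(best$features)) ||
      (rec == best$recall && length(feats) == length(best$features) &&
        paste(sort(feats), collapse = ";") < paste(sort(best$features), collapse = ";"))) {
      best <<- cand
    }
    cand
  }
  for (pcs in candidate_pcs) {
    # greedy forward selection over intervals for this PC set
    chosen <- character()
    repeat {
      remaining <- setdiff(candidate_intervals, chosen)
      if (length(remaining) == 0 || evals >= budget) break
      scored <- lapply(remaining, function(iv) consider(c(chosen, iv), pcs))
      scored <- scored[!vapply(scored, is.null, TRUE)]
      if (length(scored) == 0) break
      recs <- vapply(scored, function(sc) sc$recall, 1)
      pick <- scored[[which.max(recs)]]
      prev_best <- if (length(chosen) == 0) -Inf else best_for_chosen
      if (length(chosen) > 0 && max(recs) <= prev_best) break
      chosen <- pick$intervals
      best_for_chosen <- pick$recall
      if (best_for_chosen >= 1) break
    }
    # always also evaluate the full candidate set for this PC range
    if (evals < budget && length(candidate_intervals) > 1) {
      consider(candidate_intervals, pcs)
    }
    if (evals >= budget) break
  }
  c(best, list(log = do.call(rbind, log), n_evaluated = evals))
}
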