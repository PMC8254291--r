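# Nonadditivity-aware QSAR study: labeling, splitting strategies,
# fingerprint regression with randomized hyperparameter search, evaluation
# on additive vs nonadditive test sets, and mixin experiments.

#' Select assays eligible for the QSAR study
#'
#' An assay qualifies when it produced nonadditivity output and is large
#' enough: more than `min_compounds` compounds and more than `min_cycles`
#' double-transformation cycles.
#'
#' @param summaries data frame of row-bound [assay_summary()] results.
#' @param min_compounds,min_cycles strict lower bounds (defaults 200 / 25).
#' @return character vector of `assay_id`s.
#' @export
select_assays <- function(summaries, min_compounds = 200L,
                          min_cycles = 25L) {
  ok <- summaries$n_cycles > 0 &
    summaries$n_compounds > min_compounds &
    summaries$n_cycles > min_cycles
  summaries$assay_id[ok]
}

#' Label compounds by their nonadditivity status
#'
#' A compound occurring in at least one cycle whose absolute nonadditivity
#' exceeds `threshold` is `nonadditive`; other cycle members are
#' `additive`; compounds in no cycle are `no_dtc`.
#'
#' @param assay curated assay data frame (`compound_id`, `smiles`, `pact`).
#' @param cycles data frame from [cycle_nonadditivity()].
#' @param threshold significance cut-off in log units (default 1.0, twice
#'   the heterogeneous-data experimental uncertainty).
#' @return data frame `compound_id`, `smiles`, `pact`, `in_dtc`,
#'   `na_label`.
#' @export
label_compounds <- function(assay, cycles, threshold = 1.0) {
  members <- unique(c(cycles$c1, cycles$c2, cycles$c3, cycles$c4))
  sig_cyc <- abs(cycles$nonadditivity) > threshold
  sig <- unique(c(cycles$c1[sig_cyc], cycles$c2[sig_cyc],
                  cycles$c3[sig_cyc], cycles$c4[sig_cyc]))
  out <- assay[, c("compound_id", "smiles", "pact")]
  out$in_dtc <- out$compound_id %in% members
  out$na_label <- ifelse(!out$in_dtc, "no_dtc",
                         ifelse(out$compound_id %in% sig,
                                "nonadditive", "additive"))
  out
}

# stratified split on pActivity deciles; returns list(train, test) of row
# indices into df
.stratified_split <- function(pact, train_fraction, seed) {
  .with_seed(seed, {
    n <- length(pact)
    br <- unique(stats::quantile(pact, probs = seq(0, 1, 0.1)))
    bin <- if (length(br) > 2L)
      cut(pact, breaks = br, include.lowest = TRUE) else factor(rep(1L, n))
    train <- integer(0)
    for (lv in levels(bin)) {
      idx <- which(bin == lv)
      k <- round(train_fraction * length(idx))
      train <- c(train, sample(idx, k))
    }
    list(train = sort(train), test = sort(setdiff(seq_len(n), train)))
  })
}

#' Split labeled compounds for model training
#'
#' Three strategies:
#' \describe{
#'   \item{dtc}{additive compounds occurring in cycles are split 80/20
#'     (stratified on pActivity deciles) into train and additive test; all
#'     nonadditive compounds form the nonadditive hold-out; `no_dtc`
#'     compounds are excluded.}
#'   \item{all}{as `dtc`, but compounds without cycle membership are
#'     assumed additive and join the pool.}
#'   \item{ab}{cycle-informed: iterating cycles from a seed-chosen random
#'     starting point, the singly-transformed corners (c2, c4) and the
#'     untransformed corner (c1) are assigned to training and the
#'     doubly-transformed corner (c3) to the AB test set; once assigned, a
#'     compound keeps its role and conflicting cycles are skipped.
#'     Nonadditive compounds never remain in training: those assigned
#'     there, or left unassigned, form the remaining-nonadditive test set.
#'     The AB test set is reported split into additive and nonadditive
#'     parts. With `include_non_dtc`, non-cycle compounds are split 80/20
#'     into extra training data and a fourth test set.}
#' }
#'
#' @param labeled data frame from [label_compounds()].
#' @param strategy `"dtc"`, `"all"` or `"ab"`.
#' @param cycles cycle data frame (required for `"ab"`).
#' @param seed integer seed controlling the stratified draw / starting
#'   point.
#' @param train_fraction training fraction (default 0.8).
#' @param include_non_dtc for `"ab"`: also use non-cycle compounds.
#' @return list with `strategy`, `seed`, `train` (data frame) and `tests`
#'   (named list of data frames); train and every test set are disjoint.
#' @export
make_split <- function(labeled, strategy = c("dtc", "all", "ab"),
                       cycles = NULL, seed = 1L, train_fraction = 0.8,
                       include_non_dtc = FALSE) {
  strategy <- match.arg(strategy)
  na_set <- labeled[labeled$na_label == "nonadditive", , drop = FALSE]
  if (strategy %in% c("dtc", "all")) {
    pool <- if (strategy == "dtc")
      labeled[labeled$na_label == "additive", , drop = FALSE]
    else labeled[labeled$na_label %in% c("additive", "no_dtc"), ,
                 drop = FALSE]
    sp <- .stratified_split(pool$pact, train_fraction, seed)
    out <- list(strategy = strategy, seed = seed,
                train = pool[sp$train, , drop = FALSE],
                tests = list(additive = pool[sp$test, , drop = FALSE],
                             nonadditive = na_set))
  } else {
    stopifnot(!is.null(cycles), nrow(cycles) > 0)
    role <- character(0)  # named: "train" / "ab"
    ord <- .with_seed(seed, {
      start <- sample(nrow(cycles), 1L)
      c(start:nrow(cycles), if (start > 1L) 1:(start - 1L))
    })
    for (r in ord) {
      cs <- c(cycles$c1[r], cycles$c2[r], cycles$c4[r])
      ab <- cycles$c3[r]
      if (any(role[cs] == "ab", na.rm = TRUE) ||
          isTRUE(role[ab] == "train")) next
      role[cs] <- "train"
      role[ab] <- "ab"
    }
    assigned <- names(role)
    train_ids <- assigned[role == "train"]
    ab_ids <- assigned[role == "ab"]
    sig_ids <- na_set$compound_id
    rem_na <- setdiff(sig_ids, ab_ids)           # incl. any in training
    train_ids <- setdiff(train_ids, sig_ids)
    take <- function(ids) {
      out <- labeled[match(ids, labeled$compound_id), , drop = FALSE]
      rownames(out) <- NULL
      out
    }
    tests <- list(
      ab_additive = take(setdiff(ab_ids, sig_ids)),
      ab_nonadditive = take(intersect(ab_ids, sig_ids)),
      remaining_nonadditive = take(rem_na))
    train <- take(train_ids)
    if (include_non_dtc) {
      nod <- labeled[labeled$na_label == "no_dtc", , drop = FALSE]
      if (nrow(nod)) {
        sp <- .stratified_split(nod$pact, train_fraction, seed)
        train <- rbind(train, nod[sp$train, , drop = FALSE])
        tests$non_dtc <- nod[sp$test, , drop = FALSE]
      }
    }
    out <- list(strategy = strategy, seed = seed, train = train,
                tests = tests)
  }
  all_test <- unlist(lapply(out$tests, function(t) t$compound_id))
  if (length(intersect(out$train$compound_id, all_test)))
    stop("internal error: train/test overlap")
  out
}

# ---- model training ---------------------------------------------------------

.r2 <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / sst
}
.rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

.sample_params <- function(algorithm, p) {
  switch(algorithm,
         rf = list(num.trees = sample(seq(100L, 1000L, by = 50L), 1L),
                   mtry = max(1L, floor(stats::runif(1, 0.05, 0.6) * p)),
                   min.node.size = sample(c(1L, 3L, 5L, 10L), 1L)),
         svm = list(cost = 10^stats::runif(1, -1, 3),
                    gamma = 10^stats::runif(1, -5, -1)),
         pls = list(ncomp = sample(2:min(50L, p - 1L), 1L)))
}

.fit_one <- function(algorithm, x, y, params, seed = 1L) {
  switch(algorithm,
         rf = ranger::ranger(x = x, y = y, num.trees = params$num.trees,
                             mtry = min(params$mtry, ncol(x)),
                             min.node.size = params$min.node.size,
                             num.threads = 1L, seed = seed,
                             verbose = FALSE),
         svm = e1071::svm(x = x, y = y, type = "eps-regression",
                          kernel = "radial", cost = params$cost,
                          gamma = params$gamma, scale = FALSE),
         pls = {
           if (!requireNamespace("mixOmics", quietly = TRUE))
             stop("the pls algorithm requires the mixOmics package")
           nc <- min(params$ncomp, ncol(x), nrow(x) - 1L)
           m <- mixOmics::pls(x, y, ncomp = nc, mode = "regression")
           list(model = m, ncomp = nc)
         })
}

.predict_one <- function(algorithm, fit, x) {
  switch(algorithm,
         rf = stats::predict(fit, data = x, num.threads = 1L)$predictions,
         svm = as.numeric(stats::predict(fit, x)),
         pls = {
           pr <- stats::predict(fit$model, x)
           as.numeric(pr$predict[, 1L, fit$ncomp])
         })
}

#' Train a fingerprint regression model with hyperparameter search
#'
#' Randomized hyperparameter search scored by mean cross-validated R^2,
#' followed by a refit on the full training set with the best
#' configuration. Search spaces: random forest (number of trees, mtry
#' fraction, minimum node size), RBF-kernel support vector regression
#' (cost and gamma, log-uniform) and PLS regression (number of
#' components).
#'
#' @param x numeric feature matrix (training compounds in rows).
#' @param y numeric response (pActivity).
#' @param algorithm `"rf"`, `"svm"` or `"pls"`.
#' @param n_trials number of sampled configurations (default 20; the
#'   search is randomized rather than surrogate-guided).
#' @param folds number of cross-validation folds (default 5).
#' @param seed RNG seed for fold assignment and the search.
#' @return object of class `qsar_model`: `algorithm`, `fit`, `params`,
#'   `cv_r2` (mean CV R^2 of the best configuration), `cv_rmse`,
#'   `features` (columns retained after dropping zero-variance features).
#' @export
train_model <- function(x, y, algorithm = c("rf", "svm", "pls"),
                        n_trials = 20L, folds = 5L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (stats::var(y) == 0) stop("degenerate response: zero variance")
  keep <- which(apply(x, 2L, function(col) any(col != col[1L])))
  if (!length(keep)) stop("no informative features")
  x <- x[, keep, drop = FALSE]
  if (is.null(colnames(x))) colnames(x) <- paste0("fp", keep)
  .with_seed(seed, {
    fold <- sample(rep_len(seq_len(folds), nrow(x)))
    best <- NULL
    for (trial in seq_len(n_trials)) {
      params <- .sample_params(algorithm, ncol(x))
      r2s <- numeric(folds); rmses <- numeric(folds)
      ok <- TRUE
      for (f in seq_len(folds)) {
        tr <- fold != f
        fit <- tryCatch(
          .fit_one(algorithm, x[tr, , drop = FALSE], y[tr], params,
                   seed = seed + f),
          error = function(e) NULL)
        if (is.null(fit)) { ok <- FALSE; break }
        pred <- .predict_one(algorithm, fit, x[!tr, , drop = FALSE])
        r2s[f] <- .r2(y[!tr], pred)
        rmses[f] <- .rmse(y[!tr], pred)
      }
      if (!ok) next
      score <- mean(r2s)
      if (is.null(best) || score > best$cv_r2)
        best <- list(params = params, cv_r2 = score,
                     cv_rmse = mean(rmses))
    }
    if (is.null(best)) stop("no hyperparameter configuration succeeded")
    fit <- .fit_one(algorithm, x, y, best$params, seed = seed)
    structure(list(algorithm = algorithm, fit = fit,
                   params = best$params, cv_r2 = best$cv_r2,
                   cv_rmse = best$cv_rmse, features = keep),
              class = "qsar_model")
  })
}

#' Fit a regression model with fixed hyperparameters
#'
#' Used by protocols that reuse hyperparameters established by an earlier
#' search (e.g. the mixin experiments) instead of re-searching.
#'
#' @param x feature matrix.
#' @param y response.
#' @param algorithm `"rf"`, `"svm"` or `"pls"`.
#' @param params hyperparameter list in the shape produced by
#'   [train_model()]'s `params`.
#' @param seed RNG seed for stochastic learners.
#' @return a `qsar_model`.
#' @export
fit_qsar <- function(x, y, algorithm = c("rf", "svm", "pls"), params,
                     seed = 1L) {
  algorithm <- match.arg(algorithm)
  keep <- which(apply(x, 2L, function(col) any(col != col[1L])))
  x <- x[, keep, drop = FALSE]
  if (is.null(colnames(x))) colnames(x) <- paste0("fp", keep)
  fit <- .fit_one(algorithm, x, y, params, seed = seed)
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 cv_r2 = NA_real_, cv_rmse = NA_real_, features = keep),
            class = "qsar_model")
}

#' Predict pActivities with a trained model
#'
#' @param object a `qsar_model`.
#' @param x feature matrix in the full (unfiltered) fingerprint space.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.qsar_model <- function(object, x, ...) {
  .predict_one(object$algorithm, object$fit,
               x[, object$features, drop = FALSE])
}

#' Matthews correlation coefficient
#'
#' @param truth,pred binary vectors (0/1).
#' @return MCC in `[-1, 1]`; `NA` when a marginal is degenerate (one class
#'   absent from truth or prediction).
#' @export
mcc <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / den
}

#' Evaluate a model on one or more test sets
#'
#' Continuous metrics (R^2, RMSE) plus a binarized evaluation: truths and
#' predictions are dichotomized at pActivity 5 (class 1 strictly above 5)
#' and summarized by MCC and the confusion matrix.
#'
#' @param model a `qsar_model`.
#' @param tests named list; each element a list with `x` (feature matrix)
#'   and `y` (pActivity truth).
#' @param threshold binarization threshold (default 5.0).
#' @return data frame with one row per test set: `test`, `n`, `r2`,
#'   `rmse`, `mcc`, `tp`, `tn`, `fp`, `fn`.
#' @export
evaluate_model <- function(model, tests, threshold = 5.0) {
  rows <- lapply(names(tests), function(nm) {
    x <- tests[[nm]]$x; y <- tests[[nm]]$y
    if (!nrow(x)) {
      return(data.frame(test = nm, n = 0L, r2 = NA_real_, rmse = NA_real_,
                        mcc = NA_real_, tp = 0L, tn = 0L, fp = 0L,
                        fn = 0L))
    }
    pred <- predict(model, x)
    bt <- as.integer(y > threshold)
    bp <- as.integer(pred > threshold)
    data.frame(test = nm, n = length(y), r2 = .r2(y, pred),
               rmse = .rmse(y, pred), mcc = mcc(bt, bp),
               tp = sum(bt == 1 & bp == 1), tn = sum(bt == 0 & bp == 0),
               fp = sum(bt == 0 & bp == 1), fn = sum(bt == 1 & bp == 0))
  })
  do.call(rbind, rows)
}

#' Nested mixin draws of nonadditive compounds
#'
#' Draws nonadditive compounds for augmenting a training set at several
#' fractions of the training-set size. The draws are nested (each smaller
#' fraction is a subset of the next), so the fixed nonadditive hold-out —
#' the pool minus the largest draw — is identical across fractions and
#' never overlaps any augmented training set.
#'
#' @param na_pool data frame of nonadditive compounds (with `compound_id`
#'   and `pact`).
#' @param train_size number of training compounds the fractions refer to.
#' @param fractions increasing mixin fractions (defaults: quartiles of the
#'   per-assay nonadditive-compound fraction, 0.6%, 1.3%, 2.6%).
#' @param seed RNG seed.
#' @return list with `draws` (named list of compound ID vectors, one per
#'   fraction including `0`) and `holdout` (data frame).
#' @export
mixin_draws <- function(na_pool, train_size,
                        fractions = c(0.006, 0.013, 0.026), seed = 1L) {
  stopifnot(all(diff(fractions) > 0))
  ks <- round(fractions * train_size)
  if (max(ks) > nrow(na_pool))
    stop("nonadditive pool too small for requested fraction")
  .with_seed(seed, {
    sp <- .stratified_split(na_pool$pact,
                            max(ks) / nrow(na_pool), seed)
    q3 <- na_pool$compound_id[sp$train]
    # force the largest draw to its exact size (stratification rounds)
    if (length(q3) > max(ks)) {
      q3 <- sample(q3, max(ks))
    } else if (length(q3) < max(ks)) {
      extra <- setdiff(na_pool$compound_id, q3)
      q3 <- c(q3, sample(extra, max(ks) - length(q3)))
    }
    draws <- list("0" = character(0))
    prev <- sample(q3)   # random order once; prefixes give nesting
    for (i in seq_along(ks))
      draws[[as.character(fractions[i])]] <- sort(prev[seq_len(ks[i])])
    holdout <- na_pool[!na_pool$compound_id %in% q3, , drop = FALSE]
    list(draws = draws, holdout = holdout)
  })
}
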