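# Scenario protocols and result analysis. Scenario A trains and tests on
# unloaded gait (10-fold cross-validation at trial level, every subject in
# every training fold); Scenario B trains on unloaded and tests on loaded
# gait (the covariate stress test); Scenario C is B with the x9 augmented
# training set. Test data are never augmented.

#' Top-k accuracy
#'
#' For rankings, the fraction of samples whose true class appears among the
#' first `k` positions; for ensemble decisions (`k = 1`), the fraction of
#' correct predictions, with `None` outputs counting as errors.
#'
#' @param x a [top_rankings()] matrix or an `ensemble_decision` data frame.
#' @param labels true class ids.
#' @param k cutoff (ignored for decisions).
#' @return a single number in `[0, 1]`.
#' @export
topk_accuracy <- function(x, labels, k = 1L) {
  if (inherits(x, "ensemble_decision")) {
    if (nrow(x) == 0L) stop("empty decision set", call. = FALSE)
    return(decision_accuracy(x, labels))
  }
  topp_accuracy(x, labels, p = min(k, ncol(x)))
}

fit_harness <- function(train, configs, seed) {
  models <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    models[[i]] <- fit_classifier(
      train, architecture = cf$architecture,
      config = if (is.null(cf$config)) list() else cf$config,
      seed = seed + i,
      classifier_id = if (is.null(names(configs)[i]) ||
                          names(configs)[i] == "")
        cf$architecture else names(configs)[i])
  }
  models
}

evaluate_split <- function(models, test, labels_test, T, lambda_grid) {
  posts <- lapply(models, predict, newdata = test)
  rankings <- lapply(posts, top_rankings, T = T)
  base <- data.frame(
    classifier = vapply(models, function(m) m$classifier_id, character(1)),
    top1 = vapply(rankings, topp_accuracy, numeric(1), labels = labels_test,
                  p = 1L),
    top5 = vapply(rankings, function(r)
      topp_accuracy(r, labels_test, p = min(5L, ncol(r))), numeric(1)),
    stringsAsFactors = FALSE)
  rf <- rank_fusion(models, T = T)
  dec_ro <- predict(rf, posts, strategy = "rank_order")
  sw <- sweep_lambda(rf, posts, labels_test, grid = lambda_grid)
  dec_tt <- predict(rf, posts, strategy = "topT", lambda = sw$lambda_star)
  list(base = base, fusion = rf,
       rank_order = list(accuracy = decision_accuracy(dec_ro, labels_test),
                         ties = sum(dec_ro$tie), decision = dec_ro),
       topT = list(accuracy = sw$accuracy, lambda_star = sw$lambda_star,
                   ties = sum(dec_tt$tie), decision = dec_tt,
                   curve = sw$curve),
       posteriors = posts)
}

#' Run a train/test scenario end to end
#'
#' Fits the configured base classifiers, builds the rank-fusion ensemble on
#' their validation splits, and evaluates base and ensemble accuracy under
#' the requested protocol:
#' * `"A"` -- reference: k-fold cross-validation over the unloaded cycles,
#'   folds drawn at trial level within each subject (closed-set: every
#'   subject appears in every training fold); mean and sd across folds.
#' * `"B"` -- covariate stress: train on all unloaded, test on all loaded
#'   cycles.
#' * `"C"` -- as B, with [expand_scenario_c()] applied to the training set
#'   only (the test set is never augmented).
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param unloaded,loaded two [gait_dataset()]s sharing the subject roster.
#' @param configs list of classifier specs, each a list with
#'   `architecture` and optional `config`; list names become classifier
#'   ids.
#' @param seed integer seed (fold assignment, fitting, augmentation).
#' @param T ranking depth of the ensemble.
#' @param lambda_grid grid for the Top-T lambda sweep.
#' @param folds number of cross-validation folds (scenario A).
#' @return an object of class `scenario_report`.
#' @export
run_scenario <- function(scenario = c("A", "B", "C"), unloaded, loaded,
                         configs, seed = 1L, T = 5L,
                         lambda_grid = seq(0.1, 5, by = 0.1), folds = 10L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(unloaded, "gait_dataset"))
  labels_unl <- dataset_labels(unloaded)
  T <- min(T, length(unique(labels_unl)))  # Top-T cannot exceed the classes

  if (scenario == "A") {
    set.seed(seed)
    fold_of <- integer(length(labels_unl))
    for (s in unique(labels_unl)) {
      idx <- which(labels_unl == s)
      if (length(idx) < folds) {
        stop("subject ", s, " has fewer cycles than folds", call. = FALSE)
      }
      fold_of[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    per_fold <- vector("list", folds)
    for (f in seq_len(folds)) {
      train <- gait_dataset(unloaded$cycles[fold_of != f])
      test <- gait_dataset(unloaded$cycles[fold_of == f])
      models <- fit_harness(train, configs, seed + 100L * f)
      per_fold[[f]] <- evaluate_split(models, test, labels_unl[fold_of == f],
                                      T, lambda_grid)
    }
    base_mat <- sapply(per_fold, function(r) r$base$top1)
    top5_mat <- sapply(per_fold, function(r) r$base$top5)
    if (is.null(dim(base_mat))) {
      base_mat <- matrix(base_mat, nrow = 1L)
      top5_mat <- matrix(top5_mat, nrow = 1L)
    }
    base <- data.frame(
      classifier = per_fold[[1L]]$base$classifier,
      top1 = rowMeans(base_mat), top1_sd = apply(base_mat, 1, stats::sd),
      top5 = rowMeans(top5_mat), top5_sd = apply(top5_mat, 1, stats::sd),
      stringsAsFactors = FALSE)
    ro_acc <- vapply(per_fold, function(r) r$rank_order$accuracy, numeric(1))
    tt_acc <- vapply(per_fold, function(r) r$topT$accuracy, numeric(1))
    ensemble <- data.frame(
      strategy = c("rank_order", "topT"),
      accuracy = c(mean(ro_acc), mean(tt_acc)),
      accuracy_sd = c(stats::sd(ro_acc), stats::sd(tt_acc)),
      lambda_star = c(NA_real_,
                      mean(vapply(per_fold, function(r) r$topT$lambda_star,
                                  numeric(1)))),
      ties = c(sum(vapply(per_fold, function(r) r$rank_order$ties, numeric(1))),
               sum(vapply(per_fold, function(r) r$topT$ties, numeric(1)))),
      stringsAsFactors = FALSE)
    curve <- per_fold[[1L]]$topT$curve
    curve$accuracy <- rowMeans(sapply(per_fold, function(r) r$topT$curve$accuracy))
    report <- list(scenario = scenario, base = base, ensemble = ensemble,
                   lambda_curve = curve, folds = folds,
                   per_fold = lapply(per_fold, function(r)
                     r[c("base", "rank_order", "topT")]))
  } else {
    stopifnot(inherits(loaded, "gait_dataset"))
    train <- unloaded
    if (scenario == "C") train <- expand_scenario_c(train, seed = seed)
    labels_test <- dataset_labels(loaded)
    models <- fit_harness(train, configs, seed)
    res <- evaluate_split(models, loaded, labels_test, T, lambda_grid)
    ensemble <- data.frame(
      strategy = c("rank_order", "topT"),
      accuracy = c(res$rank_order$accuracy, res$topT$accuracy),
      accuracy_sd = NA_real_,
      lambda_star = c(NA_real_, res$topT$lambda_star),
      ties = c(res$rank_order$ties, res$topT$ties),
      stringsAsFactors = FALSE)
    report <- list(scenario = scenario, base = res$base, ensemble = ensemble,
                   lambda_curve = res$topT$curve, fusion = res$fusion,
                   decisions = list(rank_order = res$rank_order$decision,
                                    topT = res$topT$decision),
                   test_labels = labels_test,
                   test_posteriors = res$posteriors,
                   val_posteriors = lapply(models, `[[`, "val_posteriors"),
                   val_labels = models[[1L]]$val_labels,
                   train_size = length(train$cycles),
                   test_size = length(loaded$cycles))
  }
  structure(report, class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> Scenario %s\n", x$scenario))
  cat("base classifiers (Top-1 / Top-5):\n")
  for (i in seq_len(nrow(x$base))) {
    if (!is.null(x$base$top1_sd)) {
      cat(sprintf("  %-16s %.4f +/- %.4f  /  %.4f\n", x$base$classifier[i],
                  x$base$top1[i], x$base$top1_sd[i], x$base$top5[i]))
    } else {
      cat(sprintf("  %-16s %.4f  /  %.4f\n", x$base$classifier[i],
                  x$base$top1[i], x$base$top5[i]))
    }
  }
  cat("ensemble:\n")
  for (i in seq_len(nrow(x$ensemble))) {
    cat(sprintf("  %-12s accuracy %.4f%s, ties %d\n",
                x$ensemble$strategy[i], x$ensemble$accuracy[i],
                if (!is.na(x$ensemble$lambda_star[i]))
                  sprintf(" (lambda* = %g)", x$ensemble$lambda_star[i]) else "",
                x$ensemble$ties[i]))
  }
  invisible(x)
}

#' Leave-one-out ablation of the ensemble
#'
#' Removes each base classifier in turn, recomputes the rank and weight
#' tables with the remaining K - 1 (ranks are re-derived, not inherited),
#' re-votes on the test set, and reports accuracy, the change against the
#' full ensemble, the number of voting ties, and (for the Top-T strategy)
#' the re-swept lambda optimum.
#'
#' @param val_posteriors list of K posterior matrices on the labelled
#'   validation set (weight estimation data).
#' @param labels_val validation labels.
#' @param test_posteriors list of K posterior matrices on the test set.
#' @param labels_test test labels.
#' @param strategy `"topT"` or `"rank_order"`.
#' @param lambda `"sweep"` (re-optimize per variant) or a fixed number
#'   (Top-T strategy only).
#' @param T ranking depth.
#' @param lambda_grid sweep grid.
#' @return data frame with one row for the full ensemble (`removed =
#'   "none"`) and one per removed classifier: `removed`, `accuracy`,
#'   `delta`, `ties`, `lambda_star`.
#' @export
ablate_leave_one_out <- function(val_posteriors, labels_val,
                                 test_posteriors, labels_test,
                                 strategy = c("topT", "rank_order"),
                                 lambda = "sweep", T = 5L,
                                 lambda_grid = seq(0.1, 5, by = 0.1)) {
  strategy <- match.arg(strategy)
  K <- length(val_posteriors)
  if (K < 2L) stop("ablation needs at least 2 classifiers", call. = FALSE)
  ids <- vapply(seq_len(K), function(j) {
    id <- attr(val_posteriors[[j]], "classifier_id")
    if (is.null(id)) paste0("clf", j) else id
  }, character(1))

  eval_subset <- function(keep) {
    rf <- rank_fusion(val_posteriors[keep], labels_val, T = T)
    if (strategy == "rank_order") {
      dec <- predict(rf, test_posteriors[keep], strategy = "rank_order")
      data.frame(accuracy = decision_accuracy(dec, labels_test),
                 ties = sum(dec$tie), lambda_star = NA_real_)
    } else if (identical(lambda, "sweep")) {
      sw <- sweep_lambda(rf, test_posteriors[keep], labels_test,
                         grid = lambda_grid)
      dec <- predict(rf, test_posteriors[keep], lambda = sw$lambda_star)
      data.frame(accuracy = sw$accuracy, ties = sum(dec$tie),
                 lambda_star = sw$lambda_star)
    } else {
      dec <- predict(rf, test_posteriors[keep], lambda = lambda)
      data.frame(accuracy = decision_accuracy(dec, labels_test),
                 ties = sum(dec$tie), lambda_star = lambda)
    }
  }

  full <- eval_subset(seq_len(K))
  rows <- list(cbind(data.frame(removed = "none"), full, delta = 0))
  for (j in seq_len(K)) {
    r <- eval_subset(setdiff(seq_len(K), j))
    rows[[j + 1L]] <- cbind(data.frame(removed = ids[j]), r,
                            delta = r$accuracy - full$accuracy)
  }
  out <- do.call(rbind, rows)
  out[, c("removed", "accuracy", "delta", "ties", "lambda_star")]
}

#' Body-mass-gap analysis of misclassifications
#'
#' For every misclassified sample (with a concrete wrong prediction; `None`
#' outputs carry no predicted identity and are excluded from the pairing),
#' computes the absolute body-mass difference between the true and the
#' predicted subject, then summarizes the gaps as a histogram and an
#' empirical cumulative distribution evaluated at the requested thresholds.
#' In a GRF-based system errors are expected to concentrate among subjects
#' of similar mass, because force amplitudes scale with body weight.
#'
#' @param decisions an `ensemble_decision` data frame, or a character
#'   vector of predicted class ids (`NA` = None).
#' @param labels true class ids.
#' @param roster data frame with columns `subject_id` and `body_mass_kg`
#'   covering every class.
#' @param bin_width_kg histogram bin width.
#' @param thresholds_kg ECDF evaluation points; the defaults are the
#'   briefcase mass (4.6 kg) and 11 kg.
#' @return list of class `mass_gap_analysis`: `n_errors`, `n_none`,
#'   `gaps_kg`, `hist` (data frame `bin_lo`, `bin_hi`, `count`), `ecdf`
#'   (data frame `threshold_kg`, `fraction`), `median_gap_kg`, and
#'   `median_all_pairs_kg` (the median over all distinct subject pairs,
#'   for reference). With zero errors the histogram is empty and the ECDF
#'   fractions are `NA` (reported as such).
#' @export
mass_confusion_analysis <- function(decisions, labels, roster,
                                    bin_width_kg = 1,
                                    thresholds_kg = c(4.6, 11)) {
  pred <- if (inherits(decisions, "ensemble_decision")) decisions$pred
          else as.character(decisions)
  labels <- as.character(labels)
  mass <- roster$body_mass_kg
  names(mass) <- roster$subject_id
  if (!all(labels %in% names(mass)) ||
      !all(stats::na.omit(pred) %in% names(mass))) {
    stop("roster does not cover all classes", call. = FALSE)
  }
  wrong <- !is.na(pred) & pred != labels
  gaps <- abs(mass[labels[wrong]] - mass[pred[wrong]])
  names(gaps) <- NULL

  all_pairs <- abs(outer(mass, mass, "-"))
  median_all <- stats::median(all_pairs[upper.tri(all_pairs)])

  if (length(gaps)) {
    breaks <- seq(0, ceiling(max(gaps) / bin_width_kg + 1) * bin_width_kg,
                  by = bin_width_kg)
    counts <- graphics::hist(gaps, breaks = breaks, plot = FALSE)$counts
    hist_df <- data.frame(bin_lo = breaks[-length(breaks)],
                          bin_hi = breaks[-1L], count = counts)
    ecdf_df <- data.frame(threshold_kg = thresholds_kg,
                          fraction = vapply(thresholds_kg,
                                            function(th) mean(gaps <= th),
                                            numeric(1)))
    med <- stats::median(gaps)
  } else {
    hist_df <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                          count = integer(0))
    ecdf_df <- data.frame(threshold_kg = thresholds_kg, fraction = NA_real_)
    med <- NA_real_
  }
  structure(list(n_errors = sum(wrong) + sum(is.na(pred)),
                 n_none = sum(is.na(pred)),
                 gaps_kg = gaps, hist = hist_df, ecdf = ecdf_df,
                 median_gap_kg = med, median_all_pairs_kg = median_all),
            class = "mass_gap_analysis")
}

#' @export
print.mass_gap_analysis <- function(x, ...) {
  cat(sprintf("<mass_gap_analysis> %d errors (%d None)\n", x$n_errors,
              x$n_none))
  if (length(x$gaps_kg)) {
    cat(sprintf("  median mass gap of confused pairs: %.2f kg (all pairs: %.2f kg)\n",
                x$median_gap_kg, x$median_all_pairs_kg))
    for (i in seq_len(nrow(x$ecdf))) {
      cat(sprintf("  ECDF(%.1f kg) = %.3f\n", x$ecdf$threshold_kg[i],
                  x$ecdf$fraction[i]))
    }
  } else {
    cat("  no concrete misclassifications; ECDF undefined\n")
  }
  invisible(x)
}
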