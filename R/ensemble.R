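# Rank-based ensemble fusion. Each of K base classifiers turns its
# posterior vector into a Top-T ranking; fusion happens on ranks only,
# never on the probabilities themselves. Two strategies are provided:
# weighted rank-order voting (each classifier casts one vote, weighted by
# its Top-1 quality rank) and additive weighted Top-T voting (each
# classifier casts T votes with position weights f_p and quality weights
# w_{j,p}, traded off by lambda).

SCORE_TOL <- 1e-12  # relative tolerance for declaring fused-score ties

#' Extract Top-T rankings from a posterior matrix
#'
#' Sorts each row's posteriors in descending order and keeps the first
#' `T` class ids. Exact posterior ties are broken by ascending class id
#' (deterministic and backend-independent).
#'
#' @param P an `M x C` posterior matrix with class ids as column names.
#' @param T ranking depth, `1 <= T <= C`.
#' @return an `M x T` integer matrix of class indices (class
#'   `top_rankings`), with attributes `classes` (the class ids) and
#'   `classifier_id` (inherited from `P` if present).
#' @export
top_rankings <- function(P, T = 5L) {
  C <- ncol(P)
  if (T < 1L || T > C) stop("T must be in 1..C", call. = FALSE)
  M <- nrow(P)
  out <- matrix(0L, M, T)
  for (m in seq_len(M)) {
    out[m, ] <- order(-P[m, ], seq_len(C))[seq_len(T)]
  }
  structure(out, classes = colnames(P),
            classifier_id = attr(P, "classifier_id"),
            class = c("top_rankings", class(out)))
}

#' Top-p accuracy of a ranking
#'
#' Fraction of samples whose true class appears at ranking position `<= p`.
#'
#' @param rankings a [top_rankings()] matrix.
#' @param labels true class ids (character) or indices (integer), length M.
#' @param p cutoff position, `1 <= p <= T`.
#' @return a single number in `[0, 1]`.
#' @export
topp_accuracy <- function(rankings, labels, p = 1L) {
  if (nrow(rankings) == 0L) stop("empty sample set", call. = FALSE)
  stopifnot(p >= 1L, p <= ncol(rankings))
  y <- label_index(labels, attr(rankings, "classes"))
  hits <- vapply(seq_len(nrow(rankings)),
                 function(m) y[m] %in% rankings[m, seq_len(p)], logical(1))
  mean(hits)
}

label_index <- function(labels, classes) {
  if (is.numeric(labels)) return(as.integer(labels))
  idx <- match(as.character(labels), classes)
  if (anyNA(idx)) stop("labels contain unknown classes", call. = FALSE)
  idx
}

#' Rank and weight classifiers from a Top-p accuracy table
#'
#' Given the `K x T` matrix of Top-p accuracies, assigns each classifier a
#' per-position rank: rank = 1 + number of strictly better classifiers at
#' that position; classifiers tied at a position are ordered by their Top-1
#' accuracy, and if the tie persists they share the rank. Quality weights
#' are `w = (K + 1 - R) / K`, and the position weights of the Top-T
#' strategy are `f_p = (T + 1 - p) / T`.
#'
#' @param acc `K x T` accuracy matrix (rows = classifiers), values in
#'   `[0, 1]`; row names identify the classifiers.
#' @return a list of class `rank_weight_table` with elements `acc`, `R`
#'   (integer ranks), `w`, `f`, `K`, `T`.
#' @export
rank_weight_table <- function(acc) {
  acc <- as.matrix(acc)
  if (any(!is.finite(acc))) stop("non-finite accuracies", call. = FALSE)
  K <- nrow(acc); T <- ncol(acc)
  top1 <- acc[, 1L]
  R <- matrix(0L, K, T, dimnames = dimnames(acc))
  for (p in seq_len(T)) {
    a <- acc[, p]
    base <- vapply(seq_len(K), function(j) 1L + sum(a > a[j]), integer(1))
    for (r0 in unique(base)) {
      grp <- which(base == r0)
      if (length(grp) == 1L) {
        R[grp, p] <- r0
      } else {
        # tie: order within the group by Top-1 accuracy; a persistent tie
        # (equal Top-1 as well) shares the rank
        R[grp, p] <- r0 + vapply(grp, function(j)
          sum(top1[grp] > top1[j]), integer(1))
      }
    }
  }
  structure(list(acc = acc, R = R, w = (K + 1 - R) / K,
                 f = (T + 1 - seq_len(T)) / T, K = K, T = T),
            class = "rank_weight_table")
}

#' @export
print.rank_weight_table <- function(x, ...) {
  cat(sprintf("<rank_weight_table> K = %d classifiers, T = %d positions\n",
              x$K, x$T))
  cat("Top-p accuracies:\n")
  print(round(x$acc, 4))
  cat("ranks:\n")
  print(x$R)
  invisible(x)
}

# shared scoring core: adds coef[j, p] to the score of the class ranked at
# position p by classifier j, for all samples at once
accumulate_scores <- function(rankings, coef, C) {
  M <- nrow(rankings[[1L]])
  scores <- matrix(0, M, C)
  rows <- seq_len(M)
  for (j in seq_along(rankings)) {
    for (p in seq_len(ncol(coef))) {
      idx <- cbind(rows, rankings[[j]][, p])
      scores[idx] <- scores[idx] + coef[j, p]
    }
  }
  scores
}

decide_from_scores <- function(scores, rankings, table, classes) {
  M <- nrow(scores)
  pred <- rep(NA_integer_, M)
  tie <- logical(M)
  top1_acc <- table$acc[, 1L]
  best_j <- which(top1_acc == max(top1_acc))
  for (m in seq_len(M)) {
    s <- scores[m, ]
    mx <- max(s)
    tol <- SCORE_TOL * max(1, abs(mx))
    cand <- which(s >= mx - tol)
    if (length(cand) == 1L) {
      pred[m] <- cand
    } else {
      tie[m] <- TRUE
      pred[m] <- resolve_tie(cand,
                             vapply(rankings[best_j],
                                    function(r) r[m, 1L], integer(1)))
    }
  }
  structure(
    data.frame(pred = ifelse(is.na(pred), NA_character_, classes[pred]),
               tie = tie, stringsAsFactors = FALSE),
    scores = scores, classes = classes,
    class = c("ensemble_decision", "data.frame"))
}

#' Resolve a fused-score tie
#'
#' When two or more classes attain the maximal fused score, the tie is
#' resolved by the Top-1 indication of the best base classifier (the one
#' with maximal Top-1 validation accuracy; if several classifiers share
#' that maximum they must indicate unanimously). If the indicated class is
#' not unique or lies outside the tied set, the ensemble outputs `None`
#' (`NA`).
#'
#' @param tied_classes integer indices of the tied classes.
#' @param best_top1 integer vector: the Top-1 class index of each maximal-
#'   accuracy classifier for this sample.
#' @return a single class index, or `NA_integer_` for `None`.
#' @export
resolve_tie <- function(tied_classes, best_top1) {
  u <- unique(best_top1)
  if (length(u) == 1L && u %in% tied_classes) return(u)
  NA_integer_
}

check_rankings <- function(rankings, K = NULL) {
  M <- unique(vapply(rankings, nrow, integer(1)))
  if (length(M) != 1L) stop("mismatched sample sets", call. = FALSE)
  cls <- lapply(rankings, attr, "classes")
  cls <- cls[!vapply(cls, is.null, logical(1))]
  if (length(cls) > 1L && !all(vapply(cls, identical, logical(1), cls[[1L]]))) {
    stop("rankings disagree on the class set", call. = FALSE)
  }
  if (!is.null(K) && length(rankings) != K) {
    stop("expected ", K, " rankings, got ", length(rankings), call. = FALSE)
  }
  invisible(M)
}

#' Weighted rank-order vote
#'
#' Every classifier votes once, for its Top-1 class, with weight
#' `w_{j,1}`; the class with the maximal summed weight wins. Score ties go
#' to [resolve_tie()].
#'
#' @param rankings list of K [top_rankings()] over the same samples.
#' @param table a [rank_weight_table()] for the same K classifiers.
#' @param classes class ids (defaults to the rankings' class attribute).
#' @return an `ensemble_decision` data frame: `pred` (class id or `NA` for
#'   None) and `tie` (logical), with the score matrix as attribute
#'   `scores`.
#' @export
vote_rank_order <- function(rankings, table, classes = NULL) {
  check_rankings(rankings, table$K)
  if (is.null(classes)) classes <- attr(rankings[[1L]], "classes")
  C <- length(classes)
  coef <- matrix(table$w[, 1L], ncol = 1L)
  scores <- accumulate_scores(lapply(rankings, function(r)
    r[, 1L, drop = FALSE]), coef, C)
  decide_from_scores(scores, rankings, table, classes)
}

#' Rank-based additive weighted Top-T vote
#'
#' Every classifier casts `T` votes; the vote for the class it ranks at
#' position `p` carries the coefficient `lambda * f_p + (1 - lambda) *
#' w_{j,p}`. `lambda` regulates the relative influence of the ranking
#' position versus the classifier-quality correction; values above 1 are
#' allowed (the `(1 - lambda)` term then turns negative, taken literally).
#' With `T = 1` and `lambda = 0` the strategy reduces exactly to
#' [vote_rank_order()].
#'
#' @inheritParams vote_rank_order
#' @param lambda nonnegative position/quality trade-off.
#' @return an `ensemble_decision` data frame (see [vote_rank_order()]).
#' @export
vote_topT_additive <- function(rankings, table, lambda = 1, classes = NULL) {
  check_rankings(rankings, table$K)
  stopifnot(lambda >= 0)
  if (is.null(classes)) classes <- attr(rankings[[1L]], "classes")
  C <- length(classes)
  coef <- lambda * matrix(table$f, table$K, table$T, byrow = TRUE) +
    (1 - lambda) * table$w
  scores <- accumulate_scores(rankings, coef, C)
  decide_from_scores(scores, rankings, table, classes)
}

#' Fit a rank-fusion ensemble
#'
#' The central estimator of the package. Takes the K base classifiers'
#' posterior matrices on a labelled evaluation set (by default each fitted
#' model's persisted 20% validation split, which was not used to fit the
#' model), extracts Top-T rankings, computes the `K x T` Top-p accuracy
#' table, and derives the rank and weight tables that drive both voting
#' strategies.
#'
#' @param x either a list of fitted [fit_classifier()] models (their stored
#'   validation posteriors and labels are used) or a list of `M x C`
#'   posterior matrices.
#' @param labels evaluation labels (required when `x` is a list of
#'   matrices).
#' @param T ranking depth (default 5, matching the K = 5, Top-5 operating
#'   point).
#' @return an object of class `rank_fusion`: the [rank_weight_table()] plus
#'   the class set and classifier ids.
#' @export
rank_fusion <- function(x, labels = NULL, T = 5L) {
  if (length(x) < 1L) stop("need at least one classifier", call. = FALSE)
  if (inherits(x[[1L]], "grf_classifier")) {
    models <- x
    posteriors <- lapply(models, function(m) m$val_posteriors)
    if (any(vapply(posteriors, is.null, logical(1)))) {
      stop("models carry no validation posteriors; fit with val_frac > 0",
           call. = FALSE)
    }
    labels <- models[[1L]]$val_labels
    for (m in models) {
      if (!identical(m$val_labels, labels)) {
        stop("models were fitted with different validation splits",
             call. = FALSE)
      }
    }
  } else {
    posteriors <- x
    if (is.null(labels)) stop("labels required with posterior matrices",
                              call. = FALSE)
  }
  classes <- colnames(posteriors[[1L]])
  T <- min(T, length(classes))  # a Top-T list cannot exceed the class count
  ids <- vapply(seq_along(posteriors), function(j) {
    id <- attr(posteriors[[j]], "classifier_id")
    if (is.null(id)) paste0("clf", j) else id
  }, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  rankings <- lapply(posteriors, top_rankings, T = T)
  acc <- t(vapply(rankings, function(r) {
    vapply(seq_len(T), function(p) topp_accuracy(r, labels, p), numeric(1))
  }, numeric(T)))
  if (T == 1L) acc <- matrix(acc, ncol = 1L)
  rownames(acc) <- ids
  table <- rank_weight_table(acc)
  structure(c(table, list(classes = classes, classifier_ids = ids)),
            class = c("rank_fusion", "rank_weight_table"))
}

#' @export
print.rank_fusion <- function(x, ...) {
  cat(sprintf("<rank_fusion> K = %d classifiers, T = %d, %d classes\n",
              x$K, x$T, length(x$classes)))
  cat(sprintf("  validation Top-1: %s\n",
              paste(sprintf("%s %.3f", x$classifier_ids, x$acc[, 1L]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.rank_fusion <- function(object, ...) {
  cat(sprintf("Rank-fusion ensemble of %d classifiers (Top-%d)\n",
              object$K, object$T))
  cat("\nTop-p accuracy table (validation):\n")
  print(round(object$acc, 4))
  cat("\nranks R:\n"); print(object$R)
  cat("\nquality weights w = (K + 1 - R) / K:\n"); print(round(object$w, 3))
  cat("\nposition weights f:", round(object$f, 3), "\n")
  invisible(object)
}

#' Predict with a fitted rank-fusion ensemble
#'
#' @param object a [rank_fusion()] ensemble.
#' @param posteriors list of K posterior matrices over the same samples
#'   (one per base classifier, same order as at fit time), or a list of
#'   [top_rankings()].
#' @param strategy `"topT"` (additive weighted Top-T vote) or
#'   `"rank_order"` (weighted Top-1 vote).
#' @param lambda trade-off parameter of the Top-T strategy.
#' @param ... unused.
#' @return an `ensemble_decision` data frame (see [vote_rank_order()]).
#' @export
predict.rank_fusion <- function(object, posteriors,
                                strategy = c("topT", "rank_order"),
                                lambda = 1, ...) {
  strategy <- match.arg(strategy)
  rankings <- as_rankings(posteriors, object$T)
  if (strategy == "rank_order") {
    vote_rank_order(rankings, object, classes = object$classes)
  } else {
    vote_topT_additive(rankings, object, lambda = lambda,
                       classes = object$classes)
  }
}

as_rankings <- function(posteriors, T) {
  lapply(posteriors, function(P) {
    if (inherits(P, "top_rankings")) {
      if (ncol(P) < T) stop("rankings shallower than T", call. = FALSE)
      return(P)
    }
    top_rankings(P, T)
  })
}

#' Sweep the lambda parameter of the Top-T strategy
#'
#' Evaluates the additive weighted Top-T vote over a lambda grid (default
#' `0.1, 0.2, ..., 5.0`) on a labelled evaluation set; `None` outputs count
#' as errors. The optimum is the smallest grid value attaining the maximal
#' accuracy.
#'
#' @param object a [rank_fusion()] ensemble.
#' @param posteriors list of K posterior matrices (or rankings) on the
#'   evaluation samples.
#' @param labels true class ids of the evaluation samples.
#' @param grid lambda grid (nonempty, nonnegative).
#' @return a list of class `lambda_sweep`: `lambda_star`, `accuracy` (at
#'   the optimum), `curve` (data frame `lambda`, `accuracy`, `ties`).
#' @export
sweep_lambda <- function(object, posteriors, labels,
                         grid = seq(0.1, 5, by = 0.1)) {
  if (length(grid) == 0L) stop("empty lambda grid", call. = FALSE)
  rankings <- as_rankings(posteriors, object$T)
  acc <- numeric(length(grid))
  ties <- integer(length(grid))
  for (i in seq_along(grid)) {
    dec <- vote_topT_additive(rankings, object, lambda = grid[i],
                              classes = object$classes)
    acc[i] <- decision_accuracy(dec, labels)
    ties[i] <- sum(dec$tie)
  }
  best <- which.max(acc)  # first = smallest lambda on ties
  structure(list(lambda_star = grid[best], accuracy = acc[best],
                 curve = data.frame(lambda = grid, accuracy = acc,
                                    ties = ties)),
            class = "lambda_sweep")
}

#' @export
print.lambda_sweep <- function(x, ...) {
  cat(sprintf("<lambda_sweep> %d grid points; best accuracy %.4f at lambda = %g\n",
              nrow(x$curve), x$accuracy, x$lambda_star))
  invisible(x)
}

#' @export
plot.lambda_sweep <- function(x, ...) {
  plot(x$curve$lambda, x$curve$accuracy, type = "l",
       xlab = expression(lambda), ylab = "Top-1 accuracy",
       main = "Ensemble accuracy vs lambda", ...)
  graphics::abline(v = x$lambda_star, lty = 2)
  invisible(x)
}

#' @export
plot.rank_fusion <- function(x, ...) {
  graphics::matplot(seq_len(x$T), t(x$acc), type = "b", pch = 19,
                    xlab = "ranking position p", ylab = "Top-p accuracy",
                    main = "Validation Top-p accuracy per classifier", ...)
  graphics::legend("bottomright", legend = x$classifier_ids,
                   col = seq_len(x$K), lty = seq_len(x$K), cex = 0.8)
  invisible(x)
}

decision_accuracy <- function(decision, labels) {
  mean(!is.na(decision$pred) & decision$pred == as.character(labels))
}
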