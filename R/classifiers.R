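# Base-classifier harness: turns gait datasets into fitted classifiers that
# emit row-stochastic class-posterior matrices. Five 1D deep templates plus
# a deterministic nearest-centroid reference backend; the ensemble layer is
# agnostic to which backend produced the posteriors.

#' Convert a gait dataset to a (time, channel, sample) array
#'
#' @param ds a [gait_dataset()].
#' @param downsample integer decimation factor (keep every k-th sample).
#' @return numeric array of dim `(L, 6, M)`.
#' @keywords internal
dataset_to_array <- function(ds, downsample = 1L) {
  keep <- seq(1L, ds$unified_length, by = as.integer(downsample))
  M <- length(ds$cycles)
  x <- array(0, c(length(keep), 6L, M))
  for (i in seq_len(M)) x[, , i] <- ds$cycles[[i]]$channels[keep, ]
  dimnames(x) <- list(NULL, GRF_CHANNELS, vapply(ds$cycles, cycle_key,
                                                 character(1)))
  x
}

# stratified 80/20 trial-level split; every class keeps at least one
# training cycle, classes with a single cycle contribute no validation data
split_validation <- function(labels, val_frac = 0.2) {
  val <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_val <- min(length(idx) - 1L, floor(val_frac * length(idx)))
    if (n_val > 0) {
      val <- c(val, sample(idx, n_val))
    }
  }
  sort(val)
}

standardize_channels <- function(x, center, scale) {
  L <- dim(x)[1]
  for (c in seq_len(dim(x)[2])) {
    x[, c, ] <- (x[, c, ] - center[c]) / scale[c]
  }
  x
}

flatten_samples <- function(x) {
  d <- dim(x)
  t(matrix(x, d[1] * d[2], d[3]))
}

#' Fit a base classifier on a gait dataset
#'
#' Trains one classifier for closed-set person identification. The input of
#' every model is the six stacked force channels over the unified cycle
#' length; the output layer has one unit per enrolled subject. Neural
#' templates (`cnn`, `cnn_lstm_fc`, `resnet1d`, `convmixer1d`,
#' `inception_time`) are trained with Adam and categorical cross-entropy,
#' early-stopping on the loss of a stratified 20% validation split held out
#' at trial level; `nearest_centroid` (the fast deterministic reference
#' backend: per-class mean waveform, posteriors proportional to inverse
#' distances) needs no iterative training but records the same split. The
#' split indices and the model's validation posteriors are stored so that
#' ensemble weights can later be estimated on exactly the data not used for
#' fitting.
#'
#' @param train a [gait_dataset()] with at least 2 subjects.
#' @param architecture one of `"cnn"`, `"cnn_lstm_fc"`, `"resnet1d"`,
#'   `"convmixer1d"`, `"inception_time"`, `"nearest_centroid"`.
#' @param config named list overriding the template defaults (see
#'   [sample_config()] for the tunable fields). Extra fields understood by
#'   the harness: `downsample` (input decimation factor), `epochs`,
#'   `patience`, `channels` (channel subset for `nearest_centroid`).
#' @param seed integer seed controlling initialization, the validation
#'   split, minibatch order and dropout.
#' @param val_frac held-out validation fraction (default 0.2).
#' @param classifier_id label attached to the model's posterior matrices.
#' @param verbose print per-epoch validation loss.
#' @return an object of class `grf_classifier`.
#' @export
fit_classifier <- function(train, architecture = "nearest_centroid",
                           config = list(), seed = 1L, val_frac = 0.2,
                           classifier_id = architecture, verbose = FALSE) {
  stopifnot(inherits(train, "gait_dataset"))
  architecture <- match.arg(architecture, ARCHITECTURES)
  labels <- dataset_labels(train)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("training set must contain at least 2 subjects", call. = FALSE)
  }
  set.seed(seed)
  val_idx <- split_validation(labels, val_frac)
  train_idx <- setdiff(seq_along(labels), val_idx)
  downsample <- if (!is.null(config$downsample)) config$downsample else 1L
  chan_sel <- if (!is.null(config$channels)) config$channels else 1:6

  x <- dataset_to_array(train, downsample)
  y <- match(labels, classes)

  model <- list(architecture = architecture, classes = classes,
                classifier_id = classifier_id, seed = seed,
                downsample = as.integer(downsample), channels = chan_sel,
                input_len = dim(x)[1], unified_length = train$unified_length,
                val_idx = val_idx, train_idx = train_idx)

  if (architecture == "nearest_centroid") {
    feats <- flatten_samples(x[, chan_sel, , drop = FALSE])
    cent <- matrix(0, length(classes), ncol(feats))
    for (ci in seq_along(classes)) {
      rows <- train_idx[labels[train_idx] == classes[ci]]
      cent[ci, ] <- colMeans(feats[rows, , drop = FALSE])
    }
    model$centroids <- cent
    model$config <- config
  } else {
    epochs <- if (!is.null(config$epochs)) config$epochs else 100
    patience <- if (!is.null(config$patience)) config$patience else 10
    # fixed per-channel affine standardization, estimated on the training
    # portion and stored with the model (a conditioning transform: it uses
    # no subject-level information such as body weight)
    tr <- x[, , train_idx, drop = FALSE]
    ch_mean <- apply(tr, 2, mean)
    ch_sd <- apply(tr, 2, stats::sd)
    ch_sd[!is.finite(ch_sd) | ch_sd == 0] <- 1
    model$center <- ch_mean
    model$scale <- ch_sd
    built <- build_network(architecture, config, dim(x)[1], 6L,
                           length(classes))
    xs <- standardize_channels(x, ch_mean, ch_sd)
    fitted <- nn_fit(built$net,
                     xs[, , train_idx, drop = FALSE], y[train_idx],
                     if (length(val_idx)) xs[, , val_idx, drop = FALSE],
                     if (length(val_idx)) y[val_idx],
                     epochs = epochs,
                     batch_size = built$config$batch_size,
                     lr = built$config$lr, patience = patience,
                     verbose = verbose)
    model$net <- fitted$net
    model$val_loss <- fitted$val_loss
    model$epochs_trained <- fitted$epoch
    model$config <- built$config
  }
  class(model) <- "grf_classifier"

  if (length(val_idx)) {
    sub <- gait_dataset(train$cycles[val_idx])
    model$val_posteriors <- predict(model, sub)
    model$val_labels <- labels[val_idx]
    top1 <- classes[max.col(model$val_posteriors, ties.method = "first")]
    model$val_accuracy <- mean(top1 == model$val_labels)
  }
  model
}

#' @export
print.grf_classifier <- function(x, ...) {
  cat(sprintf("<grf_classifier> %s (%s): %d classes, input %d x 6\n",
              x$classifier_id, x$architecture, length(x$classes),
              x$input_len))
  if (!is.null(x$val_accuracy)) {
    cat(sprintf("  validation Top-1 accuracy: %.3f (%d held-out cycles)\n",
                x$val_accuracy, length(x$val_idx)))
  }
  invisible(x)
}

#' Predict class posteriors for new gait cycles
#'
#' @param object a fitted [fit_classifier()] model.
#' @param newdata a [gait_dataset()] padded to the model's trained length,
#'   or a `(L, 6, M)` array.
#' @param ... unused.
#' @return an `M x C` row-stochastic posterior matrix (class
#'   `posterior_matrix`); column names are the class ids, attribute
#'   `classifier_id` names the producing model.
#' @export
predict.grf_classifier <- function(object, newdata, ...) {
  C <- length(object$classes)
  empty <- function() {
    P <- matrix(numeric(0), 0, C, dimnames = list(NULL, object$classes))
    structure(P, class = c("posterior_matrix", class(P)),
              classifier_id = object$classifier_id)
  }
  if (inherits(newdata, "gait_dataset")) {
    if (length(newdata$cycles) == 0L) return(empty())
    if (newdata$unified_length != object$unified_length) {
      stop("newdata length ", newdata$unified_length,
           " does not match the trained length ", object$unified_length,
           call. = FALSE)
    }
    x <- dataset_to_array(newdata, object$downsample)
  } else {
    x <- newdata
  }
  M <- dim(x)[3]
  if (M == 0L) return(empty())
  if (object$architecture == "nearest_centroid") {
    feats <- flatten_samples(x[, object$channels, , drop = FALSE])
    cent <- object$centroids
    d2 <- outer(rowSums(feats^2), rep(1, nrow(cent))) +
      outer(rep(1, nrow(feats)), rowSums(cent^2)) -
      2 * feats %*% t(cent)
    inv <- 1 / (sqrt(pmax(d2, 0)) + 1e-8)
    P <- inv / rowSums(inv)
  } else {
    P <- nn_predict_probs(object$net,
                          standardize_channels(x, object$center,
                                               object$scale))
  }
  dimnames(P) <- list(dimnames(x)[[3]], object$classes)
  structure(P, class = c("posterior_matrix", class(P)),
            classifier_id = object$classifier_id)
}

#' Random hyperparameter search within an architecture's bounded space
#'
#' A budgeted random-search loop: samples `budget` configurations from the
#' architecture's search space (see [sample_config()]), fits each with
#' [fit_classifier()], and returns the configuration with the best
#' validation Top-1 accuracy.
#'
#' @param architecture a neural template name.
#' @param train a [gait_dataset()].
#' @param budget number of sampled configurations (>= 1).
#' @param seed integer seed; configuration `b` uses derived seed `seed + b`,
#'   so larger budgets extend the same draw stream.
#' @param fixed named list of config fields forced onto every sampled
#'   configuration (e.g. `downsample`, `epochs`).
#' @return list with `config` (best), `val_accuracy`, and `trials` (a data
#'   frame of all sampled results).
#' @export
random_search <- function(architecture, train, budget = 5, seed = 1L,
                          fixed = list()) {
  stopifnot(budget >= 1)
  best <- NULL
  rows <- vector("list", budget)
  for (b in seq_len(budget)) {
    set.seed(seed + b)
    cfg <- utils::modifyList(sample_config(architecture), fixed)
    model <- fit_classifier(train, architecture, cfg, seed = seed + b)
    acc <- if (is.null(model$val_accuracy)) NA_real_ else model$val_accuracy
    rows[[b]] <- data.frame(trial = b, val_accuracy = acc)
    if (is.null(best) || (!is.na(acc) && acc > best$val_accuracy)) {
      best <- list(config = cfg, val_accuracy = acc, model = model)
    }
  }
  list(config = best$config, val_accuracy = best$val_accuracy,
       trials = do.call(rbind, rows))
}
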