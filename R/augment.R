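# The four training-set augmentation operators. All of them act on stance
# samples only (swing samples stay exactly zero), preserve the cycle length
# and the 6-channel layout, never touch the class label, and are
# deterministic given (cycle, parameters, seed).

maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
}

#' Band-limited noise injection (jittering)
#'
#' Adds low-amplitude noise to every channel on its limb's stance window:
#' `x'[n] = x[n] + a * RMS(x) * s[n]`, where `s` is white Gaussian noise
#' low-pass filtered with a 4th-order Butterworth filter (30 Hz cutoff by
#' default, restricting the perturbation to the physiological band of GRF
#' signals) and then rescaled to unit RMS over the stance window, and
#' `RMS(x)` is the root mean square of the channel over its stance window.
#' The scaling factor is `a_v` for the two vertical channels and `a_other`
#' (twice `a_v` by default) for the four shear channels. All-zero channels
#' are returned unchanged (their RMS is 0).
#'
#' @param cycle a [grf_cycle()].
#' @param a_v,a_other noise scale for vertical / other channels.
#' @param cutoff_hz,filter_order Butterworth low-pass applied to the noise
#'   (never to the signal itself).
#' @param threshold stance detection threshold, newtons.
#' @param seed optional integer seed.
#' @return a new [grf_cycle()].
#' @export
augment_jitter <- function(cycle, a_v = 0.01, a_other = 0.02,
                           cutoff_hz = 30, filter_order = 4,
                           threshold = 10, seed = NULL) {
  stopifnot(inherits(cycle, "grf_cycle"))
  maybe_seed(seed)
  ch <- cycle$channels
  fs <- cycle$sample_rate
  bf <- signal::butter(filter_order, cutoff_hz / (fs / 2), type = "low")
  found_stance <- FALSE
  for (limb in list(LEFT_CHANNELS, RIGHT_CHANNELS)) {
    fv <- ch[, limb[2L]]
    if (!any(fv > threshold)) next
    found_stance <- TRUE
    iv <- detect_stance(fv, threshold)
    idx <- iv[1L]:iv[2L]
    for (ci in seq_along(limb)) {
      col <- limb[ci]
      x <- ch[idx, col]
      rms <- sqrt(mean(x^2))
      if (rms == 0) next
      s <- as.numeric(signal::filter(bf, stats::rnorm(length(idx))))
      s_rms <- sqrt(mean(s^2))
      if (s_rms == 0) next
      s <- s / s_rms
      a <- if (ci == 2L) a_v else a_other
      ch[idx, col] <- x + a * rms * s
    }
  }
  if (!found_stance) stop("no detectable stance on either limb", call. = FALSE)
  cycle$channels <- ch
  cycle
}

shift_columns <- function(mat, k) {
  n <- nrow(mat)
  out <- matrix(0, n, ncol(mat))
  if (k == 0) return(mat)
  if (k > 0) out[(k + 1):n, ] <- mat[1:(n - k), , drop = FALSE]
  else out[1:(n + k), ] <- mat[(1 - k):n, , drop = FALSE]
  out
}

#' Per-leg time shifting
#'
#' Shifts each leg's three channels along the time axis by an integer number
#' of samples drawn independently per leg from `Uniform{-max_shift ..
#' +max_shift}` (asynchronously, emulating variability in the timing between
#' the two limbs). Vacated positions are filled with zeros; the total length
#' is preserved. The default +/-15 samples at 960 Hz is about +/-15.6 ms,
#' under 2.5% of a typical stance.
#'
#' @param cycle a [grf_cycle()].
#' @param max_shift maximal absolute shift, samples.
#' @param shift_left,shift_right optional forced shifts (testing hooks);
#'   `NULL` means draw.
#' @param seed optional integer seed.
#' @return a new [grf_cycle()].
#' @export
augment_time_shift <- function(cycle, max_shift = 15,
                               shift_left = NULL, shift_right = NULL,
                               seed = NULL) {
  stopifnot(inherits(cycle, "grf_cycle"))
  n <- nrow(cycle$channels)
  if (n < 2 * max_shift) {
    stop("cycle shorter than twice the maximal shift", call. = FALSE)
  }
  maybe_seed(seed)
  if (is.null(shift_left)) shift_left <- sample(-max_shift:max_shift, 1L)
  if (is.null(shift_right)) shift_right <- sample(-max_shift:max_shift, 1L)
  stopifnot(abs(shift_left) <= max_shift, abs(shift_right) <= max_shift)
  ch <- cycle$channels
  ch[, LEFT_CHANNELS] <- shift_columns(ch[, LEFT_CHANNELS, drop = FALSE],
                                       as.integer(shift_left))
  ch[, RIGHT_CHANNELS] <- shift_columns(ch[, RIGHT_CHANNELS, drop = FALSE],
                                        as.integer(shift_right))
  cycle$channels <- ch
  cycle
}

#' Left-stance window cropping with resampling
#'
#' Randomly removes up to 3% of the left limb's stance samples (split
#' between the stance start and end by a uniform draw) and linearly
#' resamples the shortened stance back to its original length. Applied to
#' the left leg only, so the operator perturbs temporal structure without
#' compounding natural left/right asymmetry; the right leg and the total
#' length are untouched.
#'
#' @param cycle a [grf_cycle()].
#' @param max_crop_frac maximal cropped fraction of the stance (<= 0.03).
#' @param threshold stance detection threshold, newtons.
#' @param crop optional forced number of cropped samples (testing hook);
#'   `0` makes the operator the identity.
#' @param seed optional integer seed.
#' @return a new [grf_cycle()].
#' @export
augment_window_crop <- function(cycle, max_crop_frac = 0.03,
                                threshold = 10, crop = NULL, seed = NULL) {
  stopifnot(inherits(cycle, "grf_cycle"), max_crop_frac > 0)
  maybe_seed(seed)
  iv <- detect_stance(cycle$channels[, "L_V"], threshold)
  len <- stance_length(iv)
  c_max <- floor(max_crop_frac * len)
  if (len < 34L || c_max < 1L) {
    stop("left stance too short to crop (need >= 34 samples)", call. = FALSE)
  }
  if (is.null(crop)) crop <- sample(c_max, 1L)
  crop <- as.integer(crop)
  if (crop == 0L) return(cycle)
  stopifnot(crop >= 1L, crop <= c_max)
  from_start <- sample(0:crop, 1L)
  from_end <- crop - from_start
  idx <- iv[1L]:iv[2L]
  keep <- idx[(from_start + 1L):(len - from_end)]
  xout <- seq(1, length(keep), length.out = len)
  for (col in LEFT_CHANNELS) {
    seg <- cycle$channels[keep, col]
    cycle$channels[idx, col] <-
      stats::approx(seq_along(seg), seg, xout = xout)$y
  }
  cycle
}

#' Same-class mixup
#'
#' Forms a convex combination `x' = gamma * x1 + (1 - gamma) * x2` of two
#' cycles of the same subject, with `gamma ~ Uniform(0.85, 0.95)` so the
#' result stays dominated by one gait instance while gaining controlled
#' intra-class variability. The output inherits the first cycle's metadata.
#'
#' @param c1,c2 two [grf_cycle()]s of the same subject and equal length.
#' @param gamma_range range of the mixing coefficient.
#' @param gamma optional forced coefficient (testing hook).
#' @param seed optional integer seed.
#' @return a new [grf_cycle()].
#' @export
augment_mixup <- function(c1, c2, gamma_range = c(0.85, 0.95),
                          gamma = NULL, seed = NULL) {
  stopifnot(inherits(c1, "grf_cycle"), inherits(c2, "grf_cycle"))
  if (!identical(c1$subject_id, c2$subject_id)) {
    stop("mixup requires two cycles of the same subject", call. = FALSE)
  }
  if (nrow(c1$channels) != nrow(c2$channels)) {
    stop("mixup requires equal-length cycles", call. = FALSE)
  }
  maybe_seed(seed)
  if (is.null(gamma)) gamma <- stats::runif(1, gamma_range[1], gamma_range[2])
  c1$channels <- gamma * c1$channels + (1 - gamma) * c2$channels
  c1
}

# The eight augmentation recipes of the x9 training-set expansion, applied
# in the order named. "mixup" combines the working cycle with a raw
# same-subject partner.
SCENARIO_C_RECIPES <- list(
  c("jitter"),
  c("time_shift"),
  c("window_crop"),
  c("jitter", "time_shift"),
  c("jitter", "window_crop"),
  c("time_shift", "window_crop"),
  c("jitter", "mixup"),
  c("jitter", "time_shift", "window_crop")
)

#' Expand a training set nine-fold for the augmented scenario
#'
#' For every original cycle, emits the original plus eight augmented
#' variants: jittering; time shifting; window cropping; jittering + time
#' shifting; jittering + window cropping; time shifting + window cropping;
#' jittering + mixup; and jittering + time shifting + window cropping.
#' Mixup partners are drawn uniformly among the other training cycles of
#' the same subject and condition (falling back, with a warning, to the
#' cycle itself for a subject with a single cycle). Labels are never
#' altered; augmented variants get trial ids `1000 * trial + recipe` so
#' keys stay unique.
#'
#' @param train a [gait_dataset()].
#' @param seed integer seed; each (cycle, recipe) pair gets a derived seed.
#' @return a [gait_dataset()] with `9 *` the input cycle count.
#' @export
expand_scenario_c <- function(train, seed = 1L) {
  stopifnot(inherits(train, "gait_dataset"))
  if (length(train$cycles) == 0L) stop("empty training set", call. = FALSE)
  labels <- dataset_labels(train)
  conds <- vapply(train$cycles, function(cy) cy$condition, character(1))
  out <- vector("list", 9L * length(train$cycles))
  pos <- 1L
  for (i in seq_along(train$cycles)) {
    orig <- train$cycles[[i]]
    out[[pos]] <- orig
    pos <- pos + 1L
    partners <- setdiff(which(labels == labels[i] & conds == conds[i]), i)
    for (v in seq_along(SCENARIO_C_RECIPES)) {
      set.seed((seed + 7919 * i + v) %% 2147483629)
      cy <- orig
      for (op in SCENARIO_C_RECIPES[[v]]) {
        cy <- switch(op,
          jitter = augment_jitter(cy),
          time_shift = augment_time_shift(cy),
          window_crop = augment_window_crop(cy),
          mixup = {
            if (length(partners) == 0L) {
              warning("subject ", labels[i],
                      " has a single cycle; mixup partner is the cycle itself",
                      call. = FALSE)
              j <- i
            } else {
              j <- if (length(partners) == 1L) partners else sample(partners, 1L)
            }
            augment_mixup(cy, train$cycles[[j]])
          })
      }
      cy$trial_id <- 1000L * orig$trial_id + v
      out[[pos]] <- cy
      pos <- pos + 1L
    }
  }
  gait_dataset(out)
}
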