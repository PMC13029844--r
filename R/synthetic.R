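GRAVITY <- 9.81

#' Configuration for the synthetic gait population generator
#'
#' The generator emulates the statistical structure of a force-plate gait
#' study: a cohort with body mass ~ Normal(74.33, 16.63^2) kg truncated to
#' a physical range, 14-20 trials per walking condition, and a 4.6 kg
#' briefcase carried in one self-chosen hand as the loading covariate.
#' Carrying a load raises the effective weight, inflates the carrying-side
#' vertical peaks more than the contralateral ones, increases medial-lateral
#' effort on the carrying side, and slightly lengthens stance.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param trials_min,trials_max inclusive range of trials per condition,
#'   drawn per subject and condition.
#' @param sample_rate plate sampling frequency, Hz.
#' @param briefcase_mass_kg mass of the hand-carried load.
#' @param delta_carry,delta_contra vertical amplitude inflation of the
#'   carrying-side and contralateral limb under load (`delta_carry >=
#'   delta_contra >= 0`).
#' @param ml_gain multiplicative medial-lateral gain on the carrying side
#'   under load.
#' @param load_stance_inflation relative stance-duration increase under load.
#' @param amp_noise_sd trial-to-trial multiplicative amplitude noise sd
#'   (per limb and channel).
#' @param timing_noise_sd trial-to-trial jitter sd of peak timings, as a
#'   fraction of stance.
#' @param stance_noise_sd trial-to-trial stance-duration jitter sd, seconds.
#' @param mass_mean,mass_sd,mass_bounds body-mass distribution (kg).
#' @param height_mean,height_sd body-height distribution (cm).
#' @param seed master seed; every cycle's seed is derived from it by a fixed
#'   counter scheme, so datasets are reproducible and single cycles
#'   regenerable.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 215,
                             trials_min = 14, trials_max = 20,
                             sample_rate = 960,
                             briefcase_mass_kg = 4.6,
                             delta_carry = 0.06,
                             delta_contra = 0.02,
                             ml_gain = 1.3,
                             load_stance_inflation = 0.03,
                             amp_noise_sd = 0.02,
                             timing_noise_sd = 0.01,
                             stance_noise_sd = 0.03,
                             mass_mean = 74.33, mass_sd = 16.63,
                             mass_bounds = c(45, 130),
                             height_mean = 174.41, height_sd = 9.49,
                             seed = 1L) {
  stopifnot(n_subjects >= 2, trials_min >= 1, trials_max >= trials_min,
            sample_rate > 0, briefcase_mass_kg >= 0,
            delta_carry >= delta_contra, delta_contra >= 0,
            amp_noise_sd >= 0, timing_noise_sd >= 0, stance_noise_sd >= 0,
            mass_bounds[1] > 0, mass_bounds[2] > mass_bounds[1])
  structure(as.list(environment()), class = "generator_config")
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Sample a synthetic subject population
#'
#' Draws one generative profile per subject: body mass (truncated normal),
#' height, carrying hand (fair coin), stance duration, and the per-channel
#' waveform template parameters. Vertical peak amplitudes `a1`, `a2` and the
#' mid-stance valley are expressed as multiples of body weight, so absolute
#' peak forces grow with body mass across subjects -- the property that makes
#' body mass a weak biometric and mass-gap error analysis meaningful.
#'
#' @param config a [generator_config()].
#' @return data frame of class `subject_profiles`, one row per subject.
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_subjects
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  set.seed(config$seed)
  prof <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    body_mass_kg = rtruncnorm1(n, config$mass_mean, config$mass_sd,
                               config$mass_bounds[1], config$mass_bounds[2]),
    height_cm = stats::rnorm(n, config$height_mean, config$height_sd),
    carrying_hand = sample(c("left", "right"), n, replace = TRUE),
    stance_duration_s = stats::runif(n, 0.60, 0.75),
    # vertical template: two peaks a1, a2, mid-stance valley (x body weight)
    a1 = stats::runif(n, 1.05, 1.25),
    a2 = stats::runif(n, 1.05, 1.25),
    valley = stats::runif(n, 0.70, 0.85),
    t1 = stats::runif(n, 0.22, 0.28),
    t2 = stats::runif(n, 0.72, 0.78),
    w1 = stats::runif(n, 0.06, 0.10),
    w2 = stats::runif(n, 0.06, 0.10),
    # anterior-posterior braking / propulsion lobes (x body weight)
    ap_brake = stats::runif(n, 0.15, 0.25),
    ap_prop = stats::runif(n, 0.15, 0.25),
    # medial-lateral amplitude (x body weight)
    ml_amp = stats::runif(n, 0.03, 0.10),
    # mild subject-specific left/right amplitude asymmetry
    right_asym = stats::runif(n, 0.96, 1.04),
    stringsAsFactors = FALSE
  )
  class(prof) <- c("subject_profiles", "data.frame")
  prof
}

# smooth plateau window: 0 at the stance edges, 1 on the interior, linear
# ramps of relative width r. Guarantees stance-only support and a fast
# loading/unloading edge so threshold stance detection recovers ~all of it.
plateau_window <- function(u, r = 0.04) {
  pmax(0, pmin(1, u / r, (1 - u) / r))
}

limb_stance_waveform <- function(profile, weight_n, n_samples,
                                 amp_factor = c(1, 1, 1),
                                 t_shift = c(0, 0), ml_gain = 1) {
  u <- seq(0, 1, length.out = n_samples)
  env <- plateau_window(u)
  t1 <- profile$t1 + t_shift[1]
  t2 <- profile$t2 + t_shift[2]
  fv <- env * profile$valley +
    (profile$a1 - profile$valley) * exp(-((u - t1) / profile$w1)^2) +
    (profile$a2 - profile$valley) * exp(-((u - t2) / profile$w2)^2)
  fv <- pmax(0, fv * weight_n * amp_factor[2])
  fap <- env * (-profile$ap_brake * exp(-((u - 0.18) / 0.10)^2) +
                  profile$ap_prop * exp(-((u - 0.82) / 0.10)^2))
  fap <- fap * weight_n * amp_factor[1]
  fml <- env * profile$ml_amp *
    (0.7 * exp(-((u - 0.30) / 0.15)^2) + exp(-((u - 0.70) / 0.15)^2))
  fml <- fml * weight_n * amp_factor[3] * ml_gain
  # zero out everything the envelope already kills, then force exact zeros
  # at the edges so stance support is crisp
  cbind(AP = fap, V = fv, ML = fml)
}

derive_cycle_seed <- function(master_seed, subj_index, cond_code, trial) {
  as.integer((as.numeric(master_seed) * 1000003 + subj_index * 10007 +
                cond_code * 101 + trial) %% 2147483629)
}

#' Generate one synthetic GRF gait cycle
#'
#' Builds a six-channel cycle from a subject profile: the left stance starts
#' the cycle, the right stance is placed so that the vertical impulse of
#' both limbs equals the effective weight times the stride period (the
#' defining property of steady walking), and a trailing margin is appended.
#' The vertical channel has the canonical two-peak (M) shape, the
#' anterior-posterior channel the braking/propulsion (S) shape. Under a
#' loaded condition the effective weight includes the briefcase and the
#' carrying-side limb takes the larger share.
#'
#' @param profile one row of [sample_population()] output (or a list with
#'   the same fields).
#' @param condition `"unloaded"`, `"loaded_left"` or `"loaded_right"`.
#' @param trial_seed integer seed making the trial reproducible.
#' @param config a [generator_config()].
#' @param trial_id trial index stored in the cycle metadata.
#' @return a [grf_cycle()] with attribute `stance_truth`, the generator's
#'   ground-truth stance intervals per limb.
#' @export
generate_cycle <- function(profile, condition, trial_seed, config,
                           trial_id = 1L) {
  condition <- match.arg(condition, GRF_CONDITIONS)
  profile <- as.list(profile)
  fs <- config$sample_rate
  set.seed(trial_seed)

  loaded <- condition != "unloaded"
  carry_left <- condition == "loaded_left"
  mass_eff <- profile$body_mass_kg + if (loaded) config$briefcase_mass_kg else 0
  weight_eff <- mass_eff * GRAVITY

  # per-limb vertical share under load: the carrying side works harder
  share <- c(left = 1, right = profile$right_asym)
  ml_gain <- c(left = 1, right = 1)
  if (loaded) {
    if (carry_left) {
      share <- share * c(1 + config$delta_carry, 1 + config$delta_contra)
      ml_gain["left"] <- config$ml_gain
    } else {
      share <- share * c(1 + config$delta_contra, 1 + config$delta_carry)
      ml_gain["right"] <- config$ml_gain
    }
  }

  stance_s <- profile$stance_duration_s *
    (if (loaded) 1 + config$load_stance_inflation else 1)
  stance_n <- numeric(2)
  waves <- vector("list", 2)
  for (k in 1:2) {
    dur <- stance_s + stats::rnorm(1, 0, config$stance_noise_sd)
    dur <- max(dur, 0.3)
    stance_n[k] <- max(34L, as.integer(round(dur * fs)))
    amp <- 1 + stats::rnorm(3, 0, config$amp_noise_sd)
    tsh <- stats::rnorm(2, 0, config$timing_noise_sd)
    waves[[k]] <- limb_stance_waveform(
      profile, weight_eff * share[k], stance_n[k],
      amp_factor = amp, t_shift = tsh, ml_gain = ml_gain[k])
  }

  # place the right stance so total vertical impulse = effective weight x
  # stride period, with stride period = 2 x right-stance offset
  impulse_samples <- (sum(waves[[1]][, "V"]) + sum(waves[[2]][, "V"])) /
    (2 * weight_eff)
  offset <- max(stance_n[1] %/% 2L, as.integer(round(impulse_samples)))
  margin <- as.integer(round(0.10 * stance_n[2]))
  n_total <- max(offset + stance_n[2], stance_n[1]) + margin

  channels <- matrix(0, nrow = n_total, ncol = 6,
                     dimnames = list(NULL, GRF_CHANNELS))
  channels[seq_len(stance_n[1]), LEFT_CHANNELS] <- waves[[1]]
  channels[offset + seq_len(stance_n[2]), RIGHT_CHANNELS] <- waves[[2]]

  cy <- grf_cycle(channels, subject_id = profile$subject_id,
                  condition = condition, trial_id = trial_id,
                  sample_rate = fs, body_mass_kg = profile$body_mass_kg)
  attr(cy, "stance_truth") <- list(
    left = c(start = 1L, end = stance_n[1]),
    right = c(start = offset + 1L, end = offset + stance_n[2]))
  cy
}

#' Build a two-condition synthetic study
#'
#' Generates, for every subject, `trials_min`-`trials_max` unloaded cycles
#' and the same range of loaded cycles (briefcase in the subject's fixed
#' carrying hand), pads everything to one common reference length, and
#' returns the unloaded and loaded halves as two datasets sharing the
#' subject roster.
#'
#' @param config a [generator_config()].
#' @return list with elements `unloaded` and `loaded` (two
#'   [gait_dataset()]s) and `profiles` (the generating population).
#' @export
build_study <- function(config) {
  profiles <- sample_population(config)
  set.seed(config$seed + 1L)
  n <- nrow(profiles)
  trange <- config$trials_min:config$trials_max
  draw_trials <- function(n) {
    if (length(trange) == 1L) rep(trange, n) else sample(trange, n, replace = TRUE)
  }
  trials_unl <- draw_trials(n)
  trials_load <- draw_trials(n)

  cycles <- list()
  for (i in seq_len(n)) {
    prof <- profiles[i, ]
    load_cond <- if (prof$carrying_hand == "left") "loaded_left" else "loaded_right"
    for (t in seq_len(trials_unl[i])) {
      cycles[[length(cycles) + 1L]] <- generate_cycle(
        prof, "unloaded", derive_cycle_seed(config$seed, i, 0L, t), config,
        trial_id = t)
    }
    for (t in seq_len(trials_load[i])) {
      cycles[[length(cycles) + 1L]] <- generate_cycle(
        prof, load_cond, derive_cycle_seed(config$seed, i, 1L, t), config,
        trial_id = t)
    }
  }
  all_ds <- pad_to_uniform(cycles)
  cond <- vapply(all_ds$cycles, function(cy) cy$condition, character(1))
  list(
    unloaded = gait_dataset(all_ds$cycles[cond == "unloaded"]),
    loaded = gait_dataset(all_ds$cycles[cond != "unloaded"]),
    profiles = profiles
  )
}
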