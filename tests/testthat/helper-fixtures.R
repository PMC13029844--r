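# Hand-buildable fixtures: square-pulse cycles with exactly known stance
# support, and small synthetic studies.

# A cycle whose limbs carry constant-force square pulses: left stance on
# samples left_on, right stance on right_on (1-based index vectors).
square_cycle <- function(n = 100, left_on = 11:40, right_on = 51:80,
                         left_level = c(50, 700, 30),
                         right_level = c(45, 650, 25),
                         subject_id = "S1", condition = "unloaded",
                         trial_id = 1L, sample_rate = 960,
                         body_mass_kg = 70) {
  ch <- matrix(0, n, 6)
  for (k in 1:3) ch[left_on, k] <- left_level[k]
  for (k in 1:3) ch[right_on, k + 3] <- right_level[k]
  grf_cycle(ch, subject_id = subject_id, condition = condition,
            trial_id = trial_id, sample_rate = sample_rate,
            body_mass_kg = body_mass_kg)
}

# small noise-free study configuration: subjects are perfectly separable
noiseless_config <- function(n_subjects = 3, trials = 5, seed = 1) {
  generator_config(n_subjects = n_subjects, trials_min = trials,
                   trials_max = trials, amp_noise_sd = 0,
                   timing_noise_sd = 0, stance_noise_sd = 0, seed = seed)
}

small_config <- function(n_subjects = 5, trials = 10, seed = 1) {
  generator_config(n_subjects = n_subjects, trials_min = trials,
                   trials_max = trials, seed = seed)
}

dataset_labels_test <- function(ds) {
  vapply(ds$cycles, function(cy) cy$subject_id, character(1))
}

# posterior matrix from explicit rows
post_matrix <- function(rows, classes, id = "clf") {
  P <- do.call(rbind, rows)
  colnames(P) <- classes
  structure(P, classifier_id = id)
}

# rankings object built directly from a matrix of class indices
make_rankings <- function(mat, classes) {
  structure(as.matrix(mat), classes = classes,
            class = c("top_rankings", "matrix", "array"))
}
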