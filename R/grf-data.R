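# Fixed channel convention: left limb first, then right; within a limb
# anterior-posterior, vertical, medial-lateral. All I/O and all classifiers
# assume this order.
GRF_CHANNELS <- c("L_AP", "L_V", "L_ML", "R_AP", "R_V", "R_ML")
LEFT_CHANNELS <- 1:3
RIGHT_CHANNELS <- 4:6
VERTICAL_CHANNELS <- c(2L, 5L)
GRF_CONDITIONS <- c("unloaded", "loaded_left", "loaded_right")

#' Construct a single GRF gait cycle
#'
#' A gait cycle holds the six force channels of one stride measured on two
#' force plates (one stance per limb), on a shared time axis aligned at the
#' left heel strike. Forces are stored in raw newtons; body mass is carried
#' as metadata only and is never used to rescale the signals, because a
#' deployed force-plate identification system cannot assume the subject's
#' mass is known.
#'
#' @param channels numeric matrix with N rows and 6 columns in the order
#'   `L_AP, L_V, L_ML, R_AP, R_V, R_ML` (anterior-posterior, vertical,
#'   medial-lateral for the left then right limb), in newtons.
#' @param subject_id subject label (coerced to character).
#' @param condition one of `"unloaded"`, `"loaded_left"`, `"loaded_right"`.
#' @param trial_id integer trial index.
#' @param sample_rate sampling frequency in Hz (default 960).
#' @param body_mass_kg positive body mass in kg (metadata).
#' @return an object of class `grf_cycle`.
#' @export
grf_cycle <- function(channels, subject_id, condition = "unloaded",
                      trial_id = 1L, sample_rate = 960, body_mass_kg = NA_real_) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 6L) {
    stop("a GRF cycle must have exactly 6 channels, got ", ncol(channels),
         call. = FALSE)
  }
  if (!is.numeric(channels) || anyNA(channels)) {
    stop("channels must be numeric and free of NA", call. = FALSE)
  }
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a single positive number", call. = FALSE)
  }
  condition <- match.arg(condition, GRF_CONDITIONS)
  colnames(channels) <- GRF_CHANNELS
  structure(
    list(
      subject_id = as.character(subject_id),
      condition = condition,
      trial_id = as.integer(trial_id),
      sample_rate = sample_rate,
      channels = channels,
      body_mass_kg = as.numeric(body_mass_kg)
    ),
    class = "grf_cycle"
  )
}

#' @export
print.grf_cycle <- function(x, ...) {
  cat(sprintf(
    "<grf_cycle> subject %s, %s, trial %d: %d samples x 6 channels @ %g Hz\n",
    x$subject_id, x$condition, x$trial_id, nrow(x$channels), x$sample_rate))
  peaks <- apply(x$channels[, VERTICAL_CHANNELS, drop = FALSE], 2, max)
  cat(sprintf("  peak vertical force L/R: %.1f / %.1f N; body mass %.1f kg\n",
              peaks[1], peaks[2], x$body_mass_kg))
  invisible(x)
}

#' @export
length.grf_cycle <- function(x) nrow(x$channels)

cycle_key <- function(cycle) {
  paste(cycle$subject_id, cycle$condition, cycle$trial_id, sep = "__")
}

#' Detect the stance interval on a vertical force channel
#'
#' The stance phase is the interval where the foot loads the plate; it is
#' located from the vertical component as the envelope of threshold
#' exceedances: the interval runs from the first to the last sample above
#' `threshold`, tolerating brief sub-threshold dips inside it. Indices are
#' 1-based and inclusive at both ends.
#'
#' @param fv numeric vector, vertical force in newtons.
#' @param threshold positive force threshold in newtons. The default 10 N is
#'   far above force-plate noise and far below any body weight.
#' @return integer vector `c(start, end)` of class `stance_interval`.
#' @export
detect_stance <- function(fv, threshold = 10) {
  if (length(fv) < 1L) stop("empty series", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be positive", call. = FALSE)
  }
  above <- which(fv > threshold)
  if (length(above) == 0L) {
    stop("no stance detected: no sample exceeds ", threshold, " N",
         call. = FALSE)
  }
  structure(c(start = above[1L], end = above[length(above)]),
            class = "stance_interval")
}

stance_length <- function(interval) {
  unname(interval[2L] - interval[1L] + 1L)
}

#' Validate the structural invariants of a GRF cycle
#'
#' Checks that all six channels share one length, that vertical channels are
#' nonnegative up to `eps`, and that each limb's channels are exactly zero
#' outside that limb's stance interval (signals are stance-only by
#' construction: the plates read zero while the foot is airborne).
#'
#' @param cycle a [grf_cycle()].
#' @param threshold stance detection threshold in newtons.
#' @param eps tolerance for negative vertical noise.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_cycle <- function(cycle, threshold = 10, eps = 1e-6) {
  stopifnot(inherits(cycle, "grf_cycle"))
  ch <- cycle$channels
  if (any(ch[, VERTICAL_CHANNELS] < -eps)) {
    stop("vertical force below -eps", call. = FALSE)
  }
  for (limb in list(LEFT_CHANNELS, RIGHT_CHANNELS)) {
    fv <- ch[, limb[2L]]
    if (!any(fv > threshold)) next  # silent limb: must be all zero
    iv <- detect_stance(fv, threshold)
    nz <- which(rowSums(abs(ch[, limb, drop = FALSE])) > 0)
    # the nonzero support may exceed the thresholded interval only by the
    # short loading/unloading ramps at the stance edges
    margin <- max(2L, ceiling(0.1 * stance_length(iv)))
    if (nz[1L] < iv[1L] - margin || nz[length(nz)] > iv[2L] + margin) {
      stop("nonzero samples outside the stance interval", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Pad a collection of cycles to a uniform length
#'
#' The length of the longest cycle is taken as the reference and all shorter
#' cycles are padded with trailing zeros (cycles are aligned at the first
#' heel strike, so padding is appended at the end). Existing samples are
#' never modified. At a 960 Hz plate the study-scale reference length is
#' N = 1471 samples (about 1.53 s).
#'
#' @param cycles list of [grf_cycle()] with a common sample rate.
#' @return a [gait_dataset()] with `unified_length = max` input length.
#' @export
pad_to_uniform <- function(cycles) {
  if (length(cycles) == 0L) stop("empty cycle collection", call. = FALSE)
  rates <- vapply(cycles, function(cy) cy$sample_rate, numeric(1))
  if (length(unique(rates)) != 1L) {
    stop("mixed sample rates: ", paste(unique(rates), collapse = ", "),
         call. = FALSE)
  }
  n_max <- max(vapply(cycles, length, integer(1)))
  padded <- lapply(cycles, function(cy) {
    n <- nrow(cy$channels)
    if (n < n_max) {
      cy$channels <- rbind(cy$channels,
                           matrix(0, nrow = n_max - n, ncol = 6L,
                                  dimnames = list(NULL, GRF_CHANNELS)))
    }
    cy
  })
  gait_dataset(padded)
}

#' Construct a gait dataset
#'
#' A gait dataset is an ordered collection of equal-length [grf_cycle()]s
#' together with a subject roster (per-subject body mass and per-condition
#' trial counts). Keys `(subject, condition, trial)` must be unique.
#'
#' @param cycles list of [grf_cycle()], all with the same length and rate.
#' @return object of class `gait_dataset` with elements `cycles`,
#'   `unified_length`, `sample_rate`, `manifest` (a data frame roster).
#' @export
gait_dataset <- function(cycles) {
  if (length(cycles) == 0L) {
    return(structure(list(cycles = list(), unified_length = 0L,
                          sample_rate = NA_real_,
                          manifest = empty_roster()),
                     class = "gait_dataset"))
  }
  lens <- vapply(cycles, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("cycles have unequal lengths; use pad_to_uniform()", call. = FALSE)
  }
  keys <- vapply(cycles, cycle_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (subject, condition, trial) keys: ",
         paste(keys[duplicated(keys)], collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      cycles = cycles,
      unified_length = lens[1L],
      sample_rate = cycles[[1L]]$sample_rate,
      manifest = build_roster(cycles)
    ),
    class = "gait_dataset"
  )
}

empty_roster <- function() {
  data.frame(subject_id = character(), body_mass_kg = numeric(),
             n_cycles = integer(), stringsAsFactors = FALSE)
}

build_roster <- function(cycles) {
  ids <- vapply(cycles, function(cy) cy$subject_id, character(1))
  mass <- vapply(cycles, function(cy) cy$body_mass_kg, numeric(1))
  cond <- vapply(cycles, function(cy) cy$condition, character(1))
  subjects <- sort(unique(ids))
  counts <- table(factor(ids, subjects), factor(cond, GRF_CONDITIONS))
  data.frame(
    subject_id = subjects,
    body_mass_kg = vapply(subjects, function(s) mass[match(s, ids)], numeric(1)),
    n_unloaded = as.integer(counts[, "unloaded"]),
    n_loaded_left = as.integer(counts[, "loaded_left"]),
    n_loaded_right = as.integer(counts[, "loaded_right"]),
    n_cycles = as.integer(rowSums(counts)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("<gait_dataset> %d cycles, %d subjects, N = %d samples @ %g Hz\n",
              length(x$cycles), nrow(x$manifest), x$unified_length,
              x$sample_rate))
  invisible(x)
}

#' @export
summary.gait_dataset <- function(object, ...) {
  m <- object$manifest
  cat(sprintf("Gait dataset: %d cycles from %d subjects\n",
              length(object$cycles), nrow(m)))
  cat(sprintf("  unified length: %d samples (%.3f s at %g Hz)\n",
              object$unified_length,
              object$unified_length / object$sample_rate, object$sample_rate))
  if (nrow(m)) {
    cat(sprintf("  body mass: %.1f +/- %.1f kg\n",
                mean(m$body_mass_kg), stats::sd(m$body_mass_kg)))
    cat(sprintf("  cycles per condition: %d unloaded, %d loaded_left, %d loaded_right\n",
                sum(m$n_unloaded), sum(m$n_loaded_left), sum(m$n_loaded_right)))
  }
  invisible(m)
}

dataset_labels <- function(ds) {
  vapply(ds$cycles, function(cy) cy$subject_id, character(1))
}

#' Write a gait dataset to disk
#'
#' Two on-disk layouts are supported. `"csv"` writes one plain-text file per
#' cycle (columns `sample_index, L_AP, L_V, L_ML, R_AP, R_V, R_ML`, full
#' double precision) plus a JSON manifest naming every cycle file, the
#' subject roster, the sample rate and the channel convention. `"rds"`
#' serializes the whole dataset to a single file, round-tripping bit for
#' bit; use it for large synthetic populations.
#'
#' @param ds a [gait_dataset()].
#' @param path directory (`csv`) or file path (`rds`).
#' @param format `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "gait_dataset"))
  if (format == "rds") {
    saveRDS(ds, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cycle_rows <- lapply(ds$cycles, function(cy) {
    file <- paste0(cycle_key(cy), ".csv")
    df <- data.frame(sample_index = seq_len(nrow(cy$channels)) - 1L,
                     cy$channels, check.names = FALSE)
    utils::write.csv(df, file.path(path, file), row.names = FALSE)
    list(file = file, subject = cy$subject_id, condition = cy$condition,
         trial = cy$trial_id, body_mass_kg = cy$body_mass_kg)
  })
  manifest <- list(
    sample_rate_hz = ds$sample_rate,
    unified_length = ds$unified_length,
    channel_order = GRF_CHANNELS,
    subjects = if (nrow(ds$manifest)) {
      lapply(seq_len(nrow(ds$manifest)), function(i) {
        list(id = ds$manifest$subject_id[i],
             body_mass_kg = ds$manifest$body_mass_kg[i])
      })
    } else list(),
    cycles = cycle_rows
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a gait dataset from disk
#'
#' Counterpart of [write_dataset()]. Validates channel count, key
#' uniqueness and the sample rate. Forces are kept in raw newtons; no
#' body-weight normalization is ever applied.
#'
#' @param path directory with `manifest.json` (`csv`) or an RDS file.
#' @param format `"csv"` or `"rds"`.
#' @return a [gait_dataset()].
#' @export
read_dataset <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    ds <- readRDS(path)
    if (!inherits(ds, "gait_dataset")) stop("not a gait_dataset file", call. = FALSE)
    return(ds)
  }
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json under ", path, call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path)
  rate <- as.numeric(man$sample_rate_hz)
  if (!is.finite(rate) || rate <= 0) {
    stop("manifest sample_rate_hz must be positive", call. = FALSE)
  }
  mass_of <- vapply(man$subjects, function(s) as.numeric(s$body_mass_kg),
                    numeric(1))
  names(mass_of) <- vapply(man$subjects, function(s) as.character(s$id),
                           character(1))
  cycles <- lapply(man$cycles, function(entry) {
    df <- utils::read.csv(file.path(path, entry$file), check.names = FALSE)
    cols <- setdiff(names(df), "sample_index")
    if (!identical(cols, GRF_CHANNELS)) {
      stop("cycle file ", entry$file, " does not have the 6 expected channels",
           call. = FALSE)
    }
    subj <- as.character(entry$subject)
    grf_cycle(as.matrix(df[, GRF_CHANNELS]),
              subject_id = subj,
              condition = entry$condition,
              trial_id = entry$trial,
              sample_rate = rate,
              body_mass_kg = if (!is.null(entry$body_mass_kg))
                as.numeric(entry$body_mass_kg) else unname(mass_of[subj]))
  })
  roster_ids <- names(mass_of)
  cycle_ids <- unique(vapply(cycles, function(cy) cy$subject_id, character(1)))
  if (!all(cycle_ids %in% roster_ids)) {
    stop("cycle subjects missing from the manifest roster", call. = FALSE)
  }
  gait_dataset(cycles)
}
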