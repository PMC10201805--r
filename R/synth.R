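# Synthetic single-channel EEG-like segments. These emulate the qualitative
# class contrasts of real epilepsy corpora -- ictal activity with markedly
# larger amplitude and lower complexity (rhythmic ~3 Hz spike-and-wave) than
# broadband background -- without claiming physiological realism. They make
# every downstream stage testable without external downloads.

.synth_classes <- c("background", "interictal_like", "ictal_like")

# default amplitude scale per class: ictal-like amplitude is 3x background,
# mirroring the gross amplitude contrast between seizure and background EEG
.synth_amp_default <- c(background = 1, interictal_like = 1, ictal_like = 3)

.base_sd_uv <- 20 # microvolt scale of a unit-amplitude background segment

#' Synthetic segment configuration
#'
#' @param class_name One of `"background"` (band-limited 1/f^beta Gaussian
#'   noise), `"interictal_like"` (background plus sparse biphasic spikes) or
#'   `"ictal_like"` (high-amplitude spike-and-wave oscillation with
#'   reduced-variance noise).
#' @param fs Sampling rate in Hz (default 173.61).
#' @param n_samples Segment length (>= 64; default 4097).
#' @param amplitude_scale Positive amplitude multiplier; defaults to 1 for
#'   background/interictal-like and 3 for ictal-like.
#' @param spike_rate Expected interictal spike events per second.
#' @param oscillation_hz Spike-and-wave repetition rate for ictal-like
#'   segments (default 3 Hz, the classic absence-seizure signature, inside
#'   the A4/D4 analysis bands).
#' @param noise_exponent Spectral slope beta of the 1/f^beta background
#'   (default 1, pink noise).
#' @param seed Integer seed fixing the full sample path.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(class_name = "background", fs = 173.61,
                         n_samples = 4097, amplitude_scale = NULL,
                         spike_rate = 0.8, oscillation_hz = 3,
                         noise_exponent = 1, seed = 0) {
  if (!(class_name %in% .synth_classes)) {
    stop("unknown class_name '", class_name, "'; one of: ",
         paste(.synth_classes, collapse = ", "), call. = FALSE)
  }
  stopifnot(fs > 0, n_samples >= 64, spike_rate >= 0, oscillation_hz > 0)
  if (is.null(amplitude_scale)) {
    amplitude_scale <- .synth_amp_default[[class_name]]
  }
  stopifnot(amplitude_scale > 0)
  structure(list(class_name = class_name, fs = fs,
                 n_samples = as.integer(n_samples),
                 amplitude_scale = amplitude_scale, spike_rate = spike_rate,
                 oscillation_hz = oscillation_hz,
                 noise_exponent = noise_exponent, seed = as.integer(seed)),
            class = "synth_config")
}

# band-limited 1/f^(beta/2) amplitude-shaped Gaussian noise, unit SD
.colored_noise <- function(n, fs, beta) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freq <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L))) * fs / n
  gain <- numeric(n)
  band <- freq >= 0.5 & freq <= 0.95 * fs / 2
  gain[band] <- freq[band]^(-beta / 2)
  x <- Re(stats::fft(W * gain, inverse = TRUE)) / n
  x / std(x)
}

#' Generate one synthetic EEG-like segment
#'
#' Deterministic given the configuration: identical `(cfg, seed)` yields a
#' bit-identical sample path. The caller's RNG state is left untouched.
#'
#' @param cfg A [synth_config()].
#' @return An unlabeled [eeg_segment()] with `source_id`
#'   `"<class>_seed<seed>"`.
#' @export
generate_segment <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)
  n <- cfg$n_samples
  fs <- cfg$fs
  amp <- cfg$amplitude_scale * .base_sd_uv
  x <- switch(cfg$class_name,
    background = amp * .colored_noise(n, fs, cfg$noise_exponent),
    interictal_like = {
      bg <- amp * .colored_noise(n, fs, cfg$noise_exponent)
      n_spikes <- stats::rpois(1L, cfg$spike_rate * n / fs)
      if (n_spikes > 0L) {
        tt <- seq(-0.035, 0.035, by = 1 / fs)
        s <- 0.012 # spike half-width in seconds
        tmpl <- -(tt / s) * exp(-tt^2 / (2 * s^2))
        tmpl <- tmpl / max(abs(tmpl))
        centers <- sample.int(n, n_spikes, replace = TRUE)
        amps <- amp * (4 + stats::rnorm(n_spikes, 0, 0.5))
        for (k in seq_len(n_spikes)) {
          idx <- centers[k] + seq_along(tmpl) - (length(tmpl) %/% 2L)
          ok <- idx >= 1L & idx <= n
          bg[idx[ok]] <- bg[idx[ok]] + amps[k] * tmpl[ok]
        }
      }
      bg
    },
    ictal_like = {
      phase <- 2 * pi * cfg$oscillation_hz * (seq_len(n) - 1L) / fs +
        stats::runif(1L, 0, 2 * pi)
      saw <- 2 * ((phase / (2 * pi)) %% 1) - 1       # slow wave
      spk <- exp(20 * (cos(phase) - 1))              # sharp spike per cycle
      wave <- saw + 2 * spk
      wave <- wave / std(wave)
      noise <- 0.3 * .colored_noise(n, fs, cfg$noise_exponent)
      y <- wave + noise
      amp * y / std(y)
    })
  eeg_segment(x, fs = fs,
              source_id = paste0(cfg$class_name, "_seed", cfg$seed))
}

# hierarchical per-segment seed: master seed -> (class index, replicate)
.derive_seed <- function(seed, class_idx, rep_idx) {
  as.integer((abs(as.double(seed)) * 1000003 + class_idx * 10007 + rep_idx) %%
               2147483562)
}

#' Generate a labeled synthetic dataset
#'
#' Per-segment seeds are derived deterministically from the master seed,
#' class index and replicate index, so a dataset is extensible (more
#' replicates, more classes) without reshuffling existing segments.
#'
#' @param n_per_class Segments per class (>= 1).
#' @param classes Character vector of class names (see [synth_config()]).
#' @param base_cfg Named list of [synth_config()] overrides applied to every
#'   class (e.g. `list(fs = 173.61, n_samples = 512)`).
#' @param seed Master seed.
#' @param label_map Named integer vector class -> label; default labels
#'   `ictal_like` 1 and every other class 0.
#' @return List of labeled [eeg_segment()]s, grouped by class, with
#'   `source_id` `"<class>_<replicate>"`.
#' @export
generate_dataset <- function(n_per_class, classes = c("background", "ictal_like"),
                             base_cfg = list(), seed = 0, label_map = NULL) {
  stopifnot(n_per_class >= 1)
  if (length(classes) == 0L) stop("empty class list", call. = FALSE)
  if (is.null(label_map)) {
    label_map <- stats::setNames(as.integer(classes == "ictal_like"), classes)
  }
  out <- list()
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    for (ri in seq_len(n_per_class)) {
      args <- c(list(class_name = cls,
                     seed = .derive_seed(seed, ci, ri)), base_cfg)
      seg <- generate_segment(do.call(synth_config, args))
      seg$label <- label_map[[cls]]
      seg$source_id <- sprintf("%s_%03d", cls, ri)
      out[[length(out) + 1L]] <- seg
    }
  }
  out
}

#' Write a dataset as an on-disk fixture tree
#'
#' Emits a directory layout mimicking the public corpora -- one
#' subdirectory per set holding one file per segment -- in either the Bonn
#' ASCII dialect (one sample per line) or the MAT dialect (one numeric
#' vector per v5 MAT file), readable by [read_bonn_segment()] /
#' [read_delhi_segment()].
#'
#' @param dataset List of [eeg_segment()]s (e.g. from
#'   [generate_dataset()]).
#' @param root Output directory (created if needed).
#' @param dialect `"bonn"` or `"delhi"`.
#' @param sets Optional character vector (one per segment) of set
#'   subdirectory names; default strips the replicate suffix from each
#'   `source_id`.
#' @return Invisibly, the written file paths.
#' @export
write_fixture_tree <- function(dataset, root, dialect = c("bonn", "delhi"),
                               sets = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(sets)) {
    sets <- vapply(dataset, function(s) sub("_[^_]*$", "", s$source_id),
                   character(1))
  }
  stopifnot(length(sets) == length(dataset))
  paths <- character(length(dataset))
  for (i in seq_along(dataset)) {
    seg <- dataset[[i]]
    dir <- file.path(root, sets[i])
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("cannot create ", dir, call. = FALSE)
    if (dialect == "bonn") {
      paths[i] <- file.path(dir, paste0(seg$source_id, ".txt"))
      writeLines(sprintf("%.10g", seg$samples), paths[i])
    } else {
      paths[i] <- file.path(dir, paste0(seg$source_id, ".mat"))
      write_mat5(paths[i], stats::setNames(list(seg$samples), "data"))
    }
  }
  invisible(paths)
}

#' Read a fixture/dataset tree back into segments grouped by set
#'
#' Scans the per-set subdirectories of `root` and parses each file with the
#' dialect's reader.
#'
#' @inheritParams write_fixture_tree
#' @param root Directory containing one subdirectory per set.
#' @return Named list: set name -> list of [eeg_segment()]s.
#' @export
read_segment_tree <- function(root, dialect = c("bonn", "delhi")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  sets <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  if (length(sets) == 0L) stop("no set subdirectories under ", root,
                               call. = FALSE)
  reader <- if (dialect == "bonn") read_bonn_segment else read_delhi_segment
  pat <- if (dialect == "bonn") "\\.(txt|TXT)$" else "\\.(mat|MAT)$"
  out <- lapply(sets, function(s) {
    files <- sort(list.files(file.path(root, s), pattern = pat,
                             full.names = TRUE), method = "radix")
    lapply(files, reader)
  })
  stats::setNames(out, sets)
}
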