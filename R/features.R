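#' Canonical 20-feature name set
#'
#' Column order of the subband feature vector: all STD features over
#' D1..D4, A4, then all SampEn, ApEn and FuzzyEn blocks in the same subband
#' order.
#'
#' @param levels Decomposition depth (default 4).
#' @return Character vector of feature names, e.g. `"D1 STD"`.
#' @export
feature_names <- function(levels = 4) {
  bands <- c(paste0("D", seq_len(levels)), paste0("A", levels))
  unlist(lapply(c("STD", "SampEn", "ApEn", "FuzzyEn"),
                function(f) paste(bands, f)))
}

#' Extract the subband feature vector from one decomposition
#'
#' Computes STD, SampEn, ApEn and FuzzyEn on each subband of a
#' [dwt_decompose()] result, yielding the 20-feature vector (for 4 levels).
#' The entropy tolerance `r` is resolved per subband from that subband's own
#' SD when the policy is relative, since each subband has its own amplitude
#' scale. Undefined SampEn (no template matches) is capped at
#' `log(N-m) + log(N-m-1) - log(2)` when `cap_undefined = TRUE` (default),
#' otherwise re-raised.
#'
#' @param sb A `subband_set` from [dwt_decompose()].
#' @param p An [entropy_params()] policy.
#' @param cap_undefined Substitute the conventional cap for undefined
#'   SampEn instead of failing?
#' @return Named numeric vector in [feature_names()] order.
#' @export
extract_features <- function(sb, p = entropy_params(), cap_undefined = TRUE) {
  stopifnot(inherits(sb, "subband_set"))
  bands <- c(paste0("D", seq_len(sb$levels)), paste0("A", sb$levels))
  # a subband whose variance is numerically zero relative to the segment's
  # overall scale carries only floating-point residue (e.g. the detail bands
  # of a constant input); its entropies are those of a constant: zero
  sds <- vapply(bands, function(b) std(sb$subbands[[b]]), numeric(1))
  amp <- max(vapply(bands, function(b) max(abs(sb$subbands[[b]])), numeric(1)))
  degenerate <- sds <= 1e-10 * amp
  per_band <- lapply(seq_along(bands), function(bi) {
    x <- sb$subbands[[bands[bi]]]
    if (degenerate[bi]) {
      return(c(STD = std(x), SampEn = 0, ApEn = 0, FuzzyEn = 0))
    }
    se <- tryCatch(sampen(x, p), eegseize_sampen_undefined = function(e) {
      if (cap_undefined) sampen_cap(length(x), p$m) else stop(e)
    })
    c(STD = std(x), SampEn = se, ApEn = apen(x, p), FuzzyEn = fuzzyen(x, p))
  })
  names(per_band) <- bands
  out <- unlist(lapply(c("STD", "SampEn", "ApEn", "FuzzyEn"), function(f) {
    vapply(bands, function(b) per_band[[b]][[f]], numeric(1))
  }))
  names(out) <- feature_names(sb$levels)
  out
}

#' Full preprocessing + feature extraction for a batch of segments
#'
#' For each labeled segment: optional Butterworth band-pass, optional
#' wavelet denoising, multilevel DWT decomposition, then the 20-feature
#' vector. Returns the stacked [feature_matrix()].
#'
#' @param segments List of labeled [eeg_segment()]s.
#' @param config A [pipeline_config()].
#' @return A [feature_matrix()] with one row per segment, labels taken from
#'   the segments.
#' @export
segments_to_features <- function(segments, config = pipeline_config()) {
  stopifnot(length(segments) >= 1L)
  labels <- vapply(segments, function(s) {
    if (is.null(s$label)) stop("all segments must be labeled", call. = FALSE)
    as.integer(s$label)
  }, integer(1))
  p <- entropy_params(m = config$m, r = config$r, n = config$fuzzy_n)
  seen_warnings <- character(0)
  rows <- withCallingHandlers(lapply(segments, function(seg) {
    if (isTRUE(config$bandpass)) {
      seg <- bandpass(seg, low = config$low, high = config$high,
                      order = config$order)
    }
    if (isTRUE(config$denoise)) {
      seg <- wavelet_denoise(seg, wavelet = config$wavelet,
                             levels = config$levels)
    }
    sb <- dwt_decompose(seg, wavelet = config$wavelet, levels = config$levels,
                        representation = config$representation)
    extract_features(sb, p, cap_undefined = config$cap_undefined)
  }), warning = function(w) {
    # each segment triggers the same design warnings; report each once
    seen_warnings <<- unique(c(seen_warnings, conditionMessage(w)))
    invokeRestart("muffleWarning")
  })
  for (msg in seen_warnings) warning(msg, call. = FALSE)
  feature_matrix(do.call(rbind, rows), labels)
}

#' Pipeline configuration
#'
#' All tunable knobs of the preprocessing/feature/selection/classification
#' pipeline with their defaults: 4th-order Butterworth band-pass 0.01 Hz to
#' the upper analysis edge, db4 denoising and 4-level decomposition,
#' reconstructed-subband features with m = 2, r = 0.2 x subband SD, fuzzy
#' exponent 2, recursive selection down to 10 features with 200 trees, and
#' the compact 1-D CNN classifier.
#'
#' @param bandpass,low,high,order Band-pass toggle and Butterworth design.
#' @param denoise Apply wavelet denoising before decomposition?
#' @param wavelet,levels Wavelet basis and decomposition depth.
#' @param representation Feature domain: `"reconstructed"` subband signals
#'   (default) or raw `"coefficients"`.
#' @param m,r,fuzzy_n Entropy policy (see [entropy_params()]).
#' @param cap_undefined Cap undefined SampEn values (see
#'   [extract_features()]).
#' @param k_final,n_trees Feature-selection target size and forest size.
#' @param selection_scope `"fold"` (selection re-fit inside each training
#'   fold; leak-proof default) or `"global"` (selected once on all rows).
#' @param classifier `"cnn"` (default) or `"svm"` comparison baseline.
#' @param train A [train_config()] for the classifier.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bandpass = TRUE, low = 0.01, high = NULL,
                            order = 4, denoise = TRUE,
                            wavelet = "db4", levels = 4,
                            representation = c("reconstructed", "coefficients"),
                            m = 2, r = 0.2, fuzzy_n = 2, cap_undefined = TRUE,
                            k_final = 10, n_trees = 200,
                            selection_scope = c("fold", "global"),
                            classifier = c("cnn", "svm"),
                            train = train_config()) {
  structure(list(bandpass = bandpass, low = low, high = high, order = order,
                 denoise = denoise, wavelet = wavelet, levels = levels,
                 representation = match.arg(representation),
                 m = m, r = r, fuzzy_n = fuzzy_n,
                 cap_undefined = cap_undefined,
                 k_final = k_final, n_trees = n_trees,
                 selection_scope = match.arg(selection_scope),
                 classifier = match.arg(classifier), train = train),
            class = "pipeline_config")
}
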