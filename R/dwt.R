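# Daubechies orthogonal scaling (reconstruction low-pass) filters.
# Standard published coefficients, normalised so sum = sqrt(2).
.db_rec_lo <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
          -0.12940952255126037),
  db3 = c(0.33267055295008263, 0.8068915093110925, 0.45987750211849154,
          -0.13501102001025458, -0.08544127388202666, 0.03522629188570953),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db5 = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729,
          0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
          0.07757149384004572, -0.006241490212798274, -0.012580751999081999,
          0.0033357252854737712),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.09750160558732304, 0.027522865530305727, -0.03158203931748603,
          0.0005538422011614961, 0.004777257510945511, -0.0010773010853084796),
  db7 = c(0.07785205408500918, 0.3965393194819173, 0.7291320908462351,
          0.4697822874051931, -0.14390600392856498, -0.22403618499387498,
          0.07130921926683026, 0.08061260915108308, -0.03802993693501441,
          -0.01657454163066688, 0.01255099855609984, 0.0004295779729213665,
          -0.0018016407040474908, 0.00035371379997452024),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705, 0.0006754494064505693,
          -0.00011747678412476953)
)

#' Orthogonal wavelet filter bank
#'
#' Returns the four filters (decomposition/reconstruction, low/high-pass) of
#' an orthogonal Daubechies wavelet. The high-pass filters are the quadrature
#' mirrors of the low-pass pair.
#'
#' @param wavelet Wavelet name, `"db1"` through `"db8"` (default `"db4"`).
#' @return A list with elements `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` and
#'   the filter length `length`.
#' @export
wavelet_filters <- function(wavelet = "db4") {
  rec_lo <- .db_rec_lo[[wavelet]]
  if (is.null(rec_lo)) {
    stop("unsupported wavelet '", wavelet, "'; available: ",
         paste(names(.db_rec_lo), collapse = ", "), call. = FALSE)
  }
  qmf <- rec_lo * rep_len(c(-1, 1), length(rec_lo))
  list(dec_lo = rev(rec_lo), dec_hi = qmf,
       rec_lo = rec_lo, rec_hi = rev(qmf),
       length = length(rec_lo))
}

# valid true convolution: v[k] = sum_j f[j] * s[k + F - j], k = 1..len(s)-F+1
.conv_valid <- function(s, f) {
  F <- length(f)
  if (length(s) < F) stop("signal shorter than filter", call. = FALSE)
  drop(stats::embed(s, F) %*% f)
}

# full convolution via zero padding
.conv_full <- function(s, f) {
  F <- length(f)
  .conv_valid(c(numeric(F - 1), s, numeric(F - 1)), f)
}

.upsample2 <- function(x) {
  u <- numeric(2L * length(x))
  u[seq(1L, length(u), by = 2L)] <- x
  u
}

# One analysis step. Symmetric half-point extension keeps
# floor((n + F - 1)/2) coefficients per branch; the periodized mode is the
# boundary-free orthogonal variant (requires even length) with n/2 per branch.
.dwt_step <- function(x, flt, boundary) {
  n <- length(x)
  F <- flt$length
  if (boundary == "symmetric") {
    if (n < 2L) stop("input too short for one decomposition level", call. = FALSE)
    ext <- c(x[pmin(n, (F - 1L):1L)], x, x[pmax(1L, n:(n - F + 2L))])
    vA <- .conv_valid(ext, flt$dec_lo)
    vD <- .conv_valid(ext, flt$dec_hi)
    idx <- seq(2L, length(vA), by = 2L)
    list(cA = vA[idx], cD = vD[idx])
  } else { # periodized
    if (n %% 2L != 0L) {
      stop("periodized decomposition requires an even-length signal at every ",
           "level (got length ", n, "); use boundary = \"symmetric\"",
           call. = FALSE)
    }
    # circular convolution, aligned so .idwt_step below is the exact inverse
    circ <- function(f) {
      vapply(seq(2L, n, by = 2L) , function(k) {
        j <- seq_len(F)
        sum(f * x[(((k + F %/% 2L - 1L) - j) %% n) + 1L])
      }, numeric(1))
    }
    list(cA = circ(flt$dec_lo), cD = circ(flt$dec_hi))
  }
}

# One synthesis step; n = target output length.
.idwt_step <- function(cA, cD, flt, boundary, n) {
  F <- flt$length
  yf <- .conv_full(.upsample2(cA), flt$rec_lo) +
        .conv_full(.upsample2(cD), flt$rec_hi)
  if (boundary == "symmetric") {
    out_len <- 2L * length(cA) - F + 2L
    y <- yf[(F - 1L):(F - 2L + out_len)]
    if (length(y) < n) stop("cannot reconstruct to requested length", call. = FALSE)
    y[seq_len(n)]
  } else {
    m <- 2L * length(cA)
    out <- numeric(m)
    o <- F %/% 2L - 1L
    pos <- ((seq_along(yf) - 1L - o) %% m) + 1L
    for (k in seq_along(yf)) out[pos[k]] <- out[pos[k]] + yf[k]
    out[seq_len(n)]
  }
}

# Multilevel analysis: returns list(cA = deepest approximation,
# cD = list(D1, D2, ..., DL), lengths = input length at each level).
.wavedec <- function(x, flt, levels, boundary) {
  cD <- vector("list", levels)
  lengths <- integer(levels)
  a <- x
  for (lev in seq_len(levels)) {
    lengths[lev] <- length(a)
    s <- .dwt_step(a, flt, boundary)
    cD[[lev]] <- s$cD
    a <- s$cA
  }
  list(cA = a, cD = cD, lengths = lengths)
}

.waverec <- function(dec, flt, boundary) {
  a <- dec$cA
  for (lev in rev(seq_along(dec$cD))) {
    a <- .idwt_step(a, dec$cD[[lev]], flt, boundary, dec$lengths[lev])
  }
  a
}

#' Dyadic subband frequency edges
#'
#' Nominal frequency intervals `[low, high)` covered by the detail subbands
#' D1..DL and the deepest approximation AL of an L-level dyadic wavelet
#' decomposition at sampling rate `fs`: D1 spans `[fs/4, fs/2)`, each deeper
#' detail halves the band, and AL spans `[0, fs/2^(L+1))`.
#'
#' @param fs Sampling rate in Hz.
#' @param levels Number of decomposition levels (>= 1).
#' @return A data frame with columns `subband`, `low_hz`, `high_hz`, one row
#'   per subband, details first (D1..DL) then the approximation.
#' @examples
#' band_edges(173.61, 4) # A4 topping out at fs/32 = 5.4 Hz (1 dp)
#' @export
band_edges <- function(fs, levels) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0,
            is.numeric(levels), length(levels) == 1L, levels >= 1)
  levels <- as.integer(levels)
  d <- data.frame(
    subband = paste0("D", seq_len(levels)),
    low_hz = fs / 2^(seq_len(levels) + 1L),
    high_hz = fs / 2^seq_len(levels),
    stringsAsFactors = FALSE
  )
  rbind(d, data.frame(subband = paste0("A", levels),
                      low_hz = 0, high_hz = fs / 2^(levels + 1L),
                      stringsAsFactors = FALSE))
}

#' Decompose an EEG segment into wavelet subbands
#'
#' Runs a multilevel discrete wavelet transform (cascaded half-band filter
#' pairs) on a segment and returns the five subbands D1..DL, AL either as raw
#' coefficient sequences or as full-length reconstructed time-domain signals.
#' In `"reconstructed"` mode each subband is the inverse transform with every
#' other subband zeroed, so the five signals sum to the original segment.
#'
#' @param seg An [eeg_segment()] (or bare numeric vector).
#' @param wavelet Wavelet name (default `"db4"`).
#' @param levels Decomposition depth (default 4).
#' @param representation `"reconstructed"` (default) or `"coefficients"`.
#' @param boundary Boundary handling: `"symmetric"` half-point extension
#'   (default) or `"periodic"` (orthogonal, boundary-free; requires the
#'   length to be divisible by `2^levels`).
#' @return An object of class `subband_set`: a list with `subbands` (named
#'   list D1..DL, AL), `fs`, `representation` and `boundary`.
#' @export
dwt_decompose <- function(seg, wavelet = "db4", levels = 4,
                          representation = c("reconstructed", "coefficients"),
                          boundary = c("symmetric", "periodic")) {
  representation <- match.arg(representation)
  boundary <- match.arg(boundary)
  x <- segment_samples(seg)
  fs <- segment_fs(seg)
  levels <- as.integer(levels)
  if (length(x) < 2^levels) {
    stop("segment of length ", length(x), " is too short for ", levels,
         "-level decomposition (need >= ", 2^levels, " samples)", call. = FALSE)
  }
  flt <- wavelet_filters(wavelet)
  dec <- .wavedec(x, flt, levels, boundary)
  nm <- c(paste0("D", seq_len(levels)), paste0("A", levels))
  if (representation == "coefficients") {
    sub <- c(dec$cD, list(dec$cA))
  } else {
    sub <- vector("list", levels + 1L)
    for (lev in seq_len(levels)) {
      d2 <- dec
      d2$cA <- numeric(length(dec$cA))
      for (l2 in seq_len(levels)) {
        if (l2 != lev) d2$cD[[l2]] <- numeric(length(dec$cD[[l2]]))
      }
      sub[[lev]] <- .waverec(d2, flt, boundary)
    }
    dA <- dec
    for (l2 in seq_len(levels)) dA$cD[[l2]] <- numeric(length(dec$cD[[l2]]))
    sub[[levels + 1L]] <- .waverec(dA, flt, boundary)
  }
  names(sub) <- nm
  structure(list(subbands = sub, fs = fs, representation = representation,
                 boundary = boundary, wavelet = wavelet, levels = levels,
                 n = length(x)),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat("<subband_set> ", x$wavelet, ", ", x$levels, " levels, ",
      x$representation, " (", x$boundary, " boundary), fs = ", x$fs, " Hz\n",
      sep = "")
  for (nm in names(x$subbands)) {
    cat("  ", nm, ": length ", length(x$subbands[[nm]]), "\n", sep = "")
  }
  invisible(x)
}

#' Wavelet shrinkage denoising
#'
#' Multilevel DWT, soft thresholding of every detail level with the universal
#' threshold `sigma * sqrt(2 log N)` where `sigma` is the robust noise
#' estimate `median(|D1|)/0.6745` from the finest detail coefficients, then
#' reconstruction. Output length equals input length.
#'
#' @inheritParams dwt_decompose
#' @param threshold_rule Either `"universal"` (default) or a function
#'   `(coefs_by_level, n) -> threshold` returning one non-negative number.
#' @return An [eeg_segment()] with the denoised samples (metadata preserved).
#' @export
wavelet_denoise <- function(seg, wavelet = "db4", levels = 4,
                            boundary = c("symmetric", "periodic"),
                            threshold_rule = "universal") {
  boundary <- match.arg(boundary)
  x <- segment_samples(seg)
  levels <- as.integer(levels)
  if (length(x) < 2^levels) {
    stop("segment too short for ", levels, "-level denoising", call. = FALSE)
  }
  flt <- wavelet_filters(wavelet)
  dec <- .wavedec(x, flt, levels, boundary)
  if (is.function(threshold_rule)) {
    thr <- threshold_rule(dec$cD, length(x))
  } else {
    sigma <- stats::median(abs(dec$cD[[1L]])) / 0.6745
    thr <- sigma * sqrt(2 * log(length(x)))
  }
  soft <- function(w) sign(w) * pmax(abs(w) - thr, 0)
  dec$cD <- lapply(dec$cD, soft)
  y <- .waverec(dec, flt, boundary)
  out <- as_eeg_segment(seg)
  out$samples <- y
  out
}
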