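#' Entropy estimator parameters
#'
#' One parameter policy shared by the three entropy estimators: embedding
#' dimension `m`, tolerance `r` (absolute, or a fraction of the analysed
#' signal's SD when `relative = TRUE`), and the fuzzy membership gradient
#' exponent `n` (fuzzy entropy only). Defaults follow the canonical
#' Pincus/Richman/Chen conventions: m = 2, r = 0.2 x SD, n = 2.
#'
#' @param m Embedding dimension (>= 1).
#' @param r Tolerance (> 0); interpreted relative to signal SD when
#'   `relative = TRUE` (default).
#' @param n Fuzzy gradient exponent (>= 1).
#' @param relative Should `r` be scaled by the signal's population SD?
#' @return A list of class `entropy_params`.
#' @export
entropy_params <- function(m = 2, r = 0.2, n = 2, relative = TRUE) {
  stopifnot(m >= 1, r > 0, n >= 1)
  structure(list(m = as.integer(m), r = r, n = n, relative = isTRUE(relative)),
            class = "entropy_params")
}

.resolve_r <- function(x, p) {
  if (p$relative) p$r * std(x) else p$r
}

.check_entropy_input <- function(x, p) {
  if (length(x) <= p$m + 1L) {
    stop("sequence of length ", length(x),
         " too short for embedding dimension m = ", p$m, call. = FALSE)
  }
}

#' Population standard deviation
#'
#' Standard deviation with divisor `N` (population form), the time-domain
#' amplitude feature used alongside the entropies.
#'
#' @param x Numeric sequence (length >= 1).
#' @return Non-negative scalar.
#' @examples
#' std(c(1, 2, 3, 4)) # sqrt(1.25)
#' @export
std <- function(x) {
  if (length(x) < 1L) stop("empty sequence", call. = FALSE)
  m <- mean(x)
  sqrt(sum((x - m)^2) / length(x))
}

#' Approximate entropy (ApEn)
#'
#' Pincus regularity statistic `Phi^m(r) - Phi^(m+1)(r)` where `Phi^m` is
#' the mean log fraction of templates within Chebyshev distance `r`,
#' self-matches included, with `N - m + 1` templates at dimension `m`.
#' Lower values indicate a more regular (predictable) signal.
#'
#' @param x Numeric sequence, length > m + 1.
#' @param p An [entropy_params()] policy.
#' @return Non-negative scalar.
#' @export
apen <- function(x, p = entropy_params()) {
  x <- as.numeric(x)
  .check_entropy_input(x, p)
  .apen_cpp(x, p$m, .resolve_r(x, p))
}

#' Sample entropy (SampEn)
#'
#' `-log(A/B)` where `B` (`A`) is the number of template pairs within
#' Chebyshev distance `r` at dimension `m` (`m + 1`); self-matches are
#' excluded and both dimensions use the same `N - m` templates, so the
#' pattern counts are directly comparable. When no pairs match at either
#' dimension the statistic is undefined and a condition of class
#' `eegseize_sampen_undefined` is raised; callers may catch it and
#' substitute the conventional cap `log(N-m) + log(N-m-1) - log(2)`.
#'
#' @inheritParams apen
#' @return Non-negative scalar.
#' @export
sampen <- function(x, p = entropy_params()) {
  x <- as.numeric(x)
  .check_entropy_input(x, p)
  cnt <- .sampen_counts_cpp(x, p$m, .resolve_r(x, p))
  B <- cnt[1L]; A <- cnt[2L]
  if (A == 0 || B == 0) {
    stop(structure(
      class = c("eegseize_sampen_undefined", "error", "condition"),
      list(message = paste0("sample entropy undefined: matched pairs B = ",
                            B, ", A = ", A),
           call = sys.call(-1), n = length(x), m = p$m)))
  }
  -log(A / B)
}

# cap used when SampEn is undefined (no matches at dimension m+1):
# log of the largest representable pair-count ratio at this N, m
sampen_cap <- function(n, m) log(n - m) + log(n - m - 1) - log(2)

#' Fuzzy entropy (FuzzyEn)
#'
#' Chen's fuzzy-membership entropy: templates are baseline-removed (each
#' vector minus its own mean), pair similarity is the exponential membership
#' `exp(-(d/r)^n)` of the Chebyshev distance `d`, `phi^m` is the mean
#' pairwise similarity excluding self-pairs, and the statistic is
#' `log(phi^m) - log(phi^(m+1))`.
#'
#' @inheritParams apen
#' @return Non-negative scalar.
#' @export
fuzzyen <- function(x, p = entropy_params()) {
  x <- as.numeric(x)
  .check_entropy_input(x, p)
  phi <- .fuzzyen_phi_cpp(x, p$m, .resolve_r(x, p), p$n)
  log(phi[1L]) - log(phi[2L])
}
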