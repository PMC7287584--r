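## Refined composite multiscale sample entropy (RCME) and refined multiscale
## permutation entropy (RMPE) of the resultant waist acceleration over
## coarseness scales 1..80. The O(n^2) template-match count runs in C++.

#' Split a series into non-overlapping fixed-length epochs
#'
#' The trailing remainder that does not fill a whole epoch is discarded; a
#' warning is emitted when no full epoch fits.
#'
#' @param x A `scalar_series`.
#' @param epoch_s Epoch length in seconds (default 60).
#' @return A list of class `epoch_set` with `epochs` (list of numeric
#'   vectors, each exactly `epoch_s * sample_rate` samples) and
#'   `sample_rate`.
#' @export
split_epochs <- function(x, epoch_s = 60) {
  len <- as.integer(round(epoch_s * x$sample_rate))
  n_ep <- length(x$values) %/% len
  if (n_ep == 0L)
    warning("series shorter than one epoch; no epochs produced")
  epochs <- lapply(seq_len(n_ep), function(k)
    x$values[((k - 1L) * len + 1L):(k * len)])
  structure(list(epochs = epochs, sample_rate = x$sample_rate),
            class = "epoch_set")
}

#' Coarse-grain a series by non-overlapping block means
#'
#' `y_j = mean(x[offset + (j-1) tau : offset + j tau - 1])`. The `offset`
#' (1..tau) selects which of the `tau` possible block alignments is used —
#' the composite entropy variants pool over all of them.
#'
#' @param x Numeric vector.
#' @param tau Coarseness scale (block length).
#' @param offset Block alignment, 1..tau (default 1).
#' @return Numeric vector of block means, length
#'   `floor((length(x) - offset + 1) / tau)`.
#' @export
coarse_grain <- function(x, tau, offset = 1) {
  if (offset < 1 || offset > tau)
    stop("`offset` must lie in 1..tau", call. = FALSE)
  if (length(x) < tau) stop("series shorter than `tau`", call. = FALSE)
  n_blocks <- (length(x) - offset + 1L) %/% tau
  if (n_blocks == 0L) return(numeric())
  if (tau == 1L) return(x[offset:length(x)])
  m <- matrix(x[offset:(offset + n_blocks * tau - 1L)], nrow = tau)
  colMeans(m)
}

#' Refined composite multiscale sample entropy
#'
#' For each coarseness scale `tau`, template-match counts are pooled over
#' all `tau` coarse-graining offsets before the logarithm:
#' `RCME(tau) = -ln(sum_k A_k / sum_k B_k)`, where `B_k` counts unordered
#' template pairs of length `m` within Chebyshev distance `r` on the k-th
#' offset's coarse-grained series and `A_k` those also matching at the
#' `(m+1)`-th sample (self-matches excluded, the same template index range
#' used for both counts). The tolerance r (`r_frac * sd(x)`) is fixed once
#' from the un-coarsened epoch, so the profile is invariant to affine
#' transforms of the signal. At `tau = 1` this is plain sample entropy.
#'
#' @param x Numeric epoch (e.g. one minute of resultant acceleration).
#' @param m Template length (default 4).
#' @param r_frac Tolerance as a fraction of the epoch SD (default 0.3).
#' @param taus Integer scales (default `1:80`).
#' @param r Absolute tolerance overriding `r_frac * sd(x)` when given.
#' @return An [entropy_profile()] of kind `"RCME"`; scales with zero match
#'   counts are `NA`.
#' @export
rcme <- function(x, m = 4, r_frac = 0.3, taus = 1:80, r = NULL) {
  if (is.null(r)) r <- r_frac * sd(x)
  vals <- vapply(taus, function(tau) {
    if (length(x) < (m + 1) * tau) return(NA_real_)
    B <- 0; A <- 0
    for (k in seq_len(tau)) {
      y <- coarse_grain(x, tau, k)
      cnt <- sampen_pair_counts(y, m, r)
      B <- B + cnt[1]; A <- A + cnt[2]
    }
    if (B == 0 || A == 0) return(NA_real_)
    -log(A / B)
  }, numeric(1))
  entropy_profile(taus, vals, "RCME")
}

#' Plain sample entropy (single series)
#'
#' `-ln(A/B)` with the Richman-Moorman counting convention; equals
#' `rcme(x, taus = 1)` and is exposed for direct use and cross-checks.
#'
#' @param x Numeric vector.
#' @param m Template length (default 4).
#' @param r Absolute Chebyshev tolerance.
#' @return Sample entropy in nats (`NA` when no templates match).
#' @export
sample_entropy <- function(x, m = 4, r) {
  cnt <- sampen_pair_counts(x, m, r)
  if (cnt[1] == 0 || cnt[2] == 0) return(NA_real_)
  -log(cnt[2] / cnt[1])
}

#' Refined multiscale permutation entropy
#'
#' For each scale, ordinal patterns of `m` consecutive coarse-grained
#' samples (delay 1, ties broken by index order) are tallied on every
#' coarse-graining offset; the relative frequencies are averaged across
#' offsets and the Shannon entropy of the averaged distribution is
#' reported in nats (maximum `ln(m!)`). Invariant to strictly monotone
#' amplitude transforms.
#'
#' @param x Numeric epoch.
#' @param m Pattern order (default 4; `m! = 24` patterns).
#' @param taus Integer scales (default `1:80`).
#' @param normalize Divide by `ln(m!)` (default `FALSE`).
#' @return An [entropy_profile()] of kind `"RMPE"`.
#' @export
rmpe <- function(x, m = 4, taus = 1:80, normalize = FALSE) {
  vals <- vapply(taus, function(tau) {
    if ((length(x) - tau + 1L) %/% tau < m) return(NA_real_)
    acc <- NULL
    for (k in seq_len(tau)) {
      y <- coarse_grain(x, tau, k)
      if (length(y) < m) next
      cnt <- ordinal_pattern_counts(y, m)
      p <- cnt / sum(cnt)
      acc <- if (is.null(acc)) p else acc + p
    }
    if (is.null(acc)) return(NA_real_)
    p <- acc / sum(acc)
    p <- p[p > 0]
    h <- -sum(p * log(p))
    if (normalize) h / log(factorial(m)) else h
  }, numeric(1))
  entropy_profile(taus, vals, "RMPE")
}

#' Session-level entropy profile
#'
#' Computes the chosen entropy on every epoch and averages per scale across
#' epochs; scales undefined on some epochs are averaged over the epochs
#' where they are defined.
#'
#' @param epochs An `epoch_set` from [split_epochs()].
#' @param kind `"RCME"` or `"RMPE"`.
#' @param m Template length / pattern order (default 4).
#' @param r_frac RCME tolerance fraction (default 0.3).
#' @param taus Integer scales (default `1:80`).
#' @return An [entropy_profile()]; empty (`length 0`) when there are no
#'   epochs.
#' @export
session_entropy <- function(epochs, kind = c("RCME", "RMPE"), m = 4,
                            r_frac = 0.3, taus = 1:80) {
  kind <- match.arg(kind)
  if (length(epochs$epochs) == 0)
    return(entropy_profile(integer(), numeric(), kind, 0L))
  profs <- lapply(epochs$epochs, function(ep)
    if (kind == "RCME") rcme(ep, m = m, r_frac = r_frac, taus = taus)$values
    else rmpe(ep, m = m, taus = taus)$values)
  mat <- do.call(rbind, profs)
  vals <- colMeans(mat, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  entropy_profile(taus, vals, kind, length(epochs$epochs))
}
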