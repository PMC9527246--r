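# ---- resting-state preprocessing and coupling ------------------------------

#' Trim scanner-stabilization volumes
#'
#' Removes the first `n` volumes of a series (columns of a matrix or leading
#' elements of a vector).
#'
#' @param series Numeric vector or matrix (rows = channels, cols = volumes).
#' @param n Number of volumes to drop (default 6).
#' @return Trimmed series.
#' @export
trim_volumes <- function(series, n = 6) {
  if (is.matrix(series)) series[, -seq_len(n), drop = FALSE] else series[-seq_len(n)]
}

#' Artifact (spike) flags for a rest run
#'
#' Union of three per-volume criteria: global-signal deviation greater than
#' 3 SD from the run mean, volume-to-volume translational motion greater
#' than 1 mm on any axis, and volume-to-volume rotational motion greater
#' than 0.05 radians on any axis.
#'
#' @param series Channels x volumes matrix (global signal = column mean) or
#'   a vector already representing the global signal.
#' @param motion Volumes x 6 motion table (translations mm, rotations rad).
#' @param gs_sd Global-signal threshold in SD units (default 3).
#' @param trans_mm Translational threshold in mm (default 1).
#' @param rot_rad Rotational threshold in radians (default 0.05).
#' @return Sorted integer vector of flagged volume indices.
#' @export
art_flags <- function(series, motion, gs_sd = 3, trans_mm = 1, rot_rad = 0.05) {
  gs <- if (is.matrix(series)) colMeans(series) else series
  motion <- as.matrix(motion)
  if (nrow(motion) != length(gs)) stop("motion rows must match volumes")
  zs <- (gs - mean(gs)) / stats::sd(gs)
  f1 <- which(abs(zs) > gs_sd)
  d <- abs(diff(motion))
  f2 <- which(apply(d[, 1:3, drop = FALSE], 1, max) > trans_mm) + 1L
  f3 <- which(apply(d[, 4:6, drop = FALSE], 1, max) > rot_rad) + 1L
  sort(unique(c(f1, f2, f3)))
}

#' aCompCor nuisance components
#'
#' Top-k principal-component time courses of the noise-mask voxel matrix
#' (stand-in for eroded white-matter/CSF signals), computed on centered,
#' unsmoothed series.
#'
#' @param noise_series Voxels x volumes matrix of noise-mask signals.
#' @param k Number of components (default 5). If `k` exceeds the matrix
#'   rank, fewer components are returned with a warning. `k = 0` returns a
#'   zero-column matrix.
#' @return Volumes x k matrix of component time courses; attribute
#'   `var_explained` holds the eigenvalue shares.
#' @export
acompcor <- function(noise_series, k = 5) {
  if (k == 0) {
    return(structure(matrix(numeric(0), ncol(noise_series), 0), var_explained = numeric(0)))
  }
  X <- t(noise_series)                 # volumes x voxels
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-10
  r <- sum(pos)
  if (k > r) {
    warning(sprintf("requested %d components but rank is %d", k, r))
    k <- r
  }
  comp <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  structure(comp, var_explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}

#' Ideal FFT band-pass filter
#'
#' Zeroes every Fourier component whose frequency lies outside
#' `[band[1], band[2]]` Hz (DC removed with the low side). Transition
#' handling is the ideal brick wall: a bin is retained iff its frequency is
#' inside the closed band.
#'
#' @param x Numeric vector, or channels x volumes matrix (filtered per row).
#' @param tr Sampling interval in seconds.
#' @param band Passband in Hz (default 0.008-0.09).
#' @return Filtered series, same shape.
#' @export
bandpass <- function(x, tr, band = c(0.008, 0.09)) {
  if (is.matrix(x)) return(t(apply(x, 1, bandpass, tr = tr, band = band)))
  n <- length(x)
  f <- (seq_len(n) - 1) / (n * tr)
  f <- pmin(f, 1 / tr - f)             # two-sided frequency axis
  keep <- f >= band[1] & f <= band[2]
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

#' Nuisance regression and temporal filtering
#'
#' Regresses out the six motion parameters, their first-order temporal
#' derivatives, one indicator per flagged volume, and the aCompCor
#' components; then band-pass filters the residuals (filtering after
#' regression, in that order).
#'
#' @param series Channels x volumes matrix (or vector).
#' @param motion Volumes x 6 motion table.
#' @param flags Flagged volume indices (spike indicators regressed, volumes
#'   retained).
#' @param components Volumes x k aCompCor matrix (or NULL).
#' @param tr Sampling interval (s).
#' @param band Passband in Hz.
#' @return Denoised series, same shape as input.
#' @export
denoise <- function(series, motion, flags = integer(0), components = NULL,
                    tr = 1.5, band = c(0.008, 0.09)) {
  vec <- !is.matrix(series)
  Y <- if (vec) matrix(series, nrow = 1) else series
  n <- ncol(Y)
  motion <- as.matrix(motion)
  if (nrow(motion) != n) stop("regressor/series length mismatch")
  deriv <- rbind(0, diff(motion))
  X <- cbind(1, motion, deriv)
  if (length(flags) > 0) {
    S <- matrix(0, n, length(flags))
    S[cbind(flags, seq_along(flags))] <- 1
    X <- cbind(X, S)
  }
  if (!is.null(components) && ncol(components) > 0) {
    if (nrow(components) != n) stop("regressor/series length mismatch")
    X <- cbind(X, components)
  }
  qrX <- qr(X)
  res <- t(qr.resid(qrX, t(Y)))
  out <- bandpass(res, tr = tr, band = band)
  if (vec) out[1, ] else out
}

#' Inter-ROI coupling (Fisher z)
#'
#' Fisher-transformed Pearson correlation between two (denoised) ROI-mean
#' time series.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Fisher z (clipped as in [fisher_z()]); errors on constant input.
#' @export
roi_coupling <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant series: coupling undefined")
  as.numeric(fisher_z(stats::cor(a, b)))
}

#' Coupling deltas for a cohort
#'
#' Post-minus-pre Fisher-z coupling per participant, computed on identically
#' preprocessed series.
#'
#' @param rest Named list per participant with `pre` and `post` 2 x T
#'   matrices (rows = the two ROIs).
#' @param preprocess Optional function applied to each series matrix before
#'   coupling (e.g., trimming + denoising); default identity.
#' @return Data.frame: `participant`, `z_pre`, `z_post`, `delta`.
#' @export
coupling_deltas <- function(rest, preprocess = identity) {
  rows <- lapply(names(rest), function(id) {
    pre <- preprocess(rest[[id]]$pre)
    post <- preprocess(rest[[id]]$post)
    zp <- roi_coupling(pre[1, ], pre[2, ])
    zq <- roi_coupling(post[1, ], post[2, ])
    data.frame(participant = id, z_pre = zp, z_post = zq, delta = zq - zp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Brain-behavior correlation
#'
#' Pearson correlation between coupling deltas and memory scores with
#' `t = r * sqrt(n-2) / sqrt(1-r^2)` on `n - 2` df. One-tailed tests (the
#' a-priori direction: positive) report a one-sided 95% CI whose upper bound
#' is 1; two-tailed tests report the standard Fisher CI.
#'
#' @param deltas,scores Numeric vectors (complete pairs only).
#' @param tail `"one"` or `"two"`.
#' @return List: `r`, `t`, `df`, `p`, `ci` (length-2).
#' @export
brain_behavior <- function(deltas, scores, tail = c("one", "two")) {
  tail <- match.arg(tail)
  ok <- stats::complete.cases(deltas, scores)
  x <- deltas[ok]; y <- scores[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  r <- stats::cor(x, y)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- if (tail == "one") stats::pt(tval, n - 2, lower.tail = FALSE)
       else 2 * stats::pt(-abs(tval), n - 2)
  z <- atanh(r); se <- 1 / sqrt(n - 3)
  ci <- if (tail == "one") c(tanh(z - stats::qnorm(0.95) * se), 1)
        else tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  list(r = r, t = tval, df = n - 2, p = p, ci = ci, n = n)
}

#' Williams test for two dependent correlations
#'
#' Tests H0: rho12 = rho13 when variables 2 and 3 are themselves correlated
#' (r23), on n - 3 degrees of freedom.
#'
#' @param r12,r13,r23 Sample correlations (|r| < 1).
#' @param n Sample size (> 3).
#' @return List: `t`, `df`, `p` (two-tailed).
#' @export
williams_test <- function(r12, r13, r23, n) {
  if (any(abs(c(r12, r13, r23)) >= 1)) stop("correlations must satisfy |r| < 1")
  if (n <= 3) stop("n must exceed 3")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= 0) stop("correlations do not form a positive-definite matrix")
  rbar <- (r12 + r13) / 2
  tval <- (r12 - r13) * sqrt(
    ((n - 1) * (1 + r23)) /
      (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3)
  )
  list(t = tval, df = n - 3, p = 2 * stats::pt(-abs(tval), n - 3))
}
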