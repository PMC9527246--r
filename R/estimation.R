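# ---- single-trial pattern estimation (LSS) ---------------------------------

#' Canonical double-gamma HRF
#'
#' The canonical shape: gamma density peaking at ~6 s minus an undershoot
#' gamma peaking at ~16 s scaled by the peak:undershoot ratio.
#'
#' @param peak_delay,undershoot_delay Peak/undershoot delays in seconds.
#' @param peak_disp,undershoot_disp Dispersions (gamma scale parameters).
#' @param ratio Undershoot amplitude relative to the peak (default 1/6).
#' @param length_s Kernel length in seconds (default 32).
#' @return A list of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_disp = 1, undershoot_disp = 1,
                     ratio = 1 / 6, length_s = 32) {
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, length_s = length_s), class = "hrf_spec")
}

#' Evaluate an HRF kernel
#'
#' @param t Time points in seconds.
#' @param spec An [hrf_spec()].
#' @return Kernel values (peak normalized to 1).
#' @export
hrf_kernel <- function(t, spec = hrf_spec()) {
  h <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_disp,
                     scale = spec$peak_disp) -
    spec$ratio * stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_disp,
                               scale = spec$undershoot_disp)
  fine <- seq(0, spec$length_s, by = 0.01)
  hmax <- max(stats::dgamma(fine, shape = spec$peak_delay / spec$peak_disp,
                            scale = spec$peak_disp) -
                spec$ratio * stats::dgamma(fine, shape = spec$undershoot_delay / spec$undershoot_disp,
                                           scale = spec$undershoot_disp))
  h / hmax
}

#' HRF-convolved event regressors sampled at the TR grid
#'
#' Boxcars (onset, duration) are convolved with the HRF on a 0.1 s grid and
#' sampled at volume acquisition times (0-based).
#'
#' @param onsets,durations Event timing in seconds (one regressor per event).
#' @param n_vol Number of volumes.
#' @param tr Repetition time in seconds.
#' @param spec An [hrf_spec()].
#' @param groups Optional integer/factor of length `length(onsets)`; events
#'   sharing a level are summed into one column.
#' @return Matrix `n_vol x n_regressors`.
#' @export
hrf_design <- function(onsets, durations, n_vol, tr, spec = hrf_spec(),
                       groups = seq_along(onsets)) {
  dt <- 0.1
  total <- n_vol * tr + spec$length_s
  grid <- seq(0, total, by = dt)
  kern <- hrf_kernel(seq(0, spec$length_s, by = dt), spec)
  glev <- unique(groups)
  out <- matrix(0, n_vol, length(glev))
  vol_t <- (seq_len(n_vol) - 1) * tr
  for (k in seq_along(glev)) {
    sel <- which(groups == glev[k])
    box <- numeric(length(grid))
    for (i in sel) {
      on <- onsets[i]
      idx <- which(grid >= on & grid < on + durations[i])
      box[idx] <- box[idx] + 1
    }
    conv <- stats::convolve(box, rev(kern), type = "open")[seq_along(grid)] * dt
    out[, k] <- stats::approx(grid, conv, xout = vol_t, rule = 2)$y
  }
  colnames(out) <- as.character(glev)
  out
}

#' Framewise displacement and scrub flags
#'
#' Power-style FD: the sum of absolute backward differences of the six
#' rigid-body parameters, with rotations (radians) converted to millimetres
#' on a 50 mm sphere. The first volume has FD 0.
#'
#' @param motion Volumes x 6 matrix: 3 translations (mm), 3 rotations (rad).
#' @param threshold Flagging threshold in mm (default 0.9).
#' @param radius Rotation-to-arc radius in mm (default 50).
#' @return List: `fd` (numeric per volume), `flags` (integer volume indices
#'   with FD > threshold).
#' @export
framewise_displacement <- function(motion, threshold = 0.9, radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion table must have 6 columns (3 trans, 3 rot)")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            radius * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, flags = which(fd > threshold))
}

.trial_type_labels <- c("coarse congruent", "coarse incongruent",
                        "detailed congruent", "detailed incongruent",
                        "forgotten")

.trial_type <- function(grain, congruency) {
  ifelse(grain == "forgotten", "forgotten", paste(grain, congruency))
}

#' Build the LSS design matrix for one target trial
#'
#' First column: the target trial's cue period, HRF-convolved. Then up to
#' five nuisance columns grouping the run's remaining trials by type (coarse
#' congruent, coarse incongruent, detailed congruent, detailed incongruent,
#' forgotten; empty groups dropped), response-window regressors (both
#' response screens jointly by default, or separately), six motion columns,
#' and one indicator column per flagged volume. All-zero columns are
#' dropped.
#'
#' @param run_events Data.frame for one run: columns `onset`, `dur_cue`,
#'   `dur_context_resp`, `dur_scene_resp`, `grain`, `congruency`, and a
#'   trial identifier.
#' @param target_row Row index of the target trial within `run_events`.
#' @param motion Volumes x 6 motion table.
#' @param flags Integer indices of scrub-flagged volumes.
#' @param n_vol Number of retained volumes.
#' @param tr Repetition time (s).
#' @param spec An [hrf_spec()].
#' @param response_windows `"joint"` (one regressor for all response screens
#'   in the run) or `"separate"` (context and scene screens separately).
#' @return List of class `lss_design`: `X` (matrix), `target_col` (= 1),
#'   `cols` (labels).
#' @export
build_lss_design <- function(run_events, target_row, motion, flags, n_vol, tr,
                             spec = hrf_spec(),
                             response_windows = c("joint", "separate")) {
  response_windows <- match.arg(response_windows)
  if (nrow(run_events) == 0) stop("empty run")
  if (target_row < 1 || target_row > nrow(run_events)) stop("target trial not in run")
  ev <- run_events
  cong <- ifelse(is.na(ev$congruency), "incongruent", ev$congruency)
  ttype <- .trial_type(ev$grain, cong)
  target <- hrf_design(ev$onset[target_row], ev$dur_cue[target_row], n_vol, tr, spec)
  others <- setdiff(seq_len(nrow(ev)), target_row)
  nuis <- NULL
  nuis_labels <- character(0)
  if (length(others) > 0) {
    grp <- factor(ttype[others], levels = .trial_type_labels)
    grp <- droplevels(grp)
    nuis <- hrf_design(ev$onset[others], ev$dur_cue[others], n_vol, tr, spec,
                       groups = as.character(grp))
    nuis_labels <- colnames(nuis)
  }
  # response windows: context screen follows the cue; scene screen follows it
  resp_on <- c(ev$onset + ev$dur_cue, ev$onset + ev$dur_cue + ev$dur_context_resp)
  resp_dur <- c(ev$dur_context_resp, ev$dur_scene_resp)
  resp_grp <- if (response_windows == "joint") {
    rep("response", 2 * nrow(ev))
  } else {
    rep(c("resp_context", "resp_scene"), each = nrow(ev))
  }
  resp <- hrf_design(resp_on, resp_dur, n_vol, tr, spec, groups = resp_grp)
  motion <- as.matrix(motion)
  if (nrow(motion) != n_vol) stop("motion rows must equal retained volumes")
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  spikes <- NULL
  if (length(flags) > 0) {
    spikes <- matrix(0, n_vol, length(flags))
    spikes[cbind(flags, seq_along(flags))] <- 1
    colnames(spikes) <- sprintf("spike_%03d", flags)
  }
  X <- cbind(target = target[, 1],
             if (!is.null(nuis)) nuis,
             resp, motion,
             if (!is.null(spikes)) spikes)
  colnames(X)[1] <- "target"
  keep <- colSums(abs(X)) > 0
  X <- X[, keep, drop = FALSE]
  structure(list(X = X, target_col = 1L,
                 cols = colnames(X), tr = tr), class = "lss_design")
}

#' Fit one LSS model
#'
#' Per-voxel ordinary least squares with an intercept appended; returns the
#' target column's beta and t map (t = beta / SE, SE from the residual
#' variance and the design Gram inverse). In zero-residual fits t is `Inf`
#' and the beta map should be used instead.
#'
#' @param Y Voxels x volumes data matrix.
#' @param design An `lss_design` from [build_lss_design()].
#' @return List of class `trial_tmap`: `beta`, `t` (per voxel), `df`
#'   (residual degrees of freedom), `rank`.
#' @export
lss_fit <- function(Y, design) {
  X <- cbind(design$X, intercept = 1)
  n <- nrow(X)
  if (ncol(Y) != n) stop("design rows must match number of volumes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    if (!1 %in% keep) stop("design rank-deficient at the target column")
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("dropping collinear columns: ", paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
  }
  coefs <- qr.coef(qrX, t(Y))                   # p x voxels
  fitted <- X %*% coefs
  res <- t(Y) - fitted
  df <- n - qrX$rank
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  j <- which(colnames(X) == "target")
  se <- sqrt(sigma2 * XtXinv[j, j])
  beta <- coefs[j, ]
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  structure(list(beta = beta, t = tval, df = df, rank = qrX$rank),
            class = "trial_tmap")
}

#' Estimate all trials of a set of runs
#'
#' Runs the full LSS loop: framewise displacement on each run's motion table,
#' one design and fit per trial, deterministic trial order. Encoding runs are
#' never modeled; input runs are retrieval runs.
#'
#' @param runs Named list, one element per run: `data` (voxels x volumes),
#'   `motion`, `events` (trial rows with onset/durations/grain/congruency),
#'   `tr`.
#' @param spec An [hrf_spec()].
#' @param use_beta Return beta maps instead of t maps as `pattern`.
#' @param fd_threshold Scrub threshold in mm.
#' @param ... Passed to [build_lss_design()].
#' @return List: `patterns` (voxels x trials matrix of t or beta values),
#'   `meta` (trial metadata incl. run), `fits` (per-trial `trial_tmap`s).
#' @export
estimate_all_trials <- function(runs, spec = hrf_spec(), use_beta = FALSE,
                                fd_threshold = 0.9, ...) {
  pats <- list(); metas <- list(); fits <- list()
  for (rn in seq_along(runs)) {
    run <- runs[[rn]]
    n_vol <- ncol(run$data)
    fd <- framewise_displacement(run$motion, threshold = fd_threshold)
    for (i in seq_len(nrow(run$events))) {
      des <- build_lss_design(run$events, i, run$motion, fd$flags, n_vol,
                              run$tr, spec, ...)
      fit <- tryCatch(lss_fit(run$data, des), error = function(e) {
        stop(sprintf("run %d trial %d: %s", rn, i, conditionMessage(e)))
      })
      pat <- if (use_beta) fit$beta else fit$t
      pats[[length(pats) + 1]] <- pat
      m <- run$events[i, , drop = FALSE]
      m$run <- rn
      metas[[length(metas) + 1]] <- m
      fits[[length(fits) + 1]] <- fit
    }
  }
  meta <- if (length(metas)) do.call(rbind, metas) else NULL
  if (!is.null(meta)) rownames(meta) <- NULL
  list(patterns = if (length(pats)) do.call(cbind, pats) else
    matrix(numeric(0), 0, 0), meta = meta, fits = fits)
}
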