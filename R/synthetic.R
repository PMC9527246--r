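# ---- synthetic cohorts with known ground truth -----------------------------

#' Default trial-outcome probability table
#'
#' P(grain | operational congruency, delay). Values are a qualitative,
#' a-priori calibration to the published memory-quality pattern (congruent
#' retained better; coarse memory rising over the long delay for congruent
#' pairs only); they are artifact choices, not a fit to any data.
#'
#' @return Data.frame with columns `congruency`, `delay`, `p_detailed`,
#'   `p_coarse` (P(forgotten) is the remainder).
#' @export
default_prob_table <- function() {
  data.frame(
    congruency = rep(c("congruent", "incongruent"), each = 2),
    delay      = rep(c("short", "long"), 2),
    p_detailed = c(0.45, 0.27, 0.42, 0.30),
    p_coarse   = c(0.05, 0.14, 0.05, 0.06),
    stringsAsFactors = FALSE
  )
}

#' Default pattern-component weight table
#'
#' Per (ROI, congruency, delay): weights of the shared context, scene and
#' item components plus voxel noise SD in the trial-pattern generative model
#' `pattern = w_ctx*u_ctx + w_scene*u_scene + w_item*u_item + noise`.
#' Defaults encode the qualitative target structure: medial-prefrontal
#' context integration grows over the long delay for congruent pairs only;
#' anterior hippocampus gains context coding and posterior hippocampus gains
#' scene coding over the delay irrespective of congruency.
#'
#' @return Data.frame with columns `roi`, `congruency`, `delay`, `w_ctx`,
#'   `w_scene`, `w_item`, `noise_sd`.
#' @export
default_weight_table <- function() {
  g <- expand.grid(
    roi = c("mpfc", "ahipp", "phipp"),
    congruency = c("congruent", "incongruent"),
    delay = c("short", "long"),
    stringsAsFactors = FALSE
  )
  g$w_ctx <- 0.3
  g$w_ctx[g$roi == "mpfc" & g$congruency == "congruent" & g$delay == "long"] <- 0.6
  g$w_ctx[g$roi == "ahipp"] <- ifelse(g$delay[g$roi == "ahipp"] == "long", 0.5, 0.25)
  g$w_ctx[g$roi == "phipp"] <- 0.2
  g$w_scene <- 0.2
  g$w_scene[g$roi == "phipp" & g$delay == "long"] <- 0.5
  g$w_item <- 1
  g$noise_sd <- 1
  g
}

#' Cohort configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults state the
#' simulated world once: 23 participants in two counterbalancing groups
#' (10 A / 13 B), 300-voxel ROIs, the behavioral probability table of
#' [default_prob_table()], an encoding-judgment flip probability of 0.066
#' per run (implying ~81.6% all-three-runs consistency), and rest coupling
#' expressed on the Fisher-z scale with the post-minus-pre change linked to
#' the long-delay coarse-congruent memory score.
#'
#' @param n_participants Cohort size.
#' @param group_split Named vector, participants per counterbalancing group.
#' @param rois Named integer vector of ROI voxel counts.
#' @param prob_table See [default_prob_table()].
#' @param weight_table See [default_weight_table()].
#' @param encoding_flip_prob Per-run probability that an encoding judgment
#'   contradicts the pair's intended congruency.
#' @param coarse_dontknow_ratio Probability that a coarse trial's scene
#'   response is "don't know" rather than the similar same-context scene.
#' @param forgotten_dontknow_ratio Probability that a forgotten trial's
#'   context response is "don't know" rather than the wrong context.
#' @param bold BOLD noise spec: list(white_sd, ar1, drift_amp, tr).
#' @param rest Rest-coupling spec: list(pre_mean, pre_sd, delta_mean,
#'   delta_sd, beta, link_sd, score_ref, n_vol, n_trim, exact_corr,
#'   power_target). `beta` is Fisher-z change per percentage point of the
#'   long-delay coarse-congruent score.
#' @return A validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 23,
                          group_split = c(A = 10, B = 13),
                          rois = c(mpfc = 300, ahipp = 300, phipp = 300),
                          prob_table = default_prob_table(),
                          weight_table = default_weight_table(),
                          encoding_flip_prob = 0.066,
                          coarse_dontknow_ratio = 0.5,
                          forgotten_dontknow_ratio = 0.5,
                          bold = list(white_sd = 1, ar1 = 0.3, drift_amp = 0.5, tr = 1.5),
                          rest = list(pre_mean = 0.3, pre_sd = 0.1,
                                      delta_mean = 0.05, delta_sd = 0.0,
                                      beta = 0.015, link_sd = 0.05,
                                      score_ref = 14, n_vol = 240, n_trim = 6,
                                      exact_corr = TRUE, power_target = 0.75)) {
  if (sum(group_split) != n_participants) {
    stop("group_split must sum to n_participants")
  }
  p_rest <- 1 - prob_table$p_detailed - prob_table$p_coarse
  if (any(prob_table$p_detailed < 0 | prob_table$p_coarse < 0 | p_rest < -1e-12)) {
    stop("probabilities per (congruency, delay) cell must be in [0,1] and sum to <= 1")
  }
  if (any(weight_table$noise_sd <= 0)) stop("noise_sd must be > 0")
  if (any(rois < 10)) stop("ROIs need at least 10 voxels")
  structure(list(
    n_participants = n_participants, group_split = group_split, rois = rois,
    prob_table = prob_table, weight_table = weight_table,
    encoding_flip_prob = encoding_flip_prob,
    coarse_dontknow_ratio = coarse_dontknow_ratio,
    forgotten_dontknow_ratio = forgotten_dontknow_ratio,
    bold = bold, rest = rest
  ), class = "cohort_config")
}

.participant_ids <- function(config) {
  sprintf("sub%02d", seq_len(config$n_participants))
}

.participant_groups <- function(config) {
  rep(names(config$group_split), config$group_split)
}

#' Simulate cohort behavior
#'
#' For each participant: builds the two stimulus lists and retrieval
#' schedules, simulates the three encoding judgments per pair (intended
#' congruency flipped with `encoding_flip_prob` per run), operationalizes
#' congruency, draws each retrieval trial's memory grain from
#' P(grain | operational congruency, delay), and constructs context/scene
#' responses consistent with the drawn grain.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the full cohort is reproducible from it.
#' @return List with `outcomes` (trial-level data.frame), `judgments`
#'   (per pair x run), `scores` (from [compute_scores()]), and `truth`
#'   (the generator's grain draw per trial, for recovery tests).
#' @export
simulate_behavior <- function(config, seed = 1L) {
  ids <- .participant_ids(config)
  groups <- .participant_groups(config)
  sc <- scene_table()
  all_out <- vector("list", length(ids))
  all_jdg <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rng <- .local_rng(seed * 1000L + i)
    pool <- make_object_pool()
    lists <- make_stimulus_lists(pool, seed = seed * 1000L + i)
    per_delay <- lapply(c(short = "short", long = "long"), function(d) {
      lst <- lists[[d]]
      sched <- make_retrieval_schedule(lst, seed = seed * 1000L + i +
                                         ifelse(d == "short", 0L, 500000L))
      # encoding judgments: intended congruency, flipped per run with p
      intended_rel <- lst$intended_congruency == "congruent"
      flips <- matrix(rng$runif(3 * nrow(lst)) < config$encoding_flip_prob, ncol = 3)
      jdg <- matrix(ifelse(xor(intended_rel, flips), "related", "unrelated"), ncol = 3)
      op <- operationalize_congruency(jdg)
      names(op) <- lst$object_id
      # grain per trial from the probability table
      pt <- config$prob_table[config$prob_table$delay == d, ]
      probs <- pt[match(op[sched$object_id], pt$congruency), c("p_detailed", "p_coarse")]
      u <- rng$runif(nrow(sched))
      grain <- ifelse(u < probs$p_detailed, "detailed",
                      ifelse(u < probs$p_detailed + probs$p_coarse, "coarse", "forgotten"))
      # responses consistent with grain
      true_ctx <- sched$context
      true_scene <- sched$scene_id
      other_scene_same_ctx <- vapply(true_scene, function(s) {
        cand <- sc$scene_id[sc$context == sc$context[sc$scene_id == s]]
        cand[cand != s]
      }, character(1))
      ctx_resp <- true_ctx
      scn_resp <- true_scene
      is_coarse <- grain == "coarse"
      dk <- rng$runif(nrow(sched)) < config$coarse_dontknow_ratio
      scn_resp[is_coarse] <- ifelse(dk[is_coarse], "dont_know",
                                    other_scene_same_ctx[is_coarse])
      is_forg <- grain == "forgotten"
      dk2 <- rng$runif(nrow(sched)) < config$forgotten_dontknow_ratio
      wrong_ctx <- ifelse(true_ctx == "beach", "kitchen", "beach")
      ctx_resp[is_forg] <- ifelse(dk2[is_forg], "dont_know", wrong_ctx[is_forg])
      scn_resp[is_forg] <- ifelse(dk2[is_forg], "absent", "dont_know")
      out <- data.frame(
        participant = ids[i], group = groups[i], delay = d,
        run_index = sched$run_index, trial_index = sched$trial_index,
        onset = sched$onset, object_id = sched$object_id,
        scene_id = sched$scene_id, context = sched$context,
        intended_congruency = sched$intended_congruency,
        congruency = unname(op[sched$object_id]),
        context_response = ctx_resp, scene_response = scn_resp,
        grain_truth = grain, stringsAsFactors = FALSE
      )
      jd <- data.frame(participant = ids[i], delay = d, object_id = lst$object_id,
                       j1 = jdg[, 1], j2 = jdg[, 2], j3 = jdg[, 3],
                       stringsAsFactors = FALSE)
      list(out = out, jdg = jd)
    })
    all_out[[i]] <- rbind(per_delay$short$out, per_delay$long$out)
    all_jdg[[i]] <- rbind(per_delay$short$jdg, per_delay$long$jdg)
  }
  outcomes <- do.call(rbind, all_out)
  # score responses through the analysis path (must reproduce grain_truth)
  outcomes$grain <- classify_grain(outcomes$context_response,
                                   outcomes$scene_response,
                                   outcomes$scene_id)
  rownames(outcomes) <- NULL
  list(
    outcomes = outcomes,
    judgments = do.call(rbind, all_jdg),
    scores = compute_scores(outcomes),
    truth = outcomes[, c("participant", "delay", "object_id", "grain_truth")]
  )
}

#' Simulate trial-level ROI patterns
#'
#' Generative model: for each trial,
#' `pattern = w_ctx*u_ctx(context) + w_scene*u_scene(scene) +
#'  w_item*u_item(object) + noise`, with the component vectors drawn i.i.d.
#' standard normal per participant x ROI and fixed across trials, and weights
#' looked up by (operational congruency, delay, ROI). At large voxel counts
#' the expected Pearson correlation between two trials equals the ratio of
#' shared component variance to total variance.
#'
#' @param config A [cohort_config()].
#' @param outcomes Trial table from [simulate_behavior()].
#' @param roi ROI name (must be in `names(config$rois)`).
#' @param seed Integer seed.
#' @param n_voxels Optional override of the configured ROI size.
#' @return List: `patterns` (voxels x trials matrix) and `meta` (one row per
#'   trial: participant, delay, run_index, object_id, scene_id, context,
#'   congruency, grain, trial_id).
#' @export
simulate_trial_patterns <- function(config, outcomes, roi = "mpfc", seed = 1L,
                                    n_voxels = NULL) {
  if (!roi %in% names(config$rois)) stop("unknown ROI: ", roi)
  V <- if (is.null(n_voxels)) config$rois[[roi]] else n_voxels
  wt <- config$weight_table[config$weight_table$roi == roi, ]
  sc <- scene_table()
  if (!all(outcomes$scene_id %in% sc$scene_id)) stop("unknown scene label")
  if (!all(outcomes$context %in% sc$context)) stop("unknown context label")
  ids <- unique(outcomes$participant)
  mats <- vector("list", length(ids))
  metas <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rng <- .local_rng(seed * 1000L + 700L + i)
    oc <- outcomes[outcomes$participant == ids[i], ]
    u_ctx <- matrix(rng$rnorm(V * 2), V, dimnames = list(NULL, c("beach", "kitchen")))
    u_scene <- matrix(rng$rnorm(V * 4), V, dimnames = list(NULL, sc$scene_id))
    objs <- unique(oc$object_id)
    u_item <- matrix(rng$rnorm(V * length(objs)), V, dimnames = list(NULL, objs))
    cong <- ifelse(is.na(oc$congruency), "incongruent", oc$congruency)
    wrow <- match(paste(cong, oc$delay), paste(wt$congruency, wt$delay))
    noise <- matrix(rng$rnorm(V * nrow(oc)), V)
    pat <- u_ctx[, oc$context] * rep(wt$w_ctx[wrow], each = V) +
      u_scene[, oc$scene_id] * rep(wt$w_scene[wrow], each = V) +
      u_item[, oc$object_id] * rep(wt$w_item[wrow], each = V) +
      noise * rep(wt$noise_sd[wrow], each = V)
    meta <- oc[, c("participant", "delay", "run_index", "trial_index",
                   "object_id", "scene_id", "context", "congruency", "grain")]
    meta$roi <- roi
    meta$trial_id <- sprintf("%s_%s_run%d_t%02d", ids[i], oc$delay,
                             oc$run_index, oc$trial_index)
    colnames(pat) <- meta$trial_id
    mats[[i]] <- pat
    metas[[i]] <- meta
  }
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  list(patterns = do.call(cbind, mats), meta = meta)
}

#' Simulate one BOLD run
#'
#' Per-voxel signal is the sum over trials of the trial's per-voxel amplitude
#' times an HRF-convolved boxcar at the trial's cue onset, plus AR(1) noise
#' and a slow polynomial drift. The motion table is a small random walk with
#' optional injected translation spikes that exceed the framewise-displacement
#' scrub threshold.
#'
#' @param schedule One run's rows of a retrieval schedule.
#' @param amplitudes Voxels x trials matrix of ground-truth amplitudes
#'   (columns follow the schedule's trial order).
#' @param config A [cohort_config()] (uses `config$bold`).
#' @param seed Integer seed.
#' @param n_spikes Number of injected motion spikes (default 1).
#' @param spike_mm Spike magnitude in mm (default 1.2, above the 0.9 FD
#'   threshold).
#' @param duration Optional run duration in seconds (default: schedule end
#'   plus 20 s of washout).
#' @return List: `data` (voxels x volumes), `motion` (volumes x 6), `tr`,
#'   `spike_volumes` (ground truth), `regressors` (volumes x trials
#'   HRF-convolved design used for generation).
#' @export
simulate_bold_run <- function(schedule, amplitudes, config, seed = 1L,
                              n_spikes = 1L, spike_mm = 1.2, duration = NULL) {
  b <- config$bold
  tr <- b$tr
  onsets <- schedule$onset
  dur_trial <- schedule$dur_cue
  end_need <- max(onsets + dur_trial)
  duration <- if (is.null(duration)) end_need + 20 else duration
  if (duration < end_need) stop("run too short for schedule")
  n_vol <- ceiling(duration / tr)
  R <- hrf_design(onsets, rep(dur_trial, length(onsets)), n_vol, tr)
  rng <- .local_rng(seed)
  V <- nrow(amplitudes)
  stopifnot(ncol(amplitudes) == nrow(schedule))
  # AR(1) noise per voxel
  eps <- matrix(rng$rnorm(V * n_vol, sd = b$white_sd), V)
  if (b$ar1 != 0) {
    for (t in 2:n_vol) eps[, t] <- b$ar1 * eps[, t - 1] + eps[, t]
  }
  tt <- seq_len(n_vol) / n_vol
  drift <- b$drift_amp * outer(rng$rnorm(V), tt - mean(tt)) +
    b$drift_amp * outer(rng$rnorm(V), (tt - mean(tt))^2)
  Y <- amplitudes %*% t(R) + eps + drift
  motion <- cbind(matrix(rng$rnorm(n_vol * 3, sd = 0.01), n_vol),    # mm
                  matrix(rng$rnorm(n_vol * 3, sd = 1e-4), n_vol))    # rad
  motion <- apply(motion, 2, cumsum)
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  spike_volumes <- integer(0)
  if (n_spikes > 0) {
    spike_volumes <- sort(rng$pick(seq(2, n_vol - 1), n_spikes))
    for (s in spike_volumes) motion[seq(s, n_vol), "tx"] <-
      motion[seq(s, n_vol), "tx"] + spike_mm
  }
  list(data = Y, motion = motion, tr = tr, spike_volumes = spike_volumes,
       regressors = R)
}

#' Simulate a pre/post rest-series pair for one participant
#'
#' Two ROI time series share a latent signal. The pre-encoding Fisher-z
#' coupling is drawn from N(pre_mean, pre_sd^2); the post-minus-pre change is
#' `delta_mean + beta * (score - score_ref) + N(0, link_sd^2) +
#' N(0, delta_sd^2)`, linking connectivity change to the participant's
#' long-delay coarse-congruent memory score. With `exact_corr = TRUE`
#' (default) the raw series are constructed so their empirical Pearson
#' correlation equals the target exactly; band-limited analyses then perturb
#' it only through filtering.
#'
#' @param config A [cohort_config()] (uses `config$rest`).
#' @param score The participant's long-delay coarse-congruent percent score.
#' @param seed Integer seed.
#' @return List: `pre`, `post` (each a 2 x n_vol matrix, rows = ROIs),
#'   `z_pre_target`, `z_post_target`, `delta_target`.
#' @export
simulate_rest_pair <- function(config, score, seed = 1L) {
  rs <- config$rest
  rng <- .local_rng(seed)
  z_pre <- rs$pre_mean + rs$pre_sd * rng$rnorm(1)
  delta <- rs$delta_mean + rs$beta * (score - rs$score_ref) +
    rs$link_sd * rng$rnorm(1) + rs$delta_sd * rng$rnorm(1)
  z_post <- z_pre + delta
  make_series <- function(z_target) {
    r <- tanh(z_target)
    n <- rs$n_vol
    s <- rng$rnorm(n); e1 <- rng$rnorm(n); e2 <- rng$rnorm(n)
    if (isTRUE(rs$exact_corr)) {
      # construct y so the empirical Pearson correlation with x is exactly r
      norm01 <- function(v) {
        v <- v - mean(v)
        v / sqrt(sum(v^2) / (length(v) - 1))
      }
      x <- norm01(s)
      ey <- e2 - mean(e2)
      ey <- ey - x * sum(x * ey) / sum(x^2)
      ey <- norm01(ey)
      y <- r * x + sqrt(1 - r^2) * ey
      rbind(roi1 = x, roi2 = y)
    } else {
      c0 <- sqrt(max(r, 0))
      x <- c0 * s + sqrt(1 - c0^2) * e1
      y <- c0 * s + sqrt(1 - c0^2) * e2
      rbind(roi1 = x, roi2 = y)
    }
  }
  list(pre = make_series(z_pre), post = make_series(z_post),
       z_pre_target = z_pre, z_post_target = z_post, delta_target = delta)
}

#' Simulate a full cohort (behavior + rest coupling)
#'
#' Convenience orchestrator: behavioral outcomes and scores for all
#' participants, plus pre/post rest pairs for the first `n_rest` participants
#' (rest coupling is linked to each participant's long-delay
#' coarse-congruent score). Trial patterns and BOLD runs are generated on
#' demand via [simulate_trial_patterns()] / [simulate_bold_run()].
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param n_rest Number of participants with rest scans (default 17).
#' @return List: `behavior` (see [simulate_behavior()]), `rest` (per
#'   participant: series pair + targets), `rest_scores` (the linked scores).
#' @export
simulate_cohort <- function(config, seed = 1L, n_rest = 17L) {
  beh <- simulate_behavior(config, seed)
  ids <- .participant_ids(config)[seq_len(min(n_rest, config$n_participants))]
  sc <- beh$scores
  rest <- lapply(seq_along(ids), function(i) {
    s <- sc$coarse_pct[sc$participant == ids[i] & sc$delay == "long" &
                         sc$condition == "congruent"]
    s <- if (length(s) == 0 || is.na(s)) config$rest$score_ref else s
    out <- simulate_rest_pair(config, s, seed = seed * 1000L + 900L + i)
    out$participant <- ids[i]
    out$score <- s
    out
  })
  names(rest) <- ids
  list(behavior = beh,
       rest = rest,
       rest_scores = vapply(rest, `[[`, numeric(1), "score"))
}
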