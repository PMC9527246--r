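# ---- experiment design: stimulus lists and run schedules -------------------

#' Scene lookup table
#'
#' The four repeating background scenes: two beaches and two kitchens.
#'
#' @return A data.frame with columns `scene_id` and `context`.
#' @export
scene_table <- function() {
  data.frame(
    scene_id = c("BeachA", "BeachB", "KitchenA", "KitchenB"),
    context  = c("beach", "beach", "kitchen", "kitchen"),
    stringsAsFactors = FALSE
  )
}

#' Construct an object pool
#'
#' Builds the pool of unique objects from which the two stimulus lists are
#' drawn. Objects are either typical of one of the two schematic contexts or
#' neutral (typical of neither).
#'
#' @param n_beach,n_kitchen,n_neutral Number of beach-typical, kitchen-typical
#'   and neutral objects (defaults 60/60/40).
#' @return A data.frame with columns `object_id`, `object_type`.
#' @export
make_object_pool <- function(n_beach = 60, n_kitchen = 60, n_neutral = 40) {
  stopifnot(n_beach >= 0, n_kitchen >= 0, n_neutral >= 0)
  type <- rep(c("beach-typical", "kitchen-typical", "neutral"),
              times = c(n_beach, n_kitchen, n_neutral))
  data.frame(
    object_id = sprintf("obj%03d", seq_along(type)),
    object_type = type,
    stringsAsFactors = FALSE
  )
}

# per-list demand by object type for one 80-pair list
.list_demand <- c("beach-typical" = 30, "kitchen-typical" = 30, "neutral" = 20)

#' Build the two 80-pair stimulus lists
#'
#' Each delay (short/long) gets a list of 80 object-scene pairs: 40 congruent
#' (20 beach-typical objects on beaches, 20 kitchen-typical on kitchens) and
#' 40 incongruent (10 beach-typical and 10 neutral objects on kitchens,
#' 10 kitchen-typical and 10 neutral on beaches). Within a context the pairs
#' are split evenly between its two scenes, so each scene carries 20 pairs
#' per list (10 congruent, 10 incongruent). Objects are assigned
#' pseudo-randomly per seed and never reused across the two lists.
#'
#' @param pool Object pool from [make_object_pool()].
#' @param seed Integer seed controlling the assignment.
#' @return A named list with elements `short` and `long`, each a data.frame of
#'   `StimulusPair` rows: `object_id`, `object_type`, `scene_id`, `context`,
#'   `intended_congruency`, `delay_list`.
#' @export
make_stimulus_lists <- function(pool, seed = 1L) {
  counts <- table(factor(pool$object_type, names(.list_demand)))
  deficit <- 2 * .list_demand - as.numeric(counts)
  if (any(deficit > 0)) {
    bad <- names(.list_demand)[which.max(deficit)]
    stop(sprintf(
      "object pool too small: need %d '%s' objects for two lists, have %d",
      2 * .list_demand[[bad]], bad, sum(pool$object_type == bad)
    ))
  }
  if (anyDuplicated(pool$object_id)) stop("object_ids must be unique")

  rng <- .local_rng(seed)
  draw <- function(avail, n) {
    idx <- rng$sample(length(avail), n)
    list(take = avail[idx], left = avail[-idx])
  }
  by_type <- split(pool$object_id, pool$object_type)
  # shuffle within type once; lists consume from the front
  for (ty in names(by_type)) by_type[[ty]] <- by_type[[ty]][rng$sample(length(by_type[[ty]]))]

  one_list <- function(delay) {
    take <- function(ty, n) {
      ids <- by_type[[ty]][seq_len(n)]
      by_type[[ty]] <<- by_type[[ty]][-seq_len(n)]
      ids
    }
    # composition per the printed 20/20/10/10/10/10 table
    blocks <- list(
      list(ids = take("beach-typical", 20),   context = "beach",   cong = "congruent"),
      list(ids = take("kitchen-typical", 20), context = "kitchen", cong = "congruent"),
      list(ids = take("beach-typical", 10),   context = "kitchen", cong = "incongruent"),
      list(ids = take("neutral", 10),         context = "kitchen", cong = "incongruent"),
      list(ids = take("kitchen-typical", 10), context = "beach",   cong = "incongruent"),
      list(ids = take("neutral", 10),         context = "beach",   cong = "incongruent")
    )
    sc <- scene_table()
    rows <- lapply(blocks, function(b) {
      scenes <- sc$scene_id[sc$context == b$context]
      n <- length(b$ids)
      # even split between the two scenes of the context, randomized order
      assign <- rep(scenes, each = n / 2)[rng$sample(n)]
      data.frame(object_id = b$ids, scene_id = assign, context = b$context,
                 intended_congruency = b$cong, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$object_type <- pool$object_type[match(out$object_id, pool$object_id)]
    out$delay_list <- delay
    out[rng$sample(nrow(out)), c("object_id", "object_type", "scene_id",
                                 "context", "intended_congruency", "delay_list")]
  }
  short <- one_list("short")
  long <- one_list("long")
  rownames(short) <- rownames(long) <- NULL
  list(short = short, long = long)
}

# Counter-based RNG wrapper: keeps all design randomness on an isolated stream
# so callers' .Random.seed is never touched.
.local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      })
      f(...)
    }
  }
  list(
    sample  = with_state(function(n, size = n) sample.int(n, size)),
    runif   = with_state(stats::runif),
    rnorm   = with_state(stats::rnorm),
    pick    = with_state(function(x, n = 1, replace = FALSE, prob = NULL) {
      x[sample.int(length(x), n, replace = replace, prob = prob)]
    })
  )
}

#' Encoding-run schedules
#'
#' Produces `n_runs` encoding runs, each presenting all pairs of the list once
#' in a pseudo-random order in which adjacent trials never share a scene.
#' Orders are drawn by rejection resampling (up to `max_attempts` full
#' permutations) followed by a deterministic repair pass that swaps each
#' offending trial with the nearest position where the swap is legal.
#'
#' Per-trial timing: 0.1 s scene alone, 2 s object overlay, 1 s response
#' window, then a jittered fixation of 1, 1.5 or 2 s.
#'
#' @param stim_list One stimulus list (data.frame of pairs).
#' @param n_runs Number of encoding runs (default 3).
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling cap before the repair pass runs.
#' @return A data.frame of trial rows with phase, run/trial indices, onset and
#'   component durations plus the pair labels.
#' @export
make_encoding_schedule <- function(stim_list, n_runs = 3, seed = 1L,
                                   max_attempts = 100L) {
  if (nrow(stim_list) == 0) stop("stimulus list is empty")
  rng <- .local_rng(seed + 1000L)
  runs <- lapply(seq_len(n_runs), function(r) {
    ord <- NULL
    for (a in seq_len(max_attempts)) {
      cand <- rng$sample(nrow(stim_list))
      if (!any(stim_list$scene_id[cand][-1] ==
               stim_list$scene_id[cand][-length(cand)])) {
        ord <- cand
        break
      }
    }
    if (is.null(ord)) ord <- .repair_adjacency(cand, stim_list$scene_id)
    sc <- stim_list$scene_id[ord]
    if (any(sc[-1] == sc[-length(sc)])) {
      stop("could not schedule encoding run without same-scene adjacency")
    }
    jitter <- rng$pick(c(1, 1.5, 2), length(ord), replace = TRUE)
    dur <- 0.1 + 2 + 1
    onset <- cumsum(c(0, (dur + jitter)[-length(ord)]))
    data.frame(
      phase = "encoding", run_index = r, trial_index = seq_along(ord),
      onset = onset, dur_scene = 0.1, dur_overlay = 2, dur_response = 1,
      dur_jitter = jitter,
      stim_list[ord, c("object_id", "scene_id", "context", "intended_congruency")],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out
}

# Deterministic repair: walk the order; where scene[i] == scene[i-1], swap
# position i with the nearest position j (by |j - i|, later first on ties)
# such that both endpoints are legal after the swap.
.repair_adjacency <- function(ord, scene) {
  n <- length(ord)
  sc <- scene[ord]
  # adjacent pairs touched by swapping positions i and j
  touched <- function(i, j) {
    p <- c(i - 1, i, j - 1, j)
    unique(p[p >= 1 & p < n])
  }
  violated <- function(s, p) s[p] == s[p + 1]
  # a swap is acceptable if it fixes the violation at (i-1, i) and creates
  # no new violation among the touched pairs; violations elsewhere are
  # handled by later iterations of the scan
  acceptable <- function(i, j) {
    s <- sc
    tmp <- s[i]; s[i] <- s[j]; s[j] <- tmp
    p <- touched(i, j)
    if (violated(s, i - 1)) return(FALSE)
    all(!violated(s, p) | violated(sc, p))
  }
  for (i in seq(2, n)) {
    if (sc[i] != sc[i - 1]) next
    cand <- setdiff(order(abs(seq_len(n) - i), -(seq_len(n))), i)
    done <- FALSE
    for (j in cand) {
      if (sc[j] == sc[i]) next
      if (acceptable(i, j)) {
        tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
        tmp <- sc[i]; sc[i] <- sc[j]; sc[j] <- tmp
        done <- TRUE
        break
      }
    }
    if (!done) stop("adjacency repair failed: no legal swap position")
  }
  # the forward scan can leave a violation only if no acceptable swap
  # existed at some position; verify and fail loudly rather than return bad
  if (any(sc[-1] == sc[-n])) stop("adjacency repair failed to converge")
  ord
}

#' Cued-retrieval schedules
#'
#' Tests each pair exactly once, split evenly across `n_runs` runs in a random
#' order. Per-trial timing: 2 s object cue, 2 s context-response window, 2 s
#' scene-response window (shown only after a kitchen/beach context choice; the
#' slot is scheduled and marked usable downstream), then 3-6 s jittered
#' fixation in 0.5 s steps.
#'
#' @inheritParams make_encoding_schedule
#' @param n_runs Number of retrieval runs (default 4).
#' @return A data.frame of trial rows as in [make_encoding_schedule()], with
#'   durations `dur_cue`, `dur_context_resp`, `dur_scene_resp`, `dur_jitter`.
#' @export
make_retrieval_schedule <- function(stim_list, n_runs = 4, seed = 1L) {
  n <- nrow(stim_list)
  if (n == 0) stop("stimulus list is empty")
  if (n %% n_runs != 0) {
    stop(sprintf("list size %d not divisible by n_runs = %d", n, n_runs))
  }
  rng <- .local_rng(seed + 2000L)
  per_run <- n / n_runs
  ord <- rng$sample(n)
  runs <- lapply(seq_len(n_runs), function(r) {
    idx <- ord[seq.int((r - 1) * per_run + 1, r * per_run)]
    jitter <- rng$pick(seq(3, 6, by = 0.5), per_run, replace = TRUE)
    dur <- 2 + 2 + 2
    onset <- cumsum(c(0, (dur + jitter)[-per_run]))
    data.frame(
      phase = "retrieval", run_index = r, trial_index = seq_len(per_run),
      onset = onset, dur_cue = 2, dur_context_resp = 2, dur_scene_resp = 2,
      dur_jitter = jitter,
      stim_list[idx, c("object_id", "scene_id", "context", "intended_congruency")],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out
}

#' Export a schedule as BIDS-style events tables
#'
#' Writes one TSV per run with columns `onset`, `duration`, `trial_type`,
#' `object_id`, `scene_id`, `context`, `congruency_intended`.
#'
#' @param schedule A schedule from [make_encoding_schedule()] or
#'   [make_retrieval_schedule()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_events_tsv <- function(schedule, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dur <- if (schedule$phase[1] == "encoding") {
    schedule$dur_scene + schedule$dur_overlay + schedule$dur_response
  } else {
    schedule$dur_cue + schedule$dur_context_resp + schedule$dur_scene_resp
  }
  ev <- data.frame(
    onset = schedule$onset, duration = dur, trial_type = schedule$phase,
    object_id = schedule$object_id, scene_id = schedule$scene_id,
    context = schedule$context,
    congruency_intended = schedule$intended_congruency
  )
  paths <- vapply(split(seq_len(nrow(ev)), schedule$run_index), function(i) {
    p <- file.path(dir, sprintf("%s_run-%02d_events.tsv",
                                schedule$phase[1], schedule$run_index[i[1]]))
    utils::write.table(ev[i, ], p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
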