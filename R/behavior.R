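# ---- behavioral scoring: congruency, memory grain, exclusions --------------

#' Operationalize congruency from encoding judgments
#'
#' Each pair is judged related/unrelated on each of the three encoding runs;
#' the pair counts as congruent when at least two judgments are "related".
#' Pairs with more than one missing judgment are indeterminate (`NA`) and are
#' dropped from condition totals by downstream scoring.
#'
#' @param judgments Character vector of length 3 (one per encoding run) with
#'   values in `related`, `unrelated`, `missing`; or a matrix/data.frame with
#'   3 columns, one row per pair.
#' @return `"congruent"`, `"incongruent"`, or `NA` (vectorized over rows).
#' @export
operationalize_congruency <- function(judgments) {
  j <- if (is.null(dim(judgments))) matrix(judgments, nrow = 1) else as.matrix(judgments)
  if (ncol(j) != 3) stop("exactly one judgment per encoding run (3) required")
  bad <- !j %in% c("related", "unrelated", "missing")
  if (any(bad)) stop("judgments must be 'related', 'unrelated' or 'missing'")
  n_missing <- rowSums(j == "missing")
  n_related <- rowSums(j == "related")
  out <- ifelse(n_related >= 2, "congruent", "incongruent")
  out[n_missing > 1] <- NA_character_
  out
}

#' Classify a retrieval trial's memory grain
#'
#' Detailed: correct context and correct specific scene. Coarse: correct
#' context but the scene response was "don't know" or the other (visually
#' similar) scene of the same context. Everything else — wrong context or
#' "don't know" context — is forgotten. A missing response is treated as
#' "don't know".
#'
#' @param context_response `"kitchen"`, `"beach"` or `"dont_know"` (vectorized).
#' @param scene_response Scene id, `"dont_know"`, or `"absent"` when no scene
#'   window was offered (i.e., after a "don't know" context response).
#' @param true_scene True scene id (e.g., `"BeachA"`).
#' @return Character vector in `detailed`, `coarse`, `forgotten`.
#' @export
classify_grain <- function(context_response, scene_response, true_scene) {
  sc <- scene_table()
  if (!all(true_scene %in% sc$scene_id)) stop("unknown true_scene id")
  context_response[is.na(context_response)] <- "dont_know"
  scene_response[is.na(scene_response)] <- "dont_know"
  true_context <- sc$context[match(true_scene, sc$scene_id)]
  no_context <- context_response == "dont_know"
  if (any(!no_context & scene_response == "absent")) {
    # scene window exists exactly when a context was chosen
    stop("scene_response 'absent' recorded for a trial with a context choice")
  }
  if (any(no_context & !scene_response %in% c("absent", "dont_know"))) {
    stop("scene_response recorded for a trial where no scene window was offered")
  }
  ctx_ok <- context_response == true_context
  scene_ok <- scene_response == true_scene
  same_ctx_scene <- scene_response %in% sc$scene_id &
    sc$context[match(scene_response, sc$scene_id)] == true_context
  out <- rep("forgotten", length(context_response))
  out[ctx_ok & (scene_response == "dont_know" | (same_ctx_scene & !scene_ok))] <- "coarse"
  out[ctx_ok & scene_ok] <- "detailed"
  out
}

#' Per-participant memory scores
#'
#' Computes, for each participant x delay x operational-congruency cell, the
#' percent of that condition's trials retrieved as detailed, coarse, and their
#' sum (total percent correct, i.e., context retrieved regardless of scene).
#' Trials with indeterminate congruency are excluded from denominators.
#'
#' @param outcomes Data.frame with columns `participant`, `delay`,
#'   `congruency` (operational; may contain `NA`), `grain`.
#' @return Data.frame with `participant`, `delay`, `condition`, `n_trials`,
#'   `detailed_pct`, `coarse_pct`, `total_pct`. Empty cells are emitted with
#'   `n_trials = 0` and `NA` scores.
#' @export
compute_scores <- function(outcomes) {
  stopifnot(all(c("participant", "delay", "congruency", "grain") %in% names(outcomes)))
  oc <- outcomes[!is.na(outcomes$congruency), ]
  cells <- expand.grid(
    participant = unique(outcomes$participant),
    delay = unique(outcomes$delay),
    condition = c("congruent", "incongruent"),
    stringsAsFactors = FALSE
  )
  cells <- cells[order(cells$participant, cells$delay, cells$condition), ]
  res <- mapply(function(p, d, cond) {
    g <- oc$grain[oc$participant == p & oc$delay == d & oc$congruency == cond]
    n <- length(g)
    if (n == 0) return(c(0, NA, NA, NA))
    det <- 100 * sum(g == "detailed") / n
    coa <- 100 * sum(g == "coarse") / n
    c(n, det, coa, det + coa)
  }, cells$participant, cells$delay, cells$condition)
  cells$n_trials <- res[1, ]
  cells$detailed_pct <- res[2, ]
  cells$coarse_pct <- res[3, ]
  cells$total_pct <- res[4, ]
  rownames(cells) <- NULL
  cells
}

#' Apply the below-chance exclusion rule
#'
#' A participant whose total percent correct at a delay — pooled over both
#' congruency conditions — is strictly below `threshold` (chance = 33%, three
#' context options) loses that delay's data only; the other delay is retained.
#'
#' @param outcomes Trial-level outcomes (as for [compute_scores()]); the
#'   pooled total is computed from these.
#' @param scores Optional score table from [compute_scores()] to filter.
#' @param threshold Exclusion threshold in percent (default 33; strict `<`).
#' @return A list with `outcomes` (filtered), `scores` (filtered, or `NULL`),
#'   and `log`: data.frame of excluded (participant, delay, pooled_total).
#' @export
apply_exclusions <- function(outcomes, scores = NULL, threshold = 33) {
  oc <- outcomes[!is.na(outcomes$congruency), ]
  key <- paste(oc$participant, oc$delay, sep = "\r")
  pooled <- tapply(oc$grain != "forgotten", key, function(x) 100 * mean(x))
  parts <- do.call(rbind, strsplit(names(pooled), "\r", fixed = TRUE))
  log <- data.frame(participant = parts[, 1], delay = parts[, 2],
                    pooled_total = as.numeric(pooled),
                    stringsAsFactors = FALSE)
  log <- log[log$pooled_total < threshold, , drop = FALSE]
  rownames(log) <- NULL
  drop_key <- paste(log$participant, log$delay)
  keep_out <- !paste(outcomes$participant, outcomes$delay) %in% drop_key
  out <- list(outcomes = outcomes[keep_out, , drop = FALSE], scores = NULL, log = log)
  if (!is.null(scores)) {
    keep_sc <- !paste(scores$participant, scores$delay) %in% drop_key
    out$scores <- scores[keep_sc, , drop = FALSE]
  }
  out
}

#' Encoding-judgment consistency
#'
#' Percent of pairs judged identically on all three encoding runs (the strict
#' reading); `mode = "pairwise"` instead averages agreement over the three
#' run pairs. Pairs with any missing judgment are excluded from the
#' denominator.
#'
#' @param judgments Matrix/data.frame, 3 columns (runs), one row per pair.
#' @param mode `"all3"` (default) or `"pairwise"`.
#' @return Percent consistent, scalar.
#' @export
judgment_consistency <- function(judgments, mode = c("all3", "pairwise")) {
  mode <- match.arg(mode)
  j <- as.matrix(judgments)
  if (ncol(j) != 3) stop("3 judgments per pair required")
  ok <- rowSums(j == "missing") == 0
  j <- j[ok, , drop = FALSE]
  if (nrow(j) == 0) return(NA_real_)
  if (mode == "all3") {
    100 * mean(j[, 1] == j[, 2] & j[, 2] == j[, 3])
  } else {
    100 * mean((as.numeric(j[, 1] == j[, 2]) + (j[, 1] == j[, 3]) + (j[, 2] == j[, 3])) / 3)
  }
}
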