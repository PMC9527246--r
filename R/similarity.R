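# ---- condition-paired pattern similarity -----------------------------------

.fisher_clip <- 1 - 1e-7

#' Fisher z transform with clipping
#'
#' `atanh(r)` with `|r|` clipped at `1 - 1e-7` so z stays finite; an
#' attribute marks whether clipping occurred.
#'
#' @param r Pearson correlation(s).
#' @return Fisher-z value(s); attribute `clipped` is a logical vector.
#' @export
fisher_z <- function(r) {
  clipped <- abs(r) > .fisher_clip
  z <- atanh(pmin(pmax(r, -.fisher_clip), .fisher_clip))
  attr(z, "clipped") <- clipped
  z
}

#' Z-score a pattern vector
#'
#' Centers and scales across voxels using the population SD, so the result
#' has mean 0 and population SD 1. Constant vectors are an error (callers
#' flag and exclude such trials).
#'
#' @param x Numeric vector (length >= 2).
#' @return Z-scored vector.
#' @export
zscore_pattern <- function(x) {
  if (length(x) < 2) stop("pattern must have at least 2 voxels")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0 || !is.finite(s)) stop("constant or non-finite pattern vector")
  (x - mean(x)) / s
}

# z-score all columns; returns matrix plus index of degenerate columns
.zscore_columns <- function(patterns, axis = c("voxel", "trial")) {
  axis <- match.arg(axis)
  if (axis == "trial") {
    # across-trial per-voxel normalization (alternative mode)
    mu <- rowMeans(patterns)
    sd <- sqrt(rowMeans((patterns - mu)^2))
    sd[sd == 0] <- NA
    out <- (patterns - mu) / sd
    return(list(z = out, bad = integer(0)))
  }
  mu <- colMeans(patterns)
  ctr <- sweep(patterns, 2, mu)
  s <- sqrt(colMeans(ctr^2))
  bad <- which(s == 0 | !is.finite(s))
  s[s == 0] <- NA
  list(z = sweep(ctr, 2, s, "/"), bad = bad)
}

#' Admissible pairs for the congruency (context) scheme
#'
#' Every trial with the context correctly retrieved (coarse or detailed) is
#' paired with every other such trial of the *same* operational congruency,
#' the same participant, ROI and delay, from a *different* run. Pairs are
#' labeled `within` when the two trials share the schematic context and
#' `across` otherwise. Cross-congruency pairs are never formed.
#'
#' @param meta Trial metadata (one row per pattern column): `participant`,
#'   `delay`, `run_index`, `context`, `scene_id`, `congruency`, `grain`.
#' @param grains Grains eligible for pairing (default coarse + detailed; use
#'   `"forgotten"` for the forgotten-trial control variant).
#' @return Data.frame of pair stubs: `i`, `j` (column indices into the
#'   pattern matrix), `participant`, `delay`, `congruency`, `pair_label`,
#'   `run_i`, `run_j`, `scheme`.
#' @export
pair_scheme_congruency <- function(meta, grains = c("coarse", "detailed")) {
  keep <- which(meta$grain %in% grains & !is.na(meta$congruency))
  .build_pairs(meta, keep, function(m, a, b) {
    ifelse(m$context[a] == m$context[b], "within", "across")
  }, scheme = if (identical(grains, "forgotten")) "congruency-forgotten" else "congruency")
}

#' Admissible pairs for the scene-granularity scheme
#'
#' Restricted to detailed trials (context and specific scene both correct).
#' Same-congruency, same-participant/delay, cross-run pairs labeled
#' `same` (identical scene), `similar` (the other scene of the same
#' context), or `other` (a scene of the opposing context). The three labels
#' partition all admissible pairs.
#'
#' @inheritParams pair_scheme_congruency
#' @export
pair_scheme_granularity <- function(meta, grains = "detailed") {
  keep <- which(meta$grain %in% grains & !is.na(meta$congruency))
  .build_pairs(meta, keep, function(m, a, b) {
    ifelse(m$scene_id[a] == m$scene_id[b], "same",
           ifelse(m$context[a] == m$context[b], "similar", "other"))
  }, scheme = if (identical(grains, "forgotten")) "granularity-forgotten" else "granularity")
}

.build_pairs <- function(meta, keep, label_fun, scheme) {
  if (length(keep) < 2) {
    return(data.frame(i = integer(0), j = integer(0), participant = character(0),
                      delay = character(0), congruency = character(0),
                      pair_label = character(0), run_i = integer(0),
                      run_j = integer(0), scheme = character(0)))
  }
  grp <- paste(meta$participant[keep], meta$delay[keep], meta$congruency[keep],
               sep = "\r")
  res <- lapply(split(keep, grp), function(idx) {
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    a <- cmb[1, ]; b <- cmb[2, ]
    ok <- meta$run_index[a] != meta$run_index[b]
    a <- a[ok]; b <- b[ok]
    if (length(a) == 0) return(NULL)
    data.frame(i = a, j = b, participant = meta$participant[a],
               delay = meta$delay[a], congruency = meta$congruency[a],
               pair_label = label_fun(meta, a, b),
               run_i = meta$run_index[a], run_j = meta$run_index[b],
               scheme = scheme, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(i = integer(0), j = integer(0), participant = character(0),
                      delay = character(0), congruency = character(0),
                      pair_label = character(0), run_i = integer(0),
                      run_j = integer(0), scheme = character(0)))
  }
  rownames(out) <- NULL
  out
}

#' Compute pairwise similarities for pair stubs
#'
#' Z-scores each pattern column (within-vector across voxels by default),
#' computes Pearson correlations for the requested pairs, and Fisher
#' transforms them with clipping. Degenerate (constant) patterns are
#' excluded and their pairs dropped, with the exclusions reported.
#'
#' @param stubs Pair stubs from a `pair_scheme_*` function.
#' @param patterns Voxels x trials matrix (columns indexed by `stubs$i/j`).
#' @param zscore_axis `"voxel"` (within-vector, default) or `"trial"`
#'   (across-trial per-voxel mode).
#' @return The stubs with `r` and `z` columns appended; attribute
#'   `excluded_trials` lists dropped pattern columns.
#' @export
compute_similarities <- function(stubs, patterns, zscore_axis = c("voxel", "trial")) {
  zscore_axis <- match.arg(zscore_axis)
  zs <- .zscore_columns(patterns, axis = if (zscore_axis == "voxel") "voxel" else "trial")
  if (length(zs$bad) > 0) {
    drop <- stubs$i %in% zs$bad | stubs$j %in% zs$bad
    stubs <- stubs[!drop, , drop = FALSE]
  }
  if (nrow(stubs) == 0) {
    stubs$r <- numeric(0); stubs$z <- numeric(0)
    attr(stubs, "excluded_trials") <- zs$bad
    return(stubs)
  }
  Z <- zs$z
  V <- nrow(Z)
  # Pearson r between z-scored (pop-sd) columns is the mean cross product
  r <- colSums(Z[, stubs$i, drop = FALSE] * Z[, stubs$j, drop = FALSE]) / V
  if (zscore_axis == "trial") {
    # across-trial mode does not normalize columns; fall back to cor()
    r <- vapply(seq_len(nrow(stubs)), function(k) {
      stats::cor(Z[, stubs$i[k]], Z[, stubs$j[k]])
    }, numeric(1))
  }
  stubs$r <- as.numeric(r)
  z <- fisher_z(stubs$r)
  stubs$z <- as.numeric(z)
  stubs$clipped <- attr(z, "clipped")
  attr(stubs, "excluded_trials") <- zs$bad
  stubs
}

#' Mean activation over an ROI
#'
#' Univariate control: the mean of a trial's t-map (or beta-map) over the
#' ROI's voxels.
#'
#' @param tmap Numeric vector of per-voxel values for one trial.
#' @param roi_voxels Integer indices of the ROI's voxels (default: all).
#' @return Scalar mean.
#' @export
univariate_mean <- function(tmap, roi_voxels = seq_along(tmap)) {
  if (length(roi_voxels) == 0) stop("empty ROI")
  mean(tmap[roi_voxels])
}

#' Long-format similarity table
#'
#' Convenience wrapper: builds pair stubs for a scheme and computes r/z,
#' returning the long-format table consumed by the stats module.
#'
#' @param patterns,meta From [simulate_trial_patterns()] or
#'   [estimate_all_trials()] (with matching metadata).
#' @param scheme `"congruency"`, `"granularity"`, or their
#'   `"-forgotten"` variants.
#' @param zscore_axis Passed to [compute_similarities()].
#' @return Data.frame with pair labels and Fisher-z similarities.
#' @export
similarity_table <- function(patterns, meta,
                             scheme = c("congruency", "granularity",
                                        "congruency-forgotten",
                                        "granularity-forgotten"),
                             zscore_axis = "voxel") {
  scheme <- match.arg(scheme)
  stubs <- switch(scheme,
    "congruency" = pair_scheme_congruency(meta),
    "granularity" = pair_scheme_granularity(meta),
    "congruency-forgotten" = pair_scheme_congruency(meta, grains = "forgotten"),
    "granularity-forgotten" = pair_scheme_granularity(meta, grains = "forgotten")
  )
  compute_similarities(stubs, patterns, zscore_axis = zscore_axis)
}
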