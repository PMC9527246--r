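# ---- mixed models, EMMs, contrasts, assumption rules -----------------------

#' Fit a linear mixed-effects model for memory or similarity data
#'
#' Restricted-maximum-likelihood fit of `response ~ f1 * f2 (* f3)` with a
#' random intercept for each participant and a random adjustment for the
#' counterbalancing group. Fixed factors use sum-to-zero contrasts so the
#' term-wise F tests are orthogonal under balance. When `weights_by` is
#' given, the model is (re)fit with nlme so the residual variance can differ
#' across the levels of that factor (varIdent); the random structure is then
#' reduced to the participant intercept.
#'
#' Denominator degrees of freedom: Satterthwaite approximation is not
#' available in this build's backends, so F and t tests use the residual
#' (containment) df `n - rank(X)`, reported and labeled
#' `df_method = "containment"` — never silently substituted.
#'
#' @param data Data.frame.
#' @param response Response column name (numeric).
#' @param fixed Character vector of fixed-factor column names (crossed).
#' @param participant,group Grouping column names.
#' @param transform `"identity"` or `"sqrt"` (applied before fitting).
#' @param weights_by Optional column name whose levels get separate residual
#'   variances (switches the backend to nlme).
#' @param group_random Include the counterbalancing-group random term
#'   (lme4 backend only; default TRUE).
#' @return Object of class `schemasim_mm`.
#' @export
fit_mixed_model <- function(data, response, fixed,
                            participant = "participant", group = "group",
                            transform = c("identity", "sqrt"),
                            weights_by = NULL, group_random = TRUE) {
  transform <- match.arg(transform)
  stopifnot(all(c(response, fixed, participant) %in% names(data)))
  d <- data
  d$.y <- d[[response]]
  if (transform == "sqrt") {
    if (any(d$.y < 0, na.rm = TRUE)) stop("sqrt transform requires nonnegative response")
    d$.y <- sqrt(d$.y)
  }
  d <- d[stats::complete.cases(d[, c(".y", fixed, participant)]), , drop = FALSE]
  for (f in fixed) {
    d[[f]] <- factor(d[[f]])
    stats::contrasts(d[[f]]) <- stats::contr.sum(nlevels(d[[f]]))
  }
  d[[participant]] <- factor(d[[participant]])
  has_group <- group %in% names(d) && length(unique(d[[group]])) > 1
  fix_rhs <- paste(fixed, collapse = " * ")
  fixed_formula <- stats::as.formula(paste(".y ~", fix_rhs))
  X <- stats::model.matrix(fixed_formula, d)
  backend <- if (is.null(weights_by)) "lme4" else "nlme"
  if (backend == "lme4") {
    rand <- paste0("(1 | ", participant, ")")
    if (has_group && group_random) rand <- paste(rand, "+ (1 |", group, ")")
    form <- stats::as.formula(paste(".y ~", fix_rhs, "+", rand))
    fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                       control = lme4::lmerControl(
                                         check.conv.singular = "ignore",
                                         check.nobs.vs.nlev = "ignore",
                                         check.nobs.vs.nRE = "ignore",
                                         calc.derivs = FALSE)))
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    resid_vec <- stats::resid(fit)
    singular <- lme4::isSingular(fit)
  } else {
    stopifnot(weights_by %in% names(d))
    d$.wcell <- factor(d[[weights_by]])
    fit <- nlme::lme(fixed = fixed_formula,
                     random = stats::as.formula(paste("~ 1 |", participant)),
                     weights = nlme::varIdent(form = ~ 1 | .wcell),
                     data = d, method = "REML",
                     control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                                msMaxIter = 200))
    beta <- nlme::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    resid_vec <- stats::resid(fit, type = "response")
    singular <- FALSE
  }
  structure(list(
    fit = fit, backend = backend, data = d, response = response,
    fixed = fixed, participant = participant, group = group,
    transform = transform, weights_by = weights_by,
    beta = beta, V = V, X = X, assign = attr(X, "assign"),
    terms = attr(stats::terms(fixed_formula), "term.labels"),
    df = nrow(X) - qr(X)$rank, df_method = "containment",
    residuals = as.numeric(resid_vec), singular = singular
  ), class = "schemasim_mm")
}

#' Term-wise F tests
#'
#' Wald F test per fixed-effect term: `F = (Lb)'(LVL')^{-1}(Lb)/q` with `L`
#' selecting the term's sum-contrast coefficients, on (q, df_containment)
#' degrees of freedom.
#'
#' @param model A `schemasim_mm`.
#' @return Data.frame: `effect`, `F`, `df_num`, `df_den`, `p`, `df_method`.
#' @export
anova_table <- function(model) {
  rows <- lapply(seq_along(model$terms), function(k) {
    idx <- which(model$assign == k)
    L <- matrix(0, length(idx), length(model$beta))
    L[cbind(seq_along(idx), idx)] <- 1
    est <- L %*% model$beta
    Fval <- as.numeric(t(est) %*% solve(L %*% model$V %*% t(L)) %*% est) / length(idx)
    data.frame(effect = model$terms[k], F = Fval, df_num = length(idx),
               df_den = model$df,
               p = stats::pf(Fval, length(idx), model$df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$df_method <- model$df_method
  out
}

# fixed-effect design rows for a grid of factor combinations
.grid_matrix <- function(model, grid) {
  for (f in model$fixed) {
    grid[[f]] <- factor(grid[[f]], levels = levels(model$data[[f]]))
    stats::contrasts(grid[[f]]) <- stats::contr.sum(nlevels(grid[[f]]))
  }
  stats::model.matrix(stats::as.formula(
    paste("~", paste(model$fixed, collapse = " * "))), grid)
}

#' Estimated marginal means
#'
#' Cell predictions on the full factor grid, averaged with equal weight per
#' cell into the requested margins — the equal-cell-weight definition, which
#' estimates what the marginal means would be with equal trial numbers per
#' condition. Empty (non-observed) cells are still estimable from the model.
#'
#' @param model A `schemasim_mm`.
#' @param margins Character vector of factor names to retain (default: all
#'   fixed factors, i.e., the cell means).
#' @return Object of class `schemasim_emm`: data.frame of margins with
#'   `emmean`, `se`, `df`, plus attributes `L` (weight matrix) and `V`.
#' @export
emm_table <- function(model, margins = model$fixed) {
  stopifnot(all(margins %in% model$fixed))
  grid <- expand.grid(lapply(model$fixed, function(f) levels(model$data[[f]])),
                      stringsAsFactors = FALSE)
  names(grid) <- model$fixed
  Xg <- .grid_matrix(model, grid)
  key <- if (length(margins) > 0) {
    interaction(grid[, margins, drop = FALSE], drop = TRUE, lex.order = TRUE)
  } else factor(rep("overall", nrow(grid)))
  lev <- levels(key)
  L <- t(vapply(lev, function(l) {
    w <- as.numeric(key == l)
    colMeans(Xg[w == 1, , drop = FALSE])
  }, numeric(ncol(Xg))))
  est <- as.numeric(L %*% model$beta)
  se <- sqrt(diag(L %*% model$V %*% t(L)))
  out <- unique(grid[, margins, drop = FALSE])
  out <- out[order(interaction(out, drop = TRUE, lex.order = TRUE)), , drop = FALSE]
  res <- cbind(out, data.frame(emmean = est, se = se, df = model$df))
  rownames(res) <- NULL
  structure(res, L = L, V = model$V, df = model$df, class = c("schemasim_emm", "data.frame"))
}

#' Pairwise contrasts of estimated marginal means
#'
#' All pairwise differences between the EMM rows, with t tests on the
#' model's (containment) df and 95% confidence intervals.
#'
#' @param emm A `schemasim_emm` from [emm_table()].
#' @return Data.frame: `contrast`, `estimate`, `se`, `t`, `df`, `p`,
#'   `ci_lo`, `ci_hi`.
#' @export
pairwise_contrasts <- function(emm) {
  L <- attr(emm, "L"); V <- attr(emm, "V"); df <- attr(emm, "df")
  lab <- apply(emm[, setdiff(names(emm), c("emmean", "se", "df")), drop = FALSE],
               1, paste, collapse = ",")
  n <- nrow(emm)
  if (n < 2) stop("need at least two margins to contrast")
  cmb <- utils::combn(n, 2)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1, k]; j <- cmb[2, k]
    l <- L[i, ] - L[j, ]
    est <- emm$emmean[i] - emm$emmean[j]
    se <- sqrt(as.numeric(t(l) %*% V %*% l))
    tval <- if (se > 0) est / se else 0
    ci <- est + c(-1, 1) * stats::qt(0.975, df) * se
    data.frame(contrast = paste(lab[i], "-", lab[j]), estimate = est, se = se,
               t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residual assumption checks
#'
#' Shapiro-Wilk on the model residuals (deterministic evenly-spaced
#' subsample of 5000 when n exceeds the test's limit) and a Brown-Forsythe
#' (median-centered Levene) test of variance homogeneity across the cells of
#' the fixed factors.
#'
#' @param model A `schemasim_mm`.
#' @param alpha Decision threshold (default 0.05).
#' @return List: `normality` (`statistic`, `p`, `verdict`), `levene`
#'   (`F`, `df`, `p`, `verdict`), `recommend` (character: none, sqrt,
#'   weights, or both).
#' @export
assumption_checks <- function(model, alpha = 0.05) {
  r <- model$residuals
  rs <- if (length(r) > 5000) r[round(seq(1, length(r), length.out = 5000))] else r
  sw <- if (length(rs) >= 3) stats::shapiro.test(rs) else
    list(statistic = NA, p.value = NA)
  cells <- interaction(model$data[, model$fixed, drop = FALSE], drop = TRUE)
  lev <- if (nlevels(cells) > 1 && length(r) > nlevels(cells)) {
    z <- abs(r - stats::ave(r, cells, FUN = stats::median))
    a <- stats::anova(stats::lm(z ~ cells))
    list(F = a$`F value`[1], df = a$Df, p = a$`Pr(>F)`[1])
  } else list(F = NA, df = c(NA, NA), p = NA)
  norm_bad <- !is.na(sw$p.value) && sw$p.value < alpha
  het_bad <- !is.na(lev$p) && lev$p < alpha
  rec <- if (norm_bad && het_bad) "both" else if (norm_bad) "sqrt" else
    if (het_bad) "weights" else "none"
  list(
    normality = list(statistic = unname(sw$statistic), p = sw$p.value,
                     verdict = if (is.na(sw$p.value)) "untested" else
                       if (norm_bad) "non-normal" else "normal"),
    levene = list(F = lev$F, df = lev$df, p = lev$p,
                  verdict = if (is.na(lev$p)) "untested" else
                    if (het_bad) "heteroskedastic" else "homoskedastic"),
    recommend = rec
  )
}

#' Fit with the assumption-rule engine
#'
#' Deterministic state machine mirroring the analysis procedure: fit; if
#' residuals are non-normal, refit on the square-root-transformed response
#' and recheck; if Levene indicates heteroskedasticity, refit with per-level
#' residual variance weights (varIdent over the interaction of fixed
#' factors). Every step is logged.
#'
#' @inheritParams fit_mixed_model
#' @param alpha Threshold for the checks.
#' @return List: `model` (final `schemasim_mm`), `steps` (character log),
#'   `checks` (final check results).
#' @export
fit_with_rules <- function(data, response, fixed,
                           participant = "participant", group = "group",
                           alpha = 0.05, group_random = TRUE) {
  steps <- character(0)
  m <- fit_mixed_model(data, response, fixed, participant, group,
                       transform = "identity", group_random = group_random)
  steps <- c(steps, "fit: identity, homoskedastic")
  ck <- assumption_checks(m, alpha)
  transform <- "identity"
  if (ck$normality$verdict == "non-normal" && all(data[[response]] >= 0, na.rm = TRUE)) {
    transform <- "sqrt"
    m <- fit_mixed_model(data, response, fixed, participant, group,
                         transform = "sqrt", group_random = group_random)
    steps <- c(steps, "refit: sqrt transform (residuals non-normal)")
    ck <- assumption_checks(m, alpha)
  }
  if (ck$levene$verdict == "heteroskedastic") {
    d2 <- data
    d2$.cell <- interaction(d2[, fixed, drop = FALSE], drop = TRUE)
    m2 <- tryCatch(
      fit_mixed_model(d2, response, fixed, participant, group,
                      transform = transform, weights_by = ".cell"),
      error = function(e) NULL
    )
    if (!is.null(m2)) {
      m <- m2
      steps <- c(steps, "refit: per-cell variance weights (Levene rejected)")
      ck <- assumption_checks(m, alpha)
    } else {
      steps <- c(steps, "weights refit failed to converge; keeping previous model")
    }
  }
  list(model = m, steps = steps, checks = ck)
}

#' Morey within-subject standard errors
#'
#' For plotting: each participant's mean is removed and the grand mean added
#' back; the per-condition SE of the normalized values is then inflated by
#' `sqrt(M/(M-1))` for `M` conditions. Participants missing any condition
#' are dropped from the normalization (with a message). With `M = 1` the
#' correction is undefined and the plain SE is returned with a warning.
#'
#' @param data Data.frame of one value per participant x condition
#'   (pre-averaged).
#' @param participant,condition,value Column names.
#' @return Data.frame: `condition`, `mean`, `se_morey`, `n`.
#' @export
morey_sem <- function(data, participant = "participant",
                      condition = "condition", value = "value") {
  d <- data[, c(participant, condition, value)]
  names(d) <- c("p", "c", "y")
  d <- d[stats::complete.cases(d), ]
  conds <- unique(d$c)
  M <- length(conds)
  full <- names(which(tapply(d$c, d$p, function(x) length(unique(x))) == M))
  if (length(full) < length(unique(d$p))) {
    message("dropping ", length(unique(d$p)) - length(full),
            " participant(s) missing conditions from normalization")
  }
  d <- d[d$p %in% full, ]
  pm <- tapply(d$y, d$p, mean)
  gm <- mean(d$y)
  d$norm <- d$y - pm[as.character(d$p)] + gm
  agg <- do.call(rbind, lapply(conds, function(cc) {
    v <- d$norm[d$c == cc]
    raw <- d$y[d$c == cc]
    data.frame(condition = cc, mean = mean(raw),
               se = stats::sd(v) / sqrt(length(v)),
               se_raw = stats::sd(raw) / sqrt(length(raw)), n = length(v),
               stringsAsFactors = FALSE)
  }))
  if (M == 1) {
    # normalization degenerates (all values equal the grand mean)
    warning("single condition: Morey correction undefined, returning plain SE")
    agg$se_morey <- agg$se_raw
  } else {
    agg$se_morey <- agg$se * sqrt(M / (M - 1))
  }
  agg[, c("condition", "mean", "se_morey", "n")]
}
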