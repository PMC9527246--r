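test_that("mixed-model F agrees with ordinary ANOVA when participants add nothing", {
  set.seed(10)
  d <- expand.grid(participant = sprintf("s%02d", 1:16),
                   congruency = c("congruent", "incongruent"),
                   delay = c("short", "long"), stringsAsFactors = FALSE)
  d$group <- ifelse(d$participant <= "s08", "A", "B")
  d$y <- 40 + 15 * (d$congruency == "congruent") + rnorm(nrow(d), 0, 4)
  m <- fit_mixed_model(d, "y", c("congruency", "delay"), group_random = FALSE)
  at <- anova_table(m)
  oracle <- anova(aov(y ~ congruency * delay, d))
  for (eff in c("congruency", "delay", "congruency:delay")) {
    expect_equal(at$F[at$effect == eff], oracle[eff, "F value"],
                 tolerance = 0.01)
  }
  expect_equal(at$df_method, rep("containment", 3))
  expect_equal(unique(at$df_den), nrow(d) - 4)
})

test_that("null responses yield non-significant fixed effects", {
  set.seed(2)
  d <- expand.grid(participant = sprintf("s%02d", 1:12),
                   congruency = c("c", "i"), delay = c("s", "l"),
                   stringsAsFactors = FALSE)
  d$group <- "A"
  # participant offsets only; conditions identical up to tiny noise
  off <- setNames(rnorm(12, 0, 5), sprintf("s%02d", 1:12))
  d$y <- 50 + off[d$participant] + rnorm(nrow(d), 0, 0.5)
  at <- anova_table(fit_mixed_model(d, "y", c("congruency", "delay")))
  expect_true(all(at$p > 0.001))
})

test_that("EMMs equal raw cell means under balance and up-weight sparse cells", {
  set.seed(3)
  d <- expand.grid(participant = sprintf("s%02d", 1:10),
                   f1 = c("a", "b"), f2 = c("x", "y"), stringsAsFactors = FALSE)
  d$group <- "A"
  d$y <- rnorm(nrow(d), 20, 3)
  m <- fit_mixed_model(d, "y", c("f1", "f2"), group_random = FALSE)
  emm <- emm_table(m)
  raw <- aggregate(y ~ f1 + f2, d, mean)
  merged <- merge(emm, raw, by = c("f1", "f2"))
  expect_equal(merged$emmean, merged$y, tolerance = 1e-6)
  # hand-worked unbalanced case: cells (a,x) = {1,3}; (a,y) = {10}
  d2 <- data.frame(
    participant = paste0("q", 1:7),
    f1 = c("a", "a", "a", "b", "b", "b", "b"),
    f2 = c("x", "x", "y", "x", "x", "y", "y"),
    y = c(1, 3, 10, 4, 6, 8, 8), group = "A", stringsAsFactors = FALSE
  )
  m2 <- fit_mixed_model(d2, "y", c("f1", "f2"), group_random = FALSE)
  emma <- emm_table(m2, "f1")
  expect_equal(emma$emmean[emma$f1 == "a"], 6.0, tolerance = 1e-6)
  expect_equal(mean(d2$y[d2$f1 == "a"]), 14 / 3, tolerance = 1e-6) # raw differs
  # constant response: every EMM equals the constant
  d$y <- 7
  mc <- fit_mixed_model(d, "y", c("f1", "f2"), group_random = FALSE)
  expect_equal(emm_table(mc)$emmean, rep(7, 4), tolerance = 1e-8)
})

test_that("pairwise contrasts are antisymmetric with zero for equal margins", {
  set.seed(4)
  d <- expand.grid(participant = sprintf("s%02d", 1:8),
                   f1 = c("a", "b"), stringsAsFactors = FALSE)
  d$group <- "A"
  d$y <- 10 + 3 * (d$f1 == "a") + rnorm(nrow(d))
  m <- fit_mixed_model(d, "y", "f1", group_random = FALSE)
  emm <- emm_table(m)
  ct <- pairwise_contrasts(emm)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$estimate, emm$emmean[1] - emm$emmean[2])
  # antisymmetry: reversing the margin order flips the sign exactly
  emm_rev <- emm
  emm_rev[1:2, ] <- emm[2:1, ]
  attr(emm_rev, "L") <- attr(emm, "L")[2:1, ]
  ct_rev <- pairwise_contrasts(emm_rev)
  expect_equal(ct_rev$estimate, -ct$estimate)
  expect_equal(ct_rev$se, ct$se)
  # identical margins -> zero estimate, t = 0
  d$y <- 5 + rep(rnorm(8), 2)[match(d$participant, sprintf("s%02d", 1:8))]
  m0 <- fit_mixed_model(d, "y", "f1", group_random = FALSE)
  ct0 <- pairwise_contrasts(emm_table(m0))
  expect_equal(ct0$estimate, 0, tolerance = 1e-8)
})

test_that("assumption checks detect injected heteroskedasticity and skew", {
  set.seed(6)
  d <- expand.grid(participant = sprintf("s%02d", 1:30),
                   f1 = c("a", "b"), stringsAsFactors = FALSE)
  d$group <- "A"
  # 4x the SD (16x variance) in condition b
  d$y <- 10 + ifelse(d$f1 == "b", rnorm(nrow(d), 0, 8), rnorm(nrow(d), 0, 2))
  m <- fit_mixed_model(d, "y", "f1", group_random = FALSE)
  ck <- assumption_checks(m)
  expect_equal(ck$levene$verdict, "heteroskedastic")
  expect_true(ck$recommend %in% c("weights", "both"))
  # clean normal data: nothing recommended
  set.seed(60)
  d$y <- rnorm(nrow(d), 10, 2)
  ck2 <- assumption_checks(fit_mixed_model(d, "y", "f1", group_random = FALSE))
  expect_equal(ck2$levene$verdict, "homoskedastic")
  expect_equal(ck2$normality$verdict, "normal")
  expect_equal(ck2$recommend, "none")
})

test_that("the rule engine applies sqrt then variance weights as needed", {
  set.seed(8)
  d <- expand.grid(participant = sprintf("s%02d", 1:40),
                   f1 = c("a", "b"), stringsAsFactors = FALSE)
  d$group <- "A"
  # right-skewed response: sqrt should trigger and reduce skew
  d$y <- rexp(nrow(d), rate = 0.2)^1.5
  res <- fit_with_rules(d, "y", "f1")
  expect_true(any(grepl("sqrt", res$steps)))
  expect_lt(abs(skewness(sqrt(d$y))), abs(skewness(d$y)))
  expect_equal(res$model$transform, "sqrt")
  # heteroskedastic world: weights refit via nlme varIdent
  d$y <- 10 + ifelse(d$f1 == "b", rnorm(nrow(d), 0, 8), rnorm(nrow(d), 0, 1))
  res2 <- fit_with_rules(d, "y", "f1")
  expect_true(any(grepl("weights", res2$steps)))
  expect_equal(res2$model$backend, "nlme")
  at <- anova_table(res2$model)
  expect_true(all(is.finite(at$F)))
})

test_that("Morey within-subject SEs match the hand-worked example", {
  # pure between-subject offset: normalized values identical -> SE 0
  d0 <- data.frame(participant = rep(c("p1", "p2"), each = 2),
                   condition = rep(c("a", "b"), 2), value = c(1, 3, 11, 13))
  m0 <- morey_sem(d0)
  expect_equal(m0$se_morey, c(0, 0))
  expect_equal(m0$mean, c(6, 8))
  # hand-worked 2x2: p1 = (1, 5), p2 = (2, 2)
  # participant means 3, 2; grand mean 2.5
  # normalized: p1 -> (0.5, 4.5); p2 -> (2.5, 2.5)
  # condition a: sd(0.5, 2.5)/sqrt(2) = sqrt(2)/2 = 1; times sqrt(2/1)
  d1 <- data.frame(participant = rep(c("p1", "p2"), each = 2),
                   condition = rep(c("a", "b"), 2), value = c(1, 5, 2, 2))
  m1 <- morey_sem(d1)
  expect_equal(m1$se_morey, c(1, 1) * sqrt(2), tolerance = 1e-10)
  # M = 1: plain SE with a warning
  d2 <- data.frame(participant = c("p1", "p2", "p3"), condition = "a",
                   value = c(1, 2, 3))
  expect_warning(m2 <- morey_sem(d2), "undefined")
  expect_equal(m2$se_morey, sd(1:3) / sqrt(3))
  # participants missing a condition are dropped from normalization
  d3 <- rbind(d1, data.frame(participant = "p3", condition = "a", value = 9))
  expect_message(m3 <- morey_sem(d3), "missing conditions")
  expect_equal(m3$se_morey, m1$se_morey)
})

test_that("weighted (nlme) models estimate per-level residual variances", {
  set.seed(9)
  d <- expand.grid(participant = sprintf("s%02d", 1:30),
                   f1 = c("a", "b"), stringsAsFactors = FALSE)
  d$group <- "A"
  d$y <- 5 + ifelse(d$f1 == "b", rnorm(nrow(d), 0, 6), rnorm(nrow(d), 0, 1.5))
  m <- fit_mixed_model(d, "y", "f1", weights_by = "f1")
  expect_equal(m$backend, "nlme")
  vs <- coef(m$fit$modelStruct$varStruct, unconstrained = FALSE, allCoef = TRUE)
  expect_gt(max(vs) / min(vs), 2.5)   # variance ratio detected
  at <- anova_table(m)
  expect_true(all(at$p >= 0 & at$p <= 1))
})
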