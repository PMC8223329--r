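# Nested linear mixed models, the epigenome-wide scan, CpG selection, and
# the case-only onset analysis.

test_that("degenerate random effects reduce to ordinary least squares", {
  set.seed(1)
  n <- 240
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  y <- 1 + 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(n)   # i.i.d., no clustering
  person <- rep(sprintf("p%03d", 1:120), each = 2)
  pair <- rep(sprintf("q%03d", 1:60), each = 4)
  fit <- fit_nested_lmm(y, X, person, pair)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(fit$coefficients$estimate - ols)), 1e-6)
  expect_lt(fit$varcomp["v_pair"] + fit$varcomp["v_person"], 1e-6)
})

test_that("fixed effects equal direct GLS at the estimated variance components", {
  # 3 pairs x 2 persons x 2 observations; the mixed-model fixed effects
  # must equal the closed-form GLS solution at the fitted V
  set.seed(2)
  pair <- rep(c("A", "B", "C"), each = 4)
  person <- rep(sprintf("i%d", 1:6), each = 2)
  x <- rnorm(12)
  u_pair <- rep(rnorm(3, 0, 1), each = 4)
  u_person <- rep(rnorm(6, 0, 0.8), each = 2)
  y <- 2 + 0.7 * x + u_pair + u_person + rnorm(12, 0, 0.5)
  fit <- fit_nested_lmm(y, cbind(x = x), person, pair)
  vc <- fit$varcomp
  Zp <- outer(pair, unique(pair), `==`) * 1
  Zi <- outer(person, unique(person), `==`) * 1
  V <- vc["v_pair"] * tcrossprod(Zp) + vc["v_person"] * tcrossprod(Zi) +
    vc["v_resid"] * diag(12)
  X <- cbind(1, x)
  Vi <- solve(V)
  gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_lt(max(abs(fit$coefficients$estimate - gls)), 1e-6)
})

test_that("rank-deficient designs fail naming the collinear column", {
  y <- rnorm(20)
  X <- cbind(a = 1:20, b = 2 * (1:20))
  expect_error(fit_nested_lmm(y, X, rep(1:10, each = 2), rep(1:5, each = 4)),
               "collinear.*b")
  expect_error(fit_nested_lmm(y, X[, 1, drop = FALSE], rep(1:10, each = 2),
                              rep(1:10, 2)),
               "exactly one pair")
})

test_that("constant CpGs are excluded with a reason, and smoking recoding is affine-invariant", {
  co <- small_cohort(seed = 15)
  co$methylation[, "cgN00002"] <- 0.5
  ew <- run_ewas(co, "non-stroke CVD")
  expect_true("cgN00002" %in% attr(ew, "excluded"))
  expect_false("cgN00002" %in% ew$cpg)
  # recoding smoking 1/2/3 to 0/1/2 shifts only the intercept
  co2 <- co
  co2$longitudinal$smoking <- co2$longitudinal$smoking - 1L
  ew2 <- run_ewas(co2, "non-stroke CVD")
  m <- merge(as.data.frame(ew), as.data.frame(ew2), by = "cpg")
  expect_lt(max(abs(m$beta.x - m$beta.y)), 1e-8)
})

test_that("estimates are invariant to person relabelling and row order", {
  co <- small_cohort(seed = 16, n_null = 3, n_signal = 0)
  ew1 <- run_ewas(co, "non-stroke CVD")
  co2 <- co
  perm <- sample(nrow(co2$samples))
  co2$samples <- co2$samples[perm, ]
  co2$methylation <- co2$methylation[perm, , drop = FALSE]
  ew2 <- run_ewas(co2, "non-stroke CVD")
  m <- merge(as.data.frame(ew1), as.data.frame(ew2), by = "cpg")
  expect_lt(max(abs(m$beta.x - m$beta.y)), 1e-8)
  expect_error(run_ewas(co, "no such category"), "absent")
})

test_that("CpG selection: threshold branch, fallback branch, ties and k", {
  tab <- data.frame(cpg = sprintf("cg%02d", 1:30), p = rep(0.5, 30))
  tab$rank <- 1:30
  class(tab) <- c("ewas_table", "data.frame")
  # all p equal: exactly k, ties broken lexicographically
  sel <- select_cpgs(tab, k = 20, alpha = 2e-7)
  expect_equal(length(sel), 20)
  expect_equal(sel, sort(tab$cpg)[1:20])
  # one CpG below threshold: only that one
  tab$p[17] <- 1e-9
  expect_equal(select_cpgs(tab, k = 20, alpha = 2e-7), "cg17")
  # k larger than the table: all, with a warning
  expect_warning(sel_all <- select_cpgs(tab[1:5, ], k = 20, alpha = 0),
                 "exceeds")
  expect_equal(length(sel_all), 5)
})

test_that("multiple-testing thresholds reproduce the quoted values", {
  expect_equal(bonferroni_alpha(255356, signif_digits = 1), 2e-7)
  expect_equal(bonferroni_alpha(20 * 4), 6.25e-4)
  expect_equal(bonferroni_alpha(20 * 7), 0.05 / 140)
})

test_that("onset analysis: seed-reproducible, degenerate summaries coincide, guards", {
  co <- small_cohort(seed = 17, n_null = 2, n_signal = 1, traits = "BMI",
                     satsa_missingness = FALSE)
  # keep only the first occasion's methylation: first = last = mean = random
  keep <- co$samples$occasion == co$schedule$labels[1]
  co1 <- co
  co1$methylation[!keep, ] <- NA_real_
  on1 <- onset_case_only(co1, "non-stroke CVD", colnames(co1$methylation),
                         seed = 3)
  est <- split(on1$estimate, on1$summary)
  for (s in c("last", "mean", "random"))
    expect_equal(est[[s]], est[["first"]], tolerance = 1e-10)
  # random summary is deterministic given the seed
  a <- onset_case_only(co, "non-stroke CVD", colnames(co$methylation),
                       summaries = "random", seed = 9)
  b <- onset_case_only(co, "non-stroke CVD", colnames(co$methylation),
                       summaries = "random", seed = 9)
  expect_equal(a$estimate, b$estimate)
  # threshold recorded for 20 CpGs x 4 summaries
  expect_equal(attr(onset_case_only(co, "non-stroke CVD",
                                    rep(colnames(co$methylation), 7)[1:20],
                                    summaries = "first", seed = 1),
                    "alpha"), 6.25e-4)
  # fewer than 3 eligible cases: refuse
  co2 <- co
  co2$events$diagnosis_age <- co2$events$baseline_age <- NULL
  co2$events$diagnosis_age <- ifelse(co2$events$event == 1,
                                     co2$individuals$baseline_age[
                                       match(co2$events$person,
                                             co2$individuals$person)] - 5,
                                     NA)
  expect_error(onset_case_only(co2, "non-stroke CVD",
                               colnames(co2$methylation), seed = 1),
               "fewer than 3")
})

test_that("signal CpGs with a strong outcome link dominate the top 20", {
  # 5 signal CpGs among 200 nulls; strong link: large intercept effect on
  # risk and early diagnoses so most case occasions code 1
  mk_ev <- list(list(category = "non-stroke CVD", intercept = -0.45,
                     coef = c(i_m = 5, s_m = 0, i_rf = 0, s_rf = 0),
                     cpg = 1:5, age_window = c(-2, 2)))
  set.seed(71)
  reps <- 25
  all5 <- logical(reps)
  for (r in seq_len(reps)) {
    co <- simulate_cohort(sim_config(seed = 5000 + r, n_null_cpgs = 200,
                                     n_signal_cpgs = 5,
                                     event_models = mk_ev))
    ew <- run_ewas(co, "non-stroke CVD")
    all5[r] <- sum(grepl("^cgS", ew$cpg[ew$rank <= 20])) == 5
  }
  expect_gte(mean(all5), 0.9)
})

test_that("p-values are approximately uniform on a null cohort", {
  # null CpGs simulated under the scan's assumed covariance structure
  # (person and pair intercepts, no person-specific slopes): with a
  # time-dependent exposure, random slopes would be a genuine source of
  # miscalibration, not an implementation defect
  null_par <- altsr_params(mu = rep(0, 4), psi = diag(c(0.09, 0, 1, 0.01)),
                           a = 0, b = 0, c = 0.3, d = 0)
  co <- simulate_cohort(sim_config(seed = 19, n_null_cpgs = 300,
                                   n_signal_cpgs = 0,
                                   signal_params = null_par))
  ew <- run_ewas(co, "non-stroke CVD")
  ks <- suppressWarnings(ks.test(ew$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
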