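# The twin-cohort generator and the bivariate ALT-SR process.

test_that("schedule and parameter validation", {
  expect_error(occasion_schedule(c("a", "b"), c(1, 2)), "first slope loading")
  expect_error(occasion_schedule(c("a", "b"), c(0, 0)), "strictly increasing")
  bad <- diag(c(1, 1, 1, -0.5))
  expect_error(altsr_params(psi = bad), "positive semi-definite")
  expect_error(altsr_params(a = 1.2), "stationary")
  expect_error(altsr_params(pair_icc_mz = 0.1, pair_icc_dz = 0.4),
               "pair_icc_mz >= pair_icc_dz")
})

test_that("all dynamics off gives i.i.d. standard bivariate normal occasions", {
  par <- altsr_params(mu = rep(0, 4), psi = matrix(0, 4, 4),
                      a = 0, b = 0, c = 0, d = 0,
                      sigma_e1 = diag(2), sigma_e = diag(2))
  sim <- simulate_bivariate_altsr(par, n_subjects = 20000, seed = 5)
  Y <- cbind(sim$dnam, sim$trait)
  se_m <- 1 / sqrt(20000)
  expect_lt(max(abs(colMeans(Y))), 4 * se_m)
  expect_lt(max(abs(apply(Y, 2, var) - 1)), 4 * sqrt(2 / 20000))
  # adjacent-occasion and cross-construct correlations are null
  expect_lt(max(abs(cor(Y)[upper.tri(diag(10))])), 4 * se_m)
})

test_that("a single methylation-to-trait cross-lag produces the stated lag covariance", {
  n <- 1e5
  par <- altsr_params(mu = rep(0, 4), psi = matrix(0, 4, 4),
                      a = 0, b = 0, c = 0, d = 0.5,
                      sigma_e1 = diag(2), sigma_e = diag(2))
  sim <- simulate_bivariate_altsr(par, n_subjects = n, seed = 6)
  for (t in 2:5) {
    x <- sim$resid_dnam[, t - 1]; y <- sim$resid_trait[, t]
    target <- 0.5 * var(x)
    se <- sqrt((var(x) * var(y) + cov(x, y)^2) / n)
    expect_lt(abs(cov(x, y) - target), 3 * se)
  }
})

test_that("sample mean trajectory follows the latent growth means", {
  par <- altsr_params()
  lam <- occasion_schedule()$loadings
  sim <- simulate_bivariate_altsr(par, n_subjects = 2000, seed = 7)
  expected <- par$mu[3] + lam * par$mu[4]
  sd_t <- apply(sim$trait, 2, sd)
  expect_lt(max(abs(colMeans(sim$trait) - expected) / (sd_t / sqrt(2000))), 4)
})

test_that("default cohort matches the study composition", {
  co <- simulate_cohort(sim_config(seed = 2, n_null_cpgs = 2))
  expect_equal(nrow(co$individuals), 535)
  expect_equal(sum(co$individuals$zygosity == "MZ"), 187)
  expect_equal(sum(co$individuals$zygosity == "DZ"), 347)
  expect_equal(sum(co$individuals$zygosity == "unknown"), 1)
  # beta values bounded, ages non-decreasing within person
  expect_true(all(co$methylation >= 0 & co$methylation <= 1, na.rm = TRUE))
  ages <- tapply(co$longitudinal$age, co$longitudinal$person,
                 function(a) all(diff(a) >= 0))
  expect_true(all(ages))
  # co-twins share pair id and zygosity
  tw <- co$individuals[grepl("^T", co$individuals$pair), ]
  zz <- tapply(tw$zygosity, tw$pair, function(z) length(unique(z)))
  expect_true(all(zz == 1))
  # HDL and LDL absent at the first occasion under the SATSA pattern
  first <- co$longitudinal[co$longitudinal$occasion == "IPT3", ]
  expect_true(all(is.na(first$HDL)))
  expect_true(all(is.na(first$LDL)))
})

test_that("a single MZ pair yields two individuals sharing pair and zygosity", {
  co <- simulate_cohort(sim_config(n_mz_pairs = 1, n_dz_pairs = 0,
                                   n_singletons = 0, n_null_cpgs = 1,
                                   n_signal_cpgs = 0, seed = 3,
                                   event_models = list(
                                     list(category = "non-stroke CVD",
                                          intercept = -1,
                                          coef = c(i_m = 0, s_m = 0,
                                                   i_rf = 0, s_rf = 0),
                                          cpg = 1, age_window = c(-2, 10)))))
  expect_equal(nrow(co$individuals), 2)
  expect_equal(length(unique(co$individuals$pair)), 1)
  expect_equal(unique(co$individuals$zygosity), "MZ")
})

test_that("the cohort is a deterministic function of the seed", {
  cfg <- sim_config(seed = 42, n_null_cpgs = 3, n_signal_cpgs = 1,
                    n_mz_pairs = 10, n_dz_pairs = 10, n_singletons = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$longitudinal, b$longitudinal)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$events, b$events)
})

test_that("MZ co-twins are more alike than DZ co-twins in methylation baseline", {
  co <- simulate_cohort(sim_config(seed = 8, n_null_cpgs = 40,
                                   n_signal_cpgs = 0, satsa_missingness = FALSE))
  first <- co$samples$occasion == "IPT3"
  meth <- co$methylation[first, ]
  person <- co$samples$person[first]
  ind <- co$individuals
  icc_of <- function(zyg) {
    pairs <- unique(ind$pair[ind$zygosity == zyg & grepl("^T", ind$pair)])
    r <- vapply(colnames(meth), function(cg) {
      m <- tapply(meth[, cg], person, identity)
      tw <- t(vapply(pairs, function(p) {
        pr <- ind$person[ind$pair == p]
        c(m[[pr[1]]], m[[pr[2]]])
      }, c(0, 0)))
      cor(tw[, 1], tw[, 2])
    }, 0)
    mean(r)
  }
  expect_gt(icc_of("MZ"), icc_of("DZ"))
  expect_gt(icc_of("DZ"), 0)
})

test_that("event assignment extremes and calibration", {
  cfg <- sim_config(seed = 5, n_null_cpgs = 0, n_signal_cpgs = 1,
                    signal_traits = "BMI")
  co <- simulate_cohort(cfg)
  none <- assign_events(co, list(list(category = "x", intercept = -Inf,
                                      coef = c(i_m = 0, s_m = 0, i_rf = 0,
                                               s_rf = 0),
                                      cpg = 1, age_window = c(-2, 10))))
  expect_equal(sum(none$events$event[none$events$category == "x"]), 0)
  all_ <- assign_events(co, list(list(category = "x", intercept = Inf,
                                      coef = c(i_m = 0, s_m = 0, i_rf = 0,
                                               s_rf = 0),
                                      cpg = 1, age_window = c(-2, 10))))
  expect_equal(sum(all_$events$event[all_$events$category == "x"]), 535)
  expect_error(assign_events(co, list(list(category = "x", intercept = 0,
                                           coef = c(i_m = 1, s_m = 0,
                                                    i_rf = 0, s_rf = 0),
                                           cpg = "cgZZ",
                                           age_window = c(-2, 10)))),
               "unknown signal CpG")

  # empirical event fraction matches the closed-form mean logistic
  # probability (numeric integration over the latent distribution)
  mdl <- cfg$event_models[[1]]
  cf <- mdl$coef[c("i_m", "s_m")]
  par <- co$truth$params
  m_u <- sum(cf * par$mu[1:2])
  v_u <- drop(t(cf) %*% par$psi[1:2, 1:2] %*% cf)
  p_closed <- stats::integrate(function(u)
    plogis(mdl$intercept + u) * dnorm(u, m_u, sqrt(v_u)),
    -Inf, Inf)$value
  reps <- 100
  fr <- numeric(reps)
  for (r in seq_len(reps)) {
    cr <- simulate_cohort(sim_config(seed = 1000 + r, n_null_cpgs = 0,
                                     n_signal_cpgs = 1,
                                     signal_traits = "BMI"))
    e <- cr$events
    fr[r] <- mean(e$event[e$category == "non-stroke CVD"])
  }
  mc_se <- sd(fr) / sqrt(reps)
  expect_lt(abs(mean(fr) - p_closed), 3 * mc_se)
})

test_that("missingness rules behave and calibrate to the measurement counts", {
  cfg <- sim_config(seed = 4, n_null_cpgs = 2, n_signal_cpgs = 1,
                    satsa_missingness = FALSE)
  co <- simulate_cohort(cfg)
  # retention 1 everywhere: unchanged
  same <- apply_missingness(co, data.frame(variable = "HDL",
                                           occasion = "IPT5", retention = 1))
  expect_identical(same$longitudinal, co$longitudinal)
  # HDL retention 0 at IPT3: no HDL at IPT3 for anyone
  gone <- apply_missingness(co, data.frame(variable = "HDL",
                                           occasion = "IPT3", retention = 0))
  expect_true(all(is.na(
    gone$longitudinal$HDL[gone$longitudinal$occasion == "IPT3"])))
  expect_error(apply_missingness(co, data.frame(variable = "HDL",
                                                occasion = "IPT3",
                                                retention = 1.4)),
               "retention")
  # methylation retention 0.5: mean fraction of persons with >= 3 of 5
  # measurements within 0.05 of the study's 269/535
  rules <- missingness_satsa(co$schedule)
  fr <- vapply(1:40, function(r) {
    masked <- apply_missingness(co, rules, seed = 2000 + r)
    cnt <- tapply(!is.na(masked$methylation[, 1]), masked$samples$person, sum)
    mean(cnt >= 3)
  }, 0)
  expect_lt(abs(mean(fr) - 269 / 535), 0.05)
})

test_that("simulation configurations round-trip through JSON", {
  cfg <- sim_config(seed = 12, n_null_cpgs = 3, n_mz_pairs = 5,
                    n_dz_pairs = 5, n_singletons = 2)
  f <- tempfile(fileext = ".json")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg2)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$events, b$events)
})

test_that("cohorts round-trip through TSV", {
  co <- small_cohort(seed = 6, n_null = 2, n_signal = 1, traits = "BMI")
  dir <- tempfile()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$individuals$person, co$individuals$person)
  expect_equal(back$methylation, co$methylation, tolerance = 1e-9)
  expect_equal(back$schedule$loadings, co$schedule$loadings)
  expect_equal(nrow(back$events), nrow(co$events))
})
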