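# FIML likelihood, estimation, fit statistics, covariance of estimates,
# standardization.

# plain-R Gaussian log-density oracle, independent of the C++ kernel
mvn_ll_oracle <- function(Y, mu, Sigma) {
  tot <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    S <- Sigma[o, o, drop = FALSE]
    r <- Y[i, o] - mu[o]
    tot <- tot - 0.5 * (length(o) * log(2 * pi) +
                          determinant(S)$modulus[1] +
                          drop(t(r) %*% solve(S) %*% r))
  }
  tot
}

test_that("FIML log-likelihood matches the casewise Gaussian oracle", {
  set.seed(4)
  mu <- c(1, -0.5, 2)
  Sigma <- matrix(c(1, 0.3, 0.2, 0.3, 1.5, -0.4, 0.2, -0.4, 2), 3)
  Y <- matrix(rnorm(60), 20, 3)
  # complete data
  pats <- altsr:::miss_patterns(Y)
  expect_equal(altsr:::fiml_ll_moments_cpp(Y, mu, Sigma, pats),
               mvn_ll_oracle(Y, mu, Sigma), tolerance = 1e-10)
  # one observed variable per row: sum of univariate normal densities
  Y1 <- Y
  Y1[cbind(1:20, 1 + (1:20) %% 3)] <- NA
  Y1[cbind(1:20, 1 + (2 + 1:20) %% 3)] <- NA
  pats1 <- altsr:::miss_patterns(Y1)
  ll_uni <- sum(vapply(1:20, function(i) {
    j <- which(!is.na(Y1[i, ]))
    dnorm(Y1[i, j], mu[j], sqrt(Sigma[j, j]), log = TRUE)
  }, 0))
  expect_equal(altsr:::fiml_ll_moments_cpp(Y1, mu, Sigma, pats1), ll_uni,
               tolerance = 1e-10)
  # 4-row, 3-variable toy with one missing cell, term by term
  Yt <- rbind(c(0.5, 1.2, -0.3), c(1.1, NA, 0.4),
              c(-0.2, 0.9, 1.5), c(0.0, 0.3, -1.0))
  expect_equal(altsr:::fiml_ll_moments_cpp(Yt, mu, Sigma,
                                           altsr:::miss_patterns(Yt)),
               mvn_ll_oracle(Yt, mu, Sigma), tolerance = 1e-10)
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(7)
  n <- 150
  x <- rnorm(n)
  y <- 0.4 * x + rnorm(n)
  z <- 0.6 * y + rnorm(n)
  d <- data.frame(y = y, z = z, x = x)
  d$z[sample(n, 25)] <- NA
  pt <- parameter_table(rbind(
    pt_row("ly", "=~", "y", free = FALSE, value = 1),
    pt_row("lz", "=~", "z", free = FALSE, value = 1),
    pt_row("lz", "~", "ly"), pt_row("ly", "~", "x"),
    pt_row("ly", "~~", "ly"), pt_row("lz", "~~", "lz"),
    pt_row("ly", "~1", ""), pt_row("lz", "~1", ""),
    pt_row("y", "~~", "y", free = FALSE, value = 0),
    pt_row("z", "~~", "z", free = FALSE, value = 0)))
  m <- sem_model(pt, manifest = c("y", "z"), exo = "x")
  prep <- altsr:::sem_data(m, d)
  th <- altsr:::sem_start(m, prep) + 0.1
  ga <- altsr:::fiml_negll_grad_cpp(th, m$templates, m$fmap, prep$Y, prep$X,
                                    prep$patterns)
  gn <- altsr:::num_grad(function(t)
    altsr:::fiml_negll_cpp(t, m$templates, m$fmap, prep$Y, prep$X,
                           prep$patterns), th)
  expect_lt(max(abs(ga$grad - gn) / (abs(gn) + 1)), 1e-5)
  expect_equal(ga$nll, altsr:::fiml_negll_cpp(th, m$templates, m$fmap,
                                              prep$Y, prep$X, prep$patterns))
})

test_that("saturated specification gives T ~ 0, RMSEA 0, CFI 1", {
  set.seed(2)
  d <- data.frame(y1 = rnorm(80), y2 = rnorm(80))
  d$y2 <- d$y2 + 0.5 * d$y1
  pt <- parameter_table(rbind(
    pt_row("y1", "~~", "y1"), pt_row("y2", "~~", "y2"),
    pt_row("y1", "~~", "y2"),
    pt_row("y1", "~1", ""), pt_row("y2", "~1", "")))
  f <- sem_fit(sem_model(pt, manifest = c("y1", "y2")), d)
  expect_true(f$converged)
  expect_lt(abs(f$Tstat), 1e-6)
  fi <- fit_indices(f)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$cfi, 1)
})

test_that("fit-index arithmetic matches the closed form", {
  fi <- altsr:::fit_indices_values(T = 50, df = 20, n = 500, Tb = 500,
                                   dfb = 30)
  expect_equal(fi$rmsea, sqrt(30 / 10000), tolerance = 1e-12)
  expect_equal(fi$cfi, 1 - 30 / 470, tolerance = 1e-12)
  # T = df: RMSEA 0
  expect_equal(altsr:::fit_indices_values(20, 20, 500, 500, 30)$rmsea, 0)
})

test_that("regression coefficients, standardization and scale equivariance", {
  set.seed(9)
  n <- 400
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  d <- data.frame(y = y, x = x)
  m <- sem_model(pt_regression(), manifest = c("y", "x"))
  f <- sem_fit(m, d)
  ols <- coef(lm(y ~ x, data = d))
  expect_equal(unname(coef(f)["b"]), unname(ols["x"]), tolerance = 1e-5)
  # standardized slope equals the Pearson correlation
  s <- standardize(f)
  expect_equal(s$std[s$par_id == "b" & !is.na(s$par_id)][1], cor(x, y),
               tolerance = 1e-5)
  # multiplying a manifest by 10: unstandardized changes, standardized and
  # T statistic invariant
  d10 <- transform(d, y = 10 * y)
  f10 <- sem_fit(m, d10)
  s10 <- standardize(f10)
  expect_equal(s10$std[s10$par_id == "b" & !is.na(s10$par_id)][1],
               s$std[s$par_id == "b" & !is.na(s$par_id)][1],
               tolerance = 1e-4)
  expect_equal(f10$Tstat, f$Tstat, tolerance = 1e-4)
  expect_equal(unname(coef(f10)["b"]), 10 * unname(coef(f)["b"]),
               tolerance = 1e-4)
})

test_that("two-predictor path model matches lm on standardized data", {
  set.seed(12)
  n <- 300
  x1 <- rnorm(n); x2 <- 0.4 * x1 + rnorm(n)
  y <- 0.3 * x1 - 0.5 * x2 + rnorm(n)
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  pt <- parameter_table(rbind(
    pt_row("ly", "=~", "y", free = FALSE, value = 1),
    pt_row("ly", "~", "x1", label = "b1"),
    pt_row("ly", "~", "x2", label = "b2"),
    pt_row("ly", "~~", "ly"), pt_row("ly", "~1", ""),
    pt_row("y", "~~", "y", free = FALSE, value = 0)))
  f <- sem_fit(sem_model(pt, manifest = "y", exo = c("x1", "x2")), d)
  bl <- coef(lm(scale(y) ~ scale(x1) + scale(x2)))
  s <- standardize(f)
  # ML vs n-1 scaling cancels in the ratio; allow small numeric slack
  expect_equal(s$std[s$par_id == "b1" & !is.na(s$par_id)][1],
               unname(bl[2]), tolerance = 1e-3)
  expect_equal(s$std[s$par_id == "b2" & !is.na(s$par_id)][1],
               unname(bl[3]), tolerance = 1e-3)
})

test_that("complete-data FIML equals the moment-based ML solution", {
  # with complete data the casewise likelihood depends on the data only
  # through the sample mean and covariance; check the fitted implied
  # moments maximize the Wishart discrepancy by comparing log-likelihoods
  set.seed(21)
  n <- 300
  d <- data.frame(y1 = rnorm(n))
  d$y2 <- 0.6 * d$y1 + rnorm(n)
  pt <- parameter_table(rbind(
    pt_row("f", "=~", "y1", free = FALSE, value = 1),
    pt_row("f", "=~", "y2", label = "l2"),
    pt_row("f", "~~", "f"),
    pt_row("y1", "~~", "y1", label = "tv"),
    pt_row("y2", "~~", "y2", label = "tv"),
    pt_row("y1", "~1", ""), pt_row("y2", "~1", "")))
  m <- sem_model(pt)
  f <- sem_fit(m, d)
  expect_true(f$converged)
  imp <- implied_moments(m, coef(f))
  Y <- as.matrix(d)
  ll_model <- altsr:::fiml_ll_moments_cpp(Y, imp$mu, imp$Sigma,
                                          altsr:::miss_patterns(Y))
  expect_equal(ll_model, f$loglik, tolerance = 1e-6)
  # F_ML at the optimum computed from sample moments reproduces T
  mu_s <- colMeans(Y)
  S <- cov(Y) * (n - 1) / n
  ll_sat <- altsr:::fiml_ll_moments_cpp(Y, mu_s, S,
                                        altsr:::miss_patterns(Y))
  expect_equal(f$Tstat, 2 * (ll_sat - ll_model), tolerance = 1e-4)
})

test_that("log-likelihood is invariant to row order and id relabelling", {
  set.seed(30)
  n <- 120
  d <- data.frame(y1 = rnorm(n), y2 = rnorm(n))
  d$y2[sample(n, 30)] <- NA
  pt <- parameter_table(rbind(
    pt_row("y1", "~~", "y1"), pt_row("y2", "~~", "y2"),
    pt_row("y1", "~~", "y2"),
    pt_row("y1", "~1", ""), pt_row("y2", "~1", "")))
  m <- sem_model(pt, manifest = c("y1", "y2"))
  f1 <- sem_fit(m, d)
  f2 <- sem_fit(m, d[sample(n), ])
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
})

test_that("scaled gradient norm at the optimum is below tolerance", {
  set.seed(33)
  sim <- simulate_bivariate_altsr(recovery_params(), n_subjects = 300,
                                  seed = 33)
  res <- fit_altsr_matrix(sim)
  expect_true(res$fit$converged)
  expect_lt(res$fit$grad_norm, 1e-5)
})

test_that("cluster-robust covariance: singleton clusters equal the plain sandwich", {
  set.seed(14)
  n <- 200
  d <- data.frame(y = rnorm(n), x = rnorm(n))
  d$y <- d$y + 0.3 * d$x
  m <- sem_model(pt_regression(), manifest = c("y", "x"))
  f1 <- sem_fit(m, d, cluster = seq_len(n))
  f2 <- sem_fit(m, d, cluster = NULL)
  expect_equal(vcov(f1, robust = TRUE), vcov(f2, robust = TRUE),
               tolerance = 1e-8)
  # sandwich is symmetric positive semi-definite
  V <- vcov(f1, robust = TRUE)
  expect_equal(V, t(V))
  expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
})

test_that("EM for the unrestricted Gaussian recovers moments", {
  set.seed(18)
  n <- 400
  S <- matrix(c(1, 0.5, 0.5, 2), 2)
  Z <- altsr:::rmvn(n, c(1, -1), S)
  # complete data: exact ML moments
  em <- em_mvn(Z)
  expect_equal(em$mu, colMeans(Z), tolerance = 1e-6)
  expect_equal(em$Sigma, cov(Z) * (n - 1) / n, tolerance = 1e-5)
  # MCAR missingness: close to the truth, likelihood non-decreasing
  Z[sample(n, 100), 2] <- NA
  em2 <- em_mvn(Z)
  expect_lt(max(abs(em2$mu - c(1, -1))), 0.2)
  expect_lt(max(abs(em2$Sigma - S)), 0.35)
})

test_that("defined quantities use the delta method consistently", {
  set.seed(40)
  n <- 250
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  pt <- parameter_table(rbind(
    pt_row("ly", "=~", "y", free = FALSE, value = 1),
    pt_row("ly", "~", "x", label = "b"),
    pt_row("ly", "~~", "ly", label = "v"),
    pt_row("ly", "~1", ""),
    pt_row("y", "~~", "y", free = FALSE, value = 0),
    pt_row("bsq", ":=", "b * b"),
    pt_row("bv", ":=", "b + v")))
  f <- sem_fit(sem_model(pt, manifest = "y", exo = "x"),
               data.frame(y = y, x = x))
  defs <- sem_defined(f, robust = FALSE)
  b <- coef(f)["b"]; v <- coef(f)["v"]
  expect_equal(defs$estimate[defs$name == "bsq"], unname(b^2),
               tolerance = 1e-10)
  # delta-method SE of b^2 is |2 b| se(b)
  seb <- sqrt(vcov(f)["b", "b"])
  expect_equal(defs$se[defs$name == "bsq"], unname(abs(2 * b) * seb),
               tolerance = 1e-4)
  expect_equal(defs$estimate[defs$name == "bv"], unname(b + v),
               tolerance = 1e-10)
})
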