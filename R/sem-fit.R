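# Full-information maximum likelihood SEM estimation.
#
# Missing manifest values are handled casewise (each row contributes the
# Gaussian log-density of its observed subvector); exogenous covariates must
# be complete and are conditioned on. The likelihood-ratio statistic is
# computed against an unrestricted ("saturated") conditional Gaussian model
# estimated by EM, which is required under missingness.

#' Fit a structural equation model by FIML
#'
#' The workhorse estimator behind the cross-lagged (ALT-SR) and mediation
#' stages. Maximizes the casewise Gaussian likelihood of the manifest
#' variables given the exogenous covariates, with missing data handled by
#' full-information maximum likelihood.
#'
#' Start values: fixed loadings as declared; free variances at half the
#' observed variance of the (first) associated manifest; regressions and
#' covariances at 0; latent means at 0; manifest intercepts at sample
#' means. On non-convergence the fit is retried twice from jittered starts.
#' Convergence requires relative log-likelihood change below \code{rel_tol}
#' and scaled gradient norm \code{max|g|/(1+|logLik|)} below
#' \code{grad_tol}.
#'
#' @param model a [sem_model()]
#' @param data data.frame with columns for all manifest and exogenous
#'   variables; rows with all manifests missing, or any covariate missing,
#'   are dropped (counted in the fit object)
#' @param cluster optional cluster identifier (e.g. twin-pair id), aligned
#'   with \code{data} rows, for sandwich standard errors
#' @param start optional named start vector overriding the defaults
#' @param control list: \code{rel_tol} (default 1e-9), \code{grad_tol}
#'   (1e-5), \code{max_iter} (500), \code{restarts} (2)
#' @return an object of class \code{semfit}
#' @export
sem_fit <- function(model, data, cluster = NULL, start = NULL,
                    control = list()) {
  stopifnot(inherits(model, "sem_model"))
  ctl <- modify_defaults(list(rel_tol = 1e-9, grad_tol = 1e-5,
                              max_iter = 500, restarts = 2), control)
  prep <- sem_data(model, data, cluster)
  th0 <- sem_start(model, prep)
  if (!is.null(start)) {
    idx <- match(names(start), model$theta_names)
    if (anyNA(idx)) stop("unknown start-value names: ",
                         paste(names(start)[is.na(idx)], collapse = ", "))
    th0[idx] <- start
  }

  negll <- function(th) fiml_negll_cpp(th, model$templates, model$fmap,
                                       prep$Y, prep$X, prep$patterns)
  grad <- function(th) fiml_negll_grad_cpp(th, model$templates, model$fmap,
                                           prep$Y, prep$X, prep$patterns)$grad

  # step scaling from the start values evens out parameters living on very
  # different scales (e.g. raw beta-value variances vs trait variances)
  pscale <- 1 / pmax(abs(th0), 0.05)
  run_opt <- function(par0) {
    opt <- stats::nlminb(par0, negll, gradient = grad, scale = pscale,
                         control = list(iter.max = ctl$max_iter,
                                        eval.max = 4 * ctl$max_iter,
                                        rel.tol = min(ctl$rel_tol, 1e-10)))
    # scaled gradient: |g_i| measured against each parameter's natural
    # scale, relative to the log-likelihood magnitude
    sg <- function(par, obj) max(abs(grad(par)) / pscale) / (1 + abs(obj))
    # polish with BFGS if the gradient is not yet flat
    sgn <- sg(opt$par, opt$objective)
    if (sgn >= ctl$grad_tol) {
      po <- stats::optim(opt$par, negll, grad, method = "BFGS",
                         control = list(maxit = ctl$max_iter,
                                        reltol = 1e-14,
                                        parscale = 1 / pscale))
      if (po$value <= opt$objective) {
        opt$par <- po$par; opt$objective <- po$value
      }
      sgn <- sg(opt$par, opt$objective)
    }
    list(opt = opt, grad_norm = sgn,
         converged = is.finite(opt$objective) && opt$objective < 1e11 &&
           sgn < ctl$grad_tol)
  }
  best <- run_opt(th0)
  attempt <- 0L
  while (!best$converged && attempt < ctl$restarts) {
    attempt <- attempt + 1L
    set_start <- th0 * (1 + stats::rnorm(length(th0), 0, 0.1)) +
      stats::rnorm(length(th0), 0, 0.05)
    cand <- run_opt(set_start)
    if (cand$converged || cand$opt$objective < best$opt$objective)
      best <- cand
  }
  theta <- best$opt$par
  names(theta) <- model$theta_names
  ll <- -best$opt$objective

  # saturated (unrestricted) and baseline models for the LR statistic
  h1 <- sem_h1(prep)
  base <- sem_baseline(prep)
  p <- length(model$ov); q <- ncol(prep$X)
  npar_h1 <- p + p * q + p * (p + 1) / 2
  npar_base <- 2 * p
  Tstat <- max(0, 2 * (h1$loglik - ll))
  df <- npar_h1 - model$npar
  Tb <- max(0, 2 * (h1$loglik - base$loglik))
  dfb <- npar_h1 - npar_base

  # Heywood check: negative variance estimates
  pt <- model$ptable
  var_rows <- pt$free & pt$op == "~~" & pt$lhs == pt$rhs
  heywood <- any(theta[match(unique(pt$par_id[var_rows]),
                             model$theta_names)] < 0, na.rm = TRUE)
  if (heywood) warning("Heywood case: negative variance estimate(s)")

  fit <- structure(list(
    model = model, theta = theta, loglik = ll,
    npar = model$npar, n = nrow(prep$Y), n_dropped = prep$n_dropped,
    converged = best$converged, grad_norm = best$grad_norm,
    Tstat = Tstat, df = df, T_baseline = Tb, df_baseline = dfb,
    loglik_h1 = h1$loglik, loglik_baseline = base$loglik,
    heywood = heywood, prep = prep,
    cache = new.env(parent = emptyenv())), class = "semfit")
  fit
}

# --- data preparation -------------------------------------------------------

sem_data <- function(model, data, cluster = NULL) {
  miss_ov <- setdiff(model$ov, names(data))
  if (length(miss_ov)) stop("data lacks manifest column(s): ",
                            paste(miss_ov, collapse = ", "))
  miss_x <- setdiff(model$exo, names(data))
  if (length(miss_x)) stop("data lacks covariate column(s): ",
                           paste(miss_x, collapse = ", "))
  Y <- as.matrix(data[, model$ov, drop = FALSE])
  storage.mode(Y) <- "double"
  X <- if (length(model$exo))
    as.matrix(data[, model$exo, drop = FALSE]) else matrix(0, nrow(Y), 0)
  storage.mode(X) <- "double"
  keep <- rowSums(!is.na(Y)) > 0 & (ncol(X) == 0 | stats::complete.cases(X))
  n_dropped <- sum(!keep)
  Y <- Y[keep, , drop = FALSE]; X <- X[keep, , drop = FALSE]
  cl <- if (!is.null(cluster)) as.character(cluster)[keep] else NULL
  if (nrow(Y) == 0) stop("no usable rows after dropping empty/incomplete cases")
  list(Y = Y, X = X, patterns = miss_patterns(Y), cluster = cl,
       n_dropped = n_dropped)
}

# group rows by missingness pattern; 0-based indices for the C++ kernel
miss_patterns <- function(Y) {
  obs <- !is.na(Y)
  key <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  split_rows <- split(seq_len(nrow(Y)), key)
  lapply(split_rows, function(rows) {
    list(rows = as.integer(rows - 1L),
         cols = as.integer(which(obs[rows[1], ]) - 1L))
  })
}

sem_start <- function(model, prep) {
  pt <- model$ptable
  th <- numeric(model$npar)
  names(th) <- model$theta_names
  v_ov <- apply(prep$Y, 2, stats::var, na.rm = TRUE)
  v_ov[!is.finite(v_ov) | v_ov <= 0] <- 1
  m_ov <- colMeans(prep$Y, na.rm = TRUE)
  first_ind <- function(lv) {
    j <- match(lv, model$lv)
    nz <- which(model$templates$Lambda[, j] != 0)
    if (length(nz)) nz[1] else NA_integer_
  }
  for (k in seq_along(model$theta_names)) {
    rows <- which(pt$par_id == model$theta_names[k])
    row <- pt[rows[1], ]
    if (!is.na(row$value)) { th[k] <- row$value; next }
    th[k] <- if (row$op == "~~" && row$lhs == row$rhs) {
      if (row$lhs %in% model$ov) 0.5 * v_ov[row$lhs]
      else { i <- first_ind(row$lhs); if (is.na(i)) 0.5 else 0.5 * v_ov[i] }
    } else if (row$op == "~1" && row$lhs %in% model$ov) {
      m_ov[row$lhs]
    } else if (row$op == "=~") 1 else 0
  }
  # free latent means: least-squares fit of the manifest sample means under
  # the template loadings (B = 0 at start), so growth-factor means start
  # near the data rather than at zero
  mean_rows <- which(pt$free & pt$op == "~1" & pt$lhs %in% model$lv)
  if (length(mean_rows)) {
    free_lv <- unique(pt$lhs[mean_rows])
    L <- model$templates$Lambda[, free_lv, drop = FALSE]
    ok <- is.finite(m_ov)
    if (sum(ok) >= length(free_lv) && qr(L[ok, , drop = FALSE])$rank ==
        length(free_lv)) {
      resid_mean <- m_ov[ok] - model$templates$nu[ok, 1]
      a_hat <- qr.solve(L[ok, , drop = FALSE], resid_mean)
      for (r in mean_rows)
        th[match(pt$par_id[r], names(th))] <- a_hat[match(pt$lhs[r], free_lv)]
    }
  }
  th
}

num_grad <- function(f, x, h = NULL) {
  if (is.null(h)) h <- 1e-6 * (abs(x) + 1e-2)
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    g[i] <- (f(xp) - f(xm)) / (2 * h[i])
  }
  g
}

num_hessian <- function(f, x, h = NULL) {
  if (is.null(h)) h <- 1e-4 * (abs(x) + 1e-2)
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  fp <- fm <- numeric(k)
  for (i in seq_len(k)) {
    xp <- x; xp[i] <- x[i] + h[i]; fp[i] <- f(xp)
    xm <- x; xm[i] <- x[i] - h[i]; fm[i] <- f(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  for (i in seq_len(k)) for (j in seq_len(i - 1)) {
    xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
    xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
    H[i, j] <- H[j, i] <-
      (f(xpp) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + f(xmm)) /
      (2 * h[i] * h[j])
  }
  H
}

# --- saturated and baseline models -----------------------------------------

# Unrestricted conditional Gaussian model. With covariates, the joint MVN of
# (Y, X) is estimated by EM; since X is complete, the joint ML factorises
# into the (saturated) marginal of X and the unrestricted multivariate
# regression of Y on X, so the conditional log-likelihood is the joint minus
# the exact marginal of X.
sem_h1 <- function(prep) {
  Z <- cbind(prep$Y, prep$X)
  em <- em_mvn(Z)
  ll_joint <- em$loglik
  ll_x <- 0
  if (ncol(prep$X) > 0) {
    X <- prep$X
    mu <- colMeans(X)
    S <- crossprod(sweep(X, 2, mu)) / nrow(X)
    ll_x <- fiml_ll_moments_cpp(X, mu, S,
                                miss_patterns(X))
  }
  list(loglik = ll_joint - ll_x, em = em)
}

# Independence baseline: free means and variances, all covariances and
# covariate effects zero; factorises into univariate Gaussian ML fits.
sem_baseline <- function(prep) {
  ll <- 0
  for (j in seq_len(ncol(prep$Y))) {
    y <- prep$Y[, j]; y <- y[!is.na(y)]
    v <- mean((y - mean(y))^2)
    ll <- ll + sum(stats::dnorm(y, mean(y), sqrt(v), log = TRUE))
  }
  list(loglik = ll)
}

#' EM estimation of a multivariate normal with missing data
#'
#' Standard EM for the unstructured mean vector and covariance matrix under
#' missing-at-random Gaussian data; used as the saturated reference model
#' for likelihood-ratio fit statistics under missingness.
#'
#' @param Z numeric matrix with NA for missing entries
#' @param max_iter,tol iteration cap and relative log-likelihood tolerance
#' @return list with \code{mu}, \code{Sigma}, \code{loglik}, \code{iter}
#' @export
em_mvn <- function(Z, max_iter = 500, tol = 1e-10) {
  Z <- as.matrix(Z)
  d <- ncol(Z); n <- nrow(Z)
  pats <- miss_patterns(Z)
  mu <- colMeans(Z, na.rm = TRUE)
  S <- stats::cov(Z, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  diag(S)[!is.finite(diag(S)) | diag(S) <= 0] <- 1
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev)) S <- S + diag(d) * (1e-8 * max(ev) - min(ev))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    Esum <- numeric(d)
    EZZ <- matrix(0, d, d)
    for (pat in pats) {
      rows <- pat$rows + 1L; o <- pat$cols + 1L
      mset <- setdiff(seq_len(d), o)
      Zo <- Z[rows, o, drop = FALSE]
      nr <- length(rows)
      if (length(mset) == 0) {
        Esum <- Esum + colSums(Zo)
        EZZ <- EZZ + crossprod(Zo)
        next
      }
      Soo <- S[o, o, drop = FALSE]
      K <- S[mset, o, drop = FALSE] %*% solve(Soo)
      cond_cov <- S[mset, mset, drop = FALSE] -
        K %*% S[o, mset, drop = FALSE]
      Em <- matrix(mu[mset], nr, length(mset), byrow = TRUE) +
        sweep(Zo, 2, mu[o]) %*% t(K)
      full <- matrix(0, nr, d)
      full[, o] <- Zo; full[, mset] <- Em
      Esum <- Esum + colSums(full)
      cp <- crossprod(full)
      cp[mset, mset] <- cp[mset, mset, drop = FALSE] + nr * cond_cov
      EZZ <- EZZ + cp
    }
    mu <- Esum / n
    S <- EZZ / n - tcrossprod(mu)
    S <- (S + t(S)) / 2
    ll <- fiml_ll_moments_cpp(Z, mu, S, pats)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = S, loglik = ll, iter = it)
}

# --- fit indices ------------------------------------------------------------

#' Likelihood-ratio fit statistics and indices
#'
#' Computes the chi-square statistic against the saturated model, its
#' degrees of freedom and p-value, RMSEA and CFI. RMSEA =
#' \code{sqrt(max(T - df, 0) / (df * n))} with n the number of analysis
#' rows (persons); CFI = \code{1 - max(T - df, 0) / max(Tb - dfb, T - df,
#' 0)}. With df = 0 the model is saturated: RMSEA 0, CFI 1.
#'
#' @param fit a \code{semfit}
#' @return named list: \code{T}, \code{df}, \code{p}, \code{rmsea},
#'   \code{cfi}
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "semfit"))
  fit_indices_values(fit$Tstat, fit$df, fit$n, fit$T_baseline,
                     fit$df_baseline)
}

fit_indices_values <- function(T, df, n, Tb, dfb) {
  if (df <= 0) return(list(T = T, df = df, p = NA_real_, rmsea = 0, cfi = 1))
  rmsea <- sqrt(max(T - df, 0) / (df * n))
  denom <- max(Tb - dfb, T - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(T - df, 0) / denom
  list(T = T, df = df, p = stats::pchisq(T, df, lower.tail = FALSE),
       rmsea = rmsea, cfi = min(max(cfi, 0), 1))
}

# --- covariance of estimates ------------------------------------------------

#' Covariance matrix of SEM estimates
#'
#' Ordinary covariance is the inverse observed information. With
#' \code{robust = TRUE}, a cluster sandwich is returned: \eqn{A^{-1} B
#' A^{-1}} with A the observed information and B the outer product of
#' per-cluster score sums, scaled by G/(G-1) for G clusters. Without a
#' cluster variable each row is its own cluster.
#'
#' @param object a \code{semfit}
#' @param robust logical, cluster-robust sandwich?
#' @param ... unused
#' @export
vcov.semfit <- function(object, robust = FALSE, ...) {
  key <- if (robust) "vcov_robust" else "vcov"
  if (!is.null(object$cache[[key]])) return(object$cache[[key]])
  A <- sem_information(object)
  Ainv <- tryCatch(solve(A), error = function(e) {
    warning("observed information is singular; using pseudo-inverse")
    pseudo_inverse(A)
  })
  V <- if (!robust) Ainv else {
    sc <- sem_scores(object)  # n x k casewise scores of logLik
    cl <- object$prep$cluster
    if (is.null(cl)) cl <- as.character(seq_len(nrow(sc)))
    g <- rowsum(sc, cl)
    G <- nrow(g)
    B <- crossprod(g) * G / max(G - 1, 1)
    Ainv %*% B %*% Ainv
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(object$model$theta_names, object$model$theta_names)
  object$cache[[key]] <- V
  V
}

sem_information <- function(fit) {
  if (!is.null(fit$cache$info)) return(fit$cache$info)
  model <- fit$model; prep <- fit$prep
  grad <- function(th) fiml_negll_grad_cpp(th, model$templates, model$fmap,
                                           prep$Y, prep$X, prep$patterns)$grad
  # central differences of the analytic gradient
  th <- fit$theta
  h <- 1e-5 * (abs(th) + 1e-2)
  k <- length(th)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    tp <- th; tp[i] <- th[i] + h[i]
    tm <- th; tm[i] <- th[i] - h[i]
    H[, i] <- (grad(tp) - grad(tm)) / (2 * h[i])
  }
  H <- (H + t(H)) / 2
  fit$cache$info <- H
  H
}

# casewise score matrix (derivatives of each row's log-likelihood)
sem_scores <- function(fit) {
  if (!is.null(fit$cache$scores)) return(fit$cache$scores)
  model <- fit$model; prep <- fit$prep
  th <- fit$theta
  k <- length(th)
  h <- 1e-6 * (abs(th) + 1e-2)
  sc <- matrix(0, nrow(prep$Y), k)
  for (i in seq_len(k)) {
    tp <- th; tp[i] <- th[i] + h[i]
    tm <- th; tm[i] <- th[i] - h[i]
    cp <- fiml_casewise_cpp(tp, model$templates, model$fmap, prep$Y, prep$X,
                            prep$patterns)
    cm <- fiml_casewise_cpp(tm, model$templates, model$fmap, prep$Y, prep$X,
                            prep$patterns)
    sc[, i] <- (cp - cm) / (2 * h[i])
  }
  fit$cache$scores <- sc
  sc
}

pseudo_inverse <- function(A, tol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  pos <- abs(e$values) > tol * max(abs(e$values))
  e$vectors[, pos, drop = FALSE] %*%
    diag(1 / e$values[pos], sum(pos)) %*% t(e$vectors[, pos, drop = FALSE])
}

# --- parameter summary, standardization, defined quantities -----------------

#' @export
coef.semfit <- function(object, ...) object$theta

#' @export
logLik.semfit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' Parameter estimates with standard errors and tests
#'
#' @param fit a \code{semfit}
#' @param robust use cluster-robust standard errors (default TRUE when the
#'   fit carries a cluster variable)
#' @return data.frame: parameter, estimate, se, z, p, std (standardized
#'   estimate)
#' @export
sem_estimates <- function(fit, robust = !is.null(fit$prep$cluster)) {
  V <- vcov(fit, robust = robust)
  se <- sqrt(pmax(diag(V), 0))
  z <- fit$theta / ifelse(se > 0, se, NA_real_)
  std <- standardize(fit)
  std_par <- std$std[match(fit$model$theta_names, std$par_id)]
  data.frame(parameter = fit$model$theta_names, estimate = unname(fit$theta),
             se = unname(se), z = unname(z),
             p = 2 * stats::pnorm(-abs(unname(z))),
             std = unname(std_par), stringsAsFactors = FALSE)
}

#' Standardized estimates
#'
#' Scales loadings, regressions and covariances by model-implied standard
#' deviations of source and target variables (covariate standard deviations
#' from the data); variances become proportions of total variance.
#' Covariate-explained latent variance is included in the implied totals.
#'
#' @param fit a \code{semfit}
#' @return data.frame, one row per parameter-table row, with \code{std}
#' @export
standardize <- function(fit) {
  model <- fit$model
  imp <- implied_moments(model, fit$theta)
  m <- length(model$lv)
  IB <- solve(diag(m) - imp$B)
  q <- length(model$exo)
  Sx <- if (q > 0) {
    X <- fit$prep$X
    crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  } else matrix(0, 0, 0)
  V_lat <- IB %*% (imp$Psi + if (q > 0)
    imp$Gamma %*% Sx %*% t(imp$Gamma) else 0 * imp$Psi) %*% t(IB)
  Sig_tot <- imp$Lambda %*% V_lat %*% t(imp$Lambda) + imp$Theta
  sd_lv <- sqrt(pmax(diag(V_lat), 0)); names(sd_lv) <- model$lv
  sd_ov <- sqrt(pmax(diag(Sig_tot), 0)); names(sd_ov) <- model$ov
  sd_x <- if (q > 0) sqrt(diag(Sx)) else numeric(0)
  if (q > 0) names(sd_x) <- model$exo
  sd_of <- function(v) {
    if (v %in% model$lv) sd_lv[[v]]
    else if (v %in% model$ov) sd_ov[[v]]
    else sd_x[[v]]
  }
  pt <- model$ptable
  est <- ifelse(pt$free, fit$theta[match(pt$par_id, model$theta_names)],
                pt$value)
  std <- rep(NA_real_, nrow(pt))
  for (r in seq_len(nrow(pt))) {
    lhs <- pt$lhs[r]; rhs <- pt$rhs[r]; op <- pt$op[r]
    std[r] <- switch(op,
      "=~" = { d <- sd_of(rhs)
               if (d > 0) est[r] * sd_of(lhs) / d else NA_real_ },
      "~"  = { d <- sd_of(lhs)
               if (d > 0) est[r] * sd_of(rhs) / d else NA_real_ },
      "~~" = { d <- sd_of(lhs) * sd_of(rhs)
               if (d > 0) est[r] / d else NA_real_ },
      "~1" = { d <- sd_of(lhs); if (d > 0) est[r] / d else NA_real_ })
  }
  out <- data.frame(lhs = pt$lhs, op = pt$op, rhs = pt$rhs,
                    par_id = pt$par_id, est = est, std = std,
                    stringsAsFactors = FALSE)
  out
}

#' Defined quantities with delta-method standard errors
#'
#' Evaluates \code{":="} rows of the parameter table (arithmetic
#' expressions in parameter labels) at the estimates, with first-order
#' delta-method variances \eqn{g^T V g}.
#'
#' @param fit a \code{semfit}
#' @param robust use cluster-robust covariance
#' @return data.frame: name, estimate, se, z, p
#' @export
sem_defined <- function(fit, robust = !is.null(fit$prep$cluster)) {
  defs <- fit$model$defined
  if (nrow(defs) == 0)
    return(data.frame(name = character(0), estimate = numeric(0),
                      se = numeric(0), z = numeric(0), p = numeric(0)))
  V <- vcov(fit, robust = robust)
  th <- fit$theta
  evalq_ <- function(expr_str, theta) {
    eval(parse(text = expr_str)[[1]], envir = as.list(theta))
  }
  out <- lapply(seq_len(nrow(defs)), function(i) {
    f <- function(t) { names(t) <- names(th); evalq_(defs$rhs[i], t) }
    val <- f(th)
    g <- num_grad(f, th)
    se <- sqrt(max(0, drop(t(g) %*% V %*% g)))
    z <- if (se > 0) val / se else NA_real_
    data.frame(name = defs$lhs[i], estimate = val, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.semfit <- function(x, ...) {
  fi <- fit_indices(x)
  cat("semfit:", x$npar, "free parameters, n =", x$n,
      if (!x$converged) "(NOT CONVERGED)" else "", "\n")
  cat(sprintf("  logLik %.3f | chisq %.3f on %d df (p = %.3g) | RMSEA %.4f | CFI %.4f\n",
              x$loglik, fi$T, fi$df, fi$p, fi$rmsea, fi$cfi))
  invisible(x)
}

#' @export
summary.semfit <- function(object, robust = !is.null(object$prep$cluster),
                           ...) {
  out <- list(fit = object, indices = fit_indices(object),
              estimates = sem_estimates(object, robust = robust),
              defined = sem_defined(object, robust = robust),
              robust = robust)
  class(out) <- "summary.semfit"
  out
}

#' @export
print.summary.semfit <- function(x, ...) {
  print(x$fit)
  cat("\nEstimates (", if (x$robust) "cluster-robust" else "ordinary",
      " SEs):\n", sep = "")
  print(x$estimates, digits = 4, row.names = FALSE)
  if (nrow(x$defined)) {
    cat("\nDefined quantities:\n")
    print(x$defined, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Export a fitted SEM as tables
#'
#' Writes the estimate table as TSV and a JSON fit summary next to it.
#' @param fit a \code{semfit}
#' @param path_tsv,path_json output paths
#' @export
write_semfit <- function(fit, path_tsv, path_json) {
  est <- sem_estimates(fit)
  utils::write.table(est, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fi <- fit_indices(fit)
  jsonlite::write_json(list(loglik = fit$loglik, npar = fit$npar, n = fit$n,
                            converged = fit$converged, chisq = fi$T,
                            df = fi$df, p = fi$p, rmsea = fi$rmsea,
                            cfi = fi$cfi),
                       path_json, auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

modify_defaults <- function(defaults, x) {
  stopifnot(is.list(x))
  defaults[names(x)] <- x
  defaults
}
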