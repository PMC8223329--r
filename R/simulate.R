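# Twin-cohort simulator with a bivariate ALT-SR data-generating process.
#
# The generator is the package's ground truth: methylation (on a latent
# logit scale) and one cardiometabolic trait follow a latent growth curve
# plus a first-order autoregressive/cross-lagged process on the
# occasion-specific residuals. Co-twin resemblance enters through a
# pair-level share of the latent intercept variance (MZ > DZ).

#' Assessment-occasion schedule
#'
#' Ordered occasion labels with linear-growth slope loadings; the default
#' is the five in-person-testing waves IPT3, IPT5, IPT6, IPT8, IPT9 with
#' loadings 0, 2, 3, 5, 6 (the time metric, in years from the first
#' occasion).
#'
#' @param labels character vector of occasion identifiers
#' @param loadings numeric slope loadings, strictly increasing, first 0
#' @export
occasion_schedule <- function(labels = c("IPT3", "IPT5", "IPT6", "IPT8", "IPT9"),
                              loadings = c(0, 2, 3, 5, 6)) {
  stopifnot(length(labels) == length(loadings), length(labels) >= 2)
  if (loadings[1] != 0) stop("first slope loading must be 0")
  if (any(diff(loadings) <= 0)) stop("slope loadings must be strictly increasing")
  structure(list(labels = as.character(labels), loadings = as.numeric(loadings)),
            class = "occasion_schedule")
}

#' Generative parameters of the bivariate ALT-SR process
#'
#' @param mu numeric length 4: latent means of (methylation intercept,
#'   methylation slope, trait intercept, trait slope); methylation on its
#'   latent (logit) scale, trait in trait units
#' @param psi 4x4 covariance of the growth factors (same ordering)
#' @param a,c autoregressive coefficients per transition (methylation and
#'   trait); \code{|a|, |c| < 1}
#' @param b cross-lag, trait residual into next methylation residual
#' @param d cross-lag, methylation residual into next trait residual
#' @param sigma_e1 2x2 first-occasion residual covariance (methylation,
#'   trait)
#' @param sigma_e 2x2 innovation covariance for later occasions
#' @param beta_cov optional 4xq matrix of covariate effects on the growth
#'   factors (columns named by covariate)
#' @param pair_icc_mz,pair_icc_dz share of intercept variance common to
#'   co-twins; \code{pair_icc_mz >= pair_icc_dz >= 0}
#' @export
altsr_params <- function(mu = c(0, 0.01, 0, 0),
                         psi = diag(c(0.09, 4e-4, 1, 0.01)),
                         a = 0.2, b = 0, c = 0.35, d = 0.25,
                         sigma_e1 = diag(c(0.0225, 0.3)),
                         sigma_e = diag(c(0.0225, 0.3)),
                         beta_cov = NULL,
                         pair_icc_mz = 0.5, pair_icc_dz = 0.25) {
  psi <- as.matrix(psi); sigma_e1 <- as.matrix(sigma_e1)
  sigma_e <- as.matrix(sigma_e)
  check_psd <- function(M, name, dim) {
    if (!all(dim(M) == dim)) stop(name, " must be ", dim[1], "x", dim[2])
    if (max(abs(M - t(M))) > 1e-10) stop(name, " must be symmetric")
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop(name, " must be positive semi-definite")
  }
  check_psd(psi, "psi", c(4, 4))
  check_psd(sigma_e1, "sigma_e1", c(2, 2))
  check_psd(sigma_e, "sigma_e", c(2, 2))
  if (abs(a) >= 1 || abs(c) >= 1)
    stop("|a| and |c| must be < 1 for a stationary residual process")
  if (!(pair_icc_mz >= pair_icc_dz && pair_icc_dz >= 0 && pair_icc_mz <= 1))
    stop("need pair_icc_mz >= pair_icc_dz >= 0 (and <= 1)")
  if (!is.null(beta_cov)) {
    beta_cov <- as.matrix(beta_cov)
    if (nrow(beta_cov) != 4) stop("beta_cov must have 4 rows")
  }
  structure(list(mu = mu, psi = psi, a = a, b = b, c = c, d = d,
                 sigma_e1 = sigma_e1, sigma_e = sigma_e,
                 beta_cov = beta_cov, pair_icc_mz = pair_icc_mz,
                 pair_icc_dz = pair_icc_dz),
            class = "altsr_params")
}

rmvn <- function(n, mu, S) {
  d <- length(mu)
  if (d == 0) return(matrix(0, n, 0))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(ev), d)
  sweep(matrix(stats::rnorm(n * d), n, d) %*% t(L), 2, mu, `+`)
}

#' Simulate paired latent trajectories from the bivariate ALT-SR process
#'
#' For each subject and occasion t, observed = intercept + loading_t * slope
#' + covariate effects + e_t, where e_1 ~ N(0, sigma_e1) and
#' e_t = A e_(t-1) + innovation with A = rbind(c(a, b), c(d, c)) (b maps the
#' trait residual into methylation, d maps the methylation residual into
#' the trait).
#'
#' @param params an [altsr_params()]
#' @param schedule an [occasion_schedule()]
#' @param n_subjects number of subjects
#' @param covariates optional data.frame (n_subjects rows) whose columns
#'   match \code{colnames(params$beta_cov)}
#' @param seed integer seed; the output is a deterministic function of it
#' @param pair_id optional pair identifier per subject (co-twins share a
#'   pair-level intercept component)
#' @param icc per-subject intercept-variance share for the pair component
#'   (0 for independent subjects)
#' @return list: \code{dnam}, \code{trait} (n x T matrices, latent/linear
#'   scale), \code{latent} (growth factors), \code{resid_dnam},
#'   \code{resid_trait}
#' @export
simulate_bivariate_altsr <- function(params, schedule = occasion_schedule(),
                                     n_subjects, covariates = NULL,
                                     seed = NULL, pair_id = NULL, icc = 0) {
  stopifnot(inherits(params, "altsr_params"),
            inherits(schedule, "occasion_schedule"), n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  lam <- schedule$loadings
  T_ <- length(lam)
  n <- n_subjects
  mu_eta <- matrix(params$mu, n, 4, byrow = TRUE)
  if (!is.null(params$beta_cov)) {
    if (is.null(covariates)) stop("params carry beta_cov but no covariates given")
    X <- as.matrix(covariates[, colnames(params$beta_cov), drop = FALSE])
    mu_eta <- mu_eta + X %*% t(params$beta_cov)
  }
  icc <- rep(icc, length.out = n)
  psi <- params$psi
  if (is.null(pair_id) || all(icc == 0)) {
    eta <- mu_eta + rmvn(n, rep(0, 4), psi)
  } else {
    # split the intercept block (coords 1 and 3) into a pair-shared and an
    # individual component; marginal covariance stays psi
    eta <- matrix(0, n, 4)
    for (lev in unique(icc)) {
      idx <- which(icc == lev)
      Sh <- matrix(0, 4, 4)
      Sh[c(1, 3), c(1, 3)] <- lev * psi[c(1, 3), c(1, 3)]
      Un <- psi - Sh
      if (min(eigen(Un, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
        stop("psi minus pair-shared intercept block is not PSD; lower the ICC")
      pid <- pair_id[idx]
      upid <- unique(pid)
      shared <- rmvn(length(upid), rep(0, 4), Sh)
      eta[idx, ] <- shared[match(pid, upid), , drop = FALSE] +
        rmvn(length(idx), rep(0, 4), Un)
    }
    eta <- eta + mu_eta
  }
  A <- rbind(c(params$a, params$b), c(params$d, params$c))
  e_m <- matrix(0, n, T_); e_r <- matrix(0, n, T_)
  e1 <- rmvn(n, c(0, 0), params$sigma_e1)
  e_m[, 1] <- e1[, 1]; e_r[, 1] <- e1[, 2]
  for (t in 2:T_) {
    z <- rmvn(n, c(0, 0), params$sigma_e)
    prev <- cbind(e_m[, t - 1], e_r[, t - 1])
    cur <- prev %*% t(A) + z
    e_m[, t] <- cur[, 1]; e_r[, t] <- cur[, 2]
  }
  dnam <- eta[, 1] + outer(eta[, 2], lam) + e_m
  trait <- eta[, 3] + outer(eta[, 4], lam) + e_r
  colnames(dnam) <- colnames(trait) <- schedule$labels
  latent <- data.frame(i_m = eta[, 1], s_m = eta[, 2],
                       i_rf = eta[, 3], s_rf = eta[, 4])
  list(dnam = dnam, trait = trait, latent = latent,
       resid_dnam = e_m, resid_trait = e_r)
}

#' Default generative settings per cardiometabolic trait
#'
#' Intercept/slope means and variances and residual variances in the
#' trait's customary units (lipids mmol/L, blood pressure mmHg, BMI
#' kg/m^2); slopes are per unit of the loading metric (years).
#' @return data.frame keyed by trait
#' @export
trait_defaults <- function() {
  data.frame(
    trait = c("TC", "LDL", "HDL", "TG", "SBP", "DBP", "BMI"),
    i_mean = c(6.2, 4.1, 1.4, 1.4, 145, 85, 26),
    s_mean = c(-0.03, -0.03, -0.005, 0.01, 0.3, -0.2, 0.05),
    i_var = c(1.0, 0.81, 0.12, 0.36, 324, 81, 12.3),
    s_var = c(0.0025, 0.0025, 4e-4, 9e-4, 1.0, 0.25, 0.0225),
    e_var = c(0.3, 0.25, 0.0225, 0.2, 100, 36, 0.81),
    lipid = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for a synthetic twin cohort
#'
#' Defaults emulate the SATSA-like study composition: 83 MZ pairs, 155 DZ
#' pairs and 59 single twins (535 individuals), baseline age 72.7 (SD 9.3)
#' years, 58.5\% female.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons twin composition
#' @param baseline_age_mean,baseline_age_sd years
#' @param female_prop fraction female
#' @param smoking_probs initial probabilities of (non, ex, current) smoker
#' @param smoking_switch_prob per-occasion probability of moving category
#' @param statin_prop fraction of statin-ever users
#' @param n_null_cpgs,n_signal_cpgs CpG panel composition; signal CpGs are
#'   coupled to one trait each (round-robin over \code{signal_traits})
#' @param signal_traits traits to couple signal CpGs to
#' @param signal_params [altsr_params()] for signal CpG-trait pairs (the
#'   methylation margin; trait margins are rescaled per trait_defaults)
#' @param pair_icc_mz,pair_icc_dz co-twin intercept-variance shares
#' @param event_models list of event-model specifications, see
#'   [assign_events()]
#' @param satsa_missingness apply the SATSA pattern (HDL/LDL absent at the
#'   first occasion; methylation retained with probability 0.5 per
#'   occasion)
#' @param seed integer; fully determines the cohort
#' @export
sim_config <- function(n_mz_pairs = 83, n_dz_pairs = 155, n_singletons = 59,
                       baseline_age_mean = 72.7, baseline_age_sd = 9.3,
                       female_prop = 0.585,
                       smoking_probs = c(0.55, 0.29, 0.16),
                       smoking_switch_prob = 0.1,
                       statin_prop = 0.18,
                       n_null_cpgs = 195, n_signal_cpgs = 5,
                       signal_traits = c("TC", "LDL", "SBP", "DBP", "BMI"),
                       signal_params = altsr_params(),
                       pair_icc_mz = 0.5, pair_icc_dz = 0.25,
                       event_models = default_event_models(),
                       satsa_missingness = TRUE,
                       schedule = occasion_schedule(),
                       seed = 1) {
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0, n_singletons >= 0,
            n_null_cpgs >= 0, n_signal_cpgs >= 0,
            female_prop >= 0, female_prop <= 1,
            statin_prop >= 0, statin_prop <= 1,
            abs(sum(smoking_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

#' Default event models for the three outcome categories
#'
#' Logistic links from the first signal CpG's latent growth factors to the
#' per-person event probability; intercepts set so marginal prevalences are
#' near the study's 39.6/20.2/15.9 percent. The diagnosis-age window spans
#' 2 years before baseline to 4 years past the last occasion so that some
#' diagnoses precede all occasions and some fall between occasions.
#' @export
default_event_models <- function() {
  mk <- function(cat, int) list(category = cat, intercept = int,
                                coef = c(i_m = 0.9, s_m = 1.5, i_rf = 0,
                                         s_rf = 0),
                                cpg = 1L, age_window = c(-2, 10))
  list(mk("non-stroke CVD", -0.42), mk("overall stroke", -1.38),
       mk("ischemic stroke", -1.67))
}

#' Simulate a complete twin cohort
#'
#' Generates individuals (MZ/DZ pairs plus singletons), longitudinal trait
#' records, a methylation beta matrix, events, and the simulation truth.
#' Signal CpGs follow the bivariate ALT-SR process coupled to one trait
#' each; null CpGs have all dynamic paths at zero and no outcome link.
#' Latent methylation is mapped to the beta scale by the inverse logit
#' (clipped to [0.001, 0.999] as a guard).
#'
#' @param config a [sim_config()]
#' @return an object of class \code{twin_cohort}
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sch <- config$schedule
  T_ <- length(sch$labels)
  td <- trait_defaults()

  # individuals -------------------------------------------------------------
  n_pairs <- config$n_mz_pairs + config$n_dz_pairs
  n <- 2 * n_pairs + config$n_singletons
  person <- sprintf("P%04d", seq_len(n))
  pair <- character(n); zyg <- character(n)
  k <- 0
  if (n_pairs > 0) {
    pair[seq_len(2 * n_pairs)] <- rep(sprintf("T%04d", seq_len(n_pairs)),
                                      each = 2)
    zyg[seq_len(2 * n_pairs)] <- rep(c(rep("MZ", config$n_mz_pairs),
                                       rep("DZ", config$n_dz_pairs)), each = 2)
    k <- 2 * n_pairs
  }
  if (config$n_singletons > 0) {
    idx <- (k + 1):n
    pair[idx] <- sprintf("S%04d", seq_along(idx))
    # singleton zygosity split to emulate the study's 187 MZ / 347 DZ /
    # 1 unknown individual composition (21, 37, 1 among 59 singletons)
    ns <- config$n_singletons
    n_unk <- if (ns >= 3) 1L else 0L
    n_mz_s <- round((ns - n_unk) * 21 / 58)
    zyg[idx] <- c(rep("MZ", n_mz_s), rep("DZ", ns - n_unk - n_mz_s),
                  rep("unknown", n_unk))
  }
  sex <- stats::rbinom(n, 1, config$female_prop)      # female = 1
  bage_pair <- stats::rnorm(n_pairs, config$baseline_age_mean,
                            config$baseline_age_sd)
  bage <- c(rep(bage_pair, each = 2),
            stats::rnorm(config$n_singletons, config$baseline_age_mean,
                         config$baseline_age_sd))[seq_len(n)]
  statin <- stats::rbinom(n, 1, config$statin_prop)
  individuals <- data.frame(person = person, pair = pair, zygosity = zyg,
                            sex = sex, baseline_age = bage,
                            statin_ever = statin, stringsAsFactors = FALSE)
  icc <- ifelse(zyg == "MZ", config$pair_icc_mz,
                ifelse(zyg == "DZ", config$pair_icc_dz, 0))

  # smoking: persistent category with small per-occasion switch probability
  smoke <- matrix(0L, n, T_)
  smoke[, 1] <- sample.int(3, n, replace = TRUE, prob = config$smoking_probs)
  for (t in 2:T_) {
    switch_ <- stats::runif(n) < config$smoking_switch_prob
    smoke[, t] <- ifelse(switch_, sample.int(3, n, replace = TRUE),
                         smoke[, t - 1])
  }

  # traits and signal CpGs ---------------------------------------------------
  sig_traits <- rep(config$signal_traits,
                    length.out = max(config$n_signal_cpgs, 1))
  cpg_sig <- if (config$n_signal_cpgs > 0)
    sprintf("cgS%05d", seq_len(config$n_signal_cpgs)) else character(0)
  cpg_null <- if (config$n_null_cpgs > 0)
    sprintf("cgN%05d", seq_len(config$n_null_cpgs)) else character(0)
  cpgs <- c(cpg_sig, cpg_null)

  trait_vals <- list()   # trait -> n x T matrix
  meth_lat <- list()     # cpg  -> n x T latent matrix
  truth_lat <- list()
  base <- config$signal_params

  trait_par <- function(tr, coupled) {
    row <- td[td$trait == tr, ]
    mu <- c(base$mu[1], base$mu[2], row$i_mean, row$s_mean)
    psi <- base$psi
    psi[3, 3] <- row$i_var; psi[4, 4] <- row$s_var
    # mild positive intercept-slope coupling within construct
    psi[1, 2] <- psi[2, 1] <- 0.2 * sqrt(psi[1, 1] * psi[2, 2])
    psi[3, 4] <- psi[4, 3] <- 0.2 * sqrt(psi[3, 3] * psi[4, 4])
    se1 <- base$sigma_e1; se <- base$sigma_e
    se1[2, 2] <- se[2, 2] <- row$e_var
    # cross-lags act on the trait's own scale: d is stated per unit of the
    # (small) latent methylation residual, scaled into trait units so the
    # standardized effect is comparable across traits
    d_scaled <- if (coupled) base$d * sqrt(row$e_var / base$sigma_e[2, 2]) else 0
    b_scaled <- if (coupled) base$b * sqrt(base$sigma_e[1, 1] / row$e_var) else 0
    altsr_params(mu = mu, psi = psi, a = if (coupled) base$a else 0,
                 b = b_scaled, c = base$c, d = d_scaled,
                 sigma_e1 = se1, sigma_e = se,
                 pair_icc_mz = config$pair_icc_mz,
                 pair_icc_dz = config$pair_icc_dz)
  }

  # one generative stream per trait; the first signal CpG assigned to a
  # trait is the coupled methylation margin, further CpGs on the same trait
  # get their own stream (their coupling refers to a latent trait copy)
  all_traits <- td$trait
  trait_owner <- rep(NA_integer_, length(all_traits))
  names(trait_owner) <- all_traits
  for (j in seq_len(config$n_signal_cpgs)) {
    tr <- sig_traits[j]
    if (is.na(trait_owner[tr])) trait_owner[tr] <- j
  }
  for (tr in all_traits) {
    owner <- trait_owner[tr]
    coupled <- !is.na(owner)
    pp <- trait_par(tr, coupled)
    sim <- simulate_bivariate_altsr(pp, sch, n, seed = NULL,
                                    pair_id = pair, icc = icc)
    trait_vals[[tr]] <- sim$trait
    if (coupled) {
      cg <- cpg_sig[owner]
      meth_lat[[cg]] <- sim$dnam
      truth_lat[[cg]] <- data.frame(person = person, cpg = cg, trait = tr,
                                    sim$latent, stringsAsFactors = FALSE)
    }
  }
  # remaining signal CpGs (trait already owned): independent coupled stream
  for (j in seq_len(config$n_signal_cpgs)) {
    cg <- cpg_sig[j]
    if (!is.null(meth_lat[[cg]])) next
    tr <- sig_traits[j]
    sim <- simulate_bivariate_altsr(trait_par(tr, TRUE), sch, n, seed = NULL,
                                    pair_id = pair, icc = icc)
    meth_lat[[cg]] <- sim$dnam
    truth_lat[[cg]] <- data.frame(person = person, cpg = cg, trait = tr,
                                  sim$latent, stringsAsFactors = FALSE)
  }
  # null CpGs: no dynamics, no coupling, no outcome link
  null_par <- altsr_params(mu = c(base$mu[1], base$mu[2], 0, 0),
                           psi = base$psi, a = 0, b = 0, c = 0, d = 0,
                           sigma_e1 = base$sigma_e1, sigma_e = base$sigma_e,
                           pair_icc_mz = config$pair_icc_mz,
                           pair_icc_dz = config$pair_icc_dz)
  for (cg in cpg_null) {
    sim <- simulate_bivariate_altsr(null_par, sch, n, seed = NULL,
                                    pair_id = pair, icc = icc)
    meth_lat[[cg]] <- sim$dnam
  }

  # longitudinal table -------------------------------------------------------
  longi <- data.frame(
    person = rep(person, times = T_),
    occasion = rep(sch$labels, each = n),
    age = rep(bage, times = T_) + rep(sch$loadings, each = n),
    smoking = as.integer(smoke),
    stringsAsFactors = FALSE)
  for (tr in all_traits) longi[[tr]] <- as.numeric(trait_vals[[tr]])
  ord <- order(longi$person, match(longi$occasion, sch$labels))
  longi <- longi[ord, ]
  rownames(longi) <- NULL

  # methylation beta matrix --------------------------------------------------
  sample_id <- paste(rep(person, times = T_), rep(sch$labels, each = n),
                     sep = "_")
  beta <- matrix(NA_real_, n * T_, length(cpgs),
                 dimnames = list(sample_id, cpgs))
  for (cg in cpgs)
    beta[, cg] <- pmin(pmax(stats::plogis(as.numeric(meth_lat[[cg]])),
                            0.001), 0.999)
  samples <- data.frame(sample_id = sample_id,
                        person = rep(person, times = T_),
                        occasion = rep(sch$labels, each = n),
                        age = rep(bage, times = T_) + rep(sch$loadings, each = n),
                        stringsAsFactors = FALSE)
  ord <- order(samples$person, match(samples$occasion, sch$labels))
  samples <- samples[ord, ]; beta <- beta[samples$sample_id, , drop = FALSE]
  rownames(samples) <- NULL

  truth <- list(latent = do.call(rbind, truth_lat),
                signal_cpgs = cpg_sig, signal_traits = sig_traits,
                params = base)
  cohort <- structure(list(individuals = individuals, longitudinal = longi,
                           methylation = beta, samples = samples,
                           events = NULL, truth = truth, schedule = sch,
                           config = config),
                      class = "twin_cohort")
  ev_models <- config$event_models
  if (config$n_signal_cpgs == 0) {
    # no latent truth to link to: events depend on the intercept alone
    ev_models <- lapply(ev_models, function(m) {
      m$coef[] <- 0
      m
    })
  }
  cohort <- assign_events(cohort, ev_models, seed = NULL)
  if (config$satsa_missingness)
    cohort <- apply_missingness(cohort, missingness_satsa(sch), seed = NULL)
  cohort
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat("twin_cohort:", nrow(x$individuals), "individuals,",
      ncol(x$methylation), "CpGs,",
      sum(!is.na(x$methylation[, 1])), "methylation samples\n")
  if (!is.null(x$events))
    for (cat_ in unique(x$events$category))
      cat(sprintf("  %s: %d events\n", cat_,
                  sum(x$events$event[x$events$category == cat_])))
  invisible(x)
}

#' Assign disease events from the latent simulation truth
#'
#' Per outcome category, an event indicator is drawn from a logistic
#' function of the designated signal CpG's latent growth factors; diagnosis
#' age is uniform over \code{baseline_age + age_window}, so that some
#' diagnoses precede all occasions and some fall between occasions.
#'
#' @param cohort a \code{twin_cohort} carrying simulation truth
#' @param event_models list of models: \code{category}, \code{intercept}
#'   (logit scale; -Inf/Inf allowed), \code{coef} (named vector over i_m,
#'   s_m, i_rf, s_rf), \code{cpg} (index or id of the signal CpG whose
#'   latents drive the risk), \code{age_window}
#' @param seed optional seed (NULL continues the current RNG stream)
#' @export
assign_events <- function(cohort, event_models, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort$individuals)
  ev <- list()
  for (m in event_models) {
    if (is.null(m$category)) stop("event model lacks a category name")
    eta <- rep(m$intercept, n)
    if (any(m$coef != 0)) {
      for (cg in m$cpg) {   # risk may sum over several signal CpGs
        lat <- event_latents(cohort, modifyList(m, list(cpg = cg)))
        eta <- eta + as.matrix(lat[, names(m$coef)]) %*% m$coef
      }
    }
    p <- stats::plogis(eta)
    event <- stats::rbinom(n, 1, p)
    dage <- ifelse(event == 1,
                   cohort$individuals$baseline_age +
                     stats::runif(n, m$age_window[1], m$age_window[2]),
                   NA_real_)
    ev[[m$category]] <- data.frame(
      person = cohort$individuals$person, category = m$category,
      event = event, diagnosis_age = dage,
      censored_age = cohort$individuals$baseline_age +
        max(cohort$schedule$loadings),
      stringsAsFactors = FALSE)
  }
  cohort$events <- do.call(rbind, ev)
  rownames(cohort$events) <- NULL
  cohort
}

event_latents <- function(cohort, m) {
  tl <- cohort$truth$latent
  if (is.null(tl)) stop("cohort carries no simulation truth; cannot link events")
  cg <- if (is.numeric(m$cpg)) cohort$truth$signal_cpgs[m$cpg] else m$cpg
  if (is.na(cg) || !cg %in% tl$cpg) stop("unknown signal CpG for event model: ",
                                         m$cpg)
  lat <- tl[tl$cpg == cg, ]
  lat[match(cohort$individuals$person, lat$person), ]
}

#' Missingness rules and the SATSA preset
#'
#' Rules are a data.frame (variable, occasion, retention) giving the
#' probability that a value is retained; unlisted combinations are retained
#' with probability 1. The variable \code{"methylation"} masks whole
#' methylation samples. The SATSA preset drops HDL and LDL entirely at the
#' first occasion and retains methylation samples with probability 0.5 per
#' occasion (so half the persons keep >= 3 of 5 measurements).
#'
#' @param schedule an [occasion_schedule()]
#' @export
missingness_satsa <- function(schedule = occasion_schedule()) {
  first <- schedule$labels[1]
  rbind(data.frame(variable = c("HDL", "LDL"), occasion = first,
                   retention = 0, stringsAsFactors = FALSE),
        data.frame(variable = "methylation", occasion = schedule$labels,
                   retention = 0.5, stringsAsFactors = FALSE))
}

#' Apply missingness rules to a cohort
#' @param cohort a \code{twin_cohort}
#' @param rules data.frame (variable, occasion, retention), see
#'   [missingness_satsa()]
#' @param seed optional seed
#' @export
apply_missingness <- function(cohort, rules, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("variable", "occasion", "retention") %in% names(rules)))
  if (any(rules$retention < 0 | rules$retention > 1))
    stop("retention probabilities must be in [0, 1]")
  for (r in seq_len(nrow(rules))) {
    v <- rules$variable[r]; occ <- rules$occasion[r]
    p <- rules$retention[r]
    if (v == "methylation") {
      idx <- which(cohort$samples$occasion == occ)
      drop_ <- idx[stats::runif(length(idx)) >= p]
      if (length(drop_)) cohort$methylation[drop_, ] <- NA_real_
    } else {
      if (!v %in% names(cohort$longitudinal))
        stop("unknown variable in missingness rules: ", v)
      idx <- which(cohort$longitudinal$occasion == occ)
      drop_ <- idx[stats::runif(length(idx)) >= p]
      if (length(drop_)) cohort$longitudinal[[v]][drop_] <- NA_real_
    }
  }
  cohort
}

#' Serialize a simulation configuration to JSON
#'
#' The document mirrors [sim_config()] field by field (generative parameter
#' matrices are stored as nested arrays) and reads back to an equivalent
#' configuration.
#' @param config a [sim_config()]
#' @param path JSON file path
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$schedule <- list(labels = config$schedule$labels,
                     loadings = config$schedule$loadings)
  x$signal_params <- unclass(config$signal_params)
  x$event_models <- lapply(config$event_models, function(m) {
    m$coef <- as.list(m$coef)   # keep the latent-factor names in the JSON
    m
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", force = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) unlist(v, use.names = TRUE)
  sp <- x$signal_params
  x$signal_params <- altsr_params(
    mu = num(sp$mu), psi = matrix(num(sp$psi), 4, 4, byrow = TRUE),
    a = sp$a, b = sp$b, c = sp$c, d = sp$d,
    sigma_e1 = matrix(num(sp$sigma_e1), 2, 2, byrow = TRUE),
    sigma_e = matrix(num(sp$sigma_e), 2, 2, byrow = TRUE),
    pair_icc_mz = sp$pair_icc_mz, pair_icc_dz = sp$pair_icc_dz)
  x$schedule <- occasion_schedule(num(x$schedule$labels),
                                  num(x$schedule$loadings))
  x$event_models <- lapply(x$event_models, function(m) {
    m$coef <- num(m$coef)
    m$age_window <- num(m$age_window)
    m$cpg <- num(m$cpg)
    m$intercept <- m$intercept[[1]]
    m
  })
  x$smoking_probs <- num(x$smoking_probs)
  x$signal_traits <- num(x$signal_traits)
  do.call(sim_config, x)
}

# --- cohort input/output ----------------------------------------------------

#' Write / read a cohort as plain TSV tables
#'
#' Writes individuals, longitudinal records, events and samples as TSV, the
#' methylation matrix as TSV (rows = "person_occasion" sample ids, columns
#' = CpG ids), and the simulation parameters as JSON.
#' @param cohort a \code{twin_cohort}
#' @param dir output directory (created if needed)
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(cohort$individuals, "individuals.tsv")
  wt(cohort$longitudinal, "longitudinal.tsv")
  if (!is.null(cohort$events)) wt(cohort$events, "events.tsv")
  wt(cohort$samples, "samples.tsv")
  meth <- data.frame(sample_id = rownames(cohort$methylation),
                     cohort$methylation, check.names = FALSE)
  wt(meth, "methylation.tsv")
  jsonlite::write_json(list(labels = cohort$schedule$labels,
                            loadings = cohort$schedule$loadings),
                       file.path(dir, "schedule.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rt <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE)
  sch <- jsonlite::read_json(file.path(dir, "schedule.json"),
                             simplifyVector = TRUE)
  meth <- rt("methylation.tsv")
  mat <- as.matrix(meth[, -1, drop = FALSE])
  rownames(mat) <- meth$sample_id
  ev_path <- file.path(dir, "events.tsv")
  structure(list(individuals = rt("individuals.tsv"),
                 longitudinal = rt("longitudinal.tsv"),
                 methylation = mat, samples = rt("samples.tsv"),
                 events = if (file.exists(ev_path)) rt("events.tsv") else NULL,
                 truth = NULL,
                 schedule = occasion_schedule(sch$labels, sch$loadings),
                 config = NULL),
            class = "twin_cohort")
}
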