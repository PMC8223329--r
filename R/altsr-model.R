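# Stage 2: bivariate autoregressive latent trajectory models with
# structured residuals (ALT-SR) per CpG x trait, and the cross-lagged path
# classification behind the result figures.

LIPID_TRAITS <- c("TC", "LDL", "HDL", "TG")
ALL_TRAITS <- c("TC", "LDL", "HDL", "TG", "SBP", "DBP", "BMI")

# occasion suffix used in path labels: digits of the label if any, else the
# occasion index ("IPT3" -> a3, matching the aX/bX/cX/dX convention)
occ_num <- function(labels) {
  num <- gsub("\\D", "", labels)
  ifelse(num == "", as.character(seq_along(labels)), num)
}

#' Schedule used for a given trait
#'
#' HDL and LDL are modelled on four occasions (the first occasion has no
#' HDL/LDL measurements); their slope loadings are the full schedule's
#' spacing re-anchored at the second occasion (0, 1, 3, 4 by default).
#' @param trait trait name
#' @param schedule the cohort's full [occasion_schedule()]
#' @export
trait_schedule <- function(trait, schedule = occasion_schedule()) {
  if (trait %in% c("HDL", "LDL")) {
    lab <- schedule$labels[-1]
    lam <- schedule$loadings[-1] - schedule$loadings[2]
    occasion_schedule(lab, lam)
  } else schedule
}

#' Build the ALT-SR specification for one CpG and one trait
#'
#' The model combines a linear latent growth curve (intercept loadings
#' fixed 1, slope loadings fixed to the schedule) for each construct with a
#' first-order autoregressive/cross-lagged process on occasion-specific
#' structured residuals (one phantom latent per manifest, loading 1,
#' manifest unique variance 0). Residual variances and the within-occasion
#' residual covariance are equality-constrained across occasions except the
#' first; autoregressive (a: methylation, c: trait) and cross-lagged paths
#' (b: trait to methylation, d: methylation to trait) are free per
#' transition. All growth-factor covariances are free. Sex and baseline age
#' regress onto the four growth factors, plus statin-ever for lipid traits.
#' Methylation enters rescaled x10.
#'
#' @param cpg CpG id
#' @param trait one of TC, LDL, HDL, TG, SBP, DBP, BMI
#' @param schedule the cohort's full schedule (reduced automatically for
#'   HDL/LDL)
#' @param rescale methylation rescale factor (default 10)
#' @param covariates override the default covariate set (sex and baseline
#'   age, plus statin for lipids); \code{character(0)} for none
#' @return object of class \code{altsr_spec}: parameter table, covariates,
#'   schedule used, and the a/b/c/d path map
#' @export
build_alt_sr_spec <- function(cpg, trait, schedule = occasion_schedule(),
                              rescale = 10, covariates = NULL) {
  if (!trait %in% ALL_TRAITS) stop("unknown trait: ", trait)
  sch <- trait_schedule(trait, schedule)
  if (is.null(covariates)) {
    covariates <- c("sex", "bage")
    if (trait %in% LIPID_TRAITS) covariates <- c(covariates, "statin")
  }
  occ <- sch$labels; lam <- sch$loadings; T_ <- length(occ)
  num <- occ_num(occ)
  m_ov <- paste0("dnam.", occ); r_ov <- paste0("trait.", occ)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- pt_row(...)
  gf <- c("dnam.i", "dnam.s", "trait.i", "trait.s")
  for (t in seq_len(T_)) {
    add("dnam.i", "=~", m_ov[t], free = FALSE, value = 1)
    add("dnam.s", "=~", m_ov[t], free = FALSE, value = lam[t])
    add("trait.i", "=~", r_ov[t], free = FALSE, value = 1)
    add("trait.s", "=~", r_ov[t], free = FALSE, value = lam[t])
    # structured residual: phantom latent, manifest uniqueness 0
    add(paste0("e.dnam.", occ[t]), "=~", m_ov[t], free = FALSE, value = 1)
    add(paste0("e.trait.", occ[t]), "=~", r_ov[t], free = FALSE, value = 1)
    add(m_ov[t], "~~", m_ov[t], free = FALSE, value = 0)
    add(r_ov[t], "~~", r_ov[t], free = FALSE, value = 0)
  }
  # growth-factor means and full covariance block
  for (g in gf) add(g, "~1", "")
  for (i in seq_along(gf)) for (j in i:length(gf))
    add(gf[i], "~~", gf[j])
  # structured-residual (co)variances: first occasion free on its own,
  # later occasions equality-constrained (innovation covariance)
  for (t in seq_len(T_)) {
    lm_ <- if (t == 1) "v1.e.dnam" else "v.e.dnam"
    lr <- if (t == 1) "v1.e.trait" else "v.e.trait"
    lc <- if (t == 1) "cov1.e" else "cov.e"
    add(paste0("e.dnam.", occ[t]), "~~", paste0("e.dnam.", occ[t]),
        label = lm_)
    add(paste0("e.trait.", occ[t]), "~~", paste0("e.trait.", occ[t]),
        label = lr)
    add(paste0("e.dnam.", occ[t]), "~~", paste0("e.trait.", occ[t]),
        label = lc)
  }
  # AR and cross-lagged paths between adjacent occasions, free per transition
  path_map <- list()
  for (t in 2:T_) {
    f <- occ[t - 1]; to <- occ[t]; s <- num[t - 1]
    lab <- c(a = paste0("a", s), c = paste0("c", s),
             b = paste0("b", s), d = paste0("d", s))
    add(paste0("e.dnam.", to), "~", paste0("e.dnam.", f), label = lab["a"])
    add(paste0("e.trait.", to), "~", paste0("e.trait.", f), label = lab["c"])
    add(paste0("e.dnam.", to), "~", paste0("e.trait.", f), label = lab["b"])
    add(paste0("e.trait.", to), "~", paste0("e.dnam.", f), label = lab["d"])
    path_map[[t - 1]] <- data.frame(
      label = unname(lab),
      kind = c("AR_dnam", "AR_trait", "CL_trait_to_dnam",
               "CL_dnam_to_trait"),
      from = f, to = to, stringsAsFactors = FALSE)
  }
  for (g in gf) for (x in covariates) add(g, "~", x)
  pt <- parameter_table(do.call(rbind, rows))
  structure(list(cpg = cpg, trait = trait, schedule = sch,
                 covariates = covariates, rescale = rescale,
                 ptable = pt, path_map = do.call(rbind, path_map),
                 manifest = c(m_ov, r_ov)),
            class = "altsr_spec")
}

#' @export
print.altsr_spec <- function(x, ...) {
  cat("altsr_spec:", x$cpg, "x", x$trait, "on",
      length(x$schedule$labels), "occasions;",
      sum(x$ptable$free), "free parameters\n")
  invisible(x)
}

# wide person-level analysis table for SEM stages: dnam.<occ> (rescaled),
# trait.<occ>, covariates, pair id
sem_wide_data <- function(cohort, cpg, trait, sch, rescale = 10,
                          covariates = c("sex", "bage")) {
  ind <- cohort$individuals
  occ <- sch$labels
  out <- data.frame(person = ind$person, pair = ind$pair,
                    sex = ind$sex, bage = ind$baseline_age - 70,
                    statin = ind$statin_ever, stringsAsFactors = FALSE)
  skey <- paste(cohort$samples$person, cohort$samples$occasion)
  lkey <- paste(cohort$longitudinal$person, cohort$longitudinal$occasion)
  for (o in occ) {
    k <- paste(ind$person, o)
    mi <- match(k, skey)
    out[[paste0("dnam.", o)]] <- rescale * cohort$methylation[mi, cpg]
    out[[paste0("trait.", o)]] <- cohort$longitudinal[[trait]][match(k, lkey)]
  }
  out
}

#' Fit an ALT-SR specification to a cohort
#'
#' Delegates to [sem_fit()] with twin-pair cluster ids; records the
#' fit-index screen (chi-square p > 0.05, RMSEA < 0.06, CFI > 0.95). The
#' screen is reported, not used to drop models. Non-converged or degenerate
#' fits are returned as a no-output record with a reason, never partially
#' reported.
#'
#' @param spec an [build_alt_sr_spec()] result
#' @param cohort a \code{twin_cohort}
#' @param stratum "all", "MZ" or "DZ" (at least 30 persons required)
#' @param control passed to [sem_fit()]
#' @return an \code{altsr_fit} (a \code{semfit} with screen and spec) or an
#'   \code{altsr_noout} record
#' @export
fit_alt_sr <- function(spec, cohort, stratum = "all", control = list()) {
  stopifnot(inherits(spec, "altsr_spec"))
  persons <- stratum_persons(cohort, stratum)
  if (length(persons) < 30)
    stop("stratum '", stratum, "' has fewer than 30 persons (",
         length(persons), ")")
  sub <- if (stratum == "all") cohort else subset_cohort(cohort, persons)
  d <- sem_wide_data(sub, spec$cpg, spec$trait, spec$schedule,
                     rescale = spec$rescale, covariates = spec$covariates)
  # need within-person repeated information on at least two occasions
  obs_occ <- vapply(spec$schedule$labels, function(o)
    any(!is.na(d[[paste0("dnam.", o)]]) | !is.na(d[[paste0("trait.", o)]])),
    TRUE)
  if (sum(obs_occ) < 2)
    return(structure(list(converged = FALSE,
                          reason = "fewer than two occasions with data",
                          spec = spec), class = "altsr_noout"))
  model <- sem_model(spec$ptable, manifest = spec$manifest,
                     exo = spec$covariates)
  fit <- tryCatch(sem_fit(model, d, cluster = d$pair, control = control),
                  error = function(e)
                    structure(list(converged = FALSE,
                                   reason = conditionMessage(e),
                                   spec = spec), class = "altsr_noout"))
  if (inherits(fit, "altsr_noout")) return(fit)
  if (!fit$converged)
    return(structure(list(converged = FALSE, reason = "non-convergence",
                          grad_norm = fit$grad_norm, spec = spec),
                     class = "altsr_noout"))
  fi <- fit_indices(fit)
  fit$screen <- list(chisq_p = fi$p, rmsea = fi$rmsea, cfi = fi$cfi,
                     well_fit = isTRUE(fi$p > 0.05 && fi$rmsea < 0.06 &&
                                         fi$cfi > 0.95))
  fit$spec <- spec
  class(fit) <- c("altsr_fit", class(fit))
  fit
}

#' Classify autoregressive and cross-lagged paths of a fitted ALT-SR model
#'
#' Maps every a/b/c/d parameter to a path record with its standardized
#' estimate and cluster-robust p-value, flagged significant at \code{alpha}
#' (typically 0.05 / (n CpGs x n traits)).
#'
#' @param fit an \code{altsr_fit} (or any \code{semfit} of an ALT-SR
#'   specification, with \code{spec} supplied explicitly)
#' @param alpha significance level
#' @param spec the \code{altsr_spec} the fit corresponds to
#' @return data.frame: cpg, trait, kind, from, to, label, estimate, std,
#'   se, p, significant
#' @export
classify_paths <- function(fit, alpha, spec = fit$spec) {
  stopifnot(inherits(fit, "semfit"), inherits(spec, "altsr_spec"))
  est <- sem_estimates(fit, robust = TRUE)
  pm <- spec$path_map
  i <- match(pm$label, est$parameter)
  out <- data.frame(cpg = spec$cpg, trait = spec$trait,
                    kind = pm$kind, from = pm$from, to = pm$to,
                    label = pm$label,
                    estimate = est$estimate[i], std = est$std[i],
                    se = est$se[i], p = est$p[i],
                    significant = est$p[i] < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Map generative ALT-SR parameters to the model's free-parameter vector
#'
#' Translates an [altsr_params()] object into the named theta vector of the
#' compiled specification built by [build_alt_sr_spec()] (growth-factor
#' means and covariances, first-occasion and innovation residual
#' covariances, and the per-transition a/b/c/d paths). This is the bridge
#' used by the generator-versus-engine moment consistency checks.
#'
#' @param model a compiled [sem_model()] of an ALT-SR specification
#' @param params an [altsr_params()]
#' @param spec the [build_alt_sr_spec()] the model was compiled from
#' @return named numeric vector in \code{model$theta_names} order
#' @export
altsr_generative_theta <- function(model, params, spec) {
  th <- numeric(model$npar)
  names(th) <- model$theta_names
  gf <- c("dnam.i", "dnam.s", "trait.i", "trait.s")
  set <- function(nm, v) {
    i <- match(nm, names(th))
    if (is.na(i)) stop("parameter not in model: ", nm)
    th[i] <<- v
  }
  for (i in 1:4) {
    set(paste(gf[i], "~1", ""), params$mu[i])
    for (j in i:4) set(paste(gf[i], "~~", gf[j]), params$psi[i, j])
  }
  set("v1.e.dnam", params$sigma_e1[1, 1])
  set("v1.e.trait", params$sigma_e1[2, 2])
  set("cov1.e", params$sigma_e1[1, 2])
  set("v.e.dnam", params$sigma_e[1, 1])
  set("v.e.trait", params$sigma_e[2, 2])
  set("cov.e", params$sigma_e[1, 2])
  pm <- spec$path_map
  val <- c(AR_dnam = params$a, AR_trait = params$c,
           CL_trait_to_dnam = params$b, CL_dnam_to_trait = params$d)
  for (r in seq_len(nrow(pm))) set(pm$label[r], val[[pm$kind[r]]])
  th
}

#' Summarize cross-lagged path classifications over a CpG panel
#'
#' @param path_sets list of [classify_paths()] tables (one per converged
#'   CpG x trait fit)
#' @return list: \code{counts} (significant paths by kind),
#'   \code{plot_table} (long format: cpg, trait, transition, kind, std
#'   estimate, significant), \code{n_models}
#' @export
summarize_crosslag <- function(path_sets) {
  kinds <- c("AR_dnam", "AR_trait", "CL_trait_to_dnam", "CL_dnam_to_trait")
  if (length(path_sets) == 0) {
    return(list(counts = data.frame(kind = kinds, n_significant = 0L),
                plot_table = data.frame(), n_models = 0L))
  }
  all <- do.call(rbind, path_sets)
  cnt <- vapply(kinds, function(k)
    sum(all$significant[all$kind == k], na.rm = TRUE), 0L)
  plot_table <- data.frame(
    cpg = all$cpg, trait = all$trait,
    transition = paste(all$from, "->", all$to),
    kind = all$kind, std = all$std, significant = all$significant,
    stringsAsFactors = FALSE)
  list(counts = data.frame(kind = kinds, n_significant = as.integer(cnt),
                           row.names = NULL),
       plot_table = plot_table, n_models = length(path_sets))
}
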