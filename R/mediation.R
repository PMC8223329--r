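# Stage 3: latent growth curve mediation from methylation growth factors
# through a trait's slope to CVD, on pre-diagnosis observations.

#' Restrict a cohort to pre-diagnosis observations
#'
#' For diagnosed persons, keeps only occasions strictly before the
#' diagnosis age; undiagnosed persons keep all records. A per-person
#' outcome indicator (ever diagnosed) is attached as
#' \code{cohort$outcome}. Persons diagnosed before their first occasion
#' contribute the indicator with zero longitudinal records; their count is
#' recorded in \code{attr(cohort$outcome, "n_no_records")}.
#'
#' @param cohort a \code{twin_cohort} with events
#' @param outcome_category event category
#' @export
restrict_pre_diagnosis <- function(cohort, outcome_category) {
  if (is.null(cohort$events)) stop("cohort has no events table")
  ev <- cohort$events[cohort$events$category == outcome_category, ]
  if (nrow(ev) == 0) stop("unknown outcome category: ", outcome_category)
  dage <- function(person) ev$diagnosis_age[match(person, ev$person)]
  da_l <- dage(cohort$longitudinal$person)
  keep_l <- is.na(da_l) | cohort$longitudinal$age < da_l
  cohort$longitudinal <- cohort$longitudinal[keep_l, ]
  da_s <- dage(cohort$samples$person)
  keep_s <- is.na(da_s) | cohort$samples$age < da_s
  cohort$samples <- cohort$samples[keep_s, ]
  cohort$methylation <- cohort$methylation[keep_s, , drop = FALSE]
  outcome <- data.frame(person = cohort$individuals$person,
                        y = as.integer(cohort$individuals$person %in%
                                         ev$person[ev$event == 1]),
                        stringsAsFactors = FALSE)
  n_norec <- sum(outcome$y == 1 &
                   !outcome$person %in% cohort$longitudinal$person)
  attr(outcome, "n_no_records") <- n_norec
  cohort$outcome <- outcome
  cohort
}

#' Mediation model specification
#'
#' @param cpg CpG id; @param trait trait name; @param outcome_category
#'   event category; @param schedule the cohort's full schedule;
#'   @param rescale methylation rescale factor
#' @param covariates override the default covariate set (sex and baseline
#'   age, plus statin for lipids); \code{character(0)} for none
#' @return object of class \code{mediation_spec}
#' @export
mediation_spec <- function(cpg, trait, outcome_category,
                           schedule = occasion_schedule(), rescale = 10,
                           covariates = NULL) {
  if (!trait %in% ALL_TRAITS) stop("unknown trait: ", trait)
  sch <- trait_schedule(trait, schedule)
  if (is.null(covariates)) {
    covariates <- c("sex", "bage")
    if (trait %in% LIPID_TRAITS) covariates <- c(covariates, "statin")
  }
  structure(list(cpg = cpg, trait = trait,
                 outcome_category = outcome_category, schedule = sch,
                 covariates = covariates, rescale = rescale),
            class = "mediation_spec")
}

#' Build the mediation parameter table
#'
#' Two parallel linear growth curves (methylation and trait, loadings as in
#' the cross-lagged stage) with correlated growth factors; mediation
#' regressions m1 (methylation intercept to trait slope) and m2
#' (methylation slope to trait slope); outcome regressions x1, x2
#' (methylation intercept/slope to CVD), x3, x4 (trait intercept/slope to
#' CVD); defined quantities mirs = x4*m1, msrs = x4*m2, total_mi = x1 +
#' x4*m1, total_ms = x2 + x4*m2. The binary outcome is treated as a
#' continuous endogenous variable (linear-probability convention).
#' Covariates regress onto the growth factors.
#'
#' @param spec a [mediation_spec()]
#' @return a [parameter_table()]
#' @export
build_mediation_spec <- function(spec) {
  stopifnot(inherits(spec, "mediation_spec"))
  sch <- spec$schedule
  occ <- sch$labels; lam <- sch$loadings; T_ <- length(occ)
  m_ov <- paste0("dnam.", occ); r_ov <- paste0("trait.", occ)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- pt_row(...)
  for (t in seq_len(T_)) {
    add("dnam.i", "=~", m_ov[t], free = FALSE, value = 1)
    add("dnam.s", "=~", m_ov[t], free = FALSE, value = lam[t])
    add("trait.i", "=~", r_ov[t], free = FALSE, value = 1)
    add("trait.s", "=~", r_ov[t], free = FALSE, value = lam[t])
    add(m_ov[t], "~~", m_ov[t])     # occasion-specific measurement residual
    add(r_ov[t], "~~", r_ov[t])
  }
  # outcome as single-indicator phantom latent (residual variance on the
  # latent side, manifest uniqueness 0)
  add("cvd.l", "=~", "cvd", free = FALSE, value = 1)
  add("cvd", "~~", "cvd", free = FALSE, value = 0)
  add("cvd.l", "~~", "cvd.l")
  add("cvd.l", "~1", "")
  gf <- c("dnam.i", "dnam.s", "trait.i", "trait.s")
  for (g in gf) add(g, "~1", "")
  for (g in gf) add(g, "~~", g)
  # free covariances among the exogenous growth factors
  add("dnam.i", "~~", "dnam.s")
  add("dnam.i", "~~", "trait.i")
  add("dnam.s", "~~", "trait.i")
  # mediation and outcome regressions
  add("trait.s", "~", "dnam.i", label = "m1")
  add("trait.s", "~", "dnam.s", label = "m2")
  add("cvd.l", "~", "dnam.i", label = "x1")
  add("cvd.l", "~", "dnam.s", label = "x2")
  add("cvd.l", "~", "trait.i", label = "x3")
  add("cvd.l", "~", "trait.s", label = "x4")
  for (g in gf) for (x in spec$covariates) add(g, "~", x)
  add("mirs", ":=", "x4 * m1")
  add("msrs", ":=", "x4 * m2")
  add("total_mi", ":=", "x1 + x4 * m1")
  add("total_ms", ":=", "x2 + x4 * m2")
  parameter_table(do.call(rbind, rows))
}

#' Fit the mediation model
#'
#' Restricts the cohort to pre-diagnosis observations, fits the mediation
#' SEM by FIML with twin-pair clustering, and reports direct (x1-x4),
#' mediation (m1, m2), indirect (x4*m1, x4*m2) and total effects with
#' delta-method cluster-robust standard errors.
#'
#' @param spec a [mediation_spec()]
#' @param cohort a \code{twin_cohort} with events (pre-restriction is
#'   applied internally; a cohort already carrying \code{$outcome} is used
#'   as-is)
#' @param stratum "all", "MZ" or "DZ"
#' @param alpha significance level for the flags (typically 0.05 / (n CpGs
#'   x n traits))
#' @param control passed to [sem_fit()]
#' @return object of class \code{mediation_fit}: \code{effects} data.frame
#'   (effect, estimate, se, z, p, significant), \code{converged}, and the
#'   underlying \code{semfit}
#' @export
fit_mediation <- function(spec, cohort, stratum = "all", alpha = 0.05 / 140,
                          control = list()) {
  stopifnot(inherits(spec, "mediation_spec"))
  persons <- stratum_persons(cohort, stratum)
  if (length(persons) < 30)
    stop("stratum '", stratum, "' has fewer than 30 persons (",
         length(persons), ")")
  sub <- if (stratum == "all") cohort else subset_cohort(cohort, persons)
  if (is.null(sub$outcome))
    sub <- restrict_pre_diagnosis(sub, spec$outcome_category)
  d <- sem_wide_data(sub, spec$cpg, spec$trait, spec$schedule,
                     rescale = spec$rescale, covariates = spec$covariates)
  d$cvd <- sub$outcome$y[match(d$person, sub$outcome$person)]
  if (length(unique(stats::na.omit(d$cvd))) < 2)
    stop("degenerate outcome: all persons share the same ",
         spec$outcome_category, " status")
  pt <- build_mediation_spec(spec)
  model <- sem_model(pt, manifest = c(paste0("dnam.", spec$schedule$labels),
                                      paste0("trait.", spec$schedule$labels),
                                      "cvd"),
                     exo = spec$covariates)
  fit <- sem_fit(model, d, cluster = d$pair, control = control)
  if (!fit$converged)
    return(structure(list(converged = FALSE, reason = "non-convergence",
                          grad_norm = fit$grad_norm, spec = spec),
                     class = "mediation_fit"))
  est <- sem_estimates(fit, robust = TRUE)
  direct <- est[match(c("x1", "x2", "x3", "x4", "m1", "m2"), est$parameter), ]
  defs <- sem_defined(fit, robust = TRUE)
  eff <- rbind(
    data.frame(effect = direct$parameter, estimate = direct$estimate,
               se = direct$se, z = direct$z, p = direct$p,
               stringsAsFactors = FALSE),
    data.frame(effect = defs$name, estimate = defs$estimate, se = defs$se,
               z = defs$z, p = defs$p, stringsAsFactors = FALSE))
  eff$significant <- eff$p < alpha
  rownames(eff) <- NULL
  structure(list(converged = TRUE, effects = eff, fit = fit, spec = spec,
                 alpha = alpha), class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("mediation_fit:", x$spec$cpg, "x", x$spec$trait,
        "- no output (", x$reason, ")\n")
    return(invisible(x))
  }
  cat("mediation_fit:", x$spec$cpg, "x", x$spec$trait, "->",
      x$spec$outcome_category, "\n")
  print(x$effects, digits = 4, row.names = FALSE)
  invisible(x)
}
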