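# Stage 1: per-CpG linear mixed models with person-nested-in-pair random
# intercepts, CpG ranking/selection, and the case-only onset analysis.

#' Fit a nested linear mixed model (person within twin pair)
#'
#' Gaussian mixed model with random intercepts for twin pair and for person
#' nested within pair: V = v_pair Z Z' + v_person Z Z' + v_resid I.
#' Estimation is delegated to \pkg{lme4}; fixed-effect inference uses Wald
#' z tests (large-sample normal reference, as the study pipeline reports
#' only p-values). Singletons form pairs of size one, so their pair
#' variance contribution is absorbed gracefully.
#'
#' @param response numeric vector
#' @param fixed_design numeric matrix (no intercept column needed; one is
#'   added), row-aligned with \code{response}
#' @param person_ids,pair_ids grouping vectors; every person must map to
#'   exactly one pair
#' @param method "REML" or "ML"
#' @return object of class \code{nested_lmm}: \code{coefficients}
#'   data.frame (estimate, se, z, p), \code{varcomp} (v_pair, v_person,
#'   v_resid), \code{loglik}, counts, \code{converged}
#' @export
fit_nested_lmm <- function(response, fixed_design, person_ids, pair_ids,
                           method = c("REML", "ML")) {
  method <- match.arg(method)
  fixed_design <- as.matrix(fixed_design)
  stopifnot(length(response) == nrow(fixed_design),
            length(person_ids) == length(response),
            length(pair_ids) == length(response))
  pp <- unique(data.frame(p = person_ids, q = pair_ids))
  if (anyDuplicated(pp$p))
    stop("every person must map to exactly one pair")
  X <- cbind(`(Intercept)` = 1, fixed_design)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop("rank-deficient fixed design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- data.frame(.y = response, .person = factor(person_ids),
                   .pair = factor(pair_ids))
  df <- cbind(df, as.data.frame(fixed_design))
  terms <- colnames(fixed_design)
  fml <- stats::as.formula(paste(
    ".y ~", paste(c(sprintf("`%s`", terms), "(1 | .pair/.person)"),
                  collapse = " + ")))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = df, REML = (method == "REML"),
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_pair <- vc$vcov[vc$grp == ".pair"]
  v_person <- vc$vcov[vc$grp == ".person:.pair"]
  v_resid <- vc$vcov[vc$grp == "Residual"]
  # values below 1e-10 reported as 0
  clamp <- function(v) if (length(v) && v < 1e-10) 0 else v
  co <- summary(fit)$coefficients
  z <- co[, "t value"]
  cf <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                   se = co[, "Std. Error"], z = z,
                   p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  rownames(cf) <- NULL
  conv <- is.null(fit@optinfo$conv$lme4$code)
  structure(list(coefficients = cf,
                 varcomp = c(v_pair = clamp(v_pair),
                             v_person = clamp(v_person),
                             v_resid = clamp(v_resid)),
                 loglik = as.numeric(stats::logLik(fit)),
                 method = method,
                 n_obs = nrow(df), n_persons = nlevels(df$.person),
                 n_pairs = nlevels(df$.pair),
                 converged = conv, lmer_fit = fit),
            class = "nested_lmm")
}

#' @export
print.nested_lmm <- function(x, ...) {
  cat("nested_lmm (", x$method, "): ", x$n_obs, " obs, ", x$n_persons,
      " persons, ", x$n_pairs, " pairs\n", sep = "")
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat("variance components:",
      sprintf("pair %.4g, person %.4g, residual %.4g\n",
              x$varcomp[1], x$varcomp[2], x$varcomp[3]))
  invisible(x)
}

# EWAS design shared by run_ewas and the onset analysis: time-dependent CVD
# indicator, repeated age, sex (female = 1), repeated smoking (ordinal
# numeric 1/2/3, as coded).
ewas_frame <- function(cohort, outcome_category) {
  cvd <- code_cvd_time_dependent(cohort, outcome_category)
  s <- cohort$samples
  key <- paste(s$person, s$occasion)
  li <- cohort$longitudinal
  lkey <- paste(li$person, li$occasion)
  ind <- cohort$individuals
  data.frame(
    person = s$person,
    pair = ind$pair[match(s$person, ind$person)],
    occasion = s$occasion,
    cvd = cvd$cvd[match(key, paste(cvd$person, cvd$occasion))],
    age = s$age,
    sex = ind$sex[match(s$person, ind$person)],
    smoking = li$smoking[match(key, lkey)],
    stringsAsFactors = FALSE)
}

#' Epigenome-wide association scan against a CVD outcome
#'
#' One nested linear mixed model per CpG: methylation beta value as the
#' response; fixed effects are the time-dependent CVD indicator, repeated
#' age, sex and repeated smoking; random intercepts for person nested in
#' twin pair. CpGs with (near-)constant methylation are excluded with a
#' reason. Models are refit per CpG from a shared fitted structure for
#' speed.
#'
#' @param cohort a \code{twin_cohort} with events
#' @param outcome_category one of the event categories in
#'   \code{cohort$events}
#' @param cpgs optional subset of CpG ids (default: all columns)
#' @return \code{ewas_table}: data.frame (cpg, beta, se, z, p, rank) sorted
#'   by p, with excluded CpGs in \code{attr(, "excluded")}
#' @export
run_ewas <- function(cohort, outcome_category, cpgs = NULL) {
  if (is.null(cohort$events) ||
      !outcome_category %in% cohort$events$category)
    stop("outcome category absent from events table: ", outcome_category)
  if (is.null(cpgs)) cpgs <- colnames(cohort$methylation)
  fr <- ewas_frame(cohort, outcome_category)
  keep <- stats::complete.cases(fr[, c("cvd", "age", "sex", "smoking")]) &
    rowSums(!is.na(cohort$methylation[, cpgs, drop = FALSE])) > 0
  fr <- fr[keep, ]
  meth <- cohort$methylation[keep, cpgs, drop = FALSE]
  fr$.person <- factor(fr$person); fr$.pair <- factor(fr$pair)
  base_fit <- NULL
  rows <- vector("list", length(cpgs))
  excluded <- character(0)
  for (j in seq_along(cpgs)) {
    y <- meth[, j]
    if (stats::sd(y, na.rm = TRUE) < 1e-12 || all(is.na(y))) {
      excluded <- c(excluded, cpgs[j])
      next
    }
    if (is.null(base_fit)) {
      fr$.y <- y
      base_fit <- suppressWarnings(suppressMessages(
        lme4::lmer(.y ~ cvd + age + sex + smoking + (1 | .pair/.person),
                   data = fr, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE))))
      fit <- base_fit
    } else {
      fit <- suppressWarnings(suppressMessages(lme4::refit(base_fit, y)))
    }
    co <- summary(fit)$coefficients
    est <- co["cvd", "Estimate"]; se <- co["cvd", "Std. Error"]
    z <- est / se
    rows[[j]] <- data.frame(cpg = cpgs[j], beta = est, se = se, z = z,
                            p = 2 * stats::pnorm(-abs(z)),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0) stop("no non-degenerate CpGs to test")
  tab <- tab[order(tab$p, tab$cpg), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "excluded") <- excluded
  attr(tab, "outcome") <- outcome_category
  class(tab) <- c("ewas_table", "data.frame")
  tab
}

#' Select CpGs for downstream modelling
#'
#' Returns all CpGs below the epigenome-wide threshold; if none reach it,
#' the k lowest-p CpGs (ties broken by CpG id, lexicographic).
#'
#' @param table an \code{ewas_table}
#' @param k fallback count (default 20)
#' @param alpha epigenome-wide threshold (default 2e-7, i.e. 0.05/255356
#'   rounded to one significant figure)
#' @export
select_cpgs <- function(table, k = 20, alpha = 2e-7) {
  stopifnot(nrow(table) > 0)
  if (k > nrow(table)) {
    warning("k exceeds the number of tested CpGs; returning all")
    k <- nrow(table)
  }
  hits <- table$cpg[table$p < alpha]
  if (length(hits)) return(sort(hits))
  ord <- order(table$p, table$cpg)
  table$cpg[ord][seq_len(k)]
}

#' Bonferroni-style significance thresholds
#'
#' @param n_tests number of tests
#' @param base familywise level (default 0.05)
#' @param signif_digits if given, round to this many significant figures
#'   (the epigenome-wide threshold is quoted at one significant figure)
#' @export
bonferroni_alpha <- function(n_tests, base = 0.05, signif_digits = NULL) {
  stopifnot(n_tests >= 1)
  a <- base / n_tests
  if (!is.null(signif_digits)) a <- signif(a, signif_digits)
  a
}

#' Case-only analysis of CVD onset age
#'
#' Restricted to persons diagnosed after at least one of their methylation
#' measurement occasions. Per CpG and per methylation summary (first, last,
#' random, mean measurement), a linear mixed model of onset age on the
#' summary with a twin-pair random intercept and the scan-stage covariates
#' (taken at the summarised measurement; averaged for the mean summary).
#'
#' @param cohort a \code{twin_cohort} with events
#' @param outcome_category event category
#' @param cpg_ids CpGs to test
#' @param summaries subset of c("first", "last", "random", "mean")
#' @param seed seed for the random-measurement summary
#' @return data.frame (cpg, summary, estimate, se, z, p, n_cases) with the
#'   Bonferroni threshold 0.05/(length(cpg_ids) * 4) in
#'   \code{attr(, "alpha")}
#' @export
onset_case_only <- function(cohort, outcome_category, cpg_ids,
                            summaries = c("first", "last", "random", "mean"),
                            seed = 1) {
  summaries <- match.arg(summaries, several.ok = TRUE)
  set.seed(seed)
  ev <- cohort$events[cohort$events$category == outcome_category &
                        cohort$events$event == 1, ]
  fr <- ewas_frame(cohort, outcome_category)
  measured <- rowSums(!is.na(cohort$methylation[, cpg_ids, drop = FALSE])) > 0
  fr <- fr[measured, ]
  meth <- cohort$methylation[measured, cpg_ids, drop = FALSE]
  fr$onset <- ev$diagnosis_age[match(fr$person, ev$person)]
  # diagnosed after at least one measurement occasion
  keep <- !is.na(fr$onset) & !is.na(fr$smoking)
  fr <- fr[keep, ]; meth <- meth[keep, , drop = FALSE]
  eligible <- unique(fr$person[fr$age < fr$onset])
  keep <- fr$person %in% eligible
  fr <- fr[keep, ]; meth <- meth[keep, , drop = FALSE]
  if (length(eligible) < 3)
    stop("fewer than 3 eligible cases for the onset analysis")
  ord <- order(fr$person, fr$age)
  fr <- fr[ord, ]; meth <- meth[ord, , drop = FALSE]
  idx_by_person <- split(seq_len(nrow(fr)), fr$person)
  pick <- list(
    first = vapply(idx_by_person, function(i) i[1], 0L),
    last = vapply(idx_by_person, function(i) i[length(i)], 0L),
    random = vapply(idx_by_person, function(i)
      if (length(i) == 1) i else i[sample.int(length(i), 1)], 0L))
  out <- list()
  for (s in summaries) {
    if (s == "mean") {
      per <- data.frame(
        person = names(idx_by_person),
        onset = vapply(idx_by_person, function(i) fr$onset[i[1]], 0),
        pair = vapply(idx_by_person, function(i) fr$pair[i[1]], ""),
        age = vapply(idx_by_person, function(i) mean(fr$age[i]), 0),
        sex = vapply(idx_by_person, function(i) fr$sex[i[1]], 0),
        smoking = vapply(idx_by_person, function(i) mean(fr$smoking[i]), 0),
        stringsAsFactors = FALSE)
      msum <- t(vapply(idx_by_person, function(i)
        colMeans(meth[i, , drop = FALSE]), numeric(length(cpg_ids))))
    } else {
      ii <- pick[[s]]
      per <- data.frame(person = names(idx_by_person), onset = fr$onset[ii],
                        pair = fr$pair[ii], age = fr$age[ii],
                        sex = fr$sex[ii], smoking = fr$smoking[ii],
                        stringsAsFactors = FALSE)
      msum <- meth[ii, , drop = FALSE]
    }
    for (j in seq_along(cpg_ids)) {
      fitd <- data.frame(.y = per$onset, .pair = factor(per$pair),
                         meth = msum[, j], age = per$age, sex = per$sex,
                         smoking = per$smoking)
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(.y ~ meth + age + sex + smoking + (1 | .pair),
                   data = fitd, REML = TRUE,
                   control = lme4::lmerControl(
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore",
                     calc.derivs = FALSE))))
      co <- summary(fit)$coefficients
      z <- co["meth", "t value"]
      out[[paste(s, j)]] <- data.frame(
        cpg = cpg_ids[j], summary = s, estimate = co["meth", "Estimate"],
        se = co["meth", "Std. Error"], z = z,
        p = 2 * stats::pnorm(-abs(z)), n_cases = nrow(per),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "alpha") <- bonferroni_alpha(length(cpg_ids) * 4)
  res
}

#' Manhattan-style export of an EWAS table
#' @param table an \code{ewas_table}
#' @param path TSV output path
#' @export
write_ewas <- function(table, path) {
  d <- data.frame(cpg = table$cpg, index = seq_len(nrow(table)),
                  neg_log10_p = -log10(table$p))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
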