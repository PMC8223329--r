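# Data coding and orchestration: time-dependent outcome coding, Friedewald
# LDL imputation, covariate codings, and the full EWAS -> ALT-SR ->
# mediation pipeline over outcome categories and zygosity strata.

#' Friedewald imputation of missing LDL
#'
#' LDL = TC - HDL - TG/5 (all in mmol/L or all in mg/dL with TG/5 on the
#' same scale). Applied only where LDL is missing and TC, HDL, TG are all
#' present; existing LDL values are never overwritten.
#'
#' @param longitudinal data.frame with columns TC, HDL, TG, LDL
#' @return the table with LDL imputed where possible; the number of imputed
#'   and still-missing values in attributes \code{imputed} and
#'   \code{unimputable}
#' @export
impute_ldl <- function(longitudinal) {
  stopifnot(all(c("TC", "HDL", "TG", "LDL") %in% names(longitudinal)))
  miss <- is.na(longitudinal$LDL)
  can <- miss & !is.na(longitudinal$TC) & !is.na(longitudinal$HDL) &
    !is.na(longitudinal$TG)
  longitudinal$LDL[can] <- longitudinal$TC[can] - longitudinal$HDL[can] -
    longitudinal$TG[can] / 5
  attr(longitudinal, "imputed") <- sum(can)
  attr(longitudinal, "unimputable") <- sum(miss & !can)
  longitudinal
}

#' Time-dependent CVD coding per (person, occasion)
#'
#' An occasion strictly before the diagnosis age is coded 0 (no CVD);
#' occasions at or after diagnosis are coded 1. Never-diagnosed persons are
#' 0 throughout. Implemented on the age scale (age at occasion vs age at
#' diagnosis), equivalent to the calendar-date rule.
#'
#' @param cohort a \code{twin_cohort} with events
#' @param outcome_category event category
#' @return data.frame (person, occasion, age, cvd)
#' @export
code_cvd_time_dependent <- function(cohort, outcome_category) {
  if (is.null(cohort$events)) stop("cohort has no events table")
  ev <- cohort$events[cohort$events$category == outcome_category, ]
  if (nrow(ev) == 0) stop("unknown outcome category: ", outcome_category)
  li <- cohort$longitudinal
  dage <- ev$diagnosis_age[match(li$person, ev$person)]
  cvd <- as.integer(!is.na(dage) & li$age >= dage)
  data.frame(person = li$person, occasion = li$occasion, age = li$age,
             cvd = cvd, stringsAsFactors = FALSE)
}

#' Numeric covariate codings
#'
#' Applies the study codings to raw category labels: sex female = 1, male =
#' 0; smoking non-smoker = 1, ex-smoker = 2, current = 3 (ordinal numeric);
#' statin-ever = 1 if statin use recorded at least once. BMI is computed as
#' weight (kg) / height (m)^2 where absent and both are available.
#'
#' @param cohort a \code{twin_cohort}; \code{individuals$sex} may be
#'   numeric already or labels "female"/"male"; \code{longitudinal$smoking}
#'   numeric or labels "non-smoker"/"ex-smoker"/"current smoker";
#'   an optional \code{longitudinal$statin} per-occasion indicator is
#'   collapsed to \code{individuals$statin_ever}
#' @return the cohort with coded columns
#' @export
code_covariates <- function(cohort) {
  ind <- cohort$individuals
  if (!is.numeric(ind$sex)) {
    sx <- tolower(as.character(ind$sex))
    bad <- !sx %in% c("female", "male")
    if (any(bad)) stop("unknown sex label in individuals row(s): ",
                       paste(which(bad), collapse = ", "))
    ind$sex <- as.integer(sx == "female")
  }
  li <- cohort$longitudinal
  if (!is.null(li$smoking) && !is.numeric(li$smoking)) {
    sm <- tolower(as.character(li$smoking))
    map <- c("non-smoker" = 1L, "ex-smoker" = 2L, "current smoker" = 3L)
    bad <- !(sm %in% names(map) | is.na(li$smoking))
    if (any(bad)) stop("unknown smoking label in longitudinal row(s): ",
                       paste(which(bad), collapse = ", "))
    li$smoking <- unname(map[sm])
  }
  if (!is.null(li$statin)) {
    ever <- tapply(li$statin, li$person, function(v) as.integer(any(v == 1,
                                                                    na.rm = TRUE)))
    ind$statin_ever <- as.integer(ever[ind$person])
  }
  if (all(c("weight", "height") %in% names(li))) {
    need <- if ("BMI" %in% names(li)) is.na(li$BMI) else rep(TRUE, nrow(li))
    bmi <- li$weight / li$height^2
    if (!"BMI" %in% names(li)) li$BMI <- NA_real_
    li$BMI[need] <- bmi[need]
  }
  cohort$individuals <- ind
  cohort$longitudinal <- li
  cohort
}

#' Multiple-testing rules for the pipeline stages
#'
#' EWAS: 0.05 / n_cpgs rounded to one significant figure; cross-lagged and
#' mediation stages: 0.05 / (n_selected x n_traits); onset analysis:
#' 0.05 / (n_selected x 4 summaries).
#'
#' @param n_cpgs CpGs scanned; @param n_selected CpGs carried forward;
#' @param n_traits traits modelled
#' @return named list of alphas
#' @export
alpha_rules <- function(n_cpgs, n_selected = 20, n_traits = 7) {
  list(ewas = bonferroni_alpha(n_cpgs, signif_digits = 1),
       altsr = bonferroni_alpha(n_selected * n_traits),
       mediation = bonferroni_alpha(n_selected * n_traits),
       onset = bonferroni_alpha(n_selected * 4))
}

stratum_persons <- function(cohort, stratum) {
  ind <- cohort$individuals
  switch(stratum,
         all = ind$person,
         MZ = ind$person[ind$zygosity == "MZ"],
         DZ = ind$person[ind$zygosity == "DZ"],
         stop("unknown stratum: ", stratum))
}

subset_cohort <- function(cohort, persons) {
  keep_i <- cohort$individuals$person %in% persons
  keep_l <- cohort$longitudinal$person %in% persons
  keep_s <- cohort$samples$person %in% persons
  cohort$individuals <- cohort$individuals[keep_i, ]
  cohort$longitudinal <- cohort$longitudinal[keep_l, ]
  cohort$samples <- cohort$samples[keep_s, ]
  cohort$methylation <- cohort$methylation[keep_s, , drop = FALSE]
  if (!is.null(cohort$events))
    cohort$events <- cohort$events[cohort$events$person %in% persons, ]
  if (!is.null(cohort$truth$latent))
    cohort$truth$latent <- cohort$truth$latent[
      cohort$truth$latent$person %in% persons, ]
  cohort
}

#' Run the full analysis pipeline
#'
#' EWAS scan, CpG selection, ALT-SR per selected CpG x trait, then
#' mediation per CpG x trait, per outcome category and per stratum (all /
#' MZ / DZ). Writes TSV tables and a JSON run manifest recording alphas,
#' seeds, and a convergence ledger in which fitted + no-output = attempted
#' for every stage.
#'
#' @param cohort a \code{twin_cohort}
#' @param outcomes event categories to run
#' @param strata subset of c("all", "MZ", "DZ")
#' @param traits traits for the cross-lagged stage
#' @param n_top_cpgs fallback selection size (default 20)
#' @param mediation_restrict run mediation only for CpG x trait pairs with
#'   at least one significant cross-lagged path (default FALSE: all pairs)
#' @param out_dir output directory; NULL for no file output
#' @param seed seed for the random pieces (onset random summary)
#' @return nested list of per-outcome, per-stratum results plus the manifest
#' @export
run_full_pipeline <- function(cohort,
                              outcomes = unique(cohort$events$category),
                              strata = "all",
                              traits = c("TC", "LDL", "HDL", "TG", "SBP",
                                         "DBP", "BMI"),
                              n_top_cpgs = 20,
                              mediation_restrict = FALSE,
                              out_dir = NULL, seed = 1) {
  stopifnot(all(strata %in% c("all", "MZ", "DZ")))
  n_cpgs <- ncol(cohort$methylation)
  alphas <- alpha_rules(n_cpgs, n_selected = n_top_cpgs,
                        n_traits = length(traits))
  manifest <- list(seed = seed, n_cpgs = n_cpgs, alphas = alphas,
                   outcomes = outcomes, strata = strata, traits = traits,
                   convergence = list())
  results <- list()
  for (oc in outcomes) {
    for (st in strata) {
      persons <- stratum_persons(cohort, st)
      if (length(persons) == 0) {
        manifest$convergence[[paste(oc, st)]] <-
          list(skipped = "no persons in stratum")
        next
      }
      sub <- subset_cohort(cohort, persons)
      ewas <- run_ewas(sub, oc)
      sel <- select_cpgs(ewas, k = min(n_top_cpgs, nrow(ewas)),
                         alpha = alphas$ewas)
      fits <- list(); paths <- list(); med <- list()
      attempted <- 0L; fitted_ <- 0L
      for (cg in sel) for (tr in traits) {
        attempted <- attempted + 1L
        spec <- build_alt_sr_spec(cg, tr, sub$schedule)
        # batch mode: Heywood flags are carried on the fit objects and
        # counted below rather than surfaced as warnings per model
        f <- tryCatch(suppressWarnings(fit_alt_sr(spec, sub, stratum = "all")),
                      error = function(e) list(converged = FALSE,
                                               reason = conditionMessage(e)))
        key <- paste(cg, tr, sep = ".")
        fits[[key]] <- f
        if (isTRUE(f$converged)) {
          fitted_ <- fitted_ + 1L
          paths[[key]] <- classify_paths(f, alphas$altsr)
        }
      }
      cls <- summarize_crosslag(paths)
      med_pairs <- expand.grid(cpg = sel, trait = traits,
                               stringsAsFactors = FALSE)
      if (mediation_restrict && nrow(cls$counts)) {
        sig <- unique(do.call(rbind, paths)[
          do.call(rbind, paths)$significant &
            grepl("^CL", do.call(rbind, paths)$kind),
          c("cpg", "trait")])
        med_pairs <- merge(med_pairs, sig)
      }
      med_attempt <- 0L; med_fitted <- 0L
      for (i in seq_len(nrow(med_pairs))) {
        med_attempt <- med_attempt + 1L
        key <- paste(med_pairs$cpg[i], med_pairs$trait[i], sep = ".")
        mm <- tryCatch(
          suppressWarnings(
            fit_mediation(mediation_spec(med_pairs$cpg[i],
                                         med_pairs$trait[i],
                                         oc, schedule = sub$schedule),
                          sub, stratum = "all", alpha = alphas$mediation)),
          error = function(e) list(converged = FALSE,
                                   reason = conditionMessage(e)))
        med[[key]] <- mm
        if (isTRUE(mm$converged)) med_fitted <- med_fitted + 1L
      }
      results[[oc]][[st]] <- list(ewas = ewas, selected = sel,
                                  altsr = fits, paths = paths,
                                  crosslag = cls, mediation = med)
      n_heywood <- sum(vapply(fits, function(f) isTRUE(f$heywood), TRUE)) +
        sum(vapply(med, function(m)
          isTRUE(m$converged) && isTRUE(m$fit$heywood), TRUE))
      manifest$convergence[[paste(oc, st)]] <- list(
        altsr_attempted = attempted, altsr_fitted = fitted_,
        altsr_no_output = attempted - fitted_, n_heywood = n_heywood,
        mediation_attempted = med_attempt, mediation_fitted = med_fitted,
        mediation_no_output = med_attempt - med_fitted)
      if (!is.null(out_dir)) {
        d <- file.path(out_dir, gsub("[^A-Za-z0-9]+", "_", oc), st)
        dir.create(file.path(d, "tables"), recursive = TRUE,
                   showWarnings = FALSE)
        dir.create(file.path(d, "figures_data"), recursive = TRUE,
                   showWarnings = FALSE)
        utils::write.table(as.data.frame(ewas),
                           file.path(d, "tables", "ewas.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        write_ewas(ewas, file.path(d, "figures_data", "manhattan.tsv"))
        utils::write.table(cls$plot_table,
                           file.path(d, "figures_data", "crosslag.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        med_tab <- do.call(rbind, lapply(names(med), function(k) {
          if (!isTRUE(med[[k]]$converged)) return(NULL)
          cbind(pair = k, med[[k]]$effects)
        }))
        if (!is.null(med_tab))
          utils::write.table(med_tab,
                             file.path(d, "tables", "mediation.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(results = results, manifest = manifest)
}
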