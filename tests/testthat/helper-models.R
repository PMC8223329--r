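# shared fixtures: small parameter tables and cohorts built in code

# univariate regression y ~ x in SEM form (phantom latents, zero uniqueness)
pt_regression <- function() {
  parameter_table(rbind(
    pt_row("ly", "=~", "y", free = FALSE, value = 1),
    pt_row("lx", "=~", "x", free = FALSE, value = 1),
    pt_row("ly", "~", "lx", label = "b"),
    pt_row("lx", "~~", "lx"), pt_row("ly", "~~", "ly"),
    pt_row("lx", "~1", ""), pt_row("ly", "~1", ""),
    pt_row("y", "~~", "y", free = FALSE, value = 0),
    pt_row("x", "~~", "x", free = FALSE, value = 0)))
}

# linear latent growth curve on the default 5-occasion schedule
pt_lgm <- function(loadings = c(0, 2, 3, 5, 6), free_resid = TRUE) {
  occ <- paste0("y", seq_along(loadings))
  rows <- list()
  for (t in seq_along(loadings)) {
    rows[[length(rows) + 1]] <- pt_row("i", "=~", occ[t], free = FALSE,
                                       value = 1)
    rows[[length(rows) + 1]] <- pt_row("s", "=~", occ[t], free = FALSE,
                                       value = loadings[t])
    rows[[length(rows) + 1]] <- pt_row(occ[t], "~~", occ[t],
                                       free = free_resid,
                                       value = if (free_resid) NA else 0.25,
                                       label = "theta")
  }
  rows[[length(rows) + 1]] <- pt_row("i", "~~", "i")
  rows[[length(rows) + 1]] <- pt_row("s", "~~", "s")
  rows[[length(rows) + 1]] <- pt_row("i", "~~", "s")
  rows[[length(rows) + 1]] <- pt_row("i", "~1", "")
  rows[[length(rows) + 1]] <- pt_row("s", "~1", "")
  parameter_table(do.call(rbind, rows))
}

# small fast cohort for end-to-end smoke tests
small_cohort <- function(seed = 11, n_null = 4, n_signal = 2,
                         traits = c("BMI", "SBP"), ...) {
  simulate_cohort(sim_config(seed = seed, n_null_cpgs = n_null,
                             n_signal_cpgs = n_signal,
                             signal_traits = traits, ...))
}

# generative parameters on symmetric unit-ish scales, used by recovery and
# direction-detection checks (b = 0, d carries the signal)
recovery_params <- function(d = 0.3, b = 0) {
  altsr_params(mu = c(0, 0.02, 0, 0.02),
               psi = diag(c(0.25, 0.01, 0.25, 0.01)),
               a = 0.2, b = b, c = 0.2, d = d,
               sigma_e1 = diag(2), sigma_e = diag(2))
}

# fit the covariate-free bivariate ALT-SR to matrices from
# simulate_bivariate_altsr; returns list(fit, spec)
fit_altsr_matrix <- function(sim, spec = NULL, cluster = NULL) {
  if (is.null(spec))
    spec <- build_alt_sr_spec("cg", "BMI", covariates = character(0))
  occ <- spec$schedule$labels
  d <- as.data.frame(cbind(sim$dnam, sim$trait))
  names(d) <- c(paste0("dnam.", occ), paste0("trait.", occ))
  model <- sem_model(spec$ptable, manifest = spec$manifest)
  list(fit = sem_fit(model, d, cluster = cluster), spec = spec,
       model = model)
}

subset_cohort_n <- function(co, n) {
  altsr:::subset_cohort(co, co$individuals$person[seq_len(n)])
}

expect_no_na <- function(x) expect_false(anyNA(x))
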