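#' Declarative SEM parameter tables
#'
#' A parameter table is the declarative specification consumed by
#' [sem_model()]. Each row declares one model element, in the style familiar
#' from SEM software:
#'
#' \describe{
#'   \item{\code{"=~"}}{factor loading: \code{lhs} (latent) loads on
#'     \code{rhs} (manifest).}
#'   \item{\code{"~"}}{regression: \code{lhs} (latent) on \code{rhs}
#'     (latent or exogenous covariate).}
#'   \item{\code{"~~"}}{(co)variance: both sides manifest (residual
#'     covariance) or both latent.}
#'   \item{\code{"~1"}}{mean/intercept of \code{lhs}.}
#'   \item{\code{":="}}{defined quantity: \code{rhs} is an arithmetic
#'     expression in parameter labels, evaluated at the estimates with
#'     delta-method standard errors.}
#' }
#'
#' Rows sharing a \code{label} share one free parameter (equality
#' constraint). Non-free rows carry their fixed \code{value}.
#'
#' @param rows data.frame with columns \code{lhs}, \code{op}, \code{rhs},
#'   and optionally \code{free} (logical, default TRUE), \code{value}
#'   (fixed value or start value), \code{label}.
#' @return A validated \code{sem_ptable} data.frame.
#' @export
parameter_table <- function(rows) {
  stopifnot(is.data.frame(rows), all(c("lhs", "op", "rhs") %in% names(rows)))
  pt <- data.frame(lhs = as.character(rows$lhs),
                   op = as.character(rows$op),
                   rhs = as.character(rows$rhs),
                   stringsAsFactors = FALSE)
  pt$free <- if ("free" %in% names(rows)) as.logical(rows$free) else TRUE
  pt$value <- if ("value" %in% names(rows)) as.numeric(rows$value) else NA_real_
  pt$label <- if ("label" %in% names(rows)) as.character(rows$label) else NA_character_
  pt$label[!is.na(pt$label) & pt$label == ""] <- NA_character_
  bad_op <- setdiff(unique(pt$op), c("=~", "~", "~~", "~1", ":="))
  if (length(bad_op))
    stop("unknown parameter-table operator(s): ", paste(bad_op, collapse = ", "))
  fixed <- !pt$free & pt$op != ":="
  if (any(fixed & !is.finite(pt$value)))
    stop("fixed parameter rows must carry a finite value")
  lab_n <- table(pt$label[!is.na(pt$label) & pt$op != ":="])
  class(pt) <- c("sem_ptable", "data.frame")
  pt
}

#' Shorthand row constructor for parameter tables
#' @param lhs,op,rhs row content, see [parameter_table()]
#' @param free logical, is the parameter free
#' @param value fixed value (if not free) or start value
#' @param label equality-constraint / reference label
#' @return one-row data.frame
#' @export
pt_row <- function(lhs, op, rhs, free = TRUE, value = NA_real_,
                   label = NA_character_) {
  data.frame(lhs = lhs, op = op, rhs = rhs, free = free, value = value,
             label = label, stringsAsFactors = FALSE)
}

#' Compile a parameter table to model matrices
#'
#' Maps the declarative table to LISREL-style matrices with a free-parameter
#' map honouring equality constraints: loading matrix Lambda (manifest x
#' latent), latent regression matrix B (zero diagonal), latent covariance
#' Psi, manifest residual covariance Theta, latent means alpha, manifest
#' intercepts nu, and covariate regressions Gamma (latent x covariate).
#' Exogenous covariates are conditioned on: their own moments are not model
#' parameters.
#'
#' @param pt a [parameter_table()]
#' @param manifest character vector of manifest (endogenous observed)
#'   variable names; inferred from loadings if omitted
#' @param exo character vector of exogenous covariate names
#' @return an object of class \code{sem_model}
#' @export
sem_model <- function(pt, manifest = NULL, exo = character()) {
  pt <- parameter_table(pt)
  defs <- pt[pt$op == ":=", , drop = FALSE]
  pt <- pt[pt$op != ":=", , drop = FALSE]

  lv <- unique(pt$lhs[pt$op == "=~"])
  mentioned <- unique(c(pt$lhs, pt$rhs[pt$op != "~1"]))
  if (is.null(manifest)) {
    manifest <- unique(pt$rhs[pt$op == "=~"])
    manifest <- setdiff(manifest, c(lv, exo))
  }
  ov <- manifest
  unknown <- setdiff(mentioned, c(ov, lv, exo))
  if (length(unknown))
    stop("variables not declared as manifest, latent or exogenous: ",
         paste(unknown, collapse = ", "))

  p <- length(ov); m <- length(lv); q <- length(exo)
  tmpl <- list(Lambda = matrix(0, p, m, dimnames = list(ov, lv)),
               B      = matrix(0, m, m, dimnames = list(lv, lv)),
               Psi    = matrix(0, m, m, dimnames = list(lv, lv)),
               Theta  = matrix(0, p, p, dimnames = list(ov, ov)),
               Gamma  = matrix(0, m, max(q, 0), dimnames = list(lv, exo)),
               alpha  = matrix(0, m, 1, dimnames = list(lv, NULL)),
               nu     = matrix(0, p, 1, dimnames = list(ov, NULL)))

  # assign theta indices: one per label group, one per unlabelled free row
  pt$par_id <- NA_character_
  free_rows <- which(pt$free)
  for (i in free_rows) {
    pt$par_id[i] <- if (!is.na(pt$label[i])) pt$label[i]
    else paste(pt$lhs[i], pt$op[i], pt$rhs[i])
  }
  theta_names <- unique(pt$par_id[free_rows])
  npar <- length(theta_names)

  fmap <- lapply(tmpl, function(M) list(idx = integer(0), par = integer(0)))
  cell <- function(row) {
    lhs <- row$lhs; rhs <- row$rhs; op <- row$op
    if (op == "=~") {
      if (!(lhs %in% lv) || !(rhs %in% ov))
        stop("loading must be latent =~ manifest: ", lhs, " =~ ", rhs)
      list(list(mat = "Lambda", i = match(rhs, ov), j = match(lhs, lv)))
    } else if (op == "~") {
      if (!(lhs %in% lv))
        stop("regression lhs must be latent (use a phantom latent for ",
             "endogenous manifests): ", lhs)
      if (rhs %in% lv)
        list(list(mat = "B", i = match(lhs, lv), j = match(rhs, lv)))
      else if (rhs %in% exo)
        list(list(mat = "Gamma", i = match(lhs, lv), j = match(rhs, exo)))
      else stop("regression rhs must be latent or exogenous: ", rhs)
    } else if (op == "~~") {
      if (lhs %in% lv && rhs %in% lv) {
        i <- match(lhs, lv); j <- match(rhs, lv)
        if (i == j) list(list(mat = "Psi", i = i, j = j))
        else list(list(mat = "Psi", i = i, j = j),
                  list(mat = "Psi", i = j, j = i))
      } else if (lhs %in% ov && rhs %in% ov) {
        i <- match(lhs, ov); j <- match(rhs, ov)
        if (i == j) list(list(mat = "Theta", i = i, j = j))
        else list(list(mat = "Theta", i = i, j = j),
                  list(mat = "Theta", i = j, j = i))
      } else stop("covariance must be latent-latent or manifest-manifest: ",
                  lhs, " ~~ ", rhs)
    } else if (op == "~1") {
      if (lhs %in% lv) list(list(mat = "alpha", i = match(lhs, lv), j = 1))
      else if (lhs %in% ov) list(list(mat = "nu", i = match(lhs, ov), j = 1))
      else stop("unknown mean target: ", lhs)
    }
  }

  for (r in seq_len(nrow(pt))) {
    row <- pt[r, ]
    cells <- cell(row)
    for (cc in cells) {
      li <- cc$i + (cc$j - 1L) * nrow(tmpl[[cc$mat]])  # 1-based linear index
      if (row$free) {
        fmap[[cc$mat]]$idx <- c(fmap[[cc$mat]]$idx, li - 1L)  # 0-based for C++
        fmap[[cc$mat]]$par <- c(fmap[[cc$mat]]$par,
                                match(row$par_id, theta_names) - 1L)
      } else {
        tmpl[[cc$mat]][li] <- row$value
      }
    }
  }
  fmap <- lapply(fmap, function(f)
    list(idx = as.integer(f$idx), par = as.integer(f$par)))

  structure(list(ptable = pt, defined = defs, ov = ov, lv = lv, exo = exo,
                 templates = tmpl, fmap = fmap,
                 theta_names = theta_names, npar = npar),
            class = "sem_model")
}

#' @export
print.sem_model <- function(x, ...) {
  cat("sem_model:", length(x$ov), "manifest,", length(x$lv), "latent,",
      length(x$exo), "exogenous;", x$npar, "free parameters\n")
  invisible(x)
}

#' Model-implied moments
#'
#' Evaluates the implied mean vector and covariance matrix of the manifest
#' variables at a parameter vector: \eqn{\mu = \nu + \Lambda (I-B)^{-1}
#' \alpha} (at covariate value 0) and \eqn{\Sigma = \Lambda (I-B)^{-1} \Psi
#' (I-B)^{-T} \Lambda^T + \Theta}.
#'
#' @param model a [sem_model()]
#' @param theta numeric vector of free parameters, in
#'   \code{model$theta_names} order
#' @return list with \code{mu}, \code{Sigma}, the filled matrices, and
#'   \code{MGamma} (\eqn{\Lambda (I-B)^{-1} \Gamma}, covariate effects on
#'   the manifest means)
#' @export
implied_moments <- function(model, theta) {
  stopifnot(inherits(model, "sem_model"), length(theta) == model$npar)
  out <- fiml_implied_cpp(theta, model$templates, model$fmap)
  if (!out$ok) stop("singular (I - B) at the supplied parameter values")
  dimnames(out$Sigma) <- list(model$ov, model$ov)
  out$mu <- drop(out$mu); names(out$mu) <- model$ov
  out
}

# serialize / deserialize parameter tables -----------------------------------

#' Write / read a parameter table as TSV
#' @param pt a parameter table
#' @param path file path
#' @export
write_ptable <- function(pt, path) {
  utils::write.table(as.data.frame(pt)[, c("lhs", "op", "rhs", "free",
                                           "value", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_ptable
#' @export
read_ptable <- function(path) {
  parameter_table(utils::read.delim(path, stringsAsFactors = FALSE))
}
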