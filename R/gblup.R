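#' Fit a GBLUP mixed model
#'
#' Fits the animal model `y = X b + Z u + e` with `u ~ N(0, G sigma_a2)`
#' and `e ~ N(0, I sigma_e2)` by AI-REML (see [reml_fit()]) and solves
#' for genomic estimated breeding values (GEBVs).  Records named in
#' `mask_ids` have their phenotypes withheld from the fit; their GEBVs
#' (and those of any genotyped-but-unphenotyped sample in `g`) are
#' obtained through the relationship-matrix block linking them to the
#' training samples.
#'
#' @param formula Model formula, e.g. `ww ~ herd + birth_type`.  The
#'   right-hand side names fixed-effect columns of `data`
#'   (treatment-coded); `ww ~ 1` fits an intercept-only model.
#' @param data Data frame with a sample-id column (default `"id"`), the
#'   response and the fixed-effect columns.
#' @param g A `grm` covering (at least) the phenotyped samples.
#' @param id_col Name of the sample-id column in `data`.
#' @param mask_ids Optional character vector of validation sample ids
#'   whose phenotypes are excluded from the fit.
#' @param control A [reml_control()].
#' @return An object of class `gblup` with components `varcomp`
#'   (class `varcomp`), `coefficients` (fixed effects), `gebv` (named
#'   vector over all samples of `g`), `in_training` (named logical),
#'   `fitted.values`, `residuals` (training records), `loglik`, `call`.
#' @examples
#' cfg <- sim_config(n_samples = 120, n_markers = 300, n_chromosomes = 3,
#'                   seed = 11)
#' geno <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(geno, cfg)
#' G <- condition_psd(vanraden_grm(geno))
#' fit <- gblup(ww ~ herd + birth_type, data = sim$pheno, g = G)
#' fit
#' @export
gblup <- function(formula, data, g, id_col = "id", mask_ids = NULL,
                  control = reml_control()) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data),
            inherits(g, "grm"))
  if (!id_col %in% names(data)) err("no `", id_col, "` column in data")
  resp <- all.vars(formula[[2]])
  if (!resp %in% names(data)) err("response `", resp, "` not in data")

  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) err("duplicated sample ids in data")
  keep <- is.finite(data[[resp]]) & ids %in% g$samples
  if (!is.null(mask_ids)) keep <- keep & !(ids %in% mask_ids)
  if (sum(keep) < 3) err("fewer than 3 training records")
  train <- data[keep, , drop = FALSE]
  tid <- ids[keep]

  mf <- stats::model.frame(formula, data = train)
  y <- stats::model.response(mf)
  X <- drop_aliased(stats::model.matrix(attr(mf, "terms"), mf))

  design <- structure(list(y = y, X = X, ids = tid,
                           idx = match(tid, g$samples)),
                      class = "mm_design")
  vc <- reml_fit(design, g, control)
  pred <- gblup_predict(design, g, vc, predict_ids = g$samples)
  u <- stats::setNames(pred$gebv, pred$id)

  fitted_tr <- drop(X %*% vc$beta) + u[tid]
  out <- structure(list(
    call = match.call(), formula = formula, varcomp = vc,
    coefficients = vc$beta,
    gebv = u,
    in_training = stats::setNames(g$samples %in% tid, g$samples),
    y = stats::setNames(y, tid), X = X,
    fitted.values = stats::setNames(fitted_tr, tid),
    residuals = stats::setNames(y - fitted_tr, tid),
    loglik = vc$loglik,
    grm_info = list(n_samples = length(g$samples),
                    n_markers = g$n_markers, gamma = g$gamma)
  ), class = "gblup")
  out
}

#' Genomic breeding values from a fitted variance structure
#'
#' Solves the mixed-model equations on the training records
#' (`lambda = sigma_e2 / sigma_a2`) and propagates breeding values to
#' `predict_ids` through the relationship matrix:
#' `u_hat = sigma_a2 * G[predict, train] V^{-1} (y - X b_hat)` with
#' `V = sigma_a2 G[train, train] + sigma_e2 I`.
#'
#' @param design An `mm_design` (training records only; validation
#'   phenotypes must already be withheld).
#' @param g A `grm` covering training and prediction samples.
#' @param vc A `varcomp` from [reml_fit()].
#' @param predict_ids Samples to predict (default: all samples of `g`).
#' @return A data frame with `id`, `gebv` (kg deviation) and
#'   `in_training`.
#' @export
gblup_predict <- function(design, g, vc, predict_ids = g$samples) {
  stopifnot(inherits(g, "grm"), inherits(vc, "varcomp"))
  d <- as_design(design, g)
  pidx <- match(predict_ids, g$samples)
  if (anyNA(pidx)) err("predict_ids not covered by the GRM")
  n <- length(d$y)
  if (vc$sigma_a2 <= 0 || vc$sigma_a2 < 1e-12 * (vc$sigma_a2 + vc$sigma_e2)) {
    warning("sigma_a2 is (near) zero; all GEBVs are 0")
    return(data.frame(id = predict_ids, gebv = 0,
                      in_training = predict_ids %in% d$ids,
                      stringsAsFactors = FALSE))
  }
  Gtt <- g$values[d$idx, d$idx, drop = FALSE]
  V <- vc$sigma_a2 * Gtt + diag(vc$sigma_e2, n)
  cV <- chol(V)
  ViX <- backsolve(cV, forwardsolve(t(cV), d$X))
  Viy <- backsolve(cV, forwardsolve(t(cV), d$y))
  beta <- solve(crossprod(d$X, ViX), crossprod(d$X, Viy))
  r <- d$y - drop(d$X %*% beta)
  Vir <- backsolve(cV, forwardsolve(t(cV), r))
  u <- vc$sigma_a2 * drop(g$values[pidx, d$idx, drop = FALSE] %*% Vir)
  data.frame(id = predict_ids, gebv = u,
             in_training = predict_ids %in% d$ids,
             stringsAsFactors = FALSE)
}

#' Extract genomic breeding values
#'
#' @param object A fitted [gblup()] model.
#' @param ids Samples to return (default all).
#' @return A data frame with `id`, `gebv`, `in_training`.
#' @export
gebv <- function(object, ids = NULL) {
  stopifnot(inherits(object, "gblup"))
  if (is.null(ids)) ids <- names(object$gebv)
  miss <- setdiff(ids, names(object$gebv))
  if (length(miss)) err("unknown sample id(s): ", paste(miss, collapse = ", "))
  data.frame(id = ids, gebv = unname(object$gebv[ids]),
             in_training = unname(object$in_training[ids]),
             stringsAsFactors = FALSE)
}

#' @export
print.gblup <- function(x, ...) {
  cat("GBLUP mixed model (AI-REML)\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  %d training records, %d genotyped samples\n",
              length(x$y), x$grm_info$n_samples))
  cat(sprintf("  sigma_a2 %.4f, sigma_e2 %.4f, h2 %.3f, logLik %.3f\n",
              x$varcomp$sigma_a2, x$varcomp$sigma_e2, x$varcomp$h2,
              x$loglik))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  vc <- object$varcomp
  se_tab <- data.frame(estimate = object$coefficients)
  structure(list(call = object$call, varcomp = vc,
                 coefficients = se_tab,
                 n_train = length(object$y),
                 n_samples = object$grm_info$n_samples,
                 gamma = object$grm_info$gamma,
                 gebv_summary = summary(object$gebv)),
            class = "summary.gblup")
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat("GBLUP mixed model (AI-REML)\n  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  records: %d training / %d genotyped\n", x$n_train, x$n_samples))
  if (!is.null(x$gamma)) cat(sprintf("  blended GRM, gamma = %.3f\n", x$gamma))
  cat(sprintf("\nVariance components:\n  sigma_a2 %.4f  sigma_e2 %.4f  h2 %.4f (logLik %.3f%s)\n",
              x$varcomp$sigma_a2, x$varcomp$sigma_e2, x$varcomp$h2,
              x$varcomp$loglik,
              if (x$varcomp$converged) "" else ", NOT converged"))
  cat("\nFixed effects:\n")
  print(round(x$coefficients, 4))
  cat("\nGEBV distribution (kg):\n")
  print(signif(x$gebv_summary, 4))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$coefficients

#' @export
fitted.gblup <- function(object, ...) object$fitted.values

#' @export
residuals.gblup <- function(object, ...) object$residuals

#' @export
predict.gblup <- function(object, ids = NULL, ...) gebv(object, ids)

#' @export
logLik.gblup <- function(object, ...) {
  structure(object$loglik, df = 2 + length(object$coefficients),
            class = "logLik")
}

#' Simulate phenotypes from a fitted GBLUP model
#'
#' Draws `y* = X b_hat + u* + e*` for the training records, with
#' `u* ~ N(0, sigma_a2 G)` and `e* ~ N(0, sigma_e2 I)` at the REML
#' estimates.  Requires the fitting `grm` to be supplied again (it is
#' not stored in the object to keep fits light).
#'
#' @param object A fitted [gblup()] model.
#' @param nsim Number of replicate phenotype vectors.
#' @param seed Optional seed.
#' @param g The `grm` used in the fit.
#' @param ... Unused.
#' @return A data frame with one column per replicate, rows aligned to
#'   the training records.
#' @export
simulate.gblup <- function(object, nsim = 1, seed = NULL, g, ...) {
  stopifnot(inherits(object, "gblup"), inherits(g, "grm"))
  tid <- names(object$y)
  idx <- match(tid, g$samples)
  if (anyNA(idx)) err("the supplied grm does not cover the training samples")
  n <- length(tid)
  Gtt <- g$values[idx, idx, drop = FALSE]
  ch <- chol(Gtt + diag(1e-8, n))
  vc <- object$varcomp
  mu <- drop(object$X %*% object$coefficients)
  with_seed(seed, {
    out <- replicate(nsim, {
      u <- sqrt(vc$sigma_a2) * drop(crossprod(ch, stats::rnorm(n)))
      mu + u + stats::rnorm(n, 0, sqrt(vc$sigma_e2))
    })
    out <- as.data.frame(out)
    names(out) <- paste0("sim_", seq_len(nsim))
    rownames(out) <- tid
    out
  })
}

#' Plot a fitted GBLUP model
#'
#' Scatter of the fixed-effect-adjusted phenotype against the GEBV for
#' the training records, with the identity-through-origin least-squares
#' line.
#'
#' @param x A fitted [gblup()] model.
#' @param ... Passed to [plot()].
#' @export
plot.gblup <- function(x, ...) {
  tid <- names(x$y)
  adj <- x$y - drop(x$X %*% x$coefficients)
  u <- x$gebv[tid]
  plot(u, adj, xlab = "GEBV (kg)", ylab = "adjusted phenotype (kg)",
       main = "GBLUP training fit", ...)
  graphics::abline(stats::lm(adj ~ u), lty = 2)
  invisible(x)
}
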