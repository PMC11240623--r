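#' Build the mixed-model design from a phenotype table
#'
#' Treatment-codes the herd and birth-type fixed effects (first level as
#' reference, intercept included), checks the design for rank
#' deficiency and drops aliased columns with a message, and records the
#' mapping from phenotype records to positions in the genotyped sample
#' order.
#'
#' @param pheno Data frame with columns `id`, `ww`, `herd`,
#'   `birth_type` (see [read_phenotypes()]).
#' @param sample_order Character vector of genotyped sample ids; every
#'   phenotyped sample must appear in it.
#' @return An object of class `mm_design`: list with `y` (response,
#'   kg), `X` (full-column-rank fixed-effect design), `ids` (record
#'   ids) and `idx` (position of each record in `sample_order`).
#' @export
build_design <- function(pheno, sample_order) {
  stopifnot(is.data.frame(pheno),
            all(c("id", "ww", "herd", "birth_type") %in% names(pheno)))
  idx <- match(pheno$id, sample_order)
  if (anyNA(idx)) {
    err("phenotyped sample(s) absent from sample_order: ",
        paste(utils::head(pheno$id[is.na(idx)], 5), collapse = ", "))
  }
  df <- data.frame(herd = factor(pheno$herd),
                   birth_type = factor(pheno$birth_type))
  terms <- c("herd", "birth_type")[vapply(df, nlevels, 0L) > 1]
  for (v in names(df)[vapply(df, nlevels, 0L) == 1]) {
    message("fixed effect `", v, "` has a single level and contributes no columns")
  }
  for (v in c("herd", "birth_type")) {
    lone <- names(which(table(df[[v]]) == 1))
    if (length(lone)) {
      warning("fixed effect `", v, "` level(s) with a single observation: ",
              paste(lone, collapse = ", "))
    }
  }
  X <- if (length(terms)) {
    stats::model.matrix(stats::reformulate(terms), data = df)
  } else {
    matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  }
  X <- drop_aliased(X)
  structure(list(y = as.numeric(pheno$ww), X = X,
                 ids = as.character(pheno$id), idx = idx),
            class = "mm_design")
}

# Drop linearly dependent design columns (pivoted QR), with a message.
drop_aliased <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[-seq_len(q$rank)]]
    message("dropping aliased design column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  X
}

#' Narrow-sense heritability from variance components
#'
#' @param sigma_a2 Additive-genetic variance (>= 0).
#' @param sigma_e2 Residual variance (>= 0); the two must not both be
#'   zero.
#' @return `sigma_a2 / (sigma_a2 + sigma_e2)`.
#' @examples
#' heritability(1.135, 8.153)  # 0.122 at 3 dp
#' @export
heritability <- function(sigma_a2, sigma_e2) {
  if (any(sigma_a2 < 0) || any(sigma_e2 < 0)) {
    err("variance components must be non-negative")
  }
  tot <- sigma_a2 + sigma_e2
  if (any(tot == 0)) err("both variance components are zero")
  sigma_a2 / tot
}

#' Control parameters for the REML fitter
#'
#' @param max_iter Maximum number of iterations (default 100).
#' @param tol Convergence tolerance on the change in restricted
#'   log-likelihood (default `1e-8`).
#' @param verbose Print the iteration trace.
#' @return A list of class `reml_control`.
#' @export
reml_control <- function(max_iter = 100L, tol = 1e-8, verbose = FALSE) {
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 verbose = isTRUE(verbose)), class = "reml_control")
}

#' Fit variance components by average-information REML
#'
#' Fits the single-kernel animal model `y = X b + u + e` with
#' `u ~ N(0, G sigma_a2)` and `e ~ N(0, I sigma_e2)` by restricted
#' maximum likelihood.  The relationship matrix is eigen-rotated once,
#' after which each iteration is an average-information (AI) update
#' with expectation-maximization fallback steps whenever the AI step is
#' not defined or does not improve the restricted likelihood;
#' step-halving keeps accepted log-likelihoods monotone.  Estimates are
#' clamped at `1e-8` times the phenotypic variance.
#'
#' @param design An `mm_design` from [build_design()] (or a list with
#'   numeric `y`, matrix `X`, and `idx`/`ids` aligned to `g`).
#' @param g A `grm` covering at least the phenotyped samples; condition
#'   it with [condition_psd()] if it may be singular.
#' @param control A [reml_control()].
#' @return An object of class `varcomp`: `sigma_a2`, `sigma_e2`, `h2`,
#'   `loglik`, `n_iter`, `converged`, plus the GLS fixed-effect
#'   estimates in `$beta` and the iteration log-likelihood trace in
#'   `attr(, "ll_trace")`.
#' @export
reml_fit <- function(design, g, control = reml_control()) {
  stopifnot(inherits(g, "grm"))
  d <- as_design(design, g)
  H <- g$values[d$idx, d$idx, drop = FALSE]
  fit <- reml_eigen(d$y, d$X, H, control)
  fit
}

as_design <- function(design, g) {
  if (inherits(design, "mm_design")) {
    idx <- match(design$ids, g$samples)
    if (anyNA(idx)) err("design records not covered by the GRM")
    list(y = design$y, X = design$X, idx = idx, ids = design$ids)
  } else if (is.list(design) && !is.null(design$y) && !is.null(design$X)) {
    idx <- design$idx
    if (is.null(idx)) idx <- match(design$ids, g$samples)
    list(y = as.numeric(design$y), X = as.matrix(design$X), idx = idx,
         ids = design$ids)
  } else err("design must be an mm_design or a list with y, X, idx")
}

# Core REML engine in the eigen-rotated space of H (the phenotyped-sample
# block of G).  All per-iteration work is O(n p^2).
reml_eigen <- function(y, X, H, control = reml_control()) {
  n <- length(y); p <- ncol(X)
  if (n < p + 2) err("too few records for the fixed-effect design")
  ee <- eigen(H, symmetric = TRUE)
  dvec <- ee$values
  U <- ee$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  vp <- stats::var(y)
  lo <- 1e-8 * vp

  # restricted log-likelihood and P-products at th
  eval_ll <- function(th) {
    v <- th[1] * dvec + th[2]
    if (any(v <= 0)) return(NULL)
    vi <- 1 / v
    XtVi <- Xt * vi
    B <- crossprod(Xt, XtVi)
    cB <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(cB)) return(NULL)
    beta <- backsolve(cB, forwardsolve(t(cB), crossprod(XtVi, yt)))
    Py <- vi * (yt - drop(Xt %*% beta))
    ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(cB))) + sum(yt * Py))
    list(ll = ll, vi = vi, B = B, cB = cB, beta = beta, Py = Py)
  }
  # apply P to a vector, given state
  apply_P <- function(st, w) {
    viw <- st$vi * w
    viw - st$vi * drop(Xt %*% backsolve(st$cB, forwardsolve(t(st$cB),
                                                            crossprod(Xt, viw))))
  }
  tr_P_diag <- function(st, gdiag) {
    # tr(P diag(gdiag)) = sum(vi*g) - tr(B^-1 Xt' diag(vi g vi) Xt)
    A <- crossprod(Xt, Xt * (st$vi^2 * gdiag))
    sum(st$vi * gdiag) - sum(chol2inv(st$cB) * A)
  }

  # The restricted-likelihood surface can be bimodal at small n; the
  # iteration therefore runs from several starting heritabilities and
  # the best-likelihood solution is kept.
  run_from <- function(th) {
  st <- eval_ll(th)
  if (is.null(st)) err("REML likelihood undefined at starting values")
  ll_trace <- st$ll
  converged <- FALSE
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    Py <- st$Py
    w_a <- dvec * Py
    yPVaPy <- sum(Py * w_a)
    yPVePy <- sum(Py * Py)
    trPVa <- tr_P_diag(st, dvec)
    trPVe <- tr_P_diag(st, rep(1, n))
    sc <- c(-0.5 * (trPVa - yPVaPy), -0.5 * (trPVe - yPVePy))

    Pwa <- apply_P(st, w_a)
    Pwe <- apply_P(st, Py)
    AI <- 0.5 * rbind(c(sum(w_a * Pwa), sum(w_a * Pwe)),
                      c(sum(Py * Pwa), sum(Py * Pwe)))

    # candidate updates: AI step, boundary-projected AI step (Newton on
    # the free coordinate when the other is clamped), EM step, and
    # single-coordinate Newton steps.  The best improving candidate
    # (after step-halving) is accepted, which keeps the algorithm an
    # AI-REML with EM fallback while remaining stable at the boundary.
    cands <- list()
    step_ai <- tryCatch(drop(solve(AI, sc)), error = function(e) NULL)
    if (!is.null(step_ai) && all(is.finite(step_ai)) &&
        all(diag(AI) > 0)) {
      if (it > 1L) cands <- c(cands, list(step_ai))
      at_lo <- th <= lo * (1 + 1e-6)
      if (any(at_lo & step_ai < 0)) {
        pr <- c(0, 0)
        free <- which(!(at_lo & step_ai < 0))
        if (length(free)) pr[free] <- sc[free] / diag(AI)[free]
        cands <- c(cands, list(pr))
      }
    }
    step_em <- c(th[1]^2 * (yPVaPy - trPVa) / n,
                 th[2]^2 * (yPVePy - trPVe) / n)
    cands <- c(cands, list(step_em))
    if (!is.null(step_ai) && all(diag(AI) > 0)) {
      cands <- c(cands, list(c(sc[1] / AI[1, 1], 0)),
                 list(c(0, sc[2] / AI[2, 2])))
    }

    best <- NULL
    for (step in cands) {
      if (any(!is.finite(step))) next
      for (h in 0:25) {
        th_new <- pmax(th + step / 2^h, lo)
        if (all(th_new == th)) break
        st_new <- eval_ll(th_new)
        if (!is.null(st_new) && st_new$ll > st$ll &&
            (is.null(best) || st_new$ll > best$ll)) {
          best <- c(st_new, list(th = th_new))
          break
        }
      }
    }
    if (is.null(best)) { converged <- TRUE; break }  # no uphill move exists
    delta_ll <- best$ll - st$ll
    th <- best$th
    st <- best[setdiff(names(best), "th")]
    ll_trace <- c(ll_trace, st$ll)
    if (control$verbose) {
      message(sprintf("iter %d: sigma_a2 %.6g sigma_e2 %.6g ll %.8f",
                      it, th[1], th[2], st$ll))
    }
    if (abs(delta_ll) < control$tol) { converged <- TRUE; break }
  }
  list(th = th, st = st, ll_trace = ll_trace, converged = converged,
       n_iter = it)
  }

  starts <- lapply(c(0.5, 0.1, 0.9),
                   function(h) c(a = h * vp, e = (1 - h) * vp))
  runs <- lapply(starts, run_from)
  best <- runs[[which.max(vapply(runs, function(r) r$st$ll, numeric(1)))]]
  th <- best$th; st <- best$st

  out <- structure(list(sigma_a2 = unname(th[1]), sigma_e2 = unname(th[2]),
                        h2 = unname(th[1] / sum(th)), loglik = st$ll,
                        n_iter = best$n_iter, converged = best$converged,
                        beta = stats::setNames(drop(st$beta), colnames(X))),
                   class = "varcomp")
  attr(out, "ll_trace") <- best$ll_trace
  out
}

#' @export
print.varcomp <- function(x, ...) {
  cat("REML variance components\n")
  cat(sprintf("  sigma_a2 = %.4f  sigma_e2 = %.4f  h2 = %.4f\n",
              x$sigma_a2, x$sigma_e2, x$h2))
  cat(sprintf("  REML log-likelihood %.4f after %d iteration(s)%s\n",
              x$loglik, x$n_iter,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Write a variance-component report
#'
#' @param vc A `varcomp` from [reml_fit()].
#' @param path Output file; `key<TAB>value` lines.
#' @return Invisibly, `path`.
#' @export
write_varcomp <- function(vc, path) {
  stopifnot(inherits(vc, "varcomp"))
  keys <- c(sigma_a2 = vc$sigma_a2, sigma_e2 = vc$sigma_e2, h2 = vc$h2,
            loglik = vc$loglik, n_iter = vc$n_iter,
            converged = as.integer(vc$converged))
  writeLines(paste(names(keys), format(keys, digits = 12), sep = "\t"), path)
  invisible(path)
}
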