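#' Fixed-effect single-marker scan
#'
#' For every marker, regresses the phenotype on an intercept, the
#' supplied covariates, the current pseudo-QTN dosages and the marker
#' dosage by ordinary least squares, and reports the marker
#' coefficient's two-sided t-test p-value.  Markers lying within
#' `spacing_bp` of a pseudo-QTN (same chromosome) are tested with that
#' pseudo-QTN dropped from the covariates, which avoids the
#' self-masking artifact; the pseudo-QTNs themselves are scored by the
#' t-test of their own coefficient in the joint covariate model.
#' Markers collinear with the design are flagged and assigned p = 1.
#'
#' @param geno A [geno_matrix()] with no missing dosages.
#' @param pheno Numeric phenotype vector aligned to `geno$samples`, or
#'   a phenotype data frame (columns `id`, `ww`) matched by id.
#' @param covariates Optional numeric design matrix of non-genetic
#'   covariates (no intercept column; e.g. treatment-coded herd and
#'   birth-type contrasts), rows aligned to samples.
#' @param qtn_ids Character ids of pseudo-QTN markers used as fixed
#'   covariates (may be empty).
#' @param spacing_bp Exclusion-window half-width around each pseudo-QTN
#'   (default 1 Mb).
#' @return An object of class `gwas_result`: list with `scan` (data
#'   frame `id`, `chrom`, `pos`, `effect`, `se`, `p`, `is_pseudo_qtn`,
#'   `flagged`), `pseudo_qtn_ids`, `n_iterations`, `converged`.
#' @export
glm_scan <- function(geno, pheno, covariates = NULL,
                     qtn_ids = character(0), spacing_bp = 1e6) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (anyNA(geno$dosages)) err("missing dosages; impute before scanning")
  y <- align_pheno(pheno, geno$samples)
  n <- length(y); m <- ncol(geno$dosages)
  M <- geno$dosages
  storage.mode(M) <- "double"

  qtn_ids <- unique(as.character(qtn_ids))
  qtn_idx <- match(qtn_ids, geno$map$id)
  if (anyNA(qtn_idx)) err("pseudo-QTN id(s) not in the marker map")

  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  W <- cbind(C, M[, qtn_idx, drop = FALSE])
  qW <- qr(W)
  if (qW$rank < ncol(W)) {
    W <- W[, qW$pivot[seq_len(qW$rank)], drop = FALSE]
    qW <- qr(W)
  }
  df <- n - qW$rank - 1L
  if (df < 1) err("not enough residual degrees of freedom for the scan")

  ry <- qr.resid(qW, y)
  RM <- qr.resid(qW, M)
  sxx <- colSums(RM^2)
  sxy <- colSums(RM * ry)
  tot <- colSums(scale(M, scale = FALSE)^2)
  collinear <- sxx <= pmax(1e-12, 1e-10 * tot)
  b <- ifelse(collinear, NA_real_, sxy / sxx)
  rss <- pmax(sum(ry^2) - b * sxy, 0)
  se <- sqrt(rss / df / sxx)
  tstat <- b / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  pval[collinear] <- 1
  se[collinear] <- NA_real_

  # pseudo-QTNs: coefficient tests from the joint model
  if (length(qtn_idx)) {
    WtW <- crossprod(W)
    co <- drop(solve(WtW, crossprod(W, y)))
    resid <- y - drop(W %*% co)
    s2 <- sum(resid^2) / (n - qW$rank)
    ses <- sqrt(diag(solve(WtW)) * s2)
    names(co) <- names(ses) <- colnames(W)
    qcols <- match(colnames(M)[qtn_idx], colnames(W))
    for (k in seq_along(qtn_idx)) {
      j <- qtn_idx[k]; col <- qcols[k]
      if (is.na(col)) {  # dropped as collinear within the qtn block
        b[j] <- NA_real_; se[j] <- NA_real_; pval[j] <- 1
        collinear[j] <- TRUE
        next
      }
      b[j] <- co[col]; se[j] <- ses[col]
      pval[j] <- 2 * stats::pt(-abs(co[col] / ses[col]), n - qW$rank)
    }

    # markers inside a pseudo-QTN window: retest with that QTN dropped
    for (j in setdiff(window_markers(geno$map, qtn_idx, spacing_bp), qtn_idx)) {
      near <- qtn_idx[geno$map$chrom[qtn_idx] == geno$map$chrom[j] &
                        abs(geno$map$pos[qtn_idx] - geno$map$pos[j]) <= spacing_bp]
      keep_cols <- setdiff(colnames(W), colnames(M)[near])
      Wj <- W[, keep_cols, drop = FALSE]
      qWj <- qr(Wj)
      dfj <- n - qWj$rank - 1L
      ryj <- qr.resid(qWj, y)
      rxj <- qr.resid(qWj, M[, j])
      sxxj <- sum(rxj^2)
      if (sxxj <= max(1e-12, 1e-10 * tot[j]) || dfj < 1) {
        b[j] <- NA_real_; se[j] <- NA_real_; pval[j] <- 1; collinear[j] <- TRUE
        next
      }
      sxyj <- sum(rxj * ryj)
      b[j] <- sxyj / sxxj
      rssj <- max(sum(ryj^2) - b[j] * sxyj, 0)
      se[j] <- sqrt(rssj / dfj / sxxj)
      pval[j] <- 2 * stats::pt(-abs(b[j] / se[j]), dfj)
      collinear[j] <- FALSE
    }
  }

  scan <- data.frame(id = geno$map$id, chrom = geno$map$chrom,
                     pos = geno$map$pos, effect = b, se = se, p = pval,
                     is_pseudo_qtn = seq_len(m) %in% qtn_idx,
                     flagged = collinear, stringsAsFactors = FALSE)
  structure(list(scan = scan, pseudo_qtn_ids = qtn_ids,
                 n_iterations = 1L, converged = TRUE,
                 covariates = colnames(C)[-1]),
            class = "gwas_result")
}

# indices of markers within spacing of any pseudo-QTN (incl. the QTNs)
window_markers <- function(map, qtn_idx, spacing_bp) {
  out <- integer(0)
  for (j in qtn_idx) {
    out <- c(out, which(map$chrom == map$chrom[j] &
                          abs(map$pos - map$pos[j]) <= spacing_bp))
  }
  unique(out)
}

align_pheno <- function(pheno, samples) {
  if (is.data.frame(pheno)) {
    idx <- match(samples, pheno$id)
    if (anyNA(idx)) err("phenotype table does not cover all genotyped samples")
    y <- as.numeric(pheno$ww[idx])
  } else {
    y <- as.numeric(pheno)
    if (length(y) != length(samples)) {
      err("phenotype vector length does not match the sample count")
    }
  }
  if (anyNA(y)) err("phenotypes contain missing values")
  y
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("gwas_result: %d markers scanned, %d pseudo-QTN(s), %d iteration(s)%s\n",
              nrow(x$scan), length(x$pseudo_qtn_ids), x$n_iterations,
              if (x$converged) "" else " (NOT converged)"))
  top <- x$scan[order(x$scan$p), ][1:min(5, nrow(x$scan)), c("id", "chrom", "pos", "effect", "p")]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Control parameters for the iterative scan
#'
#' @param max_iter Maximum fixed/random iterations (default 10).
#' @param spacing_bp Minimum spacing between pseudo-QTNs and the
#'   covariate-exclusion window (default 1 Mb).
#' @param set_sizes Candidate pseudo-QTN set sizes swept at each
#'   random-model step (default `c(2, 4, 8, 16)`).
#' @param prefilter_p Only markers below this scan p-value enter the
#'   candidate pool (default 0.01).
#' @return A list of class `farmcpu_control`.
#' @export
farmcpu_control <- function(max_iter = 10L, spacing_bp = 1e6,
                            set_sizes = c(2L, 4L, 8L, 16L),
                            prefilter_p = 0.01) {
  structure(list(max_iter = as.integer(max_iter), spacing_bp = spacing_bp,
                 set_sizes = sort(unique(as.integer(set_sizes))),
                 prefilter_p = prefilter_p),
            class = "farmcpu_control")
}

#' Iterative fixed/random-model association scan (FarmCPU style)
#'
#' Alternates (a) a fixed-effect single-marker scan with the current
#' pseudo-QTNs as covariates ([glm_scan()]) and (b) a random-model step
#' that re-selects the pseudo-QTN set: the most significant markers
#' passing a p-value pre-filter, subject to a minimum spacing, are
#' swept over candidate set sizes, each size scored by the REML
#' likelihood of an animal model whose kinship is built from the
#' candidate markers alone, and the best-scoring set is accepted only
#' if its likelihood is no worse than the previously accepted one.
#' Iteration stops when the pseudo-QTN set repeats, the likelihood
#' stops improving, or `max_iter` is reached.
#'
#' @inheritParams glm_scan
#' @param control A [farmcpu_control()].
#' @return A `gwas_result` whose `scan` holds the final-iteration
#'   p-values and whose `pseudo_qtn_ids` is the accepted set;
#'   `attr(, "loglik_trace")` records the accepted REML likelihoods.
#' @export
farmcpu <- function(geno, pheno, covariates = NULL,
                    control = farmcpu_control()) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(control, "farmcpu_control"))
  y <- align_pheno(pheno, geno$samples)
  n <- length(y)
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)

  qtn <- character(0)
  best_ll <- -Inf
  ll_trace <- numeric(0)
  seen <- list(character(0))
  converged <- FALSE
  scan <- NULL
  scan_qtn <- NULL
  it <- 0L

  while (it < control$max_iter) {
    it <- it + 1L
    res <- glm_scan(geno, y, covariates, qtn, control$spacing_bp)
    scan <- res$scan; scan_qtn <- qtn

    pool <- scan[!scan$flagged & scan$p < control$prefilter_p, , drop = FALSE]
    pool <- pool[order(pool$p, pool$chrom, pool$pos), , drop = FALSE]
    spaced <- space_filter(pool, control$spacing_bp)
    if (nrow(spaced) == 0) { converged <- TRUE; break }

    sizes <- unique(pmin(control$set_sizes, nrow(spaced)))
    cand_ll <- vapply(sizes, function(s) {
      ids <- spaced$id[seq_len(s)]
      Gc <- condition_psd(vanraden_grm(subset_geno(geno, markers = ids)))
      reml_eigen(y, X0, Gc$values, reml_control(max_iter = 50, tol = 1e-6))$loglik
    }, numeric(1))
    s_best <- sizes[which.max(cand_ll)]
    ll_best <- max(cand_ll)
    new_qtn <- spaced$id[seq_len(s_best)]

    if (setequal(new_qtn, qtn)) { converged <- TRUE; break }
    if (ll_best < best_ll) { converged <- TRUE; break }  # monotone acceptance
    if (any(vapply(seen, function(s) setequal(s, new_qtn), logical(1)))) {
      qtn <- new_qtn
      converged <- TRUE
      break
    }
    qtn <- new_qtn
    best_ll <- ll_best
    ll_trace <- c(ll_trace, ll_best)
    seen <- c(seen, list(qtn))
  }

  if (!identical(sort(scan_qtn), sort(qtn))) {
    res <- glm_scan(geno, y, covariates, qtn, control$spacing_bp)
    scan <- res$scan
  }
  out <- structure(list(scan = scan, pseudo_qtn_ids = qtn,
                        n_iterations = it, converged = converged,
                        covariates = colnames(X0)[-1]),
                   class = "gwas_result")
  attr(out, "loglik_trace") <- ll_trace
  out
}

# greedy minimum-spacing thinning of a p-sorted candidate table
space_filter <- function(pool, spacing_bp) {
  keep <- logical(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    prior <- which(keep)
    clash <- any(pool$chrom[prior] == pool$chrom[i] &
                   abs(pool$pos[prior] - pool$pos[i]) < spacing_bp)
    keep[i] <- !clash
  }
  pool[keep, , drop = FALSE]
}

#' Select the top fraction of markers by p-value
#'
#' Picks the `round(fraction * m)` markers with the smallest p-values
#' (round-half-even), ties broken by (p, chromosome, position) in a
#' stable order -- the prior-marker sets at 5/10/15/20%.
#'
#' @param result A `gwas_result`.
#' @param fraction Fraction of markers to keep, in `(0, 1]`.
#' @return An object of class `marker_set`: list with `ids` (genome
#'   order not guaranteed; selection order by significance),
#'   `fraction` and `source`.
#' @export
select_top <- function(result, fraction) {
  stopifnot(inherits(result, "gwas_result"))
  check_fraction(fraction, "fraction", lo_open = TRUE)
  m <- nrow(result$scan)
  k <- round(fraction * m)
  if (k < 1) err("fraction selects no markers (round(fraction * m) < 1)")
  o <- order(result$scan$p, result$scan$chrom, result$scan$pos)
  structure(list(ids = result$scan$id[o][seq_len(k)],
                 fraction = fraction,
                 source = sprintf("top %.3g%% of %d markers by scan p-value",
                                  100 * fraction, m)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d markers (%s)\n", length(x$ids), x$source))
  invisible(x)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param m Number of tested markers (>= 1).
#' @param alpha Family-wise significance level in `(0, 1]`; `alpha = 1`
#'   gives the `1/m` convention, `alpha = 0.05` the usual corrected
#'   level.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  stopifnot(m >= 1)
  check_fraction(alpha, "alpha", lo_open = TRUE)
  alpha / m
}

#' Write an association scan as TSV
#'
#' Columns `chrom, pos, id, effect, se, p, is_pseudo_qtn`, consumable
#' by Manhattan/QQ plotting tools.
#'
#' @param result A `gwas_result`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gwas <- function(result, path) {
  stopifnot(inherits(result, "gwas_result"))
  utils::write.table(result$scan[c("chrom", "pos", "id", "effect", "se",
                                   "p", "is_pseudo_qtn")],
                     path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
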