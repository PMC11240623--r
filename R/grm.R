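#' Genomic relationship matrix (VanRaden)
#'
#' Builds the VanRaden genomic relationship matrix
#' `G = Z Z' / (2 * sum(p_i (1 - p_i)))`, where `Z` is the dosage matrix
#' column-centered by twice the observed counted-allele frequency
#' `p_i`.  Frequencies are computed on the samples actually present in
#' the matrix.  Monomorphic markers contribute nothing and are excluded
#' from the denominator with a warning.
#'
#' @param g A [geno_matrix()] with no missing dosages (run
#'   [mean_impute()] first if needed).
#' @return An object of class `grm`: a list with `values` (symmetric
#'   `n x n` matrix), `samples`, `n_markers` (markers entering the
#'   denominator), `gamma` (`NULL` unless blended) and `conditioned`.
#' @examples
#' g <- geno_matrix(rbind(c(0L, 2L), c(2L, 0L)),
#'                  data.frame(chrom = 1L, pos = c(1L, 2L),
#'                             id = c("m1", "m2"), a1 = "A", a2 = "C"),
#'                  c("s1", "s2"))
#' vanraden_grm(g)$values
#' @export
vanraden_grm <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  dos <- g$dosages
  if (anyNA(dos)) err("missing dosages; impute before building a GRM")
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) err("all markers are monomorphic; GRM undefined")
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic marker(s) excluded from the GRM denominator")
  }
  Z <- sweep(dos, 2L, 2 * p, "-")
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  new_grm(G, g$samples, n_markers = sum(poly))
}

new_grm <- function(values, samples, n_markers = NA_integer_, gamma = NULL,
                    conditioned = FALSE) {
  values <- (values + t(values)) / 2  # enforce exact symmetry
  dimnames(values) <- list(samples, samples)
  structure(list(values = values, samples = as.character(samples),
                 n_markers = n_markers, gamma = gamma,
                 conditioned = conditioned),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, %s markers%s%s\n",
              length(x$samples),
              if (is.na(x$n_markers)) "?" else x$n_markers,
              if (!is.null(x$gamma)) sprintf(", blended (gamma = %.3f)", x$gamma) else "",
              if (isTRUE(x$conditioned)) ", diagonal-conditioned" else ""))
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.4f\n",
              mean(diag(x$values)),
              (sum(x$values) - sum(diag(x$values))) /
                (length(x$values) - length(x$samples))))
  invisible(x)
}

#' Partition a marker map by a prior marker set
#'
#' Splits the markers of a genotype matrix (or marker-id vector) into
#' the prior set selected by the association scan and the remainder,
#' both in genome order.  Used to build the `G1` (prior) and `G2`
#' (remaining) relationship matrices.
#'
#' @param all_markers A [geno_matrix()], or a character vector of marker
#'   ids in genome order.
#' @param prior A [select_top()] marker set, or a character vector of
#'   marker ids.  Must be a non-empty strict subset of `all_markers`.
#' @return A list with character vectors `prior` and `remaining`.
#' @export
partition_markers <- function(all_markers, prior) {
  ids <- if (inherits(all_markers, "geno_matrix")) all_markers$map$id
         else as.character(all_markers)
  pid <- if (inherits(prior, "marker_set")) prior$ids else as.character(prior)
  if (length(pid) == 0) err("prior marker set is empty; G1 undefined")
  missing <- setdiff(pid, ids)
  if (length(missing)) {
    err("prior marker(s) absent from the map: ",
        paste(utils::head(missing, 5), collapse = ", "))
  }
  keep <- ids %in% pid
  if (all(keep)) err("prior set contains every marker; G2 undefined")
  list(prior = ids[keep], remaining = ids[!keep])
}

#' Blend two relationship matrices by genetic-variance shares
#'
#' Forms `G3 = gamma * G1 + (1 - gamma) * G2` with
#' `gamma = var_g1 / (var_g1 + var_g2)`, the share of the summed
#' genetic variances attributed to the prior-marker kernel.  The two
#' variances are typically the REML genetic-variance estimates from
#' separate single-kernel fits of the same trait.
#'
#' @param G1,G2 `grm` objects over identical samples in identical order.
#' @param var_g1,var_g2 Non-negative genetic variances (kg^2), not both
#'   zero.
#' @return A `grm` with the blend weight stored in `$gamma`.
#' @examples
#' # printed-table arithmetic: 1.369 / (1.369 + 1.083) = 0.558
#' round(1.369 / (1.369 + 1.083), 3)
#' @export
blend_grm <- function(G1, G2, var_g1, var_g2) {
  stopifnot(inherits(G1, "grm"), inherits(G2, "grm"))
  if (!identical(G1$samples, G2$samples)) {
    err("G1 and G2 must cover the same samples in the same order")
  }
  if (var_g1 < 0 || var_g2 < 0) err("genetic variances must be non-negative")
  if (var_g1 + var_g2 == 0) err("both genetic variances are zero; blend undefined")
  gamma <- var_g1 / (var_g1 + var_g2)
  vals <- gamma * G1$values + (1 - gamma) * G2$values
  nm <- G1$n_markers + G2$n_markers
  new_grm(vals, G1$samples, n_markers = nm, gamma = gamma)
}

#' Condition a relationship matrix to be positive definite
#'
#' REML needs an invertible `G`.  If the minimum eigenvalue is below
#' `1e-8`, a multiple of `epsilon` is added to the diagonal until the
#' spectrum clears that floor, and the `conditioned` flag is set.
#'
#' @param g A `grm` (symmetric).
#' @param epsilon Diagonal increment per step (default `1e-6`).
#' @return The (possibly unchanged) `grm`.
#' @export
condition_psd <- function(g, epsilon = 1e-6) {
  stopifnot(inherits(g, "grm"), epsilon > 0)
  ev_min <- min(eigen(g$values, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min >= 1e-8) return(g)
  k <- ceiling((1e-8 - ev_min) / epsilon)
  vals <- g$values + diag(k * epsilon, nrow(g$values))
  new_grm(vals, g$samples, n_markers = g$n_markers, gamma = g$gamma,
          conditioned = TRUE)
}

#' Principal components of a relationship matrix
#'
#' Eigen-decomposes the double-centered relationship matrix and returns
#' the top-`k` sample coordinates scaled by the square root of their
#' eigenvalues -- the usual population-structure PCA on a GRM.
#'
#' @param g A `grm`.
#' @param k Number of components (`<= n`).
#' @return A data frame with `id` and columns `PC1..PCk`; the
#'   eigenvalues are attached as `attr(, "eigenvalues")`.
#' @export
grm_pca <- function(g, k = 2L) {
  stopifnot(inherits(g, "grm"))
  n <- length(g$samples)
  if (k > n) err("k must not exceed the number of samples")
  C <- diag(n) - matrix(1 / n, n, n)
  ee <- eigen(C %*% g$values %*% C, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  coords <- ee$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  out <- data.frame(id = g$samples, coords, stringsAsFactors = FALSE)
  names(out) <- c("id", paste0("PC", seq_len(k)))
  attr(out, "eigenvalues") <- ee$values
  out
}

#' Linkage-disequilibrium decay
#'
#' For every intra-chromosomal marker pair closer than `max_dist_bp`,
#' computes the squared Pearson correlation of dosages and averages it
#' within distance bins of width `bin_bp`.
#'
#' @param g A [geno_matrix()] with no missing dosages, markers in
#'   genome order.
#' @param max_dist_bp Maximum pair distance considered (default 1 Mb).
#' @param bin_bp Bin width in bp (default 100 kb).
#' @param max_pairs_per_chrom Optional cap on pairs per chromosome
#'   (random subsample, seeded internally) to bound work on dense maps.
#' @return A data frame with `bin_start`, `bin_end`, `n_pairs`,
#'   `mean_r2`; zero rows (with a warning) when no pair qualifies.
#' @export
ld_decay <- function(g, max_dist_bp = 1e6, bin_bp = 1e5,
                     max_pairs_per_chrom = Inf) {
  stopifnot(inherits(g, "geno_matrix"))
  if (anyNA(g$dosages)) err("missing dosages; impute before LD analysis")
  dist <- numeric(0); r2 <- numeric(0)
  for (cc in unique(g$map$chrom)) {
    ci <- which(g$map$chrom == cc)
    if (length(ci) < 2) next
    pos <- g$map$pos[ci]
    pairs <- which(outer(pos, pos, function(a, b) b - a) > 0 &
                     outer(pos, pos, function(a, b) b - a) <= max_dist_bp,
                   arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    if (nrow(pairs) > max_pairs_per_chrom) {
      pairs <- pairs[with_seed(length(ci),
                               sample.int(nrow(pairs), max_pairs_per_chrom)), ,
                     drop = FALSE]
    }
    d <- pos[pairs[, 2]] - pos[pairs[, 1]]
    X <- g$dosages[, ci, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    ok <- sds[pairs[, 1]] > 0 & sds[pairs[, 2]] > 0
    pairs <- pairs[ok, , drop = FALSE]; d <- d[ok]
    if (nrow(pairs) == 0) next
    rr <- vapply(seq_len(nrow(pairs)), function(i) {
      stats::cor(X[, pairs[i, 1]], X[, pairs[i, 2]])^2
    }, numeric(1))
    dist <- c(dist, d); r2 <- c(r2, rr)
  }
  if (length(dist) == 0) {
    warning("no eligible intra-chromosomal pairs within max_dist_bp")
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      n_pairs = integer(0), mean_r2 = numeric(0)))
  }
  bin <- pmin(floor((dist - 1) / bin_bp), ceiling(max_dist_bp / bin_bp) - 1)
  agg <- tapply(r2, bin, mean)
  cnt <- tapply(r2, bin, length)
  b <- as.integer(names(agg))
  data.frame(bin_start = b * bin_bp + 1, bin_end = (b + 1) * bin_bp,
             n_pairs = as.integer(cnt), mean_r2 = unname(as.numeric(agg)))
}

#' Write / read a relationship matrix
#'
#' `write_grm()` stores a `grm` either as a plain whitespace-delimited
#' square matrix with an `.ids` sidecar (`format = "matrix"`), or in the
#' GCTA-style lower-triangle text layout (`format = "gcta"`:
#' `<prefix>.grm.txt` with columns `i j n_markers value` plus
#' `<prefix>.grm.id`).  `read_grm()` reads either layout back.
#'
#' @param g A `grm`.
#' @param prefix Output path prefix.
#' @param format `"matrix"` or `"gcta"`.
#' @return `write_grm()` invisibly returns the paths written;
#'   `read_grm()` returns a `grm`.
#' @export
write_grm <- function(g, prefix, format = c("matrix", "gcta")) {
  stopifnot(inherits(g, "grm"))
  format <- match.arg(format)
  if (format == "matrix") {
    mpath <- paste0(prefix, ".grm.matrix")
    ipath <- paste0(prefix, ".grm.ids")
    utils::write.table(format(g$values, digits = 17), mpath, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(g$samples, ipath)
    invisible(c(mpath, ipath))
  } else {
    n <- length(g$samples)
    lower <- which(row(g$values) >= col(g$values), arr.ind = TRUE)
    tab <- data.frame(i = lower[, 1], j = lower[, 2],
                      n_markers = if (is.na(g$n_markers)) 0 else g$n_markers,
                      value = g$values[lower])
    tab <- tab[order(tab$i, tab$j), ]
    gpath <- paste0(prefix, ".grm.txt")
    ipath <- paste0(prefix, ".grm.id")
    utils::write.table(format(tab, digits = 17), gpath, quote = FALSE,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(g$samples, g$samples), ipath,
                       quote = FALSE, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    invisible(c(gpath, ipath))
  }
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix, format = c("matrix", "gcta")) {
  format <- match.arg(format)
  if (format == "matrix") {
    ids <- readLines(paste0(prefix, ".grm.ids"))
    vals <- as.matrix(utils::read.table(paste0(prefix, ".grm.matrix")))
    new_grm(unname(vals), ids)
  } else {
    ids <- utils::read.table(paste0(prefix, ".grm.id"),
                             colClasses = "character")[[2]]
    tab <- utils::read.table(paste0(prefix, ".grm.txt"))
    n <- length(ids)
    vals <- matrix(0, n, n)
    vals[cbind(tab[[1]], tab[[2]])] <- tab[[4]]
    vals[cbind(tab[[2]], tab[[1]])] <- tab[[4]]
    g <- new_grm(vals, ids, n_markers = tab[[3]][1])
    g
  }
}
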