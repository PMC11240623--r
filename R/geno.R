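#' Genotype matrix container
#'
#' Bundles an `n_samples x n_markers` allele-dosage matrix with its marker
#' map and sample ids.  Dosages count copies of the marker's counted (A1)
#' allele and take values 0, 1, 2 or `NA` (missing); after
#' [mean_impute()] they are real-valued.
#'
#' @param dosages Numeric or integer matrix, samples in rows, markers in
#'   columns.  Allowed values are 0, 1, 2 and `NA` unless the matrix has
#'   been imputed.
#' @param map Data frame with one row per marker and columns `chrom`
#'   (integer chromosome, autosomes 1-26 for sheep), `pos` (1-based bp),
#'   `id` (unique marker id), `a1` (counted allele) and `a2`.
#' @param samples Character vector of unique sample ids, one per row of
#'   `dosages`.
#' @param validate Set to `FALSE` to skip invariant checks (internal use).
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `dosages`, `map` and `samples`.
#' @examples
#' g <- geno_matrix(
#'   dosages = rbind(c(0L, 1L), c(2L, NA), c(1L, 1L)),
#'   map = data.frame(chrom = c(1L, 1L), pos = c(100L, 200L),
#'                    id = c("m1", "m2"), a1 = "A", a2 = "C"),
#'   samples = c("s1", "s2", "s3"))
#' g
#' @export
geno_matrix <- function(dosages, map, samples, validate = TRUE) {
  dosages <- as.matrix(dosages)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  samples <- as.character(samples)
  obj <- structure(list(dosages = dosages, map = map, samples = samples),
                   class = "geno_matrix")
  if (validate) validate_geno(obj)
  obj
}

validate_geno <- function(g, imputed_ok = TRUE) {
  need <- c("chrom", "pos", "id", "a1", "a2")
  if (!all(need %in% names(g$map))) {
    err("marker map must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(g$map) != ncol(g$dosages)) {
    err("marker map rows (", nrow(g$map), ") do not match dosage columns (",
        ncol(g$dosages), ")")
  }
  if (length(g$samples) != nrow(g$dosages)) {
    err("sample ids (", length(g$samples), ") do not match dosage rows (",
        nrow(g$dosages), ")")
  }
  if (anyDuplicated(g$map$id)) err("duplicate marker ids in map")
  if (anyDuplicated(g$samples)) err("duplicate sample ids")
  # map sorted by (chrom, pos)
  o <- order(g$map$chrom, g$map$pos)
  if (!identical(o, seq_len(nrow(g$map)))) {
    err("marker map must be sorted by (chrom, pos)")
  }
  if (is.integer(g$dosages) || !anyNA(match(unique(as.vector(g$dosages)),
                                            c(0, 1, 2, NA)))) {
    # integer-coded: only 0/1/2/NA allowed
    v <- g$dosages
    bad <- !(is.na(v) | v == 0 | v == 1 | v == 2)
    if (any(bad)) err("integer dosages must be 0, 1, 2 or NA")
  } else if (!imputed_ok) {
    err("dosages contain non-integer values; expected raw 0/1/2 calls")
  }
  invisible(g)
}

#' @export
print.geno_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$dosages))
  cat(sprintf("geno_matrix: %d samples x %d markers on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom))))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", n_miss,
              100 * n_miss / length(x$dosages)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param g A [geno_matrix()].
#' @param samples,markers Character ids (or logical/integer index vectors)
#'   selecting rows/columns; `NULL` keeps everything.
#' @return A `geno_matrix` restricted to the selection, order preserved
#'   from `g` (genome order for markers).
#' @export
subset_geno <- function(g, samples = NULL, markers = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  ri <- seq_along(g$samples)
  ci <- seq_len(nrow(g$map))
  if (!is.null(samples)) {
    if (is.character(samples)) {
      ri <- match(samples, g$samples)
      if (anyNA(ri)) err("unknown sample id(s): ",
                         paste(samples[is.na(ri)], collapse = ", "))
      ri <- sort(ri)  # preserve stored order
    } else ri <- ri[samples]
  }
  if (!is.null(markers)) {
    if (is.character(markers)) {
      ci <- match(markers, g$map$id)
      if (anyNA(ci)) err("unknown marker id(s): ",
                         paste(markers[is.na(ci)], collapse = ", "))
      ci <- sort(ci)  # genome order
    } else ci <- ci[markers]
  }
  geno_matrix(g$dosages[ri, ci, drop = FALSE],
              g$map[ci, , drop = FALSE],
              g$samples[ri], validate = FALSE)
}

# Observed frequency of the counted allele per marker (missing excluded).
counted_allele_freq <- function(dosages) {
  colMeans(dosages, na.rm = TRUE) / 2
}
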