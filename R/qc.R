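#' Four-stage SNP and sample quality control
#'
#' Applies the standard PLINK-style filters in a fixed order, each stage
#' operating on the matrix surviving the previous one:
#' 1. per-marker missingness (`--geno`): drop markers whose missing-call
#'    rate exceeds `geno_thresh`;
#' 2. per-sample missingness (`--mind`): drop samples whose missing rate
#'    over the surviving markers exceeds `mind_thresh`;
#' 3. minor allele frequency (`--maf`): drop markers with folded MAF
#'    below `maf_thresh` (monomorphic markers always fail);
#' 4. Hardy-Weinberg equilibrium (`--hwe`): drop markers whose exact-test
#'    p-value falls below `hwe_alpha`.
#'
#' Allele frequencies and HWE are computed after sample removal, on
#' non-missing calls only.
#'
#' @param g A [geno_matrix()] with raw 0/1/2/`NA` calls.
#' @param geno_thresh,mind_thresh Missing-rate thresholds in `[0, 1]`
#'   (defaults 0.1, common PLINK practice).
#' @param maf_thresh Folded minor-allele-frequency threshold in `[0, 1]`
#'   (default 0.01).
#' @param hwe_alpha HWE significance level in `(0, 1)` (default `1e-6`).
#' @param hwe_test `"exact"` (default) for the genotype-count exact test,
#'   `"chisq"` for the 1-df chi-square approximation.
#' @return A list with elements `geno` (the filtered [geno_matrix()]) and
#'   `report` (a `qc_report`: per-stage removal counts, input and
#'   retained totals).
#' @examples
#' g <- simulate_genotypes(sim_config(n_samples = 50, n_markers = 40,
#'                                    n_chromosomes = 2, seed = 1))
#' qc <- apply_qc(g)
#' qc$report
#' @export
apply_qc <- function(g, geno_thresh = 0.1, mind_thresh = 0.1,
                     maf_thresh = 0.01, hwe_alpha = 1e-6,
                     hwe_test = c("exact", "chisq")) {
  stopifnot(inherits(g, "geno_matrix"))
  check_fraction(geno_thresh, "geno_thresh")
  check_fraction(mind_thresh, "mind_thresh")
  check_fraction(maf_thresh, "maf_thresh")
  check_fraction(hwe_alpha, "hwe_alpha", lo_open = TRUE, hi_open = TRUE)
  hwe_test <- match.arg(hwe_test)
  m0 <- ncol(g$dosages); n0 <- nrow(g$dosages)

  # stage 1: per-marker missingness
  miss_m <- colMeans(is.na(g$dosages))
  keep <- miss_m <= geno_thresh
  n_geno <- sum(!keep)
  if (!any(keep)) err("all markers removed at the per-marker missingness stage")
  g <- subset_geno(g, markers = keep)

  # stage 2: per-sample missingness on surviving markers
  miss_s <- rowMeans(is.na(g$dosages))
  keep_s <- miss_s <= mind_thresh
  n_mind <- sum(!keep_s)
  if (!any(keep_s)) err("all samples removed at the per-sample missingness stage")
  g <- subset_geno(g, samples = keep_s)

  # stage 3: MAF, frequencies recomputed on retained samples
  p <- counted_allele_freq(g$dosages)
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_thresh & !is.na(maf)
  n_maf <- sum(!keep)
  if (!any(keep)) err("all markers removed at the MAF stage")
  g <- subset_geno(g, markers = keep)

  # stage 4: HWE on genotype counts of retained samples
  n_aa <- colSums(g$dosages == 2, na.rm = TRUE)
  n_ab <- colSums(g$dosages == 1, na.rm = TRUE)
  n_bb <- colSums(g$dosages == 0, na.rm = TRUE)
  pvals <- if (hwe_test == "exact") {
    vapply(seq_along(n_ab), function(j) hwe_exact(n_ab[j], n_aa[j], n_bb[j]),
           numeric(1))
  } else {
    vapply(seq_along(n_ab), function(j) hwe_chisq(n_ab[j], n_aa[j], n_bb[j]),
           numeric(1))
  }
  keep <- pvals >= hwe_alpha
  n_hwe <- sum(!keep)
  if (!any(keep)) err("all markers removed at the HWE stage")
  g <- subset_geno(g, markers = keep)

  report <- structure(list(
    markers_input = m0, samples_input = n0,
    markers_removed_geno = n_geno,
    samples_removed_mind = n_mind,
    markers_removed_maf = n_maf,
    markers_removed_hwe = n_hwe,
    markers_retained = ncol(g$dosages),
    samples_retained = nrow(g$dosages),
    thresholds = c(geno = geno_thresh, mind = mind_thresh,
                   maf = maf_thresh, hwe = hwe_alpha)
  ), class = "qc_report")
  stopifnot(report$markers_input == report$markers_retained + n_geno + n_maf + n_hwe,
            report$samples_input == report$samples_retained + n_mind)
  list(geno = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP/sample quality control\n")
  cat(sprintf("  markers: %d in, %d removed by missingness, %d by MAF, %d by HWE, %d retained\n",
              x$markers_input, x$markers_removed_geno, x$markers_removed_maf,
              x$markers_removed_hwe, x$markers_retained))
  cat(sprintf("  samples: %d in, %d removed by missingness, %d retained\n",
              x$samples_input, x$samples_removed_mind, x$samples_retained))
  cat(sprintf("  thresholds: geno %.3g, mind %.3g, maf %.3g, hwe %.3g\n",
              x$thresholds["geno"], x$thresholds["mind"],
              x$thresholds["maf"], x$thresholds["hwe"]))
  invisible(x)
}

#' Write a QC report as a machine-readable summary
#'
#' @param report A `qc_report` from [apply_qc()].
#' @param path Output file; written as `key<TAB>value` lines.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  flat <- c(unlist(report[setdiff(names(report), "thresholds")]),
            stats::setNames(report$thresholds,
                            paste0("threshold_", names(report$thresholds))))
  writeLines(paste(names(flat), flat, sep = "\t"), path)
  invisible(path)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on observed genotype counts, summing the
#' probabilities of all heterozygote configurations (given the allele
#' counts) no more probable than the observed one.  Probabilities are
#' built by the standard stable recurrence from the modal heterozygote
#' count.
#'
#' @param n_het Observed heterozygote count.
#' @param n_hom1,n_hom2 Observed counts of the two homozygote classes.
#' @return The exact p-value (1 when a marker carries no copies of one
#'   allele, where the test is degenerate).
#' @export
hwe_exact <- function(n_het, n_hom1, n_hom2) {
  stopifnot(n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (n_rare == 0) return(1)

  # heterozygote counts share the parity of the rare-allele count
  het_vals <- seq.int(n_rare %% 2, n_rare, by = 2)
  probs <- numeric(length(het_vals))
  # start at the mode and apply the ratio recurrence outwards
  mid <- round(n_rare * (2 * n - n_rare) / (2 * n))
  if (mid %% 2 != n_rare %% 2) mid <- mid + 1
  mid <- min(mid, n_rare)
  i_mid <- match(mid, het_vals)
  probs[i_mid] <- 1
  if (i_mid > 1) {
    for (i in seq(i_mid, 2)) {
      het <- het_vals[i]
      hom_r <- (n_rare - het) / 2
      hom_c <- n - het - hom_r
      # P(het-2) / P(het)
      probs[i - 1] <- probs[i] * het * (het - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  if (i_mid < length(het_vals)) {
    for (i in seq(i_mid, length(het_vals) - 1)) {
      het <- het_vals[i]
      hom_r <- (n_rare - het) / 2
      hom_c <- n - het - hom_r
      # P(het+2) / P(het)
      probs[i + 1] <- probs[i] * 4 * hom_r * hom_c /
        ((het + 2) * (het + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, het_vals)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# 1-df chi-square HWE test (optional alternative to the exact test).
hwe_chisq <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  p <- (2 * n_hom1 + n_het) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_hom1, n_het, n_hom2)
  stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing dosage by the marker's mean observed dosage
#' (twice the counted-allele frequency), yielding a real-valued matrix
#' suitable for relationship-matrix and regression work.  Haplotype-based
#' imputation is out of scope; mean imputation is the package's
#' documented stand-in.
#'
#' @param g A [geno_matrix()]; every marker must have at least one
#'   non-missing call (run [apply_qc()] first).
#' @return The imputed [geno_matrix()] (numeric dosages, no `NA`).
#' @export
mean_impute <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  dos <- g$dosages
  if (!anyNA(dos)) return(g)
  n_obs <- colSums(!is.na(dos))
  if (any(n_obs == 0)) {
    err("marker(s) with no observed calls: ",
        paste(utils::head(g$map$id[n_obs == 0], 5), collapse = ", "),
        " -- apply_qc() must run before imputation")
  }
  mu <- colMeans(dos, na.rm = TRUE)
  dos <- matrix(as.numeric(dos), nrow(dos), ncol(dos),
                dimnames = dimnames(dos))
  idx <- which(is.na(dos), arr.ind = TRUE)
  dos[idx] <- mu[idx[, 2L]]
  geno_matrix(dos, g$map, g$samples, validate = FALSE)
}

#' Read a phenotype and fixed-effect table
#'
#' Reads a delimited text file with a header into the package's
#' phenotype layout: one row per sample with the trait value (weaning
#' weight, kg) and the herd and birth-type fixed-effect levels.  Rows
#' with a missing trait value are dropped (with a message).
#'
#' @param path Input file.
#' @param column_map Named character vector mapping the canonical names
#'   `id`, `ww`, `herd`, `birth_type` to the file's column names.
#' @param sep Field delimiter (default `","`).
#' @return A data frame with columns `id`, `ww`, `herd`, `birth_type`.
#' @export
read_phenotypes <- function(path,
                            column_map = c(id = "id", ww = "ww",
                                           herd = "herd",
                                           birth_type = "birth_type"),
                            sep = ",") {
  need <- c("id", "ww", "herd", "birth_type")
  if (!all(need %in% names(column_map))) {
    err("column_map must name columns for ", paste(need, collapse = ", "))
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(column_map[need]), names(raw))
  if (length(missing_cols)) {
    err("column(s) not in file: ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(id = as.character(raw[[column_map["id"]]]),
                    ww = as.numeric(raw[[column_map["ww"]]]),
                    herd = as.character(raw[[column_map["herd"]]]),
                    birth_type = as.character(raw[[column_map["birth_type"]]]),
                    stringsAsFactors = FALSE)
  drop <- !is.finite(out$ww)
  if (any(drop)) {
    message(sum(drop), " row(s) dropped for missing trait value")
    out <- out[!drop, , drop = FALSE]
  }
  if (anyDuplicated(out$id)) {
    err("duplicated sample id(s): ",
        paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  }
  if (any(out$ww <= 0)) err("trait values must be positive (kg)")
  if (any(!nzchar(out$herd)) || any(!nzchar(out$birth_type))) {
    err("fixed-effect levels must be non-empty")
  }
  rownames(out) <- NULL
  out
}
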