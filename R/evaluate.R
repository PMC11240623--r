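#' k-fold partition of sample ids
#'
#' @param sample_ids Character vector of ids (`n >= k`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed; the partition is deterministic per seed.
#' @return A named integer vector mapping each id to a fold in `1..k`;
#'   fold sizes differ by at most one.
#' @examples
#' table(kfold_split(sprintf("s%03d", 1:503), k = 5, seed = 1))
#' @export
kfold_split <- function(sample_ids, k = 5L, seed = 1L) {
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  if (k < 2) err("k must be at least 2")
  if (k > n) err("k must not exceed the number of samples")
  with_seed(seed, {
    stats::setNames(sample(rep_len(seq_len(k), n)), sample_ids)
  })
}

#' Cross-validated genomic prediction accuracy
#'
#' Five-fold (by default) cross-validation of GBLUP: for each fold the
#' model is refitted by REML on the remaining folds, GEBVs for the
#' held-out samples are obtained through the relationship matrix, and
#' the fold's Pearson correlation between GEBV and the
#' fixed-effect-adjusted phenotype (`y - X b_hat` from the training
#' fit; set `adjust = FALSE` for the raw phenotype) is recorded.
#' Accuracy is the mean fold correlation divided by `sqrt(h2)` (or by
#' `h2` with `denominator = "h2"`), where `h2` comes from the
#' full-group REML fit on the same matrix.
#'
#' @param pheno Phenotype data frame (`id`, `ww`, `herd`,
#'   `birth_type`).
#' @param g A conditioned `grm` covering all phenotyped samples.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold split (ignored when `folds` given).
#' @param folds Optional precomputed [kfold_split()] assignment, so
#'   several matrices can share identical folds.
#' @param denominator `"sqrt_h2"` (default) or `"h2"`.
#' @param adjust Correlate against the adjusted phenotype (default) or
#'   the raw one.
#' @param h2 Heritability for the denominator; default: estimated by a
#'   full-group REML fit on `g`.
#' @param control A [reml_control()].
#' @return An object of class `cv_result`: `folds`, per-fold `fold_r`,
#'   `mean_r`, `accuracy`, `h2_used`, `seed`, `denominator`.
#' @export
cv_accuracy <- function(pheno, g, k = 5L, seed = 1L, folds = NULL,
                        denominator = c("sqrt_h2", "h2"), adjust = TRUE,
                        h2 = NULL, control = reml_control()) {
  stopifnot(inherits(g, "grm"))
  denominator <- match.arg(denominator)
  design <- build_design(pheno, g$samples)
  if (is.null(folds)) folds <- kfold_split(design$ids, k, seed)
  if (!setequal(names(folds), design$ids)) {
    err("fold assignment does not cover exactly the phenotyped samples")
  }
  k <- max(folds)

  if (is.null(h2)) h2 <- reml_fit(design, g, control)$h2
  if (h2 <= 0) err("non-positive heritability; accuracy undefined")

  fold_r <- numeric(k)
  for (f in seq_len(k)) {
    val_ids <- names(folds)[folds == f]
    tr <- !(design$ids %in% val_ids)
    d_tr <- structure(list(y = design$y[tr],
                           X = design$X[tr, , drop = FALSE],
                           ids = design$ids[tr],
                           idx = design$idx[tr]), class = "mm_design")
    vc <- reml_fit(d_tr, g, control)
    pred <- gblup_predict(d_tr, g, vc, predict_ids = val_ids)
    vi <- match(val_ids, design$ids)
    y_val <- design$y[vi]
    if (adjust) {
      y_val <- y_val - drop(design$X[vi, , drop = FALSE] %*% vc$beta)
    }
    if (stats::sd(pred$gebv) == 0 || stats::sd(y_val) == 0) {
      warning("fold ", f, ": zero variance; correlation recorded as 0")
      fold_r[f] <- 0
    } else {
      fold_r[f] <- stats::cor(pred$gebv, y_val)
    }
  }
  den <- if (denominator == "sqrt_h2") sqrt(h2) else h2
  structure(list(folds = folds, fold_r = fold_r, mean_r = mean(fold_r),
                 accuracy = mean(fold_r) / den, h2_used = h2, seed = seed,
                 denominator = denominator),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean r = %.4f, accuracy = %.4f (h2 = %.3f, / %s)\n",
              max(x$folds), x$mean_r, x$accuracy, x$h2_used,
              if (x$denominator == "sqrt_h2") "sqrt(h2)" else "h2"))
  cat("  fold r:", paste(sprintf("%.3f", x$fold_r), collapse = " "), "\n")
  invisible(x)
}

#' Percent change in prediction accuracy
#'
#' The promotion of a prior-informed model over the plain-GBLUP
#' baseline: `100 * (accuracy_new - accuracy_base) / accuracy_base`.
#'
#' @param accuracy_base Baseline accuracy (non-zero).
#' @param accuracy_new Accuracy of the comparison model.
#' @return Percent change (unrounded; reports format it to 2 dp).
#' @examples
#' promotion(0.075, 0.090)  # +20%
#' @export
promotion <- function(accuracy_base, accuracy_new) {
  if (any(accuracy_base == 0)) err("baseline accuracy is zero; promotion undefined")
  100 * (accuracy_new - accuracy_base) / accuracy_base
}

#' Descriptive statistics of a trait
#'
#' One summary row in the conventional layout: n, mean, sd (n-1
#' denominator), median, 10% two-sided trimmed mean, scaled median
#' absolute deviation (constant 1.4826), min, max and the standard
#' error of the mean.
#'
#' @param x Numeric vector of trait values (>= 2), or a phenotype data
#'   frame with a `ww` column.
#' @return A one-row data frame `n, mean, sd, median, trimmed, mad,
#'   min, max, se`.
#' @export
descriptive_stats <- function(x) {
  if (is.data.frame(x)) x <- x$ww
  x <- as.numeric(x)
  if (length(x) < 2) err("need at least two records")
  s <- stats::sd(x)
  data.frame(n = length(x), mean = mean(x), sd = s,
             median = stats::median(x), trimmed = mean(x, trim = 0.1),
             mad = stats::mad(x), min = min(x), max = max(x),
             se = s / sqrt(length(x)))
}

#' Two-group cross design: GWAS priors feeding genomic selection
#'
#' Reproduces the full experimental layout: the population is split in
#' two; each group in turn serves as the discovery set for the
#' iterative association scan ([farmcpu()]) while the other is the
#' validation set.  For every prior fraction, the validation group's
#' markers are partitioned into the top-fraction prior set and the
#' remainder, VanRaden matrices `G1`/`G2` are built on the validation
#' genotypes, two single-kernel REML fits give the genetic variances
#' whose shares define the blend weight `gamma`, and the blended `G3`
#' is scored by k-fold cross-validated accuracy against the plain-`G`
#' baseline (identical folds within a validation group).
#'
#' @param geno An imputed [geno_matrix()] over the whole population.
#' @param pheno Phenotype data frame covering the same samples.
#' @param fractions Prior-marker fractions (default
#'   `c(0.05, 0.10, 0.15, 0.20)`).
#' @param k CV folds (default 5).
#' @param seed Seed driving the population split and fold assignments.
#' @param farmcpu_ctrl A [farmcpu_control()].
#' @param reml_ctrl A [reml_control()].
#' @param denominator Accuracy denominator convention, see
#'   [cv_accuracy()].
#' @return A `design_report`: data frame with one row per
#'   (validation group, prior fraction, matrix) combination -- columns
#'   `group`, `prior`, `matrix`, `sigma_a2`, `sigma_e2`, `h2`,
#'   `weight`, `accuracy`, `promotion` -- with the run seed attached as
#'   an attribute.
#' @export
run_two_group_design <- function(geno, pheno,
                                 fractions = c(0.05, 0.10, 0.15, 0.20),
                                 k = 5L, seed = 1L,
                                 farmcpu_ctrl = farmcpu_control(),
                                 reml_ctrl = reml_control(),
                                 denominator = c("sqrt_h2", "h2")) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (anyNA(geno$dosages)) err("impute genotypes before running the design")
  denominator <- match.arg(denominator)
  for (f in fractions) check_fraction(f, "fractions", lo_open = TRUE,
                                      hi_open = TRUE)
  split <- split_population(geno$samples, seed)
  groups <- list(group1 = split$group1, group2 = split$group2)

  rows <- list()
  for (gi in 1:2) {
    val_name <- names(groups)[gi]
    disc_ids <- groups[[3 - gi]]
    val_ids <- groups[[gi]]

    disc_geno <- subset_geno(geno, samples = disc_ids)
    disc_pheno <- pheno[match(disc_geno$samples, pheno$id), , drop = FALSE]
    disc_design <- build_design(disc_pheno, disc_geno$samples)
    covar <- disc_design$X[, -1, drop = FALSE]
    gwas <- farmcpu(disc_geno, disc_design$y, covar, farmcpu_ctrl)

    val_geno <- subset_geno(geno, samples = val_ids)
    val_pheno <- pheno[match(val_geno$samples, pheno$id), , drop = FALSE]
    val_design <- build_design(val_pheno, val_geno$samples)
    folds <- kfold_split(val_design$ids, k, seed + gi)

    G <- condition_psd(vanraden_grm(val_geno))
    vc_g <- reml_fit(val_design, G, reml_ctrl)
    cv_g <- cv_accuracy(val_pheno, G, k, folds = folds, h2 = vc_g$h2,
                        denominator = denominator, control = reml_ctrl)
    rows[[length(rows) + 1]] <- report_row(val_name, NA, "G", vc_g, NA,
                                           cv_g$accuracy, NA)

    for (f in fractions) {
      ms <- select_top(gwas, f)
      part <- partition_markers(val_geno, ms)
      G1 <- condition_psd(vanraden_grm(subset_geno(val_geno,
                                                   markers = part$prior)))
      G2 <- condition_psd(vanraden_grm(subset_geno(val_geno,
                                                   markers = part$remaining)))
      vc1 <- reml_fit(val_design, G1, reml_ctrl)
      vc2 <- reml_fit(val_design, G2, reml_ctrl)
      G3 <- condition_psd(blend_grm(G1, G2, vc1$sigma_a2, vc2$sigma_a2))
      vc3 <- reml_fit(val_design, G3, reml_ctrl)
      cv3 <- cv_accuracy(val_pheno, G3, k, folds = folds, h2 = vc3$h2,
                         denominator = denominator, control = reml_ctrl)
      rows[[length(rows) + 1]] <- report_row(val_name, f, "G1", vc1,
                                             G3$gamma, NA, NA)
      rows[[length(rows) + 1]] <- report_row(val_name, f, "G2", vc2,
                                             1 - G3$gamma, NA, NA)
      rows[[length(rows) + 1]] <- report_row(val_name, f, "G3", vc3, NA,
                                             cv3$accuracy,
                                             promotion(cv_g$accuracy,
                                                       cv3$accuracy))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("design_report", "data.frame"), seed = seed,
            k = k, denominator = denominator)
}

report_row <- function(group, prior, matrix, vc, weight, accuracy, promotion) {
  data.frame(group = group, prior = prior, matrix = matrix,
             sigma_a2 = vc$sigma_a2, sigma_e2 = vc$sigma_e2, h2 = vc$h2,
             weight = weight, accuracy = accuracy, promotion = promotion,
             stringsAsFactors = FALSE)
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("Two-group cross design (seed %s, %s-fold CV)\n",
              attr(x, "seed"), attr(x, "k")))
  df <- as.data.frame(x)
  df$prior <- ifelse(is.na(df$prior), "-", sprintf("%.0f%%", 100 * df$prior))
  df$weight <- ifelse(is.na(df$weight), "-", sprintf("%.3f", df$weight))
  df$accuracy <- ifelse(is.na(df$accuracy), "-", sprintf("%.3f", df$accuracy))
  df$promotion <- ifelse(is.na(df$promotion), "-",
                         sprintf("%+.2f%%", df$promotion))
  for (v in c("sigma_a2", "sigma_e2", "h2")) df[[v]] <- round(df[[v]], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a design report as TSV
#'
#' @param report A `design_report`.
#' @param path Output file; the run configuration is echoed in `#`
#'   header lines.
#' @return Invisibly, `path`.
#' @export
write_design_report <- function(report, path) {
  stopifnot(inherits(report, "design_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s k=%s denominator=%s", attr(report, "seed"),
                     attr(report, "k"), attr(report, "denominator")), con)
  utils::write.table(as.data.frame(report), con, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
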