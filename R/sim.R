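#' Configuration for the synthetic population generator
#'
#' Collects the parameters of the simulated sheep-like population.  The
#' defaults describe the study design the package targets: roughly one
#' thousand merino ewes genotyped at ~42K autosomal SNPs on 26
#' chromosomes, a weaning-weight trait of mean 28.27 kg and standard
#' deviation 3.19 kg, narrow-sense heritability 0.3, a handful of larger
#' QTL on a polygenic background, and herd plus birth-type fixed
#' effects.
#'
#' @param n_samples Number of individuals (default 1007).
#' @param n_markers Number of SNPs (default 41956).
#' @param n_chromosomes Number of autosomes (default 26).
#' @param chrom_length_bp Length of each chromosome in bp (default 1e8,
#'   i.e. a ~2.6 Gb genome).
#' @param ld_rho Per-bp decay rate of the latent haplotype correlation;
#'   adjacent-marker correlation is `exp(-ld_rho * distance)` (default
#'   2e-6, giving appreciable LD below ~1 Mb).
#' @param maf_min Lower bound for simulated allele frequencies, in
#'   `(0, 0.5)`; realized frequencies are kept above `0.6 * maf_min` by
#'   redrawing offending columns.
#' @param n_qtl Number of explicit QTL (default 10).
#' @param qtl_variance_fraction Share of genetic variance carried by the
#'   explicit QTL, the rest being polygenic (default 0.3).
#' @param qtl_af_scaled If `TRUE`, QTL effects are scaled by
#'   `(2 p (1-p))^(-1/2)` so each QTL contributes equal variance
#'   (default `FALSE`: unscaled normal effects).
#' @param h2_target Narrow-sense heritability in `(0, 1)` (default 0.3).
#' @param trait_mean,trait_sd Phenotype mean and standard deviation in
#'   kg (defaults 28.27 and 3.19).
#' @param herd_effects,birth_type_effects Named numeric vectors of fixed
#'   effect sizes (kg); levels are assigned uniformly at random.
#' @param seed Integer seed; all randomness in the generator flows
#'   through it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1007L,
                       n_markers = 41956L,
                       n_chromosomes = 26L,
                       chrom_length_bp = 1e8,
                       ld_rho = 2e-6,
                       maf_min = 0.01,
                       n_qtl = 10L,
                       qtl_variance_fraction = 0.3,
                       qtl_af_scaled = FALSE,
                       h2_target = 0.3,
                       trait_mean = 28.27,
                       trait_sd = 3.19,
                       herd_effects = c(H1 = 0, H2 = 0.8, H3 = -0.5,
                                        H4 = 1.2, H5 = 0.3),
                       birth_type_effects = c(single = 0, twin = -1.5),
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  check_fraction(cfg$h2_target, "h2_target", lo_open = TRUE, hi_open = TRUE)
  check_fraction(cfg$maf_min, "maf_min", hi = 0.5, lo_open = TRUE,
                 hi_open = TRUE)
  check_fraction(cfg$qtl_variance_fraction, "qtl_variance_fraction")
  stopifnot(cfg$n_samples >= 2, cfg$n_markers >= 1,
            cfg$n_chromosomes >= 1, cfg$n_qtl <= cfg$n_markers,
            cfg$ld_rho >= 0, cfg$trait_sd > 0)
  cfg
}

#' Simulate genotypes with linkage disequilibrium
#'
#' Generates biallelic SNP genotypes on `n_chromosomes` autosomes.
#' Marker positions are drawn uniformly per chromosome and sorted.  Each
#' of the `2n` haplotypes is a latent Gaussian AR(1) chain thresholded
#' at the marker's allele frequency, so marginal frequencies are exact
#' while the correlation between nearby markers decays with bp distance
#' at rate `ld_rho` (a first-order Markov stand-in for recombination;
#' no coalescent machinery).  Realized minor allele frequencies below
#' `0.6 * maf_min` are repaired by redrawing the column.
#'
#' @param cfg A [sim_config()].
#' @return A [geno_matrix()] with integer 0/1/2 dosages (no missing
#'   calls).
#' @examples
#' g <- simulate_genotypes(sim_config(n_samples = 20, n_markers = 30,
#'                                    n_chromosomes = 2, seed = 7))
#' dim(g)
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- as.integer(cfg$n_samples)
    m <- as.integer(cfg$n_markers)
    nc <- as.integer(cfg$n_chromosomes)
    counts <- diff(round(seq(0, m, length.out = nc + 1)))
    dos <- matrix(0L, n, m)
    chrom <- integer(m); pos <- integer(m)
    off <- 0L
    for (cc in seq_len(nc)) {
      mc <- counts[cc]
      if (mc == 0L) next
      pc <- sort(sample.int(cfg$chrom_length_bp, mc))
      p <- stats::runif(mc, cfg$maf_min, 1 - cfg$maf_min)
      thr <- stats::qnorm(p)
      # latent AR(1) per haplotype, vectorized over the 2n haplotypes
      z <- stats::rnorm(2L * n)
      hap_dose <- function(zv, thv) as.integer(zv < thv)
      col <- hap_dose(z, thr[1])
      dos[, off + 1L] <- col[seq_len(n)] + col[n + seq_len(n)]
      if (mc > 1L) {
        a <- exp(-cfg$ld_rho * diff(pc))
        for (j in 2:mc) {
          z <- a[j - 1L] * z + sqrt(1 - a[j - 1L]^2) * stats::rnorm(2L * n)
          col <- hap_dose(z, thr[j])
          dos[, off + j] <- col[seq_len(n)] + col[n + seq_len(n)]
        }
      }
      chrom[off + seq_len(mc)] <- cc
      pos[off + seq_len(mc)] <- pc
      off <- off + mc
    }
    # enforce the realized-MAF floor by redrawing (LD-free) offending columns
    floor_maf <- 0.6 * cfg$maf_min
    f <- colMeans(dos) / 2
    bad <- which(pmin(f, 1 - f) < floor_maf)
    for (j in bad) {
      p <- stats::runif(1, max(cfg$maf_min, floor_maf * 1.5), 1 - cfg$maf_min)
      for (try in 1:100) {
        col <- stats::rbinom(n, 2L, p)
        fr <- mean(col) / 2
        if (min(fr, 1 - fr) >= floor_maf) break
      }
      dos[, j] <- col
    }
    map <- data.frame(chrom = chrom, pos = pos,
                      id = sprintf("M%06d", seq_len(m)),
                      a1 = "A", a2 = "C", stringsAsFactors = FALSE)
    samples <- sprintf("ind%05d", seq_len(n))
    dimnames(dos) <- list(samples, map$id)
    geno_matrix(dos, map, samples, validate = FALSE)
  })
}

#' Simulate a quantitative trait on a genotype matrix
#'
#' Builds true breeding values as the sum of a few explicit QTL and a
#' dense polygenic term over the remaining markers (column-centered
#' dosages), scales them so that `var(TBV) / var(TBV + e)` equals
#' `h2_target`, adds herd and birth-type fixed effects and an
#' independent normal residual, and rounds the phenotype to two
#' decimals (kg).
#'
#' @param g A [geno_matrix()] with no missing dosages.
#' @param cfg A [sim_config()]; the phenotype stage uses a seed offset
#'   from `cfg$seed` so it does not replay the genotype stream.
#' @return A list with `pheno` (data frame `id`, `ww`, `herd`,
#'   `birth_type`) and `truth` (class `sim_truth`: QTL ids and scaled
#'   effects, true breeding values, realized heritability, fixed-effect
#'   assignments).
#' @export
simulate_phenotypes <- function(g, cfg) {
  stopifnot(inherits(g, "geno_matrix"), inherits(cfg, "sim_config"))
  if (anyNA(g$dosages)) err("genotypes contain missing calls; impute first")
  check_fraction(cfg$h2_target, "h2_target", lo_open = TRUE, hi_open = TRUE)
  with_seed(cfg$seed + 1000003L, {
    n <- nrow(g$dosages); m <- ncol(g$dosages)
    M <- scale(g$dosages, center = TRUE, scale = FALSE)
    n_qtl <- min(cfg$n_qtl, m)
    qtl_idx <- if (n_qtl > 0) sort(sample.int(m, n_qtl)) else integer(0)
    f_qtl <- if (n_qtl == 0) 0 else cfg$qtl_variance_fraction

    g_qtl <- rep(0, n); a_qtl <- numeric(0)
    if (n_qtl > 0) {
      a_qtl <- stats::rnorm(n_qtl)
      if (cfg$qtl_af_scaled) {
        p <- counted_allele_freq(g$dosages)[qtl_idx]
        a_qtl <- a_qtl / sqrt(pmax(2 * p * (1 - p), 1e-8))
      }
      g_qtl <- drop(M[, qtl_idx, drop = FALSE] %*% a_qtl)
    }
    poly_idx <- setdiff(seq_len(m), qtl_idx)
    a_poly <- stats::rnorm(length(poly_idx))
    g_poly <- drop(M[, poly_idx, drop = FALSE] %*% a_poly)

    sd0 <- function(x) if (stats::sd(x) > 0) stats::sd(x) else 1
    s_qtl <- if (n_qtl > 0) sqrt(f_qtl) / sd0(g_qtl) else 0
    s_poly <- sqrt(1 - f_qtl) / sd0(g_poly)
    gg <- s_qtl * g_qtl + s_poly * g_poly
    sig_g <- sqrt(cfg$h2_target) * cfg$trait_sd
    scl <- sig_g / sd0(gg)
    tbv <- gg * scl

    e <- stats::rnorm(n, 0, sqrt(1 - cfg$h2_target) * cfg$trait_sd)
    herd <- sample(names(cfg$herd_effects), n, replace = TRUE)
    bt <- sample(names(cfg$birth_type_effects), n, replace = TRUE)
    fixed <- unname(cfg$herd_effects[herd] + cfg$birth_type_effects[bt])
    y <- round(cfg$trait_mean + fixed + tbv + e, 2)

    pheno <- data.frame(id = g$samples, ww = y, herd = herd,
                        birth_type = bt, stringsAsFactors = FALSE)
    truth <- structure(list(
      qtl_ids = g$map$id[qtl_idx],
      qtl_effects = a_qtl * s_qtl * scl,
      tbv = stats::setNames(tbv, g$samples),
      realized_h2 = stats::var(tbv) / (stats::var(tbv) + stats::var(e)),
      fixed_effects = stats::setNames(fixed, g$samples),
      herd = stats::setNames(herd, g$samples),
      birth_type = stats::setNames(bt, g$samples)
    ), class = "sim_truth")
    list(pheno = pheno, truth = truth)
  })
}

#' Randomly split a population into two near-equal groups
#'
#' @param samples Character vector of sample ids (>= 2).
#' @param seed Integer seed.
#' @return A list with `group1` (`floor(n/2)` ids) and `group2`
#'   (the rest), each in the original order.
#' @examples
#' split_population(sprintf("s%04d", 1:1007), seed = 3)$group1[1:3]
#' @export
split_population <- function(samples, seed = 1L) {
  samples <- as.character(samples)
  n <- length(samples)
  if (n < 2) err("need at least two samples to split")
  with_seed(seed, {
    idx <- sample.int(n)
    g1 <- sort(idx[seq_len(floor(n / 2))])
    list(group1 = samples[g1], group2 = samples[-g1])
  })
}
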