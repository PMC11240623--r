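# Small fixture builders shared across test files.

# geno_matrix from a bare dosage matrix; markers laid out on one
# chromosome at 1 Mb spacing unless positions are supplied.
toy_geno <- function(dos, chrom = NULL, pos = NULL) {
  m <- ncol(dos)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) {
    pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1000000L
  }
  map <- data.frame(chrom = chrom, pos = pos,
                    id = sprintf("t%03d", seq_len(m)),
                    a1 = "A", a2 = "C", stringsAsFactors = FALSE)
  geno_matrix(dos, map, sprintf("s%03d", seq_len(nrow(dos))))
}

# small simulated population with phenotypes
sim_pop <- function(n = 150, m = 200, seed = 1, ...) {
  args <- list(...)
  if (is.null(args$n_qtl)) args$n_qtl <- min(10L, m %/% 2L)
  cfg <- do.call(sim_config, c(list(
    n_samples = n, n_markers = m,
    n_chromosomes = max(2L, min(5L, m %/% 40L)),
    seed = seed), args))
  g <- simulate_genotypes(cfg)
  c(list(geno = g, cfg = cfg), simulate_phenotypes(g, cfg))
}

# Hand-written PLINK .bed encoder, independent of write_plink():
# builds each SNP-major byte from explicit 2-bit codes.
hand_write_bed <- function(dosages, prefix) {
  n <- nrow(dosages); m <- ncol(dosages)
  code_of <- function(d) {
    if (is.na(d)) 1L else if (d == 2) 0L else if (d == 1) 2L else 3L
  }
  bytes <- integer(0)
  for (j in seq_len(m)) {
    codes <- vapply(dosages[, j], code_of, integer(1))
    codes <- c(codes, rep(1L, (4 - n %% 4) %% 4))
    for (b in seq_len(length(codes) / 4)) {
      q <- codes[(4 * b - 3):(4 * b)]
      bytes <- c(bytes, q[1] + q[2] * 4L + q[3] * 16L + q[4] * 64L)
    }
  }
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, bytes)), paste0(prefix, ".bed"))
  bim <- data.frame(1L, sprintf("t%03d", seq_len(m)), 0,
                    seq_len(m) * 1000000L, "A", "C")
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(sprintf("s%03d", seq_len(n)), sprintf("s%03d", seq_len(n)),
                    0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
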