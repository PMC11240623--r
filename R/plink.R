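#' Read PLINK binary genotypes
#'
#' Reads a PLINK 1 binary fileset (`.bed`/`.bim`/`.fam`, SNP-major,
#' magic bytes `0x6c 0x1b 0x01`) into a [geno_matrix()].  Dosages count
#' copies of the A1 allele (`.bim` column 5); the missing genotype code
#' is mapped to `NA`.  Marker and sample order are taken from `.bim` and
#' `.fam`.
#'
#' @param bed_path,bim_path,fam_path Paths to the three files.  If only
#'   `bed_path` is given, the `.bim`/`.fam` paths are derived from it.
#' @return A [geno_matrix()].
#' @seealso [write_plink()], [apply_qc()]
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) err("file not found: ", p)
  }
  bim <- utils::read.table(bim_path, header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 2L) err("malformed .fam: expected >= 2 columns")
  samples <- fam[[2L]]
  n <- length(samples)
  m <- nrow(bim)

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    err("not a PLINK .bed file (bad magic bytes): ", bed_path)
  }
  if (raw[3L] != as.raw(0x01)) {
    err("only SNP-major .bed files are supported: ", bed_path)
  }
  bpm <- ceiling(n / 4)  # bytes per marker
  if (length(raw) != 3L + bpm * m) {
    err(sprintf(".bed size (%d bytes) inconsistent with %d samples x %d markers",
                length(raw), n, m))
  }
  body <- as.integer(raw[-(1:3)])  # byte values 0..255

  # 2-bit codes, sample k within byte: 00 hom A1 -> 2, 01 missing -> NA,
  # 10 het -> 1, 11 hom A2 -> 0.
  code_dose <- c(2L, NA_integer_, 1L, 0L)
  dos <- matrix(NA_integer_, nrow = bpm * 4L, ncol = m)
  bytes <- matrix(body, nrow = bpm, ncol = m)
  for (k in 0:3) {
    code <- bytes %/% 4L^k %% 4L
    dos[seq.int(k + 1L, by = 4L, length.out = bpm), ] <- code_dose[code + 1L]
  }
  dos <- dos[seq_len(n), , drop = FALSE]
  rownames(dos) <- samples
  colnames(dos) <- bim$id
  geno_matrix(dos, bim[c("chrom", "id", "pos", "a1", "a2")], samples)
}

#' Write PLINK binary genotypes
#'
#' Writes a [geno_matrix()] as a PLINK 1 SNP-major `.bed`/`.bim`/`.fam`
#' fileset, the inverse of [read_plink()].  Dosages must be raw integer
#' calls (0/1/2/`NA`); imputed real-valued matrices cannot be encoded.
#'
#' @param g A [geno_matrix()].
#' @param prefix Output path prefix; `<prefix>.bed`, `.bim` and `.fam`
#'   are written.
#' @return Invisibly, the three paths written.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "geno_matrix"))
  dos <- g$dosages
  v <- as.vector(dos)
  if (!all(is.na(v) | v %in% c(0, 1, 2))) {
    err("dosages must be integer 0/1/2/NA calls to write PLINK binary")
  }
  n <- nrow(dos); m <- ncol(dos)
  bpm <- ceiling(n / 4)

  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(1L, nrow = bpm * 4L, ncol = m)  # pad with missing code
  code[seq_len(n), ] <- ifelse(is.na(dos), 1L,
                               ifelse(dos == 2, 0L, ifelse(dos == 1, 2L, 3L)))
  k <- 0:3
  packed <- matrix(0L, nrow = bpm, ncol = m)
  for (j in k) {
    packed <- packed + code[seq.int(j + 1L, by = 4L, length.out = bpm), ,
                            drop = FALSE] * 4L^j
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(packed), con)

  bim <- data.frame(g$map$chrom, g$map$id, 0, g$map$pos, g$map$a1, g$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(g$samples, g$samples, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}
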