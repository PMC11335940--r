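#' Write a panel as SHAPEIT-style haps/sample files
#'
#' The `.haps` file has one row per variant: chromosome, SNP id, position,
#' reference allele, alternate allele, then `2N` space-separated 0/1 alleles
#' (two columns per sample, in sample order). The `.sample` file carries two
#' header rows followed by one row per sample with id, sex and phenotype.
#' On disk sex and phenotype use the PLINK-style 1/2 dialect
#' (sex: 1/2 for in-memory 0/1; phenotype: 1 = control, 2 = case).
#'
#' @param panel A [phased_panel()].
#' @param prefix Output path prefix; `<prefix>.haps` and `<prefix>.sample`
#'   are written.
#' @return Invisibly, the two file paths.
#' @export
write_haps_sample <- function(panel, prefix) {
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  haps_path <- paste0(prefix, ".haps")
  sample_path <- paste0(prefix, ".sample")
  v <- panel$variants
  allele_block <- apply(t(panel$haps), 1L, paste, collapse = " ")
  lines <- paste(v$chrom, v$id, v$pos, v$ref, v$alt, allele_block)
  writeLines(lines, haps_path)
  n <- n_samples(panel)
  ids <- sprintf("%s_%d", panel$label, seq_len(n))
  hdr <- c("ID_1 ID_2 missing sex phenotype", "0 0 0 D B")
  body <- paste(ids, ids, 0L, panel$sex + 1L, panel$phenotype + 1L)
  writeLines(c(hdr, body), sample_path)
  invisible(c(haps = haps_path, sample = sample_path))
}

#' Read SHAPEIT-style haps/sample files into a panel
#'
#' Inverse of [write_haps_sample()]: a write/read round trip reproduces the
#' haplotype matrix, phenotype and sex exactly.
#'
#' @param prefix Path prefix of the `.haps`/`.sample` pair.
#' @param label Population label; defaults to the prefix's base name.
#' @return A [phased_panel()].
#' @export
read_haps_sample <- function(prefix, label = basename(prefix)) {
  haps_path <- paste0(prefix, ".haps")
  sample_path <- paste0(prefix, ".sample")
  if (!file.exists(haps_path)) stop("missing file: ", haps_path)
  if (!file.exists(sample_path)) stop("missing file: ", sample_path)
  raw <- utils::read.table(haps_path, header = FALSE,
                           colClasses = "character")
  variants <- data.frame(chrom = raw[[1L]], pos = as.integer(raw[[3L]]),
                         id = raw[[2L]], ref = raw[[4L]], alt = raw[[5L]],
                         stringsAsFactors = FALSE)
  mat <- as.matrix(raw[, -(1:5), drop = FALSE])
  haps <- t(matrix(as.integer(mat), nrow(raw), ncol(raw) - 5L))
  samp <- utils::read.table(sample_path, header = TRUE, skip = 1L,
                            col.names = c("id1", "id2", "missing", "sex",
                                          "phenotype"))
  phased_panel(label, variants, haps,
               phenotype = as.integer(samp$phenotype) - 1L,
               sex = as.integer(samp$sex) - 1L)
}

#' Write a panel as a minimal phased VCF
#'
#' Emits a VCFv4.2 file with a GT field using the phased `|` separator;
#' sample order and haplotype pairing follow the panel.
#'
#' @param panel A [phased_panel()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_phased_vcf <- function(panel, path) {
  n <- n_samples(panel)
  ids <- sprintf("%s_%d", panel$label, seq_len(n))
  a1 <- panel$haps[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  a2 <- panel$haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2), n, ncol(panel$haps))
  v <- panel$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  rows <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(t(gt), 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
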