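#' Construct a phased case-control panel
#'
#' A `phased_panel` bundles one population's phased haplotypes with its
#' variant map and per-sample phenotype and sex. Haplotype rows are paired:
#' rows `2i - 1` and `2i` are the two chromosome copies of sample `i`.
#'
#' @param label Population label (single string).
#' @param variants `data.frame` with columns `chrom`, `pos` (1-based bp,
#'   strictly increasing within a chromosome), `id`, `ref`, `alt`.
#' @param haps Integer matrix of 0/1 alleles, dimension
#'   `(2 * n_samples) x nrow(variants)`.
#' @param phenotype Integer vector per sample; 0 = control, 1 = case.
#' @param sex Integer vector per sample; coded 0/1.
#'
#' @return An object of class `phased_panel`.
#' @export
phased_panel <- function(label, variants, haps, phenotype, sex) {
  stopifnot(is.character(label), length(label) == 1L)
  variants <- as.data.frame(variants)
  req <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (nrow(haps) %% 2L != 0L)
    stop("haplotype matrix must have an even number of rows (paired per sample)")
  n <- nrow(haps) / 2L
  if (length(phenotype) != n || length(sex) != n)
    stop("phenotype and sex must have one entry per sample")
  if (ncol(haps) != nrow(variants))
    stop("haplotype matrix has ", ncol(haps), " columns but ", nrow(variants),
         " variants")
  if (any(haps != 0L & haps != 1L))
    stop("haplotype matrix entries must be 0 or 1")
  if (!all(phenotype %in% c(0L, 1L))) stop("phenotype must be coded 0/1")
  if (!all(sex %in% c(0L, 1L))) stop("sex must be coded 0/1")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  structure(
    list(label = label, variants = variants, haps = haps,
         phenotype = as.integer(phenotype), sex = as.integer(sex)),
    class = "phased_panel"
  )
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf(
    "phased_panel '%s': %d samples (%d cases / %d controls), %d variants\n",
    x$label, n_samples(x), sum(x$phenotype == 1L), sum(x$phenotype == 0L),
    nrow(x$variants)))
  invisible(x)
}

#' Number of samples in a panel
#' @param panel A `phased_panel`.
#' @return Integer sample count.
#' @export
n_samples <- function(panel) nrow(panel$haps) %/% 2L

#' Alternate-allele frequency of every variant
#'
#' @param panel A `phased_panel`.
#' @return Numeric vector of alt-allele frequencies (column means of the
#'   haplotype matrix).
#' @export
alt_freq <- function(panel) colMeans(panel$haps)

#' Filter variants by minor allele frequency
#'
#' Keeps exactly the variants whose folded frequency `min(f, 1 - f)` is at
#' least `threshold`, preserving order. The default reproduces the usual
#' GWAS quality-control rule of excluding SNPs with MAF < 5%; the boundary
#' value is kept.
#'
#' @param panel A `phased_panel`.
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @return A `phased_panel` restricted to the retained variants.
#' @export
filter_snp_maf <- function(panel, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  f <- alt_freq(panel)
  keep <- pmin(f, 1 - f) >= threshold
  if (!any(keep))
    stop("no variant passes MAF >= ", threshold, " in panel '", panel$label, "'")
  phased_panel(panel$label, panel$variants[keep, , drop = FALSE],
               panel$haps[, keep, drop = FALSE], panel$phenotype, panel$sex)
}
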