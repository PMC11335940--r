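#' Enumerate sliding haplotype windows
#'
#' Windows of `window_size` consecutive SNPs are laid along each chromosome
#' at offsets 0, `step`, `2*step`, ...; a trailing stretch shorter than the
#' window is not emitted, so every window has exactly `window_size` SNPs. A
#' chromosome with `M` SNPs yields `floor((M - window_size)/step) + 1`
#' windows (0 when `M < window_size`). Each window's block coordinate is the
#' (floored) mean of its first and last SNP position, giving the marker a
#' single representative bp.
#'
#' @param panel A [phased_panel()].
#' @param window_size Number of SNPs per window (default 15).
#' @param step Offset between consecutive window starts, in SNPs (default 2).
#' @return `data.frame` with one row per window: `chrom`, `window_id`,
#'   `start_idx`/`end_idx` (1-based inclusive column indices into the
#'   panel's variant table), `pos_start`, `pos_end`, `block_coord`, and
#'   `snp_ids` (comma-separated).
#' @export
enumerate_windows <- function(panel, window_size = 15L, step = 2L) {
  stopifnot(window_size >= 2L, step >= 1L)
  v <- panel$variants
  out <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    m <- length(idx)
    if (m < window_size) next
    starts <- seq(1L, m - window_size + 1L, by = step)
    s <- idx[starts]
    e <- idx[starts + window_size - 1L]
    out[[ch]] <- data.frame(
      chrom = ch,
      start_idx = s, end_idx = e,
      pos_start = v$pos[s], pos_end = v$pos[e],
      block_coord = (v$pos[s] + v$pos[e]) %/% 2L,
      snp_ids = vapply(seq_along(s), function(i)
        paste(v$id[s[i]:e[i]], collapse = ","), character(1)),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), window_id = integer(0),
                      start_idx = integer(0), end_idx = integer(0),
                      pos_start = integer(0), pos_end = integer(0),
                      block_coord = integer(0), snp_ids = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  cbind(window_id = seq_len(nrow(res)), res)
}

#' Derive haplotype alleles for one window
#'
#' Every distinct phased sequence observed over the window's SNPs becomes a
#' haplotype allele. Each allele is treated as one side of a pseudo-biallelic
#' marker (H = this allele, N = all other alleles): per sample, the count of
#' copies carried (0, 1 or 2) maps deterministically to the NN/NH/HH
#' genotype. Alleles are ordered by descending frequency, ties broken by
#' lexicographic sequence.
#'
#' @param panel A [phased_panel()].
#' @param window One row of [enumerate_windows()] output.
#' @return List with `alleles` (`data.frame`: `marker_id`, `allele_seq`,
#'   `freq`) and `counts` (integer matrix, samples x alleles).
#' @export
call_hap_alleles <- function(panel, window) {
  cols <- window$start_idx:window$end_idx
  sub <- panel$haps[, cols, drop = FALSE]
  seqs <- do.call(paste0, as.data.frame(sub))
  tab <- table(seqs)
  freq <- as.numeric(tab) / length(seqs)
  ord <- order(-freq, names(tab))
  alleles <- names(tab)[ord]
  freq <- freq[ord]
  code <- match(seqs, alleles)
  odd <- seq(1L, length(seqs), by = 2L)
  counts <- vapply(seq_along(alleles), function(a) {
    hit <- as.integer(code == a)
    hit[odd] + hit[odd + 1L]
  }, integer(length(odd)))
  counts <- matrix(counts, nrow = length(odd))
  marker_id <- sprintf("%s:%d:%s", window$chrom, window$block_coord, alleles)
  list(alleles = data.frame(marker_id = marker_id, allele_seq = alleles,
                            freq = freq, stringsAsFactors = FALSE),
       counts = counts)
}

#' Filter haplotype alleles by frequency
#'
#' Removes alleles with `freq < threshold` or `freq > 1 - threshold`: the
#' pseudo-marker is biallelic (H vs N), so an allele close to fixation is as
#' uninformative as a rare one. The boundary value survives.
#'
#' @param alleles Allele `data.frame` as produced by [call_hap_alleles()].
#' @param threshold Haplotype MAF threshold in `[0, 0.5]` (default 0.01).
#' @return Logical keep vector aligned with the rows of `alleles`.
#' @export
hap_maf_keep <- function(alleles, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  alleles$freq >= threshold & alleles$freq <= 1 - threshold
}

#' Subset an allele table to the alleles passing the frequency filter
#'
#' Convenience wrapper around [hap_maf_keep()] returning the filtered
#' allele `data.frame` itself.
#'
#' @inheritParams hap_maf_keep
#' @return `alleles` restricted to surviving rows.
#' @export
filter_hap_maf <- function(alleles, threshold = 0.01) {
  alleles[hap_maf_keep(alleles, threshold), , drop = FALSE]
}

#' Call all haplotype pseudo-markers of a panel
#'
#' Runs [call_hap_alleles()] over every window and applies the haplotype
#' frequency filter, producing the panel's marker set.
#'
#' @param panel A [phased_panel()].
#' @param windows Output of [enumerate_windows()]; computed with defaults
#'   when omitted.
#' @param hap_maf Haplotype MAF threshold (default 0.01).
#' @param window_size,step Passed to [enumerate_windows()] when `windows`
#'   is missing.
#' @return List of class `hap_markers`: `markers` (`data.frame` with
#'   `marker_id`, `chrom`, `window_id`, `block_coord`, `pos_start`,
#'   `pos_end`, `snp_ids`, `allele_seq`, `freq`) and `counts` (integer
#'   matrix, samples x markers, columns named by `marker_id`).
#' @export
call_markers <- function(panel, windows = NULL, hap_maf = 0.01,
                         window_size = 15L, step = 2L) {
  if (is.null(windows))
    windows <- enumerate_windows(panel, window_size, step)
  marker_rows <- list()
  count_cols <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    hw <- call_hap_alleles(panel, w)
    keep <- hap_maf_keep(hw$alleles, hap_maf)
    if (!any(keep)) next
    al <- hw$alleles[keep, , drop = FALSE]
    marker_rows[[length(marker_rows) + 1L]] <- data.frame(
      marker_id = al$marker_id, chrom = w$chrom, window_id = w$window_id,
      block_coord = w$block_coord, pos_start = w$pos_start,
      pos_end = w$pos_end, snp_ids = w$snp_ids, allele_seq = al$allele_seq,
      freq = al$freq, stringsAsFactors = FALSE)
    count_cols[[length(count_cols) + 1L]] <- hw$counts[, keep, drop = FALSE]
  }
  if (!length(marker_rows))
    stop("no haplotype allele passes the frequency filter")
  markers <- do.call(rbind, marker_rows)
  rownames(markers) <- NULL
  counts <- do.call(cbind, count_cols)
  colnames(counts) <- markers$marker_id
  structure(list(markers = markers, counts = counts,
                 population_label = panel$label),
            class = "hap_markers")
}

#' @export
print.hap_markers <- function(x, ...) {
  cat(sprintf("hap_markers '%s': %d markers over %d windows, %d samples\n",
              x$population_label, nrow(x$markers),
              length(unique(x$markers$window_id)), nrow(x$counts)))
  invisible(x)
}

#' Export haplotype pseudo-markers as PLINK ped/map files
#'
#' Writes the NN/NH/HH genotypes as two-character allele columns (`N` and
#' `H` as allele symbols): count 0 becomes `N N`, 1 becomes `N H`, 2 becomes
#' `H H`. The companion `.map` holds chromosome, marker id, 0 cM, and the
#' block coordinate.
#'
#' @param hm A [call_markers()] result.
#' @param panel The [phased_panel()] the markers were called on (provides
#'   phenotype and sex for the ped columns).
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return Invisibly, the two file paths.
#' @export
export_ped <- function(hm, panel, prefix) {
  if (!nrow(hm$markers)) stop("empty marker set")
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  n <- nrow(hm$counts)
  ids <- sprintf("%s_%d", panel$label, seq_len(n))
  geno <- c("N N", "N H", "H H")[hm$counts + 1L]
  geno <- matrix(geno, n, ncol(hm$counts))
  ped <- paste(ids, ids, 0L, 0L, panel$sex + 1L, panel$phenotype + 1L,
               apply(geno, 1L, paste, collapse = " "))
  writeLines(ped, paste0(prefix, ".ped"))
  map <- paste(hm$markers$chrom, hm$markers$marker_id, 0L,
               hm$markers$block_coord)
  writeLines(map, paste0(prefix, ".map"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Read a ped/map pair written by [export_ped()] back into counts
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @return List with `counts` (samples x markers integer matrix named by
#'   marker id), `phenotype`, `sex` (0/1 in-memory coding) and `map`
#'   `data.frame`.
#' @export
read_ped <- function(prefix) {
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           colClasses = "character")
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           col.names = c("chrom", "marker_id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "integer", "integer"))
  g <- as.matrix(ped[, -(1:6), drop = FALSE])
  n_mark <- ncol(g) / 2L
  h1 <- g[, seq(1L, 2L * n_mark, by = 2L), drop = FALSE] == "H"
  h2 <- g[, seq(2L, 2L * n_mark, by = 2L), drop = FALSE] == "H"
  counts <- matrix(as.integer(h1) + as.integer(h2), nrow(ped), n_mark)
  colnames(counts) <- map$marker_id
  list(counts = counts,
       phenotype = as.integer(ped[[6L]]) - 1L,
       sex = as.integer(ped[[5L]]) - 1L,
       map = map)
}
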