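#' Merge member haplotype intervals into a region
#'
#' A reported region spans from the lowest start to the highest end among
#' the haplotypes it merges.
#'
#' @param members `data.frame` or matrix with columns `start` and `end`
#'   (1-based inclusive bp), or a list of `c(start, end)` pairs.
#' @return Named numeric vector `c(start, end)`.
#' @export
merge_region <- function(members) {
  if (is.list(members) && !is.data.frame(members))
    members <- do.call(rbind, lapply(members, function(x)
      data.frame(start = x[[1L]], end = x[[2L]])))
  members <- as.data.frame(members)
  stopifnot(nrow(members) >= 1L)
  c(start = min(members$start), end = max(members$end))
}

#' Filter anchored meta results to reportable risk regions
#'
#' An anchored haplotype qualifies when its pooled p-value is strictly
#' below the genome-wide threshold, every contributing population shows
#' increased risk (per-population `beta > 0`; no per-population
#' significance is demanded), and all populations contributed. Qualifying
#' haplotypes that overlap on the same chromosome are then merged
#' transitively into one region spanning the lowest start and the highest
#' end among them; the region is represented by its most significant joint
#' SNP, whose pooled estimates it reports.
#'
#' @param am An [anchored_meta()] result. Overlap grouping happens here, so
#'   passing the unresolved candidate set keeps the full extent of every
#'   overlapping significant haplotype; passing a [resolve_overlaps()]
#'   result restricts each region's span to its representative haplotypes.
#' @param alpha Genome-wide significance threshold (default `5e-8`).
#' @param k_required Number of populations that must contribute; defaults
#'   to the number of populations present in the input.
#' @return `data.frame` of regions: `chrom`, `start_bp`, `end_bp` (1-based
#'   inclusive, merged over the member haplotypes), `joint_snp`, `snp_pos`,
#'   `n_anchors` (qualifying anchors merged into the region), and the
#'   pooled meta columns of the representative anchor. Zero rows when
#'   nothing passes.
#' @export
filter_regions <- function(am, alpha = 5e-8, k_required = NULL) {
  stopifnot(inherits(am, "anchored_meta"), alpha > 0, alpha <= 1)
  a <- am$anchors
  empty <- data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), joint_snp = character(0),
                      snp_pos = integer(0), n_anchors = integer(0))
  if (is.null(a) || !nrow(a)) return(empty)
  if (is.null(k_required))
    k_required <- length(unique(am$details$population))
  pass <- a$log10_p < log10(alpha) & a$all_risk & a$k == k_required
  a <- a[pass, , drop = FALSE]
  if (!nrow(a)) return(empty)
  grp <- overlap_groups(a)
  rows <- lapply(unique(grp), function(g) {
    sub <- a[grp == g, , drop = FALSE]
    win <- select_joint_snp(sub)
    span <- merge_region(data.frame(start = sub$region_start,
                                    end = sub$region_end))
    cbind(data.frame(chrom = win$chrom, start_bp = as.integer(span[["start"]]),
                     end_bp = as.integer(span[["end"]]),
                     joint_snp = win$snp_id, snp_pos = win$snp_pos,
                     n_anchors = nrow(sub), stringsAsFactors = FALSE),
          win[, c("k", "beta_re", "se_re", "or_re", "ci_low", "ci_high",
                  "log10_p", "q_stat", "q_df", "p_q", "i2", "tau2")])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start_bp), ]
  rownames(out) <- NULL
  out
}

#' Write region outputs: summary table, BED, and forest-plot data
#'
#' Emits (a) a summary TSV with one row per region (joint SNP, chromosome,
#' joint-SNP bp, OR, 95% CI, p), (b) a BED file of the merged regions
#' (0-based half-open, so a 1-based inclusive region `start..end` becomes
#' `start-1 end`), and (c) a forest-plot TSV with one row per population
#' plus a summary row per region. All files are written with headers even
#' when the region list is empty (BED excepted — it has no header).
#'
#' @param regions Output of [filter_regions()].
#' @param am The [anchored_meta()] result the regions came from (supplies
#'   per-population rows for the forest data).
#' @param dir Output directory.
#' @param prefix File name prefix (default `"regions"`).
#' @return Invisibly, a named vector of the three paths.
#' @export
write_region_outputs <- function(regions, am, dir, prefix = "regions") {
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  bed <- file.path(dir, paste0(prefix, ".bed"))
  forest <- file.path(dir, paste0(prefix, "_forest.tsv"))

  tab <- data.frame(joint_snp = regions$joint_snp, chrom = regions$chrom,
                    bp = regions$snp_pos, or = regions$or_re,
                    ci_low = regions$ci_low, ci_high = regions$ci_high,
                    log10_p = regions$log10_p, start_bp = regions$start_bp,
                    end_bp = regions$end_bp, i2 = regions$i2,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  bed_df <- data.frame(chrom = regions$chrom,
                       start = regions$start_bp - 1L,
                       end = regions$end_bp,
                       name = regions$joint_snp)
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  rows <- list()
  for (i in seq_len(nrow(regions))) {
    s <- regions$joint_snp[i]
    d <- am$details[am$details$snp_id == s, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      joint_snp = s, label = d$population, marker_id = d$marker_id,
      or = d$odds_ratio, ci_low = d$ci_low, ci_high = d$ci_high,
      log10_p = d$log10_p, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      joint_snp = s, label = "meta", marker_id = NA_character_,
      or = regions$or_re[i], ci_low = regions$ci_low[i],
      ci_high = regions$ci_high[i], log10_p = regions$log10_p[i],
      stringsAsFactors = FALSE)
  }
  forest_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(joint_snp = character(0), label = character(0),
               marker_id = character(0), or = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               log10_p = numeric(0))
  utils::write.table(forest_df, forest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(table = tsv, bed = bed, forest = forest))
}

#' Forest plot for one reported region
#'
#' Draws per-population odds ratios with 95% confidence intervals and the
#' pooled random-effects summary on a log OR axis.
#'
#' @param regions Output of [filter_regions()].
#' @param am The matching [anchored_meta()] result.
#' @param joint_snp Which region to plot; defaults to the first.
#' @return Invisibly, the plotted `data.frame`.
#' @export
plot_forest <- function(regions, am, joint_snp = regions$joint_snp[1L]) {
  stopifnot(joint_snp %in% regions$joint_snp)
  i <- match(joint_snp, regions$joint_snp)
  d <- am$details[am$details$snp_id == joint_snp, , drop = FALSE]
  df <- data.frame(label = c(d$population, "Summary"),
                   or = c(d$odds_ratio, regions$or_re[i]),
                   lo = c(d$ci_low, regions$ci_low[i]),
                   hi = c(d$ci_high, regions$ci_high[i]))
  n <- nrow(df)
  ys <- rev(seq_len(n))
  graphics::plot(log(df$or), ys, pch = c(rep(15, n - 1L), 18),
                 cex = c(rep(1.2, n - 1L), 1.8),
                 xlim = range(log(c(df$lo, df$hi, 1))), ylim = c(0.5, n + 0.5),
                 yaxt = "n", xlab = "log odds ratio", ylab = "",
                 main = sprintf("%s (chr%s)", joint_snp, regions$chrom[i]))
  graphics::segments(log(df$lo), ys, log(df$hi), ys)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = ys, labels = df$label, las = 1)
  invisible(df)
}
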