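#' DerSimonian-Laird random-effects inverse-variance meta-analysis
#'
#' Pools per-population log odds ratios with inverse-variance weights and a
#' method-of-moments between-study variance. With fixed weights
#' `w_i = 1/se_i^2`, Cochran's `Q = sum w_i (b_i - b_fixed)^2` on `k - 1`
#' degrees of freedom yields
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; the pooled
#' estimate then uses re-weights `1/(se_i^2 + tau2)`. `I2` is the percent of
#' total variation attributable to between-study heterogeneity,
#' `max(0, (Q - (k-1))/Q) * 100` (0 when `Q = 0`).
#'
#' @param betas Numeric vector of per-study log odds ratios (`k >= 2`).
#' @param ses Positive standard errors of `betas`.
#' @return One-row `data.frame`: `k`, `beta_re`, `se_re`, `or_re`,
#'   `ci_low`, `ci_high` (95%, OR scale), `log10_p` (two-sided Wald),
#'   `q_stat`, `q_df`, `p_q` (chi-square upper tail), `i2` (percent),
#'   `tau2`.
#' @export
dl_random_effects <- function(betas, ses) {
  k <- length(betas)
  if (k < 2L) stop("meta-analysis needs at least 2 studies")
  if (length(ses) != k) stop("betas and ses must have equal length")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("all ses must be > 0")
  w <- 1 / ses^2
  beta_fixed <- sum(w * betas) / sum(w)
  q_stat <- sum(w * (betas - beta_fixed)^2)
  q_df <- k - 1L
  tau2 <- max(0, (q_stat - q_df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (ses^2 + tau2)
  beta_re <- sum(ws * betas) / sum(ws)
  se_re <- 1 / sqrt(sum(ws))
  z <- beta_re / se_re
  qn <- stats::qnorm(0.975)
  i2 <- if (q_stat > 0) max(0, (q_stat - q_df) / q_stat) * 100 else 0
  data.frame(
    k = k, beta_re = beta_re, se_re = se_re, or_re = exp(beta_re),
    ci_low = exp(beta_re - qn * se_re), ci_high = exp(beta_re + qn * se_re),
    log10_p = (log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10),
    q_stat = q_stat, q_df = q_df,
    p_q = stats::pchisq(q_stat, q_df, lower.tail = FALSE),
    i2 = min(100, i2), tau2 = tau2)
}

# Long marker -> SNP membership for the estimable rows of one scan.
scan_snp_map <- function(scan) {
  ok <- scan[scan$status == "ok", , drop = FALSE]
  if (!nrow(ok)) return(list())
  ids <- strsplit(ok$snp_ids, ",", fixed = TRUE)
  long <- data.frame(marker_id = rep(ok$marker_id, lengths(ids)),
                     snp_id = unlist(ids), stringsAsFactors = FALSE)
  split(long$marker_id, long$snp_id)
}

#' Index SNPs shared by surviving haplotypes of every population
#'
#' A SNP qualifies as an anchor candidate only if it is a constituent of at
#' least one estimable haplotype marker in every population.
#'
#' @param scans Named list of [run_population_scan()] outputs, one per
#'   population.
#' @return Named list mapping each common `snp_id` to a per-population list
#'   of the marker ids whose windows contain it. Empty (with a warning)
#'   when no SNP is anchorable.
#' @export
index_common_snps <- function(scans) {
  stopifnot(length(scans) >= 1L, !is.null(names(scans)))
  maps <- lapply(scans, scan_snp_map)
  common <- Reduce(intersect, lapply(maps, names))
  if (!length(common)) {
    warning("no SNP is shared by surviving haplotypes of every population")
    return(structure(list(), names = character(0)))
  }
  common <- sort(common)
  out <- lapply(common, function(s) lapply(maps, `[[`, s))
  names(out) <- common
  out
}

#' Anchored cross-population meta-analysis of haplotype markers
#'
#' Haplotypes are rarely identical across populations, so results are
#' combined through joint SNPs: for every SNP present in surviving
#' haplotypes of all populations, each population contributes its most
#' significant haplotype containing that SNP, and the contributed log ORs
#' and SEs are pooled with [dl_random_effects()]. The joint SNP is only an
#' anchor — the pooled estimate, p-value and frequency describe the
#' haplotypes it represents.
#'
#' @param scans Named list of [run_population_scan()] outputs.
#' @param variant_map `data.frame` with columns `id` and `pos` giving the bp
#'   of every SNP id (union over populations); used for anchor tie-breaking
#'   and reporting.
#' @return List of class `anchored_meta`: `anchors` (`data.frame`, one row
#'   per candidate joint SNP: `snp_id`, `chrom`, `snp_pos`,
#'   `region_start`/`region_end` — the lowest start and highest end of the
#'   chosen haplotypes — `all_risk`, and the [dl_random_effects()] columns)
#'   and `details` (per-population chosen markers, one row per
#'   population per anchor).
#' @export
anchored_meta <- function(scans, variant_map) {
  idx <- index_common_snps(scans)
  pos_of <- stats::setNames(variant_map$pos, variant_map$id)
  anchors <- list()
  details <- list()
  for (s in names(idx)) {
    chosen <- lapply(names(scans), function(pop) {
      rows <- scans[[pop]][scans[[pop]]$marker_id %in% idx[[s]][[pop]] &
                             scans[[pop]]$status == "ok", , drop = FALSE]
      rows <- rows[order(rows$log10_p, rows$marker_id), , drop = FALSE]
      rows[1L, , drop = FALSE]
    })
    ch <- do.call(rbind, chosen)
    meta <- dl_random_effects(ch$beta, ch$se)
    anchors[[s]] <- cbind(
      data.frame(snp_id = s, chrom = ch$chrom[1L],
                 snp_pos = unname(pos_of[s]),
                 region_start = min(ch$pos_start),
                 region_end = max(ch$pos_end),
                 all_risk = all(ch$beta > 0), stringsAsFactors = FALSE),
      meta)
    details[[s]] <- cbind(snp_id = s, ch)
  }
  anchors <- do.call(rbind, anchors)
  details <- do.call(rbind, details)
  if (!is.null(anchors)) {
    ord <- order(anchors$chrom, anchors$snp_pos, anchors$snp_id)
    anchors <- anchors[ord, ]
    rownames(anchors) <- NULL
    rownames(details) <- NULL
  }
  structure(list(anchors = anchors, details = details),
            class = "anchored_meta")
}

#' Select the joint SNP among anchor candidates
#'
#' Returns the candidate with the smallest pooled p-value; ties are broken
#' by smaller bp, then lexicographic SNP id.
#'
#' @param anchors Anchor `data.frame` (rows of `anchored_meta()$anchors`).
#' @return The winning row.
#' @export
select_joint_snp <- function(anchors) {
  stopifnot(nrow(anchors) >= 1L)
  ord <- order(anchors$log10_p, anchors$snp_pos, anchors$snp_id)
  anchors[ord[1L], , drop = FALSE]
}

#' Collapse overlapping anchored haplotypes to their best joint SNP
#'
#' Anchors whose haplotype regions overlap on the same chromosome are
#' grouped transitively (interval-graph connected components); within each
#' group only the most significant anchor — the joint SNP with the smallest
#' pooled p — is retained.
#'
#' @param am An [anchored_meta()] result.
#' @return An `anchored_meta` with one anchor per overlap group.
#' @export
resolve_overlaps <- function(am) {
  stopifnot(inherits(am, "anchored_meta"))
  a <- am$anchors
  if (is.null(a) || !nrow(a)) return(am)
  grp <- overlap_groups(a)
  keep <- vapply(unique(grp), function(g)
    select_joint_snp(a[grp == g, , drop = FALSE])$snp_id, character(1))
  anchors <- am$anchors[am$anchors$snp_id %in% keep, , drop = FALSE]
  details <- am$details[am$details$snp_id %in% keep, , drop = FALSE]
  rownames(anchors) <- NULL
  rownames(details) <- NULL
  structure(list(anchors = anchors, details = details),
            class = "anchored_meta")
}

# Transitive overlap grouping of anchors on [region_start, region_end],
# within chromosome. Returns a group label per row of `a` (anchors
# data.frame); intervals are 1-based inclusive, touching counts as overlap.
overlap_groups <- function(a) {
  grp <- character(nrow(a))
  for (ch in unique(a$chrom)) {
    idx <- which(a$chrom == ch)
    ord <- idx[order(a$region_start[idx], a$region_end[idx])]
    g <- 0L
    hi <- -Inf
    for (i in ord) {
      if (a$region_start[i] > hi) g <- g + 1L
      grp[i] <- paste0(ch, ":", g)
      hi <- max(hi, a$region_end[i])
    }
  }
  grp
}

#' @export
print.anchored_meta <- function(x, ...) {
  n <- if (is.null(x$anchors)) 0L else nrow(x$anchors)
  cat(sprintf("anchored_meta: %d candidate joint SNPs\n", n))
  invisible(x)
}
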