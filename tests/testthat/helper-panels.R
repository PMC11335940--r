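# Small deterministic panel builders used across test files.

# Panel from an explicit haplotype matrix; positions default to 1 kb grid.
make_panel <- function(haps, pos = NULL, label = "TEST",
                       phenotype = NULL, sex = NULL, chrom = "1") {
  haps <- as.matrix(haps)
  m <- ncol(haps)
  n <- nrow(haps) / 2L
  if (is.null(pos)) pos <- seq(10000L, by = 1000L, length.out = m)
  if (is.null(phenotype)) phenotype <- rep_len(c(0L, 1L), n)
  if (is.null(sex)) sex <- rep_len(c(0L, 1L), n)
  variants <- data.frame(chrom = chrom, pos = as.integer(pos),
                         id = sprintf("s%03d", seq_len(m)),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  phased_panel(label, variants, haps, phenotype, sex)
}

# Random panel with given haplotype row count and SNP count.
random_panel <- function(n_hap, m, seed = 1, label = "RND") {
  set.seed(seed)
  make_panel(matrix(rbinom(n_hap * m, 1L, runif(m, 0.1, 0.9)[rep(1:m, each = n_hap)]),
                    n_hap, m), label = label)
}

# Synthetic anchored_meta object for joint_meta / regions tests.
# `rows` is a data.frame with at least snp_id, region_start, region_end,
# log10_p; remaining anchor columns get sensible defaults.
make_anchored <- function(rows, details = NULL, k = 3L) {
  defaults <- data.frame(chrom = "1", snp_pos = rows$region_start,
                         all_risk = TRUE, k = k, beta_re = 0.5,
                         se_re = 0.1, or_re = exp(0.5), ci_low = exp(0.3),
                         ci_high = exp(0.7), q_stat = 0, q_df = k - 1L,
                         p_q = 1, i2 = 0, tau2 = 0,
                         stringsAsFactors = FALSE)
  for (nm in names(defaults))
    if (is.null(rows[[nm]])) rows[[nm]] <- defaults[[nm]]
  if (is.null(details)) {
    details <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i)
      data.frame(snp_id = rows$snp_id[i],
                 population = paste0("POP", seq_len(k)),
                 marker_id = paste0(rows$snp_id[i], "_m"),
                 beta = 0.5, se = 0.1, odds_ratio = exp(0.5),
                 ci_low = exp(0.3), ci_high = exp(0.7), log10_p = -5,
                 freq = 0.2, pos_start = rows$region_start[i],
                 pos_end = rows$region_end[i],
                 stringsAsFactors = FALSE)))
  }
  structure(list(anchors = rows, details = details),
            class = "anchored_meta")
}

# One-marker scan row for index_common_snps tests.
make_scan_row <- function(marker_id, snp_ids, population, log10_p = -5,
                          beta = 0.5, se = 0.1, status = "ok",
                          pos_start = 100L, pos_end = 200L) {
  data.frame(marker_id = marker_id, chrom = "1", window_id = 1L,
             block_coord = (pos_start + pos_end) %/% 2L,
             pos_start = pos_start, pos_end = pos_end,
             snp_ids = paste(snp_ids, collapse = ","),
             allele_seq = "0", freq = 0.2, population = population,
             beta = beta, se = se, z = beta / se, log10_p = log10_p,
             odds_ratio = exp(beta), ci_low = exp(beta - 0.2),
             ci_high = exp(beta + 0.2), allele_freq = 0.2,
             n_cases = 100L, n_controls = 100L, status = status,
             stringsAsFactors = FALSE)
}
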