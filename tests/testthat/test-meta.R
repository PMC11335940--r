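test_that("homogeneous inputs collapse to the common effect", {
  m <- dl_random_effects(c(0.5, 0.5, 0.5), c(0.1, 0.1, 0.1))
  expect_equal(m$beta_re, 0.5)
  expect_equal(m$q_stat, 0)
  expect_equal(m$tau2, 0)
  expect_equal(m$i2, 0)
  expect_equal(m$se_re, 0.1 / sqrt(3))
})

test_that("DerSimonian-Laird matches the hand-computed oracle", {
  # frozen from independent evaluation of the moment equations
  m <- dl_random_effects(c(0.5, 0.7, 0.3), c(0.1, 0.2, 0.15))
  expect_equal(m$beta_re, 0.477914, tolerance = 1e-3)
  expect_equal(m$se_re, 0.094159, tolerance = 1e-3)
  expect_equal(m$q_stat, 2.688525, tolerance = 1e-3)
  expect_equal(m$tau2, 0.007241, tolerance = 1e-3)
  expect_equal(m$i2, 25.6098, tolerance = 1e-3)
})

test_that("DL agrees with an independent meta-analysis implementation", {
  set.seed(88)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    b <- rnorm(k, 0.4, 0.3)
    s <- runif(k, 0.05, 0.4)
    mine <- dl_random_effects(b, s)
    ref <- metafor::rma(yi = b, sei = s, method = "DL")
    expect_equal(mine$beta_re, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(mine$se_re, ref$se, tolerance = 1e-8)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(mine$q_stat, ref$QE, tolerance = 1e-8)
    expect_equal(mine$i2, ref$I2, tolerance = 1e-6)
  }
})

test_that("tau2 truncates at zero whenever Q <= k - 1", {
  set.seed(4)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    m <- dl_random_effects(rnorm(k, 0.2, 0.05), runif(k, 0.1, 0.3))
    if (m$q_stat <= m$q_df) expect_equal(m$tau2, 0)
    expect_gte(m$tau2, 0)
    expect_true(m$ci_low < m$or_re && m$or_re < m$ci_high)
  }
})

test_that("meta-analysis rejects degenerate inputs", {
  expect_error(dl_random_effects(0.5, 0.1), "at least 2")
  expect_error(dl_random_effects(c(0.5, 0.6), c(0.1, 0)), "ses")
  expect_error(dl_random_effects(c(0.5, 0.6), c(0.1, -1)), "ses")
})

test_that("common-SNP indexing equals the set-intersection oracle", {
  s <- function(i) sprintf("s%02d", i)
  scans <- list(
    POP1 = make_scan_row("m1", s(1:15), "POP1"),
    POP2 = make_scan_row("m2", s(3:17), "POP2"),
    POP3 = make_scan_row("m3", s(5:19), "POP3"))
  idx <- index_common_snps(scans)
  oracle <- Reduce(intersect, list(s(1:15), s(3:17), s(5:19)))
  expect_setequal(names(idx), oracle)
  expect_true(all(names(idx) %in% s(5:15)))
  expect_identical(idx[[s(5)]]$POP1, "m1")

  # identical panels: every SNP of every surviving window is common
  scans2 <- list(A = make_scan_row("m", s(1:15), "A"),
                 B = make_scan_row("m", s(1:15), "B"))
  expect_setequal(names(index_common_snps(scans2)), s(1:15))

  # a population with no surviving markers empties the map
  scans3 <- list(A = make_scan_row("m", s(1:15), "A"),
                 B = make_scan_row("m", s(1:15), "B", status = "skip_separation"))
  expect_warning(idx3 <- index_common_snps(scans3), "no SNP")
  expect_length(idx3, 0L)
})

test_that("joint-SNP selection is the argmin with deterministic tie-breaks", {
  a <- make_anchored(data.frame(
    snp_id = c("rsA", "rsB"), region_start = c(100L, 100L),
    region_end = c(200L, 200L), log10_p = c(-9, -7)))$anchors
  expect_equal(select_joint_snp(a)$snp_id, "rsA")
  expect_equal(select_joint_snp(a[1, , drop = FALSE])$snp_id, "rsA")

  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:20, 1)
    cand <- make_anchored(data.frame(
      snp_id = sprintf("rs%03d", sample(999, n)),
      region_start = sample(1000L, n), region_end = 2000L,
      log10_p = round(rnorm(n, -6, 1), 1)))$anchors
    cand$snp_pos <- sample(100L, n, replace = TRUE)
    # brute-force argmin with stated tie-breaks
    best <- cand[order(cand$log10_p, cand$snp_pos, cand$snp_id), ][1, ]
    expect_identical(select_joint_snp(cand)$snp_id, best$snp_id)
  }
})

test_that("overlap resolution keeps the best anchor per transitive group", {
  # disjoint anchors all survive
  am <- make_anchored(data.frame(
    snp_id = c("a", "b"), region_start = c(100L, 500L),
    region_end = c(200L, 600L), log10_p = c(-9, -8)))
  expect_setequal(resolve_overlaps(am)$anchors$snp_id, c("a", "b"))

  # three mutually overlapping anchors: only the smallest p remains
  am <- make_anchored(data.frame(
    snp_id = c("a", "b", "c"), region_start = c(100L, 150L, 120L),
    region_end = c(300L, 400L, 350L), log10_p = c(-8, -10, -9)))
  expect_identical(resolve_overlaps(am)$anchors$snp_id, "b")

  # random interval sets vs brute-force connected components + argmin
  set.seed(61)
  for (i in 1:15) {
    n <- sample(2:12, 1)
    st <- sample(1000L, n)
    am <- make_anchored(data.frame(
      snp_id = sprintf("rs%02d", seq_len(n)), region_start = st,
      region_end = st + sample(50:400, n, replace = TRUE),
      log10_p = rnorm(n, -6)))
    a <- am$anchors
    overlaps <- outer(seq_len(n), seq_len(n), Vectorize(function(x, y)
      a$region_start[x] <= a$region_end[y] &&
        a$region_start[y] <= a$region_end[x]))
    comp <- seq_len(n)  # transitive closure by label propagation
    repeat {
      new <- vapply(seq_len(n), function(x) min(comp[overlaps[x, ]]),
                    integer(1))
      if (identical(new, comp)) break
      comp <- new
    }
    oracle <- vapply(unique(comp), function(g) {
      sub <- a[comp == g, , drop = FALSE]
      sub$snp_id[which.min(sub$log10_p)]
    }, character(1))
    expect_setequal(resolve_overlaps(am)$anchors$snp_id, oracle)
  }
})

test_that("anchored meta pools the most significant haplotype per population", {
  s <- function(i) sprintf("s%02d", i)
  p1 <- rbind(make_scan_row("w1", s(1:15), "POP1", log10_p = -6, beta = 0.5),
              make_scan_row("w2", s(3:17), "POP1", log10_p = -9, beta = 0.7,
                            pos_start = 150L, pos_end = 260L))
  p2 <- make_scan_row("v1", s(5:19), "POP2", log10_p = -5, beta = 0.4,
                      pos_start = 190L, pos_end = 300L)
  vmap <- data.frame(id = s(1:19), pos = seq(10L, by = 10L, length.out = 19))
  am <- anchored_meta(list(POP1 = p1, POP2 = p2), vmap)
  # common SNPs: (s3..s17) via w2 or (s1..s15) via w1, intersected with s5..s19
  expect_setequal(am$anchors$snp_id, s(5:17))
  # at s5..s15, POP1 contributes its smaller-p haplotype w2
  d <- am$details[am$details$snp_id == s(10) & am$details$population == "POP1", ]
  expect_identical(d$marker_id, "w2")
  # pooled estimate equals a direct DL call on the chosen pair
  a10 <- am$anchors[am$anchors$snp_id == s(10), ]
  ref <- dl_random_effects(c(0.7, 0.4), c(0.1, 0.1))
  expect_equal(a10$beta_re, ref$beta_re)
  expect_equal(a10$log10_p, ref$log10_p)
  # merged interval spans the chosen haplotypes
  expect_equal(a10$region_start, 150)
  expect_equal(a10$region_end, 300)
})

test_that("anchoring soundness: the joint SNP sits in the chosen haplotype of every population", {
  cfg <- pipeline_config(sim = sim_config(n_cases = 150, n_controls = 150,
                                          n_snps = 60,
                                          causal_window_index = 10,
                                          causal_allele_logOR = log(2),
                                          seed = 77))
  res <- run_pipeline(cfg, write_files = FALSE)
  am <- res$meta
  for (i in seq_len(nrow(am$anchors))) {
    s <- am$anchors$snp_id[i]
    d <- am$details[am$details$snp_id == s, ]
    expect_equal(nrow(d), am$anchors$k[i])
    for (j in seq_len(nrow(d)))
      expect_true(s %in% strsplit(d$snp_ids[j], ",")[[1]])
  }
})
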