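test_that("identical configs give bit-identical panels and output files", {
  cfg <- sim_config(n_populations = 2, n_cases = 40, n_controls = 40,
                    n_snps = 40, seed = 11)
  p1 <- simulate_panels(cfg)
  p2 <- simulate_panels(cfg)
  expect_identical(p1, p2)

  d1 <- file.path(tempdir(), "det1"); dir.create(d1, showWarnings = FALSE)
  d2 <- file.path(tempdir(), "det2"); dir.create(d2, showWarnings = FALSE)
  write_haps_sample(p1[[1]], file.path(d1, "pop"))
  write_haps_sample(p2[[1]], file.path(d2, "pop"))
  expect_identical(unname(tools::md5sum(file.path(d1, "pop.haps"))),
                   unname(tools::md5sum(file.path(d2, "pop.haps"))))
  expect_identical(readLines(file.path(d1, "pop.sample")),
                   readLines(file.path(d2, "pop.sample")))
})

test_that("null simulations center the causal-window case/control frequency difference", {
  diffs <- vapply(1:200, function(s) {
    cfg <- sim_config(n_populations = 1, n_cases = 60, n_controls = 60,
                      n_snps = 40, causal_window_index = 5,
                      causal_allele_logOR = 0, maf_floor = 0, seed = 7000 + s)
    panels <- simulate_panels(cfg)
    ca <- attr(panels, "causal")
    p <- panels[[1]]
    cols <- match(ca$snp_ids, p$variants$id)
    allele <- as.integer(strsplit(ca$allele_seq, "")[[1]])
    sub <- p$haps[, cols, drop = FALSE]
    hit <- rowSums(sub == matrix(allele, nrow(sub), length(allele),
                                 byrow = TRUE)) == length(allele)
    dose <- hit[c(TRUE, FALSE)] + hit[c(FALSE, TRUE)]
    mean(dose[p$phenotype == 1]) / 2 - mean(dose[p$phenotype == 0]) / 2
  }, numeric(1))
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("full SNP overlap yields identical variant lists across populations", {
  cfg <- sim_config(n_populations = 3, n_cases = 30, n_controls = 30,
                    n_snps = 40, snp_overlap_fraction = 1, maf_floor = 0,
                    seed = 3)
  panels <- simulate_panels(cfg)
  expect_identical(panels[[1]]$variants, panels[[2]]$variants)
  expect_identical(panels[[2]]$variants, panels[[3]]$variants)
})

test_that("per-window haplotype diversity matches a brute-force re-read of the haps file", {
  cfg <- sim_config(n_populations = 1, n_cases = 50, n_controls = 50,
                    n_snps = 200, founder_pool_size = 20, recomb_rate = 0.01,
                    seed = 1)
  panel <- simulate_panels(cfg)[[1]]
  prefix <- file.path(tempdir(), "divers")
  write_haps_sample(panel, prefix)

  # independent oracle: parse the emitted .haps text and tally distinct rows
  raw <- strsplit(readLines(paste0(prefix, ".haps")), " ")
  mat <- t(vapply(raw, function(r) as.integer(r[-(1:5)]),
                  integer(2L * n_samples(panel))))
  m <- nrow(mat)  # variants as rows here
  starts <- seq(1L, m - 15L + 1L, by = 2L)
  oracle_counts <- vapply(starts, function(s) {
    block <- t(mat[s:(s + 14L), , drop = FALSE])
    nrow(unique(block))
  }, integer(1))

  wins <- enumerate_windows(panel, 15L, 2L)
  pkg_counts <- vapply(seq_len(nrow(wins)), function(i)
    nrow(call_hap_alleles(panel, wins[i, ])$alleles), integer(1))
  expect_equal(pkg_counts, oracle_counts)
  expect_equal(mean(pkg_counts), mean(oracle_counts))
})

test_that("no variant violates the MAF floor after filtering, in any panel", {
  cfg <- sim_config(n_cases = 100, n_controls = 100, n_snps = 60,
                    maf_floor = 0.05, seed = 21)
  for (p in simulate_panels(cfg)) {
    f <- alt_freq(p)
    expect_true(all(pmin(f, 1 - f) >= 0.05))
  }
})

test_that("haps/sample writer emits the documented layout and round-trips", {
  # 1 sample, 1 variant, haplotypes (0, 1)
  p1 <- make_panel(matrix(c(0L, 1L), 2, 1), phenotype = 1L, sex = 0L)
  prefix <- file.path(tempdir(), "tiny")
  write_haps_sample(p1, prefix)
  line <- readLines(paste0(prefix, ".haps"))
  expect_length(line, 1L)
  expect_match(line, "0 1$")

  # 3 samples x 4 variants -> 4 .haps rows
  p3 <- make_panel(matrix(rbinom(24, 1, 0.5), 6, 4))
  write_haps_sample(p3, prefix)
  expect_length(readLines(paste0(prefix, ".haps")), 4L)

  # round trip is exact
  cfg <- sim_config(n_populations = 1, n_cases = 30, n_controls = 30,
                    n_snps = 30, seed = 9)
  pan <- simulate_panels(cfg)[[1]]
  write_haps_sample(pan, prefix)
  back <- read_haps_sample(prefix, label = pan$label)
  expect_identical(back$haps, pan$haps)
  expect_identical(back$phenotype, pan$phenotype)
  expect_identical(back$sex, pan$sex)
  expect_equal(back$variants, pan$variants, ignore_attr = TRUE)
})

test_that("phased VCF writer emits one phased GT per sample and variant", {
  p <- make_panel(matrix(c(0L, 1L, 1L, 1L), 2, 2), phenotype = 1L, sex = 0L)
  path <- file.path(tempdir(), "tiny.vcf")
  write_phased_vcf(p, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2L)
  expect_match(body[1], "0\\|1$")
  expect_match(body[2], "1\\|1$")
})

test_that("embedded effect of ln(2) is recovered by the causal-marker logistic fit", {
  covered <- vapply(1:100, function(s) {
    cfg <- sim_config(n_populations = 1, n_cases = 500, n_controls = 500,
                      n_snps = 40, causal_window_index = 7,
                      causal_allele_logOR = log(2), maf_floor = 0,
                      seed = 8000 + s)
    panels <- simulate_panels(cfg)
    ca <- attr(panels, "causal")
    p <- panels[[1]]
    cols <- match(ca$snp_ids, p$variants$id)
    allele <- as.integer(strsplit(ca$allele_seq, "")[[1]])
    sub <- p$haps[, cols, drop = FALSE]
    hit <- rowSums(sub == matrix(allele, nrow(sub), length(allele),
                                 byrow = TRUE)) == length(allele)
    dose <- hit[c(TRUE, FALSE)] + hit[c(FALSE, TRUE)]
    fit <- fit_logistic(dose, p$phenotype, p$sex)
    fit$status == "ok" &&
      fit$beta - qnorm(0.975) * fit$se <= log(2) &&
      fit$beta + qnorm(0.975) * fit$se >= log(2)
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_snps = 20, causal_window_index = 10),
               "causal_window_index")
  expect_error(sim_config(maf_floor = 1.2), "probabilities")
  expect_error(sim_config(n_cases = 0), "counts")
})
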