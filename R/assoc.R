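#' Logistic association of one pseudo-marker with case/control status
#'
#' Fits `logit P(case) = b0 + beta * count + b_sex * sex` by
#' iteratively reweighted least squares, with the haplotype-allele count
#' (0/1/2) entering additively. Convergence is declared when the maximum
#' absolute score drops below `1e-8` or the parameter change below `1e-10`;
#' at most 50 iterations are attempted. Standard errors come from the
#' inverse observed information. P-values are kept in log10 space so that
#' genome-wide tails far below double-precision underflow remain usable.
#'
#' Unestimable fits are reported as skip records rather than numbers: a
#' marker with no variation (`skip_monomorphic`), a phenotype with a single
#' class (`skip_single_class`), or complete/quasi-separation, flagged when
#' `|beta| > 15` or the fit fails to converge (`skip_separation`).
#'
#' @param counts Integer vector of per-sample allele counts in `{0, 1, 2}`.
#' @param phenotype Integer vector, 0 = control / 1 = case.
#' @param sex Optional 0/1 covariate vector; omit for an unadjusted fit.
#' @return One-row `data.frame`: `beta`, `se`, `z`, `log10_p`,
#'   `odds_ratio`, `ci_low`, `ci_high` (95%, on the OR scale),
#'   `allele_freq`, `n_cases`, `n_controls`, `status` (`"ok"` or a skip
#'   reason; estimates are `NA` for skips).
#' @export
fit_logistic <- function(counts, phenotype, sex = NULL) {
  core <- fit_logistic_core(counts, phenotype, sex)
  data.frame(beta = core[["beta"]], se = core[["se"]], z = core[["z"]],
             log10_p = core[["log10_p"]], odds_ratio = core[["odds_ratio"]],
             ci_low = core[["ci_low"]], ci_high = core[["ci_high"]],
             allele_freq = core[["allele_freq"]],
             n_cases = as.integer(core[["n_cases"]]),
             n_controls = as.integer(core[["n_controls"]]),
             status = c("ok", "skip_single_class", "skip_monomorphic",
                        "skip_separation")[core[["status_code"]]],
             stringsAsFactors = FALSE)
}

# Numeric-vector backend of fit_logistic; status_code 1 = ok,
# 2 = skip_single_class, 3 = skip_monomorphic, 4 = skip_separation.
fit_logistic_core <- function(counts, phenotype, sex = NULL) {
  n_ca <- sum(phenotype == 1L)
  n_co <- sum(phenotype == 0L)
  out <- c(beta = NA_real_, se = NA_real_, z = NA_real_,
           log10_p = NA_real_, odds_ratio = NA_real_, ci_low = NA_real_,
           ci_high = NA_real_, allele_freq = mean(counts) / 2,
           n_cases = n_ca, n_controls = n_co, status_code = 1)
  if (n_ca == 0L || n_co == 0L) { out[["status_code"]] <- 2; return(out) }
  r <- range(counts)
  if (r[1L] == r[2L]) { out[["status_code"]] <- 3; return(out) }

  x <- if (is.null(sex)) cbind(1, counts) else cbind(1, counts, sex)
  y <- as.numeric(phenotype)
  beta <- numeric(ncol(x))
  converged <- FALSE
  for (it in seq_len(50L)) {
    mu <- stats::plogis(drop(x %*% beta))
    score <- drop(crossprod(x, y - mu))
    info <- crossprod(x * (mu * (1 - mu)), x)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(score)) < 1e-8 || max(abs(step)) < 1e-10) {
      converged <- TRUE
      break
    }
  }
  if (!converged || abs(beta[2L]) > 15) {
    out[["status_code"]] <- 4
    return(out)
  }
  mu <- stats::plogis(drop(x %*% beta))
  info <- crossprod(x * (mu * (1 - mu)), x)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc) || any(diag(vc) <= 0)) {
    out[["status_code"]] <- 4
    return(out)
  }
  b <- beta[2L]
  se <- sqrt(vc[2L, 2L])
  z <- b / se
  q <- stats::qnorm(0.975)
  out[["beta"]] <- b
  out[["se"]] <- se
  out[["z"]] <- z
  out[["log10_p"]] <- (log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10)
  out[["odds_ratio"]] <- exp(b)
  out[["ci_low"]] <- exp(b - q * se)
  out[["ci_high"]] <- exp(b + q * se)
  out
}

#' Association scan of all haplotype pseudo-markers in one population
#'
#' Applies [fit_logistic()] (sex-adjusted) to every marker of a
#' [call_markers()] result, returning one row per marker — estimates for
#' clean fits, skip records otherwise — in deterministic
#' (chrom, block_coord, marker_id) order.
#'
#' @param panel The [phased_panel()] the markers belong to.
#' @param hm A [call_markers()] result for the same panel.
#' @return `data.frame` with marker metadata (`marker_id`, `chrom`,
#'   `window_id`, `block_coord`, `pos_start`, `pos_end`, `snp_ids`,
#'   `allele_seq`, `freq`, `population`) plus the [fit_logistic()] columns.
#' @export
run_population_scan <- function(panel, hm) {
  stopifnot(inherits(hm, "hap_markers"))
  mk <- hm$markers
  fits <- t(vapply(seq_len(nrow(mk)), function(j)
    fit_logistic_core(hm$counts[, j], panel$phenotype, panel$sex),
    numeric(11L)))
  fit_df <- as.data.frame(fits[, 1:10, drop = FALSE])
  fit_df$n_cases <- as.integer(fit_df$n_cases)
  fit_df$n_controls <- as.integer(fit_df$n_controls)
  fit_df$status <- c("ok", "skip_single_class", "skip_monomorphic",
                     "skip_separation")[fits[, "status_code"]]
  out <- cbind(mk, population = panel$label, fit_df)
  out <- out[order(out$chrom, out$block_coord, out$marker_id), ]
  rownames(out) <- NULL
  out
}

#' Write a population scan as a summary-statistics TSV
#'
#' @param scan Output of [run_population_scan()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
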