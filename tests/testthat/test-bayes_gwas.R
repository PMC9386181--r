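# small shared fixture: moderate signal so the chain has something to find
gwas_fixture <- function(seed = 101, n = 300, n_snps = 200, n_qtl = 4,
                         h2 = 0.4) {
  cfg <- sim_config(n_samples = n, n_snps = n_snps, n_qtl = n_qtl, h2 = h2,
                    chrom_lengths = c("1" = 20e6, "2" = 20e6),
                    ld_block_size = 5, within_block_r = 0.5, seed = seed)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)
  list(g = g, ph = ph, cfg = cfg)
}

test_that("model spec validates pi and burn-in", {
  expect_error(gwas_spec(pi = 0), "pi")
  expect_error(gwas_spec(pi = 1.2), "pi")
  expect_warning(gwas_spec(pi = 1), "empties")
  expect_error(gwas_spec(n_iter = 100, burn_in = 100), "burn_in")
})

test_that("degenerate inputs are rejected", {
  fx <- gwas_fixture()
  ph <- fx$ph$pheno
  ph$trait <- 1
  expect_error(run_bayes_c(fx$g, ph, gwas_spec(mode = "bayesC")), "constant")
  few <- fx$ph$pheno[1:4, ]
  expect_error(
    run_bayes_c(list(geno = fx$g$geno[1:4, ], map = fx$g$map), few,
                gwas_spec(mode = "bayesC")),
    "fewer samples")
})

test_that("Bayes C recovers variance components on a known-h2 fixture", {
  fx <- gwas_fixture(seed = 111, n = 500, n_snps = 300, h2 = 0.5)
  spec <- gwas_spec(pi = 0.97, n_iter = 1500, burn_in = 300, seed = 5,
                    mode = "bayesC")
  fit <- run_bayes_c(fx$g, fx$ph$pheno, spec)
  expect_gte(fit$h2, 0.4); expect_lte(fit$h2, 0.6)

  # pure-noise phenotype: genetic variance collapses
  ph0 <- fx$ph$pheno
  set.seed(99); ph0$trait <- rnorm(nrow(ph0))
  fit0 <- run_bayes_c(fx$g, ph0, spec)
  expect_lt(fit0$sigma2_g, 0.15 * var(ph0$trait))
})

test_that("Bayes B finds a planted large-effect window and recovers h2", {
  fx <- gwas_fixture(seed = 121, n = 400, n_snps = 300, n_qtl = 1, h2 = 0.4)
  spec <- gwas_spec(pi = 0.99, n_iter = 2000, burn_in = 500, seed = 6)
  fit <- run_bayes_b(fx$g, fx$ph$pheno, spec)
  expect_s3_class(fit$window_table, "tbl_df")
  expect_lt(abs(fit$h2_posterior_mean - 0.4), 0.15)
  qtl_snp <- fx$ph$truth$qtl_snps$snp_id[1]
  qtl_window <- tidy(fit)$window[match(qtl_snp, fx$g$map$snp_id)]
  top <- fit$window_table$window[which.max(fit$window_table$prop_vg)]
  expect_identical(top, qtl_window)
  # window shares sum to ~100% of the genetic variance
  expect_gt(sum(fit$window_table$prop_vg), 50)
  expect_lt(sum(fit$window_table$prop_vg), 150)
  # tidy/glance expose the posterior summaries
  td <- tidy(fit)
  expect_identical(nrow(td), ncol(fx$g$geno))
  expect_true(all(td$inclusion_prob >= 0 & td$inclusion_prob <= 1))
  gl <- glance(fit)
  expect_identical(gl$n_windows, length(fit$window_levels))
})

test_that("pi near 1 empties the model", {
  fx <- gwas_fixture(seed = 131, n = 150, n_snps = 80)
  spec <- gwas_spec(pi = 1 - 1e-12, n_iter = 600, burn_in = 100, seed = 2)
  fit <- run_bayes_b(fx$g, fx$ph$pheno, spec)
  expect_lt(max(fit$inclusion_prob), 0.02)
  expect_lt(fit$h2_posterior_mean, 0.05)
})

test_that("Bayes B with huge prior df matches Bayes C on matched seeds", {
  fx <- gwas_fixture(seed = 141, n = 300, n_snps = 150, h2 = 0.4)
  base <- list(pi = 0.97, n_iter = 1500, burn_in = 300, seed = 9,
               nu_beta = 1e8)
  c_fit <- run_bayes_c(fx$g, fx$ph$pheno,
                       do.call(gwas_spec, c(base, mode = "bayesC")))
  b_fit <- run_bayes_b(fx$g, fx$ph$pheno,
                       do.call(gwas_spec, c(base, mode = "bayesB")),
                       priors = list(sigma2_g = var(fx$ph$pheno$trait) / 2,
                                     sigma2_e = var(fx$ph$pheno$trait) / 2))
  expect_lt(abs(b_fit$h2_posterior_mean - c_fit$h2), 0.02 + 0.02)
})

test_that("posterior summaries are exchangeable under SNP permutation", {
  fx <- gwas_fixture(seed = 151, n = 250, n_snps = 200)
  spec <- gwas_spec(pi = 0.98, n_iter = 1200, burn_in = 300, seed = 4)
  fit1 <- run_bayes_b(fx$g, fx$ph$pheno, spec)
  set.seed(8); perm <- sample(ncol(fx$g$geno))
  gp <- list(geno = fx$g$geno[, perm], map = fx$g$map[perm, ])
  fit2 <- run_bayes_b(gp, fx$ph$pheno, spec)
  expect_lt(abs(fit1$h2_posterior_mean - fit2$h2_posterior_mean), 0.05)
  w1 <- dplyr::arrange(fit1$window_table, window)
  w2 <- dplyr::arrange(fit2$window_table, window)
  expect_identical(w1$window, w2$window)
  expect_lt(max(abs(w1$prop_vg - w2$prop_vg)), 5)
})

test_that("window indexing follows the floor((pos-1)/1e6) convention", {
  # a position in the 16th Mb of chromosome 23 lands in window 23_15
  map <- tibble::tibble(snp_id = c("r1", "r2", "r3"), chrom = "23",
                        pos = c(15000692L, 15992208L, 999999L))
  idx <- floor((map$pos - 1) / 1e6)
  expect_identical(idx, c(15, 15, 0))
  set.seed(10)
  geno <- matrix(sample(0:2, 30 * 3, replace = TRUE), 30, 3,
                 dimnames = list(sprintf("s%02d", 1:30), map$snp_id))
  pheno <- tibble::tibble(sample_id = rownames(geno),
                          trait = rnorm(30) + geno[, 1],
                          group = rep(c("a", "b"), 15),
                          covariate = rnorm(30))
  fit <- run_bayes_b(list(geno = geno, map = map), pheno,
                     gwas_spec(pi = 0.5, n_iter = 400, burn_in = 100, seed = 3))
  expect_setequal(fit$window_table$window, c("23_15", "23_0"))
  expect_identical(
    fit$window_table$n_snps[fit$window_table$window == "23_15"], 2L)
})

test_that("relevance threshold arithmetic and inclusive boundary", {
  w100 <- tibble::tibble(chrom = "1", window_index = 0:99, window = paste0("1_", 0:99),
                         prop_vg = rep(1, 100))
  out <- call_relevant_windows(w100, multiplier = 5)
  expect_identical(attr(out, "threshold_pct"), 5)
  # hand case: props (0.25, 0.19, 0.20) at threshold 0.20 -> 2 relevant
  # (500 windows at multiplier 1 put the threshold at exactly 100/500 = 0.20)
  w500 <- tibble::tibble(chrom = "1", window_index = 0:499,
                         window = paste0("1_", 0:499),
                         prop_vg = c(0.25, 0.19, 0.20, rep(0, 497)))
  out3 <- call_relevant_windows(w500, multiplier = 1)
  expect_equal(attr(out3, "threshold_pct"), 0.20)
  expect_identical(sum(out3$relevant), 2L)
  expect_error(call_relevant_windows(w500[0, ]), "empty")
})

test_that("window report writes an ordered TSV with the relevance flag", {
  w <- tibble::tibble(chrom = c("2", "1", "1"), window_index = c(0, 5, 1),
                      window = c("2_0", "1_5", "1_1"),
                      first_pos = 1, last_pos = 2, n_snps = 1L,
                      prop_vg = c(3, 1, 2))
  out <- call_relevant_windows(w, multiplier = 1)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  manhattan_window_report(out, tmp)
  back <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_identical(back$window, c("1_1", "1_5", "2_0"))
  expect_identical(nrow(back), 3L)
  expect_true("relevant" %in% names(back))
})

test_that("null fixtures rarely flag relevant windows", {
  flagged <- total <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_samples = 120, n_snps = 100, n_qtl = 1, h2 = 0.3,
                      chrom_lengths = c("1" = 10e6, "2" = 10e6),
                      group_effect_sd = 0, seed = 2000 + s)
    g <- simulate_genotypes(cfg)
    set.seed(3000 + s)
    pheno <- tibble::tibble(sample_id = rownames(g$geno),
                            trait = rnorm(nrow(g$geno)),
                            group = rep_len(c("a", "b"), nrow(g$geno)),
                            covariate = rnorm(nrow(g$geno)))
    fit <- run_bayes_b(g, pheno,
                       gwas_spec(pi = 0.99, n_iter = 800, burn_in = 200,
                                 seed = s))
    w <- call_relevant_windows(fit$window_table)
    flagged <- flagged + sum(w$relevant)
    total <- total + nrow(w)
  }
  expect_lte(flagged / total, 0.05)
})

test_that("small-instance posterior matches brute-force enumeration", {
  set.seed(77)
  n <- 50
  A <- matrix(sample(0:2, n * 3, replace = TRUE, prob = c(.25, .5, .25)), n, 3)
  A <- scale(A, scale = FALSE)
  s2b <- 0.2; s2e <- 1
  y <- A %*% c(0.8, 0, -0.4) + rnorm(n, 0, sqrt(s2e))
  y <- y - mean(y)
  exact <- oracle_bayes_enum(A, y, pi0 = 0.5, sigma2_beta = s2b, sigma2_e = s2e)

  geno <- A + 2  # wrapper re-centres; any affine shift is equivalent
  map <- tibble::tibble(snp_id = paste0("m", 1:3), chrom = "1",
                        pos = c(1e5L, 2e5L, 3e5L))
  pheno <- tibble::tibble(sample_id = paste0("s", 1:n), trait = as.vector(y))
  spec <- gwas_spec(pi = 0.5, n_iter = 30000, burn_in = 2000, seed = 12,
                    mode = "bayesC", fixed_effect_columns = character(),
                    covariate_columns = character(), intercept = FALSE,
                    fix_sigma2_e = s2e, fix_sigma2_beta = s2b)
  fit <- run_bayes_b(list(geno = geno, map = map), pheno,
                     spec = local({s <- spec; s$mode <- "bayesB"; s}),
                     priors = list(sigma2_g = s2b, sigma2_e = s2e))
  expect_lt(max(abs(fit$inclusion_prob - exact)), 0.03)
})
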