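#' Model specification for the Bayes B / Bayes C GWAS
#'
#' @param pi prior probability that a SNP is excluded from the model
#'   (study-scale default 0.9997; use smaller values on small fixtures).
#' @param n_iter total MCMC iterations (default 41000).
#' @param burn_in discarded initial iterations (default 1000).
#' @param nu_beta prior degrees of freedom for the SNP effect variance.
#' @param nu_e prior degrees of freedom for the residual variance.
#' @param seed RNG seed for the chain.
#' @param mode `"bayesB"` (per-locus effect variance, scaled inverse
#'   chi-square) or `"bayesC"` (one shared effect variance).
#' @param fixed_effect_columns phenotype columns treated as factors (fixed
#'   effects); default the contemporary group.
#' @param covariate_columns phenotype columns entering as standardized
#'   covariates; default the carcass-weight covariate.
#' @param intercept include an intercept in the fixed-effect design.
#' @param fix_sigma2_e,fix_sigma2_beta optional fixed values for the variance
#'   components (used for controlled comparisons against enumeration
#'   oracles); `NULL` means sample them.
#' @param save_beta_chain keep the full per-iteration SNP effect matrix
#'   (memory heavy; small fixtures only).
#' @return a `gwas_spec` list.
#' @export
gwas_spec <- function(pi = 0.9997, n_iter = 41000, burn_in = 1000,
                      nu_beta = 4, nu_e = 4, seed = 1L,
                      mode = c("bayesB", "bayesC"),
                      fixed_effect_columns = "group",
                      covariate_columns = "covariate",
                      intercept = TRUE,
                      fix_sigma2_e = NULL, fix_sigma2_beta = NULL,
                      save_beta_chain = FALSE) {
  mode <- match.arg(mode)
  if (pi <= 0 || pi >= 1) {
    if (pi == 1) warning("pi = 1 empties the model; all effects will be zero")
    else stop("pi must lie in (0, 1)", call. = FALSE)
  }
  if (burn_in >= n_iter) stop("burn_in must be < n_iter", call. = FALSE)
  structure(list(pi = pi, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), nu_beta = nu_beta,
                 nu_e = nu_e, seed = as.integer(seed), mode = mode,
                 fixed_effect_columns = fixed_effect_columns,
                 covariate_columns = covariate_columns,
                 intercept = isTRUE(intercept),
                 fix_sigma2_e = fix_sigma2_e,
                 fix_sigma2_beta = fix_sigma2_beta,
                 save_beta_chain = isTRUE(save_beta_chain)),
            class = "gwas_spec")
}

# fixed-effect design: intercept + full-rank factor dummies + standardized
# covariates; may legitimately have zero columns
build_design <- function(pheno, spec) {
  n <- nrow(pheno)
  X <- if (spec$intercept) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
       else matrix(0, n, 0)
  for (fc in spec$fixed_effect_columns) {
    f <- factor(pheno[[fc]])
    if (nlevels(f) > 1) {
      d <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(d) <- paste0(fc, levels(f)[-1])
      X <- cbind(X, d)
    }
  }
  for (cc in spec$covariate_columns) {
    v <- pheno[[cc]]
    if (stats::sd(v) > 0) v <- (v - mean(v)) / stats::sd(v)
    X <- cbind(X, matrix(v, ncol = 1, dimnames = list(NULL, cc)))
  }
  X
}

# centre genotype columns at twice the allele frequency; mean-impute missing
center_genotypes <- function(geno) {
  G <- as.matrix(geno)
  storage.mode(G) <- "double"
  p2 <- colMeans(G, na.rm = TRUE)
  for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- p2[j]
  sweep(G, 2, p2)
}

# GenSel-style effect-variance prior scale, derived from a genetic-variance
# estimate: S2_beta = s2g (nu-2) / (nu (1-pi) sum 2 p (1-p))
effect_var_scale <- function(sigma2_g, nu_beta, pi, geno) {
  p <- colMeans(as.matrix(geno), na.rm = TRUE) / 2
  het <- sum(2 * p * (1 - p))
  sigma2_g * (nu_beta - 2) / (nu_beta * (1 - pi) * het)
}

check_gwas_inputs <- function(geno, pheno, spec) {
  y <- pheno$trait
  if (anyNA(y)) stop("phenotype contains missing values", call. = FALSE)
  if (stats::var(y) == 0)
    stop("degenerate input: phenotype is constant", call. = FALSE)
  n_levels <- sum(vapply(spec$fixed_effect_columns,
                         function(fc) nlevels(factor(pheno[[fc]])), 0L))
  if (nrow(pheno) < n_levels + 2)
    stop("fewer samples than fixed-effect levels + 2", call. = FALSE)
  if (nrow(geno) != nrow(pheno))
    stop("genotype and phenotype sample counts differ", call. = FALSE)
}

run_sampler <- function(geno, pheno, spec, s2_beta_scale, s2_e_prior_mean,
                        window_idx, n_windows) {
  y <- pheno$trait
  A <- center_genotypes(geno)
  X <- build_design(pheno, spec)
  s2_e_scale <- s2_e_prior_mean * (spec$nu_e - 2) / spec$nu_e
  set.seed(spec$seed)
  .bayes_mcmc_cpp(A, X, y, spec$pi, spec$n_iter, spec$burn_in,
                  spec$nu_beta, s2_beta_scale, spec$nu_e, s2_e_scale,
                  spec$mode == "bayesB",
                  spec$fix_sigma2_e %||% -1, spec$fix_sigma2_beta %||% -1,
                  as.integer(window_idx), as.integer(n_windows),
                  spec$save_beta_chain)
}

#' Bayes C stage: estimate genetic and residual variances
#'
#' Runs the shared-effect-variance mixture model to obtain posterior means
#' of the genetic variance (variance across individuals of the genomic
#' values, per kept iteration) and the residual variance, used as priors for
#' the Bayes B association stage.
#'
#' @param geno genotype set (`map` + `geno`) or a bare samples x SNPs matrix.
#' @param pheno phenotype tibble with columns `trait` plus the fixed-effect /
#'   covariate columns named in `spec`.
#' @param spec a [gwas_spec()] with `mode = "bayesC"`.
#' @return a `bayesc_fit` list with `sigma2_g`, `sigma2_e`, `h2` and the
#'   retained chains.
#' @export
run_bayes_c <- function(geno, pheno, spec = gwas_spec(mode = "bayesC")) {
  if (spec$mode != "bayesC") stop("spec$mode must be 'bayesC'", call. = FALSE)
  G <- if (is.list(geno) && !is.null(geno$geno)) geno$geno else geno
  check_gwas_inputs(G, pheno, spec)
  y <- pheno$trait
  s2b <- effect_var_scale(stats::var(y) / 2, spec$nu_beta, spec$pi, G)
  res <- run_sampler(G, pheno, spec, s2b, stats::var(y) / 2,
                     window_idx = rep(0L, ncol(G)), n_windows = 1L)
  structure(list(
    sigma2_g = mean(res$sigma2_g_samples),
    sigma2_e = mean(res$sigma2_e_samples),
    h2 = mean(res$sigma2_g_samples /
                (res$sigma2_g_samples + res$sigma2_e_samples)),
    sigma2_g_samples = as.vector(res$sigma2_g_samples),
    sigma2_e_samples = as.vector(res$sigma2_e_samples),
    spec = spec), class = "bayesc_fit")
}

#' Bayes B stage: whole-genome association fit with window decomposition
#'
#' Fits `y = Xb + sum_j a_j beta_j delta_j + e` with per-locus effect
#' variances, accumulating posterior mean effects, inclusion probabilities,
#' variance-component chains, and the per-iteration variance of each 1-Mb
#' window's genomic values for the window table.
#'
#' @inheritParams run_bayes_c
#' @param snp_map tibble (snp_id, chrom, pos) aligned with the genotype
#'   columns; taken from `geno$map` when present.
#' @param priors a [run_bayes_c()] fit (or list with `sigma2_g`, `sigma2_e`)
#'   supplying the variance priors; when `NULL` a Bayes C stage is run first
#'   at the same spec settings.
#' @param window_bp window width in bp (1 Mb default).
#' @return a `gwas_fit` object; see [window_variance()], [tidy.gwas_fit()],
#'   [glance.gwas_fit()], [autoplot.gwas_fit()].
#' @export
run_bayes_b <- function(geno, pheno, spec = gwas_spec(mode = "bayesB"),
                        priors = NULL, snp_map = NULL, window_bp = 1e6) {
  G <- if (is.list(geno) && !is.null(geno$geno)) geno$geno else geno
  snp_map <- snp_map %||% geno$map
  if (is.null(snp_map))
    stop("snp_map required (snp_id, chrom, pos)", call. = FALSE)
  check_gwas_inputs(G, pheno, spec)
  if (is.null(priors)) {
    cspec <- spec; cspec$mode <- "bayesC"; class(cspec) <- "gwas_spec"
    priors <- run_bayes_c(G, pheno, cspec)
  }
  # occupied windows only, ordered by (chrom, window index)
  widx <- floor((snp_map$pos - 1) / window_bp)
  wkey <- paste(snp_map$chrom, widx, sep = "_")
  ord <- order(snp_map$chrom, widx)
  wlevels <- unique(wkey[ord])
  if (length(wlevels) == 0) stop("empty window set", call. = FALSE)
  window_id <- match(wkey, wlevels) - 1L

  s2b <- effect_var_scale(priors$sigma2_g, spec$nu_beta, spec$pi, G)
  res <- run_sampler(G, pheno, spec, s2b, priors$sigma2_e,
                     window_id, length(wlevels))
  h2_samples <- res$sigma2_g_samples /
    (res$sigma2_g_samples + res$sigma2_e_samples)
  fit <- structure(list(
    posterior_mean_effect = as.vector(res$beta_mean),
    inclusion_prob = as.vector(res$inclusion_prob),
    b_mean = as.vector(res$b_mean),
    sigma2_g_samples = as.vector(res$sigma2_g_samples),
    sigma2_e_samples = as.vector(res$sigma2_e_samples),
    h2_posterior_mean = mean(h2_samples),
    window_var_samples = res$window_var_samples,
    window_levels = wlevels,
    window_id = window_id,
    snp_map = snp_map,
    window_bp = window_bp,
    beta_samples = res$beta_samples,
    priors = list(sigma2_g = priors$sigma2_g, sigma2_e = priors$sigma2_e),
    spec = spec), class = "gwas_fit")
  fit$window_table <- window_variance(fit)
  fit
}

#' Decompose genetic variance into SNP windows
#'
#' For each kept iteration t and window w, the window's share is
#' `Var_individuals(g_w) / Var_individuals(g_total)` where `g_w` is the sum
#' of included SNP effects times centred genotypes inside w; the posterior
#' mean share x 100 is reported. Iterations with zero total genetic variance
#' are skipped.
#'
#' @param fit a `gwas_fit` from [run_bayes_b()].
#' @return tibble: chrom, window_index, window (label `chrom_index`),
#'   first_pos, last_pos, n_snps, prop_vg (percent).
#' @export
window_variance <- function(fit) {
  stopifnot(inherits(fit, "gwas_fit"))
  tot <- fit$sigma2_g_samples
  keep <- tot > 0
  props <- if (any(keep)) {
    colMeans(fit$window_var_samples[keep, , drop = FALSE] / tot[keep]) * 100
  } else rep(0, length(fit$window_levels))
  map <- fit$snp_map
  widx <- floor((map$pos - 1) / fit$window_bp)
  wkey <- paste(map$chrom, widx, sep = "_")
  info <- tibble::tibble(chrom = map$chrom, window_index = widx,
                         window = wkey, pos = map$pos) |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     window_index = dplyr::first(.data$window_index),
                     first_pos = min(.data$pos), last_pos = max(.data$pos),
                     n_snps = dplyr::n(), .groups = "drop")
  info <- info[match(fit$window_levels, info$window), ]
  info$prop_vg <- as.vector(props)
  dplyr::arrange(
    dplyr::select(info, "chrom", "window_index", "window", "first_pos",
                  "last_pos", "n_snps", "prop_vg"),
    .data$chrom, .data$window_index)
}

#' Flag relevant QTL windows
#'
#' Under an infinitesimal model each of the n occupied windows is expected
#' to explain 100/n percent of the genetic variance; windows explaining at
#' least `multiplier` times that expectation are flagged as relevant QTL
#' regions (boundary inclusive).
#'
#' @param windows window table from [window_variance()] (column `prop_vg`).
#' @param multiplier fold-over-expectation threshold (default 5).
#' @return the table with a `relevant` flag, plus attributes
#'   `expected_pct` and `threshold_pct`.
#' @export
call_relevant_windows <- function(windows, multiplier = 5) {
  n <- nrow(windows)
  if (n < 1) stop("empty window table", call. = FALSE)
  expected <- 100 / n
  threshold <- multiplier * expected
  out <- dplyr::mutate(windows, relevant = .data$prop_vg >= threshold)
  attr(out, "expected_pct") <- expected
  attr(out, "threshold_pct") <- threshold
  out
}

#' Ordered window report
#'
#' Writes the window table, ordered by (chrom, window_index), as TSV; the
#' companion figure is [autoplot.gwas_fit()].
#'
#' @param windows window table (ideally after [call_relevant_windows()]).
#' @param path optional TSV output path.
#' @return the ordered tibble, invisibly when `path` is given.
#' @export
manhattan_window_report <- function(windows, path = NULL) {
  out <- dplyr::arrange(windows, .data$chrom, .data$window_index)
  if (!is.null(path)) {
    readr::write_tsv(out, path)
    return(invisible(out))
  }
  out
}

#' @export
print.gwas_fit <- function(x, ...) {
  cat("Bayes", sub("bayes", "", x$spec$mode), "whole-genome regression fit\n")
  cat(sprintf("  SNPs: %d   windows: %d   iterations: %d (burn-in %d)\n",
              length(x$posterior_mean_effect), length(x$window_levels),
              x$spec$n_iter, x$spec$burn_in))
  cat(sprintf("  posterior mean h2: %.3f\n", x$h2_posterior_mean))
  invisible(x)
}

#' Per-SNP posterior summaries
#'
#' @param x a `gwas_fit`.
#' @param ... unused.
#' @return tibble: snp_id, chrom, pos, window, effect (posterior mean of
#'   beta x delta), inclusion_prob.
#' @export
tidy.gwas_fit <- function(x, ...) {
  tibble::tibble(snp_id = x$snp_map$snp_id, chrom = x$snp_map$chrom,
                 pos = x$snp_map$pos,
                 window = x$window_levels[x$window_id + 1L],
                 effect = x$posterior_mean_effect,
                 inclusion_prob = x$inclusion_prob)
}

#' One-row fit summary
#'
#' @param x a `gwas_fit`.
#' @param ... unused.
#' @return tibble with h2, sigma2_g, sigma2_e, n_snps, n_windows, n_iter,
#'   burn_in, pi.
#' @export
glance.gwas_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2_posterior_mean,
                 sigma2_g = mean(x$sigma2_g_samples),
                 sigma2_e = mean(x$sigma2_e_samples),
                 n_snps = length(x$posterior_mean_effect),
                 n_windows = length(x$window_levels),
                 n_iter = x$spec$n_iter, burn_in = x$spec$burn_in,
                 pi = x$spec$pi)
}
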