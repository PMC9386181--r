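#' Simulation configuration
#'
#' Bundles every knob of the synthetic genotype / phenotype / expression
#' generator into one validated object. Defaults emulate a beef-cattle
#' muscle-transcriptome study design: ~200 steers, LD-blocked biallelic
#' genotypes with MAF at or above the 5% QC floor, a moderately heritable
#' carcass trait (h-squared around 0.2) with contemporary-group fixed effects
#' and a carcass-weight covariate, and an RNA-seq count matrix carrying
#' planted cis (<= 1 Mb) and trans (> 1 Mb) regulatory effects plus batch
#' structure.
#'
#' @param n_samples number of individuals.
#' @param n_snps total number of SNPs across chromosomes.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param ld_block_size SNPs per LD block (blocks are independent).
#' @param within_block_r latent Gaussian-copula correlation within a block,
#'   in `[0, 1)`; 0 gives independent SNPs.
#' @param maf_range length-2 interval for allele frequencies; lower bound must
#'   be >= 0.05 (mirrors the MAF QC floor).
#' @param n_qtl number of trait QTL.
#' @param qtl_equal_effects if `TRUE`, QTL get equal-magnitude effects with
#'   random signs (each QTL window carries an equal share of the genetic
#'   variance by construction); if `FALSE` (default) effects are Gaussian, so
#'   shares vary.
#' @param h2 narrow-sense genomic heritability, strictly inside (0, 1),
#'   defined as var(genetic) / (var(genetic) + var(residual)).
#' @param n_groups number of contemporary groups (fixed-effect levels).
#' @param group_effect_sd SD of contemporary-group effects (trait units).
#' @param covariate_effect regression coefficient of the standard-normal
#'   carcass-weight covariate on the trait.
#' @param n_genes number of genes in the expression matrix.
#' @param cis_effect_sd,trans_effect_sd magnitude of planted eQTL effects
#'   (log2-expression units per allele copy); signs are random, so planted
#'   effects are detectably non-zero by construction.
#' @param n_cis_eqtl,n_trans_eqtl numbers of planted cis / trans pairs.
#' @param n_cis_at_qtl of the cis pairs, how many must sit on trait-QTL SNPs
#'   (requires passing `qtl_snps` to [simulate_expression()]); lets
#'   end-to-end fixtures carry regulatory variants inside QTL windows.
#' @param expr_noise_sd residual SD of latent log2 expression.
#' @param n_batches number of technical batches in the expression data.
#' @param batch_effect_sd SD of per-gene batch shifts (log2 units).
#' @param libsize_range length-2 interval of total library sizes (counts).
#' @param missing_rate genotype missingness rate injected after simulation
#'   (default 0 so QC fixtures are clean unless asked otherwise).
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 200,
                       n_snps = 1000,
                       chrom_lengths = c("1" = 50e6, "2" = 50e6),
                       ld_block_size = 10,
                       within_block_r = 0.9,
                       maf_range = c(0.1, 0.5),
                       n_qtl = 5,
                       qtl_equal_effects = FALSE,
                       h2 = 0.25,
                       n_groups = 4,
                       group_effect_sd = 0.5,
                       covariate_effect = 0.3,
                       n_genes = 100,
                       cis_effect_sd = 1,
                       trans_effect_sd = 1,
                       n_cis_eqtl = 10,
                       n_trans_eqtl = 5,
                       n_cis_at_qtl = 0,
                       expr_noise_sd = 0.5,
                       n_batches = 2,
                       batch_effect_sd = 0.5,
                       libsize_range = c(5e5, 2e6),
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(n_samples = n_samples, n_snps = n_snps,
              chrom_lengths = unlist(chrom_lengths), ld_block_size = ld_block_size,
              within_block_r = within_block_r, maf_range = maf_range,
              n_qtl = n_qtl, qtl_equal_effects = isTRUE(qtl_equal_effects),
              h2 = h2, n_groups = n_groups,
              group_effect_sd = group_effect_sd,
              covariate_effect = covariate_effect,
              n_genes = n_genes, cis_effect_sd = cis_effect_sd,
              trans_effect_sd = trans_effect_sd,
              n_cis_eqtl = n_cis_eqtl, n_trans_eqtl = n_trans_eqtl,
              n_cis_at_qtl = n_cis_at_qtl,
              expr_noise_sd = expr_noise_sd, n_batches = n_batches,
              batch_effect_sd = batch_effect_sd,
              libsize_range = libsize_range, missing_rate = missing_rate,
              seed = as.integer(seed))
  counts <- c("n_samples", "n_snps", "ld_block_size", "n_qtl", "n_groups",
              "n_genes", "n_batches")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 1)
      stop(f, " must be a positive count", call. = FALSE)
  }
  if (cfg$h2 <= 0 || cfg$h2 >= 1)
    stop("h2 must lie strictly inside (0, 1)", call. = FALSE)
  if (cfg$within_block_r < 0 || cfg$within_block_r >= 1)
    stop("within_block_r must lie in [0, 1)", call. = FALSE)
  if (cfg$maf_range[1] < 0.05)
    stop("maf_range lower bound must be >= 0.05", call. = FALSE)
  if (cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be an interval within [0.05, 0.5]", call. = FALSE)
  if (is.null(names(cfg$chrom_lengths)))
    stop("chrom_lengths must be a named vector", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# genotype block via a Gaussian copula on latent gametes: two independent
# latent MVN draws per sample (one per allele copy), exchangeable correlation
# r within the block, thresholded at the Hardy-Weinberg allele-frequency
# quantile, so margins are Binomial(2, p) and LD is controlled by r.
sim_geno_block <- function(n, p_alleles, r) {
  m <- length(p_alleles)
  thr <- stats::qnorm(p_alleles)
  draw_gamete <- function() {
    if (r > 0) {
      z_shared <- stats::rnorm(n)
      z <- sqrt(r) * matrix(z_shared, n, m) +
        sqrt(1 - r) * matrix(stats::rnorm(n * m), n, m)
    } else {
      z <- matrix(stats::rnorm(n * m), n, m)
    }
    sweep(z, 2, thr, `<`) * 1L
  }
  draw_gamete() + draw_gamete()
}

#' Simulate LD-blocked biallelic genotypes
#'
#' Draws genotype codes `{0, 1, 2}` for `n_samples` x `n_snps` with SNPs
#' grouped into LD blocks: within a block, allele draws share a latent
#' Gaussian factor with correlation `within_block_r`; blocks are independent.
#' Positions are drawn uniformly per chromosome (unique, 1-based, sorted).
#' Blocks whose realized minor allele frequencies dip below 0.05 are
#' rejection-resampled so fixtures pass the MAF QC filter untouched.
#'
#' @param cfg a [sim_config()].
#' @return a list with `geno` (samples x SNPs integer matrix, dimnames set)
#'   and `map` (tibble: snp_id, chrom, pos).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n_chr <- length(cfg$chrom_lengths)
    # SNPs per chromosome proportional to length
    alloc <- round(cfg$n_snps * cfg$chrom_lengths / sum(cfg$chrom_lengths))
    alloc[n_chr] <- cfg$n_snps - sum(alloc[-n_chr])
    if (any(alloc > cfg$chrom_lengths))
      stop("n_snps exceeds what chrom_lengths can hold with unique positions",
           call. = FALSE)
    map <- purrr::map2_dfr(names(cfg$chrom_lengths), alloc, function(chr, k) {
      if (k <= 0) return(NULL)
      tibble::tibble(chrom = chr,
                     pos = sort(sample.int(cfg$chrom_lengths[[chr]], k)))
    })
    map$snp_id <- paste0("snp_", map$chrom, "_", map$pos)
    map <- dplyr::select(map, "snp_id", "chrom", "pos")

    n <- cfg$n_samples
    geno <- matrix(0L, n, nrow(map))
    # blocks never span chromosomes
    start <- 1L
    for (chr in unique(map$chrom)) {
      idx <- which(map$chrom == chr)
      blocks <- split(idx, ceiling(seq_along(idx) / cfg$ld_block_size))
      for (blk in blocks) {
        lo <- cfg$maf_range[1]
        for (attempt in seq_len(200)) {
          # SNPs in one LD block share a base allele frequency (plus jitter),
          # as in real haplotype blocks; dissimilar frequencies would cap the
          # achievable genotype correlation
          base_p <- stats::runif(1, lo, cfg$maf_range[2])
          p_all <- pmin(pmax(base_p + stats::runif(length(blk), -0.05, 0.05),
                             lo), cfg$maf_range[2])
          g <- sim_geno_block(n, p_all, cfg$within_block_r)
          maf <- pmin(colMeans(g) / 2, 1 - colMeans(g) / 2)
          if (all(maf >= 0.05)) break
          # widen away from the floor if the block keeps failing
          if (attempt == 50) lo <- max(lo, min(0.1, cfg$maf_range[2]))
          if (attempt == 200)
            stop("could not realize MAF >= 0.05 in an LD block", call. = FALSE)
        }
        geno[, blk] <- g
      }
      start <- start + length(idx)
    }
    if (cfg$missing_rate > 0) {
      miss <- stats::runif(length(geno)) < cfg$missing_rate
      geno[miss] <- NA_integer_
    }
    dimnames(geno) <- list(sprintf("sample_%03d", seq_len(n)), map$snp_id)
    list(geno = geno, map = map)
  })
}

#' Simulate a phenotype with planted QTL and fixed effects
#'
#' Builds the generative counterpart of the association model
#' `y = Xb + sum_j a_j beta_j + e`: contemporary-group effects, a
#' standard-normal covariate (carcass weight stand-in), `n_qtl` additive QTL
#' effects, and Gaussian noise. Realized genetic and residual components are
#' rescaled so var(g) / (var(g) + var(e)) equals `h2` exactly; ground truth
#' records the planted effects.
#'
#' @param g output of [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return list with `pheno` (tibble: sample_id, trait, group, covariate) and
#'   `truth` (list: qtl_snps tibble of snp_id/effect, true_h2, sigma2_g,
#'   sigma2_e).
#' @export
simulate_phenotype <- function(g, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_qtl > ncol(g$geno))
    stop("n_qtl must not exceed n_snps", call. = FALSE)
  withr::with_seed(cfg$seed + 1L, {
    n <- nrow(g$geno)
    qtl_idx <- sort(sample.int(ncol(g$geno), cfg$n_qtl))
    eff <- if (cfg$qtl_equal_effects %||% FALSE)
      sample(c(-1, 1), cfg$n_qtl, replace = TRUE)
    else stats::rnorm(cfg$n_qtl)
    G <- g$geno[, qtl_idx, drop = FALSE]
    G[is.na(G)] <- 0
    gval <- unname(drop(G %*% eff))
    # rescale so realized variances hit the h2 contract exactly
    sg <- stats::sd(gval)
    if (sg == 0) stop("planted QTL are monomorphic; increase n_samples")
    scale_g <- sqrt(cfg$h2) / sg
    gval <- (gval - mean(gval)) * scale_g
    eff <- eff * scale_g
    e <- stats::rnorm(n)
    e <- (e - mean(e)) / stats::sd(e) * sqrt(1 - cfg$h2)
    grp <- factor(rep_len(seq_len(cfg$n_groups), n))
    grp_eff <- stats::rnorm(cfg$n_groups, 0, cfg$group_effect_sd)
    covariate <- stats::rnorm(n)
    y <- grp_eff[as.integer(grp)] + cfg$covariate_effect * covariate + gval + e

    pheno <- tibble::tibble(sample_id = rownames(g$geno),
                            trait = y,
                            group = paste0("cg", as.integer(grp)),
                            covariate = covariate)
    truth <- list(
      qtl_snps = tibble::tibble(snp_id = g$map$snp_id[qtl_idx], effect = eff),
      true_h2 = cfg$h2,
      sigma2_g = stats::var(gval),
      sigma2_e = stats::var(e),
      genetic_values = gval)
    list(pheno = pheno, truth = truth)
  })
}

#' Simulate an RNA-seq count matrix with planted cis/trans eQTL
#'
#' Latent log2 expression = gene baseline + batch shift + planted additive
#' genotype effects + Gaussian noise; counts are Poisson with sample exposure
#' libsize x 2^latent / normalizer, so CPM followed by log2 recovers the
#' latent signal through a monotone link. Planted cis pairs respect the
#' <= 1 Mb rule against the emitted gene map; trans pairs are > 1 Mb away
#' (usually another chromosome).
#'
#' @param g output of [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return list with `counts` (genes x samples integer matrix), `gene_map`
#'   (tibble: gene_id, chrom, start, end; 1-based inclusive), `batches`
#'   (tibble: sample_id, batch) and `truth` (tibble: snp_id, gene_id, beta,
#'   class).
#' @export
simulate_expression <- function(g, cfg, qtl_snps = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_cis_eqtl + cfg$n_trans_eqtl > cfg$n_genes * ncol(g$geno))
    stop("more planted eQTL than available SNP-gene pairs", call. = FALSE)
  withr::with_seed(cfg$seed + 2L, {
    n <- nrow(g$geno)
    map <- g$map
    chroms <- names(cfg$chrom_lengths)
    gene_chr <- sample(chroms, cfg$n_genes, replace = TRUE,
                       prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
    gene_len <- sample(2000:50000, cfg$n_genes, replace = TRUE)
    gene_start <- purrr::map2_int(gene_chr, gene_len, function(chr, len)
      sample.int(max(1L, cfg$chrom_lengths[[chr]] - len), 1L))
    gene_map <- tibble::tibble(
      gene_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
      chrom = gene_chr, start = gene_start,
      end = gene_start + gene_len - 1L)

    dist_tbl <- classify_pairs(map, gene_map)  # reuses the scan's classifier
    cis_pool <- dplyr::filter(dist_tbl, .data$class == "cis")
    trans_pool <- dplyr::filter(dist_tbl, .data$class == "trans")
    if (nrow(cis_pool) < cfg$n_cis_eqtl)
      stop("impossible cis placement: no (or too few) SNPs within 1 Mb of ",
           "any gene; enlarge n_snps or shrink chromosomes", call. = FALSE)
    if (nrow(trans_pool) < cfg$n_trans_eqtl)
      stop("too few trans SNP-gene pairs available", call. = FALSE)
    n_at_qtl <- min(cfg$n_cis_at_qtl %||% 0, cfg$n_cis_eqtl)
    at_qtl <- cis_pool[0, ]
    if (n_at_qtl > 0 && !is.null(qtl_snps)) {
      pool_q <- dplyr::filter(cis_pool, .data$snp_id %in% qtl_snps)
      if (nrow(pool_q) == 0) {
        warning("no gene lies within the cis window of any QTL SNP; ",
                "cis pairs planted at random SNPs instead")
      } else {
        at_qtl <- dplyr::slice_sample(pool_q, n = min(n_at_qtl, nrow(pool_q)))
      }
    }
    rest <- dplyr::anti_join(cis_pool, at_qtl, by = c("snp_id", "gene_id"))
    planted <- dplyr::bind_rows(
      at_qtl,
      dplyr::slice_sample(rest, n = cfg$n_cis_eqtl - nrow(at_qtl)),
      dplyr::slice_sample(trans_pool, n = cfg$n_trans_eqtl))
    planted$beta <- sample(c(-1, 1), nrow(planted), replace = TRUE) *
      ifelse(planted$class == "cis", cfg$cis_effect_sd, cfg$trans_effect_sd)

    baseline <- stats::runif(cfg$n_genes, 3, 9)
    latent <- matrix(baseline, cfg$n_genes, n) +
      matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$expr_noise_sd),
             cfg$n_genes, n)
    batch <- rep_len(seq_len(cfg$n_batches), n)
    if (cfg$n_batches > 1 && cfg$batch_effect_sd > 0) {
      bshift <- matrix(stats::rnorm(cfg$n_genes * cfg$n_batches, 0,
                                    cfg$batch_effect_sd),
                       cfg$n_genes, cfg$n_batches)
      latent <- latent + bshift[, batch, drop = FALSE]
    }
    geno0 <- g$geno; geno0[is.na(geno0)] <- 0
    for (k in seq_len(nrow(planted))) {
      gi <- match(planted$gene_id[k], gene_map$gene_id)
      si <- match(planted$snp_id[k], map$snp_id)
      latent[gi, ] <- latent[gi, ] + planted$beta[k] * geno0[, si]
    }

    libsize <- round(stats::runif(n, cfg$libsize_range[1],
                                  cfg$libsize_range[2]))
    expo <- 2^latent
    rate <- sweep(expo, 2, colSums(expo), `/`)
    counts <- matrix(stats::rpois(length(rate),
                                  lambda = sweep(rate, 2, libsize, `*`)),
                     cfg$n_genes, n)
    dimnames(counts) <- list(gene_map$gene_id, rownames(g$geno))

    list(counts = counts, gene_map = gene_map,
         batches = tibble::tibble(sample_id = rownames(g$geno),
                                  batch = paste0("batch", batch)),
         truth = dplyr::select(planted, "snp_id", "gene_id", "beta", "class"))
  })
}

#' Write simulated fixtures to disk
#'
#' Emits the formats the pipeline consumes: VCF v4.2 genotypes, phenotype TSV
#' (sample, trait, group, covariate), counts TSV (genes x samples), gene map
#' TSV (1-based inclusive intervals), batch TSV and ground-truth JSON.
#'
#' @param sim list with elements `geno` (from [simulate_genotypes()]),
#'   `pheno` (from [simulate_phenotype()]), `expr` (from
#'   [simulate_expression()]).
#' @param dir output directory, created if absent.
#' @return invisibly, a named vector of file paths.
#' @export
write_fixtures <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    pheno = file.path(dir, "phenotypes.tsv"),
    counts = file.path(dir, "counts.tsv"),
    gene_map = file.path(dir, "gene_map.tsv"),
    batches = file.path(dir, "batches.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  write_vcf_genotypes(sim$geno, paths[["vcf"]])
  readr::write_tsv(sim$pheno$pheno, paths[["pheno"]])
  counts_df <- tibble::as_tibble(sim$expr$counts, rownames = "gene_id")
  readr::write_tsv(counts_df, paths[["counts"]])
  readr::write_tsv(sim$expr$gene_map, paths[["gene_map"]])
  readr::write_tsv(sim$expr$batches, paths[["batches"]])
  truth <- list(
    qtl_snps = sim$pheno$truth$qtl_snps,
    true_h2 = sim$pheno$truth$true_h2,
    true_eqtl = sim$expr$truth,
    batch_assignment = sim$expr$batches)
  jsonlite::write_json(truth, paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
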