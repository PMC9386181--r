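#' Classify SNP-gene pairs as cis or trans
#'
#' Distance is 0 when the SNP lies inside the gene body (1-based inclusive
#' interval), otherwise the distance to the nearest gene boundary. A pair is
#' cis when the SNP sits no more than `cis_window` bp from the gene
#' (boundary inclusive), trans otherwise; different chromosomes are trans
#' with an infinite distance sentinel.
#'
#' @param snp_map tibble: snp_id, chrom, pos.
#' @param gene_map tibble: gene_id, chrom, start, end (1-based inclusive).
#' @param cis_window cis distance bound in bp (default 1 Mb).
#' @return tibble: snp_id, gene_id, class, distance — one row per pair.
#' @export
classify_pairs <- function(snp_map, gene_map, cis_window = 1e6) {
  if (any(gene_map$start > gene_map$end))
    stop("gene intervals must have start <= end", call. = FALSE)
  pairs <- tidyr::crossing(
    tibble::tibble(snp_id = snp_map$snp_id, snp_chrom = snp_map$chrom,
                   pos = snp_map$pos),
    tibble::tibble(gene_id = gene_map$gene_id, gene_chrom = gene_map$chrom,
                   start = gene_map$start, end = gene_map$end))
  d <- ifelse(pairs$snp_chrom != pairs$gene_chrom, Inf,
              ifelse(pairs$pos >= pairs$start & pairs$pos <= pairs$end, 0,
                     pmin(abs(pairs$pos - pairs$start),
                          abs(pairs$pos - pairs$end))))
  tibble::tibble(snp_id = pairs$snp_id, gene_id = pairs$gene_id,
                 class = ifelse(d <= cis_window, "cis", "trans"),
                 distance = d)
}

#' Matrix eQTL scan: every SNP against every gene
#'
#' Residualizes genotypes and expression against the covariate design
#' (with intercept), then computes, for every SNP-gene pair, the slope,
#' t statistic (`t = r sqrt(df) / sqrt(1 - r^2)`, `df = n - 1 - q` with q
#' the number of design columns including the intercept) and two-sided
#' p-value of the additive linear regression. Numerically identical to
#' per-pair OLS that includes the covariates.
#'
#' Missing genotypes are mean-imputed per SNP before residualization.
#' SNPs or genes with zero variance after residualization are skipped and
#' counted in the `n_skipped_*` attributes.
#'
#' @param geno genotype set (`map` + samples x SNPs `geno`) or matrix.
#' @param expr log2-CPM matrix, genes x samples.
#' @param covariates tibble of per-sample covariates (factors become
#'   dummies), or `NULL` for intercept-only.
#' @param snp_map,gene_map maps for cis/trans labelling; `snp_map` defaults
#'   to `geno$map`.
#' @param cis_window cis bound in bp.
#' @return tibble: snp_id, gene_id, beta, t_stat, p_value, class, distance,
#'   with attributes `n_skipped_snps`, `n_skipped_genes`, `df`.
#' @export
scan_eqtl <- function(geno, expr, covariates = NULL, snp_map = NULL,
                      gene_map = NULL, cis_window = 1e6) {
  is_set <- is.list(geno) && !is.null(geno$geno)
  G <- if (is_set) geno$geno else geno
  snp_map <- snp_map %||% (if (is_set) geno$map)
  expr <- as.matrix(expr)
  samples <- intersect(rownames(G), colnames(expr))
  if (length(samples) == 0)
    stop("no shared samples between genotypes and expression", call. = FALSE)
  G <- G[samples, , drop = FALSE]
  Y <- t(expr[, samples, drop = FALSE])   # samples x genes
  n <- length(samples)

  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    cv <- covariates
    if ("sample_id" %in% names(cv)) {
      cv <- cv[match(samples, cv$sample_id), , drop = FALSE]
      cv$sample_id <- NULL
    }
    for (nm in names(cv)) {
      v <- cv[[nm]]
      if (is.character(v) || is.factor(v)) {
        f <- factor(v)
        if (nlevels(f) > 1) X <- cbind(X, stats::model.matrix(~f)[, -1, drop = FALSE])
      } else X <- cbind(X, v)
    }
  }
  q <- qr(X)
  if (q$rank < ncol(X)) stop("covariate design is rank deficient", call. = FALSE)
  df <- n - 1 - ncol(X)
  if (df < 1) stop("not enough samples for the covariate design", call. = FALSE)

  Gm <- apply(as.matrix(G), 2, function(v) {
    v <- as.numeric(v); v[is.na(v)] <- mean(v, na.rm = TRUE); v })
  Gres <- Gm - X %*% qr.coef(q, Gm)
  Yres <- Y - X %*% qr.coef(q, Y)
  sg2 <- colSums(Gres^2)
  sy2 <- colSums(Yres^2)
  ok_snp <- sg2 > 1e-12
  ok_gene <- sy2 > 1e-12

  Gu <- Gres[, ok_snp, drop = FALSE]
  Yu <- Yres[, ok_gene, drop = FALSE]
  cross <- crossprod(Gu, Yu)                       # snp x gene sums of products
  r <- cross / sqrt(outer(sg2[ok_snp], sy2[ok_gene]))
  r <- pmin(pmax(r, -1), 1)
  beta <- cross / sg2[ok_snp]
  tt <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tt), df)

  snp_ids <- colnames(G) %||% snp_map$snp_id
  gene_ids <- rownames(expr) %||% paste0("gene", seq_len(ncol(Y)))
  out <- tibble::tibble(
    snp_id = rep(snp_ids[ok_snp], times = sum(ok_gene)),
    gene_id = rep(gene_ids[ok_gene], each = sum(ok_snp)),
    beta = as.vector(beta), t_stat = as.vector(tt), p_value = as.vector(pv))
  if (!is.null(snp_map) && !is.null(gene_map)) {
    cls <- classify_pairs(snp_map[snp_map$snp_id %in% out$snp_id, ],
                          gene_map[gene_map$gene_id %in% out$gene_id, ],
                          cis_window)
    out <- dplyr::left_join(out, cls, by = c("snp_id", "gene_id"))
  }
  attr(out, "n_skipped_snps") <- sum(!ok_snp)
  attr(out, "n_skipped_genes") <- sum(!ok_gene)
  attr(out, "df") <- df
  out
}

#' Benjamini-Hochberg FDR, separately per cis/trans class
#'
#' Applies the step-up BH adjustment within each class (each class has its
#' own test count m), mirroring separate cis and trans discovery lists.
#'
#' @param records eQTL tibble with `p_value` and `class` columns (records
#'   without a class are adjusted as one group).
#' @param fdr_threshold significance bound recorded in the `significant`
#'   column (default 0.05).
#' @return the records with `fdr` and `significant` columns added.
#' @export
bh_fdr <- function(records, fdr_threshold = 0.05) {
  if (any(records$p_value < 0 | records$p_value > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  grp <- if ("class" %in% names(records)) records$class else "all"
  records$fdr <- NA_real_
  for (cl in unique(grp)) {
    i <- grp == cl
    records$fdr[i] <- stats::p.adjust(records$p_value[i], method = "BH")
  }
  records$significant <- records$fdr < fdr_threshold
  records
}
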