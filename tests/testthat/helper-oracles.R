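# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation of the quantity it checks, kept separate from the package's
# code paths.

# per-pair OLS with covariates via lm(): the slow reference for scan_eqtl
oracle_ols_pair <- function(g, y, covariates = NULL) {
  df <- data.frame(y = y, g = g)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  fit <- stats::lm(y ~ ., data = df)
  co <- summary(fit)$coefficients
  list(beta = co["g", "Estimate"], t = co["g", "t value"],
       p = co["g", "Pr(>|t|)"])
}

# posterior inclusion probabilities for the mixture model with FIXED
# variance components, by enumeration over all 2^p inclusion patterns;
# marginal likelihood of each pattern is Gaussian with beta integrated out
oracle_bayes_enum <- function(A, y, pi0, sigma2_beta, sigma2_e) {
  n <- nrow(A); p <- ncol(A)
  patterns <- as.matrix(expand.grid(rep(list(0:1), p)))
  logw <- apply(patterns, 1, function(d) {
    k <- sum(d)
    S <- diag(sigma2_e, n)
    if (k > 0) {
      Ad <- A[, d == 1, drop = FALSE]
      S <- S + sigma2_beta * tcrossprod(Ad)
    }
    ch <- chol(S)
    ld <- 2 * sum(log(diag(ch)))
    quad <- sum(backsolve(ch, y, transpose = TRUE)^2)
    -0.5 * (ld + quad) + k * log(1 - pi0) + (p - k) * log(pi0)
  })
  w <- exp(logw - max(logw)); w <- w / sum(w)
  as.vector(crossprod(patterns, w))
}

# exhaustive sliding-window LD pruning: full r2 matrix up front, windows
# enumerated one by one, the removal rule applied to exhaustion in each
oracle_ld_prune <- function(map, G, r2_max, window_snps, step_snps) {
  removed <- rep(FALSE, nrow(map))
  maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)[order(map$pos[map$chrom == chr])]
    m <- length(idx)
    r2 <- suppressWarnings(stats::cor(G[, idx, drop = FALSE])^2)
    s <- 1L
    repeat {
      win <- s:min(s + window_snps - 1L, m)
      repeat {
        act <- win[!removed[idx[win]]]
        pair <- NULL
        if (length(act) >= 2) {
          for (i in act) {
            for (j in act[act > i]) {
              v <- r2[i, j]
              if (!is.na(v) && v >= r2_max) { pair <- c(i, j); break }
            }
            if (!is.null(pair)) break
          }
        }
        if (is.null(pair)) break
        gi <- idx[pair]
        drop <- if (maf[gi[1]] < maf[gi[2]]) gi[1]
                else if (maf[gi[2]] < maf[gi[1]]) gi[2]
                else gi[which.max(map$pos[gi])]
        removed[drop] <- TRUE
      }
      if (s + window_snps - 1L >= m) break
      s <- s + step_snps
    }
  }
  map$snp_id[!removed]
}

# small deterministic genotype set for unit tests
toy_geno_set <- function(n = 20, p = 8, seed = 42, chrom = "1") {
  set.seed(seed)
  geno <- matrix(sample(0:2, n * p, replace = TRUE, prob = c(.4, .4, .2)),
                 n, p)
  pos <- sort(sample.int(5e6, p))
  map <- tibble::tibble(snp_id = paste0("s", seq_len(p)), chrom = chrom,
                        pos = pos)
  dimnames(geno) <- list(sprintf("sample_%03d", seq_len(n)), map$snp_id)
  list(geno = geno, map = map)
}
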