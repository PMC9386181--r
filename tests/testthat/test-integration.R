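test_that("ld_r2 matches a direct Pearson computation and its edge cases", {
  a <- c(0, 1, 2, 0, 1, 2); b <- c(0, 1, 1, 0, 1, 2)
  expect_equal(ld_r2(a, b), cor(a, b)^2, tolerance = 1e-12)
  expect_identical(ld_r2(a, a), 1)
  expect_identical(ld_r2(a, 2 - a), 1)      # perfect negative LD
  expect_true(is.na(ld_r2(a, rep(1, 6))))   # constant vector
  expect_error(ld_r2(a, b[-1]), "length mismatch")
  # pairwise-complete handling of missing genotypes
  am <- c(a, NA); bm <- c(b, 2)
  expect_equal(ld_r2(am, bm), cor(a, b)^2, tolerance = 1e-12)
})

test_that("eQTL-QTL intersection is exact set algebra with per-window tallies", {
  snp_map <- tibble::tibble(
    snp_id = paste0("s", 1:10), chrom = c(rep("23", 6), rep("2", 4)),
    pos = c(15000692L, 15992208L, 16000001L, 14999999L, 15500000L, 2e6L,
            1e6L, 15e6L, 3e6L, 999999L))
  eqtl <- tibble::tibble(snp_id = paste0("s", 1:10),
                         gene_id = paste0("g", 1:10),
                         class = rep(c("cis", "trans"), 5),
                         beta = rnorm(10))
  windows <- tibble::tibble(chrom = c("23", "2"), window_index = c(15, 0))
  ov <- intersect_eqtl_qtl(eqtl, windows, snp_map)
  # 23_15 spans [15000001, 16000000]: s1, s2, s5 inside; 2_0 spans
  # [1, 1000000]: s7, s10 inside
  expect_setequal(ov$eqtl$snp_id, c("s1", "s2", "s5", "s7", "s10"))
  tal <- setNames(ov$window_tally$n_eqtl, ov$window_tally$window)
  expect_identical(tal[["23_15"]], 3L)
  expect_identical(tal[["2_0"]], 2L)
  expect_identical(nrow(ov$eqtl) + (nrow(eqtl) - nrow(ov$eqtl)), nrow(eqtl))
  # no relevant windows -> empty set
  empty <- intersect_eqtl_qtl(eqtl, windows[0, ], snp_map)
  expect_identical(nrow(empty$eqtl), 0L)
  expect_error(intersect_eqtl_qtl(eqtl, dplyr::bind_rows(windows, windows[1, ]),
                                  snp_map), "overlapping")
})

test_that("per-SNP class roll-up distinguishes cis-only, trans-only and both", {
  snp_map <- tibble::tibble(snp_id = c("a", "b", "c"), chrom = "1",
                            pos = c(100L, 200L, 300L))
  eqtl <- tibble::tibble(
    snp_id = c("a", "a", "b", "c"),
    gene_id = c("g1", "g2", "g3", "g4"),
    class = c("cis", "trans", "cis", "trans"),
    beta = c(1, -1, 2, -2))
  windows <- tibble::tibble(chrom = "1", window_index = 0)
  ov <- intersect_eqtl_qtl(eqtl, windows, snp_map)
  acts <- setNames(ov$snp_classes$n_snps, ov$snp_classes$acts)
  expect_identical(acts[["both"]], 1L)
  expect_identical(acts[["cis"]], 1L)
  expect_identical(acts[["trans"]], 1L)
})

test_that("LD pruning removes the lower-MAF member of a high-LD pair", {
  set.seed(31)
  n <- 400
  base <- rbinom(n, 2, 0.4)  # MAF 0.4
  low <- base
  flip <- runif(n) < 0.1
  low[flip] <- pmax(0L, base[flip] - 1L)  # correlated, lower frequency
  g <- list(map = tibble::tibble(snp_id = c("hi_maf", "lo_maf"), chrom = "1",
                                 pos = c(100L, 200L)),
            geno = cbind(hi_maf = base, lo_maf = low))
  stopifnot(ld_r2(base, low) >= 0.5)
  pr <- ld_prune(g, prune_params())
  expect_identical(pr$tags, "hi_maf")
  expect_identical(pr$removed, "lo_maf")
})

test_that("independent SNPs are never pruned", {
  set.seed(32)
  n <- 300
  geno <- sapply(1:15, function(i) rbinom(n, 2, runif(1, 0.2, 0.5)))
  colnames(geno) <- paste0("v", 1:15)
  g <- list(map = tibble::tibble(snp_id = colnames(geno), chrom = "1",
                                 pos = sort(sample.int(1e6, 15))),
            geno = geno)
  r2max <- max(combn(15, 2, function(ij) ld_r2(geno[, ij[1]], geno[, ij[2]])))
  stopifnot(r2max < 0.5)
  pr <- ld_prune(g, prune_params(window_snps = 5, step_snps = 2))
  expect_identical(pr$tags, g$map$snp_id)
  expect_identical(ld_prune(list(map = g$map[0, ], geno = geno[, 0]))$tags,
                   character())
})

test_that("pruning agrees with the exhaustive window-enumeration oracle", {
  set.seed(33)
  for (rep in 1:50) {
    n <- 120
    p <- 12
    # blocks of correlated SNPs to force prune decisions
    z <- rbinom(n, 2, 0.45)
    geno <- sapply(1:p, function(j) {
      if (j %% 3 == 0) z <- rbinom(n, 2, runif(1, 0.1, 0.5))
      w <- runif(n) < 0.15
      out <- z; out[w] <- sample(0:2, sum(w), replace = TRUE)
      z <<- out
      out
    })
    colnames(geno) <- paste0("x", 1:p)
    map <- tibble::tibble(snp_id = colnames(geno),
                          chrom = rep(c("1", "2"), each = p / 2),
                          pos = rep(sort(sample.int(5e6, p / 2)), 2))
    g <- list(map = map, geno = geno)
    params <- prune_params(r2_max = 0.5, window_snps = 5, step_snps = 2)
    got <- ld_prune(g, params)$tags
    want <- oracle_ld_prune(map, geno, 0.5, 5, 2)
    expect_identical(got, want)
  }
})

test_that("networks carry signed edges, TF flags, degrees and round-trip exactly", {
  eqtl <- tibble::tibble(
    snp_id = c(rep("tag1", 9), "tag2"),
    gene_id = c(paste0("gene", 1:9), "gene1"),
    beta = c(rep(c(0.5, -0.5), length.out = 9), -2),
    class = c(rep("cis", 5), rep("trans", 5)))
  net <- build_network(eqtl, tag_snps = c("tag1", "tag2"),
                       tf_list = c("gene2", "gene9"))
  deg <- igraph::degree(net, mode = "out")
  expect_identical(unname(deg[["tag1"]]), 9)   # one SNP regulating nine genes
  expect_identical(sum(igraph::V(net)$is_tf), 2L)
  signs <- igraph::E(net)$sign
  expect_identical(signs[igraph::E(net)$beta < 0],
                   rep("negative", sum(eqtl$beta < 0)))
  # an edge to a pruned-away SNP violates the contract
  expect_error(build_network(eqtl, tag_snps = "tag1"), "pruned-away")
  # empty TF list flags nothing
  net0 <- build_network(eqtl, c("tag1", "tag2"))
  expect_false(any(igraph::V(net0)$is_tf))

  tmp <- withr::local_tempfile(fileext = ".graphml")
  etsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tmp, etsv)
  back <- read_network(tmp)
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  expect_identical(igraph::ecount(back), igraph::ecount(net))
  eb <- igraph::as_data_frame(back); en <- igraph::as_data_frame(net)
  ord <- function(d) d[order(d$from, d$to), ]
  expect_equal(ord(eb)$beta, ord(en)$beta, tolerance = 1e-12)
  expect_identical(ord(eb)$sign, ord(en)$sign)
  edges <- readr::read_tsv(etsv, show_col_types = FALSE)
  expect_identical(nrow(edges), 10L)
})

test_that("window BED export converts 1-based windows to 0-based half-open", {
  w <- tibble::tibble(chrom = c("23", "2"), window_index = c(15, 0))
  bed <- windows_to_bed(w)
  expect_identical(bed$start, c(15000000L, 0L))
  expect_identical(bed$end, c(16000000L, 1000000L))
  # round-trip: a SNP at 15000692 lies inside 23_15 in both conventions
  expect_true(bed$start[1] < 15000692 && 15000692 <= bed$end[1])
})
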