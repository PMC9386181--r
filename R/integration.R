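#' LD pruning parameters
#'
#' Sliding-window pairwise pruning in the PLINK `--indep-pairwise` style:
#' window of `window_snps` SNPs advanced by `step_snps`, removing one member
#' of any retained pair with r-squared at or above `r2_max`.
#'
#' @param r2_max r-squared ceiling (default 0.5).
#' @param window_snps window size in SNPs (default 100).
#' @param step_snps step in SNPs (default 10).
#' @return a `prune_params` list.
#' @export
prune_params <- function(r2_max = 0.5, window_snps = 100, step_snps = 10) {
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must lie in (0, 1]", call. = FALSE)
  if (step_snps > window_snps) stop("step must be <= window", call. = FALSE)
  structure(list(r2_max = r2_max, window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps)), class = "prune_params")
}

#' Pairwise LD as squared Pearson correlation
#'
#' Computed on additive genotype codes over pairwise-complete samples;
#' `NA` if either vector is constant.
#'
#' @param a,b genotype vectors of equal length.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Intersect significant eQTL with relevant QTL windows
#'
#' Keeps an eQTL record iff its SNP position falls inside a relevant
#' window's span `[index * 1e6 + 1, (index + 1) * 1e6]` on that chromosome.
#' Also rolls up, per retained SNP, whether it acts in cis only, trans only,
#' or both.
#'
#' @param eqtl significant eQTL records (needs snp_id, gene_id, class).
#' @param windows relevant window table (chrom, window_index; typically the
#'   `relevant == TRUE` rows from [call_relevant_windows()]).
#' @param snp_map tibble (snp_id, chrom, pos) locating the eQTL SNPs.
#' @param window_bp window width (1 Mb default).
#' @return list with `eqtl` (kept records + `window` label), `window_tally`
#'   (tibble: window, n_eqtl) and `snp_classes` (tibble: acts n_snps with
#'   acts in cis/trans/both).
#' @export
intersect_eqtl_qtl <- function(eqtl, windows, snp_map, window_bp = 1e6) {
  if (nrow(windows) > 0) {
    dup <- duplicated(windows[, c("chrom", "window_index")])
    if (any(dup)) stop("overlapping windows in input", call. = FALSE)
  }
  pos <- snp_map$pos[match(eqtl$snp_id, snp_map$snp_id)]
  chrom <- snp_map$chrom[match(eqtl$snp_id, snp_map$snp_id)]
  widx <- floor((pos - 1) / window_bp)
  wkey <- paste(chrom, widx, sep = "_")
  rel <- paste(windows$chrom, windows$window_index, sep = "_")
  keep <- wkey %in% rel
  kept <- eqtl[keep, , drop = FALSE]
  kept$window <- wkey[keep]
  tally <- dplyr::count(kept, .data$window, name = "n_eqtl")
  snp_classes <- kept |>
    dplyr::distinct(.data$snp_id, .data$class) |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(acts = if (dplyr::n() == 2) "both"
                     else dplyr::first(.data$class), .groups = "drop") |>
    dplyr::count(.data$acts, name = "n_snps")
  list(eqtl = kept, window_tally = tally, snp_classes = snp_classes)
}

#' LD-prune candidate SNPs to tag-SNPs
#'
#' Slides a window of `window_snps` SNPs along each chromosome (SNPs sorted
#' by position), advancing `step_snps` at a time. Within a window, while any
#' retained pair has r-squared at or above `r2_max`, the member with the
#' lower MAF is removed (tie: the later position). Removal is sticky across
#' windows; the result is order-deterministic.
#'
#' @param geno genotype set restricted to the candidate SNPs (`map` +
#'   samples x SNPs `geno`).
#' @param params a [prune_params()].
#' @return list with `tags` (kept snp_id vector) and `removed`.
#' @export
ld_prune <- function(geno, params = prune_params()) {
  map <- geno$map
  if (nrow(map) == 0) return(list(tags = character(), removed = character()))
  G <- as.matrix(geno$geno)
  maf <- pmin(colMeans(G, na.rm = TRUE) / 2, 1 - colMeans(G, na.rm = TRUE) / 2)
  removed <- rep(FALSE, nrow(map))
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    idx <- idx[order(map$pos[idx])]
    m <- length(idx)
    starts <- seq(1L, max(1L, m), by = params$step_snps)
    for (s in starts) {
      w <- idx[s:min(s + params$window_snps - 1L, m)]
      repeat {
        active <- w[!removed[w]]
        if (length(active) < 2) break
        worst <- NULL
        for (i in seq_len(length(active) - 1)) {
          for (j in seq((i + 1), length(active))) {
            r2 <- ld_r2(G[, active[i]], G[, active[j]])
            if (!is.na(r2) && r2 >= params$r2_max) { worst <- c(active[i], active[j]); break }
          }
          if (!is.null(worst)) break
        }
        if (is.null(worst)) break
        mafs <- maf[worst]
        drop <- if (mafs[1] < mafs[2]) worst[1]
                else if (mafs[2] < mafs[1]) worst[2]
                else worst[which.max(map$pos[worst])]
        removed[drop] <- TRUE
      }
      if (s + params$window_snps - 1L >= m) break
    }
  }
  list(tags = map$snp_id[!removed], removed = map$snp_id[removed])
}

#' Build a signed SNP-gene regulation network
#'
#' One edge per (tag SNP, gene) association, signed by the regression beta
#' (positive/negative), carrying the cis/trans class; gene nodes are flagged
#' when present in the supplied transcription-factor list.
#'
#' @param eqtl eQTL records restricted to tag SNPs (snp_id, gene_id, beta,
#'   class).
#' @param tag_snps character vector of tag-SNP ids from [ld_prune()].
#' @param tf_list character vector of TF gene ids (may be empty).
#' @return an [igraph::igraph] of class `regulation_network`; SNP nodes have
#'   `type = "snp"`, genes `type = "gene"` with `is_tf`.
#' @export
build_network <- function(eqtl, tag_snps, tf_list = character()) {
  bad <- setdiff(unique(eqtl$snp_id), tag_snps)
  if (length(bad) > 0)
    stop("edge references pruned-away SNP(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  eqtl <- eqtl[eqtl$snp_id %in% tag_snps, , drop = FALSE]
  snps <- unique(eqtl$snp_id)
  genes <- unique(eqtl$gene_id)
  nodes <- tibble::tibble(
    name = c(snps, genes),
    type = c(rep("snp", length(snps)), rep("gene", length(genes))),
    is_tf = c(rep(FALSE, length(snps)), genes %in% tf_list))
  edges <- tibble::tibble(
    from = eqtl$snp_id, to = eqtl$gene_id, beta = eqtl$beta,
    class = eqtl$class %||% NA_character_,
    sign = ifelse(eqtl$beta >= 0, "positive", "negative"))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  class(g) <- c("regulation_network", class(g))
  g
}

#' Write / read a regulation network
#'
#' GraphML preserves node and edge attributes exactly; an edge-list TSV
#' (snp, gene, beta, sign, class) is written alongside when `edge_tsv` is
#' given.
#'
#' @param network a `regulation_network`.
#' @param path GraphML output path.
#' @param edge_tsv optional edge-list TSV path.
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path, edge_tsv = NULL) {
  igraph::write_graph(network, path, format = "graphml")
  if (!is.null(edge_tsv)) {
    el <- igraph::as_data_frame(network, what = "edges")
    readr::write_tsv(tibble::as_tibble(el), edge_tsv)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  class(g) <- c("regulation_network", class(g))
  g
}

#' Export windows as BED
#'
#' Converts the 1-based inclusive window span `[index * 1e6 + 1,
#' (index + 1) * 1e6]` to BED's 0-based half-open convention
#' `[index * 1e6, (index + 1) * 1e6)`.
#'
#' @param windows window table (chrom, window_index).
#' @param path output BED path.
#' @param window_bp window width.
#' @return invisibly, the BED tibble (chrom, start, end, name).
#' @export
windows_to_bed <- function(windows, path = NULL, window_bp = 1e6) {
  bed <- tibble::tibble(
    chrom = windows$chrom,
    start = as.integer(windows$window_index * window_bp),
    end = as.integer((windows$window_index + 1) * window_bp),
    name = paste(windows$chrom, windows$window_index, sep = "_"))
  if (!is.null(path))
    readr::write_tsv(bed, path, col_names = FALSE)
  invisible(bed)
}
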