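#' Pipeline run configuration
#'
#' One object wiring every stage: synthetic-data generation (optional),
#' variant QC, expression preparation, the two-stage Bayes GWAS, the eQTL
#' scan, and the integration step. A single global seed is fanned out to the
#' stages through fixed offsets so each stage is independently reproducible.
#'
#' @param out_dir directory for all stage outputs.
#' @param sim a [sim_config()] for synthetic runs, or `NULL` when the input
#'   paths point at real data.
#' @param filter a [filter_params()].
#' @param gwas a [gwas_spec()] (mode is set per stage internally).
#' @param prune a [prune_params()].
#' @param cis_window cis bound in bp.
#' @param fdr_threshold eQTL significance bound.
#' @param window_multiplier fold-over-expectation for relevant windows.
#' @param tf_list character vector of TF gene ids.
#' @param seed global seed.
#' @param paths named list of input paths (vcf, pheno, counts, gene_map,
#'   batches) for non-synthetic runs.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, sim = sim_config(), filter = filter_params(),
                       gwas = gwas_spec(pi = 0.995, n_iter = 4000,
                                        burn_in = 1000),
                       prune = prune_params(), cis_window = 1e6,
                       fdr_threshold = 0.05, window_multiplier = 5,
                       tf_list = character(), seed = 1L, paths = list()) {
  structure(list(out_dir = out_dir, sim = sim, filter = filter, gwas = gwas,
                 prune = prune, cis_window = cis_window,
                 fdr_threshold = fdr_threshold,
                 window_multiplier = window_multiplier, tf_list = tf_list,
                 seed = as.integer(seed), paths = paths),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return a `run_config` (for the reader); invisibly `path` (writer).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    out_dir = y$out_dir,
    sim = if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL,
    filter = do.call(filter_params, y$filter %||% list()),
    gwas = do.call(gwas_spec, y$gwas %||% list()),
    prune = do.call(prune_params, y$prune %||% list()),
    cis_window = y$cis_window %||% 1e6,
    fdr_threshold = y$fdr_threshold %||% 0.05,
    window_multiplier = y$window_multiplier %||% 5,
    tf_list = y$tf_list %||% character(),
    seed = y$seed %||% 1L,
    paths = y$paths %||% list())
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  y <- unclass(cfg)
  if (!is.null(y$sim)) {
    y$sim <- unclass(y$sim)
    # named atomic vectors lose their names in YAML; maps survive
    y$sim$chrom_lengths <- as.list(y$sim$chrom_lengths)
  }
  y$filter <- unclass(y$filter)
  y$gwas <- unclass(y$gwas)
  y$prune <- unclass(y$prune)
  yaml::write_yaml(y, path)
  invisible(path)
}

stage_seed <- function(cfg, index)
  as.integer((as.numeric(cfg$seed) * 131 + index) %% 2147483647)

#' Run the integrative pipeline
#'
#' Orchestrates fixture generation, variant QC, expression preparation, the
#' Bayes C then Bayes B GWAS, the eQTL scan with class-wise FDR, and the
#' QTL/eQTL intersection with LD pruning and network export. Each stage
#' writes its outputs under `cfg$out_dir` and an entry into the JSON
#' manifest (parameters, input md5 hashes, row counts, wall clock).
#'
#' @param cfg a [run_config()].
#' @param stages subset of
#'   `c("synthetic", "qc", "expr", "gwas", "eqtl", "integrate")`.
#' @return the manifest, invisibly; also written to
#'   `file.path(cfg$out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(cfg, stages = c("synthetic", "qc", "expr", "gwas",
                                         "eqtl", "integrate")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list())
  state <- new.env(parent = emptyenv())
  note <- function(stage, outputs, info = list()) {
    files <- unlist(outputs)
    manifest$stages[[stage]] <<- c(list(
      outputs = as.list(files),
      md5 = as.list(unname(tools::md5sum(files[file.exists(files)]))),
      elapsed_s = round(as.numeric(Sys.time()) - state$t0, 2)), info)
  }

  if ("synthetic" %in% stages) {
    state$t0 <- as.numeric(Sys.time())
    sim_cfg <- cfg$sim
    if (is.null(sim_cfg)) stop("synthetic stage requires cfg$sim", call. = FALSE)
    sim_cfg$seed <- stage_seed(cfg, 1L)
    state$geno <- simulate_genotypes(sim_cfg)
    state$pheno <- simulate_phenotype(state$geno, sim_cfg)
    state$expr <- simulate_expression(state$geno, sim_cfg,
                                      qtl_snps = state$pheno$truth$qtl_snps$snp_id)
    paths <- write_fixtures(list(geno = state$geno, pheno = state$pheno,
                                 expr = state$expr),
                            file.path(cfg$out_dir, "fixtures"))
    cfg$paths <- as.list(paths)
    note("synthetic", paths, list(n_samples = nrow(state$geno$geno),
                                  n_snps = ncol(state$geno$geno)))
  }

  load_geno <- function() {
    state$geno %||% {
      if (is.null(cfg$paths$vcf)) stop("missing upstream artifact: run the ",
                                       "synthetic (or qc) stage first, or ",
                                       "set paths$vcf", call. = FALSE)
      read_vcf_genotypes(cfg$paths$vcf)
    }
  }
  load_pheno <- function() {
    if (!is.null(state$pheno)) state$pheno$pheno
    else readr::read_tsv(cfg$paths$pheno, show_col_types = FALSE)
  }

  if ("qc" %in% stages) {
    state$t0 <- as.numeric(Sys.time())
    fv <- filter_variants(load_geno(), cfg$filter)
    state$geno <- fv$vcf
    tally_path <- file.path(cfg$out_dir, "qc_tally.json")
    jsonlite::write_json(fv$tally, tally_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    note("qc", tally_path,
         list(n_kept = ncol(fv$vcf$geno)))
  }

  if ("expr" %in% stages) {
    state$t0 <- as.numeric(Sys.time())
    counts <- if (!is.null(state$expr)) state$expr$counts else {
      df <- readr::read_tsv(cfg$paths$counts, show_col_types = FALSE)
      m <- as.matrix(df[, -1]); rownames(m) <- df[[1]]; m
    }
    lcpm <- log2_transform(cpm_normalize(counts))
    fg <- filter_genes(lcpm)
    batches <- if (!is.null(state$expr)) state$expr$batches
               else if (!is.null(cfg$paths$batches))
                 readr::read_tsv(cfg$paths$batches, show_col_types = FALSE)
    x <- fg$matrix
    if (!is.null(batches)) x <- center_batches(x, batches)
    state$lcpm <- x
    out <- file.path(cfg$out_dir, "log2cpm_filtered.tsv")
    readr::write_tsv(tibble::as_tibble(x, rownames = "gene_id"), out)
    note("expr", out, list(n_genes_kept = nrow(x)))
  }

  if ("gwas" %in% stages) {
    state$t0 <- as.numeric(Sys.time())
    geno <- load_geno(); pheno <- load_pheno()
    cspec <- cfg$gwas; cspec$mode <- "bayesC"
    cspec$seed <- stage_seed(cfg, 2L); class(cspec) <- "gwas_spec"
    priors <- run_bayes_c(geno, pheno, cspec)
    bspec <- cfg$gwas; bspec$mode <- "bayesB"
    bspec$seed <- stage_seed(cfg, 3L); class(bspec) <- "gwas_spec"
    fit <- run_bayes_b(geno, pheno, bspec, priors = priors)
    windows <- call_relevant_windows(fit$window_table,
                                    cfg$window_multiplier)
    state$fit <- fit; state$windows <- windows
    wpath <- file.path(cfg$out_dir, "windows.tsv")
    manhattan_window_report(windows, wpath)
    epath <- file.path(cfg$out_dir, "snp_effects.tsv")
    readr::write_tsv(tidy(fit), epath)
    vpath <- file.path(cfg$out_dir, "variance_chains.tsv")
    readr::write_tsv(tibble::tibble(sigma2_g = fit$sigma2_g_samples,
                                    sigma2_e = fit$sigma2_e_samples), vpath)
    note("gwas", c(wpath, epath, vpath),
         list(h2 = fit$h2_posterior_mean,
              n_relevant = sum(windows$relevant),
              threshold_pct = attr(windows, "threshold_pct")))
  }

  if ("eqtl" %in% stages) {
    state$t0 <- as.numeric(Sys.time())
    if (is.null(state$lcpm)) stop("missing upstream artifact: run the expr ",
                                  "stage first", call. = FALSE)
    geno <- load_geno(); pheno <- load_pheno()
    gene_map <- if (!is.null(state$expr)) state$expr$gene_map
                else readr::read_tsv(cfg$paths$gene_map, show_col_types = FALSE)
    state$gene_map <- gene_map
    covs <- pheno[, intersect("group", names(pheno)), drop = FALSE]
    covs$sample_id <- pheno$sample_id
    recs <- scan_eqtl(geno, state$lcpm, covariates = covs,
                      gene_map = gene_map, cis_window = cfg$cis_window) |>
      bh_fdr(cfg$fdr_threshold)
    state$eqtl <- recs
    sig <- dplyr::filter(recs, .data$significant)
    p1 <- file.path(cfg$out_dir, "eqtl_all.tsv")
    p2 <- file.path(cfg$out_dir, "eqtl_significant.tsv")
    readr::write_tsv(recs, p1); readr::write_tsv(sig, p2)
    note("eqtl", c(p1, p2),
         list(n_tests = nrow(recs), n_significant = nrow(sig),
              n_cis = sum(sig$class == "cis"),
              n_trans = sum(sig$class == "trans")))
  }

  if ("integrate" %in% stages) {
    state$t0 <- as.numeric(Sys.time())
    if (is.null(state$windows) || is.null(state$eqtl))
      stop("missing upstream artifact: run the gwas and eqtl stages first",
           call. = FALSE)
    geno <- load_geno()
    sig <- dplyr::filter(state$eqtl, .data$significant)
    rel <- dplyr::filter(state$windows, .data$relevant)
    ov <- intersect_eqtl_qtl(sig, rel, geno$map)
    cand <- unique(ov$eqtl$snp_id)
    idx <- match(cand, geno$map$snp_id)
    sub <- list(map = geno$map[idx, , drop = FALSE],
                geno = geno$geno[, idx, drop = FALSE])
    pruned <- ld_prune(sub, cfg$prune)
    net_eqtl <- dplyr::filter(ov$eqtl, .data$snp_id %in% pruned$tags)
    net <- build_network(net_eqtl, pruned$tags, cfg$tf_list)
    gpath <- file.path(cfg$out_dir, "network.graphml")
    tpath <- file.path(cfg$out_dir, "network_edges.tsv")
    write_network(net, gpath, tpath)
    bpath <- file.path(cfg$out_dir, "relevant_windows.bed")
    windows_to_bed(rel, bpath)
    jpath <- file.path(cfg$out_dir, "integration_tallies.json")
    jsonlite::write_json(list(window_tally = ov$window_tally,
                              snp_classes = ov$snp_classes),
                         jpath, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    note("integrate", c(gpath, tpath, bpath, jpath),
         list(n_candidate = length(cand), n_tags = length(pruned$tags),
              n_edges = nrow(net_eqtl)))
  }

  mpath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
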