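#' Variant QC parameters
#'
#' Defaults mirror a standard bovine SNP QC: site quality `QUAL >= 30`, total
#' depth `DP > 10` (strict), call rate `>= 0.95`, `MAF >= 0.05`, autosomes
#' only (1..29 for cattle), biallelic only.
#'
#' @param qual_min minimum phred site quality (inclusive).
#' @param dp_min minimum total INFO depth (strict `>`).
#' @param callrate_min minimum fraction of non-missing genotypes (inclusive).
#' @param maf_min minimum minor allele frequency (inclusive).
#' @param autosomes character vector of chromosome labels to keep.
#' @param biallelic_only drop records with more than one ALT allele.
#' @return a `filter_params` list.
#' @export
filter_params <- function(qual_min = 30, dp_min = 10, callrate_min = 0.95,
                          maf_min = 0.05, autosomes = as.character(1:29),
                          biallelic_only = TRUE) {
  stopifnot(callrate_min >= 0, callrate_min <= 1, maf_min >= 0, maf_min <= 0.5)
  structure(list(qual_min = qual_min, dp_min = dp_min,
                 callrate_min = callrate_min, maf_min = maf_min,
                 autosomes = as.character(autosomes),
                 biallelic_only = isTRUE(biallelic_only)),
            class = "filter_params")
}

#' Read a VCF into a genotype set
#'
#' Parses diploid biallelic GT calls into additive codes `{0, 1, 2, NA}`.
#' Multi-allelic records are kept in the map (so the biallelic filter can
#' count them) with genotypes coded as the count of first-ALT alleles.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return list with `map` (tibble: snp_id, chrom, pos, ref, alt, qual, dp)
#'   and `geno` (samples x SNPs integer matrix).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0("snp_", fix$CHROM[no_id], "_", fix$POS[no_id])
  map <- tibble::tibble(
    snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)), dp = dp)
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- geno_from_gt(gt)
  rownames(geno) <- colnames(gt)
  colnames(geno) <- map$snp_id
  list(map = map, geno = geno)
}

# "0/1", "0|1", "./." etc. -> 0,1,2,NA (count of '1' alleles);
# gt is variants x samples, result is samples x variants
geno_from_gt <- function(gt) {
  x <- sub(":.*", "", as.vector(gt))
  x[is.na(x)] <- "./."
  a1 <- substr(x, 1, 1); a2 <- substr(x, 3, 3)
  bad <- a1 == "." | a2 == "." | a2 == ""
  out <- (a1 == "1") + (a2 == "1")
  out[bad] <- NA_integer_
  malformed <- !bad & (!(a1 %in% c("0", "1", "2")) | !(a2 %in% c("0", "1", "2")))
  if (any(malformed))
    stop("malformed genotype field: ", x[which(malformed)[1]], call. = FALSE)
  t(matrix(out, nrow(gt), ncol(gt)))
}

#' Write a genotype set as VCF v4.2
#'
#' Plain-text writer (GT field only, 1-based positions) for simulated or
#' merged genotype sets.
#'
#' @param g list with `map` and `geno` as from [read_vcf_genotypes()] or
#'   [simulate_genotypes()].
#' @param path output path.
#' @param qual,dp optional per-site QUAL / INFO DP vectors (taken from the
#'   map when present).
#' @return invisibly, `path`.
#' @export
write_vcf_genotypes <- function(g, path, qual = NULL, dp = NULL) {
  map <- g$map
  qual <- qual %||% map[["qual"]] %||% rep(100, nrow(map))
  dp <- dp %||% map[["dp"]] %||% rep(100L, nrow(map))
  ref <- map[["ref"]] %||% rep("A", nrow(map))
  alt <- map[["alt"]] %||% rep("G", nrow(map))
  gt <- matrix("./.", nrow(map), nrow(g$geno))
  gcode <- t(g$geno)  # snps x samples
  gt[!is.na(gcode) & gcode == 0L] <- "0/0"
  gt[!is.na(gcode) & gcode == 1L] <- "0/1"
  gt[!is.na(gcode) & gcode == 2L] <- "1/1"
  body <- paste(map$chrom, map$pos, map$snp_id, ref, alt, qual, ".",
                paste0("DP=", dp), "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total Depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(g$geno)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Apply variant QC filters
#'
#' A record survives iff (when `apply_site_quality`) `qual >= qual_min` and
#' `dp > dp_min`, and call rate `>= callrate_min`, `MAF >= maf_min`,
#' chromosome in `autosomes`, and biallelic. The tally attributes each
#' removed record to the FIRST criterion it fails, in that order.
#'
#' @param vcf genotype set from [read_vcf_genotypes()].
#' @param params a [filter_params()].
#' @param apply_site_quality apply the QUAL / DP site filters (only sensible
#'   for call-set VCFs that carry them).
#' @return list with `vcf` (filtered set) and `tally` (tibble:
#'   criterion, n_removed, plus `kept` and `input` rows).
#' @export
filter_variants <- function(vcf, params = filter_params(),
                            apply_site_quality = FALSE) {
  map <- vcf$map
  geno <- vcf$geno
  n <- nrow(map)
  fail <- rep(NA_character_, n)
  mark <- function(bad, label) {
    newly <- bad & is.na(fail)
    fail[newly] <<- label
  }
  if (apply_site_quality) {
    if (anyNA(map$qual))
      stop("non-numeric QUAL at ", map$snp_id[which(is.na(map$qual))[1]],
           call. = FALSE)
    mark(map$qual < params$qual_min, "qual")
    mark(is.na(map$dp) | map$dp <= params$dp_min, "dp")
  }
  callrate <- colMeans(!is.na(geno))
  mark(callrate < params$callrate_min, "callrate")
  af <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  mark(maf < params$maf_min, "maf")
  mark(!(map$chrom %in% params$autosomes), "autosome")
  if (params$biallelic_only)
    mark(grepl(",", map[["alt"]] %||% rep("G", n)), "biallelic")

  keep <- is.na(fail)
  crit <- c(if (apply_site_quality) c("qual", "dp"),
            "callrate", "maf", "autosome",
            if (params$biallelic_only) "biallelic")
  tally <- tibble::tibble(
    criterion = c(crit, "kept", "input"),
    n = c(vapply(crit, function(k) sum(fail == k, na.rm = TRUE), 0L),
          sum(keep), n))
  list(vcf = list(map = map[keep, , drop = FALSE],
                  geno = geno[, keep, drop = FALSE]),
       tally = tally)
}

#' Genotype concordance between two call sets
#'
#' Proportion of exactly matching additive genotype codes over pairs where
#' both calls are non-missing; `NA` when no comparable pair exists.
#' Symmetric in its arguments.
#'
#' @param a,b numeric vectors (or matrices of equal shape) of codes
#'   `{0, 1, 2, NA}` in the same sample order.
#' @return proportion in `[0, 1]`, or `NA` if nothing is comparable.
#' @export
genotype_concordance <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  mean(a[ok] == b[ok])
}

#' Merge a genotype panel with transcribed variants by position
#'
#' Keys on (chrom, pos) only: transcribed variants at a position already in
#' the panel are dropped (the panel call is retained), after computing
#' genotype concordance at the overlap. Alleles at overlaps are harmonized by
#' direct REF/ALT match or by swap (genotypes flipped `g -> 2 - g`);
#' unmatched allele pairs are excluded from the concordance denominator and
#' counted.
#'
#' @param panel,transcribed genotype sets (`map` + `geno`); `geno` may be
#'   `NULL` for position-only bookkeeping (concordance is then `NA`).
#' @return list with `merged` (map + geno, sorted by chrom then pos) and
#'   `report` (tibble: n_panel, n_transcribed, n_overlap_positions,
#'   n_unique_transcribed, n_merged, n_allele_mismatch, concordance).
#' @export
merge_snp_sets <- function(panel, transcribed) {
  key <- function(m) paste(m$chrom, m$pos, sep = ":")
  kp <- key(panel$map); kt <- key(transcribed$map)
  if (anyDuplicated(kp))
    stop("duplicate positions in panel: ",
         paste(utils::head(kp[duplicated(kp)], 5), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(kt))
    stop("duplicate positions in transcribed set: ",
         paste(utils::head(kt[duplicated(kt)], 5), collapse = ", "),
         call. = FALSE)
  overlap <- kt %in% kp
  n_overlap <- sum(overlap)

  concordance <- NA_real_
  n_mismatch <- 0L
  if (n_overlap > 0 && !is.null(panel$geno) && !is.null(transcribed$geno)) {
    samples <- intersect(rownames(panel$geno), rownames(transcribed$geno))
    if (length(samples) < nrow(panel$geno) ||
        length(samples) < nrow(transcribed$geno))
      warning("sample rosters differ; concordance computed on the intersection")
    ip <- match(kt[overlap], kp)
    it <- which(overlap)
    p_ref <- panel$map[["ref"]]; p_alt <- panel$map[["alt"]]
    t_ref <- transcribed$map[["ref"]]; t_alt <- transcribed$map[["alt"]]
    have_alleles <- !is.null(p_ref) && !is.null(t_ref)
    matches <- 0; comparable <- 0
    for (k in seq_len(n_overlap)) {
      gp <- panel$geno[samples, ip[k]]
      gt <- transcribed$geno[samples, it[k]]
      if (have_alleles) {
        pr <- p_ref[ip[k]]; pa <- p_alt[ip[k]]
        tr <- t_ref[it[k]]; ta <- t_alt[it[k]]
        if (identical(pr, tr) && identical(pa, ta)) {
          # direct match
        } else if (identical(pr, ta) && identical(pa, tr)) {
          gt <- 2L - gt  # swapped ref/alt
        } else {
          n_mismatch <- n_mismatch + 1L
          next
        }
      }
      ok <- !is.na(gp) & !is.na(gt)
      matches <- matches + sum(gp[ok] == gt[ok])
      comparable <- comparable + sum(ok)
    }
    concordance <- if (comparable > 0) matches / comparable else NA_real_
  }

  uniq <- transcribed$map[!overlap, , drop = FALSE]
  merged_map <- dplyr::bind_rows(panel$map, uniq)
  ord <- order(merged_map$chrom, merged_map$pos)
  merged_map <- merged_map[ord, , drop = FALSE]
  merged_geno <- NULL
  if (!is.null(panel$geno) && !is.null(transcribed$geno)) {
    samples <- intersect(rownames(panel$geno), rownames(transcribed$geno))
    merged_geno <- cbind(panel$geno[samples, , drop = FALSE],
                         transcribed$geno[samples, !overlap, drop = FALSE])
    merged_geno <- merged_geno[, ord, drop = FALSE]
  }
  report <- tibble::tibble(
    n_panel = nrow(panel$map),
    n_transcribed = nrow(transcribed$map),
    n_overlap_positions = n_overlap,
    n_unique_transcribed = nrow(transcribed$map) - n_overlap,
    n_merged = nrow(merged_map),
    n_allele_mismatch = n_mismatch,
    concordance = concordance)
  list(merged = list(map = merged_map, geno = merged_geno), report = report)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
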