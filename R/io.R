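# Format readers/writers binding the modules into a runnable tool: VCF and
# PLINK-style transposed text genotypes, phenotype TSV, scan-result TSV,
# and cohort alignment by sample id.

#' Read genotypes from a VCF file
#'
#' Biallelic records are exposed as ALT-allele dosage vectors (use
#' [orient_minor()] or the scan functions, which orient internally, for
#' minor-allele dosage).  Multiallelic records are skipped with a warning
#' count; missing or half-missing GT fields become `NA`; phased (`|`) and
#' unphased (`/`) separators are both accepted and phase is ignored.
#'
#' @param path VCF file (plain or bgzipped).
#' @return list with `G` (sample-by-SNP dosage matrix, sample ids as row
#'   names), `map` (data frame `chrom`, `pos`, `id`) and `n_skipped`
#'   multiallelic records.
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_skipped <- sum(multi)
  if (n_skipped > 0)
    warning(n_skipped, " multiallelic record(s) skipped", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(rownames(gt), names(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (nrow(fix) == 0) stop("no biallelic records in ", path, call. = FALSE)
  alleles <- gsub("|", "/", gt, fixed = TRUE)
  lookup <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  vals <- unname(lookup[alleles])          # anything else (./., .) -> NA
  dim(vals) <- dim(alleles)
  G <- t(vals)
  dimnames(G) <- list(colnames(gt), fix[, "ID"])
  map <- data.frame(chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    id = fix[, "ID"], stringsAsFactors = FALSE)
  list(G = G, map = map, n_skipped = n_skipped)
}

#' Write a dosage matrix as a plain-text VCF
#'
#' Inverse of [read_vcf_genotypes()] for synthetic data: each dosage (0, 1,
#' 2, `NA`) becomes an unphased GT (`0/0`, `0/1`, `1/1`, `./.`) with REF `A`
#' and ALT `T`.
#'
#' @param G sample-by-SNP dosage matrix.
#' @param map data frame with `chrom`, `pos`, `id` per SNP.
#' @param ids sample identifiers (default `G`'s row names or `S1..Sn`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, map, path, ids = NULL) {
  if (is.null(ids)) ids <- rownames(G)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(G)))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(ncol(G)), function(j) {
    gts <- ifelse(is.na(G[, j]), "./.", gt_code[as.character(G[, j])])
    paste(c(map$chrom[j], map$pos[j], map$id[j], "A", "T", ".", "PASS",
            ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read genotypes from PLINK-style transposed text
#'
#' Expects a `.tped`-style file (chrom, id, genetic distance, position,
#' then two allele columns per sample) and a `.tfam`-style file whose
#' second column holds the sample ids.  Alleles are recoded to dosage of
#' the per-SNP minor allele; `0` codes a missing allele.
#'
#' @param tped,tfam file paths.
#' @return as [read_vcf_genotypes()].
#' @export
read_tped_genotypes <- function(tped, tfam) {
  fam <- utils::read.table(tfam, header = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(fam[[2]])
  tp <- utils::read.table(tped, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tp) != 4 + 2 * length(ids))
    stop("tped column count does not match tfam sample count", call. = FALSE)
  n <- length(ids); m <- nrow(tp)
  G <- matrix(NA_real_, n, m, dimnames = list(ids, as.character(tp[[2]])))
  for (j in seq_len(m)) {
    a1 <- as.character(unlist(tp[j, 4 + 2 * seq_len(n) - 1]))
    a2 <- as.character(unlist(tp[j, 4 + 2 * seq_len(n)]))
    miss <- a1 == "0" | a2 == "0"
    al <- c(a1[!miss], a2[!miss])
    lv <- names(sort(table(al)))             # minor allele first
    if (length(lv) > 2)
      stop("more than two alleles at row ", j, " of ", tped, call. = FALSE)
    minor <- lv[1]
    G[, j] <- ifelse(miss, NA_real_,
                     (a1 == minor) + (a2 == minor))
  }
  map <- data.frame(chrom = as.character(tp[[1]]), pos = as.integer(tp[[4]]),
                    id = as.character(tp[[2]]), stringsAsFactors = FALSE)
  list(G = G, map = map, n_skipped = 0L)
}

#' Read a binary phenotype table
#'
#' Two-column tab-separated file with a header: sample id and status
#' (0 = control, 1 = case, `NA` allowed).  Duplicate ids and non-binary
#' status values are errors naming the offending row.
#'
#' @param path TSV file.
#' @return named numeric vector of statuses keyed by sample id.
#' @export
read_phenotype <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (nrow(ph) == 0) stop("phenotype file has no data rows", call. = FALSE)
  if (ncol(ph) < 2) stop("phenotype file needs id and status columns",
                         call. = FALSE)
  ids <- as.character(ph[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[duplicated(ids)][1], call. = FALSE)
  status <- suppressWarnings(as.numeric(ph[[2]]))
  bad <- which(!is.na(ph[[2]]) & (is.na(status) | !(status %in% c(0, 1))))
  if (length(bad))
    stop("non-binary status at row ", bad[1], ": '", ph[[2]][bad[1]], "'",
         call. = FALSE)
  n_na <- sum(is.na(status))
  if (n_na > 0) message(n_na, " sample(s) with missing phenotype")
  stats::setNames(status, ids)
}

#' Align genotypes and phenotype by sample id
#'
#' @param geno list with `G` and `map` as returned by the readers.
#' @param pheno named status vector from [read_phenotype()].
#' @return list `G`, `map`, `y`, `ids` restricted to the shared samples, in
#'   the genotype file's order.
#' @export
align_cohort <- function(geno, pheno) {
  ids <- rownames(geno$G)
  if (is.null(ids)) stop("genotype matrix has no sample ids", call. = FALSE)
  common <- intersect(ids, names(pheno))
  if (!length(common)) stop("no shared sample ids", call. = FALSE)
  y <- unname(pheno[common])
  if (sum(y == 1, na.rm = TRUE) == 0 || sum(y == 0, na.rm = TRUE) == 0)
    stop("need at least one case and one control", call. = FALSE)
  list(G = geno$G[common, , drop = FALSE], map = geno$map, y = y,
       ids = common)
}

#' Write scan results as TSV
#'
#' @param scan data frame from [sliding_window_scan()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  out <- scan
  out$p_raw <- formatC(out$p_raw, format = "e", digits = 6)
  out$p_bonf <- formatC(out$p_bonf, format = "e", digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate a deterministic small fixture bundle
#'
#' Writes three synthetic datasets (a causal SNP pair with a CH effect, a
#' tagging quartet at a specified r2, and a null region) as plain-text VCF +
#' phenotype TSV, plus a `truth.json` with the generating parameters.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; a fixed seed gives a byte-identical bundle.
#' @param n samples per dataset.
#' @return invisible list of generating truths.
#' @export
make_fixtures <- function(dir, seed = 1, n = 600) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n))
  truth <- list(seed = seed, n = n)

  # (a) causal pair with CH effect
  q <- c(0.06, 0.06); alpha <- 0.08; grr <- 8
  gp <- simulate_hwe_pair(q[1], q[2], n)
  y <- simulate_phenotype_ch(gp$g1, gp$g2, alpha, grr, mode = "causal")
  Ga <- cbind(gp$g1, gp$g2)
  rownames(Ga) <- ids
  mapa <- data.frame(chrom = "1", pos = c(1000L, 2000L),
                     id = c("causal1", "causal2"))
  write_vcf(Ga, mapa, file.path(dir, "causal_pair.vcf"))
  .write_pheno(ids, y, file.path(dir, "causal_pair_pheno.tsv"))
  truth$causal_pair <- list(q = q, alpha = alpha, grr = grr)

  # (b) tagging quartet at a target r2 (feasible for the 0.08/0.10 pair)
  r2 <- 0.5
  hm1 <- haplotypes_for_target_r2(0.08, 0.1, r2)
  hm2 <- haplotypes_for_target_r2(0.08, 0.1, r2)
  qt <- simulate_linked_quartet(hm1, hm2, n)
  yq <- simulate_phenotype_ch(qt$g_causal1, qt$g_causal2, alpha, grr,
                              mode = "causal")
  Gb <- cbind(qt$g_causal1, qt$g_tag1, qt$g_causal2, qt$g_tag2)
  rownames(Gb) <- ids
  mapb <- data.frame(chrom = "1", pos = c(1000L, 1500L, 2000L, 2500L),
                     id = c("causal1", "tag1", "causal2", "tag2"))
  write_vcf(Gb, mapb, file.path(dir, "tagging_quartet.vcf"))
  .write_pheno(ids, yq, file.path(dir, "tagging_quartet_pheno.tsv"))
  truth$tagging_quartet <- list(r2_target = r2, q_causal = 0.08,
                                q_tag = 0.1, alpha = alpha, grr = grr)

  # (c) null region: genotypes without phenotype effect
  rm0 <- region_model(m = 30, portion_causal = 0, grr = 1, rare_frac = 0.4)
  reg <- simulate_region(rm0, n)
  rownames(reg$G) <- ids
  write_vcf(reg$G, reg$map, file.path(dir, "null_region.vcf"))
  .write_pheno(ids, reg$y, file.path(dir, "null_region_pheno.tsv"))
  truth$null_region <- list(m = 30, grr = 1)

  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

.write_pheno <- function(ids, y, path) {
  utils::write.table(data.frame(sample_id = ids, status = y),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
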