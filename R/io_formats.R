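#' Read GWAS summary statistics
#'
#' Expects a tab-delimited table with header columns SNP, CHR, BP, A1, A2,
#' BETA, SE, P, N (order free). Common synonyms are resolved through an
#' alias map: MARKERNAME/RSID -> SNP, CHROM -> CHR, POS -> BP,
#' EFFECT_ALLELE -> A1, OTHER_ALLELE -> A2, EFFECT/B -> BETA, OR -> BETA
#' (log-transformed on read), STDERR -> SE, PVAL/PVALUE -> P. Gzip input is
#' handled transparently. Lines starting with `##` before the header carry
#' trait metadata (`##trait=...` and `##h2_zscore=...`).
#'
#' @param path file path (plain or .gz).
#' @return `sumstats` data.frame with attributes `trait` and `h2_zscore`
#'   (NA if absent).
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "r")  # file() decompresses gz transparently
  on.exit(close(con))
  meta <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("empty summary-statistics file: ", path)
    if (startsWith(ln, "##")) meta <- c(meta, ln) else break
  }
  header <- strsplit(ln, "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(con, sep = "\t", col.names = header,
                          colClasses = NA, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  names(df) <- .resolve_sumstats_names(names(df))
  needed <- c("SNP", "CHR", "BP", "A1", "A2", "SE", "P", "N")
  if ("OR" %in% names(df) && !"BETA" %in% names(df)) {
    df$BETA <- log(df$OR)
    df$OR <- NULL
  }
  missing_cols <- setdiff(c(needed, "BETA"), names(df))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N")]
  df$CHR <- as.character(df$CHR)
  .validate_sumstats(df)
  tr <- sub("^##trait=", "", grep("^##trait=", meta, value = TRUE))
  hz <- sub("^##h2_zscore=", "", grep("^##h2_zscore=", meta, value = TRUE))
  attr(df, "trait") <- if (length(tr)) tr[1] else NA_character_
  attr(df, "h2_zscore") <- if (length(hz)) as.numeric(hz[1]) else NA_real_
  class(df) <- c("sumstats", "data.frame")
  df
}

.resolve_sumstats_names <- function(nm) {
  alias <- c(MARKERNAME = "SNP", RSID = "SNP", ID = "SNP",
             CHROM = "CHR", CHROMOSOME = "CHR",
             POS = "BP", POSITION = "BP",
             EFFECT_ALLELE = "A1", OTHER_ALLELE = "A2", REF = "A2", ALT = "A1",
             EFFECT = "BETA", B = "BETA",
             STDERR = "SE", STDERR_BETA = "SE",
             PVAL = "P", PVALUE = "P", P_VALUE = "P",
             NTOTAL = "N", N_TOTAL = "N")
  up <- toupper(nm)
  ifelse(up %in% names(alias), alias[up], up)
}

.validate_sumstats <- function(df) {
  bad_allele <- !(df$A1 %in% c("A", "C", "G", "T")) |
    !(df$A2 %in% c("A", "C", "G", "T"))
  if (any(bad_allele))
    stop("invalid allele code for variant(s): ",
         paste(utils::head(df$SNP[bad_allele], 10), collapse = ", "),
         " (line ", paste(utils::head(which(bad_allele), 10), collapse = ","), ")")
  bad_p <- !is.finite(df$P) | df$P <= 0 | df$P > 1
  if (any(bad_p))
    stop("p-value outside (0,1] for variant(s): ",
         paste(utils::head(df$SNP[bad_p], 10), collapse = ", "))
  bad_se <- !is.finite(df$SE) | df$SE <= 0
  if (any(bad_se))
    stop("non-positive standard error for variant(s): ",
         paste(utils::head(df$SNP[bad_se], 10), collapse = ", "))
  invisible(df)
}

#' Write GWAS summary statistics
#'
#' Tab-delimited with header SNP, CHR, BP, A1, A2, BETA, SE, P, N, preceded
#' by `##trait=` / `##h2_zscore=` metadata lines when present. A `.gz`
#' suffix triggers gzip compression.
#'
#' @param stats a `sumstats` data.frame.
#' @param path destination path.
#' @export
write_sumstats <- function(stats, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (!is.null(attr(stats, "trait")) && !is.na(attr(stats, "trait")))
    writeLines(paste0("##trait=", attr(stats, "trait")), con)
  hz <- attr(stats, "h2_zscore")
  if (!is.null(hz) && !is.na(hz))
    writeLines(paste0("##h2_zscore=", format(hz, digits = 15)), con)
  cols <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N")
  writeLines(paste(cols, collapse = "\t"), con)
  utils::write.table(format(as.data.frame(stats)[, cols], digits = 15,
                            trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Filter GWAS traits on heritability z-score
#'
#' Keeps traits whose LD-score heritability z exceeds `z_min` (strictly;
#' a boundary z is excluded) and whose mandatory columns are complete.
#' Traits lacking the metadata are excluded and counted in a message.
#'
#' @param traits list of `sumstats` objects.
#' @param z_min threshold (default 5).
#' @return the retained sublist, input order preserved.
#' @export
select_gwas <- function(traits, z_min = 5) {
  if (length(traits) == 0) return(traits)
  keep <- vapply(traits, function(tr) {
    z <- attr(tr, "h2_zscore")
    ok_meta <- !is.null(z) && !is.na(z) && z > z_min
    ok_cols <- all(c("SNP", "A1", "A2", "BETA", "SE", "P", "N") %in% names(tr)) &&
      !anyNA(tr$BETA) && !anyNA(tr$P)
    ok_meta && ok_cols
  }, logical(1))
  if (any(!keep))
    message(sum(!keep), " trait(s) excluded by h2 z-score/completeness filter")
  traits[keep]
}

#' Write genotypes to a minimal VCF (4.2 subset)
#'
#' One biallelic record per variant with REF = other allele (a2), ALT =
#' effect allele (a1), and per-sample `GT:DS` fields. Integer dosages are
#' emitted as unphased genotypes with matching DS; fractional dosages get
#' `./.` GT and the fractional DS. Missing dosages are `./.` with DS `.`.
#'
#' @param variants variant table (chrom, pos, id, a1, a2).
#' @param genotypes subjects x variants dosage matrix (effect-allele count).
#' @param path destination path.
#' @export
write_vcf <- function(variants, genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">"),
             con)
  samples <- rownames(genotypes)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(genotypes)))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  gt_of <- function(d) {
    if (is.na(d)) return("./.:.")
    if (d %in% 0:2) {
      gt <- c("0/0", "0/1", "1/1")[d + 1]
      paste0(gt, ":", d)
    } else paste0("./.:", format(d, digits = 6))
  }
  lines <- character(nrow(variants))
  for (v in seq_len(nrow(variants))) {
    fields <- vapply(genotypes[, v], gt_of, character(1))
    lines[v] <- paste(c(variants$chrom[v], variants$pos[v], variants$id[v],
                        variants$a2[v], variants$a1[v], ".", "PASS", ".",
                        "GT:DS", fields), collapse = "\t")
  }
  writeLines(lines, con)
}

#' Read genotypes from a VCF (GT or DS)
#'
#' Parsed with vcfR. Dosage is the count of the ALT allele (the effect
#' allele by convention). DS is preferred when present; otherwise GT allele
#' counts are used. Multi-allelic records are skipped with a warning
#' reporting the count. Missing genotypes become NA (mean-imputed later,
#' at scoring time).
#'
#' @param path VCF path.
#' @return list with `variants` (chrom, pos, id, a1 = ALT, a2 = REF) and
#'   `genotypes` (subjects x variants matrix, NA for missing).
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no usable records in VCF")
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = fix[, "ID"],
                         a1 = fix[, "ALT"],  # ALT = effect allele
                         a2 = fix[, "REF"],
                         stringsAsFactors = FALSE)
  fmt <- vcf@gt[, "FORMAT"]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    geno <- t(ds)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    cnt <- function(g) {
      if (is.na(g) || grepl(".", g, fixed = TRUE)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    }
    geno <- t(apply(gt, c(1, 2), cnt))
  }
  colnames(geno) <- variants$id
  list(variants = variants, genotypes = geno)
}

#' Read / write a per-subject cohort table (TSV)
#'
#' @param path TSV path.
#' @return data.frame with one row per subject.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate subject ids in cohort table")
  df
}

#' @rdname read_cohort
#' @param cohort data.frame to write.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
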