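#' Write a cohort as a dosage VCF plus sample table
#'
#' VCFv4.2 with one biallelic record per variant; REF = A2, ALT = A1 (the
#' coded allele), FORMAT `DS` carrying the A1 dosage to 4 decimals
#' (missing = `.`). Imputed variants carry `INFO IMPUTED;R2=<r2>`.
#'
#' @param genotypes a [dosage_matrix()].
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  D <- genotypes$dosages
  samples <- rownames(D)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=loctransfer",
    "##INFO=<ID=IMPUTED,Number=0,Type=Flag,Description=\"Imputed variant\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation r-squared\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"A1 (ALT) allelic dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  info <- ifelse(v$imputed,
                 ifelse(is.na(v$imp_r2), "IMPUTED",
                        sprintf("IMPUTED;R2=%.4f", v$imp_r2)),
                 ".")
  ds <- matrix(sprintf("%.4f", D), nrow = nrow(D))
  ds[is.na(D)] <- "."
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$A2[j], v$A1[j], ".", "PASS",
            info[j], "DS", ds[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a dosage VCF into a dosage matrix
#'
#' Backed by `VariantAnnotation::readVcf`. The per-sample `DS` field is
#' preferred when present; otherwise dosage is the ALT-allele count derived
#' from `GT`. Multi-allelic records are rejected and counted. Positions are
#' 1-based as in the VCF; A1 = ALT (coded allele), A2 = REF.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return A [dosage_matrix()]; attribute `n_multiallelic_skipped` records
#'   dropped records.
#' @export
read_dosage_vcf <- function(path) {
  check_that(file.exists(path), "VCF not found: %s", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt != 1
  n_multi <- sum(multi)
  if (all(multi)) abort("no biallelic records in %s", path)
  keep <- !multi
  geno <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(geno)) {
    D <- geno$DS[keep, , drop = FALSE]
    storage.mode(D) <- "numeric"
  } else if ("GT" %in% names(geno)) {
    gt <- geno$GT[keep, , drop = FALSE]
    D <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    counts <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
                "1|0" = 1, "1/1" = 2, "1|1" = 2)
    D[] <- counts[gt]
  } else {
    abort("VCF %s has neither DS nor GT in FORMAT", path)
  }
  info <- VariantAnnotation::info(vcf)
  imputed <- if ("IMPUTED" %in% names(info)) info$IMPUTED[keep] else
    rep(FALSE, sum(keep))
  imp_r2 <- if ("R2" %in% names(info)) as.numeric(info$R2[keep]) else
    rep(NA_real_, sum(keep))
  variants <- data.frame(
    id = names(rr)[keep],
    chrom = as.character(GenomeInfoDb::seqnames(rr))[keep],
    pos = BiocGenerics::start(rr)[keep],
    A1 = vapply(as.list(alt[keep]), function(x) as.character(x)[1], character(1)),
    A2 = as.character(VariantAnnotation::ref(vcf))[keep],
    imputed = imputed, imp_r2 = imp_r2,
    stringsAsFactors = FALSE
  )
  out <- dosage_matrix(t(D), variants)
  attr(out, "n_multiallelic_skipped") <- n_multi
  out
}

#' Write / read the tab-separated sample table
#'
#' Columns: `id`, `status` (1 = case, 0 = control), `age`, `sex` (M/F),
#' `bmi`, `xhet` (X-heterozygosity proxy).
#'
#' @param samples sample data.frame.
#' @param path TSV path.
#' @return `path` / the sample data.frame.
#' @export
write_sample_table <- function(samples, path) {
  data.table::fwrite(samples, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  check_that(file.exists(path), "sample table not found: %s", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  required <- c("id", "status", "age", "sex", "bmi")
  miss <- setdiff(required, names(df))
  check_that(length(miss) == 0, "sample table missing columns: %s",
             paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df
}

#' Read an index-locus catalog
#'
#' TSV with header columns `SNP, CHR, BP, RISK_ALLELE, REPORTED_OR, PANEL,
#' GENE` (GENE optional annotation). Duplicate SNP ids and unparseable
#' odds ratios are rejected with informative errors.
#'
#' @param path catalog TSV path.
#' @return data.frame of index loci.
#' @export
read_index_catalog <- function(path) {
  check_that(file.exists(path), "index catalog not found: %s", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t",
                                        colClasses = list(character = "SNP")))
  required <- c("SNP", "CHR", "BP", "RISK_ALLELE", "REPORTED_OR", "PANEL")
  miss <- setdiff(required, names(df))
  check_that(length(miss) == 0, "index catalog missing column(s): %s",
             paste(miss, collapse = ", "))
  if (anyDuplicated(df$SNP)) {
    abort("duplicated SNP id(s) in catalog: %s",
          paste(unique(df$SNP[duplicated(df$SNP)]), collapse = ", "))
  }
  or_num <- suppressWarnings(as.numeric(df$REPORTED_OR))
  if (any(is.na(or_num))) {
    abort("unparseable REPORTED_OR at line(s): %s",
          paste(which(is.na(or_num)) + 1L, collapse = ", "))
  }
  df$REPORTED_OR <- or_num
  check_that(all(or_num > 0), "reported OR must be > 0")
  if (is.null(df$GENE)) df$GENE <- NA_character_
  df
}

# Fixed numeric formatting shared by the writers: 4 decimals for
# frequencies/beta/se, scientific with 2 significant digits for p.
fmt4 <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
fmtp <- function(x) ifelse(is.na(x), "NA", sprintf("%.1E", x))

#' Write per-variant association results as TSV
#' @param assoc an [assoc_scan()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assoc_tsv <- function(assoc, path) {
  out <- data.frame(
    SNP = assoc$id, CHR = assoc$chrom, BP = assoc$pos,
    A1 = assoc$A1, A2 = assoc$A2,
    A1_FREQ = fmt4(assoc$a1_freq), BETA = fmt4(assoc$beta),
    SE = fmt4(assoc$se), P = fmtp(assoc$p), N = assoc$n_used,
    CODE = assoc$code, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write haplotype blocks as BED-like text
#'
#' Standard BED convention: 0-based half-open start (`start_bp - 1`),
#' 1-based inclusive end.
#'
#' @param blocks a [gabriel_blocks()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  if (is.null(blocks) || nrow(blocks) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- data.frame(chrom = blocks$chrom, start = blocks$start_bp - 1L,
                    end = blocks$end_bp,
                    name = sprintf("block%03d", seq_len(nrow(blocks))),
                    n_snps = blocks$n_snps, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write transferability calls as TSV
#' @param calls a [transfer_calls()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transfer_tsv <- function(calls, path) {
  out <- data.frame(
    SNP = calls$snp, STATUS = calls$status, INDEX_P = fmtp(calls$index_p),
    CONSISTENT = calls$consistent, BEST_SNP = calls$best_snp,
    BEST_P = fmtp(calls$best_p), P_ADJ = fmtp(calls$p_adj),
    N_EFF = fmt4(calls$n_eff), R2_TO_INDEX = fmt4(calls$r2_to_index),
    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a key: value pipeline configuration file
#'
#' One `key: value` pair per line; `#` comments ignored. Values that parse
#' as numbers become numeric.
#'
#' @param path config path.
#' @return Named list.
#' @export
read_config <- function(path) {
  check_that(file.exists(path), "config not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    check_that(length(kv) == 3, "unparseable config line: %s", ln)
    key <- trimws(kv[2])
    val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
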