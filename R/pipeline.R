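#' Run the full transferability pipeline
#'
#' Stage order: sample QC -> variant QC -> genotype PCA -> dosage
#' association -> per-index-locus LD blocks and effective-tests correction
#' -> exact/local transferability -> block-size fine-mapping -> directional
#' sign-consistency summary. Every stage count (samples/variants in and
#' out) is recorded in a machine-readable run log; the whole run is
#' reproducible from (inputs, seed).
#'
#' @param genotypes study [dosage_matrix()] (true genotypes or dosages), or
#'   a VCF path.
#' @param samples sample table (data.frame or TSV path).
#' @param catalog index-locus catalog (data.frame or TSV path).
#' @param ref_genotypes optional reference-panel [dosage_matrix()] for the
#'   fine-mapping block comparison (e.g. from [panel_genotypes()]).
#' @param thresholds a [qc_thresholds()].
#' @param k_pcs number of genotype PCs used as covariates.
#' @param alpha significance level for transferability.
#' @param r2_min LD eligibility threshold for local calls.
#' @param max_pair_distance_bp Gabriel pair distance cap.
#' @param min_relatedness_variants minimum pruned variants for IBD.
#' @param out_dir optional directory: when given, all artifacts are written
#'   (VCF-free text formats: association TSV, blocks BED, transfer TSV, QC
#'   report TSV, run log JSON).
#' @return list of class `pipeline_result`: `qc_samples`, `qc_variants`,
#'   `assoc`, `lambda_gc`, `blocks`, `ref_blocks`, `calls`, `fine_mapping`,
#'   `sign_consistency`, `log`.
#' @export
run_pipeline <- function(genotypes, samples, catalog, ref_genotypes = NULL,
                         thresholds = qc_thresholds(), k_pcs = 3L,
                         alpha = 0.05, r2_min = 0.3,
                         max_pair_distance_bp = 5e5,
                         min_relatedness_variants = 200L,
                         out_dir = NULL) {
  if (is.character(genotypes)) genotypes <- read_dosage_vcf(genotypes)
  if (is.character(samples)) samples <- read_sample_table(samples)
  if (is.character(catalog)) catalog <- read_index_catalog(catalog)
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("pipeline stage '%s' failed: %s (completed stages: %s)",
            name, conditionMessage(e), paste(names(log), collapse = ", "))
    })
  }

  log$input <- list(n_samples = nrow(genotypes$dosages),
                    n_variants = ncol(genotypes$dosages),
                    n_loci = nrow(catalog))

  sq <- stage("sample_qc", sample_qc(genotypes, samples, thresholds,
                                     min_relatedness_variants))
  g1 <- genotypes[match(sq$retained, sample_ids(genotypes)), ]
  s1 <- samples[match(sq$retained, samples$id), ]
  log$sample_qc <- list(n_in = nrow(genotypes$dosages),
                        n_out = length(sq$retained),
                        excluded = as.list(table(sq$report$samples$reason)))

  vq <- stage("variant_qc", variant_qc(g1, thresholds, s1))
  g2 <- g1[, vq$retained]
  log$variant_qc <- list(n_in = ncol(g1$dosages), n_out = length(vq$retained),
                         excluded = as.list(table(vq$report$variants$reason)))

  pca <- stage("pca", {
    pruned <- ld_prune(g2)
    genotype_pca(g2, pruned, k = k_pcs)
  })
  log$pca <- list(k = k_pcs, eigenvalues = pca$eigenvalues)

  assoc <- stage("association", assoc_scan(g2, s1, pcs = pca$scores))
  lambda <- attr(assoc, "lambda_gc")
  log$association <- list(n_variants = nrow(assoc), lambda_gc = lambda)

  blocks <- stage("blocks", {
    pl <- pair_ld_table(g2, max_pair_distance_bp)
    gabriel_blocks(pl, g2$variants$pos, chrom = g2$variants$chrom[1],
                   variant_ids_ = g2$variants$id)
  })
  log$blocks <- list(n_blocks = nrow(blocks))

  ref_blocks <- NULL
  if (!is.null(ref_genotypes)) {
    ref_blocks <- stage("ref_blocks", {
      pl <- pair_ld_table(ref_genotypes, max_pair_distance_bp)
      gabriel_blocks(pl, ref_genotypes$variants$pos,
                     chrom = ref_genotypes$variants$chrom[1],
                     variant_ids_ = ref_genotypes$variants$id)
    })
    log$ref_blocks <- list(n_blocks = nrow(ref_blocks))
  }

  calls <- stage("transferability",
                 transfer_calls(catalog, assoc, g2, blocks,
                                alpha = alpha, r2_min = r2_min))
  log$transferability <- as.list(table(calls$status))

  fine <- NULL
  if (!is.null(ref_blocks)) {
    fine <- stage("fine_mapping", {
      rows <- lapply(seq_len(nrow(catalog)), function(k) {
        snp <- catalog$SNP[k]
        pos <- assoc$pos[match(snp, assoc$id)]
        if (is.na(pos)) return(NULL)
        cb <- compare_blocks(blocks, ref_blocks, snp, pos, assoc)
        data.frame(snp = snp, study_span = cb$study_span,
                   ref_span = cb$ref_span, fine_mapped = cb$fine_mapped,
                   refined = cb$refined, best_snp = cb$best_snp,
                   best_p = cb$best_p, index_p = cb$index_p,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    log$fine_mapping <- list(n_fine_mapped = sum(fine$fine_mapped))
  }

  tested <- !is.na(calls$consistent)
  sign <- list(n_consistent = sum(calls$consistent[tested]),
               n_tested = sum(tested))
  sign$p <- if (sign$n_tested > 0)
    sign_consistency_test(sign$n_consistent, sign$n_tested) else NA_real_
  log$sign_consistency <- sign

  res <- structure(list(
    qc_samples = sq, qc_variants = vq, assoc = assoc, lambda_gc = lambda,
    blocks = blocks, ref_blocks = ref_blocks, calls = calls,
    fine_mapping = fine, sign_consistency = sign, log = log
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_assoc_tsv(assoc, file.path(out_dir, "association.tsv"))
    write_blocks_bed(blocks, file.path(out_dir, "blocks.bed"))
    write_transfer_tsv(calls, file.path(out_dir, "transfer_calls.tsv"))
    tag_unit <- function(df, unit) {
      if (nrow(df) == 0) {
        return(data.frame(unit = character(), id = character(),
                          reason = character(), stringsAsFactors = FALSE))
      }
      cbind(unit = unit, df)
    }
    qc_all <- rbind(tag_unit(sq$report$samples, "sample"),
                    tag_unit(vq$report$variants, "variant"))
    data.table::fwrite(qc_all, file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE)
    if (!is.null(fine)) {
      data.table::fwrite(fine, file.path(out_dir, "fine_mapping.tsv"),
                         sep = "\t", quote = FALSE, na = "NA")
    }
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  samples retained: %d\n", length(x$qc_samples$retained)))
  cat(sprintf("  variants retained: %d\n", length(x$qc_variants$retained)))
  cat(sprintf("  lambda_GC: %.3f\n", x$lambda_gc))
  cat(sprintf("  blocks: %d\n", nrow(x$blocks)))
  cat(sprintf("  transfer calls: %s\n",
              paste(sprintf("%s=%d", names(table(x$calls$status)),
                            table(x$calls$status)), collapse = " ")))
  cat(sprintf("  sign consistency: %d/%d (p = %.2e)\n",
              x$sign_consistency$n_consistent, x$sign_consistency$n_tested,
              x$sign_consistency$p))
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort as VCF + sample
#' table), `power` (emit a power TSV grid), `run` (full pipeline on a
#' VCF + sample table + catalog). Invoked by the `exec/loctransfer`
#' script; callable directly with an argument vector for testing.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return Exit status, invisibly (0 = success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: loctransfer <simulate|power|run> [options]\n")
    return(invisible(1L))
  }
  sub <- args[1]
  rest <- args[-1]
  if (sub == "power") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
      optparse::make_option("--or-values", type = "character",
                            default = "1.1,1.2,1.3,1.4,1.5"),
      optparse::make_option("--raf-values", type = "character",
                            default = "0.05,0.1,0.2,0.3,0.4"),
      optparse::make_option("--n-cases", type = "integer", default = 1035L),
      optparse::make_option("--n-controls", type = "integer", default = 740L),
      optparse::make_option("--alpha", type = "double", default = 0.05),
      optparse::make_option("--out", type = "character", default = "power.tsv")
    )), args = rest)
    g <- power_grid(as.numeric(strsplit(opts$`or-values`, ",")[[1]]),
                    as.numeric(strsplit(opts$`raf-values`, ",")[[1]]),
                    opts$`n-cases`, opts$`n-controls`, opts$alpha)
    data.table::fwrite(g, opts$out, sep = "\t", quote = FALSE)
    return(invisible(0L))
  }
  if (sub == "simulate") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
      optparse::make_option("--n-cases", type = "integer", default = 250L),
      optparse::make_option("--n-controls", type = "integer", default = 250L),
      optparse::make_option("--n-blocks", type = "integer", default = 10L),
      optparse::make_option("--snps-per-block", type = "integer", default = 10L),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out-prefix", type = "character",
                            default = "cohort")
    )), args = rest)
    panel <- simulate_panel(opts$`n-blocks`, opts$`snps-per-block`,
                            n_haplotypes = 200L, within_block_ld = 0.9,
                            seed = derive_seed(opts$seed, "panel"))
    cfg <- cohort_config(opts$`n-cases`, opts$`n-controls`, seed = opts$seed)
    coh <- simulate_cohort(panel, cfg)
    write_dosage_vcf(coh$genotypes, paste0(opts$`out-prefix`, ".vcf"))
    write_sample_table(coh$samples, paste0(opts$`out-prefix`, ".samples.tsv"))
    return(invisible(0L))
  }
  if (sub == "run") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
      optparse::make_option("--vcf", type = "character"),
      optparse::make_option("--samples", type = "character"),
      optparse::make_option("--catalog", type = "character"),
      optparse::make_option("--out", type = "character", default = "results"),
      optparse::make_option("--alpha", type = "double", default = 0.05),
      optparse::make_option("--k-pcs", type = "integer", default = 3L)
    )), args = rest)
    for (f in c(opts$vcf, opts$samples, opts$catalog)) {
      check_that(!is.null(f) && file.exists(f), "input not found: %s",
                 if (is.null(f)) "(missing argument)" else f)
    }
    run_pipeline(opts$vcf, opts$samples, opts$catalog,
                 alpha = opts$alpha, k_pcs = opts$`k-pcs`,
                 out_dir = opts$out)
    return(invisible(0L))
  }
  cat(sprintf("unknown subcommand: %s\n", sub))
  invisible(1L)
}
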