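read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), ...)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Read the cohort input tables
#'
#' Tab-delimited readers for the four input formats: sample sheet
#' (`patient_id`, `cohort`, `sex`, `purity`, `grade`, `ER`, `PR`,
#' `HER2`), germline variant table (`patient_id`, `gene`, `variant_id`,
#' `variant_type`, `clinvar_class`, `gnomad_faf`, `bayesdel`,
#' `spliceai_max`, `cadd`, `suspicious_vus`, optional `class3`), HR score
#' table (`patient_id`, `chord_prob`, `chord_brca1_prob`,
#' `chord_brca2_prob`, `hrdetect_prob`, `hrdsum_score`) and ASCAT-like
#' segment table (`patient_id`, `chrom`, `start`, `end`, `major`,
#' `minor`).
#'
#' @param path file path.
#' @return data.frame.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
read_sample_sheet <- function(path) {
  x <- read_tsv(path)
  need_cols(x, c("patient_id"), "sample sheet")
  x
}

#' @rdname cohort-io
#' @export
read_variant_table <- function(path) {
  x <- read_tsv(path)
  need_cols(x, c("patient_id", "gene", "variant_id"), "variant table")
  if (!is.null(x$suspicious_vus)) {
    x$suspicious_vus <- as.logical(x$suspicious_vus)
  }
  x
}

#' @rdname cohort-io
#' @export
read_hr_scores <- function(path) {
  x <- read_tsv(path)
  need_cols(x, c("patient_id"), "HR score table")
  x
}

#' @rdname cohort-io
#' @export
read_segments <- function(path) {
  x <- read_tsv(path)
  need_cols(x, c("chrom", "start", "end", "major", "minor"),
            "segment table")
  x
}

#' @rdname cohort-io
#' @export
read_genome_annotation <- function(path) {
  validate_genome(read_tsv(path))
}

need_cols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0) {
    stop(what, " is missing columns: ", paste(miss, collapse = ", "))
  }
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  write_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  write_tsv(cohort$scores, file.path(dir, "hr_scores.tsv"))
  write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Minimal VCF ingestion of pre-annotated germline variants
#'
#' Reads a VCF whose INFO field carries `GENE`, and optionally `CLASS3`
#' (a precomputed P/LP | VUS | B/LB call) and `FAF` (gnomAD filtering
#' allele frequency), into the variant-table layout. Patient identity is
#' taken from the `PID` INFO key when present, else from the single sample
#' column name. Requires the vcfR package.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return variant data.frame as for [read_variant_table()].
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF ingestion requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_of <- function(key) vcfR::extract.info(v, element = key)
  gene <- info_of("GENE")
  class3 <- info_of("CLASS3")
  faf <- suppressWarnings(as.numeric(info_of("FAF")))
  pid <- info_of("PID")
  if (all(is.na(pid))) {
    smp <- colnames(v@gt)
    pid <- rep(if (length(smp) >= 2) smp[2] else "sample1", nrow(fix))
  }
  data.frame(
    patient_id = pid,
    gene = gene,
    variant_id = paste0(fix$CHROM, ":", fix$POS, fix$REF, ">", fix$ALT),
    variant_type = ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1,
                          "SNV", "indel"),
    clinvar_class = NA_character_,
    gnomad_faf = faf,
    bayesdel = NA_real_, spliceai_max = NA_real_, cadd = NA_real_,
    suspicious_vus = FALSE,
    class3 = class3,
    stringsAsFactors = FALSE)
}
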