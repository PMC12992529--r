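PANEL_GENES <- c("BRCA1", "BRCA2", "ATM", "BARD1", "BRIP1", "CHEK2",
                 "PALB2", "PTEN", "RAD51C", "RAD51D", "TP53")
BRCA_GENES <- c("BRCA1", "BRCA2")

#' Curation thresholds
#'
#' @param faf_max gnomAD filtering-allele-frequency cutoff at or above
#'   which a variant is collapsed to benign/likely benign (default 1e-4).
#' @param bayesdel_min,spliceai_min optional score cutoffs above which a
#'   VUS is flagged "suspicious"; both default to NULL (the flag is then
#'   taken from the input column only, since no published cutoffs define
#'   suspicion here).
#' @return list of class `"curation_thresholds"`.
#' @export
curation_thresholds <- function(faf_max = 1e-4, bayesdel_min = NULL,
                                spliceai_min = NULL) {
  structure(list(faf_max = faf_max, bayesdel_min = bayesdel_min,
                 spliceai_min = spliceai_min),
            class = "curation_thresholds")
}

#' Collapse variant annotations into three classes
#'
#' Collapses a variant's annotations to one of P/LP, VUS, or B/LB.
#' Precedence: a gnomAD filtering allele frequency at or above `faf_max`
#' forces B/LB; otherwise a ClinVar P/LP or B/LB assertion is taken as-is;
#' everything else (ClinVar VUS/conflicting, or frequency evidence alone)
#' is VUS. Bioinformatic scores (BayesDel, SpliceAI, CADD) never set the
#' class; at most they set the suspicious-VUS flag. A precomputed `class3`
#' value on the variant bypasses the collapse.
#'
#' @param variant one-row data.frame or list with fields `clinvar_class`,
#'   `gnomad_faf`, and optionally `class3`, `bayesdel`, `spliceai_max`.
#' @param thresholds a [curation_thresholds()].
#' @return one of `"P/LP"`, `"VUS"`, `"B/LB"`.
#' @export
collapse_classification <- function(variant,
                                    thresholds = curation_thresholds()) {
  cls <- variant$class3
  if (!is.null(cls) && length(cls) == 1 && !is.na(cls) && nzchar(cls)) {
    return(match.arg(cls, c("P/LP", "VUS", "B/LB")))
  }
  faf <- variant$gnomad_faf
  cv <- variant$clinvar_class
  has_faf <- !is.null(faf) && length(faf) == 1 && !is.na(faf)
  has_cv <- !is.null(cv) && length(cv) == 1 && !is.na(cv) && cv != "absent"
  if (!has_faf && !has_cv) {
    stop("variant ", variant$variant_id %||% "<unnamed>",
         " has no usable classification annotation")
  }
  if (has_faf && (faf < 0 || faf > 1)) stop("gnomad_faf outside [0,1]")
  if (has_faf && faf >= thresholds$faf_max) return("B/LB")
  if (has_cv) {
    if (cv %in% c("P", "LP")) return("P/LP")
    if (cv %in% c("B", "LB")) return("B/LB")
    return("VUS")  # VUS or conflicting assertions
  }
  "VUS"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign a variant category (A-F)
#'
#' Crosses the collapsed class with the gene set: BRCA1/2 map to A (P/LP),
#' C (VUS), E (B/LB); the other nine panel genes map to B, D, F. A
#' suspicious VUS in a non-BRCA gene is conservatively promoted to B; a
#' suspicious VUS in BRCA1/2 stays C.
#'
#' @param gene panel gene symbol.
#' @param class3 collapsed class (`"P/LP"`, `"VUS"`, `"B/LB"`).
#' @param suspicious_vus logical flag.
#' @return single character, one of `"A"` to `"F"`.
#' @export
assign_category <- function(gene, class3, suspicious_vus = FALSE) {
  if (!gene %in% PANEL_GENES) {
    stop("gene '", gene, "' is outside the 11-gene panel")
  }
  class3 <- match.arg(class3, c("P/LP", "VUS", "B/LB"))
  in_brca <- gene %in% BRCA_GENES
  if (class3 == "P/LP") return(if (in_brca) "A" else "B")
  if (class3 == "B/LB") return(if (in_brca) "E" else "F")
  if (!in_brca && isTRUE(suspicious_vus)) return("B")
  if (in_brca) "C" else "D"
}

#' Assign a patient's germline group from their variant categories
#'
#' Precedence: (1) any category B (other-gene P/LP or suspicious VUS)
#' excludes the patient; (2) an other-gene VUS (D) with no BRCA1/2 P/LP
#' (A) and no BRCA1/2 VUS (C) also excludes; (3) else a BRCA1 P/LP makes
#' the patient BRCA1-positive; (4) else a BRCA2 P/LP makes them
#' BRCA2-positive; (5) else any BRCA1/2 VUS puts them in the VUS group;
#' (6) else they are BRCA1/2-negative. When both BRCA genes carry P/LP
#' variants, BRCA1 wins with a warning. With `sensitivity = TRUE` the
#' exclusion rules (1)-(2) are disabled. With `strict_exclusion = TRUE`,
#' rule (2) ignores the "no A" clause so that an A+D combination is
#' Excluded rather than positive.
#'
#' @param categories character vector of categories for one patient
#'   (possibly empty).
#' @param genes parallel vector of gene symbols (needed to tell BRCA1 from
#'   BRCA2 category-A variants; may be omitted if no "A" present).
#' @param sensitivity disable the exclusion rules?
#' @param strict_exclusion make other-gene VUS exclude even A carriers?
#' @return one of `"BRCA1_POS"`, `"BRCA2_POS"`, `"NEGATIVE"`,
#'   `"EXCLUDED"`, `"BRCA12_VUS"`.
#' @export
assign_group <- function(categories, genes = NULL, sensitivity = FALSE,
                         strict_exclusion = FALSE) {
  if (length(categories) == 0) return("NEGATIVE")
  has <- function(k) any(categories == k)
  if (!sensitivity) {
    if (has("B")) return("EXCLUDED")
    excl_d <- if (strict_exclusion) has("D") && !has("C")
              else has("D") && !has("A") && !has("C")
    if (excl_d) return("EXCLUDED")
  }
  if (has("A")) {
    a_genes <- unique(genes[categories == "A"])
    if (all(c("BRCA1", "BRCA2") %in% a_genes)) {
      warning("patient carries P/LP variants in both BRCA1 and BRCA2; ",
              "assigned BRCA1_POS")
    }
    return(if ("BRCA1" %in% a_genes) "BRCA1_POS" else "BRCA2_POS")
  }
  if (has("C")) return("BRCA12_VUS")
  "NEGATIVE"
}

#' Curate a variant table: classes and categories
#'
#' Vectorised convenience wrapper: collapses each row's class (honouring a
#' `class3` override column) and assigns its category.
#'
#' @param variants variant data.frame with at least `patient_id`, `gene`,
#'   `variant_id`; classification columns as in
#'   [collapse_classification()]; optional logical `suspicious_vus`.
#' @param thresholds a [curation_thresholds()].
#' @return the input with `class3` and `category` columns filled.
#' @export
curate_variants <- function(variants, thresholds = curation_thresholds()) {
  n <- nrow(variants)
  if (is.null(variants$suspicious_vus)) variants$suspicious_vus <- FALSE
  variants$suspicious_vus[is.na(variants$suspicious_vus)] <- FALSE
  # optional score-derived suspicion
  if (!is.null(thresholds$bayesdel_min) && !is.null(variants$bayesdel)) {
    hit <- !is.na(variants$bayesdel) &
      variants$bayesdel >= thresholds$bayesdel_min
    variants$suspicious_vus <- variants$suspicious_vus | hit
  }
  if (!is.null(thresholds$spliceai_min) && !is.null(variants$spliceai_max)) {
    hit <- !is.na(variants$spliceai_max) &
      variants$spliceai_max >= thresholds$spliceai_min
    variants$suspicious_vus <- variants$suspicious_vus | hit
  }
  class3 <- character(n)
  for (i in seq_len(n)) {
    class3[i] <- collapse_classification(variants[i, , drop = FALSE],
                                         thresholds)
  }
  variants$class3 <- class3
  variants$category <- vapply(seq_len(n), function(i) {
    assign_category(variants$gene[i], class3[i],
                    variants$suspicious_vus[i])
  }, character(1))
  variants
}

#' Partition a cohort into the five germline groups
#'
#' Joins the curated variant table to the sample sheet and assigns every
#' patient exactly one group. Patients with no variant rows are
#' BRCA1/2-negative. A variant row whose patient is missing from the
#' sample sheet is a referential-integrity error.
#'
#' @param variants curated variant table (with `category`; see
#'   [curate_variants()]).
#' @param samples sample sheet with a `patient_id` column.
#' @param sensitivity,strict_exclusion passed to [assign_group()].
#' @return list of class `"cohort_partition"`: `$groups` — data.frame with
#'   `patient_id`, `group`, and carrier flags `has_A_BRCA1`/`has_A_BRCA2`
#'   used by the sensitivity reanalysis; `$counts` — named group counts.
#' @export
partition_cohort <- function(variants, samples, sensitivity = FALSE,
                             strict_exclusion = FALSE) {
  ids <- samples$patient_id
  if (anyDuplicated(ids)) stop("duplicate patient_id in sample sheet")
  orphan <- setdiff(unique(variants$patient_id), ids)
  if (length(orphan) > 0) {
    stop("variant rows reference patients absent from the sample sheet: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  idx <- split(seq_len(nrow(variants)), variants$patient_id)
  group <- character(length(ids))
  has_a1 <- logical(length(ids)); has_a2 <- logical(length(ids))
  for (i in seq_along(ids)) {
    rows <- idx[[ids[i]]]
    if (is.null(rows)) {
      group[i] <- "NEGATIVE"
    } else {
      cats <- variants$category[rows]
      genes <- variants$gene[rows]
      group[i] <- assign_group(cats, genes, sensitivity = sensitivity,
                               strict_exclusion = strict_exclusion)
      has_a1[i] <- any(cats == "A" & genes == "BRCA1")
      has_a2[i] <- any(cats == "A" & genes == "BRCA2")
    }
  }
  groups <- data.frame(patient_id = ids, group = group,
                       has_A_BRCA1 = has_a1, has_A_BRCA2 = has_a2,
                       stringsAsFactors = FALSE)
  lev <- c("BRCA1_POS", "BRCA2_POS", "NEGATIVE", "EXCLUDED", "BRCA12_VUS")
  counts <- table(factor(group, levels = lev))
  structure(list(groups = groups,
                 counts = stats::setNames(as.integer(counts), lev)),
            class = "cohort_partition")
}

#' @export
print.cohort_partition <- function(x, ...) {
  cat("Cohort partition (", sum(x$counts), " patients )\n", sep = "")
  print(x$counts)
  invisible(x)
}
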