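# Accept either a cohort_partition or its bare group data.frame.
as_group_table <- function(groups) {
  if (inherits(groups, "cohort_partition")) groups$groups else groups
}

#' Two-group category counts for an HR category
#'
#' Cross-tabulates one HR category (HRP, HRD, or an HRD CHORD subtype)
#' between a case germline group (BRCA1- or BRCA2-positive) and the
#' BRCA1/2-negative control group. Excluded and BRCA1/2-VUS patients are
#' omitted. In subtype categories, HRD patients with an undetermined
#' subtype stay in the denominators but are counted in no subtype category.
#'
#' @param groups data.frame with columns `patient_id`, `group`
#'   (as produced by [partition_cohort()]).
#' @param calls data.frame with columns `patient_id`, `tool`, `status`,
#'   `subtype` (as produced by [call_hr()]).
#' @param case_group `"BRCA1_POS"` or `"BRCA2_POS"`.
#' @param category one of `"HRP"`, `"HRD"`, `"HRD_BRCA1_subtype"`,
#'   `"HRD_BRCA2_subtype"`.
#' @param tool which prediction tool's calls to count (default `"CHORD"`).
#' @return list with fields `category`, `x_case`, `n_case`, `x_ctrl`,
#'   `n_ctrl`.
#' @export
category_counts <- function(groups, calls, case_group, category,
                            tool = "CHORD") {
  groups <- as_group_table(groups)
  case_group <- match.arg(case_group, c("BRCA1_POS", "BRCA2_POS"))
  category <- match.arg(category, c("HRP", "HRD", "HRD_BRCA1_subtype",
                                    "HRD_BRCA2_subtype"))
  calls <- calls[calls$tool == tool & !is.na(calls$status), , drop = FALSE]
  m <- merge(groups[, c("patient_id", "group")],
             calls[, c("patient_id", "status", "subtype")],
             by = "patient_id")
  in_cat <- switch(category,
    HRP = m$status == "HRP",
    HRD = m$status == "HRD",
    HRD_BRCA1_subtype = m$status == "HRD" & m$subtype == "BRCA1_type",
    HRD_BRCA2_subtype = m$status == "HRD" & m$subtype == "BRCA2_type")
  case <- m$group == case_group
  ctrl <- m$group == "NEGATIVE"
  if (!any(case)) {
    stop("empty case group '", case_group, "' after joining HR calls")
  }
  list(category = category,
       x_case = sum(in_cat & case), n_case = sum(case),
       x_ctrl = sum(in_cat & ctrl), n_ctrl = sum(ctrl))
}

#' Likelihood ratio for a tumour feature with a Katz log-scale CI
#'
#' Estimates the ratio of the category proportion in germline-positive
#' cases over BRCA1/2-negative controls, LR = p_case / p_ctrl. When either
#' category count is zero, a Haldane continuity correction adds 0.5 to all
#' four implicit 2x2 cells (both numerators and, twice, both denominators)
#' before estimation. The confidence interval is the Wald interval on the
#' log scale (Katz), exp(log LR +/- z * SE) with
#' SE^2 = (1 - p_case) / (n_case' p_case) + (1 - p_ctrl) / (n_ctrl' p_ctrl),
#' where n' are the corrected denominators.
#'
#' @param counts list as returned by [category_counts()], or the
#'   four counts given separately via `x_case`, `n_case`, `x_ctrl`, `n_ctrl`.
#' @param x_case,n_case,x_ctrl,n_ctrl counts, used when `counts` is NULL.
#' @param z normal quantile for the interval (default 1.96, i.e. 95%).
#' @return object of class `"lr_result"`: list with `lr`, `ci_low`,
#'   `ci_high`, `correction_c` (0 or 0.5), `z`, `p_case`, `p_ctrl`
#'   and the input counts.
#' @examples
#' compute_lr(x_case = 27, n_case = 27, x_ctrl = 35, n_ctrl = 232)
#' @export
compute_lr <- function(counts = NULL, x_case, n_case, x_ctrl, n_ctrl,
                       z = 1.96) {
  if (!is.null(counts)) {
    x_case <- counts$x_case; n_case <- counts$n_case
    x_ctrl <- counts$x_ctrl; n_ctrl <- counts$n_ctrl
  }
  stopifnot(length(x_case) == 1, length(x_ctrl) == 1)
  if (n_case <= 0 || n_ctrl <= 0) stop("group sizes must be positive")
  if (x_case < 0 || x_ctrl < 0 || x_case > n_case || x_ctrl > n_ctrl) {
    stop("counts must satisfy 0 <= x <= n in both groups")
  }
  cc <- if (x_case == 0 || x_ctrl == 0) 0.5 else 0
  p_case <- (x_case + cc) / (n_case + 2 * cc)
  p_ctrl <- (x_ctrl + cc) / (n_ctrl + 2 * cc)
  lr <- p_case / p_ctrl
  se <- sqrt((1 - p_case) / ((n_case + 2 * cc) * p_case) +
             (1 - p_ctrl) / ((n_ctrl + 2 * cc) * p_ctrl))
  structure(list(lr = lr,
                 ci_low = exp(log(lr) - z * se),
                 ci_high = exp(log(lr) + z * se),
                 se_log = se,
                 correction_c = cc, z = z,
                 p_case = p_case, p_ctrl = p_ctrl,
                 x_case = x_case, n_case = n_case,
                 x_ctrl = x_ctrl, n_ctrl = n_ctrl),
            class = "lr_result")
}

#' @export
print.lr_result <- function(x, ...) {
  cat(sprintf("LR %.2f (%.2f, %.2f)%s\n", x$lr, x$ci_low, x$ci_high,
              if (x$correction_c > 0) "  [Haldane 0.5 correction]" else ""))
  invisible(x)
}

#' Evidence mapping configuration
#'
#' Thresholds for the Bayesian conversion of a likelihood ratio to an
#' ACMG/AMP evidence strength. Strength tiers are powers of the odds of
#' pathogenicity equivalent to Very Strong evidence: supporting =
#' odds^(1/8), moderate = odds^(1/4), strong = odds^(1/2), very strong =
#' odds. The benign side uses the reciprocals.
#'
#' @param odds_very_strong odds corresponding to Very Strong evidence
#'   (default 350).
#' @param ci_gate when TRUE (default), an LR whose confidence interval
#'   contains 1 is assigned zero points with label "Not significant".
#' @return list of class `"evidence_config"`.
#' @export
evidence_config <- function(odds_very_strong = 350, ci_gate = TRUE) {
  stopifnot(odds_very_strong > 1)
  structure(list(odds_very_strong = odds_very_strong,
                 thresholds = odds_very_strong ^ c(supporting = 1 / 8,
                                                   moderate = 1 / 4,
                                                   strong = 1 / 2,
                                                   very_strong = 1),
                 points = c(supporting = 1L, moderate = 2L,
                            strong = 4L, very_strong = 8L),
                 ci_gate = ci_gate),
            class = "evidence_config")
}

#' Convert a likelihood ratio to an ACMG/AMP evidence assignment
#'
#' Maps the point estimate through exponentially scaled thresholds
#' (inclusive on the more extreme side): pathogenic Supporting/Moderate/
#' Strong/Very Strong at LR >= 350^(1/8), 350^(1/4), 350^(1/2), 350 with
#' points +1/+2/+4/+8; the benign side is mirrored at the reciprocal
#' thresholds with negative points. An LR between the supporting bounds is
#' "Indeterminate" (0 points). When `ci_gate` is on and the confidence
#' interval contains 1, an LR that would otherwise carry evidence is
#' downgraded to "Not significant" (0 points); an indeterminate LR keeps
#' its "Indeterminate" label.
#'
#' @param result an `lr_result` from [compute_lr()], or a bare positive
#'   number (then no CI gating is possible unless `ci` is given).
#' @param config an [evidence_config()].
#' @param ci optional length-2 numeric CI when `result` is a bare number.
#' @return list of class `"evidence_assignment"` with `strength_label`
#'   and integer `points`.
#' @examples
#' lr_to_evidence(compute_lr(x_case = 27, n_case = 27,
#'                           x_ctrl = 35, n_ctrl = 232))
#' @export
lr_to_evidence <- function(result, config = evidence_config(), ci = NULL) {
  if (inherits(result, "lr_result")) {
    lr <- result$lr
    ci <- c(result$ci_low, result$ci_high)
  } else {
    lr <- as.numeric(result)
  }
  if (!is.finite(lr) || lr <= 0) stop("likelihood ratio must be positive")
  th <- config$thresholds
  pts <- config$points
  tier <- function(v) {
    if (v >= th[["very_strong"]]) "very_strong"
    else if (v >= th[["strong"]]) "strong"
    else if (v >= th[["moderate"]]) "moderate"
    else if (v >= th[["supporting"]]) "supporting"
    else NA_character_
  }
  label_of <- c(supporting = "Supporting", moderate = "Moderate",
                strong = "Strong", very_strong = "Very Strong")
  if (lr >= 1) {
    k <- tier(lr)
    side <- "Pathogenic"
    points <- if (is.na(k)) 0L else pts[[k]]
  } else {
    k <- tier(1 / lr)
    side <- "Benign"
    points <- if (is.na(k)) 0L else -pts[[k]]
  }
  if (is.na(k)) {
    label <- "Indeterminate"
  } else {
    label <- paste(side, label_of[[k]])
  }
  gated <- FALSE
  if (config$ci_gate && !is.null(ci) && !is.na(k)) {
    if (min(ci) <= 1 && max(ci) >= 1) {
      label <- "Not significant"
      points <- 0L
      gated <- TRUE
    }
  }
  structure(list(strength_label = label, points = points, ci_gated = gated),
            class = "evidence_assignment")
}

#' @export
print.evidence_assignment <- function(x, ...) {
  cat(sprintf("%s (%+d)\n", x$strength_label, x$points))
  invisible(x)
}

row_labels <- function(gene, stratified) {
  if (stratified) {
    c("HRP", "HRD BRCA1 subtype", "HRD BRCA2 subtype")
  } else {
    c("HRP", "HRD")
  }
}

category_of_label <- function(label) {
  switch(label,
    "HRP" = "HRP", "HRD" = "HRD",
    "HRD BRCA1 subtype" = "HRD_BRCA1_subtype",
    "HRD BRCA2 subtype" = "HRD_BRCA2_subtype")
}

#' Calibrate HR status as germline BRCA1/2 variant evidence
#'
#' The central fitting function. For each gene (BRCA1 and BRCA2) it
#' compares HR-category proportions between the germline-positive group and
#' the BRCA1/2-negative control group, estimates a Haldane-corrected
#' likelihood ratio with a Katz 95% confidence interval per category, and
#' converts each LR to an ACMG/AMP evidence strength and signed points.
#' Dichotomous mode uses the categories HRP and HRD; stratified mode (CHORD
#' only in practice) splits HRD into BRCA1-subtype and BRCA2-subtype rows,
#' leaving undetermined-subtype HRD patients in the denominators only.
#'
#' @param groups group table from [partition_cohort()].
#' @param calls HR call table from [call_hr()].
#' @param tool prediction tool whose calls are calibrated.
#' @param stratified also fit the CHORD-subtype-stratified rows?
#' @param z normal quantile for the CIs.
#' @param config an [evidence_config()].
#' @return object of class `"hr_calibration"`; its `$table` is a data.frame
#'   with one row per (gene, mode, category): counts, proportions, `lr`,
#'   `ci_low`, `ci_high`, `correction_c`, `strength_label`, `points`.
#' @seealso [sensitivity_reanalysis()], [vus_evidence_report()]
#' @export
hr_calibration <- function(groups, calls, tool = "CHORD",
                           stratified = tool == "CHORD", z = 1.96,
                           config = evidence_config()) {
  modes <- c("dichotomous", if (stratified) "stratified")
  rows <- list()
  for (gene in c("BRCA1", "BRCA2")) {
    case_group <- paste0(gene, "_POS")
    for (mode in modes) {
      for (lab in row_labels(gene, mode == "stratified")) {
        cnt <- category_counts(groups, calls, case_group,
                               category_of_label(lab), tool = tool)
        lr <- compute_lr(cnt, z = z)
        ev <- lr_to_evidence(lr, config = config)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, mode = mode, category = lab,
          x_ctrl = cnt$x_ctrl, n_ctrl = cnt$n_ctrl,
          prop_ctrl = cnt$x_ctrl / cnt$n_ctrl,
          x_case = cnt$x_case, n_case = cnt$n_case,
          prop_case = cnt$x_case / cnt$n_case,
          lr = lr$lr, ci_low = lr$ci_low, ci_high = lr$ci_high,
          correction_c = lr$correction_c,
          strength_label = ev$strength_label, points = ev$points,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(table = do.call(rbind, rows), tool = tool,
                 stratified = stratified, z = z, config = config),
            class = "hr_calibration")
}

#' @export
print.hr_calibration <- function(x, digits = 2, ...) {
  cat(sprintf("HR-status evidence calibration (%s)\n", x$tool))
  tb <- x$table
  for (gene in unique(tb$gene)) {
    for (mode in unique(tb$mode[tb$gene == gene])) {
      cat(sprintf("\n%s - %s\n", gene,
                  if (mode == "stratified") "Stratified by subtype"
                  else "Dichotomous"))
      sub <- tb[tb$gene == gene & tb$mode == mode, , drop = FALSE]
      out <- data.frame(
        category = sub$category,
        negative = sprintf("%d (%.2f)", sub$x_ctrl, sub$prop_ctrl),
        positive = sprintf("%d (%.2f)", sub$x_case, sub$prop_case),
        `LR (95% CI)` = sprintf("%.2f (%.2f, %.2f)", sub$lr,
                                sub$ci_low, sub$ci_high),
        evidence = sprintf("%s (%+d)", sub$strength_label, sub$points),
        check.names = FALSE)
      print(out, row.names = FALSE)
    }
  }
  invisible(x)
}

#' @export
summary.hr_calibration <- function(object, ...) {
  tb <- object$table
  cat(sprintf("Calibration of %s HR calls: %d rows, control n = %d\n",
              object$tool, nrow(tb), tb$n_ctrl[1]))
  print(object)
  invisible(tb)
}

#' @export
coef.hr_calibration <- function(object, ...) {
  tb <- object$table
  stats::setNames(tb$lr, paste(tb$gene, tb$mode, tb$category, sep = ":"))
}

#' @export
confint.hr_calibration <- function(object, parm, level = 0.95, ...) {
  tb <- object$table
  if (abs(level - stats::pnorm(object$z) * 2 + 1) > 1e-6) {
    warning("intervals were fitted at z = ", object$z,
            "; 'level' is ignored")
  }
  m <- cbind(lower = tb$ci_low, upper = tb$ci_high)
  rownames(m) <- paste(tb$gene, tb$mode, tb$category, sep = ":")
  m
}

#' Sensitivity reanalysis including Excluded carriers
#'
#' Re-partitions the cohort with the exclusion rules disabled so that
#' Excluded patients carrying a BRCA1/2 P/LP variant (category A) join the
#' corresponding positive case group, then refits the calibration. By
#' default the remaining Excluded patients stay out of the control group;
#' set `include_excluded_controls = TRUE` to add them to the negatives.
#'
#' @param groups group table from [partition_cohort()]; must carry the
#'   per-patient category summary columns (`has_A_BRCA1`, `has_A_BRCA2`).
#' @param calls HR call table.
#' @param include_excluded_controls move non-carrier Excluded patients into
#'   the control group as well?
#' @inheritParams hr_calibration
#' @return list of class `"hr_sensitivity"` with the refitted
#'   `$calibration`, the `$baseline` fit, and `$delta` — a data.frame
#'   comparing LR, points and labels row by row.
#' @export
sensitivity_reanalysis <- function(groups, calls, tool = "CHORD",
                                   stratified = tool == "CHORD",
                                   include_excluded_controls = FALSE,
                                   z = 1.96, config = evidence_config()) {
  groups <- as_group_table(groups)
  baseline <- hr_calibration(groups, calls, tool = tool,
                             stratified = stratified, z = z, config = config)
  g2 <- groups
  excl <- g2$group == "EXCLUDED"
  g2$group[excl & g2$has_A_BRCA1] <- "BRCA1_POS"
  g2$group[excl & !g2$has_A_BRCA1 & g2$has_A_BRCA2] <- "BRCA2_POS"
  if (include_excluded_controls) {
    g2$group[g2$group == "EXCLUDED"] <- "NEGATIVE"
  }
  refit <- hr_calibration(g2, calls, tool = tool, stratified = stratified,
                          z = z, config = config)
  delta <- data.frame(
    gene = baseline$table$gene, mode = baseline$table$mode,
    category = baseline$table$category,
    lr_baseline = baseline$table$lr, lr_sensitivity = refit$table$lr,
    points_baseline = baseline$table$points,
    points_sensitivity = refit$table$points,
    label_baseline = baseline$table$strength_label,
    label_sensitivity = refit$table$strength_label,
    stringsAsFactors = FALSE)
  structure(list(calibration = refit, baseline = baseline, delta = delta,
                 groups = g2),
            class = "hr_sensitivity")
}

#' @export
print.hr_sensitivity <- function(x, ...) {
  cat("Sensitivity reanalysis (Excluded BRCA1/2 carriers moved to cases)\n")
  print(x$delta, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-variant evidence report for BRCA1/2 VUS carriers
#'
#' For each BRCA1/2 VUS (category C) carried by a patient in the
#' BRCA1/2-VUS group, reports the tumour HR status, the CHORD subtype, a
#' subtype-gene concordance flag, and the evidence the matching calibration
#' row would contribute to that variant. An HRD tumour whose subtype names
#' the other gene contributes no evidence towards pathogenicity
#' (discordant, 0 points). Undetermined subtypes (and non-CHORD tools) fall
#' back to the dichotomous HRD row, with concordance NA.
#'
#' @param variants variant table (rows with `category == "C"` are
#'   reported).
#' @param groups group table from [partition_cohort()].
#' @param calls HR call table.
#' @param calibration an [hr_calibration()] fit used to look up row
#'   evidence; defaults to fitting one from `groups` and `calls`.
#' @param tool prediction tool.
#' @return data.frame with one row per category-C variant: `patient_id`,
#'   `gene`, `variant_id`, `hr_status`, `subtype`, `concordant`,
#'   `strength_label`, `points`.
#' @export
vus_evidence_report <- function(variants, groups, calls,
                                calibration = NULL, tool = "CHORD") {
  groups <- as_group_table(groups)
  if (is.null(calibration)) {
    calibration <- hr_calibration(groups, calls, tool = tool)
  }
  tb <- calibration$table
  vus <- variants[!is.na(variants$category) & variants$category == "C", ,
                  drop = FALSE]
  vus <- merge(vus, groups[, c("patient_id", "group")], by = "patient_id")
  vus <- vus[vus$group == "BRCA12_VUS", , drop = FALSE]
  calls <- calls[calls$tool == tool, , drop = FALSE]
  vus <- merge(vus, calls[, c("patient_id", "status", "subtype")],
               by = "patient_id", all.x = TRUE)
  lookup_row <- function(gene, category) {
    hit <- tb$gene == gene & tb$category == category
    if (!any(hit)) hit <- tb$gene == gene & tb$category == "HRD" &
        tb$mode == "dichotomous"
    tb[which(hit)[1], , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(vus)), function(i) {
    v <- vus[i, ]
    gene <- v$gene
    status <- v$status
    subtype <- v$subtype
    concordant <- NA
    label <- "No call"; points <- 0L
    if (!is.na(status) && status == "HRP") {
      row <- lookup_row(gene, "HRP")
      label <- row$strength_label; points <- row$points
    } else if (!is.na(status) && status == "HRD") {
      if (!is.na(subtype) && subtype %in% c("BRCA1_type", "BRCA2_type")) {
        subtype_gene <- sub("_type", "", subtype)
        concordant <- subtype_gene == gene
        if (concordant) {
          row <- lookup_row(gene, paste("HRD", gene, "subtype"))
          label <- row$strength_label; points <- row$points
        } else {
          label <- "Discordant subtype"; points <- 0L
        }
      } else {
        row <- lookup_row(gene, "HRD")
        label <- row$strength_label; points <- row$points
      }
    }
    data.frame(patient_id = v$patient_id, gene = gene,
               variant_id = v$variant_id,
               hr_status = if (is.na(status)) NA_character_ else status,
               subtype = if (is.na(subtype)) NA_character_ else subtype,
               concordant = concordant,
               strength_label = label, points = points,
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0) {
    return(data.frame(patient_id = character(), gene = character(),
                      variant_id = character(), hr_status = character(),
                      subtype = character(), concordant = logical(),
                      strength_label = character(), points = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
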