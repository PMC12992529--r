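#' Decision thresholds for the HR prediction tools
#'
#' Published cutoffs: CHORD probability > 0.5, HRDetect probability > 0.7
#' (both strict), HRDsum score >= 42 (inclusive; the FDA-approved scar
#' biomarker cutoff). `subtype_min_prob` is the minimum CHORD gene-subtype
#' probability required to name a subtype; below it (or on an exact tie)
#' an HRD call is "undetermined".
#'
#' @param chord_cut,hrdetect_cut probabilities in \[0,1\].
#' @param hrdsum_cut non-negative scar-count cutoff.
#' @param subtype_min_prob minimum subtype probability.
#' @return list of class `"threshold_config"`.
#' @export
threshold_config <- function(chord_cut = 0.5, hrdetect_cut = 0.7,
                             hrdsum_cut = 42, subtype_min_prob = 0.5) {
  stopifnot(is.finite(chord_cut), chord_cut >= 0, chord_cut <= 1,
            is.finite(hrdetect_cut), hrdetect_cut >= 0, hrdetect_cut <= 1,
            is.finite(hrdsum_cut))
  structure(list(chord_cut = chord_cut, hrdetect_cut = hrdetect_cut,
                 hrdsum_cut = hrdsum_cut,
                 subtype_min_prob = subtype_min_prob),
            class = "threshold_config")
}

#' Dichotomise one tool's score into HRD/HRP
#'
#' CHORD and HRDetect call HRD on a strict inequality (score > cutoff);
#' HRDsum calls HRD at score >= cutoff. A missing score yields an NA call
#' (a missing-data marker, not an error), which downstream tables drop.
#'
#' @param scores one-row data.frame or list with the tool's score column
#'   (`chord_prob`, `hrdetect_prob` or `hrdsum_score`).
#' @param tool `"CHORD"`, `"HRDetect"` or `"HRDsum"`.
#' @param config a [threshold_config()].
#' @return list with `tool`, `status` (`"HRD"`/`"HRP"`/NA) and `subtype`
#'   (`"not_applicable"` except for CHORD HRD calls, where
#'   [call_chord_subtype()] refines it).
#' @export
call_hr_status <- function(scores, tool, config = threshold_config()) {
  tool <- match.arg(tool, c("CHORD", "HRDetect", "HRDsum"))
  s <- switch(tool,
    CHORD = scores$chord_prob,
    HRDetect = scores$hrdetect_prob,
    HRDsum = scores$hrdsum_score)
  if (is.null(s) || length(s) != 1 || is.na(s)) {
    return(list(tool = tool, status = NA_character_,
                subtype = NA_character_))
  }
  hrd <- switch(tool,
    CHORD = s > config$chord_cut,
    HRDetect = s > config$hrdetect_cut,
    HRDsum = s >= config$hrdsum_cut)
  list(tool = tool, status = if (hrd) "HRD" else "HRP",
       subtype = "not_applicable")
}

#' Assign the CHORD gene subtype of an HRD call
#'
#' CHORD decomposes its HRD probability into BRCA1-type and BRCA2-type
#' components (driven by 1-10 kb vs 1-100 kb structural duplication
#' patterns). An HRD tumour is assigned the subtype with the larger
#' component when that maximum reaches `subtype_min_prob`; an exact tie or
#' a sub-threshold maximum is "undetermined". HRP tumours have subtype
#' "not_applicable".
#'
#' @param scores one-row data.frame or list with `chord_prob`,
#'   `chord_brca1_prob`, `chord_brca2_prob`.
#' @param config a [threshold_config()].
#' @return list with `tool = "CHORD"`, `status`, `subtype`.
#' @export
call_chord_subtype <- function(scores, config = threshold_config()) {
  p <- scores$chord_prob
  p1 <- scores$chord_brca1_prob
  p2 <- scores$chord_brca2_prob
  if (any(vapply(list(p, p1, p2),
                 function(v) is.null(v) || length(v) != 1 || is.na(v),
                 logical(1)))) {
    return(list(tool = "CHORD", status = NA_character_,
                subtype = NA_character_))
  }
  if (p1 + p2 > p + 1e-9) {
    stop("CHORD subtype probabilities exceed the HRD probability (",
         p1, " + ", p2, " > ", p, ")")
  }
  base <- call_hr_status(scores, "CHORD", config)
  if (is.na(base$status) || base$status == "HRP") {
    base$subtype <- if (is.na(base$status)) NA_character_ else
      "not_applicable"
    return(base)
  }
  mx <- max(p1, p2)
  base$subtype <- if (mx < config$subtype_min_prob || p1 == p2) {
    "undetermined"
  } else if (p1 > p2) "BRCA1_type" else "BRCA2_type"
  base
}

#' Call HR status (and CHORD subtype) for a whole score table
#'
#' @param scores data.frame with `patient_id` and the score columns
#'   produced by [simulate_cohort()].
#' @param tools tools to call; default all three.
#' @param config a [threshold_config()].
#' @return data.frame with columns `patient_id`, `tool`, `status`,
#'   `subtype` (one row per patient per tool; missing scores give NA
#'   status).
#' @export
call_hr <- function(scores, tools = c("CHORD", "HRDetect", "HRDsum"),
                    config = threshold_config()) {
  tools <- match.arg(tools, c("CHORD", "HRDetect", "HRDsum"),
                     several.ok = TRUE)
  rows <- lapply(tools, function(tool) {
    res <- lapply(seq_len(nrow(scores)), function(i) {
      row <- scores[i, , drop = FALSE]
      if (tool == "CHORD") call_chord_subtype(row, config)
      else call_hr_status(row, tool, config)
    })
    data.frame(patient_id = scores$patient_id,
               tool = tool,
               status = vapply(res, `[[`, character(1), "status"),
               subtype = vapply(res, `[[`, character(1), "subtype"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise concordance between tools' HR calls
#'
#' @param calls call table from [call_hr()] covering at least two tools.
#' @return data.frame with one row per tool pair: counts of joint HRD,
#'   joint HRP, discordant calls, and the agreement fraction over the
#'   overlapping patients with non-missing calls.
#' @export
concordance_table <- function(calls) {
  tools <- unique(calls$tool)
  if (length(tools) < 2) stop("need calls from at least two tools")
  pairs <- utils::combn(tools, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    a <- calls[calls$tool == pr[1] & !is.na(calls$status),
               c("patient_id", "status")]
    b <- calls[calls$tool == pr[2] & !is.na(calls$status),
               c("patient_id", "status")]
    m <- merge(a, b, by = "patient_id", suffixes = c("_a", "_b"))
    if (nrow(m) == 0) {
      warning("no overlapping patients for ", pr[1], " vs ", pr[2])
    }
    both_hrd <- sum(m$status_a == "HRD" & m$status_b == "HRD")
    both_hrp <- sum(m$status_a == "HRP" & m$status_b == "HRP")
    disc <- nrow(m) - both_hrd - both_hrp
    data.frame(tool_a = pr[1], tool_b = pr[2], n = nrow(m),
               both_hrd = both_hrd, both_hrp = both_hrp,
               discordant = disc,
               agreement = if (nrow(m) > 0)
                 (both_hrd + both_hrp) / nrow(m) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
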