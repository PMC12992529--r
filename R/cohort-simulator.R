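# Run an expression under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

GROUP_LEVELS <- c("BRCA1_POS", "BRCA2_POS", "NEGATIVE", "EXCLUDED",
                  "BRCA12_VUS")

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions of the 350-patient breast-cancer
#' cohort: group sizes 27 / 21 / 232 / 62 / 8; CHORD HRD probability per
#' group (1.00, 19/21, 35/232, 18/62, 6/8); CHORD subtype distribution
#' among HRD tumours per group; and pathology marker frequencies (the
#' printed ER-negative and grade-3 rates for the three analysis groups).
#'
#' @param group_sizes named integer vector over the five germline groups.
#' @param group_probs optional named probabilities; when given in
#'   stochastic mode, group sizes are drawn multinomially with total
#'   `sum(group_sizes)`.
#' @param hr_given_group named P(HRD | group).
#' @param subtype_given_group_hrd named list; each element a length-3
#'   probability vector over (BRCA1_type, BRCA2_type, undetermined).
#' @param pathology_given_group named list; each element has `grade3`,
#'   `er_neg`, `pr_neg`, `her2_neg` frequencies.
#' @param missing_rate probability a pathology marker is missing.
#' @param seed integer seed.
#' @param mode `"fixture"` (exact deterministic counts) or `"stochastic"`.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(
    group_sizes = c(BRCA1_POS = 27, BRCA2_POS = 21, NEGATIVE = 232,
                    EXCLUDED = 62, BRCA12_VUS = 8),
    group_probs = NULL,
    hr_given_group = c(BRCA1_POS = 1.0, BRCA2_POS = 19 / 21,
                       NEGATIVE = 35 / 232, EXCLUDED = 18 / 62,
                       BRCA12_VUS = 6 / 8),
    subtype_given_group_hrd = list(
      BRCA1_POS = c(BRCA1_type = 1, BRCA2_type = 0, undetermined = 0),
      BRCA2_POS = c(BRCA1_type = 2 / 19, BRCA2_type = 17 / 19,
                    undetermined = 0),
      NEGATIVE = c(BRCA1_type = 17 / 35, BRCA2_type = 15 / 35,
                   undetermined = 3 / 35),
      EXCLUDED = c(BRCA1_type = 8 / 18, BRCA2_type = 8 / 18,
                   undetermined = 2 / 18),
      BRCA12_VUS = c(BRCA1_type = 5 / 6, BRCA2_type = 1 / 6,
                     undetermined = 0)),
    pathology_given_group = list(
      BRCA1_POS = c(grade3 = 19 / 27, er_neg = 24 / 27, pr_neg = 0.80,
                    her2_neg = 0.90),
      BRCA2_POS = c(grade3 = 12 / 21, er_neg = 2 / 21, pr_neg = 0.30,
                    her2_neg = 0.85),
      NEGATIVE = c(grade3 = 66 / 232, er_neg = 73 / 232, pr_neg = 0.35,
                   her2_neg = 0.85),
      EXCLUDED = c(grade3 = 66 / 232, er_neg = 73 / 232, pr_neg = 0.35,
                   her2_neg = 0.85),
      BRCA12_VUS = c(grade3 = 66 / 232, er_neg = 73 / 232, pr_neg = 0.35,
                     her2_neg = 0.85)),
    missing_rate = 0, seed = 1L,
    mode = c("fixture", "stochastic")) {
  mode <- match.arg(mode)
  group_sizes <- group_sizes[GROUP_LEVELS]
  if (anyNA(group_sizes) || any(group_sizes < 0)) {
    stop("group_sizes must cover all five groups with non-negative counts")
  }
  if (sum(group_sizes) == 0) stop("total cohort size is zero")
  chk01 <- function(p, what) {
    if (any(!is.finite(p) | p < 0 | p > 1)) {
      stop(what, " contains a probability outside [0,1]")
    }
  }
  chk01(hr_given_group, "hr_given_group")
  if (!is.null(group_probs)) chk01(group_probs, "group_probs")
  chk01(missing_rate, "missing_rate")
  for (g in names(subtype_given_group_hrd)) {
    p <- subtype_given_group_hrd[[g]]
    chk01(p, paste0("subtype_given_group_hrd$", g))
    if (abs(sum(p) - 1) > 1e-9) {
      stop("subtype probabilities for ", g, " do not sum to 1")
    }
  }
  for (g in names(pathology_given_group)) {
    chk01(pathology_given_group[[g]], paste0("pathology_given_group$", g))
  }
  structure(list(group_sizes = group_sizes, group_probs = group_probs,
                 hr_given_group = hr_given_group,
                 subtype_given_group_hrd = subtype_given_group_hrd,
                 pathology_given_group = pathology_given_group,
                 missing_rate = missing_rate,
                 seed = as.integer(seed), mode = mode),
            class = "cohort_config")
}

# Germline variant rows that make the curation module reassign exactly the
# intended group. Patient i within their group gets a reproducible recipe.
variant_rows_for <- function(patient_id, group, i) {
  other <- c("ATM", "PALB2", "CHEK2", "RAD51C", "BARD1", "BRIP1",
             "RAD51D", "TP53", "PTEN")
  row <- function(gene, clinvar, suspicious = FALSE, faf = NA_real_,
                  type = "SNV") {
    data.frame(patient_id = patient_id, gene = gene,
               variant_id = paste0(gene, ":c.", 100 + i, "A>G"),
               variant_type = type, clinvar_class = clinvar,
               gnomad_faf = faf, bayesdel = NA_real_,
               spliceai_max = NA_real_, cadd = NA_real_,
               suspicious_vus = suspicious, class3 = NA_character_,
               stringsAsFactors = FALSE)
  }
  switch(group,
    BRCA1_POS = row("BRCA1", "P"),
    BRCA2_POS = row("BRCA2", if (i %% 2 == 0) "P" else "LP"),
    BRCA12_VUS = row(if (i == 6) "BRCA2" else "BRCA1", "VUS"),
    NEGATIVE = {
      # a third carry an incidental benign finding; the rest carry nothing
      if (i %% 3 == 0) {
        gene <- if (i %% 6 == 0) "BRCA2" else other[1 + (i %% 9)]
        row(gene, "B", faf = 0.002)
      } else {
        NULL
      }
    },
    EXCLUDED = {
      # patients 1-2: BRCA1 P/LP + other-gene P/LP (sensitivity carriers)
      # patients 3-5: BRCA2 P/LP + other-gene P/LP
      # patients 6-36: other-gene P/LP (or suspicious VUS) only
      # patients 37-62: other-gene plain VUS only
      g_other <- other[1 + (i %% 9)]
      if (i <= 2) {
        rbind(row("BRCA1", "P"), row(g_other, "P"))
      } else if (i <= 5) {
        rbind(row("BRCA2", "P"), row(g_other, "LP"))
      } else if (i <= 30) {
        row(g_other, "P")
      } else if (i <= 36) {
        row(g_other, "VUS", suspicious = TRUE)
      } else {
        row(g_other, "VUS")
      }
    })
}

# Deterministic vector with exactly round(p * n) TRUE values, spread over
# the first positions.
exact_flags <- function(n, p) {
  k <- round(p * n)
  c(rep(TRUE, k), rep(FALSE, n - k))
}

score_for_truth <- function(status, subtype, stochastic,
                            config = threshold_config()) {
  if (status == "HRD") {
    if (stochastic) {
      chord <- stats::runif(1, 0.62, 0.99)
      hrdetect <- stats::runif(1, 0.75, 0.99)
      hrdsum <- round(stats::runif(1, 45, 80))
    } else {
      chord <- 0.95; hrdetect <- 0.95; hrdsum <- 60
    }
    if (subtype == "BRCA1_type") {
      p1 <- if (stochastic) stats::runif(1, config$subtype_min_prob + 0.02,
                                         chord - 0.05) else 0.90
      p2 <- min(0.05, chord - p1)
    } else if (subtype == "BRCA2_type") {
      p2 <- if (stochastic) stats::runif(1, config$subtype_min_prob + 0.02,
                                         chord - 0.05) else 0.90
      p1 <- min(0.05, chord - p2)
    } else {  # undetermined: both components below the naming threshold
      u <- if (stochastic) stats::runif(1, 0.1, 0.44) else 0.45
      u <- min(u, chord / 2)
      p1 <- u; p2 <- u
    }
  } else {
    chord <- if (stochastic) stats::runif(1, 0.01, 0.45) else 0.05
    hrdetect <- if (stochastic) stats::runif(1, 0.01, 0.65) else 0.05
    hrdsum <- if (stochastic) round(stats::runif(1, 0, 38)) else 10
    p1 <- chord / 4; p2 <- chord / 4
  }
  c(chord_prob = chord, chord_brca1_prob = p1, chord_brca2_prob = p2,
    hrdetect_prob = hrdetect, hrdsum_score = hrdsum)
}

#' Simulate a synthetic cohort
#'
#' Generates the three cohort tables the downstream analysis consumes: a
#' sample sheet, a germline variant table whose curation reproduces each
#' patient's intended group, and an HR score table whose dichotomisation
#' reproduces each patient's HR truth. Fixture mode emits exact
#' deterministic counts (in particular, the default configuration
#' reproduces the published 350-patient group-by-HR-call cross-tabulation);
#' stochastic mode draws groups, HR status, subtype, scores and pathology
#' at the configured rates.
#'
#' @param config a [cohort_config()].
#' @return list of class `"synthetic_cohort"` with data.frames `samples`,
#'   `variants`, `scores`, and `truth` (patient_id, group, hr_status,
#'   subtype).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  stochastic <- config$mode == "stochastic"
  sizes <- config$group_sizes
  if (stochastic && !is.null(config$group_probs)) {
    draw <- stats::rmultinom(1, sum(sizes),
                             config$group_probs[GROUP_LEVELS])[, 1]
    sizes <- stats::setNames(draw, GROUP_LEVELS)
  }
  total <- sum(sizes)
  group <- rep(GROUP_LEVELS, times = sizes)
  within <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  ids <- sprintf("P%04d", seq_len(total))

  # HR truth
  status <- character(total); subtype <- character(total)
  for (g in GROUP_LEVELS) {
    sel <- which(group == g)
    if (length(sel) == 0) next
    p_hrd <- config$hr_given_group[[g]]
    ps <- config$subtype_given_group_hrd[[g]]
    if (stochastic) {
      hrd <- stats::runif(length(sel)) < p_hrd
      sub <- sample(names(ps), length(sel), replace = TRUE, prob = ps)
    } else {
      hrd <- exact_flags(length(sel), p_hrd)
      n_hrd <- sum(hrd)
      k <- round(ps * n_hrd)
      k[1] <- n_hrd - sum(k[-1])  # exact allocation
      sub <- rep(names(ps), times = pmax(k, 0))
      sub <- c(sub, rep(names(ps)[1], n_hrd - length(sub)))
      if (g == "EXCLUDED" && n_hrd >= 5) {
        # the BRCA1/BRCA2 carriers among the Excluded (within-group
        # positions 1-2 and 3-5) get gene-concordant subtypes; the
        # remaining multiset is preserved
        want <- c("BRCA1_type", "BRCA1_type", rep("BRCA2_type", 3))
        pool <- sub
        for (s2 in want) {
          hit <- match(s2, pool)
          if (!is.na(hit)) pool <- pool[-hit]
        }
        sub <- c(want, pool)[seq_len(n_hrd)]
      }
    }
    status[sel] <- ifelse(hrd, "HRD", "HRP")
    subtype[sel][status[sel] == "HRP"] <- "not_applicable"
    if (stochastic) {
      subtype[sel][hrd] <- sub[hrd]
    } else {
      subtype[sel][hrd] <- sub
    }
  }

  # scores consistent with truth under the decision thresholds
  sc <- t(vapply(seq_len(total), function(i) {
    score_for_truth(status[i], subtype[i], stochastic)
  }, numeric(5)))
  scores <- data.frame(patient_id = ids, sc, stringsAsFactors = FALSE)

  # variants
  vlist <- lapply(seq_len(total), function(i) {
    variant_rows_for(ids[i], group[i], within[i])
  })
  variants <- do.call(rbind, vlist[!vapply(vlist, is.null, logical(1))])
  rownames(variants) <- NULL

  # pathology and sample sheet
  grade <- character(total); er <- character(total)
  pr <- character(total); her2 <- character(total)
  for (g in GROUP_LEVELS) {
    sel <- which(group == g)
    if (length(sel) == 0) next
    pp <- config$pathology_given_group[[g]]
    flag <- function(p) {
      if (stochastic) stats::runif(length(sel)) < p
      else exact_flags(length(sel), p)
    }
    g3 <- flag(pp[["grade3"]])
    grade[sel] <- ifelse(g3, "3", ifelse(seq_along(sel) %% 3 == 0,
                                         "1", "2"))
    er[sel] <- ifelse(flag(pp[["er_neg"]]), "neg", "pos")
    pr[sel] <- ifelse(flag(pp[["pr_neg"]]), "neg", "pos")
    her2[sel] <- ifelse(flag(pp[["her2_neg"]]), "neg", "pos")
  }
  if (config$missing_rate > 0) {
    for (v in c("grade", "er", "pr", "her2")) {
      x <- get(v)
      x[stats::runif(total) < config$missing_rate] <- "missing"
      assign(v, x)
    }
  }
  cohorts <- rep(c("FamilialBreast", "TCGA-BRCA", "MAGIC", "Q-IMPROvE"),
                 length.out = total)
  purity <- if (stochastic) round(stats::rbeta(total, 5.8, 4.2), 2)
            else rep(0.58, total)
  samples <- data.frame(patient_id = ids, cohort = cohorts,
                        sex = "female", purity = purity, grade = grade,
                        ER = er, PR = pr, HER2 = her2,
                        stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = ids, group = group,
                      hr_status = status, subtype = subtype,
                      stringsAsFactors = FALSE)
  structure(list(samples = samples, variants = variants, scores = scores,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (%s mode), %d variant rows\n",
              nrow(x$samples), x$config$mode, nrow(x$variants)))
  print(table(factor(x$truth$group, levels = GROUP_LEVELS)))
  invisible(x)
}

#' The deterministic 350-patient fixture cohort
#'
#' Shorthand for `simulate_cohort(cohort_config(mode = "fixture"))`: the
#' exact published group structure and group-conditional HR calls.
#'
#' @param seed seed (the fixture is deterministic; the seed only matters
#'   for the tie-breaking of nothing in practice).
#' @return a `synthetic_cohort`.
#' @export
fixture_cohort <- function(seed = 1L) {
  simulate_cohort(cohort_config(seed = seed, mode = "fixture"))
}

#' Simulate an allele-specific copy-number segment profile
#'
#' Builds a whole-genome segment tiling whose genomic-scar score separates
#' HRD from HRP by construction. Each chromosome starts as one balanced
#' 1+1 segment; scar events are then carved in: an interstitial 1+0 LOH
#' segment on the q arm (16-25 Mb), a telomeric 2+1 allelic-imbalance
#' region on the p arm (12 Mb up to the centromere), and a balanced 2+2
#' block at the q telomere (11-14 Mb) contributing a state transition
#' only. HRD profiles place the LOH and telomeric-AI events on every
#' chromosome (plus the 2+2 block on half of them); HRP profiles place a
#' single random event on a small fraction of chromosomes.
#'
#' @param hr_status `"HRD"` or `"HRP"`.
#' @param genome genome annotation (default [toy_genome()]).
#' @param seed integer seed.
#' @param event_prob optional named numeric `c(loh=, tai=, block=)`
#'   per-chromosome event probabilities overriding the status defaults;
#'   a scalar is recycled (0 gives the balanced zero-event genome).
#' @return segment data.frame (`chrom`, `start`, `end`, `major`, `minor`).
#' @export
simulate_segments <- function(hr_status, genome = toy_genome(),
                              seed = 1L, event_prob = NULL) {
  hr_status <- match.arg(hr_status, c("HRD", "HRP"))
  genome <- validate_genome(genome)
  if (is.null(event_prob)) {
    event_prob <- if (hr_status == "HRD") {
      c(loh = 1, tai = 1, block = 0.5)
    } else {
      c(loh = 0.08, tai = 0.08, block = 0.08)
    }
  }
  if (length(event_prob) == 1) {
    event_prob <- c(loh = event_prob, tai = event_prob,
                    block = event_prob)
  }
  with_seed(seed, {
    out <- lapply(seq_len(nrow(genome)), function(ci) {
      gi <- genome[ci, ]
      simulate_chrom_segments(gi, event_prob)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

simulate_chrom_segments <- function(gi, event_prob) {
  L <- gi$length; cs <- gi$cen_start; ce <- gi$cen_end
  cuts <- c(0, L)
  cn <- list()  # events as (start, end, major, minor)
  add <- function(s, e, ma, mi) {
    cn[[length(cn) + 1L]] <<- c(s, e, ma, mi)
  }
  # telomeric AI on the p arm (stays clear of the centromere)
  if (cs > 14e6 && stats::runif(1) < event_prob[["tai"]]) {
    t <- stats::runif(1, 12e6, cs - 2e6)
    add(0, t, 2, 1)
  }
  # interstitial LOH on the q arm
  qlen <- L - ce
  if (qlen >= 24e6 && stats::runif(1) < event_prob[["loh"]]) {
    l <- stats::runif(1, 16e6, min(25e6, qlen - 8e6))
    a <- ce + stats::runif(1, 1e6, 5e6)
    a <- min(a, L - l - 1e6)
    add(a, a + l, 1, 0)
  }
  # balanced 2+2 block at the q telomere; needs clearance from the LOH
  if (stats::runif(1) < event_prob[["block"]]) {
    b <- stats::runif(1, 11e6, 14e6)
    lo <- L - b
    loh_end <- if (length(cn) > 0) max(vapply(cn, `[`, 0, 2)) else 0
    if (lo - loh_end >= 10e6 && lo > ce) add(lo, L, 2, 2)
  }
  # assemble the tiling: background 1+1 around the events
  ev <- if (length(cn) > 0) {
    m <- do.call(rbind, cn)
    m[order(m[, 1]), , drop = FALSE]
  } else {
    matrix(numeric(0), ncol = 4)
  }
  rows <- list(); pos <- 0
  for (r in seq_len(nrow(ev))) {
    s <- ev[r, 1]; e <- ev[r, 2]
    if (s > pos) rows[[length(rows) + 1L]] <- c(pos, s, 1, 1)
    rows[[length(rows) + 1L]] <- c(s, e, ev[r, 3], ev[r, 4])
    pos <- e
  }
  if (pos < L) rows[[length(rows) + 1L]] <- c(pos, L, 1, 1)
  m <- do.call(rbind, rows)
  data.frame(chrom = gi$chrom, start = round(m[, 1]), end = round(m[, 2]),
             major = m[, 3], minor = m[, 4], stringsAsFactors = FALSE)
}
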