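#' Build a contingency table of HR status against a pathology marker
#'
#' Rows with a missing marker value are excluded before construction; zero
#' marginal rows/columns are dropped with a warning.
#'
#' @param samples sample sheet with the marker column.
#' @param calls HR call table ([call_hr()]).
#' @param marker one of `"grade"`, `"ER"`, `"PR"`, `"HER2"`, `"TNBC"`.
#' @param tool prediction tool.
#' @return integer matrix (HR status x marker levels).
#' @export
marker_table <- function(samples, calls, marker = "ER", tool = "CHORD") {
  marker <- match.arg(marker, c("grade", "ER", "PR", "HER2", "TNBC"))
  calls <- calls[calls$tool == tool & !is.na(calls$status), ]
  m <- merge(samples, calls[, c("patient_id", "status")],
             by = "patient_id")
  v <- if (marker == "TNBC") {
    ok <- m$ER %in% c("pos", "neg") & m$PR %in% c("pos", "neg") &
      m$HER2 %in% c("pos", "neg")
    ifelse(ok, ifelse(m$ER == "neg" & m$PR == "neg" & m$HER2 == "neg",
                      "TNBC", "non-TNBC"), NA)
  } else {
    x <- as.character(m[[marker]])
    x[x == "missing"] <- NA
    x
  }
  keep <- !is.na(v)
  tab <- table(status = m$status[keep], marker = v[keep])
  tab <- drop_zero_margins(tab)
  tab
}

drop_zero_margins <- function(tab) {
  rz <- rowSums(tab) == 0
  cz <- colSums(tab) == 0
  if (any(rz) || any(cz)) {
    warning("dropping zero-marginal rows/columns before testing")
    tab <- tab[!rz, !cz, drop = FALSE]
  }
  tab
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic on (r-1)(c-1) degrees of freedom; no Yates
#' continuity correction by default.
#'
#' @param table integer matrix (at least 2x2 after dropping zero
#'   marginals).
#' @param correct apply the Yates correction (2x2 only)?
#' @return list with `statistic`, `dof`, `p_value` and the `expected`
#'   counts.
#' @export
chi_square_independence <- function(table, correct = FALSE) {
  table <- drop_zero_margins(as.matrix(table))
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("need at least a 2x2 table with positive marginals")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), dof = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

#' Cramér's V effect size
#'
#' V = sqrt(chi2 / (n * (min(r, c) - 1))) from the uncorrected Pearson
#' statistic; no bias correction.
#'
#' @param table integer matrix.
#' @return value in \[0, 1\].
#' @export
cramers_v <- function(table) {
  table <- as.matrix(table)
  chi2 <- chi_square_independence(table, correct = FALSE)$statistic
  n <- sum(table)
  k <- min(nrow(table), ncol(table)) - 1
  sqrt(chi2 / (n * k))
}

# Rank-sum statistic of sample a within the pooled midranks.
ranksum_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)])
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Two-sided rank-sum test using midranks for ties. When both samples have
#' at most `exact_max` observations the p-value is computed by exhaustive
#' enumeration of all rank assignments (which remains valid under ties,
#' unlike the classical exact distribution); otherwise the tie-corrected
#' normal approximation is used.
#'
#' @param a,b numeric samples.
#' @param exact_max exact enumeration threshold per sample (default 8).
#' @param correct apply a 0.5 continuity correction in the normal
#'   approximation (default TRUE; improves small-sample agreement with the
#'   exact distribution)?
#' @return list with `statistic` (rank sum of `a`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 8, correct = TRUE) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    warning("all values identical across both samples; p = 1")
    return(list(statistic = ranksum_stat(a, b), p_value = 1,
                method = "degenerate"))
  }
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (na <= exact_max && nb <= exact_max) {
    idx <- utils::combn(n, na)
    ws <- colSums(matrix(r[idx], nrow = na))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    return(list(statistic = w, p_value = p, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  dev <- abs(w - mu)
  if (correct) dev <- max(0, dev - 0.5)
  z <- dev / sqrt(sigma2)
  list(statistic = w, p_value = 2 * stats::pnorm(-abs(z)),
       method = "normal")
}

#' Marker-association summary across tools
#'
#' @param samples sample sheet.
#' @param calls HR call table.
#' @param markers markers to test.
#' @param tool prediction tool.
#' @return data.frame: marker, n, chi2, dof, p, cramers_v.
#' @export
associate_markers <- function(samples, calls,
                              markers = c("grade", "ER", "PR", "HER2",
                                          "TNBC"),
                              tool = "CHORD") {
  rows <- lapply(markers, function(mk) {
    tab <- marker_table(samples, calls, mk, tool)
    ct <- chi_square_independence(tab)
    data.frame(marker = mk, n = sum(tab), chi2 = ct$statistic,
               dof = ct$dof, p = ct$p_value, cramers_v = cramers_v(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
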