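#' Validate a genome annotation table
#'
#' @param genome data.frame with columns `chrom`, `length`, `cen_start`,
#'   `cen_end` (base pairs, 0-based half-open).
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_genome <- function(genome) {
  need <- c("chrom", "length", "cen_start", "cen_end")
  if (!all(need %in% names(genome))) {
    stop("genome annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(genome) < 1) stop("genome annotation has no chromosomes")
  bad <- !(genome$cen_start > 0 & genome$cen_end > genome$cen_start &
             genome$cen_end < genome$length)
  if (any(bad)) {
    stop("centromere outside chromosome bounds on: ",
         paste(genome$chrom[bad], collapse = ", "))
  }
  genome
}

#' A small toy genome annotation
#'
#' Chromosome lengths and centromere positions for a reduced genome used
#' by the simulator and in examples. Lengths taper from 240 Mb down over
#' `n_chrom` chromosomes; centromeres sit at 40-50% of each chromosome.
#' Real reference coordinates are deliberately not used.
#'
#' @param n_chrom number of chromosomes (2 to 23).
#' @return genome annotation data.frame (`chrom`, `length`, `cen_start`,
#'   `cen_end`).
#' @export
toy_genome <- function(n_chrom = 22) {
  stopifnot(n_chrom >= 2, n_chrom <= 23)
  i <- seq_len(n_chrom)
  len <- round(seq(240e6, 60e6, length.out = n_chrom) / 1e6) * 1e6
  cen_mid <- round(len * (0.40 + 0.10 * (i %% 2)) / 1e6) * 1e6
  data.frame(chrom = paste0("chr", i),
             length = len,
             cen_start = cen_mid - 2e6,
             cen_end = cen_mid + 2e6,
             stringsAsFactors = FALSE)
}

#' Normalise an allele-specific copy-number segment table
#'
#' Sorts segments by (chrom, start), checks them against the genome
#' annotation, rejects overlaps, and merges exactly adjacent segments with
#' identical (major, minor) copy counts. Gaps between segments are
#' tolerated. Coordinates are 0-based half-open; pass `one_based = TRUE`
#' for 1-based inclusive input, converted on read.
#'
#' @param segments data.frame with `chrom`, `start`, `end`, `major`,
#'   `minor` (and optionally `patient_id`, ignored here).
#' @param genome genome annotation (see [validate_genome()]).
#' @param one_based input uses 1-based inclusive coordinates?
#' @return the normalised segment data.frame.
#' @export
preprocess_segments <- function(segments, genome, one_based = FALSE) {
  genome <- validate_genome(genome)
  seg <- segments[, c("chrom", "start", "end", "major", "minor")]
  if (one_based) seg$start <- seg$start - 1
  if (any(seg$start >= seg$end)) stop("segment with start >= end")
  if (any(seg$major < 0 | seg$minor < 0)) stop("negative copy count")
  if (any(seg$major < seg$minor)) stop("segment with major < minor")
  unknown <- setdiff(unique(seg$chrom), genome$chrom)
  if (length(unknown) > 0) {
    stop("segments on chromosomes absent from the annotation: ",
         paste(unknown, collapse = ", "))
  }
  lens <- stats::setNames(genome$length, genome$chrom)
  if (any(seg$end > lens[seg$chrom])) {
    bad <- which(seg$end > lens[seg$chrom])[1]
    stop("segment beyond chromosome length: ", seg$chrom[bad], ":",
         seg$start[bad], "-", seg$end[bad])
  }
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  out <- lapply(split(seg, seg$chrom), function(s) {
    if (nrow(s) > 1) {
      ov <- s$start[-1] < s$end[-nrow(s)]
      if (any(ov)) {
        i <- which(ov)[1]
        stop("overlapping segments on ", s$chrom[1], ": ",
             s$start[i], "-", s$end[i], " and ",
             s$start[i + 1], "-", s$end[i + 1])
      }
    }
    merge_adjacent(s)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Merge runs of exactly adjacent segments sharing (major, minor).
merge_adjacent <- function(s) {
  if (nrow(s) <= 1) return(s)
  keep <- 1L
  for (i in 2:nrow(s)) {
    j <- keep[length(keep)]
    if (s$start[i] == s$end[j] && s$major[i] == s$major[j] &&
        s$minor[i] == s$minor[j]) {
      s$end[j] <- s$end[i]
    } else {
      keep <- c(keep, i)
    }
  }
  s[keep, , drop = FALSE]
}

#' Count long interstitial LOH segments (HRD-LOH)
#'
#' Counts segments with minor allele count 0 whose length is at least
#' `min_len` and which do not span the entire chromosome (whole-chromosome
#' LOH reflects chromosome loss rather than a recombination scar).
#'
#' @param segments preprocessed segments (see [preprocess_segments()]).
#' @param genome genome annotation.
#' @param min_len minimum segment length in bp (default 15 Mb).
#' @return integer count.
#' @export
count_hrd_loh <- function(segments, genome, min_len = 15e6) {
  genome <- validate_genome(genome)
  lens <- stats::setNames(genome$length, genome$chrom)
  hit <- segments$minor == 0 &
    (segments$end - segments$start) >= min_len &
    !(segments$start == 0 & segments$end == lens[segments$chrom])
  sum(hit)
}

#' Count large-scale state transitions (LST)
#'
#' After discarding segments shorter than `smooth_len` and re-merging
#' identical neighbours, counts copy-number-changing junctions between
#' consecutive segments where both flanks are at least `min_flank` long,
#' the gap between them is below `smooth_len`, and the junction does not
#' cross the centromere.
#'
#' @param segments preprocessed segments.
#' @param genome genome annotation.
#' @param smooth_len segments below this length are absorbed; also the
#'   maximum junction gap (default 3 Mb).
#' @param min_flank minimum flank length (default 10 Mb).
#' @return integer count.
#' @export
count_lst <- function(segments, genome, smooth_len = 3e6,
                      min_flank = 10e6) {
  genome <- validate_genome(genome)
  cen <- genome[, c("chrom", "cen_start", "cen_end")]
  total <- 0L
  for (s in split(segments, segments$chrom)) {
    s <- s[(s$end - s$start) >= smooth_len, , drop = FALSE]
    if (nrow(s) < 2) next
    s <- merge_over_gaps(s, smooth_len)
    if (nrow(s) < 2) next
    ci <- cen[cen$chrom == s$chrom[1], ]
    for (i in seq_len(nrow(s) - 1)) {
      a <- s[i, ]; b <- s[i + 1, ]
      if (a$major == b$major && a$minor == b$minor) next
      if ((a$end - a$start) < min_flank) next
      if ((b$end - b$start) < min_flank) next
      if ((b$start - a$end) >= smooth_len) next
      # junction interval must not touch the centromere
      if (a$end < ci$cen_end && b$start > ci$cen_start) next
      total <- total + 1L
    }
  }
  total
}

# After smoothing, re-merge identical-CN neighbours separated by less than
# `gap_max` (the removed fragment leaves a gap).
merge_over_gaps <- function(s, gap_max) {
  keep <- 1L
  for (i in 2:nrow(s)) {
    j <- keep[length(keep)]
    if (s$major[i] == s$major[j] && s$minor[i] == s$minor[j] &&
        (s$start[i] - s$end[j]) < gap_max) {
      s$end[j] <- s$end[i]
    } else {
      keep <- c(keep, i)
    }
  }
  s[keep, , drop = FALSE]
}

#' Count telomeric allelic imbalances (NtAI)
#'
#' Counts maximal runs of consecutive allelically imbalanced segments
#' (major != minor) that reach a chromosome end, lie entirely on one side
#' of the centromere, do not span the whole chromosome, and are at least
#' `min_len` long.
#'
#' @param segments preprocessed segments.
#' @param genome genome annotation.
#' @param min_len minimum run length in bp (default 11 Mb).
#' @return integer count.
#' @export
count_ntai <- function(segments, genome, min_len = 11e6) {
  genome <- validate_genome(genome)
  total <- 0L
  for (s in split(segments, segments$chrom)) {
    gi <- genome[genome$chrom == s$chrom[1], ]
    ai <- s$major != s$minor
    if (!any(ai)) next
    r <- rle(ai)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run_start <- s$start[starts[k]]
      run_end <- s$end[ends[k]]
      if (!(run_start == 0 || run_end == gi$length)) next
      if (run_start == 0 && run_end == gi$length) next
      if (run_start < gi$cen_end && run_end > gi$cen_start) next
      if ((run_end - run_start) < min_len) next
      total <- total + 1L
    }
  }
  total
}

#' Combine the three scar counts into an HRDsum result
#'
#' @param loh,lst,ntai non-negative integer counts.
#' @param cut HRD decision cutoff (default 42, inclusive).
#' @return list of class `"scar_result"`: `loh`, `lst`, `ntai`, `hrdsum`,
#'   `status` (`"HRD"` if hrdsum >= cut else `"HRP"`).
#' @export
hrdsum_total <- function(loh, lst, ntai, cut = 42) {
  if (any(c(loh, lst, ntai) < 0)) stop("scar counts must be non-negative")
  hrdsum <- loh + lst + ntai
  structure(list(loh = loh, lst = lst, ntai = ntai, hrdsum = hrdsum,
                 status = if (hrdsum >= cut) "HRD" else "HRP", cut = cut),
            class = "scar_result")
}

#' @export
print.scar_result <- function(x, ...) {
  cat(sprintf("HRDsum %d (LOH %d + LST %d + NtAI %d) -> %s (cut %s)\n",
              x$hrdsum, x$loh, x$lst, x$ntai, x$status,
              format(x$cut)))
  invisible(x)
}

#' Score one patient's segment profile
#'
#' Convenience wrapper: preprocess, run the three counters, sum.
#'
#' @inheritParams preprocess_segments
#' @param loh_min,lst_smooth,lst_flank,ntai_min counter parameters in bp.
#' @param cut HRD cutoff.
#' @return a `scar_result` (see [hrdsum_total()]).
#' @export
score_scars <- function(segments, genome, loh_min = 15e6,
                        lst_smooth = 3e6, lst_flank = 10e6,
                        ntai_min = 11e6, cut = 42, one_based = FALSE) {
  seg <- preprocess_segments(segments, genome, one_based = one_based)
  hrdsum_total(count_hrd_loh(seg, genome, min_len = loh_min),
               count_lst(seg, genome, smooth_len = lst_smooth,
                         min_flank = lst_flank),
               count_ntai(seg, genome, min_len = ntai_min),
               cut = cut)
}
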