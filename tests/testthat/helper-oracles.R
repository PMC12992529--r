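# Independent brute-force scar counters: literal restatements of the
# counting rules, written as plain scans so they can disagree with the
# package implementation if either is wrong.

oracle_loh <- function(seg, genome, min_len = 15e6) {
  n <- 0L
  for (i in seq_len(nrow(seg))) {
    len_chrom <- genome$length[genome$chrom == seg$chrom[i]]
    whole <- seg$start[i] == 0 && seg$end[i] == len_chrom
    if (seg$minor[i] == 0 && (seg$end[i] - seg$start[i]) >= min_len &&
        !whole) {
      n <- n + 1L
    }
  }
  n
}

oracle_lst <- function(seg, genome, smooth_len = 3e6, min_flank = 10e6) {
  n <- 0L
  for (chrom in unique(seg$chrom)) {
    s <- seg[seg$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    s <- s[(s$end - s$start) >= smooth_len, , drop = FALSE]
    # fixpoint re-merge of identical-CN neighbours with a small gap
    repeat {
      merged <- FALSE
      if (nrow(s) >= 2) {
        for (i in seq_len(nrow(s) - 1)) {
          same <- s$major[i] == s$major[i + 1] &&
            s$minor[i] == s$minor[i + 1]
          if (same && (s$start[i + 1] - s$end[i]) < smooth_len) {
            s$end[i] <- s$end[i + 1]
            s <- s[-(i + 1), , drop = FALSE]
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) break
    }
    if (nrow(s) < 2) next
    gi <- genome[genome$chrom == chrom, ]
    for (i in seq_len(nrow(s) - 1)) {
      cn_change <- !(s$major[i] == s$major[i + 1] &&
                       s$minor[i] == s$minor[i + 1])
      flanks_ok <- (s$end[i] - s$start[i]) >= min_flank &&
        (s$end[i + 1] - s$start[i + 1]) >= min_flank
      gap_ok <- (s$start[i + 1] - s$end[i]) < smooth_len
      junction <- c(s$end[i], s$start[i + 1])
      across_cen <- junction[1] < gi$cen_end && junction[2] > gi$cen_start
      if (cn_change && flanks_ok && gap_ok && !across_cen) n <- n + 1L
    }
  }
  n
}

oracle_ntai <- function(seg, genome, min_len = 11e6) {
  n <- 0L
  for (chrom in unique(seg$chrom)) {
    s <- seg[seg$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    gi <- genome[genome$chrom == chrom, ]
    i <- 1L
    while (i <= nrow(s)) {
      if (s$major[i] != s$minor[i]) {
        j <- i
        while (j < nrow(s) && s$major[j + 1] != s$minor[j + 1]) j <- j + 1
        run_start <- s$start[i]; run_end <- s$end[j]
        touches_end <- run_start == 0 || run_end == gi$length
        whole <- run_start == 0 && run_end == gi$length
        across_cen <- run_start < gi$cen_end && run_end > gi$cen_start
        long_enough <- (run_end - run_start) >= min_len
        if (touches_end && !whole && !across_cen && long_enough) {
          n <- n + 1L
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  n
}

# A tiny test genome: one or more 100 Mb chromosomes, centromere 40-50 Mb.
tiny_genome <- function(n = 1) {
  data.frame(chrom = paste0("c", seq_len(n)), length = 100e6,
             cen_start = 40e6, cen_end = 50e6, stringsAsFactors = FALSE)
}

seg_row <- function(chrom, start, end, major, minor) {
  data.frame(chrom = chrom, start = start, end = end, major = major,
             minor = minor, stringsAsFactors = FALSE)
}

# Random small segment profile: a full or gapped tiling of a tiny genome
# with random allele-specific copy-number states.
random_profile <- function(genome, max_seg = 8, gap_prob = 0.15) {
  states <- list(c(1, 1), c(2, 1), c(1, 0), c(2, 2), c(2, 0), c(3, 1),
                 c(3, 0), c(0, 0), c(4, 2))
  out <- list()
  for (i in seq_len(nrow(genome))) {
    L <- genome$length[i]
    k <- sample(1:max_seg, 1)
    cuts <- sort(c(0, L, round(runif(k - 1, 1e5, L - 1e5))))
    cuts <- unique(cuts)
    for (j in seq_len(length(cuts) - 1)) {
      if (runif(1) < gap_prob) next  # leave a gap
      cn <- states[[sample(length(states), 1)]]
      out[[length(out) + 1L]] <- seg_row(genome$chrom[i], cuts[j],
                                         cuts[j + 1], cn[1], cn[2])
    }
  }
  if (length(out) == 0) {
    return(seg_row(genome$chrom[1], 0, genome$length[1], 1, 1))
  }
  do.call(rbind, out)
}

# Textbook Pearson chi-square: sum over cells of (O - E)^2 / E.
oracle_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
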