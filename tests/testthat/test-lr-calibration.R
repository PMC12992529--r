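fixture_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      co <- fixture_cohort()
      cur <- curate_variants(co$variants)
      part <- partition_cohort(cur, co$samples)
      calls <- call_hr(co$scores, "CHORD")
      memo <<- list(cohort = co, variants = cur, part = part,
                    calls = calls,
                    fit = hr_calibration(part, calls, tool = "CHORD"))
    }
    memo
  }
})

test_that("published likelihood ratios and intervals reproduce at 2 dp", {
  r2 <- function(x) round(x, 2)
  cases <- list(
    # x_case, n_case, x_ctrl, n_ctrl, lr, lo, hi
    list(27, 27, 35, 232, 6.63, 4.88, 9.00),
    list(0, 27, 197, 232, 0.02, 0.00, 0.33),
    list(19, 21, 35, 232, 6.00, 4.29, 8.39),
    list(2, 21, 197, 232, 0.11, 0.03, 0.42),
    list(17, 21, 15, 232, 12.52, 7.36, 21.31),
    list(2, 21, 17, 232, 1.30, 0.32, 5.25),
    list(0, 27, 15, 232, 0.27, 0.02, 4.37))
  for (cs in cases) {
    r <- compute_lr(x_case = cs[[1]], n_case = cs[[2]],
                    x_ctrl = cs[[3]], n_ctrl = cs[[4]])
    expect_equal(r2(r$lr), cs[[5]])
    expect_equal(r2(r$ci_low), cs[[6]])
    expect_equal(r2(r$ci_high), cs[[7]])
  }
  expect_equal(compute_lr(x_case = 5, n_case = 10, x_ctrl = 5,
                          n_ctrl = 10)$lr, 1)
  # the subtype-stratified BRCA1 estimate consistent with its own CI
  r <- compute_lr(x_case = 27, n_case = 27, x_ctrl = 17, n_ctrl = 232)
  expect_equal(r2(r$lr), 13.65)
  expect_equal(r2(r$ci_low), 8.64)
  expect_equal(r2(r$ci_high), 21.57)
})

test_that("the continuity correction activates exactly on zero cells", {
  set.seed(31)
  for (i in 1:100) {
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    r <- compute_lr(x_case = x1, n_case = n1, x_ctrl = x2, n_ctrl = n2)
    if (x1 == 0 || x2 == 0) {
      expect_equal(r$correction_c, 0.5)
    } else {
      expect_equal(r$correction_c, 0)
      expect_equal(r$lr, (x1 / n1) / (x2 / n2))
      # swapping case and control inverts the estimate
      r_sw <- compute_lr(x_case = x2, n_case = n2, x_ctrl = x1,
                         n_ctrl = n1)
      expect_equal(r_sw$lr, 1 / r$lr)
    }
  }
  expect_error(compute_lr(x_case = 3, n_case = 0, x_ctrl = 1,
                          n_ctrl = 10), "positive")
  expect_error(compute_lr(x_case = 11, n_case = 10, x_ctrl = 1,
                          n_ctrl = 10), "0 <= x <= n")
})

test_that("evidence mapping matches the published strengths and points", {
  ev <- function(...) lr_to_evidence(compute_lr(...))
  e1 <- ev(x_case = 27, n_case = 27, x_ctrl = 35, n_ctrl = 232)
  expect_equal(e1$strength_label, "Pathogenic Moderate")
  expect_equal(e1$points, 2L)
  e2 <- ev(x_case = 0, n_case = 27, x_ctrl = 197, n_ctrl = 232)
  expect_equal(e2$strength_label, "Benign Strong")
  expect_equal(e2$points, -4L)
  e3 <- ev(x_case = 2, n_case = 21, x_ctrl = 197, n_ctrl = 232)
  expect_equal(e3$strength_label, "Benign Moderate")
  expect_equal(e3$points, -2L)
  # CI containing 1 forces zero despite a moderate-band estimate
  e4 <- ev(x_case = 0, n_case = 27, x_ctrl = 15, n_ctrl = 232)
  expect_equal(e4$strength_label, "Not significant")
  expect_equal(e4$points, 0L)
  # within the indeterminate band the label stays Indeterminate
  e5 <- ev(x_case = 2, n_case = 21, x_ctrl = 17, n_ctrl = 232)
  expect_equal(e5$strength_label, "Indeterminate")
  expect_equal(e5$points, 0L)
  # boundary is inclusive on the extreme side
  e6 <- lr_to_evidence(350^(1 / 4), ci = c(1.5, 20))
  expect_equal(e6$strength_label, "Pathogenic Moderate")
  expect_equal(e6$points, 2L)
  e7 <- lr_to_evidence(350, ci = c(10, 10000))
  expect_equal(e7$points, 8L)
  expect_equal(lr_to_evidence(1.0)$strength_label, "Indeterminate")
  expect_error(lr_to_evidence(-2), "positive")
})

test_that("evidence mapping is reciprocal under LR inversion", {
  set.seed(17)
  lrs <- c(exp(runif(300, log(1 / 2000), log(2000))),
           350^(c(1, 1 / 2, 1 / 4, 1 / 8)), 1)
  mirror <- c("Pathogenic Very Strong" = "Benign Very Strong",
              "Pathogenic Strong" = "Benign Strong",
              "Pathogenic Moderate" = "Benign Moderate",
              "Pathogenic Supporting" = "Benign Supporting",
              "Indeterminate" = "Indeterminate")
  for (lr in lrs) {
    ci <- c(lr * 0.8, lr * 1.25)
    a <- lr_to_evidence(lr, ci = ci)
    b <- lr_to_evidence(1 / lr, ci = rev(1 / ci))
    expect_equal(b$points, -a$points, info = lr)
    lab <- a$strength_label
    expected <- if (lab %in% names(mirror)) mirror[[lab]]
      else if (lab %in% mirror) names(mirror)[match(lab, mirror)]
      else lab
    expect_equal(b$strength_label, expected, info = lr)
  }
})

test_that("counts are conserved across categories within each group", {
  fx <- fixture_fit()
  tb <- fx$fit$table
  for (gene in c("BRCA1", "BRCA2")) {
    d <- tb[tb$gene == gene & tb$mode == "dichotomous", ]
    expect_equal(sum(d$x_case), d$n_case[1])
    expect_equal(sum(d$x_ctrl), d$n_ctrl[1])
    s <- tb[tb$gene == gene & tb$mode == "stratified", ]
    hrd <- d[d$category == "HRD", ]
    sub_case <- sum(s$x_case[s$category != "HRP"])
    sub_ctrl <- sum(s$x_ctrl[s$category != "HRP"])
    # subtype counts plus undetermined make up the HRD total
    expect_lte(sub_case, hrd$x_case)
    expect_equal(hrd$x_ctrl - sub_ctrl, 3)  # the undetermined negatives
  }
})

test_that("katz intervals agree with a parametric bootstrap on small counts", {
  set.seed(53)
  cases <- list(c(8, 20, 5, 40), c(3, 15, 10, 60), c(12, 30, 6, 25))
  for (cs in cases) {
    r <- compute_lr(x_case = cs[1], n_case = cs[2], x_ctrl = cs[3],
                    n_ctrl = cs[4])
    b1 <- rbinom(10000, cs[2], cs[1] / cs[2]) / cs[2]
    b2 <- rbinom(10000, cs[4], cs[3] / cs[4]) / cs[4]
    ok <- b1 > 0 & b2 > 0
    q <- quantile(log(b1[ok] / b2[ok]), c(0.025, 0.975))
    width <- q[[2]] - q[[1]]
    expect_lt(abs(log(r$ci_low) - q[[1]]) / width, 0.25)
    expect_lt(abs(log(r$ci_high) - q[[2]]) / width, 0.25)
  }
})

test_that("sensitivity reanalysis moves the Excluded carriers into the cases", {
  fx <- fixture_fit()
  sens <- sensitivity_reanalysis(fx$part, fx$calls)
  tb <- sens$calibration$table
  expect_equal(tb$n_case[tb$gene == "BRCA1"][1], 29)
  expect_equal(tb$n_case[tb$gene == "BRCA2"][1], 24)
  expect_equal(sens$delta$label_baseline, sens$delta$label_sensitivity)
  expect_equal(sens$delta$points_baseline, sens$delta$points_sensitivity)

  # without Excluded patients the reanalysis is a no-op
  keep <- fx$part$groups$group != "EXCLUDED"
  g0 <- fx$part$groups[keep, ]
  s0 <- sensitivity_reanalysis(g0, fx$calls)
  expect_equal(s0$calibration$table, s0$baseline$table)
})

test_that("the VUS report assigns gene-concordant evidence only", {
  fx <- fixture_fit()
  rep <- vus_evidence_report(fx$variants, fx$part, fx$calls,
                             calibration = fx$fit)
  expect_equal(nrow(rep), 8)
  expect_equal(sum(rep$hr_status == "HRD"), 6)
  expect_equal(sum(rep$gene == "BRCA1" & rep$hr_status == "HRD"), 5)
  expect_equal(sum(rep$gene == "BRCA2" & rep$hr_status == "HRD"), 1)
  hrd <- rep[rep$hr_status == "HRD", ]
  expect_true(all(hrd$concordant))
  expect_true(all(hrd$points == 2L))
  hrp <- rep[rep$hr_status == "HRP", ]
  expect_true(all(hrp$points < 0))

  # a discordant subtype contributes nothing towards pathogenicity
  v <- fx$variants[fx$variants$category == "C" &
                     fx$variants$gene == "BRCA2", ][1, ]
  calls2 <- fx$calls
  i <- calls2$patient_id == v$patient_id
  calls2$status[i] <- "HRD"
  calls2$subtype[i] <- "BRCA1_type"
  rep2 <- vus_evidence_report(fx$variants, fx$part, calls2,
                              calibration = fx$fit)
  row <- rep2[rep2$patient_id == v$patient_id, ]
  expect_false(row$concordant)
  expect_equal(row$points, 0L)
  expect_equal(row$strength_label, "Discordant subtype")
})

test_that("degenerate all-HRP cohorts are handled via the correction", {
  fx <- fixture_fit()
  calls <- fx$calls
  calls$status <- "HRP"
  calls$subtype <- "not_applicable"
  fit <- hr_calibration(fx$part, calls, tool = "CHORD")
  hrd_rows <- fit$table[fit$table$category != "HRP", ]
  expect_true(all(hrd_rows$correction_c == 0.5))
  expect_true(all(hrd_rows$points == 0))
})
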