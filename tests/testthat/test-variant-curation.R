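mkvar <- function(gene = "BRCA1", clinvar = NA_character_,
                  faf = NA_real_, cadd = NA_real_, class3 = NA_character_,
                  suspicious = FALSE, id = "v1") {
  data.frame(patient_id = "P1", gene = gene, variant_id = id,
             variant_type = "SNV", clinvar_class = clinvar,
             gnomad_faf = faf, bayesdel = NA_real_,
             spliceai_max = NA_real_, cadd = cadd,
             suspicious_vus = suspicious, class3 = class3,
             stringsAsFactors = FALSE)
}

test_that("classification collapse follows the FAF-then-ClinVar precedence", {
  expect_equal(collapse_classification(mkvar(clinvar = "P")), "P/LP")
  expect_equal(collapse_classification(mkvar(clinvar = "LP")), "P/LP")
  expect_equal(collapse_classification(mkvar(clinvar = "LB")), "B/LB")
  expect_equal(collapse_classification(mkvar(clinvar = "VUS")), "VUS")
  expect_equal(collapse_classification(mkvar(clinvar = "conflicting")),
               "VUS")
  # a common variant is benign regardless of a ClinVar P assertion
  expect_equal(collapse_classification(mkvar(clinvar = "absent",
                                             faf = 0.002)), "B/LB")
  expect_equal(collapse_classification(mkvar(clinvar = "P", faf = 0.002)),
               "B/LB")
  # rare frequency alone cannot establish pathogenicity
  expect_equal(collapse_classification(mkvar(clinvar = "absent",
                                             faf = 1e-6)), "VUS")
  # a precomputed class bypasses the collapse
  expect_equal(collapse_classification(mkvar(class3 = "P/LP",
                                             faf = 0.002)), "P/LP")
  expect_error(collapse_classification(mkvar(cadd = 25)),
               "no usable classification")
})

test_that("categories cross class with the BRCA vs other-gene split", {
  expect_equal(assign_category("BRCA1", "P/LP"), "A")
  expect_equal(assign_category("BRCA2", "P/LP"), "A")
  expect_equal(assign_category("PALB2", "P/LP"), "B")
  expect_equal(assign_category("BRCA2", "VUS"), "C")
  expect_equal(assign_category("ATM", "VUS"), "D")
  expect_equal(assign_category("ATM", "VUS", suspicious_vus = TRUE), "B")
  expect_equal(assign_category("BRCA1", "VUS", suspicious_vus = TRUE),
               "C")
  expect_equal(assign_category("BRCA1", "B/LB"), "E")
  expect_equal(assign_category("CHEK2", "B/LB"), "F")
  expect_error(assign_category("MLH1", "P/LP"), "outside the 11-gene panel")
})

test_that("group assignment follows the exclusion-first precedence", {
  expect_equal(assign_group(c("A"), "BRCA1"), "BRCA1_POS")
  expect_equal(assign_group(c("A"), "BRCA2"), "BRCA2_POS")
  expect_equal(assign_group(c("A", "B"), c("BRCA1", "PALB2")), "EXCLUDED")
  expect_equal(assign_group(c("E", "F"), c("BRCA1", "ATM")), "NEGATIVE")
  expect_equal(assign_group(c("C"), "BRCA2"), "BRCA12_VUS")
  expect_equal(assign_group(c("C", "D"), c("BRCA2", "ATM")), "BRCA12_VUS")
  expect_equal(assign_group(c("D"), "ATM"), "EXCLUDED")
  expect_equal(assign_group(character(0)), "NEGATIVE")
  # the open A+D combination: positive by default, Excluded in strict mode
  expect_equal(assign_group(c("A", "D"), c("BRCA1", "ATM")), "BRCA1_POS")
  expect_equal(assign_group(c("A", "D"), c("BRCA1", "ATM"),
                            strict_exclusion = TRUE), "EXCLUDED")
  # sensitivity mode disables the exclusion rules
  expect_equal(assign_group(c("A", "B"), c("BRCA2", "PALB2"),
                            sensitivity = TRUE), "BRCA2_POS")
  expect_warning(
    g <- assign_group(c("A", "A"), c("BRCA1", "BRCA2")),
    "both BRCA1 and BRCA2")
  expect_equal(g, "BRCA1_POS")
})

test_that("cohort partition reproduces the published group counts", {
  co <- fixture_cohort()
  cur <- curate_variants(co$variants)
  part <- partition_cohort(cur, co$samples)
  expect_equal(part$counts,
               c(BRCA1_POS = 27L, BRCA2_POS = 21L, NEGATIVE = 232L,
                 EXCLUDED = 62L, BRCA12_VUS = 8L))
  # curation reassigns exactly the intended group for every patient
  m <- merge(part$groups, co$truth, by = "patient_id")
  expect_true(all(m$group.x == m$group.y))
})

test_that("partition is exhaustive, order-invariant and robust", {
  co <- fixture_cohort()
  cur <- curate_variants(co$variants)
  part <- partition_cohort(cur, co$samples)
  expect_equal(nrow(part$groups), nrow(co$samples))
  expect_true(all(part$groups$group %in%
                    c("BRCA1_POS", "BRCA2_POS", "NEGATIVE", "EXCLUDED",
                      "BRCA12_VUS")))
  expect_equal(sum(part$counts), nrow(co$samples))
  # permuting variant rows changes nothing
  set.seed(11)
  perm <- cur[sample(nrow(cur)), ]
  expect_equal(partition_cohort(perm, co$samples)$groups, part$groups)
  # patients without variants are negative
  empty <- cur[0, ]
  sheet <- data.frame(patient_id = sprintf("N%02d", 1:10))
  p0 <- partition_cohort(empty, sheet)
  expect_true(all(p0$groups$group == "NEGATIVE"))
  # orphan variant row
  orphan <- cur[1, ]; orphan$patient_id <- "GHOST"
  expect_error(partition_cohort(rbind(cur, orphan), co$samples),
               "absent from the sample sheet")
})

test_that("adding a category-B variant always lands a patient in EXCLUDED", {
  co <- fixture_cohort()
  cur <- curate_variants(co$variants)
  set.seed(7)
  for (pid in sample(co$samples$patient_id, 25)) {
    extra <- mkvar(gene = "PALB2", clinvar = "P", id = "extraB")
    extra$patient_id <- pid
    cur2 <- curate_variants(rbind(co$variants, extra))
    part2 <- partition_cohort(cur2, co$samples)
    expect_equal(part2$groups$group[part2$groups$patient_id == pid],
                 "EXCLUDED")
  }
})

test_that("variant tables round-trip through TSV and minimal VCF", {
  co <- fixture_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  v <- read_variant_table(file.path(dir, "variants.tsv"))
  expect_equal(nrow(v), nrow(co$variants))
  expect_equal(v$gene, co$variants$gene)
  s <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(s$patient_id, co$samples$patient_id)
  skip_if_not_installed("vcfR")
  vcf <- file.path(dir, "mini.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CLASS3,Number=1,Type=String,Description=\"Class\">",
    "##INFO=<ID=FAF,Number=1,Type=Float,Description=\"gnomAD FAF\">",
    "##INFO=<ID=PID,Number=1,Type=String,Description=\"Patient\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr17\t43045703\t.\tG\tA\t.\tPASS\tGENE=BRCA1;CLASS3=P/LP;PID=P0001",
    "chr13\t32338000\t.\tT\tTA\t.\tPASS\tGENE=BRCA2;CLASS3=VUS;FAF=0.00001;PID=P0002"),
    vcf)
  x <- read_variants_vcf(vcf)
  expect_equal(x$gene, c("BRCA1", "BRCA2"))
  expect_equal(x$class3, c("P/LP", "VUS"))
  expect_equal(x$variant_type, c("SNV", "indel"))
  expect_equal(curate_variants(x)$category, c("A", "C"))
})
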