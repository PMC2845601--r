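test_that("screen tables read into one cohort per dose with separators stripped", {
  screens <- redSetterScreen()
  expect_named(screens, c("0.7% EMS", "1% EMS"))
  tab <- screenTable(screens[["0.7% EMS"]])
  expect_equal(nrow(tab), 7L)
  rab <- tab[tab$gene == "Rab11a", ]
  expect_equal(rab$families_screened, 1373L)  # "1,373" in the file
  expect_equal(rab$mutations, 1L)
  # dash means zero
  expect_equal(screenTable(screens[["1% EMS"]])$mutations[7], 0L)
})

test_that("header-only files, missing columns and bad cells are handled", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tamplicon_kb\tfamilies_screened\tmutations\tdose", f)
  expect_length(readScreenTable(f), 0L)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tamplicon_kb\tfamilies_screened\tdose",
               "A\t1.0\t10\td"), f2)
  expect_error(readScreenTable(f2), "mutations",
               class = "tillkit_format_error")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tamplicon_kb\tfamilies_screened\tmutations\tdose",
               "A\t1.0\tten\t1\td"), f3)
  expect_error(readScreenTable(f3), "row 1",
               class = "tillkit_parse_error")
})

test_that("thousands separators parse locale-independently", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tamplicon_kb\tfamilies_screened\tmutations\tdose",
               "A\t1.0\t3,885\t2\td",
               "B\t1.0\t3885\t2\td"), f)
  tab <- screenTable(readScreenTable(f)[[1]])
  expect_identical(tab$families_screened[1], tab$families_screened[2])
  expect_identical(tab$families_screened[1], 3885L)
})

test_that("screen tables round-trip through write and read", {
  screens <- screenCohortsFixture()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeScreenTable(screens, f)
  back <- readScreenTable(f)
  for (d in names(screens))
    expect_equal(screenTable(back[[d]]), screenTable(screens[[d]]))
  # no thousands separators on output
  expect_false(any(grepl(",", readLines(f))))
})

test_that("amplicon FASTA + interval files load with bounds checking", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">Exp1", strrep("ACGTT", 205),   # 1025 bp
               ">bare", "acgtacgt"), fa)
  iv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# 1-based inclusive amplicon coordinates",
               "name\tstart\tend\tframe",
               "Exp1\t101\t700\t0"), iv)
  amps <- readAmpliconAnnotations(fa, iv)
  expect_equal(ampliconKb(amps$Exp1), 1.025)
  expect_equal(length(cdsSegments(amps$Exp1)), 1L)
  # record without intervals: no CDS, sequence uppercased
  expect_null(cdsSegments(amps$bare))
  expect_equal(as.character(refSequence(amps$bare)), "ACGTACGT")

  iv2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tstart\tend", "Exp1\t10\t5"), iv2)
  expect_error(readAmpliconAnnotations(fa, iv2),
               class = "tillkit_bounds_error")

  iv3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tstart\tend", "bare\t2\t2000"), iv3)
  expect_error(readAmpliconAnnotations(fa, iv3),
               class = "tillkit_bounds_error")

  fa2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">dup", "ACGT", ">dup", "ACGT"), fa2)
  expect_error(readAmpliconAnnotations(fa2),
               class = "tillkit_duplicate_error")
})

test_that("mutation VCF writes one data line per record and round-trips", {
  recs <- mutationRecords(
    gene = c("Exp1", "Exp1", "RIN"),
    family_id = c("F012", "F900", NA),
    position = c(42L, 901L, 17L),
    ref = c("C", "G", "A"), alt = c("T", "A", "T"),
    region = c("coding", "noncoding", "unknown"),
    effect = c("missense", NA, NA))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeMutations(recs, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 3L)
  expect_equal(strsplit(body[1], "\t")[[1]][2], "42")
  expect_equal(readMutations(f), recs)

  # empty set: header only, reads back empty
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeMutations(emptyMutationRecords(), f2)
  expect_true(all(startsWith(readLines(f2), "#")))
  expect_equal(nrow(readMutations(f2)), 0L)
})

test_that("written VCF is parseable by an independent VCF reader", {
  skip_if_not_installed("VariantAnnotation")
  recs <- mutationRecords("Exp1", "F012", c(42L, 99L), c("C", "G"),
                          c("T", "A"), region = "coding",
                          effect = c("missense", "silent"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeMutations(recs, f)
  vcf <- VariantAnnotation::readVcf(f)
  expect_equal(unname(BiocGenerics::start(SummarizedExperiment::rowRanges(vcf))),
               c(42L, 99L))
  expect_equal(as.character(VariantAnnotation::ref(vcf)), c("C", "G"))
  expect_equal(unlist(VariantAnnotation::info(vcf)$EFFECT),
               c("missense", "silent"), ignore_attr = TRUE)
})

test_that("invalid mutation records are rejected", {
  expect_error(mutationRecords("g", "f", 1, "A", "A"), "ref equals alt")
  expect_error(mutationRecords("g", "f", 1, "A", "N"), "invalid base")
  amp <- ampliconTarget("g", lengthKb = 0.1)
  expect_error(mutationRecords("g", "f", 150, "A", "C", amplicon = amp),
               class = "tillkit_bounds_error")
})

test_that("ledger summary reproduces attrition accounting", {
  led <- ledgerSummary(redSetterLedger())
  one <- led[led$dose == "1% EMS", ]
  expect_equal(one$m3_failures, 574L)
  expect_equal(one$m3_failure_rate_pct, 29.8)
  tot <- led[led$dose == "Total", ]
  expect_equal(tot$m3_families, 5508L)
  expect_equal(tot$seeds_treated, 23000L)
  expect_equal(tot$m1_transplanted, 13000L)
  expect_equal(tot$m2_families, 6667L)
  expect_equal(tot$m3_failures, 1159L)
  # totals are per-dose sums (conservation)
  perDose <- led[led$dose != "Total", ]
  for (col in c("seeds_treated", "m1_transplanted", "m2_families",
                "m3_families"))
    expect_equal(sum(perDose[[col]]), tot[[col]])
})

test_that("ledger edge cases: no failures, broken monotonicity", {
  led <- populationLedger("d", 100, 80, 50, 50)
  expect_equal(ledgerSummary(led)$m3_failure_rate_pct[1], 0)
  expect_error(populationLedger("d", 100, 80, 50, 60), "monotone")
})
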