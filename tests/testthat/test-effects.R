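test_that("codon effects match simple amino-acid comparisons", {
  expect_equal(codonEffect("GAA", "GAG"), "silent")    # both Glu
  expect_equal(codonEffect("TGG", "TGA"), "nonsense")  # Trp -> stop
  expect_equal(codonEffect("TGA", "TGG"), "stop-loss")
  expect_equal(codonEffect("GAA", "GTA"), "missense")
  expect_error(codonEffect("GAA", "GAA"), class = "tillkit_domain_error")
  expect_error(codonEffect("GAA", "CTA"), class = "tillkit_domain_error")
  expect_error(codonEffect("GAN", "GAA"), class = "tillkit_domain_error")
})

test_that("codon effects agree with a translate-and-compare oracle on all single-base neighbors", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (ref in codons) {
    chars <- strsplit(ref, "")[[1]]
    for (p in 1:3) for (b in setdiff(bases, chars[p])) {
      alt <- chars; alt[p] <- b
      alt <- paste(alt, collapse = "")
      expect_equal(codonEffect(ref, alt), codonEffectOracle(ref, alt),
                   label = sprintf("%s>%s", ref, alt))
    }
  }
})

test_that("annotation assigns regions and effects from CDS structure", {
  amp <- spliceToyAmplicon()
  # position 14 is between the CDS segments: an intron base
  intron <- annotateMutations(mutationRecords("toy", "f", 14, "T", "A"), amp)
  expect_equal(intron$region, "noncoding")
  expect_true(is.na(intron$effect))
  # position 9 is codon 2 third base: GCA -> GCC, both Ala
  silent <- annotateMutations(mutationRecords("toy", "f", 9, "A", "C"), amp)
  expect_equal(silent$region, "coding")
  expect_equal(silent$effect, "silent")
})

test_that("codons spanning a CDS junction are spliced before classification", {
  amp <- spliceToyAmplicon()
  # codon 3 "AAA" sits on amplicon positions 10, 11, 19; manual oracle:
  # AAA(Lys) -> AAG(Lys) silent at pos 19; AAA -> ATA(Ile) missense at 11
  atJunction <- annotateMutations(
    mutationRecords("toy", "f", 19, "A", "G"), amp)
  expect_equal(atJunction$effect, "silent")
  inFirstSegment <- annotateMutations(
    mutationRecords("toy", "f", 11, "A", "T"), amp)
  expect_equal(inFirstSegment$effect, "missense")
})

test_that("frame offsets shift codon phase and truncated codons stay unclassified", {
  # same sequence, first CDS base completes an upstream codon (offset 1):
  # complete codons then start at position 5: TGG|CAA|A+AC|GAA|TGG|TG
  amp <- ampliconTarget("toy", sequence = "CCCATGGCAAAGTTTTTTACGAATGGTGACCC",
                        cdsSegments = cbind(c(4, 19), c(11, 28)),
                        frameOffset = 1L)
  # position 4 belongs to the upstream-truncated codon: coding, effect NA
  trunc <- annotateMutations(mutationRecords("toy", "f", 4, "A", "G"), amp)
  expect_equal(trunc$region, "coding")
  expect_true(is.na(trunc$effect))
  # position 6 is now the middle base of codon "TGG" (positions 5-7):
  # G>C gives TCG (Trp -> Ser), missense
  mis <- annotateMutations(mutationRecords("toy", "f", 6, "G", "C"), amp)
  expect_equal(mis$effect, "missense")
})

test_that("annotation is idempotent and checks the reference base", {
  amp <- spliceToyAmplicon()
  recs <- mutationRecords("toy", "f", c(9, 14, 19), c("A", "T", "A"),
                          c("C", "A", "G"))
  once <- annotateMutations(recs, amp)
  expect_identical(annotateMutations(once, amp), once)
  expect_error(annotateMutations(mutationRecords("toy", "f", 9, "G", "A"),
                                 amp),
               "position 9", class = "tillkit_consistency_error")
})

test_that("amplicons without CDS annotation yield unknown regions", {
  amp <- ampliconTarget("bare", sequence = "ACGTACGTAC")
  out <- annotateMutations(mutationRecords("bare", "f", 3, "G", "A"), amp)
  expect_equal(out$region, "unknown")
  expect_true(is.na(out$effect))
})

test_that("effect summary uses coding records as its percentage base", {
  recs <- mutationRecords("g", "f", 1:10, "G", "A",
                          region = rep(c("coding", "noncoding"), c(8, 2)),
                          effect = c(rep("silent", 3), rep("missense", 5),
                                     NA, NA))
  s <- effectSummary(recs)
  expect_equal(s$effects$pct[s$effects$effect == "silent"], 37.5)
  expect_equal(s$effects$pct[s$effects$effect == "missense"], 62.5)
  expect_equal(s$noncoding, 2L)
  expect_equal(s$coding_total, 8L)
  allNon <- effectSummary(mutationRecords("g", "f", 1:3, "G", "A",
                                          region = "noncoding"))
  expect_equal(sum(allNon$effects$count), 0L)
  expect_true(all(is.na(allNon$effects$pct)))
})

test_that("simulated cohorts recover the silent fraction expected by site enumeration", {
  amp <- spliceToyAmplicon()
  probs <- defaultSpectrumProbs()
  chars <- strsplit(as.character(refSequence(amp)), "")[[1]]
  lookup <- vapply(substitutionClasses(), function(cl) {
    # ref bases compatible with each class, from first principles
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    refs <- substr(cl, 1, 2)
    strsplit(refs, "")[[1]]
  }, character(2))
  # enumeration oracle: P(silent | coding & classifiable) under the
  # simulator's class-then-uniform-compatible-site sampling
  num <- 0; den <- 0
  for (cl in substitutionClasses()) {
    if (probs[[cl]] == 0) next
    refPair <- lookup[, cl]
    sites <- which(chars %in% refPair)
    for (p in sites) {
      # class determines alt given ref
      altFor <- function(r) {
        alts <- setdiff(c("A", "C", "G", "T"), r)
        alts[vapply(alts, function(a)
          as.character(canonicalClass(r, a)) == cl, logical(1))]
      }
      rec <- tryCatch(
        annotateMutations(mutationRecords("toy", "f", p, chars[p],
                                          altFor(chars[p])), amp),
        error = function(e) NULL)
      if (is.null(rec) || rec$region != "coding" || is.na(rec$effect)) next
      w <- probs[[cl]] / length(sites)
      den <- den + w
      if (rec$effect == "silent") num <- num + w
    }
  }
  expected <- num / den
  # simulate a large cohort on the same amplicon and compare
  params <- simulationParams(ratePerKb = 50, amplicons = amp,
                             families = 60L, seed = 99L)
  scr <- simulateScreen(params)
  ann <- annotateMutations(mutations(scr), amp)
  cod <- ann[ann$region == "coding" & !is.na(ann$effect), ]
  observed <- mean(cod$effect == "silent")
  se <- sqrt(expected * (1 - expected) / nrow(cod))
  expect_lt(abs(observed - expected), 4 * se + 1e-9)
})
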