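# Fixtures are built in code at test time.

# Published seven-gene screen, typed independently of the packaged TSV so
# reader and estimator can be checked against a hand-entered copy.
screenFixture <- function() {
  list(
    gene = c("Rab11a", "PG", "Exp1", "RIN", "Gr", "Lcy-b", "Lcy-e"),
    kb = c(0.407, 2.587, 1.025, 1.331, 1.409, 1.274, 1.414),
    n07 = c(1373, 2791, 3885, 3885, 3885, 3801, 3630),
    m07 = c(1, 7, 14, 4, 5, 4, 6),
    n1 = c(713, 963, 1284, 1284, 1284, 1252, 1185),
    m1 = c(3, 2, 6, 8, 3, 3, 0),
    printed07 = c(559, 1031, 284, 1293, 1095, 1211, 855),
    printed1 = c(97, 1246, 219, 214, 603, 532, NA))
}

screenCohortsFixture <- function() {
  fx <- screenFixture()
  list(
    "0.7% EMS" = cohortScreen("0.7% EMS", data.frame(
      gene = fx$gene, amplicon_kb = fx$kb,
      families_screened = fx$n07, mutations = fx$m07)),
    "1% EMS" = cohortScreen("1% EMS", data.frame(
      gene = fx$gene, amplicon_kb = fx$kb,
      families_screened = fx$n1, mutations = fx$m1)))
}

# 32 bp toy amplicon whose third codon spans a CDS junction.
spliceToyAmplicon <- function() {
  seq <- "CCCATGGCAAAGTTTTTTACGAATGGTGACCC"
  # CDS segments 4..11 (ATGGCAAA) and 19..28 (ACGAATGGTG); spliced CDS
  # "ATGGCAAAACGAATGGTG" = ATG GCA AAA CGA ATG GTG, so codon 3 ("AAA")
  # sits on amplicon positions 10, 11 and 19 (spans the junction)
  ampliconTarget("toy", sequence = seq,
                 cdsSegments = cbind(c(4, 19), c(11, 28)))
}

# independent translate-and-compare oracle built on Biostrings::translate,
# a different code path than the GENETIC_CODE lookup inside codonEffect
codonEffectOracle <- function(refCodon, altCodon) {
  aa <- function(codon)
    as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                       no.init.codon = TRUE))
  refAA <- aa(refCodon); altAA <- aa(altCodon)
  if (refAA == altAA) "silent"
  else if (altAA == "*") "nonsense"
  else if (refAA == "*") "stop-loss"
  else "missense"
}

observationsFixture <- function() {
  validateObservations(data.frame(
    plant_code = c("P1", "P1", "P2", "P3", "P3", "P4"),
    family_id = c("F001", "F001", "F001", "F002", "F002", "F003"),
    class = c("Seed", "Sterility", "Seed", "Fruit colour",
              "Fruit colour", "Sterility"),
    subclass = c("No germination", "Total sterility", "No germination",
                 "Yellow fruit", "Yellow fruit", "Partial sterility"),
    stringsAsFactors = FALSE))
}
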