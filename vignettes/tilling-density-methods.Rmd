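---
title: "Mutation-density estimation in EMS TILLING screens"
author: "tillkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation-density estimation in EMS TILLING screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillkit)
```

# The problem

TILLING (Targeting Induced Local Lesions IN Genomes) screens a chemically
mutagenized population for point mutations in genes of interest. Seeds are
treated with EMS (ethylmethane sulfonate), selfed through the M1 and M2
generations, and DNA from pooled M3 families is screened amplicon by
amplicon with a mismatch-specific endonuclease. Two quantities summarize
such a resource:

* the **mutation density**, conventionally reported in reciprocal form as
  "1 mutation / X kb" of screened sequence, which determines how many
  families must be screened to find an allele in a gene of given size; and
* the **substitution spectrum**, the distribution of induced changes over
  the six strand-symmetric base-pair-change classes
  (`r paste(substitutionClasses(), collapse = ", ")`), which for EMS is
  expected to be dominated by GC/AT transitions.

tillkit implements the estimators, the classifiers, a coding-effect
annotator, a phenotype-catalog layer, and a forward simulator that checks
the density estimator by parameter recovery. The seven-gene validation
screen of the Red Setter tomato EMS populations ships as worked-example
data (`redSetterScreen()`, `redSetterLedger()`).

# The density estimator

For one amplicon of length $L$ kb screened over $N$ M3 families with $m$
mutations found, the per-amplicon reciprocal density is

$$ D = \frac{L \, N}{m} \quad \text{kb per mutation}, $$

undefined (rendered `"-"`) when $m = 0$. No correction is applied at the
amplicon level: per-gene table cells are raw screened kb over observed
counts.

The population average over amplicons $i$ applies the Mendelian
segregation correction $c$:

$$ \bar D = c \cdot \frac{\sum_i L_i N_i}{\sum_i m_i}, \qquad c = 0.75
\text{ by default.} $$

The correction's logic: each M3 family descends from a single M2 plant.
For any given induced allele the M2 parent is, under 1:2:1 Mendelian
segregation, homozygous wild type with probability 1/4 — and such a family
cannot reveal the allele no matter how much of it is screened. A quarter
of the screened kb is therefore blind, so the effective denominator is
$0.75 \sum L_i N_i$; equivalently the observed count $\sum m_i$
understates induced mutations by 4/3. Amplicons with $m_i = 0$ still
contribute their screened kb to the numerator — dropping them would bias
the average low.

`populationDensity()` exposes $c$ as a parameter so the corrected
($c = 0.75$) and uncorrected ($c = 1$) estimators can be compared; the
estimator is linear in $c$, a property the test suite asserts.

```{r}
screens <- redSetterScreen()
densityReport(screens)
```

The per-gene cells above reproduce the published table exactly. The
corrected population averages recompute to 1/592 kb (0.7% EMS) and
1/327 kb (1% EMS) from the printed inputs, about 3% higher than the
published overall values of 1/574 kb and 1/322 kb. The published averages
evidently used more input precision (unrounded amplicon lengths or
per-amplicon family counts) than the printed table carries; the
recomputed values are the faithful function of the printed inputs, and
the package documents the discrepancy rather than adjusting toward the
published numbers.

An exact Poisson (Garwood) interval on the population density is
available through `populationDensityCI()`. This is an extension beyond
the published point estimates and is flagged as such in pipeline output.

# Substitution classes and coding effects

`canonicalClass()` collapses the 12 ordered single-base substitutions
onto the six classes by complementing any pyrimidine-reference change, so
a change and its reverse complement always share a class; the partition
and the strand invariance are tested exhaustively.

Transition bookkeeping deserves a note. Chemically the two transitions
are GC/AT and AT/GC (purine to purine on one strand). EMS-spectrum
reports, however, often quote "the transition percentage" counting GC/AT
alone, since that is the EMS signature class. `substitutionKind()` and
the spectrum summary take a `definition` argument — `"chemical"` (the
default) or `"gc-at-only"` — so either convention can be reported; the
six-class table itself is identical under both.

`codonEffect()` classifies single-base codon changes under the standard
nuclear genetic code into silent, missense, nonsense and stop-loss.
Stop-loss is included for completeness of the enumeration even where a
screen observes none. `annotateMutations()` locates each mutation's codon
on the spliced CDS of its amplicon, so codons spanning CDS-segment
junctions are handled; the segment list plus a frame offset (how many
bases of the first segment complete a codon begun upstream of the
amplicon) fix the phase. Effect percentages in `effectSummary()` are
computed over coding records only, matching how exonic silent/missense
splits are quoted.

Design choices here that were genuinely open:

* **CDS on the forward strand only.** Genes on the genomic reverse strand
  must be supplied as reverse-complemented amplicons. This keeps
  coordinates single-stranded and testable; the alternative (a strand
  flag with internal flipping) doubles the coordinate cases for no gain
  at amplicon scale. A consequence is that "annotate, then
  reverse-complement everything" is not an identity on effect labels —
  coding effects are intrinsically strand-specific — whereas the
  substitution spectrum is strand-invariant, and is tested as such.
* **Codons truncated by the amplicon boundary** (a frame offset leaves up
  to two leading bases, and the 3' end may cut a codon) are reported as
  `region = "coding"` with `effect = NA` rather than guessed.
* Splice-site or regulatory impact is not modeled; intronic positions are
  plain `noncoding`.

# The forward simulator

`simulateScreen()` generates screens under exactly the generative model
the corrected estimator assumes:

1. per family and amplicon, induced variants are Poisson with mean
   $\rho L$, where $\rho$ is the true per-kb rate — EMS lesions at these
   densities are sparse and independent, so a Poisson count law is the
   natural choice;
2. each variant segregates into the sampled M3 family unless the M2
   parent was homozygous wild type (probability 1/4 under the default
   1:2:1 `segregationProbs`);
3. a segregating variant is detected with probability `detectionProb`
   (default 1).

By Poisson thinning and superposition these three stages collapse to one
draw per amplicon, $m \sim \text{Poisson}(N L \rho \cdot 0.75 \cdot
p_{det})$, which is how the implementation samples counts; classes are
then drawn from `spectrumProbs` (default: the empirical low-dose tomato
spectrum, 9:1:3:2:0:0) and positions uniformly over class-compatible
sites when the amplicon has a sequence (a GC/AT change needs a G or C
reference base), uniformly with synthesized reference bases otherwise.

What the simulator emulates: screening effort ($N$ families per
amplicon), amplicon sizes, Mendelian loss, imperfect detection, the
class spectrum, and seeded reproducibility. What it does not: chimeric M1
plants (each family descends from one germline genome — exactly the
assumption the 0.75 factor encodes), family-to-family rate
heterogeneity, pooling artifacts (`plantsPooled = 4` and `poolSize = 8`
are carried as screen metadata, but detection is governed by
`detectionProb` alone — mismatch-endonuclease sensitivity in 8-fold
pools, mutant:wild-type allele ratio about 1:15 with heterozygous
parents, is not quantified in the source material, so detection is an
explicit assumption rather than a hidden model), and natural
polymorphism contaminating the mutant calls. Passing recovery tests
therefore validate the estimator *under its own assumptions*; they do
not establish detection completeness in a real screen — the
`detectionProb = 0.75` sensitivity test in the suite shows exactly how
undetected alleles masquerade as a lower mutation rate.

`recoveryExperiment()` simulates replicate screens at a known
$1/\rho$, re-estimates with both estimators, and reports bias and
Monte-Carlo standard error. The validation settings used by the test
suite — the seven published amplicon sizes, 1,284 families, a true
density of 1/322 kb, 200 replicates — were chosen to mirror the
high-dose screen design while keeping the whole experiment around a
second of compute; at those settings the Monte-Carlo standard error of
the corrected estimator's mean is a few kb, small enough to resolve the
4/3 inflation of the uncorrected estimator many standard errors away
from the truth. Replicates with zero detected mutations (possible at
tiny designs) are excluded and counted rather than imputed.

# Phenotype catalog

`phenotypeVocabulary()` ships the fixed controlled vocabulary — 17
classes, 51 subclasses — including subclasses with zero recorded plants:
the vocabulary is the instrument, counts are data. Validation is
case-insensitive and whitespace-normalized, and unknown terms report the
nearest valid term by edit distance. `summarizeCatalog()` counts distinct
plants per class and subclass (a plant may appear in several classes but
counts once toward the any-trait fraction), and `queryCatalog()` filters
conjunctively by plant, family, class and subclass. The published
39%/37% any-trait/multi-trait figures require per-plant linkage that the
published per-subclass totals do not carry, so they are not recomputable
targets; the summary computes both fractions for any observation set it
is given.

# Numerical conventions

* Rendered densities round half away from zero to integer kb; percentages
  to one decimal, same rule. All thirteen published per-gene cells
  reproduce under it (none is a tie, but the rule is fixed regardless).
* Zero-mutation cells render `"-"` and parse back as 0; thousands
  separators are accepted on input and never emitted.
* Undefined quantities (density with $m = 0$, percentages over an empty
  base) are `NA` markers, not errors; `populationDensity()` on a cohort
  with no mutations returns `NA` rather than throwing, so a pipeline can
  still write its report with `"-"` markers.
* Dose labels are opaque text keys. Nothing parses "0.7%" out of a
  label; the dose-to-rate mapping belongs to the simulator's parameters.
* All simulation randomness flows from one integer seed; identical
  parameters and seed give identical screens, reports and JSON artifacts
  (the timestamp field aside).

# Limitations

* The estimator treats screened kb as fully informative given
  segregation and detection; it does not model amplicon-specific
  detection windows (primer-proximal blind zones) or GC-content effects.
* Genome-wide extrapolation (mutations per genome) is deliberately out of
  scope: genome size enters nowhere in the arithmetic.
* The spectrum table classifies whatever records it is given; when a
  published spectrum is based on a validated subset of discovered
  mutations, reconciling counts is the caller's responsibility.
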