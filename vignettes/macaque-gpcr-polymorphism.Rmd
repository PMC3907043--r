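---
title: "Comparative polymorphism analysis of macaque GPCR cohorts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative polymorphism analysis of macaque GPCR cohorts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macgpcr)
```

# Scope and model

`macgpcr` implements a comparative polymorphism analysis for targeted
resequencing of G-protein coupled receptor (GPCR) genes in three macaque
populations — Chinese-origin rhesus, Indian-origin rhesus (*Macaca
mulatta*) and cynomolgus (*M. fascicularis*) macaques — of the kind used
to evaluate macaques as models of human receptor variation. The pipeline
has six analysis stages over standard-format inputs (VCF, GFF3, FASTA,
TSV):

1. **Consequence annotation.** Each biallelic variant is assigned one
   region per gene model (CDS, 5'/3' UTR, intron, upstream, downstream
   within a configurable 2 kb flank) and, within the CDS, a coding effect.
   SNVs are evaluated per codon on the coding strand under the standard
   genetic code; indels are frameshifts when the allele-length difference
   is not a multiple of three. One canonical transcript per gene is used;
   when a GFF3 carries several, the longest CDS wins.
2. **Population genetics.** Per population and site we count called
   individuals $n$, alternate alleles $a \in [0, 2n]$ and carriers $c$.
   Missing genotypes reduce $n$ and are never imputed — the per-site $n$
   therefore varies, as in real capture data. A variant is a *singleton*
   when exactly one animal cohort-wide carries the alternate (even if
   homozygous) and *common* with two or more carriers. The unfolded site
   frequency spectrum (SFS) is the histogram of $a$ over sites segregating
   in a population; common variants are partitioned into the seven regions
   of the three-population Venn diagram by carrier presence/absence.
3. **Ortholog domains.** Human and macaque ortholog proteins are aligned
   globally (Needleman–Wunsch, BLOSUM62, affine gaps costing
   $\mathrm{open} + L\cdot\mathrm{extend}$ with defaults 10 and 0.5).
   Human secondary-structure intervals over the 15 canonical GPCR classes
   (N-terminus, TM1–TM7, ICL1–ICL3, ECL1–ECL3, C-terminus) are
   transliterated to the macaque protein as the span of the aligned
   residues; boundary residues opposite gaps shrink intervals inward, and
   intervals aligned wholly to gaps are flagged unmapped. A macaque
   consensus sequence substitutes alternate alleles fixed in every
   population (frequency 1 among called genotypes; missing calls do not
   block fixation), and fixed human–macaque codon differences are
   classified synonymous/non-synonymous. Densities are events per residue
   pooled over genes within each domain class — not per-gene averages —
   separately for singleton/common × synonymous/non-synonymous
   polymorphism and for divergence.
4. **Prediction consensus.** Three external predictors (PolyPhen-2-, SIFT-
   and EvoD-style binary calls, supplied as a table) are aggregated per
   variant. A variant is *eligible* only when its macaque position aligns
   gaplessly to a human residue identical to the macaque reference amino
   acid. With three calls the damaging-vote count maps 3/2/1/0 to
   deleterious / likely deleterious / likely neutral / neutral; with two
   calls unanimity decides and a split is ambiguous; with fewer, ambiguous.
   This vote rule is deliberately isolated in one function
   (`consensus_classify()`) so an alternative scheme can be swapped in.
   Damaging fractions count {deleterious, likely deleterious} and can
   include or exclude ambiguous calls from the denominator (included by
   default; both modes exposed because the convention is not fixed by any
   single standard).
5. **Cross-species matching.** Human variants with allele frequency
   strictly above 0.5% are matched against common macaque non-synonymous
   variants at aligned residues. A gapless column with the same ancestral
   amino acid yields a *recurrent* match when the derived alleles agree
   and a *shared-position divergent* match otherwise. The commonness
   criteria are intentionally asymmetric — a frequency threshold on the
   human side, a carrier count (≥ 2 animals) on the macaque side — because
   the two data sources report different quantities. Frequencies labelled
   "MAF" in the curated reference tables are treated as alternate-allele
   frequencies: one cynomolgus value (0.83) exceeds 0.5, which is
   impossible for a minor allele. Gene + domain co-occurrence records
   every (gene, domain class) holding common non-synonymous variation in
   both species.
6. **Reporting.** `run_pipeline()` executes all stages and writes a
   TSV/JSON bundle plus a STRUCTURE-format genotype export (two rows per
   individual, alleles 1/2, missing −9). Reports are deterministic:
   re-running on the same inputs reproduces identical files.

# The synthetic-data generator

`simulate_cohort()` produces every input with known truth. Its defaults
*are* the study conditions: population sizes 20/44/32; genes laid out as
generic seven-transmembrane receptors (domain-length fractions 15%
N-terminus, 7 × 6% TM helices, 10% ICL3, 21% C-terminus, short remaining
loops); per-genotype missingness 2%.

Site frequencies are drawn i.i.d. per site from a skewed neutral law
$p(i) \propto 1/i^{1+\kappa}$ over derived-allele counts
$i = 1..2n{-}1$ within a randomly chosen population *scope* (private to
one population, both rhesus populations, or the whole cohort; default
probabilities 0.25/0.30/0.25 private, 0.08 rhesus, 0.12 all). The scope
mechanism stands in for the species and subspecies splits: it governs
sharing proportions without simulating coalescent history. The default
skew $\kappa = 1$ was chosen analytically so the expected singleton share
$p(1) = 1/\sum_i i^{-(1+\kappa)} \approx 0.62$ falls inside the 60–82%
band reported for comparable cohorts; $\kappa = 0$ recovers the standard
neutral spectrum, against whose closed form the generator is tested
(singleton share within 3 standard errors).

Purifying constraint is emulated by *thinning*: candidate coding SNVs are
drawn uniformly, and non-synonymous candidates are kept with a per-domain
acceptance multiplier (TM 0.2, ICL1/ICL2 0.4, ECL 0.7, ICL3 0.9, termini
1.0 — most constrained to least), stop gains with probability 0.15,
synonymous candidates always. Human–macaque divergence uses the same
multipliers for non-synonymous substitutions and a flat rate for
synonymous ones, at codons free of macaque polymorphism. Planted
cross-species events (defaults 9 recurrent, 5 shared-position divergent,
6 co-occurrences, mirroring the magnitudes of the reference survey) are
made structurally recoverable: planted macaque variants are forced common
(carriers in ≥ 2 distinct animals, exempt from missingness) and
background human variant rows are placed only at codons carrying no
macaque variant, so recurrent matches are exactly the planted ones.
Predictor calls come from a latent per-variant damaging state
(probability 0.55) with 5% per-predictor flip noise and 5% missingness.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: coalescent/LD structure and recombination
(frequencies are i.i.d. across sites), frequency–selection coupling (the
constraint thinning removes non-synonymous *sites* but does not shift the
frequencies of the survivors, so simulated synonymous and non-synonymous
spectra share the same singleton share, whereas in real cohorts the
non-synonymous spectrum is markedly more singleton-skewed), sequencing
error and depth variation, indel divergence between the orthologs (protein lengths are
equal by default; domain transfer under indels is exercised by
hand-constructed alignments in the test suite), multi-transcript genes,
and ascertainment bias in the human variant table.

# Numerical and design choices

* **Coordinates** are 1-based and closed everywhere; indels use the VCF
  anchor-base convention. Multiallelic sites are decomposed into one
  biallelic record per alternate allele, never dropped.
* **Alignment** is global, not local, because orthologs are full-length
  curated sequences; gap parameters are configurable. Tie-breaking among
  equal-scoring paths follows the aligner's deterministic traceback; the
  test suite pins score optimality against an independent
  dynamic-programming oracle on short pairs, where the optimum is unique
  up to path.
* **"Fixed"** requires zero alternate-allele heterogeneity among called
  genotypes in every population — the strictest reading; missing
  genotypes do not block fixation. A fixed frame-breaking indel excludes
  the gene from divergence.
* **Variants spanning a CDS boundary** are classified CDS (frameshift if
  indel) — conservative handling of a rare case.
* **High-frequency ranking** uses the maximum per-population
  alternate-allele frequency, descending, with genomic-coordinate
  tie-break; "most common" has no unique definition and this one is
  declared.
* **Singleton classification is cohort-wide** by default (one carrier
  among all 96 animals); the per-population view is available through
  `build_sfs()` whose singleton class is per population by construction.
* **Degenerate inputs**: an empty VCF yields empty-but-valid reports; an
  empty stratum yields an NA damaging fraction rather than an error;
  genes without alignments are skipped from cross-species matching with
  the skip visible in the outputs.

# Problem sizes

The shipped analysis scripts and tests run at desk scale, chosen as the
package's own validation conditions: 12 genes × 300 codons for the
worked pipeline (≈ 2–3 thousand variants over 96 animals), 20 × 300 with
denser mutation for parameter-recovery checks (> 2,000 non-synonymous
events, enough to resolve the five constraint tiers), and 30 × 100 in a
single population for the neutral-spectrum comparison (> 2,000
segregating sites). Headline genome-wide counts of the motivating study
design (10^5 variants over 377 receptors) are products of raw sequencing
volume and are out of scope; every property validated here is
scale-invariant.

# Limitations

The consensus vote rule is a stand-in for published "evolutionarily
balanced" predictor-combination schemes, which are not restated in the
survey literature this package's tables derive from; it is isolated for
replacement. Reference tables ship as curated TSVs and the synthetic
ortholog sequences built around them are labelled stand-ins — positions
and amino acids are real, the surrounding sequence is not. UTR annotation
quality is taken from the supplied GFF3 as-is.
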