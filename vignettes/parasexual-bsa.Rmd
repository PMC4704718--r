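---
title: "Mapping classical fungal mutants by parasexual bulk segregant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping classical fungal mutants by parasexual bulk segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parabsa)
```

## The model

`parabsa` models the identification of a recessive trait mutation in an
asexual filamentous fungus by bulk segregant analysis (BSA) through the
parasexual cycle. The biological chain it formalizes is:

1. **Diploid formation.** Two haploid parents carrying complementary
   spore-color markers (one fawn `fwnA` mutant, one olive `olvA` mutant)
   and complementary auxotrophies fuse into a heterokaryon; black-spored,
   prototrophic colonies identify the heterozygous diploid.
   `form_diploid()` enforces exactly these two selection requirements and
   refuses non-complementary parents, because without them neither the
   balanced heterokaryon nor the visual diploid screen exists.
2. **Haploidization.** Under benomyl the diploid loses one homolog of
   each chromosome pair. `haploidize()` draws every chromosome
   independently from homolog A or B with probability 1/2. With
   probability `p_mitotic_rec` per chromosome a segregant instead
   receives a single-breakpoint mitotic recombinant: the breakpoint is
   uniform on `[1, length)`, the proximal source uniform on {A, B}.
   Whole-chromosome provenance (including breakpoints) is recorded on
   every segregant, so allele inheritance is auditable after the fact.
3. **Phenotype and pooling.** `derive_phenotypes()` encodes the marker
   chemistry of the cross: `fwnA` is epistatic over `olvA` (a double
   mutant is visually fawn); uridine prototrophy is conferred only by the
   `olvA::pyrG` insertion, because both native `pyrG` loci in the cross
   are defective — this is what makes double mutants detectable as
   fawn-but-prototrophic; `argB::hygB` removes arginine prototrophy;
   `nac` (the trait mutation, a laeA-type regulator allele) abolishes
   acidification; `prtT` lowers protease activity. `select_pool()`
   collects the trait carriers.
4. **Pooled sequencing.** `simulate_sample_calls()` draws per-site depth
   `Poisson(mean_depth)` and alt reads `Binomial(depth, q)` with
   `q = p(1-e) + (1-p)e/3`: each read errs with probability `e`, and an
   error lands on any of the three other bases uniformly.
5. **SNP pipeline.** `validate_variants()` accepts a site when the
   in-sample variant frequency is at least 0.7 in at least 20 reads,
   both boundaries inclusive and without quality filtering;
   `derive_parental_snpset()` keeps sites validated in exactly one
   parent. `scan_pool_conservation()` orients every pool frequency to
   the trait parent's allele, so conservation is always "fraction of the
   pool carrying the mutagenized parent's allele".
   `classify_conservation()` splits fully conserved / high / unlinked,
   `annotate_coding_effect()` triages candidates by coding consequence,
   and `rank_candidates()` orders them.
6. **Linkage.** `pairwise_linkage()` counts parental vs nonparental
   segregants per marker pair and reports `r = NPS/N × 100%`;
   `segregation_ratio_test()` is the exact two-sided binomial test of
   1:1 segregation.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_freq` | 0.7 | fraction | in-sample variant validation threshold, inclusive |
| `min_depth` | 20 | reads | minimum coverage for validation, inclusive |
| `pool_min_freq` | 0.3 | fraction | reporting floor for pool variants; does not affect classes above it |
| `full_threshold` | 0.995 | fraction | lower bound of "fully conserved" |
| `high_threshold` | 0.95 | fraction | lower bound of "high" conservation |
| `p_mitotic_rec` | 0.013 | per chromosome per segregant | calibrated so about one crossover is expected on a given chromosome among 78 pool members, matching the single recombinant the pool-scan design anticipates |
| `mean_depth_strain` / `mean_depth_pool` | 100 / 300 | reads/site | keep the 0.7/20 filter comfortably exercised; depth itself is not a published per-site quantity, only total yields are |
| `error_rate` | 0.002 | per read | typical short-read substitution scale |

The conservation class boundaries deserve a note: no numeric definition
of "completely conserved" versus "high (~98%)" exists beyond the
observed 78/78 and 77/78 pools, so the defaults are chosen to put those
two observations in the intended classes with headroom
(78/78 = 1 ≥ 0.995; 77/78 = 0.987 ∈ [0.95, 0.995)). Both are arguments,
not constants. Classification prefers exact genotype-level conservation
when pool genotypes are available, falling back to the read-level
estimate: at realistic pool depths (~300×) read noise alone would
occasionally push a truly fixed allele below any sharp threshold, which
is a sequencing artifact, not a genetic signal.

## The synthetic study fixture

`study_config()` + `build_study_fixture()` reconstruct a complete
mapping experiment deterministically from a seed:

* 8 chromosomes (3.0 and 3.5 Mb for the two marker-bearing ones,
  1.0–1.6 Mb otherwise — small enough to regenerate in seconds, large
  enough to hold the published causal coordinate);
* six classical markers; the color pair sits on chromosome "I" with the
  `argB` marker, the trait marker on chromosome II at the causal
  coordinate, `prtT` on chromosome VI;
* 52 inter-parental SNPs. Chromosome II carries six from the trait
  parent inside a ~1.4 Mb window: the causal G→C at 1,762,101 (codon
  327, GCC→CCC, Ala→Pro, in a single-exon laeA-like toy gene), an
  intronic SNP in a two-exon fumR-like toy gene, one noncoding SNP, and
  three sites distal to the pool recombinant's breakpoint. The other 46
  are placed uniformly (seeded) on the remaining chromosomes and split
  evenly between the parents; two of them are planted inside toy genes
  (the prtT-13 T→C in a CTA codon, and a tester-parent SNP in a
  reverse-strand gene) so that the coding triage and strand handling are
  exercised by realistic inputs. Only the counts, not the coordinates,
  of the scattered SNPs carry information, so synthetic placement is
  adequate;
* 140 segregants whose marker marginals match the published table
  exactly (64/76 color, 78/62 uridine, 64/76 arginine, 78/62
  acidification, 72/68 protease), with exactly two fwnA/olvA double
  mutants, zero black recombinants, and two arginine-side recombinants.
  These cells are satisfied by constrained construction — the plate
  sampling rule that produced the real marginals (at most two
  differently colored sectors per plate) is not modelled, so free
  simulation would only match them in expectation — while the joint
  assignment across chromosomes is randomized by independent seeded
  shuffles, consistent with independent chromosome assortment. One
  published pairwise table is knowingly not reproduced cell-for-cell:
  its arginine-marker joint counts are arithmetically inconsistent with
  the marker marginals under any single-crossover model (they require a
  negative class count), so the fixture matches the marginals and
  accepts 2/2 instead of 1/1 off-diagonal recombinants;
* the 78 nonacidifying segregants form the pool; exactly one member is
  a chromosome-II recombinant with breakpoint at 2.0 Mb, placed between
  the causal site and the distal SNP trio, reproducing the
  3 × 78/78 + 3 × 77/78 conservation signature.

`write_fixture()` emits everything as plain text (FASTA, GFF3, TSV,
minimal VCF with `DP:AD` fields) with a checksum manifest;
byte-identical across runs with the same seed.

### What the generator does *not* emulate

Aneuploid or partially diploid sectors, non-independent segregants from
shared sectors, unequal DNA contribution of pool members, mapping bias,
indels, multi-allelic sites, and base-quality structure are all absent.
Passing tests therefore demonstrate the statistical logic of the method
— conservation contrast, filter behaviour, linkage estimation — under
its own assumptions, not robustness of any real variant-calling stack.

## Numerical and design choices

* **Coordinates** are 1-based fully closed (GFF3 convention); SNP
  ref/alt are forward-strand bases, complemented for reverse-strand
  genes (VCF convention).
* **Inclusive thresholds.** The validation filter compares
  `alt/depth ≥ min_freq` with a `1e-9` slack so that exact rational
  boundaries such as 14/20 against 0.7 are never lost to floating-point
  representation. Depth-0 sites are skipped and logged, never validated.
* **Crossover model.** At most one crossover per chromosome per
  segregant, breakpoint uniform: mitotic recombination is rare, and a
  single event is the only signal the pool scan is designed around;
  richer models would add unconstrained parameters.
* **Ranking tie-breaks** are total and deterministic: conservation
  class, then consequence (missense/nonsense, synonymous, intronic,
  noncoding), then descending conservation, then chromosome and
  position.
* **Recombination frequencies above 50%** are reported as computed with
  a flag, rather than clamped: on finite tables they indicate
  mis-specified phase, and hiding them would hide the problem.
* **No multiple-testing control** in the scan: the method uses absolute
  conservation, not hypothesis tests; per-SNP exact binomial deviations
  from 0.5 are emitted as auxiliary output only.
* **Seeding.** Every stochastic component takes an explicit seed and
  runs under `withr::with_seed`, so the caller's RNG state is never
  disturbed and a master seed fans out to per-stage child seeds kept
  inside the 32-bit range `set.seed` requires.
* **Problem sizes in the test suite.** The stochastic property checks
  use 200 replicate pools (mean unlinked frequency vs 50%), 50
  replicate full-pipeline crosses (causal-SNP recovery), 10,000
  segregants (co-segregation limits) and depth 10^5 (read/genotype
  agreement); these sizes give three-standard-error margins that are
  tight relative to the effects tested while keeping the whole suite in
  the low minutes on one CPU.

## Known limitations

* The phenotype map is the chemistry of *this* cross (six channels, the
  `olvA::pyrG` and `hygB` insertions); other marker systems need their
  own mapping.
* The conservation scan assumes a haploid pool of euploid segregants;
  contamination by diploid sectors would compress the conservation
  contrast and is not modelled.
* Conservation of a linked SNP equals one minus the recombinant
  fraction only under the single-crossover model; double crossovers
  (not simulated) would break the monotone distance–conservation
  relationship.
* The two published span figures for the conserved region (1.4 vs
  1.6 Mb) are not reconciled; the pipeline reports the observed span of
  conserved SNPs and leaves interpretation to the analyst.
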