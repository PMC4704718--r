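# parabsa

Bulk segregant analysis (BSA) through the fungal parasexual cycle.

## The problem

Classical mutants of asexual industrial fungi such as *Aspergillus niger*
cannot be mapped by meiotic crossing: the species has no sexual cycle.
The parasexual cycle offers a workaround — two complementary-marked
haploid parents are fused into a heterozygous diploid, and haploid
segregants are recovered by spontaneous loss of one homolog of each
chromosome pair (accelerated with benomyl). Chromosomes therefore
segregate as whole units, separated only by rare mitotic crossovers.

Pooling the segregants that display the mutant trait and sequencing the
pool then localizes the causal mutation: at the causal site every pool
member carries the mutagenized parent's allele (conservation
$c = m/n = 1$), SNPs linked to it are conserved at
$c = 1 - f_\mathrm{rec}$ where $f_\mathrm{rec}$ is the fraction of pool
members recombinant between the two sites, and unlinked SNPs sit near
$c = 0.5$. Classical two-point linkage between phenotype markers uses the
recombination frequency $r = \mathrm{NPS}/N \times 100\%$, with
nonparental segregants (NPS) counted against the parents' allele
combinations.

`parabsa` implements this whole workflow as composable, seeded
components, for methodologists who want to study the design of
parasexual BSA experiments (pool sizes, depths, filter thresholds) and
for teaching:

* **Cross simulation** — diploid selection from complementary-marked
  parents, haploidization by whole-chromosome loss with at most one
  uniform-breakpoint mitotic crossover per chromosome, phenotype
  derivation (including spore-color epistasis and marker insertions),
  trait-based pool selection.
* **Pooled sequencing simulation** — per-site Poisson depth and binomial
  alt counts under a symmetric read-error model.
* **SNP pipeline** — variant validation (frequency ≥ 0.7 in ≥ 20 reads,
  both inclusive, no quality filtering), inter-parental SNP derivation,
  pool conservation scan oriented to the trait parent's allele,
  conservation classes (fully conserved / high / unlinked), coding-effect
  annotation via GFF3 gene models and the standard genetic code, and
  candidate ranking.
* **Linkage analysis** — per-marker allele distributions, all-pairs
  PS/NPS counts and recombination frequencies, exact binomial
  segregation-ratio tests.
* **Study fixture** — a deterministic synthetic reconstruction of a real
  mapping cross: 8 chromosomes, 6 classical markers, 52 inter-parental
  SNPs, 140 segregants matching the published marker marginals, and a
  78-member nonacidifying pool containing exactly one chromosome-II
  recombinant.

## Worked example

```r
library(parabsa)

fx <- build_study_fixture(study_config(rng_seed = 1))
length(fx$segregants)            # 140 haploid segregants
length(fx$pool$member_ids)       # 78 nonacidifying pool members

snpset <- derive_parental_snpset(fx$calls_A, fx$calls_B)
nrow(snpset)                     # 52 inter-parental SNPs

records <- classify_conservation(
  scan_pool_conservation(snpset, fx$calls_pool, fx$pool_genotypes))
table(records$conservation_class)
#> fully_conserved  high  unlinked
#>               3     3        46

effects <- annotate_snps(snpset, fx$reference$genes, fx$reference$genome)
ranked  <- rank_candidates(records, effects)
ranked[1, c("snp_id", "pos", "consequence", "ref_codon", "alt_codon",
            "ref_aa", "alt_aa", "codon_index")]
#>           snp_id     pos consequence ref_codon alt_codon ref_aa alt_aa codon_index
#> 1 snp_II_1762101 1762101    missense       GCC       CCC      A      P         327
```

The top-ranked candidate is the chromosome II G→C SNP at position
1762101: the only fully conserved SNP in a protein-coding region,
changing codon 327 from GCC (Ala) to CCC (Pro) in the toy laeA-like
gene. The three SNPs distal to the single pool recombinant's breakpoint
are conserved at 77/78 = 98.7% ("high"), everything off chromosome II
sits near 50%.

Two-point marker linkage on the same cohort:

```r
allele_distribution(fx$table)        # e.g. nac: 78 A (nonacidifying) / 62 B
pairwise_linkage(fx$table, "fwnA", "olvA")$r_percent   # 0 (color pair)
```

A thin command-line front end wraps the same functions:

```sh
Rscript exec/parabsa make-fixture --seed 1 --out fixture/
Rscript exec/parabsa run-all --fixture-dir fixture/ --out run/
```

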