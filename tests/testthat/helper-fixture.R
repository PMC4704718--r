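# Shared objects for the whole suite. The study fixture is built once
# (seed 42) and reused; individual tests that need different seeds build
# their own reduced configurations.

study_fx <- build_study_fixture(study_config(rng_seed = 42))

# A small two-chromosome universe for cross-simulation unit tests:
# two markers on chromosome c1 (positions 300 and 700), one on c2.
small_karyotype <- karyotype_map(c("c1", "c2"), c(1000, 800))

small_markers <- marker_table(data.frame(
  marker_id = c("fwnA", "olvA", "nac"),
  chrom = c("c1", "c1", "c2"),
  pos = c(300, 700, 400),
  wild_allele = c("w", "w", "w"),
  mutant_allele = c("m", "m", "m"),
  phenotype_channel = c("spore_color", "spore_color", "acidification"),
  epistasis_rank = c(1L, 2L, 1L),
  stringsAsFactors = FALSE))

small_snps <- snp_table(data.frame(
  snp_id = c("s1", "s2"), chrom = c("c1", "c2"), pos = c(500, 200),
  ref = c("A", "C"), alt = c("G", "T"),
  origin_parent = c("A", "B"), stringsAsFactors = FALSE))

small_parents <- list(
  parent_A = haploid_genotype(
    "pA",
    c(fwnA = "mutant", olvA = "wild", nac = "mutant"),
    c(s1 = "alt", s2 = "ref")),
  parent_B = haploid_genotype(
    "pB",
    c(fwnA = "wild", olvA = "mutant", nac = "wild"),
    c(s1 = "ref", s2 = "alt")))

# form_diploid for the small universe requires study-style complementary
# auxotrophies (pyrG/argB); bypass selection and build the diploid directly.
small_diploid <- structure(
  list(homolog_A = small_parents$parent_A,
       homolog_B = small_parents$parent_B),
  class = "diploid_genotype")

# A second small universe whose two same-chromosome markers (nac at 300,
# prtT at 700 on c1) are observable through independent phenotype channels,
# unlike the color pair, so recombinants between them are directly visible.
obs_markers <- marker_table(data.frame(
  marker_id = c("nac", "prtT"),
  chrom = c("c1", "c1"),
  pos = c(300, 700),
  wild_allele = c("w", "w"),
  mutant_allele = c("m", "m"),
  phenotype_channel = c("acidification", "protease"),
  epistasis_rank = c(1L, 1L),
  stringsAsFactors = FALSE))

obs_parents <- list(
  parent_A = haploid_genotype("pA", c(nac = "mutant", prtT = "mutant"),
                              c(s1 = "alt")),
  parent_B = haploid_genotype("pB", c(nac = "wild", prtT = "wild"),
                              c(s1 = "ref")))

obs_diploid <- structure(
  list(homolog_A = obs_parents$parent_A, homolog_B = obs_parents$parent_B),
  class = "diploid_genotype")

obs_snps <- snp_table(data.frame(
  snp_id = "s1", chrom = "c1", pos = 500, ref = "A", alt = "G",
  origin_parent = "A", stringsAsFactors = FALSE))

# Brute-force oracle for the validation filter using exact integer
# arithmetic (freq >= 0.7 as 10 * alt >= 7 * depth).
oracle_validate_07_20 <- function(depth, alt) {
  depth > 0 & depth >= 20 & 10 * alt >= 7 * depth
}
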