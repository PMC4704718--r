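test_that("diploid selection requires complementary parents", {
  p <- study_fx$parents
  markers <- study_fx$config$markers
  d <- form_diploid(p$parent_A, p$parent_B, markers)
  expect_identical(d$homolog_A$marker_alleles, p$parent_A$marker_alleles)
  expect_identical(d$homolog_A$snp_alleles, p$parent_A$snp_alleles)
  ph <- diploid_phenotype(d, markers)
  expect_equal(ph$spore_color, "black")
  expect_true(ph$pyrG_prototroph)
  expect_true(ph$argB_prototroph)
  expect_true(ph$acidifying)
  expect_error(form_diploid(p$parent_A, p$parent_A, markers),
               class = "selection_impossible")
})

test_that("haploidization without crossover co-inherits whole chromosomes", {
  seg <- haploidize(small_diploid, cross_config(200, 0, rng_seed = 5),
                    small_karyotype, small_markers, small_snps)
  expect_length(seg, 200)
  for (s in seg) {
    expect_true(all(s$provenance %in% c("A", "B")))
    # fwnA, olvA and s1 all sit on c1: alleles must trace to one homolog
    src <- s$provenance[["c1"]]
    parent <- if (src == "A") small_parents$parent_A else small_parents$parent_B
    expect_equal(s$genotype$marker_alleles[["fwnA"]],
                 parent$marker_alleles[["fwnA"]])
    expect_equal(s$genotype$marker_alleles[["olvA"]],
                 parent$marker_alleles[["olvA"]])
    expect_equal(s$genotype$snp_alleles[["s1"]], parent$snp_alleles[["s1"]])
  }
  # each chromosome drawn from homolog A with probability 1/2
  frac_A <- mean(vapply(seg, function(s) s$provenance[["c1"]] == "A", logical(1)))
  expect_lt(abs(frac_A - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("forced crossover frequency matches breakpoint enumeration", {
  # two loci at 300 and 700 on a 1000 bp chromosome; with exactly one
  # uniform breakpoint on [1, 1000) a nonparental combination arises iff
  # the breakpoint falls in [300, 699]: 400 of the 999 possible breakpoints.
  expected <- 400 / 999
  n <- 4000
  seg <- haploidize(obs_diploid, cross_config(n, 1, rng_seed = 9),
                    karyotype_map("c1", 1000), obs_markers, obs_snps)
  # parent A is mutant at both loci, so a nonparental combination means
  # exactly one of the two alleles is mutant
  nonparental <- vapply(seg, function(s) {
    (s$genotype$marker_alleles[["nac"]] == "mutant") !=
      (s$genotype$marker_alleles[["prtT"]] == "mutant")
  }, logical(1))
  expect_lt(abs(mean(nonparental) - expected),
            3 * sqrt(expected * (1 - expected) / n))
})

test_that("provenance codes are consistent with inherited alleles", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      seg <- haploidize(small_diploid,
                        cross_config(50, runif(1), rng_seed = sample(1e6, 1)),
                        small_karyotype, small_markers, small_snps)
      for (s in seg) {
        for (i in seq_len(nrow(small_markers))) {
          src <- parabsa:::source_at(s$provenance, small_markers$chrom[i],
                                     small_markers$pos[i])
          parent <- if (src == "A") small_parents$parent_A else small_parents$parent_B
          id <- small_markers$marker_id[i]
          expect_equal(s$genotype$marker_alleles[[id]],
                       parent$marker_alleles[[id]])
        }
      }
    }
  })
})

test_that("phenotype derivation implements the cross's marker chemistry", {
  markers <- study_fx$config$markers
  ph_A <- derive_phenotypes(study_fx$parents$parent_A, markers)
  expect_equal(ph_A$spore_color, "fawn")
  expect_false(ph_A$pyrG_prototroph)
  expect_true(ph_A$argB_prototroph)
  expect_false(ph_A$acidifying)
  expect_false(ph_A$protease_full)
  expect_true(ph_A$hygromycin_resistant)

  ph_B <- derive_phenotypes(study_fx$parents$parent_B, markers)
  expect_equal(ph_B$spore_color, "olive")
  expect_true(ph_B$pyrG_prototroph)
  expect_false(ph_B$argB_prototroph)
  expect_true(ph_B$acidifying)
  expect_true(ph_B$protease_full)

  # fwnA epistasis: a fwnA/olvA double mutant is fawn and pyrG prototrophic
  double <- haploid_genotype("dbl", c(
    fwnA = "mutant", olvA = "mutant", pyrG = "mutant", argB = "wild",
    nac = "wild", prtT = "wild"), character(0))
  ph_d <- derive_phenotypes(double, markers)
  expect_equal(ph_d$spore_color, "fawn")
  expect_true(ph_d$pyrG_prototroph)

  wild <- haploid_genotype("wt", setNames(rep("wild", 6), markers$marker_id),
                           character(0))
  ph_w <- derive_phenotypes(wild, markers)
  expect_equal(ph_w$spore_color, "black")
  expect_true(ph_w$argB_prototroph)
  expect_true(ph_w$acidifying)
  expect_false(ph_w$hygromycin_resistant)
  expect_false(ph_w$pyrG_prototroph)  # native pyrG alleles are defective

  incomplete <- haploid_genotype("x", c(fwnA = "wild"), character(0))
  expect_error(derive_phenotypes(incomplete, markers),
               class = "incomplete_genotype")
})

test_that("no genotype is both fawn and olive; fwnA masks olvA", {
  markers <- study_fx$config$markers
  withr::with_seed(31, {
    for (rep in 1:50) {
      al <- sample(c("wild", "mutant"), 6, replace = TRUE)
      g <- haploid_genotype("g", setNames(al, markers$marker_id), character(0))
      ph <- derive_phenotypes(g, markers)
      expect_true(ph$spore_color %in% c("black", "fawn", "olive"))
      if (al[markers$marker_id == "fwnA"] == "mutant")
        expect_equal(ph$spore_color, "fawn")
    }
  })
})

test_that("pool selection filters by trait, preserving order", {
  seg <- haploidize(small_diploid, cross_config(60, 0, rng_seed = 3),
                    small_karyotype, small_markers, small_snps)
  carriers <- vapply(seg, function(s)
    s$genotype$marker_alleles[["nac"]] == "mutant", logical(1))
  pool <- select_pool(seg, is_nonacidifying, small_markers)
  expect_length(pool, sum(carriers))
  expect_identical(vapply(pool, `[[`, character(1), "segregant_id"),
                   vapply(seg[carriers], `[[`, character(1), "segregant_id"))
  all_of_them <- select_pool(seg, function(ph) TRUE, small_markers)
  expect_identical(all_of_them, seg)
  expect_warning(empty <- select_pool(seg, function(ph) FALSE, small_markers),
                 "empty pool")
  expect_length(empty, 0)
})

test_that("without crossover, same-chromosome loci never recombine and
           different-chromosome loci approach 50%", {
  n <- 10000
  seg <- haploidize(small_diploid, cross_config(n, 0, rng_seed = 77),
                    small_karyotype, small_markers, small_snps)
  tab <- segregants_to_table(seg, small_markers)
  same_chrom <- pairwise_linkage(tab, "fwnA", "olvA")
  expect_equal(same_chrom$nps_count, 0)
  expect_equal(same_chrom$r_percent, 0)
  diff_chrom <- pairwise_linkage(tab, "fwnA", "nac")
  expect_lt(abs(diff_chrom$r_percent - 50), 3 * sqrt(2500 / n))
})
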