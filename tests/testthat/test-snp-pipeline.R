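calls_df <- function(depth, alt, id = sprintf("s%d", seq_along(depth))) {
  sample_calls(data.frame(snp_id = id, chrom = "c1", pos = seq_along(depth),
                          ref = "A", alt = "G", depth = depth,
                          alt_count = alt, stringsAsFactors = FALSE), "x")
}

test_that("variant validation applies inclusive 0.7 / 20-read thresholds", {
  # depth 19 at frequency 1.0 fails coverage; depth 20 with 14 alt reads
  # (frequency exactly 0.7) passes both
  calls <- calls_df(depth = c(19, 20, 20, 100, 0),
                    alt = c(19, 14, 13, 69, 0))
  v <- validate_variants(calls)
  expect_setequal(as.character(v), "s2")
  expect_equal(attr(v, "skipped"), "s5")
})

test_that("validation equals the brute-force oracle on random tables", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      depth <- sample(0:60, 200, replace = TRUE)
      alt <- vapply(depth, function(d) sample(0:d, 1), integer(1))
      calls <- calls_df(depth, alt)
      got <- calls$snp_id %in% validate_variants(calls)
      expect_identical(got, oracle_validate_07_20(depth, alt))
    }
  })
})

test_that("inter-parental SNP derivation keeps exactly-one-parent variants", {
  depth <- rep(50, 4)
  a <- calls_df(depth, alt = c(50, 0, 49, 1))
  b <- calls_df(depth, alt = c(0, 50, 48, 0))
  snpset <- derive_parental_snpset(a, b)
  expect_setequal(snpset$snp_id, c("s1", "s2"))
  expect_equal(snpset$origin_parent[snpset$snp_id == "s1"], "A")
  expect_equal(snpset$origin_parent[snpset$snp_id == "s2"], "B")
  expect_equal(attr(snpset, "shared"), "s3")
})

test_that("conservation scan orients frequencies to the trait parent", {
  fx <- study_fx
  snpset <- derive_parental_snpset(fx$calls_A, fx$calls_B)
  rec <- scan_pool_conservation(snpset, fx$calls_pool, fx$pool_genotypes)
  causal <- rec[rec$snp_id == "snp_II_1762101", ]
  expect_equal(causal$genotype_conservation, 1.0)
  distal <- rec[rec$pos %in% fx$config$chrII_distal_pos, ]
  expect_equal(distal$genotype_conservation, rep(77 / 78, 3))
  # origin-B SNPs are oriented to the trait parent's (reference) allele
  b_snp <- rec[rec$origin_parent == "B", ][1, ]
  raw_alt <- true_pool_frequency(fx$pool_genotypes, b_snp$snp_id)
  expect_equal(b_snp$genotype_conservation, 1 - raw_alt)
  expect_false(any(rec$below_threshold[rec$origin_parent == "A" &
                                         rec$chrom == "II"]))
})

test_that("read-level conservation of a 77/78 pool concentrates on 0.9872", {
  pool <- lapply(1:78, function(i) haploid_genotype(
    sprintf("g%d", i), character(0),
    c(s1 = if (i <= 77) "alt" else "ref")))
  snps <- snp_table(data.frame(snp_id = "s1", chrom = "II", pos = 100,
                               ref = "G", alt = "C", origin_parent = "A"))
  calls <- simulate_sample_calls(pool, snps, coverage_model(1e5, 0, rng_seed = 15))
  rec <- scan_pool_conservation(snps, calls, pool)
  expect_lt(abs(rec$read_frequency - 77 / 78), 0.01)
  expect_equal(rec$genotype_conservation, 77 / 78)
})

test_that("conservation classes split at 0.995 and 0.95", {
  rec <- data.frame(snp_id = c("a", "b", "c"), chrom = "II", pos = 1:3,
                    ref = "G", alt = "C", origin_parent = "A",
                    pool_depth = 100,
                    read_frequency = c(0.99, 0.99, 0.99),
                    genotype_conservation = c(1.0, 77 / 78, 0.51),
                    below_threshold = FALSE)
  cls <- classify_conservation(rec)$conservation_class
  expect_equal(cls, c("fully_conserved", "high", "unlinked"))
  # read frequency is the fallback when genotypes are unavailable
  rec$genotype_conservation <- NA_real_
  expect_equal(classify_conservation(rec)$conservation_class,
               rep("high", 3))
})

test_that("coding-effect annotation recovers the published substitutions", {
  ref <- study_fx$reference
  causal <- ref$snps[ref$snps$snp_id == "snp_II_1762101", ]
  eff <- annotate_coding_effect(causal, ref$genes, ref$genome)
  expect_equal(eff$gene_id, "laeA_toy")
  expect_equal(eff$codon_index, 327L)
  expect_equal(eff$ref_codon, "GCC")
  expect_equal(eff$alt_codon, "CCC")
  expect_equal(eff$ref_aa, "A")
  expect_equal(eff$alt_aa, "P")
  expect_equal(eff$consequence, "missense")

  prtT <- ref$snps[ref$snps$chrom == "VI" & ref$snps$pos == 800449, ]
  eff2 <- annotate_coding_effect(prtT, ref$genes, ref$genome)
  expect_equal(eff2$ref_codon, "CTA")
  expect_equal(eff2$alt_codon, "CCA")
  expect_equal(eff2$ref_aa, "L")
  expect_equal(eff2$alt_aa, "P")
  expect_equal(eff2$consequence, "missense")

  intronic <- list(chrom = "II", pos = 1550000,
                   ref = as.character(Biostrings::subseq(
                     ref$genome[["II"]], 1550000, 1550000)), alt = "A")
  if (intronic$ref == "A") intronic$alt <- "C"
  eff3 <- annotate_coding_effect(intronic, ref$genes, ref$genome)
  expect_equal(eff3$consequence, "intronic")
  expect_equal(eff3$gene_id, "fumR_toy")

  noncoding <- ref$snps[ref$snps$chrom == "III", ][1, ]
  expect_equal(annotate_coding_effect(noncoding, ref$genes,
                                      ref$genome)$consequence, "noncoding")

  mismatch <- causal
  mismatch$ref <- "A"
  expect_error(annotate_coding_effect(mismatch, ref$genes, ref$genome),
               class = "reference_mismatch")
})

test_that("third-position wobble changes are synonymous", {
  genome <- c(c1 = paste0("TTTTTTTTT", "ATGGCCTAA", "TTT"))
  gene <- gene_model("g", "c1", "+", cbind(10, 18))
  # GCC -> GCA: codon 2 third position
  snp <- list(chrom = "c1", pos = 15, ref = "C", alt = "A")
  eff <- annotate_coding_effect(snp, list(gene), genome)
  expect_equal(eff$consequence, "synonymous")
  expect_equal(eff$ref_aa, "A")
  expect_equal(eff$alt_aa, "A")
})

test_that("candidate ranking puts conserved coding SNPs first", {
  fx <- study_fx
  snpset <- derive_parental_snpset(fx$calls_A, fx$calls_B)
  rec <- classify_conservation(
    scan_pool_conservation(snpset, fx$calls_pool, fx$pool_genotypes))
  eff <- annotate_snps(snpset, fx$reference$genes, fx$reference$genome)
  ranked <- rank_candidates(rec, eff)
  expect_equal(ranked$snp_id[1], "snp_II_1762101")
  expect_equal(ranked$consequence[1], "missense")
  expect_equal(sum(ranked$conservation_class == "fully_conserved"), 3)

  expect_equal(nrow(rank_candidates(rec[0, ], eff[0, ])), 0)
})

test_that("ranking agrees with a brute-force sort of the stated key", {
  withr::with_seed(17, {
    n <- 40
    rec <- data.frame(
      snp_id = sprintf("s%02d", 1:n),
      chrom = sample(c("I", "II", "III"), n, replace = TRUE),
      pos = sample(1e6, n), ref = "G", alt = "C",
      origin_parent = "A", pool_depth = 100,
      read_frequency = runif(n),
      genotype_conservation = NA_real_, below_threshold = FALSE)
    rec <- classify_conservation(rec)
    eff <- data.frame(
      snp_id = rec$snp_id,
      gene_id = NA, codon_index = NA, ref_codon = NA, alt_codon = NA,
      ref_aa = NA, alt_aa = NA,
      consequence = sample(c("missense", "nonsense", "synonymous",
                             "intronic", "noncoding"), n, replace = TRUE))
    ranked <- rank_candidates(rec, eff)
    oracle <- merge(rec, eff, by = "snp_id")
    cls_key <- c(fully_conserved = 1, high = 2, unlinked = 3)
    csq_key <- c(missense = 1, nonsense = 1, synonymous = 2, intronic = 3,
                 noncoding = 4)
    oracle <- oracle[order(cls_key[oracle$conservation_class],
                           csq_key[oracle$consequence],
                           -oracle$read_frequency, oracle$chrom, oracle$pos), ]
    expect_equal(ranked$snp_id, oracle$snp_id)
  })
})
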