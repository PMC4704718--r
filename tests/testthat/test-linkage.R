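toy_table <- function(codes) {
  df <- as.data.frame(codes, stringsAsFactors = FALSE)
  df$segregant_id <- sprintf("s%d", seq_len(nrow(df)))
  genotype_table(df, markers = names(codes))
}

test_that("allele distribution tallies the fixture's published marginals", {
  dist <- allele_distribution(study_fx$table)
  expect_true(all(dist$count_A + dist$count_B == 140))
  expect_equal(dist$count_A[dist$marker_id == "nac"], 78)   # nonacidifying
  expect_equal(dist$count_B[dist$marker_id == "nac"], 62)   # acidifying
  expect_equal(dist$count_A[dist$marker_id == "fwnA"], 64)
  expect_equal(dist$count_B[dist$marker_id == "olvA"], 76)
  expect_equal(dist$count_B[dist$marker_id == "pyrG"], 78)  # pyrG+
  expect_equal(dist$count_A[dist$marker_id == "argB"], 64)  # argB+
  expect_equal(dist$count_A[dist$marker_id == "prtT"], 72)  # protease-low
})

test_that("allele distribution equals a brute-force column tally", {
  single <- toy_table(list(m1 = "A", m2 = "B"))
  d1 <- allele_distribution(single)
  expect_equal(d1$count_A, c(1, 0))
  expect_equal(d1$count_B, c(0, 1))
  withr::with_seed(23, {
    codes <- list(m1 = sample(c("A", "B"), 50, TRUE),
                  m2 = sample(c("A", "B"), 50, TRUE))
    d <- allele_distribution(toy_table(codes))
    expect_equal(d$count_A, c(sum(codes$m1 == "A"), sum(codes$m2 == "A")))
  })
  expect_error(toy_table(list(m1 = "C")), class = "parse_error")
})

test_that("pairwise linkage counts parental vs nonparental segregants", {
  # zero-recombinant color pair of the fixture
  color <- pairwise_linkage(study_fx$table, "fwnA", "olvA")
  expect_equal(color$nps_count, 0)
  expect_equal(color$r_percent, 0)
  expect_equal(color$ps_count + color$nps_count, 140)

  # four combinations equally frequent: independence, r = 50%
  balanced <- toy_table(list(x = rep(c("A", "A", "B", "B"), 10),
                             y = rep(c("A", "B", "A", "B"), 10)))
  expect_equal(pairwise_linkage(balanced, "x", "y")$r_percent, 50)

  withr::with_seed(29, {
    codes <- list(x = sample(c("A", "B"), 80, TRUE),
                  y = sample(c("A", "B"), 80, TRUE))
    tab <- toy_table(codes)
    got <- pairwise_linkage(tab, "x", "y")
    xt <- table(codes$x, codes$y)
    expect_equal(got$ps_count, xt["A", "A"] + xt["B", "B"])
    expect_equal(got$nps_count, xt["A", "B"] + xt["B", "A"])
    expect_equal(got$r_percent, got$nps_count / 80 * 100)
  })
  expect_error(pairwise_linkage(balanced, "x", "zz"), class = "key_error")
})

test_that("linkage matrix covers all unordered pairs consistently", {
  tab3 <- toy_table(list(a = rep("A", 5), b = rep("B", 5),
                         c = c("A", "A", "B", "B", "A")))
  m <- linkage_matrix(tab3)
  expect_equal(nrow(m), 3)
  m6 <- linkage_matrix(study_fx$table)
  expect_equal(nrow(m6), choose(6, 2))
  expect_true(all(m6$ps_count + m6$nps_count == 140))
  for (j in seq_len(nrow(m6))) {
    direct <- pairwise_linkage(study_fx$table, m6$marker_x[j], m6$marker_y[j])
    expect_equal(m6$r_percent[j], direct$r_percent)
  }
})

test_that("segregation test is the exact two-sided binomial", {
  expect_equal(segregation_ratio_test(5, 10)$p_value, 1.0)
  expect_equal(segregation_ratio_test(0, 10)$p_value, 2 * (1 / 2)^10,
               tolerance = 1e-12)
  # brute-force pmf oracle: sum probabilities of outcomes no more likely
  # than the observed one
  oracle <- function(k, n) {
    pmf <- dbinom(0:n, n, 0.5)
    sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
  }
  for (case in list(c(78, 140), c(64, 140), c(30, 41), c(100, 200))) {
    expect_equal(segregation_ratio_test(case[1], case[2])$p_value,
                 oracle(case[1], case[2]), tolerance = 1e-9)
  }
  expect_error(segregation_ratio_test(0, 0), class = "undefined_test")
})

test_that("recombination estimator is unbiased at 50% for unlinked markers", {
  r_hats <- withr::with_seed(37, {
    vapply(1:200, function(rep) {
      seg <- haploidize(small_diploid, cross_config(140, 0),
                        small_karyotype, small_markers, small_snps)
      tab <- segregants_to_table(seg, small_markers)
      pairwise_linkage(tab, "fwnA", "nac")$r_percent
    }, numeric(1))
  })
  se_of_mean <- sqrt(2500 / 140) / sqrt(200)
  expect_lt(abs(mean(r_hats) - 50), 3 * se_of_mean)
})

test_that("same-chromosome recombination matches the uniform-breakpoint model", {
  # E[r] = p_rec * P(breakpoint between the loci) = p * 400/999
  p <- 0.3
  expected <- p * 400 / 999 * 100
  r_hats <- withr::with_seed(41, {
    vapply(1:100, function(rep) {
      seg <- haploidize(obs_diploid, cross_config(200, p),
                        karyotype_map("c1", 1000), obs_markers, obs_snps)
      tab <- segregants_to_table(seg, obs_markers)
      pairwise_linkage(tab, "nac", "prtT")$r_percent
    }, numeric(1))
  })
  expect_lt(abs(mean(r_hats) - expected), 3 * sd(r_hats) / sqrt(100))
})
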