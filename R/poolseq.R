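#' Sequencing coverage model
#'
#' Per-site depth is Poisson with mean `mean_depth`; each read reports the
#' wrong base with probability `error_rate`, split evenly over the three
#' non-true bases. Defaults (depth 100 for single strains, error rate 0.002)
#' keep the 0.7-frequency / 20-read validation filter comfortably exercised.
#'
#' @param mean_depth Mean reads per site (positive).
#' @param error_rate Per-read error probability in `[0, 0.5)`.
#' @param rng_seed Integer seed (NA = use current RNG state).
#' @return A `coverage_model` list.
#' @export
coverage_model <- function(mean_depth = 100, error_rate = 0.002, rng_seed = NA) {
  if (mean_depth <= 0) abort("mean_depth must be positive", "validation_error")
  if (error_rate < 0 || error_rate >= 0.5)
    abort("error_rate must be in [0, 0.5)", "validation_error")
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 rng_seed = rng_seed), class = "coverage_model")
}

#' Equal-mass pool specification
#'
#' @param member_ids Unique segregant identifiers contributing equal DNA
#'   mass to the pool.
#' @return A `pool_spec` list.
#' @export
pool_spec <- function(member_ids) {
  if (anyDuplicated(member_ids)) abort("pool members must be unique", "validation_error")
  structure(list(member_ids = as.character(member_ids)), class = "pool_spec")
}

#' True alternate-allele frequency of a pool at one SNP
#'
#' @param pool List of [haploid_genotype()] objects (the pool members).
#' @param snp_id SNP identifier.
#' @return `m/n` where `m` members carry the alt allele out of `n`.
#' @export
true_pool_frequency <- function(pool, snp_id) {
  if (length(pool) == 0)
    abort("pool is empty; allele frequency undefined", "undefined_frequency")
  carriers <- vapply(pool, function(g) g$snp_alleles[[snp_id]] == "alt", logical(1))
  mean(carriers)
}

true_frequencies <- function(pool, snps) {
  if (length(pool) == 0)
    abort("pool is empty; allele frequency undefined", "undefined_frequency")
  carrier <- vapply(pool, function(g)
    unname(g$snp_alleles[snps$snp_id] == "alt"), logical(nrow(snps)))
  rowMeans(matrix(carrier, nrow = nrow(snps)))
}

#' Simulate per-site sequencing evidence for a strain or pool
#'
#' For each SNP site the depth is drawn `Poisson(mean_depth)` and the
#' alt-read count `Binomial(depth, q)` with
#' `q = p (1 - e) + (1 - p) e/3`, where `p` is the true alt frequency
#' (0 or 1 for a single strain, the member fraction for a pool) and `e` the
#' per-read error rate.
#'
#' @param x A single [haploid_genotype()] or a list of them (a pool).
#' @param snps The [snp_table()] of sites to simulate.
#' @param model A [coverage_model()].
#' @param sample_id Sample name recorded on the call table.
#' @return A `sample_calls` data.frame with columns `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `depth`, `alt_count` and attribute `sample_id`.
#' @export
simulate_sample_calls <- function(x, snps, model, sample_id = NULL) {
  pool <- if (inherits(x, "haploid_genotype")) list(x) else x
  sample_id <- sample_id %||%
    (if (length(pool) == 1) pool[[1]]$strain_id else sprintf("pool%d", length(pool)))
  p <- true_frequencies(pool, snps)
  q <- p * (1 - model$error_rate) + (1 - p) * model$error_rate / 3
  with_seed_if(model$rng_seed, {
    depth <- rpois(nrow(snps), model$mean_depth)
    alt_count <- rbinom(nrow(snps), depth, q)
    sample_calls(data.frame(snp_id = snps$snp_id, chrom = snps$chrom,
                            pos = snps$pos, ref = snps$ref, alt = snps$alt,
                            depth = depth, alt_count = alt_count,
                            stringsAsFactors = FALSE),
                 sample_id = sample_id)
  })
}

#' Validated per-site call table
#'
#' @param df Data.frame with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`; `0 <= alt_count <= depth` is enforced.
#' @param sample_id Sample name.
#' @return A `sample_calls` data.frame.
#' @export
sample_calls <- function(df, sample_id) {
  need <- c("snp_id", "chrom", "pos", "ref", "alt", "depth", "alt_count")
  if (!all(need %in% names(df)))
    abort(paste("call table must have columns:", paste(need, collapse = ", ")),
          "validation_error")
  if (any(df$alt_count < 0) || any(df$alt_count > df$depth))
    abort("alt_count must lie in [0, depth] at every site", "consistency_error")
  structure(as.data.frame(df), sample_id = sample_id,
            class = c("sample_calls", "data.frame"))
}
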