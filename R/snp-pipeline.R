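#' Variant validation and pool-scan parameters
#'
#' Thresholds of the SNP validation step: a site is accepted as a variant in
#' a sample when its alternate-allele frequency is at least `min_freq` in at
#' least `min_depth` overlapping reads, with no quality-based filtering.
#' `pool_min_freq` is the reporting floor applied to the pooled sample: pool
#' variants below it are flagged rather than reported as conserved calls.
#'
#' @param min_freq Minimum in-sample variant frequency (default 0.7,
#'   boundary inclusive).
#' @param min_depth Minimum read depth (default 20, boundary inclusive).
#' @param pool_min_freq Minimal reported pool variant frequency (default 0.3).
#' @return A `snp_filter_params` list.
#' @export
snp_filter_params <- function(min_freq = 0.7, min_depth = 20L,
                              pool_min_freq = 0.3) {
  if (min_freq <= 0 || min_freq > 1) abort("min_freq must be in (0, 1]", "validation_error")
  if (min_depth < 1) abort("min_depth must be >= 1", "validation_error")
  if (pool_min_freq <= 0 || pool_min_freq > 1)
    abort("pool_min_freq must be in (0, 1]", "validation_error")
  structure(list(min_freq = min_freq, min_depth = as.integer(min_depth),
                 pool_min_freq = pool_min_freq), class = "snp_filter_params")
}

#' Validate variant sites in one sample
#'
#' A site passes iff `depth >= min_depth` and
#' `alt_count / depth >= min_freq`; both comparisons are inclusive and no
#' quality information is consulted. Zero-depth sites are never validated
#' and are returned in the `skipped` attribute.
#'
#' @param calls A [sample_calls()] table.
#' @param params [snp_filter_params()].
#' @return Character vector of validated `snp_id`s, with attribute
#'   `skipped` listing zero-depth site ids.
#' @export
validate_variants <- function(calls, params = snp_filter_params()) {
  zero <- calls$depth == 0
  freq_ok <- !zero & geq(calls$alt_count / pmax(calls$depth, 1L), params$min_freq)
  pass <- calls$depth >= params$min_depth & freq_ok
  structure(calls$snp_id[pass], skipped = calls$snp_id[zero])
}

#' Derive the inter-parental SNP set from two parent call tables
#'
#' A site enters the SNP set when it is validated as a variant in exactly
#' one parent; that parent is recorded as the origin of the alternate
#' allele. Sites validated in both parents are shared variants against the
#' reference, carry no information about the cross, and are excluded (their
#' ids are kept in the `shared` attribute).
#'
#' @param calls_A,calls_B [sample_calls()] tables over the same site
#'   universe.
#' @param params [snp_filter_params()].
#' @return A [snp_table()] of the inter-parental SNPs with `origin_parent`
#'   assigned, attribute `shared` listing excluded shared-variant ids.
#' @export
derive_parental_snpset <- function(calls_A, calls_B,
                                   params = snp_filter_params()) {
  if (!identical(calls_A$snp_id, calls_B$snp_id))
    abort("parent call tables must cover the same site universe", "validation_error")
  in_A <- calls_A$snp_id %in% validate_variants(calls_A, params)
  in_B <- calls_B$snp_id %in% validate_variants(calls_B, params)
  keep <- xor(in_A, in_B)
  out <- calls_A[keep, c("snp_id", "chrom", "pos", "ref", "alt")]
  out$origin_parent <- ifelse(in_A[keep], "A", "B")
  rownames(out) <- NULL
  structure(snp_table(out), shared = calls_A$snp_id[in_A & in_B])
}

#' Scan pool conservation of the inter-parental SNPs
#'
#' For every SNP the pooled read frequency is oriented to the trait
#' parent's allele, so "conservation" always measures the fraction of the
#' pool carrying the mutagenized parent's allele at that site: for a SNP
#' whose alternate allele originates from the trait parent the oriented
#' frequency is `alt_count/depth`, otherwise `1 - alt_count/depth`. When
#' pool member genotypes are available the exact genotype-level
#' conservation is computed alongside the read-level estimate. Oriented
#' read frequencies below `pool_min_freq` are flagged `below_threshold`;
#' zero-depth sites are emitted with missing frequency and flagged.
#'
#' @param snpset A [snp_table()] (e.g. from [derive_parental_snpset()]).
#' @param pool_calls [sample_calls()] for the pooled sample.
#' @param pool_genotypes Optional list of [haploid_genotype()] pool members.
#' @param params [snp_filter_params()].
#' @param trait_parent Which parent carries the trait ("A", the
#'   mutagenized parent, by default).
#' @return A `conservation_records` data.frame with columns `snp_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `origin_parent`, `pool_depth`,
#'   `read_frequency`, `genotype_conservation`, `below_threshold`.
#' @export
scan_pool_conservation <- function(snpset, pool_calls, pool_genotypes = NULL,
                                   params = snp_filter_params(),
                                   trait_parent = "A") {
  idx <- match(snpset$snp_id, pool_calls$snp_id)
  if (anyNA(idx))
    abort("pool calls do not cover every SNP in the set", "validation_error")
  depth <- pool_calls$depth[idx]
  alt_freq <- ifelse(depth > 0, pool_calls$alt_count[idx] / depth, NA_real_)
  oriented <- ifelse(snpset$origin_parent == trait_parent, alt_freq, 1 - alt_freq)
  geno <- rep(NA_real_, nrow(snpset))
  if (!is.null(pool_genotypes)) {
    raw <- true_frequencies(pool_genotypes, snpset)
    geno <- ifelse(snpset$origin_parent == trait_parent, raw, 1 - raw)
  }
  structure(
    data.frame(snp_id = snpset$snp_id, chrom = snpset$chrom, pos = snpset$pos,
               ref = snpset$ref, alt = snpset$alt,
               origin_parent = snpset$origin_parent,
               pool_depth = depth, read_frequency = oriented,
               genotype_conservation = geno,
               below_threshold = is.na(oriented) | oriented < params$pool_min_freq,
               stringsAsFactors = FALSE),
    class = c("conservation_records", "data.frame"))
}

#' Classify pool conservation of each SNP
#'
#' Adds a `conservation_class` column: `fully_conserved` when conservation
#' is at least `full_threshold`, `high` when at least `high_threshold`,
#' otherwise `unlinked`. Genotype-level conservation is preferred over the
#' read-level estimate when available. The defaults (0.995, 0.95) place a
#' 78/78 pool in the fully conserved class and a 77/78 pool (98.7%) in the
#' high class.
#'
#' @param records A `conservation_records` data.frame from
#'   [scan_pool_conservation()].
#' @param full_threshold,high_threshold Class boundaries (inclusive).
#' @return `records` with a `conservation_class` column added.
#' @export
classify_conservation <- function(records, full_threshold = 0.995,
                                  high_threshold = 0.95) {
  cons <- ifelse(is.na(records$genotype_conservation),
                 records$read_frequency, records$genotype_conservation)
  cls <- ifelse(is.na(cons), NA_character_,
                ifelse(geq(cons, full_threshold), "fully_conserved",
                       ifelse(geq(cons, high_threshold), "high", "unlinked")))
  records$conservation_class <- cls
  records
}

#' Annotate the coding effect of a SNP
#'
#' Locates the SNP within the supplied gene models. Inside a CDS the codon
#' change and amino-acid change are computed with the standard genetic code
#' (ref/alt are forward-strand bases and are complemented for
#' reverse-strand genes); inside a gene's extent but outside its CDS the
#' SNP is intronic; outside every gene it is noncoding. The reference base
#' is checked against the genome sequence.
#'
#' @param snp One-row [snp_table()] (or list with `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param genes List of [gene_model()] objects.
#' @param genome Named `DNAStringSet`/character of chromosome sequences.
#' @return A `coding_effect` list with fields `gene_id`, `codon_index`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `consequence`.
#' @export
annotate_coding_effect <- function(snp, genes, genome) {
  seqs <- as_genome(genome)
  if (!snp$chrom %in% names(seqs))
    abort(sprintf("chromosome %s absent from genome", snp$chrom), "coordinate_error")
  chrseq <- seqs[[snp$chrom]]
  if (snp$pos < 1 || snp$pos > length(chrseq))
    abort("SNP position out of chromosome bounds", "coordinate_error")
  genome_base <- as.character(Biostrings::subseq(chrseq, snp$pos, snp$pos))
  if (genome_base != snp$ref)
    abort(sprintf("reference mismatch at %s:%d (genome %s, table %s)",
                  snp$chrom, snp$pos, genome_base, snp$ref),
          "reference_mismatch")

  effect <- function(gene_id = NA_character_, codon_index = NA_integer_,
                     ref_codon = NA_character_, alt_codon = NA_character_,
                     ref_aa = NA_character_, alt_aa = NA_character_,
                     consequence) {
    structure(list(gene_id = gene_id, codon_index = codon_index,
                   ref_codon = ref_codon, alt_codon = alt_codon,
                   ref_aa = ref_aa, alt_aa = alt_aa,
                   consequence = consequence), class = "coding_effect")
  }

  intronic_gene <- NULL
  for (gene in genes) {
    if (gene$chrom != snp$chrom) next
    span <- gene_span(gene)
    if (snp$pos < span[1] || snp$pos > span[2]) next
    in_cds <- any(gene$cds$start <= snp$pos & snp$pos <= gene$cds$end)
    if (!in_cds) { intronic_gene <- gene; next }
    lk <- codon_lookup(gene, snp$pos)
    cds <- extract_cds(gene, seqs)
    ref_codon <- substr(cds, 3L * lk$codon_index - 2L, 3L * lk$codon_index)
    ref_base <- if (gene$strand == "+") snp$ref else comp_base(snp$ref)
    alt_base <- if (gene$strand == "+") snp$alt else comp_base(snp$alt)
    stopifnot(substr(ref_codon, lk$offset_in_codon, lk$offset_in_codon) == ref_base)
    alt_codon <- ref_codon
    substr(alt_codon, lk$offset_in_codon, lk$offset_in_codon) <- alt_base
    ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
    alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
    consequence <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "nonsense" else "missense"
    return(effect(gene$gene_id, lk$codon_index, ref_codon, alt_codon,
                  ref_aa, alt_aa, consequence))
  }
  if (!is.null(intronic_gene))
    return(effect(gene_id = intronic_gene$gene_id, consequence = "intronic"))
  effect(consequence = "noncoding")
}

#' Annotate all SNPs of a set
#'
#' @param snps A [snp_table()].
#' @inheritParams annotate_coding_effect
#' @return Data.frame of coding effects, one row per SNP.
#' @export
annotate_snps <- function(snps, genes, genome) {
  if (nrow(snps) == 0)
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      codon_index = integer(0), ref_codon = character(0),
                      alt_codon = character(0), ref_aa = character(0),
                      alt_aa = character(0), consequence = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    eff <- annotate_coding_effect(snps[i, ], genes, genome)
    data.frame(snp_id = snps$snp_id[i], gene_id = eff$gene_id,
               codon_index = eff$codon_index, ref_codon = eff$ref_codon,
               alt_codon = eff$alt_codon, ref_aa = eff$ref_aa,
               alt_aa = eff$alt_aa, consequence = eff$consequence,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

consequence_rank <- function(x) {
  unname(c(missense = 1, nonsense = 1, synonymous = 2, intronic = 3,
           noncoding = 4)[x])
}

class_rank <- function(x) {
  unname(c(fully_conserved = 1, high = 2, unlinked = 3)[x])
}

#' Rank candidate causal SNPs
#'
#' Orders SNPs by conservation class (fully conserved, then high, then
#' unlinked), within a class by coding-effect triage (missense/nonsense
#' before synonymous before intronic before noncoding), and breaks
#' remaining ties by descending conservation, then chromosome and position.
#'
#' @param records Classified `conservation_records`
#'   (see [classify_conservation()]).
#' @param effects Annotation data.frame from [annotate_snps()].
#' @return The merged records, ordered, with a `rank` column.
#' @export
rank_candidates <- function(records, effects) {
  merged <- merge(records, effects, by = "snp_id", sort = FALSE)
  cons <- ifelse(is.na(merged$genotype_conservation),
                 merged$read_frequency, merged$genotype_conservation)
  ord <- order(class_rank(merged$conservation_class),
               consequence_rank(merged$consequence),
               -cons, merged$chrom, merged$pos)
  out <- merged[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Auxiliary binomial deviation-from-0.5 p-values for pool frequencies
#'
#' The conservation scan itself uses absolute conservation, not a test
#' statistic; these exact binomial p-values (alt reads vs depth against
#' p = 1/2) are reported as auxiliary output only.
#'
#' @param records `conservation_records`.
#' @return Numeric vector of two-sided exact binomial p-values.
#' @export
pool_deviation_pvalues <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    d <- records$pool_depth[i]
    if (is.na(d) || d == 0) return(NA_real_)
    k <- round(records$read_frequency[i] * d)
    binom.test(k, d, p = 0.5)$p.value
  }, numeric(1))
}
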