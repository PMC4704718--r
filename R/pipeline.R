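#' Pipeline configuration
#'
#' Collects the file paths and parameters of a full analysis run. Can be
#' built directly or loaded from a YAML file with the same field names.
#'
#' @param fixture_dir Directory holding a fixture written by
#'   [write_fixture()] (supplies defaults for all input paths).
#' @param out_dir Output directory.
#' @param calls_A,calls_B,calls_pool,genome,gff3,snps,markers,segregants,pool
#'   Individual input paths; default to the standard fixture file names
#'   under `fixture_dir`.
#' @param params A [snp_filter_params()].
#' @param full_threshold,high_threshold Conservation class boundaries.
#' @param rng_seed Seed recorded in output headers.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fixture_dir, out_dir,
                            calls_A = file.path(fixture_dir, "calls_parent_A.vcf"),
                            calls_B = file.path(fixture_dir, "calls_parent_B.vcf"),
                            calls_pool = file.path(fixture_dir, "calls_pool.vcf"),
                            genome = file.path(fixture_dir, "genome.fa"),
                            gff3 = file.path(fixture_dir, "genes.gff3"),
                            snps = file.path(fixture_dir, "snps.tsv"),
                            markers = file.path(fixture_dir, "markers.tsv"),
                            segregants = file.path(fixture_dir, "segregants.tsv"),
                            pool = file.path(fixture_dir, "pool.tsv"),
                            params = snp_filter_params(),
                            full_threshold = 0.995, high_threshold = 0.95,
                            rng_seed = NA) {
  cfg <- structure(list(
    out_dir = out_dir, calls_A = calls_A, calls_B = calls_B,
    calls_pool = calls_pool, genome = genome, gff3 = gff3, snps = snps,
    markers = markers, segregants = segregants, pool = pool,
    params = params, full_threshold = full_threshold,
    high_threshold = high_threshold, rng_seed = rng_seed),
    class = "pipeline_config")
  inputs <- unlist(cfg[c("calls_A", "calls_B", "calls_pool", "genome",
                         "gff3", "markers", "segregants", "pool")])
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0)
    abort(paste("missing input files:", paste(missing, collapse = ", ")),
          "validation_error")
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with fields `fixture_dir`, `out_dir`, optional
#'   `min_freq`, `min_depth`, `pool_min_freq`, `full_threshold`,
#'   `high_threshold`, `rng_seed`, and any individual input path override.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- snp_filter_params(
    min_freq = y$min_freq %||% 0.7,
    min_depth = y$min_depth %||% 20L,
    pool_min_freq = y$pool_min_freq %||% 0.3)
  args <- c(list(fixture_dir = y$fixture_dir, out_dir = y$out_dir,
                 params = params,
                 full_threshold = y$full_threshold %||% 0.995,
                 high_threshold = y$high_threshold %||% 0.95,
                 rng_seed = y$rng_seed %||% NA),
            y[intersect(names(y), c("calls_A", "calls_B", "calls_pool",
                                    "genome", "gff3", "snps", "markers",
                                    "segregants", "pool"))])
  do.call(pipeline_config, args)
}

# Reconstruct pool-member SNP genotypes from the segregant table's
# provenance codes: a member carries the alternate allele at a SNP iff the
# chromosome segment covering that site traces to the SNP's origin parent.
pool_genotypes_from_table <- function(table, snps, member_ids) {
  prov_cols <- grep("^prov_", names(table), value = TRUE)
  if (length(prov_cols) == 0)
    abort("segregant table lacks provenance columns", "validation_error")
  chroms <- sub("^prov_", "", prov_cols)
  rows <- match(member_ids, table$segregant_id)
  if (anyNA(rows)) abort("pool member absent from segregant table", "key_error")
  lapply(rows, function(r) {
    prov <- setNames(unlist(table[r, prov_cols]), chroms)
    src <- vapply(seq_len(nrow(snps)), function(i)
      source_at(prov, snps$chrom[i], snps$pos[i]), character(1))
    haploid_genotype(table$segregant_id[r], character(0),
                     setNames(ifelse(src == snps$origin_parent, "alt", "ref"),
                              snps$snp_id))
  })
}

#' Run the full bulk-segregant analysis pipeline
#'
#' Stages: read parent and pool call tables; validate variants and derive
#' the inter-parental SNP set (0.7 frequency in 20 reads, both inclusive);
#' scan pool conservation (read-level, plus exact genotype-level
#' conservation reconstructed from the segregant table's provenance);
#' classify conservation; annotate coding effects against the genome and
#' gene models; rank candidates; and run the classical marker linkage
#' analysis. Writes `conservation_report.tsv`, `linkage_matrix.tsv`,
#' `allele_distribution.tsv` and `summary.json` under `out_dir`. Any stage
#' failure aborts with the stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list (also serialized as JSON).
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            "stage_error"))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # hash the analysis-relevant configuration only, so identical analyses
  # written to different directories produce identical reports
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  seed <- config$rng_seed

  calls_A <- stage("read-calls", read_variant_table(config$calls_A))
  calls_B <- stage("read-calls", read_variant_table(config$calls_B))
  calls_pool <- stage("read-calls", read_variant_table(config$calls_pool))
  genome <- stage("read-reference", read_genome_fasta(config$genome))
  annotation <- stage("read-reference", read_gene_models_gff3(config$gff3))
  seg_table <- stage("read-segregants", read_genotype_table(config$segregants))
  pool_ids <- stage("read-segregants", read_tsv(config$pool)$segregant_id)

  snpset <- stage("call-filter",
                  derive_parental_snpset(calls_A, calls_B, config$params))
  if (nrow(snpset) == 0)
    warning("no inter-parental SNPs passed validation; reports will be empty")
  pool_genotypes <- stage("pool-genotypes",
                          pool_genotypes_from_table(seg_table, snpset, pool_ids))
  records <- stage("conservation-scan",
                   scan_pool_conservation(snpset, calls_pool, pool_genotypes,
                                          config$params))
  records <- stage("classify",
                   classify_conservation(records, config$full_threshold,
                                         config$high_threshold))
  effects <- stage("annotate", annotate_snps(snpset, annotation$genes, genome))
  ranked <- stage("rank", rank_candidates(records, effects))
  ranked$binom_p_vs_half <- pool_deviation_pvalues(ranked)

  dist <- stage("linkage", allele_distribution(seg_table))
  lk <- stage("linkage", linkage_matrix(seg_table))

  write_tsv(ranked, file.path(config$out_dir, "conservation_report.tsv"),
            seed, hash)
  write_tsv(lk, file.path(config$out_dir, "linkage_matrix.tsv"), seed, hash)
  write_tsv(dist, file.path(config$out_dir, "allele_distribution.tsv"),
            seed, hash)

  coding <- ranked[ranked$consequence %in% c("missense", "nonsense"), ]
  top <- if (nrow(coding) > 0) coding[1, ] else NULL
  summary <- list(
    tool = "parabsa", version = as.character(packageVersion("parabsa")),
    config_hash = hash, seed = seed,
    n_snps = nrow(snpset),
    class_counts = as.list(table(ranked$conservation_class)),
    top_coding_candidate = if (is.null(top)) NULL else list(
      snp_id = top$snp_id, chrom = top$chrom, pos = top$pos,
      gene_id = top$gene_id, codon_index = top$codon_index,
      ref_codon = top$ref_codon, alt_codon = top$alt_codon,
      aa_change = sprintf("%s%d%s", top$ref_aa, top$codon_index, top$alt_aa),
      consequence = top$consequence,
      conservation = ifelse(is.na(top$genotype_conservation),
                            top$read_frequency, top$genotype_conservation)))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(summary)
}
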