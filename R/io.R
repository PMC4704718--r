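# ---- output headers --------------------------------------------------------

# Every tabular/VCF/JSON output starts with a comment header recording the
# tool version, a hash of the generating configuration, and the seed.
config_hash <- function(config) {
  flat <- paste(deparse(config[!vapply(config, is.function, logical(1))]),
                collapse = "")
  f <- tempfile()
  writeLines(flat, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

output_header <- function(seed = NA, hash = "none", comment = "#") {
  sprintf("%s parabsa %s config=%s seed=%s", comment,
          as.character(packageVersion("parabsa")), hash, as.character(seed))
}

write_tsv <- function(df, path, seed = NA, hash = "none") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

# ---- FASTA / GFF3 ----------------------------------------------------------

#' Write and read the toy genome as FASTA
#'
#' @param genome Named `DNAStringSet` (or named character vector).
#' @param path FASTA file path.
#' @return `write_genome_fasta` returns the path invisibly;
#'   `read_genome_fasta` returns a named `DNAStringSet`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Derive a karyotype map from a genome
#'
#' Chromosome lengths are the sequence widths; centromere positions, when
#' known, are supplied separately (they are carried in the GFF3 annotation,
#' not the FASTA).
#'
#' @param genome Named `DNAStringSet`/character.
#' @param centromere_pos Optional named numeric vector of centromere
#'   positions.
#' @return A [karyotype_map()].
#' @export
karyotype_from_genome <- function(genome, centromere_pos = NULL) {
  seqs <- as_genome(genome)
  cen <- rep(NA_real_, length(seqs))
  if (!is.null(centromere_pos))
    cen[match(names(centromere_pos), names(seqs))] <- centromere_pos
  karyotype_map(names(seqs), Biostrings::width(seqs), cen)
}

#' Write gene models and karyotype annotation as GFF3
#'
#' Emits one `chromosome` feature per karyotype entry (spanning its full
#' length), optional `centromere` features, and `gene` + `CDS` features
#' (CDS carrying `Parent` attributes) for every gene model.
#'
#' @param genes List of [gene_model()] objects.
#' @param karyotype A [karyotype_map()].
#' @param path GFF3 file path.
#' @return The path, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, karyotype, path) {
  feats <- list(GenomicRanges::GRanges(
    seqnames = karyotype$chrom,
    ranges = IRanges::IRanges(1, karyotype$length_bp),
    strand = "*", type = "chromosome", ID = karyotype$chrom))
  cen <- karyotype[!is.na(karyotype$centromere_pos), ]
  if (nrow(cen) > 0)
    feats <- c(feats, list(GenomicRanges::GRanges(
      seqnames = cen$chrom,
      ranges = IRanges::IRanges(cen$centromere_pos, cen$centromere_pos),
      strand = "*", type = "centromere",
      ID = paste0("cen_", cen$chrom))))
  for (g in genes) {
    span <- gene_span(g)
    widths <- g$cds$end - g$cds$start + 1
    before <- cumsum(widths) - widths           # bases upstream in genomic order
    if (g$strand == "-") before <- rev(cumsum(rev(widths)) - rev(widths))
    phase <- (3L - before %% 3L) %% 3L
    feats <- c(feats, list(
      GenomicRanges::GRanges(g$chrom, IRanges::IRanges(span[1], span[2]),
                             strand = g$strand, type = "gene", ID = g$gene_id),
      GenomicRanges::GRanges(g$chrom,
                             IRanges::IRanges(g$cds$start, g$cds$end),
                             strand = g$strand, type = "CDS",
                             phase = as.integer(phase),
                             ID = sprintf("%s.cds%d", g$gene_id,
                                          seq_len(nrow(g$cds))),
                             Parent = g$gene_id)))
  }
  gr <- suppressWarnings(do.call(c, feats))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models and karyotype annotation from GFF3
#'
#' Inverse of [write_gene_models_gff3()].
#'
#' @param path GFF3 file path.
#' @return List with `genes` (list of [gene_model()]) and `karyotype`
#'   (a [karyotype_map()]).
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  chroms <- gr[type == "chromosome"]
  cen <- gr[type == "centromere"]
  cen_pos <- setNames(GenomicRanges::start(cen),
                      as.character(GenomicRanges::seqnames(cen)))
  karyotype <- karyotype_map(
    chrom = as.character(gr$ID[type == "chromosome"]),
    length_bp = GenomicRanges::end(chroms),
    centromere_pos = unname(cen_pos[as.character(gr$ID[type == "chromosome"])]))
  cds <- gr[type == "CDS"]
  parents <- vapply(cds$Parent, function(p) as.character(p)[1], character(1))
  genes <- lapply(unique(parents), function(id) {
    sub <- cds[parents == id]
    gene_model(id, as.character(GenomicRanges::seqnames(sub))[1],
               as.character(GenomicRanges::strand(sub))[1],
               cbind(GenomicRanges::start(sub), GenomicRanges::end(sub)))
  })
  names(genes) <- unique(parents)
  list(genes = genes, karyotype = karyotype)
}

# ---- variant tables (minimal VCF + flat TSV mirror) ------------------------

#' Write per-site calls as a minimal VCF v4.2 subset
#'
#' One record per SNP with FORMAT fields `DP` (depth) and `AD`
#' (`ref,alt` read counts).
#'
#' @param calls A [sample_calls()] table.
#' @param path Output path (`.vcf` for VCF, anything else for the flat
#'   tab-separated mirror).
#' @param seed,hash Recorded in the file header.
#' @return The path, invisibly.
#' @export
write_variant_table <- function(calls, path, seed = NA, hash = "none") {
  if (!grepl("\\.vcf$", path)) {
    df <- calls[c("snp_id", "chrom", "pos", "ref", "alt", "depth", "alt_count")]
    return(write_tsv(df, path, seed, hash))
  }
  sample_id <- attr(calls, "sample_id") %||% "sample"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    output_header(seed, hash, comment = "##"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")), con)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.\tDP:AD\t%d:%d,%d",
                     calls$chrom, calls$pos, calls$snp_id, calls$ref,
                     calls$alt, calls$depth, calls$depth - calls$alt_count,
                     calls$alt_count), con)
  invisible(path)
}

#' Read a variant table (minimal VCF or flat TSV mirror)
#'
#' Malformed records raise a parse error naming the offending line; records
#' whose allelic depths exceed the read depth raise a consistency error.
#'
#' @param path Input path; the VCF dialect is recognized by its
#'   `##fileformat=VCF` first line.
#' @return A [sample_calls()] table.
#' @export
read_variant_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^##fileformat=VCF", first)) {
    df <- read_tsv(path, colClasses = c(snp_id = "character",
                                        chrom = "character",
                                        ref = "character", alt = "character"))
    return(sample_calls(df, sample_id = sub("\\.[^.]*$", "", basename(path))))
  }
  lines <- readLines(path)
  header_idx <- grep("^#CHROM\t", lines)
  if (length(header_idx) != 1)
    abort("VCF lacks a single #CHROM header line", "parse_error")
  header <- strsplit(lines[header_idx], "\t", fixed = TRUE)[[1]]
  sample_id <- header[10]
  body_idx <- setdiff(seq_along(lines), c(grep("^#", lines)))
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10)
      abort(sprintf("line %d: expected 10 VCF columns, found %d", i, length(f)),
            "parse_error")
    if (f[9] != "DP:AD")
      abort(sprintf("line %d: unsupported FORMAT '%s'", i, f[9]), "parse_error")
    sub_fields <- strsplit(f[10], ":", fixed = TRUE)[[1]]
    dp <- suppressWarnings(as.integer(sub_fields[1]))
    ad <- suppressWarnings(as.integer(strsplit(sub_fields[2], ",", fixed = TRUE)[[1]]))
    if (is.na(dp) || length(ad) != 2 || anyNA(ad))
      abort(sprintf("line %d: malformed DP:AD field '%s'", i, f[10]), "parse_error")
    if (sum(ad) > dp)
      abort(sprintf("line %d: AD sum %d exceeds DP %d", i, sum(ad), dp),
            "consistency_error")
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) abort(sprintf("line %d: malformed POS '%s'", i, f[2]), "parse_error")
    data.frame(snp_id = f[3], chrom = f[1], pos = pos, ref = f[4], alt = f[5],
               depth = dp, alt_count = ad[2], stringsAsFactors = FALSE)
  })
  sample_calls(do.call(rbind, rows), sample_id = sample_id)
}

# ---- genotype / definition tables ------------------------------------------

#' Write and read the segregant genotype/phenotype table
#'
#' @param table A [genotype_table()].
#' @param path TSV path.
#' @param markers Marker column names (on read; defaults to the standard
#'   six study markers present in the file).
#' @param seed,hash Recorded in the file header.
#' @return `write_genotype_table` the path invisibly; `read_genotype_table`
#'   a [genotype_table()].
#' @export
write_genotype_table <- function(table, path, seed = NA, hash = "none") {
  write_tsv(as.data.frame(table), path, seed, hash)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path, markers = NULL) {
  df <- read_tsv(path)
  if (is.null(markers))
    markers <- intersect(c("fwnA", "olvA", "pyrG", "argB", "nac", "prtT"),
                         names(df))
  genotype_table(df, markers)
}

#' Read marker and SNP definition tables
#'
#' @param path TSV path written by [write_fixture()].
#' @return A [marker_table()] or [snp_table()].
#' @export
read_marker_table <- function(path) marker_table(read_tsv(path))

#' @rdname read_marker_table
#' @export
read_snp_table <- function(path) {
  snp_table(read_tsv(path, colClasses = c(snp_id = "character",
                                          chrom = "character",
                                          ref = "character",
                                          alt = "character")))
}

# ---- fixture emission ------------------------------------------------------

#' Write the complete study fixture to a directory
#'
#' Emits the toy genome (FASTA), annotation (GFF3), marker and SNP
#' definition tables, parent genotypes, the segregant genotype/phenotype
#' table, the pool membership, simulated call tables for both parents and
#' the pool (VCF and flat mirror), and a manifest listing every file with
#' its MD5 checksum. Two runs with the same seed produce byte-identical
#' files.
#'
#' @param config A [study_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data.frame (`file`, `md5`).
#' @export
write_fixture <- function(config, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0)
    abort(sprintf("cannot write to directory %s", dir), "io_error")
  fx <- build_study_fixture(config)
  hash <- config_hash(config)
  seed <- config$rng_seed
  p <- function(f) file.path(dir, f)

  write_genome_fasta(fx$reference$genome, p("genome.fa"))
  write_gene_models_gff3(fx$reference$genes, fx$reference$karyotype,
                         p("genes.gff3"))
  write_tsv(as.data.frame(fx$reference$markers), p("markers.tsv"), seed, hash)
  write_tsv(as.data.frame(fx$reference$snps), p("snps.tsv"), seed, hash)
  parents_df <- data.frame(
    locus_type = c(rep("marker", nrow(fx$reference$markers)),
                   rep("snp", nrow(fx$reference$snps))),
    locus_id = c(fx$reference$markers$marker_id, fx$reference$snps$snp_id),
    parent_A = c(fx$parents$parent_A$marker_alleles,
                 fx$parents$parent_A$snp_alleles),
    parent_B = c(fx$parents$parent_B$marker_alleles,
                 fx$parents$parent_B$snp_alleles),
    stringsAsFactors = FALSE)
  write_tsv(parents_df, p("parents.tsv"), seed, hash)
  write_genotype_table(fx$table, p("segregants.tsv"), seed, hash)
  write_tsv(data.frame(segregant_id = fx$pool$member_ids), p("pool.tsv"),
            seed, hash)
  write_variant_table(fx$calls_A, p("calls_parent_A.vcf"), seed, hash)
  write_variant_table(fx$calls_B, p("calls_parent_B.vcf"), seed, hash)
  write_variant_table(fx$calls_pool, p("calls_pool.vcf"), seed, hash)
  write_variant_table(fx$calls_pool, p("calls_pool.tsv"), seed, hash)

  files <- c("genome.fa", "genes.gff3", "markers.tsv", "snps.tsv",
             "parents.tsv", "segregants.tsv", "pool.tsv",
             "calls_parent_A.vcf", "calls_parent_B.vcf", "calls_pool.vcf",
             "calls_pool.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, p("manifest.tsv"), seed, hash)
  invisible(manifest)
}
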