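#' Chromosome-level karyotype map
#'
#' A karyotype map defines the coordinate system of the toy genome: one row
#' per chromosome with its length and, optionally, a centromere position.
#' The parasexual cross simulated by this package segregates these
#' chromosomes as whole units, so the karyotype is consumed by every
#' downstream module.
#'
#' @param chrom Character vector of unique chromosome identifiers.
#' @param length_bp Positive integer vector of chromosome lengths in bp.
#' @param centromere_pos Optional integer vector of centromere positions
#'   (1-based bp, `NA` when unknown); must lie within `[1, length_bp]`.
#' @return A `karyotype_map` data.frame with columns `chrom`, `length_bp`,
#'   `centromere_pos`.
#' @examples
#' karyotype_map(c("I", "II"), c(3e6, 3.5e6))
#' @export
karyotype_map <- function(chrom, length_bp, centromere_pos = NA_integer_) {
  if (anyDuplicated(chrom)) abort("chromosome ids must be unique", "validation_error")
  length_bp <- as.numeric(length_bp)
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    abort("every chromosome length must be a positive number", "validation_error")
  centromere_pos <- rep_len(as.numeric(centromere_pos), length(chrom))
  bad <- !is.na(centromere_pos) & (centromere_pos < 1 | centromere_pos > length_bp)
  if (any(bad))
    abort("centromere positions must lie within [1, length_bp]", "validation_error")
  structure(
    data.frame(chrom = as.character(chrom), length_bp = length_bp,
               centromere_pos = centromere_pos, stringsAsFactors = FALSE),
    class = c("karyotype_map", "data.frame"))
}

#' Gene model with one or more CDS intervals
#'
#' Coordinates are 1-based and fully closed (GFF3 convention). Multi-interval
#' genes represent intron-containing loci; the gene extent is taken to be the
#' span from the first CDS start to the last CDS end, and positions inside
#' that span but outside every CDS interval are classified as intronic.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome identifier.
#' @param strand `"+"` (forward) or `"-"` (reverse).
#' @param cds Two-column matrix or data.frame of 1-based inclusive
#'   `(start, end)` CDS intervals; they are sorted and must not overlap, and
#'   their total length must be divisible by 3.
#' @return A `gene_model` list.
#' @examples
#' gene_model("toy", "I", "+", cbind(101, 109))
#' @export
gene_model <- function(gene_id, chrom, strand = c("+", "-"), cds) {
  strand <- match.arg(strand)
  cds <- as.data.frame(cds)
  names(cds) <- c("start", "end")
  cds <- cds[order(cds$start), , drop = FALSE]
  if (any(cds$end < cds$start))
    abort("CDS interval end precedes start", "model_error")
  if (nrow(cds) > 1 && any(cds$start[-1] <= cds$end[-nrow(cds)]))
    abort("CDS intervals overlap", "model_error")
  if (sum(cds$end - cds$start + 1) %% 3 != 0)
    abort(sprintf("total CDS length of %s is not divisible by 3", gene_id), "model_error")
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 strand = strand, cds = cds),
            class = "gene_model")
}

gene_span <- function(gene) c(min(gene$cds$start), max(gene$cds$end))

cds_length <- function(gene) sum(gene$cds$end - gene$cds$start + 1)

#' Marker definition table
#'
#' The classical phenotype markers of the cross. `epistasis_rank` orders
#' markers within a phenotype channel: the lowest-ranked mutant marker in a
#' channel determines the phenotype (e.g. a fawn-spored `fwnA` mutant masks
#' the olive `olvA` allele).
#'
#' @param df Data.frame with columns `marker_id`, `chrom`, `pos`,
#'   `wild_allele`, `mutant_allele`, `phenotype_channel`, `epistasis_rank`.
#' @return A validated `marker_table` data.frame.
#' @export
marker_table <- function(df) {
  need <- c("marker_id", "chrom", "pos", "wild_allele", "mutant_allele",
            "phenotype_channel", "epistasis_rank")
  if (!all(need %in% names(df)))
    abort(paste("marker table must have columns:", paste(need, collapse = ", ")),
          "validation_error")
  channels <- c("spore_color", "uridine_requirement", "arginine_requirement",
                "acidification", "protease", "hygromycin_resistance")
  if (!all(df$phenotype_channel %in% channels))
    abort("unknown phenotype channel", "validation_error")
  if (anyDuplicated(df[c("chrom", "pos")]))
    abort("at most one marker per (chrom, pos)", "validation_error")
  dup <- tapply(df$epistasis_rank, df$phenotype_channel, anyDuplicated)
  if (any(unlist(dup) > 0))
    abort("epistasis_rank must be unique within a phenotype channel", "validation_error")
  structure(as.data.frame(df), class = c("marker_table", "data.frame"))
}

#' SNP definition table
#'
#' Inter-parental SNPs on the forward genomic strand. `origin_parent` records
#' which parent ("A" or "B") carries the alternate allele relative to the
#' reference assembly.
#'
#' @param df Data.frame with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `origin_parent`.
#' @return A validated `snp_table` data.frame.
#' @export
snp_table <- function(df) {
  need <- c("snp_id", "chrom", "pos", "ref", "alt", "origin_parent")
  if (!all(need %in% names(df)))
    abort(paste("snp table must have columns:", paste(need, collapse = ", ")),
          "validation_error")
  ok <- df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T")
  if (!all(ok)) abort("ref/alt must be single bases in {A,C,G,T}", "validation_error")
  if (any(df$ref == df$alt)) abort("ref and alt must differ", "validation_error")
  if (!all(df$origin_parent %in% c("A", "B")))
    abort("origin_parent must be 'A' or 'B'", "validation_error")
  if (anyDuplicated(df$snp_id)) abort("snp ids must be unique", "validation_error")
  structure(as.data.frame(df), class = c("snp_table", "data.frame"))
}

#' Extract the spliced, strand-oriented coding sequence of a gene
#'
#' Concatenates the CDS intervals in genomic order and reverse-complements
#' the result for reverse-strand genes, yielding the mRNA-sense coding
#' sequence.
#'
#' @param gene A [gene_model()].
#' @param genome A named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @return Character scalar: the coding sequence, length divisible by 3.
#' @export
extract_cds <- function(gene, genome) {
  seqs <- as_genome(genome)
  if (!gene$chrom %in% names(seqs))
    abort(sprintf("chromosome %s absent from genome", gene$chrom), "coordinate_error")
  chrseq <- seqs[[gene$chrom]]
  if (max(gene$cds$end) > length(chrseq) || min(gene$cds$start) < 1)
    abort("CDS interval out of chromosome bounds", "coordinate_error")
  pieces <- vapply(seq_len(nrow(gene$cds)), function(i) {
    as.character(Biostrings::subseq(chrseq, gene$cds$start[i], gene$cds$end[i]))
  }, character(1))
  cds <- paste(pieces, collapse = "")
  if (gene$strand == "-") cds <- revcomp(cds)
  cds
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  Biostrings::DNAStringSet(genome)
}

#' Locate a genomic position within a gene's codon structure
#'
#' Maps a 1-based genomic position to its 1-based codon index and offset
#' (1-3) within the spliced, strand-oriented coding sequence.
#'
#' @inheritParams extract_cds
#' @param genomic_pos 1-based genomic position; must fall inside a CDS
#'   interval of `gene`.
#' @return List with `codon_index` and `offset_in_codon`.
#' @export
codon_lookup <- function(gene, genomic_pos) {
  hit <- which(gene$cds$start <= genomic_pos & genomic_pos <= gene$cds$end)
  if (length(hit) == 0)
    abort(sprintf("position %d is not coding in gene %s", genomic_pos, gene$gene_id),
          "noncoding_position")
  before <- if (hit > 1) sum(gene$cds$end[seq_len(hit - 1)] -
                               gene$cds$start[seq_len(hit - 1)] + 1) else 0
  fwd_offset <- before + (genomic_pos - gene$cds$start[hit]) + 1
  offset <- if (gene$strand == "+") fwd_offset else cds_length(gene) - fwd_offset + 1
  list(codon_index = as.integer(ceiling(offset / 3)),
       offset_in_codon = as.integer(offset - 3 * (ceiling(offset / 3) - 1)))
}
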