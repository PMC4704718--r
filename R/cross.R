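#' Haploid genotype
#'
#' Allele state of a haploid strain at every marker and SNP of the study
#' configuration. Marker alleles are `"wild"`/`"mutant"`; SNP alleles are
#' `"ref"`/`"alt"`.
#'
#' @param strain_id Strain identifier.
#' @param marker_alleles Named character vector, one entry per marker.
#' @param snp_alleles Named character vector, one entry per SNP.
#' @return A `haploid_genotype` list.
#' @export
haploid_genotype <- function(strain_id, marker_alleles, snp_alleles) {
  if (!all(marker_alleles %in% c("wild", "mutant")))
    abort("marker alleles must be 'wild' or 'mutant'", "validation_error")
  if (!all(snp_alleles %in% c("ref", "alt")))
    abort("snp alleles must be 'ref' or 'alt'", "validation_error")
  structure(list(strain_id = strain_id,
                 marker_alleles = marker_alleles,
                 snp_alleles = snp_alleles),
            class = "haploid_genotype")
}

#' Fuse two haploid parents into a heterozygous diploid
#'
#' Mimics diploid selection from a balanced heterokaryon: the parents must
#' carry complementary spore-color markers (one fwnA-mutant, one
#' olvA-mutant) and complementary auxotrophies, so that prototrophic,
#' black-spored diploid colonies can be selected. Parents failing either
#' requirement raise a `selection_impossible` error.
#'
#' @param parent_A,parent_B [haploid_genotype()] objects covering the same
#'   marker and SNP universe.
#' @param markers The study [marker_table()].
#' @return A `diploid_genotype` list with elements `homolog_A`, `homolog_B`.
#' @export
form_diploid <- function(parent_A, parent_B, markers) {
  if (!identical(sort(names(parent_A$marker_alleles)),
                 sort(names(parent_B$marker_alleles))) ||
      !identical(sort(names(parent_A$snp_alleles)),
                 sort(names(parent_B$snp_alleles))))
    abort("parents must share one marker/SNP universe", "validation_error")
  ph_A <- derive_phenotypes(parent_A, markers)
  ph_B <- derive_phenotypes(parent_B, markers)
  colors <- sort(c(ph_A$spore_color, ph_B$spore_color))
  if (!identical(colors, c("fawn", "olive")))
    abort("parents lack complementary color markers; diploids cannot be selected visually",
          "selection_impossible")
  complements <- (ph_A$pyrG_prototroph != ph_B$pyrG_prototroph) &&
    (ph_A$argB_prototroph != ph_B$argB_prototroph)
  if (!complements)
    abort("parents lack complementary auxotrophies; heterokaryon balance cannot be enforced",
          "selection_impossible")
  structure(list(homolog_A = parent_A, homolog_B = parent_B),
            class = "diploid_genotype")
}

#' Cross configuration for haploidization
#'
#' @param n_segregants Number of haploid segregants to generate.
#' @param p_mitotic_rec Per-chromosome, per-segregant probability that the
#'   chromosome is a single-breakpoint mitotic recombinant instead of an
#'   intact parental homolog. Default 0.013, calibrated so that about one
#'   crossover is expected on any given chromosome among 78 pool members.
#' @param rng_seed Integer seed (NA = use current RNG state).
#' @return A `cross_config` list.
#' @export
cross_config <- function(n_segregants, p_mitotic_rec = 0.013, rng_seed = NA) {
  if (n_segregants < 1) abort("n_segregants must be positive", "validation_error")
  if (p_mitotic_rec < 0 || p_mitotic_rec > 1)
    abort("p_mitotic_rec must be in [0, 1]", "validation_error")
  structure(list(n_segregants = as.integer(n_segregants),
                 p_mitotic_rec = p_mitotic_rec, rng_seed = rng_seed),
            class = "cross_config")
}

# Which homolog ("A"/"B") a locus at `pos` on `chrom` traces to, given a
# segregant's provenance code: "A", "B", or "R:<proximal>:<breakpoint>".
source_at <- function(provenance, chrom, pos) {
  code <- provenance[[chrom]]
  if (code %in% c("A", "B")) return(code)
  parts <- strsplit(code, ":", fixed = TRUE)[[1]]
  proximal <- parts[2]
  breakpoint <- as.numeric(parts[3])
  if (pos <= breakpoint) proximal else setdiff(c("A", "B"), proximal)
}

# Vectorized source_at over a locus table with `chrom` and `pos` columns;
# only recombinant chromosomes need the per-locus breakpoint comparison.
sources_at <- function(provenance, loci) {
  code <- unname(provenance[loci$chrom])
  rec <- !code %in% c("A", "B")
  if (any(rec)) {
    code[rec] <- vapply(which(rec), function(i)
      source_at(provenance, loci$chrom[i], loci$pos[i]), character(1))
  }
  code
}

# Assemble a segregant's haploid genotype from its per-chromosome provenance.
genotype_from_provenance <- function(segregant_id, provenance, diploid,
                                     markers, snps) {
  m_src <- sources_at(provenance, markers)
  s_src <- sources_at(provenance, snps)
  mk <- ifelse(m_src == "A",
               diploid$homolog_A$marker_alleles[markers$marker_id],
               diploid$homolog_B$marker_alleles[markers$marker_id])
  sn <- ifelse(s_src == "A",
               diploid$homolog_A$snp_alleles[snps$snp_id],
               diploid$homolog_B$snp_alleles[snps$snp_id])
  haploid_genotype(segregant_id,
                   setNames(mk, markers$marker_id),
                   setNames(sn, snps$snp_id))
}

new_segregant <- function(segregant_id, provenance, diploid, markers, snps) {
  structure(list(
    segregant_id = segregant_id,
    genotype = genotype_from_provenance(segregant_id, provenance, diploid,
                                        markers, snps),
    provenance = provenance), class = "segregant")
}

#' Haploidize a diploid into segregants by whole-chromosome loss
#'
#' Each segregant inherits every chromosome independently from homolog A or
#' B with probability 1/2. With probability `p_mitotic_rec` a chromosome is
#' instead a single-breakpoint mitotic recombinant: the breakpoint is
#' uniform on `[1, length_bp)`, the proximal source is chosen uniformly, and
#' loci at positions `<=` breakpoint trace to the proximal source.
#' Provenance (`"A"`, `"B"`, or `"R:<proximal>:<breakpoint>"`) is recorded
#' per chromosome.
#'
#' @param diploid A [form_diploid()] result.
#' @param config A [cross_config()].
#' @param karyotype A [karyotype_map()].
#' @param markers,snps The study [marker_table()] and [snp_table()].
#' @param id_prefix Prefix for segregant identifiers.
#' @return List of `segregant` objects of length `config$n_segregants`.
#' @export
haploidize <- function(diploid, config, karyotype, markers, snps,
                       id_prefix = "seg") {
  with_seed_if(config$rng_seed, {
    lapply(seq_len(config$n_segregants), function(i) {
      prov <- vapply(seq_len(nrow(karyotype)), function(k) {
        if (runif(1) < config$p_mitotic_rec) {
          breakpoint <- sample.int(karyotype$length_bp[k] - 1L, 1L)
          sprintf("R:%s:%d", sample(c("A", "B"), 1L), breakpoint)
        } else sample(c("A", "B"), 1L)
      }, character(1))
      names(prov) <- karyotype$chrom
      new_segregant(sprintf("%s%03d", id_prefix, i), prov, diploid,
                    markers, snps)
    })
  })
}

#' Derive the observable phenotype of a haploid genotype
#'
#' Encodes the marker chemistry of the mapping cross:
#' * spore color: fawn if the `fwnA` marker is mutant (epistatic), else
#'   olive if `olvA` is mutant, else black;
#' * uridine prototrophy: conferred only by the `olvA::pyrG` insertion
#'   (the `olvA` mutant allele) — both native `pyrG` loci in the cross are
#'   defective;
#' * arginine prototrophy: lost with the `argB::hygB` disruption;
#' * acidification: lost with the `nac` (laeA) mutant allele;
#' * full protease activity: lost with the `prtT` mutant allele;
#' * hygromycin resistance: conferred by either `hygB`-containing
#'   disruption (`fwnA` or `argB` mutant alleles).
#'
#' @param genotype A [haploid_genotype()].
#' @param markers The study [marker_table()]; every marker must have an
#'   allele state in `genotype`.
#' @return A `phenotype_record` list with fields `spore_color`,
#'   `pyrG_prototroph`, `argB_prototroph`, `acidifying`, `protease_full`,
#'   `hygromycin_resistant`.
#' @export
derive_phenotypes <- function(genotype, markers) {
  missing <- setdiff(markers$marker_id, names(genotype$marker_alleles))
  if (length(missing) > 0)
    abort(paste("genotype lacks marker state for:", paste(missing, collapse = ", ")),
          "incomplete_genotype")
  al <- genotype$marker_alleles
  is_mut <- function(id) id %in% names(al) && al[[id]] == "mutant"

  color_markers <- markers[markers$phenotype_channel == "spore_color", ]
  color_markers <- color_markers[order(color_markers$epistasis_rank), ]
  color <- "black"
  color_names <- c(fwnA = "fawn", olvA = "olive")
  for (id in color_markers$marker_id) {
    if (is_mut(id)) { color <- color_names[[id]]; break }
  }
  structure(list(
    spore_color = color,
    pyrG_prototroph = is_mut("olvA"),
    argB_prototroph = !is_mut("argB"),
    acidifying = !is_mut("nac"),
    protease_full = !is_mut("prtT"),
    hygromycin_resistant = is_mut("fwnA") || is_mut("argB")
  ), class = "phenotype_record")
}

#' Derive the phenotype of a heterozygous diploid
#'
#' The loss-of-function mutations of the cross are recessive (the
#' nonacidifying trait itself was shown recessive by the acidifying
#' diploid): those channels express the mutant state only when both
#' homologs carry the mutant allele. The functional insertions
#' (`olvA::pyrG` uridine prototrophy, the `hygB` cassettes) act
#' dominantly. A diploid from complementary parents is therefore
#' black-spored and fully prototrophic.
#'
#' @param diploid A [form_diploid()] result.
#' @param markers The study [marker_table()].
#' @return A `phenotype_record`.
#' @export
diploid_phenotype <- function(diploid, markers) {
  al_A <- diploid$homolog_A$marker_alleles
  al_B <- diploid$homolog_B$marker_alleles[names(al_A)]
  merged <- haploid_genotype(
    "diploid",
    setNames(ifelse(al_A == "mutant" & al_B == "mutant", "mutant", "wild"),
             names(al_A)),
    character(0))
  ph <- derive_phenotypes(merged, markers)
  any_mut <- function(id) al_A[[id]] == "mutant" || al_B[[id]] == "mutant"
  ph$pyrG_prototroph <- any_mut("olvA")
  ph$hygromycin_resistant <- any_mut("fwnA") || any_mut("argB")
  ph
}

#' Select segregants satisfying a phenotype predicate
#'
#' @param segregants List of `segregant` objects.
#' @param trait Predicate taking a `phenotype_record` and returning a
#'   logical, e.g. [is_nonacidifying()].
#' @param markers The study [marker_table()].
#' @return The selected segregants, order preserved. An empty selection
#'   returns an empty list with a warning.
#' @export
select_pool <- function(segregants, trait, markers) {
  keep <- vapply(segregants, function(s)
    isTRUE(trait(derive_phenotypes(s$genotype, markers))), logical(1))
  if (!any(keep)) warning("trait predicate selected no segregants; empty pool")
  segregants[keep]
}

#' Trait predicate: nonacidifying phenotype
#' @param phenotype A `phenotype_record`.
#' @return Logical.
#' @export
is_nonacidifying <- function(phenotype) !phenotype$acidifying
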