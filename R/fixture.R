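#' Study configuration for the packaged synthetic cross
#'
#' Parameters of the reconstructed mapping cross: an 8-chromosome
#' karyotype, six classical markers, 52 inter-parental SNPs (six on the
#' causal chromosome II — three fully conserved in the trait pool and
#' three distal to a single recombinant's breakpoint — and 46 spread over
#' the other seven chromosomes), 140 haploid segregants with the published
#' marker marginals, and a 78-member nonacidifying pool containing exactly
#' one chromosome-II mitotic recombinant.
#'
#' @param rng_seed Integer master seed; every stochastic choice in the
#'   fixture builders derives from it.
#' @param n_segregants Total segregants (default 140).
#' @param pool_size Trait-positive pool size (default 78).
#' @param n_double_mutants Number of fwnA/olvA double mutants (default 2).
#' @param p_mitotic_rec Per-chromosome mitotic crossover probability used
#'   for free (non-fixture) simulation (default 0.013).
#' @param mean_depth_strain,mean_depth_pool Mean sequencing depths for
#'   parent strains (100) and the pooled sample (300).
#' @param error_rate Per-read sequencing error probability (0.002).
#' @return A `study_config` list.
#' @export
study_config <- function(rng_seed = 1L, n_segregants = 140L, pool_size = 78L,
                         n_double_mutants = 2L, p_mitotic_rec = 0.013,
                         mean_depth_strain = 100, mean_depth_pool = 300,
                         error_rate = 0.002) {
  if (pool_size > n_segregants)
    abort("pool_size cannot exceed n_segregants", "validation_error")
  karyotype <- karyotype_map(
    chrom = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"),
    length_bp = c(3000000, 3500000, 1600000, 1400000, 1500000,
                  1200000, 1100000, 1000000),
    centromere_pos = c(1500000, 700000, NA, NA, NA, NA, NA, NA))
  markers <- marker_table(data.frame(
    marker_id = c("fwnA", "olvA", "pyrG", "argB", "nac", "prtT"),
    chrom = c("I", "I", "I", "I", "II", "VI"),
    pos = c(1000000, 2000000, 2000001, 2600000, 1762101, 800449),
    wild_allele = c("fwnA+", "olvA+", "pyrG378", "argB+", "nac+", "prtT+"),
    mutant_allele = c("fwnA::hygB", "olvA::pyrG", "olvA::pyrG-derived",
                      "argB::hygB", "nac-", "prtT-13"),
    phenotype_channel = c("spore_color", "spore_color", "uridine_requirement",
                          "arginine_requirement", "acidification", "protease"),
    epistasis_rank = c(1L, 2L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE))
  structure(list(
    rng_seed = as.integer(rng_seed),
    n_segregants = as.integer(n_segregants),
    pool_size = as.integer(pool_size),
    n_double_mutants = as.integer(n_double_mutants),
    n_pool_recombinants = 1L,
    n_parental_snps = 52L,
    p_mitotic_rec = p_mitotic_rec,
    mean_depth_strain = mean_depth_strain,
    mean_depth_pool = mean_depth_pool,
    error_rate = error_rate,
    karyotype = karyotype,
    markers = markers,
    causal = list(chrom = "II", pos = 1762101, ref = "G", alt = "C",
                  codon_index = 327L),
    # chromosome II linked SNPs: the three proximal sites (including the
    # causal one) stay fully conserved in the pool; the three distal sites
    # lie beyond the single pool recombinant's breakpoint.
    chrII_full_pos = c(1550000, 1650400, 1762101),
    chrII_distal_pos = c(2200000, 2600000, 2950000),
    pool_rec_breakpoint = 2000000,
    double_mutant_breakpoint = 1600000,
    argB_rec_breakpoint = 2300000
  ), class = "study_config")
}

# ---- toy genes -------------------------------------------------------------

# Gene coordinates are fixed; their sequences are generated (seeded) by
# build_reference. laeA-like: codon 327 begins at chrII:1762101.
fixture_gene_defs <- function() {
  list(
    laeA_toy = gene_model("laeA_toy", "II", "+",
                          cbind(1762101 - 978, 1762101 - 978 + 1113 - 1)),
    fumR_toy = gene_model("fumR_toy", "II", "+",
                          rbind(c(1549500, 1549799), c(1550200, 1550502))),
    prtT_toy = gene_model("prtT_toy", "VI", "+", cbind(800001, 800900)),
    oahA_toy = gene_model("oahA_toy", "V", "-", cbind(600001, 600600)))
}

set_codon <- function(orf, codon_index, codon) {
  substr(orf, 3L * codon_index - 2L, 3L * codon_index) <- codon
  orf
}

plant <- function(chrseq, start, fragment) {
  substr(chrseq, start, start + nchar(fragment) - 1L) <- fragment
  chrseq
}

#' Build the toy reference genome, gene models, and SNP definitions
#'
#' Generates seeded random chromosome sequences, plants four toy genes
#' (a laeA-like single-exon gene whose codon 327 is GCC with its first base
#' at chrII:1762101; a two-exon fumR-like gene whose intron carries a fully
#' conserved SNP; a prtT-like gene carrying a CTA codon at the prtT-13
#' T-to-C site; and a reverse-strand oahA-like gene carrying a tester-parent
#' SNP), and realizes the 52 inter-parental SNP definitions: six linked
#' sites on chromosome II from the trait parent and 46 sites spread over
#' the other seven chromosomes, split evenly between the parents.
#'
#' @param config A [study_config()].
#' @return List with elements `karyotype`, `genome` (`DNAStringSet`),
#'   `genes` (list of [gene_model()]), `snps` ([snp_table()]) and
#'   `markers`.
#' @export
build_reference <- function(config) {
  genes <- fixture_gene_defs()
  with_seed_if(child_seed(config$rng_seed, 1L), {
    chrs <- setNames(
      lapply(config$karyotype$length_bp, random_dna),
      config$karyotype$chrom)

    laeA_orf <- set_codon(random_orf(371L), 327L, "GCC")
    chrs[["II"]] <- plant(chrs[["II"]], genes$laeA_toy$cds$start[1], laeA_orf)

    fum_orf <- random_orf(201L)
    chrs[["II"]] <- plant(chrs[["II"]], 1549500, substr(fum_orf, 1, 300))
    chrs[["II"]] <- plant(chrs[["II"]], 1550200, substr(fum_orf, 301, 603))

    prtT_orf <- set_codon(random_orf(300L), 150L, "CTA")
    chrs[["VI"]] <- plant(chrs[["VI"]], 800001, prtT_orf)

    oahA_orf <- random_orf(200L)
    chrs[["V"]] <- plant(chrs[["V"]], 600001, revcomp(oahA_orf))

    snps <- realize_snps(config, chrs, genes)
    list(karyotype = config$karyotype,
         genome = Biostrings::DNAStringSet(unlist(chrs)),
         genes = genes, snps = snps, markers = config$markers)
  })
}

# Draw the 44 scattered noncoding SNP positions and assemble the full
# 52-SNP table. Runs inside build_reference's seeded scope.
realize_snps <- function(config, chrs, genes) {
  counts <- c(I = 8L, III = 7L, IV = 7L, V = 6L, VI = 5L, VII = 6L, VIII = 5L)
  blocked <- function(chrom) {
    spans <- lapply(genes, function(g)
      if (g$chrom == chrom) gene_span(g) else NULL)
    c(spans[!vapply(spans, is.null, logical(1))],
      lapply(config$markers$pos[config$markers$chrom == chrom],
             function(p) c(p, p)))
  }
  scatter <- do.call(rbind, lapply(names(counts), function(chrom) {
    len <- config$karyotype$length_bp[config$karyotype$chrom == chrom]
    bad <- blocked(chrom)
    pos <- integer(0)
    while (length(pos) < counts[[chrom]]) {
      cand <- sample.int(len, 1L)
      hit <- any(vapply(bad, function(b) cand >= b[1] && cand <= b[2], logical(1)))
      if (!hit && !cand %in% pos) pos <- c(pos, cand)
    }
    data.frame(chrom = chrom, pos = sort(pos), stringsAsFactors = FALSE)
  }))
  scatter$origin_parent <- rep_len(c("A", "B"), nrow(scatter))

  special <- data.frame(
    chrom = c(rep("II", 6), "VI", "V"),
    pos = c(config$chrII_full_pos, config$chrII_distal_pos, 800449, 600300),
    origin_parent = c(rep("A", 7), "B"),
    stringsAsFactors = FALSE)

  defs <- rbind(special, scatter)
  defs$ref <- vapply(seq_len(nrow(defs)), function(i)
    substr(chrs[[defs$chrom[i]]], defs$pos[i], defs$pos[i]), character(1))
  defs$alt <- vapply(defs$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  # the causal substitution and the prtT-13 site are fixed changes
  defs$alt[defs$chrom == "II" & defs$pos == config$causal$pos] <- config$causal$alt
  defs$alt[defs$chrom == "VI" & defs$pos == 800449] <- "C"

  ord <- order(match(defs$chrom, config$karyotype$chrom), defs$pos)
  defs <- defs[ord, ]
  defs$snp_id <- sprintf("snp_%s_%07d", defs$chrom, defs$pos)
  rownames(defs) <- NULL
  snp_table(defs[c("snp_id", "chrom", "pos", "ref", "alt", "origin_parent")])
}

#' Build the two parental haploid genotypes
#'
#' Parent A is the mutagenized, trait-carrying parent (fawn-spored
#' `fwnA::hygB`, uridine auxotroph, nonacidifying `nac`, low-protease
#' `prtT-13`) and carries the alternate allele at every origin-A SNP;
#' parent B is the tester parent (olive `olvA::pyrG`, arginine auxotroph
#' `argB::hygB`) and carries the alternate allele at every origin-B SNP.
#' Their SNP allele sets are disjoint and cover all 52 definitions.
#'
#' @param config A [study_config()].
#' @param reference A [build_reference()] result.
#' @return List with elements `parent_A`, `parent_B`.
#' @export
build_parents <- function(config, reference) {
  snps <- reference$snps
  mk <- function(mutants) {
    al <- ifelse(config$markers$marker_id %in% mutants, "mutant", "wild")
    setNames(al, config$markers$marker_id)
  }
  sn <- function(parent) {
    setNames(ifelse(snps$origin_parent == parent, "alt", "ref"), snps$snp_id)
  }
  list(
    parent_A = haploid_genotype("parent_A", mk(c("fwnA", "nac", "prtT")), sn("A")),
    parent_B = haploid_genotype("parent_B", mk(c("olvA", "pyrG", "argB")), sn("B")))
}

# ---- constrained segregant construction ------------------------------------

# Per-chromosome provenance pools matching the published marker marginals:
#   chr I : 62 pure A (fawn, argB+), 74 pure B (olive, argB-),
#           2 fwnA/olvA doubles (crossover between fwnA and olvA, proximal A),
#           2 olive/argB+ recombinants (crossover between olvA and argB,
#           proximal B)  -> color 64/76, pyrG 78+/62-, argB 64+/76-
#   chr II: 77 pure A + 1 recombinant losing the distal linked SNPs among
#           the trait carriers, 62 pure B      -> nac 78/62
#   chr VI: 72 A / 68 B                        -> prtT 72-/68+
#   others: fair coin per segregant.
fixture_provenance_pools <- function(config) {
  n <- config$n_segregants
  dbl <- sprintf("R:A:%d", config$double_mutant_breakpoint)
  argB_rec <- sprintf("R:B:%d", config$argB_rec_breakpoint)
  pool_rec <- sprintf("R:A:%d", config$pool_rec_breakpoint)
  list(
    I = c(rep("A", 62), rep("B", n - 62 - config$n_double_mutants - 2L),
          rep(dbl, config$n_double_mutants), rep(argB_rec, 2L)),
    II = c(rep("A", config$pool_size - config$n_pool_recombinants),
           rep(pool_rec, config$n_pool_recombinants),
           rep("B", n - config$pool_size)),
    VI = c(rep("A", 72), rep("B", n - 72)))
}

#' Build the 140-segregant cohort of the reconstructed cross
#'
#' Constrained cells (marker marginals, the two fwnA/olvA double mutants,
#' the single chromosome-II pool recombinant) are satisfied by
#' deterministic construction; the joint assignment across chromosomes is
#' randomized by independent seeded shuffles, consistent with independent
#' chromosome assortment. Unconstrained chromosomes segregate by a fair
#' coin.
#'
#' @param config A [study_config()].
#' @param reference A [build_reference()] result.
#' @return List with `segregants` (list of `segregant` objects) and
#'   `table` (a [genotype_table()] with phenotype and provenance columns).
#' @export
build_segregants <- function(config, reference) {
  parents <- build_parents(config, reference)
  diploid <- form_diploid(parents$parent_A, parents$parent_B, config$markers)
  pools <- fixture_provenance_pools(config)
  n <- config$n_segregants
  free_chroms <- setdiff(config$karyotype$chrom, names(pools))
  segregants <- with_seed_if(child_seed(config$rng_seed, 2L), {
    assign <- lapply(config$karyotype$chrom, function(chrom) {
      if (chrom %in% names(pools)) sample(pools[[chrom]])
      else sample(c("A", "B"), n, replace = TRUE)
    })
    names(assign) <- config$karyotype$chrom
    lapply(seq_len(n), function(i) {
      prov <- vapply(config$karyotype$chrom, function(ch) assign[[ch]][i],
                     character(1))
      new_segregant(sprintf("seg%03d", i), prov, diploid,
                    config$markers, reference$snps)
    })
  })
  check_fixture_constraints(config, segregants)
  list(segregants = segregants,
       table = segregants_to_table(segregants, config$markers))
}

check_fixture_constraints <- function(config, segregants) {
  phen <- lapply(segregants, function(s) derive_phenotypes(s$genotype, config$markers))
  n_nonacid <- sum(!vapply(phen, `[[`, logical(1), "acidifying"))
  if (n_nonacid != config$pool_size)
    abort(sprintf("constraint violated: %d trait-positive segregants, expected %d",
                  n_nonacid, config$pool_size), "construction_error")
  doubles <- sum(vapply(phen, function(p)
    p$spore_color == "fawn" && p$pyrG_prototroph, logical(1)))
  if (doubles != config$n_double_mutants)
    abort(sprintf("constraint violated: %d double mutants, expected %d",
                  doubles, config$n_double_mutants), "construction_error")
  blacks <- sum(vapply(phen, function(p) p$spore_color == "black", logical(1)))
  if (blacks != 0)
    abort("constraint violated: black-spored recombinant present", "construction_error")
  invisible(TRUE)
}

# Origin codes as scored from the observable phenotype: the two color loci
# are read from the single spore-color observation (a fawn/olvA::pyrG
# double mutant is visually fawn and scores as parental for the color
# pair), the remaining markers from their phenotype channels.
phenotype_origin_codes <- function(phenotype) {
  c(fwnA = if (phenotype$spore_color == "fawn") "A" else "B",
    olvA = if (phenotype$spore_color == "olive") "B" else "A",
    pyrG = if (phenotype$pyrG_prototroph) "B" else "A",
    argB = if (phenotype$argB_prototroph) "A" else "B",
    nac = if (phenotype$acidifying) "B" else "A",
    prtT = if (phenotype$protease_full) "B" else "A")
}

#' Convert segregants to a genotype/phenotype table
#'
#' One row per segregant: marker origin codes as scored from the
#' observable phenotype, the phenotype channels themselves, and the
#' per-chromosome provenance codes.
#'
#' @param segregants List of `segregant` objects.
#' @param markers The study [marker_table()].
#' @return A [genotype_table()].
#' @export
segregants_to_table <- function(segregants, markers) {
  rows <- lapply(segregants, function(s) {
    ph <- derive_phenotypes(s$genotype, markers)
    codes <- phenotype_origin_codes(ph)
    prov <- setNames(as.list(s$provenance),
                     paste0("prov_", names(s$provenance)))
    c(list(segregant_id = s$segregant_id), as.list(codes),
      list(spore_color = ph$spore_color,
           pyrG_prototroph = ph$pyrG_prototroph,
           argB_prototroph = ph$argB_prototroph,
           acidifying = ph$acidifying,
           protease_full = ph$protease_full,
           hygromycin_resistant = ph$hygromycin_resistant),
      prov)
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  genotype_table(df, markers = markers$marker_id)
}

#' Build the trait-positive pool of the reconstructed cross
#'
#' Selects the nonacidifying segregants (the 78 trait carriers) into the
#' sequencing pool. By construction exactly one member carries a
#' chromosome-II crossover whose breakpoint separates the causal SNP and
#' the three proximal linked SNPs (conserved 78/78) from the three distal
#' linked SNPs (conserved 77/78).
#'
#' @param config A [study_config()].
#' @param segregants The `segregants` element of [build_segregants()].
#' @return List with `pool` (a [pool_spec()]) and `genotypes` (list of
#'   member [haploid_genotype()]s).
#' @export
build_pool <- function(config, segregants) {
  members <- select_pool(segregants, is_nonacidifying, config$markers)
  list(pool = pool_spec(vapply(members, `[[`, character(1), "segregant_id")),
       genotypes = lapply(members, `[[`, "genotype"))
}

#' Freely simulate a cross and collect a fixed-size trait-positive pool
#'
#' Unlike the constrained fixture builders, this runs the haploidization
#' model itself: segregants are drawn in batches of `batch` from the
#' parental diploid until `pool_size` trait-positive (nonacidifying)
#' members have accumulated, mirroring the experimental collection of
#' segregant sectors until the pool is full.
#'
#' @param config A [study_config()].
#' @param reference A [build_reference()] result.
#' @param pool_size Number of trait carriers to collect.
#' @param p_mitotic_rec Per-chromosome crossover probability.
#' @param rng_seed Integer seed.
#' @param batch Segregants drawn per haploidization batch.
#' @return List with `pool_genotypes` (length `pool_size`) and
#'   `segregants` (all segregants drawn, trait-positive or not).
#' @export
simulate_trait_pool <- function(config, reference,
                                pool_size = config$pool_size,
                                p_mitotic_rec = config$p_mitotic_rec,
                                rng_seed = NA,
                                batch = config$n_segregants) {
  parents <- build_parents(config, reference)
  diploid <- form_diploid(parents$parent_A, parents$parent_B, config$markers)
  carriers <- list()
  all_seg <- list()
  round <- 0L
  while (length(carriers) < pool_size) {
    round <- round + 1L
    seg <- haploidize(diploid,
                      cross_config(batch, p_mitotic_rec,
                                   child_seed(rng_seed, 100L + round)),
                      config$karyotype, config$markers, reference$snps,
                      id_prefix = sprintf("b%d_seg", round))
    all_seg <- c(all_seg, seg)
    carriers <- c(carriers,
                  select_pool(seg, is_nonacidifying, config$markers))
  }
  list(pool_genotypes = lapply(carriers[seq_len(pool_size)], `[[`, "genotype"),
       segregants = all_seg)
}

#' Build the complete fixture in memory
#'
#' Convenience wrapper running [build_reference()], [build_parents()],
#' [build_segregants()] and [build_pool()], and simulating the three call
#' tables (both parents at strain depth, the pool at pool depth) with
#' seeds derived from the master seed.
#'
#' @param config A [study_config()].
#' @return List with `config`, `reference`, `parents`, `segregants`,
#'   `table`, `pool`, `pool_genotypes`, `calls_A`, `calls_B`,
#'   `calls_pool`.
#' @export
build_study_fixture <- function(config = study_config()) {
  reference <- build_reference(config)
  parents <- build_parents(config, reference)
  seg <- build_segregants(config, reference)
  pool <- build_pool(config, seg$segregants)
  strain_model <- function(stream) coverage_model(
    config$mean_depth_strain, config$error_rate, child_seed(config$rng_seed, stream))
  calls_A <- simulate_sample_calls(parents$parent_A, reference$snps,
                                   strain_model(3L), "parent_A")
  calls_B <- simulate_sample_calls(parents$parent_B, reference$snps,
                                   strain_model(4L), "parent_B")
  pool_model <- coverage_model(config$mean_depth_pool, config$error_rate,
                               child_seed(config$rng_seed, 5L))
  calls_pool <- simulate_sample_calls(pool$genotypes, reference$snps,
                                      pool_model, "segregant_pool")
  list(config = config, reference = reference, parents = parents,
       segregants = seg$segregants, table = seg$table,
       pool = pool$pool, pool_genotypes = pool$genotypes,
       calls_A = calls_A, calls_B = calls_B, calls_pool = calls_pool)
}
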