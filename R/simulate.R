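#' Probability law of the skewed neutral site frequency spectrum
#'
#' Derived-allele counts are drawn from `p(i)` proportional to
#' `1 / i^(1 + kappa)` for `i = 1 .. max_count`. `kappa = 0` is the
#' standard neutral spectrum of a constant-size population; positive
#' `kappa` skews mass toward singletons, emulating recent population
#' expansion.
#'
#' @param max_count Largest derived-allele count (typically `2n - 1`).
#' @param kappa Expansion skew, `>= 0`.
#' @return Numeric probability vector of length `max_count`.
#' @export
sfs_probs <- function(max_count, kappa = 0) {
  stopifnot(max_count >= 1, kappa >= 0)
  w <- 1 / seq_len(max_count)^(1 + kappa)
  w / sum(w)
}

#' Default per-domain non-synonymous acceptance multipliers
#'
#' Relative probability that a candidate non-synonymous change survives
#' purifying constraint, by domain class: transmembrane helices most
#' constrained, first and second intracellular loops next, extracellular
#' loops intermediate, the third intracellular loop weakly constrained and
#' the termini unconstrained.
#' @return Named numeric vector over [gpcr_domain_classes], in (0, 1].
#' @export
default_domain_multipliers <- function() {
  m <- c(Nterm = 1.0, TM1 = 0.2, ICL1 = 0.4, TM2 = 0.2, ECL1 = 0.7,
         TM3 = 0.2, ICL2 = 0.4, TM4 = 0.2, ECL2 = 0.7, TM5 = 0.2,
         ICL3 = 0.9, TM6 = 0.2, ECL3 = 0.7, TM7 = 0.2, Cterm = 1.0)
  m[gpcr_domain_classes]
}

#' Configuration of the synthetic cohort generator
#'
#' @param seed RNG seed; identical configurations produce identical
#'   cohorts.
#' @param n_genes,codons_per_gene Gene count and protein length (residues).
#' @param domain_fractions Domain-length fractions (see
#'   [default_domain_fractions()]).
#' @param pop_sizes Named vector of animals per population.
#' @param scope_probs Probability that a variant's carriers are confined to
#'   one population, to both rhesus populations, or free to occur anywhere.
#' @param kappa SFS expansion skew (see [sfs_probs()]).
#' @param domain_multipliers Per-domain non-synonymous acceptance
#'   multipliers.
#' @param coding_snv_per_codon Expected accepted coding SNVs per codon.
#' @param stop_gain_keep Acceptance probability of candidate stop gains.
#' @param frameshift_per_gene Expected frameshift indels per gene.
#' @param noncoding_per_gene Named vector of expected variant counts for
#'   intron/utr5/utr3/upstream/downstream regions.
#' @param nonsyn_divergence_rate Per-codon probability of a fixed
#'   non-synonymous human-macaque difference before domain thinning.
#' @param syn_divergence_rate Per-codon probability of a fixed synonymous
#'   difference (domain-independent).
#' @param n_recurrent,n_divergent,n_cooccur Planted cross-species events.
#' @param n_human_background Background human variant rows (placed at
#'   codons carrying no macaque variant).
#' @param p_damaging Latent probability that a non-synonymous variant is
#'   damaging.
#' @param predictor_flip,predictor_missing Per-predictor call noise and
#'   missingness.
#' @param missing_rate Per-genotype missing probability.
#' @param flank Gene flank length (bp) for upstream/downstream regions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 8L, codons_per_gene = 300L,
                       domain_fractions = default_domain_fractions(),
                       pop_sizes = c(chinese_rhesus = 20L,
                                     indian_rhesus = 44L,
                                     cynomolgus = 32L),
                       scope_probs = c(chinese = 0.25, indian = 0.30,
                                       cynomolgus = 0.25, rhesus = 0.08,
                                       all = 0.12),
                       kappa = 1.0,
                       domain_multipliers = default_domain_multipliers(),
                       coding_snv_per_codon = 0.10,
                       stop_gain_keep = 0.15,
                       frameshift_per_gene = 0.4,
                       noncoding_per_gene = c(intron = 6, utr5 = 2,
                                              utr3 = 3, upstream = 4,
                                              downstream = 4),
                       nonsyn_divergence_rate = 0.05,
                       syn_divergence_rate = 0.04,
                       n_recurrent = 9L, n_divergent = 5L, n_cooccur = 6L,
                       n_human_background = 40L,
                       p_damaging = 0.55, predictor_flip = 0.05,
                       predictor_missing = 0.05,
                       missing_rate = 0.02, flank = 2000L) {
  stopifnot(abs(sum(domain_fractions) - 1) < 1e-8,
            all(domain_multipliers > 0 & domain_multipliers <= 1),
            all(pop_sizes >= 2), kappa >= 0)
  cfg <- as.list(environment())
  cfg$scope_probs <- scope_probs / sum(scope_probs)
  class(cfg) <- "sim_config"
  cfg
}

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

# random sense codon encoding a given amino acid / any different amino acid
rand_codon <- function(aa = NULL, not_aa = NULL) {
  gc <- Biostrings::GENETIC_CODE
  pool <- SENSE_CODONS
  if (!is.null(aa)) pool <- pool[gc[pool] == aa]
  if (!is.null(not_aa)) pool <- pool[gc[pool] != not_aa]
  sample(pool, 1)
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

# sample() without the length-1 numeric trap
resample <- function(x, size = 1) x[sample.int(length(x), size)]

#' Generate a complete synthetic macaque GPCR cohort with known truth
#'
#' Produces every input the analysis pipeline reads — cohort VCF, sample
#' manifest, GFF3 gene models, genome/CDS/protein FASTAs for macaque and a
#' simulated human ortholog, human domain tables, a human variant table
#' with planted recurrent / shared-position-divergent / domain-co-occurring
#' records, and three-predictor calls — together with a truth set recording
#' the generating parameters and the true classification of every variant.
#'
#' Site frequencies are drawn from the skewed neutral law of [sfs_probs()]
#' within a randomly chosen population scope, then assigned to
#' chromosomes; candidate non-synonymous changes are thinned by the
#' per-domain constraint multipliers; human-macaque divergence is drawn
#' codon-wise at codons free of macaque polymorphism (non-synonymous
#' divergence thinned by the same multipliers, synonymous divergence
#' homogeneous). Planted variants are guaranteed common (carriers in two
#' or more distinct animals, exempt from genotype missingness).
#'
#' @param config A [sim_config()].
#' @param dir Optional directory: when given, all standard-format input
#'   files are written there.
#' @return A list with elements `cohort`, `manifest`, `models`, `genome`,
#'   `cds`, `macaque_prot`, `human_cds`, `human_prot`, `domains`,
#'   `human_variants`, `predictions`, `truth`, `config` (and `dir`,
#'   `files` when written).
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sim <- withr::with_seed(config$seed, simulate_cohort_impl(config))
  if (!is.null(dir)) sim <- write_sim_dir(sim, dir)
  sim
}

simulate_cohort_impl <- function(cfg) {
  L <- cfg$codons_per_gene
  genes <- sprintf("GPR%03d", seq_len(cfg$n_genes))
  # ---- sample manifest ----------------------------------------------------
  prefix <- c(chinese_rhesus = "ch", indian_rhesus = "in", cynomolgus = "cy")
  manifest <- dplyr::bind_rows(lapply(names(cfg$pop_sizes), function(p)
    tibble::tibble(sample_id = sprintf("%s%03d", prefix[[p]],
                                       seq_len(cfg$pop_sizes[[p]])),
                   population = p)))
  manifest <- validate_manifest(manifest)
  n_samples <- nrow(manifest)
  pop_of <- setNames(manifest$population, manifest$sample_id)

  # ---- gene architecture and sequences ------------------------------------
  utr5_len <- 60L; utr3_len <- 120L; intron_len <- 150L
  cds_len <- 3L * (L + 1L)  # includes the terminal stop codon
  models <- list(); genome <- list(); cds_seq <- character()
  domain_tbl <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    strand <- if (gi %% 2L == 1L) "+" else "-"
    chrom <- paste0("chr", gi)
    codons <- c(sample(SENSE_CODONS, L, replace = TRUE), "TAA")
    cds <- paste(codons, collapse = "")
    cds_seq[[g]] <- cds
    cds1 <- (cds_len %/% 2L)
    cds2 <- cds_len - cds1
    gs <- 3001L
    if (strand == "+") {
      utr5 <- tibble::tibble(start = gs, end = gs + utr5_len - 1L)
      c1s <- utr5$end + 1L
      cdsA <- tibble::tibble(start = c1s, end = c1s + cds1 - 1L)
      i1s <- cdsA$end + 1L
      c2s <- i1s + intron_len
      cdsB <- tibble::tibble(start = c2s, end = c2s + cds2 - 1L)
      utr3 <- tibble::tibble(start = cdsB$end + 1L,
                             end = cdsB$end + utr3_len)
      exons <- tibble::tibble(start = c(utr5$start, cdsB$start),
                              end = c(cdsA$end, utr3$end))
      cds_tbl <- dplyr::bind_rows(cdsA, cdsB)
      utr5_tbl <- utr5; utr3_tbl <- utr3
      intron <- tibble::tibble(start = i1s, end = c2s - 1L)
      ge <- utr3$end
    } else {
      # minus strand: 3'UTR at low genomic coordinates, 5'UTR at high
      utr3 <- tibble::tibble(start = gs, end = gs + utr3_len - 1L)
      c2s <- utr3$end + 1L
      cdsB <- tibble::tibble(start = c2s, end = c2s + cds2 - 1L)
      i1s <- cdsB$end + 1L
      c1s <- i1s + intron_len
      cdsA <- tibble::tibble(start = c1s, end = c1s + cds1 - 1L)
      utr5 <- tibble::tibble(start = cdsA$end + 1L,
                             end = cdsA$end + utr5_len)
      exons <- tibble::tibble(start = c(c1s, gs),
                              end = c(utr5$end, cdsB$end))
      cds_tbl <- dplyr::bind_rows(cdsA, cdsB)  # 5'->3' = descending genomic
      utr5_tbl <- utr5; utr3_tbl <- utr3
      intron <- tibble::tibble(start = i1s, end = c1s - 1L)
      ge <- utr5$end
    }
    model <- tibble::tibble(
      gene_id = g, transcript_id = paste0(g, ".t1"), chrom = chrom,
      strand = strand, gene_start = gs, gene_end = ge,
      flank = as.integer(cfg$flank), cds_len = cds_len, incomplete = FALSE,
      exons = list(exons), cds = list(cds_tbl), utr5 = list(utr5_tbl),
      utr3 = list(utr3_tbl))
    model$intron <- list(intron)
    models[[g]] <- model
    # chromosome sequence with the CDS spliced in
    chr_len <- ge + cfg$flank + 100L
    seqv <- sample(c("A", "C", "G", "T"), chr_len, replace = TRUE)
    cmap <- cds_coordinate_map(model)
    gpos <- as.integer(names(cmap))
    bases <- strsplit(cds, "")[[1]]
    seqv[gpos] <- if (strand == "+") bases else unname(comp_base(bases))
    genome[[chrom]] <- seqv
    domain_tbl[[g]] <- layout_domains(g, L, cfg$domain_fractions)
  }
  models <- dplyr::bind_rows(models)
  domains <- dplyr::bind_rows(domain_tbl)
  macaque_prot <- setNames(vapply(cds_seq, function(s)
    sub("\\*$", "", translate_dna(s)), character(1)), genes)
  domain_of_codon <- function(g, ci) {
    d <- domain_tbl[[g]]
    hit <- which(d$start <= ci & d$end >= ci)
    if (length(hit)) d$domain[hit[1]] else NA_character_
  }

  # ---- variant bookkeeping ------------------------------------------------
  # used_codon: codons carrying any variant (excluded from divergence and
  # human-row placement); reserved_codon: planted codons that background
  # variation must not touch, so planted truth stays exact
  used_codon <- lapply(setNames(genes, genes), function(g) integer())
  reserved_codon <- lapply(setNames(genes, genes), function(g) integer())
  gpos_list <- lapply(setNames(genes, genes), function(g)
    as.integer(names(cds_coordinate_map(models[models$gene_id == g, ]))))
  vrec <- list()       # per-variant record lists (bound into tibbles at end)
  gmat <- list()       # genotype rows
  add_variant <- function(chrom, pos, ref, alt, gt, gene, region, effect,
                          ci, ref_aa, alt_aa, planted = NA_character_) {
    k <- length(vrec) + 1L
    vrec[[k]] <<- list(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      key = variant_key(chrom, pos, ref, alt), gene = gene, region = region,
      effect = effect, ci = if (is.na(ci)) NA_integer_ else as.integer(ci),
      ref_aa = ref_aa, alt_aa = alt_aa,
      domain = if (!is.na(ci)) domain_of_codon(gene, min(ci, L))
               else NA_character_,
      planted = planted)
    gmat[[k]] <<- gt
  }

  scope_samples <- function(scope) {
    switch(scope,
      chinese = manifest$sample_id[manifest$population == "chinese_rhesus"],
      indian = manifest$sample_id[manifest$population == "indian_rhesus"],
      cynomolgus = manifest$sample_id[manifest$population == "cynomolgus"],
      rhesus = manifest$sample_id[manifest$population != "cynomolgus"],
      all = manifest$sample_id)
  }
  # genotype vector for a derived-allele count drawn within a random scope
  draw_genotypes <- function(force_common = FALSE) {
    scope <- sample(names(cfg$scope_probs), 1, prob = cfg$scope_probs)
    ids <- scope_samples(scope)
    n2 <- 2L * length(ids)
    gt <- setNames(rep("0/0", n_samples), manifest$sample_id)
    if (force_common) {
      i <- sample(2:6, 1)
      carriers <- sample(ids, min(i, length(ids)))
      gt[carriers] <- "0/1"
    } else {
      i <- sample.int(n2 - 1L, 1, prob = sfs_probs(n2 - 1L, cfg$kappa))
      slots <- sample.int(n2, i)
      per <- table(ids[(slots - 1L) %/% 2L + 1L])
      gt[names(per)] <- c("0/1", "1/1")[pmin(as.integer(per), 2L)]
    }
    gt
  }

  # coding SNV at a given CDS base index (1..3L); returns truth or NULL
  place_coding_snv <- function(g, cds_idx, want_alt_aa = NULL) {
    model <- models[models$gene_id == g, ]
    cds <- cds_seq[[g]]
    ci <- (cds_idx - 1L) %/% 3L + 1L
    off <- (cds_idx - 1L) %% 3L + 1L
    ref_cod <- substr(cds, 3L * ci - 2L, 3L * ci)
    ref <- substr(cds, cds_idx, cds_idx)
    alts <- setdiff(c("A", "C", "G", "T"), ref)
    for (alt in sample(alts)) {
      alt_cod <- ref_cod
      substr(alt_cod, off, off) <- alt
      aa1 <- codon_aa(ref_cod); aa2 <- codon_aa(alt_cod)
      if (!is.null(want_alt_aa)) {
        if (aa2 == want_alt_aa) {
          return(list(ci = ci, off = off, ref = ref, alt = alt,
                      aa1 = aa1, aa2 = aa2))
        }
        next
      }
      return(list(ci = ci, off = off, ref = ref, alt = alt,
                  aa1 = aa1, aa2 = aa2))
    }
    NULL
  }
  genomic_of_cds <- function(g, cds_idx) gpos_list[[g]][cds_idx]
  emit_coding <- function(g, snv, gt, planted = NA_character_) {
    model <- models[models$gene_id == g, ]
    cds_idx <- 3L * snv$ci - 3L + snv$off
    pos <- genomic_of_cds(g, cds_idx)
    ref <- snv$ref; alt <- snv$alt
    if (model$strand == "-") { ref <- comp_base(ref); alt <- comp_base(alt) }
    effect <- if (snv$aa1 == snv$aa2) "synonymous"
              else if (snv$aa2 == "*") "stop_gain"
              else "non_synonymous"
    add_variant(model$chrom, pos, unname(ref), unname(alt), gt, g, "CDS",
                effect, snv$ci, snv$aa1, snv$aa2, planted)
    used_codon[[g]] <<- c(used_codon[[g]], snv$ci)
    invisible(effect)
  }

  # ---- planted cross-species events ---------------------------------------
  plant_rec <- list(); plant_div <- list(); plant_co <- list()
  eligible_codons <- function(g) setdiff(seq_len(L), used_codon[[g]])
  plant_nonsyn_common <- function(g, ci, want_alt_aa = NULL) {
    # find a non-synonymous, non-stop SNV in codon ci
    for (off in sample(1:3)) {
      snv <- place_coding_snv(g, 3L * ci - 3L + off, want_alt_aa)
      if (!is.null(snv) && snv$aa1 != snv$aa2 && snv$aa2 != "*") {
        emit_coding(g, snv, draw_genotypes(force_common = TRUE), "planted")
        reserved_codon[[g]] <<- c(reserved_codon[[g]], ci)
        return(snv)
      }
    }
    NULL
  }
  n_planted <- cfg$n_recurrent + cfg$n_divergent + cfg$n_cooccur
  gene_cycle <- rep(genes, length.out = max(n_planted, 1))
  pi <- 0L
  for (k in seq_len(cfg$n_recurrent)) {
    pi <- pi + 1L; g <- gene_cycle[pi]
    repeat {
      ci <- resample(eligible_codons(g))
      snv <- plant_nonsyn_common(g, ci)
      if (!is.null(snv)) break
    }
    plant_rec[[k]] <- tibble::tibble(gene = g, aa_pos = snv$ci,
                                     aa1 = snv$aa1, aa2 = snv$aa2)
  }
  for (k in seq_len(cfg$n_divergent)) {
    pi <- pi + 1L; g <- gene_cycle[pi]
    repeat {
      ci <- resample(eligible_codons(g))
      snv <- plant_nonsyn_common(g, ci)
      if (!is.null(snv)) break
    }
    other <- sample(setdiff(unique(Biostrings::GENETIC_CODE),
                            c(snv$aa1, snv$aa2, "*")), 1)
    plant_div[[k]] <- tibble::tibble(gene = g, aa_pos = snv$ci,
                                     aa1 = snv$aa1, macaque_aa2 = snv$aa2,
                                     human_aa2 = other)
  }
  for (k in seq_len(cfg$n_cooccur)) {
    pi <- pi + 1L; g <- gene_cycle[pi]
    d <- domain_tbl[[g]]
    repeat {
      drow <- d[sample.int(nrow(d), 1), ]
      cand <- intersect(drow$start:drow$end, eligible_codons(g))
      if (length(cand) >= 2) break
    }
    repeat {
      ci <- resample(cand)
      snv <- plant_nonsyn_common(g, ci)
      if (!is.null(snv)) break
    }
    h_ci <- resample(setdiff(cand, snv$ci))
    aa1 <- codon_aa(substr(cds_seq[[g]], 3L * h_ci - 2L, 3L * h_ci))
    aa2 <- sample(setdiff(unique(Biostrings::GENETIC_CODE), c(aa1, "*")), 1)
    used_codon[[g]] <- c(used_codon[[g]], h_ci)
    reserved_codon[[g]] <- c(reserved_codon[[g]], h_ci)
    plant_co[[k]] <- tibble::tibble(gene = g, domain = drow$domain,
                                    aa_pos = h_ci, aa1 = aa1, aa2 = aa2)
  }

  # ---- background coding SNVs (domain-thinned) ----------------------------
  # candidate positions are drawn uniformly over the CDS; a codon may carry
  # several variants (at distinct positions), so that synonymous placement
  # stays homogeneous regardless of how many non-synonymous candidates the
  # per-domain constraint rejects elsewhere
  for (g in genes) {
    n_target <- stats::rpois(1, cfg$coding_snv_per_codon * L)
    n_target <- min(n_target, 2L * L)  # capacity bound: 3L positions
    used_pos <- integer()
    attempts <- 0L; accepted <- 0L
    while (accepted < n_target && attempts < 100L * max(n_target, 1L)) {
      attempts <- attempts + 1L
      cds_idx <- sample.int(3L * L, 1)
      ci <- (cds_idx - 1L) %/% 3L + 1L
      if (ci %in% reserved_codon[[g]] || cds_idx %in% used_pos) next
      snv <- place_coding_snv(g, cds_idx)
      if (is.null(snv)) next
      p_keep <- if (snv$aa1 == snv$aa2) 1
        else if (snv$aa2 == "*") cfg$stop_gain_keep
        else cfg$domain_multipliers[[domain_of_codon(g, ci)]]
      if (runif(1) > p_keep) next
      emit_coding(g, snv, draw_genotypes())
      used_pos <- c(used_pos, cds_idx)
      accepted <- accepted + 1L
    }
  }

  # ---- frameshift indels ---------------------------------------------------
  for (g in genes) {
    model <- models[models$gene_id == g, ]
    n_fs <- stats::rpois(1, cfg$frameshift_per_gene)
    for (k in seq_len(n_fs)) {
      found <- FALSE
      for (try in 1:200) {
        cds_idx <- sample.int(3L * L - 3L, 1)
        ci <- (cds_idx - 1L) %/% 3L + 1L
        if (!(ci %in% used_codon[[g]])) { found <- TRUE; break }
      }
      if (!found) next
      pos <- genomic_of_cds(g, cds_idx)
      chromv <- genome[[model$chrom]]
      if (runif(1) < 0.5) {  # 1-bp insertion after the anchor base
        ref <- chromv[pos]
        alt <- paste0(ref, sample(c("A", "C", "G", "T"), 1))
      } else {               # 1-bp deletion
        ref <- paste0(chromv[pos], chromv[pos + 1L])
        alt <- chromv[pos]
      }
      add_variant(model$chrom, pos, ref, alt, draw_genotypes(), g, "CDS",
                  "frameshift", ci, NA_character_, NA_character_)
      used_codon[[g]] <- c(used_codon[[g]], ci)
    }
  }

  # ---- non-coding variants -------------------------------------------------
  for (g in genes) {
    model <- models[models$gene_id == g, ]
    chromv <- genome[[model$chrom]]
    up <- if (model$strand == "+")
      c(model$gene_start - cfg$flank, model$gene_start - 1L)
    else c(model$gene_end + 1L, model$gene_end + cfg$flank)
    dn <- if (model$strand == "+")
      c(model$gene_end + 1L, model$gene_end + cfg$flank)
    else c(model$gene_start - cfg$flank, model$gene_start - 1L)
    regions <- list(
      intron = unlist(model$intron[[1]][1, c("start", "end")]),
      utr5 = unlist(model$utr5[[1]][1, c("start", "end")]),
      utr3 = unlist(model$utr3[[1]][1, c("start", "end")]),
      upstream = up, downstream = dn)
    labels <- c(intron = "intron", utr5 = "5'UTR", utr3 = "3'UTR",
                upstream = "upstream", downstream = "downstream")
    used_pos <- integer()
    for (r in names(regions)) {
      n_r <- stats::rpois(1, cfg$noncoding_per_gene[[r]])
      for (k in seq_len(n_r)) {
        repeat {
          pos <- sample(regions[[r]][1]:regions[[r]][2], 1)
          if (!(pos %in% used_pos)) break
        }
        used_pos <- c(used_pos, pos)
        ref <- chromv[pos]
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        add_variant(model$chrom, as.integer(pos), ref, alt,
                    draw_genotypes(), g, labels[[r]], "none",
                    NA_integer_, NA_character_, NA_character_)
      }
    }
  }

  # ---- assemble cohort with genotype missingness --------------------------
  col_chr <- function(f) vapply(vrec, `[[`, character(1), f)
  col_int <- function(f) vapply(vrec, `[[`, integer(1), f)
  variants <- tibble::tibble(
    chrom = col_chr("chrom"), pos = col_int("pos"), id = ".",
    ref = col_chr("ref"), alt = col_chr("alt"))
  genotypes <- do.call(rbind, gmat)
  truth_variants <- tibble::tibble(
    key = col_chr("key"), gene = col_chr("gene"), region = col_chr("region"),
    effect = col_chr("effect"), codon_index = col_int("ci"),
    ref_aa = col_chr("ref_aa"), alt_aa = col_chr("alt_aa"),
    domain = col_chr("domain"), planted = col_chr("planted"))
  planted_keys <- truth_variants$key[!is.na(truth_variants$planted)]
  if (cfg$missing_rate > 0 && nrow(genotypes)) {
    miss <- matrix(runif(length(genotypes)) < cfg$missing_rate,
                   nrow(genotypes))
    key_all <- variant_key(variants$chrom, variants$pos, variants$ref,
                           variants$alt)
    miss[key_all %in% planted_keys, ] <- FALSE
    genotypes[miss] <- "./."
  }
  cohort <- new_cohort(variants, genotypes, manifest)

  # frequency-class and sharing truth from the realised genotypes
  counts <- count_alleles(cohort)
  fc <- classify_frequency(counts)
  sh <- partition_sharing(counts, fc)
  truth_variants <- truth_variants |>
    dplyr::left_join(fc[, c("key", "class")], by = "key") |>
    dplyr::rename(freq_class = "class") |>
    dplyr::left_join(sh$assignments[, c("key", "region")],
                     by = "key", suffix = c("", "_sharing")) |>
    dplyr::rename(sharing_region = "region_sharing")

  # ---- human ortholog: divergence at unpolymorphed codons -----------------
  human_cds <- cds_seq
  div_rows <- list()
  for (g in genes) {
    cds <- cds_seq[[g]]
    free <- setdiff(seq_len(L), used_codon[[g]])
    for (ci in free) {
      cod <- substr(cds, 3L * ci - 2L, 3L * ci)
      aa <- codon_aa(cod)
      mult <- cfg$domain_multipliers[[domain_of_codon(g, ci)]]
      if (runif(1) < cfg$nonsyn_divergence_rate * mult) {
        new_cod <- rand_codon(not_aa = aa)
        substr(human_cds[[g]], 3L * ci - 2L, 3L * ci) <- new_cod
        div_rows[[length(div_rows) + 1L]] <- tibble::tibble(
          gene = g, codon = ci, kind = "non_synonymous")
      } else if (runif(1) < cfg$syn_divergence_rate) {
        syns <- setdiff(SENSE_CODONS[Biostrings::GENETIC_CODE[SENSE_CODONS]
                                     == aa], cod)
        if (length(syns)) {
          substr(human_cds[[g]], 3L * ci - 2L, 3L * ci) <-
            if (length(syns) == 1) syns else sample(syns, 1)
          div_rows[[length(div_rows) + 1L]] <- tibble::tibble(
            gene = g, codon = ci, kind = "synonymous")
        }
      }
    }
  }
  truth_divergence <- dplyr::bind_rows(div_rows)
  human_prot <- setNames(vapply(human_cds, function(s)
    sub("\\*$", "", translate_dna(s)), character(1)), genes)

  # ---- human variant table -------------------------------------------------
  hrows <- list()
  rsid <- 0L
  add_hrow <- function(g, pos, aa1, aa2, maf) {
    rsid <<- rsid + 1L
    hrows[[length(hrows) + 1L]] <<- tibble::tibble(
      gene = g, aa_pos = as.integer(pos), aa1 = aa1, aa2 = aa2,
      coords = paste0("hs_", g, ":", pos), dbsnp = sprintf("rsSIM%04d", rsid),
      maf = round(maf, 4))
  }
  for (r in plant_rec) add_hrow(r$gene, r$aa_pos, r$aa1, r$aa2,
                                runif(1, 0.01, 0.3))
  for (r in plant_div) add_hrow(r$gene, r$aa_pos, r$aa1, r$human_aa2,
                                runif(1, 0.01, 0.3))
  for (r in plant_co) add_hrow(r$gene, r$aa_pos, r$aa1, r$aa2,
                               runif(1, 0.01, 0.3))
  for (k in seq_len(cfg$n_human_background)) {
    g <- sample(genes, 1)
    cand <- setdiff(seq_len(L), used_codon[[g]])
    if (length(cand) == 0L) next
    ci <- resample(cand)
    used_codon[[g]] <- c(used_codon[[g]], ci)
    aa1 <- substr(human_prot[[g]], ci, ci)
    aa2 <- sample(setdiff(unique(Biostrings::GENETIC_CODE), c(aa1, "*")), 1)
    add_hrow(g, ci, aa1, aa2, runif(1, 0, 0.2))
  }
  human_variants <- dplyr::bind_rows(hrows)

  # ---- predictor calls -----------------------------------------------------
  nonsyn <- truth_variants[truth_variants$effect == "non_synonymous", ]
  nv <- nrow(nonsyn)
  latent <- runif(nv) < cfg$p_damaging
  predictions <- tidyr::expand_grid(idx = seq_len(nv),
                                    predictor = gpcr_predictors)
  keep <- runif(nrow(predictions)) >= cfg$predictor_missing
  predictions <- predictions[keep, , drop = FALSE]
  dmg <- latent[predictions$idx]
  flip <- runif(nrow(predictions)) < cfg$predictor_flip
  dmg <- ifelse(flip, !dmg, dmg)
  predictions <- tibble::tibble(
    key = nonsyn$key[predictions$idx], predictor = predictions$predictor,
    call = ifelse(dmg, "damaging", "tolerated"))

  truth <- list(
    variants = truth_variants,
    divergence = truth_divergence,
    recurrent = dplyr::bind_rows(plant_rec),
    divergent = dplyr::bind_rows(plant_div),
    cooccur = dplyr::bind_rows(plant_co),
    config = cfg)
  list(cohort = cohort, manifest = manifest,
       models = models[, setdiff(names(models), "intron")],
       genome = lapply(genome, paste, collapse = ""),
       cds = cds_seq, macaque_prot = macaque_prot,
       human_cds = human_cds, human_prot = human_prot,
       domains = domains, human_variants = human_variants,
       predictions = predictions, truth = truth, config = cfg)
}

# write every simulator output in its standard format
write_sim_dir <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_vcf(sim$cohort, fp("cohort.vcf"))
  write_manifest(sim$manifest, fp("manifest.tsv"))
  write_gene_models(sim$models, fp("genes.gff3"))
  write_fasta <- function(x, f) {
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(unlist(x)), fp(f))
  }
  write_fasta(sim$genome, "genome.fa")
  write_fasta(sim$cds, "macaque_cds.fa")
  write_fasta(sim$macaque_prot, "macaque_protein.fa")
  write_fasta(sim$human_cds, "human_cds.fa")
  write_fasta(sim$human_prot, "human_protein.fa")
  readr::write_tsv(sim$domains, fp("human_domains.tsv"), progress = FALSE)
  readr::write_tsv(sim$human_variants, fp("human_variants.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$predictions, fp("predictions.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$variants, fp("truth_variants.tsv"),
                   progress = FALSE)
  sim$dir <- dir
  sim$files <- list(
    vcf = fp("cohort.vcf"), manifest = fp("manifest.tsv"),
    gff3 = fp("genes.gff3"), genome = fp("genome.fa"),
    cds = fp("macaque_cds.fa"), macaque_protein = fp("macaque_protein.fa"),
    human_cds = fp("human_cds.fa"),
    human_protein = fp("human_protein.fa"),
    domains = fp("human_domains.tsv"),
    human_variants = fp("human_variants.tsv"),
    predictions = fp("predictions.tsv"))
  sim
}
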