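# Seeded synthetic-study generator.
#
# Emits a complete miniature discovery study — expression atlas, metabolite
# matrix, genome layout, domain/BLAST/GO tables, label sets and a latex
# proteome — with planted ground truth, so that every downstream stage
# (network, classifier, cluster scan, evidence merge) has a recoverable
# signal whose recovery can be checked against construction.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the study design the pipeline targets: a 16-tissue
#' expression atlas with 6 replicates per tissue, a 75-gene co-expressed
#' pathway module correlated with a handful of linked metabolites, 1908
#' flat-profile conserved (BUSCO-like) negatives, and a toy genome carrying
#' planted anchor + whitelist-domain clusters within 100 kb plus decoy
#' whitelist genes placed just beyond the scan window.
#'
#' Expression is modelled on the log2 scale as
#' `tissue effect + gene baseline + residual noise`, then exponentiated to
#' TPM. The residual standard deviations (`module_noise_sd`,
#' `negative_noise_sd`, `background_noise_sd`) are set so that the expected
#' within-tissue replicate correlation across transcripts is about 0.91,
#' matching the reproducibility reported for real multi-tissue atlases of
#' this design (see the vignette for the variance decomposition).
#'
#' @param seed integer RNG seed; all generator output is a deterministic
#'   function of the configuration including this seed.
#' @param n_tissues number of tissue types.
#' @param replicates_per_tissue biological replicates per tissue.
#' @param n_samples_drop samples dropped from the end of the design
#'   (16 x 6 = 96 by default; dropping 2 gives a 94-sample atlas).
#' @param n_genes total gene loci.
#' @param n_mia_module planted co-expressed pathway (MIA) module size.
#' @param n_negatives flat-profile conserved negatives.
#' @param module_adh_frac fraction of module genes carrying ADH domains.
#' @param n_background_adh non-module ADH-domain genes (annotation noise).
#' @param n_metabolites_linked metabolites sharing the module profile.
#' @param n_metabolites_other metabolites with independent profiles.
#' @param module_profile_sd sd (log2) of the module latent tissue profile.
#' @param module_noise_sd residual sd (log2) for module genes.
#' @param background_effect_sd sd (log2) of per-gene tissue effects for
#'   background genes.
#' @param background_noise_sd residual sd (log2) for background genes.
#' @param negative_noise_sd residual sd (log2) for conserved negatives.
#' @param baseline_logmean,baseline_logsd log2-TPM baseline distribution for
#'   non-module genes.
#' @param module_baseline_logmean,module_baseline_logsd baseline
#'   distribution for module genes (abundant in producing tissues).
#' @param label_holdout_frac fraction of module genes left unlabeled, to
#'   measure recovery of unseen pathway genes.
#' @param n_contigs contigs in the toy genome.
#' @param genes_per_contig genes placed per contig (`NULL` = place all
#'   `n_genes` evenly).
#' @param mean_gene_len,mean_intergenic mean gene length and intergenic gap
#'   in bp.
#' @param n_planted_clusters planted anchor + neighbor clusters (at most one
#'   per contig).
#' @param cluster_span_bp maximal planted anchor-to-member span budget, in
#'   bp; must stay below twice the 100 kb scan window or the planted cluster
#'   could not be guaranteed recoverable.
#' @param n_decoy_near_misses whitelist-domain genes placed 100,001-150,000
#'   bp from their nearest anchor.
#' @param proteome_size latex proteome size (genes).
#' @param proteome_adh_module module ADH genes included in the proteome.
#' @param go_oxidoreductase_frac fraction of ADH-domain genes annotated with
#'   GO:0016491.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_tissues = 16,
                              replicates_per_tissue = 6,
                              n_samples_drop = 0,
                              n_genes = 2500,
                              n_mia_module = 75,
                              n_negatives = 1908,
                              module_adh_frac = 0.4,
                              n_background_adh = 40,
                              n_metabolites_linked = 5,
                              n_metabolites_other = 15,
                              module_profile_sd = 2,
                              module_noise_sd = 0.3,
                              background_effect_sd = 1,
                              background_noise_sd = 0.8,
                              negative_noise_sd = 0.6,
                              baseline_logmean = 5,
                              baseline_logsd = 2,
                              module_baseline_logmean = 6,
                              module_baseline_logsd = 1,
                              label_holdout_frac = 0.2,
                              n_contigs = 6,
                              genes_per_contig = NULL,
                              mean_gene_len = 3000,
                              mean_intergenic = 15000,
                              n_planted_clusters = 3,
                              cluster_span_bp = 120000,
                              n_decoy_near_misses = 3,
                              proteome_size = 60,
                              proteome_adh_module = 10,
                              go_oxidoreductase_frac = 0.8) {
  cfg <- as.list(environment())
  counts <- c("n_tissues", "replicates_per_tissue", "n_samples_drop",
              "n_genes", "n_mia_module", "n_negatives", "n_background_adh",
              "n_metabolites_linked", "n_metabolites_other", "n_contigs",
              "mean_gene_len", "mean_intergenic", "n_planted_clusters",
              "cluster_span_bp", "n_decoy_near_misses", "proteome_size",
              "proteome_adh_module")
  for (nm in counts) {
    if (cfg[[nm]] < 0) stop_param("config error: ", nm, " must be >= 0")
  }
  if (cfg$n_mia_module + cfg$n_negatives > cfg$n_genes) {
    stop_param("config error: n_mia_module + n_negatives > n_genes")
  }
  if (cfg$cluster_span_bp >= 200000) {
    stop_param("config error: cluster_span_bp must be < 200,000 bp ",
               "(planted clusters would not be guaranteed recoverable)")
  }
  if (cfg$n_planted_clusters > cfg$n_contigs) {
    stop_param("config error: at most one planted cluster per contig")
  }
  for (nm in c("module_adh_frac", "label_holdout_frac",
               "go_oxidoreductase_frac")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop_param("config error: ", nm, " must be in [0, 1]")
    }
  }
  n_samples <- cfg$n_tissues * cfg$replicates_per_tissue
  if (cfg$n_samples_drop >= n_samples && n_samples > 0) {
    stop_param("config error: n_samples_drop must leave at least one sample")
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic study configuration (seed ", x$seed, ")\n", sep = "")
  cat("  atlas: ", x$n_tissues, " tissues x ", x$replicates_per_tissue,
      " replicates", if (x$n_samples_drop) paste0(" - ", x$n_samples_drop),
      " = ", x$n_tissues * x$replicates_per_tissue - x$n_samples_drop,
      " samples\n", sep = "")
  cat("  genes: ", x$n_genes, " (module ", x$n_mia_module, ", negatives ",
      x$n_negatives, ")\n", sep = "")
  cat("  genome: ", x$n_contigs, " contigs, ", x$n_planted_clusters,
      " planted clusters, ", x$n_decoy_near_misses, " decoys\n", sep = "")
  invisible(x)
}

# Pfam accessions used by the generator.
ADH_FAMILY_PFAM <- c(MDR1 = "PF00107", MDR2 = "PF08240", SDR = "PF00106",
                     AKR = "PF00248")
PFAM_NAMES <- c(PF00107 = "ADH_zinc_N", PF08240 = "ADH_N",
                PF00106 = "adh_short", PF00248 = "Aldo_ket_red",
                PF00067 = "p450", PF00201 = "UDPGT", PF03171 = "2OG-FeII_Oxy",
                PF14226 = "DIOX_N", PF00891 = "Methyltransf_2",
                PF08031 = "BBE", PF00012 = "HSP70", PF00069 = "Pkinase",
                PF00076 = "RRM_1", PF00400 = "WD40", PF01535 = "PPR",
                PF00153 = "Mito_carr")
HOUSEKEEPING_PFAM <- c("PF00012", "PF00069", "PF00076", "PF00400",
                       "PF01535", "PF00153")
KNOWN_MIA_PROTEINS <- c("CroTHAS1", "RseVR", "CroGS", "RsePR", "CroT3R")
MIA_SUBJECT_LEN <- 350L

resample <- function(x, k) x[sample.int(length(x), k)]

# Deterministic role assignment shared by all sub-generators: which genes
# form the module, the negatives, the ADH families, the planted cluster
# composition and the label holdout. Seeded independently of the value
# streams so every generator sees identical roles.
.assign_gene_roles <- function(cfg) {
  with_seed(child_seed(cfg$seed, 1L), {
    n <- cfg$n_genes
    ids <- if (n > 0) paste0("MSTRG.", seq_len(n)) else character(0)
    perm <- sample.int(n, n)
    module <- ids[perm[seq_len(cfg$n_mia_module)]]
    negatives <- ids[perm[cfg$n_mia_module + seq_len(cfg$n_negatives)]]
    background <- setdiff(ids, c(module, negatives))

    n_adh <- round(cfg$module_adh_frac * length(module))
    module_adh <- resample(module, n_adh)
    fam_cycle <- rep_len(names(ADH_FAMILY_PFAM), max(n_adh, 1))[seq_len(n_adh)]
    adh <- data.frame(gene_id = module_adh,
                      pfam_accession = unname(ADH_FAMILY_PFAM[fam_cycle]),
                      family = sub("[0-9]$", "", fam_cycle),
                      module = rep(TRUE, n_adh), stringsAsFactors = FALSE)
    n_bg_adh <- min(cfg$n_background_adh, length(background))
    bg_adh_ids <- resample(background, n_bg_adh)
    # background ADHs avoid PF08240 so annotation noise cannot create
    # accidental whitelist members near an anchor
    bg_cycle <- rep_len(c("MDR1", "SDR", "AKR"), max(n_bg_adh, 1))[seq_len(n_bg_adh)]
    if (n_bg_adh > 0) {
      adh <- rbind(adh, data.frame(
        gene_id = bg_adh_ids,
        pfam_accession = unname(ADH_FAMILY_PFAM[bg_cycle]),
        family = sub("[0-9]$", "", bg_cycle),
        module = rep(FALSE, n_bg_adh), stringsAsFactors = FALSE))
    }

    nc <- cfg$n_planted_clusters
    module_nonadh <- setdiff(module, module_adh)
    pf08240_module <- adh$gene_id[adh$module & adh$pfam_accession == "PF08240"]
    if (nc > 0 && (length(module_nonadh) < nc || length(pf08240_module) < nc)) {
      stop_param("config error: not enough module genes to plant ",
                 nc, " clusters (need ", nc, " non-ADH anchors and ", nc,
                 " PF08240 module members)")
    }
    anchors <- module_nonadh[seq_len(nc)]
    adh_members <- pf08240_module[seq_len(nc)]
    bg_pool <- setdiff(background, bg_adh_ids)
    n_special_bg <- nc + cfg$n_decoy_near_misses
    if (length(bg_pool) < n_special_bg && n_special_bg > 0) {
      stop_param("config error: not enough background genes for cluster ",
                 "members and decoys")
    }
    p450_members <- bg_pool[seq_len(nc)]
    decoys <- bg_pool[nc + seq_len(cfg$n_decoy_near_misses)]
    decoy_cluster <- if (cfg$n_decoy_near_misses > 0 && nc > 0) {
      rep_len(seq_len(nc), cfg$n_decoy_near_misses)
    } else integer(0)

    holdout <- resample(module, round(cfg$label_holdout_frac * length(module)))

    n_iso2 <- min(20L, length(setdiff(background, c(p450_members, decoys))))
    iso2 <- setdiff(background, c(p450_members, decoys))[seq_len(n_iso2)]

    p0 <- function(x, suf) if (length(x)) paste0(x, suf) else character(0)
    tx <- data.frame(
      transcript_id = c(p0(ids, ".1"), p0(iso2, ".2")),
      gene_id = c(ids, iso2), stringsAsFactors = FALSE)
    tx <- tx[order(match(tx$gene_id, ids), tx$transcript_id), , drop = FALSE]
    rownames(tx) <- NULL

    list(ids = ids, module = module, negatives = negatives,
         background = background, adh = adh, anchors = anchors,
         adh_members = adh_members, p450_members = p450_members,
         decoys = decoys, decoy_cluster = decoy_cluster, holdout = holdout,
         transcripts = tx)
  })
}

#' Generate the synthetic expression atlas, metabolite matrix and labels
#'
#' Module transcripts share one latent tissue profile plus gene-specific
#' Gaussian noise on the log2 scale; linked metabolites share the same
#' latent profile; conserved negatives have a tissue-independent log-normal
#' baseline; replicates of a tissue share the tissue mean plus replicate
#' noise. Output is deterministic given the configuration.
#'
#' @param config a [simulation_config()].
#' @return list with elements `atlas` ([expression_atlas()]),
#'   `metabolites` (raw, un-normalized [metabolite_matrix()]),
#'   `labels` ([label_set()]) and `truth` (module / negative /
#'   linked-metabolite ids and the label holdout).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  roles <- .assign_gene_roles(config)
  with_seed(child_seed(config$seed, 2L), {
    tissues <- sprintf("T%02d", seq_len(config$n_tissues))
    meta <- data.frame(
      sample_id = as.vector(t(outer(tissues, seq_len(config$replicates_per_tissue),
                                    function(t, r) paste0(t, "_r", r)))),
      tissue = rep(tissues, each = config$replicates_per_tissue),
      replicate = rep(seq_len(config$replicates_per_tissue),
                      times = config$n_tissues),
      stringsAsFactors = FALSE)
    if (config$n_samples_drop > 0) {
      meta <- meta[seq_len(nrow(meta) - config$n_samples_drop), , drop = FALSE]
    }
    ns <- nrow(meta)
    tx <- roles$transcripts
    nt <- nrow(tx)

    L <- stats::rnorm(config$n_tissues, 0, config$module_profile_sd)
    names(L) <- tissues
    gene_class <- ifelse(tx$gene_id %in% roles$module, "module",
                         ifelse(tx$gene_id %in% roles$negatives, "negative",
                                "background"))
    baseline <- ifelse(
      gene_class == "module",
      stats::rnorm(nt, config$module_baseline_logmean, config$module_baseline_logsd),
      stats::rnorm(nt, config$baseline_logmean, config$baseline_logsd))
    noise_sd <- c(module = config$module_noise_sd,
                  negative = config$negative_noise_sd,
                  background = config$background_noise_sd)[gene_class]

    tiss_idx <- match(meta$tissue, tissues)
    eff <- matrix(0, nt, config$n_tissues)
    is_mod <- gene_class == "module"
    if (any(is_mod)) {
      eff[is_mod, ] <- matrix(L, sum(is_mod), config$n_tissues, byrow = TRUE)
    }
    is_bg <- gene_class == "background"
    # per-gene tissue response; second isoforms of a gene share it
    bg_genes <- unique(tx$gene_id[is_bg])
    bg_eff <- matrix(stats::rnorm(length(bg_genes) * config$n_tissues, 0,
                                  config$background_effect_sd),
                     length(bg_genes), config$n_tissues)
    eff[is_bg, ] <- bg_eff[match(tx$gene_id[is_bg], bg_genes), , drop = FALSE]

    y <- baseline + eff[, tiss_idx, drop = FALSE] +
      matrix(stats::rnorm(nt * ns, 0, 1), nt, ns) * noise_sd
    tpm <- 2^y
    dimnames(tpm) <- list(tx$transcript_id, meta$sample_id)
    atlas <- expression_atlas(tpm, meta)

    n_met <- config$n_metabolites_linked + config$n_metabolites_other
    linked_ids <- if (config$n_metabolites_linked > 0)
      sprintf("met_linked_%02d", seq_len(config$n_metabolites_linked)) else character(0)
    other_ids <- if (config$n_metabolites_other > 0)
      sprintf("met_bg_%02d", seq_len(config$n_metabolites_other)) else character(0)
    met <- matrix(0, n_met, ns, dimnames = list(c(linked_ids, other_ids),
                                                meta$sample_id))
    for (i in seq_along(linked_ids)) {
      met[i, ] <- 2^(3 + L[tiss_idx] + stats::rnorm(ns, 0, 0.3))
    }
    for (i in seq_along(other_ids)) {
      own <- stats::rnorm(config$n_tissues, 0, 1.5)
      met[config$n_metabolites_linked + i, ] <-
        2^(6.5 + own[tiss_idx] + stats::rnorm(ns, 0, 0.3))
    }
    metabolites <- metabolite_matrix(met, normalized = FALSE)

    labelled_module <- setdiff(roles$module, roles$holdout)
    tx_of <- function(g) tx$transcript_id[tx$gene_id %in% g]
    labels <- label_set(
      positives = tx_of(labelled_module),
      negatives = tx_of(roles$negatives),
      unlabeled = setdiff(tx$transcript_id,
                          tx_of(c(labelled_module, roles$negatives))))

    list(atlas = atlas, metabolites = metabolites, labels = labels,
         truth = list(module_gene_ids = roles$module,
                      negative_gene_ids = roles$negatives,
                      linked_metabolite_ids = linked_ids,
                      holdout_gene_ids = roles$holdout))
  })
}

# Sequential placement of one contig: background genes plus an optional
# planted block (anchor, members within the scan window, decoys beyond it).
.place_contig <- function(cfg, contig, ids_bg, special = NULL) {
  rand_len <- function(k) pmax(300, round(stats::runif(k, 0.6, 1.4) * cfg$mean_gene_len))
  rand_gap <- function(k) pmax(200, round(stats::runif(k, 0.3, 1.7) * cfg$mean_intergenic))
  entries <- data.frame(id = ids_bg, len = rand_len(length(ids_bg)),
                        gap = rand_gap(length(ids_bg)),
                        stringsAsFactors = FALSE)
  planted <- NULL
  if (!is.null(special)) {
    max_gap <- min(90000, floor(cfg$cluster_span_bp / 2))
    len_anchor <- rand_len(1)
    len_m <- rand_len(2)
    g1 <- round(stats::runif(1, 2000, max_gap * 0.45))
    g2 <- round(stats::runif(1, 2000, max(2500, max_gap - g1 - len_m[1] - 1000)))
    if (g1 + len_m[1] + g2 > max_gap) {
      g2 <- max(500, max_gap - g1 - len_m[1] - 100)
    }
    sp <- data.frame(id = c(special$anchor, special$members),
                     len = c(len_anchor, len_m),
                     gap = c(rand_gap(1), g1, g2), stringsAsFactors = FALSE)
    nd <- length(special$decoys)
    if (nd > 0) {
      # decoy start offsets from the anchor end, spaced within (100 kb, 150 kb]
      spacing <- floor(48000 / nd)
      offs <- 100001 + (seq_len(nd) - 1L) * spacing +
        round(stats::runif(nd, 0, max(0, spacing - 6000)))
      prev <- g1 + len_m[1] + g2 + len_m[2]   # offset of last member end
      for (k in seq_len(nd)) {
        len_d <- rand_len(1)
        start_off <- max(offs[k], prev + 300)
        stopifnot(start_off > 100000, start_off <= 150000)
        sp <- rbind(sp, data.frame(id = special$decoys[k], len = len_d,
                                   gap = start_off - prev,
                                   stringsAsFactors = FALSE))
        prev <- start_off + len_d - 1
      }
    }
    k <- min(nrow(entries),
             max(1L, floor(nrow(entries) * stats::runif(1, 0.2, 0.6))))
    entries <- rbind(entries[seq_len(k), , drop = FALSE], sp,
                     entries[setdiff(seq_len(nrow(entries)), seq_len(k)), ,
                             drop = FALSE])
    planted <- special
  }
  pos <- 0
  start <- end <- numeric(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    start[i] <- pos + entries$gap[i]
    end[i] <- start[i] + entries$len[i] - 1
    pos <- end[i]
  }
  genes <- data.frame(gene_id = entries$id, contig = contig, start = start,
                      end = end,
                      strand = sample(c("+", "-"), nrow(entries), replace = TRUE),
                      stringsAsFactors = FALSE)
  list(genes = genes, planted = planted)
}

#' Generate the synthetic genome layout, domain table and ortholog hits
#'
#' Each planted cluster consists of one anchor gene carrying a BLAST hit
#' that passes the 90% coverage / 60% identity ortholog rule, one module
#' MDR gene with the whitelist PF08240 domain and one cytochrome P450
#' (PF00067) gene, all within 100,000 bp of the anchor span. Decoy
#' whitelist genes sit 100,001-150,000 bp from their anchor. Gene spans
#' never overlap within a contig.
#'
#' @param config a [simulation_config()].
#' @return list with elements `genes` (gene models), `domains`
#'   (domain annotations), `hits` (BLAST table with coverage) and `truth`
#'   (planted cluster composition and decoy ids).
#' @export
generate_genome_layout <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  roles <- .assign_gene_roles(config)
  with_seed(child_seed(config$seed, 3L), {
    ids <- roles$ids
    n_place <- if (is.null(config$genes_per_contig)) length(ids) else
      min(length(ids), config$n_contigs * config$genes_per_contig)
    specials <- c(roles$anchors, roles$adh_members, roles$p450_members,
                  roles$decoys)
    placeable <- unique(c(specials, resample(setdiff(ids, specials),
                                             max(0, n_place - length(specials)))))
    bg_place <- setdiff(placeable, specials)
    bg_place <- bg_place[sample.int(length(bg_place), length(bg_place))]
    contigs <- sprintf("ctg%02d", seq_len(config$n_contigs))
    split_idx <- if (length(bg_place) > 0) {
      sort(rep_len(seq_len(config$n_contigs), length(bg_place)))
    } else integer(0)

    genes <- list()
    planted_clusters <- list()
    for (ci in seq_len(config$n_contigs)) {
      special <- NULL
      if (ci <= config$n_planted_clusters) {
        special <- list(anchor = roles$anchors[ci],
                        members = c(roles$adh_members[ci], roles$p450_members[ci]),
                        decoys = roles$decoys[roles$decoy_cluster == ci])
      }
      placed <- .place_contig(config, contigs[ci], bg_place[split_idx == ci],
                              special)
      genes[[ci]] <- placed$genes
      if (!is.null(special)) {
        planted_clusters[[length(planted_clusters) + 1L]] <- list(
          contig = contigs[ci], anchor_gene_id = special$anchor,
          member_gene_ids = special$members, decoy_gene_ids = special$decoys)
      }
    }
    genes <- do.call(rbind, genes)
    if (is.null(genes)) genes <- empty_gene_models()[, 1:5]
    tx <- roles$transcripts
    genes$transcript_ids <- lapply(genes$gene_id, function(g)
      tx$transcript_id[tx$gene_id == g])
    rownames(genes) <- NULL

    # Domain annotations
    adh <- roles$adh
    domains <- data.frame(gene_id = adh$gene_id,
                          pfam_accession = adh$pfam_accession,
                          stringsAsFactors = FALSE)
    p450_genes <- c(roles$p450_members, roles$decoys)
    if (length(p450_genes) > 0) {
      domains <- rbind(domains, data.frame(gene_id = p450_genes,
                                           pfam_accession = "PF00067",
                                           stringsAsFactors = FALSE))
    }
    plain <- setdiff(genes$gene_id, c(adh$gene_id, p450_genes))
    if (length(plain) > 0) {
      domains <- rbind(domains, data.frame(
        gene_id = plain,
        pfam_accession = sample(HOUSEKEEPING_PFAM, length(plain), replace = TRUE),
        stringsAsFactors = FALSE))
    }
    # a few scattered whitelist domains on cluster-free contigs, far from
    # any anchor: realistic annotation noise that must not yield clusters
    free_contigs <- contigs[seq_len(config$n_contigs) > config$n_planted_clusters]
    free_genes <- genes$gene_id[genes$contig %in% free_contigs &
                                  !genes$gene_id %in% c(adh$gene_id, p450_genes)]
    n_scatter <- min(5L, length(free_genes))
    if (n_scatter > 0) {
      sc <- resample(free_genes, n_scatter)
      domains$pfam_accession[match(sc, domains$gene_id)] <-
        sample(c("PF00201", "PF03171", "PF00891"), n_scatter, replace = TRUE)
    }
    domains$domain_name <- unname(PFAM_NAMES[domains$pfam_accession])
    domains$score <- round(stats::runif(nrow(domains), 50, 500), 1)
    domains <- domains[order(domains$gene_id, domains$pfam_accession), ,
                       drop = FALSE]
    rownames(domains) <- NULL

    # BLAST hits vs known MIA proteins: anchors pass the 90/60 rule,
    # near-miss hits fail on identity or coverage
    hit_row <- function(gene, pident, cov, bitscore) {
      alen <- round(cov / 100 * MIA_SUBJECT_LEN)
      data.frame(query_id = paste0(gene, ".1"),
                 subject_id = sample(KNOWN_MIA_PROTEINS, 1),
                 percent_identity = round(pident, 1), alignment_length = alen,
                 mismatches = round(alen * (100 - pident) / 100),
                 gap_opens = 0, q_start = 1, q_end = alen, s_start = 1,
                 s_end = alen, evalue = 1e-80,
                 bitscore = round(bitscore, 1), coverage = round(cov, 1),
                 stringsAsFactors = FALSE)
    }
    hits <- list()
    for (a in roles$anchors) {
      hits[[length(hits) + 1L]] <- hit_row(a, stats::runif(1, 70, 98),
                                           stats::runif(1, 92, 100),
                                           stats::runif(1, 300, 600))
    }
    near_miss <- resample(setdiff(roles$ids, roles$anchors),
                          min(20L, max(0L, length(roles$ids) - length(roles$anchors))))
    for (i in seq_along(near_miss)) {
      if (i %% 2 == 0) {
        hits[[length(hits) + 1L]] <- hit_row(near_miss[i],
                                             stats::runif(1, 30, 59.5),
                                             stats::runif(1, 91, 100),
                                             stats::runif(1, 80, 200))
      } else {
        hits[[length(hits) + 1L]] <- hit_row(near_miss[i],
                                             stats::runif(1, 61, 95),
                                             stats::runif(1, 40, 88),
                                             stats::runif(1, 80, 200))
      }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else {
      h <- as.data.frame(stats::setNames(
        c(replicate(2, character(0), simplify = FALSE),
          replicate(10, numeric(0), simplify = FALSE)), BLAST6_COLS))
      h$coverage <- numeric(0)
      h
    }

    list(genes = genes, domains = domains, hits = hits,
         truth = list(planted_clusters = planted_clusters,
                      decoy_gene_ids = roles$decoys))
  })
}

#' Generate the synthetic GO table and latex proteome
#'
#' A configured fraction of ADH-domain genes receive the oxidoreductase GO
#' term GO:0016491 (half of those also GO:0055114); all other genes draw
#' from a pool of unrelated GO terms. The latex proteome contains a
#' configured number of module ADH genes plus random other genes.
#'
#' @param config a [simulation_config()].
#' @param layout output of [generate_genome_layout()].
#' @return list with elements `go` (gene/GO data.frame), `proteome`
#'   (character vector of gene ids) and `truth` (the proteome module-ADH
#'   gene ids).
#' @export
generate_go_and_proteome <- function(config, layout) {
  stopifnot(inherits(config, "simulation_config"))
  roles <- .assign_gene_roles(config)
  with_seed(child_seed(config$seed, 4L), {
    adh_genes <- sort(unique(roles$adh$gene_id))
    n_ox <- round(config$go_oxidoreductase_frac * length(adh_genes))
    ox_genes <- resample(adh_genes, n_ox)
    go <- data.frame(gene_id = ox_genes,
                     go_term = rep("GO:0016491", length(ox_genes)),
                     stringsAsFactors = FALSE)
    both <- ox_genes[seq_len(floor(n_ox / 2))]
    if (length(both) > 0) {
      go <- rbind(go, data.frame(gene_id = both, go_term = "GO:0055114",
                                 stringsAsFactors = FALSE))
    }
    other_pool <- c("GO:0008150", "GO:0006810", "GO:0016301", "GO:0003677",
                    "GO:0005515", "GO:0046983")
    others <- setdiff(roles$ids, ox_genes)
    if (length(others) > 0) {
      go <- rbind(go, data.frame(
        gene_id = others,
        go_term = sample(other_pool, length(others), replace = TRUE),
        stringsAsFactors = FALSE))
    }
    go <- go[order(go$gene_id, go$go_term), , drop = FALSE]
    rownames(go) <- NULL

    module_adh_ox <- intersect(roles$adh$gene_id[roles$adh$module], ox_genes)
    in_prot_adh <- resample(module_adh_ox,
                            min(config$proteome_adh_module, length(module_adh_ox)))
    filler_pool <- setdiff(roles$ids, in_prot_adh)
    filler <- resample(filler_pool,
                       min(max(0, config$proteome_size - length(in_prot_adh)),
                           length(filler_pool)))
    proteome <- sort(c(in_prot_adh, filler))

    list(go = go, proteome = proteome,
         truth = list(proteome_module_adh = sort(in_prot_adh)))
  })
}

#' Generate a complete synthetic study
#'
#' Runs [generate_atlas()], [generate_genome_layout()] and
#' [generate_go_and_proteome()] under deterministically derived child seeds
#' and assembles their outputs with the merged ground truth.
#'
#' @param config a [simulation_config()].
#' @return object of class `mia_study`: a list with `atlas`, `metabolites`,
#'   `labels`, `genes`, `domains`, `hits`, `go`, `proteome`, `adh_families`,
#'   `truth` and `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  atl <- generate_atlas(config)
  lay <- generate_genome_layout(config)
  gp <- generate_go_and_proteome(config, lay)
  structure(list(
    atlas = atl$atlas, metabolites = atl$metabolites, labels = atl$labels,
    genes = lay$genes, domains = lay$domains, hits = lay$hits,
    go = gp$go, proteome = gp$proteome,
    truth = c(atl$truth, lay$truth, gp$truth),
    config = config), class = "mia_study")
}

#' @export
print.mia_study <- function(x, ...) {
  cat("Synthetic discovery study (seed ", x$config$seed, ")\n", sep = "")
  cat("  atlas: ", nrow(x$atlas$tpm), " transcripts x ", ncol(x$atlas$tpm),
      " samples\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites$values), "\n", sep = "")
  cat("  genome: ", nrow(x$genes), " genes on ",
      length(unique(x$genes$contig)), " contigs; ",
      length(x$truth$planted_clusters), " planted clusters, ",
      length(x$truth$decoy_gene_ids), " decoys\n", sep = "")
  cat("  labels: ", length(x$labels$positives), " positive / ",
      length(x$labels$negatives), " negative / ",
      length(x$labels$unlabeled), " unlabeled transcripts\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes every component in the plain-text formats the readers in this
#' package consume: `atlas.tsv`, `metabolites.tsv`, `genes.gff3`,
#' `domains.tsv`, `mia_hits.tsv`, `go.tsv`, `latex_proteome.txt`,
#' `sample_meta.tsv`, `labels.json` and `ground_truth.json`.
#'
#' @param study a `mia_study` from [simulate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mia_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(study$atlas$tpm, p("atlas.tsv"), "transcript_id")
  utils::write.table(study$atlas$meta, p("sample_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(study$metabolites$values, p("metabolites.tsv"),
                   "metabolite_id")
  write_gene_models(study$genes, p("genes.gff3"))
  write_domain_table(study$domains, p("domains.tsv"))
  write_blast_tab(study$hits, p("mia_hits.tsv"))
  utils::write.table(study$go, p("go.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(study$proteome, p("latex_proteome.txt"))
  jsonlite::write_json(study$labels[c("positives", "negatives", "unlabeled")],
                       p("labels.json"), pretty = TRUE)
  jsonlite::write_json(study$truth, p("ground_truth.json"), pretty = TRUE,
                       auto_unbox = TRUE)
  invisible(dir)
}
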