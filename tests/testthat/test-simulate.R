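test_that("generation is deterministic given the configuration", {
  cfg <- simulation_config(seed = 7, n_genes = 300, n_mia_module = 20,
                           n_negatives = 100, n_background_adh = 10,
                           n_planted_clusters = 2, n_decoy_near_misses = 2)
  a1 <- generate_atlas(cfg)
  a2 <- generate_atlas(cfg)
  expect_identical(a1$atlas$tpm, a2$atlas$tpm)
  expect_identical(a1$metabolites$values, a2$metabolites$values)
  expect_identical(a1$labels, a2$labels)
  l1 <- generate_genome_layout(cfg)
  l2 <- generate_genome_layout(cfg)
  expect_identical(l1$genes, l2$genes)
  expect_identical(l1$hits, l2$hits)
  # different seed changes the draw
  a3 <- generate_atlas(simulation_config(seed = 8, n_genes = 300,
                                         n_mia_module = 20,
                                         n_negatives = 100,
                                         n_background_adh = 10,
                                         n_planted_clusters = 2,
                                         n_decoy_near_misses = 2))
  expect_false(identical(a1$atlas$tpm, a3$atlas$tpm))
})

test_that("degenerate and invalid configurations are handled", {
  cfg0 <- simulation_config(n_genes = 0, n_mia_module = 0, n_negatives = 0,
                            n_background_adh = 0, n_metabolites_linked = 0,
                            n_metabolites_other = 0, n_planted_clusters = 0,
                            n_decoy_near_misses = 0, proteome_size = 0,
                            proteome_adh_module = 0)
  a <- generate_atlas(cfg0)
  expect_equal(nrow(a$atlas$tpm), 0)
  expect_equal(length(a$labels$positives), 0)
  expect_equal(length(a$labels$negatives), 0)

  expect_error(simulation_config(n_genes = 10, n_mia_module = 8,
                                 n_negatives = 5),
               "n_mia_module \\+ n_negatives")
  expect_error(simulation_config(cluster_span_bp = 200000), "cluster_span_bp")
  expect_error(simulation_config(n_mia_module = -1), ">= 0")
})

test_that("planted module is tightly co-expressed and calibrated to noise", {
  base <- function(noise) {
    simulation_config(seed = 3, n_tissues = 16, replicates_per_tissue = 3,
                      n_genes = 200, n_mia_module = 30, n_negatives = 100,
                      n_background_adh = 5, n_planted_clusters = 0,
                      n_decoy_near_misses = 0, module_noise_sd = noise)
  }
  mean_module_r <- function(noise) {
    a <- generate_atlas(base(noise))
    tx <- paste0(a$truth$module_gene_ids, ".1")
    cc <- cor(t(log2(a$atlas$tpm[tx, ] + 1)))
    mean(cc[upper.tri(cc)])
  }
  r_low <- mean_module_r(0.2)
  expect_gte(r_low, 0.8)
  # monotone: more noise, less correlation
  r_mid <- mean_module_r(0.8)
  r_high <- mean_module_r(1.6)
  expect_gt(r_low, r_mid)
  expect_gt(r_mid, r_high)
})

test_that("genome layout satisfies the scanner's geometry by construction", {
  st <- the_study()
  genes <- st$genes
  # non-overlapping spans within each contig
  for (ctg in unique(genes$contig)) {
    g <- genes[genes$contig == ctg, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  gap_to <- function(a, b) {
    ia <- match(a, genes$gene_id); ib <- match(b, genes$gene_id)
    expect_equal(genes$contig[ia], genes$contig[ib])
    max(0, max(genes$start[ia], genes$start[ib]) -
          min(genes$end[ia], genes$end[ib]))
  }
  for (pc in st$truth$planted_clusters) {
    for (m in pc$member_gene_ids) {
      expect_lte(gap_to(pc$anchor_gene_id, m), 100000)
    }
    for (d in pc$decoy_gene_ids) {
      g <- gap_to(pc$anchor_gene_id, d)
      expect_gt(g, 100000)
      expect_lte(g, 150000)
    }
  }
  # every anchor carries a hit passing the 90/60 ortholog rule
  anchors <- assign_mia_orthologs(st$hits)
  for (pc in st$truth$planted_clusters) {
    expect_true(pc$anchor_gene_id %in% anchors$gene_id)
  }
})

test_that("GO and proteome generation honours the configuration", {
  cfg0 <- simulation_config(seed = 5, n_genes = 200, n_mia_module = 20,
                            n_negatives = 100, n_background_adh = 5,
                            n_planted_clusters = 0, n_decoy_near_misses = 0,
                            go_oxidoreductase_frac = 0, proteome_size = 30)
  lay <- generate_genome_layout(cfg0)
  gp0 <- generate_go_and_proteome(cfg0, lay)
  expect_equal(sum(gp0$go$go_term %in% c("GO:0016491", "GO:0055114")), 0)
  expect_length(gp0$proteome, 30)

  cfg1 <- simulation_config(seed = 5, n_genes = 200, n_mia_module = 20,
                            n_negatives = 100, n_background_adh = 5,
                            n_planted_clusters = 0, n_decoy_near_misses = 0,
                            go_oxidoreductase_frac = 1, proteome_adh_module = 8)
  gp1 <- generate_go_and_proteome(cfg1, generate_genome_layout(cfg1))
  lx <- latex_oxidoreductases(gp1$proteome, gp1$go,
                              generate_genome_layout(cfg1)$domains)
  # all module ADHs placed in the proteome pass the latex filter
  expect_true(all(gp1$truth$proteome_module_adh %in% lx$gene_id))
  expect_length(gp1$truth$proteome_module_adh, 8)
})

test_that("a study writes to disk and reads back through the io layer", {
  st <- the_study()
  dir <- withr::local_tempdir()
  write_study(st, dir)
  atlas <- read_matrix(file.path(dir, "atlas.tsv"), "expression")
  expect_identical(atlas, st$atlas$tpm)
  genes <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_setequal(genes$gene_id, st$genes$gene_id)
  hits <- read_blast_tab(file.path(dir, "mia_hits.tsv"))
  expect_equal(hits$coverage, st$hits$coverage)
  dom <- read_domain_table(file.path(dir, "domains.tsv"))
  expect_equal(nrow(dom), nrow(st$domains))
  labels <- jsonlite::read_json(file.path(dir, "labels.json"),
                                simplifyVector = TRUE)
  expect_setequal(labels$positives, st$labels$positives)
})
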