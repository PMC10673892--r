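mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r[[1]], subject_id = r[[2]],
               percent_identity = as.numeric(r[[3]]), alignment_length = 300,
               mismatches = 0, gap_opens = 0, q_start = 1, q_end = 300,
               s_start = 1, s_end = 300, evalue = 1e-50,
               bitscore = as.numeric(r[[5]]), coverage = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)
  }))
}

mk_genes <- function(...) {
  rows <- list(...)
  g <- do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], contig = r[[2]], start = as.numeric(r[[3]]),
               end = as.numeric(r[[4]]), strand = "+",
               stringsAsFactors = FALSE)
  }))
  g$transcript_ids <- lapply(g$gene_id, function(x) paste0(x, ".1"))
  g
}

mk_domains <- function(genes, pfams) {
  data.frame(gene_id = genes, pfam_accession = pfams, domain_name = "x",
             score = 100, stringsAsFactors = FALSE)
}

test_that("ortholog anchors require 60% identity and 90% coverage", {
  hits <- mk_hits(list("g1.1", "THAS", 61, 92, 100),
                  list("g2.1", "THAS", 59, 95, 500))
  a <- assign_mia_orthologs(hits)
  expect_equal(a$gene_id, "g1")          # 61/92 passes, 59/95 fails identity
  expect_equal(nrow(assign_mia_orthologs(hits[0, ])), 0)
  # boundary values are inclusive ("at least")
  edge <- mk_hits(list("g3.1", "VR", 60, 90, 100))
  expect_equal(assign_mia_orthologs(edge)$gene_id, "g3")
})

test_that("best passing hit per gene is chosen by bitscore", {
  hits <- mk_hits(
    list("g1.1", "THAS", 80, 95, 400), list("g1.1", "VR", 85, 96, 300),
    list("g1.1", "GS", 99, 50, 900),   # fails coverage despite top bitscore
    list("g2.1", "VR", 70, 91, 200),   list("g2.1", "THAS", 65, 94, 250),
    list("g3.1", "GS", 30, 95, 100))   # never passes
  a <- assign_mia_orthologs(hits)
  oracle <- do.call(rbind, lapply(split(hits, locus_id(hits$query_id)),
                                  function(h) {
    ok <- h[h$percent_identity >= 60 & h$coverage >= 90, ]
    if (nrow(ok) == 0) return(NULL)
    ok[which.max(ok$bitscore), c("subject_id", "bitscore")]
  }))
  expect_equal(a$gene_id, c("g1", "g2"))
  expect_equal(a$best_subject, oracle$subject_id)
  expect_equal(a$bitscore, oracle$bitscore)
})

test_that("ADH families follow their defining Pfam domains", {
  d <- mk_domains(c("a", "b", "c", "c", "e"),
                  c("PF00107", "PF00067", "PF00106", "PF00248", "PF08240"))
  expect_warning(fam <- classify_adh_family(d), "multiple families")
  expect_equal(unname(fam["a"]), "MDR")
  expect_equal(unname(fam["e"]), "MDR")    # GroES-like domain also MDR
  expect_equal(unname(fam["b"]), "none")   # P450 is not an ADH
  expect_equal(unname(fam["c"]), "AKR,SDR")
})

test_that("the 100 kb window uses span-to-span gap distance", {
  genes <- mk_genes(list("anchor", "c1", 10000, 12000),
                    list("p450", "c1", 95000, 97000))
  domains <- mk_domains(c("anchor", "p450"), c("PF00012", "PF00067"))
  cl <- scan_clusters(genes, "anchor", domains)
  expect_equal(nrow(cl), 1)                 # gap 83,000 <= 100,000
  expect_equal(cl$n_genes_of_interest, 2)
  expect_equal(cl$start, 10000)
  expect_equal(cl$end, 97000)

  genes2 <- mk_genes(list("anchor", "c1", 10000, 12000),
                     list("p450", "c1", 113000, 115000))
  expect_equal(nrow(scan_clusters(genes2, "anchor", domains)), 0)  # gap 101,000

  # exactly at the window edge is still in
  genes3 <- mk_genes(list("anchor", "c1", 10000, 12000),
                     list("p450", "c1", 112000, 114000))
  expect_equal(nrow(scan_clusters(genes3, "anchor", domains)), 1)  # gap 100,000
})

test_that("an anchor needs a distinct whitelist gene and windows merge", {
  # anchor carrying a whitelist domain does not self-satisfy the >= 2 rule
  genes <- mk_genes(list("anchor", "c1", 10000, 12000))
  domains <- mk_domains("anchor", "PF08240")
  expect_equal(nrow(scan_clusters(genes, "anchor", domains)), 0)

  # two anchors 50 kb apart sharing one member merge into a single cluster
  genes2 <- mk_genes(list("a1", "c1", 10000, 12000),
                     list("omt", "c1", 40000, 42000),
                     list("a2", "c1", 60000, 62000))
  domains2 <- mk_domains(c("a1", "omt", "a2"),
                         c("PF00012", "PF00891", "PF00012"))
  cl <- scan_clusters(genes2, c("a1", "a2"), domains2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$anchors, "a1,a2")
  expect_equal(cl$n_genes_of_interest, 3)

  expect_warning(scan_clusters(genes2, c("a1", "ghost"), domains2),
                 "absent from gene models")
})

test_that("scanner equals the all-pairs brute force on random layouts", {
  set.seed(2024)
  for (i in 1:12) {
    lay <- random_layout(n_genes = sample(10:50, 1),
                         n_contigs = sample(1:3, 1))
    got <- scan_to_sets(scan_clusters(lay$genes, lay$anchors, lay$domains))
    want <- brute_scan(lay$genes, lay$anchors, lay$domains)
    expect_identical(got, want)
  }
})

test_that("scanner output is order-invariant and window-monotone", {
  set.seed(77)
  lay <- random_layout(n_genes = 40, n_contigs = 2)
  ref <- scan_to_sets(scan_clusters(lay$genes, lay$anchors, lay$domains))
  perm <- lay$genes[sample(nrow(lay$genes)), ]
  expect_identical(scan_to_sets(scan_clusters(perm, lay$anchors, lay$domains)),
                   ref)
  small <- scan_to_sets(scan_clusters(lay$genes, lay$anchors, lay$domains,
                                      window = 30000))
  big <- scan_to_sets(scan_clusters(lay$genes, lay$anchors, lay$domains,
                                    window = 150000))
  for (s in small) {
    expect_true(any(vapply(big, function(b) all(s %in% b), logical(1))))
  }
})

test_that("planted clusters are recovered and decoys excluded", {
  st <- the_study()
  cl <- the_discovery()$clusters
  sets <- scan_to_sets(cl)
  for (pc in st$truth$planted_clusters) {
    planted <- c(pc$anchor_gene_id, pc$member_gene_ids)
    expect_true(any(vapply(sets, function(s) all(planted %in% s),
                           logical(1))))
  }
  expect_length(intersect(st$truth$decoy_gene_ids, unlist(sets)), 0)
})
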