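test_that("latex oxidoreductase filter intersects GO and ADH families", {
  go <- data.frame(gene_id = c("a", "b", "c", "d"),
                   go_term = c("GO:0016491", "GO:0055114", "GO:0008150",
                               "GO:0016491"), stringsAsFactors = FALSE)
  domains <- data.frame(gene_id = c("a", "b"),
                        pfam_accession = c("PF00106", "PF00012"),
                        stringsAsFactors = FALSE)
  expect_equal(nrow(latex_oxidoreductases(character(0), go, domains)), 0)
  lx <- latex_oxidoreductases(c("a", "b", "c"), go, domains)
  expect_equal(lx$gene_id, c("a", "b"))          # c lacks an ox term
  expect_equal(lx$adh_family, c("SDR", "none"))  # a: GO:0016491 + PF00106
  # toy proteome of 10 with 4 oxidoreductases, 2 of them ADHs
  prot <- paste0("g", 1:10)
  go2 <- data.frame(gene_id = paste0("g", 1:4), go_term = "GO:0055114",
                    stringsAsFactors = FALSE)
  dom2 <- data.frame(gene_id = c("g1", "g2"),
                     pfam_accession = c("PF00107", "PF00248"),
                     stringsAsFactors = FALSE)
  lx2 <- latex_oxidoreductases(prot, go2, dom2)
  expect_equal(nrow(lx2), 4)
  expect_equal(sum(lx2$adh_family != "none"), 2)
})

test_that("candidate merging counts methods and Venn regions exactly", {
  src <- list(A = c("a", "b", "c"), B = c("b", "c"), C = "c")
  cs <- merge_candidates(src)
  expect_equal(nrow(cs), 3)
  expect_equal(cs$n_methods[match(c("a", "b", "c"), cs$gene_id)], c(1, 2, 3))
  venn <- attr(cs, "venn")
  expect_equal(sum(venn), 3)
  expect_equal(unname(venn["A+B+C"]), 1)
  # single source: everything n_methods = 1
  one <- merge_candidates(list(only = c("x", "y")))
  expect_true(all(one$n_methods == 1))
  # idempotent and order invariant
  cs2 <- merge_candidates(src[c(3, 1, 2)])
  expect_equal(sort(cs2$gene_id), sort(cs$gene_id))
  expect_equal(cs2$n_methods[order(cs2$gene_id)],
               cs$n_methods[order(cs$gene_id)])
  # transcript ids collapse to locus before merging
  iso <- merge_candidates(list(A = "MSTRG.5.1", B = "MSTRG.5.2"))
  expect_equal(iso$gene_id, "MSTRG.5")
  expect_equal(iso$n_methods, 2L)
})

test_that("Venn regions sum to the union on random source sets", {
  set.seed(14)
  for (i in 1:10) {
    pool <- paste0("g", 1:30)
    src <- lapply(setNames(1:4, c("w", "x", "y", "z")), function(...)
      sample(pool, sample(5:20, 1)))
    cs <- merge_candidates(src)
    expect_equal(sum(attr(cs, "venn")), nrow(cs))
    # each region count matches direct membership-pattern enumeration
    pat <- apply(as.matrix(cs[names(src)]), 1, function(f)
      paste(names(src)[as.logical(f)], collapse = "+"))
    v <- attr(cs, "venn")
    tp <- table(pat)
    expect_setequal(names(v), names(tp))
    expect_equal(unname(v[names(tp)]), unname(as.integer(tp)))
  }
})

test_that("CDS completeness requires ATG, a stop and frame-length", {
  cands <- merge_candidates(list(A = c("g1", "g2", "g3", "g4")))
  cds <- c(g1 = "ATGAAATAA", g2 = "ATGAAA", g3 = "TTGAAATAA")
  out <- completeness_filter(cands, cds)
  status <- setNames(out$complete_cds, out$gene_id)
  expect_true(status[["g1"]])
  expect_false(status[["g2"]])   # no stop codon
  expect_false(status[["g3"]])   # non-ATG start
  expect_true(is.na(status[["g4"]]))  # unknown CDS retained, flagged
  dropped <- completeness_filter(cands, cds, drop_incomplete = TRUE)
  expect_setequal(dropped$gene_id, c("g1", "g4"))
})

test_that("prioritization keeps multi-method candidates, MDR first", {
  src <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3"), C = "g3")
  fam <- c(g1 = "MDR", g2 = "SDR", g3 = "MDR")
  cs <- merge_candidates(src, fam)
  top <- prioritize(cs, min_methods = 2)
  expect_equal(top$gene_id, c("g3", "g2"))
  expect_equal(prioritize(cs, min_methods = 1)$gene_id[3], "g1")
  oracle <- cs$gene_id[cs$n_methods >= 2]
  expect_setequal(top$gene_id, oracle)
  # all single-method -> empty shortlist
  single <- merge_candidates(list(A = "a", B = "b"))
  expect_equal(nrow(prioritize(single)), 0)
})

test_that("Fisher enrichment matches exact hypergeometric enumeration", {
  universe <- paste0("g", 1:100)
  gene_list <- paste0("g", 1:20)
  tm <- data.frame(gene_id = c(paste0("g", c(1:5, 30:34)), universe),
                   go_term = c(rep("GO:X", 10), rep("GO:ALL", 100)),
                   stringsAsFactors = FALSE)
  res <- fisher_enrichment(gene_list, universe, tm)
  # term covering the whole universe is uninformative
  expect_equal(res$p[res$term == "GO:ALL"], 1)
  row <- res[res$term == "GO:X", ]
  expect_equal(row$k, 5)
  expect_equal(row$K, 10)
  expect_equal(row$p, fisher_oracle(5, 10, 20, 100), tolerance = 1e-10)
  expect_error(fisher_enrichment(c("g1", "zz"), universe, tm),
               "subset of universe")
})

test_that("BH adjustment follows the step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))   # spec hand computation
  tm <- data.frame(gene_id = "g1", go_term = "GO:X",
                   stringsAsFactors = FALSE)
  set.seed(6)
  for (i in 1:20) {
    pv <- runif(sample(3:12, 1))
    adj <- p.adjust(pv, "BH")
    expect_equal(adj, bh_oracle(pv), tolerance = 1e-12)
    expect_true(all(adj >= pv - 1e-12) && all(adj <= 1))
    expect_true(all(diff(adj[order(pv)]) >= -1e-12))
  }
})

test_that("annotation and orthogroup summaries reproduce printed arithmetic", {
  ann <- summarize_annotation(n_total = 23228, n_any = 18658,
                              n_all_four = 12924)
  expect_equal(unname(ann["pct_any"]), 80.3)
  expect_equal(unname(ann["pct_all"]), 55.6)
  expect_equal(unname(summarize_annotation(n_total = 10, n_any = 0,
                                           n_all_four = 0)["pct_any"]), 0)
  # table interface
  tab <- list(g1 = c("u", "p", "g", "k"), g2 = "u", g3 = character(0))
  ann2 <- summarize_annotation(tab)
  expect_equal(unname(ann2["pct_any"]), 66.7)
  expect_equal(unname(ann2["pct_all"]), 33.3)

  og <- summarize_orthogroups(n_assigned = 272661, n_total = 295045,
                              n_orthogroups = 23480)
  expect_equal(unname(og["pct_assigned"]), 92.4)
  expect_equal(unname(og["mean_size"]), 11.6)
  solo <- summarize_orthogroups(setNames(paste0("og", 1:5), paste0("g", 1:5)))
  expect_equal(unname(solo), c(100, 1))
  toy <- summarize_orthogroups(setNames(c("a", "a", "b", "b", "c", "c", "a",
                                          NA, NA, NA), paste0("g", 1:10)))
  expect_equal(unname(toy), c(70, 2.3))
})
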