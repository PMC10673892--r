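# Independent oracles used to validate the package's core computations.
# These deliberately use naive enumeration rather than the vectorized code
# paths they check.

# Counting-based HRR oracle: rank_i(j) = 1 + number of nodes k (other than
# i and j) beating j in i's row, with ties broken by ascending index.
brute_hrr <- function(corr) {
  n <- nrow(corr)
  rank_of <- function(i, j) {
    cnt <- 0L
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      if (corr[i, k] > corr[i, j] ||
          (corr[i, k] == corr[i, j] && k < j)) {
        cnt <- cnt + 1L
      }
    }
    cnt + 1L
  }
  H <- matrix(NA_integer_, n, n, dimnames = dimnames(corr))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) H[i, j] <- max(rank_of(i, j), rank_of(j, i))
    }
  }
  H
}

# All-pairs brute-force cluster scan: returns a list of merged clusters,
# each a sorted character vector of gene ids (anchors + whitelist members).
brute_scan <- function(genes, anchor_ids, domains, window = 100000,
                       whitelist = CLUSTER_PFAM_WHITELIST) {
  acc <- sub("\\.[0-9]+$", "", domains$pfam_accession)
  wl_genes <- unique(domains$gene_id[acc %in% whitelist])
  per <- list()
  for (a in anchor_ids) {
    ai <- which(genes$gene_id == a)
    if (!length(ai)) next
    members <- character(0)
    for (k in seq_len(nrow(genes))) {
      if (genes$contig[k] != genes$contig[ai] || genes$gene_id[k] == a) next
      gap <- max(0, max(genes$start[ai], genes$start[k]) -
                   min(genes$end[ai], genes$end[k]))
      if (gap <= window && genes$gene_id[k] %in% wl_genes) {
        members <- c(members, genes$gene_id[k])
      }
    }
    if (length(members)) per[[a]] <- sort(unique(c(a, members)))
  }
  merged <- list()
  while (length(per)) {
    cur <- per[[1]]
    per <- per[-1]
    repeat {
      hit <- which(vapply(per, function(s)
        length(intersect(s, cur)) > 0, logical(1)))
      if (!length(hit)) break
      cur <- sort(unique(c(cur, unlist(per[hit]))))
      per <- per[-hit]
    }
    merged[[length(merged) + 1L]] <- cur
  }
  merged[order(vapply(merged, `[`, character(1), 1))]
}

# Cluster gene sets as produced by scan_clusters(), in comparable form.
scan_to_sets <- function(cl) {
  sets <- lapply(seq_len(nrow(cl)), function(i)
    sort(unique(c(strsplit(cl$anchors[i], ",", fixed = TRUE)[[1]],
                  cl$members[[i]]$gene_id))))
  sets[order(vapply(sets, `[`, character(1), 1))]
}

# Random toy genome layout for scanner oracle tests. Spans may overlap;
# the scanner must handle that too.
random_layout <- function(n_genes = 30, n_contigs = 2) {
  contigs <- sprintf("c%d", seq_len(n_contigs))
  genes <- data.frame(
    gene_id = sprintf("G%02d", seq_len(n_genes)),
    contig = sample(contigs, n_genes, replace = TRUE),
    start = sample.int(400000, n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(500:5000, n_genes, replace = TRUE)
  genes$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes$transcript_ids <- lapply(genes$gene_id, function(g) paste0(g, ".1"))
  pool <- c(CLUSTER_PFAM_WHITELIST, "PF00012", "PF00069", "PF00400",
            "PF01535")
  domains <- data.frame(
    gene_id = genes$gene_id,
    pfam_accession = sample(pool, n_genes, replace = TRUE),
    domain_name = "x", score = 100, stringsAsFactors = FALSE)
  anchors <- sample(genes$gene_id, sample(2:4, 1))
  list(genes = genes, domains = domains, anchors = anchors)
}

# Two-sided Fisher p by exact hypergeometric tail enumeration: sum the
# probabilities of all tables no more likely than the observed one.
fisher_oracle <- function(k, K, n, N) {
  x <- max(0, n + K - N):min(n, K)
  d <- stats::dhyper(x, K, N - K, n)
  sum(d[d <= d[x == k] * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by hand.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
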