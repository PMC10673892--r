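# Physical biosynthetic-cluster scan: anchor putative MIA orthologs on the
# genome and search 100,000 bp on either side of each anchor span for genes
# carrying pathway-associated Pfam domains.

#' Pfam domains scanned for around MIA anchors
#'
#' 2OG-Fe(II) oxygenase (PF03171), non-haem dioxygenase N-terminal
#' (PF14226), O-methyltransferase (PF00891), ADH GroES-like (PF08240),
#' cytochrome P450 (PF00067), berberine bridge enzyme-like (PF08031) and
#' UDP-glucosyltransferase (PF00201).
#'
#' @export
CLUSTER_PFAM_WHITELIST <- c("PF03171", "PF14226", "PF00891", "PF08240",
                            "PF00067", "PF08031", "PF00201")

#' Assign MIA ortholog anchors from BLAST hits
#'
#' A gene is called a putative MIA ortholog when one of its hits against
#' the known MIA protein set reaches at least `min_coverage` subject
#' coverage and `min_identity` percent identity; among passing hits the
#' best bitscore wins. Query ids are collapsed to locus level.
#'
#' @param hits data.frame from [read_blast_tab()].
#' @param min_identity minimum percent identity (default 60, inclusive).
#' @param min_coverage minimum percent coverage (default 90, inclusive).
#' @return data.frame with one row per anchored gene: `gene_id`,
#'   `best_subject`, `percent_identity`, `coverage`, `bitscore`.
#' @export
assign_mia_orthologs <- function(hits, min_identity = 60, min_coverage = 90) {
  empty <- data.frame(gene_id = character(0), best_subject = character(0),
                      percent_identity = numeric(0), coverage = numeric(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  if (anyNA(hits$coverage)) {
    stop_param("validation error: hits lack coverage; supply subject lengths ",
               "or a 13-column table")
  }
  pass <- hits[hits$percent_identity >= min_identity &
                 hits$coverage >= min_coverage, , drop = FALSE]
  if (nrow(pass) == 0) return(empty)
  pass$gene_id <- locus_id(pass$query_id)
  rows <- vapply(split(seq_len(nrow(pass)), pass$gene_id), function(ix)
    ix[which.max(pass$bitscore[ix])], integer(1))
  out <- data.frame(gene_id = names(rows),
                    best_subject = pass$subject_id[rows],
                    percent_identity = pass$percent_identity[rows],
                    coverage = pass$coverage[rows],
                    bitscore = pass$bitscore[rows],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify genes into ADH families from their Pfam domains
#'
#' MDR (medium-chain dehydrogenase/reductase) iff the gene carries PF00107
#' or PF08240 (either zinc-binding or GroES-like MDR domain suffices);
#' SDR iff PF00106; AKR iff PF00248. Genes matching several families are
#' reported as a comma-joined set with a warning.
#'
#' @param domains data.frame with columns `gene_id`, `pfam_accession`
#'   (versions are stripped if present).
#' @return named character vector gene_id -> family (`"MDR"`, `"SDR"`,
#'   `"AKR"`, `"none"`, or comma-joined combinations).
#' @export
classify_adh_family <- function(domains) {
  acc <- sub("\\.[0-9]+$", "", domains$pfam_accession)
  fam_of <- c(PF00107 = "MDR", PF08240 = "MDR", PF00106 = "SDR",
              PF00248 = "AKR")
  genes <- unique(domains$gene_id)
  out <- vapply(genes, function(g) {
    fams <- unique(stats::na.omit(unname(fam_of[acc[domains$gene_id == g]])))
    if (length(fams) == 0) "none" else
      paste(sort(fams), collapse = ",")
  }, character(1))
  multi <- out[grepl(",", out)]
  if (length(multi)) {
    warning("classify_adh_family: gene(s) in multiple families: ",
            paste(names(multi), collapse = ", "))
  }
  out
}

# Span-to-span gap in bp: 0 when spans overlap, otherwise the number of
# bases strictly between them measured start-to-end.
.span_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' Scan the genome for physically co-localized candidate clusters
#'
#' For each anchor gene, every gene on the same contig whose span lies
#' within `window` bp (span-to-span gap) and carries a whitelist Pfam
#' domain becomes a member. A region qualifies as a cluster when it holds
#' more than one gene of interest — the anchor plus at least one distinct
#' whitelist-domain gene (an anchor that itself carries a whitelist domain
#' does not self-satisfy the rule). Anchor windows sharing any gene are
#' merged; clusters are numbered by (contig, start).
#'
#' @param genes gene models from [read_gene_models()].
#' @param anchors data.frame from [assign_mia_orthologs()] (or a character
#'   vector of anchor gene ids).
#' @param domains domain table with `gene_id`, `pfam_accession`.
#' @param window scan distance in bp on either side of the anchor span.
#' @param whitelist Pfam accessions that mark genes of interest.
#' @return data.frame with one row per cluster: `cluster_id`, `contig`,
#'   `start`, `end`, `n_genes_of_interest`, `anchors` (comma-joined) and a
#'   list column `members` of data.frames (`gene_id`, `pfam_accession`).
#' @export
scan_clusters <- function(genes, anchors, domains, window = 100000,
                          whitelist = CLUSTER_PFAM_WHITELIST) {
  anchor_ids <- if (is.data.frame(anchors)) anchors$gene_id else
    as.character(anchors)
  absent <- setdiff(anchor_ids, genes$gene_id)
  if (length(absent)) {
    warning("scan_clusters: anchor gene(s) absent from gene models: ",
            paste(absent, collapse = ", "))
    anchor_ids <- setdiff(anchor_ids, absent)
  }
  empty <- data.frame(cluster_id = integer(0), contig = character(0),
                      start = numeric(0), end = numeric(0),
                      n_genes_of_interest = integer(0),
                      anchors = character(0), stringsAsFactors = FALSE)
  empty$members <- list()
  if (length(anchor_ids) == 0 || nrow(genes) == 0) return(empty)

  acc <- sub("\\.[0-9]+$", "", domains$pfam_accession)
  wl <- domains[acc %in% whitelist, , drop = FALSE]
  wl$pfam_accession <- acc[acc %in% whitelist]
  wl_genes <- unique(wl$gene_id)

  # member sets per anchor
  per_anchor <- lapply(anchor_ids, function(a) {
    ai <- match(a, genes$gene_id)
    same <- which(genes$contig == genes$contig[ai])
    gaps <- .span_gap(genes$start[ai], genes$end[ai],
                      genes$start[same], genes$end[same])
    near <- genes$gene_id[same[gaps <= window]]
    setdiff(intersect(near, wl_genes), a)
  })
  names(per_anchor) <- anchor_ids
  has_member <- lengths(per_anchor) > 0
  if (!any(has_member)) return(empty)
  live <- anchor_ids[has_member]

  # merge anchor windows that share any gene (members or anchors)
  sets <- lapply(live, function(a) union(a, per_anchor[[a]]))
  comp <- seq_along(sets)
  repeat {
    changed <- FALSE
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (comp[i] != comp[j] && length(intersect(sets[[i]], sets[[j]]))) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  out <- list()
  for (cid in unique(comp)) {
    a_here <- live[comp == cid]
    members <- sort(unique(unlist(per_anchor[a_here])))
    all_genes <- union(a_here, members)
    idx <- match(all_genes, genes$gene_id)
    mem_tab <- wl[wl$gene_id %in% members, c("gene_id", "pfam_accession"),
                  drop = FALSE]
    mem_tab <- unique(mem_tab[order(mem_tab$gene_id, mem_tab$pfam_accession), ,
                              drop = FALSE])
    rownames(mem_tab) <- NULL
    out[[length(out) + 1L]] <- list(
      contig = genes$contig[idx[1]],
      start = min(genes$start[idx]), end = max(genes$end[idx]),
      n_genes_of_interest = length(union(a_here, members)),
      anchors = paste(sort(a_here), collapse = ","),
      members = mem_tab)
  }
  ord <- order(vapply(out, `[[`, character(1), "contig"),
               vapply(out, `[[`, numeric(1), "start"))
  out <- out[ord]
  res <- data.frame(
    cluster_id = seq_along(out),
    contig = vapply(out, `[[`, character(1), "contig"),
    start = vapply(out, `[[`, numeric(1), "start"),
    end = vapply(out, `[[`, numeric(1), "end"),
    n_genes_of_interest = vapply(out, `[[`, numeric(1), "n_genes_of_interest"),
    anchors = vapply(out, `[[`, character(1), "anchors"),
    stringsAsFactors = FALSE)
  res$members <- lapply(out, `[[`, "members")
  res
}
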