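# Joint gene-metabolite co-expression network ranked by highest reciprocal
# rank (HRR). For features i and j, rank_i(j) is the position of j (1 = most
# correlated) in i's descending-correlation ordering over all other
# features, and HRR(i, j) = max(rank_i(j), rank_j(i)). Small HRR means each
# feature is among the other's closest co-expression partners; edges are
# drawn where HRR falls below a threshold (default 30, strict).

#' Combine gene and metabolite profiles over paired samples
#'
#' Builds the joint feature matrix on which the network is computed:
#' filtered transcript TPM and ppm-normalized metabolite rows are aligned
#' on the samples present in both, and log2(x + 1) transformed so that
#' correlations are not dominated by the most abundant tissues.
#'
#' @param atlas a filtered [expression_atlas()].
#' @param metabolites a ppm-normalized [metabolite_matrix()] (raw input is
#'   normalized on the fly with a message).
#' @return numeric matrix of features x paired samples with a `kind`
#'   attribute (`"transcript"` or `"metabolite"` per row).
#' @export
combined_profile_matrix <- function(atlas, metabolites = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"))
  mat <- log2(atlas$tpm + 1)
  kind <- rep("transcript", nrow(mat))
  if (!is.null(metabolites)) {
    stopifnot(inherits(metabolites, "metabolite_matrix"))
    if (!metabolites$normalized) {
      message("combined_profile_matrix: normalizing metabolites to ppm")
      metabolites <- metabolites_to_ppm(metabolites)
    }
    paired <- intersect(colnames(mat), colnames(metabolites$values))
    if (length(paired) < 3) stop_param("need >= 3 paired samples")
    mat <- rbind(mat[, paired, drop = FALSE],
                 log2(metabolites$values[, paired, drop = FALSE] + 1))
    kind <- c(kind, rep("metabolite", nrow(metabolites$values)))
  }
  if (anyDuplicated(rownames(mat))) {
    stop_param("validation error: duplicated feature ids in combined matrix")
  }
  attr(mat, "kind") <- stats::setNames(kind, rownames(mat))
  mat
}

#' Pairwise Pearson correlation over features
#'
#' @param features numeric matrix, features x samples (>= 3 samples).
#'   Constant rows carry no correlation signal and are excluded with a
#'   warning.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(features) {
  stopifnot(is.matrix(features))
  if (ncol(features) < 3) stop_param("need >= 3 samples")
  sds <- apply(features, 1, stats::sd)
  if (any(sds == 0)) {
    warning("pearson_matrix: constant feature(s) excluded: ",
            paste(rownames(features)[sds == 0], collapse = ", "))
    features <- features[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(features))
  diag(r) <- 1
  r
}

#' Highest reciprocal rank matrix
#'
#' For every ordered pair, `rank_i(j)` is the 1-based position of j in i's
#' descending-correlation ordering over all other features, with ties in
#' correlation broken by ascending feature index for determinism;
#' `HRR(i, j) = max(rank_i(j), rank_j(i))`. The diagonal is `NA`.
#'
#' @param corr symmetric correlation matrix.
#' @return integer matrix of the same dimension; symmetric, `NA` diagonal.
#' @export
hrr_matrix <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop_param("validation error: correlation matrix must be square")
  }
  n <- nrow(corr)
  ranks <- matrix(NA_integer_, n, n, dimnames = dimnames(corr))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-corr[i, others], others)]
    ranks[i, ord] <- seq_len(n - 1L)
  }
  hrr <- pmax(ranks, t(ranks))
  diag(hrr) <- NA_integer_
  hrr
}

#' Build an HRR co-expression network
#'
#' Features become nodes; an edge joins i and j iff `HRR(i, j)` is strictly
#' below `threshold` (set `inclusive = TRUE` for `<=`). Isolated nodes are
#' kept in the node table.
#'
#' @param hrr integer HRR matrix from [hrr_matrix()].
#' @param corr the matching correlation matrix (edge annotation).
#' @param threshold integer HRR cutoff (default 30).
#' @param kind optional named character vector tagging each node
#'   (`"transcript"`/`"metabolite"`).
#' @param inclusive use `HRR <= threshold` instead of strict `<`.
#' @return object of class `hrr_network` with `nodes` (data.frame `id`,
#'   `kind`), `edges` (data.frame `node_a`, `node_b`, `r`, `hrr`) and
#'   `threshold`.
#' @export
build_network <- function(hrr, corr, threshold = 30, kind = NULL,
                          inclusive = FALSE) {
  stopifnot(is.matrix(hrr), nrow(hrr) == ncol(hrr))
  ids <- rownames(hrr)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(hrr)))
  sel <- if (inclusive) hrr <= threshold else hrr < threshold
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  edges <- data.frame(node_a = ids[idx[, 1]], node_b = ids[idx[, 2]],
                      r = corr[idx], hrr = as.integer(hrr[idx]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$hrr, edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(id = ids,
                      kind = if (is.null(kind)) "transcript" else
                        unname(kind[ids]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 threshold = as.integer(threshold), inclusive = inclusive),
            class = "hrr_network")
}

#' @export
print.hrr_network <- function(x, ...) {
  cat("HRR co-expression network: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (HRR ", if (x$inclusive) "<= " else "< ",
      x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Convert an HRR network to an igraph object
#'
#' @param net an `hrr_network`.
#' @return an undirected [igraph::graph] with `r` and `hrr` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "hrr_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Query the network around bait nodes
#'
#' Extracts the subnetwork induced by the baits and their direct neighbors,
#' plus a candidate table of non-bait neighbors annotated with their best
#' (smallest) HRR to any bait — the guilt-by-association step that turns
#' known pathway genes into new candidates.
#'
#' @param net an `hrr_network`.
#' @param baits character vector of node ids; unknown baits are skipped
#'   with a warning.
#' @param adh_family optional named vector mapping locus ids to ADH family
#'   (from [classify_adh_family()]) used to tag candidates.
#' @return list with `subnetwork` (an `hrr_network` restricted to baits and
#'   neighbors) and `candidates` (data.frame `id`, `kind`, `best_hrr`,
#'   `best_bait`, `adh_family`).
#' @export
bait_neighborhood <- function(net, baits, adh_family = NULL) {
  stopifnot(inherits(net, "hrr_network"))
  missing <- setdiff(baits, net$nodes$id)
  if (length(missing)) {
    warning("bait_neighborhood: unknown bait(s) skipped: ",
            paste(missing, collapse = ", "))
  }
  baits <- intersect(baits, net$nodes$id)
  e <- net$edges
  touch <- e$node_a %in% baits | e$node_b %in% baits
  eb <- e[touch, , drop = FALSE]
  neigh <- setdiff(unique(c(eb$node_a, eb$node_b)), baits)
  keep_nodes <- union(baits, neigh)
  sub_edges <- e[e$node_a %in% keep_nodes & e$node_b %in% keep_nodes, ,
                 drop = FALSE]
  rownames(sub_edges) <- NULL
  sub <- structure(list(
    nodes = net$nodes[net$nodes$id %in% keep_nodes, , drop = FALSE],
    edges = sub_edges, threshold = net$threshold,
    inclusive = net$inclusive), class = "hrr_network")

  if (length(neigh)) {
    other <- ifelse(eb$node_a %in% baits, eb$node_b, eb$node_a)
    bait_of <- ifelse(eb$node_a %in% baits, eb$node_a, eb$node_b)
    # edges between two baits contribute no candidate
    cand_rows <- !(other %in% baits)
    best <- vapply(neigh, function(id) {
      w <- which(other == id & cand_rows)
      w[which.min(eb$hrr[w])]
    }, integer(1))
    candidates <- data.frame(
      id = neigh,
      kind = net$nodes$kind[match(neigh, net$nodes$id)],
      best_hrr = eb$hrr[best], best_bait = bait_of[best],
      stringsAsFactors = FALSE)
    candidates$adh_family <- if (is.null(adh_family)) NA_character_ else
      unname(adh_family[locus_id(candidates$id)])
    candidates <- candidates[order(candidates$best_hrr, candidates$id), ,
                             drop = FALSE]
    rownames(candidates) <- NULL
  } else {
    candidates <- data.frame(id = character(0), kind = character(0),
                             best_hrr = integer(0), best_bait = character(0),
                             adh_family = character(0),
                             stringsAsFactors = FALSE)
  }
  list(subnetwork = sub, candidates = candidates)
}
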