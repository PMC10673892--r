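# End-to-end candidate discovery: run all four evidence routes on a study
# and intersect them into a prioritized shortlist.

#' Run the full candidate-discovery pipeline
#'
#' Executes, in order: TPM filtering, metabolite ppm normalization, the
#' joint HRR co-expression network with bait-neighborhood extraction, the
#' feed-forward MIA classifier with prediction of unlabeled transcripts,
#' ortholog anchoring plus the 100 kb cluster scan, and the latex-proteome
#' oxidoreductase filter; then merges the ADH candidates of the four
#' routes and prioritizes those supported by at least `min_methods`.
#'
#' @param study a `mia_study` from [simulate_study()], or any list with the
#'   same components (`atlas`, `metabolites`, `labels`, `genes`, `domains`,
#'   `hits`, `go`, `proteome`).
#' @param hrr_threshold HRR edge cutoff (strict, default 30).
#' @param min_methods evidence routes required for the shortlist.
#' @param clf_config a [classifier_config()].
#' @param baits bait node ids for the network query; defaults to the
#'   labeled positive transcripts present in the network.
#' @param min_tpm,min_samples expression filter thresholds.
#' @return object of class `mia_discovery`: network, bait neighborhood,
#'   classifier, predictions, anchors, clusters, latex oxidoreductases,
#'   per-route ADH candidate sets, merged `candidates` and the prioritized
#'   `shortlist`.
#' @export
run_discovery <- function(study,
                          hrr_threshold = 30,
                          min_methods = 2,
                          clf_config = classifier_config(),
                          baits = NULL,
                          min_tpm = 10,
                          min_samples = 6) {
  filtered <- tpm_filter(study$atlas, min_tpm, min_samples)
  ppm <- metabolites_to_ppm(study$metabolites)
  comb <- combined_profile_matrix(filtered, ppm)
  corr <- pearson_matrix(comb)
  hrr <- hrr_matrix(corr)
  kind <- attr(comb, "kind")
  net <- build_network(hrr, corr, threshold = hrr_threshold, kind = kind)

  fam <- classify_adh_family(study$domains)
  is_adh <- function(ids) {
    f <- fam[locus_id(ids)]
    !is.na(f) & f != "none"
  }

  if (is.null(baits)) baits <- intersect(study$labels$positives, net$nodes$id)
  bn <- bait_neighborhood(net, baits, fam)
  coexpr_tx <- bn$candidates$id[bn$candidates$kind == "transcript"]
  route_coexpr <- sort(unique(locus_id(coexpr_tx[is_adh(coexpr_tx)])))

  features <- make_features(filtered)
  clf <- train_classifier(features, study$labels, clf_config)
  pred <- predict_unlabeled(clf, features, study$labels)
  route_ml <- sort(unique(locus_id(
    pred$predicted_mia[is_adh(pred$predicted_mia)])))

  anchors <- assign_mia_orthologs(study$hits)
  clusters <- scan_clusters(study$genes, anchors, study$domains)
  cluster_genes <- unique(unlist(c(
    lapply(clusters$members, function(m) m$gene_id),
    strsplit(clusters$anchors, ",", fixed = TRUE))))
  route_cluster <- sort(unique(cluster_genes[is_adh(cluster_genes)]))

  latex <- latex_oxidoreductases(study$proteome, study$go, study$domains)
  route_proteome <- sort(latex$gene_id[latex$adh_family != "none"])

  routes <- list(coexpression = route_coexpr, ml = route_ml,
                 proteome = route_proteome, cluster = route_cluster)
  candidates <- merge_candidates(routes, fam)
  shortlist <- prioritize(candidates, min_methods)

  structure(list(filtered_atlas = filtered, network = net,
                 bait_neighborhood = bn, classifier = clf,
                 predictions = pred, anchors = anchors, clusters = clusters,
                 latex = latex, adh_family = fam, routes = routes,
                 candidates = candidates, shortlist = shortlist),
            class = "mia_discovery")
}

#' @export
print.mia_discovery <- function(x, ...) {
  cat("MIA candidate discovery\n")
  cat("  network: ", nrow(x$network$nodes), " nodes, ",
      nrow(x$network$edges), " edges (HRR < ", x$network$threshold, ")\n",
      sep = "")
  cat("  classifier validation AUC: ",
      round(x$classifier$report$auc[["validation"]], 3), "; predicted MIA: ",
      length(x$predictions$predicted_mia), " transcripts\n", sep = "")
  cat("  clusters: ", nrow(x$clusters), " (", length(x$anchors$gene_id),
      " anchors)\n", sep = "")
  cat("  route ADH candidates: ",
      paste(sprintf("%s %d", names(x$routes), lengths(x$routes)),
            collapse = ", "), "\n", sep = "")
  cat("  shortlist (>= 2 routes): ", nrow(x$shortlist), " loci\n", sep = "")
  invisible(x)
}
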