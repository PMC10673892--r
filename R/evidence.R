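# Evidence integration: combine candidates from the four prediction routes
# (co-expression, classifier, latex proteome, gene clusters), filter and
# prioritize them, and compute the small summary statistics and enrichment
# tests that accompany a discovery screen.

OXIDOREDUCTASE_GO <- c("GO:0055114", "GO:0016491")

#' Oxidoreductase ADH candidates from the latex proteome
#'
#' Latex proteome members annotated with an oxidation-reduction GO term
#' (GO:0055114 oxidation-reduction process or GO:0016491 oxidoreductase
#' activity) are flagged oxidoreductases and intersected with the ADH
#' family classification.
#'
#' @param proteome character vector of proteome gene ids.
#' @param go_table data.frame with `gene_id`, `go_term`.
#' @param domains domain table used for [classify_adh_family()].
#' @return data.frame `gene_id`, `adh_family` of oxidoreductase proteome
#'   members; non-ADH oxidoreductases carry family `"none"`.
#' @export
latex_oxidoreductases <- function(proteome, go_table, domains) {
  ox_genes <- unique(go_table$gene_id[go_table$go_term %in% OXIDOREDUCTASE_GO])
  hits <- sort(intersect(proteome, ox_genes))
  fam <- classify_adh_family(domains)
  data.frame(gene_id = hits,
             adh_family = ifelse(hits %in% names(fam), unname(fam[hits]),
                                 "none"),
             stringsAsFactors = FALSE)
}

#' Merge candidates from multiple prediction routes
#'
#' Takes one id set per method, collapses ids to locus level, and returns
#' the union with per-method evidence flags, the number of supporting
#' methods, and the counts of all Venn regions.
#'
#' @param sources named list of character vectors (method -> gene ids).
#' @param adh_family optional named vector (locus -> family) used to tag
#'   candidates.
#' @return object of class `candidate_set`: a data.frame with `gene_id`,
#'   one logical column per method, `n_methods` and `adh_family`, ordered
#'   by decreasing support; the attribute `venn` holds the region counts.
#' @export
merge_candidates <- function(sources, adh_family = NULL) {
  stopifnot(is.list(sources), !is.null(names(sources)),
            all(nzchar(names(sources))))
  methods <- names(sources)
  sources <- lapply(sources, function(s) unique(locus_id(as.character(s))))
  ids <- sort(unique(unlist(sources)))
  flags <- vapply(methods, function(m) ids %in% sources[[m]],
                  logical(length(ids)))
  flags <- matrix(flags, nrow = length(ids),
                  dimnames = list(NULL, methods))
  out <- data.frame(gene_id = ids, flags, stringsAsFactors = FALSE)
  out$n_methods <- as.integer(rowSums(flags))
  out$adh_family <- if (is.null(adh_family)) NA_character_ else {
    fam <- unname(adh_family[ids])
    ifelse(is.na(fam), "none", fam)
  }
  out <- out[order(-out$n_methods, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL

  region <- apply(flags, 1, function(f) paste(methods[f], collapse = "+"))
  venn <- table(region)
  attr(out, "venn") <- stats::setNames(as.integer(venn), names(venn))
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set: ", nrow(x), " loci; supported by >= 2 methods: ",
      sum(x$n_methods >= 2), "\n", sep = "")
  NextMethod()
}

#' Flag candidates with complete coding sequences
#'
#' A CDS is complete iff it starts with ATG, ends with a stop codon
#' (TAA/TAG/TGA) and has length divisible by 3. Candidates without a
#' provided CDS are retained with `complete_cds = NA` (fail-open) so the
#' filter never silently discards evidence; set `drop_incomplete = TRUE`
#' to remove candidates whose CDS is demonstrably incomplete.
#'
#' @param candidates a `candidate_set` (or data.frame with `gene_id`).
#' @param cds named character vector of CDS nucleotide sequences.
#' @param drop_incomplete remove rows with `complete_cds == FALSE`.
#' @return the candidate set with a `complete_cds` column.
#' @export
completeness_filter <- function(candidates, cds, drop_incomplete = FALSE) {
  is_complete <- function(s) {
    s <- toupper(s)
    nchar(s) >= 6 && nchar(s) %% 3 == 0 && startsWith(s, "ATG") &&
      substring(s, nchar(s) - 2) %in% c("TAA", "TAG", "TGA")
  }
  status <- vapply(candidates$gene_id, function(g) {
    if (!g %in% names(cds)) NA else is_complete(cds[[g]])
  }, logical(1))
  candidates$complete_cds <- unname(status)
  if (drop_incomplete) {
    candidates <- candidates[is.na(candidates$complete_cds) |
                               candidates$complete_cds, , drop = FALSE]
  }
  candidates
}

#' Prioritize candidates by evidence support
#'
#' Retains candidates identified by at least `min_methods` prediction
#' routes, ranked by the number of supporting methods (descending), MDR
#' family first (the family with the strongest prior role in MIA reduction
#' steps), then gene id.
#'
#' @param candidates a `candidate_set` from [merge_candidates()].
#' @param min_methods minimum number of supporting routes (default 2).
#' @return the prioritized subset, same columns as the input.
#' @export
prioritize <- function(candidates, min_methods = 2) {
  out <- candidates[candidates$n_methods >= min_methods, , drop = FALSE]
  is_mdr <- !is.na(out$adh_family) & grepl("MDR", out$adh_family)
  out <- out[order(-out$n_methods, -is_mdr, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GO term enrichment by two-sided Fisher's exact test
#'
#' For every GO term annotated in the universe, tests the 2x2 table of
#' (in list, in universe) x (has term, lacks term) with a two-sided
#' Fisher's exact test and adjusts across terms by Benjamini-Hochberg.
#'
#' @param gene_list character vector of genes of interest (must be a
#'   subset of `universe`).
#' @param universe character vector of all genes considered.
#' @param term_map data.frame with `gene_id`, `go_term`.
#' @param alpha significance cutoff on the adjusted p-value (annotation
#'   only; all terms are returned).
#' @return data.frame with `term`, `k` (hits in list), `K` (hits in
#'   universe), `n` (list size), `N` (universe size), `p`, `p_adj`,
#'   `significant`, ordered by `p`.
#' @export
fisher_enrichment <- function(gene_list, universe, term_map, alpha = 0.05) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (length(setdiff(gene_list, universe))) {
    stop_param("validation error: gene_list must be a subset of universe")
  }
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- sort(unique(tm$go_term))
  N <- length(universe)
  n <- length(gene_list)
  res <- lapply(terms, function(t) {
    with_term <- unique(tm$gene_id[tm$go_term == t])
    K <- length(with_term)
    k <- length(intersect(with_term, gene_list))
    p <- stats::fisher.test(matrix(c(k, n - k, K - k, N - n - K + k), 2),
                            alternative = "two.sided")$p.value
    data.frame(term = t, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize functional annotation coverage
#'
#' Fraction of genes annotated by at least one source database and by all
#' four, as percentages rounded to one decimal. Accepts either an
#' annotation table (named list gene -> character vector of databases) or
#' the raw counts.
#'
#' @param annotation optional named list mapping gene ids to the databases
#'   that annotated them.
#' @param n_total total number of genes.
#' @param n_any genes annotated by at least one database (when counts are
#'   given directly).
#' @param n_all_four genes annotated by all four databases.
#' @param n_databases number of source databases (default 4).
#' @return named numeric vector `pct_any`, `pct_all`.
#' @export
summarize_annotation <- function(annotation = NULL, n_total = NULL,
                                 n_any = NULL, n_all_four = NULL,
                                 n_databases = 4) {
  if (!is.null(annotation)) {
    if (is.null(n_total)) n_total <- length(annotation)
    n_any <- sum(lengths(annotation) >= 1)
    n_all_four <- sum(vapply(annotation, function(d)
      length(unique(d)) >= n_databases, logical(1)))
  }
  if (is.null(n_total) || n_total <= 0) {
    return(c(pct_any = 0, pct_all = 0))
  }
  c(pct_any = round(100 * n_any / n_total, 1),
    pct_all = round(100 * n_all_four / n_total, 1))
}

#' Summarize orthogroup assignment
#'
#' Percentage of genes assigned to an orthogroup and the mean orthogroup
#' size (assigned genes per distinct orthogroup), rounded to one decimal.
#' Accepts either a gene -> orthogroup assignment vector (`NA` =
#' unassigned) or the raw counts.
#'
#' @param assignments optional named character vector gene -> orthogroup.
#' @param n_assigned,n_total,n_orthogroups raw counts, used when
#'   `assignments` is `NULL`.
#' @return named numeric vector `pct_assigned`, `mean_size`.
#' @export
summarize_orthogroups <- function(assignments = NULL, n_assigned = NULL,
                                  n_total = NULL, n_orthogroups = NULL) {
  if (!is.null(assignments)) {
    n_total <- length(assignments)
    n_assigned <- sum(!is.na(assignments))
    n_orthogroups <- length(unique(stats::na.omit(assignments)))
  }
  pct <- if (n_total > 0) round(100 * n_assigned / n_total, 1) else 0
  size <- if (n_orthogroups > 0) round(n_assigned / n_orthogroups, 1) else 0
  c(pct_assigned = pct, mean_size = size)
}
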