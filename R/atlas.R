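# Expression-atlas containers, preparation and QC.

#' Construct an expression atlas
#'
#' @param tpm non-negative numeric matrix, transcripts x samples, with
#'   transcript rownames and sample colnames.
#' @param meta data.frame with columns `sample_id`, `tissue`, `replicate`
#'   describing every column of `tpm`.
#' @return object of class `expression_atlas` with elements `tpm` and `meta`.
#' @export
expression_atlas <- function(tpm, meta) {
  stopifnot(is.matrix(tpm), is.numeric(tpm), is.data.frame(meta))
  if (!all(c("sample_id", "tissue", "replicate") %in% names(meta))) {
    stop_param("validation error: meta needs sample_id, tissue, replicate")
  }
  if (anyNA(tpm) || (length(tpm) && min(tpm) < 0)) {
    stop_param("validation error: TPM values must be non-negative and complete")
  }
  if (is.null(rownames(tpm)) && nrow(tpm) > 0) {
    stop_param("validation error: transcript rownames required")
  }
  if (anyDuplicated(rownames(tpm))) {
    stop_param("validation error: duplicated transcript ids")
  }
  if (!identical(colnames(tpm), meta$sample_id)) {
    stop_param("validation error: tpm columns must match meta$sample_id")
  }
  structure(list(tpm = tpm, meta = meta), class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat("Expression atlas: ", nrow(x$tpm), " transcripts x ", ncol(x$tpm),
      " samples (", length(unique(x$meta$tissue)), " tissues)\n", sep = "")
  invisible(x)
}

#' Construct a metabolite matrix
#'
#' @param values non-negative numeric matrix, metabolites x samples.
#' @param normalized whether columns are already in parts per million.
#' @return object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values, normalized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values) || (length(values) && min(values) < 0)) {
    stop_param("validation error: metabolite values must be non-negative")
  }
  structure(list(values = values, normalized = normalized),
            class = "metabolite_matrix")
}

#' Construct a label set for classifier training
#'
#' @param positives,negatives,unlabeled pairwise-disjoint character vectors
#'   of transcript ids.
#' @return object of class `label_set`.
#' @export
label_set <- function(positives, negatives, unlabeled = character(0)) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  unlabeled <- unique(as.character(unlabeled))
  if (length(intersect(positives, negatives)) ||
      length(intersect(positives, unlabeled)) ||
      length(intersect(negatives, unlabeled))) {
    stop_param("validation error: label sets must be pairwise disjoint")
  }
  structure(list(positives = positives, negatives = negatives,
                 unlabeled = unlabeled), class = "label_set")
}

#' Filter transcripts by expression support
#'
#' Retains transcripts expressed strictly above `min_tpm` TPM in strictly
#' more than `min_samples` samples — the standard atlas pre-filter before
#' co-expression analysis (defaults: > 10 TPM in at least 7 samples).
#'
#' @param atlas an [expression_atlas()].
#' @param min_tpm expression threshold (exclusive).
#' @param min_samples minimum exceedance count (exclusive).
#' @return filtered [expression_atlas()]; the sample set is unchanged.
#' @export
tpm_filter <- function(atlas, min_tpm = 10, min_samples = 6) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (min_tpm < 0) stop_param("parameter error: min_tpm must be >= 0")
  if (min_samples < 0) stop_param("parameter error: min_samples must be >= 0")
  keep <- rowSums(atlas$tpm > min_tpm) > min_samples
  expression_atlas(atlas$tpm[keep, , drop = FALSE], atlas$meta)
}

#' Normalize metabolite abundances to parts per million
#'
#' Each value is divided by its sample (column) total and multiplied by one
#' million, so every column with a nonzero total sums to 1e6. All-zero
#' columns are left as zeros and reported via the `zero_columns` attribute
#' and a warning.
#'
#' @param raw a [metabolite_matrix()] of raw abundances.
#' @return normalized [metabolite_matrix()] (`normalized = TRUE`).
#' @export
metabolites_to_ppm <- function(raw) {
  stopifnot(inherits(raw, "metabolite_matrix"))
  v <- raw$values
  tot <- colSums(v)
  zero <- tot == 0
  scale <- ifelse(zero, 0, 1e6 / tot)
  out <- sweep(v, 2, scale, "*")
  res <- metabolite_matrix(out, normalized = TRUE)
  if (any(zero)) {
    warning("metabolites_to_ppm: all-zero column(s) left unnormalized: ",
            paste(colnames(v)[zero], collapse = ", "))
    attr(res, "zero_columns") <- colnames(v)[zero]
  }
  res
}

#' Within-tissue replicate concordance
#'
#' For each tissue, the mean Pearson correlation over all replicate pairs,
#' computed across transcripts on log2(TPM + 1); the overall summary is the
#' unweighted mean and standard deviation over tissues. Tissues with fewer
#' than two replicates are excluded with a warning.
#'
#' @param atlas an [expression_atlas()].
#' @return list with `per_tissue` (named numeric vector), `mean` and `sd`.
#' @export
replicate_correlation <- function(atlas) {
  stopifnot(inherits(atlas, "expression_atlas"))
  lg <- log2(atlas$tpm + 1)
  tissues <- unique(atlas$meta$tissue)
  per <- stats::setNames(rep(NA_real_, length(tissues)), tissues)
  for (t in tissues) {
    cols <- atlas$meta$sample_id[atlas$meta$tissue == t]
    if (length(cols) < 2) {
      warning("replicate_correlation: tissue '", t,
              "' has a single replicate; excluded")
      next
    }
    cc <- stats::cor(lg[, cols, drop = FALSE])
    per[t] <- mean(cc[upper.tri(cc)])
  }
  per <- per[!is.na(per)]
  list(per_tissue = per, mean = mean(per), sd = stats::sd(per))
}

#' Classical MDS projection of atlas samples
#'
#' Classical (metric) multidimensional scaling on the distance
#' `1 - Pearson r` between samples, computed across transcripts on
#' log2(TPM + 1). Constant sample vectors are excluded with a warning.
#' Coordinates are centered at the origin.
#'
#' @param atlas an [expression_atlas()].
#' @param k number of output dimensions.
#' @return samples x k coordinate matrix.
#' @export
mds_projection <- function(atlas, k = 2) {
  stopifnot(inherits(atlas, "expression_atlas"))
  lg <- log2(atlas$tpm + 1)
  sds <- apply(lg, 2, stats::sd)
  if (any(sds == 0)) {
    warning("mds_projection: constant sample(s) excluded: ",
            paste(colnames(lg)[sds == 0], collapse = ", "))
    lg <- lg[, sds > 0, drop = FALSE]
  }
  if (ncol(lg) < 3) stop_param("mds_projection needs >= 3 usable samples")
  d <- stats::as.dist(1 - stats::cor(lg))
  coords <- stats::cmdscale(d, k = k)
  sweep(coords, 2, colMeans(coords))
}
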