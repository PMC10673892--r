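# Readers and writers for the external formats the pipeline touches.
#
# All coordinates are 1-based inclusive (GFF convention) end to end. Writers
# emit deterministic column order and full-precision floats so that valid
# files round-trip exactly through their reader.

GFF_FEATURES <- c("gene", "transcript", "mRNA", "exon", "CDS")

#' Read gene models from a GFF3/GTF file
#'
#' Accepts both the StringTie GTF dialect (`gene_id`/`transcript_id`
#' attributes on transcript and exon records) and plain GFF3 (`ID`/`Parent`).
#' Each gene locus is collapsed to a single model whose span is the
#' minimum start / maximum end over all of its features. Feature types other
#' than gene, transcript, mRNA, exon and CDS are ignored.
#'
#' @param path path to a GFF3 or GTF file.
#' @return a data.frame with one row per gene: `gene_id`, `contig`, `start`,
#'   `end` (1-based inclusive), `strand` (`+`, `-` or `.`) and a list column
#'   `transcript_ids`.
#' @seealso [write_gene_models()]
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop_param("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  if (!any(body)) return(empty_gene_models())
  for (i in which(body)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      stop_param("parse error at line ", i, ": expected >= 8 tab-separated fields, got ",
                 length(f))
    }
    st <- suppressWarnings(as.numeric(f[4]))
    en <- suppressWarnings(as.numeric(f[5]))
    if (is.na(st) || is.na(en)) {
      stop_param("parse error at line ", i, ": non-numeric start/end")
    }
    if (st < 1) stop_param("validation error at line ", i, ": start < 1")
    if (en < st) stop_param("validation error at line ", i, ": end < start")
  }
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  keep <- type %in% GFF_FEATURES
  gr <- gr[keep]
  mc <- mc[keep, , drop = FALSE]
  type <- type[keep]
  if (length(gr) == 0) return(empty_gene_models())

  if ("gene_id" %in% names(mc)) {        # GTF dialect
    gid <- as.character(mc$gene_id)
    tid <- if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id) else
      rep(NA_character_, length(gr))
  } else {                               # GFF3 dialect
    id <- as.character(mc$ID)
    parent <- vapply(as.list(mc$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    gid <- tid <- rep(NA_character_, length(gr))
    is_gene <- type == "gene"
    is_tx <- type %in% c("transcript", "mRNA")
    gid[is_gene] <- id[is_gene]
    gid[is_tx] <- parent[is_tx]
    tid[is_tx] <- id[is_tx]
    # exon/CDS point at their transcript; resolve to the gene two-pass
    tx2gene <- stats::setNames(gid[is_tx], id[is_tx])
    is_sub <- type %in% c("exon", "CDS")
    gid[is_sub] <- tx2gene[parent[is_sub]]
    tid[is_sub] <- parent[is_sub]
  }
  ok <- !is.na(gid)
  gr <- gr[ok]; gid <- gid[ok]; tid <- tid[ok]

  tx_pairs <- unique(data.frame(tid = tid, gid = gid,
                                stringsAsFactors = FALSE))
  tx_pairs <- tx_pairs[!is.na(tx_pairs$tid), , drop = FALSE]
  dup <- tx_pairs$tid[duplicated(tx_pairs$tid)]
  if (length(dup)) {
    stop_param("validation error: transcript id(s) mapped to multiple genes: ",
               paste(unique(dup), collapse = ", "))
  }

  genes <- sort(unique(gid))
  out <- data.frame(
    gene_id = genes,
    contig = vapply(genes, function(g)
      as.character(GenomicRanges::seqnames(gr[gid == g]))[1], character(1)),
    start = vapply(genes, function(g)
      min(GenomicRanges::start(gr[gid == g])), numeric(1)),
    end = vapply(genes, function(g)
      max(GenomicRanges::end(gr[gid == g])), numeric(1)),
    strand = vapply(genes, function(g) {
      s <- as.character(GenomicRanges::strand(gr[gid == g]))[1]
      if (s == "*") "." else s
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$transcript_ids <- lapply(genes, function(g)
    sort(unique(stats::na.omit(tid[gid == g]))))
  out
}

empty_gene_models <- function() {
  out <- data.frame(gene_id = character(0), contig = character(0),
                    start = numeric(0), end = numeric(0),
                    strand = character(0), stringsAsFactors = FALSE)
  out$transcript_ids <- list()
  out
}

#' Write gene models as GFF3
#'
#' Emits one `gene` record per locus plus one `mRNA` record per transcript
#' (transcripts inherit the locus span, which is all the model stores).
#'
#' @param genes gene-model data.frame as returned by [read_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    strand <- if (g$strand == ".") "." else g$strand
    lines <- c(lines, paste(g$contig, "miaminer", "gene", g$start, g$end, ".",
                            strand, ".", paste0("ID=", g$gene_id), sep = "\t"))
    for (tx in genes$transcript_ids[[i]]) {
      lines <- c(lines, paste(g$contig, "miaminer", "mRNA", g$start, g$end, ".",
                              strand, ".",
                              paste0("ID=", tx, ";Parent=", g$gene_id),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

BLAST6_COLS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore")

#' Read tabular BLAST hits (outfmt 6, optionally with a coverage column)
#'
#' Standard 12-column BLAST tabular output, optionally extended with a 13th
#' subject-coverage column (`scovhsp`, percent). When the coverage column is
#' absent, coverage is computed as `100 * alignment_length / subject_length`
#' from `subject_lengths`; with neither available, coverage is `NA` and the
#' result carries the attribute `coverage_missing = TRUE`.
#'
#' @param path path to the tab-separated hit table.
#' @param subject_lengths optional named numeric vector of subject protein
#'   lengths (residues), used to derive coverage for 12-column input.
#' @return data.frame of hits with the 12 standard outfmt-6 columns plus
#'   `coverage` (percent of the subject covered by the alignment).
#' @export
read_blast_tab <- function(path, subject_lengths = NULL) {
  if (!file.exists(path)) stop_param("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || length(nf) == 0) {
    out <- as.data.frame(stats::setNames(
      c(replicate(2, character(0), simplify = FALSE),
        replicate(10, numeric(0), simplify = FALSE)), BLAST6_COLS))
    out$coverage <- numeric(0)
    return(out)
  }
  bad <- which(!nf %in% c(12L, 13L))
  if (length(bad)) {
    stop_param("parse error at line ", bad[1], ": expected 12 or 13 columns, got ",
               nf[bad[1]])
  }
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = "character", fill = FALSE)
  out <- stats::setNames(raw[, 1:12], BLAST6_COLS)
  for (col in BLAST6_COLS[3:12]) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(v)) {
      stop_param("parse error: non-numeric value in column '", col,
                 "' at line ", which(is.na(v))[1])
    }
    out[[col]] <- v
  }
  if (ncol(raw) >= 13) {
    cov <- suppressWarnings(as.numeric(raw[[13]]))
    if (anyNA(cov)) stop_param("parse error: non-numeric coverage column")
    out$coverage <- cov
  } else if (!is.null(subject_lengths)) {
    slen <- subject_lengths[out$subject_id]
    if (anyNA(slen)) {
      stop_param("validation error: missing subject length for ",
                 paste(unique(out$subject_id[is.na(slen)]), collapse = ", "))
    }
    out$coverage <- 100 * out$alignment_length / as.numeric(slen)
  } else {
    out$coverage <- NA_real_
    attr(out, "coverage_missing") <- TRUE
  }
  if (any(out$percent_identity < 0 | out$percent_identity > 100)) {
    stop_param("validation error: percent_identity outside [0, 100]")
  }
  if (any(!is.na(out$coverage) & (out$coverage < 0 | out$coverage > 100 + 1e-9))) {
    stop_param("validation error: coverage outside [0, 100]")
  }
  if (any(out$evalue < 0)) stop_param("validation error: negative evalue")
  out
}

#' Write BLAST hits as 13-column tabular text
#'
#' @param hits data.frame as returned by [read_blast_tab()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  lines <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    paste(h$query_id, h$subject_id, fmt_num(h$percent_identity),
          fmt_num(h$alignment_length), fmt_num(h$mismatches),
          fmt_num(h$gap_opens), fmt_num(h$q_start), fmt_num(h$q_end),
          fmt_num(h$s_start), fmt_num(h$s_end), fmt_num(h$evalue),
          fmt_num(h$bitscore), fmt_num(h$coverage), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled numeric matrix from TSV
#'
#' First column holds feature ids, the header row holds sample ids. Missing
#' values are rejected for expression matrices and treated as zero (with a
#' message) for metabolite matrices.
#'
#' @param path path to the TSV file.
#' @param kind `"expression"` or `"metabolite"`.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path, kind = c("expression", "metabolite")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_param("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1) {
    stop_param("parse error at line ", which(nf != nf[1])[1], ": ragged row (",
               nf[which(nf != nf[1])[1]], " fields, expected ", nf[1], ")")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop_param("validation error: duplicated feature id(s): ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (anyNA(mat)) {
    if (kind == "expression") {
      stop_param("validation error: missing values in expression matrix")
    }
    message("read_matrix: ", sum(is.na(mat)),
            " missing metabolite value(s) set to 0")
    mat[is.na(mat)] <- 0
  }
  mat
}

#' Write a labelled numeric matrix as TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @param feature_col header for the id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, feature_col = "feature_id") {
  header <- paste(c(feature_col, colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], fmt_num(mat[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a protein-domain annotation table
#'
#' Simplified hmmscan-style TSV with header
#' `gene_id  pfam_accession  domain_name  score`. Accession versions are
#' stripped on read so that all downstream matching is version-agnostic.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene_id`, `pfam_accession`,
#'   `domain_name`, `score`.
#' @export
read_domain_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "pfam_accession", "domain_name", "score")
  if (!all(need %in% names(df))) {
    stop_param("parse error: domain table must have columns ",
               paste(need, collapse = ", "))
  }
  df$pfam_accession <- strip_pfam_version(df$pfam_accession)
  df$score <- as.numeric(df$score)
  df[need]
}

#' Write a protein-domain annotation table
#' @param domains data.frame as returned by [read_domain_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  lines <- c(paste("gene_id", "pfam_accession", "domain_name", "score",
                   sep = "\t"),
             vapply(seq_len(nrow(domains)), function(i)
               paste(domains$gene_id[i], domains$pfam_accession[i],
                     domains$domain_name[i], fmt_num(domains$score[i]),
                     sep = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-to-GO annotation table
#'
#' TSV with header `gene_id  go_term`, one row per association.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene_id`, `go_term`.
#' @export
read_go_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "go_term") %in% names(df))) {
    stop_param("parse error: GO table must have columns gene_id, go_term")
  }
  df[c("gene_id", "go_term")]
}
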