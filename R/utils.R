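# Internal helpers shared across modules.

#' Collapse transcript identifiers to locus identifiers
#'
#' StringTie-style transcript ids append an isoform index to the locus id
#' (`MSTRG.5283.1` is isoform 1 of locus `MSTRG.5283`). Network analyses work
#' at transcript level while genome scans work at locus level; this is the
#' join key between them. A trailing `.<integer>` is stripped only when the
#' remainder still contains a digit, so locus ids such as `MSTRG.5283`
#' (remainder `MSTRG`) pass through unchanged.
#'
#' @param ids character vector of transcript or gene identifiers.
#' @return character vector of locus-level identifiers.
#' @examples
#' locus_id(c("MSTRG.5283.1", "MSTRG.5283", "geneA"))
#' @export
locus_id <- function(ids) {
  stopifnot(is.character(ids))
  stripped <- sub("\\.[0-9]+$", "", ids)
  strip_ok <- grepl("\\.[0-9]+$", ids) & grepl("[0-9]", stripped)
  ifelse(strip_ok, stripped, ids)
}

#' Strip the version suffix from Pfam accessions
#'
#' Pfam accessions are cited both versioned (`PF00107.26`) and unversioned
#' (`PF00107`); all domain matching in this package is version-agnostic.
#'
#' @param acc character vector of Pfam accessions.
#' @return accessions with any `.N` version suffix removed.
#' @export
strip_pfam_version <- function(acc) {
  out <- sub("\\.[0-9]+$", "", acc)
  bad <- !grepl("^PF[0-9]{5}$", out)
  if (any(bad)) {
    stop("invalid Pfam accession(s): ", paste(unique(out[bad]), collapse = ", "))
  }
  out
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed derivation; keeps results < 2^31 for R's set.seed.
child_seed <- function(seed, k) {
  (as.numeric(seed) %% 1e8) * 13L + k
}

# Numeric formatting used by all writers: full double precision, deterministic.
fmt_num <- function(x) sprintf("%.17g", x)

stop_param <- function(...) stop(..., call. = FALSE)
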