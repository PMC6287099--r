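#' Variant tables
#'
#' A variant table is a tibble with one row per variant site and the class
#' `"variant_table"`. Positions are 0-based internally (converted from the
#' 1-based VCF convention on read, converted back on write). Columns:
#'
#' * `chrom`, `pos` — chromosome and 0-based position.
#' * `ref`, `alt` — reference allele and list-column of alternate alleles,
#'   all over `{A,C,G,T}` (indel alleles are anchored VCF-style strings).
#' * `kind` — `"SNP"`, `"insertion"` or `"deletion"`.
#' * `qual` — site quality (`NA` when the caller reported none).
#' * `hom_len` — reference homopolymer context length (indel filter input).
#' * `gt` — list-column; each element a 2 x n_samples integer matrix of
#'   allele indices (0 = ref) with sample names as column names; `NA` marks
#'   a missing call.
#' * `phased` — list-column of per-sample logical phasing flags.
#' * `ad` — list-column; each element an (1 + n_alt) x n_samples matrix of
#'   per-allele read depths, or `NULL` when the record carries no depths.
#'
#' Multi-allelic records are kept intact; operations that require biallelic
#' sites skip the rest explicitly rather than splitting records (splitting
#' would distort the read-depth semantics the pooled-heterozygosity scan
#' relies on).
#'
#' @param chrom,pos,ref,alt,kind,qual,hom_len,gt,phased,ad Columns as
#'   described above (`alt`, `gt`, `phased`, `ad` are lists).
#' @param samples Character vector of sample identifiers, in column order of
#'   the `gt` matrices.
#' @return A `variant_table` tibble.
#' @export
variant_table <- function(chrom, pos, ref, alt, kind, gt, phased, ad = NULL,
                          qual = NA_real_, hom_len = NA_integer_,
                          samples = NULL) {
  n <- length(pos)
  if (is.null(ad)) ad <- rep(list(NULL), n)
  tb <- tibble::tibble(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.list(alt),
    kind = as.character(kind),
    qual = rep_len(as.double(qual), n),
    hom_len = rep_len(as.integer(hom_len), n),
    gt = as.list(gt),
    phased = as.list(phased),
    ad = as.list(ad)
  )
  tb <- dplyr::arrange(tb, chrom, pos)
  if (is.null(samples)) {
    samples <- if (n > 0) colnames(tb$gt[[1]]) else character()
  }
  new_variant_table(tb, samples)
}

new_variant_table <- function(tb, samples) {
  attr(tb, "samples") <- as.character(samples)
  class(tb) <- unique(c("variant_table", class(tb)))
  validate_variant_table(tb)
}

validate_variant_table <- function(vt) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "kind", "gt", "phased",
                  "ad") %in% names(vt)))
  if (nrow(vt) == 0) return(vt)
  if (any(vt$pos < 0)) stop("variant positions must be >= 0", call. = FALSE)
  if (any(!nzchar(vt$ref))) stop("empty REF allele", call. = FALSE)
  smp <- vt_samples(vt)
  bad <- purrr::pmap_lgl(list(vt$gt, vt$alt, vt$ad), function(g, a, d) {
    n_all <- 1L + length(a)
    idx <- g[!is.na(g)]
    if (length(idx) && (any(idx < 0) || any(idx >= n_all))) return(TRUE)
    if (!is.null(d) && nrow(d) != n_all) return(TRUE)
    ncol(g) != length(smp)
  })
  if (any(bad)) {
    stop("invalid variant record(s) at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  vt
}

#' Sample identifiers of a variant table
#' @param vt A `variant_table`.
#' @return Character vector of sample ids.
#' @export
vt_samples <- function(vt) {
  smp <- attr(vt, "samples")
  if (is.null(smp) && nrow(vt) > 0) smp <- colnames(vt$gt[[1]])
  smp %||% character()
}

#' Is each site a biallelic SNP?
#' @param vt A `variant_table`.
#' @return Logical vector along rows.
#' @export
vt_is_biallelic_snp <- function(vt) {
  vt$kind == "SNP" & lengths(vt$alt) == 1L
}

#' Alternate-allele dosage matrix
#'
#' For biallelic sites, the per-sample count (0/1/2) of the alternate allele;
#' `NA` where the genotype is missing. Rows are sites, columns samples.
#'
#' @param vt A `variant_table` (all rows must be biallelic).
#' @param samples Samples to include (default all).
#' @return Integer matrix, `nrow(vt)` x `length(samples)`.
#' @export
allele_dosage <- function(vt, samples = vt_samples(vt)) {
  miss <- setdiff(samples, vt_samples(vt))
  if (length(miss)) {
    stop("sample(s) not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(vt) == 0) {
    return(matrix(integer(), 0, length(samples),
                  dimnames = list(NULL, samples)))
  }
  if (any(lengths(vt$alt) != 1L)) {
    stop("allele_dosage() requires biallelic sites", call. = FALSE)
  }
  out <- t(vapply(vt$gt, function(g) {
    gs <- g[, samples, drop = FALSE]
    colSums(gs == 1L)
  }, numeric(length(samples))))
  colnames(out) <- samples
  out
}

#' Pooled per-allele read depths
#'
#' Sums allelic depths over `samples` at each site. Sites without depth data
#' return `NULL` entries.
#'
#' @param vt A `variant_table`.
#' @param samples Samples to pool.
#' @return List of numeric vectors (one depth per allele) or `NULL`.
#' @keywords internal
pooled_allele_depth <- function(vt, samples = vt_samples(vt)) {
  purrr::map(vt$ad, function(d) {
    if (is.null(d)) return(NULL)
    rowSums(d[, samples, drop = FALSE])
  })
}

#' Subset a variant table to sites polymorphic within a sample set
#'
#' Keeps sites where, among the given samples' non-missing genotype calls, at
#' least two distinct alleles are observed. Used to derive per-breed SNP sets
#' for breed-level desert scans.
#'
#' @param vt A `variant_table`.
#' @param samples Samples defining the sub-cohort.
#' @return A `variant_table` restricted to polymorphic sites; its sample set
#'   is unchanged (all samples retained).
#' @export
subset_polymorphic <- function(vt, samples) {
  if (nrow(vt) == 0) return(vt)
  keep <- purrr::map_lgl(vt$gt, function(g) {
    a <- g[, samples, drop = FALSE]
    a <- a[!is.na(a)]
    length(unique(a)) >= 2L
  })
  out <- vt[keep, ]
  new_variant_table(out, vt_samples(vt))
}

#' @importFrom rlang %||%
NULL
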