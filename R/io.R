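#' Read a VCF file into a variant table
#'
#' Parses a VCF 4.x file (via vcfR) into the package's [variant_table()]
#' model. Positions are shifted from 1-based VCF to the internal 0-based
#' convention; multi-allelic records are preserved; records are ordered by
#' `(chrom, pos)`. `GT` is required; `AD` is honoured when present; the
#' `HRUN` INFO key (reference homopolymer run length) populates `hom_len`.
#'
#' @param path Path to an (optionally gzipped) VCF file.
#' @param samples Optional character vector restricting to a sample subset;
#'   an unknown sample is an error.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0) {
    hdr_samples <- colnames(v@gt)
    hdr_samples <- setdiff(hdr_samples, "FORMAT")
    smp <- samples %||% hdr_samples
    return(variant_table(character(), integer(), character(), list(),
                         character(), list(), list(), samples = smp))
  }
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    stop("VCF records without a GT field are not supported", call. = FALSE)
  }
  hdr_samples <- setdiff(colnames(v@gt), "FORMAT")
  if (is.null(samples)) {
    samples <- hdr_samples
  } else {
    miss <- setdiff(samples, hdr_samples)
    if (length(miss)) {
      stop("sample(s) absent from VCF header: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }

  gt_raw <- vcfR::extract.gt(v, "GT")[, samples, drop = FALSE]
  has_ad <- any(grepl("(^|:)AD(:|$)", fmt))
  ad_raw <- if (has_ad) {
    suppressWarnings(vcfR::extract.gt(v, "AD")[, samples, drop = FALSE])
  }
  hrun <- suppressWarnings(vcfR::extract.info(v, "HRUN", as.numeric = TRUE))

  alt <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                  fixed = TRUE)
  ref <- fix[, "REF"]
  kind <- variant_kind(ref, alt)
  n <- nrow(fix)
  gt <- vector("list", n)
  ph <- vector("list", n)
  ad <- vector("list", n)
  for (i in seq_len(n)) {
    parsed <- parse_gt_strings(gt_raw[i, ], samples)
    gt[[i]] <- parsed$gt
    ph[[i]] <- parsed$phased
    if (has_ad && !all(is.na(ad_raw[i, ]))) {
      ad[[i]] <- parse_ad_strings(ad_raw[i, ], 1L + length(alt[[i]]), samples)
    }
  }
  variant_table(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = ref, alt = alt, kind = kind,
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    hom_len = if (is.null(hrun)) NA_integer_ else as.integer(hrun),
    gt = gt, phased = ph, ad = ad, samples = samples
  )
}

variant_kind <- function(ref, alt) {
  vapply(seq_along(ref), function(i) {
    a <- alt[[i]]
    if (nchar(ref[[i]]) == 1L && length(a) && all(nchar(a) == 1L)) return("SNP")
    if (length(a) && all(nchar(a) >= nchar(ref[[i]]))) return("insertion")
    "deletion"
  }, character(1))
}

parse_gt_strings <- function(x, samples) {
  phased <- grepl("|", x, fixed = TRUE)
  parts <- strsplit(ifelse(is.na(x), ".", x), "[/|]")
  g <- vapply(parts, function(p) {
    p <- suppressWarnings(as.integer(p))
    c(p, NA_integer_)[1:2]
  }, integer(2))
  colnames(g) <- samples
  names(phased) <- samples
  list(gt = g, phased = phased)
}

parse_ad_strings <- function(x, n_alleles, samples) {
  m <- vapply(strsplit(ifelse(is.na(x), ".", x), ",", fixed = TRUE),
              function(p) {
                p <- suppressWarnings(as.integer(p))
                out <- rep(0L, n_alleles)
                out[seq_len(min(length(p), n_alleles))] <-
                  p[seq_len(min(length(p), n_alleles))]
                out[is.na(out)] <- 0L
                out
              }, integer(n_alleles))
  m <- matrix(m, nrow = n_alleles, dimnames = list(NULL, samples))
  m
}

#' Write a variant table to a VCF 4.2 file
#'
#' Serializes a [variant_table()] back to plain-text VCF; positions revert to
#' the 1-based convention. `read_vcf(write_vcf(x))` reproduces `x`.
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path, contigs = NULL) {
  smp <- vt_samples(vt)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=caprisweep",
           '##INFO=<ID=HRUN,Number=1,Type=Integer,Description="Reference homopolymer run length">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", smp), collapse = "\t"))
  body <- character(nrow(vt))
  for (i in seq_len(nrow(vt))) {
    g <- vt$gt[[i]]
    ph <- vt$phased[[i]]
    sep <- ifelse(ph[smp], "|", "/")
    a1 <- g[1, smp]; a2 <- g[2, smp]
    gt_str <- paste0(ifelse(is.na(a1), ".", a1), sep,
                     ifelse(is.na(a2), ".", a2))
    d <- vt$ad[[i]]
    if (is.null(d)) {
      fmt <- "GT"
      cells <- gt_str
    } else {
      fmt <- "GT:AD"
      ad_str <- apply(d[, smp, drop = FALSE], 2, paste, collapse = ",")
      cells <- paste0(gt_str, ":", ad_str)
    }
    info <- if (!is.na(vt$hom_len[[i]])) {
      sprintf("HRUN=%d", vt$hom_len[[i]])
    } else "."
    body[i] <- paste(c(vt$chrom[[i]], vt$pos[[i]] + 1L, ".", vt$ref[[i]],
                       paste(vt$alt[[i]], collapse = ","),
                       ifelse(is.na(vt$qual[[i]]), ".",
                              format(vt$qual[[i]], trim = TRUE)),
                       "PASS", info, fmt, cells), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Reads BED3+ (0-based, half-open). With `merge = TRUE` (default, the
#' callable-mask reading), overlapping or bookended intervals per chromosome
#' are unioned and sorted; with `merge = FALSE` rows are kept as-is (sorted)
#' with any name column retained — used for QTL and CNV interval files.
#'
#' @param path BED file path.
#' @param merge Union overlapping intervals?
#' @return Tibble with `chrom`, `start`, `end` (+ `name` if present and
#'   `merge = FALSE`).
#' @export
read_bed <- function(path, merge = TRUE) {
  tb <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  if (nrow(tb) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  out <- tibble::tibble(chrom = as.character(tb[[1]]),
                        start = as.integer(tb[[2]]),
                        end = as.integer(tb[[3]]))
  if (any(out$start >= out$end)) {
    stop("BED interval with start >= end in ", path, call. = FALSE)
  }
  if (!merge) {
    if (ncol(tb) >= 4) out$name <- as.character(tb[[4]])
    return(dplyr::arrange(out, chrom, start))
  }
  merge_intervals(out)
}

#' Union overlapping intervals per chromosome
#'
#' @param tb Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param min_gapwidth Intervals separated by a gap smaller than this are
#'   joined (default 1: overlapping or bookended intervals union).
#' @return Sorted tibble of disjoint intervals.
#' @export
merge_intervals <- function(tb, min_gapwidth = 1L) {
  if (nrow(tb) == 0) return(tb[c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(intervals_to_granges(tb),
                              min.gapwidth = min_gapwidth)
  granges_to_tibble(gr)
}

intervals_to_granges <- function(tb) {
  GenomicRanges::GRanges(
    seqnames = tb$chrom,
    ranges = IRanges::IRanges(start = tb$start + 1L, end = tb$end)
  )
}

granges_to_tibble <- function(gr) {
  tb <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  dplyr::arrange(tb, chrom, start)
}

#' Write intervals (optionally with extra columns) as BED
#' @param tb Tibble with `chrom`, `start`, `end` and optional extra columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(tb, path) {
  readr::write_tsv(tb, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features (1-based inclusive GFF3 coordinates,
#' converted to 0-based half-open). When a gene has several transcripts the
#' transcript with the longest total CDS is retained, so each gene maps to
#' one CDS chain. CDS features whose parentage cannot be traced to a gene
#' are an error.
#'
#' @param path GFF3 file path.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`, and a
#'   `cds` list-column of tibbles (`start`, `end`, genomic order).
#' @export
read_gff3 <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  feat_id <- as.character(g$ID)
  parent <- vapply(g$Parent, function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
  is_gene <- g$type == "gene"
  gene_of <- stats::setNames(feat_id[is_gene], feat_id[is_gene])
  is_tx <- g$type %in% c("mRNA", "transcript")
  tx_gene <- stats::setNames(parent[is_tx], feat_id[is_tx])

  cds <- g[g$type == "CDS", , drop = FALSE]
  cds_parent <- parent[g$type == "CDS"]
  cds_gene <- ifelse(cds_parent %in% names(tx_gene), tx_gene[cds_parent],
                     ifelse(cds_parent %in% names(gene_of), cds_parent,
                            NA_character_))
  if (any(is.na(cds_gene))) {
    stop("CDS feature(s) without a resolvable parent gene in ", path,
         call. = FALSE)
  }
  cds_tx <- ifelse(cds_parent %in% names(tx_gene), cds_parent,
                   paste0(cds_parent, ".tx"))

  genes <- g[is_gene, , drop = FALSE]
  out <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    gid <- feat_id[is_gene][i]
    sel <- cds_gene == gid
    cds_tb <- tibble::tibble(start = integer(), end = integer())
    if (any(sel)) {
      # longest-CDS transcript represents the gene
      sub <- cds[sel, , drop = FALSE]
      txs <- cds_tx[sel]
      len_by_tx <- tapply(sub$end - sub$start + 1L, txs, sum)
      best <- names(len_by_tx)[which.max(len_by_tx)]
      sub <- sub[txs == best, , drop = FALSE]
      cds_tb <- tibble::tibble(start = as.integer(sub$start) - 1L,
                               end = as.integer(sub$end))
      cds_tb <- dplyr::arrange(cds_tb, start)
    }
    tibble::tibble(
      gene_id = gid,
      chrom = as.character(genes$seqid[i]),
      start = as.integer(genes$start[i]) - 1L,
      end = as.integer(genes$end[i]),
      strand = as.character(genes$strand[i]),
      cds = list(cds_tb)
    )
  })
  dplyr::arrange(out, chrom, start)
}

#' Read a sample-to-group assignment table
#'
#' Expects a TSV with header `sample<TAB>group`. Sample ids must be unique.
#'
#' @param path TSV path.
#' @param vcf_samples Optional sample vector (e.g. from a variant table) to
#'   validate against; unknown samples are an error.
#' @return Tibble with `sample`, `group`.
#' @export
read_group_table <- function(path, vcf_samples = NULL) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "group") %in% names(tb))) {
    stop("group table must have columns 'sample' and 'group'", call. = FALSE)
  }
  tb <- tibble::tibble(sample = as.character(tb$sample),
                       group = as.character(tb$group))
  if (anyDuplicated(tb$sample)) {
    stop("duplicate sample ids in group table", call. = FALSE)
  }
  if (!is.null(vcf_samples)) {
    miss <- setdiff(tb$sample, vcf_samples)
    if (length(miss)) {
      stop("group table sample(s) absent from VCF: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  tb
}

#' Samples belonging to one or more groups
#' @param groups Tibble from [read_group_table()].
#' @param which Group label(s).
#' @return Character vector of sample ids (group-table order).
#' @export
group_samples <- function(groups, which) {
  miss <- setdiff(which, unique(groups$group))
  if (length(miss)) {
    stop("unknown group(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  groups$sample[groups$group %in% which]
}

#' Read a FASTA reference
#' @param path FASTA path.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)
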