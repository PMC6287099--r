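#' Classify SNP effects against gene models
#'
#' Assigns each biallelic SNP one of the categories `intergenic`, `intronic`,
#' `synonymous`, `nonsynonymous` or `other_coding`, by locating it against
#' gene spans and CDS chains and, for coding sites, substituting the
#' alternate base into the reference codon. Stop-gain/stop-loss changes are
#' folded into `nonsynonymous` and flagged via `stop_change`. Minus-strand
#' genes are handled by reverse complement. Sites falling into the CDS of a
#' gene whose CDS length is not a multiple of three (partial model at a
#' contig edge) are reported as `other_coding`.
#'
#' @param vt A [variant_table()]; only biallelic SNP rows are classified.
#' @param genes Gene-model tibble from [read_gff3()] / [plant_genes()].
#' @param reference A `DNAStringSet` (names = chromosomes).
#' @return Tibble with `chrom`, `pos`, `category`, `gene_id`, `codon_ref`,
#'   `codon_alt`, `aa_ref`, `aa_alt`, `stop_change`.
#' @export
classify_effects <- function(vt, genes, reference) {
  bi <- vt_is_biallelic_snp(vt)
  sub <- vt[bi, ]
  n <- nrow(sub)
  out <- tibble::tibble(
    chrom = sub$chrom, pos = sub$pos,
    category = rep("intergenic", n),
    gene_id = NA_character_,
    codon_ref = NA_character_, codon_alt = NA_character_,
    aa_ref = NA_character_, aa_alt = NA_character_,
    stop_change = FALSE
  )
  if (n == 0 || nrow(genes) == 0) return(out)

  ref_ok <- purrr::map_lgl(seq_len(n), function(i) {
    chr <- sub$chrom[i]
    if (!chr %in% names(reference)) return(FALSE)
    as.character(Biostrings::subseq(reference[[chr]], sub$pos[i] + 1L,
                                    sub$pos[i] + 1L)) == sub$ref[i]
  })
  if (!all(ref_ok)) {
    bad <- which(!ref_ok)[1]
    stop("reference mismatch at ", sub$chrom[bad], ":", sub$pos[bad] + 1L,
         call. = FALSE)
  }

  site_gr <- GenomicRanges::GRanges(sub$chrom,
                                    IRanges::IRanges(sub$pos + 1L, sub$pos + 1L))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # one gene per site: first (leftmost) overlapping gene wins deterministically
  first <- !duplicated(qh)
  maps <- data.frame(site = qh[first], gene = sh[first])

  cds_maps <- cds_position_maps(genes, reference)

  for (k in seq_len(nrow(maps))) {
    i <- maps$site[k]; gi <- maps$gene[k]
    gid <- genes$gene_id[gi]
    out$gene_id[i] <- gid
    m <- cds_maps[[gid]]
    idx <- match(sub$pos[i], m$gpos)
    if (is.na(idx)) {
      out$category[i] <- "intronic"
      next
    }
    if (length(m$gpos) %% 3L != 0L) {
      out$category[i] <- "other_coding"
      next
    }
    codon_i <- (idx - 1L) %/% 3L
    within <- (idx - 1L) %% 3L
    codon <- m$cds_seq[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
    alt_base <- sub$alt[[i]][1]
    if (genes$strand[gi] == "-") alt_base <- dna_complement(alt_base)
    codon_alt <- codon
    codon_alt[within + 1L] <- alt_base
    aa_ref <- Biostrings::GENETIC_CODE[[paste(codon, collapse = "")]]
    aa_alt <- Biostrings::GENETIC_CODE[[paste(codon_alt, collapse = "")]]
    out$codon_ref[i] <- paste(codon, collapse = "")
    out$codon_alt[i] <- paste(codon_alt, collapse = "")
    out$aa_ref[i] <- aa_ref
    out$aa_alt[i] <- aa_alt
    out$stop_change[i] <- xor(aa_ref == "*", aa_alt == "*")
    out$category[i] <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
  }
  out
}

# Per-gene map: genomic positions of CDS bases in translation order plus the
# reference CDS sequence in reading orientation.
cds_position_maps <- function(genes, reference) {
  maps <- vector("list", nrow(genes))
  names(maps) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    cds <- genes$cds[[i]]
    if (nrow(cds) == 0) {
      maps[[i]] <- list(gpos = integer(), cds_seq = character())
      next
    }
    gpos <- unlist(purrr::map2(cds$start, cds$end, function(s, e) s:(e - 1L)))
    chr_seq <- reference[[genes$chrom[i]]]
    bases <- strsplit(as.character(
      Biostrings::extractAt(chr_seq,
                            IRanges::IRanges(gpos + 1L, gpos + 1L))
    ), "")
    bases <- vapply(bases, `[`, character(1), 1)
    if (genes$strand[i] == "-") {
      gpos <- rev(gpos)
      bases <- dna_complement(rev(bases))
    }
    maps[[i]] <- list(gpos = gpos, cds_seq = bases)
  }
  maps
}

dna_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' Nonsynonymous/synonymous ratio per minor-allele-frequency bin
#'
#' Joins effect calls with per-site minor allele frequencies and tabulates
#' counts of nonsynonymous and synonymous SNPs per MAF bin (default width
#' 0.05 over (0, 0.5]) plus an overall row. Bins with no synonymous SNPs
#' report `NA` ratios rather than infinities.
#'
#' @param effects Tibble from [classify_effects()].
#' @param sites Site summary tibble (needs `chrom`, `pos`, `maf`), e.g.
#'   `site_summaries(vt)$sites`.
#' @param bin_width MAF bin width.
#' @return Tibble with `maf_bin`, `n_nonsynonymous`, `n_synonymous`, `ns_s`.
#' @export
ns_s_spectrum <- function(effects, sites, bin_width = 0.05) {
  joined <- dplyr::inner_join(effects, sites[, c("chrom", "pos", "maf")],
                              by = c("chrom", "pos"))
  joined <- joined[joined$category %in% c("synonymous", "nonsynonymous") &
                     joined$maf > 0, ]
  if (nrow(joined) == 0) {
    return(tibble::tibble(maf_bin = character(),
                          n_nonsynonymous = integer(),
                          n_synonymous = integer(), ns_s = double()))
  }
  brk <- seq(0, 0.5, by = bin_width)
  joined$maf_bin <- cut(joined$maf, breaks = brk, include.lowest = FALSE)
  per_bin <- joined |>
    dplyr::count(.data$maf_bin, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (col in c("nonsynonymous", "synonymous")) {
    if (!col %in% names(per_bin)) per_bin[[col]] <- 0L
  }
  out <- tibble::tibble(
    maf_bin = as.character(per_bin$maf_bin),
    n_nonsynonymous = per_bin$nonsynonymous,
    n_synonymous = per_bin$synonymous
  )
  out <- dplyr::bind_rows(out, tibble::tibble(
    maf_bin = "overall",
    n_nonsynonymous = sum(out$n_nonsynonymous),
    n_synonymous = sum(out$n_synonymous)
  ))
  out$ns_s <- ifelse(out$n_synonymous > 0,
                     out$n_nonsynonymous / out$n_synonymous, NA_real_)
  out
}

#' Three-way site partition of classified SNPs
#'
#' Collapses effect categories into the intergenic / intronic / coding
#' partition and reports counts and proportions.
#'
#' @param effects Tibble from [classify_effects()].
#' @return Tibble with `partition`, `n`, `proportion`.
#' @export
effect_partition <- function(effects) {
  part <- dplyr::case_when(
    effects$category == "intergenic" ~ "intergenic",
    effects$category == "intronic" ~ "intronic",
    TRUE ~ "coding"
  )
  tb <- tibble::tibble(partition = factor(part, c("intergenic", "intronic",
                                                  "coding"))) |>
    dplyr::count(.data$partition, .drop = FALSE, name = "n")
  tb$proportion <- if (sum(tb$n) > 0) tb$n / sum(tb$n) else 0
  tb$partition <- as.character(tb$partition)
  tb
}
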