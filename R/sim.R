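#' Configuration for the cohort simulator
#'
#' Assembles and validates the parameter list driving [simulate_cohort()].
#' The defaults emulate the resequencing design the scans were built for:
#' three domesticated breeds of five diploid samples each plus one wild
#' outgroup of four, mean sequencing depth 29x with base-error-driven
#' allelic-depth noise, and an optional hard selective sweep in one breed.
#' Population sizes and per-generation rates are desk-scale rescalings
#' (small N with proportionally inflated mu, r, s), the usual forward-time
#' compromise.
#'
#' @param N Diploid size of every population (default 100).
#' @param L Chromosome length in bp (default 1e6).
#' @param mu Per-bp per-generation mutation rate (default 5e-7; theta =
#'   4*N*mu = 2e-4/bp at the defaults).
#' @param rec Per-bp per-generation recombination rate (default 4e-8,
#'   calibrated so a conditioned hard sweep's hitchhiking footprint spans
#'   roughly one 100-kb scan window).
#' @param burnin_gens Ancestral burn-in generations (default `6 * N`,
#'   bringing diversity to >95% of the equilibrium expectation).
#' @param split_gens Generations from the wild/domestic split to the
#'   present (default 200).
#' @param breed_gens Generations from the breed split to the present
#'   (default 100; must be <= `split_gens`). A conditioned sweep needs
#'   enough generations to fix (~ 300 at `s = 0.1`).
#' @param n_breeds Number of domestic breeds (default 3).
#' @param breed_names,wild_name Group labels.
#' @param sample_sizes Named diploid sample counts per terminal group
#'   (default 5 per breed, 4 wild).
#' @param s Selection coefficient of the swept allele (0 = neutral;
#'   fitnesses 1, 1 + s/2, 1 + s).
#' @param sweep_breed Focal breed index for the sweep (default 1).
#' @param sweep_pos Selected-site position (default: centre of the 100-kb
#'   window containing `L / 2`).
#' @param sweep_start_gen Generations after the breed split at which the
#'   mutant is introduced (default 0).
#' @param condition_on_fixation Resimulate the focal-breed epoch until the
#'   swept allele fixes (default TRUE when `s > 0`).
#' @param max_retries Retry cap for the conditioned sweep (default 300).
#' @param depth_mean Mean sequencing depth lambda (default 29).
#' @param error_rate Per-read base error rate epsilon (default 1e-3).
#' @param mask_dropout Expected fraction of the chromosome punched out of
#'   the callable mask (default 0.1).
#' @param mask_hole_mean Mean length of a low-depth hole in bp (default
#'   2000).
#' @param n_genes,n_qtl Planted gene and QTL counts (defaults 50 and 8).
#' @param n_indels Synthetic short-indel records added to the emitted
#'   call set so the indel filters have work to do (default 200).
#' @param chrom Chromosome name (default "chr1").
#' @param seed Master seed; fixes every output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(N = 100L, L = 1e6, mu = 5e-7, rec = 4e-8,
                       burnin_gens = 6L * N, split_gens = 200L,
                       breed_gens = 100L, n_breeds = 3L,
                       breed_names = c("dairy", "cashmere", "meat"),
                       wild_name = "wild",
                       sample_sizes = NULL,
                       s = 0, sweep_breed = 1L, sweep_pos = NULL,
                       sweep_start_gen = 0L,
                       condition_on_fixation = s > 0, max_retries = 300L,
                       depth_mean = 29, error_rate = 1e-3,
                       mask_dropout = 0.1, mask_hole_mean = 2000,
                       n_genes = 50L, n_qtl = 8L, n_indels = 200L,
                       chrom = "chr1", seed = 1L) {
  breed_names <- breed_names[seq_len(n_breeds)]
  if (anyNA(breed_names)) {
    breed_names <- paste0("breed", seq_len(n_breeds))
  }
  if (is.null(sample_sizes)) {
    sample_sizes <- stats::setNames(c(rep(5L, n_breeds), 4L),
                                    c(breed_names, wild_name))
  }
  # default selected site: centre of the 100-kb window containing L/2, so
  # the sweep footprint is not split across a window boundary by default
  if (is.null(sweep_pos)) {
    sweep_pos <- min((floor(L / 2) %/% 1e5) * 1e5 + 5e4, L - 1)
  }
  cfg <- list(N = as.integer(N), L = as.integer(L), mu = mu, rec = rec,
              burnin_gens = as.integer(burnin_gens),
              split_gens = as.integer(split_gens),
              breed_gens = as.integer(breed_gens),
              n_breeds = as.integer(n_breeds),
              breed_names = breed_names, wild_name = wild_name,
              sample_sizes = sample_sizes,
              s = s, sweep_breed = as.integer(sweep_breed),
              sweep_pos = as.integer(sweep_pos),
              sweep_start_gen = as.integer(sweep_start_gen),
              condition_on_fixation = condition_on_fixation,
              max_retries = as.integer(max_retries),
              depth_mean = depth_mean, error_rate = error_rate,
              mask_dropout = mask_dropout, mask_hole_mean = mask_hole_mean,
              n_genes = as.integer(n_genes), n_qtl = as.integer(n_qtl),
              n_indels = as.integer(n_indels),
              chrom = chrom, seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(N >= 2, L >= 1000, mu >= 0, rec >= 0,
              burnin_gens >= 0, split_gens >= 0, breed_gens >= 0,
              breed_gens <= split_gens, n_breeds >= 1,
              depth_mean >= 0, error_rate >= 0, error_rate < 0.25,
              mask_dropout >= 0, mask_dropout < 1,
              all(sample_sizes <= N),
              sweep_breed >= 1, sweep_breed <= n_breeds,
              sweep_pos >= 0, sweep_pos < L,
              sweep_start_gen >= 0, sweep_start_gen <= breed_gens)
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-population cohort with known ground truth
#'
#' Forward-time Wright--Fisher simulation of an ancestral population that
#' splits into a wild outgroup and a domestic lineage, the latter splitting
#' into breeds; an optional hard sweep (additive selection, optionally
#' conditioned on fixation with epoch resimulation) runs in one focal breed.
#' Mutation is infinite-sites on integer positions; recombination is
#' Poisson crossovers per gamete. Sampled diploids receive Poisson
#' sequencing depths and error-contaminated allelic depths. All outputs
#' are byte-deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, all pipeline input files are
#'   written there (`cohort.vcf`, `callable.bed`, `genes.gff3`, `qtl.bed`,
#'   `groups.tsv`, `reference.fa`, `truth.json`).
#' @return A `cohort_sim` list: `variants` ([variant_table()]), `truth`
#'   (haplotypes, selected-site state, per-population allele frequencies,
#'   sweep window), `genes`, `qtl`, `mask`, `groups`, `reference`,
#'   `chrom_lengths`, `config`, and `paths` when files were written.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  cfg <- validate_sim_config(unclass(config))
  set.seed(cfg$seed)
  seeds <- sample.int(2147483646L, 512L)
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    if (seed_i > length(seeds)) stop("internal: seed pool exhausted")
    seeds[seed_i]
  }

  planted <- plant_genes(cfg)
  pops <- run_demography(cfg, next_seed)
  samples <- draw_samples(cfg, pops)
  site <- site_matrix_from_haps(samples$haps, cfg)
  truth_freqs <- population_frequencies(site$positions, pops, cfg)

  ref_chars <- planted$ref_chars
  ref_base <- ref_chars[site$positions + 1L]
  alt_base <- random_alt_bases(ref_base)

  depths <- emulate_depths(site$a1, site$a2, lambda = cfg$depth_mean,
                           error_rate = cfg$error_rate)
  vt <- build_variant_table(site, ref_base, alt_base, depths,
                            samples$sample_names, cfg)
  vt <- add_synthetic_indels(vt, cfg, ref_chars, samples$sample_names)

  mask <- simulate_callable_mask(cfg)
  groups <- tibble::tibble(
    sample = samples$sample_names,
    group = rep(names(cfg$sample_sizes), cfg$sample_sizes)
  )
  sel_pos <- if (cfg$s > 0) pops$sel_pos else NA_integer_
  sweep_window <- tibble::tibble(
    chrom = cfg$chrom,
    start = as.integer((max(sel_pos, 0L, na.rm = TRUE) %/% 1e5) * 1e5),
    end = as.integer(min((max(sel_pos, 0L, na.rm = TRUE) %/% 1e5 + 1) * 1e5,
                         cfg$L))
  )
  truth <- list(
    positions = site$positions,
    haplotypes = site$hap_matrix,
    sel_pos = sel_pos,
    sel_final_freq = pops$sel_final_freq,
    sweep_breed = if (cfg$s > 0) cfg$breed_names[cfg$sweep_breed]
                  else NA_character_,
    sweep_window = if (cfg$s > 0) sweep_window else NULL,
    pop_freqs = truth_freqs,
    genes_in_sweep = if (cfg$s > 0) {
      planted$genes$gene_id[planted$genes$start < sweep_window$end &
                              planted$genes$end > sweep_window$start]
    } else character()
  )
  reference <- Biostrings::DNAStringSet(
    stats::setNames(paste(ref_chars, collapse = ""), cfg$chrom))

  out <- structure(list(
    variants = vt, truth = truth, genes = planted$genes, qtl = planted$qtl,
    mask = mask, groups = groups, reference = reference,
    chrom_lengths = stats::setNames(cfg$L, cfg$chrom),
    config = cfg, paths = NULL
  ), class = "cohort_sim")
  if (!is.null(dir)) out <- write_cohort(out, dir)
  out
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<cohort_sim> %d samples in %d groups | %d variant sites on %s (%g bp)\n",
    length(vt_samples(x$variants)), dplyr::n_distinct(x$groups$group),
    nrow(x$variants), x$config$chrom, x$config$L))
  if (x$config$s > 0) {
    cat(sprintf("  sweep: s = %g at %d in '%s' (final freq %.2f)\n",
                x$config$s, x$truth$sel_pos, x$truth$sweep_breed,
                x$truth$sel_final_freq))
  }
  invisible(x)
}

#' One-row summary of a simulated cohort
#' @param x A `cohort_sim`.
#' @param ... Unused.
#' @return One-row tibble of cohort-level counts.
#' @export
glance.cohort_sim <- function(x, ...) {
  tibble::tibble(
    n_samples = length(vt_samples(x$variants)),
    n_sites = nrow(x$variants),
    n_snps = sum(x$variants$kind == "SNP"),
    n_indels = sum(x$variants$kind != "SNP"),
    n_genes = nrow(x$genes),
    L = x$config$L,
    s = x$config$s,
    sel_final_freq = x$truth$sel_final_freq
  )
}

# --- demography ------------------------------------------------------------

run_demography <- function(cfg, next_seed) {
  empty <- rep(list(integer()), 2L * cfg$N)
  used <- integer()

  anc <- wf_evolve_cpp(empty, cfg$N, cfg$L, cfg$mu, cfg$rec,
                       cfg$burnin_gens, 0, -1L, used, next_seed(),
                       purge = TRUE)
  used <- anc$used_positions

  wild <- wf_evolve_cpp(anc$haps, cfg$N, cfg$L, cfg$mu, cfg$rec,
                        cfg$split_gens, 0, -1L, used, next_seed())
  used <- wild$used_positions

  dom_gens <- cfg$split_gens - cfg$breed_gens
  dom <- wf_evolve_cpp(anc$haps, cfg$N, cfg$L, cfg$mu, cfg$rec,
                       dom_gens, 0, -1L, used, next_seed())
  used <- dom$used_positions

  breeds <- vector("list", cfg$n_breeds)
  sel_final_freq <- NA_real_
  focal <- if (cfg$s > 0) cfg$sweep_breed else 0L
  for (b in seq_len(cfg$n_breeds)) {
    if (b == focal) next  # focal breed last (retry loop below)
    res <- wf_evolve_cpp(dom$haps, cfg$N, cfg$L, cfg$mu, cfg$rec,
                         cfg$breed_gens, 0, -1L, used, next_seed())
    used <- res$used_positions
    breeds[[b]] <- res$haps
  }
  if (focal > 0L) {
    sweep_pos <- cfg$sweep_pos
    while (sweep_pos %in% used) sweep_pos <- sweep_pos + 1L
    pre_gens <- cfg$sweep_start_gen
    post_gens <- cfg$breed_gens - pre_gens
    start_haps <- dom$haps
    if (pre_gens > 0) {
      pre <- wf_evolve_cpp(start_haps, cfg$N, cfg$L, cfg$mu, cfg$rec,
                           pre_gens, 0, -1L, used, next_seed())
      used <- pre$used_positions
      start_haps <- pre$haps
    }
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      if (attempt > cfg$max_retries) {
        stop("selected allele lost in all ", cfg$max_retries,
             " sweep attempts; increase breed_gens or s", call. = FALSE)
      }
      carrier <- sample.int(length(start_haps), 1L)
      haps_try <- start_haps
      haps_try[[carrier]] <- sort(c(haps_try[[carrier]], sweep_pos))
      res <- wf_evolve_cpp(haps_try, cfg$N, cfg$L, cfg$mu, cfg$rec,
                           post_gens, cfg$s, sweep_pos,
                           c(used, sweep_pos), next_seed(),
                           stop_on_loss = TRUE)
      fixed <- res$sel_count == 2L * cfg$N
      if (!cfg$condition_on_fixation || fixed) {
        used <- res$used_positions
        breeds[[focal]] <- res$haps
        sel_final_freq <- res$sel_count / (2 * cfg$N)
        break
      }
      # failed attempt: discard its mutations (none survive in any lineage)
    }
  }
  list(wild = wild$haps, breeds = breeds, used = used,
       sel_final_freq = sel_final_freq,
       sel_pos = if (focal > 0L) sweep_pos else NA_integer_)
}

draw_samples <- function(cfg, pops) {
  pools <- c(pops$breeds, list(pops$wild))
  names(pools) <- c(cfg$breed_names, cfg$wild_name)
  haps <- list()
  sample_names <- character()
  for (grp in names(cfg$sample_sizes)) {
    n <- cfg$sample_sizes[[grp]]
    ind <- sample.int(cfg$N, n)  # diploid indices, without replacement
    for (j in seq_len(n)) {
      haps <- c(haps, pools[[grp]][2L * ind[j] - 1L], pools[[grp]][2L * ind[j]])
    }
    sample_names <- c(sample_names, sprintf("%s_%d", grp, seq_len(n)))
  }
  list(haps = haps, sample_names = sample_names)
}

# Binary hap x site matrix over positions segregating among sampled haps.
site_matrix_from_haps <- function(haps, cfg) {
  all_pos <- sort(unique(unlist(haps)))
  n_hap <- length(haps)
  m <- matrix(0L, n_hap, length(all_pos))
  for (i in seq_len(n_hap)) {
    m[i, match(haps[[i]], all_pos)] <- 1L
  }
  seg <- colSums(m) > 0L & colSums(m) < n_hap
  m <- m[, seg, drop = FALSE]
  positions <- all_pos[seg]
  # odd rows = haplotype 1, even rows = haplotype 2 of each diploid
  a1 <- t(m[seq(1L, n_hap, by = 2L), , drop = FALSE])
  a2 <- t(m[seq(2L, n_hap, by = 2L), , drop = FALSE])
  list(positions = positions, hap_matrix = m, a1 = a1, a2 = a2)
}

population_frequencies <- function(positions, pops, cfg) {
  pools <- c(pops$breeds, list(pops$wild))
  names(pools) <- c(cfg$breed_names, cfg$wild_name)
  out <- tibble::tibble(pos = positions)
  for (grp in names(pools)) {
    cnt <- tabulate(match(unlist(pools[[grp]]), positions),
                    nbins = length(positions))
    out[[grp]] <- cnt / length(pools[[grp]])
  }
  out
}

random_alt_bases <- function(ref_base) {
  bases <- c("A", "C", "G", "T")
  vapply(ref_base, function(b) sample(setdiff(bases, b), 1L), character(1),
         USE.NAMES = FALSE)
}

#' Emulate per-site, per-sample allelic read depths
#'
#' Total depth per sample per site is Poisson(`lambda`); reads are assigned
#' to the sample's two haplotype alleles binomially (p = 0.5); each read is
#' miscalled to a uniformly random other base with probability
#' `error_rate`, so a read crosses to the other *listed* allele with
#' probability `error_rate / 3` and is dropped (unlisted base) otherwise.
#'
#' @param a1,a2 Integer matrices (sites x samples) of the two haplotype
#'   alleles (0 = ref, 1 = alt).
#' @param lambda Mean depth (>= 0).
#' @param error_rate Per-read error probability (0 <= e < 0.25).
#' @return List of matrices `ref` and `alt` (sites x samples) of read
#'   counts supporting each allele, and `depth` (total reads drawn).
#' @export
emulate_depths <- function(a1, a2, lambda = 29, error_rate = 1e-3) {
  stopifnot(lambda >= 0, error_rate >= 0, error_rate < 0.25)
  n <- length(a1)
  dims <- dim(a1)
  depth <- matrix(stats::rpois(n, lambda), dims[1], dims[2])
  from_h1 <- matrix(stats::rbinom(n, depth, 0.5), dims[1], dims[2])
  from_h2 <- depth - from_h1
  reads_ref_true <- from_h1 * (a1 == 0L) + from_h2 * (a2 == 0L)
  reads_alt_true <- from_h1 * (a1 == 1L) + from_h2 * (a2 == 1L)
  keep_ref <- matrix(stats::rbinom(n, reads_ref_true, 1 - error_rate),
                     dims[1], dims[2])
  keep_alt <- matrix(stats::rbinom(n, reads_alt_true, 1 - error_rate),
                     dims[1], dims[2])
  cross_ref <- matrix(stats::rbinom(n, reads_alt_true, error_rate / 3),
                      dims[1], dims[2])
  cross_alt <- matrix(stats::rbinom(n, reads_ref_true, error_rate / 3),
                      dims[1], dims[2])
  list(ref = keep_ref + cross_ref, alt = keep_alt + cross_alt,
       depth = depth)
}

build_variant_table <- function(site, ref_base, alt_base, depths,
                                sample_names, cfg) {
  n_site <- length(site$positions)
  n_smp <- length(sample_names)
  gt <- vector("list", n_site)
  ad <- vector("list", n_site)
  ph <- rep(list(stats::setNames(rep(TRUE, n_smp), sample_names)), n_site)
  for (i in seq_len(n_site)) {
    g <- rbind(site$a1[i, ], site$a2[i, ])
    colnames(g) <- sample_names
    gt[[i]] <- g
    d <- rbind(depths$ref[i, ], depths$alt[i, ])
    colnames(d) <- sample_names
    ad[[i]] <- d
  }
  variant_table(
    chrom = rep(cfg$chrom, n_site), pos = site$positions,
    ref = ref_base, alt = as.list(alt_base),
    kind = rep("SNP", n_site), qual = 100,
    gt = gt, phased = ph, ad = ad, samples = sample_names
  )
}

# Synthetic 1-8 bp indel records with quality/homopolymer metadata so the
# indel filters are exercised end-to-end; placed at unused positions.
add_synthetic_indels <- function(vt, cfg, ref_chars, sample_names) {
  if (cfg$n_indels == 0) return(vt)
  n <- cfg$n_indels
  taken <- vt$pos
  pos <- sample.int(cfg$L - 10L, 2L * n) - 1L
  pos <- setdiff(pos, taken)[seq_len(min(n, length(setdiff(pos, taken))))]
  n <- length(pos)
  len <- sample(1:8, n, replace = TRUE,
                prob = c(.35, .2, .15, .1, .08, .05, .04, .03))
  is_ins <- stats::runif(n) < 0.5
  qual <- stats::runif(n, 5, 60)
  hom <- pmin(1L + stats::rgeom(n, 0.25), 20L)
  n_smp <- length(sample_names)
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    anchor <- ref_chars[pos[i] + 1L]
    if (is_ins[i]) {
      ref <- anchor
      alt <- paste0(anchor, paste(sample(bases, len[i], replace = TRUE),
                                  collapse = ""))
    } else {
      ref <- paste0(anchor, paste(ref_chars[(pos[i] + 2L):(pos[i] + 1L + len[i])],
                                  collapse = ""))
      alt <- anchor
    }
    p <- stats::runif(1, 0.05, 0.95)
    g <- matrix(as.integer(stats::rbinom(2L * n_smp, 1L, p)), nrow = 2)
    colnames(g) <- sample_names
    rows[[i]] <- list(pos = pos[i], ref = ref, alt = alt,
                      kind = if (is_ins[i]) "insertion" else "deletion",
                      qual = qual[i], hom = hom[i], gt = g)
  }
  ph <- rep(list(stats::setNames(rep(TRUE, n_smp), sample_names)), n)
  ind_vt <- variant_table(
    chrom = rep(cfg$chrom, n),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = purrr::map(rows, function(r) r$alt),
    kind = vapply(rows, `[[`, character(1), "kind"),
    qual = vapply(rows, `[[`, double(1), "qual"),
    hom_len = vapply(rows, `[[`, integer(1), "hom"),
    gt = purrr::map(rows, "gt"), phased = ph,
    samples = sample_names
  )
  merged <- dplyr::bind_rows(vt, ind_vt)
  merged <- dplyr::arrange(merged, chrom, pos)
  new_variant_table(merged, sample_names)
}

simulate_callable_mask <- function(cfg) {
  n_holes <- stats::rpois(1, cfg$mask_dropout * cfg$L / cfg$mask_hole_mean)
  if (n_holes == 0) {
    return(tibble::tibble(chrom = cfg$chrom, start = 0L, end = cfg$L))
  }
  hs <- sort(sample.int(cfg$L, n_holes)) - 1L
  hl <- pmax(50L, as.integer(stats::rexp(n_holes, 1 / cfg$mask_hole_mean)))
  holes <- tibble::tibble(chrom = cfg$chrom, start = hs,
                          end = pmin(hs + hl, cfg$L))
  holes <- merge_intervals(holes)
  # complement within [0, L)
  starts <- c(0L, holes$end)
  ends <- c(holes$start, cfg$L)
  keep <- starts < ends
  tibble::tibble(chrom = cfg$chrom, start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]))
}

# --- file emission ---------------------------------------------------------

write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    mask = file.path(dir, "callable.bed"),
    gff3 = file.path(dir, "genes.gff3"),
    qtl = file.path(dir, "qtl.bed"),
    groups = file.path(dir, "groups.tsv"),
    reference = file.path(dir, "reference.fa"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(sim$variants, paths$vcf, contigs = sim$chrom_lengths)
  write_bed(sim$mask, paths$mask)
  write_gff3(sim$genes, paths$gff3)
  qtl_out <- sim$qtl
  readr::write_tsv(qtl_out, paths$qtl, col_names = FALSE, progress = FALSE)
  readr::write_tsv(sim$groups, paths$groups, progress = FALSE)
  Biostrings::writeXStringSet(sim$reference, paths$reference)
  truth_json <- sim$truth
  truth_json$haplotypes <- NULL  # matrices stay in the R object
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  sim$paths <- paths
  sim
}

#' Write gene models as GFF3
#' @param genes Gene-model tibble (with `cds` list-column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$gene_id
    lines <- c(lines, sprintf(
      "%s\tcaprisweep\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chrom, g$start + 1L, g$end, g$strand, gid))
    tid <- paste0(gid, ".t1")
    lines <- c(lines, sprintf(
      "%s\tcaprisweep\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
      g$chrom, g$start + 1L, g$end, g$strand, tid, gid))
    cds <- g$cds[[1]]
    # phase in translation order
    ord <- if (g$strand == "-") rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
    phase <- integer(nrow(cds))
    acc <- 0L
    for (k in ord) {
      phase[k] <- (3L - (acc %% 3L)) %% 3L
      acc <- acc + (cds$end[k] - cds$start[k])
    }
    for (k in seq_len(nrow(cds))) {
      lines <- c(lines, sprintf(
        "%s\tcaprisweep\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
        g$chrom, cds$start[k] + 1L, cds$end[k], g$strand, phase[k], tid, tid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# --- gene/QTL planting -----------------------------------------------------

#' Plant gene models and QTL intervals into a simulated chromosome
#'
#' Places non-overlapping multi-exon genes (stop-free CDS on either strand,
#' lengths divisible by three, terminal stop codon) and random QTL
#' intervals. When the configuration requests a sweep, the first gene is
#' centred on the selected site so the sweep region always contains a gene.
#' Also builds the reference sequence: random bases outside CDS, the
#' planted codons inside.
#'
#' @param cfg A [sim_config()]. Uses the current RNG state (call within a
#'   seeded context, as [simulate_cohort()] does).
#' @return List with `genes` (tibble), `qtl` (tibble) and `ref_chars`
#'   (character vector of bases, length `L`).
#' @export
plant_genes <- function(cfg) {
  bases <- c("A", "C", "G", "T")
  ref_chars <- sample(bases, cfg$L, replace = TRUE)
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  sense_codons <- setdiff(codons, stops)

  occupied <- tibble::tibble(start = integer(), end = integer())
  genes <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    placed <- FALSE
    for (try in seq_len(300L)) {
      n_cod <- sample(80:300, 1L)
      n_ex <- sample(1:3, 1L)
      cuts <- sort(sample(seq_len(n_cod - 1L), n_ex - 1L))
      ex_cod <- diff(c(0L, cuts, n_cod))
      ex_len <- ex_cod * 3L
      introns <- if (n_ex > 1) sample(200:2000, n_ex - 1L, replace = TRUE)
                 else integer()
      span <- sum(ex_len) + sum(introns)
      if (span >= cfg$L - 2L) next
      start <- if (i == 1L && cfg$s > 0) {
        max(0L, min(cfg$L - span - 1L,
                    as.integer(cfg$sweep_pos - span %/% 2L)))
      } else {
        sample.int(cfg$L - span, 1L) - 1L
      }
      end <- start + span
      clash <- any(occupied$start < end & occupied$end > start)
      if (clash) next
      strand <- sample(c("+", "-"), 1L)
      cds_starts <- start + cumsum(c(0L, utils::head(ex_len, -1) + introns))
      cds <- tibble::tibble(start = as.integer(cds_starts),
                            end = as.integer(cds_starts + ex_len))
      # stop-free codons, terminal stop
      cod_seq <- c(sample(sense_codons, n_cod - 1L, replace = TRUE), "TAA")
      cds_bases <- strsplit(paste(cod_seq, collapse = ""), "")[[1]]
      gpos <- unlist(purrr::map2(cds$start, cds$end, function(s, e) s:(e - 1L)))
      if (strand == "-") {
        ref_chars[gpos + 1L] <- rev(dna_complement(cds_bases))
      } else {
        ref_chars[gpos + 1L] <- cds_bases
      }
      occupied <- dplyr::bind_rows(occupied,
                                   tibble::tibble(start = start, end = end))
      genes[[i]] <- tibble::tibble(
        gene_id = sprintf("gene%03d", i), chrom = cfg$chrom,
        start = as.integer(start), end = as.integer(end),
        strand = strand, cds = list(cds))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("chromosome too small to place ", cfg$n_genes, " genes",
           call. = FALSE)
    }
  }
  genes <- dplyr::arrange(dplyr::bind_rows(genes), start)

  qtl_len <- sample(50000:200000, cfg$n_qtl, replace = TRUE)
  qtl_len <- pmin(qtl_len, cfg$L - 1L)
  qtl_start <- vapply(qtl_len, function(l) sample.int(cfg$L - l, 1L) - 1L,
                      integer(1))
  qtl <- tibble::tibble(chrom = cfg$chrom,
                        start = as.integer(qtl_start),
                        end = as.integer(qtl_start + qtl_len),
                        name = sprintf("QTL%03d", seq_len(cfg$n_qtl)))
  qtl <- dplyr::arrange(qtl, start)

  list(genes = genes, qtl = qtl, ref_chars = ref_chars)
}
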