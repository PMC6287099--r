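# Shared fixtures, built in code at test time.

# Hand-built variant table: `spec` is a list of lists with fields
# pos, ref, alt (chr vector), gt (2 x n matrix), ad (optional matrix),
# kind, qual, hom_len, phased (default TRUE).
make_vt <- function(spec, samples, chrom = "chr1") {
  n <- length(spec)
  gt <- lapply(spec, function(s) {
    g <- if (is.null(s$gt)) matrix(0L, 2, length(samples)) else s$gt
    colnames(g) <- samples
    storage.mode(g) <- "integer"
    g
  })
  ad <- lapply(spec, function(s) {
    if (is.null(s$ad)) return(NULL)
    a <- s$ad
    colnames(a) <- samples
    a
  })
  ph <- lapply(spec, function(s) {
    p <- if (is.null(s$phased)) TRUE else s$phased
    stats::setNames(rep_len(p, length(samples)), samples)
  })
  variant_table(
    chrom = rep(chrom, n),
    pos = vapply(spec, function(s) s$pos, numeric(1)),
    ref = vapply(spec, function(s) if (is.null(s$ref)) "A" else s$ref,
                 character(1)),
    alt = lapply(spec, function(s) if (is.null(s$alt)) "G" else s$alt),
    kind = vapply(spec, function(s) if (is.null(s$kind)) "SNP" else s$kind,
                  character(1)),
    qual = vapply(spec, function(s) if (is.null(s$qual)) 50 else s$qual,
                  numeric(1)),
    hom_len = vapply(spec, function(s) {
      if (is.null(s$hom_len)) NA_integer_ else as.integer(s$hom_len)
    }, integer(1)),
    gt = gt, phased = ph, ad = ad, samples = samples
  )
}

gt2 <- function(a1, a2) matrix(as.integer(c(a1, a2)), nrow = 2, byrow = TRUE)

# One small simulated cohort shared across test files (memoised).
tiny_cohort_env <- new.env()
tiny_cohort <- function() {
  if (is.null(tiny_cohort_env$sim)) {
    tiny_cohort_env$sim <- simulate_cohort(sim_config(
      N = 40L, L = 200000L, burnin_gens = 240L, split_gens = 60L,
      breed_gens = 30L, n_genes = 8L, n_qtl = 3L, n_indels = 40L,
      seed = 424242L))
  }
  tiny_cohort_env$sim
}

# Gene-dense cohort for effect-annotation oracles (memoised).
effects_cohort <- function() {
  if (is.null(tiny_cohort_env$eff_sim)) {
    tiny_cohort_env$eff_sim <- simulate_cohort(sim_config(
      N = 30L, L = 200000L, mu = 2e-6, burnin_gens = 200L,
      split_gens = 40L, breed_gens = 20L, n_genes = 25L, n_qtl = 2L,
      n_indels = 0L, seed = 777L))
  }
  tiny_cohort_env$eff_sim
}

# Random panel of phased haplotypes (for EHH property tests).
random_panel <- function(n_hap, n_site, L = 1e5, pop = "p") {
  pos <- sort(sample.int(L, n_site))
  h <- matrix(rbinom(n_hap * n_site, 1, runif(n_site, 0.1, 0.9)[
    rep(seq_len(n_site), each = n_hap)]), n_hap, n_site)
  # ensure >= 4 haplotypes and no invariant requirements violated
  haplotype_panel(h, pos, pop)
}
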