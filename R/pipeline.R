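#' Pipeline run configuration
#'
#' Builds the full configuration of an end-to-end run. Defaults are the
#' protocol constants of this scan family: 10-kb SNP-rate windows normalized by
#' callable length (windows under 1 kb callable rejected), lowest-10%
#' desert rule with 10-kb gap joining, SAG overlap > 30%, 100-kb sweep
#' windows, ZHp <= -3 OR ZFst >= 3 for the domestication scan,
#' ZFst >= 4 AND top-1% XP-EHH for the breed scans, SNP depth >= 8 with
#' het calls needing 4 reads per allele, and indel quality/homopolymer/
#' length cutoffs 20/10/5. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults below.
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    simulate = TRUE,
    sim = list(),                 # overrides for sim_config()
    inputs = list(),              # vcf/mask/gff3/qtl/groups/reference paths
    wild_group = "wild",
    snp_min_depth = 8,
    het_min_reads = 4,
    snp_depth_mode = "any_below",
    indel_max_len = 5,
    indel_min_quality = 20,
    indel_max_homopolymer = 10,
    maf_bin_width = 0.05,
    desert_window = 10000L,
    desert_step = 10000L,
    desert_min_callable = 1000L,
    desert_quantile = 0.10,
    desert_join_gap = 10000L,
    sag_min_overlap = 0.30,
    large_desert_min_length = 100000L,
    top_deserts_k = 10L,
    sweep_window = 100000L,
    sweep_step = 100000L,
    zhp_cut = -3,
    zfst_cut_dag = 3,
    zfst_cut_tag = 4,
    xpehh_top_frac = 0.01,
    fst_estimator = "hudson",
    ehh_min = 0.05,
    ehh_max_extension_bp = 1e6,
    xpehh_max_cores = 2000L,
    xpehh_aggregate = "max",
    make_plots = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$desert_window > 0, cfg$sweep_window > 0,
            cfg$desert_quantile > 0, cfg$desert_quantile < 1,
            cfg$xpehh_top_frac > 0, cfg$xpehh_top_frac <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> QC -> effect annotation -> per-breed
#' desert scan -> domestication sweep scan -> per-breed Fst/XP-EHH scan ->
#' gene classification -> QTL cross-reference -> report, writing every
#' table to `run_dir` together with a manifest (config hash, seed, file
#' checksums). Reruns with the same config produce identical tables.
#'
#' @param config A [run_config()].
#' @param run_dir Output directory (created).
#' @return A `pipeline_run` list with the in-memory results and `run_dir`;
#'   also writes `summary.json` and `manifest.json`.
#' @export
run_pipeline <- function(config = run_config(), run_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(run_dir, "pipeline.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    message(msg)
    cat(msg, "\n", file = log_file, append = TRUE)
  }
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    log_line("stage ", name, " ...")
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }

  set.seed(config$seed)

  # -- inputs ---------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    sim <- stage("simulate", {
      scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
      simulate_cohort(scfg, dir = file.path(run_dir, "inputs"))
    })
    vt <- sim$variants
    mask <- sim$mask
    genes <- sim$genes
    qtl <- sim$qtl
    groups <- sim$groups
    chrom_lengths <- sim$chrom_lengths
    truth <- sim$truth
  } else {
    sim <- NULL
    truth <- NULL
    inp <- config$inputs
    need <- c("vcf", "mask", "gff3", "qtl", "groups")
    miss <- setdiff(need, names(inp))
    if (length(miss)) {
      stop("inputs missing (simulate = FALSE): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    vt <- stage("read_inputs", read_vcf(inp$vcf))
    mask <- read_bed(inp$mask)
    genes <- read_gff3(inp$gff3)
    qtl <- read_bed(inp$qtl, merge = FALSE)
    groups <- read_group_table(inp$groups, vt_samples(vt))
    chrom_lengths <- tapply(mask$end, mask$chrom, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                     names(chrom_lengths))
  }
  breeds <- setdiff(unique(groups$group), config$wild_group)

  # -- qc -------------------------------------------------------------------
  vt_f <- stage("qc", {
    v1 <- filter_snps_by_depth(vt, config$snp_min_depth,
                               config$het_min_reads,
                               mode = config$snp_depth_mode)
    rep1 <- qc_report(v1)
    v2 <- suppressWarnings(
      filter_indels(v1, config$indel_max_len, config$indel_min_quality,
                    config$indel_max_homopolymer))
    rep2 <- qc_report(v2)
    readr::write_tsv(dplyr::bind_rows(rep1, rep2),
                     file.path(run_dir, "filter_report.tsv"),
                     progress = FALSE)
    v2
  })
  summaries <- site_summaries(vt_f, groups)

  # -- effect annotation ----------------------------------------------------
  effects <- NULL
  ns_s <- NULL
  partition <- NULL
  if (!is.null(sim) || !is.null(config$inputs$reference)) {
    reference <- if (!is.null(sim)) sim$reference else
      read_fasta(config$inputs$reference)
    effects <- stage("annotate", classify_effects(vt_f, genes, reference))
    partition <- effect_partition(effects)
    ns_s <- ns_s_spectrum(effects, summaries$sites, config$maf_bin_width)
    readr::write_tsv(effects, file.path(run_dir, "effects.tsv"),
                     progress = FALSE)
    readr::write_tsv(partition, file.path(run_dir, "site_partition.tsv"),
                     progress = FALSE)
    readr::write_tsv(ns_s, file.path(run_dir, "ns_s_spectrum.tsv"),
                     progress = FALSE)
  }

  # -- per-breed desert scan ------------------------------------------------
  deserts <- list()
  sags <- list()
  desert_windows <- list()
  stage("desert", {
    for (b in breeds) {
      bsamp <- group_samples(groups, b)
      bvt <- subset_polymorphic(vt_f[vt_f$kind == "SNP", ], bsamp)
      w <- snp_rate_windows(bvt, mask, window = config$desert_window,
                            step = config$desert_step,
                            chrom_lengths = chrom_lengths,
                            min_callable = config$desert_min_callable)
      d <- call_deserts(w, quantile = config$desert_quantile,
                        join_gap = config$desert_join_gap)
      s <- classify_sags(d, genes, config$sag_min_overlap)
      desert_windows[[b]] <- w
      deserts[[b]] <- d
      sags[[b]] <- s
      readr::write_tsv(w, file.path(run_dir, sprintf("windows_%s.tsv", b)),
                       progress = FALSE)
      write_bed(d, file.path(run_dir, sprintf("deserts_%s.bed", b)))
      readr::write_tsv(s, file.path(run_dir, sprintf("sags_%s.tsv", b)),
                       progress = FALSE)
    }
    NULL
  })

  # -- domestication scan ---------------------------------------------------
  dom_stats <- stage("sweep", {
    st <- scan_domestication(vt_f, groups, config$wild_group,
                             chrom_lengths, window = config$sweep_window,
                             step = config$sweep_step,
                             estimator = config$fst_estimator)
    readr::write_tsv(st, file.path(run_dir, "domestication_windows.tsv"),
                     progress = FALSE)
    st
  })
  dags <- classify_dags(dom_stats, genes, config$zhp_cut,
                        config$zfst_cut_dag)
  readr::write_tsv(tidy(dags), file.path(run_dir, "dags.tsv"),
                   progress = FALSE)

  # -- per-breed Fst + XP-EHH and TAGs -------------------------------------
  breed_stats <- list()
  tags <- list()
  stage("ehh", {
    for (b in breeds) {
      st <- scan_breed(vt_f, groups, focal = b,
                       wild_group = config$wild_group,
                       chrom_lengths = chrom_lengths,
                       window = config$sweep_window,
                       step = config$sweep_step,
                       estimator = config$fst_estimator,
                       max_cores = config$xpehh_max_cores,
                       min_ehh = config$ehh_min,
                       max_extension_bp = config$ehh_max_extension_bp,
                       aggregate = config$xpehh_aggregate)
      breed_stats[[b]] <- st
      tg <- if (all(is.na(st$xpehh))) NULL else
        classify_tags(st, genes, config$zfst_cut_tag,
                      config$xpehh_top_frac)
      tags[[b]] <- tg
      readr::write_tsv(st, file.path(run_dir,
                                     sprintf("breed_windows_%s.tsv", b)),
                       progress = FALSE)
      if (!is.null(tg)) {
        readr::write_tsv(tidy(tg),
                         file.path(run_dir, sprintf("tags_%s.tsv", b)),
                         progress = FALSE)
      }
    }
    NULL
  })

  # -- QTL cross-reference --------------------------------------------------
  qtl_hits <- stage("classify", {
    all_sag <- dplyr::bind_rows(sags[breeds][!vapply(sags[breeds], is.null,
                                                     logical(1))])
    sag_genes <- unique(all_sag$gene_id[all_sag$sag])
    hits <- crossref_qtl(genes, qtl)
    hits$sag <- hits$gene_id %in% sag_genes
    hits$dag <- hits$gene_id %in% tidy(dags)$gene_id
    tag_genes <- unique(unlist(purrr::map(tags, function(t) {
      if (is.null(t)) character() else tidy(t)$gene_id
    })))
    hits$tag <- hits$gene_id %in% tag_genes
    readr::write_tsv(hits, file.path(run_dir, "qtl_crossref.tsv"),
                     progress = FALSE)
    hits
  })

  # -- plots ----------------------------------------------------------------
  if (isTRUE(config$make_plots)) {
    stage("plots", {
      grDevices::pdf(file.path(run_dir, "sweep_tracks.pdf"), 9, 6)
      print(plot_sweep_tracks(dom_stats, config$zhp_cut,
                              config$zfst_cut_dag))
      print(plot_snp_rate(desert_windows, config$desert_quantile))
      grDevices::dev.off()
    })
  }

  # -- report ---------------------------------------------------------------
  recovery <- sweep_recovery(truth, tags, config)
  summary <- list(
    n_sites_input = nrow(vt),
    n_sites_kept = nrow(vt_f),
    n_snps_kept = sum(vt_f$kind == "SNP"),
    n_indels_kept = sum(vt_f$kind != "SNP"),
    site_partition = partition,
    ns_s_overall = if (!is.null(ns_s)) ns_s$ns_s[ns_s$maf_bin == "overall"]
                   else NULL,
    deserts = purrr::imap(deserts, function(d, b) {
      list(n = nrow(d), total_bp = sum(d$length))
    }),
    n_sags = purrr::imap(sags, function(s, b) sum(s$sag)),
    n_dag_windows = nrow(dags$windows),
    n_dags = nrow(tidy(dags)),
    n_tags = purrr::imap(tags, function(t, b) {
      if (is.null(t)) 0L else nrow(tidy(t))
    }),
    n_qtl_gene_overlaps = nrow(qtl_hits),
    sweep_recovery = recovery
  )
  jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  manifest_files <- sort(setdiff(
    list.files(run_dir, recursive = TRUE),
    c("manifest.json", "pipeline.log", "sweep_tracks.pdf")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("caprisweep")),
    seed = config$seed,
    config_hash = config_hash(config),
    timings = timings,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(run_dir, manifest_files))),
      manifest_files))
  )
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("done")

  structure(list(
    run_dir = run_dir, config = config, sim = sim,
    variants = vt_f, summaries = summaries, effects = effects,
    ns_s = ns_s, partition = partition,
    desert_windows = desert_windows, deserts = deserts, sags = sags,
    dom_stats = dom_stats, dags = dags,
    breed_stats = breed_stats, tags = tags,
    qtl_hits = qtl_hits, summary = summary
  ), class = "pipeline_run")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

# Truth-based sweep recovery: was the true sweep window flagged in the
# sweep breed's TAG windows?
sweep_recovery <- function(truth, tags, config) {
  if (is.null(truth) || is.null(truth$sweep_window) ||
      is.na(truth$sweep_breed)) {
    return(NULL)
  }
  tg <- tags[[truth$sweep_breed]]
  if (is.null(tg)) return(list(recall = 0, n_flagged = 0L))
  w <- tg$windows
  hit <- any(w$chrom == truth$sweep_window$chrom &
               w$start < truth$sweep_window$end &
               w$end > truth$sweep_window$start)
  list(
    recall = as.numeric(hit),
    n_flagged = nrow(w),
    precision = if (nrow(w) > 0) {
      mean(w$chrom == truth$sweep_window$chrom &
             w$start < truth$sweep_window$end &
             w$end > truth$sweep_window$start)
    } else NA_real_
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> ", x$run_dir, "\n", sep = "")
  cat(sprintf("  sites kept: %d / %d\n", x$summary$n_sites_kept,
              x$summary$n_sites_input))
  cat(sprintf("  DAG genes: %d | TAG genes: %s\n", x$summary$n_dags,
              paste(unlist(x$summary$n_tags), collapse = "/")))
  invisible(x)
}

#' Summarise a completed run directory
#'
#' Reads `summary.json` and the output tables of a pipeline run, verifies
#' that every expected output is present (missing files are an error
#' listing the absentees) and recounts headline numbers from the files
#' themselves.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return List with the parsed summary, recounted values and the manifest.
#' @export
report_summary <- function(run_dir) {
  need <- c("summary.json", "manifest.json", "filter_report.tsv",
            "domestication_windows.tsv", "dags.tsv")
  miss <- need[!file.exists(file.path(run_dir, need))]
  if (length(miss)) {
    stop("missing pipeline output(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  summary <- jsonlite::read_json(file.path(run_dir, "summary.json"))
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
  dag_tb <- readr::read_tsv(file.path(run_dir, "dags.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  desert_files <- list.files(run_dir, "^deserts_.*\\.bed$",
                             full.names = TRUE)
  recount <- list(
    n_dags = nrow(dag_tb),
    n_deserts = stats::setNames(
      lapply(desert_files, function(f) {
        nrow(readr::read_tsv(f, col_names = FALSE, show_col_types = FALSE,
                             progress = FALSE))
      }),
      gsub("^deserts_|\\.bed$", "", basename(desert_files)))
  )
  list(summary = summary, recount = recount, manifest = manifest)
}
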