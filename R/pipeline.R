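#' Pipeline configuration
#'
#' Exactly one of `input` (paths to a two-row DArTseq CSV and an accession
#' metadata CSV) or `simulation` (a [sim_config()]) must be given.
#'
#' @param input list(genotypes = path, meta = path) or `NULL`.
#' @param simulation a [sim_config()] or `NULL`.
#' @param filter a [filter_config()].
#' @param n_positions,width_bp window geometry (defaults 250 / 500 kb).
#' @param unique_thresholds unique-allele frequency thresholds
#'   (default c(0.25, 0.05): common and rare variants).
#' @param k_range,n_replicates admixture K range and replicate starts
#'   (defaults 1:6 and 3 for desk-scale runs; the full survey design is
#'   1:16 with 6).
#' @param admix_max_iter EM iteration cap per replicate (default 300).
#' @param ibd_cutoff duplicate PI-HAT cutoff (default 0.95).
#' @param d_low duplicate distance ceiling (default 0.05).
#' @param amova_permutations label permutations (default 199).
#' @param core_max_nodes search budget for [extract_core()] (default 2000).
#' @param seed global seed; per-stage seeds are derived by fixed offsets so
#'   stages are independently reproducible.
#' @param out_dir output directory for CSVs and the JSON manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            filter = filter_config(),
                            n_positions = 250, width_bp = 5e5,
                            unique_thresholds = c(0.25, 0.05),
                            k_range = 1:6, n_replicates = 3,
                            admix_max_iter = 300,
                            ibd_cutoff = 0.95, d_low = 0.05,
                            amova_permutations = 199, core_max_nodes = 2000,
                            seed = 1, out_dir = tempfile("dartpool_run")) {
  if (is.null(input) == is.null(simulation)) {
    stop("exactly one of input paths or a simulation block must be given")
  }
  structure(list(input = input, simulation = simulation, filter = filter,
                 n_positions = n_positions, width_bp = width_bp,
                 unique_thresholds = unique_thresholds, k_range = k_range,
                 n_replicates = n_replicates,
                 admix_max_iter = admix_max_iter, ibd_cutoff = ibd_cutoff,
                 d_low = d_low, amova_permutations = amova_permutations,
                 core_max_nodes = core_max_nodes,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes filter, diversity summaries, SNP-type accounting, window tracks,
#' unique-allele timeline, Jaccard distances, PCoA, AMOVA, IBD duplicate
#' detection, admixture with delta-K, and core-collection extraction,
#' writing one CSV per stage plus a JSON manifest. A stage failure aborts
#' with a stage-named error after writing the partial manifest.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage log lines (default FALSE).
#' @return list with all stage results plus `manifest` (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("dartpool")),
                   seed = cfg$seed, stages = list())
  res <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, na = "null")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    out
  }
  note <- function(name, file, n_rows) {
    manifest$stages[[name]] <<- list(status = "ok", output = file,
                                     n_rows = n_rows)
    say("stage %-16s -> %s (%d rows)", name, file, n_rows)
  }

  # 1. load or simulate
  panel <- stage("load", {
    if (!is.null(cfg$simulation)) {
      sim <- cfg$simulation
      sim$seed <- cfg$seed
      generate_panel(sim)
    } else {
      dat <- read_dartseq_tworow(cfg$input$genotypes)
      meta <- accession_meta(utils::read.csv(cfg$input$meta,
                                             stringsAsFactors = FALSE))
      list(genotypes = dat$genotypes, info = dat$info, meta = meta,
           truth = NULL)
    }
  })
  meta <- panel$meta
  note("load", "(in memory)", nrow(panel$genotypes))

  # 2. filter
  filt <- stage("filter", filter_loci(panel$genotypes, panel$info,
                                      cfg$filter))
  gm <- filt$genotypes
  info <- filt$info
  f <- file.path(cfg$out_dir, "filter_report.csv")
  write_table(filt$report, f)
  note("filter", f, nrow(filt$report))

  # 3. diversity summaries
  divsum <- stage("diversity", group_summaries(gm, info, meta))
  f <- file.path(cfg$out_dir, "diversity_summaries.csv")
  write_table(divsum, f)
  note("diversity", f, nrow(divsum))

  # 4. SNP types + heterogeneity + homozygous fractions
  snp <- stage("snp_types", snp_type_table(info))
  f <- file.path(cfg$out_dir, "snp_type_stats.csv")
  write_table(snp$stats, f)
  note("snp_types", f, nrow(snp$stats))
  hetero <- stage("heterogeneity", cultivar_heterogeneity(gm))
  f <- file.path(cfg$out_dir, "cultivar_heterogeneity.csv")
  write_table(hetero, f)
  note("heterogeneity", f, nrow(hetero))

  # 5. genome-scan tracks between earliest and latest periods
  groups <- period_split(meta)
  scan <- stage("genome_scan", selection_scan_report(
    gm, info, groups[[1L]], groups[[length(groups)]],
    n_positions = cfg$n_positions, width_bp = cfg$width_bp))
  f <- file.path(cfg$out_dir, "scan_fst_pow.csv")
  write_table(scan$fst_pow, f)
  note("genome_scan", f, nrow(scan$fst_pow))

  # 6. unique-allele timeline at both thresholds
  ua <- stage("unique_alleles", do.call(rbind, lapply(
    cfg$unique_thresholds,
    function(th) unique_allele_timeline(gm, info, meta, th))))
  f <- file.path(cfg$out_dir, "unique_alleles.csv")
  write_table(ua, f)
  note("unique_alleles", f, nrow(ua))

  # 7. distances + summary
  D <- stage("distance", jaccard_distance(gm))
  f <- file.path(cfg$out_dir, "jaccard_distance.csv")
  utils::write.csv(signif(unclass(D), 12), f)
  note("distance", f, nrow(D))
  dsum <- stage("distance_summary", group_distance_summary(D, meta))
  f <- file.path(cfg$out_dir, "distance_summary.csv")
  write_table(dsum, f)
  note("distance_summary", f, nrow(dsum))

  # 8. PCoA
  ord <- stage("pcoa", pcoa(D, n_axes = 3))
  pc <- data.frame(accession_id = rownames(ord$coordinates),
                   ord$coordinates,
                   stringsAsFactors = FALSE)
  f <- file.path(cfg$out_dir, "pcoa_coordinates.csv")
  write_table(pc, f)
  note("pcoa", f, nrow(pc))

  # 9. AMOVA
  am <- stage("amova", amova(D, meta$period_group,
                             n_permutations = cfg$amova_permutations,
                             seed = cfg$seed + 101L))
  f <- file.path(cfg$out_dir, "amova.csv")
  write_table(am$table, f)
  note("amova", f, nrow(am$table))

  # 10. IBD duplicates
  ibd <- stage("ibd", ibd_pihat(gm))
  clusters <- duplicate_clusters(ibd$pihat, cfg$ibd_cutoff)
  f <- file.path(cfg$out_dir, "ibd_pihat.csv")
  utils::write.csv(signif(unclass(ibd$pihat), 12), f)
  note("ibd", f, nrow(ibd$pihat))

  # 11. admixture + delta-K
  adm <- stage("admixture", fit_admixture_series(
    gm, k_range = cfg$k_range, n_replicates = cfg$n_replicates,
    seed = cfg$seed + 202L, max_iter = cfg$admix_max_iter))
  dk <- stage("delta_k", evanno_delta_k(adm$loglik))
  f <- file.path(cfg$out_dir, "delta_k.csv")
  write_table(dk$table, f)
  note("delta_k", f, nrow(dk$table))
  chosen <- if (is.na(dk$chosen_k)) max(cfg$k_range) else dk$chosen_k
  aligned <- stage("align", align_replicates(adm$fits[[as.character(chosen)]]))
  Q <- aligned$consensus_q
  f <- file.path(cfg$out_dir, "membership_q.csv")
  write_table(data.frame(accession_id = rownames(Q), signif(Q, 12)), f)
  note("align", f, nrow(Q))

  verdicts <- stage("duplicates", duplicate_verdict(meta, D, Q, clusters,
                                                    cfg$d_low))
  f <- file.path(cfg$out_dir, "duplicate_verdicts.csv")
  write_table(verdicts, f)
  note("duplicates", f, nrow(verdicts))

  # 12. core collection
  core <- stage("core", extract_core(gm, max_nodes = cfg$core_max_nodes))
  core_tab <- data.frame(accession_id = rownames(gm),
                         selected = rownames(gm) %in% core$selected,
                         stringsAsFactors = FALSE)
  f <- file.path(cfg$out_dir, "core_collection.csv")
  write_table(core_tab, f)
  note("core", f, nrow(core_tab))

  manifest$parameters <- list(
    filter = cfg$filter, n_positions = cfg$n_positions,
    width_bp = cfg$width_bp, unique_thresholds = cfg$unique_thresholds,
    k_range = range(cfg$k_range), n_replicates = cfg$n_replicates,
    ibd_cutoff = cfg$ibd_cutoff, d_low = cfg$d_low,
    amova_permutations = cfg$amova_permutations)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(c(list(panel = panel, filter = filt, diversity = divsum,
                   snp_types = snp, heterogeneity = hetero, scan = scan,
                   unique_alleles = ua, distance = D,
                   distance_summary = dsum, pcoa = ord, amova = am,
                   ibd = ibd, clusters = clusters, delta_k = dk,
                   membership_q = Q, verdicts = verdicts, core = core,
                   manifest = manifest)))
}
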