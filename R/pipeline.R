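## End-to-end pipeline: simulate -> rates -> DPI -> inference -> evaluation,
## as one reproducible run with a flat config, per-stage logging and TSV
## outputs. Also builds the small bundled test fixtures.

#' Pipeline run configuration
#'
#' @param kind `"simulation"` (designs simulated on a Yule chronogram) or
#'   `"empirical"` (alignments, chronogram and reference read from disk).
#' @param model_tag `"JTT"` or `"K2P"`.
#' @param n_taxa,root_depth Yule chronogram parameters (simulation).
#' @param designs list of [simulation_design()]; default
#'   [standard_design_grid()] with `n_replicates`.
#' @param n_replicates replicates per design for the default grid.
#' @param alignment_paths,chronogram_path,reference_path inputs for an
#'   empirical run (FASTA/PHYLIP alignments, Newick trees).
#' @param support support metric for EPP and cumulative paths.
#' @param bootstrap_reps bootstrap replicates.
#' @param n_gamma_categories gamma categories for inference.
#' @param h1,h2 DPI epoch (Myr); `h2 = NULL` means the root depth.
#' @param seed master seed: all stage seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(kind = c("simulation", "empirical"),
                       model_tag = c("JTT", "K2P"),
                       n_taxa = 28, root_depth = 973,
                       designs = NULL, n_replicates = 10,
                       alignment_paths = NULL, chronogram_path = NULL,
                       reference_path = NULL,
                       support = "ml_bp", bootstrap_reps = 100,
                       n_gamma_categories = 4, h1 = 0, h2 = NULL, seed = 1) {
  kind <- match.arg(kind)
  model_tag <- match.arg(toupper(model_tag), c("JTT", "K2P"))
  if (kind == "empirical") {
    if (is.null(alignment_paths) || is.null(chronogram_path))
      stop("empirical run requires 'alignment_paths' and 'chronogram_path'")
  }
  structure(list(kind = kind, model_tag = model_tag, n_taxa = n_taxa,
                 root_depth = root_depth, designs = designs,
                 n_replicates = n_replicates,
                 alignment_paths = alignment_paths,
                 chronogram_path = chronogram_path,
                 reference_path = reference_path,
                 support = support, bootstrap_reps = bootstrap_reps,
                 n_gamma_categories = n_gamma_categories,
                 h1 = h1, h2 = h2, seed = as.integer(seed)),
            class = "run_config")
}

#' Assemble a study from empirical inputs
#'
#' @param alignments named list of [pi_alignment()] (names = gene ids).
#' @param chronogram ultrametric tree (Myr) used for rate estimation.
#' @param model_tag `"JTT"` or `"K2P"`.
#' @return a `pi_study` with one replicate per gene.
#' @export
assemble_study <- function(alignments, chronogram, model_tag = c("JTT", "K2P")) {
  model_tag <- match.arg(toupper(model_tag), c("JTT", "K2P"))
  chronogram <- as_chronogram(chronogram)
  ids <- names(alignments)
  if (is.null(ids)) ids <- sprintf("gene%03d", seq_along(alignments))
  genes <- lapply(seq_along(alignments), function(i)
    list(gene_id = ids[i], replicate = 1L,
         design = list(model_tag = model_tag),
         alignment = alignments[[i]], rates_true = NULL, seed = NA))
  manifest <- data.frame(gene_id = ids, replicate = 1L,
                         mean_rate = NA, gamma_alpha = NA,
                         model_tag = model_tag,
                         n_sites = vapply(alignments, ncol, integer(1)),
                         seed = NA)
  structure(list(chronogram = chronogram, genes = genes, manifest = manifest),
            class = "pi_study")
}

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Execute a pipeline run
#'
#' Simulates (or loads) the study, runs the full evaluation, and writes
#' the manifest, per-stage tables and a run log into `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param dry_run validate the config and print the stage plan without
#'   computing.
#' @return the [evaluate_study()] result, invisibly (`NULL` for a dry
#'   run).
#' @export
run_pipeline <- function(config, out_dir, dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  plan <- c(
    sprintf("stage 1  %s study (%s)", config$kind, config$model_tag),
    "stage 2  per-site rate estimation on the chronogram",
    sprintf("stage 3  DPI over [%s, %s] and gene ranking", config$h1,
            if (is.null(config$h2)) "root" else config$h2),
    sprintf("stage 4  gene-tree inference + %s supports (%d bootstrap reps)",
            config$support, config$bootstrap_reps),
    "stage 5  RF / PPP-EPP / cumulative-path evaluation")
  if (dry_run) {
    cat(plan, sep = "\n")
    return(invisible(NULL))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                                    sprintf(...)),
                            file = log_path, append = TRUE)
  logf("run started, seed %d", config$seed)

  if (config$kind == "simulation") {
    designs <- config$designs
    if (is.null(designs))
      designs <- standard_design_grid(config$model_tag,
                                      n_replicates = config$n_replicates)
    chrono <- generate_chronogram(config$n_taxa, config$root_depth,
                                  seed = child_seed(config$seed, 0))
    study <- build_study(designs, chrono, seed = config$seed)
  } else {
    alignments <- lapply(config$alignment_paths, read_alignment)
    if (is.null(names(alignments)))
      names(alignments) <- sub("\\.[^.]*$", "", basename(config$alignment_paths))
    chrono <- read_newick(config$chronogram_path, rooted = TRUE, file = TRUE)
    study <- assemble_study(alignments, chrono, config$model_tag)
  }
  .write_tsv(study$manifest, file.path(out_dir, "manifest.tsv"),
             "gene_id, replicate, design parameters, seed")
  logf("study ready: %d gene alignments", length(study$genes))

  ev_settings <- evaluation_settings(
    support = config$support, h1 = config$h1, h2 = config$h2,
    rates = rate_settings(config$model_tag),
    inference = inference_settings(config$model_tag,
                                   n_gamma_categories = config$n_gamma_categories,
                                   bootstrap_reps = config$bootstrap_reps,
                                   seed = config$seed),
    seed = config$seed)
  reference <- if (config$kind == "empirical" && !is.null(config$reference_path))
    read_newick(config$reference_path, file = TRUE) else NULL
  ev <- evaluate_study(study, ev_settings, reference = reference)
  logf("evaluation done: %d genes, %d excluded",
       nrow(ev$genes), if (is.null(ev$excluded)) 0L else nrow(ev$excluded))
  if (!is.null(ev$excluded)) {
    .write_tsv(ev$excluded, file.path(out_dir, "excluded.tsv"),
               "gene_id, replicate, reason")
    for (i in seq_len(nrow(ev$excluded)))
      logf("excluded %s rep %d: %s", ev$excluded$gene_id[i],
           ev$excluded$replicate[i], ev$excluded$reason[i])
  }
  .write_tsv(ev$genes, file.path(out_dir, "genes.tsv"),
             "gene_id, dpi, rank (1 = highest DPI), mean RF, PLRS")
  .write_tsv(ev$pairs, file.path(out_dir, "pairs.tsv"),
             "gene_hi, gene_lo, ppp, epp, n_hi, n_lo")
  .write_tsv(ev$correlations, file.path(out_dir, "correlations.tsv"),
             "analysis, n, Pearson r, two-sided p")
  .write_tsv(ev$paths, file.path(out_dir, "paths.tsv"),
             "k, ideal, worst, average, dpi_order cumulative support")
  logf("run finished")
  invisible(ev)
}

#' Scaled-down headline simulation evaluation
#'
#' Runs the full simulated-data evaluation on the standard 50-design
#' grid (10 mean rates x 5 heterogeneity regimes, 300 sites, 20%
#' invariant, fixed counts) over a seeded 28-taxon, 973-Myr Yule
#' chronogram, at compute-scaled settings: `n_replicates` replicates per
#' design (DPI and RF averaged over all of them), bootstrap supports on
#' `support_replicates` replicate(s) with `bootstrap_reps` resamplings,
#' two-category discrete gamma for inference, and a slightly coarsened
#' per-site rate optimizer. Runs in roughly 8 minutes (AA) + 2.5 minutes
#' (DNA) on one CPU. See the methods vignette for what this scaling does
#' and does not preserve.
#'
#' @param model_tag `"JTT"` or `"K2P"`.
#' @param seed master seed (chronogram, simulation and inference).
#' @param support support metric for the paired EPP analysis.
#' @param n_replicates replicates per design.
#' @param bootstrap_reps bootstrap resamplings.
#' @param support_replicates replicates per gene that get supports.
#' @param n_gamma_categories inference gamma categories.
#' @return an [evaluate_study()] result.
#' @export
run_headline_evaluation <- function(model_tag = c("JTT", "K2P"), seed = 1,
                                    support = if (model_tag == "JTT") "ml_bp"
                                              else "mp_bp",
                                    n_replicates = 3, bootstrap_reps = 25,
                                    support_replicates = 1,
                                    n_gamma_categories = 2) {
  model_tag <- match.arg(toupper(model_tag), c("JTT", "K2P"))
  designs <- standard_design_grid(model_tag, n_replicates = n_replicates)
  chrono <- generate_chronogram(28, 973, seed = child_seed(seed, 0))
  study <- build_study(designs, chrono, seed = seed)
  settings <- evaluation_settings(
    support = support,
    rates = rate_settings(model_tag, n_grid = 15, tol = 1e-3),
    inference = inference_settings(model_tag,
                                   n_gamma_categories = n_gamma_categories,
                                   bootstrap_reps = bootstrap_reps,
                                   seed = seed),
    support_replicates = support_replicates,
    seed = seed)
  evaluate_study(study, settings)
}

#' Bundled test fixtures
#'
#' Three deterministic miniature inputs: a strong-signal 4-taxon gene
#' (1000 congruent sites at a moderate rate), an 8-taxon / 6-gene
#' mini-study spanning a 30x rate range, and a saturated 4-taxon gene
#' (rate x depth far beyond the informative regime).
#'
#' @param seed integer seed.
#' @return list with `strong4` (alignment + chronogram + rates),
#'   `mini8` (a `pi_study`), `saturated` (alignment + chronogram +
#'   rates).
#' @export
make_fixtures <- function(seed = 1) {
  ch4 <- as_chronogram(read_newick("((A:50,B:50):50,(C:50,D:50):50);"))
  strong_rates <- site_rate_vector(rep(0.002, 1000), "generating")
  strong <- simulate_alignment(ch4, strong_rates, "K2P",
                               seed = child_seed(seed, 11))
  sat_rates <- site_rate_vector(rep(0.2, 300), "generating")
  saturated <- simulate_alignment(ch4, sat_rates, "K2P",
                                  seed = child_seed(seed, 12))
  ## rates span ~12x but stay below ~0.5 substitutions root-to-tip, so the
  ## mini-study sits in the non-saturated regime where DPI order should
  ## track performance
  designs <- lapply(seq(1e-4, 1.2e-3, length.out = 6), function(r)
    simulation_design(r, gamma_alpha = NA, n_categories = 1,
                      invariant_fraction = 0.2, n_sites = 200,
                      model_tag = "K2P", n_replicates = 1))
  names(designs) <- sprintf("mini%02d", seq_along(designs))
  ch8 <- generate_chronogram(8, 400, seed = child_seed(seed, 13))
  mini8 <- build_study(designs, ch8, seed = child_seed(seed, 14))
  list(strong4 = list(alignment = strong, chronogram = ch4,
                      rates = strong_rates),
       mini8 = mini8,
       saturated = list(alignment = saturated, chronogram = ch4,
                        rates = sat_rates))
}
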