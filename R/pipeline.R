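#' Experiment configuration
#'
#' Bundles every setting of the synthetic missing-data experiment:
#' two-deme demography, GTR+Gamma model, bycatch masking, the
#' coverage-threshold grid, DAPC settings, skyline MCMC settings, and the
#' dates-only / monophyly controls. Defaults follow the study conditions:
#' a mitogenome-length alignment, mostly-conferta composition, ~120-year
#' heterochronous sampling window, per-sample coverage spread over
#' 5-100%, eleven thresholds from 5% to 65%, a 30% PC retention rule, the
#' `[0.01, 0.99]` admixture interval, an exponential(10000) prior on
#' \eqn{\nu} and 10% burnin.
#'
#' @param n_conferta,n_armigera samples per deme.
#' @param seq_length alignment length in bp.
#' @param demography a [demography_config()].
#' @param gtr a [gtr_params()].
#' @param mask_target per-sample coverage target: scalar, vector, or
#'   `function(n)`.
#' @param mean_block_length mean missing-run length in bp.
#' @param thresholds coverage thresholds (default eleven values 5-65%).
#' @param retain_fraction PC retention fraction for the DAPC.
#' @param admix_low,admix_high admixture interval endpoints.
#' @param clock_rate substitutions/site/year used for tree estimation
#'   (defaults to the GTR clock rate).
#' @param min_overlap pairwise-deletion overlap floor for tree estimation.
#' @param chain_length,sample_every,burnin_frac,prior_mean,n_groups skyline
#'   MCMC settings (chain defaults are desk-scale).
#' @param n_dates_only_trees size of the dates-only tree set.
#' @param monophyly_n_subsample trees evaluated for the monophyly
#'   distribution.
#' @param seed root seed; every stage derives its own stream from it.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_conferta = 200L, n_armigera = 60L,
                              seq_length = 15390L,
                              demography = demography_config(
                                nu_conferta = 5000, nu_armigera = 5000,
                                migration_rate = 1e-4,
                                growth = list(rate = 0.02,
                                              plateau_year = 1900),
                                sampling_window = c(1900, 2020)),
                              gtr = gtr_params(
                                exchangeabilities = c(1, 10, 1, 1, 10, 1),
                                base_freqs = c(0.35, 0.15, 0.10, 0.40),
                                gamma_shape = 1, n_categories = 4L,
                                clock_rate = 1e-6),
                              mask_target = function(n) stats::runif(n, 0.05, 1),
                              mean_block_length = 300,
                              thresholds = default_thresholds(),
                              retain_fraction = 0.30,
                              admix_low = 0.01, admix_high = 0.99,
                              clock_rate = NULL, min_overlap = 10L,
                              chain_length = 2e4, sample_every = 20,
                              burnin_frac = 0.10, prior_mean = 10000,
                              n_groups = NULL,
                              n_dates_only_trees = 100L,
                              monophyly_n_subsample = 1000L,
                              seed = 1L) {
  cfg <- list(
    n_conferta = n_conferta, n_armigera = n_armigera,
    seq_length = seq_length, demography = demography, gtr = gtr,
    mask_target = mask_target, mean_block_length = mean_block_length,
    thresholds = thresholds, retain_fraction = retain_fraction,
    admix_low = admix_low, admix_high = admix_high,
    clock_rate = if (is.null(clock_rate)) gtr$clock_rate else clock_rate,
    min_overlap = min_overlap,
    chain_length = chain_length, sample_every = sample_every,
    burnin_frac = burnin_frac, prior_mean = prior_mean,
    n_groups = n_groups,
    n_dates_only_trees = n_dates_only_trees,
    monophyly_n_subsample = monophyly_n_subsample,
    seed = as.integer(seed)
  )
  class(cfg) <- "experiment_config"
  cfg
}

#' Run the full synthetic missing-data experiment
#'
#' Simulates a two-deme genealogy and mitogenome alignment, masks it into
#' patchy bycatch data, builds the coverage-threshold datasets, and per
#' threshold runs the DAPC (membership, admixture, site loadings), the
#' distance-based dated tree, the Bayesian skyline, and the monophyly
#' statistic against a dates-only control. Cross-threshold summaries
#' (admixed proportion against dataset composition; root height against
#' coverage) and a machine-readable index of every output are written to
#' `out_dir`. Identical configurations and seeds yield byte-identical
#' outputs; a failing stage is logged with its stage name and the
#' remaining datasets still run.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir writable output directory (created if absent).
#' @return invisibly, the report bundle: a list with the simulated truth,
#'   per-threshold results, cross-threshold summaries, the stage log and
#'   the output index.
#' @export
run_experiment <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(stage, msg = "ok") {
    log <<- c(log, paste0(stage, ": ", msg))
  }
  fail <- function(stage, e) note(stage, paste0("FAILED - ", conditionMessage(e)))
  paths <- character(0)
  reg <- function(p) { paths <<- c(paths, p); p }

  root <- cfg$seed
  meta <- synthesize_meta(cfg$n_conferta, cfg$n_armigera,
                          cfg$demography$sampling_window,
                          seed = derive_seed(root, "meta"))
  write_meta_csv(meta, reg(file.path(out_dir, "meta.csv")))
  note("meta")

  gen <- simulate_genealogy(meta, cfg$demography,
                            seed = derive_seed(root, "genealogy"))
  write_dated_tree(gen, reg(file.path(out_dir, "true_tree.nwk")),
                   reg(file.path(out_dir, "tip_dates.csv")))
  note("genealogy")

  aln <- simulate_sequences(gen, cfg$gtr, cfg$seq_length,
                            seed = derive_seed(root, "sequences"))
  note("sequences")

  masked <- apply_bycatch_mask(aln, mask_config(
    target_coverage = cfg$mask_target,
    mean_block_length = cfg$mean_block_length,
    seed = derive_seed(root, "mask")))
  write_alignment_fasta(masked, reg(file.path(out_dir, "alignment_masked.fasta")))
  note("mask")

  cov <- coverage_proportion(masked)
  utils::write.csv(
    data.frame(id = names(cov$per_sample),
               coverage = round(unname(cov$per_sample), 6)),
    reg(file.path(out_dir, "coverage.csv")), row.names = FALSE, quote = FALSE)
  subsets <- suppressWarnings(threshold_subsets(masked, cfg$thresholds))
  utils::write.csv(threshold_manifest(subsets),
                   reg(file.path(out_dir, "manifest.csv")),
                   row.names = FALSE)
  note("threshold")

  labels_of <- function(s) {
    stats::setNames(meta$prior_cluster, meta$id)[rownames(s)]
  }
  armigera_ids <- meta$id[meta$prior_cluster == "armigera"]

  per_threshold <- list()
  for (th in names(subsets)) {
    sub <- subsets[[th]]
    res <- list(threshold = as.numeric(th),
                n = if (is.null(sub)) 0L else nrow(sub))
    tdir <- file.path(out_dir, paste0("th_", th))
    dir.create(tdir, showWarnings = FALSE)
    if (is.null(sub)) {
      note(paste0("dataset ", th), "empty - skipped")
      per_threshold[[th]] <- res
      next
    }
    labs <- labels_of(sub)

    # --- DAPC ------------------------------------------------------------
    tryCatch({
      enc <- encode_alignment(sub)
      pca <- pca_reduce(enc, cfg$retain_fraction)
      fit <- dapc_fit(pca, labs, enc)
      fit$admixed <- classify_admixed(fit$membership,
                                      cfg$admix_low, cfg$admix_high)
      memb <- data.frame(id = rownames(fit$membership),
                         round(fit$membership, 6),
                         admixed = fit$admixed, row.names = NULL)
      utils::write.csv(memb, reg(file.path(tdir, "membership.csv")),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(fit$site_loadings,
                       reg(file.path(tdir, "loadings.csv")),
                       row.names = FALSE, quote = FALSE)
      jsonlite::write_json(list(
        threshold = as.numeric(th), n_samples = nrow(sub),
        n_pcs = fit$n_pcs_retained,
        prop_admixed = mean(fit$admixed),
        prop_armigera = mean(labs == "armigera")
      ), reg(file.path(tdir, "dapc_summary.json")),
      auto_unbox = TRUE, digits = NA)
      res$dapc <- list(admixed = fit$admixed, labels = labs,
                       prop_admixed = mean(fit$admixed))
      note(paste0("dapc ", th))
    }, error = function(e) fail(paste0("dapc ", th), e))

    # --- tree + skyline --------------------------------------------------
    tryCatch(withCallingHandlers({
      est <- estimate_tree(sub, meta, cfg$clock_rate, cfg$min_overlap)
      write_dated_tree(est, reg(file.path(tdir, "tree.nwk")),
                       reg(file.path(tdir, "tree_tip_dates.csv")))
      sky <- skyline_mcmc(est, n_groups = cfg$n_groups,
                          prior_mean = cfg$prior_mean,
                          chain_length = cfg$chain_length,
                          sample_every = cfg$sample_every,
                          burnin_frac = cfg$burnin_frac,
                          seed = derive_seed(root, "skyline", th))
      write_skyline_csv(sky, reg(file.path(tdir, "skyline.csv")),
                        reg(file.path(tdir, "trace.csv")))
      res$tree <- est
      res$root_height <- root_height(est)
      res$skyline <- sky$trajectory
      note(paste0("tree+skyline ", th))
    }, warning = function(w) {
      note(paste0("tree+skyline ", th),
           paste0("warning - ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) fail(paste0("tree+skyline ", th), e))

    # --- monophyly: sequence-informed tree and dates-only control --------
    tryCatch({
      foc <- intersect(armigera_ids, rownames(sub))
      if (length(foc) >= 1L && !is.null(res$tree)) {
        res$monophyly_seq <- largest_monophyletic_proportion(res$tree, foc)
      }
      if (length(foc) >= 1L && nrow(sub) >= 2L) {
        meta_sub <- meta[meta$id %in% rownames(sub), , drop = FALSE]
        dtrees <- simulate_dates_only_trees(
          meta_sub, prior_mean = cfg$prior_mean,
          n_trees = cfg$n_dates_only_trees,
          seed = derive_seed(root, "dates_only", th))
        md <- monophyly_distribution(dtrees, foc,
                                     n_subsample = cfg$monophyly_n_subsample,
                                     seed = derive_seed(root, "monophyly", th))
        write_monophyly(md, reg(file.path(tdir, "monophyly_dates.csv")),
                        reg(file.path(tdir, "monophyly.json")))
        res$monophyly_dates <- md
      }
      note(paste0("monophyly ", th))
    }, error = function(e) fail(paste0("monophyly ", th), e))

    per_threshold[[th]] <- res
  }

  # --- cross-threshold summaries -----------------------------------------
  summaries <- list()
  dapc_sets <- Filter(function(r) !is.null(r$dapc), per_threshold)
  if (length(dapc_sets) >= 3L) {
    fit <- admixture_vs_composition(lapply(dapc_sets, function(r) r$dapc))
    summaries$admixture_regression <- list(
      slope = fit$slope, intercept = fit$intercept,
      r_squared = fit$r_squared, p_value = fit$p_value)
    pts <- attr(fit, "points")
    pts$threshold <- vapply(dapc_sets, function(r) r$threshold, numeric(1))
    utils::write.csv(pts, reg(file.path(out_dir, "admixture_vs_composition.csv")),
                     row.names = FALSE, quote = FALSE)
    note("admixture regression")
  }
  rh <- data.frame(
    threshold = vapply(per_threshold, function(r) r$threshold, numeric(1)),
    n = vapply(per_threshold, function(r) r$n, numeric(1)),
    root_height = vapply(per_threshold, function(r) {
      if (is.null(r$root_height)) NA_real_ else r$root_height
    }, numeric(1)),
    row.names = NULL)
  utils::write.csv(rh, reg(file.path(out_dir, "root_heights.csv")),
                   row.names = FALSE, quote = FALSE)
  summaries$root_heights <- rh

  rel <- vapply(paths, function(p) {
    if (startsWith(p, out_dir)) substring(p, nchar(out_dir) + 2L) else p
  }, character(1))
  index <- list(seed = root, outputs = sort(unname(rel)), log = log)
  jsonlite::write_json(index, file.path(out_dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log, file.path(out_dir, "stages.log"))

  invisible(list(meta = meta, truth = list(tree = gen),
                 alignment = masked, per_threshold = per_threshold,
                 summaries = summaries, log = log,
                 index = index))
}
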