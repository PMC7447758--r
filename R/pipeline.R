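#' Run the full inference-selection-validation pipeline
#'
#' Executes the complete workflow on one dataset: (1) simulate a dataset
#' from a random network, or load one from disk; (2) for each method, pick
#' candidate penalties from a sparsity sweep; (3) nested bootstrap with FDR
#' control per candidate; (4) balanced-error cross-validated wRSS of every
#' FDR-passing network against its shuffled-topology null; (5) select the
#' overall best network — the one that outperforms its null distribution by
#' the largest margin (lowest wRSS ratio to the null median), ties broken
#' toward sparser networks.  A second dataset block triggers independent
#' validation of the selected network under the same cross-validation
#' strategy.
#'
#' All stochastic stages consume seeds derived deterministically from the
#' single `seed` entry, so two runs with an equal config are identical.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `simulation` (list: n_genes, links_per_gene, activating_fraction,
#'   replicates, snr) or `data` (list: y, p, optional groups);
#'   `methods` (default `"lsco"`); `penalties_per_method` (default 3);
#'   `sweep_points` (default 12); `n_nested`, `n_boot`, `alpha`, `n_null`,
#'   `truncate`; `seed`; optional `validation` (a second simulation/data
#'   block); optional `out_dir` for TSV/JSON outputs.
#' @return A report list: per-candidate penalty, selected network link
#'   count, wRSS, ratio to null median and empirical p; the selected best
#'   network; all seeds and executed replicate counts.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$simulation) && is.null(config$data))
    stop("config must contain a 'simulation' or 'data' block", call. = FALSE)
  seed <- config$seed %||% 1L
  seeds <- deriveSeeds(seed, 64)
  methods <- config$methods %||% "lsco"
  kpen <- config$penalties_per_method %||% 3
  n_nested <- config$n_nested %||% 8
  n_boot <- config$n_boot %||% 25
  alpha <- config$alpha %||% 0.05
  n_null <- config$n_null %||% 100
  truncate <- config$truncate %||% TRUE

  loadBlock <- function(block, s1, s2) {
    if (!is.null(block$y)) {
      list(ds = readDataset(block$y, block$p, block$groups), truth = NULL)
    } else {
      net <- randomGRN(block$n_genes, block$links_per_gene %||% 3,
                       block$activating_fraction %||% 0.5, seed = s1)
      des <- makeDesign(block$n_genes,
                        mode = block$mode %||% "single",
                        replicates = block$replicates %||% 3,
                        genes = networkGenes(net), seed = s2)
      list(ds = simulateDataset(net, des, snr = block$snr %||% 10,
                                seed = s2),
           truth = net)
    }
  }
  main <- loadBlock(config$simulation %||% config$data, seeds[1], seeds[2])
  ds <- main$ds

  candidates <- list()
  si <- 3
  for (method in methods) {
    # candidate native densities straddle the 3-5 links/gene expected of
    # natural regulatory systems
    dens <- config$density_targets %||% seq(3, 5, length.out = kpen)
    pick <- lapply(dens, function(lg)
      list(penalty = penaltyForDensity(ds, method, lg)))
    for (cand in pick) {
      si <- si + 1
      nb <- nestBoot(ds, method, cand$penalty, n_nested = n_nested,
                     n_boot = n_boot, alpha = alpha, seed = seeds[si])
      if (is.null(nb$network)) {
        candidates[[length(candidates) + 1]] <- list(
          method = method, penalty = cand$penalty, passed_fdr = FALSE)
        next
      }
      si <- si + 1
      null <- nullDistribution(nb$network, ds, "shuffled_topology",
                               n = n_null, seed = seeds[si],
                               truncate = truncate)
      candidates[[length(candidates) + 1]] <- list(
        method = method, penalty = cand$penalty, passed_fdr = TRUE,
        network = nb$network, fdr_cutoff = nb$fdr@cutoff,
        links = sparsityStats(nb$network)$links,
        wrss = null@observed, ratio_to_median = null@ratioToMedian,
        empirical_p = null@empiricalP)
    }
  }
  passed <- Filter(function(c) isTRUE(c$passed_fdr), candidates)
  if (length(passed) == 0) stop("pipeline: no candidate passed FDR control",
                                call. = FALSE)
  ratios <- vapply(passed, `[[`, numeric(1), "ratio_to_median")
  nlinks <- vapply(passed, `[[`, numeric(1), "links")
  best <- passed[[order(ratios, nlinks)[1]]]

  report <- list(
    seed = seed,
    settings = list(methods = methods, n_nested = n_nested, n_boot = n_boot,
                    alpha = alpha, n_null = n_null, truncate = truncate),
    candidates = lapply(candidates, function(c)
      c[setdiff(names(c), "network")]),
    best = best[setdiff(names(best), "network")],
    best_network = best$network,
    truth = main$truth)

  if (!is.null(config$validation)) {
    val <- loadBlock(config$validation, seeds[60], seeds[61])
    vnull <- nullDistribution(best$network, val$ds, "shuffled_topology",
                              n = n_null, seed = seeds[62],
                              truncate = truncate)
    report$validation <- list(wrss = vnull@observed,
                              ratio_to_median = vnull@ratioToMedian,
                              empirical_p = vnull@empiricalP)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    writeNetwork(best$network,
                 file.path(config$out_dir, "best_network.tsv"), "tsv")
    writeNetwork(best$network,
                 file.path(config$out_dir, "best_network.json"), "json")
    jsonlite::write_json(report[setdiff(names(report),
                                        c("best_network", "truth"))],
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  report
}
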