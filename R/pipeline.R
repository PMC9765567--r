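# End-to-end orchestration: simulate (or load) -> QC -> project -> converge
# -> DIMA -> trade-offs -> mutation correlates -> report.

#' Build and validate a pipeline configuration
#'
#' All thresholds of the downstream screens live here, with the defaults
#' used throughout the package: panel FDR 0.05, WT-discrimination FDR
#' 0.005, DIMA minimum change 5 activity units, growth-correlation median
#' |R| 0.75, PCA candidate loading 0.10 in components explaining >= 5%,
#' ANCOVA R-squared 0.95.
#'
#' @param out_dir output directory for stage tables and the report
#' @param seed integer seed (drives simulation and any permutation tests)
#' @param input_dir optional directory of input CSVs (as written by
#'   [write_dataset()]); when NULL a synthetic dataset is simulated
#' @param simulate_params list of overrides for [simulate_ale_dataset()]
#' @param fdr,wt_fdr,min_change,r_min,weight_min,ev_min,r2_min thresholds
#' @param r2_qc replicate-concordance threshold
#' @param exclusions optional PCA outlier exclusion data.frame (jump,
#'   imodulon)
#' @return a validated `pipeline_config` list
#' @export
pipeline_config <- function(out_dir, seed = 1, input_dir = NULL,
                            simulate_params = list(), fdr = 0.05,
                            wt_fdr = 0.005, min_change = 5, r_min = 0.75,
                            weight_min = 0.10, ev_min = 0.05, r2_min = 0.95,
                            r2_qc = 0.9, exclusions = NULL) {
  cfg <- list(out_dir = out_dir, seed = seed, input_dir = input_dir,
              simulate_params = simulate_params, fdr = fdr, wt_fdr = wt_fdr,
              min_change = min_change, r_min = r_min, weight_min = weight_min,
              ev_min = ev_min, r2_min = r2_min, r2_qc = r2_qc,
              exclusions = exclusions)
  for (th in c("fdr", "wt_fdr", "ev_min", "r2_min", "r2_qc")) {
    v <- cfg[[th]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      stop("invalid threshold ", th, ": must be a single value in (0, 1]",
           call. = FALSE)
    }
  }
  for (th in c("min_change", "r_min", "weight_min")) {
    v <- cfg[[th]]
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      stop("invalid threshold ", th, call. = FALSE)
    }
  }
  if (length(seed) != 1 || is.na(seed) || seed != as.integer(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in analysis order, writes every stage's table under
#' `out_dir`, and produces a machine-readable `summary.json` plus a
#' human-readable `summary.txt` whose counts all trace to rows of the stage
#' tables. A stage failure aborts with the stage name; partial outputs are
#' retained alongside a `FAILED` marker.
#'
#' @param config a `pipeline_config`
#' @return invisibly, a list with every stage result and the summary
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_lines <- character()
  log_msg <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, " failed: ", conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ds <- stage("data", {
    if (is.null(config$input_dir)) {
      args <- utils::modifyList(list(seed = config$seed), config$simulate_params)
      d <- do.call(simulate_ale_dataset, args)
      write_dataset(d, file.path(out, "data"))
      log_msg("simulated dataset under seed ", config$seed, ": ",
              nrow(d$design), " samples, ", nrow(d$X), " genes")
      d
    } else {
      d <- read_dataset(config$input_dir)
      log_msg("loaded dataset from ", config$input_dir, ": ",
              nrow(d$design), " samples")
      d
    }
  })
  meta <- ds$design
  categories <- attr(ds$M, "categories")

  qc <- stage("qc", {
    groups <- split(meta$sample_id, paste(meta$strain, meta$flask_index))
    r <- replicate_qc(ds$X, groups, r2_min = config$r2_qc)
    log_msg("replicate QC: ", length(r$kept), " kept, ",
            length(r$removed), " removed (R2 >= ", config$r2_qc, ")")
    r
  })
  X <- ds$X[, qc$kept, drop = FALSE]
  meta <- meta[meta$sample_id %in% qc$kept, , drop = FALSE]

  A <- stage("project", {
    a <- project_activities(ds$M, X)
    log_msg("projected ", nrow(a), " iModulons onto ", ncol(a), " samples; ",
            sprintf("explained variance %.1f%%",
                    100 * explained_variance(ds$M, a, X)))
    a
  })

  conv <- stage("converge", classify_convergence(ds$phenotypes, fdr = config$fdr))
  write_csv_precise(conv, file.path(out, "convergence.csv"))
  log_msg("convergence screen: ", sum(conv$label == "convergent"), " convergent, ",
          sum(conv$label == "divergent"), " divergent of ", nrow(conv))

  growth_phen <- stage("growth_phenotypes", {
    conv_ids <- conv$phenotype_id[conv$label == "convergent"]
    ph <- ds$phenotypes[ds$phenotypes$stage %in% c("WT", "EP"), ]
    key <- paste(ph$strain, ph$stage)
    vals <- tapply(ph$value, list(ph$phenotype_id, key), mean)
    g_key <- tapply(meta$growth_rate[meta$stage %in% c("WT", "EP")],
                    paste(meta$strain[meta$stage %in% c("WT", "EP")],
                          meta$stage[meta$stage %in% c("WT", "EP")]), mean)
    vals <- vals[, names(g_key), drop = FALSE]
    scr <- growth_correlation_screen(vals, as.numeric(g_key), fdr = config$fdr)
    scr$convergent <- scr$target %in% conv_ids
    scr
  })
  write_csv_precise(growth_phen, file.path(out, "growth_correlation_phenotypes.csv"))

  null <- stage("replicate_null", {
    groups <- split(meta$sample_id, paste(meta$strain, meta$flask_index))
    fit_replicate_null(A, groups)
  })
  log_msg(sprintf("replicate null: meanlog %.3f sdlog %.3f (n = %d)",
                  null$mu, null$sigma, null$n_fit))

  dimas <- stage("dima", dima_screen(A, meta, null, categories = categories,
                                     min_change = config$min_change,
                                     alpha = config$fdr))
  write_csv_precise(dimas$wt_ep, file.path(out, "dima_wt_ep.csv"))
  write_csv_precise(dimas$jumps, file.path(out, "dima_jumps.csv"))
  write_csv_precise(dimas$category_counts, file.path(out, "dima_category_counts.csv"))

  wt_disc <- stage("wt_discriminating",
                   wt_discriminating(A, meta, fdr = config$wt_fdr))
  write_csv_precise(wt_disc, file.path(out, "wt_discriminating.csv"))

  gc_im <- stage("growth_imodulons",
                 growth_correlated_imodulons(A, meta, r_min = config$r_min))
  write_csv_precise(gc_im, file.path(out, "growth_correlated_imodulons.csv"))

  jumpsA <- stage("jumps", compute_jumps(A, meta, mutations = ds$mutations))
  tro <- stage("tradeoffs", {
    pca <- jump_pca(jumpsA$delta, exclusions = config$exclusions)
    cand <- select_candidates(pca$loadings, pca$ev_ratio,
                              weight_min = config$weight_min,
                              ev_min = config$ev_min)
    log_msg("trade-off candidates from PCA: ", length(cand), " iModulons")
    detect_tradeoffs(A, meta, cand, r2_min = config$r2_min, fdr = config$fdr,
                     categories = categories)
  })
  write_csv_precise(tro, file.path(out, "tradeoffs.csv"))

  mc <- stage("mutcorr", {
    jumpsF <- compute_jumps(ds$flux_matrix, meta)
    feats <- build_features(ds$mutations, jumpsA$jumps)
    screen_correlates(feats,
                      delta_flux = jumpsF$delta[rownames(jumpsA$delta), ,
                                                drop = FALSE],
                      delta_activity = jumpsA$delta,
                      fdr = config$fdr, seed = config$seed)
  })
  write_csv_precise(mc, file.path(out, "mutation_correlates.csv"))

  summary_obj <- list(
    parameters = config[c("seed", "fdr", "wt_fdr", "min_change", "r_min",
                          "weight_min", "ev_min", "r2_min", "r2_qc")],
    counts = list(
      samples_kept = length(qc$kept),
      samples_removed = length(qc$removed),
      phenotypes_tested = nrow(conv),
      convergent = sum(conv$label == "convergent"),
      divergent = sum(conv$label == "divergent"),
      convergent_growth_correlated = sum(growth_phen$significant &
                                           growth_phen$convergent),
      wt_discriminating_imodulons = sum(wt_disc$selected),
      dima_wt_ep_significant = sum(dimas$wt_ep$significant),
      growth_correlated_imodulons = sum(gc_im$selected),
      tradeoff_pairs = nrow(tro),
      mutation_correlates_flux = sum(mc$significant & mc$target_kind == "flux"),
      mutation_correlates_imodulon = sum(mc$significant &
                                           mc$target_kind == "imodulon")
    )
  )
  jsonlite::write_json(summary_obj, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c("ALE multi-omics pipeline summary", "",
           paste0("seed: ", config$seed),
           paste0(names(summary_obj$counts), ": ",
                  unlist(summary_obj$counts)))
  writeLines(txt, file.path(out, "summary.txt"))
  writeLines(log_lines, file.path(out, "pipeline.log"))
  invisible(list(dataset = ds, qc = qc, activities = A, convergence = conv,
                 growth_phenotypes = growth_phen, null = null, dima = dimas,
                 wt_discriminating = wt_disc,
                 growth_imodulons = gc_im, tradeoffs = tro,
                 mutation_correlates = mc, summary = summary_obj))
}
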