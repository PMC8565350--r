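#' Run the full simulate / segment / colocalize / gel / stats pipeline
#'
#' Drives every stage from one declarative configuration (YAML file or
#' list): synthetic imaging conditions are rendered and written to TIFF
#' with a manifest, loaded back, thresholded and scored; a synthetic gel is
#' rendered, measured and converted to bound fractions; condition-level
#' statistics are computed; and a checksummed report of every artifact is
#' returned. Each stage draws its seed deterministically from the master
#' seed and the stage name, so a full run is a pure function of the
#' configuration.
#'
#' Configuration schema (all blocks optional except `out_dir`):
#' \preformatted{
#' seed: 1
#' out_dir: runs/demo
#' stages: [simulate, coloc, gel, stats]   # default: all
#' imaging:
#'   conditions:
#'     - condition_id: rho_1
#'       enrichment_rho: 1.0
#'       n_images: 4
#'       ...any imaging_scenario() argument...
#' gel:
#'   bound_fraction_true: 0.5
#'   ...any gel_scenario() argument...
#' }
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @param seed Optional master seed overriding `config$seed`.
#' @return A list of class `run_report`: `config_hash`, `artifacts`
#'   (tibble of path + md5 checksum), `results` (per-image colocalization),
#'   `gel` (bound-fraction table), `stats`, and the path of the run log.
#' @export
run_pipeline <- function(config, seed = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    abort("`config` must be a YAML path or a list.")
  }
  cfg <- validate_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)

  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img_dir <- file.path(out_dir, "images")
  log_path <- file.path(out_dir, "run_log.txt")
  cat("", file = log_path)
  log_stage <- function(stage, t0) {
    cat(sprintf("%s\telapsed %.3fs\n", stage,
                as.numeric(Sys.time()) - t0), file = log_path, append = TRUE)
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  # hash the scientific content only, so the same analysis written to a
  # different directory keeps the same identity
  hash_cfg <- cfg
  hash_cfg$out_dir <- NULL
  hash_path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hash_cfg, hash_path)
  config_hash <- unname(tools::md5sum(hash_path))
  unlink(hash_path)

  artifacts <- c(config = cfg_path)
  results <- NULL
  gel_tbl <- NULL
  stats_tbl <- NULL

  run_simulate <- "simulate" %in% cfg$stages && !is.null(cfg$imaging)
  run_coloc <- "coloc" %in% cfg$stages && !is.null(cfg$imaging)
  run_gel <- "gel" %in% cfg$stages && !is.null(cfg$gel)
  run_stats <- "stats" %in% cfg$stages

  manifest_path <- file.path(out_dir, "manifest.csv")
  if (run_simulate) {
    t0 <- as.numeric(Sys.time())
    rows <- purrr::map(cfg$imaging$conditions, function(cc) {
      args <- cc
      args$seed <- derive_seed(cfg$seed, paste0("imaging_", cc$condition_id))
      sc <- do.call(imaging_scenario, args)
      sim <- simulate_imaging_condition(sc)
      write_condition_tiff(sim$condition, img_dir, truth = sim$truth)
    })
    manifest <- dplyr::bind_rows(rows)
    write_manifest(manifest, manifest_path)
    artifacts <- c(artifacts, manifest = manifest_path,
                   stats::setNames(manifest$path,
                                   paste0("tiff_", manifest$condition_id)))
    log_stage("simulate", t0)
  }

  if (run_coloc) {
    t0 <- as.numeric(Sys.time())
    if (!file.exists(manifest_path)) {
      abort("coloc stage needs a manifest; run the simulate stage first.")
    }
    manifest <- read_manifest(manifest_path)
    results <- purrr::map(manifest$condition_id, function(id) {
      coloc_condition(load_condition(manifest, id))
    }) |>
      dplyr::bind_rows()
    detail_path <- file.path(out_dir, "results.csv")
    summary_path <- file.path(out_dir, "results_summary.csv")
    write_coloc_results(results, detail_path, summary_path)
    artifacts <- c(artifacts, results = detail_path,
                   results_summary = summary_path)
    log_stage("coloc", t0)
  }

  if (run_gel) {
    t0 <- as.numeric(Sys.time())
    args <- cfg$gel
    args$seed <- derive_seed(cfg$seed, "gel")
    gs <- do.call(gel_scenario, args)
    sim <- simulate_gel_image(gs)
    gel_path <- file.path(out_dir, "gel.tif")
    lanes_path <- file.path(out_dir, "gel_lanes.csv")
    write_gel_tiff(sim$image, gel_path)
    write.csv(sim$lanes, lanes_path, row.names = FALSE)
    meas <- measure_gel(read_gel_image(gel_path), sim$lanes)
    gel_tbl <- bound_fraction_table(meas)
    gel_results_path <- file.path(out_dir, "gel_results.csv")
    write.csv(gel_tbl, gel_results_path, row.names = FALSE)
    artifacts <- c(artifacts, gel_image = gel_path, gel_lanes = lanes_path,
                   gel_results = gel_results_path)
    log_stage("gel", t0)
  }

  if (run_stats) {
    t0 <- as.numeric(Sys.time())
    pieces <- list()
    if (!is.null(results)) {
      pooled <- pooled_summary(results)
      pieces$pooled <- tibble(
        analysis = "pooled_C_R", term = "mean",
        estimate = pooled$mean, sd = pooled$sd, n = pooled$n,
        p_value = NA_real_, decision = NA_character_
      )
      vv <- suppressWarnings(as.numeric(results$variable_value))
      if (length(unique(vv[!is.na(vv)])) >= 3) {
        tr <- trend_test(vv, results$C_R, variable = results$variable_name[1])
        pieces$trend <- tibble(
          analysis = "trend_C_R", term = tr$variable,
          estimate = tr$slope, sd = NA_real_, n = tr$n,
          p_value = NA_real_, decision = tr$decision
        )
      }
      counts <- table(results$condition_id)
      if (length(counts) >= 2 && all(counts >= 3)) {
        pw <- pairwise_rank_sum(results, "condition_id", "C_R")
        pieces$pairwise <- tibble(
          analysis = "rank_sum",
          term = paste(pw$group_a, "vs", pw$group_b),
          estimate = pw$mean_difference, sd = NA_real_,
          n = NA_integer_, p_value = pw$p_value, decision = NA_character_
        )
      }
    }
    if (!is.null(gel_tbl)) {
      gsum <- summarize_bound_fraction(gel_tbl)
      pieces$gel <- tibble(
        analysis = "bound_fraction", term = gsum$pair,
        estimate = gsum$mean_T_pct, sd = gsum$sd_T_pct,
        n = gsum$n_gels, p_value = NA_real_, decision = NA_character_
      )
    }
    stats_tbl <- dplyr::bind_rows(pieces)
    if (nrow(stats_tbl) > 0) {
      stats_path <- file.path(out_dir, "stats.csv")
      write.csv(stats_tbl, stats_path, row.names = FALSE)
      artifacts <- c(artifacts, stats = stats_path)
    }
    log_stage("stats", t0)
  }

  report <- list(
    config_hash = config_hash,
    artifacts = tibble(
      artifact = names(artifacts),
      path = unname(artifacts),
      md5 = unname(tools::md5sum(unname(artifacts)))
    ),
    results = results, gel = gel_tbl, stats = stats_tbl,
    log = log_path
  )
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> config", substr(x$config_hash, 1, 8), "\n")
  cat(sprintf("  %d artifact(s):\n", nrow(x$artifacts)))
  for (i in seq_len(nrow(x$artifacts))) {
    cat(sprintf("  - %s  %s\n", substr(x$artifacts$md5[i], 1, 8),
                x$artifacts$path[i]))
  }
  invisible(x)
}

# Structural validation; fails before any stage touches the filesystem.
validate_config <- function(cfg) {
  if (is.null(cfg$out_dir) || !is.character(cfg$out_dir)) {
    abort("config must name an `out_dir`.")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$stages <- cfg$stages %||% c("simulate", "coloc", "gel", "stats")
  bad <- setdiff(cfg$stages, c("simulate", "coloc", "gel", "stats"))
  if (length(bad) > 0) {
    abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  }
  if (!is.null(cfg$imaging)) {
    if (is.null(cfg$imaging$conditions) ||
        !is.list(cfg$imaging$conditions) ||
        length(cfg$imaging$conditions) == 0) {
      abort("`imaging` block needs a non-empty `conditions` list.")
    }
    ids <- vapply(cfg$imaging$conditions,
                  function(cc) cc$condition_id %||% NA_character_, "")
    if (anyNA(ids) || anyDuplicated(ids) > 0) {
      abort("every imaging condition needs a unique `condition_id`.")
    }
    known <- names(formals(imaging_scenario))
    for (cc in cfg$imaging$conditions) {
      extra <- setdiff(names(cc), c(known, "seed"))
      if (length(extra) > 0) {
        abort(paste0("unknown imaging field(s) in '", cc$condition_id,
                     "': ", paste(extra, collapse = ", ")))
      }
    }
  }
  if (!is.null(cfg$gel)) {
    extra <- setdiff(names(cfg$gel), names(formals(gel_scenario)))
    if (length(extra) > 0) {
      abort(paste("unknown gel field(s):", paste(extra, collapse = ", ")))
    }
  }
  cfg
}
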