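#' End-to-end pipeline orchestration
#'
#' Chains the stages phantom -> process -> segment -> cluster (-> density)
#' from a single configuration, with seeding, per-stage parameter records,
#' output checksums and a machine-readable run report. Two runs with the
#' same configuration and seed produce byte-identical cell tables and
#' cluster labels.
#'
#' @name pipeline
NULL

#' Build a run configuration
#'
#' @param output_dir directory for all stage outputs.
#' @param input_dir experiment directory (required when the phantom stage is
#'   disabled).
#' @param stages character vector of enabled stages, in order, from
#'   `c("phantom", "process", "segment", "cluster", "density")`.
#' @param seed global RNG seed recorded in every output's provenance.
#' @param phantom list of [phantom_config()] arguments (phantom stage).
#' @param blank_cycles blank cycles handed to the phantom channel map.
#' @param process list: `refine_stitch`, `subtract`, `deconvolve_sigma`.
#' @param segment list of [seg_params()] arguments plus `membrane_channel`.
#' @param cluster list: `K`, `exclude`, `cofactor`.
#' @param density list: `window`, `n_windows`.
#' @param cells_csv pre-existing cell table (allows `cluster` without
#'   `segment`).
#' @return validated `run_config` list.
#' @export
run_config <- function(output_dir, input_dir = NULL,
                       stages = c("phantom", "process", "segment", "cluster"),
                       seed = 1L, phantom = list(), blank_cycles = integer(0),
                       process = list(), segment = list(), cluster = list(),
                       density = list(), cells_csv = NULL) {
  known <- c("phantom", "process", "segment", "cluster", "density")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg <- structure(list(output_dir = output_dir, input_dir = input_dir,
                        stages = stages, seed = as.integer(seed),
                        phantom = phantom, blank_cycles = blank_cycles,
                        process = process, segment = segment,
                        cluster = cluster, density = density,
                        cells_csv = cells_csv), class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  st <- cfg$stages
  if ("process" %in% st && !"phantom" %in% st && is.null(cfg$input_dir))
    stop("process stage needs an input_dir when no phantom stage is enabled")
  if ("segment" %in% st && !"process" %in% st)
    stop("segment stage needs the process stage")
  if ("cluster" %in% st && !"segment" %in% st && is.null(cfg$cells_csv))
    stop("cluster stage needs a segment stage or a cells_csv path")
  if ("density" %in% st && !"cluster" %in% st)
    stop("density stage needs the cluster stage")
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML run-configuration file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML has no matrix/data.frame literals; coerce the phantom blocks
  if (!is.null(y$phantom$drift))
    y$phantom$drift <- do.call(rbind, lapply(y$phantom$drift, unlist))
  if (!is.null(y$phantom$cell_types))
    y$phantom$cell_types <- as.data.frame(
      lapply(y$phantom$cell_types, unlist), stringsAsFactors = FALSE)
  do.call(run_config, y)
}

#' Run the pipeline
#'
#' Executes the enabled stages in order; each stage consumes the previous
#' stage's outputs. A machine-readable report (stage parameters, output
#' files, md5 checksums, durations, seed) is written to
#' `<output_dir>/run_report.json` and returned. A stage failure halts the
#' run; the report up to that point is still written.
#'
#' @param config a [run_config()].
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list(),
                 config_hash = config_hash(config))
  out <- function(...) file.path(config$output_dir, ...)
  state <- new.env()
  write_report <- function() {
    jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
  }
  on.exit(write_report())
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res),
                                     seconds = elapsed)
      write_report()
      stop("stage '", name, "' failed: ", conditionMessage(res))
    }
    files <- res$files %||% character(0)
    report$stages[[name]] <<- list(
      status = "ok", seconds = elapsed, params = res$params %||% list(),
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(files)), basename(files))))
    res
  }

  if ("phantom" %in% config$stages) {
    run_stage("phantom", function() {
      pc <- do.call(phantom_config,
                    utils::modifyList(list(seed = config$seed), config$phantom))
      ph <- generate_tissue_phantom(pc, blank_cycles = config$blank_cycles)
      raw_dir <- out("raw")
      write_phantom(ph, raw_dir)
      state$input_dir <- raw_dir
      state$truth <- ph$truth
      list(params = list(seed = config$seed, n_cells = pc$n_cells,
                         n_cycles = pc$n_cycles),
           files = list.files(raw_dir, full.names = TRUE))
    })
  } else {
    state$input_dir <- config$input_dir
  }

  if ("process" %in% config$stages) {
    run_stage("process", function() {
      stack <- read_experiment(state$input_dir)
      p <- config$process
      pr <- process_stack(stack,
                          refine_stitch = isTRUE(p$refine_stitch),
                          subtract = p$subtract %||% TRUE,
                          deconvolve_sigma = p$deconvolve_sigma %||% 0)
      state$mosaic <- pr$mosaic
      drift_csv <- out("drift.csv")
      utils::write.csv(pr$drift, drift_csv, row.names = FALSE)
      mosaic_tif <- out("mosaic.tif")
      pages <- lapply(seq_len(dim(pr$mosaic)[3]), function(k)
        pmin(pmax(pr$mosaic[, , k], 0), 65535) / 65535)
      tiff::writeTIFF(pages, mosaic_tif, bits.per.sample = 16L)
      prov <- out("provenance.json")
      jsonlite::write_json(list(seed = config$seed,
                                provenance = attr(pr$mosaic, "provenance")),
                           prov, auto_unbox = TRUE)
      list(params = p, files = c(drift_csv, mosaic_tif, prov))
    })
  }

  if ("segment" %in% config$stages) {
    run_stage("segment", function() {
      s <- config$segment
      membrane_channel <- s$membrane_channel
      s$membrane_channel <- NULL
      sp <- do.call(seg_params, s)
      membrane <- if (!is.null(membrane_channel) &&
                      membrane_channel %in% dimnames(state$mosaic)[[3]])
        state$mosaic[, , membrane_channel]
      labels <- segment_cells(state$mosaic[, , "nuclear"], membrane, sp)
      tb <- quantify_cells(labels, state$mosaic)
      state$cells <- tb
      cells_csv <- out("cells.csv")
      write_cell_table(tb, cells_csv)
      cells_fcs <- out("cells.fcs")
      write_cell_table(tb, cells_fcs)
      list(params = c(sp, list(membrane_channel = membrane_channel)),
           files = c(cells_csv, cells_fcs))
    })
  } else if (!is.null(config$cells_csv)) {
    tb <- read_cell_table(config$cells_csv)
    attr(tb, "markers") <- setdiff(
      names(tb)[vapply(tb, is.numeric, logical(1))],
      c("id", "tile", "x_px", "y_px", "x_mm", "y_mm", "area", "cluster",
        "nuclear"))
    state$cells <- tb
  }

  if ("cluster" %in% config$stages) {
    run_stage("cluster", function() {
      cl <- config$cluster
      feats <- prepare_features(state$cells,
                                exclude = cl$exclude %||% character(0),
                                cofactor = cl$cofactor %||% 5)
      K <- cl$K %||% 30L
      res <- xshift_cluster(feats, K)
      state$cells$cluster <- res$labels
      state$clusters <- res
      clusters_csv <- out("clusters.csv")
      write_cell_table(state$cells, clusters_csv)
      prof_csv <- out("cluster_profiles.csv")
      utils::write.csv(profile_clusters(res, state$cells), prof_csv,
                       row.names = FALSE)
      list(params = list(K = K, n_clusters = res$n_clusters),
           files = c(clusters_csv, prof_csv))
    })
  }

  if ("density" %in% config$stages) {
    run_stage("density", function() {
      d <- config$density
      counts <- sample_density(state$cells, dim(state$mosaic)[1:2],
                               window = d$window %||% 100L,
                               n_windows = d$n_windows %||% 500L,
                               seed = config$seed)
      dc <- density_correlation(counts)
      rho_csv <- out("rho.csv")
      utils::write.csv(dc$rho, rho_csv)
      list(params = d, files = rho_csv)
    })
  }

  write_report()
  invisible(report)
}

# stable hash of the configuration (md5 of its serialized YAML)
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}
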