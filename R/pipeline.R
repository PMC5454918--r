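#' Pipeline configuration and end-to-end execution
#'
#' A pipeline configuration (YAML file or R list) names the stages to run
#' and their per-module parameter blocks. Stages execute in dependency
#' order: `simulate` and/or `localize` produce localization tables,
#' `cluster` consumes the ALU channel, `shells` profiles the
#' heterochromatin channel around the cluster centres, `dose` fits the
#' dose-response model; `probe` is independent. Every run writes its
#' intermediates plus a JSON manifest (tool version, config hash, input
#' digests, per-stage record counts) to the output directory.
#'
#' @name pipeline
NULL

pipeline_keys <- c("seed", "out_dir", "stages", "simulate", "localize",
                   "cluster", "shells", "dose", "probe")
pipeline_stages <- c("simulate", "localize", "cluster", "shells", "dose",
                     "probe")

#' Load and validate a pipeline configuration
#'
#' Unknown top-level keys and unknown stages are rejected; stage
#' dependencies are checked before anything runs (e.g. `shells` requires a
#' cluster source, `cluster` a localization source).
#'
#' @param config path to a YAML file, or a named list.
#' @return the validated configuration list.
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    cl_assert(file.exists(config), "no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  cl_assert(is.list(config), "config must be a list or a YAML path")
  unknown <- setdiff(names(config), pipeline_keys)
  cl_assert(length(unknown) == 0L,
            "unknown config key(s): ", paste(unknown, collapse = ", "))
  stages <- config$stages
  cl_assert(length(stages) > 0, "config must name at least one stage")
  bad <- setdiff(unlist(stages), pipeline_stages)
  cl_assert(length(bad) == 0L, "unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- unlist(stages)
  has_points <- any(c("simulate", "localize") %in% stages) ||
    !is.null(config$cluster$points)
  if ("cluster" %in% stages) {
    cl_assert(has_points,
              "stage 'cluster' needs a localization source: ",
              "a simulate/localize stage or cluster$points")
  }
  if ("shells" %in% stages) {
    cl_assert("cluster" %in% stages || !is.null(config$shells$clusters),
              "stage 'shells' needs clusters: add stage 'cluster' or shells$clusters")
    cl_assert(has_points || !is.null(config$shells$targets),
              "stage 'shells' needs target points")
  }
  if ("localize" %in% stages) {
    cl_assert(!is.null(config$localize$stack),
              "stage 'localize' needs localize$stack (a TIFF path)")
  }
  config$stages <- stages
  config
}

take_args <- function(block, fn) {
  block <- block %||% list()
  block[intersect(names(block), names(formals(fn)))]
}

#' Run the analysis pipeline
#'
#' @param config configuration (path or list), see
#'   [load_pipeline_config()].
#' @return the run manifest (also written to `out_dir/manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  config <- load_pipeline_config(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  manifest <- list(tool = "comboloc",
                   version = as.character(utils::packageVersion("comboloc")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed, stages = list(), inputs = list())
  cfg_file <- file.path(out_dir, "config.used.yaml")
  yaml::write_yaml(config, cfg_file)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))

  points <- NULL
  clusters <- NULL
  for (stage in config$stages) {
    if (stage == "simulate") {
      args <- take_args(config$simulate, nucleus_model)
      if (is.null(args$seed)) args$seed <- seed
      nuc <- generate_nucleus(do.call(nucleus_model, args))
      points <- nuc$points
      f <- file.path(out_dir, "simulated_points.tsv")
      write_localization_table(points, f)
      manifest$stages$simulate <- list(records = nrow(points), output = f)
    } else if (stage == "localize") {
      stack <- read_stack(config$localize$stack)
      manifest$inputs[[config$localize$stack]] <-
        unname(tools::md5sum(config$localize$stack))
      args <- take_args(config$localize, localize_stack)
      args$stack <- stack
      args$channel <- config$localize$channel %||% "ch0"
      args$pixel_size_nm <- config$localize$pixel_size_nm %||% 100
      points <- do.call(localize_stack, args)
      f <- file.path(out_dir, "localizations.tsv")
      write_localization_table(points, f)
      manifest$stages$localize <- list(records = nrow(points), output = f)
    } else if (stage == "cluster") {
      if (!is.null(config$cluster$points)) {
        points <- read_localization_table(config$cluster$points)
        manifest$inputs[[config$cluster$points]] <-
          unname(tools::md5sum(config$cluster$points))
      }
      ch <- config$cluster$channel %||% "alu"
      sel <- points[points$channel == ch, , drop = FALSE]
      res <- find_clusters(sel,
                           radius_nm = config$cluster$radius_nm %||% 100,
                           min_points = config$cluster$min_points %||% 10L)
      clusters <- res$clusters
      f <- file.path(out_dir, "clusters.csv")
      write_cluster_table(clusters, f)
      manifest$stages$cluster <- list(records = nrow(clusters), output = f)
    } else if (stage == "shells") {
      if (!is.null(config$shells$clusters)) {
        cdf <- utils::read.csv(config$shells$clusters)
        clusters <- tibble::as_tibble(cdf)
      }
      targets <- points
      if (!is.null(config$shells$targets)) {
        targets <- read_localization_table(config$shells$targets)
      }
      ch <- config$shells$channel %||% "het"
      targets <- targets[targets$channel == ch, , drop = FALSE]
      prof <- mean_shell_profile(
        clusters, targets,
        shell_width_nm = config$shells$shell_width_nm %||% 10,
        max_radius_nm = config$shells$max_radius_nm %||% 1000)
      f <- file.path(out_dir, "shell_profile.csv")
      write_shell_profile(prof, f)
      manifest$stages$shells <- list(records = nrow(prof), output = f)
    } else if (stage == "dose") {
      if (!is.null(config$dose$counts)) {
        counts <- tibble::as_tibble(utils::read.csv(config$dose$counts))
        manifest$inputs[[config$dose$counts]] <-
          unname(tools::md5sum(config$dose$counts))
      } else {
        args <- take_args(config$dose, generate_dose_series)
        if (is.null(args$seed)) args$seed <- seed
        counts <- do.call(generate_dose_series, args)
      }
      fit <- fit_dose_response(counts)
      f <- file.path(out_dir, "dose_fit.json")
      jsonlite::write_json(list(a = fit$a, b = fit$b, c = fit$c,
                                rss = fit$rss, doses = fit$doses,
                                n_per_dose = fit$n_per_dose),
                           f, auto_unbox = TRUE, digits = NA)
      manifest$stages$dose <- list(records = nrow(counts), output = f)
    } else if (stage == "probe") {
      genome <- read_fasta(config$probe$genome)
      manifest$inputs[[config$probe$genome]] <-
        unname(tools::md5sum(config$probe$genome))
      probe <- config$probe$sequence %||% alu_probe()
      hits <- scan_kmer(genome, probe,
                        strand_policy = config$probe$strand %||% "both")
      f <- file.path(out_dir, "probe_hits.bed")
      write_hits_bed(hits, f)
      manifest$stages$probe <- list(records = nrow(hits), output = f)
    }
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
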