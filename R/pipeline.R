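# End-to-end orchestration: simulate -> resolve indexing modes -> relative
# scaling -> dose-decay analysis -> merging statistics -> report.

log_stage <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

#' Run the full dose-decay analysis pipeline
#'
#' Stages: (1) simulate the multi-crystal experiment; (2) resolve the
#' two-state indexing ambiguity by correlation maximization; (3) per
#' crystal, split frames into quality wedges, compute per-wedge summary
#' statistics, fit relative K/B scales against the first wedge, and fit
#' the exponential decay model to the normalized mean intensities;
#' (4) summarize the cohort; (5) merge wedges across crystals (merging
#' wedge size) and compute merging statistics.
#'
#' @param config \code{run_config} from \code{\link{default_config}}.
#' @param seed master seed; a rerun with the same seed reproduces the
#'   report exactly.
#' @param out_dir optional output directory: reflection files, CSV tables
#'   and a JSON report are written there.
#' @return object of class \code{dose_report}: list with \code{modes},
#'   \code{subset_stats} (per crystal x wedge data.frame, including K and
#'   relative B), \code{decay_fits}, \code{fit_table}, \code{cohort},
#'   \code{merging} (per merge-wedge statistics), \code{manifest},
#'   \code{seed}.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  group <- point_group_ops(config$point_group)
  op <- reindex_operator(group = group)

  log_stage("simulate: %d crystals x %d frames", nrow(config$crystals),
            config$n_frames)
  sim <- simulate_experiment(config, seed = seed)

  log_stage("resolve: indexing-ambiguity resolution")
  partials <- lapply(sim$crystals, function(cr) {
    merge_partial(cr$observations, group, crystal_id = cr$crystal_id)
  })
  assignment <- resolve_modes(partials, op = op, group = group,
                              min_common = config$min_common)
  resolved <- apply_modes(sim$crystals, assignment, op = op)

  log_stage("analyze: wedge statistics, scaling and decay fits")
  sched_q <- dose_schedule(config$dose_per_frame, config$subset_size_quality)
  stats_rows <- list()
  fits <- list()
  for (cid in names(resolved)) {
    obs <- resolved[[cid]]
    wedges <- split_subsets(obs, sched_q, n_frames = config$n_frames)
    first_stats <- subset_summary(wedges[[1L]], config$cell_a,
                                  shell = config$shell)
    ref_mp <- merge_partial(wedges[[1L]], group, crystal_id = cid)
    per_wedge <- lapply(seq_along(wedges), function(i) {
      w <- wedges[[i]]
      ss <- subset_summary(w, config$cell_a, shell = config$shell,
                           first = if (i == 1L) NULL else first_stats)
      sf <- if (i == 1L) {
        list(K = 1, B = 0, n_common = nrow(ref_mp))
      } else {
        fit_relative_scale(merge_partial(w, group, crystal_id = cid),
                           ref_mp, config$cell_a)
      }
      data.frame(crystal_id = cid, subset_index = ss$subset_index,
                 dose = ss$dose, n_obs = ss$n_obs,
                 mean_intensity = ss$mean_intensity,
                 mean_intensity_norm = ss$mean_intensity_norm,
                 shell_i_over_sigma = ss$shell_i_over_sigma,
                 shell_i_over_sigma_norm = ss$shell_i_over_sigma_norm,
                 K = sf$K, B = sf$B, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, per_wedge)
    stats_rows[[cid]] <- tab
    fits[[cid]] <- fit_decay(tab$dose, tab$mean_intensity_norm)
  }
  subset_stats <- do.call(rbind, stats_rows)
  rownames(subset_stats) <- NULL

  cohort <- summarize_cohort(fits, cryo_half_dose = config$cryo_half_dose)

  log_stage("stats: cross-crystal merging statistics")
  sched_m <- dose_schedule(config$dose_per_frame, config$subset_size_merge)
  n_merge <- config$n_frames %/% config$subset_size_merge
  merging <- do.call(rbind, lapply(seq_len(n_merge), function(i) {
    pooled <- do.call(rbind, lapply(resolved, function(obs) {
      obs[obs$frame > (i - 1L) * config$subset_size_merge &
            obs$frame <= i * config$subset_size_merge, , drop = FALSE]
    }))
    cbind(data.frame(subset_index = i, dose = subset_dose(i, sched_m)),
          merging_statistics(pooled, config$cell_a, group,
                             d_min = config$d_min, d_max = config$d_max,
                             seed = seed))
  }))

  fit_table <- do.call(rbind, lapply(names(fits), function(cid) {
    f <- fits[[cid]]
    data.frame(crystal_id = cid, I0 = f$I0, I0_se = f$I0_se, I1 = f$I1,
               I1_se = f$I1_se, beta = f$beta, beta_se = f$beta_se,
               d_star = f$d_star, d_half = f$d_half,
               undamaged_fraction = f$undamaged_fraction,
               stringsAsFactors = FALSE)
  }))

  report <- structure(list(
    modes = assignment, subset_stats = subset_stats, decay_fits = fits,
    fit_table = fit_table, cohort = cohort, merging = merging,
    manifest = sim$manifest, config = config, seed = as.integer(seed)),
    class = "dose_report")

  if (!is.null(out_dir)) write_report(report, sim, out_dir)
  report
}

#' Write pipeline outputs to a directory
#'
#' Writes per-crystal reflection files, the manifest, CSV tables (wedge
#' statistics, fit parameters, merging statistics) and one JSON report.
#'
#' @param report \code{dose_report}.
#' @param sim the \code{sim_experiment} the report was computed from
#'   (for reflection files); may be NULL to skip them.
#' @param out_dir output directory, created if missing.
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(report, sim = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  if (!is.null(sim)) {
    for (cr in sim$crystals) {
      write_reflections(cr$observations,
                        file.path(out_dir, paste0(cr$crystal_id, ".hkl")),
                        cell_a = cfg$cell_a, point_group = cfg$point_group,
                        dose_per_frame = cfg$dose_per_frame)
    }
    utils::write.csv(sim$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report$subset_stats,
                   file.path(out_dir, "subset_stats.csv"), row.names = FALSE)
  utils::write.csv(report$fit_table,
                   file.path(out_dir, "decay_fits.csv"), row.names = FALSE)
  utils::write.csv(report$merging,
                   file.path(out_dir, "merging_stats.csv"), row.names = FALSE)
  json <- list(
    seed = report$seed,
    modes = as.list(report$modes$modes),
    fit_table = report$fit_table,
    cohort = unclass(report$cohort),
    merging = report$merging
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' @export
print.dose_report <- function(x, ...) {
  cat("dose-decay analysis report (seed ", x$seed, ")\n\n", sep = "")
  print(x$modes)
  cat("\nper-crystal decay fits:\n")
  print(x$fit_table, digits = 4)
  cat("\n")
  print(x$cohort)
  invisible(x)
}

#' Read a run configuration from a JSON file
#'
#' Fields mirror \code{\link{default_config}}; \code{crystals} may be given
#' as a data.frame-like array of records with columns crystal, i0, i1,
#' beta. Missing fields take the defaults.
#'
#' @param path JSON file path.
#' @return \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$crystals)) raw$crystals <- as.data.frame(raw$crystals)
  if (!is.null(raw$shell)) raw$shell <- as.numeric(raw$shell)
  do.call(default_config, raw)
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate} (write reflection files and manifest),
#' \code{resolve} (indexing-mode report), \code{analyze} (scaling, decay
#' fits and cohort summary), \code{stats} (merging statistics), \code{run}
#' (everything). All subcommands execute the pipeline deterministically
#' from the seed and write the requested outputs under \code{--out}.
#'
#' @param args character vector of command-line arguments; defaults to
#'   \code{commandArgs(trailingOnly = TRUE)}.
#' @return exit status, invisibly (0 on success).
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("simulate", "resolve", "analyze", "stats", "run")
  if (!length(args) || !(args[1L] %in% cmds)) {
    message("usage: dosewedge <", paste(cmds, collapse = "|"),
            "> [--config PATH] [--seed INT] [--out DIR] ",
            "[--subset-size INT] [--dose-per-frame FLOAT]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "dosewedge_out"),
    optparse::make_option("--subset-size", type = "integer", default = NULL,
                          dest = "subset_size"),
    optparse::make_option("--dose-per-frame", type = "double", default = NULL,
                          dest = "dose_per_frame")
  ))
  opt <- optparse::parse_args(parser, args = args[-1L])
  config <- if (is.null(opt$config)) default_config() else
    read_run_config(opt$config)
  if (!is.null(opt$subset_size)) {
    config$subset_size_quality <- as.integer(opt$subset_size)
  }
  if (!is.null(opt$dose_per_frame)) {
    config$dose_per_frame <- opt$dose_per_frame
  }
  t0 <- Sys.time()
  status <- tryCatch({
    if (cmd == "simulate") {
      sim <- simulate_experiment(config, seed = opt$seed)
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      for (cr in sim$crystals) {
        write_reflections(cr$observations,
                          file.path(opt$out, paste0(cr$crystal_id, ".hkl")),
                          cell_a = config$cell_a,
                          point_group = config$point_group,
                          dose_per_frame = config$dose_per_frame)
      }
      utils::write.csv(sim$manifest, file.path(opt$out, "manifest.csv"),
                       row.names = FALSE)
    } else {
      report <- run_pipeline(config, seed = opt$seed, out_dir = opt$out)
      if (cmd == "resolve") print(report$modes)
      if (cmd == "analyze") {
        print(report$fit_table, digits = 4)
        print(report$cohort)
      }
      if (cmd == "stats") print(report$merging, digits = 4)
      if (cmd == "run") print(report)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  log_stage("%s finished in %.1f s (status %d)", cmd,
            as.numeric(difftime(Sys.time(), t0, units = "secs")), status)
  invisible(status)
}
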