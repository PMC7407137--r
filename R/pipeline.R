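stage_seed <- function(root_seed, stage) {
  # deterministic per-stage split of the root seed, kept inside 32-bit range
  offsets <- c(simulate = 101L, count = 211L, fit = 307L, diagnose = 401L)
  (as.integer(root_seed) + offsets[[stage]] * 9973L) %% 2147483647L
}

default_pipeline_config <- function() {
  list(
    out_dir = "permflow_run",
    seed = 1L,
    window_ps = 10,
    stages = c("simulate", "count", "fit", "diagnose"),
    simulate = list(kind = "trajectory",    # "trajectory" or "counts"
                    n_molecules = 100L, n_frames = 1000L, n_events = 40L,
                    frame_ps = 10, box_z = 80,
                    z_lower = -18, z_upper = 18,
                    # used when kind == "counts"
                    n_windows = 1000L, rho = 0.9, sigma = 0.5, nu = 4,
                    phi = 0.5, lambda1 = log(0.1)),
    count = list(traj = NULL, slab = "infer",
                 z_lower = NULL, z_upper = NULL, box_z = NULL),
    fit = list(counts = NULL, chains = 4L, draws = 2000L, warmup = 1000L,
               target_accept = 0.9, max_treedepth = 10L,
               on_fail = "error"),
    diagnose = list(counts = NULL, tail_threshold_quantile = 0.99,
                    use_fit = TRUE))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Build a pipeline configuration
#'
#' Merges user overrides into the default configuration for
#' [run_pipeline()]. Pass a nested list mirroring the stage structure, or a
#' path to a JSON/YAML file.
#'
#' @param config nested list of overrides, or a JSON/YAML file path.
#' @return A complete configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs require the yaml package", call. = FALSE)
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  structure(merge_config(default_pipeline_config(), config),
            class = "pipeline_config")
}

#' Run the simulate / count / fit / diagnose pipeline
#'
#' Executes the requested stages in order, each stage's file output feeding
#' the next: `simulate` writes either a kinematic trajectory TSV or a
#' synthetic count CSV; `count` turns a trajectory into a count series;
#' `fit` samples the latent-rate posterior and writes long-format draws
#' plus a JSON summary (including the time-averaged posterior mean flow in
#' molecules/ns); `diagnose` writes the Poisson-comparison report. Every
#' run writes `manifest.json` (config, package version, per-stage seeds,
#' outputs, wall times); a failed stage halts the pipeline with the stage
#' named, with completed outputs retained and the manifest marking the run
#' incomplete. All randomness derives from the root seed via a fixed
#' per-stage split, so a rerun from the same manifest reproduces outputs.
#'
#' @param config a [pipeline_config()], override list, or config file path.
#' @param quiet suppress per-stage messages.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package = "permflow",
                   version = as.character(packageVersion("permflow")),
                   config = unclass(cfg), seed = cfg$seed,
                   stages = list(), complete = FALSE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  save_manifest <- function()
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  paths <- list(traj = cfg$count$traj, counts = cfg$fit$counts, fit = NULL)
  fit_obj <- NULL

  for (stage in cfg$stages) {
    t0 <- Sys.time()
    sseed <- stage_seed(cfg$seed, stage)
    say("[%s] starting (seed %d)", stage, sseed)
    res <- tryCatch({
      switch(stage,
        simulate = {
          s <- cfg$simulate
          if (identical(s$kind, "counts")) {
            gc_ <- generator_config(n_windows = s$n_windows,
                                    window_ps = cfg$window_ps, rho = s$rho,
                                    sigma = s$sigma, nu = s$nu, phi = s$phi,
                                    lambda1 = s$lambda1, seed = sseed)
            y <- simulate_count_series(gc_)
            paths$counts <- file.path(cfg$out_dir, "simulated_counts.csv")
            write_counts(y, paths$counts)
            list(outputs = paths$counts)
          } else {
            sched <- random_schedule(s$n_molecules, s$n_frames, s$n_events,
                                     seed = sseed)
            slab <- membrane_slab(s$z_lower, s$z_upper)
            traj <- simulate_membrane_trajectory(sched, slab, seed = sseed,
                                                 frame_ps = s$frame_ps,
                                                 box_z = s$box_z)
            paths$traj <- file.path(cfg$out_dir, "simulated_trajectory.tsv")
            write_trajectory_tsv(traj, paths$traj,
                                 meta = list(schedule = sched$events,
                                             slab = unclass(slab)))
            list(outputs = paths$traj)
          }
        },
        count = {
          if (is.null(paths$traj) || !file.exists(paths$traj))
            stop("count stage needs a trajectory file", call. = FALSE)
          traj <- read_trajectory_tsv(paths$traj)
          cc <- cfg$count
          slab <- if (!is.null(cc$z_lower) && !is.null(cc$z_upper))
            membrane_slab(cc$z_lower, cc$z_upper)
          else {
            side <- jsonlite::read_json(paste0(paths$traj, ".json"),
                                        simplifyVector = TRUE)
            if (!is.null(side$meta$slab))
              membrane_slab(side$meta$slab$z_lower, side$meta$slab$z_upper)
            else stop("no slab bounds given and none in the trajectory ",
                      "sidecar; supply z_lower/z_upper", call. = FALSE)
          }
          y <- count_crossings(traj, slab, window_ps = cfg$window_ps)
          paths$counts <- file.path(cfg$out_dir, "counts.csv")
          write_counts(y, paths$counts)
          list(outputs = paths$counts)
        },
        fit = {
          if (is.null(paths$counts) || !file.exists(paths$counts))
            stop("fit stage needs a counts file", call. = FALSE)
          y <- read_counts(paths$counts)
          f <- cfg$fit
          fit_obj <- sample_posterior(
            y, n_chains = f$chains, n_draws = f$draws,
            n_warmup = f$warmup, seed = sseed,
            target_accept = f$target_accept,
            max_treedepth = f$max_treedepth, on_fail = f$on_fail)
          fit_dir <- file.path(cfg$out_dir, "posterior")
          dir.create(fit_dir, showWarnings = FALSE)
          draws_path <- file.path(fit_dir, "draws.csv")
          write_draws_long(fit_obj, draws_path)
          rates <- summarize_rates(fit_obj)
          qfun <- function(m) as.list(setNames(
            quantile(m, c(0.025, 0.5, 0.975)),
            c("q2.5", "median", "q97.5")))
          summ <- list(mean_flow_molecules_per_ns = rates$mean_flow,
                       rho = qfun(fit_obj$rho), sigma = qfun(fit_obj$sigma),
                       nu = qfun(fit_obj$nu), phi = qfun(fit_obj$phi),
                       diagnostics = fit_obj$diagnostics,
                       n_divergent = fit_obj$n_divergent)
          summ_path <- file.path(fit_dir, "summary.json")
          jsonlite::write_json(summ, summ_path, auto_unbox = TRUE,
                               digits = NA, pretty = TRUE,
                               dataframe = "columns")
          paths$fit <- fit_dir
          list(outputs = c(draws_path, summ_path))
        },
        diagnose = {
          if (is.null(paths$counts) || !file.exists(paths$counts))
            stop("diagnose stage needs a counts file", call. = FALSE)
          y <- read_counts(paths$counts)
          report_path <- file.path(cfg$out_dir, "report.json")
          write_diagnostics_report(
            y, report_path,
            fit = if (isTRUE(cfg$diagnose$use_fit)) fit_obj else NULL,
            tail_threshold_quantile = cfg$diagnose$tail_threshold_quantile)
          list(outputs = report_path)
        },
        stop("unknown stage: ", stage, call. = FALSE))
    }, error = function(e) e)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      manifest$stages[[stage]] <- list(status = "failed", seed = sseed,
                                       error = conditionMessage(res),
                                       wall_s = elapsed)
      save_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(res)), call. = FALSE)
    }
    manifest$stages[[stage]] <- list(status = "ok", seed = sseed,
                                     outputs = res$outputs,
                                     wall_s = elapsed)
    say("[%s] done in %.1f s", stage, elapsed)
    save_manifest()
  }
  manifest$complete <- TRUE
  save_manifest()
  invisible(manifest)
}

#' Write posterior draws in long format
#'
#' One row per (chain, draw, parameter): `rho`, `sigma`, `nu`, `phi` and
#' each `lambda[i]`.
#'
#' @param fit a `flow_fit`.
#' @param path CSV output path.
#' @param lambda_stride keep every `lambda_stride`-th window to bound file
#'   size (default 1 = all windows).
#' @return `path`, invisibly.
#' @export
write_draws_long <- function(fit, path, lambda_stride = 1L) {
  nd <- fit$n_draws
  nc <- fit$n_chains
  base <- expand.grid(draw = seq_len(nd), chain = seq_len(nc))
  blocks <- lapply(c("rho", "sigma", "nu", "phi"), function(p)
    data.frame(chain = base$chain, draw = base$draw, parameter = p,
               value = as.vector(fit[[p]])))
  keep <- seq(1L, dim(fit$lambda)[3], by = lambda_stride)
  lam_blocks <- lapply(keep, function(i)
    data.frame(chain = base$chain, draw = base$draw,
               parameter = sprintf("lambda[%d]", i),
               value = as.vector(fit$lambda[, , i])))
  out <- do.call(rbind, c(blocks, lam_blocks))
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
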