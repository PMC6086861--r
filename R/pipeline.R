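#' Pipeline run configuration
#'
#' Builds the full configuration for [run_pipeline()], starting from a
#' demonstration-scale default (two groups of 8 and 6 subjects, 64 ROIs,
#' 160 frames, 20 null graphs, 200 permutations) that completes in minutes
#' on one CPU. Every key can be overridden; unknown keys are rejected so
#' typos cannot silently fall back to defaults. Study-scale runs override
#' the `simulate`, `graph` and `stats` entries (e.g. 18 + 11 subjects, 141
#' ROIs, 246 frames, 100 nulls, 5000 permutations).
#'
#' @param ... named overrides; nested lists merge key-wise (e.g.
#'   `stats = list(n_perms = 5000)`).
#' @return a nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    stages = list(simulate = TRUE, qc = TRUE, connectivity = TRUE,
                  graph = TRUE, stats = TRUE),
    paths = list(input = NULL, output = "rsfcnet_run"),
    simulate = list(n_per_group = c(I = 8L, NI = 6L), n_frames = 160L,
                    tr_seconds = 2, roi_count = 64L, noise_sd = 0,
                    motion_spike_rate = 0.05, behavior_coupling = 0.4,
                    planted_delta = 0.15, n_runs = 2L,
                    n_discard_per_run = 5L, fc_delta_sd = 0.05),
    qc = list(fd_thresh = 0.8, dvars_thresh = 0.05, low_hz = 0.009,
              high_hz = 0.1, min_frames = 100L, head_radius_mm = 50,
              rotations = "radians", rule = "union", filter = "fft"),
    graph = list(densities = seq(0.15, 0.35, by = 0.01), n_nulls = 20L,
                 compute_sigma = TRUE, n_swaps_per_edge = 10L),
    stats = list(n_perms = 200L, alpha_fc = 0.05, alpha_nodal = 0.01,
                 covariates = c("age", "scanner"), fdr = FALSE)
  )
  merge_config(defaults, list(...), path = "")
}

merge_config <- function(base, override, path) {
  unknown <- setdiff(names(override), names(base))
  if (length(unknown))
    stopf("unknown config key(s): %s",
          paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]],
                                paste0(path, ".", k))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  if (path == "") class(base) <- "pipeline_config"
  base
}

#' @rdname pipeline_config
#' @param path YAML file of overrides (same nesting as the defaults).
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Load an input bundle from disk
#'
#' Reads the external-format bundle ([write_cohort()] layout): per-session
#' ROI TSV and six-column motion file, `design.tsv`, `partition.tsv`, and
#' `acquisition.json`. Cross-validates the bundle: signal and motion frame
#' counts must match (per subject/session), the partition must cover every
#' ROI, and the design must cover every subject; each mismatch raises a
#' distinct named error.
#'
#' @param dir bundle directory.
#' @return list: `sessions` (named `fc_timeseries` list), `design`,
#'   `partition`, `tr_seconds`, `n_runs`, `n_discard_per_run`.
#' @export
load_inputs <- function(dir) {
  need <- file.path(dir, c("design.tsv", "partition.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stopf("missing input file(s): %s", paste(miss, collapse = ", "))
  design <- utils::read.delim(file.path(dir, "design.tsv"),
                              stringsAsFactors = FALSE)
  design$group <- factor(design$group, levels = unique(design$group))
  if ("scanner" %in% names(design))
    design$scanner <- factor(design$scanner)
  partition <- read_partition(file.path(dir, "partition.tsv"))
  acq_path <- file.path(dir, "acquisition.json")
  acq <- if (file.exists(acq_path)) jsonlite::read_json(acq_path)
         else list(tr_seconds = 2, n_runs = 1L, n_discard_per_run = 5L)
  sessions <- list()
  for (i in seq_len(nrow(design))) {
    for (s in c("ses-1", "ses-2")) {
      stem <- file.path(dir, paste(gsub("\\.", "_", design$subject[i]), s,
                                   sep = "_"))
      sig_path <- paste0(stem, "_roits.tsv")
      mot_path <- paste0(stem, "_motion.txt")
      if (!file.exists(sig_path))
        stopf("design covers %s but %s is missing", design$subject[i],
              sig_path)
      ts <- read_roi_timeseries(sig_path, tr = acq$tr_seconds,
                                subject = design$subject[i], session = s,
                                motion_path = if (file.exists(mot_path))
                                  mot_path else NULL)
      validate_partition(partition, colnames(ts$signal))
      sessions[[paste(design$subject[i], s, sep = ".")]] <- ts
    }
  }
  list(sessions = sessions, design = design, partition = partition,
       tr_seconds = acq$tr_seconds, n_runs = acq$n_runs,
       n_discard_per_run = acq$n_discard_per_run)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order — simulate (or load), qc,
#' connectivity, graph, stats — writing every intermediate table in the
#' package's external formats plus a JSON run manifest (config echo, stage
#' wall-clock, output-file MD5 hashes, warnings, versions). Each stochastic
#' stage consumes a named seed derived from the master seed by a fixed
#' offset, so toggling stages does not shift downstream seeds. Subjects
#' whose sessions fall below the minimum-frame rule after scrubbing are
#' dropped listwise from the statistics stage.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_run`: `manifest`, and (as enabled)
#'   `qc`, `blocks`, `profiles`, `results`, `behavior`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$paths$output
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  manifest <- list(config = unclass(config),
                   versions = list(rsfcnet = as.character(
                     utils::packageVersion("rsfcnet")),
                     R = R.version.string),
                   stages = list(), warnings = character(),
                   behavior_sign_convention =
                     "symptom scales: improvement = score decrease",
                   qc_order = paste("discard > FD/DVARS on unfiltered >",
                                    "interpolate flagged > band-pass/detrend > censor"))
  timings <- list()
  t_stage <- function(name, code) {
    t0 <- Sys.time()
    res <- force(code)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    logf("stage %s done in %.1fs", name, timings[[name]])
    res
  }
  run <- list()

  # --- simulate / load -------------------------------------------------
  if (isTRUE(config$stages$simulate)) {
    bundle <- t_stage("simulate", {
      sim <- config$simulate
      sc <- synthetic_config(n_per_group = sim$n_per_group,
                             n_frames = sim$n_frames,
                             tr_seconds = sim$tr_seconds,
                             roi_count = sim$roi_count,
                             noise_sd = sim$noise_sd,
                             motion_spike_rate = sim$motion_spike_rate,
                             behavior_coupling = sim$behavior_coupling,
                             seed = derive_seed(config$seed, 1L),
                             n_runs = sim$n_runs,
                             n_discard_per_run = sim$n_discard_per_run,
                             fc_delta_sd = sim$fc_delta_sd)
      cohort <- simulate_cohort(sc, planted_delta = sim$planted_delta)
      write_cohort(cohort, file.path(out_dir, "input"))
      list(sessions = cohort$sessions, design = cohort$design,
           partition = cohort$partition, tr_seconds = sim$tr_seconds,
           n_runs = sim$n_runs, n_discard_per_run = sim$n_discard_per_run)
    })
  } else {
    if (is.null(config$paths$input))
      stopf("stages$simulate is off and paths$input is not set")
    bundle <- t_stage("load", load_inputs(config$paths$input))
  }

  # --- qc ---------------------------------------------------------------
  excluded <- character()
  if (isTRUE(config$stages$qc)) {
    qc_dir <- file.path(out_dir, "qc")
    dir.create(qc_dir, showWarnings = FALSE)
    qc_all <- t_stage("qc", {
      lapply(names(bundle$sessions), function(key) {
        ts <- bundle$sessions[[key]]
        ts <- discard_initial_volumes(ts, bundle$n_discard_per_run,
                                      n_runs = bundle$n_runs)
        qc <- compute_qc(ts, config$qc$fd_thresh, config$qc$dvars_thresh,
                         config$qc$head_radius_mm, config$qc$rotations)
        ts <- interpolate_censored(ts, which(!qc$keep))
        ts <- bandpass_detrend(ts, config$qc$low_hz, config$qc$high_hz,
                               method = config$qc$filter)
        res <- withCallingHandlers(
          scrub(ts, qc, config$qc$fd_thresh, config$qc$dvars_thresh,
                rule = config$qc$rule, min_frames = config$qc$min_frames),
          rsfcnet_low_frames = function(w) {
            manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        write_qc_report(res$qc, file.path(qc_dir, gsub("\\.", "_", key)))
        res
      }) -> out
      names(out) <- names(bundle$sessions)
      out
    })
    bundle$sessions <- lapply(qc_all, `[[`, "ts")
    run$qc <- lapply(qc_all, `[[`, "qc")
    excl_keys <- names(run$qc)[vapply(run$qc, `[[`, logical(1L), "exclude")]
    excluded <- unique(sub("\\..*$", "", excl_keys))
    if (length(excluded))
      logf("excluded (listwise, < min frames): %s",
           paste(excluded, collapse = ", "))
  }

  # --- connectivity ----------------------------------------------------
  if (isTRUE(config$stages$connectivity)) {
    fc_dir <- file.path(out_dir, "connectivity")
    dir.create(fc_dir, showWarnings = FALSE)
    t_stage("connectivity", {
      run$fc <- lapply(bundle$sessions, fc_matrix)
      run$blocks <- lapply(run$fc, block_summary,
                           partition = bundle$partition)
      for (key in names(run$fc)) {
        stem <- file.path(fc_dir, gsub("\\.", "_", key))
        write_fc_matrix(run$fc[[key]], paste0(stem, "_fcz.tsv"))
        write_block_table(run$blocks[[key]], paste0(stem, "_blocks.tsv"))
      }
      NULL
    })
  }

  # --- graph -----------------------------------------------------------
  if (isTRUE(config$stages$graph)) {
    g_dir <- file.path(out_dir, "graph")
    dir.create(g_dir, showWarnings = FALSE)
    if (is.null(run$fc))
      stopf("graph stage requires the connectivity stage")
    t_stage("graph", {
      keys <- names(run$fc)
      run$profiles <- stats::setNames(lapply(seq_along(keys), function(i)
        graph_metric_profile(run$fc[[keys[i]]],
                             densities = config$graph$densities,
                             n_nulls = config$graph$n_nulls,
                             compute_sigma = config$graph$compute_sigma,
                             n_swaps_per_edge = config$graph$n_swaps_per_edge,
                             seed = derive_seed(config$seed, 300L + i))),
        keys)
      for (key in keys)
        write_graph_profile(run$profiles[[key]],
                            file.path(g_dir, gsub("\\.", "_", key)))
      NULL
    })
  }

  # --- stats -----------------------------------------------------------
  if (isTRUE(config$stages$stats)) {
    t_stage("stats", {
      design <- bundle$design[!(bundle$design$subject %in% excluded), ,
                              drop = FALSE]
      per_sub <- function(tabs) {
        out <- lapply(design$subject, function(sj)
          list(tabs[[paste0(sj, ".ses-1")]], tabs[[paste0(sj, ".ses-2")]]))
        stats::setNames(out, design$subject)
      }
      res <- run_interaction_suite(
        block_tables = if (!is.null(run$blocks)) per_sub(run$blocks),
        profiles = if (!is.null(run$profiles)) per_sub(run$profiles),
        design = design,
        covariate_cols = config$stats$covariates,
        n_perms = config$stats$n_perms,
        seed = derive_seed(config$seed, 400L),
        alpha_fc = config$stats$alpha_fc,
        alpha_nodal = config$stats$alpha_nodal,
        fdr = config$stats$fdr)
      utils::write.table(res, file.path(out_dir, "interaction_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      run$results <- res
      # brain-behavior follow-up on significant connectivity blocks
      if (!is.null(run$blocks)) {
        covs <- design[config$stats$covariates]
        bb <- list()
        sig <- res[res$outcome_type == "fc_block" & res$sig_fc, , drop = FALSE]
        bt <- per_sub(run$blocks)
        for (j in seq_len(nrow(sig))) {
          ab <- strsplit(sig$outcome[j], "-", fixed = TRUE)[[1L]]
          dmet <- vapply(bt, function(s)
            s[[2L]]$mean_z[ab[1L], ab[2L]] - s[[1L]]$mean_z[ab[1L], ab[2L]],
            numeric(1L))
          for (beh in c("inattention", "internalizing")) {
            c1 <- paste0(beh, "_t1"); c2 <- paste0(beh, "_t2")
            if (!all(c(c1, c2) %in% names(design))) next
            dbe <- design[[c2]] - design[[c1]]
            r <- brain_behavior_correlation(dmet, dbe, covs,
                                            metric = sig$outcome[j],
                                            behavior = beh)
            bb[[length(bb) + 1L]] <- data.frame(
              metric = r$metric, behavior = beh, r = r$r, p = r$p,
              n = r$n, stringsAsFactors = FALSE)
          }
        }
        if (length(bb)) {
          bbt <- do.call(rbind, bb)
          utils::write.table(bbt, file.path(out_dir, "brain_behavior.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          run$behavior <- bbt
        }
      }
      NULL
    })
  }

  # --- manifest --------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in% c("run_manifest.json", "run.log")]
  manifest$stages <- timings
  manifest$excluded_subjects <- excluded
  files <- sort(files)
  manifest$output_hashes <- as.list(tools::md5sum(files))
  names(manifest$output_hashes) <-
    substring(files, nchar(out_dir) + 2L)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run$manifest <- manifest
  structure(run, class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n  stages:",
      paste(sprintf("%s (%.1fs)", names(x$manifest$stages),
                    unlist(x$manifest$stages)), collapse = ", "), "\n")
  if (!is.null(x$results)) {
    sig <- x$results[x$results$sig_fc & x$results$outcome_type == "fc_block", ]
    cat(sprintf("  %d outcomes tested; %d connectivity blocks at alpha = %g\n",
                nrow(x$results), nrow(sig),
                attr(x$results, "alpha_fc") %||% 0.05))
  }
  invisible(x)
}
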