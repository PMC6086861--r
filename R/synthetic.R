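#' Block-level functional-connectivity specification
#'
#' Target mean Fisher-z connectivity per system-pair block, optionally
#' distinct for each (group, time) cell of a two-group, two-timepoint
#' design. Diagonal cells refer to intra-system blocks (off-diagonal ROI
#' pairs within a system), never the matrix diagonal.
#'
#' Baseline magnitudes default to intra-network z = 0.3 and inter-network
#' z = 0.1; these are plausibility assumptions for resting-state cohorts,
#' not published values, and are fully configurable.
#'
#' @param systems system labels (order defines the block layout).
#' @param intra,inter baseline Fisher-z for intra- and inter-system blocks.
#' @param groups,times labels of the design cells.
#' @return an object of class `block_fc_spec`: a named list of symmetric
#'   K x K z matrices, one per `group:time` cell.
#' @examples
#' spec <- block_fc_spec()
#' spec <- plant_interaction_effect(spec, block = c("SVN", "SVN"),
#'                                  delta = 0.15, group = "NI", time = 2)
#' @export
block_fc_spec <- function(systems = c("SVN", "DAN", "DMN", "ECN", "SMN",
                                      "Visual", "Limbic", "Subcortical"),
                          intra = 0.3, inter = 0.1,
                          groups = c("I", "NI"), times = c(1L, 2L)) {
  k <- length(systems)
  base <- matrix(inter, k, k, dimnames = list(systems, systems))
  diag(base) <- intra
  check_block_z(base)
  cells <- as.vector(outer(groups, times, paste, sep = ":"))
  z <- stats::setNames(rep(list(base), length(cells)), cells)
  structure(list(z = z, systems = systems, groups = groups, times = times),
            class = "block_fc_spec")
}

check_block_z <- function(z) {
  if (!isSymmetric(unname(z), tol = 1e-12))
    stopf("block z table must be symmetric")
  if (any(abs(z) >= 3))
    stopf("block z values must satisfy |z| < 3")
  invisible(z)
}

#' @rdname block_fc_spec
#' @param spec a `block_fc_spec`.
#' @param block length-2 character vector naming the system pair (order
#'   irrelevant; equal entries select an intra-system block).
#' @param delta additive change in target z for the selected cells.
#' @param group,time design cells the effect applies to (vectors allowed).
#' @export
plant_interaction_effect <- function(spec, block, delta, group, time) {
  stopifnot(inherits(spec, "block_fc_spec"), length(block) == 2L)
  if (!all(block %in% spec$systems))
    stopf("unknown system(s): %s", paste(setdiff(block, spec$systems),
                                         collapse = ", "))
  for (g in group) for (t in time) {
    cell <- paste(g, t, sep = ":")
    if (!cell %in% names(spec$z)) stopf("no design cell '%s'", cell)
    z <- spec$z[[cell]]
    z[block[1L], block[2L]] <- z[block[1L], block[2L]] + delta
    z[block[2L], block[1L]] <- z[block[1L], block[2L]]
    check_block_z(z)
    spec$z[[cell]] <- z
  }
  spec
}

#' @export
print.block_fc_spec <- function(x, ...) {
  cat(sprintf("<block_fc_spec> %d systems, cells: %s\n",
              length(x$systems), paste(names(x$z), collapse = ", ")))
  invisible(x)
}

#' Expand a block z table into a ROI-level covariance matrix
#'
#' Inverts the FC measurement model: the target mean Fisher-z per block is
#' mapped to the correlation `tanh(z)` shared by every ROI pair in that
#' block, with unit variances. If the resulting matrix is not positive
#' definite it is repaired by clipping eigenvalues at a small positive floor
#' and rescaling the diagonal back to one; the repair is recorded in the
#' `"repair"` attribute.
#'
#' @param partition a `network_partition` covering the ROIs.
#' @param block_z symmetric K x K matrix of target Fisher-z per system pair
#'   (K = number of systems, rows/cols in partition system order).
#' @param eig_floor eigenvalue floor used by the repair.
#' @return a symmetric positive-definite ROI x ROI covariance matrix with
#'   unit diagonal; attribute `repair` records whether clipping occurred.
#' @examples
#' p <- default_partition(32)
#' z <- matrix(0.1, 8, 8); diag(z) <- 0.3
#' dimnames(z) <- list(levels(p$system), levels(p$system))
#' cv <- build_block_covariance(p, z)
#' @export
build_block_covariance <- function(partition, block_z, eig_floor = 1e-6) {
  check_block_z(block_z)
  sys_levels <- levels(partition$system)
  if (is.null(rownames(block_z))) {
    if (nrow(block_z) != length(sys_levels))
      stopf("block_z dimension %d does not match %d systems",
            nrow(block_z), length(sys_levels))
    dimnames(block_z) <- list(sys_levels, sys_levels)
  }
  if (!all(sys_levels %in% rownames(block_z)))
    stopf("block_z lacks system(s): %s",
          paste(setdiff(sys_levels, rownames(block_z)), collapse = ", "))
  lab <- as.character(partition$system)
  r <- tanh(block_z[lab, lab, drop = FALSE])
  diag(r) <- 1
  dimnames(r) <- list(partition$roi, partition$roi)
  ev <- eigen(r, symmetric = TRUE)
  repaired <- FALSE
  if (min(ev$values) < eig_floor) {
    vals <- pmax(ev$values, eig_floor)
    r2 <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(r2))
    if (any(d <= 0)) {
      bad <- unique(lab[d <= 0])
      stopf("covariance repair failed for block(s): %s",
            paste(bad, collapse = ", "))
    }
    r <- r2 / tcrossprod(d)
    diag(r) <- 1
    r <- (r + t(r)) / 2
    dimnames(r) <- list(partition$roi, partition$roi)
    repaired <- TRUE
  }
  structure(r, repair = list(repaired = repaired,
                             method = "eigenvalue clip + diagonal rescale",
                             eig_floor = eig_floor,
                             min_eigenvalue = min(ev$values)))
}

#' Simulate a subject's ROI time series from a target covariance
#'
#' Frames are drawn independently from a multivariate normal with the given
#' correlation structure, scaled to a BOLD-like positive baseline so that
#' fractional DVARS is well defined downstream. An optional AR(1)
#' coefficient adds temporal smoothness; it is off by default because every
#' downstream statistic is correlation-based and permutation operates at
#' subject level.
#'
#' @param cov positive-definite ROI covariance (correlation) matrix.
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed; output is deterministic given the seed.
#' @param baseline,signal_sd mean signal level and fluctuation SD of the
#'   generated series (the BOLD convention of ~1% fluctuations around a
#'   grand-mean-scaled baseline).
#' @param noise_sd SD of additional i.i.d. observation noise, in units of
#'   `signal_sd`; attenuates observed correlations by `1/(1 + noise_sd^2)`.
#' @param ar1 lag-1 autoregressive coefficient in [0, 1).
#' @param tr,subject,session metadata for the returned series.
#' @return an `fc_timeseries` (no motion trace attached).
#' @export
simulate_subject_timeseries <- function(cov, n_frames, seed,
                                        baseline = 1000, signal_sd = 10,
                                        noise_sd = 0, ar1 = 0, tr = 2,
                                        subject = "sub-01", session = "ses-1") {
  if (!is_count(n_frames, min = 2L)) stopf("n_frames must be an integer >= 2")
  ch <- tryCatch(chol(cov), error = function(e)
    stopf("covariance is not positive definite: %s", conditionMessage(e)))
  r <- ncol(cov)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_frames * r), n_frames, r)
    if (ar1 > 0) {
      for (t in 2:n_frames) z[t, ] <- ar1 * z[t - 1L, ] + sqrt(1 - ar1^2) * z[t, ]
    }
    x <- z %*% ch
    if (noise_sd > 0)
      x <- x + noise_sd * matrix(stats::rnorm(n_frames * r), n_frames, r)
    sig <- baseline + signal_sd * x
    colnames(sig) <- colnames(cov)
    fc_timeseries(sig, tr = tr, subject = subject, session = session)
  })
}

#' Inject motion spikes into a time series
#'
#' Builds a six-parameter motion trace that is a smooth low-amplitude random
#' walk except at spike events, where the head moves out by `spike_fd_mm`
#' and back on the next frame, so the framewise displacement equals
#' `spike_fd_mm` exactly at both frames of the event. At the event's onset
#' frame the signal receives a transient global offset sized as a fraction
#' of the grand mean, so fractional DVARS exceeds its threshold at the
#' onset (the jump) and the return frame (the jump back) — the same two
#' frames FD flags. Both frames of every event are recorded as spike
#' frames, making planted spikes exactly recoverable by FD/DVARS
#' thresholding.
#'
#' @param ts an `fc_timeseries`.
#' @param spike_rate expected fraction of frames carrying a spike (0 to
#'   0.5); each event covers two frames.
#' @param spike_fd_mm FD value produced at each spike frame (default 1.6).
#' @param seed RNG seed.
#' @param dvars_step_frac transient signal offset at event onsets, as a
#'   fraction of the grand mean (default 0.10, a 10% whole-brain jump).
#' @param base_trans_sd,base_rot_sd per-frame SD of the background random
#'   walk in mm and radians; defaults give realistic sub-threshold FD
#'   (~0.2 mm per frame) and ~1 mm absolute displacement over a run.
#' @return a list: `ts` (the series with perturbed signal and motion trace
#'   attached) and `spike_frames` (integer frame indices, possibly empty).
#' @export
inject_motion <- function(ts, spike_rate, spike_fd_mm = 1.6, seed = 1L,
                          dvars_step_frac = 0.10,
                          base_trans_sd = 0.05, base_rot_sd = 8e-4) {
  stopifnot(inherits(ts, "fc_timeseries"))
  if (!is_number(spike_rate) || spike_rate < 0 || spike_rate >= 0.5)
    stopf("spike_rate must be in [0, 0.5)")
  n <- n_frames(ts)
  with_seed(seed, {
    deltas <- cbind(matrix(stats::rnorm(3 * (n - 1), sd = base_trans_sd),
                           n - 1L, 3L),
                    matrix(stats::rnorm(3 * (n - 1), sd = base_rot_sd),
                           n - 1L, 3L))
    n_events <- round_half_away(stats::rbinom(1L, n - 1L, spike_rate) / 2)
    # event onsets need frame t+1 to exist and events must not overlap
    onsets <- integer(0)
    if (n_events > 0) {
      for (cand in sample(2:(n - 1L))) {
        if (length(onsets) >= n_events) break
        if (all(abs(cand - onsets) >= 2L)) onsets <- c(onsets, cand)
      }
      onsets <- sort(onsets)
    }
    spike_frames <- sort(c(onsets, onsets + 1L))
    if (length(onsets)) {
      deltas[spike_frames - 1L, ] <- 0
      deltas[onsets - 1L, 1L] <- spike_fd_mm     # out ...
      deltas[onsets, 1L] <- -spike_fd_mm         # ... and back
    }
    motion <- apply(rbind(0, deltas), 2L, cumsum)
    sig <- ts$signal
    if (length(onsets)) {
      step <- dvars_step_frac * mean(sig)
      sig[onsets, ] <- sig[onsets, ] + step
    }
    list(ts = ts_replace(ts, signal = sig, motion = motion),
         spike_frames = as.integer(spike_frames))
  })
}

#' Simulate behavior scores coupled to connectivity change
#'
#' Per-subject behavior change is generated as
#' `coupling * standardized(delta_fc) + sqrt(1 - coupling^2) * noise`, so the
#' population correlation between connectivity change and behavior change
#' equals `coupling` (when group offsets are zero). The change is scaled,
#' shifted by a per-group offset, and split into time-1 / time-2 scores.
#' Both symptom scales decrease with improvement; a positive coupling means
#' subjects whose connectivity increases improve less.
#'
#' @param design a study-design data.frame (`subject`, `group`, ...).
#' @param delta_fc per-subject connectivity change, one value per row of
#'   `design`.
#' @param coupling target correlation between -1 and 1.
#' @param seed RNG seed.
#' @param behavior column-name stem (e.g. `"inattention"`).
#' @param baseline_mean,baseline_sd time-1 score distribution.
#' @param delta_scale SD of the behavior change attributable to the coupled
#'   component (score units).
#' @param group_offset named per-group additive mean change (score units);
#'   defaults to zero.
#' @return `design` with `<behavior>_t1` and `<behavior>_t2` columns filled.
#' @export
simulate_behavior <- function(design, delta_fc, coupling, seed = 1L,
                              behavior = "inattention",
                              baseline_mean = 17, baseline_sd = 4.5,
                              delta_scale = 3,
                              group_offset = NULL) {
  n <- nrow(design)
  if (length(delta_fc) < n)
    stopf("delta_fc has %d values for %d subjects", length(delta_fc), n)
  if (!is_number(coupling) || abs(coupling) > 1)
    stopf("coupling must be in [-1, 1]")
  delta_fc <- delta_fc[seq_len(n)]
  s <- delta_fc - mean(delta_fc)
  sdv <- stats::sd(delta_fc)
  s <- if (sdv > 0) s / sdv else s
  with_seed(seed, {
    noise <- stats::rnorm(n)
    delta <- coupling * s + sqrt(1 - coupling^2) * noise
    t1 <- baseline_mean + baseline_sd * stats::rnorm(n)
    off <- rep(0, n)
    if (!is.null(group_offset))
      off <- unname(group_offset[as.character(design$group)])
    t2 <- t1 + delta_scale * delta + off
    design[[paste0(behavior, "_t1")]] <- t1
    design[[paste0(behavior, "_t2")]] <- t2
    design
  })
}

#' Simulation settings for a synthetic cohort
#'
#' Defaults mirror the study dimensions the pipeline targets: two groups of
#' 18 (intervention, `I`) and 11 (non-intervention, `NI`) subjects, 246
#' acquired frames per session at TR = 2 s collected as two concatenated
#' runs, 141 ROIs over 8 systems, and a planted group-by-time increase of
#' z = 0.15 in the intra-SVN block of the non-intervention group at time 2
#' (the intervention group stays flat), with behavior change coupled to the
#' planted block at r = 0.4.
#'
#' @param n_per_group named subject counts (intervention first).
#' @param n_frames acquired frames per session.
#' @param tr_seconds repetition time (s).
#' @param roi_count number of ROIs.
#' @param noise_sd i.i.d. observation-noise scale (see
#'   [simulate_subject_timeseries()]).
#' @param motion_spike_rate expected fraction of frames with motion spikes.
#' @param behavior_coupling correlation between planted-block connectivity
#'   change and behavior change.
#' @param seed master RNG seed for the cohort.
#' @param n_runs,n_discard_per_run acquisition structure used downstream by
#'   the volume-discard stage.
#' @param fc_delta_sd SD of the subject-level random deviation added to the
#'   coupled block at time 2 (Fisher-z units); gives subjects individual
#'   connectivity trajectories.
#' @param coupling_block system pair whose change drives behavior.
#' @param scanner_effect additive Fisher-z offset applied to all blocks for
#'   sessions acquired on the second scanner (default 0).
#' @param age_mean,age_sd subject age distribution (years).
#' @param spike_fd_mm FD magnitude of planted spikes.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = c(I = 18L, NI = 11L),
                             n_frames = 246L, tr_seconds = 2,
                             roi_count = 141L, noise_sd = 0,
                             motion_spike_rate = 0.05,
                             behavior_coupling = 0.4, seed = 1L,
                             n_runs = 2L, n_discard_per_run = 5L,
                             fc_delta_sd = 0.05,
                             coupling_block = c("SVN", "SVN"),
                             scanner_effect = 0,
                             age_mean = 9.2, age_sd = 1.4,
                             spike_fd_mm = 1.6) {
  if (length(n_per_group) != 2L || any(n_per_group < 2L))
    stopf("n_per_group must give two counts >= 2")
  if (!is_count(n_frames, min = 64L)) stopf("n_frames must be >= 64")
  if (!is_count(roi_count, min = 16L)) stopf("roi_count must be >= 16")
  if (motion_spike_rate < 0 || motion_spike_rate >= 0.5)
    stopf("motion_spike_rate must be in [0, 0.5)")
  if (abs(behavior_coupling) > 1) stopf("|behavior_coupling| must be <= 1")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate a study-design table
#'
#' @param config a `synthetic_config`.
#' @param seed RNG seed (defaults to the config seed).
#' @return data.frame: `subject`, `group`, `age`, `scanner`. Scanner labels
#'   follow the two-scanner split of the emulated study (majority of the
#'   intervention group on the newer scanner, the reverse for the
#'   non-intervention group), making scanner a genuinely confounded
#'   covariate.
#' @export
simulate_design <- function(config, seed = config$seed) {
  n <- config$n_per_group
  groups <- names(n)
  if (is.null(groups)) groups <- c("I", "NI")
  with_seed(derive_seed(seed, 101L), {
    subj <- sprintf("sub-%02d", seq_len(sum(n)))
    group <- factor(rep(groups, times = n), levels = groups)
    age <- stats::rnorm(sum(n), config$age_mean, config$age_sd)
    p_new <- c(13 / 18, 2 / 11)[as.integer(group)]
    scanner <- ifelse(stats::runif(sum(n)) < p_new, "Prisma", "TimTrio")
    data.frame(subject = subj, group = group, age = round(age, 1),
               scanner = factor(scanner, levels = c("TimTrio", "Prisma")),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete two-session cohort
#'
#' Composes the block-covariance model, per-session multivariate-normal
#' time-series simulation, motion-spike injection, and behavior coupling
#' into a full input bundle with its ground truth. Fully reproducible from
#' the config seed.
#'
#' @param config a [synthetic_config()].
#' @param spec a [block_fc_spec()]; by default the baseline spec with the
#'   planted non-intervention intra-SVN increase of z = 0.15 at time 2.
#' @param planted_delta z change used when `spec` is built internally.
#' @return an object of class `fc_cohort`: `sessions` (named list of
#'   `fc_timeseries`, names `<subject>.<session>`), `design`, `partition`,
#'   `config`, and `ground_truth` (planted block z per cell, per-subject
#'   true connectivity change, spike frames per session, seed).
#' @export
simulate_cohort <- function(config = synthetic_config(), spec = NULL,
                            planted_delta = 0.15) {
  stopifnot(inherits(config, "synthetic_config"))
  partition <- default_partition(config$roi_count)
  systems <- levels(partition$system)
  if (is.null(spec)) {
    spec <- block_fc_spec(systems = systems)
    if (planted_delta != 0)
      spec <- plant_interaction_effect(spec, block = config$coupling_block,
                                       delta = planted_delta,
                                       group = "NI", time = 2L)
  }
  design <- simulate_design(config)
  n_sub <- nrow(design)
  cb <- config$coupling_block

  # subject-level random trajectory on the coupled block (time 2 only)
  subj_dev <- with_seed(derive_seed(config$seed, 202L),
                        stats::rnorm(n_sub, 0, config$fc_delta_sd))
  true_delta <- numeric(n_sub)
  sessions <- list()
  spikes <- list()
  repair_any <- FALSE
  for (i in seq_len(n_sub)) {
    g <- as.character(design$group[i])
    z1 <- spec$z[[paste(g, 1L, sep = ":")]]
    z2 <- spec$z[[paste(g, 2L, sep = ":")]]
    z2[cb[1L], cb[2L]] <- z2[cb[1L], cb[2L]] + subj_dev[i]
    z2[cb[2L], cb[1L]] <- z2[cb[1L], cb[2L]]
    if (config$scanner_effect != 0 && design$scanner[i] == "Prisma") {
      z1 <- z1 + config$scanner_effect
      z2 <- z2 + config$scanner_effect
    }
    true_delta[i] <- z2[cb[1L], cb[2L]] - z1[cb[1L], cb[2L]]
    for (s in 1:2) {
      z <- if (s == 1L) z1 else z2
      cov <- build_block_covariance(partition, z)
      repair_any <- repair_any || attr(cov, "repair")$repaired
      ts <- simulate_subject_timeseries(
        cov, config$n_frames,
        seed = derive_seed(config$seed, 1000L + 2L * i + s),
        noise_sd = config$noise_sd, tr = config$tr_seconds,
        subject = design$subject[i], session = paste0("ses-", s))
      inj <- inject_motion(ts, config$motion_spike_rate,
                           spike_fd_mm = config$spike_fd_mm,
                           seed = derive_seed(config$seed, 5000L + 2L * i + s))
      key <- paste(design$subject[i], paste0("ses-", s), sep = ".")
      sessions[[key]] <- inj$ts
      spikes[[key]] <- inj$spike_frames
    }
  }
  design <- simulate_behavior(design, true_delta, config$behavior_coupling,
                              seed = derive_seed(config$seed, 303L),
                              behavior = "inattention", baseline_mean = 17,
                              baseline_sd = 4.5, delta_scale = 3,
                              group_offset = c(I = -3.1, NI = -1.6))
  design <- simulate_behavior(design, true_delta, config$behavior_coupling,
                              seed = derive_seed(config$seed, 404L),
                              behavior = "internalizing", baseline_mean = 9.6,
                              baseline_sd = 6.5, delta_scale = 3,
                              group_offset = c(I = -2.5, NI = -1.8))
  gt <- list(block_z = lapply(spec$z, function(m) m),
             coupling_block = cb,
             behavior_coupling = config$behavior_coupling,
             true_delta_fc = stats::setNames(true_delta, design$subject),
             spike_frames = spikes,
             covariance_repaired = repair_any,
             seed = config$seed)
  structure(list(sessions = sessions, design = design, partition = partition,
                 config = config, ground_truth = gt),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("<fc_cohort> %d subjects (%s), %d sessions, %d ROIs, %d frames\n",
              nrow(x$design),
              paste(sprintf("%s=%d", levels(x$design$group),
                            table(x$design$group)), collapse = ", "),
              length(x$sessions), x$config$roi_count, x$config$n_frames))
  invisible(x)
}

#' Write a cohort to disk in the pipeline's external formats
#'
#' Per session: `<subject>_<session>_roits.tsv` (signal) and
#' `<subject>_<session>_motion.txt` (six-column motion trace); plus
#' `design.tsv`, `partition.tsv` and `ground_truth.json`.
#'
#' @param cohort an `fc_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$sessions)) {
    ts <- cohort$sessions[[key]]
    stem <- file.path(dir, gsub("\\.", "_", key))
    write_roi_timeseries(ts, paste0(stem, "_roits.tsv"))
    write_motion(ts$motion, paste0(stem, "_motion.txt"))
  }
  utils::write.table(cohort$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_partition(cohort$partition, file.path(dir, "partition.tsv"))
  gt <- cohort$ground_truth
  gt$block_z <- lapply(gt$block_z, function(m)
    list(systems = rownames(m), z = unname(m)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  meta <- list(tr_seconds = cohort$config$tr_seconds,
               n_runs = cohort$config$n_runs,
               n_discard_per_run = cohort$config$n_discard_per_run)
  jsonlite::write_json(meta, file.path(dir, "acquisition.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
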