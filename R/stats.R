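#' Ordinary least-squares residualization
#'
#' Residuals of `values` after regressing on an intercept plus the given
#' covariates — the standard way nuisance effects (age, scanner) are
#' removed before correlation or permutation testing.
#'
#' @param values numeric vector.
#' @param covariates data.frame or matrix of covariates (factors allowed);
#'   `NULL` means intercept only (residuals are the centered values).
#' @return residual vector of the same length.
#' @export
residualize <- function(values, covariates = NULL) {
  x <- covariate_matrix(covariates, length(values))
  if (length(values) <= ncol(x))
    stopf("need n > number of covariates + 1 (n = %d, columns = %d)",
          length(values), ncol(x))
  qx <- qr(x)
  if (qx$rank < ncol(x)) stopf("covariates are rank deficient")
  as.numeric(qr.resid(qx, values))
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1L))
  if (is.data.frame(covariates)) {
    x <- stats::model.matrix(~ ., data = covariates)
  } else {
    x <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  }
  if (nrow(x) != n) stopf("covariates have %d rows for %d values", nrow(x), n)
  x
}

# pooled-variance two-sample t on y grouped by a logical vector (TRUE = group A)
pooled_t <- function(y, in_a) {
  n1 <- sum(in_a); n2 <- sum(!in_a)
  m1 <- mean(y[in_a]); m2 <- mean(y[!in_a])
  sp2 <- (sum((y[in_a] - m1)^2) + sum((y[!in_a] - m2)^2)) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Group-by-time interaction statistic for a 2x2 repeated design
#'
#' In a two-group, two-timepoint design the interaction is exactly the
#' between-group difference in within-subject change, so the statistic is a
#' pooled-variance two-sample t on per-subject change scores after
#' covariates are regressed out (Freedman-Lane style adjustment). `F = t^2`
#' is reported alongside.
#'
#' @param delta per-subject change scores (time 2 minus time 1).
#' @param group two-level factor/character vector; the statistic's sign is
#'   first level minus second level.
#' @param covariates optional per-subject covariate table.
#' @return list: `t`, `F`, `df`, `group_means` (raw mean change per group).
#' @examples
#' interaction_statistic(c(2, 1, 3, 0, 1, -1),
#'                       rep(c("A", "B"), each = 3))$t  # ~2.449
#' @export
interaction_statistic <- function(delta, group, covariates = NULL) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L) stopf("group must have exactly 2 levels")
  if (any(table(group) < 2L)) stopf("each group needs at least 2 subjects")
  adj <- residualize(delta, covariates)
  tt <- pooled_t(adj, group == levels(group)[1L])
  gm <- tapply(delta, group, mean)
  list(t = tt, F = tt^2, df = length(delta) - 2L,
       group_means = stats::setNames(as.numeric(gm), names(gm)))
}

#' Permutation test for the group-by-time interaction
#'
#' Freedman-Lane scheme: the reduced (covariates-only) model is fitted to
#' the change scores, its residuals are permuted across subjects (whole
#' subjects move, so the within-subject pairing is intact), the permuted
#' outcome is re-adjusted for covariates, and the group statistic is
#' recomputed. `p = (1 + #{|t*| >= |t|}) / (1 + n_perms)`, two-sided.
#' Without covariates, when the number of distinct group assignments is at
#' most `n_perms`, all assignments are enumerated for an exact p-value.
#'
#' @param delta per-subject change scores.
#' @param group two-level grouping vector.
#' @param covariates optional covariate table.
#' @param n_perms permutations (>= 100; default 5000).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param outcome label carried into the result.
#' @return object of class `perm_interaction`: `outcome`, `statistic` (t),
#'   `F`, `p`, `n_perms`, `exact`, `seed`, `group_means`.
#' @export
permutation_interaction_test <- function(delta, group, covariates = NULL,
                                         n_perms = 5000L, seed = 1L,
                                         outcome = "outcome") {
  if (!is_count(n_perms, 100L)) stopf("n_perms must be an integer >= 100")
  group <- droplevels(factor(group))
  obs <- interaction_statistic(delta, group, covariates)
  n <- length(delta)
  in_a <- group == levels(group)[1L]
  n1 <- sum(in_a)
  exact <- is.null(covariates) && choose(n, n1) <= n_perms
  if (exact) {
    centered <- delta - mean(delta)
    sets <- utils::combn(n, n1)
    stats <- apply(sets, 2L, function(ix) {
      lab <- rep(FALSE, n); lab[ix] <- TRUE
      pooled_t(centered, lab)
    })
    p <- mean(abs(stats) >= abs(obs$t) - 1e-12)
    n_used <- ncol(sets)
  } else {
    x <- covariate_matrix(covariates, n)
    qx <- qr(x)
    fit <- as.numeric(qr.fitted(qx, delta))
    e <- as.numeric(qr.resid(qx, delta))
    perms <- with_seed(seed, replicate(n_perms, sample.int(n)))
    ep <- matrix(e[perms], n, n_perms)           # permuted residuals
    ystar <- fit + ep
    rstar <- ystar - qr.fitted(qx, ystar)        # re-adjusted outcomes
    # vectorized pooled t over columns
    s1 <- colSums(rstar[in_a, , drop = FALSE]);  s2 <- colSums(rstar[!in_a, , drop = FALSE])
    m1 <- s1 / n1; m2 <- s2 / (n - n1)
    ss1 <- colSums(rstar[in_a, , drop = FALSE]^2) - n1 * m1^2
    ss2 <- colSums(rstar[!in_a, , drop = FALSE]^2) - (n - n1) * m2^2
    sp2 <- (ss1 + ss2) / (n - 2)
    stats <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / (n - n1)))
    p <- (1 + sum(abs(stats) >= abs(obs$t) - 1e-12)) / (1 + n_perms)
    n_used <- n_perms
  }
  structure(list(outcome = outcome, statistic = obs$t, F = obs$F, p = p,
                 n_perms = n_used, exact = exact, seed = seed,
                 group_means = obs$group_means),
            class = "perm_interaction")
}

#' @export
print.perm_interaction <- function(x, ...) {
  cat(sprintf("<perm_interaction> %s: t = %.3f, p = %.4f (%s, %d perms)\n",
              x$outcome, x$statistic, x$p,
              if (x$exact) "exact" else "sampled", x$n_perms))
  cat(sprintf("  mean change: %s\n",
              paste(sprintf("%s = %.3f", names(x$group_means),
                            x$group_means), collapse = ", ")))
  invisible(x)
}

#' Run the interaction-test suite over connectivity and topology outcomes
#'
#' One permutation test per outcome: every system-pair connectivity block
#' (change in block mean z), each integrated global metric, and each
#' integrated nodal metric at every node. Raw p-values are reported with
#' flags at both alpha levels; no familywise correction is applied by
#' default (an optional Benjamini-Hochberg column is available).
#'
#' @param block_tables named list (by subject) of length-2 lists of
#'   `block_fc` (time 1, time 2), or `NULL` to skip connectivity outcomes.
#' @param profiles named list (by subject) of length-2 lists of
#'   `graph_profile`, or `NULL` to skip topology outcomes.
#' @param design study-design data.frame with `subject`, `group`, and the
#'   covariate columns.
#' @param covariate_cols column names regressed out (default age + scanner).
#' @param n_perms,seed permutation settings (per-outcome seeds derived).
#' @param alpha_fc,alpha_nodal significance flags reported in the output.
#' @param fdr add a Benjamini-Hochberg adjusted column (default FALSE).
#' @return data.frame: `outcome_type`, `outcome`, `statistic`, `p`,
#'   significance flags, and per-group mean changes.
#' @export
run_interaction_suite <- function(block_tables = NULL, profiles = NULL,
                                  design,
                                  covariate_cols = c("age", "scanner"),
                                  n_perms = 5000L, seed = 1L,
                                  alpha_fc = 0.05, alpha_nodal = 0.01,
                                  fdr = FALSE) {
  subjects <- design$subject
  covs <- if (length(covariate_cols)) design[covariate_cols] else NULL
  outcomes <- list()   # each: list(type, name, delta vector)
  if (!is.null(block_tables)) {
    bt <- block_tables[subjects]
    if (any(vapply(bt, is.null, logical(1L))))
      stopf("block_tables missing subject(s): %s",
            paste(subjects[vapply(bt, is.null, logical(1L))], collapse = ", "))
    b1 <- bt[[1L]][[1L]]$mean_z
    ut <- which(upper.tri(b1, diag = TRUE), arr.ind = TRUE)
    for (j in seq_len(nrow(ut))) {
      a <- rownames(b1)[ut[j, 1L]]; b <- colnames(b1)[ut[j, 2L]]
      delta <- vapply(bt, function(s)
        s[[2L]]$mean_z[a, b] - s[[1L]]$mean_z[a, b], numeric(1L))
      if (any(is.na(delta))) next
      outcomes[[length(outcomes) + 1L]] <-
        list(type = "fc_block", name = paste(a, b, sep = "-"), delta = delta)
    }
  }
  if (!is.null(profiles)) {
    pf <- profiles[subjects]
    if (any(vapply(pf, is.null, logical(1L))))
      stopf("profiles missing subject(s)")
    for (gm in names(pf[[1L]][[1L]]$integrated$global)) {
      delta <- vapply(pf, function(s)
        s[[2L]]$integrated$global[[gm]] - s[[1L]]$integrated$global[[gm]],
        numeric(1L))
      outcomes[[length(outcomes) + 1L]] <-
        list(type = "global", name = gm, delta = delta)
    }
    for (nm in c("strength", "clustering", "closeness")) {
      nodes <- names(pf[[1L]][[1L]]$integrated$nodal[[nm]])
      d2 <- vapply(pf, function(s)
        s[[2L]]$integrated$nodal[[nm]] - s[[1L]]$integrated$nodal[[nm]],
        numeric(length(nodes)))
      for (k in seq_along(nodes)) {
        outcomes[[length(outcomes) + 1L]] <-
          list(type = paste0("nodal_", nm), name = nodes[k],
               delta = d2[k, ])
      }
    }
  }
  if (!length(outcomes)) stopf("no outcomes to test")
  rows <- vector("list", length(outcomes))
  for (i in seq_along(outcomes)) {
    o <- outcomes[[i]]
    res <- permutation_interaction_test(o$delta, design$group, covs,
                                        n_perms = n_perms,
                                        seed = derive_seed(seed, 9000L + i),
                                        outcome = o$name)
    rows[[i]] <- data.frame(outcome_type = o$type, outcome = o$name,
                            statistic = res$statistic, p = res$p,
                            sig_fc = res$p < alpha_fc,
                            sig_nodal = res$p < alpha_nodal,
                            mean_change_1 = unname(res$group_means[1L]),
                            mean_change_2 = unname(res$group_means[2L]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[7:8] <- paste0("mean_change_", levels(factor(design$group)))
  if (fdr) out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  attr(out, "alpha_fc") <- alpha_fc
  attr(out, "alpha_nodal") <- alpha_nodal
  attr(out, "n_perms") <- n_perms
  attr(out, "seed") <- seed
  out
}

#' Covariate-residualized brain-behavior correlation
#'
#' Both change vectors are residualized on the covariates, then correlated
#' (Pearson). The two-sided p-value uses a t reference on
#' `n - 2 - q` degrees of freedom, where `q` covariate columns were removed
#' — the df penalty accounts for the residualization.
#'
#' @param delta_metric per-subject change in a brain measure.
#' @param delta_behavior per-subject change in a behavior score (symptom
#'   scales: improvement = decrease).
#' @param covariates optional covariate table.
#' @param metric,behavior labels for the result.
#' @return object of class `brain_behavior`: `r`, `p`, `n`, `df`, labels.
#' @export
brain_behavior_correlation <- function(delta_metric, delta_behavior,
                                       covariates = NULL,
                                       metric = "metric",
                                       behavior = "behavior") {
  n <- length(delta_metric)
  if (n < 5L) stopf("need at least 5 subjects")
  if (length(delta_behavior) != n) stopf("vector lengths differ")
  rm_ <- residualize(delta_metric, covariates)
  rb <- residualize(delta_behavior, covariates)
  tol <- 1e-10
  if (stats::sd(rm_) <= tol * max(1, stats::sd(delta_metric)) ||
      stats::sd(rb) <= tol * max(1, stats::sd(delta_behavior)))
    stopf("a vector is constant after residualization")
  r <- stats::cor(rm_, rb)
  q <- ncol(covariate_matrix(covariates, n)) - 1L
  df <- n - 2L - q
  if (df < 1L) stopf("not enough residual degrees of freedom")
  tval <- r * sqrt(df / max(1 - r^2, 1e-15))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(metric = metric, behavior = behavior, r = r, p = min(p, 1),
                 n = n, df = df),
            class = "brain_behavior")
}

#' @export
print.brain_behavior <- function(x, ...) {
  cat(sprintf("<brain_behavior> %s ~ %s: r = %.3f, p = %.4f (n = %d, df = %d)\n",
              x$metric, x$behavior, x$r, x$p, x$n, x$df))
  invisible(x)
}
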