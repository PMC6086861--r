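#' Proportional density threshold
#'
#' Zeroes negative connectivity (only positive FC enters the graph), then
#' retains the `round(d * R(R-1)/2)` strongest positive weights so that
#' graphs from different subjects have equal edge counts. Rounding is
#' half-away-from-zero; ties at the cutoff are broken by first occurrence
#' in row-major upper-triangle order, so runs are reproducible. Weights are
#' kept, not binarized.
#'
#' @param fc symmetric ROI x ROI Fisher-z matrix (`fc_zmatrix` or plain).
#' @param density fraction of possible edges to retain, in (0, 1].
#' @return an object of class `fc_graph`: `weights` (non-negative symmetric
#'   matrix, zero diagonal), `density`, `n_edges`, `n_requested`, and
#'   `short` (TRUE when fewer positive entries existed than requested, in
#'   which case all positives are kept and a warning is recorded).
#' @examples
#' m <- matrix(runif(25), 5, 5); m <- (m + t(m)) / 2; diag(m) <- 0
#' g <- apply_density_threshold(m, 0.5)
#' g$n_edges
#' @export
apply_density_threshold <- function(fc, density) {
  if (!is_number(density) || density <= 0 || density > 1)
    stopf("density must be in (0, 1]")
  w <- as.matrix(fc)
  r <- nrow(w)
  diag(w) <- 0
  w[w < 0] <- 0
  n_pairs <- r * (r - 1) / 2
  m <- round_half_away(density * n_pairs)
  if (m < 1) stopf("density %g yields no edges on %d nodes", density, r)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]   # row-major
  vals <- w[ut]
  pos <- which(vals > 0)
  if (length(pos) == 0L) stopf("no positive weights: graph would be empty")
  short <- length(pos) < m
  if (short) {
    warning(sprintf("only %d positive weights for %d requested edges; keeping all",
                    length(pos), m))
    keep <- pos
  } else {
    keep <- pos[order(-vals[pos])[seq_len(m)]]   # order() is stable: row-major tie-break
  }
  out <- matrix(0, r, r, dimnames = dimnames(w))
  out[ut[keep, , drop = FALSE]] <- vals[keep]
  out <- out + t(out)
  structure(list(weights = out, density = density,
                 n_edges = length(keep), n_requested = m, short = short),
            class = "fc_graph")
}

#' @export
print.fc_graph <- function(x, ...) {
  cat(sprintf("<fc_graph> %d nodes, %d edges (density %.2f)%s\n",
              nrow(x$weights), x$n_edges, x$density,
              if (x$short) " [fewer positives than requested]" else ""))
  invisible(x)
}

# accept either an fc_graph or a bare non-negative weight matrix
graph_weights <- function(g) {
  if (inherits(g, "fc_graph")) return(g$weights)
  w <- as.matrix(g)
  if (any(w < 0)) stopf("weights must be non-negative")
  diag(w) <- 0
  w
}

#' Nodal strength and binary degree
#'
#' Strength is the weighted degree, `sum_j w_ij`; the binary degree (count
#' of nonzero edges) is the classical centrality on the thresholded
#' topology. Strength is the primary "degree centrality" on weighted
#' graphs; both are available.
#'
#' @param g an `fc_graph` (or non-negative symmetric weight matrix).
#' @return named numeric vector, one value per node.
#' @export
nodal_strength <- function(g) rowSums(graph_weights(g))

#' @rdname nodal_strength
#' @export
nodal_degree <- function(g) rowSums(graph_weights(g) > 0)

#' Onnela weighted clustering coefficient
#'
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w'_ij w'_jh w'_hi)^{1/3}` with
#' weights normalized by the graph maximum, `w' = w / max(w)`; `C_i = 0`
#' for nodes of binary degree below 2.
#'
#' @param g an `fc_graph` (or weight matrix).
#' @return per-node clustering coefficients between 0 and 1.
#' @export
nodal_clustering <- function(g) {
  w <- graph_weights(g)
  mx <- max(w)
  if (mx == 0) return(stats::setNames(rep(0, nrow(w)), rownames(w)))
  wh <- (w / mx)^(1 / 3)
  num <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  stats::setNames(cc, rownames(w))
}

#' All-pairs shortest path lengths on a weighted graph
#'
#' Edge lengths are reciprocal weights (`1/w`): strong connections are
#' short. Unreachable pairs get `Inf`; the diagonal is 0.
#'
#' @param g an `fc_graph` (or weight matrix).
#' @return symmetric node x node distance matrix.
#' @export
shortest_path_lengths <- function(g) {
  w <- graph_weights(g)
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  dimnames(d) <- dimnames(w)
  d
}

#' Harmonic closeness centrality
#'
#' `closeness_i = (1 / (R - 1)) * sum_{j != i} 1 / d_ij`, with `1/Inf = 0`,
#' so the measure is finite on disconnected graphs (an isolated node gets
#' 0). Its mean over nodes equals the global efficiency.
#'
#' @param g an `fc_graph` (or weight matrix).
#' @param d optional precomputed distance matrix.
#' @return per-node closeness values.
#' @export
nodal_closeness <- function(g, d = NULL) {
  if (is.null(d)) d <- shortest_path_lengths(g)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (nrow(d) - 1)
}

#' Global efficiency
#'
#' Mean of `1/d_ij` over all ordered node pairs: the canonical network
#' integration measure, equal to the mean harmonic closeness.
#'
#' @inheritParams nodal_closeness
#' @return scalar between 0 and 1 for max-normalized unit-weight graphs.
#' @export
global_efficiency <- function(g, d = NULL) mean(nodal_closeness(g, d))

#' Characteristic path length
#'
#' Mean shortest-path distance over reachable ordered pairs; the fraction
#' of unreachable pairs is reported in the `"unreachable_frac"` attribute.
#'
#' @inheritParams nodal_closeness
#' @return scalar with attribute `unreachable_frac`.
#' @export
characteristic_path_length <- function(g, d = NULL) {
  if (is.null(d)) d <- shortest_path_lengths(g)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  if (!any(finite)) stopf("graph has no reachable node pairs")
  structure(mean(off[finite]),
            unreachable_frac = mean(!finite))
}

#' Degree-preserving rewired null graph
#'
#' Randomizes topology by Maslov-Sneppen double-edge swaps (preserving
#' every node's binary degree exactly), then reassigns the original weight
#' multiset to the rewired edges in random order. Swap attempts that would
#' create self-loops or multi-edges are rejected, the standard behavior of
#' the sampler; on graphs with no legal swaps (e.g. complete graphs) the
#' topology is returned unchanged.
#'
#' @param g an `fc_graph` (or weight matrix) with at least 2 edges.
#' @param n_swaps_per_edge attempted swaps per edge (default 10).
#' @param seed RNG seed.
#' @return an `fc_graph` with identical degree sequence and weight multiset.
#' @export
rewire_null <- function(g, n_swaps_per_edge = 10L, seed = 1L) {
  w <- graph_weights(g)
  ig <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                            diag = FALSE)
  n_edges <- igraph::ecount(ig)
  if (n_edges < 2L) stopf("need at least 2 edges to rewire")
  with_seed(seed, {
    rw <- igraph::rewire(ig, igraph::keeping_degseq(
      loops = FALSE, niter = n_swaps_per_edge * n_edges))
    el <- igraph::as_edgelist(rw, names = FALSE)
    wts <- sample(w[upper.tri(w)][w[upper.tri(w)] > 0])
    out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
    out[el] <- wts
    out[el[, c(2L, 1L), drop = FALSE]] <- wts
    dens <- if (inherits(g, "fc_graph")) g$density
            else n_edges / (nrow(w) * (nrow(w) - 1) / 2)
    structure(list(weights = out, density = dens, n_edges = n_edges,
                   n_requested = n_edges, short = FALSE),
              class = "fc_graph")
  })
}

#' Small-worldness against rewired null models
#'
#' `sigma = (C / <C_rand>) / (L / <L_rand>)`: mean Onnela clustering and
#' characteristic path length, each normalized by their means over
#' degree-preserving rewired null graphs. `sigma > 1` indicates
#' small-world organization (more clustered than random at comparable path
#' length).
#'
#' @param g an `fc_graph` (or weight matrix).
#' @param n_nulls number of null graphs (>= 2; default 100).
#' @param n_swaps_per_edge swap attempts per edge per null.
#' @param seed RNG seed (null i gets a seed derived from it).
#' @return list of class `small_world`: `sigma`, `C`, `L`, null means/SDs,
#'   `n_nulls`, `seed`.
#' @export
small_worldness <- function(g, n_nulls = 100L, n_swaps_per_edge = 10L,
                            seed = 1L) {
  if (!is_count(n_nulls, 2L)) stopf("n_nulls must be an integer >= 2")
  C <- mean(nodal_clustering(g))
  L <- as.numeric(characteristic_path_length(g))
  c_rand <- l_rand <- numeric(n_nulls)
  for (i in seq_len(n_nulls)) {
    null <- rewire_null(g, n_swaps_per_edge, seed = derive_seed(seed, i))
    c_rand[i] <- mean(nodal_clustering(null))
    l_rand[i] <- as.numeric(characteristic_path_length(null))
  }
  sigma <- (C / mean(c_rand)) / (L / mean(l_rand))
  structure(list(sigma = sigma, C = C, L = L,
                 C_rand_mean = mean(c_rand), C_rand_sd = stats::sd(c_rand),
                 L_rand_mean = mean(l_rand), L_rand_sd = stats::sd(l_rand),
                 n_nulls = n_nulls, seed = seed),
            class = "small_world")
}

#' @export
print.small_world <- function(x, ...) {
  cat(sprintf(paste0("<small_world> sigma = %.3f  (C = %.3f vs null %.3f; ",
                     "L = %.3f vs null %.3f; %d nulls)\n"),
              x$sigma, x$C, x$C_rand_mean, x$L, x$L_rand_mean, x$n_nulls))
  invisible(x)
}

#' Integrate a metric curve across the density grid
#'
#' Trapezoidal integral over density divided by the density range, so a
#' constant curve integrates to itself and integrated metrics stay on the
#' per-density scale.
#'
#' @param values numeric vector (one value per density) or matrix
#'   (densities in rows, e.g. nodes in columns).
#' @param densities strictly increasing density grid (>= 2 points); default
#'   15% to 35% in steps of 1%.
#' @return scalar (vector input) or vector over columns (matrix input).
#' @export
integrate_over_densities <- function(values, densities = seq(0.15, 0.35, by = 0.01)) {
  if (length(densities) < 2L) stopf("need at least 2 densities")
  if (any(diff(densities) <= 0)) stopf("densities must be strictly increasing")
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  if (nrow(v) != length(densities))
    stopf("values has %d rows for %d densities", nrow(v), length(densities))
  dx <- diff(densities)
  aux <- (v[-nrow(v), , drop = FALSE] + v[-1L, , drop = FALSE]) / 2
  out <- colSums(aux * dx) / (max(densities) - min(densities))
  if (is.matrix(values)) stats::setNames(out, colnames(values)) else as.numeric(out)
}

#' Full topology profile of a connectivity matrix
#'
#' Thresholds the matrix at every density of the grid, computes nodal
#' (strength, binary degree, Onnela clustering, harmonic closeness) and
#' global (efficiency, mean clustering, characteristic path length, and
#' optionally small-worldness) measures per density, and integrates each
#' across the grid.
#'
#' @param fc symmetric Fisher-z matrix (`fc_zmatrix` or plain).
#' @param densities density grid (default 0.15 to 0.35 step 0.01).
#' @param n_nulls null graphs per density for sigma (default 100).
#' @param compute_sigma set `FALSE` to skip the (expensive) small-world
#'   normalization.
#' @param n_swaps_per_edge swap attempts per edge in each null.
#' @param seed RNG seed for the null models.
#' @return an object of class `graph_profile`: `densities`; `nodal`, a list
#'   of density x node matrices; `global`, a data.frame per density;
#'   `integrated`, with `nodal` (per-node vectors) and `global` (named
#'   scalars).
#' @export
graph_metric_profile <- function(fc, densities = seq(0.15, 0.35, by = 0.01),
                                 n_nulls = 100L, compute_sigma = TRUE,
                                 n_swaps_per_edge = 10L, seed = 1L) {
  r <- nrow(fc)
  nd <- length(densities)
  roi <- rownames(fc)
  if (is.null(roi)) roi <- sprintf("ROI%03d", seq_len(r))
  nodal <- list(strength = matrix(NA_real_, nd, r, dimnames = list(NULL, roi)),
                degree = matrix(NA_real_, nd, r, dimnames = list(NULL, roi)),
                clustering = matrix(NA_real_, nd, r, dimnames = list(NULL, roi)),
                closeness = matrix(NA_real_, nd, r, dimnames = list(NULL, roi)))
  glob <- data.frame(density = densities, efficiency = NA_real_,
                     clustering = NA_real_, path_length = NA_real_,
                     sigma = NA_real_)
  for (i in seq_len(nd)) {
    g <- apply_density_threshold(fc, densities[i])
    d <- shortest_path_lengths(g)
    nodal$strength[i, ] <- nodal_strength(g)
    nodal$degree[i, ] <- nodal_degree(g)
    nodal$clustering[i, ] <- nodal_clustering(g)
    nodal$closeness[i, ] <- nodal_closeness(g, d)
    glob$efficiency[i] <- global_efficiency(g, d)
    glob$clustering[i] <- mean(nodal$clustering[i, ])
    glob$path_length[i] <- as.numeric(characteristic_path_length(g, d))
    if (compute_sigma)
      glob$sigma[i] <- small_worldness(g, n_nulls, n_swaps_per_edge,
                                       seed = derive_seed(seed, 7000L + i))$sigma
  }
  integ_nodal <- lapply(nodal, integrate_over_densities, densities = densities)
  gcols <- c("efficiency", "clustering", "path_length",
             if (compute_sigma) "sigma")
  integ_global <- vapply(gcols, function(cn)
    integrate_over_densities(glob[[cn]], densities), numeric(1L))
  structure(list(densities = densities, nodal = nodal, global = glob,
                 integrated = list(nodal = integ_nodal, global = integ_global),
                 subject = attr(fc, "subject"), session = attr(fc, "session")),
            class = "graph_profile")
}

#' @export
print.graph_profile <- function(x, ...) {
  cat(sprintf("<graph_profile> %s %s: %d densities [%.2f, %.2f], %d nodes\n",
              x$subject %||% "?", x$session %||% "?",
              length(x$densities), min(x$densities), max(x$densities),
              ncol(x$nodal$strength)))
  cat("integrated global:\n")
  print(round(x$integrated$global, 4))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a graph profile
#'
#' Long-format per-density TSV plus an integrated-values TSV.
#' @param profile a `graph_profile`.
#' @param stem output path stem.
#' @export
write_graph_profile <- function(profile, stem) {
  nd <- length(profile$densities)
  long <- do.call(rbind, lapply(names(profile$nodal), function(mn) {
    m <- profile$nodal[[mn]]
    data.frame(density = rep(profile$densities, ncol(m)),
               metric = mn, node = rep(colnames(m), each = nd),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))
  gl <- utils::stack(profile$global[, -1L])
  long <- rbind(long, data.frame(density = rep(profile$densities, 4L),
                                 metric = as.character(gl$ind),
                                 node = "global", value = gl$values))
  utils::write.table(long, paste0(stem, "_metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  integ <- rbind(
    do.call(rbind, lapply(names(profile$integrated$nodal), function(mn)
      data.frame(metric = mn, node = names(profile$integrated$nodal[[mn]]),
                 value = unname(profile$integrated$nodal[[mn]])))),
    data.frame(metric = names(profile$integrated$global), node = "global",
               value = unname(profile$integrated$global)))
  utils::write.table(integ, paste0(stem, "_integrated.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}
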