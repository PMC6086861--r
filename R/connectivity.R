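#' Fisher r-to-z transform
#'
#' `z = atanh(r)`, with correlations within `1e-7` of +/-1 clipped to
#' `+/-(1 - 1e-7)` before the transform so duplicated signals map to a
#' large finite z rather than infinity.
#'
#' @param r correlation value(s) between -1 and 1.
#' @return Fisher z value(s).
#' @examples
#' fisher_z(0.5)  # 0.5 * log(3)
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stopf("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' ROI-pairwise functional connectivity matrix
#'
#' Pearson correlation between every pair of ROI time courses on the
#' surviving frames, Fisher r-to-z transformed, diagonal fixed at zero.
#'
#' @param ts an `fc_timeseries` (already preprocessed/scrubbed).
#' @return a symmetric ROI x ROI matrix of class `fc_zmatrix` with zero
#'   diagonal; subject/session carried in attributes.
#' @export
fc_matrix <- function(ts) {
  stopifnot(inherits(ts, "fc_timeseries"))
  x <- ts$signal
  if (nrow(x) < 2L) stopf("need at least 2 frames to correlate")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance ROI(s): %s",
          paste(utils::head(colnames(x)[sds == 0], 5L), collapse = ", "))
  z <- fisher_z(stats::cor(x))
  diag(z) <- 0
  z <- (z + t(z)) / 2
  structure(z, class = c("fc_zmatrix", class(z)),
            subject = ts$subject, session = ts$session)
}

#' @export
print.fc_zmatrix <- function(x, ...) {
  cat(sprintf("<fc_zmatrix> %s %s: %d x %d, mean off-diagonal z = %.3f\n",
              attr(x, "subject"), attr(x, "session"), nrow(x), ncol(x),
              mean(x[upper.tri(x)])))
  invisible(x)
}

#' Intra- and inter-network block summary of a connectivity matrix
#'
#' Averages Fisher-z values over all ROI pairs within each system-pair
#' block. Intra-system cells average the off-diagonal pairs inside the
#' system; the matrix diagonal never contributes. Negative z values are
#' retained (the positive-only rule applies to graph construction, not to
#' block summaries). A system with fewer than 2 ROIs has an undefined intra
#' value, reported as `NA`.
#'
#' @param fc an `fc_zmatrix` (or plain symmetric matrix with ROI dimnames).
#' @param partition a `network_partition` covering the matrix ROIs.
#' @return an object of class `block_fc`: `mean_z` and `n_pairs`, both
#'   symmetric K x K matrices over the partition's systems.
#' @export
block_summary <- function(fc, partition) {
  roi <- rownames(fc)
  if (is.null(roi)) roi <- partition$roi[seq_len(nrow(fc))]
  idx <- partition_index(partition, roi)
  k <- length(idx)
  systems <- names(idx)
  mean_z <- n_pairs <- matrix(NA_real_, k, k,
                              dimnames = list(systems, systems))
  for (a in seq_len(k)) {
    for (b in a:k) {
      ia <- idx[[a]]; ib <- idx[[b]]
      if (a == b) {
        if (length(ia) < 2L) next
        sub <- fc[ia, ia, drop = FALSE]
        vals <- sub[upper.tri(sub)]
      } else {
        vals <- as.vector(fc[ia, ib, drop = FALSE])
      }
      mean_z[a, b] <- mean_z[b, a] <- mean(vals)
      n_pairs[a, b] <- n_pairs[b, a] <- length(vals)
    }
  }
  structure(list(mean_z = mean_z, n_pairs = n_pairs,
                 subject = attr(fc, "subject"), session = attr(fc, "session")),
            class = "block_fc")
}

#' @export
print.block_fc <- function(x, ...) {
  cat(sprintf("<block_fc> %d systems; mean z:\n", nrow(x$mean_z)))
  print(round(x$mean_z, 3))
  invisible(x)
}

#' Long-format view of a block summary
#'
#' @param x a `block_fc`.
#' @param ... unused.
#' @return data.frame: `system_a`, `system_b`, `mean_z`, `n_pairs` (upper
#'   triangle incl. intra cells; K(K+1)/2 rows).
#' @export
as.data.frame.block_fc <- function(x, ...) {
  k <- nrow(x$mean_z)
  ut <- which(upper.tri(x$mean_z, diag = TRUE), arr.ind = TRUE)
  data.frame(system_a = rownames(x$mean_z)[ut[, 1L]],
             system_b = colnames(x$mean_z)[ut[, 2L]],
             mean_z = x$mean_z[ut], n_pairs = x$n_pairs[ut],
             stringsAsFactors = FALSE)
}

#' Read / write connectivity matrices and block tables
#'
#' Matrices are square TSV with a ROI header row and ROI row names; block
#' tables are long-format TSV (`system_a`, `system_b`, `mean_z`, `n_pairs`).
#' @param fc an `fc_zmatrix`; `x` a `block_fc`.
#' @param path file path.
#' @export
write_fc_matrix <- function(fc, path) {
  utils::write.table(as.matrix(fc), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
  structure(m, class = c("fc_zmatrix", class(m)))
}

#' @rdname write_fc_matrix
#' @param x a `block_fc`.
#' @export
write_block_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
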