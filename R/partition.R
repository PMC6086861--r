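#' Intrinsic-network partition of a ROI set
#'
#' A partition assigns every region of interest (ROI) to exactly one
#' functional system. The default layout mirrors a common whole-brain
#' parcellation: 111 cortical ROIs spread over seven intrinsic connectivity
#' networks (salience/ventral attention, dorsal attention, default mode,
#' executive control, somatomotor, visual, limbic) plus 30 subcortical
#' regions, 141 ROIs in total. The exact ROI identities of any published
#' atlas are data, not code; this layout is a synthetic stand-in with the
#' same system sizes and block structure.
#'
#' @param roi_count total number of ROIs. For the default 141 the canonical
#'   7+1 system layout is used; other counts are split proportionally over
#'   the same eight labels (at least 2 ROIs per system).
#' @param systems character vector of system labels.
#' @return a data.frame with columns `roi` (character ROI id) and `system`
#'   (factor with one level per system), of class `network_partition`.
#' @examples
#' p <- default_partition(141)
#' table(p$system)
#' @export
default_partition <- function(roi_count = 141L,
                              systems = c("SVN", "DAN", "DMN", "ECN",
                                          "SMN", "Visual", "Limbic",
                                          "Subcortical")) {
  if (!is_count(roi_count, min = 16L))
    stopf("roi_count must be an integer >= 16, got %s", format(roi_count))
  k <- length(systems)
  if (roi_count == 141L && k == 8L) {
    sizes <- c(16L, 16L, 20L, 17L, 16L, 14L, 12L, 30L)
  } else {
    sizes <- rep(roi_count %/% k, k)
    sizes[seq_len(roi_count %% k)] <- sizes[seq_len(roi_count %% k)] + 1L
  }
  if (any(sizes < 2L))
    stopf("partition would give a system fewer than 2 ROIs; use fewer systems")
  part <- data.frame(
    roi = sprintf("ROI%03d", seq_len(roi_count)),
    system = factor(rep(systems, times = sizes), levels = systems),
    stringsAsFactors = FALSE
  )
  class(part) <- c("network_partition", "data.frame")
  part
}

#' Validate a partition against a ROI set
#'
#' @param partition a `network_partition` data.frame (`roi`, `system`).
#' @param roi_names ROI names the partition must cover (order-sensitive).
#' @return the partition, invisibly, or an error naming the mismatch.
#' @export
validate_partition <- function(partition, roi_names = NULL) {
  if (!is.data.frame(partition) || !all(c("roi", "system") %in% names(partition)))
    stopf("partition must be a data.frame with columns 'roi' and 'system'")
  if (anyDuplicated(partition$roi))
    stopf("partition assigns ROI '%s' more than once",
          partition$roi[duplicated(partition$roi)][1L])
  if (any(is.na(partition$system)))
    stopf("partition has ROIs with missing system labels")
  if (!is.null(roi_names)) {
    missing <- setdiff(roi_names, partition$roi)
    if (length(missing))
      stopf("partition-coverage error: ROI(s) %s not assigned to any system",
            paste(utils::head(missing, 5L), collapse = ", "))
    extra <- setdiff(partition$roi, roi_names)
    if (length(extra))
      stopf("partition lists unknown ROI(s): %s",
            paste(utils::head(extra, 5L), collapse = ", "))
  }
  invisible(partition)
}

#' Read / write a partition table
#'
#' Tab-separated with header columns `roi` and `system`.
#' @param path file path.
#' @return `read_partition`: a `network_partition`; `write_partition`: the
#'   path, invisibly.
#' @export
read_partition <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("roi", "system") %in% names(tab)))
    stopf("partition file %s lacks 'roi'/'system' columns", path)
  tab$system <- factor(tab$system, levels = unique(tab$system))
  class(tab) <- c("network_partition", "data.frame")
  validate_partition(tab)
  tab
}

#' @rdname read_partition
#' @param partition a `network_partition`.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(partition, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# index list: ROI indices per system, in matrix (roi_names) order
partition_index <- function(partition, roi_names) {
  validate_partition(partition, roi_names)
  idx <- match(roi_names, partition$roi)
  split(seq_along(roi_names), partition$system[idx], drop = FALSE)
}
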