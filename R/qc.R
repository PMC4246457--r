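#' Coverage uniformity QC for a pooled screen
#'
#' Pooling the per-well PCR products without normalizing their concentration
#' relies on reasonably even coverage. The uniformity rule flags every well
#' whose depth falls outside [mean/5, 5*mean] (closed interval), where the
#' mean is taken over wells that received at least one read — empty wells
#' reflect failed clones, not pooling skew, and are reported separately.
#'
#' @param perWellDepth named numeric vector of per-well read depths.
#' @return list: \code{per_well_depth}, \code{mean_depth}, \code{min_depth},
#'   \code{max_depth}, \code{bounds} (the [mean/5, 5*mean] interval),
#'   \code{uniform_fraction} (fraction of covered wells within bounds),
#'   \code{flagged_wells}, \code{empty_wells}.
#' @export
coverageQC <- function(perWellDepth) {
  if (length(perWellDepth) == 0 || all(perWellDepth < 1))
    stop("no data: every well is empty", call. = FALSE)
  if (is.null(names(perWellDepth)))
    names(perWellDepth) <- paste0("well", seq_along(perWellDepth))
  covered <- perWellDepth[perWellDepth >= 1]
  m <- mean(covered)
  bounds <- c(lower = m / 5, upper = 5 * m)
  inside <- covered >= bounds[["lower"]] & covered <= bounds[["upper"]]
  list(per_well_depth = perWellDepth,
       mean_depth = m,
       min_depth = min(covered),
       max_depth = max(covered),
       bounds = bounds,
       uniform_fraction = mean(inside),
       flagged_wells = names(covered)[!inside],
       empty_wells = names(perWellDepth)[perWellDepth < 1])
}

#' Write the coverage QC report as TSV
#'
#' @param qc result of \code{\link{coverageQC}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCoverageQC <- function(qc, path) {
  df <- data.frame(well = names(qc$per_well_depth),
                   depth = as.numeric(qc$per_well_depth),
                   stringsAsFactors = FALSE)
  df$flagged <- df$well %in% qc$flagged_wells
  df$empty <- df$well %in% qc$empty_wells
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
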