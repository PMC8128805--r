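## Gray-level run-length features in four directions.

rlm_stat_names <- c("ShrtREmp", "LngREmph", "GLevNonU", "RLNonUni", "Fraction")
rlm_dir_prefix <- c("Horzl", "Vertl", "45dgr", "135dr")

## Maximal in-mask runs along one direction. Returns a two-column matrix
## (level, length); runs are broken by the mask boundary. Directions follow
## the image convention x = column, y = row (y downward): Horzl = (1,0),
## Vertl = (0,1), 45dgr = (1,-1), 135dr = (1,1).
rlm_runs <- function(levels, direction) {
  nr <- nrow(levels); nc <- ncol(levels)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  group <- switch(direction,
                  Horzl = rows,
                  Vertl = cols,
                  `45dgr` = rows + cols,   # traversed along increasing x
                  `135dr` = cols - rows)
  ## order cells by line, then along the line
  ord <- order(as.vector(group), as.vector(cols), as.vector(rows))
  v <- as.vector(levels)[ord]
  g <- as.vector(group)[ord]
  v[is.na(v)] <- 0L           # sentinel: off-mask breaks runs
  ## breaks between lines also terminate runs
  brk <- c(TRUE, g[-1] != g[-length(g)] | v[-1] != v[-length(v)])
  run_id <- cumsum(brk)
  len <- tabulate(run_id)
  val <- v[brk]
  keep <- val > 0L
  cbind(level = val[keep], length = len[keep])
}

#' Run-length matrix features
#'
#' For each of the four scan directions (0, 45, 90 and 135 degrees) the
#' maximal runs of equal quantized gray level inside the ROI mask are
#' collected and five classical run-length statistics are emitted: short-run
#' emphasis, long-run emphasis, gray-level non-uniformity, run-length
#' non-uniformity and fraction of image in runs (number of runs divided by
#' the in-mask pixel count). Names carry the MaZda direction prefixes
#' `Horzl_`, `Vertl_`, `45dgr_`, `135dr_` (e.g. `45dgr_LngREmph`).
#'
#' @param roi a `quantized_roi`.
#' @return named numeric vector of length 20.
#' @export
rlm_features <- function(roi) {
  stopifnot(inherits(roi, "quantized_roi"))
  roi <- roi_crop(roi)
  N <- sum(roi$mask)
  out <- numeric(0)
  for (dir in rlm_dir_prefix) {
    runs <- rlm_runs(roi$levels, dir)
    if (nrow(runs) == 0) {
      vals <- rep(NA_real_, 5L)
    } else {
      l <- runs[, "length"]
      g <- runs[, "level"]
      C <- nrow(runs)
      vals <- c(sum(1 / l^2) / C,
                sum(l^2) / C,
                sum(tabulate(g)^2) / C,
                sum(tabulate(l)^2) / C,
                C / N)
    }
    names(vals) <- paste0(dir, "_", rlm_stat_names)
    out <- c(out, vals)
  }
  out
}
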