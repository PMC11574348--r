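# Tail-body momentum cross-correlogram over step-cycle-aligned epochs.
#
# C[i, j] is the Pearson correlation, computed across epochs, between the
# tail momentum at time bin i and the body momentum at time bin j (bins in
# seconds relative to the swing peak). Hotspots/coldspots are the largest
# 8-connected components of the cells in the extreme upper/lower
# percentile tails of the correlation distribution.

#' Build the tail-body cross-correlogram
#'
#' @param tail_epochs,body_epochs \code{step_cycles} objects (or plain
#'   epoch matrices, epochs in rows) of identical shape, with >= 3 epochs.
#' @param within_trial If \code{TRUE}, epochs are mean-centred before
#'   correlating, so C[i, j] reflects within-trial co-variation of tail
#'   bin i with body bin j (the off-diagonal structure is then a pure lag
#'   structure) rather than across-trial level differences.
#' @return An object of class \code{crosscorrelogram}: list with
#'   \code{matrix} (tail bins in rows), \code{n_trials}, \code{bin_times}.
#'   Bins with zero across-epoch variance yield \code{NA} entries, which
#'   are excluded from percentile pools.
#' @export
build_correlogram <- function(tail_epochs, body_epochs,
                              within_trial = FALSE) {
  te <- if (inherits(tail_epochs, "step_cycles")) tail_epochs$epochs
        else as.matrix(tail_epochs)
  be <- if (inherits(body_epochs, "step_cycles")) body_epochs$epochs
        else as.matrix(body_epochs)
  if (!all(dim(te) == dim(be)))
    stop("tail and body epoch sets must have identical shape")
  if (nrow(te) < 3) stop("need >= 3 epochs for a correlogram")
  if (within_trial) {
    te <- te - rowMeans(te)
    be <- be - rowMeans(be)
  }
  C <- suppressWarnings(stats::cor(te, be))  # bins x bins across epochs
  C[!is.finite(C)] <- NA
  bt <- if (inherits(tail_epochs, "step_cycles")) tail_epochs$bin_times
        else seq_len(ncol(te))
  structure(list(matrix = C, n_trials = nrow(te), bin_times = bt),
            class = "crosscorrelogram")
}

#' @export
print.crosscorrelogram <- function(x, ...) {
  cat("Cross-correlogram:", nrow(x$matrix), "x", ncol(x$matrix),
      "bins across", x$n_trials, "epochs\n")
  rng <- range(x$matrix, na.rm = TRUE)
  cat("  correlation range", round(rng[1], 3), "..", round(rng[2], 3), "\n")
  invisible(x)
}

# 8-connected components of a logical matrix; returns a list of cell-index
# matrices (row, col), largest first
connected_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comps <- list()
  k <- 0L
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  for (start in which(mask & lab == 0L)) {
    k <- k + 1L
    queue <- start
    lab[start] <- k
    cells <- start
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% nrow(mask) + 1L
      c0 <- (cur - 1L) %/% nrow(mask) + 1L
      rr <- r + nb$dr; cc <- c0 + nb$dc
      ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
      idx <- (cc[ok] - 1L) * nrow(mask) + rr[ok]
      idx <- idx[mask[idx] & lab[idx] == 0L]
      if (length(idx)) {
        lab[idx] <- k
        queue <- c(queue, idx)
        cells <- c(cells, idx)
      }
    }
    comps[[k]] <- cbind(row = (cells - 1L) %% nrow(mask) + 1L,
                        col = (cells - 1L) %/% nrow(mask) + 1L)
  }
  comps[order(vapply(comps, nrow, integer(1)), decreasing = TRUE)]
}

#' Detect hotspot and coldspot regions
#'
#' Cells in the upper \code{pct} percent tail (hotspots) and lower tail
#' (coldspots) of the correlation distribution are collected; within each
#' set the largest 8-connected region is returned (ties broken by larger
#' absolute mean correlation).
#'
#' @param C A \code{crosscorrelogram}.
#' @param pct Tail percentage (0 < pct < 50; default 5, i.e. the 5th and
#'   95th percentiles).
#' @return List with \code{hotspot} and \code{coldspot}, each a list with
#'   \code{cells} (matrix of row/col indices, possibly empty),
#'   \code{size}, \code{mean_correlation} and \code{threshold}.
#' @export
find_extreme_regions <- function(C, pct = 5) {
  stopifnot(inherits(C, "crosscorrelogram"))
  if (pct <= 0 || pct >= 50) stop("pct must lie in (0, 50)")
  vals <- C$matrix[is.finite(C$matrix)]
  if (!length(vals)) stop("correlogram has no defined cells")
  hi <- stats::quantile(vals, 1 - pct / 100, names = FALSE)
  lo <- stats::quantile(vals, pct / 100, names = FALSE)
  pick <- function(mask, kind, thr) {
    mask[is.na(mask)] <- FALSE
    if (!any(mask))
      return(list(kind = kind, cells = cbind(row = integer(0),
                                             col = integer(0)),
                  size = 0L, mean_correlation = NA_real_, threshold = thr))
    comps <- connected_components(mask)
    sizes <- vapply(comps, nrow, integer(1))
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
      # ties: the more extreme mean correlation, in the tail's direction
      mc <- vapply(comps[best], function(cl) mean(C$matrix[cl]), numeric(1))
      best <- best[if (kind == "hotspot") which.max(mc) else which.min(mc)]
    } else best <- best[1]
    cl <- comps[[best]]
    list(kind = kind, cells = cl, size = nrow(cl),
         mean_correlation = mean(C$matrix[cl]), threshold = thr)
  }
  list(hotspot = pick(C$matrix >= hi & is.finite(C$matrix), "hotspot", hi),
       coldspot = pick(C$matrix <= lo & is.finite(C$matrix), "coldspot", lo))
}

#' Correlogram diagonal
#'
#' Zero-lag (same time bin) correlation between tail and body momentum
#' through the step cycle.
#'
#' @param C A \code{crosscorrelogram} (square matrix).
#' @return Data.frame with \code{bin_time} (s relative to the swing peak)
#'   and \code{correlation}.
#' @export
correlogram_diagonal <- function(C) {
  stopifnot(inherits(C, "crosscorrelogram"))
  m <- C$matrix
  if (nrow(m) != ncol(m)) stop("correlogram must be square")
  data.frame(bin_time = C$bin_times, correlation = diag(m))
}
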