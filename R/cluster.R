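# Recruitment counting and neutrophil cluster-size statistics at the wound.

#' Count recruited cells near the wound
#'
#' Number of cell centroids inside the axis-aligned square of side
#' \code{2 * halfWidthUm} centred on the wound (default a 200 x 200 um
#' square); membership is closed (boundary counts).
#'
#' @param centroids data.frame or matrix with columns (x, y) in
#'   micrometres; optionally a \code{frame} column for per-frame counts.
#' @param woundCenter numeric (x, y) of the wound centre in micrometres.
#' @param halfWidthUm half-width of the square in micrometres (default
#'   100).
#' @return if \code{centroids} has a \code{frame} column, a data.frame
#'   \code{frame, count}; otherwise a single integer count.
#' @export
recruitmentCount <- function(centroids, woundCenter, halfWidthUm = 100) {
  cen <- as.data.frame(centroids)
  names(cen)[1:2] <- c("x", "y")
  inSq <- abs(cen$x - woundCenter[1]) <= halfWidthUm &
    abs(cen$y - woundCenter[2]) <= halfWidthUm
  if ("frame" %in% names(cen)) {
    out <- stats::aggregate(inSq, by = list(frame = cen$frame),
                            FUN = sum)
    names(out)[2] <- "count"
    out
  } else sum(inSq)
}

#' Mean neutrophil cluster size over a time window
#'
#' Drops segmented surfaces with area strictly below \code{minAreaUm2}
#' (spurious detections; objects exactly at the threshold are retained)
#' and averages the remaining areas across all retained object-frame
#' observations within the time window. Per-frame means are available as
#' an alternative aggregation.
#'
#' @param records data.frame with columns \code{frame, area_um2} (e.g. one
#'   row per segmented object per frame).
#' @param minAreaUm2 area filter in square micrometres (default 60).
#' @param window numeric (first, last) frame of the averaging window;
#'   default all frames.
#' @param perFrame if TRUE, average within frames first, then across
#'   frames.
#' @return list with \code{mean} (NA with a warning when nothing is
#'   retained), \code{n} retained observations, and \code{excluded} count.
#' @export
clusterSize <- function(records, minAreaUm2 = 60, window = NULL,
                        perFrame = FALSE) {
  df <- as.data.frame(records)
  if (!is.null(window))
    df <- df[df$frame >= window[1] & df$frame <= window[2], , drop = FALSE]
  if (nrow(df) == 0L) stop("window does not overlap the data")
  small <- df$area_um2 < minAreaUm2
  for (i in which(small))
    .logExclusion("clusterSize", sprintf("frame %s object %d", df$frame[i], i),
                  sprintf("area %.1f um^2 < %g um^2", df$area_um2[i],
                          minAreaUm2))
  kept <- df[!small, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("no objects retained by the area filter")
    return(list(mean = NA_real_, n = 0L, excluded = sum(small)))
  }
  m <- if (perFrame) mean(tapply(kept$area_um2, kept$frame, mean))
  else mean(kept$area_um2)
  list(mean = m, n = nrow(kept), excluded = sum(small))
}

#' Candidate owa from a maximum-intensity time projection
#'
#' Computes the pixelwise maximum-intensity projection over time,
#' thresholds it (high-density neutrophil areas are distinguishable by
#' intensity), and returns the polygonal outline of the largest connected
#' component as a candidate occupied wound area. The result is a starting
#' point; the final owa remains user-editable.
#'
#' @param frames list of numeric intensity matrices (one per time point).
#' @param threshold intensity threshold on the projection.
#' @param minAreaPx smallest acceptable component (default 50 px).
#' @param pixelSize micrometres per pixel.
#' @return an [OwaPolygon-class] in micrometres.
#' @export
owaFromTimeProjection <- function(frames, threshold, minAreaPx = 50L,
                                  pixelSize = 1) {
  stopifnot(length(frames) >= 1L)
  proj <- Reduce(pmax, frames)
  bw <- proj >= threshold
  lab <- EBImage::bwlabel(bw * 1L)
  if (max(lab) == 0) stop("owa error: empty component after thresholding")
  areas <- tabulate(lab[lab > 0])
  big <- which.max(areas)
  if (areas[big] < minAreaPx)
    stop("owa error: largest component below the area floor")
  comp <- EBImage::fillHull((lab == big) * 1L)
  oc <- EBImage::ocontour(comp)[[1]]
  # ocontour returns 0-based (x, y) pixel indices along the boundary;
  # thin to every other vertex to keep the polygon simple and light
  v <- oc[seq(1, nrow(oc), by = 2), , drop = FALSE]
  owaPolygon((v + 0.5) * pixelSize)
}
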