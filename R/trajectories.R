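# Track ingestion, forward/reverse classification against the owa, and the
# motility statistics: instantaneous speed, distance-to-owa, approach-angle
# cosine, straightness, net reverse traffic.

#' Load and filter cell trajectories
#'
#' Reads trajectories from a CSV spot export (columns
#' \code{track_id, t_s, x_um, y_um}, optionally \code{label}) or a
#' data.frame. Points outside the fin polygon, when one is supplied, are
#' dropped before the duration filter (movement outside the fin, e.g. in
#' the CHT, is excluded from interstitial analyses). Tracks shorter than
#' \code{minDuration} time points are then removed (the three-time-point
#' duration threshold excludes short-lived tracks; a 3-point track is
#' retained). Optionally restricts to an analysis time window.
#'
#' @param tracks path to a CSV file or a data.frame.
#' @param minDuration minimum number of time points (default 3, inclusive).
#' @param finPolygon optional [OwaPolygon-class]; points outside are
#'   dropped first.
#' @param timeWindow optional numeric (t0, t1) in seconds; points outside
#'   are dropped before filtering.
#' @return data.frame of retained points, sorted by track and time, with an
#'   \code{attr(, "excluded")} data.frame recording dropped tracks and
#'   reasons.
#' @export
loadTracks <- function(tracks, minDuration = 3L, finPolygon = NULL,
                       timeWindow = NULL) {
  df <- if (is.character(tracks)) {
    tr <- try(utils::read.csv(tracks, stringsAsFactors = FALSE),
              silent = TRUE)
    if (inherits(tr, "try-error")) stop("parse error reading ", tracks)
    tr
  } else as.data.frame(tracks)
  need <- c("track_id", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("parse error: required columns ", paste(need, collapse = ","))
  bad <- which(!is.finite(df$t_s) | !is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad))
    stop("parse error at line(s) ", paste(utils::head(bad + 1L, 5),
                                          collapse = ", "),
         ": non-finite coordinates")
  df <- df[order(df$track_id, df$t_s), , drop = FALSE]
  mono <- tapply(df$t_s, df$track_id, function(tt) all(diff(tt) > 0))
  if (!all(mono))
    stop("data error: non-monotone time within track ",
         names(mono)[!mono][1])
  if (!is.null(timeWindow))
    df <- df[df$t_s >= timeWindow[1] & df$t_s <= timeWindow[2], ,
             drop = FALSE]
  if (!is.null(finPolygon))
    df <- df[pointInPolygon(df$x_um, df$y_um, finPolygon), , drop = FALSE]
  counts <- table(df$track_id)
  short <- names(counts)[counts < minDuration]
  for (id in short)
    .logExclusion("loadTracks", id,
                  sprintf("%d time point(s) < duration threshold %d",
                          counts[[id]], minDuration))
  out <- df[!df$track_id %in% short, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(
    track_id = short,
    reason = rep("below duration threshold", length(short)))
  out
}

.classifyOne <- function(x, y, owa) {
  ins <- pointInPolygon(x, y, owa)
  n <- length(x)
  if (!any(ins)) {
    d0 <- distanceToOwa(x[1], y[1], owa)
    d1 <- distanceToOwa(x[n], y[n], owa)
    cat_ <- if (d1 < d0) "forward_nonintersecting" else "away_nonintersecting"
    return(list(category = cat_, fwd = NULL, rev = NULL))
  }
  firstIn <- which(ins)[1]
  lastIn <- which(ins)[length(which(ins))]
  fwd <- if (firstIn > 1L) c(1L, firstIn - 1L) else NULL
  rev <- if (lastIn < n) c(lastIn, n) else NULL
  cat_ <- if (!is.null(rev)) "reverse"
  else if (!is.null(fwd)) "forward_intersecting"
  else "unclassified_inside"
  list(category = cat_, fwd = fwd, rev = rev)
}

#' Classify tracks as forward/reverse relative to the owa
#'
#' A track intersecting the owa with its first point outside yields a
#' forward segment running from its first point to the last point before
#' first entry (points after intersection are excluded from the forward
#' segment). If points exist after its final in-owa residence, it also
#' yields a reverse segment from the last in-owa point to the track end.
#' Non-intersecting tracks are labelled forward- or away-moving according
#' to whether the track end is closer to the owa than its start. Tracks
#' that never leave the owa and have no prior outside point are reported as
#' \code{unclassified_inside}.
#'
#' @param tracks data.frame from [loadTracks()].
#' @param owa an [OwaPolygon-class].
#' @return data.frame with one row per track: \code{track_id, category,
#'   fwd_start, fwd_end, rev_start, rev_end} (point indices within the
#'   track, NA when absent).
#' @export
classifyTracks <- function(tracks, owa) {
  idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    s <- tracks[idx[[as.character(id)]], , drop = FALSE]
    cl <- .classifyOne(s$x_um, s$y_um, owa)
    data.frame(track_id = id, category = cl$category,
               fwd_start = if (is.null(cl$fwd)) NA_integer_ else cl$fwd[1],
               fwd_end = if (is.null(cl$fwd)) NA_integer_ else cl$fwd[2],
               rev_start = if (is.null(cl$rev)) NA_integer_ else cl$rev[1],
               rev_end = if (is.null(cl$rev)) NA_integer_ else cl$rev[2])
  })
  do.call(rbind, out)
}

#' Per-step motility records
#'
#' For each consecutive point pair of each track computes the instantaneous
#' speed \eqn{v_t = |\Delta r| / \Delta t} (micrometres/minute), the
#' distance \eqn{d_t} from the step's start point to the nearest
#' owa-perimeter point (0 inside the owa), and the approach-angle cosine
#' \eqn{\cos\theta_t} between the step displacement and the vector from the
#' start point to the nearest perimeter point (+1 directly toward the owa,
#' -1 directly away; undefined for zero-displacement steps and in-owa
#' starts). Each step carries the phase (forward/reverse/unclassified) of
#' the segment its start index falls in.
#'
#' @param tracks data.frame from [loadTracks()].
#' @param owa an [OwaPolygon-class].
#' @param classifications optional output of [classifyTracks()]; computed
#'   when missing.
#' @return data.frame \code{track_id, t, v_t, d_t, cos_theta, inside_owa,
#'   phase}, one row per step (n - 1 per track).
#' @export
stepRecords <- function(tracks, owa, classifications = NULL) {
  if (is.null(classifications)) classifications <- classifyTracks(tracks, owa)
  idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  clIdx <- split(seq_len(nrow(classifications)), classifications$track_id)
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    s <- tracks[idx[[as.character(id)]], , drop = FALSE]
    n <- nrow(s)
    if (n < 2L) return(NULL)
    dt <- diff(s$t_s)
    if (any(dt <= 0)) stop("data error: non-positive time step in track ", id)
    dx <- diff(s$x_um); dy <- diff(s$y_um)
    disp <- sqrt(dx^2 + dy^2)
    v <- disp / (dt / 60)
    x0 <- s$x_um[-n]; y0 <- s$y_um[-n]
    npp <- nearestPerimeterPoint(x0, y0, owa)
    inside <- pointInPolygon(x0, y0, owa)
    d <- npp$dist; d[inside] <- 0
    tx <- npp$nx - x0; ty <- npp$ny - y0
    tn <- sqrt(tx^2 + ty^2)
    cosT <- (dx * tx + dy * ty) / (disp * tn)
    cosT[inside | disp == 0 | tn == 0] <- NA_real_
    cosT <- pmin(pmax(cosT, -1), 1)
    cl <- classifications[clIdx[[as.character(id)]], , drop = FALSE]
    phase <- rep("unclassified", n - 1L)
    if (nrow(cl) == 1L) {
      if (!is.na(cl$fwd_start)) {
        # the step leaving the last pre-entry point still starts outside
        idx <- seq.int(cl$fwd_start, min(cl$fwd_end, n - 1L))
        phase[idx] <- "forward"
      }
      if (!is.na(cl$rev_start)) {
        idx <- seq.int(cl$rev_start, cl$rev_end - 1L)
        phase[idx] <- "reverse"
      }
    }
    data.frame(track_id = id, t = s$t_s[-n], v_t = v, d_t = d,
               cos_theta = cosT, inside_owa = inside, phase = phase)
  })
  do.call(rbind, out)
}

.binnedProfile <- function(value, binVar, binEdges, group = NULL,
                           perCell = FALSE) {
  bin <- findInterval(binVar, binEdges, rightmost.closed = TRUE)
  keep <- bin >= 1 & bin <= length(binEdges) - 1 & is.finite(value)
  do.call(rbind, lapply(seq_len(length(binEdges) - 1L), function(b) {
    sel <- keep & bin == b
    v <- value[sel]
    if (perCell && length(v)) {
      g <- group[sel]
      v <- tapply(v, g, mean)
    }
    data.frame(bin_lo = binEdges[b], bin_hi = binEdges[b + 1L],
               mean = if (length(v)) mean(v) else NA_real_,
               sem = .sem(v), n = length(v))
  }))
}

.scopeSteps <- function(steps, classifications,
                        scope = c("forward_all", "reverse", "all")) {
  scope <- match.arg(scope)
  if (scope == "all") return(steps)
  if (scope == "reverse") return(steps[steps$phase == "reverse", ,
                                       drop = FALSE])
  # forward_all: forward segments of intersecting tracks plus all steps of
  # non-intersecting toward-moving tracks
  fwdNon <- classifications$track_id[
    classifications$category == "forward_nonintersecting"]
  steps[steps$phase == "forward" | steps$track_id %in% fwdNon, ,
        drop = FALSE]
}

#' Speed-vs-distance profile
#'
#' Mean instantaneous speed per distance-from-owa bin. The forward scope
#' pools forward segments of owa-intersecting tracks with all steps of
#' non-intersecting but toward-moving tracks. Aggregation is either across
#' cell steps, or per cell first (average speed per track within each bin,
#' then across tracks).
#'
#' @param steps data.frame from [stepRecords()].
#' @param classifications data.frame from [classifyTracks()].
#' @param binEdges distance bin edges in micrometres (default 25-um bins up
#'   to the data maximum).
#' @param scope \code{"forward_all"}, \code{"reverse"} or \code{"all"}.
#' @param aggregation \code{"per_step"} or \code{"per_cell"}.
#' @return data.frame \code{bin_lo, bin_hi, mean, sem, n}; empty scope
#'   yields all-NA means with a warning.
#' @export
speedVsDistance <- function(steps, classifications, binEdges = NULL,
                            scope = c("forward_all", "reverse", "all"),
                            aggregation = c("per_step", "per_cell")) {
  scope <- match.arg(scope)
  aggregation <- match.arg(aggregation)
  s <- .scopeSteps(steps, classifications, scope)
  if (is.null(binEdges))
    binEdges <- seq(0, max(25, 25 * ceiling(max(s$d_t, 0) / 25)), by = 25)
  if (nrow(s) == 0L) {
    warning("empty scope: no steps to profile")
    return(.binnedProfile(numeric(), numeric(), binEdges))
  }
  .binnedProfile(s$v_t, s$d_t, binEdges, group = s$track_id,
                 perCell = aggregation == "per_cell")
}

#' Speed-vs-orientation profile
#'
#' Mean instantaneous speed per approach-angle-cosine bin, restricted to
#' the zone within \code{zoneUm} of the owa perimeter (excluding in-owa
#' steps, where the cosine is undefined).
#'
#' @param steps data.frame from [stepRecords()].
#' @param binEdges cosine bin edges over [-1, 1] (default 8 bins of 0.25).
#' @param zoneUm zone half-width in micrometres (default 50: steps with
#'   \code{0 < d_t <= zoneUm}).
#' @param aggregation \code{"per_step"} or \code{"per_cell"}.
#' @return data.frame \code{bin_lo, bin_hi, mean, sem, n}.
#' @export
speedVsCosine <- function(steps, binEdges = seq(-1, 1, by = 0.25),
                          zoneUm = 50,
                          aggregation = c("per_step", "per_cell")) {
  aggregation <- match.arg(aggregation)
  s <- steps[is.finite(steps$cos_theta) & steps$d_t > 0 &
               steps$d_t <= zoneUm, , drop = FALSE]
  if (nrow(s) == 0L) {
    warning("empty zone: no steps with defined cos theta")
    return(.binnedProfile(numeric(), numeric(), binEdges))
  }
  .binnedProfile(s$v_t, s$cos_theta, binEdges, group = s$track_id,
                 perCell = aggregation == "per_cell")
}

#' Track straightness near the owa
#'
#' Restricts a track to its points within \code{zoneUm} of the owa (in-owa
#' points count as distance 0 and are included), in temporal order, and
#' returns the net displacement between the first and last retained point
#' divided by the cumulative path length over them. Tracks whose restricted
#' cumulative path is shorter than \code{minPathUm} are excluded (too
#' little movement for a representative straightness), as are tracks with
#' fewer than two zone points.
#'
#' @param tracks data.frame from [loadTracks()].
#' @param owa an [OwaPolygon-class].
#' @param zoneUm zone width in micrometres (default 50).
#' @param minPathUm minimum cumulative path length in micrometres
#'   (default 10).
#' @return data.frame \code{track_id, straightness, cumulative_um,
#'   excluded, reason}; straightness is NA for excluded tracks.
#' @export
trackStraightness <- function(tracks, owa, zoneUm = 50, minPathUm = 10) {
  idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    s <- tracks[idx[[as.character(id)]], , drop = FALSE]
    d <- distanceToOwa(s$x_um, s$y_um, owa)
    z <- s[d <= zoneUm, , drop = FALSE]
    if (nrow(z) < 2L) {
      .logExclusion("straightness", id, "fewer than 2 points in zone")
      return(data.frame(track_id = id, straightness = NA_real_,
                        cumulative_um = NA_real_, excluded = TRUE,
                        reason = "fewer than 2 zone points"))
    }
    seg <- sqrt(diff(z$x_um)^2 + diff(z$y_um)^2)
    cum <- sum(seg)
    if (cum < minPathUm) {
      .logExclusion("straightness", id,
                    sprintf("restricted path %.2f um < %g um", cum,
                            minPathUm))
      return(data.frame(track_id = id, straightness = NA_real_,
                        cumulative_um = cum, excluded = TRUE,
                        reason = "restricted path below minimum"))
    }
    net <- sqrt((z$x_um[nrow(z)] - z$x_um[1])^2 +
                  (z$y_um[nrow(z)] - z$y_um[1])^2)
    data.frame(track_id = id, straightness = net / cum,
               cumulative_um = cum, excluded = FALSE, reason = "")
  })
  do.call(rbind, out)
}

#' Net reverse traffic
#'
#' The number of reverse track segments divided by the number of
#' owa-intersecting forward tracks. Tracks not intersecting the owa are
#' excluded from both counts, so the ratio measures dispersal among cells
#' that actually reached the wound cluster.
#'
#' @param classifications data.frame from [classifyTracks()].
#' @return list with \code{n_forward_intersecting}, \code{n_reverse} and
#'   \code{ratio} (NA with a warning when no track entered the owa).
#' @examples
#' cl <- data.frame(track_id = 1:4,
#'                  category = c("reverse", "reverse",
#'                               "forward_intersecting",
#'                               "forward_intersecting"),
#'                  fwd_start = 1, fwd_end = 2, rev_start = c(3, 3, NA, NA),
#'                  rev_end = c(5, 5, NA, NA))
#' netReverseTraffic(cl)$ratio  # 0.5
#' @export
netReverseTraffic <- function(classifications) {
  entered <- !is.na(classifications$fwd_start) &
    classifications$category %in% c("forward_intersecting", "reverse")
  nFwd <- sum(entered)
  nRev <- sum(!is.na(classifications$rev_start))
  if (nFwd == 0L) {
    warning("net reverse traffic undefined: no forward-intersecting track")
    return(list(n_forward_intersecting = 0L, n_reverse = nRev,
                ratio = NA_real_))
  }
  list(n_forward_intersecting = nFwd, n_reverse = nRev,
       ratio = nRev / nFwd)
}

#' Mean speed within the owa
#'
#' Mean instantaneous speed over steps whose start point lies inside the
#' owa, optionally aggregated per cohort.
#'
#' @param steps data.frame from [stepRecords()].
#' @param cohort optional factor of the same length as \code{nrow(steps)};
#'   when given, the mean and SEM are reported per cohort level.
#' @return data.frame \code{cohort, mean, sem, n}; a single row with
#'   cohort \code{"all"} when no cohort is given. NA mean with a warning
#'   when no step starts inside the owa.
#' @export
speedWithinOwa <- function(steps, cohort = NULL) {
  if (is.null(cohort)) cohort <- rep("all", nrow(steps))
  sel <- steps$inside_owa
  if (!any(sel)) {
    warning("no steps start inside the owa")
    return(data.frame(cohort = unique(cohort), mean = NA_real_,
                      sem = NA_real_, n = 0L))
  }
  v <- steps$v_t[sel]; g <- cohort[sel]
  do.call(rbind, lapply(unique(g), function(cc) {
    vv <- v[g == cc]
    data.frame(cohort = cc, mean = mean(vv), sem = .sem(vv),
               n = length(vv))
  }))
}
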