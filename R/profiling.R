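# From T2 map + tendon mask to the length-normalized T2 distribution
# profile: partial-volume filtering, geodesic length parameterization from
# the footprint (lateral) end to the musculotendinous (medial) end, equal-
# width binning of mean T2 over percent length, and three-segment summaries.

#' Tendon mask with designated ends
#'
#' A binary mask of tendon voxels together with two seed voxels marking the
#' lateral (footprint) and medial (musculotendinous junction) ends of the
#' tendon.  The mask must form a single 8-connected component containing
#' both seeds.
#'
#' @param voxels Logical matrix on the map grid.
#' @param lateral_seed,medial_seed Integer (row, col) coordinates of the two
#'   end voxels; both must lie inside the mask.
#' @return An object of class \code{tendon_mask}.
#' @export
tendon_mask <- function(voxels, lateral_seed, medial_seed) {
  stopifnot(is.matrix(voxels))
  voxels <- voxels != 0
  lateral_seed <- as.integer(lateral_seed)[1:2]
  medial_seed <- as.integer(medial_seed)[1:2]
  for (s in list(lateral_seed, medial_seed)) {
    if (any(s < 1L) || s[1] > nrow(voxels) || s[2] > ncol(voxels) ||
        !voxels[s[1], s[2]]) {
      stop("seed voxel lies outside the mask", call. = FALSE)
    }
  }
  comp <- connected_component(voxels, lateral_seed)
  if (!comp[medial_seed[1], medial_seed[2]]) {
    stop("mask is disconnected: medial seed not reachable from lateral seed",
         call. = FALSE)
  }
  if (sum(comp) != sum(voxels)) {
    stop(sprintf("mask is not a single connected component (%d of %d voxels reachable)",
                 sum(comp), sum(voxels)), call. = FALSE)
  }
  structure(list(voxels = voxels, lateral_seed = lateral_seed,
                 medial_seed = medial_seed),
            class = "tendon_mask")
}

# 8-connected flood fill from a seed
connected_component <- function(voxels, seed) {
  nr <- nrow(voxels); nc <- ncol(voxels)
  comp <- matrix(FALSE, nr, nc)
  stack <- (seed[2] - 1L) * nr + seed[1]
  comp[stack] <- TRUE
  shifts <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  while (length(stack)) {
    cur <- stack
    stack <- integer(0)
    for (s in shifts) {
      nb <- cur + s
      r0 <- (cur - 1L) %% nr + 1L
      ok <- nb >= 1L & nb <= nr * nc
      # forbid row wrap-around across column boundaries
      dr <- abs(((nb - 1L) %% nr + 1L) - r0)
      ok <- ok & dr <= 1L
      nb <- nb[ok]
      nb <- nb[voxels[nb] & !comp[nb]]
      if (length(nb)) {
        comp[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
    stack <- unique(stack)
  }
  comp
}

#' Filter a T2 map for noise and partial-volume effects
#'
#' Keeps mask voxels whose fit is valid, whose T2 lies within
#' \code{t2_bounds}, and whose fit quality r2 is at least \code{r2_min}.
#' The default bounds (5, 120) ms with r2 >= 0.7 are chosen to exclude
#' low-signal bone (very short T2, poor fits) and bursal fluid (very long
#' T2) while keeping even markedly degenerated tendon.
#'
#' @param map A \code{\link{t2_map}}.
#' @param mask A \code{\link{tendon_mask}} or logical matrix.
#' @param t2_bounds Numeric (lo, hi) in ms, lo < hi.
#' @param r2_min Minimum coefficient of determination in [0, 1].
#' @return An object of class \code{t2_filter}: logical \code{keep} matrix
#'   and a \code{removed} count per criterion (invalid fit, T2 below lo, T2
#'   above hi, r2 below threshold; a voxel counts once, tested in that
#'   order).  Warns when more than half the mask is removed.
#' @export
filter_t2_map <- function(map, mask, t2_bounds = c(5, 120), r2_min = 0.7) {
  stopifnot(inherits(map, "t2_map"), length(t2_bounds) == 2L,
            t2_bounds[1] < t2_bounds[2], r2_min >= 0, r2_min <= 1)
  m <- if (inherits(mask, "tendon_mask")) mask$voxels else mask
  if (!identical(dim(m), dim(map$t2))) {
    stop("mask grid does not match the T2 map grid", call. = FALSE)
  }
  n_mask <- sum(m)
  invalid <- m & !map$valid
  low <- m & map$valid & map$t2 < t2_bounds[1]
  high <- m & map$valid & map$t2 > t2_bounds[2]
  badr2 <- m & map$valid & map$t2 >= t2_bounds[1] & map$t2 <= t2_bounds[2] &
    (is.na(map$r2) | map$r2 < r2_min)
  keep <- m & map$valid & !low & !high & !badr2
  removed <- c(invalid_fit = sum(invalid), t2_low = sum(low),
               t2_high = sum(high), r2_low = sum(badr2))
  if (n_mask > 0 && sum(keep) < n_mask / 2) {
    warning(sprintf("filter removed %d of %d mask voxels (> 50%%)",
                    n_mask - sum(keep), n_mask), call. = FALSE)
  }
  structure(list(keep = keep, removed = removed, n_mask = n_mask,
                 n_kept = sum(keep), t2_bounds = t2_bounds, r2_min = r2_min),
            class = "t2_filter")
}

#' Geodesic length parameterization of a tendon mask
#'
#' Assigns every mask voxel a normalized along-tendon coordinate based on
#' within-mask geodesic distances (shortest paths on the 8-connected voxel
#' graph with physical step lengths).  With d_lat and d_med the geodesic
#' distances of a voxel from the lateral and medial seeds and
#' L = d_lat(medial seed) the seed-to-seed geodesic length, the position is
#'   100 * (d_lat - d_med + L) / (2 L),
#' clamped into [0, 100].  Using the difference of the two distance fields
#' cancels the transverse detour a voxel off the central axis pays towards
#' either seed, so on a straight band the coordinate reduces exactly to the
#' axis coordinate.  The lateral seed sits at 0 %, the medial seed at
#' 100 %; end-cap voxels beyond a seed are clamped to that end.
#'
#' @param mask A \code{\link{tendon_mask}}.
#' @param voxel_spacing In-plane voxel size in mm (scalar, isotropic).
#' @return An object of class \code{length_field}: \code{position} matrix
#'   (percent, NA outside mask) and \code{tendon_length_mm}, the geodesic
#'   footprint-to-junction distance.
#' @export
parameterize_length <- function(mask, voxel_spacing = 1) {
  stopifnot(inherits(mask, "tendon_mask"), voxel_spacing > 0)
  vox <- mask$voxels
  nr <- nrow(vox); nc <- ncol(vox)
  idx <- which(vox)
  id_of <- match(seq_len(nr * nc), idx)  # grid index -> node id

  # 8-neighbour edges (each undirected pair once: E, S, SE, NE)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  edges <- list(); weights <- list()
  step <- list(E = c(0L, 1L, 1), S = c(1L, 0L, 1),
               SE = c(1L, 1L, sqrt(2)), NE = c(-1L, 1L, sqrt(2)))
  for (s in step) {
    r2 <- rows + s[1]; c2 <- cols + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    src <- idx[ok]
    in_mask <- vox[nb]
    edges[[length(edges) + 1L]] <- rbind(id_of[src[in_mask]], id_of[nb[in_mask]])
    weights[[length(weights) + 1L]] <- rep(s[3], sum(in_mask))
  }
  g <- igraph::make_graph(edges = c(do.call(cbind, edges)),
                          n = length(idx), directed = FALSE)
  w <- unlist(weights) * voxel_spacing
  lat_id <- id_of[(mask$lateral_seed[2] - 1L) * nr + mask$lateral_seed[1]]
  med_id <- id_of[(mask$medial_seed[2] - 1L) * nr + mask$medial_seed[1]]
  d_lat <- as.vector(igraph::distances(g, v = lat_id, weights = w))
  d_med <- as.vector(igraph::distances(g, v = med_id, weights = w))
  if (any(!is.finite(d_lat)) || any(!is.finite(d_med))) {
    stop("mask is disconnected: some voxels unreachable from the seeds",
         call. = FALSE)
  }
  len <- d_lat[med_id]
  if (len <= 0) stop("lateral and medial seeds coincide", call. = FALSE)
  pos_vec <- pmin(100, pmax(0, 100 * (d_lat - d_med + len) / (2 * len)))
  position <- matrix(NA_real_, nr, nc)
  position[idx] <- pos_vec
  structure(list(position = position, tendon_length_mm = len, mask = mask),
            class = "length_field")
}

#' Bin a filtered T2 map into a length-normalized distribution profile
#'
#' Equal-width bins partition [0, 100] percent of tendon length; each bin's
#' value is the arithmetic mean T2 of the filtered voxels whose position
#' falls in it (half-open bins, last bin closed).  Empty bins are kept with
#' count 0 and NA mean.
#'
#' @param map A \code{\link{t2_map}}.
#' @param filtered A \code{\link{t2_filter}} or logical keep matrix.
#' @param length_field A \code{\link{parameterize_length}} result.
#' @param n_bins Number of bins (>= 3; default 100, i.e. 1 % bins).
#' @return An object of class \code{t2_profile}: \code{bin_centers} (percent),
#'   \code{bin_means} (ms), \code{bin_counts}, \code{n_bins}.
#' @export
bin_profile <- function(map, filtered, length_field, n_bins = 100L) {
  stopifnot(inherits(map, "t2_map"), inherits(length_field, "length_field"),
            n_bins >= 3L)
  keep <- if (inherits(filtered, "t2_filter")) filtered$keep else filtered
  idx <- which(keep)
  if (!length(idx)) stop("no filtered voxels to bin", call. = FALSE)
  pos <- length_field$position[idx]
  if (anyNA(pos)) {
    stop("filtered voxels outside the length field; filter within the mask",
         call. = FALSE)
  }
  width <- 100 / n_bins
  bin <- pmin(floor(pos / width) + 1L, n_bins)  # last bin closed at 100
  t2 <- map$t2[idx]
  counts <- tabulate(bin, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(t2[bin == b]), numeric(1))
  means <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  structure(list(bin_centers = (seq_len(n_bins) - 0.5) * width,
                 bin_means = means, bin_counts = counts,
                 n_bins = as.integer(n_bins)),
            class = "t2_profile")
}

#' @export
print.t2_profile <- function(x, ...) {
  cat(sprintf("<t2_profile> %d bins, %d voxels, %d empty bins\n",
              x$n_bins, sum(x$bin_counts), sum(x$bin_counts == 0)))
  invisible(x)
}

#' Convert a profile to a data frame
#'
#' @param x A \code{t2_profile}.
#' @param ... Unused.
#' @return Data frame with columns \code{bin_center_pct}, \code{mean_t2_ms},
#'   \code{n_voxels}, \code{segment}.
#' @export
as.data.frame.t2_profile <- function(x, ...) {
  data.frame(bin_center_pct = x$bin_centers,
             mean_t2_ms = x$bin_means,
             n_voxels = x$bin_counts,
             segment = segment_of(x$bin_centers),
             stringsAsFactors = FALSE)
}

# segment of a percent position: lateral [0, 100/3), middle [100/3, 200/3),
# medial [200/3, 100]
segment_of <- function(x) {
  seg <- ifelse(x < 100 / 3, "lateral", ifelse(x < 200 / 3, "middle", "medial"))
  factor(seg, levels = c("lateral", "middle", "medial"))
}

#' Label mask voxels by tendon segment
#'
#' Divides the normalized length into three equivalent segments starting
#' from the footprint: lateral [0, 100/3), middle [100/3, 200/3), medial
#' [200/3, 100].  Boundary positions fall into the more medial segment
#' (half-open convention).
#'
#' @param length_field A \code{\link{parameterize_length}} result.
#' @return A factor matrix-shaped object: \code{labels} (factor levels
#'   lateral/middle/medial as a character matrix, NA outside mask).
#' @export
split_segments <- function(length_field) {
  stopifnot(inherits(length_field, "length_field"))
  pos <- length_field$position
  lab <- matrix(NA_character_, nrow(pos), ncol(pos))
  in_mask <- !is.na(pos)
  lab[in_mask] <- as.character(segment_of(pos[in_mask]))
  lab
}

#' Per-segment mean T2 summaries
#'
#' For each of the three tendon segments, the mean and standard deviation
#' (n - 1 denominator) of the T2 values of all filtered voxels in that
#' segment, plus the voxel count.  Empty segments yield NA summaries with
#' a missing-segment attribute.
#'
#' @param map A \code{\link{t2_map}}.
#' @param filtered A \code{\link{t2_filter}} or logical keep matrix.
#' @param labels Segment label matrix from \code{\link{split_segments}}.
#' @return Data frame with columns \code{segment}, \code{mean_t2},
#'   \code{sd_t2}, \code{n_voxels}; attribute \code{missing_segments}.
#' @export
segment_means <- function(map, filtered, labels) {
  stopifnot(inherits(map, "t2_map"))
  keep <- if (inherits(filtered, "t2_filter")) filtered$keep else filtered
  segs <- c("lateral", "middle", "medial")
  out <- data.frame(segment = factor(segs, levels = segs),
                    mean_t2 = NA_real_, sd_t2 = NA_real_, n_voxels = 0L)
  for (i in seq_along(segs)) {
    idx <- which(keep & !is.na(labels) & labels == segs[i])
    out$n_voxels[i] <- length(idx)
    if (length(idx)) {
      v <- map$t2[idx]
      out$mean_t2[i] <- mean(v)
      out$sd_t2[i] <- if (length(v) > 1) sd(v) else 0
    }
  }
  attr(out, "missing_segments") <- segs[out$n_voxels == 0L]
  out
}
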