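# Graph-based dynamic-programming segmentation of retinal boundaries in
# OCT B-scans, total-retinal-thickness (TRT) maps, optic-disc masking and
# longitudinal change analysis.
#
# Boundaries are minimum-cost left-to-right paths through the B-scan:
# node weights derive from the signed vertical intensity gradient under
# the requested polarity, and virtual padding columns let the path enter
# and leave at any row.

W_MIN <- 1e-5

# Signed vertical gradient normalized to [0,1] under the polarity.
polarity_gradient <- function(band, polarity) {
  g <- rbind(band[2, ] - band[1, ],
             (band[-(1:2), , drop = FALSE] -
                band[seq_len(nrow(band) - 2), , drop = FALSE]) / 2,
             band[nrow(band), ] - band[nrow(band) - 1, ])
  if (polarity == "bright_to_dark") g <- -g
  rng <- range(g)
  if (rng[2] - rng[1] <= 0) return(NULL)  # degenerate, flat band
  (g - rng[1]) / (rng[2] - rng[1])
}

#' Segment one boundary in a B-scan by dynamic programming
#'
#' Finds the minimum-cost 8-connected path across the columns of the
#' search band. The cost of stepping between horizontally adjacent pixels
#' `a` and `b` is `2 - (g_a + g_b) + w_min`, where `g` is the signed
#' vertical gradient under the requested polarity, normalized to \[0,1\]
#' over the band, and `w_min = 1e-5` keeps weights positive. Virtual
#' zero-cost padding columns on both sides let the path start and end at
#' any row.
#'
#' @param bscan depth x width intensity matrix.
#' @param polarity `"dark_to_bright"` (ILM-type edge) or
#'   `"bright_to_dark"` (OS-RPE-type edge).
#' @param search_band integer range of rows to search (default all).
#' @param forbidden optional logical matrix (same size as the band) of
#'   disallowed nodes (used to keep one boundary below another).
#' @return list with `path` (row per column, in full-image coordinates),
#'   `degenerate` flag (zero gradient everywhere -> flat path + warning)
#'   and `edge_strength` (normalized gradient along the path).
#' @export
segment_boundary <- function(bscan,
                             polarity = c("dark_to_bright", "bright_to_dark"),
                             search_band = NULL, forbidden = NULL) {
  polarity <- match.arg(polarity)
  if (is.null(search_band)) search_band <- seq_len(nrow(bscan))
  band <- bscan[search_band, , drop = FALSE]
  H <- nrow(band); W <- ncol(band)
  g <- polarity_gradient(band, polarity)
  if (is.null(g)) {
    warning("zero gradient everywhere in the band: flat path returned")
    mid <- search_band[ceiling(H / 2)]
    return(list(path = rep(mid, W), degenerate = TRUE,
                edge_strength = rep(0, W)))
  }
  if (!is.null(forbidden)) g[forbidden] <- -1e6
  # DP over columns; virtual padding columns (g = 1) contribute the entry
  # edge 1 + w_min - g at the first column and symmetrically at the last
  cost <- matrix(Inf, H, W)
  back <- matrix(0L, H, W)
  cost[, 1] <- 1 + W_MIN - g[, 1]
  for (c in 2:W) {
    prev <- cost[, c - 1] - g[, c - 1]
    best <- prev; arg <- rep(0L, H)
    up <- c(Inf, prev[-H])       # from row r-1
    dn <- c(prev[-1], Inf)       # from row r+1
    sel <- up < best; best[sel] <- up[sel]; arg[sel] <- -1L
    sel <- dn < best; best[sel] <- dn[sel]; arg[sel] <- 1L
    cost[, c] <- best + (2 + W_MIN) - g[, c]
    back[, c] <- arg
  }
  path <- integer(W)
  path[W] <- which.min(cost[, W] + 1 + W_MIN - g[, W])  # exit padding edge
  for (c in W:2) path[c - 1] <- path[c] + back[path[c], c]
  list(path = search_band[path], degenerate = FALSE,
       edge_strength = g[cbind(path, seq_len(W))])
}

#' Segment ILM and OS-RPE boundaries through an OCT volume
#'
#' Per B-scan, the inner limiting membrane (ILM; dark-to-bright edge) is
#' found first over the whole depth, then the OS-RPE boundary
#' (bright-to-dark) constrained at least `min_separation` px below the
#' ILM path. Columns where either boundary sits on a weak edge (vessel
#' shadows) are interpolated from their neighbors and flagged invalid.
#'
#' @param vol an `oct_volume` from [gen_oct_volume()] (or a compatible
#'   list with `data` and `axial_scale`).
#' @param min_separation minimum ILM to OS-RPE distance, px (default 20).
#' @param edge_floor minimum normalized edge strength for a trusted
#'   column (fraction of the B-scan's median path strength).
#' @return An object of class `boundary_set`: list with matrices `ilm_px`,
#'   `osrpe_px` (fractionally interpolated rows, B-scans x width) and
#'   logical `valid`.
#' @export
segment_volume <- function(vol, min_separation = 20, edge_floor = 0.25) {
  arr <- vol$data
  nb <- dim(arr)[1]; depth <- dim(arr)[2]; wd <- dim(arr)[3]
  ilm <- matrix(NA_real_, nb, wd); osr <- ilm
  valid <- matrix(TRUE, nb, wd)
  for (b in seq_len(nb)) {
    bs <- arr[b, , ]
    s1 <- segment_boundary(bs, "dark_to_bright")
    # forbid nodes above ILM + min_separation for the second boundary
    rows <- seq_len(depth)
    forb <- outer(rows, s1$path + min_separation, "<")
    s2 <- segment_boundary(bs, "bright_to_dark", forbidden = forb)
    bad <- s1$degenerate | s2$degenerate |
      s1$edge_strength < edge_floor * median(s1$edge_strength) |
      s2$edge_strength < edge_floor * median(s2$edge_strength) |
      s2$path <= s1$path
    p1 <- as.numeric(s1$path); p2 <- as.numeric(s2$path)
    if (any(bad) && !all(bad)) {
      p1[bad] <- NA; p2[bad] <- NA
      p1 <- interp_na(p1); p2 <- interp_na(p2)
    }
    ilm[b, ] <- p1; osr[b, ] <- p2
    valid[b, ] <- !bad
  }
  structure(list(ilm_px = ilm, osrpe_px = osr, valid = valid,
                 axial_scale = vol$axial_scale),
            class = "boundary_set")
}

#' En-face total-retinal-thickness map with optic-disc mask
#'
#' `TRT = (OS-RPE row - ILM row) * axial_scale` per en-face position; a
#' circular region of `disc_diameter_deg` degrees of visual angle
#' centered on the optic disc (hard to segment) is masked out and never
#' enters any statistic.
#'
#' @param bounds a `boundary_set` from [segment_volume()].
#' @param vol the `oct_volume` the boundaries came from (provides the
#'   en-face angular scales and disc center).
#' @param disc_diameter_deg disc mask diameter in degrees (default 8; the
#'   figure is read as a diameter and is configurable).
#' @return An object of class `thickness_map`: `trt_um` matrix (`NA`
#'   where masked), logical `mask`, en-face coordinate vectors in
#'   degrees.
#' @export
trt_map <- function(bounds, vol, disc_diameter_deg = 8) {
  trt <- (bounds$osrpe_px - bounds$ilm_px) * bounds$axial_scale
  nb <- nrow(trt); wd <- ncol(trt)
  ydeg <- (seq_len(nb) - (nb + 1) / 2) * vol$en_face_scale[1]
  xdeg <- (seq_len(wd) - (wd + 1) / 2) * vol$en_face_scale[2]
  dc <- vol$disc_center
  D2 <- outer((ydeg - dc[2])^2, (xdeg - dc[1])^2, "+")
  mask <- D2 <= (disc_diameter_deg / 2)^2
  trt[mask] <- NA_real_
  structure(list(trt_um = trt, mask = mask, x_deg = xdeg, y_deg = ydeg,
                 disc_center = dc),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("thickness_map: %d x %d, mean TRT %.1f um (%d cells masked)\n",
              nrow(x$trt_um), ncol(x$trt_um),
              mean(x$trt_um, na.rm = TRUE), sum(x$mask)))
  invisible(x)
}

#' Longitudinal TRT change between two co-registered maps
#'
#' Per-cell difference `map_t - map_0` under the union of the two disc
#' masks, with the mean change (um), mean percent change, and mean change
#' within eccentricity annuli around the map center.
#'
#' @param map_t,map_0 `thickness_map` objects on the same grid.
#' @param ecc_edges eccentricity bin edges in degrees; default splits the
#'   covered eccentricity range into three equal annuli.
#' @return list with `diff_um` (matrix), `mean_change_um`,
#'   `pct_change`, and `ecc_bins` (data frame of annulus edges and mean
#'   change).
#' @export
trt_change <- function(map_t, map_0, ecc_edges = NULL) {
  if (!all(dim(map_t$trt_um) == dim(map_0$trt_um)))
    stop("maps are not on the same grid", call. = FALSE)
  d <- map_t$trt_um - map_0$trt_um
  ok <- is.finite(d)
  if (!any(ok)) stop("no overlapping unmasked cells", call. = FALSE)
  ecc <- sqrt(outer(map_0$y_deg^2, map_0$x_deg^2, "+"))
  if (is.null(ecc_edges))
    ecc_edges <- seq(0, max(ecc[ok]) + 1e-9, length.out = 4)
  bins <- data.frame(ecc_lo = head(ecc_edges, -1),
                     ecc_hi = tail(ecc_edges, -1),
                     mean_change_um = NA_real_, n = NA_integer_)
  for (i in seq_len(nrow(bins))) {
    sel <- ok & ecc >= bins$ecc_lo[i] & ecc < bins$ecc_hi[i]
    bins$n[i] <- sum(sel)
    if (any(sel)) bins$mean_change_um[i] <- mean(d[sel])
  }
  list(diff_um = d,
       mean_change_um = mean(d[ok]),
       pct_change = 100 * mean(d[ok]) / mean(map_0$trt_um[ok]),
       ecc_bins = bins)
}
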