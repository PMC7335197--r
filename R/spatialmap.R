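#' Per-pixel whisker-tuning map
#'
#' Each pixel of an axon's mask inherits the axon's windowed C2 and B2
#' response amplitudes and whisker selectivity index. Pixels claimed by more
#' than one axon are excluded to avoid double counting.
#'
#' @param axons list of merged axons (with `axon_id`, `pixel_mask`).
#' @param responses data.frame with columns `axon_id`, `amp_c2`, `amp_b2`,
#'   `wsi` (e.g. the `wsi` table of [axon_response()] for one lick group).
#' @return data.frame per pixel: `row`, `col`, `axon_id`, `response_c2`,
#'   `response_b2`, `pixel_wsi`.
#' @export
pixel_tuning_map <- function(axons, responses) {
  if (length(axons) == 0)
    return(data.frame(row = integer(0), col = integer(0),
                      axon_id = integer(0), response_c2 = numeric(0),
                      response_b2 = numeric(0), pixel_wsi = numeric(0)))
  pieces <- lapply(axons, function(ax) {
    r <- responses[responses$axon_id == ax$axon_id, ]
    if (nrow(r) != 1) return(NULL)
    data.frame(row = ax$pixel_mask[, 1], col = ax$pixel_mask[, 2],
               axon_id = ax$axon_id, response_c2 = r$amp_c2,
               response_b2 = r$amp_b2, pixel_wsi = r$wsi)
  })
  map <- do.call(rbind, pieces)
  if (is.null(map)) return(pixel_tuning_map(list(), responses))
  key <- paste(map$row, map$col)
  dup <- key %in% key[duplicated(key)]
  map[!dup, , drop = FALSE]
}

#' Fit a Gaussian confidence ellipse to 2-D points
#'
#' Mean and covariance of the coordinates define an ellipse whose semi-axes
#' are `sqrt(lambda_i * q)` with `q` the chi-square quantile (2 df) at the
#' confidence level: for 2-D Gaussian data the ellipse contains the stated
#' fraction of points in expectation.
#'
#' @param points n x 2 matrix (or data.frame) of coordinates; n >= 3,
#'   non-collinear.
#' @param confidence confidence level (default 0.9).
#' @return an `ellipse_fit`: `center`, `covariance`, `confidence`,
#'   `semi_axes` (decreasing), `orientation` (eigenvector columns), `area`.
#' @export
fit_confidence_ellipse <- function(points, confidence = 0.9) {
  pts <- as.matrix(points)
  if (nrow(pts) < 3) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(pts)
  S <- stats::cov(pts)
  if (!all(is.finite(S)) || det(S) <= .Machine$double.eps * sum(diag(S))^2)
    stop("degenerate point cloud: covariance not positive definite",
         call. = FALSE)
  q <- stats::qchisq(confidence, df = 2)
  e <- eigen(S, symmetric = TRUE)
  semi <- sqrt(pmax(e$values, 0) * q)
  structure(list(center = ctr, covariance = S, confidence = confidence,
                 semi_axes = semi, orientation = e$vectors,
                 area = pi * prod(semi)),
            class = "ellipse_fit")
}

#' Ellipse boundary polygon
#'
#' @param fit an `ellipse_fit`.
#' @param n_vertices number of boundary vertices (default 512).
#' @return n x 2 matrix of vertices, counter-clockwise.
#' @export
ellipse_polygon <- function(fit, n_vertices = 512) {
  stopifnot(inherits(fit, "ellipse_fit"))
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  unit <- rbind(cos(th) * fit$semi_axes[1], sin(th) * fit$semi_axes[2])
  ccw <- t(fit$orientation %*% unit + fit$center)
  # eigen() does not fix handedness; enforce counter-clockwise order
  if (polygon_area_signed(ccw) < 0) ccw <- ccw[rev(seq_len(nrow(ccw))), ]
  ccw
}

polygon_area_signed <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area (shoelace)
#'
#' @param p n x 2 vertex matrix.
#' @return nonnegative area.
#' @export
polygon_area <- function(p) {
  if (is.null(p) || nrow(p) < 3) return(0)
  abs(polygon_area_signed(p))
}

#' Intersection of two convex polygons
#'
#' Sutherland–Hodgman clipping of `subject` against each half-plane of the
#' counter-clockwise convex polygon `clip`. Exact for convex inputs, which is
#' all the ellipse-overlap computation needs.
#'
#' @param subject,clip vertex matrices (n x 2), counter-clockwise.
#' @return vertex matrix of the intersection (possibly 0 rows).
#' @export
clip_convex_polygons <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(matrix(numeric(0), 0, 2))
    a <- clip[i, ]
    b <- clip[if (i == nc) 1 else i + 1, ]
    # signed distance: positive = inside (left of a->b for CCW clip polygon)
    side <- (b[1] - a[1]) * (out[, 2] - a[2]) - (b[2] - a[2]) * (out[, 1] - a[1])
    n <- nrow(out)
    nxt <- c(seq_len(n)[-1], 1)
    newpts <- list()
    for (k in seq_len(n)) {
      kn <- nxt[k]
      p1in <- side[k] >= 0
      p2in <- side[kn] >= 0
      if (p1in) newpts[[length(newpts) + 1]] <- out[k, ]
      if (xor(p1in, p2in)) {
        t <- side[k] / (side[k] - side[kn])
        newpts[[length(newpts) + 1]] <- out[k, ] + t * (out[kn, ] - out[k, ])
      }
    }
    out <- if (length(newpts)) do.call(rbind, newpts) else matrix(numeric(0), 0, 2)
  }
  out
}

#' Overlap index of two confidence ellipses
#'
#' The area of the intersection of the two ellipses divided by their mean
#' area: 0 when the ellipses are disjoint, 1 when the domains are identical.
#' The intersection is computed by clipping 512-vertex polygonal
#' approximations of the ellipse boundaries.
#'
#' @param e1,e2 `ellipse_fit` objects.
#' @param n_vertices polygon resolution.
#' @return list: `overlap_index`, `intersection_area`, `mean_ellipse_area`.
#' @export
ellipse_overlap_index <- function(e1, e2, n_vertices = 512) {
  p1 <- ellipse_polygon(e1, n_vertices)
  p2 <- ellipse_polygon(e2, n_vertices)
  inter <- clip_convex_polygons(p1, p2)
  ia <- polygon_area(inter)
  ma <- (polygon_area(p1) + polygon_area(p2)) / 2
  list(overlap_index = ia / ma, intersection_area = ia,
       mean_ellipse_area = ma)
}

#' Spatial overlap of C2- and B2-tuned pixel populations
#'
#' Selects strongly tuned pixels (WSI above `wsi_threshold` for C2, below
#' `-wsi_threshold` for B2), fits a 90% confidence ellipse to each population
#' and reports the ellipse overlap index — the spatial-segregation statistic
#' for a field of view.
#'
#' @param map pixel tuning map from [pixel_tuning_map()].
#' @param wsi_threshold tuning threshold (default 0.75).
#' @param confidence ellipse confidence level (default 0.9).
#' @param min_pixels minimum tuned pixels per population.
#' @return one-row data.frame: `n_pixels_c2`, `n_pixels_b2`, `area_c2`,
#'   `area_b2`, `intersection_area`, `overlap_index` (NA when either
#'   population is too small).
#' @export
field_overlap <- function(map, wsi_threshold = 0.75, confidence = 0.9,
                          min_pixels = 3) {
  c2 <- map[!is.na(map$pixel_wsi) & map$pixel_wsi > wsi_threshold, ]
  b2 <- map[!is.na(map$pixel_wsi) & map$pixel_wsi < -wsi_threshold, ]
  out <- data.frame(n_pixels_c2 = nrow(c2), n_pixels_b2 = nrow(b2),
                    area_c2 = NA_real_, area_b2 = NA_real_,
                    intersection_area = NA_real_, overlap_index = NA_real_)
  if (nrow(c2) < min_pixels || nrow(b2) < min_pixels) return(out)
  e_c2 <- fit_confidence_ellipse(cbind(c2$row, c2$col), confidence)
  e_b2 <- fit_confidence_ellipse(cbind(b2$row, b2$col), confidence)
  ov <- ellipse_overlap_index(e_c2, e_b2)
  out$area_c2 <- e_c2$area
  out$area_b2 <- e_b2$area
  out$intersection_area <- ov$intersection_area
  out$overlap_index <- ov$overlap_index
  out
}
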