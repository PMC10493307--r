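# Classical Sholl analysis on the skeleton: concentric rings about the
# soma at fixed radial increments; an intersection is a distinct run of
# skeleton pixels inside a one-pixel-wide annulus at each ring.

#' Locate the soma centre of a cell mask
#'
#' The soma is taken as the centre of the largest inscribed disk: the
#' maximum of the Euclidean distance transform of the mask. Ties break
#' deterministically to the lowest `(y, x)`.
#'
#' @param mask a [binary_mask()].
#' @return Named vector `c(x, y)` in um (pixel `(1,1)` centre is `(0,0)`).
#' @export
find_soma_center <- function(mask) {
  px <- as_mask_pixels(mask)
  if (!any(px)) stop("mask is empty")
  psz <- if (inherits(mask, "binary_mask")) mask$pixel_size else 1
  d <- EBImage::distmap(matrix(as.numeric(px), nrow(px)))
  d <- as.matrix(d)
  best <- max(d)
  cand <- which(d == best, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  r <- unname(cand[1, 1]); c <- unname(cand[1, 2])
  c(x = (c - 1) * psz, y = (r - 1) * psz)
}

# number of connected components over the vertex subset `keep` (logical
# over 1..n) given an edge list (two-column matrix of vertex ids)
.count_components <- function(keep, edges) {
  ids <- which(keep)
  if (length(ids) == 0L) return(0L)
  pos <- integer(length(keep)); pos[ids] <- seq_along(ids)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
  if (nrow(edges)) {
    sub <- edges[keep[edges[, 1]] & keep[edges[, 2]], , drop = FALSE]
    for (e in seq_len(nrow(sub))) {
      ri <- find(pos[sub[e, 1]]); rj <- find(pos[sub[e, 2]])
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_along(ids), find, integer(1))))
}

# raw 8-adjacency edge list among a set of pixel coordinates within an
# image of dimensions `dims`
.pixel_edges <- function(coords, dims) {
  n <- nrow(coords)
  if (n == 0L) return(matrix(integer(), ncol = 2))
  id <- matrix(0L, dims[1], dims[2])
  id[coords] <- seq_len(n)
  out <- list()
  for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    tr <- coords[, 1] + d[1]; tc <- coords[, 2] + d[2]
    ok <- tr >= 1L & tr <= dims[1] & tc >= 1L & tc <= dims[2]
    tid <- integer(n)
    tid[ok] <- id[cbind(tr[ok], tc[ok])]
    hit <- which(tid > 0L)
    if (length(hit))
      out[[length(out) + 1L]] <- cbind(hit, tid[hit])
  }
  if (length(out)) do.call(rbind, out) else
    matrix(integer(), ncol = 2)
}

#' Sholl intersection profile of a skeleton
#'
#' Counts, for each concentric ring of radius `step_um x 1..n_radii`
#' around `center`, the number of distinct transversal process crossings.
#' A crossing is a skeleton step from inside the ring to outside; steps
#' sharing pixels are grouped into runs separately on each side of the
#' ring, and the ring's count is the larger of the two run counts — so a
#' bifurcation sitting on a ring still contributes one crossing per
#' emerging child, while a branch merely grazing the ring without
#' crossing it contributes none.
#'
#' @param skel a `skeleton`.
#' @param center soma centre, named `c(x, y)` in um (see
#'   [find_soma_center()]).
#' @param step_um radial increment between rings, um (default 5).
#' @param n_radii number of rings (default 13).
#' @return A `sholl_profile`: `center`, `radii`, `counts`, `total`.
#' @export
sholl_profile <- function(skel, center, step_um = 5, n_radii = 13L) {
  stopifnot(inherits(skel, "skeleton"))
  if (n_radii <= 0L) stop("`n_radii` must be positive")
  if (step_um <= 0) stop("`step_um` must be positive")
  psz <- skel$pixel_size
  dm <- dim(skel$pixels)
  cx <- center[["x"]]; cy <- center[["y"]]
  if (cx < 0 || cy < 0 || cx > (dm[2] - 1) * psz || cy > (dm[1] - 1) * psz)
    stop("`center` lies outside the image")
  w <- which(skel$pixels)
  co <- arrayInd(w, dm)
  d <- sqrt(((co[, 2] - 1) * psz - cx)^2 + ((co[, 1] - 1) * psz - cy)^2)
  edges <- .pixel_edges(co, dm)
  radii <- step_um * seq_len(n_radii)
  counts <- vapply(radii, function(r) {
    if (!nrow(edges)) return(0L)
    inside <- d <= r
    straddle <- inside[edges[, 1]] != inside[edges[, 2]]
    if (!any(straddle)) return(0L)
    touched <- unique(as.vector(edges[straddle, ]))
    keep_in <- logical(length(d)); keep_out <- logical(length(d))
    keep_in[touched] <- inside[touched]
    keep_out[touched] <- !inside[touched]
    max(.count_components(keep_in, edges),
        .count_components(keep_out, edges))
  }, integer(1))
  structure(list(center = c(x = cx, y = cy), radii = radii,
                 counts = counts, total = sum(counts),
                 step_um = step_um),
            class = "sholl_profile")
}

#' Plot group-mean Sholl curves
#'
#' Simple base-graphics plot of mean intersections (+/- SD ribbons as
#' segments) against ring radius per group, from the long per-cell table
#' written by the pipeline.
#'
#' @param sholl_long data.frame with columns `group`, `radius_um`,
#'   `n_intersections`.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the group x radius mean matrix.
#' @export
plot_sholl_curves <- function(sholl_long, ...) {
  mu <- tapply(sholl_long$n_intersections,
               list(sholl_long$radius_um, sholl_long$group), mean)
  sdv <- tapply(sholl_long$n_intersections,
                list(sholl_long$radius_um, sholl_long$group), sd)
  r <- as.numeric(rownames(mu))
  graphics::matplot(r, mu, type = "b", pch = 16, lty = 1,
                    xlab = "radius (um)",
                    ylab = "intersections (mean +/- SD)", ...)
  for (j in seq_len(ncol(mu)))
    graphics::segments(r, mu[, j] - sdv[, j], r, mu[, j] + sdv[, j],
                       col = j)
  graphics::legend("topright", colnames(mu), col = seq_len(ncol(mu)),
                   pch = 16, bty = "n")
  invisible(mu)
}

#' Sum of Sholl intersections over a distal radius window
#'
#' Inclusive sum of ring counts with radii in `[window[1], window[2]]` —
#' the distal-process complexity measure (e.g. 35-45 um in the prefrontal
#' cortex, 40-55 um in hippocampal CA1). Both endpoints must be members of
#' the profile's radius grid.
#'
#' @param profile a [sholl_profile()].
#' @param window `c(lo, hi)` in um.
#' @return The summed intersection count.
#' @export
distal_sum <- function(profile, window) {
  stopifnot(inherits(profile, "sholl_profile"), length(window) == 2L)
  if (!all(window %in% profile$radii))
    stop("window endpoints must lie on the radius grid (",
         paste(profile$radii, collapse = ", "), ")")
  sel <- profile$radii >= window[1] & profile$radii <= window[2]
  sum(profile$counts[sel])
}
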