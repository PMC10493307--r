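#' Convex-hull perimeter and area of a cell silhouette
#'
#' Computes the convex hull over foreground pixel centers and returns its
#' perimeter (CHP, um) and area (CHA, um^2) — territory-size proxies for
#' the cell. With fewer than three non-collinear pixels the hull
#' degenerates: CHP falls back to twice the maximum pairwise distance and
#' CHA to 0, with a warning.
#'
#' @param mask a [binary_mask()] (or logical matrix with `pixel_size`).
#' @param pixel_size um per pixel, taken from the mask when omitted.
#' @return A list with `chp` (um) and `cha` (um^2).
#' @export
convex_hull_metrics <- function(mask, pixel_size = NULL) {
  px <- as_mask_pixels(mask)
  if (is.null(pixel_size))
    pixel_size <- if (inherits(mask, "binary_mask")) mask$pixel_size else 1
  w <- which(px)
  if (length(w) == 0L) stop("mask has no foreground pixels")
  co <- arrayInd(w, dim(px))
  x <- co[, 2]; y <- co[, 1]
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  degenerate <- length(h) < 3L
  if (!degenerate) {
    nh <- length(h); nxt <- c(2:nh, 1)
    area <- abs(sum(hx * hy[nxt] - hx[nxt] * hy)) / 2
    if (area == 0) degenerate <- TRUE
  }
  if (degenerate) {
    dmax <- 0
    if (length(hx) >= 2L)
      dmax <- max(dist(cbind(hx, hy)))
    warning("degenerate hull (<3 non-collinear pixels): CHA set to 0")
    return(list(chp = 2 * dmax * pixel_size, cha = 0))
  }
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  list(chp = per * pixel_size, cha = area * pixel_size^2)
}

#' Classify the morphological scenario of a cell against controls
#'
#' Distinguishes the two degradation modes of the process tree: *atrophy*
#' (shorter processes with preserved branching: a significant deficit in
#' total length but not in branches/endpoints), *deramification* (loss of
#' branches and endpoints without a length deficit) and their *combined*
#' form (deficits in all three). "Significant" means more than `z_crit`
#' control SDs below the control mean. A reporting aid only; it feeds no
#' statistics.
#'
#' @param cell list or one-row data.frame with `total_length`,
#'   `n_branches`, `n_endpoints`.
#' @param reference list with numeric vectors `mean` and `sd`, each named
#'   `total_length`, `n_branches`, `n_endpoints` (the control-group
#'   summary).
#' @param z_crit deficit threshold in control SDs (default 1.96).
#' @return One of `"none"`, `"atrophy"`, `"deramification"`, `"combined"`.
#' @export
classify_scenario <- function(cell, reference, z_crit = 1.96) {
  need <- c("total_length", "n_branches", "n_endpoints")
  if (is.null(reference) || !all(need %in% names(reference$mean)) ||
      !all(need %in% names(reference$sd)))
    stop("`reference` must carry mean and sd for ", paste(need, collapse = ", "))
  deficit <- vapply(need, function(m) {
    s <- reference$sd[[m]]
    if (s <= 0) return(FALSE)
    (reference$mean[[m]] - as.numeric(cell[[m]])) / s > z_crit
  }, logical(1))
  deram <- deficit[["n_branches"]] && deficit[["n_endpoints"]]
  if (deficit[["total_length"]] && deram) return("combined")
  if (deficit[["total_length"]]) return("atrophy")
  if (deram) return("deramification")
  "none"
}
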