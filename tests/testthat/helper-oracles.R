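# Independent oracles used across the suite. Each reimplements the checked
# quantity from scratch (igraph, dense sampling, naive loops) and never
# shares code with the package internals it validates.

# --- pixel-graph skeleton oracle (igraph) -------------------------------
# Adjacency: 8-neighbourhood, with a diagonal link discounted when the two
# pixels share an orthogonal foreground neighbour. Quantities:
#   endpoints = degree-1 vertices
#   branches  = E - E_jj - n_slab + n_pure_cycles
#   length    = sum of edge weights minus junction-junction contact weights
# where E_jj are edges between two junction (degree >= 3) pixels, n_slab
# the number of degree-2 pixels and pure cycles the all-slab components.
oracle_skeleton <- function(px, pixel_size) {
  skip_if_not_installed("igraph")
  co <- which(px, arr.ind = TRUE)
  n <- nrow(co)
  if (n == 0L) return(list(n_branches = 0L, n_endpoints = 0L,
                           total_length = 0))
  key <- paste(co[, 1], co[, 2], sep = ",")
  idx <- stats::setNames(seq_len(n), key)
  fg <- function(r, c) !is.na(idx[paste(r, c, sep = ",")])
  from <- integer(); to <- integer(); wgt <- numeric()
  for (i in seq_len(n)) {
    r <- co[i, 1]; c <- co[i, 2]
    for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      j <- idx[paste(r + d[1], c + d[2], sep = ",")]
      if (is.na(j)) next
      diagonal <- d[1] != 0 && d[2] != 0
      if (diagonal && (fg(r + d[1], c) || fg(r, c + d[2]))) next
      from <- c(from, i); to <- c(to, unname(j))
      wgt <- c(wgt, if (diagonal) sqrt(2) else 1)
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  deg <- igraph::degree(g)
  jj <- deg[from] >= 3L & deg[to] >= 3L
  comp <- igraph::components(g)
  pure_cycles <- sum(vapply(seq_len(comp$no), function(k) {
    v <- which(comp$membership == k)
    length(v) > 2L && all(deg[v] == 2L)
  }, logical(1)))
  list(n_branches = length(from) - sum(jj) - sum(deg == 2L) + pure_cycles,
       n_endpoints = sum(deg == 1L),
       total_length = (sum(wgt) - sum(wgt[jj])) * pixel_size)
}

# --- brute-force convex hull (Andrew's monotone chain, own code) --------
oracle_hull <- function(px, pixel_size) {
  co <- which(px, arr.ind = TRUE)
  pts <- unique(cbind(x = co[, 2], y = co[, 1]))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(rows) {
    h <- list()
    for (i in seq_len(nrow(rows))) {
      p <- rows[i, ]
      while (length(h) >= 2 &&
             cross(h[[length(h) - 1]], h[[length(h)]], p) <= 0)
        h[[length(h)]] <- NULL
      h[[length(h) + 1]] <- p
    }
    h
  }
  lower <- build(pts)
  upper <- build(pts[rev(seq_len(nrow(pts))), , drop = FALSE])
  hull <- do.call(rbind, c(lower[-length(lower)], upper[-length(upper)]))
  nh <- nrow(hull); nxt <- c(2:nh, 1)
  per <- sum(sqrt((hull[nxt, 1] - hull[, 1])^2 +
                    (hull[nxt, 2] - hull[, 2])^2))
  area <- abs(sum(hull[, 1] * hull[nxt, 2] - hull[nxt, 1] * hull[, 2])) / 2
  list(chp = per * pixel_size, cha = area * pixel_size^2)
}

# --- naive 3x3 median with edge replication -----------------------------
oracle_median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- pmin(pmax(i + (-1:1), 1), nr)
    cj <- pmin(pmax(j + (-1:1), 1), nc)
    out[i, j] <- median(m[ri, cj])
  }
  out
}

# --- segment-circle crossings by dense sampling -------------------------
oracle_ring_crossings <- function(segments, radii, n_samples = 4000L) {
  vapply(radii, function(r) {
    total <- 0L
    for (s in seq_len(nrow(segments))) {
      tt <- seq(0, 1, length.out = n_samples)
      x <- segments$x0[s] + tt * (segments$x[s] - segments$x0[s])
      y <- segments$y0[s] + tt * (segments$y[s] - segments$y0[s])
      inside <- sqrt(x^2 + y^2) <= r
      flips <- sum(inside[-1] != inside[-n_samples])
      # half-open (0, 1]: a flip in the first sampling interval belongs to
      # the parent segment's end, drop crossings at t = 0 exactly
      total <- total + flips
    }
    as.integer(total)
  }, integer(1))
}

# --- forced-swim immobility by 1 ms discretization ----------------------
oracle_fst <- function(intervals, window = c(120, 360)) {
  grid <- seq(window[1] + 5e-4, window[2] - 5e-4, by = 1e-3)
  inside <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(intervals)))
    inside <- inside | (grid >= intervals[i, 1] & grid <= intervals[i, 2])
  sum(inside) * 1e-3
}

# --- permutation p-value for the Pearson correlation --------------------
oracle_perm_p <- function(x, y, n_perm = 1e4, seed = 1) {
  set.seed(seed)
  r_obs <- abs(cor(x, y))
  r_perm <- replicate(n_perm, abs(cor(x, sample(y))))
  (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
}

# small helper: rasterize a straight ray from the origin as a 1-px line
ray_skeleton <- function(length_um, angle_deg, pixel_size = 0.25,
                         canvas_um = 60) {
  n <- 2L * ceiling(canvas_um / (2 * pixel_size)) + 1L
  ctr <- (n + 1L) / 2
  px <- matrix(FALSE, n, n)
  tt <- seq(0, length_um, by = pixel_size / 4)
  r <- round(ctr + tt * sin(angle_deg * pi / 180) / pixel_size)
  c <- round(ctr + tt * cos(angle_deg * pi / 180) / pixel_size)
  px[unique(cbind(r, c))] <- TRUE
  list(skel = as_skeleton(px, pixel_size),
       center = c(x = (ctr - 1) * pixel_size, y = (ctr - 1) * pixel_size))
}
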