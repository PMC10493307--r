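# Synthetic astrocytes with analytically known morphometric ground truth.
# The cell is a continuous centerline tree (soma centre + tapering process
# segments); ground truth (branches, endpoints, total length, Sholl
# crossings, hull) is computed on that tree, never on the raster, so the
# generator validates the pixel pipeline instead of sharing its code path.

#' Parametric model of a branching GFAP+ astrocyte
#'
#' Describes a soma disk plus a tree of straight process segments grown
#' outward from the soma centre. Every potential tree node has its random
#' draws (segment length, branch decision, angular deviation) assigned in a
#' fixed enumeration, so shrinking `deramification_factor` prunes branches
#' without re-randomizing the rest of the cell, and `atrophy_factor`
#' rescales segment lengths in place.
#'
#' @param soma_radius soma disk radius, um (>= 0).
#' @param primary_processes number of primary processes leaving the soma.
#' @param branch_prob probability that a node bifurcates (otherwise the
#'   process continues as a single segment) while `depth < max_depth`.
#' @param segment_mean,segment_sd segment length distribution, um.
#' @param angle_spread angular deviation of child segments from their
#'   parent direction, degrees (uniform in +/- spread).
#' @param process_width rasterized process diameter, um.
#' @param max_depth maximum tree depth (number of segments root-to-tip).
#' @param atrophy_factor multiplier in (0, 1] on all segment lengths
#'   (smaller cell, same topology).
#' @param deramification_factor multiplier in (0, 1] on the branching
#'   probability (fewer branches, similar segment lengths).
#' @return An `astrocyte_model` list.
#' @export
astrocyte_model <- function(soma_radius = 5, primary_processes = 6,
                            branch_prob = 0.55, segment_mean = 12,
                            segment_sd = 3, angle_spread = 35,
                            process_width = 1.5, max_depth = 4,
                            atrophy_factor = 1, deramification_factor = 1) {
  stopifnot(soma_radius >= 0, primary_processes >= 0,
            branch_prob >= 0, branch_prob <= 1,
            segment_mean > 0, segment_sd >= 0,
            angle_spread >= 0, process_width > 0, max_depth >= 1)
  if (atrophy_factor <= 0 || atrophy_factor > 1)
    stop("`atrophy_factor` must lie in (0, 1]")
  if (deramification_factor <= 0 || deramification_factor > 1)
    stop("`deramification_factor` must lie in (0, 1]")
  structure(list(
    soma_radius = soma_radius,
    primary_processes = as.integer(primary_processes),
    branch_prob = branch_prob,
    segment_mean = segment_mean, segment_sd = segment_sd,
    angle_spread = angle_spread, process_width = process_width,
    max_depth = as.integer(max_depth),
    atrophy_factor = atrophy_factor,
    deramification_factor = deramification_factor),
    class = "astrocyte_model")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Grow the continuous centerline tree. Potential nodes of each primary are
# enumerated as a binary heap (node i has children 2i, 2i+1); all random
# numbers are pre-drawn over the full potential tree in that fixed order.
grow_tree <- function(model, seed) {
  k <- model$primary_processes
  if (k == 0L)
    return(data.frame(id = integer(), parent = integer(),
                      x0 = numeric(), y0 = numeric(),
                      x = numeric(), y = numeric(), depth = integer()))
  npot <- 2L^model$max_depth - 1L
  with_seed(seed, {
    segs <- vector("list", k)
    sector <- pi / k
    clamp0 <- min(80, if (k >= 2) 180 / k - 5 else 80) * pi / 180
    jit <- if (model$angle_spread > 0) max(sector - clamp0, 0) else 0
    for (p in seq_len(k)) {
      base_ang <- 2 * pi * (p - 1) / k + runif(1, -1, 1) * jit
      u <- runif(npot)
      len_raw <- rnorm(npot, model$segment_mean, model$segment_sd)
      dev <- runif(npot, -1, 1) * model$angle_spread * pi / 180
      len <- pmax(len_raw, 0.5) * model$atrophy_factor
      p_eff <- model$branch_prob * model$deramification_factor

      id <- integer(); parent <- integer()
      x0 <- numeric(); y0 <- numeric(); x1 <- numeric(); y1 <- numeric()
      depth <- integer()
      # iterative growth in heap order; root segment is node 1.
      # Sibling branches split to opposite sides by at least spread/2 so
      # rasterized branches separate cleanly; single continuations only
      # wiggle. Each primary's subtree is confined to its own angular
      # sector (deviation from the primary axis clamped to the sector
      # half-width, at most 80 degrees), emulating the territorial,
      # non-overlapping organization of astrocyte processes — and
      # guaranteeing subtrees of different primaries never cross.
      spread <- model$angle_spread * pi / 180
      clamp <- clamp0
      queue <- 1L
      rel_of <- numeric(npot); sx <- numeric(npot); sy <- numeric(npot)
      rel_of[1] <- 0; sx[1] <- 0; sy[1] <- 0
      while (length(queue)) {
        i <- queue[1]; queue <- queue[-1]
        d <- floor(log2(i)) + 1L
        rel <- rel_of[i]
        a <- base_ang + rel
        ex <- sx[i] + len[i] * cos(a)
        ey <- sy[i] + len[i] * sin(a)
        id <- c(id, i); parent <- c(parent, i %/% 2L)
        x0 <- c(x0, sx[i]); y0 <- c(y0, sy[i])
        x1 <- c(x1, ex); y1 <- c(y1, ey); depth <- c(depth, d)
        if (d < model$max_depth) {
          if (u[i] < p_eff) {
            kids <- c(2L * i, 2L * i + 1L)
            half <- spread * (0.5 + 0.25 * (abs(dev[kids]) + 1) / 2)
            drel <- c(-half[1], half[2])
          } else {
            kids <- 2L * i
            drel <- dev[kids] * spread / 3
          }
          for (kk in seq_along(kids)) {
            ch <- kids[kk]
            rel_of[ch] <- max(-clamp, min(clamp, rel + drel[kk]))
            sx[ch] <- ex; sy[ch] <- ey
            queue <- c(queue, ch)
          }
        }
      }
      segs[[p]] <- data.frame(primary = p, id = id, parent = parent,
                              x0 = x0, y0 = y0, x = x1, y = y1,
                              depth = depth)
    }
    do.call(rbind, segs)
  })
}

# Exact crossings of tree segments with a circle of radius r about the
# origin: roots of |P0 + t (P1 - P0)|^2 = r^2 with t in (0, 1], summed over
# segments. Vertices shared by parent/child are counted once (half-open t).
segment_ring_crossings <- function(tree, radii) {
  if (nrow(tree) == 0L) return(rep(0L, length(radii)))
  dx <- tree$x - tree$x0; dy <- tree$y - tree$y0
  a <- dx^2 + dy^2
  b <- 2 * (tree$x0 * dx + tree$y0 * dy)
  c0 <- tree$x0^2 + tree$y0^2
  vapply(radii, function(r) {
    cc <- c0 - r^2
    disc <- b^2 - 4 * a * cc
    n <- 0L
    ok <- disc > 0 & a > 0
    if (any(ok)) {
      sq <- sqrt(disc[ok])
      t1 <- (-b[ok] - sq) / (2 * a[ok])
      t2 <- (-b[ok] + sq) / (2 * a[ok])
      n <- sum(t1 > 0 & t1 <= 1) + sum(t2 > 0 & t2 <= 1)
    }
    as.integer(n)
  }, integer(1))
}

# Chain decomposition of the realized tree: endpoints are degree-1 nodes,
# branches are maximal chains between nodes of degree != 2 (the soma centre
# is a node of degree = number of primaries).
tree_topology <- function(tree) {
  if (nrow(tree) == 0L)
    return(list(n_branches = 0L, n_endpoints = 0L, total_length = 0))
  key <- paste(tree$primary, tree$id)
  pkey <- ifelse(tree$parent == 0L, "root", paste(tree$primary, tree$parent))
  nodes <- c("root", key)
  idx <- setNames(seq_along(nodes), nodes)
  ne <- nrow(tree)
  from <- idx[pkey]; to <- idx[key]
  deg <- tabulate(c(from, to), nbins = length(nodes))
  adj <- vector("list", length(nodes))
  for (e in seq_len(ne)) {
    adj[[from[e]]] <- c(adj[[from[e]]], to[e])
    adj[[to[e]]] <- c(adj[[to[e]]], from[e])
  }
  n_endpoints <- sum(deg == 1L)
  n_chains2 <- 0L
  for (v in seq_along(nodes)) {
    if (deg[v] == 2L || deg[v] == 0L) next
    for (w in adj[[v]]) {
      prev <- v; cur <- w
      while (deg[cur] == 2L) {
        nxt <- setdiff(adj[[cur]], prev)[1]
        prev <- cur; cur <- nxt
      }
      n_chains2 <- n_chains2 + 1L
    }
  }
  seg_len <- sqrt((tree$x - tree$x0)^2 + (tree$y - tree$y0)^2)
  list(n_branches = n_chains2 %/% 2L, n_endpoints = n_endpoints,
       total_length = sum(seg_len))
}

polygon_metrics <- function(x, y) {
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  nh <- length(h)
  nxt <- c(2:nh, 1)
  per <- sum(sqrt((hx[nxt] - hx)^2 + (hy[nxt] - hy)^2))
  area <- abs(sum(hx * hy[nxt] - hx[nxt] * hy)) / 2
  list(perimeter = per, area = area)
}

#' Generate a synthetic astrocyte mask with ground truth
#'
#' Grows the continuous centerline tree defined by `model`, rasterizes it
#' (disks of diameter `process_width` stamped along each segment, plus the
#' soma disk) and returns both the binary mask and the ground truth
#' computed on the continuous tree: branch/endpoint counts after merging
#' pass-through nodes, exact total length, exact segment-circle Sholl
#' crossings, and convex-hull perimeter/area of the centerline silhouette.
#'
#' @param model an [astrocyte_model()].
#' @param seed integer seed; the same seed reproduces the cell bit for bit.
#' @param pixel_size raster resolution, um per pixel.
#' @param canvas_um optional square canvas side, um; auto-sized to the cell
#'   when `NULL`. Too small a canvas is an error naming the offending
#'   dimension.
#' @param sholl_step,n_radii ring spacing (um) and ring count for the
#'   ground-truth Sholl counts (defaults 5 um x 13 rings).
#' @return A list with `mask` (a [binary_mask()]) and `truth` (list:
#'   `n_branches`, `n_endpoints`, `total_length`, `sholl_radii`,
#'   `sholl_counts`, `chp`, `cha`, `soma_center` in um raster coordinates,
#'   and the `segments` table of the centerline tree).
#' @export
generate_astrocyte <- function(model, seed = 1L, pixel_size = 0.25,
                               canvas_um = NULL, sholl_step = 5,
                               n_radii = 13L) {
  stopifnot(inherits(model, "astrocyte_model"), pixel_size > 0)
  if (model$primary_processes == 0L && model$soma_radius <= 0)
    stop("degenerate model: zero primary processes and zero soma radius")
  tree <- grow_tree(model, seed)

  half_need <- model$soma_radius + model$process_width / 2 + 2 * pixel_size
  if (nrow(tree))
    half_need <- max(half_need,
                     max(abs(c(tree$x0, tree$x, tree$y0, tree$y))) +
                       model$process_width / 2 + 2 * pixel_size)
  if (is.null(canvas_um)) canvas_um <- 2 * half_need
  ext_x <- if (nrow(tree)) max(abs(c(tree$x0, tree$x))) else 0
  ext_y <- if (nrow(tree)) max(abs(c(tree$y0, tree$y))) else 0
  margin <- model$process_width / 2
  if (2 * (max(ext_x, model$soma_radius) + margin) > canvas_um)
    stop(sprintf("canvas overflow along x: need %.1f um, canvas %.1f um",
                 2 * (ext_x + margin), canvas_um))
  if (2 * (max(ext_y, model$soma_radius) + margin) > canvas_um)
    stop(sprintf("canvas overflow along y: need %.1f um, canvas %.1f um",
                 2 * (ext_y + margin), canvas_um))

  n <- 2L * ceiling(canvas_um / (2 * pixel_size)) + 1L  # odd => exact centre
  ctr <- (n + 1L) / 2                                   # centre pixel (1-based)
  px <- matrix(FALSE, n, n)

  # soma disk
  if (model$soma_radius > 0)
    px <- .cpp_stamp_disks(px, ctr - 1, ctr - 1, model$soma_radius / pixel_size)
  # processes: stamp disks along each segment at 0.3 px spacing
  if (nrow(tree)) {
    rad_px <- max(model$process_width / 2 / pixel_size, 0.72)
    rows <- numeric(0); cols <- numeric(0)
    for (s in seq_len(nrow(tree))) {
      L <- sqrt((tree$x[s] - tree$x0[s])^2 + (tree$y[s] - tree$y0[s])^2)
      np <- max(2L, ceiling(L / pixel_size / 0.3) + 1L)
      tt <- seq(0, 1, length.out = np)
      xs <- tree$x0[s] + tt * (tree$x[s] - tree$x0[s])
      ys <- tree$y0[s] + tt * (tree$y[s] - tree$y0[s])
      cols <- c(cols, xs / pixel_size + ctr - 1)
      rows <- c(rows, ys / pixel_size + ctr - 1)
    }
    px <- .cpp_stamp_disks(px, rows, cols, rad_px)
  }

  topo <- tree_topology(tree)
  radii <- sholl_step * seq_len(n_radii)
  counts <- segment_ring_crossings(tree, radii)

  # hull of the centerline silhouette: soma circle + all segment vertices
  th <- seq(0, 2 * pi, length.out = 181L)[-181L]
  hx <- model$soma_radius * cos(th); hy <- model$soma_radius * sin(th)
  if (nrow(tree)) {
    hx <- c(hx, tree$x0, tree$x); hy <- c(hy, tree$y0, tree$y)
  }
  hull <- polygon_metrics(hx, hy)

  soma_um <- c(x = (ctr - 1) * pixel_size, y = (ctr - 1) * pixel_size)
  truth <- list(
    n_branches = topo$n_branches, n_endpoints = topo$n_endpoints,
    total_length = topo$total_length,
    sholl_radii = radii, sholl_counts = counts,
    chp = hull$perimeter, cha = hull$area,
    soma_center = soma_um,
    segments = tree)
  list(mask = binary_mask(px, pixel_size), truth = truth)
}

#' Add imaging noise to a binary mask
#'
#' Turns a mask into an intensity image (background 0, foreground
#' `foreground`) and corrupts it with salt-and-pepper flips, Poisson shot
#' noise and/or additive Gaussian noise. With all noise off, thresholding
#' the output at any level in `(0, foreground)` recovers the mask exactly.
#'
#' @param mask a [binary_mask()].
#' @param salt_pepper_fraction per-pixel flip probability in `[0, 1)`.
#' @param gaussian_sd additive Gaussian noise SD (intensity units).
#' @param poisson replace each intensity with a Poisson draw of that mean.
#' @param seed integer seed for reproducibility.
#' @param foreground foreground intensity (default 200).
#' @return An [image_stack()] (2D).
#' @export
add_noise <- function(mask, salt_pepper_fraction = 0, gaussian_sd = 0,
                      poisson = FALSE, seed = NULL, foreground = 200) {
  stopifnot(inherits(mask, "binary_mask"))
  if (salt_pepper_fraction < 0 || salt_pepper_fraction >= 1)
    stop("`salt_pepper_fraction` must lie in [0, 1)")
  img <- matrix(ifelse(mask$pixels, foreground, 0),
                nrow(mask$pixels), ncol(mask$pixels))
  with_seed(seed, {
    if (salt_pepper_fraction > 0) {
      flip <- runif(length(img)) < salt_pepper_fraction
      img[flip] <- foreground - img[flip]
    }
    if (poisson) img[] <- rpois(length(img), lambda = img)
    if (gaussian_sd > 0)
      img[] <- pmax(img + rnorm(length(img), 0, gaussian_sd), 0)
  })
  image_stack(img, pixel_size = mask$pixel_size)
}
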