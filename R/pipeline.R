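# End-to-end pipeline: image chain -> per-cell morphometry -> per-animal
# aggregation -> Z-scores -> group statistics and morphology-behavior
# correlation. Runs on real TIFF stacks or fully synthetically.

#' Measure one cell: image chain plus all morphometric descriptors
#'
#' Applies the image chain as needed (projection for stacks, 8-bit
#' conversion, thresholding, despeckling — already-binary masks skip
#' straight to measurement), skeletonizes, and returns skeleton metrics,
#' convex-hull metrics and the Sholl profile with its distal-window sum.
#'
#' @param x an [image_stack()] (2D or 3D) or a [binary_mask()].
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_level level for `method = "fixed"`.
#' @param apply_despeckle run the 3x3 median on the thresholded mask
#'   (default TRUE, the standard order).
#' @param pre_smooth optionally despeckle the grey image before
#'   thresholding (default off).
#' @param sholl_step,n_radii Sholl ring spacing (um) and ring count.
#' @param distal_window distal radius window `c(lo, hi)` in um.
#' @param center soma centre override, named `c(x, y)` um; located by
#'   [find_soma_center()] when `NULL`.
#' @param keep_images return the mask and skeleton alongside the numbers.
#' @return A list: `metrics` (one-row data.frame with `n_branches`,
#'   `n_endpoints`, `total_length_um`, `chp_um`, `cha_um2`, `sholl_total`,
#'   `distal_sum`, `threshold_level`), `profile` (the [sholl_profile()]),
#'   and optionally `mask`/`skeleton`.
#' @export
analyze_cell <- function(x, threshold_method = "otsu",
                         threshold_level = NULL, apply_despeckle = TRUE,
                         pre_smooth = FALSE, sholl_step = 5, n_radii = 13L,
                         distal_window = c(35, 45), center = NULL,
                         keep_images = FALSE) {
  level <- NA_integer_
  if (inherits(x, "image_stack")) {
    img <- max_intensity_projection(x)
    img <- to_8bit(img)
    if (pre_smooth) img <- despeckle(img)
    mask <- threshold_mask(img, method = threshold_method,
                           level = threshold_level, quiet = TRUE)
    level <- attr(mask, "level")
    if (apply_despeckle) mask <- despeckle(mask)
  } else {
    mask <- if (inherits(x, "binary_mask")) x else
      stop("`x` must be an image_stack or binary_mask")
  }
  # crop to the cell's bounding box (1 px pad): every downstream stage
  # scales with pixel area and is translation-invariant
  w <- which(mask$pixels, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask after thresholding")
  r0 <- max(1L, min(w[, 1]) - 1L); r1 <- min(nrow(mask$pixels), max(w[, 1]) + 1L)
  c0 <- max(1L, min(w[, 2]) - 1L); c1 <- min(ncol(mask$pixels), max(w[, 2]) + 1L)
  mask <- binary_mask(mask$pixels[r0:r1, c0:c1, drop = FALSE],
                      mask$pixel_size)
  if (!is.null(center))
    center <- c(x = center[["x"]] - (c0 - 1) * mask$pixel_size,
                y = center[["y"]] - (r0 - 1) * mask$pixel_size)
  skel <- skeletonize(mask)
  sk <- analyze_skeleton(skel)
  hull <- convex_hull_metrics(mask)
  if (is.null(center)) center <- find_soma_center(mask)
  prof <- sholl_profile(skel, center, step_um = sholl_step,
                        n_radii = n_radii)
  ds <- distal_sum(prof, distal_window)
  metrics <- data.frame(
    n_branches = sk$n_branches, n_endpoints = sk$n_endpoints,
    total_length_um = sk$total_length,
    chp_um = hull$chp, cha_um2 = hull$cha,
    sholl_total = prof$total, distal_sum = ds,
    threshold_level = level)
  out <- list(metrics = metrics, profile = prof)
  if (keep_images) { out$mask <- mask; out$skeleton <- skel }
  out
}

#' Default per-group morphology degradation factors
#'
#' `c(atrophy, deramification)` multipliers applied to the base cell model
#' for each simulated group: the PID state shrinks segment lengths to 0.8
#' and branching probability to 0.7 of control; EA restores most of both.
#' @return Named list of length-2 vectors.
#' @export
default_group_factors <- function() {
  list(sham = c(atrophy = 1, deramification = 1),
       PID = c(atrophy = 0.8, deramification = 0.7),
       EA = c(atrophy = 0.92, deramification = 0.88))
}

.apply_factors <- function(model, factors) {
  model$atrophy_factor <- model$atrophy_factor * factors[[1]]
  model$deramification_factor <- model$deramification_factor * factors[[2]]
  model
}

#' Simulate a full morphology-plus-behavior experiment
#'
#' Generates, for each animal of each group, `cells_per_animal` synthetic
#' astrocytes (group-specific atrophy/deramification factors), runs every
#' cell through the complete image chain (noise, 8-bit, threshold,
#' despeckle, skeletonize, Sholl), simulates the matching behavioral
#' cohort and computes per-animal Z-scores.
#'
#' @param seed master seed; every cell and the cohort derive their seeds
#'   from it.
#' @param n_animals animals per group.
#' @param cells_per_animal cells imaged per animal (default 5).
#' @param region region label for the output tables (default `"PFC"`).
#' @param base_model the control-group [astrocyte_model()].
#' @param group_factors named list of `c(atrophy, deramification)` per
#'   group, see [default_group_factors()].
#' @param cohort_means,cohort_sds behavioral group parameter matrices
#'   (defaults as in [cohort_spec()]).
#' @param pixel_size raster resolution for the synthetic images, um/px.
#' @param salt_pepper,gaussian_sd imaging noise injected before the image
#'   chain.
#' @param distal_window distal Sholl window, um.
#' @param control control group label for Z-scores and scenarios.
#' @return A list: `cells` (per-cell morphometry with scenario labels),
#'   `sholl` (long per-cell per-radius table), `animals` (per-animal
#'   aggregated morphometry joined with Z-scores), `behavior` (raw
#'   cohort), `zscores`, and `seed`.
#' @export
simulate_experiment <- function(seed = 1L, n_animals = 10L,
                                cells_per_animal = 5L, region = "PFC",
                                base_model = astrocyte_model(),
                                group_factors = default_group_factors(),
                                cohort_means = .default_cohort_means(),
                                cohort_sds = .default_cohort_sds(),
                                pixel_size = 0.5, salt_pepper = 0.002,
                                gaussian_sd = 8, distal_window = c(35, 45),
                                control = "sham") {
  groups <- names(group_factors)
  n_cells <- length(groups) * n_animals * cells_per_animal
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_cells + 1L))
  cohort_seed <- seeds[n_cells + 1L]

  cohort <- simulate_cohort(cohort_spec(
    groups = groups, n = n_animals, means = cohort_means[groups, ],
    sds = cohort_sds[groups, ], seed = cohort_seed))
  z <- zscore_table(cohort, control = control)

  rows <- vector("list", n_cells)
  sholl_rows <- vector("list", n_cells)
  i <- 0L
  for (g in groups) {
    model <- .apply_factors(base_model, group_factors[[g]])
    for (a in seq_len(n_animals)) {
      aid <- sprintf("%s_%02d", g, a)
      for (cidx in seq_len(cells_per_animal)) {
        i <- i + 1L
        cell <- generate_astrocyte(model, seed = seeds[i],
                                   pixel_size = pixel_size)
        img <- add_noise(cell$mask, salt_pepper_fraction = salt_pepper,
                         gaussian_sd = gaussian_sd, seed = seeds[i])
        res <- analyze_cell(img, distal_window = distal_window)
        cell_id <- sprintf("%s_c%02d", aid, cidx)
        rows[[i]] <- cbind(data.frame(cell_id = cell_id, animal_id = aid,
                                      region = region, group = g),
                           res$metrics)
        sholl_rows[[i]] <- data.frame(cell_id = cell_id, animal_id = aid,
                                      region = region, group = g,
                                      radius_um = res$profile$radii,
                                      n_intersections = res$profile$counts)
      }
    }
  }
  cells <- do.call(rbind, rows)
  sholl <- do.call(rbind, sholl_rows)

  # scenario labels against the control-group cell summary
  ctl <- cells[cells$group == control, ]
  ref <- list(
    mean = c(total_length = mean(ctl$total_length_um),
             n_branches = mean(ctl$n_branches),
             n_endpoints = mean(ctl$n_endpoints)),
    sd = c(total_length = sd(ctl$total_length_um),
           n_branches = sd(ctl$n_branches),
           n_endpoints = sd(ctl$n_endpoints)))
  cells$scenario <- vapply(seq_len(nrow(cells)), function(r)
    classify_scenario(list(total_length = cells$total_length_um[r],
                           n_branches = cells$n_branches[r],
                           n_endpoints = cells$n_endpoints[r]), ref),
    character(1))

  metr <- c("n_branches", "n_endpoints", "total_length_um", "chp_um",
            "cha_um2", "sholl_total", "distal_sum")
  animals <- aggregate_per_animal(cells, metrics = metr)
  animals <- merge(animals,
                   z[, c("animal_id", "z_spt", "z_sit", "z_epmt", "z_fst",
                         "z_composite")],
                   by = "animal_id")
  animals <- animals[order(animals$group, animals$animal_id), ]
  list(cells = cells, sholl = sholl, animals = animals, behavior = cohort,
       zscores = z, seed = seed)
}

#' Pipeline configuration
#'
#' Collects every decision the pipeline makes so a run is reproducible
#' from its config alone. All arguments of [simulate_experiment()] are
#' accepted; `behavior_csv` replaces the simulated cohort with measured
#' data, `images_csv` (columns `path`, `animal_id`, `group`, `region`,
#'   plus optional `pixel_size`) replaces the synthetic cells with TIFF
#' masks/stacks, and `behavior = FALSE` requests a morphometry-only run.
#'
#' @param ... overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(seed = 1L, n_animals = 10L, cells_per_animal = 5L,
              region = "PFC", pixel_size = 0.5, salt_pepper = 0.002,
              gaussian_sd = 8, distal_window = c(35, 45),
              control = "sham", correlation_methods = c("pearson",
                                                        "spearman"),
              behavior = TRUE, behavior_csv = NULL, images_csv = NULL,
              group_factors = default_group_factors())
  ov <- list(...)
  bad <- setdiff(names(ov), c(names(cfg), "base_model", "cohort_means",
                              "cohort_sds"))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  for (k in c("seed", "n_animals", "cells_per_animal"))
    cfg[[k]] <- as.integer(cfg[[k]])
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a plain-text file
#'
#' Accepts either YAML or simple `key=value` lines (one per line, `#`
#' comments allowed); values are passed to [pipeline_config()].
#'
#' @param path config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  vals <- if (all(grepl("=", lines, fixed = TRUE))) {
    kv <- strsplit(lines, "=", fixed = TRUE)
    out <- lapply(kv, function(p) {
      v <- trimws(paste(p[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
      if (!anyNA(num)) num
      else if (v %in% c("TRUE", "FALSE", "true", "false"))
        as.logical(toupper(v))
      else v
    })
    names(out) <- trimws(vapply(kv, `[`, "", 1))
    out
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the yaml package; use key=value lines")
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, vals)
}

.measure_tiff_cells <- function(tab, cfg) {
  rows <- list(); sholl_rows <- list()
  for (r in seq_len(nrow(tab))) {
    psz <- if ("pixel_size" %in% names(tab)) tab$pixel_size[r] else
      cfg$pixel_size
    stk <- read_stack_tiff(tab$path[r], pixel_size = psz)
    res <- analyze_cell(stk, distal_window = cfg$distal_window)
    cid <- sprintf("%s_c%02d", tab$animal_id[r], r)
    rows[[r]] <- cbind(data.frame(cell_id = cid,
                                  animal_id = tab$animal_id[r],
                                  region = tab$region[r],
                                  group = tab$group[r]), res$metrics)
    sholl_rows[[r]] <- data.frame(cell_id = cid, radius_um =
                                    res$profile$radii,
                                  n_intersections = res$profile$counts)
  }
  list(cells = do.call(rbind, rows), sholl = do.call(rbind, sholl_rows))
}

#' Run the full analysis pipeline and write the report bundle
#'
#' Executes every stage — synthetic generation (or TIFF input), the image
#' chain, morphometry, Sholl, behavioral Z-scores, group ANOVA/Tukey
#' tables and morphology-behavior correlations — and writes all tables
#' plus a run log to `outdir`. Any stage failure aborts with the stage
#' name.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the list of result tables.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("astromorph_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  say("run_pipeline seed=%d control=%s region=%s", config$seed,
      config$control, config$region)
  say("distal window: %g-%g um; Sholl 5 um x 13 rings",
      config$distal_window[1], config$distal_window[2])
  say("Z directions: spt=-1 si_ratio=-1 epm_open=-1 fst_immobility=+1")

  with_behavior <- isTRUE(config$behavior) || !is.null(config$behavior_csv)

  if (is.null(config$images_csv)) {
    sim <- stage("synthesis+morphometry", simulate_experiment(
      seed = config$seed, n_animals = config$n_animals,
      cells_per_animal = config$cells_per_animal, region = config$region,
      group_factors = config$group_factors,
      pixel_size = config$pixel_size, salt_pepper = config$salt_pepper,
      gaussian_sd = config$gaussian_sd,
      distal_window = config$distal_window, control = config$control))
    cells <- sim$cells; sholl <- sim$sholl
    behavior <- sim$behavior; zsc <- sim$zscores; animals <- sim$animals
    say("synthetic cells: %d (%d groups x %d animals x %d cells)",
        nrow(cells), length(config$group_factors), config$n_animals,
        config$cells_per_animal)
  } else {
    tab <- stage("image input", read.csv(config$images_csv,
                                         stringsAsFactors = FALSE))
    mm <- stage("morphometry", .measure_tiff_cells(tab, config))
    cells <- mm$cells; sholl <- mm$sholl
    behavior <- NULL; zsc <- NULL; animals <- NULL
    if (!is.null(config$behavior_csv)) {
      behavior <- stage("behavior input",
                        read.csv(config$behavior_csv,
                                 stringsAsFactors = FALSE))
      zsc <- stage("zscores", zscore_table(behavior,
                                           control = config$control))
    }
    metr <- c("n_branches", "n_endpoints", "total_length_um", "chp_um",
              "cha_um2", "sholl_total", "distal_sum")
    animals <- aggregate_per_animal(cells, metrics = metr)
    if (!is.null(zsc))
      animals <- merge(animals, zsc[, c("animal_id", "z_composite")],
                       by = "animal_id")
  }
  say("mean threshold level: %.1f",
      mean(cells$threshold_level, na.rm = TRUE))

  metr <- c("n_branches", "n_endpoints", "total_length_um", "chp_um",
            "cha_um2", "sholl_total", "distal_sum")
  gsum <- stage("group summaries",
                do.call(rbind, lapply(metr, function(m)
                  group_summary(cells, m))))
  anova_tab <- NULL
  if (length(unique(cells$group)) >= 2L) {
    anova_tab <- stage("ANOVA/Tukey", do.call(rbind, lapply(metr, function(m) {
      res <- one_way_anova_tukey(cells[[m]], cells$group)
      cbind(metric = m, level = "cell", F = res$F, p = res$p, res$tukey)
    })))
  } else {
    say("single group: ANOVA stage skipped")
  }

  corr_tab <- NULL
  if (with_behavior && !is.null(animals) && "z_composite" %in% names(animals)) {
    corr_tab <- stage("correlation", do.call(rbind, lapply(
      intersect(metr, names(animals)), function(m) {
        do.call(rbind, lapply(config$correlation_methods, function(meth) {
          ct <- correlate(animals[[m]], animals$z_composite, method = meth)
          data.frame(metric = m, method = meth, r = ct$r, p = ct$p,
                     n = ct$n)
        }))
      })))
    say("correlations computed on %d animals (unit of analysis: animal)",
        nrow(animals))
  } else {
    say("no behavior inputs: correlation stage skipped")
  }

  wcsv <- function(df, name) {
    if (!is.null(df)) write.csv(df, file.path(outdir, name),
                                row.names = FALSE)
  }
  wcsv(cells, "cells.csv")
  wcsv(sholl, "sholl_long.csv")
  wcsv(gsum, "group_summary.csv")
  wcsv(anova_tab, "anova_tukey.csv")
  wcsv(behavior, "behavior.csv")
  wcsv(zsc, "behavior_z.csv")
  wcsv(animals, "animals.csv")
  wcsv(corr_tab, "correlations.csv")
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(list(cells = cells, sholl = sholl, group_summary = gsum,
                 anova = anova_tab, behavior = behavior, zscores = zsc,
                 animals = animals, correlations = corr_tab,
                 outdir = outdir))
}
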