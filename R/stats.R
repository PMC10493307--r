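# Group statistics behind the reporting surface: one-/two-way fixed-effects
# ANOVA with Tukey HSD (studentized-range) multiple comparisons via
# stats::aov / stats::TukeyHSD, and Pearson/Spearman correlation via
# stats::cor.test.

#' One-way ANOVA with Tukey HSD comparisons
#'
#' @param values numeric response.
#' @param group group labels (coerced to factor), >= 2 groups with n >= 2
#'   each.
#' @return A list: `F`, `p`, `df` (c(between, within)) and `tukey`, a
#'   data.frame with one row per group pair (`diff`, `lwr`, `upr`,
#'   `p_adj`).
#' @export
one_way_anova_tukey <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  cnt <- table(group)
  if (any(cnt < 2L))
    stop("every group needs n >= 2 (got ",
         paste(names(cnt)[cnt < 2], collapse = ", "), ")")
  if (length(values) != length(group)) stop("lengths differ")
  fit <- aov(values ~ group)
  tab <- summary(fit)[[1]]
  Fv <- tab$`F value`[1]
  pv <- tab$`Pr(>F)`[1]
  tk <- TukeyHSD(fit)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(F = Fv, p = pv, df = tab$Df, tukey = tukey)
}

#' Two-way fixed-effects ANOVA (group x radius)
#'
#' Standard two-factor decomposition with interaction, as used for Sholl
#' curves (group x ring radius), plus per-radius group contrasts with
#' Tukey adjustment for the ring-wise comparisons.
#'
#' @param values numeric response.
#' @param group,radius the two crossed factors; the layout must be
#'   complete with at least 2 replicates per cell.
#' @return A list: `table` (data.frame with `effect`, `df`, `F`, `p` for
#'   group, radius and interaction) and `per_radius` (data.frame of Tukey
#'   pairwise group contrasts within each radius).
#' @export
two_way_anova <- function(values, group, radius) {
  group <- factor(group); radius <- factor(radius)
  if (length(values) != length(group) || length(values) != length(radius))
    stop("lengths differ")
  cnt <- table(group, radius)
  if (any(cnt == 0L)) stop("incomplete layout: empty group x radius cell")
  if (any(cnt < 2L))
    stop("single replicate per cell: no within-cell variance")
  fit <- aov(values ~ group * radius)
  tab <- summary(fit)[[1]]
  eff <- trimws(rownames(tab))
  keep <- eff != "Residuals"
  main <- data.frame(effect = c("group", "radius", "interaction"),
                     df = tab$Df[keep], F = tab$`F value`[keep],
                     p = tab$`Pr(>F)`[keep])
  per <- do.call(rbind, lapply(levels(radius), function(r) {
    sel <- radius == r
    res <- one_way_anova_tukey(values[sel], group[sel])
    cbind(radius = r, res$tukey)
  }))
  list(table = main, per_radius = per)
}

#' Correlation between a morphometric measure and behavior
#'
#' Pearson product-moment correlation with its t-based p-value, or
#' Spearman rank correlation (Pearson on average ranks, asymptotic
#' p-value).
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list: `r`, `p`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 3L) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, method = method,
       n = length(x))
}

#' Aggregate per-cell morphometry to one row per animal and region
#'
#' Behavioral correlations use the animal as the unit of analysis, so the
#' (typically 5) cells per animal are collapsed by `policy`.
#'
#' @param cells data.frame with `animal_id`, `group`, `region` and numeric
#'   metric columns.
#' @param metrics metric columns to aggregate (default: all numeric).
#' @param policy `"mean"` or `"median"`.
#' @return One row per animal x region, group labels preserved.
#' @export
aggregate_per_animal <- function(cells, metrics = NULL,
                                 policy = c("mean", "median")) {
  policy <- match.arg(policy)
  fun <- if (policy == "mean") mean else median
  if (is.null(metrics))
    metrics <- names(cells)[vapply(cells, is.numeric, logical(1))]
  if (!all(c("animal_id", "group", "region") %in% names(cells)))
    stop("`cells` needs animal_id, group and region columns")
  agg <- aggregate(cells[metrics],
                   by = list(animal_id = cells$animal_id,
                             region = cells$region,
                             group = cells$group),
                   FUN = fun)
  agg[order(agg$region, agg$group, agg$animal_id), , drop = FALSE]
}

#' Per-group mean and SD summary
#'
#' @param df data.frame; `metric` a numeric column name; `by` the grouping
#'   column (default `"group"`).
#' @return data.frame with `group`, `metric`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(df, metric, by = "group") {
  g <- factor(df[[by]], levels = unique(df[[by]]))
  v <- df[[metric]]
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    x <- v[g == lev]
    data.frame(group = lev, metric = metric, n = length(x),
               mean = mean(x), sd = if (length(x) >= 2) sd(x) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
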