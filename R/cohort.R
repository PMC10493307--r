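# Simulated behavioral cohorts. Group means/SDs default to the printed
# last-week values of the sham / PID (post-ischemic depression) / EA
# (electroacupuncture) groups: sucrose preference (%), social-interaction
# ratio, open-arm time (s) and forced-swim immobility (s).

.default_cohort_means <- function() {
  rbind(sham = c(spt = 75.42, si_ratio = 1.18, epm_open = 47.33,
                 fst_immobility = 76.08),
        PID  = c(spt = 65.10, si_ratio = 0.46, epm_open = 13.40,
                 fst_immobility = 111.6),
        EA   = c(spt = 71.22, si_ratio = 0.80, epm_open = 23.33,
                 fst_immobility = 103.0))
}

.default_cohort_sds <- function() {
  rbind(sham = c(spt = 3.58, si_ratio = 0.12, epm_open = 7.19,
                 fst_immobility = 7.34),
        PID  = c(spt = 3.35, si_ratio = 0.06, epm_open = 3.41,
                 fst_immobility = 8.21),
        EA   = c(spt = 3.46, si_ratio = 0.07, epm_open = 4.66,
                 fst_immobility = 13.37))
}

# metric support: SPT clipped to [0,100], ratio and times to >= 0, open-arm
# time to the 300 s session, immobility to the 240 s scored window.
.cohort_bounds <- function() {
  list(spt = c(0, 100), si_ratio = c(0, Inf), epm_open = c(0, 300),
       fst_immobility = c(0, 240))
}

#' Specification of a simulated behavioral cohort
#'
#' @param groups group labels (rows of `means`/`sds`).
#' @param n animals per group (scalar or per-group vector, each >= 2).
#' @param means,sds group x metric matrices with columns `spt`, `si_ratio`,
#'   `epm_open`, `fst_immobility`; defaults are the printed sham/PID/EA
#'   group means and SDs.
#' @param rho latent correlation between an animal's four test outcomes
#'   (Gaussian copula); 0 (the default) draws each metric independently.
#' @param seed integer seed stored with the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups = c("sham", "PID", "EA"), n = 12,
                        means = .default_cohort_means(),
                        sds = .default_cohort_sds(),
                        rho = 0, seed = 1L) {
  means <- as.matrix(means); sds <- as.matrix(sds)
  if (is.null(rownames(means))) rownames(means) <- groups
  if (is.null(rownames(sds))) rownames(sds) <- groups
  means <- means[groups, , drop = FALSE]
  sds <- sds[groups, , drop = FALSE]
  n <- rep_len(n, length(groups))
  if (any(n < 2)) stop("each group needs n >= 2")
  if (any(sds < 0)) stop("sds must be >= 0")
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1)")
  structure(list(groups = groups, n = as.integer(n), means = means,
                 sds = sds, rho = rho, seed = as.integer(seed)),
            class = "cohort_spec")
}

# inverse-CDF truncated normal: u ~ U(0,1) mapped through the normal CDF
# restricted to [lo, hi]
.qtruncnorm <- function(u, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), length(u)))
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

#' Simulate a behavioral cohort
#'
#' Draws one row per animal from per-group truncated normals (see
#' [cohort_spec()]); a positive `rho` correlates the four tests through a
#' Gaussian copula. Deterministic for a fixed spec (the seed lives in the
#' spec).
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame with columns `animal_id`, `group`, `spt`,
#'   `si_ratio`, `epm_open`, `fst_immobility`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  metrics <- colnames(spec$means)
  bounds <- .cohort_bounds()
  nm <- length(metrics)
  with_seed(spec$seed, {
    out <- vector("list", length(spec$groups))
    aid <- 0L
    for (g in seq_along(spec$groups)) {
      ng <- spec$n[g]
      # latent equicorrelated normals -> uniforms
      z <- matrix(rnorm(ng * nm), ng, nm)
      if (spec$rho > 0) {
        S <- matrix(spec$rho, nm, nm); diag(S) <- 1
        z <- z %*% chol(S)
      }
      u <- pnorm(z)
      vals <- sapply(seq_len(nm), function(j) {
        b <- bounds[[metrics[j]]]
        .qtruncnorm(u[, j], spec$means[g, j], spec$sds[g, j], b[1], b[2])
      })
      vals <- matrix(vals, ng, nm, dimnames = list(NULL, metrics))
      df <- data.frame(animal_id = sprintf("%s_%02d", spec$groups[g],
                                           seq_len(ng)),
                       group = spec$groups[g])
      out[[g]] <- cbind(df, as.data.frame(vals))
      aid <- aid + ng
    }
    do.call(rbind, out)
  })
}
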