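## Simulation of case-ascertained triads from the X-linked penetrance model
## and Monte-Carlo power estimation.
##
## Because case-only triads are analysed conditionally on the child being
## affected, simulation draws each family's phased configuration (t, u, f)
## directly from the normalised case-triad distribution of the model --
## mathematically identical to prospective simulation with ascertainment
## rejection, and much faster.

#' Simulation specification
#'
#' Describes one window of markers (a single SNP is the common case) and the
#' generative truth for simulating case-parent triads.
#'
#' @param haplotype_frequencies simplex of haplotype frequencies in
#'   lexicographic haplotype order; for a single SNP use
#'   `c(1 - maf, maf)` so the variant allele is the second haplotype.
#' @param true_rr_single_dose vector of true single-dose relative risks
#'   (reference entry 1; only ratios matter).
#' @param model a [penetrance_spec()] or model name.
#' @param n_triads number of case-parent triads.
#' @param sex_ratio_cases probability that a case is male.
#' @param missing_rate per-call missing probability applied independently to
#'   every individual x marker genotype.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(haplotype_frequencies, true_rr_single_dose,
                     model = "no_xinactivation", n_triads,
                     sex_ratio_cases = 0.5, missing_rate = 0, seed = NULL) {
  p <- as.numeric(haplotype_frequencies)
  r <- as.numeric(true_rr_single_dose)
  H <- length(p)
  stopifnot(H >= 2, abs(log2(H) - round(log2(H))) < 1e-9,
            all(p >= 0), abs(sum(p) - 1) < 1e-8,
            length(r) == H, all(r >= 0), any(r > 0),
            n_triads >= 1,
            sex_ratio_cases >= 0, sex_ratio_cases <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(haplotype_frequencies = p / sum(p),
                 true_rr_single_dose = r,
                 model = as_penetrance_spec(model),
                 n_triads = as.integer(n_triads),
                 sex_ratio_cases = sex_ratio_cases,
                 missing_rate = missing_rate,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 n_loci = as.integer(round(log2(H)))),
            class = "sim_spec")
}

#' Single-SNP simulation specification from a minor allele frequency
#'
#' @param maf minor allele frequency of the variant allele.
#' @param rr true single-dose relative risk of the variant allele.
#' @param ... further arguments to [sim_spec()].
#' @return A `sim_spec` for one SNP with haplotypes (major, variant).
#' @export
snp_sim_spec <- function(maf, rr, ...) {
  sim_spec(haplotype_frequencies = c(1 - maf, maf),
           true_rr_single_dose = c(1, rr), ...)
}

## Case-triad configuration distribution over all H^3 cells for one sex.
config_distribution <- function(p, r, model, sex) {
  H <- length(p)
  grid <- expand.grid(t = seq_len(H), u = seq_len(H), f = seq_len(H))
  w <- cell_prob_core(grid$t, grid$u, grid$f, rep(sex, nrow(grid)), p, r, model)
  list(grid = grid, prob = w)
}

#' Simulate case-parent triads
#'
#' Child sex is Bernoulli(`sex_ratio_cases`); each triad's phased
#' configuration is drawn exactly from the case-ascertained distribution of
#' the penetrance model for that sex; genotypes are then unphased (mothers
#' and girls reported as unordered pairs) and masked at the missing rate.
#' Reproducible given the seed.
#'
#' @param spec a [sim_spec()].
#' @return A `triad_data` object with a synthetic marker map (markers
#'   `snp1..snpL` on X, alleles A/C with C the variant).
#' @export
simulate_triads <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  p <- spec$haplotype_frequencies
  r <- spec$true_rr_single_dose
  model <- spec$model$model
  L <- spec$n_loci; H <- length(p); n <- spec$n_triads
  if (model == "males_only") {
    if (sum(p * male_risk(r, model)) <= 0)
      stop("degenerate frequencies: no support where risk is positive")
  } else if (sum(p * r) <= 0) {
    stop("degenerate frequencies: no support where risk is positive")
  }
  map <- data.frame(marker_id = paste0("snp", seq_len(L)),
                    chromosome = "X",
                    position_bp = 1000000L + (seq_len(L) - 1L) * 5000L,
                    allele1 = "A", allele2 = "C",
                    stringsAsFactors = FALSE)
  codes <- enumerate_haplotypes(list(start_index = 0L, length = L), map)$codes

  sex <- ifelse(stats::runif(n) < spec$sex_ratio_cases, 1L, 2L)
  if (model == "males_only") sex[] <- 1L
  if (model == "females_only") sex[] <- 2L
  tuf <- matrix(0L, n, 3L)
  for (s in c(1L, 2L)) {
    who <- which(sex == s)
    if (!length(who)) next
    dist <- config_distribution(p, r, model, s)
    if (all(dist$prob <= 0)) stop("degenerate frequencies for this sex stratum")
    cells <- sample.int(nrow(dist$grid), length(who), replace = TRUE,
                        prob = dist$prob)
    tuf[who, ] <- as.matrix(dist$grid[cells, ])
  }
  m_a <- codes[tuf[, 1], , drop = FALSE]; m_b <- codes[tuf[, 2], , drop = FALSE]
  mother1 <- pmin(m_a, m_b); mother2 <- pmax(m_a, m_b)
  father <- codes[tuf[, 3], , drop = FALSE]
  child1 <- matrix(NA_integer_, n, L); child2 <- matrix(NA_integer_, n, L)
  boys <- sex == 1L
  child1[boys, ] <- codes[tuf[boys, 1], , drop = FALSE]
  if (any(!boys)) {
    c_a <- codes[tuf[!boys, 1], , drop = FALSE]
    c_b <- codes[tuf[!boys, 3], , drop = FALSE]
    child1[!boys, ] <- pmin(c_a, c_b); child2[!boys, ] <- pmax(c_a, c_b)
  }
  if (spec$missing_rate > 0) {
    mask <- function(g) { g[matrix(stats::runif(n * L) < spec$missing_rate, n, L)] <- NA_integer_; g }
    mm <- matrix(stats::runif(n * L) < spec$missing_rate, n, L)
    mother1[mm] <- NA_integer_; mother2[mm] <- NA_integer_
    father <- mask(father)
    cm <- matrix(stats::runif(n * L) < spec$missing_rate, n, L)
    child1[cm] <- NA_integer_
    child2[cm & !boys] <- NA_integer_
  }
  triad_dataset(map, sprintf("fam%05d", seq_len(n)), sex,
                mother1, mother2, father, child1, child2,
                provenance = sprintf(
                  "simulated: model %s, n = %d, %d locus/loci, missing rate %g",
                  model, n, L, spec$missing_rate))
}

#' Simulate a panel of independent SNPs
#'
#' Draws each family's sex once, then samples every SNP independently from
#' its own single-SNP case-triad distribution (linkage equilibrium between
#' markers). At most one SNP is typically given a non-null relative risk;
#' this is the generator behind null-scan calibration and planted-effect
#' scan checks.
#'
#' @param mafs vector of per-SNP minor allele frequencies.
#' @param rrs vector of per-SNP true variant relative risks (1 = null).
#' @param model a [penetrance_spec()] or model name.
#' @param n_triads number of triads.
#' @param sex_ratio_cases probability a case is male.
#' @param missing_rate per-call missing probability.
#' @param seed integer seed.
#' @return A `triad_data` with `length(mafs)` markers.
#' @export
simulate_snp_panel <- function(mafs, rrs = rep(1, length(mafs)),
                               model = "no_xinactivation", n_triads,
                               sex_ratio_cases = 0.5, missing_rate = 0,
                               seed = NULL) {
  stopifnot(length(mafs) == length(rrs), length(mafs) >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- length(mafs); n <- n_triads
  model <- as_penetrance_spec(model)$model
  sex <- ifelse(stats::runif(n) < sex_ratio_cases, 1L, 2L)
  if (model == "males_only") sex[] <- 1L
  if (model == "females_only") sex[] <- 2L
  mother1 <- mother2 <- father <- child1 <- child2 <-
    matrix(NA_integer_, n, L)
  boys <- sex == 1L
  for (j in seq_len(L)) {
    p <- c(1 - mafs[j], mafs[j]); r <- c(1, rrs[j])
    for (s in c(1L, 2L)) {
      who <- which(sex == s)
      if (!length(who)) next
      dist <- config_distribution(p, r, model, s)
      cells <- sample.int(8L, length(who), replace = TRUE, prob = dist$prob)
      g <- as.matrix(dist$grid[cells, ])
      mother1[who, j] <- pmin(g[, 1], g[, 2])
      mother2[who, j] <- pmax(g[, 1], g[, 2])
      father[who, j] <- g[, 3]
      if (s == 1L) child1[who, j] <- g[, 1]
      else { child1[who, j] <- pmin(g[, 1], g[, 3]); child2[who, j] <- pmax(g[, 1], g[, 3]) }
    }
  }
  if (missing_rate > 0) {
    mm <- matrix(stats::runif(n * L) < missing_rate, n, L)
    mother1[mm] <- NA_integer_; mother2[mm] <- NA_integer_
    father[matrix(stats::runif(n * L) < missing_rate, n, L)] <- NA_integer_
    cm <- matrix(stats::runif(n * L) < missing_rate, n, L)
    child1[cm] <- NA_integer_
    child2[cm & !boys] <- NA_integer_
  }
  map <- data.frame(marker_id = paste0("snp", seq_len(L)),
                    chromosome = "X",
                    position_bp = 1000000L + (seq_len(L) - 1L) * 5000L,
                    allele1 = "A", allele2 = "C",
                    stringsAsFactors = FALSE)
  triad_dataset(map, sprintf("fam%05d", seq_len(n)), sex,
                mother1, mother2, father, child1, child2,
                provenance = sprintf(
                  "simulated SNP panel: model %s, n = %d, %d independent SNPs",
                  model, n, L))
}

#' Monte-Carlo power of the window LRT
#'
#' For each replicate: simulate triads under `spec`, fit the matching model,
#' and record whether the window LRT p-value falls below `alpha`. For the
#' sex-stratified models the sample size is halved and only the analysed sex
#' simulated (mirroring a design where half the ascertained cases are of
#' each sex). Replicates whose fit fails or does not converge are excluded
#' with a warning.
#'
#' @param spec a [sim_spec()]; its `seed` spawns one sub-seed per replicate.
#' @param n_replicates number of simulation replicates.
#' @param alpha significance level.
#' @param min_freq pruning threshold used in the per-replicate fits.
#' @return A `power_result`: power, Monte-Carlo standard error, replicate
#'   counts and the spec.
#' @export
estimate_power <- function(spec, n_replicates = 1000L, alpha = 0.05,
                           min_freq = 0.01) {
  stopifnot(inherits(spec, "sim_spec"), n_replicates >= 1)
  model <- spec$model$model
  stratified <- model %in% c("males_only", "females_only")
  n_use <- if (stratified) max(1L, as.integer(round(spec$n_triads / 2))) else spec$n_triads
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  pvals <- rep(NA_real_, n_replicates)
  for (i in seq_len(n_replicates)) {
    s_i <- spec
    s_i$seed <- rep_seeds[i]
    s_i$n_triads <- n_use
    dat <- simulate_triads(s_i)
    fit <- tryCatch(fit_window(dat, spec = spec$model, min_freq = min_freq),
                    xtriad_error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit$converged)) pvals[i] <- fit$p_value
  }
  ok <- !is.na(pvals)
  n_failed <- sum(!ok)
  if (!any(ok)) stop("all replicates failed to produce a fit")
  if (n_failed > 0)
    warning(sprintf("%d of %d replicates failed to converge and were excluded",
                    n_failed, n_replicates))
  power <- mean(pvals[ok] < alpha)
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / sum(ok)),
                 n_replicates = sum(ok),
                 n_failed = n_failed,
                 alpha = alpha,
                 n_triads_fitted = n_use,
                 spec = spec,
                 p_values = pvals),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power_result: power %.3f (MC SE %.3f) over %d replicates, alpha %g\n",
              x$power, x$mc_se, x$n_replicates, x$alpha))
  invisible(x)
}

#' Power over a grid of relative risks, allele frequencies and sample sizes
#'
#' Evaluates [estimate_power()] over the Cartesian product of single-SNP
#' scenarios. Each grid cell receives its own seed derived from the master
#' seed, so the grid is reproducible and cells are independent.
#'
#' @param rr_values true variant relative risks.
#' @param maf_values minor allele frequencies.
#' @param n_values triad sample sizes (halved internally for the
#'   sex-stratified models).
#' @param models character vector of model names.
#' @param n_replicates replicates per cell.
#' @param alpha significance level.
#' @param seed master seed.
#' @return A data.frame keyed by (model, rr, maf, n) with power, Monte-Carlo
#'   standard error, effective replicate count and a note for failed cells.
#' @export
power_grid <- function(rr_values, maf_values, n_values,
                       models = "no_xinactivation", n_replicates = 200L,
                       alpha = 0.05, seed = 1L) {
  stopifnot(length(rr_values) >= 1, length(maf_values) >= 1,
            length(n_values) >= 1, length(models) >= 1)
  grid <- expand.grid(model = models, rr = rr_values, maf = maf_values,
                      n = n_values, stringsAsFactors = FALSE)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  grid$power <- NA_real_; grid$mc_se <- NA_real_
  grid$n_replicates <- NA_integer_; grid$note <- ""
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch(
      estimate_power(snp_sim_spec(grid$maf[i], grid$rr[i],
                                  model = grid$model[i],
                                  n_triads = grid$n[i],
                                  seed = cell_seeds[i]),
                     n_replicates = n_replicates, alpha = alpha),
      error = function(e) e)
    if (inherits(res, "power_result")) {
      grid$power[i] <- res$power
      grid$mc_se[i] <- res$mc_se
      grid$n_replicates[i] <- res$n_replicates
    } else grid$note[i] <- conditionMessage(res)
  }
  attr(grid, "seed") <- seed
  attr(grid, "alpha") <- alpha
  grid
}
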