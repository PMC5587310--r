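## Likelihood maximisation for one window: EM for haplotype frequencies
## under the null (all relative risks 1), rare-haplotype pruning, and
## quasi-Newton maximisation of the observed-data likelihood for the full
## model, with Wald confidence intervals and a window-level LRT.

#' Null-model haplotype frequency estimation by EM
#'
#' Maximises the observed-data likelihood with all relative risks fixed at 1
#' (pure haplotype-frequency estimation). The E-step weights each compatible
#' configuration of a family by the product of current frequencies; the
#' M-step is the weighted haplotype-count update (each configuration
#' contributes its transmitted, untransmitted and paternal haplotype). The
#' likelihood is non-decreasing over iterations; iteration stops when the
#' gain falls below `tol` or after `max_iter` iterations. The reference
#' haplotype is set to the most frequent (ties broken by lexicographically
#' smallest label).
#'
#' @param families family list (see [loglik()]).
#' @param haps starting `hap_table` (frequencies used as initial values).
#' @param tol log-likelihood gain below which EM stops.
#' @param max_iter iteration cap.
#' @return List with `haps` (fitted frequencies, reference set), `loglik`,
#'   `n_iter`, `converged` and the per-iteration log-likelihood `trace`.
#' @export
fit_null <- function(families, haps, tol = 1e-8, max_iter = 1000L) {
  fl <- flatten_families(families)
  H <- length(haps$frequencies)
  p <- haps$frequencies
  if (all(p == 0) || any(p < 0)) p <- rep(1 / H, H)
  N3 <- 3 * sum(fl$w_f)
  trace <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    w <- p[fl$Ti] * p[fl$Ui] * p[fl$Fi]
    S <- wtab(fl$fam_idx, w, fl$K)
    if (any(S <= 0)) {
      ## a family has zero mass under current p; restart from uniform once
      p <- rep(1 / H, H)
      w <- p[fl$Ti] * p[fl$Ui] * p[fl$Fi]
      S <- wtab(fl$fam_idx, w, fl$K)
      if (any(S <= 0)) stop("family with zero probability mass under any frequencies")
    }
    ll <- sum(fl$w_f * log(S))
    trace <- c(trace, ll)
    if (it > 1L && ll - ll_prev < tol) { converged <- TRUE; break }
    ll_prev <- ll
    post <- w / S[fl$fam_idx] * fl$w_f[fl$fam_idx]
    cnt <- wtab(fl$Ti, post, H) + wtab(fl$Ui, post, H) + wtab(fl$Fi, post, H)
    p <- cnt / N3
  }
  haps$frequencies <- p
  haps$reference <- choose_reference(p, haps$haplotypes)
  list(haps = haps, loglik = trace[length(trace)], n_iter = length(trace),
       converged = converged, trace = trace)
}

choose_reference <- function(p, labels) {
  cands <- which(p > max(p) - 1e-12)
  as.integer(cands[order(labels[cands])][1])
}

#' Prune rare haplotypes after the null fit
#'
#' Haplotypes with fitted frequency below `min_freq` are removed and the
#' remaining frequencies renormalised; configurations referencing a pruned
#' haplotype are deleted, and families left with no configuration are
#' excluded (their weight is returned as `n_families_dropped`).
#'
#' @param haps `hap_table` with null-fitted frequencies.
#' @param min_freq pruning threshold.
#' @param families family list.
#' @return List `haps`, `families`, `pruned` (labels removed) and
#'   `n_families_dropped`.
#' @export
prune_rare <- function(haps, min_freq = 0.01, families = list()) {
  keep <- haps$frequencies >= min_freq
  if (sum(keep) < 2L)
    stop_xtriad("window uninformative: fewer than 2 haplotypes above the frequency threshold",
                "xtriad_uninformative")
  pruned <- haps$haplotypes[!keep]
  if (!any(!keep))
    return(list(haps = haps, families = families, pruned = character(),
                n_families_dropped = 0))
  newindex <- cumsum(keep)
  newindex[!keep] <- NA_integer_
  haps2 <- hap_table(haps$haplotypes[keep], haps$codes[keep, , drop = FALSE],
                     haps$frequencies[keep] / sum(haps$frequencies[keep]),
                     reference = NA_integer_, marker_ids = haps$marker_ids)
  haps2$reference <- choose_reference(haps2$frequencies, haps2$haplotypes)
  dropped <- 0
  fams2 <- list()
  for (f in families) {
    cfg <- f$configs
    ok <- rowSums(matrix(keep[cfg], nrow = nrow(cfg))) == 3L
    cfg <- cfg[ok, , drop = FALSE]
    if (!nrow(cfg)) { dropped <- dropped + (f$weight %||% 1); next }
    cfg[] <- newindex[cfg]
    f$configs <- cfg
    fams2[[length(fams2) + 1L]] <- f
  }
  if (!length(fams2))
    stop_xtriad("window uninformative: no family compatible with the retained haplotypes",
                "xtriad_uninformative")
  list(haps = haps2, families = fams2, pruned = pruned,
       n_families_dropped = dropped)
}

#' Full-model fit: joint maximisation over frequencies and relative risks
#'
#' Maximises the observed-data log-likelihood jointly over haplotype
#' frequencies (softmax-transformed) and log relative risks (reference fixed
#' at 0), starting from the null EM frequencies and r = 1. Standard errors
#' come from the inverse of the numerically differentiated observed
#' information on the transformed scale; 95% Wald intervals on log r are
#' exponentiated. The window LRT compares all r free against all r = 1 with
#' `df = H - 1` and a chi-square reference.
#'
#' @param families family list (already pruned; for the sex-stratified
#'   models the other sex must have been excluded).
#' @param haps pruned `hap_table` with reference set (if unset, the most
#'   frequent haplotype is used).
#' @param spec a [penetrance_spec()].
#' @param reference optional reference haplotype override (index or label).
#' @param max_abs_log_rr cap on |log r| used to flag separation.
#' @return A `window_fit` object.
#' @export
fit_full <- function(families, haps, spec, reference = NULL,
                     max_abs_log_rr = 15) {
  spec <- as_penetrance_spec(spec)
  if (spec$model == "males_only") families <- Filter(function(f) f$sex == 1L, families)
  if (spec$model == "females_only") families <- Filter(function(f) f$sex == 2L, families)
  if (!length(families))
    stop_xtriad("no families available for this model/sex selection", "xtriad_no_data")
  fl <- flatten_families(families)
  H <- length(haps$frequencies)

  ## null EM on exactly these families so full and null are nested on the
  ## same data (guarantees lrt >= 0)
  null_fit <- fit_null(families, haps)
  p0 <- pmax(null_fit$haps$frequencies, 1e-10)
  p0 <- p0 / sum(p0)
  ref <- resolve_reference(reference, haps) %||% null_fit$haps$reference

  model <- spec$model
  beta_pos <- setdiff(seq_len(H), ref)
  unpack <- function(par) {
    a <- c(0, par[seq_len(H - 1L)])
    p <- exp(a - max(a)); p <- p / sum(p)
    b <- numeric(H); b[beta_pos] <- par[H:(2L * H - 2L)]
    list(p = p, b = b, r = exp(b))
  }
  negll <- function(par) {
    th <- unpack(par)
    ll <- ll_flat(fl, th$p, th$r, model)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  init <- c(log(p0[-1]) - log(p0[1]), rep(0, H - 1L))
  opt <- stats::optim(init, negll, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-14))
  boundary <- FALSE
  if (any(abs(opt$par[H:(2L * H - 2L)]) > max_abs_log_rr)) {
    ## separation: refit with |log r| bounded, flag the boundary
    boundary <- TRUE
    opt <- stats::optim(pmin(pmax(opt$par, -30), 30), negll, method = "L-BFGS-B",
                        lower = c(rep(-30, H - 1L), rep(-max_abs_log_rr, H - 1L)),
                        upper = c(rep(30, H - 1L), rep(max_abs_log_rr, H - 1L)),
                        control = list(maxit = 1000L, factr = 1e4))
  }
  th <- unpack(opt$par)
  ll_full <- -opt$value
  ll_null <- null_fit$loglik
  if (ll_full < ll_null - 1e-8) {
    ## numerical slip: the null is a boundary point of the full model
    th <- unpack(c(log(p0[-1]) - log(p0[1]), rep(0, H - 1L)))
    ll_full <- ll_null
  }

  ## Wald inference on log r from the observed information
  se_b <- rep(NA_real_, H)
  singular <- FALSE
  hess <- try(stats::optimHess(opt$par, negll), silent = TRUE)
  if (!inherits(hess, "try-error")) {
    vc <- try(solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(is.finite(diag(vc)))) {
      d <- diag(vc)[H:(2L * H - 2L)]
      if (all(d > 0)) se_b[beta_pos] <- sqrt(d) else singular <- TRUE
    } else singular <- TRUE
  } else singular <- TRUE
  se_b[ref] <- 0
  z <- stats::qnorm(0.975)
  rr <- th$r
  ci_lo <- exp(th$b - z * se_b); ci_hi <- exp(th$b + z * se_b)
  dd <- rr^2
  dd_lo <- exp(2 * th$b - z * 2 * se_b); dd_hi <- exp(2 * th$b + z * 2 * se_b)
  ci_lo[ref] <- ci_hi[ref] <- 1; dd_lo[ref] <- dd_hi[ref] <- 1

  df <- H - 1L
  lrt <- max(0, 2 * (ll_full - ll_null))
  haps_out <- haps
  haps_out$frequencies <- th$p
  haps_out$reference <- ref
  structure(list(
    haplotype_table = haps_out,
    rr_single_dose = rr,
    rr_ci = cbind(lower = ci_lo, upper = ci_hi),
    rr_double_dose = dd,
    rr_dd_ci = cbind(lower = dd_lo, upper = dd_hi),
    rr_boys = implied_boy_rr(rr, spec),
    se_log_rr = se_b,
    loglik_full = ll_full,
    loglik_null = ll_null,
    lrt_statistic = lrt,
    df = df,
    p_value = lrt_pvalue(ll_full, ll_null, df),
    n_families_used = sum(fl$w_f),
    pruned_haplotypes = character(),
    converged = opt$convergence == 0L && !singular,
    boundary = boundary,
    singular_information = singular,
    model = spec$model), class = "window_fit")
}

resolve_reference <- function(reference, haps) {
  if (is.null(reference)) return(NULL)
  if (is.character(reference)) {
    ref <- match(reference, haps$haplotypes)
    if (is.na(ref)) stop("reference haplotype '", reference, "' not in table")
    return(as.integer(ref))
  }
  stopifnot(reference >= 1, reference <= length(haps$haplotypes))
  as.integer(reference)
}

#' Likelihood-ratio p-value
#'
#' @param loglik_full,loglik_null log-likelihoods of the nested fits
#'   (`loglik_full >= loglik_null` up to 1e-8).
#' @param df degrees of freedom (number of free relative risks).
#' @return Upper-tail chi-square probability of `2 * (loglik_full -
#'   loglik_null)` at `df`.
#' @export
lrt_pvalue <- function(loglik_full, loglik_null, df) {
  stopifnot(df >= 1)
  if (loglik_full < loglik_null - 1e-8)
    stop("internal consistency error: full log-likelihood below null")
  stat <- max(0, 2 * (loglik_full - loglik_null))
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' @export
print.window_fit <- function(x, ...) {
  ht <- x$haplotype_table
  cat(sprintf("window_fit (%s): %d haplotypes, %g families\n",
              x$model, length(ht$haplotypes), x$n_families_used))
  df <- data.frame(haplotype = ht$haplotypes,
                   freq = round(ht$frequencies, 4),
                   RR = round(x$rr_single_dose, 4),
                   ci_lo = round(x$rr_ci[, 1], 4),
                   ci_hi = round(x$rr_ci[, 2], 4),
                   RR_dd = round(x$rr_double_dose, 4))
  df$ref <- seq_len(nrow(df)) == ht$reference
  print(df, row.names = FALSE)
  cat(sprintf("LRT = %.4g on %d df, p = %.4g\n", x$lrt_statistic, x$df, x$p_value))
  if (length(x$pruned_haplotypes))
    cat("pruned:", paste(x$pruned_haplotypes, collapse = ", "), "\n")
  invisible(x)
}

## ---- window preparation ----------------------------------------------------

## Group families by identical (sex, window genotype) pattern and enumerate
## configurations once per pattern; returns the family list plus exclusion
## counts. Sex filtering for the stratified models happens here.
prepare_window <- function(data, window, spec, config_cap = 65536L) {
  spec <- as_penetrance_spec(spec)
  idx <- window$start_index + seq_len(window$length)
  keep <- rep(TRUE, length(data$families))
  if (spec$model == "males_only") keep <- data$sex == 1L
  if (spec$model == "females_only") keep <- data$sex == 2L
  if (!any(keep))
    stop_xtriad("no triads of the requested sex", "xtriad_no_data")
  rows <- which(keep)
  gm1 <- data$mother1[rows, idx, drop = FALSE]
  gm2 <- data$mother2[rows, idx, drop = FALSE]
  gf <- data$father[rows, idx, drop = FALSE]
  gc1 <- data$child1[rows, idx, drop = FALSE]
  gc2 <- data$child2[rows, idx, drop = FALSE]
  sexv <- data$sex[rows]
  pat_key <- paste(sexv,
                   apply(gm1, 1, paste, collapse = ","),
                   apply(gm2, 1, paste, collapse = ","),
                   apply(gf, 1, paste, collapse = ","),
                   apply(gc1, 1, paste, collapse = ","),
                   apply(gc2, 1, paste, collapse = ","), sep = "|")
  haps <- enumerate_haplotypes(window, data$map)
  u <- !duplicated(pat_key)
  urows <- which(u)
  counts <- table(factor(pat_key, levels = pat_key[u]))
  families <- list()
  n_mendel <- 0
  for (k in seq_along(urows)) {
    i <- urows[k]
    cfg <- configs_for_pattern(gm1[i, ], gm2[i, ], gf[i, ], gc1[i, ], gc2[i, ],
                               sexv[i], haps$codes, config_cap = config_cap,
                               family_id = data$families[rows[i]])
    if (!nrow(cfg)) { n_mendel <- n_mendel + as.numeric(counts[k]); next }
    families[[length(families) + 1L]] <-
      list(sex = sexv[i], configs = cfg, weight = as.numeric(counts[k]))
  }
  if (!length(families))
    stop_xtriad("all families Mendelian-inconsistent in this window", "xtriad_no_data")
  list(haps = haps, families = families, n_mendelian_excluded = n_mendel,
       n_families = sum(vapply(families, `[[`, 0, "weight")))
}

#' Fit one window end-to-end
#'
#' Convenience wrapper running the full pipeline on one window: enumerate
#' haplotypes and configurations (grouping families with identical genotype
#' patterns), drop Mendelian-inconsistent families, fit the null EM, prune
#' rare haplotypes, and fit the full model.
#'
#' @param data a `triad_data` object.
#' @param window a window from [make_windows()]; default is the whole map
#'   (must then have at most 4 markers).
#' @param spec a [penetrance_spec()] or model name.
#' @param min_freq rare-haplotype pruning threshold.
#' @param config_cap per-family configuration cap.
#' @param reference optional reference haplotype override.
#' @return A `window_fit` with Mendelian-exclusion and pruning metadata.
#' @export
fit_window <- function(data, window = NULL, spec = penetrance_spec(),
                       min_freq = 0.01, config_cap = 65536L,
                       reference = NULL) {
  spec <- as_penetrance_spec(spec)
  if (is.null(window))
    window <- list(start_index = 0L, length = nrow(data$map),
                   marker_ids = data$map$marker_id)
  prep <- prepare_window(data, window, spec, config_cap)
  nf <- fit_null(prep$families, prep$haps)
  pr <- prune_rare(nf$haps, min_freq, prep$families)
  fit <- fit_full(pr$families, pr$haps, spec, reference = reference)
  fit$pruned_haplotypes <- pr$pruned
  fit$n_mendelian_excluded <- prep$n_mendelian_excluded
  fit$n_pruned_families <- pr$n_families_dropped
  fit$window <- window
  fit
}
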