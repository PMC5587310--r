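## The X-linked case-parent triad penetrance model.
##
## A window of 1-4 contiguous SNPs defines H = 2^length haplotypes with
## population frequencies p_h and single-dose relative risks r_h in girls
## (reference haplotype r = 1). A fully phased explanation of one triad is a
## configuration (t, u, f): the maternal transmitted and untransmitted
## haplotypes and the paternal haplotype. Conditional on the child being an
## affected case of known sex, the probability of a configuration is
##
##   boys:  p_t p_u p_f r^(m)_t / C_m,   C_m = sum_h p_h r^(m)_h
##   girls: p_t p_u p_f r_t r_f / C_f,   C_f = (sum_h p_h r_h)^2
##
## where r^(m) is the boy coupling: r^2 under X-inactivation, r without.
## Sex-specific baseline prevalences cancel in this conditional likelihood,
## so case-only triads estimate p and r but no baselines.

#' Penetrance model specification
#'
#' Chooses which of the four model parameterisations is fitted. All models
#' assume a multiplicative dose-response in girls, so the double-dose
#' relative risk is the square of the single-dose relative risk. Under
#' `"xinactivation"` the boy relative risk equals the girls' double-dose
#' risk; under `"no_xinactivation"` it equals the girls' single-dose risk.
#' `"males_only"` and `"females_only"` fit one sex alone.
#'
#' @param model one of `"no_xinactivation"`, `"xinactivation"`,
#'   `"males_only"`, `"females_only"`.
#' @return An object of class `penetrance_spec`.
#' @export
penetrance_spec <- function(model = c("no_xinactivation", "xinactivation",
                                      "males_only", "females_only")) {
  model <- match.arg(model)
  structure(list(model = model, dose_response = "multiplicative"),
            class = "penetrance_spec")
}

as_penetrance_spec <- function(spec) {
  if (inherits(spec, "penetrance_spec")) spec else penetrance_spec(spec)
}

#' @export
print.penetrance_spec <- function(x, ...) {
  cat(sprintf("penetrance_spec: %s (multiplicative dose-response)\n", x$model))
  invisible(x)
}

#' Multiplicative dose-response: implied double-dose relative risk
#'
#' Under the multiplicative model the relative risk for girls carrying two
#' copies of a haplotype is the square of the single-dose relative risk.
#'
#' @param rr_single single-dose relative risk(s).
#' @return `rr_single^2`.
#' @export
double_dose_rr <- function(rr_single) {
  stopifnot(is.numeric(rr_single), all(rr_single >= 0))
  rr_single^2
}

#' Boy relative risk implied by the X-inactivation coupling
#'
#' @param rr_single girls' single-dose relative risk(s).
#' @param spec a [penetrance_spec()] (or model name).
#' @return The boy relative risk: `rr_single^2` under X-inactivation,
#'   `rr_single` without; for `males_only` the fitted risks are already the
#'   boys' own, and for `females_only` no boy risk is implied (`NA`).
#' @export
implied_boy_rr <- function(rr_single, spec) {
  spec <- as_penetrance_spec(spec)
  switch(spec$model,
         xinactivation = rr_single^2,
         no_xinactivation = rr_single,
         males_only = rr_single,
         females_only = rep(NA_real_, length(rr_single)))
}

#' Enumerate the haplotypes of a window
#'
#' All `2^length` allele combinations over the window's markers, ordered
#' lexicographically by allele label, with uniform initial frequencies and
#' the reference haplotype unset.
#'
#' @param window a window as returned by [make_windows()] (0-based
#'   `start_index` and `length` in 1..4).
#' @param map a marker map data.frame (see [triad_dataset()]).
#' @return A `hap_table`: list with `haplotypes` (label strings), `codes`
#'   (H x length matrix of allele codes 1/2), `frequencies` and `reference`.
#' @export
enumerate_haplotypes <- function(window, map) {
  idx <- window$start_index + seq_len(window$length)
  stopifnot(window$length >= 1, window$length <= 4,
            all(idx >= 1), all(idx <= nrow(map)))
  sub <- map[idx, , drop = FALSE]
  if (any(is.na(sub$allele2)))
    stop(sprintf("marker %s is monomorphic in the data; filter before analysis",
                 sub$marker_id[which(is.na(sub$allele2))[1]]))
  L <- window$length
  H <- 2L^L
  codes <- matrix(0L, H, L)
  for (l in seq_len(L))
    codes[, l] <- ((seq_len(H) - 1L) %/% 2L^(L - l)) %% 2L + 1L
  labels <- vapply(seq_len(H), function(h)
    paste(vapply(seq_len(L), function(l)
      c(sub$allele1[l], sub$allele2[l])[codes[h, l]], ""), collapse = ""),
    "")
  ord <- order(labels)
  hap_table(haplotypes = labels[ord], codes = codes[ord, , drop = FALSE],
            frequencies = rep(1 / H, H), reference = NA_integer_,
            marker_ids = sub$marker_id)
}

hap_table <- function(haplotypes, codes, frequencies, reference = NA_integer_,
                      marker_ids = NULL) {
  stopifnot(length(haplotypes) == nrow(codes),
            length(frequencies) == length(haplotypes),
            all(frequencies >= 0),
            abs(sum(frequencies) - 1) < 1e-10,
            anyDuplicated(haplotypes) == 0)
  if (!is.na(reference))
    stopifnot(reference >= 1, reference <= length(haplotypes))
  structure(list(haplotypes = haplotypes, codes = codes,
                 frequencies = frequencies, reference = as.integer(reference),
                 marker_ids = marker_ids),
            class = "hap_table")
}

#' @export
print.hap_table <- function(x, ...) {
  cat(sprintf("hap_table: %d haplotypes over %d marker(s)\n",
              length(x$haplotypes), ncol(x$codes)))
  df <- data.frame(haplotype = x$haplotypes, frequency = round(x$frequencies, 6))
  if (!is.na(x$reference)) df$reference <- seq_along(x$haplotypes) == x$reference
  print(df, row.names = FALSE)
  invisible(x)
}

#' Enumerate the triad configurations compatible with observed genotypes
#'
#' A configuration assigns the maternal transmitted, maternal untransmitted
#' and paternal haplotypes. A configuration is compatible when, at every
#' observed marker: the mother's unordered pair equals
#' \{transmitted, untransmitted\}; the father's hemizygous allele equals the
#' paternal haplotype; a boy's allele equals the transmitted haplotype; a
#' girl's unordered pair equals \{transmitted, paternal\}. Missing markers
#' impose no constraint. An empty result indicates Mendelian inconsistency.
#'
#' @param triad a triad record as returned by [extract_triad()].
#' @param window the window (markers are taken from the triad's full-length
#'   genotype vectors at the window's positions).
#' @param haps the window's `hap_table`.
#' @param config_cap maximum number of configurations tolerated before the
#'   family is declared too ambiguous.
#' @return Integer matrix with columns `t`, `u`, `f`, one row per
#'   configuration (possibly zero rows).
#' @export
enumerate_configs <- function(triad, window, haps, config_cap = 65536L) {
  idx <- window$start_index + seq_len(window$length)
  cfg <- configs_for_pattern(
    m1 = triad$mother1[idx], m2 = triad$mother2[idx],
    fa = triad$father[idx],
    c1 = triad$child1[idx], c2 = triad$child2[idx],
    sex = if (identical(triad$child_sex, "male")) 1L else 2L,
    codes = haps$codes, config_cap = config_cap,
    family_id = triad$family_id %||% "<unnamed>")
  cfg
}

## Core configuration enumeration on window-local coded genotypes.
configs_for_pattern <- function(m1, m2, fa, c1, c2, sex, codes,
                                config_cap = 65536L, family_id = "<unnamed>") {
  H <- nrow(codes)
  fok <- rep(TRUE, H)
  for (l in which(!is.na(fa))) fok <- fok & codes[, l] == fa[l]
  M <- matrix(TRUE, H, H)
  for (l in which(!is.na(m1))) {
    a <- codes[, l]
    lo <- outer(a, a, pmin); hi <- outer(a, a, pmax)
    M <- M & lo == m1[l] & hi == m2[l]
  }
  if (sex == 1L) {
    tok <- rep(TRUE, H)
    for (l in which(!is.na(c1))) tok <- tok & codes[, l] == c1[l]
    G <- NULL
  } else {
    G <- matrix(TRUE, H, H)   # G[t, f]
    for (l in which(!is.na(c1))) {
      a <- codes[, l]
      lo <- outer(a, a, pmin); hi <- outer(a, a, pmax)
      G <- G & lo == c1[l] & hi == c2[l]
    }
  }
  pieces <- vector("list", H)
  total <- 0L
  for (t in seq_len(H)) {
    if (sex == 1L && !tok[t]) next
    us <- which(M[t, ])
    if (!length(us)) next
    fs <- if (sex == 1L) which(fok) else which(fok & G[t, ])
    if (!length(fs)) next
    total <- total + length(us) * length(fs)
    if (total > config_cap)
      stop_xtriad(sprintf("family %s too ambiguous: more than %d compatible configurations",
                          family_id, config_cap), "xtriad_config_cap")
    pieces[[t]] <- cbind(t = t, u = rep(us, times = length(fs)),
                         f = rep(fs, each = length(us)))
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) {
    out <- matrix(integer(), 0L, 3L)
    colnames(out) <- c("t", "u", "f")
    return(out)
  }
  do.call(rbind, pieces)
}

## Sex-specific boy risk vector implied by the model coupling.
male_risk <- function(r, model) {
  switch(model,
         xinactivation = r^2,
         no_xinactivation = r,
         males_only = r,
         females_only = stop("females_only model has no male stratum"))
}

## Vectorised configuration probabilities for mixed-sex rows.
cell_prob_core <- function(Ti, Ui, Fi, sexv, p, r, model) {
  base <- p[Ti] * p[Ui] * p[Fi]
  out <- numeric(length(Ti))
  b <- sexv == 1L
  if (any(b)) {
    rm <- male_risk(r, model)
    Cm <- sum(p * rm)
    if (Cm <= 0) stop("degenerate parameters: zero male normalizer")
    out[b] <- base[b] * rm[Ti[b]] / Cm
  }
  if (any(!b)) {
    S <- sum(p * r)
    if (S <= 0) stop("degenerate parameters: zero female normalizer")
    out[!b] <- base[!b] * r[Ti[!b]] * r[Fi[!b]] / S^2
  }
  out
}

#' Probability of one triad configuration under the case-ascertained model
#'
#' @param config list with haplotype indices `t`, `u`, `f` and `child_sex`
#'   (`"male"` or `"female"`).
#' @param haps the window `hap_table` supplying frequencies.
#' @param params numeric vector of single-dose relative risks (reference
#'   entry 1).
#' @param spec a [penetrance_spec()].
#' @return The configuration probability, conditional on an affected child
#'   of the given sex. Over all configurations of one sex these sum to 1.
#' @export
cell_probability <- function(config, haps, params, spec) {
  spec <- as_penetrance_spec(spec)
  r <- as.numeric(params)
  stopifnot(length(r) == length(haps$frequencies), all(is.finite(r)), all(r > 0))
  sexv <- if (identical(config$child_sex, "male")) 1L else 2L
  cell_prob_core(config$t, config$u, config$f, sexv,
                 haps$frequencies, r, spec$model)
}

## ---- family-list representation -------------------------------------------
##
## Fitting operates on a list of "families": each element is
##   list(sex = 1|2, configs = integer matrix (t,u,f), weight = count)
## where weight aggregates families sharing an identical genotype pattern.

flatten_families <- function(families) {
  nrows <- vapply(families, function(f) nrow(f$configs), 0L)
  if (any(nrows == 0L))
    stop("family with zero compatible configurations must be excluded upstream")
  K <- length(families)
  cfg <- do.call(rbind, lapply(families, `[[`, "configs"))
  fam_idx <- rep(seq_len(K), nrows)
  sex_f <- vapply(families, `[[`, 0L, "sex")
  w_f <- vapply(families, function(f) as.numeric(f$weight %||% 1), 0)
  list(Ti = cfg[, 1], Ui = cfg[, 2], Fi = cfg[, 3],
       sex_row = sex_f[fam_idx], fam_idx = fam_idx,
       sex_f = sex_f, w_f = w_f, K = K)
}

ll_flat <- function(fl, p, r, model) {
  pr <- cell_prob_core(fl$Ti, fl$Ui, fl$Fi, fl$sex_row, p, r, model)
  S <- wtab(fl$fam_idx, pr, fl$K)
  if (any(S <= 0)) return(-Inf)
  sum(fl$w_f * log(S))
}

#' Observed-data log-likelihood of a set of triads
#'
#' Sums, over families, the log of the total probability of that family's
#' compatible configurations under the case-ascertained model.
#'
#' @param families list of family entries, each
#'   `list(sex = 1 or 2, configs = matrix, weight = count)` as produced by
#'   the window-preparation step (see [fit_window()]); `weight` defaults
#'   to 1.
#' @param haps `hap_table` supplying frequencies.
#' @param params numeric vector of single-dose relative risks.
#' @param spec a [penetrance_spec()].
#' @return Scalar log-likelihood.
#' @export
loglik <- function(families, haps, params, spec) {
  spec <- as_penetrance_spec(spec)
  r <- as.numeric(params)
  stopifnot(length(r) == length(haps$frequencies))
  fl <- flatten_families(families)
  if (spec$model == "males_only" && any(fl$sex_f != 1L))
    stop("males_only model: female triads must be excluded first")
  if (spec$model == "females_only" && any(fl$sex_f != 2L))
    stop("females_only model: male triads must be excluded first")
  ll_flat(fl, haps$frequencies, r, spec$model)
}
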