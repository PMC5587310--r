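## Independent oracles, deliberately written as direct transliterations of
## the model definitions rather than reusing the package's fitting path.

## Brute-force observed-data log-likelihood: for every family, sum the
## case-ascertained cell probability over ALL H^3 phased configurations,
## testing compatibility directly against the raw genotype calls.
bf_loglik <- function(data, p, r, model) {
  window <- list(start_index = 0L, length = nrow(data$map))
  haps <- enumerate_haplotypes(window, data$map)
  codes <- haps$codes
  H <- length(p); L <- ncol(codes)
  rm <- switch(model, xinactivation = r^2, males_only = r, r)
  Cm <- sum(p * rm); Cf <- sum(p * r)^2
  ll <- 0
  for (i in seq_along(data$families)) {
    tr <- extract_triad(data, i)
    s <- 0
    for (t in seq_len(H)) for (u in seq_len(H)) for (fh in seq_len(H)) {
      ok <- TRUE
      for (l in seq_len(L)) {
        if (!is.na(tr$mother1[l])) {
          pr <- sort(c(codes[t, l], codes[u, l]))
          if (pr[1] != tr$mother1[l] || pr[2] != tr$mother2[l]) { ok <- FALSE; break }
        }
        if (!is.na(tr$father[l]) && codes[fh, l] != tr$father[l]) { ok <- FALSE; break }
        if (tr$child_sex == "male") {
          if (!is.na(tr$child1[l]) && codes[t, l] != tr$child1[l]) { ok <- FALSE; break }
        } else if (!is.na(tr$child1[l])) {
          pc <- sort(c(codes[t, l], codes[fh, l]))
          if (pc[1] != tr$child1[l] || pc[2] != tr$child2[l]) { ok <- FALSE; break }
        }
      }
      if (ok) {
        base <- p[t] * p[u] * p[fh]
        s <- s + if (tr$child_sex == "male") base * rm[t] / Cm
                 else base * r[t] * r[fh] / Cf
      }
    }
    if (s <= 0) stop("oracle: family with no compatible configuration")
    ll <- ll + log(s)
  }
  ll
}

## Hand-computed Benjamini-Hochberg step-up values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
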