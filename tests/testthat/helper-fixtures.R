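## Small programmatic fixtures shared across the test files.

snp_map <- function(L = 1L) {
  data.frame(marker_id = paste0("snp", seq_len(L)),
             chromosome = "X",
             position_bp = 1000L * seq_len(L),
             allele1 = "A", allele2 = "C",
             stringsAsFactors = FALSE)
}

## Single-SNP dataset of n het mothers (A/C); `trans` is the transmitted
## allele code per family, `fa` the father's allele code, `sex` 1/2.
het_mother_data <- function(trans, fa, sex) {
  n <- length(trans)
  stopifnot(length(fa) == n, length(sex) == n)
  m1 <- matrix(1L, n, 1); m2 <- matrix(2L, n, 1)
  child1 <- matrix(NA_integer_, n, 1); child2 <- matrix(NA_integer_, n, 1)
  boys <- sex == 1L
  child1[boys, 1] <- trans[boys]
  child1[!boys, 1] <- pmin(trans[!boys], fa[!boys])
  child2[!boys, 1] <- pmax(trans[!boys], fa[!boys])
  triad_dataset(snp_map(1L), sprintf("f%04d", seq_len(n)), sex,
                m1, m2, matrix(fa, n, 1), child1, child2)
}

## Balanced complete-data transmission fixture: T variant transmissions and
## U non-variant from het mothers, with father allele counts chosen so the
## joint MLE of the retrospective likelihood equals T/U (fathers mirror the
## transmitted counts for boys, the untransmitted counts for girls).
transmission_fixture <- function(T_var, U_ref, sex = 1L) {
  trans <- c(rep(2L, T_var), rep(1L, U_ref))
  fa <- if (sex == 1L) c(rep(2L, T_var), rep(1L, U_ref))
        else c(rep(2L, U_ref), rep(1L, T_var))
  het_mother_data(trans, fa, rep(sex, T_var + U_ref))
}

## Build the family list consumed by loglik()/fit_null() from a dataset.
families_for <- function(data, window = NULL) {
  if (is.null(window))
    window <- list(start_index = 0L, length = nrow(data$map))
  haps <- enumerate_haplotypes(window, data$map)
  fams <- list()
  for (i in seq_along(data$families)) {
    cfg <- enumerate_configs(extract_triad(data, i), window, haps)
    if (nrow(cfg))
      fams[[length(fams) + 1L]] <- list(sex = data$sex[i], configs = cfg,
                                        weight = 1)
  }
  list(haps = haps, families = fams)
}

write_fixture_ped <- function(lines, map_lines) {
  dir <- tempfile("fixture")
  dir.create(dir)
  ped <- file.path(dir, "fix.ped"); map <- file.path(dir, "fix.map")
  writeLines(lines, ped); writeLines(map_lines, map)
  list(ped = ped, map = map)
}
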