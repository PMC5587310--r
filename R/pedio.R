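## PLINK-style ped/map input, triad assembly, QC filters and result output.
##
## Genotypes are stored internally as integer codes 1/2 indexing the two
## allele labels of each marker in the map; NA is missing. Mothers and girls
## carry an unordered pair per marker (stored sorted, code1 <= code2), fathers
## and boys a single hemizygous allele.

#' Construct a triad dataset
#'
#' Low-level constructor for the container holding a marker map and the
#' genotypes of a set of case-parent triads. Used by [read_ped_map()] and
#' [simulate_triads()]; also handy for building small datasets in code.
#'
#' @param map data.frame with columns `marker_id`, `chromosome`,
#'   `position_bp`, `allele1`, `allele2` (single-character labels; `allele2`
#'   may be `NA` for a marker observed monomorphic).
#' @param families character vector of unique family identifiers.
#' @param sex integer vector, 1 = male child, 2 = female child.
#' @param mother1,mother2 integer matrices (families x markers) with the
#'   mother's unordered allele pair coded 1/2; rows are sorted so that
#'   `mother1 <= mother2`; both `NA` when the call is missing.
#' @param father integer matrix with the father's hemizygous allele code.
#' @param child1,child2 integer matrices with the child's genotype; for boys
#'   `child2` is `NA` throughout and `child1` holds the single allele.
#' @param provenance character vector of free-text processing notes.
#' @return An object of class `triad_data`.
#' @export
triad_dataset <- function(map, families, sex, mother1, mother2, father,
                          child1, child2, provenance = character()) {
  map <- validate_marker_map(map)
  n <- length(families); L <- nrow(map)
  if (anyDuplicated(families)) stop("family identifiers must be unique")
  if (length(sex) != n) stop("sex vector length must match number of families")
  if (!all(sex %in% c(1L, 2L))) stop("sex codes must be 1 (male) or 2 (female)")
  for (nm in c("mother1", "mother2", "father", "child1", "child2")) {
    m <- get(nm)
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != L)
      stop(sprintf("'%s' must be a %d x %d matrix", nm, n, L))
    if (!all(m %in% c(1L, 2L, NA)))
      stop(sprintf("'%s' must contain codes 1, 2 or NA", nm))
  }
  ## enforce unordered storage and paired missingness
  swap <- !is.na(mother1) & !is.na(mother2) & mother1 > mother2
  if (any(swap)) { tmp <- mother1[swap]; mother1[swap] <- mother2[swap]; mother2[swap] <- tmp }
  miss <- is.na(mother1) | is.na(mother2)
  mother1[miss] <- NA_integer_; mother2[miss] <- NA_integer_
  boys <- sex == 1L
  if (any(!is.na(child2[boys, , drop = FALSE])))
    stop("boys must carry a single hemizygous allele (child2 must be NA)")
  g <- !boys
  swap <- matrix(FALSE, n, L)
  swap[g, ] <- !is.na(child1[g, , drop = FALSE]) & !is.na(child2[g, , drop = FALSE]) &
    child1[g, , drop = FALSE] > child2[g, , drop = FALSE]
  if (any(swap)) { tmp <- child1[swap]; child1[swap] <- child2[swap]; child2[swap] <- tmp }
  gm <- matrix(FALSE, n, L)
  gm[g, ] <- is.na(child1[g, , drop = FALSE]) | is.na(child2[g, , drop = FALSE])
  child1[gm] <- NA_integer_; child2[gm] <- NA_integer_
  structure(list(map = map, families = as.character(families),
                 sex = as.integer(sex),
                 mother1 = mother1, mother2 = mother2, father = father,
                 child1 = child1, child2 = child2,
                 provenance = provenance),
            class = "triad_data")
}

validate_marker_map <- function(map) {
  need <- c("marker_id", "chromosome", "position_bp", "allele1", "allele2")
  if (!all(need %in% names(map)))
    stop("map must have columns ", paste(need, collapse = ", "))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (anyDuplicated(map$marker_id)) stop("marker ids must be unique")
  if (any(map$position_bp <= 0)) stop("marker positions must be positive")
  if (is.unsorted(map$position_bp, strictly = TRUE))
    stop("marker positions must be strictly increasing")
  same <- !is.na(map$allele2) & map$allele1 == map$allele2
  if (any(same)) stop("the two allele labels of a marker must be distinct")
  rownames(map) <- NULL
  map
}

#' Number of triads and markers
#' @param x a `triad_data` object
#' @param ... ignored
#' @export
print.triad_data <- function(x, ...) {
  cat(sprintf("triad_data: %d case-parent triads, %d X-linked markers\n",
              length(x$families), nrow(x$map)))
  cat(sprintf("  child sex: %d boys, %d girls\n",
              sum(x$sex == 1L), sum(x$sex == 2L)))
  if (length(x$provenance))
    cat("  provenance:\n", paste0("   - ", x$provenance, "\n"), sep = "")
  invisible(x)
}

#' Read PLINK-style ped/map files and assemble case-parent triads
#'
#' Parses a whitespace-delimited pedigree file (six leading columns: family,
#' individual, father, mother, sex, phenotype; then two allele columns per
#' marker) together with its marker map, and assembles one triad per family
#' from any individual whose paternal and maternal identifiers both resolve
#' within the family. Individuals not forming a complete trio are dropped
#' with a logged count; extra children beyond the first are logged and
#' skipped. Male X genotypes given as a homozygous pair are collapsed to a
#' single allele; a male carrying two distinct alleles at a marker has that
#' genotype set to missing, with a counted warning.
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file (chromosome, id, genetic distance
#'   (optional, ignored), physical position in bp). Chromosome labels "X" and
#'   "23" are accepted as equivalent.
#' @param missing_code allele symbol denoting a missing call (default "0").
#' @return A [triad_dataset()] object.
#' @export
read_ped_map <- function(ped_path, map_path, missing_code = "0") {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character",
                               stringsAsFactors = FALSE)
  if (nrow(map_raw) < 1L) stop("map file has no markers")
  if (!ncol(map_raw) %in% c(3L, 4L))
    stop("map file must have 3 or 4 columns (chromosome, id[, cM], bp)")
  pos_col <- ncol(map_raw)
  chrom <- ifelse(map_raw[[1]] == "23", "X", map_raw[[1]])
  map <- data.frame(marker_id = map_raw[[2]],
                    chromosome = chrom,
                    position_bp = as.integer(map_raw[[pos_col]]),
                    allele1 = NA_character_, allele2 = NA_character_,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$marker_id)) stop("duplicate marker ids in map file")
  if (any(is.na(map$position_bp)) || any(map$position_bp <= 0))
    stop("map positions must be positive integers")
  prov <- character()
  if (is.unsorted(map$position_bp)) {
    ord <- order(map$position_bp)
    map <- map[ord, ]
    prov <- c(prov, "map sorted by physical position")
  } else ord <- seq_len(nrow(map))
  if (anyDuplicated(map$position_bp)) stop("duplicate marker positions in map file")
  L <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("ped file is empty")
  toks <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * L
  nf <- lengths(toks)
  if (any(nf != expected))
    stop(sprintf("ped parse error: line %d has %d fields, expected %d",
                 which(nf != expected)[1], nf[nf != expected][1], expected))
  ped <- do.call(rbind, toks)
  fid <- ped[, 1]; iid <- ped[, 2]; pat <- ped[, 3]; mat <- ped[, 4]
  sexcode <- ped[, 5]
  al <- ped[, -(1:6), drop = FALSE]
  a1 <- al[, 2 * ord - 1, drop = FALSE]   # reorder to sorted map
  a2 <- al[, 2 * ord, drop = FALSE]
  a1[a1 == missing_code] <- NA; a2[a2 == missing_code] <- NA
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA; a2[miss] <- NA

  ## derive the two allele labels per marker from the observed symbols
  g1 <- matrix(NA_integer_, nrow(ped), L)
  g2 <- matrix(NA_integer_, nrow(ped), L)
  for (j in seq_len(L)) {
    obs <- sort(unique(c(a1[, j], a2[, j])))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2L)
      stop(sprintf("marker %s has %d observed alleles; biallelic SNPs required",
                   map$marker_id[j], length(obs)))
    map$allele1[j] <- if (length(obs) >= 1L) obs[1] else NA_character_
    map$allele2[j] <- if (length(obs) == 2L) obs[2] else NA_character_
    if (length(obs)) {
      g1[, j] <- match(a1[, j], obs)
      g2[, j] <- match(a2[, j], obs)
    }
  }

  ## triad assembly: a child is any individual whose parental pointers both
  ## resolve to individuals of the same family
  key <- paste(fid, iid, sep = "\r")
  n_ind <- nrow(ped)
  used <- rep(FALSE, n_ind)
  fam_ids <- character(); sex <- integer()
  m_rows <- integer(); f_rows <- integer(); c_rows <- integer()
  n_extra_children <- 0L
  for (f in unique(fid)) {
    in_fam <- which(fid == f)
    kids <- in_fam[pat[in_fam] != "0" & mat[in_fam] != "0" &
                   paste(f, pat[in_fam], sep = "\r") %in% key &
                   paste(f, mat[in_fam], sep = "\r") %in% key]
    if (!length(kids)) next
    if (length(kids) > 1L) n_extra_children <- n_extra_children + length(kids) - 1L
    k <- kids[1]
    if (!sexcode[k] %in% c("1", "2"))
      stop(sprintf("impossible sex code '%s' for child %s in family %s",
                   sexcode[k], iid[k], f))
    frow <- in_fam[iid[in_fam] == pat[k]][1]
    mrow <- in_fam[iid[in_fam] == mat[k]][1]
    fam_ids <- c(fam_ids, f); sex <- c(sex, as.integer(sexcode[k]))
    m_rows <- c(m_rows, mrow); f_rows <- c(f_rows, frow); c_rows <- c(c_rows, k)
    used[c(k, frow, mrow)] <- TRUE
  }
  if (!length(fam_ids)) stop_xtriad("no complete case-parent trio found", "xtriad_no_data")
  n_dropped <- sum(!used)

  n <- length(fam_ids)
  collapse_male <- function(rows) {
    ## hemizygous: collapse homozygous pair to one allele; distinct alleles
    ## are impossible on X and set to missing with a counted warning
    x1 <- g1[rows, , drop = FALSE]; x2 <- g2[rows, , drop = FALSE]
    het <- !is.na(x1) & !is.na(x2) & x1 != x2
    x1[het] <- NA_integer_
    list(g = x1, n_het = sum(het))
  }
  fa <- collapse_male(f_rows)
  mother1 <- g1[m_rows, , drop = FALSE]; mother2 <- g2[m_rows, , drop = FALSE]
  child1 <- matrix(NA_integer_, n, L); child2 <- matrix(NA_integer_, n, L)
  boys <- sex == 1L
  if (any(boys)) {
    cb <- collapse_male(c_rows[boys])
    child1[boys, ] <- cb$g
  } else cb <- list(n_het = 0L)
  if (any(!boys)) {
    child1[!boys, ] <- g1[c_rows[!boys], , drop = FALSE]
    child2[!boys, ] <- g2[c_rows[!boys], , drop = FALSE]
  }
  n_male_het <- fa$n_het + cb$n_het
  if (n_male_het > 0L)
    warning(sprintf("%d male genotype(s) with two distinct alleles set to missing",
                    n_male_het))
  prov <- c(prov,
            sprintf("read %d individuals; assembled %d triads; dropped %d individuals outside complete trios",
                    n_ind, n, n_dropped),
            if (n_extra_children > 0L)
              sprintf("skipped %d additional child(ren) beyond the first per family", n_extra_children),
            if (n_male_het > 0L)
              sprintf("set %d heterozygous male genotype call(s) to missing", n_male_het))
  out <- triad_dataset(map, fam_ids, sex, mother1, mother2, fa$g,
                       child1, child2, provenance = prov)
  attr(out, "n_male_het_warnings") <- n_male_het
  attr(out, "n_individuals_dropped") <- n_dropped
  out
}

#' Write a triad dataset as PLINK-style ped/map files
#'
#' Inverse of [read_ped_map()]: fathers and boys are written as homozygous
#' allele pairs, missing calls as the missing code.
#'
#' @param data a `triad_data` object.
#' @param ped_path,map_path output file paths.
#' @param missing_code symbol used for missing alleles.
#' @return Invisibly, `data`.
#' @export
write_ped_map <- function(data, ped_path, map_path, missing_code = "0") {
  map <- data$map
  utils::write.table(data.frame(map$chromosome, map$marker_id, 0L, map$position_bp),
                     map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n <- length(data$families); L <- nrow(map)
  sym <- function(code, j) {
    lab <- c(map$allele1[j], map$allele2[j])
    out <- lab[code]
    out[is.na(out)] <- missing_code
    out
  }
  rows <- character(3L * n)
  for (i in seq_len(n)) {
    f <- data$families[i]
    gm <- gf <- gc <- character(2L * L)
    for (j in seq_len(L)) {
      gm[2 * j - 1] <- sym(data$mother1[i, j], j); gm[2 * j] <- sym(data$mother2[i, j], j)
      gf[2 * j - 1] <- gf[2 * j] <- sym(data$father[i, j], j)
      if (data$sex[i] == 1L) {
        gc[2 * j - 1] <- gc[2 * j] <- sym(data$child1[i, j], j)
      } else {
        gc[2 * j - 1] <- sym(data$child1[i, j], j); gc[2 * j] <- sym(data$child2[i, j], j)
      }
    }
    rows[3 * i - 2] <- paste(c(f, "father", "0", "0", "1", "0", gf), collapse = " ")
    rows[3 * i - 1] <- paste(c(f, "mother", "0", "0", "2", "0", gm), collapse = " ")
    rows[3 * i]     <- paste(c(f, "child", "father", "mother", data$sex[i], "2", gc),
                             collapse = " ")
  }
  writeLines(rows, ped_path)
  invisible(data)
}

#' Quality-control filtering of a triad dataset
#'
#' Applies, in order: removal of individuals (and hence their whole triad)
#' with more than `ind_missing_max` missing genotype calls; removal of SNPs
#' with more than `snp_missing_max` missing calls across the retained
#' individuals; removal of SNPs with minor allele frequency below `maf_min`.
#' The MAF is computed over all retained X alleles, counting mothers and
#' girls twice and fathers and boys once.
#'
#' @param data a `triad_data` object.
#' @param ind_missing_max maximum tolerated per-individual missing fraction.
#' @param snp_missing_max maximum tolerated per-SNP missing fraction.
#' @param maf_min minimum minor allele frequency.
#' @return A list with elements `data` (the filtered `triad_data`) and
#'   `report` (a `qc_report` with the per-filter counts).
#' @export
qc_filter <- function(data, ind_missing_max = 0.10, snp_missing_max = 0.01,
                      maf_min = 0.01) {
  stopifnot(ind_missing_max >= 0, ind_missing_max <= 1,
            snp_missing_max >= 0, snp_missing_max <= 1,
            maf_min >= 0, maf_min <= 1)
  L <- nrow(data$map)
  ## 1. individual missingness (per-marker call missing fraction)
  miss_m <- rowMeans(is.na(data$mother1))
  miss_f <- rowMeans(is.na(data$father))
  miss_c <- rowMeans(is.na(data$child1))
  over <- cbind(miss_m, miss_f, miss_c) > ind_missing_max
  n_ind_removed <- sum(over)
  keep_fam <- rowSums(over) == 0L
  d <- subset_triads(data, keep_fam)
  if (!length(d$families))
    stop_xtriad("no data left after individual-missingness filter", "xtriad_no_data")

  ## 2. SNP missingness across all retained individuals
  n_fam <- length(d$families)
  snp_miss <- (colSums(is.na(d$mother1)) + colSums(is.na(d$father)) +
               colSums(is.na(d$child1))) / (3 * n_fam)
  keep_snp1 <- snp_miss <= snp_missing_max
  n_snp_miss <- sum(!keep_snp1)
  d <- subset_markers(d, keep_snp1)
  if (!nrow(d$map))
    stop_xtriad("no markers left after SNP-missingness filter", "xtriad_no_data")

  ## 3. minor allele frequency
  maf <- dataset_maf(d)
  keep_snp2 <- maf >= maf_min
  n_snp_maf <- sum(!keep_snp2)
  d <- subset_markers(d, keep_snp2)
  if (!nrow(d$map))
    stop_xtriad("no markers left after MAF filter", "xtriad_no_data")

  d$provenance <- c(d$provenance,
                    sprintf("qc_filter: removed %d individual(s) (> %.3g missing) dropping %d triad(s); %d SNP(s) for missingness > %.3g; %d SNP(s) for MAF < %.3g",
                            n_ind_removed, ind_missing_max, sum(!keep_fam),
                            n_snp_miss, snp_missing_max, n_snp_maf, maf_min))
  report <- structure(list(n_individuals_removed = n_ind_removed,
                           n_triads_removed = sum(!keep_fam),
                           n_snps_removed_missingness = n_snp_miss,
                           n_snps_removed_maf = n_snp_maf,
                           n_triads_retained = length(d$families),
                           n_snps_retained = nrow(d$map),
                           thresholds = list(ind_missing_max = ind_missing_max,
                                             snp_missing_max = snp_missing_max,
                                             maf_min = maf_min)),
                      class = "qc_report")
  list(data = d, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  cat(sprintf("  individuals over missingness threshold: %d (removing %d triads)\n",
              x$n_individuals_removed, x$n_triads_removed))
  cat(sprintf("  SNPs removed for missingness: %d\n", x$n_snps_removed_missingness))
  cat(sprintf("  SNPs removed for MAF: %d\n", x$n_snps_removed_maf))
  cat(sprintf("  retained: %d triads, %d SNPs\n",
              x$n_triads_retained, x$n_snps_retained))
  invisible(x)
}

#' Minor allele frequencies of a triad dataset
#'
#' Allele counting weights each X chromosome once: mothers and girls
#' contribute two alleles per marker, fathers and boys one.
#'
#' @param data a `triad_data` object.
#' @return Numeric vector of per-marker minor allele frequencies.
#' @export
dataset_maf <- function(data) {
  boys <- data$sex == 1L
  cnt2 <- colSums(data$mother1 == 2L, na.rm = TRUE) +
    colSums(data$mother2 == 2L, na.rm = TRUE) +
    colSums(data$father == 2L, na.rm = TRUE) +
    colSums(data$child1[boys, , drop = FALSE] == 2L, na.rm = TRUE) +
    colSums(data$child1[!boys, , drop = FALSE] == 2L, na.rm = TRUE) +
    colSums(data$child2[!boys, , drop = FALSE] == 2L, na.rm = TRUE)
  tot <- colSums(!is.na(data$mother1)) * 2L +
    colSums(!is.na(data$father)) +
    colSums(!is.na(data$child1[boys, , drop = FALSE])) +
    colSums(!is.na(data$child1[!boys, , drop = FALSE])) * 2L
  freq2 <- ifelse(tot > 0, cnt2 / tot, 0)
  pmin(freq2, 1 - freq2)
}

subset_triads <- function(data, keep) {
  data$families <- data$families[keep]
  data$sex <- data$sex[keep]
  for (nm in c("mother1", "mother2", "father", "child1", "child2"))
    data[[nm]] <- data[[nm]][keep, , drop = FALSE]
  data
}

subset_markers <- function(data, keep) {
  data$map <- data$map[keep, , drop = FALSE]
  rownames(data$map) <- NULL
  for (nm in c("mother1", "mother2", "father", "child1", "child2"))
    data[[nm]] <- data[[nm]][, keep, drop = FALSE]
  data
}

#' Extract one triad record
#'
#' @param data a `triad_data` object.
#' @param i triad index or family id.
#' @return A list with the family id, child sex (`"male"`/`"female"`) and the
#'   coded genotype vectors of mother, father and child.
#' @export
extract_triad <- function(data, i) {
  if (is.character(i)) i <- match(i, data$families)
  stopifnot(!is.na(i), i >= 1, i <= length(data$families))
  list(family_id = data$families[i],
       child_sex = if (data$sex[i] == 1L) "male" else "female",
       mother1 = data$mother1[i, ], mother2 = data$mother2[i, ],
       father = data$father[i, ],
       child1 = data$child1[i, ], child2 = data$child2[i, ])
}
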