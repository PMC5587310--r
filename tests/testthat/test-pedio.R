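test_that("ped/map parsing assembles triads, maps missing codes and collapses male genotypes", {
  map_lines <- c("X snp1 0 1000", "23 snp2 0 2000")
  ped <- c("fam1 dad 0 0 1 1  G G  A A",
           "fam1 mom 0 0 2 1  A G  A C",
           "fam1 kid dad mom 2 2  A G  A A")
  fx <- write_fixture_ped(ped, map_lines)
  d <- read_ped_map(fx$ped, fx$map)
  expect_s3_class(d, "triad_data")
  expect_length(d$families, 1)
  expect_equal(nrow(d$map), 2)
  expect_equal(d$map$chromosome, c("X", "X"))
  expect_equal(d$sex, 2L)
  ## marker 1 alleles sorted A < G; girl child A/G
  expect_equal(d$map$allele1, c("A", "A"))
  expect_equal(d$map$allele2, c("G", "C"))
  expect_equal(unname(d$child1[1, ]), c(1L, 1L))
  expect_equal(unname(d$child2[1, ]), c(2L, 1L))
  expect_equal(unname(d$father[1, ]), c(2L, 1L))

  ## missing code 0 0 for the father at marker 1: triad retained, call NA
  ped2 <- ped
  ped2[1] <- "fam1 dad 0 0 1 1  0 0  A A"
  fx2 <- write_fixture_ped(ped2, map_lines)
  d2 <- read_ped_map(fx2$ped, fx2$map)
  expect_length(d2$families, 1)
  expect_true(is.na(d2$father[1, 1]))
  expect_false(is.na(d2$father[1, 2]))

  ## a male child with two distinct alleles is impossible on X: set missing
  ped3 <- c("fam1 dad 0 0 1 1  G G  A A",
            "fam1 mom 0 0 2 1  A G  A C",
            "fam1 kid dad mom 1 2  A G  A A")
  fx3 <- write_fixture_ped(ped3, map_lines)
  expect_warning(d3 <- read_ped_map(fx3$ped, fx3$map), "distinct alleles")
  expect_true(is.na(d3$child1[1, 1]))
  expect_equal(attr(d3, "n_male_het_warnings"), 1L)

  ## malformed column counts and impossible sex codes are hard errors
  fx4 <- write_fixture_ped(c(ped, "fam2 solo 0 0 1 1  A A"), map_lines)
  expect_error(read_ped_map(fx4$ped, fx4$map), "line 4")
  ped5 <- ped
  ped5[3] <- "fam1 kid dad mom 3 2  A G  A A"
  fx5 <- write_fixture_ped(ped5, map_lines)
  expect_error(read_ped_map(fx5$ped, fx5$map), "sex code")
})

test_that("incomplete trios are dropped and extra children logged", {
  map_lines <- "X snp1 0 1000"
  ped <- c("fam1 dad 0 0 1 1  A A",
           "fam1 mom 0 0 2 1  A C",
           "fam1 kid dad mom 2 2  A C",
           "fam1 kid2 dad mom 1 2  C C",
           "fam2 orphan 0 0 1 1  A A")
  fx <- write_fixture_ped(ped, map_lines)
  d <- read_ped_map(fx$ped, fx$map)
  expect_equal(d$families, "fam1")
  expect_equal(attr(d, "n_individuals_dropped"), 2L)  # kid2 + orphan
  expect_match(paste(d$provenance, collapse = " "), "additional child")
})

test_that("qc_filter applies the individual, SNP-missingness and MAF rules in order", {
  set.seed(401)
  d <- simulate_snp_panel(mafs = c(0.3, 0.3, 0.005), n_triads = 400, seed = 401)
  res <- qc_filter(d)
  expect_equal(res$report$n_snps_removed_maf, 1)
  expect_equal(res$report$n_snps_removed_missingness, 0)
  expect_equal(res$data$map$marker_id, c("snp1", "snp2"))

  ## an individual missing 15% of calls removes its whole triad
  d2 <- simulate_snp_panel(mafs = rep(0.3, 20), n_triads = 50, seed = 402)
  d2$mother1[1, 1:3] <- NA_integer_; d2$mother2[1, 1:3] <- NA_integer_
  res2 <- qc_filter(d2, snp_missing_max = 0.2)
  expect_equal(res2$report$n_individuals_removed, 1)
  expect_equal(res2$report$n_triads_retained, 49)
  expect_false("fam00001" %in% res2$data$families)

  ## fully observed dataset with common alleles passes untouched
  d3 <- simulate_snp_panel(mafs = rep(0.3, 5), n_triads = 100, seed = 403)
  res3 <- qc_filter(d3)
  expect_equal(res3$report$n_individuals_removed, 0)
  expect_equal(res3$report$n_snps_removed_missingness, 0)
  expect_equal(res3$report$n_snps_removed_maf, 0)
  expect_equal(res3$data$mother1, d3$mother1)

  ## idempotence: a second pass changes nothing
  res3b <- qc_filter(res3$data)
  expect_equal(res3b$data[c("map", "families", "mother1", "father", "child1")],
               res3$data[c("map", "families", "mother1", "father", "child1")])
})

test_that("allele counting recovers the simulation frequency (mothers/girls twice, fathers/boys once)", {
  d <- simulate_snp_panel(mafs = 0.3, n_triads = 5000, seed = 404)
  ## the case-ascertained null does not distort allele frequencies
  expect_lt(abs(dataset_maf(d) - 0.3), 0.02)
})

test_that("ped/map round-trip preserves genotype content", {
  d <- simulate_triads(sim_spec(c(0.5, 0.2, 0.2, 0.1), c(1, 1.4, 0.8, 1),
                                n_triads = 60, missing_rate = 0.1, seed = 405))
  dir <- tempfile("rt"); dir.create(dir)
  ped <- file.path(dir, "d.ped"); map <- file.path(dir, "d.map")
  write_ped_map(d, ped, map)
  d2 <- read_ped_map(ped, map)
  expect_equal(d2$map$marker_id, d$map$marker_id)
  expect_equal(d2$map$position_bp, d$map$position_bp)
  expect_equal(d2$sex, d$sex)
  for (nm in c("mother1", "mother2", "father", "child1", "child2"))
    expect_equal(unname(d2[[nm]]), unname(d[[nm]]), label = nm)
  ## writing the re-read dataset reproduces the same files (idempotence)
  ped2 <- file.path(dir, "d2.ped")
  write_ped_map(d2, ped2, file.path(dir, "d2.map"))
  expect_identical(readLines(ped2), readLines(ped))
})

test_that("scan results serialize to TSV and round-trip through JSON", {
  d <- simulate_snp_panel(mafs = c(0.3, 0.25), n_triads = 150, seed = 406)
  tab <- run_scan(d, window_length = 1)
  dir <- tempfile("out"); dir.create(dir)
  tsv <- file.path(dir, "res.tsv")
  write_results(tab, tsv, "tsv")
  lines <- readLines(tsv)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(tab) + 1L)  # header + one row per window
  back <- read_results(tsv, "tsv")
  expect_equal(back$p_value, tab$p_value, tolerance = 1e-9)

  js <- file.path(dir, "res.json")
  write_results(tab, js, "json")
  rt <- read_results(js, "json")
  expect_length(rt$windows, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    expect_equal(rt$windows[[i]]$p_value, tab$p_value[i], tolerance = 1e-12)
    expect_equal(rt$windows[[i]]$loglik_full, tab$loglik_full[i], tolerance = 1e-12)
    expect_equal(rt$windows[[i]]$rr_single_dose,
                 as.numeric(strsplit(tab$rr_single_dose[i], ";")[[1]]),
                 tolerance = 1e-12)
  }
})

test_that("a pruned haplotype is recorded in its window's output row", {
  d <- simulate_triads(sim_spec(c(0.55, 0.30, 0.146, 0.004), c(1, 1, 1, 1),
                                n_triads = 500, seed = 407))
  tab <- run_scan(d, window_length = 2)
  expect_equal(nrow(tab), 1)
  expect_match(tab$pruned, ".")  # non-empty label
  expect_equal(tab$n_haplotypes, 3)
})
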