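## Sliding-window scan across the marker map, with FDR control by
## Benjamini-Hochberg q-values, and TSV/JSON result output.

#' Sliding windows over a marker map
#'
#' Overlapping windows of a fixed length (1 to 4 consecutive SNPs), stepping
#' one marker at a time.
#'
#' @param n_markers number of markers.
#' @param length window length, 1 to 4.
#' @return List of windows, each `list(start_index, length)` with 0-based
#'   inclusive `start_index`.
#' @export
make_windows <- function(n_markers, length = 1L) {
  length <- as.integer(length)
  if (length < 1L || length > 4L) stop("window length must be between 1 and 4")
  if (length > n_markers) stop("window length exceeds number of markers")
  lapply(0:(n_markers - length), function(s)
    list(start_index = s, length = length))
}

#' Benjamini-Hochberg q-values
#'
#' The step-up adjusted p-values `q_(i) = min_(j >= i) p_(j) * m / j`
#' (sorted ascending, mapped back to input order), used to declare
#' significance at a chosen FDR level (the scans here use q <= 0.1).
#' Missing p-values (failed windows) are excluded from `m` and returned as
#' `NA`.
#'
#' @param p vector of p-values in \[0, 1\], `NA` allowed.
#' @return Vector of q-values of the same length.
#' @export
compute_qvalues <- function(p) {
  if (!length(p)) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Chromosome-wide sliding-window scan
#'
#' For each window: enumerate haplotypes and compatible configurations,
#' drop Mendelian-inconsistent families (counted per window), fit the null
#' EM, prune rare haplotypes, fit the full penetrance model, and record
#' relative risks, the window LRT p-value and metadata. Windows that turn
#' out uninformative (fewer than two common haplotypes, or no compatible
#' family) are recorded with missing p-values and excluded from the FDR
#' denominator. q-values are computed across all successful windows of the
#' scan. The scan is deterministic given its input.
#'
#' @param data a QC'd `triad_data` object.
#' @param window_length number of consecutive SNPs per window (1-4).
#' @param spec a [penetrance_spec()] or model name.
#' @param min_freq rare-haplotype pruning threshold.
#' @param config_cap per-family configuration cap.
#' @return A `scan_table`: data.frame with one row per window (semicolon-
#'   joined per-haplotype fields) and the per-window `window_fit` objects in
#'   `attr(, "fits")`.
#' @export
run_scan <- function(data, window_length = 1L, spec = penetrance_spec(),
                     min_freq = 0.01, config_cap = 65536L) {
  spec <- as_penetrance_spec(spec)
  windows <- make_windows(nrow(data$map), window_length)
  n <- length(windows)
  fits <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    w <- windows[[i]]
    fit <- tryCatch(fit_window(data, w, spec, min_freq, config_cap),
                    xtriad_error = function(e) e)
    fits[[i]] <- fit
    rows[[i]] <- scan_row(w, fit, data$map, spec)
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$p_value)))
    stop_xtriad("no window could be fitted", "xtriad_no_data")
  tab$q_value <- compute_qvalues(tab$p_value)
  attr(tab, "fits") <- fits
  attr(tab, "meta") <- list(model = spec$model, window_length = window_length,
                            min_freq = min_freq, n_markers = nrow(data$map),
                            n_triads = length(data$families))
  class(tab) <- c("scan_table", "data.frame")
  tab
}

scan_row <- function(w, fit, map, spec) {
  idx <- w$start_index + seq_len(w$length)
  base <- data.frame(
    window = w$start_index + 1L,
    start_index = w$start_index,
    window_length = w$length,
    marker_ids = paste(map$marker_id[idx], collapse = ";"),
    positions_bp = paste(map$position_bp[idx], collapse = ";"),
    model = spec$model,
    stringsAsFactors = FALSE)
  if (inherits(fit, "window_fit")) {
    ht <- fit$haplotype_table
    cbind(base, data.frame(
      status = "ok",
      n_families = fit$n_families_used,
      n_mendelian_excluded = fit$n_mendelian_excluded %||% 0,
      n_haplotypes = length(ht$haplotypes),
      haplotypes = paste(ht$haplotypes, collapse = ";"),
      reference = ht$haplotypes[ht$reference],
      frequencies = paste(signif(ht$frequencies, 7), collapse = ";"),
      rr_single_dose = paste(signif(fit$rr_single_dose, 7), collapse = ";"),
      rr_ci_lower = paste(signif(fit$rr_ci[, 1], 7), collapse = ";"),
      rr_ci_upper = paste(signif(fit$rr_ci[, 2], 7), collapse = ";"),
      rr_double_dose = paste(signif(fit$rr_double_dose, 7), collapse = ";"),
      rr_boys = paste(signif(fit$rr_boys, 7), collapse = ";"),
      pruned = paste(fit$pruned_haplotypes, collapse = ";"),
      loglik_null = fit$loglik_null,
      loglik_full = fit$loglik_full,
      lrt = fit$lrt_statistic,
      df = fit$df,
      p_value = fit$p_value,
      converged = fit$converged,
      stringsAsFactors = FALSE))
  } else {
    cbind(base, data.frame(
      status = if (inherits(fit, "xtriad_uninformative")) "uninformative" else "failed",
      n_families = NA_real_, n_mendelian_excluded = NA_real_,
      n_haplotypes = NA_integer_, haplotypes = "", reference = "",
      frequencies = "", rr_single_dose = "", rr_ci_lower = "",
      rr_ci_upper = "", rr_double_dose = "", rr_boys = "", pruned = "",
      loglik_null = NA_real_, loglik_full = NA_real_, lrt = NA_real_,
      df = NA_integer_, p_value = NA_real_, converged = NA,
      stringsAsFactors = FALSE))
  }
}

#' @export
print.scan_table <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("scan_table: %d windows of length %d, model %s (%d triads)\n",
              nrow(x), meta$window_length, meta$model, meta$n_triads))
  top <- x[order(x$p_value), c("window", "marker_ids", "p_value", "q_value")]
  cat("top windows:\n")
  print(utils::head(as.data.frame(top), 5), row.names = FALSE)
  invisible(x)
}

#' Write scan results to TSV or JSON
#'
#' One record per window: marker ids and positions, model label,
#' per-haplotype single-dose relative risks with 95% confidence intervals
#' and double-dose risks, the window LRT p-value and q-value, the number of
#' informative triads, and any pruned haplotypes. TSV is tab-delimited with
#' a header (and `#`-prefixed metadata lines); floats carry at least six
#' significant digits. JSON round-trips all numeric fields at full
#' precision.
#'
#' @param table a `scan_table`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @param metadata optional named list echoed into the output header.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path, format = c("tsv", "json"),
                          metadata = NULL) {
  format <- match.arg(format)
  if (!nrow(table)) stop("empty scan table")
  meta <- c(attr(table, "meta"), metadata)
  df <- as.data.frame(table)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(meta))
      writeLines(sprintf("# %s: %s", nm, paste(format(meta[[nm]]), collapse = " ")), con)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) ifelse(is.na(v), "NA", format(v, digits = 10)))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    recs <- lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, ])
      for (nm in c("haplotypes", "pruned")) r[[nm]] <- strsplit(r[[nm]], ";")[[1]]
      for (nm in c("frequencies", "rr_single_dose", "rr_ci_lower",
                   "rr_ci_upper", "rr_double_dose", "rr_boys"))
        r[[nm]] <- as.numeric(strsplit(r[[nm]], ";")[[1]])
      r$marker_ids <- strsplit(r$marker_ids, ";")[[1]]
      r$positions_bp <- as.integer(strsplit(r$positions_bp, ";")[[1]])
      r
    })
    jsonlite::write_json(list(metadata = meta, windows = recs), path,
                         auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' Read scan results written by [write_results()]
#'
#' @param path input path.
#' @param format `"tsv"` or `"json"`.
#' @return For TSV, a data.frame; for JSON, the list with `metadata` and
#'   `windows` records.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}

#' Manhattan-style plot of a scan
#'
#' Plots -log10 p against window start position with a horizontal line at
#' the largest p-value whose q-value is below the FDR threshold (cosmetic;
#' the q-values themselves are the normative significance measure).
#'
#' @param table a `scan_table`.
#' @param fdr FDR threshold marked on the plot.
#' @param ... passed to [plot()].
#' @return Invisibly, `table`.
#' @export
plot_scan <- function(table, fdr = 0.1, ...) {
  pos <- as.numeric(vapply(strsplit(table$positions_bp, ";"), `[`, "", 1))
  p <- table$p_value
  graphics::plot(pos / 1e6, -log10(p), pch = 16, cex = 0.6,
                 xlab = "position (Mb)", ylab = expression(-log[10](p)), ...)
  sig <- !is.na(table$q_value) & table$q_value <= fdr
  if (any(sig)) {
    thr <- max(p[sig])
    graphics::abline(h = -log10(thr), lty = 2, col = "grey40")
  }
  invisible(table)
}
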