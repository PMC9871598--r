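# File formats: delimited time-series tables (comma or tab, auto-detected,
# optional ROI-name header), network matrix CSV, edge-list TSV (0-based ROI
# indices), cohort manifest TSV (subject_id, path, label) and JSON reports.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a subject's ROI time series from delimited text
#'
#' Comma- or tab-separated values are auto-detected; a single non-numeric
#' first row is treated as ROI names.
#'
#' @param path file path.
#' @param subject_id identifier stored in the result (default: file name).
#' @return An [fbn_ts].
#' @export
read_timeseries <- function(path, subject_id = basename(path)) {
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  dat <- read.table(path, sep = sep, header = has_header,
                    check.names = FALSE)
  m <- as.matrix(dat)
  if (!is.numeric(m)) stop("non-numeric values in ", path)
  if (!all(is.finite(m))) stop("non-finite values in ", path)
  fbn_ts(m, subject_id = subject_id)
}

#' Write a time series as CSV
#' @param ts an [fbn_ts].
#' @param path output path.
#' @export
write_timeseries <- function(ts, path) {
  ts <- as_fbn_ts(ts)
  m <- ts$data
  if (is.null(colnames(m))) colnames(m) <- sprintf("ROI%d", seq_len(ncol(m)))
  write.table(m, path, sep = ",", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' Write a network weight matrix as CSV
#' @param net an `fbn` fit or square matrix.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  w <- if (inherits(net, "fbn")) net$weights else as.matrix(net)
  if (is.null(colnames(w))) colnames(w) <- sprintf("ROI%d", seq_len(ncol(w)))
  write.table(w, path, sep = ",", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' Write a network as an edge-list TSV
#'
#' Columns `roi_i`, `roi_j`, `weight` with 0-based ROI indices. Symmetric
#' networks (to 1e-12) are written as the upper triangle only (`i < j`);
#' asymmetric ones list every off-diagonal entry.
#'
#' @inheritParams write_network
#' @export
write_edge_list <- function(net, path) {
  w <- if (inherits(net, "fbn")) net$weights else as.matrix(net)
  n <- ncol(w)
  if (max(abs(w - t(w))) <= 1e-12) {
    idx <- feature_index(n)
    df <- data.frame(roi_i = idx[, 1L] - 1L, roi_j = idx[, 2L] - 1L,
                     weight = extract_upper_features(w))
  } else {
    ij <- expand.grid(i = seq_len(n), j = seq_len(n))
    ij <- ij[ij$i != ij$j, ]
    df <- data.frame(roi_i = ij$i - 1L, roi_j = ij$j - 1L,
                     weight = w[cbind(ij$i, ij$j)])
  }
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' Tab-separated file with header columns `subject_id`, `path`,
#' `label` (0/1). Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest path.
#' @return Data frame with columns `subject_id`, `path`, `label`.
#' @export
read_manifest <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!all(df$label %in% c(0L, 1L)))
    stop("manifest labels must be 0 or 1")
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df
}

#' Write a simulated cohort to disk
#'
#' Per-subject time-series CSVs, a manifest TSV, the true edge support as a
#' TSV and the generating configuration as a JSON sidecar.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.csv", cohort$subject_ids)
  for (k in seq_along(cohort$ts))
    write_timeseries(cohort$ts[[k]], file.path(dir, files[k]))
  manifest <- data.frame(subject_id = cohort$subject_ids, path = files,
                         label = cohort$labels)
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  gt <- cohort$ground_truth
  write.table(
    data.frame(roi_i = gt$support[, 1L] - 1L, roi_j = gt$support[, 2L] - 1L),
    file.path(dir, "true_edges.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(unclass(gt$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Write a classification report as JSON
#' @param report an `fbn_loocv_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
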