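#' Write a recording to its HDF5 container
#'
#' Layout: dataset `/signals` (channels x samples, float64, microvolts),
#' group `/markers` with datasets `onset_sample`, `label`,
#' `duration_samples`, and root attributes `sampling_rate`, `channel_labels`
#' and `id`. Round-trips bit-exactly through [read_recording()].
#'
#' @param rec a [recording()].
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "bci_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rec$signals, path, "signals")
  rhdf5::h5createGroup(path, "markers")
  rhdf5::h5write(rec$markers$onset_sample, path, "markers/onset_sample")
  rhdf5::h5write(rec$markers$label, path, "markers/label")
  rhdf5::h5write(rec$markers$duration_samples, path, "markers/duration_samples")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(rec$sampling_rate, fid, "sampling_rate")
  rhdf5::h5writeAttribute(rec$channel_labels, fid, "channel_labels")
  rhdf5::h5writeAttribute(rec$id, fid, "id")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a recording from its HDF5 container
#'
#' @param path file written by [write_recording()].
#' @return a [recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  signals <- rhdf5::h5read(path, "signals")
  mk <- markers_table(
    onset_sample = as.integer(rhdf5::h5read(path, "markers/onset_sample")),
    label = as.character(rhdf5::h5read(path, "markers/label")),
    duration_samples = as.integer(rhdf5::h5read(path, "markers/duration_samples")))
  fid <- rhdf5::H5Fopen(path)
  fs <- as.numeric(rhdf5::h5readAttributes(fid, "/")$sampling_rate)
  ch <- as.character(rhdf5::h5readAttributes(fid, "/")$channel_labels)
  id <- as.character(rhdf5::h5readAttributes(fid, "/")$id)
  rhdf5::H5Fclose(fid)
  recording(signals, fs, channel_labels = ch, markers = mk, id = id)
}

#' Read / write marker tables as CSV
#'
#' CSV columns: `onset_sample` (0-based), `label`, `duration_samples`.
#'
#' @param path CSV file path.
#' @return [read_markers_csv()] returns a marker data.frame.
#' @export
read_markers_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(label = "character"))
  markers_table(df$onset_sample, df$label, df$duration_samples)
}

#' @rdname read_markers_csv
#' @param markers marker data.frame ([markers_table()]).
#' @export
write_markers_csv <- function(markers, path) {
  utils::write.csv(markers, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read / write control-interval tables as CSV
#'
#' Intervals are half-open `[start_sample, end_sample)` in 0-based samples.
#'
#' @param path CSV file path.
#' @return [read_intervals_csv()] returns a data.frame with columns
#'   `start_sample`, `end_sample`.
#' @export
read_intervals_csv <- function(path) {
  df <- utils::read.csv(path)
  data.frame(start_sample = as.integer(df$start_sample),
             end_sample = as.integer(df$end_sample))
}

#' @rdname read_intervals_csv
#' @param intervals data.frame with `start_sample`, `end_sample` columns.
#' @export
write_intervals_csv <- function(intervals, path) {
  utils::write.csv(intervals, path, row.names = FALSE)
  invisible(path)
}

#' Read a subjects-by-classifiers performance CSV
#'
#' First column: subject identifier; remaining columns: one score per
#' classifier (accuracy or AUC).
#'
#' @param path CSV file path.
#' @return a [performance_table()].
#' @export
read_performance_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("performance CSV needs a subject column and >= 2 classifiers")
  scores <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(scores) <- "double"
  performance_table(scores, subject_ids = as.character(df[[1]]),
                    classifier_ids = colnames(df)[-1])
}

#' Path to a bundled benchmark performance table
#'
#' The package ships, as plain-text fixtures, the per-subject test
#' performances of seven classifiers from a published sensory-motor BCI
#' comparison study: accuracies for 21 subjects operating synchronous BCIs
#' and AUCs for 8 subjects operating self-paced BCIs, each under band-power
#' (`bp`) and Morlet (`morlet`) feature extraction. These tables feed the
#' statistics layer ([rank_table()], [friedman_rank_test()],
#' [holm_posthoc()]).
#'
#' @param paradigm `"synchronous"` or `"selfpaced"`.
#' @param features `"bp"` or `"morlet"`.
#' @return path to the CSV fixture.
#' @export
benchmark_table_path <- function(paradigm = c("synchronous", "selfpaced"),
                                 features = c("bp", "morlet")) {
  paradigm <- match.arg(paradigm)
  features <- match.arg(features)
  fn <- sprintf("%s_%s.csv",
                switch(paradigm, synchronous = "sync_accuracy",
                       selfpaced = "selfpaced_auc"), features)
  path <- system.file("extdata", fn, package = "bcibench")
  if (path == "") stop("fixture not found: ", fn)
  path
}
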