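#' Trial-based multichannel recording container
#'
#' Constructs and validates the raw-data container used throughout the
#' package: a set of trials, each a channels-by-samples matrix of analog
#' amplitudes, with per-trial time axes in seconds, channel labels and a
#' sampling rate in Hz.  The layout mirrors the trial-based raw format
#' common in electrophysiology toolchains (fields `trial`, `time`,
#' `label`, `fsample`).
#'
#' @param trials list of numeric matrices, each `length(labels)` rows
#'   (channels) by number-of-samples columns.
#' @param times list of strictly increasing numeric vectors (seconds),
#'   one per trial, each of length `ncol(trials[[i]])` and with step
#'   `1/fsample` (relative tolerance 1e-6).
#' @param labels character vector of channel names.
#' @param fsample sampling rate in Hz (positive scalar).
#' @return An object of class `raw_dataset`.
#' @export
raw_dataset <- function(trials, times, labels, fsample) {
  x <- structure(list(trials = trials, times = times,
                      labels = as.character(labels),
                      fsample = as.numeric(fsample)),
                 class = "raw_dataset")
  validate_raw_dataset(x)
}

#' Validate a raw_dataset container
#'
#' Checks every container invariant and fails with an error naming the
#' offending field or trial index.
#'
#' @param x object to validate.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_raw_dataset <- function(x) {
  for (f in c("trials", "times", "labels", "fsample"))
    if (is.null(x[[f]])) stop("malformed container: missing field '", f, "'")
  if (!is.numeric(x$fsample) || length(x$fsample) != 1L || x$fsample <= 0)
    stop("malformed container: 'fsample' must be a positive scalar")
  if (length(x$trials) != length(x$times))
    stop("malformed container: ", length(x$trials), " trials but ",
         length(x$times), " time vectors")
  if (length(x$trials) == 0L) stop("malformed container: no trials")
  nch <- length(x$labels)
  for (i in seq_along(x$trials)) {
    tr <- x$trials[[i]]; tm <- x$times[[i]]
    if (!is.matrix(tr)) stop("trial ", i, ": not a matrix")
    if (nrow(tr) != nch)
      stop("trial ", i, ": ", nrow(tr), " channels but ", nch, " labels")
    if (ncol(tr) != length(tm))
      stop("trial ", i, ": ", ncol(tr), " samples but time vector of length ",
           length(tm))
    dt <- diff(tm)
    if (any(dt <= 0)) stop("trial ", i, ": time vector not strictly increasing")
    if (any(abs(dt * x$fsample - 1) > 1e-6 * max(1, abs(dt * x$fsample))))
      stop("trial ", i, ": time step inconsistent with fsample")
  }
  invisible(x)
}

#' @export
print.raw_dataset <- function(x, ...) {
  ns <- vapply(x$trials, ncol, 1L)
  cat("<raw_dataset> ", length(x$labels), " channel(s) [",
      paste(x$labels, collapse = ", "), "], ", length(x$trials),
      " trial(s), ", min(ns), "-", max(ns), " samples @ ", x$fsample,
      " Hz\n", sep = "")
  invisible(x)
}

n_trials <- function(data) length(data$trials)

# Extract one channel of one trial as a numeric vector.
channel_series <- function(data, label, trial) {
  i <- match(label, data$labels)
  if (is.na(i)) stop("unknown channel '", label, "'")
  data$trials[[trial]][i, ]
}

#' State-space reconstruction and estimation parameters
#'
#' Bundles the delay-embedding and neighbour-search parameters: embedding
#' dimension `d`, embedding delay `tau` (samples), prediction time `u`
#' (samples), neighbour mass `k` for the fixed-mass search and the
#' Theiler exclusion window (samples).  The same `d` and `tau` are
#' applied to both signals of an analysed pair.
#'
#' @param d embedding dimension (integer >= 1).
#' @param tau embedding delay in samples (integer >= 1).
#' @param u prediction time in samples (integer >= 1).
#' @param k number of neighbours for the fixed-mass search (default 4).
#' @param theiler Theiler exclusion window in samples (integer >= 0).
#' @return An object of class `embedding_spec`.
#' @export
embedding_spec <- function(d, tau, u, k = 4L, theiler = 0L) {
  d <- as.integer(d); tau <- as.integer(tau); u <- as.integer(u)
  k <- as.integer(k); theiler <- as.integer(theiler)
  if (d < 1L) stop("embedding dimension d must be >= 1")
  if (tau < 1L) stop("embedding delay tau must be >= 1")
  if (u < 1L) stop("prediction time u must be >= 1")
  if (k < 1L) stop("neighbour count k must be >= 1")
  if (theiler < 0L) stop("theiler window must be >= 0")
  structure(list(d = d, tau = tau, u = u, k = k, theiler = theiler),
            class = "embedding_spec")
}

#' @export
print.embedding_spec <- function(x, ...) {
  cat(sprintf("<embedding_spec> d=%d tau=%d u=%d k=%d theiler=%d\n",
              x$d, x$tau, x$u, x$k, x$theiler))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Serialization.  The native container is plain-text JSON; a per-trial CSV
# directory is also supported.  Numeric values survive a round trip exactly
# (digits = NA writes full double precision).

#' Read a trial-based dataset from disk
#'
#' @param path file (JSON container) or directory (CSV format) to read.
#' @param format `"json"` for the native single-file container or
#'   `"csvdir"` for a directory with `labels.txt`, `fsample.txt` and one
#'   `trial_<i>.csv` (samples x channels) per trial.
#' @return A validated [raw_dataset()].
#' @export
load_dataset <- function(path, format = c("json", "csvdir")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    for (f in c("trial", "time", "label", "fsample"))
      if (is.null(obj[[f]])) stop("malformed container: missing field '", f, "'")
    trials <- lapply(obj$trial, function(m)
      do.call(rbind, lapply(m, function(row) as.numeric(unlist(row)))))
    times <- lapply(obj$time, function(v) as.numeric(unlist(v)))
    raw_dataset(trials, times, as.character(unlist(obj$label)),
                as.numeric(obj$fsample))
  } else {
    labf <- file.path(path, "labels.txt")
    fsf <- file.path(path, "fsample.txt")
    if (!file.exists(labf)) stop("malformed container: missing field 'label'")
    if (!file.exists(fsf)) stop("malformed container: missing field 'fsample'")
    labels <- readLines(labf)
    fsample <- as.numeric(readLines(fsf)[1])
    files <- list.files(path, pattern = "^trial_[0-9]+\\.csv$")
    if (length(files) == 0L) stop("malformed container: missing field 'trial'")
    ord <- order(as.integer(sub("^trial_([0-9]+)\\.csv$", "\\1", files)))
    files <- files[ord]
    trials <- lapply(files, function(f) {
      m <- as.matrix(read.table(file.path(path, f), sep = ",", header = TRUE))
      t(m)  # stored samples x channels
    })
    times <- lapply(trials, function(m) seq_len(ncol(m)) / fsample)
    raw_dataset(trials, times, labels, fsample)
  }
}

#' Write a trial-based dataset to disk
#'
#' Inverse of [load_dataset()]; the JSON container round-trips every
#' numeric field exactly.
#'
#' @param data a [raw_dataset()].
#' @param path destination file (json) or directory (csvdir).
#' @param format see [load_dataset()].
#' @return `path`, invisibly.
#' @export
save_dataset <- function(data, path, format = c("json", "csvdir")) {
  format <- match.arg(format)
  validate_raw_dataset(data)
  if (format == "json") {
    obj <- list(trial = data$trials, time = data$times,
                label = data$labels, fsample = data$fsample)
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                         always_decimal = TRUE, matrix = "rowmajor")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    writeLines(data$labels, file.path(path, "labels.txt"))
    writeLines(format(data$fsample, digits = 17), file.path(path, "fsample.txt"))
    for (i in seq_along(data$trials)) {
      m <- t(data$trials[[i]])
      colnames(m) <- data$labels
      write.table(m, file.path(path, sprintf("trial_%d.csv", i)),
                  sep = ",", row.names = FALSE, qmethod = "double")
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Result containers

#' Per-trial transfer-entropy / mutual-information results
#'
#' One record per (channel pair, direction, trial) holding the TE and MI
#' estimates in nats.  Negative values are possible (finite-sample bias)
#' and are preserved.
#'
#' @param table data.frame with columns `source`, `target`, `trial`,
#'   `te_nats`, `mi_nats`.
#' @param spec the [embedding_spec()] (or named list of specs per pair)
#'   used for estimation.
#' @param provenance named list (config hash, seed, package version).
#' @return An object of class `te_result_set`.
#' @export
te_result_set <- function(table, spec, provenance = list()) {
  need <- c("source", "target", "trial", "te_nats", "mi_nats")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("result table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(table$te_nats)))
    stop("non-finite te_nats in result table")
  structure(list(table = table, spec = spec, provenance = provenance),
            class = "te_result_set")
}

#' @export
print.te_result_set <- function(x, ...) {
  cat("<te_result_set> ", nrow(x$table), " records (",
      length(unique(paste(x$table$source, x$table$target))),
      " directed pair(s))\n", sep = "")
  invisible(x)
}

#' Write analysis results to disk
#'
#' Writes two files named from a common stem: `<fileidout>_TE_output.*`
#' with the per-trial TE/MI values and `<fileidout>_TEpermtest_output.*`
#' with the permutation-test summary.  JSON preserves full double
#' precision; TSV has one row per (pair, direction, trial) / per test.
#'
#' @param results list with elements `te` (a [te_result_set()]) and
#'   optionally `permtest` (data.frame as returned by the analysis
#'   pipelines).
#' @param fileidout output path stem.
#' @param format `"json"` or `"tsv"`.
#' @return character vector of the two file paths written.
#' @export
save_results <- function(results, fileidout, format = c("json", "tsv")) {
  format <- match.arg(format)
  ext <- format
  te_path <- paste0(fileidout, "_TE_output.", ext)
  pt_path <- paste0(fileidout, "_TEpermtest_output.", ext)
  te <- if (inherits(results, "te_result_set")) results else results$te
  if (is.null(te)) stop("results must contain a te_result_set")
  pt <- if (inherits(results, "te_result_set")) NULL else results$permtest
  spec_plain <- if (inherits(te$spec, "embedding_spec")) unclass(te$spec)
  else if (is.list(te$spec)) lapply(te$spec, unclass) else te$spec
  if (format == "json") {
    jsonlite::write_json(list(table = te$table, spec = spec_plain,
                              provenance = te$provenance),
                         te_path, digits = I(17), auto_unbox = TRUE,
                         always_decimal = TRUE, dataframe = "columns")
    jsonlite::write_json(if (is.null(pt)) list() else pt, pt_path,
                         digits = I(17), auto_unbox = TRUE,
                         always_decimal = TRUE, dataframe = "columns")
  } else {
    write.table(te$table, te_path, sep = "\t", row.names = FALSE,
                qmethod = "double")
    write.table(if (is.null(pt)) data.frame() else pt, pt_path, sep = "\t",
                row.names = FALSE, qmethod = "double")
  }
  c(te_path, pt_path)
}

#' Read a TE result table written by [save_results()]
#'
#' @param path path to a `*_TE_output.json` file.
#' @return A [te_result_set()].
#' @export
load_results <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tab <- as.data.frame(obj$table)
  spec <- obj$spec
  if (!is.null(spec$d))
    spec <- embedding_spec(spec$d, spec$tau, spec$u, spec$k, spec$theiler)
  te_result_set(tab, spec, as.list(obj$provenance))
}
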