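#' Spike train set
#'
#' Container for raw per-cell spike times preceding binning.
#'
#' @param spikes List of numeric vectors, one per cell, of spike times in
#'   seconds. Each vector is sorted ascending; times must lie in
#'   `[0, duration)`.
#' @param duration Recording duration in seconds. Defaults to just past the
#'   last spike.
#' @return An object of class `spike_train_set` with elements `spikes`,
#'   `n_cells`, `duration`.
#' @examples
#' sts <- spike_train_set(list(c(0.005, 0.012), c(0.031)), duration = 0.1)
#' @export
spike_train_set <- function(spikes, duration = NULL) {
  if (!is.list(spikes)) stop("`spikes` must be a list of numeric vectors")
  spikes <- lapply(spikes, function(s) sort(as.numeric(s)))
  if (is.null(duration)) {
    mx <- suppressWarnings(max(unlist(spikes), -Inf))
    duration <- if (is.finite(mx)) mx + 1e-9 else 0
  }
  for (s in spikes) {
    if (any(s < 0) || any(s >= duration))
      stop("spike times must lie in [0, duration)")
  }
  structure(list(spikes = spikes, n_cells = length(spikes),
                 duration = as.numeric(duration)),
            class = "spike_train_set")
}

#' Binary population raster
#'
#' An N x T matrix of 0/1 spike words: entry (i, t) indicates whether cell i
#' fired at least one spike in time bin t. The column at a fixed t is the
#' population "word" for that bin.
#'
#' @param data Matrix of 0/1 values, cells in rows, time bins in columns.
#' @param bin_width Bin width in seconds (default 0.02, i.e. 20 ms).
#' @param cell_ids Optional character labels, one per row.
#' @return Object of class `binary_raster`.
#' @export
binary_raster <- function(data, bin_width = 0.02, cell_ids = NULL) {
  data <- as.matrix(data)
  if (!all(data %in% c(0L, 1L))) stop("raster entries must be 0 or 1")
  storage.mode(data) <- "integer"
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(data)))
  if (length(cell_ids) != nrow(data)) stop("cell_ids length mismatch")
  if (bin_width <= 0) stop("bin_width must be positive")
  structure(list(data = data, bin_width = as.numeric(bin_width),
                 cell_ids = as.character(cell_ids)),
            class = "binary_raster")
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf("binary_raster: %d cells x %d bins (%.0f ms bins), mean rate %.3f\n",
              nrow(x$data), ncol(x$data), x$bin_width * 1000, mean(x$data)))
  invisible(x)
}

#' @export
dim.binary_raster <- function(x) dim(x$data)

#' Aligned repeats of a raster
#'
#' @param rasters List of [binary_raster] objects with identical dimensions
#'   and bin widths, one per stimulus repeat.
#' @return Object of class `repeat_set` with elements `rasters`, `n_repeats`.
#' @export
repeat_set <- function(rasters) {
  if (length(rasters) < 1) stop("need at least one repeat")
  d <- dim(rasters[[1]]$data)
  bw <- rasters[[1]]$bin_width
  for (r in rasters) {
    if (!inherits(r, "binary_raster")) stop("all repeats must be binary_raster")
    if (!identical(dim(r$data), d) || r$bin_width != bw)
      stop("all repeats must share N, T and bin_width")
  }
  structure(list(rasters = rasters, n_repeats = length(rasters)),
            class = "repeat_set")
}

#' Bin spike trains into a binary raster
#'
#' A bin is set to 1 whenever at least one spike falls in the half-open
#' interval `[t * bin_width, (t + 1) * bin_width)`; multiple spikes in a bin
#' still give 1. Spikes at exactly `duration` are dropped by the half-open
#' convention.
#'
#' @param spikes A [spike_train_set].
#' @param bin_width Bin width in seconds; default 20 ms.
#' @return A [binary_raster] with `T = ceiling(duration / bin_width)` bins.
#' @examples
#' sts <- spike_train_set(list(c(0.005, 0.012), numeric(0)), duration = 0.04)
#' bin_spikes(sts, 0.02)$data
#' @export
bin_spikes <- function(spikes, bin_width = 0.02) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (bin_width <= 0) stop("bin_width must be positive")
  if (spikes$n_cells == 0) stop("no cells")
  T_ <- as.integer(ceiling(spikes$duration / bin_width))
  if (T_ < 1) T_ <- 1L
  data <- matrix(0L, spikes$n_cells, T_)
  for (i in seq_len(spikes$n_cells)) {
    b <- floor(spikes$spikes[[i]] / bin_width) + 1
    b <- b[b >= 1 & b <= T_]
    data[i, unique(b)] <- 1L
  }
  binary_raster(data, bin_width)
}

#' Circularly shuffle each cell's spike train
#'
#' Each row is independently circularly shifted by a uniform random offset,
#' destroying cross-cell correlations while preserving each cell's spike
#' count and (circular) autocorrelation exactly. Used as the uncorrelated
#' null for model-order selection.
#'
#' @param raster A [binary_raster] with at least 2 bins.
#' @param seed Integer seed.
#' @return A [binary_raster] of the same dimensions.
#' @export
circular_shuffle <- function(raster, seed = 1L) {
  stopifnot(inherits(raster, "binary_raster"))
  T_ <- ncol(raster$data)
  if (T_ < 2) stop("need at least 2 bins")
  shifts <- with_seed(seed, sample.int(T_, nrow(raster$data), replace = TRUE)) - 1L
  out <- raster$data
  for (i in seq_len(nrow(out))) {
    s <- shifts[i] %% T_
    if (s > 0) out[i, ] <- out[i, c((T_ - s + 1):T_, 1:(T_ - s))]
  }
  binary_raster(out, raster$bin_width, raster$cell_ids)
}

#' Encode raster columns as word strings
#'
#' Words are read cell 1 to cell N (first cell is the most significant /
#' leftmost character).
#' @param raster A [binary_raster].
#' @return Character vector of length T of "0"/"1" strings.
#' @export
word_strings <- function(raster) {
  apply(raster$data, 2, paste, collapse = "")
}

#' Empirical word-frequency table
#'
#' Counts each distinct binary population word observed in a raster.
#'
#' @param raster A [binary_raster].
#' @return A data.frame with columns `word` (0/1 string, cell 1 leftmost),
#'   `count`, and `frequency` (counts / T), sorted by decreasing count.
#' @export
word_frequencies <- function(raster) {
  ws <- word_strings(raster)
  tab <- table(ws)
  out <- data.frame(word = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$frequency <- out$count / length(ws)
  out <- out[order(-out$count, out$word), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- file formats ----------------------------------------------------------

#' Read spike times from CSV
#'
#' Expects a header `cell_id,time_s`. Cells are ordered by first appearance
#' unless `cell_ids` is given.
#' @param path CSV file path.
#' @param duration Optional recording duration in seconds.
#' @param cell_ids Optional vector fixing the cell order (cells without
#'   spikes are kept as empty trains).
#' @return A [spike_train_set].
#' @export
read_spikes_csv <- function(path, duration = NULL, cell_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "time_s") %in% names(df)))
    stop("expected columns cell_id,time_s")
  if (is.null(cell_ids)) cell_ids <- unique(df$cell_id)
  spikes <- lapply(cell_ids, function(cid) df$time_s[df$cell_id == cid])
  spike_train_set(spikes, duration)
}

#' Write / read a raster as (optionally gzipped) TSV
#'
#' Rows are cells, columns are bins, values 0/1. The bin width is stored in
#' a `# bin_width_s=` comment on the first line.
#' @param raster A [binary_raster].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `write_raster_tsv` returns `path` invisibly; `read_raster_tsv`
#'   returns a [binary_raster].
#' @export
write_raster_tsv <- function(raster, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width_s=%.17g", raster$bin_width), con)
  utils::write.table(raster$data, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  bw <- 0.02
  if (grepl("^# bin_width_s=", first)) {
    bw <- as.numeric(sub("^# bin_width_s=", "", first))
    data <- as.matrix(utils::read.table(con, sep = "\t"))
  } else {
    data <- rbind(as.integer(strsplit(first, "\t")[[1]]),
                  as.matrix(utils::read.table(con, sep = "\t")))
  }
  dimnames(data) <- NULL
  binary_raster(data, bw)
}

#' Write a word-frequency table as TSV
#' @param words Data frame from [word_frequencies()].
#' @param path Output path.
#' @export
write_word_table <- function(words, path) {
  utils::write.table(words, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
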