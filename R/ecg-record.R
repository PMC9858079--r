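#' Construct a single-lead ECG record
#'
#' The basic container passed between all stages of the pipeline: a numeric
#' sample vector in millivolts, its sampling rate, a record identifier and an
#' optional rhythm class label.
#'
#' @param samples numeric vector of amplitudes (mV); must be finite, length >= 2.
#' @param fs sampling rate in Hz (> 0).
#' @param id record identifier (character scalar).
#' @param rhythm optional rhythm class, one of `"normal"`, `"bradycardia"`,
#'   `"tachycardia"`, or `NA` when unknown.
#' @return An object of class `ecg_record`: a list with elements `samples`,
#'   `fs`, `id`, `rhythm`.
#' @examples
#' r <- ecg_record(sin(2 * pi * 1 * seq(0, 2, by = 1 / 250)), fs = 250)
#' r
#' @export
ecg_record <- function(samples, fs, id = "rec", rhythm = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("an ECG record needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("ECG samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  }
  if (!is.na(rhythm) && !rhythm %in% rhythm_classes()) {
    stop("unknown rhythm label: ", rhythm, call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         id = as.character(id), rhythm = rhythm),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<ecg_record '%s'>  %d samples @ %g Hz (%.2f s)",
              x$id, length(x$samples), x$fs, dur))
  if (!is.na(x$rhythm)) cat("  rhythm:", x$rhythm)
  cat(sprintf("\n  range [%.3f, %.3f] mV\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' The three rhythm classes used throughout the package
#'
#' @return Character vector `c("normal", "bradycardia", "tachycardia")`.
#' @export
rhythm_classes <- function() c("normal", "bradycardia", "tachycardia")

#' Read / write ECG records as plain CSV
#'
#' The on-disk format is a two-column CSV (`sample_index`, `mV`); the sampling
#' rate, record id and rhythm label travel in `#`-prefixed header comments so a
#' record round-trips losslessly.
#'
#' @param path file path.
#' @param record an [ecg_record].
#' @param fs sampling rate override when the file has no header comment.
#' @return `read_ecg_csv` returns an [ecg_record]; `write_ecg_csv` returns
#'   `path` invisibly.
#' @export
read_ecg_csv <- function(path, fs = NULL) {
  header <- readLines(path, n = 10L)
  meta <- header[startsWith(header, "#")]
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*=")[1], meta, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub(".*=", "", hit[1]))
  }
  fs_file <- get_meta("fs")
  if (is.null(fs) && is.null(fs_file)) {
    stop("sampling rate not in file header; supply 'fs'", call. = FALSE)
  }
  fs <- if (is.null(fs)) as.numeric(fs_file) else fs
  id <- get_meta("id")
  rhythm <- get_meta("rhythm")
  df <- utils::read.csv(path, comment.char = "#")
  ecg_record(df$mV, fs = fs,
             id = if (is.null(id)) "rec" else id,
             rhythm = if (is.null(rhythm)) NA_character_ else rhythm)
}

#' @rdname read_ecg_csv
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# fs = ", record$fs),
    paste0("# id = ", record$id),
    if (!is.na(record$rhythm)) paste0("# rhythm = ", record$rhythm)
  ), con)
  utils::write.csv(
    data.frame(sample_index = seq_along(record$samples), mV = record$samples),
    con, row.names = FALSE
  )
  invisible(path)
}

#' Write / read beat annotations as a long-format CSV sidecar
#'
#' Columns: `record_id`, `beat`, `fiducial`, `sample_index` — one row per
#' fiducial point.
#'
#' @param annotations a `beat_annotations` data frame (see [delineate_beats])
#'   or the `truth` component of [synthesize_record].
#' @param path file path.
#' @export
write_annotations_csv <- function(annotations, path) {
  fids <- fiducial_names()
  long <- do.call(rbind, lapply(seq_len(nrow(annotations)), function(i) {
    data.frame(
      record_id = if ("record_id" %in% names(annotations))
        annotations$record_id[i] else NA_character_,
      beat = annotations$beat[i],
      fiducial = fids,
      sample_index = unlist(annotations[i, fids], use.names = FALSE)
    )
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  long <- utils::read.csv(path)
  wide <- stats::reshape(long, idvar = c("record_id", "beat"),
                         timevar = "fiducial", direction = "wide")
  names(wide) <- sub("^sample_index\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[, c("record_id", "beat", fiducial_names())]
}

# canonical fiducial ordering used by the generator and the delineator
fiducial_names <- function() {
  c("P_on", "P_peak", "P_off", "QRS_on", "Q", "R", "S",
    "QRS_off", "T_on", "T_peak", "T_off")
}

# run `expr` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
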