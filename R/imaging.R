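#' Render a time-frequency representation to a fixed-size RGB image
#'
#' Deterministic rasterization used to build classifier datasets. Values are
#' min-max normalized per image (a degenerate all-equal matrix renders as a
#' uniform image) and mapped through a fixed 256-level perceptually uniform
#' colormap, then bilinearly resized to `size x size`. No axes or annotations
#' are drawn.
#'
#' * `tf_grid` (spectrogram): the dB-converted PSD, frequency increasing
#'   upward.
#' * `scalogram`: coefficient magnitudes, scale increasing upward.
#' * `irisgram`: top-down orthographic projection of the annular `(X, Y, Z)`
#'   surface; pixels outside the annulus take the colormap's floor color.
#'
#' @param representation a `tf_grid`, `irisgram` or `scalogram`.
#' @param colormap name accepted by [grDevices::hcl.colors] (default
#'   `"viridis"`).
#' @param size output side length in pixels (default 224).
#' @return An object of class `rep_image`: integer array `size x size x 3`
#'   with values in 0–255, plus attributes `wave`, `label`, `record_id`,
#'   `beat`, `representation` when derivable.
#' @export
render_image <- function(representation, colormap = "viridis", size = 224L) {
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256L, colormap)))
  to_idx <- function(m) {
    rng <- range(m)
    if (rng[1] == rng[2]) {
      matrix(1L, nrow = nrow(m), ncol = ncol(m))
    } else {
      matrix(as.integer(round((m - rng[1]) / (rng[2] - rng[1]) * 255)) + 1L,
             nrow = nrow(m))
    }
  }
  if (inherits(representation, "irisgram")) {
    idx <- rasterize_polar(representation, size)
    kind <- "irisgram"
  } else if (inherits(representation, "scalogram")) {
    vals <- representation$values[rev(seq_len(nrow(representation$values))), ,
                                  drop = FALSE]
    idx <- resize_index(to_idx(vals), size)
    kind <- "scalogram"
  } else if (inherits(representation, "tf_grid")) {
    z <- psd_to_db(representation$psd)
    idx <- resize_index(to_idx(z[rev(seq_len(nrow(z))), , drop = FALSE]), size)
    kind <- "spectrogram"
  } else {
    stop("unsupported representation", call. = FALSE)
  }
  img <- array(0L, dim = c(size, size, 3L))
  for (ch in 1:3) {
    img[, , ch] <- matrix(pal[idx, ch], nrow = size)
  }
  structure(img, class = "rep_image", representation = kind)
}

# bilinear-resized colormap index matrix: resize the normalized values, not
# the indices, to avoid palette interpolation artifacts
resize_index <- function(idx, size) {
  v <- (idx - 1L) / 255
  img <- EBImage::resize(EBImage::Image(t(v)), w = size, h = size)
  m <- t(EBImage::imageData(img))
  m[m < 0] <- 0
  m[m > 1] <- 1
  matrix(as.integer(round(m * 255)) + 1L, nrow = size)
}

# project an irisgram's annular surface onto a size x size Cartesian raster;
# nearest (frequency, angle) lookup per pixel, floor color outside the annulus
rasterize_polar <- function(ir, size) {
  zrng <- range(ir$Z)
  zn <- if (zrng[1] == zrng[2]) {
    matrix(0, nrow = nrow(ir$Z), ncol = ncol(ir$Z))
  } else {
    (ir$Z - zrng[1]) / (zrng[2] - zrng[1])
  }
  rmax <- max(ir$rho)
  rmin <- min(ir$rho)
  ax <- seq(-rmax, rmax, length.out = size)
  px <- matrix(rep(ax, each = size), nrow = size)        # x per column
  py <- matrix(rep(rev(ax), times = size), nrow = size)  # y per row (up)
  rr <- sqrt(px^2 + py^2)
  th <- atan2(py, px)
  inside <- rr >= rmin & rr <= rmax
  fi <- pmin(length(ir$rho),
             pmax(1L, round((rr - rmin) / (rmax - rmin) * (length(ir$rho) - 1L)) + 1L))
  ti <- pmin(length(ir$theta),
             pmax(1L, round((th + pi) / (2 * pi) * (length(ir$theta) - 1L)) + 1L))
  out <- matrix(1L, nrow = size, ncol = size)
  sel <- which(inside)
  out[sel] <- as.integer(round(zn[cbind(fi[sel], ti[sel])] * 255)) + 1L
  out
}

#' Write a rendered image to a PNG file
#'
#' @param image a `rep_image`.
#' @param path output path.
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "rep_image"))
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' Build a labeled image dataset from ECG records
#'
#' Runs delineation and segment extraction on each record, computes the
#' chosen time-frequency representation per segment, renders it to a
#' 224x224x3 PNG and stores it under a class-named subdirectory of `out_dir`.
#' Records yielding no delineated beats are skipped (logged via `message`).
#'
#' @param records list of preprocessed, labeled [ecg_record]s.
#' @param wave_kind `"P"`, `"QRS"` or `"T"`.
#' @param representation_kind `"irisgram"`, `"scalogram"` or `"spectrogram"`.
#' @param out_dir output directory (created if needed).
#' @param colormap,size rendering options, see [render_image].
#' @return A data frame of class `dataset_manifest` with columns `path`,
#'   `class`, `wave`, `representation`, `record_id`, `beat`.
#' @export
build_dataset <- function(records, wave_kind, representation_kind, out_dir,
                          colormap = "viridis", size = 224L) {
  wave_kind <- match.arg(wave_kind, c("P", "QRS", "T"))
  representation_kind <- match.arg(representation_kind,
                                   c("irisgram", "scalogram", "spectrogram"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (rec in records) {
    stopifnot(inherits(rec, "ecg_record"))
    ann <- suppressWarnings(delineate_beats(rec))
    if (nrow(ann) == 0L) {
      message("record '", rec$id, "' skipped: no delineated beats")
      next
    }
    segs <- suppressWarnings(extract_wave_segments(rec, ann, wave_kind))
    cls_dir <- file.path(out_dir, rec$rhythm)
    dir.create(cls_dir, showWarnings = FALSE)
    for (seg in segs) {
      rep_obj <- suppressWarnings(switch(
        representation_kind,
        irisgram = irisgram(seg),
        scalogram = cwt_scalogram(seg),
        spectrogram = stft_spectrogram(seg)
      ))
      img <- render_image(rep_obj, colormap = colormap, size = size)
      fname <- sprintf("%s_%s_%s_beat%03d.png",
                       gsub("[^A-Za-z0-9_-]", "_", rec$id),
                       wave_kind, representation_kind, seg$beat)
      path <- file.path(cls_dir, fname)
      write_image_png(img, path)
      rows[[length(rows) + 1L]] <- data.frame(
        path = path, class = rec$rhythm, wave = wave_kind,
        representation = representation_kind,
        record_id = rec$id, beat = seg$beat
      )
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(0), class = character(0), wave = character(0),
               representation = character(0), record_id = character(0),
               beat = integer(0))
  if (anyDuplicated(manifest$path)) {
    stop("duplicate image paths in manifest (record ids not unique?)",
         call. = FALSE)
  }
  class(manifest) <- c("dataset_manifest", "data.frame")
  manifest
}

#' Stratified train/test split of a dataset manifest
#'
#' Splits each class independently so the train fraction holds per class
#' (within rounding). A class with a single row goes entirely to train with a
#' warning. Train and test are disjoint and jointly exhaustive.
#'
#' @param manifest a `dataset_manifest` (any data frame with a `class`
#'   column).
#' @param train_fraction fraction per class assigned to train (default 0.7).
#' @param seed integer seed making the split reproducible.
#' @return List with elements `train` and `test`, both manifests.
#' @export
split_dataset <- function(manifest, train_fraction = 0.7, seed = 1L) {
  stopifnot(is.data.frame(manifest), "class" %in% names(manifest))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("'train_fraction' must be in (0, 1)", call. = FALSE)
  }
  idx_train <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(manifest)), manifest$class), function(ix) {
      if (length(ix) == 1L) {
        warning("class with a single row assigned entirely to train",
                call. = FALSE)
        return(ix)
      }
      sample(ix, round(train_fraction * length(ix)))
    }), use.names = FALSE)
  })
  list(train = manifest[sort(idx_train), , drop = FALSE],
       test = manifest[setdiff(seq_len(nrow(manifest)), idx_train), ,
                       drop = FALSE])
}

#' Stratified k-fold partition of a dataset manifest
#'
#' Shuffles each class (seeded) and deals rows round-robin into `k` folds of
#' near-equal size; every row appears in exactly one test fold.
#'
#' @param manifest a `dataset_manifest`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return List of `k` elements, each `list(train = ..., test = ...)`.
#' @export
kfold_split <- function(manifest, k = 5L, seed = 1L) {
  stopifnot(is.data.frame(manifest), "class" %in% names(manifest))
  k <- as.integer(k)
  counts <- table(manifest$class)
  if (any(counts < k)) {
    stop("every class needs at least k = ", k, " rows", call. = FALSE)
  }
  fold <- integer(nrow(manifest))
  with_seed(seed, {
    for (ix in split(seq_len(nrow(manifest)), manifest$class)) {
      fold[sample(ix)] <- rep(seq_len(k), length.out = length(ix))
    }
  })
  lapply(seq_len(k), function(i) {
    list(train = manifest[fold != i, , drop = FALSE],
         test = manifest[fold == i, , drop = FALSE])
  })
}
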