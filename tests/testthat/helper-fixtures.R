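# shared fixtures: small synthetic records and label-set builders

FID <- c("P_on", "P_peak", "P_off", "QRS_on", "Q", "R", "S",
         "QRS_off", "T_on", "T_peak", "T_off")

fiducial_errors_ms <- function(ann, truth) {
  tr <- truth[match(ann$R, truth$R), ]
  abs(as.matrix(ann[FID]) - as.matrix(tr[FID])) / 360 * 1000
}

# a manifest-shaped data frame without any image files (for split tests)
fake_manifest <- function(n_per_class,
                          classes = c("normal", "bradycardia", "tachycardia")) {
  n <- rep(n_per_class, length.out = length(classes))
  data.frame(
    path = sprintf("img_%04d.png", seq_len(sum(n))),
    class = rep(classes, n),
    wave = "T", representation = "scalogram",
    record_id = "fake", beat = seq_len(sum(n))
  )
}

# write a tiny separable 3-class image set: class k = constant intensity
# band + seeded speckle; returns a manifest
make_toy_image_dataset <- function(dir, n_per_class = 12, side = 24,
                                   seed = 99) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  classes <- c("bradycardia", "normal", "tachycardia")
  means <- c(0.15, 0.5, 0.85)
  rows <- list()
  set.seed(seed)
  for (k in seq_along(classes)) {
    cdir <- file.path(dir, classes[k])
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      img <- array(pmin(1, pmax(0, means[k] + stats::rnorm(side^2 * 3, 0, 0.03))),
                   dim = c(side, side, 3))
      p <- file.path(cdir, sprintf("toy_%s_%02d.png", classes[k], i))
      png::writePNG(img, p)
      rows[[length(rows) + 1]] <- data.frame(
        path = p, class = classes[k], wave = "T",
        representation = "toy", record_id = "toy", beat = i)
    }
  }
  do.call(rbind, rows)
}
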