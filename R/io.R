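#' Read a fundus image file
#'
#' Reads PNG/JPEG/TIFF into a [FundusImage-class]. Values are normalized to
#' `[0,1]` (16-bit inputs by their maximum representable value); grayscale
#' inputs are replicated to three channels. The FOV defaults to all-`TRUE`
#' unless `detectFov` is set, which thresholds away the dark border.
#'
#' @param path image file.
#' @param grade optional grade label.
#' @param detectFov estimate the field of view from the dark background.
#' @return a [FundusImage-class].
#' @export
readFundus <- function(path, grade = NA_character_, detectFov = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (max(a) > 1) a <- a / max(a)     # 16-bit style payloads
  if (length(dim(a)) == 2) {
    a <- array(rep(a, 3), dim = c(dim(a), 3))
  } else if (dim(a)[3] > 3) {
    a <- a[, , 1:3]
  }
  ## EBImage is x,y ordered; transpose to row-major H x W
  arr <- array(0, dim = c(dim(a)[2], dim(a)[1], 3))
  for (k in 1:3) arr[, , k] <- t(a[, , k])
  arr <- clip01(arr)
  fov <- if (detectFov) {
    gray <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
    gray > 0.05
  } else matrix(TRUE, dim(arr)[1], dim(arr)[2])
  new("FundusImage", image = arr, fov = fov, grade = grade)
}

#' Write a fundus image as PNG
#'
#' @param path output file.
#' @param fundus a [FundusImage-class] or H x W x 3 array.
#' @export
writeFundus <- function(path, fundus) {
  arr <- if (is(fundus, "FundusImage")) imageData(fundus) else fundus
  a <- array(0, dim = c(dim(arr)[2], dim(arr)[1], 3))
  for (k in 1:3) a[, , k] <- t(arr[, , k])
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Write and read binary masks as PNG
#'
#' 8-bit lossless round trip: a written mask reads back identically.
#'
#' @param path PNG file.
#' @param mask logical matrix.
#' @return `readMask` returns a logical matrix.
#' @export
writeMask <- function(path, mask) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3) a <- a[, , 1]
  t(a) > 0.5
}

#' Read a grade-labels CSV
#'
#' Schema `filename, grade`. Rows labeled `"ungradable"` are read, then
#' excluded with a message reporting the count; any other label outside the
#' five HR grades is an error.
#'
#' @param path CSV file.
#' @return data.frame with gradable rows only.
#' @export
readLabels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("filename", "grade") %in% names(df)))
    stop("labels CSV must have columns 'filename' and 'grade'")
  bad <- !df$grade %in% hrGrades(withUngradable = TRUE)
  if (any(bad))
    stop(sprintf("unknown grade label(s): %s",
                 paste(unique(df$grade[bad]), collapse = ", ")))
  un <- df$grade == "ungradable"
  if (any(un))
    message(sprintf("excluded %d ungradable image(s)", sum(un)))
  df[!un, , drop = FALSE]
}

#' Resize an image array
#'
#' Bilinear resize to the working dimensions (width x height in pixels).
#'
#' @param arr H x W x 3 array or H x W matrix.
#' @param width,height target size (default 300 x 250, the working size).
#' @return resized array/matrix.
#' @export
resizeImage <- function(arr, width = 300L, height = 250L) {
  if (is.matrix(arr))
    return(t(as.matrix(EBImage::resize(EBImage::Image(t(arr)),
                                       w = width, h = height))))
  out <- array(0, dim = c(height, width, 3))
  for (k in 1:3)
    out[, , k] <- t(as.matrix(EBImage::resize(EBImage::Image(t(arr[, , k])),
                                              w = width, h = height)))
  clip01(out)
}

#' Pipeline configuration
#'
#' A serializable configuration for [runPipeline()]; [readPipelineConfig()]
#' and [writePipelineConfig()] round-trip it through YAML.
#'
#' @param ... overrides of the defaults (see the return value).
#' @return named list of class `"pipelineConfig"` with entries `seed`,
#'   `lambda` (enhancement sampling parameter), `segmentation` (list:
#'   `depth`, `base_channels`, `epochs`, `learning_rate`, `threshold`),
#'   `classifier` (`"improved_svm"`, `"improved_knn"`, `"svm:<kind>"` or
#'   `"knn:<kind>"`), `cv_k`, `image_size` (`c(height, width)`) and
#'   `output_dir` (`NA` for no artifacts).
#' @export
pipelineConfig <- function(...) {
  cfg <- list(seed = 1L, lambda = 0.2,
              segmentation = list(depth = 2L, base_channels = 8L,
                                  epochs = 20L, learning_rate = 1e-2,
                                  threshold = 0.5),
              classifier = "improved_svm", cv_k = 5L,
              image_size = c(64L, 64L), output_dir = NA_character_)
  over <- list(...)
  cfg <- modifyList(cfg, over)
  structure(cfg, class = "pipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

#' @rdname pipelineConfig
#' @param config a `pipelineConfig`.
#' @export
writePipelineConfig <- function(path, config) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Parse a classifier name into a spec
#'
#' Accepts `"improved_svm"`, `"improved_knn"`, `"svm:<kind>"` and
#' `"knn:<kind>"`.
#'
#' @param name classifier name string.
#' @return a `classifierSpec`.
#' @export
classifierSpecFromName <- function(name) {
  if (name %in% c("improved_svm", "improved_knn"))
    return(improvedVariant(name))
  if (startsWith(name, "svm:")) return(svmVariant(sub("^svm:", "", name)))
  if (startsWith(name, "knn:")) return(knnVariant(sub("^knn:", "", name)))
  stop(sprintf("unknown classifier '%s'", name))
}
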