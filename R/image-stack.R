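# The universal carrier between stages: a 3-D array of CT numbers plus the
# geometry metadata every measurement needs.

#' Image stack
#'
#' A stack of reconstructed axial CT images in Hounsfield units with its
#' geometry. `data` is indexed `[row, col, slice]` with row 1 at the top of
#' the image; physical coordinates are mm from the image centre, x right,
#' y up.
#'
#' @param data 3-D numeric array `[row, col, slice]` (a matrix is promoted to
#'   a single-slice stack).
#' @param pixel_spacing in-plane pixel spacing in mm.
#' @param slice_thickness slice thickness in mm.
#' @return an `image_stack` object.
#' @export
image_stack <- function(data, pixel_spacing, slice_thickness = 0.5) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a [row, col, slice] array", call. = FALSE)
  }
  if (dim(data)[1] != dim(data)[2]) {
    stop("only square in-plane matrices are supported", call. = FALSE)
  }
  stopifnot_scalar(pixel_spacing, "pixel_spacing", positive = TRUE)
  stopifnot_scalar(slice_thickness, "slice_thickness", positive = TRUE)
  structure(
    list(data = data, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d px, %d slice(s), %g mm/px, slice %g mm\n",
    d[1], d[2], d[3], x$pixel_spacing, x$slice_thickness))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Number of slices in a stack
#' @param stack an [image_stack()].
#' @return integer slice count.
#' @export
n_slices <- function(stack) dim(stack$data)[3]

#' Write an image stack as a raw array plus YAML sidecar
#'
#' Stores the HU array as little-endian float64 (`<prefix>.raw`) and the
#' geometry metadata as YAML (`<prefix>.yaml`). The pairing round-trips
#' bit-identically through [read_stack()].
#'
#' @param stack an [image_stack()].
#' @param prefix file path without extension.
#' @return `prefix`, invisibly.
#' @export
write_stack <- function(stack, prefix) {
  if (!inherits(stack, "image_stack")) {
    stop("`stack` must be an image_stack", call. = FALSE)
  }
  d <- dim(stack$data)
  meta <- list(
    format = "phantomiq-raw-v1",
    dtype = "float64",
    byte_order = "little",
    rows = d[1], cols = d[2], slices = d[3],
    pixel_spacing_mm = stack$pixel_spacing,
    slice_thickness_mm = stack$slice_thickness
  )
  yaml::write_yaml(meta, paste0(prefix, ".yaml"))
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.vector(stack$data), con, size = 8L, endian = "little")
  invisible(prefix)
}

#' Read an image stack written by [write_stack()]
#'
#' @param prefix file path without extension (or the `.yaml` sidecar path).
#' @return an [image_stack()].
#' @export
read_stack <- function(prefix) {
  prefix <- sub("\\.(yaml|raw)$", "", prefix)
  yml <- paste0(prefix, ".yaml")
  raw <- paste0(prefix, ".raw")
  if (!file.exists(yml)) {
    stop(sprintf("missing sidecar metadata '%s'", yml), call. = FALSE)
  }
  if (!file.exists(raw)) {
    stop(sprintf("missing raw array '%s'", raw), call. = FALSE)
  }
  meta <- yaml::read_yaml(yml)
  need <- c("rows", "cols", "slices", "pixel_spacing_mm",
            "slice_thickness_mm")
  if (!all(need %in% names(meta))) {
    stop(sprintf("sidecar '%s' lacks fields: %s", yml,
                 paste(setdiff(need, names(meta)), collapse = ", ")),
         call. = FALSE)
  }
  n <- meta$rows * meta$cols * meta$slices
  con <- file(raw, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "double", n = n, size = 8L, endian = "little")
  if (length(v) != n) {
    stop(sprintf("'%s' holds %d values, sidecar promises %d", raw,
                 length(v), n), call. = FALSE)
  }
  image_stack(array(v, dim = c(meta$rows, meta$cols, meta$slices)),
              pixel_spacing = meta$pixel_spacing_mm,
              slice_thickness = meta$slice_thickness_mm)
}

#' Load an image stack from disk
#'
#' Accepts a raw + YAML pair written by [write_stack()], given either as the
#' common path prefix, the `.yaml` sidecar, or a directory containing exactly
#' one such pair. DICOM series are not supported by this build and are
#' rejected with a message.
#'
#' @param path prefix, sidecar path, or directory.
#' @return an [image_stack()].
#' @export
load_stack <- function(path) {
  if (dir.exists(path)) {
    if (length(list.files(path, pattern = "\\.dcm$", ignore.case = TRUE))) {
      stop("DICOM series input is not supported; convert the series to the ",
           "raw + YAML stack format (see write_stack())", call. = FALSE)
    }
    ymls <- list.files(path, pattern = "\\.yaml$", full.names = TRUE)
    if (length(ymls) != 1L) {
      stop(sprintf(
        "directory '%s' must hold exactly one raw + YAML stack (found %d)",
        path, length(ymls)), call. = FALSE)
    }
    return(read_stack(ymls))
  }
  read_stack(path)
}

#' Serialize a phantom specification to YAML
#' @param spec a [phantom_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  if (!inherits(spec, "phantom_spec")) {
    stop("`spec` must be a phantom_spec", call. = FALSE)
  }
  x <- list(
    grid = list(matrix_size = spec$grid$matrix_size,
                field_of_view = spec$grid$field_of_view,
                slice_thickness = spec$grid$slice_thickness),
    background_hu = spec$background_hu,
    body_diameter_mm = spec$body_diameter_mm,
    blur_sigma_mm = spec$blur_sigma_mm,
    n_slices = spec$n_slices,
    noise = list(sigma_hu = spec$noise$sigma_hu,
                 texture = spec$noise$texture,
                 correlation_length_mm = spec$noise$correlation_length_mm,
                 seed = spec$noise$seed,
                 target_curve = if (!is.null(spec$noise$target_curve)) {
                   as.list(spec$noise$target_curve)
                 }),
    inserts = lapply(spec$inserts, function(i) {
      list(center = i$center, diameter = i$diameter,
           contrast_hu = i$contrast_hu, label = i$label)
    })
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a phantom specification from YAML
#' @param path file written by [write_phantom_spec()] (or hand-authored with
#'   the same fields).
#' @return a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  tc <- x$noise$target_curve
  phantom_spec(
    grid = grid_spec(x$grid$matrix_size, x$grid$field_of_view,
                     x$grid$slice_thickness %||% 0.5),
    background_hu = x$background_hu %||% 0,
    inserts = lapply(x$inserts, function(i) {
      disk_insert(unlist(i$center), i$diameter, i$contrast_hu,
                  i$label %||% "insert")
    }),
    blur_sigma_mm = x$blur_sigma_mm %||% 0,
    noise = noise_model(x$noise$sigma_hu %||% 0,
                        x$noise$texture %||% "white",
                        correlation_length_mm = x$noise$correlation_length_mm,
                        target_curve = if (!is.null(tc)) as.data.frame(tc),
                        seed = x$noise$seed %||% 1L),
    n_slices = x$n_slices %||% 1L,
    body_diameter_mm = x$body_diameter_mm %||% 200
  )
}
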