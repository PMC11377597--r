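#' Construct an image volume
#'
#' A light container for a 3-D scalar grid on a common analysis space:
#' a numeric array plus voxel sizes in mm and a free-text space tag. All
#' pipeline stages operate on `image_volume` objects and refuse volumes
#' that are not on the same grid (see [assert_same_grid()]); registration
#' is an upstream concern and is never performed here.
#'
#' Missing voxels are encoded as `NA` and are excluded from every mask,
#' mean and count downstream.
#'
#' @param data 3-D numeric array.
#' @param voxel_size_mm numeric triple of strictly positive voxel sizes
#'   (x, y, z) in mm.
#' @param space free-text identifier of the common space.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size_mm = c(2, 2, 2), space = "synthetic-common") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("image_volume: data must be a 3-D array, got ", length(dim(data)), " dims")
  if (any(dim(data) < 1L))
    stop("image_volume: all three dimensions must be >= 1")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    stop("image_volume: voxel sizes must be three strictly positive reals")
  storage.mode(data) <- "double"
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, space = as.character(space)[1]),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, space '%s'\n",
              d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3], x$space))
  v <- x$data[is.finite(x$data)]
  if (length(v))
    cat(sprintf("  finite voxels: %d; range [%.4g, %.4g]\n", length(v), min(v), max(v)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Read a 3-D NIfTI-1 volume
#'
#' Reads a `.nii` / `.nii.gz` file into an [image_volume()]. Voxel sizes are
#' taken from the header. 4-D files are rejected here: PET frame series go
#' through [average_frames()] after loading each frame individually.
#'
#' @param path path to a NIfTI-1 file.
#' @param space space tag to attach; defaults to the file path's basename.
#' @return An `image_volume`.
#' @export
load_volume <- function(path, space = NULL) {
  if (!file.exists(path))
    stop("load_volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("load_volume: ", path, " is ", length(d),
         "-D; only 3-D volumes are accepted here. For 4-D PET frame series, ",
         "load frames individually and combine with average_frames().")
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("load_volume: non-positive voxel size in header of ", path)
  image_volume(array(as.numeric(img), dim = d), voxel_size_mm = pd,
               space = if (is.null(space)) basename(path) else space)
}

#' Write an image volume as NIfTI-1
#'
#' @param vol an [image_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assert two volumes share one grid
#'
#' Passes iff the dimensions match exactly and the voxel sizes agree within
#' 1e-3 mm per axis. Every downstream operation consuming two volumes calls
#' this first; mismatched grids never reach a statistic.
#'
#' @param a,b `image_volume` objects.
#' @param tol_mm voxel-size tolerance in mm.
#' @return `TRUE` invisibly, or an error listing both shapes.
#' @export
assert_same_grid <- function(a, b, tol_mm = 1e-3) {
  stopifnot(inherits(a, "image_volume"), inherits(b, "image_volume"))
  da <- dim(a$data); db <- dim(b$data)
  if (!identical(da, db))
    stop("grid mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  if (any(abs(a$voxel_size_mm - b$voxel_size_mm) > tol_mm))
    stop("voxel size mismatch: (", paste(signif(a$voxel_size_mm, 6), collapse = ", "),
         ") vs (", paste(signif(b$voxel_size_mm, 6), collapse = ", "), ") mm")
  invisible(TRUE)
}

#' Binarize a volume into a logical mask
#'
#' Masks are defined as value > 0.5 on integer or probability volumes;
#' `NA` voxels are excluded (FALSE).
#'
#' @param vol an `image_volume` or a numeric/logical array.
#' @return A logical 3-D array.
#' @export
as_mask <- function(vol) {
  x <- if (inherits(vol, "image_volume")) vol$data else vol
  if (is.logical(x)) { x[is.na(x)] <- FALSE; return(x) }
  m <- !is.na(x) & x > 0.5
  m
}

#' Construct an integer label atlas
#'
#' @param labels 3-D non-negative integer array; 0 = background.
#' @param name_table named character vector or data.frame mapping every
#'   nonzero label to a region name.
#' @param voxel_size_mm voxel sizes (mm).
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, name_table, voxel_size_mm = c(2, 2, 2)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("label_atlas: labels must be 3-D")
  if (any(labels < 0, na.rm = TRUE) || any(labels != round(labels), na.rm = TRUE))
    stop("label_atlas: labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  if (is.data.frame(name_table))
    name_table <- stats::setNames(as.character(name_table[[2]]), name_table[[1]])
  present <- sort(unique(labels[labels > 0L & !is.na(labels)]))
  missing_lab <- setdiff(as.character(present), names(name_table))
  if (length(missing_lab))
    stop("label_atlas: labels without a name: ", paste(missing_lab, collapse = ", "))
  structure(list(labels = labels, name_table = name_table,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %s voxels, %d regions\n",
              paste(dim(x$labels), collapse = "x"),
              length(x$name_table)))
  invisible(x)
}

# internal: image_volume view of atlas for grid checks
.atlas_as_volume <- function(atlas) {
  image_volume(array(as.numeric(atlas$labels), dim = dim(atlas$labels)),
               voxel_size_mm = atlas$voxel_size_mm, space = "atlas")
}

#' Load a subject covariate table
#'
#' Reads a CSV (header row, UTF-8) of per-subject demographics and
#' acquisition covariates and validates the fields each group requires.
#' Required for every row: `subject_id`, `group` (control/athlete), `age`
#' (years, > 0), `tiv` (mL, > 0). Athletes must additionally carry
#' `scanner` (PETCT or HRRT) and `scan_window` (W80_100 or W80_90).
#' Unknown columns are preserved as auxiliary fields.
#'
#' @param path CSV path.
#' @return A validated `data.frame`, one row per subject.
#' @export
load_subject_table <- function(path) {
  if (!file.exists(path)) stop("load_subject_table: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_subjects(df)
}

#' Validate a subject table already in memory
#'
#' @param df data.frame of subject records.
#' @return `df` with typed columns, or an error naming row and column.
#' @export
validate_subjects <- function(df) {
  req <- c("subject_id", "group", "age", "tiv")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("subject table: missing required column(s): ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("subject table: duplicate subject_id values")
  if (!all(df$group %in% c("control", "athlete")))
    stop("subject table: group must be 'control' or 'athlete'")
  for (col in c("age", "tiv")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad))
      stop("subject table: row ", bad[1], ", column '", col,
           "': must be a positive number, got '", df[[col]][bad[1]], "'")
    df[[col]] <- v
  }
  ath <- df$group == "athlete"
  if (any(ath)) {
    for (col in c("scanner", "scan_window")) {
      if (!col %in% names(df))
        stop("subject table: athletes require column '", col, "'")
      bad <- which(ath & (is.na(df[[col]]) | df[[col]] == ""))
      if (length(bad))
        stop("subject table: row ", bad[1], ": athlete missing '", col, "'")
    }
    if (!all(df$scanner[ath] %in% c("PETCT", "HRRT")))
      stop("subject table: scanner must be PETCT or HRRT")
    if (!all(df$scan_window[ath] %in% c("W80_100", "W80_90")))
      stop("subject table: scan_window must be W80_100 or W80_90")
  }
  df
}
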