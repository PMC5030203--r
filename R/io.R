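#' Read and write frame-resolution TAC tables
#'
#' TAC tables are plain CSV with header columns `frame_start_s`,
#' `frame_end_s`, `value` (comma separator, `.` decimal, UTF-8). On reading,
#' the file's frame timing must match the supplied schedule to within 1e-6 s;
#' mismatches are an error, never silently coerced.
#'
#' @param path CSV file path.
#' @param schedule The [frame_schedule()] the table is expected to match.
#' @param x A [tac()] to write.
#' @return `read_tac_table()` returns a [tac()] bound to `schedule`;
#'   `write_tac_table()` returns `path` invisibly.
#' @export
read_tac_table <- function(path, schedule, units = "Bq/mL") {
  assert_schedule(schedule)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_start_s", "frame_end_s", "value")
  if (!all(need %in% names(df))) {
    stop("TAC table must have columns ", paste(need, collapse = ", "))
  }
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v)) stop("non-numeric values in column ", col)
    if (anyNA(v) || !all(is.finite(v))) stop("non-finite values in column ", col)
  }
  if (nrow(df) != nrow(schedule)) {
    stop("TAC table has ", nrow(df), " rows but the schedule has ",
      nrow(schedule), " frames")
  }
  if (max(abs(df$frame_start_s - schedule$start_s)) > 1e-6 ||
    max(abs(df$frame_end_s - schedule$end_s)) > 1e-6) {
    stop("TAC table frame timing does not match the schedule")
  }
  tac(schedule, df$value, units = units)
}

#' @rdname read_tac_table
#' @param units Units label attached on reading / recorded implicitly on writing.
#' @export
write_tac_table <- function(x, path) {
  if (!is_tac(x)) stop("expected a tac")
  utils::write.csv(
    data.frame(frame_start_s = x$start_s, frame_end_s = x$end_s, value = x$value),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Read and write blood curves as CSV
#'
#' Blood curves are stored as CSV with columns `time_s`, `activity_bq_ml`.
#'
#' @param path CSV file path.
#' @param curve A [blood_curve()] to write.
#' @inheritParams blood_curve
#' @return `read_blood_curve()` returns a [blood_curve()];
#'   `write_blood_curve()` returns `path` invisibly.
#' @export
read_blood_curve <- function(path, tracer = NULL, calibrated = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "activity_bq_ml")
  if (!all(need %in% names(df))) {
    stop("blood curve CSV must have columns ", paste(need, collapse = ", "))
  }
  for (col in need) {
    if (!is.numeric(df[[col]])) stop("non-numeric values in column ", col)
    if (anyNA(df[[col]]) || !all(is.finite(df[[col]]))) {
      stop("non-finite values in column ", col)
    }
  }
  blood_curve(df$time_s, df$activity_bq_ml, tracer = tracer, calibrated = calibrated)
}

#' @rdname read_blood_curve
#' @export
write_blood_curve <- function(curve, path) {
  if (!is_blood_curve(curve)) stop("expected a blood_curve")
  utils::write.csv(
    data.frame(time_s = curve$time_s, activity_bq_ml = curve$activity),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers over RNifti for parametric maps and label volumes. Voxel
#' dimensions (mm) are recorded in the header.
#'
#' @param vol A 3D numeric array.
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param voxel_mm Length-3 voxel size in mm.
#' @return `read_volume()` returns a plain 3D array with a `voxel_mm`
#'   attribute; `write_volume()` returns `path` invisibly.
#' @export
write_volume <- function(vol, path, voxel_mm = c(2.036, 2.036, 2.0)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_mm") <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  out
}
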