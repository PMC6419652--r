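#' Write a 3-D image to NIfTI-1
#'
#' Millimetre voxel spacing goes in the header pixdim; axis 3 is
#' cranio-caudal.
#'
#' @param image a \code{\link{phantom_image}}.
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "phantom_image"))
  img <- RNifti::asNifti(image$values)
  RNifti::pixdim(img) <- image$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D NIfTI image
#'
#' @param path input path.
#' @return A \code{\link{phantom_image}}.
#' @export
read_image <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  if (length(dim(vals)) != 3L) stop("expected a 3-D image: ", path)
  phantom_image(vals, RNifti::pixdim(img)[1:3])
}

#' Write a respiratory trace to CSV
#'
#' Header is \code{time_s,amplitude_mm}.
#'
#' @param trace a \code{\link{respiratory_trace}}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "respiratory_trace"))
  df <- data.frame(time_s = trace$times_s, amplitude_mm = trace$amplitudes_mm)
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a respiratory trace from CSV
#'
#' Validates the header and strict time monotonicity, naming the offending
#' row on failure.
#'
#' @param path input path.
#' @return A \code{\link{respiratory_trace}}.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_mm") %in% names(df)))
    stop("trace CSV must have header time_s,amplitude_mm")
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop("trace times not strictly increasing at row ", bad[1] + 1L)
  respiratory_trace(df$time_s, df$amplitude_mm)
}

# Serialize numeric columns at 9 significant digits for stable diffs.
format_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 9, format = "g")
  df
}

#' Write a data table as CSV (9 significant digits)
#'
#' @param df data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a data table written by \code{\link{write_table}}
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_table <- function(path) utils::read.csv(path, check.names = FALSE)

#' Load a run configuration from YAML
#'
#' Fields missing from the file fall back to \code{\link{default_config}}
#' values.
#'
#' @param path YAML file.
#' @return A config list (see \code{\link{default_config}}).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' Write a run configuration to YAML
#'
#' @param config config list.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
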