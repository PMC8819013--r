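# DiffractionMovie: the common currency of both pipelines -- a 3-D stack of
# photon counts with the exposure time attached.

#' Diffraction movie container
#'
#' @param counts 3-D numeric array `(rows, cols, frames)` of photon counts.
#' @param exposure Exposure time per frame, s.
#' @return An object of class `diffraction_movie`.
#' @export
diffraction_movie <- function(counts, exposure) {
  if (!is.array(counts) || length(dim(counts)) != 3L) {
    stop("`counts` must be a 3-D array (rows, cols, frames)", call. = FALSE)
  }
  if (!is.numeric(exposure) || exposure <= 0) {
    stop("`exposure` must be a positive time in seconds", call. = FALSE)
  }
  structure(list(counts = counts, exposure = exposure), class = "diffraction_movie")
}

#' @export
print.diffraction_movie <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<diffraction_movie> %d x %d px, %d frames @ %g s (total %g counts)\n",
    d[1], d[2], d[3], x$exposure, sum(x$counts)
  ))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie A [diffraction_movie()].
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$counts)[3]

#' Extract one frame
#' @param movie A [diffraction_movie()].
#' @param i Frame index.
#' @return Numeric matrix.
#' @export
movie_frame <- function(movie, i) movie$counts[, , i]
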