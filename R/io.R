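#' Homography JSON I/O
#'
#' Reads/writes a homography as a row-major 3x3 JSON array, the exchange
#' format used by the command-line tools.
#'
#' @param H [homography] (or 3x3 matrix).
#' @param path JSON file path.
#' @return [homography] (reader) or `path` invisibly (writer).
#' @export
write_homography <- function(H, path) {
  H <- unclass(homography(H))
  jsonlite::write_json(lapply(1:3, function(i) H[i, ]), path, digits = NA)
  invisible(path)
}

#' @rdname write_homography
#' @export
read_homography <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(m)) m <- do.call(rbind, m)
  homography(m)
}

#' Write a registration result bundle
#'
#' Writes the standard result set of one registration: the homography
#' (`homography.json`), the per-epoch loss trace (`loss_trace.csv`), the
#' warped moving image (`warped.png`) and a green/magenta blend with the
#' fixed image (`blend.png`).
#'
#' @param fit [register_homography()] result.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_registration_bundle <- function(fit, dir) {
  stopifnot(inherits(fit, "flim_registration"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_homography(fit$H, file.path(dir, "homography.json"))
  utils::write.csv(data.frame(epoch = seq_along(fit$loss_trace),
                              ppm_l1 = fit$loss_trace),
                   file.path(dir, "loss_trace.csv"), row.names = FALSE)
  write_image(fit$warped, file.path(dir, "warped.png"))
  write_image(blend_images(fit$warped, fit$fixed, "greyscale"),
              file.path(dir, "blend.png"))
  invisible(dir)
}
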