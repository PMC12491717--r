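# Text dialect for particle outline detections: one detection per line,
# tab-separated fields — frame_id, confidence, then the vertex coordinates
# x1 y1 ... xn yn in pixels. Lines starting with '#' are comments. Chosen
# for diff-ability and streaming parsing; the format a segmentation model
# exporting "predicted outlines" to text would use.

#' Write particle outlines to a text file
#'
#' Confidence is written with 6 decimals and vertex coordinates with 2
#' decimals; [read_outline_file()] reproduces them exactly at that
#' precision.
#'
#' @param detections an `outline_set` or list of [particle_outline()]s.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_outline_file <- function(detections, path) {
  lines <- vapply(detections, function(d) {
    paste(c(d$frame_id, sprintf("%.6f", d$confidence),
            sprintf("%.2f", as.vector(t(d$outline)))), collapse = "\t")
  }, "")
  writeLines(c("# pelletscope outlines v1", lines), path)
  invisible(path)
}

#' Read particle outlines from a text file
#'
#' @param path input path in the outline dialect (see
#'   [write_outline_file()]).
#' @param source source tag stored on the outlines (default `"external"`).
#' @return an `outline_set`.
#' @export
read_outline_file <- function(path, source = "external") {
  lines <- readLines(path)
  dets <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    parts <- strsplit(raw, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 8L)
      stop_parse("line ", ln, ": expected frame_id, confidence and at ",
                 "least 3 vertices (8+ fields), got ", length(parts))
    conf <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(conf))
      stop_parse("line ", ln, ": confidence '", parts[2L], "' is not numeric")
    if (conf < 0 || conf > 1)
      stop_validation("line ", ln, ": confidence ", conf, " outside [0, 1]")
    coords <- suppressWarnings(as.numeric(parts[-(1:2)]))
    if (any(is.na(coords)))
      stop_parse("line ", ln, ": non-numeric coordinate")
    if (length(coords) %% 2L != 0L)
      stop_parse("line ", ln, ": odd number of coordinates")
    dets[[length(dets) + 1L]] <- particle_outline(
      parts[1L], matrix(coords, ncol = 2L, byrow = TRUE),
      confidence = conf, source = source)
  }
  outline_set(dets)
}
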