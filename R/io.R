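#' Write and read display images as PNG
#'
#' @param display a \code{crt_display}.
#' @param path file path.
#' @return \code{write_display_png} returns the path invisibly;
#'   \code{read_display_png} returns the H x W x 3 pixel array.
#' @export
write_display_png <- function(display, path) {
  png::writePNG(display$pixels, path)
  invisible(path)
}

#' @rdname write_display_png
#' @export
read_display_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3]
  px
}

#' Write trial traces to a long-format CSV
#'
#' One row per trial step: trial index, condition code, step, hand row
#' and column, speed, gate, and the velocity readout peak.
#'
#' @param x a \code{crt_experiment}, or a list of \code{crt_trace}.
#' @param path output CSV path.
#' @export
write_traces_csv <- function(x, path) {
  traces <- if (inherits(x, "crt_experiment")) x$traces else x
  rows <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    k <- length(tr$speeds)
    data.frame(trial = i, code = tr$code, step = seq_len(k),
               hand_row = tr$positions[-1, 1][seq_len(k)],
               hand_col = tr$positions[-1, 2][seq_len(k)],
               speed = tr$speeds, gate = tr$gate,
               peak_vel_activation = tr$peak_vel,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write the condition summary to CSV
#'
#' @param x a \code{crt_experiment} or a summary data frame.
#' @param path output CSV path.
#' @export
write_summary_csv <- function(x, path) {
  s <- if (inherits(x, "crt_experiment")) x$summary else x
  utils::write.csv(s, path, row.names = FALSE)
  invisible(path)
}

#' Write a batch manifest to CSV
#'
#' @param batch result of \code{\link{crt_batch}}.
#' @param path output CSV path.
#' @param image_dir optional directory; when given, each display is also
#'   written as \code{<code>.png} there and the manifest gains the path.
#' @export
write_manifest_csv <- function(batch, path, image_dir = NULL) {
  man <- batch$manifest
  if (!is.null(image_dir)) {
    dir.create(image_dir, showWarnings = FALSE, recursive = TRUE)
    codes <- unique(man$code)
    for (code in codes)
      write_display_png(batch$displays[[match(code, man$code)]],
                        file.path(image_dir, paste0(code, ".png")))
    man$image_path <- file.path(image_dir, paste0(man$code, ".png"))
  }
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-condition reference table (CSV)
#'
#' Expected columns: target_size, distractor_config, target_position,
#' il, md -- the format consumed by \code{\link{compare_reference}}.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_reference_csv <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target_size", "distractor_config", "target_position",
            "il", "md")
  if (!all(need %in% names(ref)))
    stop("reference table needs columns: ", paste(need, collapse = ", "))
  ref
}
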