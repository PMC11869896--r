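#' Binarise a display image into a foreground mask
#'
#' The pre-attentive front end first separates items from the uniform
#' background: a pixel is foreground when its colour differs from the
#' background colour by more than a small tolerance (maximum absolute
#' channel difference). No adaptive thresholding is needed because the
#' generator guarantees a uniform background.
#'
#' @param display a \code{crt_display}, or an H x W x 3 pixel array.
#' @param background background RGB; defaults to the standard palette.
#' @param tol foreground tolerance on the channel difference.
#' @return Logical H x W matrix marking item pixels.
#' @export
binarize_display <- function(display,
                             background = crt_config()$palette$background,
                             tol = crt_config()$vision$binarize_tol) {
  px <- if (inherits(display, "crt_display")) display$pixels else display
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 3)
  dev <- pmax(abs(px[, , 1] - background[1]),
              abs(px[, , 2] - background[2]),
              abs(px[, , 3] - background[3]))
  mask <- dev > tol
  if (!any(mask)) stop("no items found (empty foreground)")
  mask
}

#' Extract item descriptions from a binary mask
#'
#' Labels 4-connected components, and measures one item per component:
#' centroid (mean pixel coordinate), pixel area, and mean RGB colour.
#' Items are returned ordered left to right by centroid column.
#'
#' @param mask logical matrix from \code{\link{binarize_display}}.
#' @param display the display the mask came from (for colours).
#' @return Data frame with one row per item: centroid_row, centroid_col,
#'   area, and the mean colour channels r, g, b.
#' @export
extract_items <- function(mask, display) {
  px <- if (inherits(display, "crt_display")) display$pixels else display
  lab <- EBImage::bwlabel(mask * 1L)
  n <- max(lab)
  if (n != 3)
    stop("unexpected item count: found ", n, " connected components, need 3")
  rows <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  cols <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  items <- do.call(rbind, lapply(seq_len(n), function(k) {
    sel <- lab == k
    data.frame(centroid_row = mean(rows[sel]),
               centroid_col = mean(cols[sel]),
               area = sum(sel),
               r = mean(px[, , 1][sel]),
               g = mean(px[, , 2][sel]),
               b = mean(px[, , 3][sel]))
  }))
  items[order(items$centroid_col), , drop = FALSE]
}

#' Classify extracted items and reconstruct the condition code
#'
#' The unique odd-coloured item is the target; the other two are
#' distractors. Sizes are classified by comparing areas: when two area
#' clusters exist, each area is compared with the midpoint of the min and
#' max area (equality tolerance \code{size_tol}); when all three areas are
#' equal within tolerance, the shared area is compared with the absolute
#' split \code{area_split} (defaults to the midpoint of the rendered small
#' and large disc areas), which disambiguates the all-small from the
#' all-large displays.
#'
#' @param items data frame from \code{\link{extract_items}} (ordered
#'   left to right).
#' @param size_tol area tolerance (pixels) for treating areas as equal.
#' @param area_split absolute area above which an item is "large", used
#'   only when all items share one size.
#' @param colour_tol tolerance for treating two item colours as equal.
#' @return List: \code{code} (reconstructed condition string),
#'   \code{roles} ("target"/"distractor" per item), \code{size_classes}
#'   ("small"/"large" per item), \code{target_position} (1..3).
#' @export
classify_items <- function(items,
                           size_tol = crt_config()$vision$size_tol,
                           area_split = crt_config()$vision$area_split,
                           colour_tol = 0.1) {
  if (nrow(items) != 3) stop("need exactly 3 items")
  cols <- as.matrix(items[, c("r", "g", "b")])
  same <- function(i, j) max(abs(cols[i, ] - cols[j, ])) <= colour_tol
  s12 <- same(1, 2); s13 <- same(1, 3); s23 <- same(2, 3)
  odd <- if (s12 && !s13 && !s23) 3L else
    if (s13 && !s12 && !s23) 2L else
      if (s23 && !s12 && !s13) 1L else NA_integer_
  if (is.na(odd))
    stop("oddity violated: item colours are all equal or all distinct")
  a <- items$area
  large <- if (max(a) - min(a) <= size_tol) {
    rep(mean(a) > area_split, 3)      # one size class: absolute fallback
  } else {
    a > (min(a) + max(a)) / 2
  }
  letters3 <- ifelse(seq_len(3) == odd,
                     ifelse(large, "T", "t"),
                     ifelse(large, "D", "d"))
  list(code = paste(letters3, collapse = ""),
       roles = ifelse(seq_len(3) == odd, "target", "distractor"),
       size_classes = ifelse(large, "large", "small"),
       target_position = odd)
}

#' Assign per-item saliency levels from the level table
#'
#' Each item's saliency is a tuned lookup by its code letter. The default
#' table encodes the similarity-grouping ordering
#' small target (5.0) > large target (4.8) > small distractor (4.6) >
#' large distractor (4.4); tables violating this ordering are allowed for
#' experimentation but trigger a warning.
#'
#' @param code condition code.
#' @param level_table named numeric vector over \{t, T, d, D\}.
#' @return Numeric length-3 vector of levels (left, middle, right).
#' @examples
#' assign_saliency("ddT")   # 4.6 4.6 4.8
#' @export
assign_saliency <- function(code, level_table = crt_config()$levels) {
  letters3 <- parse_code(code)
  stopifnot(all(c("t", "T", "d", "D") %in% names(level_table)))
  if (!(level_table[["t"]] > level_table[["T"]] &&
        level_table[["T"]] > level_table[["d"]] &&
        level_table[["d"]] > level_table[["D"]]))
    warning("saliency table violates the ordering t > T > d > D")
  unname(level_table[letters3])
}

#' Movement-onset scaling factor from distractor proximity grouping
#'
#' The factor depends only on the distractor size pair (dd, Dd/dD, DD),
#' never on target size or position; it later scales the movement onset
#' delay, coupling proximity grouping to initiation latency.
#'
#' @param code condition code.
#' @param factor_table named numeric vector over \{dd, Dd, DD\}; the
#'   mirrored arrangement dD shares the Dd entry.
#' @return Scalar scaling factor.
#' @examples
#' proximity_scaling("ddT")                       # 0.125 (tuned table)
#' proximity_scaling("DDt", c(dd = 0.35, Dd = 0.2, DD = 0))  # 0
#' @export
proximity_scaling <- function(code, factor_table = crt_config()$factors) {
  unname(factor_table[[distractor_pair(code)]])
}

#' Full pre-attentive parse of a display image
#'
#' Runs binarisation, connected-component extraction, odd-colour/size
#' classification, saliency assignment and proximity scaling in one call:
#' the complete visual processing front end.
#'
#' @param display a \code{crt_display} or pixel array.
#' @param config a \code{crt_config}.
#' @return List: \code{items} (left-to-right data frame), \code{code},
#'   \code{target_position}, \code{levels} (per item), \code{s_prox}.
#' @examples
#' parse_display(crt_display("ddT"))$levels   # 4.6 4.6 4.8
#' @export
parse_display <- function(display, config = crt_config()) {
  mask <- binarize_display(display, config$palette$background,
                           config$vision$binarize_tol)
  items <- extract_items(mask, display)
  cls <- classify_items(items, config$vision$size_tol,
                        config$vision$area_split)
  list(items = cbind(items, role = cls$roles,
                     size_class = cls$size_classes),
       code = cls$code,
       target_position = cls$target_position,
       levels = assign_saliency(cls$code, config$levels),
       s_prox = proximity_scaling(cls$code, config$factors))
}
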