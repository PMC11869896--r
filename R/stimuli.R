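#' Enumerate the 24 display condition codes
#'
#' A condition code is a three-letter string over \{t, T, d, D\}, one letter
#' per item position (left, middle, right). Letter identity encodes the
#' role (t/T target, d/D distractor) and case encodes size (lower = small,
#' upper = large). The full design crosses target position (3) x target
#' size (2) x distractor arrangement \{dd, Dd, dD, DD\} (4) = 24 displays;
#' both left-right arrangements of mixed distractors are included.
#'
#' @return Character vector of 24 unique codes in canonical order
#'   (target position, then target size, then distractor arrangement).
#' @examples
#' codes <- crt_codes()
#' length(codes)        # 24
#' "ddT" %in% codes     # TRUE
#' @export
crt_codes <- function() {
  arrangements <- c("dd", "Dd", "dD", "DD")
  out <- character(0)
  for (pos in 1:3) {
    for (tsize in c("t", "T")) {
      for (arr in arrangements) {
        letters3 <- character(3)
        letters3[pos] <- tsize
        letters3[-pos] <- strsplit(arr, "")[[1]]
        out <- c(out, paste(letters3, collapse = ""))
      }
    }
  }
  out
}

## Split a code into per-position letters, with validation.
parse_code <- function(code) {
  if (!is.character(code) || length(code) != 1 || nchar(code) != 3 ||
      grepl("[^tTdD]", code))
    stop("malformed condition code: ", deparse(code),
         " (want 3 letters over {t,T,d,D})")
  letters3 <- strsplit(code, "")[[1]]
  n_target <- sum(letters3 %in% c("t", "T"))
  if (n_target != 1)
    stop("condition code must contain exactly one target letter: ", code)
  letters3
}

## Mirror a code left-right (reverse positions, keep case).
mirror_code <- function(code) {
  paste(rev(parse_code(code)), collapse = "")
}

## Distractor size pair of a code, pooled over arrangement: "dd","Dd","DD".
## Counting avoids locale-dependent letter ordering.
distractor_pair <- function(code) {
  d <- parse_code(code)[!(parse_code(code) %in% c("t", "T"))]
  c("dd", "Dd", "DD")[sum(d == "D") + 1]
}

#' Render a three-item display image from a condition code
#'
#' Items are filled circles on a uniform background, centred on one
#' horizontal row at three fixed columns. The odd-coloured item is the
#' target; size (small/large radius) is the task-irrelevant feature. Item
#' centroids keep a border margin of at least the largest radius plus the
#' half-width of the downstream interaction kernels, so no activation blob
#' is clipped at the lattice border.
#'
#' @param code condition code, an element of \code{\link{crt_codes}}.
#' @param geometry geometry list as in \code{crt_config()$geometry}.
#' @param palette palette list (background/target/distractor RGB in [0,1]).
#' @return An object of class \code{crt_display}: list with \code{pixels}
#'   (H x W x 3 array in [0,1]), \code{config} (symbolic description:
#'   data frame of items plus \code{code} and \code{target_position}).
#' @examples
#' d <- crt_display("ddT")
#' d$config$items$area          # 13 13 29
#' @export
crt_display <- function(code,
                        geometry = crt_config()$geometry,
                        palette = crt_config()$palette) {
  letters3 <- parse_code(code)
  size <- geometry$size
  radii <- ifelse(letters3 %in% c("T", "D"), geometry$r_large,
                  geometry$r_small)
  margin_ok <- function(centre, radius) {
    min(centre - 1, size - centre) >= geometry$margin &&
      min(centre - 1, size - centre) >= radius
  }
  for (k in 1:3) {
    if (!margin_ok(geometry$item_row, radii[k]) ||
        !margin_ok(geometry$item_cols[k], radii[k]))
      stop("geometry violates the border margin rule (item ", k, ")")
  }
  # items must stay 4-disconnected: at least one empty column between discs
  for (k in 1:2) {
    if (diff(geometry$item_cols[k + 0:1]) < radii[k] + radii[k + 1] + 2)
      stop("items ", k, " and ", k + 1,
           " touch or overlap; widen item spacing")
  }
  px <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) px[, , ch] <- palette$background[ch]
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  occupied <- matrix(FALSE, size, size)
  items <- data.frame(
    centroid_row = numeric(3), centroid_col = numeric(3),
    colour_label = character(3), size_class = character(3),
    area = integer(3), stringsAsFactors = FALSE
  )
  for (k in 1:3) {
    mask <- (rows - geometry$item_row)^2 +
      (cols - geometry$item_cols[k])^2 <= radii[k]^2
    if (any(mask & occupied)) stop("items overlap; widen item spacing")
    occupied <- occupied | mask
    is_target <- letters3[k] %in% c("t", "T")
    colr <- if (is_target) palette$target else palette$distractor
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[mask] <- colr[ch]
      px[, , ch] <- plane
    }
    items$centroid_row[k] <- mean(rows[mask])
    items$centroid_col[k] <- mean(cols[mask])
    items$colour_label[k] <- if (is_target) "target_colour" else
      "distractor_colour"
    items$size_class[k] <- if (letters3[k] %in% c("T", "D")) "large" else
      "small"
    items$area[k] <- sum(mask)
  }
  structure(
    list(pixels = px,
         config = list(items = items, code = code,
                       target_position = c("left", "middle",
                                           "right")[which(letters3 %in%
                                                            c("t", "T"))])),
    class = "crt_display")
}

#' @export
print.crt_display <- function(x, ...) {
  cat(sprintf("crt_display '%s' (%dx%d px), target %s\n",
              x$config$code, dim(x$pixels)[1], dim(x$pixels)[2],
              x$config$target_position))
  invisible(x)
}

#' Build a randomised batch of display trials
#'
#' Each set contains every one of the 24 condition codes exactly once, in
#' an order shuffled by the seeded generator; the batch concatenates
#' \code{n_sets} such sets (the reference experiment uses 25 sets = 600
#' trials). Identical seeds give identical batches.
#'
#' @param n_sets number of sets (>= 1).
#' @param seed integer master seed for the shuffle.
#' @param geometry,palette forwarded to \code{\link{crt_display}}.
#' @return List with \code{displays} (list of \code{crt_display}) and
#'   \code{manifest} (data frame: set, trial, code, seed) where
#'   \code{seed} is the derived per-trial seed.
#' @export
crt_batch <- function(n_sets, seed = 1L,
                      geometry = crt_config()$geometry,
                      palette = crt_config()$palette) {
  stopifnot(n_sets >= 1)
  codes <- crt_codes()
  # render each unique code once; displays are deterministic given geometry
  rendered <- lapply(codes, crt_display, geometry = geometry,
                     palette = palette)
  names(rendered) <- codes
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  manifest <- do.call(rbind, lapply(seq_len(n_sets), function(s) {
    data.frame(set = s, trial = seq_along(codes),
               code = sample(codes), stringsAsFactors = FALSE)
  }))
  manifest$seed <- trial_seed(seed, manifest$set, manifest$trial)
  list(displays = rendered[manifest$code], manifest = manifest)
}

## Deterministic per-trial seed derivation: independent trials, one master
## seed, values kept inside 32-bit integer range.
trial_seed <- function(master, set, trial) {
  as.integer((as.numeric(master) * 7919 + set * 104729 + trial * 131) %%
               2147483647)
}
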