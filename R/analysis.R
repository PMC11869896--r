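## Least-squares polynomial fit of a speed series, evaluated on a dense
## grid (step `by`). Degree is capped so the fit is always determined.
fit_speed_curve <- function(speeds, poly_degree = 10, by = 0.01) {
  n <- length(speeds)
  if (n < 2) stop("speed series too short to fit")
  deg <- min(poly_degree, n - 1)
  t <- seq_len(n)
  fit <- stats::lm(speeds ~ stats::poly(t, deg, raw = FALSE))
  tt <- seq(1, n, by = by)
  list(t = tt, y = unname(stats::predict(fit, data.frame(t = tt))))
}

#' Initiation latency from a hand-speed series
#'
#' The speed series is fitted with a least-squares polynomial (degree 10
#' by default, to improve the temporal resolution of the estimate), and
#' the initiation latency is the earliest fractional time at which the
#' fitted curve crosses \code{frac} (default 10\%) of the maximum hand
#' speed of the whole run -- the global maximum across all trials, not the
#' per-trial maximum -- from below.
#'
#' @param speeds per-step hand speed series of one trial.
#' @param global_max_speed maximum fitted hand speed across all trials of
#'   the run.
#' @param poly_degree polynomial degree for the fit.
#' @param frac threshold fraction of the global maximum.
#' @param sustain steps the fitted curve must remain above threshold
#'   after the crossing; a high-degree polynomial oscillates around zero
#'   over long pre-movement stretches, and the sustain requirement
#'   rejects those spurious crossings.
#' @return Initiation latency in (fractional) steps.
#' @export
initiation_latency <- function(speeds, global_max_speed,
                               poly_degree = 10, frac = 0.1,
                               sustain = 5) {
  stopifnot(length(speeds) > 0, global_max_speed > 0)
  thr <- frac * global_max_speed
  fc <- fit_speed_curve(speeds, poly_degree)
  by <- fc$t[2] - fc$t[1]
  hold <- max(1L, round(sustain / by))
  above <- fc$y >= thr
  if (!any(above)) stop("no movement detected: fitted speed never reaches ",
                        signif(thr, 3))
  # candidate upward crossings (or an immediately supra-threshold start)
  cand <- which(c(above[1], !above[-length(above)] & above[-1]))
  for (i in cand) {
    upto <- min(length(above), i + hold - 1L)
    if (all(above[i:upto])) {
      if (i == 1) return(fc$t[1])
      t0 <- fc$t[i - 1]; t1 <- fc$t[i]
      y0 <- fc$y[i - 1]; y1 <- fc$y[i]
      return(t0 + (thr - y0) / (y1 - y0) * (t1 - t0))
    }
  }
  stop("no movement detected: no sustained upward threshold crossing")
}

#' Maximum deviation of a trajectory from the straight reach line
#'
#' Largest unsigned perpendicular distance between trajectory points and
#' the straight line through the start position and the target.
#'
#' @param positions n x 2 matrix of (row, col) hand positions.
#' @param start,target length-2 endpoints of the reference line
#'   (must differ).
#' @return Maximum deviation in pixels.
#' @export
max_deviation <- function(positions, start, target) {
  v <- target - start
  L <- sqrt(sum(v^2))
  if (L == 0) stop("degenerate reference line: start equals target")
  dr <- positions[, 1] - start[1]
  dc <- positions[, 2] - start[2]
  max(abs(dr * v[2] - dc * v[1]) / L)
}

#' Test a speed profile for bell shape (unimodality)
#'
#' Smooths the series with a centred moving average and counts local
#' maxima whose topographic prominence exceeds \code{prominence_frac}
#' times the smoothed range. A profile is bell-shaped when exactly one
#' prominent peak remains.
#'
#' @param speeds per-step speed series.
#' @param smooth_window moving-average window (odd, steps).
#' @param prominence_frac prominence criterion as a fraction of the
#'   smoothed profile's range.
#' @return List: \code{is_unimodal}, \code{peak_time} (step index of the
#'   dominant peak), \code{n_peaks} (count of prominent peaks).
#' @export
bell_shape <- function(speeds, smooth_window = 9, prominence_frac = 0.2) {
  n <- length(speeds)
  if (n < 3) return(list(is_unimodal = FALSE, peak_time = NA, n_peaks = 0L))
  k <- min(smooth_window, if (n %% 2) n else n - 1)
  pad <- (k - 1) / 2
  padded <- c(rep(speeds[1], pad), speeds, rep(speeds[n], pad))
  s <- as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2))
  s <- s[(pad + 1):(pad + n)]
  rng <- max(s) - min(s)
  if (rng <= 0) return(list(is_unimodal = FALSE, peak_time = NA,
                            n_peaks = 0L))
  # collapse ties, then local maxima of the step pattern
  r <- rle(s)
  v <- r$values
  ends <- cumsum(r$lengths)
  m <- length(v)
  if (m == 1) return(list(is_unimodal = FALSE, peak_time = NA,
                          n_peaks = 0L))
  is_peak <- vapply(seq_len(m), function(i) {
    left <- if (i == 1) -Inf else v[i - 1]
    right <- if (i == m) -Inf else v[i + 1]
    v[i] > left && v[i] > right
  }, TRUE)
  peak_idx <- which(is_peak)
  prominence <- vapply(peak_idx, function(i) {
    h <- v[i]
    lmin <- if (i == 1) min(v[1]) else {
      j <- rev(seq_len(i - 1))
      higher <- j[v[j] > h]
      lo <- if (length(higher)) (max(higher) + 1):(i - 1) else seq_len(i - 1)
      min(v[lo])
    }
    rmin <- if (i == m) min(v[m]) else {
      j <- (i + 1):m
      higher <- j[v[j] > h]
      hi <- if (length(higher)) (i + 1):(min(higher) - 1) else (i + 1):m
      min(v[hi])
    }
    h - max(lmin, rmin)
  }, 0)
  prominent <- prominence >= prominence_frac * rng
  n_peaks <- sum(prominent)
  top <- peak_idx[prominent][which.max(v[peak_idx[prominent]])]
  list(is_unimodal = n_peaks == 1L,
       peak_time = if (n_peaks >= 1) ends[top] else NA,
       n_peaks = as.integer(n_peaks))
}

## Decompose a condition code into the factorial design cells.
code_condition <- function(code) {
  letters3 <- parse_code(code)
  tpos <- which(letters3 %in% c("t", "T"))
  data.frame(
    target_size = if (letters3[tpos] == "T") "large" else "small",
    distractor_config = distractor_pair(code),
    target_position = c("left", "middle", "right")[tpos],
    stringsAsFactors = FALSE
  )
}

#' Per-trial reach measures for a set of traces
#'
#' Computes initiation latency (against the run-global fitted speed
#' maximum), maximum deviation, and the bell-shape flag for every
#' converged trace; non-convergent traces get NA measures.
#'
#' @param traces list of \code{crt_trace}.
#' @param poly_degree,frac forwarded to \code{\link{initiation_latency}}.
#' @return Data frame: code, condition cells, il, md, bell, success,
#'   converged.
#' @export
trial_measures <- function(traces, poly_degree = 10, frac = 0.1) {
  conv <- vapply(traces, `[[`, TRUE, "converged")
  curves <- vector("list", length(traces))
  for (i in seq_along(traces))
    if (conv[i] && length(traces[[i]]$speeds) >= 2)
      curves[[i]] <- fit_speed_curve(traces[[i]]$speeds, poly_degree)
  gmax <- max(vapply(curves[!vapply(curves, is.null, TRUE)],
                     function(fc) max(fc$y), 0))
  out <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    cc <- code_condition(tr$code)
    il <- md <- NA_real_; bell <- NA
    if (conv[i]) {
      il <- tryCatch(initiation_latency(tr$speeds, gmax, poly_degree, frac),
                     error = function(e) NA_real_)
      md <- max_deviation(tr$positions, tr$positions[1, ],
                          tr$target_centroid)
      bell <- bell_shape(tr$speeds)$is_unimodal
    }
    cbind(data.frame(code = tr$code, stringsAsFactors = FALSE), cc,
          data.frame(il = il, md = md, bell = bell,
                     success = tr$success, converged = tr$converged))
  }))
  attr(out, "global_max_speed") <- gmax
  out
}

#' Condition summary of reach measures
#'
#' Means and dispersions of initiation latency and maximum deviation per
#' design cell (target size x distractor configuration x target
#' position). Trials that did not converge on the target are excluded
#' from the means and counted in \code{n_excluded}.
#'
#' @param traces list of \code{crt_trace}.
#' @param measures optional precomputed \code{\link{trial_measures}}.
#' @return Data frame keyed by the design cells with mean_il, sd_il,
#'   sem_il, mean_md, sd_md, sem_md, n, n_excluded.
#' @export
summarize_traces <- function(traces, measures = NULL) {
  m <- if (is.null(measures)) trial_measures(traces) else measures
  keep <- m$success & !is.na(m$il)
  cells <- unique(m[, c("target_size", "distractor_config",
                        "target_position")])
  cells <- cells[order(cells$target_size, cells$distractor_config,
                       cells$target_position), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- keep &
      m$target_size == cells$target_size[i] &
      m$distractor_config == cells$distractor_config[i] &
      m$target_position == cells$target_position[i]
    all_cell <- m$target_size == cells$target_size[i] &
      m$distractor_config == cells$distractor_config[i] &
      m$target_position == cells$target_position[i]
    n <- sum(sel)
    data.frame(
      cells[i, , drop = FALSE],
      mean_il = mean(m$il[sel]), sd_il = stats::sd(m$il[sel]),
      sem_il = stats::sd(m$il[sel]) / sqrt(max(n, 1)),
      mean_md = mean(m$md[sel]), sd_md = stats::sd(m$md[sel]),
      sem_md = stats::sd(m$md[sel]) / sqrt(max(n, 1)),
      n = n, n_excluded = sum(all_cell) - n,
      row.names = NULL
    )
  }))
  out
}

#' Compare normalised condition profiles against a reference table
#'
#' Min-max normalises the per-condition IL and MD vectors of the model
#' summary and of a user-supplied reference table independently to
#' [0, 1], then reports both the sum of squared differences and the sum
#' of absolute differences for each measure (the headline error metric of
#' profile fits is ambiguous between the two, so both are emitted,
#' labelled).
#'
#' @param model_summary data frame from \code{\link{summarize_traces}}.
#' @param reference data frame with columns target_size,
#'   distractor_config, target_position, il, md; keys must match the
#'   model summary's cells.
#' @return List of class \code{crt_comparison}: normalised vectors and
#'   per-measure errors \code{sse_il}, \code{sae_il}, \code{sse_md},
#'   \code{sae_md}.
#' @export
compare_reference <- function(model_summary, reference) {
  need <- c("target_size", "distractor_config", "target_position",
            "il", "md")
  if (!all(need %in% names(reference)))
    stop("reference table needs columns: ", paste(need, collapse = ", "))
  key <- function(d) paste(d$target_size, d$distractor_config,
                           d$target_position)
  mk <- key(model_summary); rk <- key(reference)
  missing_keys <- setdiff(mk, rk)
  if (length(missing_keys))
    stop("reference table is missing conditions: ",
         paste(missing_keys, collapse = "; "))
  ref <- reference[match(mk, rk), ]
  mm <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) stop("zero range: cannot min-max normalise a ",
                             "constant condition vector")
    (x - rng[1]) / diff(rng)
  }
  m_il <- mm(model_summary$mean_il); r_il <- mm(ref$il)
  m_md <- mm(model_summary$mean_md); r_md <- mm(ref$md)
  structure(list(
    conditions = mk,
    model_il = m_il, reference_il = r_il,
    model_md = m_md, reference_md = r_md,
    sse_il = sum((m_il - r_il)^2), sae_il = sum(abs(m_il - r_il)),
    sse_md = sum((m_md - r_md)^2), sae_md = sum(abs(m_md - r_md))
  ), class = "crt_comparison")
}

#' @export
print.crt_comparison <- function(x, ...) {
  cat("Normalised model-vs-reference comparison\n")
  cat(sprintf("  IL: sum sq diff %.4g, sum abs diff %.4g\n",
              x$sse_il, x$sae_il))
  cat(sprintf("  MD: sum sq diff %.4g, sum abs diff %.4g\n",
              x$sse_md, x$sae_md))
  invisible(x)
}
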