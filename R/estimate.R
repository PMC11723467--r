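#' Four-channel force signal
#'
#' Light wrapper validating a uniformly sampled force/torque recording with
#' channels Fx, Fy, Fz (N) and Mz (N mm).
#'
#' @param x Data.frame with columns `Fx`, `Fy`, `Fz`, `Mz` (a `t` column is
#'   added if missing).
#' @param fs Sampling frequency (Hz).
#' @return Object of class `force_signal` (a data.frame with attribute
#'   `fs`).
#' @export
force_signal <- function(x, fs) {
  need <- c("Fx", "Fy", "Fz", "Mz")
  if (!all(need %in% names(x)))
    stop("signal must have channels ", paste(need, collapse = ", "))
  if (any(!is.finite(as.matrix(x[need]))))
    stop("signal values must be finite")
  if (!"t" %in% names(x)) x$t <- (seq_len(nrow(x)) - 0.5) / fs
  x <- as.data.frame(x)[, c("t", need)]
  attr(x, "fs") <- fs
  class(x) <- c("force_signal", "data.frame")
  x
}

#' Tumbling-window segmentation
#'
#' Cuts the signal into consecutive non-overlapping windows of `ns`
#' samples; a trailing remainder shorter than `ns` is dropped. Each
#' segment's physical span is `l = vd * ns / fs` mm.
#'
#' @param sig A [force_signal()] (or data.frame with the four channels).
#' @param ns Window length in samples (>= 2).
#' @param feed Nominal feed rate vd (mm/s), used only to report `l`.
#' @return List of segments; each has `m` (ordinal), `channels`
#'   (`ns x 4` matrix), `t_mid`, `t_span` and `l`. Empty list (with a
#'   warning) when the signal is shorter than `ns`.
#' @export
tumble_segment <- function(sig, ns, feed = NULL) {
  stopifnot(ns >= 2)
  chans <- as.matrix(sig[, c("Fx", "Fy", "Fz", "Mz")])
  n_seg <- nrow(chans) %/% ns
  if (n_seg == 0L) {
    warning("signal shorter than one window (", nrow(chans), " < ", ns, ")")
    return(list())
  }
  fs <- attr(sig, "fs")
  t <- if ("t" %in% names(sig)) sig$t else (seq_len(nrow(chans)) - 0.5) / fs
  lapply(seq_len(n_seg), function(m) {
    rows <- ((m - 1) * ns + 1):(m * ns)
    list(m = m, channels = chans[rows, , drop = FALSE],
         t_mid = mean(range(t[rows])), t_span = range(t[rows]),
         l = if (!is.null(feed)) feed * ns / fs else NA_real_)
  })
}

#' Dynamic time warping distance
#'
#' Alignment distance between two sequences under the absolute-difference
#' local cost: `C(i,j) = |a_i - b_j| + min(C(i-1,j), C(i,j-1), C(i-1,j-1))`,
#' returning the accumulated cost at the final corner. Zero for identical
#' sequences; never larger than the lockstep sum of pointwise differences.
#'
#' @param a,b Numeric sequences (non-empty).
#' @return Non-negative scalar distance.
#' @export
dtw_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("dtw_distance: empty input sequence")
  .dtw_distance_cpp(a, b)
}

#' Similarity field of a segment against the prediction bank
#'
#' For every grid (i, j, k), the channel-weighted DTW distance (smaller =
#' more similar) or the channel-weighted Pearson correlation (larger = more
#' similar) between the segment and the grid's predicted sequence.
#' Zero-variance channels under the Pearson method contribute 0 similarity.
#'
#' @param seg A segment from [tumble_segment()] (or an `ns x 4` matrix).
#' @param bank A [predict_bank()] result.
#' @param method `"dtw"` or `"pearson"`.
#' @param weights Per-channel weights (Fx, Fy, Fz, Mz).
#' @return 3-D array `d[i, j, k]` with attributes `method` and `weights`.
#' @export
similarity_field <- function(seg, bank, method = c("dtw", "pearson"),
                             weights = c(1, 1, 1, 1)) {
  method <- match.arg(method)
  chans <- if (is.list(seg)) seg$channels else as.matrix(seg)
  if (nrow(chans) != bank$ns)
    stop("segment length ", nrow(chans), " does not match bank ns = ",
         bank$ns)
  d <- field_values(chans, bank, method, weights)
  out <- array(NA_real_, dim = c(bank$plan$n_layers, bank$plan$n_paths,
                                 bank$plan$grids_per_path))
  out[cbind(bank$index$i, bank$index$j, bank$index$k)] <- d
  attr(out, "method") <- method
  attr(out, "weights") <- weights
  out
}

# similarity values in bank-entry order (lexicographic in (i, j, k))
field_values <- function(chans, bank, method, weights) {
  if (method == "dtw") {
    .dtw_field_cpp(chans, as.numeric(bank$seq), dim(bank$seq), weights)
  } else {
    ne <- dim(bank$seq)[3]
    d <- numeric(ne)
    for (c in seq_len(4)) {
      if (weights[c] == 0) next
      bm <- matrix(bank$seq[, c, ], nrow = bank$ns)
      r <- suppressWarnings(as.numeric(stats::cor(chans[, c], bm)))
      r[!is.finite(r)] <- 0 # zero-variance channel: no evidence
      d <- d + weights[c] * r
    }
    d
  }
}

#' Estimate the tip position from one segment
#'
#' Scans the whole bank (optionally restricted to an index window), takes
#' the most similar grid -- the arg-minimum of the DTW field or the
#' arg-maximum of the Pearson field, ties broken towards the
#' lexicographically smallest (i, j, k) -- and reports that grid's landmark
#' as the tip position.
#'
#' @inheritParams similarity_field
#' @param entries Optional integer vector of bank entry numbers to scan
#'   (default: all).
#' @return One-row data.frame: `i`, `j`, `k`, `x`, `y`, `z`, `score`,
#'   `method`.
#' @export
estimate_tip <- function(seg, bank, method = c("dtw", "pearson"),
                         weights = c(1, 1, 1, 1), entries = NULL) {
  method <- match.arg(method)
  chans <- if (is.list(seg)) seg$channels else as.matrix(seg)
  if (dim(bank$seq)[3] == 0L) stop("empty prediction bank")
  sub <- bank
  if (!is.null(entries)) {
    sub$seq <- bank$seq[, , entries, drop = FALSE]
    sub$index <- bank$index[entries, ]
  }
  d <- field_values(chans, sub, method, weights)
  best <- if (method == "dtw") which.min(d) else which.max(d)
  hit <- sub$index[best, ]
  data.frame(i = hit$i, j = hit$j, k = hit$k, x = hit$x, y = hit$y,
             z = hit$z, score = d[best], method = method)
}

#' Estimate the tip trajectory over a whole run
#'
#' Segments the signal path-by-path with a tumbling window (the execution
#' schedule fixes which planned path each window belongs to) and matches
#' every segment against the bank.
#'
#' @param sig A [force_signal()] covering the executed paths in order
#'   (`plan$samples_per_path` samples per path).
#' @param bank A [predict_bank()] result.
#' @param plan The executed [milling_plan()].
#' @param method `"dtw"` or `"pearson"`.
#' @param weights Per-channel weights.
#' @return Data.frame with one row per segment: `seg` (global ordinal),
#'   `ord` (executed path ordinal), `exec_layer`, `exec_path`, `seg_k`
#'   (window ordinal within the path), `t_mid`, `x_sched` (the window
#'   midpoint's planned along-path position), `seg_rms` (mean force
#'   magnitude of the window, used to flag air-cutting segments), matched
#'   `i`, `j`, `k`, `x`, `y`, `z`, `score`, `method`.
#' @export
estimate_track <- function(sig, bank, plan, method = c("dtw", "pearson"),
                           weights = c(1, 1, 1, 1)) {
  method <- match.arg(method)
  paths <- plan_paths(plan)
  spp <- plan$samples_per_path
  if (nrow(sig) < spp * nrow(paths))
    stop("signal shorter than the executed plan (", nrow(sig), " < ",
         spp * nrow(paths), " samples)")
  out <- vector("list", nrow(paths) * plan$grids_per_path)
  seg_id <- 0L
  for (r in seq_len(nrow(paths))) {
    rows <- ((r - 1) * spp + 1):(r * spp)
    segs <- tumble_segment(sig[rows, , drop = FALSE], plan$ns, plan$feed)
    for (s in segs) {
      seg_id <- seg_id + 1L
      est <- estimate_tip(s, bank, method, weights)
      x_sched <- if (paths$dir[r] > 0)
        paths$x0[r] + (s$m - 0.5) * plan$grid_length
      else paths$x1[r] - (s$m - 0.5) * plan$grid_length
      rms <- mean(sqrt(rowSums(s$channels[, 1:3, drop = FALSE]^2)))
      out[[seg_id]] <- cbind(
        data.frame(seg = seg_id, ord = paths$ord[r],
                   exec_layer = paths$layer[r], exec_path = paths$path[r],
                   seg_k = s$m, t_mid = s$t_mid, x_sched = x_sched,
                   seg_rms = rms), est)
    }
  }
  do.call(rbind, out[seq_len(seg_id)])
}
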