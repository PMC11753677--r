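#' Sliding-window segmentation of a trajectory
#'
#' Cuts a trajectory into all contiguous segments of `w` consecutive grid
#' points (step size 1), yielding `n_points - w + 1` window segments.
#'
#' @param traj a [trajectory()].
#' @param w window size, `2 <= w <= length(traj$times)`.
#' @param sample_index index of the parent sample, carried in each segment.
#' @return list of `window_segment` objects with fields `sample_index`,
#'   `start_index`, `times`, `states`.
#' @export
sliding_windows <- function(traj, w, sample_index = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$times)
  if (w < 2 || w > n)
    stop("window size w must be in [2, ", n, "], got ", w)
  lapply(seq_len(n - w + 1L), function(s) {
    idx <- s:(s + w - 1L)
    structure(list(sample_index = as.integer(sample_index),
                   start_index = as.integer(s),
                   times = traj$times[idx],
                   states = traj$states[idx, , drop = FALSE]),
              class = "window_segment")
  })
}

# pooled windows over every trajectory in a list
pool_windows <- function(trajectories, w) {
  unlist(lapply(seq_along(trajectories), function(i)
    sliding_windows(trajectories[[i]], w, sample_index = i)),
    recursive = FALSE)
}

#' Shuffle pooled windows into training batches
#'
#' Windows from all samples are pooled, globally shuffled with the given
#' seed, and chunked into consecutive groups of `b`. A trailing partial
#' batch is kept. Every window appears exactly once across the batch set.
#'
#' @param windows list of window segments (pooled over samples).
#' @param b batch size, `>= 1`.
#' @param seed shuffle seed.
#' @return object of class `batch_set`: list with `batches` (list of lists
#'   of segments), `batch_size`, `shuffle_seed`.
#' @export
make_batches <- function(windows, b, seed = 1) {
  if (length(windows) == 0) stop("empty window list")
  stopifnot(b >= 1)
  perm <- withr_seed(seed, sample.int(length(windows)))
  shuffled <- windows[perm]
  starts <- seq(1, length(shuffled), by = b)
  batches <- lapply(starts, function(s)
    shuffled[s:min(s + b - 1, length(shuffled))])
  structure(list(batches = batches, batch_size = as.integer(b),
                 shuffle_seed = as.integer(seed)),
            class = "batch_set")
}
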