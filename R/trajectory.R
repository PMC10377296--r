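#' Cell detection trajectory
#'
#' Container for a per-subject tumor cell detection trajectory: at each
#' migration step \code{t} the incremental region \eqn{\Delta R(t)} is probed
#' and \code{m[t]} cells are detected in total, of which \code{m_star[t]} are
#' malignant. Cumulative totals \eqn{M_t = \sum_{s \le t} m_s} and
#' \eqn{M^*_t} are computed, never stored redundantly.
#'
#' @param m integer vector of per-step total detected cell counts (length T).
#' @param m_star integer vector of per-step malignant detected counts.
#' @param delta_voxels positive integer vector, voxel count of each
#'   incremental region \eqn{|\Delta R(t)|}. Recycled if length 1.
#' @param v_initial optional initial ROI volume in cubic millimetres.
#' @param truncated logical flag set by the simulator when the cell
#'   population was exhausted before the requested number of steps.
#'
#' @return An object of class \code{cell_trajectory}: a list with elements
#'   \code{steps} (data.frame with columns \code{step}, \code{m},
#'   \code{m_star}, \code{delta_voxels}), \code{n_steps}, \code{M} and
#'   \code{M_star} (cumulative totals), \code{v_initial}, \code{truncated}.
#' @examples
#' traj <- cell_trajectory(m = c(4, 2, 5), m_star = c(1, 1, 3))
#' traj$M        # 4 6 11
#' traj$M_star   # 1 2 5
#' @export
cell_trajectory <- function(m, m_star, delta_voxels = 1L, v_initial = NULL,
                            truncated = FALSE) {
  if (length(m) < 1L) stop("a trajectory needs at least one step")
  if (length(m_star) != length(m)) {
    stop("'m' and 'm_star' must have the same length")
  }
  m <- as.numeric(m)
  m_star <- as.numeric(m_star)
  delta_voxels <- rep_len(as.numeric(delta_voxels), length(m))
  if (any(m < 0) || any(m_star < 0)) stop("counts must be nonnegative")
  if (any(m != round(m)) || any(m_star != round(m_star))) {
    stop("counts must be integers")
  }
  if (any(m_star > m)) stop("'m_star' cannot exceed 'm' at any step")
  if (any(delta_voxels <= 0)) stop("'delta_voxels' must be positive")
  if (!is.null(v_initial)) {
    v_initial <- as.numeric(v_initial)
    if (length(v_initial) != 1L || v_initial < 0) {
      stop("'v_initial' must be a single nonnegative volume in mm^3")
    }
  }
  structure(
    list(
      steps = data.frame(step = seq_along(m), m = m, m_star = m_star,
                         delta_voxels = delta_voxels),
      n_steps = length(m),
      M = cumsum(m),
      M_star = cumsum(m_star),
      v_initial = v_initial,
      truncated = isTRUE(truncated)
    ),
    class = "cell_trajectory"
  )
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat("Cell detection trajectory:", x$n_steps, "migration step(s)\n")
  cat("  total detected M_T =", x$M[x$n_steps],
      " malignant M*_T =", x$M_star[x$n_steps], "\n")
  if (!is.null(x$v_initial)) cat("  initial volume:", x$v_initial, "mm^3\n")
  if (x$truncated) cat("  (truncated: population exhausted)\n")
  invisible(x)
}

#' Read or write a trajectory as CSV
#'
#' CSV layout: columns \code{step}, \code{m}, \code{m_star},
#' \code{delta_voxels}. \code{v_initial} travels in a \code{#} comment header
#' line when present.
#'
#' @param path file path.
#' @param traj a \code{\link{cell_trajectory}}.
#' @return \code{read_trajectory_csv} returns a \code{cell_trajectory};
#'   \code{write_trajectory_csv} returns \code{path} invisibly.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  v_init <- NULL
  if (startsWith(first, "# v_initial=")) {
    v_init <- as.numeric(sub("# v_initial=", "", first))
  }
  df <- utils::read.csv(path, comment.char = "#")
  required <- c("step", "m", "m_star", "delta_voxels")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("malformed trajectory CSV ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[order(df$step), , drop = FALSE]
  cell_trajectory(df$m, df$m_star, df$delta_voxels, v_initial = v_init)
}

#' @rdname read_trajectory_csv
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "cell_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$v_initial)) {
    writeLines(sprintf("# v_initial=%.17g", traj$v_initial), con)
  }
  utils::write.csv(traj$steps, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
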