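#' Microtubule length trace
#'
#' Per-frame lengths (um) of one traced microtubule in one cell, measured
#' at a fixed frame interval.  The canonical acquisition is 10 frames over
#' a 30 s period, but any trace with at least 2 frames is accepted.
#'
#' @param lengths Numeric vector of lengths, um, all > 0, length >= 2.
#' @param frame_interval Seconds between frames, > 0.
#' @param cell_id,mt_id Identifiers.
#' @return Object of class `mt_trace`.
#' @export
mt_trace <- function(lengths, frame_interval = 3, cell_id = "cell1",
                     mt_id = "mt1") {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 2) stop("a trace needs at least 2 frames")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all lengths must be finite and > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(cell_id = as.character(cell_id),
                 mt_id = as.character(mt_id),
                 lengths = lengths,
                 frame_interval = frame_interval),
            class = "mt_trace")
}

#' Maximum length change of a microtubule trace
#'
#' The dynamicity read-out: `100 * (longest - shortest) / longest` percent,
#' in `[0, 100)`.  A warning (not an error) is emitted when the trace does
#' not have the canonical 10 frames, since the statistic is well defined
#' for any trace length.
#'
#' @param trace An [mt_trace()], or a bare numeric vector of lengths.
#' @return Percent, in `[0, 100)`.
#' @export
#' @examples
#' max_length_change(mt_trace(c(10, 8, 6)))  # 40
max_length_change <- function(trace) {
  lengths <- if (inherits(trace, "mt_trace")) trace$lengths else as.numeric(trace)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all lengths must be finite and > 0")
  if (length(lengths) != 10)
    warning("trace has ", length(lengths), " frames (canonical acquisition is 10)")
  100 * (max(lengths) - min(lengths)) / max(lengths)
}

#' Longest microtubule per cell
#'
#' For each cell, the maximum over its traces of the per-trace maximum
#' length; 2-3 microtubules are typically traced per cell and the group
#' median of the per-cell longest lengths is the reported statistic.
#'
#' @param traces List of [mt_trace()] objects.
#' @return Named numeric vector, um, one entry per cell; attribute
#'   `median` carries the group median.
#' @export
longest_mt_per_cell <- function(traces) {
  if (length(traces) == 0) stop("empty trace group")
  stopifnot(all(vapply(traces, inherits, logical(1), "mt_trace")))
  cells <- vapply(traces, `[[`, character(1), "cell_id")
  maxima <- vapply(traces, function(tr) max(tr$lengths), numeric(1))
  per_cell <- tapply(maxima, cells, max)
  out <- as.numeric(per_cell)
  names(out) <- names(per_cell)
  attr(out, "median") <- stats::median(out)
  out
}

# Mann-Whitney U (pairs where a > b, + half ties)
mw_u_stat <- function(a, b) {
  r <- rank(c(a, b))
  n1 <- length(a)
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney / Wilcoxon rank-sum two-group comparison
#'
#' Exact permutation test (full enumeration of group assignments, ties
#' handled naturally) for combined n <= `exact_limit`; otherwise the
#' normal approximation with tie correction and continuity correction.
#' The two-sided p-value is the probability, under random relabelling, of
#' a U statistic at least as far from its null mean as observed, making it
#' symmetric in group order.
#'
#' @param values_a,values_b Numeric vectors, each non-empty.
#' @param exact_limit Enumeration cutoff on the combined sample size
#'   (default 12; C(12,6) = 924 assignments).
#' @return List with `statistic` (U of group a), `p_value`, `method`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
compare_groups <- function(values_a, values_b, exact_limit = 12) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("values must be finite")
  pooled <- c(a, b)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  u_obs <- mw_u_stat(a, b)
  mu <- n1 * n2 / 2
  if (length(unique(pooled)) == 1) {
    warning("all values identical across both groups")
    return(list(statistic = u_obs, p_value = 1, method = "degenerate"))
  }
  if (n <= exact_limit) {
    idx <- utils::combn(n, n1)
    r <- rank(pooled)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    r <- rank(pooled)
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = u_obs, p_value = p, method = method)
}

#' Summarize microtubule dynamicity per group
#'
#' Pools traces across cells within each group (the analysis unit is the
#' microtubule), computes per-trace maximum length change, and compares the
#' two groups with the Mann-Whitney test.
#'
#' @param traces_a,traces_b Lists of [mt_trace()] objects.
#' @return List with per-group `mlc` vectors (percent), group `medians`,
#'   and the `test` result from [compare_groups()].
#' @export
mt_group_comparison <- function(traces_a, traces_b) {
  mlc <- function(trs) vapply(trs, function(tr)
    suppressWarnings(max_length_change(tr)), numeric(1))
  va <- mlc(traces_a); vb <- mlc(traces_b)
  list(mlc = list(a = va, b = vb),
       medians = c(a = stats::median(va), b = stats::median(vb)),
       test = compare_groups(va, vb))
}
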