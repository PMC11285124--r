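# shared input checks for the DP engines
.check_codes <- function(codes) {
  codes <- as.integer(codes)
  if (length(codes) == 0L) stop("codes must be non-empty")
  if (anyNA(codes) || any(codes < 0L | codes > 3L))
    stop("codes must be 2-bit symbols in 0..3")
  codes
}

.check_scores8 <- function(scores8) {
  scores8 <- as.matrix(scores8)
  if (ncol(scores8) != 4L || nrow(scores8) < 1L)
    stop("scores8 must be a K x 4 matrix")
  storage.mode(scores8) <- "integer"
  if (anyNA(scores8) || any(scores8 < -128L | scores8 > 127L))
    stop("scores8 entries must lie in the int8 range [-128, 127]")
  scores8
}

#' Maximum single-segment ungapped Viterbi score
#'
#' Full-precision form of the filter statistic: the best score of any
#' ungapped diagonal alignment between the sequence and the model's match
#' states, via the recurrence
#' `M(i,j) = max(0, M(i-1,j-1)) + scores(j, codes[i])`
#' with out-of-range predecessors contributing 0, maximized over all cells.
#' Equivalently, the maximum over all diagonal segments of the segment sum,
#' where extension only continues while the running prefix stays positive.
#'
#' @param codes Integer vector of 2-bit symbols (0..3).
#' @param scores `K x 4` numeric (or integer) score matrix, rows = model
#'   positions, columns = A, C, G, T.
#' @return The maximum score (real; at least the best single-cell score).
#' @export
ssv_max_score <- function(codes, scores) {
  codes <- .check_codes(codes)
  scores <- as.matrix(scores)
  if (ncol(scores) != 4L) stop("scores must have 4 columns (A, C, G, T)")
  storage.mode(scores) <- "double"
  ssv_max_score_cpp(codes, scores)
}

#' One 8-bit cell update
#'
#' The elementary processing-element rule, vectorized over cells: with
#' accumulator `m` in \[0, 255\] and signed 8-bit addend `p`, the
#' intermediate sum is `t = m + p`; `t < 0` resets to 0 (underflow),
#' `t >= 256` reports a hit and resets to 0 (overflow past the fixed
#' threshold), otherwise the accumulator becomes `t`. This arithmetic form
#' is equivalent to the 8-bit full-adder carry/sign-bit logic of the
#' hardware cell.
#'
#' @param m Integer vector of accumulators in \[0, 255\].
#' @param p Integer vector of addends in \[-128, 127\] (recycled).
#' @return List with `score` (new accumulators) and `hit` (logical).
#' @export
cell_update <- function(m, p) {
  m <- as.integer(m); p <- as.integer(p)
  if (any(m < 0L | m > 255L)) stop("accumulator out of [0, 255]")
  if (any(p < -128L | p > 127L)) stop("addend out of [-128, 127]")
  t <- m + p
  hit <- t >= 256L
  score <- ifelse(t < 0L | hit, 0L, t)
  list(score = as.integer(score), hit = hit)
}

#' Threshold hits, row-major evaluation
#'
#' Runs the 8-bit reset recurrence over the whole matrix in row-major order
#' and reports every cell whose intermediate sum reaches 256. This is the
#' reference evaluation order; [ssv_hits_segmented()] must produce the
#' identical hit set.
#'
#' @param codes Integer vector of 2-bit symbols (0..3).
#' @param scores8 `K x 4` integer matrix of projected int8 scores.
#' @return Integer matrix with columns `seq_pos`, `model_pos`: 0-based
#'   coordinates of threshold-crossing cells (0 rows if none).
#' @export
ssv_hits_rowmajor <- function(codes, scores8) {
  codes <- .check_codes(codes)
  scores8 <- .check_scores8(scores8)
  h <- ssv_hits_rowmajor_cpp(codes, scores8)
  colnames(h) <- c("seq_pos", "model_pos")
  h
}

#' Threshold hits, segmented evaluation order
#'
#' Evaluates the identical recurrence in the accelerator's order: the padded
#' target is cut into length-`n` segments; for each segment all model
#' positions are swept as width-`n` column passes, and the rightmost cell of
#' each column is carried to the leftmost cell of the next segment via a
#' score queue (the first segment seeds with zeros). The dataflow is
#' identical to row-major, so the hit set is exactly equal; only the
#' traversal order differs.
#'
#' @param db Either a `SequenceDB` (its `concatenated` codes and `n` are
#'   used) or an integer code vector.
#' @param scores8 `K x 4` integer matrix of projected int8 scores.
#' @param n Segment width; required when `db` is a plain code vector,
#'   otherwise defaults to `db$n`. The (padded) length must be a multiple of
#'   `n`.
#' @return Integer matrix with columns `seq_pos`, `model_pos` (0-based
#'   global coordinates).
#' @export
ssv_hits_segmented <- function(db, scores8, n = NULL) {
  if (inherits(db, "SequenceDB")) {
    codes <- db$concatenated
    if (is.null(n)) n <- db$n
  } else {
    codes <- db
    if (is.null(n)) stop("segment width n is required for a plain code vector")
  }
  codes <- .check_codes(codes)
  scores8 <- .check_scores8(scores8)
  if (length(codes) %% n != 0L)
    stop("length of the (padded) code vector must be a multiple of n")
  h <- ssv_hits_segmented_cpp(codes, scores8, as.integer(n))
  colnames(h) <- c("seq_pos", "model_pos")
  h
}

#' Default hardware segment width
#'
#' The reference accelerator instantiates 12,288 cell processing elements;
#' the software engine uses the same default segment width (results are
#' independent of `n`, which only fixes the padding granularity and
#' traversal order).
#' @export
DEFAULT_SEGMENT_WIDTH <- 12288L
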