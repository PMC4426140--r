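#' Recombination schemes for the linked block
#'
#' The linked block consists of the beneficial locus with I deleterious loci
#' to its left and J to its right. Only single crossover with a wildtype
#' haplotype is modelled, so a carrier of class (i,j) can only lose a
#' contiguous outer run of alleles on one side per birth: its recombinant
#' offspring are (k,j) with k < i or (i,k) with k < j. `r_target()` returns
#' the per-birth probability of one such transition, `r_total()` their sum
#' \eqn{r_{(i,j)}}.
#'
#' Three modes are supported:
#' * `interval_recombination()`: each entry is the probability that the
#'   single crossover falls in the interval between adjacent linked loci
#'   (entry 1 = interval adjacent to the beneficial locus). Transition
#'   probabilities are then independent of the source class:
#'   \eqn{r^{(i,j)}_{(i,k)} = right[k+1]}.
#' * `uniform_recombination()`: every interval probability equal to `rho`,
#'   so \eqn{r_{(i,j)} = (i+j)\rho}.
#' * `matrix_recombination()`: fully general, possibly source-dependent
#'   transition probabilities (such schemes cannot be interpreted as
#'   physical crossover intervals and are rejected by the simulator).
#'
#' @param left_intervals,right_intervals numeric vectors of per-birth
#'   crossover probabilities, length I and J.
#' @return A `recomb_scheme`.
#' @examples
#' rec <- uniform_recombination(0, 2, 1e-4)
#' r_total(rec, 0, 2) # 2e-4
#' @export
interval_recombination <- function(left_intervals = numeric(),
                                   right_intervals = numeric()) {
  left_intervals <- as.numeric(left_intervals)
  right_intervals <- as.numeric(right_intervals)
  if (any(left_intervals < 0) || any(right_intervals < 0))
    stop("interval probabilities must be >= 0")
  if (sum(left_intervals) + sum(right_intervals) >= 1)
    stop("total crossover probability must be < 1")
  structure(list(mode = "intervals",
                 I = length(left_intervals), J = length(right_intervals),
                 left = left_intervals, right = right_intervals,
                 rL = NULL, rR = NULL),
            class = "recomb_scheme")
}

#' @rdname interval_recombination
#' @param I,J numbers of linked deleterious loci left/right of the
#'   beneficial locus.
#' @param rho common per-interval crossover probability.
#' @export
uniform_recombination <- function(I, J, rho) {
  stopifnot(rho >= 0)
  if ((I + J) * rho >= 1)
    stop("(I + J) * rho must be < 1: the total recombination probability of the founder class would reach 1")
  interval_recombination(rep(rho, I), rep(rho, J))
}

#' @rdname interval_recombination
#' @param rL,rR arrays of source-dependent transition probabilities:
#'   `rL[i+1, j+1, k+1]` is \eqn{r^{(i,j)}_{(k,j)}} for k < i and
#'   `rR[i+1, j+1, k+1]` is \eqn{r^{(i,j)}_{(i,k)}} for k < j. Entries with
#'   k >= i (resp. k >= j) are ignored.
#' @export
matrix_recombination <- function(rL, rR) {
  dL <- if (is.null(rL)) c(1L, 1L, 0L) else dim(rL)
  dR <- if (is.null(rR)) c(1L, 1L, 0L) else dim(rR)
  I <- max(dL[1L], dR[1L]) - 1L
  J <- max(dL[2L], dR[2L]) - 1L
  sc <- structure(list(mode = "matrix", I = I, J = J,
                       left = NULL, right = NULL, rL = rL, rR = rR),
                  class = "recomb_scheme")
  for (i in 0:I) for (j in 0:J) {
    rt <- r_total(sc, i, j)
    if (rt >= 1) stop(sprintf("r_total(%d,%d) = %g reaches 1", i, j, rt))
    if (any(r_targets_left(sc, i, j) < 0) || any(r_targets_right(sc, i, j) < 0))
      stop("recombination probabilities must be >= 0")
  }
  sc
}

## vector of r^{(i,j)}_{(k,j)}, k = 0..i-1 (empty when i = 0)
r_targets_left <- function(rec, i, j) {
  if (i == 0L) return(numeric())
  if (rec$mode == "matrix") {
    if (is.null(rec$rL)) return(rep(0, i))
    rec$rL[i + 1L, j + 1L, seq_len(i)]
  } else rec$left[seq_len(i)]
}

## vector of r^{(i,j)}_{(i,k)}, k = 0..j-1
r_targets_right <- function(rec, i, j) {
  if (j == 0L) return(numeric())
  if (rec$mode == "matrix") {
    if (is.null(rec$rR)) return(rep(0, j))
    rec$rR[i + 1L, j + 1L, seq_len(j)]
  } else rec$right[seq_len(j)]
}

#' @rdname interval_recombination
#' @param rec a `recomb_scheme`.
#' @param i,j source class.
#' @param side `"left"` for targets (k, j), `"right"` for targets (i, k).
#' @param k target index (number of alleles kept on that side, 0-based).
#' @export
r_target <- function(rec, i, j, side = c("left", "right"), k) {
  side <- match.arg(side)
  v <- if (side == "left") r_targets_left(rec, i, j) else r_targets_right(rec, i, j)
  if (k + 1L > length(v)) stop("not a valid recombination target of this class")
  v[k + 1L]
}

#' @rdname interval_recombination
#' @export
r_total <- function(rec, i, j) {
  sum(r_targets_left(rec, i, j)) + sum(r_targets_right(rec, i, j))
}

#' @export
print.recomb_scheme <- function(x, ...) {
  cat(sprintf("Recombination scheme (%s): I = %d, J = %d, r_(I,J) = %.6g\n",
              x$mode, x$I, x$J, r_total(x, x$I, x$J)))
  invisible(x)
}
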