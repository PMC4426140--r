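#' Additive selection scheme over haplotype classes
#'
#' Builds the Malthusian fitness table \eqn{\sigma_{(i,j;f)}} for every
#' carrier haplotype class from per-allele fitness costs. A class
#' \eqn{(i,j;f)} carries the beneficial allele, the \eqn{i} nearest linked
#' deleterious alleles to its left, the \eqn{j} nearest to its right and
#' \eqn{f} unlinked deleterious alleles. Fitness is Malthusian relative to
#' wildtype (wildtype = 0, death rate of a class is \eqn{1-\sigma}), and
#' under additivity
#' \deqn{\sigma_{(i,j;f)} = \sigma_{ben} - \sum_{m \le i} left[m]
#'       - \sum_{m \le j} right[m] - f\,u.}
#'
#' @param sigma_ben Malthusian fitness of the beneficial allele on a clean
#'   background (\eqn{\sigma_{(0,0;0)}}); must be in (0, 1).
#' @param left_effects,right_effects numeric vectors of non-negative fitness
#'   costs of the linked deleterious alleles, ordered outward from the
#'   beneficial locus (element 1 is the nearest allele).
#' @param unlinked_effect common non-negative cost of each unlinked allele.
#'   Per-allele unlinked effects are deliberately not supported: unlinked
#'   alleles are treated as exchangeable.
#' @param F number of unlinked deleterious loci.
#' @return An object of class `selection_scheme`: the full
#'   \eqn{(I+1)\times(J+1)\times(F+1)} array of class fitnesses plus the
#'   architecture counts.
#' @examples
#' sel <- additive_selection(0.08, right_effects = c(0.01, 0.075))
#' sigma_of(sel, 0, 2) # -0.005
#' @export
additive_selection <- function(sigma_ben, left_effects = numeric(),
                               right_effects = numeric(),
                               unlinked_effect = 0, F = 0L) {
  stopifnot(length(sigma_ben) == 1L, is.finite(sigma_ben))
  if (sigma_ben >= 1) stop("sigma_ben must be < 1 (death rate 1 - sigma must stay positive)")
  if (any(left_effects < 0) || any(right_effects < 0) || unlinked_effect < 0)
    stop("allele effects are fitness costs and must be >= 0")
  if (F > 0 && length(unlinked_effect) != 1L)
    stop("unlinked alleles share one common effect; supply a single 'unlinked_effect'")
  I <- length(left_effects); J <- length(right_effects); F <- as.integer(F)
  sig <- array(NA_real_, dim = c(I + 1L, J + 1L, F + 1L))
  for (i in 0:I) for (j in 0:J) for (f in 0:F) {
    sig[i + 1L, j + 1L, f + 1L] <- sigma_ben -
      sum(left_effects[seq_len(i)]) - sum(right_effects[seq_len(j)]) -
      f * unlinked_effect
  }
  if (any(sig >= 1)) stop("a class fitness reached 1; death rates must stay positive")
  new_selection_scheme(sig, additive = TRUE,
                       effects = list(sigma_ben = sigma_ben,
                                      left = as.numeric(left_effects),
                                      right = as.numeric(right_effects),
                                      unlinked = unlinked_effect))
}

#' Explicit fitness table
#'
#' Wraps a user-supplied array of class fitnesses \eqn{\sigma_{(i,j;f)}}
#' (dimension \eqn{(I+1)\times(J+1)\times(F+1)}, index 1 = zero alleles).
#' A matrix is accepted for \eqn{F=0}.
#'
#' @param sigma numeric array (or matrix when there are no unlinked loci).
#' @return A `selection_scheme`.
#' @export
selection_table <- function(sigma) {
  if (is.matrix(sigma)) sigma <- array(sigma, dim = c(dim(sigma), 1L))
  if (!is.array(sigma) || length(dim(sigma)) != 3L)
    stop("sigma must be an (I+1) x (J+1) x (F+1) array or an (I+1) x (J+1) matrix")
  if (anyNA(sigma)) stop("sigma table contains missing values")
  if (any(sigma >= 1)) stop("all class fitnesses must be < 1")
  new_selection_scheme(sigma, additive = FALSE, effects = NULL)
}

new_selection_scheme <- function(sigma, additive, effects) {
  d <- dim(sigma)
  if (sigma[1L, 1L, 1L] <= 0)
    stop("sigma_(0,0;0) must be > 0: the beneficial allele must be advantageous on a clean background")
  structure(list(sigma = sigma,
                 I = d[1L] - 1L, J = d[2L] - 1L, F = d[3L] - 1L,
                 additive = additive, effects = effects),
            class = "selection_scheme")
}

#' Class fitness accessor
#'
#' @param sel a `selection_scheme`.
#' @param i,j,f allele counts of the class (left-linked, right-linked,
#'   unlinked).
#' @return \eqn{\sigma_{(i,j;f)}}.
#' @export
sigma_of <- function(sel, i, j, f = 0L) {
  sel$sigma[i + 1L, j + 1L, f + 1L]
}

#' @export
print.selection_scheme <- function(x, ...) {
  cat(sprintf("Selection scheme (%s): I = %d, J = %d, F = %d\n",
              if (x$additive) "additive" else "explicit table", x$I, x$J, x$F))
  cat(sprintf("  sigma_ben = %.6g", x$sigma[1, 1, 1]))
  if (x$I + x$J > 0)
    cat(sprintf(", sigma_(I,J;0) = %.6g", x$sigma[x$I + 1, x$J + 1, 1]))
  cat("\n")
  invisible(x)
}
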