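#' Own-type establishment probability
#'
#' Probability that a single carrier of a class with fitness `sigma` and
#' total recombination probability `r_total` founds an infinite lineage of
#' its own exact type: \eqn{(\sigma - r)/(1 - r)}, floored at 0. A class
#' with \eqn{\sigma - r > 0} is called supercritical; at or below the
#' boundary the own-type lineage is doomed (critical classes are treated as
#' subcritical).
#'
#' @param sigma Malthusian fitness of the class.
#' @param r_total its total per-birth recombination probability, < 1.
#' @return A probability.
#' @export
own_type_establishment <- function(sigma, r_total) {
  stopifnot(r_total >= 0, r_total < 1)
  max(0, (sigma - r_total) / (1 - r_total))
}

is_supercritical <- function(sc, i, j) {
  sigma_of(sc$selection, i, j, 0L) - r_total(sc$recombination, i, j) > 0
}

#' Which haplotype rescues the introgression process
#'
#' Conditioned on survival of the early stochastic phase, exactly one
#' haplotype class (i,j) (with all unlinked alleles already shed) is assumed
#' to establish; this function computes the distribution
#' \eqn{P^{(I,J;F)}_{(i,j)}} of that rescue type. A supercritical founder
#' establishes itself (delta distribution); a subcritical founder is rescued
#' through one of its recombination pathways, and the distribution is the
#' recursion-weighted average of the target classes' distributions, each
#' pathway weighted by its rate times the survival probability of the
#' target. Unlinked alleles enter through the binomial transmission weights
#' and through the non-recombinant births that shed unlinked alleles only.
#' The resulting entries are nonzero only for supercritical classes and sum
#' to one.
#'
#' For a supercritical founder without unlinked load, `refine_founder`
#' (the default) replaces the delta approximation by the exact own-type
#' split: the founder's own type establishes with probability
#' \eqn{\frac{(\sigma-r)/(1-r)}{1-Q_{(I,J)}}}
#' (see [conditional_establishment_supercritical()]) and the complementary
#' mass is distributed over its recombination pathways. The two treatments
#' coincide as \eqn{r_{(I,J)} \to 0}; the refinement is what the
#' concatenated hitchhiking probability of a single linked allele is built
#' on, and it matters whenever \eqn{r_{(I,J)}} is comparable to
#' \eqn{\sigma_{(I,J)}^2/\sigma_{(0,0)}}. Classes interior to the
#' recursion always use the delta approximation.
#'
#' @inheritParams introgression_probability
#' @param refine_founder use the exact own-type split for a supercritical
#'   founder (see Details); `FALSE` gives the plain delta approximation.
#' @return An object of class `rescue_distribution`: matrix `P` over target
#'   classes (rows i = 0..I, columns j = 0..J).
#' @examples
#' sc <- scenario(10000,
#'                additive_selection(0.075, right_effects = c(0.005, 0.1)),
#'                uniform_recombination(0, 2, 1e-4))
#' rescue_distribution(sc)
#' @export
rescue_distribution <- function(sc, ext = NULL, refine_founder = TRUE) {
  stopifnot(inherits(sc, "scenario"))
  if (is.null(ext)) ext <- extinction_table(sc)
  I <- sc$I; J <- sc$J; Fn <- sc$F
  ## P[[i+1, j+1, f+1]]: rescue distribution for a process founded by one
  ## (i,j;f) individual, as an (I+1) x (J+1) matrix; NULL = no supercritical
  ## class reachable (the process cannot be rescued).
  P <- vector("list", (I + 1L) * (J + 1L) * (Fn + 1L))
  dim(P) <- c(I + 1L, J + 1L, Fn + 1L)
  zero <- matrix(0, I + 1L, J + 1L)

  for (ij in 0:(I + J)) for (i in 0:min(ij, I)) {
    j <- ij - i
    if (j > J) next
    rt <- r_total(sc$recombination, i, j)
    rl <- r_targets_left(sc$recombination, i, j)
    rr <- r_targets_right(sc$recombination, i, j)
    super <- sigma_of(sc$selection, i, j, 0L) - rt > 0
    for (f in 0:Fn) {
      if (super) {
        d <- zero; d[i + 1L, j + 1L] <- 1
        P[[i + 1L, j + 1L, f + 1L]] <- d
        next
      }
      w <- choose(f, 0:f) * 0.5^f
      num <- zero; den <- 0
      for (l in 0:f) {
        if (i > 0) for (k in 0:(i - 1L)) {
          surv <- ext$survival[k + 1L, j + 1L, l + 1L]
          tgt <- P[[k + 1L, j + 1L, l + 1L]]
          wt <- w[l + 1L] * rl[k + 1L] * surv
          if (wt > 0 && !is.null(tgt)) {
            num <- num + wt * tgt
            den <- den + wt
          }
        }
        if (j > 0) for (k in 0:(j - 1L)) {
          surv <- ext$survival[i + 1L, k + 1L, l + 1L]
          tgt <- P[[i + 1L, k + 1L, l + 1L]]
          wt <- w[l + 1L] * rr[k + 1L] * surv
          if (wt > 0 && !is.null(tgt)) {
            num <- num + wt * tgt
            den <- den + wt
          }
        }
        if (l < f) {  # non-recombinant birth shedding unlinked alleles only
          surv <- ext$survival[i + 1L, j + 1L, l + 1L]
          tgt <- P[[i + 1L, j + 1L, l + 1L]]
          wt <- w[l + 1L] * (1 - rt) * surv
          if (wt > 0 && !is.null(tgt)) {
            num <- num + wt * tgt
            den <- den + wt
          }
        }
      }
      if (den > 0) P[[i + 1L, j + 1L, f + 1L]] <- num / den
      # otherwise left NULL: no supercritical class reachable from here
    }
  }

  res <- P[[I + 1L, J + 1L, Fn + 1L]]
  if (is.null(res))
    stop("no supercritical haplotype is reachable from the founder; the rescue distribution is undefined")

  if (refine_founder && Fn == 0L && is_supercritical(sc, I, J)) {
    own <- conditional_establishment_supercritical(sc, ext)
    rl <- r_targets_left(sc$recombination, I, J)
    rr <- r_targets_right(sc$recombination, I, J)
    num <- zero; den <- 0
    if (I > 0) for (k in 0:(I - 1L)) {
      wt <- rl[k + 1L] * ext$survival[k + 1L, J + 1L, 1L]
      tgt <- P[[k + 1L, J + 1L, 1L]]
      if (wt > 0 && !is.null(tgt)) { num <- num + wt * tgt; den <- den + wt }
    }
    if (J > 0) for (k in 0:(J - 1L)) {
      wt <- rr[k + 1L] * ext$survival[I + 1L, k + 1L, 1L]
      tgt <- P[[I + 1L, k + 1L, 1L]]
      if (wt > 0 && !is.null(tgt)) { num <- num + wt * tgt; den <- den + wt }
    }
    if (den > 0) {
      res <- (1 - own) * num / den
      res[I + 1L, J + 1L] <- res[I + 1L, J + 1L] + own
    }
  }
  structure(list(P = res, I = I, J = J, F = Fn), class = "rescue_distribution")
}

#' @export
print.rescue_distribution <- function(x, ...) {
  cat(sprintf("Rescue-type distribution for founder (I,J;F) = (%d,%d;%d)\n",
              x$I, x$J, x$F))
  nz <- which(x$P > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz)))
    cat(sprintf("  P[(%d,%d)] = %.6g\n", nz[r, 1] - 1L, nz[r, 2] - 1L,
                x$P[nz[r, 1], nz[r, 2]]))
  invisible(x)
}

#' Conditional establishment probability of a supercritical founder
#'
#' For a supercritical founder class, the probability that the founder's own
#' type is the one that establishes, conditioned on survival of the
#' process: \eqn{P^{(I,J)}_{(I,J)} = \frac{(\sigma-r)/(1-r)}{1-Q_{(I,J)}}}.
#' Without recombination this equals 1 (survival and own-type establishment
#' coincide); its first-order expansion in r is
#' \eqn{1 - r\,\sigma_{(0,0)}(1-\sigma_{(I,J)})/\sigma_{(I,J)}^2}.
#'
#' @inheritParams introgression_probability
#' @export
conditional_establishment_supercritical <- function(sc, ext = NULL) {
  if (!is_supercritical(sc, sc$I, sc$J))
    stop("the founder class is not supercritical")
  if (is.null(ext)) ext <- extinction_table(sc)
  surv <- ext$survival[sc$I + 1L, sc$J + 1L, 1L]
  if (surv <= 0) stop("founder survival probability is 0")
  own_type_establishment(sigma_of(sc$selection, sc$I, sc$J, 0L),
                         r_total(sc$recombination, sc$I, sc$J)) / surv
}

#' Leading-order survival probability of a subcritical founder
#'
#' Diagnostic companion to the exact recursion: the expected number of
#' recombinant offspring founding successful lineages,
#' \deqn{\sum_k r^{(I,J)}_{target_k} (1 - Q_{target_k}) /
#'       (r_{(I,J)} - \sigma_{(I,J)}),}
#' which approximates \eqn{1 - Q_{(I,J)}} when at most one rescue lineage is
#' likely. A warning is issued when it deviates from the exact value by
#' more than 10 percent (the linear term overestimates when rescue is not
#' rare along a pathway).
#'
#' @inheritParams introgression_probability
#' @export
survival_leading_order <- function(sc, ext = NULL) {
  I <- sc$I; J <- sc$J
  s <- sigma_of(sc$selection, I, J, 0L)
  rt <- r_total(sc$recombination, I, J)
  if (s - rt >= 0) stop("the founder class must be subcritical")
  if (is.null(ext)) ext <- extinction_table(sc)
  num <- 0
  if (I > 0) num <- num + sum(r_targets_left(sc$recombination, I, J) *
                                ext$survival[seq_len(I), J + 1L, 1L])
  if (J > 0) num <- num + sum(r_targets_right(sc$recombination, I, J) *
                                ext$survival[I + 1L, seq_len(J), 1L])
  val <- num / (rt - s)
  exact <- ext$survival[I + 1L, J + 1L, 1L]
  if (exact > 0 && abs(val - exact) / exact > 0.1)
    warning(sprintf(
      "leading-order survival %.3g deviates from the exact value %.3g; the linear term overestimates here",
      val, exact))
  val
}
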