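#' Monte-Carlo estimates from the full Moran model
#'
#' Runs the exact stochastic model: a haploid Moran population of `N`
#' individuals into which one hybrid of class (I,J;F) is introduced. Each
#' event chooses two parents uniformly with replacement; with the
#' per-interval crossover probabilities of the scenario a single crossover
#' is placed in the linked block; each unlinked allele is transmitted from
#' either parent with probability 1/2; the offspring replaces a victim
#' drawn with probability proportional to \eqn{1-\sigma} (also with
#' replacement). A replicate is absorbed when the beneficial allele is lost
#' or when the population is monomorphic for one beneficial-carrying linked
#' haplotype (unlinked loci are ignored for absorption). Haplotypes that
#' carry introgressed deleterious alleles but not the beneficial allele are
#' tracked as real individuals.
#'
#' Two estimands are supported. By default every replicate is an
#' introgression attempt and the introgression probability is the success
#' fraction; with `establishment_threshold` set, a replicate already counts
#' as successful once the beneficial-allele count reaches that fraction of
#' `N` (extinction from such frequencies is vanishingly unlikely, and
#' stopping there makes large-replicate estimates affordable). With
#' `condition_on_success = TRUE` the simulator runs until `successes`
#' replicates have ended in fixation and reports the distribution of the
#' fixed linked haplotype — the hitchhiking estimand.
#'
#' @inheritParams introgression_probability
#' @param replicates number of introgression attempts (default mode).
#' @param seed integer seed (recorded in the result).
#' @param condition_on_success if `TRUE`, run until `successes` fixations.
#' @param successes target number of successful replicates in conditioned
#'   mode.
#' @param establishment_threshold optional frequency in (0, 1]; see above.
#' @param first_established_threshold optional frequency; when set, the
#'   first linked class whose carrier count reaches it is recorded per
#'   successful replicate (a direct observation of the rescue type).
#' @param max_attempts cap on attempts in conditioned mode.
#' @param max_events safety cap on events per replicate; replicates hitting
#'   it are reported in `nonconverged`.
#' @return An object of class `sim_estimate`.
#' @export
moran_estimate <- function(sc, replicates = 10000, seed = NULL,
                           condition_on_success = FALSE, successes = 1000,
                           establishment_threshold = NULL,
                           first_established_threshold = NULL,
                           max_attempts = 1e9, max_events = 1e9) {
  stopifnot(inherits(sc, "scenario"))
  if (!is.null(seed)) set.seed(seed)
  ints <- simulator_intervals(sc)
  sel <- sc$selection
  thresh <- if (is.null(establishment_threshold)) 0
            else ceiling(establishment_threshold * sc$N)
  firstc <- if (is.null(first_established_threshold)) 0
            else ceiling(first_established_threshold * sc$N)
  res <- .moran_run(as.integer(sc$N), sc$I, sc$J, sc$F,
                    ints$left, ints$right,
                    sel$additive,
                    if (sel$additive) sel$effects$sigma_ben else 0,
                    if (sel$additive) sel$effects$left else numeric(),
                    if (sel$additive) sel$effects$right else numeric(),
                    if (sel$additive) sel$effects$unlinked else 0,
                    if (sel$additive) numeric() else as.numeric(sel$sigma),
                    mode = if (condition_on_success) 1L else 0L,
                    replicates = if (condition_on_success) successes else replicates,
                    max_attempts = max_attempts,
                    thresh_count = thresh,
                    first_count = firstc,
                    max_events = max_events)
  p <- res$successes / res$attempts
  out <- list(introgression_prob = p,
              introgression_se = sqrt(p * (1 - p) / res$attempts),
              replicates = res$attempts, successes = res$successes,
              nonconverged = res$nonconverged, seed = seed,
              conditioned = condition_on_success)
  if (length(res$fixed_i)) {
    keys <- paste(res$fixed_i, res$fixed_j, sep = ",")
    tab <- table(keys)
    fp <- stats::setNames(as.numeric(tab) / length(keys), names(tab))
    out$fixation_dist <- fp
    out$fixation_se <- sqrt(fp * (1 - fp) / length(keys))
  }
  if (length(res$first_i)) {
    ok <- res$first_i >= 0
    keys <- paste(res$first_i[ok], res$first_j[ok], sep = ",")
    tab <- table(keys)
    out$first_established <- stats::setNames(as.numeric(tab) / length(keys),
                                             names(tab))
  }
  if (res$successes < 10)
    warning(sprintf("only %d successful replicates; estimates are unreliable",
                    as.integer(res$successes)))
  class(out) <- "sim_estimate"
  out
}

#' Run a single Moran replicate
#'
#' @inheritParams moran_estimate
#' @return A list with `outcome` (`"lost"` or `"fixed"`) and, for
#'   fixations, the fixed linked class `(i, j)`.
#' @export
moran_replicate <- function(sc, seed = NULL, max_events = 1e9) {
  est <- suppressWarnings(moran_estimate(sc, replicates = 1, seed = seed,
                                         max_events = max_events))
  if (est$nonconverged > 0) stop("replicate exceeded max_events")
  if (est$successes == 0) list(outcome = "lost")
  else list(outcome = "fixed",
            class = as.integer(strsplit(names(est$fixation_dist), ",")[[1]]))
}

## crossover interval probabilities shared verbatim with the analytics; a
## source-class-dependent matrix scheme has no single-crossover physical
## interpretation and is rejected
simulator_intervals <- function(sc) {
  rec <- sc$recombination
  if (rec$mode != "matrix")
    return(list(left = rec$left, right = rec$right))
  left <- if (sc$I > 0) r_targets_left(rec, sc$I, sc$J) else numeric()
  right <- if (sc$J > 0) r_targets_right(rec, sc$I, sc$J) else numeric()
  for (i in 0:sc$I) for (j in 0:sc$J) {
    tl <- r_targets_left(rec, i, j); tr <- r_targets_right(rec, i, j)
    if ((i > 0 && any(abs(tl - left[seq_len(i)]) > 1e-15)) ||
        (j > 0 && any(abs(tr - right[seq_len(j)]) > 1e-15)))
      stop("the recombination scheme is source-class dependent and cannot be realized by physical crossover intervals; the simulator requires an interval-consistent scheme")
  }
  list(left = left, right = right)
}

#' @export
print.sim_estimate <- function(x, ...) {
  cat(sprintf("Moran-model estimate (%s replicates, seed %s)\n",
              format(x$replicates, big.mark = ","),
              if (is.null(x$seed)) "unset" else x$seed))
  cat(sprintf("  introgression probability: %.6g (SE %.2g)\n",
              x$introgression_prob, x$introgression_se))
  if (!is.null(x$fixation_dist)) {
    for (k in seq_along(x$fixation_dist))
      cat(sprintf("  P[type (%s) fixes | success] = %.4f (SE %.4f)\n",
                  names(x$fixation_dist)[k], x$fixation_dist[k],
                  x$fixation_se[k]))
  }
  if (x$nonconverged > 0)
    cat(sprintf("  non-converged replicates: %d\n", as.integer(x$nonconverged)))
  invisible(x)
}
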