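#' Which haplotype ultimately fixes
#'
#' Concatenates the stochastic and deterministic phases: each positive-
#' fitness class (k,l) establishes in the stochastic phase with its rescue
#' probability, then either survives its sweep or is displaced by a fitter
#' recombinant, so that
#' \deqn{P(\mathrm{type}\ (i,j)\ \mathrm{fixes}) = \sum_{(k,l)}
#'   P^{(I,J;F)}_{(k,l)}\, P_{det}^{((k,l)\to(i,j))}.}
#' Deterministic-phase rows are computed in closed form when the
#' established class has at most one fitter escape target and that target
#' cannot itself be displaced; otherwise (or when `verify_mc = TRUE`) the
#' Monte-Carlo engine of [det_phase_monte_carlo()] is used.
#'
#' @inheritParams introgression_probability
#' @param mc_reps replicates for Monte-Carlo deterministic rows.
#' @param seed optional integer seed for the Monte-Carlo rows.
#' @param verify_mc force Monte-Carlo rows even where a closed form exists.
#' @return An object of class `fixation_distribution` with matrices
#'   `conditional` (fixation probabilities given successful introgression,
#'   summing to 1) and `unconditional` (multiplied by the introgression
#'   probability), the scalar `introgression_prob`, a matrix `se` of
#'   Monte-Carlo standard errors (0 for closed-form entries) and a `method`
#'   matrix.
#' @examples
#' sc <- scenario(500, additive_selection(0.012, right_effects = 0.002),
#'                uniform_recombination(0, 1, 0.003))
#' fixation_distribution(sc)
#' @export
fixation_distribution <- function(sc, mc_reps = 10000L, seed = NULL,
                                  verify_mc = FALSE) {
  ext <- extinction_table(sc)
  resc <- rescue_distribution(sc, ext)
  I <- sc$I; J <- sc$J
  cond <- matrix(0, I + 1L, J + 1L)
  se2 <- matrix(0, I + 1L, J + 1L)
  method <- matrix("", I + 1L, J + 1L)
  est_classes <- which(resc$P > 0, arr.ind = TRUE)

  for (rix in seq_len(nrow(est_classes))) {
    k <- est_classes[rix, 1L] - 1L; l <- est_classes[rix, 2L] - 1L
    w <- resc$P[k + 1L, l + 1L]
    row <- det_phase_row(sc, c(k, l), mc_reps = mc_reps, seed = seed,
                         verify_mc = verify_mc)
    for (nm in names(row$P)) {
      ij <- as.integer(strsplit(nm, ",")[[1L]])
      cond[ij[1L] + 1L, ij[2L] + 1L] <-
        cond[ij[1L] + 1L, ij[2L] + 1L] + w * row$P[nm]
      se2[ij[1L] + 1L, ij[2L] + 1L] <-
        se2[ij[1L] + 1L, ij[2L] + 1L] + (w * row$se[nm])^2
      cell <- method[ij[1L] + 1L, ij[2L] + 1L]
      if (!grepl(row$method, cell, fixed = TRUE))
        method[ij[1L] + 1L, ij[2L] + 1L] <- paste0(cell, if (nzchar(cell)) "+", row$method)
    }
  }
  p_intro <- introgression_probability(sc, ext)
  structure(list(conditional = cond, unconditional = cond * p_intro,
                 introgression_prob = p_intro, se = sqrt(se2),
                 method = method, I = I, J = J),
            class = "fixation_distribution")
}

## deterministic-phase row for one established class: closed form when the
## escape structure is a single terminal target, Monte-Carlo otherwise
det_phase_row <- function(sc, established, mc_reps, seed, verify_mc = FALSE) {
  k <- established[1L]; l <- established[2L]
  cand <- fitter_onestep_targets(sc, k, l)
  if (nrow(cand) == 0L) {
    return(list(P = stats::setNames(1, paste(k, l, sep = ",")),
                se = stats::setNames(0, paste(k, l, sep = ",")),
                method = "closed_form"))
  }
  terminal <- nrow(cand) == 1L &&
    nrow(fitter_onestep_targets(sc, cand$i[1L], cand$j[1L])) == 0L
  if (terminal && !verify_mc) {
    se <- sigma_of(sc$selection, k, l, 0L)
    sw <- sweep_model(sc$N, se, cand$sigma[1L], cand$r[1L],
                      nu_bar = effective_initial_size(se, r_total(sc$recombination, k, l)))
    pret <- retention_probability_single(sw, use_nu_bar = sw$nu_bar < 0.5 * sc$N)
    P <- c(pret, 1 - pret)
    names(P) <- c(paste(k, l, sep = ","), paste(cand$i[1L], cand$j[1L], sep = ","))
    return(list(P = P, se = stats::setNames(c(0, 0), names(P)),
                method = "closed_form"))
  }
  row <- det_phase_monte_carlo(sc, c(k, l), reps = mc_reps, seed = seed)
  list(P = row$P, se = row$se, method = "monte_carlo")
}

## fitter one-step escape targets (single crossover) of class (k,l)
fitter_onestep_targets <- function(sc, k, l) {
  se <- sigma_of(sc$selection, k, l, 0L)
  out <- data.frame(i = integer(), j = integer(), sigma = numeric(), r = numeric())
  rl <- r_targets_left(sc$recombination, k, l)
  rr <- r_targets_right(sc$recombination, k, l)
  if (k > 0) for (m in 0:(k - 1L)) {
    st <- sigma_of(sc$selection, m, l, 0L)
    if (rl[m + 1L] > 0 && st > se && st > 0)
      out <- rbind(out, data.frame(i = m, j = l, sigma = st, r = rl[m + 1L]))
  }
  if (l > 0) for (m in 0:(l - 1L)) {
    st <- sigma_of(sc$selection, k, m, 0L)
    if (rr[m + 1L] > 0 && st > se && st > 0)
      out <- rbind(out, data.frame(i = k, j = m, sigma = st, r = rr[m + 1L]))
  }
  out
}

#' @export
print.fixation_distribution <- function(x, ...) {
  cat(sprintf("Fixation distribution (introgression probability %.4g)\n",
              x$introgression_prob))
  nz <- which(x$conditional > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1L] - 1L; j <- nz[r, 2L] - 1L
    cat(sprintf("  P[type (%d,%d) fixes | introgression] = %.4f (%s%s)\n",
                i, j, x$conditional[i + 1L, j + 1L], x$method[i + 1L, j + 1L],
                if (x$se[i + 1L, j + 1L] > 0)
                  sprintf(", SE %.4f", x$se[i + 1L, j + 1L]) else ""))
  }
  invisible(x)
}

#' Hitchhiking probability of a haplotype
#'
#' The probability, conditioned on successful introgression, that the
#' haplotype `target = (i, j)` (the beneficial allele plus its i + j linked
#' deleterious alleles) fixes in the population; a read-off from
#' [fixation_distribution()].
#'
#' @inheritParams fixation_distribution
#' @param target integer vector (i, j).
#' @export
hitchhiking_probability <- function(sc, target = c(sc$I, sc$J),
                                    mc_reps = 10000L, seed = NULL) {
  fd <- fixation_distribution(sc, mc_reps = mc_reps, seed = seed)
  unname(fd$conditional[target[1L] + 1L, target[2L] + 1L])
}

#' Reduction factor due to a second, subcritical linked allele
#'
#' In the configuration I = 0, J = 2 with the outer allele subcritical
#' (\eqn{\sigma_{(0,2)} - r_{(0,2)} < 0}) and the inner one able to
#' hitchhike, the second allele reduces the hitchhiking probability of the
#' first by the factor
#' \deqn{c = \frac{1}{1 + \frac{r^{(0,2)}_{(0,1)}\sigma_{(0,1)}}
#'   {r^{(0,2)}_{(0,0)}\sigma_{(0,0)}}},}
#' equivalently \eqn{r^{(0,2)}_{(0,1)}/r^{(0,2)}_{(0,0)} =
#' \frac{1-c}{c}\frac{\sigma_{(0,0)}}{\sigma_{(0,1)}}}. Only the ratio of
#' recombination distances matters; the strength of the second allele does
#' not (provided it is strong enough to be subcritical).
#'
#' @inheritParams introgression_probability
#' @export
reduction_factor <- function(sc) {
  if (sc$I != 0 || sc$J != 2)
    stop("reduction_factor applies to the I = 0, J = 2 configuration")
  s00 <- sigma_of(sc$selection, 0, 0, 0L)
  s01 <- sigma_of(sc$selection, 0, 1, 0L)
  if (sigma_of(sc$selection, 0, 2, 0L) - r_total(sc$recombination, 0, 2) >= 0)
    stop("the outer allele must be subcritical for the reduction factor to apply")
  if (s01 - r_total(sc$recombination, 0, 1) <= 0)
    stop("the inner allele must itself be able to hitchhike")
  r00 <- r_target(sc$recombination, 0, 2, "right", 0)
  r01 <- r_target(sc$recombination, 0, 2, "right", 1)
  1 / (1 + r01 * s01 / (r00 * s00))
}

#' Back-of-envelope estimates for standard two-allele configurations
#'
#' Closed-form quick estimates, each labelled with its validity assumption
#' and returned as `NA` with `applicable = FALSE` when the scenario does
#' not match its configuration:
#' * `rescue_ratio`: for I = 0, J = 2 with the outer allele subcritical,
#'   \eqn{P^{(0,2)}_{(0,1)} \approx r_1\sigma_{(0,1)}/(r_0\sigma_{(0,0)} +
#'   r_1\sigma_{(0,1)})}.
#' * `hitchhiking`: the same ratio multiplied by the single-hitchhiker
#'   retention probability.
#' * `flanked`: for I = J = 1 with only (0,1) and (1,0) supercritical and
#'   (1,1) subcritical, the analogous ratio
#'   \eqn{r^{(1,1)}_{(0,1)}\sigma_{(0,1)} /
#'   (r^{(1,1)}_{(1,0)}\sigma_{(1,0)} + r^{(1,1)}_{(0,1)}\sigma_{(0,1)})}.
#' * `one_sided`: for I = 0 and general J with classes (0,0)..(0,j)
#'   supercritical, the rescue weights
#'   \eqn{P_{(0,k)} \approx r_k\sigma_{(0,k)}/\sum_{l\le j} r_l\sigma_{(0,l)}}.
#' * `relevance_threshold`: the second allele matters when its distance to
#'   the hitchhiker is below \eqn{r^{(0,1)}_{(0,0)}\sigma_{(0,0)}/\sigma_{(0,1)}}.
#'
#' @inheritParams introgression_probability
#' @return A list of entries `list(value, applicable, assumption)`.
#' @export
quick_estimates <- function(sc) {
  s <- function(i, j) sigma_of(sc$selection, i, j, 0L)
  out <- list()
  na_entry <- function(assumption)
    list(value = NA_real_, applicable = FALSE, assumption = assumption)

  if (sc$I == 0 && sc$J == 2 &&
      s(0, 2) - r_total(sc$recombination, 0, 2) < 0 &&
      s(0, 1) - r_total(sc$recombination, 0, 1) > 0) {
    r0 <- r_target(sc$recombination, 0, 2, "right", 0)
    r1 <- r_target(sc$recombination, 0, 2, "right", 1)
    ratio <- r1 * s(0, 1) / (r0 * s(0, 0) + r1 * s(0, 1))
    sw <- sweep_model(sc$N, s(0, 1), s(0, 0),
                      r_target(sc$recombination, 0, 1, "right", 0))
    out$rescue_ratio <- list(value = ratio, applicable = TRUE,
                             assumption = "outer allele subcritical, tight linkage")
    out$hitchhiking <- list(
      value = ratio * retention_probability_single(sw, use_nu_bar = sw$nu_bar < 0.5 * sc$N),
      applicable = TRUE,
      assumption = "outer allele subcritical, tight linkage")
    out$relevance_threshold <- list(value = r0 * s(0, 0) / s(0, 1),
                                    applicable = TRUE,
                                    assumption = "second allele matters below this distance")
  } else {
    out$rescue_ratio <- na_entry("requires I = 0, J = 2 with subcritical outer allele")
    out$hitchhiking <- out$rescue_ratio
    out$relevance_threshold <- out$rescue_ratio
  }

  if (sc$I == 1 && sc$J == 1 &&
      s(1, 1) - r_total(sc$recombination, 1, 1) < 0 &&
      s(0, 1) - r_total(sc$recombination, 0, 1) > 0 &&
      s(1, 0) - r_total(sc$recombination, 1, 0) > 0) {
    r01 <- r_target(sc$recombination, 1, 1, "left", 0)   # (1,1) -> (0,1)
    r10 <- r_target(sc$recombination, 1, 1, "right", 0)  # (1,1) -> (1,0)
    out$flanked <- list(
      value = r01 * s(0, 1) / (r10 * s(1, 0) + r01 * s(0, 1)),
      applicable = TRUE,
      assumption = "flanking configuration, (1,1) subcritical, both single hitchhikers viable")
  } else {
    out$flanked <- na_entry("requires I = J = 1 with subcritical (1,1)")
  }

  if (sc$I == 0 && sc$J >= 1) {
    sup <- vapply(0:sc$J, function(k)
      s(0, k) - r_total(sc$recombination, 0, k) > 0, logical(1))
    jmax <- if (any(sup)) max(which(sup)) - 1L else -1L
    ## applies when (0,0)..(0,jmax) are supercritical and (0,jmax+1).. are not
    if (jmax >= 0 && jmax < sc$J && all(sup[seq_len(jmax + 1L)])) {
      rk <- vapply(0:jmax, function(k)
        r_target(sc$recombination, 0, sc$J, "right", k), numeric(1))
      num <- rk * vapply(0:jmax, function(k) s(0, k), numeric(1))
      out$one_sided <- list(value = stats::setNames(num / sum(num),
                                                    paste0("0,", 0:jmax)),
                            applicable = TRUE,
                            assumption = "one-sided chain, tight linkage")
    } else out$one_sided <- na_entry("requires a subcritical founder with supercritical classes (0,0)..(0,j)")
  } else {
    out$one_sided <- na_entry("requires I = 0")
  }
  out
}
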