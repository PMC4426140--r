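#' Sweep model for the deterministic phase
#'
#' After the stochastic phase one carrier haplotype is established and
#' sweeps. Its frequency path is modelled deterministically (logistic
#' growth started from an effective initial size \eqn{\bar\nu}), while
#' fitter recombinants arise as a time-inhomogeneous branching process that
#' may displace it.
#'
#' @param N population size.
#' @param sigma_est Malthusian fitness of the established haplotype (> 0).
#' @param sigma_targets fitnesses of the one-step recombinant escape
#'   classes; each must exceed `sigma_est` (a less fit recombinant cannot
#'   displace the sweep).
#' @param r_targets recombination probabilities from the established class
#'   to those targets.
#' @param nu_bar effective initial size in individuals; defaults to
#'   \eqn{1/p_{est}} via [effective_initial_size()] with
#'   `r_total = sum(r_targets)`.
#' @return An object of class `sweep_model`.
#' @export
sweep_model <- function(N, sigma_est, sigma_targets, r_targets,
                        nu_bar = NULL) {
  stopifnot(length(sigma_targets) == length(r_targets))
  if (sigma_est <= 0) stop("sigma_est must be > 0")
  if (any(sigma_targets <= sigma_est))
    stop("every escape target must be fitter than the established haplotype")
  if (is.null(nu_bar))
    nu_bar <- effective_initial_size(sigma_est, sum(r_targets))
  if (nu_bar < 1) stop("nu_bar must be >= 1")
  structure(list(N = N, sigma_est = sigma_est,
                 sigma_targets = as.numeric(sigma_targets),
                 r_targets = as.numeric(r_targets), nu_bar = nu_bar),
            class = "sweep_model")
}

#' Effective initial size of an established lineage
#'
#' A lineage conditioned on establishment grows faster than the
#' deterministic path early on; this is absorbed by starting the logistic
#' path at the mean of the (exponential) effective-size distribution,
#' \eqn{\bar\nu = 1/p_{est} = (1-r)/(\sigma-r)}.
#'
#' @inheritParams own_type_establishment
#' @export
effective_initial_size <- function(sigma, r_total) {
  p <- own_type_establishment(sigma, r_total)
  if (p <= 0) stop("the class is not supercritical; no establishment to condition on")
  1 / p
}

#' Logistic sweep frequency
#'
#' \deqn{x(t) = \frac{\bar\nu e^{\sigma t}}{N - \bar\nu + \bar\nu e^{\sigma t}}}
#'
#' @param t time (units of Moran events per individual), >= 0.
#' @param sweep a [sweep_model()].
#' @export
logistic_frequency <- function(t, sweep) {
  stopifnot(all(t >= 0))
  nu <- sweep$nu_bar; N <- sweep$N; s <- sweep$sigma_est
  # overflow-safe form of nu e^{st} / (N - nu + nu e^{st})
  1 / (1 + (N - nu) / nu * exp(-s * t))
}

#' Establishment probability of an escape recombinant born at time T
#'
#' An escape recombinant with fitness \eqn{\sigma'} born while the
#' established type (fitness \eqn{\sigma}) is at frequency x faces death
#' rate \eqn{1 - \sigma' + x\sigma}; its establishment probability is
#' \deqn{p_{est}(T) = \frac{\sigma'(\sigma'-\sigma)}
#'   {(\sigma'-\sigma)(1-x(T)) + \sigma' x(T)}.}
#' It interpolates from \eqn{\sigma'} on an empty background to
#' \eqn{\sigma' - \sigma} once the sweep has completed.
#'
#' @inheritParams logistic_frequency
#' @param T birth time of the recombinant.
#' @param target index of the escape target in `sweep$sigma_targets`.
#' @export
escape_establishment_probability <- function(T, sweep, target = 1L) {
  st <- sweep$sigma_targets[target]
  se <- sweep$sigma_est
  x <- logistic_frequency(T, sweep)
  st * (st - se) / ((st - se) * (1 - x) + st * x)
}

#' Retention probability of a single hitchhiker during the sweep
#'
#' The established haplotype fixes iff no successful escape recombinant is
#' generated during its sweep. With a single escape target the expected
#' number of successful escapes integrates in closed form and
#' \deqn{P_{det} = \left(\frac{\sigma' - \frac{\bar\nu}{N}\sigma}
#'   {\sigma' - \sigma(1-\frac{\bar\nu}{N})}\right)^{-N r\,
#'   \sigma'(\sigma'-\sigma)/\sigma^2},}
#' where \eqn{\sigma} is the established fitness and \eqn{\sigma'} the
#' escape fitness. With `use_nu_bar = FALSE` the start of the sweep is
#' treated as negligible (\eqn{\bar\nu/N \to 0}) and the base collapses to
#' \eqn{\sigma'/(\sigma'-\sigma)}. Accounting for the conditioned fast
#' early growth matters quantitatively whenever \eqn{N(\sigma-r)} is small.
#'
#' @inheritParams logistic_frequency
#' @param use_nu_bar if `TRUE` (default) use the \eqn{\bar\nu} of `sweep`,
#'   requiring \eqn{\bar\nu < N/2}; if `FALSE` take the \eqn{\bar\nu/N \to 0}
#'   limit.
#' @return A probability.
#' @examples
#' sw <- sweep_model(500, 0.01, 0.012, 0.003)
#' retention_probability_single(sw)               # ~0.80
#' retention_probability_single(sw, use_nu_bar = FALSE)  # ~0.52
#' @export
retention_probability_single <- function(sweep, use_nu_bar = TRUE) {
  if (length(sweep$sigma_targets) != 1L)
    stop("retention_probability_single expects exactly one escape target")
  st <- sweep$sigma_targets; se <- sweep$sigma_est; r <- sweep$r_targets
  frac <- if (use_nu_bar) {
    if (sweep$nu_bar >= 0.5 * sweep$N)
      stop("the closed form requires nu_bar < N/2")
    sweep$nu_bar / sweep$N
  } else 0
  base <- (st - frac * se) / (st - se * (1 - frac))
  expo <- -sweep$N * r * st * (st - se) / se^2
  base^expo
}

#' Retention probability with several linked hitchhikers
#'
#' For a supercritical established class (I,J), the probability that all of
#' its deleterious alleles hitchhike to fixation is the product of
#' single-target retention factors over the I + J one-step recombinant
#' targets (each of which must be fitter than the established class):
#' \deqn{\prod_k \left(\frac{\sigma_k}{\sigma_k-\sigma_{(I,J)}}\right)
#'   ^{-N r_k \sigma_k(\sigma_k-\sigma_{(I,J)})/\sigma_{(I,J)}^2}.}
#' By default each factor uses the \eqn{\bar\nu/N \to 0} base; set
#' `use_nu_bar = TRUE` to correct every factor by the established class'
#' effective initial size.
#'
#' @inheritParams introgression_probability
#' @param established class (i, j) that established in the stochastic
#'   phase; defaults to the founder (I, J).
#' @param use_nu_bar see [retention_probability_single()].
#' @export
retention_probability_full <- function(sc, established = c(sc$I, sc$J),
                                       use_nu_bar = FALSE) {
  i <- established[1L]; j <- established[2L]
  se <- sigma_of(sc$selection, i, j, 0L)
  rt <- r_total(sc$recombination, i, j)
  if (se - rt <= 0) stop("the established class must be supercritical")
  nu <- effective_initial_size(se, rt)
  rl <- r_targets_left(sc$recombination, i, j)
  rr <- r_targets_right(sc$recombination, i, j)
  st <- c(if (i > 0) sc$selection$sigma[seq_len(i), j + 1L, 1L],
          if (j > 0) sc$selection$sigma[i + 1L, seq_len(j), 1L])
  rk <- c(rl, rr)
  if (length(st) == 0L) return(1)
  if (any(st <= se))
    stop("every one-step recombinant target must be fitter than the established class")
  prod(vapply(seq_along(st), function(k) {
    sw <- sweep_model(sc$N, se, st[k], rk[k], nu_bar = nu)
    retention_probability_single(sw, use_nu_bar = use_nu_bar)
  }, numeric(1)))
}

## ---------------------------------------------------------------------------
## Monte-Carlo deterministic phase with several competing escape types.
##
## Between establishment events, the frequencies of the established carrier
## classes follow the multi-type replicator dynamics with constant
## Malthusian fitnesses, which has the closed form
##   x_k(t) = c_k exp(sigma_k t) / (c_w + sum_m c_m exp(sigma_m t)).
## A candidate escape type c (fitter than every established type) born at
## time T establishes with probability p_c(T) solving the backward Riccati
## equation p' = -(sigma_c - sbar(t)) p + p^2, which in u = 1/p is linear
## and is integrated on a time grid. Successful candidates arrive as an
## inhomogeneous Poisson stream with intensity
##   sum_src N r_{src->c} x_src(t) (1 - x_tot(t)) p_c(t)
## and join the deterministic system at size 1/p_c(T).
## ---------------------------------------------------------------------------

## backward solve of u' = a(t) u - 1 on grid tt, terminal value u_end;
## returns u(tt). a >= 0 is assumed (candidate fitter than sbar).
riccati_u <- function(tt, a, u_end) {
  n <- length(tt)
  u <- numeric(n)
  u[n] <- u_end
  for (k in (n - 1L):1L) {
    dt <- tt[k + 1L] - tt[k]
    dA <- 0.5 * (a[k] + a[k + 1L]) * dt
    eA <- exp(-dA)
    ## u(t_k) = e^{-dA} u(t_{k+1}) + int_{t_k}^{t_{k+1}} e^{-(A(s)-A(t_k))} ds
    u[k] <- eA * u[k + 1L] + 0.5 * dt * (1 + eA)
  }
  u
}

#' Monte-Carlo deterministic phase
#'
#' Generalizes the single-target closed form to several competing escape
#' types. Per replicate, the established classes follow deterministic
#' (replicator) frequency paths; candidate escape recombinants fitter than
#' every currently established class arrive as a time-inhomogeneous Poisson
#' stream, thinned by their time-dependent establishment probability
#' (computed from a birth-death process whose death rate includes the mean
#' population fitness); accepted candidates join the deterministic system
#' at their effective initial size. A replicate ends when the leading class
#' reaches frequency \eqn{1 - \bar\nu_{lead}/N} — the same frequency window
#' over which the single-target closed form integrates its hazard, beyond
#' which the deterministic path is no longer trusted — and that class is
#' recorded as fixed.
#'
#' Candidates that are not fitter than the current leading class are
#' ignored: they would be displaced by the ongoing sweep and do not alter
#' the final outcome.
#'
#' @inheritParams retention_probability_full
#' @param reps number of Monte-Carlo replicates.
#' @param seed optional integer seed.
#' @param sample_nu if `TRUE`, draw the effective initial size of every
#'   established lineage from its exponential distribution instead of using
#'   the mean.
#' @param n_grid number of grid points per deterministic segment.
#' @param max_events safety cap on establishment events per replicate;
#'   replicates hitting it are reported as non-converged, not silently
#'   truncated.
#' @return An object of class `det_phase_row`: named vector `P` of fixation
#'   probabilities over final classes "i,j", binomial `se`, `reps`, and the
#'   number of non-converged replicates.
#' @export
det_phase_monte_carlo <- function(sc, established = c(sc$I, sc$J),
                                  reps = 10000L, seed = NULL,
                                  sample_nu = FALSE, n_grid = 400L,
                                  max_events = 12L) {
  i0 <- established[1L]; j0 <- established[2L]
  se0 <- sigma_of(sc$selection, i0, j0, 0L)
  rt0 <- r_total(sc$recombination, i0, j0)
  if (se0 - rt0 <= 0) stop("the established class must be supercritical")
  if (!is.null(seed)) set.seed(seed)
  N <- sc$N
  nu0 <- effective_initial_size(se0, rt0)

  ## positive-fitness classes reachable by allele loss, keyed "i,j"
  key <- function(i, j) paste(i, j, sep = ",")
  wins <- integer(0)
  nonconv <- 0L

  one_rep <- function() {
    ids <- matrix(c(i0, j0), ncol = 2)        # established classes
    sig <- se0
    nu <- if (sample_nu) max(1, stats::rexp(1, rate = 1 / nu0)) else nu0
    nus <- nu
    x <- min(nu / N, 0.45)
    events <- 0L
    t_off <- 0
    repeat {
      lead <- which.max(sig)
      ## the deterministic path is trusted up to frequency 1 - nu_lead/N
      ## (mirroring the integration window of the closed form); beyond it
      ## the leader is taken to fix without further successful escapes
      cw <- 1 - sum(x)
      target_f <- 1 - min(0.45, max(1, nus[lead]) / N)
      if (x[lead] >= target_f)
        return(key(ids[lead, 1L], ids[lead, 2L]))
      f_lead <- function(t) {
        e <- exp(sig * t)
        x[lead] * e[lead] / (cw + sum(x * e)) - target_f
      }
      t_hi <- 1
      while (f_lead(t_hi) < 0 && t_hi < 1e7) t_hi <- t_hi * 2
      if (t_hi >= 1e7) return(NA_character_)   # degenerate; report non-convergence
      T1 <- stats::uniroot(f_lead, c(0, t_hi), tol = 1e-8)$root
      tt <- seq(0, T1, length.out = n_grid + 1L)
      ee <- exp(outer(tt, sig))                 # (n_grid+1) x n_types
      den <- cw + as.numeric(ee %*% x)
      xx <- sweep(ee, 2, x, `*`) / den          # frequency paths
      xtot <- rowSums(xx)
      sbar <- as.numeric(xx %*% sig)

      ## candidate escape types: fitter than the leader, one crossover away
      cand <- list()
      for (m in seq_len(nrow(ids))) {
        ci <- ids[m, 1L]; cj <- ids[m, 2L]
        rl <- r_targets_left(sc$recombination, ci, cj)
        rr <- r_targets_right(sc$recombination, ci, cj)
        add <- function(ti, tj, r) {
          if (r <= 0) return()
          stgt <- sigma_of(sc$selection, ti, tj, 0L)
          if (stgt <= sig[lead]) return()
          if (any(ids[, 1L] == ti & ids[, 2L] == tj)) return()
          k <- key(ti, tj)
          if (is.null(cand[[k]]))
            cand[[k]] <<- list(i = ti, j = tj, sigma = stgt,
                               rate = rep(0, nrow(ids)))
          cand[[k]]$rate[m] <<- cand[[k]]$rate[m] + r
        }
        if (ci > 0) for (k in 0:(ci - 1L)) add(k, cj, rl[k + 1L])
        if (cj > 0) for (k in 0:(cj - 1L)) add(ci, k, rr[k + 1L])
      }
      if (length(cand) == 0L)
        return(key(ids[lead, 1L], ids[lead, 2L]))

      ## first successful escape, if any, before the leader fixes
      t_event <- Inf; c_event <- NULL; p_event <- NA_real_
      for (cd in cand) {
        a <- cd$sigma - sbar
        ## terminal value: the leader keeps sweeping logistically past the
        ## window, for which the Riccati solution is available in closed form
        xl <- xx[n_grid + 1L, lead]
        p_end <- cd$sigma * (cd$sigma - sig[lead]) /
          ((cd$sigma - sig[lead]) * (1 - xl) + cd$sigma * xl)
        u <- riccati_u(tt, a, 1 / p_end)
        p <- 1 / u
        lam <- N * as.numeric(xx %*% cd$rate) * (1 - xtot) * p
        H <- c(0, cumsum(0.5 * (lam[-1L] + lam[-length(lam)]) * diff(tt)))
        E <- stats::rexp(1)
        if (H[length(H)] >= E) {
          kk <- which(H >= E)[1L]
          frac <- (E - H[kk - 1L]) / max(H[kk] - H[kk - 1L], 1e-300)
          te <- tt[kk - 1L] + frac * (tt[kk] - tt[kk - 1L])
          if (te < t_event) {
            t_event <- te; c_event <- cd
            pk <- p[kk - 1L] + frac * (p[kk] - p[kk - 1L])
            p_event <- pk
          }
        }
      }
      if (!is.finite(t_event))
        return(key(ids[lead, 1L], ids[lead, 2L]))

      ## advance to the event and add the new established class
      e <- exp(sig * t_event)
      den_e <- cw + sum(x * e)
      x <- x * e / den_e
      nu_new <- if (sample_nu) max(1, stats::rexp(1, rate = p_event)) else 1 / p_event
      x_new <- min(nu_new / N, 0.45 * (1 - sum(x)))
      ids <- rbind(ids, c(c_event$i, c_event$j))
      sig <- c(sig, c_event$sigma)
      x <- c(x, x_new)
      nus <- c(nus, nu_new)
      t_off <- t_off + t_event
      events <- events + 1L
      if (events >= max_events) return(NA_character_)
    }
  }

  out <- character(reps)
  for (r in seq_len(reps)) out[r] <- one_rep()
  nonconv <- sum(is.na(out))
  out <- out[!is.na(out)]
  tab <- table(out)
  P <- as.numeric(tab) / length(out)
  names(P) <- names(tab)
  structure(list(P = P, se = sqrt(P * (1 - P) / length(out)),
                 reps = length(out), nonconverged = nonconv,
                 established = established),
            class = "det_phase_row")
}

#' @export
print.det_phase_row <- function(x, ...) {
  cat(sprintf("Deterministic-phase fixation row from class (%d,%d), %d replicates\n",
              x$established[1], x$established[2], x$reps))
  for (k in seq_along(x$P))
    cat(sprintf("  P[(%s)] = %.4f (SE %.4f)\n", names(x$P)[k], x$P[k], x$se[k]))
  if (x$nonconverged > 0)
    cat(sprintf("  non-converged replicates: %d\n", x$nonconverged))
  invisible(x)
}
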