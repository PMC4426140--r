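#' Model scenario
#'
#' A complete model instance: a haploid resident population of `N`
#' individuals into which a single hybrid enters carrying the beneficial
#' allele, `I` and `J` linked deleterious alleles to its left and right and
#' `F` unlinked ones, together with the fitness and recombination schemes
#' over all haplotype classes.
#'
#' @param N population size (haploid individuals), at least 2.
#' @param selection a [selection_table()] or [additive_selection()] scheme.
#' @param recombination a `recomb_scheme`; defaults to no recombination.
#' @return An object of class `scenario`.
#' @examples
#' sc <- scenario(10000,
#'                additive_selection(0.08, right_effects = c(0.01, 0.075)),
#'                uniform_recombination(0, 2, 1e-4))
#' introgression_probability(sc)
#' @export
scenario <- function(N, selection, recombination = NULL) {
  stopifnot(inherits(selection, "selection_scheme"))
  if (is.null(recombination))
    recombination <- uniform_recombination(selection$I, selection$J, 0)
  stopifnot(inherits(recombination, "recomb_scheme"))
  sc <- structure(list(N = as.numeric(N),
                       I = selection$I, J = selection$J, F = selection$F,
                       selection = selection, recombination = recombination),
                  class = "scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  if (!is.finite(sc$N) || sc$N < 2) stop("N must be a finite population size >= 2")
  if (sc$recombination$I != sc$I || sc$recombination$J != sc$J)
    stop(sprintf(
      "recombination scheme covers I = %d, J = %d but the selection scheme has I = %d, J = %d",
      sc$recombination$I, sc$recombination$J, sc$I, sc$J))
  for (i in 0:sc$I) for (j in 0:sc$J) {
    rt <- r_total(sc$recombination, i, j)
    if (rt < 0 || rt >= 1)
      stop(sprintf("r_total(%d,%d) = %g out of [0,1)", i, j, rt))
    for (f in 0:sc$F)
      if (sigma_of(sc$selection, i, j, f) >= 1)
        stop(sprintf("sigma_(%d,%d;%d) >= 1: death rate would be non-positive", i, j, f))
  }
  invisible(sc)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Introgression scenario: N = %g, I = %d, J = %d, F = %d\n",
              x$N, x$I, x$J, x$F))
  cat(sprintf("  sigma_(0,0;0) = %.6g, sigma_(I,J;F) = %.6g, r_(I,J) = %.6g\n",
              sigma_of(x$selection, 0, 0, 0),
              sigma_of(x$selection, x$I, x$J, x$F),
              r_total(x$recombination, x$I, x$J)))
  invisible(x)
}

#' Read and write scenario configuration files
#'
#' The configuration format is JSON (YAML is also accepted on reading when
#' the yaml package is installed) with fields `N`, `F`, `sigma_ben`,
#' `left_effects`, `right_effects`, `unlinked_effect`, an optional explicit
#' `sigma_table` (list of `{i, j, f, sigma}` entries, which overrides the
#' additive fields when present) and `recombination` with `mode` equal to
#' `"uniform"` (`rho` plus `I`, `J`), `"intervals"` (`left_intervals`,
#' `right_intervals`) or `"matrix"` (list of
#' `{i, j, side, k, r}` entries). All probabilities and fitnesses are
#' dimensionless.
#'
#' @param path file path.
#' @return `load_scenario()` returns a validated `scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  scenario_from_config(cfg)
}

scenario_from_config <- function(cfg) {
  need <- function(x, what) {
    if (is.null(x)) stop("config is missing required field: ", what)
    x
  }
  rcfg <- need(cfg$recombination, "recombination")
  mode <- need(rcfg$mode, "recombination$mode")
  rec <- switch(mode,
    uniform = uniform_recombination(need(rcfg$I, "recombination$I"),
                                    need(rcfg$J, "recombination$J"),
                                    need(rcfg$rho, "recombination$rho")),
    intervals = interval_recombination(
      as.numeric(unlist(rcfg$left_intervals)),
      as.numeric(unlist(rcfg$right_intervals))),
    matrix = {
      e <- need(rcfg$entries, "recombination$entries")
      e <- as.data.frame(e)
      I <- max(c(0L, e$i)); J <- max(c(0L, e$j))
      rL <- array(0, c(I + 1L, J + 1L, max(1L, I)))
      rR <- array(0, c(I + 1L, J + 1L, max(1L, J)))
      for (row in seq_len(nrow(e))) {
        if (e$side[row] == "left")
          rL[e$i[row] + 1L, e$j[row] + 1L, e$k[row] + 1L] <- e$r[row]
        else rR[e$i[row] + 1L, e$j[row] + 1L, e$k[row] + 1L] <- e$r[row]
      }
      matrix_recombination(if (I > 0) rL else NULL, if (J > 0) rR else NULL)
    },
    stop("unknown recombination mode: ", mode))

  Fn <- if (is.null(cfg$F)) 0L else as.integer(cfg$F)
  sel <- if (!is.null(cfg$sigma_table)) {
    tab <- as.data.frame(cfg$sigma_table)
    I <- max(tab$i); J <- max(tab$j); Ft <- max(c(0L, tab$f))
    sig <- array(NA_real_, c(I + 1L, J + 1L, Ft + 1L))
    for (row in seq_len(nrow(tab)))
      sig[tab$i[row] + 1L, tab$j[row] + 1L,
          (if (is.null(tab$f)) 0L else tab$f[row]) + 1L] <- tab$sigma[row]
    selection_table(sig)
  } else {
    additive_selection(need(cfg$sigma_ben, "sigma_ben"),
                       as.numeric(unlist(cfg$left_effects)),
                       as.numeric(unlist(cfg$right_effects)),
                       if (is.null(cfg$unlinked_effect)) 0 else cfg$unlinked_effect,
                       Fn)
  }
  scenario(need(cfg$N, "N"), sel, rec)
}

#' @rdname load_scenario
#' @param sc a `scenario`.
#' @export
write_scenario <- function(sc, path) {
  cfg <- list(N = sc$N, I = sc$I, J = sc$J, F = sc$F)
  sel <- sc$selection
  if (sel$additive) {
    cfg$sigma_ben <- sel$effects$sigma_ben
    cfg$left_effects <- sel$effects$left
    cfg$right_effects <- sel$effects$right
    cfg$unlinked_effect <- sel$effects$unlinked
  } else {
    grid <- expand.grid(i = 0:sc$I, j = 0:sc$J, f = 0:sc$F)
    grid$sigma <- mapply(function(i, j, f) sigma_of(sel, i, j, f),
                         grid$i, grid$j, grid$f)
    cfg$sigma_table <- grid
  }
  rec <- sc$recombination
  cfg$recombination <- if (rec$mode == "matrix") {
    rows <- list()
    for (i in 0:sc$I) for (j in 0:sc$J) {
      tl <- r_targets_left(rec, i, j); tr <- r_targets_right(rec, i, j)
      for (k in seq_along(tl))
        rows[[length(rows) + 1L]] <- data.frame(i = i, j = j, side = "left",
                                                k = k - 1L, r = tl[k])
      for (k in seq_along(tr))
        rows[[length(rows) + 1L]] <- data.frame(i = i, j = j, side = "right",
                                                k = k - 1L, r = tr[k])
    }
    list(mode = "matrix", entries = do.call(rbind, rows))
  } else {
    list(mode = "intervals", left_intervals = rec$left,
         right_intervals = rec$right)
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
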