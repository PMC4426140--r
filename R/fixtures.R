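#' Built-in scenario fixtures
#'
#' Ready-made scenarios covering the standard study configurations:
#' one beneficial allele with unlinked load (`fig2`, `fig3a`, `fig3b`),
#' a single linked hitchhiker at two population sizes (`fig4a`--`fig4d`,
#' `worked_example_10_2`), a second linked allele on the same side
#' (`fig5a`--`fig5d`, `fig7`) or flanking (`fig6a`--`fig6d`, `fig8`), and
#' many-allele architectures (`fig9`). Sweep fixtures carry a `sweep`
#' attribute with the parameter grid they are intended to be evaluated
#' over.
#'
#' @param name fixture name; call `scenario_fixtures()` for the list.
#' @return A `scenario` (with an optional `sweep` attribute).
#' @examples
#' sc <- scenario_fixture("worked_example_10_2")
#' hitchhiking_probability(sc, c(0, 1))
#' @export
scenario_fixture <- function(name) {
  f <- fixture_table()[[name]]
  if (is.null(f))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fixture_table()), collapse = ", "))
  f()
}

#' @rdname scenario_fixture
#' @export
scenario_fixtures <- function() names(fixture_table())

fixture_table <- function() list(
  fig2 = function() {
    ## beneficial allele with F unlinked alleles of constant total cost
    sc <- scenario(10000, additive_selection(0.08, unlinked_effect = 0.01, F = 4),
                   uniform_recombination(0, 0, 0))
    attr(sc, "sweep") <- list(F = 0:10, total_cost = 0.04)
    sc
  },
  fig3a = function() {
    sc <- scenario(10000,
                   additive_selection(0.075, right_effects = c(0.005, 0.02, 0.065),
                                      unlinked_effect = 0.01, F = 4),
                   uniform_recombination(0, 3, 1e-4))
    attr(sc, "sweep") <- list(F = 0:8)
    sc
  },
  fig3b = function() {
    sc <- scenario(10000,
                   additive_selection(0.075, right_effects = c(0.005, 0.02, 0.065),
                                      unlinked_effect = 0.05, F = 4),
                   uniform_recombination(0, 3, 1e-4))
    attr(sc, "sweep") <- list(F = 0:8)
    sc
  },
  fig4a = function() fig4_fixture(10000),
  fig4b = function() fig4_fixture(500),
  fig4c = function() fig4_fixture(10000),
  fig4d = function() fig4_fixture(500),
  fig5a = function() fig5_fixture(-0.03),
  fig5b = function() fig5_fixture(0.065),
  fig5c = function() fig5_fixture(-0.03),
  fig5d = function() fig5_fixture(0.065),
  fig6a = function() fig6_fixture(0.07, -0.025),   # sigma11 = -0.03
  fig6b = function() fig6_fixture(0.04, 0.03),     # sigma11 = -0.005
  fig6c = function() fig6_fixture(0.07, -0.025),
  fig6d = function() fig6_fixture(0.04, 0.03),
  fig7 = function() {
    sc <- fig5_fixture(-0.03)
    attr(sc, "sweep") <- list(sigma02 = seq(-0.08, 0.07, by = 0.005))
    sc
  },
  fig8 = function() {
    sc <- fig6_fixture(0.07, -0.025)
    attr(sc, "sweep") <- list(sigma10 = seq(-0.08, 0.07, by = 0.005))
    sc
  },
  fig9 = function() {
    sc <- scenario(10000,
                   additive_selection(0.08,
                                      left_effects = c(0.082, rep(0.01, 9)),
                                      right_effects = c(0.01, 0.075, rep(0.01, 8))),
                   uniform_recombination(10, 10, 1e-4))
    attr(sc, "sweep") <- list(I = 0:10, J = 2)
    sc
  },
  worked_example_10_2 = function()
    scenario(500, additive_selection(0.012, right_effects = 0.002),
             uniform_recombination(0, 1, 0.003))
)

fig4_fixture <- function(N) {
  sc <- scenario(N, additive_selection(0.012, right_effects = 0.002),
                 uniform_recombination(0, 1, 1e-4))
  attr(sc, "sweep") <- list(r01 = 10^seq(-5, -1.5, by = 0.25))
  sc
}

fig5_fixture <- function(sigma02) {
  sc <- scenario(10000,
                 additive_selection(0.075,
                                    right_effects = c(0.005, 0.07 - sigma02)),
                 uniform_recombination(0, 2, 1e-4))
  attr(sc, "sweep") <- list(r12 = 10^seq(-5, -1.5, by = 0.25))
  sc
}

fig6_fixture <- function(sigma01, sigma10) {
  sc <- scenario(10000,
                 additive_selection(0.075,
                                    left_effects = 0.075 - sigma10,
                                    right_effects = 0.075 - sigma01),
                 uniform_recombination(1, 1, 1e-4))
  attr(sc, "sweep") <- list(r10 = 10^seq(-5, -1.5, by = 0.25))
  sc
}

#' @rdname scenario_fixture
#' @param path output file for the fixture configuration.
#' @export
export_fixture <- function(name, path) {
  sc <- scenario_fixture(name)
  write_scenario(sc, path)
  invisible(path)
}

#' Write a result table
#'
#' Writes a data frame of results as TSV (default) or JSON, with floats at
#' full precision. Columns are whatever the producing function documented;
#' Monte-Carlo estimates always travel with their standard errors.
#'
#' @param table a data frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(format(table, digits = 17, trim = TRUE, scientific = NA),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}
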