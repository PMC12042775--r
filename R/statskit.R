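#' Welch's two-sided t test
#'
#' The unequal-variance t test:
#' `t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite (real-valued) degrees of freedom and a two-sided
#' p value from the central t distribution.
#'
#' @param a,b Numeric samples, each with n >= 2; not both of zero variance.
#' @return Object of class `welch_test`: `t_statistic`,
#'   `degrees_of_freedom`, `p_two_sided`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_validation("each sample needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    stop_validation("both samples have zero variance")
  na <- length(a); nb <- length(b)
  se2a <- va / na; se2b <- vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  structure(list(t_statistic = t, degrees_of_freedom = df,
                 p_two_sided = 2 * stats::pt(-abs(t), df)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch's t test (two-sided): t = %.4f, df = %.2f, p = %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_two_sided))
  invisible(x)
}

#' Bonferroni-corrected significance level
#'
#' `alpha / m` for `m` simultaneous tests (e.g. 0.05/2 = 0.025,
#' 0.05/4 = 0.0125).
#'
#' @param alpha Familywise level, 0 < alpha <= 1.
#' @param m Number of tests, >= 1.
#' @return Corrected per-test level.
#' @export
bonferroni_level <- function(alpha, m) {
  if (!(alpha > 0 && alpha <= 1)) stop_validation("alpha must be in (0, 1]")
  if (!is_count(m, 1)) stop_validation("m must be an integer >= 1")
  alpha / m
}

#' Fraction of vesicles carrying at least one tag
#'
#' Under Poisson labeling with mean `lambda` tag copies per vesicle, the
#' fraction of vesicles with at least one copy is `1 - exp(-lambda)` —
#' at lambda = 4.2 this already exceeds 98%.
#'
#' @param lambda Mean tag copies per vesicle (>= 0).
#' @return Fraction in [0, 1].
#' @export
poisson_labeled_fraction <- function(lambda) {
  if (any(lambda < 0)) stop_validation("lambda must be >= 0")
  1 - exp(-lambda)
}

#' Liposome mol\% equivalent to a vesicle surface density
#'
#' Converts a cellular ganglioside density to the total mol\% of a
#' symmetric-bilayer liposome whose *outer leaflet* matches the vesicle
#' surface density: `cell_mol_pct * enrichment * leaflet_factor`. With the
#' GM1 figures (0.0158 mol\% in cells, 29.7-fold enrichment in vesicles,
#' leaflet factor 2) this gives 0.94 mol\%.
#'
#' @param cell_mol_pct Ganglioside-to-lipid molar ratio in cells (mol\%).
#' @param enrichment Fold enrichment in the vesicle membrane vs cells.
#' @param leaflet_factor 2 for a symmetric bilayer in which the label
#'   distributes over both leaflets but only the outer one is compared;
#'   1 for an outer-leaflet-only density.
#' @return Equivalent liposome mol\% at full precision (round only when
#'   reporting).
#' @export
liposome_equivalent_molpct <- function(cell_mol_pct, enrichment,
                                       leaflet_factor = 2) {
  if (cell_mol_pct < 0 || enrichment < 0 || leaflet_factor < 0)
    stop_validation("all arguments must be >= 0")
  cell_mol_pct * enrichment * leaflet_factor
}
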