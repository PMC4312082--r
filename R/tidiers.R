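# broom-style tidiers for the fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_clustered_binary
#' @param x A `gee_fit`.
#' @param ... Unused.
#' @export
tidy.gee_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$robust_se),
         naive.std.error = unname(x$naive_se),
         statistic = unname(x$wald_z),
         p.value = unname(x$p.value))
}

#' @rdname fit_clustered_binary
#' @export
glance.gee_fit <- function(x, ...) {
  tibble(n = x$n, n.clusters = x$n_clusters, alpha = x$alpha,
         phi = x$phi, iterations = x$iterations)
}

#' @rdname anova_duncan
#' @param x An `anova_duncan` fit.
#' @param ... Unused.
#' @export
tidy.anova_duncan <- function(x, ...) {
  dplyr::mutate(x$groups, alpha = x$alpha)
}

#' @rdname anova_duncan
#' @export
glance.anova_duncan <- function(x, ...) {
  dplyr::mutate(x$anova, mse = x$mse, harmonic_n = x$harmonic_n)
}

#' @rdname prevalence_table
#' @param x A `prevalence_table`.
#' @param ... Unused.
#' @export
glance.prevalence_table <- function(x, ...) {
  tibble(n = sum(x$n), n_plaque = sum(x$n_plaque),
         overall_pct = attr(x, "overall_pct"))
}
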