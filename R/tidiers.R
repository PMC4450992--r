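#' Tidy a fitted stage mixture
#'
#' @param x A [fit_stage_mixture()] result.
#' @param ... Unused.
#' @return One row per mixture component: `component`, `weight`, `mean`,
#'   `variance`.
#' @export
tidy.stage_mixture <- function(x, ...) {
  tibble(component = seq_len(x$m), weight = x$tau, mean = x$mu,
         variance = x$sigma2)
}

#' One-row summary of a fitted stage mixture
#'
#' @param x A [fit_stage_mixture()] result.
#' @param ... Unused.
#' @return A tibble with `stage`, `m`, `n`, `loglik`, `bic`.
#' @export
glance.stage_mixture <- function(x, ...) {
  tibble(stage = x$stage, m = x$m, n = x$n, loglik = x$loglik, bic = x$bic)
}

#' Tidy a correlation matrix into long format
#'
#' @param x A [spearman_matrix()] result.
#' @param ... Unused.
#' @return A tibble with `gene1`, `gene2`, `rho` (all ordered pairs).
#' @export
tidy.correlation_matrix <- function(x, ...) {
  g <- x$genes
  tibble(gene1 = rep(g, times = length(g)),
         gene2 = rep(g, each = length(g)),
         rho = as.vector(x$rho))
}

#' Per-attractor summary of a simulation
#'
#' @param x A [simulate_population()] result.
#' @param ... Unused.
#' @return One row per attractor: `attractor`, `n_cells`, `fraction`.
#' @export
tidy.sim_result <- function(x, ...) {
  tibble(attractor = 1:3,
         n_cells = as.integer(round(x$fractions * x$config$n_cells)),
         fraction = unname(x$fractions))
}

#' One-row summary of a simulation
#'
#' @param x A [simulate_population()] result.
#' @param ... Unused.
#' @return A tibble with the model, perturbation flag (any unequal
#'   degradation rate), seed and the three attractor fractions.
#' @export
glance.sim_result <- function(x, ...) {
  tibble(model = x$model,
         perturbed = length(unique(x$params$gamma)) > 1,
         seed = x$config$seed,
         n_cells = x$config$n_cells,
         frac1 = x$fractions[["1"]],
         frac2 = x$fractions[["2"]],
         frac3 = x$fractions[["3"]])
}

#' Tidy the landscape surface into a long table
#'
#' @param x A [build_landscape()] result.
#' @param ... Unused.
#' @return The `(t, x, z, stage)` surface tibble.
#' @export
tidy.landscape_surface <- function(x, ...) x$surface
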