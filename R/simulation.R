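#' Configuration of the annealed differentiation simulation
#'
#' The population simulation pushes cells out of the progenitor attractor by
#' annealing the auto-activation strength: at step `t` (1-based) the circuit
#' runs with `alpha_t = alpha0 * alpha_decay^(t-1)` while each TF receives
#' additive Gaussian noise scaled by `noise_t = noise0 * noise_decay^(t-1)`.
#' As `alpha` falls the balanced progenitor state loses stability, leaving a
#' bistable system whose two attractors are the committed lineages.
#'
#' @param n_cells Cells per population (default 1000).
#' @param n_steps Simulation steps (default 100).
#' @param force_coeff Weight of the deterministic circuit force (default 0.2).
#' @param noise0 Initial noise coefficient (default 0.5).
#' @param noise_decay Per-step geometric decay of the noise (default 0.98).
#' @param alpha0 Initial auto-activation strength (default 1.5).
#' @param alpha_decay Per-step geometric decay of `alpha` (default 0.98).
#' @param init_mean,init_sd Mean and sd of the Gaussian initial
#'   concentrations (defaults 1.5 and 1; draws are clipped at 0), placing
#'   most cells near the progenitor state.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_cells = 1000, n_steps = 100, force_coeff = 0.2,
                       noise0 = 0.5, noise_decay = 0.98, alpha0 = 1.5,
                       alpha_decay = 0.98, init_mean = 1.5, init_sd = 1,
                       seed = 1) {
  if (n_cells < 1 || n_steps < 1) abort("need n_cells, n_steps >= 1")
  if (noise_decay <= 0 || noise_decay > 1 || alpha_decay <= 0 ||
      alpha_decay > 1) {
    abort("decay factors must lie in (0, 1]")
  }
  if (init_sd <= 0) abort("init_sd must be positive")
  structure(list(n_cells = as.integer(n_cells), n_steps = as.integer(n_steps),
                 force_coeff = force_coeff, noise0 = noise0,
                 noise_decay = noise_decay, alpha0 = alpha0,
                 alpha_decay = alpha_decay, init_mean = init_mean,
                 init_sd = init_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the differentiation of a cell population
#'
#' Each cell is a point in the circuit's state space, initialised with every
#' TF concentration drawn from `N(init_mean, init_sd)` clipped at 0. At step
#' `t` the state is updated by the explicit rule
#' `state <- state + force_coeff * rhs(state; alpha_t) + noise_t * eps`,
#' with `eps` i.i.d. standard normal per TF per cell, then clipped at 0
#' (negative concentrations are meaningless and, with an even Hill power,
#' would spuriously activate). After the last step each cell is assigned to
#' the nearest stable attractor of the terminal (fully annealed) system.
#'
#' @param model `"two_tf"` or `"two_cluster"`.
#' @param p [circuit_params()]; its `alpha` is overridden by the annealing
#'   schedule, its `gamma` pattern defines the (un)perturbed circuit.
#' @param cfg A [sim_config()].
#' @param terminal_fps Optional precomputed [find_fixed_points()] result for
#'   the terminal parameters (reused across seeds to avoid refitting).
#' @return A list of class `"sim_result"`: `final_states` (tibble of
#'   terminal coordinates plus `assignment`), `fractions` (named proportions
#'   for attractors `1`, `2`, `3`, summing to 1), `model`, `params`, `config`
#'   and `terminal_fps`.
#' @examples
#' \donttest{
#' res <- simulate_population("two_tf", circuit_params(),
#'                            sim_config(n_cells = 200, seed = 1))
#' res$fractions
#' }
#' @export
simulate_population <- function(model, p = circuit_params(),
                                cfg = sim_config(), terminal_fps = NULL) {
  model <- match.arg(model, c("two_tf", "two_cluster"))
  stopifnot(inherits(p, "circuit_params"), inherits(cfg, "sim_config"))
  d <- circuit_dim(model)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(cfg$seed)

  state <- matrix(pmax(rnorm(cfg$n_cells * d, cfg$init_mean, cfg$init_sd), 0),
                  nrow = cfg$n_cells, ncol = d)
  for (t in seq_len(cfg$n_steps)) {
    alpha_t <- cfg$alpha0 * cfg$alpha_decay^(t - 1)
    noise_t <- cfg$noise0 * cfg$noise_decay^(t - 1)
    p_t <- circuit_params(alpha = alpha_t, beta = p$beta, n = p$n, s = p$s,
                          gamma = p$gamma)
    force <- circuit_rhs(model, state, p_t)
    state <- state + cfg$force_coeff * force +
      noise_t * matrix(rnorm(cfg$n_cells * d), nrow = cfg$n_cells)
    state <- pmax(state, 0)
    if (any(state > 1e3)) {
      bad <- which(state > 1e3, arr.ind = TRUE)[1, 1]
      abort(paste0("simulation diverged for cell ", bad, " at step ", t))
    }
  }

  alpha_T <- cfg$alpha0 * cfg$alpha_decay^(cfg$n_steps - 1)
  p_final <- circuit_params(alpha = alpha_T, beta = p$beta, n = p$n, s = p$s,
                            gamma = p$gamma)
  if (is.null(terminal_fps)) {
    terminal_fps <- find_fixed_points(model, p_final,
                                      n_starts = if (d == 2) 15 else 9,
                                      coarse_4d = 5)
  }
  assignment <- assign_attractor(state, model, p_final, fps = terminal_fps)
  fractions <- setNames(tabulate(assignment, 3) / cfg$n_cells,
                        c("1", "2", "3"))
  final <- as_tibble(as.data.frame(state))
  names(final) <- if (d == 2) c("u", "v") else c("u1", "u2", "v1", "v2")
  if (d == 4) {
    final$x <- final$u1 + final$u2
    final$y <- final$v1 + final$v2
  }
  final$assignment <- assignment
  structure(list(final_states = final, fractions = fractions, model = model,
                 params = p, config = cfg, terminal_fps = terminal_fps),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Differentiation simulation (", x$model, "), ",
      x$config$n_cells, " cells, ", x$config$n_steps, " steps\n", sep = "")
  cat("fractions:", paste(sprintf("attractor %s = %.3f", names(x$fractions),
                                  x$fractions), collapse = ", "), "\n")
  invisible(x)
}

# label the stable attractors of a fixed-point set:
# 1 = dominant first TF/cluster, 3 = dominant second, 2 = balanced (if any)
attractor_labels <- function(fps, model) {
  stable <- fps[fps$kind == "stable", , drop = FALSE]
  if (nrow(stable) == 0) abort("the terminal system has no stable attractor")
  if (model == "two_tf") {
    a <- stable$u
    b <- stable$v
    pos <- cbind(stable$u, stable$v)
  } else {
    a <- stable$x
    b <- stable$y
    pos <- cbind(stable$x, stable$y)
  }
  diff <- a - b
  k <- nrow(stable)
  lab <- integer(k)
  if (k >= 3) {
    # most first-dominant root is 1, most second-dominant 3, middle 2;
    # extra marginal roots (if any) inherit the balanced label
    lab[] <- 2L
    lab[which.max(diff)] <- 1L
    lab[which.min(diff)] <- 3L
  } else if (k == 2) {
    lab <- ifelse(diff >= diff[order(diff, decreasing = TRUE)][1], 1L, 3L)
    lab[which.max(diff)] <- 1L
    lab[which.min(diff)] <- 3L
  } else {
    lab <- if (abs(diff) < 1e-6) 2L else if (diff > 0) 1L else 3L
  }
  list(labels = lab, positions = pos)
}

#' Assign cells to terminal attractors
#'
#' Labels each final state with the nearest stable fixed point of the
#' terminal (annealed) circuit, by Euclidean distance — measured in the
#' cluster totals `(x, y)` for the two-cluster model. Attractor 1 is the
#' root dominated by the first TF (or cluster), attractor 3 the root
#' dominated by the second, attractor 2 the balanced root when it still
#' exists. Exact distance ties break deterministically to the lower label.
#'
#' @param state Matrix of states (one row per cell) or a single state vector.
#' @param model `"two_tf"` or `"two_cluster"`.
#' @param p_final [circuit_params()] of the terminal system (annealed
#'   `alpha`); used only when `fps` is not supplied.
#' @param fps Optional precomputed [find_fixed_points()] for the terminal
#'   system.
#' @return Integer labels in `{1, 2, 3}`, one per cell.
#' @export
assign_attractor <- function(state, model, p_final, fps = NULL) {
  model <- match.arg(model, c("two_tf", "two_cluster"))
  d <- circuit_dim(model)
  m <- if (is.matrix(state)) state else matrix(state, nrow = 1)
  if (is.null(fps)) {
    fps <- find_fixed_points(model, p_final,
                             n_starts = if (d == 2) 15 else 9, coarse_4d = 5)
  }
  al <- attractor_labels(fps, model)
  pts <- if (model == "two_cluster") cbind(m[, 1] + m[, 2], m[, 3] + m[, 4])
         else m
  dist2 <- sapply(seq_len(nrow(al$positions)), function(k) {
    rowSums(sweep(pts, 2, al$positions[k, ])^2)
  })
  dist2 <- matrix(dist2, nrow = nrow(m))
  # order candidate attractors by label so ties resolve to the lower label
  ord <- order(al$labels)
  dist2 <- dist2[, ord, drop = FALSE]
  labs <- al$labels[ord]
  labs[apply(dist2, 1, function(z) which(z <= min(z) + 1e-9)[1])]
}

#' Compare lineage fractions across circuit configurations
#'
#' Summarises the four canonical simulation configurations (two-TF and
#' two-cluster, each unperturbed and with one degradation rate raised): per
#' configuration the mean fraction of cells in each attractor, and for each
#' model the perturbed-minus-unperturbed change. The headline robustness
#' contrast is the perturbed fraction of attractor 1 — the lineage whose TF
#' (or cluster member) is destabilised — which collapses in the two-TF
#' circuit but is buffered by the two-cluster circuit.
#'
#' @param results A named list with elements `two_tf`, `two_tf_perturbed`,
#'   `two_cluster`, `two_cluster_perturbed`; each a `sim_result` or a list
#'   of `sim_result`s over seeds (averaged).
#' @return A tibble with one row per configuration: `model`, `perturbed`,
#'   `n_runs`, `frac1`, `frac2`, `frac3` and `delta1`/`delta3` (change from
#'   the matching unperturbed run; `NA` for unperturbed rows).
#' @export
robustness_table <- function(results) {
  need <- c("two_tf", "two_tf_perturbed", "two_cluster",
            "two_cluster_perturbed")
  if (!all(need %in% names(results))) {
    abort(paste0("results must contain: ", paste(need, collapse = ", ")))
  }
  mean_frac <- function(r) {
    if (inherits(r, "sim_result")) r <- list(r)
    f <- do.call(rbind, lapply(r, function(x) x$fractions))
    c(colMeans(f), n_runs = length(r))
  }
  rows <- lapply(need, function(nm) {
    f <- mean_frac(results[[nm]])
    tibble(config = nm,
           model = sub("_perturbed$", "", nm),
           perturbed = grepl("perturbed$", nm),
           n_runs = as.integer(f[["n_runs"]]),
           frac1 = f[["1"]], frac2 = f[["2"]], frac3 = f[["3"]])
  })
  out <- dplyr::bind_rows(rows)
  base <- out[!out$perturbed, c("model", "frac1", "frac3")]
  out <- dplyr::left_join(out, base, by = "model",
                          suffix = c("", "_base"))
  out$delta1 <- ifelse(out$perturbed, out$frac1 - out$frac1_base, NA_real_)
  out$delta3 <- ifelse(out$perturbed, out$frac3 - out$frac3_base, NA_real_)
  out$frac1_base <- NULL
  out$frac3_base <- NULL
  pert <- out[out$perturbed, ]
  if (pert$frac1[pert$model == "two_cluster"] <=
      pert$frac1[pert$model == "two_tf"]) {
    warn(paste0("perturbed two-cluster fraction(1) does not exceed the ",
                "perturbed two-TF fraction(1); the robustness ordering ",
                "did not reproduce in this run"))
  }
  out
}
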