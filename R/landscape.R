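#' Project cells onto the landscape's cell-state axis
#'
#' Computes the first two principal components of the mean-subtracted
#' expression values (covariance PCA, applied internally if the input is not
#' already centred) and derives each cell's angular coordinate `theta`
#' about an origin shifted into a cell-free region of the PC1-PC2 plane.
#' The angle is measured counter-clockwise from the positive PC1 axis and
#' lies in (-pi, pi]. Sorting cells by `theta` orders them by fate along the
#' left-right axis of the epigenetic landscape.
#'
#' The sign of each principal component is fixed so that its
#' largest-magnitude gene loading is positive, making the projection (and
#' hence `theta`) reproducible across runs and platforms; raw PCA signs are
#' arbitrary. Cells falling within 1e-6 radians of the branch cut at
#' `theta = pi` are reported with a message, since densities estimated on
#' `theta` treat it as a linear coordinate.
#'
#' @param x An expression table.
#' @param origin Numeric length-2, the shifted origin `(pc1, pc2)` about
#'   which angles are taken (default `c(-0.5, 0)`, a cell-free spot for
#'   data on the qRT-PCR scale of the reference dataset), or `"auto"` to
#'   place the origin in a cell-free region below the point cloud at
#'   `(0, min(pc2) - 0.2 * range(pc2))`. From a below-cloud origin every
#'   cell lies in the upper half-plane, so `theta` stays inside `(0, pi)`
#'   (no fate can straddle the branch cut) and each fate occupies its own
#'   angular sector; use it when the PCA scale or orientation of the data
#'   differs from the reference dataset.
#' @return A tibble of class `"projected_cells"` with columns `cell_id`,
#'   `stage`, optionally `lineage`, `pc1`, `pc2`, `theta`; attributes
#'   `origin`, `rotation` (gene loadings) and `sdev`.
#' @examples
#' pr <- pca_project(generate_synthetic(synthetic_config(seed = 1)))
#' dplyr::count(pr, stage)
#' @export
pca_project <- function(x, origin = c(-0.5, 0)) {
  x <- as_tibble(x)
  genes <- setdiff(names(x), META_COLS)
  if (nrow(x) < 3 || length(genes) < 2) {
    abort("PCA projection needs at least 3 cells and 2 genes")
  }
  centred <- mean_subtract(x)
  m <- as.matrix(as.data.frame(centred)[, genes, drop = FALSE])
  pc <- prcomp(m, center = FALSE, scale. = FALSE)
  flip <- vapply(1:2, function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, 1:2, drop = FALSE], 2, flip, `*`)
  rot <- sweep(pc$rotation[, 1:2, drop = FALSE], 2, flip, `*`)
  if (identical(origin, "auto")) {
    origin <- c(0, min(scores[, 2]) - 0.2 * diff(range(scores[, 2])))
  }
  theta <- atan2(scores[, 2] - origin[2], scores[, 1] - origin[1])
  theta[theta <= -pi] <- pi
  near_cut <- abs(pi - abs(theta)) < 1e-6
  if (any(near_cut)) {
    inform(paste0(sum(near_cut), " cell(s) within 1e-6 of the angular branch",
                  " cut at theta = pi; consider moving `origin`"))
  }
  out <- dplyr::bind_cols(
    x[intersect(META_COLS, names(x))],
    tibble(pc1 = scores[, 1], pc2 = scores[, 2], theta = theta)
  )
  structure(out, origin = origin, rotation = rot, sdev = pc$sdev,
            class = c("projected_cells", class(tibble())))
}

#' Fit a per-stage Gaussian mixture on the angular coordinate
#'
#' Models the cell-state distribution of one developmental stage as a 1-D
#' Gaussian mixture over `theta`, choosing the number of cell types
#' (components) among `1:max_components` by BIC with unequal component
#' variances, as the mclust family of model-based clustering does. The
#' component count is the number of distinct cell types the stage supports:
#' 1 before the first bifurcation, 2 when ICM and TE separate, 3 once EPI,
#' PE and TE coexist.
#'
#' Component counts are only entertained when the stage can support them:
#' a count `m` requires on average at least `min_per_component` cells per
#' component (default 25), since each unequal-variance component spends
#' three parameters and, below a few dozen cells per component, chance gaps
#' in a unimodal sample are routinely mistaken for extra cell types. Among
#' counts whose BIC lies within 2 units of the optimum (the conventional
#' positive-evidence margin), the smallest count wins.
#'
#' @param theta Numeric vector of angular coordinates for cells of one stage
#'   (at least 5 values).
#' @param max_components Largest component count considered (default 4).
#' @param stage Optional stage label stored in the result.
#' @param variance_floor Lower bound on component variances; degenerate input
#'   (all values identical) yields a single component at this floor.
#' @param min_per_component Average cells required per component for a
#'   component count to be considered (default 25).
#' @return A list of class `"stage_mixture"` with elements `stage`, `m`
#'   (component count), `tau` (weights), `mu` (means, sorted increasing),
#'   `sigma2` (variances), `n`, `loglik`, `bic`.
#' @seealso [mixture_density()], [build_landscape()]
#' @export
fit_stage_mixture <- function(theta, max_components = 4, stage = NA,
                              variance_floor = 1e-6,
                              min_per_component = 25) {
  theta <- as.numeric(theta)
  if (length(theta) < 5) abort("need at least 5 cells to fit a stage mixture")
  max_components <- max(1L, min(max_components,
                                length(theta) %/% min_per_component))
  if (sd(theta) < sqrt(variance_floor)) {
    return(new_stage_mixture(stage, tau = 1, mu = mean(theta),
                             sigma2 = variance_floor,
                             n = length(theta), loglik = NA_real_,
                             bic = NA_real_))
  }
  n <- length(theta)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(1L)  # kmeans restarts; fitting is deterministic given the data
  cand <- list()
  for (G in seq_len(max_components)) {
    fit <- fit_gmm_1d(theta, G)
    if (is.null(fit)) next
    cand[[length(cand) + 1]] <- list(
      fit = fit, G = G,
      bic = mclust::bic("V", fit$loglik, n = n, d = 1, G = G))
  }
  if (length(cand) == 0) abort("mixture fitting failed for this stage")
  # smallest component count whose BIC is within 2 units of the maximum:
  # differences below the conventional positive-evidence threshold do not
  # justify an extra cell type
  bics <- vapply(cand, function(cc) cc$bic, numeric(1))
  best <- cand[[which(bics >= max(bics) - 2)[1]]]
  p <- best$fit$parameters
  sigma2 <- p$variance$sigmasq
  if (length(sigma2) == 1) sigma2 <- rep(sigma2, best$G)
  ord <- order(p$mean)
  new_stage_mixture(stage,
                    tau = p$pro[ord], mu = as.numeric(p$mean)[ord],
                    sigma2 = pmax(sigma2[ord], variance_floor),
                    n = n, loglik = best$fit$loglik, bic = best$bic)
}

# EM fit of a G-component unequal-variance 1-D Gaussian mixture.
# EM only finds a local optimum, so each G is started both from mclust's
# model-based hierarchical partition and from a multi-restart kmeans
# partition, keeping the better likelihood; the hierarchical start can
# strand a component across an empty gap, which kmeans avoids.
fit_gmm_1d <- function(x, G) {
  n <- length(x)
  fits <- list()
  default_fit <- tryCatch(
    mclust::Mclust(x, G = G, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  fits <- list(default_fit)
  if (G > 1) {
    fits[[2]] <- tryCatch({
      km <- stats::kmeans(x, centers = G, nstart = 20)
      mclust::me(data = x, modelName = "V", z = mclust::unmap(km$cluster))
    }, error = function(e) NULL)
  }
  fits <- Filter(function(f) !is.null(f) && is.finite(f$loglik), fits)
  if (length(fits) == 0) return(NULL)
  fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]
}

new_stage_mixture <- function(stage, tau, mu, sigma2, n, loglik, bic) {
  tau <- tau / sum(tau)
  structure(list(stage = stage, m = length(mu), tau = tau, mu = mu,
                 sigma2 = sigma2, n = n, loglik = loglik,
                 bic = suppressWarnings(max(bic))),
            class = "stage_mixture")
}

#' @export
print.stage_mixture <- function(x, ...) {
  cat("Gaussian mixture over theta",
      if (!is.na(x$stage)) paste0(" (stage ", x$stage, ")"), ": ",
      x$m, " component(s), n = ", x$n, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Mixture probability density
#'
#' Evaluates `f(x) = sum_k tau_k * N(x | mu_k, sigma2_k)`, the stage's
#' estimated cell-state density along the angular coordinate.
#'
#' @param sm A [fit_stage_mixture()] result.
#' @param x Numeric positions (radians).
#' @return Densities, the same length as `x`; always non-negative.
#' @export
mixture_density <- function(sm, x) {
  stopifnot(inherits(sm, "stage_mixture"))
  out <- numeric(length(x))
  for (k in seq_len(sm$m)) {
    out <- out + sm$tau[k] * dnorm(x, sm$mu[k], sqrt(sm$sigma2[k]))
  }
  out
}

#' Pseudo-potential scaling parameters
#'
#' The landscape height is the Boltzmann-form pseudo-potential
#' `U = -rho * ln(f) + omega`: high probability density maps to deep valleys.
#' `rho` and `omega` only scale and shift the surface; `tilt_rate` adds
#' `tilt_rate * t` along the developmental-time axis to depict the loss of
#' differentiation potency (a visual device, default 0); `floor_density`
#' bounds the density away from zero so `U` stays finite where `f`
#' underflows.
#'
#' @param rho Positive scale (default 1).
#' @param omega Additive offset (default 0).
#' @param tilt_rate Potential units added per unit stage time (default 0).
#' @param floor_density Small positive density floor (default 1e-12).
#' @return A list of class `"potential_params"`.
#' @export
potential_params <- function(rho = 1, omega = 0, tilt_rate = 0,
                             floor_density = 1e-12) {
  if (rho <= 0) abort("rho must be positive")
  if (floor_density <= 0) abort("floor_density must be positive")
  structure(list(rho = rho, omega = omega, tilt_rate = tilt_rate,
                 floor_density = floor_density), class = "potential_params")
}

#' Boltzmann pseudo-potential of a probability density
#'
#' @param f_value Non-negative density value(s).
#' @param params A [potential_params()].
#' @return `-rho * log(pmax(f_value, floor_density)) + omega`; strictly
#'   decreasing in `f_value` above the floor.
#' @export
pseudo_potential <- function(f_value, params = potential_params()) {
  stopifnot(inherits(params, "potential_params"))
  if (any(f_value < 0)) abort("densities must be non-negative")
  -params$rho * log(pmax(f_value, params$floor_density)) + params$omega
}

#' Assemble the Waddington landscape surface
#'
#' Builds the pseudo-potential surface `U(t, x)` over developmental time
#' `t = log2(stage)` and the angular coordinate `x`. At each observed stage
#' the row is the pseudo-potential of that stage's mixture; rows between
#' consecutive stages are filled by linear interpolation of `U` in `t`, and
#' the tilt term `tilt_rate * t` is added after interpolation. When the
#' projected cells are supplied, each cell is given ball coordinates
#' `(x = theta, t = stage time, z = U)` for rendering on the surface,
#' optionally coloured by the mean expression of a gene set (e.g. the
#' average of a lineage's TF cluster).
#'
#' @param mixtures List of [fit_stage_mixture()] results with distinct,
#'   increasing `stage` fields; at least two stages.
#' @param x_resolution Number of grid points along `x` (default 200).
#' @param params [potential_params()] controlling scale, tilt and floor.
#' @param cells Optional `projected_cells` tibble from [pca_project()].
#' @param x_range Numeric length-2 grid extent; defaults to the span of the
#'   cells' `theta` (or component means +/- 4 sd) padded by 10%.
#' @param interp_rows Interpolated rows between consecutive stages
#'   (default 10).
#' @param color_expr,color_genes Optional expression table and gene subset;
#'   each cell's colour scalar is its mean expression over `color_genes`.
#' @return A list of class `"landscape_surface"`: `surface` (tibble `t`,
#'   `x`, `z`, `stage` — `NA` stage for interpolated rows), `cells` (tibble
#'   with ball coordinates, or `NULL`), `params`.
#' @examples
#' m <- generate_synthetic(synthetic_config(seed = 1))
#' pr <- pca_project(m)
#' mixes <- lapply(split(pr$theta, pr$stage)[c("16", "32", "64")],
#'                 fit_stage_mixture)
#' for (s in names(mixes)) mixes[[s]]$stage <- as.integer(s)
#' surf <- build_landscape(mixes, x_resolution = 100)
#' @export
build_landscape <- function(mixtures, x_resolution = 200,
                            params = potential_params(), cells = NULL,
                            x_range = NULL, interp_rows = 10,
                            color_expr = NULL, color_genes = NULL) {
  stopifnot(length(mixtures) >= 2,
            all(vapply(mixtures, inherits, logical(1), "stage_mixture")))
  stages <- vapply(mixtures, function(m) as.numeric(m$stage), numeric(1))
  if (anyNA(stages) || anyDuplicated(stages) || is.unsorted(stages)) {
    abort("mixtures must carry distinct stage labels in increasing order")
  }
  if (is.null(x_range)) {
    if (!is.null(cells)) {
      x_range <- range(cells$theta)
    } else {
      x_range <- range(unlist(lapply(mixtures, function(m)
        c(m$mu - 4 * sqrt(m$sigma2), m$mu + 4 * sqrt(m$sigma2)))))
    }
    x_range <- x_range + c(-0.1, 0.1) * diff(x_range)
  }
  x_grid <- seq(x_range[1], x_range[2], length.out = x_resolution)
  t_obs <- stage_time(stages)
  u_obs <- lapply(mixtures, function(m)
    pseudo_potential(mixture_density(m, x_grid),
                     potential_params(params$rho, params$omega,
                                      tilt_rate = 0,
                                      floor_density = params$floor_density)))
  rows <- list()
  for (i in seq_along(stages)) {
    rows[[length(rows) + 1]] <- tibble(t = t_obs[i], x = x_grid,
                                       z = u_obs[[i]], stage = stages[i])
    if (i < length(stages) && interp_rows > 0) {
      for (j in seq_len(interp_rows)) {
        w <- j / (interp_rows + 1)
        tj <- (1 - w) * t_obs[i] + w * t_obs[i + 1]
        rows[[length(rows) + 1]] <- tibble(
          t = tj, x = x_grid,
          z = (1 - w) * u_obs[[i]] + w * u_obs[[i + 1]],
          stage = NA_real_)
      }
    }
  }
  surface <- dplyr::arrange(dplyr::bind_rows(rows), .data$t, .data$x)
  surface$z <- surface$z + params$tilt_rate * surface$t

  cell_tbl <- NULL
  if (!is.null(cells)) {
    idx <- match(cells$stage, stages)
    if (anyNA(idx)) {
      abort("every cell's stage needs a fitted mixture in `mixtures`")
    }
    z <- vapply(seq_len(nrow(cells)), function(i) {
      pseudo_potential(mixture_density(mixtures[[idx[i]]], cells$theta[i]),
                       params)
    }, numeric(1))
    z <- z + params$tilt_rate * stage_time(cells$stage)
    cell_tbl <- tibble(cell_id = cells$cell_id, stage = cells$stage,
                       x = cells$theta, t = stage_time(cells$stage), z = z)
    if (!is.null(color_expr) && !is.null(color_genes)) {
      v <- expr_values(color_expr)[, color_genes, drop = FALSE]
      cell_tbl$color <- rowMeans(v)[cell_tbl$cell_id]
    }
  }
  structure(list(surface = surface, cells = cell_tbl, params = params),
            class = "landscape_surface")
}

#' @export
print.landscape_surface <- function(x, ...) {
  st <- unique(x$surface$stage[!is.na(x$surface$stage)])
  cat("Waddington landscape surface: stages ", paste(st, collapse = ", "),
      "; grid ", length(unique(x$surface$x)), " x ",
      length(unique(x$surface$t)), "\n", sep = "")
  invisible(x)
}

#' Shapiro-Wilk normality check with Q-Q export
#'
#' Tests whether the angular coordinates of one stage (or one segment of a
#' stage) are consistent with a single Gaussian cell-state distribution, the
#' assumption behind modelling each cell type as one mixture component.
#' Stages containing several cell types fail the test while single-type
#' segments pass, which is the diagnostic used to justify the mixture model.
#'
#' @param theta Numeric vector, 3 to 5000 values.
#' @return A list with `statistic` (Shapiro-Wilk W), `p_value`, and
#'   `qq_points`, a tibble of ordered `(theoretical, sample)` normal
#'   quantile pairs for a Q-Q plot.
#' @export
validate_normality <- function(theta) {
  n <- length(theta)
  if (n < 3 || n > 5000) {
    abort("normality check requires between 3 and 5000 values")
  }
  sw <- shapiro.test(theta)
  s <- sort(theta)
  p <- (seq_len(n) - 0.375) / (n + 0.25)  # Blom plotting positions
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       qq_points = tibble(theoretical = qnorm(p), sample = s))
}

#' Fit mixtures for every stage of a projection
#'
#' Convenience wrapper: splits `theta` by stage and fits one
#' [fit_stage_mixture()] per stage with at least `min_cells` cells.
#'
#' @param projected A `projected_cells` tibble.
#' @param max_components Passed to [fit_stage_mixture()].
#' @param min_cells Stages with fewer cells are dropped (default 5).
#' @return A list of `stage_mixture` objects ordered by stage.
#' @export
fit_all_stages <- function(projected, max_components = 4, min_cells = 5) {
  split_theta <- split(projected$theta, projected$stage)
  split_theta <- split_theta[lengths(split_theta) >= min_cells]
  stages <- as.integer(names(split_theta))
  out <- lapply(seq_along(stages), function(i) {
    fit_stage_mixture(split_theta[[i]], max_components = max_components,
                      stage = stages[i])
  })
  out[order(stages)]
}
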