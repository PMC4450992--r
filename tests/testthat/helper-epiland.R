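# shared fixtures and independent oracles, built in code at test time

# a small, fast synthetic dataset (same generative model, fewer cells)
small_synth <- function(seed = 1, ...) {
  generate_synthetic(synthetic_config(
    cells_per_stage = c(`8` = 30, `16` = 40, `32` = 60, `64` = 80),
    seed = seed, ...))
}

# write a toy Ct table to a temp file and return the path
write_toy_ct <- function(dir = tempdir()) {
  path <- file.path(dir, "toy_ct.tsv")
  writeLines(c("cell_id\tstage\tg1\tg2",
               "c1\t1\t28\t20",
               "c2\t2\t19\t20",
               "c3\t4\t10\t20"), path)
  path
}

# independent attractor oracle: damped forward Euler integration to a
# terminus, from every point of a lattice; counts distinct end points
descent_termini <- function(model, p, domain = c(0, 3), resolution = 20,
                            dt = 0.05, steps = 3000, digits = 3) {
  rhs <- if (model == "two_tf") two_tf_rhs else two_cluster_rhs
  ax <- seq(domain[1], domain[2], length.out = resolution)
  grid <- as.matrix(expand.grid(ax, ax))
  if (model == "two_cluster") {
    grid <- cbind(grid[, 1] / 2, grid[, 1] / 2, grid[, 2] / 2, grid[, 2] / 2)
  }
  st <- grid
  for (i in seq_len(steps)) st <- pmax(st + dt * rhs(st, p), 0)
  unique(round(st, digits))
}
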