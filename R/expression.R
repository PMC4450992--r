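#' Single-cell expression tables
#'
#' An expression table is a tibble with one row per cell: a `cell_id` column
#' (unique character), a `stage` column (number of blastomeres, one of
#' 1, 2, 4, 8, 16, 32, 64), an optional `lineage` column
#' (`ICM`/`TE`/`EPI`/`PE`/`unknown`), and one numeric column per gene.
#' Values are expression units on the qRT-PCR scale `baseline - Ct`
#' (so 0 means undetected and larger means more expressed); they are always
#' finite and non-negative.
#'
#' @param x A data frame to validate / a validated expression table.
#' @return `as_expression_table()` returns the table with class
#'   `"epiland_expr"`; `expr_genes()` returns the gene column names;
#'   `expr_values()` returns the cells-by-genes numeric matrix with
#'   `cell_id` rownames.
#' @examples
#' m <- generate_synthetic(synthetic_config(seed = 1))
#' head(expr_genes(m))
#' dim(expr_values(m))
#' @name expression_table
NULL

META_COLS <- c("cell_id", "stage", "lineage")

#' @rdname expression_table
#' @export
as_expression_table <- function(x) {
  x <- as_tibble(x)
  if (!all(c("cell_id", "stage") %in% names(x))) {
    abort("an expression table needs `cell_id` and `stage` columns")
  }
  x$cell_id <- as.character(x$cell_id)
  if (anyDuplicated(x$cell_id)) {
    abort(paste0("duplicate cell id: ",
                 paste(unique(x$cell_id[duplicated(x$cell_id)]), collapse = ", ")))
  }
  stage <- suppressWarnings(as.integer(x$stage))
  bad <- is.na(stage) | !stage %in% STAGES
  if (any(bad)) {
    abort(paste0("stage must be one of ", paste(STAGES, collapse = "/"),
                 "; offending cells: ",
                 paste(head(x$cell_id[bad], 5), collapse = ", ")))
  }
  x$stage <- stage
  if ("lineage" %in% names(x)) {
    x$lineage <- as.character(x$lineage)
    bad <- !x$lineage %in% LINEAGES
    if (any(bad)) {
      abort(paste0("unknown lineage label: ",
                   paste(unique(x$lineage[bad]), collapse = ", ")))
    }
  }
  genes <- setdiff(names(x), META_COLS)
  if (length(genes) == 0) abort("no gene columns found")
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene column: ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  for (g in genes) {
    v <- x[[g]]
    if (!is.numeric(v)) {
      abort(paste0("non-numeric value in gene column `", g, "`"))
    }
    if (anyNA(v) || any(!is.finite(v))) {
      abort(paste0("missing or non-finite value in gene column `", g,
                   "` (missing values are not supported)"))
    }
    if (any(v < 0)) {
      abort(paste0("negative expression value in gene column `", g, "`"))
    }
  }
  class(x) <- c("epiland_expr", class(tibble()))
  x
}

#' @rdname expression_table
#' @export
expr_genes <- function(x) setdiff(names(x), META_COLS)

#' @rdname expression_table
#' @export
expr_values <- function(x) {
  m <- as.matrix(as.data.frame(x)[, expr_genes(x), drop = FALSE])
  rownames(m) <- x$cell_id
  m
}

#' Read a single-cell qRT-PCR expression table
#'
#' Reads a delimited text file (tab or comma separated, sniffed from the
#' header line) with columns `cell_id`, `stage`, optionally `lineage`, and one
#' column per gene. When `input_is_ct = TRUE`, raw Ct cycle-threshold values
#' are converted to expression units as `baseline - Ct`; Ct values above the
#' baseline (undetected transcripts) are clipped to expression 0 with a
#' warning, matching the convention that the assay's detection floor is the
#' baseline cycle.
#'
#' @param path Path to the delimited file.
#' @param baseline Ct baseline subtracted from raw Ct values (default 28).
#' @param input_is_ct If `TRUE`, values in the file are Ct cycles and are
#'   transformed to `baseline - Ct`; if `FALSE` (default) values are stored
#'   as-is and must already be non-negative expression units.
#' @return An expression table (see [as_expression_table()]).
#' @seealso [write_expression_table()], [generate_synthetic()]
#' @export
read_expression_table <- function(path, baseline = 28, input_is_ct = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  spec <- list(cell_id = readr::col_character(),
               stage = readr::col_integer())
  if ("lineage" %in% strsplit(header, delim, fixed = TRUE)[[1]]) {
    spec$lineage <- readr::col_character()
  }
  raw <- suppressWarnings(readr::read_delim(
    path, delim = delim,
    col_types = do.call(readr::cols,
                        c(spec, .default = list(readr::col_double()))),
    progress = FALSE, show_col_types = FALSE))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(paste0("could not parse `", path, "`: non-numeric value at row ",
                 prob$row[1], ", column ", prob$col[1]))
  }
  if (!"cell_id" %in% names(raw)) abort("missing `cell_id` column")
  if (!"stage" %in% names(raw)) abort("missing `stage` column")
  if (input_is_ct) {
    genes <- setdiff(names(raw), META_COLS)
    n_clip <- 0L
    for (g in genes) {
      expr <- baseline - raw[[g]]
      n_clip <- n_clip + sum(expr < 0, na.rm = TRUE)
      raw[[g]] <- pmax(expr, 0)
    }
    if (n_clip > 0) {
      warn(paste0(n_clip, " Ct value(s) above the baseline of ", baseline,
                  " clipped to expression 0"))
    }
  }
  as_expression_table(raw)
}

#' Write an expression table to a delimited file
#'
#' Inverse of [read_expression_table()] (with `input_is_ct = FALSE`): values
#' are written in full precision so that a write/read round trip reproduces
#' the table exactly.
#'
#' @param x An expression table.
#' @param path Output path; `.tsv` extension selects tab, anything else comma.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  x <- as_expression_table(x)
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(x, path)
  } else {
    readr::write_csv(x, path)
  }
  invisible(path)
}

#' Centre each gene across cells
#'
#' Subtracts the per-gene mean across all cells, the preprocessing applied
#' before PCA. The result keeps the expression-table layout but is allowed to
#' contain negative (centred) values, so it is returned as a plain tibble.
#' Applying the operation twice equals applying it once.
#'
#' @param x An expression table (or a previously centred tibble).
#' @return A tibble with the same columns; each gene column has mean zero.
#' @export
mean_subtract <- function(x) {
  x <- as_tibble(x)
  genes <- setdiff(names(x), META_COLS)
  for (g in genes) x[[g]] <- x[[g]] - mean(x[[g]])
  x
}

#' Configuration of the synthetic preimplantation dataset
#'
#' Describes a synthetic single-cell qRT-PCR experiment with the stage and
#' coexpression structure of mouse preimplantation development: unimodal cell
#' populations through the 16-cell stage, an ICM/TE split at the 32-cell
#' stage and an EPI/PE/TE trichotomy at the 64-cell stage, driven by three
#' gene clusters (TE-like, PE-like, EPI-like) that are positively correlated
#' within a cluster and anti-correlated across clusters.
#'
#' Defaults mirror the real dataset's shape: 442 cells across the seven
#' stages, 48 genes with cluster sizes 17/10/12 (the remaining 9 genes are
#' lineage-uninformative), expression on the `28 - Ct` scale (0 to 18 units).
#' Lineage proportions are 1:1 ICM:TE at the 32-cell stage and 1:1:2
#' EPI:PE:TE at the 64-cell stage, roughly the composition of a blastocyst.
#'
#' @param cells_per_stage Named integer vector, cells per stage.
#' @param n_genes Total number of genes.
#' @param cluster_sizes Sizes of the TE-like, PE-like and EPI-like clusters;
#'   must sum to at most `n_genes`.
#' @param within_cluster_corr Target correlation of the noise shared within a
#'   cluster, in (0, 1].
#' @param mean_high,mean_low Expression means of the "on" and "off" states.
#' @param noise_sd Per-measurement Gaussian standard deviation.
#' @param seed Integer seed making the draw reproducible.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(cells_per_stage = c(`1` = 8, `2` = 16, `4` = 24,
                                                 `8` = 48, `16` = 80,
                                                 `32` = 120, `64` = 146),
                             n_genes = 48,
                             cluster_sizes = c(TE = 17, PE = 10, EPI = 12),
                             within_cluster_corr = 0.15,
                             mean_high = 14,
                             mean_low = 2,
                             noise_sd = 1.5,
                             seed = 1) {
  cfg <- list(cells_per_stage = cells_per_stage, n_genes = as.integer(n_genes),
              cluster_sizes = cluster_sizes,
              within_cluster_corr = within_cluster_corr,
              mean_high = mean_high, mean_low = mean_low,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (length(cfg$cluster_sizes) != 3 || sum(cfg$cluster_sizes) > cfg$n_genes) {
    abort("cluster_sizes must be three counts summing to at most n_genes")
  }
  if (!all(as.integer(names(cells_per_stage)) %in% STAGES)) {
    abort(paste0("cells_per_stage names must be stages ",
                 paste(STAGES, collapse = "/")))
  }
  if (!(cfg$mean_high > cfg$mean_low && cfg$mean_low >= 0)) {
    abort("need mean_high > mean_low >= 0")
  }
  if (cfg$noise_sd <= 0) abort("noise_sd must be positive")
  if (cfg$within_cluster_corr <= 0 || cfg$within_cluster_corr > 1) {
    abort("within_cluster_corr must be in (0, 1]")
  }
  structure(cfg, class = "synthetic_config")
}

# per-lineage state means for the three gene clusters (TE, PE, EPI order)
synthetic_states <- function(cfg) {
  hi <- cfg$mean_high
  lo <- cfg$mean_low
  mid <- (hi + lo) / 2
  mid_hi <- (hi + mid) / 2
  list(
    progenitor = c(TE = mid, PE = mid, EPI = mid),
    ICM = c(TE = lo, PE = mid_hi, EPI = mid_hi),
    TE32 = c(TE = hi, PE = lo, EPI = lo),
    TE = c(TE = hi, PE = lo, EPI = lo),
    PE = c(TE = lo, PE = hi, EPI = mid),
    EPI = c(TE = lo, PE = mid, EPI = hi)
  )
}

#' Generate a synthetic single-cell expression dataset
#'
#' Draws an expression table from the generative model described in
#' [synthetic_config()]. Cells at stages up to 16 blastomeres come from a
#' single progenitor state with all clusters at an intermediate mean; 32-cell
#' cells split evenly between an ICM-like state (TE cluster off, PE/EPI
#' clusters intermediate-high) and a TE-like state (TE cluster on, others
#' off); 64-cell cells come from TE-high, PE-high and EPI-high states in a
#' 2:1:1 ratio. Noise within a cluster shares a per-cell latent factor so
#' that cluster members are positively correlated; values are clipped at 0
#' so the output always satisfies the expression-table invariants.
#'
#' @param cfg A [synthetic_config()].
#' @return An expression table with `lineage` labels (`unknown` before the
#'   32-cell stage).
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  states <- synthetic_states(cfg)
  ncl <- cfg$cluster_sizes
  cluster_of <- rep(c(names(ncl), "none"),
                    c(ncl, cfg$n_genes - sum(ncl)))
  gene_names <- synthetic_gene_names(cfg)
  mid <- (cfg$mean_high + cfg$mean_low) / 2
  r <- cfg$within_cluster_corr

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(cfg$seed)

  rows <- list()
  for (st in as.integer(names(cfg$cells_per_stage))) {
    n <- cfg$cells_per_stage[[as.character(st)]]
    lin <- if (st < 32) {
      rep("unknown", n)
    } else if (st == 32) {
      rep_len(c("ICM", "TE"), n)
    } else {
      rep_len(c("TE", "TE", "PE", "EPI"), n)
    }
    state_key <- ifelse(lin == "unknown", "progenitor",
                        ifelse(st == 32 & lin == "TE", "TE32", lin))
    vals <- matrix(0, n, cfg$n_genes)
    for (i in seq_len(n)) {
      mu_cl <- states[[state_key[i]]]
      mu <- ifelse(cluster_of == "none", mid, mu_cl[cluster_of])
      latent <- setNames(rnorm(3), names(ncl))
      shared <- ifelse(cluster_of == "none", 0, latent[cluster_of])
      eps <- rnorm(cfg$n_genes)
      vals[i, ] <- mu + cfg$noise_sd * (sqrt(r) * shared + sqrt(1 - r) * eps)
    }
    vals <- pmax(vals, 0)
    colnames(vals) <- gene_names
    rows[[as.character(st)]] <- dplyr::bind_cols(
      tibble(cell_id = sprintf("s%d_c%03d", st, seq_len(n)),
             stage = st, lineage = lin),
      as_tibble(vals)
    )
  }
  as_expression_table(dplyr::bind_rows(rows))
}

# gene names: marker genes of each lineage cluster first, then generic names
synthetic_gene_names <- function(cfg) {
  markers <- list(TE = c("Cdx2", "Eomes", "Gata3"),
                  PE = c("Gata4", "Gata6", "Sox17"),
                  EPI = c("Nanog", "Fgf4", "Sox2"))
  out <- character(0)
  for (cl in names(cfg$cluster_sizes)) {
    k <- cfg$cluster_sizes[[cl]]
    nm <- head(markers[[cl]], k)
    if (k > length(nm)) nm <- c(nm, sprintf("%s_g%02d", cl, seq_len(k - length(nm))))
    out <- c(out, nm)
  }
  extra <- cfg$n_genes - sum(cfg$cluster_sizes)
  if (extra > 0) out <- c(out, sprintf("other_g%02d", seq_len(extra)))
  out
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
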