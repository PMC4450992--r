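#' Gene-gene Spearman correlation at one stage
#'
#' Computes the pairwise Spearman rank correlation of gene expression
#' profiles over the cells of one developmental stage (default the 64-cell
#' stage, where all three lineages coexist and the TF clusters show their
#' clearest mutual structure). Ties receive average ranks. A gene that is
#' constant at the stage has no defined rank correlation; its entries are
#' set to 0 with a warning (diagonal stays 1).
#'
#' @param x An expression table.
#' @param stage Stage to subset on (default 64).
#' @return An object of class `"correlation_matrix"`: a list with `genes`
#'   and `rho`, a symmetric unit-diagonal matrix in `[-1, 1]`.
#' @export
spearman_matrix <- function(x, stage = 64) {
  x <- as_tibble(x)
  sub <- x[x$stage == stage, , drop = FALSE]
  if (nrow(sub) < 3) abort("need at least 3 cells at the requested stage")
  m <- as.matrix(as.data.frame(sub)[, setdiff(names(sub), META_COLS),
                                    drop = FALSE])
  const <- apply(m, 2, function(v) max(v) == min(v))
  rho <- suppressWarnings(cor(m, method = "spearman"))
  if (any(const)) {
    warn(paste0("constant gene(s) at stage ", stage, ": ",
                paste(colnames(m)[const], collapse = ", "),
                "; their correlations are reported as 0"))
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  diag(rho) <- 1
  structure(list(genes = colnames(m), rho = rho, stage = stage),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Spearman correlation of ", length(x$genes), " genes at the ",
      x$stage, "-cell stage\n", sep = "")
  invisible(x)
}

#' Hierarchical gene clusters from a correlation matrix
#'
#' Agglomerative hierarchical clustering of genes on the dissimilarity
#' `d = 1 - rho`, cut into `k` clusters. With `k = 3` on blastocyst-stage
#' data the clusters correspond to the TE, PE and EPI transcription-factor
#' modules; when the canonical markers are present, clusters are labelled by
#' which of *Cdx2* (TE), *Gata4* (PE) and *Nanog* (EPI) they contain.
#'
#' @param cm A [spearman_matrix()] result.
#' @param k Number of clusters (default 3, the two blastocyst bifurcations).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return A tibble of class `"gene_clusters"` with columns `gene`,
#'   `cluster` (integer id in dendrogram order) and `label` (marker-derived
#'   lineage name or `cluster<k>`), carrying the `hclust` tree as attribute
#'   `dendrogram` and the heatmap leaf order as attribute `ordering`.
#' @export
cluster_genes <- function(cm, k = 3, linkage = "complete") {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (k > length(cm$genes)) abort("k cannot exceed the number of genes")
  d <- as.dist(1 - cm$rho)
  hc <- hclust(d, method = linkage)
  assignment <- cutree(hc, k = k)
  markers <- c(Cdx2 = "TE", Gata4 = "PE", Nanog = "EPI")
  label_of <- setNames(paste0("cluster", seq_len(k)), seq_len(k))
  for (g in names(markers)) {
    if (g %in% cm$genes) label_of[as.character(assignment[g])] <- markers[[g]]
  }
  out <- tibble(gene = cm$genes,
                cluster = unname(assignment),
                label = unname(label_of[as.character(assignment)]))
  structure(out, dendrogram = hc, ordering = hc$order,
            class = c("gene_clusters", class(tibble())))
}

#' Mean within- versus between-cluster correlation
#'
#' Diagnostic for a gene partition: the average Spearman correlation of
#' gene pairs inside the same cluster versus pairs in different clusters.
#' A meaningful module structure has the former clearly above the latter.
#'
#' @param cm A [spearman_matrix()] result.
#' @param clusters A [cluster_genes()] result (or any tibble with `gene`
#'   and `cluster` columns covering `cm$genes`).
#' @return A tibble with one row: `within`, `between`, `separation`
#'   (their difference).
#' @export
cluster_separation <- function(cm, clusters) {
  idx <- match(cm$genes, clusters$gene)
  if (anyNA(idx)) abort("clusters must cover every gene of the matrix")
  cl <- clusters$cluster[idx]
  same <- outer(cl, cl, `==`)
  off <- !diag(length(cl))
  tibble(within = mean(cm$rho[same & off]),
         between = mean(cm$rho[!same]),
         separation = mean(cm$rho[same & off]) - mean(cm$rho[!same]))
}
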