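#' Cooccurrence weight of a gene pair
#'
#' For each sample the smaller of the two genes' hit counts is added to a
#' running total: `sum_samples min(count_a, count_b)`. The weight is
#' symmetric and never exceeds either gene's total hits.
#'
#' @param counts_a,counts_b Equal-length non-negative per-sample count
#'   vectors over the same samples.
#' @return Single numeric weight.
#' @export
#' @examples
#' pair_weight(c(3, 0, 2), c(1, 5, 2)) # 3
pair_weight <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) {
    stop("count vectors differ in length")
  }
  stopifnot(all(counts_a >= 0), all(counts_b >= 0))
  sum(pmin(counts_a, counts_b))
}

#' Build the gene cooccurrence network
#'
#' Node weight = total hits per gene across samples; edge weight for every
#' unordered gene pair = [pair_weight()]. All pairs are defined (zero-weight
#' edges can be dropped on export).
#'
#' @param counts Non-negative samples x genes count matrix with column names.
#' @return List of class `bis_cooccurrence`: `nodes`
#'   (`data.frame(gene, total_hits)`) and `edges`
#'   (`data.frame(gene_a, gene_b, weight)`).
#' @export
build_network <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0), !is.null(colnames(counts)))
  genes <- colnames(counts)
  nodes <- data.frame(gene = genes, total_hits = colSums(counts),
                      stringsAsFactors = FALSE, row.names = NULL)
  pairs <- utils::combn(length(genes), 2)
  edges <- data.frame(
    gene_a = genes[pairs[1, ]],
    gene_b = genes[pairs[2, ]],
    weight = vapply(seq_len(ncol(pairs)), function(k) {
      sum(pmin(counts[, pairs[1, k]], counts[, pairs[2, k]]))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges), class = "bis_cooccurrence")
}

#' Write a cooccurrence network as node and edge tables
#'
#' @param network A [build_network()] result.
#' @param nodes_path,edges_path Output TSV paths.
#' @param drop_zero Drop zero-weight edges on export.
#' @return Invisibly, the network.
#' @export
write_network <- function(network, nodes_path, edges_path,
                          drop_zero = FALSE) {
  stopifnot(inherits(network, "bis_cooccurrence"))
  edges <- network$edges
  if (drop_zero) edges <- edges[edges$weight > 0, , drop = FALSE]
  utils::write.table(network$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(network)
}
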