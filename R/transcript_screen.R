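#' Keep the best hit per read
#'
#' For each read id exactly one record is retained: lowest E-value, ties
#' broken by highest bit score, remaining ties by subject name ascending.
#' Idempotent on its own output.
#'
#' @param records Hit table with `qseqid`, `sseqid`, `evalue`, `bitscore`.
#' @return One record per distinct read id.
#' @export
best_hit_per_read <- function(records) {
  stopifnot(all(c("qseqid", "sseqid", "evalue", "bitscore") %in%
                  names(records)))
  if (nrow(records) == 0) return(records)
  ord <- order(records$qseqid, records$evalue, -records$bitscore,
               records$sseqid, method = "radix")
  out <- records[ord, , drop = FALSE]
  out <- out[!duplicated(out$qseqid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Depth- and length-normalized expression value
#'
#' `scale * count / (total_reads * protein_length_nt)`: hits per read per
#' coding nucleotide, scaled (by 1e9 by default) to a human-readable range.
#' Zero counts map to exactly 0; the value is strictly increasing in count,
#' halves when protein length doubles, and is invariant under scaling count
#' and reads together.
#'
#' @param count Non-negative hit count(s).
#' @param total_reads Total reads in the transcriptome (>= 1).
#' @param protein_length_nt Coding length in nucleotides (>= 3).
#' @param scale Scale factor (only relative comparisons are meaningful).
#' @return Numeric value(s).
#' @export
#' @examples
#' normalize_expression(10, 1e6, 1000) # 10
normalize_expression <- function(count, total_reads, protein_length_nt,
                                 scale = 1e9) {
  if (any(protein_length_nt < 3)) stop("protein_length_nt must be >= 3")
  if (any(total_reads < 1)) stop("total_reads must be >= 1")
  stopifnot(all(count >= 0))
  scale * count / (total_reads * protein_length_nt)
}

#' Expression profile of one metatranscriptome
#'
#' Filters records at the E-value cutoff, keeps the best hit per read,
#' tallies raw counts per roster gene and normalizes by read depth and
#' protein nucleotide length.
#'
#' @param records Raw hit table for the sample.
#' @param total_reads Total reads of the transcriptome.
#' @param roster A [bis_roster()].
#' @param max_evalue E-value cutoff.
#' @return List of class `expression_profile`: `raw_counts` and `expression`
#'   (named over the 18 roster genes), `total_reads`.
#' @export
expression_profile <- function(records, total_reads, roster = bis_roster(),
                               max_evalue = 0.001) {
  kept <- best_hit_per_read(filter_hits(records, max_evalue))
  counts <- count_hits(kept, roster)[roster$name]
  expr <- normalize_expression(counts, total_reads, roster$length_nt)
  names(expr) <- roster$name
  structure(list(raw_counts = counts, expression = expr,
                 total_reads = total_reads),
            class = "expression_profile")
}

#' Fraction of samples expressing at least a threshold number of genes
#'
#' A sample passes when at least `threshold_genes` roster genes have a
#' nonzero raw count.
#'
#' @param raw_counts Samples x genes matrix of raw (best-hit) counts.
#' @param threshold_genes Minimum expressed genes per passing sample.
#' @return List: `n_passing`, `n_samples`, `percent`.
#' @export
expression_presence <- function(raw_counts, threshold_genes = 15) {
  stopifnot(is.matrix(raw_counts), nrow(raw_counts) >= 1,
            threshold_genes >= 0)
  passing <- rowSums(raw_counts > 0) >= threshold_genes
  list(n_passing = sum(passing), n_samples = nrow(raw_counts),
       percent = 100 * sum(passing) / nrow(raw_counts))
}

#' Replicate-supported expression call per condition
#'
#' A gene is called expressed in a condition when it has a nonzero raw count
#' in at least `min_replicates` of the condition's replicate cultures.
#'
#' @param replicate_counts Replicates x genes matrix for one condition.
#' @param min_replicates Minimum supporting replicates (default 2 of 3).
#' @return Named logical vector over genes.
#' @export
replicate_expression_call <- function(replicate_counts, min_replicates = 2) {
  stopifnot(is.matrix(replicate_counts), min_replicates >= 1)
  colSums(replicate_counts > 0) >= min_replicates
}
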