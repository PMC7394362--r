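#' Write genome proteins as FASTA
#'
#' @param genome Genome protein table.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_protein_fasta <- function(genome, path) {
  seqs <- Biostrings::AAStringSet(setNames(genome$sequence,
                                           genome$protein_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*", "", names(seqs))
  out
}

#' Write / read a genome feature table
#'
#' Tab-separated with header: `replicon_id`, `protein_id`, `start`, `end`,
#' `strand`, `index`.
#'
#' @param genome Genome protein table.
#' @param path TSV path.
#' @return Invisibly `path` (write); the table (read).
#' @export
write_feature_table <- function(genome, path) {
  cols <- c("replicon_id", "protein_id", "start", "end", "strand", "index")
  utils::write.table(genome[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read a genome (feature table + protein FASTA)
#'
#' @param feature_path Feature table TSV.
#' @param fasta_path Protein FASTA.
#' @return Genome protein table with sequences attached.
#' @export
read_genome <- function(feature_path, fasta_path) {
  feats <- read_feature_table(feature_path)
  seqs <- read_protein_fasta(fasta_path)
  miss <- setdiff(feats$protein_id, names(seqs))
  if (length(miss)) stop("sequences missing for: ", miss[1])
  feats$sequence <- unname(seqs[feats$protein_id])
  feats[order(feats$index), , drop = FALSE]
}

#' Write / read an anchor hit table
#'
#' Tab-separated with header: `protein_id`, `profile`, `bitscore`, `evalue`.
#'
#' @param hits Anchor hit table.
#' @param path TSV path.
#' @export
write_anchor_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_anchor_hits
#' @export
read_anchor_hits <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read / write a 12-column tabular alignment hit file
#'
#' The standard headerless layout: `qseqid`, `sseqid`, `pident`, `length`,
#' `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#' `bitscore`.
#'
#' @param path File path.
#' @return `data.frame` with the 12 named columns.
#' @export
read_alignment_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) {
    return(empty_hit_table())
  }
  utils::read.table(path, sep = "\t", header = FALSE, col.names = cols,
                    stringsAsFactors = FALSE)
}

#' @rdname read_alignment_hits
#' @param records Hit table to write.
#' @export
write_alignment_hits <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read the sample metadata table
#'
#' Tab-separated with header: `sample_id`, `donor_id`, `group`, `body_site`,
#' `total_reads`.
#'
#' @param samples Metadata table.
#' @param path TSV path.
#' @export
write_sample_metadata <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a counts (or scores) matrix with row ids
#'
#' @param m Matrix with rownames.
#' @param path TSV path.
#' @param id_col Name of the leading id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, id_col = "sample_id") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(m) <- df[[id_col]]
  m
}

#' Write a locus summary table
#'
#' @param summary Locus summary from [find_bis_loci()].
#' @param path TSV path.
#' @export
write_loci_table <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write locus spans as GFF3
#'
#' @param summary Locus summary from [find_bis_loci()].
#' @param path GFF3 path.
#' @export
write_loci_gff3 <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(summary))) {
    attrs <- sprintf("ID=bis_locus_%d;architecture=%s;complete=%s", i,
                     summary$architecture[i],
                     tolower(summary$complete[i]))
    writeLines(paste(summary$replicon_id[i], "bisminer", "gene_cluster",
                     summary$start_nt[i], summary$end_nt[i], ".", ".", ".",
                     attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Write a taxonomic profile
#'
#' @param profile `data.frame(clade, abundance)`.
#' @param path Output path.
#' @export
write_taxonomic_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
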