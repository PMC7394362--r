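#' Aggregate sample hit profiles to donor level
#'
#' Per-gene hit counts are averaged across each donor's samples (to account
#' for donors sequenced more than once); the presence count is the number of
#' roster genes with a nonzero donor mean. Aggregation is independent of
#' sample order.
#'
#' @param counts Samples x genes count matrix, rownames = sample ids.
#' @param samples Metadata `data.frame` with `sample_id`, `donor_id`,
#'   `group`.
#' @param bacteroidetes Optional named per-sample Bacteroidetes percent;
#'   averaged per donor.
#' @return List of class `bis_donor_profiles`: `donors` (`data.frame`:
#'   `donor_id`, `group`, `n_samples`, `presence_count`, and `bacteroidetes`
#'   when supplied) and `mean_counts` (donors x genes matrix).
#' @export
aggregate_by_donor <- function(counts, samples, bacteroidetes = NULL) {
  stopifnot(is.matrix(counts),
            all(c("sample_id", "donor_id", "group") %in% names(samples)))
  idx <- match(rownames(counts), samples$sample_id)
  if (anyNA(idx)) {
    stop("sample without metadata: ",
         rownames(counts)[which(is.na(idx))[1]])
  }
  donor <- samples$donor_id[idx]
  if (anyNA(donor) || any(donor == "")) {
    stop("sample with unknown donor: ",
         rownames(counts)[which(is.na(donor) | donor == "")[1]])
  }
  n_samples <- rowsum(rep(1L, nrow(counts)), donor)
  mean_counts <- rowsum(counts, donor) / as.vector(n_samples)
  donor_ids <- rownames(mean_counts)
  donors <- data.frame(
    donor_id = donor_ids,
    group = samples$group[idx][match(donor_ids, donor)],
    n_samples = as.integer(n_samples[donor_ids, 1]),
    presence_count = as.integer(rowSums(mean_counts > 0)),
    stringsAsFactors = FALSE
  )
  if (!is.null(bacteroidetes)) {
    b <- bacteroidetes[rownames(counts)]
    if (anyNA(b)) stop("bacteroidetes abundance missing for some samples")
    bm <- rowsum(as.numeric(b), donor)
    donors$bacteroidetes <- bm[donor_ids, 1] / donors$n_samples
  }
  rownames(donors) <- NULL
  structure(list(donors = donors, mean_counts = mean_counts),
            class = "bis_donor_profiles")
}

#' Prevalence distribution of presence counts
#'
#' For each k in 0..`n_genes`, the percent of donors with presence count
#' exactly k and at least k. The >=-curve is non-increasing and starts at
#' 100% for k = 0.
#'
#' @param presence_counts Integer vector of per-donor presence counts.
#' @param n_genes Roster size.
#' @return `data.frame`: `k`, `pct_eq`, `pct_ge`.
#' @export
prevalence_distribution <- function(presence_counts, n_genes = 18) {
  stopifnot(length(presence_counts) > 0,
            all(presence_counts >= 0), all(presence_counts <= n_genes))
  k <- 0:n_genes
  n <- length(presence_counts)
  data.frame(
    k = k,
    pct_eq = 100 * vapply(k, function(x) sum(presence_counts == x),
                          numeric(1)) / n,
    pct_ge = 100 * vapply(k, function(x) sum(presence_counts >= x),
                          numeric(1)) / n
  )
}

#' Parse a taxonomic profile into phylum abundances
#'
#' Reads a two-column clade/abundance table (profiler output layout; `#`
#' comment lines skipped), extracts phylum-rank rows (clades whose final rank
#' is `p__`) and returns their percents keyed by phylum name.
#'
#' @param path Path to the profile file.
#' @return Named numeric vector of phylum percents.
#' @export
parse_taxonomic_profile <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- numeric(0)
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    value <- suppressWarnings(as.numeric(fields[2]))
    if (length(fields) != 2 || is.na(value)) {
      stop("unparseable taxonomic profile line ", i, " in ", path)
    }
    if (grepl("\\|p__[^|]+$", fields[1])) {
      out[sub(".*\\|p__", "", fields[1])] <- value
    }
  }
  out
}

#' Bacteroidetes relative abundance of a profile
#'
#' @param path Path to a clade/abundance profile file.
#' @return Bacteroidetes percent; 0 when the phylum is absent.
#' @export
bacteroidetes_abundance <- function(path) {
  phyla <- parse_taxonomic_profile(path)
  if ("Bacteroidetes" %in% names(phyla)) unname(phyla[["Bacteroidetes"]]) else 0
}

#' Length-normalized donor mean hits
#'
#' Divides donor-mean hit counts by each gene's coding length in nucleotides
#' (for outputs comparing genes of different sizes); off the main prevalence
#' path.
#'
#' @param mean_counts Donors x genes matrix of mean hits.
#' @param roster A [bis_roster()].
#' @return Matrix of mean hits per nucleotide.
#' @export
normalize_counts_by_length <- function(mean_counts, roster = bis_roster()) {
  stopifnot(all(colnames(mean_counts) %in% roster$name))
  len <- roster$length_nt[match(colnames(mean_counts), roster$name)]
  sweep(mean_counts, 2, len, "/")
}
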