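#' Filter alignment hit records at an E-value cutoff
#'
#' Retains records with `evalue <= max_evalue` (the cutoff is inclusive; the
#' threshold is configurable).
#'
#' @param records Hit table with at least `qseqid`, `sseqid`, `evalue`.
#' @param max_evalue E-value cutoff.
#' @return Retained rows.
#' @export
filter_hits <- function(records, max_evalue = 0.001) {
  stopifnot(all(c("qseqid", "sseqid", "evalue") %in% names(records)))
  ev <- suppressWarnings(as.numeric(records$evalue))
  bad <- which(is.na(ev) | ev < 0)
  if (length(bad)) {
    stop("malformed E-value in hit record row ", bad[1])
  }
  records[ev <= max_evalue, , drop = FALSE]
}

#' Tally hits per roster gene
#'
#' Counts all retained records per gene ("nonmutually exclusive": one read
#' may contribute to several genes; no best-hit selection in metagenome
#' mode). Subjects outside the roster are tallied under `"other"` with a
#' message.
#'
#' @param records Filtered hit table.
#' @param roster A [bis_roster()].
#' @return Named integer vector over the 18 roster genes plus `"other"`.
#' @export
count_hits <- function(records, roster = bis_roster()) {
  out <- setNames(integer(nrow(roster) + 1), c(roster$name, "other"))
  if (nrow(records) == 0) return(out)
  subj <- records$sseqid
  unknown <- !(subj %in% roster$name)
  if (any(unknown)) {
    message(sum(unknown), " hit(s) to subjects outside the roster counted ",
            "under 'other'")
    subj[unknown] <- "other"
  }
  tab <- table(subj)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Per-sample per-gene coverage score
#'
#' `log10(1e6 * hits / total_reads + 1)`: hits per million reads, log10(x+1)
#' transformed. Zero hits score exactly 0; the score is strictly increasing
#' in hits and invariant under scaling hits and reads together.
#'
#' @param hits Non-negative hit count(s).
#' @param total_reads Total reads in the sample (>= 1); recycled.
#' @return Numeric score(s).
#' @export
#' @examples
#' coverage_score(10, 1e6) # log10(11)
coverage_score <- function(hits, total_reads) {
  if (any(total_reads < 1)) stop("total_reads must be >= 1")
  stopifnot(all(hits >= 0))
  log10(1e6 * hits / total_reads + 1)
}

#' Build the samples x genes coverage score matrix
#'
#' @param counts Integer matrix, samples x roster genes (rownames = sample
#'   ids).
#' @param total_reads Per-sample total reads, recycled along rows.
#' @param body_site Optional per-sample body-site labels, attached as the
#'   `body_site` attribute for grouping.
#' @return Numeric matrix of coverage scores with the same dimnames.
#' @export
build_score_matrix <- function(counts, total_reads, body_site = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) >= 1,
            length(total_reads) %in% c(1L, nrow(counts)))
  m <- coverage_score(counts, matrix(rep(total_reads, length.out = nrow(counts)),
                                     nrow = nrow(counts), ncol = ncol(counts)))
  dimnames(m) <- dimnames(counts)
  if (!is.null(body_site)) {
    stopifnot(length(body_site) == nrow(counts))
    attr(m, "body_site") <- body_site
  }
  m
}

#' Per-body-site sample positivity
#'
#' A sample is positive when at least one roster gene has a nonzero count.
#' Body sites with no samples are absent from the output.
#'
#' @param counts Samples x genes count matrix.
#' @param body_site Per-sample body-site labels.
#' @return `data.frame`: `body_site`, `n_samples`, `n_with_hit`, `percent`.
#' @export
site_prevalence <- function(counts, body_site) {
  stopifnot(is.matrix(counts), length(body_site) == nrow(counts))
  positive <- rowSums(counts > 0) > 0
  sites <- sort(unique(body_site))
  out <- data.frame(
    body_site = sites,
    n_samples = vapply(sites, function(s) sum(body_site == s), integer(1)),
    n_with_hit = vapply(sites, function(s) sum(positive[body_site == s]),
                        integer(1)),
    stringsAsFactors = FALSE
  )
  out$percent <- 100 * out$n_with_hit / out$n_samples
  rownames(out) <- NULL
  out
}
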