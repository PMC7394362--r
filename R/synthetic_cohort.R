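#' Specify a synthetic metagenome cohort
#'
#' Describes the donor/sample structure and count model that
#' [generate_cohort()] realises. Defaults mirror a multi-cohort gut
#' metagenome study: 214 healthy donors, 103 with IBD (split into Crohn's
#' disease and ulcerative colitis) and 28 with prediabetes, each sequenced
#' one to five times. Per-sample per-gene read hits for the genes a donor
#' carries follow a negative binomial (over-dispersed, zero-inflated at low
#' means); the number of genes a donor carries is drawn around
#' `baseline_carried_mean`, reduced by `median_shift` for the IBD groups, so
#' the healthy-vs-IBD difference in donor-median presence counts is planted
#' at approximately `median_shift`.
#'
#' @param n_donors Named integer vector over groups (subset of `healthy`,
#'   `ibd_cd`, `ibd_uc`, `prediabetes`).
#' @param samples_per_donor Length-2 integer range (inclusive).
#' @param count_mean,count_dispersion Negative-binomial `mu` and `size` for
#'   carried genes.
#' @param baseline_carried_mean,carried_sd Normal model (rounded, clipped to
#'   0..18) for the number of roster genes a donor carries; core genes are
#'   sampled with 3x weight.
#' @param median_shift Planted reduction of carried genes in IBD donors.
#' @param reads_meanlog,reads_sdlog Log-normal model for per-sample total
#'   reads.
#' @param bacteroidetes_shape Named list of `c(alpha, beta)` Beta parameters
#'   per group for donor-level Bacteroidetes relative abundance (fraction,
#'   reported as percent).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_donors = c(healthy = 214, ibd_cd = 52, ibd_uc = 51,
                                     prediabetes = 28),
                        samples_per_donor = c(1, 5),
                        count_mean = 5, count_dispersion = 2,
                        baseline_carried_mean = 13, carried_sd = 2,
                        median_shift = 2,
                        reads_meanlog = log(1e6), reads_sdlog = 0.3,
                        bacteroidetes_shape = list(
                          healthy = c(10, 10), ibd_cd = c(8, 12),
                          ibd_uc = c(8, 12), prediabetes = c(10, 10)),
                        seed = 1L) {
  groups <- names(n_donors)
  if (is.null(groups) || length(n_donors) == 0) {
    stop("n_donors must be a nonempty named vector of group sizes")
  }
  bad <- setdiff(groups, c("healthy", "ibd_cd", "ibd_uc", "prediabetes"))
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  stopifnot(all(n_donors >= 0), count_dispersion > 0, count_mean >= 0,
            length(samples_per_donor) == 2,
            samples_per_donor[1] >= 1,
            samples_per_donor[2] >= samples_per_donor[1])
  spec <- list(n_donors = n_donors, samples_per_donor = samples_per_donor,
               count_mean = count_mean, count_dispersion = count_dispersion,
               baseline_carried_mean = baseline_carried_mean,
               carried_sd = carried_sd, median_shift = median_shift,
               reads_meanlog = reads_meanlog, reads_sdlog = reads_sdlog,
               bacteroidetes_shape = bacteroidetes_shape, seed = seed)
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic cohort of sample hit profiles
#'
#' Realises a [cohort_spec()]: draws each donor's carried gene set (core
#' genes preferred 3:1), the number of samples per donor, per-sample total
#' reads, per-sample per-gene hit counts, and donor-level Bacteroidetes
#' abundance.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `bis_cohort` with elements
#'   \describe{
#'     \item{samples}{`data.frame`: `sample_id`, `donor_id`, `group`,
#'       `body_site`, `total_reads`.}
#'     \item{counts}{integer matrix, samples x 18 roster genes, rownames =
#'       sample ids.}
#'     \item{donors}{`data.frame`: `donor_id`, `group`, `n_samples`,
#'       `carried` (planted gene count), `carried_genes` (comma-joined),
#'       `bacteroidetes` (planted percent).}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  roster <- bis_roster()
  weights <- ifelse(roster$core, 3, 1)
  with_seed(spec$seed, {
    donors_list <- list()
    samples_list <- list()
    counts_list <- list()
    for (grp in names(spec$n_donors)) {
      ng <- spec$n_donors[[grp]]
      if (ng == 0) next
      shift <- if (grp %in% c("ibd_cd", "ibd_uc")) spec$median_shift else 0
      carried_n <- pmin(18L, pmax(0L, round(
        rnorm(ng, spec$baseline_carried_mean - shift, spec$carried_sd))))
      shp <- spec$bacteroidetes_shape[[grp]] %||% c(10, 10)
      bact <- 100 * rbeta(ng, shp[1], shp[2])
      for (d in seq_len(ng)) {
        donor_id <- sprintf("%s_d%03d", grp, d)
        carried <- if (carried_n[d] > 0) {
          sample(roster$name, carried_n[d], prob = weights)
        } else {
          character(0)
        }
        ns <- sample(seq(spec$samples_per_donor[1],
                         spec$samples_per_donor[2]), 1L)
        cnt <- matrix(0L, nrow = ns, ncol = nrow(roster),
                      dimnames = list(NULL, roster$name))
        if (length(carried) > 0) {
          cnt[, carried] <- matrix(
            rnbinom(ns * length(carried), mu = spec$count_mean,
                    size = spec$count_dispersion),
            nrow = ns)
        }
        sample_ids <- sprintf("%s_s%d", donor_id, seq_len(ns))
        rownames(cnt) <- sample_ids
        total_reads <- pmax(1, round(rlnorm(ns, spec$reads_meanlog,
                                            spec$reads_sdlog)))
        samples_list[[donor_id]] <- data.frame(
          sample_id = sample_ids, donor_id = donor_id, group = grp,
          body_site = "gut", total_reads = total_reads,
          stringsAsFactors = FALSE)
        counts_list[[donor_id]] <- cnt
        donors_list[[donor_id]] <- data.frame(
          donor_id = donor_id, group = grp, n_samples = ns,
          carried = length(carried),
          carried_genes = paste(carried, collapse = ","),
          bacteroidetes = bact[d], stringsAsFactors = FALSE)
      }
    }
    samples <- do.call(rbind, samples_list)
    rownames(samples) <- NULL
    counts <- do.call(rbind, counts_list)
    donors <- do.call(rbind, donors_list)
    rownames(donors) <- NULL
    structure(list(samples = samples, counts = counts, donors = donors),
              class = "bis_cohort")
  })
}

#' Generate a per-read alignment hit table for one sample
#'
#' Emulates a 12-column tabular alignment file (BLAST outfmt 6 layout) for a
#' sample's gene hit counts: each true hit gets an E-value log-uniform on
#' 1e-30 to 1e-3, and an additional `decoy_rate` fraction of records carry
#' E-values above 1e-3 (up to 10) that downstream filtering at E <= 0.001 must
#' remove.
#'
#' @param counts Named non-negative integer vector over roster genes.
#' @param roster A [bis_roster()].
#' @param decoy_rate Fraction (of the true-hit total) of decoy records.
#' @param seed Integer seed.
#' @param sample_id Used to build read ids.
#' @return `data.frame` with the 12 standard columns `qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`.
#' @export
generate_alignment_hits <- function(counts, roster = bis_roster(),
                                    decoy_rate = 0, seed = NULL,
                                    sample_id = "S1") {
  stopifnot(decoy_rate >= 0, decoy_rate <= 1)
  counts <- counts[counts > 0]
  with_seed(seed, {
    n_true <- sum(counts)
    genes_true <- rep(names(counts), counts)
    n_decoy <- round(decoy_rate * n_true)
    genes_decoy <- if (n_decoy > 0) {
      sample(roster$name, n_decoy, replace = TRUE)
    } else {
      character(0)
    }
    genes <- c(genes_true, genes_decoy)
    n <- length(genes)
    if (n == 0) {
      return(empty_hit_table())
    }
    ev <- c(10^runif(n_true, -30, -3),
            10^runif(n_decoy, log10(0.0011), 1))
    alen <- sample(20:60, n, replace = TRUE)
    qs <- sample(1:40, n, replace = TRUE)
    slen_aa <- roster$length_aa[match(genes, roster$name)]
    ss <- vapply(slen_aa - alen + 1L,
                 function(u) sample.int(max(u, 1L), 1L), integer(1))
    data.frame(
      qseqid = sprintf("%s_r%06d", sample_id, seq_len(n)),
      sseqid = genes,
      pident = round(runif(n, 30, 100), 1),
      length = alen,
      mismatch = sample(0:10, n, replace = TRUE),
      gapopen = sample(0:2, n, replace = TRUE),
      qstart = qs,
      qend = qs + 3L * alen - 1L,
      sstart = ss,
      send = ss + alen - 1L,
      evalue = ev,
      bitscore = round(runif(n, 25, 150), 1),
      stringsAsFactors = FALSE
    )
  })
}

empty_hit_table <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), stringsAsFactors = FALSE)
}

#' Generate per-sample taxonomic profiles
#'
#' Emulates clade/relative-abundance profiler output: one two-column table
#' per sample with a kingdom row and phylum rows (Bacteroidetes, Firmicutes,
#' Proteobacteria, Actinobacteria) summing to 100 at each rank. Per-sample
#' Bacteroidetes values jitter around the donor's planted abundance.
#'
#' @param cohort A [generate_cohort()] result.
#' @param spec The [cohort_spec()] used (its seed, offset, drives the jitter).
#' @return Named list (by sample id) of `data.frame(clade, abundance)`.
#' @export
generate_taxonomic_profiles <- function(cohort, spec) {
  stopifnot(inherits(cohort, "bis_cohort"))
  donors <- cohort$donors
  samples <- cohort$samples
  with_seed(spec$seed + 77L, {
    out <- lapply(seq_len(nrow(samples)), function(i) {
      donor_bact <- donors$bacteroidetes[match(samples$donor_id[i],
                                               donors$donor_id)]
      x <- min(max(donor_bact + rnorm(1, 0, 2), 0.1), 99.0)
      rest <- 100 - x
      w <- abs(c(Firmicutes = 7, Proteobacteria = 2, Actinobacteria = 1) +
                 rnorm(3, 0, 0.2))
      other <- rest * w / sum(w)
      data.frame(
        clade = c("k__Bacteria",
                  "k__Bacteria|p__Bacteroidetes",
                  "k__Bacteria|p__Firmicutes",
                  "k__Bacteria|p__Proteobacteria",
                  "k__Bacteria|p__Actinobacteria"),
        abundance = c(100, x, other[["Firmicutes"]],
                      other[["Proteobacteria"]], other[["Actinobacteria"]]),
        stringsAsFactors = FALSE
      )
    })
    names(out) <- samples$sample_id
    out
  })
}
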