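#' Filter sheath anchor hits at the gathering thresholds
#'
#' Retains profile hits with bit score strictly greater than `min_bitscore`
#' and E-value strictly less than `max_evalue`, preserving input order.
#'
#' @param hits `data.frame` with columns `protein_id`, `bitscore`, `evalue`.
#' @param min_bitscore,max_evalue Gathering thresholds of the sheath profile.
#' @return The retained rows.
#' @export
filter_anchor_hits <- function(hits, min_bitscore = 31.4, max_evalue = 1e-9) {
  stopifnot(is.finite(min_bitscore), is.finite(max_evalue),
            all(c("protein_id", "bitscore", "evalue") %in% names(hits)))
  hits[hits$bitscore > min_bitscore & hits$evalue < max_evalue, ,
       drop = FALSE]
}

#' Extract the genome neighborhood around an anchor protein
#'
#' Returns the proteins whose genome-order index lies within `flank` of the
#' anchor's index, clipped to the table bounds.
#'
#' @param genome Genome protein table (see [generate_genome()]).
#' @param anchor_protein_id Protein id of the anchor.
#' @param flank Number of proteins taken on each side.
#' @return Ordered sub-table including the anchor.
#' @export
extract_neighborhood <- function(genome, anchor_protein_id, flank = 20) {
  stopifnot(flank >= 0)
  i <- match(anchor_protein_id, genome$protein_id)
  if (is.na(i)) stop("anchor protein not found in genome: ", anchor_protein_id)
  anchor_index <- genome$index[i]
  keep <- genome$index >= anchor_index - flank &
    genome$index <= anchor_index + flank
  genome[keep, , drop = FALSE]
}

#' Pairwise global-alignment identity of two protein sequences
#'
#' Needleman-Wunsch global alignment (match +2, mismatch -1, gap -2 by
#' default, no terminal-gap forgiveness); identity is the number of identical
#' aligned residue pairs divided by the length of the shorter sequence. Among
#' tied optimal alignments, the one with the most identical pairs is scored.
#'
#' @param a,b Nonempty amino-acid strings.
#' @param match,mismatch,gap Alignment scoring parameters.
#' @return Identity in `[0, 1]`.
#' @seealso [alignment_stats()] for identity plus aligned-fraction coverage.
#' @export
#' @examples
#' pairwise_identity("AAAA", "AAAT") # 0.75
pairwise_identity <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  alignment_stats(a, b, match, mismatch, gap)[["identity"]]
}

#' Alignment identity and coverage statistics
#'
#' @inheritParams pairwise_identity
#' @return Named numeric vector: `identity`, `coverage` (aligned non-gap
#'   pairs / shorter length), `score`, `matches`, `aligned`.
#' @export
alignment_stats <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  nw_stats_cpp(a, b, match, mismatch, gap)
}

#' Greedy centroid clustering at an identity threshold
#'
#' UCLUST-style greedy clustering: proteins are processed in descending
#' length order (ties broken by id, ascending); each joins the earliest
#' created cluster whose centroid it matches at identity >= threshold,
#' otherwise it founds a new cluster with itself as centroid. Every protein
#' lands in exactly one cluster, and membership is independent of input
#' order.
#'
#' @param proteins Named character vector of sequences (names are ids), or a
#'   `data.frame` with columns `protein_id` and `sequence`.
#' @param identity_threshold Identity threshold in `(0, 1]`.
#' @param match,mismatch,gap Alignment scoring (see [pairwise_identity()]).
#' @return List of clusters, each `list(centroid_id, member_ids, size)`, in
#'   cluster creation order.
#' @export
greedy_cluster <- function(proteins, identity_threshold = 0.5,
                           match = 2, mismatch = -1, gap = -2) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (is.data.frame(proteins)) {
    ids <- proteins$protein_id
    seqs <- proteins$sequence
  } else {
    ids <- names(proteins)
    seqs <- unname(proteins)
  }
  stopifnot(!is.null(ids), !anyDuplicated(ids), all(nchar(seqs) > 0))
  if (length(ids) == 0) return(list())
  ord <- order(-nchar(seqs), ids, method = "radix")
  ids <- ids[ord]
  seqs <- seqs[ord]
  assign <- greedy_cluster_cpp(seqs, identity_threshold, match, mismatch, gap)
  lapply(seq_len(max(assign)), function(k) {
    members <- ids[assign == k]
    list(centroid_id = members[1], member_ids = members,
         size = length(members))
  })
}

#' Drop clusters below a minimum size
#'
#' @param clusters Output of [greedy_cluster()].
#' @param min_size Minimum member count retained.
#' @return Filtered cluster list.
#' @export
filter_clusters <- function(clusters, min_size = 4) {
  stopifnot(min_size >= 1)
  clusters[vapply(clusters, function(cl) cl$size >= min_size, logical(1))]
}

#' Annotate cluster representatives against the roster references
#'
#' Assigns each representative the role of its best-identity reference,
#' provided identity >= `min_identity` over >= `min_coverage` of the shorter
#' sequence, else `"unannotated"`. All cluster members inherit their
#' centroid's role. The default identity threshold (0.45) sits between the
#' chance-identity ceiling of unrelated same-length-band proteins under the
#' global-alignment statistic (about 0.40) and the within-family identity of
#' true homologs, so random sequences stay unannotated.
#'
#' @param representatives Named character vector of representative sequences.
#' @param references Named character vector of the 18 roster reference
#'   sequences ([bis_reference_proteins()]).
#' @param roster A [bis_roster()] (maps reference names to roles).
#' @param min_identity,min_coverage Annotation thresholds.
#' @return Named character vector: representative id -> role.
#' @export
annotate_roles <- function(representatives,
                           references = bis_reference_proteins(),
                           roster = bis_roster(),
                           min_identity = 0.45, min_coverage = 0.5) {
  stopifnot(all(roster$name %in% names(references)))
  roles <- vapply(representatives, function(s) {
    best_role <- "unannotated"
    best_ident <- -1
    for (nm in roster$name) {
      st <- nw_stats_cpp(s, references[[nm]], 2, -1, -2)
      if (st[["identity"]] > best_ident &&
            st[["identity"]] >= min_identity &&
            st[["coverage"]] >= min_coverage) {
        best_ident <- st[["identity"]]
        best_role <- roster$role[roster$name == nm]
      }
    }
    best_role
  }, character(1))
  names(roles) <- names(representatives)
  roles
}

#' Trim an annotated neighborhood to a candidate locus
#'
#' The retained span is bounded by the outermost calls of the boundary roles
#' DUF4255 and FtsH/ATPase (inclusive), in whichever order they occur; if
#' either boundary role is absent the span runs from the first to the last
#' annotated gene.
#'
#' @param neighborhood `data.frame` with columns `replicon_id`, `protein_id`,
#'   `role` (role label or `"unannotated"`), in genome order; `start`/`end`
#'   coordinates are carried through when present.
#' @return A `bis_locus`: list with `replicon_id`, `gene_calls`
#'   (`data.frame(protein_id, role)`), `start_nt`/`end_nt` (when coordinates
#'   were supplied), `complete = NA`, `architecture = "unclassified"`.
#' @export
trim_locus <- function(neighborhood) {
  stopifnot(all(c("protein_id", "role") %in% names(neighborhood)))
  annotated <- which(neighborhood$role != "unannotated" &
                       !is.na(neighborhood$role))
  if (length(annotated) == 0) stop("neighborhood has no annotated roles")
  boundary <- which(neighborhood$role %in% c("duf4255", "ftsh_atpase"))
  has_both <- all(c("duf4255", "ftsh_atpase") %in% neighborhood$role)
  span <- if (has_both) range(boundary) else range(annotated)
  rows <- neighborhood[span[1]:span[2], , drop = FALSE]
  locus <- list(
    replicon_id = if ("replicon_id" %in% names(rows)) rows$replicon_id[1]
                  else NA_character_,
    gene_calls = data.frame(protein_id = rows$protein_id, role = rows$role,
                            stringsAsFactors = FALSE),
    start_nt = if ("start" %in% names(rows)) min(rows$start) else NA,
    end_nt = if ("end" %in% names(rows)) max(rows$end) else NA,
    complete = NA,
    architecture = "unclassified"
  )
  class(locus) <- "bis_locus"
  locus
}

#' Is a locus complete?
#'
#' A locus is complete when it carries at least one call of each role in
#' [bis_core_roles()]: the three baseplate proteins, a sheath, a tube and the
#' FtsH/ATPase.
#'
#' @param locus A `bis_locus` from [trim_locus()].
#' @return Logical.
#' @export
assess_completeness <- function(locus) {
  stopifnot(inherits(locus, "bis_locus"))
  all(bis_core_roles() %in% locus$gene_calls$role)
}

#' Classify the architecture of a complete locus
#'
#' Rule order: architecture 3 if the FtsH/ATPase call precedes the DUF4157
#' call (the inverted pair of the compact arrangement); else architecture 1
#' if the locus has >= 2 sheath and >= 2 tube calls; else architecture 2 if
#' it has exactly one sheath call; else `"unclassified"`. Incomplete loci are
#' always `"unclassified"`.
#'
#' @param locus A `bis_locus` whose `complete` field has been set (see
#'   [assess_completeness()]).
#' @return `"1"`, `"2"`, `"3"` or `"unclassified"`.
#' @export
classify_architecture <- function(locus) {
  stopifnot(inherits(locus, "bis_locus"))
  if (!isTRUE(locus$complete)) return("unclassified")
  roles <- locus$gene_calls$role
  f <- match("ftsh_atpase", roles)
  d <- match("duf4157", roles)
  if (!is.na(f) && !is.na(d) && f < d) return("3")
  if (sum(roles == "sheath") >= 2 && sum(roles == "tube") >= 2) return("1")
  if (sum(roles == "sheath") == 1) return("2")
  "unclassified"
}

merge_index_ranges <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  ms <- starts[1]
  me <- ends[1]
  out <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1) {
      me <- max(me, ends[i])
    } else {
      out[[length(out) + 1]] <- c(ms, me)
      ms <- starts[i]
      me <- ends[i]
    }
  }
  out[[length(out) + 1]] <- c(ms, me)
  out
}

#' Find BIS loci across a set of genomes
#'
#' The full neighborhood-mining pipeline: anchor hits are filtered at the
#' sheath-profile gathering thresholds; up to `flank` proteins are extracted
#' on either side of each surviving anchor; overlapping neighborhoods on one
#' replicon are merged; all neighborhood proteins from all genomes are pooled
#' and clustered greedily at `identity_threshold`; clusters with fewer than
#' `min_cluster_size` members are dropped; cluster representatives are
#' annotated against the roster references and members inherit the role; each
#' merged neighborhood is trimmed at the DUF4255/FtsH boundary roles,
#' assessed for completeness and classified by architecture.
#'
#' Note that clusters are formed across genomes, so a gene family must recur
#' in at least `min_cluster_size` neighborhoods to be annotated: run the
#' finder on a pooled genome set, not genome by genome.
#'
#' @param genomes A genome protein table or list of them.
#' @param anchor_hits Anchor hit table(s) (`protein_id`, `bitscore`,
#'   `evalue`), concatenated across genomes.
#' @param references,roster Annotation references (see [annotate_roles()]).
#' @param flank Neighborhood half-width in proteins.
#' @param min_bitscore,max_evalue Anchor gathering thresholds.
#' @param identity_threshold Greedy clustering threshold.
#' @param min_cluster_size Minimum cluster membership analysed further.
#' @param min_identity,min_coverage Role annotation thresholds.
#' @return List with `loci` (list of `bis_locus`, completeness and
#'   architecture filled in) and `summary` (`data.frame`: `replicon_id`,
#'   `n_genes`, `start_nt`, `end_nt`, `complete`, `architecture`, `roles`).
#' @export
find_bis_loci <- function(genomes, anchor_hits,
                          references = bis_reference_proteins(),
                          roster = bis_roster(),
                          flank = 20, min_bitscore = 31.4, max_evalue = 1e-9,
                          identity_threshold = 0.5, min_cluster_size = 4,
                          min_identity = 0.45, min_coverage = 0.5) {
  if (is.data.frame(genomes)) genomes <- list(genomes)
  anchors <- filter_anchor_hits(anchor_hits, min_bitscore, max_evalue)

  neighborhoods <- list()
  for (g in genomes) {
    idx <- g$index[g$protein_id %in% anchors$protein_id]
    if (length(idx) == 0) next
    lo <- pmax(min(g$index), idx - flank)
    hi <- pmin(max(g$index), idx + flank)
    for (rng in merge_index_ranges(lo, hi)) {
      neighborhoods[[length(neighborhoods) + 1]] <-
        g[g$index >= rng[1] & g$index <= rng[2], , drop = FALSE]
    }
  }
  empty_summary <- data.frame(
    replicon_id = character(0), n_genes = integer(0), start_nt = numeric(0),
    end_nt = numeric(0), complete = logical(0), architecture = character(0),
    roles = character(0), stringsAsFactors = FALSE)
  if (length(neighborhoods) == 0) {
    return(list(loci = list(), summary = empty_summary))
  }

  pool <- unique(do.call(rbind, lapply(neighborhoods, function(nb) {
    nb[, c("protein_id", "sequence")]
  })))
  clusters <- filter_clusters(
    greedy_cluster(pool, identity_threshold = identity_threshold),
    min_size = min_cluster_size)

  role_of <- character(0)
  if (length(clusters) > 0) {
    reps <- vapply(clusters, function(cl) {
      pool$sequence[match(cl$centroid_id, pool$protein_id)]
    }, character(1))
    names(reps) <- vapply(clusters, `[[`, character(1), "centroid_id")
    rep_roles <- annotate_roles(reps, references, roster,
                                min_identity = min_identity,
                                min_coverage = min_coverage)
    for (k in seq_along(clusters)) {
      role_of[clusters[[k]]$member_ids] <- rep_roles[[k]]
    }
  }

  loci <- list()
  rows <- list()
  for (nb in neighborhoods) {
    nb$role <- unname(role_of[nb$protein_id])
    nb$role[is.na(nb$role)] <- "unannotated"
    if (all(nb$role == "unannotated")) next
    locus <- trim_locus(nb)
    locus$complete <- assess_completeness(locus)
    locus$architecture <- classify_architecture(locus)
    loci[[length(loci) + 1]] <- locus
    rows[[length(rows) + 1]] <- data.frame(
      replicon_id = locus$replicon_id,
      n_genes = nrow(locus$gene_calls),
      start_nt = locus$start_nt, end_nt = locus$end_nt,
      complete = locus$complete, architecture = locus$architecture,
      roles = paste(locus$gene_calls$role, collapse = ","),
      stringsAsFactors = FALSE)
  }
  summary <- if (length(rows)) do.call(rbind, rows) else empty_summary
  rownames(summary) <- NULL
  list(loci = loci, summary = summary)
}

#' @export
print.bis_locus <- function(x, ...) {
  cat(sprintf("BIS locus on %s: %d genes, %s, architecture %s\n",
              x$replicon_id, nrow(x$gene_calls),
              if (isTRUE(x$complete)) "complete" else "incomplete",
              x$architecture))
  cat(" roles:", paste(x$gene_calls$role, collapse = " "), "\n")
  invisible(x)
}
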