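#' Generate a synthetic genome protein table
#'
#' Builds an ordered protein table for one replicon, optionally embedding a
#' planted BIS locus in one of the three architectures. Locus proteins are
#' derived from the roster reference sequences by substituting 5-12% of
#' positions, so that within-family identity stays well above the 50%
#' clustering threshold; protein lengths (roster and random flanks alike)
#' are confined to 200-250 residues so that the chance identity of
#' unrelated pairs, which grows as sequence lengths diverge under the
#' shorter-sequence identity denominator, stays well below it. In
#' architecture 3 the gp27 and gp6 proteins are truncated to 85% length,
#' mirroring the shortened forms of the compact arrangement.
#'
#' @param architecture One of `"1"`, `"2"`, `"3"` (planted locus), `"none"`
#'   (random proteins only) or `"decoy"` (a lone sheath-like gene with no
#'   accompanying baseplate or tube genes).
#' @param flank_genes Number of random non-BIS proteins on each side of the
#'   planted locus (and the total count for `"none"`).
#' @param seed Integer seed; a fixed seed reproduces the table exactly.
#' @return A `data.frame` with columns `replicon_id`, `protein_id`, `start`,
#'   `end`, `strand`, `index` (0-based genome order), `sequence`, plus
#'   generator ground-truth columns `true_gene` and `true_role` (`NA` for
#'   random proteins; never consulted by the locus finder).
#' @export
#' @examples
#' g <- generate_genome("1", flank_genes = 5, seed = 1)
#' table(g$true_role)
generate_genome <- function(architecture = c("1", "2", "3", "none", "decoy"),
                            flank_genes = 25, seed = NULL) {
  architecture <- as.character(architecture[1])
  if (!architecture %in% c("1", "2", "3", "none", "decoy")) {
    stop("unknown architecture label: ", architecture)
  }
  stopifnot(flank_genes >= 0)
  roster <- bis_roster()
  refs <- bis_reference_proteins(roster)
  with_seed(seed, {
    if (architecture %in% c("1", "2", "3")) {
      locus_names <- bis_architecture_template(architecture)
    } else if (architecture == "decoy") {
      locus_names <- "Sheath1"
    } else {
      locus_names <- character(0)
    }
    locus_seqs <- vapply(locus_names, function(nm) {
      s <- mutate_protein(refs[[nm]], runif(1, 0.05, 0.12))
      if (architecture == "3" && nm %in% c("gp27", "gp6")) {
        s <- substr(s, 1L, ceiling(nchar(s) * 0.85))
      }
      s
    }, character(1))

    n_left <- if (architecture == "none") flank_genes else flank_genes
    n_right <- if (architecture == "none") 0L else flank_genes
    flank_seq <- function(n) {
      vapply(seq_len(n), function(i) random_protein(sample(200:250, 1L)),
             character(1))
    }
    left <- flank_seq(n_left)
    right <- flank_seq(n_right)

    seqs <- c(left, unname(locus_seqs), right)
    genes <- c(rep(NA_character_, length(left)), locus_names,
               rep(NA_character_, length(right)))
    roles <- ifelse(is.na(genes), NA_character_,
                    roster$role[match(genes, roster$name)])

    replicon_id <- sprintf("syn_arch%s_s%s", architecture,
                           if (is.null(seed)) "NA" else seed)
    n <- length(seqs)
    strand <- ifelse(is.na(genes), sample(c("+", "-"), n, replace = TRUE), "+")
    gaps <- sample(20:200, n, replace = TRUE)
    len_nt <- 3L * nchar(seqs) + 3L
    end <- cumsum(gaps + len_nt)
    start <- end - len_nt + 1L
    data.frame(
      replicon_id = replicon_id,
      protein_id = sprintf("%s_p%04d", replicon_id, seq_len(n)),
      start = start,
      end = end,
      strand = strand,
      index = seq_len(n) - 1L,
      sequence = seqs,
      true_gene = genes,
      true_role = roles,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a sheath-profile anchor hit table for a genome
#'
#' Emulates the tabular output of a profile search with the phage sheath
#' family: every sheath-like protein in the genome receives a hit passing the
#' gathering thresholds (bit score > 31.4, E < 1e-9), and a few random
#' proteins receive sub-threshold noise hits (either a low bit score or a
#' high E-value) that [filter_anchor_hits()] must remove.
#'
#' @param genome A table from [generate_genome()].
#' @param seed Integer seed.
#' @param n_noise Number of sub-threshold noise hits.
#' @return `data.frame` with columns `protein_id`, `profile`, `bitscore`,
#'   `evalue`.
#' @export
generate_anchor_hits <- function(genome, seed = NULL, n_noise = 5) {
  with_seed(seed, {
    sheath_ids <- genome$protein_id[!is.na(genome$true_role) &
                                      genome$true_role == "sheath"]
    true_hits <- data.frame(
      protein_id = sheath_ids,
      profile = rep("phage_sheath_1", length(sheath_ids)),
      bitscore = runif(length(sheath_ids), 60, 400),
      evalue = 10^runif(length(sheath_ids), -40, -12),
      stringsAsFactors = FALSE
    )
    pool <- setdiff(genome$protein_id, sheath_ids)
    n_noise <- min(n_noise, length(pool))
    noise <- data.frame(
      protein_id = if (n_noise > 0) sample(pool, n_noise) else character(0),
      profile = rep("phage_sheath_1", n_noise),
      bitscore = numeric(n_noise),
      evalue = numeric(n_noise),
      stringsAsFactors = FALSE
    )
    if (n_noise > 0) {
      low_score <- runif(n_noise) < 0.5
      noise$bitscore <- ifelse(low_score, runif(n_noise, 5, 31.3),
                               runif(n_noise, 40, 200))
      noise$evalue <- ifelse(low_score, 10^runif(n_noise, -30, -12),
                             10^runif(n_noise, -8, -1))
    }
    out <- rbind(true_hits, noise)
    rownames(out) <- NULL
    out
  })
}
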