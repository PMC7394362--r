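# Independent brute-force reimplementations used as oracles.

# Exhaustive enumeration of every global alignment (no memoisation, no DP):
# returns the identity of the lexicographically best (score, matches)
# alignment, matches normalised by the shorter sequence length.
oracle_identity <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A)
  nb <- length(B)
  best <- c(-Inf, -Inf)
  rec <- function(i, j, score, matches) {
    if (i > na && j > nb) {
      if (score > best[1] + 1e-9 ||
            (score > best[1] - 1e-9 && matches > best[2])) {
        best <<- c(score, matches)
      }
      return(invisible(NULL))
    }
    if (i <= na && j <= nb) {
      eq <- A[i] == B[j]
      rec(i + 1, j + 1, score + if (eq) match else mismatch, matches + eq)
    }
    if (i <= na) rec(i + 1, j, score + gap, matches)
    if (j <= nb) rec(i, j + 1, score + gap, matches)
    invisible(NULL)
  }
  rec(1, 1, 0, 0)
  best[2] / min(na, nb)
}

# Naive re-run of the greedy clustering rule (plain R loop).
oracle_greedy <- function(ids, seqs, threshold) {
  ord <- order(-nchar(seqs), ids, method = "radix")
  ids <- ids[ord]
  seqs <- seqs[ord]
  centroid_seq <- character(0)
  centroid_id <- character(0)
  members <- list()
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (k in seq_along(centroid_seq)) {
      if (pairwise_identity(seqs[i], centroid_seq[k]) >= threshold) {
        members[[k]] <- c(members[[k]], ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroid_seq <- c(centroid_seq, seqs[i])
      centroid_id <- c(centroid_id, ids[i])
      members[[length(centroid_seq)]] <- ids[i]
    }
  }
  lapply(seq_along(centroid_id), function(k) {
    list(centroid_id = centroid_id[k], member_ids = members[[k]],
         size = length(members[[k]]))
  })
}

# Per-gene tally by explicit loop.
oracle_count <- function(records, genes) {
  out <- setNames(integer(length(genes)), genes)
  for (i in seq_len(nrow(records))) {
    s <- records$sseqid[i]
    if (s %in% genes) out[s] <- out[s] + 1L
  }
  out
}

# Best hit per read by explicit per-read scan.
oracle_best_hit <- function(records) {
  keep <- integer(0)
  for (q in sort(unique(records$qseqid))) {
    rows <- which(records$qseqid == q)
    rows <- rows[order(records$evalue[rows], -records$bitscore[rows],
                       records$sseqid[rows], method = "radix")]
    keep <- c(keep, rows[1])
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact two-sided permutation p for the rank-sum statistic (midranks).
oracle_perm_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  combs <- utils::combn(length(pooled), na)
  ws <- colSums(matrix(r[combs], nrow = na))
  w <- sum(r[seq_len(na)])
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Substitute a fraction of residues (never to the original letter).
mutate_seq <- function(seq, rate) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), round(rate * length(chars)))
  for (p in pos) chars[p] <- sample(setdiff(aa, chars[p]), 1)
  paste(chars, collapse = "")
}

# Small planted-genome batch plus its anchor hit table.
make_genome_batch <- function(architecture, n, seed0, flank_genes = 10) {
  genomes <- lapply(seq_len(n), function(i) {
    generate_genome(architecture, flank_genes = flank_genes,
                    seed = seed0 + i)
  })
  anchors <- do.call(rbind, lapply(seq_len(n), function(i) {
    generate_anchor_hits(genomes[[i]], seed = seed0 + 1000L + i)
  }))
  list(genomes = genomes, anchors = anchors)
}
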