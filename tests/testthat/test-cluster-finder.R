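test_that("anchor filtering applies strict gathering thresholds", {
  hits <- data.frame(
    protein_id = c("a", "b", "c", "d", "e"),
    bitscore = c(31.4, 31.5, 100, 100, 20),
    evalue = c(1e-20, 1e-20, 1e-9, 1e-10, 1e-30))
  kept <- filter_anchor_hits(hits)
  # boundary values (bitscore == 31.4, evalue == 1e-9) are excluded
  expect_equal(kept$protein_id, c("b", "d"))
})

test_that("neighborhood extraction clips at replicon ends", {
  g <- generate_genome("1", flank_genes = 5, seed = 2)
  anchor <- g$protein_id[3]
  nb <- extract_neighborhood(g, anchor, flank = 4)
  expect_equal(nb$index, 0:6)
  nb2 <- extract_neighborhood(g, g$protein_id[nrow(g)], flank = 2)
  expect_equal(nrow(nb2), 3)
  expect_error(extract_neighborhood(g, "nope"), "anchor protein not found")
})

test_that("pairwise identity matches hand-computed alignments", {
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("MKT", "MKT"), 1)
  # one residue shared, normalised by the shorter length
  expect_equal(pairwise_identity("A", "CAK"), 1)
  expect_equal(pairwise_identity("ACDEF", "ACDEF"), 1)
  expect_error(alignment_stats("", "A"), "empty sequence")
  st <- alignment_stats("AAAA", "AAAT")
  expect_equal(unname(st[c("matches", "aligned", "score")]), c(3, 4, 5))
})

test_that("identity is symmetric and bounded on random pairs", {
  set.seed(401)
  for (i in 1:50) {
    a <- random_aa(sample(5:60, 1))
    b <- random_aa(sample(5:60, 1))
    ab <- pairwise_identity(a, b)
    expect_equal(ab, pairwise_identity(b, a))
    expect_gte(ab, 0)
    expect_lte(ab, 1)
  }
})

test_that("greedy clustering groups mutants and separates random proteins", {
  set.seed(17)
  base1 <- random_aa(120)
  base2 <- random_aa(120)
  fam1 <- vapply(1:4, function(i) mutate_seq(base1, 0.1), character(1))
  fam2 <- vapply(1:3, function(i) mutate_seq(base2, 0.1), character(1))
  lone <- random_aa(120)
  prots <- setNames(c(fam1, fam2, lone),
                    c(paste0("f1_", 1:4), paste0("f2_", 1:3), "lone"))
  cl <- greedy_cluster(prots, identity_threshold = 0.5)
  expect_length(cl, 3)
  sizes <- sort(vapply(cl, `[[`, integer(1), "size"))
  expect_equal(sizes, c(1L, 3L, 4L))
  groups <- lapply(cl, function(x) sort(sub("_.*", "", x$member_ids)))
  expect_true(any(vapply(groups, function(g) all(g == "f1"), logical(1))))
  kept <- filter_clusters(cl, min_size = 4)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$size, 4)
})

test_that("clustering is invariant to input order", {
  set.seed(23)
  prots <- setNames(
    vapply(1:20, function(i) random_aa(sample(50:80, 1)), character(1)),
    sprintf("p%02d", 1:20))
  cl1 <- greedy_cluster(prots, 0.3)
  cl2 <- greedy_cluster(prots[sample(20)], 0.3)
  key <- function(cl) {
    sort(vapply(cl, function(x) paste(sort(x$member_ids), collapse = ","),
                character(1)))
  }
  expect_identical(key(cl1), key(cl2))
})

test_that("role annotation recognises references and rejects random proteins", {
  refs <- bis_reference_proteins()
  roster <- bis_roster()
  roles <- annotate_roles(refs[c("Sheath1", "gp27", "LysM")])
  expect_equal(unname(roles), c("sheath", "baseplate_gp27", "lysm"))
  set.seed(37)
  rand <- setNames(vapply(1:10, function(i) random_aa(sample(200:250, 1)),
                          character(1)), paste0("r", 1:10))
  expect_true(all(annotate_roles(rand) == "unannotated"))
  # mutated copies still map back to their ancestor's role
  mut <- setNames(mutate_seq(refs[["Tube1"]], 0.12), "m1")
  expect_equal(unname(annotate_roles(mut)), "tube")
})

test_that("locus trimming is bounded by the DUF4255/FtsH roles", {
  nb <- data.frame(
    replicon_id = "r1",
    protein_id = paste0("p", 1:9),
    role = c("unannotated", "duf4255", "sheath", "unannotated", "tube",
             "ftsh_atpase", "unannotated", "lysm", "unannotated"),
    start = (1:9) * 100, end = (1:9) * 100 + 50)
  locus <- trim_locus(nb)
  # span runs boundary to boundary even past interior unannotated genes,
  # and excludes annotated genes outside the boundary pair
  expect_equal(locus$gene_calls$protein_id, paste0("p", 2:6))
  expect_equal(locus$start_nt, 200)
  expect_equal(locus$end_nt, 650)
  # without both boundaries: first to last annotated gene
  nb$role[2] <- "unannotated"
  locus2 <- trim_locus(nb)
  expect_equal(locus2$gene_calls$protein_id, paste0("p", 3:8))
  nb$role <- "unannotated"
  expect_error(trim_locus(nb), "no annotated roles")
})

test_that("completeness requires all six core roles", {
  mk <- function(roles) {
    structure(list(replicon_id = "r", complete = NA,
                   gene_calls = data.frame(protein_id = seq_along(roles),
                                           role = roles),
                   architecture = "unclassified"),
              class = "bis_locus")
  }
  full <- mk(c("baseplate_gp25", "baseplate_gp27", "baseplate_gp6",
               "sheath", "tube", "ftsh_atpase"))
  expect_true(assess_completeness(full))
  expect_false(assess_completeness(mk(c("baseplate_gp25", "sheath", "tube"))))
})

test_that("architecture classification follows the documented rule order", {
  mk <- function(roles, complete = TRUE) {
    structure(list(replicon_id = "r", complete = complete,
                   gene_calls = data.frame(protein_id = seq_along(roles),
                                           role = roles),
                   architecture = "unclassified"),
              class = "bis_locus")
  }
  core <- c("baseplate_gp25", "baseplate_gp27", "baseplate_gp6")
  expect_equal(classify_architecture(
    mk(c("duf4255", "sheath", "sheath", "tube", core, "tube",
         "duf4157", "ftsh_atpase"))), "1")
  expect_equal(classify_architecture(
    mk(c("duf4255", "sheath", "tube", core, "tube",
         "duf4157", "ftsh_atpase"))), "2")
  expect_equal(classify_architecture(
    mk(c("ftsh_atpase", "duf4157", "sheath", "tube", core, "tube"))), "3")
  expect_equal(classify_architecture(
    mk(c("sheath", "tube", core, "ftsh_atpase"), complete = FALSE)),
    "unclassified")
})

test_that("the full finder recovers a planted locus and nothing else", {
  batch <- make_genome_batch("2", 5, 7000, flank_genes = 8)
  res <- find_bis_loci(batch$genomes, batch$anchors)
  expect_equal(nrow(res$summary), 5)
  expect_true(all(res$summary$complete))
  expect_true(all(res$summary$architecture == "2"))
  expect_true(all(res$summary$n_genes == 15))
  # locus span matches the planted gene coordinates
  g1 <- batch$genomes[[1]]
  planted <- g1[!is.na(g1$true_gene), ]
  row1 <- res$summary[res$summary$replicon_id == g1$replicon_id[1], ]
  expect_equal(row1$start_nt, min(planted$start))
  expect_equal(row1$end_nt, max(planted$end))
})

test_that("genomes without a locus produce no complete loci", {
  batch <- make_genome_batch("none", 5, 7100, flank_genes = 10)
  res <- find_bis_loci(batch$genomes, batch$anchors)
  expect_equal(sum(res$summary$complete), 0)
})
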