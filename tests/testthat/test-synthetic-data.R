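test_that("roster has 18 genes, a ten-gene core, and consistent lengths", {
  r <- bis_roster()
  expect_equal(nrow(r), 18)
  expect_equal(sum(r$core), 10)
  expect_equal(r$length_nt, 3L * r$length_aa + 3L)
  expect_true(all(r$length_aa >= 200 & r$length_aa <= 250))
  expect_true(all(bis_core_roles() %in% r$role))
})

test_that("architecture templates match the three conserved arrangements", {
  a1 <- bis_architecture_template("1")
  a2 <- bis_architecture_template("2")
  a3 <- bis_architecture_template("3")
  expect_length(a1, 18)
  expect_length(a2, 15)
  expect_length(a3, 13)
  expect_equal(sum(a1 %in% c("Sheath1", "Sheath2")), 2)
  expect_equal(sum(a2 %in% c("Sheath1", "Sheath2")), 1)
  # compact form: FtsH/ATPase precedes DUF4157
  expect_lt(match("FtsH/ATPase", a3), match("DUF4157", a3))
  expect_gt(match("FtsH/ATPase", a1), match("DUF4157", a1))
  expect_error(bis_architecture_template("4"), "unknown architecture")
})

test_that("reference proteins are reproducible across calls", {
  r1 <- bis_reference_proteins()
  r2 <- bis_reference_proteins()
  expect_identical(r1, r2)
  expect_equal(unname(nchar(r1)), bis_roster()$length_aa)
})

test_that("generated genomes plant the full locus with sane coordinates", {
  g <- generate_genome("1", flank_genes = 8, seed = 42)
  expect_equal(nrow(g), 8 + 18 + 8)
  expect_equal(g$index, seq_len(nrow(g)) - 1L)
  expect_true(all(g$start < g$end))
  expect_true(all(diff(g$start) > 0))
  planted <- g$true_gene[!is.na(g$true_gene)]
  expect_equal(planted, bis_architecture_template("1"))
  # planted genes stay near their ancestors, flanks are random
  refs <- bis_reference_proteins()
  ident <- vapply(which(!is.na(g$true_gene)), function(i) {
    pairwise_identity(g$sequence[i], refs[[g$true_gene[i]]])
  }, numeric(1))
  expect_true(all(ident >= 0.8))
  flank_len <- nchar(g$sequence[is.na(g$true_gene)])
  expect_true(all(flank_len >= 200 & flank_len <= 250))
})

test_that("genome generation is seed-deterministic", {
  expect_identical(generate_genome("2", flank_genes = 5, seed = 7),
                   generate_genome("2", flank_genes = 5, seed = 7))
  expect_false(identical(generate_genome("2", flank_genes = 5, seed = 7),
                         generate_genome("2", flank_genes = 5, seed = 8)))
  expect_error(generate_genome("bogus"), "unknown architecture")
})

test_that("architecture 3 genomes shorten gp27 and gp6", {
  g <- generate_genome("3", flank_genes = 3, seed = 11)
  r <- bis_roster()
  for (nm in c("gp27", "gp6")) {
    len <- nchar(g$sequence[which(g$true_gene == nm)])
    expect_equal(len, ceiling(r$length_aa[r$name == nm] * 0.85))
  }
})

test_that("anchor hits cover every sheath and only sub-threshold noise", {
  g <- generate_genome("1", flank_genes = 10, seed = 5)
  hits <- generate_anchor_hits(g, seed = 6)
  sheaths <- g$protein_id[!is.na(g$true_role) & g$true_role == "sheath"]
  kept <- filter_anchor_hits(hits)
  expect_setequal(kept$protein_id, sheaths)
  noise <- hits[!hits$protein_id %in% sheaths, ]
  expect_true(all(noise$bitscore <= 31.4 | noise$evalue >= 1e-9))
})

test_that("cohort generation realises the spec structure deterministically", {
  spec <- cohort_spec(n_donors = c(healthy = 12, ibd_cd = 6, ibd_uc = 6,
                                   prediabetes = 4), seed = 9)
  ch <- generate_cohort(spec)
  expect_identical(ch, generate_cohort(spec))
  expect_equal(nrow(ch$donors), 28)
  expect_equal(as.vector(table(ch$donors$group)[c("healthy", "ibd_cd")]),
               c(12L, 6L))
  expect_equal(nrow(ch$counts), nrow(ch$samples))
  expect_equal(colnames(ch$counts), bis_roster()$name)
  expect_true(all(ch$samples$total_reads >= 1))
  expect_true(all(ch$donors$n_samples >= 1 & ch$donors$n_samples <= 5))
})

test_that("samples only ever hit the genes their donor carries", {
  ch <- generate_cohort(cohort_spec(n_donors = c(healthy = 10), seed = 21))
  for (d in seq_len(nrow(ch$donors))) {
    carried <- strsplit(ch$donors$carried_genes[d], ",")[[1]]
    sids <- ch$samples$sample_id[ch$samples$donor_id == ch$donors$donor_id[d]]
    sub <- ch$counts[sids, , drop = FALSE]
    absent <- setdiff(colnames(sub), carried)
    expect_true(all(sub[, absent] == 0))
  }
})

test_that("alignment hit tables split true hits and decoys at E = 1e-3", {
  counts <- c(Sheath1 = 5L, gp25 = 3L, Tip = 0L)
  h <- generate_alignment_hits(counts, decoy_rate = 0.5, seed = 31,
                               sample_id = "T1")
  expect_equal(nrow(h), 8 + 4)
  expect_identical(h, generate_alignment_hits(counts, decoy_rate = 0.5,
                                              seed = 31, sample_id = "T1"))
  kept <- filter_hits(h, 0.001)
  expect_equal(nrow(kept), 8)
  expect_equal(sort(as.vector(table(kept$sseqid))), c(3L, 5L))
  expect_equal(ncol(h), 12)
  h0 <- generate_alignment_hits(c(Sheath1 = 0L), seed = 1)
  expect_equal(nrow(h0), 0)
})

test_that("taxonomic profiles sum to 100 per rank and track donor abundance", {
  spec <- cohort_spec(n_donors = c(healthy = 6), seed = 13)
  ch <- generate_cohort(spec)
  profs <- generate_taxonomic_profiles(ch, spec)
  expect_equal(names(profs), ch$samples$sample_id)
  for (p in profs) {
    phyla <- p$abundance[grepl("\\|p__", p$clade)]
    expect_equal(sum(phyla), 100, tolerance = 1e-9)
  }
  bact <- vapply(profs, function(p) {
    p$abundance[grepl("p__Bacteroidetes", p$clade)]
  }, numeric(1))
  planted <- ch$donors$bacteroidetes[match(ch$samples$donor_id,
                                           ch$donors$donor_id)]
  expect_true(all(abs(bact - planted) < 10))
})
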