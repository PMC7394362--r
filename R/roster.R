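#' The 18-protein BIS roster
#'
#' The Bacteroidales injection system (BIS) gene cluster is screened against a
#' fixed roster of 18 predicted proteins: two sheaths, two tubes, the three
#' baseplate components (gp25, gp27, gp6), the FtsH/ATPase, LysM, Spike, Tip,
#' the DUF4255 and DUF4157 domain proteins, and five hypothetical proteins.
#' Ten of these (the `core` column) cooccur at high frequency in gut
#' metagenomes.
#'
#' @return A `data.frame` of class `bis_roster` with columns `name`, `role`,
#'   `core`, `length_aa` and `length_nt` (`3 * length_aa + 3`, the coding
#'   length including the stop codon).
#' @export
#' @examples
#' r <- bis_roster()
#' nrow(r) # 18
bis_roster <- function() {
  df <- data.frame(
    name = c("Sheath1", "Sheath2", "Tube1", "Tube2", "FtsH/ATPase",
             "gp25", "gp27", "gp6", "LysM", "Spike", "Tip",
             "DUF4255", "DUF4157", "Hyp1", "Hyp2", "Hyp3", "Hyp4", "Hyp5"),
    role = c("sheath", "sheath", "tube", "tube", "ftsh_atpase",
             "baseplate_gp25", "baseplate_gp27", "baseplate_gp6",
             "lysm", "spike", "tip", "duf4255", "duf4157",
             rep("hypothetical", 5)),
    core = c(TRUE, TRUE, FALSE, FALSE, TRUE,
             TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
             FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    length_aa = c(250L, 240L, 215L, 210L, 245L,
                  205L, 235L, 225L, 200L, 230L, 220L,
                  212L, 208L, 202L, 218L, 228L, 206L, 242L),
    stringsAsFactors = FALSE
  )
  df$length_nt <- 3L * df$length_aa + 3L
  class(df) <- c("bis_roster", "data.frame")
  df
}

#' Roles required for a complete BIS locus
#'
#' A candidate locus is called complete when it carries at least one gene for
#' each core structural role: the three baseplate proteins, a sheath, a tube
#' and the FtsH/ATPase.
#'
#' @return Character vector of role labels.
#' @export
bis_core_roles <- function() {
  c("baseplate_gp25", "baseplate_gp27", "baseplate_gp6",
    "sheath", "tube", "ftsh_atpase")
}

#' Gene order template of a BIS architecture
#'
#' The three conserved genetic arrangements of the BIS cluster:
#' architecture 1 carries two sheath and two tube genes with hypothetical
#' genes interleaved among the baseplate genes and between Tube2 and LysM;
#' architecture 2 has a single sheath and lacks those two hypotheticals;
#' architecture 3 is the most compact, lacks four hypotheticals, carries
#' shortened gp27/gp6, and has the FtsH/ATPase and DUF4157 pair inverted
#' (FtsH/ATPase preceding DUF4157).
#'
#' @param architecture `"1"`, `"2"` or `"3"` (numeric accepted).
#' @return Character vector of roster gene names in locus order.
#' @export
bis_architecture_template <- function(architecture) {
  switch(as.character(architecture),
    "1" = c("DUF4255", "Hyp1", "Sheath1", "Sheath2", "Tube1", "gp25", "Hyp2",
            "gp27", "Hyp3", "gp6", "Spike", "Tip", "Tube2", "Hyp4", "LysM",
            "Hyp5", "DUF4157", "FtsH/ATPase"),
    "2" = c("DUF4255", "Hyp1", "Sheath1", "Tube1", "gp25", "gp27", "Hyp3",
            "gp6", "Spike", "Tip", "Tube2", "LysM", "Hyp5", "DUF4157",
            "FtsH/ATPase"),
    "3" = c("FtsH/ATPase", "DUF4157", "Sheath1", "Tube1", "gp25", "gp27",
            "gp6", "Spike", "Tip", "Tube2", "LysM", "Hyp1", "DUF4255"),
    stop("unknown architecture template: ", architecture)
  )
}

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) {
  paste(sample(.aa_alphabet, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  n_mut <- round(rate * length(chars))
  if (n_mut > 0) {
    pos <- sample.int(length(chars), n_mut)
    for (p in pos) {
      chars[p] <- sample(setdiff(.aa_alphabet, chars[p]), 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Reference protein sequences for the roster
#'
#' Synthetic reference sequences, one per roster gene, generated from a fixed
#' internal seed so they are identical across sessions. They serve as the
#' annotation references for [annotate_roles()] and as the ancestors from
#' which the synthetic-genome generator derives planted locus genes.
#'
#' @param roster A [bis_roster()] table.
#' @return Named character vector of amino-acid sequences.
#' @export
bis_reference_proteins <- function(roster = bis_roster()) {
  with_seed(190537L, {
    refs <- vapply(roster$length_aa, random_protein, character(1))
    names(refs) <- roster$name
    refs
  })
}
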