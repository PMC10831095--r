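# Shared fixtures: a small hand-written taxonomy and hit-list builders.
# Everything is built in code; no binary fixtures.

# taxids:
#   562   E. coli-like bacterium (all six ranks filled)
#   9606  human-like metazoan
#   4932  yeast-like fungus
#   33090 plant-like lineage absent below phylum
#   777   bacterium with an absent kingdom
tiny_lineages <- function() {
  data.frame(
    taxid = c(562L, 9606L, 4932L, 33090L, 777L),
    superkingdom = c("Bacteria", "Eukaryota", "Eukaryota", "Eukaryota",
                     "Bacteria"),
    kingdom = c("Bacteria_incertae", "Metazoa", "Fungi", "Viridiplantae", NA),
    phylum = c("Pseudomonadota", "Chordata", "Ascomycota", "Streptophyta", NA),
    class = c("Gammaproteobacteria", "Mammalia", "Saccharomycetes", NA, NA),
    order = c("Enterobacterales", "Primates", "Saccharomycetales", NA, NA),
    family = c("Enterobacteriaceae", "Hominidae", "Saccharomycetaceae", NA, NA),
    stringsAsFactors = FALSE
  )
}

tiny_taxonomy <- function() taxonomy_table(tiny_lineages())

# Hit list with hits from the given taxids, bitscores strictly decreasing
# unless supplied.
hits_from_taxids <- function(qid, taxids, bitscores = NULL, pident = 50) {
  n <- length(taxids)
  if (n == 0L) return(hit_list(qid, NULL))
  if (is.null(bitscores)) bitscores <- seq(100, by = -1, length.out = n)
  hit_list(qid, data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    subject_taxid = taxids,
    bitscore = bitscores,
    pident = rep_len(pident, n),
    evalue = NA_real_
  ))
}

# A complete miniature screening fixture: human-like host genome of 3 contigs,
# one of which is a bacterial contaminant, plus one contig with no hits.
tiny_screen_fixture <- function() {
  proteome <- setNames(
    rep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", 9),
    c(sprintf("hostA_p%d", 1:3), sprintf("hostB_p%d", 1:2),
      sprintf("bact_p%d", 1:2), sprintf("dark_p%d", 1:2)))
  membership <- setNames(
    c(rep("ctgA", 3), rep("ctgB", 2), rep("ctgX", 2), rep("ctgD", 2)),
    names(proteome))
  hit_lists <- c(
    lapply(sprintf("hostA_p%d", 1:3), function(q)
      hits_from_taxids(q, c(9606L, 9606L, 9606L))),
    lapply(sprintf("hostB_p%d", 1:2), function(q)
      hits_from_taxids(q, c(9606L, 4932L))),
    lapply(sprintf("bact_p%d", 1:2), function(q)
      hits_from_taxids(q, c(562L, 562L)))
  )
  names(hit_lists) <- vapply(hit_lists, query_id, "")
  genome <- query_genome_spec("human_like", setNames(
    c("Eukaryota", "Metazoa", "Chordata", "Mammalia", "Primates", "Hominidae"),
    rank_ladder()))
  list(proteome = proteome, membership = membership, hit_lists = hit_lists,
       genome = genome, taxonomy = tiny_taxonomy())
}

random_aa <- function(n, len, seed) {
  withr::with_seed(seed, {
    setNames(
      vapply(seq_len(n), function(i) {
        paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                       "Q","R","S","T","V","W","Y"), len, replace = TRUE),
              collapse = "")
      }, ""),
      sprintf("rseq%03d", seq_len(n)))
  })
}
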