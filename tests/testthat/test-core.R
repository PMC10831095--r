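# independent prefix-scan oracle over a label sequence (NA = absent)
prefix_oracle <- function(labels) {
  if (length(labels) == 0L || is.na(labels[1])) return(0L)
  n <- 0L
  for (l in labels) {
    if (is.na(l) || l != labels[1]) break
    n <- n + 1L
  }
  n
}

test_that("hit-list trimming keeps the top-scoring run of the first taxon", {
  tax <- tiny_taxonomy()
  # kingdom labels along the sorted list: Fungi,Fungi,Fungi,Bacteria_incertae,Fungi
  hl <- hits_from_taxids("q", c(4932L, 4932L, 4932L, 562L, 4932L))
  tr <- trim_hit_list(hl, "kingdom", tax)
  expect_equal(nrow(tr), 3L)
  expect_equal(unique(tr$subject_taxid), 4932L)
  # single hit: prefix of length 1
  expect_equal(nrow(trim_hit_list(hits_from_taxids("q", 4932L), "kingdom", tax)), 1L)
  # empty list stays empty
  expect_equal(nrow(trim_hit_list(hit_list("q", NULL), "kingdom", tax)), 0L)
  # absent rank on the best hit terminates the prefix immediately
  expect_equal(nrow(trim_hit_list(hits_from_taxids("q", c(777L, 562L)),
                                  "kingdom", tax)), 0L)
})

test_that("trimming matches the prefix-scan oracle on random label sequences", {
  tax <- tiny_taxonomy()
  pool <- c(9606L, 4932L, 562L, 33090L, 777L)
  withr::with_seed(99, {
    for (i in 1:200) {
      n <- sample(0:12, 1)
      taxids <- if (n > 0) sample(pool, n, replace = TRUE) else integer(0)
      hl <- hits_from_taxids("q", taxids)
      labels <- if (n > 0) {
        vapply(hl$subject_taxid,
               function(t) label_at_rank(tax, t, "kingdom"), "")
      } else character(0)
      expect_equal(nrow(trim_hit_list(hl, "kingdom", tax)),
                   prefix_oracle(labels))
    }
  })
})

test_that("protein calls follow the best hit with top-cap agreement confidence", {
  tax <- tiny_taxonomy()
  # no hits: UNCLASSIFIED with zero confidence
  cl0 <- call_protein_taxon(hit_list("q0", NULL), "kingdom", tax)
  expect_equal(cl0$label, UNCLASSIFIED)
  expect_equal(cl0$confidence, 0)
  expect_equal(cl0$n_hits_total, 0L)
  # 20 agreeing hits, cap 10: confidence 1
  cl1 <- call_protein_taxon(hits_from_taxids("q1", rep(9606L, 20)),
                            "kingdom", tax, cap = 10)
  expect_equal(cl1$label, "Metazoa")
  expect_equal(cl1$confidence, 1.0)
  expect_equal(cl1$n_hits_total, 20L)
  expect_equal(cl1$n_hits_retained, 20L)
  # labels B,B,B,F,F,F,F,F,F,F: call = best hit's label, confidence 3/10
  cl2 <- call_protein_taxon(
    hits_from_taxids("q2", c(rep(562L, 3), rep(4932L, 7))),
    "kingdom", tax, cap = 10)
  expect_equal(cl2$label, "Bacteria_incertae")
  expect_equal(cl2$confidence, 0.3)
  expect_equal(cl2$n_hits_retained, 3L)
  # best hit absent at the rank: UNCLASSIFIED
  cl3 <- call_protein_taxon(hits_from_taxids("q3", c(777L, 9606L)),
                            "kingdom", tax)
  expect_equal(cl3$label, UNCLASSIFIED)
  expect_equal(cl3$confidence, 0)
})

test_that("label is UNCLASSIFIED exactly when confidence is zero", {
  tax <- tiny_taxonomy()
  pool <- c(9606L, 4932L, 562L, 777L)
  withr::with_seed(31, {
    for (i in 1:100) {
      n <- sample(0:8, 1)
      cl <- call_protein_taxon(
        hits_from_taxids("q", if (n > 0) sample(pool, n, TRUE) else integer(0)),
        "kingdom", tax)
      expect_equal(cl$label == UNCLASSIFIED, cl$confidence == 0)
      expect_lte(cl$n_hits_retained, cl$n_hits_total)
    }
  })
})

make_calls <- function(labels) {
  data.frame(protein_id = sprintf("p%03d", seq_along(labels)),
             rank = "kingdom", label = labels,
             confidence = ifelse(labels == UNCLASSIFIED, 0, 1),
             n_hits_total = 5L, n_hits_retained = 3L,
             stringsAsFactors = FALSE)
}

host_genome <- function() {
  query_genome_spec("host", setNames(
    c("Eukaryota", "Metazoa", "Chordata", "Mammalia", "Primates", "Hominidae"),
    rank_ladder()))
}

test_that("contig consensus removes alien-majority contigs and spares HGT minorities", {
  g <- host_genome()
  # all five proteins alien: removed
  calls <- make_calls(rep("Bacteria_incertae", 5))
  v <- contig_consensus(calls, setNames(rep("c1", 5), calls$protein_id),
                        g, "kingdom", threshold = 0.5)
  expect_equal(v$decision, "REMOVE")
  expect_equal(v$alien_fraction, 1)
  expect_equal(v$dominant_alien_label, "Bacteria_incertae")
  # 1 alien among 10 host genes: kept (HGT-sparing)
  calls2 <- make_calls(c("Bacteria_incertae", rep("Metazoa", 10)))
  v2 <- contig_consensus(calls2, setNames(rep("c1", 11), calls2$protein_id),
                         g, "kingdom", threshold = 0.5)
  expect_equal(v2$decision, "KEEP")
  expect_equal(v2$alien_fraction, 1 / 11)
  # all proteins unclassified: kept, alien fraction 0
  calls3 <- make_calls(rep(UNCLASSIFIED, 4))
  v3 <- contig_consensus(calls3, setNames(rep("c1", 4), calls3$protein_id),
                         g, "kingdom", threshold = 0.5)
  expect_equal(v3$decision, "KEEP")
  expect_equal(v3$alien_fraction, 0)
  expect_equal(v3$votes_unclassified, 4L)
  expect_equal(v3$dominant_alien_label, "NONE")
})

test_that("dominant alien label breaks ties lexicographically and missing membership errors", {
  g <- host_genome()
  calls <- make_calls(c("Fungi", "Bacteria_incertae", "Fungi",
                        "Bacteria_incertae"))
  v <- contig_consensus(calls, setNames(rep("c1", 4), calls$protein_id),
                        g, "kingdom", 0.5)
  expect_equal(v$dominant_alien_label, "Bacteria_incertae")
  expect_error(
    contig_consensus(calls, setNames(rep("c1", 3), calls$protein_id[1:3]),
                     g, "kingdom", 0.5),
    "p004")
})

test_that("consensus equals a brute-force recount on small vote configurations", {
  g <- host_genome()
  vocab <- c("Metazoa", "Fungi", "Bacteria_incertae", UNCLASSIFIED)
  mismatches <- 0L
  for (n in 1:4) {
    configs <- do.call(expand.grid,
                       c(rep(list(vocab), n), stringsAsFactors = FALSE))
    for (i in seq_len(nrow(configs))) {
      labels <- unlist(configs[i, ], use.names = FALSE)
      calls <- make_calls(labels)
      membership <- setNames(rep("ctg", n), calls$protein_id)
      v <- contig_consensus(calls, membership, g, "kingdom", threshold = 0.5)
      # independent recount
      h <- sum(labels == "Metazoa")
      a <- sum(labels %in% c("Fungi", "Bacteria_incertae"))
      u <- n - h - a
      expected_frac <- if (h + a > 0) a / (h + a) else 0
      dec <- if (h + a > 0 && expected_frac >= 0.5) "REMOVE" else "KEEP"
      ok <- v$votes_host == h && v$votes_alien == a &&
        v$votes_unclassified == u && v$n_proteins == n &&
        isTRUE(all.equal(v$alien_fraction, expected_frac)) &&
        v$decision == dec
      if (!ok) mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("end-to-end screening partitions the proteome and removes contaminant contigs atomically", {
  fx <- tiny_screen_fixture()
  out_dir <- withr::local_tempdir()
  report <- decontaminate(fx$proteome, fx$membership, fx$hit_lists,
                          fx$taxonomy, fx$genome, rank = "kingdom",
                          threshold = 0.5, min_pident = 20,
                          out_dir = out_dir)
  # the bacterial contig goes, everything else stays
  expect_setequal(report$removed, c("bact_p1", "bact_p2"))
  expect_setequal(report$kept,
                  setdiff(names(fx$proteome), c("bact_p1", "bact_p2")))
  # partition invariant
  expect_setequal(c(report$kept, report$removed), names(fx$proteome))
  expect_length(intersect(report$kept, report$removed), 0L)
  # contig atomicity
  for (ctg in unique(fx$membership)) {
    members <- names(fx$membership)[fx$membership == ctg]
    expect_true(all(members %in% report$kept) ||
                all(members %in% report$removed))
  }
  # dark contig (no hits at all) is kept
  expect_true(all(c("dark_p1", "dark_p2") %in% report$kept))
  # outputs exist and the cleaned FASTA holds exactly the kept proteins in order
  expect_true(all(file.exists(file.path(
    out_dir, c("cleaned.faa", "removed.tsv", "verdicts.tsv", "summary.json")))))
  cleaned <- Biostrings::readAAStringSet(file.path(out_dir, "cleaned.faa"))
  expect_identical(names(cleaned), report$kept)
  summ <- jsonlite::read_json(file.path(out_dir, "summary.json"))
  expect_equal(summ$n_removed, 2L)
  expect_equal(summ$removed_by_source$Bacteria_incertae, 2L)
})

test_that("screening aborts before any work when ids do not match membership", {
  fx <- tiny_screen_fixture()
  bad_membership <- fx$membership[-1]
  expect_error(
    decontaminate(fx$proteome, bad_membership, fx$hit_lists, fx$taxonomy,
                  fx$genome),
    "hostA_p1")
})

test_that("raising the threshold never increases removals", {
  fx <- tiny_screen_fixture()
  n_removed <- vapply(c(0.25, 0.5, 0.75, 1.0), function(th) {
    r <- decontaminate(fx$proteome, fx$membership, fx$hit_lists, fx$taxonomy,
                       fx$genome, threshold = th)
    length(r$removed)
  }, 1L)
  expect_true(all(diff(n_removed) <= 0))
})

test_that("identical inputs produce byte-identical output files", {
  fx <- tiny_screen_fixture()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  decontaminate(fx$proteome, fx$membership, fx$hit_lists, fx$taxonomy,
                fx$genome, out_dir = d1)
  decontaminate(fx$proteome, fx$membership, fx$hit_lists, fx$taxonomy,
                fx$genome, out_dir = d2)
  for (f in c("cleaned.faa", "removed.tsv", "verdicts.tsv", "summary.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("the per-protein alien score is the contig's alien fraction", {
  fx <- tiny_screen_fixture()
  report <- decontaminate(fx$proteome, fx$membership, fx$hit_lists,
                          fx$taxonomy, fx$genome)
  scores <- alien_score_per_protein(report)
  expect_equal(unname(scores["hostA_p1"]), 0)    # all-host contig
  expect_equal(unname(scores["bact_p1"]), 1)     # all-alien contig
  expect_equal(unname(scores["dark_p1"]), 0)     # unclassifiable contig
  expect_true(all(scores >= 0 & scores <= 1))
  # the 1-alien / 10-host contig scores 1/11
  g <- host_genome()
  calls <- make_calls(c("Fungi", rep("Metazoa", 10)))
  membership <- setNames(rep("c1", 11), calls$protein_id)
  v <- contig_consensus(calls, membership, g, "kingdom", 0.5)
  expect_equal(v$alien_fraction, 1 / 11)
})
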