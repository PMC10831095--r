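#' Label marking a protein that could not be classified
#'
#' Returned as the taxon label when a query has no hits passing the filters,
#' or when its best hit's lineage is absent at the decision rank. Reserved:
#' real taxon names must not collide with it.
#' @export
UNCLASSIFIED <- "UNCLASSIFIED"

#' Describe the query genome being screened
#'
#' @param genome_id Identifier of the query genome.
#' @param self_lineage Named character vector over [rank_ladder()] giving the
#'   expected lineage of the query genome; may have absent (`NA`) ranks, but
#'   must be labeled at any rank at which decontamination is attempted.
#' @return Object of class `query_genome_spec`.
#' @export
query_genome_spec <- function(genome_id, self_lineage) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  self_lineage <- self_lineage[rank_ladder()]
  names(self_lineage) <- rank_ladder()
  if (all(is.na(self_lineage))) {
    stop("self_lineage must label at least one rank", call. = FALSE)
  }
  structure(list(genome_id = genome_id, self_lineage = self_lineage),
            class = "query_genome_spec")
}

#' Trim a hit list to the top-scoring run of one taxon
#'
#' Implements hit-list trimming: the ranked list is cut down to the maximal
#' prefix in which every hit carries the same taxon label (at the decision
#' rank) as the best hit. A hit whose lineage is absent at the rank terminates
#' the prefix. The non-fixed size of this window is what makes the call robust
#' to sporadically mislabeled reference proteins.
#'
#' @param x A [hit_list()], already sorted (the class invariant).
#' @param rank One of [rank_ladder()].
#' @param taxonomy A [taxonomy_table()] covering all subject taxids.
#' @return The trimmed [hit_list()]; empty when the input is empty or the best
#'   hit is absent at `rank`.
#' @export
trim_hit_list <- function(x, rank, taxonomy) {
  stopifnot(inherits(x, "hit_list"))
  .check_rank(rank)
  if (nrow(x) == 0L) return(x)
  labels <- .labels_at_rank(taxonomy, x$subject_taxid, rank)
  if (is.na(labels[1])) {
    return(hit_list(query_id(x), NULL))
  }
  agree <- !is.na(labels) & labels == labels[1]
  n_keep <- if (all(agree)) length(agree) else which(!agree)[1] - 1L
  hit_list(query_id(x), as.data.frame(x)[seq_len(n_keep), , drop = FALSE])
}

#' Call the taxon of one protein from its ranked hits
#'
#' The best hit's taxon label at the decision rank becomes the protein's call;
#' a protein with no hits, or whose best hit is absent at the rank, is
#' `UNCLASSIFIED`. The confidence score is the fraction of agreeing labels
#' among the top `min(cap, n)` hits (default window 10, mirroring the top-10
#' taxon support ratio), so many agreeing hits give confidence near 1 while a
#' single supporting hit in a deep list gives a low value.
#'
#' @param x A [hit_list()].
#' @param rank One of [rank_ladder()].
#' @param taxonomy A [taxonomy_table()].
#' @param cap Size of the confidence window; default 10.
#' @return A list of class `protein_taxon_call` with fields `protein_id`,
#'   `rank`, `label`, `confidence`, `n_hits_total`, `n_hits_retained`.
#' @export
call_protein_taxon <- function(x, rank, taxonomy, cap = 10L) {
  stopifnot(inherits(x, "hit_list"))
  .check_rank(rank)
  if (cap < 1L) stop("cap must be >= 1", call. = FALSE)
  n <- nrow(x)
  if (n == 0L) {
    return(structure(list(protein_id = query_id(x), rank = rank,
                          label = UNCLASSIFIED, confidence = 0,
                          n_hits_total = 0L, n_hits_retained = 0L),
                     class = "protein_taxon_call"))
  }
  labels <- .labels_at_rank(taxonomy, x$subject_taxid, rank)
  retained <- if (is.na(labels[1])) 0L else {
    agree <- !is.na(labels) & labels == labels[1]
    if (all(agree)) length(agree) else which(!agree)[1] - 1L
  }
  if (is.na(labels[1])) {
    label <- UNCLASSIFIED
    confidence <- 0
  } else {
    label <- labels[1]
    m <- min(cap, n)
    top <- labels[seq_len(m)]
    confidence <- sum(!is.na(top) & top == label) / m
  }
  structure(list(protein_id = query_id(x), rank = rank, label = label,
                 confidence = confidence, n_hits_total = n,
                 n_hits_retained = as.integer(retained)),
            class = "protein_taxon_call")
}

#' @export
print.protein_taxon_call <- function(x, ...) {
  cat("<protein_taxon_call> ", x$protein_id, " @", x$rank, ": ", x$label,
      " (confidence ", format(x$confidence, digits = 3), ", ",
      x$n_hits_retained, "/", x$n_hits_total, " hits retained)\n", sep = "")
  invisible(x)
}

#' Call taxa for a set of proteins
#'
#' Vectorized driver over [call_protein_taxon()]: proteins without a hit list
#' (no hit in the reference) get an `UNCLASSIFIED` row.
#'
#' @param protein_ids Character vector of all query protein ids.
#' @param hit_lists Named list of [hit_list()] objects (subset of
#'   `protein_ids`).
#' @inheritParams call_protein_taxon
#' @return data.frame with one row per protein: `protein_id`, `rank`, `label`,
#'   `confidence`, `n_hits_total`, `n_hits_retained`.
#' @export
call_proteins <- function(protein_ids, hit_lists, rank, taxonomy, cap = 10L) {
  .check_rank(rank)
  rows <- lapply(protein_ids, function(p) {
    hl <- hit_lists[[p]]
    if (is.null(hl)) hl <- hit_list(p, NULL)
    cl <- call_protein_taxon(hl, rank, taxonomy, cap)
    data.frame(protein_id = cl$protein_id, rank = cl$rank, label = cl$label,
               confidence = cl$confidence, n_hits_total = cl$n_hits_total,
               n_hits_retained = cl$n_hits_retained, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Contig-level consensus over per-protein taxon votes
#'
#' Each protein on a contig votes host (its label equals the query genome's
#' own label at the decision rank), alien (classified, but different), or
#' unclassified. A contig is removed when classified votes exist and the alien
#' fraction among them reaches the threshold. Unclassified votes are excluded
#' from the denominator, so contigs where every protein lacks hits are kept:
#' absence of evidence is not treated as evidence of contamination. This
#' contig-context step is also what spares horizontally transferred genes — a
#' minority alien vote on a host-dominated contig never reaches the threshold.
#'
#' @param calls data.frame as returned by [call_proteins()].
#' @param membership Named character vector mapping protein id to contig id.
#' @param genome A [query_genome_spec()] labeled at `rank`.
#' @param rank One of [rank_ladder()].
#' @param threshold Alien-fraction removal threshold in (0, 1\]; default 0.5
#'   (strict majority of classified votes).
#' @return data.frame of contig verdicts: `contig_id`, `rank`, `n_proteins`,
#'   `votes_host`, `votes_alien`, `votes_unclassified`, `alien_fraction`,
#'   `decision` (`KEEP`/`REMOVE`), `dominant_alien_label` (`NONE` when no
#'   alien vote).
#' @export
contig_consensus <- function(calls, membership, genome, rank, threshold = 0.5) {
  stopifnot(is.data.frame(calls), inherits(genome, "query_genome_spec"))
  .check_rank(rank)
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  self_label <- genome$self_lineage[[rank]]
  if (is.na(self_label)) {
    stop("query genome lineage is absent at rank '", rank, "'", call. = FALSE)
  }
  missing <- setdiff(calls$protein_id, names(membership))
  if (length(missing) > 0L) {
    stop("protein(s) missing from membership: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  contig <- unname(membership[calls$protein_id])
  vote <- ifelse(calls$label == UNCLASSIFIED, "unclassified",
                 ifelse(calls$label == self_label, "host", "alien"))
  rows <- lapply(split(seq_len(nrow(calls)), contig), function(idx) {
    v <- vote[idx]
    h <- sum(v == "host"); a <- sum(v == "alien"); u <- sum(v == "unclassified")
    classified <- h + a
    frac <- if (classified > 0L) a / classified else 0
    decision <- if (classified > 0L && frac >= threshold) "REMOVE" else "KEEP"
    dom <- "NONE"
    if (a > 0L) {
      tab <- table(calls$label[idx][v == "alien"])
      top <- names(tab)[tab == max(tab)]
      dom <- sort(top)[1]
    }
    data.frame(n_proteins = length(idx), votes_host = h, votes_alien = a,
               votes_unclassified = u, alien_fraction = frac,
               decision = decision, dominant_alien_label = dom,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(contig_id = names(rows), rank = rank,
                          stringsAsFactors = FALSE), out)
  out <- out[order(out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen a proteome and remove contaminant contigs
#'
#' The end-to-end decontamination procedure: filter each protein's ranked hit
#' list by identity (and excluded taxids), call a taxon per protein at the
#' decision rank, form contig-level consensus votes, and remove every contig
#' whose consensus contradicts the query genome's lineage — together with all
#' proteins it encodes.
#'
#' @param proteome Query proteome: FASTA path or `AAStringSet`.
#' @param membership Named character vector protein id -> contig id covering
#'   every proteome sequence (see [membership_from_gff3()],
#'   [membership_from_tsv()]).
#' @param hit_lists Named list of [hit_list()] objects (precomputed m8 via
#'   [read_tabular_hits()], or [toy_search()] output).
#' @param taxonomy A [taxonomy_table()].
#' @param genome A [query_genome_spec()].
#' @param rank Decision rank; default `"kingdom"`.
#' @param threshold Contig removal threshold; default 0.5.
#' @param min_pident Minimum percent identity for hits; default 20.
#' @param cap Confidence window size; default 10.
#' @param excluded_taxids Subject taxids dropped before calling (typically the
#'   query genome's own taxid, so database copies of its own proteins cannot
#'   mask contamination).
#' @param out_dir If non-`NULL`, write `cleaned.faa`, `removed.tsv`,
#'   `verdicts.tsv` and `summary.json` there.
#' @return Object of class `decontamination_report`: `kept` and `removed`
#'   protein id vectors (input order), `calls`, `verdicts`, `params`.
#' @export
decontaminate <- function(proteome, membership, hit_lists, taxonomy, genome,
                          rank = "kingdom", threshold = 0.5, min_pident = 20,
                          cap = 10L, excluded_taxids = integer(0),
                          out_dir = NULL) {
  seqs <- .as_seq_vector(proteome)
  protein_ids <- names(seqs)
  unmapped <- setdiff(protein_ids, names(membership))
  if (length(unmapped) > 0L) {
    stop("proteome sequence(s) missing from membership: ",
         paste(utils::head(unmapped, 10), collapse = ", "), call. = FALSE)
  }
  filtered <- lapply(hit_lists, filter_hits, min_pident = min_pident,
                     excluded_taxids = excluded_taxids)
  calls <- call_proteins(protein_ids, filtered, rank, taxonomy, cap)
  verdicts <- contig_consensus(calls, membership, genome, rank, threshold)
  removed_contigs <- verdicts$contig_id[verdicts$decision == "REMOVE"]
  on_removed <- unname(membership[protein_ids]) %in% removed_contigs
  report <- structure(
    list(
      kept = protein_ids[!on_removed],
      removed = protein_ids[on_removed],
      calls = calls,
      verdicts = verdicts,
      membership = membership[protein_ids],
      params = list(genome_id = genome$genome_id, rank = rank,
                    threshold = threshold, min_pident = min_pident,
                    cap = as.integer(cap),
                    excluded_taxids = as.integer(excluded_taxids))
    ),
    class = "decontamination_report"
  )
  if (!is.null(out_dir)) {
    write_report(report, seqs, out_dir)
  }
  report
}

#' @export
print.decontamination_report <- function(x, ...) {
  n_rm_ctg <- sum(x$verdicts$decision == "REMOVE")
  cat("<decontamination_report> ", x$params$genome_id, " @", x$params$rank,
      ": ", length(x$kept), " proteins kept, ", length(x$removed),
      " removed on ", n_rm_ctg, " contig(s)\n", sep = "")
  invisible(x)
}

#' Write decontamination outputs to a directory
#'
#' Emits the cleaned proteome FASTA (kept proteins, input order preserved),
#' `removed.tsv` (protein, contig, call label, confidence), `verdicts.tsv`
#' (one row per contig) and `summary.json` (counts overall and per alien
#' source label, plus the parameters used). Outputs are byte-deterministic for
#' identical inputs.
#'
#' @param report A `decontamination_report`.
#' @param seqs Named character vector of the input proteome sequences.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, seqs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kept_seqs <- seqs[report$kept]
  Biostrings::writeXStringSet(Biostrings::AAStringSet(kept_seqs),
                              file.path(out_dir, "cleaned.faa"))
  calls <- report$calls
  rownames(calls) <- calls$protein_id
  removed_tab <- data.frame(
    protein_id = report$removed,
    contig_id = unname(report$membership[report$removed]),
    label = calls[report$removed, "label"],
    confidence = calls[report$removed, "confidence"],
    stringsAsFactors = FALSE
  )
  utils::write.table(removed_tab, file.path(out_dir, "removed.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$verdicts, file.path(out_dir, "verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rm_verdicts <- report$verdicts[report$verdicts$decision == "REMOVE", ,
                                 drop = FALSE]
  by_source <- if (nrow(rm_verdicts) > 0L) {
    agg <- tapply(rm_verdicts$n_proteins, rm_verdicts$dominant_alien_label, sum)
    as.list(agg[order(names(agg))])
  } else {
    stats::setNames(list(), character(0))
  }
  summary <- list(
    genome_id = report$params$genome_id,
    n_proteins = length(report$kept) + length(report$removed),
    n_kept = length(report$kept),
    n_removed = length(report$removed),
    n_contigs = nrow(report$verdicts),
    n_contigs_removed = nrow(rm_verdicts),
    removed_by_source = by_source,
    params = report$params
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Continuous per-protein contamination score
#'
#' Assigns every protein the alien fraction of its contig — the quantity the
#' removal threshold sweeps over — so that a ROC curve over proteins is well
#' defined. A protein on an all-host contig scores 0, on an all-alien contig
#' 1.
#'
#' @param report A `decontamination_report`.
#' @return Named numeric vector in \[0, 1\], one entry per input protein.
#' @export
alien_score_per_protein <- function(report) {
  stopifnot(inherits(report, "decontamination_report"))
  frac <- stats::setNames(report$verdicts$alien_fraction,
                          report$verdicts$contig_id)
  proteins <- names(report$membership)
  stats::setNames(unname(frac[unname(report$membership)]), proteins)
}
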