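#' @importFrom data.table data.table := .N
NULL

# Accept a FASTA path, an AAStringSet, or a named character vector of
# sequences; return a named character vector.
.as_seq_vector <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readAAStringSet(x)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
    return(seqs)
  }
  if (methods::is(x, "XStringSet")) {
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
    return(seqs)
  }
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("expected a FASTA path, an AAStringSet, or a named character vector",
       call. = FALSE)
}

.as_taxid_map <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    dt <- data.table::fread(x, sep = "\t", header = FALSE,
                            colClasses = "character")
    if (ncol(dt) < 2L) stop("taxid map needs two columns: seq_id, taxid",
                            call. = FALSE)
    tx <- suppressWarnings(as.integer(dt[[2L]]))
    if (anyNA(tx)) {
      stop("non-integer taxid at line ", which(is.na(tx))[1], " of ", x,
           call. = FALSE)
    }
    return(stats::setNames(tx, dt[[1L]]))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(stats::setNames(as.integer(x), names(x)))
  }
  stop("expected a two-column TSV path or a named integer vector", call. = FALSE)
}

# (id, pos, kmer) long table for a named character vector of sequences.
.kmer_table <- function(seqs, k) {
  lens <- nchar(seqs)
  usable <- lens >= k
  seqs <- seqs[usable]
  lens <- lens[usable]
  if (length(seqs) == 0L) {
    return(data.table::data.table(id = character(0), pos = integer(0),
                                  kmer = character(0)))
  }
  n_kmers <- lens - k + 1L
  ids <- rep(names(seqs), n_kmers)
  pos <- unlist(lapply(n_kmers, seq_len), use.names = FALSE)
  kmer <- substring(rep(seqs, n_kmers), pos, pos + k - 1L)
  data.table::data.table(id = ids, pos = pos, kmer = kmer)
}

#' Deterministic shared-k-mer protein search
#'
#' A small, fully deterministic stand-in for a fast protein search engine,
#' used to drive the classifier at test and benchmark scale. Each query is
#' scored against every reference sequence by the number of distinct shared
#' amino-acid k-mers; the bitscore is twice that count (an arbitrary fixed
#' scale — only the ordering matters downstream). Percent identity is
#' approximated by the best shared-k-mer diagonal: the largest number of
#' k-mer matches lying on one alignment diagonal, converted to query coverage.
#'
#' @param queries Query proteome: FASTA path, `AAStringSet`, or named
#'   character vector.
#' @param reference Reference proteome in the same forms.
#' @param taxid_map Map from reference sequence id to taxid: two-column TSV
#'   path (`seq_id`, `taxid`) or a named integer vector.
#' @param k K-mer length, at least 3; default 4.
#' @return Named list of [hit_list()] objects, one per query (queries with no
#'   shared k-mer get an empty hit list).
#' @export
toy_search <- function(queries, reference, taxid_map, k = 4L) {
  if (k < 3L) stop("k must be >= 3", call. = FALSE)
  qseqs <- .as_seq_vector(queries)
  rseqs <- .as_seq_vector(reference)
  taxids <- .as_taxid_map(taxid_map)
  missing_tax <- setdiff(names(rseqs), names(taxids))
  if (length(missing_tax) > 0L) {
    stop("reference sequence(s) missing from taxid map: ",
         paste(utils::head(missing_tax, 5), collapse = ", "), call. = FALSE)
  }

  empty <- lapply(names(qseqs), function(q) hit_list(q, NULL))
  names(empty) <- names(qseqs)
  if (length(rseqs) == 0L || length(qseqs) == 0L) return(empty)

  qk <- .kmer_table(qseqs, k)
  rk <- .kmer_table(rseqs, k)
  if (nrow(qk) == 0L || nrow(rk) == 0L) return(empty)
  data.table::setnames(qk, c("qid", "qpos", "kmer"))
  data.table::setnames(rk, c("sid", "spos", "kmer"))

  # distinct-kmer intersection drives the score
  qu <- unique(qk[, c("qid", "kmer")])
  ru <- unique(rk[, c("sid", "kmer")])
  data.table::setkey(ru, kmer)
  shared <- ru[qu, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(shared) == 0L) return(empty)
  score_tab <- shared[, list(n_shared = .N), by = c("qid", "sid")]

  # positional join for the best diagonal (pident approximation)
  pos <- rk[qk, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  pos[, "diag" := pos$qpos - pos$spos]
  diag_tab <- pos[, list(n_diag = .N), by = c("qid", "sid", "diag")]
  best_diag <- diag_tab[, list(best = max(n_diag)), by = c("qid", "sid")]

  score_tab <- best_diag[score_tab, on = c("qid", "sid")]
  qlen <- nchar(qseqs)
  cov <- (score_tab$best + k - 1) / qlen[score_tab$qid]
  score_tab[, "pident" := pmin(100, 100 * cov)]
  score_tab[, "bitscore" := 2 * score_tab$n_shared]

  out <- empty
  chunks <- split(as.data.frame(score_tab), score_tab$qid)
  for (q in names(chunks)) {
    d <- chunks[[q]]
    out[[q]] <- hit_list(q, data.frame(
      subject_id = d$sid,
      subject_taxid = unname(taxids[d$sid]),
      bitscore = d$bitscore,
      pident = d$pident,
      evalue = NA_real_
    ))
  }
  out
}
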