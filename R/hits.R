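#' Construct a ranked hit list for one query protein
#'
#' A hit list holds the ranked homology hits of a single query against the
#' taxonomy-aware reference: subject id, subject taxid, bitscore, percent
#' identity, optional E-value. Hits are sorted by decreasing bitscore; ties are
#' broken by higher percent identity, then lexicographic subject id, so that
#' downstream calls are reproducible.
#'
#' @param query_id Query protein id.
#' @param hits data.frame with columns `subject_id`, `subject_taxid`,
#'   `bitscore`, `pident` and optionally `evalue`.
#' @return Object of class `hit_list`: the sorted data.frame with a
#'   `query_id` attribute.
#' @export
hit_list <- function(query_id, hits) {
  stopifnot(is.character(query_id), length(query_id) == 1L)
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(subject_id = character(0),
                       subject_taxid = integer(0),
                       bitscore = numeric(0),
                       pident = numeric(0),
                       evalue = numeric(0))
  }
  needed <- c("subject_id", "subject_taxid", "bitscore", "pident")
  if (!all(needed %in% names(hits))) {
    stop("hit data.frame must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!("evalue" %in% names(hits))) hits$evalue <- NA_real_
  hits <- hits[, c(needed, "evalue"), drop = FALSE]
  hits$subject_taxid <- as.integer(hits$subject_taxid)
  if (any(hits$bitscore < 0, na.rm = TRUE)) {
    stop("bitscore must be non-negative", call. = FALSE)
  }
  if (any(hits$pident < 0 | hits$pident > 100, na.rm = TRUE)) {
    stop("pident must lie in [0, 100]", call. = FALSE)
  }
  ord <- order(-hits$bitscore, -hits$pident, hits$subject_id, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  structure(hits, query_id = query_id, class = c("hit_list", "data.frame"))
}

#' @export
print.hit_list <- function(x, ...) {
  cat("<hit_list> query ", attr(x, "query_id"), ": ", nrow(x), " hit(s)\n",
      sep = "")
  if (nrow(x) > 0L) print.data.frame(utils::head(x, 10L))
  invisible(x)
}

#' Query id of a hit list
#' @param x A [hit_list()].
#' @return Character scalar.
#' @export
query_id <- function(x) attr(x, "query_id")

#' Read ranked homology hits from BLAST/MMseqs tabular output
#'
#' Parses 12-column BLAST `outfmt 6` / MMseqs `m8` tabular output, optionally
#' extended with a subject-taxid (`staxids`) column, into one [hit_list()] per
#' query. Queries absent from the file simply have no entry — that is the
#' "no hit in the reference" case and yields an UNCLASSIFIED call downstream.
#'
#' @param path Path to the tabular file.
#' @param taxid_column Column index (1-based) holding subject taxids; default
#'   13, the first column after the standard 12.
#' @param multi_taxid Policy for multi-valued taxid cells
#'   (semicolon-separated lists): `"error"` (default) or `"first"`.
#' @return Named list of [hit_list()] objects, one per query id present.
#' @export
read_tabular_hits <- function(path, taxid_column = 13L,
                              multi_taxid = c("error", "first")) {
  multi_taxid <- match.arg(multi_taxid)
  if (!file.exists(path)) stop("hits file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", fill = FALSE)
  if (nrow(dt) == 0L) return(stats::setNames(list(), character(0)))
  if (ncol(dt) < 12L || ncol(dt) < taxid_column) {
    stop("expected >= max(12, taxid_column) columns in ", path,
         " but found ", ncol(dt), call. = FALSE)
  }
  qseqid <- dt[[1L]]
  sseqid <- dt[[2L]]
  pident_raw <- dt[[3L]]
  evalue_raw <- dt[[11L]]
  bitscore_raw <- dt[[12L]]
  taxid_raw <- dt[[taxid_column]]

  if (multi_taxid == "first") {
    taxid_raw <- sub(";.*$", "", taxid_raw)
  } else if (any(grepl(";", taxid_raw, fixed = TRUE))) {
    line <- which(grepl(";", taxid_raw, fixed = TRUE))[1]
    stop("multi-valued taxid cell at line ", line, " of ", path,
         " (use multi_taxid = \"first\" to take the first)", call. = FALSE)
  }

  check_numeric <- function(v, what) {
    x <- suppressWarnings(as.numeric(v))
    if (anyNA(x)) {
      stop("non-numeric ", what, " at line ", which(is.na(x))[1], " of ", path,
           call. = FALSE)
    }
    x
  }
  pident <- check_numeric(pident_raw, "pident")
  bitscore <- check_numeric(bitscore_raw, "bitscore")
  evalue <- check_numeric(evalue_raw, "evalue")
  taxid <- suppressWarnings(as.integer(taxid_raw))
  if (anyNA(taxid)) {
    stop("non-numeric taxid at line ", which(is.na(taxid))[1], " of ", path,
         call. = FALSE)
  }

  df <- data.frame(subject_id = sseqid, subject_taxid = taxid,
                   bitscore = bitscore, pident = pident, evalue = evalue,
                   stringsAsFactors = FALSE)
  by_query <- split(df, qseqid)
  out <- lapply(names(by_query), function(q) hit_list(q, by_query[[q]]))
  stats::setNames(out, names(by_query))
}

#' Filter a hit list by identity and excluded taxids
#'
#' Retains exactly the hits with `pident >= min_pident` whose subject taxid is
#' not excluded; order is preserved. The canonical identity threshold is 20
#' percent. Excluding the query genome's own taxid stops self-hits from public
#' references (which contain the query's own deposited proteins) from always
#' confirming the host label and masking contamination.
#'
#' @param x A [hit_list()].
#' @param min_pident Minimum percent identity in \[0, 100\]; default 20.
#' @param excluded_taxids Integer vector of subject taxids to drop.
#' @return A filtered [hit_list()].
#' @export
filter_hits <- function(x, min_pident = 20, excluded_taxids = integer(0)) {
  stopifnot(inherits(x, "hit_list"))
  if (min_pident < 0 || min_pident > 100) {
    stop("min_pident must lie in [0, 100]", call. = FALSE)
  }
  keep <- x$pident >= min_pident & !(x$subject_taxid %in% excluded_taxids)
  hit_list(query_id(x), as.data.frame(x)[keep, , drop = FALSE])
}

#' Write hit lists to a BLAST outfmt-6 style tabular file
#'
#' Emits the 12 standard columns plus `staxids` (column 13). Unused coordinate
#' columns are written as zeros. Round-trips with [read_tabular_hits()].
#'
#' @param hit_lists Named list of [hit_list()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hit_lists, path) {
  rows <- lapply(hit_lists, function(hl) {
    if (nrow(hl) == 0L) return(NULL)
    data.frame(
      qseqid = query_id(hl), sseqid = hl$subject_id,
      pident = hl$pident, length = 0L, mismatch = 0L, gapopen = 0L,
      qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
      evalue = ifelse(is.na(hl$evalue), 1, hl$evalue),
      bitscore = hl$bitscore, staxids = hl$subject_taxid,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame()
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Run an external homology search engine
#'
#' Thin adapter over DIAMOND or MMseqs2 producing an m8 tabular file that
#' [read_tabular_hits()] can ingest. The package's own tests never require an
#' engine binary; the deterministic [toy_search()] fills that role at test
#' scale.
#'
#' @param engine `"diamond"` or `"mmseqs"`.
#' @param queries Query proteome FASTA path.
#' @param db Engine-formatted database path.
#' @param out Output m8 path.
#' @param sensitivity Engine sensitivity setting, propagated verbatim
#'   (e.g. `"2"` for a very fast MMseqs search).
#' @param threads Number of worker threads.
#' @param dry_run If `TRUE`, return the command line (character vector)
#'   without executing.
#' @return `out` invisibly, or the command vector when `dry_run = TRUE`.
#' @export
run_external_engine <- function(engine = c("diamond", "mmseqs"), queries, db,
                                out, sensitivity = "2", threads = 1L,
                                dry_run = FALSE) {
  engine <- match.arg(engine)
  cmd <- switch(engine,
    diamond = c("diamond", "blastp", "--query", queries, "--db", db,
                "--out", out, "--outfmt", "6", "--sensitive",
                "--threads", as.character(threads)),
    mmseqs = c("mmseqs", "easy-search", queries, db, out, tempfile("mmseqs_tmp"),
               "-s", as.character(sensitivity),
               "--threads", as.character(threads),
               "--format-output",
               "query,target,pident,alnlen,mismatch,gapopen,qstart,qend,tstart,tend,evalue,bits,taxid")
  )
  if (dry_run) return(cmd)
  exe <- Sys.which(cmd[1])
  if (!nzchar(exe)) {
    stop("search engine not found on PATH: ", engine,
         " (install it or supply precomputed tabular hits)", call. = FALSE)
  }
  status <- system2(cmd[1], cmd[-1])
  if (status != 0L) {
    stop(engine, " exited with status ", status, call. = FALSE)
  }
  invisible(out)
}
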