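#' The six fixed taxonomic ranks, from broadest to narrowest
#'
#' Every taxonomic call in taxsieve is made at one of six fixed ranks:
#' superkingdom, kingdom, phylum, class, order, family. Functions that take a
#' `rank` argument accept exactly these names.
#'
#' @return Character vector of the six rank names in decreasing breadth.
#' @export
#' @examples
#' rank_ladder()
rank_ladder <- function() {
  c("superkingdom", "kingdom", "phylum", "class", "order", "family")
}

.check_rank <- function(rank) {
  if (!(is.character(rank) && length(rank) == 1L && rank %in% rank_ladder())) {
    stop("rank must be one of: ", paste(rank_ladder(), collapse = ", "),
         " (got ", deparse(rank), ")", call. = FALSE)
  }
  rank
}

#' Construct a taxonomy table from a lineage data frame
#'
#' A taxonomy table maps taxids to ranked lineages. Missing ranks are
#' represented explicitly as `NA` ("absent"), distinct from the empty string:
#' a protein whose best hit is absent at the decision rank contributes an
#' UNCLASSIFIED vote rather than a silently coerced label.
#'
#' @param lineages data.frame with a `taxid` column plus the six columns named
#'   by [rank_ladder()]. Empty strings are converted to `NA`.
#' @param provenance Tag recording where the table came from
#'   (`"flat-tsv"` or `"ncbi-dump"`).
#' @return An object of class `taxonomy_table`.
#' @export
taxonomy_table <- function(lineages, provenance = "flat-tsv") {
  stopifnot(is.data.frame(lineages))
  needed <- c("taxid", rank_ladder())
  missing_cols <- setdiff(needed, names(lineages))
  if (length(missing_cols) > 0L) {
    stop("lineage table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  lineages <- lineages[, needed, drop = FALSE]
  lineages$taxid <- as.integer(lineages$taxid)
  if (anyNA(lineages$taxid) || any(lineages$taxid <= 0L)) {
    stop("taxids must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(lineages$taxid)) {
    dup <- unique(lineages$taxid[duplicated(lineages$taxid)])
    stop("duplicate taxid(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  for (r in rank_ladder()) {
    v <- trimws(as.character(lineages[[r]]))
    v[!is.na(v) & v == ""] <- NA_character_
    lineages[[r]] <- v
  }
  all_absent <- rowSums(!is.na(as.matrix(lineages[, rank_ladder()]))) == 0L
  if (any(all_absent)) {
    stop("taxid(s) with no rank labeled at all: ",
         paste(lineages$taxid[all_absent], collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      lineages = lineages,
      index = stats::setNames(seq_len(nrow(lineages)), lineages$taxid),
      provenance = provenance
    ),
    class = "taxonomy_table"
  )
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat("<taxonomy_table> ", nrow(x$lineages), " taxids (", x$provenance, ")\n",
      sep = "")
  invisible(x)
}

#' Read a flat lineage TSV into a taxonomy table
#'
#' The canonical internal taxonomy format: a tab-separated file with a header
#' row naming columns `taxid`, `superkingdom`, `kingdom`, `phylum`, `class`,
#' `order`, `family`. An empty cell marks an absent rank.
#'
#' @param path Path to the TSV file.
#' @return A [taxonomy_table()].
#' @export
read_lineage_tsv <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path, call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character",
                      na.strings = NULL, quote = ""),
    error = function(e) stop("failed to parse lineage TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  needed <- c("taxid", rank_ladder())
  if (!all(needed %in% names(dt))) {
    stop("lineage TSV '", path, "' must have header columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(dt)
  bad <- which(is.na(suppressWarnings(as.integer(df$taxid))))
  if (length(bad) > 0L) {
    stop("non-integer taxid at line ", bad[1] + 1L, " of ", path, call. = FALSE)
  }
  taxonomy_table(df, provenance = "flat-tsv")
}

#' Write a taxonomy table to a flat lineage TSV
#'
#' Round-trips exactly with [read_lineage_tsv()]: absent ranks are written as
#' empty cells and read back as absent.
#'
#' @param taxonomy A [taxonomy_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage_tsv <- function(taxonomy, path) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  df <- taxonomy$lineages
  for (r in rank_ladder()) df[[r]][is.na(df[[r]])] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Convert an NCBI-style taxonomy dump into a taxonomy table
#'
#' Reads pipe-delimited `nodes.dmp` (taxid, parent taxid, rank) and
#' `names.dmp` (scientific names) and resolves, for each requested taxid, the
#' labels at the six fixed ranks by climbing the parent chain. Ranks not
#' encountered on the path to the root are absent.
#'
#' @param dir Directory containing `nodes.dmp` and `names.dmp`.
#' @param taxids Optional integer vector restricting which taxids to resolve;
#'   default all taxids in `nodes.dmp`.
#' @return A [taxonomy_table()] with provenance `"ncbi-dump"`.
#' @export
read_ncbi_taxdump <- function(dir, taxids = NULL) {
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  for (p in c(nodes_path, names_path)) {
    if (!file.exists(p)) stop("taxonomy dump file not found: ", p, call. = FALSE)
  }
  parse_dmp <- function(path, n_fields) {
    lines <- readLines(path)
    parts <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
    bad <- which(vapply(parts, length, 1L) < n_fields)
    if (length(bad) > 0L) {
      stop("malformed dump row at line ", bad[1], " of ", path, call. = FALSE)
    }
    parts
  }
  nodes <- parse_dmp(nodes_path, 3L)
  node_taxid <- as.integer(vapply(nodes, `[[`, "", 1L))
  node_parent <- as.integer(vapply(nodes, `[[`, "", 2L))
  node_rank <- vapply(nodes, `[[`, "", 3L)
  if (anyNA(node_taxid)) stop("non-integer taxid in ", nodes_path, call. = FALSE)
  parent_of <- stats::setNames(node_parent, node_taxid)
  rank_of <- stats::setNames(node_rank, node_taxid)

  nm <- parse_dmp(names_path, 4L)
  nm_class <- vapply(nm, `[[`, "", 4L)
  sci <- nm[nm_class == "scientific name"]
  name_of <- stats::setNames(
    vapply(sci, `[[`, "", 2L),
    vapply(sci, `[[`, "", 1L)
  )

  if (is.null(taxids)) taxids <- node_taxid
  taxids <- as.integer(taxids)
  ladder <- rank_ladder()
  rows <- lapply(taxids, function(t) {
    labels <- stats::setNames(rep(NA_character_, 6L), ladder)
    cur <- t
    seen <- integer(0)
    while (!is.na(cur) && !(cur %in% seen)) {
      seen <- c(seen, cur)
      r <- rank_of[as.character(cur)]
      if (!is.na(r) && r %in% ladder) {
        labels[r] <- unname(name_of[as.character(cur)])
      }
      nxt <- parent_of[as.character(cur)]
      if (is.na(nxt) || nxt == cur) break
      cur <- unname(nxt)
    }
    c(list(taxid = t), as.list(labels))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  taxonomy_table(df, provenance = "ncbi-dump")
}

.taxonomy_row <- function(taxonomy, taxid) {
  i <- taxonomy$index[as.character(taxid)]
  if (is.na(i)) {
    stop("unknown taxid: ", taxid, call. = FALSE)
  }
  unname(i)
}

#' Look up the label of a taxid at one rank
#'
#' @param taxonomy A [taxonomy_table()].
#' @param taxid Integer taxid; must be present in the table (unknown taxids
#'   are an error, never a silent empty lineage).
#' @param rank One of [rank_ladder()].
#' @return The taxon name, or `NA_character_` when the rank is absent for this
#'   taxid.
#' @export
label_at_rank <- function(taxonomy, taxid, rank) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  .check_rank(rank)
  i <- .taxonomy_row(taxonomy, taxid)
  taxonomy$lineages[[rank]][i]
}

#' Retrieve the full six-rank lineage of a taxid
#'
#' @inheritParams label_at_rank
#' @return Named character vector over [rank_ladder()]; absent ranks are `NA`.
#' @export
lineage_of <- function(taxonomy, taxid) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  i <- .taxonomy_row(taxonomy, taxid)
  out <- vapply(rank_ladder(), function(r) taxonomy$lineages[[r]][i], "")
  out
}

# Vectorized lookup used on hot paths: returns NA for absent rank, errors on
# unknown taxids.
.labels_at_rank <- function(taxonomy, taxids, rank) {
  idx <- taxonomy$index[as.character(taxids)]
  if (anyNA(idx)) {
    unknown <- unique(taxids[is.na(idx)])
    stop("unknown taxid(s): ", paste(utils::head(unknown, 5), collapse = ", "),
         call. = FALSE)
  }
  taxonomy$lineages[[rank]][unname(idx)]
}
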