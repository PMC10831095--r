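#' Protein-to-contig membership tables
#'
#' Decontamination needs to know which contig or scaffold encodes each
#' protein; coordinates are irrelevant, only co-location matters. A membership
#' table is a named character vector mapping protein id to contig id, with a
#' `dialect` attribute recording its source format.
#'
#' @name membership
NULL

.membership <- function(protein_ids, contig_ids, dialect) {
  if (any(!nzchar(contig_ids))) stop("empty contig id", call. = FALSE)
  tab <- unique(data.frame(protein_id = protein_ids, contig_id = contig_ids,
                           stringsAsFactors = FALSE))
  dup <- tab$protein_id[duplicated(tab$protein_id)]
  if (length(dup) > 0L) {
    stop("protein(s) assigned to more than one contig: ",
         paste(utils::head(unique(dup), 10), collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(tab$contig_id, tab$protein_id)
  attr(out, "dialect") <- dialect
  out
}

#' Derive protein-contig membership from a GFF3 annotation
#'
#' Features of the chosen type are matched; their seqid column (the contig or
#' scaffold) becomes the contig id and the chosen attribute the protein id.
#' Multiple lines of one protein (e.g. its CDS segments) collapse to a single
#' entry; a protein spanning two seqids is an error, since a protein cannot
#' vote on two contigs.
#'
#' @param gff Path to a GFF3 file.
#' @param id_attribute Attribute holding the protein id; default `"ID"`
#'   (e.g. `"protein_id"` for RefSeq-style annotations).
#' @param feature_type Feature type to match; default `"CDS"` (use `"mRNA"`
#'   when protein ids live on transcript features).
#' @return Named character vector protein id -> contig id (see [membership]).
#' @export
membership_from_gff3 <- function(gff, id_attribute = "ID",
                                 feature_type = "CDS") {
  if (!file.exists(gff)) stop("GFF3 file not found: ", gff, call. = FALSE)
  gr <- rtracklayer::import(gff, format = "gff3")
  sel <- as.character(gr$type) == feature_type
  if (!any(sel)) {
    warning("no '", feature_type, "' features in ", gff,
            "; membership is empty")
    return(.membership(character(0), character(0), "gff3"))
  }
  gr <- gr[sel]
  mc <- S4Vectors::mcols(gr)
  if (!(id_attribute %in% names(mc))) {
    stop("attribute '", id_attribute, "' absent from all '", feature_type,
         "' features in ", gff, call. = FALSE)
  }
  ids <- as.character(mc[[id_attribute]])
  if (anyNA(ids)) {
    # locate the offending data line for the error message
    data_lines <- which(!grepl("^#", readLines(gff)))
    all_types <- as.character(S4Vectors::mcols(
      rtracklayer::import(gff, format = "gff3"))$type)
    feat_lines <- data_lines[all_types == feature_type]
    bad <- which(is.na(ids))[1]
    stop("feature without '", id_attribute, "' attribute at line ",
         feat_lines[bad], " of ", gff, call. = FALSE)
  }
  contigs <- as.character(GenomicRanges::seqnames(gr))
  cross <- tapply(contigs, ids, function(v) length(unique(v)) > 1L)
  if (any(cross)) {
    stop("protein(s) spanning multiple contigs: ",
         paste(utils::head(names(cross)[cross], 10), collapse = ", "),
         call. = FALSE)
  }
  .membership(ids, contigs, "gff3")
}

#' Read protein-contig membership from a two-column TSV
#'
#' Expects a header line naming columns `protein_id` and `contig_id`.
#' Duplicate consistent rows are deduplicated; a protein mapped to two
#' different contigs is an error.
#'
#' @param tsv Path to the TSV file.
#' @return Named character vector protein id -> contig id (see [membership]).
#' @export
membership_from_tsv <- function(tsv) {
  if (!file.exists(tsv)) stop("membership file not found: ", tsv, call. = FALSE)
  dt <- data.table::fread(tsv, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  if (!all(c("protein_id", "contig_id") %in% names(dt))) {
    stop("membership TSV must have header columns protein_id, contig_id",
         call. = FALSE)
  }
  .membership(dt$protein_id, dt$contig_id, "tsv")
}

#' Extract protein-contig membership from FASTA headers
#'
#' Some annotation pipelines encode the scaffold in the protein FASTA header
#' itself. This dialect applies a regular expression with one capture group
#' to each full header line; the capture is the contig id.
#'
#' @param fasta Proteome FASTA path (or `AAStringSet`).
#' @param pattern Regular expression with exactly one capture group matching
#'   the contig id within the header.
#' @return Named character vector protein id -> contig id (see [membership]).
#' @export
membership_from_fasta_headers <- function(fasta, pattern) {
  headers <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    names(Biostrings::readAAStringSet(fasta))
  } else {
    names(.as_seq_vector(fasta))
  }
  ids <- sub("\\s.*$", "", headers)
  m <- regmatches(headers, regexec(pattern, headers))
  bad <- vapply(m, length, 1L) < 2L
  if (any(bad)) {
    stop("header(s) not matching contig pattern: ",
         paste(utils::head(headers[bad], 5), collapse = "; "), call. = FALSE)
  }
  contigs <- vapply(m, `[[`, "", 2L)
  .membership(ids, contigs, "fasta-header")
}

#' Write a membership table as a two-column TSV
#'
#' Round-trips with [membership_from_tsv()].
#'
#' @param membership Named character vector protein id -> contig id.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_membership_tsv <- function(membership, path) {
  utils::write.table(
    data.frame(protein_id = names(membership), contig_id = unname(membership),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
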