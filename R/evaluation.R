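AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

# Run code under a local Mersenne-Twister seed and restore RNG state after.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with integer indices (replicate number, grid position)
#' into a new seed below 2^31, so every stochastic step of a sweep is fully
#' determined by one master seed.
#'
#' @param master Master seed (integer).
#' @param ... Integer indices to mix in.
#' @return A positive integer seed.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483629
  s <- as.numeric(master) %% m
  for (v in c(...)) {
    s <- (s * 69069 + as.numeric(v) + 1) %% m
  }
  as.integer(s + 1)
}

.random_aa_seq <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Mutate an amino-acid sequence at a fixed per-position rate
#'
#' Each position is substituted, independently with probability `rate`, by a
#' different residue drawn uniformly from the 19 alternatives. Used by the
#' mock-reference and mock-proteome generators to emulate divergence between
#' a protein family's members.
#'
#' @param seq Amino-acid sequence (single string).
#' @param rate Per-position substitution probability in \[0, 1\].
#' @return Mutated sequence.
#' @export
mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(AA_ALPHABET, ch), 1L)
    }, "")
  }
  paste(chars, collapse = "")
}

#' Generate a mock taxonomy-aware reference database
#'
#' A desk-scale stand-in for a clustered protein reference such as UniRef:
#' for each taxon, `n_families` independent random amino-acid family seeds
#' are drawn, and each seed is accompanied by `n_variants` mutated copies
#' (per-position substitution rate = `divergence`). Because family seeds are
#' independent random sequences, k-mer sharing across families is negligible
#' and [toy_search()] separates the taxa at every rank where their lineages
#' differ. Fully deterministic under `seed`.
#'
#' @param taxa data.frame with columns `taxid`, `n_families`, and the six
#'   rank columns of [rank_ladder()].
#' @param divergence Per-position mutation rate of variants in \[0, 1\].
#' @param n_variants Mutated copies per family seed; default 4.
#' @param seq_len Length range (min, max) of family seeds; default 120-240.
#' @param seed Integer seed.
#' @param dir If non-`NULL`, write `reference.faa`, `taxid_map.tsv` and
#'   `lineage.tsv` there.
#' @return Object of class `mock_reference`: `$reference` (named sequences),
#'   `$taxid_map`, `$taxonomy` ([taxonomy_table()]), `$families` (named list
#'   taxid -> family seed sequences), and `$paths` when `dir` was given.
#' @export
mock_reference <- function(taxa, divergence = 0.05, n_variants = 4L,
                           seq_len = c(120L, 240L), seed = 1L, dir = NULL) {
  stopifnot(is.data.frame(taxa),
            all(c("taxid", "n_families", rank_ladder()) %in% names(taxa)),
            divergence >= 0, divergence <= 1)
  .with_seed(seed, {
    families <- list()
    ref_seqs <- character(0)
    taxid_map <- integer(0)
    for (i in seq_len(nrow(taxa))) {
      taxid <- as.integer(taxa$taxid[i])
      nf <- as.integer(taxa$n_families[i])
      seeds <- vapply(seq_len(nf), function(j) {
        .random_aa_seq(sample(seq_len[1]:seq_len[2], 1L))
      }, "")
      names(seeds) <- sprintf("t%d_fam%03d", taxid, seq_len(nf))
      families[[as.character(taxid)]] <- seeds
      for (j in seq_len(nf)) {
        variants <- vapply(seq_len(n_variants), function(v) {
          mutate_seq(seeds[j], divergence)
        }, "")
        ids <- sprintf("%s_v%02d", names(seeds)[j], seq_len(n_variants))
        entry <- c(stats::setNames(seeds[j], names(seeds)[j]),
                   stats::setNames(variants, ids))
        ref_seqs <- c(ref_seqs, entry)
        taxid_map <- c(taxid_map,
                       stats::setNames(rep(taxid, length(entry)), names(entry)))
      }
    }
    taxonomy <- taxonomy_table(taxa[, c("taxid", rank_ladder())],
                               provenance = "flat-tsv")
    out <- structure(list(reference = ref_seqs, taxid_map = taxid_map,
                          taxonomy = taxonomy, families = families,
                          divergence = divergence),
                     class = "mock_reference")
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      faa <- file.path(dir, "reference.faa")
      Biostrings::writeXStringSet(Biostrings::AAStringSet(ref_seqs), faa)
      map_path <- file.path(dir, "taxid_map.tsv")
      utils::write.table(
        data.frame(seq_id = names(taxid_map), taxid = unname(taxid_map)),
        map_path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
      lin_path <- file.path(dir, "lineage.tsv")
      write_lineage_tsv(taxonomy, lin_path)
      out$paths <- list(reference = faa, taxid_map = map_path,
                        lineage = lin_path)
    }
    out
  })
}

#' Generate a mock annotated proteome from a mock reference
#'
#' Draws proteins as mutated copies of one taxon's family seeds (cycling
#' through the families), so each protein finds its own family's reference
#' variants as top hits under [toy_search()]. Optionally packs the proteins
#' into contigs of fixed size, yielding the membership table of an annotated
#' genome.
#'
#' @param ref A [mock_reference()].
#' @param taxid Which taxon's families to draw from.
#' @param n_proteins Number of proteins to generate.
#' @param divergence Per-position mutation rate relative to the family seed.
#' @param seed Integer seed.
#' @param prefix Id prefix for proteins and contigs.
#' @param contig_size Proteins per contig; `NULL` for no membership.
#' @return List with `$proteome` (named sequences) and `$membership` (or
#'   `NULL`).
#' @export
mock_proteome <- function(ref, taxid, n_proteins, divergence = 0.05, seed = 1L,
                          prefix = paste0("g", taxid), contig_size = NULL) {
  stopifnot(inherits(ref, "mock_reference"))
  seeds <- ref$families[[as.character(taxid)]]
  if (is.null(seeds)) stop("taxid ", taxid, " not in mock reference",
                           call. = FALSE)
  .with_seed(seed, {
    fam_idx <- rep_len(seq_along(seeds), n_proteins)
    seqs <- vapply(fam_idx, function(j) mutate_seq(seeds[j], divergence), "")
    names(seqs) <- sprintf("%s_p%05d", prefix, seq_len(n_proteins))
    membership <- NULL
    if (!is.null(contig_size)) {
      contig <- sprintf("%s_ctg%04d",
                        prefix, ceiling(seq_len(n_proteins) / contig_size))
      membership <- stats::setNames(contig, names(seqs))
    }
    list(proteome = seqs, membership = membership)
  })
}

#' Specify one synthetic contamination replicate
#'
#' The spike-in design transfers a fixed number of randomly selected donor
#' proteins into the recipient proteome, packed onto random virtual contigs
#' of fixed size. Spike levels and contig sizes are restricted to the
#' canonical benchmark grid.
#'
#' @param donor_genome_id,recipient_genome_id Identifiers of the two genomes.
#' @param spike_level Number of transferred proteins; one of 100, 200, 400,
#'   800, 1600, 3200.
#' @param contig_size Alien proteins per virtual contig; one of 1, 2, 5, 10,
#'   20.
#' @param replicate_seed Integer seed fully determining protein selection and
#'   contig assignment.
#' @return Object of class `synthetic_mix_spec`.
#' @export
synthetic_mix_spec <- function(donor_genome_id, recipient_genome_id,
                               spike_level, contig_size, replicate_seed) {
  if (!(spike_level %in% c(100L, 200L, 400L, 800L, 1600L, 3200L))) {
    stop("spike_level must be one of 100, 200, 400, 800, 1600, 3200",
         call. = FALSE)
  }
  if (!(contig_size %in% c(1L, 2L, 5L, 10L, 20L))) {
    stop("contig_size must be one of 1, 2, 5, 10, 20", call. = FALSE)
  }
  structure(list(donor_genome_id = donor_genome_id,
                 recipient_genome_id = recipient_genome_id,
                 spike_level = as.integer(spike_level),
                 contig_size = as.integer(contig_size),
                 replicate_seed = as.integer(replicate_seed)),
            class = "synthetic_mix_spec")
}

#' Build an artificially contaminated proteome
#'
#' Samples `spike_level` donor proteins without replacement, renames them into
#' a spike namespace, packs them into virtual contigs of `contig_size` (the
#' last contig may be smaller), and merges them with the recipient proteome.
#' Ground-truth labels are attached: spiked proteins appear only on virtual
#' contigs, host contigs contain no spikes.
#'
#' @param spec A [synthetic_mix_spec()].
#' @param donor Donor proteome: named character vector of sequences.
#' @param recipient List with `$proteome` and `$membership` (the annotated
#'   recipient genome).
#' @return Object of class `labeled_mix`: `$proteome`, `$membership`,
#'   `$truth` (named vector `HOST`/`SPIKE`), `$origin` (spiked id -> donor
#'   id), `$spec`.
#' @export
generate_mix <- function(spec, donor, recipient) {
  stopifnot(inherits(spec, "synthetic_mix_spec"))
  donor <- .as_seq_vector(donor)
  if (length(donor) < spec$spike_level) {
    stop("donor has ", length(donor), " proteins; spike_level ",
         spec$spike_level, " requested", call. = FALSE)
  }
  .with_seed(spec$replicate_seed, {
    picked <- sample(names(donor), spec$spike_level, replace = FALSE)
    new_ids <- sprintf("spike|%s", picked)
    n_ctg <- ceiling(spec$spike_level / spec$contig_size)
    contig <- sprintf("spike_%s_ctg%05d", spec$donor_genome_id,
                      ceiling(seq_len(spec$spike_level) / spec$contig_size))
    spiked <- stats::setNames(unname(donor[picked]), new_ids)
    proteome <- c(recipient$proteome, spiked)
    membership <- c(recipient$membership, stats::setNames(contig, new_ids))
    truth <- stats::setNames(
      c(rep("HOST", length(recipient$proteome)), rep("SPIKE", length(spiked))),
      names(proteome))
    structure(list(proteome = proteome, membership = membership,
                   truth = truth,
                   origin = stats::setNames(picked, new_ids),
                   n_virtual_contigs = n_ctg, spec = spec),
              class = "labeled_mix")
  })
}

#' ROC curve and AUC for host/spike classification
#'
#' Computes the receiver operating characteristic of a continuous
#' contamination score against ground-truth labels. The AUC uses the
#' rank-based (Mann-Whitney) formulation with midrank handling of ties, and
#' the curve is traced by sweeping a threshold over the distinct score
#' values.
#'
#' @param scores Named numeric vector of per-protein scores (higher = more
#'   contaminant-like).
#' @param truth Named vector with values `"HOST"` or `"SPIKE"` covering the
#'   same proteins.
#' @return Object of class `roc_result`: `$thresholds`, `$tpr`, `$fpr`,
#'   `$auc`.
#' @export
roc_auc <- function(scores, truth) {
  if (is.null(names(scores)) || is.null(names(truth))) {
    stop("scores and truth must be named", call. = FALSE)
  }
  common <- names(scores)
  if (!setequal(common, names(truth))) {
    stop("scores and truth must cover the same proteins", call. = FALSE)
  }
  truth <- truth[common]
  if (!all(truth %in% c("HOST", "SPIKE"))) {
    stop("truth values must be HOST or SPIKE", call. = FALSE)
  }
  is_spike <- truth == "SPIKE"
  n1 <- sum(is_spike); n0 <- sum(!is_spike)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute a ROC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[is_spike]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thresholds, function(t) mean(scores[is_spike] >= t), 0)
  fpr <- vapply(thresholds, function(t) mean(scores[!is_spike] >= t), 0)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", format(x$auc, digits = 4), " (",
      length(x$thresholds), " threshold points)\n", sep = "")
  invisible(x)
}

#' Top-k taxon support ratio of one protein
#'
#' The fraction of the `min(k, n)` best-scoring hits whose taxon label at the
#' given rank matches the expected query taxon. A value near 1 suggests a
#' genuine host protein; near 0, strong disagreement between the expected and
#' observed taxon — a contamination signature. With fewer than `k` hits the
#' available count is the denominator. `NA` when there are no hits.
#'
#' @param x A [hit_list()].
#' @param expected_label Expected taxon label of the query genome at `rank`.
#' @param rank One of [rank_ladder()].
#' @param taxonomy A [taxonomy_table()].
#' @param k Window size; default 10.
#' @return Ratio in \[0, 1\], or `NA` when the hit list is empty.
#' @export
taxon_support_ratio <- function(x, expected_label, rank, taxonomy, k = 10L) {
  stopifnot(inherits(x, "hit_list"))
  .check_rank(rank)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  n <- nrow(x)
  if (n == 0L) return(NA_real_)
  m <- min(k, n)
  labels <- .labels_at_rank(taxonomy, x$subject_taxid[seq_len(m)], rank)
  sum(!is.na(labels) & labels == expected_label) / m
}

#' Select confirmed-contaminant contigs by marker counts
#'
#' Ground-truth filter for manually curated genomes: a contig counts as a
#' confirmed contaminant when it carries at least `min_proteins` proteins, of
#' which at least `min_target` carry marker hits specific to the contaminant
#' lineage and at most `max_other` carry markers specific to the host lineage.
#' The canonical parameterisation (100, 20, 0) reflects screening an oak
#' assembly for ascomycete contigs with no plant-specific markers.
#'
#' @param marker_calls Named character vector protein id -> `"TARGET"`,
#'   `"OTHER"` or `"NONE"` (marker classes are computed externally).
#' @param membership Named character vector protein id -> contig id.
#' @param min_proteins Minimum proteins per contig; default 100.
#' @param min_target Minimum TARGET-marker proteins; default 20.
#' @param max_other Maximum OTHER-marker proteins; default 0.
#' @return Sorted character vector of selected contig ids.
#' @export
marker_contig_filter <- function(marker_calls, membership,
                                 min_proteins = 100L, min_target = 20L,
                                 max_other = 0L) {
  missing <- setdiff(names(marker_calls), names(membership))
  if (length(missing) > 0L) {
    stop("protein(s) missing from membership: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  contigs <- unname(membership[names(marker_calls)])
  n_all <- table(membership)
  n_target <- table(contigs[marker_calls == "TARGET"])
  n_other <- table(contigs[marker_calls == "OTHER"])
  ids <- sort(unique(unname(membership)))
  cnt <- function(tab, id) if (id %in% names(tab)) as.integer(tab[[id]]) else 0L
  sel <- vapply(ids, function(id) {
    cnt(n_all, id) >= min_proteins &&
      cnt(n_target, id) >= min_target &&
      cnt(n_other, id) <= max_other
  }, TRUE)
  ids[sel]
}

#' Run the spike-in benchmark sweep
#'
#' For every combination of spike level, virtual-contig size, decision rank
#' and replicate, builds an artificially contaminated proteome with
#' [generate_mix()], screens it with [decontaminate()] (hits come from one
#' [toy_search()] of recipient + donor against the mock reference, computed
#' once and reused across replicates — the search is per-protein), and
#' records AUC (over the continuous alien score), plus sensitivity and
#' specificity of the binary removal decision. Replicate seeds are derived
#' from one master seed.
#'
#' @param donor List with `$id` and `$proteome`.
#' @param recipient List with `$id`, `$proteome`, `$membership`.
#' @param reference A [mock_reference()] (or any list with `$reference`,
#'   `$taxid_map`, `$taxonomy`).
#' @param genome A [query_genome_spec()] for the recipient.
#' @param spike_levels,contig_sizes,ranks Grid axes.
#' @param replicates Replicates per grid cell; must be >= 1.
#' @param master_seed Master seed for the sweep.
#' @param threshold,min_pident,cap Screening parameters (see
#'   [decontaminate()]).
#' @param k Toy-search k-mer length.
#' @return data.frame with one row per (spike_level, contig_size, rank,
#'   replicate): columns `donor`, `recipient`, `rank`, `spike_level`,
#'   `contig_size`, `replicate`, `auc`, `sensitivity`, `specificity`.
#' @export
benchmark_sweep <- function(donor, recipient, reference, genome,
                            spike_levels = c(100L, 400L),
                            contig_sizes = c(1L, 5L, 20L),
                            ranks = "superkingdom",
                            replicates = 10L, master_seed = 1L,
                            threshold = 0.5, min_pident = 20, cap = 10L,
                            k = 4L) {
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  all_queries <- c(recipient$proteome, donor$proteome)
  hits <- toy_search(all_queries, reference$reference, reference$taxid_map,
                     k = k)
  grid <- expand.grid(spike_level = as.integer(spike_levels),
                      contig_size = as.integer(contig_sizes),
                      rank = ranks, replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    seed_i <- derive_seed(master_seed, g$spike_level, g$contig_size,
                          match(g$rank, rank_ladder()), g$replicate)
    spec <- synthetic_mix_spec(donor$id, recipient$id, g$spike_level,
                               g$contig_size, seed_i)
    mix <- generate_mix(spec, donor$proteome, recipient)
    mix_hits <- hits[names(recipient$proteome)]
    spike_hits <- hits[unname(mix$origin)]
    names(spike_hits) <- names(mix$origin)
    spike_hits <- lapply(names(spike_hits), function(id) {
      hit_list(id, as.data.frame(spike_hits[[id]]))
    })
    names(spike_hits) <- names(mix$origin)
    report <- decontaminate(mix$proteome, mix$membership,
                            c(mix_hits, spike_hits), reference$taxonomy,
                            genome, rank = g$rank, threshold = threshold,
                            min_pident = min_pident, cap = cap)
    scores <- alien_score_per_protein(report)
    auc <- roc_auc(scores, mix$truth)$auc
    spike_ids <- names(mix$truth)[mix$truth == "SPIKE"]
    host_ids <- names(mix$truth)[mix$truth == "HOST"]
    data.frame(donor = donor$id, recipient = recipient$id, rank = g$rank,
               spike_level = g$spike_level, contig_size = g$contig_size,
               replicate = g$replicate, auc = auc,
               sensitivity = mean(spike_ids %in% report$removed),
               specificity = mean(host_ids %in% report$kept),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
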