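#' Built-in anchoring aligner
#'
#' Desk-scale, dependency-free anchoring: exact k-mer seeding on both
#' strands, collinear chaining by a banded dynamic programme that maximizes
#' the number of chained seeds subject to a maximum join distance,
#' identity estimated as matched-seed span over chained span and
#' query coverage as the fraction of alignable (non-N) query bases covered by
#' chained seeds. The best chain per strand is reported first (`rank` 1);
#' further chains (after masking the best chain's target span) expose
#' multi-copy targets. Deterministic.
#'
#' Any function with the same signature and return shape can stand in for
#' this aligner (for example an adapter around an external long-read
#' mapper); every higher-level operation takes the aligner as an argument.
#'
#' @param query,target DNA strings (character scalars).
#' @param k Seed length (default 21).
#' @param max_occ Per-k-mer occurrence cap in the target; seeds from k-mers
#'   more frequent than this are dropped (repeat filter, default 64).
#' @param max_chains Chains reported per strand (default 2).
#' @param max_join Maximum distance (bp, on query and target) bridged by one
#'   chain step (default 5000); larger jumps start a new chain, so the
#'   copies of a duplicated locus surface as separate chains.
#' @return Tibble with columns `strand`, `tstart`, `tend`, `qstart`, `qend`
#'   (1-based closed), `n_seeds`, `identity`, `coverage`, `rank`.
#' @examples
#' t <- paste0(strrep("A", 30), "GATTACAGATTACAGATTACAG", strrep("C", 30))
#' builtin_anchor_align("GATTACAGATTACAGATTACAG", t, k = 11)
#' @export
builtin_anchor_align <- function(query, target, k = 21L, max_occ = 64L,
                                 max_chains = 2L, max_join = 5000L) {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(target), length(target) == 1L)
  if (nchar(query) < k) {
    abort(sprintf("query (length %d) is shorter than k = %d", nchar(query), k))
  }
  as_tibble(cpp_anchor_hits(query, target, as.integer(k), as.integer(max_occ),
                            as.integer(max_chains), as.integer(max_join),
                            64L))[, -1]
}

#' Map query intervals onto a donor assembly
#'
#' Batch anchoring of named query sequences (typically reference gene bodies
#' or gap-flank marker intervals) against every record of a donor assembly.
#' For each query the best hit by (coverage, identity) lexicographic order is
#' kept. A query is `"unmapped"` when its best hit falls below the coverage
#' or identity thresholds, and `"duplicated"` when a second, well-separated
#' hit scores close to the best one (such markers are excluded as anchors,
#' since duplicated genes are a known cause of mis-anchoring).
#'
#' @param queries Named character vector of query sequences, or a tibble
#'   with columns `id` and `seq`.
#' @param donor An [assembly].
#' @param k,max_occ See [builtin_anchor_align()].
#' @param min_identity,min_coverage Acceptance thresholds (defaults 0.9;
#'   chosen to tolerate subspecies-level point divergence while rejecting
#'   paralogs).
#' @param dup_ratio A second hit with coverage at least `dup_ratio` times
#'   the best hit's coverage (and identity above threshold) flags the query
#'   as duplicated (default 0.8).
#' @param aligner Anchoring function honouring the [builtin_anchor_align()]
#'   contract.
#' @return Tibble: `id`, `status` (`mapped`/`unmapped`/`duplicated`/`all_n`),
#'   `donor_seq_id`, `start`, `end`, `strand`, `identity`, `coverage`,
#'   `n_seeds`.
#' @export
anchor_map <- function(queries, donor, k = 21L, max_occ = 64L,
                       min_identity = 0.9, min_coverage = 0.9,
                       dup_ratio = 0.8, max_join = 5000L, aligner = NULL) {
  stopifnot(is_assembly(donor))
  if (is.character(queries)) queries <- tibble(id = names(queries), seq = unname(queries))
  stopifnot(all(c("id", "seq") %in% names(queries)))
  n_valid <- nchar(gsub("N", "", queries$seq, fixed = TRUE))

  hit_rows <- vector("list", nrow(donor$info))
  for (i in seq_len(nrow(donor$info))) {
    target <- as.character(donor$seqs[[i]])
    h <- if (is.null(aligner)) {
      as_tibble(cpp_anchor_hits(queries$seq, target, as.integer(k),
                                as.integer(max_occ), 2L, as.integer(max_join),
                                64L))
    } else {
      bind_rows(lapply(seq_len(nrow(queries)), function(qi) {
        out <- aligner(queries$seq[qi], target, k = k)
        if (nrow(out)) out$query <- qi
        out
      }))
    }
    if (nrow(h)) h$donor_seq_id <- donor$info$seq_id[i]
    hit_rows[[i]] <- h
  }
  hits <- bind_rows(hit_rows)

  out <- lapply(seq_len(nrow(queries)), function(qi) {
    base <- tibble(id = queries$id[qi], status = "unmapped",
                   donor_seq_id = NA_character_, start = NA_integer_,
                   end = NA_integer_, strand = NA_character_,
                   identity = NA_real_, coverage = NA_real_,
                   n_seeds = NA_integer_)
    if (n_valid[qi] == 0) { base$status <- "all_n"; return(base) }
    h <- hits[!is.na(hits$query) & hits$query == qi, , drop = FALSE]
    if (nrow(h) == 0) return(base)
    h <- h[order(-h$coverage, -h$identity), , drop = FALSE]
    b <- h[1, , drop = FALSE]
    if (b$coverage < min_coverage || b$identity < min_identity) return(base)
    # competing hits: anywhere else in the donor, outside the best chain span
    rest <- h[-1, , drop = FALSE]
    separate <- rest$donor_seq_id != b$donor_seq_id |
      rest$tstart > b$tend | rest$tend < b$tstart
    dup <- any(separate & rest$coverage >= dup_ratio * b$coverage &
                 rest$identity >= min_identity)
    # extend the chained span to the full query extent (ungapped estimate),
    # so anchor boundaries stay exact when terminal seeds die to mismatches
    qlen <- nchar(queries$seq[qi])
    tlen <- donor$info$length[match(b$donor_seq_id, donor$info$seq_id)]
    if (b$strand == "+") {
      s_ext <- b$tstart - (b$qstart - 1L)
      e_ext <- b$tend + (qlen - b$qend)
    } else {
      s_ext <- b$tstart - (qlen - b$qend)
      e_ext <- b$tend + (b$qstart - 1L)
    }
    tibble(id = queries$id[qi],
           status = if (dup) "duplicated" else "mapped",
           donor_seq_id = b$donor_seq_id,
           start = max(1L, as.integer(s_ext)),
           end = min(tlen, as.integer(e_ext)),
           strand = b$strand, identity = b$identity, coverage = b$coverage,
           n_seeds = b$n_seeds)
  })
  bind_rows(out)
}

#' Locate one reference gene in a donor assembly
#'
#' Extracts the gene body from the reference and anchors it in the donor.
#' Returns a one-row anchor hit, or a zero-row tibble when the best hit
#' falls below the thresholds or the gene is duplicated in the donor.
#'
#' @param gene One-row gene tibble (`gene_id`, `seq_id`, `start`, `end`).
#' @param reference,donor [assembly] objects.
#' @inheritParams anchor_map
#' @export
map_gene_to_donor <- function(gene, reference, donor, k = 21L,
                              min_identity = 0.9, min_coverage = 0.9,
                              aligner = NULL) {
  stopifnot(nrow(gene) == 1)
  s <- asm_subseq(reference, gene$seq_id, gene$start, gene$end)
  if (nchar(gsub("N", "", s, fixed = TRUE)) == 0) {
    abort(paste0("gene ", gene$gene_id, " is all-N in the reference: unmappable marker"))
  }
  res <- anchor_map(setNames(s, gene$gene_id), donor, k = k,
                    min_identity = min_identity, min_coverage = min_coverage,
                    aligner = aligner)
  res[res$status == "mapped", , drop = FALSE]
}

#' Compare gene order and orientation across assemblies
#'
#' Checks whether each assembly presents the listed genes in the reference
#' order with consistent relative orientation. A full reversal of the order
#' with all relative strands flipped counts as concordant (the whole region
#' may sit on the other strand in that assembly). Genes absent from an
#' assembly are noted and, unless `strict`, do not break concordance.
#'
#' @param gene_ids Gene ids in reference positional order.
#' @param anchor_tables Named list of anchor tibbles (from [anchor_map()]),
#'   one per assembly.
#' @param strict Treat absences as discordance (default `FALSE`).
#' @param region Optional region label carried into the result.
#' @return Tibble: `assembly_id`, `n_present`, `concordant`, `flipped`,
#'   `note`; attribute `"region"` carries the label.
#' @export
compare_gene_order <- function(gene_ids, anchor_tables, strict = FALSE,
                               region = NA_character_) {
  rows <- imap(anchor_tables, function(tab, aid) {
    tab <- tab[tab$id %in% gene_ids & tab$status == "mapped", , drop = FALSE]
    absent <- setdiff(gene_ids, tab$id)
    note <- character()
    if (length(absent)) note <- c(note, paste0("absent: ", paste(absent, collapse = ",")))
    if (nrow(tab) == 0) {
      return(tibble(assembly_id = aid, n_present = 0L,
                    concordant = !strict || length(absent) == 0,
                    flipped = NA, note = paste(note, collapse = "; ")))
    }
    if (length(unique(tab$donor_seq_id)) > 1) {
      note <- c(note, "genes split across donor sequences")
      return(tibble(assembly_id = aid, n_present = nrow(tab), concordant = FALSE,
                    flipped = NA, note = paste(note, collapse = "; ")))
    }
    ref_order <- gene_ids[gene_ids %in% tab$id]
    obs <- tab$id[order(tab$start)]
    strands <- setNames(tab$strand, tab$id)
    fwd_ok <- identical(obs, ref_order) && all(strands == "+")
    rev_ok <- identical(obs, rev(ref_order)) && all(strands == "-")
    conc <- fwd_ok || rev_ok
    if (strict && length(absent)) conc <- FALSE
    if (!fwd_ok && !rev_ok) {
      mism <- obs[obs != ref_order]
      bad_strand <- names(strands)[strands != (if (identical(obs, rev(ref_order))) "-" else "+")]
      if (length(mism)) note <- c(note, paste0("order differs at: ", paste(unique(mism), collapse = ",")))
      if (length(bad_strand)) note <- c(note, paste0("strand differs at: ", paste(bad_strand, collapse = ",")))
    }
    tibble(assembly_id = aid, n_present = nrow(tab), concordant = conc,
           flipped = rev_ok, note = paste(note, collapse = "; "))
  })
  out <- bind_rows(rows)
  attr(out, "region") <- region
  out
}
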