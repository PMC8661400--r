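#' Curation parameters
#'
#' All thresholds of the workflow in one named list, with the defaults used
#' throughout the documentation. Every value can be overridden by passing a
#' modified list to [curate_assembly()].
#'
#' @param ... Named overrides of the defaults.
#' @export
curation_config <- function(...) {
  cfg <- list(
    min_run = 10L,                 # minimum N-run length counted as a gap
    arbitrary_lengths = c(25L, 200L),
    k = 21L,                       # anchor seed length
    max_occ = 64L,                 # per-k-mer occurrence cap (repeat filter)
    min_identity = 0.9,            # anchor acceptance
    min_coverage = 0.9,
    flank_len = 100L,              # candidate flank validation
    min_flank_identity = 0.95,
    adjacency_tol = 20L,
    post_flank_len = 200L,         # post-splice junction verification
    junction_window = 50L,
    min_support = 3L,              # donors that must agree on a placement
    telomere_motifs = c("TTAGG", "CCTAA"),
    telomere_window = 1000L,
    telomere_min_density = 0.4,
    terminal_zone = 10000L,
    redundant_min_coverage = 0.9,
    redundant_min_identity = 0.98
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) abort(paste0("unknown config entries: ", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  cfg
}

#' Run the full curation workflow
#'
#' Stage order: gap census with flanking-gene context; marker anchoring in
#' every donor; GCS candidate extraction, flank validation and depth
#' scoring; candidate ranking; scaffold placement by gene-order consensus;
#' telomere recovery proposals; splice application with liftover; post-splice
#' junction checks (events that fail are rolled back and their gaps
#' reported open); annotation lifting; redundancy removal; report. A failure
#' at any per-gap step quarantines that gap with a reason — it never aborts
#' the run. The workflow contains no randomness: identical inputs give
#' identical output.
#'
#' @param reference Reference [assembly] (chromosome records are curated;
#'   unplaced/unlocalized records are treated as scaffolds).
#' @param genes Gene tibble (`gene_id`, `seq_id`, `start`, `end`, `strand`),
#'   covering chromosomes and, optionally, scaffolds.
#' @param donors Named list; each element `list(assembly =, class =)` with
#'   class `"reassembly"` or `"alternative"`.
#' @param depth Optional named list of `depth_track`s keyed like `donors`
#'   (reference reads mapped to each donor).
#' @param config A [curation_config()] list.
#' @param stages `"full"` or `"selection"` (stop after candidate ranking;
#'   used for fast screening of candidate quality).
#' @return An object of class `curation`; see [tidy.curation()] and
#'   [glance.curation()].
#' @export
curate_assembly <- function(reference, genes, donors, depth = NULL,
                            config = curation_config(),
                            stages = c("full", "selection")) {
  stages <- match.arg(stages)
  stopifnot(is_assembly(reference))
  for (dn in names(donors)) {
    stopifnot(is_assembly(donors[[dn]]$assembly),
              donors[[dn]]$class %in% c("reassembly", "alternative"))
  }
  cfg <- config
  chrom_ids <- asm_ids(reference, "chromosome")
  chrom_genes <- genes[genes$seq_id %in% chrom_ids, , drop = FALSE]

  # ---- census --------------------------------------------------------------
  gaps <- gap_census(reference, chrom_genes, min_run = cfg$min_run,
                     arbitrary_lengths = cfg$arbitrary_lengths)

  # ---- markers -------------------------------------------------------------
  marker_defs <- list(); marker_q <- list()
  for (i in seq_len(nrow(gaps))) {
    gp <- gaps[i, ]
    if (!gp$closable) next
    mk <- gap_markers(gp, chrom_genes)
    if (is.null(mk)) { gaps$closable[i] <- FALSE; next }
    marker_defs[[gp$gap_id]] <- mk
    for (s in c("up", "down")) {
      m <- mk$markers[mk$markers$side == s, ]
      qid <- paste0(gp$gap_id, "|", s)
      marker_q[[qid]] <- asm_subseq(reference, gp$seq_id, m$start, m$end)
    }
  }
  marker_q <- unlist(marker_q)

  # ---- anchor markers in every donor --------------------------------------
  anchors <- list()
  for (dn in names(donors)) {
    anchors[[dn]] <- if (length(marker_q)) {
      anchor_map(marker_q, donors[[dn]]$assembly, k = cfg$k,
                 max_occ = cfg$max_occ, min_identity = cfg$min_identity,
                 min_coverage = cfg$min_coverage)
    } else tibble()
  }

  # ---- candidates ----------------------------------------------------------
  cand_rows <- list()
  for (gid in names(marker_defs)) {
    gp <- gaps[gaps$gap_id == gid, ]
    mk <- marker_defs[[gid]]
    for (dn in names(donors)) {
      an <- anchors[[dn]]
      up <- an[an$id == paste0(gid, "|up"), , drop = FALSE]
      dn_hit <- an[an$id == paste0(gid, "|down"), , drop = FALSE]
      cand <- tryCatch({
        if (nrow(up) != 1 || up$status != "mapped" ||
            nrow(dn_hit) != 1 || dn_hit$status != "mapped") {
          reason <- unique(c(up$status, dn_hit$status))
          reason <- setdiff(reason, "mapped")
          tibble(gap_id = gid, donor_id = dn,
                 source_class = donors[[dn]]$class,
                 donor_seq_id = NA_character_, donor_start = NA_integer_,
                 donor_end = NA_integer_, strand = NA_character_,
                 sequence = NA_character_, gcs_length = NA_integer_,
                 ref_seq_id = mk$replaced$seq_id,
                 replaced_start = mk$replaced$start,
                 replaced_end = mk$replaced$end,
                 up_flank = NA_character_, down_flank = NA_character_,
                 up_flank_identity = NA_real_, down_flank_identity = NA_real_,
                 depth_mean = NA_real_, depth_cv = NA_real_,
                 status = "rejected",
                 reason = paste0("anchor_", paste(reason, collapse = "/")))
        } else {
          ext <- extract_gcs(gp, donors[[dn]]$assembly,
                             up[, ], dn_hit[, ], mk, donor_id = dn,
                             source_class = donors[[dn]]$class,
                             min_run = cfg$min_run, flank_len = cfg$flank_len)
          suppressWarnings(validate_flanks(
            ext, reference, flank_len = cfg$flank_len,
            min_flank_identity = cfg$min_flank_identity,
            adjacency_tol = cfg$adjacency_tol))
        }
      }, error = function(e) {
        tibble(gap_id = gid, donor_id = dn, source_class = donors[[dn]]$class,
               status = "rejected", reason = paste0("error: ", conditionMessage(e)))
      })
      cand_rows[[paste(gid, dn)]] <- cand
    }
  }
  candidates <- bind_rows(cand_rows)
  if (nrow(candidates)) candidates <- add_depth_stats(candidates, depth)

  # ---- selection -----------------------------------------------------------
  selections <- list()
  for (gid in names(marker_defs)) {
    sel <- rank_candidates(candidates[candidates$gap_id == gid, , drop = FALSE])
    if (nrow(sel)) selections[[gid]] <- mutate(sel, status = "selected")
  }
  selections <- bind_rows(selections)
  if (nrow(selections) == 0 && nrow(candidates) == 0) {
    selections <- candidates
  }

  res <- structure(list(
    reference = reference, genes = genes, gaps = gaps, anchors = anchors,
    candidates = candidates, selections = selections, config = cfg
  ), class = "curation")
  if (stages == "selection") return(res)

  # ---- gap-closing events --------------------------------------------------
  events <- NULL
  if (nrow(selections)) {
    events <- splice_events(
      seq_id = selections$ref_seq_id, start = selections$replaced_start,
      end = selections$replaced_end, replacement = selections$sequence,
      type = "gap_close", donor_id = selections$donor_id,
      donor_start = selections$donor_start, donor_end = selections$donor_end,
      strand = selections$strand,
      event_id = paste0("close_", selections$gap_id))
    # a shared replaced interval (two gaps in one gene) needs only one event
    events <- distinct(events, .data$seq_id, .data$start, .data$end,
                       .keep_all = TRUE)
  }

  # ---- scaffold placement by consensus ------------------------------------
  scaffold_ids <- asm_ids(reference, c("unplaced", "unlocalized"))
  ref_anchor_genes <- NULL
  placements <- tibble()
  if (length(scaffold_ids)) {
    gene_seq <- function(tb) {
      setNames(vapply(seq_len(nrow(tb)), function(i) {
        asm_subseq(reference, tb$seq_id[i], tb$start[i], tb$end[i])
      }, character(1)), tb$gene_id)
    }
    ref_anchors <- list(); scaf_anchor <- list()
    scaf_genes_all <- genes[genes$seq_id %in% scaffold_ids, , drop = FALSE]
    if (nrow(scaf_genes_all)) {
      refq <- gene_seq(chrom_genes)
      scq <- gene_seq(scaf_genes_all)
      for (dn in names(donors)) {
        ref_anchors[[dn]] <- anchor_map(refq, donors[[dn]]$assembly, k = cfg$k,
                                        max_occ = cfg$max_occ,
                                        min_identity = cfg$min_identity,
                                        min_coverage = cfg$min_coverage)
        scaf_anchor[[dn]] <- anchor_map(scq, donors[[dn]]$assembly, k = cfg$k,
                                        max_occ = cfg$max_occ,
                                        min_identity = cfg$min_identity,
                                        min_coverage = cfg$min_coverage)
      }
    }
    placements <- bind_rows(lapply(scaffold_ids, function(sid) {
      sg <- scaf_genes_all[scaf_genes_all$seq_id == sid, , drop = FALSE]
      if (nrow(sg) == 0) {
        return(tibble(scaffold_id = sid, action = "unresolved",
                      target_seq = NA_character_, target_start = NA_integer_,
                      target_end = NA_integer_, orientation = NA_character_,
                      supporting_assemblies = 0L, gap_id = NA_character_,
                      note = "no_markers"))
      }
      sh <- lapply(scaf_anchor, function(t) t[t$id %in% sg$gene_id, , drop = FALSE])
      consensus_place_scaffold(sid, sg, sh, ref_anchors, chrom_genes, gaps,
                               min_support = cfg$min_support)
    }))
  }

  # ---- telomere recovery ---------------------------------------------------
  telo_params <- list(motifs = cfg$telomere_motifs, window = cfg$telomere_window,
                      min_density = cfg$telomere_min_density,
                      terminal_zone = cfg$terminal_zone)
  ref_scan <- do.call(scan_telomeres, c(list(asm = reference), telo_params))
  absent <- ref_scan$calls[ref_scan$calls$call == "absent", , drop = FALSE]
  donor_order <- names(donors)[order(vapply(donors, function(d) d$class, character(1)) != "reassembly",
                                     names(donors))]
  telo_log <- list(); telo_events <- NULL
  for (i in seq_len(nrow(absent))) {
    sid <- absent$seq_id[i]; side <- absent$end[i]
    got <- NULL
    for (dn in donor_order) {
      prop <- tryCatch(
        recover_telomere(reference, chrom_genes, sid, side,
                         donors[[dn]]$assembly, dn,
                         ref_scan = ref_scan, k = cfg$k,
                         min_identity = cfg$min_identity,
                         min_coverage = cfg$min_coverage,
                         telomere_params = telo_params),
        error = function(e) list(event = NULL, reason = conditionMessage(e)))
      telo_log[[paste(sid, side, dn)]] <- tibble(
        seq_id = sid, end = side, donor_id = dn, reason = prop$reason)
      if (!is.null(prop$event)) { got <- prop$event; break }
    }
    if (!is.null(got)) telo_events <- bind_rows(telo_events, got)
  }
  # drop telomere events that would overlap an accepted gap-close event
  if (!is.null(telo_events) && !is.null(events)) {
    keep <- vapply(seq_len(nrow(telo_events)), function(i) {
      ev <- telo_events[i, ]
      !any(events$seq_id == ev$seq_id & events$start <= ev$end &
             events$end >= ev$start)
    }, logical(1))
    telo_events <- telo_events[keep, , drop = FALSE]
  }
  all_events <- bind_rows(events, telo_events)

  # ---- apply, verify, roll back failures ----------------------------------
  chroms <- asm_subset(reference, chrom_ids)
  post <- tibble()
  if (!is.null(all_events) && nrow(all_events)) {
    for (attempt in 1:2) {
      ap <- apply_splices(chroms, all_events)
      post <- post_splice_check(ap$assembly, chroms, ap$chain,
                                flank_len = cfg$post_flank_len,
                                junction_window = cfg$junction_window,
                                min_identity = cfg$min_flank_identity,
                                adjacency_tol = cfg$adjacency_tol)
      bad <- post$event_id[!post$pass]
      if (!length(bad)) break
      all_events <- all_events[!all_events$event_id %in% bad, , drop = FALSE]
      if (!nrow(all_events)) { ap <- apply_splices(chroms, all_events); break }
    }
    corrected_chroms <- ap$assembly
    chain <- ap$chain
  } else {
    ap <- apply_splices(chroms, splice_events(character(), integer(), integer(),
                                              character())[0, ])
    corrected_chroms <- ap$assembly
    chain <- ap$chain
    all_events <- splice_events(character(), integer(), integer(), character())[0, ]
  }

  # ---- lift annotation -----------------------------------------------------
  lifted <- lift_annotation(chrom_genes, chain)

  # ---- redundancy removal --------------------------------------------------
  redundancy <- tibble()
  retained_scaffolds <- scaffold_ids
  if (length(scaffold_ids)) {
    redundancy <- detect_redundant(asm_subset(reference, scaffold_ids),
                                   corrected_chroms, chain,
                                   min_coverage = cfg$redundant_min_coverage,
                                   min_identity = cfg$redundant_min_identity,
                                   k = cfg$k, max_occ = cfg$max_occ)
    retained_scaffolds <- redundancy$scaffold_id[redundancy$action == "retained"]
  }
  corrected <- {
    keep_seqs <- c(setNames(as.character(corrected_chroms$seqs),
                            corrected_chroms$info$seq_id),
                   setNames(lapply(retained_scaffolds, asm_seq, asm = reference),
                            retained_scaffolds))
    info_sc <- reference$info[match(retained_scaffolds, reference$info$seq_id), , drop = FALSE]
    assembly(unlist(keep_seqs),
             role = c(corrected_chroms$info$role, info_sc$role),
             associated_chromosome = c(corrected_chroms$info$associated_chromosome,
                                       info_sc$associated_chromosome))
  }
  cor_scan <- do.call(scan_telomeres, c(list(asm = corrected), telo_params))

  # ---- report --------------------------------------------------------------
  applied_close <- all_events[all_events$type == "gap_close", , drop = FALSE]
  closed <- if (nrow(selections) && nrow(applied_close)) {
    # a gap is closed when the event replacing its interval was applied
    # (two gaps sharing one replaced interval are closed by one event)
    selections[paste(selections$ref_seq_id, selections$replaced_start) %in%
                 paste(applied_close$seq_id, applied_close$start), , drop = FALSE]
  } else NULL
  closures <- if (is.null(closed) || nrow(closed) == 0) {
    tibble(gap_id = character(), gap_bp = integer(), replaced_bp = integer(),
           gcs_source = character(), gcs_bp = integer())
  } else {
    tibble(
      gap_id = closed$gap_id,
      gap_bp = gaps$length[match(closed$gap_id, gaps$gap_id)],
      replaced_bp = closed$replaced_end - closed$replaced_start + 1L,
      gcs_source = closed$donor_id,
      gcs_bp = closed$gcs_length)
  }
  open_gaps <- gaps[!gaps$gap_id %in% closures$gap_id, , drop = FALSE]
  open_reason <- vapply(open_gaps$gap_id, function(gid) {
    if (!gid %in% gaps$gap_id[gaps$closable]) return("no_flanking_anchors")
    cc <- candidates[candidates$gap_id == gid, , drop = FALSE]
    if (nrow(cc) == 0) return("no_candidates")
    if (any(cc$status == "validated")) return("splice_failed_verification")
    paste(unique(cc$reason[!is.na(cc$reason)]), collapse = "/")
  }, character(1))
  applied_telo <- all_events[all_events$type == "telomere_add", , drop = FALSE]
  removed <- if (nrow(redundancy)) {
    redundancy$scaffold_id[redundancy$action == "redundant"]
  } else character()
  removed_bp <- sum(reference$info$length[match(removed, reference$info$seq_id)])
  totals <- tibble(
    n_gaps_before = nrow(gaps),
    n_gaps_closed = nrow(closures),
    closed_bp = sum(closures$gap_bp),
    n_telomeres_recovered = nrow(applied_telo),
    telomere_bp = sum(nchar(applied_telo$replacement)),
    n_scaffolds_removed = length(removed),
    scaffold_bp = removed_bp,
    grand_total_bp = sum(closures$gap_bp) + sum(nchar(applied_telo$replacement)) + removed_bp)

  res$placements <- placements
  res$telomeres <- list(before = ref_scan, after = cor_scan,
                        log = bind_rows(telo_log), events = applied_telo)
  res$events <- all_events
  res$post_checks <- post
  res$corrected <- corrected
  res$chain <- chain
  res$lifted_genes <- lifted
  res$redundancy <- redundancy
  res$report <- list(
    census_before = census_summary(gaps),
    census_after = census_summary(gap_census(corrected, min_run = cfg$min_run,
                                             arbitrary_lengths = cfg$arbitrary_lengths)),
    closures = closures,
    open_gaps = mutate(open_gaps, reason = unname(open_reason)),
    totals = totals,
    removed_scaffolds = removed)
  res
}

#' @export
print.curation <- function(x, ...) {
  cat("<curation>\n")
  if (!is.null(x$report)) {
    print(glance(x))
  } else {
    cat(sprintf("  selection stage: %d gap(s), %d candidate(s), %d selected\n",
                nrow(x$gaps), nrow(x$candidates), nrow(x$selections)))
  }
  invisible(x)
}

#' Tidy a curation result
#'
#' `tidy()` returns the per-gap closure table (gap size, replaced-region
#' size, GCS source and size); `glance()` a one-row summary of the totals.
#'
#' @param x A `curation` object.
#' @param ... Unused.
#' @method tidy curation
#' @export
tidy.curation <- function(x, ...) {
  if (is.null(x$report)) return(x$selections)
  x$report$closures
}

#' @rdname tidy.curation
#' @method glance curation
#' @export
glance.curation <- function(x, ...) {
  if (is.null(x$report)) {
    return(tibble(n_gaps = nrow(x$gaps),
                  n_candidates = nrow(x$candidates),
                  n_selected = nrow(x$selections)))
  }
  x$report$totals
}

#' Summarize a closure table
#'
#' Exact integer bookkeeping over per-gap closure rows: number of closed
#' gaps, total and maximum closed gap length, and closure counts per GCS
#' source.
#'
#' @param closures Tibble with at least `gap_bp` and `gcs_source` (the
#'   format produced by `tidy()` on a curation result, or a transcribed
#'   closure manifest).
#' @return List with `totals` (one-row tibble: `n_closed`, `total_gap_bp`,
#'   `max_gap_bp`) and `by_source` (tibble `gcs_source`, `n`).
#' @export
summarize_closures <- function(closures) {
  stopifnot(all(c("gap_bp", "gcs_source") %in% names(closures)))
  if (any(closures$gap_bp < 0)) abort("negative gap size")
  list(
    totals = tibble(
      n_closed = nrow(closures),
      total_gap_bp = sum(closures$gap_bp),
      max_gap_bp = if (nrow(closures)) max(closures$gap_bp) else 0L),
    by_source = closures |> group_by(.data$gcs_source) |>
      summarise(n = n(), .groups = "drop")
  )
}

#' Census checks against a published reference
#'
#' Runs the gap census and terminal-gene distance computations on a local
#' copy of a published assembly and its annotation, returning the headline
#' numbers (gap count, arbitrary-length count, largest gap, within-gene
#' count, per-chromosome last-gene-to-end distances, scaffold count) for
#' comparison with published values.
#'
#' @param fasta_path,gff_path Local files (genome FASTA and gene GFF3).
#' @param chromosome_ids Ids of the chromosome records in the FASTA; all
#'   other records are treated as unplaced scaffolds.
#' @param distance_chromosomes Ids for which the distance from the last
#'   gene to the sequence end is reported.
#' @param min_run,arbitrary_lengths Census parameters.
#' @return List with `summary` (one-row tibble) and `distances`.
#' @export
verify_reference_census <- function(fasta_path, gff_path, chromosome_ids,
                                    distance_chromosomes = character(),
                                    min_run = 10L,
                                    arbitrary_lengths = c(25L, 200L)) {
  asm <- read_fasta_assembly(fasta_path)
  other <- setdiff(asm$info$seq_id, chromosome_ids)
  asm <- set_roles(asm, tibble(seq_id = other, role = "unplaced"))
  genes <- read_gff3_genes(gff_path)
  gaps <- gap_census(asm, genes, min_run = min_run,
                     arbitrary_lengths = arbitrary_lengths)
  dist <- bind_rows(lapply(distance_chromosomes, function(sid) {
    g <- genes[genes$seq_id == sid, , drop = FALSE]
    len <- asm$info$length[match(sid, asm$info$seq_id)]
    tibble(seq_id = sid, last_gene_to_end = len - max(g$end))
  }))
  list(summary = cbind(census_summary(gaps),
                       tibble(n_scaffolds = length(other))),
       distances = dist, gaps = gaps)
}

#' Write the outputs of a curation run
#'
#' Emits the corrected FASTA, the lifted gene GFF3, the edit ledger
#' (AGP-like TSV plus JSON), the gap table, scaffold decisions and the
#' report JSON into a directory.
#'
#' @param cur A full `curation` result.
#' @param dir Output directory (created if needed).
#' @export
write_curation <- function(cur, dir) {
  if (is.null(cur$report)) abort("write_curation needs a full curation run")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta_assembly(cur$corrected, file.path(dir, "corrected.fa"))
  lg <- cur$lifted_genes
  ok <- !is.na(lg$new_start)
  write_gff3_genes(
    tibble(gene_id = lg$gene_id[ok], seq_id = lg$new_seq_id[ok],
           start = lg$new_start[ok], end = lg$new_end[ok],
           strand = lg$strand[ok]),
    file.path(dir, "lifted_genes.gff3"))
  if (any(!ok)) {
    readr::write_tsv(lg[!ok, ], file.path(dir, "genes_needing_review.tsv"),
                     progress = FALSE)
  }
  write_edit_ledger(cur$chain, file.path(dir, "edit_ledger.tsv"),
                    file.path(dir, "edit_ledger.json"))
  readr::write_tsv(cur$gaps, file.path(dir, "gaps.tsv"), progress = FALSE)
  readr::write_tsv(select(cur$candidates, -"sequence", -"up_flank", -"down_flank"),
                   file.path(dir, "candidates.tsv"), progress = FALSE)
  if (nrow(cur$placements)) {
    readr::write_tsv(cur$placements, file.path(dir, "placements.tsv"), progress = FALSE)
  }
  if (nrow(cur$redundancy)) {
    readr::write_tsv(cur$redundancy, file.path(dir, "redundancy.tsv"), progress = FALSE)
  }
  rep <- cur$report
  jsonlite::write_json(
    list(census_before = rep$census_before, census_after = rep$census_after,
         closures = rep$closures,
         open_gaps = rep$open_gaps[, c("gap_id", "reason")],
         totals = rep$totals, removed_scaffolds = rep$removed_scaffolds),
    file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, na = "null", digits = NA)
  invisible(dir)
}
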