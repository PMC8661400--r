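#' Scan sequences for telomeric repeat density
#'
#' Tiles each sequence with fixed windows and reports, per window, the
#' fraction of bases covered by matches of each telomeric motif (insect
#' telomere repeat TTAGG and its reverse complement CCTAA by default) and by
#' the motif set as a whole. A distal telomere is called `present` at a
#' sequence end when any window within the terminal zone reaches
#' `min_density` combined coverage.
#'
#' @param asm An [assembly].
#' @param motifs Character vector of motifs (default `c("TTAGG", "CCTAA")`).
#' @param window Window length in bp (default 1000).
#' @param min_density Minimum in-window coverage for a telomere call
#'   (default 0.4).
#' @param terminal_zone Length of the terminal zone inspected at each end
#'   (default 10000 bp).
#' @param role Record roles to scan (default `"chromosome"`).
#' @return List of class `telomere_scan`: `windows` (per-window densities)
#'   and `calls` (`seq_id`, `end` = `"left"`/`"right"`, `call`,
#'   `max_density`).
#' @export
scan_telomeres <- function(asm, motifs = c("TTAGG", "CCTAA"), window = 1000L,
                           min_density = 0.4, terminal_zone = 10000L,
                           role = "chromosome") {
  stopifnot(is_assembly(asm))
  ids <- if (is.null(role)) asm$info$seq_id else asm_ids(asm, role)
  win_rows <- list(); call_rows <- list()
  for (sid in ids) {
    s <- asm$seqs[[match(sid, asm$info$seq_id)]]
    len <- length(s)
    starts <- seq.int(1L, len, by = window)
    ends <- pmin(starts + window - 1L, len)
    wins <- IRanges::IRanges(start = starts, end = ends)
    cover <- function(motif) {
      m <- Biostrings::matchPattern(motif, s)
      if (length(m) == 0) return(numeric(length(wins)))
      r <- IRanges::reduce(IRanges::ranges(m))
      ov <- IRanges::findOverlaps(wins, r)
      w <- numeric(length(wins))
      if (length(ov)) {
        inter <- IRanges::pintersect(wins[S4Vectors::queryHits(ov)],
                                     r[S4Vectors::subjectHits(ov)])
        tapply_w <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
        w[as.integer(names(tapply_w))] <- as.numeric(tapply_w)
      }
      w
    }
    per_motif <- lapply(motifs, cover)
    names(per_motif) <- motifs
    widths <- ends - starts + 1L
    tab <- tibble(seq_id = sid, win_start = starts, win_end = ends)
    for (m in motifs) tab[[paste0("density_", m)]] <- per_motif[[m]] / widths
    # motifs are each other's reverse complements and cannot co-cover a base
    tab$density <- Reduce(`+`, per_motif) / widths
    tab$density <- pmin(tab$density, 1)
    win_rows[[sid]] <- tab
    for (side in c("left", "right")) {
      zone <- if (side == "left") {
        tab$win_start <= terminal_zone
      } else {
        tab$win_end >= len - terminal_zone + 1L
      }
      dmax <- if (any(zone)) max(tab$density[zone]) else 0
      call_rows[[paste(sid, side)]] <- tibble(
        seq_id = sid, end = side,
        call = if (dmax >= min_density) "present" else "absent",
        max_density = dmax)
    }
  }
  structure(list(windows = bind_rows(win_rows), calls = bind_rows(call_rows),
                 params = list(motifs = motifs, window = window,
                               min_density = min_density,
                               terminal_zone = terminal_zone)),
            class = "telomere_scan")
}

#' @export
print.telomere_scan <- function(x, ...) {
  cat("<telomere_scan>\n")
  print(x$calls)
  invisible(x)
}

#' Propose a telomere graft from a donor
#'
#' When a chromosome end lacks its distal telomere, the terminal gene is
#' used as an anchor: it is located in the donor, and if the donor carries
#' telomeric sequence beyond the matching anchor position, the reference
#' span from the anchor's outer boundary to the sequence end is replaced by
#' the donor span from its matching boundary to the donor sequence end. The
#' corrected anchor-to-end distance therefore equals the donor's.
#'
#' @param reference Reference [assembly].
#' @param genes Gene tibble on the reference.
#' @param seq_id Chromosome to repair.
#' @param end `"left"` or `"right"`.
#' @param donor Donor [assembly]; `donor_id` its label.
#' @param ref_scan,donor_scan Optional precomputed [scan_telomeres()] results
#'   for reference and donor (recomputed when `NULL`).
#' @param k,min_identity,min_coverage Anchoring parameters.
#' @param telomere_params List of parameters passed to [scan_telomeres()].
#' @return List with `event` (one-row event tibble, or `NULL`) and `reason`
#'   (`"proposed"`, `"already_telomeric"`, `"no_anchor_gene"`,
#'   `"anchor_unmapped"`, `"no_donor_telomere"`); errors with
#'   `duplicated_anchor` when the anchor gene is duplicated in the donor.
#' @export
recover_telomere <- function(reference, genes, seq_id, end = c("right", "left"),
                             donor, donor_id, ref_scan = NULL, donor_scan = NULL,
                             k = 21L, min_identity = 0.9, min_coverage = 0.9,
                             telomere_params = list()) {
  end <- match.arg(end)
  scan_args <- function(a, role) {
    do.call(scan_telomeres, c(list(asm = a, role = role), telomere_params))
  }
  if (is.null(ref_scan)) ref_scan <- scan_args(asm_subset(reference, seq_id), NULL)
  rc <- ref_scan$calls
  rc <- rc[rc$seq_id == seq_id & rc$end == end, , drop = FALSE]
  if (nrow(rc) && rc$call == "present") {
    return(list(event = NULL, reason = "already_telomeric"))
  }
  g <- genes[genes$seq_id == seq_id, , drop = FALSE]
  if (nrow(g) == 0) return(list(event = NULL, reason = "no_anchor_gene"))
  g <- g[order(g$start), , drop = FALSE]
  anchor <- if (end == "right") g[nrow(g), ] else g[1, ]

  aseq <- asm_subseq(reference, seq_id, anchor$start, anchor$end)
  hit <- anchor_map(setNames(aseq, anchor$gene_id), donor, k = k,
                    min_identity = min_identity, min_coverage = min_coverage)
  if (hit$status == "duplicated") {
    abort(paste0("duplicated_anchor: terminal anchor gene ", anchor$gene_id,
                 " has multiple loci in donor ", donor_id))
  }
  if (hit$status != "mapped") return(list(event = NULL, reason = "anchor_unmapped"))

  donor_len <- donor$info$length[match(hit$donor_seq_id, donor$info$seq_id)]
  # which donor end corresponds to the reference end, given relative strand
  donor_side <- if ((end == "right") == (hit$strand == "+")) "right" else "left"
  if (is.null(donor_scan)) donor_scan <- scan_args(asm_subset(donor, hit$donor_seq_id), NULL)
  dc <- donor_scan$calls
  dc <- dc[dc$seq_id == hit$donor_seq_id & dc$end == donor_side, , drop = FALSE]
  if (!nrow(dc) || dc$call != "present") {
    return(list(event = NULL, reason = "no_donor_telomere"))
  }

  ref_len <- reference$info$length[match(seq_id, reference$info$seq_id)]
  if (donor_side == "right") {
    dspan <- c(hit$end + 1L, donor_len)
  } else {
    dspan <- c(1L, hit$start - 1L)
  }
  if (dspan[2] < dspan[1]) return(list(event = NULL, reason = "no_donor_telomere"))
  repl <- asm_subseq(donor, hit$donor_seq_id, dspan[1], dspan[2])
  if (hit$strand == "-") repl <- revcomp_chr(repl)
  if (end == "right") {
    rs <- anchor$end + 1L; re <- ref_len
  } else {
    rs <- 1L; re <- anchor$start - 1L
  }
  ev <- splice_events(seq_id = seq_id, start = rs, end = re, replacement = repl,
                      type = "telomere_add", donor_id = donor_id,
                      donor_start = dspan[1], donor_end = dspan[2],
                      strand = hit$strand,
                      event_id = paste0("telo_", seq_id, "_", end))
  list(event = ev, reason = "proposed", anchor_gene = anchor$gene_id,
       donor_distance = dspan[2] - dspan[1] + 1L)
}

#' Place an unlocalized scaffold by gene-order consensus
#'
#' For each donor assembly, the scaffold's genes are located and their
#' neighbourhood recorded: the donor sequence they land on, the interval
#' they span, the scaffold's orientation there, and the reference genes
#' whose donor positions bracket that interval (which translate the donor
#' locus back into reference coordinates). When at least `min_support`
#' donors agree on (reference chromosome, overlapping target interval,
#' orientation), the location is accepted: action `place`, or `close_gap`
#' when the consensus interval overlaps a reference gap.
#'
#' @param scaffold_id Scaffold label.
#' @param scaffold_genes Genes annotated on the scaffold (coordinates local
#'   to the scaffold), ordered table with `gene_id`, `start`, `strand`.
#' @param scaf_hits Named list (by donor id) of [anchor_map()] results for
#'   the scaffold genes.
#' @param ref_anchors Named list (by donor id) of [anchor_map()] results for
#'   the reference genes.
#' @param ref_genes Reference gene tibble (reference coordinates).
#' @param gaps Gap tibble on the reference (may be zero-row).
#' @param min_support Donors that must agree (default 3, reading "more than
#'   two assemblies" literally).
#' @return One-row decision tibble: `scaffold_id`, `action`, `target_seq`,
#'   `target_start`, `target_end`, `orientation`, `supporting_assemblies`,
#'   `gap_id`, `note`.
#' @export
consensus_place_scaffold <- function(scaffold_id, scaffold_genes, scaf_hits,
                                     ref_anchors, ref_genes, gaps,
                                     min_support = 3L) {
  decision <- function(action, target = NULL, support = 0L, gap_id = NA_character_,
                       note = NA_character_) {
    tibble(scaffold_id = scaffold_id, action = action,
           target_seq = target$seq %||% NA_character_,
           target_start = target$start %||% NA_integer_,
           target_end = target$end %||% NA_integer_,
           orientation = target$orient %||% NA_character_,
           supporting_assemblies = as.integer(support), gap_id = gap_id,
           note = note)
  }
  scaffold_genes <- scaffold_genes[order(scaffold_genes$start), , drop = FALSE]
  if (nrow(scaffold_genes) == 0) return(decision("unresolved", note = "no_markers"))

  evidence <- list()
  for (did in names(scaf_hits)) {
    h <- scaf_hits[[did]]
    h <- h[h$id %in% scaffold_genes$gene_id & h$status == "mapped", , drop = FALSE]
    if (nrow(h) == 0) next
    if (length(unique(h$donor_seq_id)) > 1) next
    dseq <- h$donor_seq_id[1]
    ord_ref <- scaffold_genes$gene_id[scaffold_genes$gene_id %in% h$id]
    obs <- h$id[order(h$start)]
    fwd <- identical(obs, ord_ref) && all(h$strand == "+")
    rev_ <- identical(obs, rev(ord_ref)) && all(h$strand == "-")
    if (!fwd && !rev_) next
    orient <- if (fwd) "+" else "-"
    span <- c(min(h$start), max(h$end))

    ra <- ref_anchors[[did]]
    ra <- ra[ra$status == "mapped" & ra$donor_seq_id == dseq, , drop = FALSE]
    up <- ra[ra$end <= span[1], , drop = FALSE]
    dn <- ra[ra$start >= span[2], , drop = FALSE]
    if (nrow(up) == 0 || nrow(dn) == 0) next
    up <- up[which.max(up$end), ]
    dn <- dn[which.min(dn$start), ]
    gu <- ref_genes[ref_genes$gene_id == up$id, , drop = FALSE]
    gd <- ref_genes[ref_genes$gene_id == dn$id, , drop = FALSE]
    if (nrow(gu) == 0 || nrow(gd) == 0 || gu$seq_id != gd$seq_id) next
    lo <- min(gu$end, gd$end) + 1L
    hi <- max(gu$start, gd$start) - 1L
    if (hi < lo) next
    # relative strand of the bracketing region flips the final orientation
    rel <- up$strand
    final_orient <- if (orient == rel) "+" else "-"
    evidence[[did]] <- tibble(donor_id = did, target_seq = gu$seq_id,
                              target_start = lo, target_end = hi,
                              orientation = final_orient)
  }
  ev <- bind_rows(evidence)
  if (nrow(ev) == 0) return(decision("unresolved", note = "no_consistent_evidence"))

  # group agreeing donors: same chromosome and orientation, overlapping target
  best <- NULL
  for (i in seq_len(nrow(ev))) {
    grp <- ev[ev$target_seq == ev$target_seq[i] &
                ev$orientation == ev$orientation[i] &
                ev$target_start <= ev$target_end[i] &
                ev$target_end >= ev$target_start[i], , drop = FALSE]
    if (is.null(best) || nrow(grp) > nrow(best)) best <- grp
  }
  support <- nrow(best)
  target <- list(seq = best$target_seq[1],
                 start = max(best$target_start),
                 end = min(best$target_end),
                 orient = best$orientation[1])
  if (target$end < target$start) { target$start <- min(best$target_start); target$end <- max(best$target_end) }
  if (support < min_support) {
    return(decision("unresolved", target, support,
                    note = sprintf("support %d < %d", support, min_support)))
  }
  g <- gaps[gaps$seq_id == target$seq & gaps$start <= target$end &
              gaps$end >= target$start, , drop = FALSE]
  if (nrow(g)) {
    return(decision("close_gap", target, support, gap_id = g$gap_id[1],
                    note = paste0("consensus overlaps ", g$gap_id[1])))
  }
  decision("place", target, support)
}

#' Detect scaffolds made redundant by the applied edits
#'
#' Aligns each unplaced/unlocalized scaffold to the corrected assembly. A
#' scaffold is redundant when at least `min_coverage` of its length aligns
#' at `min_identity` or better *and* the aligned footprint intersects an
#' inserted span (its content is already represented by an applied edit).
#' A scaffold that aligns well but entirely outside inserted spans is
#' retained with a note: it was already represented before curation and is
#' not this workflow's business to delete.
#'
#' @param scaffolds [assembly] (or subset) of scaffold records.
#' @param corrected Corrected [assembly].
#' @param chain The `liftover_chain` that produced `corrected`.
#' @param min_coverage,min_identity Redundancy thresholds (defaults 0.9 and
#'   0.98).
#' @param k,max_occ Anchoring parameters.
#' @return Decision tibble: `scaffold_id`, `action`
#'   (`redundant`/`retained`), `coverage`, `identity`, `target_seq`,
#'   `intersects_inserted`, `note`.
#' @export
detect_redundant <- function(scaffolds, corrected, chain, min_coverage = 0.9,
                             min_identity = 0.98, k = 21L, max_occ = 64L) {
  inserted <- chain[chain$inserted_length > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(scaffolds$info)), function(i) {
    sid <- scaffolds$info$seq_id[i]
    q <- as.character(scaffolds$seqs[[i]])
    best <- NULL
    for (j in seq_len(nrow(corrected$info))) {
      tid <- corrected$info$seq_id[j]
      h <- as_tibble(cpp_anchor_hits(q, as.character(corrected$seqs[[j]]),
                                     as.integer(k), as.integer(max_occ), 4L,
                                     5000L, 64L))
      h <- h[h$identity >= min_identity, , drop = FALSE]
      if (nrow(h) == 0) next
      cov <- min(1, sum(h$coverage))
      cand <- list(target = tid, coverage = cov,
                   identity = max(h$identity), hits = h)
      if (is.null(best) || cand$coverage > best$coverage) best <- cand
    }
    if (is.null(best) || best$coverage < min_coverage) {
      return(tibble(scaffold_id = sid, action = "retained", coverage = best$coverage %||% 0,
                    identity = best$identity %||% NA_real_, target_seq = best$target %||% NA_character_,
                    intersects_inserted = FALSE, note = "no confident alignment"))
    }
    ins <- inserted[inserted$new_seq_id == best$target, , drop = FALSE]
    hit_ins <- FALSE
    if (nrow(ins)) {
      for (r in seq_len(nrow(best$hits))) {
        if (any(best$hits$tstart[r] <= ins$new_end & best$hits$tend[r] >= ins$new_start)) {
          hit_ins <- TRUE; break
        }
      }
    }
    tibble(scaffold_id = sid,
           action = if (hit_ins) "redundant" else "retained",
           coverage = best$coverage, identity = best$identity,
           target_seq = best$target, intersects_inserted = hit_ins,
           note = if (hit_ins) "aligned within replaced region"
                  else "aligned outside replaced regions")
  })
  bind_rows(rows)
}
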