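#' Derive the marker intervals that anchor a gap
#'
#' The flanking genes of a gap act as synteny markers that localize the
#' corresponding region in a donor assembly. For an intergenic gap the
#' markers are the upstream and downstream gene bodies and the replaced
#' region runs from the end of the upstream gene to the start of the
#' downstream gene (exclusive of both genes). For a gap contained in a gene,
#' the whole gene is replaced and the markers are the N-free gene fragments
#' on either side of the gap, so that each marker can be anchored without
#' interference from the N-run.
#'
#' @param gap One-row gap tibble with flank context (see [assign_flanks()]).
#' @param genes Gene tibble.
#' @return List with `mode` (`"within"` or `"between"`), `replaced`
#'   (`seq_id`, `start`, `end`) and `markers` (two-row tibble: `side`,
#'   `start`, `end`), or `NULL` when the gap has no usable anchors.
#' @export
gap_markers <- function(gap, genes) {
  stopifnot(nrow(gap) == 1)
  if (!is.na(gap$within_gene)) {
    g <- genes[genes$gene_id == gap$within_gene, , drop = FALSE]
    up <- c(g$start, gap$start - 1L)
    dn <- c(gap$end + 1L, g$end)
    if (up[2] < up[1] || dn[2] < dn[1]) return(NULL)
    return(list(
      mode = "within",
      replaced = tibble(seq_id = gap$seq_id, start = g$start, end = g$end),
      markers = tibble(side = c("up", "down"),
                       start = c(up[1], dn[1]), end = c(up[2], dn[2]))
    ))
  }
  if (is.na(gap$upstream_gene) || is.na(gap$downstream_gene)) return(NULL)
  gu <- genes[genes$gene_id == gap$upstream_gene, , drop = FALSE]
  gd <- genes[genes$gene_id == gap$downstream_gene, , drop = FALSE]
  list(
    mode = "between",
    replaced = tibble(seq_id = gap$seq_id, start = gu$end + 1L, end = gd$start - 1L),
    markers = tibble(side = c("up", "down"),
                     start = c(gu$start, gd$start), end = c(gu$end, gd$end))
  )
}

#' Extract a gap-closing sequence (GCS) candidate from a donor
#'
#' Given the anchored positions of the gap's two markers in a donor
#' assembly, cuts out the donor sequence that corresponds to the reference
#' replaced region: between the markers (intergenic gaps) or spanning the
#' whole containing gene (within-gene gaps). When the donor region lies on
#' the minus strand relative to the reference, the candidate is
#' reverse-complemented so it always reads in reference orientation. The
#' `flank_len` donor bases immediately outside each end of the GCS are
#' recorded for later flank validation.
#'
#' Candidates are rejected (with a reason) rather than silently dropped:
#' `split_anchor` when the two markers land on different donor sequences,
#' `order_conflict` when their order or strands are inconsistent, and
#' `donor_gapped` when the extracted span itself contains an N-run of
#' `min_run` or more (a donor that failed in the same region cannot close
#' the gap).
#'
#' @param gap One-row gap tibble (with flank context).
#' @param donor Donor [assembly].
#' @param up_hit,down_hit One-row anchor tibbles for the up/down markers
#'   (donor coordinates of the *marker intervals* from [gap_markers()]).
#' @param markers Result of [gap_markers()] for this gap.
#' @param donor_id,source_class Donor label and class (`"reassembly"` or
#'   `"alternative"`).
#' @param min_run N-run length that disqualifies a donor span (default 10).
#' @param flank_len Validation flank length recorded with the candidate
#'   (default 100).
#' @return One-row candidate tibble with `status` `"candidate"` or
#'   `"rejected"` plus a `reason`.
#' @export
extract_gcs <- function(gap, donor, up_hit, down_hit, markers,
                        donor_id, source_class = c("alternative", "reassembly"),
                        min_run = 10L, flank_len = 100L) {
  source_class <- match.arg(source_class)
  base <- tibble(
    gap_id = gap$gap_id, donor_id = donor_id, source_class = source_class,
    donor_seq_id = NA_character_, donor_start = NA_integer_,
    donor_end = NA_integer_, strand = NA_character_, sequence = NA_character_,
    gcs_length = NA_integer_, ref_seq_id = markers$replaced$seq_id,
    replaced_start = markers$replaced$start, replaced_end = markers$replaced$end,
    up_flank = NA_character_, down_flank = NA_character_,
    up_flank_identity = NA_real_, down_flank_identity = NA_real_,
    depth_mean = NA_real_, depth_cv = NA_real_,
    status = "rejected", reason = NA_character_
  )
  if (nrow(up_hit) != 1 || nrow(down_hit) != 1) { base$reason <- "missing_anchor"; return(base) }
  if (up_hit$donor_seq_id != down_hit$donor_seq_id) { base$reason <- "split_anchor"; return(base) }
  if (up_hit$strand != down_hit$strand) { base$reason <- "order_conflict"; return(base) }
  rel_strand <- up_hit$strand
  within <- identical(markers$mode, "within")

  if (rel_strand == "+") {
    if (within) { ds <- up_hit$start; de <- down_hit$end }
    else { ds <- up_hit$end + 1L; de <- down_hit$start - 1L }
  } else {
    if (within) { ds <- down_hit$start; de <- up_hit$end }
    else { ds <- down_hit$end + 1L; de <- up_hit$start - 1L }
  }
  if (is.na(ds) || is.na(de) || de < ds) { base$reason <- "order_conflict"; return(base) }

  dseq_len <- donor$info$length[match(up_hit$donor_seq_id, donor$info$seq_id)]
  if (ds < 1 || de > dseq_len) { base$reason <- "order_conflict"; return(base) }
  s <- asm_subseq(donor, up_hit$donor_seq_id, ds, de)
  if (grepl(paste0("N{", min_run, ",}"), s)) { base$reason <- "donor_gapped"; return(base) }
  if (rel_strand == "-") s <- revcomp_chr(s)

  # donor context just outside the GCS, oriented to the reference frame
  left_ok <- ds - flank_len >= 1
  right_ok <- de + flank_len <= dseq_len
  left_fl <- if (left_ok) asm_subseq(donor, up_hit$donor_seq_id, ds - flank_len, ds - 1L) else NA_character_
  right_fl <- if (right_ok) asm_subseq(donor, up_hit$donor_seq_id, de + 1L, de + flank_len) else NA_character_
  if (rel_strand == "+") {
    up_fl <- left_fl; down_fl <- right_fl
  } else {
    up_fl <- if (!is.na(right_fl)) revcomp_chr(right_fl) else NA_character_
    down_fl <- if (!is.na(left_fl)) revcomp_chr(left_fl) else NA_character_
  }

  mutate(base,
         donor_seq_id = up_hit$donor_seq_id, donor_start = ds, donor_end = de,
         strand = rel_strand, sequence = s, gcs_length = nchar(s),
         up_flank = up_fl, down_flank = down_fl,
         status = "candidate", reason = NA_character_)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Validate a candidate's flanks against the reference
#'
#' The donor bases immediately outside each end of the GCS must correspond
#' to reference sequence adjacent to the replaced interval; otherwise the
#' candidate was extracted from the wrong locus (e.g. a paralogous repeat
#' array). Each recorded flank is placed on a bounded reference window by an
#' exact sliding ungapped scan; the identity at the best placement is the
#' flank identity, and the placement must land within `adjacency_tol` bases
#' of the replaced interval's end.
#'
#' A flank that was unavailable at extraction (donor sequence boundary) is
#' recorded as unassessable; the candidate keeps status `"candidate"` with a
#' warning note instead of being validated.
#'
#' @param candidate One-row candidate tibble from [extract_gcs()].
#' @param reference Reference [assembly].
#' @param flank_len Flank length (default 100; must match extraction).
#' @param min_flank_identity Minimum identity per flank (default 0.95 —
#'   strict enough to reject repeat-array decoys).
#' @param adjacency_tol Maximum distance between the flank placement and the
#'   replaced interval end (default 20 bp, absorbing small indel jitter).
#' @return The candidate with `up_flank_identity`, `down_flank_identity`
#'   and `status` `"validated"` or `"rejected"` (`reason = "flank_mismatch"`).
#' @export
validate_flanks <- function(candidate, reference, flank_len = 100L,
                            min_flank_identity = 0.95, adjacency_tol = 20L) {
  stopifnot(nrow(candidate) == 1)
  if (candidate$status != "candidate") return(candidate)
  ref_len <- reference$info$length[match(candidate$ref_seq_id, reference$info$seq_id)]
  pad <- 30L

  score_flank <- function(flank, side) {
    if (is.na(flank)) return(list(identity = NA_real_, adjacent = NA))
    if (side == "up") {
      lo <- max(1L, candidate$replaced_start - flank_len - adjacency_tol - pad)
      hi <- min(ref_len, candidate$replaced_start - 1L + adjacency_tol)
      expected_end <- candidate$replaced_start - 1L
    } else {
      lo <- max(1L, candidate$replaced_end + 1L - adjacency_tol)
      hi <- min(ref_len, candidate$replaced_end + flank_len + adjacency_tol + pad)
      expected_end <- NA_integer_
    }
    if (hi - lo + 1L < nchar(flank)) return(list(identity = 0, adjacent = FALSE))
    win <- asm_subseq(reference, candidate$ref_seq_id, lo, hi)
    sc <- cpp_hamming_scan(flank, win, 5L)
    if (is.na(sc$offset)) return(list(identity = 0, adjacent = FALSE))
    if (side == "up") {
      match_end <- lo + sc$offset - 1L + nchar(flank) - 1L
      adj <- abs(match_end - expected_end) <= adjacency_tol
    } else {
      match_start <- lo + sc$offset - 1L
      adj <- abs(match_start - (candidate$replaced_end + 1L)) <= adjacency_tol
    }
    list(identity = sc$identity, adjacent = adj)
  }

  up <- score_flank(candidate$up_flank, "up")
  dn <- score_flank(candidate$down_flank, "down")
  candidate$up_flank_identity <- up$identity
  candidate$down_flank_identity <- dn$identity
  if (is.na(up$identity) || is.na(dn$identity)) {
    candidate$reason <- "flank_unassessable"
    warn(paste0(candidate$gap_id, "/", candidate$donor_id,
                ": flank at donor sequence boundary; candidate not validated"))
    return(candidate)
  }
  ok <- up$identity >= min_flank_identity && dn$identity >= min_flank_identity &&
    isTRUE(up$adjacent) && isTRUE(dn$adjacent)
  candidate$status <- if (ok) "validated" else "rejected"
  candidate$reason <- if (ok) NA_character_ else "flank_mismatch"
  candidate
}

#' Depth summary over an interval
#'
#' Arithmetic mean and coefficient of variation (population standard
#' deviation over mean; 0 when the mean is 0) of per-base depths.
#'
#' @param track A `depth_track`.
#' @param seq_id Sequence id within the track.
#' @param start,end 1-based closed interval.
#' @return One-row tibble `mean`, `cv`.
#' @export
coverage_stats <- function(track, seq_id, start, end) {
  if (!seq_id %in% names(track)) abort(paste0("no depth for sequence: ", seq_id))
  v <- track[[seq_id]]
  if (start > end) abort("empty interval")
  if (start < 1 || end > length(v)) abort("interval outside depth track bounds")
  x <- v[start:end]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  tibble(mean = m, cv = if (m == 0) 0 else s / m)
}

#' Attach depth statistics to candidates
#'
#' @param candidates Candidate tibble.
#' @param depth Named list of `depth_track`s keyed by donor id (reference
#'   reads mapped to each donor assembly), or `NULL`.
#' @export
add_depth_stats <- function(candidates, depth) {
  if (is.null(depth) || nrow(candidates) == 0) return(candidates)
  for (i in seq_len(nrow(candidates))) {
    ci <- candidates[i, ]
    if (ci$status == "rejected" || is.na(ci$donor_seq_id)) next
    tr <- depth[[ci$donor_id]]
    if (is.null(tr) || !ci$donor_seq_id %in% names(tr)) next
    if (ci$donor_start > ci$donor_end) next
    st <- coverage_stats(tr, ci$donor_seq_id, ci$donor_start, ci$donor_end)
    candidates$depth_mean[i] <- st$mean
    candidates$depth_cv[i] <- st$cv
  }
  candidates
}

#' Select the best validated candidate for a gap
#'
#' Deterministic total order: (1) any validated re-assembly-class candidate
#' beats all alternative-class ones (a re-assembly is built from the
#' reference's own reads, so it is the least diverged source); (2) within a
#' class, higher depth mean wins (best read support); (3) ties by lower
#' depth CV (more uniform support); (4) then shorter sequence; (5) then
#' lexicographic donor id. Candidates that are not `"validated"` are never
#' selected, whatever their depth. Permuting the input never changes the
#' selection.
#'
#' @param candidates Candidate tibble (one gap's candidates).
#' @return One-row tibble (the selection) or a zero-row tibble.
#' @export
rank_candidates <- function(candidates) {
  ok <- candidates[candidates$status == "validated", , drop = FALSE]
  if (nrow(ok) == 0) return(ok)
  key_mean <- ifelse(is.na(ok$depth_mean), -Inf, ok$depth_mean)
  key_cv <- ifelse(is.na(ok$depth_cv), Inf, ok$depth_cv)
  ord <- order(ok$source_class != "reassembly", -key_mean, key_cv,
               ok$gcs_length, ok$donor_id)
  ok[ord[1], , drop = FALSE]
}
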