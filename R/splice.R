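#' Build a splice-event table
#'
#' A splice event replaces one interval of a pre-edit sequence with a
#' replacement string (possibly empty, for deletions; the interval may have
#' width zero, `start = p + 1, end = p`, for pure insertions after `p`).
#' Events always reference *pre-edit* coordinates; they carry provenance
#' (donor and donor interval, orientation) and an event type:
#' `gap_close`, `telomere_add`, `scaffold_place` or `other`.
#'
#' @param seq_id,start,end Replaced interval (1-based closed, pre-edit).
#' @param replacement Replacement sequence(s).
#' @param type Event type(s).
#' @param donor_id,donor_start,donor_end,strand Provenance (optional).
#' @param event_id Stable ids; autogenerated when omitted.
#' @return Tibble of events.
#' @export
splice_events <- function(seq_id, start, end, replacement, type = "other",
                          donor_id = NA_character_, donor_start = NA_integer_,
                          donor_end = NA_integer_, strand = NA_character_,
                          event_id = NULL) {
  n <- max(length(seq_id), length(start), length(end), length(replacement))
  if (length(start) == 0) n <- 0L
  if (is.null(event_id)) event_id <- sprintf("ev%03d", seq_len(n))
  tibble(event_id = event_id, seq_id = rep_len(seq_id, n),
         start = rep_len(as.integer(start), n), end = rep_len(as.integer(end), n),
         replacement = rep_len(replacement, n), type = rep_len(type, n),
         donor_id = rep_len(donor_id, n),
         donor_start = rep_len(as.integer(donor_start), n),
         donor_end = rep_len(as.integer(donor_end), n),
         strand = rep_len(strand, n))
}

#' Apply splice events to an assembly
#'
#' Applies non-overlapping replacement events right-to-left within each
#' sequence (so recorded pre-edit intervals never need rewriting) and
#' returns the corrected assembly together with the liftover chain the
#' edits induce. Edited records are renamed with `prefix` (mirroring the
#' `cor_` naming convention for corrected chromosomes); untouched records
#' keep their ids.
#'
#' Events must not overlap within a sequence (an error lists the offending
#' pair) and must lie within bounds. Re-applying an event list to an
#' already-corrected assembly is rejected: events reference pre-edit ids and
#' coordinates only.
#'
#' @param asm Pre-edit [assembly].
#' @param events Event tibble from [splice_events()].
#' @param prefix Prefix for edited record ids (default `"cor_"`).
#' @return List with `assembly` (corrected) and `chain` (a
#'   `liftover_chain`: per-event old/new coordinates and cumulative deltas).
#' @export
apply_splices <- function(asm, events, prefix = "cor_") {
  stopifnot(is_assembly(asm))
  applied <- attr(asm, "applied_events")
  if (!is.null(applied) && any(events$event_id %in% applied)) {
    abort("events already applied to this assembly (pre-edit coordinates only)")
  }
  if (nrow(events) == 0) {
    chain <- empty_chain(asm)
    return(list(assembly = asm, chain = chain))
  }
  unknown <- setdiff(unique(events$seq_id), asm$info$seq_id)
  if (length(unknown)) abort(paste0("events reference unknown sequence(s): ",
                                    paste(unknown, collapse = ", ")))
  events <- arrange(events, .data$seq_id, .data$start, .data$event_id)
  new_seqs <- as.character(asm$seqs)
  names(new_seqs) <- asm$info$seq_id
  chain_rows <- list()
  edited <- character()

  for (sid in unique(events$seq_id)) {
    ev <- events[events$seq_id == sid, , drop = FALSE]
    len <- nchar(new_seqs[[sid]])
    if (any(ev$start < 1 | ev$end > len | ev$end < ev$start - 1L)) {
      abort(paste0("event interval out of bounds on ", sid))
    }
    if (nrow(ev) > 1) {
      ov <- which(ev$end[-nrow(ev)] >= ev$start[-1])
      if (length(ov)) {
        abort(sprintf("overlapping events on %s: %s and %s", sid,
                      ev$event_id[ov[1]], ev$event_id[ov[1] + 1]))
      }
    }
    ins_len <- nchar(ev$replacement)
    old_w <- ev$end - ev$start + 1L
    delta <- ins_len - old_w
    cum_before <- cumsum(c(0L, head(delta, -1)))
    new_start <- ev$start + cum_before
    new_end <- new_start + ins_len - 1L
    s <- new_seqs[[sid]]
    for (i in rev(seq_len(nrow(ev)))) {
      pre <- if (ev$start[i] > 1) substr(s, 1, ev$start[i] - 1L) else ""
      post <- if (ev$end[i] < nchar(s)) substr(s, ev$end[i] + 1L, nchar(s)) else ""
      s <- paste0(pre, ev$replacement[i], post)
    }
    new_seqs[[sid]] <- s
    edited <- c(edited, sid)
    chain_rows[[sid]] <- tibble(
      seq_id = sid, new_seq_id = paste0(prefix, sid),
      event_id = ev$event_id, type = ev$type,
      old_start = ev$start, old_end = ev$end,
      new_start = new_start, new_end = new_end,
      inserted_length = ins_len, delta = delta,
      donor_id = ev$donor_id, donor_start = ev$donor_start,
      donor_end = ev$donor_end, strand = ev$strand
    )
  }

  ids <- asm$info$seq_id
  new_ids <- ifelse(ids %in% edited, paste0(prefix, ids), ids)
  names(new_seqs) <- new_ids
  out <- assembly(new_seqs, asm$info$role, asm$info$associated_chromosome)
  attr(out, "applied_events") <- c(applied, events$event_id)

  chain <- bind_rows(chain_rows)
  attr(chain, "old_lengths") <- setNames(asm$info$length, ids)
  attr(chain, "new_lengths") <- setNames(out$info$length, new_ids)
  attr(chain, "id_map") <- setNames(new_ids, ids)
  class(chain) <- c("liftover_chain", class(chain))
  list(assembly = out, chain = chain)
}

empty_chain <- function(asm) {
  chain <- tibble(seq_id = character(), new_seq_id = character(),
                  event_id = character(), type = character(),
                  old_start = integer(), old_end = integer(),
                  new_start = integer(), new_end = integer(),
                  inserted_length = integer(), delta = integer(),
                  donor_id = character(), donor_start = integer(),
                  donor_end = integer(), strand = character())
  attr(chain, "old_lengths") <- setNames(asm$info$length, asm$info$seq_id)
  attr(chain, "new_lengths") <- setNames(asm$info$length, asm$info$seq_id)
  attr(chain, "id_map") <- setNames(asm$info$seq_id, asm$info$seq_id)
  class(chain) <- c("liftover_chain", class(chain))
  chain
}

#' Translate positions through a liftover chain
#'
#' Positions left of all edits are unchanged; positions right of an edit are
#' shifted by the cumulative length delta; positions inside a replaced
#' (direction `"old2new"`) or inserted (direction `"new2old"`) interval get
#' status `"inside_edit"` and `NA`. The map is strictly monotone outside
#' edits and `new2old` inverts `old2new` there.
#'
#' @param chain A `liftover_chain`.
#' @param seq_id Sequence id (pre-edit id for `old2new`, corrected id for
#'   `new2old`).
#' @param pos Integer vector of positions.
#' @param direction `"old2new"` (default) or `"new2old"`.
#' @return Tibble: `pos`, `lifted`, `status`.
#' @export
lift_position <- function(chain, seq_id, pos, direction = c("old2new", "new2old")) {
  direction <- match.arg(direction)
  old <- direction == "old2new"
  known <- if (old) names(attr(chain, "old_lengths")) else names(attr(chain, "new_lengths"))
  if (!seq_id %in% known) abort(paste0("unknown sequence id: ", seq_id))
  len <- (if (old) attr(chain, "old_lengths") else attr(chain, "new_lengths"))[[seq_id]]
  if (any(pos < 1 | pos > len)) abort("position out of sequence bounds")
  ev <- if (old) chain[chain$seq_id == seq_id, , drop = FALSE]
        else chain[chain$new_seq_id == seq_id, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(tibble(pos = pos, lifted = as.integer(pos), status = "unchanged"))
  }
  ev <- ev[order(ev$old_start), , drop = FALSE]
  s <- if (old) ev$old_start else ev$new_start
  e <- if (old) ev$old_end else ev$new_end
  d <- if (old) ev$delta else -ev$delta
  lifted <- integer(length(pos))
  status <- character(length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    inside <- which(p >= s & p <= e)
    if (length(inside)) {
      lifted[i] <- NA_integer_; status[i] <- "inside_edit"
    } else {
      shift <- sum(d[e < p])
      lifted[i] <- p + shift
      status[i] <- if (shift == 0) "unchanged" else "shifted"
    }
  }
  tibble(pos = pos, lifted = lifted, status = status)
}

#' Lift gene annotations through a chain
#'
#' Genes entirely outside replaced intervals are coordinate-shifted. A gene
#' whose body coincides with a replaced interval (the within-gene closure
#' case, where the donor's complete gene was pasted in) is re-anchored to
#' the inserted span. A gene that strictly contains an edit keeps its
#' lifted outer coordinates (`spans_edit`). Any other overlap is flagged
#' `review` with `NA` coordinates — genes are never silently dropped.
#'
#' @param genes Gene tibble.
#' @param chain A `liftover_chain`.
#' @return `genes` plus `new_seq_id`, `new_start`, `new_end`, `lift_status`.
#' @export
lift_annotation <- function(genes, chain) {
  id_map <- attr(chain, "id_map")
  out <- mutate(genes,
                new_seq_id = unname(id_map[.data$seq_id]),
                new_start = NA_integer_, new_end = NA_integer_,
                lift_status = "unchanged")
  for (i in seq_len(nrow(out))) {
    g <- out[i, ]
    if (is.na(g$new_seq_id)) { out$lift_status[i] <- "review"; next }
    ev <- chain[chain$seq_id == g$seq_id, , drop = FALSE]
    exact <- which(ev$old_start == g$start & ev$old_end == g$end)
    if (length(exact)) {
      out$new_start[i] <- ev$new_start[exact[1]]
      out$new_end[i] <- ev$new_end[exact[1]]
      out$lift_status[i] <- "reanchored"
      next
    }
    ls <- lift_position(chain, g$seq_id, c(g$start, g$end))
    if (any(ls$status == "inside_edit")) {
      out$lift_status[i] <- "review"
      next
    }
    out$new_start[i] <- ls$lifted[1]
    out$new_end[i] <- ls$lifted[2]
    spans <- any(ev$old_start > g$start & ev$old_end < g$end)
    out$lift_status[i] <- if (spans) "spans_edit"
      else if (any(ls$status == "shifted")) "shifted" else "unchanged"
  }
  out
}

#' Verify an applied splice in the corrected assembly
#'
#' The `flank_len` corrected bases on each side of the inserted span are
#' reference-derived; each must place back (exact sliding ungapped scan)
#' onto the reference immediately outside the replaced interval, confirming
#' that the insertion landed at the intended junctions. For gap-closing
#' events the junctions must additionally be N-free within
#' `junction_window` bases.
#'
#' A flank that runs off the corrected sequence (telomere grafts at a
#' chromosome end) is unassessable on that side: the check passes with a
#' note.
#'
#' @param corrected Corrected [assembly].
#' @param reference Pre-edit [assembly].
#' @param chain The `liftover_chain` from [apply_splices()].
#' @param event_ids Events to check (default: all in the chain).
#' @param expected Optional tibble (`event_id`, `start`, `end`) giving an
#'   independent expectation of each event's replaced interval (for example
#'   the gap interval the event claims to close); junction flanks are
#'   checked against these coordinates. Defaults to the chain's recorded
#'   intervals.
#' @param flank_len Junction flank length (default 200).
#' @param junction_window N-free window around each junction (default 50).
#' @param min_identity Minimum flank placement identity (default 0.95).
#' @param adjacency_tol Placement tolerance in bp (default 20).
#' @return Tibble: `event_id`, `pass`, `reason`, `note`.
#' @export
post_splice_check <- function(corrected, reference, chain, event_ids = NULL,
                              expected = NULL, flank_len = 200L,
                              junction_window = 50L,
                              min_identity = 0.95, adjacency_tol = 20L) {
  if (is.null(event_ids)) event_ids <- chain$event_id
  pad <- 30L
  rows <- lapply(event_ids, function(eid) {
    ev <- chain[chain$event_id == eid, , drop = FALSE]
    if (nrow(ev) != 1) abort(paste0("unknown event id: ", eid))
    if (!is.null(expected) && eid %in% expected$event_id) {
      xp <- expected[expected$event_id == eid, , drop = FALSE]
      ev$old_start <- xp$start
      ev$old_end <- xp$end
    }
    ref_len <- reference$info$length[match(ev$seq_id, reference$info$seq_id)]
    cor_len <- corrected$info$length[match(ev$new_seq_id, corrected$info$seq_id)]
    note <- character(); fail <- character()

    check_side <- function(side) {
      if (side == "up") {
        cs <- ev$new_start - flank_len; ce <- ev$new_start - 1L
        if (cs < 1) return("upstream flank unassessable (sequence start)")
        fl <- asm_subseq(corrected, ev$new_seq_id, cs, ce)
        lo <- max(1L, ev$old_start - flank_len - adjacency_tol - pad)
        hi <- min(ref_len, ev$old_start - 1L + adjacency_tol)
        expected <- ev$old_start - 1L
        at_end <- FALSE
      } else {
        cs <- ev$new_end + 1L; ce <- ev$new_end + flank_len
        if (ce > cor_len) return("downstream flank unassessable (sequence end)")
        fl <- asm_subseq(corrected, ev$new_seq_id, cs, ce)
        lo <- max(1L, ev$old_end + 1L - adjacency_tol)
        hi <- min(ref_len, ev$old_end + flank_len + adjacency_tol + pad)
        expected <- ev$old_end + 1L
        at_end <- TRUE
      }
      if (hi - lo + 1L < nchar(fl)) return(structure("junction_mismatch", fail = TRUE))
      win <- asm_subseq(reference, ev$seq_id, lo, hi)
      sc <- cpp_hamming_scan(fl, win, 5L)
      placed <- lo + sc$offset - 1L
      ok <- if (!at_end) {
        sc$identity >= min_identity &&
          abs((placed + nchar(fl) - 1L) - expected) <= adjacency_tol
      } else {
        sc$identity >= min_identity && abs(placed - expected) <= adjacency_tol
      }
      if (!ok) structure("junction_mismatch", fail = TRUE) else NULL
    }

    for (side in c("up", "down")) {
      r <- check_side(side)
      if (is.null(r)) next
      if (isTRUE(attr(r, "fail"))) fail <- c(fail, as.character(r)) else note <- c(note, r)
    }

    if (ev$type == "gap_close") {
      jw <- junction_window
      win_lo <- max(1L, ev$new_start - jw)
      win_hi <- min(cor_len, ev$new_end + jw)
      left <- asm_subseq(corrected, ev$new_seq_id, win_lo,
                         min(cor_len, ev$new_start + jw - 1L))
      right <- asm_subseq(corrected, ev$new_seq_id,
                          max(1L, ev$new_end - jw + 1L), win_hi)
      if (grepl("N", left, fixed = TRUE) || grepl("N", right, fixed = TRUE)) {
        fail <- c(fail, "junction_contains_N")
      }
    }
    tibble(event_id = eid, pass = length(fail) == 0,
           reason = if (length(fail)) paste(unique(fail), collapse = ";") else NA_character_,
           note = if (length(note)) paste(note, collapse = "; ") else NA_character_)
  })
  bind_rows(rows)
}

#' Write the edit ledger
#'
#' AGP-like TSV (one row per event: pre-edit interval, action, donor,
#' donor interval, orientation) plus a JSON log of the same records.
#'
#' @param chain A `liftover_chain`.
#' @param path_tsv,path_json Output paths (either may be `NULL`).
#' @export
write_edit_ledger <- function(chain, path_tsv = NULL, path_json = NULL) {
  led <- tibble(seq_id = chain$seq_id, old_start = chain$old_start,
                old_end = chain$old_end, action = chain$type,
                donor = chain$donor_id, donor_start = chain$donor_start,
                donor_end = chain$donor_end, orientation = chain$strand,
                new_seq_id = chain$new_seq_id, new_start = chain$new_start,
                new_end = chain$new_end, event_id = chain$event_id)
  if (!is.null(path_tsv)) readr::write_tsv(led, path_tsv, progress = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(led, path_json, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE, na = "null")
  }
  invisible(led)
}
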