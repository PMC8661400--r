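#' Find assembly gaps (maximal N-runs)
#'
#' Scans each record for maximal runs of `N` of length at least `min_run`.
#' Runs are maximal by construction (flanked by non-N bases or by the
#' sequence boundary). Gap ids are assigned `"<seq>_gap<i>"` left to right,
#' numbered from 1 within each sequence, so ids are stable under re-runs.
#'
#' @param asm An [assembly].
#' @param min_run Minimum N-run length to report (default 10). The default
#'   ignores isolated ambiguous bases while catching the shortest placeholder
#'   gaps (25 bp) used in real assemblies.
#' @param role Which record roles to scan (default `"chromosome"`;
#'   set to `NULL` to scan everything).
#' @return Tibble with columns `gap_id`, `seq_id`, `start`, `end` (1-based
#'   closed over the N-run), `length`.
#' @examples
#' asm <- assembly(c(s1 = paste0("ACGT", strrep("N", 12), "ACGT")))
#' find_gaps(asm)
#' @export
find_gaps <- function(asm, min_run = 10L, role = "chromosome") {
  stopifnot(is_assembly(asm), min_run >= 1)
  ids <- if (is.null(role)) asm$info$seq_id else asm_ids(asm, role)
  rows <- lapply(ids, function(sid) {
    s <- asm$seqs[[match(sid, asm$info$seq_id)]]
    m <- Biostrings::matchPattern("N", s)
    if (length(m) == 0) return(NULL)
    runs <- IRanges::reduce(IRanges::ranges(m))
    runs <- runs[IRanges::width(runs) >= min_run]
    if (length(runs) == 0) return(NULL)
    tibble(
      gap_id = sprintf("%s_gap%d", sid, seq_along(runs)),
      seq_id = sid,
      start = IRanges::start(runs),
      end = IRanges::end(runs),
      length = IRanges::width(runs)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(gap_id = character(), seq_id = character(),
                  start = integer(), end = integer(), length = integer())
  }
  out
}

#' Classify gaps as arbitrary or size-estimated
#'
#' A gap is `"arbitrary"` when its length is exactly one of the placeholder
#' lengths used by the assembler (by default 25 and 200 bp), and
#' `"estimated"` otherwise. Classification is a pure function of length:
#' the two classes are exhaustive and exclusive.
#'
#' @param gaps Gap tibble from [find_gaps()].
#' @param arbitrary_lengths Integer set of placeholder lengths.
#' @return `gaps` with a `gap_class` column.
#' @export
classify_gaps <- function(gaps, arbitrary_lengths = c(25L, 200L)) {
  mutate(gaps, gap_class = if_else(.data$length %in% arbitrary_lengths,
                                   "arbitrary", "estimated"))
}

#' Attach flanking- and containing-gene context to gaps
#'
#' For each gap, `upstream_gene` is the gene with the greatest end at or
#' before the gap start on the same sequence, `downstream_gene` the gene with
#' the least start at or after the gap end, and `within_gene` the gene whose
#' body contains the whole gap interval. Ties on equal coordinates are broken
#' by lexicographic gene id. Gaps with no gene on one side (sequence
#' boundary) keep `NA` there and are marked `closable = FALSE`, since the
#' flanking-gene method cannot anchor them.
#'
#' @param gaps Gap tibble.
#' @param genes Gene tibble (`gene_id`, `seq_id`, `start`, `end`, `strand`).
#' @return `gaps` with `upstream_gene`, `downstream_gene`, `within_gene`,
#'   `closable` columns.
#' @export
assign_flanks <- function(gaps, genes) {
  if (nrow(gaps) == 0) {
    return(mutate(gaps, upstream_gene = character(), downstream_gene = character(),
                  within_gene = character(), closable = logical()))
  }
  genes <- arrange(genes, .data$seq_id, .data$start, .data$gene_id)
  per_gap <- function(sid, gs, ge) {
    g <- genes[genes$seq_id == sid, , drop = FALSE]
    up <- g[g$end <= gs, , drop = FALSE]
    up <- if (nrow(up)) {
      up <- up[order(-up$end, up$gene_id), , drop = FALSE]; up$gene_id[1]
    } else NA_character_
    dn <- g[g$start >= ge, , drop = FALSE]
    dn <- if (nrow(dn)) {
      dn <- dn[order(dn$start, dn$gene_id), , drop = FALSE]; dn$gene_id[1]
    } else NA_character_
    wi <- g[g$start <= gs & g$end >= ge, , drop = FALSE]
    wi <- if (nrow(wi)) {
      wi <- wi[order(wi$start, wi$gene_id), , drop = FALSE]; wi$gene_id[1]
    } else NA_character_
    tibble(upstream_gene = up, downstream_gene = dn, within_gene = wi)
  }
  ctx <- purrr::pmap(list(gaps$seq_id, gaps$start, gaps$end), per_gap) |> bind_rows()
  out <- bind_cols_safe(gaps, ctx)
  mutate(out, closable = !is.na(.data$within_gene) |
           (!is.na(.data$upstream_gene) & !is.na(.data$downstream_gene)))
}

bind_cols_safe <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- b[[nm]]
  a
}

#' Summarize a gap census
#'
#' Exact integer totals over the gap table: gap count, counts by class,
#' minimum/maximum/total length and the number of gaps contained within
#' gene bodies.
#'
#' @param gaps Classified gap tibble (after [classify_gaps()]; the
#'   within-gene count requires [assign_flanks()] context and is `NA`
#'   without it).
#' @return One-row tibble.
#' @export
census_summary <- function(gaps) {
  n <- nrow(gaps)
  tibble(
    n_gaps = n,
    n_arbitrary = if (n && "gap_class" %in% names(gaps)) sum(gaps$gap_class == "arbitrary") else 0L,
    n_estimated = if (n && "gap_class" %in% names(gaps)) sum(gaps$gap_class == "estimated") else 0L,
    min_length = if (n) min(gaps$length) else 0L,
    max_length = if (n) max(gaps$length) else 0L,
    total_length = if (n) sum(gaps$length) else 0L,
    n_within_gene = if ("within_gene" %in% names(gaps)) sum(!is.na(gaps$within_gene)) else NA_integer_
  )
}

#' Gap census of an annotated assembly
#'
#' Convenience wrapper: find, classify and contextualize gaps in one call.
#'
#' @inheritParams find_gaps
#' @inheritParams classify_gaps
#' @param genes Optional gene tibble for flank context.
#' @export
gap_census <- function(asm, genes = NULL, min_run = 10L,
                       arbitrary_lengths = c(25L, 200L), role = "chromosome") {
  gaps <- classify_gaps(find_gaps(asm, min_run = min_run, role = role),
                        arbitrary_lengths = arbitrary_lengths)
  if (!is.null(genes)) gaps <- assign_flanks(gaps, genes)
  gaps
}

#' Export a gap table as BED3
#'
#' @param gaps Gap tibble.
#' @param path Output path.
#' @export
write_gaps_bed <- function(gaps, path) {
  bed <- tibble(chrom = gaps$seq_id, start = gaps$start - 1L, end = gaps$end)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
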