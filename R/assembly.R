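#' Assembly container
#'
#' An `assembly` bundles a set of DNA sequences (as a
#' [Biostrings::DNAStringSet]) with a per-record metadata table. Each record
#' has a role: `"chromosome"` for placed sequences, `"unplaced"` for scaffolds
#' with no chromosome assignment, or `"unlocalized"` for scaffolds associated
#' with a chromosome but without a position (these must carry
#' `associated_chromosome`).
#'
#' Sequences are uppercased on ingest and any IUPAC ambiguity code other than
#' `N` is coerced to `N` (with a message giving the count), because the gap
#' census is defined on maximal N-runs. All coordinates used throughout the
#' package are 1-based closed intervals, the native convention of GFF3 and of
#' the Bioconductor ranges infrastructure.
#'
#' @param seqs A named character vector or `DNAStringSet` of sequences.
#' @param role Character vector (recycled) of record roles.
#' @param associated_chromosome Optional character vector (recycled) giving
#'   the associated chromosome for unlocalized records.
#' @return An object of class `assembly` with elements `seqs` (DNAStringSet)
#'   and `info` (tibble with columns `seq_id`, `role`,
#'   `associated_chromosome`, `length`).
#' @examples
#' asm <- assembly(c(chr1 = "ACGTACGTNNNNACGT"))
#' asm
#' @export
assembly <- function(seqs, role = "chromosome", associated_chromosome = NA_character_) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs)) abort("`seqs` must be a named character vector or DNAStringSet")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) abort("all sequences must be named")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(nchar(seqs) == 0)) abort("sequences must be non-empty")
  seqs <- normalize_dna(seqs)
  info <- tibble(
    seq_id = ids,
    role = rep_len(role, length(seqs)),
    associated_chromosome = rep_len(as.character(associated_chromosome), length(seqs)),
    length = unname(nchar(seqs))
  )
  bad_role <- setdiff(unique(info$role), c("chromosome", "unplaced", "unlocalized"))
  if (length(bad_role)) abort(paste0("unknown record role: ", paste(bad_role, collapse = ", ")))
  miss <- info$role == "unlocalized" & is.na(info$associated_chromosome)
  if (any(miss)) {
    abort(paste0("unlocalized records need an associated chromosome: ",
                 paste(info$seq_id[miss], collapse = ", ")))
  }
  structure(
    list(seqs = Biostrings::DNAStringSet(seqs), info = info),
    class = "assembly"
  )
}

# uppercase and coerce non-ACGTN IUPAC codes to N, reporting the count
normalize_dna <- function(seqs) {
  up <- toupper(seqs)
  n_other <- sum(vapply(up, function(s) {
    nchar(gsub("[ACGTN]", "", s, perl = TRUE))
  }, numeric(1)))
  if (n_other > 0) {
    inform(sprintf("coerced %d non-ACGTN ambiguity code(s) to N", n_other))
    up <- vapply(up, function(s) gsub("[^ACGTN]", "N", s, perl = TRUE),
                 character(1), USE.NAMES = TRUE)
  }
  up
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d record(s), %s bp total\n",
              nrow(x$info), format(sum(x$info$length), big.mark = ",")))
  print(x$info, n = 10)
  invisible(x)
}

is_assembly <- function(x) inherits(x, "assembly")

#' Sequence accessors
#'
#' `asm_seq()` returns one record's sequence as a character scalar;
#' `asm_subseq()` a 1-based closed subinterval of it; `asm_ids()` the record
#' ids, optionally restricted by role.
#'
#' @param asm An [assembly].
#' @param seq_id Record id.
#' @param start,end 1-based closed interval bounds.
#' @param role Optional role filter for `asm_ids()`.
#' @return Character scalar (sequences) or character vector (ids).
#' @export
asm_seq <- function(asm, seq_id) {
  stopifnot(is_assembly(asm))
  i <- match(seq_id, asm$info$seq_id)
  if (is.na(i)) abort(paste0("unknown sequence id: ", seq_id))
  as.character(asm$seqs[[i]])
}

#' @rdname asm_seq
#' @export
asm_subseq <- function(asm, seq_id, start, end) {
  s <- asm_seq(asm, seq_id)
  n <- nchar(s)
  if (start < 1 || end > n || start > end) {
    abort(sprintf("interval [%d, %d] out of bounds for %s (length %d)",
                  start, end, seq_id, n))
  }
  substr(s, start, end)
}

#' @rdname asm_seq
#' @export
asm_ids <- function(asm, role = NULL) {
  stopifnot(is_assembly(asm))
  info <- asm$info
  if (!is.null(role)) info <- info[info$role %in% role, , drop = FALSE]
  info$seq_id
}

#' Subset or combine assemblies
#'
#' @param asm An [assembly].
#' @param seq_ids Record ids to keep (in the given order).
#' @export
asm_subset <- function(asm, seq_ids) {
  stopifnot(is_assembly(asm))
  missing <- setdiff(seq_ids, asm$info$seq_id)
  if (length(missing)) abort(paste0("unknown sequence id: ", paste(missing, collapse = ", ")))
  i <- match(seq_ids, asm$info$seq_id)
  structure(list(seqs = asm$seqs[i], info = asm$info[i, , drop = FALSE]),
            class = "assembly")
}

#' Read a FASTA file into an assembly
#'
#' Records keep file order; lowercase bases are uppercased and non-ACGTN
#' codes coerced to N. Record roles are not inferred from header naming
#' dialects; pass them explicitly via `roles` (default: all `"chromosome"`).
#'
#' @param path FASTA file.
#' @param roles Optional tibble with columns `seq_id`, `role` and optionally
#'   `associated_chromosome`, applied after reading.
#' @return An [assembly].
#' @export
read_fasta_assembly <- function(path, roles = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA header id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- setNames(as.character(set), ids)
  asm <- assembly(seqs)
  if (!is.null(roles)) asm <- set_roles(asm, roles)
  asm
}

#' @rdname read_fasta_assembly
#' @param asm An [assembly].
#' @param roles_tbl Tibble with `seq_id`, `role`, optionally
#'   `associated_chromosome`.
#' @export
set_roles <- function(asm, roles_tbl) {
  stopifnot(is_assembly(asm))
  roles_tbl <- as_tibble(roles_tbl)
  i <- match(roles_tbl$seq_id, asm$info$seq_id)
  if (anyNA(i)) abort("roles table names unknown sequence ids")
  asm$info$role[i] <- roles_tbl$role
  if ("associated_chromosome" %in% names(roles_tbl)) {
    asm$info$associated_chromosome[i] <- roles_tbl$associated_chromosome
  }
  assembly(as.character(asm$seqs), asm$info$role, asm$info$associated_chromosome)
}

#' Write an assembly to FASTA
#'
#' Deterministic output: records in assembly order, sequence lines wrapped at
#' `line_width`.
#'
#' @param asm An [assembly].
#' @param path Output path.
#' @param line_width Positive integer wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta_assembly <- function(asm, path, line_width = 80L) {
  stopifnot(is_assembly(asm), line_width >= 1)
  Biostrings::writeXStringSet(asm$seqs, filepath = path, width = as.integer(line_width))
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps rows of `feature_type` only and returns 1-based closed coordinates
#' as they appear in the file. The gene identifier is taken from the
#' `id_attribute` GFF3 attribute (default `ID`).
#'
#' @param path GFF3 file.
#' @param feature_type Feature type to retain (default `"gene"`).
#' @param id_attribute Attribute key holding the gene id.
#' @return Tibble with columns `gene_id`, `seq_id`, `start`, `end`, `strand`.
#' @export
read_gff3_genes <- function(path, feature_type = "gene", id_attribute = "ID") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readLines(path, warn = FALSE)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  if (length(body)) {
    fields <- strsplit(raw[body], "\t", fixed = TRUE)
    types <- vapply(fields, function(f) if (length(f) >= 3) f[[3]] else NA_character_, character(1))
    keep <- which(types == feature_type)
    for (j in keep) {
      f <- fields[[j]]
      s <- suppressWarnings(as.numeric(f[[4]])); e <- suppressWarnings(as.numeric(f[[5]]))
      if (!is.na(s) && !is.na(e) && s > e) {
        abort(sprintf("GFF3 line %d: start (%s) > end (%s)", body[j], f[[4]], f[[5]]))
      }
      if (!grepl(paste0("(^|;)\\s*", id_attribute, "="), f[[9]])) {
        abort(sprintf("GFF3 line %d: missing %s attribute", body[j], id_attribute))
      }
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == feature_type]
  if (length(gr) == 0) {
    return(tibble(gene_id = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  key <- if (id_attribute == "ID") "ID" else id_attribute
  ids <- as.character(S4Vectors::mcols(gr)[[key]])
  genes <- tibble(
    gene_id = ids,
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicate gene id in annotation: ",
                 paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")))
  }
  genes
}

#' Write gene models to GFF3
#'
#' @param genes Tibble as returned by [read_gff3_genes()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @export
write_gff3_genes <- function(genes, path, source = "gapsmith") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seq_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a per-base depth track
#'
#' Reads the 3-column TSV produced by depth tools (sequence, 1-based
#' position, integer depth) into dense per-base integer vectors. Positions
#' absent from the file default to depth 0. Sequence lengths are taken from
#' `seq_lengths` (named vector); sequences present there but absent from the
#' file get all-zero tracks.
#'
#' @param path TSV file (no header).
#' @param seq_lengths Named integer vector of sequence lengths.
#' @return A named list of integer vectors, class `depth_track`.
#' @export
read_depth_track <- function(path, seq_lengths) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  d <- readr::read_tsv(path, col_names = c("seq", "pos", "depth"),
                       col_types = readr::cols(
                         seq = readr::col_character(),
                         pos = readr::col_double(),
                         depth = readr::col_character()),
                       progress = FALSE)
  depth_num <- suppressWarnings(as.numeric(d$depth))
  bad <- which(is.na(depth_num) | depth_num != floor(depth_num) | depth_num < 0)
  if (length(bad)) {
    abort(sprintf("line %d: depth '%s' is not a non-negative integer",
                  bad[1], d$depth[bad[1]]))
  }
  tracks <- lapply(seq_lengths, function(len) integer(len))
  for (sid in unique(d$seq)) {
    rows <- d$seq == sid
    if (!sid %in% names(tracks)) {
      tracks[[sid]] <- integer(max(d$pos[rows]))
    }
    v <- tracks[[sid]]
    p <- d$pos[rows]
    if (any(p < 1 | p > length(v))) abort(paste0("depth position out of bounds on ", sid))
    v[p] <- as.integer(depth_num[rows])
    tracks[[sid]] <- v
  }
  structure(tracks, class = "depth_track")
}

#' @rdname read_depth_track
#' @param track A `depth_track`.
#' @export
write_depth_track <- function(track, path) {
  rows <- lapply(names(track), function(sid) {
    v <- track[[sid]]
    nz <- which(v > 0)
    if (!length(nz)) return(NULL)
    tibble(seq = sid, pos = nz, depth = v[nz])
  })
  readr::write_tsv(bind_rows(rows), path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Build a depth track from in-memory vectors
#'
#' @param vectors Named list of non-negative integer vectors.
#' @export
depth_track <- function(vectors) {
  stopifnot(is.list(vectors), !is.null(names(vectors)))
  if (any(vapply(vectors, function(v) any(v < 0), logical(1)))) {
    abort("depths must be non-negative")
  }
  structure(lapply(vectors, as.integer), class = "depth_track")
}
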