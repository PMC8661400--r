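#' Default configuration for the synthetic truth set
#'
#' The generator emulates the study design the package targets: a
#' chromosome-level truth genome with gene models, telomeric repeat arrays
#' at both ends and tandem-repeat arrays around gap sites; a degraded
#' reference derived from the truth by planting N-runs (a mix of arbitrary
#' 25/200 bp placeholders and size-estimated runs, some inside genes, one
#' excising a gene-bearing region onto an unlocalized scaffold) and by
#' truncating two distal telomeres; donor assemblies mutated from the truth
#' at stated rates (one re-assembly-class donor at divergence 0, two
#' alternative-class donors at 1% point divergence, one of which carries a
#' local inversion across a gap region); per-donor Poisson depth tracks with
#' a planted dropout; and scaffolds that are planted redundant, novel, or
#' duplicated copies of untouched regions.
#'
#' Two gaps are planted unclosable: every donor carries an N-run at the same
#' locus, emulating assemblies that all fail in the same highly repetitive
#' region. One further gap is closable only from the alternative donors (the
#' re-assembly donor is gapped there), which exercises depth-based ranking.
#'
#' @param n_chromosomes,chromosome_length,genes_per_chromosome Genome shape
#'   (defaults 3 x 500 kb, 50 genes each).
#' @param gene_length,intergenic Ranges (bp) sampled uniformly.
#' @param telomere_n Number of terminal telomeric repeats (default 400,
#'   i.e. 2 kb arrays).
#' @param gap_slots Fractions of the gene list at which the four gap sites
#'   per chromosome are placed.
#' @param depth_mean,dropout_mean Poisson depth means for normal and
#'   dropout regions.
#' @param donors Tibble with `name`, `class`, `sub_rate`.
#' @param truncate_extra Non-telomeric bp removed along with each truncated
#'   telomere (default 4000).
#' @return Config list for [generate_truth_set()].
#' @export
truth_config <- function(n_chromosomes = 3L, chromosome_length = 500000L,
                         genes_per_chromosome = 50L,
                         gene_length = c(1500L, 4000L),
                         intergenic = c(2000L, 8000L),
                         telomere_n = 400L,
                         gap_slots = c(0.16, 0.36, 0.56, 0.76),
                         depth_mean = 35, dropout_mean = 2,
                         donors = tibble(
                           name = c("reFlye", "altA", "altB"),
                           class = c("reassembly", "alternative", "alternative"),
                           sub_rate = c(0, 0.01, 0.01)),
                         truncate_extra = 4000L) {
  plan <- tibble(
    chr = rep(1:3, each = 4),
    slot = rep(1:4, times = 3),
    type = c("between", "within", "between", "within",
             "between", "excision", "between", "within",
             "between", "within", "between", "between"),
    class = c("estimated", "arbitrary25", "arbitrary200", "estimated",
              "estimated", "estimated", "arbitrary25", "arbitrary200",
              "estimated", "arbitrary25", "estimated", "arbitrary200"),
    donor_fail = c("none", "none", "none", "none",
                   "none", "none", "none", "none",
                   "all", "all", "reassembly", "none"),
    inversion = c(FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, TRUE, FALSE,
                  FALSE, FALSE, FALSE, FALSE)
  )
  plan <- plan[plan$chr <= n_chromosomes, , drop = FALSE]
  list(n_chromosomes = n_chromosomes, chromosome_length = chromosome_length,
       genes_per_chromosome = genes_per_chromosome, gene_length = gene_length,
       intergenic = intergenic, telomere_n = telomere_n,
       gap_slots = gap_slots, gap_plan = plan,
       depth_mean = depth_mean, dropout_mean = dropout_mean,
       donors = donors, truncate_extra = truncate_extra)
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_repeat_array <- function(target_len) {
  motif_len <- sample(6:20, 1)
  motif <- random_dna(motif_len)
  reps <- max(1L, ceiling(target_len / motif_len))
  substr(strrep(motif, reps), 1, target_len)
}

#' Mutate a truth genome into a donor assembly
#'
#' Applies uniform random substitutions at `sub_rate`, then optional
#' inversions (reverse complement of stated intervals), then optional small
#' indels at `indel_rate` (1-3 bp each, half deletions half insertions).
#' With all rates zero and no inversions the donor equals the truth.
#'
#' @param truth An [assembly].
#' @param sub_rate,indel_rate Per-base rates in `[0, 0.05]`.
#' @param inversions Optional tibble `seq_id`, `start`, `end` of intervals
#'   to reverse-complement (must not overlap).
#' @param seed Integer seed.
#' @param prefix Prefix for donor record ids.
#' @return An [assembly].
#' @export
mutate_donor <- function(truth, sub_rate = 0, indel_rate = 0,
                         inversions = NULL, seed = 1L, prefix = "") {
  stopifnot(sub_rate >= 0, sub_rate <= 0.05, indel_rate >= 0, indel_rate <= 0.05)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  if (!is.null(inversions) && nrow(inversions) > 1) {
    for (sid in unique(inversions$seq_id)) {
      iv <- inversions[inversions$seq_id == sid, , drop = FALSE]
      iv <- iv[order(iv$start), , drop = FALSE]
      if (nrow(iv) > 1 && any(iv$end[-nrow(iv)] >= iv$start[-1])) {
        abort("overlapping inversion intervals")
      }
    }
  }
  seqs <- as.character(truth$seqs)
  names(seqs) <- truth$info$seq_id
  for (sid in names(seqs)) {
    v <- strsplit(seqs[[sid]], "", fixed = TRUE)[[1]]
    if (sub_rate > 0) {
      n_sub <- rbinom(1, length(v), sub_rate)
      if (n_sub > 0) {
        pos <- sample.int(length(v), n_sub)
        v[pos] <- vapply(v[pos], function(b) sample(setdiff(bases, b), 1),
                         character(1), USE.NAMES = FALSE)
      }
    }
    s <- paste(v, collapse = "")
    if (!is.null(inversions)) {
      iv <- inversions[inversions$seq_id == sid, , drop = FALSE]
      for (r in seq_len(nrow(iv))) {
        seg <- revcomp_chr(substr(s, iv$start[r], iv$end[r]))
        s <- paste0(substr(s, 1, iv$start[r] - 1L), seg,
                    substr(s, iv$end[r] + 1L, nchar(s)))
      }
    }
    if (indel_rate > 0) {
      v <- strsplit(s, "", fixed = TRUE)[[1]]
      n_ind <- rbinom(1, length(v), indel_rate)
      if (n_ind > 0) {
        pos <- sort(sample.int(length(v) - 5L, n_ind), decreasing = TRUE)
        for (p in pos) {
          w <- sample(1:3, 1)
          if (runif(1) < 0.5) {
            v <- v[-(p:(p + w - 1L))]
          } else {
            v <- append(v, sample(bases, w, replace = TRUE), after = p)
          }
        }
      }
      s <- paste(v, collapse = "")
    }
    seqs[[sid]] <- s
  }
  names(seqs) <- paste0(prefix, names(seqs))
  assembly(seqs)
}

#' Generate a seeded synthetic truth set
#'
#' Builds the full test universe described in [truth_config()]: the truth
#' genome, the degraded reference (with its scaffold records appended), the
#' gene annotation in reference coordinates, the donor assemblies, per-donor
#' depth tracks, and a manifest recording every planted feature so that each
#' pipeline stage can be checked against ground truth. All outputs are pure
#' functions of `(config, seed)`.
#'
#' @param config A [truth_config()] list.
#' @param seed Integer seed.
#' @return List: `truth`, `reference`, `genes`, `donors` (named list of
#'   `list(assembly, class)`), `depth` (named list of `depth_track`s),
#'   `manifest`.
#' @export
generate_truth_set <- function(config = truth_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  gpc <- cfg$genes_per_chromosome
  telo_len <- cfg$telomere_n * 5L
  slots <- pmax(3L, pmin(gpc - 3L, round(gpc * cfg$gap_slots)))
  if (any(diff(slots) < 4L)) abort("gap slots too close together for this gene count")

  gene_rows <- list(); site_rows <- list(); chr_seqs <- character()
  for (ci in seq_len(cfg$n_chromosomes)) {
    sid <- paste0("chr", ci)
    plan <- cfg$gap_plan[cfg$gap_plan$chr == ci, , drop = FALSE]
    slot_of <- setNames(rep(NA_character_, gpc), seq_len(gpc))
    plan$gene_index <- slots[plan$slot]

    parts <- character(); pos <- 0L
    add <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
    add(strrep("CCTAA", cfg$telomere_n))
    add(random_dna(3000L))

    genes <- tibble(gene_id = character(), start = integer(), end = integer(),
                    strand = character())
    sites <- list()
    for (gi in seq_len(gpc)) {
      row <- plan[plan$gene_index == gi, , drop = FALSE]
      between_here <- nrow(row) == 1 && row$type %in% c("between")
      within_here <- nrow(row) == 1 && row$type == "within"

      if (between_here) {
        add(random_dna(600L))
        add(random_repeat_array(800L))
        core_len <- if (row$class == "estimated") sample(9000:13000, 1) else sample(4000:6000, 1)
        core_start <- pos + 1L
        add(random_dna(core_len))
        core_end <- pos
        add(random_repeat_array(800L))
        add(random_dna(600L))
        n_len <- switch(row$class, estimated = core_len,
                        arbitrary25 = 25L, arbitrary200 = 200L)
        sites[[length(sites) + 1L]] <- tibble(
          seq_id = sid, type = row$type, class = row$class,
          donor_fail = row$donor_fail, inversion = row$inversion,
          truth_start = core_start, truth_end = core_end, n_len = n_len,
          gene_index = gi)
      } else {
        add(random_dna(sample(cfg$intergenic[1]:cfg$intergenic[2], 1)))
      }

      span_len <- NA_integer_
      if (within_here) {
        span_len <- if (row$class == "estimated") sample(800:1500, 1) else sample(1500:3000, 1)
        glen <- span_len + 1700L + sample(200:600, 1)
      } else {
        glen <- sample(cfg$gene_length[1]:cfg$gene_length[2], 1)
      }
      gstart <- pos + 1L
      add(random_dna(glen))
      gend <- pos
      genes <- bind_rows(genes, tibble(
        gene_id = sprintf("g%d_%03d", ci, gi), start = gstart, end = gend,
        strand = sample(c("+", "-"), 1)))
      if (within_here) {
        ws <- gstart + 800L
        we <- ws + span_len - 1L
        n_len <- switch(row$class, estimated = span_len,
                        arbitrary25 = 25L, arbitrary200 = 200L)
        sites[[length(sites) + 1L]] <- tibble(
          seq_id = sid, type = "within", class = row$class,
          donor_fail = row$donor_fail, inversion = row$inversion,
          truth_start = ws, truth_end = we, n_len = n_len, gene_index = gi)
      }
    }
    # pad, tail buffer, right telomere; pad sits in the subtelomeric desert
    used <- pos + 6000L + telo_len
    pad <- cfg$chromosome_length - used
    if (pad < 0) abort("infeasible plan: chromosome_length too small for the layout")
    add(random_dna(pad))
    add(random_dna(6000L))
    add(strrep("TTAGG", cfg$telomere_n))
    chr_seqs[[sid]] <- paste(parts, collapse = "")

    # excision site: genes at index i, i+1 move to a scaffold
    exc <- plan[plan$type == "excision", , drop = FALSE]
    if (nrow(exc)) {
      gi <- exc$gene_index
      g_prev <- genes[gi - 1L, ]; g_next <- genes[gi + 2L, ]
      ex_start <- g_prev$end + 400L
      ex_end <- g_next$start - 400L
      sites[[length(sites) + 1L]] <- tibble(
        seq_id = sid, type = "excision", class = "estimated",
        donor_fail = exc$donor_fail, inversion = exc$inversion,
        truth_start = ex_start, truth_end = ex_end,
        n_len = ex_end - ex_start + 1L, gene_index = gi)
    }
    genes$seq_id <- sid
    gene_rows[[sid]] <- genes
    site_rows[[sid]] <- bind_rows(sites)
  }

  truth <- assembly(chr_seqs)
  truth_genes <- bind_rows(gene_rows)
  sites <- bind_rows(site_rows) |> arrange(.data$seq_id, .data$truth_start)

  # --- degrade: N-runs for every gap site, truncate two right telomeres ----
  ev_gap <- splice_events(
    seq_id = sites$seq_id, start = sites$truth_start, end = sites$truth_end,
    replacement = strrep("N", sites$n_len), type = "gap_plant",
    event_id = sprintf("plant%02d", seq_len(nrow(sites))))
  trunc <- tibble(seq_id = paste0("chr", c(1L, 2L)), end = "right")
  trunc <- trunc[trunc$seq_id %in% truth$info$seq_id, , drop = FALSE]
  ev_tr <- NULL
  if (nrow(trunc)) {
    lens <- truth$info$length[match(trunc$seq_id, truth$info$seq_id)]
    cut <- lens - telo_len - cfg$truncate_extra + 1L
    ev_tr <- splice_events(seq_id = trunc$seq_id, start = cut, end = lens,
                           replacement = "", type = "telomere_truncate",
                           event_id = sprintf("trunc%02d", seq_len(nrow(trunc))))
  }
  deg <- apply_splices(truth, bind_rows(ev_gap, ev_tr), prefix = "")
  degraded <- deg$assembly
  dchain <- deg$chain

  # gap-site reference coordinates (the planted N-run intervals)
  site_ref <- dchain[match(ev_gap$event_id, dchain$event_id), , drop = FALSE]
  sites$ref_start <- site_ref$new_start
  sites$ref_end <- site_ref$new_end
  sites$closable <- sites$donor_fail != "all"

  # annotation in reference coordinates; excised genes move to the scaffold
  exc_sites <- sites[sites$type == "excision", , drop = FALSE]
  ref_gene_rows <- list(); scaf_gene_rows <- list()
  for (i in seq_len(nrow(truth_genes))) {
    g <- truth_genes[i, ]
    exc <- exc_sites[exc_sites$seq_id == g$seq_id &
                       exc_sites$truth_start <= g$start &
                       exc_sites$truth_end >= g$end, , drop = FALSE]
    if (nrow(exc)) {
      scaf_gene_rows[[length(scaf_gene_rows) + 1L]] <- mutate(
        g, seq_id = "scaffold_1",
        start = g$start - exc$truth_start + 1L,
        end = g$end - exc$truth_start + 1L)
      next
    }
    lifted <- lift_position(dchain, g$seq_id, c(g$start, g$end))
    ref_gene_rows[[length(ref_gene_rows) + 1L]] <- mutate(
      g, start = lifted$lifted[1], end = lifted$lifted[2])
  }
  ref_genes <- bind_rows(ref_gene_rows)
  scaf_genes <- bind_rows(scaf_gene_rows)

  # --- scaffolds ------------------------------------------------------------
  take_span <- function(site, len) {
    lo <- site$truth_start + 500L
    asm_subseq(truth, site$seq_id, lo, min(site$truth_end, lo + len - 1L))
  }
  est_between <- sites[sites$type == "between" & sites$class == "estimated" &
                         sites$donor_fail == "none", , drop = FALSE]
  scafs <- character(); scaf_meta <- list()
  if (nrow(exc_sites)) {
    scafs[["scaffold_1"]] <- asm_subseq(truth, exc_sites$seq_id[1],
                                        exc_sites$truth_start[1], exc_sites$truth_end[1])
    scaf_meta[["scaffold_1"]] <- tibble(
      scaffold_id = "scaffold_1", category = "excised_gap_region",
      role = "unlocalized", associated_chromosome = exc_sites$seq_id[1],
      expected = "redundant")
  }
  for (j in seq_len(min(2L, nrow(est_between)))) {
    id <- paste0("scaffold_", length(scafs) + 1L)
    scafs[[id]] <- take_span(est_between[j, ], 8000L)
    scaf_meta[[id]] <- tibble(scaffold_id = id, category = "planted_redundant",
                              role = "unplaced",
                              associated_chromosome = NA_character_,
                              expected = "redundant")
  }
  id <- paste0("scaffold_", length(scafs) + 1L)
  scafs[[id]] <- random_dna(12000L)
  scaf_meta[[id]] <- tibble(scaffold_id = id, category = "novel",
                            role = "unplaced", associated_chromosome = NA_character_,
                            expected = "retained")
  id <- paste0("scaffold_", length(scafs) + 1L)
  dup_chr <- paste0("chr", cfg$n_chromosomes)
  # a region clear of every gap site and replaced interval (genes 4-5)
  dup_g <- truth_genes[truth_genes$seq_id == dup_chr, , drop = FALSE][4:5, ]
  scafs[[id]] <- asm_subseq(truth, dup_chr, dup_g$start[1] - 300L,
                            dup_g$end[2] + 300L)
  scaf_meta[[id]] <- tibble(scaffold_id = id, category = "duplicate_region",
                            role = "unplaced", associated_chromosome = NA_character_,
                            expected = "retained")
  scaf_meta <- bind_rows(scaf_meta)

  ref_seqs <- as.character(degraded$seqs)
  names(ref_seqs) <- degraded$info$seq_id
  reference <- assembly(
    c(ref_seqs, scafs),
    role = c(rep("chromosome", length(ref_seqs)), scaf_meta$role),
    associated_chromosome = c(rep(NA_character_, length(ref_seqs)),
                              scaf_meta$associated_chromosome))
  genes <- bind_rows(ref_genes, scaf_genes)

  # --- donors ---------------------------------------------------------------
  donors <- list()
  for (d in seq_len(nrow(cfg$donors))) {
    dn <- cfg$donors$name[d]
    inv <- NULL
    inv_sites <- sites[sites$inversion, , drop = FALSE]
    if (dn == "altB" && nrow(inv_sites)) {
      gsel <- truth_genes[truth_genes$seq_id == inv_sites$seq_id[1], , drop = FALSE]
      gi <- inv_sites$gene_index[1]
      inv <- tibble(seq_id = inv_sites$seq_id[1],
                    start = gsel$start[gi - 1L] - 1000L,
                    end = gsel$end[gi] + 1000L)
    }
    da <- mutate_donor(truth, sub_rate = cfg$donors$sub_rate[d],
                       inversions = inv, seed = seed * 131L + d,
                       prefix = paste0(dn, "_"))
    # plant donor N-runs where this donor class fails
    fail <- sites[sites$donor_fail == "all" |
                    (sites$donor_fail == "reassembly" &
                       cfg$donors$class[d] == "reassembly"), , drop = FALSE]
    if (nrow(fail)) {
      mid <- (fail$truth_start + fail$truth_end) %/% 2L
      half <- pmin(1000L, (fail$truth_end - fail$truth_start) %/% 3L)
      evf <- splice_events(seq_id = paste0(dn, "_", fail$seq_id),
                           start = mid - half, end = mid + half,
                           replacement = strrep("N", 2L * half + 1L),
                           type = "donor_fail",
                           event_id = sprintf("df%s%02d", dn, seq_len(nrow(fail))))
      da <- apply_splices(da, evf, prefix = "")$assembly
    }
    donors[[dn]] <- list(assembly = da, class = cfg$donors$class[d])
  }

  # --- depth: Poisson per base on each donor, with a planted dropout --------
  depth <- list()
  alt_only <- sites[sites$donor_fail == "reassembly", , drop = FALSE]
  for (dn in names(donors)) {
    da <- donors[[dn]]$assembly
    tr <- lapply(setNames(seq_len(nrow(da$info)), da$info$seq_id), function(i) {
      rpois(da$info$length[i], cfg$depth_mean)
    })
    if (dn == "altA" && nrow(alt_only)) {
      for (r in seq_len(nrow(alt_only))) {
        sid2 <- paste0(dn, "_", alt_only$seq_id[r])
        span <- alt_only$truth_start[r]:alt_only$truth_end[r]
        tr[[sid2]][span] <- rpois(length(span), cfg$dropout_mean)
      }
    }
    depth[[dn]] <- depth_track(tr)
  }

  manifest <- list(
    seed = seed,
    gaps = select(sites, "seq_id", "type", "class", "donor_fail", "closable",
                  "truth_start", "truth_end", "n_len", "ref_start", "ref_end"),
    truth_genes = truth_genes,
    truncated_telomeres = trunc,
    scaffolds = scaf_meta,
    donors = cfg$donors,
    expected = list(
      n_gaps = nrow(sites), n_closable = sum(sites$closable),
      n_truncated_telomeres = nrow(trunc),
      n_redundant = sum(scaf_meta$expected == "redundant"),
      alt_only_winner_class = "alternative")
  )
  list(truth = truth, reference = reference, genes = genes, donors = donors,
       depth = depth, manifest = manifest)
}

#' Write a truth set to files
#'
#' Emits the standard-format views of a generated truth set: truth and
#' reference FASTA, gene GFF3, donor FASTAs, per-donor depth TSVs and the
#' manifest JSON. Intended for small configurations and interoperability
#' checks; the in-memory objects are the primary interface.
#'
#' @param ts Result of [generate_truth_set()].
#' @param dir Output directory (created if needed).
#' @export
write_truth_set <- function(ts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta_assembly(ts$truth, file.path(dir, "truth.fa"))
  write_fasta_assembly(ts$reference, file.path(dir, "reference.fa"))
  write_gff3_genes(ts$genes, file.path(dir, "genes.gff3"))
  for (dn in names(ts$donors)) {
    write_fasta_assembly(ts$donors[[dn]]$assembly,
                         file.path(dir, paste0("donor_", dn, ".fa")))
    write_depth_track(ts$depth[[dn]], file.path(dir, paste0("depth_", dn, ".tsv")))
  }
  jsonlite::write_json(ts$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null",
                       digits = NA)
  invisible(dir)
}
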