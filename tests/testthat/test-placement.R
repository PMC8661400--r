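test_that("telomere scan calls dense terminal arrays and ignores background", {
  arr <- strrep("TTAGG", 200)              # 1 kb of telomeric repeat
  set.seed(51)
  s <- paste0(rand_dna(4000), arr)
  sc <- scan_telomeres(assembly(c(chr = s)), role = NULL)
  calls <- sc$calls
  expect_equal(calls$call[calls$end == "right"], "present")
  last_win <- sc$windows[nrow(sc$windows), ]
  expect_equal(last_win$density, 1)

  # uniform random sequence: expected motif coverage ~ 5 * 2/4^5 per base,
  # far below the call threshold; compare against a brute-force motif count
  set.seed(52)
  r <- rand_dna(10000)
  scr <- scan_telomeres(assembly(c(chr = r)), role = NULL)
  brute <- sum(attr(gregexpr("TTAGG", r)[[1]], "match.length") > 0) +
    sum(attr(gregexpr("CCTAA", r)[[1]], "match.length") > 0)
  brute_cov <- 5 * max(0, brute) / 10000
  expect_lt(max(scr$windows$density), 0.05)
  expect_lt(abs(mean(scr$windows$density) - brute_cov), 0.02)
  expect_true(all(scr$calls$call == "absent"))
})

test_that("telomere density is invariant under reverse complement with motif swap", {
  set.seed(53)
  s <- paste0(strrep("CCTAA", 300), rand_dna(8500),
              strrep("TTAGG", 180), rand_dna(1500),
              strrep("TTAGG", 120))          # length multiple of window
  stopifnot(nchar(s) %% 1000 == 0)
  a <- scan_telomeres(assembly(c(chr = s)), role = NULL)
  b <- scan_telomeres(assembly(c(chr = revcomp(s))), role = NULL)
  expect_equal(b$windows$density, rev(a$windows$density))
  expect_equal(b$windows$density_TTAGG, rev(a$windows$density_CCTAA))
  cab <- a$calls; cba <- b$calls
  expect_equal(cba$call[cba$end == "left"], cab$call[cab$end == "right"])
  expect_equal(cba$call[cba$end == "right"], cab$call[cab$end == "left"])
})

test_that("truncated chromosome ends are called absent, intact ends present", {
  ts <- get_small_ts()
  sc <- scan_telomeres(ts$reference)
  calls <- sc$calls
  trunc <- ts$manifest$truncated_telomeres
  for (i in seq_len(nrow(calls))) {
    expect_equal(calls$call[i],
                 if (any(trunc$seq_id == calls$seq_id[i] &
                           trunc$end == calls$end[i])) "absent" else "present",
                 info = paste(calls$seq_id[i], calls$end[i]))
  }
})

test_that("telomere recovery restores the donor's anchor-to-end distance", {
  ts <- get_small_ts()
  donor <- ts$donors$reFlye$assembly
  prop <- recover_telomere(ts$reference, ts$genes, "chr1", "right",
                           donor, "reFlye")
  expect_equal(prop$reason, "proposed")
  ev <- prop$event
  g <- ts$genes[ts$genes$seq_id == "chr1", ]
  last_gene <- g[which.max(g$end), ]
  expect_equal(ev$start, last_gene$end + 1L)
  expect_equal(ev$end, ts$reference$info$length[1])
  expect_equal(prop$donor_distance, nchar(ev$replacement))
  # the grafted tail is the truth chromosome's tail, byte for byte
  # (divergence-0 donor; upstream gaps are untouched by this event)
  truth_chr1 <- asm_seq(ts$truth, "chr1")
  expect_identical(ev$replacement,
                   substr(truth_chr1,
                          nchar(truth_chr1) - prop$donor_distance + 1L,
                          nchar(truth_chr1)))

  # already-telomeric ends yield no proposal
  noprop <- recover_telomere(ts$reference, ts$genes, "chr3", "right",
                             donor, "reFlye")
  expect_null(noprop$event)
  expect_equal(noprop$reason, "already_telomeric")
})

test_that("a duplicated terminal anchor gene is a hard error", {
  ts <- get_small_ts()
  g <- ts$genes[ts$genes$seq_id == "chr1", ]
  last_gene <- g[which.max(g$end), ]
  gene_seq <- asm_subseq(ts$reference, "chr1", last_gene$start, last_gene$end)
  chr1 <- asm_seq(ts$truth, "chr1")
  dup <- assembly(c(dchr = paste0(substr(chr1, 1, 20000), gene_seq,
                                  substr(chr1, 20001, nchar(chr1)))))
  expect_error(
    recover_telomere(ts$reference, ts$genes, "chr1", "right", dup, "dup"),
    "duplicated_anchor")
})

test_that("consensus placement needs agreement from min_support donors", {
  ts <- get_small_ts()
  scaf_genes <- ts$genes[ts$genes$seq_id == "scaffold_1", ]
  expect_gt(nrow(scaf_genes), 0L)
  chrom_genes <- ts$genes[startsWith(ts$genes$seq_id, "chr"), ]
  gq <- setNames(vapply(seq_len(nrow(chrom_genes)), function(i) {
    asm_subseq(ts$reference, chrom_genes$seq_id[i], chrom_genes$start[i],
               chrom_genes$end[i])
  }, character(1)), chrom_genes$gene_id)
  sq <- setNames(vapply(seq_len(nrow(scaf_genes)), function(i) {
    asm_subseq(ts$reference, "scaffold_1", scaf_genes$start[i], scaf_genes$end[i])
  }, character(1)), scaf_genes$gene_id)
  ref_anchors <- lapply(ts$donors, function(d) anchor_map(gq, d$assembly))
  scaf_hits <- lapply(ts$donors, function(d) anchor_map(sq, d$assembly))
  gaps <- gap_census(ts$reference, chrom_genes)

  dec <- consensus_place_scaffold("scaffold_1", scaf_genes, scaf_hits,
                                  ref_anchors, chrom_genes, gaps)
  expect_equal(dec$action, "close_gap")
  expect_gte(dec$supporting_assemblies, 3L)
  expect_equal(dec$target_seq, "chr2")

  # with a single donor the same evidence is below the support threshold
  dec1 <- consensus_place_scaffold("scaffold_1", scaf_genes, scaf_hits[1],
                                   ref_anchors[1], chrom_genes, gaps)
  expect_equal(dec1$action, "unresolved")

  # donor order never changes the decision
  perm <- c(3, 1, 2)
  dec_p <- consensus_place_scaffold("scaffold_1", scaf_genes, scaf_hits[perm],
                                    ref_anchors[perm], chrom_genes, gaps)
  expect_equal(dec_p$action, dec$action)
  expect_equal(dec_p$target_seq, dec$target_seq)
  expect_equal(dec_p$supporting_assemblies, dec$supporting_assemblies)

  # no markers, no placement
  dec0 <- consensus_place_scaffold("scaffold_4", scaf_genes[0, ], scaf_hits,
                                   ref_anchors, chrom_genes, gaps)
  expect_equal(dec0$action, "unresolved")
  expect_equal(dec0$note, "no_markers")
})

test_that("redundancy detection separates planted copies from genuine content", {
  cur <- get_small_curation()
  ts <- get_small_ts()
  red <- cur$redundancy
  man <- ts$manifest$scaffolds
  # exact confusion matrix at divergence 0: no off-diagonal entries
  for (i in seq_len(nrow(man))) {
    expect_equal(red$action[red$scaffold_id == man$scaffold_id[i]],
                 man$expected[i], info = man$scaffold_id[i])
  }
  # the duplicate-of-untouched-region scaffold aligns but outside edits
  dup <- red[red$scaffold_id ==
               man$scaffold_id[man$category == "duplicate_region"], ]
  expect_equal(dup$action, "retained")
  expect_gte(dup$coverage, 0.9)
  expect_false(dup$intersects_inserted)
})
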