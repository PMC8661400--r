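test_that("splice application does exact length bookkeeping", {
  set.seed(41)
  s <- rand_dna(100)
  asm <- assembly(c(chr = s))
  ev <- splice_events("chr", 11L, 20L, rand_dna(15))
  out <- apply_splices(asm, ev)
  expect_equal(out$assembly$info$length, 105L)
  expect_equal(out$chain$delta, 5L)
  expect_equal(out$assembly$info$seq_id, "cor_chr")
  # prefix + replacement + suffix structure
  cs <- asm_seq(out$assembly, "cor_chr")
  expect_equal(substr(cs, 1, 10), substr(s, 1, 10))
  expect_equal(substr(cs, 26, 105), substr(s, 21, 100))

  # zero events: identity, empty chain
  out0 <- apply_splices(asm, splice_events(character(), integer(), integer(),
                                           character()))
  expect_identical(as.character(out0$assembly$seqs), as.character(asm$seqs))
  expect_equal(nrow(out0$chain), 0L)
})

test_that("planted multi-event splices reassemble the truth string", {
  set.seed(42)
  truth <- rand_dna(3000)
  spans <- list(c(301L, 500L), c(1201L, 1210L), c(2401L, 2900L))
  ref <- truth
  for (sp in rev(spans)) {
    ref <- paste0(substr(ref, 1, sp[1] - 1L), strrep("N", 40L),
                  substr(ref, sp[2] + 1L, nchar(ref)))
  }
  asm <- assembly(c(chr = ref))
  # recompute the N-run intervals on the degraded coordinates
  gaps <- find_gaps(asm, role = NULL)
  repl <- vapply(spans, function(sp) substr(truth, sp[1], sp[2]), character(1))
  ev <- splice_events("chr", gaps$start, gaps$end, repl, type = "gap_close")
  out <- apply_splices(asm, ev)
  expect_identical(asm_seq(out$assembly, "cor_chr"), truth)
  # sum of deltas equals the length change
  expect_equal(sum(out$chain$delta), nchar(truth) - nchar(ref))
})

test_that("overlapping, out-of-bounds and re-applied events are rejected", {
  asm <- assembly(c(chr = rand_dna(200)))
  ev <- splice_events("chr", c(10L, 15L), c(20L, 30L), c("AAA", "CCC"))
  expect_error(apply_splices(asm, ev), "overlapping.*ev001.*ev002")
  expect_error(apply_splices(asm, splice_events("chr", 150L, 300L, "A")),
               "out of bounds")
  expect_error(apply_splices(asm, splice_events("nope", 1L, 5L, "A")),
               "unknown sequence")
  ok <- splice_events("chr", 10L, 20L, "GGG")
  out <- apply_splices(asm, ok)
  # the corrected assembly refuses the same event list again
  expect_error(apply_splices(out$assembly, ok), "already applied")
  # with an identity prefix the explicit guard still rejects re-application
  out2 <- apply_splices(asm, ok, prefix = "")
  expect_error(apply_splices(out2$assembly, ok, prefix = ""), "already applied")
})

test_that("position lifting shifts by cumulative delta and inverts outside edits", {
  asm <- assembly(c(chr = rand_dna(500)))
  ev <- splice_events("chr", c(11L, 101L), c(20L, 140L),
                      c(rand_dna(15), rand_dna(10)))
  out <- apply_splices(asm, ev)
  ch <- out$chain
  expect_equal(lift_position(ch, "chr", 5L)$lifted, 5L)
  expect_equal(lift_position(ch, "chr", 30L)$lifted, 35L)   # +5 after edit 1
  expect_equal(lift_position(ch, "chr", 200L)$lifted, 175L) # +5 - 30
  expect_equal(lift_position(ch, "chr", 15L)$status, "inside_edit")
  expect_error(lift_position(ch, "nope", 1L), "unknown sequence")

  # invertibility on every outside-edit position
  outside <- setdiff(1:500, c(11:20, 101:140))
  fwd <- lift_position(ch, "chr", outside)
  back <- lift_position(ch, "cor_chr", fwd$lifted, direction = "new2old")
  expect_equal(back$lifted, outside)
  # strict monotonicity
  expect_true(all(diff(fwd$lifted) > 0))
})

test_that("annotation lifting shifts, re-anchors and flags genes correctly", {
  set.seed(43)
  asm <- assembly(c(chr = rand_dna(2000)))
  genes <- tibble::tibble(
    gene_id = c("left", "right", "replaced", "spanning"),
    seq_id = "chr",
    start = c(50L, 1500L, 600L, 1000L),
    end = c(200L, 1700L, 800L, 1300L),
    strand = "+")
  ev <- splice_events("chr", c(600L, 1100L), c(800L, 1150L),
                      c(rand_dna(250), rand_dna(51)), type = "gap_close")
  out <- apply_splices(asm, ev)
  lifted <- lift_annotation(genes, out$chain)
  expect_equal(lifted$lift_status[lifted$gene_id == "left"], "unchanged")
  expect_equal(lifted$new_start[lifted$gene_id == "left"], 50L)
  expect_equal(lifted$lift_status[lifted$gene_id == "right"], "shifted")
  expect_equal(lifted$new_start[lifted$gene_id == "right"], 1549L)
  # gene body == replaced interval: re-anchored onto the inserted span
  expect_equal(lifted$lift_status[lifted$gene_id == "replaced"], "reanchored")
  expect_equal(lifted$new_start[lifted$gene_id == "replaced"],
               out$chain$new_start[1])
  expect_equal(lifted$new_end[lifted$gene_id == "replaced"],
               out$chain$new_end[1])
  # gene strictly containing an edit keeps lifted outer coordinates
  expect_equal(lifted$lift_status[lifted$gene_id == "spanning"], "spans_edit")
  expect_true(all(!is.na(lifted$new_start[lifted$gene_id == "spanning"])))
})

test_that("sequence outside edits is conserved byte-for-byte", {
  set.seed(44)
  for (i in 1:5) {
    n <- sample(2000:4000, 1)
    s <- rand_dna(n)
    k <- sample(1:4, 1)
    starts <- sort(sample(seq(100L, n - 400L, by = 350L), k))
    ends <- starts + sample(10:200, k, TRUE)
    repl <- vapply(sample(0:300, k, TRUE), rand_dna, character(1))
    ev <- splice_events("chr", starts, ends, repl)
    out <- apply_splices(assembly(c(chr = s)), ev)
    cs <- asm_seq(out$assembly, "cor_chr")
    expect_equal(nchar(cs), n + sum(out$chain$delta))
    # every outside-edit segment must be identical under the lift
    bounds <- c(0L, as.vector(rbind(starts - 1L, ends)), n)
    for (j in seq(1, length(bounds) - 1, by = 2)) {
      a <- bounds[j] + 1L; b <- bounds[j + 1L]
      if (a > b) next
      la <- lift_position(out$chain, "chr", a)$lifted
      lb <- lift_position(out$chain, "chr", b)$lifted
      expect_identical(substr(cs, la, lb), substr(s, a, b))
    }
  }
})

test_that("post-splice junction checks pass clean splices and catch offsets", {
  set.seed(45)
  truth <- rand_dna(4000)
  ref <- paste0(substr(truth, 1, 1500), strrep("N", 30), substr(truth, 2001, 4000))
  asm <- assembly(c(chr = ref))
  gaps <- find_gaps(asm, role = NULL)
  good <- splice_events("chr", gaps$start, gaps$end,
                        substr(truth, 1501, 2000), type = "gap_close",
                        event_id = "good")
  out <- apply_splices(asm, good)
  chk <- post_splice_check(out$assembly, asm, out$chain)
  expect_true(chk$pass)

  # a splice landed 500 bp away from the gap it claims to close: checking
  # the junctions against the gap's own interval exposes the offset
  bad <- splice_events("chr", gaps$start - 500L, gaps$end - 500L,
                       substr(truth, 1501, 2000), type = "gap_close",
                       event_id = "bad")
  outb <- apply_splices(asm, bad)
  chkb <- post_splice_check(outb$assembly, asm, outb$chain,
                            expected = tibble::tibble(event_id = "bad",
                                                      start = gaps$start,
                                                      end = gaps$end))
  expect_false(chkb$pass)
  expect_match(chkb$reason, "junction")

  # telomere graft at the sequence end: downstream flank unassessable
  telo <- splice_events("chr", nchar(ref) - 99L, nchar(ref),
                        paste0(rand_dna(200), strrep("TTAGG", 100)),
                        type = "telomere_add", event_id = "telo")
  outt <- apply_splices(asm, telo)
  chkt <- post_splice_check(outt$assembly, asm, outt$chain)
  expect_true(chkt$pass)
  expect_match(chkt$note, "unassessable")
})
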