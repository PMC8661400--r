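test_that("exact containment yields a full-identity forward hit", {
  set.seed(21)
  t <- rand_dna(8000)
  q <- substr(t, 3001, 3600)
  h <- builtin_anchor_align(q, t)
  best <- h[h$rank == 1 & h$strand == "+", ]
  expect_equal(best$tstart, 3001L)
  expect_equal(best$tend, 3600L)
  expect_equal(best$identity, 1)
  expect_equal(best$coverage, 1)
})

test_that("reverse-complement queries hit the same interval on the minus strand", {
  set.seed(22)
  for (i in 1:5) {
    t <- rand_dna(5000)
    a <- sample(1000:3000, 1)
    q <- substr(t, a, a + 499)
    fwd <- builtin_anchor_align(q, t)
    rev <- builtin_anchor_align(revcomp(q), t)
    f1 <- fwd[fwd$rank == 1, ][which.max(fwd$coverage[fwd$rank == 1]), ]
    r1 <- rev[rev$rank == 1, ][which.max(rev$coverage[rev$rank == 1]), ]
    expect_equal(r1$tstart, f1$tstart)
    expect_equal(r1$tend, f1$tend)
    expect_setequal(c(f1$strand, r1$strand), c("+", "-"))
  }
})

test_that("multi-copy queries produce as many chains as a substring scan finds", {
  set.seed(23)
  unit <- rand_dna(400)
  t <- paste0(rand_dna(1000), unit, rand_dna(1200), unit, rand_dna(1000))
  h <- builtin_anchor_align(unit, t, max_chains = 4L)
  plus <- h[h$strand == "+" & h$coverage > 0.9, ]
  naive <- length(gregexpr(unit, t, fixed = TRUE)[[1]])
  expect_equal(nrow(plus), naive)
  expect_equal(sort(plus$tstart), as.integer(gregexpr(unit, t, fixed = TRUE)[[1]]))
})

test_that("queries shorter than k are rejected", {
  expect_error(builtin_anchor_align("ACGT", rand_dna(100), k = 21L), "shorter than k")
})

test_that("gene mapping onto an identical donor reproduces coordinates exactly", {
  ts <- get_small_ts()
  truth <- ts$truth
  genes <- ts$genes[ts$genes$seq_id == "chr1", ][c(2, 5, 10, 18), ]
  donor <- assembly(setNames(as.character(truth$seqs), truth$info$seq_id))
  for (i in seq_len(nrow(genes))) {
    hit <- map_gene_to_donor(genes[i, ], truth, donor)
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$donor_seq_id, genes$seq_id[i])
    expect_equal(hit$start, genes$start[i])
    expect_equal(hit$end, genes$end[i])
    expect_equal(hit$identity, 1)
    expect_equal(hit$strand, "+")
  }
})

test_that("genes are recovered in 1%-diverged donors near their planted location", {
  ts <- get_small_ts()
  genes <- ts$manifest$truth_genes    # truth coordinates = donor coordinates
  genes <- genes[(genes$end - genes$start + 1L) >= 200L, ]
  donor <- ts$donors$altA$assembly    # 1% point divergence, no indels
  gq <- setNames(
    vapply(seq_len(nrow(genes)), function(i) {
      asm_subseq(ts$truth, genes$seq_id[i], genes$start[i], genes$end[i])
    }, character(1)), genes$gene_id)
  hits <- anchor_map(gq, donor)
  ok <- hits$status == "mapped" &
    abs(hits$start - genes$start) <= 50L &
    abs(hits$end - genes$end) <= 50L
  expect_gte(mean(ok), 0.95)
  mapped <- hits$status == "mapped"
  expect_gt(mean(hits$identity[mapped]), 0.95)
})

test_that("absent and duplicated markers are reported, not guessed", {
  set.seed(25)
  gene_seq <- rand_dna(900)
  donor_absent <- assembly(c(d1 = rand_dna(6000)))
  h <- anchor_map(setNames(gene_seq, "g"), donor_absent)
  expect_equal(h$status, "unmapped")

  donor_dup <- assembly(c(d1 = paste0(rand_dna(2000), gene_seq, rand_dna(2000),
                                      gene_seq, rand_dna(2000))))
  h2 <- anchor_map(setNames(gene_seq, "g"), donor_dup)
  expect_equal(h2$status, "duplicated")

  ref <- assembly(c(chr = paste0(rand_dna(100), strrep("N", 60), rand_dna(100))))
  gene <- tibble::tibble(gene_id = "gN", seq_id = "chr", start = 101L, end = 160L,
                         strand = "+")
  expect_error(map_gene_to_donor(gene, ref, donor_absent), "all-N")
})

test_that("gene-order comparison honours global flips and flags swaps", {
  set.seed(26)
  gs <- vapply(1:4, function(i) rand_dna(600), character(1))
  region <- paste0(rand_dna(400), gs[1], rand_dna(300), gs[2], rand_dna(300),
                   gs[3], rand_dna(300), gs[4], rand_dna(400))
  ids <- paste0("g", 1:4)
  q <- setNames(gs, ids)

  same <- anchor_map(q, assembly(c(d = region)))
  flipped <- anchor_map(q, assembly(c(d = revcomp(region))))
  swapped_region <- paste0(rand_dna(400), gs[2], rand_dna(300), gs[1],
                           rand_dna(300), gs[3], rand_dna(300), gs[4], rand_dna(400))
  swapped <- anchor_map(q, assembly(c(d = swapped_region)))
  dropped <- anchor_map(q[-2], assembly(c(d = region)))

  cmp <- compare_gene_order(ids, list(a1 = same, a2 = same, a3 = same))
  expect_true(all(cmp$concordant))

  cmp_flip <- compare_gene_order(ids, list(a = flipped))
  expect_true(cmp_flip$concordant)
  expect_true(cmp_flip$flipped)

  cmp_swap <- compare_gene_order(ids, list(a = swapped))
  expect_false(cmp_swap$concordant)
  expect_match(cmp_swap$note, "order differs")

  cmp_abs <- compare_gene_order(ids, list(a = dropped))
  expect_true(cmp_abs$concordant)
  expect_match(cmp_abs$note, "absent: g2")
  expect_false(compare_gene_order(ids, list(a = dropped), strict = TRUE)$concordant)
})
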