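# A hand-built mini locus: upstream gene, repeat-flanked core, downstream
# gene. The reference carries an N-run in place of the core; donors carry the
# full truth sequence. Small enough that every coordinate is known exactly.
make_mini_locus <- function(seed = 31, n_len = 50L) {
  set.seed(seed)
  pad1 <- rand_dna(1000); up <- rand_dna(800); pre <- rand_dna(400)
  core <- rand_dna(1200); post <- rand_dna(400); down <- rand_dna(800)
  pad2 <- rand_dna(1000)
  truth <- paste0(pad1, up, pre, core, post, down, pad2)
  ref <- paste0(pad1, up, pre, strrep("N", n_len), post, down, pad2)
  up_start <- nchar(pad1) + 1L
  up_end <- up_start + 800L - 1L
  down_start <- nchar(pad1) + 800L + 400L + n_len + 400L + 1L
  genes <- tibble::tibble(
    gene_id = c("gU", "gD"), seq_id = "chr",
    start = c(up_start, down_start), end = c(up_end, down_start + 800L - 1L),
    strand = "+")
  list(truth = truth, reference = assembly(c(chr = ref)), genes = genes,
       donor = assembly(c(dchr = truth)),
       truth_span = c(nchar(pad1) + 800L + 1L, nchar(pad1) + 800L + 2000L))
}

mini_candidate <- function(loc, donor = loc$donor, donor_id = "d1",
                           source_class = "reassembly") {
  gaps <- gap_census(loc$reference, loc$genes, role = NULL)
  mk <- gap_markers(gaps[1, ], loc$genes)
  q <- c(asm_subseq(loc$reference, "chr", mk$markers$start[1], mk$markers$end[1]),
         asm_subseq(loc$reference, "chr", mk$markers$start[2], mk$markers$end[2]))
  names(q) <- c("up", "down")
  hits <- anchor_map(q, donor)
  extract_gcs(gaps[1, ], donor, hits[hits$id == "up", ], hits[hits$id == "down", ],
              mk, donor_id = donor_id, source_class = source_class)
}

test_that("extraction from a faithful donor restores the truth span exactly", {
  loc <- make_mini_locus()
  cand <- mini_candidate(loc)
  expect_equal(cand$status, "candidate")
  truth_gcs <- substr(loc$truth, loc$truth_span[1], loc$truth_span[2])
  expect_identical(cand$sequence, truth_gcs)
  val <- validate_flanks(cand, loc$reference)
  expect_equal(val$status, "validated")
  expect_equal(val$up_flank_identity, 1)
  expect_equal(val$down_flank_identity, 1)
})

test_that("extraction is equivariant under reverse-complementing the donor", {
  loc <- make_mini_locus()
  cand_f <- mini_candidate(loc)
  donor_rc <- assembly(c(dchr = revcomp(asm_seq(loc$donor, "dchr"))))
  cand_r <- mini_candidate(loc, donor = donor_rc)
  expect_equal(cand_r$strand, "-")
  expect_identical(cand_r$sequence, cand_f$sequence)
  expect_identical(cand_r$up_flank, cand_f$up_flank)
  expect_identical(cand_r$down_flank, cand_f$down_flank)
})

test_that("within-gene gaps replace the whole containing gene", {
  set.seed(32)
  pad1 <- rand_dna(900); head5 <- rand_dna(900); mid <- rand_dna(700)
  tail3 <- rand_dna(900); pad2 <- rand_dna(900)
  truth <- paste0(pad1, head5, mid, tail3, pad2)
  ref <- paste0(pad1, head5, strrep("N", 25L), tail3, pad2)
  genes <- tibble::tibble(gene_id = "gW", seq_id = "chr", start = 901L,
                          end = 900L + 900L + 25L + 900L, strand = "+")
  reference <- assembly(c(chr = ref))
  donor <- assembly(c(d = truth))
  gaps <- gap_census(reference, genes, role = NULL)
  expect_equal(gaps$within_gene, "gW")
  mk <- gap_markers(gaps[1, ], genes)
  expect_equal(mk$mode, "within")
  expect_equal(mk$replaced$start, genes$start)
  expect_equal(mk$replaced$end, genes$end)
  q <- setNames(c(asm_subseq(reference, "chr", mk$markers$start[1], mk$markers$end[1]),
                  asm_subseq(reference, "chr", mk$markers$start[2], mk$markers$end[2])),
                c("up", "down"))
  hits <- anchor_map(q, donor)
  cand <- extract_gcs(gaps[1, ], donor, hits[hits$id == "up", ],
                      hits[hits$id == "down", ], mk, donor_id = "d")
  # the candidate is the donor's complete gene: head + mid + tail
  expect_identical(cand$sequence, paste0(head5, mid, tail3))
  expect_equal(validate_flanks(cand, reference)$status, "validated")
})

test_that("inconsistent anchors are rejected with the right reasons", {
  loc <- make_mini_locus()
  gaps <- gap_census(loc$reference, loc$genes, role = NULL)
  mk <- gap_markers(gaps[1, ], loc$genes)
  hit <- function(seq_id, start, end, strand = "+") {
    tibble::tibble(id = "x", status = "mapped", donor_seq_id = seq_id,
                   start = start, end = end, strand = strand,
                   identity = 1, coverage = 1, n_seeds = 10L)
  }
  split <- extract_gcs(gaps[1, ], loc$donor, hit("dchr", 1001, 1800),
                       hit("other", 100, 900), mk, donor_id = "d")
  expect_equal(split$reason, "split_anchor")

  conflict <- extract_gcs(gaps[1, ], loc$donor, hit("dchr", 3000, 3800),
                          hit("dchr", 1001, 1800), mk, donor_id = "d")
  expect_equal(conflict$reason, "order_conflict")

  strands <- extract_gcs(gaps[1, ], loc$donor, hit("dchr", 1001, 1800),
                         hit("dchr", 3001, 3800, "-"), mk, donor_id = "d")
  expect_equal(strands$reason, "order_conflict")

  gapped_donor <- assembly(c(dchr = paste0(
    substr(loc$truth, 1, 2500), strrep("N", 80),
    substr(loc$truth, 2581, nchar(loc$truth)))))
  gd <- mini_candidate(loc, donor = gapped_donor)
  expect_equal(gd$reason, "donor_gapped")
})

test_that("flank identity is Hamming-exact and thresholded at 0.95", {
  loc <- make_mini_locus(seed = 33)
  donor_seq <- asm_seq(loc$donor, "dchr")
  gcs_start <- loc$truth_span[1]           # donor coords equal truth coords
  flip <- function(s, positions) {
    v <- strsplit(s, "")[[1]]
    v[positions] <- chartr("ACGT", "CATG", v[positions])
    paste(v, collapse = "")
  }
  # substitutions clustered at the flank start so the marker gene still maps
  for (n_sub in c(5L, 6L)) {
    pos <- gcs_start - 100L + c(2L, 4L, 6L, 8L, 10L, 12L)[seq_len(n_sub)] - 1L
    mutated <- flip(donor_seq, pos)
    donor <- assembly(c(dchr = mutated))
    cand <- mini_candidate(loc, donor = donor)
    val <- validate_flanks(cand, loc$reference)
    hamming <- sum(strsplit(cand$up_flank, "")[[1]] !=
                     strsplit(asm_subseq(loc$reference, "chr",
                                         cand$replaced_start - 100L,
                                         cand$replaced_start - 1L), "")[[1]])
    expect_equal(val$up_flank_identity, 1 - hamming / 100)
    if (n_sub == 5L) {
      expect_equal(val$status, "validated")
    } else {
      expect_equal(val$status, "rejected")
      expect_equal(val$reason, "flank_mismatch")
    }
  }
})

test_that("candidates extracted at a decoy locus fail flank validation", {
  loc <- make_mini_locus(seed = 34)
  # pretend the anchors matched a paralogous cassette elsewhere in the donor:
  # shift both hits 3 kb away from the true locus
  gaps <- gap_census(loc$reference, loc$genes, role = NULL)
  mk <- gap_markers(gaps[1, ], loc$genes)
  decoy_donor <- assembly(c(dchr = paste0(asm_seq(loc$donor, "dchr"), rand_dna(6000))))
  hit <- function(start, end) {
    tibble::tibble(id = "x", status = "mapped", donor_seq_id = "dchr",
                   start = start, end = end, strand = "+",
                   identity = 0.99, coverage = 0.99, n_seeds = 10L)
  }
  cand <- extract_gcs(gaps[1, ], decoy_donor, hit(5801L, 6600L), hit(8801L, 9600L),
                      mk, donor_id = "d")
  expect_equal(cand$status, "candidate")
  val <- validate_flanks(cand, loc$reference)
  expect_equal(val$status, "rejected")
  expect_equal(val$reason, "flank_mismatch")
})

test_that("coverage statistics match brute-force arithmetic", {
  tr <- depth_track(list(s = c(rep(10L, 20))))
  expect_equal(coverage_stats(tr, "s", 1, 20), tibble::tibble(mean = 10, cv = 0))

  tr2 <- depth_track(list(s = c(0L, 10L)))
  st <- coverage_stats(tr2, "s", 1, 2)
  expect_equal(st$mean, 5)
  expect_equal(st$cv, 1)

  set.seed(35)
  v <- sample(0:60, 500, TRUE)
  tr3 <- depth_track(list(s = v))
  st3 <- coverage_stats(tr3, "s", 101, 400)
  x <- v[101:400]
  expect_equal(st3$mean, mean(x))
  expect_equal(st3$cv, sqrt(mean((x - mean(x))^2)) / mean(x))

  expect_error(coverage_stats(tr3, "s", 10, 5), "empty")
  expect_error(coverage_stats(tr3, "nope", 1, 5), "no depth")
})

test_that("candidate ranking is the documented total order", {
  row <- function(donor, class, mean = NA, cv = NA, len = 1000L,
                  status = "validated") {
    tibble::tibble(gap_id = "g", donor_id = donor, source_class = class,
                   gcs_length = len, depth_mean = mean, depth_cv = cv,
                   status = status, up_flank_identity = 1,
                   down_flank_identity = 1)
  }
  # re-assembly class beats alternative regardless of depth
  c1 <- dplyr::bind_rows(row("re", "reassembly", 20), row("alt", "alternative", 30))
  expect_equal(rank_candidates(c1)$donor_id, "re")
  # within a class, higher mean wins
  c2 <- dplyr::bind_rows(row("a", "alternative", 30), row("b", "alternative", 20))
  expect_equal(rank_candidates(c2)$donor_id, "a")
  # CV breaks mean ties, length breaks CV ties, donor id breaks length ties
  c3 <- dplyr::bind_rows(row("a", "alternative", 30, 0.5),
                         row("b", "alternative", 30, 0.2))
  expect_equal(rank_candidates(c3)$donor_id, "b")
  c4 <- dplyr::bind_rows(row("a", "alternative", 30, 0.2, 2000L),
                         row("b", "alternative", 30, 0.2, 1500L))
  expect_equal(rank_candidates(c4)$donor_id, "b")
  c5 <- dplyr::bind_rows(row("b", "alternative"), row("a", "alternative"))
  expect_equal(rank_candidates(c5)$donor_id, "a")
  # nothing validated, nothing selected
  c6 <- row("a", "alternative", status = "rejected")
  expect_equal(nrow(rank_candidates(c6)), 0L)
})

test_that("ranking is permutation invariant and never selects invalid candidates", {
  set.seed(36)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    cands <- tibble::tibble(
      gap_id = "g", donor_id = paste0("d", 1:n),
      source_class = sample(c("reassembly", "alternative"), n, TRUE),
      gcs_length = sample(500:5000, n),
      depth_mean = ifelse(runif(n) < 0.3, NA, round(runif(n, 5, 50), 2)),
      depth_cv = round(runif(n, 0, 1), 3),
      status = sample(c("validated", "rejected", "candidate"), n, TRUE),
      up_flank_identity = round(runif(n, 0.8, 1), 3),
      down_flank_identity = round(runif(n, 0.8, 1), 3))
    sel <- rank_candidates(cands)
    perm <- cands[sample(n), ]
    sel2 <- rank_candidates(perm)
    if (nrow(sel)) {
      expect_equal(sel$donor_id, sel2$donor_id)
      expect_equal(sel$status, "validated")
    } else {
      expect_equal(nrow(sel2), 0L)
      expect_false(any(cands$status == "validated"))
    }
  }
})
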