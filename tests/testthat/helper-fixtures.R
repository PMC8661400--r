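# Shared fixtures. The small truth set is generated once per test run and
# memoized; it uses the same planted-feature plan as the default study-scale
# configuration, scaled to keep unit tests fast.

small_truth_config <- function() {
  truth_config(chromosome_length = 160000L, genes_per_chromosome = 20L,
               intergenic = c(800L, 2500L))
}

.fixture_env <- new.env(parent = emptyenv())

get_small_ts <- function(seed = 7L) {
  key <- paste0("ts", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_truth_set(small_truth_config(), seed = seed)
  }
  .fixture_env[[key]]
}

get_small_curation <- function(seed = 7L) {
  key <- paste0("cur", seed)
  if (is.null(.fixture_env[[key]])) {
    ts <- get_small_ts(seed)
    .fixture_env[[key]] <- curate_assembly(ts$reference, ts$genes, ts$donors,
                                           depth = ts$depth)
  }
  .fixture_env[[key]]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
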