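# Shared test helpers: small deterministic sequence generators and the
# brute-force folding oracle wrappers.

random_test_rna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Maximum score over the exhaustive structure enumeration, optionally
# honouring forced-unpaired constraints (filtering the enumeration keeps
# the oracle independent of the DP's constraint handling).
oracle_max_score <- function(sequence, constraints = integer(0)) {
  structs <- enumerate_structures(sequence)
  if (length(constraints)) {
    structs <- Filter(function(s) {
      !NROW(s$pairs) || !any(s$pairs %in% constraints)
    }, structs)
  }
  max(vapply(structs, `[[`, numeric(1), "score"))
}

test_library <- function() load_aptamer_library()

# A tiny scored repressor design on a poly-U window context.
tiny_scored_repressor <- function(lib = test_library(), window = c(5L, 24L)) {
  d <- assemble_repressor(strrep("A", 20), lib$theophylline, copies = 2L,
                          id = "tiny_rep", window = window, region = "utr5")
  d$scores <- score_design(d)
  d
}
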