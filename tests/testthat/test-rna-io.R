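write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

write_tmp_annotation <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("read_transcripts normalises DNA input and enforces annotation", {
  fa <- write_tmp_fasta(list(x = "ATGC"))
  ann <- write_tmp_annotation(data.frame(id = "x", utr5_end = 0, cds_end = 4,
                                         capped = TRUE))
  expect_message(txs <- read_transcripts(fa, ann), "T -> U")
  expect_identical(txs$x$sequence, "AUGC")
  expect_identical(txs$x$utr5_end, 0L)

  # invariant violation: annotation end beyond the sequence
  ann_bad <- write_tmp_annotation(data.frame(id = "x", utr5_end = 10,
                                             cds_end = 10, capped = TRUE))
  expect_error(read_transcripts(fa, ann_bad), "utr5_end")

  # a record without an annotation row is named in the error
  fa2 <- write_tmp_fasta(list(x = "ATGC", y = "GGGG"))
  expect_error(read_transcripts(fa2, ann), "y")

  # non-nucleotide characters are rejected with their position
  fa3 <- write_tmp_fasta(list(x = "ANGC"))
  expect_error(suppressMessages(read_transcripts(fa3, ann)), "position 2")
})

test_that("transcript constructor enforces region invariants", {
  expect_error(transcript("t", "AUGC", utr5_end = 3, cds_end = 2), "cds_end")
  expect_error(transcript("t", "", utr5_end = 0, cds_end = 0), "empty")
  tx <- transcript("t", "AAAUUUGGG", utr5_end = 3, cds_end = 9, capped = FALSE)
  expect_false(tx$capped)
})

test_that("aptamer libraries are validated on load", {
  lib <- load_aptamer_library()
  expect_s3_class(lib, "aptamer_library")
  expect_setequal(names(lib),
                  c("theophylline", "tetracycline", "eif4g", "beta_catenin",
                    "nfkb", "vegf", "opn"))
  expect_identical(lib$eif4g$role, "effector")
  expect_true(all(vapply(lib, function(a) a$binding_bonus > 0, logical(1))))
  # every reference structure is balanced and matches its sequence length
  for (a in lib) {
    expect_identical(nchar(a$reference_structure), nchar(a$sequence))
    expect_silent(dotbracket_to_pairs(a$reference_structure))
  }

  # unbalanced reference structure names the offending aptamer
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(list(id = "broken", ligand = "x",
                                 sequence = "GGGAAACCC",
                                 reference_structure = "(((...)).",
                                 stem = c(1, 3), role = "sensor",
                                 binding_bonus = 5)),
                       bad, auto_unbox = TRUE)
  expect_error(load_aptamer_library(bad), "broken")

  # duplicate ids rejected
  dup <- tempfile(fileext = ".json")
  entry <- list(id = "a", ligand = "x", sequence = "GGGAAACCC",
                reference_structure = "(((...)))", stem = c(1, 3),
                role = "sensor", binding_bonus = 5)
  jsonlite::write_json(list(entry, entry), dup, auto_unbox = TRUE)
  expect_error(load_aptamer_library(dup), "duplicate")

  # empty library loads with a warning
  empty <- tempfile(fileext = ".json")
  writeLines("[]", empty)
  expect_warning(out <- load_aptamer_library(empty), "empty")
  expect_length(out, 0L)
})

test_that("design reports round-trip and reject unscored designs", {
  lib <- test_library()
  d1 <- tiny_scored_repressor(lib)
  d2 <- tiny_scored_repressor(lib, window = c(30L, 49L))
  d2$id <- "tiny_rep2"
  tsv <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tsv, sub("\\.tsv$", ".fa", tsv))))

  paths <- write_design_report(list(d1, d2), tsv)
  tab <- utils::read.delim(tsv)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("exposedness", "preservation", "composite", "pass") %in%
                    names(tab)))

  # FASTA round-trip preserves device sequences exactly
  back <- Biostrings::readRNAStringSet(paths$fasta)
  expect_identical(as.character(back[["tiny_rep"]]), d1$full_sequence)

  # empty report: header only
  empty_tsv <- tempfile(fileext = ".tsv")
  write_design_report(list(), empty_tsv)
  expect_identical(nrow(utils::read.delim(empty_tsv)), 0L)

  # unscored designs are a precondition failure
  d3 <- assemble_repressor(strrep("A", 20), lib$theophylline, id = "noscore")
  expect_error(write_design_report(list(d3), tempfile()), "noscore")
})

test_that("reading a written FASTA changes nothing (idempotent normalisation)", {
  d <- tiny_scored_repressor()
  tsv <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tsv, sub("\\.tsv$", ".fa", tsv))))
  paths <- write_design_report(list(d), tsv)
  fa <- write_tmp_fasta(list(x = as.character(
    Biostrings::readRNAStringSet(paths$fasta)[[1L]])))
  ann <- write_tmp_annotation(data.frame(id = "x", utr5_end = 0,
                                         cds_end = nchar(d$full_sequence),
                                         capped = TRUE))
  tx <- read_transcripts(fa, ann)
  expect_identical(tx$x$sequence, d$full_sequence)
})
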