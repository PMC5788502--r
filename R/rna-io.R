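#' Transcript object
#'
#' A target mRNA with region annotation. Coordinates are 1-based and
#' inclusive throughout the package: `utr5_end` is the index of the last
#' 5'-UTR base (0 if there is no 5'-UTR) and `cds_end` the index of the
#' last CDS base, so `0 <= utr5_end <= cds_end <= nchar(sequence)`.
#' `capped` distinguishes the ordinary 5'-capped reporter from the
#' "uncapped" construct in which the reporter ORF sits downstream of a
#' primary ORF (the configuration used for recruitment-based activation).
#'
#' @param id Transcript identifier.
#' @param sequence RNA string (DNA-style input is normalised, `T -> U`).
#' @param utr5_end Last base of the 5'-UTR (0 = none).
#' @param cds_end Last base of the CDS.
#' @param capped Logical; is the mRNA 5'-capped?
#' @return An object of class `transcript`.
#' @export
transcript <- function(id, sequence, utr5_end, cds_end, capped = TRUE) {
  sequence <- normalize_rna(sequence, what = sprintf("sequence of '%s'", id))
  n <- nchar(sequence)
  utr5_end <- as.integer(utr5_end)
  cds_end <- as.integer(cds_end)
  if (is.na(utr5_end) || is.na(cds_end) ||
      utr5_end < 0L || utr5_end > cds_end || cds_end > n) {
    stop(sprintf(
      "invalid annotation for '%s': need 0 <= utr5_end (%s) <= cds_end (%s) <= length (%d)",
      id, utr5_end, cds_end, n), call. = FALSE)
  }
  structure(list(id = as.character(id), sequence = sequence,
                 utr5_end = utr5_end, cds_end = cds_end,
                 capped = isTRUE(as.logical(capped))),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("transcript '%s': %d nt, 5'UTR 1-%d, CDS %d-%d, %s\n",
              x$id, nchar(x$sequence), x$utr5_end, x$utr5_end + 1L,
              x$cds_end, if (x$capped) "capped" else "uncapped"))
  invisible(x)
}

#' Read target transcripts from FASTA plus a sidecar annotation table
#'
#' The FASTA carries the sequences (DNA or RNA; `T` is normalised to `U`
#' and a note is emitted once per file). The tab-separated annotation table
#' must have columns `id`, `utr5_end`, `cds_end`, `capped`; every FASTA
#' record must have exactly one annotation row.
#'
#' @param fasta_path Path to the FASTA file.
#' @param annotation_path Path to the annotation TSV.
#' @return List of [transcript()] objects.
#' @export
read_transcripts <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("id", "utr5_end", "cds_end", "capped")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann$id)) {
    stop("duplicate ids in annotation table: ",
         paste(unique(ann$id[duplicated(ann$id)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(ids, ann$id)
  if (length(missing)) {
    stop("no annotation row for record(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- unname(as.character(seqs))
  if (any(grepl("[tT]", raw))) {
    message("note: DNA-style input in '", basename(fasta_path),
            "' normalised to RNA (T -> U)")
  }
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    row <- ann[ann$id == ids[k], ]
    out[[k]] <- transcript(ids[k], raw[k], row$utr5_end, row$cds_end,
                           as.logical(row$capped))
  }
  names(out) <- ids
  out
}

#' Aptamer object
#'
#' A ligand-binding RNA module with its reference secondary structure and
#' the stem region used for antisense sequestration in switch designs.
#' `role` distinguishes sensor aptamers (detect a signal molecule or
#' protein) from effector aptamers (recruit translation machinery, e.g.
#' eIF4G). `binding_bonus` is the free-energy-like stabilisation credited
#' to the ligand-bound aptamer, in the same arbitrary units as the fold
#' score.
#'
#' @param id Identifier.
#' @param ligand Ligand name (e.g. "theophylline", "eIF4G").
#' @param sequence RNA string.
#' @param reference_structure Dot-bracket string of the same length.
#' @param stem Integer vector `c(start, end)` (1-based inclusive) of the
#'   stem region within the sequence.
#' @param role `"sensor"` or `"effector"`.
#' @param binding_bonus Positive score units added on ligand binding.
#' @return An object of class `aptamer`.
#' @export
aptamer <- function(id, ligand, sequence, reference_structure, stem,
                    role = c("sensor", "effector"), binding_bonus = 5) {
  role <- match.arg(role)
  sequence <- normalize_rna(sequence, what = sprintf("aptamer '%s'", id))
  n <- nchar(sequence)
  if (nchar(reference_structure) != n) {
    stop(sprintf("aptamer '%s': structure length %d != sequence length %d",
                 id, nchar(reference_structure), n), call. = FALSE)
  }
  ref_pairs <- dotbracket_to_pairs(reference_structure,
                                   what = sprintf("aptamer '%s'", id))
  stem <- as.integer(stem)
  if (length(stem) != 2L || stem[1L] < 1L || stem[2L] > n || stem[1L] > stem[2L]) {
    stop(sprintf("aptamer '%s': stem interval must lie within the sequence", id),
         call. = FALSE)
  }
  if (!is.numeric(binding_bonus) || binding_bonus <= 0) {
    stop(sprintf("aptamer '%s': binding_bonus must be > 0", id), call. = FALSE)
  }
  structure(list(id = as.character(id), ligand = as.character(ligand),
                 sequence = sequence,
                 reference_structure = reference_structure,
                 reference_pairs = ref_pairs,
                 stem = stem, role = role,
                 binding_bonus = as.numeric(binding_bonus)),
            class = "aptamer")
}

#' @export
print.aptamer <- function(x, ...) {
  cat(sprintf("aptamer '%s' (%s, %s): %d nt, stem %d-%d, bonus %.1f\n",
              x$id, x$ligand, x$role, nchar(x$sequence),
              x$stem[1L], x$stem[2L], x$binding_bonus))
  cat(" ", x$sequence, "\n ", x$reference_structure, "\n", sep = "")
  invisible(x)
}

# The sequence of the annotated stem region.
aptamer_stem_seq <- function(apt) substr(apt$sequence, apt$stem[1L], apt$stem[2L])

#' Load an aptamer library from JSON
#'
#' The JSON schema is an array of objects with fields `id`, `ligand`,
#' `sequence`, `reference_structure`, `stem` (two-element array, 1-based
#' inclusive), `role` and `binding_bonus`. All entries are validated on
#' load: balanced dot-bracket, stem inside the sequence, unique ids.
#'
#' @param json_path Path to the JSON file. The package ships a synthetic
#'   library at `system.file("extdata", "aptamer_library_synthetic.json",
#'   package = "sigcon")` (the default).
#' @return A named list of [aptamer()] objects, class `aptamer_library`.
#' @export
load_aptamer_library <- function(json_path = system.file(
    "extdata", "aptamer_library_synthetic.json", package = "sigcon")) {
  raw <- jsonlite::read_json(json_path)
  entries <- if (!is.null(raw$entries)) raw$entries else raw
  if (length(entries) == 0L) {
    warning("aptamer library '", basename(json_path), "' is empty")
    return(structure(list(), class = "aptamer_library"))
  }
  ids <- vapply(entries, function(e) as.character(e$id), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate aptamer id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- lapply(entries, function(e) {
    aptamer(id = e$id, ligand = e$ligand, sequence = e$sequence,
            reference_structure = e$reference_structure,
            stem = unlist(e$stem), role = e$role,
            binding_bonus = e$binding_bonus)
  })
  names(out) <- ids
  structure(out, class = "aptamer_library")
}

#' @export
print.aptamer_library <- function(x, ...) {
  cat(sprintf("aptamer library: %d entries\n", length(x)))
  for (a in x) {
    cat(sprintf("  %-22s %-14s %-8s %2d nt\n", a$id, a$ligand, a$role,
                nchar(a$sequence)))
  }
  invisible(x)
}

#' Write a design report (TSV + companion FASTA)
#'
#' One row per scored design: identity, topology, target window, antisense
#' sequence, the three selection scores, the composite and the pass flag.
#' A companion FASTA (same path with extension `.fa`) holds the full
#' device sequences. Unscored designs are a hard error.
#'
#' @param designs List of scored [connector_design] objects (may be empty).
#' @param path Output TSV path.
#' @return Invisibly, the paths written (`tsv`, `fasta`).
#' @export
write_design_report <- function(designs, path) {
  unscored <- vapply(designs, function(d) is.null(d$scores), logical(1))
  if (any(unscored)) {
    stop("design(s) lacking scores: ",
         paste(vapply(designs[unscored], `[[`, character(1), "id"),
               collapse = ", "),
         "; run score_design() first", call. = FALSE)
  }
  df <- design_report_table(designs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fasta <- paste0(tools::file_path_sans_ext(path), ".fa")
  seqs <- Biostrings::RNAStringSet(vapply(designs, `[[`, character(1),
                                          "full_sequence"))
  names(seqs) <- vapply(designs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, fasta)
  invisible(list(tsv = path, fasta = fasta))
}

# Flat summary table of scored designs.
design_report_table <- function(designs) {
  cols <- c("id", "topology", "target_id", "window_start", "window_end",
            "region", "antisense", "exposedness", "preservation",
            "position_prior", "composite", "pass")
  if (length(designs) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(df)
  }
  do.call(rbind, lapply(designs, function(d) {
    data.frame(id = d$id, topology = d$topology,
               target_id = if (is.null(d$target_id)) NA_character_ else d$target_id,
               window_start = if (is.null(d$window)) NA_integer_ else d$window[1L],
               window_end = if (is.null(d$window)) NA_integer_ else d$window[2L],
               region = if (is.null(d$region)) NA_character_ else d$region,
               antisense = d$antisense,
               exposedness = d$scores$exposedness,
               preservation = d$scores$preservation,
               position_prior = d$scores$position_prior,
               composite = d$scores$composite,
               pass = d$scores$pass,
               stringsAsFactors = FALSE)
  }))
}
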