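#' Fixture generation parameters
#'
#' Bundles the seed and composition parameters for deterministic fixture
#' generation. Every random choice in fixture construction flows through
#' this single seed.
#'
#' @param seed Integer RNG seed.
#' @param transcript_length Transcript length (nt).
#' @param utr5_length 5'-UTR length (nt), `< transcript_length`.
#' @param gc_content Fraction of G+C in random sequence, in \[0, 1\].
#' @param aptamer_stem_length Toy-aptamer stem length (bp, >= 3).
#' @param aptamer_loop_length Toy-aptamer loop length (nt, >= 3).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, transcript_length = 400L,
                         utr5_length = 60L, gc_content = 0.5,
                         aptamer_stem_length = 6L, aptamer_loop_length = 5L) {
  stopifnot(transcript_length > 0L, utr5_length > 0L,
            utr5_length < transcript_length,
            gc_content >= 0, gc_content <= 1,
            aptamer_stem_length >= 3L, aptamer_loop_length >= 3L)
  structure(list(seed = as.integer(seed),
                 transcript_length = as.integer(transcript_length),
                 utr5_length = as.integer(utr5_length),
                 gc_content = gc_content,
                 aptamer_stem_length = as.integer(aptamer_stem_length),
                 aptamer_loop_length = as.integer(aptamer_loop_length)),
            class = "fixture_spec")
}

random_rna <- function(n, gc_content) {
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, U = (1 - gc_content) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a reproducible pseudo-random transcript
#'
#' @param spec A [fixture_spec()].
#' @param id Transcript id.
#' @return A [transcript()] with `utr5_end = utr5_length` and
#'   `cds_end = transcript_length`. Same spec (seed) => identical output.
#' @export
generate_fixture_transcript <- function(spec, id = "fixture_tx") {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  transcript(id, random_rna(spec$transcript_length, spec$gc_content),
             utr5_end = spec$utr5_length, cds_end = spec$transcript_length)
}

#' Generate a toy hairpin aptamer
#'
#' A perfect hairpin: a G/C stem of the requested length around an
#' unreactive C-only loop, with reference structure
#' `"(" x stem + "." x loop + ")" x stem` and the 5' stem half recorded
#' as the stem interval. The G/C stem and C loop guarantee that the fold
#' engine recovers the reference stem and that the hairpin does not
#' cross-react with A/U-rich antisense domains.
#'
#' @param spec A [fixture_spec()].
#' @param id,ligand,role,binding_bonus Passed to [aptamer()].
#' @return An [aptamer()].
#' @export
generate_toy_aptamer <- function(spec, id = "toy_apt", ligand = "toy_ligand",
                                 role = "sensor", binding_bonus = 5) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  s <- spec$aptamer_stem_length
  l <- spec$aptamer_loop_length
  ref <- paste0(strrep("(", s), strrep(".", l), strrep(")", s))
  # resample (deterministically) until the fold engine recovers the
  # reference hairpin -- the generator's contract
  for (try in 1:100) {
    stem5 <- paste(sample(c("G", "C"), s, replace = TRUE), collapse = "")
    seqn <- paste0(stem5, strrep("C", l), reverse_complement(stem5))
    if (identical(fold(seqn)$dotbracket, ref)) break
  }
  aptamer(id, ligand, seqn, ref, stem = c(1L, s), role = role,
          binding_bonus = binding_bonus)
}

# ---- engineered demonstration target and device pool ---------------------

# Window layout of the demonstration target (1-based starts, width 20).
# Strong windows sit near the 5' end, weak ones deep in the CDS; window
# composition is low-complexity (poly-U or poly-A) so that the designed
# antisense domains stay unpaired in the max-pairing fold model, i.e. the
# pool emulates the outcome of the fold-and-select step.
DEMO_WINDOWS <- data.frame(
  name = c("s5", "s15", "s35", "s55", "w520", "w560", "w600", "w640"),
  start = c(5L, 15L, 35L, 55L, 520L, 560L, 600L, 640L),
  base = c("U", "U", "U", "A", "U", "U", "U", "U"),
  stringsAsFactors = FALSE)

#' Engineered demonstration target transcript
#'
#' A 760-nt synthetic reporter stand-in (5'-UTR 1-120, CDS 121-720) with
#' implanted low-complexity antisense windows: strong sites near the 5'
#' end (starts 5, 15, 35, 55) and weak sites deep in the CDS (520, 560,
#' 600, 640). The site at 55 is the sequence complement of the poly-U
#' sites, providing the complementary antisense pairs needed for XOR/XNOR
#' gates. Filler sequence is random with the given seed.
#'
#' @param seed Integer seed for the filler sequence.
#' @param capped Logical cap status of the construct.
#' @return A [transcript()].
#' @export
demo_target <- function(seed = 1L, capped = TRUE) {
  set.seed(seed)
  n <- 760L
  v <- rna_chars(random_rna(n, 0.5))
  for (k in seq_len(nrow(DEMO_WINDOWS))) {
    idx <- DEMO_WINDOWS$start[k]:(DEMO_WINDOWS$start[k] + 19L)
    v[idx] <- DEMO_WINDOWS$base[k]
  }
  transcript(if (capped) "rluc_capped" else "rluc_uncapped",
             paste(v, collapse = ""),
             utr5_end = 120L, cds_end = 720L, capped = capped)
}

demo_window_seq <- function(target, name) {
  w <- DEMO_WINDOWS[DEMO_WINDOWS$name == name, ]
  list(start = w$start, end = w$start + 19L,
       seq = substr(target$sequence, w$start, w$start + 19L),
       region = if (w$start <= 120L) "utr5" else "cds")
}

#' Seeded demonstration device pool
#'
#' Builds, scores and parameterises the standard pool of signal-connector
#' devices used by the gate simulations: strong and weak repressors and
#' ligand-gated (switch) activators sensing theophylline (logic-high 1000
#' uM, K = 300 uM) or tetracycline (logic-high 100 uM, K = 20 uM), on the
#' capped (repressors) and uncapped (activators) demonstration targets.
#' Strength classes arise from the 5'-distance prior of the target
#' windows. All randomness flows through `seed`.
#'
#' @param seed Integer seed.
#' @return List with `target_capped`, `target_uncapped`, `library`,
#'   `devices` (list of `list(design, params)` bundles) and `inputs`
#'   (logic-high map).
#' @export
demo_device_pool <- function(seed = 1L) {
  lib <- load_aptamer_library()
  capped <- demo_target(seed, capped = TRUE)
  uncapped <- demo_target(seed, capped = FALSE)

  par_rep <- list(theophylline = load_device_params("theophylline_repressor"),
                  tetracycline = load_device_params("tetracycline_repressor"))
  par_act <- list(theophylline = load_device_params("theophylline_switch_activator"),
                  tetracycline = load_device_params("tetracycline_switch_activator"))
  sensor_apt <- list(theophylline = lib$theophylline,
                     tetracycline = lib$tetracycline)

  layout <- data.frame(
    window = c("s5", "s35", "s15", "s55", "w520", "w560", "w600",
               "s5", "s35", "s15", "s55", "w520", "w560", "w640"),
    ligand = c("theophylline", "tetracycline", "theophylline", "tetracycline",
               "theophylline", "tetracycline", "theophylline",
               "theophylline", "tetracycline", "theophylline", "tetracycline",
               "theophylline", "tetracycline", "tetracycline"),
    topology = rep(c("repressor", "switch_activator"), each = 7L),
    stringsAsFactors = FALSE)

  devices <- vector("list", nrow(layout))
  for (k in seq_len(nrow(layout))) {
    lig <- layout$ligand[k]
    topo <- layout$topology[k]
    target <- if (topo == "repressor") capped else uncapped
    w <- demo_window_seq(target, layout$window[k])
    antisense <- reverse_complement(w$seq)
    id <- sprintf("%s_%s_%s", substr(topo, 1L, 3L), lig, layout$window[k])
    d <- if (topo == "repressor") {
      assemble_repressor(antisense, sensor_apt[[lig]], copies = 2L,
                         linker = "", id = id, target_id = target$id,
                         window = c(w$start, w$end), region = w$region)
    } else {
      assemble_switch_activator(make_switch_sensor(sensor_apt[[lig]], antisense),
                                antisense, lib$eif4g, copies = 2L,
                                linker = "", id = id, target_id = target$id,
                                window = c(w$start, w$end), region = w$region)
    }
    d$scores <- score_design(d, target)
    params <- if (topo == "repressor") par_rep[[lig]] else par_act[[lig]]
    devices[[k]] <- gate_device(d, params)
  }
  names(devices) <- vapply(devices, function(d) d$design$id, character(1))

  list(target_capped = capped, target_uncapped = uncapped, library = lib,
       devices = devices,
       inputs = c(theophylline = 1000, tetracycline = 100))
}

#' Demonstration network/classifier scenario inputs
#'
#' Deterministic designs for the pathway scenarios: a protein-sensing
#' repressor for the rewiring scenario, a ribozyme-flanked repressor for
#' the AND-gate cell classifier, and the four NF-kB-sensing devices (two
#' ligand-gated activators, two repressors) of the ON/OFF redirection
#' scenario.
#'
#' @param seed Integer seed.
#' @return List with `rewire` (design + params), `classifier` (design +
#'   params) and `redirect` (activators, repressors, params).
#' @export
demo_scenarios <- function(seed = 1L) {
  lib <- load_aptamer_library()
  target <- demo_target(seed, capped = TRUE)
  prot <- load_device_params("protein_sensor")
  theo <- load_device_params("theophylline_repressor")

  mk_rep <- function(sensor, window, id, target_id = NULL) {
    w <- demo_window_seq(target, window)
    d <- assemble_repressor(reverse_complement(w$seq), sensor, copies = 2L,
                            linker = "", id = id,
                            target_id = if (is.null(target_id)) target$id else target_id,
                            window = c(w$start, w$end), region = w$region)
    d$scores <- score_design(d, if (is.null(target_id)) target else NULL)
    d
  }
  mk_switch <- function(sensor, window, id, target_id) {
    w <- demo_window_seq(target, window)
    antisense <- reverse_complement(w$seq)
    d <- assemble_switch_activator(make_switch_sensor(sensor, antisense),
                                   antisense, lib$eif4g, copies = 2L,
                                   linker = "", id = id,
                                   target_id = target_id,
                                   window = c(w$start, w$end), region = w$region)
    d$scores <- score_design(d)
    d
  }

  rewire_design <- mk_rep(lib$beta_catenin, "s5", "rew_bcat_cmyc", "c-Myc")
  classifier <- mk_rep(lib$theophylline, "s5", "cls_theo_bcl2", "BCL2")
  classifier$ribozyme_flanked <- TRUE

  redirect <- list(
    activators = list(mk_switch(lib$nfkb, "s5", "red_nfkb_bax", "Bax"),
                      mk_switch(lib$nfkb, "s15", "red_nfkb_p21", "p21")),
    repressors = list(mk_rep(lib$nfkb, "s35", "red_nfkb_bcl2", "BCL2"),
                      mk_rep(lib$nfkb, "s55", "red_nfkb_cmyc", "c-Myc")),
    params = prot)

  list(rewire = list(design = rewire_design, params = prot),
       classifier = list(design = classifier, params = theo),
       redirect = redirect)
}

#' Write fixture files to a directory
#'
#' Emits a fixture transcript (FASTA + annotation TSV), the demonstration
#' targets, and a copy of the packaged aptamer library, for use from the
#' command line.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [fixture_spec()].
#' @return Invisibly, the named vector of paths written.
#' @export
write_fixtures <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- generate_fixture_transcript(spec)
  demo <- demo_target(spec$seed, capped = TRUE)
  seqs <- Biostrings::RNAStringSet(c(tx$sequence, demo$sequence))
  names(seqs) <- c(tx$id, demo$id)
  fasta <- file.path(dir, "transcripts.fa")
  Biostrings::writeXStringSet(seqs, fasta)
  ann <- data.frame(id = c(tx$id, demo$id),
                    utr5_end = c(tx$utr5_end, demo$utr5_end),
                    cds_end = c(tx$cds_end, demo$cds_end),
                    capped = c(tx$capped, demo$capped))
  ann_path <- file.path(dir, "transcripts.tsv")
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lib_src <- system.file("extdata", "aptamer_library_synthetic.json",
                         package = "sigcon")
  lib_path <- file.path(dir, "aptamer_library.json")
  file.copy(lib_src, lib_path, overwrite = TRUE)
  invisible(c(fasta = fasta, annotation = ann_path, library = lib_path))
}
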