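#' Enumerate antisense target windows on a transcript
#'
#' Slides a window of the given length across the requested region(s) of
#' the transcript (5'-UTR, CDS or both). All windows lie fully inside the
#' region; coordinates are 1-based inclusive and ascend by start.
#'
#' @param x A [transcript()].
#' @param region `"utr5"`, `"cds"` or `"both"`.
#' @param length Window length in nt (default 20, the standard antisense
#'   domain length).
#' @param step Step between window starts.
#' @return Data frame with columns `start`, `end`, `region` (possibly
#'   zero rows, with a warning, if the region is shorter than the window).
#' @export
enumerate_windows <- function(x, region = c("utr5", "cds", "both"),
                              length = 20L, step = 1L) {
  stopifnot(inherits(x, "transcript"))
  region <- match.arg(region)
  length <- as.integer(length)
  step <- as.integer(step)
  stopifnot(length >= 1L, step >= 1L)
  spans <- list()
  if (region %in% c("utr5", "both")) {
    spans$utr5 <- c(1L, x$utr5_end)
  }
  if (region %in% c("cds", "both")) {
    spans$cds <- c(x$utr5_end + 1L, x$cds_end)
  }
  out <- list()
  for (nm in names(spans)) {
    lo <- spans[[nm]][1L]; hi <- spans[[nm]][2L]
    if (hi - lo + 1L < length) {
      warning(sprintf("region '%s' of '%s' (span %d) is shorter than the window (%d)",
                      nm, x$id, max(0L, hi - lo + 1L), length))
      next
    }
    starts <- seq.int(lo, hi - length + 1L, by = step)
    out[[nm]] <- data.frame(start = starts, end = starts + length - 1L,
                            region = nm, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      region = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start), , drop = FALSE]
}

# ---- chimera assembly ----------------------------------------------------

# Internal: build full sequence + module coordinate table from an ordered
# list of (kind, id, seq) parts.
assemble_modules <- function(parts) {
  parts <- Filter(function(p) nchar(p$seq) > 0L, parts)
  pos <- 1L
  rows <- list()
  seqs <- character(length(parts))
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    w <- nchar(p$seq)
    rows[[k]] <- data.frame(kind = p$kind, id = p$id, start = pos,
                            end = pos + w - 1L, stringsAsFactors = FALSE)
    seqs[k] <- p$seq
    pos <- pos + w
  }
  list(full_sequence = paste(seqs, collapse = ""),
       modules = do.call(rbind, rows))
}

new_connector_design <- function(id, topology, antisense, parts, linker,
                                 sensor = NULL, effector = NULL, copies = NA_integer_,
                                 target_id = NULL, window = NULL, region = NULL,
                                 flags = character(0)) {
  asm <- assemble_modules(parts)
  structure(list(id = id, topology = topology, target_id = target_id,
                 window = window, region = region,
                 antisense = antisense, linker = linker,
                 sensor = sensor, effector = effector,
                 copies = as.integer(copies),
                 modules = asm$modules, full_sequence = asm$full_sequence,
                 flags = flags, ribozyme_flanked = FALSE, scores = NULL),
            class = "connector_design")
}

#' @export
print.connector_design <- function(x, ...) {
  cat(sprintf("connector design '%s' (%s): %d nt\n", x$id, x$topology,
              nchar(x$full_sequence)))
  if (!is.null(x$target_id)) {
    cat(sprintf("  target %s window %d-%d (%s)\n", x$target_id,
                x$window[1L], x$window[2L],
                if (is.null(x$region)) "?" else x$region))
  }
  cat(sprintf("  modules: %s\n",
              paste(sprintf("%s[%d-%d]", x$modules$id, x$modules$start,
                            x$modules$end), collapse = " + ")))
  if (!is.null(x$scores)) {
    cat(sprintf("  exposedness %.3f, preservation %.3f, prior %.3f, composite %.3f (%s)\n",
                x$scores$exposedness, x$scores$preservation,
                x$scores$position_prior, x$scores$composite,
                if (x$scores$pass) "pass" else "fail"))
  }
  invisible(x)
}

check_copies <- function(copies) {
  if (!copies %in% 1:3) {
    stop("copies must be 1, 2 or 3 (valencies beyond 3 are out of scope)",
         call. = FALSE)
  }
  as.integer(copies)
}

#' Assemble a repressor signal-connector
#'
#' Repressor topology: a 20-nt antisense domain followed by `copies`
#' sensor-aptamer modules separated by linkers. The ligand-aptamer complex
#' acts as a roadblock to ribosome scanning (5'-UTR targets) or elongation
#' (CDS targets).
#'
#' @param antisense Antisense RNA string (reverse complement of the target
#'   window).
#' @param sensor A sensor-role [aptamer()].
#' @param copies Number of aptamer copies (1-3; default 2).
#' @param linker Optional spacer placed before each aptamer module
#'   (default: direct fusion, the least-interfering choice under the
#'   pairing model).
#' @param id Design identifier.
#' @param target_id,window,region Optional provenance of the antisense
#'   window on the target (1-based inclusive `c(start, end)`).
#' @return A `connector_design` of topology `"repressor"`.
#' @export
assemble_repressor <- function(antisense, sensor, copies = 2L, linker = "",
                               id = NULL, target_id = NULL, window = NULL,
                               region = NULL) {
  copies <- check_copies(copies)
  stopifnot(inherits(sensor, "aptamer"))
  if (sensor$role != "sensor") {
    stop("repressor topology requires a sensor-role aptamer", call. = FALSE)
  }
  antisense <- normalize_rna(antisense, "antisense")
  if (nchar(linker) > 0L) linker <- normalize_rna(linker, "linker")
  if (is.null(id)) id <- sprintf("rep_%s_%dx", sensor$ligand, copies)
  parts <- c(list(list(kind = "antisense", id = "antisense", seq = antisense)),
             unlist(lapply(seq_len(copies), function(i) list(
               list(kind = "linker", id = sprintf("linker%d", i), seq = linker),
               list(kind = "aptamer", id = sensor$id, seq = sensor$sequence))),
               recursive = FALSE))
  new_connector_design(id, "repressor", antisense, parts, linker,
                       sensor = sensor, copies = copies, target_id = target_id,
                       window = window, region = region)
}

#' Assemble an activator signal-connector
#'
#' Activator topology: antisense domain plus `copies` effector (eIF4G)
#' aptamer modules. Tethering eIF4G to the target mRNA promotes formation
#' of initiation complexes and enhances translation. A single effector
#' copy is accepted but flagged `"reduced-efficacy"`: removing one copy
#' from the two-copy design dramatically decreases activation, while a
#' third adds little.
#'
#' @inheritParams assemble_repressor
#' @param effector An effector-role [aptamer()] (eIF4G-like).
#' @return A `connector_design` of topology `"activator"`.
#' @export
assemble_activator <- function(antisense, effector, copies = 2L, linker = "",
                               id = NULL, target_id = NULL, window = NULL,
                               region = NULL) {
  copies <- check_copies(copies)
  stopifnot(inherits(effector, "aptamer"))
  if (effector$role != "effector") {
    stop("activator topology requires an effector-role aptamer (e.g. eIF4G)",
         call. = FALSE)
  }
  antisense <- normalize_rna(antisense, "antisense")
  if (nchar(linker) > 0L) linker <- normalize_rna(linker, "linker")
  if (is.null(id)) id <- sprintf("act_%s_%dx", effector$ligand, copies)
  parts <- c(list(list(kind = "antisense", id = "antisense", seq = antisense)),
             unlist(lapply(seq_len(copies), function(i) list(
               list(kind = "linker", id = sprintf("linker%d", i), seq = linker),
               list(kind = "aptamer", id = effector$id, seq = effector$sequence))),
               recursive = FALSE))
  flags <- if (copies == 1L) "reduced-efficacy" else character(0)
  new_connector_design(id, "activator", antisense, parts, linker,
                       effector = effector, copies = copies,
                       target_id = target_id, window = window, region = region,
                       flags = flags)
}

# Best antiparallel placement of the stem against the antisense: returns the
# offset (0-based shift into the antisense), the number of complementary
# positions, and the mismatching stem positions at that placement.
stem_complementarity <- function(antisense, stem_seq) {
  va <- rna_chars(antisense)
  vs <- rna_chars(stem_seq)
  ls <- length(vs)
  if (length(va) < ls) {
    return(list(offset = 0L, matches = 0L, mismatches = seq_len(ls)))
  }
  best <- list(offset = 0L, matches = -1L, mismatches = integer(0))
  for (off in 0:(length(va) - ls)) {
    # stem 5'->3' pairs the antisense 3'->5' within the placed window
    win <- rev(va[(off + 1L):(off + ls)])
    ok <- is_wc_pair(vs, win)
    if (sum(ok) > best$matches) {
      best <- list(offset = off, matches = sum(ok), mismatches = which(!ok))
    }
  }
  best
}

#' Assemble a ligand-gated switch activator
#'
#' Sequestration-switch topology: a sensor aptamer whose stem is
#' complementary to the antisense domain, followed by the antisense and
#' `copies` effector (eIF4G) aptamer modules. Without ligand the antisense
#' is base-paired to the sensor stem and the device is inert; ligand
#' binding stabilises the aptamer fold, frees the antisense and lets the
#' device engage its target. The OFF-state sequestration is verified at
#' build time with [evaluate_switch()].
#'
#' @param sensor Sensor [aptamer()] whose stem sequesters the antisense.
#' @inheritParams assemble_repressor
#' @param effector Effector-role [aptamer()].
#' @return A `connector_design` of topology `"switch_activator"`.
#' @export
assemble_switch_activator <- function(sensor, antisense, effector, copies = 2L,
                                      linker = "", id = NULL,
                                      target_id = NULL, window = NULL,
                                      region = NULL) {
  copies <- check_copies(copies)
  stopifnot(inherits(sensor, "aptamer"), inherits(effector, "aptamer"))
  if (sensor$role != "sensor") stop("'sensor' must be a sensor-role aptamer",
                                    call. = FALSE)
  if (effector$role != "effector") {
    stop("'effector' must be an effector-role aptamer", call. = FALSE)
  }
  antisense <- normalize_rna(antisense, "antisense")
  if (nchar(linker) > 0L) linker <- normalize_rna(linker, "linker")
  stem_seq <- aptamer_stem_seq(sensor)
  comp <- stem_complementarity(antisense, stem_seq)
  if (length(comp$mismatches) > 0L) {
    stop(sprintf(
      "antisense is not complementary to the sensor stem: %d mismatch(es) at stem position(s) %s",
      length(comp$mismatches), paste(comp$mismatches, collapse = ", ")),
      call. = FALSE)
  }
  if (is.null(id)) id <- sprintf("sw_%s_%s_%dx", sensor$ligand, effector$ligand,
                                 copies)
  parts <- c(list(list(kind = "aptamer", id = sensor$id, seq = sensor$sequence),
                  list(kind = "linker", id = "linker0", seq = linker),
                  list(kind = "antisense", id = "antisense", seq = antisense)),
             unlist(lapply(seq_len(copies), function(i) list(
               list(kind = "linker", id = sprintf("linker%d", i), seq = linker),
               list(kind = "aptamer", id = effector$id, seq = effector$sequence))),
               recursive = FALSE))
  d <- new_connector_design(id, "switch_activator", antisense, parts, linker,
                            sensor = sensor, effector = effector,
                            copies = copies, target_id = target_id,
                            window = window, region = region)
  st <- evaluate_switch(d, ligand_present = FALSE)
  if (st$state != "OFF") {
    warning(sprintf("switch '%s' is leaky: ON without ligand (on %.2f vs off %.2f)",
                    id, st$on_score, st$off_score))
  }
  d
}

# Module coordinate helpers -------------------------------------------------

antisense_span <- function(design) {
  m <- design$modules[design$modules$kind == "antisense", ][1L, ]
  c(m$start, m$end)
}

aptamer_modules <- function(design) {
  design$modules[design$modules$kind == "aptamer", , drop = FALSE]
}

sensor_module_span <- function(design) {
  m <- design$modules
  row <- m[m$kind == "aptamer" & m$id == design$sensor$id, ][1L, ]
  c(row$start, row$end)
}

#' 5'-distance efficacy prior
#'
#' Both repression and activation efficacy fall off with the distance of
#' the target window from the 5' end of the mRNA (early interception of
#' scanning ribosomes is most effective). The prior is the simplest
#' strictly decreasing positive form, `exp(-(start - 1) / lambda)`: 1 for
#' a window starting at the first base, `1/e` at a distance of `lambda`
#' nt.
#'
#' @param window_start 1-based start of the target window.
#' @param x The target [transcript()] (used for range checking).
#' @param lambda Decay length in nt (default 300).
#' @return Efficacy prior in (0, 1].
#' @export
position_prior <- function(window_start, x = NULL, lambda = 300) {
  stopifnot(all(window_start >= 1L))
  if (!is.null(x)) stopifnot(inherits(x, "transcript"),
                             all(window_start <= nchar(x$sequence)))
  exp(-(window_start - 1) / lambda)
}

#' Score a signal-connector design
#'
#' Folds the assembled chimera with the package fold engine and computes
#' the two structural selection criteria plus the positional prior:
#'
#' * **exposedness** -- fraction of antisense nucleotides left unpaired in
#'   the folded chimera (the antisense must stay available to invade the
#'   target). For repressors and activators this is the ligand-free fold;
#'   for switch designs the ON state is scored, approximated by folding
#'   with the ligand-occupied sensor aptamer excluded from pairing.
#' * **preservation** -- fraction of each aptamer's reference base pairs
#'   reproduced (shifted by the module offset) in the chimera fold,
#'   averaged over aptamer copies. The occupied sensor of a switch design
#'   counts as fully preserved since its fold is enforced by the ligand.
#' * **position_prior** -- [position_prior()] of the target window (1 when
#'   the design has no window annotation).
#'
#' The composite score is the product of the three factors; a design
#' passes when exposedness and preservation both reach their thresholds.
#'
#' @param design A `connector_design`.
#' @param target Optional target [transcript()]; when given together with
#'   a window annotation, the antisense is checked to be the exact reverse
#'   complement of the window.
#' @param library Optional [load_aptamer_library()] result providing
#'   reference structures for aptamer ids not embedded in the design.
#' @param tau_e,tau_p Pass thresholds for exposedness and preservation.
#' @param lambda Positional decay length, see [position_prior()].
#' @return A `structure_score`: list with `exposedness`, `preservation`,
#'   `position_prior`, `composite`, `pass`.
#' @export
score_design <- function(design, target = NULL, library = NULL,
                         tau_e = 0.8, tau_p = 0.8, lambda = 300) {
  stopifnot(inherits(design, "connector_design"))
  if (!is.null(target) && !is.null(design$window)) {
    win_seq <- substr(target$sequence, design$window[1L], design$window[2L])
    if (reverse_complement(win_seq) != design$antisense) {
      stop(sprintf("design '%s': antisense is not the reverse complement of window %d-%d on '%s'",
                   design$id, design$window[1L], design$window[2L], target$id),
           call. = FALSE)
    }
  }
  constraints <- integer(0)
  if (design$topology == "switch_activator") {
    sp <- sensor_module_span(design)
    constraints <- sp[1L]:sp[2L]
  }
  fold_res <- fold(design$full_sequence, constraints = constraints)
  partner <- pair_partner_map(fold_res)

  as_span <- antisense_span(design)
  as_idx <- as_span[1L]:as_span[2L]
  exposedness <- mean(is.na(partner[as_idx]))

  mods <- aptamer_modules(design)
  pres <- numeric(0)
  pair_key <- if (NROW(fold_res$pairs)) {
    paste(fold_res$pairs[, 1L], fold_res$pairs[, 2L])
  } else character(0)
  for (k in seq_len(nrow(mods))) {
    apt <- lookup_aptamer(design, mods$id[k], library)
    if (design$topology == "switch_activator" && mods$id[k] == design$sensor$id) {
      pres <- c(pres, 1)   # ligand-occupied sensor: fold enforced
      next
    }
    ref <- apt$reference_pairs
    if (NROW(ref) == 0L) { pres <- c(pres, 1); next }
    off <- mods$start[k] - 1L
    shifted <- paste(ref[, 1L] + off, ref[, 2L] + off)
    pres <- c(pres, mean(shifted %in% pair_key))
  }
  preservation <- if (length(pres)) mean(pres) else 1

  prior <- if (is.null(design$window)) 1 else
    position_prior(design$window[1L], target, lambda = lambda)

  score <- structure(list(exposedness = exposedness,
                          preservation = preservation,
                          position_prior = prior,
                          composite = exposedness * preservation * prior,
                          pass = exposedness >= tau_e && preservation >= tau_p),
                     class = "structure_score")
  score
}

lookup_aptamer <- function(design, id, library) {
  for (slot in c("sensor", "effector")) {
    a <- design[[slot]]
    if (!is.null(a) && a$id == id) return(a)
  }
  if (!is.null(library) && id %in% names(library)) return(library[[id]])
  stop(sprintf("no reference structure available for aptamer '%s'", id),
       call. = FALSE)
}

#' Score a list of designs in place
#'
#' Convenience wrapper over [score_design()] that stores each score in the
#' design's `scores` field.
#'
#' @inheritParams score_design
#' @param designs List of `connector_design` objects.
#' @return The list with `scores` filled in.
#' @export
score_designs <- function(designs, target = NULL, library = NULL,
                          tau_e = 0.8, tau_p = 0.8, lambda = 300) {
  lapply(designs, function(d) {
    d$scores <- score_design(d, target, library, tau_e, tau_p, lambda)
    d
  })
}

#' Rank scored designs
#'
#' Drops designs failing the exposedness/preservation thresholds and
#' orders the rest by composite score (descending), breaking ties by
#' smaller window start, then id. Pure function of the stored scores.
#'
#' @param designs List of scored `connector_design` objects.
#' @param tau_e,tau_p Selection thresholds re-applied to the stored
#'   exposedness/preservation values.
#' @return The ordered sublist of passing designs.
#' @export
rank_designs <- function(designs, tau_e = 0.8, tau_p = 0.8) {
  unscored <- vapply(designs, function(d) is.null(d$scores), logical(1))
  if (any(unscored)) stop("all designs must be scored before ranking",
                          call. = FALSE)
  keep <- vapply(designs, function(d) {
    d$scores$exposedness >= tau_e && d$scores$preservation >= tau_p
  }, logical(1))
  kept <- designs[keep]
  if (length(kept) == 0L) return(kept)
  comp <- vapply(kept, function(d) d$scores$composite, numeric(1))
  ws <- vapply(kept, function(d) {
    if (is.null(d$window)) .Machine$integer.max else d$window[1L]
  }, numeric(1))
  ids <- vapply(kept, `[[`, character(1), "id")
  kept[order(-comp, ws, ids)]
}

#' Evaluate the two-state logic of a sequestration switch
#'
#' Compares the stability of the two mutually exclusive conformations of a
#' switch design:
#'
#' * **OFF (sequestered)** -- the antisense domain is base-paired to the
#'   sensor stem, disrupting the aptamer fold. Its score is the
#'   antisense:stem duplex score plus the fold score of the rest of the
#'   chimera.
#' * **ON (aptamer formed)** -- the sensor aptamer adopts its reference
#'   fold and the antisense is free. Its score is the aptamer reference
#'   score plus the same rest-fold, plus `binding_bonus` when the ligand
#'   is present.
#'
#' Both conformations share the rest-of-chimera fold (computed once with
#' the antisense and sensor excluded from pairing), so the comparison
#' isolates the duplex-versus-aptamer competition that the ligand decides.
#' The state is `"ON"` iff `on_score > off_score`; a tie is OFF, so a
#' perfectly complementary switch rests OFF without ligand and any
#' positive binding bonus flips it ON.
#'
#' @param design A `connector_design` of topology `"switch_activator"`.
#' @param ligand_present Logical.
#' @return A `switch_state`: list with `off_score`, `on_score`, `state`.
#' @export
evaluate_switch <- function(design, ligand_present) {
  stopifnot(inherits(design, "connector_design"))
  if (design$topology != "switch_activator") {
    stop("evaluate_switch() requires a switch_activator design", call. = FALSE)
  }
  sensor <- design$sensor
  W <- pair_weight_matrix()
  v <- rna_chars(design$full_sequence)

  sp <- sensor_module_span(design)
  as_span <- antisense_span(design)
  frozen <- c(sp[1L]:sp[2L], as_span[1L]:as_span[2L])
  base <- fold(design$full_sequence, constraints = frozen)$score

  # duplex: stem 5'->3' against the best antiparallel antisense placement
  stem_seq <- aptamer_stem_seq(sensor)
  comp <- stem_complementarity(design$antisense, stem_seq)
  vs <- rna_chars(stem_seq)
  va <- rna_chars(design$antisense)
  win <- rev(va[(comp$offset + 1L):(comp$offset + length(vs))])
  duplex <- sum(W[cbind(vs, win)])

  ref_score <- score_pairs(rna_chars(sensor$sequence), sensor$reference_pairs, W)

  off_score <- base + duplex
  on_score <- base + ref_score + if (isTRUE(ligand_present)) sensor$binding_bonus else 0
  structure(list(off_score = off_score, on_score = on_score,
                 state = if (on_score > off_score) "ON" else "OFF"),
            class = "switch_state")
}

#' @export
print.switch_state <- function(x, ...) {
  cat(sprintf("switch state: %s (on %.2f vs off %.2f)\n",
              x$state, x$on_score, x$off_score))
  invisible(x)
}

#' Derive a design-matched switch sensor aptamer
#'
#' For a sequestration switch the sensor stem must be complementary to the
#' design's antisense domain, so the stem is engineered per design: the 5'
#' stem half is the reverse complement of the leading `stem_len` antisense
#' nucleotides, the 3' half closes the hairpin, and the ligand identity
#' and binding bonus are inherited from the base aptamer.
#'
#' @param base A sensor [aptamer()] providing ligand identity and bonus.
#' @param antisense The design's antisense domain.
#' @param stem_len Stem length in bp (default 6).
#' @param loop Loop sequence (default `"CCCCC"`).
#' @return A new sensor [aptamer()] whose stem sequesters the antisense.
#' @export
make_switch_sensor <- function(base, antisense, stem_len = 6L, loop = "CCCCC") {
  stopifnot(inherits(base, "aptamer"), base$role == "sensor")
  antisense <- normalize_rna(antisense, "antisense")
  stem_len <- as.integer(stem_len)
  stopifnot(stem_len >= 3L, nchar(antisense) >= stem_len)
  stem3 <- substr(antisense, 1L, stem_len)
  stem5 <- reverse_complement(stem3)
  seqn <- paste0(stem5, loop, stem3)
  ref <- paste0(strrep("(", stem_len), strrep(".", nchar(loop)),
                strrep(")", stem_len))
  aptamer(id = paste0(base$id, "_sw"), ligand = base$ligand, sequence = seqn,
          reference_structure = ref, stem = c(1L, stem_len), role = "sensor",
          binding_bonus = base$binding_bonus)
}
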