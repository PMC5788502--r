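#' Mutual-sequestration factor between two devices
#'
#' Two signal-connectors whose antisense domains are complementary form an
#' intermolecular duplex that inactivates both ("annihilation"). The
#' interaction is modelled all-or-none: if the antiparallel Watson-Crick
#' complementarity between the two antisense domains reaches the
#' threshold (default 16 of 20 nt), the factor is 0 (both devices inert);
#' otherwise 1 (no interaction).
#'
#' @param d1,d2 `connector_design` objects.
#' @param threshold Minimum number of complementary positions.
#' @return 0 or 1.
#' @export
annihilate <- function(d1, d2, threshold = 16L) {
  stopifnot(inherits(d1, "connector_design"), inherits(d2, "connector_design"))
  m <- antiparallel_matches(d1$antisense, d2$antisense)
  if (m >= threshold) 0 else 1
}

#' Digitise an analog reporter level
#'
#' Threshold at the midpoint of the calibrated ON and OFF reporter
#' levels; values at the midpoint digitise to 1.
#'
#' @param analog Analog output level(s).
#' @param on_level,off_level Calibrated reporter levels (`on_level >
#'   off_level` required).
#' @return Integer bit(s).
#' @export
digitize <- function(analog, on_level, off_level) {
  if (!(on_level > off_level)) {
    stop("on_level must be strictly greater than off_level", call. = FALSE)
  }
  as.integer(analog >= (on_level + off_level) / 2)
}

# Device bundles: a scored design plus its regulation parameters.
gate_device <- function(design, params) {
  stopifnot(inherits(design, "connector_design"),
            inherits(params, "regulation_params"))
  if (is.null(design$scores)) stop("gate devices must be scored", call. = FALSE)
  list(design = design, params = params)
}

device_ligand <- function(dev) dev$design$sensor$ligand
device_efficacy <- function(dev) dev$design$scores$composite

# Full-occupancy single-device effect used for recipe checks and ON/OFF
# calibration.
device_full_effect <- function(dev, high) {
  th <- occupancy(high, dev$params)
  if (dev$design$topology == "repressor") {
    repression_output(device_efficacy(dev), dev$design$copies, high, dev$params)
  } else {
    activation_output(device_efficacy(dev), dev$design$copies, th, dev$params)
  }
}

GATE_TYPES <- c("NOT", "AND", "NAND", "OR", "NOR", "XOR", "XNOR")

#' Build a logic-gate circuit from a device pool
#'
#' Selects devices from a ranked pool of scored signal-connectors
#' according to the recipe of the requested gate and calibrates the
#' digitisation levels:
#'
#' * **NOT** (1 input): one strong repressor; output high only without
#'   ligand.
#' * **NOR**: one strong repressor per input ligand, antisense domains
#'   non-complementary.
#' * **NAND**: one functionally weak repressor per ligand; each alone
#'   leaves expression near baseline, together they repress
#'   synergistically.
#' * **AND**: one functionally weak ligand-gated activator per ligand;
#'   each alone barely activates, together they activate synergistically.
#' * **OR**: one strong ligand-gated activator per ligand,
#'   non-complementary.
#' * **XOR**: two strong ligand-gated activators with complementary
#'   antisense domains: either alone activates, both together annihilate.
#' * **XNOR**: two strong repressors with complementary antisense
#'   domains: either alone represses, both together annihilate.
#'
#' A device is *functionally strong* when its single-device
#' full-occupancy effect crosses the significance bound (fold >=
#' `strong_fold_min` for activators, relative expression <=
#' `strong_rep_max` for repressors), and *functionally weak* when it
#' stays within the weak bound (fold <= `weak_fold_max`, expression >=
#' `weak_rep_min`). Pools that cannot supply the required class raise an
#' error naming the missing class; in particular an AND gate cannot be
#' built from individually strong activators.
#'
#' @param gate_type One of `"NOT"`, `"AND"`, `"NAND"`, `"OR"`, `"NOR"`,
#'   `"XOR"`, `"XNOR"`.
#' @param device_pool List of devices, each `list(design =
#'   <scored connector_design>, params = <regulation_params>)`.
#' @param inputs Named vector mapping ligand to its logic-high
#'   concentration (uM). NOT gates use the first entry only.
#' @param reporter_mode `"capped"` (repressor gates) or `"uncapped"`
#'   (recruitment-activation gates); defaults to the recipe's mode.
#' @param synergy Synergy exponent applied to the combined effect of
#'   co-bound devices of the same arm (default 2).
#' @param annihilation_threshold Complementarity threshold passed to
#'   [annihilate()].
#' @param weak_fold_max,strong_fold_min,weak_rep_min,strong_rep_max
#'   Functional class bounds (see above).
#' @return A `circuit_spec`.
#' @export
build_gate <- function(gate_type, device_pool,
                       inputs = c(theophylline = 1000, tetracycline = 100),
                       reporter_mode = NULL, synergy = 2,
                       annihilation_threshold = 16L,
                       weak_fold_max = 4, strong_fold_min = 6,
                       weak_rep_min = 0.7, strong_rep_max = 0.5) {
  gate_type <- match.arg(toupper(gate_type), GATE_TYPES)
  stopifnot(length(inputs) >= 1L, !is.null(names(inputs)))
  if (anyDuplicated(names(inputs))) stop("input ligands must be distinct",
                                         call. = FALSE)
  if (gate_type == "NOT") inputs <- inputs[1L] else inputs <- inputs[1:2]

  topo_needed <- if (gate_type %in% c("NOT", "NOR", "NAND", "XNOR")) {
    "repressor"
  } else {
    "switch_activator"
  }
  default_mode <- if (topo_needed == "repressor") "capped" else "uncapped"
  if (is.null(reporter_mode)) reporter_mode <- default_mode
  if (reporter_mode != default_mode) {
    stop(sprintf("%s gates use the %s reporter construct", gate_type,
                 default_mode), call. = FALSE)
  }

  class_of <- function(dev, high) {
    eff <- device_full_effect(dev, high)
    if (dev$design$topology == "repressor") {
      if (eff <= strong_rep_max) "strong" else if (eff >= weak_rep_min) "weak"
      else "intermediate"
    } else {
      if (eff >= strong_fold_min) "strong" else if (eff <= weak_fold_max) "weak"
      else "intermediate"
    }
  }

  # candidate devices per ligand, by topology + functional class,
  # strongest-composite first
  candidates <- function(ligand, want_class) {
    sel <- Filter(function(dev) {
      dev$design$topology == topo_needed &&
        device_ligand(dev) == ligand &&
        class_of(dev, inputs[[ligand]]) == want_class
    }, device_pool)
    sel[order(-vapply(sel, device_efficacy, numeric(1)))]
  }

  want <- if (gate_type %in% c("NAND", "AND")) "weak" else "strong"
  picked <- list()
  for (lig in names(inputs)) {
    cand <- candidates(lig, want)
    if (gate_type %in% c("XOR", "XNOR") && length(picked) == 1L) {
      # second device must annihilate the first
      cand <- Filter(function(dev) {
        annihilate(picked[[1L]]$design, dev$design,
                   annihilation_threshold) == 0
      }, cand)
      if (length(cand) == 0L) {
        stop(sprintf(
          "cannot build %s: no %s %s sensing %s with antisense complementary to '%s'",
          gate_type, want, topo_needed, lig, picked[[1L]]$design$id),
          call. = FALSE)
      }
    } else if (gate_type %in% c("NOR", "OR") && length(picked) == 1L) {
      cand <- Filter(function(dev) {
        annihilate(picked[[1L]]$design, dev$design,
                   annihilation_threshold) == 1
      }, cand)
    }
    if (length(cand) == 0L) {
      stop(sprintf("cannot build %s: no %s %s sensing %s in the pool",
                   gate_type, want, topo_needed, lig), call. = FALSE)
    }
    picked[[lig]] <- cand[[1L]]
  }

  # calibrated ON/OFF reporter levels
  full <- vapply(names(inputs),
                 function(lig) device_full_effect(picked[[lig]], inputs[[lig]]),
                 numeric(1))
  levels <- switch(gate_type,
    NOT = c(on = 1, off = full[[1L]]),
    NOR = ,
    XNOR = c(on = 1, off = max(full)),
    NAND = c(on = 1, off = prod(full)^synergy),
    AND = c(on = prod(full)^synergy, off = 1),
    OR = ,
    XOR = c(on = min(full), off = 1))

  structure(list(gate_type = gate_type, devices = picked, inputs = inputs,
                 reporter_mode = reporter_mode,
                 on_level = unname(levels["on"]),
                 off_level = unname(levels["off"]),
                 synergy = synergy,
                 annihilation_threshold = annihilation_threshold),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf("%s gate (%s reporter): inputs %s\n", x$gate_type,
              x$reporter_mode,
              paste(sprintf("%s@%g uM", names(x$inputs), x$inputs),
                    collapse = ", ")))
  for (lig in names(x$devices)) {
    cat(sprintf("  %s -> %s (composite %.3f)\n", lig,
                x$devices[[lig]]$design$id,
                device_efficacy(x$devices[[lig]])))
  }
  cat(sprintf("  on/off levels %.3g / %.3g, synergy %g\n",
              x$on_level, x$off_level, x$synergy))
  invisible(x)
}

#' Simulate a gate truth table
#'
#' Evaluates the reporter output for every combination of logic inputs.
#' For each row, sensor occupancies are computed from the logic-high
#' concentrations; ligand-bound complementary device pairs annihilate
#' each other; repressors multiply relative-expression factors and
#' activators multiply fold terms, with the synergy exponent applied when
#' two or more devices of the same arm are co-bound; the analog output is
#' digitised against the calibrated midpoint.
#'
#' @param spec A `circuit_spec` from [build_gate()].
#' @return A `truth_table`: data frame with one column per input ligand
#'   (bits), `analog` and `digital`.
#' @export
simulate_gate <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  ligs <- names(spec$inputs)
  nd <- length(spec$devices)
  grid <- expand.grid(rep(list(0:1), length(ligs)), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- ligs
  grid <- grid[do.call(order, grid), , drop = FALSE]  # 00, 01, 10, 11
  rownames(grid) <- NULL

  analog <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    L <- spec$inputs * as.numeric(grid[r, ligs])
    dev_L <- vapply(spec$devices, function(d) L[[device_ligand(d)]], numeric(1))
    theta <- vapply(seq_len(nd), function(k) {
      occupancy(dev_L[k], spec$devices[[k]]$params)
    }, numeric(1))
    bound <- theta >= 0.5
    eff <- vapply(spec$devices, device_efficacy, numeric(1))

    # ligand-bound complementary pairs sequester each other
    if (nd >= 2L) {
      for (a in 1:(nd - 1L)) for (b in (a + 1L):nd) {
        if (bound[a] && bound[b] &&
            annihilate(spec$devices[[a]]$design, spec$devices[[b]]$design,
                       spec$annihilation_threshold) == 0) {
          eff[a] <- 0
          eff[b] <- 0
        }
      }
    }

    E <- 1; A <- 1; n_rep <- 0L; n_act <- 0L
    for (k in seq_len(nd)) {
      dev <- spec$devices[[k]]
      if (dev$design$topology == "repressor") {
        E <- E * repression_output(eff[k], dev$design$copies, dev_L[k],
                                   dev$params)
        if (bound[k] && eff[k] > 0) n_rep <- n_rep + 1L
      } else {
        A <- A * activation_output(eff[k], dev$design$copies, theta[k],
                                   dev$params)
        if (bound[k] && eff[k] > 0) n_act <- n_act + 1L
      }
    }
    if (n_rep >= 2L) E <- E^spec$synergy
    if (n_act >= 2L) A <- A^spec$synergy
    analog[r] <- E * A
  }
  out <- cbind(grid,
               data.frame(analog = analog,
                          digital = digitize(analog, spec$on_level,
                                             spec$off_level)))
  class(out) <- c("truth_table", "data.frame")
  out
}

#' @export
print.truth_table <- function(x, ...) {
  print.data.frame(x, digits = 4)
  invisible(x)
}

# ---- network simulation --------------------------------------------------

#' Define a connector-regulated gene network
#'
#' Species follow production/decay kinetics; connector-mediated edges
#' modulate the *translational* production of their target in response to
#' the concentration of a sensor species.
#'
#' @param species Data frame with columns `name`, `production`, `decay`,
#'   `init` (all rates > 0).
#' @param edges List of edges, each `list(sensor =, target =, sign =
#'   "activate"|"repress", params = <regulation_params>, efficacy =,
#'   copies =)`.
#' @return A `network_model`.
#' @export
network_model <- function(species, edges = list()) {
  stopifnot(is.data.frame(species),
            all(c("name", "production", "decay", "init") %in% names(species)))
  if (any(species$production <= 0) || any(species$decay <= 0)) {
    stop("production and decay rates must be > 0", call. = FALSE)
  }
  for (e in edges) {
    stopifnot(all(c("sensor", "target", "sign", "params") %in% names(e)))
    if (!e$sensor %in% species$name || !e$target %in% species$name) {
      stop(sprintf("edge %s -> %s refers to an undeclared species",
                   e$sensor, e$target), call. = FALSE)
    }
    if (!e$sign %in% c("activate", "repress")) {
      stop("edge sign must be 'activate' or 'repress'", call. = FALSE)
    }
  }
  structure(list(species = species, edges = edges), class = "network_model")
}

edge_modifier <- function(e, sensor_conc) {
  eff <- if (is.null(e$efficacy)) 1 else e$efficacy
  cp <- if (is.null(e$copies)) 2L else e$copies
  if (e$sign == "repress") {
    repression_output(eff, cp, sensor_conc, e$params)
  } else {
    activation_output(eff, cp, occupancy(sensor_conc, e$params), e$params)
  }
}

#' Simulate network dynamics (fixed-step RK4)
#'
#' Integrates `d[X]/dt = production_X * prod(edge modifiers) - decay_X *
#' [X]` with the classical fixed-step fourth-order Runge-Kutta method
#' (via `deSolve`, `method = "rk4"`). Connector edges act on protein
#' production only; a transcript-level readout of a target is therefore
#' its unmodified production/decay balance. Perturbations are timed
#' events: `set` replaces a species' concentration, `production` replaces
#' its production rate from that time on (a knockdown is a production
#' event with a small value).
#'
#' @param model A [network_model()].
#' @param t_end End time (default 100).
#' @param dt Fixed step (default 0.01).
#' @param perturbations Optional data frame with columns `time`,
#'   `species`, `action` (`"set"` or `"production"`), `value`.
#' @return Data frame of trajectories: `time` plus one column per
#'   species.
#' @export
simulate_network <- function(model, t_end = 100, dt = 0.01,
                             perturbations = NULL) {
  stopifnot(inherits(model, "network_model"), dt > 0, t_end > 0)
  sp <- model$species
  y <- stats::setNames(sp$init, sp$name)
  production <- stats::setNames(sp$production, sp$name)
  decay <- stats::setNames(sp$decay, sp$name)

  deriv <- function(t, y, parms) {
    mods <- stats::setNames(rep(1, length(y)), names(y))
    for (e in model$edges) {
      mods[e$target] <- mods[e$target] * edge_modifier(e, max(y[e$sensor], 0))
    }
    list(parms$production * mods - parms$decay * y)
  }

  ev_times <- numeric(0)
  if (!is.null(perturbations) && nrow(perturbations) > 0L) {
    stopifnot(all(c("time", "species", "action", "value") %in%
                    names(perturbations)))
    perturbations <- perturbations[order(perturbations$time), , drop = FALSE]
    ev_times <- unique(perturbations$time)
  }
  bounds <- unique(c(0, ev_times[ev_times > 0 & ev_times < t_end], t_end))
  bounds <- sort(bounds)

  out <- NULL
  for (b in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[b]; t1 <- bounds[b + 1L]
    if (t0 %in% ev_times) {
      evs <- perturbations[perturbations$time == t0, , drop = FALSE]
      for (r in seq_len(nrow(evs))) {
        nm <- evs$species[r]
        if (!nm %in% names(y)) stop("perturbation refers to unknown species '",
                                    nm, "'", call. = FALSE)
        if (evs$action[r] == "set") y[nm] <- evs$value[r]
        else if (evs$action[r] == "production") production[nm] <- evs$value[r]
        else stop("unknown perturbation action '", evs$action[r], "'",
                  call. = FALSE)
      }
    }
    times <- seq(t0, t1, by = dt)
    if (times[length(times)] < t1) times <- c(times, t1)
    seg <- deSolve::ode(y = y, times = times, func = deriv,
                        parms = list(production = production, decay = decay),
                        method = "rk4")
    if (any(!is.finite(seg))) {
      bad <- which(apply(!is.finite(seg), 1L, any))[1L]
      stop(sprintf("non-finite state at t = %.4g", seg[bad, "time"]),
           call. = FALSE)
    }
    seg <- as.data.frame(seg)
    y <- stats::setNames(as.numeric(seg[nrow(seg), -1L]), names(y))
    out <- if (is.null(out)) seg else rbind(out, seg[-1L, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Packaged OPN-VEGF feedback-loop models
#'
#' Two-species feedback loops between osteopontin (OPN) and VEGF mediated
#' by signal-connectors. In the positive loop each protein activates
#' translation of the other (two eIF4G aptamer copies on a sensing
#' riboswitch); in the negative loop OPN activates VEGF while VEGF
#' represses OPN (two VEGF-sensing aptamer copies on the anti-OPN
#' antisense). Default kinetics: production 1, decay 0.1 per species
#' (unregulated steady state 10 concentration units); connector edges use
#' K = 30, h = 2, Emax_r = 0.8, Fmax = 3, efficacy 0.9.
#'
#' @param type `"positive"` or `"negative"`.
#' @return A [network_model()].
#' @export
opn_vegf_loop <- function(type = c("positive", "negative")) {
  type <- match.arg(type)
  params <- load_device_params("opn_vegf_loop")
  species <- data.frame(name = c("OPN", "VEGF"), production = 1, decay = 0.1,
                        init = 10, stringsAsFactors = FALSE)
  e_act <- function(sensor, target) {
    list(sensor = sensor, target = target, sign = "activate", params = params,
         efficacy = 0.9, copies = 2L)
  }
  e_rep <- function(sensor, target) {
    list(sensor = sensor, target = target, sign = "repress", params = params,
         efficacy = 0.9, copies = 2L)
  }
  edges <- if (type == "positive") {
    list(e_act("OPN", "VEGF"), e_act("VEGF", "OPN"))
  } else {
    list(e_act("OPN", "VEGF"), e_rep("VEGF", "OPN"))
  }
  network_model(species, edges)
}

#' Rewire a transcription-factor pathway at the translational level
#'
#' Models the uncoupling of transcript and protein readouts when a
#' repressor signal-connector senses a transcription factor: the
#' transcriptional arm is untouched (mRNA rises with the factor) while
#' the connector represses translation of the same target in proportion
#' to factor occupancy.
#'
#' @param tf_level Transcription-factor (sensor protein) concentration.
#' @param design A scored repressor `connector_design` with a
#'   protein-sensing aptamer.
#' @param params [regulation_params()] of the connector (its `K`/`h` also
#'   parameterise the transcriptional response).
#' @param tx_fold Maximal transcriptional fold-induction of the target by
#'   the factor (default 2, the modest qPCR-scale induction typical of
#'   transcription-factor stimulation).
#' @return List with `mrna` and `protein` relative readouts (baseline 1).
#' @export
rewire_scenario <- function(tf_level, design, params, tx_fold = 2) {
  stopifnot(inherits(design, "connector_design"),
            design$topology == "repressor",
            !is.null(design$scores))
  th <- occupancy(tf_level, params)
  mrna <- 1 + (tx_fold - 1) * th
  protein <- mrna * repression_output(device_efficacy(list(design = design)),
                                      design$copies, tf_level, params)
  list(mrna = mrna, protein = protein)
}

#' Tumour-targeting AND-gate classifier
#'
#' A ribozyme-flanked repressor expressed from the hTERT promoter: the
#' device exists only in cells where the promoter is active, and
#' represses its survival-gene target only when its ligand is also
#' present, so knockdown requires both inputs.
#'
#' @param promoter_active Logical; is the (hTERT) promoter active in this
#'   cell?
#' @param ligand_present Logical; is the ligand supplied?
#' @param design A scored repressor `connector_design` with
#'   `ribozyme_flanked = TRUE`.
#' @param params [regulation_params()] of the device.
#' @param ligand_high Ligand concentration when present (uM).
#' @return Fractional knockdown of the survival gene in \[0, 1).
#' @export
and_classifier <- function(promoter_active, ligand_present, design, params,
                           ligand_high = 1000) {
  stopifnot(inherits(design, "connector_design"),
            design$topology == "repressor", !is.null(design$scores))
  if (!isTRUE(design$ribozyme_flanked)) {
    stop("the classifier device must be a ribozyme-flanked repressor",
         call. = FALSE)
  }
  if (!isTRUE(promoter_active) || !isTRUE(ligand_present)) return(0)
  1 - repression_output(device_efficacy(list(design = design)), design$copies,
                        ligand_high, params)
}

#' Simultaneous ON/OFF redirection of an oncogenic signal
#'
#' Four devices sensing the same oncogenic signal (NF-kB-like): two
#' ligand-gated activators drive tumour suppressors up while two
#' repressors push oncogenes down, simultaneously, in proportion to the
#' sensor level.
#'
#' @param sensor_level Concentration of the sensed oncogenic signal.
#' @param activators List of two scored `switch_activator` designs.
#' @param repressors List of two scored `repressor` designs.
#' @param params_act,params_rep [regulation_params()] for the two arms.
#' @return Data frame with columns `gene`, `arm`, `output` (relative to
#'   baseline 1).
#' @export
redirect_scenario <- function(sensor_level, activators, repressors,
                              params_act, params_rep) {
  stopifnot(length(activators) == 2L, length(repressors) == 2L)
  for (d in activators) {
    stopifnot(inherits(d, "connector_design"),
              d$topology == "switch_activator", !is.null(d$scores))
  }
  for (d in repressors) {
    stopifnot(inherits(d, "connector_design"),
              d$topology == "repressor", !is.null(d$scores))
  }
  th <- occupancy(sensor_level, params_act)
  rows <- list()
  for (d in activators) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = if (is.null(d$target_id)) d$id else d$target_id,
      arm = "activated",
      output = activation_output(device_efficacy(list(design = d)), d$copies,
                                 th, params_act),
      stringsAsFactors = FALSE)
  }
  for (d in repressors) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = if (is.null(d$target_id)) d$id else d$target_id,
      arm = "repressed",
      output = repression_output(device_efficacy(list(design = d)), d$copies,
                                 sensor_level, params_rep),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
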