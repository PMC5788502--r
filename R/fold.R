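#' Secondary-structure object
#'
#' Container for a predicted RNA secondary structure: a non-crossing set of
#' base pairs, the equivalent dot-bracket string and the total pairing score
#' (arbitrary stability units, higher = more stable).
#'
#' @param sequence RNA string the structure belongs to.
#' @param pairs Integer matrix with columns `i`, `j` (1-based, `i < j`).
#' @param score Total pairing score.
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(sequence, pairs, score) {
  n <- nchar(sequence)
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (NROW(pairs) > 0L) {
    stopifnot(all(pairs >= 1L), all(pairs <= n),
              all(pairs[, 1L] < pairs[, 2L]))
    idx <- c(pairs)
    if (anyDuplicated(idx)) stop("an index appears in more than one pair")
  }
  structure(list(sequence = sequence,
                 dotbracket = pairs_to_dotbracket(pairs, n),
                 pairs = pairs,
                 score = score),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "\n",
      sprintf("%d pairs, score %.6g\n", NROW(x$pairs), x$score), sep = "")
  invisible(x)
}

# Shared folding model parameters. min_loop = 3 forbids pairs (i, j) with
# j - i < 4; weights reward GC > AU > GU (wobble).
fold_defaults <- function() list(min_loop = 3L, weights = c(GC = 3, AU = 2, GU = 1))

#' Predict a maximum-score secondary structure
#'
#' Weighted base-pair maximisation (Nussinov-style dynamic programming) over
#' non-crossing structures with a minimum hairpin loop of `min_loop`
#' unpaired bases. Pair weights default to GC = 3, AU = 2, GU = 1. The
#' traceback is deterministic: where several structures attain the maximum
#' score, the branch pairing the smallest 5' index wins, and among those the
#' pair with the shortest span.
#'
#' This is a transparent structural model -- it makes no claim of
#' thermodynamic accuracy -- chosen because it admits an exact brute-force
#' oracle ([enumerate_structures()]) against which it can be verified.
#'
#' @param sequence RNA string (DNA-style input normalised).
#' @param constraints Optional integer vector of 1-based positions forced to
#'   stay unpaired.
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @param weights Named vector of pair weights (`GC`, `AU`, `GU`).
#' @return An [rna_structure()] attaining the maximum score.
#' @examples
#' fold("GGGAAACCC")  # the 3-pair hairpin, score 9
#' @export
fold <- function(sequence, constraints = integer(0),
                 min_loop = 3L, weights = c(GC = 3, AU = 2, GU = 1)) {
  s <- normalize_rna(sequence)
  v <- rna_chars(s)
  n <- length(v)
  constraints <- as.integer(constraints)
  if (length(constraints) && (min(constraints) < 1L || max(constraints) > n)) {
    stop("constraint indices out of range", call. = FALSE)
  }
  blocked <- logical(n)
  blocked[constraints] <- TRUE
  W <- pair_weight_matrix(weights)
  m1 <- as.integer(min_loop) + 1L

  if (n < m1 + 1L) {
    return(rna_structure(s, matrix(integer(0), ncol = 2), 0))
  }

  # M[i, j]: best score over interval i..j (cells with j < i stay 0).
  M <- matrix(0, n + 1L, n)
  for (span in m1:(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]
      if (!blocked[i]) {
        ks <- (i + m1):j
        w <- W[v[i], v[ks]]
        keep <- w > 0 & !blocked[ks]
        if (any(keep)) {
          ks <- ks[keep]
          cand <- w[keep] + M[i + 1L, ks - 1L] + M[, j][ks + 1L]
          best <- max(best, cand)
        }
      }
      M[i, j] <- best
    }
  }

  eps <- 1e-9
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    while (j - i >= m1 && M[i, j] > eps) {
      paired <- FALSE
      if (!blocked[i]) {
        for (k in (i + m1):j) {     # ascending k = shortest span first
          w <- W[v[i], v[k]]
          if (w > 0 && !blocked[k] &&
              abs(w + M[i + 1L, k - 1L] + M[k + 1L, j] - M[i, j]) < eps) {
            pairs <- rbind(pairs, c(i, k))
            if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
            j <- k - 1L
            i <- i + 1L
            paired <- TRUE
            break
          }
        }
      }
      if (!paired) i <- i + 1L
    }
  }

  score <- score_pairs(v, pairs, W)
  rna_structure(s, pairs, score)
}

#' Exhaustively enumerate all valid secondary structures
#'
#' Brute-force oracle: every non-crossing structure respecting the minimum
#' loop length, including the empty structure, each scored under the same
#' weights as [fold()]. Guarded to short sequences; intended for testing and
#' verification only.
#'
#' @inheritParams fold
#' @param max_n Length guard (default 25).
#' @return List of [rna_structure()] objects.
#' @export
enumerate_structures <- function(sequence, min_loop = 3L,
                                 weights = c(GC = 3, AU = 2, GU = 1),
                                 max_n = 25L) {
  s <- normalize_rna(sequence)
  v <- rna_chars(s)
  n <- length(v)
  if (n > max_n) {
    stop("enumerate_structures() is an exhaustive oracle for testing; ",
         "sequence length ", n, " exceeds the guard of ", max_n, call. = FALSE)
  }
  W <- pair_weight_matrix(weights)
  m1 <- as.integer(min_loop) + 1L
  memo <- new.env(parent = emptyenv())

  # All pair sets over interval i..j, as a list of integer matrices.
  recur <- function(i, j) {
    if (j - i < m1) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- recur(i + 1L, j)                      # i unpaired
    for (k in (i + m1):j) {
      if (W[v[i], v[k]] > 0) {
        left <- recur(i + 1L, k - 1L)
        right <- recur(k + 1L, j)
        for (a in left) for (b in right) {
          out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
        }
      }
    }
    memo[[key]] <- out
    out
  }

  lapply(recur(1L, n), function(p) {
    p <- p[order(p[, 1L]), , drop = FALSE]
    rna_structure(s, p, score_pairs(v, p, W))
  })
}

#' Count valid secondary structures by dynamic programming
#'
#' Independent counting recurrence used to cross-check the exhaustive
#' enumeration: `C(i,j) = C(i+1,j) + sum_k C(i+1,k-1) * C(k+1,j)` over
#' pairable `k`.
#'
#' @inheritParams fold
#' @return Number of valid structures (including the empty one).
#' @export
count_structures <- function(sequence, min_loop = 3L,
                             weights = c(GC = 3, AU = 2, GU = 1)) {
  s <- normalize_rna(sequence)
  v <- rna_chars(s)
  n <- length(v)
  W <- pair_weight_matrix(weights)
  m1 <- as.integer(min_loop) + 1L
  C <- matrix(1, n + 2L, n + 1L)   # empty intervals count 1
  if (n < m1 + 1L) return(1)
  for (span in m1:(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      tot <- C[i + 1L, j]
      for (k in (i + m1):j) {
        if (W[v[i], v[k]] > 0) {
          right <- if (k + 1L > j) 1 else C[k + 1L, j]
          tot <- tot + C[i + 1L, k - 1L] * right
        }
      }
      C[i, j] <- tot
    }
  }
  C[1L, n]
}

#' Per-index partner map of a structure
#'
#' @param x An [rna_structure()] (or a pair matrix).
#' @param length Sequence length; defaults to the structure's own.
#' @return Integer vector: position `i` holds its partner's index, or
#'   `NA` if unpaired. The map is an involution.
#' @export
pair_partner_map <- function(x, length = NULL) {
  pairs <- if (inherits(x, "rna_structure")) x$pairs else x
  n <- if (is.null(length)) nchar(x$sequence) else as.integer(length)
  partner <- rep(NA_integer_, n)
  if (NROW(pairs) > 0L) {
    partner[pairs[, 1L]] <- pairs[, 2L]
    partner[pairs[, 2L]] <- pairs[, 1L]
  }
  partner
}

#' Write a structure in connect (.ct) format
#'
#' Minimal connect-format writer for interoperability with structure
#' viewers.
#'
#' @param x An [rna_structure()].
#' @param path Output file path.
#' @export
write_ct <- function(x, path) {
  stopifnot(inherits(x, "rna_structure"))
  v <- rna_chars(x$sequence)
  n <- length(v)
  partner <- pair_partner_map(x)
  partner[is.na(partner)] <- 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d  ENERGY = %.2f", n, x$score), con)
  writeLines(sprintf("%d %s %d %d %d %d",
                     seq_len(n), v, seq_len(n) - 1L,
                     c(seq_len(n - 1L) + 1L, 0L), partner, seq_len(n)), con)
  invisible(path)
}
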