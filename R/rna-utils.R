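#' @keywords internal
"_PACKAGE"

RNA_BASES <- c("A", "C", "G", "U")

# Watson-Crick complement (RNA)
RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

#' Normalise a nucleotide string to the RNA alphabet
#'
#' Upper-cases the input and maps `T` to `U` so that DNA-style input is
#' accepted transparently. Any character outside `A/C/G/U` after
#' normalisation is a hard error reporting the first offending position.
#'
#' @param x Character scalar, a nucleotide sequence.
#' @param what Label used in error messages.
#' @return The normalised RNA string.
#' @export
normalize_rna <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  y <- chartr("tT", "uU", x)
  y <- toupper(y)
  bad <- regexpr("[^ACGU]", y)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d in %s",
                 substr(y, bad, bad), as.integer(bad), what), call. = FALSE)
  }
  if (nchar(y) == 0L) stop(sprintf("%s is empty", what), call. = FALSE)
  y
}

rna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Reverse complement of an RNA string
#'
#' Watson-Crick reverse complement: the sequence is reversed and
#' `A<->U`, `G<->C` exchanged. Applying it twice is the identity.
#'
#' @param x RNA string (DNA-style `T` accepted and normalised).
#' @return RNA string of the same length.
#' @examples
#' reverse_complement("AUGC")  # "GCAU"
#' @export
reverse_complement <- function(x) {
  v <- rna_chars(normalize_rna(x))
  paste(rev(unname(RNA_COMP[v])), collapse = "")
}

# Pairing weight lookup used across the package: GC=3, AU=2, GU=1.
pair_weight_matrix <- function(weights = c(GC = 3, AU = 2, GU = 1)) {
  W <- matrix(0, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  W["G", "C"] <- W["C", "G"] <- weights[["GC"]]
  W["A", "U"] <- W["U", "A"] <- weights[["AU"]]
  W["G", "U"] <- W["U", "G"] <- weights[["GU"]]
  W
}

# TRUE where two bases form a Watson-Crick pair (no wobble); vectorised.
is_wc_pair <- function(a, b) unname(RNA_COMP[a] == b)

#' Convert a dot-bracket string to a two-column pair matrix
#'
#' @param db Dot-bracket string using `(`, `)` and `.`.
#' @param what Label used in error messages.
#' @return Integer matrix with columns `i`, `j` (1-based, `i < j`),
#'   zero rows for an unpaired structure.
#' @export
dotbracket_to_pairs <- function(db, what = "structure") {
  v <- rna_chars(db)
  if (any(!v %in% c("(", ")", "."))) {
    stop(sprintf("%s contains characters other than '(', ')', '.'", what),
         call. = FALSE)
  }
  stack <- integer(0)
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(v)) {
    if (v[k] == "(") {
      stack <- c(stack, k)
    } else if (v[k] == ")") {
      if (length(stack) == 0L) {
        stop(sprintf("unbalanced dot-bracket in %s: ')' at position %d has no partner",
                     what, k), call. = FALSE)
      }
      out <- rbind(out, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) {
    stop(sprintf("unbalanced dot-bracket in %s: '(' at position %d is never closed",
                 what, stack[1L]), call. = FALSE)
  }
  out[order(out[, 1L]), , drop = FALSE]
}

pairs_to_dotbracket <- function(pairs, n) {
  v <- rep(".", n)
  if (NROW(pairs) > 0L) {
    v[pairs[, 1L]] <- "("
    v[pairs[, 2L]] <- ")"
  }
  paste(v, collapse = "")
}

# Score a pair set under the package weights.
score_pairs <- function(seq_chars, pairs, W = pair_weight_matrix()) {
  if (NROW(pairs) == 0L) return(0)
  sum(W[cbind(seq_chars[pairs[, 1L]], seq_chars[pairs[, 2L]])])
}

# Antiparallel complementarity count between two strands: position i of `a`
# is matched against position n - i + 1 of `b`; only Watson-Crick pairs count.
antiparallel_matches <- function(a, b) {
  va <- rna_chars(a)
  vb <- rev(rna_chars(b))
  n <- min(length(va), length(vb))
  sum(is_wc_pair(va[seq_len(n)], vb[seq_len(n)]))
}
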