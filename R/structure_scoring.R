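# Step 4: secondary structure of the full gRNA (guide + scaffold) and the
# number of guide bases locked into intramolecular pairs. The default engine
# is base-pair maximization (Nussinov-style dynamic programming with a
# minimum hairpin-loop size), pseudoknot-free and deterministic; externally
# computed dot-bracket structures (e.g. a thermodynamic MFE fold) can be
# imported instead.

#' Folding parameters
#'
#' @param min_loop Minimum hairpin loop size in unpaired bases (default 3,
#'   the standard steric minimum).
#' @param allow_gu Allow G-U wobble pairs in addition to Watson-Crick
#'   (default TRUE).
#' @param scaffold RNA string appended 3' of the 20-nt guide before folding.
#'   Defaults to the canonical single-guide tracrRNA-fusion scaffold shipped
#'   with the package; use \code{""} for guide-only folding.
#' @return An object of class \code{fold_params}.
#' @export
fold_params <- function(min_loop = 3L, allow_gu = TRUE,
                        scaffold = default_scaffold()) {
  min_loop <- as.integer(min_loop)
  stopifnot(min_loop >= 0L, is.logical(allow_gu),
            is.character(scaffold), length(scaffold) == 1L)
  scaffold <- toupper(scaffold)
  if (grepl("[^ACGU]", scaffold) && nzchar(scaffold)) {
    stop("scaffold must be an RNA string over A/C/G/U")
  }
  structure(list(min_loop = min_loop, allow_gu = allow_gu,
                 scaffold = scaffold),
            class = "fold_params")
}

#' The bundled sgRNA scaffold sequence
#'
#' The 76-nt Streptococcus pyogenes single-guide scaffold (crRNA repeat
#' fused to the tracrRNA), read from the package's editable data file.
#'
#' @return RNA string.
#' @export
default_scaffold <- function() {
  path <- system.file("extdata", "sgrna_scaffold.txt",
                      package = "gRNAdesign")
  if (!nzchar(path) || !file.exists(path)) {
    stop("bundled scaffold file is missing or the package is not installed")
  }
  s <- toupper(paste(readLines(path, warn = FALSE), collapse = ""))
  s <- gsub("\\s", "", s)
  if (!nzchar(s) || grepl("[^ACGU]", s)) {
    stop("bundled scaffold file is corrupt: expected an RNA string")
  }
  s
}

#' Convert DNA to RNA (T to U)
#' @param seq DNA string.
#' @return RNA string, uppercase.
#' @export
dna_to_rna <- function(seq) {
  chartr("Tt", "Uu", toupper(seq))
}

.pair_ok_matrix <- function(bases, allow_gu) {
  pairs <- c("AU", "UA", "GC", "CG")
  if (allow_gu) pairs <- c(pairs, "GU", "UG")
  outer(bases, bases, function(a, b) paste0(a, b) %in% pairs)
}

#' Predict a maximum-base-pair secondary structure
#'
#' Dynamic program maximizing the number of allowed base pairs (Watson-Crick
#' plus optional G-U wobble) subject to the minimum hairpin-loop size and no
#' pseudoknots. Among co-optimal structures the traceback deterministically
#' prefers leaving the left index unpaired, then the pairing partner with
#' the smallest position.
#'
#' @param sequence RNA string over A/C/G/U (use \code{\link{dna_to_rna}}
#'   for DNA input).
#' @param params A \code{fold_params}; its \code{scaffold} field is ignored
#'   here (\code{fold} folds exactly the sequence given).
#' @return An object of class \code{dot_bracket}: list with \code{sequence},
#'   \code{structure} (dot-bracket string), \code{pairs} (two-column matrix
#'   of 1-based paired positions, i < j), \code{n_pairs}.
#' @export
fold <- function(sequence, params = fold_params(scaffold = "")) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            inherits(params, "fold_params"))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("cannot fold an empty sequence")
  if (grepl("[^ACGU]", sequence)) {
    stop("fold expects an RNA string over A/C/G/U",
         if (grepl("T", sequence)) " (convert DNA with dna_to_rna())" else "")
  }
  n <- nchar(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  min_loop <- params$min_loop
  ok <- .pair_ok_matrix(bases, params$allow_gu)

  # M[i, j] = max pairs in sequence[i..j]; padded so M[n+1, *] reads 0
  M <- matrix(0L, nrow = n + 1L, ncol = n + 1L)
  if (n >= min_loop + 2L) {
    for (d in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        best <- M[i + 1L, j]
        js <- (i + min_loop + 1L):j
        js <- js[ok[i, js]]
        if (length(js)) {
          vals <- 1L + M[i + 1L, js - 1L] + M[cbind(js + 1L, j)]
          best <- max(best, vals)
        }
        M[i, j] <- best
      }
    }
  }

  # traceback with the documented tie-break
  pairs <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (i >= j || j - i < min_loop + 1L || M[i, j] == 0L) next
    if (M[i, j] == M[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
      next
    }
    for (jp in (i + min_loop + 1L):j) {
      if (ok[i, jp] &&
          M[i, j] == 1L + M[i + 1L, jp - 1L] +
            (if (jp + 1L > j) 0L else M[jp + 1L, j])) {
        pairs <- rbind(pairs, c(i, jp))
        stack[[length(stack) + 1L]] <- c(i + 1L, jp - 1L)
        if (jp + 1L <= j) stack[[length(stack) + 1L]] <- c(jp + 1L, j)
        break
      }
    }
  }

  struct <- rep(".", n)
  if (nrow(pairs)) {
    struct[pairs[, 1L]] <- "("
    struct[pairs[, 2L]] <- ")"
  }
  structure(list(sequence = sequence,
                 structure = paste(struct, collapse = ""),
                 pairs = pairs, n_pairs = nrow(pairs)),
            class = "dot_bracket")
}

#' @export
print.dot_bracket <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "  (", x$n_pairs, " pairs)\n",
      sep = "")
  invisible(x)
}

#' Import an externally predicted dot-bracket structure
#'
#' Validates bracket balance and the hairpin-loop constraint (errors), and
#' pairing complementarity (warnings only: thermodynamic engines may pair
#' non-canonically).
#'
#' @param sequence RNA string.
#' @param dot_bracket_text Structure string over "(", ")", "." of the same
#'   length.
#' @param params A \code{fold_params} supplying \code{min_loop} and
#'   \code{allow_gu} for validation.
#' @return A \code{dot_bracket} object.
#' @export
import_structure <- function(sequence, dot_bracket_text,
                             params = fold_params(scaffold = "")) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != nchar(dot_bracket_text)) {
    stop("sequence and structure have different lengths")
  }
  if (grepl("[^().]", dot_bracket_text)) {
    stop("structure may contain only '(', ')' and '.'")
  }
  chars <- strsplit(dot_bracket_text, "", fixed = TRUE)[[1L]]
  open_stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      open_stack <- c(open_stack, k)
    } else if (chars[k] == ")") {
      if (!length(open_stack)) stop("unbalanced brackets: unmatched ')'")
      i <- open_stack[length(open_stack)]
      open_stack <- open_stack[-length(open_stack)]
      pairs <- rbind(pairs, c(i, k))
    }
  }
  if (length(open_stack)) stop("unbalanced brackets: unmatched '('")
  if (nrow(pairs)) {
    loop_sizes <- pairs[, 2L] - pairs[, 1L] - 1L
    # only innermost (hairpin-closing) pairs are constrained, but a span
    # shorter than min_loop can never contain a legal nested pair either
    if (any(loop_sizes < params$min_loop)) {
      bad <- which(loop_sizes < params$min_loop)[1L]
      stop(sprintf(
        "hairpin loop closed by pair (%d,%d) has %d unpaired base(s); minimum is %d",
        pairs[bad, 1L], pairs[bad, 2L], loop_sizes[bad], params$min_loop))
    }
    bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    ok <- .pair_ok_matrix(bases, params$allow_gu)
    bad <- !ok[pairs]
    if (any(bad)) {
      warning(sum(bad), " pair(s) are not ",
              if (params$allow_gu) "Watson-Crick/GU" else "Watson-Crick",
              " complementary")
    }
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  structure(list(sequence = sequence, structure = dot_bracket_text,
                 pairs = pairs, n_pairs = nrow(pairs)),
            class = "dot_bracket")
}

#' Count guide bases sequestered by secondary structure
#'
#' The 20-nt guide occupies positions 1-20 of the folded gRNA; a guide base
#' engaged in an intramolecular pair is unavailable for DNA binding. The
#' complementary count (unpaired, binding-competent guide bases) is
#' \code{guide_length} minus the returned value; both appear in reports.
#'
#' @param structure A \code{dot_bracket} of the full gRNA.
#' @param guide_length Number of 5' positions forming the guide (default 20).
#' @return Integer: number of guide positions that are paired.
#' @export
guide_loop_bases <- function(structure, guide_length = 20L) {
  stopifnot(inherits(structure, "dot_bracket"))
  if (nchar(structure$structure) < guide_length) {
    stop("structure is shorter than the guide (", guide_length, " nt)")
  }
  paired <- unique(as.vector(structure$pairs))
  sum(paired <= guide_length)
}

#' AT content of a guide sequence
#'
#' @param guide DNA string over A/C/G/T (a 20-nt guide in normal use, in
#'   which case the result is a multiple of 5).
#' @return Percent of A or T bases, in [0, 100].
#' @export
at_content <- function(guide) {
  stopifnot(is.character(guide), length(guide) == 1L)
  guide <- toupper(guide)
  if (!nzchar(guide)) stop("empty guide sequence")
  if (grepl("[^ACGT]", guide)) {
    stop("guide contains N or non-ACGT characters; ",
         "such candidates are excluded upstream")
  }
  bases <- strsplit(guide, "", fixed = TRUE)[[1L]]
  100 * sum(bases %in% c("A", "T")) / length(bases)
}
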