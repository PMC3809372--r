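# Step 2: map each candidate 23-mer back to the reference genome allowing a
# small number of mismatches (Hamming distance, ungapped) and classify
# uniqueness. The engine is a pigeonhole-split exact k-mer index: the 23-mer
# is cut into max_mismatches + 1 contiguous parts, so any placement within
# the mismatch budget matches at least one part exactly; seed hits are then
# verified over the full window.

#' Search parameters for off-target mapping
#'
#' Defaults mirror a short-read aligner run in mismatch mode: at most one
#' mismatch over the literal 23-mer (PAM included), up to 10 reported hits,
#' and a 16-bp seed. The seed length is retained for interface compatibility;
#' the pigeonhole split guarantees full sensitivity at the configured
#' mismatch budget regardless of its value.
#'
#' @param max_mismatches Maximum Hamming distance (default 1).
#' @param max_hits Cap on reported alignments (default 10).
#' @param seed_length Nominal seed length (default 16).
#' @return An object of class \code{search_params}.
#' @export
search_params <- function(max_mismatches = 1L, max_hits = 10L,
                          seed_length = 16L) {
  max_mismatches <- as.integer(max_mismatches)
  max_hits <- as.integer(max_hits)
  seed_length <- as.integer(seed_length)
  stopifnot(max_mismatches >= 0L, max_mismatches <= 3L,
            max_hits >= 1L, seed_length >= 1L, seed_length <= 23L)
  structure(list(max_mismatches = max_mismatches, max_hits = max_hits,
                 seed_length = seed_length),
            class = "search_params")
}

# contiguous split of `total` positions into `k` near-equal parts
.part_bounds <- function(total, k) {
  sizes <- rep(total %/% k, k)
  extra <- total %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  cbind(start = c(1L, utils::head(ends, -1L) + 1L), end = ends)
}

#' Build an exact k-mer index over a genome
#'
#' Indexes, for every chromosome (forward strand), the start positions of all
#' overlapping k-mers at the part lengths implied by the pigeonhole split of
#' 23 into \code{max_mismatches + 1} parts. k-mers containing N are never
#' used as exact seeds (an N in the genome matches no query base and counts
#' as a mismatch at verification).
#'
#' @param g A \code{genome}.
#' @param params A \code{search_params}.
#' @return An object of class \code{target_index}.
#' @export
build_index <- function(g, params = search_params()) {
  stopifnot(inherits(g, "genome"), inherits(params, "search_params"))
  if (sum(g$lengths) == 0L) stop("cannot index an empty genome")
  bounds <- .part_bounds(23L, params$max_mismatches + 1L)
  klens <- unique(bounds[, "end"] - bounds[, "start"] + 1L)
  tables <- lapply(g$records, function(s) {
    L <- nchar(s)
    per_len <- lapply(klens, function(k) {
      if (L < k) return(new.env(hash = TRUE, parent = emptyenv()))
      starts <- seq_len(L - k + 1L)
      kmers <- substring(s, starts, starts + k - 1L)
      keep <- !grepl("N", kmers, fixed = TRUE)
      list2env(split(starts[keep], kmers[keep]),
               envir = new.env(hash = TRUE, parent = emptyenv()))
    })
    names(per_len) <- as.character(klens)
    per_len
  })
  structure(list(genome = g, params = params, bounds = bounds,
                 tables = tables),
            class = "target_index")
}

# Hamming mismatch offsets between two equal-length strings
.mismatch_offsets <- function(a, b) {
  which(utf8ToInt(a) != utf8ToInt(b))
}

#' Find all genomic placements of a 23-mer within the mismatch budget
#'
#' Searches both strands; hits are ordered by mismatch count, chromosome
#' (genome record order), start, then "+" before "-", and truncated after
#' \code{max_hits} with a flag. Mismatch positions are reported 1-based in
#' the 23-mer's own 5'-to-3' orientation.
#'
#' @param target_23mer A 23-nt DNA string with no N.
#' @param index A \code{target_index} from \code{\link{build_index}}.
#' @param params Optional \code{search_params}; its mismatch budget must not
#'   exceed the one the index was built with. Defaults to the index's params.
#' @return An object of class \code{hit_summary}: list with \code{hits}
#'   (data.frame: chrom, start, end, strand, mismatches, mismatch_positions
#'   list-column), \code{n_hits_reported}, \code{truncated}.
#' @export
find_hits <- function(target_23mer, index, params = NULL) {
  stopifnot(inherits(index, "target_index"))
  if (is.null(params)) params <- index$params
  stopifnot(inherits(params, "search_params"))
  if (params$max_mismatches > index$params$max_mismatches) {
    stop("index was built for max_mismatches = ",
         index$params$max_mismatches,
         "; rebuild it to search at a larger budget")
  }
  target_23mer <- toupper(target_23mer)
  if (nchar(target_23mer) != 23L) stop("target must be exactly 23 bp")
  if (grepl("[^ACGT]", target_23mer)) {
    stop("target 23-mer must contain only A/C/G/T (no N)")
  }
  g <- index$genome
  bounds <- index$bounds
  m <- params$max_mismatches
  queries <- c("+" = target_23mer, "-" = reverse_complement(target_23mer))
  hits <- list()
  for (chrom in names(g$records)) {
    s <- g$records[[chrom]]
    L <- g$lengths[[chrom]]
    if (L < 23L) next
    tabs <- index$tables[[chrom]]
    for (strand in c("+", "-")) {
      q <- queries[[strand]]
      cand <- integer(0)
      for (p in seq_len(nrow(bounds))) {
        a <- bounds[p, "start"]; b <- bounds[p, "end"]
        env <- tabs[[as.character(b - a + 1L)]]
        pos <- env[[substr(q, a, b)]]
        if (!is.null(pos)) cand <- c(cand, pos - (a - 1L))
      }
      cand <- unique(cand[cand >= 1L & cand <= L - 22L])
      if (!length(cand)) next
      windows <- substring(s, cand, cand + 22L)
      for (i in seq_along(cand)) {
        off <- .mismatch_offsets(windows[i], q)
        if (length(off) > m) next
        # report mismatch offsets in the query 23-mer's 5'->3' orientation
        if (strand == "-") off <- sort(24L - off)
        hits[[length(hits) + 1L]] <- list(
          chrom = chrom, start = cand[i], end = cand[i] + 22L,
          strand = strand, mismatches = length(off),
          mismatch_positions = off
        )
      }
    }
  }
  if (length(hits)) {
    df <- data.frame(
      chrom = vapply(hits, `[[`, "", "chrom"),
      start = vapply(hits, `[[`, 0L, "start"),
      end = vapply(hits, `[[`, 0L, "end"),
      strand = vapply(hits, `[[`, "", "strand"),
      mismatches = vapply(hits, `[[`, 0L, "mismatches"),
      stringsAsFactors = FALSE
    )
    df$mismatch_positions <- lapply(hits, `[[`, "mismatch_positions")
    ord <- order(df$mismatches, match(df$chrom, names(g$records)),
                 df$start, match(df$strand, c("+", "-")))
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     mismatches = integer(0), stringsAsFactors = FALSE)
    df$mismatch_positions <- list()
  }
  truncated <- nrow(df) > params$max_hits
  if (truncated) df <- df[seq_len(params$max_hits), , drop = FALSE]
  structure(list(hits = df, n_hits_reported = nrow(df),
                 truncated = truncated),
            class = "hit_summary")
}

#' @export
print.hit_summary <- function(x, ...) {
  cat(x$n_hits_reported, "hit(s)",
      if (x$truncated) "(truncated at cap)" else "", "\n")
  if (x$n_hits_reported > 0L) {
    print(x$hits[, c("chrom", "start", "end", "strand", "mismatches")])
  }
  invisible(x)
}

#' Classify the mapping uniqueness of a hit summary
#'
#' A candidate is "unique" when it maps to exactly one genomic place within
#' the mismatch budget, "unmapped" with zero placements, "multi" otherwise
#' (including when the reporting cap was hit).
#'
#' @param summary A \code{hit_summary}.
#' @return One of \code{"unique"}, \code{"multi"}, \code{"unmapped"}.
#' @export
classify_uniqueness <- function(summary) {
  stopifnot(inherits(summary, "hit_summary"))
  n <- summary$n_hits_reported
  if (n == 0L) "unmapped"
  else if (n == 1L && !summary$truncated) "unique"
  else "multi"
}
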