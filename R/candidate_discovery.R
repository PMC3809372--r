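# Step 1 of the design pipeline: scan query sequences on both strands for
# every 23-bp window matching N20-NGG (20-nt guide followed by an NGG PAM).

# start positions of a zero-width lookahead match (captures overlapping hits)
.lookahead_starts <- function(seq, body) {
  g <- gregexpr(paste0("(?=", body, ")"), seq, perl = TRUE)[[1L]]
  if (g[1L] == -1L) integer(0) else as.integer(g)
}

#' Scan a query sequence for N20-NGG candidate targets
#'
#' Finds every (possibly overlapping) 23-bp window whose last two bases are
#' GG on either strand; reverse-strand candidates appear as a CC dinucleotide
#' at window positions 1-2 on the forward strand and are reported in guide
#' orientation. Windows whose 23-mer contains an N are dropped and counted.
#'
#' @param query_id Name of the source record.
#' @param query_seq DNA string over A/C/G/T/N.
#' @return A data.frame of class \code{candidate_targets} with columns
#'   \code{query_id}, \code{query_start}, \code{query_end}, \code{strand},
#'   \code{guide} (20 nt), \code{pam} (3 nt, NGG), \code{target_23mer};
#'   ordered by query_start, then "+" before "-". The number of N-containing
#'   windows dropped is attached as attribute \code{n_dropped}.
#' @export
scan_candidates <- function(query_id, query_seq) {
  stopifnot(is.character(query_id), length(query_id) == 1L,
            is.character(query_seq), length(query_seq) == 1L)
  query_seq <- toupper(query_seq)
  if (grepl("[^ACGTN]", query_seq)) {
    stop("query sequence contains characters outside A/C/G/T/N")
  }
  empty <- data.frame(
    query_id = character(0), query_start = integer(0),
    query_end = integer(0), strand = character(0), guide = character(0),
    pam = character(0), target_23mer = character(0),
    stringsAsFactors = FALSE
  )
  class(empty) <- c("candidate_targets", "data.frame")
  L <- nchar(query_seq)
  if (L < 23L) {
    warning("query '", query_id, "' is shorter than 23 bp; no candidates")
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }

  one_strand <- function(s) {
    clean <- .lookahead_starts(s, "[ACGT]{21}GG")
    with_n <- .lookahead_starts(s, "[ACGTN]{21}GG")
    list(starts = clean, dropped = length(setdiff(with_n, clean)))
  }

  fwd <- one_strand(query_seq)
  rc <- reverse_complement(query_seq)
  rev <- one_strand(rc)

  rows <- list()
  if (length(fwd$starts)) {
    rows[[1L]] <- data.frame(
      query_id = query_id,
      query_start = fwd$starts,
      query_end = fwd$starts + 22L,
      strand = "+",
      guide = substring(query_seq, fwd$starts, fwd$starts + 19L),
      pam = substring(query_seq, fwd$starts + 20L, fwd$starts + 22L),
      stringsAsFactors = FALSE
    )
  }
  if (length(rev$starts)) {
    # window at p' on the reverse complement covers forward [L-p'-21, L-p'+1]
    rows[[2L]] <- data.frame(
      query_id = query_id,
      query_start = L - rev$starts - 21L,
      query_end = L - rev$starts + 1L,
      strand = "-",
      guide = substring(rc, rev$starts, rev$starts + 19L),
      pam = substring(rc, rev$starts + 20L, rev$starts + 22L),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out)) {
    out$target_23mer <- paste0(out$guide, out$pam)
    out <- out[order(out$query_start, match(out$strand, c("+", "-"))), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  n_dropped <- fwd$dropped + rev$dropped
  if (n_dropped > 0L) {
    message("scan_candidates: dropped ", n_dropped,
            " window(s) containing N in '", query_id, "'")
  }
  class(out) <- c("candidate_targets", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Anchor candidates to genomic coordinates
#'
#' Given the genomic region a query sequence was taken from (forward strand),
#' offsets each candidate's query coordinates into genome space. Strand is
#' composed: a minus-strand candidate on a plus-strand anchor is a
#' minus-strand genomic target.
#'
#' @param candidates A \code{candidate_targets} data.frame.
#' @param query_region A \code{genomic_region} whose length equals the query
#'   length and whose strand is "+", or NULL to leave candidates unanchored.
#' @param query_length Length of the query sequence (used to validate the
#'   anchor; optional when \code{query_region} is NULL).
#' @return The candidates with added columns \code{chrom}, \code{g_start},
#'   \code{g_end}, \code{g_strand} (NA when unanchored).
#' @export
map_to_genome <- function(candidates, query_region = NULL,
                          query_length = NULL) {
  stopifnot(inherits(candidates, "candidate_targets") ||
              is.data.frame(candidates))
  n <- nrow(candidates)
  if (is.null(query_region)) {
    candidates$chrom <- rep(NA_character_, n)
    candidates$g_start <- rep(NA_integer_, n)
    candidates$g_end <- rep(NA_integer_, n)
    candidates$g_strand <- rep(NA_character_, n)
    return(candidates)
  }
  stopifnot(inherits(query_region, "genomic_region"))
  if (query_region$strand != "+") {
    stop("query anchor region must be on the + strand")
  }
  anchor_len <- query_region$end - query_region$start + 1L
  if (!is.null(query_length) && anchor_len != query_length) {
    stop(sprintf("anchor length (%d) does not match query length (%d)",
                 anchor_len, query_length))
  }
  candidates$chrom <- rep(query_region$chrom, n)
  candidates$g_start <- query_region$start + candidates$query_start - 1L
  candidates$g_end <- query_region$start + candidates$query_end - 1L
  candidates$g_strand <- candidates$strand
  candidates
}
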