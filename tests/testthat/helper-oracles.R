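# Independent oracles used across the suite. None of these call the
# package's own search/fold engines.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# Brute-force placement search: Hamming distance computed at EVERY window on
# both strands (Biostrings::neditStartingAt, ungapped, N never matches),
# keeping windows within the budget. Returns a data.frame (unordered set).
bf_find_hits <- function(query23, g, max_mm) {
  rows <- list()
  for (chrom in names(g$records)) {
    s <- g$records[[chrom]]
    L <- nchar(s)
    if (L < 23L) next
    subj <- Biostrings::DNAString(s)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") query23 else reverse_complement(query23)
      d <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subj,
                                       starting.at = seq_len(L - 22L),
                                       with.indels = FALSE, fixed = TRUE)
      keep <- which(d <= max_mm)
      if (length(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = keep, strand = strand,
          mismatches = as.integer(d[keep]), stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# pure-R sliding-window search, independent of both Biostrings and the
# package engine (used on small inputs to cross-check both routes)
slide_find_hits <- function(query23, g, max_mm) {
  rows <- list()
  for (chrom in names(g$records)) {
    s <- g$records[[chrom]]
    L <- nchar(s)
    if (L < 23L) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") query23 else reverse_complement(query23)
      for (st in seq_len(L - 22L)) {
        d <- hamming(substr(s, st, st + 22L), pat)
        if (d <= max_mm) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start = st, strand = strand, mismatches = d,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

hit_key <- function(df) {
  sort(sprintf("%s:%d:%s:%d", df$chrom, df$start, df$strand,
               df$mismatches))
}

# exhaustive enumeration of all pseudoknot-free structures; returns the
# maximum number of allowed pairs (no memoization -> true enumeration)
enumerate_max_pairs <- function(seq, min_loop = 3L, allow_gu = TRUE) {
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  allowed <- c("AU", "UA", "GC", "CG", if (allow_gu) c("GU", "UG"))
  ok <- outer(bases, bases, function(a, b) paste0(a, b) %in% allowed)
  rec <- function(i, j) {
    if (i >= j || j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (jp in (i + min_loop + 1L):j) {
      if (ok[i, jp]) {
        best <- max(best, 1L + rec(i + 1L, jp - 1L) + rec(jp + 1L, j))
      }
    }
    best
  }
  rec(1L, length(bases))
}

# naive interval-overlap oracle for variant annotation
bf_overlapping <- function(region, variants) {
  hit <- variants$chrom == region$chrom &
    variants$ref_end >= region$start & variants$pos <= region$end
  variants[hit, , drop = FALSE]
}

tmp_fasta <- function(records, wrap = NULL) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  lines <- character(0)
  for (nm in names(records)) {
    s <- records[[nm]]
    if (is.null(wrap)) {
      lines <- c(lines, paste0(">", nm), s)
    } else {
      starts <- seq(1L, nchar(s), by = wrap)
      lines <- c(lines, paste0(">", nm),
                 substring(s, starts, pmin(starts + wrap - 1L, nchar(s))))
    }
  }
  writeLines(lines, path)
  path
}

tmp_text <- function(lines, fileext = ".txt") {
  path <- withr::local_tempfile(fileext = fileext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
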