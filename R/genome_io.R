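# Coordinate conventions used package-wide: positions are 1-based and
# inclusive on the forward genome axis; strand is "+" or "-" and only controls
# which sequence fetch() returns, never the coordinates themselves.

#' @keywords internal
"_PACKAGE"

.DNA_BASES <- c("A", "C", "G", "T", "N")
# IUPAC ambiguity codes accepted on input and coerced to N
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")

#' Read a (multi-record) FASTA file into a genome object
#'
#' Sequences are uppercased; IUPAC ambiguity codes other than A/C/G/T/N are
#' coerced to N with a message reporting how many bases were coerced.
#' Characters outside the IUPAC nucleotide alphabet abort with the offending
#' line number.
#'
#' @param path Path to a FASTA file. Lines may be wrapped or unwrapped.
#' @return An object of class \code{genome}: a list with \code{records}
#'   (named character vector of uppercase DNA over A/C/G/T/N) and
#'   \code{lengths} (named integer vector).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  con <- file(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  header_idx <- grep("^>", lines)
  if (length(header_idx) == 0L) stop("no records in FASTA file: ", path)
  if (header_idx[1L] != 1L &&
      any(nzchar(trimws(lines[seq_len(header_idx[1L] - 1L)])))) {
    stop("sequence data before first FASTA header in ", path)
  }
  names_raw <- sub("^>\\s*", "", lines[header_idx])
  nm <- sub("\\s.*$", "", names_raw)
  if (any(!nzchar(nm))) stop("empty record name in FASTA file: ", path)
  if (anyDuplicated(nm)) {
    stop("duplicate record name in FASTA file: ",
         nm[duplicated(nm)][1L])
  }
  bounds <- c(header_idx, length(lines) + 1L)
  n_coerced <- 0L
  records <- character(length(header_idx))
  legal <- paste0(c(.DNA_BASES, .IUPAC_AMBIG), collapse = "")
  for (i in seq_along(header_idx)) {
    from <- header_idx[i] + 1L
    to <- bounds[i + 1L] - 1L
    seq_lines <- if (from > to) character(0) else lines[from:to]
    seq_lines <- toupper(trimws(seq_lines))
    bad <- grepl(sprintf("[^%s]", legal), seq_lines)
    if (any(bad)) {
      line_no <- (from:to)[which(bad)[1L]]
      stop("illegal non-IUPAC character in FASTA line ", line_no,
           " of ", path)
    }
    s <- paste(seq_lines, collapse = "")
    n_coerced <- n_coerced + nchar(s) -
      nchar(gsub(sprintf("[%s]", paste0(.IUPAC_AMBIG, collapse = "")), "", s))
    s <- chartr(paste0(.IUPAC_AMBIG, collapse = ""),
                strrep("N", length(.IUPAC_AMBIG)), s)
    records[i] <- s
  }
  if (n_coerced > 0L) {
    message("read_fasta: coerced ", n_coerced,
            " ambiguous IUPAC base(s) to N")
  }
  names(records) <- nm
  genome(records)
}

#' Construct a genome object from named sequences
#'
#' @param records Named character vector of DNA sequences (A/C/G/T/N).
#' @return A \code{genome} object.
#' @export
genome <- function(records) {
  stopifnot(is.character(records), length(records) >= 1L)
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all genome records must be named")
  }
  if (anyDuplicated(names(records))) stop("duplicate chromosome names")
  records <- toupper(records)
  if (any(grepl("[^ACGTN]", records))) {
    stop("genome sequences must be over the alphabet A/C/G/T/N")
  }
  structure(
    list(records = records, lengths = nchar(records)),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat("genome object with", length(x$records), "sequence(s):\n")
  for (nm in names(x$records)) {
    cat(sprintf("  %s  %d bp\n", nm, x$lengths[[nm]]))
  }
  invisible(x)
}

#' Write a genome object to FASTA
#'
#' @param g A \code{genome} object.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(g, path, width = 60L) {
  stopifnot(inherits(g, "genome"))
  out <- character(0)
  for (nm in names(g$records)) {
    s <- g$records[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, paste0(">", nm),
             substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(out, path)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' Standard Watson-Crick complement (N maps to N), then reversal.
#'
#' @param seq DNA string over A/C/G/T/N (case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("reverse_complement: sequence contains characters outside A/C/G/T/N")
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Construct a genomic region
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates on the forward axis.
#' @param strand "+" or "-".
#' @return An object of class \code{genomic_region}.
#' @export
genomic_region <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(is.character(chrom), nzchar(chrom), strand %in% c("+", "-"))
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid region coordinates: start must satisfy 1 <= start <= end")
  }
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_region")
}

#' Render a region as "chrom:start-end(strand)"
#' @param region A \code{genomic_region}.
#' @return A string such as \code{"chr22:37196884-37196906(+)"}.
#' @export
format_region <- function(region) {
  stopifnot(inherits(region, "genomic_region"))
  sprintf("%s:%d-%d(%s)", region$chrom, region$start, region$end,
          region$strand)
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(format_region(x), "\n")
  invisible(x)
}

#' Parse "chrom:start-end" or "chrom:start-end(strand)" into a region
#' @param text Region string.
#' @return A \code{genomic_region} (strand defaults to "+").
#' @export
parse_region <- function(text) {
  m <- regmatches(
    text,
    regexec("^([^:]+):([0-9]+)-([0-9]+)(\\(([+-])\\))?$", text)
  )[[1L]]
  if (length(m) == 0L) stop("cannot parse region string: ", text)
  strand <- if (nzchar(m[6L])) m[6L] else "+"
  genomic_region(m[2L], as.integer(m[3L]), as.integer(m[4L]), strand)
}

#' Fetch the sequence of a region
#'
#' Returns the forward-strand substring for strand "+", and its reverse
#' complement for strand "-". Length always equals \code{end - start + 1}.
#'
#' @param g A \code{genome}.
#' @param region A \code{genomic_region} within chromosome bounds.
#' @return DNA string.
#' @export
fetch <- function(g, region) {
  stopifnot(inherits(g, "genome"), inherits(region, "genomic_region"))
  if (!region$chrom %in% names(g$records)) {
    stop("unknown chromosome: ", region$chrom)
  }
  len <- g$lengths[[region$chrom]]
  if (region$start < 1L || region$end > len) {
    stop(sprintf("region %s out of bounds for %s (length %d)",
                 format_region(region), region$chrom, len))
  }
  s <- substr(g$records[[region$chrom]], region$start, region$end)
  if (region$strand == "-") reverse_complement(s) else s
}
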