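# Step 3: intersect target regions with a catalogue of known variants
# (SNPs and indels, dbSNP-style VCF) and compute each variant's distance to
# the region's 3' end.

#' Read the CHROM/POS/ID/REF/ALT columns of a VCF file
#'
#' Accepts plain or gzip-compressed VCF 4.x. INFO/FORMAT/sample columns are
#' ignored; a multi-allelic record stays one row with comma-separated ALT.
#'
#' @param path Path to a VCF file (".vcf" or ".vcf.gz").
#' @return A data.frame of class \code{variant_table} with columns
#'   \code{chrom}, \code{pos} (1-based position of the first REF base),
#'   \code{id}, \code{ref}, \code{alt} (comma-joined), \code{ref_end}
#'   (\code{pos + nchar(ref) - 1}), and \code{kind} in
#'   \{"snp", "indel", "other"\}.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  is_data <- !startsWith(lines, "#") & nzchar(lines)
  data_lines <- lines[is_data]
  line_no <- which(is_data)
  n <- length(data_lines)
  chrom <- character(n); pos <- integer(n); id <- character(n)
  ref <- character(n); alt <- character(n)
  if (n > 0L) {
    fields <- strsplit(data_lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 5L)) {
      stop("malformed VCF data line ", line_no[which(nf < 5L)[1L]],
           ": fewer than 5 tab-separated fields")
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    pos_chr <- vapply(fields, `[[`, "", 2L)
    if (any(!grepl("^[0-9]+$", pos_chr))) {
      stop("non-integer POS at VCF data line ",
           line_no[which(!grepl("^[0-9]+$", pos_chr))[1L]])
    }
    pos <- as.integer(pos_chr)
    id <- vapply(fields, `[[`, "", 3L)
    ref <- toupper(vapply(fields, `[[`, "", 4L))
    alt <- toupper(vapply(fields, `[[`, "", 5L))
  }
  alts <- strsplit(alt, ",", fixed = TRUE)
  kind <- vapply(seq_len(n), function(i) {
    a <- alts[[i]]
    if (nchar(ref[i]) == 1L && all(nchar(a) == 1L)) "snp"
    else if (any(nchar(a) != nchar(ref[i]))) "indel"
    else "other"
  }, "")
  out <- data.frame(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
                    ref_end = pos + nchar(ref) - 1L, kind = kind,
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Variants overlapping a target region, with 3'-end distances
#'
#' A variant overlaps when its reference span \code{[pos, pos+nchar(ref)-1]}
#' intersects the region. The distance convention: the region's 3'-terminal
#' base (PAM-proximal end of the 23-bp target) is at distance 0; for a
#' multi-base variant the intersecting base nearest the 3' end is used.
#' On the "+" strand the 3' end is \code{region$end}; on "-" it is
#' \code{region$start}.
#'
#' @param region A \code{genomic_region}.
#' @param variants A \code{variant_table} from \code{\link{read_vcf}}.
#' @param normalize_chr If TRUE, a leading "chr" is stripped from both sides
#'   before chromosome-name comparison.
#' @return The overlapping rows with an added \code{dist_3prime} column,
#'   sorted by \code{dist_3prime} ascending (ties by position).
#' @export
overlap_variants <- function(region, variants, normalize_chr = FALSE) {
  stopifnot(inherits(region, "genomic_region"), is.data.frame(variants))
  vchrom <- variants$chrom
  rchrom <- region$chrom
  if (normalize_chr) {
    vchrom <- sub("^chr", "", vchrom)
    rchrom <- sub("^chr", "", rchrom)
  }
  on_chrom <- which(vchrom == rchrom)
  out <- variants[integer(0), , drop = FALSE]
  if (length(on_chrom)) {
    v <- variants[on_chrom, , drop = FALSE]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = v$pos, end = v$ref_end),
      IRanges::IRanges(start = region$start, end = region$end)
    )
    out <- v[S4Vectors::queryHits(ov), , drop = FALSE]
  }
  if (nrow(out)) {
    near3 <- if (region$strand == "+") {
      pmin(out$ref_end, region$end)
    } else {
      pmax(out$pos, region$start)
    }
    out$dist_3prime <- if (region$strand == "+") {
      region$end - near3
    } else {
      near3 - region$start
    }
    out <- out[order(out$dist_3prime, out$pos), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out$dist_3prime <- integer(0)
  }
  out
}

#' Count variants overlapping a target region
#'
#' Both SNPs and indels count toward the per-candidate total; the report
#' retains \code{kind} so users can filter.
#'
#' @param annotated Output of \code{\link{overlap_variants}}.
#' @return Integer count.
#' @export
count_snps <- function(annotated) {
  nrow(annotated)
}
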