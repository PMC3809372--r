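# Seeded generators for toy genomes, query records and VCFs with known
# ground truth, plus the bundled set of published human guides, so every
# pipeline stage is testable without any download.

#' Specification for a synthetic fixture genome
#'
#' @param seed Integer RNG seed; all output is deterministic given it.
#' @param genome_length Background genome length in bp.
#' @param gc_fraction Background GC fraction in [0, 1].
#' @param implants List of implant descriptions, each a list with
#'   \code{seq} (a 23-mer), \code{n_exact}, \code{n_1mm}, \code{n_2mm}
#'   (numbers of exact, 1-mismatch and 2-mismatch copies to place).
#' @param variant_plan List of planned variants, each a list with either
#'   \code{implant} (implant number; placed relative to its first exact
#'   copy) and \code{offset} (1-based within the 23-mer), or an absolute
#'   \code{pos}; plus \code{kind} in \{"snp", "del", "ins"\} and an optional
#'   \code{id}.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed, genome_length, gc_fraction = 0.5,
                         implants = list(), variant_plan = list()) {
  stopifnot(is.numeric(seed), genome_length >= 23L,
            gc_fraction >= 0, gc_fraction <= 1)
  for (im in implants) {
    stopifnot(is.list(im), nchar(im$seq) == 23L,
              !grepl("[^ACGT]", toupper(im$seq)))
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, implants = implants,
                 variant_plan = variant_plan),
            class = "fixture_spec")
}

.random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

.mutate_kmer <- function(seq_chars, k) {
  pos <- sample(seq_along(seq_chars), k)
  for (p in pos) {
    seq_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), seq_chars[p]), 1L)
  }
  list(chars = seq_chars, pos = sort(pos))
}

# brute-force count of <=1-mismatch placements of a 23-mer on both strands:
# Hamming distance at every window via Biostrings (independent of the
# package's own search engine)
.bf_place_count <- function(seq23, chrom_seq) {
  L <- nchar(chrom_seq)
  if (L < 23L) return(0L)
  subj <- Biostrings::DNAString(chrom_seq)
  n <- 0L
  for (pat in c(seq23, reverse_complement(seq23))) {
    d <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subj,
                                     starting.at = seq_len(L - 22L),
                                     with.indels = FALSE, fixed = TRUE)
    n <- n + sum(d <= 1L)
  }
  n
}

#' Generate a toy genome with implanted target copies
#'
#' Places the requested exact / 1-mismatch / 2-mismatch copies of each
#' implant 23-mer at non-overlapping positions (forward strand) in an i.i.d.
#' background of the requested GC content, and verifies by brute force that
#' no accidental extra placements within 1 mismatch exist, regenerating with
#' a fresh background if they do.
#'
#' @param spec A \code{fixture_spec}.
#' @param chrom_name Chromosome name for the single synthetic sequence.
#' @return A list with \code{genome} (a \code{genome} object), \code{truth}
#'   (data.frame: implant, copy, start, end, strand, mismatches,
#'   mismatch_positions, seq_placed), and \code{attempts}.
#' @export
make_genome <- function(spec, chrom_name = "chr1") {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  total_len <- sum(vapply(
    spec$implants, function(im) (im$n_exact + im$n_1mm + im$n_2mm) * 25L, 0L
  ))
  if (total_len > spec$genome_length) {
    stop("implants cannot be placed without overlap in a genome of ",
         spec$genome_length, " bp")
  }
  for (attempt in 1:50) {
    chars <- .random_dna(spec$genome_length, spec$gc_fraction)
    truth <- list()
    occupied <- integer(0)
    ok <- TRUE
    for (ii in seq_along(spec$implants)) {
      im <- spec$implants[[ii]]
      base_chars <- strsplit(toupper(im$seq), "", fixed = TRUE)[[1L]]
      plan <- c(rep(0L, im$n_exact), rep(1L, im$n_1mm), rep(2L, im$n_2mm))
      for (ci in seq_along(plan)) {
        placed <- FALSE
        for (try in 1:200) {
          start <- sample.int(spec$genome_length - 22L, 1L)
          span <- start:(start + 22L)
          if (!any(span %in% occupied)) {
            mm <- plan[ci]
            if (mm == 0L) {
              copy <- base_chars; mm_pos <- integer(0)
            } else {
              mut <- .mutate_kmer(base_chars, mm)
              copy <- mut$chars; mm_pos <- mut$pos
            }
            chars[span] <- copy
            occupied <- c(occupied, span)
            truth[[length(truth) + 1L]] <- data.frame(
              implant = ii, copy = ci, start = start, end = start + 22L,
              strand = "+", mismatches = mm,
              mismatch_positions = paste(mm_pos, collapse = ","),
              seq_placed = paste(copy, collapse = ""),
              stringsAsFactors = FALSE
            )
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    chrom_seq <- paste(chars, collapse = "")
    truth <- do.call(rbind, truth)
    # verify no accidental extra <=1-mismatch placements
    expected <- vapply(seq_along(spec$implants), function(ii) {
      im <- spec$implants[[ii]]
      im$n_exact + im$n_1mm
    }, 0L)
    observed <- vapply(seq_along(spec$implants), function(ii) {
      .bf_place_count(toupper(spec$implants[[ii]]$seq), chrom_seq)
    }, 0L)
    if (all(observed == expected)) {
      recs <- chrom_seq
      names(recs) <- chrom_name
      return(list(genome = genome(recs), truth = truth,
                  attempts = attempt))
    }
  }
  stop("could not generate a genome free of accidental implant copies; ",
       "increase genome_length or change the seed")
}

#' Generate a VCF with variants at planned offsets
#'
#' REF alleles are taken from the generated genome so the file is internally
#' consistent; a SNP's ALT is the next base in A-C-G-T cyclic order, a
#' deletion's REF spans 3 genome bases, an insertion adds "AC" after the
#' anchor base.
#'
#' @param spec A \code{fixture_spec}.
#' @param fixture Output of \code{\link{make_genome}} for the same spec.
#' @return A list with \code{vcf_text} (VCF 4.2) and \code{truth}
#'   (data.frame: pos, id, kind, implant, offset, expected_dist — distance
#'   to the 3' end of the implant's first exact copy, NA for unanchored
#'   variants).
#' @export
make_vcf <- function(spec, fixture) {
  stopifnot(inherits(spec, "fixture_spec"))
  g <- fixture$genome
  chrom <- names(g$records)[1L]
  chrom_seq <- g$records[[chrom]]
  L <- nchar(chrom_seq)
  rows <- list()
  for (vi in seq_along(spec$variant_plan)) {
    vp <- spec$variant_plan[[vi]]
    kind <- match.arg(vp$kind, c("snp", "del", "ins"))
    if (!is.null(vp$implant)) {
      tt <- fixture$truth
      anchor <- tt[tt$implant == vp$implant & tt$mismatches == 0L, ][1L, ]
      stopifnot(vp$offset >= 1L, vp$offset <= 23L)
      pos <- anchor$start + vp$offset - 1L
      expected_dist <- anchor$end - pos   # "+" implants: 3' end = region end
      implant <- vp$implant; offset <- vp$offset
    } else {
      pos <- vp$pos
      expected_dist <- NA_integer_
      implant <- NA_integer_; offset <- NA_integer_
    }
    if (pos < 1L || pos > L) stop("variant position ", pos,
                                  " outside genome")
    ref_base <- substr(chrom_seq, pos, pos)
    if (kind == "snp") {
      cyc <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
      ref <- ref_base; alt <- cyc[[ref_base]]
    } else if (kind == "del") {
      if (pos + 2L > L) stop("deletion at ", pos, " runs off the genome")
      ref <- substr(chrom_seq, pos, pos + 2L); alt <- ref_base
    } else {
      ref <- ref_base; alt <- paste0(ref_base, "AC")
    }
    id <- if (!is.null(vp$id)) vp$id else sprintf("rsFIX%04d", vi)
    rows[[vi]] <- data.frame(pos = pos, id = id, ref = ref, alt = alt,
                             kind = kind, implant = implant,
                             offset = offset,
                             expected_dist = expected_dist,
                             stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(0), id = character(0), ref = character(0),
               alt = character(0), kind = character(0),
               implant = integer(0), offset = integer(0),
               expected_dist = integer(0), stringsAsFactors = FALSE)
  truth <- truth[order(truth$pos), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, L),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(truth)) {
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
            chrom, truth$pos, truth$id, truth$ref, truth$alt)
  } else character(0)
  list(vcf_text = paste(c(header, body, ""), collapse = "\n"),
       truth = truth)
}

#' The default end-to-end fixture specification
#'
#' A 50-kb background (GC 0.45) carrying three published human guide
#' sequences with PAMs: a unique PVALB-derived target that receives one SNP
#' 2 bp from its 3' end, an AAVS1-derived target with an extra 1-mismatch
#' copy (two mapping places), and a VEGFA-derived target with a 2-mismatch
#' copy that must stay outside the 1-mismatch budget.
#'
#' @param seed RNG seed (default 101).
#' @return A \code{fixture_spec}.
#' @export
default_fixture_spec <- function(seed = 101L) {
  fixture_spec(
    seed = seed, genome_length = 50000L, gc_fraction = 0.45,
    implants = list(
      list(seq = "ATTGGGTGTTCAGGGCAGAGTGG", n_exact = 1L, n_1mm = 0L,
           n_2mm = 0L),
      list(seq = "GGGGCCACTAGGGACAGGATCGG", n_exact = 1L, n_1mm = 1L,
           n_2mm = 0L),
      list(seq = "GACCCCCTCCACCCCGCCTCAGG", n_exact = 1L, n_1mm = 0L,
           n_2mm = 1L)
    ),
    variant_plan = list(
      list(implant = 1L, offset = 21L, kind = "snp", id = "rsFIXPVALB")
    )
  )
}

#' Build query records around a fixture's implanted targets
#'
#' Extracts the genomic neighbourhood of each implant's first exact copy
#' (with flanks) as query records, and also a single concatenated record
#' covering all implants for one-section ranking runs.
#'
#' @param fixture Output of \code{\link{make_genome}}.
#' @param flank Flank size in bp on each side (default 30).
#' @return List with \code{per_implant} (named character vector of query
#'   sequences), \code{anchors} (named vector of "chrom:start-end" strings),
#'   and \code{combined} (one unanchored concatenated sequence).
#' @export
fixture_queries <- function(fixture, flank = 30L) {
  g <- fixture$genome
  chrom <- names(g$records)[1L]
  L <- g$lengths[[chrom]]
  tt <- fixture$truth
  exact <- tt[tt$mismatches == 0L & !duplicated(tt$implant), , drop = FALSE]
  seqs <- character(0); anchors <- character(0)
  for (k in seq_len(nrow(exact))) {
    s <- max(1L, exact$start[k] - flank)
    e <- min(L, exact$end[k] + flank)
    qid <- sprintf("implant%d", exact$implant[k])
    seqs[qid] <- fetch(g, genomic_region(chrom, s, e, "+"))
    anchors[qid] <- sprintf("%s:%d-%d", chrom, s, e)
  }
  list(per_implant = seqs, anchors = anchors,
       combined = paste(seqs, collapse = ""))
}

#' Load the bundled reference set of published human guides
#'
#' Eight experimentally tested 20-nt guides against human PVALB, AAVS1 and
#' VEGFA, with their reported genomic places, overlapping-SNP counts,
#' loop-base counts, AT%, and editing efficiencies. Genomic coordinates and
#' rsIDs are carried as opaque display strings (they refer to hg19 /
#' dbSNP135 and are not re-derivable offline).
#'
#' @return A data.frame with one row per guide.
#' @export
load_reference_set <- function() {
  path <- system.file("extdata", "reference_guides.csv",
                      package = "gRNAdesign")
  if (!nzchar(path) || !file.exists(path)) {
    stop("bundled reference guide file is missing")
  }
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("gene", "guide", "genomic_places", "n_places", "n_snps",
              "bp_in_loops", "at_percent", "efficiency", "assay")
  if (nrow(ref) != 8L || !all(needed %in% names(ref)) ||
      any(nchar(ref$guide) != 20L)) {
    stop("bundled reference guide file is corrupt")
  }
  ref
}
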