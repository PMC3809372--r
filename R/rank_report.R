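# Step 5: assemble per-candidate scores (hits, variants, structure, AT%),
# rank, and render TSV/HTML reports; run_pipeline ties the stages together.

.primary_locus <- function(cand_row, hit_df) {
  # the candidate's own locus: the anchored region when known, otherwise the
  # best (first 0-mismatch, else first) hit
  if (!is.na(cand_row$g_start)) {
    return(genomic_region(cand_row$chrom, cand_row$g_start, cand_row$g_end,
                          cand_row$g_strand))
  }
  if (nrow(hit_df) == 0L) return(NULL)
  zero <- which(hit_df$mismatches == 0L)
  i <- if (length(zero)) zero[1L] else 1L
  genomic_region(hit_df$chrom[i], hit_df$start[i], hit_df$end[i],
                 hit_df$strand[i])
}

.variant_details <- function(ann) {
  if (nrow(ann) == 0L) return("")
  paste(sprintf("%s(%d bp to 3' end)", ann$id, ann$dist_3prime),
        collapse = ";")
}

#' Score candidate targets against a genome, variant set, and fold model
#'
#' For each candidate: genome-wide placements within the mismatch budget,
#' variants overlapping the candidate's own locus (off-target-locus variants
#' are kept per hit but not scored), the folded guide+scaffold structure with
#' sequestered/free guide-base counts, and AT%.
#'
#' @param candidates Output of \code{\link{scan_candidates}}, optionally
#'   anchored with \code{\link{map_to_genome}} (unanchored candidates use
#'   their best exact hit as their own locus).
#' @param g A \code{genome}.
#' @param index A \code{target_index} over \code{g}.
#' @param variants Optional \code{variant_table}; NULL leaves candidates
#'   unannotated (\code{n_variants = 0}, \code{unannotated = TRUE}).
#' @param fparams A \code{fold_params}.
#' @param sparams A \code{search_params}.
#' @param normalize_chr Passed to \code{\link{overlap_variants}}.
#' @return The candidates with columns \code{n_hits}, \code{truncated},
#'   \code{uniqueness}, \code{n_variants}, \code{variant_details},
#'   \code{loop_sequestered}, \code{loop_free}, \code{at_percent},
#'   \code{structure}, \code{unannotated}, plus list-columns \code{hits}
#'   and \code{hit_variants}.
#' @export
score_candidates <- function(candidates, g, index, variants = NULL,
                             fparams = fold_params(),
                             sparams = search_params(),
                             normalize_chr = FALSE) {
  if (!"g_start" %in% names(candidates)) {
    candidates <- map_to_genome(candidates, NULL)
  }
  n <- nrow(candidates)
  cols <- list(n_hits = integer(n), truncated = logical(n),
               uniqueness = character(n), n_variants = integer(n),
               variant_details = character(n),
               loop_sequestered = integer(n), loop_free = integer(n),
               at_percent = numeric(n), structure = character(n),
               unannotated = logical(n))
  hit_list <- vector("list", n)
  hitvar_list <- vector("list", n)
  fold_cache <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    cand <- candidates[i, , drop = FALSE]
    hs <- find_hits(cand$target_23mer, index, sparams)
    hit_list[[i]] <- hs$hits
    cols$n_hits[i] <- hs$n_hits_reported
    cols$truncated[i] <- hs$truncated
    cols$uniqueness[i] <- classify_uniqueness(hs)

    if (is.null(variants)) {
      cols$unannotated[i] <- TRUE
      hitvar_list[[i]] <- list()
    } else {
      per_hit <- lapply(seq_len(nrow(hs$hits)), function(k) {
        r <- genomic_region(hs$hits$chrom[k], hs$hits$start[k],
                            hs$hits$end[k], hs$hits$strand[k])
        overlap_variants(r, variants, normalize_chr = normalize_chr)
      })
      hitvar_list[[i]] <- per_hit
      own <- .primary_locus(cand, hs$hits)
      ann <- if (is.null(own)) {
        variants[integer(0), , drop = FALSE]
      } else {
        overlap_variants(own, variants, normalize_chr = normalize_chr)
      }
      cols$n_variants[i] <- count_snps(ann)
      cols$variant_details[i] <- .variant_details(ann)
    }

    key <- cand$guide
    db <- fold_cache[[key]]
    if (is.null(db)) {
      grna <- paste0(dna_to_rna(cand$guide), fparams$scaffold)
      db <- fold(grna, fparams)
      fold_cache[[key]] <- db
    }
    seq_n <- guide_loop_bases(db, 20L)
    cols$loop_sequestered[i] <- seq_n
    cols$loop_free[i] <- 20L - seq_n
    cols$structure[i] <- db$structure
    cols$at_percent[i] <- at_content(cand$guide)
  }
  for (nm in names(cols)) candidates[[nm]] <- cols[[nm]]
  candidates$hits <- hit_list
  candidates$hit_variants <- hitvar_list
  class(candidates) <- c("scored_candidates", "data.frame")
  candidates
}

#' Rank scored candidates
#'
#' Stable sort by, in order: number of mapping hits ascending with unmapped
#' candidates last ("hits"), overlapping variants at the candidate's own
#' locus ascending ("snps"), guide bases sequestered by structure ascending
#' ("loops"), AT% descending ("at" — a higher AT content is preferred), and
#' query position ascending ("start"). Keys beyond the first two are
#' extensions over the classic hits-then-SNPs sort and can be dropped via
#' \code{rank_keys} (e.g. \code{c("hits", "snps")} for the classic order).
#'
#' @param scored A \code{scored_candidates} data.frame.
#' @param rank_keys Character subset of
#'   \code{c("hits", "snps", "loops", "at", "start")}, in priority order.
#' @return The rows reordered with a \code{rank} column (1..N, no gaps).
#' @export
rank_candidates <- function(scored,
                            rank_keys = c("hits", "snps", "loops", "at",
                                          "start")) {
  stopifnot(is.data.frame(scored))
  bad <- setdiff(rank_keys, c("hits", "snps", "loops", "at", "start"))
  if (length(bad)) stop("unknown rank key(s): ", paste(bad, collapse = ", "))
  if (nrow(scored) == 0L) {
    scored$rank <- integer(0)
    return(scored)
  }
  keys <- list(
    hits = ifelse(scored$n_hits == 0L, Inf, scored$n_hits),
    snps = scored$n_variants,
    loops = scored$loop_sequestered,
    at = -scored$at_percent,
    start = scored$query_start
  )
  ord <- do.call(order, c(unname(keys[rank_keys]),
                          list(method = "radix")))
  scored <- scored[ord, , drop = FALSE]
  scored$rank <- seq_len(nrow(scored))
  rownames(scored) <- NULL
  scored
}

.REPORT_COLUMNS <- c("rank", "query_id", "query_start", "strand", "guide",
                     "pam", "genomic_region", "n_hits", "truncated",
                     "n_variants", "variant_details", "loop_sequestered",
                     "loop_free", "at_percent")

.report_table <- function(ranked) {
  genomic_region_str <- ifelse(
    is.na(ranked$g_start), ".",
    sprintf("%s:%d-%d(%s)", ranked$chrom, ranked$g_start, ranked$g_end,
            ranked$g_strand)
  )
  data.frame(
    rank = ranked$rank, query_id = ranked$query_id,
    query_start = ranked$query_start, strand = ranked$strand,
    guide = ranked$guide, pam = ranked$pam,
    genomic_region = genomic_region_str, n_hits = ranked$n_hits,
    truncated = ranked$truncated, n_variants = ranked$n_variants,
    variant_details = ranked$variant_details,
    loop_sequestered = ranked$loop_sequestered,
    loop_free = ranked$loop_free,
    at_percent = ranked$at_percent,
    stringsAsFactors = FALSE
  )
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a ranked candidate table as TSV or HTML text
#'
#' The TSV has one header row and the columns rank, query_id, query_start,
#' strand, guide, pam, genomic_region, n_hits, truncated, n_variants,
#' variant_details, loop_sequestered, loop_free, at_percent. The HTML report
#' shows the same table plus each candidate's full gRNA dot-bracket
#' structure.
#'
#' @param ranked Output of \code{\link{rank_candidates}} (possibly empty).
#' @param format "tsv" or "html".
#' @return A single string.
#' @export
render_report <- function(ranked, format = c("tsv", "html")) {
  format <- match.arg(format)
  if (nrow(ranked) == 0L) {
    tab <- data.frame(matrix(character(0), ncol = length(.REPORT_COLUMNS),
                             dimnames = list(NULL, .REPORT_COLUMNS)),
                      stringsAsFactors = FALSE)
  } else {
    tab <- .report_table(ranked)
  }
  if (format == "tsv") {
    header <- paste(.REPORT_COLUMNS, collapse = "\t")
    if (nrow(tab) == 0L) return(paste0(header, "\n"))
    body <- apply(tab, 1L, function(r) paste(trimws(r), collapse = "\t"))
    return(paste0(paste(c(header, body), collapse = "\n"), "\n"))
  }
  # html
  rows <- character(0)
  if (nrow(tab) > 0L) {
    for (i in seq_len(nrow(tab))) {
      cells <- paste0("<td>", .html_escape(trimws(unlist(tab[i, ]))),
                      "</td>", collapse = "")
      rows <- c(rows, paste0("<tr>", cells, "</tr>"))
      rows <- c(rows, sprintf(
        "<tr><td colspan=\"%d\"><pre>%s\n%s</pre></td></tr>",
        length(.REPORT_COLUMNS),
        .html_escape(paste0(dna_to_rna(ranked$guide[i]), "...")),
        .html_escape(ranked$structure[i])
      ))
    }
  }
  head_cells <- paste0("<th>", .REPORT_COLUMNS, "</th>", collapse = "")
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
    "<title>gRNA design report</title>",
    "<style>table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:2px 6px;",
    "font-family:monospace}</style></head>\n<body>\n",
    "<h1>Candidate guide RNAs</h1>\n<table>\n",
    "<tr>", head_cells, "</tr>\n",
    paste(rows, collapse = "\n"),
    "\n</table>\n</body></html>\n"
  )
}

#' Run the full guide-design pipeline
#'
#' Scan one or more query sequences for N20-NGG candidates, map them to the
#' reference genome at the mismatch budget, annotate overlapping variants,
#' fold guide+scaffold, rank, and render a report. With multiple query
#' records, candidates are ranked within each record (one report section per
#' record).
#'
#' @param query_fasta Path to the query FASTA (one or many records).
#' @param genome_fasta Path to the reference genome FASTA.
#' @param vcf Optional path to a VCF of known variants; NULL skips
#'   annotation.
#' @param out Optional output path; when given, the rendered report is
#'   written there.
#' @param format "tsv" or "html".
#' @param anchor Optional genomic anchor(s) for the query record(s): a
#'   single "chrom:start-end" string (single-record query) or a named
#'   character vector keyed by query record name.
#' @param sparams,fparams Search and fold parameters.
#' @param rank_keys Passed to \code{\link{rank_candidates}}.
#' @param normalize_chr Strip "chr" prefixes when matching VCF chromosomes.
#' @return Invisibly, the combined ranked \code{scored_candidates}
#'   data.frame (with a \code{rank} column per query section).
#' @export
run_pipeline <- function(query_fasta, genome_fasta, vcf = NULL, out = NULL,
                         format = c("tsv", "html"), anchor = NULL,
                         sparams = search_params(),
                         fparams = fold_params(),
                         rank_keys = c("hits", "snps", "loops", "at",
                                       "start"),
                         normalize_chr = FALSE) {
  format <- match.arg(format)
  g <- read_fasta(genome_fasta)
  queries <- read_fasta(query_fasta)
  variants <- if (is.null(vcf)) NULL else read_vcf(vcf)
  message("loaded ", length(queries$records), " query record(s), genome of ",
          length(g$records), " sequence(s)",
          if (!is.null(variants)) paste0(", ", nrow(variants), " variant(s)")
          else "")
  index <- build_index(g, sparams)
  sections <- list()
  for (qid in names(queries$records)) {
    qseq <- queries$records[[qid]]
    cands <- scan_candidates(qid, qseq)
    qanchor <- NULL
    if (!is.null(anchor)) {
      a <- if (length(anchor) == 1L && is.null(names(anchor))) anchor
           else unname(anchor[qid])
      if (!is.null(a) && !is.na(a)) qanchor <- parse_region(a)
    }
    cands <- map_to_genome(cands, qanchor, query_length = nchar(qseq))
    scored <- score_candidates(cands, g, index, variants,
                               fparams = fparams, sparams = sparams,
                               normalize_chr = normalize_chr)
    ranked <- rank_candidates(scored, rank_keys = rank_keys)
    message(qid, ": ", nrow(ranked), " candidate(s)")
    sections[[qid]] <- ranked
  }
  combined <- do.call(rbind, sections)
  if (is.null(combined)) combined <- rank_candidates(
    score_candidates(scan_candidates("empty", strrep("A", 23L)),
                     g, index, NULL, fparams, sparams))
  rownames(combined) <- NULL
  if (nrow(combined) == 0L) {
    warning("no candidate targets found in any query record")
  }
  if (!is.null(out)) {
    writeLines(render_report(combined, format), out, sep = "")
    message("report written to ", out)
  }
  invisible(combined)
}
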