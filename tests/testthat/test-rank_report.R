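scored_stub <- function(n_hits, n_variants, loop_seq = 5L, at = 50,
                        query_start = 1L, id = "q") {
  df <- data.frame(
    query_id = id, query_start = query_start,
    query_end = query_start + 22L, strand = "+",
    guide = strrep("A", 20), pam = "AGG",
    target_23mer = paste0(strrep("A", 20), "AGG"),
    chrom = NA_character_, g_start = NA_integer_, g_end = NA_integer_,
    g_strand = NA_character_,
    n_hits = n_hits, truncated = FALSE,
    uniqueness = ifelse(n_hits == 1L, "unique",
                        ifelse(n_hits == 0L, "unmapped", "multi")),
    n_variants = n_variants, variant_details = "",
    loop_sequestered = loop_seq, loop_free = 20L - loop_seq,
    at_percent = at, structure = strrep(".", 96),
    unannotated = FALSE, stringsAsFactors = FALSE
  )
  df$hits <- list(NULL)
  df$hit_variants <- list(NULL)
  df
}

test_that("ranking puts fewer SNPs first among equally unique candidates", {
  # three equally unique candidates with 0, 2 and 3 overlapping SNPs
  x <- rbind(scored_stub(1L, 3L, query_start = 1L),
             scored_stub(1L, 0L, query_start = 10L),
             scored_stub(1L, 2L, query_start = 20L))
  r <- rank_candidates(x)
  expect_identical(r$n_variants, c(0L, 2L, 3L))
  expect_identical(r$rank, 1:3)
})

test_that("mapping hits dominate SNP counts; unmapped candidates sort last", {
  x <- rbind(scored_stub(2L, 0L, query_start = 1L),
             scored_stub(1L, 5L, query_start = 10L),
             scored_stub(0L, 0L, query_start = 20L))
  r <- rank_candidates(x)
  expect_identical(r$n_hits, c(1L, 2L, 0L))
})

test_that("ranking is stable, idempotent, and extension keys can be dropped", {
  x <- rbind(scored_stub(1L, 1L, loop_seq = 9L, at = 30, query_start = 5L),
             scored_stub(1L, 1L, loop_seq = 6L, at = 45, query_start = 1L),
             scored_stub(1L, 1L, loop_seq = 6L, at = 45, query_start = 3L))
  r <- rank_candidates(x)
  # loops ascending, then AT descending, then query_start
  expect_identical(r$loop_sequestered, c(6L, 6L, 9L))
  expect_identical(r$query_start, c(1L, 3L, 5L))
  # idempotence
  r2 <- rank_candidates(r)
  expect_identical(r2$query_start, r$query_start)
  # classic two-key mode: full-key ties keep input order (stable sort)
  classic <- rank_candidates(x, rank_keys = c("hits", "snps"))
  expect_identical(classic$query_start, c(5L, 1L, 3L))
  expect_identical(classic$rank, 1:3)
  expect_error(rank_candidates(x, rank_keys = "banana"), "unknown rank key")
})

test_that("score_candidates ties hits, own-locus variants, folding and AT together", {
  set.seed(61)
  target <- "ATTGGGTGTTCAGGGCAGAGTGG"
  bg <- strsplit(random_dna(600), "", fixed = TRUE)[[1L]]
  bg[101:123] <- strsplit(target, "", fixed = TRUE)[[1L]]
  g <- genome(c(chrT = paste(bg, collapse = "")))
  idx <- build_index(g)
  anchor <- genomic_region("chrT", 81, 160, "+")
  cands <- map_to_genome(scan_candidates("q", fetch(g, anchor)), anchor,
                         query_length = 80L)
  cand <- cands[cands$target_23mer == target, ]
  expect_identical(nrow(cand), 1L)

  vcf <- tmp_text(c("##fileformat=VCFv4.2",
                    "#CHROM\tPOS\tID\tREF\tALT",
                    "chrT\t121\trs_own\tA\tG",
                    "chrT\t400\trs_far\tA\tG"), ".vcf")
  scored <- score_candidates(cand, g, idx, read_vcf(vcf))
  expect_identical(scored$n_hits, 1L)
  expect_identical(scored$uniqueness, "unique")
  expect_identical(scored$n_variants, 1L)
  expect_identical(scored$variant_details, "rs_own(2 bp to 3' end)")
  expect_identical(scored$at_percent, 45)
  expect_identical(scored$loop_sequestered + scored$loop_free, 20L)
  expect_false(scored$unannotated)

  # without a VCF the candidate is flagged unannotated
  bare <- score_candidates(cand, g, idx, NULL)
  expect_identical(bare$n_variants, 0L)
  expect_true(bare$unannotated)
})

test_that("TSV rendering follows the column contract and round-trips numerics", {
  x <- scored_stub(1L, 1L, loop_seq = 6L, at = 45)
  x$variant_details <- "rs_test(2 bp to 3' end)"
  x$chrom <- "chr22"; x$g_start <- 37196884L; x$g_end <- 37196906L
  x$g_strand <- "+"
  r <- rank_candidates(x)
  tsv <- render_report(r, "tsv")
  lines <- strsplit(tsv, "\n", fixed = TRUE)[[1L]]
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  expect_identical(header, c("rank", "query_id", "query_start", "strand",
                             "guide", "pam", "genomic_region", "n_hits",
                             "truncated", "n_variants", "variant_details",
                             "loop_sequestered", "loop_free", "at_percent"))
  parsed <- utils::read.delim(text = tsv, stringsAsFactors = FALSE)
  expect_identical(parsed$rank, 1L)
  expect_identical(parsed$genomic_region, "chr22:37196884-37196906(+)")
  expect_identical(parsed$variant_details, "rs_test(2 bp to 3' end)")
  expect_identical(parsed$n_hits, 1L)
  expect_identical(parsed$at_percent, 45L)
  expect_identical(parsed$loop_sequestered, 6L)

  # empty report is header-only
  empty <- render_report(rank_candidates(x[0, , drop = FALSE]), "tsv")
  expect_identical(strsplit(empty, "\n")[[1L]], lines[1L])
  expect_error(render_report(r, "pdf"))
})

test_that("HTML rendering carries the table and the dot-bracket structures", {
  x <- scored_stub(1L, 0L)
  html <- render_report(rank_candidates(x), "html")
  expect_match(html, "<table>")
  expect_match(html, strrep("\\.", 96))
  expect_match(html, "loop_sequestered")
})

test_that("run_pipeline is an end-to-end batch run with per-record sections", {
  set.seed(62)
  bg <- strsplit(random_dna(3000), "", fixed = TRUE)[[1L]]
  t1 <- "ATTGGGTGTTCAGGGCAGAGTGG"
  t2 <- "GGGGCCACTAGGGACAGGATCGG"
  bg[501:523] <- strsplit(t1, "", fixed = TRUE)[[1L]]
  bg[1501:1523] <- strsplit(t2, "", fixed = TRUE)[[1L]]
  g <- genome(c(chr1 = paste(bg, collapse = "")))
  gf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, gf)
  qf <- tmp_text(c(">geneA", fetch(g, genomic_region("chr1", 481, 543, "+")),
                   ">geneB", fetch(g, genomic_region("chr1", 1481, 1543, "+")),
                   ">geneC", strrep("AT", 20)), ".fa")
  out <- withr::local_tempfile(fileext = ".tsv")
  res <- suppressMessages(run_pipeline(
    qf, gf, out = out,
    anchor = c(geneA = "chr1:481-543", geneB = "chr1:1481-1543")
  ))
  tab <- utils::read.delim(out, stringsAsFactors = FALSE)
  expect_identical(sort(unique(tab$query_id)), c("geneA", "geneB"))
  # ranks restart at 1 within each record section
  for (qid in unique(tab$query_id)) {
    expect_identical(sort(tab$rank[tab$query_id == qid]),
                     seq_len(sum(tab$query_id == qid)))
  }
  expect_true(all(tab$truncated == FALSE))
  # without a VCF every row is unannotated with zero variants
  expect_true(all(tab$n_variants == 0L))
  expect_true(all(res$unannotated))
  # implanted guides are present and anchored
  expect_true("ATTGGGTGTTCAGGGCAGAG" %in% tab$guide)
  expect_true(any(grepl("chr1:501-523", tab$genomic_region)))
})
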