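make_implanted_genome <- function(bg_len, implant_seqs_positions, seed) {
  # implant_seqs_positions: list of list(seq=..., pos=...)
  set.seed(seed)
  chars <- strsplit(random_dna(bg_len), "", fixed = TRUE)[[1L]]
  for (ip in implant_seqs_positions) {
    chars[ip$pos:(ip$pos + nchar(ip$seq) - 1L)] <-
      strsplit(ip$seq, "", fixed = TRUE)[[1L]]
  }
  genome(c(chr1 = paste(chars, collapse = "")))
}

mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
  }
  paste(ch, collapse = "")
}

test_that("find_hits recovers implanted exact and 1-mismatch copies, not 2-mismatch ones", {
  q <- "ATTGGGTGTTCAGGGCAGAGTGG"
  g <- make_implanted_genome(5000, list(
    list(seq = q, pos = 1000L),
    list(seq = mutate_at(q, 7L), pos = 2500L),
    list(seq = mutate_at(q, c(3L, 15L)), pos = 4000L)
  ), seed = 31)
  idx <- build_index(g)
  hs <- find_hits(q, idx)
  expect_identical(hs$n_hits_reported, 2L)
  expect_false(hs$truncated)
  expect_identical(hs$hits$start, c(1000L, 2500L))
  expect_identical(hs$hits$mismatches, c(0L, 1L))
  expect_identical(hs$hits$mismatch_positions[[2L]], 7L)
  # cross-check both placements against an independent sliding scan
  expect_identical(hit_key(hs$hits), hit_key(slide_find_hits(q, g, 1L)))

  # at mismatch budget 0 only the exact copy remains (monotone subset)
  idx0 <- build_index(g, search_params(max_mismatches = 0L))
  hs0 <- find_hits(q, idx0, search_params(max_mismatches = 0L))
  expect_identical(hs0$hits$start, 1000L)
  expect_true(all(hit_key(hs0$hits) %in% hit_key(hs$hits)))
})

test_that("the reporting cap truncates deterministically", {
  q <- "ATTGGGTGTTCAGGGCAGAGTGG"
  g <- make_implanted_genome(
    2000, lapply(seq(1, 12) * 150L, function(p) list(seq = q, pos = p)),
    seed = 32
  )
  idx <- build_index(g)
  hs <- find_hits(q, idx)
  expect_identical(hs$n_hits_reported, 10L)
  expect_true(hs$truncated)
  # first max_hits placements in (mismatches, chrom, start, strand) order
  full <- find_hits(q, idx, search_params(max_hits = 1000L))
  expect_identical(hs$hits$start, full$hits$start[1:10])
  expect_identical(full$n_hits_reported, 12L)
})

test_that("uniqueness classification follows the hit count and cap", {
  q <- "ATTGGGTGTTCAGGGCAGAGTGG"
  g1 <- make_implanted_genome(3000, list(list(seq = q, pos = 500L)), 33)
  expect_identical(classify_uniqueness(find_hits(q, build_index(g1))),
                   "unique")
  g2 <- make_implanted_genome(3000, list(list(seq = q, pos = 500L),
                                         list(seq = q, pos = 1500L)), 34)
  expect_identical(classify_uniqueness(find_hits(q, build_index(g2))),
                   "multi")
  hs0 <- find_hits(q, build_index(make_implanted_genome(100, list(), 35)))
  expect_identical(classify_uniqueness(hs0), "unmapped")
  # cap of 1 with 2 placements present is not "unique"
  hs_cap <- find_hits(q, build_index(g2), search_params(max_hits = 1L))
  expect_identical(hs_cap$n_hits_reported, 1L)
  expect_true(hs_cap$truncated)
  expect_identical(classify_uniqueness(hs_cap), "multi")
})

test_that("input validation: length, N content, budget exceeding the index", {
  g <- genome(c(chr1 = random_dna(200)))
  idx <- build_index(g)
  expect_error(find_hits("ACGT", idx), "23")
  expect_error(find_hits(paste0(strrep("A", 22), "N"), idx), "no N")
  expect_error(find_hits(strrep("A", 23), idx,
                         search_params(max_mismatches = 2L)),
               "rebuild")
  expect_error(build_index(genome(c(chr1 = ""))), regexp = ".")
})

test_that("hits on the reverse complement are the strand-flipped hits of the query", {
  set.seed(36)
  for (k in 1:10) {
    g <- genome(c(chr1 = random_dna(800)))
    q <- substr(g$records[["chr1"]], 300, 322)
    idx <- build_index(g)
    a <- find_hits(q, idx)$hits
    b <- find_hits(reverse_complement(q), idx)$hits
    expect_identical(nrow(a), nrow(b))
    flip <- function(s) ifelse(s == "+", "-", "+")
    expect_identical(
      sort(sprintf("%s:%d:%s:%d", a$chrom, a$start, a$strand,
                   a$mismatches)),
      sort(sprintf("%s:%d:%s:%d", b$chrom, b$start, flip(b$strand),
                   b$mismatches))
    )
  }
})

test_that("engine agrees with the brute-force oracle on randomized genomes (with N and multi-chrom)", {
  set.seed(37)
  for (k in 1:120) {
    n_chrom <- sample(1:2, 1)
    recs <- vapply(seq_len(n_chrom), function(i) {
      s <- random_dna(sample(60:900, 1), gc = runif(1, 0.25, 0.75))
      if (runif(1) < 0.3) {  # sprinkle N into the genome
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        ch[sample(seq_along(ch), max(1L, length(ch) %/% 50))] <- "N"
        s <- paste(ch, collapse = "")
      }
      s
    }, "")
    names(recs) <- paste0("c", seq_len(n_chrom))
    g <- genome(recs)
    q <- if (runif(1) < 0.5) {
      # extract a window so self-hits are guaranteed (skip if it has N)
      s <- recs[[1L]]
      st <- sample(nchar(s) - 22L, 1)
      w <- substr(s, st, st + 22L)
      if (grepl("N", w, fixed = TRUE)) random_dna(23) else w
    } else {
      random_dna(23)
    }
    m <- sample(0:1, 1)
    idx <- build_index(g, search_params(max_mismatches = m))
    got <- find_hits(q, idx,
                     search_params(max_mismatches = m, max_hits = 100000L))
    expect_identical(hit_key(got$hits), hit_key(bf_find_hits(q, g, m)))
  }
})

test_that("every candidate scanned from a genome-anchored query finds its own locus exactly", {
  set.seed(38)
  g <- genome(c(chr1 = random_dna(4000, gc = 0.55)))
  idx <- build_index(g)
  anchor <- genomic_region("chr1", 1001, 1400, "+")
  qseq <- fetch(g, anchor)
  cands <- map_to_genome(scan_candidates("q", qseq), anchor,
                         query_length = 400L)
  expect_gt(nrow(cands), 0L)
  for (i in seq_len(nrow(cands))) {
    hs <- find_hits(cands$target_23mer[i], idx)
    self <- hs$hits$start == cands$g_start[i] &
      hs$hits$strand == cands$g_strand[i] & hs$hits$mismatches == 0L
    expect_true(any(self))
  }
})
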