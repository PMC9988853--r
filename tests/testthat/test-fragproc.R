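# PAF parsing and the overlap-merge / pass-merge / annotation / filter rules.

paf_line <- function(qname = "r1", qlen = 1000, qs = 0, qe = 500,
                     strand = "+", tname = "chr1", tlen = 8e6, ts = 1000,
                     te = 1500, mapq = 60) {
  paste(qname, qlen, qs, qe, strand, tname, tlen, ts, te, qe - qs, qe - qs,
        mapq, sep = "\t")
}

test_that("parse_paf parses, groups and skips malformed lines", {
  p <- parse_paf(paf_line())
  expect_equal(nrow(p$fragments), 1L)
  expect_equal(p$n_skipped, 0L)
  # end <= start is skipped and counted
  p2 <- parse_paf(c(paf_line(), paf_line(ts = 2000, te = 2000)))
  expect_equal(nrow(p2$fragments), 1L)
  expect_equal(p2$n_skipped, 1L)
  # 3 lines, 2 read names -> 2 groups
  p3 <- parse_paf(c(paf_line("a"), paf_line("a", qs = 500, qe = 900),
                    paf_line("b")))
  expect_equal(length(unique(p3$fragments$read_id)), 2L)
  expect_error(parse_paf(paf_line(ts = 10, te = 10)), "no parseable")
})

test_that("coincident overlapping fragments merge; dislocated ones drop the shorter", {
  base <- function(rs, re, ts, te, chrom = "chr1", strand = "+", mapq = 60L) {
    data.table::data.table(read_id = "r", read_start = rs, read_end = re,
                           chrom = chrom, start = ts, end = te,
                           strand = strand, mapq = mapq,
                           frag_class = NA_character_, pass = "primary")
  }
  # same strand, genomic positions dislocated 30 bp (< 50) -> merged
  fr <- rbind(base(0L, 500L, 1000L, 1500L),
              base(400L, 900L, 1430L, 1930L, mapq = 30L))
  m <- merge_overlapping_fragments(fr)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1000L)
  expect_equal(m$end, 1930L)
  expect_equal(m$read_start, 0L)
  expect_equal(m$read_end, 900L)
  expect_equal(m$mapq, 60L)   # max of inputs
  # dislocated 60 bp (> 50) -> shorter read span dropped
  fr2 <- rbind(base(0L, 900L, 1000L, 1900L),
               base(500L, 900L, 1560L, 1960L))
  m2 <- merge_overlapping_fragments(fr2)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$read_end - m2$read_start, 900L)
  # different chromosomes, read spans 900 and 400 -> the 400 bp one dropped
  fr3 <- rbind(base(0L, 900L, 1000L, 1900L),
               base(300L, 700L, 5000L, 5400L, chrom = "chr2"))
  m3 <- merge_overlapping_fragments(fr3)
  expect_equal(m3$chrom, "chr1")
  # non-overlapping fragments untouched
  fr4 <- rbind(base(0L, 400L, 1000L, 1400L),
               base(400L, 800L, 3000L, 3400L))
  expect_equal(nrow(merge_overlapping_fragments(fr4)), 2L)
})

test_that("overlap merging matches the brute-force oracle and is idempotent", {
  set.seed(99)
  for (rep in 1:400) {
    df <- random_read_frags("r", sample(2:5, 1))
    got <- as.data.frame(merge_overlapping_fragments(df))
    want <- oracle_merge_one_read(df)
    key <- function(x) {
      x <- x[order(x$read_start, x$start), ]
      paste(x$read_start, x$read_end, x$chrom, x$start, x$end, x$strand,
            x$mapq, collapse = ";")
    }
    expect_equal(key(got), key(want))
    # idempotence
    again <- as.data.frame(merge_overlapping_fragments(got))
    expect_equal(key(again), key(got))
  }
})

test_that("gap-pass fragments are accepted only in unaligned read space", {
  prim <- parse_paf(paf_line(qs = 0, qe = 500))$fragments
  gap_inside <- parse_paf(paf_line(qs = 600, qe = 900, ts = 5000, te = 5300),
                          pass = "gap")$fragments
  gap_covered <- parse_paf(paf_line(qs = 100, qe = 400, ts = 5000, te = 5300),
                           pass = "gap")$fragments
  expect_equal(nrow(merge_alignment_passes(prim, gap_inside)), 2L)
  expect_equal(nrow(merge_alignment_passes(prim, gap_covered)), 1L)
  # small random cases vs interval-overlap oracle
  set.seed(7)
  for (rep in 1:100) {
    p <- random_read_frags("r", 2)
    g <- random_read_frags("r", 2)
    g$pass <- "gap"
    got <- merge_alignment_passes(data.table::as.data.table(p),
                                  data.table::as.data.table(g))
    keep <- vapply(seq_len(nrow(g)), function(i) {
      all(pmin(p$read_end, g$read_end[i]) -
            pmax(p$read_start, g$read_start[i]) <= 50)
    }, logical(1))
    expect_equal(nrow(got), nrow(p) + sum(keep))
  }
})

test_that("extract_gaps returns the complement of the aligned union", {
  fr <- data.frame(read_start = 100L, read_end = 200L)
  g <- extract_gaps(300L, fr, min_gap = 50)
  expect_equal(g$start, c(0L, 200L))
  expect_equal(g$end, c(100L, 300L))
  # full coverage -> empty
  expect_equal(nrow(extract_gaps(200L, data.frame(read_start = 0L,
                                                  read_end = 200L))), 0L)
  # random layouts vs complement-of-union oracle
  set.seed(17)
  for (rep in 1:100) {
    k <- sample(1:4, 1)
    rs <- sort(sample.int(900, k))
    fr <- data.frame(read_start = rs,
                     read_end = pmin(rs + sample(50:300, k, TRUE), 1000L))
    got <- extract_gaps(1000L, fr, min_gap = 20)
    covered <- rep(FALSE, 1000)
    for (i in seq_len(k)) covered[(fr$read_start[i] + 1):fr$read_end[i]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    want <- data.frame(start = starts[!r$values], end = ends[!r$values])
    want <- want[want$end - want$start >= 20, ]
    expect_equal(got$start, as.integer(want$start))
    expect_equal(got$end, as.integer(want$end))
  }
})

test_that("restriction annotation classifies ends within 30 bp of boundaries", {
  cfg <- sim_config(chromosomes = data.frame(name = "c1", length = 10000))
  g <- build_genome(cfg, fasta = c(c1 = paste0(
    paste(rep("A", 2000), collapse = ""), "GATC",
    paste(rep("A", 2000), collapse = ""), "GATC",
    paste(rep("A", 5992), collapse = ""))))
  # sites at 2000 and 4004
  fr <- data.table::data.table(
    read_id = "r", read_start = c(0L, 300L, 600L),
    read_end = c(300L, 600L, 900L), chrom = "c1",
    start = c(2000L, 2010L, 2031L), end = c(4004L, 4030L, 3000L),
    strand = "+", mapq = 60L, frag_class = NA_character_, pass = "primary")
  ann <- annotate_restriction(fr, g)
  expect_equal(ann$frag_class,
               c("both_ends_matched", "both_ends_matched", "unmatched"))
  # one end 31 bp away -> one_end_matched
  fr2 <- data.table::copy(fr[1])[, `:=`(start = 2000L, end = 4035L)]
  expect_equal(annotate_restriction(fr2, g)$frag_class, "one_end_matched")
  expect_error(annotate_restriction(
    data.table::copy(fr)[, chrom := "nope"], g), "missing")
  # random fragments vs nearest-boundary oracle
  set.seed(5)
  b <- c(0, sort(sample.int(9999, 40)), 10000)
  g$sites$c1 <- as.integer(b[-c(1, length(b))])
  rnd <- data.table::data.table(
    read_id = "r", read_start = 0L, read_end = 100L, chrom = "c1",
    start = sample.int(9000, 300), strand = "+", mapq = 60L,
    frag_class = NA_character_, pass = "primary")
  rnd[, end := start + sample.int(900, 300)]
  ann2 <- annotate_restriction(rnd, g)
  want <- mapply(oracle_frag_class, rnd$start, rnd$end,
                 MoreArgs = list(boundaries = b))
  expect_equal(ann2$frag_class, unname(want))
})

test_that("mapq filter drops only low-mapq fragments without match ends", {
  fr <- data.table::data.table(
    read_id = "r", mapq = c(5L, 5L, 60L, 9L, 10L),
    frag_class = c("unmatched", "one_end_matched", "unmatched",
                   "both_ends_matched", "unmatched"))
  kept <- filter_fragments(fr)
  expect_equal(kept$mapq, c(5L, 60L, 9L, 10L))
  # monotonicity: raising min_mapq never increases the surviving count
  set.seed(3)
  rnd <- data.table::data.table(
    read_id = "r", mapq = sample(0:60, 500, TRUE),
    frag_class = sample(c("unmatched", "one_end_matched",
                          "both_ends_matched"), 500, TRUE))
  n_prev <- Inf
  for (mq in c(0, 5, 10, 30, 61)) {
    n <- nrow(filter_fragments(rnd, min_mapq = mq))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("multiway assembly sorts by read position and records order", {
  fr <- data.table::data.table(
    read_id = c("a", "a", "a", "a", "b"),
    read_start = c(300L, 0L, 600L, 900L, 0L),
    read_end = c(600L, 300L, 900L, 1200L, 100L),
    chrom = "chr1", start = 1L, end = 2L, strand = "+", mapq = 60L,
    frag_class = "both_ends_matched", pass = "primary")
  mw <- assemble_multiway(fr)
  expect_equal(mw[read_id == "a", n], rep(4L, 4))
  expect_equal(mw[read_id == "a", read_start], c(0L, 300L, 600L, 900L))
  expect_false(mw[read_id == "b", informative][1])
  expect_equal(nrow(assemble_multiway(fr[0])), 0L)
})

test_that("noiseless simulation round-trips exactly through the pipeline", {
  mw <- process_paf(fix_noiseless$paf, NULL, fix_genome)
  tf <- fix_noiseless$truth_fragments
  got <- as.data.frame(mw[order(read_id, frag_index),
                          c("read_id", "frag_index", "chrom", "start", "end",
                            "strand")])
  want <- as.data.frame(tf[order(read_id, frag_index),
                           c("read_id", "frag_index", "chrom", "start", "end",
                             "strand")])
  expect_equal(got, want, ignore_attr = TRUE)
  expect_true(all(mw$frag_class == "both_ends_matched"))
  # order statistics equal the truth orders
  orders <- mw[, .N, by = read_id]
  tr <- fix_noiseless$truth_reads
  expect_equal(orders$N[match(tr$read_id, orders$read_id)], tr$n)
})

test_that("split alignments and gap-pass withholding are reconstructed", {
  cfg <- sim_config(chromosomes = fix_config$chromosomes, n_reads = 250,
                    split_rate = 0.4, jitter_sd = 0, low_mapq_rate = 0,
                    gap_pass_rate = 0.2)
  s <- simulate_reads(fix_genome, fix_arch, cfg, seed = 55)
  mw <- process_paf(s$paf, s$gap_paf, fix_genome)
  got <- as.data.frame(mw[order(read_id, frag_index),
                          c("read_id", "frag_index", "chrom", "start", "end",
                            "strand")])
  want <- as.data.frame(s$truth_fragments[
    order(read_id, frag_index),
    c("read_id", "frag_index", "chrom", "start", "end", "strand")])
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("multiway TSV writer and reader round-trip", {
  mw <- truth_as_multiway(fix_noiseless)
  tmp <- tempfile(fileext = ".tsv")
  n <- write_multiway_tsv(mw, tmp)
  expect_equal(n, nrow(mw))
  back <- read_multiway_tsv(tmp)
  expect_equal(back$start, mw$start)
  expect_equal(back$read_id, mw$read_id)
  unlink(tmp)
})
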