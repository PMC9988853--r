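# Pair decomposition, juicer medium output, binning, balancing,
# compartment eigenvector, insulation, distance profiles.

test_that("decomposition yields C(n,2) pairs with n-1 adjacent", {
  mw2 <- mw_from_mids(list(list(read_id = "a", chrom = c("chr1", "chr1"),
                                mid = c(1000, 5000))))
  p2 <- decompose_pairwise(mw2)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$adjacency, "adj")
  mw5 <- mw_from_mids(list(list(
    read_id = "a", chrom = rep("chr1", 5),
    mid = c(1e4, 5e4, 2e4, 9e4, 3e4))))
  p5 <- decompose_pairwise(mw5)
  expect_equal(nrow(p5), 10L)
  expect_equal(sum(p5$adjacency == "adj"), 4L)
  expect_equal(sum(p5$adjacency == "nonadj"), 6L)
  # n < 2 -> empty
  mw1 <- mw_from_mids(list(list(read_id = "a", chrom = "chr1", mid = 100)))
  expect_message(p1 <- decompose_pairwise(mw1), "no reads")
  expect_equal(nrow(p1), 0L)
})

test_that("pooled pair count matches enumeration and partitions adj/nonadj", {
  mw <- truth_as_multiway(fix_noiseless)
  pr <- decompose_pairwise(mw)
  ns <- fix_noiseless$truth_reads$n
  expect_equal(nrow(pr), sum(choose(ns, 2)))
  expect_equal(sum(pr$adjacency == "adj"), sum(pmax(ns - 1L, 0L)))
  # per read |adj| = n-1, |pairs| = C(n,2)
  per <- pr[, list(adj = sum(adjacency == "adj"), tot = .N), by = read_id]
  nn <- mw[, list(n = n[1]), by = read_id]
  m <- merge(per, nn, by = "read_id")
  expect_true(all(m$adj == m$n - 1L))
  expect_true(all(m$tot == choose(m$n, 2)))
  # trans flag iff chromosomes differ, ends canonically ordered
  expect_equal(pr$trans, pr$chrom1 != pr$chrom2)
  same <- pr$chrom1 == pr$chrom2
  expect_true(all(pr$pos1[same] <= pr$pos2[same]))
})

test_that("juicer medium writer emits the 11-field convention and round-trips", {
  mw <- mw_from_mids(list(list(read_id = "a", chrom = c("chr1", "chr2"),
                               mid = c(1000, 2000))))
  mw$strand <- c("+", "-")
  pr <- decompose_pairwise(mw)
  tmp <- tempfile()
  n <- write_pairs_medium(pr, tmp, genome = fix_genome)
  expect_equal(n, 1L)
  fields <- strsplit(readLines(tmp), " ")[[1]]
  expect_length(fields, 11L)
  # strand encoding 0/16 and 1-based positions
  expect_equal(as.integer(fields[c(2, 6)]), c(0L, 16L))
  expect_equal(as.integer(fields[4]), pr$pos1 + 1L)
  # frag field = restriction fragment index
  expect_equal(as.integer(fields[5]),
               fragment_index(fix_genome, pr$chrom1, pr$pos1))
  back <- read_pairs_medium(tmp)
  expect_equal(back$pos1, pr$pos1)
  expect_equal(back$strand2, pr$strand2)
  unlink(tmp)
  # larger round trip preserves the pair multiset
  mwb <- truth_as_multiway(fix_noiseless)
  prb <- decompose_pairwise(mwb)
  tmp2 <- tempfile()
  write_pairs_medium(prb, tmp2)
  bb <- read_pairs_medium(tmp2)
  key <- function(x) sort(paste(x$chrom1, x$pos1, x$chrom2, x$pos2))
  expect_equal(key(bb), key(prb))
  unlink(tmp2)
})

test_that("binning conserves mass and matches a histogram oracle", {
  pr <- data.table::data.table(
    read_id = "a", chrom1 = "chr1", pos1 = 1000L, strand1 = "+", mapq1 = 60L,
    chrom2 = "chr1", pos2 = 99000L, strand2 = "+", mapq2 = 60L,
    adjacency = "adj", trans = FALSE)
  cm <- bin_pairs(pr, data.frame(name = "chr1", length = 2e5), 5e4)
  expect_equal(as.numeric(cm$mat[1, 2]), 1)
  expect_equal(sum(cm$mat), 1)
  # random pairs vs direct tabulation
  set.seed(23)
  n <- 500
  p1 <- sample.int(2e5, n) - 1L
  p2 <- sample.int(2e5, n) - 1L
  prs <- data.table::data.table(
    read_id = "r", chrom1 = "chr1", pos1 = pmin(p1, p2), strand1 = "+",
    mapq1 = 60L, chrom2 = "chr1", pos2 = pmax(p1, p2), strand2 = "+",
    mapq2 = 60L, adjacency = "adj", trans = FALSE)
  cm2 <- bin_pairs(prs, data.frame(name = "chr1", length = 2e5), 5e4)
  expect_equal(sum(cm2$mat), n)
  want <- table(paste(pmin(p1 %/% 5e4, p2 %/% 5e4),
                      pmax(p1 %/% 5e4, p2 %/% 5e4)))
  got <- Matrix::summary(cm2$mat)
  got_key <- paste(got$i - 1L, got$j - 1L)
  expect_equal(sort(got_key), sort(names(want)))
  expect_equal(got$x[match(names(want), got_key)], as.numeric(want))
})

test_that("iterative correction flattens row sums", {
  # already-uniform matrix -> equal weights
  pr <- data.table::CJ(i = 0:3, j = 0:3)[i <= j]
  prs <- data.table::data.table(
    read_id = "r", chrom1 = "chr1", pos1 = as.integer(pr$i * 1e4 + 5),
    strand1 = "+", mapq1 = 60L, chrom2 = "chr1",
    pos2 = as.integer(pr$j * 1e4 + 5), strand2 = "+", mapq2 = 60L,
    adjacency = "adj", trans = FALSE)
  cm <- bin_pairs(prs, data.frame(name = "chr1", length = 4e4), 1e4)
  cm$mat <- Matrix::Matrix(upper.tri(matrix(1, 4, 4), diag = TRUE) * 1,
                           sparse = TRUE)
  b <- balance_ic(cm)
  expect_equal(stats::sd(b$weights), 0, tolerance = 1e-8)
  # 4x4 hand matrix vs an independent fixed-point iteration
  M <- matrix(c(4, 2, 1, 0,
                2, 6, 3, 1,
                1, 3, 8, 2,
                0, 1, 2, 5), 4, 4)
  cm$mat <- Matrix::Matrix(M * upper.tri(M, diag = TRUE), sparse = TRUE)
  cm$weights <- NULL
  b2 <- balance_ic(cm, max_iter = 2000, tol = 1e-12)
  W <- M * outer(b2$weights, b2$weights)
  expect_lt(stats::sd(rowSums(W)) / mean(rowSums(W)), 1e-8)
  expect_equal(mean(rowSums(W)), 1, tolerance = 1e-6)
  # oracle: plain power iteration on the same update rule
  bb <- rep(1, 4); MM <- M
  for (it in 1:2000) {
    d <- rowSums(MM) / mean(rowSums(MM))
    MM <- MM / outer(d, d)
    bb <- bb * d
  }
  w_oracle <- 1 / (bb * sqrt(mean(rowSums(MM))))
  expect_equal(b2$weights, w_oracle, tolerance = 1e-8)
})

test_that("eigenvector recovers a planted checkerboard and obeys the marker", {
  nb <- 40
  lab <- rep(c(1, -1), nb / 2)
  M <- (outer(lab, lab) + 3) * 25   # same-label 100, cross 50
  cm <- structure(list(
    bins = data.table::data.table(chrom = "chr1",
                                  start = as.integer((0:(nb - 1)) * 1e5),
                                  end = as.integer((1:nb) * 1e5),
                                  bin_id = 1:nb),
    mat = Matrix::Matrix(M * upper.tri(M, diag = TRUE), sparse = TRUE),
    resolution = 1e5, weights = NULL), class = "contact_matrix")
  marker <- ifelse(lab > 0, 5, 1)
  ev <- eigenvector_compartments(cm, marker = marker)
  expect_gte(mean(sign(ev$score) == lab), 0.95)
  # flipping the marker track flips all signs
  ev2 <- eigenvector_compartments(cm, marker = -marker)
  expect_equal(ev2$score, -ev$score)
  # constant matrix is flagged degenerate
  cmc <- cm
  cmc$mat <- Matrix::Matrix(upper.tri(matrix(1, nb, nb), diag = TRUE) * 1,
                            sparse = TRUE)
  evc <- eigenvector_compartments(cmc)
  expect_true(all(evc$degenerate))
  expect_true(all(is.na(evc$score)))
  # short chromosome skipped with warning
  cms <- cm
  cms$bins <- cms$bins[1:5][, bin_id := 1:5]
  cms$mat <- cm$mat[1:5, 1:5]
  expect_warning(eigenvector_compartments(cms), "skipped")
})

test_that("insulation is zero on uniform matrices and matches a window oracle", {
  nb <- 30
  M <- matrix(4, nb, nb)
  cm <- structure(list(
    bins = data.table::data.table(chrom = "chr1",
                                  start = as.integer((0:(nb - 1)) * 5e4),
                                  end = as.integer((1:nb) * 5e4),
                                  bin_id = 1:nb),
    mat = Matrix::Matrix(M * upper.tri(M, diag = TRUE), sparse = TRUE),
    resolution = 5e4, weights = NULL), class = "contact_matrix")
  ins <- insulation_scores(cm, windows = c(2, 5, 10))
  expect_true(all(abs(ins$score[!is.na(ins$score)]) < 1e-10))
  # edge bins masked
  w2 <- ins[ins$window == 2]
  expect_true(all(is.na(w2$score[c(1, 2, nb - 1, nb)])))
  # hand 6x6 matrix vs direct window sums
  H <- matrix(c(9, 5, 1, 1, 0, 0,
                5, 8, 4, 1, 1, 0,
                1, 4, 9, 2, 1, 1,
                1, 1, 2, 7, 5, 2,
                0, 1, 1, 5, 8, 4,
                0, 0, 1, 2, 4, 9), 6, 6, byrow = TRUE)
  cmh <- structure(list(
    bins = data.table::data.table(chrom = "chr1",
                                  start = as.integer((0:5) * 5e4),
                                  end = as.integer((1:6) * 5e4),
                                  bin_id = 1:6),
    mat = Matrix::Matrix(H * upper.tri(H, diag = TRUE), sparse = TRUE),
    resolution = 5e4, weights = rep(1, 6)), class = "contact_matrix")
  insh <- insulation_scores(cmh, windows = 2)
  raw <- rep(NA_real_, 6)
  for (i in 3:4) raw[i] <- mean(H[(i - 2):(i - 1), (i + 1):(i + 2)])
  want <- log2(raw / mean(raw, na.rm = TRUE))
  expect_equal(insh$score, want, tolerance = 1e-10)
  # a planted TAD boundary is a local insulation minimum
  blocks <- rep(1:3, each = 10)
  Mt <- (outer(blocks, blocks, "==") * 6 + 1) * 10
  cmt <- cm
  cmt$mat <- Matrix::Matrix(Mt * upper.tri(Mt, diag = TRUE), sparse = TRUE)
  cmt$weights <- NULL
  inst <- insulation_scores(cmt, windows = 5)
  sc <- inst$score
  for (b in c(10, 20)) {
    inside <- min(sc[c(b, b + 1)])
    expect_lt(inside, sc[b - 2])
    expect_lt(inside, sc[b + 3])
  }
})

test_that("distance profiles compute cover/adjacent/separated correctly", {
  mw <- mw_from_mids(list(list(read_id = "a", chrom = rep("chr1", 3),
                               mid = c(1e4, 5e5, 1.2e6))))
  dp <- distance_profiles(mw)
  expect_equal(dp$reads$cover, 1.19e6)
  d <- dp$distances
  expect_setequal(d[d$type == "adjacent", distance], c(4.9e5, 7e5))
  expect_equal(d[d$type == "separated", distance], 1.19e6)
  # all-trans read -> empty distances
  mwt <- mw_from_mids(list(list(read_id = "t", chrom = c("chr1", "chr2"),
                                mid = c(1e4, 2e4))))
  dpt <- distance_profiles(mwt)
  expect_true(is.na(dpt$reads$cover))
  expect_equal(nrow(dpt$distances), 0L)
  # order strata and the cover-vs-order correlation on simulated reads
  mws <- truth_as_multiway(fix_noiseless)
  dps <- distance_profiles(mws)
  expect_true(all(dps$reads$stratum[dps$reads$n <= 3] == "lw"))
  expect_true(all(dps$reads$stratum[dps$reads$n >= 10] == "hg"))
  med <- tapply(dps$reads$cover, dps$reads$stratum, median, na.rm = TRUE)
  if (all(c("lw", "md") %in% names(med))) {
    expect_gt(med[["md"]], med[["lw"]])
  }
  # cover >= every pair distance
  mx <- merge(dps$distances[type != "cover"],
              dps$reads[, c("read_id", "cover")], by = "read_id")
  expect_true(all(mx$distance <= mx$cover + 1e-9))
})
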