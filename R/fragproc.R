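# Fragment processing: PAF alignments -> clean multiway reads.
#
# All coordinates are 0-based half-open. Overlap between two fragments of one
# read is judged on READ coordinates (concatemer fragments tile the read);
# whether an overlapping pair is merged or resolved by dropping the shorter
# fragment is decided by GENOMIC coincidence of the overlapped portion.

.paf_cols <- c("read_id", "qlen", "read_start", "read_end", "strand",
               "chrom", "tlen", "start", "end", "nmatch", "alen", "mapq")

#' Parse PAF alignment records into per-read fragments
#'
#' @param x a file path, a character vector of PAF lines, or a data.table
#'   with the 12 mandatory PAF columns.
#' @param pass label for the alignment pass ("primary" or "gap").
#' @return list with `fragments` (data.table keyed by read_id) and
#'   `n_skipped` (malformed lines dropped).
#' @export
parse_paf <- function(x, pass = "primary") {
  if (is.data.frame(x)) {
    dt <- as.data.table(x)
    if (ncol(dt) >= 12L) dt <- dt[, 1:12]
    setnames(dt, .paf_cols)
  } else {
    if (length(x) == 1L && !grepl("\t", x) && file.exists(x)) {
      x <- readLines(x)
    }
    fields <- strsplit(x, "\t", fixed = TRUE)
    ok <- vapply(fields, length, 1L) >= 12L
    dt <- rbindlist(lapply(fields[ok], function(f) as.list(f[1:12])))
    if (nrow(dt)) {
      setnames(dt, .paf_cols)
      for (cc in c("qlen", "read_start", "read_end", "tlen", "start", "end",
                   "nmatch", "alen", "mapq")) {
        dt[, (cc) := suppressWarnings(as.integer(get(cc)))]
      }
    }
  }
  n_in <- nrow(dt)
  if (n_in > 0L) {
    good <- with(dt, !is.na(read_start) & !is.na(read_end) & !is.na(start) &
                   !is.na(end) & !is.na(mapq) & read_end > read_start &
                   end > start & strand %in% c("+", "-"))
    dt <- dt[good]
  }
  if (nrow(dt) == 0L) stop("no parseable PAF records")
  frags <- dt[, list(read_id, read_start, read_end, chrom, start, end,
                     strand, mapq,
                     frag_class = NA_character_, pass = pass, qlen)]
  setkey(frags, read_id)
  list(fragments = frags, n_skipped = n_in - nrow(frags))
}

# genomic projection of a read interval [os, oe) through fragment f
.project <- function(rs, re, gs, ge, strand, os, oe) {
  if (strand == "+") c(gs + (os - rs), gs + (oe - rs))
  else c(ge - (oe - rs), ge - (os - rs))
}

# do two read-overlapping fragments coincide genomically within tol?
.coincident <- function(f1, f2, tol) {
  if (f1$chrom != f2$chrom || f1$strand != f2$strand) return(FALSE)
  os <- max(f1$read_start, f2$read_start)
  oe <- min(f1$read_end, f2$read_end)
  p1 <- .project(f1$read_start, f1$read_end, f1$start, f1$end, f1$strand, os, oe)
  p2 <- .project(f2$read_start, f2$read_end, f2$start, f2$end, f2$strand, os, oe)
  abs(p1[1] - p2[1]) <= tol && abs(p1[2] - p2[2]) <= tol
}

.merge_one_read <- function(fr, tol) {
  repeat {
    n <- nrow(fr)
    if (n <= 1L) break
    setorder(fr, read_start, read_end)
    hit <- NULL
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (fr$read_start[j] < fr$read_end[i]) { hit <- c(i, j); break }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    i <- hit[1]; j <- hit[2]
    if (.coincident(fr[i], fr[j], tol)) {
      merged <- fr[i]
      merged[, `:=`(read_start = min(fr$read_start[c(i, j)]),
                    read_end = max(fr$read_end[c(i, j)]),
                    start = min(fr$start[c(i, j)]),
                    end = max(fr$end[c(i, j)]),
                    mapq = max(fr$mapq[c(i, j)]))]
      fr <- rbind(fr[-c(i, j)], merged)
    } else {
      span <- fr$read_end - fr$read_start
      # drop shorter read span; ties: keep higher mapq, then earlier start
      drop <- if (span[i] != span[j]) {
        if (span[i] < span[j]) i else j
      } else if (fr$mapq[i] != fr$mapq[j]) {
        if (fr$mapq[i] < fr$mapq[j]) i else j
      } else j
      fr <- fr[-drop]
    }
  }
  fr
}

#' Merge or resolve overlapping fragments of each read
#'
#' Pairs of fragments that overlap on read coordinates are merged into their
#' union (on both axes, mapq = max) when same chromosome and strand and the
#' genomic projections of the overlapped portion agree within `coincide_tol`
#' at both ends; otherwise the fragment with the shorter read span is
#' discarded. Repeated to a fixed point, so the result is idempotent.
#'
#' @param fragments fragment data.table (one or many reads).
#' @param coincide_tol genomic coincidence tolerance in bp (default 50).
#' @return fragment data.table with no read-coordinate overlaps left.
#' @export
merge_overlapping_fragments <- function(fragments, coincide_tol = 50) {
  fragments <- as.data.table(fragments)
  if (nrow(fragments) == 0L) return(fragments)
  out <- fragments[, .merge_one_read(copy(.SD), coincide_tol), by = read_id]
  setkey(out, read_id)
  out[]
}

#' Combine primary and gap-realignment passes of one read set
#'
#' A gap-pass fragment is accepted only where its read interval overlaps no
#' primary fragment by more than `coincide_tol`; conflicts are resolved in
#' favour of the primary pass.
#'
#' @param primary,gap fragment data.tables from [parse_paf()].
#' @param coincide_tol read-overlap tolerance in bp.
#' @return combined fragment data.table.
#' @export
merge_alignment_passes <- function(primary, gap, coincide_tol = 50) {
  primary <- as.data.table(primary)
  gap <- as.data.table(gap)
  if (nrow(gap) == 0L) return(primary)
  keep <- vapply(seq_len(nrow(gap)), function(i) {
    g <- gap[i]
    p <- primary[read_id == g$read_id]
    if (nrow(p) == 0L) return(TRUE)
    ov <- pmin(p$read_end, g$read_end) - pmax(p$read_start, g$read_start)
    all(ov <= coincide_tol)
  }, logical(1))
  out <- rbind(primary, gap[keep])
  setkey(out, read_id)
  out[]
}

#' Unaligned read intervals of one read
#'
#' @param read_length total read length (bp).
#' @param fragments fragments of one read (read coordinates).
#' @param min_gap minimum gap length to report.
#' @return data.table of maximal unaligned intervals `start`, `end`, sorted.
#' @export
extract_gaps <- function(read_length, fragments, min_gap = 100) {
  iv <- as.data.table(fragments)[, list(read_start, read_end)]
  setorder(iv, read_start)
  gaps <- list()
  cur <- 0L
  for (i in seq_len(nrow(iv))) {
    if (iv$read_start[i] > cur) {
      gaps[[length(gaps) + 1L]] <- c(cur, iv$read_start[i])
    }
    cur <- max(cur, iv$read_end[i])
  }
  if (cur < read_length) gaps[[length(gaps) + 1L]] <- c(cur, read_length)
  if (!length(gaps)) {
    return(data.table(start = integer(), end = integer()))
  }
  g <- as.data.table(do.call(rbind, gaps))
  setnames(g, c("start", "end"))
  g[end - start >= min_gap][order(start)]
}

#' Annotate fragments with restriction-digestion classes
#'
#' A genomic fragment end is a "match end" when it lies within `end_tol` bp
#' of an in-silico digestion boundary (a cut site or a chromosome end). Both
#' ends matched = fully digested.
#'
#' @param fragments fragment data.table.
#' @param genome a `genome_model` covering every referenced chromosome.
#' @param end_tol match tolerance in bp (default 30).
#' @return fragments with `frag_class` set to one of both_ends_matched,
#'   one_end_matched, unmatched.
#' @export
annotate_restriction <- function(fragments, genome, end_tol = 30) {
  fragments <- as.data.table(fragments)
  missing <- setdiff(unique(fragments$chrom), genome$chromosomes$name)
  if (length(missing)) {
    stop("fragment chromosome(s) missing from genome: ",
         paste(missing, collapse = ", "))
  }
  near_site <- function(ch, pos) {
    s <- c(0L, genome$sites[[ch]],
           genome$chromosomes[name == ch, as.integer(length)])
    i <- findInterval(pos, s)
    lo <- s[pmax(i, 1L)]
    hi <- s[pmin(i + 1L, length(s))]
    pmin(abs(pos - lo), abs(hi - pos)) <= end_tol
  }
  fragments[, frag_class := {
    m1 <- near_site(.BY$chrom, start)
    m2 <- near_site(.BY$chrom, end)
    ifelse(m1 & m2, "both_ends_matched",
           ifelse(m1 | m2, "one_end_matched", "unmatched"))
  }, by = chrom]
  fragments[]
}

#' Filter unreliable fragments
#'
#' A fragment is discarded only when its mapq is below `min_mapq` AND it has
#' no match end; low-mapq fragments with digestion evidence survive.
#'
#' @param fragments annotated fragment data.table.
#' @param min_mapq mapq threshold (default 10).
#' @return filtered fragment data.table.
#' @export
filter_fragments <- function(fragments, min_mapq = 10) {
  fragments <- as.data.table(fragments)
  fragments[!(mapq < min_mapq & frag_class == "unmatched")]
}

#' Assemble surviving fragments into multiway reads
#'
#' @param fragments filtered fragment data.table.
#' @return data.table ordered by read and read_start with `frag_index`,
#'   per-read order `n` and an `informative` flag (n >= 2). Reads with no
#'   surviving fragment are absent.
#' @export
assemble_multiway <- function(fragments) {
  mw <- as.data.table(fragments)
  if (nrow(mw) == 0L) return(mw)
  setorder(mw, read_id, read_start)
  mw[, frag_index := seq_len(.N), by = read_id]
  mw[, n := .N, by = read_id]
  mw[, informative := n >= 2L]
  mw[]
}

#' Run the whole fragment-processing pipeline on PAF input
#'
#' parse -> overlap merge -> pass combination -> overlap merge ->
#' restriction annotation -> mapq filter -> multiway assembly.
#'
#' @param paf primary-pass PAF (path, lines or data.table).
#' @param gap_paf optional gap-realignment PAF.
#' @param genome a `genome_model`.
#' @param coincide_tol,end_tol,min_mapq rule parameters.
#' @return multiway fragment data.table (see [assemble_multiway()]).
#' @export
process_paf <- function(paf, gap_paf = NULL, genome, coincide_tol = 50,
                        end_tol = 30, min_mapq = 10) {
  p <- parse_paf(paf, pass = "primary")$fragments
  p <- merge_overlapping_fragments(p, coincide_tol)
  if (!is.null(gap_paf) &&
      (is.data.frame(gap_paf) && nrow(gap_paf) > 0L ||
       is.character(gap_paf))) {
    g <- parse_paf(gap_paf, pass = "gap")$fragments
    p <- merge_alignment_passes(p, g, coincide_tol)
    p <- merge_overlapping_fragments(p, coincide_tol)
  }
  p <- annotate_restriction(p, genome, end_tol)
  p <- filter_fragments(p, min_mapq)
  assemble_multiway(p)
}

#' Write multiway fragments as TSV
#'
#' Column order is fixed: read_id, frag_index, n, chrom, start, end, strand,
#' mapq, frag_class.
#'
#' @param mw multiway fragment data.table.
#' @param path output file.
#' @return number of rows written, invisibly.
#' @export
write_multiway_tsv <- function(mw, path) {
  out <- as.data.table(mw)[, list(read_id, frag_index, n, chrom, start, end,
                                  strand, mapq, frag_class)]
  fwrite(out, path, sep = "\t")
  invisible(nrow(out))
}

#' Read a multiway fragment TSV written by [write_multiway_tsv()]
#' @param path input file.
#' @return multiway fragment data.table.
#' @export
read_multiway_tsv <- function(path) {
  fread(path, sep = "\t")
}
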