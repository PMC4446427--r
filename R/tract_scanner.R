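# Tract scanning and censuses.
#
# A tract is a maximal run of a single base (A, T, G or C) of length 4-13 on
# the reference.  Runs of A or G read 5'->3' on the forward strand
# (purine_strand "+"); runs of T or C are the reverse-complement view of an
# A- or G-run on the minus strand (purine_strand "-").  Flanking bases are
# always reported on the purine strand, so for "-" tracts they are the
# complements of the forward-strand neighbors, swapped 5'/3'.

#' Scan a sequence for maximal A- and G-tracts
#'
#' Finds every maximal run of a single base of length 4 to 13 together with
#' its two flanking bases.  Characters outside A,C,G,T are treated as N: they
#' never extend a run, and a run abutting an N keeps the N as its flank.
#' Runs longer than 13 bp are excluded entirely (not truncated), and runs
#' touching either end of the sequence (no defined flank) are excluded,
#' because the positional coordinate system requires both positions 0 and
#' n+1 to exist.
#'
#' @param chrom_id sequence identifier (single non-empty string).
#' @param seq the nucleotide sequence as a single string.
#' @param min_n,max_n tract length bounds (defaults 4 and 13).
#' @return a data.frame with one row per tract and columns `chrom`,
#'   `start`/`end` (0-based half-open reference coordinates), `n` (length),
#'   `tract_class` ("A" or "G"), `purine_strand` ("+" or "-"), and `flank5`,
#'   `flank3` (bases at purine-strand positions 0 and n+1).
#' @export
#' @examples
#' scan_sequence("c1", "CAAAAT")
#' scan_sequence("c1", "ATTTTG")  # reverse-complement view of the T-run
scan_sequence <- function(chrom_id, seq, min_n = 4L, max_n = 13L) {
  if (!is.character(chrom_id) || length(chrom_id) != 1L || is.na(chrom_id) ||
      !nzchar(chrom_id))
    stop("chrom_id must be a single non-empty string")
  if (length(seq) != 1L) stop("seq must be a single string")
  if (!nzchar(seq)) return(empty_tracts())

  chars <- seq_chars(seq)
  runs <- char_runs(chars)
  L <- length(chars)
  keep <- runs$base %in% .BASES & runs$len >= min_n & runs$len <= max_n &
    runs$start > 0L & runs$end < L
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(empty_tracts())

  left <- chars[runs$start]        # forward base 5' of the run (0-based start-1)
  right <- chars[runs$end + 1L]    # forward base 3' of the run
  plus <- runs$base %in% c("A", "G")
  data.frame(
    chrom = chrom_id,
    start = as.integer(runs$start),
    end = as.integer(runs$end),
    n = as.integer(runs$len),
    tract_class = ifelse(runs$base %in% c("A", "T"), "A", "G"),
    purine_strand = ifelse(plus, "+", "-"),
    flank5 = ifelse(plus, left, comp_base(right)),
    flank3 = ifelse(plus, right, comp_base(left)),
    stringsAsFactors = FALSE
  )
}

#' Scan all records of a FASTA file (or a named character vector)
#'
#' @param x path to a FASTA file (gzip allowed) or a named character vector of
#'   sequences.
#' @param ... passed to [scan_sequence()].
#' @return tract data.frame as from [scan_sequence()], rows ordered by record.
#' @export
scan_fasta <- function(x, ...) {
  seqs <- if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    ss <- Biostrings::readDNAStringSet(x)
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else x
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  do.call(rbind, lapply(names(seqs),
                        function(nm) scan_sequence(nm, seqs[[nm]], ...)))
}

tracts_granges <- function(tracts) {
  GenomicRanges::GRanges(tracts$chrom,
                         IRanges::IRanges(tracts$start + 1L, tracts$end))
}

intervals_granges <- function(intervals) {
  stopifnot_cols(intervals, c("chrom", "start", "end"), "interval table")
  GenomicRanges::GRanges(intervals$chrom,
                         IRanges::IRanges(intervals$start + 1L, intervals$end))
}

#' Build a tract census
#'
#' Counts tracts per (tract_class, n, flank5, flank3) stratum, for use as the
#' normalization denominator of every F statistic.  When a mask is given,
#' only tracts wholly contained in a (merged) mask interval are counted: the
#' tract is the unit of normalization, so partial overlap does not count.
#'
#' @param tracts tract data.frame from [scan_sequence()].
#' @param mask optional data.frame of 0-based half-open intervals with columns
#'   `chrom`, `start`, `end` (e.g. exons); merged before containment testing.
#' @param region optional label recorded on the result.
#' @return data.frame (`tract_class`, `n`, `flank5`, `flank3`, `count`) with
#'   attribute `region`.  Tracts with an N flank are present here (they count
#'   in the per-(class, n) marginals) and are dropped only by
#'   flank-conditioned analyses.
#' @seealso [census_marginal()] for the per-(class, n) totals.
#' @export
build_census <- function(tracts, mask = NULL, region = NULL) {
  stopifnot_cols(tracts, c("chrom", "start", "end", "n", "tract_class",
                           "flank5", "flank3"), "tracts")
  if (!is.null(mask) && nrow(tracts)) {
    gr <- tracts_granges(tracts)
    mr <- GenomicRanges::reduce(intervals_granges(mask))
    inside <- IRanges::overlapsAny(gr, mr, type = "within")
    tracts <- tracts[inside, , drop = FALSE]
  }
  if (!nrow(tracts)) {
    cen <- data.frame(tract_class = character(0), n = integer(0),
                      flank5 = character(0), flank3 = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  } else {
    cen <- aggregate(list(count = rep(1L, nrow(tracts))),
                     tracts[c("tract_class", "n", "flank5", "flank3")], sum)
    cen <- cen[order(cen$tract_class, cen$n, cen$flank5, cen$flank3), ]
    rownames(cen) <- NULL
  }
  attr(cen, "region") <- region
  cen
}

#' Per-(class, n) marginal counts of a census
#'
#' @param census census from [build_census()].
#' @param flank5,flank3 optional single-base filters; when given, strata with
#'   an N flank are excluded by construction.
#' @return data.frame (`tract_class`, `n`, `count`).
#' @export
census_marginal <- function(census, flank5 = NULL, flank3 = NULL) {
  keep <- rep(TRUE, nrow(census))
  if (!is.null(flank5)) keep <- keep & census$flank5 == flank5
  if (!is.null(flank3)) keep <- keep & census$flank3 == flank3
  cen <- census[keep, , drop = FALSE]
  if (!nrow(cen))
    return(data.frame(tract_class = character(0), n = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  out <- aggregate(list(count = cen$count), cen[c("tract_class", "n")], sum)
  out[order(out$tract_class, out$n), , drop = FALSE]
}

#' Percent difference between two censuses
#'
#' Compares tract counts per (class, n) between two genomes/regions.  Because
#' the sequence amounts behind two censuses generally differ, each census is
#' first normalized to its per-class total over the scanned length range, and
#' the difference of proportions is reported:
#' `(propA - propB) / propB * 100`.  Set `normalize = FALSE` to difference the
#' raw counts instead.
#'
#' @param censusA,censusB censuses from [build_census()].
#' @param normalize normalize to per-class proportions first (default TRUE).
#' @return data.frame (`tract_class`, `n`, `percent_difference`); strata with
#'   a zero denominator are reported as NA.
#' @export
census_percent_difference <- function(censusA, censusB, normalize = TRUE) {
  a <- census_marginal(censusA)
  b <- census_marginal(censusB)
  if (!nrow(a) || !nrow(b)) stop("both censuses must be nonempty")
  m <- merge(a, b, by = c("tract_class", "n"), all = TRUE,
             suffixes = c("_a", "_b"))
  m$count_a[is.na(m$count_a)] <- 0L
  m$count_b[is.na(m$count_b)] <- 0L
  va <- m$count_a
  vb <- m$count_b
  if (normalize) {
    ta <- ave(m$count_a, m$tract_class, FUN = sum)
    tb <- ave(m$count_b, m$tract_class, FUN = sum)
    va <- ifelse(ta > 0, m$count_a / ta, NA_real_)
    vb <- ifelse(tb > 0, m$count_b / tb, NA_real_)
  }
  m$percent_difference <- ifelse(!is.na(vb) & vb > 0, (va - vb) / vb * 100,
                                 NA_real_)
  out <- m[order(m$tract_class, m$n),
           c("tract_class", "n", "percent_difference")]
  rownames(out) <- NULL
  out
}

#' Fraction of tracts (or tract base pairs) overlapping an interval set
#'
#' @param tracts tract data.frame.
#' @param intervals data.frame of 0-based half-open intervals (`chrom`,
#'   `start`, `end`), e.g. TFBS clusters or nucleosome footprints.
#' @param unit `"tract"` counts tracts with at least 1 bp of overlap;
#'   `"bp"` counts overlapping tract base pairs.
#' @return data.frame (`tract_class`, `n`, `percent`) in percent of the
#'   stratum total (tracts or base pairs).  An empty interval set gives 0.
#' @export
intersect_fraction <- function(tracts, intervals, unit = c("tract", "bp")) {
  unit <- match.arg(unit)
  stopifnot_cols(tracts, c("chrom", "start", "end", "n", "tract_class"),
                 "tracts")
  strata <- aggregate(list(total = tracts$n),
                      tracts[c("tract_class", "n")],
                      if (unit == "bp") sum else length)
  if (is.null(intervals) || !nrow(intervals)) {
    strata$percent <- ifelse(strata$total > 0, 0, NA_real_)
    return(strata[order(strata$tract_class, strata$n),
                  c("tract_class", "n", "percent")])
  }
  gr <- tracts_granges(tracts)
  mr <- GenomicRanges::reduce(intervals_granges(intervals))
  if (unit == "tract") {
    hit <- as.numeric(IRanges::overlapsAny(gr, mr))
  } else {
    hits <- GenomicRanges::findOverlaps(gr, mr)
    ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                    mr[S4Vectors::subjectHits(hits)])
    hit <- rep(0, nrow(tracts))
    w <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    hit[as.integer(names(w))] <- as.numeric(w)
  }
  num <- aggregate(list(overlap = hit), tracts[c("tract_class", "n")], sum)
  m <- merge(strata, num, by = c("tract_class", "n"))
  m$percent <- ifelse(m$total > 0, m$overlap / m$total * 100, NA_real_)
  out <- m[order(m$tract_class, m$n), c("tract_class", "n", "percent")]
  rownames(out) <- NULL
  out
}
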