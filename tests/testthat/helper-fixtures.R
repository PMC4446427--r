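# Shared fixtures and independent oracles for the test suite.

COMP_TBL <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

rc <- function(s) {
  paste(rev(unname(COMP_TBL[strsplit(toupper(s), "")[[1]]])), collapse = "")
}

random_dna <- function(len, p_n = 0) {
  b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (p_n > 0) {
    nn <- runif(len) < p_n
    b[nn] <- "N"
  }
  paste(b, collapse = "")
}

# Brute-force maximal-run finder built on regular expressions, fully
# independent of the package scanner (lookaround enforces maximality, so
# over-long runs match nothing rather than being truncated).
oracle_scan <- function(chrom, seq, min_n = 4L, max_n = 13L) {
  s <- gsub("[^ACGT]", "N", toupper(seq))
  L <- nchar(s)
  rows <- list()
  for (b in c("A", "C", "G", "T")) {
    pat <- sprintf("(?<!%s)%s{%d,%d}(?!%s)", b, b, min_n, max_n, b)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      start0 <- m[k] - 1L
      end0 <- start0 + lens[k]
      if (start0 == 0L || end0 == L) next     # no defined flank
      left <- substr(s, start0, start0)
      right <- substr(s, end0 + 1L, end0 + 1L)
      plus <- b %in% c("A", "G")
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = start0, end = end0, n = lens[k],
        tract_class = if (b %in% c("A", "T")) "A" else "G",
        purine_strand = if (plus) "+" else "-",
        flank5 = if (plus) left else unname(COMP_TBL[right]),
        flank3 = if (plus) right else unname(COMP_TBL[left]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(homotract::scan_sequence(chrom, ""))   # canonical empty layout
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

sort_tracts <- function(df) {
  out <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Minimal assignment-row constructor for spectra unit tests.
make_assignment <- function(category, tract_class = "A", n = 5L,
                            position = NA_integer_, location = NA_character_,
                            sub_from = NA_character_, sub_to = NA_character_,
                            flank5 = "T", flank3 = "T", tract_start = 10L,
                            chrom = "c1", indel_size = 0L) {
  data.frame(chrom = chrom, tract_start = tract_start,
             tract_end = tract_start + n, n = n, tract_class = tract_class,
             purine_strand = "+", flank5 = flank5, flank3 = flank3,
             pos = tract_start + 1L, ref = "A", alt = "T",
             category = category, position = position, location = location,
             sub_from = sub_from, sub_to = sub_to, extends_tract = FALSE,
             cpg_context = FALSE, indel_size = indel_size,
             stringsAsFactors = FALSE)
}

# Census constructor: counts per (class, n) with a single flank stratum.
make_census <- function(tract_class, n, count, flank5 = "T", flank3 = "T") {
  data.frame(tract_class = tract_class, n = n, flank5 = flank5,
             flank3 = flank3, count = count, stringsAsFactors = FALSE)
}
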