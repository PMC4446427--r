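# VCF normalization and tract assignment.
#
# Coordinate conventions: VCF positions are 1-based; tract start/end are
# 0-based half-open.  The purine-strand position of a 0-based reference
# coordinate x within a tract is p = x - start + 1 on "+" tracts and
# p = end - x on "-" tracts, so p = 0 is the 5' flank and p = n + 1 the 3'
# flank of the purine-rich strand in both orientations.

#' Normalize raw VCF records
#'
#' Splits multi-allelic records, drops non-variant and multi-nucleotide
#' records, trims shared prefix/suffix to the parsimonious representation and
#' left-aligns indels to their leftmost equivalent placement (the standard
#' convention of population call sets, which makes homopolymer indels
#' comparable).  Records whose REF allele does not match the reference are
#' dropped with a warning.
#'
#' @param records data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (ALT may be comma-separated for multi-allelic sites).
#' @param reference named character vector (or DNAStringSet) of reference
#'   sequences covering the VCF contigs.
#' @param max_indel maximum indel size eligible for tract analysis
#'   (default 200 bp); larger events are dropped.
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `vtype` ("SNV", "INS",
#'   "DEL"), `size` (0 for SNVs).
#' @export
normalize_variants <- function(records, reference, max_indel = 200L) {
  stopifnot_cols(records, c("chrom", "pos", "ref", "alt"), "records")
  reference <- as_reference(reference)
  bad <- setdiff(unique(records$chrom), names(reference))
  if (length(bad))
    stop("contig(s) absent from reference: ", paste(bad, collapse = ", "))
  if (!nrow(records)) return(empty_variants())

  # split multi-allelics
  alts <- strsplit(as.character(records$alt), ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(records)), lengths(alts))
  v <- data.frame(chrom = records$chrom[idx],
                  pos = as.integer(records$pos[idx]),
                  ref = toupper(as.character(records$ref[idx])),
                  alt = toupper(unlist(alts)),
                  stringsAsFactors = FALSE)
  v <- v[v$alt != "*" & v$alt != "." & v$ref != v$alt, , drop = FALSE]
  if (!nrow(v)) return(empty_variants())

  n_in <- nrow(v)
  out <- vector("list", n_in)
  dropped_ref <- 0L
  for (i in seq_len(n_in)) {
    chrom <- v$chrom[i]
    s <- reference[[chrom]]
    norm <- normalize_one(v$pos[i], v$ref[i], v$alt[i], s)
    if (is.null(norm)) next
    if (!norm$ok) { dropped_ref <- dropped_ref + 1L; next }
    out[[i]] <- data.frame(chrom = chrom, pos = norm$pos, ref = norm$ref,
                           alt = norm$alt, stringsAsFactors = FALSE)
  }
  if (dropped_ref)
    warning(dropped_ref, " record(s) failed the reference allele check and ",
            "were dropped")
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty_variants())
  rl <- nchar(out$ref); al <- nchar(out$alt)
  out$vtype <- ifelse(rl == 1L & al == 1L, "SNV",
                      ifelse(al > rl, "INS", "DEL"))
  out$size <- abs(al - rl)
  mnv <- out$vtype != "SNV" & out$size == 0L
  if (any(mnv)) {
    warning(sum(mnv), " multi-nucleotide record(s) dropped")
    out <- out[!mnv, , drop = FALSE]
  }
  big <- out$size > max_indel
  if (any(big)) out <- out[!big, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Parsimony-trim and left-align a single allele pair against sequence s.
# Returns list(pos, ref, alt, ok) or NULL for a degenerate record.
normalize_one <- function(pos, ref, alt, s) {
  L <- nchar(s)
  if (pos < 1L || pos + nchar(ref) - 1L > L) return(list(ok = FALSE))
  if (substr(s, pos, pos + nchar(ref) - 1L) != ref) return(list(ok = FALSE))
  # right-trim; when an allele empties, prepend the previous reference base
  repeat {
    rl <- nchar(ref); al <- nchar(alt)
    if (rl >= 1L && al >= 1L && !(rl == 1L && al == 1L) &&
        substr(ref, rl, rl) == substr(alt, al, al)) {
      ref <- substr(ref, 1L, rl - 1L)
      alt <- substr(alt, 1L, al - 1L)
      if (!nchar(ref) || !nchar(alt)) {
        if (pos == 1L) {        # cannot left-extend past the sequence start
          b <- substr(s, pos + max(nchar(ref), nchar(alt)),
                      pos + max(nchar(ref), nchar(alt)))
          ref <- paste0(ref, b); alt <- paste0(alt, b)
          break
        }
        pos <- pos - 1L
        b <- substr(s, pos, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  # left-trim while both alleles keep at least one base
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L); pos <- pos + 1L
  }
  if (ref == alt) return(NULL)
  list(pos = as.integer(pos), ref = ref, alt = alt, ok = TRUE)
}

empty_variants <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vtype = character(0), size = integer(0),
             stringsAsFactors = FALSE)
}

as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet"))
    reference <- setNames(as.character(reference),
                          sub("\\s.*$", "", names(reference)))
  if (!is.character(reference) || is.null(names(reference)))
    stop("reference must be a named character vector or DNAStringSet")
  toupper(reference)
}

#' Remove duplicate variant records
#'
#' Unique on (chrom, pos, ref, alt), stably ordered by coordinate; same pos
#' with different alleles is kept.
#'
#' @param records normalized variant data.frame.
#' @return deduplicated, coordinate-sorted data.frame.
#' @export
dedupe_variants <- function(records) {
  if (!nrow(records)) return(records)
  key <- paste(records$chrom, records$pos, records$ref, records$alt,
               sep = "\r")
  records <- records[!duplicated(key), , drop = FALSE]
  records <- records[order(records$chrom, records$pos, records$ref,
                           records$alt), , drop = FALSE]
  rownames(records) <- NULL
  records
}

# purine-strand position of 0-based reference coordinate x within a tract
purine_pos <- function(x, start, end, strand) {
  ifelse(strand == "+", x - start + 1L, end - x)
}

#' Assign an SNV to a tract
#'
#' Places a single-nucleotide variant in purine-strand coordinates.  Returns
#' `NULL` when the SNV does not touch the tract or its two flanking bases.
#' Substitutions are complemented for "-" tracts so they always read on the
#' purine strand.
#'
#' @param tract single-row tract data.frame.
#' @param v single-row normalized variant with `vtype == "SNV"`.
#' @return one-row assignment data.frame (see [map_variants()]) or NULL.
#' @export
assign_snv <- function(tract, v) {
  if (v$vtype != "SNV") stop("assign_snv expects an SNV")
  if (v$chrom != tract$chrom) return(NULL)
  x <- v$pos - 1L
  if (x < tract$start - 1L || x > tract$end) return(NULL)
  p <- purine_pos(x, tract$start, tract$end, tract$purine_strand)
  minus <- tract$purine_strand == "-"
  from <- if (minus) comp_base(v$ref) else v$ref
  to <- if (minus) comp_base(v$alt) else v$alt
  in_tract <- p >= 1L && p <= tract$n
  base <- tract$tract_class
  data.frame(
    chrom = tract$chrom, tract_start = tract$start, tract_end = tract$end,
    n = tract$n, tract_class = tract$tract_class,
    purine_strand = tract$purine_strand,
    flank5 = tract$flank5, flank3 = tract$flank3,
    pos = v$pos, ref = v$ref, alt = v$alt,
    category = if (in_tract) "tract_SNV" else "flank_SNV",
    position = as.integer(p), location = NA_character_,
    sub_from = from, sub_to = to,
    extends_tract = !in_tract && to == base,
    cpg_context = base == "G" && p == 1L && tract$flank5 == "C",
    indel_size = 0L, stringsAsFactors = FALSE)
}

#' Assign an indel to a tract (slippage vs. general indel)
#'
#' Classification is by apply-and-rescan: the edit is applied to a local
#' window of the reference (tract +/- 200 bp, enlarged if needed), the window
#' is re-scanned for maximal runs, and the run covering the tract locus is
#' compared with the original tract.  If it has the same base, length n+1 or
#' n-1, and both flanking base identities unchanged, the event is slippage
#' (`slippage_plus` / `slippage_minus`).  Otherwise, if the edit touches the
#' tract or its flanks, it is a general indel: insertions get a junction
#' index j in 0..n+1 (insertion between purine positions j and j+1),
#' deletions a location class (`before_tract`, `in_tract`, `after_tract`).
#' Events not touching the tract return NULL.
#'
#' @param tract single-row tract data.frame.
#' @param v single-row normalized variant with `vtype` "INS" or "DEL".
#' @param reference named character vector (or DNAStringSet).
#' @return one-row assignment data.frame or NULL.
#' @export
assign_indel <- function(tract, v, reference) {
  reference <- as_reference(reference)
  if (!v$vtype %in% c("INS", "DEL")) stop("assign_indel expects an indel")
  if (v$chrom != tract$chrom) return(NULL)
  cls <- classify_indel(tract, v, reference[[tract$chrom]])
  if (is.null(cls)) return(NULL)
  indel_row(tract, v, category = cls$category, position = cls$position,
            location = cls$location)
}

# classification core; `tract` and `v` may be one-row data.frames or plain
# lists (the hot path passes lists), `s` the reference sequence string
classify_indel <- function(tract, v, s) {
  L <- nchar(s)
  start <- tract$start; end <- tract$end; n <- tract$n
  strand <- tract$purine_strand
  fb <- if (strand == "+") tract$tract_class else
    comp_base(tract$tract_class)                 # forward-strand run base
  # window [w0, w1) 0-based, wide enough to contain tract, flanks and edit
  w0 <- max(0L, min(start - 200L, v$pos - 2L))
  w1 <- min(L, max(end + 200L, v$pos - 1L + nchar(v$ref) + 1L))
  local <- substr(s, w0 + 1L, w1)
  a <- v$pos - 1L - w0                           # 0-based edit offset in window
  edited <- paste0(substr(local, 1L, a), v$alt,
                   substr(local, a + nchar(v$ref) + 1L, nchar(local)))
  delta <- nchar(v$alt) - nchar(v$ref)
  # map a 0-based genomic coordinate through the edit into the edited window
  map0 <- function(x) ifelse(x <= v$pos - 1L, x - w0, x - w0 + delta)

  if (v$size == 1L) {
    ech <- seq_chars(edited)
    runs <- char_runs(ech)
    want_n <- n + if (v$vtype == "INS") 1L else -1L
    ts <- map0(start); te <- map0(end - 1L) + 1L  # mapped tract span
    sel <- which(runs$base == fb & runs$len == want_n &
                   runs$end > ts - 1L & runs$start < te + 1L)
    for (k in sel) {
      rs <- runs$start[k]; re <- runs$end[k]
      lf_ok <- rs > 0L && ech[rs] == substr(s, start, start)
      rf_ok <- re < length(ech) && ech[re + 1L] ==
        substr(s, end + 1L, end + 1L)
      if (lf_ok && rf_ok)
        return(list(category = if (v$vtype == "INS") "slippage_plus"
                    else "slippage_minus",
                    position = NA_integer_, location = NA_character_))
    }
  }

  if (v$vtype == "INS") {
    # breakpoint between 0-based x = pos-1 and pos (after the anchor base)
    j <- if (strand == "+") v$pos - start else end - v$pos
    if (j < 0L || j > n + 1L) return(NULL)
    return(list(category = "indel_ins", position = as.integer(j),
                location = ins_location(j, n)))
  }
  # deletion: deleted 0-based bases are pos .. pos + size - 1
  d0 <- v$pos; d1 <- v$pos + v$size - 1L
  if (d1 < start - 1L || d0 > end) return(NULL)
  pp <- purine_pos(c(d0, d1), start, end, strand)
  loc <- if (min(pp) <= 0L) "before_tract"
         else if (max(pp) >= n + 1L) "after_tract"
         else "in_tract"
  list(category = "indel_del", position = NA_integer_, location = loc)
}

# map an insertion junction to the location classes used by F Indel
ins_location <- function(j, n) {
  ifelse(j <= 0L, "before_tract", ifelse(j >= n, "after_tract", "in_tract"))
}

indel_row <- function(tract, v, category, position, location) {
  data.frame(
    chrom = tract$chrom, tract_start = tract$start, tract_end = tract$end,
    n = tract$n, tract_class = tract$tract_class,
    purine_strand = tract$purine_strand,
    flank5 = tract$flank5, flank3 = tract$flank3,
    pos = v$pos, ref = v$ref, alt = v$alt,
    category = category, position = position, location = location,
    sub_from = NA_character_, sub_to = NA_character_,
    extends_tract = FALSE, cpg_context = FALSE,
    indel_size = as.integer(v$size), stringsAsFactors = FALSE)
}

#' Map a variant stream onto a tract stream
#'
#' Interval-joins coordinate-sorted tracts and normalized variants and runs
#' [assign_snv()] / [assign_indel()] on every pair that can interact.  A
#' variant overlapping several tracts is assigned to each.
#'
#' @param tracts coordinate-sorted tract data.frame.
#' @param variants coordinate-sorted normalized variant data.frame
#'   (see [normalize_variants()], [dedupe_variants()]).
#' @param reference named character vector (or DNAStringSet); required to
#'   classify indels.
#' @return assignment data.frame, one row per (tract, variant) assignment,
#'   ordered by tract: tract key columns (`chrom`, `tract_start`,
#'   `tract_end`, `n`, `tract_class`, `purine_strand`, `flank5`, `flank3`),
#'   variant columns (`pos`, `ref`, `alt`), and `category`, `position`
#'   (p for SNVs, junction j for insertions), `location` (deletions and
#'   insertions, for F Indel), `sub_from`/`sub_to` (purine strand, SNVs),
#'   `extends_tract`, `cpg_context`, `indel_size`.
#' @export
map_variants <- function(tracts, variants, reference) {
  reference <- as_reference(reference)
  if (nrow(tracts) > 1L) {
    o <- order(tracts$chrom, tracts$start)
    if (any(o != seq_len(nrow(tracts)))) stop("tracts must be sorted")
  }
  if (nrow(variants) > 1L) {
    o <- order(variants$chrom, variants$pos)
    if (any(o != seq_len(nrow(variants)))) stop("variants must be sorted")
  }
  if (!nrow(tracts) || !nrow(variants)) return(empty_assignments())

  # flank-extended tract span, 1-based: [start, end + 1]
  tgr <- GenomicRanges::GRanges(tracts$chrom,
                                IRanges::IRanges(tracts$start,
                                                 tracts$end + 1L))
  # variant reach, 1-based: SNV the site; INS the two bases around the
  # breakpoint; DEL anchor plus deleted span
  vstart <- ifelse(variants$vtype == "SNV", variants$pos, variants$pos)
  vend <- ifelse(variants$vtype == "SNV", variants$pos,
                 ifelse(variants$vtype == "INS", variants$pos + 1L,
                        variants$pos + variants$size))
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(vstart, vend))
  hits <- GenomicRanges::findOverlaps(vgr, tgr)
  if (!length(hits)) return(empty_assignments())
  vi <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)

  snv <- variants$vtype[vi] == "SNV"
  parts <- list()
  if (any(snv)) parts$snv <- assign_snv_batch(tracts[ti[snv], , drop = FALSE],
                                              variants[vi[snv], , drop = FALSE])
  if (any(!snv)) {
    rows <- which(!snv)
    tI <- ti[rows]; vI <- vi[rows]
    m <- length(rows)
    cat_v <- character(m); pos_v <- integer(m); loc_v <- character(m)
    keep <- logical(m)
    for (k in seq_len(m)) {
      i <- tI[k]; j <- vI[k]
      tr1 <- list(chrom = tracts$chrom[i], start = tracts$start[i],
                  end = tracts$end[i], n = tracts$n[i],
                  tract_class = tracts$tract_class[i],
                  purine_strand = tracts$purine_strand[i])
      v1 <- list(pos = variants$pos[j], ref = variants$ref[j],
                 alt = variants$alt[j], vtype = variants$vtype[j],
                 size = variants$size[j])
      cls <- classify_indel(tr1, v1, reference[[tr1$chrom]])
      if (is.null(cls)) next
      keep[k] <- TRUE
      cat_v[k] <- cls$category
      pos_v[k] <- if (is.na(cls$position)) NA_integer_ else cls$position
      loc_v[k] <- if (is.na(cls$location)) NA_character_ else cls$location
    }
    if (any(keep)) {
      tI <- tI[keep]; vI <- vI[keep]
      parts$indel <- data.frame(
        chrom = tracts$chrom[tI], tract_start = tracts$start[tI],
        tract_end = tracts$end[tI], n = tracts$n[tI],
        tract_class = tracts$tract_class[tI],
        purine_strand = tracts$purine_strand[tI],
        flank5 = tracts$flank5[tI], flank3 = tracts$flank3[tI],
        pos = variants$pos[vI], ref = variants$ref[vI],
        alt = variants$alt[vI],
        category = cat_v[keep], position = pos_v[keep],
        location = loc_v[keep],
        sub_from = NA_character_, sub_to = NA_character_,
        extends_tract = FALSE, cpg_context = FALSE,
        indel_size = as.integer(variants$size[vI]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(parts)) return(empty_assignments())
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$tract_start, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# vectorized assign_snv over parallel (tract, variant) rows
assign_snv_batch <- function(tr, va) {
  x <- va$pos - 1L
  p <- purine_pos(x, tr$start, tr$end, tr$purine_strand)
  keep <- p >= 0L & p <= tr$n + 1L
  tr <- tr[keep, , drop = FALSE]; va <- va[keep, , drop = FALSE]
  p <- p[keep]
  if (!length(p)) return(NULL)
  minus <- tr$purine_strand == "-"
  from <- ifelse(minus, comp_base(va$ref), va$ref)
  to <- ifelse(minus, comp_base(va$alt), va$alt)
  in_tract <- p >= 1L & p <= tr$n
  data.frame(
    chrom = tr$chrom, tract_start = tr$start, tract_end = tr$end,
    n = tr$n, tract_class = tr$tract_class, purine_strand = tr$purine_strand,
    flank5 = tr$flank5, flank3 = tr$flank3,
    pos = va$pos, ref = va$ref, alt = va$alt,
    category = ifelse(in_tract, "tract_SNV", "flank_SNV"),
    position = as.integer(p), location = NA_character_,
    sub_from = from, sub_to = to,
    extends_tract = !in_tract & to == tr$tract_class,
    cpg_context = tr$tract_class == "G" & p == 1L & tr$flank5 == "C",
    indel_size = 0L, stringsAsFactors = FALSE)
}

empty_assignments <- function() {
  data.frame(chrom = character(0), tract_start = integer(0),
             tract_end = integer(0), n = integer(0),
             tract_class = character(0), purine_strand = character(0),
             flank5 = character(0), flank3 = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             category = character(0), position = integer(0),
             location = character(0), sub_from = character(0),
             sub_to = character(0), extends_tract = logical(0),
             cpg_context = logical(0), indel_size = integer(0),
             stringsAsFactors = FALSE)
}
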