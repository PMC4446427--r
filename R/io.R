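# Readers and writers for the standard formats the pipeline touches.

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line width (default 70).
#' @return the path, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path (gzip allowed).
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' Write variant records as a minimal VCF 4.2 file
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @return the path, invisibly.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=homotract")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants))
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", variants$chrom,
            as.integer(variants$pos), variants$ref, variants$alt)
  else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file into the raw record layout
#'
#' Uses vcfR; returns the columns [normalize_variants()] expects.  ALT stays
#' comma-separated for multi-allelic sites.
#'
#' @param path VCF path (plain or bgzip).
#' @return data.frame `chrom`, `pos`, `ref`, `alt`.
#' @export
read_vcf_file <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
             ref = fx[, "REF"], alt = fx[, "ALT"], stringsAsFactors = FALSE)
}

#' Write a tract table as BED6+2
#'
#' Columns: chrom, start, end, name "class:n", score 0, strand (purine
#' strand), flank5, flank3.
#'
#' @param tracts tract data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tracts_bed <- function(tracts, path) {
  bed <- data.frame(tracts$chrom, tracts$start, tracts$end,
                    paste0(tracts$tract_class, ":", tracts$n), 0L,
                    tracts$purine_strand, tracts$flank5, tracts$flank3)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read nucleosome midpoints from BED / bedGraph / WIG
#'
#' Each interval contributes its center (left-of-center base for even
#' widths) as a dyad position.
#'
#' @param path file path; format inferred by rtracklayer.
#' @return data.frame `chrom`, `pos` (0-based dyad coordinate).
#' @export
read_midpoints_bed <- function(path) {
  gr <- rtracklayer::import(path)
  start0 <- GenomicRanges::start(gr) - 1L
  w <- GenomicRanges::width(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = start0 + (w - 1L) %/% 2L, stringsAsFactors = FALSE)
}

#' Read a BED file of intervals
#'
#' @param path BED path.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
read_intervals_bed <- function(path) {
  gr <- rtracklayer::import(path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Read a base-pair-step parameter table
#'
#' TSV with columns `frame`, `step_label`, `shift`, `slide`, `rise`, `tilt`,
#' `roll`, `twist`.
#'
#' @param path TSV path.
#' @return data.frame in the [v_step_by_step()] layout.
#' @export
read_step_params <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("frame", "step_label", STEP_PARAMS), "step table")
  df
}

#' Read a phosphate coordinate table
#'
#' TSV with columns `frame`, `strand`, `resid`, `x`, `y`, `z`.
#' @param path TSV path.
#' @return data.frame for [groove_width()].
#' @export
read_phosphate_trace <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("frame", "strand", "resid", "x", "y", "z"),
                 "phosphate trace")
  df
}

#' Read a water-bridge count table
#'
#' TSV with columns `frame`, `position`, `count`.
#' @param path TSV path.
#' @return data.frame for [bridge_occupancy()].
#' @export
read_bridge_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("frame", "position", "count"), "bridge counts")
  df
}

# Write a tidy table as TSV, prefixed with the run-manifest hash comment.
write_stat_tsv <- function(df, path, manifest_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest_hash))
    writeLines(paste0("# run: ", manifest_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
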