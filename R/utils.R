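# Small shared internals: complementation, seeded RNG scoping, run finding.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Complement bases
#'
#' Vectorized single-character complementation (N maps to N).
#' @param x character vector of single bases.
#' @return character vector of complements.
#' @keywords internal
comp_base <- function(x) {
  out <- .COMP[x]
  out[is.na(out)] <- "N"
  unname(out)
}

#' Reverse-complement a DNA string
#'
#' @param s a single character string over A,C,G,T,N (case-insensitive).
#' @return the reverse complement, uppercase.
#' @export
#' @examples
#' revcomp("CAAAAT")
revcomp <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  chartr("ACGTNacgtn", "TGCANTGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.  seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Split a sequence string into an uppercase character vector with everything
# outside {A,C,G,T} collapsed to N.
seq_chars <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ch[!ch %in% .BASES] <- "N"
  ch
}

# Maximal single-base runs in a character vector; returns a data.frame with
# 0-based half-open coordinates.  No length restriction here.
char_runs <- function(chars) {
  r <- rle(chars)
  end1 <- cumsum(r$lengths)
  data.frame(base = r$values,
             start = end1 - r$lengths,   # 0-based
             end = end1,                 # exclusive
             len = r$lengths,
             stringsAsFactors = FALSE)
}

# zero-row tract table with the canonical column set
empty_tracts <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             n = integer(0), tract_class = character(0),
             purine_strand = character(0), flank5 = character(0),
             flank3 = character(0), stringsAsFactors = FALSE)
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}
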