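#' Primer definitions for the two COI markers
#'
#' A primer definition names a marker, its forward and reverse primers (IUPAC
#' degenerate DNA, written 5'->3' on their respective strands) and the
#' expected primer-stripped insert length in nucleotides.
#'
#' @param marker_id Marker name, e.g. `"COI1"`.
#' @param forward_seq,reverse_seq IUPAC DNA strings.
#' @param expected_insert_len Expected insert length (nt) between the primers.
#' @param max_mismatches Default per-primer mismatch tolerance for matching.
#' @return An object of class `primer_def`.
#' @export
primer_def <- function(marker_id, forward_seq, reverse_seq,
                       expected_insert_len, max_mismatches = 0L) {
  stopifnot(nchar(marker_id) > 0, expected_insert_len > 0)
  for (s in c(forward_seq, reverse_seq)) {
    if (nchar(s) == 0 || grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", s))
      stop("primer sequence must be non-empty IUPAC DNA: ", s)
  }
  structure(list(marker_id = marker_id,
                 forward_seq = toupper(forward_seq),
                 reverse_seq = toupper(reverse_seq),
                 expected_insert_len = as.integer(expected_insert_len),
                 max_mismatches = as.integer(max_mismatches)),
            class = "primer_def")
}

#' Default universal metazoan COI primer set
#'
#' Two COI primer pairs targeting the Folmer barcode region: `COI1`
#' (mlCOIintF / jgHCO2198, 313 nt insert) and `COI2` (LCO1490 forward plus an
#' internal degenerate reverse primer, 325 nt insert). Inosine positions of
#' the published jgHCO2198 are written as N. The published internal COI2
#' reverse primer binds the same conserved motif as the COI1 forward primer,
#' so on a synthetic barcode its site would coincide with the COI1 forward
#' site; the default therefore uses an orthogonal degenerate stand-in of the
#' same length and degeneracy, which keeps every primer's binding site unique
#' per barcode. Real runs supply their own primer sequences via the config.
#'
#' @return A named list of [primer_def()] objects.
#' @export
default_primer_set <- function() {
  list(
    COI1 = primer_def("COI1",
                      forward_seq = "GGWACWGGWTGAACWGTWTAYCCYCC",
                      reverse_seq = "TANACYTCNGGRTGNCCRAARAAYCA",
                      expected_insert_len = 313L),
    COI2 = primer_def("COI2",
                      forward_seq = "GGTCAACAAATCATAAAGATATTGG",
                      reverse_seq = "CCTARNGAYTCNGGRTGNCA",
                      expected_insert_len = 325L)
  )
}

#' Reverse complement of DNA strings (IUPAC aware)
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Expand a degenerate IUPAC primer into one concrete realization
#'
#' Each degenerate position is replaced by a base drawn uniformly from the
#' code's expansion, using the current RNG state.
#'
#' @param primer IUPAC DNA string.
#' @return Concrete ACGT string of the same length.
#' @keywords internal
realize_primer <- function(primer) {
  exp_tab <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(primer), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- exp_tab[[ch]]
    if (is.null(opts)) stop("not an IUPAC code: ", ch)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
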