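#' Strip the allele suffix from a V-gene call
#'
#' Convergence grouping uses the V gene excluding allele information: the
#' substring of the call before the first \code{"*"}. Calls without an allele
#' designator are returned unchanged, so the operation is idempotent.
#'
#' @param v_call Character vector of V-gene calls, e.g. \code{"TRBV12-3*01"}.
#' @return Character vector of allele-stripped V-gene names.
#' @examples
#' strip_allele(c("TRBV12-3*01", "TCRBV05-01"))
#' @export
strip_allele <- function(v_call) {
  if (!is.character(v_call) || any(is.na(v_call)) || any(!nzchar(v_call))) {
    stop("'v_call' must be a character vector of non-empty strings")
  }
  sub("\\*.*$", "", v_call)
}

#' Translate a CDR3 nucleotide junction to amino acids
#'
#' Standard-genetic-code translation of in-frame CDR3 nucleotide sequences.
#' Stop codons translate to \code{"*"}; a clone whose junction contains a stop
#' is non-productive (see \code{\link{has_stop}}).
#'
#' @param cdr3_nt Character vector of A/C/G/T sequences, each with length
#'   divisible by 3.
#' @return Character vector of amino-acid sequences (possibly containing
#'   \code{"*"}).
#' @examples
#' translate_cdr3("TGTGCC")
#' @export
translate_cdr3 <- function(cdr3_nt) {
  if (!is.character(cdr3_nt) || any(is.na(cdr3_nt))) {
    stop("'cdr3_nt' must be a character vector without NA")
  }
  cdr3_nt <- toupper(cdr3_nt)
  if (any(grepl("[^ACGT]", cdr3_nt))) {
    stop("non-ACGT character in CDR3 nucleotide sequence")
  }
  if (any(nchar(cdr3_nt) %% 3L != 0L)) {
    stop("CDR3 nucleotide length not divisible by 3 (out of frame)")
  }
  out <- character(length(cdr3_nt))
  nonempty <- nzchar(cdr3_nt)
  if (any(nonempty)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(cdr3_nt[nonempty]),
                                no.init.codon = TRUE)
    out[nonempty] <- as.character(aa)
  }
  out
}

#' Does an amino-acid sequence contain a stop?
#'
#' @param cdr3_aa Character vector of amino-acid sequences.
#' @return Logical vector: \code{TRUE} where a \code{"*"} is present.
#' @export
has_stop <- function(cdr3_aa) {
  grepl("*", cdr3_aa, fixed = TRUE)
}

#' Effective CDR3 length after anchor elimination
#'
#' The reported CDR3 junction includes the conserved anchor residues (the
#' N-terminal cysteine and the C-terminal phenylalanine/tryptophan). The
#' error model's length term uses the junction length minus the two anchors.
#'
#' @param cdr3_aa Character vector of CDR3 amino-acid sequences (length >= 2).
#' @return Integer vector of effective lengths (amino acids).
#' @examples
#' effective_cdr3_length("CASSLGQAYEQYF")  # 13 aa -> 11
#' @export
effective_cdr3_length <- function(cdr3_aa) {
  if (!is.character(cdr3_aa) || any(is.na(cdr3_aa))) {
    stop("'cdr3_aa' must be a character vector without NA")
  }
  n <- nchar(cdr3_aa)
  if (any(n < 2L)) {
    stop("degenerate CDR3: amino-acid sequence shorter than 2 residues")
  }
  as.integer(n - 2L)
}

# codon -> amino acid lookup (standard code), and aa -> codons for
# back-translation; stop codons excluded from the sense table
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  list(codon_to_aa = gc,
       sense_codons = names(gc)[gc != "*"],
       aa_to_codons = split(names(gc)[gc != "*"], gc[gc != "*"]))
}

.codon_env <- new.env(parent = emptyenv())

.codons <- function() {
  if (is.null(.codon_env$tab)) .codon_env$tab <- .codon_table()
  .codon_env$tab
}
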