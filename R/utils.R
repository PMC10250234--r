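# Internal residue helpers. All sequences are handled as uppercase RNA
# ({A,C,G,U,N}) internally; DNA is converted at I/O when rna_mode is on.

RNA_ALPHABET <- c("A", "C", "G", "U", "N")

# codes used by the C++ kernels: A=0 C=1 G=2 U=3 N=4 gap=5
encode_residues <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "U", "N", "-")) - 1L
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    abort(sprintf("illegal residue '%s' at position %d", chars[bad], bad))
  }
  code
}

decode_residues <- function(code) {
  paste(c("A", "C", "G", "U", "N", "-")[code + 1L], collapse = "")
}

#' Reverse complement of an RNA string
#'
#' N maps to N; the input must be uppercase RNA.
#' @param x a single RNA string over `{A,C,G,U,N}`.
#' @return the reverse complement string.
#' @export
revcomp_rna <- function(x) {
  chartr("ACGUN", "UGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# canonical 5'->3' pair test on single characters (vectorised)
is_canonical_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

normalize_residues <- function(x, rna_mode, lenient = FALSE, id = "?") {
  x <- toupper(x)
  if (rna_mode) x <- chartr("T", "U", x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  alphabet <- if (rna_mode) RNA_ALPHABET else c("A", "C", "G", "T", "N")
  bad <- !(chars %in% alphabet)
  if (any(bad)) {
    iupac <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
    if (lenient && all(chars[bad] %in% iupac)) {
      chars[bad] <- "N"
      return(paste(chars, collapse = ""))
    }
    pos <- which(bad)[1]
    abort(sprintf("record '%s': illegal residue '%s' at position %d",
                  id, chars[pos], pos))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
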