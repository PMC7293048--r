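#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
NULL

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

abort_alphabet <- function(seq, alphabet) {
  abort(
    sprintf(
      "invalid %s sequence: characters outside {%s} in %s",
      alphabet, paste(if (alphabet == "RNA") RNA_BASES else DNA_BASES, collapse = ","),
      encodeString(substr(seq, 1, 40), quote = "\"")
    ),
    class = "tasitune_alphabet_error"
  )
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Any character outside A/C/G/U raises an
#' alphabet error. All small-RNA logic in the package works in the RNA
#' alphabet; conversion happens at input boundaries.
#'
#' @param seq A character scalar.
#' @return A character scalar over A/C/G/U.
#' @export
as_rna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  out <- chartr("t", "u", toupper(seq))
  out <- chartr("T", "U", out)
  if (grepl("[^ACGU]", out)) abort_alphabet(out, "RNA")
  out
}

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and converts U to T (the explicit RNA->DNA boundary used by the
#' cloning layer). Characters outside A/C/G/T raise an alphabet error.
#'
#' @inheritParams as_rna
#' @return A character scalar over A/C/G/T.
#' @export
as_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  out <- chartr("U", "T", toupper(seq))
  if (grepl("[^ACGT]", out)) abort_alphabet(out, "DNA")
  out
}

#' Reverse complement of a nucleotide string
#'
#' Standard antiparallel complement via Biostrings. The operation is an
#' involution: `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param seq A character scalar.
#' @param alphabet `"RNA"` or `"DNA"`.
#' @return The reverse complement, same alphabet.
#' @examples
#' reverse_complement("AUGC", "RNA")  # "GCAU"
#' @export
reverse_complement <- function(seq, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "RNA") {
    seq <- as_rna(seq)
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(seq)))
  } else {
    seq <- as_dna(seq)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

gc_fraction <- function(seq) {
  ch <- seq_chars(seq)
  mean(ch %in% c("G", "C"))
}

max_homopolymer_run <- function(seq) {
  r <- rle(seq_chars(seq))
  max(r$lengths)
}

## Coerce a user-supplied transcriptome (path to FASTA, DNAStringSet, or a
## named character vector) to a named character vector of DNA sequences.
load_sequences <- function(x, what = "transcriptome") {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x) %||% as.character(seq_along(x)))
  } else if (is.character(x)) {
    out <- toupper(x)
    if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
      abort(sprintf("%s sequences must be named", what), class = "tasitune_input_error")
    }
  } else {
    abort(sprintf("cannot interpret %s input of class <%s>", what, class(x)[1]),
          class = "tasitune_input_error")
  }
  if (length(out) == 0L) {
    abort(sprintf("%s is empty", what), class = "tasitune_input_error")
  }
  if (anyDuplicated(names(out))) {
    abort(sprintf("duplicate ids in %s: %s", what,
                  paste(unique(names(out)[duplicated(names(out))]), collapse = ", ")),
          class = "tasitune_input_error")
  }
  out
}
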