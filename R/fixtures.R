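## All fixture randomness flows through one seeded generator via
## withr::with_seed; no ambient entropy is read.

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Random DNA with no BsaI recognition site (rejection sampling; draws stay
## inside the caller's seeded stream, so results are deterministic).
random_dna_bsai_free <- function(n, config = tasitune_config()) {
  for (i in 1:100) {
    s <- random_dna(n)
    if (nrow(scan_bsai(s, config)) == 0L) return(s)
  }
  abort("could not generate a BsaI-free segment", class = "tasitune_internal_error")
}

#' Generate a synthetic transcriptome fixture
#'
#' Uniform-random transcripts of seeded, reproducible sequence; optionally
#' implants the perfect target site (reverse complement) of a guide at a
#' stated offset of one transcript, so the off-target scanner is guaranteed
#' a score-0 hit at known coordinates. Identical arguments give
#' byte-identical output.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param n_transcripts Number of transcripts (> 0).
#' @param length_range Length range in nt, `c(min, max)`.
#' @param implant Optional list: `guide` (sequence or [guide()]),
#'   `transcript` (index, default 1) and `offset` (0-based, default 30)
#'   where the guide's perfect site is written.
#' @param path Optional path; if given the transcriptome is also written as
#'   FASTA.
#' @return A named `DNAStringSet` (ids `tx01`, `tx02`, ...).
#' @export
make_transcriptome <- function(seed, n_transcripts = 20L,
                               length_range = c(300L, 600L),
                               implant = NULL, path = NULL) {
  if (n_transcripts < 1L) {
    abort("n_transcripts must be >= 1", class = "tasitune_input_error")
  }
  seqs <- withr::with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_transcripts, replace = TRUE)
    vapply(lens, random_dna, character(1))
  })
  names(seqs) <- sprintf("tx%02d", seq_len(n_transcripts))
  if (!is.null(implant)) {
    g <- as_guide(implant$guide)
    idx <- implant$transcript %||% 1L
    offset <- implant$offset %||% 30L
    site <- reverse_complement(as_dna(g$sequence), "DNA")
    if (offset < 0L || offset + nchar(site) > nchar(seqs[[idx]])) {
      abort(sprintf("implant offset %d is beyond transcript %d (%d nt)",
                    offset, idx, nchar(seqs[[idx]])),
            class = "tasitune_input_error")
    }
    seqs[[idx]] <- paste0(substr(seqs[[idx]], 1L, offset), site,
                          substr(seqs[[idx]], offset + nchar(site) + 1L,
                                 nchar(seqs[[idx]])))
  }
  out <- Biostrings::DNAStringSet(seqs)
  if (!is.null(path)) Biostrings::writeXStringSet(out, path)
  out
}

#' Generate a synthetic cloning-ready backbone fixture
#'
#' Builds a synthetic plasmid mirroring the published AtTAS1c "B/c" vector
#' layout: upstream promoter placeholder, 21-nt miR173 target site, slot D1
#' (the site's retained 11-nt 3' half plus endogenous filler ending in the
#' TTTA overhang region), a stuffer cassette between two inverted,
#' outward-cutting BsaI sites, and a downstream truncated-precursor region
#' that opens with the TCGG overhang region (the start of the endogenous D4
#' slot). The released stuffer defaults to the 1461-bp cassette size of the
#' published vectors. The sequence is synthetic throughout: it reproduces
#' the layout and cloning chemistry, not the real plasmid sequence.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param stuffer_len Released-fragment length in bp (>= 20; default 1461).
#' @param mir173_cassette Append a BsaI-free AtMIR173 co-expression
#'   cassette placeholder downstream (the layout used outside Arabidopsis).
#' @param upstream_len,tail_len Flanking filler lengths in nt.
#' @param name Backbone label.
#' @return A [precursor_backbone()] object.
#' @export
make_backbone_fixture <- function(seed, stuffer_len = 1461L,
                                  mir173_cassette = FALSE,
                                  upstream_len = 150L, tail_len = 80L,
                                  name = "synthetic-AtTAS1c-D2-Bc") {
  if (stuffer_len < 20L) {
    abort("stuffer_len must be >= 20 bp (two BsaI sites plus spacers and overhangs)",
          class = "tasitune_input_error")
  }
  internal_len <- stuffer_len - 18L   # 4 (TTTA) + 1 + 6 + internal + 6 + 1 = released
  withr::with_seed(seed, {
    for (attempt in 1:50) {
      upstream <- random_dna_bsai_free(upstream_len)
      mir173_site <- random_dna_bsai_free(21L)
      d1_filler <- random_dna_bsai_free(6L)
      stuffer_internal <- random_dna_bsai_free(internal_len)
      spacers <- c(random_dna(1L), random_dna(1L))
      endo <- c(
        "2" = random_dna_bsai_free(21L),
        "3" = random_dna_bsai_free(21L),
        "4" = paste0("TCGG", random_dna_bsai_free(17L)),
        "5" = random_dna_bsai_free(21L)
      )
      tail_seq <- random_dna_bsai_free(tail_len)
      cassette <- if (mir173_cassette)
        paste0("TTAATTAA", random_dna_bsai_free(200L)) else ""

      ## Layout along the plus strand. The TTTA at the end of slot D1 and
      ## the TCGG opening the downstream endogenous D4 slot double as the
      ## BsaI overhang regions: the minus-strand site (GAGACC) cuts 5/1 nt
      ## upstream of itself, the plus-strand site (GGTCTC) 1/5 nt
      ## downstream, each leaving a 4-nt 5' overhang.
      vector_seq <- paste0(
        upstream, mir173_site,
        d1_filler, "TTTA",                 # completes slot D1 after the 11-nt site 3' half
        spacers[1], "GAGACC",              # minus-strand BsaI, cuts leftward
        stuffer_internal,
        "GGTCTC", spacers[2],              # plus-strand BsaI, cuts rightward
        endo[["4"]],                       # downstream resumes with endogenous D4 (TCGG...)
        endo[["5"]], tail_seq, cassette
      )
      sites <- scan_bsai(vector_seq)
      ## Junction safety for the maximal all-filler insert (core D2..D5):
      ## the assembled region downstream of D1 would read TTTA + core +
      ## the vector's own endogenous D4/D5 tail.
      after_insert <- paste0("TTTA", paste(endo, collapse = ""),
                             endo[["4"]], endo[["5"]], tail_seq, cassette)
      if (nrow(sites) == 2L && identical(sites$strand, c("-", "+")) &&
          nrow(scan_bsai(after_insert)) == 0L) {
        return(precursor_backbone(
          vector_seq, mir173_start = upstream_len,
          endogenous_slots = endo, mir173_cassette = mir173_cassette,
          name = name
        ))
      }
    }
  })
  abort("failed to generate a valid backbone fixture", class = "tasitune_internal_error")
}

#' Load the packaged synthetic cloning vector
#'
#' The package ships a synthetic stand-in for the pENTR-AtTAS1c-D2-B/c
#' entry vector (plain-text FASTA plus a JSON annotation sidecar under
#' `inst/extdata/`): same layout, cloning chemistry and 1461-bp released
#' cassette as the published vector, but synthetic sequence throughout.
#'
#' @return A [precursor_backbone()] object.
#' @export
load_packaged_backbone <- function() {
  fa <- system.file("extdata", "pENTR_AtTAS1c_D2_Bc_synthetic.fasta",
                    package = "tasitune", mustWork = TRUE)
  meta <- jsonlite::read_json(
    system.file("extdata", "pENTR_AtTAS1c_D2_Bc_synthetic.json",
                package = "tasitune", mustWork = TRUE),
    simplifyVector = TRUE)
  seqs <- load_sequences(fa, what = "backbone vector")
  precursor_backbone(seqs[[1]], mir173_start = meta$mir173_start,
                     endogenous_slots = unlist(meta$endogenous_slots),
                     mir173_cassette = isTRUE(meta$mir173_cassette),
                     name = names(seqs)[1])
}
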