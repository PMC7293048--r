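#' Scan a DNA sequence for BsaI recognition sites
#'
#' Reports every occurrence of the recognition sequence GGTCTC on the plus
#' strand and of its reverse complement GAGACC (a minus-strand site) with
#' 0-based start coordinates on the plus strand.
#'
#' @param seq A DNA string.
#' @param config A [tasitune_config()] list (enzyme record override).
#' @return A tibble (`start` 0-based, `strand`) ordered by `start`.
#' @examples
#' scan_bsai("AAGGTCTCAA")  # one plus-strand site at 2
#' @export
scan_bsai <- function(seq, config = tasitune_config()) {
  seq <- as_dna(seq)
  rec <- config$enzyme$recognition
  rec_rc <- reverse_complement(rec, "DNA")
  find_all <- function(pat) {
    m <- gregexpr(pat, seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  }
  out <- dplyr::bind_rows(
    tibble(start = find_all(rec), strand = "+"),
    tibble(start = find_all(rec_rc), strand = "-")
  )
  dplyr::arrange(out, .data$start)
}

## Locate and validate the inverted BsaI pair of a cloning-ready vector.
## The outward-cutting configuration has the minus-strand site (GAGACC on
## the plus strand, start q) upstream of the plus-strand site (GGTCTC,
## start p). BsaI cuts 1 nt beyond its recognition sequence leaving 4-nt 5'
## overhangs, so digestion cuts the top strand at q-5 and p+7 and the
## bottom strand at q-1 and p+11 (0-based plus-strand coordinates). The
## released fragment is p - q + 12 bp and carries both recognition sites;
## the vector ends expose the overhang regions [q-5, q-1) and [p+7, p+11).
locate_bsai_pair <- function(seq, config = tasitune_config()) {
  sites <- scan_bsai(seq, config)
  if (nrow(sites) != 2L) {
    abort(sprintf("cloning-ready vector must contain exactly 2 BsaI sites (found %d)",
                  nrow(sites)), class = "tasitune_vector_error")
  }
  if (!identical(sites$strand, c("-", "+"))) {
    abort("the two BsaI sites must be inverted and cut outward (minus-strand site upstream of plus-strand site)",
          class = "tasitune_vector_error")
  }
  q <- sites$start[1]
  p <- sites$start[2]
  if (q < 5L || p + 11L > nchar(seq)) {
    abort("BsaI cut positions fall outside the vector", class = "tasitune_vector_error")
  }
  list(
    q = q, p = p,
    left_keep_end = q - 5L,                       # top strand retained [0, q-5)
    right_keep_start = p + 7L,                    # top strand retained [p+7, L)
    left_overhang = substr(seq, q - 4L, q - 1L),  # plus-strand [q-5, q-1)
    right_overhang = substr(seq, p + 8L, p + 11L),# plus-strand [p+7, p+11)
    released_length = p - q + 12L
  )
}

#' Length of the cassette released by BsaI digestion
#'
#' Simulates BsaI digestion of a vector carrying two inverted,
#' outward-cutting sites and returns the length of the released stuffer
#' fragment (both strands have this length; each end is a 4-nt 5'
#' overhang). The released-fragment length is this package's definition of
#' "cassette length".
#'
#' @param vector_seq The vector DNA sequence.
#' @param config A [tasitune_config()] list.
#' @return Integer fragment length in bp.
#' @export
excised_stuffer_length <- function(vector_seq, config = tasitune_config()) {
  locate_bsai_pair(as_dna(vector_seq), config)$released_length
}

#' Construct a precursor backbone record
#'
#' The cloning-ready, truncated AtTAS1c cassette: the miR173 target site,
#' the trigger-cleavage offset that anchors the DCL4 phasing register, the
#' inverted BsaI pair flanking the stuffer, and the endogenous 21-nt slot
#' sequences used as filler for unoccupied positions. miR173-guided
#' cleavage occurs between target-site positions 10 and 11, so the site's
#' 3' half (11 nt) is retained downstream and opens slot D1.
#'
#' @param sequence Vector DNA sequence (cloning-ready, with stuffer).
#' @param mir173_start 0-based start of the 21-nt miR173 target site.
#' @param endogenous_slots Named character vector (names `"2"`..`"5"`) of
#'   21-nt DNA fillers for unoccupied slots.
#' @param mir173_cassette Logical: does the vector carry a co-expression
#'   AtMIR173 cassette (required outside Arabidopsis)? If so it must be
#'   free of BsaI sites.
#' @param name Backbone label.
#' @return An object of class `tasitune_backbone`.
#' @export
precursor_backbone <- function(sequence, mir173_start, endogenous_slots,
                               mir173_cassette = FALSE, name = "backbone") {
  sequence <- as_dna(sequence)
  mir173_start <- as.integer(mir173_start)
  cleavage_offset <- mir173_start + 10L
  pair <- locate_bsai_pair(sequence)
  site_seq <- substr(sequence, mir173_start + 1L, mir173_start + 21L)
  if (nchar(site_seq) != 21L) {
    abort("miR173 target site must be 21 nt inside the vector",
          class = "tasitune_vector_error")
  }
  if (pair$left_keep_end != cleavage_offset + 17L) {
    abort("left BsaI cut must fall 17 nt downstream of the cleavage offset (end of slot D1 minus the 4-nt overhang)",
          class = "tasitune_vector_error")
  }
  if (pair$left_overhang != "TTTA" || pair$right_overhang != "TCGG") {
    abort("vector overhang regions must be TTTA (left) and TCGG (right) for the TTTA/CCGA oligo chemistry",
          class = "tasitune_vector_error")
  }
  stopifnot(length(endogenous_slots) == 4L,
            identical(sort(names(endogenous_slots)), c("2", "3", "4", "5")))
  endogenous_slots <- vapply(endogenous_slots, as_dna, character(1))
  if (any(nchar(endogenous_slots) != 21L)) {
    abort("endogenous slot fillers must be 21 nt", class = "tasitune_vector_error")
  }
  structure(
    list(name = name, sequence = sequence,
         mir173_site = c(start = mir173_start, end = mir173_start + 21L),
         cleavage_offset = cleavage_offset,
         bsa1_sites = scan_bsai(sequence),
         stuffer_length = pair$released_length,
         endogenous_slots = endogenous_slots,
         mir173_cassette = mir173_cassette),
    class = "tasitune_backbone"
  )
}

#' @export
print.tasitune_backbone <- function(x, ...) {
  cat(sprintf("<precursor backbone> %s: %d bp; miR173 site [%d,%d); cleavage offset %d; stuffer %d bp%s\n",
              x$name, nchar(x$sequence), x$mir173_site["start"], x$mir173_site["end"],
              x$cleavage_offset, x$stuffer_length,
              if (x$mir173_cassette) "; AtMIR173 cassette" else ""))
  invisible(x)
}

slot_coords <- function(cleavage_offset, k) {
  c(start = cleavage_offset + 21L * (k - 1L), end = cleavage_offset + 21L * k)
}

#' Place guides into DCL4 positions of the precursor
#'
#' Builds the syn-tasiRNA insert and the assembled construct. Slot k
#' (3'Dk\[+\]) spans backbone coordinates
#' `[cleavage_offset + 21(k-1), cleavage_offset + 21k)`. Position 1 is
#' reserved: slot D1 retains the 3' half of the miR173 target site and
#' cannot express a syn-tasiRNA. The insert core always covers slots
#' D2..max(3, most distal occupied slot); unoccupied core slots carry the
#' endogenous AtTAS1c filler. Guides are converted U->T at this boundary
#' (logged via message).
#'
#' @param backbone A [precursor_backbone()].
#' @param guides Named list/character vector mapping positions (`"2"`..
#'   `"5"`) to 21-nt guide sequences (RNA or DNA), or a data frame with
#'   columns `position` and `guide` (and optionally `name`).
#' @param quiet Suppress the U->T conversion message.
#' @return An object of class `tasitune_precursor_construct` with the slot
#'   assignment table, the insert core, and the fully assembled vector
#'   sequence (stuffer excised, insert ligated; no BsaI site remains).
#' @export
assemble_precursor <- function(backbone, guides, quiet = FALSE) {
  stopifnot(inherits(backbone, "tasitune_backbone"))
  if (is.data.frame(guides)) {
    pos <- as.integer(guides$position)
    seqs <- as.character(guides$guide)
    nms <- if ("name" %in% names(guides)) guides$name else
      sprintf("guide-D%d", pos)
  } else {
    pos <- as.integer(names(guides))
    seqs <- as.character(unlist(guides))
    nms <- sprintf("guide-D%d", pos)
  }
  if (any(is.na(pos))) {
    abort("guide positions must be integers 2..5", class = "tasitune_input_error")
  }
  if (any(pos == 1L)) {
    abort("position 3'D1[+] holds the 3' half of the miR173 target site and cannot carry a syn-tasiRNA",
          class = "tasitune_forbidden_slot_error")
  }
  if (any(pos < 2L | pos > 5L)) {
    abort("positions must be in 2..5 (3'D2[+]..3'D5[+])", class = "tasitune_input_error")
  }
  if (anyDuplicated(pos)) {
    abort("duplicate precursor position requested", class = "tasitune_conflict_error")
  }
  if (length(pos) == 0L) {
    abort("at least one guide is required", class = "tasitune_input_error")
  }
  had_u <- grepl("U", toupper(seqs))
  seqs_dna <- vapply(seqs, as_dna, character(1), USE.NAMES = FALSE)
  if (any(had_u) && !quiet) {
    message(sprintf("converted %d guide(s) from RNA to DNA (U->T) for cloning",
                    sum(had_u)))
  }
  if (any(nchar(seqs_dna) != 21L)) {
    abort("guides must be 21 nt", class = "tasitune_length_error")
  }
  for (i in seq_along(seqs_dna)) {
    if (nrow(scan_bsai(seqs_dna[i])) > 0L) {
      abort(sprintf("guide at position D%d contains a BsaI recognition site; incompatible with golden-gate cloning",
                    pos[i]), class = "tasitune_cloning_error")
    }
  }

  k_max <- max(3L, max(pos))
  core_slots <- 2L:k_max
  assignments <- tibble(
    position = core_slots,
    slot = sprintf("3'D%d[+]", core_slots),
    name = ifelse(core_slots %in% pos, nms[match(core_slots, pos)],
                  sprintf("AtTAS1c-D%d", core_slots)),
    sequence = ifelse(core_slots %in% pos, seqs_dna[match(core_slots, pos)],
                      unname(backbone$endogenous_slots[as.character(core_slots)])),
    role = ifelse(core_slots %in% pos, "guide", "endogenous_filler")
  )
  core <- paste(assignments$sequence, collapse = "")
  if (nrow(scan_bsai(core)) > 0L) {
    abort("insert core contains a BsaI recognition site; incompatible with golden-gate cloning",
          class = "tasitune_cloning_error")
  }

  pair <- locate_bsai_pair(backbone$sequence)
  assembled <- paste0(
    substr(backbone$sequence, 1L, pair$left_keep_end),          # [0, q-5)
    "TTTA", core,
    substr(backbone$sequence, pair$right_keep_start + 1L,
           nchar(backbone$sequence))                            # [p+7, L)
  )
  if (nrow(scan_bsai(assembled)) > 0L) {
    abort("assembly would create a BsaI recognition site at an insert junction",
          class = "tasitune_cloning_error")
  }
  cleav <- backbone$cleavage_offset
  for (i in seq_len(nrow(assignments))) {
    cc <- slot_coords(cleav, assignments$position[i])
    stopifnot(substr(assembled, cc["start"] + 1L, cc["end"]) == assignments$sequence[i])
  }
  structure(
    list(backbone = backbone, assignments = assignments, core = core,
         k_max = k_max, cleavage_offset = cleav, assembled_sequence = assembled),
    class = "tasitune_precursor_construct"
  )
}

#' @export
print.tasitune_precursor_construct <- function(x, ...) {
  cat(sprintf("<precursor construct> %d bp; insert core %d bp (slots D2..D%d)\n",
              nchar(x$assembled_sequence), nchar(x$core), x$k_max))
  print(x$assignments, ...)
  invisible(x)
}

#' Simulate DCL4 phased processing of an assembled construct
#'
#' Returns the consecutive, non-overlapping 21-mers measured from the
#' miR173-guided cleavage offset (the phasing register): slot D1 first
#' (carrying the 11-nt 3' half of the miR173 target site as its prefix),
#' then D2, D3, ... to the end of the precursor (a trailing partial slot is
#' dropped). The guide placed at position k is released verbatim as the
#' k-th phased small RNA.
#'
#' @param construct A [assemble_precursor()] result, or a raw DNA sequence
#'   (then `cleavage_offset` must be given).
#' @param cleavage_offset 0-based phasing anchor when `construct` is a raw
#'   sequence.
#' @return A tibble: `k`, `slot`, `start`, `end` (0-based on the assembled
#'   sequence) and `sequence` (RNA).
#' @export
simulate_phasing <- function(construct, cleavage_offset = NULL) {
  if (inherits(construct, "tasitune_precursor_construct")) {
    seq <- construct$assembled_sequence
    cleav <- construct$cleavage_offset
  } else {
    seq <- as_dna(construct)
    cleav <- cleavage_offset %||%
      abort("cleavage_offset is required for a raw sequence",
            class = "tasitune_input_error")
  }
  starts <- seq.int(cleav, nchar(seq) - 21L, by = 21L)
  tibble(
    k = seq_along(starts),
    slot = sprintf("3'D%d[+]", seq_along(starts)),
    start = as.integer(starts), end = as.integer(starts) + 21L,
    sequence = vapply(starts, function(s)
      as_rna(substr(seq, s + 1L, s + 21L)), character(1))
  )
}

#' Design the golden-gate cloning oligonucleotide pair
#'
#' The insert duplex core spans slots D2..max(3, most distal occupied
#' slot), so its length is `21 * (max(3, k_max) - 1)` bp. The top oligo is
#' 5'-TTTA + core sense strand; the bottom oligo is 5'-CCGA + core
#' antisense strand. Both oligos are core + 4 nt long: 46 nt for the
#' standard single-D2, single-D3 or dual-D2&D3 configurations; a D5 guide
#' extends the core to 84 bp (88-nt oligos). Annealing the pair
#' reconstitutes the core flanked by the TTTA/CCGA 4-nt 5' extensions that
#' match the BsaI-digested vector ends.
#'
#' @param construct A [assemble_precursor()] result.
#' @return An object of class `tasitune_oligo_pair` with fields `top`,
#'   `bottom` and `duplex_core_len`.
#' @export
design_oligos <- function(construct) {
  stopifnot(inherits(construct, "tasitune_precursor_construct"))
  core <- construct$core
  if (nrow(scan_bsai(core)) > 0L) {
    abort("insert core contains a BsaI recognition site", class = "tasitune_cloning_error")
  }
  structure(
    list(top = paste0("TTTA", core),
         bottom = paste0("CCGA", reverse_complement(core, "DNA")),
         duplex_core_len = nchar(core)),
    class = "tasitune_oligo_pair"
  )
}

#' @export
print.tasitune_oligo_pair <- function(x, ...) {
  cat(sprintf("<oligo pair> core %d bp, oligos %d nt\n  top    5'-%s-3'\n  bottom 5'-%s-3'\n",
              x$duplex_core_len, nchar(x$top), x$top, x$bottom))
  invisible(x)
}

#' Anneal an oligo pair into the insert duplex
#'
#' Checks that the two single strands are complementary over the duplex
#' core and returns the core with the two 4-nt 5' overhangs.
#'
#' @param pair A [design_oligos()] result or a list with `top`/`bottom`.
#' @return List: `core`, `top_overhang`, `bottom_overhang`.
#' @export
anneal_oligos <- function(pair) {
  top <- as_dna(pair$top)
  bottom <- as_dna(pair$bottom)
  if (nchar(top) != nchar(bottom)) {
    abort("oligos must have equal length", class = "tasitune_ligation_error")
  }
  core <- substr(top, 5L, nchar(top))
  if (reverse_complement(core, "DNA") != substr(bottom, 5L, nchar(bottom))) {
    abort("oligos do not anneal: strands are not complementary over the duplex core",
          class = "tasitune_ligation_error")
  }
  list(core = core, top_overhang = substr(top, 1L, 4L),
       bottom_overhang = substr(bottom, 1L, 4L))
}

#' Simulate BsaI digestion and directional ligation (golden gate)
#'
#' Digests the vector at its two inverted BsaI sites (excising the stuffer
#' cassette), checks orientation-specifically that the annealed insert's 5'
#' overhangs match the exposed vector ends (top oligo overhang against the
#' upstream end, bottom oligo overhang against the downstream end), and
#' returns the ligated plasmid. The reaction is seamless and idempotent:
#' the product carries no BsaI recognition site, so re-digestion finds
#' nothing.
#'
#' @param vector_seq Vector DNA with exactly two inverted BsaI sites.
#' @param oligo_pair A [design_oligos()] result.
#' @param config A [tasitune_config()] list.
#' @return The ligated plasmid DNA sequence (character scalar).
#' @export
golden_gate_assemble <- function(vector_seq, oligo_pair, config = tasitune_config()) {
  vector_seq <- as_dna(vector_seq)
  pair <- locate_bsai_pair(vector_seq, config)
  duplex <- anneal_oligos(oligo_pair)
  ## The vector's upstream end exposes a bottom-strand 5' overhang that is
  ## the reverse complement of plus-strand [q-5, q-1); the insert's top
  ## overhang must equal that plus-strand region. Downstream, the vector
  ## exposes the plus-strand overhang [p+7, p+11); the insert's bottom
  ## overhang must be its reverse complement.
  if (duplex$top_overhang != pair$left_overhang ||
      duplex$bottom_overhang != reverse_complement(pair$right_overhang, "DNA")) {
    abort(sprintf("overhang mismatch: insert %s/%s vs vector ends %s/%s; ligation is orientation-specific",
                  duplex$top_overhang, duplex$bottom_overhang,
                  pair$left_overhang, pair$right_overhang),
          class = "tasitune_ligation_error")
  }
  product <- paste0(
    substr(vector_seq, 1L, pair$left_keep_end),
    duplex$top_overhang, duplex$core,
    substr(vector_seq, pair$right_keep_start + 1L, nchar(vector_seq))
  )
  if (nrow(scan_bsai(product, config)) > 0L) {
    abort("ligation product retains a BsaI recognition site",
          class = "tasitune_cloning_error")
  }
  product
}

#' Write the feature table of a construct
#'
#' Plain-text (TSV) annotation of an assembled construct: miR173 target
#' site, cleavage offset, each 21-nt slot with its role, and the former
#' BsaI scar positions. Coordinates are 0-based half-open on the assembled
#' sequence.
#'
#' @param construct A [assemble_precursor()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_construct_features <- function(construct, path) {
  stopifnot(inherits(construct, "tasitune_precursor_construct"))
  cleav <- construct$cleavage_offset
  rows <- dplyr::bind_rows(
    tibble(feature = "miR173_target_site",
           start = unname(construct$backbone$mir173_site["start"]),
           end = unname(construct$backbone$mir173_site["end"]),
           label = "trigger site"),
    tibble(feature = "cleavage_offset", start = cleav, end = cleav,
           label = "phasing register anchor"),
    tibble(feature = "slot", start = cleav, end = cleav + 21L,
           label = "3'D1[+] (miR173 site 3' half)"),
    tibble(feature = "slot",
           start = cleav + 21L * (construct$assignments$position - 1L),
           end = cleav + 21L * construct$assignments$position,
           label = sprintf("%s: %s (%s)", construct$assignments$slot,
                           construct$assignments$name, construct$assignments$role))
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a construct or backbone as FASTA
#'
#' @param x A construct, backbone, or named character vector.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_sequence_fasta <- function(x, path) {
  seqs <- if (inherits(x, "tasitune_precursor_construct")) {
    stats::setNames(x$assembled_sequence, "assembled_construct")
  } else if (inherits(x, "tasitune_backbone")) {
    stats::setNames(x$sequence, x$name)
  } else {
    x
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
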