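## Evaluate the design heuristics on one candidate guide (RNA). Returns a
## named logical vector: TRUE = heuristic satisfied.
guide_heuristics <- function(guide_rna, config) {
  d <- config$design
  dna <- as_dna(guide_rna)
  c(
    five_prime_U = substr(guide_rna, 1, 1) == "U",
    pos19_C = substr(guide_rna, 19, 19) == "C",
    gc_content = {
      gc <- gc_fraction(guide_rna)
      gc >= d$gc_min && gc <= d$gc_max
    },
    homopolymer = max_homopolymer_run(guide_rna) <= d$max_homopolymer,
    no_bsai = nrow(scan_bsai(dna)) == 0L
  )
}

enabled_heuristics <- function(config) {
  d <- config$design
  c(five_prime_U = isTRUE(d$require_5p_U), pos19_C = isTRUE(d$require_pos19_C),
    gc_content = TRUE, homopolymer = TRUE, no_bsai = isTRUE(d$forbid_bsai))
}

#' Design candidate guide small RNAs against a target transcript
#'
#' Enumerates every 21-nt window on the transcript sense strand, builds the
#' guide as the window's reverse complement, keeps candidates satisfying the
#' enabled design heuristics (5' U, position-19 C, 30-60% GC, no >=5-nt
#' homopolymer, no BsaI site — see [tasitune_config()]), screens each
#' against the transcriptome with the intended transcript excluded from
#' failure, and returns the top `n` ranked by fewest heuristic violations,
#' then largest worst-case off-target margin (the minimum score on any
#' unintended transcript; larger = safer), then 5'-most site.
#'
#' @param transcript A single-record FASTA path, `DNAStringSet` of length 1,
#'   or named character scalar: the target transcript.
#' @param transcriptome Transcriptome to screen against (see
#'   [scan_transcriptome()]); should include the target transcript.
#' @param n Number of candidates to return (fewer if fewer pass).
#' @param cutoff Off-target specificity cutoff (default from config).
#' @param config A [tasitune_config()] list.
#' @return A tibble of class `tasitune_guide_candidates`, one row per
#'   retained candidate: `rank`, `name`, `guide`, `site`, `start`, `end`
#'   (0-based on the transcript), `gc`, one logical column per heuristic,
#'   `n_violations`, `offtarget_margin`, `pass`. Zero passing candidates
#'   yields an empty tibble with a warning.
#' @export
design_guides <- function(transcript, transcriptome, n = 3L, cutoff = NULL,
                          config = tasitune_config()) {
  tr <- load_sequences(transcript, what = "target transcript")
  if (length(tr) != 1L) {
    abort("exactly one target transcript is required", class = "tasitune_input_error")
  }
  target_id <- names(tr)
  tr_seq <- chartr("U", "T", toupper(tr[[1]]))
  L <- config$pairing$guide_length
  if (nchar(tr_seq) < L) {
    abort(sprintf("transcript '%s' (%d nt) is shorter than the guide length (%d nt)",
                  target_id, nchar(tr_seq), L),
          class = "tasitune_input_error")
  }
  if (n < 1L) abort("n must be >= 1", class = "tasitune_input_error")
  cutoff <- cutoff %||% config$offtarget$cutoff
  enabled <- enabled_heuristics(config)

  starts <- seq_len(nchar(tr_seq) - L + 1L)       # 1-based window starts
  rows <- purrr::map(starts, function(t) {
    site_dna <- substr(tr_seq, t, t + L - 1L)
    g_rna <- reverse_complement(as_rna(site_dna), "RNA")
    h <- guide_heuristics(g_rna, config)
    tibble(start = t - 1L, end = t - 1L + L, site = as_rna(site_dna),
           guide = g_rna, gc = gc_fraction(g_rna), !!!as.list(h),
           n_violations = sum(!h), retained = all(h[enabled]))
  })
  cand <- dplyr::bind_rows(rows)
  cand <- dplyr::filter(cand, .data$retained)
  cand$retained <- NULL

  if (nrow(cand)) {
    screens <- purrr::map(cand$guide, function(g)
      scan_transcriptome(g, transcriptome, cutoff = cutoff, intended = target_id,
                         config = config))
    cand$offtarget_margin <- purrr::map_dbl(screens, "min_unintended_score")
    cand$pass <- purrr::map_lgl(screens, "pass")
    cand <- dplyr::filter(cand, .data$pass)
  }
  if (!nrow(cand)) {
    warning(sprintf("no candidate guide against '%s' passes the design and specificity filters",
                    target_id))
    cand <- dplyr::mutate(cand,
                          offtarget_margin = numeric(0), pass = logical(0))
  }
  cand <- dplyr::arrange(cand, .data$n_violations,
                         dplyr::desc(.data$offtarget_margin), .data$start)
  cand <- utils::head(cand, n)
  cand <- dplyr::mutate(cand,
    rank = dplyr::row_number(),
    name = sprintf("syn-tasiR-%s-%02d", target_id, .data$rank),
    transcript_id = target_id, .before = 1)
  class(cand) <- c("tasitune_guide_candidates", class(cand))
  cand
}

#' Generate the consecutive 3'-end mismatch variant series of a guide
#'
#' Variant k (k = 1..`k_max`, default 5) substitutes guide positions
#' (L-k+1)..L — the 3'-terminal k positions — setting each guide base equal
#' to the opposing target-site base. Identical bases can neither
#' Watson-Crick pair nor wobble, so variant k is guaranteed to show a
#' 3'-terminal mismatch run of exactly k against the parent's site, for any
#' parent sequence. If a transcriptome is supplied each variant is
#' re-screened and flagged (never silently dropped) if it gains an
#' off-target.
#'
#' @param parent A [guide()] or nucleotide string: the unmutated guide.
#' @param site The parent's target site ([target_site()] or string).
#' @param k_max Number of variants, 1..(guide length - 1); default 5.
#' @param transcriptome Optional transcriptome for re-screening.
#' @param intended Transcript ids excluded from off-target failure.
#' @param cutoff Specificity cutoff for the re-screen.
#' @param config A [tasitune_config()] list.
#' @return An object of class `tasitune_variant_series`: the parent, the
#'   site, a tibble `variants` (`k`, `name`, `guide`, `three_prime_run`,
#'   `offtarget_pass`) and the per-variant screen reports (if screened).
#' @export
make_mismatch_series <- function(parent, site, k_max = NULL, transcriptome = NULL,
                                 intended = character(), cutoff = NULL,
                                 config = tasitune_config()) {
  g <- as_guide(parent)
  s <- if (inherits(site, "tasitune_target_site")) site else
    target_site("site", 0L, site)
  k_max <- k_max %||% config$series$k_max
  L <- nchar(g$sequence)
  if (k_max < 1L || k_max > L - 1L) {
    abort(sprintf("k_max must be in 1..%d (got %s)", L - 1L, k_max),
          class = "tasitune_input_error")
  }
  if (nchar(s$sequence) != L) {
    abort("site and guide lengths differ", class = "tasitune_length_error")
  }
  opposite <- rev(seq_chars(s$sequence))    # base facing each guide position

  variants <- purrr::map(seq_len(k_max), function(k) {
    ch <- seq_chars(g$sequence)
    tail_pos <- (L - k + 1L):L
    ch[tail_pos] <- opposite[tail_pos]
    vseq <- paste(ch, collapse = "")
    tibble(k = k, name = sprintf("%s-%dM", g$name, k), guide = vseq,
           three_prime_run = pairing_profile(vseq, s)$three_prime_run)
  })
  variants <- dplyr::bind_rows(variants)

  reports <- NULL
  if (!is.null(transcriptome)) {
    reports <- purrr::map(variants$guide, function(v)
      scan_transcriptome(v, transcriptome, cutoff = cutoff, intended = intended,
                         config = config))
    names(reports) <- variants$name
    variants$offtarget_pass <- purrr::map_lgl(reports, "pass")
  } else {
    variants$offtarget_pass <- NA
  }
  structure(list(parent = g, site = s, variants = variants, reports = reports),
            class = "tasitune_variant_series")
}

#' @export
print.tasitune_variant_series <- function(x, ...) {
  cat(sprintf("<variant series> parent %s, %d 3'-end mismatch variants\n",
              x$parent$name, nrow(x$variants)))
  print(x$variants, ...)
  invisible(x)
}

#' Write guides to FASTA
#'
#' @param x A `tasitune_guide_candidates` tibble, a
#'   `tasitune_variant_series`, or a named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_guides_fasta <- function(x, path) {
  seqs <- if (inherits(x, "tasitune_variant_series")) {
    stats::setNames(c(x$parent$sequence, x$variants$guide),
                    c(x$parent$name, x$variants$name))
  } else if (is.data.frame(x)) {
    stats::setNames(x$guide, x$name)
  } else {
    x
  }
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
  invisible(path)
}
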