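#' Construct a guide small RNA
#'
#' A guide is a 21-nt small RNA held in the RNA alphabet (T on input is
#' normalized to U). Position 1 is the guide 5' end; 3'-end mutations sit at
#' positions 21, 20, ... counting backwards.
#'
#' @param sequence Nucleotide string; T is accepted and converted to U.
#' @param name Label for the guide.
#' @param origin One of `"designed"`, `"variant"`, `"user"`.
#' @param parent For variants, the label of the unmutated parent guide.
#' @param length Expected length (default 21).
#' @return An object of class `tasitune_guide`.
#' @export
guide <- function(sequence, name = "guide", origin = c("user", "designed", "variant"),
                  parent = NULL, length = 21L) {
  origin <- match.arg(origin)
  sequence <- as_rna(sequence)
  if (nchar(sequence) != length) {
    abort(sprintf("guide '%s' is %d nt; expected %d", name, nchar(sequence), length),
          class = "tasitune_length_error")
  }
  structure(list(sequence = sequence, name = name, origin = origin, parent = parent),
            class = "tasitune_guide")
}

as_guide <- function(x, ...) {
  if (inherits(x, "tasitune_guide")) x else guide(x, ...)
}

#' @export
print.tasitune_guide <- function(x, ...) {
  cat(sprintf("<guide> %s (%s%s): 5'-%s-3'\n", x$name, x$origin,
              if (is.null(x$parent)) "" else paste0(" of ", x$parent), x$sequence))
  invisible(x)
}

#' Construct a target site
#'
#' A 21-nt window on the sense strand of a transcript, in 0-based half-open
#' coordinates. The stored sequence is the transcript substring at
#' `[start, end)`, held as RNA.
#'
#' @param transcript_id Transcript label.
#' @param start 0-based start of the site on the transcript.
#' @param sequence The site sequence (sense strand); T normalized to U.
#' @return An object of class `tasitune_target_site`.
#' @export
target_site <- function(transcript_id, start, sequence) {
  sequence <- as_rna(sequence)
  structure(
    list(transcript_id = transcript_id, start = as.integer(start),
         end = as.integer(start) + nchar(sequence), sequence = sequence),
    class = "tasitune_target_site"
  )
}

## Per-position pair classification. Guide position i faces site position
## L - i + 1 (antiparallel: guide 5' end opposite site 3' end).
pair_class <- function(guide_base, site_base) {
  wc <- (guide_base == "A" & site_base == "U") |
        (guide_base == "U" & site_base == "A") |
        (guide_base == "G" & site_base == "C") |
        (guide_base == "C" & site_base == "G")
  wob <- (guide_base == "G" & site_base == "U") |
         (guide_base == "U" & site_base == "G")
  ifelse(wc, "WC", ifelse(wob, "wobble", "mismatch"))
}

#' Per-position pairing profile of a guide against a target site
#'
#' Classifies every guide position as Watson-Crick (`WC`), G:U `wobble`
#' (guide G opposite site U, or guide U opposite site G) or `mismatch`,
#' under the antiparallel convention that guide position i faces site
#' position L - i + 1. Also reports the number of mismatches and wobbles and
#' `three_prime_run`, the length of the maximal run of consecutive
#' mismatches ending at the guide 3' end (position 21) — the quantity that
#' drives the 3'-mismatch sensitivity tiers.
#'
#' @param guide A [guide()] or nucleotide string.
#' @param site A [target_site()] or nucleotide string of equal length.
#' @return An object of class `tasitune_pairing_profile` with a per-position
#'   tibble (`position`, `guide_base`, `site_base`, `label`) and counts.
#' @examples
#' g <- "UUCGGACGUAUCGUAGCAUCC"
#' pairing_profile(g, reverse_complement(g))  # all WC
#' @export
pairing_profile <- function(guide, site) {
  g <- as_guide(guide)
  s <- if (inherits(site, "tasitune_target_site")) site else
    target_site("site", 0L, site)
  if (nchar(g$sequence) != nchar(s$sequence)) {
    abort(sprintf("guide (%d nt) and site (%d nt) differ in length",
                  nchar(g$sequence), nchar(s$sequence)),
          class = "tasitune_length_error")
  }
  L <- nchar(g$sequence)
  gc <- seq_chars(g$sequence)
  sc <- seq_chars(s$sequence)
  opposite <- rev(sc)                      # opposite[i] faces guide position i
  labels <- pair_class(gc, opposite)
  mism <- labels == "mismatch"
  run <- 0L
  for (i in L:1) {
    if (!mism[i]) break
    run <- run + 1L
  }
  structure(
    list(
      guide_name = g$name, site_id = s$transcript_id,
      pairs = tibble(position = seq_len(L), guide_base = gc,
                     site_base = opposite, label = labels),
      n_mismatch = sum(mism), n_wobble = sum(labels == "wobble"),
      three_prime_run = run
    ),
    class = "tasitune_pairing_profile"
  )
}

#' @export
print.tasitune_pairing_profile <- function(x, ...) {
  sym <- c(WC = "|", wobble = "o", mismatch = "x")
  cat(sprintf("<pairing profile> %s vs %s\n", x$guide_name, x$site_id))
  cat(sprintf("  guide 5'-%s-3'\n", paste(x$pairs$guide_base, collapse = "")))
  cat(sprintf("           %s\n", paste(sym[x$pairs$label], collapse = "")))
  cat(sprintf("  site  3'-%s-5'\n", paste(x$pairs$site_base, collapse = "")))
  cat(sprintf("  mismatches: %d  wobbles: %d  3'-terminal mismatch run: %d\n",
              x$n_mismatch, x$n_wobble, x$three_prime_run))
  invisible(x)
}

profile_string <- function(profile) {
  paste(c(WC = "|", wobble = "o", mismatch = "x")[profile$pairs$label],
        collapse = "")
}

#' Write a plain-text pairing profile report
#'
#' One line per guide position: index, guide base, opposing site base and
#' the pair label.
#'
#' @param profile A [pairing_profile()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_report <- function(profile, path) {
  stopifnot(inherits(profile, "tasitune_pairing_profile"))
  header <- sprintf("# %s vs %s; mismatches=%d wobbles=%d three_prime_run=%d",
                    profile$guide_name, profile$site_id, profile$n_mismatch,
                    profile$n_wobble, profile$three_prime_run)
  lines <- sprintf("%2d\t%s\t%s\t%s", profile$pairs$position,
                   profile$pairs$guide_base, profile$pairs$site_base,
                   profile$pairs$label)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Classify silencing sensitivity from a pairing profile
#'
#' Two deterministic rule sets map mismatch counts to an ordinal tier:
#' \describe{
#'   \item{`syntasi_3prime` (default)}{Driven by the run of consecutive
#'     mismatches at the guide 3' end: 0-1 tolerated (`unaffected`),
#'     2-3 `diminished`, 4 or more `abolished`.}
#'   \item{`site_5prime`}{The classical target-site rule, counting
#'     mismatches at the target-site 5' end (the same region, seen from the
#'     site): 0-3 `unaffected`, 4-5 `diminished`, 6 or more `abolished`.}
#' }
#' The classification is monotone: more 3'-terminal mismatches never move
#' the tier toward `unaffected`.
#'
#' @param profile A [pairing_profile()], or an integer run length.
#' @param rule_set `"syntasi_3prime"` or `"site_5prime"`.
#' @return An object of class `tasitune_sensitivity_tier` with fields
#'   `label`, `rule_set` and `run`.
#' @export
classify_sensitivity <- function(profile, rule_set = c("syntasi_3prime", "site_5prime")) {
  rule_set <- match.arg(rule_set)
  run <- if (inherits(profile, "tasitune_pairing_profile")) {
    if (profile$three_prime_run > nrow(profile$pairs)) {
      abort("three_prime_run exceeds guide length", class = "tasitune_invariant_error")
    }
    profile$three_prime_run
  } else {
    as.integer(profile)
  }
  if (run < 0L) abort("mismatch run must be >= 0", class = "tasitune_input_error")
  label <- if (rule_set == "syntasi_3prime") {
    if (run <= 1L) "unaffected" else if (run <= 3L) "diminished" else "abolished"
  } else {
    if (run <= 3L) "unaffected" else if (run <= 5L) "diminished" else "abolished"
  }
  structure(list(label = label, rule_set = rule_set, run = run),
            class = "tasitune_sensitivity_tier")
}

#' @export
print.tasitune_sensitivity_tier <- function(x, ...) {
  cat(sprintf("<sensitivity> %s (%s rule, 3'-mismatch run %d)\n",
              x$label, x$rule_set, x$run))
  invisible(x)
}
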