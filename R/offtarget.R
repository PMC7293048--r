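## Penalty lookup matrix: rows = guide positions 1..L, columns = opposing
## transcript base (RNA) A,C,G,U plus "other" (ambiguity codes score as
## mismatch). Seed positions carry doubled penalties.
penalty_matrix <- function(guide_rna, scheme) {
  gc <- seq_chars(guide_rna)
  L <- length(gc)
  site_bases <- c(RNA_BASES, "N")
  P <- matrix(0, nrow = L, ncol = length(site_bases),
              dimnames = list(NULL, site_bases))
  for (j in seq_along(site_bases)) {
    cls <- if (site_bases[j] == "N") rep("mismatch", L) else
      pair_class(gc, rep(site_bases[j], L))
    P[, j] <- c(WC = 0, wobble = scheme$wobble, mismatch = scheme$mismatch)[cls]
  }
  seed <- seq_len(L) >= scheme$seed_start & seq_len(L) <= scheme$seed_end
  P[seed, ] <- P[seed, ] * scheme$seed_multiplier
  P
}

scheme_from_config <- function(config) {
  c(config$offtarget[c("mismatch", "wobble", "bulge", "seed_multiplier", "bulges")],
    config$pairing[c("seed_start", "seed_end")])
}

#' Score a guide against a single target site
#'
#' TargetFinder-style additive penalty: 1 per mismatch, 0.5 per G:U wobble,
#' every penalty doubled at guide seed positions 2-13. 0 means a perfect
#' site. Scanning is gapless; the bulge penalty constant is reserved.
#'
#' @param guide A [guide()] or nucleotide string.
#' @param site A [target_site()] or nucleotide string of equal length.
#' @param config A [tasitune_config()] list.
#' @return A non-negative numeric score.
#' @examples
#' g <- "UUCGGACGUAUCGUAGCAUCC"
#' score_site(g, reverse_complement(g))  # 0
#' @export
score_site <- function(guide, site, config = tasitune_config()) {
  scheme <- scheme_from_config(config)
  if (isTRUE(scheme$bulges)) {
    abort("single-base bulge scoring is not implemented; use gapless mode",
          class = "tasitune_input_error")
  }
  p <- pairing_profile(guide, site)
  seed <- p$pairs$position >= scheme$seed_start & p$pairs$position <= scheme$seed_end
  pen <- c(WC = 0, wobble = scheme$wobble, mismatch = scheme$mismatch)[p$pairs$label]
  sum(pen * ifelse(seed, scheme$seed_multiplier, 1))
}

## Vectorized scores of every guide-length window on the sense strand of one
## transcript (DNA or RNA input). Window w (1-based start t on transcript)
## places site position j opposite guide position L - j + 1.
score_windows <- function(guide_rna, transcript_seq, scheme) {
  L <- nchar(guide_rna)
  tr <- chartr("T", "U", toupper(transcript_seq))
  S <- seq_chars(tr)
  W <- length(S) - L + 1L
  if (W < 1L) return(numeric(0))
  P <- penalty_matrix(guide_rna, scheme)
  bi <- match(S, RNA_BASES)
  bi[is.na(bi)] <- 5L                       # ambiguity -> mismatch column
  idx <- outer(seq_len(W), 0:(L - 1L), "+") # site position t+j-1 for j=1..L
  gpos <- rep(L:1, each = W)                # guide position facing column j
  pen <- P[cbind(gpos, as.vector(bi[idx]))]
  rowSums(matrix(pen, nrow = W, ncol = L))
}

#' Scan a transcriptome for predicted target sites of a guide
#'
#' Scores every guide-length window on the sense strand of every transcript
#' (optionally also the antisense strand) with [score_site()]'s penalty
#' scheme, and reports all sites at or below `report_threshold`. The report
#' passes the specificity filter iff no site on an *unintended* transcript
#' scores at or below `cutoff`.
#'
#' @param guide A [guide()] or nucleotide string.
#' @param transcriptome A multi-FASTA path, `DNAStringSet`, or named
#'   character vector of transcript sequences.
#' @param cutoff Specificity cutoff (default from config: 4).
#' @param intended Character vector of transcript ids the guide is meant to
#'   target; hits on these never fail the filter.
#' @param report_threshold Retain hits with score <= this (default: cutoff).
#' @param antisense Also scan the antisense strand (off by default: small
#'   RNAs target mRNA).
#' @param config A [tasitune_config()] list.
#' @return An object of class `tasitune_offtarget_report`: hit tibble
#'   (`transcript_id`, `start`, `end` 0-based half-open, `strand`, `score`,
#'   `profile`, `intended`) sorted by ascending score, plus `pass` and the
#'   minimum unintended score observed anywhere (`min_unintended_score`).
#' @export
scan_transcriptome <- function(guide, transcriptome, cutoff = NULL,
                               intended = character(), report_threshold = NULL,
                               antisense = FALSE, config = tasitune_config()) {
  g <- as_guide(guide)
  seqs <- load_sequences(transcriptome)
  scheme <- scheme_from_config(config)
  cutoff <- cutoff %||% config$offtarget$cutoff
  report_threshold <- report_threshold %||% cutoff
  if (cutoff < 0) abort("cutoff must be >= 0", class = "tasitune_input_error")
  L <- nchar(g$sequence)

  hit_rows <- list()
  min_unintended <- Inf
  for (id in sort(names(seqs))) {
    strands <- if (antisense) c("+", "-") else "+"
    for (strand in strands) {
      seq_i <- if (strand == "+") seqs[[id]] else
        reverse_complement(as_dna(seqs[[id]]), "DNA")
      sc <- score_windows(g$sequence, seq_i, scheme)
      if (!length(sc)) next
      if (!(id %in% intended)) min_unintended <- min(min_unintended, min(sc))
      keep <- which(sc <= report_threshold)
      if (length(keep)) {
        seq_u <- chartr("T", "U", toupper(seq_i))   # ambiguity codes kept
        hit_rows[[length(hit_rows) + 1L]] <- tibble(
          transcript_id = id, start = keep - 1L, end = keep - 1L + L,
          strand = strand, score = sc[keep],
          site = vapply(keep, function(t)
            substr(seq_u, t, t + L - 1L), character(1))
        )
      }
    }
  }
  hits <- if (length(hit_rows)) dplyr::bind_rows(hit_rows) else
    tibble(transcript_id = character(), start = integer(), end = integer(),
           strand = character(), score = numeric(), site = character())
  gc_chars <- seq_chars(g$sequence)
  hits$profile <- vapply(hits$site, function(s) {
    labels <- pair_class(gc_chars, rev(seq_chars(s)))  # N etc. -> mismatch
    paste(c(WC = "|", wobble = "o", mismatch = "x")[labels], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  hits$intended <- hits$transcript_id %in% intended
  hits <- dplyr::arrange(hits, score, transcript_id, start)
  hits <- dplyr::select(hits, "transcript_id", "start", "end", "strand",
                        "score", "profile", "intended")
  pass <- !any(hits$score <= cutoff & !hits$intended)
  structure(
    list(guide = g, intended = intended, hits = hits, cutoff = cutoff,
         report_threshold = report_threshold, pass = pass,
         min_unintended_score = min_unintended),
    class = "tasitune_offtarget_report"
  )
}

#' @export
print.tasitune_offtarget_report <- function(x, ...) {
  cat(sprintf("<off-target report> guide %s: %d hit(s) at score <= %g; %s (cutoff %g)\n",
              x$guide$name, nrow(x$hits), x$report_threshold,
              if (x$pass) "PASS" else "FAIL", x$cutoff))
  if (nrow(x$hits)) print(x$hits, ...)
  invisible(x)
}

#' Write an off-target hit table
#'
#' Tab-separated: guide, transcript, start, end, strand, score, profile,
#' intended; one header line.
#'
#' @param report A [scan_transcriptome()] report.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_offtarget_tsv <- function(report, path) {
  stopifnot(inherits(report, "tasitune_offtarget_report"))
  tab <- dplyr::mutate(report$hits, guide = report$guide$name, .before = 1)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
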