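# Independent brute-force oracles. These deliberately re-derive everything
# position by position with plain loops, sharing no code path with the
# package internals they check.

oracle_pair_class <- function(g, s) {
  wc <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"))
  if (any(vapply(wc, function(p) p[1] == g && p[2] == s, logical(1)))) return("WC")
  if ((g == "G" && s == "U") || (g == "U" && s == "G")) return("wobble")
  "mismatch"
}

oracle_profile <- function(guide, site) {
  g <- strsplit(guide, "")[[1]]
  s <- strsplit(site, "")[[1]]
  L <- length(g)
  labels <- character(L)
  for (i in seq_len(L)) labels[i] <- oracle_pair_class(g[i], s[L - i + 1])
  run <- 0
  i <- L
  while (i >= 1 && labels[i] == "mismatch") {
    run <- run + 1
    i <- i - 1
  }
  list(labels = labels, n_mismatch = sum(labels == "mismatch"),
       n_wobble = sum(labels == "wobble"), three_prime_run = run)
}

oracle_score <- function(guide, site, mismatch = 1, wobble = 0.5,
                         seed_start = 2, seed_end = 13, seed_mult = 2) {
  prof <- oracle_profile(guide, site)
  total <- 0
  for (i in seq_along(prof$labels)) {
    pen <- switch(prof$labels[i], WC = 0, wobble = wobble, mismatch = mismatch)
    if (i >= seed_start && i <= seed_end) pen <- pen * seed_mult
    total <- total + pen
  }
  total
}

# Exhaustive gapless window scan over a named character vector of DNA
# transcripts; returns every window with score <= threshold.
oracle_scan <- function(guide, transcripts, threshold) {
  rows <- list()
  for (id in names(transcripts)) {
    tr <- chartr("T", "U", toupper(transcripts[[id]]))
    L <- nchar(guide)
    if (nchar(tr) < L) next
    for (t in 1:(nchar(tr) - L + 1)) {
      sc <- oracle_score(guide, substr(tr, t, t + L - 1))
      if (sc <= threshold) {
        rows[[length(rows) + 1]] <- data.frame(
          transcript_id = id, start = t - 1L, end = t - 1L + L, score = sc)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), start = integer(),
               end = integer(), score = numeric())
  out[order(out$score, out$transcript_id, out$start), , drop = FALSE]
}

oracle_bsai <- function(seq) {
  hits <- list()
  n <- nchar(seq)
  for (i in seq_len(max(0, n - 5))) {
    w <- substr(seq, i, i + 5)
    if (w == "GGTCTC") hits[[length(hits) + 1]] <- data.frame(start = i - 1L, strand = "+")
    if (w == "GAGACC") hits[[length(hits) + 1]] <- data.frame(start = i - 1L, strand = "-")
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(), strand = character())
  out[order(out$start), , drop = FALSE]
}

# Independent annealing check: the largest 3' overlap of the top oligo with
# the reverse complement of the bottom oligo defines the duplex; whatever
# protrudes at each 5' end is its overhang.
oracle_anneal <- function(top, bottom) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[strsplit(bottom, "")[[1]]]), collapse = "")
  best <- 0
  for (ov in seq_len(min(nchar(top), nchar(rc)))) {
    if (substr(top, nchar(top) - ov + 1, nchar(top)) == substr(rc, 1, ov)) best <- ov
  }
  list(core = substr(rc, 1, best),
       top_overhang = substr(top, 1, nchar(top) - best),
       bottom_overhang = substr(bottom, 1, nchar(bottom) - best))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# A fixed guide satisfying every design heuristic (5' U, pos 19 C, 8/21 GC
# within 30-60%, no homopolymer >= 5, no BsaI in guide or complement).
good_guide <- function() "UAUGGACGUAUCAUAGCACCC"

# Build a transcript whose only heuristic-compliant window is an implanted
# site: the rest of the transcript is pure G/C, so every window fully or
# partly inside the body fails the 30-60% GC rule or the 5'-U rule.
gc_rich_transcript_with_site <- function(seed, len = 500, offset = 0) {
  withr::with_seed(seed, {
    body <- paste(sample(c("G", "C"), len, replace = TRUE), collapse = "")
  })
  site <- reverse_complement(chartr("U", "T", good_guide()), "DNA")
  paste0(substr(body, 1, offset), site, substr(body, offset + 22, len))
}
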