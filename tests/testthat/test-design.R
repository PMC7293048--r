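test_that("a fixture transcript with one compliant window yields it as rank 1", {
  tr <- c(TGT = gc_rich_transcript_with_site(401))
  tx <- c(tr, as.character(make_transcriptome(402, n_transcripts = 6,
                                              length_range = c(150, 250))))
  cand <- design_guides(tr, tx, n = 3)
  expect_gte(nrow(cand), 1)
  expect_equal(cand$guide[1], good_guide())
  expect_equal(cand$start[1], 0L)
  expect_equal(cand$rank[1], 1L)
  expect_true(all(nchar(cand$guide) == 21))
})

test_that("n larger than the number of passing candidates truncates gracefully", {
  tr <- c(TGT = gc_rich_transcript_with_site(403))
  tx <- c(tr, as.character(make_transcriptome(404, n_transcripts = 4,
                                              length_range = c(150, 200))))
  few <- design_guides(tr, tx, n = 2)
  many <- design_guides(tr, tx, n = 500)
  expect_lte(nrow(many), 500)
  expect_gte(nrow(many), nrow(few))
  expect_equal(few$guide, many$guide[seq_len(nrow(few))])
})

test_that("designed guides are perfect reverse complements of their sites", {
  tr <- c(TGT = gc_rich_transcript_with_site(405))
  tx <- c(tr, as.character(make_transcriptome(406, n_transcripts = 4,
                                              length_range = c(150, 200))))
  cand <- design_guides(tr, tx, n = 5)
  for (i in seq_len(nrow(cand))) {
    p <- pairing_profile(cand$guide[i], cand$site[i])
    expect_equal(p$n_mismatch, 0)
    expect_equal(p$n_wobble, 0)
  }
})

test_that("candidate ranking equals an exhaustive per-window oracle", {
  withr::with_seed(407, {
    tr_seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                    collapse = "")
  })
  tr <- c(TGT = tr_seq)
  tx <- c(tr, as.character(make_transcriptome(408, n_transcripts = 6,
                                              length_range = c(150, 250))))
  cfg <- tasitune_config()
  # oracle: evaluate every window independently with loops and the
  # brute-force scanner, apply the same retention rules, and rank by
  # (violations, -margin, start)
  L <- 21
  rows <- list()
  for (t in 1:(nchar(tr_seq) - L + 1)) {
    site <- chartr("T", "U", substr(tr_seq, t, t + L - 1))
    g <- reverse_complement(site, "RNA")
    gch <- strsplit(g, "")[[1]]
    gc <- mean(gch %in% c("G", "C"))
    viol <- c(gch[1] != "U", gch[19] != "C", gc < 0.30 || gc > 0.60,
              max(rle(gch)$lengths) > 4,
              nrow(oracle_bsai(chartr("U", "T", g))) > 0)
    if (any(viol)) next
    margins <- sapply(names(tx)[names(tx) != "TGT"], function(id) {
      sc <- oracle_scan(g, tx[id], threshold = Inf)
      min(sc$score)
    })
    if (min(margins) <= cfg$offtarget$cutoff) next
    rows[[length(rows) + 1]] <- data.frame(start = t - 1L, guide = g,
                                           margin = min(margins))
  }
  want <- do.call(rbind, rows)
  want <- want[order(-want$margin, want$start), , drop = FALSE]

  got <- design_guides(tr, tx, n = nrow(want) + 5)
  expect_equal(got$guide, want$guide)
  expect_equal(got$start, want$start)
  expect_equal(got$offtarget_margin, want$margin)
})

test_that("design errors: short transcript, bad n, and the empty-result warning", {
  tx <- as.character(make_transcriptome(409, n_transcripts = 3,
                                        length_range = c(100, 150)))
  expect_error(design_guides(c(s = "ACGTACGT"), tx), class = "tasitune_input_error")
  expect_error(design_guides(tx[1], tx, n = 0), class = "tasitune_input_error")
  # a poly-G transcript offers no compliant window: empty result + warning
  expect_warning(out <- design_guides(c(g = strrep("G", 120)), tx),
                 "no candidate")
  expect_equal(nrow(out), 0)
})

test_that("the mismatch variant series has the declared geometry", {
  g <- good_guide()
  site <- reverse_complement(g)
  ser <- make_mismatch_series(guide(g, "syn-tasiR-X"), site)
  v <- tidy(ser)
  expect_equal(nrow(v), 5)
  expect_equal(v$name, sprintf("syn-tasiR-X-%dM", 1:5))

  for (k in 1:5) {
    # variant k: 3'-terminal mismatch run of exactly k under the oracle
    expect_equal(oracle_profile(v$guide[k], site)$three_prime_run, k)
    expect_equal(v$three_prime_run[k], k)
    # differs from the parent at exactly the k 3'-terminal positions
    diffs <- which(strsplit(v$guide[k], "")[[1]] != strsplit(g, "")[[1]])
    expect_equal(diffs, (21 - k + 1):21)
  }
  # variants k and k+1 agree everywhere except position 21-k
  for (k in 1:4) {
    d <- which(strsplit(v$guide[k], "")[[1]] != strsplit(v$guide[k + 1], "")[[1]])
    expect_equal(d, 21 - k)
  }
})

test_that("variant re-screening is deterministic and never drops variants", {
  g <- good_guide()
  site <- reverse_complement(g)
  tx <- make_transcriptome(410, n_transcripts = 8, length_range = c(150, 250),
                           implant = list(guide = g, transcript = 2, offset = 40))
  a <- make_mismatch_series(g, site, transcriptome = tx, intended = "tx02")
  b <- make_mismatch_series(g, site, transcriptome = tx, intended = "tx02")
  expect_identical(tidy(a), tidy(b))
  expect_equal(nrow(tidy(a)), 5)
  expect_type(tidy(a)$offtarget_pass, "logical")
})

test_that("variant preconditions: k_max bounds", {
  g <- good_guide()
  site <- reverse_complement(g)
  expect_error(make_mismatch_series(g, site, k_max = 0),
               class = "tasitune_input_error")
  expect_error(make_mismatch_series(g, site, k_max = 21),
               class = "tasitune_input_error")
})

test_that("guides and variant series write valid FASTA", {
  g <- good_guide()
  ser <- make_mismatch_series(guide(g, "parent"), reverse_complement(g))
  path <- withr::local_tempfile(fileext = ".fa")
  write_guides_fasta(ser, path)
  back <- Biostrings::readRNAStringSet(path)
  expect_length(back, 6)
  expect_equal(as.character(back[[1]]), g)
})
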