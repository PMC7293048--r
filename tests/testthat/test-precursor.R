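backbone <- make_backbone_fixture(501)
g_d2 <- guide("UACGAUCGAUAGCAUGCAUCC", "gA")
g_d3 <- guide("UGCAUUGCAUGGAUCGAAUCC", "gB")

test_that("a single guide at D2 lands exactly one slot downstream of the cleavage site", {
  con <- assemble_precursor(backbone, list(`2` = g_d2$sequence), quiet = TRUE)
  cleav <- backbone$cleavage_offset
  dna <- chartr("U", "T", g_d2$sequence)
  # slot formula: [cleav + 21*(k-1), cleav + 21*k)
  expect_equal(substr(con$assembled_sequence, cleav + 21 + 1, cleav + 42), dna)
  # cross-check by substring search: the guide occurs exactly once, there
  expect_equal(gregexpr(dna, con$assembled_sequence, fixed = TRUE)[[1]][1],
               cleav + 21 + 1)
})

test_that("position 1 is rejected: slot D1 belongs to the miR173 target site", {
  expect_error(assemble_precursor(backbone, list(`1` = g_d2$sequence)),
               class = "tasitune_forbidden_slot_error")
})

test_that("dual guides at D2 and D3 occupy adjacent 21-nt slots with no gap", {
  con <- assemble_precursor(backbone,
                            list(`2` = g_d2$sequence, `3` = g_d3$sequence),
                            quiet = TRUE)
  expect_equal(con$core,
               paste0(chartr("U", "T", g_d2$sequence), chartr("U", "T", g_d3$sequence)))
  ph <- simulate_phasing(con)
  expect_equal(ph$sequence[2], g_d2$sequence)
  expect_equal(ph$sequence[3], g_d3$sequence)
})

test_that("assembly input errors: duplicates, bad positions, BsaI guides", {
  expect_error(assemble_precursor(backbone, data.frame(position = c(2, 2),
                                                       guide = c(g_d2$sequence, g_d3$sequence))),
               class = "tasitune_conflict_error")
  expect_error(assemble_precursor(backbone, list(`6` = g_d2$sequence)),
               class = "tasitune_input_error")
  bsai_guide <- "TAGGTCTCATGCATGCATGCA"   # contains GGTCTC
  expect_error(assemble_precursor(backbone, list(`2` = bsai_guide)),
               class = "tasitune_cloning_error")
})

test_that("phased 21-mers tile the precursor and start with the miR173 site 3' half", {
  con <- assemble_precursor(backbone, list(`2` = g_d2$sequence), quiet = TRUE)
  ph <- simulate_phasing(con)
  # tiling: no overlap, no gap
  expect_equal(ph$start, con$cleavage_offset + 21 * (ph$k - 1))
  expect_equal(ph$end - ph$start, rep(21L, nrow(ph)))
  # slot D1 prefix = retained 11-nt 3' half of the miR173 target site
  site <- substr(backbone$sequence, backbone$mir173_site["start"] + 1,
                 backbone$mir173_site["end"])
  expect_equal(substr(ph$sequence[1], 1, 11),
               chartr("T", "U", substr(site, 11, 21)))
  expect_equal(ph$sequence[2], g_d2$sequence)
})

test_that("a 1-nt deletion upstream of slot D3 desynchronizes downstream slots only", {
  con <- assemble_precursor(backbone,
                            list(`2` = g_d2$sequence, `3` = g_d3$sequence),
                            quiet = TRUE)
  seq0 <- con$assembled_sequence
  cut <- con$cleavage_offset + 30   # inside slot D2, upstream of D3
  edited <- paste0(substr(seq0, 1, cut), substr(seq0, cut + 2, nchar(seq0)))
  ph0 <- simulate_phasing(seq0, cleavage_offset = con$cleavage_offset)
  ph1 <- simulate_phasing(edited, cleavage_offset = con$cleavage_offset)
  expect_equal(ph1$sequence[1], ph0$sequence[1])
  expect_false(ph1$sequence[2] == ph0$sequence[2]) # deletion falls inside D2
  expect_false(ph1$sequence[3] == ph0$sequence[3]) # D3+ shifted out of register
})

test_that("oligo geometry follows the insert-span rule", {
  con2 <- assemble_precursor(backbone, list(`2` = g_d2$sequence), quiet = TRUE)
  p2 <- design_oligos(con2)
  expect_equal(nchar(p2$top), 46)
  expect_equal(nchar(p2$bottom), 46)
  expect_equal(p2$duplex_core_len, 42)

  con5 <- assemble_precursor(backbone, list(`5` = g_d2$sequence), quiet = TRUE)
  p5 <- design_oligos(con5)
  expect_equal(p5$duplex_core_len, 84)   # 21 * 4
  expect_equal(nchar(p5$top), 88)
  expect_equal(nchar(p5$bottom), 88)

  # annealing (independent overlap-based routine) reconstitutes the core
  # with TTTA / CCGA 5' extensions
  for (pair in list(p2, p5)) {
    ann <- oracle_anneal(pair$top, pair$bottom)
    expect_equal(ann$top_overhang, "TTTA")
    expect_equal(ann$bottom_overhang, "CCGA")
    expect_equal(ann$core, substr(pair$top, 5, nchar(pair$top)))
  }
})

test_that("golden-gate assembly is directional, seamless and idempotent", {
  con <- assemble_precursor(backbone, list(`2` = g_d2$sequence), quiet = TRUE)
  pair <- design_oligos(con)
  product <- golden_gate_assemble(backbone$sequence, pair)
  expect_identical(product, con$assembled_sequence)
  # guide recovered at the D2 slot of the reconstituted precursor
  ph <- simulate_phasing(product, cleavage_offset = backbone$cleavage_offset)
  expect_equal(ph$sequence[2], g_d2$sequence)
  # seamless: no recognition site on either strand
  expect_equal(nrow(scan_bsai(product)), 0)
  expect_false(grepl("GGTCTC", product) || grepl("GAGACC", product))
  # re-digestion finds nothing (idempotent)
  expect_error(golden_gate_assemble(product, pair), class = "tasitune_vector_error")
  # swapped overhangs cannot ligate
  bad <- pair
  substr(bad$top, 1, 4) <- "CCGA"
  substr(bad$bottom, 1, 4) <- "TTTA"
  expect_error(golden_gate_assemble(backbone$sequence, bad),
               class = "tasitune_ligation_error")
})

test_that("BsaI scanning matches brute force on literals and 1000 random sequences", {
  expect_equal(scan_bsai("AAGGTCTCAA"),
               tibble::tibble(start = 2L, strand = "+"))
  expect_equal(scan_bsai("AAGAGACCAA"),
               tibble::tibble(start = 2L, strand = "-"))
  withr::with_seed(502, {
    for (i in 1:1000) {
      s <- paste(sample(c("A", "C", "G", "T", "G", "C"), 400, replace = TRUE),
                 collapse = "")
      got <- as.data.frame(scan_bsai(s))
      want <- oracle_bsai(s)
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
    }
  })
})

test_that("stuffer excision length follows the released-fragment convention", {
  small <- make_backbone_fixture(503, stuffer_len = 100)
  expect_equal(excised_stuffer_length(small$sequence), 100)
  expect_equal(excised_stuffer_length(backbone$sequence), 1461)
  # tandem (non-inverted) sites are not a valid cloning vector
  tandem <- paste0(strrep("A", 30), "GGTCTC", strrep("T", 50), "GGTCTC", strrep("A", 30))
  expect_error(excised_stuffer_length(tandem), class = "tasitune_vector_error")
  # inward-cutting inverted sites are rejected too
  inward <- paste0(strrep("A", 30), "GGTCTC", strrep("T", 50), "GAGACC", strrep("A", 30))
  expect_error(excised_stuffer_length(inward), class = "tasitune_vector_error")
})

test_that("round trip oligos -> assembly -> phasing recovers guides for all 15 position subsets", {
  guides <- list(`2` = g_d2$sequence, `3` = g_d3$sequence,
                 `4` = "UCGAAUGGCAUCAGAUCCAUC", `5` = "UAACGGAUUCGCAUCCAGAUC")
  subsets <- unlist(lapply(1:4, function(k) combn(names(guides), k, simplify = FALSE)),
                    recursive = FALSE)
  expect_length(subsets, 15)
  for (sub in subsets) {
    con <- assemble_precursor(backbone, guides[sub], quiet = TRUE)
    pair <- design_oligos(con)
    product <- golden_gate_assemble(backbone$sequence, pair)
    expect_identical(product, con$assembled_sequence)
    expect_equal(nrow(scan_bsai(product)), 0)
    ph <- simulate_phasing(product, cleavage_offset = backbone$cleavage_offset)
    for (pos in sub) {
      expect_equal(ph$sequence[as.integer(pos)], guides[[pos]])
    }
    # arithmetic identity: product length = vector - released stuffer
    # + core + the 4-nt overhang the insert restores to slot D1
    expect_equal(nchar(product),
                 nchar(backbone$sequence) - backbone$stuffer_length +
                   nchar(con$core) + 4)
  }
})

test_that("construct features and FASTA exports are well formed", {
  con <- assemble_precursor(backbone, list(`2` = g_d2$sequence), quiet = TRUE)
  fpath <- withr::local_tempfile(fileext = ".tsv")
  write_construct_features(con, fpath)
  feats <- utils::read.delim(fpath)
  expect_true(all(c("miR173_target_site", "cleavage_offset", "slot") %in% feats$feature))
  spath <- withr::local_tempfile(fileext = ".fa")
  write_sequence_fasta(con, spath)
  back <- Biostrings::readDNAStringSet(spath)
  expect_equal(as.character(back[[1]]), con$assembled_sequence)
})
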