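# The published sgGFP42 target region (20 nt protospacer + TGG PAM)
SITE42 <- "GCCGTCCAGCTCGACCAGGATGG"

test_that("find_pam_sites agrees with an exhaustive triplet scan", {
  hits <- find_pam_sites(SITE42, strands = "+")
  expect_true(any(hits$pos == 20L & hits$strand == "+"))
  expect_equal(hits, oracle_pam_scan(SITE42, "+"))

  expect_equal(nrow(find_pam_sites("AAAATTTT")), 0L)

  withr::with_seed(11, {
    for (k in 1:20) {
      s <- rand_dna(60)
      expect_equal(find_pam_sites(s), oracle_pam_scan(s), info = s)
    }
  })
})

test_that("find_pam_sites rejects bad characters and never matches N", {
  expect_error(find_pam_sites("ACGTX"), "outside")
  # N cannot stand in for any PAM position, including the degenerate one
  expect_equal(nrow(find_pam_sites("NGGAA", strands = "+")), 0L)
  expect_equal(nrow(find_pam_sites("ANGGA", strands = "+")), 0L)
  expect_equal(find_pam_sites("AGGAA", strands = "+")$pos, 0L)
})

test_that("design_guides reproduces the published 20 nt and 17 nt spacers", {
  g20 <- design_guides(SITE42, 20, policy = "require_matched_G", strands = "+")
  expect_equal(nrow(g20), 1L)
  expect_equal(g20$spacer, "GCCGTCCAGCTCGACCAGGA")
  expect_equal(g20$pam, "TGG")
  expect_equal(g20$start, 0L)
  expect_false(g20$five_prime_tagged)
  expect_true(g20$effective_flag)

  g17 <- design_guides(SITE42, 17, policy = "require_matched_G", strands = "+")
  expect_true("GTCCAGCTCGACCAGGA" %in% g17$spacer)
})

test_that("prepend_g tags non-G protospacers and the length rules set the flag", {
  # 17 nt protospacer starting with A, with its TGG PAM
  seq <- "ATCCAGCTCGACCAGGATGG"
  g <- design_guides(seq, 17, policy = "prepend_g", strands = "+")
  tagged <- g[g$five_prime_tagged, ]
  expect_equal(nrow(tagged), 1L)
  expect_equal(tagged$spacer, "gATCCAGCTCGACCAGGA")
  expect_equal(tagged$total_len, 18L)
  expect_equal(tagged$matched_len, 17L)
  expect_true(tagged$effective_flag)   # gN17 = 18 nt total is effective

  # same protospacer at matched length 16: tagged total 17 -> ineffective
  g16 <- design_guides(seq, 16, policy = "prepend_g", strands = "+")
  g16 <- g16[g16$start == 1L, ]
  expect_false(any(g16$effective_flag))

  # untagged 16-mers are ineffective too
  g16g <- design_guides(SITE42, 16, policy = "any", strands = "+")
  expect_false(any(g16g$effective_flag))
  # and untagged 17-mers are effective
  g17 <- design_guides(SITE42, 17, policy = "any", strands = "+")
  expect_true(all(g17$effective_flag))
})

test_that("require_matched_G only emits protospacers starting with G", {
  withr::with_seed(5, {
    for (k in 1:10) {
      s <- rand_dna(120)
      g <- design_guides(s, 18, policy = "require_matched_G")
      if (nrow(g)) expect_true(all(substr(g$spacer, 1, 1) == "G"))
    }
  })
})

test_that("design_guides validates its inputs", {
  expect_error(design_guides("", 17), "empty")
  expect_error(design_guides(SITE42, 15), "16")
  expect_error(design_guides(SITE42, 21), "20")
})

test_that("truncation reproduces all four published 17 nt spacers", {
  tab <- read_site_table()
  on <- tab[tab$is_on_target, ]
  expect_equal(nrow(on), 4L)
  for (i in seq_len(4L)) {
    g20 <- design_guides(paste0(on$spacer20[i], on$pam[i]), 20,
                         policy = "any", strands = "+")
    g20 <- g20[g20$spacer == on$spacer20[i], ]
    g17 <- truncate_guide(g20, 17)
    expect_equal(g17$spacer, on$spacer17[i], info = on$target_id[i])
    expect_equal(g17$pam, on$pam[i])
    expect_equal(g17$strand, g20$strand)
  }
})

test_that("truncation to a guide's own length is the identity", {
  g <- design_guides(SITE42, 20, policy = "any", strands = "+")
  expect_equal(truncate_guide(g, 20)$spacer, g$spacer)
})

test_that("truncation rejects invalid lengths and tagged guides", {
  g <- design_guides(SITE42, 17, policy = "any", strands = "+")[1, ]
  expect_error(truncate_guide(g, 18), "exceeds")
  expect_error(truncate_guide(g, 15), ">= 16")
  tagged <- design_guides("ATCCAGCTCGACCAGGATGG", 17,
                          policy = "prepend_g", strands = "+")
  tagged <- tagged[tagged$five_prime_tagged, ]
  expect_error(truncate_guide(tagged, 16), "tagged")
})

test_that("designing short equals designing long then truncating", {
  withr::with_seed(21, {
    for (k in 1:8) {
      s <- rand_dna(150)
      g20 <- design_guides(s, 20, policy = "any")
      g17 <- design_guides(s, 17, policy = "any")
      for (i in seq_len(nrow(g20))) {
        tr <- truncate_guide(g20[i, ], 17)
        match_row <- g17[g17$strand == tr$strand & g17$start == tr$start, ]
        expect_equal(nrow(match_row), 1L)
        expect_equal(match_row$spacer, tr$spacer)
      }
    }
  })
})

test_that("designing on the reverse complement mirrors strands and coordinates", {
  withr::with_seed(33, {
    for (k in 1:8) {
      s <- rand_dna(100)
      n <- nchar(s)
      fwd <- design_guides(s, 18, policy = "any")
      rev <- design_guides(revcomp(s), 18, policy = "any")
      expect_equal(sort(fwd$spacer), sort(rev$spacer))
      # a + guide at start x maps to a - guide at n - x - L
      key_fwd <- sort(paste(fwd$spacer, ifelse(fwd$strand == "+", "-", "+"),
                            n - fwd$start - fwd$matched_len))
      key_rev <- sort(paste(rev$spacer, rev$strand, rev$start))
      expect_equal(key_fwd, key_rev)
    }
  })
})

test_that("candidate count equals NGG sites with sufficient flank (brute force)", {
  withr::with_seed(99, {
    for (k in 1:6) {
      s <- rand_dna(200)
      L <- sample(16:20, 1)
      pams <- oracle_pam_scan(s)
      n_ok <- sum(ifelse(pams$strand == "+",
                         pams$pos >= L,
                         pams$pos + 3L + L <= nchar(s)))
      g <- design_guides(s, L, policy = "any")
      expect_equal(nrow(g), n_ok)
    }
  })
})

test_that("protospacer windows overlapping N are skipped with a warning", {
  seq <- paste0("ATCCAGCTCGNCCAGGATGG", "ACGTACGTACGTACGTACGTAGG")
  expect_warning(g <- design_guides(seq, 17, policy = "any", strands = "+"),
                 "skipped")
  expect_false(any(grepl("N", g$spacer)))
})

test_that("cloning oligos match the synthesis template and primers", {
  o <- build_cloning_oligos("GTCCAGCTCGACCAGGA")
  expect_equal(o$insert, "TCCAGCTCGACCAGGA")
  expect_equal(nchar(o$insert), 16L)
  expect_equal(nchar(o$template), 30L + 16L + 30L)
  expect_equal(o$template,
               paste0("TATATATCTTGTGGAAAGGACGAAACACCG", o$insert,
                      "GTTTTAGAGCTAGAAATAGCAAGTTAAAAT"))
  expect_equal(o$fwd_primer, "TATATATCTTGTGGAAAGGACGAA")
  expect_equal(o$rev_primer, "ATTTTAACTTGCTATTTCTAGCTCTAA")

  expect_equal(nchar(build_cloning_oligos("GCCGTCCAGCTCGACCAGGA")$insert), 19L)
  # a g-tagged spacer is accepted: the template's trailing G stands in
  expect_equal(build_cloning_oligos("gATCCAGCTCGACCAGGA")$insert,
               "ATCCAGCTCGACCAGGA")
  expect_error(build_cloning_oligos("ATCCAGCTCGACCAGGA"), "prepend_g")
})

test_that("guide TSV round-trips", {
  g <- design_guides(SITE42, 20, policy = "any")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_guides_tsv(g, path)
  expect_equal(read_guides_tsv(path), g)
})

test_that("cut site sits 3 bp 5' of the PAM on either strand", {
  g <- design_guides(SITE42, 20, policy = "any", strands = "+")
  expect_equal(guide_cut_site(g), 17L)   # between protospacer pos 17 and 18
  grev <- design_guides(revcomp(SITE42), 20, policy = "any", strands = "-")
  expect_equal(guide_cut_site(grev), 3L + 3L)
})
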