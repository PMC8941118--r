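test_that("cumulative_skew matches the GGGCCC worked example and hand cases", {
  expect_equal(cumulative_skew("GGGCCC"), c(1, 2, 3, 2, 1, 0))
  expect_equal(cumulative_skew("AAAA"), c(0, 0, 0, 0))
  expect_equal(cumulative_skew("GCTA", "T", "A"), c(0, 0, 1, 0))
  expect_equal(cumulative_skew("gggccc"), c(1, 2, 3, 2, 1, 0)) # case-blind
  # IUPAC ambiguity codes advance position but touch no counter
  expect_equal(cumulative_skew("GNNC"), c(1, 1, 1, 0))
  expect_error(cumulative_skew(""))
})

test_that("windowed_skew computes (G-C)/(G+C) per complete window", {
  expect_equal(windowed_skew("GGGCCC", 6), 0)
  expect_equal(windowed_skew("GGGG", 4), 1.0)
  expect_equal(windowed_skew("GCGCAT", 2), c(0, 0, 0))
  expect_equal(windowed_skew("GGGCCCG", 3), c(1, -1)) # trailing partial dropped
  expect_equal(windowed_skew("ATAT", 2), c(0, 0))     # G+C = 0 windows -> 0
  expect_error(windowed_skew("ACGT", 0), "window")
})

test_that("codon_position_of counts phase from the gene's own 5' end", {
  expect_equal(codon_position_of(0L, 1L, 6L), 0L)
  expect_equal(codon_position_of(4L, 1L, 6L), 1L)
  expect_equal(codon_position_of(5L, -1L, 6L), 0L)
  # full minus-strand layout of a 2-codon gene, offsets 0..5
  expect_equal(codon_position_of(0:5, -1L, 6L), c(2L, 1L, 0L, 2L, 1L, 0L))
  expect_equal(codon_position_of(0:5, 1L, 6L), c(0L, 1L, 2L, 0L, 1L, 2L))
  expect_error(codon_position_of(6L, 1L, 6L))
})

test_that("scan_chromosome handles degenerate whole-gene and gene-free toys", {
  allA <- make_record(strrep("A", 8192L))
  prof <- scan_chromosome(allA, interval = 4096L)
  expect_s3_class(prof, "scan_profile")
  expect_equal(prof$checkpoints$abspos, c(4096, 8192))
  expect_equal(prof$checkpoints$gcskew, c(0, 0))
  expect_equal(prof$checkpoints$taskew, c(-4096, -8192))
  expect_equal(tail(prof$checkpoints$ngcount, 1L), 8192)
  expect_equal(tail(prof$checkpoints$pospos, 1L), 0)

  # 8192 is not a codon multiple: codon accounting warns, strand bias still counts
  expect_warning(one_gene <- scan_chromosome(allA, gene_row("X", 0L, 8192L, 1L)),
                 "multiple of 3")
  expect_equal(tail(one_gene$checkpoints$pospos, 1L), 8192)
  expect_equal(tail(one_gene$checkpoints$ngcount, 1L), 0)

  minus_mid <- scan_chromosome(make_record(strrep("A", 12288L)),
                               gene_row("X", 3072L, 9216L, -1L))
  expect_equal(tail(minus_mid$checkpoints$pospos, 1L), -6144)
  expect_error(scan_chromosome(allA, gene_row("X", 0L, 9000L, 1L)), "bounds")
})

test_that("scan_chromosome agrees with the per-position recount oracle", {
  for (seed in 1:4) {
    toy <- random_toy_genome(len = 5000L + 997L * seed, n_genes = 5L,
                             seed = seed)
    got <- scan_chromosome(toy$record, toy$genes, interval = 512L)$checkpoints
    want <- brute_scan(toy$record, toy$genes, interval = 512L)
    for (col in names(want)) {
      expect_equal(as.numeric(got[[col]]), as.numeric(want[[col]]),
                   info = paste("seed", seed, "col", col))
    }
  }
})

test_that("scan invariants: conservation, partition, antisymmetry, intervals", {
  for (seed in 5:8) {
    toy <- random_toy_genome(len = 4096L + 1111L * seed, n_genes = 3L,
                             seed = seed)
    cp <- scan_chromosome(toy$record, toy$genes, interval = 1024L)$checkpoints
    n <- nrow(cp)
    # conservation: final skews equal total base-count differences
    expect_equal(cp$gcskew[n], cp$gcount[n] - cp$ccount[n])
    expect_equal(cp$taskew[n], cp$tcount[n] - cp$acount[n])
    # partition at every checkpoint
    expect_equal(cp$gcskew0 + cp$gcskew1 + cp$gcskew2 + cp$gcskewNG, cp$gcskew)
    expect_equal(cp$taskew0 + cp$taskew1 + cp$taskew2 + cp$taskewNG, cp$taskew)
    # interval independence of the final checkpoint
    cp1 <- scan_chromosome(toy$record, toy$genes, interval = 1L)$checkpoints
    expect_equal(as.numeric(cp1[nrow(cp1), ]), as.numeric(cp[n, ]))
    # reverse-complement antisymmetry (gene-free)
    rc <- make_record(chartr("ACGT", "TGCA",
                             paste(rev(strsplit(toy$record$residues,
                                                NULL)[[1]]), collapse = "")))
    cp_rc <- scan_chromosome(rc, interval = 1024L)$checkpoints
    expect_equal(tail(cp_rc$gcskew, 1L), -cp$gcskew[n])
    expect_equal(tail(cp_rc$taskew, 1L), -cp$taskew[n])
  }
})

test_that("genes with length not divisible by 3 are warned about and fall in NG", {
  rec <- make_record(strrep("G", 2000L))
  expect_warning(prof <- scan_chromosome(rec, gene_row("X", 0L, 1000L, 1L)),
                 "multiple of 3")
  cp <- prof$checkpoints
  expect_equal(tail(cp$gcskew0 + cp$gcskew1 + cp$gcskew2, 1L), 0)
  expect_equal(tail(cp$gcskewNG, 1L), 2000)
  expect_equal(tail(cp$pospos, 1L), 1000) # still genic for strand bias
  expect_equal(tail(cp$ngcount, 1L), 1000)
})

test_that("tally_codons classifies start/stop codons strand-symmetrically", {
  rec <- make_record(paste0("ATGAAATAA", strrep("C", 11)))
  tal <- tally_codons(rec, gene_row("X", 0L, 9L, 1L))
  expect_equal(tal$protgenecount, 1L)
  expect_equal(tal$startATG, 1L)
  expect_equal(tal$stopTAA, 1L)

  rc <- make_record(paste0("TTATTTCAT", strrep("C", 11)))
  tal_rc <- tally_codons(rc, gene_row("X", 0L, 9L, -1L))
  expect_equal(tal_rc[c("startATG", "stopTAA", "protgenecount")],
               tal[c("startATG", "stopTAA", "protgenecount")])

  odd <- tally_codons(make_record("CTGAAATGATTT"),
                      gene_row("X", 0L, 9L, 1L))
  expect_equal(odd$startXXX, 1L)
  expect_equal(odd$stopTGA, 1L)
  # buckets always sum to the gene count
  many <- rbind(gene_row("X", 0L, 9L, 1L), gene_row("X", 3L, 12L, -1L))
  t2 <- tally_codons(make_record("CTGAAATGATTT"), many)
  expect_equal(t2$startATG + t2$startGTG + t2$startTTG + t2$startXXX,
               t2$protgenecount)
  expect_equal(t2$stopTAG + t2$stopTAA + t2$stopTGA + t2$stopXXX,
               t2$protgenecount)
})

test_that("find_dnaA returns the first match or -1", {
  genes <- rbind(gene_row("X", 1200L, 2400L, 1L, "dnaA"),
                 gene_row("X", 5000L, 6200L, 1L, "DnaA"))
  expect_equal(find_dnaA(genes), 1200L)
  expect_equal(find_dnaA(genes[2:1, ]), 1200L) # coordinate order, not row order
  expect_equal(find_dnaA(gene_row("X", 0L, 9L, 1L, "recA")), -1L)
  expect_equal(find_dnaA(empty_gene_table()), -1L)
})

test_that("coding_composition computes sense-strand fractions", {
  rec <- make_record(paste0(strrep("G", 30), strrep("A", 30)))
  comp <- coding_composition(rec, gene_row("X", 0L, 30L, 1L),
                             div = 0.5, shift = 0)
  expect_equal(comp$gfrac, 1)
  expect_equal(comp$ggcfrac, 1)
  expect_equal(comp$afrac + comp$cfrac + comp$gfrac + comp$tfrac, 1)
  # same gene on the minus strand reads as all-C
  comp_m <- coding_composition(rec, gene_row("X", 0L, 30L, -1L),
                               div = 0.5, shift = 0)
  expect_equal(comp_m$cfrac, 1)
  expect_equal(comp_m$cgcfrac, 1)
  # leading/lagging split: plus-sense gene on the leading arc is leading
  expect_equal(comp$leadgfrac, 1)
  expect_equal(sum(comp$lagafrac, comp$lagcfrac, comp$laggfrac, comp$lagtfrac),
               0) # no lagging genes
})
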