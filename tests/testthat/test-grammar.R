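# Vector naming grammar and the Exp/Pro/Del/Int assembly planners.

test_that("vector names parse into their fields and round-trip through format", {
  vn <- parse_name("pE8US1.1")
  expect_identical(vn$chromosome, "E")
  expect_identical(vn$locus_number, 8L)
  expect_identical(vn$yeast_marker, "U")
  expect_identical(vn$bacterial_resistance, "S")
  expect_identical(vn$level, 1L)
  expect_identical(vn$sublevel, 1L)

  vz <- parse_name("pZUA2.3")
  expect_identical(vz$chromosome, "Z")
  expect_true(is.na(vz$locus_number))
  expect_identical(vz$bacterial_resistance, "A")
  expect_identical(c(vz$level, vz$sublevel), c(2L, 3L))

  vi <- parse_name("pZUA2.3-HPD1-ARO4-ARO7")
  expect_identical(vi$insert, "HPD1-ARO4-ARO7")
  expect_identical(format_name(vi), "pZUA2.3-HPD1-ARO4-ARO7")

  set.seed(11)
  for (i in 1:100) {
    chrom <- sample(c(LETTERS[1:6], "Z"), 1L)
    lvl <- sample(1:2, 1L)
    sub <- if (lvl == 1L) sample(1:3, 1L) else sample(2:3, 1L)
    nm <- paste0("p", chrom, if (chrom != "Z") sample(1:16, 1L) else "",
                 sample(c("U", "L"), 1L), sample(c("S", "K", "A"), 1L),
                 lvl, ".", sub)
    expect_identical(format_name(parse_name(nm)), nm)
  }
})

test_that("malformed vector names fail with the offending field named", {
  expect_error(parse_name("qE8US1.1"), class = "pf_bad_name")
  expect_error(parse_name("pZ3UA2.3"), "locus", class = "pf_bad_name")
  expect_error(parse_name("pEUS1.1"), "locus", class = "pf_bad_name")
  expect_error(parse_name("pE8XS1.1"), "marker", class = "pf_bad_name")
  expect_error(parse_name("pE8US2.1"), "sublevel", class = "pf_bad_name")
  expect_error(parse_name("pE8US1.4"), "sublevel", class = "pf_bad_name")
})

test_that("the empty-vector series enumerates 5 names per locus", {
  expect_length(enumerate_empty_vectors(character(0)), 0L)
  expect_length(enumerate_empty_vectors("IntE8"), 5L)
  loci16 <- pf_gen$loci$name[pf_gen$loci$type == "intergenic"]
  expect_length(loci16, 16L)
  names80 <- enumerate_empty_vectors(loci16)
  expect_length(names80, 80L)
  expect_true(all(!duplicated(names80)))
  expect_true(all(vapply(names80, function(n) {
    v <- parse_name(n)
    (v$level == 1L && v$sublevel %in% 1:3) ||
      (v$level == 2L && v$sublevel %in% 2:3)
  }, logical(1))))
  # the fixture set realises exactly the enumerated series
  expect_setequal(names(pf_tk$empties), names80)
})

test_that("Lvl1 assembly matches an independent string-surgery oracle and drops the reporter", {
  empty <- pf_tk$empties[["pE2US1.1"]]
  prod <- pf_lvl1()
  expect_identical(prod$id, "pE2US1.1-hrGFP")
  expect_true(dropout_check(prod, pf_syn))
  expect_length(intersect(c("mScarlet", "sfGFP"), prod$features$label), 0L)
  expect_true(all(c("promoter", "CDS", "terminator") %in% prod$features$key))
  expect_length(prod$features$label[prod$features$key == "HA"], 2L)

  # oracle: replace the dropout span (J1..J4, junctions included) with
  # J1-promoter-J2-gene-J3-terminator-J4 by direct string surgery
  J <- pf_syn$junctions$lvl1
  ent <- pf_syn$enzymes$entry
  dropout <- paste0(J[["vector_promoter"]], "A", oracle_revcomp(ent$recognition),
                    pf_tk$segments$mScarlet, pf_tk$segments$sfGFP,
                    ent$recognition, "A", J[["terminator_vector"]])
  tu <- paste0(J[["vector_promoter"]], pf_tk$parts$promoters[["TEF1"]],
               J[["promoter_gene"]], pf_tk$parts$genes[["hrGFP"]],
               J[["gene_terminator"]], pf_tk$parts$terminators[["TER1"]],
               J[["terminator_vector"]])
  expect_true(grepl(dropout, empty$seq, fixed = TRUE))
  expected <- dna_molecule("expected", sub(dropout, tu, empty$seq, fixed = TRUE),
                           "circular")
  expect_true(molecules_equal(prod, expected))
})

test_that("a junction-mismatched part aborts the Lvl1 assembly", {
  # a terminator entry in the gene slot leaves the pot unable to close
  expect_error(
    suppressMessages(assemble_lvl1(pf_tk$empties[["pE2US1.1"]],
                                   pf_tk$entries[["pL0-TEF1"]],
                                   pf_tk$entries[["pL0-TER2"]],
                                   pf_tk$entries[["pL0-TER1"]], pf_syn)),
    class = "pf_assembly_error")
})

test_that("Lvl2 assembly orders TUs by donor sublevel, independent of input order", {
  l1a <- pf_lvl1("pE2US1.1", gene = "pL0-HPD1")
  l1b <- pf_lvl1("pE2US1.2", gene = "pL0-ARO4", term = "pL0-TER2")
  l1c <- pf_lvl1("pE2US1.3", gene = "pL0-ARO7")
  p1 <- suppressMessages(assemble_lvl2(pf_tk$zeta_empties[["pZUA2.3"]],
                                       list(l1a, l1b, l1c), pf_syn))
  p2 <- suppressMessages(assemble_lvl2(pf_tk$zeta_empties[["pZUA2.3"]],
                                       list(l1c, l1a, l1b), pf_syn))
  expect_true(molecules_equal(p1, p2))
  expect_identical(p1$id, "pZUA2.3-HPD1-ARO4-ARO7")
  # genes appear along the product in sublevel order
  cds <- p1$features[p1$features$key == "CDS", ]
  ord <- cds$label[order(cds$start)]
  hpos <- match(c("HPD1", "ARO4", "ARO7"), ord)
  expect_true(all(diff(hpos) == 1L) || all(diff(rev(hpos)) == 1L))

  # two TUs on a Lvl2.2
  p22 <- suppressMessages(assemble_lvl2(pf_tk$zeta_empties[["pZUA2.2"]],
                                        list(l1b, l1a), pf_syn))
  expect_length(p22$features$label[p22$features$key == "CDS"], 2L)

  # duplicate positional sublevels are rejected before digestion
  l1a2 <- pf_lvl1("pB1US1.1", gene = "pL0-ARO4")
  expect_error(assemble_lvl2(pf_tk$zeta_empties[["pZUA2.2"]],
                             list(l1a, l1a2), pf_syn),
               class = "pf_validation")
  expect_error(assemble_lvl2(pf_tk$zeta_empties[["pZUA2.3"]],
                             list(l1a, l1b), pf_syn),
               class = "pf_validation")
})

test_that("promoter insertion lands upstream of hrGFP with the RFP dropout gone", {
  J <- pf_syn$junctions$lvl1
  amp <- make_amplicon(pf_tk$parts$promoters[["PRO1"]],
                       J[["vector_promoter"]], J[["promoter_gene"]],
                       pf_syn$enzymes$entry, "amp-PRO1",
                       feature("promoter", "PRO1", 0L, 200L))
  prod <- suppressMessages(assemble_pro(pf_tk$pro, amp, pf_syn))
  expect_identical(prod$id, "pProUA-PRO1")
  expect_false("mScarlet" %in% prod$features$label)
  prom <- prod$features[prod$features$label == "PRO1", ]
  gfp <- prod$features[prod$features$label == "hrGFP", ]
  gap <- (gfp$start - prom$end) %% seq_length(prod)
  expect_lte(gap, 20L)
  # re-ligation without insert keeps the reporter: rejected
  expect_error(suppressMessages(assemble_pro(pf_tk$pro,
                                             pf_tk$entries[["pL0-TER1"]],
                                             pf_syn)),
               class = "pf_assembly_error")
})

test_that("disruption vectors take both arms and reject swapped junctions", {
  arms <- pf_amplicon_arms("ARO8")
  prod <- suppressMessages(assemble_del(pf_tk$del, arms$up, arms$down,
                                        "ARO8", pf_syn))
  expect_identical(prod$id, "pDelUK-ARO8")
  expect_true(dropout_check(prod, pf_syn))
  expect_setequal(prod$features$label[prod$features$key == "HA"],
                  c("ARO8_up", "ARO8_down"))
  expect_true("URA3" %in% prod$features$label)
  # swapped arms: junction mismatch caught before digestion of the pot
  expect_error(suppressMessages(assemble_del(pf_tk$del, arms$down, arms$up,
                                             "ARO8", pf_syn)),
               class = "pf_validation")
})

test_that("homology-arm exchange moves the TU section, switches resistance and drops sfGFP", {
  l1a <- pf_lvl1("pE2US1.1", gene = "pL0-HPD1")
  l1b <- pf_lvl1("pE2US1.2", gene = "pL0-ARO4", term = "pL0-TER2")
  l1c <- pf_lvl1("pE2US1.3", gene = "pL0-ARO7")
  l2 <- suppressMessages(assemble_lvl2(pf_tk$zeta_empties[["pZUA2.3"]],
                                       list(l1a, l1b, l1c), pf_syn))
  empty <- pf_tk$empties[["pA1US1.1"]]
  ex <- suppressMessages(exchange_has(l2, empty, pf_syn))
  expect_identical(ex$product$id, "pA1US-HPD1-ARO4-ARO7")
  expect_false("sfGFP" %in% ex$product$features$label)
  expect_identical(ex$product$features$label[ex$product$features$key == "resistance"],
                   "SpecR")
  expect_setequal(ex$product$features$label[ex$product$features$key == "HA"],
                  c("IntA1_up", "IntA1_down"))
  # reciprocal product carries the old backbone and the reporter
  expect_true("sfGFP" %in% ex$reciprocal$features$label)

  # central-section length conservation vs independent site arithmetic
  aari <- pf_syn$enzymes$exchange
  central_len <- function(m) {
    cuts <- plasmidforge:::enzyme_cuts(m, aari)
    n <- seq_length(m)
    arcs <- c((cuts$top[2L] - cuts$top[1L]) %% n,
              (cuts$top[1L] - cuts$top[2L]) %% n)
    arcs
  }
  # one arc of the product equals an arc of each parent (backbone/central)
  expect_true(length(intersect(central_len(ex$product), central_len(l2))) >= 1L)
  expect_true(length(intersect(central_len(ex$product), central_len(empty))) >= 1L)

  # exchanging a vector with itself returns the vector
  self <- suppressMessages(exchange_has(l2, l2, pf_syn))
  expect_true(molecules_equal(self$product, l2))

  # reversibility: exchanging back onto a Zeta empty restores the original
  back <- suppressMessages(exchange_has(ex$product,
                                        pf_tk$zeta_empties[["pZUA2.3"]],
                                        pf_syn))
  expect_true(molecules_equal(back$product, l2))

  # site-count precondition
  expect_error(exchange_has(pf_tk$cas, empty, pf_syn),
               class = "pf_validation")
})

test_that("TU transfer into a disruption vector is irreversible (product is exchange-site-free)", {
  l1a <- pf_lvl1("pE2US1.1", gene = "pL0-HPD1")
  ex <- suppressMessages(exchange_has(l1a, pf_tk$empties[["pA1US1.1"]],
                                      pf_syn))
  arms <- pf_amplicon_arms("AAT1")
  delv <- suppressMessages(assemble_del(pf_tk$del, arms$up, arms$down,
                                        "AAT1", pf_syn))
  tr <- suppressMessages(transfer_to_del(ex$product, delv, pf_syn))
  expect_identical(tr$id, "pDelUK-AAT1::HPD1")
  expect_equal(nrow(find_sites(tr, pf_syn$enzymes$exchange$recognition)), 0L)
  expect_setequal(tr$features$label[tr$features$key == "HA"],
                  c("AAT1_up", "AAT1_down"))
  # length arithmetic: product = pDel - its marker dropout + donor central
  aari <- pf_syn$enzymes$exchange
  arc <- function(m) {
    cuts <- plasmidforge:::enzyme_cuts(m, aari)
    n <- seq_length(m)
    sort(c((cuts$top[2L] - cuts$top[1L]) %% n,
           (cuts$top[1L] - cuts$top[2L]) %% n))
  }
  a_del <- arc(delv)
  a_don <- arc(ex$product)
  expect_true(seq_length(tr) %in% c(a_del[1L] + a_don[2L],
                                    a_del[2L] + a_don[1L],
                                    a_del[1L] + a_don[1L],
                                    a_del[2L] + a_don[2L]))
})
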