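# Cre-lox marker excision and lambda-Red single-oligo recombineering.

lox <- pf_syn$lox

# toy circle: lox71 - marker - lox66 - backbone(with origin feature)
toy_lox_circle <- function(marker_len = 60L, backbone_len = 100L) {
  set.seed(101)
  mseq <- random_seq(marker_len)
  bseq <- random_seq(backbone_len)
  seq <- paste0(lox$lox71_seq, mseq, lox$lox66_seq, bseq)
  feats <- rbind(
    feature("lox_site", "lox71", 0L, 34L),
    feature("marker", "URA3", 34L, 34L + marker_len),
    feature("lox_site", "lox66", 34L + marker_len, 68L + marker_len),
    feature("origin", "ori", 68L + marker_len, 68L + marker_len + backbone_len))
  list(mol = dna_molecule("toy_lox", seq, "circular", feats),
       marker = mseq, backbone = bseq)
}

test_that("Cre excision matches the string-surgery oracle and conserves total sequence", {
  toy <- toy_lox_circle()
  res <- cre_excise(toy$mol, lox)
  # oracle: retained = lox72 + backbone; excised = loxP + marker
  expect_true(molecules_equal(res$retained,
                              dna_molecule("o1", paste0(lox$lox72_seq, toy$backbone),
                                           "circular")))
  expect_true(molecules_equal(res$excised,
                              dna_molecule("o2", paste0(lox$loxP_seq, toy$marker),
                                           "circular")))
  expect_identical(res$retained_site, "lox72")
  expect_identical(res$excised_site, "loxP")
  # conservative recombination: lengths add up exactly
  expect_equal(seq_length(res$retained) + seq_length(res$excised),
               seq_length(toy$mol))
  # the retained circle keeps the origin, not the marker
  expect_true("ori" %in% res$retained$features$label)
  expect_false("URA3" %in% res$retained$features$label)
})

test_that("Cre excision of fixture Lvl1 plasmids removes the marker and is idempotent", {
  for (id in c("pC1US1.1", "pD1US1.1", "pE2US1.1")) {
    l1 <- pf_lvl1(id)
    res <- cre_excise(l1, lox)
    expect_false("URA3" %in% res$retained$features$label, info = id)
    expect_true("URA3" %in% res$excised$features$label, info = id)
    expect_equal(seq_length(res$retained) + seq_length(res$excised),
                 seq_length(l1), info = id)
    # idempotence: the retained product has no lox66/lox71 pair left
    expect_error(cre_excise(res$retained, lox), class = "pf_no_substrate")
    expect_equal(nrow(find_sites(res$retained, lox$lox72_seq)), 1L)
  }
})

test_that("Cre substrates are validated: absence, inversion, ambiguity", {
  expect_error(cre_excise(pf_tk$cas, lox), class = "pf_no_substrate")
  toy <- toy_lox_circle()
  # invert the lox66 site
  inv <- toy$mol
  s66 <- 34L + 60L
  substr(inv$seq, s66 + 1L, s66 + 34L) <- oracle_revcomp(lox$lox66_seq)
  expect_error(cre_excise(inv, lox), class = "pf_inversion")
  # a third site makes the substrate ambiguous
  amb <- dna_molecule("amb", paste0(toy$mol$seq, lox$lox66_seq), "circular")
  expect_error(cre_excise(amb, lox), class = "pf_ambiguous")
  # the pair is still found when the whole cassette sits on the minus strand
  flip <- dna_molecule("flip", oracle_revcomp(toy$mol$seq), "circular",
                       plasmidforge:::flip_features(toy$mol$features,
                                                    seq_length(toy$mol)))
  res <- cre_excise(flip, lox)
  expect_identical(res$retained_site, "lox72")
})

test_that("parallel assembly yields marker-based and marker-free versions differing by the lox-flanked segment", {
  inputs <- list(pf_tk$empties[["pE2US1.1"]], pf_tk$entries[["pL0-TEF1"]],
                 pf_tk$entries[["pL0-hrGFP"]], pf_tk$entries[["pL0-TER1"]])
  pair <- suppressMessages(marker_free_pair(inputs, pf_syn$enzymes$entry, lox))
  expect_true("URA3" %in% pair$marker_based$features$label)
  expect_false("URA3" %in% pair$marker_free$features$label)
  # diff oracle: the versions differ by marker + lox flanks - hybrid site
  delta <- seq_length(pair$marker_based) - seq_length(pair$marker_free)
  marker_span <- nchar(pf_tk$segments$ura3) + 2L * 34L
  expect_equal(delta, marker_span - 34L)

  # marker excision and arm exchange commute
  ex_then_mex <- cre_excise(
    suppressMessages(exchange_has(pair$marker_based,
                                  pf_tk$empties[["pA1US1.1"]],
                                  pf_syn))$product, lox)$retained
  mex_then_ex <- suppressMessages(exchange_has(pair$marker_free,
                                               pf_tk$empties[["pA1US1.1"]],
                                               pf_syn))$product
  expect_true(molecules_equal(ex_then_mex, mex_then_ex))
})

test_that("marker-free version is absent, with a warning, when the marker lacks lox flanks", {
  # toy acceptor/donor pair with no lox sites anywhere
  mk <- function(id, seq) dna_molecule(id, seq, "circular")
  acceptor <- mk("acc", paste0(strrep("CA", 15L), "AATG", "A", "GAGACC",
                               strrep("GT", 20L), "GGTCTC", "A", "GCTT",
                               strrep("AG", 15L)))
  donorv <- mk("don", paste0(strrep("TC", 12L), "GGTCTC", "A", "AATG",
                             strrep("CT", 18L), "GCTT", "A", "GAGACC",
                             strrep("GA", 12L)))
  expect_warning(
    pair <- suppressMessages(marker_free_pair(list(acceptor, donorv),
                                              pf_syn$enzymes$entry, lox)),
    "no lox")
  expect_null(pair$marker_free)
  expect_s3_class(pair$marker_based, "dna_molecule")
})

test_that("oligo recombineering replaces exactly the cassette and nothing else", {
  helper <- pf_tk$cas
  spacer <- strrep("AG", 10L)
  olig <- design_oligo(spacer, helper)
  expect_equal(nchar(olig$seq), 90L)
  out <- lambda_red_replace(helper, olig)
  # arithmetic oracle: product length = helper - cassette + 20
  cass_len <- nchar(pf_tk$segments$rpsl_kanr)
  expect_equal(seq_length(out), seq_length(helper) - cass_len + 20L)
  expect_true(counterselect_check(out))
  expect_false(counterselect_check(helper))
  # locality: outside [left-homology start, right-homology end] untouched
  slot <- helper$features[grepl("rpsL", helper$features$label), ]
  n <- seq_length(helper)
  upstream <- plasmidforge:::circ_substr(helper$seq, slot$end %% n,
                                         n - (slot$end - slot$start))
  # product frame: 35-nt left homology, 20-nt spacer, then everything else
  kept <- plasmidforge:::circ_substr(out$seq, 55L, seq_length(out) - 20L)
  expect_identical(kept, upstream)
  # either oligo orientation gives the same product
  out2 <- lambda_red_replace(helper, oligo90(oracle_revcomp(olig$seq)))
  expect_true(molecules_equal(out, out2))
})

test_that("recombineering round-trips when swapping spacers back and forth", {
  hA <- lambda_red_replace(pf_tk$cas, design_oligo(strrep("AC", 10L),
                                                   pf_tk$cas))
  hB <- lambda_red_replace(hA, design_oligo(strrep("GT", 10L), hA))
  hA2 <- lambda_red_replace(hB, design_oligo(strrep("AC", 10L), hB))
  expect_true(molecules_equal(hA2, hA))
})

test_that("recombineering validates homology targets: absence, multiplicity, orientation", {
  helper <- pf_tk$cas
  none <- oligo90(paste0(random_seq(35L), strrep("A", 20L), random_seq(35L)))
  set.seed(5)
  expect_error(lambda_red_replace(helper, none), class = "pf_no_target")
  olig <- design_oligo(strrep("AG", 10L), helper)
  # duplicate the left homology elsewhere: ambiguous
  dup <- dna_molecule("dup", paste0(helper$seq, "TT", olig$left_homology),
                      "circular", helper$features)
  expect_error(lambda_red_replace(dup, olig), class = "pf_ambiguous")
  # homologies swapped: wrong order around the circle
  swapped <- oligo90(left = olig$right_homology, spacer = olig$spacer,
                     right = olig$left_homology)
  expect_error(lambda_red_replace(helper, swapped), class = "pf_orientation")
  # one homology inverted: inconsistent strands
  mixed <- oligo90(left = olig$left_homology, spacer = olig$spacer,
                   right = oracle_revcomp(olig$right_homology))
  expect_error(lambda_red_replace(helper, mixed), class = "pf_orientation")
  # oligo length is enforced
  expect_error(oligo90(strrep("A", 89L)), class = "pf_invalid_oligo")
})
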