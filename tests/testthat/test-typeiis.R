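# Type IIS digestion, sticky-end ligation and one-pot Golden Gate.

bsa <- builtin_enzyme("BsaI")

# small circle with two BsaI sites at hand-computed positions
toy_two_site_circle <- function() {
  # layout: a(20) GGTCTC T ACTG b(30) TGCA A GAGACC c(40)
  # + site at 20: top cut = 20+6+1 = 27, overhang = [27,31) = ACTG
  # - site at 61: top cut = 61-5 = 56, overhang = [56,60) = TGCA
  a <- strrep("AC", 10L)
  b <- strrep("GA", 15L)
  c <- strrep("CT", 20L)
  list(mol = dna_molecule("toy", paste0(a, "GGTCTC", "T", "ACTG", b,
                                        "TGCA", "A", "GAGACC", c),
                          "circular"),
       b = b, a = a, c = c)
}

test_that("digestion reproduces hand cut-position arithmetic on a known circle", {
  toy <- toy_two_site_circle()
  fr <- digest(toy$mol, bsa)
  expect_length(fr, 2L)
  seqs <- vapply(fr, function(f) f$seq, character(1))
  insert <- paste0("ACTG", toy$b, "TGCA")
  expect_true(insert %in% seqs)
  ins <- fr[[which(seqs == insert)]]
  expect_identical(ins$left_ov, "ACTG")
  expect_identical(ins$right_ov, "TGCA")
  other <- fr[[which(seqs != insert)]]
  expect_identical(other$left_ov, "TGCA")
  expect_identical(other$right_ov, "ACTG")
  # conservation: each junction's overhang counted once
  expect_equal(sum(nchar(seqs) - 4L), seq_length(toy$mol))
})

test_that("fragment counts follow topology and zero-site circles are flagged undigested", {
  toy <- toy_two_site_circle()
  lin <- dna_molecule("lin", toy$mol$seq, "linear")
  expect_length(digest(lin, bsa), 3L)
  none <- dna_molecule("none", strrep("AC", 40L), "circular")
  out <- digest(none, bsa)
  expect_s3_class(out, "dna_molecule")
  expect_true(attr(out, "undigested"))
  # single-site circle: one fragment, self-complementary ends
  one <- dna_molecule("one", paste0(strrep("AC", 10L), "GGTCTC", "T", "ACTG",
                                    strrep("GA", 15L)), "circular")
  f1 <- digest(one, bsa)
  expect_length(f1, 1L)
  expect_identical(f1[[1L]]$left_ov, f1[[1L]]$right_ov)
  expect_equal(nchar(f1[[1L]]$seq), seq_length(one) + 4L)
})

test_that("overlapping cut windows raise an unresolvable-cut error naming positions", {
  # two sites cutting into the same 4-bp window
  clash <- dna_molecule("clash",
                        paste0(strrep("AC", 10L), "GGTCTC", "T", "ACTG", "T",
                               "GAGACC", strrep("GA", 10L)), "circular")
  expect_error(digest(clash, bsa), class = "pf_unresolvable_cut")
  expect_error(digest(clash, bsa), "position")
})

test_that("re-ligation of a digest reproduces the parent (inverse law) across fixture plasmids", {
  for (id in c("pA1US1.1", "pB1US1.3", "pE2US1.2")) {
    m <- pf_tk$empties[[id]]
    fr <- digest(m, bsa)
    expect_equal(sum(vapply(fr, function(f) nchar(f$seq), integer(1)) - 4L),
                 seq_length(m), info = id)
    rel <- ligate_cyclic(fr)
    expect_true(any(vapply(rel, molecules_equal, logical(1), m)), info = id)
  }
})

test_that("cyclic ligation enumerates exactly the products of the exhaustive permutation oracle", {
  set.seed(7)
  mk <- function(left, core_len, right) {
    seq <- paste0(left, random_seq(core_len), right)
    plasmidforge:::new_fragment(seq, left, right, "t")
  }
  # chain a-b, b-c, c-a closes into exactly one circle
  fa <- mk("AATG", 12L, "TGAC")
  fb <- mk("TGAC", 9L, "GCTT")
  fc <- mk("GCTT", 15L, "AATG")
  got <- ligate_cyclic(list(fa, fb, fc))
  expect_length(got, 1L)
  # order-independence
  got2 <- ligate_cyclic(list(fc, fa, fb))
  expect_true(molecules_equal(got[[1L]], got2[[1L]]))
  # equivalence with the brute-force oracle on several random pools
  for (rep in 1:5) {
    ovs <- c("AATG", "TGAC", "GCTT", "CCAG", "GTTC")
    pool <- lapply(1:4, function(i) {
      mk(sample(ovs, 1L), sample(6:18, 1L), sample(ovs, 1L))
    })
    got <- ligate_cyclic(pool)
    want <- oracle_circles(lapply(pool, function(f) {
      list(seq = f$seq, left = f$left_ov, right = f$right_ov)
    }))
    expect_setequal(vapply(got, function(p) oracle_canonical(p$seq), ""),
                    want)
  }
  # no complementary ends -> nothing circularises
  expect_length(ligate_cyclic(list(mk("AATG", 10L, "GCTT"),
                                   mk("CCAG", 10L, "GTTC"))), 0L)
})

test_that("one-pot Golden Gate finds the unique stable product, invariant to input order and rotation", {
  inputs <- list(pf_tk$empties[["pE2US1.1"]], pf_tk$entries[["pL0-TEF1"]],
                 pf_tk$entries[["pL0-hrGFP"]], pf_tk$entries[["pL0-TER1"]])
  rep1 <- golden_gate(inputs, bsa)
  expect_length(rep1$products, 1L)
  expect_gt(length(rep1$unstable), 0L)
  # stable product has no recognition site and is inert to re-digestion
  prod <- rep1$products[[1L]]
  expect_equal(nrow(find_sites(prod, bsa$recognition)), 0L)
  expect_true(attr(digest(prod, bsa), "undigested"))
  # input order and rotation do not change the outcome
  rep2 <- golden_gate(rev(lapply(inputs, rotate_molecule, shift = 101L)), bsa)
  expect_length(rep2$products, 1L)
  expect_true(molecules_equal(rep1$products[[1L]], rep2$products[[1L]]))
})

test_that("Golden Gate reports failure to close and undigested inputs as warnings", {
  # promoter + terminator entries share no junction: no stable circle
  rep <- golden_gate(list(pf_tk$entries[["pL0-TEF1"]],
                          pf_tk$entries[["pL0-TER1"]]), bsa)
  expect_length(rep$products, 0L)
  expect_true(any(grepl("no stable", rep$warnings)))
  # an input without sites is flagged undigested
  rep2 <- golden_gate(list(pf_tk$entries[["pL0-TEF1"]],
                           dna_molecule("inert", strrep("AC", 30L), "circular")),
                      bsa)
  expect_length(rep2$undigested, 1L)
  expect_true(any(grepl("inert", rep2$warnings)))
})

test_that("overhang fidelity hazards are detected pairwise", {
  expect_length(fidelity_check(c("AATG", "TGAA", "GCTT")), 0L)
  expect_length(fidelity_check(c("CATG")), 1L)             # palindrome
  expect_length(fidelity_check(c("AATG", "AATG")), 1L)     # duplicate
  expect_length(fidelity_check(c("AATG", "CATT")), 1L)     # revcomp collision
  expect_length(fidelity_check(c("CATG", "CATG", "AATG", "CATT")), 3L)
  # the default junction map is hazard-free
  expect_length(fidelity_check(unlist(pf_syn$junctions)), 0L)
})

test_that("enzyme definitions reject non-Type-IIS geometries", {
  expect_error(enzyme("Pal", "GAATTC", 1L, 5L), class = "pf_invalid_enzyme")
  expect_error(enzyme("Neg", "GGTCTC", -1L, 3L), class = "pf_invalid_enzyme")
  expect_error(enzyme("Three", "GGTCTC", 5L, 1L), class = "pf_invalid_enzyme")
  expect_equal(builtin_enzyme("AarI")$overhang_len, 4L)
})
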