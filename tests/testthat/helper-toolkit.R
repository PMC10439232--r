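# Shared fixture toolkit, built once per test run under a fixed seed.
pf_spec <- fixture_spec(seed = 1L)
pf_syn <- pf_spec$syntax
pf_tk <- suppressMessages(build_fixture_toolkit(pf_spec))
pf_gen <- pf_tk$genome

# a routinely used Lvl1 assembly
pf_lvl1 <- function(empty = "pE2US1.1", prom = "pL0-TEF1", gene = "pL0-hrGFP",
                    term = "pL0-TER1") {
  suppressMessages(assemble_lvl1(pf_tk$empties[[empty]], pf_tk$entries[[prom]],
                                 pf_tk$entries[[gene]], pf_tk$entries[[term]],
                                 pf_syn))
}

pf_amplicon_arms <- function(locus_name, arm_len = pf_spec$arm_len) {
  row <- pf_gen$loci[pf_gen$loci$name == locus_name, ][1L, ]
  arms <- design_has(pf_gen$chromosomes, row, arm_len = arm_len)
  D <- pf_syn$junctions$del
  list(
    up = make_amplicon(arms$left_arm, D[["up_left"]], D[["up_right"]],
                       pf_syn$enzymes$entry, paste0("amp-", locus_name, "-up"),
                       feature("HA", paste0(locus_name, "_up"), 0L, arm_len)),
    down = make_amplicon(arms$right_arm, D[["down_left"]], D[["down_right"]],
                         pf_syn$enzymes$entry, paste0("amp-", locus_name, "-down"),
                         feature("HA", paste0(locus_name, "_down"), 0L, arm_len)))
}
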