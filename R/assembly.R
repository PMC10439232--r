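# Level/sublevel assembly planners (Exp, Pro, Del) and the Int-module
# homology-arm exchange. Each planner delegates the chemistry to
# golden_gate() and then applies the same screens a bench scientist uses:
# dropout-reporter absence, expected part order, and (for the exchange)
# antibiotic-resistance switching. Screens are logged, never silent.

assembly_fail <- function(msg, report) {
  cond <- errorCondition(paste0(msg, if (length(report$warnings))
    paste0(" [", paste(report$warnings, collapse = "; "), "]") else ""),
    class = c("pf_assembly_error", "pf_error", "error"))
  cond$report <- report
  stop(cond)
}

single_stable <- function(report, what) {
  if (length(report$products) != 1L) {
    assembly_fail(sprintf("%s: expected exactly 1 stable product, got %d",
                          what, length(report$products)), report)
  }
  report$products[[1L]]
}

#' Does an assembly product pass the fluorescence dropout screen?
#'
#' TRUE iff no bacterial dropout reporter (by default mScarlet/sfGFP) remains
#' annotated on the molecule — the in-silico analogue of picking white
#' (non-fluorescent) colonies.
#' @param molecule A `dna_molecule`.
#' @param syntax Syntax config naming the dropout reporters.
#' @export
dropout_check <- function(molecule, syntax = default_syntax()) {
  !any(molecule$features$label %in% syntax$reporters$assembly_dropout &
         molecule$features$key == "reporter")
}

feature_labels <- function(m, key) m$features$label[m$features$key == key]

# order of the given labels along the plus strand of a circular product,
# read from the first homology arm
ordered_labels <- function(m, key) {
  f <- m$features[m$features$key == key, , drop = FALSE]
  f$label[order(f$start)]
}

#' Assemble a single transcription unit into an empty Lvl1 vector
#'
#' One-pot Golden Gate with the entry enzyme: promoter, gene and terminator
#' parts (supplied as entry vectors or amplicons) replace the fluorescent
#' dropout cassette of the empty vector. The product must be the unique
#' stable (site-free) circle, carry promoter-gene-terminator in order, retain
#' the empty vector's homology arms and markers, and pass [dropout_check()].
#'
#' @param empty_lvl1 Empty Lvl1 vector (`dna_molecule`).
#' @param promoter_part,gene_part,terminator_part Entry vectors or amplicons
#'   carrying the respective parts.
#' @param syntax Syntax config.
#' @return The assembled Lvl1 `dna_molecule`, named `<empty>-<gene>`.
#' @export
assemble_lvl1 <- function(empty_lvl1, promoter_part, gene_part,
                          terminator_part, syntax = default_syntax()) {
  rep <- golden_gate(list(empty_lvl1, promoter_part, gene_part,
                          terminator_part), syntax$enzymes$entry)
  prod <- single_stable(rep, sprintf("Lvl1 assembly into %s", empty_lvl1$id))
  if (!dropout_check(prod, syntax)) {
    assembly_fail("Lvl1 product retains a dropout reporter", rep)
  }
  gene_lab <- feature_labels(gene_part, "CDS")[1L]
  for (key in c("promoter", "CDS", "terminator")) {
    if (!length(feature_labels(prod, key))) {
      assembly_fail(sprintf("Lvl1 product lacks a %s feature", key), rep)
    }
  }
  if (length(feature_labels(prod, "HA")) < 2L) {
    assembly_fail("Lvl1 product lost its homology arms", rep)
  }
  prod$id <- paste0(empty_lvl1$id, "-", gene_lab %||% "TU")
  pf_log(sprintf("assembled %s (dropout screen passed)", prod$id))
  prod
}

donor_sublevel <- function(donor, syntax) {
  vn <- tryCatch(parse_name(donor$id, syntax), pf_error = function(e) NULL)
  if (is.null(vn) || vn$level != 1L) {
    pf_stop(sprintf("cannot determine Lvl1 sublevel of donor '%s' from its name",
                    donor$id), "pf_bad_name")
  }
  vn$sublevel
}

#' Combine Lvl1 transcription units into an empty Lvl2 vector
#'
#' The sublevel of each Lvl1 donor (parsed from its vector name) determines
#' the position of its TU in the product; the Lvl2 sublevel (2 or 3) fixes
#' how many TUs are required. Duplicate or missing positional sublevels are
#' a validation error raised before any digestion.
#'
#' @param empty_lvl2 Empty Lvl2 vector.
#' @param lvl1_donors List of assembled Lvl1 vectors.
#' @param syntax Syntax config.
#' @return The multi-TU Lvl2 `dna_molecule`.
#' @export
assemble_lvl2 <- function(empty_lvl2, lvl1_donors, syntax = default_syntax()) {
  vn2 <- parse_name(empty_lvl2$id, syntax)
  if (vn2$level != 2L) {
    pf_stop(sprintf("'%s' is not a Lvl2 vector", empty_lvl2$id), "pf_bad_name")
  }
  subs <- vapply(lvl1_donors, donor_sublevel, integer(1), syntax = syntax)
  need <- seq_len(vn2$sublevel)
  if (length(lvl1_donors) != vn2$sublevel || anyDuplicated(subs) ||
      !setequal(subs, need)) {
    pf_stop(sprintf("Lvl2.%d assembly requires donors with sublevels {%s}; got {%s}",
                    vn2$sublevel, paste(need, collapse = ","),
                    paste(sort(subs), collapse = ",")), "pf_validation")
  }
  rep <- golden_gate(c(list(empty_lvl2), lvl1_donors), syntax$enzymes$lvl2)
  prod <- single_stable(rep, sprintf("Lvl2 assembly into %s", empty_lvl2$id))
  if (!dropout_check(prod, syntax)) {
    assembly_fail("Lvl2 product retains a dropout reporter", rep)
  }
  # TU order in the product must follow donor sublevels, not input order
  donor_by_sub <- lvl1_donors[order(subs)]
  tu_genes <- vapply(donor_by_sub, function(d) {
    labs <- feature_labels(d, "CDS")
    labs[length(labs)]         # the TU's gene (helper Cas9 etc. not expected)
  }, character(1))
  prod$id <- paste0(empty_lvl2$id, "-", paste(tu_genes, collapse = "-"))
  pf_log(sprintf("assembled %s with %d TUs", prod$id, vn2$sublevel))
  prod
}

#' Insert a promoter into the promoter-assay vector
#'
#' Single Golden Gate step replacing the RFP dropout so the promoter lands
#' immediately upstream of the promoterless hrGFP reporter gene. A product
#' still carrying the dropout (re-ligation) is rejected.
#'
#' @param pro_empty The empty promoter-assay vector (mScarlet dropout).
#' @param promoter_amplicon Linear amplicon ([make_amplicon()]) or entry
#'   vector carrying the promoter.
#' @param syntax Syntax config.
#' @return The promoter-assay `dna_molecule`, named `pPro<marker><res>-<promoter>`.
#' @export
assemble_pro <- function(pro_empty, promoter_amplicon,
                         syntax = default_syntax()) {
  rep <- golden_gate(list(pro_empty, promoter_amplicon), syntax$enzymes$entry)
  prod <- single_stable(rep, "promoter-vector assembly")
  if (any(feature_labels(prod, "reporter") %in% syntax$reporters$pro_dropout)) {
    assembly_fail("promoter vector retains the RFP dropout", rep)
  }
  prom <- prod$features[prod$features$key == "promoter", , drop = FALSE]
  gfp <- prod$features[prod$features$key == "CDS" &
                         prod$features$label == "hrGFP", , drop = FALSE]
  if (!nrow(prom) || !nrow(gfp)) {
    assembly_fail("promoter vector must carry promoter and hrGFP", rep)
  }
  gap <- (gfp$start[1L] - prom$end[1L]) %% seq_length(prod)
  if (gap > 20L) {
    assembly_fail(sprintf("promoter is not immediately upstream of hrGFP (gap %d nt)",
                          gap), rep)
  }
  base <- sub("-mScarlet$", "", pro_empty$id)
  prod$id <- paste0(base, "-", prom$label[1L])
  pf_log(sprintf("assembled %s (RFP dropout screen passed)", prod$id))
  prod
}

#' Assemble a gene-disruption vector from two homology-arm amplicons
#'
#' Both fluorescent reporters of the dual-dropout deletion vector are
#' replaced by the upstream and downstream homology arms flanking the target
#' gene; the marker cassette between them is retained. A product retaining
#' either reporter fails the screen.
#'
#' @param del_empty The dual-reporter deletion vector.
#' @param ha_up_amplicon,ha_down_amplicon Linear amplicons carrying the arms
#'   (distinct junction pairs).
#' @param target Name of the gene being disrupted (used for the product id).
#' @param syntax Syntax config.
#' @return The disruption `dna_molecule`, named `<del_empty base>-<target>`.
#' @export
assemble_del <- function(del_empty, ha_up_amplicon, ha_down_amplicon,
                         target = "target", syntax = default_syntax()) {
  D <- syntax$junctions$del
  check_amplicon_junctions(ha_up_amplicon, D[["up_left"]], D[["up_right"]],
                           "upstream arm", syntax)
  check_amplicon_junctions(ha_down_amplicon, D[["down_left"]],
                           D[["down_right"]], "downstream arm", syntax)
  rep <- golden_gate(list(del_empty, ha_up_amplicon, ha_down_amplicon),
                     syntax$enzymes$entry)
  prod <- single_stable(rep, "disruption-vector assembly")
  if (!dropout_check(prod, syntax)) {
    assembly_fail("disruption vector retains a dropout reporter", rep)
  }
  if (length(feature_labels(prod, "HA")) < 2L) {
    assembly_fail("disruption vector must carry both homology arms", rep)
  }
  prod$id <- paste0(sub("-RG$", "", del_empty$id), "-", target)
  pf_log(sprintf("assembled %s (dual dropout screen passed)", prod$id))
  prod
}

# an amplicon must release a (site-free) part fragment carrying exactly the
# junction overhangs its slot expects; a swapped-arm amplicon fails here
check_amplicon_junctions <- function(amplicon, left_j, right_j, what, syntax) {
  enz <- syntax$enzymes$entry
  fr <- digest(amplicon, enz)
  if (inherits(fr, "dna_molecule")) {
    pf_stop(sprintf("%s amplicon '%s' has no %s sites", what, amplicon$id,
                    enz$name), "pf_validation")
  }
  ok <- any(vapply(fr, function(f) {
    (f$left_ov == left_j && f$right_ov == right_j) ||
      (f$left_ov == revcomp(right_j) && f$right_ov == revcomp(left_j))
  }, logical(1)))
  if (!ok) {
    pf_stop(sprintf("junction mismatch: %s amplicon '%s' does not release a %s...%s part",
                    what, amplicon$id, left_j, right_j), "pf_validation")
  }
  invisible(TRUE)
}

count_exchange_sites <- function(m, syntax) {
  nrow(find_sites(m, syntax$enzymes$exchange$recognition))
}

resistance_label <- function(m) {
  labs <- feature_labels(m, "resistance")
  if (!length(labs)) NA_character_ else labs[1L]
}

#' Exchange homology arms between an assembled and an empty vector
#'
#' Golden Gate with the exchange enzyme (AarI) between two undigested
#' plasmids, each carrying exactly two sites separating backbone-with-arms
#' from the central TU section. The reported `product` is the circle that
#' carries the empty vector's backbone (arms and bacterial resistance) and
#' the assembled vector's central section, and lacks the sfGFP reporter —
#' the in-silico analogue of selecting on the new antibiotic plus
#' GFP-negative phenotype. The reciprocal circle is returned alongside,
#' flagged. Both products retain the exchange sites, so the operation is
#' reversible.
#'
#' @param assembled Assembled integration vector (TU section to move).
#' @param empty Empty vector donating backbone and homology arms.
#' @param syntax Syntax config.
#' @return List with `product`, `reciprocal`, `warnings`.
#' @export
exchange_has <- function(assembled, empty, syntax = default_syntax()) {
  for (m in list(assembled, empty)) {
    k <- count_exchange_sites(m, syntax)
    if (k != 2L) {
      pf_stop(sprintf("'%s' carries %d %s sites; exactly 2 required", m$id, k,
                      syntax$enzymes$exchange$name), "pf_validation")
    }
  }
  enz <- syntax$enzymes$exchange
  frags <- c(digest(assembled, enz), digest(empty, enz))
  # exchanging a vector with itself duplicates fragments; drop exact
  # duplicates so the (non-enumerated-by-design) dimer does not appear
  key <- vapply(frags, function(f) paste(f$left_ov, f$seq, f$right_ov),
                character(1))
  frags <- frags[!duplicated(key)]
  circles <- ligate_cyclic(frags)
  res_e <- resistance_label(empty)
  has_gfp <- function(p) "sfGFP" %in% feature_labels(p, "reporter")
  desired <- Filter(function(p) identical(resistance_label(p), res_e) &&
                      !has_gfp(p), circles)
  recip <- Filter(function(p) identical(resistance_label(p),
                                        resistance_label(assembled)) &&
                    has_gfp(p), circles)
  warnings <- character()
  if (!length(desired)) {
    assembly_fail("no exchange product passes the resistance + GFP-dropout screen",
                  structure(list(products = circles, warnings = character()),
                            class = "gg_report"))
  }
  # self-exchange (or marker-free empties) can make the screen degenerate;
  # prefer the circle differing from both inputs, else the input itself
  not_input <- Filter(function(p) !molecules_equal(p, assembled) &&
                        !molecules_equal(p, empty), desired)
  product <- if (length(not_input)) not_input[[1L]] else desired[[1L]]
  if (length(desired) > 1L) {
    warnings <- c(warnings, sprintf("%d circles passed the screen; reporting the first non-parental",
                                    length(desired)))
  }
  insert <- sub("^[^-]*-", "", assembled$id)
  base <- sub("[0-9]\\.[0-9]$", "", empty$id)
  product$id <- paste0(base, "-", insert)
  reciprocal <- if (length(recip)) {
    r <- recip[[1L]]
    r$id <- paste0(assembled$id, "_backbone+", empty$id, "_central")
    r
  } else NULL
  pf_log(sprintf("HA exchange: selected %s by %s resistance and sfGFP dropout",
                 product$id, res_e))
  list(product = product, reciprocal = reciprocal, warnings = warnings)
}

#' Transfer a TU section irreversibly into an assembled disruption vector
#'
#' The marker on the disruption-vector series is flanked by exchange-enzyme
#' sites pointing inwards, so a Golden Gate reaction with an assembled
#' integration vector drops that marker and installs the TU section between
#' the deletion-locus homology arms. Because neither retained half carries
#' an exchange site, the product is stable and the transfer irreversible.
#'
#' @param assembled Assembled integration vector (TU section donor).
#' @param pdel_assembled Assembled disruption vector (arm donor).
#' @param syntax Syntax config.
#' @return The `dna_molecule` named `<pdel>::<insert>`.
#' @export
transfer_to_del <- function(assembled, pdel_assembled,
                            syntax = default_syntax()) {
  for (m in list(assembled, pdel_assembled)) {
    k <- count_exchange_sites(m, syntax)
    if (k != 2L) {
      pf_stop(sprintf("'%s' carries %d %s sites; exactly 2 required", m$id, k,
                      syntax$enzymes$exchange$name), "pf_validation")
    }
  }
  mk <- pdel_assembled$features[pdel_assembled$features$key == "marker", ,
                                drop = FALSE]
  if (!nrow(mk)) {
    pf_stop("disruption vector lacks the exchange-flanked marker cassette",
            "pf_validation")
  }
  rep <- golden_gate(list(assembled, pdel_assembled), syntax$enzymes$exchange)
  prod <- single_stable(rep, "TU transfer into disruption vector")
  if (length(feature_labels(prod, "HA")) < 2L) {
    assembly_fail("transfer product lost the deletion-locus arms", rep)
  }
  insert <- sub("^[^-]*-", "", assembled$id)
  prod$id <- paste0(pdel_assembled$id, "::", insert)
  pf_log(sprintf("irreversible transfer: %s", prod$id))
  prod
}
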