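# Sequence-level simulation of the two E. coli assembly hosts: Cre-mediated
# marker excision (lox66 x lox71 -> lox72) and lambda-Red single-oligo
# recombineering against a counter-selectable cassette.

#' Cre-lox site configuration
#'
#' The four 34-nt sites share the central 8-nt asymmetric spacer that defines
#' site directionality; lox66 carries the mutant right arm, lox71 the mutant
#' left arm, and recombination between them leaves the double-mutant lox72
#' (poorly re-recombinable, hence effectively irreversible excision) on one
#' product and a wild-type loxP on the other. Defaults are the standard
#' literature sequences; all overridable.
#'
#' @param lox66_seq,lox71_seq,lox72_seq,loxP_seq 34-nt site sequences.
#' @param retained_hybrid Which hybrid the retained (origin-carrying) product
#'   is expected to carry; a warning is emitted if the arm arrangement of the
#'   substrate yields the other hybrid.
#' @return A `lox_config` object.
#' @export
lox_config <- function(lox66_seq = "ATAACTTCGTATAATGTATGCTATACGAACGGTA",
                       lox71_seq = "TACCGTTCGTATAATGTATGCTATACGAAGTTAT",
                       lox72_seq = "TACCGTTCGTATAATGTATGCTATACGAACGGTA",
                       loxP_seq  = "ATAACTTCGTATAATGTATGCTATACGAAGTTAT",
                       retained_hybrid = "lox72") {
  sites <- c(lox66 = lox66_seq, lox71 = lox71_seq, lox72 = lox72_seq,
             loxP = loxP_seq)
  if (any(nchar(sites) != 34L)) {
    pf_stop("lox sites must be 34 nt (13-nt arms around an 8-nt spacer)",
            "pf_invalid_lox")
  }
  spacers <- substr(sites, 14L, 21L)
  if (length(unique(spacers)) != 1L) {
    pf_stop("all four lox sites must share the same 8-nt spacer",
            "pf_invalid_lox")
  }
  structure(list(lox66_seq = toupper(lox66_seq), lox71_seq = toupper(lox71_seq),
                 lox72_seq = toupper(lox72_seq), loxP_seq = toupper(loxP_seq),
                 retained_hybrid = retained_hybrid),
            class = "lox_config")
}

lox_arms <- function(site) {
  list(left = substr(site, 1L, 13L), spacer = substr(site, 14L, 21L),
       right = substr(site, 22L, 34L))
}

# Locate one lox site type on a circular molecule (both strands).
find_lox <- function(molecule, site_seq) {
  find_sites(molecule, site_seq)
}

#' Cre-mediated excision of a lox-flanked segment
#'
#' Models the Cre-expressing assembly host: a circular molecule carrying
#' exactly one lox66 and one lox71 in direct orientation resolves into two
#' circles. The circle carrying the replication origin / bacterial resistance
#' is `retained` (the marker-free construct); the lox-flanked segment
#' (normally the yeast marker) leaves on the `excised` circle. Each product
#' carries one hybrid site built from the arms that flank it — with the
#' standard lox71 ... marker ... lox66 arrangement the retained circle gets
#' the inert double-mutant lox72. Recombination is conservative:
#' `length(retained) + length(excised) == length(input)`.
#'
#' @param molecule Circular `dna_molecule`.
#' @param lox A `lox_config`.
#' @return A `cre_report`: list with `retained`, `excised`, `retained_site`,
#'   `excised_site`.
#' @export
cre_excise <- function(molecule, lox = lox_config()) {
  stopifnot(inherits(molecule, "dna_molecule"), inherits(lox, "lox_config"))
  if (molecule$topology != "circular") {
    pf_stop("Cre excision is modeled on circular substrates only",
            "pf_no_substrate")
  }
  h66 <- find_lox(molecule, lox$lox66_seq)
  h71 <- find_lox(molecule, lox$lox71_seq)
  if (nrow(h66) == 0L || nrow(h71) == 0L) {
    pf_stop(sprintf("no substrate: molecule '%s' lacks a lox66/lox71 pair",
                    molecule$id), "pf_no_substrate")
  }
  if (nrow(h66) > 1L || nrow(h71) > 1L) {
    pf_stop(sprintf("ambiguous substrate: molecule '%s' carries %d lox66 and %d lox71 sites",
                    molecule$id, nrow(h66), nrow(h71)), "pf_ambiguous")
  }
  if (h66$strand != h71$strand) {
    pf_stop("lox66 and lox71 are inverted relative to each other: inversion not modeled",
            "pf_inversion")
  }
  work <- molecule
  if (h66$strand == "-") {
    # normalise to direct repeats on the plus strand
    work <- dna_molecule(molecule$id, revcomp(molecule$seq), "circular")
    work$features <- flip_features(molecule$features, seq_length(molecule))
    h66 <- find_lox(work, lox$lox66_seq)
    h71 <- find_lox(work, lox$lox71_seq)
  }
  n <- seq_length(work)
  # order the two sites along the circle; segment A = between site1 end and
  # site2 start, segment B = the complementary arc
  p1 <- h71$position   # by convention consider lox71 the upstream site
  p2 <- h66$position
  segA_start <- (p1 + 34L) %% n
  segA_len <- (p2 - segA_start) %% n
  segB_start <- (p2 + 34L) %% n
  segB_len <- (p1 - segB_start) %% n
  segA <- circ_substr(work$seq, segA_start, segA_len)  # lox71 -> lox66 arc
  segB <- circ_substr(work$seq, segB_start, segB_len)  # lox66 -> lox71 arc
  a71 <- lox_arms(lox$lox71_seq)
  a66 <- lox_arms(lox$lox66_seq)
  # crossover in the spacer: the circle containing segB (downstream of lox66)
  # is closed by left(lox71) + spacer + right(lox66); the segA circle by
  # left(lox66) + spacer + right(lox71)
  hybrid_B <- paste0(a71$left, a71$spacer, a66$right)
  hybrid_A <- paste0(a66$left, a66$spacer, a71$right)
  circB <- dna_molecule(paste0(molecule$id, "_B"), paste0(hybrid_B, segB),
                        "circular",
                        shift_features(extract_segment_features(work, segB_start, segB_len),
                                       34L, nchar(segB) + 34L))
  circA <- dna_molecule(paste0(molecule$id, "_A"), paste0(hybrid_A, segA),
                        "circular",
                        shift_features(extract_segment_features(work, segA_start, segA_len),
                                       34L, nchar(segA) + 34L))
  circB <- add_lox_feature(circB, hybrid_B, lox)
  circA <- add_lox_feature(circA, hybrid_A, lox)
  # the retained product is the one with the replication origin / resistance
  has_backbone <- function(m) any(m$features$key %in% c("origin", "resistance"))
  if (has_backbone(circB) && !has_backbone(circA)) {
    retained <- circB; excised <- circA
  } else if (has_backbone(circA) && !has_backbone(circB)) {
    retained <- circA; excised <- circB
  } else {
    # fall back: the larger circle is retained
    if (seq_length(circB) >= seq_length(circA)) {
      retained <- circB; excised <- circA
    } else {
      retained <- circA; excised <- circB
    }
  }
  retained$id <- paste0(molecule$id, "_MF")   # marker-free
  excised$id <- paste0(molecule$id, "_excised")
  ret_site <- site_name(feature_label_site(retained), lox)
  exc_site <- site_name(feature_label_site(excised), lox)
  if (!identical(ret_site, lox$retained_hybrid)) {
    warning(sprintf("retained product carries %s, not the configured %s; check lox arm arrangement",
                    ret_site, lox$retained_hybrid), call. = FALSE)
  }
  structure(list(retained = retained, excised = excised,
                 retained_site = ret_site, excised_site = exc_site),
            class = "cre_report")
}

flip_features <- function(features, n) {
  if (!nrow(features)) return(features)
  st <- (n - features$end %% n) %% n
  width <- features$end - features$start
  features$start <- as.integer(st)
  features$end <- as.integer(st + width)
  features$strand <- ifelse(features$strand == "+", "-", "+")
  features
}

shift_features <- function(features, offset, total_len) {
  if (!nrow(features)) return(features)
  width <- features$end - features$start
  features$start <- as.integer((features$start + offset) %% total_len)
  features$end <- features$start + width
  features
}

add_lox_feature <- function(m, hybrid, lox) {
  lab <- site_name(hybrid, lox)
  m$features <- rbind(m$features, feature("lox_site", lab, 0L, 34L, "+"))
  m
}

site_name <- function(seq_or_label, lox) {
  nm <- c(lox66 = lox$lox66_seq, lox71 = lox$lox71_seq,
          lox72 = lox$lox72_seq, loxP = lox$loxP_seq)
  hit <- names(nm)[nm == seq_or_label]
  if (length(hit)) return(hit[1L])
  if (seq_or_label %in% names(nm)) return(seq_or_label)
  "lox_hybrid"
}

feature_label_site <- function(m) {
  i <- which(m$features$key == "lox_site" & m$features$start == 0L)
  if (length(i)) m$features$label[i[1L]] else circ_substr(m$seq, 0L, 34L)
}

#' @export
print.cre_report <- function(x, ...) {
  cat(sprintf("<cre_report> retained %s (%d bp, %s), excised %s (%d bp, %s)\n",
              x$retained$id, seq_length(x$retained), x$retained_site,
              x$excised$id, seq_length(x$excised), x$excised_site))
  invisible(x)
}

#' Assemble marker-based and marker-free versions in parallel
#'
#' Emulates transforming one Golden Gate reaction into both a standard host
#' and the Cre-expressing host: runs the assembly once, then excises the
#' lox-flanked marker from the product. If the product's marker lacks lox
#' flanks the marker-free version is absent, with a warning.
#'
#' @param gg_inputs List of `dna_molecule`s for the assembly.
#' @param enz Enzyme for the Golden Gate step.
#' @param lox A `lox_config`.
#' @return List with `marker_based` and `marker_free` (the latter `NULL` when
#'   no lox pair is present).
#' @export
marker_free_pair <- function(gg_inputs, enz, lox = lox_config()) {
  rep <- golden_gate(gg_inputs, enz)
  if (length(rep$products) != 1L) {
    pf_stop(sprintf("expected exactly 1 stable assembly product, got %d (%s)",
                    length(rep$products),
                    paste(rep$warnings, collapse = "; ")), "pf_assembly_error")
  }
  product <- rep$products[[1L]]
  marker_free <- tryCatch(cre_excise(product, lox)$retained,
                          pf_no_substrate = function(e) {
                            warning("assembly product has no lox-flanked marker; marker-free version not produced",
                                    call. = FALSE)
                            NULL
                          })
  list(marker_based = product, marker_free = marker_free)
}

# ---------------------------------------------------------------------------
# lambda-Red single-oligo recombineering

#' Build an Oligo90 object
#'
#' A 90-base recombineering oligonucleotide: 35-nt left homology, 20-nt
#' payload (the new CRISPR spacer) centered, 35-nt right homology.
#' @param seq 90-nt sequence, or use `left`/`spacer`/`right`.
#' @param left,spacer,right Alternative piecewise construction.
#' @return An `oligo90` object.
#' @export
oligo90 <- function(seq = NULL, left = NULL, spacer = NULL, right = NULL) {
  if (is.null(seq)) seq <- paste0(left, spacer, right)
  seq <- toupper(seq)
  if (nchar(seq) != 90L) {
    pf_stop(sprintf("recombineering oligo must be 90 nt, got %d", nchar(seq)),
            "pf_invalid_oligo")
  }
  structure(list(seq = seq,
                 left_homology = substr(seq, 1L, 35L),
                 spacer = substr(seq, 36L, 55L),
                 right_homology = substr(seq, 56L, 90L)),
            class = "oligo90")
}

#' @export
print.oligo90 <- function(x, ...) {
  cat(sprintf("<oligo90> %s | %s | %s\n", x$left_homology, x$spacer,
              x$right_homology))
  invisible(x)
}

match_unique <- function(molecule, pattern, what) {
  hits <- find_sites(molecule, pattern)
  if (nrow(hits) == 0L) {
    pf_stop(sprintf("no target: %s not found on '%s'", what, molecule$id),
            "pf_no_target")
  }
  if (nrow(hits) > 1L) {
    pf_stop(sprintf("ambiguous target: %s matches %d times on '%s'",
                    what, nrow(hits), molecule$id), "pf_ambiguous")
  }
  hits
}

#' lambda-Red replacement of a helper segment by a single 90-mer
#'
#' Models recombineering in the lambda-Red host: the oligo's two 35-nt
#' homologies must each match the circular helper exactly once; the helper
#' segment between the matches (the counter-selectable cassette on an empty
#' Cas9 helper) is replaced by the oligo's central 20-nt spacer. Homology
#' matching is exact by default; either oligo orientation is accepted (strand
#' preference affects recombineering efficiency, not product sequence).
#' Nothing outside the homology span is altered.
#'
#' @param helper Circular `dna_molecule`.
#' @param oligo An `oligo90` (or 90-nt character string).
#' @return The recombined `dna_molecule`.
#' @export
lambda_red_replace <- function(helper, oligo) {
  stopifnot(inherits(helper, "dna_molecule"))
  if (is.character(oligo)) oligo <- oligo90(oligo)
  stopifnot(inherits(oligo, "oligo90"))
  if (helper$topology != "circular") {
    pf_stop("recombineering substrate must be circular", "pf_no_target")
  }
  hl <- match_unique(helper, oligo$left_homology, "left homology")
  hr <- match_unique(helper, oligo$right_homology, "right homology")
  if (hl$strand != hr$strand) {
    pf_stop("oligo homologies anneal on opposite strands: inconsistent orientation",
            "pf_orientation")
  }
  if (hl$strand == "-") {
    return(lambda_red_replace(helper, oligo90(revcomp(oligo$seq))))
  }
  n <- seq_length(helper)
  left_end <- (hl$position + 35L) %% n
  right_start <- hr$position
  gap <- (right_start - left_end) %% n
  # the replaced arc must be the minor arc; replacing the arc that carries
  # the rest of the plasmid means the homologies are in the wrong order
  if (gap > n - 70L - gap) {
    pf_stop("homologies in inconsistent order on the helper", "pf_orientation")
  }
  # rotate so the left homology starts at 0; edit never touches the rest
  rot <- rotate_molecule(helper, hl$position)
  keep_tail <- substr(rot$seq, 35L + gap + 1L, n)
  new_seq <- paste0(substr(rot$seq, 1L, 35L), oligo$spacer, keep_tail)
  feats <- extract_segment_features(rot, 35L + gap, n - 35L - gap)
  feats <- shift_features(feats, 55L, nchar(new_seq))
  lead <- extract_segment_features(rot, 0L, 35L)
  feats <- rbind(lead, feats,
                 feature("sgRNA_cassette", "spacer", 35L, 55L, "+"))
  out <- dna_molecule(paste0(helper$id, "_recombined"), new_seq, "circular",
                      feats)
  out
}

#' Is a molecule free of the counter-selection cassette?
#'
#' TRUE iff no rpsL-kanR cassette remains — feature-wise (any feature whose
#' label mentions rpsL) and, when `cassette_seq` is supplied, sequence-wise.
#' Desired recombinants satisfy this (streptomycin selection survives only
#' when the wild-type rpsL copy is gone).
#'
#' @param molecule A `dna_molecule`.
#' @param cassette_seq Optional cassette sequence to scan for.
#' @return Logical scalar.
#' @export
counterselect_check <- function(molecule, cassette_seq = NULL) {
  stopifnot(inherits(molecule, "dna_molecule"))
  if (any(grepl("rpsL", molecule$features$label, ignore.case = TRUE))) {
    return(FALSE)
  }
  if (!is.null(cassette_seq) && nrow(find_sites(molecule, cassette_seq)) > 0L) {
    return(FALSE)
  }
  TRUE
}
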