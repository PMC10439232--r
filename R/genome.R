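# Homology-arm design from a genome and simulation of HR-mediated
# integration and disruption. HR is modeled as exact, unique, double-
# crossover replacement: arms are matched with zero mismatches, uniqueness
# is enforced genome-wide, and nothing outside the edited interval changes.

as_genome_list <- function(genome) {
  if (inherits(genome, "dna_molecule")) list(genome) else genome
}

genome_by_id <- function(genome, id) {
  mols <- as_genome_list(genome)
  ids <- vapply(mols, function(m) m$id, character(1))
  i <- which(ids == id)
  if (!length(i)) {
    pf_stop(sprintf("chromosome '%s' not present in genome", id), "pf_no_target")
  }
  mols[[i[1L]]]
}

#' Design homology arms flanking a genome locus
#'
#' Returns the `arm_len` bases immediately flanking the locus: for an
#' intergenic insertion point (zero-length interval) the two arms are
#' adjacent on the chromosome; for a disruption target they flank the
#' interval to be removed.
#'
#' @param genome A `dna_molecule` or list of chromosomes.
#' @param locus List or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open; `start == end` for pure insertion).
#' @param arm_len Arm length in bp (default 500).
#' @return List with `left_arm`, `right_arm` (plus-strand sequences).
#' @export
design_has <- function(genome, locus, arm_len = 500L) {
  arm_len <- as.integer(arm_len)
  if (arm_len < 1L) {
    pf_stop("arm_len must be >= 1", "pf_validation")
  }
  chrom <- genome_by_id(genome, locus$chrom)
  n <- seq_length(chrom)
  start <- as.integer(locus$start)
  end <- as.integer(locus$end)
  stopifnot(start <= end)
  if (start - arm_len < 0L || end + arm_len > n) {
    pf_stop(sprintf("locus %s is closer than %d bp to a chromosome end",
                    locus$name %||% "", arm_len), "pf_validation")
  }
  list(left_arm = substr(chrom$seq, start - arm_len + 1L, start),
       right_arm = substr(chrom$seq, end + 1L, end + arm_len))
}

#' Extract an integration donor from an assembled vector
#'
#' The donor is everything between the outer edges of the two annotated
#' homology arms: left arm, cassette (marker and/or TUs), right arm.
#'
#' @param vector Assembled integration vector with two `HA` features.
#' @return A `donor` list: `left_arm`, `right_arm`, `cassette` (sequence),
#'   `cassette_features`, `marker_present`.
#' @export
donor_from_vector <- function(vector) {
  ha <- vector$features[vector$features$key == "HA", , drop = FALSE]
  if (nrow(ha) != 2L) {
    pf_stop(sprintf("vector '%s' must carry exactly 2 homology-arm features, found %d",
                    vector$id, nrow(ha)), "pf_validation")
  }
  ha <- ha[order(ha$start), ]
  n <- seq_length(vector)
  # Of the two arcs between the arms, the cassette is the central section —
  # the one NOT carrying the bacterial backbone (origin/resistance). Which
  # arm comes "first" in plasmid coordinates is a rotation artefact.
  arc <- function(i, j) {        # arc from end of arm i to start of arm j
    s <- ha$end[i] %% n
    len <- (ha$start[j] - s) %% n
    list(start = s, len = len,
         feats = extract_segment_features(vector, s, len))
  }
  a12 <- arc(1L, 2L)
  a21 <- arc(2L, 1L)
  backboneish <- function(a) any(a$feats$key %in% c("origin", "resistance"))
  cass <- if (backboneish(a12) && !backboneish(a21)) a21
          else if (backboneish(a21) && !backboneish(a12)) a12
          else if (a12$len <= a21$len) a12 else a21
  first <- if (identical(cass, a12)) 1L else 2L
  second <- 3L - first
  cassette <- circ_substr(vector$seq, cass$start, cass$len)
  cfeats <- cass$feats
  left_arm <- circ_substr(vector$seq, ha$start[first],
                          ha$end[first] - ha$start[first])
  right_arm <- circ_substr(vector$seq, ha$start[second],
                           ha$end[second] - ha$start[second])
  structure(list(left_arm = left_arm, right_arm = right_arm,
                 cassette = cassette, cassette_features = cfeats,
                 marker_present = "marker" %in% cfeats$key),
            class = "donor")
}

#' Make a donor from raw pieces
#' @param left_arm,right_arm Arm sequences.
#' @param cassette Cassette sequence between the arms (may be `""` for a
#'   scarless deletion donor).
#' @param cassette_features Optional features on the cassette.
#' @export
donor <- function(left_arm, right_arm, cassette = "",
                  cassette_features = empty_features()) {
  structure(list(left_arm = toupper(left_arm), right_arm = toupper(right_arm),
                 cassette = toupper(cassette),
                 cassette_features = cassette_features,
                 marker_present = "marker" %in% cassette_features$key),
            class = "donor")
}

#' @export
print.donor <- function(x, ...) {
  cat(sprintf("<donor> arms %d/%d bp, cassette %d bp, marker %s\n",
              nchar(x$left_arm), nchar(x$right_arm), nchar(x$cassette),
              if (x$marker_present) "present" else "absent"))
  invisible(x)
}

locate_arm <- function(chromosomes, arm, what) {
  hits <- NULL
  for (m in chromosomes) {
    h <- find_sites(m, arm)
    if (nrow(h)) hits <- rbind(hits, cbind(h, chrom = m$id))
  }
  if (is.null(hits) || nrow(hits) == 0L) {
    pf_stop(sprintf("%s not found in genome", what), "pf_no_target")
  }
  if (nrow(hits) > 1L) {
    pf_stop(sprintf("%s matches the genome %d times; arms must be unique",
                    what, nrow(hits)), "pf_ambiguous")
  }
  hits
}

#' Simulate homologous-recombination integration of a donor
#'
#' Both arms must match the genome exactly once, on the same strand, in
#' order. The genomic span between the arms' inner edges is replaced by the
#' donor cassette: a pure insertion when the arms are adjacent (intergenic
#' integration), a replacement/disruption otherwise. Edited length =
#' original - deleted + cassette; nothing outside the edited interval is
#' touched.
#'
#' @param genome A `dna_molecule` or list of chromosomes.
#' @param don A `donor` (or an assembled vector, converted via
#'   [donor_from_vector()]).
#' @return The edited genome (same shape as the input: molecule or list).
#' @export
simulate_integration <- function(genome, don) {
  if (inherits(don, "dna_molecule")) don <- donor_from_vector(don)
  stopifnot(inherits(don, "donor"))
  mols <- as_genome_list(genome)
  hl <- locate_arm(mols, don$left_arm, "left arm")
  hr <- locate_arm(mols, don$right_arm, "right arm")
  if (hl$chrom != hr$chrom) {
    pf_stop("arms match different chromosomes", "pf_orientation")
  }
  if (hl$strand != hr$strand) {
    pf_stop("arms are inverted relative to each other", "pf_orientation")
  }
  if (hl$strand == "-") {
    # donor anneals in the opposite orientation; flip it and recurse
    flipped <- donor(revcomp(don$right_arm), revcomp(don$left_arm),
                     revcomp(don$cassette),
                     flip_features(don$cassette_features, nchar(don$cassette)))
    return(simulate_integration(genome, flipped))
  }
  chrom <- genome_by_id(mols, hl$chrom)
  n <- seq_length(chrom)
  left_inner <- hl$position + nchar(don$left_arm)
  right_inner <- hr$position
  if (right_inner < left_inner) {
    pf_stop("arms are in the wrong order on the chromosome", "pf_orientation")
  }
  deleted <- right_inner - left_inner
  new_seq <- paste0(substr(chrom$seq, 1L, left_inner), don$cassette,
                    substr(chrom$seq, right_inner + 1L, n))
  shift <- nchar(don$cassette) - deleted
  keep <- chrom$features[chrom$features$end <= left_inner |
                           chrom$features$start >= right_inner, , drop = FALSE]
  moved <- keep$start >= right_inner
  keep$start[moved] <- keep$start[moved] + shift
  keep$end[moved] <- keep$end[moved] + shift
  cf <- don$cassette_features
  if (nrow(cf)) {
    cf$start <- cf$start + left_inner
    cf$end <- cf$end + left_inner
  }
  edited <- dna_molecule(chrom$id, new_seq, "linear", rbind(keep, cf))
  pf_log(sprintf("integrated %d-bp cassette at %s:%d (replaced %d bp)",
                 nchar(don$cassette), chrom$id, left_inner, deleted))
  out <- lapply(mols, function(m) if (m$id == chrom$id) edited else m)
  names(out) <- vapply(mols, function(m) m$id, character(1))
  if (inherits(genome, "dna_molecule")) out[[1L]] else out
}

#' Simulate a gene disruption with an assembled deletion construct
#'
#' As [simulate_integration()], with the target interval being the open
#' reading frame between the construct's arms; the edited genome must no
#' longer carry the target ORF feature.
#'
#' @param genome Genome (molecule or list of chromosomes).
#' @param pdel_construct Assembled disruption vector (or a `donor`).
#' @param target Label of the ORF being removed (checked absent afterwards).
#' @return Edited genome.
#' @export
simulate_disruption <- function(genome, pdel_construct, target = NULL) {
  edited <- simulate_integration(genome, pdel_construct)
  if (!is.null(target)) {
    mols <- as_genome_list(edited)
    still <- any(vapply(mols, function(m)
      target %in% m$features$label[m$features$key == "CDS"], logical(1)))
    if (still) {
      pf_stop(sprintf("disruption failed: ORF '%s' still annotated after editing",
                      target), "pf_validation")
    }
  }
  edited
}

#' Verify integration junctions in an edited genome
#'
#' The in-silico analogue of junction colony PCR: extracts the two
#' arm/cassette junction sequences (k bases each side) and counts their
#' occurrences in the edited genome; each must occur exactly once.
#'
#' @param edited_genome Edited genome (molecule or list).
#' @param don The `donor` that was integrated (or assembled vector).
#' @param k Bases taken from each side of a junction (default 20).
#' @return Data frame with `junction`, `seq`, `count`, `ok`; all-ok iff both
#'   junctions are single-copy.
#' @export
verify_junctions <- function(edited_genome, don, k = 20L) {
  if (inherits(don, "dna_molecule")) don <- donor_from_vector(don)
  mols <- as_genome_list(edited_genome)
  la <- don$left_arm
  ra <- don$right_arm
  if (nchar(don$cassette) >= 2L * k) {
    j1 <- paste0(substr(la, nchar(la) - k + 1L, nchar(la)),
                 substr(don$cassette, 1L, k))
    j2 <- paste0(substr(don$cassette, nchar(don$cassette) - k + 1L,
                        nchar(don$cassette)),
                 substr(ra, 1L, k))
  } else {
    # short or empty cassette: the two junctions collapse into one span
    j1 <- paste0(substr(la, nchar(la) - k + 1L, nchar(la)), don$cassette,
                 substr(ra, 1L, k))
    j2 <- j1
  }
  count_all <- function(s) {
    sum(vapply(mols, function(m) nrow(find_sites(m, s)), integer(1)))
  }
  res <- data.frame(junction = c("left_arm/cassette", "cassette/right_arm"),
                    seq = c(j1, j2),
                    count = c(count_all(j1), count_all(j2)),
                    stringsAsFactors = FALSE)
  res$ok <- res$count == 1L
  res
}
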