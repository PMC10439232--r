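# CRISPR target scanning, cut-site computation, 90-mer oligo design and
# structural verification of the Cas9 helper plasmid.

#' Scan a sequence for Cas9 protospacers
#'
#' All 20-nt spacers adjacent to a PAM (default NGG) on both strands, with
#' the blunt double-strand-break position 3 bp 5' of the PAM (between the
#' 17th and 18th spacer base — canonical SpCas9 geometry). Deterministic
#' order: position, then strand.
#'
#' @param locus A `dna_molecule` or plain character sequence (>= 23 nt for
#'   any hit; fewer yields zero rows).
#' @param pam_pattern PAM in IUPAC code (default `"NGG"`).
#' @param spacer_len Protospacer length (default 20).
#' @return Data frame with `seq` (spacer, 5'->3' on its own strand), `pam`,
#'   `strand`, `start` (0-based plus-strand start of the spacer span) and
#'   `cut_position` (0-based plus-strand coordinate of the blunt cut).
#' @export
scan_protospacers <- function(locus, pam_pattern = "NGG", spacer_len = 20L) {
  m <- if (inherits(locus, "dna_molecule")) locus else
    dna_molecule("locus", locus, "linear")
  n <- seq_length(m)
  plen <- nchar(pam_pattern)
  out <- list()
  pams <- find_sites(m, pam_pattern)
  for (i in seq_len(nrow(pams))) {
    p <- pams$position[i]
    if (pams$strand[i] == "+") {
      s <- p - spacer_len
      if (m$topology == "linear" && s < 0L) next
      s <- ((s %% n) + n) %% n
      spacer <- circ_substr(m$seq, s, spacer_len)
      cut <- ((p - 3L) %% n + n) %% n
      out[[length(out) + 1L]] <- data.frame(
        seq = spacer, pam = circ_substr(m$seq, p, plen), strand = "+",
        start = s, cut_position = cut, stringsAsFactors = FALSE)
    } else {
      s <- p + plen
      if (m$topology == "linear" && s + spacer_len > n) next
      spacer <- revcomp(circ_substr(m$seq, s %% n, spacer_len))
      cut <- (s + 3L) %% n
      out[[length(out) + 1L]] <- data.frame(
        seq = spacer, pam = revcomp(circ_substr(m$seq, p, plen)), strand = "-",
        start = s %% n, cut_position = cut, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(seq = character(), pam = character(),
                      strand = character(), start = integer(),
                      cut_position = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cut a genome at a unique protospacer
#'
#' The spacer+PAM must occur exactly once (on either strand) in the target
#' molecule. A linear molecule is split into two linear products at the blunt
#' cut; a circular molecule is opened into one linear molecule. The cut
#' position is recorded on the result.
#'
#' @param genome A `dna_molecule`, or a list of them (searched jointly; the
#'   target must be unique across the whole set).
#' @param protospacer 20-nt spacer sequence (character) or one row of
#'   [scan_protospacers()] output.
#' @param pam_pattern PAM (default `"NGG"`).
#' @return List with `products` (list of linear `dna_molecule`s),
#'   `molecule_id`, `cut_position`, `strand`.
#' @export
cut_genome <- function(genome, protospacer, pam_pattern = "NGG") {
  if (is.data.frame(protospacer)) protospacer <- protospacer$seq[1L]
  protospacer <- toupper(protospacer)
  mols <- if (inherits(genome, "dna_molecule")) list(genome) else genome
  target <- paste0(protospacer, pam_pattern)
  hits <- list()
  for (m in mols) {
    h <- find_sites(m, target)
    if (nrow(h)) hits[[length(hits) + 1L]] <- cbind(h, id = m$id)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else NULL
  if (is.null(hits) || nrow(hits) == 0L) {
    pf_stop(sprintf("protospacer %s (PAM %s) absent from target", protospacer,
                    pam_pattern), "pf_no_target")
  }
  if (nrow(hits) > 1L) {
    pf_stop(sprintf("protospacer %s matches %d times; target must be unique",
                    protospacer, nrow(hits)), "pf_ambiguous")
  }
  m <- mols[[which(vapply(mols, function(x) x$id, character(1)) == hits$id[1L])]]
  n <- seq_length(m)
  splen <- nchar(protospacer)
  if (hits$strand[1L] == "+") {
    cut <- (hits$position[1L] + splen - 3L) %% n
  } else {
    # on the minus strand the PAM-proximal end faces the plus-strand start
    cut <- (hits$position[1L] + nchar(pam_pattern) + 3L) %% n
  }
  products <- if (m$topology == "circular") {
    list(rotate_to_linear(m, cut))
  } else {
    list(dna_molecule(paste0(m$id, "_left"), substr(m$seq, 1L, cut), "linear",
                      crop_features(m$features, 0L, cut)),
         dna_molecule(paste0(m$id, "_right"), substr(m$seq, cut + 1L, n),
                      "linear", crop_features(m$features, cut, n)))
  }
  list(products = products, molecule_id = m$id, cut_position = cut,
       strand = hits$strand[1L])
}

rotate_to_linear <- function(m, cut) {
  r <- rotate_molecule(m, cut)
  out <- dna_molecule(paste0(m$id, "_linearised"), r$seq, "linear",
                      r$features[r$features$end <= seq_length(m), , drop = FALSE])
  out
}

crop_features <- function(features, lo, hi) {
  f <- features[features$start >= lo & features$end <= hi, , drop = FALSE]
  f$start <- f$start - lo
  f$end <- f$end - lo
  f
}

# locate the spacer slot on a helper: the counter-select cassette on an
# empty helper, or the current 20-nt spacer on an already-recoded one
helper_slot <- function(helper) {
  i <- which(helper$features$key == "sgRNA_cassette" &
               grepl("rpsL|^spacer$", helper$features$label,
                     ignore.case = TRUE))
  if (!length(i)) {
    pf_stop(sprintf("helper '%s' has no cassette or spacer in the spacer slot",
                    helper$id), "pf_no_target")
  }
  helper$features[i[1L], ]
}

#' Design the 90-base re-encoding oligo for a spacer
#'
#' The oligo is the 35 nt of helper sequence immediately upstream of the
#' counter-selectable cassette, the 20-nt spacer, and the 35 nt immediately
#' downstream: recombineering with it ([lambda_red_replace()]) swaps the
#' cassette for exactly the spacer. Both flanks must be unique on the
#' helper.
#'
#' @param spacer 20-nt spacer sequence (e.g. from [scan_protospacers()]).
#' @param helper The empty Cas9 helper (`dna_molecule` with an annotated
#'   rpsL-kanR spacer slot).
#' @param homology Flank length (default 35; the oligo is
#'   `2 * homology + 20` nt — 90 with defaults).
#' @return An [oligo90()] object.
#' @export
design_oligo <- function(spacer, helper, homology = 35L) {
  if (is.data.frame(spacer)) spacer <- spacer$seq[1L]
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L) {
    pf_stop(sprintf("spacer must be 20 nt, got %d", nchar(spacer)),
            "pf_invalid_oligo")
  }
  slot <- helper_slot(helper)
  n <- seq_length(helper)
  left <- circ_substr(helper$seq, (slot$start - homology) %% n, homology)
  right <- circ_substr(helper$seq, slot$end %% n, homology)
  for (fl in c(left, right)) {
    if (nrow(find_sites(helper, fl)) != 1L) {
      pf_stop("oligo homology flank is not unique on the helper", "pf_ambiguous")
    }
  }
  oligo90(left = left, spacer = spacer, right = right)
}

#' Verify the structure of a Cas9 helper plasmid
#'
#' Annotation-level checks of the helper architecture: the guide-RNA
#' cassette elements in order (RNA-Pol-III hybrid promoter, spacer slot,
#' tracrRNA, poly-T terminator) with the spacer slot directly abutting the
#' promoter (no residual 5' linker), a Cas9 CDS annotated with its
#' C-terminal SV40 nuclear localisation signal, the nourseothricin
#' selectable marker, and a replication origin (ARS). Each missing or
#' misordered element is reported individually.
#'
#' @param molecule Annotated helper `dna_molecule`.
#' @return A `helper_model` list: `ok`, `errors` (character), `elements`
#'   (data frame of the located cassette elements), `counter_select`
#'   (is the rpsL-kanR cassette still in the slot?).
#' @export
verify_helper <- function(molecule) {
  stopifnot(inherits(molecule, "dna_molecule"))
  errors <- character()
  f <- molecule$features
  find1 <- function(key, pattern) {
    i <- which(f$key == key & grepl(pattern, f$label, ignore.case = TRUE))
    if (length(i)) f[i[1L], ] else NULL
  }
  pol3 <- find1("promoter", "SCR1|tRNA")
  slot <- {
    i <- which(f$key == "sgRNA_cassette" & grepl("rpsL|spacer", f$label,
                                                 ignore.case = TRUE))
    if (length(i)) f[i[1L], ] else NULL
  }
  tracr <- find1("sgRNA_cassette", "tracr")
  polyt <- find1("terminator", "polyT")
  cas9 <- find1("CDS", "Cas9")
  nat <- find1("marker", "Nat|nourseo")
  ars <- find1("origin", "ARS")
  for (el in list(list(pol3, "RNA-Pol-III hybrid promoter (SCR1'-tRNA)"),
                  list(slot, "spacer slot"),
                  list(tracr, "tracrRNA"),
                  list(polyt, "poly-T terminator"),
                  list(cas9, "Cas9 cassette"),
                  list(nat, "nourseothricin marker"),
                  list(ars, "ARS (replication origin)"))) {
    if (is.null(el[[1L]])) errors <- c(errors, paste0("missing ", el[[2L]]))
  }
  if (!is.null(cas9) && !grepl("SV40", cas9$label)) {
    errors <- c(errors, "Cas9 lacks the C-terminal SV40 NLS annotation")
  }
  elements <- do.call(rbind, Filter(Negate(is.null),
                                    list(pol3, slot, tracr, polyt)))
  if (!is.null(pol3) && !is.null(slot) && !is.null(tracr) && !is.null(polyt)) {
    n <- seq_length(molecule)
    rel <- function(x) ((x - pol3$start) %% n)
    ord <- c(rel(slot$start), rel(tracr$start), rel(polyt$start))
    if (is.unsorted(ord)) {
      errors <- c(errors, "guide-RNA cassette elements are out of order")
    }
    if (rel(slot$start) != rel(pol3$end) %% n) {
      errors <- c(errors,
                  "spacer slot does not directly abut the promoter (5' linker present)")
    }
    if (!is.null(tracr) && (slot$end %% n) != tracr$start) {
      errors <- c(errors, "tracrRNA does not directly follow the spacer slot")
    }
  }
  structure(list(ok = length(errors) == 0L, errors = errors,
                 elements = elements,
                 counter_select = !counterselect_check(molecule)),
            class = "helper_model")
}

#' @export
print.helper_model <- function(x, ...) {
  cat(sprintf("<helper_model> %s; counter-select cassette %s\n",
              if (x$ok) "structure OK" else paste(length(x$errors), "error(s)"),
              if (x$counter_select) "present" else "absent"))
  for (e in x$errors) cat("  error: ", e, "\n", sep = "")
  invisible(x)
}
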