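# Sequence data model: annotated DNA molecules with linear or circular
# topology, 0-based half-open feature intervals, and circular-aware search
# and comparison.

FEATURE_VOCAB <- c("promoter", "CDS", "terminator", "marker", "HA",
                   "lox_site", "overhang_junction", "reporter", "origin",
                   "resistance", "sgRNA_cassette", "misc")

#' Create an annotated DNA molecule
#'
#' The universal currency of every operation in the package: an identifier, a
#' DNA sequence over `{A,C,G,T,N}`, a topology, and a feature table.
#' Coordinates are 0-based half-open throughout; on circular molecules a
#' feature may span the origin, in which case its `end` exceeds the molecule
#' length and is understood modulo the length.
#'
#' @param id Molecule identifier (scalar character).
#' @param seq DNA sequence, any case; stored uppercase.
#' @param topology `"circular"` or `"linear"`.
#' @param features A data frame with columns `key`, `label`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`). `key` must come from the controlled vocabulary
#'   (`promoter`, `CDS`, `terminator`, `marker`, `HA`, `lox_site`,
#'   `overhang_junction`, `reporter`, `origin`, `resistance`,
#'   `sgRNA_cassette`) or be `"misc"`.
#' @return An object of class `dna_molecule`.
#' @examples
#' m <- dna_molecule("toy", "ACGTACGT", "circular")
#' seq_length(m)
#' @export
dna_molecule <- function(id, seq, topology = c("circular", "linear"),
                         features = empty_features()) {
  topology <- match.arg(topology)
  stopifnot(is_scalar_string(id), is_scalar_string(seq))
  seq <- toupper(seq)
  if (nchar(seq) == 0L) {
    pf_stop("molecule sequence must be non-empty", "pf_invalid_molecule")
  }
  if (grepl("[^ACGTN]", seq)) {
    pf_stop(sprintf("molecule '%s' contains characters outside {A,C,G,T,N}", id),
            "pf_invalid_molecule")
  }
  m <- structure(list(id = id, seq = seq, topology = topology,
                      features = empty_features()),
                 class = "dna_molecule")
  m <- set_features(m, features)
  m
}

#' @export
print.dna_molecule <- function(x, ...) {
  cat(sprintf("<dna_molecule> %s: %d bp, %s, %d feature(s)\n",
              x$id, nchar(x$seq), x$topology, nrow(x$features)))
  invisible(x)
}

#' @rdname dna_molecule
#' @param m A `dna_molecule`.
#' @export
seq_length <- function(m) nchar(m$seq)

#' An empty feature table
#' @return Zero-row data frame with the feature columns.
#' @export
empty_features <- function() {
  data.frame(key = character(), label = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Build one feature row
#' @inheritParams dna_molecule
#' @param key,label,start,end,strand Feature fields; coordinates 0-based
#'   half-open on the plus strand.
#' @export
feature <- function(key, label, start, end, strand = "+") {
  data.frame(key = key, label = label, start = as.integer(start),
             end = as.integer(end), strand = strand, stringsAsFactors = FALSE)
}

# Validate and attach a feature table; enforces the interval invariants.
set_features <- function(m, features) {
  if (is.null(features) || nrow(features) == 0L) {
    m$features <- empty_features()
    return(m)
  }
  need <- c("key", "label", "start", "end", "strand")
  if (!all(need %in% names(features))) {
    pf_stop("feature table must have columns key, label, start, end, strand",
            "pf_invalid_feature")
  }
  features <- features[, need]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  n <- seq_length(m)
  bad_key <- !(features$key %in% FEATURE_VOCAB)
  if (any(bad_key)) {
    pf_stop(sprintf("feature key(s) outside controlled vocabulary: %s",
                    paste(unique(features$key[bad_key]), collapse = ", ")),
            "pf_invalid_feature")
  }
  if (any(!nzchar(features$label))) {
    pf_stop("feature labels must be non-empty", "pf_invalid_feature")
  }
  if (any(features$start < 0L | features$start >= n)) {
    pf_stop("feature start must lie in [0, length)", "pf_invalid_feature")
  }
  if (any(features$end <= features$start)) {
    pf_stop("feature intervals must have length >= 1", "pf_invalid_feature")
  }
  wraps <- features$end > n
  if (m$topology == "linear" && any(wraps)) {
    pf_stop("origin-spanning features are only valid on circular molecules",
            "pf_invalid_feature")
  }
  if (any(features$end > 2L * n)) {
    pf_stop("feature end exceeds one full wrap of the molecule",
            "pf_invalid_feature")
  }
  if (!all(features$strand %in% c("+", "-"))) {
    pf_stop("feature strand must be '+' or '-'", "pf_invalid_feature")
  }
  rownames(features) <- NULL
  m$features <- features
  m
}

#' Extract the sequence under a feature (circular-aware)
#' @param m A `dna_molecule`.
#' @param label Feature label to look up (exact match; first hit used).
#' @return Character sequence on the feature's own strand.
#' @export
feature_seq <- function(m, label) {
  i <- which(m$features$label == label)
  if (length(i) == 0L) {
    pf_stop(sprintf("no feature labelled '%s' on molecule '%s'", label, m$id),
            "pf_missing_feature")
  }
  f <- m$features[i[1L], ]
  s <- circ_substr(m$seq, f$start, f$end - f$start)
  if (f$strand == "-") revcomp(s) else s
}

#' Search a molecule for an IUPAC pattern on both strands
#'
#' Finds all occurrences of `pattern` (IUPAC ambiguity codes allowed, e.g.
#' `"GGTCTC"`, `"NGG"`) on the plus and minus strands. On circular molecules
#' matches spanning the origin are found once; positions are reported 0-based
#' on the plus strand (start of the matched span).
#'
#' @param molecule A `dna_molecule`.
#' @param pattern IUPAC pattern (character).
#' @return Data frame with columns `position` (0-based) and `strand`, ordered
#'   by position then strand. A pattern longer than a linear molecule yields
#'   zero rows, not an error.
#' @export
find_sites <- function(molecule, pattern) {
  stopifnot(inherits(molecule, "dna_molecule"), is_scalar_string(pattern))
  pattern <- toupper(pattern)
  n <- seq_length(molecule)
  plen <- nchar(pattern)
  empty <- data.frame(position = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (plen == 0L || plen > n) return(empty)
  subject <- if (molecule$topology == "circular" && plen > 1L) {
    paste0(molecule$seq, substr(molecule$seq, 1L, plen - 1L))
  } else {
    molecule$seq
  }
  scan_one <- function(pat) {
    hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(subject),
                                     fixed = FALSE)
    starts <- Biostrings::start(hits) - 1L
    starts[starts < n]
  }
  fwd <- scan_one(pattern)
  rcp <- revcomp(pattern)
  rev <- scan_one(rcp)
  if (rcp == pattern) rev <- integer(0)   # palindromic: one strand suffices
  out <- rbind(
    data.frame(position = fwd, strand = rep("+", length(fwd)),
               stringsAsFactors = FALSE),
    data.frame(position = rev, strand = rep("-", length(rev)),
               stringsAsFactors = FALSE))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sequence-level molecule equality
#'
#' Circular molecules are equal iff one is a rotation of the other or of its
#' reverse complement; linear molecules iff the sequences match exactly or as
#' reverse complements. Comparison goes through the canonical form (the
#' lexicographically minimal rotation over both strands), so it is a proper
#' equivalence relation.
#'
#' @param a,b `dna_molecule` objects.
#' @return Logical scalar.
#' @export
molecules_equal <- function(a, b) {
  stopifnot(inherits(a, "dna_molecule"), inherits(b, "dna_molecule"))
  if (a$topology != b$topology) return(FALSE)
  if (nchar(a$seq) != nchar(b$seq)) return(FALSE)
  if (a$topology == "circular") {
    canonical_circular(a$seq) == canonical_circular(b$seq)
  } else {
    a$seq == b$seq || a$seq == revcomp(b$seq)
  }
}

#' Rotate a circular molecule so 0-based position `shift` becomes position 0
#'
#' Annotation-preserving: features are re-based modulo the length. Used to
#' normalise cut arithmetic and in tests of rotation invariance.
#' @param m A circular `dna_molecule`.
#' @param shift 0-based position that becomes the new origin.
#' @export
rotate_molecule <- function(m, shift) {
  stopifnot(inherits(m, "dna_molecule"))
  if (m$topology != "circular") {
    pf_stop("only circular molecules can be rotated", "pf_invalid_molecule")
  }
  n <- seq_length(m)
  shift <- ((shift %% n) + n) %% n
  if (shift == 0L) return(m)
  m2 <- m
  m2$seq <- circ_substr(m$seq, shift, n)
  if (nrow(m$features)) {
    st <- (m$features$start - shift) %% n
    m2$features$start <- as.integer(st)
    m2$features$end <- as.integer(st + (m$features$end - m$features$start))
  }
  m2
}

# Extract a (possibly wrapping) span [start, start+len) as a linear segment,
# carrying over the features that overlap it (truncated at the span edges,
# coordinates re-based to the segment).
extract_segment_features <- function(m, start, len) {
  n <- seq_length(m)
  if (!nrow(m$features)) return(empty_features())
  out <- list()
  for (i in seq_len(nrow(m$features))) {
    f <- m$features[i, ]
    # candidate placements of the feature start relative to the segment start
    # (-n/+n handle origin-spanning segments and origin-spanning features)
    for (off in c(-n, 0L, n)) {
      fs <- f$start - start + off
      fe <- fs + (f$end - f$start)
      lo <- max(fs, 0L)
      hi <- min(fe, len)
      if (hi - lo >= 1L) {
        g <- f
        g$start <- as.integer(lo)
        g$end <- as.integer(hi)
        out[[length(out) + 1L]] <- g
      }
    }
  }
  if (!length(out)) return(empty_features())
  res <- do.call(rbind, out)
  res <- unique(res)
  rownames(res) <- NULL
  res
}
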