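# GenBank flat-file and FASTA readers/writers.
#
# The writer emits a minimal, standards-shaped flat file (LOCUS topology
# honoured, FEATURES with /label qualifiers, ORIGIN in 60-column blocks) and
# the reader round-trips it exactly. Feature keys outside the GenBank
# standard set travel as misc_feature with a /note carrying the controlled
# key; free-text files from elsewhere are mapped onto the controlled
# vocabulary through a user-extensible table, and every mapping that falls
# back to a heuristic is logged, never silent.

# controlled key -> GenBank flat-file key
GB_KEY_OUT <- c(promoter = "promoter", CDS = "CDS", terminator = "terminator",
                origin = "rep_origin", misc = "misc_feature")

#' Feature-vocabulary mapping table
#'
#' Rules applied, in order, when reading a GenBank file written elsewhere:
#' an exact GenBank-key match, then a regular expression on the feature
#' label. Users can prepend their own rows to cover nonstandard keys.
#'
#' @return Data frame with columns `kind` (`"key"` or `"label"`), `pattern`,
#'   `key` (the controlled key assigned).
#' @export
default_vocab <- function() {
  rbind(
    data.frame(kind = "key", pattern = c("promoter", "CDS", "terminator",
                                         "rep_origin", "gene"),
               key = c("promoter", "CDS", "terminator", "origin", "CDS"),
               stringsAsFactors = FALSE),
    data.frame(kind = "label",
               pattern = c("lox", "GFP|Scarlet|RFP|mCherry|fluor",
                           "URA3|LEU2|HIS|TRP|Nat|MX|marker",
                           "AmpR|KanR|SpecR|CmR|resist|bla|aadA|aph",
                           "ori|ARS|replic", "arm|HA_|_HA|flank|homolog",
                           "tracr|sgRNA|crRNA|spacer|rpsL",
                           "term", "prom|TEF|UAS"),
               key = c("lox_site", "reporter", "marker", "resistance",
                       "origin", "HA", "sgRNA_cassette", "terminator",
                       "promoter"),
               stringsAsFactors = FALSE))
}

map_feature_key <- function(gb_key, label, note, vocab, file = "") {
  # a /note written by this package wins outright
  if (!is.na(note) && grepl("^pf_key:", note)) {
    k <- sub("^pf_key:", "", note)
    if (k %in% FEATURE_VOCAB) return(k)
  }
  keys <- vocab[vocab$kind == "key", ]
  hit <- keys$key[keys$pattern == gb_key]
  if (length(hit)) return(hit[1L])
  labs <- vocab[vocab$kind == "label", ]
  for (i in seq_len(nrow(labs))) {
    if (grepl(labs$pattern[i], label, ignore.case = TRUE)) {
      pf_log(sprintf("%s: feature key '%s' (label '%s') mapped to '%s' by label heuristic",
                     file, gb_key, label, labs$key[i]))
      return(labs$key[i])
    }
  }
  pf_log(sprintf("%s: feature key '%s' (label '%s') not in vocabulary; kept as 'misc'",
                 file, gb_key, label))
  "misc"
}

format_location <- function(start, end, strand, n) {
  # GenBank locations are 1-based inclusive
  loc <- if (end <= n) {
    sprintf("%d..%d", start + 1L, end)
  } else {
    sprintf("join(%d..%d,1..%d)", start + 1L, n, end - n)
  }
  if (strand == "-") sprintf("complement(%s)", loc) else loc
}

#' Write a molecule (or list of molecules) to a GenBank flat file
#'
#' Round-trip safe: `read_genbank()` on the output restores sequence,
#' topology and features exactly. The LOCUS date is fixed so identical
#' molecules give byte-identical files.
#'
#' @param molecule A `dna_molecule` or a list of them.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(molecule, path) {
  mols <- if (inherits(molecule, "dna_molecule")) list(molecule) else molecule
  stopifnot(length(mols) >= 1L,
            all(vapply(mols, inherits, logical(1), "dna_molecule")))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    pf_stop(sprintf("cannot write GenBank file '%s'", path), "pf_io_error")
  }
  on.exit(close(con))
  for (m in mols) {
    n <- seq_length(m)
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN 01-JAN-2000",
                       m$id, n, m$topology), con)
    writeLines(sprintf("DEFINITION  %s.", m$id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    if (nrow(m$features)) {
      for (i in seq_len(nrow(m$features))) {
        f <- m$features[i, ]
        gbk <- GB_KEY_OUT[f$key]
        if (is.na(gbk)) gbk <- "misc_feature"
        writeLines(sprintf("     %-15s %s", gbk,
                           format_location(f$start, f$end, f$strand, n)), con)
        writeLines(sprintf("                     /label=\"%s\"", f$label), con)
        if (gbk == "misc_feature" || is.na(GB_KEY_OUT[f$key]) ||
            !identical(unname(GB_KEY_OUT[f$key]), f$key)) {
          writeLines(sprintf("                     /note=\"pf_key:%s\"", f$key), con)
        }
      }
    }
    writeLines("ORIGIN", con)
    pos <- seq(1L, n, by = 60L)
    for (p in pos) {
      chunk <- substr(m$seq, p, min(p + 59L, n))
      tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(tolower(tens), collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

parse_location <- function(loc, n, file, lineno) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    rngs <- lapply(parts, parse_simple_range, file = file, lineno = lineno)
    if (length(rngs) == 2L && rngs[[1L]][2L] == n && rngs[[2L]][1L] == 1L) {
      return(list(start = rngs[[1L]][1L] - 1L, end = n + rngs[[2L]][2L],
                  strand = strand))
    }
    # non-origin join: take the envelope
    s <- min(vapply(rngs, `[`, numeric(1), 1L))
    e <- max(vapply(rngs, `[`, numeric(1), 2L))
    return(list(start = s - 1L, end = e, strand = strand))
  }
  r <- parse_simple_range(loc, file, lineno)
  list(start = r[1L] - 1L, end = r[2L], strand = strand)
}

parse_simple_range <- function(x, file, lineno) {
  x <- gsub("[<>]", "", x)
  m <- regmatches(x, regexec("^(\\d+)\\.\\.(\\d+)$", x))[[1L]]
  if (length(m) != 3L) {
    if (grepl("^\\d+$", x)) return(c(as.integer(x), as.integer(x)))
    pf_stop(sprintf("%s: line %d: cannot parse location '%s'", file, lineno, x),
            "pf_parse_error")
  }
  c(as.integer(m[2L]), as.integer(m[3L]))
}

#' Read a GenBank flat file
#'
#' Topology is taken from the LOCUS line; feature keys are mapped onto the
#' controlled vocabulary (see [default_vocab()]); heuristic mappings are
#' logged. Malformed records raise a parse error naming the file and line.
#'
#' @param path GenBank file (one or more records).
#' @param vocab Vocabulary mapping table, by default [default_vocab()].
#' @return A list of `dna_molecule` objects (one per record).
#' @export
read_genbank <- function(path, vocab = default_vocab()) {
  if (!file.exists(path)) {
    pf_stop(sprintf("GenBank file '%s' does not exist", path), "pf_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines))) {
    pf_stop(sprintf("%s: no LOCUS record found (empty or malformed file)", path),
            "pf_parse_error")
  }
  rec_starts <- grep("^LOCUS", lines)
  rec_ends <- grep("^//\\s*$", lines)
  if (length(rec_ends) < length(rec_starts)) {
    pf_stop(sprintf("%s: record starting at line %d lacks a '//' terminator",
                    path, rec_starts[length(rec_starts)]), "pf_parse_error")
  }
  mols <- vector("list", length(rec_starts))
  for (r in seq_along(rec_starts)) {
    lo <- rec_starts[r]
    hi <- rec_ends[which(rec_ends > lo)[1L]]
    mols[[r]] <- parse_gb_record(lines[lo:hi], path, lo, vocab)
  }
  mols
}

parse_gb_record <- function(rl, file, offset, vocab) {
  locus <- rl[1L]
  toks <- strsplit(trimws(locus), "\\s+")[[1L]]
  if (length(toks) < 3L) {
    pf_stop(sprintf("%s: line %d: malformed LOCUS line", file, offset),
            "pf_parse_error")
  }
  id <- toks[2L]
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  feat_i <- grep("^FEATURES", rl)
  orig_i <- grep("^ORIGIN", rl)
  if (!length(orig_i)) {
    pf_stop(sprintf("%s: record '%s' (line %d) has no ORIGIN block", file, id,
                    offset), "pf_parse_error")
  }
  # sequence
  seq_lines <- rl[(orig_i[1L] + 1L):(length(rl) - 1L)]
  seqtxt <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  n <- nchar(seqtxt)
  # features
  feats <- empty_features()
  if (length(feat_i)) {
    block <- rl[(feat_i[1L] + 1L):(orig_i[1L] - 1L)]
    cur <- NULL
    rows <- list()
    flush <- function(cur) {
      if (is.null(cur)) return(NULL)
      key <- map_feature_key(cur$gbkey, cur$label %||% cur$gbkey,
                             cur$note %||% NA_character_, vocab, file)
      feature(key, cur$label %||% cur$gbkey, cur$loc$start, cur$loc$end,
              cur$loc$strand)
    }
    for (j in seq_along(block)) {
      ln <- block[j]
      if (grepl("^     \\S", ln)) {                 # new feature line
        row <- flush(cur)
        if (!is.null(row)) rows[[length(rows) + 1L]] <- row
        toks <- strsplit(trimws(ln), "\\s+")[[1L]]
        if (length(toks) < 2L) {
          pf_stop(sprintf("%s: line %d: malformed feature line",
                          file, offset + feat_i[1L] + j - 1L), "pf_parse_error")
        }
        cur <- list(gbkey = toks[1L],
                    loc = parse_location(toks[2L], n, file,
                                         offset + feat_i[1L] + j - 1L))
      } else if (grepl("^\\s+/", ln) && !is.null(cur)) {
        q <- trimws(ln)
        if (grepl("^/label=", q)) cur$label <- gsub("^/label=\"?|\"$", "", q)
        if (grepl("^/note=", q)) cur$note <- gsub("^/note=\"?|\"$", "", q)
      }
    }
    row <- flush(cur)
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    if (length(rows)) feats <- do.call(rbind, rows)
  }
  dna_molecule(id, seqtxt, topology, feats)
}

#' Read sequences from a FASTA file
#'
#' FASTA carries no topology; all records are linear unless `circular = TRUE`
#' is supplied (applying to every record).
#'
#' @param path FASTA file.
#' @param circular Logical flag supplying the topology missing from FASTA.
#' @return List of `dna_molecule` objects.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) {
    pf_stop(sprintf("FASTA file '%s' does not exist", path), "pf_io_error")
  }
  set <- Biostrings::readDNAStringSet(path)
  topo <- if (circular) "circular" else "linear"
  lapply(seq_along(set), function(i) {
    dna_molecule(sub("\\s.*$", "", names(set)[i]), as.character(set[[i]]), topo)
  })
}

#' Write molecules to a FASTA file
#' @param molecules A `dna_molecule` or list of them.
#' @param path Output path.
#' @param width Line width for the sequence block.
#' @export
write_fasta <- function(molecules, path, width = 70L) {
  mols <- if (inherits(molecules, "dna_molecule")) list(molecules) else molecules
  set <- Biostrings::DNAStringSet(vapply(mols, function(m) m$seq, character(1)))
  names(set) <- vapply(mols, function(m) m$id, character(1))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
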