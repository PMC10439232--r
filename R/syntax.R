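# The toolkit grammar: part-type vocabulary, junction overhang assignments,
# enzyme roles, reporter/marker letter codes, and the vector naming system.

#' Default syntax configuration
#'
#' The grammar every assembly operation consults: the ordered part-type
#' vocabulary, the 4-nt junction overhang map (validated with
#' [fidelity_check()] on construction), the three enzyme roles (entry-level
#' assembly, Lvl1-to-Lvl2 assembly, and homology-arm exchange), the dropout
#' reporter vocabulary, and the one-letter marker/resistance codes used by
#' the naming system. All of it is data, not code: load an alternative
#' grammar from YAML with [read_syntax()].
#'
#' The concrete default overhangs are an internally consistent set chosen for
#' zero fidelity hazards (no duplicates, no palindromes, no cross-junction
#' reverse-complement collisions); swap in a published set via the config if
#' compatibility with an existing part collection is needed.
#'
#' @return A `syntax_config` object.
#' @export
default_syntax <- function() {
  cfg <- list(
    part_types = c("promoter", "gene", "terminator", "left_HA", "right_HA",
                   "yeast_marker", "bacterial_resistance", "backbone",
                   "reporter"),
    junctions = list(
      lvl1 = c(vector_promoter = "GGAG", promoter_gene = "AATG",
               gene_terminator = "GCTT", terminator_vector = "CGCT"),
      lvl2 = c(pos1 = "TGCC", pos2 = "GCAA", pos3 = "ACTA", pos4 = "TTAC"),
      exchange = c(backbone_central = "CAGT", central_backbone = "GTTG"),
      del = c(up_left = "AGGT", up_right = "CTTC",
              down_left = "TCCA", down_right = "GACA")),
    enzymes = list(entry = builtin_enzyme("BsaI"),
                   lvl2 = builtin_enzyme("BsmBI"),
                   exchange = builtin_enzyme("AarI")),
    reporters = list(assembly_dropout = c("mScarlet", "sfGFP"),
                     pro_dropout = "mScarlet"),
    markers = c(U = "URA3", L = "LEU2", N = "NatMX", H = "hphMX"),
    resistances = c(S = "spectinomycin", K = "kanamycin", A = "ampicillin",
                    C = "chloramphenicol"),
    lox = lox_config())
  validate_syntax(cfg)
}

validate_syntax <- function(cfg) {
  ovs <- unlist(cfg$junctions, use.names = FALSE)
  warns <- fidelity_check(ovs)
  if (length(warns)) {
    pf_stop(paste0("junction overhang map fails fidelity check: ",
                   paste(warns, collapse = "; ")), "pf_invalid_syntax")
  }
  for (role in c("entry", "lvl2", "exchange")) {
    if (!inherits(cfg$enzymes[[role]], "enzyme")) {
      pf_stop(sprintf("syntax config lacks a '%s' enzyme", role),
              "pf_invalid_syntax")
    }
  }
  structure(cfg, class = "syntax_config")
}

#' @export
print.syntax_config <- function(x, ...) {
  cat("<syntax_config>\n  enzymes:",
      paste(vapply(x$enzymes, function(e) e$name, character(1)), collapse = ", "),
      "\n  junctions:", length(unlist(x$junctions)), "overhangs\n")
  invisible(x)
}

#' Read / write a syntax configuration as YAML
#'
#' @param path YAML file.
#' @return `read_syntax()`: a validated `syntax_config`; `write_syntax()`:
#'   the path, invisibly.
#' @export
read_syntax <- function(path) {
  y <- yaml::read_yaml(path)
  y$enzymes <- lapply(y$enzymes, function(e) {
    enzyme(e$name, e$recognition, e$cut_offset_top, e$cut_offset_bottom)
  })
  y$junctions <- lapply(y$junctions, unlist)
  y$markers <- unlist(y$markers)
  y$resistances <- unlist(y$resistances)
  y$lox <- do.call(lox_config, y$lox)
  validate_syntax(y)
}

#' @rdname read_syntax
#' @param syntax A `syntax_config`.
#' @export
write_syntax <- function(syntax, path) {
  y <- unclass(syntax)
  y$enzymes <- lapply(y$enzymes, function(e) {
    list(name = e$name, recognition = e$recognition,
         cut_offset_top = e$cut_offset_top,
         cut_offset_bottom = e$cut_offset_bottom)
  })
  y$junctions <- lapply(y$junctions, as.list)
  y$markers <- as.list(y$markers)
  y$resistances <- as.list(y$resistances)
  y$lox <- as.list(unclass(y$lox))
  yaml::write_yaml(y, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Vector naming system

#' Parse a vector name
#'
#' The naming system packs chromosome, locus, yeast marker, bacterial
#' resistance, level and sublevel into a short identifier: `pE8US1.1` is an
#' empty Lvl1.1 vector with homology arms for locus 8 on chromosome E,
#' carrying a URA3 marker and spectinomycin resistance. `Z` in place of
#' chromosome+locus denotes Zeta (random-integration) flanks, which carry no
#' locus number. A `-suffix` (inserted part names) is preserved in `insert`.
#'
#' @param text Vector name, e.g. `"pE8US1.1"` or `"pZUA2.3-HPD1"`.
#' @param syntax Syntax config supplying the marker/resistance letter codes.
#' @return A `vector_name` object with fields `chromosome`, `locus_number`,
#'   `yeast_marker`, `bacterial_resistance`, `level`, `sublevel`, `insert`.
#' @export
parse_name <- function(text, syntax = default_syntax()) {
  stopifnot(is_scalar_string(text))
  m <- regmatches(text, regexec(
    "^p(Z|[A-F])([0-9]*)([A-Z])([A-Z])([0-9])\\.([0-9])(-(.+))?$", text))[[1L]]
  if (length(m) == 0L || !nzchar(m[1L])) {
    pf_stop(sprintf("cannot parse vector name '%s': expected p<chrom><locus><marker><resistance><level>.<sublevel>",
                    text), "pf_bad_name")
  }
  chrom <- m[2L]
  locus <- m[3L]
  if (chrom == "Z" && nzchar(locus)) {
    pf_stop(sprintf("'%s': Zeta vectors carry no locus number", text), "pf_bad_name")
  }
  if (chrom != "Z" && !nzchar(locus)) {
    pf_stop(sprintf("'%s': missing locus number for chromosome %s", text, chrom),
            "pf_bad_name")
  }
  if (!(m[4L] %in% names(syntax$markers))) {
    pf_stop(sprintf("'%s': unknown yeast marker letter '%s'", text, m[4L]),
            "pf_bad_name")
  }
  if (!(m[5L] %in% names(syntax$resistances))) {
    pf_stop(sprintf("'%s': unknown bacterial resistance letter '%s'", text, m[5L]),
            "pf_bad_name")
  }
  level <- as.integer(m[6L])
  sublevel <- as.integer(m[7L])
  if (!(level %in% c(0L, 1L, 2L))) {
    pf_stop(sprintf("'%s': level must be 0, 1 or 2", text), "pf_bad_name")
  }
  if (level == 1L && !(sublevel %in% 1:3)) {
    pf_stop(sprintf("'%s': Lvl1 sublevel must be 1, 2 or 3", text), "pf_bad_name")
  }
  if (level == 2L && !(sublevel %in% 2:3)) {
    pf_stop(sprintf("'%s': Lvl2 sublevel must be 2 or 3", text), "pf_bad_name")
  }
  structure(list(chromosome = chrom,
                 locus_number = if (chrom == "Z") NA_integer_ else as.integer(locus),
                 yeast_marker = m[4L], bacterial_resistance = m[5L],
                 level = level, sublevel = sublevel,
                 insert = if (nzchar(m[9L])) m[9L] else NULL),
            class = "vector_name")
}

#' @rdname parse_name
#' @param name A `vector_name`.
#' @export
format_name <- function(name) {
  stopifnot(inherits(name, "vector_name"))
  paste0("p", name$chromosome,
         if (!is.na(name$locus_number)) name$locus_number else "",
         name$yeast_marker, name$bacterial_resistance,
         name$level, ".", name$sublevel,
         if (!is.null(name$insert)) paste0("-", name$insert) else "")
}

#' @export
print.vector_name <- function(x, ...) {
  cat(sprintf("<vector_name> %s (chrom %s, locus %s, marker %s, resistance %s, Lvl%d.%d%s)\n",
              format_name(x), x$chromosome,
              ifelse(is.na(x$locus_number), "-", x$locus_number),
              x$yeast_marker, x$bacterial_resistance, x$level, x$sublevel,
              if (!is.null(x$insert)) paste0(", insert ", x$insert) else ""))
  invisible(x)
}

#' Enumerate the empty-vector series for a set of loci
#'
#' For each locus, one empty vector per sublevel in {1.1, 1.2, 1.3, 2.2,
#' 2.3} with a fixed marker/resistance pair: 5 names per locus.
#'
#' @param loci Character vector of locus names such as `"IntE8"`, `"E8"` or
#'   `"Z"` (Zeta).
#' @param marker,resistance One-letter codes (defaults URA3 / spectinomycin).
#' @param syntax Syntax config for code validation.
#' @return Character vector of vector names, `5 * length(loci)` long.
#' @export
enumerate_empty_vectors <- function(loci, marker = "U", resistance = "S",
                                    syntax = default_syntax()) {
  if (!length(loci)) return(character(0))
  sublevels <- list(c(1L, 1L), c(1L, 2L), c(1L, 3L), c(2L, 2L), c(2L, 3L))
  out <- character(0)
  for (locus in loci) {
    m <- regmatches(locus, regexec("^(Int)?(Z|[A-F])([0-9]*)$", locus))[[1L]]
    if (length(m) == 0L || !nzchar(m[1L]) ||
        (m[3L] != "Z" && !nzchar(m[4L]))) {
      pf_stop(sprintf("cannot parse locus name '%s'", locus), "pf_bad_name")
    }
    for (ls in sublevels) {
      vn <- structure(list(chromosome = m[3L],
                           locus_number = if (m[3L] == "Z") NA_integer_
                                          else as.integer(m[4L]),
                           yeast_marker = marker,
                           bacterial_resistance = resistance,
                           level = ls[1L], sublevel = ls[2L], insert = NULL),
                      class = "vector_name")
      out <- c(out, format_name(vn))
    }
  }
  out
}
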