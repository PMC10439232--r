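# Type IIS restriction digestion and sticky-end ligation, including one-pot
# Golden Gate simulation that enumerates stable circular products.
#
# Fragment convention: a fragment's `seq` is the top strand from the top-strand
# cut of its left junction to the bottom-strand cut of its right junction, so
# the 4-nt (for the default enzymes) junction duplex appears at BOTH ends of
# `seq` — `left_ov` is its prefix, `right_ov` its suffix, both written in
# top-strand sense. Two fragments ligate iff `A$right_ov == B$left_ov`
# (string equality), and the shared junction bases are counted once on
# joining. This makes digestion/ligation arithmetic exact:
# sum(len(seq) - overhang) over the fragments of a circle == circle length.

#' Define a Type IIS restriction enzyme
#'
#' Offsets count nucleotides downstream of the recognition sequence on each
#' strand; a 5' overhang requires `cut_offset_bottom > cut_offset_top`.
#' Cutting inside the recognition sequence (negative offsets) is not a
#' Type IIS geometry and is rejected.
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition sequence (non-palindromic).
#' @param cut_offset_top,cut_offset_bottom Cut positions, nt downstream of
#'   the recognition sequence on the top and bottom strand.
#' @return An `enzyme` object; `overhang_len` is derived from the offsets.
#' @examples
#' enzyme("BsaI", "GGTCTC", 1, 5)
#' @export
enzyme <- function(name, recognition, cut_offset_top, cut_offset_bottom) {
  recognition <- toupper(recognition)
  if (recognition == revcomp(recognition)) {
    pf_stop(sprintf("recognition sequence '%s' is palindromic; not usable as Type IIS",
                    recognition), "pf_invalid_enzyme")
  }
  if (cut_offset_top < 0 || cut_offset_bottom < 0) {
    pf_stop("cut offsets must be >= 0 (cutting outside the recognition sequence)",
            "pf_invalid_enzyme")
  }
  if (cut_offset_bottom < cut_offset_top) {
    pf_stop("3' overhangs (cut_offset_bottom < cut_offset_top) are not supported",
            "pf_invalid_enzyme")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset_top = as.integer(cut_offset_top),
                 cut_offset_bottom = as.integer(cut_offset_bottom),
                 overhang_len = as.integer(cut_offset_bottom - cut_offset_top)),
            class = "enzyme")
}

#' Built-in enzyme definitions
#'
#' AarI (CACCTGC 4/8) and BsaI- and BsmBI-class enzymes, all leaving 4-nt
#' 5' overhangs. Overridable through the syntax configuration.
#' @param name One of `"BsaI"`, `"BsmBI"`, `"AarI"`.
#' @export
builtin_enzyme <- function(name = c("BsaI", "BsmBI", "AarI")) {
  name <- match.arg(name)
  switch(name,
         BsaI = enzyme("BsaI", "GGTCTC", 1L, 5L),
         BsmBI = enzyme("BsmBI", "CGTCTC", 1L, 5L),
         AarI = enzyme("AarI", "CACCTGC", 4L, 8L))
}

new_fragment <- function(seq, left_ov, right_ov, parent_id,
                         features = empty_features()) {
  structure(list(seq = seq, left_ov = left_ov, right_ov = right_ov,
                 parent_id = parent_id, features = features),
            class = "dna_fragment")
}

#' @export
print.dna_fragment <- function(x, ...) {
  cat(sprintf("<fragment> %d bp [%s|...|%s] from %s\n", nchar(x$seq),
              x$left_ov, x$right_ov, x$parent_id))
  invisible(x)
}

#' Reverse-complement a fragment (flip its orientation)
#' @param frag A `dna_fragment`.
#' @export
flip_fragment <- function(frag) {
  n <- nchar(frag$seq)
  feats <- frag$features
  if (nrow(feats)) {
    st <- n - feats$end
    en <- n - feats$start
    feats$start <- as.integer(st)
    feats$end <- as.integer(en)
    feats$strand <- ifelse(feats$strand == "+", "-", "+")
  }
  new_fragment(revcomp(frag$seq), revcomp(frag$right_ov), revcomp(frag$left_ov),
               frag$parent_id, feats)
}

# All cut positions of `enz` on `molecule` as a data.frame(top, bottom) of
# 0-based top-strand coordinates (bottom > top: 5' overhang window).
enzyme_cuts <- function(molecule, enz) {
  sites <- find_sites(molecule, enz$recognition)
  if (!nrow(sites)) return(data.frame(top = integer(), bottom = integer()))
  rlen <- nchar(enz$recognition)
  n <- seq_length(molecule)
  top <- ifelse(sites$strand == "+",
                sites$position + rlen + enz$cut_offset_top,
                sites$position - enz$cut_offset_bottom)
  if (molecule$topology == "circular") {
    top <- ((top %% n) + n) %% n
    bottom <- top + enz$overhang_len
  } else {
    bottom <- top + enz$overhang_len
    if (any(top < 0) || any(bottom > n)) {
      pf_stop(sprintf("enzyme %s cut window falls off the end of linear molecule '%s'",
                      enz$name, molecule$id), "pf_unresolvable_cut")
    }
  }
  ord <- order(top)
  data.frame(top = as.integer(top[ord]), bottom = as.integer(bottom[ord]))
}

#' Digest a molecule with a Type IIS enzyme
#'
#' A circular molecule with k recognition sites yields exactly k fragments; a
#' linear molecule yields k + 1 (end fragments have blunt, non-ligatable
#' ends). A circular molecule with no sites is returned undigested, flagged
#' via the `undigested` attribute. Features are carried over and truncated at
#' cut points.
#'
#' @param molecule A `dna_molecule`.
#' @param enz An `enzyme`.
#' @return List of `dna_fragment`s, or (zero sites, circular) the molecule
#'   itself with `attr(,"undigested") = TRUE`.
#' @export
digest <- function(molecule, enz) {
  stopifnot(inherits(molecule, "dna_molecule"), inherits(enz, "enzyme"))
  cuts <- enzyme_cuts(molecule, enz)
  n <- seq_length(molecule)
  if (!nrow(cuts)) {
    out <- molecule
    attr(out, "undigested") <- TRUE
    return(out)
  }
  k <- nrow(cuts)
  # overlapping cut windows cannot be resolved into fragments
  if (k > 1L) {
    nxt_top <- c(cuts$top[-1L], cuts$top[1L] + n)
    if (any(cuts$bottom > nxt_top)) {
      i <- which(cuts$bottom > nxt_top)[1L]
      pf_stop(sprintf("unresolvable cut: windows at positions %d and %d overlap on '%s'",
                      cuts$top[i], cuts$top[i %% k + 1L], molecule$id),
              "pf_unresolvable_cut")
    }
  } else if (molecule$topology == "circular" && cuts$bottom[1L] - cuts$top[1L] > n) {
    pf_stop("unresolvable cut: overhang longer than molecule", "pf_unresolvable_cut")
  }
  frags <- list()
  if (molecule$topology == "circular") {
    for (i in seq_len(k)) {
      t0 <- cuts$top[i]
      b1 <- if (i < k) cuts$bottom[i + 1L] else cuts$bottom[1L] + n
      len <- b1 - t0
      seq <- circ_substr(molecule$seq, t0, len)
      ov <- enz$overhang_len
      frags[[i]] <- new_fragment(seq,
                                 substr(seq, 1L, ov),
                                 substr(seq, len - ov + 1L, len),
                                 molecule$id,
                                 extract_segment_features(molecule, t0, len))
    }
  } else {
    ov <- enz$overhang_len
    bounds_t <- c(0L, cuts$top)          # left edge (top cut) of each fragment
    bounds_b <- c(cuts$bottom, n)        # right edge (bottom cut)
    for (i in seq_len(k + 1L)) {
      t0 <- bounds_t[i]
      b1 <- bounds_b[i]
      seq <- substr(molecule$seq, t0 + 1L, b1)
      left <- if (i == 1L) "" else substr(seq, 1L, ov)
      right <- if (i == k + 1L) "" else substr(seq, nchar(seq) - ov + 1L, nchar(seq))
      frags[[i]] <- new_fragment(seq, left, right, molecule$id,
                                 extract_segment_features(molecule, t0, b1 - t0))
    }
  }
  frags
}

# Join a chain of fragments (already verified compatible) into one circular
# molecule; the closing junction's bases are counted once.
close_chain <- function(chain, id = NULL) {
  ov <- nchar(chain[[1L]]$left_ov)
  seqs <- vapply(chain, function(f) f$seq, character(1))
  total <- paste0(seqs[1L],
                  paste(vapply(seqs[-1L], function(s) substr(s, ov + 1L, nchar(s)),
                               character(1)), collapse = ""))
  L <- nchar(total) - ov
  seq <- substr(total, 1L, L)
  offsets <- cumsum(c(0L, vapply(chain, function(f) nchar(f$seq), integer(1)) - ov))
  rows <- list()
  for (i in seq_along(chain)) {
    fe <- chain[[i]]$features
    if (!nrow(fe)) next
    fe$start <- as.integer((fe$start + offsets[i]) %% L)
    fe$end <- fe$start + (chain[[i]]$features$end - chain[[i]]$features$start)
    rows[[length(rows) + 1L]] <- fe
  }
  feats <- if (length(rows)) unique(do.call(rbind, rows)) else empty_features()
  id <- id %||% paste0("asm_", substr(canonical_circular(seq), 1L, 0L),
                       paste(unique(vapply(chain, function(f) f$parent_id,
                                           character(1))), collapse = "+"))
  dna_molecule(id, seq, "circular", feats)
}

#' Enumerate circular ligation products of a fragment pool
#'
#' Every distinct circular molecule formable by joining fragments through
#' complementary sticky ends, each fragment used at most once per product
#' (set `max_copies = 2` to allow dimeric use of a fragment). Blunt ends do
#' not ligate unless `allow_blunt = TRUE`. Products are deduplicated by
#' canonical circular form.
#'
#' @param fragments List of `dna_fragment`s.
#' @param allow_blunt Permit blunt-end joins (default off).
#' @param max_copies Maximum uses of any one input fragment per product.
#' @return List of circular `dna_molecule`s (empty if nothing circularises).
#' @export
ligate_cyclic <- function(fragments, allow_blunt = FALSE, max_copies = 1L) {
  stopifnot(length(fragments) >= 1L,
            all(vapply(fragments, inherits, logical(1), "dna_fragment")))
  joinable <- function(a, b) {
    nchar(a$right_ov) > 0L && a$right_ov == b$left_ov ||
      (allow_blunt && nchar(a$right_ov) == 0L && nchar(b$left_ov) == 0L)
  }
  can_close <- function(chain) joinable(chain[[length(chain)]], chain[[1L]])
  products <- list()
  seen <- character()
  n <- length(fragments)
  flipped <- lapply(fragments, flip_fragment)
  used <- integer(n)
  chain <- list()
  grow <- function() {
    if (length(chain) >= 1L && can_close(chain)) {
      mol <- close_chain(chain)
      key <- canonical_circular(mol$seq)
      if (!(key %in% seen)) {
        seen <<- c(seen, key)
        products[[length(products) + 1L]] <<- mol
      }
    }
    if (length(chain) >= 2L * n * max_copies) return(invisible())
    for (i in seq_len(n)) {
      if (used[i] >= max_copies) next
      for (f in list(fragments[[i]], flipped[[i]])) {
        if (length(chain) > 0L && !joinable(chain[[length(chain)]], f)) next
        if (length(chain) == 0L && nchar(f$left_ov) == 0L && !allow_blunt) next
        used[i] <<- used[i] + 1L
        chain[[length(chain) + 1L]] <<- f
        grow()
        chain[[length(chain)]] <<- NULL
        used[i] <<- used[i] - 1L
      }
    }
    invisible()
  }
  grow()
  products
}

#' Check a set of junction overhangs for ligation-fidelity hazards
#'
#' Flags duplicated overhangs, self-complementary (palindromic) overhangs,
#' and reverse-complement collisions between distinct junctions — all of
#' which allow unintended joins in a one-pot reaction.
#'
#' @param overhang_set Character vector of overhang sequences (one per
#'   intended junction).
#' @return Character vector of warnings (empty when the set is clean).
#' @export
fidelity_check <- function(overhang_set) {
  overhang_set <- toupper(overhang_set)
  warnings <- character()
  dup <- unique(overhang_set[duplicated(overhang_set)])
  for (d in dup) {
    warnings <- c(warnings, sprintf("overhang %s used at more than one junction", d))
  }
  uniq <- unique(overhang_set)
  pal <- uniq[vapply(uniq, function(o) o == revcomp(o), logical(1))]
  for (p in pal) {
    warnings <- c(warnings, sprintf("overhang %s is palindromic (self-complementary)", p))
  }
  if (length(uniq) > 1L) {
    for (i in seq_len(length(uniq) - 1L)) {
      for (j in (i + 1L):length(uniq)) {
        if (uniq[i] == revcomp(uniq[j])) {
          warnings <- c(warnings,
                        sprintf("overhangs %s and %s are reverse complements of each other",
                                uniq[i], uniq[j]))
        }
      }
    }
  }
  warnings
}

#' One-pot Golden Gate assembly
#'
#' Digests every input with the enzyme, pools the fragments, enumerates all
#' circular ligation products, and classifies them: products free of the
#' enzyme's recognition site are *stable* (they accumulate under one-pot
#' digestion/ligation cycling and are the assembly outcome); re-ligations
#' that retain a site are listed as unstable. Inputs without a site are
#' reported undigested. Overhang-fidelity hazards are reported as warnings,
#' never errors.
#'
#' @param plasmids List of `dna_molecule`s (circular vectors and/or linear
#'   amplicons with terminal enzyme sites).
#' @param enz An `enzyme`.
#' @param max_copies Passed to [ligate_cyclic()].
#' @return A `gg_report`: list with `products` (stable), `unstable`,
#'   `undigested`, `warnings`, and `fragments`.
#' @export
golden_gate <- function(plasmids, enz, max_copies = 1L) {
  if (inherits(plasmids, "dna_molecule")) plasmids <- list(plasmids)
  stopifnot(length(plasmids) >= 1L,
            all(vapply(plasmids, inherits, logical(1), "dna_molecule")))
  pool <- list()
  undig <- list()
  for (m in plasmids) {
    d <- digest(m, enz)
    if (inherits(d, "dna_molecule")) {
      undig[[length(undig) + 1L]] <- d
    } else {
      pool <- c(pool, d)
    }
  }
  warnings <- character()
  if (length(undig)) {
    warnings <- c(warnings,
                  sprintf("input '%s' has no %s site and was not digested",
                          vapply(undig, function(m) m$id, character(1)), enz$name))
  }
  stable <- list()
  unstable <- list()
  if (length(pool)) {
    ovset <- unique(unlist(lapply(pool, function(f) c(f$left_ov, f$right_ov))))
    ovset <- ovset[nzchar(ovset)]
    # duplicates across fragments are the mechanism of assembly; only
    # palindromes and cross-junction revcomp collisions are hazards here
    warnings <- c(warnings, fidelity_check(ovset))
    all_products <- ligate_cyclic(pool, max_copies = max_copies)
    for (p in all_products) {
      if (nrow(find_sites(p, enz$recognition)) == 0L) {
        stable[[length(stable) + 1L]] <- p
      } else {
        unstable[[length(unstable) + 1L]] <- p
      }
    }
  }
  if (!length(stable)) {
    warnings <- c(warnings, "no stable (site-free) circular product can form")
  }
  structure(list(products = stable, unstable = unstable, undigested = undig,
                 warnings = warnings, fragments = pool),
            class = "gg_report")
}

#' @export
print.gg_report <- function(x, ...) {
  cat(sprintf("<gg_report> %d stable product(s), %d unstable, %d undigested input(s), %d warning(s)\n",
              length(x$products), length(x$unstable), length(x$undigested),
              length(x$warnings)))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}
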