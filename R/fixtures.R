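# Deterministic synthetic mini-toolkit and genome generator.
#
# The generator emulates the published toolkit's structure — entry vectors
# with fluorescent dropout reporters, 5 empty integration vectors per locus
# across levels/sublevels, Zeta-flank vectors, a promoter-assay vector, a
# dual-reporter deletion vector and an empty Cas9 helper with a
# counter-selectable cassette in the spacer slot — over a toy 6-chromosome
# genome, so that every operation in the package is exercisable without
# downloading any deposited plasmid.
#
# Robustness trick: none of the six Type IIS recognition motifs in play
# (GGTCTC/GAGACC, CGTCTC/GAGACG, CACCTGC/GCAGGTG) starts with T, ends with
# T, or contains TT. Every randomly generated segment therefore begins and
# ends with a TT guard, which makes it impossible for a recognition site to
# arise across a segment boundary, for any seed. Segment interiors are
# scrubbed of the motifs deterministically.

ENZ_MOTIFS <- c("GGTCTC", "GAGACC", "CGTCTC", "GAGACG", "CACCTGC", "GCAGGTG")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Remove all occurrences of the enzyme motifs from a sequence by mutating the
# middle base of each occurrence (deterministic base cycling, no RNG).
scrub_motifs <- function(seq, motifs = ENZ_MOTIFS) {
  cycle <- c(A = "C", C = "G", G = "T", T = "A")
  for (iter in 1:200) {
    hit <- NULL
    for (m in motifs) {
      p <- regexpr(m, seq, fixed = TRUE)
      if (p > 0L) { hit <- c(p, nchar(m)); break }
    }
    if (is.null(hit)) return(seq)
    mid <- hit[1L] + hit[2L] %/% 2L
    substr(seq, mid, mid) <- unname(cycle[substr(seq, mid, mid)])
  }
  pf_stop("motif scrubbing did not converge", "pf_fixture_error")
}

# A TT-guarded, motif-free random segment of exactly n bases (n >= 5).
guarded_random <- function(n) {
  stopifnot(n >= 5L)
  paste0("TT", scrub_motifs(random_dna(n - 4L)), "TT")
}

#' Specification for the synthetic fixture set
#'
#' The same seed gives byte-identical fixture files. Defaults mirror the
#' emulated toolkit's study conditions: 16 named intergenic loci across six
#' chromosomes and 500-bp homology arms.
#'
#' @param seed Integer seed driving every random choice.
#' @param n_loci Number of intergenic integration loci (default 16).
#' @param arm_len Homology-arm length in bp (default 500).
#' @param chrom_len Length of each of the six toy chromosomes.
#' @param n_promoters,n_genes,n_terminators Part-catalogue sizes.
#' @param syntax The toolkit grammar ([default_syntax()]).
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L, n_loci = 16L, arm_len = 500L,
                         chrom_len = 12000L, n_promoters = 3L, n_genes = 4L,
                         n_terminators = 2L, syntax = default_syntax()) {
  stopifnot(n_loci >= 0L, arm_len >= 1L, chrom_len >= 4L * arm_len)
  structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                 arm_len = as.integer(arm_len),
                 chrom_len = as.integer(chrom_len),
                 n_promoters = as.integer(n_promoters),
                 n_genes = as.integer(n_genes),
                 n_terminators = as.integer(n_terminators),
                 syntax = syntax),
            class = "fixture_spec")
}

#' Build the synthetic toy genome
#'
#' Six chromosomes (A-F) of random, enzyme-motif-free sequence with `n_loci`
#' named intergenic insertion loci (IntA1, IntB1, ... numbered per
#' chromosome) and three planted open reading frames (disruption targets).
#' Loci keep at least one arm length plus margin from chromosome ends.
#'
#' @param spec A [fixture_spec()].
#' @return List with `chromosomes` (list of linear `dna_molecule`s) and
#'   `loci` (data frame: `chrom`, `start`, `end`, `name`, `type`; 0-based
#'   half-open; intergenic loci have `start == end`).
#' @export
build_fixture_genome <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, build_fixture_genome_impl(spec))
}

build_fixture_genome_impl <- function(spec) {
  chrom_ids <- paste0("chr", LETTERS[1:6])
  orf_plan <- data.frame(chrom = c("chrB", "chrC", "chrE"),
                         name = c("ARO8", "ARO9", "AAT1"),
                         frac = c(0.38, 0.40, 0.42),
                         stringsAsFactors = FALSE)
  chroms <- list()
  loci <- list()
  # per-chromosome locus counts, round-robin A..F
  per <- table(factor(chrom_ids[(seq_len(spec$n_loci) - 1L) %% 6L + 1L],
                      levels = chrom_ids))
  for (ci in seq_along(chrom_ids)) {
    id <- chrom_ids[ci]
    seq <- scrub_motifs(random_dna(spec$chrom_len))
    feats <- empty_features()
    # plant disruption-target ORFs (600 bp, motif-free)
    oi <- which(orf_plan$chrom == id)
    if (length(oi)) {
      orf_seq <- guarded_random(600L)
      at <- as.integer(round(orf_plan$frac[oi] * spec$chrom_len))
      substr(seq, at + 1L, at + 600L) <- orf_seq
      feats <- rbind(feats, feature("CDS", orf_plan$name[oi], at, at + 600L))
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = id, start = at, end = at + 600L, name = orf_plan$name[oi],
        type = "ORF", stringsAsFactors = FALSE)
    }
    k <- as.integer(per[id])
    if (k > 0L) {
      pos <- as.integer(round(spec$chrom_len * seq_len(k) / (k + 1L)))
      for (j in seq_len(k)) {
        nm <- paste0("Int", substr(id, 4L, 4L), j)
        loci[[length(loci) + 1L]] <- data.frame(
          chrom = id, start = pos[j], end = pos[j], name = nm,
          type = "intergenic", stringsAsFactors = FALSE)
      }
    }
    chroms[[id]] <- dna_molecule(id, seq, "linear", feats)
  }
  loci <- do.call(rbind, loci)
  rownames(loci) <- NULL
  # invariant: every locus at least arm_len (+margin) from chromosome ends
  margin <- spec$arm_len + 10L
  stopifnot(all(loci$start >= margin), all(loci$end <= spec$chrom_len - margin))
  list(chromosomes = chroms, loci = loci)
}

#' Write the fixture genome as multi-FASTA plus a BED-like locus table
#' @param genome Result of [build_fixture_genome()].
#' @param fasta_path,loci_path Output paths.
#' @export
write_fixture_genome <- function(genome, fasta_path, loci_path) {
  write_fasta(genome$chromosomes, fasta_path)
  utils::write.table(genome$loci[, c("chrom", "start", "end", "name")],
                     loci_path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(fasta_path, loci_path))
}

#' Read a BED-like locus table (chrom, start, end, name; 0-based half-open)
#' @param path TSV file.
#' @export
read_loci <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  df$type <- ifelse(df$start == df$end, "intergenic", "ORF")
  df
}

# ---------------------------------------------------------------------------
# Plasmid construction

# piece helper: sequence plus an optional single covering feature
pc <- function(seq, key = NULL, label = NULL, strand = "+") {
  f <- if (is.null(key)) empty_features() else
    feature(key, label, 0L, nchar(seq), strand)
  list(seq = seq, features = f)
}

plasmid_from_pieces <- function(id, pieces, topology = "circular") {
  offsets <- cumsum(c(0L, vapply(pieces, function(p) nchar(p$seq), integer(1))))
  seq <- paste(vapply(pieces, function(p) p$seq, character(1)), collapse = "")
  rows <- list()
  for (i in seq_along(pieces)) {
    f <- pieces[[i]]$features
    if (nrow(f)) {
      f$start <- f$start + offsets[i]
      f$end <- f$end + offsets[i]
      rows[[length(rows) + 1L]] <- f
    }
  }
  feats <- if (length(rows)) do.call(rbind, rows) else empty_features()
  dna_molecule(id, seq, topology, feats)
}

assert_sites <- function(mol, enz, expected) {
  got <- nrow(find_sites(mol, enz$recognition))
  if (got != expected) {
    pf_stop(sprintf("fixture '%s': expected %d %s site(s), found %d",
                    mol$id, expected, enz$name, got), "pf_fixture_error")
  }
  invisible(mol)
}

#' Wrap a part sequence as a PCR amplicon with terminal Type IIS sites
#'
#' Models primer-appended enzyme sites on a PCR product: a linear molecule
#' `pad - site - spacer - left junction - part - right junction - spacer -
#' site(rc) - pad`, ready to donate the part in a Golden Gate reaction.
#'
#' @param part_seq Part sequence (insert between the junctions).
#' @param left_j,right_j 4-nt junction overhangs the part will carry.
#' @param enz Enzyme whose sites are appended (default entry enzyme).
#' @param id Molecule id.
#' @param features Optional feature table for the part (0-based on
#'   `part_seq`).
#' @return Linear `dna_molecule`.
#' @export
make_amplicon <- function(part_seq, left_j, right_j,
                          enz = builtin_enzyme("BsaI"),
                          id = "amplicon", features = empty_features()) {
  # TT guards flank the insert so no enzyme motif can straddle its edges
  head_len <- 6L + nchar(enz$recognition) + enz$cut_offset_top
  if (nrow(features)) {
    features$start <- features$start + head_len + nchar(left_j) + 2L
    features$end <- features$end + head_len + nchar(left_j) + 2L
  }
  seq <- paste0("TTCATT", enz$recognition, strrep("A", enz$cut_offset_top),
                left_j, "TT", part_seq, "TT", right_j,
                strrep("A", enz$cut_offset_top), revcomp(enz$recognition),
                "TTCATT")
  dna_molecule(id, seq, "linear", features)
}

# fixed cassette builders -----------------------------------------------------

entry_donor_wrap <- function(part_piece, left_j, right_j, enz) {
  sp <- strrep("A", enz$cut_offset_top)
  list(pc(paste0(enz$recognition, sp, left_j)),
       part_piece,
       pc(paste0(right_j, sp, revcomp(enz$recognition))))
}

# acceptor dropout for `enz`: junction - spacer - site(rc) ... site - spacer
# - junction, recognitions travelling with the dropout
acceptor_open <- function(left_j, enz) {
  pc(paste0(left_j, strrep("A", enz$cut_offset_top), revcomp(enz$recognition)))
}
acceptor_close <- function(right_j, enz) {
  pc(paste0(enz$recognition, strrep("A", enz$cut_offset_top), right_j))
}

aari_fwd <- function(x1, enz) {
  pc(paste0(enz$recognition, strrep("A", enz$cut_offset_top), x1))
}
aari_rev <- function(x2, enz) {
  pc(paste0(x2, strrep("A", enz$cut_offset_top), revcomp(enz$recognition)))
}

#' Build the synthetic mini-toolkit
#'
#' Generates the shared part catalogue and every plasmid class of the
#' emulated toolkit: one entry vector per part, the five empty
#' integration-vector sublevels (1.1, 1.2, 1.3, 2.2, 2.3) for every genome
#' locus (URA3 marker, spectinomycin resistance) plus a Zeta series
#' (ampicillin), the promoter-assay vector (`pProUA-mScarlet`), the
#' dual-reporter deletion vector (`pDelUK-RG`) and the empty Cas9 helper
#' (`pCasNA-RK`). Every plasmid is checked for its designed Type IIS site
#' counts, dropout reporters, lox flanks and (for the helper) the
#' counter-selectable cassette before being returned.
#'
#' @param spec A [fixture_spec()].
#' @param genome Optional pre-built [build_fixture_genome()] result (built
#'   from `spec` if missing).
#' @return A `fixture_toolkit` list: `parts`, `entries`, `empties`,
#'   `zeta_empties`, `pro`, `del`, `cas`, `genome`, `spec`.
#' @export
build_fixture_toolkit <- function(spec = fixture_spec(), genome = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(genome)) genome <- build_fixture_genome(spec)
  with_seed(spec$seed + 1L, build_fixture_toolkit_impl(spec, genome))
}

build_fixture_toolkit_impl <- function(spec, genome) {
  syn <- spec$syntax
  Jl1 <- syn$junctions$lvl1
  Q <- syn$junctions$lvl2
  X <- syn$junctions$exchange
  D <- syn$junctions$del
  ent <- syn$enzymes$entry
  lv2 <- syn$enzymes$lvl2
  exch <- syn$enzymes$exchange
  lox <- syn$lox

  # shared part catalogue ----------------------------------------------------
  prom_names <- c("TEF1", paste0("PRO", seq_len(max(spec$n_promoters - 1L, 0L))))
  prom_names <- prom_names[seq_len(spec$n_promoters)]
  gene_names <- c("hrGFP", "HPD1", "ARO4", "ARO7",
                  paste0("GEN", seq_len(max(spec$n_genes - 4L, 0L))))
  gene_names <- gene_names[seq_len(spec$n_genes)]
  term_names <- paste0("TER", seq_len(spec$n_terminators))
  parts <- list(
    promoters = stats::setNames(lapply(prom_names, function(x) guarded_random(200L)),
                                prom_names),
    genes = stats::setNames(lapply(gene_names, function(x) guarded_random(600L)),
                            gene_names),
    terminators = stats::setNames(lapply(term_names, function(x) guarded_random(150L)),
                                  term_names))
  seg <- list(ori = guarded_random(120L),
              ars = guarded_random(200L),
              ura3 = guarded_random(420L),
              natmx = guarded_random(380L),
              mScarlet = guarded_random(320L),
              sfGFP = guarded_random(330L),
              hrGFP_pro = parts$genes[["hrGFP"]],
              res = list(S = guarded_random(350L), K = guarded_random(350L),
                         A = guarded_random(350L), C = guarded_random(350L)),
              zeta_up = guarded_random(spec$arm_len),
              zeta_down = guarded_random(spec$arm_len),
              scr1 = guarded_random(250L),
              rpsl_kanr = guarded_random(550L),
              tracr = guarded_random(80L),
              cas9 = guarded_random(900L),
              cas9_prom = guarded_random(136L))
  res_label <- c(S = "SpecR", K = "KanR", A = "AmpR", C = "CmR")

  part_key <- c(promoters = "promoter", genes = "CDS", terminators = "terminator")
  part_junctions <- list(promoters = c(Jl1[["vector_promoter"]], Jl1[["promoter_gene"]]),
                         genes = c(Jl1[["promoter_gene"]], Jl1[["gene_terminator"]]),
                         terminators = c(Jl1[["gene_terminator"]], Jl1[["terminator_vector"]]))

  backbone_pieces <- function(res_letter) {
    list(pc(seg$ori, "origin", "ori_syn"),
         pc(seg$res[[res_letter]], "resistance", res_label[[res_letter]]))
  }
  marker_cassette <- function() {
    # lox71 upstream, lox66 downstream: the retained excision product then
    # carries the inert double-mutant lox72
    list(pc(lox$lox71_seq, "lox_site", "lox71"),
         pc(seg$ura3, "marker", "URA3"),
         pc(lox$lox66_seq, "lox_site", "lox66"))
  }
  dual_dropout <- function() {
    list(pc(seg$mScarlet, "reporter", "mScarlet"),
         pc(seg$sfGFP, "reporter", "sfGFP"))
  }

  # entry (Lvl0) vectors ------------------------------------------------------
  entries <- list()
  for (cls in names(parts)) {
    for (nm in names(parts[[cls]])) {
      jj <- part_junctions[[cls]]
      id <- paste0("pL0-", nm)
      mol <- plasmid_from_pieces(id, c(
        backbone_pieces("A"),
        entry_donor_wrap(pc(parts[[cls]][[nm]], part_key[[cls]], nm),
                         jj[1L], jj[2L], ent)))
      assert_sites(mol, ent, 2L)
      assert_sites(mol, lv2, 0L)
      assert_sites(mol, exch, 0L)
      entries[[id]] <- mol
    }
  }

  # empty integration vectors -------------------------------------------------
  locus_arms <- function(locus_row) {
    chrom <- genome$chromosomes[[locus_row$chrom]]
    list(up = substr(chrom$seq, locus_row$start - spec$arm_len + 1L, locus_row$start),
         down = substr(chrom$seq, locus_row$end + 1L, locus_row$end + spec$arm_len))
  }
  empty_exp <- function(id, level, sublevel, arm_up, arm_down, arm_label,
                        res_letter) {
    tu_region <- if (level == 1L) {
      c(list(pc(paste0(lv2$recognition, strrep("A", lv2$cut_offset_top),
                       Q[[sublevel]]))),
        list(acceptor_open(Jl1[["vector_promoter"]], ent)),
        dual_dropout(),
        list(acceptor_close(Jl1[["terminator_vector"]], ent)),
        list(pc(paste0(Q[[sublevel + 1L]], strrep("A", lv2$cut_offset_top),
                       revcomp(lv2$recognition)))))
    } else {
      c(list(acceptor_open(Q[[1L]], lv2)),
        dual_dropout(),
        list(acceptor_close(Q[[sublevel + 1L]], lv2)))
    }
    mol <- plasmid_from_pieces(id, c(
      backbone_pieces(res_letter),
      list(pc(arm_up, "HA", paste0(arm_label, "_up")),
           pc("TT"),     # guard: no enzyme motif can straddle an arm edge
           aari_fwd(X[["backbone_central"]], exch)),
      marker_cassette(),
      tu_region,
      list(aari_rev(X[["central_backbone"]], exch),
           pc("TT"),
           pc(arm_down, "HA", paste0(arm_label, "_down")))))
    assert_sites(mol, exch, 2L)
    assert_sites(mol, lv2, 2L)
    assert_sites(mol, ent, if (level == 1L) 2L else 0L)
    mol
  }

  sublevel_sets <- list(c(1L, 1L), c(1L, 2L), c(1L, 3L), c(2L, 2L), c(2L, 3L))
  empties <- list()
  iloci <- genome$loci[genome$loci$type == "intergenic", , drop = FALSE]
  for (r in seq_len(nrow(iloci))) {
    row <- iloci[r, ]
    arms <- locus_arms(row)
    short <- sub("^Int", "", row$name)
    for (ls in sublevel_sets) {
      vn <- structure(list(chromosome = substr(short, 1L, 1L),
                           locus_number = as.integer(substr(short, 2L, nchar(short))),
                           yeast_marker = "U", bacterial_resistance = "S",
                           level = ls[1L], sublevel = ls[2L], insert = NULL),
                      class = "vector_name")
      id <- format_name(vn)
      empties[[id]] <- empty_exp(id, ls[1L], ls[2L], arms$up, arms$down,
                                 row$name, "S")
    }
  }
  zeta_empties <- list()
  for (ls in sublevel_sets) {
    vn <- structure(list(chromosome = "Z", locus_number = NA_integer_,
                         yeast_marker = "U", bacterial_resistance = "A",
                         level = ls[1L], sublevel = ls[2L], insert = NULL),
                    class = "vector_name")
    id <- format_name(vn)
    zeta_empties[[id]] <- empty_exp(id, ls[1L], ls[2L], seg$zeta_up,
                                    seg$zeta_down, "Zeta", "A")
  }

  # promoter-assay vector ------------------------------------------------------
  pro_locus <- if ("IntC2" %in% iloci$name) "IntC2" else iloci$name[1L]
  pro_arms <- locus_arms(iloci[iloci$name == pro_locus, ][1L, ])
  pro <- plasmid_from_pieces("pProUA-mScarlet", c(
    backbone_pieces("A"),
    list(pc(pro_arms$up, "HA", paste0(pro_locus, "_up")),
         pc("TT"),
         aari_fwd(X[["backbone_central"]], exch)),
    marker_cassette(),
    list(pc(paste0(lv2$recognition, strrep("A", lv2$cut_offset_top), Q[[1L]])),
         acceptor_open(Jl1[["vector_promoter"]], ent),
         pc(seg$mScarlet, "reporter", "mScarlet"),
         acceptor_close(Jl1[["promoter_gene"]], ent),
         pc(parts$genes[["hrGFP"]], "CDS", "hrGFP"),
         pc(parts$terminators[[1L]], "terminator", names(parts$terminators)[1L]),
         pc(paste0(Q[[2L]], strrep("A", lv2$cut_offset_top),
                   revcomp(lv2$recognition))),
         aari_rev(X[["central_backbone"]], exch),
         pc("TT"),
         pc(pro_arms$down, "HA", paste0(pro_locus, "_down")))))
  assert_sites(pro, ent, 2L)
  assert_sites(pro, exch, 2L)
  assert_sites(pro, lv2, 2L)

  # deletion vector ------------------------------------------------------------
  del <- plasmid_from_pieces("pDelUK-RG", c(
    backbone_pieces("K"),
    list(acceptor_open(D[["up_left"]], ent),
         pc(seg$mScarlet, "reporter", "mScarlet"),
         acceptor_close(D[["up_right"]], ent),
         aari_rev_open(X[["backbone_central"]], exch)),
    marker_cassette(),
    list(aari_fwd_close(X[["central_backbone"]], exch),
         acceptor_open(D[["down_left"]], ent),
         pc(seg$sfGFP, "reporter", "sfGFP"),
         acceptor_close(D[["down_right"]], ent))))
  assert_sites(del, ent, 4L)
  assert_sites(del, exch, 2L)
  assert_sites(del, lv2, 0L)

  # empty Cas9 helper ----------------------------------------------------------
  cas <- plasmid_from_pieces("pCasNA-RK", list(
    pc(seg$ori, "origin", "ori_syn"),
    pc(seg$res$A, "resistance", "AmpR"),
    pc(seg$natmx, "marker", "NatMX"),
    pc(seg$ars, "origin", "ARS_syn"),
    pc(seg$cas9_prom, "promoter", "UAS1B8-TEF136"),
    pc(seg$cas9, "CDS", "Cas9-SV40NLS"),
    pc(parts$terminators[[1L]], "terminator", names(parts$terminators)[1L]),
    pc(seg$scr1, "promoter", "SCR1-tRNAGly"),
    pc(seg$rpsl_kanr, "sgRNA_cassette", "rpsL-kanR"),
    pc(seg$tracr, "sgRNA_cassette", "tracrRNA"),
    pc("TTTTTTTT", "terminator", "polyT")))
  assert_sites(cas, ent, 0L)
  assert_sites(cas, lv2, 0L)
  assert_sites(cas, exch, 0L)
  if (counterselect_check(cas)) {
    pf_stop("fixture helper lacks its counter-selectable cassette",
            "pf_fixture_error")
  }

  structure(list(parts = parts, entries = entries, empties = empties,
                 zeta_empties = zeta_empties, pro = pro, del = del, cas = cas,
                 genome = genome, spec = spec, segments = seg),
            class = "fixture_toolkit")
}

# AarI acceptor halves for the deletion vector: recognitions sit INSIDE the
# lox-flanked marker dropout, so the transfer product is AarI-free
# (irreversible transfer), unlike the integration vectors where the
# recognitions stay on the backbone (reversible exchange).
aari_rev_open <- function(x1, enz) {
  pc(paste0(x1, strrep("A", enz$cut_offset_top), revcomp(enz$recognition)))
}
aari_fwd_close <- function(x2, enz) {
  pc(paste0(enz$recognition, strrep("A", enz$cut_offset_top), x2))
}

#' @export
print.fixture_toolkit <- function(x, ...) {
  cat(sprintf("<fixture_toolkit> %d entry vectors, %d empty vectors (+%d Zeta), pPro/pDel/pCas, %d-chromosome genome\n",
              length(x$entries), length(x$empties), length(x$zeta_empties),
              length(x$genome$chromosomes)))
  invisible(x)
}

#' Write every toolkit plasmid as a GenBank file
#' @param toolkit A `fixture_toolkit`.
#' @param dir Output directory (created if needed).
#' @export
write_fixture_toolkit <- function(toolkit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mols <- c(toolkit$entries, toolkit$empties, toolkit$zeta_empties,
            list(toolkit$pro, toolkit$del, toolkit$cas))
  for (m in mols) {
    write_genbank(m, file.path(dir, paste0(m$id, ".gb")))
  }
  write_fixture_genome(toolkit$genome, file.path(dir, "genome.fasta"),
                       file.path(dir, "loci.tsv"))
  invisible(dir)
}
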