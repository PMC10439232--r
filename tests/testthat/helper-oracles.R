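# Independent oracles used across the suite. These deliberately avoid the
# package's own search/assembly code paths: plain regex scans, exhaustive
# permutation enumeration and O(n^2) rotation handling.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

iupac_regex <- function(p) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(p, "", fixed = TRUE)[[1L]]], collapse = "")
}

# naive O(n*m) both-strand scan, returning 0-based plus-strand positions
oracle_sites <- function(seq, pattern, circular = FALSE) {
  n <- nchar(seq)
  m <- nchar(pattern)
  if (m > n && !circular) {
    return(data.frame(position = integer(), strand = character()))
  }
  sub <- if (circular && m > 1L) paste0(seq, substr(seq, 1L, m - 1L)) else seq
  scan <- function(pat) {
    re <- paste0("^", iupac_regex(pat))
    hits <- integer()
    for (i in seq_len(nchar(sub) - m + 1L)) {
      if (grepl(re, substr(sub, i, i + m - 1L))) hits <- c(hits, i - 1L)
    }
    hits[hits < n]
  }
  fwd <- scan(pattern)
  rcp <- oracle_revcomp(pattern)
  rev <- if (rcp == pattern) integer() else scan(rcp)
  out <- rbind(data.frame(position = fwd, strand = rep("+", length(fwd))),
               data.frame(position = rev, strand = rep("-", length(rev))))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# canonical circular form by exhaustive rotation (O(n^2)); independent of
# the package's canonicalisation
oracle_canonical <- function(s) {
  n <- nchar(s)
  rots <- function(x) {
    vapply(0:(n - 1L),
           function(i) paste0(substr(x, i + 1L, n), substr(x, 1L, i)), "")
  }
  min(c(rots(s), rots(oracle_revcomp(s))))
}

# exhaustive enumeration of circular ligation products over <= ~5 fragments:
# every subset, permutation and orientation assignment
oracle_circles <- function(frag_list) {
  n <- length(frag_list)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  flip <- function(f) {
    list(seq = oracle_revcomp(f$seq), left = oracle_revcomp(f$right),
         right = oracle_revcomp(f$left))
  }
  found <- character()
  subsets <- seq_len(2L^n) - 1L
  for (mask in subsets[-1L]) {
    idx <- which(bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L)
    for (ord in perms(idx)) {
      k <- length(ord)
      for (bits in 0:(2L^k - 1L)) {
        chain <- lapply(seq_len(k), function(j) {
          f <- frag_list[[ord[j]]]
          if (bitwAnd(bits, 2L^(j - 1L)) > 0L) flip(f) else f
        })
        ok <- all(vapply(seq_len(k), function(j) {
          a <- chain[[j]]
          b <- chain[[if (j == k) 1L else j + 1L]]
          nchar(a$right) > 0L && a$right == b$left
        }, logical(1)))
        if (!ok) next
        ov <- nchar(chain[[1L]]$left)
        s <- chain[[1L]]$seq
        if (k > 1L) {
          for (j in 2:k) {
            s <- paste0(s, substr(chain[[j]]$seq, ov + 1L,
                                  nchar(chain[[j]]$seq)))
          }
        }
        s <- substr(s, 1L, nchar(s) - ov)
        found <- union(found, oracle_canonical(s))
      }
    }
  }
  found
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
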