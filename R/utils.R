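# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All user-facing errors in the package carry the class `pf_error` plus a
#' specific subclass so tests and callers can discriminate failure modes.
#' @noRd
pf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "pf_error", "error"),
                      call = call))
}

pf_log <- function(...) {
  message("[plasmidforge] ", ...)
}

#' Reverse complement of a character DNA string (IUPAC-aware)
#' @noRd
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Circular substring: extract `len` bases starting at 0-based `start`,
#' wrapping around the origin if needed.
#' @noRd
circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  stopifnot(len <= 2L * n)   # a single-cut circular digest spans len + overhang
  start <- ((start %% n) + n) %% n
  if (start + len <= n) {
    substr(seq, start + 1L, start + len)
  } else {
    substr(paste0(seq, seq), start + 1L, start + len)
  }
}

#' Index (0-based) of the lexicographically least rotation of `s`.
#'
#' Candidate refinement on the doubled string: keep all start positions tied
#' for the minimal prefix, extend the prefix one character at a time.
#' @noRd
least_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(0L)
  v <- strsplit(paste0(s, s), "", fixed = TRUE)[[1L]]
  first <- v[seq_len(n)]
  cand <- which(first == min(first))   # 1-based start positions
  k <- 0L
  while (length(cand) > 1L && k < n - 1L) {
    k <- k + 1L
    ch <- v[cand + k]
    cand <- cand[ch == min(ch)]
  }
  cand[1L] - 1L
}

#' Canonical form of a circular sequence: the lexicographically minimal
#' rotation over both strands.
#' @noRd
canonical_circular <- function(seq) {
  a <- circ_substr(seq, least_rotation(seq), nchar(seq))
  rc <- revcomp(seq)
  b <- circ_substr(rc, least_rotation(rc), nchar(rc))
  if (a <= b) a else b
}

#' Count occurrences of `pattern` (fixed string) in `subject`, overlapping.
#' @noRd
count_fixed <- function(subject, pattern) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) return(0L)
  length(Biostrings::matchPattern(pattern, Biostrings::DNAString(subject)))
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Evaluate code under a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
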