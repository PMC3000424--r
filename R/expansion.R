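# Training-data expansion: fragment full-length proteins into EST-like
# pieces and reduce redundancy by greedy identity clustering, emulating a
# CD-hit run at desk scale with exhaustive Smith-Waterman identities.

#' Fragmentation policy
#'
#' Length rules for breaking full-length proteins into EST-like fragments:
#' proteins shorter than `short_threshold` stay unchanged; those between
#' `short_threshold` and `long_threshold` yield an N-terminal and a
#' C-terminal fragment; longer ones additionally yield a central fragment.
#' Fragment lengths are drawn uniformly from `[min_len, max_len]`
#' (140-260 residues, the EST length survey's mean ~600 nt, SD ~180 nt,
#' divided by 3).  The N-terminal fragment starts within
#' `nterm_anchor_window` residues downstream of the first methionine.
#'
#' @param min_len,max_len fragment length range in residues.
#' @param short_threshold,long_threshold length class boundaries.
#' @param nterm_anchor_window N-terminal start window.
#' @return Object of class `fragmentation_policy`.
#' @export
fragmentation_policy <- function(min_len = 140L, max_len = 260L,
                                 short_threshold = 200L,
                                 long_threshold = 400L,
                                 nterm_anchor_window = 80L) {
  stopifnot(min_len < max_len, short_threshold < long_threshold)
  structure(list(min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 short_threshold = as.integer(short_threshold),
                 long_threshold = as.integer(long_threshold),
                 nterm_anchor_window = as.integer(nterm_anchor_window)),
            class = "fragmentation_policy")
}

runif_int <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (hi <= lo) return(lo)
  lo + floor(runif(1) * (hi - lo + 1L))
}

#' Fragment one full-length protein into EST-like pieces
#'
#' Applies the piecewise length rules of the policy (see
#' [fragmentation_policy()]).  The N-terminal fragment starts at a
#' uniform-random offset within the anchor window downstream of the first
#' methionine (position 1 when the sequence has none); the C-terminal
#' fragment ends at the last residue; the central fragment (long proteins
#' only) starts strictly after the anchor window and strictly before the
#' middle of the sequence.  Fragment lengths are clipped to the available
#' residues; labels are inherited and ids suffixed `_N`, `_M`, `_C`.
#' Uses the current RNG state — seed with [withr::with_seed()] or via
#' [expand_dataset()].
#'
#' @param rec one-row `peptide_set`.
#' @param policy a `fragmentation_policy`.
#' @return A `peptide_set` of 1-3 fragments (`source = "fragment"` for
#'   fragmented output; a short protein is returned unchanged).
#' @export
fragment_protein <- function(rec, policy = fragmentation_policy()) {
  stopifnot(nrow(rec) == 1L)
  s <- rec$sequence
  L <- nchar(s)
  if (L < policy$short_threshold) {
    return(peptide_set(rec$id, s, label = rec$label, source = rec$source))
  }
  draw_len <- function() runif_int(policy$min_len, policy$max_len)
  first_m <- regexpr("M", s, fixed = TRUE)
  anchor <- if (first_m > 0L) as.integer(first_m) else 1L
  # N-terminal: start within the anchor window downstream of the first M
  n_start <- runif_int(anchor, min(anchor + policy$nterm_anchor_window - 1L, L))
  n_end <- min(n_start + draw_len() - 1L, L)
  # C-terminal: ends at the last residue
  c_len <- draw_len()
  c_start <- max(1L, L - c_len + 1L)
  starts <- c(n_start, c_start)
  ends <- c(n_end, L)
  suffix <- c("_N", "_C")
  if (L > policy$long_threshold) {
    # central: start in the open interval (anchor window, middle)
    lo <- policy$nterm_anchor_window + 1L
    hi <- max(lo, L %/% 2L - 1L)
    m_start <- runif_int(lo, hi)
    m_end <- min(m_start + draw_len() - 1L, L)
    starts <- c(starts[1], m_start, starts[2])
    ends <- c(ends[1], m_end, ends[2])
    suffix <- c("_N", "_M", "_C")
  }
  peptide_set(paste0(rec$id, suffix),
              substring(s, starts, ends),
              label = rec$label, source = "fragment")
}

#' Percent identity between two peptides
#'
#' Identical positions in the best Smith-Waterman local alignment
#' (match +1, mismatch -1, gap open -2, gap extend -1) divided by the
#' length of the shorter sequence, times 100 — the short-sequence-normalized
#' identity notion greedy clustering tools use.
#'
#' @param a,b cleaned peptide strings.
#' @return Symmetric percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  if (a == b) return(100)
  sub_mat <- local_substitution_matrix()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = sub_mat, gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b)) * 100
}

local_substitution_matrix <- function() {
  m <- matrix(-1, 20, 20, dimnames = list(AMINO_ACIDS, AMINO_ACIDS))
  diag(m) <- 1
  m
}

#' Greedy redundancy reduction at an identity threshold
#'
#' Emulates greedy incremental clustering: records are visited by
#' decreasing length (ties by input order) and kept only when their
#' identity to every already-kept record is at or below the threshold.
#' Exhaustive pairwise checking replaces the word filter of the original
#' tool — fine at desk scale.  Deterministic.
#'
#' @param records a `peptide_set`.
#' @param threshold maximum allowed percent identity (default 60).
#' @return The kept records, in kept (decreasing-length) order.
#' @export
reduce_redundancy <- function(records, threshold = 60) {
  ord <- order(-nchar(records$sequence))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (pairwise_identity(records$sequence[i],
                            records$sequence[j]) > threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- records[kept, , drop = FALSE]
  class(out) <- c("peptide_set", "data.frame")
  rownames(out) <- NULL
  out
}

#' Expand a scarce EST-peptide training set
#'
#' Fragments every full-length protein with [fragment_protein()], pools the
#' fragments with the EST-derived peptides, and removes redundancy with
#' [reduce_redundancy()].  Per-class counts of the result are logged.
#'
#' @param full_length labeled `peptide_set` of full-length proteins.
#' @param est_peptides labeled `peptide_set` of EST-derived peptides.
#' @param policy a `fragmentation_policy`.
#' @param threshold identity threshold for clustering (percent).
#' @param seed RNG seed; the same seed reproduces the dataset byte-for-byte.
#' @return Expanded, labeled, redundancy-reduced `peptide_set`.
#' @export
expand_dataset <- function(full_length, est_peptides,
                           policy = fragmentation_policy(),
                           threshold = 60, seed = 1L) {
  if ((nrow(full_length) && any(is.na(full_length$label))) ||
      (nrow(est_peptides) && any(is.na(est_peptides$label)))) {
    stop("all records must be labeled")
  }
  frags <- withr::with_seed(seed, {
    parts <- lapply(seq_len(nrow(full_length)), function(i) {
      fragment_protein(full_length[i, , drop = FALSE], policy)
    })
    if (length(parts)) do.call(rbind, parts) else NULL
  })
  pool <- if (is.null(frags)) est_peptides else rbind(frags, est_peptides)
  class(pool) <- c("peptide_set", "data.frame")
  out <- reduce_redundancy(pool, threshold = threshold)
  peploc_log("expanded dataset per-class counts: ",
             paste(sprintf("%s=%d", names(table(out$label)),
                           as.integer(table(out$label))), collapse = " "))
  out
}
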