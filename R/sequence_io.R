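# Sequence input/output, cleaning, reduced-alphabet recoding, and a
# plumbing-level six-frame translation heuristic for nucleotide ESTs.

#' Construct a peptide set
#'
#' A peptide set is a plain `data.frame` with one row per (possibly partial)
#' amino-acid sequence and columns `id`, `sequence`, `label` (one of the nine
#' compartment codes in [COMPARTMENTS], or `NA`) and `source` (one of
#' `"est_derived"`, `"fragment"`, `"full_length"`, `"synthetic"`).
#'
#' @param id character vector of unique sequence identifiers.
#' @param sequence character vector of cleaned amino-acid sequences
#'   (see [clean_sequence()]).
#' @param label optional compartment codes; `NA` for unlabeled records.
#' @param source provenance tag, recycled to length.
#' @return A `data.frame` of class `peptide_set`.
#' @examples
#' peptide_set(c("a", "b"), c("MKV", "MAAG"), label = c("mit", "chl"))
#' @export
peptide_set <- function(id, sequence, label = NA_character_,
                        source = "est_derived") {
  stopifnot(length(id) == length(sequence))
  ps <- data.frame(id = as.character(id),
                   sequence = as.character(sequence),
                   label = rep_len(as.character(label), length(id)),
                   source = rep_len(as.character(source), length(id)),
                   stringsAsFactors = FALSE)
  validate_peptide_set(ps)
  class(ps) <- c("peptide_set", "data.frame")
  ps
}

validate_peptide_set <- function(ps) {
  if (anyDuplicated(ps$id)) {
    stop("duplicate sequence ids: ",
         paste(unique(ps$id[duplicated(ps$id)]), collapse = ", "))
  }
  if (any(!nzchar(ps$sequence))) stop("empty sequences are not allowed")
  bad <- !is.na(ps$label) & !(ps$label %in% COMPARTMENTS)
  if (any(bad)) {
    stop("invalid compartment code(s): ",
         paste(unique(ps$label[bad]), collapse = ", "),
         "; allowed codes: ", paste(COMPARTMENTS, collapse = ", "))
  }
  ok_src <- c("est_derived", "fragment", "full_length", "synthetic")
  if (any(!ps$source %in% ok_src)) stop("invalid source tag")
  invisible(ps)
}

#' Clean a raw peptide string
#'
#' Uppercases, strips a terminal stop symbol `*`, and removes every character
#' outside the 20-letter amino-acid alphabet (ambiguity codes B/J/X/Z, the
#' non-canonical residues U/O, gap and whitespace characters).  The number of
#' removed characters is attached as attribute `n_removed` and logged, so
#' heavily corrupted reads can be filtered downstream.
#'
#' @param raw character scalar.
#' @return Cleaned sequence with attribute `n_removed`.
#' @examples
#' clean_sequence("mkAav*")   # "MKAAV"
#' @export
clean_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- toupper(raw)
  s <- sub("\\*+$", "", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  keep <- chars %in% AMINO_ACIDS
  n_removed <- sum(!keep)
  out <- paste(chars[keep], collapse = "")
  if (!nzchar(out)) stop("no usable residues after cleaning")
  if (n_removed > 0L) {
    peploc_log(n_removed, " non-standard character(s) removed")
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Read a peptide FASTA file into a peptide set
#'
#' Sequences are cleaned with [clean_sequence()].  When a label table is
#' given (two-column TSV: id, compartment code; `#` comments allowed),
#' labels are joined by id.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param labels optional path to a label table.
#' @param source provenance tag for the records.
#' @return A `peptide_set`.
#' @export
read_fasta <- function(path, labels = NULL, source = "est_derived") {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("malformed FASTA in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (length(aa) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- vapply(as.character(aa), function(s) as.character(clean_sequence(s)),
                 character(1), USE.NAMES = FALSE)
  lab <- NA_character_
  if (!is.null(labels)) {
    lt <- read_label_table(labels)
    lab <- lt[ids]
    missing <- ids[is.na(lab) & !(ids %in% names(lt))]
    if (length(missing)) {
      peploc_log(length(missing), " record(s) without a label entry",
                 level = "warn")
    }
  }
  peptide_set(ids, seqs, label = lab, source = source)
}

#' Read a two-column (id, compartment code) label table
#' @param path TSV file; lines starting with `#` are ignored.
#' @return Named character vector mapping id to code.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("label table must have two columns (id, code)")
  codes <- trimws(tab[[2]])
  bad <- !(codes %in% COMPARTMENTS)
  if (any(bad)) {
    stop("invalid compartment code(s) in label table: ",
         paste(unique(codes[bad]), collapse = ", "),
         "; allowed codes: ", paste(COMPARTMENTS, collapse = ", "))
  }
  setNames(codes, trimws(tab[[1]]))
}

#' Write a peptide set to FASTA (and optionally a label table)
#'
#' @param records a `peptide_set`.
#' @param path output FASTA path.
#' @param labels_path optional path for a 2-column TSV of the labeled records.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, labels_path = NULL) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, filepath = path)
  if (!is.null(labels_path)) {
    lab <- records[!is.na(records$label), c("id", "label")]
    write.table(lab, labels_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# ---- reduced alphabets ----------------------------------------------------

# Group C: 8 chemical-property groups.
.GROUP_C <- c(
  D = "a", E = "a",                      # acidic
  H = "b", K = "b", R = "b",             # basic
  F = "r", W = "r", Y = "r",             # aromatic
  S = "h", T = "h",                      # small hydroxyl
  C = "s", M = "s",                      # sulphur-containing
  A = "1", G = "1", P = "1",             # aliphatic 1
  I = "2", L = "2", V = "2",             # aliphatic 2
  N = "n", Q = "n")                      # amide

# Group D: 10 structural groups.
.GROUP_D <- c(
  G = "0", A = "0",                      # monoamino monocarboxylic
  V = "1", L = "1", I = "1",             # ... unsubstituted
  P = "2", F = "2",                      # ... heterocyclic
  W = "3", Y = "3",                      # ... aromatic
  M = "4",                               # ... thioether
  S = "5", T = "5",                      # ... hydroxy
  C = "6",                               # ... mercapto
  N = "7", Q = "7",                      # ... carboxamide
  D = "8", E = "8",                      # monoamino dicarboxylic
  H = "9", K = "9", R = "9")             # diamino monocarboxylic

#' Reduced amino-acid alphabets
#'
#' Returns one of the three alphabets used for composition features:
#' `ungrouped` (identity, 20 symbols), `groupC` (8 chemical-property
#' groups: acidic, basic, aromatic, small-hydroxyl, sulphur-containing, two
#' aliphatic groups, amide) or `groupD` (10 structural groups).
#'
#' @param name one of `"ungrouped"`, `"groupC"`, `"groupD"`.
#' @return An object of class `alphabet_map` with elements `name`,
#'   `mapping` (named character vector over the 20 residues), `symbols`
#'   (the distinct group symbols, in fixed order) and `size`.
#' @examples
#' alphabet("groupC")$size  # 8
#' @export
alphabet <- function(name = c("ungrouped", "groupC", "groupD")) {
  name <- match.arg(name)
  mapping <- switch(name,
    ungrouped = setNames(AMINO_ACIDS, AMINO_ACIDS),
    groupC = .GROUP_C[AMINO_ACIDS],
    groupD = .GROUP_D[AMINO_ACIDS])
  names(mapping) <- AMINO_ACIDS
  symbols <- unique(unname(mapping))
  structure(list(name = name, mapping = mapping, symbols = symbols,
                 size = length(symbols)),
            class = "alphabet_map")
}

#' Recode a cleaned peptide into a reduced alphabet
#'
#' @param seq cleaned amino-acid string.
#' @param alpha an `alphabet_map` from [alphabet()].
#' @return String of the same length over the alphabet's group symbols.
#' @examples
#' recode("GAVLI", alphabet("groupD"))
#' @export
recode <- function(seq, alpha) {
  stopifnot(inherits(alpha, "alphabet_map"))
  bad <- setdiff(strsplit(seq, "")[[1]], names(alpha$mapping))
  if (length(bad)) {
    stop("internal error: residue(s) not in alphabet: ",
         paste(bad, collapse = ", "), " (sequence not cleaned?)")
  }
  chartr(paste(names(alpha$mapping), collapse = ""),
         paste(alpha$mapping, collapse = ""), seq)
}

# ---- frame translation (plumbing heuristic) -------------------------------

#' Six-frame translation heuristic for nucleotide ESTs
#'
#' A deliberately simple stand-in for a proper EST ORF predictor: translates
#' all six frames with the standard genetic code and returns the longest
#' stop-free translated stretch, ties broken by frame order
#' (+1, +2, +3, -1, -2, -3).  This is labeled plumbing: it knows nothing
#' about coding bias or similarity evidence and should only be used when no
#' real ORF prediction is available.
#'
#' @param nt_seq nucleotide string over A, C, G, T, N.
#' @param min_codons minimum acceptable stretch length (default 10 codons).
#' @return Peptide string; attribute `frame` gives the winning frame.
#' @export
best_frame_translate <- function(nt_seq, min_codons = 10L) {
  stopifnot(is.character(nt_seq), length(nt_seq) == 1L)
  s <- toupper(gsub("\\s", "", nt_seq))
  if (grepl("[^ACGTN]", s)) stop("nucleotide sequence contains characters outside A/C/G/T/N")
  dna <- Biostrings::DNAString(s)
  frames <- list(`+1` = dna, `+2` = NULL, `+3` = NULL)
  rc <- Biostrings::reverseComplement(dna)
  frame_seq <- function(x, off) {
    n <- length(x) - off
    if (n < 3L) return(NULL)
    Biostrings::subseq(x, start = off + 1L, width = n - n %% 3L)
  }
  frame_names <- c("+1", "+2", "+3", "-1", "-2", "-3")
  best <- NULL
  best_len <- -1L
  for (fi in seq_along(frame_names)) {
    src <- if (fi <= 3L) dna else rc
    fs <- frame_seq(src, (fi - 1L) %% 3L)
    if (is.null(fs)) next
    pep <- suppressWarnings(as.character(
      Biostrings::translate(fs, if.fuzzy.codon = "X")))
    # longest run without a stop; X (fuzzy codons from N) also breaks a run
    stretches <- strsplit(pep, "[*X]+")[[1]]
    if (!length(stretches)) next
    w <- which.max(nchar(stretches))
    if (nchar(stretches[w]) > best_len) {
      best_len <- nchar(stretches[w])
      best <- structure(stretches[w], frame = frame_names[fi])
    }
  }
  if (is.null(best) || best_len < min_codons) {
    stop("no plausible ORF: no stop-free stretch of at least ",
         min_codons, " codons in any frame")
  }
  peploc_log("heuristic frame translation used (frame ", attr(best, "frame"),
             "); this is not ORF prediction", level = "warn")
  best
}
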