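# The four feature families used to represent EST-peptides: physicochemical
# AAindex summaries, k-th order amino-acid composition on the ungrouped and
# the two reduced alphabets, and gapped pair composition; plus the fixed
# registry of the 41 representations and the tetra-peptide motif audit.

# ---- AAindex --------------------------------------------------------------

# Residue order of the two numeric rows following an AAindex1 "I" line.
.AAINDEX_ROW1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
.AAINDEX_ROW2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load an AAindex1 flat file
#'
#' Parses the classic AAindex1 format: each entry starts with an `H <id>`
#' accession line, its numeric values follow an `I` line as two rows of ten
#' (order A R N D C Q E G H I / L K M F P S T W Y V), and entries end with
#' `//`.  `NA` values are recorded as missing for that residue.
#'
#' @param path AAindex1-format file.
#' @return Object of class `aaindex_table`: list with `entries` (named list
#'   of per-residue numeric vectors) and `count`.
#' @export
load_aaindex <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  i <- 1L
  cur_id <- NULL
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "H ")) {
      cur_id <- trimws(substring(ln, 3L))
    } else if (startsWith(ln, "I ") || ln == "I") {
      if (is.null(cur_id)) stop("I-block before any H record at line ", i)
      if (i + 2L > length(lines)) stop("truncated I-block for index ", cur_id)
      vals <- suppressWarnings(as.numeric(unlist(
        strsplit(trimws(lines[c(i + 1L, i + 2L)]), "\\s+"))))
      if (length(vals) != 20L) {
        stop("unparseable I-block for index ", cur_id,
             ": expected 20 values, got ", length(vals))
      }
      v <- setNames(vals, c(.AAINDEX_ROW1, .AAINDEX_ROW2))
      entries[[cur_id]] <- v[!is.na(v)]
      i <- i + 2L
    }
    i <- i + 1L
  }
  if (!length(entries)) stop("no AAindex entries found in ", path)
  structure(list(entries = entries, count = length(entries)),
            class = "aaindex_table")
}

#' Physicochemical feature vector of a peptide
#'
#' For each amino-acid index, the index value is summed over the residues of
#' the sequence and normalized.  Residues for which an index has no value
#' (`NA` in the source file) are excluded from both the sum and the
#' denominator, so each index is normalized by the number of residues it
#' actually covers; an index covering no residue of the sequence yields 0.
#'
#' @param seq cleaned peptide string.
#' @param table an `aaindex_table` from [load_aaindex()].
#' @return Named numeric vector, one value per index (dimension
#'   `table$count`), with attributes `spec = "aaindex"` and `dimension`.
#' @export
aaindex_features <- function(seq, table) {
  stopifnot(inherits(table, "aaindex_table"), nzchar(seq))
  counts <- table(factor(strsplit(seq, "")[[1]], levels = AMINO_ACIDS))
  counts <- as.numeric(counts)
  names(counts) <- AMINO_ACIDS
  vals <- vapply(table$entries, function(v) {
    cc <- counts[names(v)]
    denom <- sum(cc)
    if (denom == 0) {
      peploc_log("index covers no residue of the sequence; value set to 0",
                 level = "warn")
      return(0)
    }
    sum(v * cc) / denom
  }, numeric(1))
  structure(vals, spec = "aaindex", dimension = table$count)
}

# ---- composition families -------------------------------------------------

all_kmers <- function(symbols, k) {
  ks <- symbols
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      ks <- as.vector(outer(ks, symbols, paste0))
    }
  }
  sort(ks)
}

sparse_or_full <- function(counts, total, spec_name, dimension,
                           symbols = NULL, k = NULL) {
  # Enumerate the full key space for small dimensions (deterministic dense
  # layout); keep only observed keys, sorted, for the huge spaces.
  if (!is.null(symbols) && dimension <= 10000L) {
    keys <- all_kmers(symbols, k)
    v <- setNames(numeric(length(keys)), keys)
    v[names(counts)] <- counts / total
  } else {
    v <- sort_by_name(counts / total)
  }
  structure(v, spec = spec_name, dimension = dimension)
}

sort_by_name <- function(x) {
  if (!length(x)) return(setNames(numeric(0), character(0)))
  x[order(names(x), method = "radix")]
}

#' k-th order composition of a peptide
#'
#' Recodes the sequence into the given alphabet, counts all overlapping
#' k-mers, and divides each count by the number of windows, L - k + 1.
#' Sequences shorter than k yield a zero vector with a warning rather than
#' an error, because genuine EST-peptides vary widely in length.
#'
#' @param seq cleaned peptide string.
#' @param alpha an `alphabet_map`.
#' @param k order (1..6 ungrouped, 1..8 for the reduced alphabets).
#' @return Named numeric vector over k-mer keys; for dimensions up to
#'   10,000 the full key space is enumerated, larger spaces are sparse
#'   (absent keys are zero).  Values sum to 1 for non-degenerate input.
#' @examples
#' kmer_composition("AAG", alphabet("ungrouped"), k = 2)
#' @export
kmer_composition <- function(seq, alpha, k) {
  stopifnot(inherits(alpha, "alphabet_map"), k >= 1L)
  rs <- recode(seq, alpha)
  L <- nchar(rs)
  spec_name <- sprintf("comp_%s_k%d", alpha$name, k)
  dimension <- as.numeric(alpha$size)^k
  if (L < k) {
    peploc_log("sequence shorter than k = ", k, "; zero vector returned",
               level = "warn")
    return(sparse_or_full(numeric(0), 1, spec_name, dimension,
                          alpha$symbols, k))
  }
  kmers <- substring(rs, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  counts <- table(kmers)
  sparse_or_full(setNames(as.numeric(counts), names(counts)), L - k + 1L,
                 spec_name, dimension, alpha$symbols, k)
}

#' Gapped pair composition of a peptide
#'
#' Frequency of ordered symbol pairs separated by exactly `x` intervening
#' residues: pairs (position i, position i + x + 1), i = 1 .. L - x - 1,
#' normalized by the pair count L - x - 1.  Dimension is |alphabet| squared.
#'
#' @param seq cleaned peptide string.
#' @param alpha an `alphabet_map`.
#' @param x gap length, 1..6.
#' @return Named numeric vector over two-symbol keys.
#' @export
gapped_composition <- function(seq, alpha, x) {
  stopifnot(inherits(alpha, "alphabet_map"), x >= 1L)
  rs <- recode(seq, alpha)
  L <- nchar(rs)
  spec_name <- sprintf("gap_%s_x%d", alpha$name, x)
  dimension <- as.numeric(alpha$size)^2
  n_pairs <- L - x - 1L
  if (n_pairs < 1L) {
    peploc_log("sequence too short for gap ", x, "; zero vector returned",
               level = "warn")
    return(sparse_or_full(numeric(0), 1, spec_name, dimension,
                          alpha$symbols, 2L))
  }
  ch <- strsplit(rs, "")[[1]]
  pairs <- paste0(ch[seq_len(n_pairs)], ch[seq_len(n_pairs) + x + 1L])
  counts <- table(pairs)
  sparse_or_full(setNames(as.numeric(counts), names(counts)), n_pairs,
                 spec_name, dimension, alpha$symbols, 2L)
}

# ---- registry -------------------------------------------------------------

feature_spec <- function(family, alphabet_name = NA_character_,
                         k = NA_integer_, x = NA_integer_, dimension) {
  name <- switch(family,
    aaindex = "aaindex",
    composition = sprintf("comp_%s_k%d", alphabet_name, k),
    gapped = sprintf("gap_%s_x%d", alphabet_name, x),
    stop("unknown feature family: ", family))
  structure(list(name = name, family = family, alphabet = alphabet_name,
                 k = k, x = x, dimension = dimension),
            class = "feature_spec")
}

#' The registry of the 41 feature representations
#'
#' Fixed, documented order: 1 AAindex summary; ungrouped composition
#' k = 1..6; group-C composition k = 1..8; group-D composition k = 1..8;
#' gapped composition x = 1..6 for each of ungrouped, group C, group D
#' (1 + 6 + 8 + 8 + 18 = 41).  The order is frozen so that concatenated and
#' stacked meta-vectors are reproducible across runs.
#'
#' @param table an `aaindex_table` (sets the AAindex spec's dimension), or
#'   `NULL` to default the AAindex dimension to 494.
#' @return Named list of 41 `feature_spec` objects.
#' @export
build_feature_registry <- function(table = NULL) {
  n_idx <- if (is.null(table)) 494L else table$count
  specs <- list(feature_spec("aaindex", dimension = n_idx))
  for (k in 1:6) {
    specs <- c(specs, list(feature_spec("composition", "ungrouped", k = k,
                                        dimension = 20^k)))
  }
  for (a in c("groupC", "groupD")) {
    sz <- alphabet(a)$size
    for (k in 1:8) {
      specs <- c(specs, list(feature_spec("composition", a, k = k,
                                          dimension = as.numeric(sz)^k)))
    }
  }
  for (a in c("ungrouped", "groupC", "groupD")) {
    sz <- alphabet(a)$size
    for (x in 1:6) {
      specs <- c(specs, list(feature_spec("gapped", a, x = x,
                                          dimension = as.numeric(sz)^2)))
    }
  }
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Extract one feature representation from a peptide
#'
#' Dispatches to the family-specific operation of `spec`.
#'
#' @param seq cleaned peptide string.
#' @param spec a `feature_spec` from [build_feature_registry()].
#' @param table an `aaindex_table`; required for the AAindex spec.
#' @return Named numeric feature vector (see the family functions).
#' @export
extract_features <- function(seq, spec, table = NULL) {
  stopifnot(inherits(spec, "feature_spec"))
  switch(spec$family,
    aaindex = {
      if (is.null(table)) stop("AAindex features require an aaindex_table")
      aaindex_features(seq, table)
    },
    composition = kmer_composition(seq, alphabet(spec$alphabet), spec$k),
    gapped = gapped_composition(seq, alphabet(spec$alphabet), spec$x),
    stop("unknown feature family: ", spec$family))
}

#' Build the feature matrix of a peptide set
#'
#' Rows are records, columns the union of observed feature keys (sorted;
#' or the full enumerated key space for small dimensions).  Sparse.
#'
#' @param records a `peptide_set`.
#' @param spec a `feature_spec`.
#' @param table an `aaindex_table` (AAindex spec only).
#' @param keys optional fixed column key set (e.g. a trained model's); keys
#'   of the data not in `keys` are dropped.
#' @return A `dgCMatrix` with rownames = record ids.
#' @export
feature_matrix <- function(records, spec, table = NULL, keys = NULL) {
  vecs <- lapply(records$sequence, extract_features, spec = spec,
                 table = table)
  if (is.null(keys)) {
    keys <- sort_keys_union(vecs)
  }
  key_index <- seq_along(keys)
  names(key_index) <- keys
  ijx <- lapply(seq_along(vecs), function(i) {
    v <- vecs[[i]]
    nz <- which(v != 0)
    j <- key_index[names(v)[nz]]
    ok <- !is.na(j)
    cbind(i = rep.int(i, sum(ok)), j = j[ok], x = as.numeric(v[nz][ok]))
  })
  ijx <- do.call(rbind, ijx)
  m <- Matrix::sparseMatrix(i = ijx[, 1], j = ijx[, 2], x = ijx[, 3],
                            dims = c(length(vecs), length(keys)),
                            dimnames = list(records$id, keys))
  methods::as(m, "CsparseMatrix")
}

sort_keys_union <- function(vecs) {
  first <- vecs[[1]]
  if (!is.null(attr(first, "dimension")) &&
      length(first) == attr(first, "dimension")) {
    return(names(first))  # full enumerated key space, already canonical
  }
  sort(unique(unlist(lapply(vecs, names))), method = "radix")
}

# ---- tetra-peptide audit --------------------------------------------------

#' Audit the tetra-peptide motifs of a labeled dataset
#'
#' Enumerates all overlapping tetra-peptides (ungrouped alphabet) and
#' reports how motif occurrences distribute over compartment classes: the
#' total occurrence count (sum of max(L - 3, 0) over records), the number
#' of distinct motifs, how many occur in exactly one class, how many are
#' absent from exactly one class, and each motif's maximal within-class
#' prevalence (the fraction of a class's members containing it).
#'
#' @param records a fully labeled `peptide_set`.
#' @return List with `total_occurrences`, `n_distinct`, `n_single_class`,
#'   `n_absent_from_one_class`, and `motifs`, a data.frame with columns
#'   motif, n_classes, best_class, prevalence.
#' @export
tetrapeptide_audit <- function(records) {
  if (any(is.na(records$label))) stop("all records must be labeled")
  L <- nchar(records$sequence)
  total <- sum(pmax(L - 3L, 0L))
  per_rec <- lapply(seq_len(nrow(records)), function(i) {
    if (L[i] < 4L) return(character(0))
    unique(substring(records$sequence[i], seq_len(L[i] - 3L),
                     seq_len(L[i] - 3L) + 3L))
  })
  n_rec <- lengths(per_rec)
  df <- data.frame(motif = unlist(per_rec),
                   class = rep(records$label, n_rec),
                   stringsAsFactors = FALSE)
  classes <- sort(unique(records$label))
  class_sizes <- table(factor(records$label, levels = classes))
  # members of each class containing each motif
  inc <- table(df$motif, factor(df$class, levels = classes))
  n_classes_per_motif <- rowSums(inc > 0)
  prev <- sweep(unclass(inc), 2, as.numeric(class_sizes), "/")
  best <- max.col(prev, ties.method = "first")
  motifs <- data.frame(motif = rownames(inc),
                       n_classes = as.integer(n_classes_per_motif),
                       best_class = classes[best],
                       prevalence = prev[cbind(seq_len(nrow(prev)), best)],
                       stringsAsFactors = FALSE, row.names = NULL)
  list(total_occurrences = total,
       n_distinct = nrow(motifs),
       n_single_class = sum(motifs$n_classes == 1L),
       n_absent_from_one_class = sum(motifs$n_classes == length(classes) - 1L),
       motifs = motifs)
}
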