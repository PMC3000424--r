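# Shared fixtures, all built in code at test time.

random_peptide <- function(n, prob = NULL) {
  paste(sample(AMINO_ACIDS, n, replace = TRUE, prob = prob), collapse = "")
}

tmp_fasta <- function(ids, seqs, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = envir)
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

tmp_labels <- function(ids, codes, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = envir)
  writeLines(c("# id\tcode", paste(ids, codes, sep = "\t")), path)
  path
}

# small aaindex fixture shared across tests (3 entries, known values)
tmp_aaindex_known <- function(envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = envir)
  rows <- function(v) c(paste0("   ", paste(sprintf("%7s", v[1:10]), collapse = " ")),
                        paste0("   ", paste(sprintf("%7s", v[11:20]), collapse = " ")))
  # order: A R N D C Q E G H I / L K M F P S T W Y V
  idx1 <- rep("1.000", 20)                      # constant index
  idx2 <- rep("0.000", 20); idx2[1] <- "2.000"; idx2[8] <- "4.000"  # A=2, G=4
  idx3 <- rep("NA", 20); idx3[1] <- "2.000"     # defined only for A
  writeLines(c("H CONST1", "D constant", "I A/L", rows(idx1), "//",
               "H AG0001", "D A and G", "I A/L", rows(idx2), "//",
               "H ONLYA1", "D only A", "I A/L", rows(idx3), "//"), path)
  path
}

# 2-D gaussian point clouds as a sparse feature matrix
toy_clouds <- function(n_per_class, centers, sd = 0.6, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(centers, function(ctr) {
      cbind(rnorm(n_per_class, ctr[1], sd), rnorm(n_per_class, ctr[2], sd))
    }))
    colnames(x) <- c("f1", "f2")
    y <- rep(names(centers), each = n_per_class)
    list(x = x, y = y)
  })
}
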