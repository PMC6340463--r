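# Shared codon utilities. Sequences are strings over A,C,G,T, IUPAC
# ambiguity codes, '-' (gap) and 'N'/'?' (missing). A codon is "missing" for
# a species if it is not a complete, unambiguous ACGT triplet.

.MISSING_CHARS <- c("-", "N", "?")

# split equal-length CDS strings into a codon matrix (species x codon)
.codon_matrix <- function(seqs) {
  seqs <- toupper(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences differ in length: ",
         paste(range(nchar(seqs)), collapse = " vs "))
  if (L %% 3L != 0L) stop("sequence length ", L, " is not divisible by 3")
  n <- L / 3L
  starts <- seq(1L, L, by = 3L)
  m <- matrix(vapply(seqs, function(s) substring(s, starts, starts + 2L),
                     character(n)),
              nrow = n, ncol = length(seqs))
  t(structure(m, dimnames = list(NULL, names(seqs))))
}

# translate a codon character vector; NA for missing/ambiguous codons
.translate_codons <- function(codons, code = NULL) {
  code <- .genetic_code(code)
  aa <- unname(code[codons])
  # pure-ACGT codons must translate; anything else is treated as missing (NA)
  invalid <- is.na(aa) & grepl("^[ACGT]{3}$", codons)
  if (any(invalid))
    stop("untranslatable ACGT codon(s): ",
         paste(unique(codons[invalid]), collapse = ", "))
  aa
}

# is each codon missing (gap/ambiguity/incomplete)?
.codon_missing <- function(codons) !grepl("^[ACGT]{3}$", toupper(codons))

# prefixes (first two bases) whose codon family is fourfold degenerate
.fourfold_prefixes <- function(code = NULL) {
  code <- .genetic_code(code)
  prefixes <- unique(substr(names(code), 1, 2))
  keep <- vapply(prefixes, function(p) {
    aa <- code[paste0(p, c("A", "C", "G", "T"))]
    length(unique(aa)) == 1L
  }, logical(1))
  prefixes[keep]
}

#' Read / write per-gene FASTA codon alignments
#'
#' `read_codon_alignments()` reads every `*.fasta`/`*.fa` file in a
#' directory (or an explicit vector of files) into a codon-alignment set:
#' a named list (gene id = file base name) of named character vectors of
#' equal-length sequences. `write_codon_alignments()` writes one FASTA per
#' gene.
#'
#' @param path Directory containing FASTA files, or a character vector of
#'   file paths.
#' @return A named list of named character vectors.
#' @export
read_codon_alignments <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  else path
  if (!length(files)) stop("no FASTA files found")
  out <- lapply(files, function(f) {
    x <- Biostrings::readBStringSet(f)
    setNames(as.character(x), names(x))
  })
  names(out) <- sub("\\.(fa|fasta)$", "", basename(files))
  out
}

#' @rdname read_codon_alignments
#' @param alignments A named list of named character vectors.
#' @param dir Output directory (created if absent).
#' @export
write_codon_alignments <- function(alignments, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in names(alignments)) {
    x <- Biostrings::BStringSet(alignments[[g]])
    Biostrings::writeXStringSet(x, file.path(dir, paste0(g, ".fasta")))
  }
  invisible(dir)
}
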