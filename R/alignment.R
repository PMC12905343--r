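#' Alignment containers
#'
#' A `paas_aln` is a character matrix (taxa in rows, sites in columns) with an
#' `alphabet` attribute. For `"amino20"` and `"nucleotide4"` each cell is a
#' single residue; for `"codon"` each cell is a three-letter codon, so the
#' number of columns is the number of codon sites. Gaps (`-`) and ambiguity
#' codes (`X`/`N`/`?`) are treated as missing data throughout: they contribute
#' a flat partial likelihood and never generate substitution events.
#'
#' @param x character matrix, rows named by taxon.
#' @param alphabet one of `"amino20"`, `"codon"`, `"nucleotide4"`.
#' @return a validated `paas_aln` object.
#' @export
paas_alignment <- function(x, alphabet = c("amino20", "codon", "nucleotide4")) {
  alphabet <- match.arg(alphabet)
  if (!is.matrix(x) || !is.character(x))
    stop("alignment must be a character matrix")
  if (is.null(rownames(x)) || anyNA(rownames(x)))
    stop("alignment rows must be named by taxon")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicate taxon id(s): ", paste(unique(dup), collapse = ", "))
  x[] <- toupper(x)
  validate_chars(x, alphabet)
  structure(x, alphabet = alphabet, class = c("paas_aln", "matrix", "array"))
}

NT_STATES <- c("A", "C", "G", "T")
MISSING_AA <- c("-", "X", "?", ".")
MISSING_NT <- c("-", "N", "?", ".")

#' Sense codons of the standard genetic code
#'
#' @return character vector of the 61 stop-free codons, in lexicographic
#'   order; names give the encoded amino acid (one-letter).
#' @export
codon_states <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  codons <- sort(names(sense))
  setNames(codons, NULL) -> out
  names(out) <- unname(sense[codons])
  out
}

#' Translate codons to amino acids
#'
#' @param codons character vector of codons; codons containing gap or
#'   ambiguity characters translate to `NA`.
#' @return character vector of one-letter amino acids (`"*"` for stops).
#' @export
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  out <- unname(gc[codons])
  out[is.na(out) & !is.na(codons)] <- NA_character_
  out
}

alphabet_states <- function(alphabet) {
  switch(alphabet,
    amino20 = AA_STATES,
    nucleotide4 = NT_STATES,
    codon = unname(codon_states()),
    stop("unknown alphabet: ", alphabet)
  )
}

is_missing_cell <- function(x, alphabet) {
  if (alphabet == "amino20") return(x %in% MISSING_AA)
  if (alphabet == "nucleotide4") return(x %in% MISSING_NT)
  # codon: any non-ACGT character makes the whole codon missing
  !grepl("^[ACGT]{3}$", x)
}

validate_chars <- function(x, alphabet) {
  states <- alphabet_states(alphabet)
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    bad <- !(row %in% states) & !is_missing_cell(row, alphabet)
    if (alphabet == "codon") {
      # a well-formed ACGT codon absent from the sense table is a stop codon
      stopc <- grepl("^[ACGT]{3}$", row) & !(row %in% states)
      if (any(stopc[-length(stopc)]))
        stop("internal stop codon in taxon '", rownames(x)[i], "' at codon site ",
             which(stopc)[1])
      bad <- bad & !stopc
    }
    if (any(bad))
      stop("invalid character '", row[which(bad)[1]], "' for alphabet ",
           alphabet, " in taxon '", rownames(x)[i], "' at site ", which(bad)[1])
  }
  invisible(x)
}

#' Read a sequence alignment
#'
#' Auto-detects FASTA (leading `>`) versus relaxed sequential PHYLIP. Codon
#' alignments are read as nucleotide text and split into codon columns; the
#' sequence length must be divisible by 3 and internal stop codons are
#' rejected.
#'
#' @param path input file.
#' @param alphabet `"amino20"`, `"codon"` or `"nucleotide4"`.
#' @return a [paas_alignment()] matrix preserving input taxon order, with
#'   characters uppercased.
#' @export
read_alignment <- function(path, alphabet = c("amino20", "codon", "nucleotide4")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  seqs <- if (startsWith(trimws(first), ">")) {
    ss <- Biostrings::readBStringSet(path)
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    read_relaxed_phylip(path)
  }
  seqs_to_alignment(seqs, alphabet)
}

read_relaxed_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  len <- suppressWarnings(as.integer(hdr[2]))
  if (is.na(n) || is.na(len))
    stop("not a PHYLIP header: '", lines[1], "'")
  body <- lines[-1]
  if (length(body) < n) stop("PHYLIP file declares ", n, " taxa, found ", length(body))
  out <- character(n); nm <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    nm[i] <- parts[1]
    out[i] <- paste(parts[-1], collapse = "")
  }
  setNames(out, nm)
}

seqs_to_alignment <- function(seqs, alphabet) {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    ref <- lens[1]
    off <- which(lens != ref)[1]
    stop("alignment rows have unequal lengths: taxon '", names(seqs)[off],
         "' has ", lens[off], " characters, expected ", ref)
  }
  if (alphabet == "codon" && lens[1] %% 3 != 0)
    stop("codon alignment length ", lens[1], " is not divisible by 3 (taxon '",
         names(seqs)[1], "')")
  chars <- strsplit(toupper(seqs), "")
  m <- do.call(rbind, chars)
  rownames(m) <- names(seqs)
  if (alphabet == "codon") {
    S <- ncol(m) / 3
    cm <- matrix("", nrow(m), S, dimnames = list(rownames(m), NULL))
    for (s in seq_len(S))
      cm[, s] <- paste0(m[, 3 * s - 2], m[, 3 * s - 1], m[, 3 * s])
    m <- cm
  }
  paas_alignment(m, alphabet)
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' Site indices in all human-facing outputs of this package are 1-based;
#' writers emit sequences verbatim so a write/read cycle is lossless.
#'
#' @param aln a `paas_aln`.
#' @param path output file.
#' @param format `"fasta"` or `"phylip"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  } else {
    writeLines(c(paste(length(seqs), nchar(seqs[1])),
                 paste(names(seqs), seqs)), path)
  }
  invisible(path)
}

# Integer-coded states (0-based; -1 = missing), rows ordered as `taxa`.
aln_state_matrix <- function(aln, taxa = rownames(aln)) {
  alphabet <- attr(aln, "alphabet")
  states <- alphabet_states(alphabet)
  miss <- is_missing_cell(unclass(aln), alphabet)
  idx <- match(unclass(aln), states) - 1L
  idx[miss] <- -1L
  m <- matrix(idx, nrow(aln), ncol(aln), dimnames = dimnames(aln))
  bad <- setdiff(taxa, rownames(m))
  if (length(bad)) stop("alignment lacks taxa: ", paste(bad, collapse = ", "))
  m[taxa, , drop = FALSE]
}
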