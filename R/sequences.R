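# Invertebrate mitochondrial genetic code (NCBI translation table 5).
# Differs from the standard code at AGA/AGG (Ser, not stop/Arg), ATA (Met)
# and TGA (Trp); the only stops are TAA and TAG.
.mito_code <- local({
  b <- c("T", "C", "A", "G")
  codons <- character(64)
  k <- 0
  for (b1 in b) for (b2 in b) for (b3 in b) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CCWW",
    "LLLLPPPPHHQQRRRR",
    "IIMMTTTTNNKKSSSS",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
})

.iupac_chars <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")

#' Translate a nucleotide sequence under the invertebrate mitochondrial code
#'
#' Codons containing IUPAC ambiguity codes or gaps translate to \code{"X"};
#' a trailing partial codon is dropped.
#'
#' @param seq nucleotide string (IUPAC alphabet, case-insensitive).
#' @param frame 0, 1 or 2: offset of the first full codon.
#' @return character vector of single-letter amino acids (\code{"*"} = stop).
#' @export
translate_mito <- function(seq, frame = 0) {
  chars <- strsplit(toupper(seq), "")[[1]]
  chars[chars == "U"] <- "T"
  bad <- !chars %in% .iupac_chars
  if (any(bad)) {
    stop("non-IUPAC character(s) in sequence: ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  if (frame > 0) chars <- chars[-seq_len(frame)]
  n_codon <- length(chars) %/% 3
  if (n_codon < 1) stop("sequence shorter than one codon after frame offset")
  chars <- chars[seq_len(3 * n_codon)]
  codons <- paste0(chars[c(TRUE, FALSE, FALSE)],
                   chars[c(FALSE, TRUE, FALSE)],
                   chars[c(FALSE, FALSE, TRUE)])
  aa <- .mito_code[codons]
  aa[is.na(aa)] <- "X"   # ambiguity anywhere in the codon
  unname(aa)
}

#' Screen a sequence for protein-coding plausibility (pseudogene check)
#'
#' A COI fragment amplified from the mitochondrial genome must translate
#' without internal stop codons under the invertebrate mitochondrial code;
#' nuclear pseudogene copies typically do not. Ambiguity codes translate to X
#' and never count as stops. The terminal codon is allowed to be a stop.
#'
#' @param seq nucleotide string.
#' @param frame reading frame 0, 1 or 2, or \code{NULL} to auto-select the
#'   first frame with no internal stops.
#' @return list with \code{coding} (logical: some tested frame is stop-free),
#'   \code{frame} (the stop-free frame, or \code{NA}), and \code{peptide}
#'   (translation in that frame, or in the requested frame when none passes).
#' @export
check_coding <- function(seq, frame = NULL) {
  frames <- if (is.null(frame)) 0:2 else frame
  pep_last <- NULL
  for (f in frames) {
    pep <- translate_mito(seq, f)
    pep_last <- pep
    internal <- pep[-length(pep)]
    if (!any(internal == "*")) {
      return(list(coding = TRUE, frame = f, peptide = pep))
    }
  }
  list(coding = FALSE, frame = NA_integer_, peptide = pep_last)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  id <- trimws(sub("^>\\s*", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  setNames(toupper(seqs), id)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# Mutate one sequence at a per-site rate with a transition:transversion bias,
# then revert any mutation that would create an internal stop codon in frame 0.
.transitions <- c(A = "G", G = "A", C = "T", T = "C")
.transversions <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

.mutate_seq <- function(seq, rate, titv = 4) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) == 0) return(seq)
  p_ti <- titv / (titv + 2)
  for (i in hit) {
    b <- chars[i]
    chars[i] <- if (runif(1) < p_ti) .transitions[[b]] else
      sample(.transversions[[b]], 1)
  }
  # keep the fragment coding: revert codons that acquired an internal stop
  n_codon <- length(chars) %/% 3
  ref <- strsplit(seq, "")[[1]]
  for (ci in seq_len(n_codon - 1)) {
    idx <- (3 * ci - 2):(3 * ci)
    if (.mito_code[paste(chars[idx], collapse = "")] == "*") {
      chars[idx] <- ref[idx]
    }
  }
  paste(chars, collapse = "")
}
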