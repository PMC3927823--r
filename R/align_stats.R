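# Alignment validation: read FASTA/NEXUS matrices and compute the summary
# statistics used to check molecular input (taxa, length, number of
# parsimony-informative sites).

iupac_ambiguity <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
allowed_chars <- c("A", "C", "G", "T", "U", iupac_ambiguity, "-", "?")

#' Read a sequence alignment from FASTA or NEXUS
#'
#' FASTA is parsed with \pkg{seqinr}; NEXUS (simple DATA/CHARACTERS block
#' with MATRIX, interleaved or sequential) with \pkg{ape}. Characters are
#' upper-cased and validated against the nucleotide alphabet plus IUPAC
#' ambiguity codes, '-' and '?'. Ragged matrices and duplicate taxa are
#' errors.
#'
#' @param path file path; format chosen by extension (.nex/.nexus vs
#'   fasta) unless given.
#' @param format "auto", "fasta" or "nexus".
#' @return object of class \code{alignment}: list with \code{taxa} and
#'   \code{seqs} (taxa x sites character matrix).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  }
  seqs <- if (format == "nexus") {
    lapply(ape::read.nexus.data(path), function(s) toupper(as.character(s)))
  } else {
    s <- seqinr::read.fasta(path, seqtype = "DNA", as.string = FALSE,
                            forceDNAtolower = FALSE, set.attributes = FALSE)
    lapply(s, function(x) toupper(as.character(x)))
  }
  taxa <- names(seqs)
  if (is.null(taxa) || anyDuplicated(taxa))
    stop("alignment has missing or duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    off <- taxa[lens != stats::median(lens)]
    stop("ragged alignment; offending taxa: ", paste(off, collapse = ", "))
  }
  if (lens[1L] < 1L) stop("alignment has zero length")
  m <- do.call(rbind, seqs)
  rownames(m) <- taxa
  bad <- setdiff(unique(as.vector(m)), allowed_chars)
  if (length(bad))
    stop("alignment contains characters outside the nucleotide/IUPAC ",
         "alphabet: ", paste(bad, collapse = " "))
  structure(list(taxa = taxa, seqs = m), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("Alignment:", length(x$taxa), "taxa x", ncol(x$seqs), "sites\n")
  invisible(x)
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when at least two distinct resolved
#' states (A, C, G, T; U counted as T) each occur in at least two taxa.
#' Gaps, '?', and IUPAC ambiguity codes are treated as missing data, a
#' conservative, deterministic choice (flagged in the summary report so
#' divergence from tools that treat ambiguities as polymorphic is
#' traceable).
#'
#' @param aln an \code{alignment}.
#' @return integer count of informative columns.
#' @export
parsimony_informative_count <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  m <- aln$seqs
  m[m == "U"] <- "T"
  informative <- apply(m, 2L, function(col) {
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    sum(tab >= 2L) >= 2L
  })
  sum(informative)
}

#' Alignment summary statistics
#'
#' @param aln an \code{alignment}.
#' @param name matrix label used in reports.
#' @return one-row data.frame: matrix, taxa, length, informative, percent
#'   (informative sites as a percentage of length, one decimal).
#' @export
alignment_summary <- function(aln, name = "alignment") {
  pis <- parsimony_informative_count(aln)
  data.frame(matrix = name, taxa = length(aln$taxa), length = ncol(aln$seqs),
             informative = pis,
             percent = round(100 * pis / ncol(aln$seqs), 1))
}
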