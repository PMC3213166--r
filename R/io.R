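#' Normalize siRNA sequence text
#'
#' Uppercases and converts T to U (the two are treated as synonyms on
#' input; U is canonical internally). Does not validate length or
#' alphabet; constructors and validity methods do that.
#'
#' @param x character vector of raw sequences.
#' @return normalized character vector.
#' @export
normalizeSequence <- function(x) {
  chartr("T", "U", toupper(trimws(x)))
}

#' Construct an SiRNADataset from vectors
#'
#' @param id character vector of unique record ids.
#' @param sequence character vector of 19-nt sense sequences (T/lowercase
#'   accepted, normalized to uppercase U).
#' @param efficacy numeric vector in \[0,100\] (% inhibition), or NULL /
#'   NA for unlabeled records.
#' @param name dataset label.
#' @return an [SiRNADataset-class].
#' @export
SiRNADataset <- function(id, sequence, efficacy = NULL, name = "dataset") {
  if (is.null(efficacy)) efficacy <- rep(NA_real_, length(id))
  rec <- data.frame(id = as.character(id),
                    sequence = normalizeSequence(sequence),
                    efficacy = as.numeric(efficacy),
                    stringsAsFactors = FALSE)
  new("SiRNADataset", records = rec, name = name)
}

#' @rdname siRNASequences
#' @aliases siRNASequences efficacies recordIds datasetName
#' @title Accessors for SiRNADataset
#' @param x an [SiRNADataset-class].
#' @return `siRNASequences`: character vector of sense 19-mers;
#'   `efficacies`: numeric vector (% inhibition, NA when unlabeled);
#'   `recordIds`: character vector; `datasetName`: character scalar.
#' @export
setMethod("siRNASequences", "SiRNADataset", function(x) x@records$sequence)

#' @rdname siRNASequences
#' @export
setMethod("efficacies", "SiRNADataset", function(x) x@records$efficacy)

#' @rdname siRNASequences
#' @export
setMethod("recordIds", "SiRNADataset", function(x) x@records$id)

#' @rdname siRNASequences
#' @export
setMethod("datasetName", "SiRNADataset", function(x) x@name)

#' @export
setMethod("length", "SiRNADataset", function(x) nrow(x@records))

#' @export
setMethod("[", "SiRNADataset", function(x, i, j, ..., drop = TRUE) {
  new("SiRNADataset", records = x@records[i, , drop = FALSE], name = x@name)
})

setMethod("show", "SiRNADataset", function(object) {
  n <- length(object)
  lab <- sum(!is.na(object@records$efficacy))
  cat(sprintf("SiRNADataset '%s': %d records (%d labeled)\n",
              object@name, n, lab))
  if (n) {
    head_n <- min(3L, n)
    for (i in seq_len(head_n))
      cat(sprintf("  %s  %s  %s\n", object@records$id[i],
                  object@records$sequence[i],
                  ifelse(is.na(object@records$efficacy[i]), "NA",
                         format(object@records$efficacy[i]))))
    if (n > head_n) cat(sprintf("  ... and %d more\n", n - head_n))
  }
})

#' Read an siRNA dataset from a delimited file
#'
#' Expects a header row with columns `id`, `sequence` and optionally
#' `efficacy`; the delimiter is auto-detected from the extension
#' (`.csv` comma, anything else tab). Sequences are normalized (T to U,
#' uppercased) and validated: exactly 19 nt over \{A,C,G,U\}, efficacy
#' in \[0,100\], unique ids. Malformed rows abort with the row number
#' and violated invariant.
#'
#' @param path file path.
#' @param format "auto", "tsv" or "csv".
#' @param name dataset label (defaults to the file stem).
#' @return an [SiRNADataset-class].
#' @export
readDataset <- function(path, format = c("auto", "tsv", "csv"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (format == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", colClasses = "character")
  if (!all(c("id", "sequence") %in% names(tab)))
    stop("dataset file must have header columns 'id' and 'sequence'")
  seqs <- normalizeSequence(tab$sequence)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) != 19L)
      stop(sprintf("row %d (id '%s'): sequence length %d violates the 19-nt invariant",
                   i, tab$id[i], nchar(seqs[i])))
    if (grepl("[^ACGU]", seqs[i]))
      stop(sprintf("row %d (id '%s'): characters outside {A,C,G,U}: %s",
                   i, tab$id[i],
                   paste(unique(strsplit(gsub("[ACGU]", "", seqs[i]), "")[[1]]),
                         collapse = ",")))
  }
  eff <- if ("efficacy" %in% names(tab)) {
    e <- suppressWarnings(as.numeric(tab$efficacy))
    bad <- which(!is.na(tab$efficacy) & tab$efficacy != "" & is.na(e))
    if (length(bad))
      stop(sprintf("row %d: efficacy '%s' is not numeric", bad[1], tab$efficacy[bad[1]]))
    out <- which(!is.na(e) & (e < 0 | e > 100))
    if (length(out))
      stop(sprintf("row %d: efficacy %g outside [0,100]", out[1], e[out[1]]))
    e
  } else rep(NA_real_, nrow(tab))
  if (anyDuplicated(tab$id))
    stop("duplicate id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  SiRNADataset(tab$id, seqs, eff, name = name)
}

#' Write an siRNA dataset to a delimited file
#'
#' Inverse of [readDataset()]: a written file read back reproduces the
#' records exactly.
#'
#' @param dataset an [SiRNADataset-class].
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @return the path, invisibly.
#' @export
writeDataset <- function(dataset, path) {
  stopifnot(is(dataset, "SiRNADataset"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(dataset@records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read target or query sequences from FASTA
#'
#' Reads a (multi-)FASTA of mRNA targets or 19-nt queries via
#' Biostrings, normalizes T to U and uppercases, and rejects records
#' containing anything outside \{A,C,G,U\} (ambiguity codes such as N
#' are not accepted).
#'
#' @param path FASTA file path.
#' @return named character vector of sequences, in file order.
#' @export
readTargetFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- normalizeSequence(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty))
    stop("FASTA record with empty sequence: ", names(seqs)[empty[1]])
  for (i in seq_along(seqs)) {
    bad <- gsub("[ACGU]", "", seqs[i])
    if (nchar(bad))
      stop(sprintf("FASTA record '%s' contains invalid characters: %s",
                   names(seqs)[i],
                   paste(unique(strsplit(bad, "")[[1]]), collapse = ",")))
  }
  seqs
}

#' Enumerate candidate 19-mer target sites along an mRNA
#'
#' Slides a 19-nt window over the target, one candidate per start
#' position: `nchar(mrna) - 18` candidates in total. Candidate ids are
#' `"<parent_id>:<start>-<end>"` with 1-based inclusive coordinates, and
#' each candidate's sequence is the sense strand (identical to the
#' target site).
#'
#' @param mrna_seq a single mRNA sequence (character; T accepted).
#' @param parent_id id prefix for the candidates.
#' @return an unlabeled [SiRNADataset-class] of all 19-mer windows.
#' @export
enumerateCandidates <- function(mrna_seq, parent_id = "target") {
  seq <- normalizeSequence(mrna_seq)
  len <- nchar(seq)
  if (len < 19L)
    stop("target mRNA must be at least 19 nt (got ", len, ")")
  starts <- seq_len(len - 18L)
  wins <- substring(seq, starts, starts + 18L)
  SiRNADataset(sprintf("%s:%d-%d", parent_id, starts, starts + 18L),
               wins, name = paste0(parent_id, "_candidates"))
}
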