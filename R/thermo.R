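#' Load nearest-neighbor thermodynamic parameters
#'
#' Reads a tab-delimited table with columns `step` (5'->3' dinucleotide
#' of the strand under evaluation), `dG37`, `dH` (kcal/mol) and `dS`
#' (cal/(mol K)); all 16 Watson-Crick steps must be present. The
#' package ships the RNA Watson-Crick stacking set of Xia et al. (1998)
#' as its default.
#'
#' @param path parameter file; default is the shipped table.
#' @return a [ThermoParams-class].
#' @export
loadThermoParams <- function(path = system.file("extdata", "thermo_nn_rna.tsv",
                                                package = "siStack")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("step", "dG37", "dH", "dS")
  if (!all(need %in% names(tab)))
    stop("thermo parameter file must have columns ", paste(need, collapse = ", "))
  mk <- function(col) stats::setNames(tab[[col]], tab$step)
  new("ThermoParams", dG37 = mk("dG37"), dH = mk("dH"), dS = mk("dS"))
}

#' @rdname loadThermoParams
#' @export
defaultThermoParams <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- loadThermoParams()
    cache
  }
})

setMethod("show", "ThermoParams", function(object) {
  cat("ThermoParams: 16 Watson-Crick nearest-neighbor steps\n")
  cat(sprintf("  dG37 range [%.2f, %.2f] kcal/mol\n",
              min(object@dG37), max(object@dG37)))
})

#' Reverse-complement RNA sequences
#'
#' Vectorized reverse complementation of sense-strand RNA sequences,
#' yielding the antisense (guide) strand.
#'
#' @param seqs character vector over \{A,C,G,U\}.
#' @return character vector of reverse complements.
#' @export
reverseComplementRNA <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(seqs)))
}

#' Duplex stacking thermodynamics of a 19-nt siRNA
#'
#' Derives the antisense strand as the reverse complement of the sense
#' 19-mer and evaluates the 18 nearest-neighbor stacks spanning
#' antisense positions 1-2, 2-3, ..., 18-19. `whole_dG` is strictly the
#' sum of the 18 stacking free energies (no duplex-initiation or
#' terminal terms); `dH` and `dS` are the analogous whole-duplex sums.
#'
#' @param seq one 19-nt sense sequence.
#' @param params a [ThermoParams-class].
#' @return list with `stacks` (numeric(18), kcal/mol, named by antisense
#'   step span), `whole_dG` (kcal/mol), `dH` (kcal/mol), `dS`
#'   (cal/(mol K)).
#' @export
computeThermo <- function(seq, params = defaultThermoParams()) {
  seq <- normalizeSequence(seq)
  if (nchar(seq) != 19L) stop("computeThermo expects a 19-nt sequence")
  if (grepl("[^ACGU]", seq)) stop("sequence contains characters outside {A,C,G,U}")
  anti <- reverseComplementRNA(seq)
  steps <- substring(anti, 1:18, 2:19)
  missing <- setdiff(steps, names(params@dG37))
  if (length(missing))
    stop("no thermodynamic parameter for step ", missing[1])
  stacks <- unname(params@dG37[steps])
  names(stacks) <- sprintf("%d-%d", 1:18, 2:19)
  list(stacks = stacks,
       whole_dG = sum(stacks),
       dH = sum(params@dH[steps]),
       dS = sum(params@dS[steps]))
}

#' Whole-duplex stacking free energy for many sequences
#'
#' Vectorized `whole_dG` (sum of the 18 antisense nearest-neighbor
#' stacks) used by candidate scanning and dG-stratified evaluation.
#'
#' @param seqs character vector of 19-nt sense sequences.
#' @param params a [ThermoParams-class].
#' @return numeric vector of whole-duplex stacking energies (kcal/mol).
#' @export
wholeDG <- function(seqs, params = defaultThermoParams()) {
  seqs <- normalizeSequence(seqs)
  if (!length(seqs)) return(numeric(0))
  anti <- reverseComplementRNA(seqs)
  vapply(anti, function(a) {
    sum(params@dG37[substring(a, 1:18, 2:19)])
  }, numeric(1), USE.NAMES = FALSE)
}
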