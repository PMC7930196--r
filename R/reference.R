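#' Reference mitogenome
#'
#' A reference object holds the 16,569-bp mitogenome that variant profiles
#' are expressed against, in rCRS coordinates (1-based). For real analyses
#' supply the rCRS (NC_012920) as a FASTA file; the packaged default is a
#' deterministic synthetic stand-in with human-mtDNA-like base composition,
#' suitable for simulation and testing but not for calling variants on real
#' sequences.
#'
#' @param fasta path to a single-record FASTA with a 16,569-bp sequence, or
#'   `NULL` for the synthetic default.
#' @return an object of class `mito_reference`: a list with `bases`
#'   (character vector of length 16,569), `length`, and `source`.
#' @export
mito_reference <- function(fasta = NULL) {
  if (is.null(fasta)) {
    return(synthetic_reference())
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) {
    stop("reference FASTA must contain exactly one sequence, found ",
         length(seqs))
  }
  if (Biostrings::width(seqs)[1] != MITO_LENGTH) {
    stop("reference sequence must have length ", MITO_LENGTH,
         ", found ", Biostrings::width(seqs)[1])
  }
  new_reference(strsplit(as.character(seqs[[1]]), "")[[1]], source = fasta)
}

#' Synthetic reference mitogenome
#'
#' Deterministically generates a 16,569-bp DNA sequence with the base
#' composition of the human mtDNA heavy strand (A 30.9%, C 31.3%, G 13.1%,
#' T 24.7%). It is NOT the rCRS: coordinates and lengths match, base
#' identities do not. The sequence is identical across sessions and
#' platforms and does not disturb the caller's RNG state.
#'
#' @return a `mito_reference` object with `source = "synthetic"`.
#' @export
synthetic_reference <- function() {
  cached <- get0("synthetic_ref", envir = .mitotempo_cache)
  if (!is.null(cached)) {
    return(cached)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(16569L)
  bases <- sample(DNA_BASES, MITO_LENGTH, replace = TRUE,
                  prob = c(0.309, 0.313, 0.131, 0.247))
  ref <- new_reference(bases, source = "synthetic")
  assign("synthetic_ref", ref, envir = .mitotempo_cache)
  ref
}

new_reference <- function(bases, source) {
  stopifnot(length(bases) == MITO_LENGTH, all(bases %in% DNA_BASES))
  structure(list(bases = bases, length = MITO_LENGTH, source = source),
            class = "mito_reference")
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("<mito_reference> ", x$length, " bp, source: ", x$source, "\n", sep = "")
  invisible(x)
}

MITO_LENGTH <- 16569L
DNA_BASES <- c("A", "C", "G", "T")

.mitotempo_cache <- new.env(parent = emptyenv())
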