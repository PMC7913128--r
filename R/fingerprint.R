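# Circular fingerprints for compound featurization.

#' Circular fingerprint featurization
#'
#' Encodes molecules as binary circular (Morgan-type, radius 4) fingerprints
#' folded to a fixed length, via OpenBabel's ECFP8 implementation
#' (ChemmineOB). The native 4096-bit fingerprint is OR-folded down to
#' `nbits`.
#'
#' @param smiles character vector of SMILES strings.
#' @param nbits folded fingerprint length (default 1024); must divide 4096.
#' @return integer 0/1 matrix with one row per molecule (rownames are the
#'   names of `smiles`, or the SMILES themselves) and `nbits` columns.
#'   Unparsable SMILES raise an error naming the offending string.
#' @examples
#' \dontrun{
#' fp <- featurize(c(ethanol = "CCO", phenol = "c1ccccc1O"))
#' tanimoto(fp[1, ], fp[2, ])
#' }
#' @export
featurize <- function(smiles, nbits = 1024) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("featurize requires the ChemmineOB package")
  }
  ids <- names(smiles)
  smiles <- as.character(smiles)
  stopifnot(length(smiles) > 0, nbits >= 1, 4096 %% nbits == 0)
  rows <- lapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) stop("unparsable SMILES: ", deparse(s))
    fp <- tryCatch(
      ChemmineOB::fingerprint_OB(ChemmineOB::forEachMol("SMILES", s, identity),
                                 "ECFP8"),
      error = function(e) stop("unparsable SMILES: ", s, call. = FALSE)
    )
    bits <- as.integer(if (is.matrix(fp)) fp[1, ] else fp)
    if (length(bits) %% nbits != 0 || !length(bits)) {
      stop("unparsable SMILES: ", s, call. = FALSE)
    }
    fold_bits(bits, nbits)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- if (!is.null(ids)) ids else smiles
  colnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

# OR-fold a bit vector down to nbits (standard fingerprint folding).
fold_bits <- function(bits, nbits) {
  stopifnot(length(bits) %% nbits == 0)
  folds <- matrix(bits, nrow = nbits)
  as.integer(rowSums(folds) > 0)
}

#' Tanimoto similarity between two binary fingerprints
#'
#' @param a,b binary 0/1 vectors of equal length.
#' @return Tanimoto (Jaccard) coefficient in \[0, 1\]; 1 for two empty
#'   fingerprints by convention.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a | b)
  if (denom == 0) return(1)
  sum(a & b) / denom
}
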