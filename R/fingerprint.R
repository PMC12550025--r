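#' Circular (ECFP4) fingerprints folded to 2048 bits
#'
#' Computes radius-2 extended-connectivity fingerprints through OpenBabel
#' and folds the native 4096-bit vector to 2048 bits by OR-ing the two
#' halves (the folding convention is fixed here so similarity values are
#' bit-exact reproducible).
#'
#' @param smiles character vector of SMILES.
#' @param nbits folded width (default 2048).
#' @return logical matrix (`length(smiles) x nbits`); rows of all-`FALSE`
#'   for unparseable molecules.
#' @export
ecfp4_fingerprint <- function(smiles, nbits = 2048L) {
  out <- matrix(FALSE, length(smiles), nbits)
  if (!length(smiles)) return(out)
  for (k in seq_along(smiles)) {
    fp <- tryCatch({
      ref <- ChemmineOB::forEachMol("SMILES", smiles[k], identity)
      as.logical(ChemmineOB::fingerprint_OB(ref, "ECFP4"))
    }, error = function(e) NULL)
    if (is.null(fp) || !length(fp)) next
    folds <- ceiling(length(fp) / nbits)
    v <- rep(FALSE, nbits)
    for (f in seq_len(folds)) {
      seg <- fp[((f - 1L) * nbits + 1L):min(f * nbits, length(fp))]
      v[seq_along(seg)] <- v[seq_along(seg)] | seg
    }
    out[k, ] <- v
  }
  out
}

#' Tanimoto similarity between fingerprint rows
#'
#' @param fp1,fp2 logical fingerprint matrices (rows = molecules).
#' @return similarity matrix (`nrow(fp1) x nrow(fp2)`); empty fingerprints
#'   give similarity 0.
#' @export
tanimoto_similarity <- function(fp1, fp2) {
  m1 <- matrix(as.numeric(fp1), nrow = nrow(fp1))
  m2 <- matrix(as.numeric(fp2), nrow = nrow(fp2))
  inter <- tcrossprod(m1, m2)
  n1 <- rowSums(m1); n2 <- rowSums(m2)
  uni <- outer(n1, n2, `+`) - inter
  s <- inter / pmax(uni, 1)
  s[uni == 0] <- 0
  s
}
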