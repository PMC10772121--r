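#' Pair residues between two structures for superposition
#'
#' Pairing is CA-based: only residues with a CA atom in both structures can
#' form a pair. `by_number` matches author residue numbers (and insertion
#' codes); `by_alignment` aligns the two one-letter sequences globally
#' (Needleman-Wunsch, BLOSUM62, gap open 10 / extend 0.5) and pairs residues
#' through gapless alignment columns.
#'
#' @param a,b `epi_structure` objects (typically single-chain/domain
#'   selections, see [select_structure()]).
#' @param mode `"by_number"` or `"by_alignment"`.
#' @return An object of class `residue_pairing`: list with `pairs` (data
#'   frame of paired residue identifiers), `xyz_a`, `xyz_b` (n x 3 CA
#'   coordinate matrices) and `source`.
#' @export
pair_residues <- function(a, b, mode = c("by_number", "by_alignment")) {
  mode <- match.arg(mode)
  ca_a <- ca_table(a)
  ca_b <- ca_table(b)
  if (nrow(ca_a) == 0 || nrow(ca_b) == 0)
    stop("both structures must contain CA atoms")

  if (mode == "by_number") {
    key_a <- paste(ca_a$resno, ca_a$insert)
    key_b <- paste(ca_b$resno, ca_b$insert)
    idx_b <- match(key_a, key_b)
    ia <- which(!is.na(idx_b))
    ib <- idx_b[ia]
  } else {
    seq_a <- paste(aa_three_to_one(ca_a$resid), collapse = "")
    seq_b <- paste(aa_three_to_one(ca_b$resid), collapse = "")
    map <- align_position_map(seq_a, seq_b)
    ia <- map$pos_a
    ib <- map$pos_b
  }
  if (length(ia) < 3)
    stop("insufficient residue pairs for superposition (need >= 3, got ",
         length(ia), ")")
  pairs <- data.frame(
    chain_a = ca_a$chain[ia], resno_a = ca_a$resno[ia], insert_a = ca_a$insert[ia],
    chain_b = ca_b$chain[ib], resno_b = ca_b$resno[ib], insert_b = ca_b$insert[ib],
    stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs,
                 xyz_a = as.matrix(ca_a[ia, c("x", "y", "z")]),
                 xyz_b = as.matrix(ca_b[ib, c("x", "y", "z")]),
                 source = mode),
            class = "residue_pairing")
}

# One CA row per residue, in order of appearance.
ca_table <- function(structure) {
  at <- structure$atoms
  at <- at[at$name == "CA" & at$element == "C" & !at$is_hetero, , drop = FALSE]
  key <- residue_key(at$chain, at$resno, at$insert)
  at <- at[!duplicated(key), , drop = FALSE]
  rownames(at) <- NULL
  at
}

# Position map of gapless columns from a global pairwise alignment.
align_position_map <- function(seq_a, seq_b) {
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5, type = "global"
  )
  ca <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  cb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pa <- cumsum(ca != "-")
  pb <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  list(pos_a = pa[keep], pos_b = pb[keep],
       aligned_a = ca, aligned_b = cb)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between the
#' paired CA sets, via singular value decomposition with reflection
#' correction (the smallest singular axis is negated when the determinant is
#' negative, so the result is always a rotation). The transform maps
#' structure B coordinates onto structure A: `x_a ~ x_b %*% t(R) + t`.
#'
#' @param pairing A [pair_residues()] result.
#' @return An object of class `superposition`: list with `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom over the paired CA atoms
#'   after the transform) and `n_pairs`.
#' @export
kabsch_superpose <- function(pairing) {
  xa <- pairing$xyz_a
  xb <- pairing$xyz_b
  n <- nrow(xa)
  if (n < 3) stop("need at least 3 pairs")
  ca <- colMeans(xa)
  cb <- colMeans(xb)
  ya <- sweep(xa, 2, ca)
  yb <- sweep(xb, 2, cb)
  sv_geom <- svd(yb)$d
  if (sv_geom[2] < 1e-8 * max(sv_geom[1], 1))
    stop("degenerate geometry: paired points are (nearly) collinear")
  h <- crossprod(yb, ya)           # 3x3 covariance, maps b-frame to a-frame
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  corr <- diag(c(1, 1, d))
  rot <- s$v %*% corr %*% t(s$u)   # x_a ~ rot %*% x_b
  trans <- as.numeric(ca - rot %*% cb)
  xb_fit <- sweep(xb %*% t(rot), 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((xa - xb_fit)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd,
                 n_pairs = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d CA pairs, rmsd %.3f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' TM-score of a fixed residue pairing under a superposition
#'
#' Computes the length-normalised template-modelling score
#' `TM = (1/L) * sum_i 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8`, where `d_i` are post-superposition
#' CA-CA distances and `L` is the length of the target (reference) chain or
#' domain. The pairing is fixed: no iterative fragment search is performed,
#' so this scores an established correspondence rather than searching for
#' the optimal one.
#'
#' @param pairing A [pair_residues()] result.
#' @param superposition A [kabsch_superpose()] result computed on the same
#'   pairing.
#' @param l_target Normalisation length (>= 16; below that `d0` leaves its
#'   domain of validity). Defaults to the number of pairs.
#' @return Numeric scalar in (0, 1].
#' @export
tm_score <- function(pairing, superposition, l_target = superposition$n_pairs) {
  if (l_target < 16)
    stop("l_target must be >= 16 (d0 normalisation is undefined below)")
  d0 <- 1.24 * (l_target - 15)^(1 / 3) - 1.8
  xb_fit <- sweep(pairing$xyz_b %*% t(superposition$rotation), 2,
                  superposition$translation, "+")
  d <- sqrt(rowSums((pairing$xyz_a - xb_fit)^2))
  sum(1 / (1 + (d / d0)^2)) / l_target
}
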