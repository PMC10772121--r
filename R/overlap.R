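# Footprint mapping onto a common reference numbering and overlap metrics.
#
# Two footprints measured on homologous receptors are compared at residue
# level: each is expressed in the reference sequence numbering via a global
# pairwise alignment, and the overlap is the per-position minimum of the two
# buried areas, summed. A residue-level convention is used (rather than an
# atom-level intersection after superposition) because the two footprints
# live on non-identical receptors where atom correspondence is undefined.

#' Map a structural footprint onto a reference sequence numbering
#'
#' Transfers per-residue buried areas through the gapless columns of a
#' global pairwise alignment (Needleman-Wunsch, BLOSUM62, gap open 10 /
#' extend 0.5, computed internally when `alignment` is not supplied).
#' Footprint residues facing an alignment gap are dropped from the map and
#' reported in `unmapped`.
#'
#' @param footprint A [compute_footprint()] result, or a data frame with
#'   columns `position` (1-based position in `source_seq`) and `dsasa`.
#' @param source_seq One-letter sequence of the molecule the footprint was
#'   measured on.
#' @param reference_seq One-letter sequence providing the reference
#'   numbering.
#' @param numbering_offset Author residue number minus sequence position for
#'   the source structure (0 when the deposited numbering starts at 1 for
#'   the first residue of `source_seq`).
#' @param alignment Optional precomputed alignment given as a list with
#'   elements `pos_a`/`pos_b` (paired source/reference positions).
#' @return An object of class `mapped_footprint`: list with `areas` (named
#'   numeric, reference position -> A^2), `unmapped` (data frame of dropped
#'   residues), `reference_length` and `provenance`.
#' @export
map_footprint <- function(footprint, source_seq, reference_seq,
                          numbering_offset = 0, alignment = NULL) {
  if (inherits(footprint, "footprint")) {
    df <- footprint$per_residue
    df <- df[df$dsasa > 0, , drop = FALSE]
    pos <- df$resno - numbering_offset
    areas <- df$dsasa
    prov <- footprint$structure_id
    bad <- pos < 1 | pos > nchar(source_seq)
    if (any(bad))
      stop("footprint residue number(s) not resolvable to source sequence ",
           "positions: ", paste(df$resno[bad], collapse = ", "),
           " (check numbering_offset)")
  } else {
    stopifnot(is.data.frame(footprint), all(c("position", "dsasa") %in% names(footprint)))
    pos <- footprint$position
    areas <- footprint$dsasa
    prov <- "data.frame"
    if (any(pos < 1 | pos > nchar(source_seq)))
      stop("footprint position(s) outside the source sequence")
  }

  if (is.null(alignment)) alignment <- align_position_map(source_seq, reference_seq)
  ref_pos <- alignment$pos_b[match(pos, alignment$pos_a)]
  mapped <- !is.na(ref_pos)

  areas_out <- numeric(0)
  if (any(mapped)) {
    areas_out <- tapply(areas[mapped], ref_pos[mapped], sum)
    areas_out <- stats::setNames(as.numeric(areas_out),
                                 names(areas_out))
  }
  unmapped <- data.frame(source_position = pos[!mapped],
                         dsasa = areas[!mapped])
  structure(list(areas = areas_out,
                 unmapped = unmapped,
                 reference_length = nchar(reference_seq),
                 provenance = prov),
            class = "mapped_footprint")
}

#' @export
print.mapped_footprint <- function(x, ...) {
  cat(sprintf("<mapped_footprint> %s: %d positions, %.1f A^2 total", x$provenance,
              length(x$areas), sum(x$areas)))
  if (nrow(x$unmapped) > 0)
    cat(sprintf(" (%d residues unmapped, %.1f A^2 dropped)",
                nrow(x$unmapped), sum(x$unmapped$dsasa)))
  cat("\n")
  invisible(x)
}

#' Overlap between two footprints in the same reference numbering
#'
#' The per-position overlap is `min(areaA, areaB)` and the overlap area is
#' its sum, so the result is symmetric in its arguments and bounded by the
#' smaller footprint total.
#'
#' @param a,b `mapped_footprint` objects sharing the same reference
#'   numbering (equal `reference_length`).
#' @return A list of class `overlap_result` with `overlap_area`,
#'   `shared_positions` (integer vector) and `per_position_overlap` (named
#'   numeric).
#' @export
footprint_overlap <- function(a, b) {
  stopifnot(inherits(a, "mapped_footprint"), inherits(b, "mapped_footprint"))
  if (a$reference_length != b$reference_length)
    stop("footprints are mapped to references of different lengths (",
         a$reference_length, " vs ", b$reference_length, ")")
  shared <- intersect(names(a$areas), names(b$areas))
  per_pos <- pmin(a$areas[shared], b$areas[shared])
  ord <- order(as.integer(shared))
  per_pos <- stats::setNames(as.numeric(per_pos)[ord], shared[ord])
  structure(list(overlap_area = sum(per_pos),
                 shared_positions = as.integer(shared[ord]),
                 per_position_overlap = per_pos),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %.1f A^2 over %d shared positions\n",
              x$overlap_area, length(x$shared_positions)))
  invisible(x)
}

#' Fraction of an epitope occluded by another footprint
#'
#' Used to ask whether a second structural element (e.g. an additional
#' receptor domain packing onto the epitope face) would cover an antibody
#' epitope: returns `overlap(epitope, occluder) / total epitope area`, a
#' fraction in \[0, 1\].
#'
#' @param epitope,occluder `mapped_footprint` objects in the same reference
#'   numbering.
#' @return Numeric scalar in \[0, 1\].
#' @export
occlusion_check <- function(epitope, occluder) {
  total <- sum(epitope$areas)
  if (total <= 0) stop("epitope footprint has zero area")
  ov <- footprint_overlap(epitope, occluder)
  min(1, ov$overlap_area / total)
}
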