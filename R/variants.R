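# Receptor-family MSA parsing, variant position mapping and epitope
# intersection. Variant positions use each receptor's own mature-protein
# numbering (the numbering used for residue labels such as D47 or H50);
# any signal-peptide offset is the caller's responsibility.

#' Read an aligned FASTA multiple sequence alignment
#'
#' All records must have identical aligned lengths; ragged input is
#' rejected. Columns are kept exactly as given (no silent trimming of
#' all-gap columns) and record order and ids are preserved.
#'
#' @param path Path to an aligned FASTA file.
#' @return An object of class `msa`: list with `ids`, `seqs` (character
#'   vector of aligned sequences, gaps as `-`) and `length` (columns).
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) stop("no sequences in alignment: ", path)
  seqs <- toupper(as.character(recs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: sequence lengths ",
         paste(unique(widths), collapse = ", "),
         " differ; input must be an aligned FASTA")
  ok <- grepl("^[A-Z*.\\-]*$", seqs)
  if (!all(ok))
    stop("alignment contains non-amino-acid characters in record(s): ",
         paste(names(recs)[!ok], collapse = ", "))
  new_msa(names(recs), unname(seqs))
}

new_msa <- function(ids, seqs) {
  structure(list(ids = ids, seqs = seqs, length = nchar(seqs[1])),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x$ids), " records x ", x$length, " columns\n", sep = "")
  invisible(x)
}

#' Write an `msa` back to aligned FASTA
#' @param msa An `msa` object.
#' @param path Output path.
#' @return `path`.
#' @export
write_msa <- function(msa, path) {
  lines <- as.vector(rbind(paste0(">", msa$ids), msa$seqs))
  writeLines(lines, path)
  path
}

#' Read a variant table (CSV)
#'
#' Expected columns: `receptor`, `position` (mature numbering of that
#' receptor), `ref`, `alt` (1-letter codes), `rs_id` (may be empty),
#' `frequency` (fraction in \[0,1\], may be NA).
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_variant_table <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("receptor", "position", "ref", "alt", "rs_id", "frequency")
  missing <- setdiff(need, names(v))
  if (length(missing) > 0)
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "))
  v$rs_id <- as.character(v$rs_id)
  if (any(v$ref == v$alt))
    stop("variant table has rows with ref == alt")
  if (any(v$position < 1))
    stop("variant positions must be >= 1")
  v
}

# Ungapped position -> alignment column for one MSA record.
seq_pos_to_column <- function(aligned_seq, position) {
  chars <- strsplit(aligned_seq, "")[[1]]
  notgap <- which(!chars %in% c("-", "."))
  if (position > length(notgap)) return(NA_integer_)
  notgap[position]
}

# Alignment column -> ungapped position (NA if the record has a gap there).
column_to_seq_pos <- function(aligned_seq, column) {
  chars <- strsplit(aligned_seq, "")[[1]]
  if (chars[column] %in% c("-", ".")) return(NA_integer_)
  sum(!chars[seq_len(column)] %in% c("-", "."))
}

#' Express a variant position in the reference receptor's numbering
#'
#' Maps a variant given in its own receptor's mature numbering through the
#' MSA columns into the reference receptor's numbering. The variant's `ref`
#' amino acid is checked against the receptor's own aligned sequence and a
#' mismatch is an error (this guards against stale numbering conventions).
#' Positions aligned to a reference gap return `NA` (unmapped).
#'
#' @param variant One row of a variant table (list or 1-row data frame with
#'   `receptor`, `position`, `ref`).
#' @param msa An [read_msa()] result containing both receptors.
#' @param reference_id MSA record id providing the reference numbering.
#' @return Integer reference position, or `NA` if the reference has a gap
#'   at the variant's column.
#' @export
to_reference_numbering <- function(variant, msa, reference_id) {
  ridx <- match(variant$receptor, msa$ids)
  if (is.na(ridx)) stop("receptor '", variant$receptor, "' not in alignment")
  refidx <- match(reference_id, msa$ids)
  if (is.na(refidx)) stop("reference '", reference_id, "' not in alignment")
  col <- seq_pos_to_column(msa$seqs[ridx], variant$position)
  if (is.na(col))
    stop("position ", variant$position, " beyond the ungapped length of ",
         variant$receptor)
  own_aa <- substr(msa$seqs[ridx], col, col)
  if (!is.null(variant$ref) && !is.na(variant$ref) && own_aa != variant$ref)
    stop("reference-inconsistency for ", variant$receptor, " position ",
         variant$position, ": alignment has '", own_aa,
         "' but variant table says '", variant$ref,
         "' (numbering conventions disagree?)")
  column_to_seq_pos(msa$seqs[refidx], col)
}

#' Intersect a variant table with a structural epitope
#'
#' Produces one row per variant (no drops, no duplicates): the variant's
#' position in reference numbering, whether that position lies in the
#' epitope (buried area at or above the footprint threshold), the buried
#' area itself, and the kinds of interface contacts touching the residue.
#'
#' @param variants Data frame from [read_variant_table()].
#' @param msa An [read_msa()] result.
#' @param footprint Buried areas in reference numbering: either a
#'   [compute_footprint()] result whose residue numbers already follow the
#'   reference numbering, a [map_footprint()] result, or a data frame with
#'   columns `position` and `dsasa`.
#' @param reference_id MSA record id of the reference receptor.
#' @param contacts Optional [classify_contacts()] data frame; target-side
#'   residue numbers (`resno_b`) are matched against reference positions.
#' @param epitope_threshold Minimum buried area (A^2) for epitope
#'   membership; defaults to the footprint's own threshold when available.
#' @return A data frame of class `epitope_variant_report`, sorted by
#'   reference position.
#' @export
intersect_epitope <- function(variants, msa, footprint, reference_id,
                              contacts = NULL, epitope_threshold = NULL) {
  area_by_pos <- footprint_positions(footprint)
  if (is.null(epitope_threshold))
    epitope_threshold <- if (inherits(footprint, "footprint"))
      footprint$epitope_threshold else 1.0

  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    ref_pos <- to_reference_numbering(v, msa, reference_id)
    area <- if (!is.na(ref_pos)) unname(area_by_pos[as.character(ref_pos)]) else NA_real_
    if (is.na(area) && !is.na(ref_pos)) area <- 0
    kinds <- ""
    if (!is.null(contacts) && !is.na(ref_pos) && nrow(contacts) > 0) {
      touching <- contacts$resno_b == ref_pos
      if (any(touching))
        kinds <- paste(sort(unique(contacts$kind[touching])), collapse = ",")
    }
    data.frame(receptor = v$receptor, position = v$position, ref = v$ref,
               alt = v$alt, rs_id = v$rs_id, frequency = v$frequency,
               reference_position = ref_pos,
               in_epitope = !is.na(ref_pos) && area >= epitope_threshold,
               buried_area = area, contact_kinds = kinds,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$reference_position, out$receptor, out$position), ]
  rownames(out) <- NULL
  class(out) <- c("epitope_variant_report", class(out))
  out
}

# Named area vector keyed by reference position, from any footprint form.
footprint_positions <- function(footprint) {
  if (inherits(footprint, "footprint")) {
    df <- footprint$per_residue
    stats::setNames(df$dsasa, as.character(df$resno))
  } else if (inherits(footprint, "mapped_footprint")) {
    footprint$areas
  } else if (is.data.frame(footprint) &&
             all(c("position", "dsasa") %in% names(footprint))) {
    stats::setNames(footprint$dsasa, as.character(footprint$position))
  } else {
    stop("unsupported footprint representation for epitope intersection")
  }
}
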