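# Interface footprinting and geometric contact classification.
#
# Heavy-atom hydrogen-bond chemistry, aromatic ring definitions and cation
# groups are embedded tables: at typical crystallographic resolution no
# hydrogens are modelled, so donor/acceptor capability of the heavy atoms is
# the only reproducible criterion.

HB_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"), TRP = "NE1"
)
HB_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  MET = "SD", CYS = "SG"
)
RING_ATOMS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)
CATION_ATOMS <- list(LYS = "NZ", ARG = "CZ")

#' Geometric criteria for interface contact classification
#'
#' Distance and angle cutoffs for the four contact classes. Defaults follow
#' common structural-biology practice: donor-acceptor distance up to 3.5 A
#' with at least 90 degrees at the donor (heavy-atom proxy angle), apolar
#' carbon-carbon contacts up to 4.5 A, parallel aromatic ring centroids up
#' to 5.5 A within 30 degrees of coplanarity, and Lys NZ / Arg CZ up to
#' 6.0 A from a ring centroid for cation-pi.
#'
#' @param hbond_da_max,hydrophobic_cc_max,pi_centroid_max,cation_pi_max
#'   Distance cutoffs in Angstrom (> 0).
#' @param hbond_angle_min Minimum antecedent-donor-acceptor angle (degrees).
#' @param pi_angle_parallel_max Maximum angle between ring planes (degrees).
#' @return A list of class `contact_criteria`.
#' @export
contact_criteria <- function(hbond_da_max = 3.5, hbond_angle_min = 90,
                             hydrophobic_cc_max = 4.5, pi_centroid_max = 5.5,
                             pi_angle_parallel_max = 30, cation_pi_max = 6.0) {
  stopifnot(hbond_da_max > 0, hydrophobic_cc_max > 0, pi_centroid_max > 0,
            cation_pi_max > 0, hbond_angle_min >= 0, hbond_angle_min <= 180,
            pi_angle_parallel_max >= 0, pi_angle_parallel_max <= 180)
  structure(as.list(environment()), class = "contact_criteria")
}

#' Per-residue buried-surface footprint of a binder on a target
#'
#' The footprint is the one-sided loss of solvent-accessible area of the
#' target upon complex formation: for every target residue,
#' `dSASA = SASA(target alone) - SASA(target in complex)`, computed with
#' identical Shrake-Rupley parameters in both states (so every per-atom loss
#' is non-negative by construction). The buried area is partitioned
#' exhaustively and exclusively among the binder chains by attributing each
#' buried target atom's loss to the chain owning the nearest binder atom;
#' the partition therefore sums to the total exactly. Waters are always
#' excluded; other heteroatoms (e.g. glycans) are excluded by default so the
#' footprint describes protein-protein burial.
#'
#' @param structure An `epi_structure` containing both chain groups.
#' @param target_chains Chain ids of the target (antigen) group.
#' @param binder_chains Chain ids of the binder (e.g. antibody heavy+light).
#' @param params A [sasa_params()] object.
#' @param epitope_threshold Minimum per-residue dSASA (A^2) for membership
#'   in the epitope set. Totals always use raw dSASA regardless of the
#'   threshold.
#' @param include_hetero Include non-water heteroatoms in both groups.
#' @return An object of class `footprint`: list with `per_residue` (data
#'   frame chain/resno/insert/resid/dsasa over all target residues),
#'   `epitope` (rows with dsasa >= threshold), `partition` (named vector,
#'   A^2 per binder chain), `total`, `epitope_threshold` and the group
#'   definitions.
#' @export
compute_footprint <- function(structure, target_chains, binder_chains,
                              params = sasa_params(), epitope_threshold = 1.0,
                              include_hetero = FALSE) {
  if (length(intersect(target_chains, binder_chains)) > 0)
    stop("target and binder chain groups overlap: ",
         paste(intersect(target_chains, binder_chains), collapse = ", "))
  if (length(target_chains) == 0 || length(binder_chains) == 0)
    stop("both chain groups must be non-empty")

  complex_s <- select_structure(structure, chains = c(target_chains, binder_chains),
                                exclude_waters = TRUE,
                                exclude_hetero = !include_hetero)
  target_s <- select_structure(complex_s, chains = target_chains)

  sasa_complex <- compute_sasa(complex_s, params)
  sasa_alone <- compute_sasa(target_s, params)

  in_target <- complex_s$atoms$chain %in% target_chains
  # align complex-state areas to the target-alone atom order via serials
  idx <- match(target_s$atoms$serial, complex_s$atoms$serial[in_target])
  complex_area <- sasa_complex$per_atom[in_target][idx]
  delta <- pmax(sasa_alone$per_atom - complex_area, 0)

  ta <- target_s$atoms
  rkey <- residue_key(ta$chain, ta$resno, ta$insert)
  per_res <- tapply(delta, factor(rkey, levels = unique(rkey)), sum)
  rt <- residue_table(target_s)
  rt$dsasa <- as.numeric(per_res[rt$key])

  # nearest-binder-chain attribution of each buried target atom
  binder_atoms <- complex_s$atoms[complex_s$atoms$chain %in% binder_chains, , drop = FALSE]
  bxyz <- as.matrix(binder_atoms[, c("x", "y", "z")])
  partition <- stats::setNames(numeric(length(binder_chains)), binder_chains)
  buried <- which(delta > 0)
  if (length(buried) > 0) {
    txyz <- as.matrix(ta[buried, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(txyz^2), rowSums(bxyz^2), "+") - 2 * tcrossprod(txyz, bxyz)
    nearest_chain <- binder_atoms$chain[max.col(-d2, ties.method = "first")]
    sums <- tapply(delta[buried], nearest_chain, sum)
    partition[names(sums)] <- as.numeric(sums)
  }

  total <- sum(delta)
  if (total == 0)
    warning("zero total buried area: the chain groups do not touch")

  fp <- structure(list(
    per_residue = rt[, c("chain", "resno", "insert", "resid", "key", "dsasa")],
    epitope = rt[rt$dsasa >= epitope_threshold,
                 c("chain", "resno", "insert", "resid", "key", "dsasa")],
    partition = partition, total = total,
    epitope_threshold = epitope_threshold,
    target_chains = target_chains, binder_chains = binder_chains,
    structure_id = structure$id
  ), class = "footprint")
  fp
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("<footprint> %s: %s buried by %s\n", x$structure_id,
              paste(x$target_chains, collapse = "+"),
              paste(x$binder_chains, collapse = "+")))
  cat(sprintf("  total buried: %.1f A^2; epitope residues (>= %.1f A^2): %d\n",
              x$total, x$epitope_threshold, nrow(x$epitope)))
  part <- paste(sprintf("%s %.1f", names(x$partition), x$partition),
                collapse = ", ")
  cat("  partition by binder chain: ", part, "\n", sep = "")
  invisible(x)
}

# --- contact machinery -------------------------------------------------------

# Carbon atoms with no N/O/S neighbour in the same residue are apolar.
apolar_carbon_flags <- function(atoms) {
  flag <- logical(nrow(atoms))
  rkey <- residue_key(atoms$chain, atoms$resno, atoms$insert)
  for (k in unique(rkey)) {
    ii <- which(rkey == k)
    sub <- atoms[ii, , drop = FALSE]
    carb <- sub$element == "C"
    if (!any(carb)) next
    pol <- sub$element %in% c("N", "O", "S")
    if (!any(pol)) { flag[ii[carb]] <- TRUE; next }
    cxyz <- as.matrix(sub[carb, c("x", "y", "z"), drop = FALSE])
    pxyz <- as.matrix(sub[pol, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(cxyz^2), rowSums(pxyz^2), "+") - 2 * tcrossprod(cxyz, pxyz)
    flag[ii[carb]] <- apply(d2, 1, min) > 1.7^2
  }
  flag
}

# Rows of `atoms` acting as hbond donors / acceptors (heavy-atom chemistry).
hb_capable <- function(atoms, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  tab <- if (role == "donor") HB_DONORS else HB_ACCEPTORS
  side <- mapply(function(res, nm) nm %in% (tab[[res]] %||% character(0)),
                 atoms$resid, atoms$name)
  if (role == "donor") {
    bb <- atoms$name == "N" & atoms$resid != "PRO"
  } else {
    bb <- atoms$name %in% c("O", "OXT")
  }
  which(side | bb)
}

# Covalently bonded heavy neighbours of atom `i` within its own residue.
antecedent_coords <- function(atoms, i, max_bond = 1.8) {
  same <- atoms$chain == atoms$chain[i] & atoms$resno == atoms$resno[i] &
    atoms$insert == atoms$insert[i]
  same[i] <- FALSE
  if (!any(same)) return(NULL)
  sub <- as.matrix(atoms[same, c("x", "y", "z"), drop = FALSE])
  p <- as.numeric(atoms[i, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(sub, 2, p)^2))
  keep <- d < max_bond
  if (!any(keep)) return(NULL)
  sub[keep, , drop = FALSE]
}

# Ring centroids and (unit) normals for aromatic residues in `atoms`.
ring_table <- function(atoms) {
  rkey <- residue_key(atoms$chain, atoms$resno, atoms$insert)
  out <- list()
  for (k in unique(rkey)) {
    ii <- which(rkey == k)
    res <- atoms$resid[ii[1]]
    defs <- RING_ATOMS[[res]]
    if (is.null(defs)) next
    for (d in defs) {
      jj <- ii[match(d, atoms$name[ii])]
      if (anyNA(jj)) next
      xyz <- as.matrix(atoms[jj, c("x", "y", "z")])
      centroid <- colMeans(xyz)
      sv <- svd(sweep(xyz, 2, centroid))
      normal <- sv$v[, 3]
      out[[length(out) + 1]] <- list(
        chain = atoms$chain[ii[1]], resno = atoms$resno[ii[1]],
        insert = atoms$insert[ii[1]], resid = res,
        label = paste0("ring[", paste(d, collapse = ","), "]"),
        centroid = centroid, normal = normal
      )
    }
  }
  out
}

contact_row <- function(kind, a_chain, a_resno, a_resid, a_atom,
                        b_chain, b_resno, b_resid, b_atom, distance, angle = NA_real_) {
  data.frame(kind = kind, chain_a = a_chain, resno_a = a_resno,
             resid_a = a_resid, atom_a = a_atom, chain_b = b_chain,
             resno_b = b_resno, resid_b = b_resid, atom_b = b_atom,
             distance = distance, angle = angle, stringsAsFactors = FALSE)
}

#' Classify interface contacts between two chain groups
#'
#' Detects four geometrically defined contact classes across the interface:
#' hydrogen bonds (donor-capable vs acceptor-capable heavy atoms, N/O/S
#' chemistry table, distance plus a heavy-atom proxy angle at the donor),
#' hydrophobic contacts (pairs of apolar carbons), pi-stacking (parallel
#' aromatic ring centroids of His/Phe/Tyr/Trp) and cation-pi (Lys NZ or Arg
#' CZ against a ring centroid). Waters and heteroatoms are excluded. The
#' result is sorted by kind, then distance. Columns `*_a` always refer to
#' `group_a` atoms and `*_b` to `group_b`, whichever side donates.
#'
#' @param structure An `epi_structure`.
#' @param group_a,group_b Disjoint chain-id sets.
#' @param criteria A [contact_criteria()] object.
#' @return A data frame of contacts (possibly 0-row) with columns `kind`,
#'   `chain_a`, `resno_a`, `resid_a`, `atom_a`, `chain_b`, `resno_b`,
#'   `resid_b`, `atom_b`, `distance`, `angle`.
#' @export
classify_contacts <- function(structure, group_a, group_b,
                              criteria = contact_criteria()) {
  if (length(intersect(group_a, group_b)) > 0)
    stop("chain groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  sa <- select_structure(structure, chains = group_a, exclude_waters = TRUE,
                         exclude_hetero = TRUE)$atoms
  sb <- select_structure(structure, chains = group_b, exclude_waters = TRUE,
                         exclude_hetero = TRUE)$atoms

  rows <- list()
  axyz <- as.matrix(sa[, c("x", "y", "z")])
  bxyz <- as.matrix(sb[, c("x", "y", "z")])
  cross_d2 <- function(i, j) {
    p <- axyz[i, , drop = FALSE]; q <- bxyz[j, , drop = FALSE]
    outer(rowSums(p^2), rowSums(q^2), "+") - 2 * tcrossprod(p, q)
  }

  # -- hydrogen bonds, both donation directions
  hb_pairs <- function(don_atoms, don_idx, acc_atoms, acc_idx, a_is_donor) {
    if (length(don_idx) == 0 || length(acc_idx) == 0) return(NULL)
    dx <- as.matrix(don_atoms[don_idx, c("x", "y", "z"), drop = FALSE])
    ax <- as.matrix(acc_atoms[acc_idx, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(dx^2), rowSums(ax^2), "+") - 2 * tcrossprod(dx, ax)
    hits <- which(d2 <= criteria$hbond_da_max^2 & d2 > 1e-6, arr.ind = TRUE)
    out <- NULL
    for (h in seq_len(nrow(hits))) {
      di <- don_idx[hits[h, 1]]; ai <- acc_idx[hits[h, 2]]
      dpos <- as.numeric(don_atoms[di, c("x", "y", "z")])
      apos <- as.numeric(acc_atoms[ai, c("x", "y", "z")])
      ante <- antecedent_coords(don_atoms, di)
      ang <- NA_real_
      if (!is.null(ante)) {
        v_da <- apos - dpos
        angs <- apply(ante, 1, function(xp) {
          v <- xp - dpos
          cosv <- sum(v * v_da) / (vec_norm(v) * vec_norm(v_da))
          acos(pmin(1, pmax(-1, cosv))) * 180 / pi
        })
        ang <- min(angs)
        if (ang < criteria$hbond_angle_min) next
      }
      dist <- sqrt(sum((apos - dpos)^2))
      out <- rbind(out, if (a_is_donor)
        contact_row("hbond", don_atoms$chain[di], don_atoms$resno[di],
                    don_atoms$resid[di], don_atoms$name[di],
                    acc_atoms$chain[ai], acc_atoms$resno[ai],
                    acc_atoms$resid[ai], acc_atoms$name[ai], dist, ang)
      else
        contact_row("hbond", acc_atoms$chain[ai], acc_atoms$resno[ai],
                    acc_atoms$resid[ai], acc_atoms$name[ai],
                    don_atoms$chain[di], don_atoms$resno[di],
                    don_atoms$resid[di], don_atoms$name[di], dist, ang))
    }
    out
  }
  rows$hb1 <- hb_pairs(sa, hb_capable(sa, "donor"), sb, hb_capable(sb, "acceptor"), TRUE)
  rows$hb2 <- hb_pairs(sb, hb_capable(sb, "donor"), sa, hb_capable(sa, "acceptor"), FALSE)

  # -- hydrophobic apolar carbon pairs
  ap_a <- which(apolar_carbon_flags(sa))
  ap_b <- which(apolar_carbon_flags(sb))
  if (length(ap_a) > 0 && length(ap_b) > 0) {
    d2 <- cross_d2(ap_a, ap_b)
    hits <- which(d2 <= criteria$hydrophobic_cc_max^2, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      ia <- ap_a[hits[, 1]]; ib <- ap_b[hits[, 2]]
      rows$phob <- contact_row("hydrophobic", sa$chain[ia], sa$resno[ia],
                               sa$resid[ia], sa$name[ia], sb$chain[ib],
                               sb$resno[ib], sb$resid[ib], sb$name[ib],
                               sqrt(d2[hits]))
    }
  }

  # -- aromatic rings: pi-stacking and cation-pi
  rings_a <- ring_table(sa)
  rings_b <- ring_table(sb)
  for (ra in rings_a) for (rb in rings_b) {
    dist <- vec_norm(ra$centroid - rb$centroid)
    if (dist > criteria$pi_centroid_max) next
    cosv <- abs(sum(ra$normal * rb$normal))
    ang <- acos(pmin(1, cosv)) * 180 / pi
    if (ang > criteria$pi_angle_parallel_max) next
    rows[[length(rows) + 1]] <-
      contact_row("pi_stack", ra$chain, ra$resno, ra$resid, ra$label,
                  rb$chain, rb$resno, rb$resid, rb$label, dist, ang)
  }
  cation_hits <- function(cat_atoms, rings, cat_is_a) {
    ci <- which(mapply(function(res, nm)
      nm %in% (CATION_ATOMS[[res]] %||% character(0)),
      cat_atoms$resid, cat_atoms$name))
    out <- NULL
    for (i in ci) for (r in rings) {
      p <- as.numeric(cat_atoms[i, c("x", "y", "z")])
      dist <- vec_norm(p - r$centroid)
      if (dist > criteria$cation_pi_max) next
      out <- rbind(out, if (cat_is_a)
        contact_row("cation_pi", cat_atoms$chain[i], cat_atoms$resno[i],
                    cat_atoms$resid[i], cat_atoms$name[i],
                    r$chain, r$resno, r$resid, r$label, dist)
      else
        contact_row("cation_pi", r$chain, r$resno, r$resid, r$label,
                    cat_atoms$chain[i], cat_atoms$resno[i],
                    cat_atoms$resid[i], cat_atoms$name[i], dist))
    }
    out
  }
  rows$cp1 <- cation_hits(sa, rings_b, TRUE)
  rows$cp2 <- cation_hits(sb, rings_a, FALSE)

  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- contact_row(character(0), character(0), integer(0), character(0),
                       character(0), character(0), integer(0), character(0),
                       character(0), numeric(0), numeric(0))
  out <- out[order(out$kind, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine a footprint and a contact list into a serialisable report
#'
#' @param footprint A [compute_footprint()] result.
#' @param contacts A [classify_contacts()] data frame from the same
#'   structure (may be 0-row).
#' @return A list of class `footprint_report` with stable key ordering,
#'   ready for `jsonlite::toJSON(..., auto_unbox = TRUE)`.
#' @export
footprint_report <- function(footprint, contacts = NULL) {
  per_res <- footprint$per_residue
  per_res <- per_res[order(per_res$chain, per_res$resno, per_res$insert), ]
  rep <- list(
    structure = footprint$structure_id,
    target_chains = footprint$target_chains,
    binder_chains = footprint$binder_chains,
    total_buried = footprint$total,
    partition = as.list(footprint$partition),
    epitope_threshold = footprint$epitope_threshold,
    epitope_residues = paste0(footprint$epitope$resid, footprint$epitope$resno),
    per_residue = per_res[per_res$dsasa > 0,
                          c("chain", "resno", "resid", "dsasa")],
    contacts = if (is.null(contacts)) NULL else contacts
  )
  class(rep) <- "footprint_report"
  rep
}

#' @export
print.footprint_report <- function(x, ...) {
  cat(sprintf("Footprint report: %s (%s buried by %s)\n", x$structure,
              paste(x$target_chains, collapse = "+"),
              paste(x$binder_chains, collapse = "+")))
  cat(sprintf("  total buried %.1f A^2 (%s)\n", x$total_buried,
              paste(sprintf("%s: %.1f", names(x$partition),
                            unlist(x$partition)), collapse = ", ")))
  cat("  epitope: ", paste(x$epitope_residues, collapse = " "), "\n", sep = "")
  if (!is.null(x$contacts) && nrow(x$contacts) > 0) {
    tab <- table(x$contacts$kind)
    cat("  contacts: ",
        paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
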