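# Deterministic synthetic fixtures: toy two-chain complexes with planted
# interface contacts, receptor-family MSAs with variant tables, and
# simulated BLI dilution series. Every generator is a pure function of its
# arguments and seed, so regeneration is byte-identical.

# NeRF internal-coordinate atom placement: position D given A-B-C, the
# C-D bond length, B-C-D angle and A-B-C-D dihedral (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit_vec(c - b)
  n <- unit_vec(pracma_cross(b - a, bc))
  m <- cbind(bc, pracma_cross(n, bc), n)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  as.numeric(c + m %*% d2)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Ideal alpha-helix backbone (phi -57, psi -47, omega 180) of n residues.
# Returns a list of per-residue matrices with rows N, CA, C, O, and the CB
# direction helper. The helix is rotated so its axis lies on +x and centred
# at the origin.
build_helix_backbone <- function(n) {
  phi <- -57; psi <- -47; omega <- 180
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231
  a_ncac <- 111.2; a_cacn <- 116.6; a_cnca <- 121.9; a_caco <- 120.5

  res <- vector("list", n)
  N <- c(0, 0, 0); CA <- c(b_nca, 0, 0)
  C <- CA + b_cac * c(cos(pi - a_ncac * pi / 180), sin(pi - a_ncac * pi / 180), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      prev <- res[[i - 1]]
      N <- place_atom(prev["N", ], prev["CA", ], prev["C", ], b_cn, a_cacn, psi)
      CA <- place_atom(prev["CA", ], prev["C", ], N, b_nca, a_cnca, omega)
      C <- place_atom(prev["C", ], N, CA, b_cac, a_ncac, phi)
    }
    res[[i]] <- rbind(N = N, CA = CA, C = C, O = c(NA, NA, NA))
  }
  for (i in seq_len(n)) {
    O <- place_atom(res[[i]]["N", ], res[[i]]["CA", ], res[[i]]["C", ],
                    b_co, a_caco, psi + 180)
    res[[i]]["O", ] <- O
  }
  # centre and align the CA principal axis with +x
  cas <- t(vapply(res, function(r) r["CA", ], numeric(3)))
  ctr <- colMeans(cas)
  pc <- svd(sweep(cas, 2, ctr))$v
  if (det(pc) < 0) pc[, 3] <- -pc[, 3]
  for (i in seq_len(n)) {
    res[[i]] <- sweep(res[[i]], 2, ctr) %*% pc
    rownames(res[[i]]) <- c("N", "CA", "C", "O")
  }
  res
}

# Tetrahedral CB position from backbone N, CA, C.
cb_position <- function(N, CA, C, bond = 1.53) {
  u1 <- unit_vec(N - CA); u2 <- unit_vec(C - CA)
  bis <- unit_vec(u1 + u2); perp <- unit_vec(pracma_cross(u1, u2))
  phi <- 51.7 * pi / 180
  CA + bond * (-cos(phi) * bis + sin(phi) * perp)
}

# Reach (A) of the A-side terminal group and length of the B-side backfill
# for each plantable contact kind.
PLANT_GEOM <- list(
  hbond = list(reach_a = 1.53 + 1.42, backfill_b = 1.25 + 1.53),
  hydrophobic = list(reach_a = 3 * 1.53, backfill_b = 2 * 1.53),
  pi_stack = list(reach_a = 4.20, backfill_b = 2.4),
  cation_pi = list(reach_a = 4 * 1.53 + 1.46, backfill_b = 2.4)
)
PLANT_CUTFIELD <- c(hbond = "hbond_da_max", hydrophobic = "hydrophobic_cc_max",
                    pi_stack = "pi_centroid_max", cation_pi = "cation_pi_max")

# Regular ring of 6 carbons (radius 1.39) centred at `centre`, lying in the
# plane orthogonal to `normal`.
hexagon_atoms <- function(centre, normal, names) {
  normal <- unit_vec(normal)
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vec(pracma_cross(normal, ref))
  e2 <- pracma_cross(normal, e1)
  ang <- (0:5) * pi / 3
  xyz <- t(vapply(ang, function(a) centre + 1.39 * (cos(a) * e1 + sin(a) * e2),
                  numeric(3)))
  rownames(xyz) <- names
  xyz
}

#' Generate a toy two-helix complex with planted interface contacts
#'
#' Builds two ideal poly-alanine alpha-helices (phi/psi -57/-47, axes along
#' x) separated along y, and realises each planted contact by substituting
#' the named residue pair and placing side-chain atoms by explicit
#' internal-coordinate construction so the key interaction distance matches
#' the target to within 0.1 A. Supported kinds and the residues used:
#' `hbond` (Ser OG donor vs Asp OD1 acceptor), `hydrophobic` (Leu CD1 vs
#' Leu CD1), `pi_stack` (Phe ring vs Phe ring, face to face), `cation_pi`
#' (Lys NZ vs Trp six-membered ring). The inter-helix separation is chosen
#' automatically (large enough that only planted atoms can touch) unless
#' `gap` is given; planted residues must be at least 5 apart along each
#' chain so contacts cannot cross-talk.
#'
#' @param n_res Residues per chain.
#' @param gap Helix axis separation in Angstrom; defaults to the planted
#'   geometry requirement, or 9.5 (touching backbones, real burial) when
#'   nothing is planted.
#' @param planted_contacts List of specs, each
#'   `list(kind =, res_a =, res_b =, distance =)` with residue numbers on
#'   chains A and B and the target interaction distance in Angstrom.
#' @param seed Kept for interface symmetry with the other generators; the
#'   construction is fully deterministic.
#' @return List with `structure` (an `epi_structure`, chains A and B),
#'   `ground_truth` (data frame kind/resno_a/resno_b/distance) and `gap`.
#' @examples
#' toy <- make_toy_complex(planted_contacts = list(
#'   list(kind = "hbond", res_a = 5, res_b = 5, distance = 2.9)))
#' classify_contacts(toy$structure, "A", "B")
#' @export
make_toy_complex <- function(n_res = 20, gap = NULL, planted_contacts = list(),
                             seed = 1) {
  stopifnot(n_res >= 4)
  crit <- contact_criteria()
  for (pc in planted_contacts) {
    if (!all(c("kind", "res_a", "res_b", "distance") %in% names(pc)))
      stop("each planted contact needs kind, res_a, res_b, distance")
    if (!pc$kind %in% names(PLANT_GEOM))
      stop("unknown planted contact kind: ", pc$kind)
    if (pc$distance > crit[[PLANT_CUTFIELD[pc$kind]]] || pc$distance <= 0)
      stop("infeasible planted geometry: ", pc$kind, " at ", pc$distance,
           " A exceeds its classification cutoff")
    if (pc$res_a < 2 || pc$res_a > n_res - 1 || pc$res_b < 2 || pc$res_b > n_res - 1)
      stop("planted residues must lie in 2..(n_res-1)")
  }
  pos_a <- vapply(planted_contacts, function(p) p$res_a, numeric(1))
  pos_b <- vapply(planted_contacts, function(p) p$res_b, numeric(1))
  if (length(pos_a) > 1 &&
      (min(diff(sort(pos_a))) < 5 || min(diff(sort(pos_b))) < 5))
    stop("planted residues must be >= 5 residues apart on each chain")

  if (is.null(gap)) {
    gap <- if (length(planted_contacts) == 0) 9.5 else
      max(vapply(planted_contacts, function(pc) {
        g <- PLANT_GEOM[[pc$kind]]
        g$reach_a + pc$distance + g$backfill_b + 6.0
      }, numeric(1)))
  }
  if (gap <= 0) stop("gap must be positive")

  bb <- build_helix_backbone(n_res)
  shift_b <- c(0, gap, 0)

  atoms <- list(); serial <- 0L
  push <- function(chain, resno, resid, name, xyz) {
    serial <<- serial + 1L
    atoms[[length(atoms) + 1L]] <<- data.frame(
      serial = serial, name = name, element = guess_element(name),
      x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1, altloc = "",
      chain = chain, resno = resno, insert = "", resid = resid,
      is_hetero = FALSE, stringsAsFactors = FALSE)
  }

  planted_at <- function(chain, resno) {
    for (k in seq_along(planted_contacts)) {
      pc <- planted_contacts[[k]]
      if ((chain == "A" && pc$res_a == resno) ||
          (chain == "B" && pc$res_b == resno)) return(pc)
    }
    NULL
  }

  gt <- list()
  for (chain in c("A", "B")) {
    off <- if (chain == "A") c(0, 0, 0) else shift_b
    for (i in seq_len(n_res)) {
      r <- sweep(bb[[i]], 2, -off)
      pc <- planted_at(chain, i)
      resid <- "ALA"
      side <- NULL   # matrix of named side-chain atoms
      if (!is.null(pc)) {
        # interface direction from this CA toward the partner CA
        partner_i <- if (chain == "A") pc$res_b else pc$res_a
        partner_ca <- bb[[partner_i]]["CA", ] +
          (if (chain == "A") shift_b else c(0, 0, 0))
        ca <- r["CA", ]
        u <- unit_vec(partner_ca - ca)
        d <- pc$distance
        g <- PLANT_GEOM[[pc$kind]]
        a_side <- chain == "A"
        build <- plant_side_chain(pc$kind, ca, u, d, g, a_side, partner_ca)
        resid <- build$resid
        side <- build$atoms
      }
      push(chain, i, resid, "N", r["N", ])
      push(chain, i, resid, "CA", r["CA", ])
      push(chain, i, resid, "C", r["C", ])
      push(chain, i, resid, "O", r["O", ])
      if (is.null(side)) {
        push(chain, i, resid, "CB", cb_position(r["N", ], r["CA", ], r["C", ]))
      } else {
        for (nm in rownames(side)) push(chain, i, resid, nm, side[nm, ])
      }
    }
  }
  at <- do.call(rbind, atoms)
  s <- new_epi_structure("toy_complex", at)

  gt <- if (length(planted_contacts) == 0) {
    data.frame(kind = character(0), resno_a = integer(0), resno_b = integer(0),
               distance = numeric(0))
  } else {
    do.call(rbind, lapply(planted_contacts, function(pc)
      data.frame(kind = pc$kind, resno_a = pc$res_a, resno_b = pc$res_b,
                 distance = pc$distance, stringsAsFactors = FALSE)))
  }
  list(structure = s, ground_truth = gt, gap = gap)
}

# Explicit side-chain construction for one side of a planted contact.
# The A side carries the "terminal" group at its natural reach along u; the
# B side is built backwards from the point at `distance` beyond the A
# terminal, backfilling toward its own CA.
plant_side_chain <- function(kind, ca, u, d, geom, a_side, partner_ca) {
  if (a_side) {
    term <- ca + geom$reach_a * u
    switch(kind,
      hbond = {
        cb <- ca + 1.53 * u
        list(resid = "SER", atoms = rbind(CB = cb, OG = term))
      },
      hydrophobic = {
        list(resid = "LEU", atoms = rbind(CB = ca + 1.53 * u,
                                          CG = ca + 3.06 * u, CD1 = term))
      },
      pi_stack = {
        ring <- hexagon_atoms(term, u, c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))
        cb <- ring["CG", ] + 1.53 * unit_vec(ca - ring["CG", ])
        list(resid = "PHE", atoms = rbind(CB = cb, ring))
      },
      cation_pi = {
        list(resid = "LYS", atoms = rbind(
          CB = ca + 1.53 * u, CG = ca + 3.06 * u, CD = ca + 4.59 * u,
          CE = ca + 6.12 * u, NZ = term))
      })
  } else {
    # B-side terminal sits exactly `d` beyond the A-side terminal, i.e. at
    # reach_a + d from the partner CA, measured along the partner's u = -u.
    term <- partner_ca + (geom$reach_a + d) * (-u)
    back <- unit_vec(ca - term)   # direction from terminal toward own CA
    switch(kind,
      hbond = {
        cg <- term + 1.25 * back
        cb <- cg + 1.53 * back
        # second carboxylate oxygen, placed laterally away from the interface
        lat <- unit_vec(pracma_cross(back, if (abs(back[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)))
        od2 <- cg + 1.25 * unit_vec(back + 1.2 * lat)
        list(resid = "ASP", atoms = rbind(CB = cb, CG = cg, OD1 = term, OD2 = od2))
      },
      hydrophobic = {
        list(resid = "LEU", atoms = rbind(CB = term + 3.06 * back,
                                          CG = term + 1.53 * back, CD1 = term))
      },
      pi_stack = {
        ring <- hexagon_atoms(term, u, c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))
        cb <- term + 2.4 * back
        list(resid = "PHE", atoms = rbind(CB = cb, ring))
      },
      cation_pi = {
        ring <- hexagon_atoms(term, u, c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
        cb <- term + 2.4 * back
        list(resid = "TRP", atoms = rbind(CB = cb, ring))
      })
  }
}

#' Generate a KIR-like multiple sequence alignment with a variant table
#'
#' Emulates the shape of a KIR2D receptor-family alignment: a gapless
#' reference receptor plus homologues differing at a controlled number of
#' columns (one homologue additionally carries a 3-column deletion so gap
#' mapping is exercised), a variant table in each receptor's own mature
#' numbering, a synthetic per-position footprint covering the chosen
#' epitope positions, and the expected epitope-intersection report for the
#' downstream stage. Everything is a pure function of the seed.
#'
#' @param n_receptors Number of receptor sequences (2..7).
#' @param n_variants Number of variant records to plant.
#' @param epitope_positions Reference positions treated as the epitope.
#' @param seq_length Ungapped reference length (also alignment width).
#' @param n_sub Substituted columns per non-reference receptor.
#' @param seed Integer seed controlling all random choices.
#' @param out_dir Optional directory; when given, `msa.afa`,
#'   `variants.csv`, `footprint.csv` and `expected_report.csv` are written
#'   there (byte-identical across reruns with the same arguments).
#' @return List with `msa`, `variants`, `footprint` (data frame
#'   position/dsasa), `expected` (data frame variant -> reference position,
#'   in_epitope) and `paths` (NULL unless `out_dir` given).
#' @export
make_kir_like_msa <- function(n_receptors = 7, n_variants = 12,
                              epitope_positions = c(41, 45, 46, 47, 48, 50, 65, 72, 87, 88),
                              seq_length = 110, n_sub = 8, seed = 1,
                              out_dir = NULL) {
  stopifnot(n_receptors >= 2, n_receptors <= 7,
            max(epitope_positions) <= seq_length)
  ids <- c("KIR2DL3", "KIR2DL1", "KIR2DL2", "KIR2DS1", "KIR2DS3",
           "KIR2DS4", "KIR2DS5")[seq_len(n_receptors)]
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

  out <- with_private_seed(seed, {
    ref <- sample(aas, seq_length, replace = TRUE)
    seqs <- list(ref)
    for (k in seq_len(n_receptors - 1)) {
      s <- ref
      cols <- sample(seq_length, n_sub)
      for (cc in cols) s[cc] <- sample(setdiff(aas, s[cc]), 1)
      seqs[[k + 1]] <- s
    }
    # last homologue gets a 3-column deletion outside the epitope
    if (n_receptors >= 3) {
      cand <- setdiff(seq(10, seq_length - 10), epitope_positions)
      gstart <- cand[sample(length(cand) - 3, 1)]
      seqs[[n_receptors]][gstart:(gstart + 2)] <- "-"
    }
    msa <- new_msa(ids, vapply(seqs, paste, character(1), collapse = ""))

    non_epi <- setdiff(seq_len(seq_length), epitope_positions)
    n_in <- min(ceiling(n_variants / 2), length(epitope_positions))
    cols_in <- sample(epitope_positions, n_in)
    cols_out <- sample(non_epi, n_variants - n_in)
    cols <- c(cols_in, cols_out)
    recs <- sample(ids, n_variants, replace = TRUE)

    rows <- list(); expected <- list()
    for (i in seq_len(n_variants)) {
      rid <- match(recs[i], ids)
      chars <- strsplit(msa$seqs[rid], "")[[1]]
      col <- cols[i]
      if (chars[col] == "-") { # variant cannot sit on a gap; nudge receptor
        rid <- 1; recs[i] <- ids[1]
        chars <- strsplit(msa$seqs[rid], "")[[1]]
      }
      own_pos <- sum(chars[seq_len(col)] != "-")
      ref_aa <- chars[col]
      alt_aa <- sample(setdiff(aas, ref_aa), 1)
      rows[[i]] <- data.frame(
        receptor = recs[i], position = own_pos, ref = ref_aa, alt = alt_aa,
        rs_id = sprintf("rs%07d", sample.int(9999999, 1)),
        frequency = round(stats::runif(1, 1e-4, 0.2), 4),
        stringsAsFactors = FALSE)
      expected[[i]] <- data.frame(
        receptor = recs[i], position = own_pos,
        reference_position = col, in_epitope = col %in% epitope_positions,
        stringsAsFactors = FALSE)
    }
    fp <- data.frame(position = sort(epitope_positions),
                     dsasa = round(stats::runif(length(epitope_positions), 5, 60), 1))
    list(msa = msa, variants = do.call(rbind, rows),
         expected = do.call(rbind, expected), footprint = fp)
  })

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(msa = file.path(out_dir, "msa.afa"),
                  variants = file.path(out_dir, "variants.csv"),
                  footprint = file.path(out_dir, "footprint.csv"),
                  expected = file.path(out_dir, "expected_report.csv"))
    write_msa(out$msa, paths$msa)
    utils::write.csv(out$variants, paths$variants, row.names = FALSE, quote = FALSE)
    utils::write.csv(out$footprint, paths$footprint, row.names = FALSE, quote = FALSE)
    utils::write.csv(out$expected, paths$expected, row.names = FALSE, quote = FALSE)
  }
  c(out, list(paths = paths, epitope_positions = epitope_positions))
}

#' Generate a simulated BLI dilution-series dataset on disk
#'
#' Simulates a two-fold dilution series under the 1:1 Langmuir model
#' (defaults: 300 s association, 600 s dissociation, the design used for
#' antibody-receptor affinity panels) and writes one CSV per well plus a
#' manifest consumable by [read_bli_dataset()].
#'
#' @param params [kinetics_params()] ground truth.
#' @param top_concentration Highest analyte concentration, M.
#' @param n_dilutions Number of two-fold dilution steps (wells).
#' @param t_assoc,t_dissoc,dt Phase lengths and sampling interval, s.
#' @param noise_sd Gaussian noise sd, nm.
#' @param seed Seed; well i uses sub-seed `seed * 1000 + i`.
#' @param out_dir Output directory (created if needed).
#' @return List with `traces`, `manifest` (path),
#'   `insufficient_for_global_fit` (TRUE when fewer than 2 wells) and
#'   `concentrations`.
#' @export
make_bli_dataset <- function(params, top_concentration = 250e-9,
                             n_dilutions = 6, t_assoc = 300, t_dissoc = 600,
                             dt = 1, noise_sd = 0, seed = 1,
                             out_dir = tempfile("bli_")) {
  stopifnot(inherits(params, "kinetics_params"), n_dilutions >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  concs <- top_concentration / 2^(seq_len(n_dilutions) - 1)
  traces <- list(); files <- character(n_dilutions)
  for (i in seq_len(n_dilutions)) {
    tr <- simulate_trace(params, concs[i], t_assoc, t_dissoc, dt,
                         noise_sd = noise_sd, seed = seed * 1000 + i)
    files[i] <- sprintf("trace_%02d.csv", i)
    utils::write.csv(data.frame(time_s = tr$times, response_nm = tr$responses),
                     file.path(out_dir, files[i]), row.names = FALSE, quote = FALSE)
    traces[[i]] <- tr
  }
  man <- data.frame(file = files, concentration_M = concs,
                    t_assoc_end_s = t_assoc)
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE, quote = FALSE)
  list(traces = traces, manifest = manifest,
       insufficient_for_global_fit = n_dilutions < 2,
       concentrations = concs)
}
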