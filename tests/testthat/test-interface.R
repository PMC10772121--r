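fast_sasa <- sasa_params(n_sphere_points = 240)

test_that("distant chains bury nothing and produce an empty epitope", {
  toy <- make_toy_complex(n_res = 6, gap = 100)
  expect_warning(fp <- compute_footprint(toy$structure, "A", "B", fast_sasa),
                 "zero")
  expect_equal(fp$total, 0)
  expect_equal(nrow(fp$epitope), 0)
  expect_equal(sum(fp$partition), 0)
})

test_that("footprint equals the direct two-state SASA difference", {
  toy <- make_toy_complex(n_res = 10, gap = 9)
  fp <- compute_footprint(toy$structure, "A", "B", fast_sasa)
  # brute-force recomputation: target alone vs target within complex
  alone <- compute_sasa(select_structure(toy$structure, "A"), fast_sasa)
  both <- compute_sasa(toy$structure, fast_sasa)
  in_a <- toy$structure$atoms$chain == "A"
  expected_total <- sum(pmax(alone$per_atom - both$per_atom[in_a], 0))
  expect_equal(fp$total, expected_total, tolerance = 1e-9)
  expect_gt(fp$total, 0)
})

test_that("chain partition is exhaustive and exclusive", {
  # three-chain complex: duplicate chain B as a second binder chain C
  toy <- make_toy_complex(n_res = 8, gap = 9)
  at <- toy$structure$atoms
  cc <- at[at$chain == "B", ]
  cc$chain <- "C"; cc$z <- cc$z + 30; cc$serial <- cc$serial + 1000L
  s3 <- epifoot:::new_epi_structure("tri", rbind(at, cc))
  fp <- compute_footprint(s3, "A", c("B", "C"), fast_sasa)
  expect_named(fp$partition, c("B", "C"))
  expect_equal(sum(fp$partition), fp$total, tolerance = 1e-9)
  expect_equal(sum(fp$per_residue$dsasa), fp$total, tolerance = 1e-9)
})

test_that("one-sided footprints are bounded by the two-sided interface area", {
  toy <- make_toy_complex(n_res = 8, gap = 9)
  fa <- compute_footprint(toy$structure, "A", "B", fast_sasa)
  fb <- compute_footprint(toy$structure, "B", "A", fast_sasa)
  expect_gte(fa$total, 0)
  expect_gte(fb$total, 0)
  two_sided <- fa$total + fb$total
  expect_lte(fa$total, two_sided)
  expect_lte(fb$total, two_sided)
})

test_that("overlapping chain groups are rejected", {
  toy <- make_toy_complex(n_res = 6)
  expect_error(compute_footprint(toy$structure, "A", c("A", "B")), "overlap")
  expect_error(classify_contacts(toy$structure, "A", "A"), "overlap")
})

test_that("planted contacts are recovered with their kind and distance", {
  plants <- list(
    list(kind = "hbond", res_a = 3, res_b = 3, distance = 2.9),
    list(kind = "hydrophobic", res_a = 9, res_b = 9, distance = 4.0),
    list(kind = "cation_pi", res_a = 15, res_b = 15, distance = 4.5)
  )
  toy <- make_toy_complex(n_res = 18, planted_contacts = plants)
  ct <- classify_contacts(toy$structure, "A", "B")
  for (p in plants) {
    hit <- ct[ct$resno_a == p$res_a & ct$resno_b == p$res_b, ]
    expect_equal(unique(hit$kind), p$kind, info = p$kind)
    expect_equal(min(abs(hit$distance - p$distance)), 0, tolerance = 0.1)
  }
  # nothing recovered between unplanted residue pairs
  planted_pairs <- vapply(plants, function(p) paste(p$res_a, p$res_b), "")
  expect_true(all(paste(ct$resno_a, ct$resno_b) %in% planted_pairs))
})

test_that("a face-to-face aromatic pair classifies as pi-stacking", {
  toy <- make_toy_complex(planted_contacts = list(
    list(kind = "pi_stack", res_a = 5, res_b = 5, distance = 5.0)))
  ct <- classify_contacts(toy$structure, "A", "B")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$kind, "pi_stack")
  expect_equal(ct$distance, 5.0, tolerance = 0.1)
  expect_lt(ct$angle, 5)
})

test_that("distant residues yield no contacts and output is kind/distance sorted", {
  toy <- make_toy_complex(n_res = 6, gap = 50)
  expect_equal(nrow(classify_contacts(toy$structure, "A", "B")), 0)

  toy2 <- make_toy_complex(n_res = 14, planted_contacts = list(
    list(kind = "hbond", res_a = 3, res_b = 3, distance = 2.9),
    list(kind = "hbond", res_a = 9, res_b = 9, distance = 3.3)))
  ct <- classify_contacts(toy2$structure, "A", "B")
  expect_false(is.unsorted(ct$distance[ct$kind == "hbond"]))
})

test_that("contact classification is invariant under rigid-body motion", {
  toy <- make_toy_complex(planted_contacts = list(
    list(kind = "hbond", res_a = 4, res_b = 4, distance = 3.0),
    list(kind = "cation_pi", res_a = 12, res_b = 12, distance = 5.0)),
    n_res = 15)
  ct0 <- classify_contacts(toy$structure, "A", "B")
  set.seed(3)
  moved <- rotate_structure(toy$structure, random_rotation(), shift = c(12, -5, 40))
  ct1 <- classify_contacts(moved, "A", "B")
  expect_equal(ct1[, setdiff(names(ct1), c("distance", "angle"))],
               ct0[, setdiff(names(ct0), c("distance", "angle"))])
  expect_equal(ct1$distance, ct0$distance, tolerance = 1e-9)
})

test_that("footprint report serialises totals consistently", {
  toy <- make_toy_complex(n_res = 8, gap = 9)
  fp <- compute_footprint(toy$structure, "A", "B", fast_sasa)
  ct <- classify_contacts(toy$structure, "A", "B")
  rep <- footprint_report(fp, ct)
  expect_equal(rep$total_buried, fp$total)
  expect_equal(sum(unlist(rep$partition)), fp$total, tolerance = 1e-9)
  json <- jsonlite::toJSON(unclass(rep), auto_unbox = TRUE, force = TRUE)
  expect_true(jsonlite::validate(json))

  expect_warning(fp0 <- compute_footprint(make_toy_complex(n_res = 5, gap = 80)$structure,
                                          "A", "B", fast_sasa))
  rep0 <- footprint_report(fp0)
  expect_equal(rep0$total_buried, 0)
})
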