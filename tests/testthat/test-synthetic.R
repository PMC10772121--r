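test_that("toy complexes are deterministic and write valid PDB", {
  t1 <- make_toy_complex(n_res = 10, planted_contacts = list(
    list(kind = "hbond", res_a = 4, res_b = 4, distance = 2.9)))
  t2 <- make_toy_complex(n_res = 10, planted_contacts = list(
    list(kind = "hbond", res_a = 4, res_b = 4, distance = 2.9)))
  expect_identical(t1$structure$atoms, t2$structure$atoms)
  f1 <- write_structure(t1$structure, tempfile(fileext = ".pdb"))
  f2 <- write_structure(t2$structure, tempfile(fileext = ".pdb"))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted geometry hits its target distance within 0.1 A", {
  for (spec in list(list(kind = "hbond", d = 3.1),
                    list(kind = "hydrophobic", d = 4.2),
                    list(kind = "pi_stack", d = 5.2),
                    list(kind = "cation_pi", d = 5.5))) {
    toy <- make_toy_complex(planted_contacts = list(
      list(kind = spec$kind, res_a = 6, res_b = 6, distance = spec$d)))
    ct <- classify_contacts(toy$structure, "A", "B")
    hit <- ct[ct$kind == spec$kind & ct$resno_a == 6 & ct$resno_b == 6, ]
    expect_gte(nrow(hit), 1)
    expect_equal(min(abs(hit$distance - spec$d)), 0, tolerance = 0.1)
  }
})

test_that("infeasible planted geometry is rejected at construction", {
  expect_error(make_toy_complex(planted_contacts = list(
    list(kind = "hbond", res_a = 4, res_b = 4, distance = 4.2))), "infeasible")
  expect_error(make_toy_complex(planted_contacts = list(
    list(kind = "nonsense", res_a = 4, res_b = 4, distance = 3))), "unknown")
  expect_error(make_toy_complex(n_res = 12, planted_contacts = list(
    list(kind = "hbond", res_a = 4, res_b = 4, distance = 2.9),
    list(kind = "hbond", res_a = 6, res_b = 6, distance = 2.9))), "apart")
})

test_that("helix backbone has ideal covalent geometry", {
  s <- select_structure(make_toy_complex(n_res = 8)$structure, "A")
  at <- s$atoms
  get <- function(resno, name) unlist(at[at$resno == resno & at$name == name,
                                         c("x", "y", "z")])
  for (i in 2:7) {
    expect_equal(sqrt(sum((get(i, "N") - get(i, "CA"))^2)), 1.458,
                 tolerance = 1e-3)
    expect_equal(sqrt(sum((get(i, "CA") - get(i, "C"))^2)), 1.525,
                 tolerance = 1e-3)
    expect_equal(sqrt(sum((get(i, "C") - get(i + 1, "N"))^2)), 1.329,
                 tolerance = 1e-3)
  }
  # alpha-helical rise per residue ~1.5 A along the axis
  cas <- at[at$name == "CA", c("x", "y", "z")]
  rise <- diff(range(cas$x)) / (nrow(cas) - 1)
  expect_equal(rise, 1.5, tolerance = 0.2)
})

test_that("MSA/variant fixtures regenerate byte-identically at a fixed seed", {
  d1 <- tempfile("fix1"); d2 <- tempfile("fix2")
  make_kir_like_msa(seed = 4, out_dir = d1)
  make_kir_like_msa(seed = 4, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and different seeds differ
  d3 <- tempfile("fix3")
  make_kir_like_msa(seed = 5, out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "msa.afa")),
                         readLines(file.path(d3, "msa.afa"))))
})

test_that("every generated fixture carries machine-readable ground truth", {
  k <- make_kir_like_msa(n_receptors = 4, n_variants = 0, seed = 2)
  expect_null(k$expected)      # no variants -> empty expected report
  k2 <- make_kir_like_msa(n_receptors = 4, n_variants = 5, seed = 2)
  expect_equal(nrow(k2$expected), 5)
  expect_true(all(c("reference_position", "in_epitope") %in% names(k2$expected)))

  toy <- make_toy_complex(planted_contacts = list(
    list(kind = "cation_pi", res_a = 5, res_b = 5, distance = 4.5)))
  expect_equal(toy$ground_truth$kind, "cation_pi")

  d <- make_bli_dataset(kinetics_params(1e5, 1e-3, 1), n_dilutions = 2,
                        dt = 20, out_dir = tempfile())
  expect_true(file.exists(d$manifest))
})

test_that("BLI fixture regeneration is byte-identical for a fixed seed", {
  p <- kinetics_params(1e5, 2.8e-4, 1)
  d1 <- tempfile("bli1"); d2 <- tempfile("bli2")
  make_bli_dataset(p, n_dilutions = 2, dt = 20, noise_sd = 0.02, seed = 6,
                   out_dir = d1)
  make_bli_dataset(p, n_dilutions = 2, dt = 20, noise_sd = 0.02, seed = 6,
                   out_dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("averaging many noisy replicates converges on the model curve", {
  p <- kinetics_params(1e5, 1e-3, 1)
  cc <- 50e-9
  clean <- simulate_trace(p, cc, dt = 30)
  reps <- vapply(1:100, function(i)
    simulate_trace(p, cc, dt = 30, noise_sd = 0.05, seed = i)$responses,
    numeric(length(clean$responses)))
  avg <- rowMeans(reps)
  se <- 0.05 / sqrt(100)
  expect_true(all(abs(avg - clean$responses) < 3 * se + 1e-12))
})
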