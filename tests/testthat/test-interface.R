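# Residue-level contacts: detection, classification, domain mapping.

test_that("planted atom pairs are found at the exact distance and respect the cutoff", {
  sf <- make_structure_fixture(
    tibble::tibble(res_a = "ALA", atom_a = "CB", res_b = "ALA", atom_b = "CB",
                   distance = 4.9))
  ct <- inter_chain_contacts(sf$model, "A", "B", cutoff = 5.0)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$distance, 4.9, tolerance = 1e-9)
  expect_equal(nrow(inter_chain_contacts(sf$model, "A", "B", cutoff = 4.5)), 0L)
  # a pair just beyond the cutoff is not a contact
  sf2 <- make_structure_fixture(
    tibble::tibble(res_a = "ALA", atom_a = "CB", res_b = "ALA", atom_b = "CB",
                   distance = 5.1))
  expect_equal(nrow(inter_chain_contacts(sf2$model, "A", "B", cutoff = 5.0)), 0L)
})

test_that("contacts are inter-chain only and hydrogens are ignored", {
  atoms <- data.frame(
    chain = c("A", "A", "B", "B"),
    resno_auth = c(1, 2, 1, 1),
    resid = "ALA",
    elety = c("CA", "CA", "CA", "HA"),
    elesy = c("C", "C", "C", "H"),
    x = c(0, 3, 100, 1),   # A1-A2 are 3 A apart; B's hydrogen is 1 A from A1
    y = 0, z = 0)
  model <- structure_model(atoms)
  ct <- inter_chain_contacts(model, "A", "B", cutoff = 5)
  expect_equal(nrow(ct), 0L)  # same-chain proximity and H atoms both excluded
  expect_error(inter_chain_contacts(model, "A", "A"),
               class = "spryscreen_chain_error")
  expect_error(inter_chain_contacts(model, "A", "C"),
               class = "spryscreen_chain_error")
})

test_that("contact classes follow the salt-bridge and polar rules", {
  sf <- make_structure_fixture(planted_contacts_spec())
  ct <- classify_contacts(inter_chain_contacts(sf$model, "A", "B"), sf$model)
  got <- ct[order(ct$resno_a), ]
  expect_identical(got$contact_class, c("salt_bridge", "polar", "generic"))
  # Asp-Lys beyond the 4 A salt-bridge cutoff degrades to polar at most
  far_salt <- make_structure_fixture(
    tibble::tibble(res_a = "ASP", atom_a = "OD1", res_b = "LYS", atom_b = "NZ",
                   distance = 4.4))
  ct2 <- classify_contacts(inter_chain_contacts(far_salt$model, "A", "B"),
                           far_salt$model)
  expect_false(ct2$contact_class == "salt_bridge")
  # every contact gets exactly one class; salt bridges lie within the cutoff
  expect_true(all(got$contact_class %in% c("salt_bridge", "polar", "generic")))
  expect_true(all(got$distance[got$contact_class == "salt_bridge"] <= 4.0))
})

test_that("domain contact fractions count distinct residues with inclusive ends", {
  ann <- tibble::tibble(protein = "TRIM25", domain = "SPRY",
                        start = 404L, end = 630L)
  mk_contacts <- function(resnos) tibble::tibble(
    chain_a = "A", resno_a = seq_along(resnos), resid_a = "ALA",
    chain_b = "B", resno_b = resnos, resid_b = "ALA",
    distance = 4.0, contact_class = "generic")
  expect_equal(
    domain_contact_fraction(mk_contacts(c(450, 500, 700)), ann,
                            "TRIM25", "SPRY", chain = "B"), 2 / 3)
  expect_equal(
    domain_contact_fraction(mk_contacts(c(410, 500)), ann,
                            "TRIM25", "SPRY", chain = "B"), 1.0)
  # both boundaries are inside; duplicated residues count once
  expect_equal(
    domain_contact_fraction(mk_contacts(c(404, 630, 631, 631)), ann,
                            "TRIM25", "SPRY", chain = "B"), 2 / 3)
  expect_error(
    domain_contact_fraction(mk_contacts(integer()), ann,
                            "TRIM25", "SPRY", chain = "B"),
    class = "spryscreen_undefined_fraction_error")
})

test_that("summarize_interface aggregates counts and the SPRY fraction", {
  td <- withr::local_tempdir()
  sf <- make_structure_fixture(planted_contacts_spec(), dir = td,
                               n_decoys_a = 0, n_decoys_b = 0)
  lens <- chain_lengths(sf$model)
  part <- chain_partition(lens, bait = "A", prey = "B")
  n <- sum(lens$length)
  pred <- complex_prediction(
    "BAITP__PREYP", "BAITP", "PREYP",
    pae_matrix(matrix(1, n, n)), part, model = sf$model)
  ann <- tibble::tibble(protein = "PREYP", domain = "SPRY",
                        start = 1L, end = 2L)
  s <- summarize_interface(pred, ann)
  expect_equal(s$n_contacts, 3L)
  expect_equal(s$n_salt_bridges, 1L)
  expect_equal(s$n_polar, 1L)
  expect_equal(s$spry_fraction, 2 / 3)  # prey residues 1..3; SPRY covers 1-2
  expect_identical(s, summarize_interface(pred, ann))  # deterministic
  # no structure -> classed error
  pred2 <- complex_prediction("x__y", "x", "y", pae_matrix(matrix(1, n, n)),
                              part)
  expect_error(summarize_interface(pred2, ann),
               class = "spryscreen_missing_structure_error")
})

test_that("summarize_interface reports an absent fraction when nothing touches", {
  sf <- make_structure_fixture(
    tibble::tibble(res_a = "ALA", atom_a = "CB", res_b = "ALA", atom_b = "CB",
                   distance = 12),
    n_decoys_a = 1, n_decoys_b = 1)
  lens <- chain_lengths(sf$model)
  part <- chain_partition(lens, bait = "A", prey = "B")
  n <- sum(lens$length)
  pred <- complex_prediction("a__b", "a", "b", pae_matrix(matrix(1, n, n)),
                             part, model = sf$model)
  s <- summarize_interface(pred, tibble::tibble(
    protein = "b", domain = "SPRY", start = 1L, end = 2L))
  expect_equal(s$n_contacts, 0L)
  expect_true(is.na(s$spry_fraction))
})

test_that("the optional PAE filter restricts contacts to confident residue pairs", {
  sf <- make_structure_fixture(planted_contacts_spec(), n_decoys_a = 0,
                               n_decoys_b = 0)
  lens <- chain_lengths(sf$model)
  part <- chain_partition(lens, bait = "A", prey = "B")
  n <- sum(lens$length)
  # contact pair (1,1) confident, (2,2) and (3,3) at high PAE
  m <- matrix(25, n, n)
  m[1, 3 + 1] <- 4; m[3 + 1, 1] <- 4
  pred <- complex_prediction("a__b", "a", "b", pae_matrix(m), part,
                             model = sf$model)
  expect_equal(summarize_interface(pred)$n_contacts, 3L)
  filtered <- summarize_interface(pred, pae_filter = 10)
  expect_equal(filtered$n_contacts, 1L)
  expect_equal(filtered$n_salt_bridges, 1L)
})

test_that("contact lists equal the O(N^2) oracle on 50 random structures", {
  set.seed(55)
  for (i in 1:50) {
    model <- random_toy_structure(sample(3:6, 1), sample(3:6, 1))
    cutoff <- runif(1, 3, 8)
    got <- inter_chain_contacts(model, "A", "B", cutoff)
    want <- contact_oracle(model, "A", "B", cutoff)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_identical(got$resno_a, want$resno_a)
      expect_identical(got$resno_b, want$resno_b)
      expect_equal(got$distance, want$distance, tolerance = 1e-12)
    }
  }
})

test_that("contact sets are nested across cutoffs", {
  set.seed(77)
  model <- random_toy_structure(6, 6)
  key <- function(ct) paste(ct$resno_a, ct$resno_b)
  c4 <- inter_chain_contacts(model, "A", "B", 4)
  c6 <- inter_chain_contacts(model, "A", "B", 6)
  expect_true(all(key(c4) %in% key(c6)))
  expect_gte(nrow(c6), nrow(c4))
})

test_that("contacts, classes and distances survive rigid motions", {
  set.seed(99)
  sf <- make_structure_fixture(planted_contacts_spec())
  base <- classify_contacts(inter_chain_contacts(sf$model, "A", "B"), sf$model)
  for (i in 1:5) {
    moved <- apply_rigid_motion(sf$model, random_rotation(), rnorm(3, 0, 50))
    got <- classify_contacts(inter_chain_contacts(moved, "A", "B"), moved)
    expect_identical(got$resno_a, base$resno_a)
    expect_identical(got$contact_class, base$contact_class)
    expect_equal(got$distance, base$distance, tolerance = 1e-6)
  }
})
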