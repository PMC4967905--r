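# Domain calling and architecture comparison.

test_that("a two-domain construction is called exactly", {
  catalog <- fix_catalog()
  protein <- orthofixr:::with_seed(2, orthofixr:::build_protein(
    catalog, catalog$family[c(1, 5)]))
  arch <- call_domains(protein$seq, catalog, protein_id = "p1")
  expect_identical(arch$family, protein$domains$family)
  expect_equal(arch$length_fraction, c(1, 1), tolerance = 0.02)
  expect_equal(arch$start, protein$domains$start, tolerance = 2)
  expect_error(call_domains("MKT", catalog[0, ]), "empty")
})

test_that("a half-length domain fragment is recovered with its true fraction", {
  # the worked case: family mean 470 residues, only ~230 present
  catalog <- build_domain_catalog(2, length_range = c(470L, 470L), seed = 9)
  fam <- catalog[1, ]
  protein <- paste0("M", substr(fam$consensus, 1L, 230L))
  arch <- call_domains(protein, catalog)
  expect_equal(nrow(arch), 1L)
  expect_equal(arch$family, fam$family)
  expect_equal(arch$length_fraction, 230 / 470, tolerance = 0.02)
})

test_that("architecture comparison classifies the canonical cases", {
  # C-terminal extension (carrier-protein-like case)
  cmp <- compare_architectures(c("A", "B", "B", "B"),
                               c("A", "B", "B", "B", "C"))
  expect_false(cmp$identical)
  expect_equal(cmp$edit, "c_terminal_extension")
  expect_equal(cmp$surplus_side, "b")
  expect_true(compare_architectures(c("A", "B"), c("A", "B"))$identical)
  # missing suffix block (split-gene N-part vs full-length)
  cmp2 <- compare_architectures(c("W", "K", "I", "U", "U", "N"),
                                c("W", "K", "I"))
  expect_false(cmp2$identical)
  expect_equal(cmp2$edit, "c_terminal_extension")
  expect_equal(cmp2$surplus_side, "a")
  expect_match(cmp2$details, "U,U,N")
  # N-terminal and internal cases
  expect_equal(compare_architectures(c("X"), c("Y", "X"))$edit,
               "n_terminal_extension")
  expect_equal(compare_architectures(c("A", "B"), c("A", "C", "B"))$edit,
               "internal_insertion")
  expect_equal(compare_architectures(c("A", "C", "B"), c("A", "B"))$edit,
               "internal_deletion")
  expect_equal(compare_architectures(c("A", "B", "B"), c("A", "B"))$edit,
               "repeat_count_change")
  expect_true(compare_architectures(c("A", "B", "B"), c("A", "B"),
                                    collapse_repeats = TRUE)$identical)
})

test_that("comparison is symmetric in the identical flag and mirrors edits", {
  cases <- list(
    list(a = c("A", "B"), b = c("A", "B", "C")),
    list(a = c("A", "B"), b = c("C", "A", "B")),
    list(a = c("A", "B", "B"), b = c("A", "B")))
  for (cs in cases) {
    f <- compare_architectures(cs$a, cs$b)
    r <- compare_architectures(cs$b, cs$a)
    expect_identical(f$identical, r$identical)
    expect_identical(f$edit, r$edit)  # category is positional, side flips
    if (!is.na(f$surplus_side))
      expect_false(identical(f$surplus_side, r$surplus_side))
  }
})

test_that("fragment architectures union into the intact architecture", {
  iv <- matrix(c(0, 300, 300, 620), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("start", "end")))
  mapping <- tibble::tibble(single_id = "z",
                            fragment_ids = list(c("x", "y")),
                            fragment_intervals = list(iv))
  fr1 <- tibble::tibble(protein_id = "x",
                        family = c("W", "K", "I"),
                        start = c(10, 110, 210), end = c(90, 190, 290),
                        score = c(100, 100, 100),
                        length_fraction = 1)
  fr2 <- tibble::tibble(protein_id = "y",
                        family = c("U", "U", "N"),
                        start = c(5, 105, 205), end = c(95, 195, 295),
                        score = c(100, 100, 100),
                        length_fraction = 1)
  un <- architecture_of_union(list(fr1, fr2), mapping)
  expect_identical(un$family, c("W", "K", "I", "U", "U", "N"))
  # single fragment unions to itself
  m1 <- tibble::tibble(single_id = "z", fragment_ids = list("x"),
                       fragment_intervals = list(iv[1, , drop = FALSE]))
  expect_identical(architecture_of_union(list(fr1), m1)$family, fr1$family)
  # a boundary hit shared by both fragments is counted once
  fr2b <- dplyr::bind_rows(
    tibble::tibble(protein_id = "y", family = "I", start = 0, end = 70,
                   score = 80, length_fraction = 0.8),
    fr2)
  iv2 <- iv; iv2[2, 1] <- 230
  m2 <- tibble::tibble(single_id = "z", fragment_ids = list(c("x", "y")),
                       fragment_intervals = list(iv2))
  un2 <- architecture_of_union(list(fr1, fr2b), m2)
  expect_identical(un2$family, c("W", "K", "I", "U", "U", "N"))
  expect_error(architecture_of_union(list(fr2, fr1), m2), "order")
})

test_that("domain calls reproduce the generator's architectures", {
  # exact at zero divergence
  clean <- fix_sim_clean()
  anc <- clean$ancestor
  ok <- vapply(anc$proteins$protein_id[1:25], function(gid) {
    arch <- call_domains(
      anc$proteins$seq[match(gid, anc$proteins$protein_id)],
      clean$catalog, protein_id = gid)
    identical(arch$family, truth_arch(anc, gid))
  }, logical(1))
  expect_true(all(ok))
  # near-exact at 20% substitution
  sim <- fix_sim()
  div <- diverge_species(sim$ancestor, 0.2, seed = 44, species = "D")
  total <- 0L; found <- 0L
  for (gid in div$proteins$protein_id[1:25]) {
    want <- truth_arch(div, gid)
    got <- call_domains(
      div$proteins$seq[match(gid, div$proteins$protein_id)],
      sim$catalog, protein_id = gid)$family
    total <- total + length(want)
    for (k in seq_along(want))
      if (k <= length(got) && got[k] == want[k]) found <- found + 1L
  }
  expect_gte(found / total, 0.99)
})

test_that("fused predictions differ from both source architectures", {
  sim <- fix_sim()
  labels <- sim$labels_b
  fus <- labels[labels$error_kind == "fusion", ]
  for (i in seq_len(nrow(fus))) {
    fseq <- sim$predicted_b$proteins$seq[
      match(fus$predicted_protein_id[i],
            sim$predicted_b$proteins$protein_id)]
    farch <- call_domains(fseq, sim$catalog)
    for (src in fus$source_gene_ids[[i]]) {
      cmp <- compare_architectures(farch$family,
                                   truth_arch(sim$truth_b, src))
      expect_false(cmp$identical)
    }
    # and the fused architecture is the concatenation of the sources
    expect_identical(
      farch$family,
      unlist(lapply(fus$source_gene_ids[[i]], truth_arch,
                    proteome = sim$truth_b), use.names = FALSE))
  }
})
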