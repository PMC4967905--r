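# Misprediction rules, junction tests, correction tiers, gene recovery.

hydrophilic_run <- function(n) paste(rep("S", n), collapse = "")
hydrophobic_run <- function(n) paste(rep("L", n), collapse = "")

test_that("windowed hydropathy finds transmembrane runs", {
  one <- paste0(hydrophilic_run(40), hydrophobic_run(19),
                hydrophilic_run(40))
  tm <- detect_tm_segments(one)
  expect_equal(nrow(tm), 1L)
  expect_lte(tm$start[1], 40L)
  expect_gte(tm$end[1], 59L)
  expect_equal(nrow(detect_tm_segments(hydrophilic_run(80))), 0L)
  two <- paste0(hydrophilic_run(30), hydrophobic_run(19),
                hydrophilic_run(30), hydrophobic_run(19),
                hydrophilic_run(30))
  expect_equal(nrow(detect_tm_segments(two)), 2L)
})

test_that("localization conflicts require a missing TM between compartments", {
  catalog <- tibble::tibble(
    family = c("carr", "pept", "wif", "kin", "any"),
    consensus = NA_character_, mean_length = 100L,
    localization = c("intracellular", "extracellular", "extracellular",
                     "intracellular", "either"),
    repeatable = FALSE)
  arch <- tibble::tibble(protein_id = "x",
                         family = c("carr", "carr", "carr", "pept"),
                         start = c(0, 110, 220, 340),
                         end = c(100, 210, 330, 440),
                         score = 100, length_fraction = 1)
  no_tm <- tibble::tibble(start = integer(), end = integer())
  flag <- check_localization_conflict(arch, catalog, no_tm)
  expect_s3_class(flag, "dogma_flag")
  expect_equal(flag$rule, "localization_conflict")
  # receptor-like: extracellular, TM, intracellular is valid
  ryk <- tibble::tibble(protein_id = "r", family = c("wif", "kin"),
                        start = c(0, 200), end = c(100, 300),
                        score = 100, length_fraction = 1)
  tm <- tibble::tibble(start = 120L, end = 139L)
  expect_null(check_localization_conflict(ryk, catalog, tm))
  # but the same architecture without the TM is flagged
  expect_s3_class(check_localization_conflict(ryk, catalog, no_tm),
                  "dogma_flag")
  # single-compartment architectures never trigger
  solo <- tibble::tibble(protein_id = "s", family = c("wif", "pept"),
                         start = c(0, 120), end = c(100, 220),
                         score = 100, length_fraction = 1)
  expect_null(check_localization_conflict(solo, catalog, no_tm))
  # "either" never triggers
  anyarch <- tibble::tibble(protein_id = "e", family = c("any", "kin"),
                            start = c(0, 120), end = c(100, 220),
                            score = 100, length_fraction = 1)
  expect_null(check_localization_conflict(anyarch, catalog, no_tm))
  bad <- dplyr::mutate(solo, family = c("nope", "pept"))
  expect_error(check_localization_conflict(bad, catalog, no_tm), "absent")
})

test_that("the truncation rule fires strictly below the threshold", {
  catalog <- tibble::tibble(family = "pept", consensus = NA_character_,
                            mean_length = 470L,
                            localization = "extracellular",
                            repeatable = FALSE)
  hit <- tibble::tibble(protein_id = "x", family = "pept", start = 0L,
                        end = 230L, score = 500,
                        length_fraction = 230 / 470)
  flag <- check_truncation(hit, catalog)
  expect_s3_class(flag, "dogma_flag")
  expect_equal(flag$rule, "domain_truncation")
  expect_null(check_truncation(dplyr::mutate(hit, length_fraction = 1.0),
                               catalog))
  expect_null(check_truncation(dplyr::mutate(hit, length_fraction = 0.6),
                               catalog))
  expect_error(check_truncation(hit, catalog, threshold = 0), "threshold")
})

test_that("EST evidence refutes injected fusion junctions", {
  sim <- fix_sim()
  labels <- sim$labels_b
  fus <- labels[labels$error_kind %in% c("fusion", "chimeric_extension"), ]
  expect_gt(nrow(fus), 0L)
  for (i in seq_len(nrow(fus))) {
    fid <- fus$predicted_protein_id[i]
    fseq <- sim$predicted_b$proteins$seq[
      match(fid, sim$predicted_b$proteins$protein_id)]
    j <- fus$junction_positions[[i]][1]
    gene_ests <- sim$ests_b[sim$ests_b$source_gene_id %in%
                              fus$source_gene_ids[[i]], ]
    v <- test_fusion_junction(fseq, j, gene_ests, protein_id = fid)
    expect_equal(v$verdict, "refuted")
    expect_gt(length(v$refuting_est_ids), 0L)
    expect_equal(length(v$supporting_est_ids), 0L)
  }
})

test_that("a true mid-gene junction with spanning ESTs is supported", {
  sim <- fix_sim()
  truth <- sim$truth_b
  # pick an intact, reasonably long gene and test a junction mid-protein
  intact <- sim$labels_b$predicted_protein_id[
    sim$labels_b$error_kind == "none"]
  lens <- nchar(truth$proteins$seq[match(intact,
                                         truth$proteins$protein_id)])
  gid <- intact[which.max(lens)]
  seq <- truth$proteins$seq[match(gid, truth$proteins$protein_id)]
  j <- nchar(seq) %/% 2L
  # deep, long EST coverage so some read spans the midpoint
  ests <- generate_ests(truth, coverage = 8,
                        length_range = c(3L * nchar(seq) - 60L,
                                         3L * nchar(seq)), seed = 5)
  v <- test_fusion_junction(seq, j, ests[ests$source_gene_id == gid, ])
  expect_equal(v$verdict, "supported")
  none <- test_fusion_junction(seq, j, ests[0, ])
  expect_equal(none$verdict, "no_evidence")
  expect_error(test_fusion_junction(seq, nchar(seq) + 10L, ests),
               "outside")
})

test_that("reference comparison assigns agreement classes", {
  sim <- fix_sim()
  ref <- sim$reference
  # an intact gene agrees on both sides
  gid <- sim$labels_b$predicted_protein_id[
    sim$labels_b$error_kind == "none"][1]
  a_arch <- call_domains(
    sim$predicted_a$proteins$seq[
      match(gid, sim$predicted_a$proteins$protein_id)],
    sim$catalog, protein_id = gid)
  b_arch <- call_domains(
    sim$predicted_b$proteins$seq[
      match(gid, sim$predicted_b$proteins$protein_id)],
    sim$catalog, protein_id = gid)
  a_seq <- sim$predicted_a$proteins$seq[
    match(gid, sim$predicted_a$proteins$protein_id)]
  cls <- classify_against_reference(a_arch, b_arch, a_seq, ref)
  expect_equal(cls$agreement, "both")
  expect_equal(cls$reference_id, gid)
  # a fused B member agrees only on the A side
  fus <- sim$labels_b[sim$labels_b$error_kind == "fusion", ]
  src <- fus$source_gene_ids[[1]][1]
  fa <- call_domains(
    sim$predicted_a$proteins$seq[
      match(src, sim$predicted_a$proteins$protein_id)],
    sim$catalog, protein_id = src)
  fb <- call_domains(
    sim$predicted_b$proteins$seq[
      match(fus$predicted_protein_id[1],
            sim$predicted_b$proteins$protein_id)],
    sim$catalog)
  fs <- sim$predicted_a$proteins$seq[
    match(src, sim$predicted_a$proteins$protein_id)]
  expect_equal(classify_against_reference(fa, fb, fs, ref)$agreement,
               "a_only")
  # nothing alignable: no reference
  expect_equal(classify_against_reference(
    fa, fb, "MPPPPGGGGSSSS", ref,
    alignment_params(min_score = 60))$agreement, "no_reference")
})

test_that("an omitted gene is recovered from the genome with its architecture", {
  sim <- fix_sim()
  omit <- sim$labels_b[sim$labels_b$error_kind == "omission", ]
  expect_gt(nrow(omit), 0L)
  src <- omit$source_gene_ids[[1]][1]
  query <- sim$predicted_a$proteins$seq[
    match(src, sim$predicted_a$proteins$protein_id)]
  rec <- find_missing_gene(query, sim$predicted_b, sim$ests_b, sim$catalog)
  expect_s3_class(rec, "correction_result")
  expect_equal(rec$action, "recover_gene")
  expect_equal(rec$evidence_tier, "translated_genome_search")
  want <- truth_arch(sim$truth_b, src)
  expect_identical(rec$corrected_architecture$family, want)
  # recovered model sits at the species divergence from the query
  id <- percent_identity(local_align(query, rec$corrected_seq))
  expect_equal(id, 1 - 0.188, tolerance = 0.05)
  expect_gt(length(rec$supporting_est_ids), 0L)
})

test_that("recovery fails when the gene's DNA is truly absent", {
  sim <- fix_sim()
  omit <- sim$labels_b[sim$labels_b$error_kind == "omission", ]
  src <- omit$source_gene_ids[[1]][1]
  row <- sim$truth_b$proteins[
    match(src, sim$truth_b$proteins$protein_id), ]
  query <- sim$predicted_a$proteins$seq[
    match(src, sim$predicted_a$proteins$protein_id)]
  # excise the locus from the scaffold
  scaffolds <- sim$predicted_b$scaffolds
  k <- match(row$scaffold_id, scaffolds$scaffold_id)
  scaffolds$seq[k] <- paste0(
    substr(scaffolds$seq[k], 1L, row$cds_start),
    substr(scaffolds$seq[k], row$cds_end + 1L,
           nchar(scaffolds$seq[k])))
  expect_null(find_missing_gene(query, scaffolds, sim$ests_b, sim$catalog))
})

test_that("fix_prediction corrects each injected error class", {
  sim <- fix_sim()
  labels <- sim$labels_b
  pred_b <- sim$predicted_b
  arch_cache <- list()
  arch_for <- function(proteome, id) {
    call_domains(
      proteome$proteins$seq[match(id, proteome$proteins$protein_id)],
      sim$catalog, protein_id = id)
  }
  # chimeric extension: EST tier trims the foreign domain
  ext <- labels[labels$error_kind == "chimeric_extension", ]
  sid <- ext$predicted_protein_id[1]
  src <- ext$source_gene_ids[[1]][1]
  s_arch <- arch_for(pred_b, sid)
  p_arch <- arch_for(sim$predicted_a, src)
  cmp <- compare_architectures(s_arch, p_arch)
  fix <- fix_prediction(sid, src, pred_b, sim$predicted_a, s_arch, p_arch,
                        cmp, sim$ests_b, sim$catalog)
  expect_equal(fix$evidence_tier, "est")
  expect_true(fix$action %in% c("trim_extension", "split"))
  expect_true(compare_architectures(fix$corrected_architecture,
                                    p_arch)$identical)
  # fission: fragments merge back into the partner architecture
  fiss <- labels[labels$error_kind == "fission", ]
  src <- fiss$source_gene_ids[[1]][1]
  frag_ids <- fiss$predicted_protein_id[
    vapply(fiss$source_gene_ids, function(s) src %in% s, logical(1))]
  maps <- map_partial_orthologs(sim$predicted_a, pred_b)
  mrow <- maps[vapply(seq_len(nrow(maps)), function(i)
    all(frag_ids %in% maps$fragment_ids[[i]]), logical(1)), ][1, ]
  s_arch <- arch_for(pred_b, frag_ids[1])
  p_arch <- arch_for(sim$predicted_a, src)
  cmp <- compare_architectures(s_arch, p_arch)
  fix <- fix_prediction(frag_ids[1], src, pred_b, sim$predicted_a, s_arch,
                        p_arch, cmp, sim$ests_b, sim$catalog,
                        mapping = mrow)
  expect_equal(fix$action, "merge")
  expect_equal(fix$evidence_tier, "translated_genome_search")
  expect_true(compare_architectures(fix$corrected_architecture,
                                    p_arch)$identical)
  # cross-scaffold fission falls back to ortholog projection
  xf <- labels[labels$error_kind == "cross_scaffold_fission", ]
  if (nrow(xf)) {
    src <- xf$source_gene_ids[[1]][1]
    frag_ids <- xf$predicted_protein_id[
      vapply(xf$source_gene_ids, function(s) src %in% s, logical(1))]
    mrow <- maps[vapply(seq_len(nrow(maps)), function(i)
      all(frag_ids %in% maps$fragment_ids[[i]]), logical(1)), ][1, ]
    s_arch <- arch_for(pred_b, frag_ids[1])
    p_arch <- arch_for(sim$predicted_a, src)
    cmp <- compare_architectures(s_arch, p_arch)
    fix <- fix_prediction(frag_ids[1], src, pred_b, sim$predicted_a,
                          s_arch, p_arch, cmp, sim$ests_b, sim$catalog,
                          mapping = mrow)
    expect_equal(fix$action, "merge")
    expect_equal(fix$evidence_tier, "ortholog_projection")
    expect_true(compare_architectures(fix$corrected_architecture,
                                      p_arch)$identical)
  }
  # truncation: genomic rebuild restores the full model
  tr <- labels[labels$error_kind == "truncation", ]
  sid <- tr$predicted_protein_id[1]
  src <- tr$source_gene_ids[[1]][1]
  s_arch <- arch_for(pred_b, sid)
  p_arch <- arch_for(sim$predicted_a, src)
  cmp <- compare_architectures(s_arch, p_arch)
  fix <- fix_prediction(sid, src, pred_b, sim$predicted_a, s_arch, p_arch,
                        cmp, sim$ests_b, sim$catalog)
  expect_false(fix$action == "none")
  expect_true(compare_architectures(fix$corrected_architecture,
                                    p_arch)$identical)
  # concordant pairs need no action
  gid <- labels$predicted_protein_id[labels$error_kind == "none"][1]
  g_arch <- arch_for(pred_b, gid)
  a_arch <- arch_for(sim$predicted_a, gid)
  cmp <- compare_architectures(g_arch, a_arch)
  fix <- fix_prediction(gid, gid, pred_b, sim$predicted_a, g_arch, a_arch,
                        cmp, sim$ests_b, sim$catalog)
  expect_equal(fix$action, "none")
})
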