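# Synthetic genome, divergence, error injection and EST generation.

test_that("every ancestral gene translates from its CDS and lies in bounds", {
  anc <- fix_sim_clean()$ancestor
  pr <- anc$proteins
  for (i in seq_len(nrow(pr))) {
    sc <- anc$scaffolds$seq[match(pr$scaffold_id[i],
                                  anc$scaffolds$scaffold_id)]
    expect_lte(pr$cds_end[i], nchar(sc))
    expect_gte(pr$cds_start[i], 0L)
    dna <- substr(sc, pr$cds_start[i] + 1L, pr$cds_end[i])
    if (pr$strand[i] == "-") dna <- orthofixr:::revcomp(dna)
    expect_identical(orthofixr:::translate_dna(dna),
                     paste0(pr$seq[i], "*"))
    expect_identical(dna, pr$cds[i])
  }
  # truth domains lie within their protein
  d <- anc$domains
  plen <- setNames(nchar(pr$seq), pr$protein_id)
  expect_true(all(d$start >= 0L & d$end <= plen[d$protein_id]))
  expect_true(all(d$end > d$start))
})

test_that("genes are separated by at least 200 nt of intergenic spacer", {
  anc <- fix_sim_clean()$ancestor
  by_sc <- split(anc$proteins, anc$proteins$scaffold_id)
  for (sc in by_sc) {
    sc <- sc[order(sc$cds_start), ]
    expect_true(all(sc$cds_start[1] >= 200L))
    if (nrow(sc) > 1L)
      expect_true(all(sc$cds_start[-1] - sc$cds_end[-nrow(sc)] >= 200L))
  }
})

test_that("mixed-compartment proteins get a TM segment, secreted ones a signal", {
  anc <- fix_sim()$ancestor
  catalog <- fix_sim()$catalog
  loc <- setNames(catalog$localization, catalog$family)
  for (gid in anc$proteins$protein_id) {
    fams <- truth_arch(anc, gid)
    has_ex <- any(loc[fams] != "intracellular")
    has_in <- any(loc[fams] == "intracellular")
    tm <- anc$tm[anc$tm$protein_id == gid, ]
    row <- anc$proteins[anc$proteins$protein_id == gid, ]
    if (has_ex && has_in) {
      expect_gte(nrow(tm), 1L)
      # detectable by the windowed hydropathy rule
      det <- detect_tm_segments(row$seq)
      expect_gte(nrow(det), 1L)
    }
    expect_identical(row$has_signal_peptide, has_ex)
    if (has_ex) expect_true(orthofixr:::has_signal_motif(row$seq))
  }
})

test_that("a repeatable family can appear as five tandem copies", {
  catalog <- fix_catalog()
  fam <- catalog$family[1]
  built <- orthofixr:::with_seed(3, orthofixr:::build_protein(
    catalog, rep(fam, 5L)))
  expect_identical(built$domains$family, rep(fam, 5L))
  arch <- call_domains(built$seq, catalog)
  expect_identical(arch$family, rep(fam, 5L))
})

test_that("divergence at probability zero is the identity", {
  anc <- fix_sim_clean()$ancestor
  d0 <- diverge_species(anc, 0, species = "X")
  expect_identical(d0$proteins$seq, anc$proteins$seq)
  expect_identical(d0$scaffolds$seq, anc$scaffolds$seq)
  expect_error(diverge_species(anc, 1.0), "probability")
})

test_that("mean ortholog identity tracks 1 - substitution probability and is monotone", {
  catalog <- build_domain_catalog(10, seed = 21)
  anc <- generate_ancestral_genome(catalog, 40, seed = 22)
  mean_id <- function(p, seed) {
    d <- diverge_species(anc, p, seed = seed, species = "X")
    mean(vapply(seq_len(nrow(anc$proteins)), function(i)
      percent_identity(local_align(anc$proteins$seq[i],
                                   d$proteins$seq[i])), numeric(1)))
  }
  ids <- c(mean_id(0.05, 31), mean_id(0.188, 32), mean_id(0.30, 33))
  expect_equal(ids[1], 0.95, tolerance = 0.012)
  expect_equal(ids[2], 0.812, tolerance = 0.012)
  expect_true(all(diff(ids) < 0))
})

test_that("an all-zero error profile reproduces the truth proteome", {
  truth <- fix_sim_clean()$truth_b
  inj <- inject_annotation_errors(truth, error_profile(), seed = 4)
  expect_identical(inj$predicted$proteins, truth$proteins)
  expect_true(all(inj$labels$error_kind == "none"))
  expect_true(all(lengths(inj$labels$source_gene_ids) == 1L))
  expect_true(all(lengths(inj$labels$junction_positions) == 0L))
})

test_that("injected errors carry coherent truth labels", {
  sim <- fix_sim()
  labels <- sim$labels_b
  truth <- sim$truth_b
  pred <- sim$predicted_b
  # conservation: predictions = genes - omissions - fusions + fission extras
  kinds <- labels$error_kind
  n_fusion <- sum(kinds == "fusion")            # one label per fused model
  n_omit <- sum(kinds == "omission")
  n_fission_frag <- sum(kinds %in% c("fission", "cross_scaffold_fission"))
  n_fission_events <- length(unique(unlist(
    labels$source_gene_ids[kinds %in% c("fission",
                                        "cross_scaffold_fission")])))
  expect_equal(nrow(pred$proteins),
               nrow(truth$proteins) - n_omit - n_fusion +
                 (n_fission_frag - n_fission_events))
  # fusion labels: >= 2 sources, >= 1 junction, architecture concatenates
  for (i in which(kinds == "fusion")) {
    src <- labels$source_gene_ids[[i]]
    expect_gte(length(src), 2L)
    expect_gte(length(labels$junction_positions[[i]]), 1L)
    fused_seq <- pred$proteins$seq[
      match(labels$predicted_protein_id[i], pred$proteins$protein_id)]
    j <- labels$junction_positions[[i]][1]
    expect_identical(substr(fused_seq, 1L, j),
                     truth$proteins$seq[match(src[1],
                                              truth$proteins$protein_id)])
  }
  # fission fragments share a source gene and reassemble the truth protein
  fiss <- labels[kinds %in% c("fission", "cross_scaffold_fission"), ]
  for (src in unique(unlist(fiss$source_gene_ids))) {
    frag_ids <- fiss$predicted_protein_id[
      vapply(fiss$source_gene_ids, function(s) src %in% s, logical(1))]
    frags <- pred$proteins[match(frag_ids, pred$proteins$protein_id), ]
    expect_identical(paste(frags$seq, collapse = ""),
                     truth$proteins$seq[match(src,
                                              truth$proteins$protein_id)])
  }
  # cross-scaffold fragments really claim different scaffolds
  for (src in unique(unlist(
    labels$source_gene_ids[kinds == "cross_scaffold_fission"]))) {
    frag_ids <- labels$predicted_protein_id[
      vapply(labels$source_gene_ids, function(s) src %in% s, logical(1))]
    scs <- pred$proteins$scaffold_id[match(frag_ids,
                                           pred$proteins$protein_id)]
    expect_gt(length(unique(scs)), 1L)
  }
  # truncation leaves less than 60% of the family mean length
  catalog <- sim$catalog
  for (i in which(kinds == "truncation")) {
    src <- labels$source_gene_ids[[i]][1]
    tdom <- truth$domains[truth$domains$protein_id == src, ]
    last <- tdom[which.max(tdom$start), ]
    new_len <- labels$junction_positions[[i]][1]
    kept <- new_len - last$start
    expect_lt(kept / catalog$mean_length[match(last$family,
                                               catalog$family)], 0.6)
  }
  # omissions leave the gene's DNA in the scaffold
  for (i in which(kinds == "omission")) {
    src <- labels$source_gene_ids[[i]][1]
    row <- truth$proteins[match(src, truth$proteins$protein_id), ]
    expect_false(src %in% pred$proteins$protein_id)
    sc <- pred$scaffolds$seq[match(row$scaffold_id,
                                   pred$scaffolds$scaffold_id)]
    piece <- if (row$strand == "+") row$cds else orthofixr:::revcomp(row$cds)
    expect_identical(substr(sc, row$cds_start + 1L, row$cds_end), piece)
  }
})

test_that("ESTs are single-gene mRNA fragments with anchored boundary reads", {
  sim <- fix_sim()
  truth <- sim$truth_b
  ests <- sim$ests_b
  expect_gt(nrow(ests), 0L)
  mrna <- setNames(truth$proteins$cds, truth$proteins$protein_id)
  for (k in seq_len(nrow(ests))) {
    m <- mrna[[ests$source_gene_id[k]]]
    expect_true(grepl(ests$seq[k], m, fixed = TRUE))
  }
  # every gene has a 5'-anchored and a 3'-anchored (stop-containing) read
  by_gene <- split(ests, ests$source_gene_id)
  expect_setequal(names(by_gene), truth$proteins$protein_id)
  for (g in by_gene) {
    expect_gte(nrow(g), 3L)
    expect_true(any(g$includes_start))
    expect_true(any(g$includes_stop))
    stop_read <- g[g$includes_stop, ][1, ]
    m <- mrna[[stop_read$source_gene_id]]
    expect_identical(substr(stop_read$seq,
                            nchar(stop_read$seq) - 2L,
                            nchar(stop_read$seq)),
                     substr(m, nchar(m) - 2L, nchar(m)))
  }
  expect_equal(nrow(generate_ests(truth, 0)), 0L)
})

test_that("5'-anchored reads of secreted genes start with the signal motif", {
  # at the truth level (no divergence) the motif is intact by construction
  sim <- fix_sim_clean()
  truth <- sim$truth_b
  secreted <- truth$proteins$protein_id[truth$proteins$has_signal_peptide]
  ests <- sim$ests_b
  starts <- ests[ests$includes_start & ests$source_gene_id %in% secreted, ]
  expect_gt(nrow(starts), 0L)
  for (k in seq_len(min(10L, nrow(starts)))) {
    aa <- orthofixr:::translate_dna(starts$seq[k])
    expect_true(orthofixr:::has_signal_motif(aa))
  }
})

test_that("no EST spans an injected fusion junction", {
  sim <- fix_sim()
  labels <- sim$labels_b
  pred <- sim$predicted_b
  fus <- labels[labels$error_kind == "fusion", ]
  for (i in seq_len(nrow(fus))) {
    fid <- fus$predicted_protein_id[i]
    fseq <- pred$proteins$seq[match(fid, pred$proteins$protein_id)]
    j <- fus$junction_positions[[i]][1]
    gene_ests <- sim$ests_b[sim$ests_b$source_gene_id %in%
                              fus$source_gene_ids[[i]], ]
    for (k in seq_len(nrow(gene_ests))) {
      hit <- orthofixr:::map_est_to_protein(fseq, gene_ests$seq[k],
                                            alignment_params())
      if (is.null(hit)) next
      spans <- hit$query_start <= j - 30L && hit$query_end >= j + 30L
      expect_false(spans)
    }
  }
})

test_that("the scenario generator is deterministic", {
  s1 <- simulate_proteome_pair(n_genes = 20, n_families = 8, seed = 6)
  s2 <- simulate_proteome_pair(n_genes = 20, n_families = 8, seed = 6)
  expect_identical(s1$predicted_b$proteins, s2$predicted_b$proteins)
  expect_identical(s1$ests_b, s2$ests_b)
  expect_identical(s1$labels_b, s2$labels_b)
})

test_that("scaffold capacity limits raise a generation error", {
  catalog <- fix_catalog()
  expect_error(
    generate_ancestral_genome(catalog, 10, seed = 1,
                              max_scaffold_length = 2000L),
    "capacity")
})
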