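# Synthetic two-species proteome-pair generator.
#
# A ground-truth ancestral proteome is built from a catalog of synthetic
# domain families; two species are derived by residue substitution; annotation
# errors (fusion, fission, cross-scaffold fragmentation, terminal truncation,
# chimeric extension, omission) are injected with truth labels; gene-boundary-
# respecting ESTs supply transcript evidence. Everything is deterministic for
# a fixed seed.

#' Build a synthetic domain-family catalog
#'
#' Families carry a consensus sequence (the stand-in for a profile model), a
#' mean length equal to the consensus length, a subcellular localization class
#' and a repeatable flag (tandem-repeat-prone families). Consensi are drawn
#' from a background amino-acid composition, hydropathy-capped so they cannot
#' mimic the transmembrane motif, and mutually dissimilar.
#'
#' @param n_families Number of families (>= 2).
#' @param length_range Two integers, consensus length range (min >= 20).
#' @param localization_mix Named proportions over
#'   `c("extracellular", "intracellular", "either")`; counts are forced to the
#'   proportions by largest-remainder rounding.
#' @param repeatable_fraction Fraction of families marked repeatable.
#' @param seed Integer seed.
#' @return A tibble with columns `family`, `consensus`, `mean_length`,
#'   `localization`, `repeatable`.
#' @export
build_domain_catalog <- function(n_families,
                                 length_range = c(40L, 200L),
                                 localization_mix = c(extracellular = 0.5,
                                                      intracellular = 0.375,
                                                      either = 0.125),
                                 repeatable_fraction = 0.2,
                                 seed = 1L) {
  if (n_families < 2L) abort("need at least two families")
  if (length_range[1] < 20L) abort("consensus length must be >= 20")
  classes <- c("extracellular", "intracellular", "either")
  mix <- localization_mix[classes]
  mix[is.na(mix)] <- 0
  names(mix) <- classes
  if (any(mix < 0) || sum(mix) <= 0)
    abort("invalid localization mix: proportions must be non-negative")
  mix <- mix / sum(mix)
  base <- floor(n_families * mix)
  rem <- n_families - sum(base)
  if (rem > 0) {
    frac <- n_families * mix - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  loc <- rep(classes, times = base)
  with_seed(seed, {
    lens <- sample_range(length_range[1], length_range[2], n_families)
    cons <- character(n_families)
    for (i in seq_len(n_families)) {
      for (try in seq_len(50L)) {
        cand <- cap_hydropathy(random_aa(lens[i]))
        ok <- TRUE
        for (j in seq_len(i - 1L))
          if (consensus_identity(cand, cons[j]) >= 0.40) { ok <- FALSE; break }
        if (ok) break
      }
      if (!ok) abort("could not generate mutually dissimilar consensi")
      cons[i] <- cand
    }
    rep_flag <- runif(n_families) < repeatable_fraction
    tibble(
      family = sprintf("fam%02d", seq_len(n_families)),
      consensus = cons,
      mean_length = as.integer(lens),
      localization = loc,
      repeatable = rep_flag)
  })
}

#' Pairwise identity of two domain consensi
#'
#' The catalog's dissimilarity measure: matching columns of the optimal local
#' alignment divided by the length of the shorter consensus, i.e. the largest
#' fraction of the shorter family that the other could explain.
#'
#' @param a,b Consensus amino-acid strings.
#' @param params An [alignment_params()].
#' @return A fraction in `[0, 1]`.
#' @export
consensus_identity <- function(a, b, params = alignment_params()) {
  local_align(a, b, params)$matches / min(nchar(a), nchar(b))
}

signal_motif <- function() paste0("M", random_aa(12L, STRONG_HYDROPHOBIC,
                                                 prob = NULL))
tm_motif <- function() random_aa(19L, STRONG_HYDROPHOBIC, prob = NULL)
linker_seq <- function(range = c(5L, 30L)) {
  random_aa(sample_range(range[1], range[2]), LINKER_RESIDUES, prob = NULL)
}

# Sample a domain-architecture (vector of family names) of n_dom slots.
sample_architecture <- function(catalog, n_dom, tandem_range = c(2L, 5L)) {
  fams <- character(0)
  while (length(fams) < n_dom) {
    i <- sample.int(nrow(catalog), 1L)
    k <- 1L
    if (catalog$repeatable[i])
      k <- min(sample_range(tandem_range[1], tandem_range[2]),
               n_dom - length(fams))
    fams <- c(fams, rep(catalog$family[i], k))
  }
  fams
}

# Assemble one protein from an ordered family vector. Extracellular (and
# "either") domains come first, intracellular last; mixed-compartment proteins
# get a transmembrane run between the blocks, and any protein with an
# extracellular block starts with a signal-peptide motif.
build_protein <- function(catalog, fams, linker_range = c(5L, 30L)) {
  loc <- catalog$localization[match(fams, catalog$family)]
  extra <- fams[loc != "intracellular"]
  intra <- fams[loc == "intracellular"]
  mixed <- length(extra) > 0L && length(intra) > 0L
  has_sig <- length(extra) > 0L
  seq <- if (has_sig) signal_motif() else "M"
  dom_rows <- list()
  tm_rows <- list()
  add_block <- function(block) {
    for (f in block) {
      seq <<- paste0(seq, linker_seq(linker_range))
      cons <- catalog$consensus[match(f, catalog$family)]
      s <- nchar(seq)
      seq <<- paste0(seq, cons)
      dom_rows[[length(dom_rows) + 1L]] <<-
        tibble(family = f, start = s, end = s + nchar(cons))
    }
  }
  add_block(extra)
  if (mixed) {
    seq <- paste0(seq, linker_seq(linker_range))
    s <- nchar(seq)
    seq <- paste0(seq, tm_motif())
    tm_rows[[1]] <- tibble(start = s, end = s + 19L)
  }
  add_block(intra)
  seq <- paste0(seq, linker_seq(c(5L, 15L)))
  list(seq = seq, domains = bind_rows(dom_rows),
       tm = if (length(tm_rows)) bind_rows(tm_rows)
       else tibble(start = integer(), end = integer()),
       has_signal_peptide = has_sig)
}

#' Generate a ground-truth ancestral proteome and genome
#'
#' Genes are intronless; domains are separated by 5-30 residue hydrophilic
#' linkers; genes sit on scaffolds with >= 200 nt intergenic spacers. Proteins
#' with extracellular domains carry a signal-peptide motif; proteins mixing
#' compartments carry a transmembrane segment between them.
#'
#' @param catalog Tibble from [build_domain_catalog()].
#' @param n_genes Number of genes (>= 1).
#' @param arch_length_dist Probabilities over 1..6 domains per gene.
#' @param seed Integer seed.
#' @param genes_per_scaffold Genes placed per scaffold.
#' @param minus_strand_prob Probability a gene is encoded on the minus strand.
#' @param spacer_range Intergenic spacer length range (nt, min >= 200).
#' @param max_scaffold_length Generation error if a scaffold would exceed this.
#' @return An [annotated_proteome()] carrying truth domains, TM segments and
#'   coding sequences.
#' @export
generate_ancestral_genome <- function(catalog, n_genes,
                                      arch_length_dist = c(0.15, 0.35, 0.25,
                                                           0.12, 0.08, 0.05),
                                      seed = 1L,
                                      genes_per_scaffold = 25L,
                                      minus_strand_prob = 0.25,
                                      spacer_range = c(200L, 500L),
                                      max_scaffold_length = Inf) {
  if (n_genes < 1L) abort("need at least one gene")
  if (spacer_range[1] < 200L) abort("intergenic spacers must be >= 200 nt")
  with_seed(seed, {
    prot_rows <- vector("list", n_genes)
    dom_rows <- vector("list", n_genes)
    tm_rows <- vector("list", n_genes)
    scaff_of <- ceiling(seq_len(n_genes) / genes_per_scaffold)
    scaff_ids <- sprintf("scaffold_%02d", scaff_of)
    scaff_dna <- list()
    cursor <- 0L
    cur_scaff <- ""
    pieces <- character(0)
    flush_scaffold <- function(id) {
      if (nzchar(cur_scaff))
        scaff_dna[[cur_scaff]] <<- paste(pieces, collapse = "")
      pieces <<- character(0); cursor <<- 0L; cur_scaff <<- id
    }
    for (g in seq_len(n_genes)) {
      if (scaff_ids[g] != cur_scaff) flush_scaffold(scaff_ids[g])
      n_dom <- sample(seq_along(arch_length_dist), 1L,
                      prob = arch_length_dist)
      fams <- sample_architecture(catalog, n_dom)
      built <- build_protein(catalog, fams)
      cds <- encode_cds(built$seq)
      strand <- if (runif(1) < minus_strand_prob) "-" else "+"
      spacer <- random_dna(sample_range(spacer_range[1], spacer_range[2]))
      gstart <- cursor + nchar(spacer)
      gend <- gstart + nchar(cds)
      if (gend > max_scaffold_length)
        abort("generation error: scaffold capacity exceeded")
      pieces <- c(pieces, spacer, if (strand == "+") cds else revcomp(cds))
      cursor <- gend
      gid <- sprintf("g%04d", g)
      prot_rows[[g]] <- tibble(
        protein_id = gid, scaffold_id = scaff_ids[g], strand = strand,
        cds_start = gstart, cds_end = gend, seq = built$seq, cds = cds,
        has_signal_peptide = built$has_signal_peptide)
      if (nrow(built$domains))
        dom_rows[[g]] <- mutate(built$domains, protein_id = gid,
                                .before = 1L)
      if (nrow(built$tm))
        tm_rows[[g]] <- mutate(built$tm, protein_id = gid, .before = 1L)
    }
    # trailing spacer on the last scaffold, then flush
    pieces <- c(pieces, random_dna(sample_range(spacer_range[1], spacer_range[2])))
    flush_scaffold("")
    scaffolds <- tibble(scaffold_id = names(scaff_dna),
                        seq = unlist(scaff_dna, use.names = FALSE))
    annotated_proteome(bind_rows(prot_rows), scaffolds,
                       domains = bind_rows(dom_rows),
                       tm = bind_rows(tm_rows), species = "ancestor")
  })
}

#' Derive a diverged species from an ancestral proteome
#'
#' Each residue is substituted with probability
#' `substitution_probability`, drawing the replacement from a
#' BLOSUM62-conditional off-diagonal distribution, so the expected pairwise
#' identity of orthologs is approximately `1 - substitution_probability`.
#' Coding sequences are re-encoded consistently and spliced back into the
#' scaffolds; domain boundaries and TM segments are carried over.
#'
#' @param ancestor An [annotated_proteome()] with truth domains.
#' @param substitution_probability Per-residue probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param species Label for the derived proteome.
#' @return A new [annotated_proteome()].
#' @export
diverge_species <- function(ancestor, substitution_probability, seed = 1L,
                            species = "derived") {
  p <- substitution_probability
  if (p < 0 || p >= 1) abort("substitution probability must be in [0, 1)")
  if (p == 0) {
    out <- ancestor
    out$species <- species
    return(out)
  }
  kern <- substitution_kernel()
  with_seed(seed, {
    prot <- ancestor$proteins
    scaffs <- setNames(ancestor$scaffolds$seq, ancestor$scaffolds$scaffold_id)
    for (i in seq_len(nrow(prot))) {
      ch <- strsplit(prot$seq[i], "", fixed = TRUE)[[1]]
      orig <- ch
      hit <- which(runif(length(ch)) < p & ch %in% AA20)
      if (length(hit)) {
        for (a in unique(orig[hit])) {
          at <- hit[orig[hit] == a]
          ch[at] <- sample(AA20, length(at), replace = TRUE, prob = kern[a, ])
        }
        prot$seq[i] <- paste(ch, collapse = "")
      }
      new_cds <- encode_cds(prot$seq[i])
      prot$cds[i] <- new_cds
      s <- prot$cds_start[i]; e <- prot$cds_end[i]
      piece <- if (prot$strand[i] == "+") new_cds else revcomp(new_cds)
      sc <- prot$scaffold_id[i]
      substr(scaffs[[sc]], s + 1L, e) <- piece
    }
    annotated_proteome(prot,
                       tibble(scaffold_id = names(scaffs),
                              seq = unname(scaffs)),
                       domains = ancestor$domains, tm = ancestor$tm,
                       species = species)
  })
}

#' Error-injection profile
#'
#' Per-gene rates of each annotation-error kind; the remainder of the
#' probability mass leaves a gene untouched.
#'
#' @param fusion,fission,cross_scaffold_fission,truncation,chimeric_extension,omission
#'   Rates in `[0, 1]`, summing to at most 1.
#' @return A named numeric vector.
#' @export
error_profile <- function(fusion = 0, fission = 0,
                          cross_scaffold_fission = 0, truncation = 0,
                          chimeric_extension = 0, omission = 0) {
  p <- c(fusion = fusion, fission = fission,
         cross_scaffold_fission = cross_scaffold_fission,
         truncation = truncation, chimeric_extension = chimeric_extension,
         omission = omission)
  if (any(p < 0) || any(p > 1) || sum(p) > 1)
    abort("error rates must lie in [0,1] and sum to at most 1")
  p
}

#' Inject annotation errors into a truth proteome
#'
#' Produces a predicted proteome in which some gene models are wrong in a
#' known way, plus a truth label per prediction. Fusion merges two adjacent
#' plus-strand genes (a translated linker joins them); fission cuts a protein
#' at an inter-domain linker into two predictions at consecutive loci;
#' cross-scaffold fission additionally claims the second fragment on a
#' different scaffold; truncation removes a terminal part of the last domain
#' leaving < 60% of the family mean; chimeric extension appends a foreign
#' domain of opposite localization; omission drops the gene while its DNA
#' stays in the scaffold.
#'
#' @param truth An [annotated_proteome()] with truth domains.
#' @param profile An [error_profile()].
#' @param catalog Domain catalog (required when `chimeric_extension > 0`).
#' @param seed Integer seed.
#' @return List with `predicted` (an [annotated_proteome()] without truth
#'   domains) and `labels` (tibble `predicted_protein_id`, `error_kind`,
#'   `source_gene_ids` list-column, `junction_positions` list-column; omitted
#'   genes appear with `predicted_protein_id = NA`).
#' @export
inject_annotation_errors <- function(truth, profile = error_profile(),
                                     catalog = NULL, seed = 1L) {
  profile <- error_profile(fusion = profile[["fusion"]],
                           fission = profile[["fission"]],
                           cross_scaffold_fission =
                             profile[["cross_scaffold_fission"]],
                           truncation = profile[["truncation"]],
                           chimeric_extension =
                             profile[["chimeric_extension"]],
                           omission = profile[["omission"]])
  if (profile[["chimeric_extension"]] > 0 && is.null(catalog))
    abort("chimeric_extension requires a domain catalog")
  prot <- truth$proteins
  doms <- truth$domains
  n <- nrow(prot)
  with_seed(seed, {
    kinds <- sample(c(names(profile), "none"), n, replace = TRUE,
                    prob = c(profile, 1 - sum(profile)))
    consumed <- rep(FALSE, n)  # genes absorbed as fusion partners
    pred <- vector("list", n)
    labels <- vector("list", n)
    gene_doms <- split(doms, doms$protein_id)
    for (i in seq_len(n)) {
      if (consumed[i]) next
      gid <- prot$protein_id[i]
      kind <- kinds[i]
      gd <- gene_doms[[gid]]
      gd <- if (is.null(gd)) tibble(protein_id = character(),
                                    family = character(),
                                    start = integer(), end = integer())
            else arrange(gd, .data$start)
      row <- prot[i, ]
      plen <- nchar(row$seq)

      if (kind == "fusion") {
        # partner = next unconsumed, untouched gene downstream on the same
        # scaffold and strand (+ only, so the merged model reads left to right)
        j <- if (i < n && !consumed[i + 1L] && kinds[i + 1L] == "none" &&
                 prot$scaffold_id[i + 1L] == row$scaffold_id &&
                 row$strand == "+" && prot$strand[i + 1L] == "+") i + 1L else NA
        if (is.na(j)) kind <- "none"
        else {
          consumed[j] <- TRUE
          partner <- prot[j, ]
          link <- random_aa(10L, LINKER_RESIDUES, prob = NULL)
          fseq <- paste0(row$seq, link, partner$seq)
          pid <- paste0(gid, "_", partner$protein_id, "_fus")
          pred[[i]] <- tibble(
            protein_id = pid, scaffold_id = row$scaffold_id, strand = "+",
            cds_start = row$cds_start, cds_end = partner$cds_end,
            seq = fseq, cds = NA_character_, has_signal_peptide =
              row$has_signal_peptide)
          labels[[i]] <- tibble(
            predicted_protein_id = pid, error_kind = "fusion",
            source_gene_ids = list(c(gid, partner$protein_id)),
            junction_positions = list(plen))
          next
        }
      }
      if (kind %in% c("fission", "cross_scaffold_fission") &&
          nrow(gd) < 2L) kind <- "none"
      if (kind %in% c("fission", "cross_scaffold_fission")) {
        k <- if (nrow(gd) == 2L) 1L else sample.int(nrow(gd) - 1L, 1L)
        cut <- (gd$end[k] + gd$start[k + 1L]) %/% 2L
        seq1 <- substr(row$seq, 1L, cut)
        seq2 <- substr(row$seq, cut + 1L, plen)
        id1 <- paste0(gid, "_n"); id2 <- paste0(gid, "_c")
        if (row$strand == "+") {
          c1 <- c(row$cds_start, row$cds_start + 3L * cut)
          c2 <- c(row$cds_start + 3L * cut, row$cds_end)
        } else {
          c1 <- c(row$cds_end - 3L * cut, row$cds_end)
          c2 <- c(row$cds_start, row$cds_end - 3L * cut)
        }
        sc2 <- row$scaffold_id
        c2_out <- c2
        if (kind == "cross_scaffold_fission") {
          others <- setdiff(truth$scaffolds$scaffold_id, row$scaffold_id)
          if (length(others)) {
            sc2 <- others[sample.int(length(others), 1L)]
            c2_out <- c(0L, 3L * nchar(seq2))
          } else kind <- "fission"
        }
        pred[[i]] <- tibble(
          protein_id = c(id1, id2),
          scaffold_id = c(row$scaffold_id, sc2),
          strand = row$strand,
          cds_start = c(c1[1], c2_out[1]), cds_end = c(c1[2], c2_out[2]),
          seq = c(seq1, seq2), cds = NA_character_,
          has_signal_peptide = c(row$has_signal_peptide, FALSE))
        labels[[i]] <- tibble(
          predicted_protein_id = c(id1, id2), error_kind = kind,
          source_gene_ids = list(gid, gid),
          junction_positions = list(cut, cut))
        next
      }
      if (kind == "truncation") {
        last <- if (nrow(gd)) gd[nrow(gd), ] else NULL
        # need a last domain long enough that the kept stub stays visible
        if (is.null(last) || (last$end - last$start) < 40L) kind <- "none"
        else {
          keep <- runif(1, 0.30, 0.55)
          new_len <- last$start + as.integer(round(keep *
                                                     (last$end - last$start)))
          pid <- paste0(gid, "_trunc")
          tseq <- substr(row$seq, 1L, new_len)
          cds_iv <- if (row$strand == "+")
            c(row$cds_start, row$cds_start + 3L * new_len)
          else c(row$cds_end - 3L * new_len, row$cds_end)
          pred[[i]] <- tibble(
            protein_id = pid, scaffold_id = row$scaffold_id,
            strand = row$strand, cds_start = cds_iv[1], cds_end = cds_iv[2],
            seq = tseq, cds = NA_character_,
            has_signal_peptide = row$has_signal_peptide)
          labels[[i]] <- tibble(
            predicted_protein_id = pid, error_kind = "truncation",
            source_gene_ids = list(gid), junction_positions = list(new_len))
          next
        }
      }
      if (kind == "chimeric_extension") {
        has_intra <- any(catalog$localization[match(gd$family,
                                                    catalog$family)] ==
                           "intracellular")
        want <- if (has_intra) "extracellular" else "intracellular"
        cand <- which(catalog$localization == want)
        if (!length(cand)) kind <- "none"
        else {
          f <- catalog[cand[sample.int(length(cand), 1L)], ]
          link <- random_aa(8L, LINKER_RESIDUES, prob = NULL)
          eseq <- paste0(row$seq, link, f$consensus)
          pid <- paste0(gid, "_ext")
          slen <- nchar(scaffold_seq(truth, row$scaffold_id))
          add <- 3L * (nchar(link) + nchar(f$consensus))
          cds_iv <- if (row$strand == "+")
            c(row$cds_start, min(slen, row$cds_end + add))
          else c(max(0L, row$cds_start - add), row$cds_end)
          pred[[i]] <- tibble(
            protein_id = pid, scaffold_id = row$scaffold_id,
            strand = row$strand, cds_start = cds_iv[1], cds_end = cds_iv[2],
            seq = eseq, cds = NA_character_,
            has_signal_peptide = row$has_signal_peptide)
          labels[[i]] <- tibble(
            predicted_protein_id = pid, error_kind = "chimeric_extension",
            source_gene_ids = list(gid), junction_positions = list(plen))
          next
        }
      }
      if (kind == "omission") {
        labels[[i]] <- tibble(
          predicted_protein_id = NA_character_, error_kind = "omission",
          source_gene_ids = list(gid), junction_positions = list(integer(0)))
        next
      }
      # untouched prediction
      pred[[i]] <- mutate(row, seq = row$seq)
      labels[[i]] <- tibble(
        predicted_protein_id = gid, error_kind = "none",
        source_gene_ids = list(gid), junction_positions = list(integer(0)))
    }
    predicted <- annotated_proteome(
      bind_rows(pred), truth$scaffolds, domains = NULL, tm = NULL,
      species = truth$species)
    list(predicted = predicted, labels = bind_rows(labels))
  })
}

#' Generate ESTs from truth genes
#'
#' Single-pass cDNA reads drawn from one gene's mRNA each; an EST never spans
#' two genes. The library is end-biased: with `round(coverage) >= 2` every
#' gene gets one 5'-anchored read (`includes_start`) and one 3'-anchored read
#' containing the stop codon (`includes_stop`); remaining reads start
#' uniformly. `covers` is the fully-covered protein-residue interval.
#'
#' @param truth An [annotated_proteome()] with `cds` sequences.
#' @param coverage Mean ESTs per gene (>= 0).
#' @param length_range EST length range in nt.
#' @param seed Integer seed.
#' @return Tibble `est_id`, `seq`, `source_gene_id`, `cover_start`,
#'   `cover_end`, `includes_start`, `includes_stop`.
#' @export
generate_ests <- function(truth, coverage, length_range = c(300L, 700L),
                          seed = 1L) {
  if (coverage < 0) abort("coverage must be >= 0")
  n_per <- as.integer(round(coverage))
  empty <- tibble(est_id = character(), seq = character(),
                  source_gene_id = character(), cover_start = integer(),
                  cover_end = integer(), includes_start = logical(),
                  includes_stop = logical())
  if (n_per == 0L) return(empty)
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(truth$proteins))) {
      gid <- truth$proteins$protein_id[i]
      mrna <- truth$proteins$cds[i]
      L <- nchar(mrna)
      plen <- nchar(truth$proteins$seq[i])
      starts <- integer(n_per); ends <- integer(n_per)
      for (k in seq_len(n_per)) {
        len <- min(L, sample_range(length_range[1], length_range[2]))
        if (k == 1L) { s <- 0L }
        else if (k == 2L) { s <- L - len }
        else s <- sample.int(L - len + 1L, 1L) - 1L
        starts[k] <- s; ends[k] <- s + len
      }
      rows[[i]] <- tibble(
        est_id = sprintf("%s_est%02d", gid, seq_len(n_per)),
        seq = substring(mrna, starts + 1L, ends),
        source_gene_id = gid,
        cover_start = pmin(as.integer(ceiling(starts / 3)), plen),
        cover_end = pmin(as.integer(floor(ends / 3)), plen),
        includes_start = starts == 0L,
        includes_stop = ends == L)
    }
    bind_rows(rows)
  })
}

#' Simulate a full two-species scenario
#'
#' Builds the catalog and ancestral genome, derives two species (all
#' substitution load on one branch, so pairwise ortholog identity is
#' approximately `1 - divergence`), injects annotation errors per species,
#' and generates ESTs. The error-free ancestor doubles as the trusted
#' reference proteome.
#'
#' @param n_genes Genes in the ancestral genome.
#' @param n_families Families in the domain catalog.
#' @param divergence Per-residue substitution probability between the species.
#' @param profile_a,profile_b [error_profile()]s for each species' predicted
#'   proteome (defaults: species A clean, species B carrying every error
#'   kind).
#' @param est_coverage Mean ESTs per gene for both species.
#' @param seed Integer master seed; sub-seeds are derived from it.
#' @return List of class `proteome_pair_sim` with elements `catalog`,
#'   `ancestor`, `truth_a`, `truth_b`, `predicted_a`, `predicted_b`,
#'   `labels_a`, `labels_b`, `ests_a`, `ests_b`, `reference`.
#' @export
simulate_proteome_pair <- function(n_genes = 160L, n_families = 24L,
                                   divergence = 0.188,
                                   profile_a = error_profile(),
                                   profile_b = error_profile(
                                     fusion = 0.04, fission = 0.04,
                                     cross_scaffold_fission = 0.02,
                                     truncation = 0.04,
                                     chimeric_extension = 0.04,
                                     omission = 0.03),
                                   est_coverage = 5,
                                   seed = 1L) {
  seeds <- seed * 13L + 0:6
  catalog <- build_domain_catalog(n_families, seed = seeds[1])
  ancestor <- generate_ancestral_genome(catalog, n_genes, seed = seeds[2])
  truth_a <- diverge_species(ancestor, 0, species = "A")
  truth_b <- diverge_species(ancestor, divergence, seed = seeds[3],
                             species = "B")
  inj_a <- inject_annotation_errors(truth_a, profile_a, catalog,
                                    seed = seeds[4])
  inj_b <- inject_annotation_errors(truth_b, profile_b, catalog,
                                    seed = seeds[5])
  structure(list(
    catalog = catalog, ancestor = ancestor,
    truth_a = truth_a, truth_b = truth_b,
    predicted_a = inj_a$predicted, predicted_b = inj_b$predicted,
    labels_a = inj_a$labels, labels_b = inj_b$labels,
    ests_a = generate_ests(truth_a, est_coverage, seed = seeds[6]),
    ests_b = generate_ests(truth_b, est_coverage, seed = seeds[7]),
    reference = ancestor), class = "proteome_pair_sim")
}

#' @export
print.proteome_pair_sim <- function(x, ...) {
  cat(sprintf(paste0("<proteome_pair_sim> %d ancestral genes, %d families; ",
                     "A: %d predictions, B: %d predictions\n"),
              nrow(x$ancestor$proteins), nrow(x$catalog),
              nrow(x$predicted_a$proteins), nrow(x$predicted_b$proteins)))
  invisible(x)
}
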