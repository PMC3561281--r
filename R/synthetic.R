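# Species-tree-aware sequence simulation with planted lysine gains.
#
# The simulator evolves protein sequences down the species tree (uniform
# substitution model, Poisson-distributed substitution counts per edge,
# no indels) and then plants a lysine gain: one column is forced to an
# ancestral residue drawn from {Q, E, R} in every species outside a
# chosen human-lineage clade and to K inside it, so that the K-bearing
# species set equals the planted clade exactly, by construction.
# Confounder patterns reproduce the failure modes the screening filters
# exist to catch.  Full ground truth is emitted for every gene.

#' Simulation configuration
#'
#' @param tree A `species_tree` (e.g. [default_species_tree()]).
#' @param n_genes Number of genes to simulate.
#' @param seq_length Protein length in residues (>= 13; default 101).
#' @param substitution_rate Expected substitutions per site per unit
#'   branch length (default 0: perfectly conserved background).  Branch
#'   lengths default to 1 per edge when the newick supplies none.
#' @param planted_branch Ladder clade name(s) receiving the planted gain;
#'   recycled over genes, so passing `names(tree$ladder)` cycles the
#'   ladder.
#' @param confounder Confounder pattern(s), recycled over genes: one of
#'   `"none"`, `"euarchontoglires_K"` (a mouse K at the site column),
#'   `"nearby_conserved_K"` (a fully conserved K at offset -2, the
#'   additional-site pattern), `"ancestral_K_shift"` (a K at offset -1
#'   conserved outside the planted clade and lost inside it, the
#'   shifted-site pattern), `"many_nonprimate_K"` (K in 8 of the
#'   non-Euarchontoglires outgroup species), `"low_conservation"`
#'   (randomized non-reference residues around the site).
#' @param missing_species Species codes whose rows are withheld from the
#'   emitted alignments (missing-data regime).
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree, n_genes = 1L, seq_length = 101L,
                       substitution_rate = 0,
                       planted_branch = "great_apes",
                       confounder = "none",
                       missing_species = character(),
                       seed = 1L) {
  stopifnot(seq_length >= 13L, substitution_rate >= 0, n_genes >= 1L)
  bad <- setdiff(planted_branch, names(tree$ladder))
  if (length(bad) > 0L)
    stop("planted_branch not in the ladder: ", paste(bad, collapse = ", "))
  confounder <- match.arg(confounder,
    c("none", "euarchontoglires_K", "nearby_conserved_K",
      "ancestral_K_shift", "many_nonprimate_K", "low_conservation"),
    several.ok = TRUE)
  bad_sp <- setdiff(missing_species, tree$phy$tip.label)
  if (length(bad_sp) > 0L)
    stop("missing_species not in the tree: ", paste(bad_sp, collapse = ", "))
  if (tree$reference %in% missing_species)
    stop("the reference species cannot be masked")
  structure(list(tree = tree, n_genes = as.integer(n_genes),
                 seq_length = as.integer(seq_length),
                 substitution_rate = substitution_rate,
                 planted_branch = planted_branch,
                 confounder = confounder,
                 missing_species = missing_species,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Evolve tip sequences down the tree: vector of residue vectors per node.
evolve_tips <- function(phy, L, rate) {
  ntip <- length(phy$tip.label)
  ord <- ape::reorder.phylo(phy, "cladewise")
  bl <- ord$edge.length %||% rep(1, nrow(ord$edge))
  seqs <- vector("list", ntip + ord$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample(AA20, L, replace = TRUE)
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    s <- seqs[[parent]]
    nsub <- stats::rpois(1L, rate * bl[e] * L)
    if (nsub > 0L) {
      pos <- sample.int(L, nsub, replace = TRUE)
      for (i in pos) s[i] <- sample(setdiff(AA20, s[i]), 1L)
    }
    seqs[[child]] <- s
  }
  stats::setNames(seqs[seq_len(ntip)], phy$tip.label)
}

#' Simulate one gene with a planted lysine gain
#'
#' @param cfg A [sim_config()]; `planted_branch` and `confounder` entries
#'   are indexed by `gene_index` (recycled).
#' @param gene_index 1-based gene index; also offsets the RNG stream so
#'   every gene is independently reproducible.
#' @return List with `alignment` (an `ortholog_alignment`), `site` (a
#'   one-row `ptm_sites` data frame) and `truth` (a one-row data frame:
#'   `gene_id`, `planted_position`, `planted_column` (0-based),
#'   `planted_branch`, `confounder`, `ancestral_residue`,
#'   `planted_window_class`, `expected_screen_status`,
#'   `expected_reason`).
#' @export
simulate_gene <- function(cfg, gene_index = 1L) {
  tree <- cfg$tree
  branch <- cfg$planted_branch[(gene_index - 1L) %%
                                 length(cfg$planted_branch) + 1L]
  confounder <- cfg$confounder[(gene_index - 1L) %%
                                 length(cfg$confounder) + 1L]
  L <- cfg$seq_length
  ref <- tree$reference
  with_seed(cfg$seed + 9973L * (gene_index %% 100000L), {
    rows <- evolve_tips(tree$phy, L, cfg$substitution_rate)
    # site position with room for the 13-mer and the -5..+5 window
    p <- sample(7:(L - 6L), 1L)
    anc <- sample(c("Q", "E", "R"), 1L)
    members <- tree$ladder[[branch]]
    # scrub chance lysines from the +/-5 window so the planted window
    # class is exact by construction
    window_pos <- setdiff(max(1L, p - 5L):min(L, p + 5L), p)
    rows <- lapply(rows, function(s) {
      s[window_pos][s[window_pos] == "K"] <- "S"
      s
    })
    # plant the gain
    rows <- stats::setNames(lapply(names(rows), function(sp) {
      s <- rows[[sp]]
      s[p] <- if (sp %in% members) "K" else anc
      s
    }), names(rows))

    expected_status <- "retained"
    expected_reason <- NA_character_
    window_class <- "new"
    if (confounder == "euarchontoglires_K") {
      eua <- species_of_clade(tree, "eua")
      carrier <- if ("mm9" %in% eua) "mm9" else eua[1L]
      rows[[carrier]][p] <- "K"
      expected_status <- "discarded"
      expected_reason <- "EUARCHONTOGLIRES_K"
    } else if (confounder == "nearby_conserved_K") {
      rows <- lapply(rows, function(s) { s[p - 2L] <- "K"; s })
      window_class <- "additional"
    } else if (confounder == "ancestral_K_shift") {
      sub <- if (anc == "R") "Q" else "R"
      rows <- stats::setNames(lapply(names(rows), function(sp) {
        s <- rows[[sp]]
        s[p - 1L] <- if (sp %in% members) sub else "K"
        s
      }), names(rows))
      window_class <- "shifted"
    } else if (confounder == "many_nonprimate_K") {
      outer <- setdiff(names(rows),
                       c(species_of_clade(tree, "pri"),
                         species_of_clade(tree, "eua")))
      carriers <- utils::head(sort(outer), 8L)
      for (sp in carriers) rows[[sp]][p] <- "K"
      expected_status <- "discarded"
      expected_reason <- "MANY_NONPRIMATE_K"
    } else if (confounder == "low_conservation") {
      noise_pos <- setdiff(max(1L, p - 10L):min(L, p + 10L), p)
      rows <- stats::setNames(lapply(names(rows), function(sp) {
        s <- rows[[sp]]
        if (sp != ref)
          s[noise_pos] <- sample(AA20, length(noise_pos), replace = TRUE)
        s
      }), names(rows))
      expected_status <- "discarded"
      expected_reason <- "LOW_CONSERVATION"
    }

    rows <- rows[setdiff(names(rows), cfg$missing_species)]
    gene_id <- sprintf("SIMG%04d", gene_index)
    aln <- new_ortholog_alignment(
      gene_id,
      vapply(rows, paste, character(1), collapse = ""),
      ref)
    peptide <- substr(aln$rows[[ref]], p - 6L, p + 6L)
    site <- data.frame(protein_id = gene_id, position = p,
                       peptide = peptide, sources = "simulated",
                       mod_kind = "ubiquitylation",
                       stringsAsFactors = FALSE)
    class(site) <- c("ptm_sites", "data.frame")
    truth <- data.frame(gene_id = gene_id,
                        planted_position = p,
                        planted_column = p - 1L,
                        planted_branch = branch,
                        confounder = confounder,
                        ancestral_residue = anc,
                        planted_window_class = window_class,
                        expected_screen_status = expected_status,
                        expected_reason = expected_reason,
                        stringsAsFactors = FALSE)
    list(alignment = aln, site = site, truth = truth)
  })
}

#' Simulate a full dataset
#'
#' Runs [simulate_gene()] for every gene of the configuration and
#' optionally writes the dataset in exactly the dialects the pipeline
#' consumes: `sites.tsv`, one FASTA per gene under `alignments/`,
#' `tree.nwk`, `clades.yaml` and `truth.tsv`.  Outputs are byte-identical
#' across runs with the same configuration.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `sites` (a `ptm_sites` data frame), `alignments`
#'   (named list of `ortholog_alignment`), `truth` (data frame) and, when
#'   written, `dir`.
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  genes <- lapply(seq_len(cfg$n_genes), function(i) simulate_gene(cfg, i))
  sites <- do.call(rbind, lapply(genes, `[[`, "site"))
  class(sites) <- c("ptm_sites", "data.frame")
  truth <- do.call(rbind, lapply(genes, `[[`, "truth"))
  alignments <- stats::setNames(lapply(genes, `[[`, "alignment"),
                                truth$gene_id)
  out <- list(sites = sites, alignments = alignments, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "alignments"), recursive = TRUE,
               showWarnings = FALSE)
    write_site_table(sites, file.path(out_dir, "sites.tsv"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (g in names(alignments))
      write_alignment_fasta(alignments[[g]],
                            file.path(out_dir, "alignments",
                                      paste0(g, ".fasta")))
    ape::write.tree(cfg$tree$phy, file.path(out_dir, "tree.nwk"))
    write_clade_config(cfg$tree, file.path(out_dir, "clades.yaml"))
    out$dir <- out_dir
  }
  out
}
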