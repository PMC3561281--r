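# Fixture builders used across the suite.  All fixtures are constructed in
# code; the only files touched are per-test tempfiles.

the_tree <- default_species_tree()

# Background filler without lysine, so fixtures control exactly where K
# occurs.
filler <- function(L) {
  base <- "ACDEFGHILMNPQRSTVW"
  substr(strrep(base, ceiling(L / nchar(base))), 1L, L)
}

# Build a gap-free alignment over the tree species (minus exclude_species).
# `edits` is a named list: species code (or "all") -> named character
# vector position -> residue.
fixture_alignment <- function(gene_id, L, edits = list(),
                              exclude_species = character(),
                              tree = the_tree) {
  species <- setdiff(tree$phy$tip.label, exclude_species)
  rows <- stats::setNames(rep(filler(L), length(species)), species)
  apply_edit <- function(sp, pos, res) {
    substr(rows[[sp]], as.integer(pos), as.integer(pos)) <<- res
  }
  if (!is.null(edits$all))
    for (pos in names(edits$all))
      for (sp in species) apply_edit(sp, pos, edits$all[[pos]])
  for (sp in setdiff(names(edits), "all")) {
    if (!sp %in% species) next
    for (pos in names(edits[[sp]])) apply_edit(sp, pos, edits[[sp]][[pos]])
  }
  ubigain:::new_ortholog_alignment(gene_id, rows, tree$reference)
}

# Place a 13-mer peptide centred at `center` into every row, then set the
# centre residue per species group.
place_peptide <- function(edits, peptide, center) {
  stopifnot(nchar(peptide) == 13L)
  chars <- strsplit(peptide, "")[[1L]]
  pos <- as.character(center - 6L + 0:12)
  pepvec <- stats::setNames(chars, pos)
  edits$all <- c(edits$all, pepvec)
  edits
}

set_center <- function(edits, center, residue_by_species) {
  for (sp in names(residue_by_species)) {
    v <- stats::setNames(residue_by_species[[sp]], as.character(center))
    edits[[sp]] <- c(edits[[sp]], v)
  }
  edits
}

great_apes_set <- c("hg19", "panTro2", "gorGor1", "ponAbe2")
apes_set <- c(great_apes_set, "nomLeu1")

# ERCC2-style human-specific gain: K 701, context ESEETLKRIEQIA, all other
# mammals Q or R at the site, perfectly conserved elsewhere.
fixture_ercc2 <- function() {
  tree <- the_tree
  edits <- place_peptide(list(), "ESEETLQRIEQIA", 701L)
  center_res <- stats::setNames(rep("Q", length(tree$phy$tip.label)),
                                tree$phy$tip.label)
  center_res[c("mm9", "rn4", "canFam2", "bosTau4", "monDom5", "ornAna1")] <- "R"
  center_res["hg19"] <- "K"
  edits <- set_center(edits, 701L, as.list(center_res))
  list(aln = fixture_alignment("ERCC2", 707L, edits),
       site = list(protein_id = "ERCC2", position = 701L,
                   peptide = "ESEETLKRIEQIA", sources = "Kim",
                   mod_kind = "ubiquitylation"))
}

# PML Lys-394-style gain: K shared by human..orangutan, gibbon present
# with the ancestral Q.
fixture_pml <- function() {
  edits <- list(all = stats::setNames("Q", "394"))
  edits <- set_center(edits, 394L,
                      stats::setNames(as.list(rep("K", 4L)), great_apes_set))
  aln <- fixture_alignment("PML", 420L, edits)
  list(aln = aln,
       site = list(protein_id = "PML", position = 394L,
                   peptide = substr(ubigain::reference_sequence(aln),
                                    388L, 400L),
                   sources = "Kim", mod_kind = "ubiquitylation"))
}

# BIRC2 Lys-448-style: K in the great apes, gibbon row missing, conserved
# K at the -2 offset in every species including human.
fixture_birc2 <- function() {
  edits <- list(all = stats::setNames(c("E", "K"), c("448", "446")))
  edits <- set_center(edits, 448L,
                      stats::setNames(as.list(rep("K", 4L)), great_apes_set))
  aln <- fixture_alignment("BIRC2", 470L, edits,
                           exclude_species = "nomLeu1")
  list(aln = aln,
       site = list(protein_id = "BIRC2", position = 448L,
                   peptide = substr(ubigain::reference_sequence(aln),
                                    442L, 454L),
                   sources = "Kim", mod_kind = "ubiquitylation"))
}

# LRPPRC Lys-613-style shifted site: novel K gained in the apes; ancestral
# K at -1 conserved in mammals including gibbon but lost in great apes.
fixture_lrpprc <- function() {
  edits <- list(all = stats::setNames(c("R", "K"), c("613", "612")))
  edits <- set_center(edits, 613L,
                      stats::setNames(as.list(rep("K", 5L)), apes_set))
  for (sp in great_apes_set)
    edits[[sp]] <- c(edits[[sp]], stats::setNames("T", "612"))
  aln <- fixture_alignment("LRPPRC", 630L, edits)
  list(aln = aln,
       site = list(protein_id = "LRPPRC", position = 613L,
                   peptide = substr(ubigain::reference_sequence(aln),
                                    607L, 619L),
                   sources = "Kim", mod_kind = "ubiquitylation"))
}

# NUP205 Lys-41-style gain that is also acetylated.
fixture_nup205 <- function() {
  edits <- list(all = stats::setNames("Q", "41"))
  edits <- set_center(edits, 41L,
                      stats::setNames(as.list(rep("K", 8L)),
                                      the_tree$ladder$simians))
  aln <- fixture_alignment("NUP205", 80L, edits)
  list(aln = aln,
       site = list(protein_id = "NUP205", position = 41L,
                   peptide = substr(ubigain::reference_sequence(aln),
                                    35L, 47L),
                   sources = "Wagner", mod_kind = "ubiquitylation"))
}

# One-row data frame -> site list, as run_pipeline does internally.
as_site <- function(df, i = 1L) as.list(df[i, , drop = FALSE])

# Minimal site TSV on disk.
write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Brute-force oracle: smallest ladder clade covering the K-bearing
# primates (direct scan, independent of the MRCA-based implementation).
brute_force_origin <- function(kset, tree = the_tree) {
  pri <- tree$ladder[[length(tree$ladder)]]
  kpri <- intersect(kset, pri)
  for (nm in names(tree$ladder))
    if (all(kpri %in% tree$ladder[[nm]])) return(nm)
  NA_character_
}

# Profile with K exactly for `kset`, residue `other` elsewhere, NA for
# `missing`.
make_profile <- function(kset, other = "Q", missing = character(),
                         tree = the_tree) {
  sp <- tree$phy$tip.label
  res <- stats::setNames(rep(other, length(sp)), sp)
  res[kset] <- "K"
  res[missing] <- NA_character_
  res
}
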