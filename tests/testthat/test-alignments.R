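write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

test_that("well-formed alignment FASTA parses into equal-length rows", {
  path <- write_fasta_lines(c(
    ">hg19 some description", strrep("MKV", 13L),
    ">panTro2", strrep("MKV", 13L),
    ">mm9", strrep("MKV", 13L)))
  aln <- parse_alignment_fasta(path, gene_id = "G1")
  expect_equal(length(aln$rows), 3L)
  expect_equal(alignment_length(aln), 39L)
  expect_equal(aln$reference, "hg19")
})

test_that("ragged, duplicated and empty FASTA inputs are format errors", {
  ragged <- write_fasta_lines(c(">hg19", strrep("A", 39L),
                                ">mm9", strrep("A", 36L)))
  expect_error(parse_alignment_fasta(ragged), "ragged")
  dup <- write_fasta_lines(c(">hg19", "AAAA", ">hg19", "CCCC"))
  expect_error(parse_alignment_fasta(dup), "duplicate species")
  empty <- write_fasta_lines(character())
  expect_error(parse_alignment_fasta(empty), "no sequences")
})

test_that("position <-> column mapping handles gaps and range checks", {
  path <- write_fasta_lines(c(">hg19", "MK-VK", ">mm9", "MKAVR"))
  aln <- parse_alignment_fasta(path)
  expect_equal(column_of_position(aln, 2L), 1L)
  expect_equal(column_of_position(aln, 3L), 3L)
  expect_error(column_of_position(aln, 5L), "out of range")
  expect_error(position_of_column(aln, 2L), "gap")
  # gapless reference: identity shift
  gapless <- parse_alignment_fasta(
    write_fasta_lines(c(">hg19", "MKVKR", ">mm9", "MKVKR")))
  for (p in 1:5) expect_equal(column_of_position(gapless, p), p - 1L)
})

test_that("column mapping inverts position mapping on random gapped rows", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(10:60, 1L)
    chars <- sample(c(AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "-"),
                    n, replace = TRUE, prob = c(rep(1, 20), 6))
    if (all(chars == "-")) chars[1L] <- "M"
    row <- paste(chars, collapse = "")
    aln <- ubigain:::new_ortholog_alignment(
      "G", c(hg19 = row, mm9 = row), "hg19")
    L <- nchar(gsub("-", "", row))
    for (p in seq_len(L))
      expect_equal(position_of_column(aln, column_of_position(aln, p)), p)
  }
})

test_that("gap, X, stop and absent species are MISSING in profiles", {
  path <- write_fasta_lines(c(">hg19", "KQRA", ">mm9", "-Xk*"))
  aln <- parse_alignment_fasta(path)
  tree <- the_tree
  prof0 <- residue_profile(aln, 0L, tree)
  expect_true(is.na(prof0[["mm9"]]))          # gap
  expect_true(is.na(residue_profile(aln, 1L)[["mm9"]]))  # X
  expect_equal(residue_profile(aln, 2L)[["mm9"]], "K")   # lowercase ok
  expect_true(is.na(residue_profile(aln, 3L)[["mm9"]]))  # stop codon
  # species absent from the file but present in the tree are MISSING
  expect_true(is.na(prof0[["rn4"]]))
  expect_equal(prof0[["hg19"]], "K")
  # a profile never reports a residue where the row has a gap (string oracle)
  for (cl in 0:3) {
    prof <- residue_profile(aln, cl)
    for (sp in names(aln$rows)) {
      ch <- toupper(substr(aln$rows[[sp]], cl + 1L, cl + 1L))
      if (ch %in% c("-", "X", "*")) expect_true(is.na(prof[[sp]]))
    }
  }
})

test_that("replace_sequence enforces length, audits, and can add species", {
  path <- write_fasta_lines(c(">hg19", "KQRA", ">mm9", "KQRA"))
  aln <- parse_alignment_fasta(path)
  aln2 <- replace_sequence(aln, "mm9", "KQKA")
  expect_equal(aln2$rows[["mm9"]], "KQKA")
  expect_equal(aln2$audit[[1L]]$old_row, "KQRA")
  expect_error(replace_sequence(aln, "mm9", "KQ"), "length")
  # gibbon-style augmentation: add a previously absent species
  aln3 <- replace_sequence(aln, "nomLeu1", "KQRA")
  expect_equal(length(aln3$rows), 3L)
  expect_true(is.na(aln3$audit[[1L]]$old_row))
})

test_that("the packaged species tree loads with the full clade ladder", {
  tree <- the_tree
  expect_equal(length(tree$phy$tip.label), 37L)
  expect_equal(length(tree$ladder), 9L)
  expect_equal(names(tree$ladder)[c(1L, 9L)], c("human", "primates"))
  expect_equal(length(species_of_clade(tree, "eua")), 8L)
  expect_setequal(tree$ladder$primates, species_of_clade(tree, "pri"))
})

test_that("ladder monophyly agrees with the brute-force bipartition oracle", {
  tree <- the_tree
  # oracle: the clade sets of the rooted topology, from its bipartitions
  parts <- ape::prop.part(tree$phy)
  clade_sets <- lapply(parts, function(idx)
    sort(attr(parts, "labels")[idx]))
  for (nm in names(tree$ladder)) {
    members <- sort(tree$ladder[[nm]])
    found <- length(members) == 1L ||
      any(vapply(clade_sets, function(s) identical(s, members), logical(1)))
    expect_true(found, info = paste("ladder clade", nm))
  }
})

test_that("invalid clade configurations fail at load with a named clade", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("(((hg19,panTro2),mm9),canFam2);", nwk)
  good <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    reference = "hg19",
    major_clades = list(pri = list("hg19", "panTro2"), eua = list("mm9"),
                        lau = list("canFam2")),
    ladder = list(list(name = "human", members = list("hg19")),
                  list(name = "primates",
                       members = list("hg19", "panTro2")))), good)
  tree <- load_species_tree(nwk, good)
  expect_equal(length(tree$ladder), 2L)

  not_mono <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    reference = "hg19",
    major_clades = list(pri = list("hg19", "mm9")),
    ladder = list(list(name = "human", members = list("hg19")),
                  list(name = "primates", members = list("hg19", "mm9")))),
    not_mono)
  expect_error(load_species_tree(nwk, not_mono), "not monophyletic")

  bad_species <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    reference = "hg19",
    major_clades = list(pri = list("hg19", "panTro2")),
    ladder = list(list(name = "human", members = list("hg19")),
                  list(name = "primates",
                       members = list("hg19", "panTro2", "gorGor1")))),
    bad_species)
  expect_error(load_species_tree(nwk, bad_species), "absent from the tree")
})
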