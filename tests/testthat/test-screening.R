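test_that("map_site finds the modified lysine and validates its context", {
  fx <- fixture_ercc2()
  m <- map_site(fx$site, fx$aln)
  expect_true(m$ok)
  expect_equal(m$column, 700L)   # gap-free fixture: 0-based = position - 1
  expect_false(m$remapped)
})

test_that("map_site rejects sites whose peptide cannot be located", {
  fx <- fixture_ercc2()
  # position holds a non-K residue and the peptide occurs nowhere
  bad <- list(protein_id = "ERCC2", position = 100L,
              peptide = "WWWWWWKWWWWWW")
  m <- map_site(bad, fx$aln)
  expect_false(m$ok)
  expect_equal(m$reason, "PEPTIDE_MISMATCH")
  # K at the reported position but flanking context disagrees
  wrong_ctx <- list(protein_id = "ERCC2", position = 701L,
                    peptide = "WWWWWWKWWWWWW")
  expect_false(map_site(wrong_ctx, fx$aln)$ok)
  expect_true(map_site(wrong_ctx, fx$aln, allow_mismatch = TRUE)$ok)
})

test_that("map_site remaps via a unique peptide hit when positions drifted", {
  # alignment whose human protein has the peptide centred at 701, but the
  # site table reports 698 (a 3-residue indel upstream in the source
  # database coordinate system); position 698 holds a non-K filler residue
  fx <- fixture_ercc2()
  site <- list(protein_id = "ERCC2", position = 698L,
               peptide = "ESEETLKRIEQIA")
  m <- map_site(site, fx$aln)
  expect_true(m$ok)
  expect_true(m$remapped)
  expect_equal(m$position, 701L)
  expect_equal(m$column, 700L)
  # X wildcards in the peptide still match
  mx <- map_site(list(protein_id = "ERCC2", position = 701L,
                      peptide = "ESXETLKRIEQXA"), fx$aln)
  expect_true(mx$ok)
})

test_that("a lysine in non-primate Euarchontoglires vetoes the site", {
  tree <- the_tree
  fail <- make_profile(c("hg19", "mm9"))
  expect_false(filter_euarchontoglires(fail, tree)$pass)
  pass <- make_profile("hg19", missing = "tupBel1")
  expect_true(filter_euarchontoglires(pass, tree)$pass)
  # all eight non-primate Euarchontoglires missing: pass, low information
  res <- filter_euarchontoglires(
    make_profile("hg19", missing = species_of_clade(tree, "eua")), tree)
  expect_true(res$pass)
  expect_true(res$low_information)
})

test_that("widespread non-primate lysines veto the site by fraction", {
  tree <- the_tree
  nonpri <- setdiff(tree$phy$tip.label, species_of_clade(tree, "pri"))
  # 10 of 26 non-primate species with K: 0.385 > 0.2 fails
  res <- filter_nonprimate_lysines(
    make_profile(c("hg19", nonpri[1:10])), tree)
  expect_false(res$pass)
  expect_equal(res$fraction, 10 / 26)
  # no non-primate K passes
  expect_true(filter_nonprimate_lysines(make_profile("hg19"), tree)$pass)
  # 1 of 20 (six species missing) = 0.05 passes
  res2 <- filter_nonprimate_lysines(
    make_profile(c("hg19", nonpri[1L]), missing = nonpri[2:7]), tree)
  expect_true(res2$pass)
  expect_equal(res2$fraction, 1 / 20)
  # MISSING everywhere: pass with low-information flag
  res3 <- filter_nonprimate_lysines(
    make_profile("hg19", missing = nonpri), tree)
  expect_true(res3$pass)
  expect_true(res3$low_information)
})

test_that("regional conservation is averaged over the flanking window", {
  tree <- the_tree
  # perfectly conserved fixture passes with identity 1
  fx <- fixture_ercc2()
  res <- filter_conservation(fx$aln, 700L, tree)
  expect_true(res$pass)
  expect_equal(res$identity, 1)
  # half the species mismatching at every window column: identity 0.5 < 0.6
  L <- 41L
  base <- filler(L)
  scrambled <- chartr("ACDEFGHILMNPQRSTVW", "CDEFGHILMNPQRSTVWA", base)
  rows <- c(hg19 = base, panTro2 = base, gorGor1 = base,
            mm9 = scrambled, canFam2 = scrambled)
  substr(rows[["hg19"]], 21L, 21L) <- "K"
  aln <- ubigain:::new_ortholog_alignment("G", rows, "hg19")
  res2 <- filter_conservation(aln, 20L, tree)
  expect_false(res2$pass)
  expect_equal(res2$identity, 0.5)
  # reference + one species matching 70% of window columns passes at 0.6
  partner <- base
  for (p in 11:16) substr(partner, p, p) <- "Y"  # 6 of 20 window columns
  rows3 <- c(hg19 = base, mm9 = partner)
  substr(rows3[["hg19"]], 21L, 21L) <- "K"
  aln3 <- ubigain:::new_ortholog_alignment("G", rows3, "hg19")
  res3 <- filter_conservation(aln3, 20L, tree)
  expect_true(res3$pass)
  expect_equal(res3$identity, 0.7)
})

test_that("the paralogy filter keys on exact human-sequence identity", {
  fx1 <- fixture_ercc2()
  fx2 <- fx1$aln; fx2$gene_id <- "ERCC2_COPY"
  other <- fixture_pml()$aln
  index <- build_reference_index(
    list(ERCC2 = fx1$aln, ERCC2_COPY = fx2, PML = other))
  expect_false(filter_multicopy("ERCC2", index)$pass)
  expect_false(filter_multicopy("ERCC2_COPY", index)$pass)
  expect_true(filter_multicopy("PML", index)$pass)
  # one residue of difference is enough to pass
  variant <- fx1$aln; variant$gene_id <- "ERCC2_VAR"
  variant$rows[["hg19"]] <- sub("^A", "C", variant$rows[["hg19"]])
  index2 <- build_reference_index(list(ERCC2 = fx1$aln, ERCC2_VAR = variant))
  expect_true(filter_multicopy("ERCC2", index2)$pass)
  expect_true(filter_multicopy("ERCC2_VAR", index2)$pass)
})

test_that("screen_site collects every failing reason, in fixed order", {
  tree <- the_tree
  fx <- fixture_ercc2()
  call <- screen_site(fx$site, fx$aln, tree)
  expect_equal(call$status, "retained")
  expect_equal(call$reasons, character())
  # plant a mouse K *and* destroy conservation: both reasons reported
  aln2 <- fx$aln
  substr(aln2$rows[["mm9"]], 701L, 701L) <- "K"
  for (sp in setdiff(names(aln2$rows), "hg19")) {
    row <- aln2$rows[[sp]]
    for (p in 691:711) if (p != 701L) substr(row, p, p) <- "W"
    aln2$rows[[sp]] <- row
  }
  call2 <- screen_site(fx$site, aln2, tree)
  expect_equal(call2$status, "discarded")
  expect_equal(call2$reasons, c("EUARCHONTOGLIRES_K", "LOW_CONSERVATION"))
  # a missing alignment is its own reason
  call3 <- screen_site(fx$site, NULL, tree)
  expect_equal(call3$reasons, "NO_ALIGNMENT")
})

test_that("the screening verdict equals the conjunction of its filters", {
  # order-independence: reasons are exactly the set of individually
  # failing predicates, for every confounder pattern
  tree <- the_tree
  cfg <- screen_config()
  sim <- sim_config(tree, n_genes = 10,
                    planted_branch = c("human", "catarrhines"),
                    confounder = c("none", "euarchontoglires_K",
                                   "many_nonprimate_K", "low_conservation",
                                   "nearby_conserved_K"),
                    seed = 99)
  d <- simulate_dataset(sim)
  for (i in seq_len(nrow(d$sites))) {
    aln <- d$alignments[[d$sites$protein_id[i]]]
    call <- screen_site(as_site(d$sites, i), aln, tree, cfg)
    prof <- residue_profile(aln, call$column, tree)
    expected <- character()
    if (!filter_euarchontoglires(prof, tree)$pass)
      expected <- c(expected, "EUARCHONTOGLIRES_K")
    if (!filter_nonprimate_lysines(prof, tree, cfg)$pass)
      expected <- c(expected, "MANY_NONPRIMATE_K")
    if (!filter_conservation(aln, call$column, tree, cfg)$pass)
      expected <- c(expected, "LOW_CONSERVATION")
    expect_setequal(call$reasons, expected)
    expect_equal(call$status == "retained", length(expected) == 0L)
  }
})

test_that("tightening thresholds only shrinks the retained set", {
  tree <- the_tree
  sim <- sim_config(tree, n_genes = 24, planted_branch = names(tree$ladder),
                    substitution_rate = 0.04, seed = 17)
  d <- simulate_dataset(sim)
  loose <- screen_config(conservation_min_identity = 0.5,
                         nonprimate_lysine_max_fraction = 0.3)
  strict <- screen_config(conservation_min_identity = 0.8,
                          nonprimate_lysine_max_fraction = 0.05)
  kept <- function(cfg) {
    keep <- vapply(seq_len(nrow(d$sites)), function(i)
      screen_site(as_site(d$sites, i),
                  d$alignments[[d$sites$protein_id[i]]],
                  tree, cfg)$status == "retained", logical(1))
    d$sites$protein_id[keep]
  }
  expect_true(all(kept(strict) %in% kept(loose)))
})
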