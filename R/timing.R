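# Dating lysine gains on the human-lineage clade ladder.
#
# A retained gain is dated to the smallest ladder clade whose member set
# covers every primate observed to carry the derived lysine: under missing
# data this is the most recent branch consistent with a single gain.
# Non-primate lysines that survived screening are treated as independent
# (homoplastic) events and logged, never merged into the dating.

#' Species carrying a lysine at a column
#' @param profile Residue profile from [residue_profile()].
#' @return Character vector of species codes whose residue is `K`
#'   (MISSING excluded).
#' @export
lysine_bearing_species <- function(profile) {
  names(profile)[!is.na(profile) & profile == "K"]
}

#' Date a gain to the smallest covering ladder clade
#'
#' Returns the first (smallest) ladder clade whose member set is a
#' superset of the lysine-bearing primates.  The implementation goes
#' through the tree: the MRCA of the K-bearing primates is found on the
#' topology and its descendant tip set is covered by the ladder; because
#' ladder clades are monophyletic and nested, this equals the brute-force
#' minimal-superset scan.  When species separating the chosen clade from
#' larger ones are all MISSING, the dating is ambiguous: every consistent
#' clade is reported in `ambiguous_clades` (the smallest is the call).
#'
#' @param profile Residue profile of the site column (over all tree
#'   species).
#' @param tree A `species_tree`.
#' @return List with `clade` (ladder clade name), `ambiguous_clades`
#'   (all ladder clades consistent with the data, smallest first) and
#'   `homoplasy_species` (non-primate K-bearers, logged).
#' @export
infer_origin_clade <- function(profile, tree) {
  ks <- lysine_bearing_species(profile)
  pri <- tree$ladder[[length(tree$ladder)]]
  kpri <- intersect(ks, pri)
  if (length(kpri) == 0L)
    stop("no lysine-bearing primate at the site column; ",
         "infer_origin_clade requires a retained gain")
  target <- if (length(kpri) >= 2L)
    clade_tips(tree$phy, ape::getMRCA(tree$phy, kpri))
  else kpri
  idx <- which(vapply(tree$ladder, function(members)
    all(target %in% members), logical(1)))[1L]
  if (is.na(idx))
    stop("lysine-bearing primates not covered by any ladder clade")
  chosen <- names(tree$ladder)[idx]

  # walk up the ladder while every species added by the next clade is
  # MISSING: those clades cannot be distinguished from the chosen one
  ambiguous <- chosen
  i <- idx
  while (i < length(tree$ladder)) {
    added <- setdiff(tree$ladder[[i + 1L]], tree$ladder[[i]])
    vals <- profile[intersect(added, names(profile))]
    if (length(vals) > 0L && all(is.na(vals))) {
      ambiguous <- c(ambiguous, names(tree$ladder)[i + 1L])
      i <- i + 1L
    } else break
  }
  list(clade = chosen,
       ambiguous_clades = ambiguous,
       homoplasy_species = setdiff(ks, pri))
}

#' Tabulate gains per ladder branch
#'
#' @param calls List of retained `site_call`s with `origin_clade` set.
#' @param tree A `species_tree`.
#' @return A `gain_summary`: list with `counts_by_clade` (named integer
#'   vector in ladder order, smallest clade first), `total_sites` and
#'   `total_proteins` (distinct gene ids).
#' @export
tabulate_gains <- function(calls, tree) {
  clades <- vapply(calls, function(x) {
    if (is.na(x$origin_clade))
      stop("tabulate_gains: call for ", x$protein_id, " pos ", x$position,
           " has no origin_clade")
    x$origin_clade
  }, character(1))
  counts <- stats::setNames(integer(length(tree$ladder)), names(tree$ladder))
  tab <- table(clades)
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts_by_clade = counts,
                 total_sites = length(calls),
                 total_proteins = length(unique(vapply(
                   calls, function(x) x$gene_id, character(1))))),
            class = "gain_summary")
}

#' @export
print.gain_summary <- function(x, ...) {
  cat("gains per human-lineage branch (", x$total_sites, " sites in ",
      x$total_proteins, " proteins):\n", sep = "")
  for (nm in names(x$counts_by_clade))
    cat(sprintf("  %-20s %d\n", nm, x$counts_by_clade[[nm]]))
  invisible(x)
}
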