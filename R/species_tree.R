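# Species tree, major-clade tags and the human-lineage clade ladder.
#
# The dating step relies on an ordered "ladder" of strictly nested clades
# on the human lineage (human < human+chimp < African great apes <
# great apes < apes < catarrhines < simians < haplorhines < primates).
# Each ladder clade corresponds to one branch of the species tree on
# which a lysine gain can be dated.

#' Load a species tree with its clade configuration
#'
#' Reads a rooted newick topology and a YAML clade configuration naming
#' the major mammalian groups (pri/eua/lau/afr/xen/met/pro) and the
#' ordered nested clade ladder on the human lineage.  All structural
#' invariants are verified at load time: ladder clades must be strictly
#' nested, contain the reference species, be monophyletic in the topology,
#' and the top ladder clade must equal the species tagged `pri`.
#'
#' @param newick_path Path to a rooted newick tree over species codes.
#' @param clades_path Path to a YAML file with keys `reference`,
#'   `major_clades` (tag -> species vector) and `ladder` (ordered list of
#'   `name`/`members` entries, smallest clade first); optionally
#'   `species_names` (code -> common name).
#' @return A `species_tree`: list with `phy` (an [ape::read.tree()]
#'   phylo), `major_clade` (named character vector species -> tag),
#'   `ladder` (named list of member vectors, smallest first), `reference`,
#'   and `species_names`.
#' @export
load_species_tree <- function(newick_path, clades_path) {
  phy <- ape::read.tree(newick_path)
  if (is.null(phy)) stop("could not read newick tree from ", newick_path)
  cfg <- yaml::read_yaml(clades_path)
  reference <- cfg$reference %||% "hg19"
  if (is.null(cfg$major_clades) || is.null(cfg$ladder))
    stop("clade config ", clades_path,
         " must define 'major_clades' and 'ladder'")
  mc_list <- lapply(cfg$major_clades, unlist)
  major_clade <- stats::setNames(
    rep(names(mc_list), lengths(mc_list)), unlist(mc_list))
  ladder <- stats::setNames(
    lapply(cfg$ladder, function(cl) unlist(cl$members)),
    vapply(cfg$ladder, function(cl) cl$name, character(1)))

  tips <- phy$tip.label
  unknown <- setdiff(names(major_clade), tips)
  if (length(unknown) > 0L)
    stop("clade config lists species absent from the tree: ",
         paste(unknown, collapse = ", "))
  for (i in seq_along(ladder)) {
    nm <- names(ladder)[i]
    members <- ladder[[i]]
    if (!all(members %in% tips))
      stop("ladder clade '", nm, "' lists species absent from the tree: ",
           paste(setdiff(members, tips), collapse = ", "))
    if (!reference %in% members)
      stop("ladder clade '", nm, "' does not contain the reference species")
    if (i > 1L) {
      prev <- ladder[[i - 1L]]
      if (!all(prev %in% members) || length(members) <= length(prev))
        stop("ladder clades must be strictly nested; '", nm,
             "' does not strictly contain '", names(ladder)[i - 1L], "'")
    }
    if (!is_monophyletic_set(phy, members))
      stop("ladder clade '", nm, "' is not monophyletic in the tree")
  }
  pri <- names(major_clade)[major_clade == "pri"]
  top <- ladder[[length(ladder)]]
  if (!setequal(pri, top))
    stop("top ladder clade '", names(ladder)[length(ladder)],
         "' must equal the species tagged 'pri'")

  structure(list(phy = phy,
                 major_clade = major_clade,
                 ladder = ladder,
                 reference = reference,
                 species_names = unlist(cfg$species_names %||% list())),
            class = "species_tree")
}

# TRUE iff `members` form exactly one clade of the rooted topology.
is_monophyletic_set <- function(phy, members) {
  if (length(members) <= 1L) return(TRUE)
  node <- ape::getMRCA(phy, members)
  setequal(clade_tips(phy, node), members)
}

# Tip labels descending from an internal node.
clade_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  ape::extract.clade(phy, node)$tip.label
}

#' The packaged 37-mammal species tree
#'
#' Loads the 37-taxon mammalian tree (human plus 10 other primates, 8
#' other Euarchontoglires, 10 Laurasiatheria, 3 Afrotheria, 2 Xenarthra,
#' 2 Metatheria, platypus) and its 9-clade human-lineage ladder shipped
#' with the package.
#'
#' @return A `species_tree`.
#' @export
default_species_tree <- function() {
  load_species_tree(
    system.file("extdata", "mammals37.nwk", package = "ubigain",
                mustWork = TRUE),
    system.file("extdata", "mammals37_clades.yaml", package = "ubigain",
                mustWork = TRUE))
}

#' Species belonging to a major clade tag
#' @param tree A `species_tree`.
#' @param tag One of `"pri"`, `"eua"`, `"lau"`, `"afr"`, `"xen"`, `"met"`,
#'   `"pro"`.
#' @return Character vector of species codes.
#' @export
species_of_clade <- function(tree, tag) {
  names(tree$major_clade)[tree$major_clade == tag]
}

#' Write a species tree's clade configuration back to YAML
#' @param tree A `species_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clade_config <- function(tree, path) {
  mc <- split(names(tree$major_clade), tree$major_clade)
  cfg <- list(reference = tree$reference,
              major_clades = lapply(mc, as.list),
              ladder = lapply(names(tree$ladder), function(nm)
                list(name = nm, members = as.list(tree$ladder[[nm]]))),
              species_names = as.list(tree$species_names))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species tree: ", length(x$phy$tip.label), " taxa, ladder of ",
      length(x$ladder), " clades (", paste(names(x$ladder), collapse = " < "),
      "), reference ", x$reference, "\n", sep = "")
  invisible(x)
}
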