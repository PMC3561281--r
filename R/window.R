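# Window classification of retained gains and acetylation cross-reference.
#
# A gained lysine may be (i) a genuinely new modification target, (ii) an
# additional target next to a conserved lysine that is itself modifiable,
# or (iii) a shifted target that replaced a nearby ancestral lysine lost
# on the same lineage.  The three classes are distinguished by scanning
# the +/-5 reference residues around the novel lysine for conserved
# alternative lysines.

#' Window report for one retained gain
#'
#' Scans the reference residues at offsets -radius..+radius (0 excluded)
#' around the gained lysine.  Offsets are counted in reference (human)
#' residues, so alignment gap columns are skipped.  For each offset the
#' fraction of non-MISSING non-primate species carrying `K` at the aligned
#' column is computed; an offset is *conserved* iff that fraction is at
#' least `conserved_min_fraction`.  Classification:
#' * `new` — no conserved offset;
#' * `additional` — a conserved offset whose lysine is also present in the
#'   reference (human) row: the old target coexists with the new one;
#' * `shifted` — conserved offset(s) exist but none retains a lysine in
#'   the reference row: the ancestral target was lost as the novel one
#'   appeared.  Whether the ancestral lysine is absent from *every*
#'   non-MISSING member of the origin clade is recorded per offset as
#'   `lost_in_origin_clade`.
#'
#' @param aln The gene's `ortholog_alignment`.
#' @param column 0-based site column of the gained lysine.
#' @param origin_clade Ladder clade name the gain was dated to.
#' @param tree A `species_tree`.
#' @param conserved_min_fraction Conserved-offset threshold (default
#'   0.75).
#' @param radius Window radius in reference residues (default 5).
#' @return A `window_report`: list with `position` (1-based site
#'   position), `offsets` (data frame: `offset`, `column`, `ref_residue`,
#'   `nonprimate_k_fraction`, `conserved`, `ref_has_K`,
#'   `lost_in_origin_clade`), `offsets_with_reference_K`,
#'   `classification`, `clipped` (window truncated at a terminus) and the
#'   parameters used.
#' @export
window_report <- function(aln, column, origin_clade, tree,
                          conserved_min_fraction = 0.75, radius = 5L) {
  p <- position_of_column(aln, column)
  L <- nchar(reference_sequence(aln))
  offsets <- setdiff(seq.int(-radius, radius), 0L)
  usable <- offsets[p + offsets >= 1L & p + offsets <= L]
  clipped <- length(usable) < length(offsets)
  pri <- species_of_clade(tree, "pri")
  clade_members <- tree$ladder[[origin_clade]]

  rows <- lapply(usable, function(o) {
    cl <- column_of_position(aln, p + o)
    prof <- residue_profile(aln, cl, tree)
    ref_res <- prof[[aln$reference]]
    np <- prof[setdiff(names(prof), pri)]
    obs <- np[!is.na(np)]
    frac <- if (length(obs) > 0L) mean(obs == "K") else NA_real_
    cm <- prof[intersect(clade_members, names(prof))]
    lost <- all(is.na(cm) | cm != "K") && any(!is.na(cm))
    data.frame(offset = o, column = cl, ref_residue = ref_res,
               nonprimate_k_fraction = frac,
               conserved = !is.na(frac) && frac >= conserved_min_fraction,
               ref_has_K = identical(ref_res, "K"),
               lost_in_origin_clade = lost,
               stringsAsFactors = FALSE)
  })
  off <- do.call(rbind, rows)
  classification <-
    if (is.null(off) || !any(off$conserved)) "new"
    else if (any(off$conserved & off$ref_has_K)) "additional"
    else "shifted"
  structure(list(position = p,
                 offsets = off,
                 offsets_with_reference_K =
                   if (is.null(off)) integer() else off$offset[off$ref_has_K],
                 classification = classification,
                 clipped = clipped,
                 origin_clade = origin_clade,
                 conserved_min_fraction = conserved_min_fraction,
                 radius = as.integer(radius)),
            class = "window_report")
}

#' Cross-reference gains with acetylation sites
#'
#' Marks each ubiquitylation site call whose exact `(protein_id,
#' position)` also appears in a deduplicated acetylation site table:
#' such lysines are targets of both modifications, suggesting regulatory
#' cross-talk.
#'
#' @param ubi_calls List of `site_call`s.
#' @param acet_sites A `ptm_sites` data frame of acetylation sites
#'   (deduplicated via [deduplicate()]); may be empty or `NULL`.
#' @return The call list with `acetylated_too` set.
#' @export
acetylation_overlap <- function(ubi_calls, acet_sites) {
  if (is.null(acet_sites) || nrow(acet_sites) == 0L) {
    return(lapply(ubi_calls, function(x) { x$acetylated_too <- FALSE; x }))
  }
  keys <- paste(acet_sites$protein_id, acet_sites$position, sep = "\r")
  lapply(ubi_calls, function(x) {
    x$acetylated_too <-
      paste(x$protein_id, x$position, sep = "\r") %in% keys
    x
  })
}

#' @export
print.window_report <- function(x, ...) {
  cat("window (+/-", x$radius, ") around position ", x$position, ": ",
      x$classification, if (x$clipped) " [clipped]" else "", "\n", sep = "")
  if (!is.null(x$offsets)) print(x$offsets, row.names = FALSE)
  invisible(x)
}
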