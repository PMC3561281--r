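# Computational screening of mapped ubiquitylation sites.
#
# Each observed site is mapped into its gene alignment and passed through
# four independent filters:
#   MULTI_COPY          the human sequence occurs in >1 gene set (paralogy)
#   EUARCHONTOGLIRES_K  a non-primate Euarchontoglires species carries K at
#                       the site column (the gain predates primates)
#   MANY_NONPRIMATE_K   too large a fraction of non-primate species carry K
#                       (recurrent/ancestral lysine, not a primate gain)
#   LOW_CONSERVATION    the region around the site is poorly conserved
#                       (alignment or orthology unreliable)
# All failing reasons are collected; a site is retained iff none fail.
# MISSING residues (gap/X/stop/absent species) never count for or against
# any filter.

#' Screening configuration
#'
#' Bundles the thresholds of the screening filters and the window
#' classifier.  The conservation and non-primate-lysine thresholds
#' operationalize judgments that were qualitative manual-inspection
#' criteria in the original screen; defaults are deliberately permissive.
#'
#' @param conservation_window Residues each side of the site over which
#'   regional conservation is measured (default 10).
#' @param conservation_min_identity Minimum mean identity-to-human over the
#'   conservation window, in `[0,1]` (default 0.6).
#' @param nonprimate_lysine_max_fraction Maximum tolerated fraction of
#'   non-primate species carrying K at the site column (default 0.2).
#' @param window_radius Residue radius of the new/additional/shifted window
#'   analysis (default 5).
#' @param conserved_min_fraction Minimum non-primate K occupancy for a
#'   window offset to count as a conserved alternative lysine (default
#'   0.75).
#' @param allow_reference_peptide_mismatch If `TRUE`, a site whose
#'   reference position holds K but whose flanking context disagrees with
#'   the reported peptide is mapped anyway instead of being rejected.
#' @return A `screen_config` list.
#' @export
screen_config <- function(conservation_window = 10L,
                          conservation_min_identity = 0.6,
                          nonprimate_lysine_max_fraction = 0.2,
                          window_radius = 5L,
                          conserved_min_fraction = 0.75,
                          allow_reference_peptide_mismatch = FALSE) {
  stopifnot(conservation_window >= 1L, window_radius >= 1L,
            conservation_min_identity >= 0, conservation_min_identity <= 1,
            nonprimate_lysine_max_fraction >= 0,
            nonprimate_lysine_max_fraction <= 1,
            conserved_min_fraction >= 0, conserved_min_fraction <= 1)
  structure(list(
    conservation_window = as.integer(conservation_window),
    conservation_min_identity = conservation_min_identity,
    nonprimate_lysine_max_fraction = nonprimate_lysine_max_fraction,
    window_radius = as.integer(window_radius),
    conserved_min_fraction = conserved_min_fraction,
    allow_reference_peptide_mismatch = allow_reference_peptide_mismatch),
    class = "screen_config")
}

# Match a peptide fragment against a reference fragment, treating 'X' on
# either side as a wildcard.
context_matches <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  all(av == bv | av == "X" | bv == "X")
}

#' Map one site onto its gene alignment
#'
#' Locates the alignment column of the modified lysine.  The reported
#' position must hold a K in the ungapped reference row and the flanking
#' reference context must equal the site peptide (allowing truncation at
#' protein termini and `X` wildcards).  If the reported position does not
#' hold a K, a unique exact occurrence of the peptide elsewhere in the
#' reference remaps the site with a logged position correction; zero or
#' multiple occurrences fail with `PEPTIDE_MISMATCH`.
#'
#' @param site One site: a list or one-row data frame with `protein_id`,
#'   `position`, `peptide`.
#' @param aln The gene's `ortholog_alignment`.
#' @param allow_mismatch Tolerate a context mismatch at a position that
#'   does hold K (see [screen_config()]).
#' @return List with `ok` (logical), `column` (0-based, or `NA`),
#'   `position` (possibly corrected), `remapped` (logical), `reason`
#'   (`NA` or `"PEPTIDE_MISMATCH"`).
#' @export
map_site <- function(site, aln, allow_mismatch = FALSE) {
  refseq <- reference_sequence(aln)
  L <- nchar(refseq)
  pep <- toupper(site$peptide)
  n <- nchar(pep)
  k <- (n + 1L) %/% 2L
  pos <- as.integer(site$position)

  ok_at <- function(p) {
    if (p < 1L || p > L) return(FALSE)
    if (substr(refseq, p, p) != "K") return(FALSE)
    left_n <- k - 1L
    right_n <- n - k
    if (p - left_n < 1L || p + right_n > L) return(FALSE)
    context_matches(substr(refseq, p - left_n, p + right_n), pep)
  }

  res_at_pos <- if (pos >= 1L && pos <= L) substr(refseq, pos, pos)
                else NA_character_
  if (!is.na(res_at_pos) && res_at_pos == "K") {
    if (ok_at(pos) || allow_mismatch)
      return(list(ok = TRUE, column = column_of_position(aln, pos),
                  position = pos, remapped = FALSE, reason = NA_character_))
    # K at the reported position but the flanking context disagrees with
    # the peptide: the site cannot be trusted
    return(list(ok = FALSE, column = NA_integer_, position = pos,
                remapped = FALSE, reason = "PEPTIDE_MISMATCH"))
  }
  # position does not hold K: fall back to a unique exact peptide search
  pattern <- chartr("X", ".", pep)
  hits <- gregexpr(pattern, refseq, perl = TRUE)[[1L]]
  hits <- hits[hits > 0L]
  centers <- hits + k - 1L
  centers <- centers[vapply(centers, ok_at, logical(1))]
  if (length(centers) == 1L)
    return(list(ok = TRUE, column = column_of_position(aln, centers),
                position = as.integer(centers), remapped = TRUE,
                reason = NA_character_))
  list(ok = FALSE, column = NA_integer_, position = pos, remapped = FALSE,
       reason = "PEPTIDE_MISMATCH")
}

#' Build the reference-sequence paralogy index
#'
#' Counts, over a collection of gene alignments, how many gene sets share
#' each exact ungapped human sequence.  Genes whose human sequence occurs
#' more than once are flagged by [filter_multicopy()] (orthology
#' uncertain).
#'
#' @param alignments Named list of `ortholog_alignment` objects.
#' @return Named integer vector: for each gene id, the number of gene sets
#'   carrying an identical human sequence.
#' @export
build_reference_index <- function(alignments) {
  seqs <- vapply(alignments, reference_sequence, character(1))
  counts <- table(seqs)
  stats::setNames(as.integer(counts[seqs]), names(alignments))
}

#' Multi-copy (paralogy) filter
#' @param gene_id Gene identifier.
#' @param index Index from [build_reference_index()].
#' @return List with `pass` (logical).
#' @export
filter_multicopy <- function(gene_id, index) {
  n <- if (gene_id %in% names(index)) index[[gene_id]] else 1L
  list(pass = n <= 1L, copies = n)
}

#' Non-primate Euarchontoglires lysine filter
#'
#' Fails iff at least one species tagged `eua` (the non-primate
#' Euarchontoglires: treeshrew, mouse, rat, kangaroo rat, guinea pig,
#' squirrel, rabbit, pika) carries a lysine aligned with the human
#' ubiquitylated lysine.  A K in this in-group implies the lysine predates
#' the primate lineage.  MISSING never triggers a fail; if every `eua`
#' species is MISSING the site passes with a low-information flag.
#'
#' @param profile Residue profile of the site column
#'   ([residue_profile()]).
#' @param tree A `species_tree`.
#' @return List with `pass`, `offending` (species with K) and
#'   `low_information` (all eua species MISSING).
#' @export
filter_euarchontoglires <- function(profile, tree) {
  eua <- intersect(species_of_clade(tree, "eua"), names(profile))
  vals <- profile[eua]
  offending <- eua[!is.na(vals) & vals == "K"]
  list(pass = length(offending) == 0L,
       offending = offending,
       low_information = all(is.na(vals)))
}

#' Many-non-primate-lysines filter
#'
#' Fails iff the fraction of non-primate species carrying K at the site
#' column, among non-primate species with an observed residue, exceeds
#' `cfg$nonprimate_lysine_max_fraction`.  A widespread non-primate K means
#' the lysine is ancestral or recurrent rather than a primate-lineage
#' gain.  MISSING species are excluded from the denominator; an empty
#' denominator passes with a low-information flag.
#'
#' @param profile Residue profile of the site column.
#' @param tree A `species_tree`.
#' @param cfg A [screen_config()].
#' @return List with `pass`, `fraction`, `low_information`.
#' @export
filter_nonprimate_lysines <- function(profile, tree, cfg = screen_config()) {
  nonpri <- setdiff(names(profile), species_of_clade(tree, "pri"))
  vals <- profile[nonpri]
  denom <- sum(!is.na(vals))
  kcount <- sum(vals == "K", na.rm = TRUE)
  frac <- if (denom > 0L) kcount / denom else NA_real_
  list(pass = denom == 0L || frac <= cfg$nonprimate_lysine_max_fraction,
       fraction = frac,
       low_information = denom == 0L)
}

#' Regional conservation filter
#'
#' Measures, over the `cfg$conservation_window` reference residues on each
#' side of the site (clipped at protein termini, site column excluded),
#' the mean fraction of non-MISSING non-reference species whose residue
#' matches the human residue, averaged across window columns.  Fails iff
#' that mean identity falls below `cfg$conservation_min_identity`.
#'
#' @param aln The gene's `ortholog_alignment`.
#' @param column 0-based site column.
#' @param tree A `species_tree`.
#' @param cfg A [screen_config()].
#' @return List with `pass` and `identity` (the mean window identity, `NA`
#'   if no informative column exists).
#' @export
filter_conservation <- function(aln, column, tree, cfg = screen_config()) {
  p <- position_of_column(aln, column)
  L <- nchar(reference_sequence(aln))
  w <- cfg$conservation_window
  positions <- setdiff(max(1L, p - w):min(L, p + w), p)
  fracs <- vapply(positions, function(q) {
    cl <- column_of_position(aln, q)
    prof <- residue_profile(aln, cl, tree)
    ref_res <- prof[[aln$reference]]
    others <- prof[setdiff(names(prof), aln$reference)]
    obs <- others[!is.na(others)]
    if (length(obs) == 0L) return(NA_real_)
    mean(obs == ref_res)
  }, numeric(1))
  identity <- if (all(is.na(fracs))) NA_real_ else mean(fracs, na.rm = TRUE)
  list(pass = is.na(identity) || identity >= cfg$conservation_min_identity,
       identity = identity)
}

#' Screen one site end to end
#'
#' Maps the site and applies the four filters in fixed order
#' (`MULTI_COPY`, `EUARCHONTOGLIRES_K`, `MANY_NONPRIMATE_K`,
#' `LOW_CONSERVATION`), collecting all failing reasons; the site is
#' retained iff none fail.  The filters are independent predicates, so
#' their order affects only the order of the reason codes, never the
#' verdict.
#'
#' @param site One site (list or one-row `ptm_sites` data frame).
#' @param aln The gene's `ortholog_alignment`, or `NULL` if the gene has
#'   no alignment (reason `NO_ALIGNMENT`).
#' @param tree A `species_tree`.
#' @param cfg A [screen_config()].
#' @param index Optional paralogy index from [build_reference_index()];
#'   when `NULL` the multi-copy filter is vacuously passed.
#' @param gene_id Gene identifier (defaults to the alignment's, or the
#'   site's `protein_id`).
#' @return A `site_call`: list with the site fields, `gene_id`, `column`
#'   (0-based, `NA` if unmapped), `position` (possibly remap-corrected),
#'   `status` (`"retained"`/`"discarded"`), `reasons` (character vector of
#'   failure codes), `flags` (e.g. `low_information`, `remapped`),
#'   `identity`, `nonprimate_k_fraction`, and placeholders `origin_clade`,
#'   `ambiguous_clades`, `homoplasy_species`, `window_class`,
#'   `acetylated_too` filled by the downstream stages.
#' @export
screen_site <- function(site, aln, tree, cfg = screen_config(),
                        index = NULL, gene_id = NULL) {
  gene_id <- gene_id %||% (if (!is.null(aln)) aln$gene_id else site$protein_id)
  call <- structure(list(
    protein_id = site$protein_id,
    position = as.integer(site$position),
    original_position = as.integer(site$position),
    peptide = toupper(site$peptide),
    sources = site$sources %||% NA_character_,
    mod_kind = site$mod_kind %||% "ubiquitylation",
    gene_id = gene_id,
    column = NA_integer_,
    status = "discarded",
    reasons = character(),
    flags = character(),
    identity = NA_real_,
    nonprimate_k_fraction = NA_real_,
    origin_clade = NA_character_,
    ambiguous_clades = character(),
    homoplasy_species = character(),
    window_class = NA_character_,
    acetylated_too = FALSE), class = "site_call")

  if (is.null(aln)) {
    call$reasons <- "NO_ALIGNMENT"
    return(call)
  }
  m <- map_site(site, aln, allow_mismatch = cfg$allow_reference_peptide_mismatch)
  if (!m$ok) {
    call$reasons <- m$reason
    return(call)
  }
  call$column <- m$column
  call$position <- m$position
  if (m$remapped) call$flags <- c(call$flags, "remapped")

  reasons <- character()
  if (!is.null(index) && !filter_multicopy(gene_id, index)$pass)
    reasons <- c(reasons, "MULTI_COPY")
  profile <- residue_profile(aln, m$column, tree)
  f_eua <- filter_euarchontoglires(profile, tree)
  if (!f_eua$pass) reasons <- c(reasons, "EUARCHONTOGLIRES_K")
  if (f_eua$low_information)
    call$flags <- c(call$flags, "low_information_euarchontoglires")
  f_np <- filter_nonprimate_lysines(profile, tree, cfg)
  call$nonprimate_k_fraction <- f_np$fraction
  if (!f_np$pass) reasons <- c(reasons, "MANY_NONPRIMATE_K")
  if (f_np$low_information)
    call$flags <- c(call$flags, "low_information_nonprimate")
  f_cons <- filter_conservation(aln, m$column, tree, cfg)
  call$identity <- f_cons$identity
  if (!f_cons$pass) reasons <- c(reasons, "LOW_CONSERVATION")

  call$reasons <- reasons
  call$status <- if (length(reasons) == 0L) "retained" else "discarded"
  call
}

#' @export
print.site_call <- function(x, ...) {
  cat(x$protein_id, " pos ", x$position, " [", x$gene_id, "]: ", x$status,
      if (length(x$reasons) > 0L)
        paste0(" (", paste(x$reasons, collapse = ","), ")") else "",
      if (!is.na(x$origin_clade)) paste0(" origin=", x$origin_clade) else "",
      if (!is.na(x$window_class)) paste0(" class=", x$window_class) else "",
      "\n", sep = "")
  invisible(x)
}
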