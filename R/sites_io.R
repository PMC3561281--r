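# Reading, validating and deduplicating PTM site tables.
#
# A site table is a TSV with required columns protein_id, position, peptide
# and an optional column source.  Each row records one experimentally
# observed modified lysine: the accession of the protein it was mapped to,
# the 1-based residue position, and the peptide centred on the modified
# lysine (13-mer, possibly shorter near protein termini).

#' Read a PTM site table
#'
#' Parses a tab-separated site table into a validated `ptm_sites` data
#' frame.  Rows that violate the site invariants (center residue not a
#' lysine, even or over-long peptide, non-amino-acid characters,
#' non-integer or non-positive position) are rejected with a per-row
#' diagnostic attached as the `"rejected"` attribute rather than silently
#' dropped.
#'
#' @param path Path to a UTF-8 TSV file with a header line and columns
#'   `protein_id`, `position`, `peptide`; an optional `source` column gives
#'   the experiment label per row.
#' @param mod_kind Modification kind of all sites in the table.
#' @param source_label Experiment label applied to rows without a `source`
#'   column entry.
#' @return A data frame of class `ptm_sites` with columns `protein_id`
#'   (character), `position` (integer, 1-based), `peptide` (uppercase
#'   character), `sources` (comma-joined experiment labels) and `mod_kind`.
#'   Attribute `"rejected"`: data frame of rejected rows with a `problem`
#'   column.
#' @export
parse_site_table <- function(path,
                             mod_kind = c("ubiquitylation", "acetylation"),
                             source_label = "unknown") {
  mod_kind <- match.arg(mod_kind)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  required <- c("protein_id", "position", "peptide")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stop("site table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"source" %in% names(raw))
    raw$source <- if ("sources" %in% names(raw)) raw$sources else NA_character_
  src <- ifelse(is.na(raw$source) | raw$source == "", source_label,
                raw$source)
  pep <- toupper(trimws(raw$peptide))
  pos <- suppressWarnings(as.integer(trimws(raw$position)))
  pos_noninteger <- is.na(pos) |
    trimws(raw$position) != as.character(pos)

  problem <- character(nrow(raw))
  problem[pos_noninteger] <- "non-integer position"
  problem[!pos_noninteger & pos < 1L] <- "position < 1"
  bad_chars <- !grepl(sprintf("^[%sX]+$", paste(AA20, collapse = "")), pep)
  problem[problem == "" & bad_chars] <- "non-amino-acid characters in peptide"
  bad_len <- nchar(pep) > 13L | nchar(pep) %% 2L == 0L
  problem[problem == "" & bad_len] <- "peptide length must be odd and <= 13"
  center <- substr(pep, (nchar(pep) + 1L) %/% 2L, (nchar(pep) + 1L) %/% 2L)
  problem[problem == "" & center != "K"] <- "center residue is not K"

  keep <- problem == ""
  sites <- data.frame(protein_id = trimws(raw$protein_id)[keep],
                      position = pos[keep],
                      peptide = pep[keep],
                      sources = src[keep],
                      mod_kind = mod_kind,
                      stringsAsFactors = FALSE)
  rejected <- data.frame(row = which(!keep),
                         protein_id = trimws(raw$protein_id)[!keep],
                         position = raw$position[!keep],
                         peptide = raw$peptide[!keep],
                         problem = problem[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L)
    warning(nrow(rejected), " row(s) of ", basename(path),
            " rejected; see attr(x, \"rejected\")", call. = FALSE)
  attr(sites, "rejected") <- rejected
  class(sites) <- c("ptm_sites", "data.frame")
  sites
}

#' Deduplicate a site table across experiments
#'
#' Collapses sites repeated across experiments to one row per
#' `(protein_id, position, mod_kind)`.  Experiment labels are unioned into
#' a sorted, comma-joined `sources` field.  When duplicated rows disagree
#' on the peptide the longer peptide is kept and the conflict recorded in
#' the `"conflicts"` attribute.
#'
#' @param sites A `ptm_sites` data frame (possibly a concatenation of
#'   several parsed tables via `rbind`).
#' @return A `ptm_sites` data frame with one row per site, sorted by
#'   `protein_id` then `position`.  Attribute `"conflicts"`: data frame of
#'   peptide conflicts (one row per conflicting key).
#' @export
deduplicate <- function(sites) {
  if (nrow(sites) == 0L) {
    attr(sites, "conflicts") <- data.frame(protein_id = character(),
                                           position = integer(),
                                           peptides = character(),
                                           stringsAsFactors = FALSE)
    return(sites)
  }
  key <- paste(sites$protein_id, sites$position, sites$mod_kind, sep = "\r")
  groups <- split(seq_len(nrow(sites)), key)
  conflicts <- list()
  rows <- lapply(groups, function(idx) {
    g <- sites[idx, , drop = FALSE]
    peps <- unique(g$peptide)
    if (length(peps) > 1L) {
      conflicts[[length(conflicts) + 1L]] <<-
        data.frame(protein_id = g$protein_id[1L],
                   position = g$position[1L],
                   peptides = paste(sort(peps), collapse = ","),
                   stringsAsFactors = FALSE)
      # keep the longest peptide; ties broken alphabetically for determinism
      peps <- peps[order(-nchar(peps), peps)]
    }
    srcs <- sort(unique(unlist(strsplit(g$sources, ",[ ]?"))))
    data.frame(protein_id = g$protein_id[1L],
               position = g$position[1L],
               peptide = peps[1L],
               sources = paste(srcs, collapse = ","),
               mod_kind = g$mod_kind[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicts") <-
    if (length(conflicts) > 0L) do.call(rbind, conflicts)
    else data.frame(protein_id = character(), position = integer(),
                    peptides = character(), stringsAsFactors = FALSE)
  class(out) <- c("ptm_sites", "data.frame")
  out
}

#' Write a site table
#'
#' Writes a `ptm_sites` data frame back to the TSV dialect accepted by
#' [parse_site_table()], with the comma-joined `sources` column.
#'
#' @param sites A `ptm_sites` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  out <- as.data.frame(sites)[, c("protein_id", "position", "peptide",
                                  "sources", "mod_kind")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
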