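# End-to-end orchestration: sites -> screening -> dating -> window ->
# acetylation cross-reference, with a run manifest recording the funnel.

#' Run the full gain-detection pipeline
#'
#' Executes every stage in order: parse/deduplicate the site table, map
#' and screen each site against its gene alignment, date each retained
#' gain to a ladder clade, classify it via the window analysis, and
#' cross-reference with acetylation sites.  Per-stage record counts are
#' collected in a manifest whose funnel (input >= non-redundant >= mapped
#' >= retained) is asserted on every run.
#'
#' @param sites A `ptm_sites` data frame, or a path to a site TSV
#'   (parsed as ubiquitylation sites).
#' @param alignments Named list of `ortholog_alignment` objects
#'   (names = gene ids), or a directory of per-gene FASTA files
#'   (`<gene_id>.fasta`/`.fa`).
#' @param tree A `species_tree`.
#' @param cfg A [screen_config()].
#' @param acetylation Optional acetylation `ptm_sites` data frame or TSV
#'   path (deduplicated internally).
#' @param gene_map Optional data frame with columns `protein_id`,
#'   `gene_id` linking site accessions to alignment files; by default the
#'   site's `protein_id` is used as the gene id.
#' @param curation Optional data frame with columns `protein_id`,
#'   `position`, `action` (`"keep"`/`"drop"`) and `reason`, applied after
#'   screening so manual curation decisions are explicit and reproducible.
#' @param out_dir Optional output directory; when given, writes
#'   `site_calls.tsv`, `gain_summary.tsv`, `window_reports.tsv` and
#'   `manifest.json`.
#' @return A `ptm_run`: list with `manifest`, `calls` (list of
#'   `site_call`), `calls_df` (flat data frame), `gains` (a
#'   `gain_summary`) and `windows` (named list of `window_report`).
#' @export
run_pipeline <- function(sites, alignments, tree, cfg = screen_config(),
                         acetylation = NULL, gene_map = NULL,
                         curation = NULL, out_dir = NULL) {
  input_digests <- list()
  if (is.character(sites)) {
    input_digests$sites <- unname(tools::md5sum(sites))
    sites <- parse_site_table(sites, "ubiquitylation")
  }
  if (is.character(alignments)) {
    dir <- alignments
    files <- sort(list.files(dir, pattern = "\\.(fa|fasta)$",
                             full.names = TRUE))
    alignments <- stats::setNames(
      lapply(files, parse_alignment_fasta, reference = tree$reference),
      tools::file_path_sans_ext(basename(files)))
  }
  if (is.character(acetylation)) {
    input_digests$acetylation <- unname(tools::md5sum(acetylation))
    acetylation <- parse_site_table(acetylation, "acetylation")
  }
  if (!is.null(acetylation)) acetylation <- deduplicate(acetylation)

  n_input <- nrow(sites)
  nr <- deduplicate(sites)
  index <- build_reference_index(alignments)
  gene_of <- function(protein_id) {
    if (!is.null(gene_map)) {
      hit <- gene_map$gene_id[match(protein_id, gene_map$protein_id)]
      if (!is.na(hit)) return(hit)
    }
    protein_id
  }

  calls <- lapply(seq_len(nrow(nr)), function(i) {
    site <- as.list(nr[i, , drop = FALSE])
    gid <- gene_of(site$protein_id)
    screen_site(site, alignments[[gid]], tree, cfg, index, gene_id = gid)
  })

  # explicit curation overrides (reproducible stand-in for by-hand review)
  if (!is.null(curation)) {
    calls <- lapply(calls, function(x) {
      j <- which(curation$protein_id == x$protein_id &
                   curation$position == x$position)
      if (length(j) == 1L) {
        x$flags <- c(x$flags, paste0("curated_", curation$action[j]))
        if (curation$action[j] == "drop") x$status <- "discarded"
        if (curation$action[j] == "keep" && !is.na(x$column)) {
          x$status <- "retained"; x$reasons <- character()
        }
      }
      x
    })
  }

  retained_idx <- which(vapply(calls, function(x)
    x$status == "retained", logical(1)))
  windows <- list()
  for (i in retained_idx) {
    x <- calls[[i]]
    aln <- alignments[[x$gene_id]]
    profile <- residue_profile(aln, x$column, tree)
    origin <- infer_origin_clade(profile, tree)
    x$origin_clade <- origin$clade
    x$ambiguous_clades <- origin$ambiguous_clades
    x$homoplasy_species <- origin$homoplasy_species
    wr <- window_report(aln, x$column, origin$clade, tree,
                        conserved_min_fraction = cfg$conserved_min_fraction,
                        radius = cfg$window_radius)
    x$window_class <- wr$classification
    windows[[paste(x$protein_id, x$position, sep = ":")]] <- wr
    calls[[i]] <- x
  }
  calls <- acetylation_overlap(calls, acetylation)

  retained <- calls[retained_idx]
  gains <- if (length(retained) > 0L) tabulate_gains(retained, tree)
           else structure(list(counts_by_clade = stats::setNames(
                  integer(length(tree$ladder)), names(tree$ladder)),
                  total_sites = 0L, total_proteins = 0L),
                  class = "gain_summary")

  mapped <- vapply(calls, function(x) !is.na(x$column), logical(1))
  wc <- vapply(retained, function(x) x$window_class, character(1))
  counts <- list(
    input_sites = n_input,
    nonredundant_sites = nrow(nr),
    mapped_sites = sum(mapped),
    genes_with_mappings = length(unique(vapply(
      calls[mapped], function(x) x$gene_id, character(1)))),
    retained_sites = length(retained),
    retained_genes = gains$total_proteins,
    gains_by_clade = as.list(gains$counts_by_clade),
    window_classes = list(new = sum(wc == "new"),
                          additional = sum(wc == "additional"),
                          shifted = sum(wc == "shifted")),
    acetylation_overlaps = sum(vapply(retained, function(x)
      isTRUE(x$acetylated_too), logical(1))))
  stopifnot(counts$input_sites >= counts$nonredundant_sites,
            counts$nonredundant_sites >= counts$mapped_sites,
            counts$mapped_sites >= counts$retained_sites)

  manifest <- list(tool = "ubigain",
                   version = as.character(utils::packageVersion("ubigain")),
                   config = unclass(cfg),
                   input_digests = input_digests,
                   counts = counts)
  run <- structure(list(manifest = manifest, calls = calls,
                        calls_df = site_calls_to_df(calls),
                        gains = gains, windows = windows),
                   class = "ptm_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Flatten site calls to a data frame
#' @param calls List of `site_call`s.
#' @return Data frame, one row per call; list-valued fields are
#'   comma-joined.
#' @export
site_calls_to_df <- function(calls) {
  if (length(calls) == 0L)
    return(data.frame(protein_id = character(), position = integer(),
                      gene_id = character(), column = integer(),
                      status = character(), reasons = character(),
                      origin_clade = character(),
                      ambiguous_clades = character(),
                      window_class = character(),
                      acetylated_too = logical(),
                      identity = numeric(),
                      nonprimate_k_fraction = numeric(),
                      flags = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(calls, function(x)
    data.frame(protein_id = x$protein_id, position = x$position,
               gene_id = x$gene_id, column = x$column,
               status = x$status,
               reasons = paste(x$reasons, collapse = ","),
               origin_clade = x$origin_clade,
               ambiguous_clades = paste(x$ambiguous_clades, collapse = ","),
               window_class = x$window_class,
               acetylated_too = x$acetylated_too,
               identity = x$identity,
               nonprimate_k_fraction = x$nonprimate_k_fraction,
               flags = paste(x$flags, collapse = ","),
               stringsAsFactors = FALSE)))
}

# Write the pipeline outputs.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$calls_df, file.path(out_dir, "site_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gdf <- data.frame(clade = names(run$gains$counts_by_clade),
                    n_gains = as.integer(run$gains$counts_by_clade),
                    stringsAsFactors = FALSE)
  utils::write.table(gdf, file.path(out_dir, "gain_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wdf <- do.call(rbind, lapply(names(run$windows), function(k) {
    w <- run$windows[[k]]
    data.frame(site = k, position = w$position,
               classification = w$classification,
               clipped = w$clipped,
               conserved_offsets = paste(
                 w$offsets$offset[w$offsets$conserved], collapse = ","),
               offsets_with_reference_K = paste(
                 w$offsets_with_reference_K, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(wdf))
    wdf <- data.frame(site = character(), position = integer(),
                      classification = character(), clipped = logical(),
                      conserved_offsets = character(),
                      offsets_with_reference_K = character())
  utils::write.table(wdf, file.path(out_dir, "window_reports.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Human-readable run report
#'
#' Renders the screening funnel, the per-branch gain table, the
#' human-specific site list and the new/additional/shifted partition.
#'
#' @param run A `ptm_run` from [run_pipeline()].
#' @return Character vector of report lines, invisibly; printed to the
#'   console.
#' @export
report <- function(run) {
  cn <- run$manifest$counts
  lines <- c(
    "== screening funnel ==",
    sprintf("input sites            %d", cn$input_sites),
    sprintf("non-redundant sites    %d", cn$nonredundant_sites),
    sprintf("mapped sites           %d (in %d genes)", cn$mapped_sites,
            cn$genes_with_mappings),
    sprintf("retained gains         %d (in %d proteins)",
            cn$retained_sites, cn$retained_genes),
    "",
    "== gains per human-lineage branch ==",
    vapply(names(run$gains$counts_by_clade), function(nm)
      sprintf("  %-20s %d", nm, run$gains$counts_by_clade[[nm]]),
      character(1)),
    "",
    "== window classes ==",
    sprintf("  new %d / additional %d / shifted %d",
            cn$window_classes$new, cn$window_classes$additional,
            cn$window_classes$shifted),
    sprintf("  acetylation overlaps: %d", cn$acetylation_overlaps))
  hs <- Filter(function(x) identical(x$origin_clade, "human"), run$calls)
  if (length(hs) > 0L) {
    lines <- c(lines, "", "== human-specific sites ==",
               vapply(hs, function(x)
                 sprintf("  %-20s %-15s %5d  %s", x$protein_id, x$peptide,
                         x$position, x$sources), character(1)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.ptm_run <- function(x, ...) {
  report(x)
  invisible(x)
}
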