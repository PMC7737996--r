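#' Path to the packaged antibody panel registry
#'
#' The package ships a transcription of the study's antibody panel: 232
#' distinct antisera occupying 280 category slots across 20 categories
#' (19 signaling-pathway groups plus the housekeeping controls), with 46
#' slots marked as cross-category overlaps and 116 proteins flagged as the
#' representative star-plot subset.
#'
#' @return Path to the registry TSV (or category TSV) inside the installed
#'   package.
#' @seealso [load_panel()]
#' @export
panel_file <- function() {
  system.file("extdata", "antibody_panel.tsv", package = "iphplc",
              mustWork = TRUE)
}

#' @rdname panel_file
#' @export
categories_file <- function() {
  system.file("extdata", "pathway_categories.tsv", package = "iphplc",
              mustWork = TRUE)
}

#' Load and validate an antibody panel registry
#'
#' Reads a tab-separated registry (one row per distinct antibody: name,
#' semicolon-joined category memberships, semicolon-joined overlap
#' categories, housekeeping flag, representative flag, optional vendor
#' code) together with a category table carrying the declared per-category
#' antibody counts and overlap counts. Membership-derived counts are
#' recomputed and cross-checked against the declared values; a mismatching
#' count cell raises a warning reporting both numbers (the packaged panel
#' has two such cells, inherited from its source table), never a rejection.
#'
#' Structural problems in the registry itself (duplicate names, an overlap
#' flag on a category the record does not list, a housekeeping record with
#' more than one category, no records at all) are errors.
#'
#' @param path Registry TSV. Defaults to the packaged panel.
#' @param categories_path Category TSV with columns `category`,
#'   `declared_count`, `declared_overlap`, `pathway_group`. Defaults to the
#'   packaged table.
#' @return A `panel_registry` object: list with `records` (data.frame),
#'   `categories` (data.frame with declared and recomputed counts),
#'   `pathway_groups` (named list of member antibody vectors, in category
#'   order), `count_mismatches` (data.frame of discrepant count cells) and
#'   `meta` (declared totals parsed from header comments).
#' @examples
#' reg <- load_panel()
#' length(reg$pathway_groups)        # 19
#' proteins_in_group(reg, "Control housekeeping proteins")
#' @export
load_panel <- function(path = panel_file(), categories_path = categories_file()) {
  raw <- readLines(path, encoding = "UTF-8")
  if (length(raw) == 0L || all(grepl("^\\s*$", raw))) {
    stop("no records: registry file is empty: ", path)
  }
  hdr <- grep("^#", raw, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+):\\s*([0-9]+)\\s*$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- as.integer(m[3])
  }

  body <- raw[!grepl("^#", raw)]
  body <- body[!grepl("^\\s*$", body)]
  if (length(body) < 2L) stop("no records: registry has a header but no rows")
  rec <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
  needed <- c("name", "categories", "overlap_in", "housekeeping",
              "representative")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols)) {
    stop("registry is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"vendor_code" %in% names(rec)) rec$vendor_code <- ""
  for (col in c("name", "categories", "overlap_in", "vendor_code")) {
    rec[[col]] <- as.character(rec[[col]])
    rec[[col]][is.na(rec[[col]])] <- ""
  }

  dup <- rec$name[duplicated(rec$name)]
  if (length(dup)) {
    rows <- which(rec$name %in% dup)
    stop("duplicate antibody name(s) in registry: ",
         paste(unique(dup), collapse = ", "),
         " (rows ", paste(rows, collapse = ", "), ")")
  }

  split_semi <- function(x) {
    lapply(strsplit(x, ";", fixed = TRUE),
           function(v) trimws(v[nzchar(trimws(v))]))
  }
  cat_list <- split_semi(rec$categories)
  ovl_list <- split_semi(rec$overlap_in)

  empty <- which(lengths(cat_list) == 0L)
  if (length(empty)) {
    stop("record(s) with no category membership (rows ",
         paste(empty, collapse = ", "), "): ",
         paste(rec$name[empty], collapse = ", "))
  }
  bad_ovl <- which(mapply(function(o, c) length(setdiff(o, c)) > 0,
                          ovl_list, cat_list))
  if (length(bad_ovl)) {
    stop("overlap flag on a category the record does not list (rows ",
         paste(bad_ovl, collapse = ", "), "): ",
         paste(rec$name[bad_ovl], collapse = ", "))
  }

  cats <- read.delim(categories_path, sep = "\t", stringsAsFactors = FALSE,
                     quote = "", comment.char = "#")
  stopifnot(all(c("category", "declared_count", "declared_overlap",
                  "pathway_group") %in% names(cats)))

  unknown <- setdiff(unique(unlist(cat_list)), cats$category)
  if (length(unknown)) {
    stop("record(s) reference unknown categor(ies): ",
         paste(unknown, collapse = ", "))
  }

  hk <- which(rec$housekeeping == 1L)
  hk_bad <- hk[lengths(cat_list[hk]) != 1L |
                 vapply(cat_list[hk], function(c)
                   !identical(c, "Control housekeeping proteins"), logical(1))]
  if (length(hk_bad)) {
    stop("housekeeping record(s) must list exactly the housekeeping ",
         "category (rows ", paste(hk_bad, collapse = ", "), "): ",
         paste(rec$name[hk_bad], collapse = ", "))
  }

  # recompute slot and overlap counts per category, overlaps included
  cats$recomputed_count <- vapply(cats$category, function(cc)
    sum(vapply(cat_list, function(c) cc %in% c, logical(1))), integer(1))
  cats$recomputed_overlap <- vapply(cats$category, function(cc)
    sum(vapply(ovl_list, function(o) cc %in% o, logical(1))), integer(1))

  mism <- cats[cats$recomputed_count != cats$declared_count |
                 cats$recomputed_overlap != cats$declared_overlap, ,
               drop = FALSE]
  if (nrow(mism)) {
    for (i in seq_len(nrow(mism))) {
      warning(sprintf(
        "count-column mismatch for '%s': declared %d (%d), recomputed %d (%d)",
        mism$category[i], mism$declared_count[i], mism$declared_overlap[i],
        mism$recomputed_count[i], mism$recomputed_overlap[i]),
        call. = FALSE)
    }
  }

  rec$categories <- vapply(cat_list, paste, character(1), collapse = ";")
  rec$overlap_in <- vapply(ovl_list, paste, character(1), collapse = ";")
  rec$housekeeping <- as.integer(rec$housekeeping)
  rec$representative <- as.integer(rec$representative)

  groups <- cats$category[cats$pathway_group == 1L]
  pathway_groups <- setNames(lapply(groups, function(g)
    rec$name[vapply(cat_list, function(c) g %in% c, logical(1))]), groups)

  reg <- structure(list(
    records = rec,
    categories = cats,
    pathway_groups = pathway_groups,
    count_mismatches = mism,
    meta = meta
  ), class = "panel_registry")

  bad_rep <- setdiff(representative_proteins(reg),
                     unlist(pathway_groups, use.names = FALSE))
  if (length(bad_rep)) {
    stop("representative protein(s) outside every pathway group: ",
         paste(bad_rep, collapse = ", "))
  }
  reg
}

#' Write a panel registry back to disk
#'
#' Inverse of [load_panel()]: writes the registry TSV (with its metadata
#' header comments) so that loading, writing and reloading yields an
#' identical registry.
#'
#' @param registry A `panel_registry`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(registry, path) {
  stopifnot(inherits(registry, "panel_registry"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(registry$meta)) {
    writeLines(sprintf("# %s: %d", k, registry$meta[[k]]), con)
  }
  cols <- c("name", "categories", "overlap_in", "housekeeping",
            "representative", "vendor_code")
  write.table(registry$records[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' List the antibodies of one panel category
#'
#' Members are returned in registry order; antibodies whose slot in the
#' category is an overlap (counted there but primarily listed elsewhere)
#' are included.
#'
#' @param registry A `panel_registry`.
#' @param group Category name, e.g. `"Control housekeeping proteins"`.
#' @return Character vector of antibody names.
#' @export
proteins_in_group <- function(registry, group) {
  stopifnot(inherits(registry, "panel_registry"))
  valid <- registry$categories$category
  if (!group %in% valid) {
    stop("unknown group '", group, "'; valid groups are: ",
         paste(valid, collapse = "; "))
  }
  rec <- registry$records
  in_g <- vapply(strsplit(rec$categories, ";", fixed = TRUE),
                 function(c) group %in% c, logical(1))
  rec$name[in_g]
}

#' Representative star-plot subset of the panel
#'
#' Returns the proteins flagged as members of the full-panel star plot,
#' ordered by pathway group (category order) and registry order within a
#' group; a protein belonging to several groups is listed once, under its
#' first group.
#'
#' @param registry A `panel_registry`.
#' @return Character vector of antibody names (116 in the packaged panel).
#' @export
representative_proteins <- function(registry) {
  stopifnot(inherits(registry, "panel_registry"))
  flagged <- registry$records$name[registry$records$representative == 1L]
  out <- character(0)
  for (g in names(registry$pathway_groups)) {
    m <- intersect(registry$pathway_groups[[g]], flagged)
    out <- c(out, setdiff(m, out))
  }
  # flagged proteins outside every pathway group (none in the packaged panel)
  c(out, setdiff(flagged, out))
}

#' Housekeeping control proteins of a panel
#'
#' @param registry A `panel_registry`.
#' @return Character vector of housekeeping antibody names.
#' @export
housekeeping_proteins <- function(registry) {
  stopifnot(inherits(registry, "panel_registry"))
  registry$records$name[registry$records$housekeeping == 1L]
}

#' @export
print.panel_registry <- function(x, ...) {
  cat(sprintf(
    "<panel_registry> %d antibodies, %d categories (%d pathway groups)\n",
    nrow(x$records), nrow(x$categories), length(x$pathway_groups)))
  cat(sprintf("  slots: %d recomputed (declared %s), overlaps: %d (declared %s)\n",
              sum(x$categories$recomputed_count),
              x$meta$declared_total_slots %||% "?",
              sum(x$categories$recomputed_overlap),
              x$meta$declared_total_overlap %||% "?"))
  cat(sprintf("  representative subset: %d; housekeeping: %s\n",
              sum(x$records$representative),
              paste(housekeeping_proteins(x), collapse = ", ")))
  if (nrow(x$count_mismatches)) {
    cat("  count tensions:",
        paste(x$count_mismatches$category, collapse = "; "), "\n")
  }
  invisible(x)
}
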