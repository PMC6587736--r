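# Reading, validation and filtering of measurement tables; tree IO and
# prune/graft against a reference phylogeny.

MEASUREMENT_COLUMNS <- c("sample_id", "species", "color_category",
                         "melanosome_type", "length_um", "width_um")

#' Validate a per-melanosome measurement table
#'
#' Checks the schema used throughout the package: one row per measured
#' melanosome with columns `sample_id`, `species`, `color_category` (one of
#' black/brown/grey/iridescent), `melanosome_type` (one of the four
#' iridescence-generating types, or `NA` for non-iridescent samples),
#' `length_um`, `width_um` (positive, micrometres). Every sample must map to
#' exactly one species, one color category and (if iridescent) one type.
#'
#' @param table data.frame to validate.
#' @return The table, invisibly, with `melanosome_type` normalized to `NA`
#'   for non-iridescent rows.
#' @export
validate_measurements <- function(table) {
  if (!is.data.frame(table)) stop("measurement table must be a data.frame")
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(table))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  table$melanosome_type[!is.na(table$melanosome_type) &
                          table$melanosome_type == ""] <- NA
  bad_cat <- which(!table$color_category %in% COLOR_CATEGORIES)
  if (length(bad_cat) > 0)
    stop("validation error: unknown color_category in row(s): ",
         paste(head(bad_cat, 10), collapse = ", "))
  bad_type <- which(!is.na(table$melanosome_type) &
                      !table$melanosome_type %in% MELANOSOME_TYPES)
  if (length(bad_type) > 0)
    stop("validation error: unknown melanosome_type in row(s): ",
         paste(head(bad_type, 10), collapse = ", "))
  bad_dim <- which(!is.finite(table$length_um) | !is.finite(table$width_um) |
                     table$length_um <= 0 | table$width_um <= 0)
  if (length(bad_dim) > 0)
    stop("validation error: nonpositive or missing length/width in row(s): ",
         paste(head(bad_dim, 10), collapse = ", "))
  per_sample <- unique(table[, c("sample_id", "species", "color_category",
                                 "melanosome_type")])
  dup <- per_sample$sample_id[duplicated(per_sample$sample_id)]
  if (length(dup) > 0)
    stop("validation error: sample(s) with inconsistent species/category/type: ",
         paste(unique(dup), collapse = ", "))
  invisible(table)
}

#' Read a per-melanosome measurement table
#'
#' Reads a comma- or tab-delimited file with a mandatory header line.
#' The delimiter is auto-detected from the header unless given.
#'
#' @param path path to a CSV/TSV file.
#' @param dialect `"auto"` (default), `"csv"`, or `"tsv"`.
#' @return A validated measurement table (data.frame).
#' @export
read_measurements <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    header <- readLines(path, n = 1L)
    dialect <- if (grepl("\t", header)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  validate_measurements(tab)
  tab
}

#' Write a measurement table
#'
#' @param table validated measurement table.
#' @param path output path; a `.tsv` extension selects tab delimiters.
#' @export
write_measurements <- function(table, path) {
  validate_measurements(table)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply dataset filters (species exclusion, small-sample flagging)
#'
#' Removes all rows belonging to excluded species (e.g. penguins, whose
#' melanosome morphology reflects their aquatic lifestyle rather than
#' color), and flags samples with fewer than `min_n` measured melanosomes.
#' Flagged samples are kept unless `drop_small = TRUE`; small samples remain
#' usable for means while sample-size-sensitive statistics (CV of length)
#' are excluded downstream instead.
#'
#' @param table measurement table.
#' @param exclude_species character vector of species to remove.
#' @param min_n samples with fewer melanosomes than this are flagged.
#' @param drop_small drop flagged samples instead of only flagging them.
#' @return list with elements `table` (filtered measurement table, with a
#'   `flagged_small` logical column) and `report` (named list of counts,
#'   serializable to JSON via [write_filter_report()]).
#' @export
filter_dataset <- function(table, exclude_species = character(),
                           min_n = 10, drop_small = FALSE) {
  validate_measurements(table)
  if (min_n < 0) stop("min_n must be >= 0")
  absent <- setdiff(exclude_species, unique(table$species))
  if (length(absent) > 0)
    warning("excluded species not present in table: ",
            paste(absent, collapse = ", "))
  excl_rows <- table$species %in% exclude_species
  removed_samples <- unique(table$sample_id[excl_rows])
  out <- table[!excl_rows, , drop = FALSE]
  counts <- table(out$sample_id)
  flagged <- names(counts)[counts < min_n]
  out$flagged_small <- out$sample_id %in% flagged
  if (drop_small) out <- out[!out$flagged_small, , drop = FALSE]
  report <- list(
    n_rows_in = nrow(table),
    n_rows_out = nrow(out),
    excluded_species = as.list(intersect(exclude_species, table$species)),
    n_samples_removed = length(removed_samples),
    samples_removed = as.list(removed_samples),
    min_n = min_n,
    n_samples_flagged = length(flagged),
    samples_flagged = as.list(flagged),
    dropped_small = drop_small
  )
  list(table = out, report = report)
}

#' @rdname filter_dataset
#' @param report filter report from [filter_dataset()].
#' @param path output JSON path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a phylogenetic tree from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream analyses
#' need: unique named tips, branch lengths present and nonnegative.
#' Polytomies are allowed.
#'
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: no tree in file")
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(tree$tip.label == ""))
    stop("parse error: tree has unnamed tips")
  if (anyDuplicated(tree$tip.label))
    stop("tip names not unique: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("parse error: tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("parse error: negative branch lengths")
  invisible(tree)
}

genus_of <- function(species, genus_map = NULL) {
  if (!is.null(genus_map)) {
    g <- unname(genus_map[species])
    miss <- is.na(g)
    if (any(miss)) g[miss] <- sub("[_ ].*$", "", species[miss])
    return(g)
  }
  sub("[_ ].*$", "", species)
}

node_age <- function(tree, node) {
  # height above the tips (ultrametric) = depth - distance from root
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths[node]
}

#' Prune a reference tree to a species set, grafting missing species
#'
#' Species absent from the reference tree are attached within their genus
#' (from `genus_map`, or the binomial prefix of the name), creating generic
#' polytomies. When the genus is represented by a clade, the new tip is
#' attached at the genus crown node with branch length equal to the crown
#' age, preserving ultrametricity; when the genus is a single tip, the new
#' tip is attached `graft_fraction` of the way down that terminal branch.
#'
#' @param tree reference phylogeny (ape `phylo`), branch lengths required.
#' @param species character vector: the analysis species set.
#' @param genus_map optional named character vector, species -> genus.
#' @param graft_fraction attachment point on a singleton genus' terminal
#'   branch, as a fraction of its length (default 0.5).
#' @return a `phylo` whose tip set equals `species` exactly.
#' @export
prune_and_graft <- function(tree, species, genus_map = NULL,
                            graft_fraction = 0.5) {
  validate_tree(tree)
  if (graft_fraction <= 0 || graft_fraction >= 1)
    stop("graft_fraction must be in (0, 1)")
  species <- unique(species)
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0) {
    tip_genera <- genus_of(tree$tip.label, genus_map)
    want_genera <- genus_of(missing, genus_map)
    unresolvable <- missing[!want_genera %in% tip_genera]
    if (length(unresolvable) > 0)
      stop("unresolvable taxa (no congener in tree): ",
           paste(unresolvable, collapse = ", "))
    for (sp in missing) {
      tip_genera <- genus_of(tree$tip.label, genus_map)
      g <- genus_of(sp, genus_map)
      members <- which(tip_genera == g)
      if (length(members) >= 2) {
        node <- ape::getMRCA(tree, tree$tip.label[members])
        age <- node_age(tree, node)
        tree <- phytools::bind.tip(tree, sp, edge.length = age, where = node)
      } else {
        tip <- members[1]
        term_edge <- tree$edge.length[tree$edge[, 2] == tip]
        pos <- graft_fraction * term_edge
        tree <- phytools::bind.tip(tree, sp, edge.length = pos,
                                   where = tip, position = pos)
      }
    }
  }
  tree <- ape::keep.tip(tree, species)
  validate_tree(tree)
  tree
}
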