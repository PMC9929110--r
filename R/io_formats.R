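#' Default column schema for allometry tables
#'
#' Maps the logical fields of an individual-tree allometry table to the
#' column names expected in a CSV file. Override entries to read files
#' with different headers.
#'
#' @return Named list with entries `species`, `dbh`, `height`, `crown_r1`,
#'   `crown_r2`, `crown_radius`.
#' @export
default_allometry_schema <- function() {
  list(
    species      = "species",
    dbh          = "dbh_cm",
    height       = "height_m",
    crown_r1     = "crown_r1_m",
    crown_r2     = "crown_r2_m",
    crown_radius = "crown_radius_m"
  )
}

#' The six functional traits analysed by default
#'
#' @return Character vector of trait column names: leaf nitrogen (%),
#'   leaf phosphorus (%), wood density (g/cm^3), leaf area (cm^2),
#'   specific leaf area (cm^2/g) and seed mass (g).
#' @export
trait_names <- function() {
  c("leaf_pct_n", "leaf_pct_p", "wood_density", "leaf_area", "sla",
    "seed_mass")
}

#' Read an individual-tree allometry table
#'
#' One row per measured tree: species code, stem diameter at breast height
#' (DBH, cm), and optionally total height (m) and crown radius (m). The
#' crown radius may be supplied directly or as two perpendicular radii,
#' in which case their arithmetic mean is stored; a record with only one
#' of the two radii uses that radius alone. Height or crown may be missing
#' on a record: the record then only enters the model(s) for which its
#' response is present.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Column-name map, see [default_allometry_schema()].
#' @return A `data.frame` of class `allometry_data` with columns
#'   `species`, `dbh_cm`, `height_m`, `crown_radius_m` (the latter two
#'   possibly `NA`), rows in file order.
#' @export
read_allometry_csv <- function(path, schema = default_allometry_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (fld in c("species", "dbh")) {
    if (!schema[[fld]] %in% names(raw)) {
      stop("allometry file is missing mandatory column '", schema[[fld]], "'")
    }
  }
  crown <- rep(NA_real_, nrow(raw))
  if (schema$crown_radius %in% names(raw)) {
    crown <- as.numeric(raw[[schema$crown_radius]])
  } else {
    r1 <- if (schema$crown_r1 %in% names(raw)) as.numeric(raw[[schema$crown_r1]]) else rep(NA_real_, nrow(raw))
    r2 <- if (schema$crown_r2 %in% names(raw)) as.numeric(raw[[schema$crown_r2]]) else rep(NA_real_, nrow(raw))
    crown <- rowMeans(cbind(r1, r2), na.rm = TRUE)
    crown[is.nan(crown)] <- NA_real_
  }
  height <- if (schema$height %in% names(raw)) as.numeric(raw[[schema$height]]) else rep(NA_real_, nrow(raw))
  obs <- data.frame(
    species        = as.character(raw[[schema$species]]),
    dbh_cm         = as.numeric(raw[[schema$dbh]]),
    height_m       = height,
    crown_radius_m = crown,
    stringsAsFactors = FALSE
  )
  validate_allometry(obs)
}

#' Validate an allometry table
#'
#' Enforces the record-level invariants: non-empty species code, strictly
#' positive DBH, and strictly positive height / crown radius where present.
#' Every rejection names the offending row.
#'
#' @param obs Data frame with columns `species`, `dbh_cm`, `height_m`,
#'   `crown_radius_m`.
#' @return `obs`, classed as `allometry_data`, invisibly unchanged.
#' @export
validate_allometry <- function(obs) {
  need <- c("species", "dbh_cm", "height_m", "crown_radius_m")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("allometry table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(obs$species) | !nzchar(obs$species))
  if (length(bad)) stop("empty species code in row(s): ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(obs$dbh_cm) | obs$dbh_cm <= 0)
  if (length(bad)) stop("non-positive or missing DBH in row(s): ", paste(bad, collapse = ", "))
  bad <- which(!is.na(obs$height_m) & obs$height_m <= 0)
  if (length(bad)) stop("non-positive height in row(s): ", paste(bad, collapse = ", "))
  bad <- which(!is.na(obs$crown_radius_m) & obs$crown_radius_m <= 0)
  if (length(bad)) stop("non-positive crown radius in row(s): ", paste(bad, collapse = ", "))
  class(obs) <- unique(c("allometry_data", class(obs)))
  obs
}

#' Read a species-level functional trait table
#'
#' Expects a `species` column plus the six trait columns of
#' [trait_names()], exactly one row per species.
#'
#' @param path Path to a CSV file.
#' @param traits Trait column names (default the standard six).
#' @param positive Require all trait values to be strictly positive
#'   (the default; the six standard traits are physical quantities).
#' @return A `data.frame` of class `trait_table`.
#' @export
read_trait_csv <- function(path, traits = trait_names(), positive = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_traits(raw, traits = traits, positive = positive)
}

#' Validate a trait table
#'
#' @inheritParams read_trait_csv
#' @param tab Data frame with a `species` column and one column per trait.
#' @return `tab`, classed as `trait_table`.
#' @export
validate_traits <- function(tab, traits = trait_names(), positive = TRUE) {
  if (!"species" %in% names(tab)) stop("trait table is missing the 'species' column")
  miss <- setdiff(traits, names(tab))
  if (length(miss)) stop("trait table is missing trait column(s): ", paste(miss, collapse = ", "))
  dup <- unique(tab$species[duplicated(tab$species)])
  if (length(dup)) stop("duplicated species in trait table: ", paste(dup, collapse = ", "))
  for (tr in traits) {
    v <- tab[[tr]]
    bad <- tab$species[is.na(v) | !is.finite(v)]
    if (length(bad)) stop("missing value for trait '", tr, "' in species: ", paste(bad, collapse = ", "))
    if (positive) {
      bad <- tab$species[v <= 0]
      if (length(bad)) stop("non-positive value for trait '", tr, "' in species: ", paste(bad, collapse = ", "))
    }
  }
  tab <- tab[, c("species", traits)]
  class(tab) <- unique(c("trait_table", class(tab)))
  tab
}

#' Read a rooted, fully resolved phylogeny from a newick file
#'
#' The comparative analyses require a strictly binary rooted tree with
#' positive branch lengths whose tips are species codes.
#'
#' @param path Path to a newick file.
#' @return An [ape::read.tree()] `phylo` object, validated.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  validate_phylogeny(tree)
}

#' Validate a phylogeny for contrast-based analyses
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) {
    stop("tree contains polytomies; resolve them (e.g. with dated branch ",
         "length information) before computing contrasts")
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length <= 0)) {
    stop("all branch lengths must be positive")
  }
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  tree
}

#' Write the pipeline's result tables to CSV
#'
#' Writes each element of `results` (species parameter summaries, trait x
#' parameter correlation table, trait x reference-diameter correlation
#' table, WAIC table, ...) to `<name>.csv` in `out_dir` with a fixed
#' column order, so that a reread reproduces the written values.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory, created if absent.
#' @return Named character vector of file paths, invisibly.
#' @export
write_result_tables <- function(results, out_dir) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(results)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], path, row.names = FALSE)
    paths[nm] <- path
  }
  invisible(paths)
}
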