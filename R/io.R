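#' Read a cladogram from a Newick file
#'
#' Reads a rooted tree topology in Newick format. Polytomies are retained.
#' Branch lengths, if present in the file, are dropped with a warning because
#' a cladogram carries topology only; durations are assigned later by
#' time-calibration. Square-bracket comments are stripped and quoted labels
#' are accepted (museum taxon labels often contain spaces; spaces become
#' underscores, matching the usual phylogenetics convention).
#'
#' @param path path to a Newick file, or a literal Newick string.
#' @return An object of class `phylo` (see [ape::read.tree()]) without
#'   branch lengths.
#' @export
#' @examples
#' tr <- read_newick("(Preondactylus,(Dimorphodon,Anurognathus));")
read_newick <- function(path) {
  txt <- if (length(path) == 1L && !file.exists(path) && grepl("\\(", path)) {
    path
  } else {
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  txt <- strip_newick_comments(txt)
  txt <- normalise_quoted_labels(txt)
  check_newick_balance(txt)
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop_fmt("Newick parse failure in '%s'", substr(txt, 1, 60))
  if (any(duplicated(phy$tip.label)))
    stop_fmt("duplicate tip labels: %s",
             paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                   collapse = ", "))
  if (ape::Ntip(phy) < 2L) stop_fmt("a cladogram needs at least 2 tips")
  if (!is.null(phy$edge.length)) {
    warn_fmt("branch lengths present in Newick input were ignored (cladogram input carries topology only)")
    phy$edge.length <- NULL
  }
  phy
}

# first unbalanced or stray character, reported by position
check_newick_balance <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop_fmt("Newick parse error: unmatched ')' at character %d", i)
    }
  }
  if (depth > 0L)
    stop_fmt("Newick parse error: %d unclosed '(' (string ends at character %d)",
             depth, length(chars))
  invisible(TRUE)
}

strip_newick_comments <- function(txt) gsub("\\[[^]]*\\]", "", txt)

normalise_quoted_labels <- function(txt) {
  m <- gregexpr("'[^']*'", txt)[[1]]
  if (m[1] == -1L) return(txt)
  pieces <- regmatches(txt, gregexpr("'[^']*'", txt))[[1]]
  fixed <- gsub(" ", "_", substr(pieces, 2, nchar(pieces) - 1))
  regmatches(txt, gregexpr("'[^']*'", txt)) <- list(fixed)
  txt
}

#' Write a tree to a Newick file
#'
#' @param tree a `phylo` object, with or without branch lengths.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a skeletal measurement table
#'
#' Parses a CSV of per-taxon skeletal element lengths (mm). Expected columns
#' are `taxon` plus any of the element columns
#' (skull, mandible, rostrum, humerus, ulna, radius, mcIV, phIV1..phIV4),
#' and optionally `status` (adult/subadult/juvenile), `rescale_factor`
#' (ratio of the largest known individual to the measured one, >= 1),
#' `age_max` and `age_min` (Ma). Missing measurements are encoded as empty
#' cells or `NA`; any other non-numeric content is an error rather than a
#' silent missing value.
#'
#' @param path path to the CSV file.
#' @return A `data.frame` with one row per taxon, numeric element columns,
#'   `status` and `rescale_factor` filled with defaults where absent.
#' @export
read_measurements <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, strip.white = TRUE)
  if (!"taxon" %in% names(raw)) stop_fmt("measurement table needs a 'taxon' column")
  if (nrow(raw) == 0L) stop_fmt("measurement table is empty")
  if (any(duplicated(raw$taxon)))
    stop_fmt("duplicate taxa in measurement table: %s",
             paste(unique(raw$taxon[duplicated(raw$taxon)]), collapse = ", "))
  out <- data.frame(taxon = raw$taxon, stringsAsFactors = FALSE)

  num_col <- function(col, what) {
    x <- raw[[col]]
    x[x %in% c("", "NA")] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop_fmt("non-numeric %s '%s' for taxon %s", what, x[bad[1]], raw$taxon[bad[1]])
    v
  }
  for (el in element_columns()) {
    if (!el %in% names(raw)) { out[[el]] <- NA_real_; next }
    v <- num_col(el, paste0("length (", el, ")"))
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop_fmt("non-positive %s length (%g) for taxon %s", el, v[bad[1]], raw$taxon[bad[1]])
    out[[el]] <- v
  }

  if ("status" %in% names(raw)) {
    st <- tolower(raw$status)
    st[st %in% c("", "na")] <- "adult"
    bad <- setdiff(unique(st), valid_statuses())
    if (length(bad)) stop_fmt("unknown ontogenetic status: %s", paste(bad, collapse = ", "))
    out$status <- st
  } else {
    warn_fmt("no 'status' column; all taxa assumed adult")
    out$status <- "adult"
  }

  if ("rescale_factor" %in% names(raw)) {
    rf <- num_col("rescale_factor", "rescale_factor")
    rf[is.na(rf)] <- 1
    if (any(rf < 1)) stop_fmt("rescale_factor < 1 for taxon %s", raw$taxon[which(rf < 1)[1]])
    out$rescale_factor <- rf
  } else out$rescale_factor <- 1

  for (col in c("age_max", "age_min")) {
    if (col %in% names(raw)) out[[col]] <- num_col(col, col)
  }
  if (all(c("age_max", "age_min") %in% names(out))) {
    bad <- which(!is.na(out$age_max) & !is.na(out$age_min) &
                   out$age_max < out$age_min)
    if (length(bad))
      stop_fmt("age_max < age_min for taxon %s", out$taxon[bad[1]])
    if (any(stats::na.omit(out$age_min) < 0)) stop_fmt("negative age_min")
  }
  out
}

#' Write a measurement table to CSV
#' @param table a measurement table as returned by [read_measurements()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a stratigraphic age table
#'
#' CSV with columns `taxon`, `age_max`, `age_min` (Ma before present,
#' `age_max >= age_min >= 0`).
#'
#' @param path path to the CSV file.
#' @return A `data.frame` with columns `taxon`, `age_max`, `age_min`.
#' @export
read_ages <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "age_max", "age_min")
  if (!all(need %in% names(df)))
    stop_fmt("age table needs columns: %s", paste(need, collapse = ", "))
  if (any(duplicated(df$taxon))) stop_fmt("duplicate taxa in age table")
  df$age_max <- as.numeric(df$age_max)
  df$age_min <- as.numeric(df$age_min)
  if (any(is.na(df$age_max) | is.na(df$age_min)))
    stop_fmt("non-numeric ages in age table")
  bad <- which(df$age_max < df$age_min)
  if (length(bad)) stop_fmt("age_max < age_min for taxon %s", df$taxon[bad[1]])
  if (any(df$age_min < 0)) stop_fmt("negative age_min in age table")
  df[need]
}

#' Write a stratigraphic age table
#' @param ages data.frame with `taxon`, `age_max`, `age_min`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ages <- function(ages, path) {
  utils::write.csv(ages[c("taxon", "age_max", "age_min")], path, row.names = FALSE)
  invisible(path)
}

#' Read / write a trait vector
#'
#' A trait vector holds one row per taxon: `value` (log10 wingspan in
#' metres), `se` (standard error on the same scale, 0 for directly summed
#' wingspans) and `provenance` (`"measured"` or `"estimated:<predictor>"`).
#'
#' @param path CSV path.
#' @return `read_traits`: a trait-vector `data.frame`.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "value", "se", "provenance")
  if (!all(need %in% names(df)))
    stop_fmt("trait table needs columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(df$value))) stop_fmt("non-finite trait values")
  if (any(df$se < 0)) stop_fmt("negative trait standard errors")
  df[need]
}

#' @rdname read_traits
#' @param traits a trait-vector `data.frame`.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits[c("taxon", "value", "se", "provenance")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a bundled geological stage age lookup
#'
#' Returns the small stage -> numeric age table shipped with the package
#' (editable CSV under `extdata/`), used to turn stage-level stratigraphic
#' assignments into numeric `age_max`/`age_min` bounds.
#'
#' @param path optional path to an alternative lookup CSV.
#' @return data.frame with columns `stage`, `age_max`, `age_min` (Ma).
#' @export
read_stage_ages <- function(path = NULL) {
  path <- path %||% system.file("extdata", "stage_ages.csv", package = "pterotrend")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("stage", "age_max", "age_min") %in% names(df)))
  df
}

#' Write fit results to JSON
#'
#' @param x a list of fit summaries (e.g. from [run_pipeline()]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration (YAML or JSON)
#' @param path path to a YAML or JSON configuration file.
#' @return a configuration list (see [pipeline_config()]).
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}
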