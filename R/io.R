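# File formats: strain-by-trait CSV tables (supplementary-table shaped),
# per-embryo trajectory CSVs with a commented metadata header, and YAML run
# configurations. CSV dialect: comma-separated, UTF-8, "." decimal, with a
# locale-comma fallback for spreadsheet exports.

#' Read a strain-by-trait table
#'
#' Expects a CSV with a header and a `species` column; trait columns are
#' matched against [trait_names()] (optionally through `column_map`). Cells
#' left blank are read as missing and reported, rows are retained. Files
#' exported with a decimal comma are detected and re-read.
#'
#' @param path CSV path.
#' @param column_map Optional named character vector mapping file column
#'   names to canonical trait names (`c(file_col = "canonical_name")`).
#' @return Data frame; attributes `missing_report` (per-column NA counts for
#'   trait columns) and `species_counts` (strains per species).
#' @export
read_trait_table <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  # spreadsheet exports in a decimal-comma locale: ';' separator and/or
  # comma decimals in otherwise numeric columns
  semicolon_header <- !"species" %in% names(df) && any(grepl(";", names(df)))
  chr_cols <- setdiff(names(df)[vapply(df, is.character, logical(1))],
                      c("species", "strain"))
  decimal_comma <- length(chr_cols) &&
    any(vapply(chr_cols,
               function(cl) any(grepl("^-?[0-9]+,[0-9]+$", df[[cl]])),
               logical(1)))
  if (semicolon_header || decimal_comma) {
    df <- utils::read.csv2(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- column_map[names(df)[hit]]
  }
  if (!"species" %in% names(df)) {
    stop("trait table must contain a 'species' column", call. = FALSE)
  }
  known <- c("species", "strain", "embryo", "qc_flags", trait_names(),
             "climate", "reproductive_mode")
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warning("unknown column(s) kept as-is: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  tr_cols <- intersect(trait_names(), names(df))
  for (cl in tr_cols) df[[cl]] <- as.numeric(df[[cl]])
  attr(df, "missing_report") <- vapply(df[tr_cols],
                                       function(v) sum(is.na(v)), integer(1))
  attr(df, "species_counts") <- table(df$species)
  df
}

#' Write a strain-by-trait table
#' @param df Data frame.
#' @param path Output CSV path.
#' @export
write_trait_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write one embryo recording as a trajectory CSV
#'
#' Metadata (labels, cell geometry, NEB frame, coordinate convention) is
#' stored in `#`-prefixed header lines; the data columns are `time_s`,
#' `ant_x_um`, `ant_y_um`, `post_x_um`, `post_y_um`.
#'
#' @param rec An `"embryo_recording"`.
#' @param path Output CSV path.
#' @export
write_trajectory_csv <- function(rec, path) {
  hdr <- c(
    "# nemaspindle trajectory v1",
    "# coordinates: x antero/posterior (origin cell center, + posterior); y transverse (origin cell equator); um; t=0 at NEB",
    sprintf("# strain: %s", rec$strain),
    sprintf("# species: %s", rec$species),
    sprintf("# cell_length_um: %.6g", rec$cell_length),
    sprintf("# cell_width_um: %.6g", rec$cell_width),
    sprintf("# ab_length_um: %.6g", rec$ab_length),
    sprintf("# p1_length_um: %.6g", rec$p1_length),
    sprintf("# neb_frame: %d", rec$neb_frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(time_s = rec$time,
                              ant_x_um = rec$ant[, "x"],
                              ant_y_um = rec$ant[, "y"],
                              post_x_um = rec$post[, "x"],
                              post_y_um = rec$post[, "y"]),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#' @param path CSV path.
#' @return An `"embryo_recording"`.
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, as = as.numeric) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop("missing metadata field '", key, "' in ", path,
                          call. = FALSE)
    as(sub(paste0("^# ", key, ": "), "", ln[1L]))
  }
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                     collapse = "\n"))
  embryo_recording(df$time_s,
                   ant = cbind(x = df$ant_x_um, y = df$ant_y_um),
                   post = cbind(x = df$post_x_um, y = df$post_y_um),
                   cell_length = meta("cell_length_um"),
                   cell_width = meta("cell_width_um"),
                   ab_length = meta("ab_length_um"),
                   p1_length = meta("p1_length_um"),
                   neb_frame = meta("neb_frame", as = as.integer),
                   strain = meta("strain", as = identity),
                   species = meta("species", as = identity))
}

#' Serialize a run or generator configuration to YAML
#' @param config A list (e.g. a `"generator_config"`); the `tree` element is
#'   stored as Newick.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$tree)) cfg$tree <- ape::write.tree(cfg$tree)
  # YAML drops names on atomic vectors; store them as maps
  cfg <- lapply(cfg, function(el) {
    if (is.atomic(el) && !is.null(names(el))) as.list(el) else el
  })
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a YAML run configuration
#' @param path YAML path.
#' @return A list; a `tree` entry is parsed back from Newick.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$tree)) cfg$tree <- parse_newick(cfg$tree)
  if (!is.null(cfg$base_traits) && !is.null(cfg$trait_models)) {
    # restore a generator configuration to its native types
    for (f in c("sigma_strain", "sigma_embryo")) cfg[[f]] <- unlist(cfg[[f]])
    cfg$bounds <- lapply(cfg$bounds, unlist)
    cfg$base_traits <- as.character(unlist(cfg$base_traits))
    class(cfg) <- "generator_config"
  }
  cfg
}

#' Export ancestral states as a node table
#'
#' Tab-separated `node`, `height`, `state` table consumable for plotting a
#' continuous trait map on the tree.
#'
#' @param anc Result of [ancestral_states_bm()].
#' @param path Output path.
#' @export
write_ancestral_table <- function(anc, path) {
  utils::write.table(anc$export, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
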