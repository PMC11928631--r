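# File formats: per-well amplitude CSV (QuantaSoft-dialect: one row per
# droplet, columns "Ch1 Amplitude" / "Ch2 Amplitude"), plate manifest CSV,
# flat key = value config files, and whole-plate read/write.

#' Read a per-well amplitude CSV
#'
#' Expects columns `Ch1 Amplitude` and `Ch2 Amplitude` (one row per
#' droplet); extra columns are preserved (a `Cluster` column, if present,
#' is kept as the ground-truth quadrant).
#'
#' @param path CSV path.
#' @param well_id Well id; defaults to the file stem.
#' @param role,group_id Well metadata.
#' @return A [well_data()].
#' @export
read_amplitude_csv <- function(path, well_id = NULL, role = "sample",
                               group_id = NULL) {
  if (is.null(well_id))
    well_id <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  if (is.null(group_id)) group_id <- well_id
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("Ch1 Amplitude", "Ch2 Amplitude")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      stop("non-numeric amplitude in '", path, "', column '", col,
           "', row ", if (length(bad) > 0) bad[1] else "unknown")
    }
  }
  droplets <- data.frame(ch1 = df[["Ch1 Amplitude"]],
                         ch2 = df[["Ch2 Amplitude"]])
  extra <- setdiff(names(df), need)
  for (col in extra) droplets[[tolower(col)]] <- df[[col]]
  well_data(well_id, role, droplets, group_id = group_id)
}

#' Write a per-well amplitude CSV
#'
#' @param well A [well_data()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplitude_csv <- function(well, path) {
  stopifnot(inherits(well, "well_data"))
  out <- data.frame(check.names = FALSE,
                    `Ch1 Amplitude` = well$droplets$ch1,
                    `Ch2 Amplitude` = well$droplets$ch2)
  if (!is.null(well$droplets$cluster))
    out$Cluster <- well$droplets$cluster
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a plate manifest CSV
#'
#' Required columns: `well`, `sample_id`, `role`, `group`, `dilution`,
#' `replicate`, `cells_per_well`. Roles are validated against
#' sample/ntc/clc/dna_control; duplicate well ids are rejected.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_plate_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("well", "sample_id", "role", "group", "dilution",
                "replicate", "cells_per_well")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("manifest '", path, "' missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$well))
    stop("duplicate well id(s) in manifest: ",
         paste(unique(df$well[duplicated(df$well)]), collapse = ", "))
  bad <- setdiff(df$role, VALID_ROLES)
  if (length(bad) > 0)
    stop("unknown role(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(VALID_ROLES, collapse = ", "))
  df
}

#' Write a plate (amplitude CSVs + manifest) to a directory
#'
#' @param plate A [plate_data()].
#' @param dir Output directory (created if needed); one `<well>.csv` per
#'   well plus `manifest.csv`.
#' @return `dir`, invisibly.
#' @export
write_plate <- function(plate, dir) {
  stopifnot(inherits(plate, "plate_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (w in plate$wells)
    write_amplitude_csv(w, file.path(dir, paste0(w$well_id, ".csv")))
  utils::write.csv(plate$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a plate from a directory written by [write_plate()]
#'
#' @param dir Directory containing `manifest.csv` and one amplitude CSV
#'   per well.
#' @return A [plate_data()].
#' @export
read_plate <- function(dir) {
  manifest <- read_plate_manifest(file.path(dir, "manifest.csv"))
  wells <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    f <- file.path(dir, paste0(row$well, ".csv"))
    if (!file.exists(f)) stop("missing amplitude file for well ", row$well)
    read_amplitude_csv(f, well_id = row$well, role = row$role,
                       group_id = row$group)
  })
  plate_data(wells, manifest)
}

#' Write a flat key = value config file
#'
#' One `key = value` line per scalar field (TOML-style flat table); list
#' fields are flattened as `parent.child`.
#'
#' @param x A named list (e.g. a [sim_config()] or [run_config()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flat_config <- function(x, path) {
  lines <- character(0)
  emit <- function(prefix, val) {
    for (nm in names(val)) {
      v <- val[[nm]]
      key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
      if (is.list(v)) emit(key, v)
      else if (length(v) == 1)
        lines <<- c(lines, sprintf("%s = %s", key, format(v, digits = 15)))
      else
        lines <<- c(lines, sprintf("%s = %s", key,
                                   paste(format(v, digits = 15),
                                         collapse = ", ")))
    }
  }
  emit("", unclass(x))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key = value config file
#'
#' Inverse of [write_flat_config()]: values that parse as numbers become
#' numeric, comma-separated values become vectors, dotted keys become
#' nested lists.
#'
#' @param path Config path.
#' @return A named list.
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed config line: ", ln)
    key <- trimws(parts[1])
    raw <- trimws(paste(parts[-1], collapse = "="))
    vals <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    val <- if (all(!is.na(num))) num else vals
    keys <- strsplit(key, ".", fixed = TRUE)[[1]]
    out <- assign_nested(out, keys, val)
  }
  out
}

assign_nested <- function(lst, keys, val) {
  if (length(keys) == 1) {
    lst[[keys]] <- val
    return(lst)
  }
  sub <- lst[[keys[1]]]
  if (is.null(sub) || !is.list(sub)) sub <- list()
  lst[[keys[1]]] <- assign_nested(sub, keys[-1], val)
  lst
}

#' Reference intra-assay replicate panel
#'
#' Published replicate measurements (TREC copies per reaction) for eight
#' crude-lysate samples measured in triplicate, used to validate the CV
#' computations against their printed per-sample CVs and grand mean.
#'
#' @return A named list of numeric triplicate vectors, ordered as printed
#'   (four biological samples, then four dilution levels in decreasing
#'   concentration).
#' @export
intra_assay_replicates <- function() {
  path <- system.file("extdata", "trec_intra_assay_replicates.csv",
                      package = "dropletquant", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)),
                function(i) as.numeric(df[i, c("rep1", "rep2", "rep3")]))
  stats::setNames(out, df$sample)
}
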