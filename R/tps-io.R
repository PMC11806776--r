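#' Read a TPS landmark file (tpsDig dialect)
#'
#' Parses `LM=`, coordinate lines (one `x y` pair per line), `ID=`, `IMAGE=`
#' and `SCALE=` keys.  Keys are matched case-insensitively and CRLF line
#' endings are accepted.  Coordinates are multiplied by `SCALE` when present,
#' so the returned values are in image units.  `CURVES`/`POINTS` blocks are
#' skipped with a warning.  All records must share the same landmark count.
#'
#' Coordinates are kept exactly as digitized (x right, y up, arbitrary
#' origin); no image-row inversion is applied -- superimposition removes the
#' convention anyway, but wireframe plots inherit it.
#'
#' @param path Path to a TPS file.
#' @return A landmark table with columns `id`, `image_file` (when present)
#'   and `x1..xk, y1..yk`.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) abort(sprintf("TPS file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  recs <- list()
  i <- 1L
  n_lines <- length(lines)
  skipped_curves <- FALSE
  while (i <= n_lines) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    m <- regmatches(line, regexec("^[Ll][Mm]=\\s*([0-9]+)\\s*$", line))[[1]]
    if (length(m) == 0) {
      abort(sprintf("Expected 'LM=<count>' at line %d of %s, found: '%s'", i, path, line))
    }
    k <- as.integer(m[2])
    if (k < 3L) abort(sprintf("Record at line %d has LM=%d; need at least 3 landmarks.", i, k))
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      if (i > n_lines) abort(sprintf("File ends before %d coordinate lines were read.", k))
      parts <- strsplit(trimws(lines[i]), "[\\s,]+", perl = TRUE)[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2L || any(is.na(vals))) {
        abort(sprintf("Non-numeric or malformed coordinate line %d: '%s'", i, lines[i]))
      }
      coords[j, ] <- vals
      i <- i + 1L
    }
    id <- NA_character_; image <- NA_character_; scl <- NA_real_
    while (i <= n_lines) {
      line <- trimws(lines[i])
      if (line == "") { i <- i + 1L; next }
      if (grepl("^[Ll][Mm]=", line)) break
      if (grepl("^[Cc][Uu][Rr][Vv][Ee][Ss]=", line) || grepl("^[Pp][Oo][Ii][Nn][Tt][Ss]=", line)) {
        skipped_curves <- TRUE
        i <- i + 1L
        while (i <= n_lines &&
               !grepl("^[A-Za-z]+=", trimws(lines[i])) &&
               trimws(lines[i]) != "") i <- i + 1L
        next
      }
      kv <- regmatches(line, regexec("^([A-Za-z]+)=(.*)$", line))[[1]]
      if (length(kv) == 0) {
        # a bare coordinate line here means the LM count was wrong
        abort(sprintf("Unexpected line %d ('%s'): more coordinate lines than LM= declares?", i, line))
      }
      key <- toupper(kv[2]); val <- trimws(kv[3])
      if (key == "ID") id <- val
      if (key == "IMAGE") image <- val
      if (key == "SCALE") {
        scl <- suppressWarnings(as.numeric(val))
        if (is.na(scl)) abort(sprintf("Non-numeric SCALE at line %d.", i))
      }
      i <- i + 1L
    }
    if (!is.na(scl)) coords <- coords * scl
    recs[[length(recs) + 1L]] <- list(coords = coords, id = id, image = image)
  }
  if (skipped_curves) warn("CURVES/POINTS blocks present in TPS file were skipped.")
  if (length(recs) == 0) {
    return(tibble::tibble(id = character(), image_file = character()))
  }
  ks <- vapply(recs, function(r) nrow(r$coords), 0L)
  if (length(unique(ks)) != 1L) {
    abort(sprintf("Records disagree on landmark count: %s", paste(unique(ks), collapse = ", ")))
  }
  ids <- vapply(recs, function(r) r$id, "")
  ids[is.na(ids)] <- sprintf("rec%04d", which(is.na(ids)))
  meta <- tibble::tibble(
    id = ids,
    image_file = vapply(recs, function(r) r$image, "")
  )
  as_landmark_tbl(lapply(recs, `[[`, "coords"), meta)
}

#' Write a landmark table to a TPS file (tpsDig dialect)
#'
#' One record per row: `LM=`, the coordinate lines (full precision), then
#' `IMAGE=` (when an `image_file` column is present and non-missing) and
#' `ID=`.  No `SCALE=` line is written: coordinates are already in final
#' units.  Field order is fixed so output is deterministic and round-trips
#' through [read_tps()].
#'
#' @param data Landmark table; row identity taken from an `id` column when
#'   present, otherwise `rec0001`-style ids are generated.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tps <- function(data, path) {
  n <- nrow(data)
  if (n == 0) { writeLines(character(), path); return(invisible(path)) }
  k <- landmark_count(data)
  m <- coord_matrix(data)
  ids <- if ("id" %in% names(data)) as.character(data$id) else sprintf("rec%04d", seq_len(n))
  imgs <- if ("image_file" %in% names(data)) as.character(data$image_file) else rep(NA_character_, n)
  out <- character(0)
  for (i in seq_len(n)) {
    cfg <- unflatten_config(m[i, ])
    out <- c(out, sprintf("LM=%d", k),
             sprintf("%.12g %.12g", cfg[, 1], cfg[, 2]))
    if (!is.na(imgs[i]) && nzchar(imgs[i])) out <- c(out, sprintf("IMAGE=%s", imgs[i]))
    out <- c(out, sprintf("ID=%s", ids[i]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Attach classifier metadata to a landmark table
#'
#' Joins a classifier table -- columns `id` (matching the TPS record ids),
#' `specimen_id`, `population`, `sex`, `image_id`, `digitization_id` -- to
#' the configurations by exact id string.  Every configuration must have
#' exactly one classifier row; classifier rows without a matching
#' configuration are ignored with a warning.
#'
#' @param data Landmark table with an `id` column.
#' @param table Data frame, or path to a CSV file, of classifiers.
#' @return The landmark table with classifier columns added.
#' @export
attach_classifiers <- function(data, table) {
  if (is.character(table)) table <- readr::read_csv(table, show_col_types = FALSE)
  table <- tibble::as_tibble(table)
  if (!"id" %in% names(table)) abort("Classifier table needs an 'id' column.")
  if (!"id" %in% names(data)) abort("Landmark table needs an 'id' column to join on.")
  dup <- table$id[duplicated(table$id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicated id(s) in classifier table: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  missing <- setdiff(data$id, table$id)
  if (length(missing) > 0) {
    abort(sprintf("No classifier row for id(s): %s", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(table$id, data$id)
  if (length(extra) > 0) {
    warn(sprintf("%d classifier row(s) without configurations were ignored.", length(extra)))
  }
  dplyr::left_join(data, table, by = "id")
}

#' Write the classifier table of a landmark table to CSV
#'
#' @param data Landmark table containing classifier columns.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_classifiers <- function(data, path) {
  cols <- intersect(
    c("id", "specimen_id", "population", "sex", "image_id", "digitization_id"),
    names(data)
  )
  readr::write_csv(data[cols], path)
  invisible(path)
}
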