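#' Read a titration peak table
#'
#' Two CSV dialects are supported. `long_csv` has one row per (point, residue)
#' with the columns `point_index, protein_total_uM, ligand_total_uM,
#' residue_id, residue_name, delta_H_ppm, delta_N_ppm, quality` (the last is
#' optional on input). `wide_csv` has one row per residue with column pairs
#' `dH_<i>, dN_<i>` (and optional `q_<i>`) per titration point; the point
#' concentrations live in `#! point:` header lines. In both dialects
#' `#! meta <key>: <value>` header lines carry dataset metadata. Rows whose
#' shifts cannot be parsed are kept with `quality = "missing"`.
#'
#' An optional `#! units: mM` header declares that concentrations are in
#' millimolar; they are converted to the package-wide micromolar convention
#' on read.
#'
#' @param source File path, or the table itself as a string / character
#'   vector of lines.
#' @param dialect `"long_csv"` (default) or `"wide_csv"`.
#' @return A validated [as_titration_data()] tibble.
#' @seealso [write_peak_table()]
#' @export
read_peak_table <- function(source, dialect = c("long_csv", "wide_csv")) {
  dialect <- match.arg(dialect)
  lines <- .as_lines(source)
  is_meta <- startsWith(lines, "#!")
  meta_lines <- lines[is_meta]
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 2) abort("peak table has no data rows")
  meta <- .parse_meta(meta_lines)
  unit_scale <- 1
  if (!is.null(meta$units$units)) {
    unit_scale <- switch(tolower(meta$units$units),
      "um" = 1, "µm" = 1, "mm" = 1000,
      abort(paste0("unknown concentration units: ", meta$units$units))
    )
  }
  if (dialect == "long_csv") {
    ds <- .read_long(body, unit_scale)
  } else {
    ds <- .read_wide(body, meta$points, unit_scale)
  }
  as_titration_data(ds, metadata = meta$meta)
}

# parse "#! meta key: value", "#! units: uM" and
# "#! point: <idx> protein_total_uM=<x> ligand_total_uM=<y>" header lines
.parse_meta <- function(meta_lines) {
  meta <- list(); points <- list(); units <- list()
  for (ln in meta_lines) {
    payload <- trimws(sub("^#!", "", ln))
    if (startsWith(payload, "meta ")) {
      kv <- sub("^meta ", "", payload)
      key <- trimws(sub(":.*$", "", kv))
      val <- trimws(sub("^[^:]*:", "", kv))
      meta[[key]] <- val
    } else if (startsWith(payload, "units:")) {
      units$units <- trimws(sub("^units:", "", payload))
    } else if (startsWith(payload, "point:")) {
      fields <- strsplit(trimws(sub("^point:", "", payload)), "[[:space:]]+")[[1]]
      idx <- as.integer(fields[1])
      kv <- strsplit(fields[-1], "=", fixed = TRUE)
      vals <- setNames(
        vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
        vapply(kv, function(p) p[1], character(1))
      )
      points[[length(points) + 1L]] <- c(point_index = idx, vals)
    }
  }
  list(meta = meta, points = points, units = units)
}

.read_long <- function(body, unit_scale) {
  tab <- readr::read_csv(
    I(paste(body, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- setdiff(.long_columns, c("residue_name", "quality"))
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("long_csv peak table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"quality" %in% names(tab)) tab$quality <- "ok"
  if (!"residue_name" %in% names(tab)) tab$residue_name <- ""
  dH <- suppressWarnings(as.numeric(tab$delta_H_ppm))
  dN <- suppressWarnings(as.numeric(tab$delta_N_ppm))
  quality <- tab$quality
  quality[is.na(quality) | !nzchar(quality)] <- "ok"
  unparseable <- (is.na(dH) | is.na(dN)) & quality == "ok"
  quality[unparseable] <- "missing"
  tibble(
    point_index = as.integer(tab$point_index),
    protein_total_uM = as.numeric(tab$protein_total_uM) * unit_scale,
    ligand_total_uM = as.numeric(tab$ligand_total_uM) * unit_scale,
    residue_id = as.integer(tab$residue_id),
    residue_name = dplyr::coalesce(tab$residue_name, ""),
    delta_H_ppm = dH, delta_N_ppm = dN, quality = quality
  )
}

.read_wide <- function(body, points, unit_scale) {
  if (length(points) == 0) {
    abort("wide_csv peak table lacks '#! point:' header lines with concentrations")
  }
  tab <- readr::read_csv(
    I(paste(body, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!"residue_id" %in% names(tab)) {
    abort("wide_csv peak table is missing required column(s): residue_id")
  }
  if (!"residue_name" %in% names(tab)) tab$residue_name <- ""
  pts <- bind_rows(lapply(points, function(p) as_tibble(as.list(p))))
  for (col in c("protein_total_uM", "ligand_total_uM")) {
    if (!col %in% names(pts)) {
      abort(paste0("wide_csv '#! point:' headers are missing ", col))
    }
  }
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    idx <- pts$point_index[i]
    hcol <- paste0("dH_", idx); ncol_ <- paste0("dN_", idx)
    qcol <- paste0("q_", idx)
    if (!hcol %in% names(tab) || !ncol_ %in% names(tab)) {
      abort(paste0("wide_csv peak table is missing column(s) ", hcol, "/", ncol_))
    }
    dH <- suppressWarnings(as.numeric(tab[[hcol]]))
    dN <- suppressWarnings(as.numeric(tab[[ncol_]]))
    quality <- if (qcol %in% names(tab)) tab[[qcol]] else rep("ok", nrow(tab))
    quality[is.na(quality) | !nzchar(quality)] <- "ok"
    quality[(is.na(dH) | is.na(dN)) & quality == "ok"] <- "missing"
    tibble(
      point_index = as.integer(idx),
      protein_total_uM = pts$protein_total_uM[i] * unit_scale,
      ligand_total_uM = pts$ligand_total_uM[i] * unit_scale,
      residue_id = as.integer(tab$residue_id),
      residue_name = dplyr::coalesce(tab$residue_name, ""),
      delta_H_ppm = dH, delta_N_ppm = dN, quality = quality
    )
  })
  bind_rows(rows)
}

#' Write a titration peak table
#'
#' Serializes a titration dataset to one of the two CSV dialects understood by
#' [read_peak_table()]. Doubles are written with 17 significant digits, so
#' `read_peak_table(write_peak_table(d))` reproduces `d` field for field.
#'
#' @param dataset A `titration_data` tibble.
#' @param dialect `"long_csv"` or `"wide_csv"`.
#' @param path Optional file path; when given the text is also written there.
#' @return The serialized table as a single string (invisibly when `path`
#'   is given).
#' @export
write_peak_table <- function(dataset, dialect = c("long_csv", "wide_csv"),
                             path = NULL) {
  dialect <- match.arg(dialect)
  validate_titration_data(dataset)
  meta <- titration_metadata(dataset)
  meta_lines <- if (length(meta) > 0) {
    paste0("#! meta ", names(meta), ": ", unlist(meta))
  } else {
    character(0)
  }
  if (dialect == "long_csv") {
    rows <- paste(
      dataset$point_index,
      .fmt_num(dataset$protein_total_uM),
      .fmt_num(dataset$ligand_total_uM),
      dataset$residue_id,
      dataset$residue_name,
      .fmt_num(dataset$delta_H_ppm),
      .fmt_num(dataset$delta_N_ppm),
      dataset$quality,
      sep = ","
    )
    lines <- c(meta_lines, paste(.long_columns, collapse = ","), rows)
  } else {
    pts <- titration_points(dataset)
    point_lines <- sprintf(
      "#! point: %d protein_total_uM=%s ligand_total_uM=%s",
      pts$point_index, .fmt_num(pts$protein_total_uM),
      .fmt_num(pts$ligand_total_uM)
    )
    wide <- dataset |>
      select("point_index", "residue_id", "residue_name",
             "delta_H_ppm", "delta_N_ppm", "quality") |>
      tidyr::pivot_wider(
        names_from = "point_index",
        values_from = c("delta_H_ppm", "delta_N_ppm", "quality")
      ) |>
      dplyr::rename_with(
        ~sub("^quality_", "q_", sub("^delta_N_ppm_", "dN_",
                                    sub("^delta_H_ppm_", "dH_", .x)))
      )
    cols <- c("residue_id", "residue_name",
              as.vector(t(outer(c("dH_", "dN_", "q_"), pts$point_index,
                                paste0))))
    wide <- wide[cols]
    cells <- vapply(cols, function(cn) {
      v <- wide[[cn]]
      if (is.numeric(v)) .fmt_num(v) else as.character(v)
    }, character(nrow(wide)))
    if (nrow(wide) == 1L) cells <- matrix(cells, nrow = 1)
    rows <- apply(cells, 1, paste, collapse = ",")
    lines <- c(meta_lines, point_lines, paste(cols, collapse = ","), rows)
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Map per-residue values onto a structure via the B-factor column
#'
#' Replaces the B-factor (temperature factor) column of a PDB file with
#' per-residue values, the standard trick for coloring a binding surface by
#' chemical-shift perturbation in molecular viewers. Only columns 61-66 of
#' `ATOM`/`HETATM` records are touched; every other byte of the file is
#' preserved. Residues absent from `per_residue_values` get 0.
#'
#' @param per_residue_values Named numeric vector (names are residue sequence
#'   numbers) or a data frame with columns `residue_id` and `value`.
#' @param pdb_in PDB file path, or its contents as a string / character
#'   vector of lines.
#' @param scale `"raw"` writes the values as given; `"percentile"` maps them
#'   to 0-100 by rank, `(rank - 1) / (n - 1) * 100`.
#' @param path Optional output file path.
#' @return The modified PDB as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
write_structure_mapping <- function(per_residue_values, pdb_in,
                                    scale = c("raw", "percentile"),
                                    path = NULL) {
  scale <- match.arg(scale)
  if (is.data.frame(per_residue_values)) {
    per_residue_values <- setNames(per_residue_values$value,
                                   per_residue_values$residue_id)
  }
  if (length(per_residue_values) == 0) {
    abort("per_residue_values is empty: nothing to map")
  }
  vals <- as.numeric(per_residue_values)
  ids <- as.integer(names(per_residue_values))
  if (anyNA(ids)) abort("per_residue_values must be named by residue number")
  if (scale == "percentile") {
    n <- length(vals)
    vals <- if (n == 1L) 100 else (rank(vals, ties.method = "average") - 1) /
      (n - 1) * 100
  }
  lines <- .as_lines(pdb_in)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) abort("pdb_in contains no ATOM/HETATM records")
  atom_lines <- lines[is_atom]
  # resSeq lives in columns 23-26 of a PDB coordinate record
  resseq <- suppressWarnings(as.integer(trimws(substr(atom_lines, 23, 26))))
  if (length(intersect(resseq, ids)) == 0) {
    abort("no residue overlap between per_residue_values and the PDB")
  }
  b <- vals[match(resseq, ids)]
  b[is.na(b)] <- 0
  bfield <- sprintf("%6.2f", b)
  wide <- nchar(bfield) > 6
  bfield[wide] <- sprintf("%6.1f", b[wide])
  bfield[nchar(bfield) > 6] <- sprintf("%6.0f", b[nchar(bfield) > 6])
  pad <- nchar(atom_lines) < 66
  atom_lines[pad] <- formatC(atom_lines[pad], width = -66)
  substr(atom_lines, 61, 66) <- bfield
  lines[is_atom] <- atom_lines
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
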