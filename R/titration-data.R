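#' Assemble and validate a titration dataset
#'
#' A titration dataset is a long tibble with one row per (titration point,
#' residue): columns `point_index`, `protein_total_uM`, `ligand_total_uM`,
#' `residue_id`, `residue_name`, `delta_H_ppm`, `delta_N_ppm`, `quality`.
#' The first point must be the apo reference (`ligand_total_uM == 0`), points
#' are strictly ordered by total ligand concentration, and every residue seen
#' at the reference carries a quality flag (`"ok"`, `"overlapped"` or
#' `"missing"`) at every point. All concentrations are in micromolar and all
#' shifts in ppm.
#'
#' @param x A data frame with the columns above (`residue_name` and `quality`
#'   may be omitted; they default to `""` and `"ok"`).
#' @param metadata Named list of free-text metadata (ligand name, temperature,
#'   buffer, ...), stored as an attribute and round-tripped by the writers.
#' @return A validated `titration_data` tibble.
#' @examples
#' pts <- tibble::tibble(
#'   point_index = rep(1:2, each = 2),
#'   protein_total_uM = 270, ligand_total_uM = rep(c(0, 100), each = 2),
#'   residue_id = rep(c(158L, 160L), 2), residue_name = rep(c("HIS", "ASN"), 2),
#'   delta_H_ppm = c(8.1, 7.9, 8.15, 7.91), delta_N_ppm = c(118, 121, 118.4, 121.1)
#' )
#' as_titration_data(pts, metadata = list(ligand = "SeDG"))
#' @export
as_titration_data <- function(x, metadata = list()) {
  x <- as_tibble(x)
  if (!"residue_name" %in% names(x)) x$residue_name <- ""
  if (!"quality" %in% names(x)) x$quality <- "ok"
  missing_cols <- setdiff(.long_columns, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "titration table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- x[.long_columns]
  x$point_index <- as.integer(x$point_index)
  x$residue_id <- as.integer(x$residue_id)
  x$residue_name <- as.character(x$residue_name)
  x$quality <- as.character(x$quality)
  for (col in c("protein_total_uM", "ligand_total_uM",
                "delta_H_ppm", "delta_N_ppm")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  x <- arrange(x, .data$point_index, .data$residue_id)
  out <- structure(x, metadata = metadata,
                   class = c("titration_data", class(tibble())))
  validate_titration_data(out)
  out
}

#' Validate the invariants of a titration dataset
#'
#' Checks concentrations, point ordering, the presence of the apo reference,
#' residue uniqueness within points, residue coverage across points, quality
#' flags, and (for `quality == "ok"` rows) plausible amide shift ranges
#' (delta_H in \[-2, 15\] ppm, delta_N in \[90, 140\] ppm).
#'
#' @param x A `titration_data` tibble (or coercible data frame).
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_titration_data <- function(x) {
  if (!all(.long_columns %in% names(x))) {
    abort(paste0("titration table is missing required column(s): ",
                 paste(setdiff(.long_columns, names(x)), collapse = ", ")))
  }
  bad_q <- setdiff(unique(x$quality), .quality_levels)
  if (length(bad_q) > 0) {
    abort(paste0("unknown quality flag(s): ", paste(bad_q, collapse = ", ")))
  }
  pts <- distinct(x, .data$point_index, .data$protein_total_uM,
                  .data$ligand_total_uM)
  if (anyDuplicated(pts$point_index) > 0) {
    abort("a point_index maps to more than one concentration pair")
  }
  pts <- arrange(pts, .data$point_index)
  if (any(!is.finite(pts$protein_total_uM)) || any(pts$protein_total_uM <= 0)) {
    abort("protein_total_uM must be finite and > 0 at every point")
  }
  if (any(!is.finite(pts$ligand_total_uM)) || any(pts$ligand_total_uM < 0)) {
    abort("ligand_total_uM must be finite and >= 0 at every point")
  }
  if (pts$ligand_total_uM[1] != 0) {
    abort("missing apo reference: the first titration point must have ligand_total_uM = 0")
  }
  if (nrow(pts) > 1 && any(diff(pts$ligand_total_uM) <= 0)) {
    abort("titration points must be strictly ordered by ligand_total_uM")
  }
  dup <- x |>
    group_by(.data$point_index, .data$residue_id) |>
    summarise(n = n(), .groups = "drop") |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated residue(s) within a titration point: residue ",
                 paste(unique(dup$residue_id), collapse = ", ")))
  }
  ref_res <- x$residue_id[x$point_index == pts$point_index[1]]
  per_point <- split(x$residue_id, x$point_index)
  for (pp in per_point) {
    miss <- setdiff(ref_res, pp)
    if (length(miss) > 0) {
      abort(paste0("residue(s) present at the apo reference are absent from a ",
                   "later point: ", paste(miss, collapse = ", "),
                   " (record them with quality = \"missing\")"))
    }
  }
  name_per_res <- tapply(x$residue_name, x$residue_id,
                         function(v) length(unique(v)))
  if (any(name_per_res > 1)) {
    abort(paste0("residue_name differs across points for residue(s): ",
                 paste(names(name_per_res)[name_per_res > 1], collapse = ", ")))
  }
  ok <- x$quality == "ok"
  bad_H <- ok & (!is.finite(x$delta_H_ppm) |
                   x$delta_H_ppm < -2 | x$delta_H_ppm > 15)
  bad_N <- ok & (!is.finite(x$delta_N_ppm) |
                   x$delta_N_ppm < 90 | x$delta_N_ppm > 140)
  if (any(bad_H) || any(bad_N)) {
    abort(paste0("amide shifts outside plausible range for quality = \"ok\" rows ",
                 "(delta_H in [-2, 15] ppm, delta_N in [90, 140] ppm); ",
                 "offending residue(s): ",
                 paste(unique(x$residue_id[bad_H | bad_N]), collapse = ", ")))
  }
  invisible(x)
}

#' Titration metadata
#'
#' @param x A `titration_data` tibble.
#' @return The named metadata list attached to the dataset.
#' @export
titration_metadata <- function(x) {
  attr(x, "metadata") %||% list()
}

#' Concentrations of the titration points
#'
#' @param x A `titration_data` tibble.
#' @return A tibble with one row per point: `point_index`,
#'   `protein_total_uM`, `ligand_total_uM`.
#' @export
titration_points <- function(x) {
  arrange(
    distinct(as_tibble(x), .data$point_index, .data$protein_total_uM,
             .data$ligand_total_uM),
    .data$point_index
  )
}

#' @export
print.titration_data <- function(x, ...) {
  pts <- titration_points(x)
  cat(sprintf(
    "<titration_data> %d points, %d residues, [P]t %s uM, [L]t %g-%g uM\n",
    nrow(pts), length(unique(x$residue_id)),
    paste(format(unique(pts$protein_total_uM)), collapse = "/"),
    min(pts$ligand_total_uM), max(pts$ligand_total_uM)
  ))
  meta <- titration_metadata(x)
  if (length(meta) > 0) {
    cat("metadata:", paste(names(meta), unlist(meta), sep = "=",
                           collapse = ", "), "\n")
  }
  NextMethod()
}
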