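#' Read a specimen measurement table
#'
#' Reads a CSV of fossil specimen measurements into a validated specimen
#' table. The file must contain the columns `specimen_id`, `species`,
#' `genus`, `clades` (semicolon-separated clade labels, possibly empty),
#' `fl_mm`, `hl_mm` (femur and humerus length in mm), `age_min_ma`,
#' `age_max_ma` (stratigraphic age bounds in Ma) and `onto_status`
#' (one of `"adult"`, `"subadult"`, `"juvenile"`, `"unknown"`).
#'
#' Rows with a missing femur or humerus length are dropped with a message
#' naming the specimen; non-positive measurements and inverted age ranges
#' are errors. Lengths outside the plausible 1--2500 mm range only raise a
#' warning, since a handful of giant or hatchling individuals are expected
#' in fossil datasets. Base-10 log columns `log_fl` and `log_hl` are added.
#'
#' @param path Path to a UTF-8 CSV file with "." as decimal separator.
#' @return A `data.frame` of class `specimen_table`, one row per specimen,
#'   with `clades` stored as a list-column of character vectors.
#' @seealso [make_variant()], [assign_clades()], [write_specimens()]
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop("specimen file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_specimen_table(raw)
}

#' Build a specimen table from a data frame
#'
#' Validates and completes an in-memory measurement table; this is the
#' function [read_specimens()] applies to the parsed CSV.
#'
#' @param df A data frame with the columns documented in [read_specimens()].
#'   `clades` may be a semicolon-separated character column or a
#'   list-column; `log_fl`/`log_hl` are recomputed if absent.
#' @return A `specimen_table` data frame.
#' @export
as_specimen_table <- function(df) {
  required <- c("specimen_id", "species", "genus", "fl_mm", "hl_mm",
                "age_min_ma", "age_max_ma", "onto_status")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("specimen table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"clades" %in% names(df)) df$clades <- ""

  drop <- is.na(df$fl_mm) | is.na(df$hl_mm)
  if (any(drop)) {
    message("dropping ", sum(drop), " specimen(s) with missing FL or HL: ",
            paste(df$specimen_id[drop], collapse = ", "))
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no usable specimens after removing missing measurements")

  bad <- which(df$fl_mm <= 0 | df$hl_mm <= 0)
  if (length(bad) > 0) {
    stop("non-positive measurement for specimen(s): ",
         paste(df$specimen_id[bad], collapse = ", "))
  }
  out_of_range <- df$fl_mm < 1 | df$fl_mm > 2500 | df$hl_mm < 1 | df$hl_mm > 2500
  if (any(out_of_range)) {
    warning("measurement outside the plausible 1-2500 mm range for: ",
            paste(df$specimen_id[out_of_range], collapse = ", "))
  }
  if (anyDuplicated(df$specimen_id)) {
    stop("duplicated specimen_id: ",
         paste(unique(df$specimen_id[duplicated(df$specimen_id)]), collapse = ", "))
  }
  if (any(is.na(df$age_min_ma)) || any(is.na(df$age_max_ma))) {
    stop("missing age bound for specimen(s): ",
         paste(df$specimen_id[is.na(df$age_min_ma) | is.na(df$age_max_ma)],
               collapse = ", "))
  }
  if (any(df$age_max_ma < df$age_min_ma) || any(df$age_min_ma < 0)) {
    stop("invalid age range (need age_max_ma >= age_min_ma >= 0) for: ",
         paste(df$specimen_id[df$age_max_ma < df$age_min_ma | df$age_min_ma < 0],
               collapse = ", "))
  }
  valid_status <- c("adult", "subadult", "juvenile", "unknown")
  if (!all(df$onto_status %in% valid_status)) {
    stop("onto_status must be one of ", paste(valid_status, collapse = "/"),
         "; offending specimen(s): ",
         paste(df$specimen_id[!df$onto_status %in% valid_status], collapse = ", "))
  }

  if (!is.list(df$clades)) {
    df$clades <- lapply(strsplit(as.character(df$clades), ";", fixed = TRUE),
                        function(x) trimws(x[nzchar(trimws(x))]))
  }
  df$log_fl <- log10(df$fl_mm)
  df$log_hl <- log10(df$hl_mm)
  rownames(df) <- NULL
  class(df) <- c("specimen_table", "data.frame")
  df
}

#' Write a specimen table back to CSV
#'
#' Inverse of [read_specimens()]: the written file reads back to an
#' identical table (clade list-columns are flattened to semicolon-separated
#' strings, log columns are recomputed on read).
#'
#' @param specimens A `specimen_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(specimens, path) {
  df <- as.data.frame(specimens)
  df$clades <- vapply(df$clades, paste, character(1), collapse = ";")
  df <- df[, c("specimen_id", "species", "genus", "clades", "fl_mm", "hl_mm",
               "age_min_ma", "age_max_ma", "onto_status")]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Subset a specimen table into a named dataset variant
#'
#' Four variants are supported:
#' \describe{
#'   \item{`complete`}{all specimens (identity).}
#'   \item{`reduced`}{one specimen per species — the one with the largest
#'     femur, ties broken by lexicographic `specimen_id`.}
#'   \item{`adult`}{drops specimens proposed to be juveniles; subadult and
#'     unknown-status specimens are retained (a conservative exclusion of
#'     juveniles only).}
#'   \item{`juvenile`}{keeps only specimens proposed to be juveniles.}
#' }
#'
#' @param specimens A `specimen_table`.
#' @param name One of `"complete"`, `"reduced"`, `"adult"`, `"juvenile"`.
#' @return A `specimen_table` with attribute `variant` set to `name`.
#' @export
make_variant <- function(specimens,
                         name = c("complete", "reduced", "adult", "juvenile")) {
  name <- match.arg(name)
  if (nrow(specimens) == 0) stop("empty specimen table")
  out <- switch(
    name,
    complete = specimens,
    reduced = {
      keep <- unlist(lapply(split(seq_len(nrow(specimens)), specimens$species),
                            function(idx) {
        sub <- specimens[idx, , drop = FALSE]
        o <- order(-sub$fl_mm, sub$specimen_id)
        idx[o[1]]
      }), use.names = FALSE)
      specimens[sort(keep), , drop = FALSE]
    },
    adult = specimens[specimens$onto_status != "juvenile", , drop = FALSE],
    juvenile = specimens[specimens$onto_status == "juvenile", , drop = FALSE]
  )
  if (nrow(out) == 0) stop("variant '", name, "' selects no specimens")
  rownames(out) <- NULL
  attr(out, "variant") <- name
  out
}

#' Attach clade labels to specimens from a species-to-clade table
#'
#' Clade membership is usually entered per species (a species can carry
#' several nested labels, e.g. a troodontid is also a maniraptoran). This
#' replaces the `clades` column of `specimens` with the labels looked up in
#' `clade_table`; species absent from the table get an empty label set and
#' a single collective warning.
#'
#' @param specimens A `specimen_table`.
#' @param clade_table Either a named list mapping species to character
#'   vectors of clade labels, or a data frame with columns `species` and
#'   `clades` (semicolon-separated).
#' @return The specimen table with updated `clades`.
#' @export
assign_clades <- function(specimens, clade_table) {
  if (is.data.frame(clade_table)) {
    stopifnot(all(c("species", "clades") %in% names(clade_table)))
    lab <- strsplit(as.character(clade_table$clades), ";", fixed = TRUE)
    lab <- lapply(lab, function(x) trimws(x[nzchar(trimws(x))]))
    clade_table <- stats::setNames(lab, clade_table$species)
  }
  hit <- specimens$species %in% names(clade_table)
  if (!all(hit)) {
    warning("species without clade-table entry (labels left empty): ",
            paste(unique(specimens$species[!hit]), collapse = ", "))
  }
  specimens$clades <- lapply(specimens$species, function(sp) {
    if (sp %in% names(clade_table)) as.character(clade_table[[sp]]) else character(0)
  })
  specimens
}

#' Specimens belonging to a named clade
#'
#' @param specimens A `specimen_table`.
#' @param clade A clade label.
#' @return Logical vector marking member rows.
#' @export
in_clade <- function(specimens, clade) {
  vapply(specimens$clades, function(x) clade %in% x, logical(1))
}

#' Pooled stratigraphic age range per species
#'
#' All specimens of a species are assumed to share its geological age; the
#' species range is the union of its specimens' ranges.
#'
#' @param specimens A `specimen_table`.
#' @return A data frame with columns `tip`, `age_min_ma`, `age_max_ma`,
#'   one row per species, suitable for [calibrate_tree()].
#' @export
species_age_ranges <- function(specimens) {
  sp <- split(specimens, specimens$species)
  out <- data.frame(
    tip = names(sp),
    age_min_ma = vapply(sp, function(d) min(d$age_min_ma), numeric(1)),
    age_max_ma = vapply(sp, function(d) max(d$age_max_ma), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
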