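#' Clean occurrence records and reconcile counts
#'
#' Applies the record-level quality filters in a fixed, audited order:
#' records flagged non-target/cultivated, records without coordinates, records
#' outside the species' native range, records with coordinate uncertainty
#' strictly greater than `max_uncertainty_km` (10 km by default; a record at
#' exactly 10 km is retained), and finally exact coordinate duplicates
#' (coordinates compared after rounding to the nearest metre; the first record
#' of each coordinate pair is kept). Records with missing uncertainty are
#' retained and counted separately so the choice is auditable. Species without
#' a native-range mask are flagged in the report (`native_range_missing`) and
#' their records dropped rather than silently passed.
#'
#' @param records Tibble of raw records with columns `species_id`, `x`, `y`
#'   (km), `uncertainty_km` (may be `NA`), and optionally `flagged_nontarget`.
#' @param native_ranges Named list mapping `species_id` to native-range cell
#'   ids on `grid`.
#' @param grid The analysis [grid_spec()].
#' @param max_uncertainty_km Uncertainty cutoff, strict `>` removal (default 10).
#' @return A list of class `qc_result`: `records` (the cleaned tibble) and
#'   `report` (one row per species: `raw`, `removed_nontarget`,
#'   `removed_no_coords`, `removed_out_of_range`, `removed_uncertain`,
#'   `duplicates_removed`, `final_unique`, `n_missing_uncertainty`,
#'   `native_range_missing`, `pathway`).
#' @examples
#' g <- grid_spec(4, 4, cell_size_km = 5)
#' rec <- tibble::tibble(
#'   species_id = "sp1", x = c(2, 2, 12), y = c(2, 2, 12),
#'   uncertainty_km = c(1, 1, 20)
#' )
#' qc_clean(rec, list(sp1 = 1:16), g)$report
#' @export
qc_clean <- function(records, native_ranges, grid, max_uncertainty_km = 10) {
  stopifnot(is.data.frame(records), inherits(grid, "grid_spec"))
  needed <- c("species_id", "x", "y", "uncertainty_km")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- tibble::as_tibble(records)
  if (!"flagged_nontarget" %in% names(records)) {
    records$flagged_nontarget <- FALSE
  }
  # species with a native range but no records at all still get a report row
  # (raw = 0, pathway "excluded")
  species <- union(unique(records$species_id), names(native_ranges))
  per_species <- lapply(species, function(sp) {
    rec <- records[records$species_id == sp, , drop = FALSE]
    raw <- nrow(rec)
    missing_range <- !(sp %in% names(native_ranges))

    keep <- !rec$flagged_nontarget
    removed_nontarget <- sum(!keep)
    rec <- rec[keep, , drop = FALSE]

    has_coords <- is.finite(rec$x) & is.finite(rec$y)
    removed_no_coords <- sum(!has_coords)
    rec <- rec[has_coords, , drop = FALSE]

    if (missing_range) {
      removed_out_of_range <- nrow(rec) # cannot verify: drop all, flag species
      rec <- rec[0, , drop = FALSE]
    } else {
      mask <- cells_to_mask(grid, native_ranges[[sp]])
      cid <- cell_at(grid, rec$x, rec$y)
      inside <- !is.na(cid) & mask[cid]
      removed_out_of_range <- sum(!inside)
      rec <- rec[inside, , drop = FALSE]
    }

    n_missing_unc <- sum(is.na(rec$uncertainty_km))
    certain <- is.na(rec$uncertainty_km) | rec$uncertainty_km <= max_uncertainty_km
    removed_uncertain <- sum(!certain)
    rec <- rec[certain, , drop = FALSE]

    key <- paste(round(rec$x, 3), round(rec$y, 3)) # metre-resolution dedupe
    dup <- duplicated(key)
    duplicates_removed <- sum(dup)
    rec <- rec[!dup, , drop = FALSE]

    list(
      records = rec,
      report = tibble::tibble(
        species_id = sp, raw = raw,
        removed_nontarget = removed_nontarget,
        removed_no_coords = removed_no_coords,
        removed_out_of_range = removed_out_of_range,
        removed_uncertain = removed_uncertain,
        duplicates_removed = duplicates_removed,
        final_unique = nrow(rec),
        n_missing_uncertainty = n_missing_unc,
        native_range_missing = missing_range
      )
    )
  })
  report <- dplyr::bind_rows(lapply(per_species, `[[`, "report"))
  report$pathway <- assign_pathway(report$final_unique)
  structure(
    list(
      records = dplyr::bind_rows(lapply(per_species, `[[`, "records")),
      report = report
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "<qc_result> %d species: %d records in, %d clean (%d model / %d buffer / %d excluded)\n",
    nrow(x$report), sum(x$report$raw), sum(x$report$final_unique),
    sum(x$report$pathway == "model"), sum(x$report$pathway == "buffer"),
    sum(x$report$pathway == "excluded")
  ))
  invisible(x)
}

#' Assign species to a modelling pathway
#'
#' Species with ten or more unique cleaned records are eligible for
#' distribution modelling; those with one to nine get the circular-buffer
#' fallback; those with none are excluded from the analysis.
#'
#' @param n_unique Integer vector of unique cleaned record counts.
#' @param min_records_for_model Eligibility cutoff (default 10, inclusive).
#' @return Character vector: `"model"`, `"buffer"`, or `"excluded"`.
#' @examples
#' assign_pathway(c(0, 9, 10))
#' @export
assign_pathway <- function(n_unique, min_records_for_model = 10) {
  stopifnot(all(n_unique >= 0))
  dplyr::case_when(
    n_unique >= min_records_for_model ~ "model",
    n_unique >= 1 ~ "buffer",
    TRUE ~ "excluded"
  )
}
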