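#' Load an Ofcom point-threshold table
#'
#' The Ofcom (UK FSA 2004-05) nutrient profiling model assigns "A" points
#' for energy, saturated fat, total sugars and sodium, and "C" points for
#' fruit/vegetable/nut (FVN) content, fibre and protein. The thresholds are
#' shipped as a plain-text key/value file so that alternative threshold
#' sets can be swapped in without touching code.
#'
#' @param path Path to a point-table configuration file. Defaults to the
#'   bundled 2004-05 tables.
#' @param fibre_basis Which fibre threshold set to use: `"aoac"`
#'   (AOAC total dietary fibre, the convention of North American food
#'   composition databases) or `"nsp"` (non-starch polysaccharide).
#'   Defaults to the value declared in the file.
#' @return An object of class `ofcom_tables`: a list with ascending
#'   threshold vectors `energy_kj`, `satfat_g`, `sugars_g`, `sodium_mg`,
#'   `fibre`, `protein_g`, the FVN point ladder `fvn_points`, the protein
#'   cap constant `cap_a_points`, the `kcal_to_kj` conversion factor and a
#'   `version` string.
#' @examples
#' tab <- ofcom_point_tables()
#' tab$sodium_mg
#' @export
ofcom_point_tables <- function(path = NULL, fibre_basis = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ofcom_points_2004_2005.conf",
                        package = "npsubstitute")
  }
  cfg <- read_kv_config(path)
  needed <- c(
    "energy_kj", "satfat_g", "sugars_g", "sodium_mg",
    "fibre_aoac_g", "fibre_nsp_g", "protein_g",
    "fvn_mid_low_points", "fvn_mid_high_points", "fvn_max_points",
    "cap_a_points", "kcal_to_kj", "fibre_basis"
  )
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) {
    stop("point-table config missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(fibre_basis)) fibre_basis <- cfg$fibre_basis
  fibre_basis <- match.arg(fibre_basis, c("aoac", "nsp"))
  fibre <- if (fibre_basis == "aoac") cfg$fibre_aoac_g else cfg$fibre_nsp_g

  for (key in c("energy_kj", "satfat_g", "sugars_g", "sodium_mg", "protein_g")) {
    if (is.unsorted(cfg[[key]], strictly = TRUE)) {
      stop("thresholds for '", key, "' must be strictly ascending", call. = FALSE)
    }
  }
  tables <- list(
    energy_kj = cfg$energy_kj,
    satfat_g = cfg$satfat_g,
    sugars_g = cfg$sugars_g,
    sodium_mg = cfg$sodium_mg,
    fibre = fibre,
    protein_g = cfg$protein_g,
    fvn_points = c(
      MIN = 0,
      LOW_MID = cfg$fvn_mid_low_points,
      HIGH_MID = cfg$fvn_mid_high_points,
      MAX = cfg$fvn_max_points
    ),
    cap_a_points = cfg$cap_a_points,
    kcal_to_kj = cfg$kcal_to_kj,
    fibre_basis = fibre_basis,
    version = if (!is.null(cfg$version)) cfg$version else "unversioned"
  )
  structure(tables, class = "ofcom_tables")
}

#' @export
print.ofcom_tables <- function(x, ...) {
  cat("<ofcom_tables> version:", x$version,
      "| fibre basis:", x$fibre_basis,
      "| protein cap at A >=", x$cap_a_points, "\n")
  invisible(x)
}
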