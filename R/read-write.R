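# CSV interchange: readers validate and normalise, writers emit the same
# schema so that write -> read round-trips field-for-field.

PACKAGE_TYPES <- c("can", "can_bpa_free", "aluminum", "composite_cpp", "glass")

SHAPES <- c("fiber", "fragment")
VERIFIED_LEVELS <- c("verified_mp", "rejected", "not_analyzed")

normalize_package_type <- function(label) {
  key <- gsub("[^a-z]+", " ", tolower(trimws(label)))
  key <- trimws(key)
  lookup <- c(
    "can"            = "can",
    "can bpa free"   = "can_bpa_free",
    "can bpa_free"   = "can_bpa_free",
    "aluminum"       = "aluminum",
    "aluminium"      = "aluminum",
    "c pp"           = "composite_cpp",
    "composite cpp"  = "composite_cpp",
    "glass"          = "glass"
  )
  # accept already-normalised tokens too
  key2 <- gsub("_", " ", key)
  out <- unname(lookup[key2])
  out
}

normalize_shape <- function(label) {
  key <- tolower(trimws(label))
  key[key %in% c("fiber", "fibre", "filament", "fiber/filament", "fibre/filament")] <- "fiber"
  key[key %in% c("fragment", "fragments")] <- "fragment"
  key
}

read_csv_strict <- function(path, required, what) {
  if (!file.exists(path)) {
    stop_canmp(sprintf("File not found: '%s'.", path), class = "io")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  check_df_cols(df, required, what)
  df
}

parse_numeric_col <- function(df, col, what, min = NULL) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(val))
  if (length(bad)) {
    stop_canmp(sprintf("%s: malformed numeric value '%s' in column '%s', row %d.",
                       what, raw[bad[1]], col, bad[1]),
               class = "validation")
  }
  if (!is.null(min)) {
    neg <- which(!is.na(val) & val < min)
    if (length(neg)) {
      stop_canmp(sprintf("%s: column '%s' must be >= %s (row %d has %s).",
                         what, col, format(min), neg[1], format(val[neg[1]])),
                 class = "validation")
    }
  }
  val
}

#' Read a product metadata table
#'
#' Reads a `products.csv` file (columns `code,party_no,species,additive_oil,
#' other_additives,product_weight_g,package_type`), validates it and
#' normalises the packaging vocabulary to the closed set
#' `can`, `can_bpa_free`, `aluminum`, `composite_cpp`, `glass`
#' ("Aluminium"/"Aluminum" spellings, "Can (BPA free)" and "C/PP" are all
#' recognised). The original label is preserved in `package_label`, and the
#' producer (the code prefix before the first hyphen) is added as a column.
#'
#' Party/lot numbers are carried as opaque strings: their formats are
#' heterogeneous (lot codes and several date styles) and never interpreted.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per product: `code`, `producer`, `party_no`,
#'   `species`, `additive_oil`, `other_additives`, `product_weight_g`,
#'   `package_type`, `package_label`.
#' @examples
#' products <- read_products(canmp_example("reference_products.csv"))
#' dplyr::count(products, package_type)
#' @export
read_products <- function(path) {
  req <- c("code", "party_no", "species", "additive_oil", "other_additives",
           "product_weight_g", "package_type")
  df <- read_csv_strict(path, req, "products table")
  if (nrow(df) == 0) {
    return(tibble(code = character(), producer = character(),
                  party_no = character(), species = character(),
                  additive_oil = character(), other_additives = character(),
                  product_weight_g = numeric(), package_type = character(),
                  package_label = character()))
  }
  dup <- df$code[duplicated(df$code)]
  if (length(dup)) {
    stop_canmp(sprintf("products table: duplicate code(s): %s.",
                       paste(unique(dup), collapse = ", ")),
               class = "validation")
  }
  weight <- parse_numeric_col(df, "product_weight_g", "products table")
  if (any(is.na(weight) | weight <= 0)) {
    bad <- which(is.na(weight) | weight <= 0)[1]
    stop_canmp(sprintf("products table: product_weight_g must be positive (row %d, code %s).",
                       bad, df$code[bad]), class = "validation")
  }
  ptype <- normalize_package_type(df$package_type)
  if (anyNA(ptype)) {
    bad <- which(is.na(ptype))[1]
    stop_canmp(sprintf("products table: unknown package label '%s' (row %d, code %s).",
                       df$package_type[bad], bad, df$code[bad]),
               class = "validation")
  }
  tibble(
    code = df$code,
    producer = producer_of(df$code),
    party_no = df$party_no,
    species = df$species,
    additive_oil = df$additive_oil,
    other_additives = df$other_additives,
    product_weight_g = weight,
    package_type = ptype,
    package_label = df$package_type
  )
}

#' Write a product table
#'
#' Writes the CSV schema read by [read_products()]. The normalised
#' `package_type` token is written, so a write/read round trip is stable.
#'
#' @param products A tibble as returned by [read_products()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_products <- function(products, path) {
  check_df_cols(products, c("code", "party_no", "species", "additive_oil",
                            "other_additives", "product_weight_g", "package_type"),
                "products")
  readr::write_csv(
    products[, c("code", "party_no", "species", "additive_oil",
                 "other_additives", "product_weight_g", "package_type")],
    path)
  invisible(path)
}

#' Read per-can observations
#'
#' Reads an `observations.csv` file (columns
#' `code,replicate,subsample_mass_g,particle_count`): one row per analysed
#' can, giving the mass of homogenised flesh digested (50 g in the reference
#' protocol) and the number of microplastic-like particles counted on its
#' filter. Validates that masses are positive, counts are non-negative
#' integers, and each brand's replicates are numbered consecutively from 1.
#'
#' @param path Path to a CSV file.
#' @return A tibble `code`, `replicate`, `subsample_mass_g`, `particle_count`.
#' @seealso [brand_concentrations()]
#' @export
read_observations <- function(path) {
  req <- c("code", "replicate", "subsample_mass_g", "particle_count")
  df <- read_csv_strict(path, req, "observations table")
  if (nrow(df) == 0) {
    return(tibble(code = character(), replicate = integer(),
                  subsample_mass_g = numeric(), particle_count = integer()))
  }
  out <- tibble(
    code = df$code,
    replicate = as.integer(parse_numeric_col(df, "replicate", "observations table", min = 1)),
    subsample_mass_g = parse_numeric_col(df, "subsample_mass_g", "observations table"),
    particle_count = parse_numeric_col(df, "particle_count", "observations table", min = 0)
  )
  validate_observations(out)
}

validate_observations <- function(obs) {
  check_df_cols(obs, c("code", "replicate", "subsample_mass_g", "particle_count"),
                "observations")
  if (any(obs$subsample_mass_g <= 0 | is.na(obs$subsample_mass_g))) {
    stop_canmp("observations: subsample_mass_g must be positive.",
               class = "validation")
  }
  if (any(obs$particle_count < 0 | obs$particle_count != floor(obs$particle_count))) {
    stop_canmp("observations: particle_count must be a non-negative integer.",
               class = "validation")
  }
  bad <- obs |>
    group_by(.data$code) |>
    summarise(ok = identical(sort(.data$replicate), seq_along(.data$replicate)),
              .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad)) {
    stop_canmp(sprintf("observations: replicates for code(s) %s are not consecutive from 1.",
                       paste(bad$code, collapse = ", ")),
               class = "validation")
  }
  mutate(obs, particle_count = as.integer(.data$particle_count))
}

#' Write per-can observations
#'
#' @param observations A tibble as returned by [read_observations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  check_df_cols(observations,
                c("code", "replicate", "subsample_mass_g", "particle_count"),
                "observations")
  readr::write_csv(
    observations[, c("code", "replicate", "subsample_mass_g", "particle_count")],
    path)
  invisible(path)
}

#' Read a particle attribute table
#'
#' Reads a `particles.csv` file (columns
#' `sample_id,shape,color,size_mm,polymer,verified`): one row per
#' microplastic-like particle, with its shape (`fiber` or `fragment`; the
#' spellings "fibre" and "filament" are normalised to `fiber`), colour label,
#' Feret diameter in mm, assigned polymer (empty for particles never put
#' through spectroscopy) and verification status (`verified_mp`, `rejected`,
#' `not_analyzed`).
#'
#' @param path Path to a CSV file.
#' @return A tibble `sample_id`, `shape`, `color`, `size_mm`, `polymer`,
#'   `verified`.
#' @seealso [composition_summary()]
#' @export
read_particles <- function(path) {
  req <- c("sample_id", "shape", "color", "size_mm", "polymer", "verified")
  df <- read_csv_strict(path, req, "particles table")
  if (nrow(df) == 0) {
    return(tibble(sample_id = character(), shape = character(),
                  color = character(), size_mm = numeric(),
                  polymer = character(), verified = character()))
  }
  shape <- normalize_shape(df$shape)
  bad <- which(!shape %in% SHAPES)
  if (length(bad)) {
    stop_canmp(sprintf("particles table: unknown shape '%s' (row %d).",
                       df$shape[bad[1]], bad[1]), class = "validation")
  }
  size <- parse_numeric_col(df, "size_mm", "particles table")
  if (any(is.na(size) | size <= 0)) {
    b <- which(is.na(size) | size <= 0)[1]
    stop_canmp(sprintf("particles table: size_mm must be positive (row %d).", b),
               class = "validation")
  }
  verified <- tolower(trimws(df$verified))
  bad <- which(!verified %in% VERIFIED_LEVELS)
  if (length(bad)) {
    stop_canmp(sprintf("particles table: unknown verification status '%s' (row %d).",
                       df$verified[bad[1]], bad[1]), class = "validation")
  }
  polymer <- df$polymer
  polymer[!is.na(polymer) & trimws(polymer) == ""] <- NA_character_
  has_poly <- !is.na(polymer) & tolower(polymer) != "unknown"
  bad <- which(has_poly & verified == "not_analyzed")
  if (length(bad)) {
    stop_canmp(sprintf("particles table: row %d has a polymer label but was never analysed.",
                       bad[1]), class = "validation")
  }
  tibble(sample_id = df$sample_id, shape = shape, color = tolower(trimws(df$color)),
         size_mm = size, polymer = polymer, verified = verified)
}

#' Write a particle table
#'
#' @param particles A tibble as returned by [read_particles()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_particles <- function(particles, path) {
  check_df_cols(particles,
                c("sample_id", "shape", "color", "size_mm", "polymer", "verified"),
                "particles")
  readr::write_csv(
    particles[, c("sample_id", "shape", "color", "size_mm", "polymer", "verified")],
    path)
  invisible(path)
}

#' Read a brand concentration table
#'
#' Reads a `concentrations.csv` file with per-brand microplastic
#' concentrations (MPs/100 g). The required columns are `code` and
#' `raw_mean_per100g`; `corrected_mean_per100g`, `std_error_per100g` and the
#' six intake columns (`micf_52` ... `mif_260`) are parsed when present, as
#' in the bundled reference table. A `grand` row (the survey-level mean) is
#' allowed and passed through.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `code` plus the numeric columns found in the file.
#' @examples
#' conc <- read_concentrations(canmp_example("reference_concentrations.csv"))
#' conc[conc$code == "D-C-1", 1:4]
#' @export
read_concentrations <- function(path) {
  df <- read_csv_strict(path, c("code", "raw_mean_per100g"), "concentrations table")
  num_cols <- setdiff(names(df), "code")
  out <- tibble(code = df$code)
  for (col in num_cols) {
    out[[col]] <- parse_numeric_col(df, col, "concentrations table", min = 0)
  }
  dup <- out$code[duplicated(out$code)]
  if (length(dup)) {
    stop_canmp(sprintf("concentrations table: duplicate code(s): %s.",
                       paste(unique(dup), collapse = ", ")),
               class = "validation")
  }
  out
}

#' Write a brand concentration table
#'
#' @param concentrations A tibble with a `code` column and numeric columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(concentrations, path) {
  check_df_cols(concentrations, c("code", "raw_mean_per100g"), "concentrations")
  readr::write_csv(concentrations, path)
  invisible(path)
}
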