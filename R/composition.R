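# Composition summaries: shape/colour/polymer shares, plastic-size
# classification, and integer-count reconstruction from printed percentages.

NATURAL_POLYMERS <- c("Cellulose", "Chitin")

SIZE_CLASS_LEVELS <- c("nanoplastic", "microplastic", "mesoplastic",
                       "macroplastic", "megaplastic")

#' Size class boundaries
#'
#' The plastic size scheme used throughout the package: nanoplastic
#' (< 1 µm), microplastic (1 µm – 5 mm), mesoplastic (5–20 mm), macroplastic
#' (20–100 mm), megaplastic (> 100 mm). Classes partition the positive reals.
#'
#' @return A tibble `label`, `lower_mm`, `upper_mm`.
#' @seealso [classify_size()]
#' @export
size_classes <- function() {
  tibble(
    label = SIZE_CLASS_LEVELS,
    lower_mm = c(0, 0.001, 5, 20, 100),
    upper_mm = c(0.001, 5, 20, 100, Inf)
  )
}

#' Classify particle sizes
#'
#' Assigns each Feret diameter to a plastic size class. Boundaries are
#' inclusive on the upper end of each class by default: exactly 5 mm is
#' microplastic, exactly 20 mm is mesoplastic, and 1 µm is microplastic.
#' Set `upper_inclusive = FALSE` for lower-inclusive (left-closed) classes.
#'
#' @param size_mm Numeric vector of Feret diameters in mm; all values must be
#'   positive.
#' @param upper_inclusive Boundary convention (default TRUE).
#' @return A factor with levels nanoplastic < microplastic < mesoplastic <
#'   macroplastic < megaplastic.
#' @examples
#' classify_size(c(0.0005, 3, 5, 5.89, 25))
#' @export
classify_size <- function(size_mm, upper_inclusive = TRUE) {
  check_number(size_mm, "size_mm")
  if (any(size_mm <= 0)) {
    stop_canmp("`size_mm` must be positive.", class = "validation")
  }
  # the 1 µm bound always belongs to microplastic; upper_inclusive governs
  # the 5 / 20 / 100 mm boundaries
  upper <- if (upper_inclusive) `<=` else `<`
  lab <- dplyr::case_when(
    size_mm < 0.001 ~ "nanoplastic",
    upper(size_mm, 5) ~ "microplastic",
    upper(size_mm, 20) ~ "mesoplastic",
    upper(size_mm, 100) ~ "macroplastic",
    TRUE ~ "megaplastic"
  )
  factor(lab, levels = SIZE_CLASS_LEVELS, ordered = TRUE)
}

#' Composition summary of a particle table
#'
#' Percentage share of particles per label along one dimension. For
#' `"shape"`, `"color"` and `"size_class"` every particle with a defined
#' value contributes; for `"polymer"` only particles with an assigned
#' polymer are summarised and spectroscopically rejected particles are
#' excluded (visual shape and colour are observed for every particle, but a
#' polymer identity only makes sense for particles confirmed on the
#' spectrometer). Natural polymers (cellulose, chitin) are retained but
#' flagged via `natural_polymer`.
#'
#' @param particles A tibble as returned by [read_particles()] or
#'   [simulate_survey()].
#' @param dimension One of `"shape"`, `"color"`, `"polymer"`, `"size_class"`.
#' @param upper_inclusive Size-class boundary convention, passed to
#'   [classify_size()].
#' @return A tibble `dimension`, `label`, `count`, `share_pct` (summing to
#'   100), plus `natural_polymer` for the polymer dimension, sorted by
#'   decreasing share. The number of particles summarised is in the
#'   `n` attribute.
#' @examples
#' p <- tibble::tibble(sample_id = "s", shape = c(rep("fragment", 4), rep("fiber", 3)),
#'                     color = "blue", size_mm = 1, polymer = NA, verified = "not_analyzed")
#' composition_summary(p, "shape")
#' @export
composition_summary <- function(particles,
                                dimension = c("shape", "color", "polymer", "size_class"),
                                upper_inclusive = TRUE) {
  dimension <- arg_match(dimension)
  check_df_cols(particles, c("shape", "color", "size_mm", "polymer", "verified"),
                "particles")
  if (nrow(particles) == 0) {
    stop_canmp("Cannot summarise an empty particle table.", class = "validation")
  }
  value <- switch(dimension,
    shape = particles$shape,
    color = particles$color,
    size_class = as.character(classify_size(particles$size_mm, upper_inclusive)),
    polymer = {
      keep <- !is.na(particles$polymer) & particles$verified != "rejected"
      particles$polymer[keep]
    }
  )
  value <- value[!is.na(value)]
  if (length(value) == 0) {
    stop_canmp(sprintf("No particles with a defined '%s' value.", dimension),
               class = "validation")
  }
  out <- tibble(label = value) |>
    count(.data$label, name = "count") |>
    mutate(dimension = dimension,
           share_pct = .data$count / sum(.data$count) * 100) |>
    select("dimension", "label", "count", "share_pct") |>
    arrange(dplyr::desc(.data$share_pct), .data$label)
  if (dimension == "polymer") {
    out <- mutate(out, natural_polymer = .data$label %in% NATURAL_POLYMERS)
  }
  attr(out, "n") <- length(value)
  out
}

#' Reconstruct integer counts from printed percentages
#'
#' Published composition tables usually print shares rounded to two decimals
#' without the underlying counts. This reverses that: it finds the smallest
#' total `n` (up to `total_hint`) such that every printed share is exactly
#' the half-up 2-decimal rounding of an integer count over `n`, and returns
#' those counts. With shares from a real count table the solution is the
#' original sample size (e.g. shares of 18.18 and 9.09 resolve to 2/11 and
#' 1/11).
#'
#' @param shares Named numeric vector of percentages, or a tibble with
#'   `label`/`polymer` and `share_pct` columns. Must sum to 100 within 0.5.
#' @param total_hint Upper bound for the search (default 500). Supply the
#'   published total when known.
#' @return A tibble `label`, `count`, `share_pct` (the exact share of the
#'   reconstruction); the resolved total is in the `n_total` attribute.
#' @examples
#' reconstruct_counts(c(a = 57.14, b = 42.86))   # 4 + 3 of 7
#' @export
reconstruct_counts <- function(shares, total_hint = 500) {
  if (is.data.frame(shares)) {
    lab_col <- intersect(c("label", "polymer"), names(shares))[1]
    if (is.na(lab_col) || !"share_pct" %in% names(shares)) {
      stop_canmp("`shares` data frame needs a label/polymer and a share_pct column.",
                 class = "validation")
    }
    shares <- setNames(shares$share_pct, shares[[lab_col]])
  }
  check_number(shares, "shares", min = 0)
  if (is.null(names(shares)) || any(!nzchar(names(shares)))) {
    stop_canmp("`shares` must be named.", class = "validation")
  }
  if (abs(sum(shares) - 100) > 0.5) {
    stop_canmp(sprintf("Shares sum to %.2f, not ~100.", sum(shares)),
               class = "validation")
  }
  target <- round_half_up(shares, 2)
  best_n <- NA_integer_
  best_err <- Inf
  for (n in seq_len(total_hint)) {
    k <- round(target * n / 100)
    if (any(k < 1) || sum(k) != n) next
    err <- max(abs(round_half_up(100 * k / n, 2) - target))
    if (err < best_err) {
      best_err <- err
      best_n <- n
    }
    if (err < 1e-9) {
      out <- tibble(label = names(shares), count = as.integer(unname(k)),
                    share_pct = unname(100 * k / n))
      attr(out, "n_total") <- n
      return(out)
    }
  }
  stop_canmp(sprintf(paste0(
    "No total up to %d reproduces the printed shares exactly; ",
    "nearest miss is n = %s (max share deviation %.3f points)."),
    total_hint, best_n, best_err), class = "reconstruction")
}

#' Combine per-shape polymer counts into overall shares
#'
#' Merges the fiber and fragment polymer count maps (usually produced by
#' [reconstruct_counts()]) and recomputes each polymer's share of the pooled
#' particles.
#'
#' @param fiber_counts,fragment_counts Tibbles with `label` and `count`
#'   columns.
#' @param expected_total If supplied, error unless the pooled count equals it
#'   (e.g. 64 confirmed particles in the reference survey).
#' @return A tibble `label`, `count`, `share_pct`, `natural_polymer`, sorted
#'   by decreasing share; the pooled total is in the `n_total` attribute.
#' @examples
#' fib <- tibble::tibble(label = "Polyamide - Nylon 6, 6", count = 1L)
#' frag <- tibble::tibble(label = "Polyolefin", count = 1L)
#' combine_polymer_shares(fib, frag)
#' @export
combine_polymer_shares <- function(fiber_counts, fragment_counts,
                                   expected_total = NULL) {
  check_df_cols(fiber_counts, c("label", "count"), "fiber_counts")
  check_df_cols(fragment_counts, c("label", "count"), "fragment_counts")
  pooled <- bind_rows(fiber_counts[, c("label", "count")],
                      fragment_counts[, c("label", "count")]) |>
    group_by(.data$label) |>
    summarise(count = sum(.data$count), .groups = "drop")
  total <- sum(pooled$count)
  if (!is.null(expected_total) && total != expected_total) {
    stop_canmp(sprintf("Pooled counts total %d, expected %d.", total, expected_total),
               class = "validation")
  }
  out <- pooled |>
    mutate(share_pct = .data$count / total * 100,
           natural_polymer = .data$label %in% NATURAL_POLYMERS) |>
    arrange(dplyr::desc(.data$share_pct), .data$label)
  attr(out, "n_total") <- total
  out
}
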