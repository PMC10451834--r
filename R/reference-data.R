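#' Published reference descriptives for a two-group adolescent sample
#'
#' Item-level summary statistics (mean, sample SD, skewness, excess
#' kurtosis) of the nine PHQ-9 symptoms and the two intolerance-of-
#' uncertainty dimensions, printed for an urban (n = 439) / rural (n = 1049)
#' adolescent survey, together with the printed pooled-variance t value per
#' item. These summaries calibrate the synthetic-data generator's default
#' thresholds and serve as inputs for recomputing the published univariate
#' tests.
#'
#' @return data frame with columns `item`, `label`, `m_urban`, `sd_urban`,
#'   `skew_urban`, `kurt_urban`, `m_rural`, `sd_rural`, `skew_rural`,
#'   `kurt_rural`, `t_printed`.
#' @export
reference_descriptives <- function() {
  data.frame(
    item = c(paste0("PHQ", 1:9), "AA", "IA"),
    label = c("Anhedonia", "Sad Mood", "Sleep", "Energy", "Appetite",
              "Guilt", "Concentration", "Motor", "Suicide",
              "Prospective anxiety", "Inhibitory anxiety"),
    m_urban = c(0.77, 0.70, 0.64, 0.81, 0.62, 0.57, 0.71, 0.49, 0.27,
                2.54, 2.41),
    sd_urban = c(0.83, 0.79, 0.87, 0.87, 0.83, 0.82, 0.87, 0.76, 0.61,
                 0.79, 0.82),
    skew_urban = c(0.89, 1.00, 1.23, 0.86, 1.20, 1.34, 1.00, 1.48, 2.51,
                   0.36, 0.50),
    kurt_urban = c(0.19, 0.47, 0.59, -0.04, 0.60, 0.99, 0.03, 1.48, 6.24,
                   0.10, 0.07),
    m_rural = c(0.84, 0.73, 0.75, 0.88, 0.69, 0.68, 0.82, 0.61, 0.40,
                2.54, 2.40),
    sd_rural = c(0.83, 0.80, 0.88, 0.87, 0.85, 0.84, 0.90, 0.82, 0.73,
                 0.83, 0.86),
    skew_rural = c(0.78, 0.90, 0.95, 0.75, 1.07, 1.04, 0.87, 1.22, 1.81,
                   0.56, 0.70),
    kurt_rural = c(0.04, 0.18, -0.03, -0.18, 0.32, 0.22, -0.14, 0.69, 2.46,
                   0.28, 0.35),
    t_printed = c(-1.41, -0.65, -2.20, -1.46, -1.47, -2.39, -2.30, -2.61,
                  -3.30, 0.05, 0.03),
    stringsAsFactors = FALSE)
}

#' Published reference group counts for the same sample
#'
#' Group sizes, gender composition and depression screening counts
#' (PHQ-9 total >= 8) of the urban/rural reference sample.
#'
#' @return list with `n` (urban, rural), `gender` (2x2 matrix, rows
#'   urban/rural, columns female/male) and `depression` (2x2 matrix, rows
#'   urban/rural, columns depressed/not_depressed).
#' @export
reference_group_counts <- function() {
  list(
    n = c(urban = 439L, rural = 1049L),
    gender = matrix(c(198L, 241L, 442L, 607L), nrow = 2, byrow = TRUE,
                    dimnames = list(c("urban", "rural"),
                                    c("female", "male"))),
    depression = matrix(c(152L, 287L, 419L, 630L), nrow = 2, byrow = TRUE,
                        dimnames = list(c("urban", "rural"),
                                        c("depressed", "not_depressed"))))
}
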