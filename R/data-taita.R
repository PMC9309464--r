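#' Reference fragment heterozygosity table for the Taita Hills
#'
#' Fragment-level admixture heterozygosity (percentage of extraspecific
#' chromosomes in the fragment's *Z. silvanus* gene pool) for the 19 named
#' montane-forest fragments of the Taita Hills known to hold the species,
#' after 300 simulated years under each habitat-change scenario at a
#' hybridization propensity of 1% (means of 50 replicates). `NA` marks a
#' fragment uninhabited under that scenario; the `mean` column averages the
#' defined scenario values and `sd` is their standard deviation. Used as the
#' reference input for the fragment-area regression cross-check (see
#' [fragment_regression()]).
#'
#' @format Tibble with 19 rows and columns `fragment` (name), `area_ha`,
#'   the five scenario columns (`control`, `edge_depletion`,
#'   `fragment_clearing`, `corridor_planting`, `plantation_conversion`, in
#'   %), `mean` and `sd`.
#' @export
taita_fragments <- tibble::tibble(
  fragment = c("Mbololo", "Ngangao", "Chawia", "Msidunyi", "Vuria extra 1",
               "Ronge", "Susu", "Fururu", "Vuria", "Ndiwenyi", "Macha E",
               "Susu extra 1", "Yale S", "Yale extra N", "Mwachora",
               "Kichuchenyi", "Wundanyi", "Yale extra 1", "Yale extra 2"),
  area_ha = c(180, 145, 91, 26, 22, 15, 14, 8, 7, 5, 4, 4, 4, 3, 2, 1, 1, 1, 1),
  control = c(6.07, 4.98, 6.64, 5.53, 10.19, 10.83, 11.36, 6.50, 11.02,
              19.45, 11.94, 17.99, 6.45, 16.05, 4.20, 18.18, 21.59, 18.10,
              20.08),
  edge_depletion = c(3.60, 12.17, 6.85, 8.73, 10.76, 10.47, 13.76, 7.08,
                     8.45, 19.85, 12.75, 15.52, 6.37, 3.06, 1.94, 28.69,
                     14.77, 14.04, 15.91),
  fragment_clearing = c(5.95, 3.97, 6.48, 7.13, 10.98, 10.52, 34.15, 13.64,
                        12.96, 21.97, 15.91, 22.63, 5.86, 5.86, 1.81, 9.09,
                        13.64, 14.65, 12.50),
  corridor_planting = c(4.81, 5.31, 5.00, 12.25, 15.09, 10.59, 12.63, 7.19,
                        14.76, 17.27, 10.03, 16.18, 5.92, 10.47, 1.28,
                        16.48, 11.24, 12.04, 23.30),
  plantation_conversion = c(6.04, 4.24, 6.69, 0.91, 0.71, 10.57, 11.31,
                            6.74, NA, 13.71, 15.60, 12.69, 14.21, 10.24,
                            3.05, 17.23, 18.94, 18.54, 17.56),
  mean = c(5.29, 6.13, 6.33, 6.91, 9.55, 10.60, 16.64, 8.23, 11.80, 18.45,
           13.25, 17.00, 7.76, 9.14, 2.46, 17.93, 16.04, 15.47, 17.87),
  sd = c(1.08, 3.42, 0.76, 4.18, 5.31, 0.14, 9.84, 3.04, 2.7, 3.13, 2.5,
         3.68, 3.61, 4.96, 1.17, 7.01, 4.17, 2.78, 4.1)
)
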