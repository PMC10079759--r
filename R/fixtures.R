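## Worked-example fixtures: the profiles and constructed networks used
## throughout the documentation and tests.

#' Worked-example profiles and networks
#'
#' Builds the recurring examples in one call: the profile (7,6,6,5) and its
#' realization, the beaded cores for (77,1,1,1), (5,1,1) and (12,1,1), the
#' scaled composition realizing (40,24,8,4,2,1), the weak-orchard example
#' (6,3), and the ten-taxon Viola profile (18,14,14,10,8,8,8,4,4,2) with its
#' realization.
#'
#' @return A list with elements `profiles` (named list of
#'   [ploidy_profile()]) and `networks` (named list of [pnet()]).
#' @export
paper_fixtures <- function() {
  profiles <- list(
    main  = ploidy_profile(c(7, 6, 6, 5)),
    doubled = ploidy_profile(c(14, 12, 12, 10)),
    simple77 = ploidy_profile(c(77, 1, 1, 1)),
    core511 = ploidy_profile(c(5, 1, 1)),
    scaled_base = ploidy_profile(c(5, 3, 1)),
    weak = ploidy_profile(c(6, 3)),
    twelve = ploidy_profile(c(12, 1, 1)),
    viola = ploidy_profile(c(18, 14, 14, 10, 8, 8, 8, 4, 4, 2))
  )
  networks <- list(
    fig2 = realize_profile(profiles$main),
    fig4 = build_B(profiles$simple77),
    fig5i = build_B(profiles$twelve),
    fig6 = compose_scaled(realize_profile(profiles$scaled_base), 3L),
    fig8 = realize_profile(profiles$weak),
    core511 = build_B(profiles$core511),
    viola = realize_profile(profiles$viola)
  )
  list(profiles = profiles, networks = networks)
}
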