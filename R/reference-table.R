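#' Published forelimb network parameters for 22 mammalian taxa
#'
#' Summary table of musculoskeletal forelimb network parameters reported in a
#' comparative study of 19 primate genera plus three outgroups (a rodent, a
#' tree shrew and a colugo): nodes (N), links (K), density (D), clustering
#' coefficient (C), characteristic path length (L), degree heterogeneity (H)
#' and number of connectivity modules (M), with D, C, L, H rounded to three
#' decimals as printed. The underlying adjacency matrices are not
#' redistributed here; the table serves as a reference for consistency checks
#' (e.g. the density identity `D = 2K / (N (N - 1))`) and group summaries.
#'
#' @return data frame with columns `taxon`, `group` (one of `"outgroup"`,
#'   `"strepsirrhine"`, `"tarsier"`, `"NWM"`, `"OWM"`, `"hominoid"`), `N`,
#'   `K`, `D`, `C`, `L`, `H`, `M`.
#' @examples
#' tab <- forelimb_parameter_table()
#' all(round_half_up(2 * tab$K / (tab$N * (tab$N - 1)), 3) == tab$D)
#' @export
forelimb_parameter_table <- function() {
  tab <- data.frame(
    taxon = c("Mus musculus", "Tupaia sp.", "Cynocephalus volans",
              "Lemur catta", "Propithecus verreauxi", "Loris tardigradus",
              "Nycticebus pygmaeus", "Tarsius syrichta",
              "Callithrix jacchus", "Saimiri sciureus", "Aotus nancymaae",
              "Pithecia pithecia", "Colobus guereza", "Cercopithecus diana",
              "Papio anubis", "Macaca fascicularis", "Hylobates lar",
              "Pongo pygmaeus", "Gorilla gorilla", "Pan troglodytes",
              "Pan paniscus", "Homo sapiens"),
    group = c("outgroup", "outgroup", "outgroup",
              "strepsirrhine", "strepsirrhine", "strepsirrhine",
              "strepsirrhine", "tarsier",
              "NWM", "NWM", "NWM", "NWM",
              "OWM", "OWM", "OWM", "OWM",
              "hominoid", "hominoid", "hominoid", "hominoid", "hominoid",
              "hominoid"),
    N = c(102L, 98L, 97L, 103L, 102L, 105L, 109L, 109L, 99L, 98L, 99L, 98L,
          103L, 105L, 105L, 105L, 101L, 94L, 92L, 99L, 95L, 94L),
    K = c(220L, 206L, 239L, 224L, 225L, 224L, 233L, 236L, 216L, 216L, 213L,
          215L, 220L, 223L, 228L, 228L, 238L, 223L, 223L, 245L, 217L, 193L),
    D = c(0.043, 0.043, 0.051, 0.043, 0.044, 0.041, 0.040, 0.040, 0.045,
          0.045, 0.044, 0.045, 0.042, 0.041, 0.042, 0.042, 0.047, 0.051,
          0.053, 0.051, 0.049, 0.044),
    C = c(0.338, 0.336, 0.349, 0.420, 0.436, 0.399, 0.416, 0.433, 0.369,
          0.389, 0.377, 0.381, 0.406, 0.418, 0.424, 0.426, 0.382, 0.376,
          0.404, 0.405, 0.423, 0.380),
    L = c(3.274, 3.320, 3.195, 3.338, 3.321, 3.387, 3.409, 3.389, 3.326,
          3.295, 3.355, 3.329, 3.368, 3.387, 3.351, 3.390, 3.320, 3.300,
          3.277, 3.313, 3.296, 3.410),
    H = c(0.964, 0.991, 0.834, 0.928, 0.897, 0.921, 0.940, 0.931, 0.926,
          0.910, 0.922, 0.894, 0.930, 0.953, 0.950, 0.930, 0.827, 0.790,
          0.765, 0.788, 0.845, 0.923),
    M = c(7L, 9L, 8L, 7L, 7L, 11L, 8L, 7L, 5L, 6L, 5L, 4L, 8L, 11L, 11L,
          10L, 8L, 6L, 8L, 11L, 7L, 5L),
    stringsAsFactors = FALSE)
  tab
}
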