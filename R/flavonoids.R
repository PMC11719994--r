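#' Reference flavonoid panel
#'
#' Canonical SMILES for seven well-characterised food-derived phenolics
#' (six flavonoids plus coumarin) that are widely studied as CNS-active
#' natural compounds. Used as embedded fixtures for the BBB scoring
#' regression suite and as handy demo molecules.
#'
#' @return Tibble with `id`, `name` and `smiles` columns.
#' @export
flavonoid_panel <- function() {
  tibble::tribble(
    ~id,                ~name,              ~smiles,
    "coumarin",         "Coumarin",         "O=c1ccc2ccccc2o1",
    "dihydromyricetin", "Dihydromyricetin", "O=C1c2c(O)cc(O)cc2OC(c2cc(O)c(O)c(O)c2)C1O",
    "quercetin",        "Quercetin",        "O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12",
    "kaempferol",       "Kaempferol",       "O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12",
    "luteolin",         "Luteolin",         "O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12",
    "astragalin",       "Astragalin",       "O=c1c(OC2OC(CO)C(O)C(O)C2O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12",
    "apigenin",         "Apigenin",         "O=c1cc(-c2ccc(O)cc2)oc2cc(O)cc(O)c12"
  )
}
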